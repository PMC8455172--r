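#' Configuration for a synthetic scratch-assay dataset
#'
#' Bundles everything needed to generate a synthetic "observed" dataset with
#' known parameters: the generating rates, the lattice geometry, the seeded
#' strip width, the initial phase counts, the experiment duration, the number
#' of tracked cells and the summary blocks to report. Defaults reproduce the
#' experimental study conditions: the 1309.09 x 1745.35 micrometre imaged
#' region, 200 micrometre seeded strips, initial counts 119/35/121
#' (red/yellow/green), 48 h duration and 20 tracked leading-edge red cells.
#'
#' @param theta A [model_params()] vector (must lie inside the prior
#'   support).
#' @param geom A [hex_geometry()].
#' @param strip_width Seeded strip width in micrometres.
#' @param counts Initial `c(n_red, n_yellow, n_green)`.
#' @param duration Hours simulated.
#' @param n_tracked Number of leading-edge red cells to track.
#' @param blocks Summary blocks to compute (see [summary_vector()]).
#' @param label Optional name for the configuration.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(theta,
                             geom = hex_geometry(),
                             strip_width = 200,
                             counts = c(119, 35, 121),
                             duration = 48,
                             n_tracked = 20,
                             blocks = c("counts", "trajectory"),
                             label = NULL) {
  theta <- as_model_params(theta)
  prior <- prior_spec()
  if (!in_prior_support(unclass(theta), prior)) {
    stop("synthetic_config(): theta lies outside the prior support",
         call. = FALSE)
  }
  structure(
    list(theta = theta, geom = geom, strip_width = strip_width,
         counts = as.integer(counts), duration = duration,
         n_tracked = n_tracked,
         blocks = match.arg(blocks, summary_blocks(), several.ok = TRUE),
         label = label),
    class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config>%s theta = (%s), %d/%d/%d cells, %g h, %d tracked, blocks: %s\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              paste(signif(unclass(x$theta), 3), collapse = ", "),
              x$counts[1], x$counts[2], x$counts[3], x$duration, x$n_tracked,
              paste(x$blocks, collapse = "+")))
  invisible(x)
}

#' Reduced-scale lattice geometry for fast studies
#'
#' A domain with one third of the experimental extent in each direction
#' (one ninth of the area), used for desk-scale parameter-recovery studies;
#' initial counts and strip width scale accordingly.
#'
#' @return A [hex_geometry()] of 436.36 x 581.78 micrometres.
#' @export
reduced_geometry <- function() {
  hex_geometry(width = 1309.09 / 3, height = 1745.35 / 3)
}

#' Synthetic configuration on the reduced geometry
#'
#' Convenience wrapper: [synthetic_config()] with [reduced_geometry()],
#' area-scaled initial counts (13/4/13) and strip width (200/3 micrometres).
#'
#' @inheritParams synthetic_config
#' @export
reduced_config <- function(theta, blocks = c("counts", "trajectory"),
                           label = NULL, n_tracked = 20) {
  synthetic_config(theta, geom = reduced_geometry(),
                   strip_width = 200 / 3, counts = c(13, 4, 13),
                   n_tracked = n_tracked, blocks = blocks, label = label)
}

#' Generate a synthetic observed dataset with known parameters
#'
#' Builds the scratch-assay initial condition with [init_random_strips()],
#' selects up to `n_tracked` leading-edge red cells, simulates the model to
#' `duration` and computes the requested summary blocks. Fully reproducible
#' given the seed.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return A list of class `synthetic_dataset` with elements `observed`
#'   (a `summary_vector`), `initial_state`, `tracked` (agent ids), `sim`
#'   (the full `sim_result`) and `config`.
#' @export
generate_synthetic_dataset <- function(config, seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  state <- init_random_strips(config$counts, config$geom, config$strip_width)
  tracked <- integer(0)
  if ("trajectory" %in% config$blocks) {
    tracked <- select_tracked_cells(state, config$n_tracked)
  }
  sim <- simulate_invasion(state, config$theta, duration = config$duration,
                           tracked = tracked)
  observed <- summarize_simulation(sim, blocks = config$blocks)
  structure(
    list(observed = observed, initial_state = state, tracked = tracked,
         sim = sim, config = config),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>\n")
  print(x$config)
  print(x$observed)
  invisible(x)
}

#' Built-in synthetic study configurations
#'
#' The parameter configurations of the synthetic recovery study: a
#' transition-varying family of four (motilities fixed at 4 per hour), a
#' motility-varying family of four (transitions fixed at 0.04/0.17/0.08 per
#' hour, motilities spanning the prior), and the experimental-geometry
#' fixture (initial counts 119/35/121 at the experiment's posterior-mean
#' rates). The two families share their first configuration.
#'
#' @param geom Geometry used for the two families (the fixture always uses
#'   the full experimental geometry). Defaults to [reduced_geometry()] so the
#'   study is desk-scale; pass [hex_geometry()] for the full-size study.
#' @return A named list of [synthetic_config()] objects.
#' @export
builtin_configs <- function(geom = reduced_geometry()) {
  full <- identical(round(geom$width, 2), round(hex_geometry()$width, 2))
  make <- function(theta, label) {
    if (full) {
      synthetic_config(theta, geom = geom, label = label)
    } else {
      reduced_config(theta, label = label)
    }
  }
  transition_family <- list(
    c(0.04, 0.17, 0.08, 4, 4, 4),
    c(0.25, 0.15, 0.22, 4, 4, 4),
    c(0.12, 0.07, 0.03, 4, 4, 4),
    c(0.30, 0.36, 0.28, 4, 4, 4))
  motility_family <- list(
    c(0.04, 0.17, 0.08, 4, 4, 4),
    c(0.04, 0.17, 0.08, 2, 5, 8),
    c(0.04, 0.17, 0.08, 8, 2, 5),
    c(0.04, 0.17, 0.08, 5, 8, 2))
  configs <- c(
    purrr::imap(transition_family,
                function(th, k) make(th, sprintf("transition_%d", k))),
    purrr::imap(motility_family,
                function(th, k) make(th, sprintf("motility_%d", k))),
    list(synthetic_config(wm983c_posterior_means(),
                          geom = hex_geometry(),
                          label = "experimental_fixture")))
  stats::setNames(configs, purrr::map_chr(configs, "label"))
}
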