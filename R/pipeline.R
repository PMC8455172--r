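#' Model simulator closure for ABC
#'
#' Builds the function `theta -> summary_vector` that the SMC-ABC sampler
#' calls once per proposal: each call re-simulates the invasion model from
#' the fixed initial condition (the calibrated or synthetic initial state),
#' tracks the same cells, and returns the requested summary blocks.
#'
#' @param initial_state A `sim_state` at time 0.
#' @param tracked Agent ids to track (required for the `trajectory` block).
#' @param duration Hours simulated per call.
#' @param blocks Summary blocks (see [summary_vector()]).
#' @return A function of a named parameter vector returning a
#'   `summary_vector`.
#' @export
lattice_simulator <- function(initial_state, tracked = integer(0),
                              duration = 48,
                              blocks = c("counts", "trajectory")) {
  stopifnot(inherits(initial_state, "sim_state"))
  blocks <- match.arg(blocks, summary_blocks(), several.ok = TRUE)
  if ("trajectory" %in% blocks && length(tracked) == 0) {
    stop("lattice_simulator(): trajectory summaries need tracked cells",
         call. = FALSE)
  }
  force(duration)
  geom <- initial_state$geom
  row0 <- as.integer(initial_state$agents$i)
  col0 <- as.integer(initial_state$agents$j)
  phase0 <- as.integer(initial_state$agents$phase)
  tracked <- as.integer(tracked)
  n_tracked <- length(tracked)
  mid <- geom$width / 2
  delta <- geom$delta

  # lean path: one sim_core call per proposal, summaries computed without
  # building the full sim_result (identical values to summarize_simulation)
  function(theta) {
    theta <- unclass(as_model_params(theta))
    res <- sim_core(
      row0 = row0, col0 = col0, phase0 = phase0,
      motility = unname(theta[c("M_r", "M_y", "M_g")]),
      transition = unname(theta[c("R_r", "R_y", "R_g")]),
      n_rows = geom$n_rows, n_cols = geom$n_cols,
      duration = duration, tracked_ids = tracked,
      max_events = -1, record_initial = FALSE, record_traj = FALSE)
    vals <- numeric(0)
    valid <- TRUE
    if ("counts" %in% blocks) {
      n <- tabulate(res$phase, nbins = 3)
      vals <- c(vals, N_r = n[1], N_y = n[2], N_g = n[3])
    }
    if ("trajectory" %in% blocks) {
      d <- delta * rowSums(res$tracked_moves) / n_tracked
      vals <- c(vals, d_r = d[1], d_y = d[2], d_g = d[3])
    }
    if ("density" %in% blocks) {
      x <- ifelse(res$row %% 2L == 0L, (res$col - 0.5) * delta,
                  (res$col - 1) * delta)
      dens <- stats::setNames(rep(NA_real_, 12), block_names$density)
      for (p in 1:3) {
        key <- substr(phase_levels()[p], 1, 1)
        for (s in c("L", "R")) {
          xs <- x[res$phase == p & (if (s == "L") x < mid else x >= mid)]
          if (length(xs) > 0) {
            q <- stats::quantile(xs, c(0.25, 0.5, 0.75), names = FALSE,
                                 type = 7)
            dens[sprintf("med_%s_%s", key, s)] <- q[2]
            dens[sprintf("iqr_%s_%s", key, s)] <- q[3] - q[1]
          }
        }
      }
      valid <- all(is.finite(dens))
      vals <- c(vals, dens)
    }
    summary_vector(vals, blocks = blocks, valid = valid)
  }
}

#' Synthetic parameter-recovery run
#'
#' One arm of the synthetic recovery study: generate an observed dataset
#' under known rates, run the SMC-ABC sampler against it with the same
#' initial condition, and apply regression adjustment. The returned fit
#' carries the generating `theta` so coverage can be checked.
#'
#' @param config A [synthetic_config()].
#' @param n_particles,alpha,c_tune,f_acc,max_sims SMC settings passed to
#'   [run_smc_abc()].
#' @param seed Integer seed controlling both dataset generation and the
#'   sampler.
#' @param verbose Print per-round diagnostics.
#' @return A list of class `recovery_run` with `dataset`, `fit`, `adjusted`
#'   (tibble of adjusted draws) and `truth`.
#' @export
recover_parameters <- function(config, n_particles = 200, alpha = 0.5,
                               c_tune = 0.01, f_acc = 0.01, max_sims = Inf,
                               seed = 1, verbose = FALSE) {
  dataset <- generate_synthetic_dataset(config, seed = seed)
  simulator <- lattice_simulator(dataset$initial_state, dataset$tracked,
                                 duration = config$duration,
                                 blocks = config$blocks)
  fit <- run_smc_abc(dataset$observed, simulator,
                     prior = prior_spec(), n_particles = n_particles,
                     alpha = alpha, c_tune = c_tune, f_acc = f_acc,
                     max_sims = max_sims, seed = seed + 1L, verbose = verbose)
  adjusted <- regression_adjust(fit)
  structure(
    list(dataset = dataset, fit = fit, adjusted = adjusted,
         truth = config$theta),
    class = "recovery_run")
}

#' @export
print.recovery_run <- function(x, ...) {
  cat("<recovery_run>\n")
  print(x$dataset$config)
  summ <- posterior_summaries(x$adjusted)
  summ$truth <- as.numeric(unclass(x$truth)[summ$param])
  summ$covered <- summ$truth >= summ$q2.5 & summ$truth <= summ$q97.5
  print(summ)
  invisible(x)
}

#' Credible-interval coverage of a recovery run
#'
#' @param run A `recovery_run`.
#' @param level Credible level (only 0.95 via the 2.5/97.5% quantiles).
#' @return A tibble with `param`, `truth`, `q2.5`, `q97.5`, `covered`.
#' @export
recovery_coverage <- function(run, level = 0.95) {
  stopifnot(inherits(run, "recovery_run"), level == 0.95)
  summ <- posterior_summaries(run$adjusted)
  summ$truth <- as.numeric(unclass(run$truth)[summ$param])
  dplyr::transmute(summ, .data$param, .data$truth, .data$q2.5, .data$q97.5,
                   covered = .data$truth >= .data$q2.5 &
                     .data$truth <= .data$q97.5)
}
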