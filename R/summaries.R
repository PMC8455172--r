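#' @name summaries
#' @title Summary statistics of an invasion experiment
#'
#' @description Three blocks of summary statistics are available, mirroring
#' what can be read off a processed scratch-assay experiment at 48 h:
#' \describe{
#'   \item{counts}{the number of red, yellow and green cells at the end of
#'     the experiment (informative about the transition rates);}
#'   \item{trajectory}{the mean distance travelled through each phase by the
#'     tracked cells, in micrometres (informative about the motility rates);}
#'   \item{density}{the median x-position and interquartile range of each
#'     colour on the left and right side of the scratch, in micrometres.}
#' }
NULL

summary_blocks <- function() c("counts", "trajectory", "density")

block_names <- list(
  counts = c("N_r", "N_y", "N_g"),
  trajectory = c("d_r", "d_y", "d_g"),
  density = c("med_r_L", "med_r_R", "med_y_L", "med_y_R", "med_g_L", "med_g_R",
              "iqr_r_L", "iqr_r_R", "iqr_y_L", "iqr_y_R", "iqr_g_L", "iqr_g_R")
)

#' Construct a summary-statistic vector
#'
#' Packs named statistics into a `summary_vector` with an explicit block
#' structure so that observed and simulated summaries can be compared by
#' [abc_discrepancy()]. Invalid vectors (e.g. a density block where one
#' colour is absent from one side) compare at infinite discrepancy.
#'
#' @param values Named numeric vector covering the requested blocks.
#' @param blocks Character subset of `"counts"`, `"trajectory"`, `"density"`.
#' @param valid Logical; `FALSE` marks the vector unusable.
#' @return A `summary_vector`.
#' @export
summary_vector <- function(values, blocks = c("counts", "trajectory"),
                           valid = TRUE) {
  blocks <- match.arg(blocks, summary_blocks(), several.ok = TRUE)
  wanted <- unlist(block_names[blocks], use.names = FALSE)
  missing <- setdiff(wanted, names(values))
  if (length(missing) > 0 && valid) {
    stop("summary_vector(): missing statistics: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- stats::setNames(rep(NA_real_, length(wanted)), wanted)
  vals[intersect(wanted, names(values))] <-
    as.numeric(values[intersect(wanted, names(values))])
  structure(vals, blocks = blocks, valid = isTRUE(valid) && all(is.finite(vals)),
            class = c("summary_vector", "numeric"))
}

#' @export
print.summary_vector <- function(x, ...) {
  cat(sprintf("<summary_vector> blocks: %s%s\n",
              paste(attr(x, "blocks"), collapse = " + "),
              if (attr(x, "valid")) "" else " [INVALID]"))
  print(round(unclass(x), 2))
  invisible(x)
}

#' Phase counts at the end of the experiment
#'
#' @param state A `sim_state`.
#' @return Named numeric `c(N_r, N_y, N_g)`.
#' @export
count_summaries <- function(state) {
  stopifnot(inherits(state, "sim_state"))
  tab <- table(factor(state$agents$phase, levels = phase_levels()))
  c(N_r = unname(tab[["red"]]), N_y = unname(tab[["yellow"]]),
    N_g = unname(tab[["green"]]))
}

#' Mean distance travelled through each phase by tracked cells
#'
#' For each tracked cell the cumulative path length (the sum of Euclidean
#' distances between consecutive recorded positions; every lattice move
#' contributes one site diameter) is accumulated separately while the cell is
#' in each phase, from the start of tracking until the cell divides or the
#' simulation ends. The summary is the mean over cells per phase; a phase a
#' cell never reached contributes zero for that cell.
#'
#' @param trajectories Tibble with columns `cell_id`, `t_h`, `x_um`, `y_um`,
#'   `phase` (as produced by [simulate_invasion()]).
#' @return Named numeric `c(d_r, d_y, d_g)` in micrometres.
#' @export
trajectory_summaries <- function(trajectories) {
  trajectories <- tibble::as_tibble(trajectories)
  if (nrow(trajectories) == 0 || length(unique(trajectories$cell_id)) == 0) {
    stop("trajectory_summaries(): no trajectory records", call. = FALSE)
  }
  per_cell <- trajectories |>
    dplyr::arrange(.data$cell_id, .data$t_h) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::mutate(
      step = sqrt((.data$x_um - dplyr::lag(.data$x_um))^2 +
                    (.data$y_um - dplyr::lag(.data$y_um))^2),
      # a segment is travelled in the phase the cell held before arriving
      step_phase = dplyr::lag(.data$phase)) |>
    dplyr::filter(!is.na(.data$step)) |>
    dplyr::group_by(.data$cell_id, .data$step_phase) |>
    dplyr::summarise(dist = sum(.data$step), .groups = "drop")
  n_cells <- length(unique(trajectories$cell_id))
  out <- vapply(phase_levels(), function(p) {
    sum(per_cell$dist[per_cell$step_phase == p]) / n_cells
  }, numeric(1))
  stats::setNames(out, c("d_r", "d_y", "d_g"))
}

#' Left/right density summaries of the cell positions
#'
#' Splits the domain down the vertical midline and, for each colour on each
#' side, computes the median and interquartile range (75th minus 25th
#' percentile, linear interpolation) of the x-positions in micrometres.
#'
#' @param state A `sim_state`.
#' @return Named numeric of 12 values (`med_r_L`, `med_r_R`, ..., `iqr_g_R`),
#'   with attribute `valid = FALSE` when any colour is absent from a side.
#' @export
density_summaries <- function(state) {
  stopifnot(inherits(state, "sim_state"))
  pos <- state_positions(state)
  mid <- state$geom$width / 2
  out <- stats::setNames(rep(NA_real_, 12), block_names$density)
  for (p in phase_levels()) {
    for (s in c("L", "R")) {
      x <- pos$x[pos$phase == p & (if (s == "L") pos$x < mid else pos$x >= mid)]
      key <- substr(p, 1, 1)
      if (length(x) > 0) {
        out[sprintf("med_%s_%s", key, s)] <- stats::median(x)
        q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
        out[sprintf("iqr_%s_%s", key, s)] <- q[2] - q[1]
      }
    }
  }
  attr(out, "valid") <- all(is.finite(out))
  out
}

#' Summarise a simulation into a summary vector
#'
#' @param sim A `sim_result` from [simulate_invasion()], or a `sim_state`
#'   when only the `counts`/`density` blocks are requested.
#' @param blocks Blocks to include; see [summary_vector()].
#' @return A `summary_vector`.
#' @export
summarize_simulation <- function(sim, blocks = c("counts", "trajectory")) {
  blocks <- match.arg(blocks, summary_blocks(), several.ok = TRUE)
  state <- if (inherits(sim, "sim_result")) sim$final_state else sim
  vals <- numeric(0)
  valid <- TRUE
  if ("counts" %in% blocks) vals <- c(vals, count_summaries(state))
  if ("trajectory" %in% blocks) {
    stopifnot(inherits(sim, "sim_result"))
    vals <- c(vals, trajectory_summaries(sim$trajectories))
  }
  if ("density" %in% blocks) {
    dens <- density_summaries(state)
    valid <- valid && isTRUE(attr(dens, "valid"))
    vals <- c(vals, dens)
  }
  summary_vector(vals, blocks = blocks, valid = valid)
}

#' ABC discrepancy between two summary vectors
#'
#' The unweighted Euclidean norm of the difference over the concatenated
#' blocks. The two vectors must carry identical block structure; if either is
#' invalid the discrepancy is `Inf` (the proposal is always rejected).
#'
#' @param s_sim,s_obs `summary_vector`s with matching blocks.
#' @return A non-negative number (possibly `Inf`).
#' @export
abc_discrepancy <- function(s_sim, s_obs) {
  stopifnot(inherits(s_sim, "summary_vector"), inherits(s_obs, "summary_vector"))
  if (!identical(attr(s_sim, "blocks"), attr(s_obs, "blocks"))) {
    stop("abc_discrepancy(): summary vectors have different block structure",
         call. = FALSE)
  }
  if (!attr(s_sim, "valid") || !attr(s_obs, "valid")) return(Inf)
  sqrt(sum((unclass(s_sim) - unclass(s_obs))^2))
}
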