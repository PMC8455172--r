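#' Classify FUCCI phase from RGB decimal codes
#'
#' Applies the channel-threshold rule used to recover cell-cycle phases from
#' processed microscopy frames: red channel > 100 with green <= 100 is G1
#' (red); both channels > 100 is eS (yellow); red <= 100 with green > 100 is
#' S/G2/M (green). Records matching no rule (both channels <= 100) are
#' unclassified and dropped with a warning.
#'
#' @param records A data frame with numeric columns `red` and `green`
#'   (0-255).
#' @return The input tibble with a `phase` factor column added and
#'   unclassified rows removed; the number of drops is recorded in the
#'   `n_unclassified` attribute.
#' @examples
#' classify_phase_rgb(data.frame(red = c(150, 150, 50), green = c(50, 150, 150)))
#' @export
classify_phase_rgb <- function(records) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("red", "green") %in% names(records)))
  r <- records$red; g <- records$green
  if (any(r < 0 | r > 255 | g < 0 | g > 255, na.rm = TRUE)) {
    stop("classify_phase_rgb(): channel values must lie in [0, 255]",
         call. = FALSE)
  }
  phase <- dplyr::case_when(
    r > 100 & g <= 100 ~ "red",
    r > 100 & g > 100 ~ "yellow",
    r <= 100 & g > 100 ~ "green",
    TRUE ~ NA_character_)
  n_drop <- sum(is.na(phase))
  if (n_drop > 0) {
    warning(sprintf("classify_phase_rgb(): dropped %d unclassified record(s)",
                    n_drop), call. = FALSE)
  }
  out <- records[!is.na(phase), ]
  out$phase <- as_phase(phase[!is.na(phase)])
  attr(out, "n_unclassified") <- n_drop
  out
}

#' Read and write cell-position tables
#'
#' Positions CSV dialect: UTF-8, header row, '.' decimal separator; columns
#' `x_um`, `y_um` (micrometres) and `phase` (red/yellow/green).
#'
#' @param path File path.
#' @return `read_positions_csv()` returns a tibble with columns `x_um`,
#'   `y_um`, `phase`.
#' @export
read_positions_csv <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("x_um", "y_um", "phase") %in% names(tb)))
  tb$phase <- as_phase(tb$phase)
  tb[c("x_um", "y_um", "phase")]
}

#' @param state A `sim_state` (its agent positions are written).
#' @rdname read_positions_csv
#' @export
write_positions_csv <- function(state, path) {
  pos <- state_positions(state)
  readr::write_csv(
    tibble::tibble(x_um = pos$x, y_um = pos$y, phase = as.character(pos$phase)),
    path)
  invisible(path)
}

#' Write tracked-cell trajectories to CSV
#'
#' Columns `cell_id`, `t_h`, `x_um`, `y_um`, `phase`.
#'
#' @param trajectories Trajectory tibble from [simulate_invasion()].
#' @param path File path.
#' @export
write_trajectory_csv <- function(trajectories, path) {
  out <- tibble::as_tibble(trajectories)
  out$phase <- as.character(out$phase)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read and write summary-statistic tables
#'
#' One row per dataset/simulation; columns are the named summary statistics
#' of the included blocks (`N_r` ... `iqr_g_R`).
#'
#' @param s A `summary_vector` (write) / file path (read).
#' @param path File path.
#' @param blocks Blocks expected when reading.
#' @return `read_summary_csv()` returns a `summary_vector`.
#' @export
write_summary_csv <- function(s, path) {
  stopifnot(inherits(s, "summary_vector"))
  readr::write_csv(tibble::as_tibble(as.list(unclass(s))), path)
  invisible(path)
}

#' @rdname write_summary_csv
#' @export
read_summary_csv <- function(path, blocks = NULL) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(tb) != 1) {
    stop("read_summary_csv(): expected exactly one row in ", path,
         call. = FALSE)
  }
  vals <- unlist(tb[1, ])
  if (is.null(blocks)) {
    blocks <- names(block_names)[purrr::map_lgl(block_names,
                                                ~ all(.x %in% names(vals)))]
  }
  summary_vector(vals, blocks = blocks)
}

#' Load an observed dataset from processed experiment exports
#'
#' Ingests the coordinate tables produced by microscopy image processing and
#' assembles the two objects the inference pipeline needs: the initial
#' simulation state (cells snapped onto the lattice, duplicates omitted) and
#' the observed summary vector. Positions may carry an explicit `phase`
#' column or RGB channel columns (`red`, `green`), in which case phases are
#' classified with [classify_phase_rgb()]. Observed summaries are either read
#' from a one-row summary CSV or computed from a final-frame position table.
#'
#' @param positions Path to the initial-frame positions CSV (columns `x_um`,
#'   `y_um` and `phase`, or `x_um`, `y_um`, `red`, `green`).
#' @param summaries Optional path to a one-row summary CSV.
#' @param final_frame Optional path to a final-frame positions CSV from which
#'   `counts`/`density` summaries are computed when no summary CSV is given.
#' @param geom A [hex_geometry()].
#' @param blocks Summary blocks to load/compute.
#' @return A list with `state` (initial `sim_state`) and `observed`
#'   (a `summary_vector`, `NULL` when neither summary source is given).
#' @export
load_observed <- function(positions, summaries = NULL, final_frame = NULL,
                          geom = hex_geometry(),
                          blocks = c("counts", "trajectory")) {
  read_pos <- function(path) {
    tb <- readr::read_csv(path, show_col_types = FALSE)
    if (!all(c("x_um", "y_um") %in% names(tb))) {
      stop("load_observed(): ", path, " lacks x_um/y_um columns", call. = FALSE)
    }
    if (!"phase" %in% names(tb)) {
      if (!all(c("red", "green") %in% names(tb))) {
        stop("load_observed(): ", path,
             " needs either a phase column or red/green RGB columns",
             call. = FALSE)
      }
      tb <- classify_phase_rgb(tb)
    }
    tb$phase <- as_phase(tb$phase)
    tb
  }
  state <- init_from_positions(read_pos(positions), geom)
  observed <- NULL
  if (!is.null(summaries)) {
    observed <- read_summary_csv(summaries, blocks = blocks)
  } else if (!is.null(final_frame)) {
    final_state <- init_from_positions(read_pos(final_frame), geom)
    observed <- summarize_simulation(final_state,
                                     blocks = intersect(blocks,
                                                        c("counts", "density")))
  }
  list(state = state, observed = observed)
}

#' Snap tracked-trajectory starting points to occupied sites
#'
#' Manually tracked starting coordinates are often slightly off-centre and
#' can land on an empty lattice site; each point is therefore mapped to the
#' occupied site minimising the Euclidean distance to it, ties broken by
#' (row, column) lexicographic order.
#'
#' @param points Data frame with columns `x`, `y` (or `x_um`, `y_um`).
#' @param state A non-empty `sim_state`.
#' @return A tibble with columns `i`, `j`, `id` (agent), `x`, `y` (site
#'   centre).
#' @export
snap_trajectory_starts <- function(points, state) {
  stopifnot(inherits(state, "sim_state"), nrow(state$agents) > 0)
  points <- tibble::as_tibble(points)
  if ("x_um" %in% names(points)) points <- dplyr::rename(points, x = "x_um")
  if ("y_um" %in% names(points)) points <- dplyr::rename(points, y = "y_um")
  occ <- state_positions(state)
  purrr::pmap_dfr(points[c("x", "y")], function(x, y) {
    d2 <- (occ$x - x)^2 + (occ$y - y)^2
    best <- which(d2 == min(d2))
    if (length(best) > 1) {
      best <- best[order(occ$i[best], occ$j[best])][1]
    }
    tibble::tibble(i = occ$i[best], j = occ$j[best], id = occ$id[best],
                   x = occ$x[best], y = occ$y[best])
  })
}

#' Write an SMC-ABC particle population to CSV
#'
#' One row per particle: the parameter columns, the discrepancy `rho` and
#' the stored simulated summaries (`S_*` columns). When the fit is written
#' together with `adjusted = TRUE`, the regression-adjusted sample is
#' written alongside with an `_adjusted` suffix.
#'
#' @param fit An `smc_abc_fit`.
#' @param path Output CSV path.
#' @param adjusted Also write the adjusted sample next to `path`.
#' @return The path(s) written, invisibly.
#' @export
write_particles_csv <- function(fit, path, adjusted = FALSE) {
  stopifnot(inherits(fit, "smc_abc_fit"))
  readr::write_csv(fit$particles, path)
  paths <- path
  if (adjusted) {
    adj_path <- sub("(\\.[^.]+)?$", "_adjusted\\1", path)
    if (identical(adj_path, path)) adj_path <- paste0(path, "_adjusted")
    readr::write_csv(regression_adjust(fit), adj_path)
    paths <- c(paths, adj_path)
  }
  invisible(paths)
}
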