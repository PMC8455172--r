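#' @importFrom rlang .data
NULL

phase_levels <- function() c("red", "yellow", "green")

as_phase <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) x <- phase_levels()[x]
  x <- tolower(as.character(x))
  if (!all(x %in% phase_levels())) {
    stop("phase must be one of 'red', 'yellow', 'green'", call. = FALSE)
  }
  factor(x, levels = phase_levels())
}

new_sim_state <- function(agents, geom, time = 0, n_omitted = 0L) {
  stopifnot(inherits(geom, "hex_geometry"))
  agents <- tibble::as_tibble(agents)
  structure(
    list(agents = agents, geom = geom, time = time,
         n_omitted = as.integer(n_omitted)),
    class = "sim_state"
  )
}

#' @export
print.sim_state <- function(x, ...) {
  counts <- table(factor(x$agents$phase, levels = phase_levels()))
  cat(sprintf(
    "<sim_state> t = %.2f h, %d agents (%d red, %d yellow, %d green) on %d x %d lattice\n",
    x$time, nrow(x$agents), counts[["red"]], counts[["yellow"]],
    counts[["green"]], x$geom$n_rows, x$geom$n_cols))
  if (x$n_omitted > 0) {
    cat(sprintf("  %d input cell(s) omitted (duplicate lattice sites)\n",
                x$n_omitted))
  }
  invisible(x)
}

check_exclusion <- function(state) {
  !anyDuplicated(state$agents[c("i", "j")]) &&
    all(in_domain(state$agents$i, state$agents$j, state$geom))
}

#' Agent positions of a simulation state as a tibble
#'
#' @param state A `sim_state`.
#' @return A tibble with columns `id`, `i`, `j`, `x`, `y`, `phase`.
#' @export
state_positions <- function(state) {
  stopifnot(inherits(state, "sim_state"))
  xy <- site_to_xy(state$agents, state$geom)
  dplyr::mutate(state$agents, x = xy$x, y = xy$y,
                .after = "j")
}

#' Initialise a simulation state from cell coordinates
#'
#' Snaps each cell (micrometre coordinates plus FUCCI phase) onto the nearest
#' lattice site via [xy_to_site()]. When several cells map to the same site
#' the first is kept and the rest are omitted (rather than displaced to the
#' next closest site); the omission count is recorded in the state and
#' reported with a message.
#'
#' @param cells A data frame with columns `x_um`, `y_um` (or `x`, `y`) and
#'   `phase` (red/yellow/green).
#' @param geom A [hex_geometry()].
#' @return A `sim_state` at time 0 satisfying the one-agent-per-site
#'   exclusion property.
#' @examples
#' cells <- data.frame(x_um = c(0, 20), y_um = c(17.3, 17.3),
#'                     phase = c("red", "green"))
#' init_from_positions(cells, hex_geometry())
#' @export
init_from_positions <- function(cells, geom) {
  cells <- tibble::as_tibble(cells)
  if ("x_um" %in% names(cells)) cells <- dplyr::rename(cells, x = "x_um")
  if ("y_um" %in% names(cells)) cells <- dplyr::rename(cells, y = "y_um")
  if (nrow(cells) == 0) {
    agents <- tibble::tibble(id = integer(), i = integer(), j = integer(),
                             phase = as_phase(character()))
    return(new_sim_state(agents, geom))
  }
  stopifnot(all(c("x", "y", "phase") %in% names(cells)))
  snapped <- xy_to_site(cells[c("x", "y")], geom)
  agents <- tibble::tibble(i = snapped$i, j = snapped$j,
                           phase = as_phase(cells$phase))
  dup <- duplicated(agents[c("i", "j")])
  if (any(dup)) {
    message(sprintf("init_from_positions(): omitted %d cell(s) mapping to already-occupied sites",
                    sum(dup)))
  }
  agents <- agents[!dup, ]
  agents <- dplyr::mutate(agents, id = dplyr::row_number(), .before = 1)
  new_sim_state(agents, geom, n_omitted = sum(dup))
}

#' Initialise a scratch-assay state with randomly seeded strips
#'
#' Emulates the initial condition of a scratch assay: cells are placed
#' uniformly at random (without replacement) on the lattice sites of two
#' vertical strips of width `strip_width` abutting the left and right domain
#' edges, leaving the central gap (the scratch) empty. The requested numbers
#' of red, yellow and green cells are assigned to the chosen sites uniformly
#' at random.
#'
#' @param counts Integer vector `c(n_red, n_yellow, n_green)`.
#' @param geom A [hex_geometry()].
#' @param strip_width Width in micrometres of each seeded strip.
#' @return A `sim_state` at time 0.
#' @examples
#' set.seed(1)
#' init_random_strips(c(119, 35, 121), hex_geometry())
#' @export
init_random_strips <- function(counts, geom, strip_width = 200) {
  stopifnot(length(counts) == 3, all(counts >= 0), strip_width > 0)
  counts <- as.integer(counts)
  total <- sum(counts)
  sites <- strip_sites(geom, strip_width)
  if (total > nrow(sites)) {
    stop(sprintf("init_random_strips(): %d cells requested but the strips hold only %d sites",
                 total, nrow(sites)), call. = FALSE)
  }
  if (total == 0) {
    agents <- tibble::tibble(id = integer(), i = integer(), j = integer(),
                             phase = as_phase(character()))
    return(new_sim_state(agents, geom))
  }
  pick <- sites[sample.int(nrow(sites), total), ]
  phases <- sample(rep(phase_levels(), times = counts))
  agents <- tibble::tibble(id = seq_len(total), i = pick$i, j = pick$j,
                           phase = as_phase(phases))
  new_sim_state(agents, geom)
}

# all lattice sites whose centre x lies within strip_width of either
# vertical domain edge
strip_sites <- function(geom, strip_width) {
  grid <- tidyr::expand_grid(i = seq_len(geom$n_rows), j = seq_len(geom$n_cols))
  xy <- site_to_xy(grid, geom)
  dplyr::filter(xy, .data$x <= strip_width | .data$x >= geom$width - strip_width)
}

#' Select leading-edge red cells for trajectory tracking
#'
#' Tracked cells must start in the red (G1) phase and sit on the leading edge
#' of the monolayer: within its lattice row, no other agent lies strictly
#' between the cell and the vertical midline of the domain. When more than
#' `n_cells` qualify, the `n_cells` nearest the midline are taken (ties broken
#' by row index); when fewer qualify, all are returned with a warning.
#'
#' @param state A `sim_state`.
#' @param n_cells Number of cells to track.
#' @return Integer vector of agent ids.
#' @export
select_tracked_cells <- function(state, n_cells = 20) {
  stopifnot(inherits(state, "sim_state"), n_cells >= 1)
  pos <- state_positions(state)
  if (!any(pos$phase == "red")) {
    stop("select_tracked_cells(): no red agents in the state", call. = FALSE)
  }
  mid <- state$geom$width / 2
  leading <- pos |>
    dplyr::mutate(side = ifelse(.data$x < mid, "left", "right"),
                  gap_dist = abs(.data$x - mid)) |>
    dplyr::group_by(.data$i, .data$side) |>
    dplyr::filter(.data$gap_dist == min(.data$gap_dist)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$phase == "red") |>
    dplyr::arrange(.data$gap_dist, .data$i)
  if (nrow(leading) < n_cells) {
    warning(sprintf("select_tracked_cells(): only %d leading-edge red cell(s) available (%d requested)",
                    nrow(leading), n_cells), call. = FALSE)
    return(leading$id)
  }
  leading$id[seq_len(n_cells)]
}
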