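#' Simulate the stochastic invasion model
#'
#' Runs the continuous-time Markov process (Gillespie algorithm) from an
#' initial state: per-phase movement attempts at rates `M_r, M_y, M_g` and
#' cell-cycle events at rates `R_r, R_y, R_g` per hour. Movement picks one of
#' the six neighbouring sites uniformly and is aborted if the target is
#' occupied or outside the domain (zero-net-flux boundaries); red-to-yellow
#' and yellow-to-green transitions are unconditional; a green cell divides by
#' placing a red daughter on a uniformly chosen neighbour and itself
#' returning to red, the whole event being aborted if the chosen site is
#' unavailable. Aborted attempts still consume simulation time.
#'
#' Randomness comes from R's global RNG stream: set a seed (or pass `seed`)
#' for bit-reproducible runs.
#'
#' @param state Initial `sim_state` (see [init_random_strips()],
#'   [init_from_positions()]).
#' @param params A [model_params()] vector.
#' @param duration Simulated time in hours.
#' @param tracked Integer ids of cells whose trajectories are recorded
#'   (every successful move and phase change, starting from the position at
#'   time 0). Tracking of a cell stops when it divides (returns to red) or at
#'   the end of the simulation.
#' @param seed Optional integer seed applied via [set.seed()] before
#'   simulating.
#' @return An object of class `sim_result`: a list with elements
#'   `final_state` (a `sim_state` at `duration`), `trajectories` (tibble
#'   `cell_id`, `t_h`, `x_um`, `y_um`, `phase`), `tracked` (tibble `cell_id`,
#'   `termination`), and `event_counts` (named numeric).
#' @examples
#' set.seed(1)
#' st <- init_random_strips(c(10, 3, 10), hex_geometry(436, 582))
#' sim <- simulate_invasion(st, model_params(0.04, 0.17, 0.08, 4, 4, 4),
#'                          duration = 6)
#' sim$final_state
#' @export
simulate_invasion <- function(state, params, duration = 48,
                              tracked = integer(0), seed = NULL) {
  stopifnot(inherits(state, "sim_state"), duration > 0)
  params <- as_model_params(params)
  if (!is.null(seed)) set.seed(seed)
  geom <- state$geom
  res <- sim_core(
    row0 = state$agents$i, col0 = state$agents$j,
    phase0 = as.integer(state$agents$phase),
    motility = unname(unclass(params)[c("M_r", "M_y", "M_g")]),
    transition = unname(unclass(params)[c("R_r", "R_y", "R_g")]),
    n_rows = geom$n_rows, n_cols = geom$n_cols,
    duration = duration, tracked_ids = as.integer(tracked),
    max_events = -1, record_initial = TRUE)
  build_sim_result(res, state, duration, tracked)
}

build_sim_result <- function(res, state, duration, tracked) {
  geom <- state$geom
  agents <- tibble::tibble(
    id = seq_along(res$row), i = res$row, j = res$col,
    phase = as_phase(res$phase))
  final_state <- new_sim_state(agents, geom, time = res$time)

  if (length(res$traj_id) > 0) {
    xy <- site_to_xy(data.frame(i = res$traj_row, j = res$traj_col), geom)
    traj <- tibble::tibble(
      cell_id = res$traj_id, t_h = res$traj_t,
      x_um = xy$x, y_um = xy$y, phase = as_phase(res$traj_phase))
  } else {
    traj <- tibble::tibble(cell_id = integer(), t_h = numeric(),
                           x_um = numeric(), y_um = numeric(),
                           phase = as_phase(character()))
  }
  tracked_tbl <- tibble::tibble(
    cell_id = as.integer(tracked),
    termination = ifelse(res$tracked_divided == 1, "divided", "simulation_end"))

  structure(
    list(final_state = final_state, trajectories = traj,
         tracked = tracked_tbl, event_counts = res$counts,
         n_events = res$n_events, duration = duration),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %.1f h, %.0f events\n", x$duration, x$n_events))
  print(x$final_state)
  if (nrow(x$tracked) > 0) {
    cat(sprintf("  %d tracked trajectories (%d ended by division)\n",
                nrow(x$tracked), sum(x$tracked$termination == "divided")))
  }
  invisible(x)
}

#' Execute a single Gillespie event
#'
#' Advances the state by one event of the continuous-time Markov process and
#' reports what happened. Useful for stepwise inspection and for validating
#' the event law; [simulate_invasion()] runs the same core to a fixed
#' duration.
#'
#' @param state A `sim_state`.
#' @param params A [model_params()] vector.
#' @param max_time Time horizon: if the exponential waiting time would pass
#'   it, no event is applied.
#' @return A list with `state` (updated `sim_state`), `event` (one of
#'   `"move_success"`, `"move_aborted"`, `"red_to_yellow"`,
#'   `"yellow_to_green"`, `"division_success"`, `"division_aborted"`,
#'   `"none"`), `dt` (waiting time in hours, `NA` if no event) and
#'   `exhausted` (`TRUE` when the total event rate is zero).
#' @export
gillespie_step <- function(state, params, max_time = Inf) {
  stopifnot(inherits(state, "sim_state"))
  params <- as_model_params(params)
  geom <- state$geom
  res <- sim_core(
    row0 = state$agents$i, col0 = state$agents$j,
    phase0 = as.integer(state$agents$phase),
    motility = unname(unclass(params)[c("M_r", "M_y", "M_g")]),
    transition = unname(unclass(params)[c("R_r", "R_y", "R_g")]),
    n_rows = geom$n_rows, n_cols = geom$n_cols,
    duration = if (is.finite(max_time)) max_time else .Machine$double.xmax,
    tracked_ids = integer(0), max_events = 1, record_initial = FALSE)
  agents <- tibble::tibble(
    id = seq_along(res$row), i = res$row, j = res$col,
    phase = as_phase(res$phase))
  event_names <- c("move_success", "move_aborted", "red_to_yellow",
                   "yellow_to_green", "division_success", "division_aborted")
  applied <- res$n_events >= 1
  list(
    state = new_sim_state(agents, geom, time = state$time + ifelse(applied, res$last_dt, 0)),
    event = if (applied) event_names[res$last_event] else "none",
    dt = if (applied) res$last_dt else NA_real_,
    exhausted = isTRUE(res$exhausted))
}
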