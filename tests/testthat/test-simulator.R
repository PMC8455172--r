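test_that("initialisation from coordinates snaps, deduplicates and preserves phases", {
  g <- hex_geometry()
  expect_equal(nrow(init_from_positions(data.frame(x_um = numeric(),
                                                   y_um = numeric(),
                                                   phase = character()),
                                        g)$agents), 0L)

  # two cells mapping to one site: first kept, second omitted
  two <- data.frame(x_um = c(0, 1), y_um = c(10 * sqrt(3), 10 * sqrt(3)),
                    phase = c("red", "green"))
  expect_message(st <- init_from_positions(two, g), "omitted 1")
  expect_equal(nrow(st$agents), 1L)
  expect_equal(st$n_omitted, 1L)
  expect_equal(as.character(st$agents$phase), "red")

  # many cells on distinct sites: counts by phase preserved
  set.seed(7)
  grid <- expand.grid(i = seq_len(g$n_rows), j = seq_len(g$n_cols))
  pick <- grid[sample.int(nrow(grid), 275), ]
  xy <- site_to_xy(pick, g)
  phases <- sample(rep(c("red", "yellow", "green"), c(119, 35, 121)))
  st <- init_from_positions(data.frame(x_um = xy$x, y_um = xy$y,
                                       phase = phases), g)
  expect_equal(nrow(st$agents), 275L)
  expect_equal(unname(count_summaries(st)), c(119, 35, 121))
  expect_true(fucciabc:::check_exclusion(st))
})

test_that("random strip seeding fills only the two edge strips with the requested counts", {
  g <- hex_geometry()
  set.seed(3)
  st <- init_random_strips(c(119, 35, 121), g, strip_width = 200)
  expect_equal(nrow(st$agents), 275L)
  expect_equal(unname(count_summaries(st)), c(119, 35, 121))
  pos <- state_positions(st)
  expect_true(all(pos$x <= 200 | pos$x >= g$width - 200))
  expect_true(fucciabc:::check_exclusion(st))

  # determinism
  set.seed(99); a <- init_random_strips(c(10, 5, 5), g)
  set.seed(99); b <- init_random_strips(c(10, 5, 5), g)
  expect_identical(a$agents, b$agents)

  expect_equal(nrow(init_random_strips(c(0, 0, 0), g)$agents), 0L)
  small <- hex_geometry(width = 100, height = 60)
  expect_error(init_random_strips(c(1000, 0, 0), small, 30), "only")
})

test_that("a single Gillespie event follows the per-class rate law", {
  g <- hex_geometry(width = 200, height = 180)
  st <- init_from_positions(data.frame(x_um = 80, y_um = 80, phase = "red"), g)

  # no rates, no events
  none <- gillespie_step(st, model_params(0, 0, 0, 0, 0, 0))
  expect_equal(none$event, "none")
  expect_true(none$exhausted)

  # one red agent with M_r = R_r = 1: next event is a transition w.p. 1/2
  set.seed(123)
  p <- model_params(1, 0, 0, 1, 0, 0)
  events <- replicate(2000, gillespie_step(st, p)$event)
  expect_true(all(events %in% c("move_success", "move_aborted",
                                "red_to_yellow")))
  frac_trans <- mean(events == "red_to_yellow")
  expect_equal(frac_trans, 0.5, tolerance = 0.05)
  # waiting times are Exponential(rate 2): mean 0.5 h
  set.seed(124)
  dts <- replicate(2000, gillespie_step(st, p)$dt)
  expect_equal(mean(dts), 0.5, tolerance = 0.05)
})

test_that("division aborts under full crowding and never breaks exclusion", {
  g <- hex_geometry(width = 200, height = 180)
  centre <- data.frame(i = 5, j = 5)
  nb <- hex_neighbours(5, 5, g)
  xy <- site_to_xy(rbind(centre, nb), g)
  cells <- data.frame(x_um = xy$x, y_um = xy$y,
                      phase = c("green", rep("red", 6)))
  st <- init_from_positions(cells, g)
  # only the green centre has positive rates; every division attempt is
  # blocked by the occupied ring
  sim <- simulate_invasion(st, model_params(0, 0, 1, 0, 0, 0),
                           duration = 20, seed = 5)
  expect_equal(nrow(sim$final_state$agents), 7L)
  expect_gt(sim$event_counts[["division_aborted"]], 0)
  expect_equal(sim$event_counts[["division_success"]], 0)
  expect_equal(sum(sim$final_state$agents$phase == "green"), 1L)
  expect_true(fucciabc:::check_exclusion(sim$final_state))
})

test_that("zero rates leave the state untouched for the whole duration", {
  g <- hex_geometry(width = 200, height = 180)
  set.seed(1)
  st <- init_random_strips(c(5, 3, 2), g, strip_width = 60)
  sim <- simulate_invasion(st, model_params(0, 0, 0, 0, 0, 0), duration = 48)
  expect_equal(sim$final_state$agents[c("i", "j", "phase")],
               st$agents[c("i", "j", "phase")])
  expect_equal(sim$final_state$time, 48)
})

test_that("simulation runs are reproducible from the seed and count divisions exactly", {
  g <- hex_geometry(width = 400, height = 400)
  set.seed(10)
  st <- init_random_strips(c(20, 8, 12), g, strip_width = 100)
  p <- model_params(0.3, 0.4, 0.3, 3, 3, 3)
  a <- simulate_invasion(st, p, duration = 24, seed = 77)
  b <- simulate_invasion(st, p, duration = 24, seed = 77)
  expect_identical(a$final_state$agents, b$final_state$agents)
  expect_identical(a$event_counts, b$event_counts)
  # one net agent per successful division, exclusion intact
  expect_equal(nrow(a$final_state$agents),
               nrow(st$agents) + a$event_counts[["division_success"]])
  expect_true(fucciabc:::check_exclusion(a$final_state))
})

test_that("an unobstructed walker makes about M*T successful moves", {
  g <- hex_geometry(width = 3000, height = 2600)
  mid <- data.frame(x_um = 1500, y_um = 1300, phase = "red")
  st <- init_from_positions(mid, g)
  p <- model_params(0, 0, 0, 1, 0, 0)
  set.seed(21)
  moves <- replicate(200, {
    simulate_invasion(st, p, duration = 48)$event_counts[["move_success"]]
  })
  # Poisson(48) attempts, all succeed in empty space far from boundaries
  expect_equal(mean(moves), 48, tolerance = 0.05)
})

test_that("mean squared displacement follows 4Dt with D = M delta^2 / 4", {
  g <- hex_geometry(width = 3000, height = 2600, delta = 20)
  start <- data.frame(x_um = 1500, y_um = 1300, phase = "red")
  st <- init_from_positions(start, g)
  x0 <- state_positions(st)$x; y0 <- state_positions(st)$y
  p <- model_params(0, 0, 0, 1, 0, 0)      # M = 1/h -> D = 100 um^2/h
  t_end <- 10
  set.seed(31)
  r2 <- replicate(1000, {
    fin <- simulate_invasion(st, p, duration = t_end)$final_state
    pos <- state_positions(fin)
    (pos$x - x0)^2 + (pos$y - y0)^2
  })
  expect_equal(mean(r2), 1 * g$delta^2 * t_end, tolerance = 0.05)
})

test_that("phase durations of isolated cells are exponential with the phase rate", {
  # a fully packed immobile lattice: transitions are unconditional and
  # independent, so each agent's red and yellow dwell times are exactly
  # Exponential(R_r) and Exponential(R_y)
  g <- hex_geometry(width = 2000, height = 1740)  # 100 x 100 sites
  grid <- expand.grid(i = seq_len(g$n_rows), j = seq_len(g$n_cols))
  xy <- site_to_xy(grid, g)
  st <- init_from_positions(data.frame(x_um = xy$x, y_um = xy$y,
                                       phase = "red"), g)
  n <- nrow(st$agents)
  expect_gte(n, 1e4)
  p <- model_params(0.5, 0.25, 0, 0, 0, 0)  # greens never divide: no crowding
  sim <- simulate_invasion(st, p, duration = 60, seed = 41,
                           tracked = seq_len(n))
  tr <- sim$trajectories
  first <- tr[tr$phase == "yellow", ]
  second <- tr[tr$phase == "green", ]
  red_dwell <- first$t_h
  yellow_dwell <- second$t_h - first$t_h[match(second$cell_id, first$cell_id)]
  expect_gt(length(red_dwell), 9000)
  ks_red <- suppressWarnings(stats::ks.test(red_dwell, "pexp", 0.5))
  ks_yellow <- suppressWarnings(stats::ks.test(yellow_dwell, "pexp", 0.25))
  expect_gt(ks_red$p.value, 0.01)
  expect_gt(ks_yellow$p.value, 0.01)
})

test_that("subpopulation means track the mean-field ODE at low density", {
  g <- hex_geometry()
  set.seed(51)
  st <- init_random_strips(c(30, 10, 20), g, strip_width = 200)
  theta <- model_params(0.2, 0.3, 0.25, 2, 2, 2)
  t_end <- 24
  set.seed(52)
  counts <- t(replicate(60, {
    count_summaries(simulate_invasion(st, theta, duration = t_end)$final_state)
  }))
  ode <- mean_field_counts(c(30, 10, 20), theta, t_end)
  expect_equal(unname(colMeans(counts)), unname(ode), tolerance = 0.1)
})

test_that("censored red dwell times truncate at the horizon", {
  # sanity on trajectory structure: times strictly increasing per cell,
  # tracked cells start red, termination labels are consistent
  g <- hex_geometry(width = 600, height = 600)
  set.seed(61)
  st <- init_random_strips(c(20, 0, 0), g, strip_width = 150)
  tracked <- select_tracked_cells(st, 10)
  sim <- simulate_invasion(st, model_params(0.3, 0.5, 0.5, 2, 2, 2),
                           duration = 24, tracked = tracked)
  tr <- sim$trajectories
  expect_setequal(unique(tr$cell_id), tracked)
  by_cell <- split(tr, tr$cell_id)
  for (cell in by_cell) {
    expect_true(all(diff(cell$t_h) > 0))
    expect_equal(as.character(cell$phase[1]), "red")
  }
  expect_true(all(sim$tracked$termination %in% c("divided", "simulation_end")))
  # a divided tracked cell's last record is its return to red
  div <- sim$tracked$cell_id[sim$tracked$termination == "divided"]
  for (id in div) {
    cell <- by_cell[[as.character(id)]]
    expect_equal(as.character(cell$phase[nrow(cell)]), "red")
  }
})

test_that("leading-edge selection takes red cells with an unhindered path to the gap", {
  g <- hex_geometry(width = 400, height = 180)   # midline at x = 200
  # row 1: reds at columns 3 and 7 (x = 40, 120): only column 7 leads
  # row 3: red at column 4 blocked by a yellow at column 8
  # row 5: red at column 9 (x = 160) leads
  cells <- data.frame(
    i = c(1, 1, 3, 3, 5),
    j = c(3, 7, 4, 8, 9),
    phase = c("red", "red", "red", "yellow", "red"))
  xy <- site_to_xy(cells[c("i", "j")], g)
  st <- init_from_positions(data.frame(x_um = xy$x, y_um = xy$y,
                                       phase = cells$phase), g)
  pos <- state_positions(st)
  expect_warning(ids <- select_tracked_cells(st, 10), "only 2")
  picked <- pos[pos$id %in% ids, ]
  expect_setequal(paste(picked$i, picked$j), c("1 7", "5 9"))
  # nearest-the-midline wins when more qualify than requested
  ids1 <- select_tracked_cells(st, 1)
  expect_equal(paste(pos$i[pos$id == ids1], pos$j[pos$id == ids1]), "5 9")
  st_empty <- init_from_positions(data.frame(x_um = 40, y_um = 40,
                                             phase = "green"), g)
  expect_error(select_tracked_cells(st_empty), "no red")
})
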