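# Independent oracles used across the test files.

# exhaustive nearest-site search over every in-domain site centre
brute_force_nearest_site <- function(x, y, geom) {
  grid <- expand.grid(i = seq_len(geom$n_rows), j = seq_len(geom$n_cols))
  xy <- site_to_xy(grid, geom)
  d2 <- (xy$x - x)^2 + (xy$y - y)^2
  best <- which.min(d2)
  c(i = xy$i[best], j = xy$j[best])
}

# mean-field subpopulation ODE at negligible crowding:
#   dN_r/dt = 2 R_g N_g - R_r N_r
#   dN_y/dt = R_r N_r - R_y N_y
#   dN_g/dt = R_y N_y - R_g N_g
mean_field_counts <- function(counts0, theta, t_end) {
  theta <- unlist(theta)
  stopifnot(all(c("R_r", "R_y", "R_g") %in% names(theta)))
  rhs <- function(t, y, parms) {
    list(c(2 * theta[["R_g"]] * y[3] - theta[["R_r"]] * y[1],
           theta[["R_r"]] * y[1] - theta[["R_y"]] * y[2],
           theta[["R_y"]] * y[2] - theta[["R_g"]] * y[3]))
  }
  out <- deSolve::ode(y = as.numeric(counts0), times = c(0, t_end),
                      func = rhs, parms = NULL)
  out[nrow(out), 2:4]
}

# plain ABC-rejection sampler (the SMC oracle): draw from the prior, keep
# draws whose simulated summary is within eps of the observed
abc_rejection <- function(observed, simulator, prior, eps, n_keep,
                          max_draws = 2e5) {
  kept <- vector("list", n_keep)
  got <- 0L
  draws <- 0L
  while (got < n_keep && draws < max_draws) {
    th <- unlist(sample_prior(prior, 1))
    draws <- draws + 1L
    rho <- abc_discrepancy(simulator(th), observed)
    if (rho <= eps) {
      got <- got + 1L
      kept[[got]] <- th
    }
  }
  stopifnot(got == n_keep)
  dplyr::bind_rows(lapply(kept, as.list))
}

# 1-parameter toy ABC problem shared by the SMC tests: uniform prior on
# [0, 1], the simulated summary is the mean of 5 normal draws around theta,
# packed into the counts block (unused slots zero)
toy_prior <- function() tibble::tibble(param = "mu", lower = 0, upper = 1)

toy_simulator <- function(theta) {
  ybar <- mean(stats::rnorm(5, mean = theta[["mu"]], sd = 0.2))
  summary_vector(c(N_r = ybar, N_y = 0, N_g = 0), blocks = "counts")
}

toy_observed <- function(value = 0.5) {
  summary_vector(c(N_r = value, N_y = 0, N_g = 0), blocks = "counts")
}

# number of well-separated modes of a kernel density estimate (local maxima
# exceeding a fraction of the global maximum)
n_density_modes <- function(x, rel_height = 0.25, adjust = 1.5) {
  d <- stats::density(x, adjust = adjust)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  sum(y[peaks] >= rel_height * max(y))
}
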