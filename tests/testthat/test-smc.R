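test_that("prior draws are uniform within their bounds", {
  pr <- prior_spec()
  set.seed(1)
  draws <- sample_prior(pr, 20000)
  for (k in seq_len(nrow(pr))) {
    x <- draws[[pr$param[k]]]
    expect_true(all(x >= pr$lower[k] & x <= pr$upper[k]))
  }
  expect_equal(mean(draws$R_r), 0.5, tolerance = 0.02)
  expect_equal(mean(draws$M_r), 5, tolerance = 0.02)
})

test_that("the tolerance update keeps the best particles at the rank threshold", {
  parts <- tibble::tibble(rho = c(3, 1, 4, 2))
  upd <- update_tolerance(parts, alpha = 0.5)
  expect_equal(upd$eps, 2)
  expect_equal(sort(upd$kept$rho), c(1, 2))
  expect_equal(upd$n_discarded, 2)

  same <- tibble::tibble(rho = rep(7, 10))
  upd2 <- update_tolerance(same, alpha = 0.5)
  expect_equal(upd2$eps, 7)
  expect_equal(nrow(upd2$kept), 5)

  big <- tibble::tibble(rho = stats::runif(1000))
  expect_equal(update_tolerance(big, 0.5)$n_discarded, 500)

  expect_error(update_tolerance(tibble::tibble(rho = c(Inf, Inf))), "infinite")
})

test_that("the move-count formula matches its closed form", {
  expect_equal(tune_Rt(0.5, 0.01), 7)
  expect_equal(tune_Rt(0.9, 0.01), 2)
  expect_equal(tune_Rt(1, 0.01), 1)
  expect_equal(tune_Rt(0, 0.01), Inf)
})

test_that("the ABC-MCMC kernel accepts iff in-support and within tolerance", {
  pr <- toy_prior()
  obs <- toy_observed(0.5)
  count_env <- new.env(); count_env$n <- 0L
  perfect <- function(theta) { count_env$n <- count_env$n + 1L; obs }

  part <- list(mu = 0.5, rho = 0.1, S = unclass(obs))
  # near-degenerate proposal stays in support; perfect simulator -> accept
  out <- mcmc_move_iteration(part, sigma = matrix(1e-20), eps = 0.2,
                             observed = obs, simulator = perfect, prior = pr)
  expect_true(out$accepted)
  expect_equal(out$rho, 0)

  # huge proposal sd: proposal lands outside [0,1] and is rejected without
  # calling the simulator
  count_env$n <- 0L
  set.seed(5)   # draw with |z| * 1e4 far outside the unit interval
  out2 <- mcmc_move_iteration(part, sigma = matrix(1e8), eps = 0.2,
                              observed = obs, simulator = perfect, prior = pr)
  expect_false(out2$accepted)
  expect_equal(count_env$n, 0L)

  # in-support proposal whose simulation misses the tolerance is rejected
  far <- function(theta) toy_observed(5)
  out3 <- mcmc_move_iteration(part, sigma = matrix(1e-20), eps = 0.2,
                              observed = obs, simulator = far, prior = pr)
  expect_false(out3$accepted)
  expect_equal(out3$theta[["mu"]], 0.5)
})

test_that("SMC-ABC matches ABC-rejection on the tractable toy model", {
  pr <- toy_prior()
  obs <- toy_observed(0.5)
  fit <- run_smc_abc(obs, toy_simulator, prior = pr, n_particles = 500,
                     eps_target = 0.05, seed = 42)
  # tolerance schedule is non-increasing and the population respects it
  eps_hist <- fit$history$eps
  expect_true(all(diff(eps_hist) <= 0))
  eps_final <- eps_hist[length(eps_hist)]
  expect_lte(eps_final, 0.05)
  expect_true(all(fit$particles$rho <= eps_final))

  set.seed(43)
  oracle <- abc_rejection(obs, toy_simulator, pr, eps = eps_final,
                          n_keep = 500)
  ks <- suppressWarnings(stats::ks.test(fit$particles$mu, oracle$mu))
  expect_gt(ks$p.value, 0.01)
  # posterior mean within 3 Monte Carlo standard errors of the oracle
  se <- sqrt(stats::var(oracle$mu) / nrow(oracle) +
               stats::var(fit$particles$mu) / nrow(fit$particles))
  expect_lt(abs(mean(fit$particles$mu) - mean(oracle$mu)), 3 * se)
})

test_that("a perfect simulator terminates immediately with the prior retained", {
  pr <- toy_prior()
  obs <- toy_observed(0.5)
  perfect <- function(theta) obs
  fit <- run_smc_abc(obs, perfect, prior = pr, n_particles = 200,
                     eps_target = 0, seed = 7)
  expect_equal(nrow(fit$history), 1L)
  expect_equal(fit$history$eps, 0)
  # particles are still prior draws: mean near 0.5
  expect_equal(mean(fit$particles$mu), 0.5, tolerance = 0.1)
})

test_that("regression adjustment solves the weighted least squares hand case", {
  # 3 particles, 1 summary, 1 parameter; weights and the WLS slope are
  # computed here from first principles (explicit arithmetic, no lm)
  pr <- toy_prior()
  obs <- toy_observed(0)
  theta <- c(0.3, 0.5, 0.7)
  s_sim <- c(-0.2, 0.1, 0.4)
  rho <- abs(s_sim)
  parts <- tibble::tibble(mu = theta, rho = rho, S_N_r = s_sim,
                          S_N_y = 0, S_N_g = 0)
  w <- 0.75 * (1 - (rho / max(rho))^2)
  lt <- log(theta / (1 - theta))
  x <- s_sim                       # S_sim - S_obs with S_obs = 0
  xbar <- sum(w * x) / sum(w)
  ybar <- sum(w * lt) / sum(w)
  beta <- sum(w * (x - xbar) * (lt - ybar)) / sum(w * (x - xbar)^2)
  expected <- stats::plogis(lt - beta * x)

  adj <- regression_adjust(parts, observed = obs, prior = pr)
  expect_equal(adj$mu, expected, tolerance = 1e-10)
  # the particle at the maximum discrepancy has Epanechnikov weight zero:
  # removing it entirely leaves the fitted slope unchanged
  beta_drop <- {
    keep <- rho < max(rho)
    wk <- w[keep]; xk <- x[keep]; lk <- lt[keep]
    xb <- sum(wk * xk) / sum(wk); yb <- sum(wk * lk) / sum(wk)
    sum(wk * (xk - xb) * (lk - yb)) / sum(wk * (xk - xb)^2)
  }
  expect_equal(beta, beta_drop, tolerance = 1e-12)
})

test_that("regression adjustment is a no-op when every simulation hits the data", {
  pr <- toy_prior()
  obs <- toy_observed(0.3)
  parts <- tibble::tibble(mu = c(0.2, 0.4, 0.6, 0.8),
                          rho = c(0.1, 0.2, 0.3, 0.4),
                          S_N_r = 0.3, S_N_y = 0, S_N_g = 0)
  adj <- regression_adjust(parts, observed = obs, prior = pr)
  expect_equal(adj$mu, parts$mu)
})

test_that("adjusted parameters always stay strictly inside the prior bounds", {
  pr <- toy_prior()
  obs <- toy_observed(0)
  set.seed(9)
  parts <- tibble::tibble(mu = stats::runif(50, 0.01, 0.99),
                          rho = stats::runif(50, 0.5, 2),
                          S_N_r = stats::rnorm(50, 0, 5),
                          S_N_y = 0, S_N_g = 0)
  adj <- regression_adjust(parts, observed = obs, prior = pr)
  expect_true(all(adj$mu > 0 & adj$mu < 1))
  # a particle sitting on a bound is nudged inside rather than diverging
  parts$mu[1] <- 1
  expect_warning(adj2 <- regression_adjust(parts, observed = obs, prior = pr),
                 "bound")
  expect_true(all(adj2$mu > 0 & adj2$mu < 1))
})

test_that("posterior summary table reports moments, quantiles and CV", {
  const <- posterior_summaries(rep(0.3, 50))
  expect_equal(const$sd, 0)
  expect_equal(const$cv_pct, 0)
  expect_equal(const$q2.5, const$q97.5)

  # CV consistency at the scale of the published motility posteriors
  set.seed(11)
  z <- as.numeric(scale(stats::rnorm(400)))
  x1 <- 0.316 + 0.0343 * z
  expect_equal(posterior_summaries(x1)$cv_pct, 10.9, tolerance = 0.01)
  x2 <- 1.12 + 0.169 * z
  expect_equal(posterior_summaries(x2)$cv_pct, 15.1, tolerance = 0.005)
})

test_that("posterior predictive draws reproduce a degenerate posterior exactly", {
  g <- hex_geometry(400, 260)
  set.seed(13)
  st <- init_random_strips(c(8, 3, 4), g, strip_width = 100)
  simfn <- lattice_simulator(st, tracked = integer(0), duration = 24,
                             blocks = "counts")
  zero <- tibble::tibble(R_r = 0, R_y = 0, R_g = 0, M_r = 0, M_y = 0, M_g = 0)
  pred <- posterior_predictive(zero, simfn, n_draws = 5, seed = 14)
  expect_true(all(pred$N_r == 8 & pred$N_y == 3 & pred$N_g == 4))
  expect_true(all(pred$N_r %% 1 == 0 & pred$N_r >= 0))
})
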