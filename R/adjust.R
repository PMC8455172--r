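#' Regression adjustment of an ABC posterior sample
#'
#' Post-processes the final particle population with Beaumont-style local
#' linear regression: each parameter is logit-transformed to the prior
#' support, `log((theta - a) / (b - theta))`, regressed on the summary
#' residuals `S_sim - S_obs` by weighted least squares with Epanechnikov
#' weights `w_i = 0.75 (1 - (rho_i / max rho)^2)`, shifted by the fitted
#' effect, and back-transformed. The transformation keeps every adjusted
#' parameter strictly inside the prior bounds.
#'
#' @param fit An `smc_abc_fit` from [run_smc_abc()], or a tibble with
#'   parameter columns, `rho` and `S_*` summary columns.
#' @param observed Observed `summary_vector` (taken from the fit when
#'   omitted).
#' @param prior A [prior_spec()] (taken from the fit when omitted).
#' @return A tibble of adjusted parameter draws (one column per parameter).
#' @export
regression_adjust <- function(fit, observed = NULL, prior = NULL) {
  if (inherits(fit, "smc_abc_fit")) {
    particles <- fit$particles
    if (is.null(observed)) observed <- fit$observed
    if (is.null(prior)) prior <- fit$prior
  } else {
    particles <- tibble::as_tibble(fit)
    if (is.null(observed) || is.null(prior)) {
      stop("regression_adjust(): observed and prior are required", call. = FALSE)
    }
  }
  s_names <- paste0("S_", names(unclass(observed)))
  stopifnot(all(s_names %in% names(particles)),
            all(prior$param %in% names(particles)))
  n <- nrow(particles)
  X <- sweep(as.matrix(particles[s_names]), 2, unclass(observed))
  rho <- particles$rho
  w <- 0.75 * (1 - (rho / max(rho))^2)
  # drop summary columns with no variation (would be collinear with the
  # intercept); warn only when genuinely informative columns are dropped
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  if (!all(keep) && any(abs(X[, !keep, drop = FALSE]) > 0)) {
    warning("regression_adjust(): dropped constant non-zero summary column(s)",
            call. = FALSE)
  }
  X <- X[, keep, drop = FALSE]
  if (n < ncol(X) + 2) {
    stop("regression_adjust(): need at least p + 2 particles for p informative summaries",
         call. = FALSE)
  }

  adjusted <- purrr::map(prior$param, function(par) {
    a <- prior$lower[prior$param == par]
    b <- prior$upper[prior$param == par]
    theta <- particles[[par]]
    # bound values would have infinite logit; nudge inside by a tiny offset
    edge <- .Machine$double.eps^0.5 * (b - a)
    on_bound <- theta <= a | theta >= b
    if (any(on_bound)) {
      warning(sprintf("regression_adjust(): %d value(s) of %s on a prior bound nudged inside",
                      sum(on_bound), par), call. = FALSE)
      theta <- pmin(pmax(theta, a + edge), b - edge)
    }
    lt <- log((theta - a) / (b - theta))
    if (ncol(X) == 0) return(theta)
    fit_wls <- stats::lm.wfit(cbind(`(Intercept)` = 1, X), lt, w)
    beta <- fit_wls$coefficients[-1]
    na_beta <- is.na(beta)
    if (any(na_beta)) {
      warning(sprintf("regression_adjust(): rank-deficient design for %s; %d collinear column(s) dropped",
                      par, sum(na_beta)), call. = FALSE)
      beta[na_beta] <- 0
    }
    lt_adj <- lt - drop(X %*% beta)
    (a + b * exp(lt_adj)) / (1 + exp(lt_adj))
  })
  tibble::as_tibble(stats::setNames(adjusted, prior$param))
}

#' Posterior summary table
#'
#' Mean, standard deviation, (2.5%, 50%, 97.5%) quantiles (linear
#' interpolation) and coefficient of variation `CV = 100 * sd / mean` per
#' parameter.
#'
#' @param sample A data frame of posterior draws (one column per parameter)
#'   or a numeric vector for a single parameter.
#' @return A tibble with columns `param`, `mean`, `sd`, `q2.5`, `median`,
#'   `q97.5`, `cv_pct`.
#' @export
posterior_summaries <- function(sample) {
  if (is.numeric(sample) && is.null(dim(sample))) {
    sample <- tibble::tibble(theta = sample)
  }
  sample <- tibble::as_tibble(sample)
  stopifnot(nrow(sample) > 0)
  purrr::map_dfr(names(sample), function(par) {
    x <- sample[[par]]
    m <- mean(x)
    s <- stats::sd(x)
    if (length(x) == 1) s <- 0
    q <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
    tibble::tibble(param = par, mean = m, sd = s,
                   q2.5 = q[1], median = q[2], q97.5 = q[3],
                   cv_pct = if (m == 0 && s == 0) 0
                            else if (m == 0) NA_real_ else 100 * s / m)
  })
}

#' Posterior predictive distribution of the summary statistics
#'
#' Draws parameter vectors from a posterior sample (with replacement),
#' simulates the model once per draw and collects the simulated summary
#' statistics, for comparison against the observed summaries.
#'
#' @param sample Data frame of posterior draws (parameter columns), or an
#'   `smc_abc_fit`.
#' @param simulator Function `theta -> summary_vector`.
#' @param n_draws Number of predictive simulations.
#' @param seed Optional integer seed.
#' @return A tibble with one row per draw: the parameter values used and the
#'   simulated summary statistics.
#' @export
posterior_predictive <- function(sample, simulator, n_draws = 100,
                                 seed = NULL) {
  if (inherits(sample, "smc_abc_fit")) {
    sample <- sample$particles[sample$prior$param]
  }
  sample <- tibble::as_tibble(sample)
  stopifnot(nrow(sample) > 0, n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(sample), n_draws, replace = TRUE)
  purrr::map_dfr(idx, function(k) {
    th <- unlist(sample[k, ])
    s <- simulator(th)
    dplyr::bind_cols(sample[k, ],
                     tibble::as_tibble(as.list(unclass(s))))
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of an SMC-ABC fit
#'
#' @param x An `smc_abc_fit`.
#' @param adjusted Apply [regression_adjust()] before summarising.
#' @param ... Unused.
#' @return A tibble as from [posterior_summaries()].
#' @export
tidy.smc_abc_fit <- function(x, adjusted = FALSE, ...) {
  draws <- if (adjusted) regression_adjust(x) else x$particles[x$prior$param]
  posterior_summaries(draws)
}

#' One-row diagnostics of an SMC-ABC fit
#'
#' @param x An `smc_abc_fit`.
#' @param ... Unused.
#' @return A tibble with `n_particles`, `n_rounds`, `final_eps`,
#'   `final_p_acc`, `n_sims`, `truncated`.
#' @export
glance.smc_abc_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_particles = nrow(x$particles),
    n_rounds = nrow(h),
    final_eps = h$eps[nrow(h)],
    final_p_acc = h$p_acc[nrow(h)],
    n_sims = x$n_sims_total,
    truncated = x$truncated)
}
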