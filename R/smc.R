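#' Uniform prior specification
#'
#' Independent uniform priors for the six model parameters: the cell-cycle
#' transition rates are uniform on 0-1 per hour (conservative relative to
#' literature doubling-time estimates) and the motility rates uniform on
#' 0-10 per hour (reflecting the wide spread of published diffusivity
#' estimates).
#'
#' @param transition Length-2 numeric `c(lower, upper)` for `R_r, R_y, R_g`.
#' @param motility Length-2 numeric `c(lower, upper)` for `M_r, M_y, M_g`.
#' @return A tibble of class `prior_spec` with columns `param`, `lower`,
#'   `upper`.
#' @examples
#' prior_spec()
#' @export
prior_spec <- function(transition = c(0, 1), motility = c(0, 10)) {
  stopifnot(transition[1] < transition[2], motility[1] < motility[2])
  out <- tibble::tibble(
    param = param_names(),
    lower = c(rep(transition[1], 3), rep(motility[1], 3)),
    upper = c(rep(transition[2], 3), rep(motility[2], 3)))
  class(out) <- c("prior_spec", class(out))
  out
}

#' Sample parameter vectors from the prior
#'
#' @param prior A [prior_spec()] (or any tibble with `param`, `lower`,
#'   `upper`).
#' @param n Number of draws.
#' @return A tibble with one column per parameter and `n` rows.
#' @export
sample_prior <- function(prior, n) {
  draws <- purrr::pmap(prior, function(param, lower, upper, ...) {
    stats::runif(n, lower, upper)
  })
  tibble::as_tibble(stats::setNames(draws, prior$param))
}

in_prior_support <- function(theta, prior) {
  all(theta[prior$param] >= prior$lower & theta[prior$param] <= prior$upper)
}

#' Adaptive tolerance update by discrepancy ranking
#'
#' Sorts the particle population by discrepancy and sets the new tolerance to
#' the discrepancy of rank `N - floor(alpha * N)`; particles above it are
#' discarded (to be replenished by resampling).
#'
#' @param particles Tibble with a numeric `rho` column.
#' @param alpha Fraction of particles discarded each round.
#' @return List with `eps` (new tolerance), `kept` (tibble of surviving
#'   particles, sorted by `rho`), `n_discarded`.
#' @export
update_tolerance <- function(particles, alpha = 0.5) {
  stopifnot(nrow(particles) >= 2, alpha > 0, alpha < 1)
  if (all(!is.finite(particles$rho))) {
    stop("update_tolerance(): all discrepancies are infinite", call. = FALSE)
  }
  n <- nrow(particles)
  n_alpha <- floor(alpha * n)
  sorted <- dplyr::arrange(particles, .data$rho)
  eps <- sorted$rho[n - n_alpha]
  list(eps = eps, kept = sorted[seq_len(n - n_alpha), ], n_discarded = n_alpha)
}

#' Number of MCMC move iterations from the acceptance rate
#'
#' `R_t = ceiling(log(c) / log(1 - p_acc))`, the number of MCMC iterations
#' needed so that each resampled particle is moved at least once with
#' probability `1 - c`; clamped to at least 1, and infinite when no move has
#' been accepted (the caller's acceptance-rate stopping rule then applies).
#'
#' @param p_acc Overall MCMC acceptance rate in `[0, 1]`.
#' @param c Move-failure tolerance.
#' @return Integer number of iterations (possibly `Inf` when `p_acc = 0`).
#' @examples
#' tune_Rt(0.5)   # 7
#' @export
tune_Rt <- function(p_acc, c = 0.01) {
  stopifnot(p_acc >= 0, p_acc <= 1, c > 0, c < 1)
  if (p_acc == 0) return(Inf)
  if (p_acc == 1) return(1)
  max(1, ceiling(log(c) / log(1 - p_acc)))
}

# One ABC-MCMC iteration on the particle population (matrix form): propose
# theta' ~ MVN(theta, Sigma); with uniform priors, a symmetric proposal and
# the indicator kernel the Metropolis-Hastings ratio reduces to: accept iff
# theta' is inside the prior support and a fresh simulation at theta' has
# rho' <= eps.
mcmc_move_particles <- function(pop, sigma_chol, eps, observed, simulator,
                                prior) {
  n <- nrow(pop$theta)
  p <- ncol(pop$theta)
  prop <- pop$theta + matrix(stats::rnorm(n * p), n, p) %*% sigma_chol
  lower <- prior$lower; upper <- prior$upper
  accepted <- logical(n)
  n_sims <- 0L
  obs_vals <- unclass(observed)
  obs_valid <- attr(observed, "valid")
  for (k in seq_len(n)) {
    th <- prop[k, ]
    if (any(th < lower | th > upper)) next        # prior density zero
    names(th) <- prior$param
    s_sim <- tryCatch(simulator(th), error = function(e) {
      warning("simulator failed during MCMC move; proposal rejected: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    n_sims <- n_sims + 1L
    if (is.null(s_sim)) next
    rho <- if (attr(s_sim, "valid") && obs_valid) {
      sqrt(sum((unclass(s_sim) - obs_vals)^2))
    } else Inf
    if (rho <= eps) {
      pop$theta[k, ] <- th
      pop$rho[k] <- rho
      pop$S[k, ] <- unclass(s_sim)
      accepted[k] <- TRUE
    }
  }
  list(pop = pop, accepted = accepted, n_sims = n_sims)
}

#' Single-particle ABC-MCMC move
#'
#' One Metropolis-Hastings iteration of the move kernel used inside the
#' SMC-ABC sampler, exposed for inspection: propose from a multivariate
#' normal centred at the current value, reject outside the prior support
#' without simulating, otherwise accept iff a fresh simulation at the
#' proposal has discrepancy within the current tolerance.
#'
#' @param particle List/tibble row with the parameter values and `rho`.
#' @param sigma Proposal covariance matrix (p x p).
#' @param eps Current tolerance.
#' @param observed Observed `summary_vector`.
#' @param simulator Function `theta -> summary_vector`.
#' @param prior A [prior_spec()].
#' @return List with `theta`, `rho`, `S` (summary of the retained value) and
#'   `accepted`.
#' @export
mcmc_move_iteration <- function(particle, sigma, eps, observed, simulator,
                                prior) {
  theta <- unlist(particle[prior$param])
  prop <- theta + drop(matrix(stats::rnorm(length(theta)), 1) %*% chol(sigma))
  names(prop) <- prior$param
  if (!in_prior_support(prop, prior)) {
    return(list(theta = theta, rho = particle$rho, S = particle$S,
                accepted = FALSE))
  }
  s_sim <- simulator(prop)
  rho <- abc_discrepancy(s_sim, observed)
  if (rho <= eps) {
    list(theta = prop, rho = rho, S = s_sim, accepted = TRUE)
  } else {
    list(theta = theta, rho = particle$rho, S = particle$S, accepted = FALSE)
  }
}

#' SMC-ABC replenishment sampler
#'
#' Samples from the ABC posterior of the model parameters by propagating a
#' particle population through an adaptive, non-increasing tolerance
#' schedule. Each round: (1) the tolerance drops to the discrepancy of rank
#' `N - floor(alpha N)` and the worst `floor(alpha N)` particles are
#' discarded; (2) discarded slots are refilled by resampling survivors with
#' replacement; (3) resampled particles are diversified by `R_t` ABC-MCMC
#' iterations with a multivariate-normal proposal whose covariance is the
#' empirical covariance of the survivors. `R_t` is tuned from a pilot
#' acceptance rate (`ceiling(R_[t-1]/2)` pilot iterations) so that every
#' particle moves at least once with probability `1 - c_tune`. The sampler
#' stops when the overall MCMC acceptance rate of a round falls to `f_acc`
#' or below, when the tolerance reaches `eps_target`, or when the simulation
#' budget is exhausted.
#'
#' @param observed Observed `summary_vector`.
#' @param simulator Function mapping a named parameter vector to a
#'   `summary_vector` with the same blocks as `observed` (one fresh model
#'   simulation per call).
#' @param prior A [prior_spec()].
#' @param n_particles Population size N.
#' @param alpha Discard fraction per round.
#' @param c_tune Move-failure tolerance `c` in the `R_t` formula.
#' @param f_acc Stopping threshold on the overall MCMC acceptance rate.
#' @param eps_target Target tolerance (0 is unattainable for continuous
#'   summaries, so stopping is in practice governed by `f_acc`).
#' @param R0 Assumed move count before the first round (the first pilot uses
#'   `ceiling(R0 / 2)` iterations).
#' @param max_sims Simulation budget; exceeding it returns the current
#'   population with `truncated = TRUE`.
#' @param seed Optional integer seed.
#' @param verbose Print per-round diagnostics.
#' @return An object of class `smc_abc_fit`: list with `particles` (tibble
#'   with parameter columns, `rho` and summary columns `S_*`), `history`
#'   (per-round tibble `t`, `eps`, `p_acc`, `R_t`, `n_sims`), `prior`,
#'   `observed`, `truncated`, `n_sims_total`.
#' @export
run_smc_abc <- function(observed, simulator, prior = prior_spec(),
                        n_particles = 1000, alpha = 0.5, c_tune = 0.01,
                        f_acc = 0.01, eps_target = 0, R0 = 10,
                        max_sims = Inf, seed = NULL, verbose = FALSE) {
  stopifnot(inherits(observed, "summary_vector"), n_particles >= 2)
  if (!is.null(seed)) set.seed(seed)

  n_sims_total <- 0L
  s_len <- length(unclass(observed))

  # initial population from the prior; particles with infinite discrepancy
  # (invalid simulated summaries) are redrawn
  theta <- as.matrix(sample_prior(prior, n_particles))
  rho <- rep(Inf, n_particles)
  S <- matrix(NA_real_, n_particles, s_len,
              dimnames = list(NULL, names(unclass(observed))))
  for (k in seq_len(n_particles)) {
    repeat {
      th <- theta[k, ]
      names(th) <- prior$param
      s_sim <- simulator(th)
      n_sims_total <- n_sims_total + 1L
      r <- abc_discrepancy(s_sim, observed)
      if (is.finite(r)) {
        rho[k] <- r
        S[k, ] <- unclass(s_sim)
        break
      }
      if (n_sims_total > max_sims) {
        stop("run_smc_abc(): simulation budget exhausted during initialisation",
             call. = FALSE)
      }
      theta[k, ] <- unlist(sample_prior(prior, 1))
    }
  }
  pop <- list(theta = theta, rho = rho, S = S)

  eps <- max(pop$rho)
  history <- tibble::tibble(t = 1L, eps = eps, p_acc = NA_real_,
                            R_t = NA_real_, n_sims = n_sims_total)
  if (verbose) message(sprintf("t = 1: eps_1 = %.4g (%d simulations)",
                               eps, n_sims_total))

  R_prev <- R0
  t_iter <- 1L
  truncated <- FALSE

  while (eps > eps_target) {
    t_iter <- t_iter + 1L
    ord <- order(pop$rho)
    n_alpha <- floor(alpha * n_particles)
    n_keep <- n_particles - n_alpha
    eps <- pop$rho[ord[n_keep]]
    keep_idx <- ord[seq_len(n_keep)]
    kept <- list(theta = pop$theta[keep_idx, , drop = FALSE],
                 rho = pop$rho[keep_idx], S = pop$S[keep_idx, , drop = FALSE])
    sigma_chol <- proposal_chol_mat(kept$theta)

    # replenish by resampling survivors with replacement
    ridx <- sample.int(n_keep, n_alpha, replace = TRUE)
    moving <- list(theta = kept$theta[ridx, , drop = FALSE],
                   rho = kept$rho[ridx], S = kept$S[ridx, , drop = FALSE])

    n_pilot <- max(1, ceiling(R_prev / 2))
    acc_total <- 0L
    iter_total <- 0L
    round_sims <- 0L
    run_iters <- function(pp, n_iter) {
      for (it in seq_len(n_iter)) {
        mv <- mcmc_move_particles(pp, sigma_chol, eps, observed, simulator,
                                  prior)
        pp <- mv$pop
        acc_total <<- acc_total + sum(mv$accepted)
        iter_total <<- iter_total + length(pp$rho)
        round_sims <<- round_sims + mv$n_sims
        if (n_sims_total + round_sims >= max_sims) break
      }
      pp
    }
    moving <- run_iters(moving, n_pilot)
    p_acc_pilot <- acc_total / iter_total
    R_t <- tune_Rt(p_acc_pilot, c_tune)
    # when the pilot rate is already at the stopping threshold the round is
    # the last one; the remaining iterations would be wasted
    if (is.finite(R_t) && R_t > n_pilot && p_acc_pilot > f_acc &&
        n_sims_total + round_sims < max_sims) {
      moving <- run_iters(moving, R_t - n_pilot)
    }
    R_t_effective <- max(n_pilot, ifelse(is.finite(R_t), R_t, n_pilot))
    p_acc <- acc_total / iter_total
    n_sims_total <- n_sims_total + round_sims

    pop <- list(theta = rbind(kept$theta, moving$theta),
                rho = c(kept$rho, moving$rho),
                S = rbind(kept$S, moving$S))
    history <- dplyr::bind_rows(history, tibble::tibble(
      t = t_iter, eps = eps, p_acc = p_acc, R_t = R_t_effective,
      n_sims = round_sims))
    if (verbose) {
      message(sprintf("t = %d: eps = %.4g, p_acc = %.3f, R_t = %d, sims = %d (total %d)",
                      t_iter, eps, p_acc, R_t_effective, round_sims,
                      n_sims_total))
    }
    R_prev <- R_t_effective

    if (p_acc <= f_acc) break
    if (n_sims_total >= max_sims) { truncated <- TRUE; break }
  }

  particles <- finalize_particles(pop, prior)
  structure(
    list(particles = particles, history = history, prior = prior,
         observed = observed, truncated = truncated,
         n_sims_total = n_sims_total),
    class = "smc_abc_fit")
}

finalize_particles <- function(pop, prior) {
  theta <- pop$theta
  colnames(theta) <- prior$param
  S <- pop$S
  colnames(S) <- paste0("S_", colnames(S))
  dplyr::bind_cols(tibble::as_tibble(theta),
                   tibble::tibble(rho = pop$rho),
                   tibble::as_tibble(S))
}

proposal_chol_mat <- function(theta) {
  sigma <- stats::cov(theta)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    warning("singular proposal covariance; falling back to diagonal variances",
            call. = FALSE)
    ch <- diag(sqrt(pmax(diag(sigma), .Machine$double.eps)),
               nrow = ncol(theta))
  }
  ch
}

#' @export
print.smc_abc_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<smc_abc_fit> %d particles, %d rounds, final eps = %.4g, final p_acc = %.3f, %d simulations%s\n",
    nrow(x$particles), nrow(h), h$eps[nrow(h)], h$p_acc[nrow(h)],
    x$n_sims_total, if (x$truncated) " [budget truncated]" else ""))
  print(posterior_summaries(x$particles[x$prior$param]))
  invisible(x)
}
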