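#' Model parameters: per-phase transition and motility rates
#'
#' The stochastic invasion model is parameterised by
#' `theta = (R_r, R_y, R_g, M_r, M_y, M_g)`: the cell-cycle transition rates
#' out of the red (G1), yellow (eS) and green (S/G2/M) phases and the
#' per-phase motility (movement-attempt) rates, all per hour. Division is the
#' green-phase cycle event: a green cell attempts to place a red daughter on
#' a random neighbouring site and itself returns to red.
#'
#' @param R_r,R_y,R_g Transition rates out of red, yellow, green (per hour).
#' @param M_r,M_y,M_g Motility rates of red, yellow, green cells (per hour).
#' @return A named numeric vector of class `model_params`.
#' @examples
#' model_params(0.04, 0.17, 0.08, 4, 4, 4)
#' @export
model_params <- function(R_r, R_y, R_g, M_r, M_y, M_g) {
  theta <- c(R_r = R_r, R_y = R_y, R_g = R_g, M_r = M_r, M_y = M_y, M_g = M_g)
  if (!all(is.finite(theta)) || any(theta < 0)) {
    stop("model_params(): all six rates must be finite and >= 0", call. = FALSE)
  }
  structure(theta, class = c("model_params", "numeric"))
}

param_names <- function() c("R_r", "R_y", "R_g", "M_r", "M_y", "M_g")

as_model_params <- function(x) {
  if (inherits(x, "model_params")) return(x)
  x <- unlist(x)
  if (is.null(names(x)) && length(x) == 6) names(x) <- param_names()
  do.call(model_params, as.list(x[param_names()]))
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> (per hour)\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Cell diffusivity implied by a motility rate
#'
#' Converts a motility (movement-attempt) rate `M` into the diffusivity of an
#' unobstructed random walker with step length `delta`: `D = M * delta^2 / 4`
#' (square micrometres per hour).
#'
#' @param M Motility rate(s), per hour.
#' @param delta Lattice step length in micrometres.
#' @return Diffusivity in um^2 per hour.
#' @examples
#' motility_to_diffusivity(4)   # 400 um^2/h
#' @export
motility_to_diffusivity <- function(M, delta = 20) M * delta^2 / 4
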