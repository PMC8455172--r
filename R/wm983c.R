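#' Published observed summaries of the WM983C scratch assay
#'
#' The observed summary statistics of the WM983C FUCCI-transduced melanoma
#' scratch-assay experiment (48 h), as published: final phase counts
#' 566/111/166 (red/yellow/green), mean per-phase trajectory distances
#' 105/40/100 micrometres over 20 tracked cells, and left/right density
#' medians and interquartile ranges in micrometres. These are inputs to the
#' experimental inference, not quantities the package computes.
#'
#' @param blocks Summary blocks to include (see [summary_vector()]).
#' @return A `summary_vector`.
#' @examples
#' wm983c_observed(c("counts", "trajectory"))
#' @export
wm983c_observed <- function(blocks = c("counts", "trajectory")) {
  values <- c(
    N_r = 566, N_y = 111, N_g = 166,
    d_r = 105, d_y = 40, d_g = 100,
    med_r_L = 155, med_r_R = 1170,
    med_y_L = 158, med_y_R = 1189,
    med_g_L = 177, med_g_R = 1129,
    iqr_r_L = 196, iqr_r_R = 197,
    iqr_y_L = 164, iqr_y_R = 144,
    iqr_g_L = 213, iqr_g_R = 207)
  summary_vector(values, blocks = blocks)
}

#' Published initial phase counts of the WM983C scratch assay
#'
#' Initial numbers of red, yellow and green cells recovered from the first
#' experimental frame: 119, 35 and 121.
#'
#' @return Integer vector `c(n_red, n_yellow, n_green)`.
#' @export
wm983c_initial_counts <- function() c(red = 119L, yellow = 35L, green = 121L)

#' Published posterior-mean rates for the WM983C experiment
#'
#' The posterior-mean parameter estimates reported for the experimental
#' inference with count and trajectory summaries: transition rates
#' 0.0411/0.192/0.193 per hour and motility rates 0.316/0.514/1.12 per hour.
#' Used as inputs to posterior predictive simulations.
#'
#' @return A [model_params()] vector.
#' @export
wm983c_posterior_means <- function() {
  model_params(R_r = 0.0411, R_y = 0.192, R_g = 0.193,
               M_r = 0.316, M_y = 0.514, M_g = 1.12)
}
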