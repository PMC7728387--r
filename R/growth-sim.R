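#' Simulate an OD600 growth curve
#'
#' Logistic trajectory \eqn{OD(t) = K N0 e^{rt} / (K + N0 (e^{rt} - 1))}
#' with \eqn{r = \ln 2 / T_d}, so the early exponential phase doubles every
#' \code{doubling_time_h} hours, sampled at the plate-reader cadence with
#' optional additive Gaussian noise.
#'
#' @param od0 inoculation density (> 0).
#' @param doubling_time_h exponential-phase doubling time, hours (> 0).
#' @param carrying_capacity saturation OD600 (> od0).
#' @param interval_min sampling interval, minutes.
#' @param duration_h total duration, hours.
#' @param noise_sd additive Gaussian noise sd on OD (0 = noiseless).
#' @param seed integer seed (used only when noise_sd > 0).
#' @param strain,replicate metadata columns.
#' @return data.frame with columns time_h, od600, strain, replicate.
#' @examples
#' gc <- generate_growth_curve(0.1, 1.5, carrying_capacity = 100,
#'                             duration_h = 8, noise_sd = 0)
#' gc$od600[gc$time_h == 1.5]  # one doubling: 0.2
#' @export
generate_growth_curve <- function(od0, doubling_time_h,
                                  carrying_capacity = 2.0,
                                  interval_min = 15, duration_h = 24,
                                  noise_sd = 0, seed = 1L,
                                  strain = "WT", replicate = 1L) {
  if (od0 <= 0) stop("od0 must be positive")
  if (doubling_time_h <= 0) stop("doubling_time_h must be positive")
  if (carrying_capacity <= od0) stop("carrying_capacity must exceed od0")
  if (interval_min <= 0 || duration_h <= 0) stop("sampling parameters must be positive")
  t <- seq(0, duration_h, by = interval_min / 60)
  r <- log(2) / doubling_time_h
  e <- exp(r * t)
  od <- carrying_capacity * od0 * e / (carrying_capacity + od0 * (e - 1))
  if (noise_sd > 0) {
    od <- with_seed(seed, pmax(od + stats::rnorm(length(od), 0, noise_sd), 1e-4))
  }
  data.frame(time_h = t, od600 = od, strain = strain,
             replicate = as.integer(replicate), stringsAsFactors = FALSE)
}
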