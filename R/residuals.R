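#' Recursive residuals as a model-fit diagnostic
#'
#' Standardised one-step-ahead prediction errors of the LNA filter under a
#' point-estimate profile (by default the posterior-mean profile at the
#' modal switch count).  If the model fits, the residuals are approximately
#' iid standard normal; reported alongside are a Kolmogorov-Smirnov
#' statistic against N(0, 1) and the lag-1 autocorrelation with its
#' white-noise band.
#'
#' @param trace fluorescence values.
#' @param times observation times (hours).
#' @param samples a `posterior_samples` object for this trace, or `NULL` to
#'   supply `profile` and `kp` directly.
#' @param profile optional [transcription_profile()] overriding the
#'   posterior summary.
#' @param kp optional [kinetic_params()]; defaults to the posterior means
#'   of the sampled parameters (with the chain's fixed `alpha`, `kappa`).
#' @return list with `residuals` (data.frame: time, residual), `ks`
#'   (statistic, p_value), `lag1_acf`, `band` and `white_noise_ok`.
#' @export
recursive_residuals <- function(trace, times, samples = NULL,
                                profile = NULL, kp = NULL) {
  if (is.null(profile)) {
    if (is.null(samples) || length(samples$K) == 0L)
      stop("need non-empty posterior samples or an explicit profile")
    profile <- posterior_profile(samples)
  }
  if (is.null(kp)) {
    if (is.null(samples)) stop("need samples or explicit kinetic parameters")
    kp <- kinetic_params(delta_m = mean(samples$delta_m),
                         delta_p = mean(samples$delta_p),
                         alpha = samples$kp$alpha,
                         kappa = samples$kp$kappa,
                         sigma2 = mean(samples$sigma2))
  }
  flt <- lna_filter(trace, times, profile, kp)
  pred <- flt$predictive
  resid <- (pred$observed - pred$mean) / pred$sd
  resid[!is.finite(resid)] <- 0
  ks <- suppressWarnings(stats::ks.test(resid, "pnorm"))
  n <- length(resid)
  r1 <- stats::acf(resid, lag.max = 1, plot = FALSE)$acf[2]
  band <- 1.96 / sqrt(n)
  list(residuals = data.frame(time = times, residual = resid),
       ks = list(statistic = unname(ks$statistic),
                 p_value = unname(ks$p.value)),
       lag1_acf = as.numeric(r1), band = band,
       white_noise_ok = abs(r1) <= band && ks$p.value > 0.05)
}
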