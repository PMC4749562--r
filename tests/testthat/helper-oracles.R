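# Independent oracles used across the suite.  These deliberately share no
# code with the package: the filter oracle integrates the moment ODEs with
# fixed-step fourth-order Runge-Kutta on a fine grid (dt = 1e-3 h) and runs
# a plain discrete Kalman update, with no matrix exponentials or caching.

oracle_kalman_loglik <- function(y, times, s, beta, dm, dp, alpha, kappa,
                                 sigma2, dt_fine = 1e-3) {
  rate_at <- function(t) beta[findInterval(t, s) + 1L]
  deriv <- function(z, b) {
    m <- z[1]; p <- z[2]; vmm <- z[3]; vmp <- z[4]; vpp <- z[5]
    c(b - dm * m,
      alpha * m - dp * p,
      b + dm * m - 2 * dm * vmm,
      alpha * vmm - (dm + dp) * vmp,
      alpha * m + dp * p + 2 * alpha * vmp - 2 * dp * vpp)
  }
  b1 <- beta[1]
  m <- b1 / dm; p <- alpha * b1 / (dm * dp)
  vmm <- m; vmp <- alpha * vmm / (dm + dp)
  vpp <- (alpha * m + dp * p + 2 * alpha * vmp) / (2 * dp)
  z <- c(m, p, vmm, vmp, vpp)
  ll <- 0
  for (i in seq_along(times)) {
    if (i > 1) {
      t0 <- times[i - 1]; t1 <- times[i]
      brks <- sort(unique(c(t0, s[s > t0 & s < t1], t1)))
      for (k in seq_len(length(brks) - 1)) {
        a <- brks[k]; bnd <- brks[k + 1]
        b <- rate_at((a + bnd) / 2)
        nstep <- max(1L, ceiling((bnd - a) / dt_fine))
        h <- (bnd - a) / nstep
        for (st in seq_len(nstep)) {
          k1 <- deriv(z, b)
          k2 <- deriv(z + h / 2 * k1, b)
          k3 <- deriv(z + h / 2 * k2, b)
          k4 <- deriv(z + h * k3, b)
          z <- z + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        }
      }
    }
    mu <- kappa * z[2]; S <- kappa^2 * z[5] + sigma2
    r <- y[i] - mu
    ll <- ll - 0.5 * (log(2 * pi) + log(S) + r^2 / S)
    g <- r / S
    kvmp <- kappa * z[4]; kvpp <- kappa * z[5]
    z <- c(z[1] + kvmp * g, z[2] + kvpp * g,
           z[3] - kvmp^2 / S, z[4] - kvmp * kvpp / S, z[5] - kvpp^2 / S)
  }
  ll
}

# chi-square goodness-of-fit of a (dependent) MCMC draw sequence against a
# discrete pmf, with counts rescaled to the chain's effective sample size
# (a plain chi-square assumes independent draws and rejects on excursions)
chisq_mcmc_p <- function(k_draws, probs, min_expected = 20) {
  n <- length(k_draws)
  a <- stats::acf(k_draws, lag.max = 50, plot = FALSE)$acf[-1]
  cut <- which(a < 0.05)[1]
  if (is.na(cut)) cut <- 50L
  n_eff <- min(n, n / (1 + 2 * sum(a[seq_len(cut)])))
  obs <- tabulate(k_draws + 1L, nbins = length(probs))
  keep <- probs * n >= min_expected
  obs_p <- c(obs[keep], sum(obs[!keep]))
  exp_p <- c(probs[keep], sum(probs[!keep]))
  obs_scaled <- round(obs_p / n * n_eff)
  suppressWarnings(stats::chisq.test(obs_scaled, p = exp_p)$p.value)
}

# brute-force O(N^2) autocovariance (biased 1/N normalisation)
oracle_acf <- function(x, max_lag) {
  n <- length(x)
  xc <- x - mean(x)
  v <- sum(xc^2) / n
  vapply(seq_len(max_lag), function(l)
    sum(xc[1:(n - l)] * xc[(1 + l):n]) / n / v, numeric(1))
}

# simulate a noisy single-switch fluorescence trace with known truth
make_switch_trace <- function(s_true = 20, beta = c(6, 30), t_max = 46,
                              dt = 0.25, kp = kinetic_params()) {
  times <- seq(0, t_max, by = dt)
  prof <- transcription_profile(s_true, beta, c(0, t_max))
  paths <- simulate_reporter_ssa(prof, kp, times)
  y <- as.numeric(apply_measurement(paths$protein, kp))
  list(y = y, times = times, profile = prof, kp = kp)
}

# hand-built posterior_samples object (for post-processing tests)
fake_samples <- function(switch_times, rates, window = c(0, 46),
                         dm = 0.7, dp = 0.35, s2 = 25,
                         kp = kinetic_params()) {
  n <- length(switch_times)
  structure(list(
    K = vapply(switch_times, length, integer(1)),
    switch_times = switch_times,
    rates = rates,
    delta_m = rep(dm, n), delta_p = rep(dp, n), sigma2 = rep(s2, n),
    loglik = rep(0, n),
    ledger = data.frame(move = character(0), proposed = integer(0),
                        accepted = integer(0)),
    window = window, min_sep = 0.5, priors = prior_spec(), kp = kp,
    mcmc = NULL, likelihood = TRUE),
    class = "posterior_samples")
}

# small track_set from a matrix of traces and given positions
tracks_from_matrix <- function(m, pos, times = NULL, background = list()) {
  if (is.null(times)) times <- seq(0, by = 0.25, length.out = nrow(m))
  tracks <- lapply(seq_len(ncol(m)), function(i)
    cell_track(sprintf("c%03d", i), times, m[, i],
               cbind(rep(pos$x[i], nrow(m)), rep(pos$y[i], nrow(m)))))
  track_set(tracks, background = background,
            zero_background = length(background) == 0L)
}
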