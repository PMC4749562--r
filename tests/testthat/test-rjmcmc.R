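test_that("birth/death proposal log-ratios cancel exactly", {
  priors <- prior_spec()
  mcmc <- mcmc_config()
  window <- c(0, 46)
  st <- list(s = c(10, 30), beta = c(2, 6, 3), dm = 0.7, dp = 0.35, s2 = 25)
  for (u in c(5, 20.3, 41)) {
    eps <- 0.42
    b <- switchtissue:::rj_birth_proposal(st, u, eps, priors, window, mcmc)
    i_new <- match(u, b$state$s)
    d <- switchtissue:::rj_death_proposal(b$state, i_new, priors, window, mcmc)
    expect_equal(b$log_prop + b$log_jac + d$log_prop + d$log_jac, 0,
                 tolerance = 1e-10)
    # death restores the original state
    expect_equal(d$state$s, st$s)
    expect_equal(d$state$beta, st$beta, tolerance = 1e-12)
  }
})

test_that("a prior-only chain reproduces the truncated geometric prior on K", {
  set.seed(501)
  times <- seq(0, 46, by = 0.25)
  ps <- rjmcmc_sample(rep(0, length(times)), times,
                      mcmc = mcmc_config(iters = 20000, burnin = 2000,
                                         thin = 10),
                      likelihood = FALSE)
  pr <- prior_spec()
  expected <- (1 - pr$k_geom_p)^(0:pr$k_max)
  expected <- expected / sum(expected)
  expect_gt(chisq_mcmc_p(ps$K, expected), 0.01)
  # ledger counts are complete
  expect_true(all(ps$ledger$accepted <= ps$ledger$proposed))
})

test_that("a constant-rate trace is recognised as switchless", {
  set.seed(502)
  kp <- kinetic_params()
  times <- seq(0, 46, by = 0.25)
  prof <- transcription_profile(numeric(0), 6, c(0, 46))
  paths <- simulate_reporter_ssa(prof, kp, times)
  y <- as.numeric(apply_measurement(paths$protein, kp))
  smp <- rjmcmc_sample(y, times,
                       mcmc = mcmc_config(iters = 6000, burnin = 1500))
  expect_gt(mean(smp$K == 0), 0.5)
})

test_that("a strong single switch is recovered with its timing", {
  set.seed(503)
  tr <- make_switch_trace(s_true = 20)
  smp <- rjmcmc_sample(tr$y, tr$times,
                       mcmc = mcmc_config(iters = 8000, burnin = 2000))
  expect_equal(posterior_modal_K(smp), 1)
  modal_s <- unlist(smp$switch_times[smp$K == 1])
  expect_lt(abs(median(modal_s) - 20), 1)
  # sampled degradation rates stay near the informative prior
  expect_lt(abs(mean(log(smp$delta_m)) - log(0.7)), 0.5)
})

test_that("simulation-based calibration: true switch time ranks are spread", {
  set.seed(504)
  ranks <- vapply(1:8, function(i) {
    s_true <- runif(1, 12, 34)
    tr <- make_switch_trace(s_true = s_true)
    smp <- rjmcmc_sample(tr$y, tr$times,
                         mcmc = mcmc_config(iters = 4000, burnin = 1000))
    pool <- pooled_switch_times(smp)
    mean(pool < s_true)
  }, numeric(1))
  # ranks should not collapse to the extremes
  expect_gt(mean(ranks > 0.02 & ranks < 0.98), 0.5)
})

test_that("hierarchical sweep pools degradation information", {
  set.seed(505)
  h <- hierarchy_spec()
  same <- hierarchical_sweep(rep(0.7, 20), rep(0.35, 20), h)
  spread <- hierarchical_sweep(c(rep(0.3, 10), rep(1.4, 10)),
                               c(rep(0.2, 10), rep(0.7, 10)), h)
  tau_same <- same$population$tau2[1]
  tau_spread <- spread$population$tau2[1]
  expect_lt(tau_same, 0.05)          # shrinks toward the hyperprior floor
  expect_gt(tau_spread, 5 * tau_same)
  expect_warning(hierarchical_sweep(0.7, 0.35, h), "single cell")
})

test_that("disabling the hierarchy reproduces independent inference", {
  set.seed(506)
  kp <- kinetic_params()
  times <- seq(0, 46, by = 0.5)
  traces <- lapply(1:2, function(i) {
    prof <- transcription_profile(numeric(0), 6, c(0, 46))
    paths <- simulate_reporter_ssa(prof, kp, times)
    as.numeric(apply_measurement(paths$protein, kp))
  })
  mc <- mcmc_config(iters = 1500, burnin = 500)
  set.seed(99)
  fit_h_off <- hierarchical_infer(traces, times, mcmc = mc, sweeps = 1,
                                  hierarchical = FALSE)
  set.seed(99)
  fit_ind <- lapply(traces, function(y)
    rjmcmc_sample(y, times, prior_spec(), kp, mc))
  expect_equal(fit_h_off$cells[[1]]$K, fit_ind[[1]]$K)
  expect_equal(fit_h_off$cells[[2]]$delta_m, fit_ind[[2]]$delta_m)
})

test_that("recursive residuals separate well-fitted from misfitted models", {
  set.seed(507)
  tr <- make_switch_trace(s_true = 20)
  # correct profile: residuals look like white noise
  res_ok <- recursive_residuals(tr$y, tr$times, profile = tr$profile,
                                kp = tr$kp)
  expect_gt(res_ok$ks$p_value, 0.01)
  expect_lt(abs(res_ok$lag1_acf), 3 * res_ok$band)
  # ignoring the switch leaves structured residuals
  wrong <- transcription_profile(numeric(0), 6, c(0, 46))
  res_bad <- recursive_residuals(tr$y, tr$times, profile = wrong, kp = tr$kp)
  expect_gt(abs(res_bad$lag1_acf), res_bad$band)
  expect_false(res_bad$white_noise_ok)
})
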