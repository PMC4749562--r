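test_that("cell placement respects its mode", {
  set.seed(201)
  one <- place_cells(1, c(0, 10, 0, 10))
  expect_equal(nrow(one), 1)
  expect_true(one$x >= 0 && one$x <= 10)
  hc <- place_cells(60, c(0, 300, 0, 300), mode = "hard-core", min_sep = 10)
  expect_gte(min(dist(hc[, c("x", "y")])), 10)
  expect_error(place_cells(500, c(0, 50, 0, 50), mode = "hard-core",
                           min_sep = 10), "infeasible|failed")
})

test_that("state-path sojourns follow the configured exponentials", {
  set.seed(202)
  cfg <- state_process_config(mean_off = 3, mean_primed = 2, mean_on = 4)
  # harvest complete sojourns from long windows
  paths <- lapply(1:60, function(i) simulate_state_path(cfg, c(0, 600)))
  st <- do.call(rbind, lapply(paths, attr, "states"))
  st$len <- st$end - st$start
  complete <- st[st$start > 0 & st$end < 600, ]
  for (nm in c("off", "primed", "on")) {
    x <- complete$len[complete$state == nm]
    mu <- switch(nm, off = 3, primed = 2, on = 4)
    expect_gt(length(x), 1000)
    se <- mu / sqrt(length(x))   # SD of an exponential equals its mean
    expect_lt(abs(mean(x) - mu), 3 * se)
    expect_gt(ks.test(x, "pexp", 1 / mu)$p.value, 0.01)
  }
})

test_that("degenerate state processes behave as limits", {
  set.seed(203)
  cfg <- state_process_config(mean_on = 1e9)
  p <- simulate_state_path(cfg, c(0, 46), start_state = "on")
  expect_length(p$switch_times, 0)
  expect_gt(p$rates, 0)
})

test_that("switch coupling propagates same-direction switches to neighbours", {
  set.seed(204)
  pos <- data.frame(x = c(0, 10, 200), y = c(0, 0, 0))
  p1 <- transcription_profile(20, c(1, 9), c(0, 46))
  p0 <- transcription_profile(numeric(0), 2, c(0, 46))
  profs <- list(p1, p0, p0)
  off <- couple_switches(profs, pos, coupling_config(probability = 0))
  expect_identical(off$profiles, profs)
  expect_equal(nrow(off$log), 0)
  on <- couple_switches(profs, pos,
                        coupling_config(probability = 1, jitter_sd = 0,
                                        mode = "insert"))
  expect_equal(on$profiles[[2]]$switch_times, 20)   # neighbour at 10 um
  expect_gt(on$profiles[[2]]$rates[2], on$profiles[[2]]$rates[1])  # same dir
  expect_length(on$profiles[[3]]$switch_times, 0)   # 200 um: out of range
  expect_equal(nrow(on$log), 1)

  # shift mode aligns an existing same-direction switch without changing
  # switch counts
  p_up <- transcription_profile(25, c(1, 9), c(0, 46))
  sh <- couple_switches(list(p1, p_up, p0), pos,
                        coupling_config(probability = 1, jitter_sd = 0))
  expect_equal(sh$profiles[[2]]$switch_times, 20)
  expect_equal(sh$profiles[[2]]$rates, p_up$rates)
  expect_length(sh$profiles[[3]]$switch_times, 0)
})

test_that("SSA paths are integer, non-negative, and hit analytic moments", {
  set.seed(205)
  kp <- kinetic_params()
  zero <- transcription_profile(numeric(0), 0, c(0, 10))
  z <- simulate_reporter_ssa(zero, kp, seq(0, 10, 0.25), init = c(0, 0))
  expect_true(all(z$mRNA == 0) && all(z$protein == 0))

  beta <- 6
  prof <- transcription_profile(numeric(0), beta, c(0, 30))
  reps <- 150
  m_end <- p_end <- numeric(reps)
  for (r in seq_len(reps)) {
    pth <- simulate_reporter_ssa(prof, kp, c(0, 30))
    m_end[r] <- pth$mRNA[2]; p_end[r] <- pth$protein[2]
    expect_true(all(pth$mRNA >= 0), info = "non-negative counts")
  }
  m_theory <- beta / kp$delta_m
  p_theory <- kp$alpha * beta / (kp$delta_m * kp$delta_p)
  expect_lt(abs(mean(m_end) - m_theory), 3 * sd(m_end) / sqrt(reps))
  expect_lt(abs(mean(p_end) - p_theory), 3 * sd(p_end) / sqrt(reps))
  # stationary mRNA is Poisson: variance/mean ratio near 1
  expect_lt(abs(var(m_end) / mean(m_end) - 1), 0.35)
})

test_that("LNA stationary moments match SSA empirical moments", {
  set.seed(206)
  kp <- kinetic_params()
  beta <- 8
  st <- lna_stationary(beta, kp)
  prof <- transcription_profile(numeric(0), beta, c(0, 40))
  reps <- 200
  mp <- t(vapply(seq_len(reps), function(r) {
    pth <- simulate_reporter_ssa(prof, kp, c(0, 40))
    c(pth$mRNA[2], pth$protein[2])
  }, numeric(2)))
  expect_lt(abs(mean(mp[, 1]) - st["m"]), 3 * sd(mp[, 1]) / sqrt(reps))
  expect_lt(abs(mean(mp[, 2]) - st["p"]), 3 * sd(mp[, 2]) / sqrt(reps))
  # variance agreement at 3 MC SEs (SE of a variance ~ var * sqrt(2/(n-1)))
  expect_lt(abs(var(mp[, 2]) - st["Vpp"]),
            3 * var(mp[, 2]) * sqrt(2 / (reps - 1)))
})

test_that("measurement model applies gain, noise and saturation", {
  set.seed(207)
  p <- 0:200
  kp0 <- kinetic_params(sigma2 = 1e-12)
  exact <- apply_measurement(p, kp0)
  expect_equal(as.numeric(exact), kp0$kappa * p, tolerance = 1e-4)
  kp <- kinetic_params(sigma2 = 25)
  two <- apply_measurement(p, kp, detectors = list(
    list(label = "sens", gain = 1, ceiling = 100),
    list(label = "insens", gain = 0.1, ceiling = Inf)))
  expect_true(all(two[, "sens"] <= 100))
  # empirical noise variance within 5% of sigma2
  pp <- rep(50, 1e4)
  y <- apply_measurement(pp, kp)
  expect_lt(abs(var(y[, 1] - kp$kappa * pp) - kp$sigma2), 0.05 * kp$sigma2)
})

test_that("tissue simulation is deterministic given the seed", {
  sim <- function() {
    set.seed(208)
    simulate_tissue(n_cells = 12, t_max = 46, coupling_cfg =
                      coupling_config(probability = 0.3))
  }
  a <- sim(); b <- sim()
  expect_identical(fluor_matrix(a$tracks), fluor_matrix(b$tracks))
  expect_identical(a$truth$positions, b$truth$positions)
  expect_length(a$tracks$times, 185)   # 46 h / 0.25 h + 1
  expect_length(a$tracks$background, 5)
})
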