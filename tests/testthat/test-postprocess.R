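test_that("switch-time mixture fitting recovers well-separated components", {
  set.seed(601)
  draws_empty <- fake_samples(rep(list(numeric(0)), 50),
                              rep(list(5), 50))
  cs <- fit_switch_mixture(draws_empty)
  expect_length(cs$means, 0)

  two <- lapply(1:400, function(i)
    sort(c(rnorm(1, 10, 0.5), rnorm(1, 30, 0.5))))
  draws_two <- fake_samples(two, rep(list(c(2, 8, 3)), 400))
  cs2 <- fit_switch_mixture(draws_two)
  expect_length(cs2$means, 2)
  expect_lt(abs(cs2$means[1] - 10), 0.3)
  expect_lt(abs(cs2$means[2] - 30), 0.3)

  one <- lapply(1:300, function(i) rnorm(1, 18, 0.4))
  draws_one <- fake_samples(one, rep(list(c(2, 8)), 300))
  cs1 <- fit_switch_mixture(draws_one)
  expect_length(cs1$means, 1)
  expect_lt(abs(cs1$means[1] - 18), 0.3)
})

test_that("two candidate switches enumerate to exactly four profiles", {
  set.seed(602)
  # draws visit every subset of the two candidates
  st <- c(rep(list(numeric(0)), 25),
          lapply(1:25, function(i) rnorm(1, 10, 0.4)),
          lapply(1:25, function(i) rnorm(1, 30, 0.4)),
          lapply(1:25, function(i) sort(c(rnorm(1, 10, 0.4),
                                          rnorm(1, 30, 0.4)))))
  rates <- c(rep(list(5), 25), rep(list(c(2, 8)), 25),
             rep(list(c(8, 3)), 25), rep(list(c(2, 8, 3)), 25))
  smp <- fake_samples(st, rates)
  cands <- fit_switch_mixture(smp)
  expect_length(cands$means, 2)
  ps <- enumerate_submodels(smp, cands)
  expect_length(ps$profiles, 4)
  ks <- sort(vapply(ps$profiles, function(p) length(p$switch_times),
                    integer(1)))
  expect_equal(ks, c(0L, 1L, 1L, 2L))
  expect_equal(sum(profile_set_weights(ps)), 1, tolerance = 1e-9)
  # weights equal the brute-force subset tabulation (25 draws each)
  expect_equal(sort(profile_set_weights(ps)), rep(0.25, 4))
})

test_that("sub-models never sampled are pruned", {
  set.seed(603)
  st <- lapply(1:60, function(i) sort(c(rnorm(1, 10, 0.3),
                                        rnorm(1, 30, 0.3))))
  smp <- fake_samples(st, rep(list(c(2, 8, 3)), 60))
  cands <- fit_switch_mixture(smp)
  ps <- enumerate_submodels(smp, cands)
  expect_length(ps$profiles, 1)
  expect_equal(ps$profiles[[1]]$weight, 1)
  expect_length(ps$profiles[[1]]$switch_times, 2)
})

test_that("profile sampling follows the weights", {
  set.seed(604)
  p1 <- transcription_profile(10, c(1, 5), c(0, 46), weight = 0.7)
  p2 <- transcription_profile(numeric(0), 3, c(0, 46), weight = 0.3)
  ps <- profile_set("c", list(p1, p2))
  draws <- replicate(1e4, length(sample_profile(ps)$switch_times))
  frac1 <- mean(draws == 1)
  se <- sqrt(0.7 * 0.3 / 1e4)
  expect_lt(abs(frac1 - 0.7), 3 * se)
})

test_that("weighted switch-count histogram equals brute-force enumeration", {
  w4 <- c(0.25, 0.25, 0.25, 0.25)
  profs <- list(
    transcription_profile(numeric(0), 5, c(0, 46), weight = w4[1]),
    transcription_profile(10, c(2, 8), c(0, 46), weight = w4[2]),
    transcription_profile(30, c(8, 3), c(0, 46), weight = w4[3]),
    transcription_profile(c(10, 30), c(2, 8, 3), c(0, 46), weight = w4[4]))
  ps <- profile_set("c", profs)
  h <- switch_count_summary(list(ps))
  expect_equal(h$K, c(0L, 1L, 2L))
  expect_equal(h$weight, c(0.25, 0.5, 0.25))
  expect_equal(attr(h, "expected_per_cell"), 1)  # 0*.25 + 1*.5 + 2*.25
})

test_that("expected switch counts separate groups with different intensity", {
  set.seed(605)
  gen_group <- function(n, mean_k) {
    lapply(seq_len(n), function(i) {
      k <- rpois(1, mean_k)
      s <- sort(runif(k, 2, 44))
      while (k > 1 && min(diff(s)) < 0.6) s <- sort(runif(k, 2, 44))
      rates <- abs(rnorm(k + 1, 6, 2)) + (seq_len(k + 1) %% 2) # adjacent differ
      profile_set(paste0("g", i),
                  list(transcription_profile(s, rates, c(0, 46), 1)))
    })
  }
  a <- gen_group(30, 0.7)
  b <- gen_group(30, 2.5)
  ka <- attr(switch_count_summary(a), "expected_per_cell")
  kb <- attr(switch_count_summary(b), "expected_per_cell")
  expect_lt(suppressWarnings(wilcox.test(ka, kb))$p.value, 0.01)
})

test_that("weighted rate distribution matches the brute-force weighted ECDF", {
  p1 <- transcription_profile(23, c(2, 8), c(0, 46), weight = 0.6)
  p2 <- transcription_profile(numeric(0), 5, c(0, 46), weight = 0.4)
  cells <- list(profile_set("c", list(p1, p2)))
  cdf <- rate_distribution(cells, mode = "cdf")
  pooled <- attr(cdf, "samples")
  # brute-force weighted ECDF at a grid point well above all rates
  expect_equal(max(cdf$cdf), 1, tolerance = 1e-6)
  brute <- function(x) sum(pooled$w[pooled$rate <= x]) / sum(pooled$w)
  for (x in c(3, 5.5, 7)) {
    smoothed <- cdf$cdf[which.min(abs(cdf$rate - x))]
    expect_lt(abs(smoothed - brute(x)), 0.2)  # kernel-smoothing tolerance
  }
  den <- rate_distribution(cells, mode = "density")
  # small mass loss from flooring the support at zero is acceptable
  expect_equal(sum(den$density) * diff(den$rate[1:2]), 1, tolerance = 0.05)
})

test_that("a switchless profile yields one censored full-window duration", {
  p <- transcription_profile(numeric(0), 5, c(0, 46))
  cells <- list(profile_set("c", list(p)))
  out <- duration_by_rate_bin(cells, binning = "q75_split", n_draws = 3)
  expect_true(all(out$samples$duration == 46))
  expect_true(all(out$samples$censored))
})

test_that("low/active classification follows the flanking rule", {
  p <- function(rates) {
    k <- length(rates) - 1
    transcription_profile(seq(10, by = 5, length.out = k), rates, c(0, 46))
  }
  expect_equal(classify_low_active(p(c(5, 1, 6))),
               c("Active", "Low", "Active"))
  expect_equal(classify_low_active(p(c(1, 5, 2))),
               c("Active", "Active", "Active"))
  expect_equal(classify_low_active(p(c(1, 2, 3))),
               c("Active", "Active", "Active"))
  expect_error(classify_low_active(p(5)), "at least one switch")
})

test_that("only multi-switch profiles contribute complete inter-switch times", {
  p2 <- transcription_profile(c(10, 30), c(2, 8, 3), c(0, 46), weight = 0.5)
  p1 <- transcription_profile(10, c(2, 8), c(0, 46), weight = 0.3)
  p0 <- transcription_profile(numeric(0), 5, c(0, 46), weight = 0.2)
  cells <- list(profile_set("c", list(p2, p1, p0)))
  out <- inter_switch_times(cells)
  expect_equal(out$samples$duration, 20)
  expect_equal(out$samples$weight, 0.5)
  none <- inter_switch_times(list(profile_set("c2", list(
    transcription_profile(10, c(2, 8), c(0, 46))))))
  expect_null(none$samples)
})

test_that("bootstrap Mann-Whitney is calibrated and powerful", {
  set.seed(606)
  mk_cells <- function(n, dur_lo, dur_hi) {
    lapply(seq_len(n), function(i) {
      s <- sort(runif(2, dur_lo, dur_hi))
      profile_set(paste0("c", i), list(
        transcription_profile(s, c(2, 8, 3), c(0, 46), 1)))
    })
  }
  same_a <- mk_cells(25, 5, 40)
  same_b <- mk_cells(25, 5, 40)
  null_res <- bootstrap_mannwhitney(same_a, same_b, B = 150)
  expect_lt(null_res$frac_below, 0.2)
  expect_false(null_res$significant)

  # pulsatile group: most intervals short; stable group: all intervals 23 h
  pulsatile <- lapply(seq_len(25), function(i) {
    s <- c(2, 4, 6, 8) + runif(1, -0.5, 0.5)
    profile_set(paste0("s", i), list(
      transcription_profile(s, c(2, 8, 3, 9, 4), c(0, 46), 1)))
  })
  stable <- lapply(seq_len(25), function(i) {
    profile_set(paste0("t", i), list(
      transcription_profile(23 + runif(1, -1, 1), c(2, 8), c(0, 46), 1)))
  })
  pow <- bootstrap_mannwhitney(pulsatile, stable, B = 150)
  expect_gt(pow$frac_below, 0.5)
  one <- bootstrap_mannwhitney(same_a, same_b, B = 1)
  expect_length(one$p_values, 1)
})
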