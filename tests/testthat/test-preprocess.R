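make_two_channel <- function(truth, sens_ceiling = 100, insens_gain = 0.1,
                             noise_sd = 0.5) {
  n <- length(truth)
  times <- seq(0, by = 0.25, length.out = n)
  sens <- pmin(truth + rnorm(n, 0, noise_sd), sens_ceiling)
  insens <- insens_gain * truth + rnorm(n, 0, noise_sd)
  cell_track("c1", times, cbind(sens = pmax(sens, 0),
                                insens = pmax(insens, 0)),
             cbind(rep(0, n), rep(0, n)))
}

test_that("detector fusion recovers the full-range signal", {
  set.seed(301)
  truth <- seq(0, 400, length.out = 185)
  tr <- make_two_channel(truth)
  out <- fuse_detectors(tr, ceiling = 100)
  expect_gt(out$fit$slope, 0)
  expect_gt(out$fit$r_squared, 0.95)
  # fused trace tracks the truth over the full range, incl. saturated part
  err <- out$track$fluor[, 1] - truth
  expect_lt(stats::median(abs(err)), 5)
  expect_lt(max(abs(err[truth > 150])), 25)
})

test_that("fusion is an identity on identical unsaturated channels", {
  n <- 50
  times <- seq(0, by = 0.25, length.out = n)
  v <- seq(1, 50, length.out = n)
  tr <- cell_track("c", times, cbind(a = v, b = v),
                   cbind(rep(0, n), rep(0, n)))
  out <- fuse_detectors(tr, ceiling = 1000, threshold = 999)
  expect_equal(out$fit$slope, 1, tolerance = 1e-8)
  expect_equal(out$fit$intercept, 0, tolerance = 1e-6)
  expect_equal(as.numeric(out$track$fluor), v, tolerance = 1e-8)
  # idempotent on already-fused single-channel input
  again <- fuse_detectors(out$track)
  expect_identical(again$track$fluor, out$track$fluor)
})

test_that("fusion fails loudly when unidentifiable", {
  n <- 30
  times <- seq(0, by = 0.25, length.out = n)
  sat <- cell_track("c", times, cbind(a = rep(100, n), b = 1:n),
                    cbind(rep(0, n), rep(0, n)))
  expect_error(fuse_detectors(sat, ceiling = 100), "unsaturated")
  set.seed(302)
  bad <- cell_track("c", times, cbind(a = 30 - (1:n) + rnorm(n, 0, .1),
                                      b = 1:n),
                    cbind(rep(0, n), rep(0, n)))
  expect_error(fuse_detectors(bad, ceiling = 100), "slope")
})

test_that("background subtraction equals the arithmetic oracle", {
  set.seed(303)
  n <- 20
  m <- matrix(runif(n * 3, 10, 50), n, 3)
  bgs <- lapply(1:5, function(i) runif(n, 0, 5))
  ts <- tracks_from_matrix(m, data.frame(x = 1:3, y = 1:3),
                           background = bgs)
  out <- subtract_background(ts)
  bg_mean <- rowMeans(do.call(cbind, bgs))
  for (i in 1:3)
    expect_equal(out$tracks[[i]]$fluor[, 1],
                 pmax(m[, i] - bg_mean, 0), ignore_attr = TRUE)
  # constant background shifts by exactly that constant
  ts2 <- tracks_from_matrix(m, data.frame(x = 1:3, y = 1:3),
                            background = list(rep(7, n)))
  out2 <- subtract_background(ts2)
  expect_equal(out2$tracks[[1]]$fluor[, 1], pmax(m[, 1] - 7, 0),
               ignore_attr = TRUE)
  # zero background is the identity
  ts3 <- tracks_from_matrix(m, data.frame(x = 1:3, y = 1:3),
                            background = list(rep(0, n)))
  expect_equal(subtract_background(ts3)$tracks[[2]]$fluor, ts3$tracks[[2]]$fluor)
})

test_that("negative results of background subtraction are floored and logged", {
  n <- 12
  m <- matrix(5, n, 1)
  ts <- tracks_from_matrix(m, data.frame(x = 1, y = 1),
                           background = list(rep(10, n)))
  expect_message(out <- subtract_background(ts), "floored")
  expect_true(all(out$tracks[[1]]$fluor == 0))
})

test_that("autocorrelation matches the direct-sum oracle", {
  set.seed(304)
  x <- c(rep(1, 30), 5, rep(1, 30)) + rnorm(61, 0, 1e-6)
  d <- autocorrelation_diagnostic(x, max_lag = 10)
  expect_equal(d$acf, oracle_acf(x, 10), tolerance = 1e-10)
  expect_error(autocorrelation_diagnostic(rep(3, 50)), "zero-variance")
  expect_error(autocorrelation_diagnostic(rnorm(8)), "short")
})

test_that("white-noise band has near-nominal coverage and flags AR(1)", {
  set.seed(305)
  n <- 185
  inside <- replicate(60, {
    d <- autocorrelation_diagnostic(rnorm(n), max_lag = 20)
    mean(!d$outside)
  })
  expect_gt(mean(inside), 0.90)
  expect_lt(mean(inside), 0.995)
  flagged <- replicate(60, {
    e <- rnorm(n)
    x <- as.numeric(stats::filter(e, 0.8, method = "recursive"))
    autocorrelation_diagnostic(x, max_lag = 5)$outside[1]
  })
  expect_gt(mean(flagged), 0.99)   # lag-1 acf of AR(1) with phi=0.8
})
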