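test_that("Ripley's K has the closed-form CSR expectation and is monotone", {
  set.seed(701)
  pos <- place_cells(100, c(0, 200, 0, 200))
  rk <- ripley_k(pos, field = c(0, 200, 0, 200), n_sim = 19)
  expect_equal(rk$K_theo, pi * rk$r^2)
  expect_true(all(diff(rk$K_obs) >= 0))
  expect_true(all(rk$K_lo <= rk$K_hi))
  expect_error(ripley_k(pos[1:5, ]), ">= 10")
})

test_that("hard-core patterns breach the lower envelope at short range", {
  set.seed(702)
  pos <- place_cells(150, c(0, 300, 0, 300), mode = "hard-core",
                     min_sep = 12)
  rk <- ripley_k(pos, field = c(0, 300, 0, 300),
                 radii = c(4, 8, 11, 20, 40), n_sim = 99)
  expect_true(all(rk$K_obs[rk$r < 12] <= rk$K_lo[rk$r < 12]))
  expect_equal(rk$K_obs[rk$r < 12], c(0, 0, 0))  # nothing below min_sep
})

test_that("pair correlation equals Pearson's r and supports the literal mode", {
  set.seed(703)
  x <- rnorm(40); y <- rnorm(40)
  expect_equal(pair_correlation(x, x), 1, tolerance = 1e-12)
  expect_equal(pair_correlation(c(1, -1, 1, -1), c(1, 1, -1, -1)), 0)
  expect_equal(pair_correlation(x, y), cor(x, y), tolerance = 1e-12)
  expect_equal(pair_correlation(x, y, standardize = FALSE), mean(x * y))
  expect_error(pair_correlation(rep(1, 10), rnorm(10)), "zero-variance")
})

test_that("identical traces give unit correlation in every distance bin", {
  set.seed(704)
  base <- cumsum(rnorm(60))
  m <- matrix(rep(base, 8), ncol = 8) +
    matrix(rnorm(60 * 8, 0, 1e-8), ncol = 8)
  pos <- data.frame(x = runif(8, 0, 60), y = runif(8, 0, 60))
  ts <- tracks_from_matrix(m, pos)
  out <- correlation_vs_distance(ts, n_boot = 19)
  expect_true(all(out$median_corr > 0.999))
  expect_true(all(out$boot_hi - out$boot_lo < 1e-3))
})

test_that("a single-pair bin degenerates to that pair's value", {
  set.seed(705)
  m <- matrix(rnorm(50 * 2), ncol = 2)
  pos <- data.frame(x = c(0, 20), y = c(0, 0))
  ts <- tracks_from_matrix(m, pos)
  out <- correlation_vs_distance(ts, n_boot = 9)
  expect_equal(nrow(out), 1)
  expect_equal(out$boot_lo, out$boot_hi, ignore_attr = TRUE)
  expect_equal(out$median_corr, cor(m[, 1], m[, 2]), tolerance = 1e-10)
})

test_that("permutation null finds nothing in unstructured or constant data", {
  set.seed(706)
  m <- matrix(rnorm(60 * 30), ncol = 30)
  pos <- data.frame(x = runif(30, 0, 100), y = runif(30, 0, 100))
  ts <- tracks_from_matrix(m, pos)
  out <- permutation_null(ts, n_perm = 499)
  expect_true(is.null(out$significant_range) ||
                sum(out$bins$significant) <= 2)
})

test_that("coupled tissue shows a low-distance significant range", {
  set.seed(707)
  sim <- simulate_tissue(n_cells = 250, field = c(0, 335, 0, 335))
  ts <- suppressMessages(subtract_background(sim$tracks))
  out <- permutation_null(ts, n_perm = 1999, max_dist = 80)
  expect_false(is.null(out$significant_range))
  expect_gte(out$significant_range[2], 15)
  expect_lte(out$significant_range[2], 45)
  # no significance beyond the coupling radius
  expect_true(all(out$bins$bin_lo[out$bins$significant] < 30))
})

test_that("connectivity classes match the worked transitive rule", {
  # three collinear cells spaced 0.9 D: ends are indirectly connected
  D <- 20
  m <- matrix(rnorm(40 * 3), ncol = 3)
  pos <- data.frame(x = c(0, 18, 36), y = c(0, 0, 0))
  ts <- tracks_from_matrix(m, pos)
  res <- connectivity_correlation(ts, D_values = D, n_perm = 9)
  cls <- attr(res, "classes")[["20"]]
  pt <- attr(res, "pair_table")
  lab <- function(i, j) as.character(cls[pt$i == i & pt$j == j])
  expect_equal(lab(1, 2), "direct")
  expect_equal(lab(2, 3), "direct")
  expect_equal(lab(1, 3), "indirect")
  # D below the minimum distance: everything unconnected
  res0 <- connectivity_correlation(ts, D_values = 10, n_perm = 9)
  expect_true(all(attr(res0, "classes")[["10"]] == "unconnected"))
})

test_that("connectivity components agree with the igraph oracle", {
  skip_if_not_installed("igraph")
  set.seed(708)
  for (rep_i in 1:3) {
    n <- 40
    pos <- data.frame(x = runif(n, 0, 120), y = runif(n, 0, 120))
    m <- matrix(rnorm(30 * n), ncol = n)
    ts <- tracks_from_matrix(m, pos)
    D <- 25
    res <- connectivity_correlation(ts, D_values = D, n_perm = 5)
    cls <- attr(res, "classes")[[as.character(D)]]
    pt <- attr(res, "pair_table")
    g <- igraph::graph_from_data_frame(
      data.frame(from = pt$i[pt$dist < D], to = pt$j[pt$dist < D]),
      directed = FALSE, vertices = data.frame(name = 1:n))
    comp <- igraph::components(g)$membership
    same <- comp[pt$i] == comp[pt$j]
    expect_equal(cls == "direct" | cls == "indirect", unname(same))
    expect_equal(cls == "direct", pt$dist < D)
  }
})

test_that("direct pairs at D1 stay connected at any larger D2", {
  set.seed(709)
  n <- 30
  pos <- data.frame(x = runif(n, 0, 100), y = runif(n, 0, 100))
  m <- matrix(rnorm(30 * n), ncol = n)
  ts <- tracks_from_matrix(m, pos)
  res <- connectivity_correlation(ts, D_values = c(15, 30), n_perm = 5)
  cl1 <- attr(res, "classes")[["15"]]
  cl2 <- attr(res, "classes")[["30"]]
  direct1 <- cl1 == "direct"
  connected2 <- cl2 != "unconnected"
  expect_true(all(connected2[direct1]))
})

test_that("simultaneous switches give zero synchrony intervals", {
  profs <- lapply(1:3, function(i)
    profile_set(paste0("c", i), list(
      transcription_profile(20, c(2, 8), c(0, 46), 1))))
  pos <- data.frame(x = c(0, 10, 50), y = c(0, 0, 0))
  out <- switch_synchrony(profs, pos, R = 1)
  expect_true(all(out$intervals$dt == 0))
  expect_true(all(out$intervals$direction == "same"))
})

test_that("coupled tissue reproduces the near/far same-direction ordering", {
  set.seed(710)
  sim <- simulate_tissue(n_cells = 90, field = c(0, 240, 0, 240))
  cells <- lapply(seq_along(sim$truth$profiles), function(i) {
    p <- sim$truth$profiles[[i]]
    profile_set(sprintf("c%03d", i), list(p))
  })
  out <- switch_synchrony(cells, sim$truth$positions, threshold = 30, R = 1)
  ks <- out$ks
  same_row <- ks[ks$comparison == "same_near_vs_far", ]
  expect_lt(same_row$p_value, 0.01)
  near <- out$intervals$dt[out$intervals$direction == "same" &
                             out$intervals$near]
  far <- out$intervals$dt[out$intervals$direction == "same" &
                            !out$intervals$near]
  expect_lt(median(near), median(far))
})
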