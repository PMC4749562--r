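#' Ripley's K with a CSR simulation envelope
#'
#' Second-order summary of a 2-D point pattern with translation edge
#' correction on a rectangular field, compared to the CSR expectation
#' `K_theo(r) = pi r^2` and a pointwise envelope from CSR simulations with
#' the same n and field (2.5/97.5 percentiles for the 95% band).  A
#' hard-core pattern (finite cell size) dips below the lower envelope at
#' radii under the exclusion distance; clustering rises above the upper
#' envelope.  The envelope is rank-based (by default the pointwise min/max
#' of the simulations, the Besag convention): with `n_sim = 39` its
#' pointwise coverage is exactly 95%, with `n_sim = 99` it is conservative
#' (98%).  Raise `n_rank` for narrower bands.
#'
#' @param positions data.frame with `x`, `y` (um); at least 10 points.
#' @param field rectangle `c(xmin, xmax, ymin, ymax)`; default the bounding
#'   box of the points.
#' @param radii evaluation radii (um); default 25 radii up to a quarter of
#'   the shorter field side.
#' @param n_sim number of CSR simulations for the envelope.
#' @param n_rank envelope rank: the band runs from the `n_rank`-th
#'   smallest to the `n_rank`-th largest simulated value (pointwise
#'   coverage `1 - 2 n_rank / (n_sim + 1)`).
#' @return object of class `ripley_result`: data.frame columns `r`,
#'   `K_obs`, `K_theo`, `K_lo`, `K_hi`, plus attribute `"field"`.
#' @export
ripley_k <- function(positions, field = NULL, radii = NULL, n_sim = 99,
                     n_rank = 1) {
  n <- nrow(positions)
  if (n < 10L) stop("need >= 10 points")
  if (is.null(field))
    field <- c(range(positions$x), range(positions$y))
  a <- field[2] - field[1]; b <- field[4] - field[3]
  if (a <= 0 || b <= 0) stop("degenerate field")
  if (is.null(radii)) radii <- seq(0, min(a, b) / 4, length.out = 26)[-1]
  if (max(radii) >= sqrt(a^2 + b^2) / 2)
    stop("radii must stay below half the field diameter")

  k_of <- function(x, y) {
    dx <- abs(outer(x, x, "-")); dy <- abs(outer(y, y, "-"))
    d <- sqrt(dx^2 + dy^2)
    keep <- upper.tri(d)
    dv <- d[keep]
    # translation correction: weight 1 / area of overlap of the field with
    # itself translated by the pair separation
    wv <- (a * b) / ((a - dx[keep]) * (b - dy[keep]))
    vapply(radii, function(r) sum(wv[dv <= r]) * 2, numeric(1)) *
      (a * b) / (n * (n - 1))
  }

  k_obs <- k_of(positions$x, positions$y)
  sims <- vapply(seq_len(n_sim), function(i)
    k_of(stats::runif(n, field[1], field[2]),
         stats::runif(n, field[3], field[4])),
    numeric(length(radii)))
  sims <- matrix(sims, nrow = length(radii))
  stopifnot(n_rank >= 1, 2 * n_rank < n_sim)
  out <- data.frame(r = radii, K_obs = k_obs, K_theo = pi * radii^2,
                    K_lo = apply(sims, 1, function(v) sort(v)[n_rank]),
                    K_hi = apply(sims, 1, function(v)
                      sort(v, decreasing = TRUE)[n_rank]))
  attr(out, "field") <- field
  class(out) <- c("ripley_result", "data.frame")
  out
}

#' Correlation between two time series
#'
#' With `standardize = TRUE` (default) both series are mean-centred and
#' unit-scaled first, making the statistic Pearson's r; with
#' `standardize = FALSE` the literal mean cross-product `N^-1 sum(x_i y_i)`
#' is returned (only scale-free if the inputs were pre-standardised).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param standardize see above.
#' @return scalar; in `[-1, 1]` when standardised.
#' @export
pair_correlation <- function(x, y, standardize = TRUE) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3L)
  if (standardize) {
    sx <- stats::sd(x) * sqrt((n - 1) / n)
    sy <- stats::sd(y) * sqrt((n - 1) / n)
    if (sx == 0 || sy == 0) stop("zero-variance series cannot be standardised")
    x <- (x - mean(x)) / sx
    y <- (y - mean(y)) / sy
  }
  mean(x * y)
}

# all-pairs correlation matrix (standardized) and pair table with
# distances and distance-bin assignment
pair_table <- function(ts, bin_width = 5, bin_start = 5, max_dist = Inf) {
  pos <- median_positions(ts)
  m <- fluor_matrix(ts)
  n <- ncol(m)
  if (n < 2L) stop("need >= 2 cells")
  ms <- scale(m)                       # columns standardised (n-1 scaling
  C <- crossprod(ms) / (nrow(m) - 1)   # cancels in the ratio: Pearson r)
  idx <- which(upper.tri(C), arr.ind = TRUE)
  d <- sqrt((pos$x[idx[, 1]] - pos$x[idx[, 2]])^2 +
              (pos$y[idx[, 1]] - pos$y[idx[, 2]])^2)
  keep <- d <= max_dist
  idx <- idx[keep, , drop = FALSE]; d <- d[keep]
  # half-open bins [5k, 5(k+1)) from bin_start; pairs below bin_start join
  # the first bin
  bin_lo <- pmax(bin_start, floor(d / bin_width) * bin_width)
  bin_lo[d < bin_start + bin_width] <- bin_start
  list(i = idx[, 1], j = idx[, 2], dist = d, bin_lo = bin_lo,
       corr = C[idx], C = C, n_cells = n)
}

#' Distance-binned correlation with bootstrap bands
#'
#' Cell pairs are partitioned into half-open distance bins (5-um width
#' starting at 5 um; closer pairs join the first bin) by the distance
#' between median cell positions.  Per bin, the correlation analysis is
#' repeated `n_boot` times with the bin's n pairs resampled with
#' replacement, recording the median each time; the 5th/95th percentiles
#' of those medians form the 90% confidence band.
#'
#' @param ts a [track_set()] (fluorescence should be preprocessed).
#' @param bin_width,bin_start bin geometry (um).
#' @param max_dist ignore pairs farther apart than this (um).
#' @param n_boot bootstrap resamples per bin (default 99).
#' @param normalise_pairs subsample every bin to the smallest bin's pair
#'   count first (the pair-count normalisation control).
#' @return object of class `distance_bin_correlation`: data.frame with
#'   `bin_lo`, `bin_hi`, `n_pairs`, `median_corr`, `boot_lo`, `boot_hi`.
#' @export
correlation_vs_distance <- function(ts, bin_width = 5, bin_start = 5,
                                    max_dist = 100, n_boot = 99,
                                    normalise_pairs = FALSE) {
  pt <- pair_table(ts, bin_width, bin_start, max_dist)
  bins <- sort(unique(pt$bin_lo))
  per_bin <- lapply(bins, function(b) pt$corr[pt$bin_lo == b])
  if (normalise_pairs) {
    n_min <- min(lengths(per_bin))
    per_bin <- lapply(per_bin, function(v)
      if (length(v) > n_min) sample(v, n_min) else v)
  }
  rows <- mapply(function(b, v) {
    med <- vapply(seq_len(n_boot), function(k)
      stats::median(sample(v, length(v), replace = TRUE)), numeric(1))
    data.frame(bin_lo = b, bin_hi = b + bin_width, n_pairs = length(v),
               median_corr = stats::median(v),
               boot_lo = stats::quantile(med, 0.05),
               boot_hi = stats::quantile(med, 0.95))
  }, bins, per_bin, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "pair_table") <- pt
  attr(out, "bin_values") <- per_bin
  class(out) <- c("distance_bin_correlation", "data.frame")
  out
}

#' Permutation null for the distance-correlation profile
#'
#' Traces are randomly permuted across cells while the spatial information
#' is unaltered, which preserves the correlation matrix and only
#' re-assigns pairs to distance bins.  Each bin's observed median
#' correlation is compared with its permutation distribution
#' (`p = (1 + #(perm >= obs)) / (n_perm + 1)`, one-sided for observed >
#' permuted — a calibrated Monte-Carlo test).  A paired t-test of the
#' `n_boot` observed against `n_boot` permuted bootstrap medians is also
#' reported per bin for descriptive comparability, but the significance
#' call uses the permutation p-value: the t-test treats dependent
#' bootstrap replicates as independent and badly overstates evidence.
#' The significant range is the maximal run of contiguous bins with
#' `p < p_threshold` (the longest such run; ties resolved toward the
#' shorter distances).
#'
#' @param ts a [track_set()].
#' @param n_perm number of label permutations (default 1999).
#' @param p_threshold per-bin significance threshold (default 0.001).
#' @param n_boot bootstrap resamples for the descriptive band and t-test.
#' @inheritParams correlation_vs_distance
#' @return list with `bins` (data.frame: bin geometry, observed median,
#'   permutation percentiles, `p_perm`, `p_ttest`, `significant`) and
#'   `significant_range` (`c(lo, hi)` in um, or `NULL`).
#' @export
permutation_null <- function(ts, bin_width = 5, bin_start = 5,
                             max_dist = 100, n_perm = 1999,
                             p_threshold = 0.001, n_boot = 99) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  pt <- pair_table(ts, bin_width, bin_start, max_dist)
  bins <- sort(unique(pt$bin_lo))
  members <- lapply(bins, function(b) which(pt$bin_lo == b))
  obs_med <- vapply(members, function(mi)
    stats::median(pt$corr[mi]), numeric(1))

  n <- pt$n_cells
  lin_idx <- function(per) (per[pt$j] - 1L) * n + per[pt$i]
  perm_med <- matrix(NA_real_, n_perm, length(bins))
  for (k in seq_len(n_perm)) {
    per <- sample.int(n)
    pc <- pt$C[lin_idx(per)]
    perm_med[k, ] <- vapply(members, function(mi)
      stats::median(pc[mi]), numeric(1))
  }
  p_perm <- vapply(seq_along(bins), function(bi)
    (1 + sum(perm_med[, bi] >= obs_med[bi])) / (n_perm + 1), numeric(1))

  # descriptive paired t-test on bootstrap medians (the field's common
  # procedure; anti-conservative, reported for comparability only)
  p_t <- vapply(seq_along(bins), function(bi) {
    v_obs <- pt$corr[pt$bin_lo == bins[bi]]
    v_perm <- perm_med[, bi]
    bo <- vapply(seq_len(n_boot), function(j)
      stats::median(sample(v_obs, length(v_obs), replace = TRUE)), numeric(1))
    bp <- sample(v_perm, n_boot, replace = TRUE)
    if (stats::sd(bo - bp) == 0) return(1)
    stats::t.test(bo, bp, paired = TRUE)$p.value
  }, numeric(1))

  sig <- p_perm < p_threshold
  out <- data.frame(bin_lo = bins, bin_hi = bins + bin_width,
                    n_pairs = as.integer(table(factor(pt$bin_lo, levels = bins))),
                    median_corr = obs_med,
                    perm_lo = apply(perm_med, 2, stats::quantile, 0.05),
                    perm_hi = apply(perm_med, 2, stats::quantile, 0.95),
                    p_perm = p_perm, p_ttest = p_t, significant = sig)
  rownames(out) <- NULL
  range_out <- NULL
  if (any(sig)) {
    # maximal run: the longest run of contiguous significant bins, ties
    # resolved toward the shorter distances
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    range_out <- c(out$bin_lo[starts[best]], out$bin_hi[ends[best]])
  }
  list(bins = out, significant_range = range_out)
}

# --- connectivity ----------------------------------------------------------

# union-find with path compression
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
      if (ra != rb) parent[rb] <- ra
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Connectivity-network correlation analysis
#'
#' Cells are treated as discs of diameter D: two cells closer than D (by
#' median positions) are directly connected, and connectivity is
#' transitive, so cells joined through a chain of connections belong to one
#' component even when farther apart than D.  Pairs are classed directly
#' connected, indirectly connected (same component, distance >= D) or
#' unconnected, and each class's trace-correlation distribution is
#' summarised together with a permuted-trace baseline.  Repeated for each
#' threshold in `D_values`.
#'
#' @param ts a [track_set()] with >= 3 cells.
#' @param D_values numeric vector of threshold distances (um).
#' @param n_perm permutations for the baseline medians.
#' @return object of class `connectivity_result`: data.frame per (D,
#'   class): `D`, `class`, `n_pairs`, `median_corr`, `q1`, `q3`,
#'   `median_perm`.  Attribute `"classes"` holds the per-D pair
#'   classification (list of factors aligned with the pair table).
#' @export
connectivity_correlation <- function(ts, D_values = seq(10, 50, by = 10),
                                     n_perm = 99) {
  pt <- pair_table(ts)
  n <- pt$n_cells
  if (n < 3L) stop("need >= 3 cells")
  class_list <- list()
  rows <- list()
  for (D in D_values) {
    direct <- pt$dist < D
    comp <- uf_components(n, cbind(pt$i[direct], pt$j[direct]))
    same_comp <- comp[pt$i] == comp[pt$j]
    cls <- factor(ifelse(direct, "direct",
                         ifelse(same_comp, "indirect", "unconnected")),
                  levels = c("direct", "indirect", "unconnected"))
    class_list[[as.character(D)]] <- cls
    perm_meds <- matrix(NA_real_, n_perm, 3)
    for (k in seq_len(n_perm)) {
      per <- sample.int(n)
      pc <- pt$C[cbind(per[pt$i], per[pt$j])]
      perm_meds[k, ] <- vapply(levels(cls), function(lv) {
        v <- pc[cls == lv]
        if (length(v)) stats::median(v) else NA_real_
      }, numeric(1))
    }
    for (li in seq_along(levels(cls))) {
      lv <- levels(cls)[li]
      v <- pt$corr[cls == lv]
      rows[[length(rows) + 1L]] <- data.frame(
        D = D, class = lv, n_pairs = length(v),
        median_corr = if (length(v)) stats::median(v) else NA_real_,
        q1 = if (length(v)) stats::quantile(v, 0.25) else NA_real_,
        q3 = if (length(v)) stats::quantile(v, 0.75) else NA_real_,
        median_perm = mean(perm_meds[, li], na.rm = TRUE))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "classes") <- class_list
  attr(out, "pair_table") <- pt
  class(out) <- c("connectivity_result", "data.frame")
  out
}

#' Switch-direction synchrony between cell pairs
#'
#' For each cell pair, one transcriptional profile is sampled per cell
#' (weight proportional) and every pair of switches — one per cell — is
#' classified by direction (same: both up or both down; opposite) and by
#' the distance between the cells (at or below the threshold versus
#' above).  The absolute time interval |dt| between the two switches is
#' recorded.  Resampling is repeated `R` times and pooled to reduce
#' profile-sampling noise (`R = 1` mirrors a single random draw).
#' One-sided KS statistics (how far the near CDF sits to the left of the
#' far CDF — the coordination hypothesis is directional) compare near
#' versus far intervals within each direction class.  Because the switch
#' pairs of one cell pair share switches (they are strongly dependent),
#' an iid KS p-value would be wildly anti-conservative at these sample
#' sizes; the reported p-value instead comes from a calibrated
#' permutation test that shuffles the near/far labels over whole cell
#' pairs, keeping each pair's switch-pair cluster intact.
#'
#' @param cells list of [profile_set()] objects.
#' @param positions data.frame with `x`, `y`, rows aligned with `cells`.
#' @param threshold distance threshold (um, default 30).
#' @param R number of profile resampling rounds.
#' @param n_perm label permutations for the KS p-values.
#' @param max_pairs cell-pair cap per class side (larger sides are
#'   subsampled at the cell-pair level before testing, for speed).
#' @return object of class `synchrony_result`: list with `intervals`
#'   (data.frame: pair_id, dt, direction, near), `ks` (data.frame per
#'   comparison: statistic, p_value), and counts of skipped no-switch
#'   cells.
#' @export
switch_synchrony <- function(cells, positions, threshold = 30, R = 100,
                             n_perm = 199, max_pairs = 2000) {
  n <- length(cells)
  stopifnot(n >= 2L, nrow(positions) == n)
  d <- as.matrix(stats::dist(positions[, c("x", "y")]))
  rows <- vector("list", 1000); ri <- 0L
  no_switch <- 0L
  for (rep_i in seq_len(R)) {
    profs <- lapply(cells, sample_profile)
    sws <- lapply(profs, function(p) {
      if (length(p$switch_times) == 0L) return(NULL)
      data.frame(t = p$switch_times, up = diff(p$rates) > 0)
    })
    if (rep_i == 1L) no_switch <- sum(vapply(sws, is.null, logical(1)))
    for (a in seq_len(n - 1)) {
      if (is.null(sws[[a]])) next
      for (b in (a + 1):n) {
        if (is.null(sws[[b]])) next
        dt <- abs(outer(sws[[a]]$t, sws[[b]]$t, "-"))
        same <- outer(sws[[a]]$up, sws[[b]]$up, "==")
        ri <- ri + 1L
        if (ri > length(rows)) rows <- c(rows, vector("list", length(rows)))
        rows[[ri]] <- data.frame(pair_id = (a - 1L) * n + b,
                                 dt = as.vector(dt),
                                 direction = ifelse(as.vector(same),
                                                    "same", "opposite"),
                                 near = d[a, b] <= threshold)
      }
    }
  }
  intervals <- do.call(rbind, rows[seq_len(ri)])
  ks <- rbind(
    ks_cluster_perm("same_near_vs_far",
                    intervals[intervals$direction == "same", ],
                    n_perm, max_pairs),
    ks_cluster_perm("opposite_near_vs_far",
                    intervals[intervals$direction == "opposite", ],
                    n_perm, max_pairs))
  structure(list(intervals = intervals, ks = ks, threshold = threshold,
                 n_no_switch_cells = no_switch),
            class = "synchrony_result")
}

# KS comparison of near vs far interval CDFs with a cell-pair-level label
# permutation null; `df` has columns pair_id, dt, near
ks_cluster_perm <- function(label, df, n_perm, max_pairs) {
  ids_near <- unique(df$pair_id[df$near])
  ids_far <- unique(df$pair_id[!df$near])
  if (length(ids_near) < 3L || length(ids_far) < 3L ||
      sum(df$near) < 3L || sum(!df$near) < 3L)
    return(data.frame(comparison = label, statistic = NA_real_,
                      p_value = NA_real_, n_x = sum(df$near),
                      n_y = sum(!df$near)))
  if (length(ids_near) > max_pairs)
    df <- df[!df$near | df$pair_id %in% sample(ids_near, max_pairs), ]
  if (length(ids_far) > max_pairs)
    df <- df[df$near | df$pair_id %in% sample(ids_far, max_pairs), ]
  ids <- unique(df$pair_id)
  near_ids <- unique(df$pair_id[df$near])
  ord <- order(df$dt)
  pid_sorted <- match(df$pair_id[ord], ids)
  is_near_pair <- ids %in% near_ids

  # one-sided KS statistic: how far the near CDF sits to the LEFT of the
  # far CDF (the coordination hypothesis is directional: near pairs switch
  # more synchronously, never less)
  ks_d <- function(near_pair_flags) {
    z <- near_pair_flags[pid_sorted]
    n1 <- sum(z); n0 <- length(z) - n1
    if (n1 == 0L || n0 == 0L) return(NA_real_)
    max(cumsum(z) / n1 - cumsum(!z) / n0)
  }
  d_obs <- ks_d(is_near_pair)
  n_near <- sum(is_near_pair)
  d_perm <- vapply(seq_len(n_perm), function(k) {
    flags <- logical(length(ids))
    flags[sample.int(length(ids), n_near)] <- TRUE
    ks_d(flags)
  }, numeric(1))
  data.frame(comparison = label, statistic = d_obs,
             p_value = (1 + sum(d_perm >= d_obs, na.rm = TRUE)) /
               (n_perm + 1),
             n_x = sum(df$near), n_y = sum(!df$near))
}
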