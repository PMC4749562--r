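#' Fit a Gaussian mixture to the marginal posterior of switch times
#'
#' Pools all switch-time draws across retained MCMC iterations and fits
#' univariate Gaussian mixtures with 1..`c_max` components, selecting the
#' component count by BIC.  The fitted components are the candidate switch
#' times of the cell.
#'
#' @param samples a `posterior_samples` object.
#' @param c_max maximum number of mixture components.
#' @return object of class `candidate_switch_set`: `means` (sorted), `sds`,
#'   `proportions`, `n_draws`; empty (zero components) when all draws have
#'   K = 0.
#' @export
fit_switch_mixture <- function(samples, c_max = 8) {
  pool <- pooled_switch_times(samples)
  empty <- structure(list(means = numeric(0), sds = numeric(0),
                          proportions = numeric(0), n_draws = 0L),
                     class = "candidate_switch_set")
  if (length(pool) == 0L) return(empty)
  g_max <- max(1L, min(c_max, floor(length(pool) / 5)))
  if (length(unique(pool)) == 1L) {
    return(structure(list(means = pool[1], sds = 1e-6, proportions = 1,
                          n_draws = length(pool)),
                     class = "candidate_switch_set"))
  }
  fit <- Mclust(pool, G = 1:g_max, modelNames = c("E", "V"),
                verbose = FALSE)
  mu <- as.numeric(fit$parameters$mean)
  var <- fit$parameters$variance$sigmasq
  if (length(var) == 1L) var <- rep(var, length(mu))
  ord <- order(mu)
  structure(list(means = mu[ord], sds = sqrt(var[ord]),
                 proportions = as.numeric(fit$parameters$pro)[ord],
                 n_draws = length(pool)),
            class = "candidate_switch_set")
}

#' @export
print.candidate_switch_set <- function(x, ...) {
  cat(sprintf("<candidate_switch_set> %d component(s) from %d draws\n",
              length(x$means), x$n_draws))
  if (length(x$means))
    cat("  means:", paste(signif(x$means, 4), collapse = ", "), "\n")
  invisible(x)
}

# map one draw's switch times to candidate components; NULL = unclassifiable
assign_draw <- function(s, candidates, n_sd = 3) {
  if (length(s) == 0L) return(integer(0))
  hits <- vapply(s, function(si) {
    z <- abs(si - candidates$means) / candidates$sds
    j <- which.min(z)
    if (z[j] <= n_sd) j else NA_integer_
  }, integer(1))
  if (anyNA(hits) || anyDuplicated(hits)) return(NULL)
  sort(hits)
}

#' Enumerate sub-models from the candidate switch set
#'
#' Each MCMC draw is mapped to the subset of candidate switch components
#' its switches fall in (nearest component within `n_sd` SDs; draws with an
#' unassignable switch are dropped as unclassifiable, with a count
#' reported).  Counting how often each subset was sampled gives the
#' sub-model weights; each sub-model's rates are the posterior means of the
#' interval rates conditional on that sub-model.  The result is the cell's
#' set of mutually exclusive transcriptional profiles.
#'
#' @param samples a `posterior_samples` object.
#' @param candidates a `candidate_switch_set` from [fit_switch_mixture()]
#'   on the same samples.
#' @param cell_id identifier for the output [profile_set()].
#' @param n_sd assignment window in component SDs.
#' @param max_unclassifiable error when more than this fraction of draws is
#'   unclassifiable (the mixture fit is then inadequate).
#' @return a [profile_set()]; sub-models never sampled carry zero weight
#'   and are pruned.
#' @export
enumerate_submodels <- function(samples, candidates, cell_id = "cell",
                                n_sd = 3, max_unclassifiable = 0.5) {
  n <- length(samples$K)
  stopifnot(n >= 1L)
  if (length(candidates$means) == 0L) {
    rate <- mean(vapply(samples$rates, function(b) b[1], numeric(1)))
    prof <- transcription_profile(numeric(0), rate, samples$window, 1)
    return(profile_set(cell_id, list(prof)))
  }
  keys <- character(n)
  assigns <- vector("list", n)
  for (i in seq_len(n)) {
    a <- assign_draw(samples$switch_times[[i]], candidates, n_sd)
    if (is.null(a)) keys[i] <- NA_character_
    else { keys[i] <- paste(a, collapse = ","); assigns[[i]] <- a }
  }
  drop <- is.na(keys)
  if (mean(drop) > max_unclassifiable)
    stop(sprintf("%.0f%% of draws unclassifiable: mixture fit inadequate",
                 100 * mean(drop)))
  if (any(drop))
    message(sum(drop), " unclassifiable draw(s) dropped")
  keys_ok <- keys[!drop]
  idx_ok <- which(!drop)
  tab <- table(keys_ok)
  profs <- lapply(names(tab), function(key) {
    members <- idx_ok[keys_ok == key]
    comp <- if (nzchar(key)) as.integer(strsplit(key, ",")[[1]]) else integer(0)
    s <- candidates$means[comp]
    # draws in this sub-model share K = length(comp), so rates align
    rates <- colMeans(do.call(rbind, samples$rates[members]))
    w <- length(members) / length(idx_ok)
    tryCatch(transcription_profile(s, rates, samples$window, weight = w),
             error = function(e) NULL)
  })
  keep <- !vapply(profs, is.null, logical(1))
  profs <- profs[keep]
  w <- vapply(profs, function(p) p$weight, numeric(1))
  profs <- lapply(profs, function(p) { p$weight <- p$weight / sum(w); p })
  profile_set(cell_id, profs)
}

#' Draw one profile from a weighted profile set
#'
#' @param ps a [profile_set()].
#' @return one [transcription_profile()], drawn with probability equal to
#'   its weight.
#' @export
sample_profile <- function(ps) {
  w <- profile_set_weights(ps)
  ps$profiles[[sample.int(length(w), 1, prob = w)]]
}

#' Weighted histogram of switch counts
#'
#' Each profile contributes its probability weight at its switch count K,
#' so the histogram is the posterior-weighted distribution of the number
#' of switches across cells.
#'
#' @param cells list of [profile_set()] objects.
#' @return data.frame with columns `K` and `weight` (summed over cells;
#'   divide by `length(cells)` for a per-cell average), plus attribute
#'   `"expected_per_cell"`, the per-cell expected switch counts.
#' @export
switch_count_summary <- function(cells) {
  stopifnot(length(cells) >= 1L)
  ks <- unlist(lapply(cells, function(ps)
    vapply(ps$profiles, function(p) length(p$switch_times), integer(1))))
  ws <- unlist(lapply(cells, profile_set_weights))
  agg <- tapply(ws, ks, sum)
  out <- data.frame(K = as.integer(names(agg)), weight = as.numeric(agg))
  attr(out, "expected_per_cell") <- vapply(cells, function(ps)
    sum(vapply(ps$profiles, function(p)
      length(p$switch_times) * p$weight, numeric(1))), numeric(1))
  out
}

weighted_silverman_bw <- function(x, w) {
  w <- w / sum(w)
  mu <- sum(w * x)
  sdw <- sqrt(max(sum(w * (x - mu)^2), 1e-12))
  n_eff <- 1 / sum(w^2)
  iqr <- diff(weighted_quantile(x, w, c(0.25, 0.75)))
  0.9 * min(sdw, if (iqr > 0) iqr / 1.34 else sdw) * n_eff^(-1 / 5)
}

#' Weighted distribution of transcription rates
#'
#' Pools every profile interval as a (rate, weight x duration) pair — an
#' interval's contribution is proportional to how long the cell spends at
#' that rate times the profile's probability — and returns a weighted
#' Gaussian kernel estimate (Silverman bandwidth on the weighted sample).
#'
#' @param cells list of [profile_set()] objects.
#' @param mode `"density"` or `"cdf"`.
#' @param n grid size.
#' @return data.frame with columns `rate` and `density` (or `cdf`);
#'   attribute `"samples"` holds the pooled weighted sample.
#' @export
rate_distribution <- function(cells, mode = c("density", "cdf"), n = 512) {
  mode <- match.arg(mode)
  pooled <- do.call(rbind, lapply(cells, function(ps)
    do.call(rbind, lapply(ps$profiles, function(p) {
      d <- profile_durations(p)
      data.frame(rate = d$rate, w = p$weight * d$duration)
    }))))
  stopifnot(nrow(pooled) >= 1L)
  w <- pooled$w / sum(pooled$w)
  if (length(unique(pooled$rate)) == 1L) {
    bw <- max(abs(pooled$rate[1]) * 0.05, 0.05)
  } else {
    bw <- weighted_silverman_bw(pooled$rate, w)
  }
  den <- stats::density(pooled$rate, weights = w, bw = bw, n = n,
                        from = max(0, min(pooled$rate) - 3 * bw),
                        to = max(pooled$rate) + 3 * bw)
  out <- if (mode == "density") {
    data.frame(rate = den$x, density = den$y)
  } else {
    dx <- diff(den$x[1:2])
    data.frame(rate = den$x, cdf = cumsum(den$y) * dx / sum(den$y * dx))
  }
  attr(out, "samples") <- pooled
  out
}

#' Durations of transcriptional states by rate bin
#'
#' Bins transcription rates (deciles, or the lowest three quartiles versus
#' the top quartile) using edges from the weighted pooled rate
#' distribution, then repeatedly samples one profile per cell (weight
#' proportional) and collects each interval's duration into its rate's
#' bin.  Window-truncated first/last intervals are censored — their
#' durations are minimum durations — but are included, flagged, rather
#' than dropped.
#'
#' @param cells list of [profile_set()] objects.
#' @param binning `"deciles"` or `"q75_split"`.
#' @param n_draws number of profile-sampling repetitions.
#' @return list with `samples` (data.frame: bin, rate, duration, censored,
#'   draw), `edges`, and `stats` (per bin: n, median, q1, q3, whisker_lo,
#'   whisker_hi).
#' @export
duration_by_rate_bin <- function(cells, binning = c("deciles", "q75_split"),
                                 n_draws = 50) {
  binning <- match.arg(binning)
  rd <- rate_distribution(cells, "density")
  pooled <- attr(rd, "samples")
  probs <- if (binning == "deciles") seq(0.1, 0.9, by = 0.1) else 0.75
  edges <- weighted_quantile(pooled$rate, pooled$w, probs)
  edges <- c(-Inf, unique(edges), Inf)
  labels <- if (binning == "q75_split") c("<75", ">75") else
    paste0("D", seq_len(length(edges) - 1))

  rows <- list()
  for (d in seq_len(n_draws)) {
    for (ps in cells) {
      p <- sample_profile(ps)
      du <- profile_durations(p)
      bin <- cut(du$rate, edges, labels = labels, right = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        bin = as.character(bin), rate = du$rate, duration = du$duration,
        censored = du$censored, draw = d)
    }
  }
  samples <- do.call(rbind, rows)
  stats_df <- do.call(rbind, lapply(labels, function(lb) {
    x <- samples$duration[samples$bin == lb]
    if (length(x) == 0L)
      return(data.frame(bin = lb, n = 0L, median = NA, q1 = NA, q3 = NA,
                        whisker_lo = NA, whisker_hi = NA))
    bs <- grDevices::boxplot.stats(x)$stats
    data.frame(bin = lb, n = length(x), median = bs[3], q1 = bs[2],
               q3 = bs[4], whisker_lo = bs[1], whisker_hi = bs[5])
  }))
  list(samples = samples, edges = edges, stats = stats_df)
}

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Classify profile intervals as Low or Active
#'
#' An interval's rate is "Low" if it is preceded and followed by higher
#' rates; every other rate — including boundary intervals — is "Active".
#' Intended for profiles with at least one switch (no-switch cells are
#' excluded from this analysis upstream).
#'
#' @param profile a [transcription_profile()] with K >= 1.
#' @return character vector of labels, one per interval.
#' @export
classify_low_active <- function(profile) {
  r <- profile$rates
  k <- length(r)
  if (k < 2L) stop("classification needs a profile with at least one switch")
  labels <- rep("Active", k)
  if (k >= 3L) {
    for (i in 2:(k - 1)) {
      if (r[i - 1] > r[i] && r[i + 1] > r[i]) labels[i] <- "Low"
    }
  }
  labels
}

#' Complete inter-switch durations
#'
#' Only profiles with more than one switch contribute: their interior
#' intervals are fully observed, so the total time spent in a single
#' transcriptional state is known (not just a minimum).  Each duration is
#' weighted by its profile's probability.
#'
#' @param cells list of [profile_set()] objects.
#' @param bw kernel bandwidth (`NULL` = weighted Silverman).
#' @param n grid size for the kernel density.
#' @return list with `samples` (data.frame: duration, weight) and
#'   `density` (data.frame: duration, density), both `NULL` if nothing
#'   contributes.
#' @export
inter_switch_times <- function(cells, bw = NULL, n = 512) {
  rows <- do.call(rbind, lapply(cells, function(ps)
    do.call(rbind, lapply(ps$profiles, function(p) {
      k <- length(p$switch_times)
      if (k < 2L) return(NULL)
      data.frame(duration = diff(p$switch_times), weight = p$weight)
    }))))
  if (is.null(rows) || nrow(rows) == 0L)
    return(list(samples = NULL, density = NULL))
  w <- rows$weight / sum(rows$weight)
  if (is.null(bw))
    bw <- if (length(unique(rows$duration)) > 1L)
      weighted_silverman_bw(rows$duration, w) else 1
  den <- stats::density(rows$duration, weights = w, bw = bw, n = n,
                        from = 0, to = max(rows$duration) + 3 * bw)
  list(samples = rows,
       density = data.frame(duration = den$x, density = den$y))
}

# cell-level weighted duration sample: pick a profile by weight, then one
# of its intervals uniformly
sample_cell_duration <- function(ps) {
  p <- sample_profile(ps)
  d <- profile_durations(p)
  d$duration[sample.int(nrow(d), 1)]
}

#' Bootstrap Mann-Whitney comparison of duration distributions
#'
#' For each bootstrap replicate, one duration is sampled per cell from its
#' weighted profile distribution and a Mann-Whitney U-test compares the
#' two groups; the histogram of the replicate p-values is summarised by
#' the mass lying below a Bonferroni-corrected significance line (default
#' 0.5%, i.e. an overall 5% level corrected for multiple testing).
#'
#' @param group_a,group_b lists of [profile_set()] objects.
#' @param B number of bootstrap replicates (>= 100 recommended; B = 1
#'   degenerates to a single test).
#' @param alpha_line the corrected significance line.
#' @return list with `p_values`, `frac_below` and `significant`
#'   (`frac_below > 0.5`: the histogram lies mostly left of the line).
#' @export
bootstrap_mannwhitney <- function(group_a, group_b, B = 200,
                                  alpha_line = 0.005) {
  stopifnot(length(group_a) >= 1L, length(group_b) >= 1L, B >= 1L)
  pv <- vapply(seq_len(B), function(b) {
    xa <- vapply(group_a, sample_cell_duration, numeric(1))
    xb <- vapply(group_b, sample_cell_duration, numeric(1))
    suppressWarnings(stats::wilcox.test(xa, xb)$p.value)
  }, numeric(1))
  frac <- mean(pv < alpha_line)
  list(p_values = pv, frac_below = frac, alpha_line = alpha_line,
       significant = frac > 0.5)
}
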