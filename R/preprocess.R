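#' Fuse dual-detector fluorescence channels
#'
#' When the signal range exceeds the detection range, two detectors at
#' different sensitivities image the same cells.  The sensitive channel is
#' regressed on the insensitive channel over timepoints where the sensitive
#' channel is below its saturation ceiling; the fused trace uses the
#' sensitive channel below the threshold and the regression-rescaled
#' insensitive channel above it.
#'
#' @param track a [cell_track()] with exactly two channels.
#' @param sensitive,insensitive channel labels or indices; by default
#'   channels 1 and 2 respectively.
#' @param ceiling saturation ceiling of the sensitive channel (a.u.); points
#'   at or above it are excluded from the regression fit.
#' @param threshold `"auto"` (95% of `ceiling`) or a numeric value below
#'   `ceiling`; above it the rescaled insensitive channel is used.
#' @return list with `track` (single-channel fused [cell_track()]) and
#'   `fit` (class `fusion_fit`: slope, intercept, threshold, r_squared,
#'   n_points).
#' @export
fuse_detectors <- function(track, sensitive = 1L, insensitive = 2L,
                           ceiling, threshold = "auto") {
  if (ncol(track$fluor) == 1L) {   # already fused: identity pass-through
    return(list(track = track,
                fit = structure(list(slope = 1, intercept = 0,
                                     threshold = Inf, r_squared = 1,
                                     n_points = length(track$times)),
                                class = "fusion_fit")))
  }
  if (ncol(track$fluor) != 2L) stop("fuse_detectors needs 1 or 2 channels")
  s <- track$fluor[, sensitive]
  i <- track$fluor[, insensitive]
  ok <- s < ceiling
  if (sum(ok) < 5L)
    stop("fewer than 5 unsaturated points: fusion fit not identifiable")
  fit <- stats::lm(s[ok] ~ i[ok])
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0)
    stop("non-positive fitted slope: channels inconsistent")
  if (identical(threshold, "auto")) threshold <- 0.95 * ceiling
  if (threshold >= ceiling)
    stop("threshold must lie below the saturation ceiling")
  fused <- ifelse(s < threshold, s, intercept + slope * i)
  out <- cell_track(track$cell_id, track$times, pmax(fused, 0),
                    track$centroids, channel_labels = "fused")
  list(track = out,
       fit = structure(list(slope = slope, intercept = intercept,
                            threshold = threshold,
                            r_squared = suppressWarnings(summary(fit)$r.squared),
                            n_points = sum(ok)),
                       class = "fusion_fit"))
}

#' Subtract the mean background trace
#'
#' Subtracts, per timepoint, the mean of the background traces (the
#' mean-of-areas convention) from every cell trace.  Negative results are
#' floored at 0; the count of floored values is reported via a message so
#' the data change is never silent.
#'
#' @param ts a [track_set()] with at least one background trace (or the
#'   explicit zero-background flag, in which case this is the identity).
#' @return a background-subtracted [track_set()].
#' @export
subtract_background <- function(ts) {
  if (length(ts$background) == 0L) return(ts)
  bg <- rowMeans(do.call(cbind, ts$background))
  n_floor <- 0L
  tracks <- lapply(ts$tracks, function(tr) {
    fl <- sweep(tr$fluor, 1, bg)
    n_floor <<- n_floor + sum(fl < 0)
    fl <- pmax(fl, 0)
    cell_track(tr$cell_id, tr$times, fl, tr$centroids, tr$channel_labels)
  })
  if (n_floor > 0)
    message(n_floor, " negative value(s) floored at 0 after background subtraction")
  track_set(tracks, background = list(), metadata = ts$metadata,
            zero_background = TRUE)
}

#' Autocorrelation diagnostic against a white-noise band
#'
#' Sample autocorrelation of the mean-centred trace at lags 1..`max_lag`
#' (biased 1/N normalisation), with the +-1.96/sqrt(N) band under which a
#' white-noise process stays with 95% probability, and flags for lags
#' outside the band.  A trace whose autocorrelation leaves the band shows
#' temporal structure beyond measurement noise.
#'
#' @param trace numeric vector, length >= 10.
#' @param max_lag maximum lag (must be < length(trace)/2).
#' @return data.frame with columns `lag`, `acf`, `band_lo`, `band_hi`,
#'   `outside`.
#' @export
autocorrelation_diagnostic <- function(trace, max_lag = 20) {
  n <- length(trace)
  if (n < 10L) stop("trace too short (need >= 10 points)")
  if (max_lag >= n / 2) stop("max_lag must be < length(trace)/2")
  if (stats::sd(trace) == 0) stop("zero-variance trace")
  r <- stats::acf(trace, lag.max = max_lag, plot = FALSE,
                  demean = TRUE)$acf[-1]
  band <- 1.96 / sqrt(n)
  data.frame(lag = seq_len(max_lag), acf = as.numeric(r),
             band_lo = -band, band_hi = band,
             outside = abs(as.numeric(r)) > band)
}
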