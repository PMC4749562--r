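#' Piecewise-constant transcription profile
#'
#' A candidate transcriptional profile for one cell: `K >= 0` switch times
#' `s_1 < ... < s_K` inside the observation window and `K + 1` interval
#' rates, one per half-open interval `[s_{i-1}, s_i)`.  Each profile carries
#' a probability weight, so a set of mutually exclusive profiles can
#' represent the post-processed posterior of a cell.
#'
#' @param switch_times numeric vector of switch times (hours), strictly
#'   increasing, strictly inside `window`.
#' @param rates numeric vector of length `length(switch_times) + 1`;
#'   non-negative transcription rates, adjacent rates must differ.
#' @param window length-2 numeric, observation window (hours).
#' @param weight probability weight in `[0, 1]`.
#' @return An object of class `transcription_profile`.
#' @export
transcription_profile <- function(switch_times = numeric(0), rates,
                                  window, weight = 1) {
  switch_times <- as.numeric(switch_times)
  rates <- as.numeric(rates)
  window <- as.numeric(window)
  stopifnot(length(window) == 2L, window[1] < window[2])
  if (length(rates) != length(switch_times) + 1L)
    stop("need one rate per interval: length(rates) == K + 1")
  if (length(switch_times) > 0L) {
    if (any(diff(switch_times) <= 0))
      stop("switch times must be strictly increasing")
    if (switch_times[1] <= window[1] || switch_times[length(switch_times)] >= window[2])
      stop("switch times must lie strictly inside the window")
  }
  if (any(rates < 0)) stop("rates must be non-negative")
  if (length(rates) > 1L && any(diff(rates) == 0))
    stop("adjacent rates must differ (zero-length switch forbidden)")
  if (weight < 0 || weight > 1) stop("weight must be in [0, 1]")
  structure(list(switch_times = switch_times, rates = rates,
                 window = window, weight = weight),
            class = "transcription_profile")
}

#' @export
print.transcription_profile <- function(x, ...) {
  cat(sprintf("<transcription_profile> K = %d, window [%g, %g] h, weight %.3g\n",
              length(x$switch_times), x$window[1], x$window[2], x$weight))
  if (length(x$switch_times))
    cat("  switches:", paste(signif(x$switch_times, 4), collapse = ", "), "\n")
  cat("  rates:   ", paste(signif(x$rates, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a profile's rate function beta(t)
#'
#' @param profile a [transcription_profile()].
#' @param t numeric vector of times.
#' @return Rates at `t` under the half-open interval convention.
#' @export
profile_rate_at <- function(profile, t) {
  idx <- findInterval(t, profile$switch_times) + 1L
  profile$rates[idx]
}

#' Interval durations of a profile
#'
#' Durations of the `K + 1` inter-switch intervals, window-truncated.  The
#' first and last intervals are flagged censored: the window clips them, so
#' their durations are lower bounds ("minimum durations").
#'
#' @param profile a [transcription_profile()].
#' @return data.frame with columns `rate`, `duration`, `censored`.
#' @export
profile_durations <- function(profile) {
  bounds <- c(profile$window[1], profile$switch_times, profile$window[2])
  k <- length(profile$rates)
  censored <- rep(FALSE, k)
  censored[1] <- TRUE
  censored[k] <- TRUE
  data.frame(rate = profile$rates, duration = diff(bounds),
             censored = censored)
}

#' Weighted set of mutually exclusive profiles for one cell
#'
#' @param cell_id cell identifier.
#' @param profiles list of [transcription_profile()]; their weights must sum
#'   to 1 (tolerance 1e-9).
#' @return An object of class `profile_set`.
#' @export
profile_set <- function(cell_id, profiles) {
  stopifnot(length(profiles) >= 1L)
  w <- vapply(profiles, function(p) p$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-9)
    stop("profile weights must sum to 1 (got ", sum(w), ")")
  structure(list(cell_id = cell_id, profiles = profiles),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("<profile_set> cell %s: %d profiles, K in {%s}\n", x$cell_id,
              length(x$profiles),
              paste(sort(unique(vapply(x$profiles,
                                       function(p) length(p$switch_times),
                                       integer(1)))), collapse = ", ")))
  invisible(x)
}

#' Weights of the profiles in a profile set
#' @param ps a [profile_set()].
#' @return numeric vector of probability weights (summing to 1).
#' @export
profile_set_weights <- function(ps) {
  vapply(ps$profiles, function(p) p$weight, numeric(1))
}
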