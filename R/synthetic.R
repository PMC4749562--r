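#' State-process configuration for the telegraph model with priming
#'
#' The transcriptional state cycles off -> primed -> on -> off, with the
#' time spent in each state exponentially distributed.  The primed state
#' transcribes at the same low rate as off (it differs only in dynamics);
#' each "on" sojourn draws its own rate from a continuous positive
#' distribution, so the population shows a continuous range of activity
#' rather than binary on-off behaviour.
#'
#' @param mean_off,mean_primed,mean_on mean sojourn times (hours).
#' @param rate_dist function `n -> n` positive "on" rates; default
#'   LogNormal(log 8, 0.5).
#' @param beta_low transcription rate in off and primed states.
#' @param primed_schedule optional function `t -> mean` giving a
#'   time-varying primed-state mean (evaluated at state entry); used for the
#'   primed-period-shortening experiment.
#' @return object of class `state_process_config`.
#' @export
state_process_config <- function(mean_off = 10, mean_primed = 8,
                                 mean_on = 12,
                                 rate_dist = function(n)
                                   stats::rlnorm(n, log(8), 0.5),
                                 beta_low = 0, primed_schedule = NULL) {
  stopifnot(mean_off > 0, mean_primed > 0, mean_on > 0, beta_low >= 0)
  structure(list(mean_off = mean_off, mean_primed = mean_primed,
                 mean_on = mean_on, rate_dist = rate_dist,
                 beta_low = beta_low, primed_schedule = primed_schedule),
            class = "state_process_config")
}

#' Spatial coupling configuration
#'
#' A generative stand-in for local (gap-junction-like) coordination: each
#' switch in a cell propagates, with some probability, to every neighbour
#' within the coupling radius at the source time plus Gaussian jitter —
#' by default aligning the neighbour's nearest same-direction own switch
#' (`mode = "shift"`, which preserves per-cell switch counts and lets
#' alignment spread through the neighbourhood graph), optionally by
#' inserting a new switch (`mode = "insert"`).  This is a statistical
#' device reproducing the observed synchrony signature, not a mechanistic
#' model of cell communication.
#'
#' @param radius coupling radius (um).
#' @param probability propagation probability per (switch, neighbour) pair.
#' @param jitter_sd SD of the timing jitter (hours).
#' @param same_direction if `TRUE` (default) propagated switches share the
#'   source switch direction.
#' @param mode `"shift"` (default) moves the neighbour's nearest
#'   same-direction own switch to the source time plus jitter, preserving
#'   each cell's switch count; `"insert"` adds a new switch in the
#'   neighbour instead, which inflates switch counts in dense
#'   neighbourhoods.
#' @return object of class `coupling_config`.
#' @export
coupling_config <- function(radius = 30, probability = 1, jitter_sd = 1,
                            same_direction = TRUE,
                            mode = c("shift", "insert")) {
  mode <- match.arg(mode)
  stopifnot(radius >= 0, probability >= 0, probability <= 1, jitter_sd >= 0)
  structure(list(radius = radius, probability = probability,
                 jitter_sd = jitter_sd, same_direction = same_direction,
                 mode = mode),
            class = "coupling_config")
}

#' Place cells in a rectangular field
#'
#' @param n number of cells.
#' @param field rectangle `c(xmin, xmax, ymin, ymax)` (um).
#' @param mode `"CSR"` (uniform iid, a homogeneous Poisson pattern
#'   conditioned on n) or `"hard-core"` (sequential rejection below
#'   `min_sep`, emulating finite cell size).
#' @param min_sep minimum separation for hard-core placement (um).
#' @param max_tries rejection budget per point before giving up.
#' @return data.frame with columns `cell_id`, `x`, `y`.
#' @export
place_cells <- function(n, field = c(0, 300, 0, 300),
                        mode = c("CSR", "hard-core"), min_sep = 10,
                        max_tries = 2000) {
  mode <- match.arg(mode)
  stopifnot(n >= 1, field[2] > field[1], field[4] > field[3])
  if (mode == "CSR") {
    x <- stats::runif(n, field[1], field[2])
    y <- stats::runif(n, field[3], field[4])
  } else {
    area <- (field[2] - field[1]) * (field[4] - field[3])
    if (n * pi * (min_sep / 2)^2 >= area)
      stop("hard-core packing infeasible: n * disc area exceeds field area")
    x <- y <- numeric(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        px <- stats::runif(1, field[1], field[2])
        py <- stats::runif(1, field[3], field[4])
        if (i == 1L ||
            min((x[seq_len(i - 1)] - px)^2 + (y[seq_len(i - 1)] - py)^2) >=
              min_sep^2) {
          x[i] <- px; y[i] <- py; ok <- TRUE; break
        }
      }
      if (!ok) stop("hard-core placement failed after ", max_tries,
                    " rejections at point ", i)
    }
  }
  data.frame(cell_id = sprintf("cell_%03d", seq_len(n)), x = x, y = y,
             stringsAsFactors = FALSE)
}

#' Simulate one cell's transcriptional state path
#'
#' Alternates off, primed and on sojourns (each Exponential with its
#' configured mean), truncated to the window, and returns the resulting
#' piecewise-constant transcription profile with weight 1.  Because off and
#' primed share `beta_low`, rate switches occur only at on-entry and
#' on-exit; the full state path is attached as attribute `"states"`.
#'
#' @param cfg a [state_process_config()].
#' @param window length-2 numeric `c(t0, t1)` (hours).
#' @param start_state `"random"` (stationary-occupancy draw) or one of
#'   `"off"`, `"primed"`, `"on"`.
#' @return a [transcription_profile()] with attribute `"states"`, a
#'   data.frame of (state, start, end, rate).
#' @export
simulate_state_path <- function(cfg, window = c(0, 46),
                                start_state = "random") {
  stopifnot(window[2] > window[1])
  means <- c(off = cfg$mean_off, primed = cfg$mean_primed, on = cfg$mean_on)
  if (identical(start_state, "random"))
    start_state <- sample(names(means), 1, prob = means / sum(means))
  cycle <- c("off", "primed", "on")
  state <- start_state
  t <- window[1]
  rows <- list()
  while (t < window[2]) {
    mu <- means[[state]]
    if (state == "primed" && !is.null(cfg$primed_schedule))
      mu <- cfg$primed_schedule(t)
    len <- stats::rexp(1, 1 / mu)
    rate <- if (state == "on") cfg$rate_dist(1) else cfg$beta_low
    t_end <- min(t + len, window[2])
    rows[[length(rows) + 1L]] <- data.frame(state = state, start = t,
                                            end = t_end, rate = rate,
                                            stringsAsFactors = FALSE)
    t <- t_end
    state <- cycle[(match(state, cycle) %% 3L) + 1L]
  }
  states <- do.call(rbind, rows)
  # collapse equal-rate neighbours into profile intervals
  sw <- numeric(0); rates <- states$rate[1]
  for (i in seq_len(nrow(states))[-1]) {
    if (states$rate[i] != rates[length(rates)]) {
      sw <- c(sw, states$start[i])
      rates <- c(rates, states$rate[i])
    }
  }
  prof <- transcription_profile(sw, rates, window, weight = 1)
  attr(prof, "states") <- states
  prof
}

#' Population occupancy of a transcriptional state
#'
#' @param paths list of profiles carrying the `"states"` attribute (from
#'   [simulate_state_path()]).
#' @param grid times at which to evaluate occupancy.
#' @param state state name, default `"on"`.
#' @return numeric vector: fraction of cells in `state` at each grid time.
#' @export
state_occupancy <- function(paths, grid, state = "on") {
  counts <- vapply(grid, function(g) {
    sum(vapply(paths, function(p) {
      st <- attr(p, "states")
      any(st$state == state & st$start <= g & g < st$end)
    }, logical(1)))
  }, numeric(1))
  counts / length(paths)
}

#' Propagate switches between neighbouring cells
#'
#' For each switch of each source cell, every neighbour within the coupling
#' radius is affected with the configured probability, at the source time
#' plus Gaussian jitter.  In `"shift"` mode (default) the neighbour's own
#' same-direction switch nearest in time is moved to that moment, so
#' per-cell switch counts stay at the generator's 0-4 scale; in `"insert"`
#' mode a new same-direction switch is added instead (the neighbour's
#' current rate shifts additively by the source's rate change until its
#' next own switch).  Events that would violate profile invariants
#' (outside the window, switch-order violations, coincident switches,
#' equal adjacent rates, direction flips of a following switch) are
#' skipped.
#'
#' @param profiles list of [transcription_profile()], index-aligned with
#'   `positions`.
#' @param positions data.frame with `x`, `y` (um).
#' @param cfg a [coupling_config()].
#' @return list with `profiles` (modified) and `log` (data.frame of
#'   propagated events: source, target, source_time, inserted_time,
#'   direction).
#' @export
couple_switches <- function(profiles, positions, cfg) {
  stopifnot(length(profiles) == nrow(positions))
  n <- length(profiles)
  original <- profiles
  log_rows <- list()
  if (cfg$probability > 0 && n > 1) {
    d <- as.matrix(stats::dist(positions[, c("x", "y")]))
    for (i in seq_len(n)) {
      # shift mode reads the source's current (possibly already aligned)
      # switches, so alignment propagates through the neighbourhood graph;
      # insert mode uses the original profiles to avoid chain inflation
      src <- if (identical(cfg$mode, "shift")) profiles[[i]] else original[[i]]
      if (length(src$switch_times) == 0L) next
      nbrs <- which(d[i, ] <= cfg$radius & seq_len(n) != i)
      for (k in seq_along(src$switch_times)) {
        s_time <- src$switch_times[k]
        delta <- src$rates[k + 1] - src$rates[k]
        for (j in nbrs) {
          if (stats::runif(1) > cfg$probability) next
          u <- s_time + stats::rnorm(1, 0, cfg$jitter_sd)
          dir_delta <- if (cfg$same_direction) delta else
            delta * sample(c(-1, 1), 1)
          res <- if (identical(cfg$mode, "shift"))
            shift_switch(profiles[[j]], u, sign(dir_delta))
          else insert_switch(profiles[[j]], u, dir_delta)
          if (is.null(res)) next
          profiles[[j]] <- res
          log_rows[[length(log_rows) + 1L]] <- data.frame(
            source = i, target = j, source_time = s_time,
            inserted_time = u, direction = sign(dir_delta))
        }
      }
    }
  }
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(source = integer(0), target = integer(0),
               source_time = numeric(0), inserted_time = numeric(0),
               direction = numeric(0))
  list(profiles = profiles, log = log)
}

# move the profile's same-direction switch nearest to u onto u; NULL if
# no such switch exists or the move would break the switch ordering
shift_switch <- function(profile, u, direction) {
  s <- profile$switch_times
  if (length(s) == 0L) return(NULL)
  w <- profile$window
  if (u <= w[1] || u >= w[2]) return(NULL)
  dirs <- sign(diff(profile$rates))
  cands <- which(dirs == direction)
  if (length(cands) == 0L) return(NULL)
  k <- cands[which.min(abs(s[cands] - u))]
  lo <- if (k > 1L) s[k - 1L] else w[1]
  hi <- if (k < length(s)) s[k + 1L] else w[2]
  if (u <= lo + 1e-9 || u >= hi - 1e-9) return(NULL)
  s[k] <- u
  st <- attr(profile, "states")
  out <- transcription_profile(s, profile$rates, w, weight = profile$weight)
  attr(out, "states") <- st
  out
}

# insert a switch at time u shifting the current rate by delta until the
# next original switch; NULL if the insertion would be invalid
insert_switch <- function(profile, u, delta) {
  w <- profile$window
  if (u <= w[1] || u >= w[2]) return(NULL)
  if (length(profile$switch_times) &&
      min(abs(profile$switch_times - u)) < 1e-9) return(NULL)
  k <- findInterval(u, profile$switch_times) + 1L
  cur <- profile$rates[k]
  new_rate <- max(0, cur + delta)
  if (new_rate == cur) return(NULL)
  sw <- append(profile$switch_times, u, after = k - 1L)
  rates <- append(profile$rates, new_rate, after = k)
  # the neighbour's next own switch must keep its direction: an insertion
  # that flips it would manufacture spurious opposite-direction synchrony
  if (length(rates) >= k + 2L) {
    nxt <- rates[k + 2L]
    if (nxt == new_rate) return(NULL)
    if (sign(nxt - new_rate) != sign(nxt - cur)) return(NULL)
  }
  st <- attr(profile, "states")
  out <- tryCatch(
    transcription_profile(sw, rates, w, weight = profile$weight),
    error = function(e) NULL)
  if (is.null(out)) return(NULL)
  attr(out, "states") <- st
  out
}

#' Exact stochastic simulation of the reporter network
#'
#' Gillespie simulation of transcription (rate `beta(t)` from the profile),
#' mRNA decay, translation and protein decay, with the time-varying rate
#' handled by restarting at switch times.  Returns integer molecule counts
#' sampled at the grid times.
#'
#' @param profile a [transcription_profile()] covering the grid.
#' @param kp [kinetic_params()].
#' @param grid sampling times (hours).
#' @param init `"stationary"` (Poisson draws at the first segment's
#'   stationary means, an approximation for protein) or integer `c(m0, p0)`.
#' @return list with integer vectors `mRNA` and `protein`.
#' @export
simulate_reporter_ssa <- function(profile, kp, grid, init = "stationary") {
  stopifnot(grid[1] >= profile$window[1] - 1e-9,
            grid[length(grid)] <= profile$window[2] + 1e-9)
  if (identical(init, "stationary")) {
    b1 <- profile$rates[1]
    m0 <- stats::rpois(1, b1 / kp$delta_m)
    p0 <- stats::rpois(1, kp$alpha * b1 / (kp$delta_m * kp$delta_p))
  } else {
    m0 <- as.integer(init[1]); p0 <- as.integer(init[2])
  }
  ssa_reporter_cpp(grid, profile$switch_times, profile$rates,
                   kp$delta_m, kp$delta_p, kp$alpha, m0, p0)
}

#' Apply the measurement / detector model
#'
#' Each channel observes `clip(gain * kappa * P + noise, 0, ceiling)`.  A
#' sensitive channel has high gain and a low saturation ceiling; an
#' insensitive channel low gain and no (or a high) ceiling.
#'
#' @param protein integer or numeric protein counts.
#' @param kp [kinetic_params()] (supplies `kappa` and `sigma2`).
#' @param detectors list of channels, each `list(label =, gain =, ceiling =)`;
#'   `ceiling` may be `Inf`.
#' @return numeric matrix, timepoints x channels.
#' @export
apply_measurement <- function(protein, kp,
                              detectors = list(list(label = "ch1", gain = 1,
                                                    ceiling = Inf))) {
  n <- length(protein)
  out <- vapply(detectors, function(d) {
    stopifnot(d$gain > 0, is.null(d$ceiling) || d$ceiling > 0)
    ceiling <- if (is.null(d$ceiling)) Inf else d$ceiling
    raw <- d$gain * kp$kappa * protein +
      stats::rnorm(n, 0, sqrt(kp$sigma2))
    pmin(pmax(raw, 0), ceiling)
  }, numeric(n))
  out <- matrix(out, nrow = n)
  colnames(out) <- vapply(detectors, function(d) d$label, character(1))
  out
}

#' Simulate a synthetic tissue end-to-end
#'
#' Places cells, draws per-cell state paths, couples switches between
#' neighbours, runs the exact reporter SSA per cell, applies the detector
#' model, and assembles a [track_set()] (with pure-noise background traces)
#' together with the full ground truth.  Deterministic given the RNG seed.
#'
#' @param n_cells number of cells (default 200, an adult-like field).
#' @param field rectangle `c(xmin, xmax, ymin, ymax)` (um).
#' @param t_max imaging duration (hours; default 46).
#' @param dt sampling interval (hours; default 0.25, the 15-min grid).
#' @param state_cfg [state_process_config()].
#' @param coupling_cfg [coupling_config()]; set `probability = 0` for an
#'   uncoupled tissue.
#' @param kp [kinetic_params()].
#' @param detectors detector spec, as in [apply_measurement()].
#' @param n_background number of background traces (default 5, matching the
#'   mean-of-five-areas convention).
#' @param placement,min_sep passed to [place_cells()].
#' @return list with `tracks` (a [track_set()]) and `truth` (list:
#'   `profiles`, `positions`, `coupling_log`, `mrna`, `protein`).
#' @export
simulate_tissue <- function(n_cells = 200, field = c(0, 300, 0, 300),
                            t_max = 46, dt = 0.25,
                            state_cfg = state_process_config(),
                            coupling_cfg = coupling_config(),
                            kp = kinetic_params(),
                            detectors = list(list(label = "ch1", gain = 1,
                                                  ceiling = Inf)),
                            n_background = 5,
                            placement = "CSR", min_sep = 10) {
  grid <- seq(0, t_max, by = dt)
  pos <- place_cells(n_cells, field, mode = placement, min_sep = min_sep)
  profiles <- lapply(seq_len(n_cells), function(i)
    simulate_state_path(state_cfg, window = c(0, t_max)))
  coupled <- couple_switches(profiles, pos, coupling_cfg)
  profiles <- coupled$profiles

  mrna <- protein <- matrix(0L, nrow = length(grid), ncol = n_cells)
  tracks <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    paths <- simulate_reporter_ssa(profiles[[i]], kp, grid)
    mrna[, i] <- paths$mRNA
    protein[, i] <- paths$protein
    fl <- apply_measurement(paths$protein, kp, detectors)
    tracks[[i]] <- cell_track(pos$cell_id[i], grid, fl,
                              cbind(rep(pos$x[i], length(grid)),
                                    rep(pos$y[i], length(grid))))
  }
  background <- lapply(seq_len(n_background), function(i)
    pmax(stats::rnorm(length(grid), 0, sqrt(kp$sigma2)), 0))
  ts <- track_set(tracks, background,
                  metadata = list(stage = "synthetic", field = field),
                  zero_background = n_background == 0)
  list(tracks = ts,
       truth = list(profiles = profiles, positions = pos,
                    coupling_log = coupled$log, mrna = mrna,
                    protein = protein))
}
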