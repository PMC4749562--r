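#' Prior specification for switch inference
#'
#' Identifiability is secured by informative log-normal priors on the
#' degradation rates (location/scale on the log scale), a truncated
#' geometric prior on the number of switches K, log-normal priors on the
#' interval rates, a uniform prior on switch times with a minimum
#' separation, and an inverse-gamma prior on the measurement noise
#' variance.  The translation rate `alpha` and fluorescence gain `kappa`
#' are fixed, not sampled: `beta`, `alpha` and `kappa` are jointly
#' unidentifiable from fluorescence alone, so rates are reported in
#' fluorescence-equivalent units.
#'
#' @param delta_m_prior,delta_p_prior length-2 `(meanlog, sdlog)`.
#' @param k_geom_p truncated-geometric parameter for K.
#' @param k_max maximum number of switches.
#' @param beta_prior length-2 `(meanlog, sdlog)` for each interval rate.
#' @param sigma2_prior length-2 `(shape, rate)` of the inverse-gamma prior.
#' @param min_sep minimum separation between switches (hours); `NULL`
#'   defaults to 2 sampling intervals at sampling time.
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(delta_m_prior = c(log(0.7), 0.15),
                       delta_p_prior = c(log(0.35), 0.15),
                       k_geom_p = 0.5, k_max = 10,
                       beta_prior = c(log(5), 1.5),
                       sigma2_prior = c(3, 50),
                       min_sep = NULL) {
  stopifnot(k_geom_p > 0, k_geom_p < 1, k_max >= 0,
            delta_m_prior[2] > 0, delta_p_prior[2] > 0, beta_prior[2] > 0,
            sigma2_prior[1] > 0, sigma2_prior[2] > 0,
            is.null(min_sep) || min_sep > 0)
  structure(list(delta_m_prior = delta_m_prior,
                 delta_p_prior = delta_p_prior,
                 k_geom_p = k_geom_p, k_max = k_max,
                 beta_prior = beta_prior, sigma2_prior = sigma2_prior,
                 min_sep = min_sep),
            class = "prior_spec")
}

#' MCMC chain configuration
#'
#' @param iters total iterations.
#' @param burnin discarded initial iterations.
#' @param thin retain every `thin`-th iteration after burn-in.
#' @param tau_birth SD of the log-normal rate split at a birth.
#' @param tau_move SD (hours) of the switch-time random walk.
#' @param tau_rate,tau_delta,tau_sigma log-scale random-walk SDs for the
#'   rates, the degradation parameters and the noise variance.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(iters = 20000, burnin = 5000, thin = 5,
                        tau_birth = 0.7, tau_move = 1.0, tau_rate = 0.3,
                        tau_delta = 0.08, tau_sigma = 0.3) {
  stopifnot(iters > burnin, thin >= 1)
  if (floor((iters - burnin) / thin) < 1L)
    stop("chain config retains zero samples")
  structure(as.list(environment()), class = "mcmc_config")
}

# --- prior densities -------------------------------------------------------

log_prior_K <- function(K, p, k_max) {
  if (K < 0 || K > k_max) return(-Inf)
  K * log(1 - p) - log(sum((1 - p)^(0:k_max)))
}

# ordered uniform with minimum separation on [t0 + d, t1 - d]
log_prior_s <- function(s, window, d) {
  K <- length(s)
  if (K == 0L) return(0)
  L_eff <- diff(window) - (K + 1) * d
  if (L_eff <= 0) return(-Inf)
  if (s[1] < window[1] + d || s[K] > window[2] - d) return(-Inf)
  if (K > 1L && any(diff(s) < d)) return(-Inf)
  lgamma(K + 1) - K * log(L_eff)
}

log_prior_beta <- function(beta, pr) {
  if (any(beta <= 0)) return(-Inf)
  sum(stats::dlnorm(beta, pr[1], pr[2], log = TRUE))
}

log_dinvgamma <- function(x, shape, rate) {
  if (x <= 0) return(-Inf)
  shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x
}

rj_log_prior <- function(st, priors, window, d) {
  log_prior_K(length(st$s), priors$k_geom_p, priors$k_max) +
    log_prior_s(st$s, window, d) +
    log_prior_beta(st$beta, priors$beta_prior) +
    stats::dlnorm(st$dm, priors$delta_m_prior[1], priors$delta_m_prior[2],
                  log = TRUE) +
    stats::dlnorm(st$dp, priors$delta_p_prior[1], priors$delta_p_prior[2],
                  log = TRUE) +
    log_dinvgamma(st$s2, priors$sigma2_prior[1], priors$sigma2_prior[2])
}

reflect_into <- function(x, lo, hi) {
  r <- hi - lo
  y <- (x - lo) %% (2 * r)
  lo + ifelse(y <= r, y, 2 * r - y)
}

# --- reversible-jump moves -------------------------------------------------
# b_K, d_K: probabilities of attempting a birth / death at switch count K
rj_bK <- function(K, k_max) if (K < k_max) 0.5 else 0
rj_dK <- function(K) if (K > 0) 0.5 else 0

# Birth: insert a switch at u ~ Unif(window), splitting the containing
# interval's rate with a log-normal perturbation exp(eps).  The acceptance
# ratio carries the reversible-jump Jacobian |d(beta_l, beta_r, s)/
# d(beta, u, eps)| = beta * exp(eps).
rj_birth_proposal <- function(st, u, eps, priors, window, d) {
  K <- length(st$s)
  j <- findInterval(u, st$s) + 1L
  beta_r <- st$beta[j] * exp(eps)
  new <- st
  new$s <- append(st$s, u, after = j - 1L)
  new$beta <- append(st$beta, beta_r, after = j)
  L <- diff(window)
  log_prop <- log(rj_dK(K + 1) / (K + 1)) -
    log(rj_bK(K, priors$k_max) * stats::dnorm(eps, 0, d$tau_birth) / L)
  log_jac <- log(st$beta[j]) + eps
  list(state = new, log_prop = log_prop, log_jac = log_jac)
}

rj_death_proposal <- function(st, i, priors, window, d) {
  K <- length(st$s)
  eps_impl <- log(st$beta[i + 1] / st$beta[i])
  new <- st
  new$s <- st$s[-i]
  new$beta <- st$beta[-(i + 1)]
  L <- diff(window)
  log_prop <- log(rj_bK(K - 1, priors$k_max) *
                    stats::dnorm(eps_impl, 0, d$tau_birth) / L) -
    log(rj_dK(K) / K)
  log_jac <- -(log(st$beta[i]) + eps_impl)
  list(state = new, log_prop = log_prop, log_jac = log_jac)
}

#' Reversible-jump MCMC over transcriptional profiles
#'
#' Samples the joint posterior of the switch count K, switch times, interval
#' rates, degradation rates and noise variance for one fluorescence trace,
#' under the LNA marginal likelihood.  Move types: birth (insert a switch
#' uniformly over the window, splitting the interval's rate with a
#' log-normal perturbation), death (its reverse), move (reflected Gaussian
#' random walk on one switch time), rate update, and log-scale random walks
#' on the degradation parameters and noise variance.  Birth/death
#' acceptance ratios include the reversible-jump Jacobian.
#'
#' @param trace fluorescence values (preprocessed: fused, background
#'   subtracted).
#' @param times observation times (hours).
#' @param priors a [prior_spec()].
#' @param kp [kinetic_params()]; supplies the fixed `alpha` and `kappa` and
#'   the chain's initial degradation/noise values.
#' @param mcmc a [mcmc_config()].
#' @param likelihood set `FALSE` for a prior-only run (the standard MCMC
#'   correctness check: the chain must then reproduce the prior).
#' @return object of class `posterior_samples`: per retained draw `K`,
#'   `switch_times`, `rates`, `delta_m`, `delta_p`, `sigma2`, `loglik`;
#'   plus an acceptance-rate `ledger` and the chain configuration.
#' @export
rjmcmc_sample <- function(trace, times, priors = prior_spec(),
                          kp = kinetic_params(), mcmc = mcmc_config(),
                          likelihood = TRUE) {
  n <- length(trace)
  stopifnot(length(times) == n, n >= 10L)
  window <- c(times[1], times[n])
  dt_grid <- times[2] - times[1]
  d_min <- if (is.null(priors$min_sep)) 2 * dt_grid else priors$min_sep

  alpha <- kp$alpha; kappa <- kp$kappa
  ll_fun <- if (likelihood) {
    # a proposal extreme enough to break the LNA filter (the Gaussian
    # moment closure degenerates for absurd rates) is simply rejected
    function(st) tryCatch(
      lna_loglik_cpp(trace, times, st$s, st$beta, st$dm, st$dp,
                     alpha, kappa, st$s2, TRUE, numeric(5)),
      error = function(e) -Inf)
  } else {
    function(st) 0
  }

  st <- list(s = numeric(0),
             beta = max(mean(trace) * kp$delta_m * kp$delta_p /
                          (alpha * kappa), 1e-3),
             dm = exp(priors$delta_m_prior[1]),
             dp = exp(priors$delta_p_prior[1]),
             s2 = priors$sigma2_prior[2] / max(priors$sigma2_prior[1] - 1, 1))
  st$ll <- ll_fun(st)
  st$lp <- rj_log_prior(st, priors, window, d_min)

  moves <- c("birth", "death", "move", "rate", "theta", "sigma2")
  proposed <- accepted <- stats::setNames(integer(6), moves)
  mh_step <- function(move, new, extra_log = 0) {
    proposed[move] <<- proposed[move] + 1L
    new$ll <- ll_fun(new)
    new$lp <- rj_log_prior(new, priors, window, d_min)
    log_a <- (new$ll + new$lp) - (st$ll + st$lp) + extra_log
    if (is.finite(log_a) && log(stats::runif(1)) < log_a) {
      accepted[move] <<- accepted[move] + 1L
      st <<- new
    }
  }

  keep_idx <- seq(mcmc$burnin + mcmc$thin, mcmc$iters, by = mcmc$thin)
  n_keep <- length(keep_idx)
  out_K <- integer(n_keep); out_dm <- out_dp <- out_s2 <- out_ll <-
    numeric(n_keep)
  out_s <- out_beta <- vector("list", n_keep)
  ki <- 1L

  for (it in seq_len(mcmc$iters)) {
    K <- length(st$s)
    # dimension move
    u_dim <- stats::runif(1)
    if (u_dim < rj_bK(K, priors$k_max)) {
      u <- stats::runif(1, window[1], window[2])
      ok <- u >= window[1] + d_min && u <= window[2] - d_min &&
        (K == 0L || min(abs(st$s - u)) >= d_min)
      if (ok) {
        eps <- stats::rnorm(1, 0, mcmc$tau_birth)
        prop <- rj_birth_proposal(st, u, eps, priors, window, mcmc)
        mh_step("birth", prop$state, prop$log_prop + prop$log_jac)
      } else proposed["birth"] <- proposed["birth"] + 1L
    } else if (u_dim < rj_bK(K, priors$k_max) + rj_dK(K)) {
      i <- sample.int(K, 1)
      prop <- rj_death_proposal(st, i, priors, window, mcmc)
      mh_step("death", prop$state, prop$log_prop + prop$log_jac)
    }
    # move one switch time (reflected at neighbours +- min separation)
    K <- length(st$s)
    if (K > 0L) {
      i <- sample.int(K, 1)
      lo <- if (i == 1L) window[1] + d_min else st$s[i - 1] + d_min
      hi <- if (i == K) window[2] - d_min else st$s[i + 1] - d_min
      if (hi > lo) {
        new <- st
        new$s[i] <- reflect_into(st$s[i] + stats::rnorm(1, 0, mcmc$tau_move),
                                 lo, hi)
        mh_step("move", new)
      }
    }
    # rate update (multiplicative random walk on one interval)
    j <- sample.int(length(st$beta), 1)
    new <- st
    new$beta[j] <- st$beta[j] * exp(stats::rnorm(1, 0, mcmc$tau_rate))
    mh_step("rate", new, log(new$beta[j] / st$beta[j]))
    # degradation parameters (joint multiplicative random walk)
    new <- st
    new$dm <- st$dm * exp(stats::rnorm(1, 0, mcmc$tau_delta))
    new$dp <- st$dp * exp(stats::rnorm(1, 0, mcmc$tau_delta))
    mh_step("theta", new, log(new$dm / st$dm) + log(new$dp / st$dp))
    # noise variance
    new <- st
    new$s2 <- st$s2 * exp(stats::rnorm(1, 0, mcmc$tau_sigma))
    mh_step("sigma2", new, log(new$s2 / st$s2))

    if (ki <= n_keep && it == keep_idx[ki]) {
      out_K[ki] <- length(st$s)
      out_s[[ki]] <- st$s
      out_beta[[ki]] <- st$beta
      out_dm[ki] <- st$dm; out_dp[ki] <- st$dp; out_s2[ki] <- st$s2
      out_ll[ki] <- st$ll
      ki <- ki + 1L
    }
  }

  structure(list(K = out_K, switch_times = out_s, rates = out_beta,
                 delta_m = out_dm, delta_p = out_dp, sigma2 = out_s2,
                 loglik = out_ll,
                 ledger = data.frame(move = moves,
                                     proposed = as.integer(proposed),
                                     accepted = as.integer(accepted)),
                 window = window, min_sep = d_min, priors = priors,
                 kp = kp, mcmc = mcmc, likelihood = likelihood),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("<posterior_samples> %d retained draws, modal K = %d\n",
              length(x$K), posterior_modal_K(x)))
  ar <- with(x$ledger, ifelse(proposed > 0, accepted / proposed, NA))
  cat("  acceptance:",
      paste(sprintf("%s %.2f", x$ledger$move, ar), collapse = ", "), "\n")
  invisible(x)
}

#' Posterior modal switch count
#' @param samples a `posterior_samples` object.
#' @return integer, the most frequent K among retained draws.
#' @export
posterior_modal_K <- function(samples) {
  tab <- table(samples$K)
  as.integer(names(tab)[which.max(tab)])
}

#' Pooled posterior switch times
#' @param samples a `posterior_samples` object.
#' @return numeric vector of all switch-time draws.
#' @export
pooled_switch_times <- function(samples) {
  unlist(samples$switch_times, use.names = FALSE)
}

#' Point-estimate profile from posterior samples
#'
#' The profile at the posterior modal K, with switch times and rates
#' averaged over the draws of that K (sorted switch times align across
#' draws because the minimum-separation prior keeps them ordered).
#'
#' @param samples a `posterior_samples` object.
#' @return a [transcription_profile()].
#' @export
posterior_profile <- function(samples) {
  K <- posterior_modal_K(samples)
  sel <- samples$K == K
  s <- if (K > 0)
    colMeans(do.call(rbind, samples$switch_times[sel])) else numeric(0)
  beta <- colMeans(do.call(rbind, samples$rates[sel]))
  transcription_profile(s, beta, samples$window, weight = 1)
}
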