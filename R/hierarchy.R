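#' Hierarchy specification for population degradation parameters
#'
#' Cells of one dataset share population-level normal distributions for
#' log delta_m and log delta_p, with conjugate hyperpriors: a normal prior
#' on each population location and an inverse-gamma prior on each
#' population variance.
#'
#' @param mu0_m,mu0_p hyperprior means of the population locations (log
#'   scale).
#' @param v0 hyperprior variance of the population locations.
#' @param a0,b0 inverse-gamma hyperprior (shape, rate) for the population
#'   variances; `b0/(a0+1)` acts as the scale floor the population variance
#'   shrinks towards when cells agree.
#' @return object of class `hierarchy_spec`.
#' @export
hierarchy_spec <- function(mu0_m = log(0.7), mu0_p = log(0.35), v0 = 1,
                           a0 = 3, b0 = 0.02) {
  stopifnot(v0 > 0, a0 > 0, b0 > 0)
  structure(list(mu0_m = mu0_m, mu0_p = mu0_p, v0 = v0, a0 = a0, b0 = b0),
            class = "hierarchy_spec")
}

gibbs_normal_update <- function(x, mu0, v0, a0, b0) {
  n <- length(x)
  # tau2 | mu, x  ~ InvGamma(a0 + n/2, b0 + sum((x-mu)^2)/2), then mu | tau2
  # one sweep: draw tau2 at the current mean estimate, then mu
  xbar <- mean(x)
  a_post <- a0 + n / 2
  b_post <- b0 + sum((x - xbar)^2) / 2
  tau2 <- 1 / stats::rgamma(1, a_post, rate = b_post)
  v_post <- 1 / (1 / v0 + n / tau2)
  m_post <- v_post * (mu0 / v0 + n * xbar / tau2)
  mu <- stats::rnorm(1, m_post, sqrt(v_post))
  c(mu = mu, tau2 = tau2)
}

#' One Gibbs sweep of the hierarchical degradation model
#'
#' Given the current per-cell degradation values, updates the population
#' location and scale of log delta_m and log delta_p from their conjugate
#' conditionals, and returns per-cell priors re-centred on the population.
#'
#' @param delta_m,delta_p numeric vectors of current per-cell values
#'   (natural scale), one per cell; at least 2 cells.
#' @param h a [hierarchy_spec()].
#' @param base_priors a [prior_spec()] whose non-degradation components are
#'   carried through.
#' @return list with `population` (data.frame: parameter, mu, tau2) and
#'   `priors` (a [prior_spec()] with re-centred degradation priors).  With a
#'   single cell the hierarchy degenerates to the fixed informative prior,
#'   with a warning.
#' @export
hierarchical_sweep <- function(delta_m, delta_p, h = hierarchy_spec(),
                               base_priors = prior_spec()) {
  stopifnot(length(delta_m) == length(delta_p))
  if (length(delta_m) < 2L) {
    warning("single cell: hierarchy degenerates to the fixed informative prior")
    return(list(population = data.frame(parameter = c("log_delta_m", "log_delta_p"),
                                        mu = c(base_priors$delta_m_prior[1],
                                               base_priors$delta_p_prior[1]),
                                        tau2 = c(base_priors$delta_m_prior[2]^2,
                                                 base_priors$delta_p_prior[2]^2)),
                priors = base_priors))
  }
  um <- gibbs_normal_update(log(delta_m), h$mu0_m, h$v0, h$a0, h$b0)
  up <- gibbs_normal_update(log(delta_p), h$mu0_p, h$v0, h$a0, h$b0)
  pr <- base_priors
  pr$delta_m_prior <- c(um["mu"], sqrt(um["tau2"]))
  pr$delta_p_prior <- c(up["mu"], sqrt(up["tau2"]))
  list(population = data.frame(parameter = c("log_delta_m", "log_delta_p"),
                               mu = c(um["mu"], up["mu"]),
                               tau2 = c(um["tau2"], up["tau2"])),
       priors = pr)
}

#' Hierarchical switch inference across cells
#'
#' Interleaves per-cell reversible-jump chains with Gibbs updates of the
#' population degradation distribution: each outer sweep runs a block of
#' each cell's chain under the current population-centred priors, then
#' updates the population from the cells' current degradation values.
#' With `hierarchical = FALSE` the cells are fitted independently under the
#' base priors (the ablation identity).
#'
#' @param traces list of numeric fluorescence traces (one per cell).
#' @param times shared observation times.
#' @param priors base [prior_spec()].
#' @param kp [kinetic_params()].
#' @param mcmc per-block [mcmc_config()].
#' @param h [hierarchy_spec()].
#' @param sweeps number of outer sweeps.
#' @param hierarchical toggle for the population coupling.
#' @return list with `cells` (list of `posterior_samples`, final block per
#'   cell) and `population` (data.frame of population parameters per sweep).
#' @export
hierarchical_infer <- function(traces, times, priors = prior_spec(),
                               kp = kinetic_params(), mcmc = mcmc_config(),
                               h = hierarchy_spec(), sweeps = 3,
                               hierarchical = TRUE) {
  n_cells <- length(traces)
  stopifnot(n_cells >= 1L)
  cur_priors <- priors
  cells <- vector("list", n_cells)
  pop_rows <- list()
  for (sw in seq_len(sweeps)) {
    cells <- lapply(traces, function(tr)
      rjmcmc_sample(tr, times, cur_priors, kp, mcmc))
    if (!hierarchical || n_cells < 2L) next
    dm <- vapply(cells, function(s) mean(s$delta_m), numeric(1))
    dp <- vapply(cells, function(s) mean(s$delta_p), numeric(1))
    up <- hierarchical_sweep(dm, dp, h, priors)
    cur_priors <- up$priors
    pop_rows[[sw]] <- cbind(sweep = sw, up$population)
  }
  list(cells = cells,
       population = if (length(pop_rows)) do.call(rbind, pop_rows) else NULL)
}
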