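# switchtissue

Quantitative analysis of pulsatile reporter-gene transcription in living
tissue. Given per-cell fluorescence time series (15-minute sampling over
~46 h) with centroid positions, the package infers **when and how strongly
each cell's transcription rate switched**, and whether neighbouring cells
**coordinate** those switches in space.

It is written for imaging groups quantifying promoter dynamics with
destabilised fluorescent reporters (e.g. prolactin-d2EGFP in pituitary
tissue), and for methodologists who want a fully simulatable testbed for
switch inference.

## The model

Reporter expression follows the stochastic reaction network

    0 --beta(t)--> mRNA,   mRNA --delta_m--> 0,
    mRNA --alpha--> mRNA + Protein,   Protein --delta_p--> 0,

with a piecewise-constant transcription rate `beta(t) = beta_i` on
`[s_{i-1}, s_i)` (K switch times, K+1 interval rates) observed through
`Y(t) = kappa * P(t) + N(0, sigma^2)`.

The pipeline:

1. **Likelihood** — a linear-noise-approximation Kalman filter with exact
   matrix-exponential moment propagation per segment (`lna_loglik`).
2. **Inference** — reversible-jump MCMC over the number, timing and size
   of switches plus degradation/noise parameters (`rjmcmc_sample`), with
   informative log-normal degradation priors and an optional hierarchical
   sweep across cells (`hierarchical_infer`).
3. **Post-processing** — a Gaussian mixture over pooled posterior switch
   times (BIC-selected), enumeration of mutually exclusive sub-model
   profiles with probability weights (`fit_switch_mixture`,
   `enumerate_submodels`), and weighted summaries: switch-count
   histograms, rate density/CDF, state durations by rate bin, inter-switch
   times, bootstrap Mann-Whitney group tests.
4. **Spatial statistics** — Ripley's K with CSR envelopes, distance-binned
   trace correlation with bootstrap bands and a calibrated permutation
   null (significant coordination range), transitive connectivity-network
   correlation, and switch-direction synchrony with KS tests
   (`ripley_k`, `correlation_vs_distance`, `permutation_null`,
   `connectivity_correlation`, `switch_synchrony`).
5. **Synthetic tissue** — a generator (telegraph process with priming,
   spatially coupled switching, exact Gillespie simulation of the reporter
   network, detector/saturation model) providing ground truth for every
   stage (`simulate_tissue`).

## Worked example

Infer the switches of a simulated cell with a known 5-fold rate jump at
20 h, then measure the spatial coordination range of a coupled tissue:

```r
library(switchtissue)
set.seed(1)

# one cell: transcription rate 6 -> 30 a.u./h at t = 20 h
kp    <- kinetic_params()
times <- seq(0, 46, by = 0.25)
truth <- transcription_profile(20, c(6, 30), c(0, 46))
paths <- simulate_reporter_ssa(truth, kp, times)
y     <- as.numeric(apply_measurement(paths$protein, kp))

smp <- rjmcmc_sample(y, times, mcmc = mcmc_config(iters = 8000,
                                                  burnin = 2000))
posterior_modal_K(smp)
#> [1] 1
ps <- enumerate_submodels(smp, fit_switch_mixture(smp), cell_id = "demo")
#> 36 unclassifiable draw(s) dropped
ps$profiles[[which.max(profile_set_weights(ps))]]
#> <transcription_profile> K = 1, window [0, 46] h, weight 0.51
#>   switches: 19.69
#>   rates:    5.092, 26.76

# an adult-scale coupled tissue (30-um coupling radius)
sim <- simulate_tissue(n_cells = 300, field = c(0, 367, 0, 367))
ts  <- subtract_background(sim$tracks)
pn  <- permutation_null(ts, n_perm = 1999, max_dist = 80)
pn$significant_range
#> [1]  5 20
```

The modal posterior has one switch, and the highest-weighted candidate
profile puts it at 19.69 h with rates 5.1 → 26.8 — the truth (20 h,
6 → 30) within posterior uncertainty; the remaining weight spreads over
profiles with extra minor switches. The permutation null — which
permutes traces over positions and is exactly calibrated — finds
correlation above chance only for cell pairs closer than 20 µm at this
seed; across seeds the endpoint of the significant range falls at
20–35 µm, bracketing the generator's 30-µm coupling radius.

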