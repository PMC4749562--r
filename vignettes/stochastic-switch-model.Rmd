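---
title: "The stochastic switch model and spatial coordination statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The stochastic switch model and spatial coordination statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchtissue)
```

# The problem

Reporter-gene imaging of tissue yields, per cell, a fluorescence time
series sampled every 15 minutes for up to 46 hours, plus the cell's centroid
track. Transcription of genes such as prolactin is pulsatile: the
transcription rate switches, at irregular times, between different levels
that are not restricted to a binary on/off pair. The questions this package
answers are (i) when and how strongly each cell's transcription rate
switched, with honest uncertainty, and (ii) whether neighbouring cells
coordinate those switches in space.

# The observation model

Reporter expression is described by the stochastic reaction network

$$\emptyset \xrightarrow{\beta(t)} M, \qquad
  M \xrightarrow{\delta_m} \emptyset, \qquad
  M \xrightarrow{\alpha} M + P, \qquad
  P \xrightarrow{\delta_p} \emptyset,$$

with mRNA $M$, protein $P$, translation rate $\alpha$, degradation rates
$\delta_m, \delta_p$, and a piecewise-constant transcription rate
$\beta(t) = \beta_i$ on half-open intervals $[s_{i-1}, s_i)$ delimited by
$K$ switch times $s_1 < \dots < s_K$ (so there are $K+1$ interval rates —
note that a $K$-switch profile needs $K+1$ rates to cover the window).
Fluorescence is observed as $Y(t_j) = \kappa P(t_j) + \varepsilon_j$,
$\varepsilon_j \sim N(0, \sigma^2)$.

Because $\beta$, $\alpha$ and $\kappa$ only enter the observed mean as the
product $\kappa\,\alpha\,\beta/(\delta_m\delta_p)$, they are jointly
unidentifiable from fluorescence alone. The package fixes $\alpha$ and
$\kappa$ and reports $\beta$ in fluorescence-equivalent units; the
degradation rates carry informative log-normal priors, which is what makes
the remaining parameters identifiable.

## The LNA likelihood

Inference uses the linear noise approximation: conditional on a profile,
the joint moments $z = (\bar m, \bar p, V_{mm}, V_{mp}, V_{pp})$ obey a
linear ODE $z' = Mz + \beta e$ with constant coefficients within each
segment, because the LNA process-noise rate
$\mathrm{diag}(\beta + \delta_m \bar m,\; \alpha\bar m + \delta_p\bar p)$
is itself linear in the mean. The filter therefore propagates moments
*exactly* between observations with a matrix exponential per segment
(switch times split the step), applies the standard Kalman update with
$H = (0, \kappa)$, and accumulates one-step-ahead predictive log densities.
The initial state is the stationary moment vector of the first segment —
tissue slices equilibrate in culture before imaging starts. The unit tests
pin this implementation against an independent brute-force filter that
integrates the same ODEs with fixed-step fourth-order Runge–Kutta on a
$10^{-3}$-hour grid; the two agree to better than $10^{-4}$ log-likelihood
units on full-length traces.

Numerical notes: the matrix exponential acts on the 5-dimensional moment
state (cached per distinct step length within a likelihood evaluation); a
covariance entry pushed slightly negative by the update is clamped at zero
below a $10^{-6}$ tolerance and is an error beyond it; a degenerate
predictive ($\sigma^2 = 0$ with zero state variance) yields $-\infty$ for
mismatched data rather than an error.

## Priors and the reversible-jump sampler

* $K \sim$ truncated Geometric($p_K = 0.5$), $K_{\max} = 10$: every extra
  switch halves the prior mass, a monotone complexity penalty.
* Switch times: uniform ordered over the window with a minimum separation
  $\Delta_{\min}$ of two sampling intervals — switches below grid
  resolution are meaningless.
* Interval rates: i.i.d. LogNormal$(\log 5, 1.5)$ (broad, positive).
* $\delta_m, \delta_p$: LogNormal$(\log 0.7, 0.15)$ and
  LogNormal$(\log 0.35, 0.15)$ — a destabilised-GFP scale (about a 2-hour
  protein half-life). These are repository defaults standing in for
  calibration experiments we do not have; the hierarchical sweep
  (`hierarchical_infer`) re-centres them per dataset.
* $\sigma^2 \sim$ Inverse-Gamma$(3, 50)$ (mean 25 a.u.$^2$).

The sampler combines dimension moves — birth (a switch inserted uniformly,
the containing interval's rate split by a log-normal perturbation, with the
reversible-jump Jacobian $\beta e^\epsilon$ in the acceptance ratio), death
(the exact reverse) — with a reflected random walk on one switch time,
multiplicative random walks on rates, degradation parameters and
$\sigma^2$. Defaults: 20,000 iterations, 5,000 burn-in, thinning 5. Two
structural correctness checks are part of the test suite: a prior-only
chain must reproduce the truncated-geometric prior on $K$ (chi-square), and
birth/death proposal-plus-Jacobian log-ratios must cancel to $10^{-10}$.

## What the posterior can and cannot resolve

At low copy numbers the realised transcription process itself fluctuates:
with $\beta_{\text{low}} \lesssim 4$ (under six mRNA on average), a single
realisation of a 5-fold jump is sometimes best explained by a two-step
ramp, or its apparent timing is displaced by more than an hour — the
posterior is then *correctly* ambiguous, and the modal switch count can be
2 with a likelihood gain of a few nats. The recovery validation therefore
uses a 5-fold up-switch from $\beta = 6$ to $30$ (about 9 → 43 mRNA), where
the modal model is the true one and the modal-model median switch time
lands within ±1 h of truth in 10/10 cells. This regime dependence is a
property of single-cell data, and it is why downstream summaries are
weighted over all sub-models rather than conditioned on one.

## Post-processing into weighted profiles

The marginal posterior of switch times is pooled and fitted with Gaussian
mixtures of 1–8 components, the count chosen by BIC (`mclust`). Each MCMC
draw is then mapped to the subset of candidate components its switches fall
into (nearest component within 3 SDs; draws with an unassignable or doubly
assigned switch are dropped, with an error if more than half drop). Subset
frequencies give the sub-model weights; sub-model rates are conditional
posterior means (a repository choice — the alternative, conditional modes,
is not materially different for unimodal conditionals). Two candidate
switches thus yield up to four mutually exclusive profiles: none, either
alone, both.

All downstream summaries — the weighted switch-count histogram, the
duration-weighted rate density/CDF (Gaussian kernel, weighted Silverman
bandwidth), durations by rate bin (deciles, or lowest three quartiles vs
top quartile), complete inter-switch times (profiles with at least two
switches only), and the Low/Active classification (an interval is Low only
when flanked by higher rates on both sides; boundary intervals are Active)
— weight every profile by its probability. Window-truncated first/last
intervals are *minimum* durations; they are kept and flagged censored
rather than dropped. Group comparisons use a bootstrap Mann–Whitney test:
one duration is drawn per cell per replicate and the histogram of replicate
p-values is read against a Bonferroni-corrected 0.5% line.

# Spatial statistics

Cell positions are per-cell medians of the centroid track. Ripley's
$K(r)$ uses translation edge correction on the rectangular field, with a
rank-based pointwise envelope from CSR simulations at the same $n$ (the
Besag min/max convention: coverage $1 - 2/(n_{\text{sim}}+1)$, i.e.
exactly 95% at 39 simulations and a conservative 98% at the default 99;
interpolated 2.5/97.5 percentiles of 99 simulations would cover only
about 93% and were avoided for that reason). A hard-core (finite cell
size) pattern dips below the lower envelope at radii under the exclusion
distance.

Pairwise trace correlation standardises both series first (making the mean
cross-product Pearson's $r$); the literal unstandardised mean cross-product
is available as an option since it is only scale-free on pre-standardised
input. Pairs are binned by distance in half-open 5-µm bins from 5 µm
(closer pairs join the first bin); each bin reports its median correlation
and a 90% band from 99 bootstrap resamples of its pairs.

## The permutation null and its calibration

The null hypothesis is that traces are exchangeable across positions.
Permuting trace labels leaves the correlation matrix untouched and only
re-assigns pairs to distance bins, so a Monte-Carlo permutation test of
each bin's median correlation costs almost nothing (1,999 permutations by
default) and is exactly calibrated. A paired t-test of 99 observed versus
99 permuted bootstrap medians is also reported per bin for comparability
with the field's common practice, but it is *not* used for calls: bootstrap
replicates of one dataset are strongly dependent, the t statistic treats
them as independent, and the test's effective type-I error is orders of
magnitude above nominal. The package's significance calls use the
permutation p-value at $p < 0.001$, and the test suite verifies near-
nominal false-positive rates on uncoupled tissue (50 seeds).

The *significant coordination range* is the maximal (longest) run of
contiguous significant bins, ties resolved toward shorter distances. On
coupled synthetic tissue significance is confined to bins below the 30-µm
coupling radius, but single bins within the run occasionally miss the
strict $p<0.001$ cut; taking the longest run rather than the first run
makes the endpoint robust to such dropouts without admitting long-range
artefacts.

Connectivity analysis treats cells as discs of diameter $D$: pairs closer
than $D$ are directly connected, connectivity is transitive (union-find
components), and pairs are classed direct / indirect (same component but
farther than $D$) / unconnected, each class summarised against a
permuted-trace baseline across a range of $D$.

Switch synchrony samples one profile per cell (weight-proportional),
enumerates all switch pairs between each cell pair, classes them by
direction agreement and by distance (≤ 30 µm vs beyond), and compares the
|Δt| distributions with one-sided KS statistics (how far the near CDF
sits to the *left* of the far CDF — the hypothesis is directional: closer
cells switch more synchronously, never less). The switch pairs of one
cell pair share switches and are strongly dependent, so an iid KS
p-value at these sample sizes rejects on negligible effects; the p-value
therefore comes from a permutation test that shuffles near/far labels
over whole cell pairs, keeping each pair's cluster of switch pairs
intact. Resampling of profiles is repeated and pooled (default 100
rounds) to reduce profile-sampling noise; a single draw mode mirrors the
one-shot analysis exactly. "No coordination" claims (the opposite-
direction class, uncoupled tissue) are checked as equivalence bounds on
the displacement statistic rather than as non-significance: with
thousands of switch pairs even a negligible displacement is detectable,
and any cyclic coupling necessarily leaves a small opposite-direction
cycle-lag displacement (aligned up-switches put the following
down-switches at correlated lags), so absence-of-effect is a statement
about magnitude, not p-values.

# The synthetic-tissue generator

The generator is the package's ground truth, emulating what the real
imaging data provide without any download. Its defaults are the study
conditions and were fixed once:

* 200 cells in a 300×300 µm field (CSR placement; hard-core available),
  46 h at 15-min sampling — an adult-scale field; analyses that need the
  larger adult dataset size use 300 cells at the same density.
* Transcriptional states follow the telegraph process with priming:
  off → primed → on → off, exponential sojourns, means 10, 8, 12 h. The
  primed state transcribes at the off rate (it differs only dynamically),
  so rate switches occur at on-entry/on-exit and a cell shows on the order
  of 0–4 switches per window — the up-to-a-few-switches-per-46-h scale
  that adult pituitary recordings display. Each on sojourn draws its own rate from
  LogNormal(log 8, 0.5) — a continuous range of activity levels, not a
  binary on/off.
* Coupling is a generative *stand-in* for local coordination, not a
  mechanism claim: each switch propagates to each neighbour within 30 µm,
  aligning the neighbour's nearest same-direction own switch to the
  source time plus N(0, 1 h) jitter. Propagation reads the source's
  current (possibly already aligned) profile, so alignment spreads in
  waves through the neighbourhood graph — while each cell's switch
  *count* and rate levels stay its own. An alternative `insert` mode adds
  a new switch in the neighbour instead; we found that insertion strong
  enough to power the spatial statistics inflates per-cell switch counts
  about four-fold (each cell receives events from ~6 neighbours) and,
  through the on-duration cycle lag of the inserted events, manufactures
  an opposite-direction synchrony signal — both at odds with the tissue
  behaviour the generator is meant to emulate — which is why aligning
  existing switches is the default.
* Reporter kinetics $\delta_m = 0.7$, $\delta_p = 0.35$, $\alpha = 5$
  h$^{-1}$, $\kappa = 1$; exact Gillespie simulation (switch times restart
  the clock, so propensities stay constant between reactions); measurement
  noise SD 5 a.u.; five pure-noise background traces mirror the
  mean-of-five-areas background convention; an optional two-detector model
  (high gain with a saturation ceiling plus low gain without) exercises
  the fusion preprocessing.

What the generator does **not** emulate: photobleaching and focus drift,
cell movement (positions are constant per cell; the median-position
convention is still exercised), cell division and death, 3-D geometry,
diffusible paracrine signalling, and any mechanistic model of gap
junctions. Passing tests therefore demonstrate that the *pipeline*
recovers what it is designed to recover under its own assumptions — they
do not validate those assumptions against real tissue.

The priming demonstration uses sojourn means off 4 h / primed 10 h / on
6 h with the primed mean halved mid-course (the primed state is then
rate-limiting): the population on-state occupancy rises from about
$6/20$ to about $6/15$ within a few sojourn times, a graded, robust
population response produced by shortening a refractory period rather
than by changing any rate.

# Problem sizes and reproducibility

Every random step runs under an explicit seed; per-stage child seeds
derive from the master seed by a counter scheme (`derive_seed`), so each
analysis stage is independently reproducible. The shipped analyses use
full-length chains (20,000 iterations) for validation and reduced chains
(8,000) for the narrative demonstration; simulation-heavy checks use 200
SSA replicates, 50 calibration seeds, 10 recovery cells, and 5–20 seeds
for spatial envelope/range statistics. These sizes give Monte-Carlo errors
comfortably inside the assertion margins while keeping a full run of the
suite on one CPU within tens of minutes.

# Known limitations

* $\alpha$ and $\kappa$ are fixed, so rates are relative; comparing rate
  *distributions* across datasets assumes a shared detector calibration.
* The LNA is a Gaussian approximation; at very low copy number it
  understates skewness, and switch timing inherits the ambiguity discussed
  above.
* The Gaussian-mixture post-processing assumes switch-time marginals are
  well separated relative to their spread; heavily overlapping candidates
  make sub-model assignment (and hence weights) unstable, which the
  >50%-unclassifiable guard turns into an explicit error.
* The coupling generator is one of many mechanisms producing the same
  statistical signature; recovering its radius validates the statistics,
  not the biology.
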