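#!/usr/bin/env Rscript
# Stage 5: spatial coordination.  On the coupled adult-like tissue:
# Ripley's K against a CSR envelope, distance-binned correlation with its
# bootstrap band, the calibrated permutation null with the significant
# coordination range, connectivity-network correlations, and the
# switch-direction synchrony analysis; the uncoupled immature-like tissue
# serves as the negative control.

suppressMessages(library(switchtissue))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 1L
set.seed(derive_seed(seed, "spatial"))

ts <- suppressMessages(subtract_background(
  load_tracks("results/tracks_adult.csv")))
pos <- median_positions(ts)

rk <- ripley_k(pos, field = c(0, 300, 0, 300), n_sim = 99)
write.csv(rk, "results/ripley_adult.csv", row.names = FALSE)
message(sprintf("Ripley's K: %.0f%% of radii inside the CSR envelope",
                100 * mean(rk$K_obs >= rk$K_lo & rk$K_obs <= rk$K_hi)))

cvd <- correlation_vs_distance(ts, max_dist = 100)
write.csv(cvd, "results/correlation_vs_distance_adult.csv",
          row.names = FALSE)

pn <- permutation_null(ts, n_perm = 1999, max_dist = 80)
write.csv(pn$bins, "results/permutation_null_adult.csv", row.names = FALSE)
if (is.null(pn$significant_range)) {
  message("no significant coordination range detected")
} else {
  message(sprintf("significant coordination range: %g-%g um",
                  pn$significant_range[1], pn$significant_range[2]))
}

conn <- connectivity_correlation(ts, D_values = seq(10, 50, by = 10))
write.csv(conn, "results/connectivity_adult.csv", row.names = FALSE)

adult_profiles <- read_profiles("results/truth_adult.json")
syn <- switch_synchrony(adult_profiles, pos, threshold = 30, R = 5)
write.csv(syn$ks, "results/synchrony_ks_adult.csv", row.names = FALSE)
same <- syn$ks[syn$ks$comparison == "same_near_vs_far", ]
message(sprintf("synchrony (same direction, <=30 um vs >30 um): KS p = %.2e",
                same$p_value))

# negative control: the uncoupled tissue
ts0 <- suppressMessages(subtract_background(
  load_tracks("results/tracks_immature.csv")))
pn0 <- permutation_null(ts0, n_perm = 1999, max_dist = 80)
write.csv(pn0$bins, "results/permutation_null_immature.csv",
          row.names = FALSE)
message(sprintf("immature-like control: %d significant bin(s)",
                sum(pn0$bins$significant)))
write_config_echo(list(stage = "spatial"), "results", seed)
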