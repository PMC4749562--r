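#!/usr/bin/env Rscript
# Stage 4: profile summaries.  Uses the ground-truth profile sets of both
# simulated tissues (every cell, weight 1) to compute the weighted
# switch-count histogram, the weighted transcription-rate CDF, state
# durations by rate bin, complete inter-switch times, and the bootstrap
# Mann-Whitney comparison of state durations between the two tissues.

suppressMessages(library(switchtissue))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 1L
set.seed(derive_seed(seed, "postprocess"))

adult <- read_profiles("results/truth_adult.json")
immature <- read_profiles("results/truth_immature.json")

counts <- switch_count_summary(adult)
write.csv(counts, "results/switch_counts_adult.csv", row.names = FALSE)
message(sprintf("adult-like tissue: mean %.2f switches per cell over 46 h",
                mean(attr(counts, "expected_per_cell"))))

cdf <- rate_distribution(adult, mode = "cdf")
write.csv(cdf, "results/rate_cdf_adult.csv", row.names = FALSE)

dur <- duration_by_rate_bin(adult, binning = "q75_split", n_draws = 20)
write.csv(dur$stats, "results/durations_by_rate_adult.csv",
          row.names = FALSE)
message(sprintf("durations (median h): low three quartiles %.1f, top quartile %.1f",
                dur$stats$median[dur$stats$bin == "<75"],
                dur$stats$median[dur$stats$bin == ">75"]))

ist <- inter_switch_times(adult)
if (!is.null(ist$density))
  write.csv(ist$density, "results/inter_switch_kde_adult.csv",
            row.names = FALSE)

mw <- bootstrap_mannwhitney(adult, immature, B = 200)
write.csv(data.frame(p_value = mw$p_values),
          "results/duration_mw_pvalues.csv", row.names = FALSE)
message(sprintf(
  "adult vs immature durations: %.0f%% of bootstrap Mann-Whitney p-values below the 0.5%% line (significant: %s)",
  100 * mw$frac_below, mw$significant))
write_config_echo(list(stage = "postprocess"), "results", seed)
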