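#!/usr/bin/env Rscript
# smFRET analysis of simulated trans-SNARE complex traces.
#
# Without syt1 the C-terminal FRET pair reports a single low-FRET state
# (~0.2, partially zippered complex); with apo-syt1 three states appear
# (0.2 / 0.5 / 0.7, progressive C-terminal zippering). Traces are simulated
# at those state means, filtered by the single-photobleach selection rule,
# pooled, and fitted with 2- and 3-component Gaussian mixtures; AIC compares
# the two descriptions.

suppressPackageStartupMessages(library(fusepore))
dir.create("results", showWarnings = FALSE)

pool_condition <- function(state_means, seed0, n_traces = 15) {
  pooled <- numeric(0)
  accepted <- 0L
  manifest <- list()
  for (i in seq_len(n_traces)) {
    tr <- simulate_smfret(state_means, state_dwell_means_s = 1,
                          total_intensity = 1000, noise_sd = 100,
                          n_frames = 300, bleach_frame = 260,
                          seed = seed0 + i)
    sel <- select_single_molecule(tr)
    manifest[[i]] <- data.frame(trace = i, accepted = sel$accepted,
                                bleach_frame = sel$bleach_frame)
    if (sel$accepted) {
      accepted <- accepted + 1L
      tr$bleach_frame <- sel$bleach_frame
      pooled <- c(pooled, fret_ratio(tr))
    }
  }
  list(pooled = pooled, accepted = accepted,
       manifest = do.call(rbind, manifest))
}

report <- list()

# apo-syt1 condition: three C-C states
syt1 <- pool_condition(c(0.2, 0.5, 0.7), seed0 = 5200)
cat(sprintf("apo-syt1: %d/15 traces accepted, %d pooled frames\n",
            syt1$accepted, length(syt1$pooled)))
sel <- select_fret_states(syt1$pooled)
fit3 <- sel$fits[["3"]]
cat(sprintf("AIC prefers m = %d; 3-state means: %s\n", sel$selected_m,
            paste(round(fit3$means, 3), collapse = ", ")))
report$syt1 <- list(selected_m = sel$selected_m, means = fit3$means,
                    weights = fit3$weights, n_frames = fit3$n_frames)
write.table(syt1$manifest, "results/smfret_manifest.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# SNAREs alone: the C-C pair shows a single low-FRET state (~0.2, partially
# zippered); a mixture fit is not meaningful for one state, so report the
# pooled ratio distribution directly
alone <- pool_condition(c(0.2), seed0 = 6200)
cat(sprintf("SNAREs alone (C-C): pooled R = %.3f +/- %.3f (%d frames)\n",
            mean(alone$pooled), sd(alone$pooled), length(alone$pooled)))
report$snare_alone <- list(mean_R = mean(alone$pooled),
                           sd_R = sd(alone$pooled),
                           n_frames = length(alone$pooled))

jsonlite::write_json(report, "results/smfret.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("written: results/smfret.json, results/smfret_manifest.tsv\n")
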