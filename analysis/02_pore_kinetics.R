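#!/usr/bin/env Rscript
# Idealize the simulated recordings from 01_simulate_pores.R and quantify:
# per-condition current levels, conductances, fraction of time open, and the
# number of exponential components the dwell-time CDFs require (AIC).

suppressPackageStartupMessages(library(fusepore))
paths <- Sys.glob("results/traces/*.tsv")
paths <- paths[!grepl("_(idealized|dwells)\\.tsv$", paths)]
if (!length(paths)) stop("run analysis/01_simulate_pores.R first")

rows <- list()
for (p in paths) {
  tr <- read_trace(p)
  tag <- tr$condition_tag
  levels <- estimate_levels(tr, 2)
  ideal <- idealize(tr, levels, dead_time_s = 2e-4)
  write_idealized(ideal, sub("\\.tsv$", "_idealized.tsv", p))
  dw <- extract_dwells(ideal)
  write_dwell_table(dw, sub("\\.tsv$", "_dwells.tsv", p))

  amp <- fit_amplitude_histogram(tr, 2)
  gamma <- conductance_from_fit(amp, tr$holding_potential_mV)
  diam <- estimate_pore_diameter(gamma$conductances_pS[["open"]],
                                 L_nm = 15, rho_ohm_cm = 100)

  sel_open <- if (length(dw$dwells$open) >= 10)
    select_model(dw$dwells$open, m_max = 3, state = "open")$selected_m
  else NA_integer_
  sel_closed <- if (length(dw$dwells$closed) >= 10)
    select_model(dw$dwells$closed, m_max = 3, state = "closed")$selected_m
  else NA_integer_

  rows[[tag]] <- data.frame(
    condition = tag,
    gamma_open_pS = round(gamma$conductances_pS[["open"]], 1),
    approx_diameter_nm = round(diam$diameter_nm, 2),
    fraction_open = round(fraction_open(dw, include_censored = TRUE), 3),
    n_open_dwells = length(dw$dwells$open),
    n_closed_dwells = length(dw$dwells$closed),
    m_open = sel_open, m_closed = sel_closed
  )
  cat(sprintf(
    "%-14s gamma = %6.1f pS (d ~ %4.2f nm), fraction open %.3f, m(open) = %s, m(closed) = %s\n",
    tag, gamma$conductances_pS[["open"]], diam$diameter_nm,
    fraction_open(dw, include_censored = TRUE),
    sel_open, sel_closed))
}
out <- do.call(rbind, rows)
write.table(out, "results/pore_kinetics_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("summary written to results/pore_kinetics_summary.tsv\n")
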