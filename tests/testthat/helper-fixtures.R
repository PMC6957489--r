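# shared fixtures: small models and hand-built containers

# dwell table built directly (bypasses idealization) for arithmetic tests
make_dwell_table <- function(open = numeric(0), closed = numeric(0),
                             partial = numeric(0),
                             censored_open = numeric(0),
                             censored_closed = numeric(0)) {
  structure(
    list(dwells = list(open = open, closed = closed, partial = partial),
         censored = list(open = censored_open, closed = censored_closed,
                         partial = numeric(0)),
         dead_time_s = 2e-4, trace_id = "fixture"),
    class = "dwell_table"
  )
}

# minimal amplitude fit object for conductance arithmetic tests
make_amplitude_fit <- function(means_pA, sds_pA = rep(1, length(means_pA)),
                               weights = rep(1 / length(means_pA),
                                             length(means_pA))) {
  ord <- order(abs(means_pA))
  structure(
    list(means_pA = means_pA[ord], sds_pA = sds_pA[ord],
         weights = weights[ord], n_components = length(means_pA),
         loglik_trace = numeric(0), n_samples = 0L),
    class = "amplitude_histogram_fit"
  )
}

# square-wave trace alternating between two current levels
square_wave_trace <- function(levels_pA, period_samples, n_periods,
                              sampling_rate_hz = 1e4) {
  x <- rep(rep(levels_pA, each = period_samples), n_periods)
  current_trace(x, sampling_rate_hz, holding_potential_mV = -60)
}

quiet_simulate_gating <- function(...) suppressMessages(simulate_gating(...))
quiet_simulate_path <- function(...) suppressMessages(simulate_path(...))
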