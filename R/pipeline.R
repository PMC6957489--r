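.pipeline_config_keys <- c(
  "seed", "model", "duration_s", "ca_free_uM", "holding_potential_mV",
  "noise_sd_pA", "n_levels", "dead_time_s", "m_max", "condition_tag",
  "smfret", "dose_response", "out_path"
)

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full single-pore analysis pipeline on a simulated recording
#'
#' Chains the package's stages end to end: simulate a gating trace,
#' estimate current levels, idealize, extract dwell times, compute the
#' fraction open, select exponential-mixture models for the opening
#' (closed-dwell) and closure (open-dwell) kinetics, fit the amplitude
#' histogram and convert it to conductances; optionally simulate and analyze
#' an smFRET dataset and a Ca2+ dose-response dataset. The report is a plain
#' list (JSON-serializable, schema-versioned, no timestamps) and the run is
#' deterministic given the seed.
#'
#' @param config named list. Required: `seed` (integer), `model` (a
#'   `gating_model` or path to a model JSON), `duration_s`, `noise_sd_pA`.
#'   Optional: `ca_free_uM`, `holding_potential_mV` (default -60),
#'   `n_levels` (default 2), `dead_time_s` (default 2e-4), `m_max`
#'   (default 3), `condition_tag`, `out_path` (write the report JSON there),
#'   `smfret` (list: `state_means`, `state_dwell_means_s`, `total_intensity`,
#'   `noise_sd`, `n_frames`, `n_traces`), `dose_response` (list:
#'   `ca_levels_uM`, `replicates`, `duration_s`). Unknown keys are rejected.
#' @return the report, invisibly also written to `out_path` when given.
#' @export
run_pipeline <- function(config) {
  if (!is.list(config) || !length(config)) stop("empty pipeline config")
  unknown <- setdiff(names(config), .pipeline_config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (key in c("seed", "model", "duration_s", "noise_sd_pA")) {
    if (is.null(config[[key]])) stop("config missing required key: ", key)
  }
  model <- config$model
  if (is.character(model)) model <- read_gating_model(model)
  stopifnot(inherits(model, "gating_model"))

  seed <- as.integer(config$seed)
  V <- config$holding_potential_mV %||% -60
  n_levels <- config$n_levels %||% 2L
  dead_time <- config$dead_time_s %||% 2e-4
  m_max <- config$m_max %||% 3L
  ca <- config$ca_free_uM %||% NA_real_
  tag <- config$condition_tag %||% "pipeline"

  trace <- run_stage("simulate", simulate_gating(
    model, config$duration_s, seed = seed, ca_free_uM = ca,
    holding_potential_mV = V, noise_sd_pA = config$noise_sd_pA,
    condition_tag = tag))

  levels <- run_stage("estimate_levels", estimate_levels(trace, n_levels))
  ideal <- run_stage("idealize", idealize(trace, levels, dead_time))
  dwells <- run_stage("extract_dwells", extract_dwells(ideal))
  fo <- run_stage("fraction_open",
                  fraction_open(dwells, include_censored = TRUE))

  kinetics <- list()
  for (st in intersect(c("closed", "open"), names(dwells$dwells))) {
    d <- dwells$dwells[[st]]
    if (length(d) >= 10L) {
      sel <- run_stage(paste0("kinetics_", st),
                       select_model(d, m_max = m_max, state = st))
      kinetics[[st]] <- list(
        selected_m = sel$selected_m,
        aic = as.list(sel$aic_values),
        amplitudes = sel$fits[[as.character(sel$selected_m)]]$amplitudes,
        rates_per_s = sel$fits[[as.character(sel$selected_m)]]$rates_per_s,
        n_dwells = length(d))
    } else {
      kinetics[[st]] <- list(selected_m = NA_integer_,
                             note = "fewer than 10 dwells", n_dwells = length(d))
    }
  }

  amp <- run_stage("conductance", fit_amplitude_histogram(trace, n_levels))
  cond <- run_stage("conductance", conductance_from_fit(amp, V))

  report <- list(
    schema_version = "1.0",
    parameters = list(seed = seed, duration_s = config$duration_s,
                      ca_free_uM = ca, holding_potential_mV = V,
                      noise_sd_pA = config$noise_sd_pA,
                      n_levels = n_levels, dead_time_s = dead_time,
                      m_max = m_max, condition_tag = tag),
    trace = list(n_samples = length(trace$samples),
                 sampling_rate_hz = trace$sampling_rate_hz),
    idealization = list(n_segments = nrow(ideal$segments),
                        levels_pA = levels),
    fraction_open = fo,
    kinetics = kinetics,
    conductance = list(
      means_pA = amp$means_pA, sds_pA = amp$sds_pA, weights = amp$weights,
      conductances_pS = as.list(cond$conductances_pS))
  )

  if (!is.null(config$smfret)) {
    sm <- config$smfret
    n_traces <- sm$n_traces %||% 10L
    pooled <- numeric(0)
    accepted <- 0L
    for (i in seq_len(n_traces)) {
      tr <- run_stage("smfret_simulate", simulate_smfret(
        sm$state_means, sm$state_dwell_means_s %||% 1,
        total_intensity = sm$total_intensity %||% 1000,
        noise_sd = sm$noise_sd %||% 0,
        n_frames = sm$n_frames %||% 200L,
        bleach_frame = as.integer((sm$n_frames %||% 200L) * 0.9),
        seed = derive_seed(seed, 7000L + i)))
      selres <- run_stage("smfret_select", select_single_molecule(tr))
      if (selres$accepted) {
        accepted <- accepted + 1L
        tr$bleach_frame <- selres$bleach_frame
        pooled <- c(pooled, fret_ratio(tr))
      }
    }
    m <- length(sm$state_means)
    fret_fit <- if (length(pooled) >= 200L && m %in% 2:3) {
      run_stage("smfret_fit", fit_fret_histogram(pooled, m))
    } else NULL
    report$smfret <- list(
      n_traces = n_traces, n_accepted = accepted,
      n_pooled_frames = length(pooled),
      state_means = if (!is.null(fret_fit)) fret_fit$means else NULL,
      weights = if (!is.null(fret_fit)) fret_fit$weights else NULL)
  }

  if (!is.null(config$dose_response)) {
    dr <- config$dose_response
    sim <- run_stage("dose_response", simulate_dose_response(
      model, dr$ca_levels_uM, dr$replicates %||% 10L,
      seed = derive_seed(seed, 9001L),
      duration_s = dr$duration_s %||% 30))
    report$dose_response <- as.list(as.data.frame(sim))
  }

  if (!is.null(config$out_path)) {
    jsonlite::write_json(report, config$out_path, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null",
                         pretty = TRUE)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-line human-readable pipeline summary
#'
#' @param report a report from [run_pipeline()].
#' @return character vector of summary lines (also printed).
#' @export
summarize_report <- function(report) {
  lines <- c(
    sprintf("trace: %d samples @ %g Hz, %d segment(s)",
            report$trace$n_samples, report$trace$sampling_rate_hz,
            report$idealization$n_segments),
    sprintf("fraction open: %.4f", report$fraction_open),
    vapply(names(report$kinetics), function(st) {
      k <- report$kinetics[[st]]
      if (is.na(k$selected_m)) {
        sprintf("%s dwells: %d (too few for kinetics)", st, k$n_dwells)
      } else {
        sprintf("%s dwells: n = %d, selected m = %d", st, k$n_dwells,
                k$selected_m)
      }
    }, character(1)),
    sprintf("conductances: %s",
            paste(sprintf("%s = %.1f pS", names(report$conductance$conductances_pS),
                          unlist(report$conductance$conductances_pS)),
                  collapse = ", "))
  )
  cat(lines, sep = "\n")
  invisible(lines)
}
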