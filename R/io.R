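# sidecar path for a data file
sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a current trace
#'
#' Traces are stored as two-column tab-separated text (`time_s`,
#' `current_pA`, current at 3 decimals) plus a JSON sidecar
#' (`<path>.json`) carrying `sampling_rate_hz`, `holding_potential_mV`,
#' `ca_free_uM`, `condition_tag` and `noise_sd_pA`.
#'
#' @param trace a `current_trace`.
#' @param path file path for the tab-separated table.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   `current_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  n <- length(trace$samples)
  df <- data.frame(
    time_s = sprintf("%.6f", (seq_len(n) - 1) / trace$sampling_rate_hz),
    current_pA = sprintf("%.3f", trace$samples)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(sampling_rate_hz = trace$sampling_rate_hz,
               holding_potential_mV = trace$holding_potential_mV,
               ca_free_uM = trace$ca_free_uM,
               condition_tag = trace$condition_tag,
               noise_sd_pA = trace$noise_sd_pA)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing sidecar JSON: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (key in c("sampling_rate_hz", "holding_potential_mV")) {
    if (is.null(meta[[key]])) stop("sidecar missing required key: ", key)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  dt <- diff(df$time_s)
  if (length(dt) && any(abs(dt - 1 / meta$sampling_rate_hz) > 1e-6)) {
    stop("non-uniform timestamps (tolerance 1e-6 s)")
  }
  current_trace(df$current_pA, meta$sampling_rate_hz,
                meta$holding_potential_mV,
                ca_free_uM = if (is.null(meta$ca_free_uM)) NA_real_
                else meta$ca_free_uM,
                noise_sd_pA = if (is.null(meta$noise_sd_pA)) NA_real_
                else meta$noise_sd_pA,
                condition_tag = if (is.null(meta$condition_tag)) ""
                else meta$condition_tag)
}

#' Write / read a two-channel FRET trace
#'
#' Three-column tab-separated text (`frame`, `donor`, `acceptor`) with a JSON
#' sidecar (`frame_interval_s`, `crosstalk`, `bleach_frame`).
#'
#' @param trace a `fret_trace`.
#' @param path file path.
#' @export
write_fret_trace <- function(trace, path) {
  stopifnot(inherits(trace, "fret_trace"))
  df <- data.frame(frame = seq_along(trace$donor),
                   donor = sprintf("%.3f", trace$donor),
                   acceptor = sprintf("%.3f", trace$acceptor))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(frame_interval_s = trace$frame_interval_s,
               crosstalk = trace$crosstalk,
               bleach_frame = trace$bleach_frame)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_fret_trace
#' @export
read_fret_trace <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing sidecar JSON: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (key in c("frame_interval_s", "crosstalk")) {
    if (is.null(meta[[key]])) stop("sidecar missing required key: ", key)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  fret_trace(df$donor, df$acceptor, meta$frame_interval_s, meta$crosstalk,
             bleach_frame = if (is.null(meta$bleach_frame) ||
                                is.na(meta$bleach_frame)) NA_integer_
             else as.integer(meta$bleach_frame))
}

#' Write / read a gating model as JSON
#'
#' @param model a `gating_model`.
#' @param path JSON file path.
#' @export
write_gating_model <- function(model, path) {
  stopifnot(inherits(model, "gating_model"))
  doc <- list(states = model$states,
              conductances_pS = unname(model$conductances_pS),
              rates_per_s = apply(model$rates_per_s, 1, as.numeric,
                                  simplify = FALSE),
              ca_modulation = model$ca_modulation)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_gating_model
#' @export
read_gating_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  Q <- do.call(rbind, lapply(doc$rates_per_s, as.numeric))
  mod <- if (is.null(doc$ca_modulation)) NULL else {
    if (is.data.frame(doc$ca_modulation)) {
      lapply(seq_len(nrow(doc$ca_modulation)),
             function(i) as.list(doc$ca_modulation[i, ]))
    } else doc$ca_modulation
  }
  gating_model(doc$states, doc$conductances_pS, Q, mod)
}

#' Write an idealized trace or dwell table as tab-separated text
#'
#' Idealized traces serialize as (`state`, `start_s`, `end_s`, `mean_pA`),
#' dwell tables as (`state`, `dwell_s`, `censored`); each file carries the
#' source-trace identifier in a leading `#` comment line.
#'
#' @param idealized an `idealized_trace`.
#' @param path file path.
#' @export
write_idealized <- function(idealized, path) {
  stopifnot(inherits(idealized, "idealized_trace"))
  fs <- idealized$sampling_rate_hz
  seg <- idealized$segments
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# trace: ", idealized$trace_id), con)
  df <- data.frame(state = seg$state,
                   start_s = sprintf("%.6f", seg$start / fs),
                   end_s = sprintf("%.6f", seg$end / fs),
                   mean_pA = sprintf("%.3f", seg$mean_pA))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_idealized
#' @param dwells a `dwell_table`.
#' @export
write_dwell_table <- function(dwells, path) {
  stopifnot(inherits(dwells, "dwell_table"))
  rows <- list()
  for (s in names(dwells$dwells)) {
    if (length(dwells$dwells[[s]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        state = s, dwell_s = dwells$dwells[[s]], censored = FALSE)
    }
    if (length(dwells$censored[[s]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        state = s, dwell_s = dwells$censored[[s]], censored = TRUE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows)
  else data.frame(state = character(0), dwell_s = numeric(0),
                  censored = logical(0))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# trace: ", dwells$trace_id), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
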