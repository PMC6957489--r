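# map levels (pA) to canonical state names: smallest |level| = closed,
# largest = open, middle (3 levels) = partial
level_state_names <- function(levels) {
  r <- rank(abs(levels), ties.method = "first")
  if (length(levels) == 2L) {
    c("closed", "open")[r]
  } else if (length(levels) == 3L) {
    c("closed", "partial", "open")[r]
  } else {
    paste0("level", r)
  }
}

#' Estimate discrete current levels from a trace
#'
#' Fits an `n_levels`-component Gaussian mixture to the current amplitude
#' histogram (via [fit_amplitude_histogram()]) and returns the component
#' means sorted by magnitude, closed (nearest 0 pA) first.
#'
#' @param trace a `current_trace` of at least 1 s.
#' @param n_levels 2 or 3.
#' @return numeric vector of level currents in pA.
#' @export
estimate_levels <- function(trace, n_levels) {
  if (!n_levels %in% 2:3) stop("n_levels must be 2 or 3")
  if (trace_duration(trace) < 1) stop("trace must be at least 1 s long")
  fit <- tryCatch(
    fit_amplitude_histogram(trace, n_levels),
    error = function(e) {
      stop("could not resolve ", n_levels, " current levels: ",
           conditionMessage(e), call. = FALSE)
    }
  )
  fit$means_pA
}

#' Idealize a current trace into discrete state segments
#'
#' Threshold-crossing event detection: each sample is assigned to the nearest
#' supplied level, using half-amplitude thresholds between levels with a
#' hysteresis of 10% of the inter-level gap. Runs shorter than `dead_time_s`
#' are merged into the flanking segment with the longer duration (ties merge
#' into the earlier segment); segment mean currents are then recomputed from
#' the raw samples.
#'
#' @param trace a `current_trace`.
#' @param levels numeric vector (>= 2 distinct values) of level currents, pA.
#' @param dead_time_s minimum resolvable event duration, s; must be at least
#'   two sample intervals. Default 0.2 ms (two samples at 10 kHz, above the
#'   ~66 us rise time of a 5 kHz Bessel filter).
#' @param hysteresis_frac hysteresis as a fraction of the inter-level gap.
#' @return object of class `idealized_trace`: a list with `segments`
#'   (data.frame: `state`, `level_index`, `start`, `end` (half-open sample
#'   indices, 0-based start), `mean_pA`), `levels_pA`, `sampling_rate_hz`,
#'   `dead_time_s`, `trace_id`.
#' @export
idealize <- function(trace, levels, dead_time_s = 2e-4,
                     hysteresis_frac = 0.1) {
  levels <- as.numeric(levels)
  if (length(levels) < 2L) stop("need at least 2 levels")
  if (anyDuplicated(levels)) stop("levels must be distinct")
  fs <- trace$sampling_rate_hz
  if (dead_time_s < 2 / fs) {
    stop("dead_time_s must be at least two sample intervals (",
         signif(2 / fs, 3), " s)")
  }
  x <- trace$samples
  idx <- assign_levels_hysteresis(x, levels, hysteresis_frac)

  r <- rle(idx)
  len <- r$lengths
  lab <- r$values
  n_dead <- as.integer(round(dead_time_s * fs))

  # merge sub-dead-time runs, shortest first (ties: earliest), into the
  # longer flanking run (ties: earlier neighbour)
  repeat {
    if (length(len) <= 1L) break
    short <- which(len < n_dead)
    if (!length(short)) break
    i <- short[which.min(len[short])]
    j <- if (i == 1L) 2L
    else if (i == length(len)) i - 1L
    else if (len[i + 1L] > len[i - 1L]) i + 1L
    else i - 1L
    lab[i] <- lab[j]
    # coalesce adjacent equal labels
    keep_r <- rle(lab)
    new_len <- as.integer(rowsum(len, rep(seq_along(keep_r$lengths),
                                          keep_r$lengths)))
    len <- new_len
    lab <- keep_r$values
  }

  ends <- cumsum(len)
  starts <- c(0L, ends[-length(ends)])
  mean_pA <- vapply(seq_along(len), function(k) {
    mean(x[(starts[k] + 1L):ends[k]])
  }, numeric(1))
  state <- level_state_names(levels)[lab]

  structure(
    list(segments = data.frame(state = state, level_index = lab,
                               start = starts, end = ends,
                               mean_pA = mean_pA, stringsAsFactors = FALSE),
         levels_pA = levels,
         sampling_rate_hz = fs,
         dead_time_s = dead_time_s,
         trace_id = trace$condition_tag),
    class = "idealized_trace"
  )
}

#' @export
print.idealized_trace <- function(x, ...) {
  cat(sprintf("Idealized trace: %d segment(s), %d level(s), dead time %.4g ms\n",
              nrow(x$segments), length(x$levels_pA), 1000 * x$dead_time_s))
  print(utils::head(x$segments, 10))
  if (nrow(x$segments) > 10) cat("  ...\n")
  invisible(x)
}

#' Extract per-state dwell times from an idealized trace
#'
#' The first and last segments are censored (their true onset/offset is
#' unknown) and excluded from the dwell lists, but their durations are
#' retained separately for fraction-open bookkeeping.
#'
#' @param idealized an `idealized_trace`.
#' @return object of class `dwell_table`: list with `dwells` (named list,
#'   state -> numeric durations in s), `censored` (same shape, the first/last
#'   segment durations), `dead_time_s`, `trace_id`.
#' @export
extract_dwells <- function(idealized) {
  seg <- idealized$segments
  if (!nrow(seg)) stop("idealized trace has no segments")
  fs <- idealized$sampling_rate_hz
  dur <- (seg$end - seg$start) / fs
  n <- nrow(seg)
  cens_idx <- unique(c(1L, n))
  interior <- setdiff(seq_len(n), cens_idx)

  states <- sort(unique(seg$state))
  dwells <- lapply(states, function(s) dur[interior][seg$state[interior] == s])
  censored <- lapply(states, function(s) dur[cens_idx][seg$state[cens_idx] == s])
  names(dwells) <- names(censored) <- states

  structure(
    list(dwells = dwells, censored = censored,
         dead_time_s = idealized$dead_time_s,
         trace_id = idealized$trace_id),
    class = "dwell_table"
  )
}

#' @export
print.dwell_table <- function(x, ...) {
  cat("Dwell table", if (nzchar(x$trace_id)) paste0("(", x$trace_id, ")"), "\n")
  for (s in names(x$dwells)) {
    cat(sprintf("  %-8s %5d dwell(s), %d censored, total %.4g s\n", s,
                length(x$dwells[[s]]), length(x$censored[[s]]),
                sum(x$dwells[[s]], x$censored[[s]])))
  }
  invisible(x)
}
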