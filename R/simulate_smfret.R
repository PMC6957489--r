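#' Construct a two-channel smFRET trace
#'
#' @param donor,acceptor per-frame donor/acceptor intensities (a.u., after
#'   background subtraction; negative values are clipped at 0). Equal length,
#'   at least 10 frames.
#' @param frame_interval_s frame interval in s (default 0.1, i.e. 100 ms).
#' @param crosstalk fraction of donor signal leaking into the acceptor
#'   channel (default 0.05, fixed by the ratio definition).
#' @param bleach_frame index of the last pre-bleach frame, or `NA`.
#' @return object of class `fret_trace`.
#' @export
fret_trace <- function(donor, acceptor, frame_interval_s = 0.1,
                       crosstalk = 0.05, bleach_frame = NA_integer_) {
  donor <- pmax(as.numeric(donor), 0)
  acceptor <- pmax(as.numeric(acceptor), 0)
  if (length(donor) != length(acceptor)) {
    stop("donor and acceptor must have equal length")
  }
  if (length(donor) < 10L) stop("a FRET trace needs at least 10 frames")
  structure(
    list(donor = donor, acceptor = acceptor,
         frame_interval_s = frame_interval_s,
         crosstalk = crosstalk,
         bleach_frame = bleach_frame),
    class = "fret_trace"
  )
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("smFRET trace: %d frames @ %.0f ms, crosstalk %.2f",
              length(x$donor), 1000 * x$frame_interval_s, x$crosstalk))
  if (!is.na(x$bleach_frame)) cat(", bleach at frame", x$bleach_frame)
  cat("\n")
  invisible(x)
}

#' Simulate a single-molecule FRET trace
#'
#' Draws a hidden state path over discrete FRET states (exponential dwell
#' times, uniform jumps among the other states), then renders noiseless
#' donor/acceptor intensities such that the crosstalk-corrected ratio
#' `R = (IA - crosstalk*ID) / (ID + IA)` applied to the noiseless frame
#' returns the state mean exactly:
#' `ID = T (1 - R) / (1 + crosstalk)`, `IA = T (R + crosstalk) / (1 + crosstalk)`
#' where `T` is the constant total intensity. Gaussian noise is then added
#' per channel (clipped at 0) and both channels drop to background (0) after
#' the single photobleaching event at `bleach_frame`.
#'
#' @param state_means FRET ratios of the hidden states, each in \[0, 1\].
#' @param state_dwell_means_s mean dwell per state, s (recycled to the number
#'   of states).
#' @param total_intensity total (donor + acceptor) intensity per frame, a.u.
#' @param noise_sd per-channel Gaussian noise sd, a.u.
#' @param n_frames number of frames (>= 10).
#' @param bleach_frame last bright frame; `NA` for no bleach within the trace.
#' @param seed integer seed.
#' @param frame_interval_s frame interval, s.
#' @param crosstalk donor-to-acceptor crosstalk fraction (default 0.05).
#' @return a `fret_trace` with fields `true_states` (per-frame state index)
#'   and `true_R` (per-frame noiseless ratio) retained for oracle tests.
#' @export
simulate_smfret <- function(state_means, state_dwell_means_s,
                            total_intensity = 1000, noise_sd = 0,
                            n_frames = 200, bleach_frame = NA_integer_,
                            seed, frame_interval_s = 0.1, crosstalk = 0.05) {
  if (any(state_means < 0 | state_means > 1)) {
    stop("state means must lie in [0, 1]")
  }
  if (total_intensity <= 0) stop("total_intensity must be > 0")
  if (n_frames < 10L) stop("n_frames must be >= 10")
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  ns <- length(state_means)
  dw <- rep_len(state_dwell_means_s, ns)
  if (any(dw <= 0)) stop("state dwell means must be > 0")

  withr::with_seed(seed, {
    # hidden CTMC sampled at frame starts
    t_frames <- (seq_len(n_frames) - 1) * frame_interval_s
    total_t <- n_frames * frame_interval_s
    cur <- sample.int(ns, 1)
    st <- integer(0); t0 <- numeric(0)
    t <- 0
    while (t < total_t) {
      st <- c(st, cur); t0 <- c(t0, t)
      t <- t + stats::rexp(1, 1 / dw[cur])
      if (ns > 1L) {
        cur <- if (ns == 2L) 3L - cur else {
          others <- setdiff(seq_len(ns), cur)
          others[sample.int(ns - 1L, 1)]
        }
      }
    }
    state_idx <- st[findInterval(t_frames, t0)]
    R_true <- state_means[state_idx]

    ID <- total_intensity * (1 - R_true) / (1 + crosstalk)
    IA <- total_intensity * (R_true + crosstalk) / (1 + crosstalk)
    if (!is.na(bleach_frame)) {
      dark <- seq_len(n_frames) > bleach_frame
      ID[dark] <- 0
      IA[dark] <- 0
      state_idx[dark] <- NA_integer_
      R_true[dark] <- NA_real_
    }
    if (noise_sd > 0) {
      ID <- ID + stats::rnorm(n_frames, sd = noise_sd)
      IA <- IA + stats::rnorm(n_frames, sd = noise_sd)
    }
    tr <- fret_trace(ID, IA, frame_interval_s, crosstalk, bleach_frame)
    tr$true_states <- state_idx
    tr$true_R <- R_true
    tr
  })
}
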