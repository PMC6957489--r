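# --- Bessel filter -----------------------------------------------------------

# 4th-order analog Bessel prototype poles, normalized so |H(j)| = -3 dB.
# Standard table values for the Thomson (maximally flat delay) filter.
.bessel4_poles <- c(-1.3700678306 + 0.4102497175i,
                    -1.3700678306 - 0.4102497175i,
                    -0.9952087644 + 1.2571057395i,
                    -0.9952087644 - 1.2571057395i)

# polynomial coefficients (descending powers) from roots, via convolution
poly_from_roots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Design a digital 4-pole low-pass Bessel filter
#'
#' Bilinear transform (with frequency prewarping) of the analog 4th-order
#' Bessel prototype, normalized to unit DC gain. Used to emulate the analog
#' anti-alias filtering of a patch/bilayer-clamp acquisition chain.
#'
#' @param cutoff_hz -3 dB cutoff frequency in Hz.
#' @param sampling_rate_hz sampling rate of the signal to be filtered, Hz.
#' @return list with numerator `b`, denominator `a`, and the DC group delay
#'   `group_delay_samples`.
#' @export
bessel_lowpass <- function(cutoff_hz, sampling_rate_hz) {
  if (cutoff_hz <= 0 || cutoff_hz >= sampling_rate_hz / 2) {
    stop("cutoff must lie in (0, sampling_rate/2)")
  }
  fs <- sampling_rate_hz
  # prewarped analog cutoff so the digital -3 dB point lands at cutoff_hz
  wc <- 2 * fs * tan(pi * cutoff_hz / fs)
  p <- .bessel4_poles * wc
  # bilinear transform: s = 2 fs (z-1)/(z+1)
  pd <- (2 * fs + p) / (2 * fs - p)
  a <- Re(poly_from_roots(pd))
  b <- poly_from_roots(rep(-1 + 0i, 4))
  b <- Re(b) * (sum(a) / sum(Re(b)))  # unit DC gain
  # DC group delay from the phase slope at a very low frequency
  w <- 1e-4
  H <- function(w) {
    z <- exp(-1i * w * (seq_along(b) - 1))
    sum(b * z) / sum(a * z)
  }
  gd <- -(Arg(H(w)) - Arg(H(0))) / w
  list(b = b, a = a, group_delay_samples = gd)
}

# forward-only filtering with integer group-delay compensation
apply_bessel <- function(x, cutoff_hz, sampling_rate_hz) {
  flt <- bessel_lowpass(cutoff_hz, sampling_rate_hz)
  y <- as.numeric(signal::filter(flt$b, flt$a, x))
  d <- round(flt$group_delay_samples)
  if (d > 0 && d < length(y)) {
    y <- c(y[(d + 1):length(y)], rep(y[length(y)], d))
  }
  y
}

# --- CTMC path simulation ----------------------------------------------------

#' Simulate a state path from a gating model
#'
#' Draws a continuous-time Markov chain trajectory: exponential holding times
#' at each state's total exit rate, jump probabilities proportional to the
#' outgoing rates. States with zero total exit rate are absorbing (the chain
#' stays there until `duration_s`); this is allowed and logged via `message()`.
#'
#' @param model a [gating_model()].
#' @param duration_s trajectory length in s (> 0).
#' @param seed integer seed (mandatory; no global random state is consumed).
#' @param ca_free_uM free Ca2+ in uM (needed when the model has modulation).
#' @param init_state starting state label; default `"closed"` if present,
#'   otherwise the first state.
#' @return data.frame with columns `state`, `t_start_s`, `t_end_s`.
#' @export
simulate_path <- function(model, duration_s, seed, ca_free_uM = NA_real_,
                          init_state = NULL) {
  stopifnot(inherits(model, "gating_model"))
  if (!is.finite(duration_s) || duration_s <= 0) {
    stop("duration_s must be > 0")
  }
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  Q <- effective_rates(model, ca_free_uM)
  states <- model$states
  if (is.null(init_state)) {
    init_state <- if ("closed" %in% states) "closed" else states[1]
  }
  if (!init_state %in% states) stop("unknown state in model: ", init_state)
  withr::with_seed(seed, {
    cur <- match(init_state, states)
    t <- 0
    st <- integer(0); t0 <- numeric(0); t1 <- numeric(0)
    absorbed_logged <- FALSE
    repeat {
      exit <- sum(Q[cur, ])
      if (exit <= 0) {
        if (!absorbed_logged) {
          message("state '", states[cur], "' has zero exit rate; treating as absorbing")
          absorbed_logged <- TRUE
        }
        st <- c(st, cur); t0 <- c(t0, t); t1 <- c(t1, duration_s)
        break
      }
      dwell <- stats::rexp(1, exit)
      tend <- min(t + dwell, duration_s)
      st <- c(st, cur); t0 <- c(t0, t); t1 <- c(t1, tend)
      if (tend >= duration_s) break
      t <- tend
      cur <- sample.int(length(states), 1, prob = Q[cur, ])
    }
    data.frame(state = states[st], t_start_s = t0, t_end_s = t1,
               stringsAsFactors = FALSE)
  })
}

# --- trace container ---------------------------------------------------------

#' Construct a current trace
#'
#' @param samples current samples in pA.
#' @param sampling_rate_hz sampling rate in Hz (> 0).
#' @param holding_potential_mV holding potential (cis minus trans, trans = 0).
#' @param ca_free_uM free Ca2+ in uM or `NA`.
#' @param noise_sd_pA simulated recording noise sd (pA), `NA` for real data.
#' @param condition_tag free-text condition label.
#' @return object of class `current_trace`.
#' @export
current_trace <- function(samples, sampling_rate_hz, holding_potential_mV,
                          ca_free_uM = NA_real_, noise_sd_pA = NA_real_,
                          condition_tag = "") {
  if (!is.finite(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be > 0")
  }
  structure(
    list(samples = as.numeric(samples),
         sampling_rate_hz = sampling_rate_hz,
         holding_potential_mV = holding_potential_mV,
         ca_free_uM = ca_free_uM,
         noise_sd_pA = noise_sd_pA,
         condition_tag = condition_tag),
    class = "current_trace"
  )
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("Current trace: %d samples @ %.0f Hz (%.3f s), holding %.0f mV\n",
              length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz, x$holding_potential_mV))
  if (!is.na(x$ca_free_uM)) cat(sprintf("  [Ca2+]free = %.3g uM\n", x$ca_free_uM))
  if (nzchar(x$condition_tag)) cat("  condition:", x$condition_tag, "\n")
  invisible(x)
}

#' Trace duration in seconds
#' @param trace a `current_trace`.
#' @export
trace_duration <- function(trace) {
  length(trace$samples) / trace$sampling_rate_hz
}

# --- full trace rendering ----------------------------------------------------

#' Simulate a single-pore current recording
#'
#' Renders a gating-model trajectory as a sampled current trace the way a
#' bilayer-clamp acquisition chain would see it: per-sample current
#' `I = conductance_pS * holding_potential_mV / 1000` pA (downward/negative
#' openings at -60 mV), additive Gaussian recording noise, 4-pole low-pass
#' Bessel filtering at `bessel_cutoff_hz`, and decimation to the output rate.
#' The simulation runs at `oversample` times the output rate before filtering
#' so that filter-induced event rounding is reproduced.
#'
#' The true hidden state path (one label per output sample) and the ideal
#' noise-free unfiltered current are attached as fields `state_path` and
#' `ideal_pA` for oracle testing.
#'
#' @inheritParams simulate_path
#' @param holding_potential_mV holding potential in mV; must be nonzero for
#'   traces intended for conductance estimation.
#' @param noise_sd_pA Gaussian recording noise sd in pA (added at the
#'   oversampled rate, before filtering).
#' @param sampling_rate_hz output sampling rate, Hz (default 10 kHz).
#' @param oversample integer oversampling factor before filtering (default 8).
#' @param bessel apply the low-pass Bessel filter (default TRUE).
#' @param bessel_cutoff_hz filter cutoff, Hz (default 5 kHz).
#' @param condition_tag free-text label stored on the trace.
#' @return a `current_trace` with extra fields `state_path` (character) and
#'   `ideal_pA` (numeric), both at the output sampling rate.
#' @export
simulate_gating <- function(model, duration_s, seed,
                            ca_free_uM = NA_real_,
                            holding_potential_mV = -60,
                            noise_sd_pA = 0,
                            sampling_rate_hz = 1e4,
                            oversample = 8L,
                            bessel = TRUE,
                            bessel_cutoff_hz = 5000,
                            init_state = NULL,
                            condition_tag = "") {
  if (!is.finite(duration_s) || duration_s <= 0) stop("duration_s must be > 0")
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  path <- simulate_path(model, duration_s, seed = seed,
                        ca_free_uM = ca_free_uM, init_state = init_state)
  gamma <- model$conductances_pS
  V <- holding_potential_mV

  fs_out <- sampling_rate_hz
  fs_int <- fs_out * oversample
  n_out <- floor(duration_s * fs_out)
  n_int <- n_out * oversample

  t_int <- (seq_len(n_int) - 1) / fs_int
  seg <- findInterval(t_int, path$t_start_s)
  ideal_int <- gamma[path$state[seg]] * V / 1000

  x <- ideal_int
  if (noise_sd_pA > 0) {
    x <- x + withr::with_seed(derive_seed(seed, 1L),
                              stats::rnorm(n_int, sd = noise_sd_pA))
  }
  if (bessel) x <- apply_bessel(x, bessel_cutoff_hz, fs_int)
  keep <- seq(1L, n_int, by = oversample)
  samples <- x[keep]

  t_out <- (seq_len(n_out) - 1) / fs_out
  seg_out <- findInterval(t_out, path$t_start_s)
  state_path <- path$state[seg_out]
  ideal_out <- unname(gamma[state_path] * V / 1000)

  tr <- current_trace(samples, fs_out, V, ca_free_uM, noise_sd_pA,
                      condition_tag)
  tr$state_path <- state_path
  tr$ideal_pA <- ideal_out
  tr$path <- path
  tr
}

# --- dose-response simulation ------------------------------------------------

#' Simulate a Ca2+ dose-response dataset from a gating model
#'
#' For each free-Ca2+ level, simulates `replicates` independent gating
#' trajectories and summarizes, per level: the mean open-state dwell time
#' (interior sojourns only), the time-weighted mean conductance over
#' conducting sojourns, and the fraction of replicates in which at least one
#' opening occurred, each with SEM across replicates.
#'
#' @param model a [gating_model()] (typically with `ca_modulation`).
#' @param ca_levels_uM free Ca2+ levels, uM; must be nonempty and distinct.
#' @param replicates trials per level (>= 2).
#' @param seed integer seed.
#' @param duration_s trajectory length per trial, s.
#' @return data.frame of class `dose_response_sim` with one row per level.
#' @export
simulate_dose_response <- function(model, ca_levels_uM, replicates, seed,
                                   duration_s = 60) {
  if (!length(ca_levels_uM)) stop("ca_levels_uM must be nonempty")
  if (length(ca_levels_uM) > 1L && length(unique(ca_levels_uM)) == 1L) {
    stop("all Ca2+ levels are equal: single-point curve is unfittable")
  }
  if (anyDuplicated(ca_levels_uM)) stop("ca_levels_uM must be distinct")
  if (replicates < 2) stop("replicates must be >= 2")
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  ca_levels_uM <- sort(ca_levels_uM)
  gamma <- model$conductances_pS
  conducting <- model$states[gamma > 0]

  rows <- lapply(seq_along(ca_levels_uM), function(i) {
    ca <- ca_levels_uM[i]
    open_means <- numeric(0)
    cond_means <- numeric(0)
    occ <- logical(replicates)
    for (r in seq_len(replicates)) {
      p <- simulate_path(model, duration_s,
                         seed = derive_seed(seed, i * 100000L + r),
                         ca_free_uM = ca)
      interior <- p[-c(1L, nrow(p)), , drop = FALSE]
      od <- interior$t_end_s[interior$state == "open"] -
        interior$t_start_s[interior$state == "open"]
      if (length(od)) open_means <- c(open_means, mean(od))
      is_cond <- p$state %in% conducting
      occ[r] <- any(is_cond)
      if (any(is_cond)) {
        dt <- p$t_end_s[is_cond] - p$t_start_s[is_cond]
        cond_means <- c(cond_means,
                        sum(gamma[p$state[is_cond]] * dt) / sum(dt))
      }
    }
    sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    pocc <- mean(occ)
    data.frame(
      ca_uM = ca,
      open_dwell_mean_s = if (length(open_means)) mean(open_means) else NA_real_,
      open_dwell_sem_s = sem(open_means),
      conductance_mean_pS = if (length(cond_means)) mean(cond_means) else NA_real_,
      conductance_sem_pS = sem(cond_means),
      occurrence_fraction = pocc,
      occurrence_sem = sqrt(pocc * (1 - pocc) / replicates),
      n = replicates
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dose_response_sim", "data.frame")
  out
}
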