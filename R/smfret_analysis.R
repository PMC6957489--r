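#' Per-frame FRET ratio of a trace
#'
#' `R = (IA - crosstalk * ID) / (ID + IA)` with the donor-to-acceptor
#' crosstalk fraction fixed at the trace's value (0.05 by convention).
#' Frames after the photobleaching event (when `bleach_frame` is set) and
#' frames with zero total intensity are excluded.
#'
#' @param trace a `fret_trace`.
#' @return numeric vector of ratios with attribute `frames` giving the frame
#'   indices used.
#' @export
fret_ratio <- function(trace) {
  stopifnot(inherits(trace, "fret_trace"))
  ID <- trace$donor; IA <- trace$acceptor
  n <- length(ID)
  keep <- rep(TRUE, n)
  if (!is.na(trace$bleach_frame)) {
    keep[seq_len(n) > trace$bleach_frame] <- FALSE
  }
  tot <- ID + IA
  keep <- keep & tot > 0
  if (!any(keep)) stop("no evaluable frames: all have ID + IA = 0")
  R <- (IA[keep] - trace$crosstalk * ID[keep]) / tot[keep]
  attr(R, "frames") <- which(keep)
  R
}

# best two-mean split of a segment: position (last index of the left part)
# and the mean drop (left minus right), by maximal standardized split statistic
.best_split <- function(x, min_seg) {
  n <- length(x)
  if (n < 2L * min_seg) return(NULL)
  cs <- cumsum(x)
  t <- min_seg:(n - min_seg)
  m1 <- cs[t] / t
  m2 <- (cs[n] - cs[t]) / (n - t)
  stat <- abs(m1 - m2) * sqrt(t * (n - t) / n)
  i <- which.max(stat)
  list(pos = t[i], drop = m1[i] - m2[i])
}

# recursive binary segmentation for intensity steps; returns data.frame of
# steps (frame = last pre-step frame, drop, significant)
.find_steps <- function(x, offset, min_seg, sigma_mult) {
  sp <- .best_split(x, min_seg)
  if (is.null(sp)) return(NULL)
  pre <- x[seq_len(sp$pos)]
  post <- x[(sp$pos + 1L):length(x)]
  noise <- stats::sd(pre)
  if (!is.finite(noise)) noise <- 0
  significant <- abs(sp$drop) > sigma_mult * noise + 1e-12
  if (!significant) return(NULL)
  rbind(
    .find_steps(pre, offset, min_seg, sigma_mult),
    data.frame(frame = offset + sp$pos, drop = sp$drop),
    .find_steps(post, offset + sp$pos, min_seg, sigma_mult)
  )
}

#' Select single-molecule traces by their photobleaching signature
#'
#' Scans the total intensity (donor + acceptor) for discrete steps using
#' recursive binary change-point segmentation (maximal two-mean split
#' statistic). A trace is accepted if and only if it contains exactly one
#' significant step, that step is downward, and its amplitude exceeds
#' `sigma_mult` times the pre-step noise sd - the signature of a single
#' photobleaching event.
#'
#' @param trace a `fret_trace` with at least 20 frames.
#' @param min_seg minimum segment length (frames) on either side of a
#'   candidate step (default 5).
#' @param sigma_mult step amplitude threshold in units of pre-step noise sd
#'   (default 3).
#' @return list with `accepted` (logical), `bleach_frame` (last bright frame,
#'   or `NA` when rejected), and `steps` (data.frame of detected steps).
#' @export
select_single_molecule <- function(trace, min_seg = 5L, sigma_mult = 3) {
  stopifnot(inherits(trace, "fret_trace"))
  total <- trace$donor + trace$acceptor
  if (length(total) < 20L) stop("need at least 20 frames")
  steps <- .find_steps(total, 0L, min_seg, sigma_mult)
  if (is.null(steps)) {
    return(list(accepted = FALSE, bleach_frame = NA_integer_,
                steps = data.frame(frame = integer(0), drop = numeric(0))))
  }
  down <- steps[steps$drop > 0, , drop = FALSE]
  accepted <- nrow(steps) == 1L && nrow(down) == 1L
  list(accepted = accepted,
       bleach_frame = if (accepted) as.integer(down$frame) else NA_integer_,
       steps = steps)
}

#' Fit a Gaussian mixture to pooled FRET ratios
#'
#' EM Gaussian mixture over pre-bleach FRET ratios pooled across accepted
#' traces; component means are reported ascending. For comparison between the
#' two- and three-state descriptions, the fit also carries an AIC computed
#' from the residual sum of squares between the observed 40-bin histogram
#' (over \[-0.1, 1.1\]) and the binned mixture probabilities, scored by
#' [aic_score()] with `3 m - 1` free parameters.
#'
#' @param R numeric pooled FRET ratios (>= 200 values).
#' @param m number of FRET states, 2 or 3.
#' @param bins number of histogram bins for the RSS/AIC (default 40).
#' @param range histogram range (default `c(-0.1, 1.1)`).
#' @param max_iter EM iteration cap (default 5000; overlapping FRET states
#'   make EM converge slowly).
#' @return object of class `fret_state_fit`: list with `means`, `sds`,
#'   `weights`, `m`, `n_frames`, `rss`, `aic`.
#' @export
fit_fret_histogram <- function(R, m, bins = 40L, range = c(-0.1, 1.1),
                               max_iter = 5000L) {
  if (!m %in% 2:3) stop("m must be 2 or 3")
  R <- as.numeric(R)
  if (length(R) < 200L) stop("need at least 200 pooled frames")
  em <- fit_gaussian_mixture(R, m, max_iter = max_iter)
  if (any(em$means < range[1] | em$means > range[2])) {
    stop("fitted FRET-state mean outside the plausible range [",
         range[1], ", ", range[2], "]")
  }
  brk <- seq(range[1], range[2], length.out = bins + 1L)
  obs <- graphics::hist(pmin(pmax(R, range[1]), range[2]), breaks = brk,
                        plot = FALSE)$counts / length(R)
  pred <- vapply(seq_len(bins), function(b) {
    sum(em$weights * (stats::pnorm(brk[b + 1L], em$means, em$sds) -
                        stats::pnorm(brk[b], em$means, em$sds)))
  }, numeric(1))
  rss <- sum((obs - pred)^2)
  structure(
    list(means = em$means, sds = em$sds, weights = em$weights,
         m = m, n_frames = length(R), rss = rss,
         aic = aic_score(bins, max(rss, 1e-12), 3L * m - 1L)),
    class = "fret_state_fit"
  )
}

#' @export
print.fret_state_fit <- function(x, ...) {
  cat(sprintf("FRET-state mixture fit (m = %d, %d frames):\n", x$m,
              x$n_frames))
  for (i in seq_len(x$m)) {
    cat(sprintf("  R = %.3f  sd %.3f  weight %.3f\n",
                x$means[i], x$sds[i], x$weights[i]))
  }
  cat(sprintf("  histogram RSS = %.3g, AIC = %.4f\n", x$rss, x$aic))
  invisible(x)
}

#' Choose between two- and three-state FRET descriptions by AIC
#'
#' @inheritParams fit_fret_histogram
#' @return list with `fits` (m = 2 and m = 3 `fret_state_fit`s when both
#'   converge) and `selected_m`.
#' @export
select_fret_states <- function(R, bins = 40L, range = c(-0.1, 1.1)) {
  fits <- list()
  for (m in 2:3) {
    f <- tryCatch(fit_fret_histogram(R, m, bins, range),
                  error = function(e) NULL)
    if (!is.null(f)) fits[[as.character(m)]] <- f
  }
  if (!length(fits)) stop("no FRET mixture fit converged")
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  list(fits = fits, selected_m = as.integer(names(fits)[which.min(aics)]))
}
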