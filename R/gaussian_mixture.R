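#' One-dimensional Gaussian mixture fit by expectation-maximization
#'
#' Work-horse behind current-amplitude histogram fitting and FRET-state
#' assignment. Components are initialized at equally spaced sample quantiles
#' (or at `init_means` when given) and updated by standard EM. The
#' log-likelihood trajectory is recorded (it is nondecreasing, which the test
#' suite asserts). Two degenerate situations are handled explicitly:
#'
#' * if the data take at most `m` distinct values, the exact solution
#'   (component per value, weights = occupancy fractions, sd at a small floor)
#'   is returned without iteration;
#' * if, after convergence, any two component means are closer than one
#'   (pooled) sd, the fit is declared collapsed and an error is thrown.
#'
#' @param x numeric data.
#' @param m number of components.
#' @param init_means optional numeric vector of starting means.
#' @param max_iter maximum EM iterations (default 500).
#' @param tol relative log-likelihood convergence tolerance.
#' @return list with `means`, `sds`, `weights` (each length `m`, sorted by
#'   mean), `loglik`, `loglik_trace`, `iterations`, `converged`, `n`.
#' @export
fit_gaussian_mixture <- function(x, m, init_means = NULL, max_iter = 500L,
                                 tol = 1e-8) {
  x <- as.numeric(x[is.finite(x)])
  n <- length(x)
  if (n < m) stop("need at least m observations")
  ux <- unique(x)
  sd_floor <- max(diff(range(x)), abs(mean(x)), 1) * 1e-9

  if (length(ux) <= m) {
    if (length(ux) < m) {
      stop("mixture components collapse: data take only ", length(ux),
           " distinct value(s) but ", m, " components were requested")
    }
    ord <- order(ux)
    means <- ux[ord]
    weights <- as.numeric(table(factor(x, levels = means))) / n
    return(list(means = means, sds = rep(sd_floor, m), weights = weights,
                loglik = NA_real_, loglik_trace = numeric(0),
                iterations = 0L, converged = TRUE, n = n))
  }

  if (is.null(init_means)) {
    init_means <- stats::quantile(x, probs = (seq_len(m) - 0.5) / m,
                                  names = FALSE)
  }
  means <- as.numeric(init_means)
  sds <- rep(stats::sd(x) / m, m)
  sds <- pmax(sds, sd_floor)
  weights <- rep(1 / m, m)

  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # E step
    dens <- vapply(seq_len(m), function(j) {
      weights[j] * stats::dnorm(x, means[j], sds[j])
    }, numeric(n))
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d <= 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_d))
    ll_trace <- c(ll_trace, ll)
    resp <- dens / rowsum_d
    # M step
    nk <- colSums(resp)
    nk[nk <= 0] <- .Machine$double.xmin
    weights <- nk / n
    means <- colSums(resp * x) / nk
    sds <- sqrt(colSums(resp * (outer(x, means, "-")^2)) / nk)
    sds <- pmax(sds, sd_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged && iter >= max_iter) {
    stop("EM did not converge within ", max_iter, " iterations")
  }
  ord <- order(means)
  means <- means[ord]; sds <- sds[ord]; weights <- weights[ord]
  if (m > 1L) {
    sep <- diff(means)
    pooled <- (sds[-m] + sds[-1]) / 2
    if (any(sep < pooled)) {
      stop("mixture components collapse: adjacent means separated by less ",
           "than one sd")
    }
  }
  list(means = means, sds = sds, weights = weights,
       loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
       iterations = iter, converged = converged, n = n)
}
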