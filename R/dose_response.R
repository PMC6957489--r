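#' Construct a dose-response curve
#'
#' @param concentrations_uM free Ca2+ concentrations, uM; strictly positive
#'   and strictly increasing.
#' @param responses mean response per concentration (pS, s, or %% depending on
#'   the observable).
#' @param sems optional per-point SEMs (same units as responses).
#' @param n_per_point optional per-point trial counts.
#' @param observable free-text tag (`"open_time"`, `"occurrence"`,
#'   `"conductance"`, ...).
#' @return object of class `dose_response_curve`.
#' @export
dose_response_curve <- function(concentrations_uM, responses, sems = NULL,
                                n_per_point = NULL, observable = "response") {
  concentrations_uM <- as.numeric(concentrations_uM)
  responses <- as.numeric(responses)
  if (any(concentrations_uM <= 0)) stop("concentrations must be > 0")
  if (is.unsorted(concentrations_uM, strictly = TRUE)) {
    stop("concentrations must be strictly increasing")
  }
  if (length(responses) != length(concentrations_uM)) {
    stop("responses and concentrations must have equal length")
  }
  if (!is.null(sems) && length(sems) != length(responses)) {
    stop("sems must match responses in length")
  }
  if (!is.null(n_per_point) && length(n_per_point) != length(responses)) {
    stop("n_per_point must match responses in length")
  }
  structure(
    list(concentrations_uM = concentrations_uM, responses = responses,
         sems = sems, n_per_point = n_per_point, observable = observable),
    class = "dose_response_curve"
  )
}

#' Hill dose-response function
#'
#' `floor + (ceiling - floor) * c^h / (ec50^h + c^h)`.
#'
#' @param conc_uM concentration(s), uM.
#' @param ec50_uM half-maximal concentration, uM.
#' @param hill Hill coefficient.
#' @param floor,ceiling response plateau values.
#' @return numeric response(s).
#' @export
hill_response <- function(conc_uM, ec50_uM, hill, floor = 0, ceiling = 1) {
  floor + (ceiling - floor) * hill_term(conc_uM, ec50_uM, hill)
}

#' Generate a noisy synthetic dose-response curve
#'
#' Hill-function responses with additive Gaussian noise of sd
#' `noise_frac * (ceiling - floor)`; the generator behind the Hill-recovery
#' tests.
#'
#' @inheritParams hill_response
#' @param noise_frac noise sd as a fraction of the dynamic range
#'   (default 0.1).
#' @param seed integer seed.
#' @param observable tag stored on the curve.
#' @return a `dose_response_curve`.
#' @export
simulate_hill_curve <- function(conc_uM, ec50_uM, hill, floor = 0,
                                ceiling = 1, noise_frac = 0.1, seed,
                                observable = "response") {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  mu <- hill_response(conc_uM, ec50_uM, hill, floor, ceiling)
  y <- withr::with_seed(seed, {
    mu + stats::rnorm(length(conc_uM), sd = noise_frac * (ceiling - floor))
  })
  dose_response_curve(conc_uM, y, observable = observable)
}

#' Fit a four-parameter Hill equation to a dose-response curve
#'
#' Weighted (1/SEM^2 when SEMs are available) nonlinear least squares of
#' `response = floor + (ceiling - floor) * c^h / (EC50^h + c^h)` using the
#' Levenberg-Marquardt algorithm, with a small multi-start over the Hill
#' coefficient. Standard errors come from the fit covariance matrix. A fit
#' whose EC50 lies outside the tested concentration range is returned with
#' `ec50_in_range = FALSE` rather than rejected.
#'
#' @param curve a [dose_response_curve()] with at least 4 concentrations
#'   spanning at least a 4-fold range and non-constant responses.
#' @param pin_floor fix the floor at 0 instead of fitting it.
#' @return object of class `hill_fit`: list with `ec50_uM`, `hill`, `floor`,
#'   `ceiling`, `se` (named vector), `converged`, `ec50_in_range`,
#'   `observable`.
#' @export
fit_hill <- function(curve, pin_floor = FALSE) {
  stopifnot(inherits(curve, "dose_response_curve"))
  conc <- curve$concentrations_uM
  y <- curve$responses
  if (length(conc) < 4) stop("need at least 4 concentrations")
  if (max(conc) / min(conc) < 4) {
    stop("concentrations must span at least a 4-fold range")
  }
  if (diff(range(y)) == 0) stop("responses are constant; nothing to fit")

  w <- NULL
  if (!is.null(curve$sems) && all(is.finite(curve$sems)) &&
      all(curve$sems > 0)) {
    w <- 1 / curve$sems^2
  }
  df <- data.frame(conc = conc, y = y)

  mid <- (min(y) + max(y)) / 2
  ec50_0 <- conc[which.min(abs(y - mid))]
  fits <- list()
  for (h0 in c(1, 2, 4, 8)) {
    start <- if (pin_floor) {
      list(ceiling = max(y), ec50 = ec50_0, h = h0)
    } else {
      list(floor = min(y), ceiling = max(y), ec50 = ec50_0, h = h0)
    }
    form <- if (pin_floor) {
      y ~ ceiling * conc^h / (ec50^h + conc^h)
    } else {
      y ~ floor + (ceiling - floor) * conc^h / (ec50^h + conc^h)
    }
    args <- list(form, data = df, start = start,
                 lower = if (pin_floor) c(-Inf, 1e-9, 1e-3)
                 else c(-Inf, -Inf, 1e-9, 1e-3),
                 control = minpack.lm::nls.lm.control(maxiter = 200))
    if (!is.null(w)) args$weights <- w
    f <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  if (!length(fits)) stop("Hill fit failed to converge")
  dev <- vapply(fits, stats::deviance, numeric(1))
  fit <- fits[[which.min(dev)]]
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) {
    stats::setNames(rep(NA_real_, length(cf)), names(cf))
  })
  ec50 <- unname(cf[["ec50"]])
  in_range <- ec50 >= min(conc) && ec50 <= max(conc)
  if (!in_range) {
    warning("fitted EC50 (", signif(ec50, 3),
            " uM) lies outside the tested concentration range")
  }
  structure(
    list(ec50_uM = ec50,
         hill = unname(cf[["h"]]),
         floor = if (pin_floor) 0 else unname(cf[["floor"]]),
         ceiling = unname(cf[["ceiling"]]),
         se = se,
         converged = TRUE,
         ec50_in_range = in_range,
         observable = curve$observable),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit (%s): EC50 = %.4g uM, h = %.3g\n", x$observable,
              x$ec50_uM, x$hill))
  cat(sprintf("  floor = %.4g, ceiling = %.4g%s\n", x$floor, x$ceiling,
              if (!x$ec50_in_range) "  [EC50 outside tested range]" else ""))
  invisible(x)
}

#' Construct an occurrence table
#'
#' One row per condition: number of independent trials and the number in
#' which a pore was detected.
#'
#' @param condition character labels.
#' @param n trial counts (>= 1).
#' @param detected detected counts (0 <= detected <= n).
#' @return data.frame of class `occurrence_table` with a `percentage` column.
#' @export
occurrence_table <- function(condition, n, detected) {
  n <- as.integer(n); detected <- as.integer(detected)
  if (any(n < 1)) stop("n must be >= 1")
  if (any(detected < 0 | detected > n)) {
    stop("detected must lie in [0, n]")
  }
  out <- data.frame(condition = as.character(condition), n = n,
                    detected = detected,
                    percentage = occurrence_percentage(detected, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("occurrence_table", "data.frame")
  out
}

#' Percentage of occurrence
#'
#' @param detected number of trials with a detected pore.
#' @param n total number of trials (>= 1).
#' @return `100 * detected / n`.
#' @export
occurrence_percentage <- function(detected, n) {
  if (any(n < 1)) stop("n must be >= 1")
  100 * detected / n
}

#' Pearson chi-squared test of two occurrence rows
#'
#' Pearson chi-squared on the 2x2 detected / not-detected contingency table,
#' one degree of freedom, without continuity correction.
#'
#' @param a,b each a list or one-row data.frame with elements `n` and
#'   `detected`.
#' @return list with `statistic`, `p_value`, `table`.
#' @export
chi2_occurrence <- function(a, b) {
  get2 <- function(r) c(n = as.numeric(r[["n"]]),
                        detected = as.numeric(r[["detected"]]))
  ra <- get2(a); rb <- get2(b)
  if (ra[["n"]] < 1 || rb[["n"]] < 1) stop("both rows need n >= 1")
  tab <- matrix(c(ra[["detected"]], ra[["n"]] - ra[["detected"]],
                  rb[["detected"]], rb[["n"]] - rb[["detected"]]),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("detected", "not_detected")))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    stop("degenerate table: an expected cell count is zero")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic),
       p_value = unname(ht$p.value),
       table = tab)
}

#' Pairwise chi-squared comparisons across an occurrence table
#'
#' @param tab an [occurrence_table()].
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return data.frame with one row per condition pair: `chi2`, `p_value`,
#'   `p_adjusted`.
#' @export
chi2_pairwise <- function(tab, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(tab, "occurrence_table"))
  idx <- utils::combn(nrow(tab), 2)
  rows <- apply(idx, 2, function(ij) {
    res <- chi2_occurrence(tab[ij[1], ], tab[ij[2], ])
    data.frame(condition_a = tab$condition[ij[1]],
               condition_b = tab$condition[ij[2]],
               chi2 = res$statistic, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  out
}
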