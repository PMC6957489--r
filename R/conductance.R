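#' Fit Gaussian components to a current-amplitude histogram
#'
#' Expectation-maximization Gaussian mixture on the raw current samples,
#' initialized from sample quantiles. Components are reported sorted by
#' current magnitude (the component nearest 0 pA, i.e. the closed/baseline
#' level, first).
#'
#' @param trace a `current_trace` with at least 1e4 samples.
#' @param n_components 2 or 3.
#' @return object of class `amplitude_histogram_fit`: list with `means_pA`,
#'   `sds_pA`, `weights`, `n_components`, `loglik_trace`, `n_samples`.
#' @export
fit_amplitude_histogram <- function(trace, n_components) {
  if (!n_components %in% 2:3) stop("n_components must be 2 or 3")
  x <- trace$samples
  if (length(x) < 1e4) {
    stop("need at least 1e4 samples for an amplitude histogram fit")
  }
  em <- fit_gaussian_mixture(x, n_components)
  ord <- order(abs(em$means))
  structure(
    list(means_pA = em$means[ord],
         sds_pA = em$sds[ord],
         weights = em$weights[ord],
         n_components = n_components,
         loglik_trace = em$loglik_trace,
         n_samples = em$n),
    class = "amplitude_histogram_fit"
  )
}

#' @export
print.amplitude_histogram_fit <- function(x, ...) {
  cat("Current-amplitude Gaussian mixture fit:\n")
  for (i in seq_len(x$n_components)) {
    cat(sprintf("  mean %8.3f pA  sd %7.3f pA  weight %.3f\n",
                x$means_pA[i], x$sds_pA[i], x$weights[i]))
  }
  invisible(x)
}

#' Convert amplitude-histogram component means to conductances
#'
#' Per-state conductance `gamma = |mean_state - mean_closed| / |V| * 1000`
#' (pA and mV give pS). The component nearest 0 pA is taken as the closed
#' reference, so `gamma(closed) = 0` by construction; conductances are
#' reported as positive magnitudes regardless of the sign convention of the
#' holding potential.
#'
#' @param fit an `amplitude_histogram_fit`.
#' @param holding_potential_mV holding potential in mV (nonzero).
#' @return object of class `conductance_estimate`: list with
#'   `conductances_pS` (named by state), `holding_potential_mV`,
#'   `closed_mean_pA`.
#' @export
conductance_from_fit <- function(fit, holding_potential_mV) {
  if (holding_potential_mV == 0) stop("holding potential must be nonzero")
  means <- fit$means_pA            # already sorted by |mean|, closed first
  closed <- means[1]
  gamma <- abs(means - closed) / abs(holding_potential_mV) * 1000
  # means are sorted by |mean|, so names run closed, (partial,) open
  names(gamma) <- if (length(means) == 2L) c("closed", "open")
  else c("closed", "partial", "open")
  structure(
    list(conductances_pS = gamma,
         holding_potential_mV = holding_potential_mV,
         closed_mean_pA = closed),
    class = "conductance_estimate"
  )
}

#' @export
print.conductance_estimate <- function(x, ...) {
  cat(sprintf("Conductance estimate at %g mV (closed mean %.3f pA):\n",
              x$holding_potential_mV, x$closed_mean_pA))
  for (s in names(x$conductances_pS)) {
    cat(sprintf("  %-8s %9.2f pS\n", s, x$conductances_pS[[s]]))
  }
  invisible(x)
}

#' Approximate pore diameter from conductance
#'
#' Solves the cylindrical-pore-plus-access-resistance relation
#' `1/gamma = 4 L rho / (pi d^2) + rho / d` (Hall access resistance on both
#' mouths) for the diameter `d`. The relation is a quadratic in `1/d` with a
#' single positive root for positive inputs. As with all conductance-based
#' pore sizing, the result is an approximation that depends on the assumed
#' pore length and solution resistivity.
#'
#' @param gamma_pS pore conductance, pS (> 0).
#' @param L_nm assumed pore length, nm (default 15, about two bilayer
#'   thicknesses for a nanodisc-membrane junction).
#' @param rho_ohm_cm solution resistivity, Ohm cm (> 0).
#' @return object of class `pore_diameter_estimate`: list with
#'   `diameter_nm`, `L_nm`, `rho_ohm_cm`, `model`.
#' @export
estimate_pore_diameter <- function(gamma_pS, L_nm = 15, rho_ohm_cm) {
  if (gamma_pS <= 0) stop("gamma_pS must be > 0")
  if (L_nm <= 0) stop("L_nm must be > 0")
  if (rho_ohm_cm <= 0) stop("rho_ohm_cm must be > 0")
  R <- 1 / (gamma_pS * 1e-12)        # Ohm
  rho <- rho_ohm_cm * 1e-2           # Ohm m
  L <- L_nm * 1e-9                   # m
  # (4 L rho / pi) u^2 + rho u - R = 0, u = 1/d
  a <- 4 * L * rho / pi
  b <- rho
  disc <- b^2 + 4 * a * R
  stopifnot(disc > 0)                # always true for positive inputs
  u <- (-b + sqrt(disc)) / (2 * a)
  stopifnot(u > 0)
  structure(
    list(diameter_nm = 1e9 / u,
         L_nm = L_nm,
         rho_ohm_cm = rho_ohm_cm,
         model = "cylinder + Hall access resistance, single effective resistivity"),
    class = "pore_diameter_estimate"
  )
}

#' @export
print.pore_diameter_estimate <- function(x, ...) {
  cat(sprintf("Approximate pore diameter: %.3f nm (L = %g nm, rho = %g Ohm cm)\n",
              x$diameter_nm, x$L_nm, x$rho_ohm_cm))
  cat("  model:", x$model, "\n")
  invisible(x)
}
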