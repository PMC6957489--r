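#' Continuous-time Markov model of fusion-pore gating
#'
#' A gating model is a small continuous-time Markov chain over pore
#' conductance states (`closed`, optionally `partial`, `open`). Each state
#' carries a conductance in pS (the closed state is 0 by definition) and the
#' off-diagonal entries of `rates_per_s` give transition rates in 1/s.
#' Optionally, individual rates can be modulated by free Ca2+ through a Hill
#' term, which is how Ca2+-sensor action (e.g. synaptotagmin-1 triggering of
#' pore opening) enters the simulator.
#'
#' @param states character vector of state labels, each one of
#'   `"closed"`, `"partial"`, `"open"` (labels may repeat only if suffixed,
#'   e.g. `"open"` and `"open2"` are not supported; use the three canonical
#'   labels).
#' @param conductances_pS numeric vector, one conductance per state in pS.
#'   The closed state must be exactly 0; a partial state, when present, must
#'   lie strictly between the closed and open conductances.
#' @param rates_per_s square numeric matrix of transition rates (1/s);
#'   off-diagonal entries must be >= 0, the diagonal is ignored and defined
#'   internally as the negative row sum (generator convention).
#' @param ca_modulation optional list of modulation rules. Each rule is a list
#'   with elements `from`, `to` (state labels), `base_rate_per_s`,
#'   `ec50_uM`, `hill`, and `direction` (`"up"` or `"down"`). The effective
#'   rate is `base * H(c)` for direction `"up"` or `base * (1 - H(c))` for
#'   `"down"`, with `H(c) = c^h / (ec50^h + c^h)`.
#'
#' @return an object of class `gating_model`.
#' @export
gating_model <- function(states, conductances_pS, rates_per_s,
                         ca_modulation = NULL) {
  states <- as.character(states)
  m <- length(states)
  if (m < 1L) stop("a gating model needs at least one state")
  if (anyDuplicated(states)) stop("state labels must be unique")
  bad <- setdiff(states, c("closed", "partial", "open"))
  if (length(bad)) {
    stop("unknown state label(s): ", paste(bad, collapse = ", "),
         " (allowed: closed, partial, open)")
  }
  conductances_pS <- as.numeric(conductances_pS)
  if (length(conductances_pS) != m) {
    stop("need one conductance per state")
  }
  if (any(conductances_pS < 0)) stop("conductances must be >= 0")
  if ("closed" %in% states && conductances_pS[states == "closed"] != 0) {
    stop("the closed state must have conductance exactly 0 pS")
  }
  if ("partial" %in% states) {
    if (!all(c("closed", "open") %in% states)) {
      stop("a partial state requires both closed and open states")
    }
    gp <- conductances_pS[states == "partial"]
    go <- conductances_pS[states == "open"]
    if (!(gp > 0 && gp < go)) {
      stop("partial-state conductance must lie strictly between closed and open")
    }
  }
  rates_per_s <- as.matrix(rates_per_s)
  if (!all(dim(rates_per_s) == c(m, m))) {
    stop("rates_per_s must be a ", m, "x", m, " matrix")
  }
  off <- rates_per_s[row(rates_per_s) != col(rates_per_s)]
  if (any(!is.finite(off)) || any(off < 0)) {
    stop("off-diagonal rates must be finite and >= 0")
  }
  diag(rates_per_s) <- 0
  dimnames(rates_per_s) <- list(states, states)
  names(conductances_pS) <- states

  if (!is.null(ca_modulation)) {
    if (!is.list(ca_modulation)) stop("ca_modulation must be a list of rules")
    if (!is.null(ca_modulation$from)) ca_modulation <- list(ca_modulation)
    for (rule in ca_modulation) {
      req <- c("from", "to", "base_rate_per_s", "ec50_uM", "hill", "direction")
      miss <- setdiff(req, names(rule))
      if (length(miss)) {
        stop("ca_modulation rule missing field(s): ", paste(miss, collapse = ", "))
      }
      if (!rule$from %in% states || !rule$to %in% states) {
        stop("ca_modulation rule names unknown state '", rule$from, "'/'",
             rule$to, "'")
      }
      if (rule$base_rate_per_s < 0 || rule$ec50_uM <= 0 || rule$hill <= 0) {
        stop("ca_modulation rule needs base_rate_per_s >= 0, ec50_uM > 0, hill > 0")
      }
      if (!rule$direction %in% c("up", "down")) {
        stop("ca_modulation direction must be 'up' or 'down'")
      }
    }
  }

  structure(
    list(states = states,
         conductances_pS = conductances_pS,
         rates_per_s = rates_per_s,
         ca_modulation = ca_modulation),
    class = "gating_model"
  )
}

#' @export
print.gating_model <- function(x, ...) {
  cat("Gating model:", length(x$states), "state(s)\n")
  for (i in seq_along(x$states)) {
    cat(sprintf("  %-8s %8.1f pS\n", x$states[i], x$conductances_pS[i]))
  }
  cat("Rates (1/s):\n")
  print(round(x$rates_per_s, 4))
  if (!is.null(x$ca_modulation)) {
    for (r in x$ca_modulation) {
      cat(sprintf("  Ca2+ modulation: %s->%s base %.3g/s, EC50 %.3g uM, h %.2f (%s)\n",
                  r$from, r$to, r$base_rate_per_s, r$ec50_uM, r$hill, r$direction))
    }
  }
  invisible(x)
}

#' Hill occupancy term
#'
#' `c^h / (ec50^h + c^h)`, the fraction of Ca2+-bound sensor at free
#' concentration `c`.
#'
#' @param conc_uM free Ca2+ concentration(s) in uM (>= 0).
#' @param ec50_uM half-maximal concentration in uM.
#' @param hill Hill coefficient (> 0).
#' @return numeric in \[0, 1\].
#' @export
hill_term <- function(conc_uM, ec50_uM, hill) {
  if (any(conc_uM < 0)) stop("concentrations must be >= 0")
  ch <- conc_uM^hill
  ch / (ec50_uM^hill + ch)
}

#' Effective rate matrix at a given free Ca2+ concentration
#'
#' Applies the model's Hill modulation rules to the base rate matrix.
#'
#' @param model a [gating_model()].
#' @param ca_free_uM free Ca2+ in uM; may be `NA` only when the model has no
#'   modulation rules.
#' @return rate matrix (1/s) with modulated entries substituted.
#' @export
effective_rates <- function(model, ca_free_uM = NA_real_) {
  Q <- model$rates_per_s
  if (is.null(model$ca_modulation)) return(Q)
  if (is.na(ca_free_uM)) {
    stop("model has Ca2+ modulation rules; ca_free_uM must be supplied")
  }
  for (rule in model$ca_modulation) {
    H <- hill_term(ca_free_uM, rule$ec50_uM, rule$hill)
    scale <- if (rule$direction == "up") H else 1 - H
    Q[rule$from, rule$to] <- rule$base_rate_per_s * scale
  }
  Q
}

#' Convenience two-state (closed/open) gating model
#'
#' @param open_conductance_pS open-state conductance in pS.
#' @param opening_rate_per_s closed -> open rate (1/s).
#' @param closing_rate_per_s open -> closed rate (1/s).
#' @param ca_modulation optional modulation rules, see [gating_model()].
#' @return a `gating_model`.
#' @export
two_state_model <- function(open_conductance_pS, opening_rate_per_s,
                            closing_rate_per_s, ca_modulation = NULL) {
  gating_model(
    states = c("closed", "open"),
    conductances_pS = c(0, open_conductance_pS),
    rates_per_s = matrix(c(0, opening_rate_per_s,
                           closing_rate_per_s, 0),
                         nrow = 2, byrow = TRUE),
    ca_modulation = ca_modulation
  )
}

#' Convenience three-state (closed/partial/open) gating model
#'
#' Linear scheme closed <-> partial <-> open; direct closed <-> open
#' transitions can be added afterwards by editing `rates_per_s`.
#'
#' @param partial_conductance_pS,open_conductance_pS state conductances, pS.
#' @param rates named numeric vector with elements `cp`, `pc`, `po`, `op`
#'   (closed->partial, partial->closed, partial->open, open->partial), 1/s.
#' @return a `gating_model`.
#' @export
three_state_model <- function(partial_conductance_pS, open_conductance_pS,
                              rates) {
  req <- c("cp", "pc", "po", "op")
  if (!all(req %in% names(rates))) {
    stop("rates must name cp, pc, po, op")
  }
  Q <- matrix(0, 3, 3)
  Q[1, 2] <- rates[["cp"]]
  Q[2, 1] <- rates[["pc"]]
  Q[2, 3] <- rates[["po"]]
  Q[3, 2] <- rates[["op"]]
  gating_model(
    states = c("closed", "partial", "open"),
    conductances_pS = c(0, partial_conductance_pS, open_conductance_pS),
    rates_per_s = Q
  )
}

# deterministic sub-seed derivation; keeps values in [0, 2^31)
derive_seed <- function(seed, index) {
  v <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(index) * 9973
  as.integer(v %% 2147483647)
}
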