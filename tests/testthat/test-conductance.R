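test_that("a noiseless two-level trace yields exact means and occupancy weights", {
  tr <- current_trace(c(rep(0, 15000), rep(-25, 5000)), 1e4, -60)
  fit <- fit_amplitude_histogram(tr, 2)
  expect_equal(fit$means_pA, c(0, -25))
  expect_equal(fit$weights, c(0.75, 0.25))
})

test_that("histogram fitting recovers programmed levels from noisy data", {
  m <- two_state_model(500, 10, 10)   # open level -30 pA at -60 mV
  tr <- simulate_gating(m, 5, seed = 19, noise_sd_pA = 2)
  fit <- fit_amplitude_histogram(tr, 2)
  expect_lt(abs(fit$means_pA[1] - 0), 0.5)
  expect_lt(abs(fit$means_pA[2] - (-30)), 0.5)
  expect_error(fit_amplitude_histogram(current_trace(rep(0, 100), 1e4, -60), 2),
               "1e4")
})

test_that("a flat noisy trace collapses the two-component fit", {
  x <- withr::with_seed(3, rnorm(2e4, 0, 2))
  expect_error(fit_amplitude_histogram(current_trace(x, 1e4, -60), 2),
               "collapse")
})

test_that("EM log-likelihood is nondecreasing and agrees with an independent fitter", {
  x <- withr::with_seed(8, c(rnorm(5000, 0, 2), rnorm(5000, -30, 2)))
  em <- fit_gaussian_mixture(x, 2)
  expect_true(all(diff(em$loglik_trace) >= -1e-8))
  suppressPackageStartupMessages(library(mclust))
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(em$means), sort(unname(mc$parameters$mean)),
               tolerance = 1e-3)
})

test_that("conductance conversion follows gamma = |dI| / |V| * 1000", {
  f <- make_amplitude_fit(c(0, -54.12))
  co <- conductance_from_fit(f, -60)
  expect_equal(unname(co$conductances_pS), c(0, 902))
  f2 <- make_amplitude_fit(c(0, -10.2))
  expect_equal(unname(conductance_from_fit(f2, -60)$conductances_pS[2]), 170)
  f3 <- make_amplitude_fit(c(-1, -1 + 1e-12))
  expect_equal(unname(conductance_from_fit(f3, -60)$conductances_pS[2]), 0,
               tolerance = 1e-9)
  expect_error(conductance_from_fit(f, 0), "nonzero")
  # invariant under sign flip of both currents and potential
  up <- conductance_from_fit(make_amplitude_fit(c(0, 54.12)), 60)
  expect_equal(co$conductances_pS, up$conductances_pS)
})

test_that("pore diameter solves the cylinder-plus-access-resistance relation", {
  # independent oracle: numeric root of 1/gamma = 4 L rho / (pi d^2) + rho / d
  oracle_d <- function(gamma_pS, L_nm, rho_ohm_cm) {
    R <- 1 / (gamma_pS * 1e-12); rho <- rho_ohm_cm * 1e-2; L <- L_nm * 1e-9
    f <- function(d) 4 * L * rho / (pi * d^2) + rho / d - R
    uniroot(f, c(1e-12, 1e-3), tol = 1e-18)$root * 1e9
  }
  est <- estimate_pore_diameter(400, 15, 100)
  expect_equal(signif(est$diameter_nm, 4), signif(oracle_d(400, 15, 100), 4))
  # strictly increasing and continuous in gamma
  gam <- seq(5, 2000, length.out = 200)
  d <- vapply(gam, function(g) estimate_pore_diameter(g, 15, 100)$diameter_nm,
              numeric(1))
  expect_true(all(diff(d) > 0))
  # d -> 0 as gamma -> 0 (d ~ sqrt(gamma) in the access-free limit)
  expect_lt(estimate_pore_diameter(1e-4, 15, 100)$diameter_nm, 0.01)
  # doubling the diameter more than doubles the conductance
  gamma_of_d <- function(d_nm, L_nm = 15, rho_ohm_cm = 100) {
    rho <- rho_ohm_cm * 1e-2; L <- L_nm * 1e-9; d <- d_nm * 1e-9
    1e12 / (4 * L * rho / (pi * d^2) + rho / d)
  }
  expect_gt(gamma_of_d(4), 2 * gamma_of_d(2))
  expect_error(estimate_pore_diameter(-1, 15, 100), "gamma")
})
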