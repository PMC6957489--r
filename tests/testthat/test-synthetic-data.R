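test_that("gating model invariants are enforced", {
  expect_error(gating_model("closed", 5, matrix(0, 1, 1)),
               "conductance exactly 0")
  expect_error(gating_model(c("closed", "open"), c(0, 100),
                            matrix(c(0, -1, 1, 0), 2, 2)), ">= 0")
  expect_error(gating_model(c("closed", "partial", "open"), c(0, 950, 900),
                            matrix(0, 3, 3)), "strictly between")
  expect_error(gating_model(c("closed", "weird"), c(0, 1), matrix(0, 2, 2)),
               "unknown state")
  m <- two_state_model(900, 5, 2,
                       ca_modulation = list(from = "closed", to = "open",
                                            base_rate_per_s = 5,
                                            ec50_uM = 200, hill = 4,
                                            direction = "up"))
  expect_s3_class(m, "gating_model")
  # Hill modulation: at EC50 the up-modulated rate is half the base rate
  Q <- effective_rates(m, 200)
  expect_equal(Q["closed", "open"], 2.5)
  expect_error(effective_rates(m, NA_real_), "ca_free_uM")
})

test_that("a rate-free open pore renders a constant current of -gamma |V| / 1000", {
  m <- gating_model("open", 902, matrix(0, 1, 1))
  tr <- quiet_simulate_gating(m, 0.5, seed = 11, noise_sd_pA = 0,
                              bessel = FALSE, init_state = "open")
  expect_equal(unique(tr$samples), -54.12)
  # with the Bessel filter on, the steady state settles to the same level
  trf <- quiet_simulate_gating(m, 0.5, seed = 11, noise_sd_pA = 0,
                               bessel = TRUE, init_state = "open")
  expect_equal(trf$samples[100:length(trf$samples)],
               rep(-54.12, length(trf$samples) - 99), tolerance = 1e-6)
})

test_that("simulated dwell times match continuous-time Markov theory", {
  m <- two_state_model(900, opening_rate_per_s = 10, closing_rate_per_s = 10)
  p <- simulate_path(m, 100, seed = 21)
  interior <- p[-c(1, nrow(p)), ]
  od <- with(interior[interior$state == "open", ], t_end_s - t_start_s)
  se <- sd(od) / sqrt(length(od))
  expect_gt(length(od), 100)
  expect_lt(abs(mean(od) - 0.1), 3 * se)

  # exponentially distributed dwells at the programmed exit rate
  m2 <- two_state_model(900, 5, 2)
  p2 <- simulate_path(m2, 1500, seed = 22)
  open_d <- with(p2[-c(1, nrow(p2)), ], (t_end_s - t_start_s)[state == "open"])
  expect_gt(length(open_d), 2000)
  ks <- suppressWarnings(ks.test(open_d, "pexp", 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("noise-free unfiltered traces carry only programmed levels and match the state path", {
  m <- two_state_model(500, 20, 20)
  tr <- simulate_gating(m, 3, seed = 5, noise_sd_pA = 0, bessel = FALSE)
  expect_true(all(tr$samples %in% c(0, -30)))
  expect_identical(tr$samples, tr$ideal_pA)
  expect_identical(tr$ideal_pA,
                   unname(m$conductances_pS[tr$state_path] *
                            tr$holding_potential_mV / 1000))
})

test_that("simulation is reproducible for a fixed seed and errors on bad input", {
  m <- two_state_model(500, 20, 20)
  a <- simulate_gating(m, 1, seed = 33, noise_sd_pA = 2)
  b <- simulate_gating(m, 1, seed = 33, noise_sd_pA = 2)
  expect_identical(a$samples, b$samples)
  c <- simulate_gating(m, 1, seed = 34, noise_sd_pA = 2)
  expect_false(identical(a$samples, c$samples))
  expect_error(simulate_gating(m, 0, seed = 1), "duration")
  expect_error(simulate_gating(m, 1, seed = 1, init_state = "flicker"),
               "unknown state")
  expect_error(simulate_path(m, 1), "seed")
})

test_that("dose-response simulation is flat without modulation and monotone with it", {
  m <- two_state_model(400, 2, 2)
  flat <- simulate_dose_response(m, c(10, 50, 250, 1250), replicates = 10,
                                 seed = 3, duration_s = 20)
  fit <- lm(open_dwell_mean_s ~ log(ca_uM), data = as.data.frame(flat))
  expect_gt(summary(fit)$coefficients[2, 4], 0.05)

  mod <- two_state_model(400, 5, 2,
                         ca_modulation = list(from = "closed", to = "open",
                                              base_rate_per_s = 5,
                                              ec50_uM = 200, hill = 4,
                                              direction = "up"))
  dr <- simulate_dose_response(mod, c(25, 50, 100, 200, 400, 800),
                               replicates = 20, seed = 17, duration_s = 60)
  expect_true(all(diff(dr$occurrence_fraction) >= 0))
  expect_error(simulate_dose_response(m, c(100, 100, 100), 10, seed = 1),
               "unfittable")
  expect_error(simulate_dose_response(m, c(10, 100), 1, seed = 1),
               "replicates")
})

test_that("smFRET rendering inverts the ratio formula exactly", {
  tr <- simulate_smfret(0.7, 1, total_intensity = 800, noise_sd = 0,
                        n_frames = 50, seed = 9)
  expect_equal(fret_ratio(tr), rep(0.7, 50), ignore_attr = TRUE)
  tr0 <- simulate_smfret(0, 1, total_intensity = 800, noise_sd = 0,
                         n_frames = 50, seed = 9)
  expect_equal(tr0$acceptor, 0.05 * tr0$donor)
  expect_error(simulate_smfret(1.2, 1, seed = 1), "\\[0, 1\\]")
  expect_error(simulate_smfret(0.5, 1, total_intensity = 0, seed = 1),
               "total_intensity")
  # bleach: both channels at background afterwards
  trb <- simulate_smfret(0.5, 1, total_intensity = 800, noise_sd = 0,
                         n_frames = 60, bleach_frame = 40, seed = 9)
  expect_true(all(trb$donor[41:60] == 0 & trb$acceptor[41:60] == 0))
  expect_length(fret_ratio(trb), 40)
})
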