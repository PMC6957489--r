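test_that("a noiseless square wave idealizes exactly", {
  # 50 ms per level at 10 kHz = 500 samples
  tr <- square_wave_trace(c(0, -25), 500, 10)
  id <- idealize(tr, c(0, -25))
  seg <- id$segments
  expect_equal(nrow(seg), 20)
  expect_equal(seg$start, seq(0, 19) * 500)
  expect_equal(seg$end, seq(1, 20) * 500)
  expect_equal(seg$state, rep(c("closed", "open"), 10))
  expect_equal(seg$mean_pA, rep(c(0, -25), 10))
})

test_that("sub-dead-time blips are absorbed into the flanking segment", {
  x <- rep(-25, 5000)
  x[2500] <- 0                      # single-sample blip, below 0.2 ms
  tr <- current_trace(x, 1e4, -60)
  id <- idealize(tr, c(0, -25))
  expect_equal(nrow(id$segments), 1)
  expect_equal(id$segments$state, "open")
})

test_that("idealization recovers the hidden state path of a noisy 3-state trace", {
  m <- three_state_model(300, 902, c(cp = 8, pc = 8, po = 8, op = 8))
  tr <- simulate_gating(m, 10, seed = 101, noise_sd_pA = 2)
  id <- idealize(tr, m$conductances_pS * tr$holding_potential_mV / 1000)
  segidx <- rep(seq_len(nrow(id$segments)),
                id$segments$end - id$segments$start)
  acc <- mean(id$segments$state[segidx] == tr$state_path)
  expect_gte(acc, 0.95)
})

test_that("idealizing a noiseless rendered trace is exact", {
  m <- two_state_model(500, 2, 2)
  tr <- simulate_gating(m, 5, seed = 42, noise_sd_pA = 0, bessel = FALSE)
  # the truth here contains no sub-dead-time sojourn, so exactness must hold
  truth <- rle(tr$state_path)
  stopifnot(all(truth$lengths >= 2))
  id <- idealize(tr, c(0, -30))
  expect_equal(id$segments$state, truth$values)
  true_ends <- cumsum(truth$lengths)
  expect_true(all(abs(id$segments$end - true_ends) <= 1))
})

test_that("dwell extraction censors the first and last segments", {
  tr <- current_trace(c(rep(0, 10000), rep(-25, 20000), rep(0, 10000)),
                      1e4, -60)
  dt <- extract_dwells(idealize(tr, c(0, -25)))
  expect_equal(dt$dwells$open, 2)
  expect_length(dt$dwells$closed, 0)
  expect_equal(sort(unlist(dt$censored)), c(1, 1), ignore_attr = TRUE)

  tr2 <- square_wave_trace(c(0, -25), 5000, 5)   # 10 segments of 0.5 s
  dt2 <- extract_dwells(idealize(tr2, c(0, -25)))
  expect_equal(length(dt2$dwells$open) + length(dt2$dwells$closed), 8)
  expect_true(all(unlist(dt2$dwells) == 0.5))
  # total dwell + censored time equals trace duration
  expect_equal(sum(unlist(dt2$dwells)) + sum(unlist(dt2$censored)),
               trace_duration(tr2))
})

test_that("interior open dwells match the programmed closing rate", {
  m <- two_state_model(500, 5, 5)
  tr <- simulate_gating(m, 200, seed = 7, noise_sd_pA = 0, bessel = FALSE,
                        oversample = 1L)
  dw <- extract_dwells(idealize(tr, c(0, -30)))
  od <- dw$dwells$open
  se <- sd(od) / sqrt(length(od))
  expect_lt(abs(mean(od) - 0.2), 3 * se)
})

test_that("idealization is invariant to a constant offset", {
  m <- two_state_model(500, 10, 10)
  tr <- simulate_gating(m, 3, seed = 55, noise_sd_pA = 2)
  id1 <- idealize(tr, c(0, -30))
  tr2 <- tr
  tr2$samples <- tr$samples + 7.5
  id2 <- idealize(tr2, c(0, -30) + 7.5)
  expect_equal(id1$segments$start, id2$segments$start)
  expect_equal(id1$segments$end, id2$segments$end)
  expect_equal(id1$segments$level_index, id2$segments$level_index)
})

test_that("idealization validates its inputs", {
  tr <- square_wave_trace(c(0, -25), 500, 4)
  expect_error(idealize(tr, c(-25, -25)), "distinct")
  expect_error(idealize(tr, c(0, -25), dead_time_s = 1e-5), "two sample")
  expect_error(estimate_levels(tr, 4), "2 or 3")
  flat <- current_trace(rep(0, 20000), 1e4, -60)
  expect_error(estimate_levels(flat, 2), "could not resolve 2")
  short <- current_trace(rep(c(0, -25), 100), 1e4, -60)
  expect_error(estimate_levels(short, 2), "1 s")
})

test_that("levels are recovered from a noisy simulated trace", {
  m <- two_state_model(500, 10, 10)   # -30 pA open level at -60 mV
  tr <- simulate_gating(m, 5, seed = 77, noise_sd_pA = 2)
  lev <- estimate_levels(tr, 2)
  expect_lt(abs(lev[1] - 0), 0.5)
  expect_lt(abs(lev[2] - (-30)), 0.5)
})
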