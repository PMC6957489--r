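conc8 <- c(25, 50, 100, 150, 250, 400, 700, 1200)

test_that("noiseless Hill curves are recovered to four significant figures", {
  curve <- dose_response_curve(conc8,
                               hill_response(conc8, 210, 4.3, 0, 1),
                               observable = "open_time")
  fit <- fit_hill(curve)
  expect_equal(signif(fit$ec50_uM, 4), 210)
  expect_equal(signif(fit$hill, 4), 4.3)
  expect_equal(fit$floor, 0, tolerance = 1e-6)
  expect_equal(fit$ceiling, 1, tolerance = 1e-4)
  expect_true(fit$ec50_in_range)
})

test_that("Hill fitting validates its inputs", {
  expect_error(fit_hill(dose_response_curve(conc8, rep(1, 8))), "constant")
  expect_error(fit_hill(dose_response_curve(c(100, 150, 200, 300),
                                            c(0.1, 0.4, 0.6, 0.9))),
               "4-fold")
  expect_error(fit_hill(dose_response_curve(c(10, 100, 1000),
                                            c(0.1, 0.5, 0.9))),
               "at least 4")
  expect_error(dose_response_curve(c(100, 50, 200, 400), 1:4),
               "strictly increasing")
  expect_error(dose_response_curve(c(-1, 50, 200, 400), 1:4), "> 0")
})

test_that("Hill fits are scale-equivariant in concentration", {
  curve <- simulate_hill_curve(conc8, 210, 4.3, 0, 1, noise_frac = 0.05,
                               seed = 12)
  f1 <- fit_hill(curve)
  curve10 <- dose_response_curve(curve$concentrations_uM * 10,
                                 curve$responses)
  f2 <- fit_hill(curve10)
  expect_equal(f2$ec50_uM / f1$ec50_uM, 10, tolerance = 1e-4)
  expect_equal(f2$hill, f1$hill, tolerance = 1e-4)
})

test_that("occurrence percentages are plain proportions", {
  expect_equal(occurrence_percentage(5, 20), 25)
  expect_equal(occurrence_percentage(0, 30), 0)
  expect_equal(occurrence_percentage(20, 20), 100)
  tab <- occurrence_table(c("a", "b"), c(20, 20), c(15, 5))
  expect_equal(tab$percentage, c(75, 25))
  expect_error(occurrence_table("a", 10, 12), "\\[0, n\\]")
})

test_that("the occurrence chi-squared matches hand computation", {
  res <- chi2_occurrence(list(n = 20, detected = 15),
                         list(n = 20, detected = 5))
  expect_equal(res$statistic, 10)
  expect_lt(res$p_value, 0.05)
  same <- chi2_occurrence(list(n = 20, detected = 8),
                          list(n = 20, detected = 8))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(chi2_occurrence(list(n = 10, detected = 0),
                               list(n = 10, detected = 0)),
               "expected cell")
})

test_that("chi-squared agrees with the textbook formula on random tables", {
  oracle_chi2 <- function(tab) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - E)^2 / E)
  }
  withr::with_seed(41, {
    for (i in 1:50) {
      n1 <- sample(5:50, 1); n2 <- sample(5:50, 1)
      d1 <- sample(1:(n1 - 1), 1); d2 <- sample(1:(n2 - 1), 1)
      res <- chi2_occurrence(list(n = n1, detected = d1),
                             list(n = n2, detected = d2))
      expect_equal(res$statistic, oracle_chi2(res$table), tolerance = 1e-9)
    }
  })
})

test_that("chi-squared p-values are calibrated under the null", {
  rejections <- withr::with_seed(23, {
    p <- replicate(2000, {
      a <- rbinom(1, 25, 0.4); b <- rbinom(1, 25, 0.4)
      out <- tryCatch(chi2_occurrence(list(n = 25, detected = a),
                                      list(n = 25, detected = b))$p_value,
                      error = function(e) NA_real_)
      out
    })
    mean(p[!is.na(p)] < 0.05)
  })
  expect_gte(rejections, 0.03)
  expect_lte(rejections, 0.08)
})

test_that("pairwise comparisons support Bonferroni adjustment", {
  tab <- occurrence_table(c("a", "b", "c"), c(30, 30, 30), c(25, 12, 5))
  pw <- chi2_pairwise(tab, adjust = "bonferroni")
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$p_adjusted >= pw$p_value))
  pw0 <- chi2_pairwise(tab)
  expect_equal(pw0$p_adjusted, pw0$p_value)
})
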