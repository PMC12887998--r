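amounts5 <- c(0.25, 1.25, 6.25, 25, 125)

test_that("log transform matches closed forms and rejects nonpositive input", {
  expect_equal(log_transform(1000, 10), 3)
  expect_equal(log_transform(8, 2), 3)
  expect_equal(log_transform(0.25, 10), log10(0.25))
  expect_error(log_transform(0), "positive")
  expect_error(log_transform(-2), "positive")
  expect_error(log_transform(1, base = 3), "base")
})

test_that("fit_line reproduces exact lines and hand-computed OLS", {
  x <- log10(amounts5)
  f <- fit_line(x, x + 1)
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)

  set.seed(5)
  for (i in 1:50) {
    n <- sample(3:8, 1)
    xs <- sort(rnorm(n)); ys <- 0.8 * xs + rnorm(n, sd = 0.3)
    f <- fit_line(xs, ys)
    o <- ols_oracle(xs, ys)
    expect_equal(f$slope, o$slope, tolerance = 1e-12)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-12)
    expect_equal(f$r_squared, o$r2, tolerance = 1e-12)
  }
  expect_equal(fit_line(c(0, 1), c(2, 5))$r_squared, 1)  # 2-point convention
  expect_error(fit_line(c(1, 1), c(2, 3)), "identical")
})

test_that("a perfect five-point curve classifies complete with nothing removed", {
  res <- count_linear_points(amounts5, 100 * amounts5)
  expect_equal(res$n_linear_points, 5L)
  expect_equal(res$category, "complete")
  expect_length(res$removed_amounts, 0)
  expect_equal(res$final_fit$r_squared, 1)
  expect_equal(res$final_fit$slope, 1, tolerance = 1e-12)
})

test_that("a floor-flattened lowest point is removed and the top four pass", {
  y <- 100 * amounts5
  y[1] <- y[1] + 2000  # background floor dominates only the 0.25 ug point
  res <- count_linear_points(amounts5, y)
  expect_equal(res$n_linear_points, 4L)
  expect_equal(res$category, "nearly_complete")
  expect_equal(res$removed_amounts, 0.25)
  # oracle: refit the top-4 subset independently
  o <- ols_oracle(log10(amounts5[2:5]), log10(y[2:5]))
  expect_equal(res$final_fit$r_squared, o$r2, tolerance = 1e-12)
  expect_gt(o$r2, 0.95)
  # and the full 5-point fit must indeed have failed
  expect_lte(ols_oracle(log10(amounts5), log10(y))$r2, 0.95)
})

test_that("flat and sparse responses are nonlinear or unquantifiable", {
  flat <- count_linear_points(amounts5, rep(500, 5))
  expect_equal(flat$category, "nonlinear")
  expect_equal(flat$n_linear_points, 0L)

  two <- count_linear_points(amounts5, c(NA, NA, NA, 100, 500))
  expect_equal(two$category, "unquantifiable")
  expect_equal(two$valid_point_count, 2L)
  expect_null(two$final_fit)

  # 4 valid values, lowest flattened: removal still possible down to 3
  y <- 100 * amounts5; y[1] <- NA; y[2] <- y[2] + 5000
  res <- count_linear_points(amounts5, y)
  expect_equal(res$n_linear_points, 3L)
  expect_equal(res$category, "partial")
  expect_equal(res$removed_amounts, 1.25)
})

test_that("iterative classifier agrees with the brute-force suffix oracle", {
  set.seed(123)
  for (i in 1:200) {
    y <- random_peptide_intensities(amounts5)
    res <- count_linear_points(amounts5, y)
    expect_identical(res$n_linear_points, suffix_oracle(amounts5, y))
  }
})

test_that("removals are always an ascending prefix of the valid amounts", {
  set.seed(321)
  for (i in 1:200) {
    y <- random_peptide_intensities(amounts5)
    res <- count_linear_points(amounts5, y)
    valid_amts <- sort(amounts5[!is.na(y) & y > 0])
    k <- length(res$removed_amounts)
    expect_identical(res$removed_amounts, valid_amts[seq_len(k)])
  }
})

test_that("raising the threshold never increases the linear-point count", {
  set.seed(77)
  for (i in 1:100) {
    y <- random_peptide_intensities(amounts5)
    lo <- count_linear_points(amounts5, y, threshold = 0.9)
    hi <- count_linear_points(amounts5, y, threshold = 0.99)
    expect_lte(hi$n_linear_points, lo$n_linear_points)
  }
})

test_that("classification is deterministic and base-invariant", {
  set.seed(9)
  y <- random_peptide_intensities(amounts5)
  a <- count_linear_points(amounts5, y)
  b <- count_linear_points(amounts5, y)
  expect_identical(a, b)
  b2 <- count_linear_points(amounts5, y, log_base = 2)
  expect_identical(a$n_linear_points, b2$n_linear_points)
  expect_identical(a$category, b2$category)
})

test_that("classify_table summarises categories and missing-point locations", {
  set.seed(15)
  coefs <- exp(runif(100, log(50), log(5000)))
  cal <- t(vapply(coefs, perfect_cal_intensities, numeric(5)))
  corrupt <- 1:10
  cal[corrupt, 1] <- cal[corrupt, 1] * 30  # ruin the lowest point only
  tab <- table_from_cal_matrix(cal)
  lin <- classify_table(tab)
  expect_equal(unname(lin$summary$counts["complete"]), 90L)
  expect_equal(unname(lin$summary$counts["nearly_complete"]), 10L)
  expect_equal(lin$summary$fraction_complete_or_nearly, 1)
  demoted <- lin$results$peptide_id[lin$results$category == "nearly_complete"]
  expect_setequal(demoted, sprintf("pep%03d", corrupt))

  # missingness concentrated at the lowest amount is reported as such
  cal2 <- t(vapply(coefs[1:20], perfect_cal_intensities, numeric(5)))
  cal2[1:9, 1] <- NA
  cal2[10, 3] <- NA
  tab2 <- table_from_cal_matrix(cal2)
  lin2 <- classify_table(tab2)
  expect_equal(lin2$summary$n_missing_calibration_points, 10L)
  expect_equal(lin2$summary$fraction_missing_at_lowest, 0.9)

  # a 2-valid-value peptide leaves the classified denominator
  cal3 <- rbind(perfect_cal_intensities(100),
                c(NA, NA, NA, 2500, 12500))
  lin3 <- classify_table(table_from_cal_matrix(cal3))
  expect_equal(lin3$summary$n_quantifiable, 1L)
  expect_equal(unname(lin3$summary$counts["unquantifiable"]), 1L)
  expect_equal(unname(lin3$summary$counts_merged["less_than_3_linear"]), 1L)
})

test_that("cross-batch consistency is 1 for identical batches and drops with one flip", {
  set.seed(25)
  coefs <- exp(runif(20, log(100), log(2000)))
  cal <- t(vapply(coefs, perfect_cal_intensities, numeric(5)))
  a <- classify_table(table_from_cal_matrix(cal, batch_id = "A"))
  b <- classify_table(table_from_cal_matrix(cal, batch_id = "B"))
  rep1 <- cross_batch_consistency(list(A = a, B = b))
  expect_equal(rep1$overall_consistency, 1)
  expect_equal(rep1$overlap["A", "B"], 20L)

  cal2 <- cal; cal2[5, ] <- 700  # flatten one peptide in batch B
  b2 <- classify_table(table_from_cal_matrix(cal2, batch_id = "B"))
  rep2 <- cross_batch_consistency(list(A = a, B = b2))
  expect_equal(rep2$consistency["A", "B"], 19 / 20)

  dis_a <- a$results; dis_b <- b$results
  dis_b$peptide_id <- paste0("other_", dis_b$peptide_id)
  expect_warning(rep3 <- cross_batch_consistency(list(A = dis_a, B = dis_b)),
                 "no peptides shared")
  expect_equal(rep3$overlap["A", "B"], 0L)
  expect_true(is.na(rep3$overall_consistency))
})
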