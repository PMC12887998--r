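amounts5 <- c(0.25, 1.25, 6.25, 25, 125)

# a small table: protein A truly doubles but has one clean peptide and one
# floor-dominated (nearly flat, hence nonlinear) peptide whose measured
# signal barely moves; protein B has two clean peptides
mixed_protein_table <- function(fc_b = 1) {
  design <- tmt11_calibration_design()
  cal <- rbind(perfect_cal_intensities(100),
               2 * amounts5 + 600,   # floor-dominated: nonlinear
               perfect_cal_intensities(300),
               perfect_cal_intensities(800))
  tab <- table_from_cal_matrix(cal, protein = c("A", "A", "B", "B"))
  d <- tab$data
  for (ch in sample_channels(design, "untreated")) {
    d[[ch]] <- c(100 * 25, 2 * 25 + 600, 300 * 25, 800 * 25)
  }
  for (ch in sample_channels(design, "treated")) {
    d[[ch]] <- c(100 * 25 * 2, 2 * 25 + 600,
                 300 * 25 * fc_b, 800 * 25 * fc_b)
  }
  peptide_quant_table(d, design)
}

test_that("linear-only selection keeps linear peptides and drops nonlinear ones", {
  tab <- mixed_protein_table()
  lin <- classify_table(tab)
  expect_setequal(
    lin$results$category[lin$results$peptide_id == "pep002"], "nonlinear")
  sel_all <- select_peptides(lin, mode = "all")
  sel_lin <- select_peptides(lin, mode = "linear_only")
  expect_equal(nrow(sel_all), 4)
  expect_setequal(sel_lin$peptide_id, c("pep001", "pep003", "pep004"))
  # nesting: linear-only is a subset of all
  expect_true(all(sel_lin$peptide_id %in% sel_all$peptide_id))
})

test_that("range gating removes peptides whose endogenous signal left the range", {
  tab <- mixed_protein_table()
  d <- tab$data
  # push pep003's treated channels a decade above its calibration range
  for (ch in sample_channels(tab$design, "treated")) {
    d[[ch]][3] <- 300 * 125 * 20
  }
  tab2 <- peptide_quant_table(d, tab$design)
  lin <- classify_table(tab2)
  ass <- assess_table(tab2, lin)
  sel <- select_peptides(lin, ass, mode = "linear_only", range_rule = "all")
  expect_false("pep003" %in% sel$peptide_id)
  sel_any <- select_peptides(lin, ass, mode = "linear_only",
                             range_rule = "any")
  expect_true("pep003" %in% sel_any$peptide_id)
})

test_that("protein rollup is the per-channel median of peptide log2 values", {
  design <- tmt11_calibration_design()
  cal <- rbind(perfect_cal_intensities(2^10 / 25),
               perfect_cal_intensities(2^11 / 25),
               perfect_cal_intensities(2^30 / 25))
  tab <- table_from_cal_matrix(cal, protein = c("P", "P", "P"))
  d <- tab$data
  for (ch in sample_channels(design)) d[[ch]] <- c(2^10, 2^11, 2^30)
  tab <- peptide_quant_table(d, design)
  r <- protein_rollup(tab)
  expect_equal(unname(r$summaries["P", "126"]), 11)
  # single-peptide protein: rollup equals that peptide's log2 values
  one <- table_from_cal_matrix(cal[1, , drop = FALSE], protein = "Q",
                               sample_value = 2^10)
  r1 <- protein_rollup(one)
  expect_equal(unname(r1$summaries["Q", sample_channels(design)]),
               rep(10, 6), ignore_attr = TRUE)
})

test_that("differential test: exact null gives fc 0 and p 1; BH matches hand computation", {
  design <- tmt11_calibration_design()
  s <- matrix(10, 3, 6,
              dimnames = list(c("A", "B", "C"), sample_channels(design)))
  # null protein A; proteins B and C shifted with within-condition spread
  s["B", ] <- c(10.0, 10.1, 9.9, 11.0, 11.1, 10.9)
  s["C", ] <- c(10.0, 10.2, 9.8, 12.0, 12.2, 11.8)
  rollup <- list(summaries = s, n_peptides = c(A = 1L, B = 1L, C = 1L),
                 n_batches = c(A = 1L, B = 1L, C = 1L), n_uncalibrated = 0L)
  res <- differential_test(rollup, design)
  a <- res[res$protein_accession == "A", ]
  expect_equal(a$log2_fc, 0)
  expect_equal(a$p_value, 1)
  expect_equal(res$log2_fc[res$protein_accession == "B"], 1)
  expect_equal(res$log2_fc[res$protein_accession == "C"], 2)

  # Benjamini-Hochberg by hand: p_(i) * n / i, cumulative minimum from the top
  p <- sort(res$p_value)
  hand <- rev(cummin(rev(p * 3 / seq_len(3))))
  expect_equal(sort(res$adj_p_value), pmin(hand, 1))
  expect_true(all(res$adj_p_value >= res$p_value))
  # BH monotone in p rank
  o <- order(res$p_value)
  expect_true(all(diff(res$adj_p_value[o]) >= -1e-12))
})

test_that("hand-checked BH example: equal-spaced p-values collapse to the largest", {
  # p = {0.01, 0.02, 0.03} over 3 tests: adjusted = {0.03, 0.03, 0.03}
  expect_equal(rev(cummin(rev(c(0.01, 0.02, 0.03) * 3 / 1:3))),
               rep(0.03, 3))
})

test_that("untestable proteins are flagged, not silently tested", {
  design <- tmt11_calibration_design()
  s <- matrix(c(10, NA, NA, 11, 11.2, 10.8), 1, 6,
              dimnames = list("X", sample_channels(design)))
  rollup <- list(summaries = s, n_peptides = c(X = 1L),
                 n_batches = c(X = 1L), n_uncalibrated = 0L)
  res <- differential_test(rollup, design)
  expect_false(res$testable)
  expect_true(is.na(res$p_value))
})

test_that("a spiked two-fold change is recovered within simulation error", {
  sim <- simulate_experiment(sim_config(n_proteins = 60, fraction_changed = 1,
                                        cv_multiplicative = 0.05, seed = 61))
  lin <- classify_table(sim$table)
  res <- quantify_proteins(sim$table, lin, mode = "all")
  m <- merge(res, sim$truth$proteins, by = "protein_accession")
  expect_equal(mean(abs(m$log2_fc - m$true_log2_fc) < 0.2), 1)
  expect_lt(abs(mean(m$log2_fc - m$true_log2_fc)), 0.05)
})

test_that("expected ratio to the 1:1 point is log2(amount/reference)", {
  sim <- simulate_experiment(sim_config(n_proteins = 20,
                                        cv_multiplicative = 0, seed = 71))
  lin <- classify_table(sim$table)
  rd <- ratio_to_reference(sim$table, lin, "130C")  # 6.25 ug
  expect_equal(rd$expected_log2_ratio, -2)
  expect_equal(rd$dispersion, 0, tolerance = 1e-12)
  rd2 <- ratio_to_reference(sim$table, lin, "129C")  # 0.25 ug
  expect_equal(rd2$expected_log2_ratio, log2(0.25 / 25))
  expect_equal(max(abs(rd2$deviation)), 0, tolerance = 1e-12)
  expect_error(ratio_to_reference(sim$table, lin, "126"),
               "not a calibration channel")
})

test_that("floor-affected dispersion shrinks under linear-only selection", {
  sim <- simulate_experiment(sim_config(n_proteins = 60,
                                        coef_meanlog = log(50),
                                        background_floor = 200, seed = 81))
  lin <- classify_table(sim$table)
  d_all <- ratio_to_reference(sim$table, lin, "129C", mode = "all")
  d_lin <- ratio_to_reference(sim$table, lin, "129C", mode = "linear_only")
  expect_lt(d_lin$dispersion, d_all$dispersion)
  expect_lt(d_lin$n, d_all$n)
})

test_that("a floored nonlinear peptide dilutes a true change; linear-only restores it", {
  tab <- mixed_protein_table()
  lin <- classify_table(tab)
  ass <- assess_table(tab, lin)
  res_all <- quantify_proteins(tab, lin, ass, mode = "all")
  res_lin <- quantify_proteins(tab, lin, ass, mode = "linear_only")
  fc_all <- res_all$log2_fc[res_all$protein_accession == "A"]
  fc_lin <- res_lin$log2_fc[res_lin$protein_accession == "A"]
  # protein A truly doubles, but its floored peptide reads ~1:1
  expect_lt(fc_all, 0.9)
  expect_equal(fc_lin, 1, tolerance = 1e-9)
  expect_gt(abs(fc_lin), abs(fc_all))

  cmp <- compare_selection_modes(res_all, res_lin)
  expect_equal(nrow(cmp$comparison), 2)
  expect_length(cmp$dropped, 0)

  # identical selections give zero discrepancies
  cmp0 <- compare_selection_modes(res_all, res_all)
  expect_equal(cmp0$n_discrepant, 0)
})

test_that("proteins with no linear peptide vanish from linear-only and are counted", {
  design <- tmt11_calibration_design()
  cal <- rbind(2 * amounts5 + 600, perfect_cal_intensities(100))
  tab <- table_from_cal_matrix(cal, protein = c("onlybad", "good"))
  lin <- classify_table(tab)
  res_lin <- quantify_proteins(tab, lin, mode = "linear_only")
  expect_false("onlybad" %in% res_lin$protein_accession)
  expect_equal(attr(res_lin, "n_proteins_dropped"), 1L)
  res_all <- quantify_proteins(tab, lin, mode = "all")
  expect_true("onlybad" %in% res_all$protein_accession)
  cmp <- compare_selection_modes(res_all, res_lin)
  expect_equal(cmp$dropped, "onlybad")
})

test_that("noiseless fold-changes match between raw and calibrated pipelines", {
  sim <- simulate_experiment(sim_config(n_proteins = 30, fraction_changed = 1,
                                        cv_multiplicative = 0, seed = 91))
  lin <- classify_table(sim$table)
  ass <- assess_table(sim$table, lin)
  raw <- quantify_proteins(sim$table, lin, ass, mode = "linear_only")
  cal <- quantify_proteins(sim$table, lin, ass, mode = "linear_only",
                           calibrated = TRUE)
  m <- merge(raw[, c("protein_accession", "log2_fc")],
             cal[, c("protein_accession", "log2_fc")],
             by = "protein_accession")
  expect_equal(m$log2_fc.x, m$log2_fc.y, tolerance = 1e-9)
  truth <- sim$truth$proteins
  mm <- merge(m, truth, by = "protein_accession")
  expect_equal(mm$log2_fc.x, mm$true_log2_fc, tolerance = 1e-9)
})
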