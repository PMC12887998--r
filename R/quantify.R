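#' @title Protein-level relative quantification
#' @description Protein abundances are summarised from peptide reporter
#'   signals (or calibrated amounts) by a median rollup on the log2 scale and
#'   compared between conditions with a Welch t test and Benjamini-Hochberg
#'   adjustment. Quantification can use all quantified peptides or only
#'   those with linear quantitative behaviour, and the two selections can be
#'   compared side by side.
#' @name quantify
NULL

category_rank <- function(category) {
  match(category, c("complete", "nearly_complete", "partial"))
}

#' Select peptides per protein for quantification
#'
#' @param linearity a `linearity_table` from [classify_table()].
#' @param assessments optional long data.frame from [assess_table()]; when
#'   given and `range_rule != "ignore"`, linear-only selection additionally
#'   requires the peptide's endogenous channels to lie within its linear
#'   range.
#' @param mode `"all"` keeps every quantified peptide (>= 3 valid
#'   calibration values not required); `"linear_only"` keeps peptides whose
#'   category is at least `min_category`.
#' @param min_category minimal category that counts as linear; default
#'   `"nearly_complete"` (four or five linear points), `"partial"` relaxes to
#'   three.
#' @param range_rule for linear-only selection: `"all"` (default) requires
#'   every non-missing endogenous channel within range, `"any"` requires at
#'   least one, `"ignore"` skips range gating.
#' @return data.frame of selected `(peptide_id, batch_id)` keys.
#' @export
select_peptides <- function(linearity, assessments = NULL,
                            mode = c("all", "linear_only"),
                            min_category = c("nearly_complete", "partial",
                                             "complete"),
                            range_rule = c("all", "any", "ignore")) {
  mode <- match.arg(mode)
  min_category <- match.arg(min_category)
  range_rule <- match.arg(range_rule)
  res <- linearity$results
  if (mode == "all") {
    return(res[, c("peptide_id", "batch_id"), drop = FALSE])
  }
  keep <- !is.na(category_rank(res$category)) &
    category_rank(res$category) <= category_rank(min_category)
  sel <- res[keep, c("peptide_id", "batch_id"), drop = FALSE]
  if (!is.null(assessments) && range_rule != "ignore" && nrow(sel) > 0) {
    pos <- !is.na(assessments$intensity) & assessments$intensity > 0
    a <- assessments[pos, , drop = FALSE]
    key <- paste(a$peptide_id, a$batch_id, sep = "\r")
    agg <- if (range_rule == "all") {
      tapply(a$within_range, key, all)
    } else {
      tapply(a$within_range, key, any)
    }
    sel_key <- paste(sel$peptide_id, sel$batch_id, sep = "\r")
    ok <- agg[sel_key]
    ok[is.na(ok)] <- TRUE  # no assessable endogenous signal: no evidence against
    sel <- sel[as.logical(ok), , drop = FALSE]
  }
  rownames(sel) <- NULL
  sel
}

#' Roll peptide values up to protein-level channel summaries
#'
#' Protein summary per channel = median of the selected peptides' log2
#' values; the value is log2 reporter intensity, or log2 calibrated amount
#' when `calibrated = TRUE` (peptides whose calibration was refused by the
#' slope floor are then dropped and counted).
#'
#' @param table a [peptide_quant_table].
#' @param selection data.frame of `(peptide_id, batch_id)` keys from
#'   [select_peptides()]; default all records.
#' @param channels channel labels to summarise (default: sample channels).
#' @param calibrated use calibrated amounts instead of raw intensities.
#' @param linearity required when `calibrated = TRUE`: the `linearity_table`
#'   providing each peptide's regression line.
#' @param slope_floor slope floor for calibration (see
#'   [calibrate_intensity()]).
#' @return List with `summaries` (numeric matrix protein x channel of median
#'   log2 values), `n_peptides` (named vector of peptides used per protein),
#'   `n_batches` (named vector) and `n_uncalibrated` (peptides dropped by the
#'   slope floor when `calibrated`).
#' @export
protein_rollup <- function(table, selection = NULL, channels = NULL,
                           calibrated = FALSE, linearity = NULL,
                           slope_floor = 0.1) {
  design <- table$design
  if (is.null(channels)) channels <- sample_channels(design)
  d <- table$data
  if (!is.null(selection)) {
    key_t <- paste(d$peptide_id, d$batch_id, sep = "\r")
    key_s <- paste(selection$peptide_id, selection$batch_id, sep = "\r")
    d <- d[key_t %in% key_s, , drop = FALSE]
  }
  if (nrow(d) == 0) {
    return(list(summaries = matrix(numeric(0), 0, length(channels),
                                   dimnames = list(NULL, channels)),
                n_peptides = integer(0), n_batches = integer(0),
                n_uncalibrated = 0L))
  }
  m <- as.matrix(d[, channels, drop = FALSE])
  m[m <= 0] <- NA  # nonpositive signal carries no usable quantitative value

  n_uncalibrated <- 0L
  if (calibrated) {
    if (is.null(linearity)) stop("calibrated rollup needs a linearity_table")
    res <- linearity$results
    log_base <- linearity$summary$log_base
    idx <- match(paste(d$peptide_id, d$batch_id, sep = "\r"),
                 paste(res$peptide_id, res$batch_id, sep = "\r"))
    if (anyNA(idx)) stop("linearity results do not cover every selected record")
    slope <- res$slope[idx]; intercept <- res$intercept[idx]
    usable <- !is.na(slope) & abs(slope) >= slope_floor
    n_uncalibrated <- sum(!usable)
    m <- log(m, log_base)
    m <- sweep(sweep(m, 1, intercept, "-"), 1, slope, "/")
    m <- log_base^m
    m[!usable, ] <- NA
  }
  lm2 <- log2(m)

  prot <- d$protein_accession
  summaries <- do.call(rbind, lapply(split(seq_len(nrow(d)), prot), function(i) {
    apply(lm2[i, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  }))
  summaries[is.nan(summaries)] <- NA
  n_peptides <- vapply(split(d$peptide_id, prot),
                       function(x) length(unique(x)), integer(1))
  n_batches <- vapply(split(d$batch_id, prot),
                      function(x) length(unique(x)), integer(1))
  list(summaries = summaries, n_peptides = n_peptides[rownames(summaries)],
       n_batches = n_batches[rownames(summaries)],
       n_uncalibrated = n_uncalibrated)
}

welch_p <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y)$p.value
}

#' Test proteins for differential abundance between two conditions
#'
#' log2 fold-change is the difference of condition means of the protein
#' channel summaries; the p-value comes from a two-sample unequal-variance
#' (Welch) t statistic, adjusted across proteins by Benjamini-Hochberg.
#'
#' @param rollup result of [protein_rollup()] over the sample channels.
#' @param design the [channel_design]; must define exactly two conditions
#'   with >= 2 replicates each.
#' @param conditions optional length-2 character vector `(reference,
#'   treatment)`; defaults to the design's condition order. Fold-changes are
#'   treatment minus reference.
#' @param selection_mode label recorded in the output.
#' @return data.frame: `protein_accession`, `log2_fc`, `p_value`,
#'   `adj_p_value`, `n_peptides_used`, `n_batches`, `selection_mode`,
#'   `testable`. Proteins with fewer than 2 non-missing summaries in a
#'   condition are flagged untestable (`p_value` `NA`, excluded from BH).
#' @export
differential_test <- function(rollup, design, conditions = NULL,
                              selection_mode = "all") {
  conds <- unique(design$condition[design$role == "sample"])
  conds <- conds[!is.na(conds)]
  if (is.null(conditions)) conditions <- conds
  if (length(conditions) != 2) stop("need exactly two conditions")
  ref_ch <- sample_channels(design, conditions[1])
  trt_ch <- sample_channels(design, conditions[2])
  if (length(ref_ch) < 2 || length(trt_ch) < 2) {
    stop("need >= 2 replicates per condition")
  }
  s <- rollup$summaries
  ref <- s[, ref_ch, drop = FALSE]
  trt <- s[, trt_ch, drop = FALSE]
  n_ref <- rowSums(!is.na(ref)); n_trt <- rowSums(!is.na(trt))
  testable <- n_ref >= 2 & n_trt >= 2
  log2_fc <- rowMeans(trt, na.rm = TRUE) - rowMeans(ref, na.rm = TRUE)
  p <- rep(NA_real_, nrow(s))
  for (i in which(testable)) p[i] <- welch_p(trt[i, ], ref[i, ])
  adj <- rep(NA_real_, nrow(s))
  adj[testable] <- stats::p.adjust(p[testable], method = "BH")
  out <- data.frame(
    protein_accession = rownames(s),
    log2_fc = unname(log2_fc),
    p_value = p, adj_p_value = adj,
    n_peptides_used = unname(rollup$n_peptides),
    n_batches = unname(rollup$n_batches),
    selection_mode = selection_mode,
    testable = testable,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' One-call protein quantification under a peptide selection mode
#'
#' @param table a [peptide_quant_table].
#' @param linearity a `linearity_table` from [classify_table()].
#' @param assessments optional [assess_table()] output for range gating.
#' @param mode,min_category,range_rule passed to [select_peptides()].
#' @param calibrated,slope_floor passed to [protein_rollup()].
#' @param conditions passed to [differential_test()].
#' @return A [differential_test()] data.frame; proteins left with no
#'   peptides under the selection are absent and counted in
#'   `attr(, "n_proteins_dropped")`.
#' @export
quantify_proteins <- function(table, linearity, assessments = NULL,
                              mode = c("all", "linear_only"),
                              min_category = "nearly_complete",
                              range_rule = "all",
                              calibrated = FALSE, slope_floor = 0.1,
                              conditions = NULL) {
  mode <- match.arg(mode)
  sel <- select_peptides(linearity, assessments, mode = mode,
                         min_category = min_category,
                         range_rule = range_rule)
  all_proteins <- unique(table$data$protein_accession)
  rollup <- protein_rollup(table, sel, calibrated = calibrated,
                           linearity = linearity, slope_floor = slope_floor)
  out <- differential_test(rollup, table$design, conditions = conditions,
                           selection_mode = mode)
  attr(out, "n_proteins_dropped") <-
    length(setdiff(all_proteins, out$protein_accession))
  attr(out, "dropped_proteins") <-
    setdiff(all_proteins, out$protein_accession)
  out
}

#' Dispersion of protein ratios to the 1:1 calibration point
#'
#' Uses the dilution points inside the calibration curve as samples of known
#' relative abundance: for a chosen dilution channel, computes each
#' protein's observed log2 ratio to the calibration channel loaded at the
#' reference (1:1) amount, compares with the expected `log2(amount /
#' reference)`, and summarises the dispersion of the deviations as the
#' median absolute deviation from the expected ratio.
#'
#' @param table a [peptide_quant_table].
#' @param linearity a `linearity_table`.
#' @param dilution_channel a calibration channel label.
#' @param mode,min_category passed to [select_peptides()] (range gating does
#'   not apply: the ratio involves calibration channels only).
#' @param per_peptide compute ratios per peptide instead of per protein
#'   after rollup.
#' @return A `ratio_dispersion`: list with `expected_log2_ratio`, `observed`
#'   (per-protein or per-peptide observed log2 ratios), `deviation`,
#'   `dispersion` (median |observed - expected|), `n`, `selection_mode`.
#' @export
ratio_to_reference <- function(table, linearity, dilution_channel,
                               mode = c("all", "linear_only"),
                               min_category = "nearly_complete",
                               per_peptide = FALSE) {
  mode <- match.arg(mode)
  design <- table$design
  amounts <- calibration_amounts(design)
  if (!dilution_channel %in% names(amounts)) {
    stop(dilution_channel, " is not a calibration channel")
  }
  ref_ch <- reference_channel(design)
  if (is.na(ref_ch)) stop("design has no calibration channel at the reference amount")
  expected <- log2(amounts[[dilution_channel]] / reference_amount(design))

  sel <- select_peptides(linearity, NULL, mode = mode,
                         min_category = min_category, range_rule = "ignore")
  if (per_peptide) {
    d <- table$data
    key_t <- paste(d$peptide_id, d$batch_id, sep = "\r")
    key_s <- paste(sel$peptide_id, sel$batch_id, sep = "\r")
    d <- d[key_t %in% key_s, , drop = FALSE]
    obs <- log2(d[[dilution_channel]]) - log2(d[[ref_ch]])
    names(obs) <- d$peptide_id
  } else {
    rollup <- protein_rollup(table, sel, channels = c(dilution_channel, ref_ch))
    obs <- rollup$summaries[, dilution_channel] - rollup$summaries[, ref_ch]
  }
  obs <- obs[is.finite(obs)]
  deviation <- obs - expected
  structure(list(
    dilution_channel = dilution_channel,
    amount_ug = amounts[[dilution_channel]],
    reference_amount_ug = reference_amount(design),
    expected_log2_ratio = unname(expected),
    observed = obs,
    deviation = deviation,
    dispersion = stats::median(abs(deviation)),
    n = length(obs),
    selection_mode = mode,
    per_peptide = per_peptide
  ), class = "ratio_dispersion")
}

#' @export
print.ratio_dispersion <- function(x, ...) {
  cat(sprintf(
    "ratio_dispersion [%s]: %s vs 1:1, expected log2 ratio %.3f, n=%d, MAD=%.4f\n",
    x$selection_mode, x$dilution_channel, x$expected_log2_ratio, x$n,
    x$dispersion))
  invisible(x)
}

#' Compare protein results between all-peptide and linear-only selection
#'
#' @param all_results,linear_results [differential_test()] data.frames
#'   computed on the same table under the two selection modes.
#' @param alpha adjusted-p significance boundary, default 0.05.
#' @return List with `comparison` (side-by-side log2 fold-changes and
#'   adjusted p-values with a `discrepant` flag for proteins crossing the
#'   significance boundary in exactly one mode), `discrepant` (that subset)
#'   and `dropped` (proteins present under all-peptide selection only).
#' @export
compare_selection_modes <- function(all_results, linear_results,
                                    alpha = 0.05) {
  merged <- merge(
    all_results[, c("protein_accession", "log2_fc", "adj_p_value",
                    "n_peptides_used")],
    linear_results[, c("protein_accession", "log2_fc", "adj_p_value",
                       "n_peptides_used")],
    by = "protein_accession", suffixes = c("_all", "_linear"))
  sig_all <- !is.na(merged$adj_p_value_all) & merged$adj_p_value_all < alpha
  sig_lin <- !is.na(merged$adj_p_value_linear) & merged$adj_p_value_linear < alpha
  merged$significant_all <- sig_all
  merged$significant_linear <- sig_lin
  merged$discrepant <- xor(sig_all, sig_lin)
  dropped <- setdiff(all_results$protein_accession,
                     linear_results$protein_accession)
  list(comparison = merged,
       discrepant = merged[merged$discrepant, , drop = FALSE],
       n_discrepant = sum(merged$discrepant),
       dropped = dropped,
       alpha = alpha)
}
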