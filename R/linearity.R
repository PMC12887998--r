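#' @title Per-peptide calibration-curve linearity
#' @description Every identified peptide gets its own internal calibration
#'   curve from the multiplexed dilution series. On log-transformed amounts
#'   and intensities an ordinary least-squares line is fit; if the fit's
#'   R-squared does not exceed the threshold, the lowest-concentration point
#'   is removed and the line refit, iterating until it does. The number of
#'   points remaining is the peptide's count of linear points, which drives
#'   its linearity category.
#' @name linearity
NULL

CATEGORY_LEVELS <- c("complete", "nearly_complete", "partial",
                     "nonlinear", "unquantifiable")

#' Log-transform an intensity or amount
#'
#' @param x positive numeric values.
#' @param base 10 (default) or 2. Classification and calibrated amounts are
#'   invariant to the base because R-squared is.
#' @return `log(x, base)`; nonpositive or missing input is an error (zeros
#'   and missing values are excluded upstream).
#' @export
log_transform <- function(x, base = 10) {
  if (!base %in% c(10, 2)) stop("log base must be 10 or 2")
  if (any(!is.finite(x) | x <= 0)) stop("log_transform requires positive input")
  log(x, base = base)
}

#' Fit a calibration line by ordinary least squares
#'
#' @param log_amount,log_intensity numeric vectors of equal length (already
#'   log-transformed), at least 2 points with distinct amounts.
#' @return A `calibration_fit`: list with `slope`, `intercept`, `r_squared`,
#'   `n_points` and `points_used` (data.frame of the input points).
#'   `r_squared` is the squared Pearson correlation of the points; with
#'   exactly 2 points it is reported as 1 but never used for classification;
#'   a flat (zero-variance) response gets 0.
#' @export
fit_line <- function(log_amount, log_intensity) {
  n <- length(log_amount)
  stopifnot(length(log_intensity) == n)
  if (n < 2) stop("fit_line needs at least 2 points")
  if (length(unique(log_amount)) < 2) stop("all amounts identical; cannot fit")
  fit <- stats::.lm.fit(cbind(1, log_amount), log_intensity)
  r2 <- if (n == 2) {
    1
  } else if (stats::sd(log_intensity) == 0) {
    0  # squared Pearson correlation undefined for a flat response
  } else {
    stats::cor(log_amount, log_intensity)^2
  }
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 r_squared = r2,
                 n_points = n,
                 points_used = data.frame(log_amount = log_amount,
                                          log_intensity = log_intensity)),
            class = "calibration_fit")
}

#' Count a peptide's linear calibration points
#'
#' Implements the iterative lowest-point-removal classifier. With fewer than
#' 3 valid (non-missing, positive) calibration values the peptide is
#' `unquantifiable`. Otherwise all valid points are fit; while the fit's
#' R-squared does not exceed `threshold` and more than 3 points remain, the
#' lowest-amount point is removed and the line refit. If the surviving fit
#' passes, the remaining count is the number of linear points; if even the 3
#' highest points fail, the peptide is `nonlinear` with fewer than 3 linear
#' points (encoded as 0).
#'
#' @param amounts numeric vector of calibration amounts (ug).
#' @param intensities matching reporter intensities; `NA` = missing.
#' @param threshold R-squared threshold, strict comparison (`R^2 >
#'   threshold`); default 0.95.
#' @param log_base passed to [log_transform()].
#' @param n_design number of calibration points in the design (defaults to
#'   `length(amounts)`); a peptide is `complete` when all of them are linear.
#' @return A `linearity_result`: list with `n_linear_points`,
#'   `valid_point_count`, `category`, `removed_amounts` (ascending prefix of
#'   the valid amounts), `final_fit` (a `calibration_fit`, or `NULL` when
#'   unquantifiable) and the retained-range bounds used downstream.
#' @export
count_linear_points <- function(amounts, intensities, threshold = 0.95,
                                log_base = 10, n_design = length(amounts)) {
  stopifnot(length(amounts) == length(intensities))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)")
  }
  valid <- !is.na(intensities) & intensities > 0
  a <- amounts[valid]
  y <- intensities[valid]
  ord <- order(a)
  a <- a[ord]; y <- y[ord]
  n_valid <- length(a)

  res <- list(n_linear_points = 0L, valid_point_count = n_valid,
              category = "unquantifiable", removed_amounts = numeric(0),
              final_fit = NULL, log_base = log_base, threshold = threshold)
  if (n_valid < 3) {
    class(res) <- "linearity_result"
    return(res)
  }

  la <- log_transform(a, log_base)
  ly <- log_transform(y, log_base)
  start <- 1L
  fit <- fit_line(la, ly)
  while (fit$r_squared <= threshold && (n_valid - start) >= 3) {
    start <- start + 1L  # drop the lowest remaining concentration
    fit <- fit_line(la[start:n_valid], ly[start:n_valid])
  }

  if (fit$r_squared > threshold) {
    k <- n_valid - start + 1L
    res$n_linear_points <- k
    res$category <- if (k >= n_design) "complete"
      else if (k == n_design - 1L) "nearly_complete"
      else "partial"
  } else {
    res$category <- "nonlinear"  # fewer than 3 linear points
  }
  res$removed_amounts <- a[seq_len(start - 1L)]
  res$final_fit <- fit
  res$retained_amounts <- a[start:n_valid]
  res$retained_log_intensity <- ly[start:n_valid]
  class(res) <- "linearity_result"
  res
}

#' @export
print.linearity_result <- function(x, ...) {
  cat("linearity_result: category=", x$category,
      ", linear points=", x$n_linear_points,
      "/", x$valid_point_count, " valid", sep = "")
  if (!is.null(x$final_fit)) {
    cat(sprintf(", R2=%.4f, slope=%.3f", x$final_fit$r_squared,
                x$final_fit$slope))
  }
  cat("\n")
  invisible(x)
}

linearity_row <- function(peptide_id, batch_id, res) {
  fit <- res$final_fit
  has_range <- res$category %in% c("complete", "nearly_complete", "partial")
  data.frame(
    peptide_id = peptide_id, batch_id = batch_id,
    valid_point_count = res$valid_point_count,
    n_linear_points = res$n_linear_points,
    slope = if (is.null(fit)) NA_real_ else fit$slope,
    intercept = if (is.null(fit)) NA_real_ else fit$intercept,
    r_squared = if (is.null(fit)) NA_real_ else fit$r_squared,
    removed_amounts = paste(res$removed_amounts, collapse = ","),
    category = res$category,
    min_retained_amount = if (has_range) min(res$retained_amounts) else NA_real_,
    max_retained_amount = if (has_range) max(res$retained_amounts) else NA_real_,
    min_retained_log_intensity = if (has_range) min(res$retained_log_intensity) else NA_real_,
    max_retained_log_intensity = if (has_range) max(res$retained_log_intensity) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Classify the linearity of every peptide in a table
#'
#' @param table a [peptide_quant_table].
#' @param threshold,log_base passed to [count_linear_points()].
#' @param use_sample_mean append the mean of the biological sample channels
#'   as an extra calibration point at the reference amount (default `FALSE`:
#'   only the dedicated calibration channels form the curve).
#' @return A `linearity_table`: list with `results` (one row per record:
#'   fit parameters, retained-range bounds, category) and `summary` (category
#'   counts and fractions — both with unquantifiable/nonlinear split and
#'   merged — plus the fraction of missing calibration points that occur at
#'   the lowest amount).
#' @export
classify_table <- function(table, threshold = 0.95, log_base = 10,
                           use_sample_mean = FALSE) {
  design <- table$design
  cal_ch <- calibration_channels(design)
  amounts <- unname(calibration_amounts(design))
  d <- table$data
  m <- intensity_matrix(table, cal_ch)

  extra_amount <- NULL
  if (use_sample_mean) {
    smp <- intensity_matrix(table, sample_channels(design))
    extra <- rowMeans(smp, na.rm = TRUE)
    extra[is.nan(extra)] <- NA_real_
    m <- cbind(m, extra)
    amounts <- c(amounts, reference_amount(design))
  }
  n_design <- length(amounts)

  rows <- vector("list", nrow(d))
  for (i in seq_len(nrow(d))) {
    res <- count_linear_points(amounts, m[i, ], threshold = threshold,
                               log_base = log_base, n_design = n_design)
    rows[[i]] <- linearity_row(d$peptide_id[i], d$batch_id[i], res)
  }
  results <- do.call(rbind, rows)

  counts <- table(factor(results$category, levels = CATEGORY_LEVELS))
  quantifiable <- results$category != "unquantifiable"
  denom <- sum(quantifiable)
  fractions <- if (denom > 0) as.numeric(counts[1:4]) / denom else rep(NA_real_, 4)
  names(fractions) <- CATEGORY_LEVELS[1:4]

  # where are the missing calibration points?
  cal_only <- intensity_matrix(table, cal_ch)
  missing_mask <- is.na(cal_only) | cal_only <= 0
  n_missing <- sum(missing_mask)
  lowest_col <- which.min(unname(calibration_amounts(design)))
  missing_at_lowest <- if (n_missing > 0) {
    sum(missing_mask[, lowest_col]) / n_missing
  } else NA_real_

  structure(list(
    results = results,
    summary = list(
      n_records = nrow(results),
      counts = stats::setNames(as.integer(counts), names(counts)),
      n_quantifiable = denom,
      fractions = fractions,
      fraction_complete_or_nearly =
        if (denom > 0) sum(results$n_linear_points >= n_design - 1L) / denom
        else NA_real_,
      counts_merged = c(
        stats::setNames(as.integer(counts[1:3]), CATEGORY_LEVELS[1:3]),
        less_than_3_linear = as.integer(counts[["nonlinear"]] +
                                        counts[["unquantifiable"]])),
      n_missing_calibration_points = n_missing,
      fraction_missing_at_lowest = missing_at_lowest,
      threshold = threshold, log_base = log_base, n_design_points = n_design
    )
  ), class = "linearity_table")
}

#' @export
print.linearity_table <- function(x, ...) {
  s <- x$summary
  cat("linearity_table: ", s$n_records, " peptide records (",
      s$n_quantifiable, " with >= 3 valid calibration values)\n", sep = "")
  print(s$counts)
  if (!is.na(s$fraction_complete_or_nearly)) {
    cat(sprintf("complete or nearly complete: %.1f%%\n",
                100 * s$fraction_complete_or_nearly))
  }
  invisible(x)
}

#' Cross-batch consistency of linearity classification
#'
#' For peptides classified `complete` or `nearly_complete` in one batch,
#' reports the fraction that keep that super-category in each other batch in
#' which they are identified, plus the peptide-overlap matrix across batches.
#'
#' @param results_by_batch named list of `linearity_table` objects (or their
#'   `$results` data.frames), one per batch.
#' @return List with `overlap` (batch x batch shared-peptide counts),
#'   `consistency` (batch x batch fraction retaining complete/nearly
#'   complete), and `overall_consistency` (pooled over ordered batch pairs).
#' @export
cross_batch_consistency <- function(results_by_batch) {
  if (length(results_by_batch) < 2) stop("need at least 2 batches")
  res <- lapply(results_by_batch, function(x) {
    if (inherits(x, "linearity_table")) x$results else x
  })
  batches <- names(res)
  if (is.null(batches)) batches <- paste0("batch", seq_along(res))
  n <- length(res)
  ids <- lapply(res, function(r) r$peptide_id)
  any_shared <- any(vapply(utils::combn(n, 2, simplify = FALSE), function(p) {
    length(intersect(ids[[p[1]]], ids[[p[2]]])) > 0
  }, logical(1)))
  if (!any_shared) warning("no peptides shared between batches")
  good <- lapply(res, function(r) {
    r$peptide_id[r$category %in% c("complete", "nearly_complete")]
  })
  overlap <- matrix(0L, n, n, dimnames = list(batches, batches))
  consistency <- matrix(NA_real_, n, n, dimnames = list(batches, batches))
  kept <- 0L; eligible <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    overlap[i, j] <- length(intersect(ids[[i]], ids[[j]]))
    if (i == j) next
    shared_good <- intersect(good[[i]], ids[[j]])
    if (length(shared_good) > 0) {
      consistency[i, j] <- length(intersect(shared_good, good[[j]])) /
        length(shared_good)
      kept <- kept + length(intersect(shared_good, good[[j]]))
      eligible <- eligible + length(shared_good)
    }
  }
  list(overlap = overlap, consistency = consistency,
       overall_consistency = if (eligible > 0) kept / eligible else NA_real_,
       n_eligible = eligible)
}
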