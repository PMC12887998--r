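#' @title Linear-range gating and intensity calibration
#' @description Once a peptide's linear calibration range is established,
#'   each endogenous sample-channel intensity can be (a) checked for lying
#'   within that range and (b) converted to a loaded-amount equivalent by
#'   inverting the peptide's regression line.
#' @name range_calibration
NULL

#' Assess whether an intensity lies within a peptide's linear range
#'
#' @param intensity observed reporter intensity (a nonpositive or missing
#'   value is assessed as out of range below the curve, not an error).
#' @param result a `linearity_result` (from [count_linear_points()]) or a
#'   single row of a `linearity_table`'s `$results`.
#' @param mode `"intensity-bounds"` (default): within range iff the
#'   log-intensity falls inside the closed interval spanned by the retained
#'   calibration points' log-intensities. `"amount-bounds"`: within range iff
#'   the back-calculated amount falls inside the retained amounts' interval.
#' @param log_base log base of the peptide's fit.
#' @param slope_floor passed to [calibrate_intensity()].
#' @return List with `within_range`, `margin_log` (signed distance to the
#'   nearest range boundary in log units; positive = inside) and
#'   `calibrated_amount_ug` (`NA` when no usable fit or calibration refused).
#'   Nonlinear/unquantifiable peptides are always out of range.
#' @export
assess_range <- function(intensity, result,
                         mode = c("intensity-bounds", "amount-bounds"),
                         log_base = 10, slope_floor = 0.1) {
  mode <- match.arg(mode)
  if (inherits(result, "linearity_result")) {
    category <- result$category
    fit <- result$final_fit
    slope <- if (is.null(fit)) NA_real_ else fit$slope
    intercept <- if (is.null(fit)) NA_real_ else fit$intercept
    log_base <- result$log_base
    lo_li <- if (length(result$retained_log_intensity))
      min(result$retained_log_intensity) else NA_real_
    hi_li <- if (length(result$retained_log_intensity))
      max(result$retained_log_intensity) else NA_real_
    lo_a <- if (length(result$retained_amounts))
      min(result$retained_amounts) else NA_real_
    hi_a <- if (length(result$retained_amounts))
      max(result$retained_amounts) else NA_real_
  } else {
    category <- result$category
    slope <- result$slope
    intercept <- result$intercept
    lo_li <- result$min_retained_log_intensity
    hi_li <- result$max_retained_log_intensity
    lo_a <- result$min_retained_amount
    hi_a <- result$max_retained_amount
  }

  out <- list(within_range = FALSE, margin_log = NA_real_,
              calibrated_amount_ug = NA_real_)
  if (!category %in% c("complete", "nearly_complete", "partial")) return(out)

  out$calibrated_amount_ug <- calibrate_intensity(
    intensity, slope = slope, intercept = intercept,
    log_base = log_base, slope_floor = slope_floor)

  if (is.na(intensity) || intensity <= 0) {
    # no signal: below any positive range
    out$margin_log <- -Inf
    return(out)
  }
  li <- log(intensity, log_base)
  if (mode == "intensity-bounds") {
    lo <- min(lo_li, hi_li); hi <- max(lo_li, hi_li)
    out$margin_log <- min(li - lo, hi - li)
  } else {
    amt <- (li - intercept) / slope
    lo <- log(lo_a, log_base); hi <- log(hi_a, log_base)
    out$margin_log <- min(amt - lo, hi - amt)
  }
  out$within_range <- out$margin_log >= 0
  out
}

#' Calibrate an intensity to a loaded-amount equivalent
#'
#' Inverts a peptide's calibration line: `amount = base^((log(intensity) -
#' intercept) / slope)`. Near-flat fits amplify intensity noise enormously
#' when inverted, so calibration is refused (returns `NA`) when `|slope|`
#' falls below `slope_floor`.
#'
#' @param intensity positive reporter intensity (vectorised).
#' @param slope,intercept calibration-line coefficients on the log/log scale.
#' @param log_base base of the logs used to fit the line.
#' @param slope_floor minimum usable `|slope|`, default 0.1.
#' @return Calibrated amount in micrograms (`NA` where refused or the
#'   intensity is nonpositive/missing).
#' @export
calibrate_intensity <- function(intensity, slope, intercept, log_base = 10,
                                slope_floor = 0.1) {
  if (is.na(slope) || abs(slope) < slope_floor) {
    return(rep(NA_real_, length(intensity)))
  }
  ok <- !is.na(intensity) & intensity > 0
  out <- rep(NA_real_, length(intensity))
  out[ok] <- log_base^((log(intensity[ok], log_base) - intercept) / slope)
  out
}

#' Assess every sample-channel intensity of a table against linear ranges
#'
#' @param table a [peptide_quant_table].
#' @param linearity a `linearity_table` from [classify_table()] on the same
#'   table.
#' @param mode,slope_floor passed to [assess_range()].
#' @param channels channel labels to assess (default: the biological sample
#'   channels).
#' @return Long data.frame: `peptide_id`, `batch_id`, `channel`, `intensity`,
#'   `within_range`, `margin_log`, `calibrated_amount_ug`.
#' @export
assess_table <- function(table, linearity,
                         mode = c("intensity-bounds", "amount-bounds"),
                         slope_floor = 0.1, channels = NULL) {
  mode <- match.arg(mode)
  res <- linearity$results
  log_base <- linearity$summary$log_base
  if (is.null(channels)) channels <- sample_channels(table$design)
  d <- table$data
  key_t <- paste(d$peptide_id, d$batch_id, sep = "\r")
  key_r <- paste(res$peptide_id, res$batch_id, sep = "\r")
  idx <- match(key_t, key_r)
  if (anyNA(idx)) stop("linearity results do not cover every table record")

  r <- res[idx, , drop = FALSE]
  has_fit <- r$category %in% c("complete", "nearly_complete", "partial")
  usable_slope <- has_fit & !is.na(r$slope) & abs(r$slope) >= slope_floor

  out <- vector("list", length(channels))
  for (c_i in seq_along(channels)) {
    ch <- channels[c_i]
    I <- d[[ch]]
    pos <- !is.na(I) & I > 0
    li <- rep(NA_real_, length(I))
    li[pos] <- log(I[pos], log_base)

    cal <- rep(NA_real_, length(I))
    k <- pos & usable_slope
    cal[k] <- log_base^((li[k] - r$intercept[k]) / r$slope[k])

    margin <- rep(NA_real_, length(I))
    if (mode == "intensity-bounds") {
      margin[has_fit] <- pmin(
        li[has_fit] - r$min_retained_log_intensity[has_fit],
        r$max_retained_log_intensity[has_fit] - li[has_fit])
    } else {
      amt <- (li - r$intercept) / r$slope
      margin[has_fit] <- pmin(
        amt[has_fit] - log(r$min_retained_amount[has_fit], log_base),
        log(r$max_retained_amount[has_fit], log_base) - amt[has_fit])
    }
    margin[has_fit & !pos] <- -Inf  # no signal: below any positive range
    within <- has_fit & pos & !is.na(margin) & margin >= 0

    out[[c_i]] <- data.frame(
      peptide_id = d$peptide_id, batch_id = d$batch_id, channel = ch,
      intensity = I, within_range = within, margin_log = margin,
      calibrated_amount_ug = cal, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
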