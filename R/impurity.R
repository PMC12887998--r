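#' @title Reporter-ion isotopic impurity correction
#' @description Each TMT reagent carries isotopologue impurities (-2/-1/+1/+2
#'   Da) that deposit a fraction of its signal into neighbouring reporter
#'   channels. Correction solves the resulting linear mixing model for the
#'   true per-channel signal.
#' @name impurity
NULL

# TMT-11 reporter channels in mass order. A +/-1 Da isotopologue lands two
# positions away in this interleaved N/C list (126 behaves as the C line:
# 126 +1 Da -> 127C); +/-2 Da lands four positions away. Spills addressed to
# positions outside the plex are lost signal, not redistributed.
TMT11_CHANNELS <- c("126", "127N", "127C", "128N", "128C", "129N", "129C",
                    "130N", "130C", "131N", "131C")
TMT11_POSITION_STEP <- 2L

#' Read an isotopic impurity specification
#'
#' Delimited text matching the vendor certificate-of-analysis layout:
#' columns `channel`, `minus2`, `minus1`, `plus1`, `plus2` holding the
#' percentage of each reagent's signal appearing -2/-1/+1/+2 Da away.
#'
#' @param path path to the TSV/CSV specification.
#' @return data.frame with those five columns.
#' @export
read_impurity_spec <- function(path) {
  if (!file.exists(path)) stop("impurity spec not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  spec <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("channel", "minus2", "minus1", "plus1", "plus2")
  miss <- setdiff(need, names(spec))
  if (length(miss)) stop("impurity spec missing column(s): ",
                         paste(miss, collapse = ", "))
  spec$channel <- as.character(spec$channel)
  spec
}

#' Build the channel mixing matrix from an impurity specification
#'
#' Entry `(i, j)` of the matrix is the fraction of reagent `j`'s signal
#' observed in channel `i`. The diagonal is `1 - (sum of all declared spill
#' percentages)/100` — spills addressed outside the channel set are lost, not
#' folded back. Off-diagonals follow reporter mass adjacency: for TMT-11
#' labels a +/-1 Da spill moves two positions in the interleaved N/C channel
#' order; for any other label set the given channel order is treated as
#' consecutive 1 Da positions.
#'
#' @param spec data.frame as returned by [read_impurity_spec()]; percentages.
#' @param design a [channel_design]; its channel set defines the matrix.
#' @return An `impurity_matrix`: square numeric matrix with channel labels as
#'   dimnames.
#' @export
build_impurity_matrix <- function(spec, design) {
  channels <- design$channel
  need <- c("channel", "minus2", "minus1", "plus1", "plus2")
  miss <- setdiff(need, names(spec))
  if (length(miss)) stop("impurity spec missing column(s): ",
                         paste(miss, collapse = ", "))
  spec <- spec[spec$channel %in% channels, , drop = FALSE]
  pct <- as.matrix(spec[, c("minus2", "minus1", "plus1", "plus2")])
  if (any(pct < 0, na.rm = TRUE)) stop("impurity percentages must be nonnegative")
  pct[is.na(pct)] <- 0
  totals <- rowSums(pct)
  if (any(totals >= 50)) {
    stop("impurity spill of >= 50% declared for channel(s): ",
         paste(spec$channel[totals >= 50], collapse = ", "))
  }

  if (all(channels %in% TMT11_CHANNELS)) {
    position <- match(channels, TMT11_CHANNELS)
    step <- TMT11_POSITION_STEP
  } else {
    position <- seq_along(channels)
    step <- 1L
  }
  names(position) <- channels

  M <- diag(1, length(channels))
  dimnames(M) <- list(channels, channels)
  offsets <- c(minus2 = -2L, minus1 = -1L, plus1 = 1L, plus2 = 2L)
  for (k in seq_len(nrow(spec))) {
    ch <- spec$channel[k]
    j <- match(ch, channels)
    M[j, j] <- 1 - totals[k] / 100
    for (o in names(offsets)) {
      frac <- spec[[o]][k] / 100
      if (is.na(frac) || frac == 0) next
      target_pos <- position[ch] + offsets[o] * step
      i <- match(target_pos, position)
      if (!is.na(i)) M[i, j] <- M[i, j] + frac
    }
  }
  class(M) <- c("impurity_matrix", class(M))
  M
}

#' Correct observed reporter intensities for isotopic impurities
#'
#' Solves `observed = M %*% true` for the true channel signals. The default
#' solver is nonnegative least squares, which cannot produce the negative
#' intensities plain inversion yields at low signal; `"inverse-clip"` inverts
#' the matrix and clips negative components to zero.
#'
#' @param intensities numeric vector of observed intensities named by (or
#'   ordered as) the matrix channels; missing channels are treated as zero
#'   for the solve and restored to missing afterwards.
#' @param M an `impurity_matrix` from [build_impurity_matrix()].
#' @param solver `"nnls"` (default) or `"inverse-clip"`.
#' @return Numeric vector of corrected intensities, same names/order,
#'   missingness preserved. Under `"inverse-clip"`, clipped components are
#'   flagged in `attr(, "clipped")`.
#' @export
correct_intensities <- function(intensities, M,
                                solver = c("nnls", "inverse-clip")) {
  solver <- match.arg(solver)
  channels <- colnames(M)
  if (!is.null(names(intensities))) {
    intensities <- intensities[channels]
  } else if (length(intensities) != ncol(M)) {
    stop("intensity vector length does not match the impurity matrix")
  }
  y <- as.numeric(intensities)
  was_missing <- is.na(y)
  y[was_missing] <- 0

  if (qr(unclass(M))$rank < ncol(M)) stop("impurity matrix is singular")

  if (solver == "nnls") {
    x <- pracma::lsqnonneg(unclass(M), y)$x
    clipped <- rep(FALSE, length(x))
  } else {
    x <- solve(unclass(M), y)
    clipped <- x < 0
    x[clipped] <- 0
  }
  x[was_missing] <- NA_real_
  names(x) <- channels
  if (solver == "inverse-clip") attr(x, "clipped") <- clipped & !was_missing
  x
}

#' Apply impurity correction to every record of a quantification table
#'
#' @param table a [peptide_quant_table].
#' @param M an `impurity_matrix` covering the design's channels.
#' @param solver passed to [correct_intensities()].
#' @return A [peptide_quant_table] with corrected intensities.
#' @export
correct_table <- function(table, M, solver = c("nnls", "inverse-clip")) {
  solver <- match.arg(solver)
  channels <- colnames(M)
  stopifnot(setequal(channels, table$design$channel))
  obs <- intensity_matrix(table, channels)
  corrected <- t(apply(obs, 1, function(row) {
    as.numeric(correct_intensities(row, M, solver = solver))
  }))
  d <- table$data
  d[, channels] <- corrected
  peptide_quant_table(d, table$design,
                      provenance = c(table$provenance,
                                     list(impurity_solver = solver)),
                      dropped = table$dropped)
}
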