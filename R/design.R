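#' Construct a TMT channel design
#'
#' A channel design maps every TMT reporter channel of a multiplexed
#' experiment to its role: a biological sample (with condition and
#' replicate) or a point of the internal multipoint calibration curve
#' (with the amount of pooled digest loaded, in micrograms).
#'
#' @param channels data.frame with columns `channel` (character label, e.g.
#'   `"126"`, `"127N"`), `role` (`"sample"` or `"calibration"`),
#'   `condition` (character, samples only), `replicate` (integer, samples
#'   only) and `amount_ug` (positive numeric, micrograms loaded).
#' @param reference_amount_ug the 1:1 loading amount in micrograms, i.e. the
#'   amount loaded for every biological sample channel.
#'
#' @return An object of class `channel_design`: the validated data.frame with
#'   calibration channels sorted by amount, carrying
#'   `attr(, "reference_amount_ug")`.
#' @export
channel_design <- function(channels, reference_amount_ug) {
  required <- c("channel", "role", "condition", "replicate", "amount_ug")
  missing_cols <- setdiff(required, names(channels))
  if (length(missing_cols) > 0) {
    stop("design is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  channels$channel <- as.character(channels$channel)
  channels$role <- as.character(channels$role)
  channels$amount_ug <- as.numeric(channels$amount_ug)

  if (anyDuplicated(channels$channel)) {
    dup <- unique(channels$channel[duplicated(channels$channel)])
    stop("duplicate channel label(s): ", paste(dup, collapse = ", "))
  }
  if (!all(channels$role %in% c("sample", "calibration"))) {
    stop("role must be 'sample' or 'calibration'")
  }
  if (any(!is.finite(channels$amount_ug) | channels$amount_ug <= 0)) {
    stop("every channel needs a positive amount_ug")
  }
  cal <- channels[channels$role == "calibration", , drop = FALSE]
  if (nrow(cal) < 3) {
    stop("insufficient calibration points: at least 3 calibration channels ",
         "are required for linearity analysis (got ", nrow(cal), ")")
  }
  if (anyDuplicated(cal$amount_ug)) {
    stop("calibration channels must have distinct amounts")
  }
  if (!is.numeric(reference_amount_ug) || length(reference_amount_ug) != 1 ||
      !is.finite(reference_amount_ug) || reference_amount_ug <= 0) {
    stop("reference_amount_ug must be a single positive number")
  }
  smp <- channels[channels$role == "sample", , drop = FALSE]
  if (nrow(smp) > 0 && any(smp$amount_ug != reference_amount_ug)) {
    stop("sample channels must be loaded at reference_amount_ug (",
         reference_amount_ug, " ug)")
  }

  # samples first (input order), then calibration sorted by amount ascending
  out <- rbind(smp, cal[order(cal$amount_ug), , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "reference_amount_ug") <- reference_amount_ug
  class(out) <- c("channel_design", "data.frame")
  out
}

#' Read a channel design from a YAML config file
#'
#' The file declares the reference (1:1) amount and one entry per channel:
#' ```yaml
#' reference_amount_ug: 25
#' channels:
#'   - {channel: "126",  role: sample, condition: untreated, replicate: 1, amount_ug: 25}
#'   - {channel: "129C", role: calibration, amount_ug: 0.25}
#' ```
#'
#' @param path path to the YAML design file.
#' @return A [channel_design] object.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  spec <- yaml::read_yaml(path)
  if (is.null(spec$channels)) stop("design file has no 'channels' section")
  rows <- lapply(spec$channels, function(ch) {
    data.frame(
      channel = as.character(ch$channel),
      role = as.character(ch$role),
      condition = if (is.null(ch$condition)) NA_character_ else as.character(ch$condition),
      replicate = if (is.null(ch$replicate)) NA_integer_ else as.integer(ch$replicate),
      amount_ug = as.numeric(ch$amount_ug),
      stringsAsFactors = FALSE
    )
  })
  channel_design(do.call(rbind, rows), spec$reference_amount_ug)
}

#' The canonical TMT-11 dilution-series design
#'
#' Six biological sample channels (two conditions in triplicate, 25 ug each)
#' plus a five-point serial dilution of the pooled digest at 0.25, 1.25,
#' 6.25, 25 and 125 ug occupying the last five channels.
#'
#' @param conditions length-2 character vector of condition names, in the
#'   order (untreated, treated).
#' @return A [channel_design] object.
#' @export
tmt11_calibration_design <- function(conditions = c("untreated", "treated")) {
  stopifnot(length(conditions) == 2)
  channels <- data.frame(
    channel = c("126", "127N", "127C", "128N", "128C", "129N",
                "129C", "130N", "130C", "131N", "131C"),
    role = c(rep("sample", 6), rep("calibration", 5)),
    condition = c(rep(conditions[1], 3), rep(conditions[2], 3), rep(NA, 5)),
    replicate = c(1:3, 1:3, rep(NA, 5)),
    amount_ug = c(rep(25, 6), 0.25, 1.25, 6.25, 25, 125),
    stringsAsFactors = FALSE
  )
  channel_design(channels, reference_amount_ug = 25)
}

#' @export
print.channel_design <- function(x, ...) {
  cat("TMT channel design: ", sum(x$role == "sample"), " sample + ",
      sum(x$role == "calibration"), " calibration channels; reference ",
      attr(x, "reference_amount_ug"), " ug\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Channel labels by role
#'
#' @param design a [channel_design].
#' @return Character vector of channel labels. Calibration channels come back
#'   sorted by loaded amount ascending.
#' @export
calibration_channels <- function(design) {
  design$channel[design$role == "calibration"]
}

#' @rdname calibration_channels
#' @param condition optional condition name to restrict sample channels to.
#' @export
sample_channels <- function(design, condition = NULL) {
  keep <- design$role == "sample"
  if (!is.null(condition)) keep <- keep & design$condition %in% condition
  design$channel[keep]
}

#' Amounts (ug) loaded on the calibration channels, ascending
#' @param design a [channel_design].
#' @export
calibration_amounts <- function(design) {
  a <- design$amount_ug[design$role == "calibration"]
  stats::setNames(a, calibration_channels(design))
}

#' Reference (1:1) amount of a design, in micrograms
#' @param design a [channel_design].
#' @export
reference_amount <- function(design) attr(design, "reference_amount_ug")

#' The calibration channel loaded at the reference amount, if any
#' @param design a [channel_design].
#' @return A channel label, or `NA` if no calibration point sits at the
#'   reference amount.
#' @export
reference_channel <- function(design) {
  amounts <- calibration_amounts(design)
  hit <- which(amounts == reference_amount(design))
  if (length(hit) == 0) NA_character_ else names(amounts)[hit[1]]
}
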