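#' @title Peptide quantification tables
#' @description Internal container tying a per-peptide (or per-PSM) reporter
#'   intensity table to the channel design it was acquired under.
#' @name peptide_quant_table
NULL

PD_EXCLUDE_FLAGS <- c("NoQuanLabels", "NoQuanValues", "ExcludedByMethod")

#' Construct a peptide quantification table
#'
#' @param data data.frame with columns `peptide_id`, `protein_accession`,
#'   `batch_id`, `quant_flag` and one numeric intensity column per channel of
#'   `design` (named by channel label). Missing intensities are `NA`; zero is
#'   a measurement only if the reader was told to keep it.
#' @param design the [channel_design] the intensities were acquired under.
#' @param provenance list of free-form provenance entries (source files,
#'   reader options).
#' @param dropped named integer vector counting records removed per
#'   quantification flag, if the table came through [read_quant_table()].
#' @return An object of class `peptide_quant_table`.
#' @export
peptide_quant_table <- function(data, design, provenance = list(),
                                dropped = integer(0)) {
  stopifnot(inherits(design, "channel_design"))
  meta <- c("peptide_id", "protein_accession", "batch_id", "quant_flag")
  miss <- setdiff(meta, names(data))
  if (length(miss)) stop("quant table is missing columns: ",
                         paste(miss, collapse = ", "))
  miss_ch <- setdiff(design$channel, names(data))
  if (length(miss_ch)) stop("no intensity column for design channel(s): ",
                            paste(miss_ch, collapse = ", "))
  data <- data[, c(meta, design$channel), drop = FALSE]
  for (ch in design$channel) {
    v <- data[[ch]]
    if (!is.numeric(v)) stop("intensity column '", ch, "' is not numeric")
    if (any(v < 0, na.rm = TRUE)) stop("negative intensity in channel ", ch)
  }
  rownames(data) <- NULL
  structure(list(data = data, design = design, provenance = provenance,
                 dropped = dropped),
            class = "peptide_quant_table")
}

#' @export
print.peptide_quant_table <- function(x, ...) {
  cat("peptide_quant_table: ", nrow(x$data), " records, ",
      length(unique(x$data$peptide_id)), " peptides, ",
      length(unique(x$data$batch_id)), " batch(es), ",
      nrow(x$design), " channels\n", sep = "")
  if (length(x$dropped)) {
    cat("dropped on read:",
        paste(names(x$dropped), x$dropped, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Reporter intensities as a numeric matrix
#'
#' @param table a [peptide_quant_table].
#' @param channels channel labels to extract (default: all design channels).
#' @return Numeric matrix, one row per record, one column per channel.
#' @export
intensity_matrix <- function(table, channels = NULL) {
  if (is.null(channels)) channels <- table$design$channel
  as.matrix(table$data[, channels, drop = FALSE])
}

parse_intensity_column <- function(x, column, zero_as_missing) {
  if (is.numeric(x)) {
    v <- as.numeric(x)
  } else {
    x <- trimws(as.character(x))
    x[x == ""] <- NA_character_
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad)) {
      stop("unparseable numeric cell in column '", column, "' at row ",
           bad[1], ": '", x[bad[1]], "'")
    }
  }
  if (zero_as_missing) v[!is.na(v) & v == 0] <- NA_real_
  v
}

# map a Proteome Discoverer abundance header onto a channel label:
# the label must appear as a standalone token ("Abundance: F1: 126, Sample")
pd_abundance_column <- function(headers, channel) {
  cand <- grepl("Abundance", headers, ignore.case = TRUE)
  tokens <- strsplit(headers, "[^0-9A-Za-z]+")
  hit <- cand & vapply(tokens, function(tk) channel %in% tk, logical(1))
  idx <- which(hit)
  if (length(idx) == 0) return(NA_integer_)
  if (length(idx) > 1) stop("ambiguous abundance column for channel ", channel)
  idx
}

#' Read a peptide/PSM quantification table
#'
#' Reads a delimited text export into the internal model, drops records whose
#' quantification flag marks them as unquantified (`"NoQuanLabels"`,
#' `"NoQuanValues"`, `"ExcludedByMethod"`) while counting them, and preserves
#' empty cells as missing values.
#'
#' @param path delimited text file (tab- or comma-separated; `.csv` implies
#'   comma).
#' @param design the [channel_design] naming the expected channels.
#' @param dialect `"generic-tsv"` expects columns `peptide_id`,
#'   `protein_accession`, optional `quant_flag`/`batch_id`, and one column per
#'   channel named by its label. `"proteome-discoverer-export"` expects
#'   `Annotated Sequence`, `Master Protein Accessions`, `Quan Info` and
#'   `Abundance: ...<label>...` columns.
#' @param batch_id batch identifier for the records; defaults to the file name
#'   without extension (one file per TMT mix).
#' @param zero_as_missing treat zero intensities as missing (default `TRUE`):
#'   downstream log-transformation is undefined at zero and an absent
#'   low-dilution signal is a missing point, not a measured zero.
#' @return A [peptide_quant_table]; `$dropped` counts removed records per flag.
#' @export
read_quant_table <- function(path, design,
                             dialect = c("generic-tsv",
                                         "proteome-discoverer-export"),
                             batch_id = NULL, zero_as_missing = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("quant table not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "", colClasses = "character")
  if (is.null(batch_id)) {
    batch_id <- sub("\\.[^.]*$", "", basename(path))
  }

  if (dialect == "generic-tsv") {
    need <- c("peptide_id", "protein_accession")
    miss <- setdiff(need, names(raw))
    if (length(miss)) stop("missing required column(s): ",
                           paste(miss, collapse = ", "))
    out <- data.frame(
      peptide_id = raw$peptide_id,
      protein_accession = raw$protein_accession,
      batch_id = if ("batch_id" %in% names(raw)) raw$batch_id else batch_id,
      quant_flag = if ("quant_flag" %in% names(raw)) raw$quant_flag else "",
      stringsAsFactors = FALSE, check.names = FALSE
    )
    for (ch in design$channel) {
      if (!ch %in% names(raw)) stop("channel column not found: ", ch)
      out[[ch]] <- parse_intensity_column(raw[[ch]], ch, zero_as_missing)
    }
  } else {
    col_seq <- grep("^Annotated Sequence$", names(raw), ignore.case = TRUE)
    col_prot <- grep("^Master Protein Accessions$", names(raw),
                     ignore.case = TRUE)
    if (!length(col_seq) || !length(col_prot)) {
      stop("missing required column(s): 'Annotated Sequence' and/or ",
           "'Master Protein Accessions'")
    }
    col_flag <- grep("^Quan Info$", names(raw), ignore.case = TRUE)
    out <- data.frame(
      peptide_id = raw[[col_seq[1]]],
      protein_accession = raw[[col_prot[1]]],
      batch_id = batch_id,
      quant_flag = if (length(col_flag)) raw[[col_flag[1]]] else "",
      stringsAsFactors = FALSE, check.names = FALSE
    )
    for (ch in design$channel) {
      idx <- pd_abundance_column(names(raw), ch)
      if (is.na(idx)) stop("channel column not found: ", ch)
      out[[ch]] <- parse_intensity_column(raw[[idx]], names(raw)[idx],
                                          zero_as_missing)
    }
  }

  out$quant_flag[is.na(out$quant_flag)] <- ""
  excluded <- out$quant_flag %in% PD_EXCLUDE_FLAGS
  dropped <- table(factor(out$quant_flag[excluded], levels = PD_EXCLUDE_FLAGS))
  dropped <- stats::setNames(as.integer(dropped), names(dropped))
  out <- out[!excluded, , drop = FALSE]

  peptide_quant_table(
    out, design,
    provenance = list(source = path, dialect = dialect,
                      zero_as_missing = zero_as_missing),
    dropped = dropped[dropped > 0]
  )
}

#' Write a quantification table in the generic TSV dialect
#'
#' Intensities are written with 17 significant digits so that a write/read
#' round trip reproduces them bit-identically; missing values become empty
#' cells.
#'
#' @param table a [peptide_quant_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(table, path) {
  d <- table$data
  out <- d[, c("peptide_id", "protein_accession", "batch_id", "quant_flag"),
           drop = FALSE]
  for (ch in table$design$channel) {
    v <- d[[ch]]
    s <- sprintf("%.17g", v)
    s[is.na(v)] <- ""
    out[[ch]] <- s
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate PSM-level rows to one record per peptide
#'
#' @param table a [peptide_quant_table] possibly holding several rows
#'   (peptide-spectrum matches) per `(peptide_id, batch_id)`.
#' @param method `"sum"` adds non-missing intensities per channel;
#'   `"max-intensity-psm"` keeps the single row with the largest total
#'   intensity across channels.
#' @return A [peptide_quant_table] with one record per `(peptide_id,
#'   batch_id)`. A channel is missing only if it was missing in every
#'   contributing row.
#' @export
aggregate_psms <- function(table, method = c("sum", "max-intensity-psm")) {
  method <- match.arg(method)
  d <- table$data
  channels <- table$design$channel
  key <- interaction(d$peptide_id, d$batch_id, drop = TRUE, sep = "\r")
  groups <- split(seq_len(nrow(d)), key)
  rows <- lapply(groups, function(idx) {
    block <- d[idx, , drop = FALSE]
    first <- block[1, c("peptide_id", "protein_accession", "batch_id",
                        "quant_flag"), drop = FALSE]
    m <- as.matrix(block[, channels, drop = FALSE])
    if (method == "sum") {
      agg <- apply(m, 2, function(col) {
        if (all(is.na(col))) NA_real_ else sum(col, na.rm = TRUE)
      })
    } else {
      totals <- rowSums(m, na.rm = TRUE)
      agg <- m[which.max(totals), ]
    }
    cbind(first, as.data.frame(as.list(agg), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  peptide_quant_table(out, table$design,
                      provenance = c(table$provenance,
                                     list(psm_aggregation = method)),
                      dropped = table$dropped)
}
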