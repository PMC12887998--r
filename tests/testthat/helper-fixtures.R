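# Plain-text fixtures are built in code at test time.

write_design_yaml <- function(path = tempfile(fileext = ".yaml")) {
  d <- tmt11_calibration_design()
  lines <- c("reference_amount_ug: 25", "channels:")
  for (i in seq_len(nrow(d))) {
    extra <- if (d$role[i] == "sample") {
      sprintf(", condition: %s, replicate: %d", d$condition[i], d$replicate[i])
    } else ""
    lines <- c(lines, sprintf(
      "  - {channel: \"%s\", role: %s, amount_ug: %s%s}",
      d$channel[i], d$role[i], format(d$amount_ug[i]), extra))
  }
  writeLines(lines, path)
  path
}

# a small generic-tsv quant fixture with controllable flags and blanks
write_generic_quant <- function(path = tempfile(fileext = ".tsv"),
                                design = tmt11_calibration_design(),
                                n = 10, flags = NULL, blank_cells = NULL) {
  set.seed(99)
  header <- c("peptide_id", "protein_accession", "quant_flag",
              design$channel)
  rows <- lapply(seq_len(n), function(i) {
    ints <- sprintf("%.6g", stats::runif(nrow(design), 100, 10000))
    if (!is.null(blank_cells) && i %in% blank_cells$row) {
      ints[blank_cells$col[blank_cells$row == i]] <- ""
    }
    flag <- if (!is.null(flags) && !is.na(flags[i])) flags[i] else ""
    c(sprintf("pep%02d", i), sprintf("prot%02d", (i - 1) %/% 2 + 1),
      flag, ints)
  })
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, "", collapse = "\t")), path)
  path
}

write_pd_quant <- function(path = tempfile(fileext = ".csv"),
                           design = tmt11_calibration_design(), n = 5,
                           flags = NULL) {
  set.seed(42)
  ab_cols <- sprintf("Abundance: F1: %s, Sample", design$channel)
  header <- c("Annotated Sequence", "Master Protein Accessions",
              "Quan Info", ab_cols)
  rows <- lapply(seq_len(n), function(i) {
    flag <- if (!is.null(flags) && !is.na(flags[i])) flags[i] else ""
    c(sprintf("[K].PEPTIDE%dR.[S]", i), sprintf("P%05d", i), flag,
      sprintf("%.5g", stats::runif(nrow(design), 50, 5000)))
  })
  txt <- c(paste(sprintf("\"%s\"", header), collapse = ","),
           vapply(rows, function(r)
             paste(sprintf("\"%s\"", r), collapse = ","), ""))
  writeLines(txt, path)
  path
}

write_impurity_tsv <- function(spec, path = tempfile(fileext = ".tsv")) {
  utils::write.table(spec, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# the vendor-style impurity layout used across impurity tests
tmt11_impurity_spec <- function() {
  data.frame(
    channel = c("126", "127N", "127C", "128N", "128C", "129N", "129C",
                "130N", "130C", "131N", "131C"),
    minus2 = c(0, 0, 0, 0, 0.3, 0.2, 0.4, 0.3, 0.5, 0.2, 0.3),
    minus1 = c(0, 0.4, 0.5, 1.1, 1.2, 2.0, 1.6, 2.3, 2.5, 3.1, 3.4),
    plus1  = c(6.9, 6.5, 6.3, 5.4, 5.1, 4.6, 4.2, 3.8, 3.2, 2.8, 2.4),
    plus2  = c(0.2, 0, 0.3, 0.2, 0.1, 0.3, 0.2, 0.1, 0.2, 0, 0.1),
    stringsAsFactors = FALSE
  )
}

# peptide table built directly from a matrix of calibration intensities
table_from_cal_matrix <- function(cal, design = tmt11_calibration_design(),
                                  sample_value = 5000,
                                  protein = NULL, batch_id = "b1") {
  n <- nrow(cal)
  smp <- sample_channels(design)
  d <- data.frame(peptide_id = sprintf("pep%03d", seq_len(n)),
                  protein_accession = if (is.null(protein))
                    sprintf("prot%03d", seq_len(n)) else protein,
                  batch_id = batch_id, quant_flag = "",
                  stringsAsFactors = FALSE, check.names = FALSE)
  for (ch in smp) d[[ch]] <- rep(sample_value, n)
  cal_ch <- calibration_channels(design)
  for (j in seq_along(cal_ch)) d[[cal_ch[j]]] <- cal[, j]
  peptide_quant_table(d, design)
}

# intensities of a perfect log-linear peptide (slope 1) at the design amounts
perfect_cal_intensities <- function(coef, design = tmt11_calibration_design()) {
  coef * unname(calibration_amounts(design))
}
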