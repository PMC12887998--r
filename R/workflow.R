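#' @title Workflow orchestration
#' @description End-to-end runners tying the modules together: read (or
#'   simulate) a quantification table, correct impurities, classify
#'   linearity, assess ranges, quantify proteins under both peptide
#'   selections, and run the background-noise study. Every output file
#'   carries the tool version, a configuration hash and the seed, so reruns
#'   on identical inputs are byte-identical.
#' @name cli_report
NULL

#' Assemble a run configuration
#'
#' @param quant_paths character vector of quantification-table files, one
#'   per TMT batch.
#' @param design_path path to a YAML design file (alternative to `design`).
#' @param design a [channel_design] given directly.
#' @param impurity_path optional isotopic impurity spec; correction is
#'   skipped (and logged) when absent.
#' @param dialect input dialect, see [read_quant_table()].
#' @param aggregate PSM aggregation method, see [aggregate_psms()], or
#'   `"none"`.
#' @param log_base,r_squared_threshold,use_sample_mean classifier settings.
#' @param min_category,range_mode,range_rule,calibrated quantification
#'   settings.
#' @param offsets background offsets for the noise study.
#' @param sim optional [sim_config()]; when given, input is simulated
#'   instead of read from `quant_paths`.
#' @param seed integer seed; mandatory for any stochastic run (simulation).
#' @param out_dir output directory (created if needed).
#' @return A validated `run_config` list.
#' @export
run_config <- function(quant_paths = NULL, design_path = NULL, design = NULL,
                       impurity_path = NULL,
                       dialect = "generic-tsv", aggregate = "none",
                       log_base = 10, r_squared_threshold = 0.95,
                       use_sample_mean = FALSE,
                       min_category = "nearly_complete",
                       range_mode = "intensity-bounds", range_rule = "all",
                       calibrated = FALSE, offsets = c(20, 50, 200),
                       sim = NULL, seed = NULL, out_dir = ".") {
  if (r_squared_threshold <= 0 || r_squared_threshold >= 1) {
    stop("r_squared_threshold must lie in (0, 1)")
  }
  if (is.null(design) && is.null(design_path) && is.null(sim)) {
    stop("provide a design, a design_path, or a sim config")
  }
  if (is.null(sim) && is.null(quant_paths)) {
    stop("provide quant_paths or a sim config")
  }
  if (!is.null(sim) && is.null(seed)) seed <- sim$seed
  if (!is.null(sim) && is.null(seed)) {
    stop("a stochastic run (simulation) requires an explicit seed")
  }
  structure(list(quant_paths = quant_paths, design_path = design_path,
                 design = design, impurity_path = impurity_path,
                 dialect = dialect, aggregate = aggregate,
                 log_base = log_base,
                 r_squared_threshold = r_squared_threshold,
                 use_sample_mean = use_sample_mean,
                 min_category = min_category, range_mode = range_mode,
                 range_rule = range_rule, calibrated = calibrated,
                 offsets = offsets, sim = sim, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

# hash of the analysis parameters (the output location is not one)
config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(x), tmp)
  unname(tools::md5sum(tmp))
}

output_header <- function(config) {
  c(paste0("# tmtcal ", as.character(utils::packageVersion("tmtcal"))),
    paste0("# config_hash ", config_hash(config)),
    paste0("# seed ", if (is.null(config$seed)) "NA" else config$seed))
}

write_output_tsv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_output_json <- function(x, path, config) {
  x <- c(list(tool = "tmtcal",
              version = as.character(utils::packageVersion("tmtcal")),
              config_hash = config_hash(config),
              seed = if (is.null(config$seed)) NA else config$seed), x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

log_msg <- function(...) message("[tmtcal] ", ...)

load_inputs <- function(config) {
  if (!is.null(config$sim)) {
    log_msg("simulating experiment (seed ", config$sim$seed, ")")
    sim <- simulate_experiment(config$sim)
    return(list(table = sim$table, truth = sim$truth))
  }
  design <- if (!is.null(config$design)) config$design
            else read_design(config$design_path)
  tables <- lapply(config$quant_paths, function(p) {
    tab <- read_quant_table(p, design, dialect = config$dialect)
    if (length(tab$dropped)) {
      log_msg("dropped on read (", basename(p), "): ",
              paste(names(tab$dropped), tab$dropped, sep = "=",
                    collapse = ", "))
    }
    if (config$aggregate != "none") tab <- aggregate_psms(tab, config$aggregate)
    tab
  })
  merged <- tables[[1]]
  if (length(tables) > 1) {
    d <- do.call(rbind, lapply(tables, function(t) t$data))
    merged <- peptide_quant_table(d, design,
                                  provenance = list(sources = config$quant_paths))
  }
  list(table = merged, truth = NULL)
}

apply_impurity <- function(table, config) {
  if (is.null(config$impurity_path)) {
    log_msg("no impurity spec given; isotopic impurity correction skipped")
    return(table)
  }
  spec <- read_impurity_spec(config$impurity_path)
  M <- build_impurity_matrix(spec, table$design)
  log_msg("correcting reporter intensities for isotopic impurities (nnls)")
  correct_table(table, M)
}

#' Run the linearity classification workflow
#'
#' Reads (or simulates) the input, applies optional impurity correction,
#' classifies every peptide's calibration curve, and writes
#' `linearity.tsv` plus `linearity_summary.json` to the output directory.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the `table`, the `linearity` results and
#'   the output paths.
#' @export
run_linearity <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- load_inputs(config)
  table <- apply_impurity(inputs$table, config)
  lin <- classify_table(table, threshold = config$r_squared_threshold,
                        log_base = config$log_base,
                        use_sample_mean = config$use_sample_mean)
  tsv <- file.path(config$out_dir, "linearity.tsv")
  write_output_tsv(lin$results, tsv, config)
  js <- file.path(config$out_dir, "linearity_summary.json")
  write_output_json(lin$summary, js, config)
  log_msg("classified ", lin$summary$n_records, " records; ",
          "complete or nearly complete: ",
          sprintf("%.1f%%", 100 * lin$summary$fraction_complete_or_nearly))
  invisible(list(table = table, linearity = lin, truth = inputs$truth,
                 paths = c(tsv, js)))
}

#' Run protein quantification under both peptide selections
#'
#' Extends [run_linearity()] with range assessment, protein quantification
#' under all-peptide and linear-only selection, and the discrepancy report.
#' Writes `proteins_all.tsv`, `proteins_linear_only.tsv` and
#' `discrepancies.tsv`.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with both result tables, the comparison, and
#'   output paths.
#' @export
run_quantify <- function(config) {
  base <- run_linearity(config)
  table <- base$table
  lin <- base$linearity
  assess <- assess_table(table, lin, mode = config$range_mode)
  res_all <- quantify_proteins(table, lin, assess, mode = "all",
                               min_category = config$min_category,
                               range_rule = config$range_rule,
                               calibrated = FALSE)
  res_lin <- quantify_proteins(table, lin, assess, mode = "linear_only",
                               min_category = config$min_category,
                               range_rule = config$range_rule,
                               calibrated = config$calibrated)
  cmp <- compare_selection_modes(res_all, res_lin)
  p1 <- write_output_tsv(res_all, file.path(config$out_dir, "proteins_all.tsv"),
                         config)
  p2 <- write_output_tsv(res_lin,
                         file.path(config$out_dir, "proteins_linear_only.tsv"),
                         config)
  p3 <- write_output_tsv(cmp$comparison,
                         file.path(config$out_dir, "discrepancies.tsv"),
                         config)
  log_msg(cmp$n_discrepant, " protein(s) cross the significance boundary in ",
          "one selection mode only; ", length(cmp$dropped),
          " dropped under linear-only")
  invisible(list(table = table, linearity = lin, assessments = assess,
                 all = res_all, linear_only = res_lin, comparison = cmp,
                 truth = base$truth, paths = c(base$paths, p1, p2, p3)))
}

#' Run the background-noise robustness study
#'
#' Applies each configured constant offset to the input (or simulated)
#' table, re-classifies linearity, quantifies proteins under both
#' selections, and tabulates per offset the count of peptides without
#' complete/nearly complete curves and — when ground truth is available —
#' the RMSE of protein log2 fold-changes against truth for the raw
#' all-peptide and the calibrated linear-only pipelines. Writes
#' `noise_study.tsv`.
#'
#' @param config a [run_config()]; `offsets` defines the study grid (0 is
#'   prepended as baseline if absent).
#' @return Invisibly, the study data.frame.
#' @export
run_noise_study <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- load_inputs(config)
  base_table <- apply_impurity(inputs$table, config)
  offsets <- sort(unique(c(0, config$offsets)))
  truth <- inputs$truth

  rows <- lapply(offsets, function(off) {
    tab <- if (off > 0) add_background_offset(base_table, off) else base_table
    lin <- classify_table(tab, threshold = config$r_squared_threshold,
                          log_base = config$log_base)
    assess <- assess_table(tab, lin, mode = config$range_mode)
    res_all <- quantify_proteins(tab, lin, assess, mode = "all",
                                 range_rule = config$range_rule,
                                 min_category = config$min_category)
    res_lin <- quantify_proteins(tab, lin, assess, mode = "linear_only",
                                 min_category = config$min_category,
                                 range_rule = config$range_rule,
                                 calibrated = TRUE)
    s <- lin$summary
    n_not_linear <- s$n_records -
      sum(lin$results$n_linear_points >= s$n_design_points - 1L)
    row <- data.frame(
      offset = off,
      n_records = s$n_records,
      n_not_complete_or_nearly = n_not_linear,
      n_nonlinear = s$counts[["nonlinear"]] + s$counts[["unquantifiable"]],
      n_proteins_all = nrow(res_all),
      n_proteins_linear = nrow(res_lin),
      rmse_fc_all_raw = NA_real_,
      rmse_fc_linear_calibrated = NA_real_
    )
    if (!is.null(truth)) {
      row$rmse_fc_all_raw <- fc_rmse(res_all, truth)
      row$rmse_fc_linear_calibrated <- fc_rmse(res_lin, truth)
    }
    row
  })
  study <- do.call(rbind, rows)
  write_output_tsv(study, file.path(config$out_dir, "noise_study.tsv"), config)
  invisible(study)
}

#' Root-mean-square error of estimated protein fold-changes against truth
#'
#' @param results a [differential_test()] data.frame.
#' @param truth the `truth` component of [simulate_experiment()].
#' @return RMSE of `log2_fc` over testable proteins present in both.
#' @export
fc_rmse <- function(results, truth) {
  m <- merge(results[results$testable, c("protein_accession", "log2_fc")],
             truth$proteins[, c("protein_accession", "true_log2_fc")],
             by = "protein_accession")
  if (nrow(m) == 0) return(NA_real_)
  sqrt(mean((m$log2_fc - m$true_log2_fc)^2))
}
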