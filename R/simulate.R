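#' @title Synthetic dilution-series experiments
#' @description Generates TMT quantification tables with known ground truth,
#'   emulating the structure of a pooled-digest dilution series multiplexed
#'   with biological samples: a log-linear true response per peptide,
#'   multiplicative lognormal measurement noise, an additive background
#'   floor, threshold-driven missingness (so missing points emerge at the
#'   lowest dilutions mechanistically), and spiked protein fold-changes.
#' @name synthsim
NULL

#' Simulation configuration
#'
#' @param n_proteins number of simulated proteins.
#' @param peptides_per_protein integer range `c(min, max)`; each protein
#'   draws its peptide count uniformly from it.
#' @param design a [channel_design]; default [tmt11_calibration_design()].
#' @param coef_meanlog overall location of the per-peptide response
#'   coefficient (intensity units per microgram loaded); the default puts
#'   the median at 2000 units/ug, so the lowest (0.25 ug) dilution sits near
#'   the scale of the background offsets studied (tens to hundreds of
#'   units).
#' @param coef_sdlog_protein,coef_sdlog_peptide the coefficient is
#'   hierarchical — a protein abundance factor shared by all of a protein's
#'   peptides times a per-peptide ionisation factor, both lognormal. The
#'   defaults (1.8 and 0.9) give a marginal across-peptide geometric SD of
#'   `exp(sqrt(1.8^2 + 0.9^2)) ~ exp(2)`, i.e. a roughly four-decade
#'   reporter-intensity dynamic range with most of the variance at the
#'   protein level, as in real proteomes.
#' @param cv_multiplicative coefficient of variation of the multiplicative
#'   lognormal measurement noise (default 0.1; set 0 for a noiseless run).
#' @param background_floor additive constant on the raw intensity scale
#'   applied to every channel (default 0).
#' @param detection_threshold intensities below it become missing (default
#'   0: nothing missing).
#' @param fraction_changed fraction of proteins given a true fold-change.
#' @param true_log2_fc magnitude of the spiked log2 fold-change; changed
#'   proteins get `+true_log2_fc` or `-true_log2_fc` with equal probability.
#' @param seed mandatory integer seed; every stochastic draw flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_proteins = 100, peptides_per_protein = c(2, 6),
                       design = tmt11_calibration_design(),
                       coef_meanlog = log(2000), coef_sdlog_protein = 1.8,
                       coef_sdlog_peptide = 0.9,
                       cv_multiplicative = 0.1, background_floor = 0,
                       detection_threshold = 0, fraction_changed = 0.2,
                       true_log2_fc = 1, seed) {
  if (missing(seed)) stop("a seed is mandatory for every stochastic run")
  stopifnot(n_proteins >= 1,
            length(peptides_per_protein) == 2,
            peptides_per_protein[1] >= 1,
            peptides_per_protein[2] >= peptides_per_protein[1],
            cv_multiplicative >= 0, background_floor >= 0,
            detection_threshold >= 0,
            fraction_changed >= 0, fraction_changed <= 1)
  structure(list(n_proteins = n_proteins,
                 peptides_per_protein = as.integer(peptides_per_protein),
                 design = design, coef_meanlog = coef_meanlog,
                 coef_sdlog_protein = coef_sdlog_protein,
                 coef_sdlog_peptide = coef_sdlog_peptide,
                 cv_multiplicative = cv_multiplicative,
                 background_floor = background_floor,
                 detection_threshold = detection_threshold,
                 fraction_changed = fraction_changed,
                 true_log2_fc = true_log2_fc, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a TMT dilution-series experiment
#'
#' The generative model per peptide and channel is
#' `intensity = coefficient * amount * fc_factor * lognormal(1, cv) + floor`,
#' thresholded to missing below the detection threshold. `fc_factor` is 1
#' for untreated samples, `2^lfc` for treated samples of a changed protein,
#' and `(1 + 2^lfc)/2` for the calibration-pool channels, which carry an
#' equal mixture of both conditions.
#'
#' @param config a [sim_config()].
#' @param batch_id batch identifier stamped on the records.
#' @return List with `table` (a [peptide_quant_table]) and `truth` (list of
#'   `peptides` — coefficients, pool factors, the analytically expected
#'   linear-point count under the configured floor — and `proteins` — true
#'   log2 fold-changes).
#' @export
simulate_experiment <- function(config, batch_id = "batch1") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  design <- config$design

  n_prot <- config$n_proteins
  proteins <- sprintf("P%04d", seq_len(n_prot))
  changed <- stats::runif(n_prot) < config$fraction_changed
  sign_fc <- sample(c(-1, 1), n_prot, replace = TRUE)
  lfc <- ifelse(changed, sign_fc * config$true_log2_fc, 0)

  pp <- config$peptides_per_protein
  npep <- if (pp[1] == pp[2]) rep(pp[1], n_prot)
          else sample(pp[1]:pp[2], n_prot, replace = TRUE)
  prot_of_pep <- rep(seq_len(n_prot), npep)
  n_pep <- length(prot_of_pep)
  peptide_id <- sprintf("PEP_%s_%02d", proteins[prot_of_pep],
                        sequence(npep))
  prot_abundance <- stats::rlnorm(n_prot, 0, config$coef_sdlog_protein)
  coef <- exp(config$coef_meanlog) * prot_abundance[prot_of_pep] *
    stats::rlnorm(n_pep, 0, config$coef_sdlog_peptide)

  channels <- design$channel
  amount <- design$amount_ug
  pool_factor <- (1 + 2^lfc) / 2
  # per-peptide, per-channel fold-change factor
  fc_factor <- matrix(1, n_pep, length(channels))
  for (j in seq_along(channels)) {
    if (design$role[j] == "calibration") {
      fc_factor[, j] <- pool_factor[prot_of_pep]
    } else if (!is.na(design$condition[j]) &&
               design$condition[j] == "treated") {
      fc_factor[, j] <- 2^lfc[prot_of_pep]
    }
  }

  mu <- coef %o% amount * fc_factor
  if (config$cv_multiplicative > 0) {
    sdlog <- sqrt(log(1 + config$cv_multiplicative^2))
    noise <- matrix(stats::rlnorm(n_pep * length(channels),
                                  meanlog = -sdlog^2 / 2, sdlog = sdlog),
                    n_pep, length(channels))
  } else {
    noise <- 1
  }
  intensity <- mu * noise + config$background_floor
  if (config$detection_threshold > 0) {
    intensity[intensity < config$detection_threshold] <- NA_real_
  }
  colnames(intensity) <- channels

  d <- data.frame(peptide_id = peptide_id,
                  protein_accession = proteins[prot_of_pep],
                  batch_id = batch_id, quant_flag = "",
                  stringsAsFactors = FALSE, check.names = FALSE)
  d <- cbind(d, as.data.frame(intensity, check.names = FALSE))

  expected_n_linear <- vapply(seq_len(n_pep), function(i) {
    expected_linear_points(coef[i] * pool_factor[prot_of_pep[i]], design,
                           background_floor = config$background_floor,
                           detection_threshold = config$detection_threshold)
  }, integer(1))

  truth <- list(
    peptides = data.frame(peptide_id = peptide_id,
                          protein_accession = proteins[prot_of_pep],
                          coefficient = coef,
                          pool_factor = pool_factor[prot_of_pep],
                          expected_n_linear = expected_n_linear,
                          stringsAsFactors = FALSE),
    proteins = data.frame(protein_accession = proteins,
                          changed = changed, true_log2_fc = lfc,
                          stringsAsFactors = FALSE),
    config = config
  )
  list(table = peptide_quant_table(
         d, design, provenance = list(simulated = TRUE, seed = config$seed)),
       truth = truth)
}

#' Expected linear-point count of a noiseless floored peptide
#'
#' With no multiplicative noise, a peptide with effective response
#' coefficient `c` sits at expected intensity `c * a + floor` at amount `a`:
#' the floor lifts each point off the log-log line by `log(1 + floor/(c a))`,
#' flattening the low dilutions. Running the deterministic classifier on
#' these expected signals yields the linear-point count the floor alone
#' predicts.
#'
#' @param coefficient effective response coefficient (units per ug),
#'   including any pool mixture factor.
#' @param design a [channel_design].
#' @param background_floor,detection_threshold as in [sim_config()].
#' @param threshold,log_base classifier settings.
#' @return Integer expected linear-point count (0 = fewer than 3).
#' @export
expected_linear_points <- function(coefficient, design, background_floor = 0,
                                   detection_threshold = 0, threshold = 0.95,
                                   log_base = 10) {
  amounts <- unname(calibration_amounts(design))
  mu <- coefficient * amounts + background_floor
  if (detection_threshold > 0) mu[mu < detection_threshold] <- NA_real_
  res <- count_linear_points(amounts, mu, threshold = threshold,
                             log_base = log_base)
  as.integer(res$n_linear_points)
}

#' Add a constant background offset to every measured intensity
#'
#' @param table a [peptide_quant_table].
#' @param offset nonnegative constant added to every non-missing intensity
#'   of every channel; missing values stay missing.
#' @return The offset [peptide_quant_table].
#' @export
add_background_offset <- function(table, offset) {
  stopifnot(is.numeric(offset), length(offset) == 1, offset >= 0)
  d <- table$data
  for (ch in table$design$channel) {
    d[[ch]] <- d[[ch]] + offset
  }
  peptide_quant_table(d, table$design,
                      provenance = c(table$provenance,
                                     list(background_offset = offset)),
                      dropped = table$dropped)
}
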