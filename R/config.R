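#' Simulation configuration
#'
#' Builds the configuration object that drives every synthetic-data
#' generator. All randomness in the package flows from the single integer
#' `seed`; the same configuration always yields bit-identical outputs.
#'
#' Defaults mirror the study design the package emulates: an 11-case /
#' 18-control sigmoid-colon cohort, a pooled reference aggregated from 8
#' non-IBS subjects, 2--6 independent qPCR plate replicates per gene with
#' 3--6 wells each, and 6 biological replicates per arm for the
#' treated-vs-vehicle cell experiments.
#'
#' @param seed integer seed; the only source of randomness.
#' @param n_genes number of genes on the simulated array.
#' @param n_de_genes number of genes planted as differentially expressed
#'   (must not exceed `n_genes`).
#' @param n_cases,n_controls cohort sizes.
#' @param log2_effect_range length-2 numeric, absolute planted case-vs-control
#'   effect range in log2 units; each planted gene draws uniformly from it
#'   with a random sign (both induced and repressed genes occur).
#' @param array_noise_sd per-measurement Gaussian noise on the log2
#'   intensity scale.
#' @param ct_noise_sd per-well Gaussian noise on the Ct (cycle) scale.
#' @param plate_replicates length-2 integer range of independent qPCR plate
#'   replicates per gene (patient experiments).
#' @param well_replicates length-2 integer range of PCR wells per patient,
#'   gene and plate.
#' @param treatment_replicates plates per arm in treated-vs-vehicle cell
#'   experiments.
#' @param pool_size number of control subjects averaged into the pooled
#'   reference arm.
#' @param amplification_efficiency fraction in (0, 1]; 1 means one cycle per
#'   doubling, the standard 2^(-ddCt) convention and the default.
#' @param patient_missing_rate probability that a given patient is absent
#'   from a given plate (lets the number of patients analyzed vary across
#'   replicates, as in real plate layouts).
#' @param treatment_fold_map optional named numeric vector of planted linear
#'   treated/vehicle folds per gene (all > 0).
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cohort <- simulate_cohort(cfg)
#' table(cohort$classification)
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_de_genes = 200L,
                       n_cases = 11L,
                       n_controls = 18L,
                       log2_effect_range = c(0.5, 2.0),
                       array_noise_sd = 0.5,
                       ct_noise_sd = 0.15,
                       plate_replicates = c(2L, 6L),
                       well_replicates = c(3L, 6L),
                       treatment_replicates = 6L,
                       pool_size = 8L,
                       amplification_efficiency = 1,
                       patient_missing_rate = 0,
                       treatment_fold_map = NULL) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    n_de_genes = as.integer(n_de_genes),
    n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls),
    log2_effect_range = as.numeric(log2_effect_range),
    array_noise_sd = as.numeric(array_noise_sd),
    ct_noise_sd = as.numeric(ct_noise_sd),
    plate_replicates = as.integer(plate_replicates),
    well_replicates = as.integer(well_replicates),
    treatment_replicates = as.integer(treatment_replicates),
    pool_size = as.integer(pool_size),
    amplification_efficiency = as.numeric(amplification_efficiency),
    patient_missing_rate = as.numeric(patient_missing_rate),
    treatment_fold_map = treatment_fold_map
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.na(cfg$seed)) stop("invalid config: seed must be an integer")
  if (cfg$n_genes < 1L) stop("invalid config: n_genes must be positive")
  if (cfg$n_de_genes < 0L) stop("invalid config: n_de_genes must be >= 0")
  if (cfg$n_de_genes > cfg$n_genes)
    stop("invalid config: n_de_genes exceeds n_genes")
  if (cfg$n_cases < 0L || cfg$n_controls < 0L)
    stop("invalid config: cohort counts must be non-negative")
  if (cfg$n_cases + cfg$n_controls < 1L)
    stop("invalid config: cohort must contain at least one sample")
  if (length(cfg$log2_effect_range) != 2L ||
      any(cfg$log2_effect_range < 0) || diff(cfg$log2_effect_range) < 0)
    stop("invalid config: log2_effect_range must be a non-decreasing pair >= 0")
  if (cfg$array_noise_sd < 0 || cfg$ct_noise_sd < 0)
    stop("invalid config: noise sds must be >= 0")
  if (length(cfg$plate_replicates) != 2L || cfg$plate_replicates[1] < 1L ||
      diff(cfg$plate_replicates) < 0)
    stop("invalid config: plate_replicates must be a valid integer range")
  if (length(cfg$well_replicates) != 2L || cfg$well_replicates[1] < 1L ||
      diff(cfg$well_replicates) < 0)
    stop("invalid config: well_replicates must be a valid integer range")
  if (cfg$treatment_replicates < 2L)
    stop("invalid config: treatment_replicates must be >= 2")
  if (cfg$pool_size < 1L) stop("invalid config: pool_size must be >= 1")
  if (cfg$amplification_efficiency <= 0 || cfg$amplification_efficiency > 1)
    stop("invalid config: amplification_efficiency must be in (0, 1]")
  if (cfg$patient_missing_rate < 0 || cfg$patient_missing_rate >= 1)
    stop("invalid config: patient_missing_rate must be in [0, 1)")
  if (!is.null(cfg$treatment_fold_map)) {
    if (is.null(names(cfg$treatment_fold_map)) ||
        any(!nzchar(names(cfg$treatment_fold_map))))
      stop("invalid config: treatment_fold_map must be a named vector")
    if (any(cfg$treatment_fold_map <= 0))
      stop("invalid config: planted folds must be > 0")
  }
  cfg
}

#' Read a simulation configuration from YAML
#'
#' Any field of [sim_config()] may appear in the file; missing fields take
#' the defaults. `treatment_fold_map` is given as a YAML mapping of gene to
#' linear fold.
#'
#' @param path path to a YAML file.
#' @param seed optional integer overriding the file's seed.
#' @return a `sim_config` object.
#' @export
read_sim_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  if (!is.null(raw$treatment_fold_map))
    raw$treatment_fold_map <- unlist(raw$treatment_fold_map)
  if (!is.null(seed)) raw$seed <- seed
  do.call(sim_config, raw)
}

# Derive a stream-specific seed so that e.g. the cohort and the array use
# decorrelated substreams of the one user seed, while staying in 32-bit range.
substream_seed <- function(seed, stream) {
  offset <- c(cohort = 11L, array = 23L, qpcr = 37L, treatment = 53L,
              pipeline = 71L)[[stream]]
  (as.integer(seed) %% 100000000L) * 19L + offset
}
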