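# Largest-remainder apportionment of n into integer counts with target
# proportions; deterministic, so cohort margins do not depend on the RNG.
apportion <- function(n, props) {
  props <- props / sum(props)
  raw <- n * props
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1L
  }
  as.integer(counts)
}

# Margins of the emulated 29-subject study population: 11 cases (8 F / 3 M;
# subtypes 1 IBS-C, 4 IBS-D, 5 IBS-M, 1 unknown) and 18 controls (12 F / 6 M).
COHORT_MARGINS <- list(
  case_sex = c(F = 8, M = 3),
  control_sex = c(F = 12, M = 6),
  case_subtype = c(`IBS-C` = 1, `IBS-D` = 4, `IBS-M` = 5, unknown = 1)
)

#' Simulate a case/control cohort table
#'
#' Generates per-sample metadata for a synthetic IBS study cohort. Sex and
#' IBS-subtype counts follow the emulated study's margins by
#' largest-remainder apportionment, so with the default configuration
#' (11 cases, 18 controls) the margins are reproduced exactly: 8 F / 3 M
#' cases, 12 F / 6 M controls, and subtypes 1 IBS-C, 4 IBS-D, 5 IBS-M,
#' 1 unknown. Controls always carry subtype `"none"`. Ages are drawn around
#' the cohort's 41--60 year range.
#'
#' @param config a [sim_config()] object.
#' @return a `data.frame` with columns `sample_id`, `classification`
#'   (`"case"`/`"control"`), `subtype` (`"IBS-C"`, `"IBS-D"`, `"IBS-M"`,
#'   `"unknown"` for cases; `"none"` for controls), `sex` (`"F"`/`"M"`) and
#'   `age` (integer years).
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 7))
#' table(cohort$classification, cohort$sex)
simulate_cohort <- function(config) {
  validate_sim_config(config)
  if (config$n_cases + config$n_controls < 1L)
    stop("invalid config: empty cohort")
  withr::with_seed(substream_seed(config$seed, "cohort"), {
    n_case <- config$n_cases
    n_ctrl <- config$n_controls
    case_sex <- rep(names(COHORT_MARGINS$case_sex),
                    apportion(n_case, COHORT_MARGINS$case_sex))
    ctrl_sex <- rep(names(COHORT_MARGINS$control_sex),
                    apportion(n_ctrl, COHORT_MARGINS$control_sex))
    subtype <- rep(names(COHORT_MARGINS$case_subtype),
                   apportion(n_case, COHORT_MARGINS$case_subtype))
    if (n_case > 0) {
      case_sex <- sample(case_sex)
      subtype <- sample(subtype)
    }
    if (n_ctrl > 0) ctrl_sex <- sample(ctrl_sex)
    age <- pmin(pmax(round(stats::rnorm(n_case + n_ctrl, 52, 4)), 18L), 90L)
    out <- data.frame(
      sample_id = c(sprintf("CASE-%03d", seq_len(n_case)),
                    sprintf("CTRL-%03d", seq_len(n_ctrl))),
      classification = rep(c("case", "control"), c(n_case, n_ctrl)),
      subtype = c(subtype, rep("none", n_ctrl)),
      sex = c(case_sex, ctrl_sex),
      age = as.integer(age),
      stringsAsFactors = FALSE
    )
    validate_cohort(out)
  })
}

#' Validate a cohort table
#'
#' Checks the cohort invariants: unique sample ids, recognized levels, a
#' subtype of `"none"` exactly for controls, and positive ages.
#'
#' @param cohort a cohort `data.frame` as produced by [simulate_cohort()] or
#'   read with [read_cohort()].
#' @return the cohort, invisibly unchanged, or an error.
#' @export
validate_cohort <- function(cohort) {
  need <- c("sample_id", "classification", "subtype", "sex", "age")
  missing <- setdiff(need, names(cohort))
  if (length(missing))
    stop("cohort is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(cohort$sample_id))
    stop("cohort sample_id values must be unique")
  if (!all(cohort$classification %in% c("case", "control")))
    stop("classification must be 'case' or 'control'")
  if (!all(cohort$subtype %in% c("IBS-C", "IBS-D", "IBS-M", "unknown", "none")))
    stop("unrecognized subtype value")
  if (!all((cohort$subtype == "none") == (cohort$classification == "control")))
    stop("subtype must be 'none' if and only if the sample is a control")
  if (!all(cohort$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  if (!all(cohort$age > 0)) stop("age must be positive")
  cohort
}

#' Simulate a genes-by-samples microarray intensity matrix
#'
#' Log2 intensities are a per-gene baseline plus, for `n_de_genes` randomly
#' chosen genes in case samples only, a planted log2 effect drawn uniformly
#' from `log2_effect_range` with a random sign (so both induced and
#' repressed genes are planted), plus i.i.d. Gaussian noise with standard
#' deviation `array_noise_sd`. The planted effects are returned as a sidecar
#' so downstream screening stages can be scored against known truth.
#'
#' @param config a [sim_config()] object.
#' @param cohort a cohort table; its `sample_id` order defines the columns.
#' @return an object of class `ibs_expression`: a list with `values` (a
#'   numeric genes x samples matrix of log2 intensities, dimnames set),
#'   `gene_ids`, `sample_ids`, and `planted_truth` (named numeric vector of
#'   planted log2 case-vs-control effects; zero-length if none).
#' @export
simulate_microarray <- function(config, cohort) {
  validate_sim_config(config)
  validate_cohort(cohort)
  if (nrow(cohort) == 0) stop("cohort must be non-empty")
  withr::with_seed(substream_seed(config$seed, "array"), {
    genes <- sprintf("G%05d", seq_len(config$n_genes))
    baseline <- stats::runif(config$n_genes, 6, 12)
    de_idx <- sort(sample.int(config$n_genes, config$n_de_genes))
    effect <- numeric(config$n_genes)
    if (config$n_de_genes > 0) {
      magnitude <- stats::runif(config$n_de_genes,
                                config$log2_effect_range[1],
                                config$log2_effect_range[2])
      effect[de_idx] <- magnitude * sample(c(-1, 1), config$n_de_genes,
                                           replace = TRUE)
    }
    is_case <- cohort$classification == "case"
    values <- matrix(baseline, nrow = config$n_genes, ncol = nrow(cohort))
    values[, is_case] <- values[, is_case] + effect
    values <- values + stats::rnorm(length(values), 0, config$array_noise_sd)
    dimnames(values) <- list(genes, cohort$sample_id)
    structure(
      list(values = values,
           gene_ids = genes,
           sample_ids = cohort$sample_id,
           planted_truth = stats::setNames(effect[de_idx], genes[de_idx])),
      class = "ibs_expression"
    )
  })
}

#' @export
print.ibs_expression <- function(x, ...) {
  cat(sprintf("ibs_expression: %d genes x %d samples, %d planted DE genes\n",
              length(x$gene_ids), length(x$sample_ids),
              length(x$planted_truth)))
  invisible(x)
}

# Per-well Ct draw around a gene baseline; efficiency E maps one fold
# doubling to log2(fold)/log2(1+E) cycles (E = 1 gives the usual one cycle).
cycles_per_fold <- function(fold, efficiency) {
  log2(fold) / log2(1 + efficiency)
}

#' Simulate a long-format qPCR Ct table
#'
#' Generates cycle-threshold measurements for a reference arm and a target
#' arm, per gene, plate and well, with the target arm shifted down by
#' `log2(fold)` cycles (at 100% amplification efficiency) relative to the
#' reference so that the standard 2^(-ddCt) estimator recovers the planted
#' fold. Supports both study designs:
#'
#' * `arms = c("pooled_control", "case_patient")`: patient biopsies against
#'   a pooled non-IBS reference. The pooled arm's Ct per gene/plate/well is
#'   the mean of `pool_size` simulated control subjects' Ct values — the
#'   in-silico analogue of physically pooling RNA. Each of `n_cases`
#'   patients appears on each plate, minus random plate dropout at rate
#'   `patient_missing_rate`; plates per gene are drawn from
#'   `plate_replicates`, wells from `well_replicates`.
#' * `arms = c("vehicle", "treated")`: a cell-line treatment experiment
#'   with `treatment_replicates` independent plates per arm and a single
#'   subject per arm.
#'
#' @param config a [sim_config()] object.
#' @param truth named numeric vector of planted linear folds
#'   (target/reference), one per gene, all > 0.
#' @param arms character pair: reference arm first, target arm second.
#' @return a `data.frame` with columns `gene`, `arm`, `subject_id`, `plate`,
#'   `well`, `ct` satisfying 0 < ct < 45 and unique
#'   (gene, arm, subject_id, plate, well) keys.
#' @export
#' @examples
#' cfg <- sim_config(seed = 3, ct_noise_sd = 0)
#' ct <- simulate_qpcr(cfg, c(TPH1 = 2), arms = c("vehicle", "treated"))
#' # one planted doubling = treated Ct exactly one cycle lower
#' aggregate(ct ~ arm, ct[ct$gene == "TPH1", ], mean)
simulate_qpcr <- function(config, truth,
                          arms = c("pooled_control", "case_patient")) {
  validate_sim_config(config)
  if (length(truth) == 0 || is.null(names(truth)))
    stop("truth must be a named vector of planted folds")
  if (any(truth <= 0)) stop("invalid config: planted folds must be > 0")
  arms <- match.arg(arms,
                    c("pooled_control", "case_patient", "vehicle", "treated"),
                    several.ok = TRUE)
  if (length(arms) != 2L || arms[1] == arms[2])
    stop("arms must be two distinct arm labels (reference first)")
  patient_design <- identical(sort(arms), c("case_patient", "pooled_control"))
  stream <- if (patient_design) "qpcr" else "treatment"
  withr::with_seed(substream_seed(config$seed, stream), {
    rows <- lapply(names(truth), function(g) {
      fold <- truth[[g]]
      shift <- cycles_per_fold(fold, config$amplification_efficiency)
      baseline <- stats::runif(1, 20, 30)
      if (patient_design) {
        n_plates <- sample_range(config$plate_replicates)
        n_wells <- sample_range(config$well_replicates)
        subjects <- sprintf("IBS-P%02d", seq_len(config$n_cases))
      } else {
        n_plates <- config$treatment_replicates
        n_wells <- sample_range(config$well_replicates)
        subjects <- "HCT116"
      }
      per_plate <- lapply(seq_len(n_plates), function(p) {
        ref_ct <- if (patient_design) {
          # pooled reference: average pool_size independent control draws
          vapply(seq_len(n_wells), function(w) {
            mean(baseline + stats::rnorm(config$pool_size, 0,
                                         config$ct_noise_sd))
          }, numeric(1))
        } else {
          baseline + stats::rnorm(n_wells, 0, config$ct_noise_sd)
        }
        ref <- data.frame(gene = g, arm = arms[1],
                          subject_id = if (patient_design) "POOL" else "HCT116",
                          plate = p, well = seq_len(n_wells), ct = ref_ct,
                          stringsAsFactors = FALSE)
        present <- subjects
        if (patient_design && config$patient_missing_rate > 0) {
          keep <- stats::runif(length(subjects)) >= config$patient_missing_rate
          if (!any(keep)) keep[1] <- TRUE   # a plate never loses all patients
          present <- subjects[keep]
        }
        tgt <- do.call(rbind, lapply(present, function(s) {
          data.frame(gene = g, arm = arms[2], subject_id = s, plate = p,
                     well = seq_len(n_wells),
                     ct = baseline - shift +
                       stats::rnorm(n_wells, 0, config$ct_noise_sd),
                     stringsAsFactors = FALSE)
        }))
        rbind(ref, tgt)
      })
      do.call(rbind, per_plate)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out$ct <- pmin(pmax(out$ct, 1e-6), 44.999)
    validate_ct_table(out)
  })
}

sample_range <- function(range) {
  if (range[1] == range[2]) range[1] else sample(range[1]:range[2], 1)
}

#' Validate a long-format Ct table
#'
#' @param ct a `data.frame` with columns `gene`, `arm`, `subject_id`,
#'   `plate`, `well`, `ct`.
#' @return the table, unchanged, or an error describing the violation.
#' @export
validate_ct_table <- function(ct) {
  need <- c("gene", "arm", "subject_id", "plate", "well", "ct")
  missing <- setdiff(need, names(ct))
  if (length(missing))
    stop("Ct table is missing columns: ", paste(missing, collapse = ", "))
  if (!all(ct$arm %in% c("case_patient", "pooled_control", "treated",
                         "vehicle")))
    stop("unrecognized arm label")
  if (!all(ct$ct > 0 & ct$ct < 45)) stop("ct values must lie in (0, 45)")
  key <- paste(ct$gene, ct$arm, ct$subject_id, ct$plate, ct$well, sep = "\r")
  if (anyDuplicated(key))
    stop("(gene, arm, subject_id, plate, well) keys must be unique")
  ct
}
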