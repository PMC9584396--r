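#' Treatment fold change and significance for one gene
#'
#' Quantifies 1,25-dihydroxyvitamin-D (or any treated-vs-vehicle) regulation
#' of a gene from cell-line Ct data: wells are averaged per plate, the fold
#' is estimated per plate by 2^(-dCt) against the paired vehicle plate and
#' averaged, and significance comes from a pooled-variance two-sample
#' t-test on the per-plate well-averaged Ct values of the two arms
#' (equal-variance assumptions are more defensible on the cycle/log scale
#' than on linear folds). Significance tiers use the two conventional
#' cut-offs p < 0.005 and p < 0.0005.
#'
#' @param ct Ct table for a single gene with arms `"treated"` and
#'   `"vehicle"`, at least 2 plates per arm.
#' @param gene optional gene id to subset `ct` by.
#' @return a one-row `data.frame`: `gene`, `fold_1_25D` (treated/vehicle),
#'   `p_value`, `n_replicates` (min plates per arm), `significance_tier`
#'   (`"ns"`, `"p<0.005"`, `"p<0.0005"`).
#' @export
treatment_fold_and_test <- function(ct, gene = NULL) {
  if (!is.null(gene)) ct <- ct[ct$gene == gene, , drop = FALSE]
  validate_ct_table(ct)
  g <- unique(ct$gene)
  if (length(g) != 1)
    stop("treatment_fold_and_test expects a single gene, got: ",
         paste(g, collapse = ", "))
  plate_ct <- stats::aggregate(ct ~ arm + plate, data = ct, FUN = mean)
  treated <- plate_ct$ct[plate_ct$arm == "treated"]
  vehicle <- plate_ct$ct[plate_ct$arm == "vehicle"]
  if (length(treated) < 2 || length(vehicle) < 2)
    stop("insufficient data: need >= 2 replicates per arm")
  est <- ddct_fold(ct, target_arm = "treated", reference_arm = "vehicle")
  fold <- mean(est$fold)
  p <- student_t_test(treated, vehicle)
  tier <- if (p < 0.0005) "p<0.0005" else if (p < 0.005) "p<0.005" else "ns"
  data.frame(gene = g, fold_1_25D = fold, p_value = p,
             n_replicates = min(length(treated), length(vehicle)),
             significance_tier = tier, stringsAsFactors = FALSE)
}

#' Does the treatment reverse the patient-cohort direction?
#'
#' `TRUE` when the cell-line treatment fold and the patient-cohort fold
#' point in opposite directions relative to 1.0 (one induced, one
#' repressed). A fold of exactly 1.0 on either side has no direction and
#' yields `FALSE`. Symmetric in its arguments and invariant under jointly
#' inverting both folds.
#'
#' @param cell_fold,patient_fold linear fold changes, both > 0 (vectorized).
#' @return logical.
#' @export
#' @examples
#' classify_reversal(3.18, 0.96)   # induced by treatment, repressed in IBS
classify_reversal <- function(cell_fold, patient_fold) {
  if (any(cell_fold <= 0) || any(patient_fold <= 0))
    stop("invalid input: folds must be > 0")
  sc <- sign(log(cell_fold))
  sp <- sign(log(patient_fold))
  sc != 0 & sp != 0 & sc == -sp
}

#' Treatment response and reversal classification for a gene set
#'
#' Runs [treatment_fold_and_test()] per gene of a treated-vs-vehicle Ct
#' table and classifies each gene as reversing or reinforcing its
#' IBS-cohort direction. Patient direction comes from the qPCR cohort
#' summary by default (the cohort-validated direction); microarray-based
#' direction is available via `direction_source`.
#'
#' @param ct treated/vehicle Ct table covering one or more genes.
#' @param patient_summary `data.frame` with columns `gene` and `mean_fold`
#'   (qPCR cohort summary, e.g. from [summarize_gene()]), used when
#'   `direction_source = "qpcr"`.
#' @param microarray_folds named numeric vector of microarray folds, used
#'   when `direction_source = "microarray"`.
#' @param direction_source `"qpcr"` (default) or `"microarray"`.
#' @return a `data.frame` with one row per gene: the
#'   [treatment_fold_and_test()] columns plus `patient_fold` and `reversal`.
#' @export
treatment_response <- function(ct, patient_summary = NULL,
                               microarray_folds = NULL,
                               direction_source = c("qpcr", "microarray")) {
  direction_source <- match.arg(direction_source)
  patient <- switch(direction_source,
    qpcr = {
      if (is.null(patient_summary))
        stop("patient_summary is required when direction_source = 'qpcr'")
      stats::setNames(patient_summary$mean_fold, patient_summary$gene)
    },
    microarray = {
      if (is.null(microarray_folds))
        stop("microarray_folds is required when direction_source = ",
             "'microarray'")
      microarray_folds
    }
  )
  genes <- unique(ct$gene)
  rows <- lapply(genes, function(g) {
    res <- treatment_fold_and_test(ct, gene = g)
    pf <- patient[[g]]
    if (is.null(pf) || is.na(pf)) {
      res$patient_fold <- NA_real_
      res$reversal <- NA
    } else {
      res$patient_fold <- pf
      res$reversal <- classify_reversal(res$fold_1_25D, pf)
    }
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
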