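#' Per-plate ddCt fold changes against a comparator arm
#'
#' Implements the standard 2^(-ddCt) relative-quantification arithmetic.
#' Wells are first averaged within (gene, arm, subject, plate). For each
#' gene, plate and target-arm subject, dCt = mean Ct(target) - mean
#' Ct(comparator on the same plate, averaged over its subjects), and the
#' per-plate fold is 2^(-dCt). With `use_reference_gene` each arm's Ct is
#' first normalized by subtracting the same subject/plate's Ct for the
#' housekeeping `reference_gene` (full ddCt); the default is direct dCt
#' against the comparator arm, which is sufficient when the comparator is a
#' fixed pooled control or a vehicle arm.
#'
#' Plates with no comparator measurement are skipped with a warning; if no
#' plate has one the call errors.
#'
#' @param ct long-format Ct table (see [validate_ct_table()]).
#' @param target_arm,reference_arm arm labels, e.g. `"case_patient"` vs
#'   `"pooled_control"` or `"treated"` vs `"vehicle"`.
#' @param use_reference_gene normalize to a housekeeping gene first.
#' @param reference_gene gene id used when `use_reference_gene` is `TRUE`.
#' @return a `data.frame` of per-plate estimates: `gene`, `subject_id`,
#'   `plate`, `fold` (linear, > 0).
#' @export
#' @examples
#' ct <- data.frame(gene = "A", arm = rep(c("vehicle", "treated"), each = 2),
#'                  subject_id = "HCT116", plate = 1, well = c(1, 2, 1, 2),
#'                  ct = c(24, 24, 23, 23))
#' ddct_fold(ct, "treated", "vehicle")   # one cycle lower -> fold 2
ddct_fold <- function(ct, target_arm, reference_arm,
                      use_reference_gene = FALSE, reference_gene = NULL) {
  validate_ct_table(ct)
  if (!any(ct$arm == target_arm) || !any(ct$arm == reference_arm))
    stop("insufficient data: both arms must be present in the Ct table")
  well_means <- stats::aggregate(
    ct ~ gene + arm + subject_id + plate, data = ct, FUN = mean
  )
  if (use_reference_gene) {
    if (is.null(reference_gene))
      stop("reference_gene must be given when use_reference_gene = TRUE")
    ref <- well_means[well_means$gene == reference_gene, ]
    if (nrow(ref) == 0)
      stop("reference gene ", reference_gene, " not found in Ct table")
    key <- function(d) paste(d$arm, d$subject_id, d$plate, sep = "\r")
    ref_ct <- stats::setNames(ref$ct, key(ref))
    well_means <- well_means[well_means$gene != reference_gene, ]
    norm <- ref_ct[key(well_means)]
    if (anyNA(norm))
      stop("reference gene missing for some (arm, subject, plate) cells")
    well_means$ct <- well_means$ct - unname(norm)
  }
  genes <- unique(well_means$gene[well_means$arm == target_arm])
  rows <- lapply(genes, function(g) {
    tgt <- well_means[well_means$gene == g & well_means$arm == target_arm, ]
    cmp <- well_means[well_means$gene == g & well_means$arm == reference_arm, ]
    plates <- unique(tgt$plate)
    have_cmp <- plates %in% cmp$plate
    if (!any(have_cmp))
      stop("insufficient data: no plate of gene ", g,
           " carries the comparator arm")
    if (any(!have_cmp))
      warning("gene ", g, ": skipping plate(s) ",
              paste(plates[!have_cmp], collapse = ", "),
              " with no comparator measurement")
    per_plate <- lapply(plates[have_cmp], function(p) {
      cmp_ct <- mean(cmp$ct[cmp$plate == p])   # pooled arm: one subject
      tp <- tgt[tgt$plate == p, ]
      data.frame(gene = g, subject_id = tp$subject_id, plate = p,
                 fold = 2^(-(tp$ct - cmp_ct)), stringsAsFactors = FALSE)
    })
    do.call(rbind, per_plate)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize per-plate fold changes for one or more genes
#'
#' Collapses per-plate fold-change estimates to a per-gene summary: subjects
#' are averaged within each plate, then `mean_fold` is the arithmetic mean
#' of the per-plate folds (linear scale) and `sem` their standard error over
#' plates (0 by convention for a single plate). Genes measured on fewer than
#' `min_plates` independent plates fail the replicate filter and are meant
#' to be excluded from reporting.
#'
#' @param estimates `data.frame` from [ddct_fold()].
#' @param min_plates minimum number of independent plate replicates
#'   (default 2).
#' @param log_scale average on the log2 scale instead (geometric mean and
#'   log-scale SEM back-transformed); off by default to match the linear
#'   fold-reporting convention.
#' @return a `data.frame` with one row per gene: `gene`, `mean_fold`,
#'   `sem`, `n_plates`, `passes_replicate_filter`.
#' @export
summarize_gene <- function(estimates, min_plates = 2L, log_scale = FALSE) {
  if (nrow(estimates) == 0) stop("insufficient data: no fold estimates")
  if (any(estimates$fold <= 0)) stop("folds must be > 0")
  plate_folds <- stats::aggregate(fold ~ gene + plate, data = estimates,
                                  FUN = mean)
  rows <- lapply(split(plate_folds, plate_folds$gene), function(d) {
    f <- if (log_scale) log2(d$fold) else d$fold
    m <- mean(f)
    s <- if (nrow(d) > 1) stats::sd(f) / sqrt(nrow(d)) else 0
    if (log_scale) { m <- 2^m; s <- 2^s - 1 }
    data.frame(gene = d$gene[1], mean_fold = m, sem = s, n_plates = nrow(d),
               passes_replicate_filter = nrow(d) >= min_plates,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene), ]
}

#' Per-patient fold changes (averaged over plates)
#'
#' One fold per (gene, subject): the arithmetic mean of that subject's
#' per-plate folds. This is the patient-level quantity that cohort summaries
#' average and that the concordance statistic consumes per replicate.
#'
#' @param estimates `data.frame` from [ddct_fold()].
#' @return a `data.frame` with columns `gene`, `subject_id`, `fold`,
#'   `n_plates`.
#' @export
patient_folds <- function(estimates) {
  out <- stats::aggregate(fold ~ gene + subject_id, data = estimates,
                          FUN = mean)
  counts <- stats::aggregate(plate ~ gene + subject_id, data = estimates,
                             FUN = length)
  names(counts)[3] <- "n_plates"
  merge(out, counts, by = c("gene", "subject_id"), sort = TRUE)
}

#' Cohort-level fold change per gene
#'
#' Patient-first averaging: each patient's plates are averaged into one
#' fold, then patients are averaged into the cohort fold — the quantity a
#' cohort heat map reports per gene.
#'
#' @param estimates `data.frame` from [ddct_fold()].
#' @return a `data.frame` with columns `gene`, `fold`, `n_patients`.
#' @export
cohort_fold <- function(estimates) {
  pf <- patient_folds(estimates)
  out <- stats::aggregate(fold ~ gene, data = pf, FUN = mean)
  n <- stats::aggregate(subject_id ~ gene, data = pf, FUN = length)
  names(n)[2] <- "n_patients"
  merge(out, n, by = "gene", sort = TRUE)
}
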