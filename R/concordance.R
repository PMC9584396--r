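#' Does a patient's qPCR fold match the microarray direction?
#'
#' A patient "matches" when their qPCR fold change points the same way as
#' the cohort microarray fold change relative to 1.0 (both induced or both
#' repressed). A fold of exactly 1.0 has no direction and counts as a
#' non-match — a conservative convention that is measure-zero under noise.
#'
#' @param patient_fold,microarray_fold linear fold changes, both > 0.
#' @return `TRUE`/`FALSE` (vectorized over `patient_fold`).
#' @export
#' @examples
#' patient_match(0.58, 0.93)   # both repressed -> TRUE
#' patient_match(1.27, 1.14)   # both induced -> TRUE
patient_match <- function(patient_fold, microarray_fold) {
  if (any(patient_fold <= 0) || any(microarray_fold <= 0))
    stop("invalid input: folds must be > 0")
  sp <- sign(log(patient_fold))
  sm <- sign(log(microarray_fold))
  sp != 0 & sm != 0 & sp == sm
}

#' Per-gene percent accuracy over technical replicates
#'
#' The concordance statistic: with x_i patients matching the microarray
#' direction out of y_i patients analyzed in replicate i,
#' \deqn{\%Accuracy = 100 \times \frac{\sum_i x_i / y_i}{R},}
#' R the number of replicates, reported to 2 decimal places. `y` may differ
#' across replicates — not every patient appears on every plate.
#'
#' @param replicates `data.frame` with integer columns `x` (matches) and
#'   `y` (patients analyzed), one row per replicate.
#' @return percent accuracy in \[0, 100\], rounded to 2 decimals.
#' @export
#' @examples
#' percent_accuracy(data.frame(x = c(9, 8, 8), y = 11))   # 75.76
percent_accuracy <- function(replicates) {
  if (NROW(replicates) == 0)
    stop("insufficient data: at least one replicate is required")
  x <- replicates$x
  y <- replicates$y
  if (any(y < 1)) stop("invariant violation: y must be >= 1")
  if (any(x < 0) || any(x > y))
    stop("invariant violation: x must satisfy 0 <= x <= y")
  round(100 * mean(x / y), 2)
}

#' Score one gene's directional concordance
#'
#' Builds the per-replicate match counts from per-plate patient folds and
#' applies [percent_accuracy()]. Each plate is one technical replicate;
#' x = patients on that plate whose fold matches the microarray direction,
#' y = patients on that plate.
#'
#' @param estimates per-plate fold estimates for one gene (columns
#'   `subject_id`, `plate`, `fold`), as from [ddct_fold()].
#' @param microarray_fold the gene's cohort microarray linear fold change.
#' @return a list of class `concordance_score`: `gene`, `replicates` (a
#'   `data.frame` with `replicate`, `x`, `y`), `percent_accuracy`.
#' @export
score_gene <- function(estimates, microarray_fold) {
  if (nrow(estimates) == 0)
    stop("insufficient data: no fold estimates for the gene")
  gene <- unique(estimates$gene)
  if (length(gene) > 1)
    stop("score_gene expects estimates for a single gene, got: ",
         paste(gene, collapse = ", "))
  reps <- lapply(split(estimates, estimates$plate), function(d) {
    data.frame(replicate = d$plate[1],
               x = sum(patient_match(d$fold, microarray_fold)),
               y = nrow(d))
  })
  reps <- do.call(rbind, reps)
  reps <- reps[order(reps$replicate), ]
  rownames(reps) <- NULL
  structure(
    list(gene = if (length(gene)) gene else NA_character_,
         replicates = reps,
         percent_accuracy = percent_accuracy(reps)),
    class = "concordance_score"
  )
}

#' @export
print.concordance_score <- function(x, ...) {
  cat(sprintf("gene %s: %.2f%% accuracy over %d replicate(s) [%s]\n",
              x$gene, x$percent_accuracy, nrow(x$replicates),
              paste(sprintf("%d/%d", x$replicates$x, x$replicates$y),
                    collapse = ", ")))
  invisible(x)
}

#' Score directional concordance for every gene in a Ct experiment
#'
#' Convenience wrapper: runs [ddct_fold()] on a patient Ct table, then
#' [score_gene()] per gene against the matching microarray folds.
#'
#' @param estimates per-plate fold estimates (all genes) from [ddct_fold()].
#' @param microarray_folds named numeric vector of cohort microarray folds.
#' @return a `data.frame` with columns `gene`, `n_replicates`,
#'   `percent_accuracy`, plus a list-column `match_counts` of per-replicate
#'   `x/y` strings.
#' @export
score_concordance <- function(estimates, microarray_folds) {
  genes <- intersect(unique(estimates$gene), names(microarray_folds))
  if (length(genes) == 0)
    stop("no genes shared between fold estimates and microarray folds")
  rows <- lapply(genes, function(g) {
    sc <- score_gene(estimates[estimates$gene == g, , drop = FALSE],
                     microarray_folds[[g]])
    data.frame(gene = g, n_replicates = nrow(sc$replicates),
               percent_accuracy = sc$percent_accuracy,
               match_counts = paste(sprintf("%d/%d", sc$replicates$x,
                                            sc$replicates$y),
                                    collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$percent_accuracy, out$gene), ]
}

#' Select the biomarker panel
#'
#' Applies the three panel criteria per gene: percent accuracy at least
#' `threshold` (default 70, compared with >=), at least two independent
#' plate replicates, and pathophysiological relevance (an explicit boolean
#' annotation, never inferred). Reports panel membership and the arithmetic
#' mean accuracy of the panel, rounded to 1 decimal.
#'
#' @param scores `data.frame` from [score_concordance()] (columns `gene`,
#'   `percent_accuracy`).
#' @param summaries `data.frame` from [summarize_gene()] (columns `gene`,
#'   `passes_replicate_filter`); keyed by the same genes.
#' @param flags named logical vector of per-gene relevance; genes absent
#'   default to `FALSE`.
#' @param threshold minimum percent accuracy (default 70).
#' @return a list: `selection` (`data.frame` with `gene`,
#'   `percent_accuracy`, `passes_accuracy`, `passes_replicates`,
#'   `pathophysiology_relevant`, `in_panel`) and `panel_mean_accuracy`
#'   (1-decimal mean over panel members; `NA` for an empty panel).
#' @export
select_panel <- function(scores, summaries, flags = NULL, threshold = 70) {
  merged <- merge(scores[, c("gene", "percent_accuracy")],
                  summaries[, c("gene", "passes_replicate_filter")],
                  by = "gene", sort = TRUE)
  if (nrow(merged) < nrow(scores))
    warning("genes missing a replicate summary were dropped: ",
            paste(setdiff(scores$gene, merged$gene), collapse = ", "))
  relevant <- if (is.null(flags)) rep(FALSE, nrow(merged))
              else !is.na(flags[merged$gene]) & unname(flags[merged$gene])
  sel <- data.frame(
    gene = merged$gene,
    percent_accuracy = merged$percent_accuracy,
    passes_accuracy = merged$percent_accuracy >= threshold,
    passes_replicates = merged$passes_replicate_filter,
    pathophysiology_relevant = relevant,
    stringsAsFactors = FALSE
  )
  sel$in_panel <- sel$passes_accuracy & sel$passes_replicates &
    sel$pathophysiology_relevant
  sel <- sel[order(-sel$percent_accuracy, sel$gene), ]
  rownames(sel) <- NULL
  mean_acc <- if (any(sel$in_panel))
    round(mean(sel$percent_accuracy[sel$in_panel]), 1) else NA_real_
  list(selection = sel, panel_mean_accuracy = mean_acc)
}
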