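#' Quantile-normalize an expression matrix across arrays
#'
#' Standard column quantile normalization: every sample is forced onto the
#' common distribution given by the row-wise mean of the sorted columns.
#' Ties within a column receive the mean of the quantiles they span. Off by
#' default in [run_de_screen()] because the synthetic generator already
#' produces calibrated arrays.
#'
#' @param values numeric genes x samples matrix (log2 scale).
#' @return a matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(values) {
  values <- as.matrix(values)
  sorted <- apply(values, 2, sort)
  target <- rowMeans(sorted)
  out <- apply(values, 2, function(col) {
    r <- rank(col, ties.method = "average")
    stats::approx(seq_along(target), target, xout = r)$y
  })
  dimnames(out) <- dimnames(values)
  out
}

#' Screen a matrix for case-vs-control differential expression
#'
#' Runs the three-test screening combination gene by gene — pooled-variance
#' Student t, Mann-Whitney U, and the empirical-Bayes moderated t — and
#' flags significance at `alpha` under the configured combination rule.
#' No multiple-testing correction is applied by default (the screen is
#' deliberately inclusive); Benjamini-Hochberg can be switched on with
#' `bh = TRUE`, in which case the rule is applied to adjusted p-values.
#'
#' The linear fold change is the ratio of arithmetic group means on the
#' linear intensity scale (case over control), the usual microarray
#' convention; `fold_method = "log2"` instead exponentiates the difference
#' of log2 means.
#'
#' @param x an `ibs_expression` object or a genes x samples numeric matrix
#'   of log2 intensities with dimnames.
#' @param cohort cohort table; `sample_id` must be a subset of the matrix
#'   columns and `classification` defines the groups.
#' @param alpha significance level (default 0.05).
#' @param rule combination rule: `"any"` (significant in at least one of
#'   the three tests; default), `"all"`, or `"moderated_only"`.
#' @param bh apply Benjamini-Hochberg adjustment before flagging.
#' @param normalize quantile-normalize the matrix first.
#' @param fold_method `"mean_ratio"` (default) or `"log2"`.
#' @return a `data.frame` sorted by `p_moderated` with columns `gene`,
#'   `fold_change`, `log2_fc`, `p_student`, `p_mw`, `p_moderated`,
#'   `significant`; the rule and alpha are recorded in attributes.
#' @export
run_de_screen <- function(x, cohort, alpha = 0.05,
                          rule = c("any", "all", "moderated_only"),
                          bh = FALSE, normalize = FALSE,
                          fold_method = c("mean_ratio", "log2")) {
  rule <- match.arg(rule)
  fold_method <- match.arg(fold_method)
  values <- if (inherits(x, "ibs_expression")) x$values else as.matrix(x)
  validate_cohort(cohort)
  missing <- setdiff(cohort$sample_id, colnames(values))
  if (length(missing))
    stop("cohort samples missing from the matrix: ",
         paste(missing, collapse = ", "))
  values <- values[, cohort$sample_id, drop = FALSE]
  if (normalize) values <- quantile_normalize(values)
  is_case <- cohort$classification == "case"
  if (sum(is_case) < 2 || sum(!is_case) < 2)
    stop("insufficient data: need at least 2 cases and 2 controls")

  case <- values[, is_case, drop = FALSE]
  ctrl <- values[, !is_case, drop = FALSE]
  linear_case <- rowMeans(2^case)
  linear_ctrl <- rowMeans(2^ctrl)
  fold <- switch(fold_method,
    mean_ratio = linear_case / linear_ctrl,
    log2 = 2^(rowMeans(case) - rowMeans(ctrl))
  )
  p_student <- vapply(seq_len(nrow(values)), function(i)
    student_t_test(case[i, ], ctrl[i, ]), numeric(1))
  p_mw <- vapply(seq_len(nrow(values)), function(i)
    mannwhitney_u_test(case[i, ], ctrl[i, ]), numeric(1))
  mod <- moderated_t_test(values, ifelse(is_case, "case", "control"))
  p_mod <- mod$p_value

  res <- data.frame(
    gene = rownames(values), fold_change = fold, log2_fc = log2(fold),
    p_student = p_student, p_mw = p_mw, p_moderated = p_mod,
    row.names = NULL, stringsAsFactors = FALSE
  )
  ps <- if (bh) {
    data.frame(s = stats::p.adjust(p_student, "BH"),
               m = stats::p.adjust(p_mw, "BH"),
               e = stats::p.adjust(p_mod, "BH"))
  } else {
    data.frame(s = p_student, m = p_mw, e = p_mod)
  }
  res$significant <- switch(rule,
    any = ps$s <= alpha | ps$m <= alpha | ps$e <= alpha,
    all = ps$s <= alpha & ps$m <= alpha & ps$e <= alpha,
    moderated_only = ps$e <= alpha
  )
  res <- res[order(res$p_moderated, res$gene), ]
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  attr(res, "rule") <- rule
  attr(res, "bh") <- bh
  attr(res, "d0") <- attr(mod, "d0")
  res
}

#' Keep the top-n genes of a DE screen by moderated-t p-value
#'
#' A rank filter for shortlisting a screen before validation (the exact
#' shortlisting rule used in the emulated study is not public, so a
#' transparent rank cut is exposed instead).
#'
#' @param de_results output of [run_de_screen()].
#' @param n number of genes to keep.
#' @return the top `n` rows by increasing `p_moderated`.
#' @export
top_n_genes <- function(de_results, n) {
  de_results[order(de_results$p_moderated,
                   de_results$gene), ][seq_len(min(n, nrow(de_results))), ]
}
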