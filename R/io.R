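#' Read and write pipeline tables
#'
#' Plain-text dialects shared by every stage: cohort CSV (`sample_id,
#' classification, subtype, sex, age`), expression TSV (genes in rows,
#' first column `gene`, remaining columns one per sample), and long-format
#' Ct CSV (`gene, arm, subject_id, plate, well, ct`). Each reader validates
#' the table's invariants on load.
#'
#' @param path file path.
#' @return the validated table (`read_*`); the path, invisibly (`write_*`).
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_cohort <- function(path) {
  validate_cohort(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname pipeline_io
#' @param cohort a cohort table.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(validate_cohort(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_expression_matrix <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "gene") stop("first column of expression TSV must be ",
                                  "'gene'")
  values <- as.matrix(d[, -1, drop = FALSE])
  rownames(values) <- d$gene
  if (!all(is.finite(values))) stop("expression values must be finite")
  structure(list(values = values, gene_ids = rownames(values),
                 sample_ids = colnames(values), planted_truth = numeric(0)),
            class = "ibs_expression")
}

#' @rdname pipeline_io
#' @param x an `ibs_expression` object or genes x samples matrix.
#' @export
write_expression_matrix <- function(x, path) {
  values <- if (inherits(x, "ibs_expression")) x$values else as.matrix(x)
  d <- data.frame(gene = rownames(values), values, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_ct_table <- function(path) {
  validate_ct_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname pipeline_io
#' @param ct a long-format Ct table.
#' @export
write_ct_table <- function(ct, path) {
  utils::write.csv(validate_ct_table(ct), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
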