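#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: one set per line, `term_id <TAB> description
#' <TAB> gene1 <TAB> gene2 ...`. Empty gene fields are dropped.
#'
#' @param path path to a `.gmt` file.
#' @return a named list of gene-id character vectors; names are term ids and
#'   each element carries its description in attribute `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line (need term, description, >=1 gene): ",
           substr(l, 1, 60))
    genes <- unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
    structure(genes, description = parts[2])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  if (anyDuplicated(names(sets))) stop("duplicate term ids in GMT")
  sets
}

#' Hypergeometric over-representation of a DE list in gene sets
#'
#' For each annotation term, tests whether the differentially expressed list
#' contains more of the term's genes than expected by chance, using the
#' upper-tail hypergeometric probability P(X >= k) for k observed overlaps
#' given a universe of N genes, K of them in the term and a DE list of n.
#' Terms are first intersected with the universe (here: all genes on the
#' array, not the genome). No multiplicity correction is applied; terms are
#' ranked by increasing p-value, ties broken by term id.
#'
#' @param de_genes character vector of DE gene ids (subset of `universe`).
#' @param annotations named list of gene-id vectors, as from [read_gmt()].
#' @param universe character vector of all testable gene ids.
#' @return a `data.frame` with columns `term_id`, `term_name`, `k`, `K`,
#'   `n`, `N`, `p_value`, sorted by increasing `p_value` then `term_id`.
#' @export
hypergeometric_enrichment <- function(de_genes, annotations, universe) {
  universe <- unique(universe)
  de_genes <- unique(de_genes)
  if (length(universe) == 0) stop("invalid input: empty universe")
  if (length(de_genes) == 0) stop("invalid input: empty DE gene list")
  outside <- setdiff(de_genes, universe)
  if (length(outside))
    stop("DE genes outside the universe: ", paste(outside, collapse = ", "))
  if (length(annotations) == 0)
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric()))
  N <- length(universe)
  n <- length(de_genes)
  rows <- lapply(names(annotations), function(id) {
    members <- intersect(annotations[[id]], universe)
    K <- length(members)
    k <- length(intersect(members, de_genes))
    # upper tail P(X >= k); phyper's lower.tail=FALSE gives P(X > k-1)
    p <- if (K == 0) 1 else stats::phyper(k - 1, K, N - K, n,
                                          lower.tail = FALSE)
    desc <- attr(annotations[[id]], "description")
    data.frame(term_id = id,
               term_name = if (is.null(desc)) id else desc,
               k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Select candidate genes for qPCR validation
#'
#' Mirrors the triage that feeds the validation stage: a gene is a
#' candidate when it is significant in the DE screen AND either belongs to
#' one of the `top_terms` most enriched annotation terms or is flagged as
#' relevant to IBS pathophysiology. The relevance flag is a human judgment
#' and only ever enters as an explicit input, never inferred. Candidates
#' are ranked by decreasing |log2 fold change|.
#'
#' @param enrichment output of [hypergeometric_enrichment()] (already
#'   sorted by p-value).
#' @param de_results output of [run_de_screen()].
#' @param annotations the same annotation list used for enrichment (needed
#'   to resolve term membership).
#' @param top_terms how many top-ranked terms define membership
#'   (default 25).
#' @param flags optional named logical vector of per-gene pathophysiology
#'   relevance; genes absent from it default to `FALSE`.
#' @return the candidate rows of `de_results`, ranked by `abs(log2_fc)`
#'   decreasing, with an added logical column `flagged`.
#' @export
select_candidates <- function(enrichment, de_results, annotations,
                              top_terms = 25L, flags = NULL) {
  top_ids <- utils::head(enrichment$term_id, top_terms)
  member_genes <- unique(unlist(annotations[top_ids], use.names = FALSE))
  flagged <- function(g) {
    if (is.null(flags)) rep(FALSE, length(g))
    else !is.na(flags[g]) & unname(flags[g])
  }
  de_sig <- de_results[de_results$significant, , drop = FALSE]
  keep <- de_sig$gene %in% member_genes | flagged(de_sig$gene)
  out <- de_sig[keep, , drop = FALSE]
  out$flagged <- flagged(out$gene)
  out <- out[order(-abs(out$log2_fc), out$gene), ]
  rownames(out) <- NULL
  out
}
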