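#' Toy annotation sets with a planted enriched term
#'
#' Builds a small GMT-style annotation list over the simulated array's
#' genes: `n_random` terms of random membership plus one
#' `"SEROTONIN_TOY"` term drawn mostly from the planted DE genes, so the
#' enrichment stage has a term it should rank first.
#'
#' @param expr an `ibs_expression` with a `planted_truth` sidecar.
#' @param seed integer seed.
#' @param n_random number of random background terms.
#' @param term_size size of each random term.
#' @return a named list of gene-id vectors (GMT-compatible).
#' @export
simulate_annotations <- function(expr, seed = 1L, n_random = 40L,
                                 term_size = 30L) {
  withr::with_seed(substream_seed(seed, "pipeline"), {
    genes <- expr$gene_ids
    sets <- lapply(seq_len(n_random), function(i)
      structure(sample(genes, min(term_size, length(genes))),
                description = sprintf("random background term %d", i)))
    names(sets) <- sprintf("TOY%04d", seq_len(n_random))
    de <- names(expr$planted_truth)
    if (length(de) >= 5) {
      planted <- unique(c(sample(de, min(25, length(de))),
                          sample(genes, 5)))
      sets$SEROTONIN_TOY <- structure(planted,
                                      description = "planted enriched term")
    }
    sets
  })
}

stage_files <- function(dir, files) {
  paths <- file.path(dir, files)
  digests <- unname(tools::md5sum(paths))
  stats::setNames(digests, files)
}

#' Run the full triage pipeline on synthetic data
#'
#' Orchestrates the stage sequence simulate -> differential expression ->
#' enrichment -> qPCR quantification -> concordance -> treatment response,
#' writing every intermediate table under `out_dir` and returning a run
#' manifest (config snapshot, seed, per-stage file digests, timings,
#' versions) together with the stage results. Reruns with the same
#' configuration produce identical manifest digests.
#'
#' Stage logic on synthetic inputs:
#' * patient qPCR truth for each validated candidate is its planted
#'   microarray effect (linear `2^effect`; 1 for unplanted genes);
#' * the treatment experiment uses `config$treatment_fold_map` when given,
#'   otherwise plants direction-reversing folds for the top candidates so
#'   the reversal stage is exercised;
#' * pathophysiology-relevance flags are a human judgment: when `flags` is
#'   `NULL` every validated candidate is treated as relevant, so panel
#'   membership is decided by the accuracy and replicate criteria alone.
#'
#' @param config a [sim_config()] object, or a path to a YAML config file.
#' @param out_dir output directory (created if needed).
#' @param seed optional integer overriding `config$seed`.
#' @param annotations named list of gene sets (e.g. [read_gmt()]); default
#'   builds toy sets with [simulate_annotations()].
#' @param flags optional named logical relevance flags.
#' @param alpha,rule DE screen settings (see [run_de_screen()]).
#' @param top_terms enrichment terms defining candidate membership.
#' @param n_candidates cap on candidates carried into qPCR validation.
#' @param threshold panel accuracy threshold (percent).
#' @return a list of class `ibs_run`: `manifest`, `cohort`, `de`,
#'   `enrichment`, `candidates`, `qpcr_summary`, `concordance`, `panel`,
#'   `treatment`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, annotations = NULL,
                         flags = NULL, alpha = 0.05, rule = "any",
                         top_terms = 25L, n_candidates = 29L,
                         threshold = 70) {
  if (is.character(config)) config <- read_sim_config(config, seed = seed)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_sim_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    out <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }

  # -- simulate ------------------------------------------------------------
  cohort <- tick("simulate", {
    ch <- simulate_cohort(config)
    write_cohort(ch, file.path(out_dir, "cohort.csv"))
    ch
  })
  expr <- simulate_microarray(config, cohort)
  write_expression_matrix(expr, file.path(out_dir, "expression.tsv"))
  jsonlite::write_json(as.list(expr$planted_truth),
                       file.path(out_dir, "planted_truth.json"),
                       auto_unbox = TRUE, digits = NA)

  # -- differential expression ----------------------------------------------
  de <- tick("de", run_de_screen(expr, cohort, alpha = alpha, rule = rule))
  utils::write.table(de, file.path(out_dir, "de_results.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  # -- enrichment + candidate triage ----------------------------------------
  if (is.null(annotations))
    annotations <- simulate_annotations(expr, seed = config$seed)
  enr <- tick("enrich", {
    if (!any(de$significant)) {
      # degenerate but valid: nothing to test for over-representation
      data.frame(term_id = character(), term_name = character(),
                 k = integer(), K = integer(), n = integer(), N = integer(),
                 p_value = numeric())
    } else {
      hypergeometric_enrichment(de$gene[de$significant], annotations,
                                expr$gene_ids)
    }
  })
  utils::write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  candidates <- select_candidates(enr, de, annotations,
                                  top_terms = top_terms, flags = flags)
  candidates <- utils::head(candidates, n_candidates)
  utils::write.table(candidates, file.path(out_dir, "candidates.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  # -- patient qPCR validation ----------------------------------------------
  truth_fold <- 2^ifelse(is.na(expr$planted_truth[candidates$gene]), 0,
                         expr$planted_truth[candidates$gene])
  names(truth_fold) <- candidates$gene
  qpcr <- tick("qpcr", {
    if (nrow(candidates) == 0) NULL
    else simulate_qpcr(config, truth_fold,
                       arms = c("pooled_control", "case_patient"))
  })
  estimates <- NULL
  summary_tbl <- NULL
  if (!is.null(qpcr)) {
    write_ct_table(qpcr, file.path(out_dir, "patient_ct.csv"))
    estimates <- ddct_fold(qpcr, "case_patient", "pooled_control")
    summary_tbl <- summarize_gene(estimates)
    utils::write.table(summary_tbl, file.path(out_dir, "qpcr_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  # -- concordance + panel ---------------------------------------------------
  panel <- NULL
  scores <- NULL
  conc <- tick("concordance", {
    if (is.null(estimates)) NULL
    else {
      keep <- summary_tbl$gene[summary_tbl$passes_replicate_filter]
      if (length(keep) == 0) NULL
      else {
        micro <- stats::setNames(de$fold_change, de$gene)[keep]
        score_concordance(estimates[estimates$gene %in% keep, ], micro)
      }
    }
  })
  if (!is.null(conc)) {
    scores <- conc
    utils::write.table(conc, file.path(out_dir, "concordance.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    panel_flags <- if (is.null(flags))
      stats::setNames(rep(TRUE, nrow(conc)), conc$gene) else flags
    panel <- select_panel(conc, summary_tbl, flags = panel_flags,
                          threshold = threshold)
    utils::write.table(panel$selection, file.path(out_dir, "panel.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  # -- treatment response ----------------------------------------------------
  treatment <- tick("vitd", {
    fold_map <- config$treatment_fold_map
    if (is.null(fold_map) && !is.null(panel) && any(panel$selection$in_panel)) {
      # default: plant reversing folds for up to 4 panel genes
      genes <- utils::head(panel$selection$gene[panel$selection$in_panel], 4)
      patient <- stats::setNames(summary_tbl$mean_fold, summary_tbl$gene)
      fold_map <- stats::setNames(
        ifelse(patient[genes] > 1, 0.5, 2.5), genes)
    }
    if (is.null(fold_map) || length(fold_map) == 0) NULL
    else {
      ct <- simulate_qpcr(config, fold_map, arms = c("vehicle", "treated"))
      write_ct_table(ct, file.path(out_dir, "treatment_ct.csv"))
      if (is.null(summary_tbl)) NULL
      else {
        tr <- treatment_response(ct, patient_summary = summary_tbl)
        utils::write.table(tr, file.path(out_dir, "treatment.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        tr
      }
    }
  })

  produced <- list.files(out_dir)
  produced <- produced[produced != "manifest.json"]
  manifest <- list(
    seed = config$seed,
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    files = as.list(stage_files(out_dir, sort(produced))),
    timings_sec = as.list(round(unlist(timings), 3)),
    versions = list(
      r = R.version.string,
      package = as.character(utils::packageVersion("ibstriage"))
    )
  )
  digests_only <- manifest[c("seed", "config", "files")]
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(
    list(manifest = manifest, digest_view = digests_only, cohort = cohort,
         de = de, enrichment = enr, candidates = candidates,
         qpcr_summary = summary_tbl, concordance = scores, panel = panel,
         treatment = treatment),
    class = "ibs_run"
  )
}

#' @export
print.ibs_run <- function(x, ...) {
  cat("ibs_run (seed ", x$manifest$seed, ")\n", sep = "")
  cat("  DE genes significant: ", sum(x$de$significant), " of ",
      nrow(x$de), "\n", sep = "")
  cat("  candidates validated by qPCR: ", nrow(x$candidates), "\n", sep = "")
  if (!is.null(x$panel)) {
    sel <- x$panel$selection
    cat("  panel: ", sum(sel$in_panel), " gene(s), mean accuracy ",
        x$panel$panel_mean_accuracy, "%\n", sep = "")
  }
  if (!is.null(x$treatment))
    cat("  treatment reversals: ", sum(x$treatment$reversal, na.rm = TRUE),
        " of ", nrow(x$treatment), "\n", sep = "")
  invisible(x)
}

#' Export a heatmap-ready long table
#'
#' Flattens either a genes x samples matrix of linear values or a per-gene
#' fold summary into a long `(gene, sample, value, direction)` table that
#' any plotting tool can consume; `direction` is the sign of `log2(value)`
#' (-1 repressed, 0 unchanged, +1 induced).
#'
#' @param x a numeric matrix with dimnames, or a `data.frame` with columns
#'   `gene` and `mean_fold` (e.g. from [summarize_gene()]).
#' @return a long `data.frame` with columns `gene`, `sample`, `value`,
#'   `direction`.
#' @export
export_heatmap_table <- function(x) {
  if (is.matrix(x)) {
    if (length(x) == 0) stop("invalid input: empty matrix")
    out <- data.frame(
      gene = rep(rownames(x), times = ncol(x)),
      sample = rep(colnames(x), each = nrow(x)),
      value = as.vector(x),
      stringsAsFactors = FALSE
    )
  } else if (is.data.frame(x) && all(c("gene", "mean_fold") %in% names(x))) {
    if (nrow(x) == 0) stop("invalid input: empty summary")
    out <- data.frame(gene = x$gene, sample = "cohort", value = x$mean_fold,
                      stringsAsFactors = FALSE)
  } else {
    stop("x must be a named matrix or a gene/mean_fold summary")
  }
  if (any(out$value <= 0)) stop("values must be positive linear quantities")
  out$direction <- sign(log2(out$value))
  out
}
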