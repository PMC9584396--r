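test_that("patient direction matching follows the sign of the log fold", {
  expect_true(patient_match(0.58, 0.93))    # both repressed
  expect_true(patient_match(1.27, 1.14))    # both induced
  expect_false(patient_match(0.58, 1.14))   # opposite directions
  expect_false(patient_match(1.0, 0.5))     # fold exactly 1: no direction
  expect_false(patient_match(1.0, 2.0))
  expect_error(patient_match(-1, 2), "invalid input")
  expect_error(patient_match(2, 0), "invalid input")
})

test_that("percent accuracy reproduces the published panel values", {
  counts <- utils::read.csv(extdata("table2_match_counts_synthetic.csv"))
  expected <- c(SLC19A1 = 100, PPARD = 92.42, TPH1 = 84.85, CD36 = 81.82,
                VIP = 81.82, SERT = 75.76, VSIG2 = 72.73)
  for (g in names(expected)) {
    reps <- counts[counts$gene == g, ]
    expect_equal(percent_accuracy(reps), unname(expected[g]),
                 label = sprintf("accuracy of %s", g))
  }
})

test_that("percent accuracy equals the literal formula on random fixtures", {
  withr::with_seed(909, {
    for (i in 1:30) {
      R <- sample(1:8, 1)
      y <- sample(3:11, R, replace = TRUE)
      x <- vapply(y, function(yy) sample(0:yy, 1), integer(1))
      expect_equal(percent_accuracy(data.frame(x = x, y = y)),
                   literal_percent_accuracy(x, y),
                   label = sprintf("fixture %d", i))
    }
  })
})

test_that("percent accuracy respects bounds, order and replication invariances", {
  reps <- data.frame(x = c(9, 8, 8), y = 11)
  expect_equal(percent_accuracy(reps), percent_accuracy(reps[c(3, 1, 2), ]))
  expect_equal(percent_accuracy(rbind(reps, reps)), percent_accuracy(reps))
  expect_equal(percent_accuracy(data.frame(x = c(11, 11), y = 11)), 100)
  expect_equal(percent_accuracy(data.frame(x = c(0, 0), y = c(5, 7))), 0)
  expect_error(percent_accuracy(data.frame(x = integer(), y = integer())),
               "insufficient data")
  expect_error(percent_accuracy(data.frame(x = 12, y = 11)),
               "invariant violation")
})

test_that("gene scoring builds per-replicate counts with varying y", {
  est <- data.frame(
    gene = "G",
    subject_id = c("P1", "P2", "P3", "P1", "P2"),
    plate = c(1, 1, 1, 2, 2),
    fold = c(0.5, 0.7, 1.3, 0.6, 0.4)
  )
  sc <- score_gene(est, microarray_fold = 0.8)
  expect_equal(sc$replicates$y, c(3, 2))
  expect_equal(sc$replicates$x, c(2, 2))
  expect_equal(sc$percent_accuracy,
               literal_percent_accuracy(c(2, 2), c(3, 2)))
})

test_that("noise-free end-to-end concordance is 100 for every planted gene", {
  cfg <- study_config(seed = 17, ct_noise_sd = 0)
  truth <- c(A = 0.5, B = 1.7, C = 0.8)
  ct <- simulate_qpcr(cfg, truth, arms = c("pooled_control", "case_patient"))
  est <- ddct_fold(ct, "case_patient", "pooled_control")
  micro <- truth   # microarray direction agrees with the planted folds
  scores <- score_concordance(est, micro)
  expect_equal(scores$percent_accuracy, rep(100, 3))
})

test_that("a null gene scores near 50 percent over many seeds", {
  accs <- vapply(1:40, function(seed) {
    cfg <- study_config(seed = seed, plate_replicates = c(3L, 3L))
    ct <- simulate_qpcr(cfg, c(G = 1.0),
                        arms = c("pooled_control", "case_patient"))
    est <- ddct_fold(ct, "case_patient", "pooled_control")
    score_gene(est, microarray_fold = 0.5)$percent_accuracy
  }, numeric(1))
  expect_equal(mean(accs), 50, tolerance = 0.15)
})

test_that("panel selection applies the three criteria and the 84.2 mean", {
  panel_tbl <- utils::read.csv(extdata("table2_panel.csv"))
  scores <- data.frame(gene = panel_tbl$gene,
                       percent_accuracy = panel_tbl$percent_accuracy)
  summaries <- data.frame(gene = panel_tbl$gene,
                          passes_replicate_filter = TRUE)
  flags <- stats::setNames(rep(TRUE, nrow(panel_tbl)), panel_tbl$gene)
  sel <- select_panel(scores, summaries, flags = flags, threshold = 70)
  expect_true(all(sel$selection$in_panel))
  expect_equal(sel$panel_mean_accuracy, 84.2)

  # threshold boundary: 70.00 passes, 69.99 does not
  boundary <- data.frame(gene = c("AT", "BELOW"),
                         percent_accuracy = c(70.00, 69.99))
  bsum <- data.frame(gene = c("AT", "BELOW"), passes_replicate_filter = TRUE)
  bflags <- c(AT = TRUE, BELOW = TRUE)
  bsel <- select_panel(boundary, bsum, flags = bflags)$selection
  expect_true(bsel$in_panel[bsel$gene == "AT"])
  expect_false(bsel$in_panel[bsel$gene == "BELOW"])

  # a missing relevance flag or failed replicate filter blocks membership
  noflag <- select_panel(scores, summaries, flags = NULL)$selection
  expect_false(any(noflag$in_panel))
  summaries2 <- summaries
  summaries2$passes_replicate_filter[1] <- FALSE
  sel2 <- select_panel(scores, summaries2, flags = flags)$selection
  expect_false(sel2$in_panel[sel2$gene == summaries2$gene[1]])
  # empty panel is a valid outcome
  empty <- select_panel(scores, summaries, flags = flags, threshold = 101)
  expect_true(is.na(empty$panel_mean_accuracy))
})
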