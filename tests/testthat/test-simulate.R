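test_that("default cohort reproduces the study margins exactly", {
  cohort <- simulate_cohort(study_config(seed = 11))
  expect_equal(nrow(cohort), 29L)
  expect_equal(sum(cohort$classification == "control"), 18L)
  expect_equal(sum(cohort$classification == "case"), 11L)
  cases <- cohort[cohort$classification == "case", ]
  expect_equal(as.vector(table(cases$sex)[c("F", "M")]), c(8L, 3L))
  ctrl <- cohort[cohort$classification == "control", ]
  expect_equal(as.vector(table(ctrl$sex)[c("F", "M")]), c(12L, 6L))
  expect_equal(sum(cases$subtype == "IBS-C"), 1L)
  expect_equal(sum(cases$subtype == "IBS-D"), 4L)
  expect_equal(sum(cases$subtype == "IBS-M"), 5L)
  expect_equal(sum(cases$subtype == "unknown"), 1L)
  expect_true(all(ctrl$subtype == "none"))
  expect_true(all(cohort$age > 0))
  expect_false(anyDuplicated(cohort$sample_id) > 0)
})

test_that("degenerate cohorts and invalid configs are handled", {
  one <- simulate_cohort(sim_config(seed = 1, n_cases = 0L, n_controls = 1L))
  expect_equal(nrow(one), 1L)
  expect_equal(one$classification, "control")
  expect_error(sim_config(n_cases = -1), "invalid config")
  expect_error(sim_config(n_genes = 0), "invalid config")
  expect_error(sim_config(n_genes = 10, n_de_genes = 11), "invalid config")
  expect_error(sim_config(ct_noise_sd = -1), "invalid config")
  expect_error(sim_config(treatment_fold_map = c(A = -2)), "invalid config")
})

test_that("generators are bit-identical under the same seed and differ across seeds", {
  cfg <- tiny_config(seed = 42)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  ch <- simulate_cohort(cfg)
  expect_identical(simulate_microarray(cfg, ch)$values,
                   simulate_microarray(cfg, ch)$values)
  truth <- c(A = 2, B = 0.5)
  expect_identical(simulate_qpcr(cfg, truth), simulate_qpcr(cfg, truth))
  cfg2 <- tiny_config(seed = 43)
  expect_false(identical(simulate_microarray(cfg, ch)$values,
                         simulate_microarray(cfg2, ch)$values))
})

test_that("noise-free microarray recovers the planted effect exactly", {
  cfg <- tiny_config(seed = 5, array_noise_sd = 1e-12)
  ch <- simulate_cohort(cfg)
  e <- simulate_microarray(cfg, ch)
  is_case <- ch$classification == "case"
  for (g in names(e$planted_truth)) {
    diff <- mean(e$values[g, is_case]) - mean(e$values[g, !is_case])
    expect_equal(diff, unname(e$planted_truth[g]), tolerance = 1e-8)
  }
  # non-planted genes show no group difference
  null_gene <- setdiff(e$gene_ids, names(e$planted_truth))[1]
  expect_equal(mean(e$values[null_gene, is_case]),
               mean(e$values[null_gene, !is_case]), tolerance = 1e-8)
})

test_that("noise-free qPCR encodes one cycle per planted doubling", {
  cfg <- tiny_config(seed = 9, ct_noise_sd = 0)
  ct <- simulate_qpcr(cfg, c(FLAT = 1, DOUBLE = 2),
                      arms = c("vehicle", "treated"))
  arm_mean <- function(g, a) mean(ct$ct[ct$gene == g & ct$arm == a])
  expect_equal(arm_mean("FLAT", "treated"), arm_mean("FLAT", "vehicle"))
  expect_equal(arm_mean("DOUBLE", "vehicle") - arm_mean("DOUBLE", "treated"),
               1)
})

test_that("qPCR tables satisfy their structural invariants", {
  cfg <- study_config(seed = 2, patient_missing_rate = 0.15)
  ct <- simulate_qpcr(cfg, c(A = 0.5, B = 2, C = 1),
                      arms = c("pooled_control", "case_patient"))
  expect_silent(validate_ct_table(ct))
  expect_true(all(ct$ct > 0 & ct$ct < 45))
  # pooled arm is a single aggregate subject
  expect_equal(unique(ct$subject_id[ct$arm == "pooled_control"]), "POOL")
  # dropout makes the number of patients vary by plate but never reach zero
  per_plate <- table(ct$gene[ct$arm == "case_patient"],
                     ct$plate[ct$arm == "case_patient"])
  expect_true(all(per_plate[per_plate > 0] >= 1))
  expect_error(simulate_qpcr(cfg, c(A = -1)), "folds must be > 0")
  expect_error(simulate_qpcr(cfg, unname(c(1, 2))), "named")
})

test_that("cohort and Ct readers validate on load", {
  cohort <- read_cohort(extdata("table1_cohort.csv"))
  expect_equal(nrow(cohort), 29L)
  bad <- cohort
  bad$subtype[bad$classification == "control"][1] <- "IBS-D"
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, tmp, row.names = FALSE)
  expect_error(read_cohort(tmp), "if and only if")
})

test_that("expression round-trips through the TSV dialect", {
  cfg <- tiny_config(seed = 3)
  ch <- simulate_cohort(cfg)
  e <- simulate_microarray(cfg, ch)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(e, tmp)
  back <- read_expression_matrix(tmp)
  expect_equal(back$values, e$values, tolerance = 1e-12)
  expect_equal(back$sample_ids, e$sample_ids)
})
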