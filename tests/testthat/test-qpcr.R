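make_ct <- function(gene, arm, subject, plate, ct) {
  data.frame(gene = gene, arm = arm, subject_id = subject, plate = plate,
             well = stats::ave(seq_along(ct),
                               paste(gene, arm, subject, plate),
                               FUN = seq_along),
             ct = ct, stringsAsFactors = FALSE)
}

test_that("ddCt arithmetic recovers textbook cases", {
  # equal arms -> fold 1
  ct <- rbind(make_ct("A", "vehicle", "S", 1, c(24, 24)),
              make_ct("A", "treated", "S", 1, c(24, 24)))
  expect_equal(ddct_fold(ct, "treated", "vehicle")$fold, 1)
  # one cycle lower -> fold 2
  ct2 <- rbind(make_ct("A", "vehicle", "S", 1, c(24, 24)),
               make_ct("A", "treated", "S", 1, c(23, 23)))
  expect_equal(ddct_fold(ct2, "treated", "vehicle")$fold, 2)
  # wells are averaged before differencing
  ct3 <- rbind(make_ct("A", "vehicle", "S", 1, c(25, 23)),
               make_ct("A", "treated", "S", 1, c(26, 24)))
  expect_equal(ddct_fold(ct3, "treated", "vehicle")$fold, 0.5)
})

test_that("reference-gene normalization cancels loading differences", {
  # target shifted by +2 cycles in treated arm, housekeeping shifted equally:
  # full ddCt must report fold 1
  ct <- rbind(make_ct("TARGET", "vehicle", "S", 1, c(24, 24)),
              make_ct("TARGET", "treated", "S", 1, c(26, 26)),
              make_ct("HK", "vehicle", "S", 1, c(20, 20)),
              make_ct("HK", "treated", "S", 1, c(22, 22)))
  est <- ddct_fold(ct, "treated", "vehicle", use_reference_gene = TRUE,
                   reference_gene = "HK")
  expect_equal(est$fold, 1)
  expect_false("HK" %in% est$gene)
  expect_error(ddct_fold(ct, "treated", "vehicle",
                         use_reference_gene = TRUE, reference_gene = "NOPE"),
               "not found")
})

test_that("plates without a comparator are skipped; all-missing errors", {
  ct <- rbind(make_ct("A", "vehicle", "S", 1, c(24, 24)),
              make_ct("A", "treated", "S", 1, c(23, 23)),
              make_ct("A", "treated", "S", 2, c(23, 23)))
  expect_warning(est <- ddct_fold(ct, "treated", "vehicle"), "skipping")
  expect_equal(est$plate, 1)
  only_target <- make_ct("A", "treated", "S", 1, c(23, 23))
  expect_error(ddct_fold(only_target, "treated", "vehicle"),
               "both arms")
})

test_that("gene summaries compute plate-level mean, SEM and the filter", {
  est <- data.frame(gene = "A", subject_id = "S", plate = 1:2,
                    fold = c(0.5, 0.7))
  s <- summarize_gene(est)
  expect_equal(s$mean_fold, 0.6)
  expect_equal(s$sem, 0.1)
  expect_equal(s$n_plates, 2L)
  expect_true(s$passes_replicate_filter)
  # single plate: filter fails, sem 0 by convention
  s1 <- summarize_gene(est[1, ])
  expect_false(s1$passes_replicate_filter)
  expect_equal(s1$sem, 0)
  # identical plates: zero dispersion
  s3 <- summarize_gene(data.frame(gene = "A", subject_id = "S", plate = 1:4,
                                  fold = 0.8))
  expect_equal(s3$sem, 0)
  # subjects are averaged within plate before plate-level statistics
  est_multi <- data.frame(gene = "A", subject_id = c("P1", "P2", "P1", "P2"),
                          plate = c(1, 1, 2, 2), fold = c(0.4, 0.6, 0.6, 0.8))
  expect_equal(summarize_gene(est_multi)$mean_fold, 0.6)
})

test_that("adding a plate never un-passes the replicate filter", {
  est <- data.frame(gene = "A", subject_id = "S", plate = 1:2,
                    fold = c(1.1, 1.3))
  before <- summarize_gene(est)$passes_replicate_filter
  more <- rbind(est, data.frame(gene = "A", subject_id = "S", plate = 3,
                                fold = 0.9))
  after <- summarize_gene(more)$passes_replicate_filter
  expect_true(!before || after)
})

test_that("reciprocal designs invert the fold exactly without noise", {
  cfg <- tiny_config(seed = 13, ct_noise_sd = 0)
  ct <- simulate_qpcr(cfg, c(G = 2.5), arms = c("vehicle", "treated"))
  fwd <- ddct_fold(ct, "treated", "vehicle")
  rev <- ddct_fold(ct, "vehicle", "treated")
  expect_equal(mean(fwd$fold) * mean(rev$fold), 1, tolerance = 1e-10)
})

test_that("planted patient folds are recovered through the full qPCR path", {
  # TPH1-like repression (0.58): per-seed cohort recovery within 10%
  cfg <- study_config(seed = 1, plate_replicates = c(3L, 3L))
  ct <- simulate_qpcr(cfg, c(TPH1 = 0.58),
                      arms = c("pooled_control", "case_patient"))
  est <- ddct_fold(ct, "case_patient", "pooled_control")
  s <- summarize_gene(est)
  expect_equal(s$mean_fold, 0.58, tolerance = 0.10)

  # mean over 20 seeds at 6 wells: within 5% of planted truth
  folds <- vapply(1:20, function(seed) {
    cfg_i <- study_config(seed = seed, well_replicates = c(6L, 6L))
    ct_i <- simulate_qpcr(cfg_i, c(G = 0.58),
                          arms = c("pooled_control", "case_patient"))
    summarize_gene(ddct_fold(ct_i, "case_patient", "pooled_control"))$mean_fold
  }, numeric(1))
  expect_equal(mean(folds), 0.58, tolerance = 0.05)
})

test_that("patient-first aggregation yields per-patient and cohort folds", {
  est <- data.frame(gene = "A",
                    subject_id = rep(c("P1", "P2"), each = 2),
                    plate = c(1, 2, 1, 2),
                    fold = c(0.4, 0.6, 1.0, 1.4))
  pf <- patient_folds(est)
  expect_equal(pf$fold[pf$subject_id == "P1"], 0.5)
  expect_equal(pf$fold[pf$subject_id == "P2"], 1.2)
  cf <- cohort_fold(est)
  expect_equal(cf$fold, 0.85)
  expect_equal(cf$n_patients, 2L)
})
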