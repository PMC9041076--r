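# Synthetic cohort generator: determinism, label bookkeeping, planted
# effects, configuration validation.

small_cfg <- function(...) {
  defaults <- list(n_hcv_positive = 6, n_svr_daa = 3, n_svr_ifn = 5,
                   n_svr_other = 1, n_true_variants = 25, artifact_rate = 6,
                   n_genes = 600, seed = 3)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

test_that("default strata are 34/8/24/3 and invalid configs are rejected", {
  cfg <- cohort_config()
  expect_identical(c(cfg$n_hcv_positive, cfg$n_svr_daa, cfg$n_svr_ifn,
                     cfg$n_svr_other), c(34, 8, 24, 3))
  b <- simulate_cohort(cohort_config(seed = 1))
  expect_identical(nrow(b$clinical), 69L)
  expect_identical(as.integer(table(b$clinical$group)[c("HCV_POSITIVE",
                     "SVR_DAA", "SVR_IFN", "SVR_OTHER")]),
                   c(34L, 8L, 24L, 3L))
  expect_error(cohort_config(n_hcv_positive = -1), "stratum")
  expect_error(cohort_config(n_hcv_positive = 0, n_svr_daa = 0,
                             n_svr_ifn = 0, n_svr_other = 0), "stratum")
  expect_error(cohort_config(signature_mixture = c(Signature.1 = 0.5)))
})

test_that("a fixed seed reproduces byte-identical outputs; seeds differ", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  simulate_cohort(small_cfg(seed = 5), out_dir = d1)
  simulate_cohort(small_cfg(seed = 5), out_dir = d2)
  simulate_cohort(small_cfg(seed = 6), out_dir = d3)
  ck1 <- report_checksums(d1); ck2 <- report_checksums(d2)
  ck3 <- report_checksums(d3)
  expect_identical(unname(ck1), unname(ck2))
  expect_false(identical(unname(ck1[["variants.maf.tsv"]]),
                         unname(ck3[["variants.maf.tsv"]])))
})

test_that("artifact bookkeeping matches the emitted truth labels", {
  b <- simulate_cohort(small_cfg(seed = 8))
  expect_identical(nrow(b$truth), nrow(b$variants))
  expect_identical(sum(b$truth$is_artifact),
                   sum(!is.na(b$truth$violated_criterion)))
  # artifact_rate 0 emits only true somatic variants
  b0 <- simulate_cohort(small_cfg(seed = 8, artifact_rate = 0))
  expect_identical(sum(b0$truth$is_artifact), 0L)
  expect_true(all(filter_cohort(b0$variants)$verdicts$passed))
})

test_that("driver prevalences land on the configured per-group counts", {
  b <- simulate_cohort(cohort_config(seed = 2))
  flags <- b$driver_flags
  grp <- b$clinical$group
  expect_identical(sum(flags[grp == "HCV_POSITIVE", "ARID2"]), 6L)
  expect_identical(sum(flags[grp != "HCV_POSITIVE", "ARID2"]), 1L)
  expect_identical(sum(flags[grp != "HCV_POSITIVE", "PREX2"]), 4L)
  expect_identical(sum(flags[grp == "SVR_DAA", "PREX2"]), 1L)
  expect_identical(sum(flags[grp == "SVR_IFN", "PREX2"]), 3L)
  # flagged drivers appear as variants in those samples
  carriers <- rownames(flags)[flags[, "ARID2"]]
  with_arid2 <- unique(b$variants$sample[b$variants$gene == "ARID2"])
  expect_true(all(carriers %in% with_arid2))
})

test_that("planted expression effects shift set means by the configured amount", {
  cfg <- cohort_config(seed = 12)
  ex <- simulate_expression_cohort(cfg)
  sets <- ex$gene_sets
  meta <- ex$meta
  m <- ex$matrix
  tum <- meta$tissue == "TUMOR"
  daa <- tum & meta$group == "SVR_DAA"
  ifn <- tum & meta$group == "SVR_IFN"
  g <- sets$TP53_INACTIVATION$genes
  diff <- mean(m[g, daa]) - mean(m[g, ifn])
  se <- cfg$gene_noise_sd * sqrt(1 / sum(daa) + 1 / sum(ifn))
  expect_lt(abs(diff - 1), 3 * se)
  # immune suppression applies to SVR normal liver, not tumors
  cyt <- sets$CYTOLYTIC_ACTIVITY$genes
  nsvr <- meta$tissue == "NORMAL" & meta$group != "HCV_POSITIVE"
  npos <- meta$tissue == "NORMAL" & meta$group == "HCV_POSITIVE"
  expect_lt(mean(m[cyt, nsvr]) - mean(m[cyt, npos]), -0.5)
})

test_that("DAA tumors carry more deleted segments on average", {
  b <- simulate_cohort(cohort_config(seed = 14))
  seg <- classify_segments(b$segments)
  burden <- compare_cnv_burden(seg, b$clinical, c("SVR_DAA", "SVR_IFN"))
  loss <- burden$per_sample$LOSS
  grp <- burden$per_sample$group
  expect_gt(mean(loss[grp == "SVR_DAA"]), mean(loss[grp == "SVR_IFN"]))
})

test_that("clinical covariates respect their invariants", {
  b <- simulate_cohort(small_cfg(seed = 19))
  cl <- b$clinical
  expect_true(all(cl$os_months >= 0 & cl$rfs_months >= 0))
  expect_true(all(cl$os_event %in% 0:1 & cl$rfs_event %in% 0:1))
  expect_true(all(cl$ihc_p53_percent >= 0 & cl$ihc_p53_percent <= 100))
  expect_true(all(cl$tumor_content > 0 & cl$tumor_content < 1))
  expect_true(all(cl$stage %in% c("I", "II", "III", "IV")))
  # null-type records are internally consistent
  expect_true(all(cl$ihc_any_reaction | cl$ihc_p53_percent == 0))
})
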