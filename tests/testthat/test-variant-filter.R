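# Ten-criterion somatic filtering and its audit trail.

clean_snv <- function(...) {
  v <- list(chrom = "1", pos = 1000L, ref = "C", alt = "T",
            variant_type = "SNV", quality_score = 100, depth = 120,
            vaf_tumor = 30, vaf_normal = 0.5, var_reads_fwd = 15L,
            var_reads_rev = 18L, avg_clipped_length = 110,
            avg_pos_as_fraction = 0.45, ref_mapq0 = 0L, ref_mapq1 = 90L,
            var_mapq0 = 0L, var_mapq1 = 33L, avg_read_len_ref = 150,
            avg_read_len_var = 152, gene = "TP53", effect = "missense")
  mods <- list(...)
  v[names(mods)] <- mods
  v
}

test_that("each criterion fires alone on a targeted violation", {
  cases <- list(
    list(mod = list(quality_score = 49), crit = 1L),
    list(mod = list(depth = 19), crit = 2L),
    list(mod = list(vaf_normal = 2.6), crit = 3L),
    list(mod = list(var_reads_rev = 0L), crit = 4L),
    list(mod = list(avg_clipped_length = 89.9), crit = 5L),
    list(mod = list(avg_pos_as_fraction = 0.049), crit = 6L),
    list(mod = list(var_mapq0 = 10L, var_mapq1 = 7L,
                    ref_mapq0 = 60L, ref_mapq1 = 40L), crit = 7L),
    list(mod = list(avg_read_len_var = 69), crit = 8L),
    list(mod = list(var_mapq0 = 6L, var_mapq1 = 6L,
                    ref_mapq0 = 0L, ref_mapq1 = 150L), crit = 9L))
  for (cs in cases) {
    v <- do.call(clean_snv, cs$mod)
    verdict <- apply_filters(v)
    expect_false(verdict$passed)
    expect_identical(verdict$failed_criteria, cs$crit)
  }
})

test_that("depth and control-VAF thresholds switch on variant type", {
  # depth 49 removes an indel but not an SNV
  expect_identical(apply_filters(clean_snv(depth = 49))$failed_criteria,
                   integer(0))
  ind <- clean_snv(variant_type = "INS", depth = 49, vaf_normal = 0)
  expect_identical(apply_filters(ind)$failed_criteria, 2L)
  # any control VAF above zero removes an indel
  ind2 <- clean_snv(variant_type = "DEL", vaf_normal = 0.1)
  expect_identical(apply_filters(ind2)$failed_criteria, 3L)
})

test_that("boundary values survive every strict inequality", {
  v <- clean_snv(quality_score = 50, depth = 20, vaf_normal = 2.5,
                 var_reads_fwd = 3L, var_reads_rev = 3L,
                 avg_clipped_length = 90, avg_pos_as_fraction = 0.05,
                 var_mapq0 = 5L, var_mapq1 = 4L,  # ratio 0.8 exactly
                 ref_mapq0 = 90L, ref_mapq1 = 30L,
                 avg_read_len_ref = 150, avg_read_len_var = 70)  # diff 80
  verdict <- apply_filters(v)
  expect_true(verdict$passed)
  expect_length(verdict$failed_criteria, 0)
})

test_that("missing metrics and unknown types are named errors", {
  v <- clean_snv(); v$depth <- NULL
  expect_error(apply_filters(v), "depth")
  expect_error(apply_filters(clean_snv(variant_type = "SV")),
               "unknown variant_type")
})

test_that("blacklist membership is criterion 10", {
  bl <- data.frame(chrom = "1", pos = 1000L, ref = "C", alt = "T")
  th <- filter_thresholds(blacklist = bl)
  expect_identical(apply_filters(clean_snv(), th)$failed_criteria, 10L)
  other <- clean_snv(pos = 2000L)
  expect_true(apply_filters(other, th)$passed)
})

test_that("verdicts match the rule-by-rule oracle on randomized variants", {
  set.seed(42)
  variants <- random_variants(400)
  for (i in seq_len(nrow(variants))) {
    got <- apply_filters(variants[i, ])
    expect_identical(got$failed_criteria, oracle_verdict(variants[i, ]),
                     info = paste("variant", i))
  }
})

test_that("relaxing a single threshold never removes a passing variant", {
  set.seed(7)
  variants <- random_variants(150)
  base <- filter_thresholds()
  relaxed <- list(
    filter_thresholds(min_quality = 40),
    filter_thresholds(min_depth_snv = 10, min_depth_indel = 30),
    filter_thresholds(max_normal_vaf_snv = 5, max_normal_vaf_indel = 1),
    filter_thresholds(min_clipped_length = 70),
    filter_thresholds(min_pos_fraction = 0.01),
    filter_thresholds(min_mapq_ratio = 0.5),
    filter_thresholds(max_len_diff = 120),
    filter_thresholds(mapq0_fisher_alpha = 0.01))
  for (i in seq_len(nrow(variants))) {
    if (!apply_filters(variants[i, ], base)$passed) next
    for (th in relaxed) {
      expect_true(apply_filters(variants[i, ], th)$passed)
    }
  }
})

test_that("mapq0_fisher handles degenerate tables", {
  expect_identical(mapq0_fisher(10, 50, 0, 20), 1)
  expect_warning(p <- mapq0_fisher(0, 0, 0, 0), "all-zero")
  expect_identical(p, 1)
  # balanced table shows no enrichment
  expect_gt(mapq0_fisher(5, 5, 5, 5), 0.1)
})

test_that("filter_cohort conserves totals and attributes artifacts to their criterion", {
  cfg <- cohort_config(n_hcv_positive = 4, n_svr_daa = 2, n_svr_ifn = 4,
                       n_svr_other = 0, n_true_variants = 30,
                       artifact_rate = 10, seed = 11)
  b <- simulate_cohort(cfg)
  res <- filter_cohort(b$variants)
  expect_identical(nrow(res$passed) + sum(!res$verdicts$passed),
                   nrow(b$variants))
  expect_identical(sum(res$summary$total), nrow(b$variants))
  # every artifact removed, attributed to exactly the violated criterion
  expect_identical(res$verdicts$passed, !b$truth$is_artifact)
  art <- which(b$truth$is_artifact)
  expect_identical(as.integer(res$verdicts$failed_criteria[art]),
                   b$truth$violated_criterion[art])
  # per-criterion removal counts sum to at least the removed total
  crit_cols <- grep("^crit_", names(res$summary))
  expect_true(all(rowSums(res$summary[crit_cols]) >= res$summary$removed))
})

test_that("an empty table filters to an empty result", {
  res <- filter_cohort(data.frame())
  expect_identical(nrow(res$summary), 0L)
  expect_identical(nrow(res$verdicts), 0L)
})
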