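# Catalogue loading, driver annotation, TMB, frequency tables, and the
# integrative expression x copy-number caller.

test_that("the packaged catalogue has the expected structure", {
  cat0 <- load_gene_catalogue()
  expect_true(all(c("TP53", "CTNNB1", "ARID2", "PREX2", "KEAP1") %in% cat0$gene))
  expect_identical(cat0$role[cat0$gene == "TP53"], "TSG")
  expect_identical(cat0$role[cat0$gene == "CTNNB1"], "ONCOGENE")
  expect_false(anyDuplicated(cat0$gene) > 0)
})

test_that("driver annotation flags catalogue genes only", {
  v <- data.frame(sample = "S1", gene = c("TP53", "NOT_A_GENE"))
  ann <- annotate_drivers(v)
  expect_identical(ann$driver, c(TRUE, FALSE))
  expect_identical(ann$driver_role, c("TSG", "NONE"))
  empty_cat <- load_gene_catalogue()[0, ]
  expect_identical(sum(annotate_drivers(v, empty_cat)$driver), 0L)
})

test_that("TMB is mutations per megabase with a guarded denominator", {
  expect_equal(compute_tmb(348, 34.8), 10)
  expect_equal(compute_tmb(data.frame(x = numeric(0)), 34.8), 0)
  expect_equal(compute_tmb(348, 57.7), 348 / 57.7)
  expect_error(compute_tmb(10, 0), "positive")
})

test_that("frequency matrix equals a direct recount and prints half-up percents", {
  clinical <- data.frame(sample = sprintf("S%02d", 1:69),
                         group = rep(c("HCV_POSITIVE", "SVR"), c(34, 35)))
  # ARID2 in 6 positives and 1 SVR; PREX2 in 1 positive, 4 SVR; a sample with
  # two PREX2 mutations still counts once
  v <- data.frame(
    sample = c(sprintf("S%02d", 1:6), "S40", "S01",
               sprintf("S%02d", 36:39), "S36"),
    gene = c(rep("ARID2", 7), rep("PREX2", 6)))
  freq <- mutation_frequency_matrix(v, clinical)
  get <- function(g, gr, col) freq[freq$gene == g & freq$group == gr, col]
  expect_identical(get("ARID2", "HCV_POSITIVE", "mutated"), 6L)
  expect_identical(get("ARID2", "HCV_POSITIVE", "percent"), 17.6)
  expect_identical(get("ARID2", "SVR", "percent"), 2.9)
  expect_identical(get("PREX2", "SVR", "mutated"), 4L)
  expect_identical(get("PREX2", "SVR", "percent"), 11.4)
  expect_identical(get("PREX2", "HCV_POSITIVE", "percent"), 2.9)
  expect_true(all(freq$mutated <= freq$total))
  # recount oracle over a random table
  set.seed(9)
  v2 <- data.frame(sample = sample(clinical$sample, 60, replace = TRUE),
                   gene = sample(c("TP53", "CTNNB1", "KEAP1"), 60, TRUE))
  freq2 <- mutation_frequency_matrix(v2, clinical)
  for (i in seq_len(nrow(freq2))) {
    members <- clinical$sample[clinical$group == freq2$group[i]]
    expect_identical(freq2$mutated[i],
                     length(unique(v2$sample[v2$gene == freq2$gene[i] &
                                               v2$sample %in% members])))
  }
  expect_error(mutation_frequency_matrix(
    data.frame(sample = "NOPE", gene = "TP53"), clinical), "missing a group")
})

amp_fixture <- function(folds, cns, role = "ONCOGENE") {
  genes <- paste0("G", seq_along(folds))
  tum <- matrix(log2(folds), ncol = 1, dimnames = list(genes, "S1"))
  nor <- matrix(0, nrow = length(folds), ncol = 1,
                dimnames = list(genes, "S1"))
  cn <- matrix(cns, ncol = 1, dimnames = list(genes, "S1"))
  cat0 <- data.frame(gene = genes, role = role, source = "x")
  call_expression_cnv_aberrations(tum, nor, cn, cat0)$calls
}

test_that("integrative caller applies inclusive five-fold and copy thresholds", {
  calls <- amp_fixture(c(5.0, 4.99, 6.0, 6.0), c(2.5, 3.0, 2.49, 2.0))
  expect_identical(calls$call, c("AMPLIFIED", "NONE", "NONE", "NONE"))
  del <- amp_fixture(c(0.2, 0.21, 0.1, 0.2), c(1.5, 1.0, 1.51, 1.6),
                     role = "TSG")
  expect_identical(del$call, c("DELETED", "NONE", "NONE", "NONE"))
  # role gates the direction: an oncogene is never DELETED
  onc_low <- amp_fixture(0.1, 1.0)
  expect_identical(onc_low$call, "NONE")
})

test_that("caller results are invariant to gene and sample order, and recall is total on planted events", {
  set.seed(10)
  genes <- paste0("G", 1:20)
  tum <- matrix(rnorm(20 * 6, 0, 0.2), nrow = 20,
                dimnames = list(genes, paste0("S", 1:6)))
  nor <- matrix(0, nrow = 20, ncol = 6, dimnames = dimnames(tum))
  cn <- matrix(2, nrow = 20, ncol = 6, dimnames = dimnames(tum))
  # plant amplifications meeting both thresholds, and near-misses
  tum["G3", "S2"] <- 3.1; cn["G3", "S2"] <- 3       # hit
  tum["G5", "S4"] <- 3.1; cn["G5", "S4"] <- 2.4     # CN fails
  tum["G7", "S5"] <- 2.0; cn["G7", "S5"] <- 3       # fold fails
  cat0 <- data.frame(gene = genes, role = "ONCOGENE", source = "x")
  res <- call_expression_cnv_aberrations(tum, nor, cn, cat0)$calls
  hits <- res[res$call == "AMPLIFIED", ]
  expect_identical(paste(hits$sample, hits$gene), "S2 G3")
  perm_g <- sample(20); perm_s <- sample(6)
  res2 <- call_expression_cnv_aberrations(tum[perm_g, perm_s],
                                          nor[perm_g, perm_s],
                                          cn[perm_g, perm_s], cat0)$calls
  hits2 <- res2[res2$call == "AMPLIFIED", ]
  expect_identical(paste(hits2$sample, hits2$gene), "S2 G3")
})

test_that("samples without a matched normal are skipped with a warning", {
  tum <- matrix(3, 1, 2, dimnames = list("G1", c("S1", "S2")))
  nor <- matrix(0, 1, 1, dimnames = list("G1", "S1"))
  cn <- matrix(3, 1, 2, dimnames = list("G1", c("S1", "S2")))
  cat0 <- data.frame(gene = "G1", role = "ONCOGENE", source = "x")
  expect_warning(res <- call_expression_cnv_aberrations(tum, nor, cn, cat0),
                 "S2")
  expect_identical(unique(res$calls$sample), "S1")
})

test_that("gene-level copy number takes the narrowest covering segment", {
  gp <- data.frame(gene = c("G1", "G2"), chrom = c("1", "2"),
                   midpoint = c(500L, 500L))
  seg <- data.frame(sample = "S1", chrom = c("1", "1", "2"),
                    start = c(1L, 400L, 1L), end = c(1000L, 600L, 400L),
                    copy_number = c(2, 1.2, 3.5))
  cn <- gene_level_copy_number(gp, seg)
  expect_equal(cn["G1", "S1"], 1.2)  # focal event wins over background
  expect_equal(cn["G2", "S1"], 2)    # uncovered midpoint defaults to 2
})
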