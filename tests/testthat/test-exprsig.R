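# Normalization, signature scoring, correlation, volcano, clustering, GMT.

test_that("75th-percentile normalization has its defining properties", {
  set.seed(21)
  raw <- matrix(rexp(500, 1 / 500) + 1, nrow = 50,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:10)))
  norm <- normalize_75th(raw)
  expect_true(all(abs(apply(norm, 2, quantile, 0.75)) < 1e-9))
  # idempotence on the log2 scale
  expect_equal(normalize_75th(norm, log2 = TRUE), norm)
  # rescaling a sample's raw values cancels out
  raw2 <- raw; raw2[, 3] <- raw2[, 3] * 2
  expect_equal(normalize_75th(raw2), norm)
  # constant sample maps to zeros
  raw3 <- raw; raw3[, 1] <- 7
  expect_true(all(normalize_75th(raw3)[, 1] == 0))
  raw[2, 2] <- 0
  expect_error(normalize_75th(raw), "g2")
})

test_that("signature scores are set means with coverage bookkeeping", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  sc <- score_signature(m, c("A", "B"))
  expect_equal(unname(sc$score), c(1.5, 4.5))
  expect_equal(sc$coverage, 1)
  # singleton set equals the gene's row
  expect_equal(unname(score_signature(m, "C")$score), unname(m["C", ]))
  # score linearity: set score = mean of singleton scores
  singles <- sapply(c("A", "B", "C"), function(g) score_signature(m, g)$score)
  expect_equal(unname(score_signature(m, c("A", "B", "C"))$score),
               unname(rowMeans(singles)))
  # absent members reduce coverage; full miss errors
  sc2 <- score_signature(m, c("A", "ZZZ"))
  expect_equal(sc2$coverage, 0.5)
  expect_error(score_signature(m, "ZZZ"), "no gene-set member")
})

test_that("the TP53-inactivation score needs all four genes", {
  m <- matrix(2, nrow = 4, ncol = 2,
              dimnames = list(c("CDC20", "PLK1", "CENPA", "KIF2C"),
                              c("s1", "s2")))
  sc <- tp53_inactivation_score(m)
  expect_equal(unname(sc$score), c(2, 2))
  expect_error(tp53_inactivation_score(m[1:3, ]), "KIF2C")
})

test_that("a planted shift moves the group score difference by the shift", {
  set.seed(33)
  genes <- c("CDC20", "PLK1", "CENPA", "KIF2C", paste0("g", 1:200))
  m <- matrix(rnorm(204 * 40, 0, 0.5), nrow = 204,
              dimnames = list(genes, paste0("s", 1:40)))
  mask <- rep(c(TRUE, FALSE), each = 20)
  m2 <- plant_expression_effect(m, genes[1:4], mask, 1)
  sc <- tp53_inactivation_score(m2)
  diff <- mean(sc$score[mask]) - mean(sc$score[!mask])
  se <- 0.5 / sqrt(4) * sqrt(1 / 20 + 1 / 20)
  expect_lt(abs(diff - 1), 3 * se)
  # untouched cells identical; shift 0 is the identity
  expect_identical(m2[5:204, ], m[5:204, ])
  expect_identical(plant_expression_effect(m, genes[1:4], mask, 0), m)
  expect_error(plant_expression_effect(m, c("CDC20", "NOPE"), mask, 1), "NOPE")
})

test_that("score correlation behaves at the monotone extremes", {
  x <- c(1, 3, 7, 9, 12)
  expect_equal(correlate_scores(x, x^3)$rho, 1)
  expect_equal(spearman(x, rev(x))$rho, -1)
  expect_warning(res <- spearman(rep(1, 5), x), "constant")
  expect_true(is.na(res$rho))
})

test_that("volcano ranks a strongly shifted gene first", {
  set.seed(44)
  m <- matrix(rnorm(100 * 32, 0, 0.5), nrow = 100,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:32)))
  mask <- rep(c(TRUE, FALSE), c(8, 24))
  m["g7", mask] <- m["g7", mask] + 2
  res <- volcano(m, mask)
  expect_identical(res$gene[1], "g7")
  expect_gt(res$log2_fc[1], 1.5)
  # fold changes of unshifted genes centered at zero
  expect_lt(abs(mean(res$log2_fc[res$gene != "g7"])), 0.1)
  # BH q is monotone in p-rank
  expect_true(all(diff(res$q) >= -1e-12))
  expect_error(volcano(m, rep(c(TRUE, FALSE), c(1, 31))), "2 samples")
})

test_that("Ward clustering recovers planted classes and is order-invariant", {
  set.seed(55)
  m <- matrix(rnorm(60 * 20), nrow = 60,
              dimnames = list(paste0("g", 1:60), paste0("s", 1:20)))
  m[1:30, 11:20] <- m[1:30, 11:20] + 4
  wc <- ward_cluster(m, k = 2)
  truth <- rep(1:2, each = 10)
  expect_true(length(unique(paste(wc$labels, truth))) == 2)
  # permuting samples leaves merge heights unchanged
  perm <- sample(20)
  wc2 <- ward_cluster(m[, perm], k = 2)
  expect_equal(sort(wc$hclust$height), sort(wc2$hclust$height))
  # duplicated sample merges first at height zero
  m3 <- cbind(m, dup = m[, 1])
  wc3 <- ward_cluster(m3)
  expect_equal(min(wc3$hclust$height), 0)
  expect_match(wc3$newick, "^\\(")
})

test_that("GMT files round-trip and the packaged sets have the stated sizes", {
  sets <- packaged_gene_sets()
  expect_identical(sort(sets$TP53_INACTIVATION$genes),
                   sort(c("CDC20", "PLK1", "CENPA", "KIF2C")))
  expect_length(sets$PI3K_MTOR_UP$genes, 134)
  expect_length(sets$TCELL_INFLAMED$genes, 18)
  expect_identical(sets$CYTOLYTIC_ACTIVITY$genes, c("GZMA", "PRF1"))
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets, ignore_attr = TRUE)
})
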