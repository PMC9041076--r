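# Independent oracles used to cross-check the implementation. These are
# written directly from the rule definitions (closed forms, enumeration),
# deliberately not sharing code with the package.

# rule-by-rule re-evaluation of the ten elimination criteria
oracle_verdict <- function(v, blacklist = NULL) {
  indel <- v$variant_type %in% c("INS", "DEL")
  failed <- c()
  if (v$quality_score < 50) failed <- c(failed, 1)
  if (!indel && v$depth < 20) failed <- c(failed, 2)
  if (indel && v$depth < 50) failed <- c(failed, 2)
  if (!indel && v$vaf_normal > 2.5) failed <- c(failed, 3)
  if (indel && v$vaf_normal > 0) failed <- c(failed, 3)
  if (xor(v$var_reads_fwd > 0, v$var_reads_rev > 0) ||
      (v$var_reads_fwd == 0 && v$var_reads_rev == 0)) failed <- c(failed, 4)
  if (v$avg_clipped_length < 90) failed <- c(failed, 5)
  if (v$avg_pos_as_fraction < 0.05) failed <- c(failed, 6)
  if (v$var_mapq0 > 0 && v$var_mapq1 / v$var_mapq0 < 0.8) failed <- c(failed, 7)
  if (abs(v$avg_read_len_ref - v$avg_read_len_var) > 80) failed <- c(failed, 8)
  if (oracle_mapq0_p(v$ref_mapq0, v$ref_mapq1, v$var_mapq0, v$var_mapq1) < 0.1) {
    failed <- c(failed, 9)
  }
  if (!is.null(blacklist) &&
      any(blacklist$chrom == v$chrom & blacklist$pos == v$pos &
          blacklist$ref == v$ref & blacklist$alt == v$alt)) {
    failed <- c(failed, 10)
  }
  as.integer(failed)
}

# hypergeometric upper tail: P[MAPQ0 count among variant reads >= observed]
oracle_mapq0_p <- function(r0, r1, v0, v1) {
  if (v0 == 0) return(1)
  K <- r0 + v0            # MAPQ0 reads in total
  N <- r0 + r1 + v0 + v1  # all reads
  n <- v0 + v1            # variant-supporting draws
  sum(dhyper(v0:min(K, n), K, N - K, n))
}

# random variant candidates straddling every threshold, boundaries included
random_variants <- function(n) {
  pick <- function(vals) sample(vals, n, replace = TRUE)
  data.frame(
    chrom = as.character(pick(1:5)), pos = sample.int(1e6, n),
    ref = pick(c("A", "C", "G", "T")), alt = pick(c("A", "C", "G", "T")),
    variant_type = pick(c("SNV", "SNV", "INS", "DEL")),
    quality_score = pick(c(10, 49, 49.9, 50, 51, 200)),
    depth = pick(c(5, 19, 20, 49, 50, 150)),
    vaf_tumor = round(runif(n, 1, 90), 1),
    vaf_normal = pick(c(0, 0.5, 2.4, 2.5, 2.6, 10)),
    var_reads_fwd = pick(c(0L, 1L, 8L)), var_reads_rev = pick(c(0L, 1L, 9L)),
    avg_clipped_length = pick(c(50, 89, 89.9, 90, 91, 120)),
    avg_pos_as_fraction = pick(c(0.01, 0.049, 0.05, 0.051, 0.5)),
    ref_mapq0 = pick(c(0L, 1L, 5L, 40L)), ref_mapq1 = pick(c(5L, 50L, 150L)),
    var_mapq0 = pick(c(0L, 0L, 1L, 4L, 10L)),
    var_mapq1 = pick(c(0L, 3L, 8L, 30L)),
    avg_read_len_ref = pick(c(100, 150, 200)),
    avg_read_len_var = pick(c(60, 100, 150, 181, 250)),
    gene = "GENE1", effect = "missense", stringsAsFactors = FALSE)
}

# closed-form chi-squared statistic for a 2x2 table, no correction
oracle_chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# two-sided Fisher p by exhaustive enumeration of tables with fixed margins
oracle_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(ks, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mann_whitney <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  u_stat <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  U_obs <- u_stat(seq_len(n))
  all_u <- combn(n + m, n, u_stat)
  p <- 2 * min(mean(all_u <= U_obs + 1e-9), mean(all_u >= U_obs - 1e-9))
  list(U = U_obs, p = min(1, p))
}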