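# Ten-criterion somatic-variant filtering with a per-criterion audit trail.
#
# A candidate is eliminated when it fulfils at least one criterion:
#   1  quality score < 50
#   2  depth of coverage < 20 (SNV) / < 50 (indel)
#   3  VAF in the matched control > 2.5% (SNV) / > 0% (indel)
#   4  variant reads on only one strand (forward or reverse, not both)
#   5  avg_clipped_length < 90
#   6  variant near read ends (avg_pos_as_fraction < 0.05)
#   7  MAPQ1/MAPQ0 read ratio < 0.8 among variant-supporting reads
#   8  |mean read length of reference reads - variant reads| > 80
#   9  enrichment in MAPQ0 reads (one-sided Fisher p < 0.1)
#   10 membership in a false-positive blacklist
# All inequalities are strict as written, so boundary values survive. All ten
# criteria are always evaluated (no short-circuit) so that the audit trail
# records every violated criterion.

VARIANT_METRIC_FIELDS <- c(
  "chrom", "pos", "ref", "alt", "variant_type", "quality_score", "depth",
  "vaf_tumor", "vaf_normal", "var_reads_fwd", "var_reads_rev",
  "avg_clipped_length", "avg_pos_as_fraction",
  "ref_mapq0", "ref_mapq1", "var_mapq0", "var_mapq1",
  "avg_read_len_ref", "avg_read_len_var")

#' Default somatic-filter thresholds
#'
#' The ten filter cutoffs, calibrated upstream on a validated mutation set and
#' treated here as fixed. VAF thresholds are percentages (2.5 means 2.5%).
#'
#' @param min_quality Minimum caller quality score.
#' @param min_depth_snv,min_depth_indel Minimum tumor depth by variant type.
#' @param max_normal_vaf_snv,max_normal_vaf_indel Maximum VAF (percent) in the
#'   matched control by variant type.
#' @param min_clipped_length Minimum mean clipped length of variant reads.
#' @param min_pos_fraction Minimum mean relative position of the variant
#'   within its reads.
#' @param min_mapq_ratio Minimum MAPQ1/MAPQ0 read ratio among variant reads.
#' @param max_len_diff Maximum |mean reference-read length - mean variant-read
#'   length|.
#' @param mapq0_fisher_alpha One-sided Fisher p cutoff for MAPQ0 enrichment.
#' @param blacklist data.frame with columns chrom, pos, ref, alt (the shipped
#'   default is empty).
#' @return A list of class `svrhcc_thresholds`.
#' @export
filter_thresholds <- function(min_quality = 50, min_depth_snv = 20,
                              min_depth_indel = 50, max_normal_vaf_snv = 2.5,
                              max_normal_vaf_indel = 0, min_clipped_length = 90,
                              min_pos_fraction = 0.05, min_mapq_ratio = 0.8,
                              max_len_diff = 80, mapq0_fisher_alpha = 0.1,
                              blacklist = empty_blacklist()) {
  th <- list(min_quality = min_quality, min_depth_snv = min_depth_snv,
             min_depth_indel = min_depth_indel,
             max_normal_vaf_snv = max_normal_vaf_snv,
             max_normal_vaf_indel = max_normal_vaf_indel,
             min_clipped_length = min_clipped_length,
             min_pos_fraction = min_pos_fraction,
             min_mapq_ratio = min_mapq_ratio, max_len_diff = max_len_diff,
             mapq0_fisher_alpha = mapq0_fisher_alpha, blacklist = blacklist)
  num <- unlist(th[setdiff(names(th), "blacklist")])
  stopifnot(all(is.finite(num)),
            mapq0_fisher_alpha > 0, mapq0_fisher_alpha < 1)
  class(th) <- "svrhcc_thresholds"
  th
}

#' @rdname filter_thresholds
#' @export
empty_blacklist <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), stringsAsFactors = FALSE)
}

#' One-sided Fisher test for MAPQ0 enrichment among variant reads
#'
#' Tests whether MAPQ0 reads are over-represented among variant-supporting
#' reads, on the 2x2 table with rows {reference reads, variant reads} and
#' columns {MAPQ0, MAPQ >= 1}.
#'
#' @param ref_mapq0,ref_mapq1 Reference-supporting read counts with mapping
#'   quality 0 and >= 1.
#' @param var_mapq0,var_mapq1 Variant-supporting read counts likewise.
#' @return One-sided p-value for MAPQ0 over-representation in variant reads.
#' @examples
#' mapq0_fisher(0, 10, 5, 0)  # 1/choose(15, 5)
#' @export
mapq0_fisher <- function(ref_mapq0, ref_mapq1, var_mapq0, var_mapq1) {
  counts <- c(ref_mapq0, ref_mapq1, var_mapq0, var_mapq1)
  stopifnot(all(counts >= 0))
  if (all(counts == 0)) {
    warning("all-zero MAPQ table; p = 1")
    return(1)
  }
  if (var_mapq0 == 0) return(1)
  tab <- matrix(c(ref_mapq0, ref_mapq1, var_mapq0, var_mapq1),
                nrow = 2, byrow = TRUE)
  # odds ratio > 1 <=> MAPQ0 enrichment in the second row (variant reads)
  stats::fisher.test(tab[2:1, ], alternative = "greater")$p.value
}

#' Apply the ten somatic filters to one variant candidate
#'
#' @param variant A one-row data.frame or named list carrying the read-level
#'   metric fields (see `VARIANT_METRIC_FIELDS` in the package source).
#' @param thresholds A [filter_thresholds()] object.
#' @return List of class `svrhcc_verdict`: `passed` and `failed_criteria`
#'   (integer ids in 1..10).
#' @export
apply_filters <- function(variant, thresholds = filter_thresholds()) {
  v <- as.list(variant)
  miss <- VARIANT_METRIC_FIELDS[!vapply(VARIANT_METRIC_FIELDS, function(f)
    !is.null(v[[f]]) && !is.na(v[[f]]), logical(1))]
  if (length(miss)) {
    stop(sprintf("variant missing metric(s): %s", paste(miss, collapse = ", ")))
  }
  if (!v$variant_type %in% c("SNV", "INS", "DEL")) {
    stop(sprintf("unknown variant_type: %s", v$variant_type))
  }
  th <- thresholds
  indel <- v$variant_type %in% c("INS", "DEL")
  failed <- integer(0)
  if (v$quality_score < th$min_quality) failed <- c(failed, 1L)
  if (v$depth < (if (indel) th$min_depth_indel else th$min_depth_snv)) {
    failed <- c(failed, 2L)
  }
  if (v$vaf_normal > (if (indel) th$max_normal_vaf_indel else th$max_normal_vaf_snv)) {
    failed <- c(failed, 3L)
  }
  if (v$var_reads_fwd == 0 || v$var_reads_rev == 0) failed <- c(failed, 4L)
  if (v$avg_clipped_length < th$min_clipped_length) failed <- c(failed, 5L)
  if (v$avg_pos_as_fraction < th$min_pos_fraction) failed <- c(failed, 6L)
  if (v$var_mapq0 > 0 && v$var_mapq1 / v$var_mapq0 < th$min_mapq_ratio) {
    failed <- c(failed, 7L)
  }
  if (abs(v$avg_read_len_ref - v$avg_read_len_var) > th$max_len_diff) {
    failed <- c(failed, 8L)
  }
  p9 <- mapq0_fisher(v$ref_mapq0, v$ref_mapq1, v$var_mapq0, v$var_mapq1)
  if (p9 < th$mapq0_fisher_alpha) failed <- c(failed, 9L)
  bl <- th$blacklist
  if (nrow(bl) && any(bl$chrom == v$chrom & bl$pos == v$pos &
                      bl$ref == v$ref & bl$alt == v$alt)) {
    failed <- c(failed, 10L)
  }
  structure(list(passed = length(failed) == 0L, failed_criteria = failed),
            class = "svrhcc_verdict")
}

#' Filter a cohort of variant tables
#'
#' Applies [apply_filters()] to every row of every per-sample variant table
#' and returns the passing variants together with a per-sample audit summary.
#'
#' @param variants A single variant data.frame (with a `sample` column) or a
#'   named list of per-sample data.frames.
#' @param thresholds A [filter_thresholds()] object.
#' @return List with `passed` (filtered table), `verdicts` (one row per input
#'   variant: sample, index, passed, failed criteria as comma string) and
#'   `summary` (per sample: total, kept, removed, and removed-by-criterion
#'   counts `crit_1` .. `crit_10`; a variant failing several criteria counts
#'   in each, so criterion counts can sum to more than `removed`).
#' @export
filter_cohort <- function(variants, thresholds = filter_thresholds()) {
  if (is.data.frame(variants)) {
    if (!"sample" %in% names(variants)) {
      variants$sample <- rep("sample1", nrow(variants))
    }
    tab <- variants
  } else {
    tab <- do.call(rbind, lapply(names(variants), function(s) {
      x <- variants[[s]]; x$sample <- s; x
    }))
  }
  if (is.null(tab) || nrow(tab) == 0) {
    return(list(passed = tab,
                verdicts = data.frame(sample = character(), index = integer(),
                                      passed = logical(),
                                      failed_criteria = character()),
                summary = data.frame(sample = character(), total = integer(),
                                     kept = integer(), removed = integer())))
  }
  verdicts <- lapply(seq_len(nrow(tab)), function(i)
    apply_filters(tab[i, , drop = FALSE], thresholds))
  pass <- vapply(verdicts, `[[`, logical(1), "passed")
  vdf <- data.frame(
    sample = tab$sample, index = seq_len(nrow(tab)), passed = pass,
    failed_criteria = vapply(verdicts, function(v)
      paste(v$failed_criteria, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  crit_mat <- t(vapply(verdicts, function(v) as.integer(1:10 %in% v$failed_criteria),
                       integer(10)))
  colnames(crit_mat) <- paste0("crit_", 1:10)
  summ <- do.call(rbind, lapply(split(seq_len(nrow(tab)), tab$sample), function(idx) {
    data.frame(sample = tab$sample[idx[1]], total = length(idx),
               kept = sum(pass[idx]), removed = sum(!pass[idx]),
               t(colSums(crit_mat[idx, , drop = FALSE])),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(passed = tab[pass, , drop = FALSE], verdicts = vdf, summary = summ)
}
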