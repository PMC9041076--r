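# Copy-number segment classification and group burden comparison.
#
# Segments are called from three statistics: the segment test p-value, the
# copy-number estimate, and the adjusted mirrored-BAF log-ratio:
#   Gain:            p < 0.001 and copy number >= 2.5
#   Loss:            p < 0.001 and copy number <= 1.5
#   Copy-neutral LOH: p < 0.001, 1.5 < copy number < 2.5, log2 mBAF adj >= 0.2
# The CN-LOH band is open at both ends so the three calls never overlap; at
# copy number exactly 2.5 or 1.5 the explicit >=/<= rules take precedence.

#' Classify one copy-number segment
#'
#' @param copy_number Segment copy-number estimate.
#' @param p_value Segment test p-value.
#' @param log2_mbaf_adj Adjusted mirrored-BAF log-ratio.
#' @return One of `"GAIN"`, `"LOSS"`, `"CN_LOH"`, `"NEUTRAL"`. Vectorized.
#' @examples
#' classify_segment(2.7, 5e-4, 0)     # GAIN
#' classify_segment(2.0, 5e-4, 0.25)  # CN_LOH
#' @export
classify_segment <- function(copy_number, p_value, log2_mbaf_adj) {
  stopifnot(all(copy_number >= 0), all(p_value >= 0), all(p_value <= 1))
  out <- rep("NEUTRAL", length(copy_number))
  sig <- p_value < 0.001
  out[sig & copy_number >= 2.5] <- "GAIN"
  out[sig & copy_number <= 1.5] <- "LOSS"
  out[sig & copy_number > 1.5 & copy_number < 2.5 & log2_mbaf_adj >= 0.2] <- "CN_LOH"
  out
}

#' Classify a table of segments
#'
#' @param segments data.frame with columns `copy_number`, `p_value`,
#'   `log2_mbaf_adj` (and any others, preserved).
#' @return The input with a `call` column appended.
#' @export
classify_segments <- function(segments) {
  stop_missing(segments, c("copy_number", "p_value", "log2_mbaf_adj"),
               "classify_segments")
  segments$call <- classify_segment(segments$copy_number, segments$p_value,
                                    segments$log2_mbaf_adj)
  segments
}

# recursive binary segmentation on mean shift; returns sorted changepoints
# (index of last point of each left segment)
bin_seg <- function(x, min_size, threshold) {
  n <- length(x)
  if (n < 2 * min_size) return(integer(0))
  best_t <- 0; best_i <- NA_integer_
  csum <- cumsum(x); total <- csum[n]
  for (i in min_size:(n - min_size)) {
    m1 <- csum[i] / i
    m2 <- (total - csum[i]) / (n - i)
    s <- stats::sd(x)
    if (s == 0) next
    tstat <- abs(m1 - m2) / (s * sqrt(1 / i + 1 / (n - i)))
    if (tstat > best_t) { best_t <- tstat; best_i <- i }
  }
  if (is.na(best_i) || best_t < threshold) return(integer(0))
  c(bin_seg(x[1:best_i], min_size, threshold), best_i,
    best_i + bin_seg(x[(best_i + 1):n], min_size, threshold))
}

#' Segment per-SNV log-ratios into copy-number segments
#'
#' A plain changepoint stage: recursive binary segmentation on the per-SNV
#' mean log2 depth ratio, then per-segment statistics. This is deliberately
#' simple plumbing upstream of [classify_segment()]; it is not an
#' allele-specific joint segmentation model.
#'
#' Per segment: the p-value is a two-sided one-sample t-test of the log-ratios
#' against 0; the copy number is `2 * 2^mean(log-ratio)`; the mBAF statistic
#' is `log2` of the mean tumor |BAF - 0.5| over the mean normal |BAF - 0.5|.
#'
#' @param snvs data.frame sorted by `pos` with columns `pos`, `log2_ratio`
#'   (tumor/normal depth log-ratio), `baf_tumor`, `baf_normal`.
#' @param sample,chrom Labels carried into the output.
#' @param min_snvs Minimum SNVs per segment; fewer input SNVs than this give
#'   a single segment (default 10).
#' @param t_threshold Split acceptance threshold on the mean-shift t statistic
#'   (default 5).
#' @return data.frame of segments: sample, chrom, start, end, n_snvs,
#'   copy_number, p_value, log2_mbaf_adj.
#' @export
segment_log_ratio <- function(snvs, sample = "sample1", chrom = "1",
                              min_snvs = 10, t_threshold = 5) {
  stop_missing(snvs, c("pos", "log2_ratio", "baf_tumor", "baf_normal"),
               "segment_log_ratio")
  if (is.unsorted(snvs$pos)) stop("SNVs must be sorted by position")
  n <- nrow(snvs)
  cps <- if (n < min_snvs) integer(0) else
    bin_seg(snvs$log2_ratio, min_snvs, t_threshold)
  bounds <- c(0, cps, n)
  segs <- lapply(seq_len(length(bounds) - 1), function(i) {
    idx <- (bounds[i] + 1):bounds[i + 1]
    lr <- snvs$log2_ratio[idx]
    p <- if (length(lr) < 2 || stats::sd(lr) == 0) 1 else
      stats::t.test(lr, mu = 0)$p.value
    mb_t <- mean(abs(snvs$baf_tumor[idx] - 0.5))
    mb_n <- mean(abs(snvs$baf_normal[idx] - 0.5))
    mbaf <- if (mb_n <= 0) 0 else log2(pmax(mb_t, 1e-6) / mb_n)
    data.frame(sample = sample, chrom = chrom,
               start = snvs$pos[idx[1]], end = snvs$pos[idx[length(idx)]],
               n_snvs = length(idx), copy_number = 2 * 2^mean(lr),
               p_value = p, log2_mbaf_adj = mbaf, stringsAsFactors = FALSE)
  })
  do.call(rbind, segs)
}

#' Compare copy-number burden between groups
#'
#' Counts GAIN/LOSS/CN_LOH segments per sample and compares each class's
#' per-sample counts between two groups with the Mann-Whitney U test.
#'
#' @param segments Classified segment table (needs `sample` and `call`).
#' @param clinical data.frame with `sample` and `group`.
#' @param groups Length-2 character vector naming the groups to compare.
#' @return List with `per_sample` (sample x class counts, with group) and
#'   `tests` (class, median per group, Mann-Whitney p).
#' @export
compare_cnv_burden <- function(segments, clinical, groups) {
  stop_missing(segments, c("sample", "call"), "compare_cnv_burden")
  stop_missing(clinical, c("sample", "group"), "compare_cnv_burden")
  if (!all(groups %in% clinical$group)) {
    stop(sprintf("unknown group(s): %s",
                 paste(setdiff(groups, clinical$group), collapse = ", ")))
  }
  classes <- c("GAIN", "LOSS", "CN_LOH")
  samples <- clinical$sample[clinical$group %in% groups]
  counts <- vapply(classes, function(cl)
    vapply(samples, function(s)
      sum(segments$sample == s & segments$call == cl), integer(1)),
    integer(length(samples)))
  per_sample <- data.frame(sample = samples,
                           group = clinical$group[match(samples, clinical$sample)],
                           counts, stringsAsFactors = FALSE)
  tests <- do.call(rbind, lapply(classes, function(cl) {
    a <- per_sample[per_sample$group == groups[1], cl]
    b <- per_sample[per_sample$group == groups[2], cl]
    p <- suppressWarnings(mann_whitney(a, b)$p)
    data.frame(class = cl, median_a = stats::median(a),
               median_b = stats::median(b), p = p, stringsAsFactors = FALSE)
  }))
  names(tests)[2:3] <- paste0("median_", groups)
  list(per_sample = per_sample, tests = tests)
}
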