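# Expression normalization, gene-set signature scoring, clustering, and
# group-contrast (volcano) statistics for genes x samples log2 matrices.

TP53_INACTIVATION_GENES <- c("CDC20", "PLK1", "CENPA", "KIF2C")

#' Log-transform and 75th-percentile normalize raw intensities
#'
#' Raw signal intensities are log2-transformed, then each sample (column) is
#' shifted so that its 75th percentile equals 0. Applying the normalization
#' to an already-normalized matrix is the identity, and rescaling a sample's
#' raw values by a constant leaves its normalized column unchanged.
#'
#' @param raw genes x samples matrix of raw intensities (> 0), or an already
#'   log2 matrix with `log2 = TRUE`.
#' @param log2 Is the input already on the log2 scale?
#' @return genes x samples matrix of normalized log2 expression.
#' @export
normalize_75th <- function(raw, log2 = FALSE) {
  m <- as.matrix(raw)
  if (!log2) {
    bad <- which(m <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("non-positive raw intensity at gene '%s', sample '%s'",
                   rownames(m)[bad[1, 1]] %||% bad[1, 1],
                   colnames(m)[bad[1, 2]] %||% bad[1, 2]))
    }
    m <- base::log2(m)
  }
  q75 <- apply(m, 2, stats::quantile, probs = 0.75, names = FALSE)
  sweep(m, 2, q75, "-")
}

#' Score a gene-set expression signature
#'
#' The signature score of a sample is the arithmetic mean of its normalized
#' log2 expression over the member genes present in the matrix.
#'
#' @param matrix Normalized genes x samples matrix.
#' @param gene_set Character vector of member genes (or a list with `genes`).
#' @param mean_type `"arithmetic"` (default) or `"geometric"` (mean on the
#'   linear scale, reported back on log2).
#' @return List of class `svrhcc_score`: `score` (named per-sample vector),
#'   `genes_used`, `coverage` (fraction of the set present).
#' @export
score_signature <- function(matrix, gene_set, mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  genes <- if (is.list(gene_set)) gene_set$genes else gene_set
  present <- intersect(genes, rownames(matrix))
  if (!length(present)) stop("no gene-set member present in the matrix")
  sub <- matrix[present, , drop = FALSE]
  score <- if (mean_type == "arithmetic") colMeans(sub)
           else base::log2(colMeans(2^sub))
  structure(list(score = score, genes_used = present,
                 coverage = length(present) / length(unique(genes))),
            class = "svrhcc_score")
}

#' TP53-inactivation score
#'
#' Mean normalized expression of CDC20, PLK1, CENPA and KIF2C — a
#' transcriptional readout of p53 pathway loss. All four genes must be
#' present.
#'
#' @param matrix Normalized genes x samples matrix.
#' @return An `svrhcc_score` (see [score_signature()]).
#' @export
tp53_inactivation_score <- function(matrix) {
  miss <- setdiff(TP53_INACTIVATION_GENES, rownames(matrix))
  if (length(miss)) {
    stop(sprintf("TP53-inactivation gene(s) missing from matrix: %s",
                 paste(miss, collapse = ", ")))
  }
  score_signature(matrix, TP53_INACTIVATION_GENES)
}

#' Correlate two signature scores
#'
#' Spearman rank correlation (average ranks for ties) between two per-sample
#' score vectors, matched by sample name when both are named.
#'
#' @param score_a,score_b `svrhcc_score` objects or numeric vectors.
#' @return List with `rho` and `p`.
#' @export
correlate_scores <- function(score_a, score_b) {
  a <- if (inherits(score_a, "svrhcc_score")) score_a$score else score_a
  b <- if (inherits(score_b, "svrhcc_score")) score_b$score else score_b
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  }
  spearman(a, b)
}

#' Per-gene two-group volcano statistics
#'
#' For every gene: log2 fold change (difference of group means on the log2
#' scale), two-sided Mann-Whitney p, and Benjamini-Hochberg q.
#'
#' @param matrix Normalized genes x samples matrix.
#' @param group_mask Logical per-sample vector (`TRUE` = group A).
#' @return data.frame sorted by p: gene, log2_fc (A minus B), p, q.
#' @export
volcano <- function(matrix, group_mask) {
  stopifnot(is.logical(group_mask), length(group_mask) == ncol(matrix))
  if (sum(group_mask) < 2 || sum(!group_mask) < 2) {
    stop("need at least 2 samples per group")
  }
  a <- matrix[, group_mask, drop = FALSE]
  b <- matrix[, !group_mask, drop = FALSE]
  p <- vapply(seq_len(nrow(matrix)), function(i)
    suppressWarnings(mann_whitney(a[i, ], b[i, ])$p), numeric(1))
  res <- data.frame(gene = rownames(matrix),
                    log2_fc = rowMeans(a) - rowMeans(b),
                    p = p, q = stats::p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  res
}

#' Ward hierarchical clustering of samples
#'
#' Ward linkage (`ward.D2`) on Euclidean distance between samples over
#' gene-wise z-scored rows (constant genes are dropped before scaling).
#'
#' @param matrix Normalized genes x samples matrix (>= 2 samples).
#' @param k Optional number of clusters to cut into.
#' @param zscore Z-score genes before clustering (default `TRUE`).
#' @return List with `hclust`, `labels` (if `k` given), and `newick` (the
#'   dendrogram as a Newick string via [ape::write.tree()]).
#' @export
ward_cluster <- function(matrix, k = NULL, zscore = TRUE) {
  if (ncol(matrix) < 2) stop("need at least 2 samples")
  m <- as.matrix(matrix)
  if (zscore) {
    sds <- apply(m, 1, stats::sd)
    m <- m[sds > 0, , drop = FALSE]
    m <- (m - rowMeans(m)) / apply(m, 1, stats::sd)
  }
  hc <- stats::hclust(stats::dist(t(m)), method = "ward.D2")
  labels <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  phy <- ape::as.phylo(hc)
  newick <- ape::write.tree(phy)
  list(hclust = hc, labels = labels, newick = newick)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (tab-separated: name, description/source, genes...).
#' @return Named list of gene sets, each a list with `name`, `source`,
#'   `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    list(name = parts[1], source = parts[2], genes = unique(parts[-(1:2)]))
  })
  stats::setNames(sets, vapply(sets, `[[`, character(1), "name"))
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list as returned by [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$source %||% "na", s$genes), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Packaged gene-set fixtures
#'
#' Loads the gene sets shipped with the package: the four-gene
#' TP53-inactivation set (printed in full in the source study), and editable
#' placeholder sets for chromosomal instability (CIN), PI3K/mTOR up
#' (padded to 134 genes with clearly synthetic `PMTU###` symbols), cytolytic
#' activity, immune cell populations, interferon response, and the T
#' cell-inflamed profile.
#'
#' @return Named list of gene sets.
#' @export
packaged_gene_sets <- function() {
  read_gmt(system.file("extdata", "gene_sets.gmt", package = "svrhcc"))
}
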