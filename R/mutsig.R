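# 96-context trinucleotide spectra and non-negative decomposition against a
# reference signature matrix (30 signatures, COSMIC v2 layout). The shipped
# reference matrix is a synthetic stand-in with the same shape and sparsity
# as the COSMIC v2 catalogue; drop-in replacement with the real TSV works.

SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

#' The 96 trinucleotide substitution classes
#'
#' Pyrimidine-centered classes ordered substitution-major: the six
#' substitutions C>A, C>G, C>T, T>A, T>C, T>G, each crossed with the four 5'
#' and four 3' flanking bases, labelled like `"A[C>T]G"`.
#'
#' @return Character vector of length 96.
#' @export
trinuc_classes <- function() {
  unlist(lapply(SUBSTITUTIONS, function(s)
    unlist(lapply(BASES, function(b5)
      paste0(b5, "[", s, "]", vapply(BASES, identity, character(1)))))))
}

revcomp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

#' Build a 96-context mutation spectrum
#'
#' Counts single-nucleotide substitutions into the 96 pyrimidine-centered
#' trinucleotide classes. Mutations whose reference base is a purine are
#' reverse-complemented (both the substitution and the flanking bases swap and
#' complement) so that a mutation and its reverse complement always land in
#' the same class. Non-SNVs and non-ACGT bases are skipped with a warning.
#'
#' @param snvs data.frame with columns `ref`, `alt`, `flank5`, `flank3`
#'   (single bases; `flank5`/`flank3` are the bases immediately 5' and 3' of
#'   the variant on the reference strand).
#' @return Named integer vector of length 96 over [trinuc_classes()].
#' @export
build_spectrum <- function(snvs) {
  classes <- trinuc_classes()
  spec <- stats::setNames(integer(96), classes)
  if (!nrow(snvs)) return(spec)
  stop_missing(snvs, c("ref", "alt", "flank5", "flank3"), "build_spectrum")
  n_skipped <- 0
  for (i in seq_len(nrow(snvs))) {
    ref <- toupper(snvs$ref[i]); alt <- toupper(snvs$alt[i])
    b5 <- toupper(snvs$flank5[i]); b3 <- toupper(snvs$flank3[i])
    if (nchar(ref) != 1 || nchar(alt) != 1 ||
        !all(c(ref, alt, b5, b3) %in% BASES)) {
      n_skipped <- n_skipped + 1
      next
    }
    if (ref %in% c("A", "G")) {  # purine reference: fold onto pyrimidine strand
      tmp5 <- revcomp_base(b3); b3 <- revcomp_base(b5); b5 <- tmp5
      ref <- revcomp_base(ref); alt <- revcomp_base(alt)
    }
    cls <- paste0(b5, "[", ref, ">", alt, "]", b3)
    spec[cls] <- spec[cls] + 1L
  }
  if (n_skipped) warning(sprintf("%d variant(s) skipped (non-SNV or non-ACGT)",
                                 n_skipped))
  spec
}

#' Load a reference signature matrix
#'
#' Reads a TSV of per-class signature probabilities (rows = the 96 classes in
#' [trinuc_classes()] order, columns = signatures) and validates that every
#' column sums to 1. The default is the synthetic 30-signature matrix shipped
#' with the package, which mimics the shape of the COSMIC v2 catalogue but is
#' not the COSMIC data.
#'
#' @param path TSV path; first column `class`, remaining columns signatures.
#' @return 96 x k numeric matrix with class rownames.
#' @export
load_signature_matrix <- function(path = system.file("extdata",
    "signatures_synthetic_v2like.tsv", package = "svrhcc")) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (nrow(m) != 96 || !identical(rownames(m), trinuc_classes())) {
    stop("signature matrix must have the 96 classes in canonical order")
  }
  if (any(m < 0) || any(abs(colSums(m) - 1) > 1e-6)) {
    stop("signature columns must be non-negative and sum to 1")
  }
  m
}

golden_section <- function(f, lo = 0, hi = 1, tol = 1e-7) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    }
  }
  x <- (a + b) / 2
  list(x = x, value = f(x))
}

#' Decompose a spectrum into reference-signature exposures
#'
#' Normalizes the spectrum to a probability vector and approximates it as a
#' non-negative combination of reference signatures by iterative forward
#' selection: at each step, for every signature, a bounded golden-section line
#' search on \[0, 1\] finds the mixing weight between the current
#' reconstruction and that signature that minimizes the squared error; the
#' best signature update is accepted, and iteration stops when the relative
#' error improvement falls below `tol`. Final weights below `weight_floor`
#' are zeroed and the remaining weights renormalized to the pre-floor total,
#' so the weight sum never increases.
#'
#' @param spectrum Length-96 non-negative counts (total > 0).
#' @param signatures 96 x k signature matrix, e.g. [load_signature_matrix()].
#' @param weight_floor Exposures below this are zeroed (default 0.06, the
#'   deconstruction convention for suppressing spurious small exposures).
#' @param tol Relative-improvement stopping tolerance (default 1e-4).
#' @param max_iter Maximum forward-selection iterations.
#' @return List of class `svrhcc_exposure`: `weights` (named, length k),
#'   `residual` (1 - sum of weights), `reconstruction_error` (sum of squared
#'   differences between the normalized spectrum and its reconstruction), and
#'   `error_trace` (error after each accepted iteration).
#' @export
decompose <- function(spectrum, signatures = load_signature_matrix(),
                      weight_floor = 0.06, tol = 1e-4, max_iter = 500) {
  stopifnot(length(spectrum) == nrow(signatures), all(spectrum >= 0))
  if (sum(spectrum) == 0) stop("cannot decompose an all-zero spectrum")
  target <- spectrum / sum(spectrum)
  w0 <- stats::setNames(numeric(ncol(signatures)), colnames(signatures))
  fit <- forward_fit(target, signatures, w0, cols = seq_len(ncol(signatures)),
                     tol = tol, max_iter = max_iter)
  w <- fit$w
  if (weight_floor > 0) {
    # floor, then re-optimize on the kept support so discarded mass is refit
    # rather than redistributed pro rata; repeat if the refit drops a kept
    # weight back under the floor
    for (pass in 1:5) {
      if (!any(w > 0 & w < weight_floor)) break
      keep <- which(w >= weight_floor)
      w[-keep] <- 0
      if (!length(keep)) break
      w[keep] <- w[keep] / sum(w) * min(sum(w), 1)
      w <- forward_fit(target, signatures, w, cols = keep,
                       tol = tol * 1e-2, max_iter = max_iter)$w
    }
    w[w < weight_floor] <- 0
  }
  structure(list(
    weights = w, residual = 1 - sum(w),
    reconstruction_error = sum((target - as.numeric(signatures %*% w))^2),
    error_trace = fit$trace), class = "svrhcc_exposure")
}

# iterative forward selection with golden-section line search, restricted to
# the given candidate columns; keeps sum(w) <= max(sum(w0), 1)
forward_fit <- function(target, signatures, w, cols, tol, max_iter) {
  recon <- as.numeric(signatures %*% w)
  err <- sum((target - recon)^2)
  trace <- err
  for (iter in seq_len(max_iter)) {
    best <- list(err = err, j = NA_integer_, alpha = NA_real_)
    for (j in cols) {
      sj <- signatures[, j]
      opt <- golden_section(function(a)
        sum((target - ((1 - a) * recon + a * sj))^2))
      if (opt$value < best$err) best <- list(err = opt$value, j = j, alpha = opt$x)
    }
    if (is.na(best$j) || (err - best$err) < tol * err) break
    w <- (1 - best$alpha) * w
    w[best$j] <- w[best$j] + best$alpha
    recon <- as.numeric(signatures %*% w)
    err <- best$err
    trace <- c(trace, err)
  }
  list(w = w, trace = trace)
}

#' Compare per-signature exposures between groups
#'
#' @param exposures samples x signatures matrix (or data.frame) of exposure
#'   weights.
#' @param groups Group label per sample (two levels compared).
#' @return data.frame with one row per signature: median weight per group and
#'   the two-sided Mann-Whitney p (NA when a group has < 2 samples).
#' @export
compare_signature_profiles <- function(exposures, groups) {
  exposures <- as.matrix(exposures)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2) stop("exactly two groups are compared")
  lv <- levels(droplevels(groups))
  a <- exposures[groups == lv[1], , drop = FALSE]
  b <- exposures[groups == lv[2], , drop = FALSE]
  res <- data.frame(
    signature = colnames(exposures),
    median_a = apply(a, 2, stats::median),
    median_b = apply(b, 2, stats::median),
    p = vapply(seq_len(ncol(exposures)), function(j) {
      if (nrow(a) < 2 || nrow(b) < 2) return(NA_real_)
      suppressWarnings(mann_whitney(a[, j], b[, j])$p)
    }, numeric(1)),
    stringsAsFactors = FALSE)
  names(res)[2:3] <- paste0("median_", lv)
  rownames(res) <- NULL
  res
}

#' Sample mutation contexts from a signature mixture
#'
#' Draws `n` trinucleotide classes from the mixture distribution implied by
#' `weights` over the reference signatures and returns them as an SNV table
#' suitable for [build_spectrum()].
#'
#' @param n Number of mutations.
#' @param weights Named non-negative mixture weights over signature columns.
#' @param signatures Reference matrix.
#' @return data.frame with `ref`, `alt`, `flank5`, `flank3`, `class`.
#' @export
sample_mutation_contexts <- function(n, weights, signatures = load_signature_matrix()) {
  stopifnot(all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  mix <- as.numeric(signatures[, names(w), drop = FALSE] %*% w)
  cls <- sample(trinuc_classes(), n, replace = TRUE, prob = mix)
  m <- regmatches(cls, regexec("^([ACGT])\\[([ACGT])>([ACGT])\\]([ACGT])$", cls))
  data.frame(
    flank5 = vapply(m, `[`, character(1), 2),
    ref    = vapply(m, `[`, character(1), 3),
    alt    = vapply(m, `[`, character(1), 4),
    flank3 = vapply(m, `[`, character(1), 5),
    class  = cls, stringsAsFactors = FALSE)
}
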