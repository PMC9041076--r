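# Cohort group-comparison statistics: 2x2 contingency tests, rank tests,
# Kaplan-Meier / log-rank survival, and the p53 immunohistochemistry rule.

#' Compare mutation frequencies between two groups
#'
#' Builds the 2x2 table `[[mutA, nA - mutA], [mutB, nB - mutB]]` and tests for
#' a frequency difference. With `method = "auto"` Fisher's exact test is used
#' whenever any expected cell count is below 5, otherwise the chi-squared test
#' without continuity correction. Both p-values are always reported.
#'
#' @param mutA,nA Mutated and total sample counts in group A.
#' @param mutB,nB Mutated and total sample counts in group B.
#' @param method `"auto"`, `"fisher"` or `"chisq"`.
#' @param correct Apply Yates continuity correction to the chi-squared test
#'   (default `FALSE`).
#' @return A list of class `svrhcc_contingency`: `table`, `test` (the test the
#'   `method` rule selected), `statistic` (chi-squared statistic), `p`
#'   (selected test), `p_chisq`, `p_fisher`, and the two group percentages
#'   (half-up, one decimal).
#' @examples
#' compare_frequencies(6, 34, 1, 35)   # ARID2-style contrast
#' @export
compare_frequencies <- function(mutA, nA, mutB, nB, method = c("auto", "fisher", "chisq"),
                                correct = FALSE) {
  method <- match.arg(method)
  if (nA <= 0 || nB <= 0) stop("group totals must be positive")
  stopifnot(mutA >= 0, mutB >= 0, mutA <= nA, mutB <= nB)
  tab <- matrix(c(mutA, nA - mutA, mutB, nB - mutB), nrow = 2, byrow = TRUE,
                dimnames = list(group = c("A", "B"), mutated = c("yes", "no")))
  p_fisher <- stats::fisher.test(tab)$p.value
  if (all(tab == 0) || sum(tab[, 1]) == 0 || sum(tab[, 2]) == 0) {
    stat <- 0
    p_chisq <- 1
  } else {
    cs <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    stat <- unname(cs$statistic)
    p_chisq <- cs$p.value
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  test <- switch(method,
    auto   = if (any(expected < 5)) "FISHER" else "CHI_SQUARED",
    fisher = "FISHER",
    chisq  = "CHI_SQUARED")
  structure(list(
    table = tab, test = test, statistic = stat,
    p = if (test == "FISHER") p_fisher else p_chisq,
    p_chisq = p_chisq, p_fisher = p_fisher,
    percent_A = percent_mutated(mutA, nA),
    percent_B = percent_mutated(mutB, nB)
  ), class = "svrhcc_contingency")
}

#' @export
print.svrhcc_contingency <- function(x, ...) {
  cat(sprintf("2x2 comparison: %.1f%% vs %.1f%% (%s p = %.4g)\n",
              x$percent_A, x$percent_B, x$test, x$p))
  print(x$table)
  invisible(x)
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two samples with average ranks for ties. The exact
#' distribution is enumerated when both samples are small (`min(n, m) <= 20`)
#' and tie-free; otherwise the tie-corrected normal approximation is used.
#'
#' @param x,y Numeric vectors.
#' @return List with `U` (statistic for the first sample), `p`, and `method`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  if (all(c(x, y) == c(x, y)[1])) {
    warning("all observations tied; p = 1")
    return(list(U = length(x) * length(y) / 2, p = 1, method = "degenerate"))
  }
  exact <- !ties && min(length(x), length(y)) <= 20
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal_tie_corrected")
}

#' Spearman rank correlation
#'
#' @param x,y Paired numeric vectors, length >= 3.
#' @return List with `rho` and `p` (two-sided; NA with a warning for a
#'   constant vector).
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3) stop("need at least 3 paired samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector; correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimates per group and the standard log-rank
#' chi-squared test for a group difference.
#'
#' @param times Follow-up times (>= 0).
#' @param events Event indicators (1/TRUE = event, 0/FALSE = censored).
#' @param groups Group labels (>= 2 levels).
#' @return List with `fit` (a [survival::survfit] object), `curves` (a
#'   data.frame of time, at-risk, survival and CI per group), `chisq` and `p`.
#' @export
km_logrank <- function(times, events, groups) {
  stopifnot(all(times >= 0), length(times) == length(events),
            length(times) == length(groups))
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  events <- as.integer(as.logical(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  sd0 <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(sd0$n) - 1
  p <- stats::pchisq(sd0$chisq, df = df, lower.tail = FALSE)
  s <- summary(fit)
  curves <- data.frame(
    group = if (is.null(s$strata)) levels(groups)[1] else
      sub("^groups=", "", as.character(s$strata)),
    time = s$time, n_risk = s$n.risk, survival = s$surv,
    lower = s$lower, upper = s$upper, stringsAsFactors = FALSE)
  list(fit = fit, curves = curves, chisq = unname(sd0$chisq), p = p)
}

#' Classify p53 immunohistochemistry
#'
#' A tumor is called mutant-pattern when at least 30% of cancer cells show a
#' distinct nuclear immunoreaction, null-type when no immunoreaction is
#' observed at all, and wild-type otherwise. The aberrant flag combines the
#' mutant-pattern and null-type calls.
#'
#' @param percent_positive Percentage of p53-positive cancer cells, in
#'   \[0, 100\].
#' @param any_immunoreaction Was any immunoreaction observed?
#' @param threshold Mutant-pattern cutoff (default 30, boundary inclusive).
#' @return List with `percent_positive`, `call` (one of `"MUTANT_PATTERN"`,
#'   `"NULL_TYPE"`, `"WILD_TYPE"`) and `aberrant`.
#' @export
classify_ihc <- function(percent_positive, any_immunoreaction, threshold = 30) {
  stopifnot(percent_positive >= 0, percent_positive <= 100)
  if (percent_positive > 0 && !any_immunoreaction) {
    stop("inconsistent IHC record: positive percentage with no immunoreaction")
  }
  call <- if (percent_positive >= threshold) "MUTANT_PATTERN"
          else if (!any_immunoreaction) "NULL_TYPE"
          else "WILD_TYPE"
  list(percent_positive = percent_positive, call = call,
       aberrant = call %in% c("MUTANT_PATTERN", "NULL_TYPE"))
}

#' Concordance of aberrant p53 IHC with TP53 mutation status
#'
#' Cross-tabulates the aberrant-IHC flag (mutant-pattern or null-type) against
#' TP53 mutation flags over paired samples and applies
#' [compare_frequencies()].
#'
#' @param ihc_aberrant Logical vector of aberrant-IHC flags.
#' @param tp53_mutated Logical vector of TP53 mutation flags, same samples.
#' @return An `svrhcc_contingency` result for aberrant-vs-mutation.
#' @export
ihc_mutation_concordance <- function(ihc_aberrant, tp53_mutated) {
  keep <- !is.na(ihc_aberrant) & !is.na(tp53_mutated)
  if (any(!keep)) warning(sprintf("%d unpaired sample(s) excluded", sum(!keep)))
  a <- ihc_aberrant[keep]; m <- tp53_mutated[keep]
  compare_frequencies(sum(a & m), sum(m), sum(a & !m), sum(!m))
}
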