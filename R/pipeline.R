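# End-to-end orchestration: simulate -> filter -> drivers -> mutsig -> cnv
# -> exprsig -> stats, with a consolidated report bundle on disk.

#' Run the full analysis pipeline
#'
#' Executes every stage in dependency order on a synthetic cohort (or a
#' pre-built bundle), writing each stage's tables plus a consolidated
#' `report.json` to `out_dir`. A fixed config seed gives byte-identical
#' output files. When the bundle carries no expression matrix the
#' expression-dependent sections are marked `"skipped"` and the remaining
#' stages run unaffected.
#'
#' @param config A [cohort_config()]; ignored when `bundle` is supplied.
#' @param out_dir Output directory for the report bundle.
#' @param bundle Optional pre-built `svrhcc_cohort` (e.g. with elements
#'   removed to exercise partial runs).
#' @param thresholds [filter_thresholds()] for the variant filter.
#' @param footprint_mb TMB denominator in megabases.
#' @return List of class `svrhcc_report` with every stage's results and
#'   `files` (written paths).
#' @export
run_pipeline <- function(config = cohort_config(), out_dir,
                         bundle = NULL, thresholds = filter_thresholds(),
                         footprint_mb = 34.8) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  result <- tryCatch({
    if (is.null(bundle)) bundle <- simulate_cohort(config)
    clinical <- bundle$clinical
    report <- list(seed = bundle$config$seed)
    p <- function(f) file.path(out_dir, f)

    stage <- "filter"
    filt <- filter_cohort(bundle$variants, thresholds)
    utils::write.table(filt$summary, p("filter_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_variants_maf(filt$passed, p("variants_filtered.maf.tsv"))
    report$filter <- list(total = nrow(bundle$variants),
                          kept = nrow(filt$passed))

    stage <- "drivers"
    ann <- annotate_drivers(filt$passed, bundle$catalogue)
    drivers <- ann[ann$driver, , drop = FALSE]
    freq <- mutation_frequency_matrix(drivers, clinical)
    utils::write.table(freq, p("mutation_frequency.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tmb <- vapply(split(ann, ann$sample), function(x)
      compute_tmb(x, footprint_mb), numeric(1))
    tmb_df <- data.frame(sample = names(tmb), tmb = unname(tmb))
    utils::write.table(tmb_df, p("tmb.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    freq_tests <- driver_group_tests(drivers, clinical)
    utils::write.table(freq_tests, p("driver_group_tests.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    onco <- oncoprint_matrix(drivers, samples = clinical$sample)
    utils::write.table(data.frame(gene = rownames(onco), onco,
                                  check.names = FALSE),
                       p("oncoprint.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    report$drivers <- list(n_driver_variants = nrow(drivers),
                           median_tmb = stats::median(tmb))

    stage <- "mutsig"
    sigs <- load_signature_matrix()
    snvs <- filt$passed[filt$passed$variant_type == "SNV", , drop = FALSE]
    exposures <- t(vapply(clinical$sample, function(s) {
      sub <- snvs[snvs$sample == s, , drop = FALSE]
      if (nrow(sub) == 0) return(stats::setNames(rep(NA_real_, ncol(sigs)),
                                                 colnames(sigs)))
      decompose(build_spectrum(sub), sigs)$weights
    }, numeric(ncol(sigs))))
    utils::write.table(data.frame(sample = rownames(exposures), exposures,
                                  check.names = FALSE),
                       p("signature_exposures.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    hcv_vs_svr <- ifelse(clinical$group == "HCV_POSITIVE", "HCV_POSITIVE", "SVR")
    sig_cmp <- compare_signature_profiles(exposures, hcv_vs_svr)
    utils::write.table(sig_cmp, p("signature_group_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$mutsig <- list(n_signatures = ncol(sigs),
                          min_comparison_p = min(sig_cmp$p, na.rm = TRUE))

    stage <- "cnv"
    seg <- classify_segments(bundle$segments)
    write_segments(seg, p("segments_classified.seg.tsv"))
    burden <- compare_cnv_burden(seg, clinical, c("SVR_DAA", "SVR_IFN"))
    utils::write.table(burden$tests, p("cnv_burden_tests.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$cnv <- list(
      n_events = sum(seg$call != "NEUTRAL"),
      deletion_burden_p = burden$tests$p[burden$tests$class == "LOSS"])

    stage <- "exprsig"
    if (is.null(bundle[["expression"]])) {
      report$exprsig <- "skipped"
      report$integrative <- "skipped"
    } else {
      em <- normalize_75th(bundle[["expression"]], log2 = TRUE)
      meta <- bundle$expression_meta
      tum <- em[, meta$column[meta$tissue == "TUMOR"], drop = FALSE]
      colnames(tum) <- meta$sample[meta$tissue == "TUMOR"]
      nor <- em[, meta$column[meta$tissue == "NORMAL"], drop = FALSE]
      colnames(nor) <- meta$sample[meta$tissue == "NORMAL"]
      tp53 <- tp53_inactivation_score(tum)
      cin <- score_signature(tum, bundle$gene_sets$CIN)
      pi3k <- score_signature(tum, bundle$gene_sets$PI3K_MTOR_UP)
      scores <- data.frame(sample = colnames(tum), tp53_inactivation =
                             tp53$score, cin = cin$score, pi3k_mtor = pi3k$score)
      utils::write.table(scores, p("signature_scores.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      grp <- clinical$group[match(colnames(tum), clinical$sample)]
      daa <- grp == "SVR_DAA"; ifn <- grp == "SVR_IFN"
      score_tests <- data.frame(
        score = c("tp53_inactivation", "cin", "pi3k_mtor"),
        p = c(mann_whitney(tp53$score[daa], tp53$score[ifn])$p,
              mann_whitney(cin$score[daa], cin$score[ifn])$p,
              mann_whitney(pi3k$score[daa], pi3k$score[ifn])$p))
      utils::write.table(score_tests, p("score_group_tests.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      svr_tumors <- daa | ifn
      cor_cin <- correlate_scores(tp53$score[svr_tumors], cin$score[svr_tumors])
      cor_pi3k <- correlate_scores(tp53$score[svr_tumors], pi3k$score[svr_tumors])
      volc <- volcano(tum[, svr_tumors, drop = FALSE], daa[svr_tumors])
      utils::write.table(volc, p("volcano.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      wc <- ward_cluster(tum, k = 2)
      writeLines(wc$newick, p("dendrogram.nwk"))
      report$exprsig <- list(
        tp53_daa_vs_ifn_p = score_tests$p[1],
        cin_daa_vs_ifn_p = score_tests$p[2],
        pi3k_daa_vs_ifn_p = score_tests$p[3],
        rho_tp53_cin = cor_cin$rho, rho_tp53_pi3k = cor_pi3k$rho,
        top_volcano_gene = volc$gene[1])

      stage <- "integrative"
      cn <- gene_level_copy_number(bundle$gene_positions, seg)
      ab <- call_expression_cnv_aberrations(tum, nor, cn, bundle$catalogue,
                                            clinical)
      utils::write.table(ab$calls[ab$calls$call != "NONE", ],
                         p("aberration_calls.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(ab$shortlist, p("aberration_shortlist.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$integrative <- list(
        n_amplified = sum(ab$calls$call == "AMPLIFIED"),
        n_deleted = sum(ab$calls$call == "DELETED"))
    }

    stage <- "stats"
    km <- km_logrank(clinical$os_months, clinical$os_event, hcv_vs_svr)
    utils::write.table(km$curves, p("survival_curves.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ihc <- lapply(seq_len(nrow(clinical)), function(i)
      classify_ihc(clinical$ihc_p53_percent[i], clinical$ihc_any_reaction[i]))
    conc <- ihc_mutation_concordance(
      vapply(ihc, `[[`, logical(1), "aberrant"),
      bundle$driver_flags[clinical$sample, "TP53"])
    report$stats <- list(os_logrank_p = km$p, ihc_concordance_p = conc$p)

    report$files <- list.files(out_dir, recursive = TRUE)
    jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    structure(c(report, list(bundle = bundle)), class = "svrhcc_report")
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}

# two-group mutation-frequency contrasts for the classic driver genes
driver_group_tests <- function(driver_variants, clinical) {
  contrasts <- list(
    c("HCV_POSITIVE", "SVR"),
    c("SVR_DAA", "SVR_IFN"))
  genes <- sort(unique(driver_variants$gene))
  do.call(rbind, lapply(contrasts, function(ct) {
    grp <- if ("SVR" %in% ct) {
      ifelse(clinical$group == "HCV_POSITIVE", "HCV_POSITIVE", "SVR")
    } else clinical$group
    keep <- grp %in% ct
    do.call(rbind, lapply(genes, function(g) {
      mut <- unique(driver_variants$sample[driver_variants$gene == g])
      inA <- clinical$sample[keep & grp == ct[1]]
      inB <- clinical$sample[keep & grp == ct[2]]
      r <- compare_frequencies(sum(inA %in% mut), length(inA),
                               sum(inB %in% mut), length(inB))
      data.frame(gene = g, group_a = ct[1], group_b = ct[2],
                 percent_a = r$percent_A, percent_b = r$percent_B,
                 test = r$test, p = r$p, stringsAsFactors = FALSE)
    }))
  }))
}

#' Checksums of a report bundle
#'
#' MD5 of every file in a pipeline output directory, for determinism checks.
#'
#' @param out_dir Report directory.
#' @return Named character vector of checksums keyed by relative path.
#' @export
report_checksums <- function(out_dir) {
  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  ck <- tools::md5sum(files)
  names(ck) <- sub(paste0("^", out_dir, "/?"), "", files)
  ck
}
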