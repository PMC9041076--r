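# Seeded synthetic-cohort generator. Emulates the statistical structure of a
# resected-HCC cohort stratified by HCV status and curative treatment
# (HCV-positive / SVR-DAA / SVR-IFN / SVR-other): group-dependent driver
# prevalences, sequencing-artifact variants that each violate one known
# filter criterion, planted log2 expression effects, a latent instability
# factor coupling the TP53-inactivation and CIN scores, excess copy-number
# deletions in DAA tumors, and exponential survival with censoring.

GROUPS <- c("HCV_POSITIVE", "SVR_DAA", "SVR_IFN", "SVR_OTHER")

#' Synthetic-cohort configuration
#'
#' Defaults encode the study conditions the generator emulates: stratum sizes
#' 34 / 8 / 24 / 3 (HCV-positive, SVR-DAA, SVR-IFN, SVR-other); driver
#' prevalences chosen so the cohort reproduces the reported per-group
#' mutation counts (ARID2 6/34 vs 1/35, PREX2 1/34 vs 4/35, KEAP1 1/34 vs
#' 4/35, TP53 enriched in DAA tumors); ~100 true somatic variants and ~20
#' injected artifacts per sample; a liver-typical signature mixture; +1 log2
#' planted shifts of the TP53-inactivation and PI3K/mTOR sets in DAA tumors
#' with immune signatures suppressed in SVR non-tumor liver; a latent factor
#' giving a 0.9 correlation between the TP53-inactivation and CIN scores;
#' and a higher expected number of deleted segments in DAA tumors.
#'
#' @param n_hcv_positive,n_svr_daa,n_svr_ifn,n_svr_other Stratum sizes.
#' @param driver_prevalence Named list group -> named vector gene -> fraction
#'   in \[0, 1\]. Per group, `round(prevalence * n)` samples are mutated.
#' @param artifact_rate Expected injected artifact variants per sample.
#' @param n_true_variants Mean true somatic variants per sample (Poisson).
#' @param expression_effects data.frame (`gene_set`, `group`, `tissue`,
#'   `shift_log2`) of planted mean shifts.
#' @param score_correlation Target correlation between the TP53-inactivation
#'   and CIN signature scores induced by the latent instability factor.
#' @param cnv_deletion_rate Named vector group -> expected deleted segments
#'   per sample.
#' @param cnv_gain_rate,cnv_loh_rate Expected gain / copy-neutral-LOH
#'   segments per sample (all groups).
#' @param signature_mixture Named weights over reference signatures (sum 1).
#' @param survival_params List: `os_rate`, `rfs_rate` (events per month) and
#'   `censor_rate`.
#' @param gene_noise_sd Gene-wise Gaussian noise SD on the log2 scale.
#' @param n_genes Size of the simulated gene universe (catalogue and
#'   signature genes are always included).
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @return List of class `svrhcc_config`.
#' @export
cohort_config <- function(
    n_hcv_positive = 34, n_svr_daa = 8, n_svr_ifn = 24, n_svr_other = 3,
    driver_prevalence = list(
      HCV_POSITIVE = c(TP53 = 0.40, CTNNB1 = 0.30, ARID2 = 6 / 34,
                       PREX2 = 1 / 34, KEAP1 = 1 / 34),
      SVR_DAA      = c(TP53 = 0.75, CTNNB1 = 0.30, ARID2 = 0,
                       PREX2 = 1 / 8, KEAP1 = 1 / 8),
      SVR_IFN      = c(TP53 = 0.25, CTNNB1 = 0.30, ARID2 = 1 / 24,
                       PREX2 = 3 / 24, KEAP1 = 3 / 24),
      SVR_OTHER    = c(TP53 = 0.30, CTNNB1 = 0.30, ARID2 = 0,
                       PREX2 = 0, KEAP1 = 0)),
    artifact_rate = 20, n_true_variants = 100,
    expression_effects = data.frame(
      gene_set = c("TP53_INACTIVATION", "PI3K_MTOR_UP", "CIN",
                   "CYTOLYTIC_ACTIVITY", "TCELL_INFLAMED"),
      group = c("SVR_DAA", "SVR_DAA", "SVR_DAA", "SVR", "SVR"),
      tissue = c("TUMOR", "TUMOR", "TUMOR", "NORMAL", "NORMAL"),
      shift_log2 = c(1, 1, 1, -1, -1), stringsAsFactors = FALSE),
    score_correlation = 0.9,
    cnv_deletion_rate = c(HCV_POSITIVE = 1.5, SVR_DAA = 4,
                          SVR_IFN = 1.5, SVR_OTHER = 1.5),
    cnv_gain_rate = 2, cnv_loh_rate = 1,
    signature_mixture = c(Signature.1 = 0.5, Signature.4 = 0.1,
                          Signature.5 = 0.25, Signature.16 = 0.15),
    survival_params = list(os_rate = 0.004, rfs_rate = 0.015,
                           censor_rate = 0.012),
    gene_noise_sd = 0.5, n_genes = 2000, seed = 1) {
  cfg <- as.list(environment())
  counts <- c(n_hcv_positive, n_svr_daa, n_svr_ifn, n_svr_other)
  if (any(counts < 0) || sum(counts) <= 0) {
    stop("stratum sizes must be non-negative with a positive total")
  }
  prev <- unlist(driver_prevalence)
  stopifnot(all(prev >= 0), all(prev <= 1),
            artifact_rate >= 0, n_true_variants >= 0,
            all(signature_mixture >= 0),
            abs(sum(signature_mixture) - 1) < 1e-8,
            score_correlation >= 0, score_correlation < 1)
  class(cfg) <- "svrhcc_config"
  cfg
}

#' Plant a mean log2 shift on a gene set
#'
#' Adds `shift_log2` to the expression of every listed gene in the masked
#' samples; all other cells are untouched.
#'
#' @param matrix genes x samples log2 matrix.
#' @param genes Genes to shift (must all be present).
#' @param sample_mask Logical vector over columns.
#' @param shift_log2 Mean shift on the log2 scale.
#' @return The shifted matrix.
#' @export
plant_expression_effect <- function(matrix, genes, sample_mask, shift_log2) {
  unknown <- setdiff(genes, rownames(matrix))
  if (length(unknown)) {
    stop(sprintf("unknown gene(s): %s", paste(unknown, collapse = ", ")))
  }
  stopifnot(is.logical(sample_mask), length(sample_mask) == ncol(matrix))
  matrix[genes, sample_mask] <- matrix[genes, sample_mask] + shift_log2
  matrix
}

# latent loading giving a target correlation between two set-mean scores with
# member-gene noise SDs se1, se2: solves a^2/sqrt((a^2+se1^2)(a^2+se2^2)) = rho
latent_loading <- function(rho, se1, se2) {
  if (rho <= 0) return(0)
  f <- function(a2) a2 / sqrt((a2 + se1^2) * (a2 + se2^2)) - rho
  sqrt(stats::uniroot(f, c(1e-9, 1e4))$root)
}

clean_variant_metrics <- function(n, variant_type) {
  indel <- variant_type %in% c("INS", "DEL")
  depth <- round(pmax(60, stats::rnorm(n, 150, 40)))
  vaf <- pmin(95, pmax(5, stats::rnorm(n, 30, 10)))
  var_reads <- pmax(2, round(depth * vaf / 100))
  fwd <- pmax(1, stats::rbinom(n, var_reads, 0.5))
  fwd <- pmin(fwd, var_reads - 1)
  data.frame(
    variant_type = variant_type,
    quality_score = round(pmax(50, stats::rnorm(n, 120, 30)), 1),
    depth = depth,
    vaf_tumor = round(vaf, 2),
    vaf_normal = round(ifelse(indel, 0, stats::runif(n, 0, 2.0)), 2),
    var_reads_fwd = fwd, var_reads_rev = var_reads - fwd,
    avg_clipped_length = round(pmax(90, stats::rnorm(n, 115, 10)), 1),
    avg_pos_as_fraction = round(stats::runif(n, 0.2, 0.8), 3),
    ref_mapq0 = stats::rpois(n, 1),
    ref_mapq1 = pmax(10, depth - var_reads),
    var_mapq0 = 0L, var_mapq1 = var_reads,
    avg_read_len_ref = round(stats::rnorm(n, 160, 8), 1),
    avg_read_len_var = 0, stringsAsFactors = FALSE)
}

# breaks exactly the chosen criterion (1..9) of an otherwise clean variant
break_criterion <- function(v, crit) {
  indel <- v$variant_type %in% c("INS", "DEL")
  if (crit == 1) v$quality_score <- round(stats::runif(1, 5, 49), 1)
  else if (crit == 2) v$depth <- round(stats::runif(1, 5, if (indel) 49 else 19))
  else if (crit == 3) v$vaf_normal <- round(stats::runif(1, 3, 15), 2)
  else if (crit == 4) { v$var_reads_rev <- 0L }
  else if (crit == 5) v$avg_clipped_length <- round(stats::runif(1, 40, 89), 1)
  else if (crit == 6) v$avg_pos_as_fraction <- round(stats::runif(1, 0, 0.045), 3)
  else if (crit == 7) {
    # low MAPQ1/MAPQ0 ratio without MAPQ0 enrichment relative to ref reads
    v$var_mapq0 <- 6L; v$var_mapq1 <- 3L
    v$ref_mapq0 <- 70L; v$ref_mapq1 <- 30L
  } else if (crit == 8) {
    v$avg_read_len_var <- v$avg_read_len_ref - round(stats::runif(1, 85, 120), 1)
  } else if (crit == 9) {
    # MAPQ0 enrichment with ratio still >= 0.8
    v$var_mapq0 <- 6L; v$var_mapq1 <- 6L
    v$ref_mapq0 <- 0L; v$ref_mapq1 <- 150L
  }
  v
}

simulate_sample_variants <- function(sample_id, driver_genes, cfg, universe,
                                     signatures) {
  n_true <- stats::rpois(1, cfg$n_true_variants)
  n_art <- stats::rpois(1, cfg$artifact_rate)
  n <- n_true + n_art + length(driver_genes)
  if (n == 0) {
    return(list(variants = NULL, truth = NULL))
  }
  vt <- sample(c("SNV", "INS", "DEL"), n, replace = TRUE,
               prob = c(0.9, 0.05, 0.05))
  vt[seq_along(driver_genes)] <- "SNV"  # planted drivers kept simple
  m <- clean_variant_metrics(n, vt)
  m$avg_read_len_var <- round(m$avg_read_len_ref + stats::rnorm(n, 0, 8), 1)
  ctx <- sample_mutation_contexts(n, cfg$signature_mixture, signatures)
  is_snv <- vt == "SNV"
  ref <- ctx$ref; alt <- ctx$alt
  ref[vt == "DEL"] <- paste0(ctx$flank5[vt == "DEL"], ctx$ref[vt == "DEL"])
  alt[vt == "DEL"] <- ctx$flank5[vt == "DEL"]
  ref[vt == "INS"] <- ctx$flank5[vt == "INS"]
  alt[vt == "INS"] <- paste0(ctx$flank5[vt == "INS"], ctx$alt[vt == "INS"])
  # background variants avoid the prevalence-controlled driver genes, so the
  # configured prevalences are exactly the cohort frequencies
  controlled <- unique(unlist(lapply(cfg$driver_prevalence, names)))
  genes <- c(driver_genes,
             sample(setdiff(universe, controlled),
                    n - length(driver_genes), replace = TRUE))
  v <- data.frame(
    sample = sample_id,
    chrom = as.character(sample.int(22, n, replace = TRUE)),
    pos = sample.int(1e8, n), ref = ref, alt = alt,
    flank5 = ctx$flank5, flank3 = ctx$flank3,
    gene = genes, effect = "missense", m, stringsAsFactors = FALSE)
  # artifacts occupy the tail rows; each violates exactly one criterion
  art_idx <- if (n_art > 0) (n - n_art + 1):n else integer(0)
  crit <- rep(NA_integer_, n)
  for (i in art_idx) {
    crit[i] <- sample(1:9, 1)
    v[i, ] <- break_criterion(v[i, , drop = FALSE], crit[i])
  }
  ord <- sample.int(n)  # shuffle so artifacts are not positionally encoded
  v <- v[ord, , drop = FALSE]
  crit <- crit[ord]
  v$variant_id <- paste0(sample_id, "_v", seq_len(n))
  truth <- data.frame(sample = sample_id, variant_id = v$variant_id,
                      is_artifact = !is.na(crit),
                      violated_criterion = crit, stringsAsFactors = FALSE)
  list(variants = v, truth = truth)
}

simulate_clinical <- function(cfg, tp53_mutated) {
  n <- cfg$n_hcv_positive + cfg$n_svr_daa + cfg$n_svr_ifn + cfg$n_svr_other
  group <- rep(GROUPS, c(cfg$n_hcv_positive, cfg$n_svr_daa,
                         cfg$n_svr_ifn, cfg$n_svr_other))
  id <- sprintf("P%03d", seq_len(n))
  stage_probs <- list(HCV_POSITIVE = c(0.15, 0.30, 0.40, 0.15),
                      SVR_DAA = c(0.25, 0.40, 0.25, 0.10),
                      SVR_IFN = c(0.35, 0.40, 0.20, 0.05),
                      SVR_OTHER = c(0.35, 0.40, 0.20, 0.05))
  vp_probs <- list(HCV_POSITIVE = c(0.70, 0.20, 0.07, 0.03),
                   SVR_DAA = c(0.40, 0.30, 0.20, 0.10),
                   SVR_IFN = c(0.85, 0.10, 0.04, 0.01),
                   SVR_OTHER = c(0.85, 0.10, 0.04, 0.01))
  liver_probs <- list(HCV_POSITIVE = c(0.05, 0.45, 0.50),
                      SVR_DAA = c(0.05, 0.25, 0.70),
                      SVR_IFN = c(0.30, 0.50, 0.20),
                      SVR_OTHER = c(0.30, 0.50, 0.20))
  stage <- vapply(group, function(g)
    sample(c("I", "II", "III", "IV"), 1, prob = stage_probs[[g]]), character(1))
  vp <- vapply(group, function(g)
    sample(c("Vp0", "Vp1", "Vp2", "Vp3"), 1, prob = vp_probs[[g]]), character(1))
  liver <- vapply(group, function(g)
    sample(c("NL", "CH_LF", "LC"), 1, prob = liver_probs[[g]]), character(1))
  sp <- cfg$survival_params
  os_t <- stats::rexp(n, sp$os_rate); os_c <- stats::rexp(n, sp$censor_rate)
  rfs_t <- stats::rexp(n, sp$rfs_rate); rfs_c <- stats::rexp(n, sp$censor_rate)
  # IHC tied to TP53 status: mutants show diffuse nuclear staining or a null
  # pattern; wild-type tumors show patchy low-level staining
  ihc <- numeric(n); reaction <- logical(n)
  for (i in seq_len(n)) {
    if (tp53_mutated[i]) {
      if (stats::runif(1) < 0.25) { ihc[i] <- 0; reaction[i] <- FALSE }
      else { ihc[i] <- round(min(100, max(30, stats::rnorm(1, 65, 15)))); reaction[i] <- TRUE }
    } else {
      if (stats::runif(1) < 0.05) { ihc[i] <- 0; reaction[i] <- FALSE }
      else { ihc[i] <- round(stats::runif(1, 1, 20)); reaction[i] <- TRUE }
    }
  }
  data.frame(
    patient_id = id, sample = id, group = group, stage = stage,
    portal_vein_invasion = vp, liver_background = liver,
    os_months = round(pmin(os_t, os_c), 1), os_event = as.integer(os_t <= os_c),
    rfs_months = round(pmin(rfs_t, rfs_c), 1),
    rfs_event = as.integer(rfs_t <= rfs_c),
    ihc_p53_percent = ihc, ihc_any_reaction = reaction,
    tumor_content = round(stats::runif(n, 0.3, 0.9), 2),
    stringsAsFactors = FALSE)
}

assign_drivers <- function(cfg, clinical) {
  # round(prevalence * n) samples per group carry each driver, so cohort
  # frequencies land exactly on the configured fractions
  genes <- unique(unlist(lapply(cfg$driver_prevalence, names)))
  flags <- matrix(FALSE, nrow(clinical), length(genes),
                  dimnames = list(clinical$sample, genes))
  for (g in GROUPS) {
    members <- which(clinical$group == g)
    prev <- cfg$driver_prevalence[[g]]
    for (gene in names(prev)) {
      k <- round(prev[[gene]] * length(members))
      if (k > 0) flags[sample(members, k), gene] <- TRUE
    }
  }
  flags
}

build_gene_universe <- function(cfg, gene_sets, catalogue) {
  core <- unique(c(catalogue$gene, unlist(lapply(gene_sets, `[[`, "genes"))))
  n_fill <- max(0, cfg$n_genes - length(core))
  c(core, sprintf("GENE%04d", seq_len(n_fill)))
}

simulate_expression <- function(cfg, clinical, gene_sets, universe) {
  n <- nrow(clinical)
  samples <- clinical$sample
  cols <- c(paste0(samples, "_T"), paste0(samples, "_N"))
  gene_mean <- stats::rnorm(length(universe), 8, 1.5)
  m <- matrix(stats::rnorm(length(universe) * 2 * n, 0, cfg$gene_noise_sd),
              nrow = length(universe),
              dimnames = list(universe, cols)) + gene_mean
  meta <- data.frame(column = cols,
                     sample = rep(samples, 2),
                     tissue = rep(c("TUMOR", "NORMAL"), each = n),
                     group = rep(clinical$group, 2), stringsAsFactors = FALSE)
  # latent instability factor couples the TP53-inactivation and CIN scores
  tp53_genes <- gene_sets$TP53_INACTIVATION$genes
  cin_genes <- gene_sets$CIN$genes
  se1 <- cfg$gene_noise_sd / sqrt(length(tp53_genes))
  se2 <- cfg$gene_noise_sd / sqrt(length(cin_genes))
  a <- latent_loading(cfg$score_correlation, se1, se2)
  z <- stats::rnorm(n)
  tumor_cols <- meta$tissue == "TUMOR"
  m[tp53_genes, tumor_cols] <- m[tp53_genes, tumor_cols] +
    rep(a * z, each = length(tp53_genes))
  m[cin_genes, tumor_cols] <- m[cin_genes, tumor_cols] +
    rep(a * z, each = length(cin_genes))
  for (i in seq_len(nrow(cfg$expression_effects))) {
    eff <- cfg$expression_effects[i, ]
    set_genes <- gene_sets[[eff$gene_set]]$genes
    if (is.null(set_genes)) next
    grp_match <- if (eff$group == "SVR") {
      meta$group %in% c("SVR_DAA", "SVR_IFN", "SVR_OTHER")
    } else meta$group == eff$group
    mask <- grp_match & meta$tissue == eff$tissue
    m <- plant_expression_effect(m, set_genes, mask, eff$shift_log2)
  }
  list(matrix = m, meta = meta)
}

simulate_segments <- function(cfg, clinical, gene_positions) {
  chrom_len <- 1.5e8
  segs <- list(); events <- list()
  for (i in seq_len(nrow(clinical))) {
    s <- clinical$sample[i]; g <- clinical$group[i]
    background <- data.frame(
      sample = s, chrom = as.character(1:22), start = 1L,
      end = as.integer(chrom_len),
      n_snvs = stats::rpois(22, 400),
      copy_number = round(stats::rnorm(22, 2, 0.04), 3),
      p_value = round(stats::runif(22, 0.2, 1), 4),
      log2_mbaf_adj = round(stats::rnorm(22, 0, 0.02), 3),
      stringsAsFactors = FALSE)
    mk_events <- function(k, cn_lo, cn_hi, mbaf_lo, mbaf_hi, type) {
      if (k == 0) return(NULL)
      st <- sample.int(chrom_len - 2e7, k)
      data.frame(
        sample = s, chrom = as.character(sample.int(22, k, replace = TRUE)),
        start = st, end = st + round(stats::runif(k, 5e6, 2e7)),
        n_snvs = stats::rpois(k, 80),
        copy_number = round(stats::runif(k, cn_lo, cn_hi), 3),
        p_value = signif(stats::runif(k, 1e-8, 5e-4), 3),
        log2_mbaf_adj = round(stats::runif(k, mbaf_lo, mbaf_hi), 3),
        truth = type, stringsAsFactors = FALSE)
    }
    ev <- rbind(
      mk_events(stats::rpois(1, cfg$cnv_deletion_rate[[g]]),
                0.6, 1.45, 0.25, 0.5, "LOSS"),
      mk_events(stats::rpois(1, cfg$cnv_gain_rate), 2.6, 4.0, 0.1, 0.4, "GAIN"),
      mk_events(stats::rpois(1, cfg$cnv_loh_rate), 1.7, 2.3, 0.25, 0.5, "CN_LOH"))
    segs[[s]] <- background
    if (!is.null(ev)) events[[s]] <- ev
  }
  ev_all <- if (length(events)) do.call(rbind, events) else NULL
  seg_all <- do.call(rbind, segs)
  if (!is.null(ev_all)) {
    seg_plain <- ev_all[, names(seg_all)]
    seg_all <- rbind(seg_all, seg_plain)
  }
  seg_all <- seg_all[order(seg_all$sample, as.integer(seg_all$chrom),
                           seg_all$start), ]
  rownames(seg_all) <- NULL
  list(segments = seg_all, event_truth = ev_all)
}

#' Simulate only the expression component of a cohort
#'
#' Draws the genes x (tumor + matched normal) log2 matrix with the
#' configured planted effects and latent score coupling, without variants,
#' segments or clinical covariates beyond the group labels. Useful for
#' replicate-based power studies of the expression layer.
#'
#' @param config A [cohort_config()].
#' @return List: `matrix`, `meta` (column, sample, tissue, group),
#'   `gene_sets`.
#' @export
simulate_expression_cohort <- function(config = cohort_config()) {
  cfg <- config
  set.seed(cfg$seed)
  gene_sets <- packaged_gene_sets()
  catalogue <- load_gene_catalogue()
  universe <- build_gene_universe(cfg, gene_sets, catalogue)
  n <- cfg$n_hcv_positive + cfg$n_svr_daa + cfg$n_svr_ifn + cfg$n_svr_other
  clinical <- data.frame(
    sample = sprintf("P%03d", seq_len(n)),
    group = rep(GROUPS, c(cfg$n_hcv_positive, cfg$n_svr_daa,
                          cfg$n_svr_ifn, cfg$n_svr_other)),
    stringsAsFactors = FALSE)
  expr <- simulate_expression(cfg, clinical, gene_sets, universe)
  list(matrix = expr$matrix, meta = expr$meta, gene_sets = gene_sets)
}

#' Simulate a full synthetic cohort
#'
#' Draws, for the configured strata: clinical covariates with survival and
#' p53 IHC; per-sample variant tables mixing true somatic variants (which
#' pass all ten filters) with injected artifacts, each violating exactly one
#' known criterion recorded in the truth labels; a genes x (tumor + matched
#' normal) log2 expression matrix with the configured planted effects and
#' latent score coupling; copy-number segment tables with planted
#' gain/loss/CN-LOH events; and the packaged gene sets and catalogue.
#' Deleted and gained event segments also shift the tumor expression of the
#' genes they span (-3 / +3 log2), so the integrative caller has signal.
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional directory; when given, every interchange file is
#'   written (variants MAF + VCF, expression TSV, segments TSV, clinical CSV,
#'   gene sets GMT, truth TSVs).
#' @return List of class `svrhcc_cohort`: `clinical`, `variants`, `truth`,
#'   `expression` (+ `expression_meta`), `segments`, `segment_truth`,
#'   `driver_flags`, `gene_sets`, `catalogue`, `gene_positions`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), out_dir = NULL) {
  cfg <- config
  set.seed(cfg$seed)
  gene_sets <- packaged_gene_sets()
  catalogue <- load_gene_catalogue()
  signatures <- load_signature_matrix()
  universe <- build_gene_universe(cfg, gene_sets, catalogue)
  gene_positions <- data.frame(
    gene = universe,
    chrom = as.character(sample.int(22, length(universe), replace = TRUE)),
    midpoint = sample.int(1.4e8, length(universe)), stringsAsFactors = FALSE)

  # drivers first so clinical IHC can be tied to TP53 status
  n <- cfg$n_hcv_positive + cfg$n_svr_daa + cfg$n_svr_ifn + cfg$n_svr_other
  pre_clinical <- data.frame(
    sample = sprintf("P%03d", seq_len(n)),
    group = rep(GROUPS, c(cfg$n_hcv_positive, cfg$n_svr_daa,
                          cfg$n_svr_ifn, cfg$n_svr_other)),
    stringsAsFactors = FALSE)
  driver_flags <- assign_drivers(cfg, pre_clinical)
  clinical <- simulate_clinical(cfg, tp53_mutated = driver_flags[, "TP53"])

  per_sample <- lapply(seq_len(nrow(clinical)), function(i) {
    drv <- colnames(driver_flags)[driver_flags[i, ]]
    simulate_sample_variants(clinical$sample[i], drv, cfg, universe, signatures)
  })
  variants <- do.call(rbind, lapply(per_sample, `[[`, "variants"))
  truth <- do.call(rbind, lapply(per_sample, `[[`, "truth"))
  rownames(variants) <- rownames(truth) <- NULL

  expr <- simulate_expression(cfg, clinical, gene_sets, universe)
  seg <- simulate_segments(cfg, clinical, gene_positions)

  # couple planted CNV events into tumor expression
  if (!is.null(seg$event_truth)) {
    ev <- seg$event_truth
    for (i in seq_len(nrow(ev))) {
      hit <- gene_positions$chrom == ev$chrom[i] &
        gene_positions$midpoint >= ev$start[i] &
        gene_positions$midpoint <= ev$end[i]
      if (!any(hit)) next
      col <- paste0(ev$sample[i], "_T")
      shift <- switch(ev$truth[i], LOSS = -3, GAIN = 3, 0)
      expr$matrix[hit, col] <- expr$matrix[hit, col] + shift
    }
  }

  bundle <- structure(list(
    clinical = clinical, variants = variants, truth = truth,
    expression = expr$matrix, expression_meta = expr$meta,
    segments = seg$segments, segment_truth = seg$event_truth,
    driver_flags = driver_flags, gene_sets = gene_sets,
    catalogue = catalogue, gene_positions = gene_positions,
    config = cfg), class = "svrhcc_cohort")
  if (!is.null(out_dir)) write_cohort(bundle, out_dir)
  bundle
}

#' Write every cohort interchange file
#'
#' @param bundle An `svrhcc_cohort`.
#' @param out_dir Output directory (created if absent).
#' @return Named vector of written paths.
#' @export
write_cohort <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_variants_maf(bundle$variants, p("variants.maf.tsv"))
  vcf_dir <- p("vcf"); dir.create(vcf_dir, showWarnings = FALSE)
  for (s in unique(bundle$variants$sample)) {
    write_variants_vcf(bundle$variants[bundle$variants$sample == s, ],
                       file.path(vcf_dir, paste0(s, ".vcf")), sample = s)
  }
  write_expression(bundle$expression, p("expression.tsv"))
  utils::write.table(bundle$expression_meta, p("expression_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_segments(bundle$segments, p("segments.seg.tsv"))
  write_clinical(bundle$clinical, p("clinical.csv"))
  write_gmt(bundle$gene_sets, p("gene_sets.gmt"))
  utils::write.table(bundle$truth, p("variant_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$catalogue, p("catalogue.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$gene_positions, p("gene_positions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  stats::setNames(files, basename(files))
}
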