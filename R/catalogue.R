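# Cancer-gene catalogue, driver annotation, tumor mutation burden, the
# gene x group mutation-frequency table, and the integrative
# expression x copy-number driver-aberration caller.

#' Load a cancer-gene catalogue
#'
#' The packaged catalogue is an editable TSV of ~100 well-known cancer genes
#' with roles (`ONCOGENE`, `TSG`, `OTHER_CANCER_GENE`) and source tags; it is
#' a desk-scale stand-in for the curated multi-source catalogues such
#' studies compile (which run to ~1000 genes).
#'
#' @param path Catalogue TSV (columns gene, role, source); default packaged.
#' @return data.frame with unique `gene`, `role`, `source`.
#' @export
load_gene_catalogue <- function(path = system.file("extdata",
    "cancer_gene_catalogue.tsv", package = "svrhcc")) {
  cat0 <- utils::read.delim(path, stringsAsFactors = FALSE)
  stop_missing(cat0, c("gene", "role"), "load_gene_catalogue")
  if (anyDuplicated(cat0$gene)) stop("duplicate gene symbols in catalogue")
  if (!all(cat0$role %in% c("ONCOGENE", "TSG", "OTHER_CANCER_GENE"))) {
    stop("catalogue roles must be ONCOGENE, TSG or OTHER_CANCER_GENE")
  }
  cat0
}

#' Flag catalogue (driver) genes in a variant table
#'
#' @param variants data.frame with a `gene` column.
#' @param catalogue [load_gene_catalogue()] data.frame (possibly empty).
#' @return The input with `driver` (logical) and `driver_role` (role or
#'   `"NONE"`) columns appended.
#' @export
annotate_drivers <- function(variants, catalogue = load_gene_catalogue()) {
  stop_missing(variants, "gene", "annotate_drivers")
  idx <- match(variants$gene, catalogue$gene)
  variants$driver <- !is.na(idx)
  variants$driver_role <- ifelse(is.na(idx), "NONE", catalogue$role[idx])
  variants
}

#' Tumor mutation burden
#'
#' Passing somatic mutations (SNVs plus indels) per megabase of sequenced
#' footprint. The default footprint of 34.8 Mb is the RefSeq exonic footprint
#' of the exome design; the full design footprint (57.7 Mb) can be supplied
#' instead.
#'
#' @param variants Filtered variant data.frame (or a count).
#' @param footprint_mb Sequenced footprint in megabases (> 0).
#' @return Mutations per megabase.
#' @examples
#' compute_tmb(348, footprint_mb = 34.8)  # 10
#' @export
compute_tmb <- function(variants, footprint_mb = 34.8) {
  if (footprint_mb <= 0) stop("footprint_mb must be positive")
  n <- if (is.data.frame(variants)) nrow(variants) else as.numeric(variants)
  n / footprint_mb
}

#' Gene x group mutation-frequency table
#'
#' A sample counts once per gene regardless of how many mutations it carries
#' in that gene. Percentages are half-up rounded to one decimal.
#'
#' @param variants Driver-flagged variant data.frame (`sample`, `gene`).
#' @param clinical data.frame with `sample` and `group` for every sample
#'   (including unmutated ones — they provide the denominators).
#' @param genes Genes to tabulate (default: all genes in `variants`).
#' @return data.frame: gene, group, mutated, total, percent.
#' @export
mutation_frequency_matrix <- function(variants, clinical,
                                      genes = sort(unique(variants$gene))) {
  stop_missing(variants, c("sample", "gene"), "mutation_frequency_matrix")
  stop_missing(clinical, c("sample", "group"), "mutation_frequency_matrix")
  nogrp <- unique(variants$sample[!variants$sample %in% clinical$sample])
  if (length(nogrp)) {
    stop(sprintf("sample(s) missing a group: %s", paste(nogrp, collapse = ", ")))
  }
  groups <- unique(clinical$group)
  out <- do.call(rbind, lapply(genes, function(g) {
    mut_samples <- unique(variants$sample[variants$gene == g])
    do.call(rbind, lapply(groups, function(gr) {
      members <- clinical$sample[clinical$group == gr]
      mutated <- sum(members %in% mut_samples)
      data.frame(gene = g, group = gr, mutated = mutated,
                 total = length(members),
                 percent = percent_mutated(mutated, length(members)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Oncoprint-style gene x sample event matrix
#'
#' @param variants Driver-flagged variants (`sample`, `gene`, optionally
#'   `variant_type`).
#' @param aberrations Optional [call_expression_cnv_aberrations()] table;
#'   AMP/DEL events are appended to the cell codes.
#' @param samples,genes Row/column universes (defaults taken from the inputs).
#' @return Character matrix genes x samples; cells like `"SNV"`, `"SNV;AMP"`,
#'   `""`.
#' @export
oncoprint_matrix <- function(variants, aberrations = NULL,
                             samples = NULL, genes = NULL) {
  samples <- samples %||% sort(unique(c(variants$sample, aberrations$sample)))
  genes <- genes %||% sort(unique(c(variants$gene, aberrations$gene)))
  m <- matrix("", nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  add <- function(g, s, code) {
    cur <- m[g, s]
    m[g, s] <<- if (nzchar(cur)) {
      if (code %in% strsplit(cur, ";")[[1]]) cur else paste(cur, code, sep = ";")
    } else code
  }
  for (i in seq_len(nrow(variants))) {
    g <- variants$gene[i]; s <- variants$sample[i]
    if (g %in% genes && s %in% samples) {
      add(g, s, variants$variant_type[i] %||% "MUT")
    }
  }
  if (!is.null(aberrations)) {
    ab <- aberrations[aberrations$call != "NONE", , drop = FALSE]
    for (i in seq_len(nrow(ab))) {
      g <- ab$gene[i]; s <- ab$sample[i]
      if (g %in% genes && s %in% samples) {
        add(g, s, c(AMPLIFIED = "AMP", DELETED = "DEL")[ab$call[i]])
      }
    }
  }
  m
}

gene_copy_number <- function(gene_pos, segments) {
  # copy number of the segment containing the gene midpoint; when segments
  # overlap the narrowest covering segment wins (a focal event inside a
  # chromosome-scale background segment), with start-position ties resolved
  # to the earlier segment; no covering segment -> NA
  hits <- which(segments$start <= gene_pos & segments$end >= gene_pos)
  if (!length(hits)) return(NA_real_)
  width <- segments$end[hits] - segments$start[hits]
  hits <- hits[order(width, segments$start[hits])]
  segments$copy_number[hits[1]]
}

#' Integrative expression x copy-number driver-aberration calls
#'
#' Amplification of an oncogene requires at least a fivefold expression
#' increase over the matched normal and a copy number of at least 2.5;
#' deletion of a tumor suppressor requires at least a fivefold decrease
#' (fold change <= 0.2) and a copy number of at most 1.5. Boundaries are
#' inclusive. The shortlist keeps genes whose two-group event counts differ
#' at Fisher p < 0.1 or that are aberrant in at least `min_events` samples.
#'
#' @param expression_tumor,expression_normal Normalized genes x samples log2
#'   matrices (matched columns = same patients). Samples without a matched
#'   normal column are skipped with a warning.
#' @param copy_number genes x samples matrix of gene-level copy number (use
#'   [gene_level_copy_number()] to derive it from segments); genes absent
#'   default to 2 (copy-neutral).
#' @param catalogue Gene catalogue; only ONCOGENE / TSG entries can be called.
#' @param clinical Optional data.frame (`sample`, `group`); when it contains
#'   exactly two groups among the scored samples the shortlist Fisher test is
#'   computed.
#' @param min_events Shortlist count threshold (default 6).
#' @return List with `calls` (sample, gene, role, fold_change linear,
#'   copy_number, call) and `shortlist` (gene, events, fisher_p, reason).
#' @export
call_expression_cnv_aberrations <- function(expression_tumor, expression_normal,
                                            copy_number, catalogue = load_gene_catalogue(),
                                            clinical = NULL, min_events = 6) {
  cat2 <- catalogue[catalogue$role %in% c("ONCOGENE", "TSG"), , drop = FALSE]
  genes <- intersect(cat2$gene, rownames(expression_tumor))
  samples <- colnames(expression_tumor)
  matched <- samples %in% colnames(expression_normal)
  if (any(!matched)) {
    warning(sprintf("sample(s) without matched normal skipped: %s",
                    paste(samples[!matched], collapse = ", ")))
  }
  samples <- samples[matched]
  calls <- do.call(rbind, lapply(samples, function(s) {
    fc <- 2^(expression_tumor[genes, s] - expression_normal[genes, s])
    cn <- if (is.null(copy_number)) rep(2, length(genes)) else {
      x <- rep(2, length(genes))
      hit <- genes %in% rownames(copy_number) & s %in% colnames(copy_number)
      if (s %in% colnames(copy_number)) {
        gi <- intersect(genes, rownames(copy_number))
        x[match(gi, genes)] <- copy_number[gi, s]
      }
      x
    }
    role <- cat2$role[match(genes, cat2$gene)]
    # relative 1e-9 slack so a fold change reconstructed through log2
    # arithmetic still hits the inclusive boundary exactly
    call <- ifelse(role == "ONCOGENE" & fc >= 5 * (1 - 1e-9) & cn >= 2.5,
                   "AMPLIFIED",
            ifelse(role == "TSG" & fc <= 0.2 * (1 + 1e-9) & cn <= 1.5,
                   "DELETED", "NONE"))
    data.frame(sample = s, gene = genes, role = role, fold_change = fc,
               copy_number = cn, call = call, stringsAsFactors = FALSE)
  }))
  rownames(calls) <- NULL
  shortlist <- NULL
  ev <- calls[calls$call != "NONE", , drop = FALSE]
  counts <- table(factor(ev$gene, levels = genes))
  two_groups <- !is.null(clinical) &&
    length(unique(clinical$group[clinical$sample %in% samples])) == 2
  shortlist <- do.call(rbind, lapply(genes, function(g) {
    n_ev <- as.integer(counts[[g]])
    fp <- NA_real_
    if (two_groups) {
      grp <- clinical$group[match(samples, clinical$sample)]
      lv <- unique(grp)
      aberr <- samples %in% ev$sample[ev$gene == g]
      fp <- compare_frequencies(sum(aberr & grp == lv[1]), sum(grp == lv[1]),
                                sum(aberr & grp == lv[2]), sum(grp == lv[2]),
                                method = "fisher")$p
    }
    keep <- (n_ev >= min_events) || (!is.na(fp) && fp < 0.1)
    if (!keep) return(NULL)
    data.frame(gene = g, events = n_ev, fisher_p = fp,
               reason = paste(c(if (!is.na(fp) && fp < 0.1) "fisher_p<0.1",
                                if (n_ev >= min_events) "events>=min"),
                              collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  list(calls = calls,
       shortlist = shortlist %||% data.frame(gene = character(),
                                             events = integer(),
                                             fisher_p = numeric(),
                                             reason = character()))
}

#' Gene-level copy number from classified segments
#'
#' Assigns each gene the copy number of the segment containing its midpoint
#' (ties at a segment boundary resolve to the earlier segment); genes not
#' covered by any segment get copy number 2.
#'
#' @param gene_positions data.frame: gene, chrom, midpoint.
#' @param segments Per-sample segment table (sample, chrom, start, end,
#'   copy_number).
#' @return genes x samples numeric matrix.
#' @export
gene_level_copy_number <- function(gene_positions, segments) {
  stop_missing(gene_positions, c("gene", "chrom", "midpoint"),
               "gene_level_copy_number")
  samples <- unique(segments$sample)
  m <- matrix(2, nrow = nrow(gene_positions), ncol = length(samples),
              dimnames = list(gene_positions$gene, samples))
  for (s in samples) {
    seg_s <- segments[segments$sample == s, , drop = FALSE]
    for (ch in unique(gene_positions$chrom)) {
      seg_c <- seg_s[seg_s$chrom == ch, , drop = FALSE]
      if (!nrow(seg_c)) next
      seg_c <- seg_c[order(seg_c$start), , drop = FALSE]
      gi <- which(gene_positions$chrom == ch)
      for (i in gi) {
        cn <- gene_copy_number(gene_positions$midpoint[i], seg_c)
        if (!is.na(cn)) m[i, s] <- cn
      }
    }
  }
  m
}
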