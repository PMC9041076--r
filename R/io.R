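# Readers and writers for the pipeline's interchange formats: MAF-like
# variant TSV, minimal VCFv4.2 with metrics in INFO, SEG-like segment TSV,
# genes x samples expression TSV, and clinical CSV.

VCF_INFO_KEYS <- c(
  VT = "variant_type", QS = "quality_score", DP2 = "depth",
  VAFT = "vaf_tumor", VAFN = "vaf_normal", VRF = "var_reads_fwd",
  VRR = "var_reads_rev", ACL = "avg_clipped_length",
  APF = "avg_pos_as_fraction", RM0 = "ref_mapq0", RM1 = "ref_mapq1",
  VM0 = "var_mapq0", VM1 = "var_mapq1", ARR = "avg_read_len_ref",
  ARV = "avg_read_len_var", GENE = "gene", EFF = "effect")

#' Write / read a MAF-like variant TSV
#'
#' Plain TSV with one row per variant candidate carrying all read-level
#' metric columns; the primary interchange format of the pipeline.
#'
#' @param variants Variant data.frame.
#' @param path File path.
#' @return `read_variants_maf` returns the data.frame.
#' @export
write_variants_maf <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_variants_maf
#' @export
read_variants_maf <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

#' Write / read variants as minimal VCFv4.2
#'
#' One site per row; the read-level filter metrics travel in INFO under
#' short keys (`QS`, `DP2`, `VAFT`, ...; see the header the writer emits).
#' The reader understands exactly this schema.
#'
#' @param variants Variant data.frame (one sample).
#' @param path File path.
#' @param sample Sample name recorded in the header.
#' @export
write_variants_vcf <- function(variants, path, sample = "sample1") {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##sample=%s", sample),
           vapply(names(VCF_INFO_KEYS), function(k) {
             typ <- if (VCF_INFO_KEYS[[k]] %in% c("variant_type", "gene", "effect"))
               "String" else "Float"
             sprintf("##INFO=<ID=%s,Number=1,Type=%s,Description=\"%s\">",
                     k, typ, VCF_INFO_KEYS[[k]])
           }, character(1)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    info <- paste(vapply(names(VCF_INFO_KEYS), function(k)
      paste0(k, "=", v[[VCF_INFO_KEYS[[k]]]]), character(1)), collapse = ";")
    paste(v$chrom, v$pos, ".", v$ref, v$alt,
          format(v$quality_score, trim = TRUE), ".", info, sep = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_variants_vcf
#' @export
read_variants_vcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character()))
  }
  fields <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  info <- lapply(strsplit(fields[, 8], ";", fixed = TRUE), function(kv) {
    parts <- strsplit(kv, "=", fixed = TRUE)
    stats::setNames(vapply(parts, `[`, character(1), 2),
                    vapply(parts, `[`, character(1), 1))
  })
  get <- function(key, as_num = TRUE) {
    x <- vapply(info, function(r) r[[key]] %||% NA_character_, character(1))
    if (as_num) as.numeric(x) else x
  }
  out <- data.frame(chrom = fields[, 1], pos = as.integer(fields[, 2]),
                    ref = fields[, 4], alt = fields[, 5],
                    stringsAsFactors = FALSE)
  for (k in names(VCF_INFO_KEYS)) {
    fld <- VCF_INFO_KEYS[[k]]
    out[[fld]] <- get(k, as_num = !fld %in% c("variant_type", "gene", "effect"))
  }
  out
}

#' Write / read a SEG-like copy-number segment TSV
#'
#' Columns: sample, chrom, start, end, n_snvs, copy_number, p_value,
#' log2_mbaf_adj (1-based inclusive coordinates).
#'
#' @param segments Segment data.frame.
#' @param path File path.
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

#' Export segments as BED (0-based half-open)
#'
#' @param segments Segment data.frame (1-based inclusive).
#' @param path File path.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- data.frame(chrom = segments$chrom, start = segments$start - 1L,
                    end = segments$end, name = paste0(segments$sample, ":",
                    segments$call %||% "SEG"))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a genes x samples expression TSV
#'
#' @param matrix Numeric matrix with gene rownames and sample colnames.
#' @param path File path.
#' @export
write_expression <- function(matrix, path) {
  df <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read the clinical covariate CSV
#'
#' @param clinical Clinical data.frame.
#' @param path File path.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_clinical
#' @export
read_clinical <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
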