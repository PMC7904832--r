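#' Write a genotype matrix as VCF 4.2
#'
#' Emits one biallelic SNP record per marker with a GT FORMAT field;
#' missing calls become `./.`.  Optional per-marker INFO allele
#' frequencies are written as `AF=` (or the given field name).
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (`.vcf`).
#' @param info_af optional numeric vector of allele frequencies, one per
#'   marker.
#' @param info_field INFO field name for `info_af`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, info_af = NULL, info_field = "AF") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=rohmap",
    sprintf("##contig=<ID=%s>", unique(gm$markers$chrom)),
    if (!is.null(info_af))
      sprintf(paste0("##INFO=<ID=%s,Number=A,Type=Float,",
                     "Description=\"Allele frequency\">"), info_field),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", gm$sample_ids), collapse = "\t")), con)
  gt_str <- c("0/0", "0/1", "1/1")
  n_mark <- nrow(gm$markers)
  info <- if (is.null(info_af)) rep(".", n_mark) else
    sprintf("%s=%s", info_field, format(info_af, trim = TRUE,
                                        scientific = FALSE))
  gt <- matrix("./.", length(gm$sample_ids), n_mark)
  ok <- !is.na(gm$calls)
  gt[ok] <- gt_str[gm$calls[ok] + 1L]
  if (n_mark > 0) {
    lines <- paste(gm$markers$chrom, gm$markers$pos, gm$markers$id,
                   gm$markers$ref, gm$markers$alt, ".", "PASS", info, "GT",
                   apply(gt, 2, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a genotype matrix as PLINK .bed/.bim/.fam
#'
#' SNP-major binary bed with the standard magic bytes; A1 is the
#' alternate (counted) allele and A2 the reference allele, so reading the
#' files back reproduces the genotype codes exactly.
#'
#' @param gm a [genotype_matrix()].
#' @param prefix output prefix (writes `prefix.bed`, `.bim`, `.fam`).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(gm, prefix) {
  n_mark <- nrow(gm$markers)
  bim <- data.frame(chrom = gm$markers$chrom, id = gm$markers$id,
                    cm = rep(0, n_mark), pos = gm$markers$pos,
                    a1 = gm$markers$alt, a2 = gm$markers$ref)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  n_ind <- length(gm$sample_ids)
  fam <- data.frame(fid = gm$sample_ids, iid = gm$sample_ids,
                    pat = rep(0, n_ind), mat = rep(0, n_ind),
                    sex = rep(0, n_ind), phe = rep(-9, n_ind))
  write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bpm <- ceiling(n_ind / 4)
  # alt-count -> two-bit code: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  two_bit <- c(`2` = 0L, `1` = 2L, `0` = 3L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- bpm * 4L
  for (j in seq_len(ncol(gm$calls))) {
    g <- gm$calls[, j]
    q <- rep(1L, pad)  # padding and missing are 01
    obs <- !is.na(g)
    q[seq_len(n_ind)][obs] <- two_bit[as.character(g[obs])]
    qm <- matrix(q, nrow = 4)
    bytes <- qm[1, ] + qm[2, ] * 4L + qm[3, ] * 16L + qm[4, ] * 64L
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Write a sample table as TSV
#'
#' @param sample_table data.frame with `sample_id`, `phenotype`, etc.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(sample_table, path) {
  write.table(sample_table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write cohort fixtures in standard formats
#'
#' Emits the genotype matrix as VCF and/or PLINK binary plus the sample
#' table as TSV; [read_genotypes()] on either output reproduces the
#' matrix.
#'
#' @param gm a [genotype_matrix()].
#' @param sample_table data.frame (optional; skipped when `NULL`).
#' @param out_dir output directory (created if needed).
#' @param formats subset of `c("vcf", "plink", "tsv")`.
#' @param basename file stem for all outputs.
#' @return named character vector of written paths.
#' @export
write_fixtures <- function(gm, sample_table = NULL, out_dir,
                           formats = c("vcf", "plink", "tsv"),
                           basename = "cohort") {
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- character()
  if ("vcf" %in% formats) {
    p <- file.path(out_dir, paste0(basename, ".vcf"))
    write_vcf(gm, p)
    out["vcf"] <- p
  }
  if ("plink" %in% formats) {
    p <- file.path(out_dir, basename)
    write_plink(gm, p)
    out["plink"] <- p
  }
  if ("tsv" %in% formats && !is.null(sample_table)) {
    p <- file.path(out_dir, paste0(basename, "_samples.tsv"))
    write_sample_table(sample_table, p)
    out["tsv"] <- p
  }
  out
}
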