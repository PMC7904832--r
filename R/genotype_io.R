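#' Construct a genotype matrix
#'
#' The in-memory substrate of ROH calling: a samples x markers matrix of
#' genotype codes (0 = homozygous reference, 1 = heterozygous,
#' 2 = homozygous alternate, `NA` = missing) together with a marker table.
#' Markers are sorted by (chromosome, position); duplicate positions on a
#' chromosome are an error.
#'
#' @param calls integer matrix, samples in rows and markers in columns,
#'   values in \{0, 1, 2, NA\}.
#' @param markers data.frame with columns `chrom`, `pos` (1-based bp),
#'   `id`, `ref`, `alt`.
#' @param sample_ids character vector of unique sample identifiers, one
#'   per row of `calls`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `markers`, `sample_ids`.
#' @export
genotype_matrix <- function(calls, markers, sample_ids) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(is.data.frame(markers),
            all(c("chrom", "pos", "id", "ref", "alt") %in% names(markers)),
            nrow(calls) == length(sample_ids),
            ncol(calls) == nrow(markers))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ", sample_ids[duplicated(sample_ids)][1])
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype codes must be 0/1/2/NA")
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)
  ord <- order(markers$chrom, markers$pos)
  if (any(ord != seq_along(ord))) {
    markers <- markers[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
  }
  dup <- duplicated(markers[c("chrom", "pos")])
  if (any(dup))
    stop("duplicate marker position: ", markers$chrom[dup][1], ":",
         markers$pos[dup][1])
  rownames(markers) <- NULL
  dimnames(calls) <- list(sample_ids, markers$id)
  structure(list(calls = calls, markers = markers,
                 sample_ids = as.character(sample_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      nrow(x$markers), "markers on",
      length(unique(x$markers$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing call fraction: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

# chromosome labels considered non-autosomal and dropped on read
NON_AUTOSOMES <- c("X", "Y", "MT", "M", "chrX", "chrY", "chrM", "chrMT",
                   "23", "24", "25", "26")

#' Read genotypes from VCF or PLINK binary files
#'
#' Reads biallelic autosomal SNPs into a [genotype_matrix()].  VCF records
#' must carry a GT FORMAT field; multi-allelic and non-SNP records, and
#' non-autosomal chromosomes, are skipped with a message.  Half-missing
#' calls (e.g. `0/.`) are treated as missing.
#'
#' @param path path to a `.vcf`/`.vcf.gz` file, or the prefix (or `.bed`
#'   path) of a PLINK `.bed`/`.bim`/`.fam` file set.
#' @param format `"vcf"`, `"plink"`, or `"auto"` (decided from the file
#'   extension).
#' @return A [genotype_matrix()] with hom-ref coded 0 relative to the
#'   file's REF (VCF) or A2 (PLINK) allele.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "plink")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "plink"
  }
  if (format == "vcf") read_vcf_genotypes(path) else read_plink_genotypes(path)
}

read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(get_fix_matrix(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF has no records: ", path)
  if (ncol(v@gt) < 2 ||
      !any(vapply(strsplit(v@gt[, "FORMAT"], ":"),
                  function(f) "GT" %in% f, logical(1))))
    stop("VCF lacks a GT FORMAT field: ", path)
  snp <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !is.na(fix$ALT)
  auto <- !fix$CHROM %in% NON_AUTOSOMES
  n_skip <- sum(!snp)
  n_sex <- sum(snp & !auto)
  if (n_skip > 0)
    message("read_genotypes: skipped ", n_skip, " multi-allelic/non-SNP records")
  if (n_sex > 0)
    message("read_genotypes: dropped ", n_sex, " non-autosomal records")
  keep <- snp & auto
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  calls <- t(gt_string_to_code(gt))
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM[is.na(ids) | ids == "."],
                                         ":", fix$POS[is.na(ids) | ids == "."])
  markers <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                        id = ids, ref = fix$REF, alt = fix$ALT,
                        stringsAsFactors = FALSE)
  genotype_matrix(calls, markers, colnames(gt))
}

# getFIX drops to a bare vector for single-record files
get_fix_matrix <- function(v) {
  x <- vcfR::getFIX(v)
  if (is.null(dim(x))) x <- t(x)
  x
}

# "0/0" -> 0, "0/1"/"1|0" -> 1, "1/1" -> 2, anything with "." -> NA
gt_string_to_code <- function(gt) {
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  ok <- !is.na(gt) & a1 %in% c("0", "1") & a2 %in% c("0", "1")
  code[ok] <- as.integer(a1[ok]) + as.integer(a2[ok])
  code
}

read_plink_genotypes <- function(prefix) {
  prefix <- sub("\\.bed$", "", prefix)
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("cannot read PLINK file: ", f)
  bim_df <- read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                       col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  fam_df <- read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  n_ind <- nrow(fam_df)
  n_snp <- nrow(bim_df)
  raw <- readBin(bed, "raw", n = 3 + ceiling(n_ind / 4) * n_snp)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK bed file: ", bed)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major PLINK bed files are supported: ", bed)
  body <- raw[-(1:3)]
  bpm <- ceiling(n_ind / 4)
  # two-bit codes per individual: 00 hom-A1, 10 het, 11 hom-A2, 01 missing
  codes <- matrix(NA_integer_, n_ind, n_snp)
  lut <- plink_byte_lut()
  for (j in seq_len(n_snp)) {
    bytes <- as.integer(body[((j - 1) * bpm + 1):(j * bpm)])
    codes[, j] <- lut[, bytes + 1L][seq_len(n_ind)]
  }
  auto <- !bim_df$chrom %in% NON_AUTOSOMES
  if (any(!auto)) {
    message("read_genotypes: dropped ", sum(!auto), " non-autosomal records")
    bim_df <- bim_df[auto, , drop = FALSE]
    codes <- codes[, auto, drop = FALSE]
  }
  # A1 is the counted (alt) allele, A2 the reference allele
  markers <- data.frame(chrom = as.character(bim_df$chrom), pos = bim_df$pos,
                        id = bim_df$id, ref = bim_df$a2, alt = bim_df$a1,
                        stringsAsFactors = FALSE)
  genotype_matrix(codes, markers, as.character(fam_df[[2]]))
}

# 4 individuals per byte, little-endian bit pairs; value = alt-allele count
plink_byte_lut <- function() {
  two_bit <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  vapply(0:255, function(b) {
    q <- c(b %% 4, (b %/% 4) %% 4, (b %/% 16) %% 4, (b %/% 64) %% 4)
    unname(two_bit[as.character(q)])
  }, integer(4))
}

#' Per-marker minor allele frequency
#'
#' Computed on non-missing calls; always in \[0, 0.5\].  Markers with no
#' non-missing calls get `NA`.
#'
#' @param gm a [genotype_matrix()].
#' @return numeric vector, one value per marker.
#' @export
marker_maf <- function(gm) {
  alt <- colSums(gm$calls, na.rm = TRUE)
  n <- colSums(!is.na(gm$calls)) * 2L
  p <- ifelse(n > 0, alt / n, NA_real_)
  pmin(p, 1 - p)
}

#' Filter markers on call rate and minor allele frequency
#'
#' Retains markers with call rate strictly above `min_call_rate` and MAF
#' strictly above `min_maf`, both computed on non-missing calls.  The
#' sample set is unchanged.
#'
#' @param gm a [genotype_matrix()].
#' @param min_call_rate minimum fraction of non-missing calls (exclusive).
#' @param min_maf minimum minor allele frequency (exclusive).
#' @return The filtered [genotype_matrix()].
#' @export
filter_markers <- function(gm, min_call_rate = 0.95, min_maf = 0.05) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 0.5)
  call_rate <- colMeans(!is.na(gm$calls))
  maf <- marker_maf(gm)
  keep <- call_rate > min_call_rate & !is.na(maf) & maf > min_maf
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message("filter_markers: removed ", n_drop, " of ", length(keep),
            " markers (call rate <= ", min_call_rate,
            " or MAF <= ", min_maf, ")")
  if (!any(keep)) warning("filter_markers: no markers remain")
  subset_markers(gm, keep)
}

subset_markers <- function(gm, keep) {
  genotype_matrix(gm$calls[, keep, drop = FALSE],
                  gm$markers[keep, , drop = FALSE],
                  gm$sample_ids)
}

#' Mask markers inside exclusion regions
#'
#' Drops markers falling inside any of the given intervals (e.g. common
#' CNV deletions supplied as a BED file), before ROH calling.
#'
#' @param gm a [genotype_matrix()].
#' @param regions data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive), e.g. from [read_bed_intervals()].
#' @return The masked [genotype_matrix()].
#' @export
exclude_markers <- function(gm, regions) {
  if (is.null(regions) || nrow(regions) == 0) return(gm)
  inside <- rep(FALSE, nrow(gm$markers))
  for (chr in unique(regions$chrom)) {
    r <- regions[regions$chrom == chr, , drop = FALSE]
    m <- gm$markers$chrom == chr
    if (!any(m)) next
    ir <- IRanges::IRanges(start = r$start, end = r$end)
    q <- IRanges::IRanges(start = gm$markers$pos[m], width = 1L)
    inside[m] <- IRanges::overlapsAny(q, ir)
  }
  if (any(inside))
    message("exclude_markers: masked ", sum(inside), " markers")
  subset_markers(gm, !inside)
}

#' Read a sample table
#'
#' Tab-separated with a header; requires `sample_id` and `phenotype`
#' (0 = control, 1 = case) columns; `cohort`, `age`, `sex` and principal
#' component columns (`PC1`, `PC2`, ...) are carried through when present.
#'
#' @param path TSV path.
#' @param gm optional [genotype_matrix()]; when given, sample ids must be
#'   a subset of its sample ids.
#' @return data.frame keyed by `sample_id`.
#' @export
read_sample_table <- function(path, gm = NULL) {
  st <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  validate_sample_table(st, gm)
}

validate_sample_table <- function(st, gm = NULL) {
  stopifnot(all(c("sample_id", "phenotype") %in% names(st)))
  st$sample_id <- as.character(st$sample_id)
  if (!all(st$phenotype %in% c(0, 1)))
    stop("phenotype must be 0 (control) or 1 (case)")
  if (anyDuplicated(st$sample_id))
    stop("duplicate sample_id in sample table")
  if (!is.null(gm) && !all(st$sample_id %in% gm$sample_ids))
    stop("sample table contains ids absent from the genotype data: ",
         setdiff(st$sample_id, gm$sample_ids)[1])
  st
}

#' Read genomic intervals from a BED file
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based inclusive convention on read.
#'
#' @param path BED path (first three columns used).
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_bed_intervals <- function(path) {
  if (!file.exists(path)) stop("cannot read BED: ", path)
  bed <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop("BED needs at least 3 columns: ", path)
  out <- data.frame(chrom = as.character(bed[[1]]),
                    start = as.integer(bed[[2]]) + 1L,
                    end = as.integer(bed[[3]]),
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("malformed BED interval in ", path)
  out
}

#' Write genomic intervals as a BED file
#'
#' The inverse of [read_bed_intervals()]: internal 1-based inclusive
#' intervals become 0-based half-open BED records.  Accepts
#' `start`/`end` or `start_bp`/`end_bp` column names, so consensus and
#' prioritized-region tables export directly.
#'
#' @param intervals data.frame with `chrom` and start/end columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  x <- normalize_intervals(intervals)
  write.table(data.frame(x$chrom, x$start - 1L, x$end), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
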