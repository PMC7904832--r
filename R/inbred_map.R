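#' Homozygosity map of inbred cases
#'
#' Restricts the cohort to cases classified inbred by F_ROH, then
#' re-derives consensus ROHs among them under the stringent map filters
#' (by default > 100 kb and > 100 SNPs — inbred tracts are long, so
#' chance sharing must be controlled harder than in the whole cohort).
#'
#' @param profiles data.frame from [summarize_homozygosity()].
#' @param sample_table data.frame with `sample_id`, `phenotype`.
#' @param segments cohort segment data.frame.
#' @param gm the [genotype_matrix()].
#' @param cutoff F_ROH inbreeding cutoff (see [classify_inbred()]).
#' @param match_threshold allelic match threshold for pooling.
#' @param min_length_kb,min_snps consensus emission filters (exclusive).
#' @return consensus data.frame (see [derive_consensus()]) restricted to
#'   inbred cases; empty with a warning when fewer than 2 inbred cases
#'   exist.
#' @export
build_inbred_map <- function(profiles, sample_table, segments, gm,
                             cutoff = 0.0156, match_threshold = 0.95,
                             min_length_kb = 100, min_snps = 100) {
  inbred <- profiles$individual_id[classify_inbred(profiles$froh, cutoff)]
  cases <- sample_table$sample_id[sample_table$phenotype == 1]
  ids <- intersect(inbred, cases)
  if (length(ids) < 2) {
    warning("build_inbred_map: fewer than 2 inbred cases; empty map")
    return(empty_consensus())
  }
  segs <- segments[segments$individual_id %in% ids, , drop = FALSE]
  consensus_roh(segs, gm, sample_table, match_threshold,
                min_length_kb, min_snps)
}

#' Intersect two interval sets
#'
#' All maximal intervals covered by both sets (pairwise intersections,
#' merged when contiguous), in 1-based inclusive coordinates.
#'
#' @param set_a,set_b data.frames with `chrom`, `start`, `end` (1-based
#'   inclusive); `start_bp`/`end_bp` column names are also accepted.
#' @return data.frame with `chrom`, `start`, `end`, sorted.
#' @export
intersect_intervals <- function(set_a, set_b) {
  a <- normalize_intervals(set_a)
  b <- normalize_intervals(set_b)
  out <- list()
  for (chr in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- IRanges::reduce(IRanges::IRanges(
      start = a$start[a$chrom == chr], end = a$end[a$chrom == chr]))
    ib <- IRanges::reduce(IRanges::IRanges(
      start = b$start[b$chrom == chr], end = b$end[b$chrom == chr]))
    ov <- IRanges::intersect(ia, ib)
    if (length(ov))
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = IRanges::start(ov), end = IRanges::end(ov),
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

normalize_intervals <- function(x) {
  if (all(c("start_bp", "end_bp") %in% names(x)))
    x <- data.frame(chrom = x$chrom, start = x$start_bp, end = x$end_bp,
                    stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(x)),
            all(x$start <= x$end))
  x
}

#' Prioritize candidate recessive regions
#'
#' Intersects the inbred-case homozygosity map with whole-cohort
#' consensus regions whose association coefficient exceeds `beta_min`
#' (risk direction), and keeps intersection fragments retaining more than
#' `min_length_kb` and more than `min_snps` markers.
#'
#' @param inbred_consensus consensus data.frame from [build_inbred_map()].
#' @param whole_results per-region association results from
#'   [consensus_assoc()] on the whole cohort.
#' @param gm the [genotype_matrix()] (for marker counts in fragments).
#' @param beta_min minimum whole-cohort beta (exclusive).
#' @param min_length_kb,min_snps emission filters (exclusive).
#' @return data.frame with `chrom`, `start_bp`, `end_bp`, `length_kb`,
#'   `n_snps`, `source_pool_id`, `whole_set_beta`,
#'   `n_inbred_case_members`.
#' @export
prioritize_regions <- function(inbred_consensus, whole_results, gm,
                               beta_min = 0.03, min_length_kb = 100,
                               min_snps = 100) {
  risk <- whole_results[!is.na(whole_results$beta) &
                          whole_results$beta > beta_min &
                          whole_results$converged, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(inbred_consensus))) {
    reg <- inbred_consensus[i, , drop = FALSE]
    hits <- risk[risk$chrom == reg$chrom &
                   risk$start_bp <= reg$end_bp &
                   risk$end_bp >= reg$start_bp, , drop = FALSE]
    for (j in seq_len(nrow(hits))) {
      lo <- max(reg$start_bp, hits$start_bp[j])
      hi <- min(reg$end_bp, hits$end_bp[j])
      length_kb <- (hi - lo + 1) / 1000
      if (length_kb <= min_length_kb) next
      n_snps <- sum(gm$markers$chrom == reg$chrom &
                      gm$markers$pos >= lo & gm$markers$pos <= hi)
      if (n_snps <= min_snps) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = reg$chrom, start_bp = lo, end_bp = hi,
        length_kb = length_kb, n_snps = n_snps,
        source_pool_id = reg$pool_id, whole_set_beta = hits$beta[j],
        n_inbred_case_members = reg$n_members, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), length_kb = numeric(),
                      n_snps = integer(), source_pool_id = integer(),
                      whole_set_beta = numeric(),
                      n_inbred_case_members = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate regions with known loci
#'
#' Generic interval join: flags regions overlapping (within `flank_bp`)
#' any interval of a user-supplied locus set, e.g. previously reported
#' disease loci as a BED file.
#'
#' @param regions data.frame with `chrom`, `start_bp`, `end_bp`.
#' @param loci data.frame with `chrom`, `start`, `end` (1-based), e.g.
#'   from [read_bed_intervals()].
#' @param flank_bp symmetric flank added to each locus.
#' @return `regions` with a logical `near_locus` column.
#' @export
annotate_loci <- function(regions, loci, flank_bp = 0) {
  regions$near_locus <- FALSE
  for (i in seq_len(nrow(regions))) {
    l <- loci[loci$chrom == regions$chrom[i], , drop = FALSE]
    regions$near_locus[i] <- any(l$start - flank_bp <= regions$end_bp[i] &
                                   l$end + flank_bp >= regions$start_bp[i])
  }
  regions
}

#' Filter sequencing variants inside individual ROHs
#'
#' Implements the recessive-candidate filtering strategy: keep per-sample
#' calls that are (i) homozygous for the alternate allele, (ii) rare —
#' population allele frequency at most `maf_max` across every configured
#' frequency INFO field, a variant absent from all fields counting as
#' novel (frequency 0), (iii) inside a called ROH of the same individual,
#' and (iv), when `regions` is given, inside a prioritized region.
#'
#' @param vcf_path VCF with per-sample GT and population-frequency INFO
#'   fields.
#' @param segments segment data.frame (the individuals' called ROHs).
#' @param maf_max maximum population allele frequency (inclusive).
#' @param freq_fields INFO field names holding population frequencies.
#' @param regions optional data.frame with `chrom`, `start_bp`, `end_bp`.
#' @return data.frame with `individual_id`, `chrom`, `pos`, `id`, `ref`,
#'   `alt`, `population_maf`, `roh_start_bp`, `roh_end_bp`, sorted by
#'   (individual, chrom, pos).
#' @export
filter_wes_variants <- function(vcf_path, segments, maf_max = 0.01,
                                freq_fields = c("AF"), regions = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  if (ncol(v@gt) < 2 ||
      !any(vapply(strsplit(v@gt[, "FORMAT"], ":"),
                  function(f) "GT" %in% f, logical(1))))
    stop("VCF lacks a GT FORMAT field: ", vcf_path)
  info_ids <- vcfR::vcf_field_names(v, tag = "INFO")$ID
  unknown <- setdiff(freq_fields, info_ids)
  if (length(unknown))
    stop("unknown frequency field(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(info_ids, collapse = ", "))
  fix <- as.data.frame(get_fix_matrix(v), stringsAsFactors = FALSE)
  fix$POS <- as.integer(fix$POS)
  freq <- matrix(0, nrow(fix), length(freq_fields))
  for (k in seq_along(freq_fields)) {
    f <- suppressWarnings(as.numeric(
      vcfR::extract.info(v, element = freq_fields[k])))
    freq[, k] <- ifelse(is.na(f), 0, f)
  }
  pop_maf <- apply(freq, 1, max)
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- gt_string_to_code(gt)
  out <- list()
  for (ind in intersect(colnames(code), unique(segments$individual_id))) {
    segs <- segments[segments$individual_id == ind, , drop = FALSE]
    hom_alt <- !is.na(code[, ind]) & code[, ind] == GT_HOM_ALT
    rare <- pop_maf <= maf_max
    keep <- which(hom_alt & rare)
    for (i in keep) {
      s <- segs[segs$chrom == fix$CHROM[i] &
                  segs$start_bp <= fix$POS[i] &
                  segs$end_bp >= fix$POS[i], , drop = FALSE]
      if (nrow(s) == 0) next
      if (!is.null(regions)) {
        inreg <- any(regions$chrom == fix$CHROM[i] &
                       regions$start_bp <= fix$POS[i] &
                       regions$end_bp >= fix$POS[i])
        if (!inreg) next
      }
      out[[length(out) + 1L]] <- data.frame(
        individual_id = ind, chrom = fix$CHROM[i], pos = fix$POS[i],
        id = fix$ID[i], ref = fix$REF[i], alt = fix$ALT[i],
        population_maf = pop_maf[i],
        roh_start_bp = s$start_bp[1], roh_end_bp = s$end_bp[1],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(individual_id = character(), chrom = character(),
                      pos = integer(), id = character(), ref = character(),
                      alt = character(), population_maf = numeric(),
                      roh_start_bp = integer(), roh_end_bp = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$individual_id, res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}
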