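#' Allelic match fraction between two overlapping segments
#'
#' Over the markers in the bp overlap of the two segments where both
#' individuals have non-missing calls, the fraction with identical
#' genotype code.  When no comparable marker exists the match is vacuously
#' 1.
#'
#' @param seg_a,seg_b one-row segment data.frames on the same chromosome
#'   with overlapping spans.
#' @param gm the [genotype_matrix()] the segments were called from.
#' @return fraction in \[0, 1\].
#' @export
allelic_match_fraction <- function(seg_a, seg_b, gm) {
  if (seg_a$chrom != seg_b$chrom)
    stop("segments on different chromosomes")
  lo <- max(seg_a$start_bp, seg_b$start_bp)
  hi <- min(seg_a$end_bp, seg_b$end_bp)
  if (lo > hi) stop("segments do not overlap")
  idx <- which(gm$markers$chrom == seg_a$chrom &
                 gm$markers$pos >= lo & gm$markers$pos <= hi)
  a <- gm$calls[seg_a$individual_id, idx]
  b <- gm$calls[seg_b$individual_id, idx]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(1)
  mean(a[ok] == b[ok])
}

#' Pool overlapping segments with allelic matching
#'
#' Deterministic greedy pooling per chromosome: segments are processed in
#' order of decreasing length (ties by start, then individual id); each
#' segment joins the first existing pool whose current consensus interval
#' it overlaps by more than `min_overlap_kb` and whose seed (longest,
#' first-processed) segment it matches at `match_threshold` or better,
#' otherwise it seeds a new pool.  Every segment belongs to exactly one
#' pool.  The overlap floor prevents a degenerate join: a segment
#' brushing a pool by a few markers would otherwise match vacuously and
#' collapse the pool's intersection to nothing.
#'
#' @param segments segment data.frame.
#' @param gm the [genotype_matrix()] the segments were called from.
#' @param match_threshold minimum allelic match fraction against the seed.
#' @param min_overlap_kb minimum overlap with the pool's running
#'   consensus interval for a segment to join (exclusive); defaults to
#'   the consensus emission floor.
#' @return `segments` with an added integer `pool_id` column.
#' @export
pool_segments <- function(segments, gm, match_threshold = 0.95,
                          min_overlap_kb = 100) {
  segments$pool_id <- NA_integer_
  if (nrow(segments) == 0) return(segments)
  next_pool <- 1L
  for (chr in sort(unique(segments$chrom))) {
    rows <- which(segments$chrom == chr)
    s <- segments[rows, , drop = FALSE]
    ord <- order(-s$length_kb, s$start_bp, s$individual_id)
    pools <- list()  # each: list(seed_row, lo, hi, rows)
    for (i in ord) {
      placed <- FALSE
      if (length(pools)) {
        for (p in seq_along(pools)) {
          pl <- pools[[p]]
          ov <- min(pl$hi, s$end_bp[i]) - max(pl$lo, s$start_bp[i]) + 1
          if (ov / 1000 <= min_overlap_kb) next
          seed <- s[pl$seed, , drop = FALSE]
          # seed overlaps the consensus interval, but may not overlap i
          if (s$start_bp[i] > seed$end_bp || s$end_bp[i] < seed$start_bp) next
          if (allelic_match_fraction(s[i, , drop = FALSE], seed, gm) >=
                match_threshold) {
            pools[[p]]$lo <- max(pl$lo, s$start_bp[i])
            pools[[p]]$hi <- min(pl$hi, s$end_bp[i])
            pools[[p]]$rows <- c(pl$rows, i)
            placed <- TRUE
            break
          }
        }
      }
      if (!placed) {
        pools[[length(pools) + 1L]] <-
          list(seed = i, lo = s$start_bp[i], hi = s$end_bp[i], rows = i)
      }
    }
    for (p in seq_along(pools)) {
      segments$pool_id[rows[pools[[p]]$rows]] <- next_pool
      next_pool <- next_pool + 1L
    }
  }
  segments
}

#' Derive consensus ROHs from pooled segments
#'
#' The consensus interval of a pool is the intersection of its member
#' segments; only pools with at least two members whose intersection is
#' longer than `min_length_kb` and contains more than `min_snps` markers
#' are emitted.  Members are annotated by phenotype when a sample table is
#' given.
#'
#' @param pooled segment data.frame with `pool_id`, from [pool_segments()].
#' @param gm the [genotype_matrix()].
#' @param sample_table optional data.frame with `sample_id`, `phenotype`.
#' @param min_length_kb minimum consensus length in kb (exclusive).
#' @param min_snps minimum markers inside the consensus (exclusive).
#' @return data.frame with `pool_id`, `chrom`, `start_bp`, `end_bp`,
#'   `length_kb`, `n_snps`, `n_members`, `n_case_members`,
#'   `n_control_members`, `members` (comma-separated ids).
#' @export
derive_consensus <- function(pooled, gm, sample_table = NULL,
                             min_length_kb = 100, min_snps = 3) {
  out <- list()
  pheno <- NULL
  if (!is.null(sample_table))
    pheno <- setNames(sample_table$phenotype, sample_table$sample_id)
  for (pid in unique(pooled$pool_id)) {
    mem <- pooled[pooled$pool_id == pid, , drop = FALSE]
    if (nrow(mem) < 2) next
    lo <- max(mem$start_bp)
    hi <- min(mem$end_bp)
    if (lo > hi) next
    length_kb <- (hi - lo + 1) / 1000
    if (length_kb <= min_length_kb) next
    n_snps <- sum(gm$markers$chrom == mem$chrom[1] &
                    gm$markers$pos >= lo & gm$markers$pos <= hi)
    if (n_snps <= min_snps) next
    ids <- unique(mem$individual_id)
    n_case <- if (is.null(pheno)) NA_integer_ else
      sum(pheno[ids] == 1, na.rm = TRUE)
    n_ctrl <- if (is.null(pheno)) NA_integer_ else
      sum(pheno[ids] == 0, na.rm = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      pool_id = pid, chrom = mem$chrom[1], start_bp = lo, end_bp = hi,
      length_kb = length_kb, n_snps = n_snps, n_members = length(ids),
      n_case_members = n_case, n_control_members = n_ctrl,
      members = paste(ids, collapse = ","), stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_consensus())
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start_bp), , drop = FALSE]
}

empty_consensus <- function() {
  data.frame(pool_id = integer(), chrom = character(), start_bp = integer(),
             end_bp = integer(), length_kb = numeric(), n_snps = integer(),
             n_members = integer(), n_case_members = integer(),
             n_control_members = integer(), members = character(),
             stringsAsFactors = FALSE)
}

#' Consensus ROHs in one call
#'
#' Convenience wrapper: [pool_segments()] then [derive_consensus()].
#'
#' @inheritParams pool_segments
#' @inheritParams derive_consensus
#' @return see [derive_consensus()].
#' @export
consensus_roh <- function(segments, gm, sample_table = NULL,
                          match_threshold = 0.95, min_length_kb = 100,
                          min_snps = 3) {
  derive_consensus(pool_segments(segments, gm, match_threshold,
                                 min_overlap_kb = min_length_kb),
                   gm, sample_table, min_length_kb, min_snps)
}
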