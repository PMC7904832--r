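#' ROH calling parameters
#'
#' Parameters of the sliding-window observational genotype-counting
#' algorithm.  Defaults: a 50-SNP window no longer than 5000 kb, tolerating
#' 1 heterozygous and 5 missing calls per window; a SNP joins a ROH when
#' more than 5\% of the windows containing it pass; emitted segments need
#' at least 100 SNPs, 1500 kb (1000 kb is the common alternative), no gap
#' between consecutive members above 1000 kb, and a density of at least
#' one SNP per 50 kb.
#'
#' @param window_snps SNPs per sliding window.
#' @param window_kb maximum window span in kb; windows spanning more are
#'   not valid windows.
#' @param window_het_max heterozygous calls tolerated per window.
#' @param window_missing_max missing calls tolerated per window.
#' @param window_hit_threshold minimum fraction (exclusive) of passing
#'   windows containing a SNP for it to be ROH-eligible.
#' @param min_snps minimum member SNPs per emitted segment.
#' @param min_length_kb minimum segment length in kb.
#' @param max_gap_kb maximum distance between consecutive member SNPs.
#' @param min_density_kb_per_snp maximum kb per member SNP.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_snps = 50, window_kb = 5000,
                       window_het_max = 1, window_missing_max = 5,
                       window_hit_threshold = 0.05,
                       min_snps = 100, min_length_kb = 1500,
                       max_gap_kb = 1000, min_density_kb_per_snp = 50) {
  p <- list(window_snps = as.integer(window_snps), window_kb = window_kb,
            window_het_max = as.integer(window_het_max),
            window_missing_max = as.integer(window_missing_max),
            window_hit_threshold = window_hit_threshold,
            min_snps = as.integer(min_snps), min_length_kb = min_length_kb,
            max_gap_kb = max_gap_kb,
            min_density_kb_per_snp = min_density_kb_per_snp)
  stopifnot(all(vapply(p, function(x) is.finite(x) && x > 0, logical(1))),
            p$window_hit_threshold <= 1)
  structure(p, class = "roh_params")
}

#' Fraction of passing windows containing each SNP
#'
#' A window is a run of `window_snps` consecutive markers whose bp span is
#' at most `window_kb`; it passes when it contains at most
#' `window_het_max` heterozygous and `window_missing_max` missing calls.
#' Each SNP's value is the number of passing windows containing it divided
#' by the number of valid windows containing it (0 when no valid window
#' contains it).
#'
#' @param calls integer vector of genotype codes (0/1/2/NA) for one
#'   individual on one chromosome, in position order.
#' @param positions bp positions, sorted ascending.
#' @param params a [roh_params()] object.
#' @return numeric vector in \[0, 1\], one value per SNP.
#' @export
snp_window_pass_fraction <- function(calls, positions, params = roh_params()) {
  n <- length(calls)
  stopifnot(length(positions) == n)
  if (is.unsorted(positions, strictly = FALSE))
    stop("positions must be sorted ascending")
  w <- params$window_snps
  if (n < w) return(rep(0, n))
  n_win <- n - w + 1L
  het <- as.integer(!is.na(calls) & calls == GT_HET)
  mis <- as.integer(is.na(calls))
  # per-window counts via cumulative sums
  cs_het <- c(0L, cumsum(het))
  cs_mis <- c(0L, cumsum(mis))
  i <- seq_len(n_win)
  span_ok <- (positions[i + w - 1L] - positions[i]) <= params$window_kb * 1000
  pass <- span_ok &
    (cs_het[i + w] - cs_het[i]) <= params$window_het_max &
    (cs_mis[i + w] - cs_mis[i]) <= params$window_missing_max
  # SNP j is contained in window starts max(1, j-w+1) .. min(j, n_win)
  cs_valid <- c(0L, cumsum(as.integer(span_ok)))
  cs_pass <- c(0L, cumsum(as.integer(pass)))
  j <- seq_len(n)
  lo <- pmax(1L, j - w + 1L)
  hi <- pmin(j, n_win)
  valid <- ifelse(hi >= lo, cs_valid[hi + 1L] - cs_valid[lo], 0L)
  npass <- ifelse(hi >= lo, cs_pass[hi + 1L] - cs_pass[lo], 0L)
  ifelse(valid > 0, npass / valid, 0)
}

#' Call runs of homozygosity for one individual on one chromosome
#'
#' A SNP is ROH-eligible when its [snp_window_pass_fraction()] exceeds
#' `window_hit_threshold` and its own call is not heterozygous (missing is
#' allowed).  Maximal runs of eligible SNPs are split wherever consecutive
#' members lie more than `max_gap_kb` apart, then filtered on `min_snps`,
#' `min_length_kb` and density.  A heterozygous call always breaks a run.
#'
#' @inheritParams snp_window_pass_fraction
#' @param chromosome chromosome label for the output.
#' @param individual_id individual identifier for the output.
#' @return data.frame of segments with columns `individual_id`, `chrom`,
#'   `start_bp`, `end_bp`, `n_snps`, `length_kb`, `n_het`, `n_missing`,
#'   sorted by `start_bp`.
#' @export
call_roh_individual <- function(calls, positions, chromosome = "1",
                                params = roh_params(),
                                individual_id = "ind") {
  frac <- snp_window_pass_fraction(calls, positions, params)
  eligible <- frac > params$window_hit_threshold &
    (is.na(calls) | calls != GT_HET)
  segs <- empty_segments()
  if (!any(eligible)) return(segs)
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- vector("list", sum(r$values))
  k <- 0L
  for (run in which(r$values)) {
    idx <- starts[run]:ends[run]
    # split at inter-member gaps above max_gap_kb
    gap <- diff(positions[idx]) > params$max_gap_kb * 1000
    piece <- cumsum(c(0L, as.integer(gap)))
    for (pc in split(idx, piece)) {
      n_snps <- length(pc)
      if (n_snps < params$min_snps) next
      start_bp <- positions[pc[1]]
      end_bp <- positions[pc[n_snps]]
      length_kb <- (end_bp - start_bp + 1) / 1000
      if (length_kb < params$min_length_kb) next
      if (length_kb / n_snps > params$min_density_kb_per_snp) next
      k <- k + 1L
      out[[k]] <- data.frame(
        individual_id = individual_id, chrom = chromosome,
        start_bp = start_bp, end_bp = end_bp, n_snps = n_snps,
        length_kb = length_kb, n_het = 0L,
        n_missing = sum(is.na(calls[pc])), stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) return(segs)
  segs <- do.call(rbind, out[seq_len(k)])
  segs[order(segs$start_bp), , drop = FALSE]
}

empty_segments <- function() {
  data.frame(individual_id = character(), chrom = character(),
             start_bp = integer(), end_bp = integer(), n_snps = integer(),
             length_kb = numeric(), n_het = integer(), n_missing = integer(),
             stringsAsFactors = FALSE)
}

#' Call runs of homozygosity across a cohort
#'
#' Applies [call_roh_individual()] to every (individual, chromosome) pair
#' and concatenates the results in (individual, chromosome, start) order.
#' Deterministic: identical inputs give identical outputs.
#'
#' @param gm a [genotype_matrix()].
#' @param params a [roh_params()] object.
#' @return data.frame of segments (see [call_roh_individual()]).
#' @export
call_roh_cohort <- function(gm, params = roh_params()) {
  chroms <- unique(gm$markers$chrom)
  chr_idx <- lapply(chroms, function(ch) which(gm$markers$chrom == ch))
  names(chr_idx) <- chroms
  out <- list()
  for (id in gm$sample_ids) {
    row <- gm$calls[id, ]
    for (ch in chroms) {
      idx <- chr_idx[[ch]]
      segs <- call_roh_individual(row[idx], gm$markers$pos[idx],
                                  chromosome = ch, params = params,
                                  individual_id = id)
      if (nrow(segs)) out[[length(out) + 1L]] <- segs
    }
  }
  if (!length(out)) return(empty_segments())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(match(res$individual_id, gm$sample_ids), res$chrom,
            res$start_bp), , drop = FALSE]
}

#' Write called segments as TSV
#'
#' @param segments segment data.frame from [call_roh_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  write.table(segments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
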