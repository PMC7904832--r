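# Independent brute-force oracles and small fixture builders.
# These deliberately re-derive results with naive loops, not via the
# package's vectorized implementations.

# enumerate every window explicitly
oracle_window_fraction <- function(calls, positions, params = roh_params()) {
  n <- length(calls)
  w <- params$window_snps
  vcount <- integer(n)
  pcount <- integer(n)
  if (n >= w) {
    for (s in 1:(n - w + 1)) {
      e <- s + w - 1
      if (positions[e] - positions[s] > params$window_kb * 1000) next
      win <- calls[s:e]
      n_het <- sum(win == 1, na.rm = TRUE)
      n_mis <- sum(is.na(win))
      vcount[s:e] <- vcount[s:e] + 1L
      if (n_het <= params$window_het_max &&
            n_mis <= params$window_missing_max)
        pcount[s:e] <- pcount[s:e] + 1L
    }
  }
  ifelse(vcount > 0, pcount / vcount, 0)
}

# enumerate candidate runs explicitly
oracle_call_roh <- function(calls, positions, params = roh_params(),
                            chrom = "1", id = "ind") {
  frac <- oracle_window_fraction(calls, positions, params)
  elig <- frac > params$window_hit_threshold &
    (is.na(calls) | calls != 1)
  segs <- list()
  i <- 1
  n <- length(calls)
  while (i <= n) {
    if (!elig[i]) { i <- i + 1; next }
    j <- i
    while (j < n && elig[j + 1] &&
             positions[j + 1] - positions[j] <= params$max_gap_kb * 1000)
      j <- j + 1
    n_snps <- j - i + 1
    length_kb <- (positions[j] - positions[i] + 1) / 1000
    if (n_snps >= params$min_snps && length_kb >= params$min_length_kb &&
          length_kb / n_snps <= params$min_density_kb_per_snp) {
      segs[[length(segs) + 1]] <- data.frame(
        individual_id = id, chrom = chrom, start_bp = positions[i],
        end_bp = positions[j], n_snps = n_snps, length_kb = length_kb,
        stringsAsFactors = FALSE)
    }
    i <- j + 1
  }
  if (!length(segs))
    return(data.frame(individual_id = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), length_kb = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, segs)
}

# per-bp membership scan on small coordinate ranges
oracle_intersect_bp <- function(a, b, max_bp = 5000) {
  out <- list()
  for (chr in union(a$chrom, b$chrom)) {
    ina <- inb <- logical(max_bp)
    aa <- a[a$chrom == chr, , drop = FALSE]
    bb <- b[b$chrom == chr, , drop = FALSE]
    for (i in seq_len(nrow(aa))) ina[aa$start[i]:aa$end[i]] <- TRUE
    for (i in seq_len(nrow(bb))) inb[bb$start[i]:bb$end[i]] <- TRUE
    both <- ina & inb
    if (!any(both)) next
    r <- rle(both)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values))
      out[[length(out) + 1]] <- data.frame(chrom = chr, start = starts[k],
                                           end = ends[k],
                                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# random chromosome: mixture of homozygous stretches, hets and missing
random_chromosome <- function(n, spacing = 10000, het_rate = 0.05,
                              mis_rate = 0.03) {
  calls <- ifelse(runif(n) < 0.5, 0L, 2L)
  calls[runif(n) < het_rate] <- 1L
  calls[runif(n) < mis_rate] <- NA_integer_
  list(calls = calls, positions = cumsum(pmax(1, round(
    runif(n, 0.4 * spacing, 1.6 * spacing)))))
}

# segment row in the caller's output shape
mk_seg <- function(id, chrom, start, end, n_snps = 100) {
  data.frame(individual_id = id, chrom = chrom, start_bp = start,
             end_bp = end, n_snps = n_snps,
             length_kb = (end - start + 1) / 1000, n_het = 0L,
             n_missing = 0L, stringsAsFactors = FALSE)
}

# genotype matrix with given calls on one chromosome at fixed spacing
mk_gm <- function(calls, spacing = 10000, chrom = "1",
                  ids = sprintf("I%d", seq_len(nrow(calls)))) {
  n_mark <- ncol(calls)
  markers <- data.frame(chrom = chrom, pos = seq_len(n_mark) * spacing,
                        id = paste0("m", seq_len(n_mark)), ref = "A",
                        alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(calls, markers, ids)
}

# minimal WES-style VCF writer for hand-built records
write_toy_vcf <- function(path, samples, records) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  for (r in records) writeLines(paste(r, collapse = "\t"), con)
  invisible(path)
}
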