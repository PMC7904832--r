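#' Synthetic cohort configuration
#'
#' Defines the generative model for a case-control genotype cohort with
#' implanted autozygous tracts.  Defaults emulate the structure of a
#' multi-cohort outbred GWAS sample at desk scale: markers at fixed
#' spacing across the 22 autosomes, Hardy-Weinberg baseline genotypes
#' with uniform allele frequencies, about 15 autozygous tracts per
#' individual with mean length near 2.1 Mb (placing NROH, AVROH, SROH and
#' F_ROH near values typical of outbred Europeans), light genotyping
#' error and missingness, and a logistic disease model with an optional
#' F_ROH effect.
#'
#' @param n_cases,n_controls expected case and control counts (phenotype
#'   is drawn from the calibrated logistic model, so realized counts vary
#'   around these).
#' @param n_cohorts number of cohort strata.
#' @param chromosomes named numeric vector of chromosome lengths in bp.
#' @param marker_spacing_bp fixed inter-marker spacing in bp.
#' @param maf_range uniform allele-frequency range for markers.
#' @param tract_rate expected autozygous tracts per individual (Poisson).
#' @param tract_length_kb function(n) drawing n tract lengths in kb;
#'   default log-normal with median 2100 kb, sdlog 0.3.
#' @param genotyping_error_rate per-call probability of conversion to a
#'   heterozygous call.
#' @param missing_rate per-call missingness probability.
#' @param beta_froh true log-odds effect of the inverse-normal-transformed
#'   implanted autozygous fraction on disease.
#' @param cohort_offsets per-cohort log-odds offsets (recycled/trimmed to
#'   `n_cohorts`).
#' @param shared_tracts optional data.frame (`chrom`, `start`, `end`,
#'   `n_cases`, `n_controls`) of autozygous tracts carried as one common
#'   haplotype by the stated numbers of cases and controls — the
#'   substrate of consensus-ROH sharing, which independently drawn
#'   tracts cannot produce (their allelic match is far below the 95\%
#'   pooling threshold).  Carriers are drawn after the phenotype, so the
#'   case/control split directly controls region-level enrichment.
#' @param seed integer seed; mandatory for reproducibility.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 250, n_controls = 250, n_cohorts = 2,
                       chromosomes = grch37_autosomes() * 1e6,
                       marker_spacing_bp = 50000,
                       maf_range = c(0.05, 0.5),
                       tract_rate = 15,
                       tract_length_kb = function(n)
                         rlnorm(n, meanlog = log(2100), sdlog = 0.3),
                       genotyping_error_rate = 0.001,
                       missing_rate = 0.01,
                       beta_froh = 0,
                       cohort_offsets = NULL,
                       shared_tracts = NULL,
                       seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  stopifnot(n_cases >= 1, n_controls >= 1, n_cohorts >= 1,
            all(chromosomes > 0), marker_spacing_bp > 0,
            maf_range[1] >= 0, maf_range[2] <= 0.5,
            tract_rate >= 0,
            genotyping_error_rate >= 0, genotyping_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (is.null(names(chromosomes)))
    names(chromosomes) <- as.character(seq_along(chromosomes))
  if (is.null(cohort_offsets))
    cohort_offsets <- if (n_cohorts == 1) 0 else
      seq(-0.2, 0.2, length.out = n_cohorts)
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 n_cohorts = n_cohorts, chromosomes = chromosomes,
                 marker_spacing_bp = marker_spacing_bp,
                 maf_range = maf_range, tract_rate = tract_rate,
                 tract_length_kb = tract_length_kb,
                 genotyping_error_rate = genotyping_error_rate,
                 missing_rate = missing_rate, beta_froh = beta_froh,
                 cohort_offsets = rep_len(cohort_offsets, n_cohorts),
                 shared_tracts = shared_tracts,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a case-control genotype cohort with autozygous tracts
#'
#' Markers are laid at fixed spacing with allele frequencies drawn once
#' per marker; baseline genotypes follow Hardy-Weinberg.  Per individual,
#' a Poisson number of autozygous tracts is implanted by redrawing every
#' covered marker as a homozygote with allele probability equal to the
#' marker's frequency; calls are then perturbed by genotyping error
#' (random conversion to heterozygous) and missingness.  Phenotype is
#' drawn from a logistic model whose intercept is calibrated so the mean
#' case probability equals the target case fraction, with per-cohort
#' offsets and `beta_froh` acting on the inverse-normal-transformed true
#' implanted fraction.  All randomness flows from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `gm` (a [genotype_matrix()]), `sample_table`
#'   (sample_id, phenotype, cohort, age, sex, PC1-PC4), and `truth`
#'   (implanted tracts, per-individual implanted fraction, generative
#'   parameters).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_ind <- config$n_cases + config$n_controls
  case_frac <- config$n_cases / n_ind
  ids <- sprintf("S%04d", seq_len(n_ind))

  chroms <- config$chromosomes
  pos_list <- lapply(chroms, function(len)
    seq(config$marker_spacing_bp, len, by = config$marker_spacing_bp))
  n_per_chr <- lengths(pos_list)
  markers <- data.frame(
    chrom = rep(names(chroms), n_per_chr),
    pos = as.integer(unlist(pos_list, use.names = FALSE)),
    stringsAsFactors = FALSE)
  markers$id <- paste0("m", seq_len(nrow(markers)))
  markers$ref <- "A"
  markers$alt <- "G"
  n_mark <- nrow(markers)
  maf <- runif(n_mark, config$maf_range[1], config$maf_range[2])

  calls <- matrix(rbinom(n_ind * n_mark, 2L, rep(maf, each = n_ind)),
                  nrow = n_ind)

  # implant autozygous tracts; overlapping tracts merge in the truth
  chr_offset <- c(0L, cumsum(n_per_chr))[seq_along(chroms)]
  names(chr_offset) <- names(chroms)
  n_tracts <- rpois(n_ind, config$tract_rate)
  tract_list <- vector("list", n_ind)
  for (i in seq_len(n_ind)) {
    k <- n_tracts[i]
    if (k == 0) next
    chr_i <- sample(seq_along(chroms), k, replace = TRUE,
                    prob = as.numeric(chroms))
    len_bp <- pmax(1, round(config$tract_length_kb(k) * 1000))
    start <- pmax(1, floor(runif(k) * (chroms[chr_i] - len_bp)) + 1)
    end <- pmin(start + len_bp - 1, chroms[chr_i])
    tr <- merge_tracts(data.frame(chrom = names(chroms)[chr_i],
                                  start = start, end = end,
                                  stringsAsFactors = FALSE))
    for (t in seq_len(nrow(tr))) {
      p0 <- pos_list[[tr$chrom[t]]]
      j <- which(p0 >= tr$start[t] & p0 <= tr$end[t]) +
        chr_offset[tr$chrom[t]]
      if (length(j))
        calls[i, j] <- 2L * rbinom(length(j), 1L, maf[j])
    }
    tr$individual_id <- ids[i]
    tract_list[[i]] <- tr
  }
  tracts <- do.call(rbind, c(tract_list,
                             list(data.frame(chrom = character(),
                                             start = numeric(),
                                             end = numeric(),
                                             individual_id = character(),
                                             stringsAsFactors = FALSE))))
  genome_bp <- sum(as.numeric(chroms))
  frac <- vapply(tract_list, function(tr)
    if (is.null(tr)) 0 else sum(tr$end - tr$start + 1) / genome_bp,
    numeric(1))

  cohort <- paste0("cohort", sample.int(config$n_cohorts, n_ind,
                                        replace = TRUE))
  x <- if (length(unique(frac)) > 1) rank_inverse_normal(frac)
       else rep(0, n_ind)
  lin <- config$cohort_offsets[as.integer(sub("cohort", "", cohort))] +
    config$beta_froh * x
  if (case_frac <= 0 || case_frac >= 1)
    stop("infeasible case fraction: ", case_frac)
  intercept <- uniroot(function(b) mean(plogis(b + lin)) - case_frac,
                       c(-20, 20))$root
  phenotype <- rbinom(n_ind, 1L, plogis(intercept + lin))

  # shared tracts: one haplotype copied into the chosen carriers, with
  # the case/control split drawn from the realized phenotype
  shared <- NULL
  if (!is.null(config$shared_tracts)) {
    sh <- config$shared_tracts
    shared <- vector("list", nrow(sh))
    for (t in seq_len(nrow(sh))) {
      p0 <- pos_list[[sh$chrom[t]]]
      j <- which(p0 >= sh$start[t] & p0 <= sh$end[t]) +
        chr_offset[sh$chrom[t]]
      hap <- 2L * rbinom(length(j), 1L, maf[j])
      case_pool <- which(phenotype == 1)
      ctrl_pool <- which(phenotype == 0)
      carriers <- c(
        case_pool[sample.int(length(case_pool),
                             min(sh$n_cases[t], length(case_pool)))],
        ctrl_pool[sample.int(length(ctrl_pool),
                             min(sh$n_controls[t], length(ctrl_pool)))])
      for (i in carriers) calls[i, j] <- hap
      shared[[t]] <- data.frame(chrom = sh$chrom[t], start = sh$start[t],
                                end = sh$end[t],
                                carriers = paste(ids[sort(carriers)],
                                                 collapse = ","),
                                stringsAsFactors = FALSE)
    }
    shared <- do.call(rbind, shared)
  }

  if (config$genotyping_error_rate > 0) {
    err <- runif(length(calls)) < config$genotyping_error_rate
    calls[err] <- GT_HET
  }
  if (config$missing_rate > 0)
    calls[runif(length(calls)) < config$missing_rate] <- NA_integer_

  sample_table <- data.frame(
    sample_id = ids, phenotype = phenotype, cohort = cohort,
    age = round(rnorm(n_ind, mean = 75, sd = 8)),
    sex = sample(c(1L, 2L), n_ind, replace = TRUE),
    PC1 = rnorm(n_ind), PC2 = rnorm(n_ind),
    PC3 = rnorm(n_ind), PC4 = rnorm(n_ind),
    stringsAsFactors = FALSE)

  list(gm = genotype_matrix(calls, markers, ids),
       sample_table = sample_table,
       truth = list(tracts = tracts, shared_tracts = shared,
                    implanted_fraction = setNames(frac, ids),
                    intercept = intercept, config = config,
                    genome_kb = genome_bp / 1000, maf = maf))
}

# merge overlapping/contiguous tracts per chromosome
merge_tracts <- function(tr) {
  out <- list()
  for (chr in unique(tr$chrom)) {
    t0 <- tr[tr$chrom == chr, , drop = FALSE]
    t0 <- t0[order(t0$start), , drop = FALSE]
    s <- t0$start[1]; e <- t0$end[1]
    for (i in seq_len(nrow(t0))[-1]) {
      if (t0$start[i] <= e + 1) {
        e <- max(e, t0$end[i])
      } else {
        out[[length(out) + 1L]] <- data.frame(chrom = chr, start = s,
                                              end = e)
        s <- t0$start[i]; e <- t0$end[i]
      }
    }
    out[[length(out) + 1L]] <- data.frame(chrom = chr, start = s, end = e)
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}
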