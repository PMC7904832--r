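#' Per-individual homozygosity parameters
#'
#' Summarizes one individual's ROH segments into NROH (count), SROH (total
#' length, kb), AVROH (mean length, kb; 0 when NROH = 0) and the genomic
#' inbreeding coefficient F_ROH = SROH / autosomal genome length.
#'
#' @param segments segment data.frame for a single individual.
#' @param autosomal_kb autosomal genome length in kb; the default is the
#'   GRCh37.p13 value 3,020,190.
#' @return one-row data.frame with `individual_id`, `nroh`, `sroh_kb`,
#'   `avroh_kb`, `froh`.
#' @export
summarize_individual <- function(segments, autosomal_kb = AUTOSOMAL_GENOME_KB) {
  stopifnot(autosomal_kb > 0)
  if (nrow(segments) == 0) {
    return(data.frame(individual_id = NA_character_, nroh = 0L, sroh_kb = 0,
                      avroh_kb = 0, froh = 0, stringsAsFactors = FALSE))
  }
  ids <- unique(segments$individual_id)
  if (length(ids) > 1)
    stop("segments belong to more than one individual: ",
         paste(ids[1:2], collapse = ", "))
  nroh <- nrow(segments)
  sroh <- sum(segments$length_kb)
  data.frame(individual_id = ids, nroh = nroh, sroh_kb = sroh,
             avroh_kb = sroh / nroh, froh = sroh / autosomal_kb,
             stringsAsFactors = FALSE)
}

#' Homozygosity parameters for every individual in a cohort
#'
#' Individuals without any called segment get NROH = SROH = AVROH =
#' F_ROH = 0 so they still enter burden models.
#'
#' @param segments segment data.frame from [call_roh_cohort()].
#' @param sample_ids all individuals to report (including ROH-free ones);
#'   defaults to those present in `segments`.
#' @inheritParams summarize_individual
#' @return data.frame with one row per individual.
#' @export
summarize_homozygosity <- function(segments, sample_ids = NULL,
                                   autosomal_kb = AUTOSOMAL_GENOME_KB) {
  if (is.null(sample_ids)) sample_ids <- unique(segments$individual_id)
  nroh <- table(factor(segments$individual_id, levels = sample_ids))
  sroh <- vapply(split(segments$length_kb,
                       factor(segments$individual_id, levels = sample_ids)),
                 sum, numeric(1))
  nroh <- as.integer(nroh)
  data.frame(individual_id = sample_ids, nroh = nroh, sroh_kb = sroh,
             avroh_kb = ifelse(nroh > 0, sroh / nroh, 0),
             froh = sroh / autosomal_kb,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank-based inverse normal transformation
#'
#' Maps the value with rank r (average ranks for ties) to
#' `qnorm((r - offset) / (n - 2 * offset + 1))`; the default Blom offset
#' is 3/8.  Monotone in the input and order-preserving.
#'
#' @param values numeric vector with at least two distinct finite values.
#' @param offset rank offset; 3/8 gives Blom scores.
#' @return transformed numeric vector, same length and order as `values`.
#' @export
rank_inverse_normal <- function(values, offset = 3 / 8) {
  stopifnot(is.numeric(values), sum(is.finite(values)) >= 2)
  if (length(unique(values[is.finite(values)])) < 2)
    stop("rank_inverse_normal: all values tied")
  n <- sum(!is.na(values))
  r <- rank(values, na.last = "keep", ties.method = "average")
  qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Classify inbred individuals by F_ROH
#'
#' Individuals with F_ROH at or above the cutoff are flagged inbred.  The
#' default cutoff 0.0156 corresponds to the expected inbreeding of
#' second-cousin offspring (second-degree consanguinity); 0.0625
#' corresponds to first-cousin offspring.
#'
#' @param froh numeric vector of inbreeding coefficients (or a profile
#'   data.frame with a `froh` column).
#' @param cutoff classification threshold.
#' @param strict use a strict `>` comparison instead of the default `>=`.
#' @return logical vector.
#' @export
classify_inbred <- function(froh, cutoff = 0.0156, strict = FALSE) {
  if (is.data.frame(froh)) froh <- froh$froh
  if (strict) froh > cutoff else froh >= cutoff
}
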