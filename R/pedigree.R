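#' GRCh37 autosome lengths
#'
#' @return named numeric vector of the 22 autosome lengths in Mb.
#' @export
grch37_autosomes <- function() {
  c(chr1 = 249.25, chr2 = 243.20, chr3 = 198.02, chr4 = 191.15,
    chr5 = 180.92, chr6 = 171.12, chr7 = 159.14, chr8 = 146.36,
    chr9 = 141.21, chr10 = 135.53, chr11 = 135.01, chr12 = 133.85,
    chr13 = 115.17, chr14 = 107.35, chr15 = 102.53, chr16 = 90.35,
    chr17 = 81.20, chr18 = 78.08, chr19 = 59.13, chr20 = 63.03,
    chr21 = 48.13, chr22 = 51.30)
}

#' Canonical consanguineous pedigrees
#'
#' Builds the pedigree adjacency for a mating between full sibs
#' (offspring expected F = 1/4), first cousins (1/16 = 0.0625) or second
#' cousins (1/64 = 0.015625); the focal offspring is the last row.
#' A custom pedigree may be given as a data.frame with columns `id`,
#' `father`, `mother` (`NA` parents for founders, parents listed before
#' children, the focal individual last).
#'
#' @param relationship `"full-sib"`, `"first-cousin"` or
#'   `"second-cousin"`.
#' @return data.frame with `id`, `father`, `mother`.
#' @export
pedigree_spec <- function(relationship = c("first-cousin", "second-cousin",
                                           "full-sib")) {
  relationship <- match.arg(relationship)
  ped <- function(id, father, mother)
    data.frame(id = id, father = father, mother = mother,
               stringsAsFactors = FALSE)
  switch(relationship,
    "full-sib" = ped(
      c("F1", "F2", "C1", "C2", "O"),
      c(NA, NA, "F1", "F1", "C1"),
      c(NA, NA, "F2", "F2", "C2")),
    "first-cousin" = ped(
      c("G1", "G2", "S1", "S2", "P1", "P2", "A", "B", "O"),
      c(NA, NA, NA, NA, "G1", "G1", "P1", "P2", "A"),
      c(NA, NA, NA, NA, "G2", "G2", "S1", "S2", "B")),
    "second-cousin" = ped(
      c("GG1", "GG2", "S1", "S2", "S3", "S4", "Q1", "Q2",
        "R1", "R2", "T1", "T2", "O"),
      c(NA, NA, NA, NA, NA, NA, "GG1", "GG1", "Q1", "Q2", "R1", "R2", "T1"),
      c(NA, NA, NA, NA, NA, NA, "GG2", "GG2", "S1", "S2", "S3", "S4", "T2")))
}

validate_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped),
            all(c("id", "father", "mother") %in% names(ped)),
            !anyDuplicated(ped$id))
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  founder <- is.na(ped$father) & is.na(ped$mother)
  if (any(!founder & (is.na(fa) | is.na(mo))))
    stop("non-founders need both parents present in the pedigree")
  # parents must precede children (acyclic, topologically ordered)
  bad <- which(!founder & (fa >= seq_len(nrow(ped)) |
                             mo >= seq_len(nrow(ped))))
  if (length(bad))
    stop("parents must be listed before their children: ", ped$id[bad[1]])
  list(father = ifelse(is.na(fa), 0L, fa),
       mother = ifelse(is.na(mo), 0L, mo))
}

#' Realized inbreeding coefficients by pedigree gene dropping
#'
#' Drops uniquely labeled founder chromosomes through the pedigree with
#' Haldane-model recombination (Poisson crossover count at the
#' chromosome's genetic map length, uniform positions, no interference)
#' and returns, per replicate, the fraction of the focal offspring's
#' genome where both homologs descend from the same founder chromosome
#' copy — the realized inbreeding coefficient F.
#'
#' @param relationship canonical pedigree name, see [pedigree_spec()];
#'   ignored when `pedigree` is given.
#' @param n_replicates number of independent replicates.
#' @param seed optional integer seed (`set.seed()` applied when given).
#' @param pedigree optional custom pedigree data.frame.
#' @param chrom_lengths_mb physical chromosome lengths in Mb.
#' @param morgans_per_mb genetic map scale; the default 0.01 is the
#'   standard coarse 1 cM/Mb approximation.
#' @return numeric vector of realized F, length `n_replicates`.
#' @examples
#' f <- simulate_pedigree_f("first-cousin", 200, seed = 1)
#' mean(f)  # close to 1/16
#' @export
simulate_pedigree_f <- function(relationship = "first-cousin",
                                n_replicates = 1000, seed = NULL,
                                pedigree = NULL,
                                chrom_lengths_mb = grch37_autosomes(),
                                morgans_per_mb = 0.01) {
  stopifnot(n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  ped <- if (is.null(pedigree)) pedigree_spec(relationship) else pedigree
  idx <- validate_pedigree(ped)
  gene_drop_f_cpp(idx$father, idx$mother,
                  chrom_lengths_mb * morgans_per_mb,
                  as.integer(n_replicates))
}
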