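---
title: "Homozygosity mapping with rohmap: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homozygosity mapping with rohmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohmap)
```

## The problem

Runs of homozygosity (ROH) — long contiguous stretches of homozygous
genotype calls — are the genomic footprint of autozygosity: both homologs
inherited identical-by-descent from a common ancestor. In a case-control
cohort, an excess of homozygosity among cases points to recessive risk
loci, and the specific genomic regions that are homozygous in (ideally
inbred) cases are the natural search space for recessive variants.
`rohmap` implements that whole chain: ROH calling, per-individual
inbreeding statistics, consensus regions shared across individuals,
burden and per-region association, classification of inbred individuals,
a homozygosity map of inbred cases, and the filtering of sequencing
variants down to rare homozygous candidates inside ROHs.

Because individual-level GWAS genotypes are almost never redistributable,
the package also ships the other half of a validation story: a pedigree
gene-dropping simulator that realizes inbreeding coefficients with known
expectations, and a synthetic-cohort generator with implanted autozygous
tracts, so every stage can be exercised and checked against ground truth
without any external data.

## ROH calling

`call_roh_cohort()` implements the sliding-window observational
genotype-counting algorithm. The window is 50 SNPs and at most 5000 kb
(`window_snps`, `window_kb`); a window tolerates 1 heterozygous and 5
missing calls (`window_het_max`, `window_missing_max`). A SNP becomes
ROH-eligible when strictly more than 5% of the valid windows containing
it pass (`window_hit_threshold`) *and* its own call is not heterozygous.
Maximal runs of eligible SNPs are split at inter-marker gaps above
1000 kb, then filtered: at least 100 member SNPs, at least 1500 kb
(1000 kb is the conventional alternative; short ROHs mostly reflect
ancient LD rather than recent parental relatedness), and at least one
SNP per 50 kb.

Three boundary conventions are deliberate and covered by a brute-force
oracle in the tests:

* only windows fully contained in the marker range are counted, so
  chromosome-end SNPs sit in fewer windows;
* a 50-SNP window whose bp span exceeds `window_kb` is not a valid
  window at all;
* a heterozygous call is never itself a run member — an interior het
  always breaks a run, and each flank must independently satisfy the
  segment filters. This is stricter than some callers, which may bridge
  a tolerated het; it is the simplest contract consistent with runs
  being *homozygous*, and the window tolerance still absorbs hets in
  the neighbourhood of a run.

Missing calls can be members when their windows pass, which is what the
five-missing-calls tolerance is for.

One practical consequence of the window rule: the first markers of a
true autozygous tract are contained in mostly tract-external windows, so
eligibility starts roughly `ceiling(0.05 * window_snps)` markers inside
the tract. Boundary accuracy is therefore a few marker spacings, not
one; the recovery tests encode exactly that.

## Homozygosity parameters

For each individual, `summarize_homozygosity()` reports NROH (segment
count), SROH (total length, kb), AVROH (= SROH/NROH) and the genomic
inbreeding coefficient

F_ROH = SROH(kb) / autosomal genome length (kb),

with 3,020,190 kb (GRCh37.p13 autosomes) as the default denominator,
configurable for other builds or for simulated genomes. Individuals
without any called segment get AVROH = 0 by convention so that no one
drops out of burden models; at 1.5 Mb calling such individuals are rare
and the alternative (dropping them) would condition the model on the
outcome of calling.

Burden parameters are heavily right-skewed, so association uses the
rank-based inverse normal transformation (`rank_inverse_normal()`,
Blom offset 3/8, average ranks for ties). The transform is monotone and
order-preserving; its sample mean is 0 by antisymmetry and its variance
approaches 1.

`classify_inbred()` flags individuals with F_ROH at or above 0.0156, the
expected inbreeding of second-cousin offspring; 0.0625 corresponds to
first-cousin offspring. The comparison is inclusive (`>=`) — the
boundary value itself denotes second-degree consanguinity — with a
`strict` argument for the exclusive reading.

## Consensus ROHs

A consensus ROH is a region shared by overlapping individual ROHs from
different people whose genotypes agree. Two segments "match" when at
least 95% of the non-missing markers in their overlap carry identical
genotype codes (`allelic_match_fraction()`; an overlap with no
comparable marker matches vacuously).

The grouping algorithm is a deliberate design choice, since overlap
pooling can be defined many ways: `pool_segments()` processes segments
per chromosome in decreasing length (ties by start, then individual id);
a segment joins the first pool whose running consensus interval it
overlaps by more than the consensus length floor (100 kb by default) and
whose *seed* (the pool's longest, first segment) it matches at
threshold, otherwise it seeds a new pool. The overlap floor matters: a
segment brushing a pool by a handful of markers matches the seed almost
vacuously, and letting it join would collapse the pool's intersection —
and hence the consensus region — to nearly nothing. Seed-matching rather than
all-pairs matching keeps the cost linear in pool count, makes the
partition deterministic and independent of input order, and anchors each
pool to its longest — best-supported — haplotype. An all-pairs rule
would be quadratic and can make pool membership depend on insertion
order. Tools that group ROHs differently will produce different pool
boundaries; the emitted consensus intervals are what downstream stages
consume, and those are defined identically: the *intersection* of the
member segments (a consensus region must be homozygous in every member),
kept when it has at least two members, more than 100 kb and more than
3 SNPs.

## Association

`fit_logistic_assoc()` is a maximum-likelihood binomial GLM with logit
link; cohort (and sex) enter as factors. Three covariate sets are
provided: model 1 = cohort + PC1–PC4, model 2 adds age, model 3 adds age
and sex. Inference is Wald (estimate ± 1.96·SE, normal p) — the routine
reporting convention for binomial GLMs, indistinguishable from
likelihood-ratio intervals at the sample sizes where these models are
fit. Per-region predictors are carrier indicators: an individual
carries a consensus region when one of its called segments covers the
region entirely (members cover their pool's intersection by
construction); `coverage = "any"` switches to any-overlap. Separated or
non-converged fits — unavoidable for regions with a handful of
carriers — are flagged and reported with p = 1 rather than failing, and
are excluded from direction tabulations.

The direction-of-effect analysis asks whether risk-direction regions
(β > 0) outnumber protective ones beyond chance:
`direction_binomial_test()` is the exact two-sided binomial test against
0.5 (minimum-likelihood-sum definition, which at p₀ = 0.5 equals
doubling the smaller tail). `tabulate_direction_categories()` repeats
the test on nested filters: A (> 100 kb, > 3 SNPs), B (> 25 SNPs),
C (> 50 SNPs), D (> 3 SNPs and per-region p < 0.05). The reported
proportion of risk regions is unrounded; formatting is the caller's
business.

The inbreeding 2×2 analysis (`two_by_two_association()`) reports the
cross-product odds ratio with a Wald CI and the 1-df Pearson chi-square
*without* continuity correction; a zero cell triggers the conventional
0.5 adjustment and a flag. `bonferroni_threshold()` is α/m.

## The homozygosity map of inbred cases and WES filtering

Inbred individuals carry long autozygous tracts, so chance sharing among
them is much likelier than in the outbred cohort; the inbred-case map
therefore uses stringent consensus filters (> 100 kb *and* > 100 SNPs).
`build_inbred_map()` re-derives consensus regions among inbred cases
only; `prioritize_regions()` intersects them with whole-cohort consensus
regions whose association coefficient exceeds 0.03 (a weak-but-risk
bound applied, by default, to the model-1 coefficient — the model whose
covariates are always available; the choice of model is an argument) and
keeps fragments that retain the length and SNP floors. Interval
arithmetic is 1-based inclusive everywhere; BED inputs are converted on
read, once, so no other module ever reasons about coordinate systems.

`filter_wes_variants()` applies the recessive-candidate strategy to a
sequencing VCF: keep homozygous-alternate calls, with population allele
frequency at most 0.01 across every configured INFO field (a variant
absent from all fields counts as novel, frequency 0 — an unobserved
allele is exactly what a recessive candidate looks like), lying inside a
called ROH of the same individual, and optionally inside a prioritized
region.

## The simulators

`simulate_pedigree_f()` is a gene-dropping simulator: founders carry
uniquely labeled chromosome copies; each meiosis draws a Poisson number
of crossovers at the chromosome's genetic length with uniform positions
(Haldane model, no interference) and a random starting phase; the focal
offspring's realized F is the fraction of the genome where its two
homologs carry the same founder label. The map is 1 cM/Mb over the 22
GRCh37 autosomes by default — the standard coarse approximation, and
configurable. Full-sib, first-cousin and second-cousin pedigrees are
built in (expectations 1/4, 1/16, 1/64); arbitrary pedigrees are
accepted as adjacency tables. The inner loop is C++ via Rcpp and uses
R's RNG, so `set.seed()` governs it; 10,000 replicates of the
second-cousin pedigree run in a few seconds.

`simulate_cohort()` generates the test substrate for everything else:
markers at fixed spacing, allele frequencies uniform on (0.05, 0.5),
Hardy–Weinberg baseline genotypes, and per individual a Poisson number
of implanted autozygous tracts whose covered markers are redrawn as
homozygotes by allele frequency. Defaults place the per-individual
summaries in the range typical of outbred European cohorts: about 15
tracts per individual with log-normal lengths of median 2.1 Mb (so
NROH ≈ 15, AVROH ≈ 2.1 Mb, SROH ≈ 32 Mb, F_ROH ≈ 0.01 against the
GRCh37 genome), marker spacing 50 kb across the 22 autosomes, 0.1%
genotyping error (random het conversion) and 1% missingness. Phenotype
comes from a logistic model whose intercept is calibrated by root
finding to the target case fraction, with per-cohort offsets and an
optional effect `beta_froh` on the inverse-normal-transformed true
implanted fraction. The truth object records every (merged) tract and
all generative parameters, and a single seed drives everything.

Two things the generator deliberately does *not* emulate:

* **Linkage disequilibrium.** Baseline genotypes are independent across
  markers. The 1.5 Mb calling threshold exists in real data precisely to
  suppress LD-driven short ROHs; an LD-free null makes false-positive
  behavior analyzable but means the simulator cannot measure how well
  that threshold separates LD stretches from autozygosity. Passing tests
  say the machinery is correct, not that 1.5 Mb is optimal for a given
  array.
* **Population haplotype sharing by descent.** Independently drawn
  autozygous tracts in two individuals match allelically at roughly
  Σp²+q² ≈ 60–65%, far below the 95% pooling threshold — so without
  further structure the simulator would produce almost no consensus
  regions, which is itself the correct null behavior. Shared regions
  are therefore injected explicitly (`shared_tracts`): one common
  haplotype copied into a chosen number of case and control carriers,
  drawn after the phenotype so the case/control split directly controls
  region-level enrichment. This is a modeling shortcut: real consensus
  ROHs arise from population haplotype frequencies, not from an oracle
  assigning carriers. It buys exact ground truth for the consensus,
  per-region association and prioritization stages.

Realized case/control counts vary around the configured targets because
phenotype is drawn from the calibrated model rather than imposed;
fixing the margins would break the logistic generative story that the
burden models assume.

## Problem sizes used in the tests

The validation suite runs at desk scale, chosen so the full suite
completes in a couple of minutes while every check retains power:
caller-vs-oracle equivalence on 200 random chromosomes of up to 500
markers; F_ROH recovery (r > 0.95 against implanted fractions) on 200
individuals × 90 Mb at 10 kb spacing with no error; effect recovery of
β = 0.3 on a 5000-individual cohort; type-I calibration of the burden
model on 2000 statistic-level null replicates of n = 500; and 10,000
gene-drop replicates per pedigree, accepted within three Monte-Carlo
standard errors of the pedigree expectations.

## Known limitations

* The caller is the observational genotype-counting algorithm only; no
  likelihood/HMM caller, and no LD pruning before calling.
* Pool assignments are contract-defined (greedy by length, seed-matched)
  and will differ from other tools' groupings even when the emitted
  consensus intervals agree closely.
* Population structure is handled by cohort indicators and user-supplied
  principal components; the package does not compute PCs, relatedness,
  or imputation.
* The WES stage filters variants; it does not annotate functional
  impact or run gene-based collapsing tests.
* Wald inference degrades for per-region fits with very few carriers;
  such fits are flagged rather than rescued (no Firth correction).
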