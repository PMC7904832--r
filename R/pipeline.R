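#' Pipeline configuration
#'
#' Collects every input path and threshold for [run_pipeline()].  All
#' numeric defaults are the package's standard analysis values: 0.95 call
#' rate / 0.05 MAF marker filters, the default [roh_params()], 95\%
#' consensus match with > 100 kb / > 3 SNPs, F_ROH inbreeding cutoff
#' 0.0156, inbred-map filters > 100 kb / > 100 SNPs with whole-set beta
#' > 0.03, and WES MAF cutoff 0.01.
#'
#' @param genotypes path to VCF or PLINK prefix.
#' @param samples path to the sample-table TSV.
#' @param out_dir output directory for stage artifacts.
#' @param wes_vcf optional WES VCF for variant filtering.
#' @param exclude_bed optional BED of regions to mask before calling.
#' @param loci_bed optional BED of known disease loci for annotation.
#' @param min_call_rate,min_maf marker filters.
#' @param roh [roh_params()] for calling.
#' @param match_threshold,consensus_min_kb,consensus_min_snps consensus
#'   thresholds.
#' @param model_tag covariate model for association stages.
#' @param inbred_cutoff F_ROH cutoff for inbred classification.
#' @param map_min_kb,map_min_snps inbred-map consensus filters.
#' @param beta_min whole-set beta threshold for prioritization.
#' @param maf_max WES population-frequency cutoff.
#' @param freq_fields INFO fields holding population frequencies.
#' @param autosomal_kb genome length for F_ROH.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes, samples, out_dir,
                            wes_vcf = NULL, exclude_bed = NULL,
                            loci_bed = NULL,
                            min_call_rate = 0.95, min_maf = 0.05,
                            roh = roh_params(),
                            match_threshold = 0.95,
                            consensus_min_kb = 100, consensus_min_snps = 3,
                            model_tag = "model1",
                            inbred_cutoff = 0.0156,
                            map_min_kb = 100, map_min_snps = 100,
                            beta_min = 0.03, maf_max = 0.01,
                            freq_fields = c("AF"),
                            autosomal_kb = AUTOSOMAL_GENOME_KB) {
  cfg <- mget(names(formals()))
  for (p in c(genotypes = genotypes, samples = samples,
              wes_vcf = wes_vcf, exclude_bed = exclude_bed,
              loci_bed = loci_bed)) {
    probe <- if (file.exists(p)) p else paste0(p, ".bed")
    if (!file.exists(probe)) stop("input path does not exist: ", p)
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the stepwise homozygosity-mapping pipeline
#'
#' Executes ingest, ROH calling, homozygosity statistics, consensus
#' derivation, burden and per-region association, direction-of-effect
#' tabulation, inbred-map prioritization and (when a WES VCF is given)
#' variant filtering, writing one TSV per stage under
#' `config$out_dir` plus a manifest with content hashes.  Stages whose
#' output file already exists are skipped, so a partially complete run
#' resumes from its intermediates; outputs are pure functions of the
#' config and inputs, so re-running on unchanged inputs reproduces
#' identical hashes.
#'
#' @param config a [pipeline_config()].
#' @return data.frame manifest (`stage`, `path`, `md5`), invisibly
#'   written to `manifest.tsv` as well.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$out_dir, c(
    segments = "segments.tsv", profiles = "profiles.tsv",
    consensus = "consensus.tsv", burden = "burden_assoc.tsv",
    region = "consensus_assoc.tsv", direction = "direction_test.tsv",
    inbred = "inbred_map.tsv", prioritized = "prioritized_regions.tsv",
    wes = "wes_candidates.tsv"))
  names(paths) <- c("segments", "profiles", "consensus", "burden",
                    "region", "direction", "inbred", "prioritized", "wes")

  gm <- read_genotypes(config$genotypes)
  if (!is.null(config$exclude_bed))
    gm <- exclude_markers(gm, read_bed_intervals(config$exclude_bed))
  gm <- filter_markers(gm, config$min_call_rate, config$min_maf)
  samples <- read_sample_table(config$samples, gm)
  message("pipeline: ", length(gm$sample_ids), " samples, ",
          nrow(gm$markers), " markers after filters")

  stage <- function(name, fun, reader = read_stage_tsv) {
    p <- paths[[name]]
    if (file.exists(p)) {
      message("pipeline: ", name, " exists, resuming from ", p)
      return(reader(p))
    }
    x <- fun()
    write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    message("pipeline: ", name, " -> ", p, " (", nrow(x), " rows)")
    x
  }

  segments <- stage("segments", function()
    call_roh_cohort(gm, config$roh))
  profiles <- stage("profiles", function() {
    pr <- summarize_homozygosity(segments, gm$sample_ids,
                                 config$autosomal_kb)
    pr$inbred <- classify_inbred(pr$froh, config$inbred_cutoff)
    pr
  })
  consensus <- stage("consensus", function()
    consensus_roh(segments, gm, samples, config$match_threshold,
                  config$consensus_min_kb, config$consensus_min_snps))
  burden <- stage("burden", function() {
    do.call(rbind, lapply(c("froh", "avroh", "nroh", "sroh"), function(p)
      as.data.frame(roh_burden_assoc(profiles, samples, p,
                                     config$model_tag))))
  })
  region <- stage("region", function()
    consensus_assoc(consensus, segments, samples, config$model_tag))
  stage("direction", function()
    tabulate_direction_categories(region))
  inbred_map <- stage("inbred", function()
    build_inbred_map(profiles, samples, segments, gm,
                     config$inbred_cutoff, config$match_threshold,
                     config$map_min_kb, config$map_min_snps))
  prioritized <- stage("prioritized", function() {
    pr <- prioritize_regions(inbred_map, region, gm, config$beta_min,
                             config$map_min_kb, config$map_min_snps)
    if (!is.null(config$loci_bed) && nrow(pr) > 0)
      pr <- annotate_loci(pr, read_bed_intervals(config$loci_bed))
    pr
  })
  if (!is.null(config$wes_vcf)) {
    stage("wes", function()
      filter_wes_variants(config$wes_vcf, segments, config$maf_max,
                          config$freq_fields,
                          if (nrow(prioritized)) prioritized else NULL))
  } else {
    paths <- paths[names(paths) != "wes"]
  }

  manifest <- data.frame(stage = names(paths), path = unname(paths),
                         md5 = unname(tools::md5sum(unname(paths))),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

read_stage_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
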