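#' Covariate sets for the three adjustment models
#'
#' Model 1 adjusts for cohort and the first four principal components;
#' model 2 additionally for age; model 3 additionally for age and sex.
#'
#' @param model_tag `"model1"`, `"model2"` or `"model3"`.
#' @return character vector of covariate column names.
#' @export
model_covariates <- function(model_tag = c("model1", "model2", "model3")) {
  model_tag <- match.arg(model_tag)
  base <- c("cohort", "PC1", "PC2", "PC3", "PC4")
  switch(model_tag,
         model1 = base,
         model2 = c(base, "age"),
         model3 = c(base, "age", "sex"))
}

#' Logistic association of a predictor with case-control status
#'
#' Maximum-likelihood binomial regression with logit link of phenotype on
#' the predictor plus covariates; cohort and sex enter as factors.  Wald
#' 95\% confidence interval and p-value for the predictor coefficient.
#' Rows with missing values in any used column are dropped and `n_used`
#' reports the remainder.  Non-convergence or separation is flagged
#' (`converged = FALSE`, `p_value = 1`) rather than fatal, since consensus
#' regions with tiny carrier counts occur routinely.
#'
#' @param data data.frame containing `phenotype` (0/1), the predictor
#'   column and the covariate columns.
#' @param predictor name of the predictor column.
#' @param covariates covariate column names (e.g. [model_covariates()]);
#'   names absent from `data` are an error.
#' @param label predictor label carried into the result.
#' @return one-row data.frame of class `roh_assoc` with `predictor`,
#'   `beta`, `ci_low`, `ci_high`, `p_value`, `n_used`, `direction`
#'   (`"risk"` if beta > 0 else `"protective"`), `converged`.
#' @export
fit_logistic_assoc <- function(data, predictor, covariates = character(),
                               label = predictor) {
  stopifnot(predictor %in% names(data))
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov))
    stop("covariate column(s) not in data: ",
         paste(missing_cov, collapse = ", "))
  cols <- c("phenotype", predictor, covariates)
  d <- data[complete.cases(data[cols]), cols, drop = FALSE]
  if (length(unique(d$phenotype)) < 2)
    stop("need both phenotype classes present")
  for (v in intersect(c("cohort", "sex"), covariates))
    d[[v]] <- factor(d[[v]])
  # drop factor covariates with a single level (e.g. one cohort)
  keep <- vapply(covariates, function(v)
    !is.factor(d[[v]]) || nlevels(d[[v]]) > 1, logical(1))
  covariates <- covariates[keep]
  rhs <- paste(c(sprintf("`%s`", predictor),
                 sprintf("`%s`", covariates)), collapse = " + ")
  form <- as.formula(paste("phenotype ~", rhs))
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = d),
    warning = function(w) invokeRestart("muffleWarning"))
  cf <- coef(summary(fit))
  row <- match(sprintf("`%s`", predictor), rownames(cf))
  if (is.na(row)) row <- match(predictor, rownames(cf))
  beta <- cf[row, "Estimate"]
  se <- cf[row, "Std. Error"]
  ok <- fit$converged && is.finite(se) && se < 100
  res <- data.frame(
    predictor = label,
    beta = beta,
    ci_low = beta - 1.96 * se,
    ci_high = beta + 1.96 * se,
    p_value = if (ok) cf[row, "Pr(>|z|)"] else 1,
    n_used = nrow(d),
    direction = if (beta > 0) "risk" else "protective",
    converged = ok,
    stringsAsFactors = FALSE)
  class(res) <- c("roh_assoc", "data.frame")
  res
}

#' @export
print.roh_assoc <- function(x, ...) {
  df <- as.data.frame(x)
  df$beta <- sprintf("%.3f", df$beta)
  df$ci <- sprintf("(%.3f, %.3f)", x$ci_low, x$ci_high)
  df$p_value <- format(x$p_value, digits = 3)
  print(df[c("predictor", "beta", "ci", "p_value", "n_used", "direction")],
        row.names = FALSE)
  invisible(x)
}

#' Burden association of a homozygosity parameter
#'
#' Merges per-individual homozygosity profiles with the sample table,
#' applies the rank-based inverse normal transformation to the burden
#' parameter, and fits the logistic model for the chosen covariate set.
#'
#' @param profiles data.frame from [summarize_homozygosity()].
#' @param sample_table data.frame with `sample_id`, `phenotype` and the
#'   covariates of the chosen model.
#' @param parameter one of `"froh"`, `"avroh"`, `"nroh"`, `"sroh"`.
#' @param model_tag adjustment model, see [model_covariates()].
#' @param transform apply [rank_inverse_normal()] to the parameter
#'   (the default, as burden parameters are heavily skewed).
#' @return a `roh_assoc` result row, see [fit_logistic_assoc()].
#' @export
roh_burden_assoc <- function(profiles, sample_table,
                             parameter = c("froh", "avroh", "nroh", "sroh"),
                             model_tag = "model1", transform = TRUE) {
  parameter <- match.arg(parameter)
  col <- switch(parameter, froh = "froh", avroh = "avroh_kb",
                nroh = "nroh", sroh = "sroh_kb")
  d <- merge(sample_table, profiles[c("individual_id", col)],
             by.x = "sample_id", by.y = "individual_id")
  x <- as.numeric(d[[col]])
  d$predictor <- if (transform) rank_inverse_normal(x) else x
  covs <- intersect(model_covariates(model_tag), names(d))
  fit_logistic_assoc(d, "predictor", covs,
                     label = if (transform) paste0("INT_", parameter)
                             else parameter)
}

#' Carrier indicator matrix for consensus ROHs
#'
#' An individual carries a consensus region when one of its called
#' segments covers the region — fully by default (consensus intervals are
#' member intersections, so members cover them by construction), or by
#' any overlap with `coverage = "any"`.
#'
#' @param consensus data.frame from [derive_consensus()].
#' @param segments cohort segment data.frame.
#' @param sample_ids individuals to score (rows of the result).
#' @param coverage `"full"` or `"any"`.
#' @return logical matrix, individuals x consensus regions.
#' @export
carrier_matrix <- function(consensus, segments, sample_ids,
                           coverage = c("full", "any")) {
  coverage <- match.arg(coverage)
  m <- matrix(FALSE, length(sample_ids), nrow(consensus),
              dimnames = list(sample_ids, NULL))
  for (j in seq_len(nrow(consensus))) {
    s <- segments[segments$chrom == consensus$chrom[j], , drop = FALSE]
    hit <- if (coverage == "full")
      s$start_bp <= consensus$start_bp[j] & s$end_bp >= consensus$end_bp[j]
    else
      s$start_bp <= consensus$end_bp[j] & s$end_bp >= consensus$start_bp[j]
    m[unique(s$individual_id[hit]), j] <- TRUE
  }
  m
}

#' Per-region association of consensus ROHs with phenotype
#'
#' Fits one logistic model per consensus region with the carrier
#' indicator as predictor, adjusted per the chosen covariate model.
#'
#' @inheritParams carrier_matrix
#' @param sample_table data.frame with `sample_id`, `phenotype`, covariates.
#' @param model_tag adjustment model, see [model_covariates()].
#' @param coverage carrier definition, see [carrier_matrix()].
#' @return `consensus` with appended columns `beta`, `ci_low`, `ci_high`,
#'   `p_value`, `n_used`, `direction`, `converged`, `n_carriers`.
#' @export
consensus_assoc <- function(consensus, segments, sample_table,
                            model_tag = "model1", coverage = "full") {
  if (nrow(consensus) == 0) {
    res <- consensus
    for (cl in c("beta", "ci_low", "ci_high", "p_value")) res[[cl]] <- numeric()
    res$n_used <- integer(); res$direction <- character()
    res$converged <- logical(); res$n_carriers <- integer()
    return(res)
  }
  cm <- carrier_matrix(consensus, segments, sample_table$sample_id, coverage)
  covs <- intersect(model_covariates(model_tag), names(sample_table))
  rows <- lapply(seq_len(nrow(consensus)), function(j) {
    d <- sample_table
    d$carrier <- as.integer(cm[d$sample_id, j])
    if (length(unique(d$carrier)) < 2) {
      data.frame(beta = 0, ci_low = 0, ci_high = 0, p_value = 1,
                 n_used = nrow(d), direction = "protective",
                 converged = FALSE, stringsAsFactors = FALSE)
    } else {
      r <- fit_logistic_assoc(d, "carrier", covs)
      r$predictor <- NULL
      as.data.frame(r)
    }
  })
  res <- cbind(consensus, do.call(rbind, rows))
  res$n_carriers <- colSums(cm)
  rownames(res) <- NULL
  res
}

#' Exact binomial test for direction-of-effect enrichment
#'
#' Tests whether risk-direction regions (beta > 0) outnumber
#' protective-direction regions beyond chance, against a fair-coin null.
#' Two-sided exact p-value (minimum-likelihood-sum definition, as in
#' [stats::binom.test()]; for p0 = 0.5 this equals doubling the smaller
#' tail, capped at 1).
#'
#' @param n_risk number of risk-direction regions.
#' @param n_protective number of protective-direction regions.
#' @return list with `probability_of_success` (risk fraction) and
#'   `p_value`.
#' @export
direction_binomial_test <- function(n_risk, n_protective) {
  n <- n_risk + n_protective
  if (n < 1) stop("no regions to test")
  bt <- binom.test(n_risk, n, p = 0.5)
  list(probability_of_success = n_risk / n, p_value = bt$p.value)
}

#' Direction-category filter definitions
#'
#' Category A: length > 100 kb and > 3 SNPs; B: > 25 SNPs; C: > 50 SNPs;
#' D: > 3 SNPs and per-region association p < 0.05.
#'
#' @return data.frame with `label`, `min_kb`, `min_snps`, `p_max`.
#' @export
direction_categories <- function() {
  data.frame(label = c("A", "B", "C", "D"),
             min_kb = 100, min_snps = c(3, 25, 50, 3),
             p_max = c(NA, NA, NA, 0.05), stringsAsFactors = FALSE)
}

#' Tabulate direction-of-effect enrichment by category
#'
#' One row for the whole result set plus one per category filter; each
#' row counts risk and protective regions and applies
#' [direction_binomial_test()].  Non-converged fits are excluded (with a
#' message when present).
#'
#' @param results data.frame from [consensus_assoc()] (needs `length_kb`,
#'   `n_snps`, `beta`, `p_value`, `converged`).
#' @param categories data.frame as [direction_categories()].
#' @return data.frame with `category`, `n`, `n_risk`, `n_protective`,
#'   `p_value`, `probability_of_success`.
#' @export
tabulate_direction_categories <- function(results,
                                          categories = direction_categories()) {
  if (!is.null(results$converged)) {
    n_bad <- sum(!results$converged)
    if (n_bad > 0) {
      message("tabulate_direction_categories: excluding ", n_bad,
              " non-converged fits")
      results <- results[results$converged, , drop = FALSE]
    }
  }
  tab_row <- function(label, r) {
    n_risk <- sum(r$beta > 0)
    n_prot <- sum(r$beta < 0)
    if (n_risk + n_prot == 0) {
      warning("category ", label, ": no regions")
      return(data.frame(category = label, n = 0L, n_risk = 0L,
                        n_protective = 0L, p_value = NA_real_,
                        probability_of_success = NA_real_,
                        stringsAsFactors = FALSE))
    }
    bt <- direction_binomial_test(n_risk, n_prot)
    data.frame(category = label, n = n_risk + n_prot, n_risk = n_risk,
               n_protective = n_prot, p_value = bt$p_value,
               probability_of_success = bt$probability_of_success,
               stringsAsFactors = FALSE)
  }
  out <- list(tab_row("all", results))
  for (i in seq_len(nrow(categories))) {
    ct <- categories[i, ]
    sel <- results$length_kb > ct$min_kb & results$n_snps > ct$min_snps
    if (!is.na(ct$p_max)) sel <- sel & results$p_value < ct$p_max
    out[[length(out) + 1L]] <- tab_row(ct$label,
                                       results[sel, , drop = FALSE])
  }
  do.call(rbind, out)
}

#' Odds ratio and chi-square test for a 2x2 exposure table
#'
#' OR = ad/bc with Wald 95\% CI; p-value from the 1-df Pearson chi-square
#' without continuity correction.  A zero cell triggers a 0.5 continuity
#' adjustment of the OR and CI (flagged in the result).
#'
#' @param a exposed cases.
#' @param b exposed controls.
#' @param c unexposed cases.
#' @param d unexposed controls.
#' @return data.frame with `odds_ratio`, `ci_low`, `ci_high`, `chi2_p`,
#'   `adjusted` (zero-cell flag).
#' @export
two_by_two_association <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0,
            a + b > 0, c + d > 0, a + c > 0, b + d > 0)
  adjusted <- any(c(a, b, c, d) == 0)
  if (adjusted) {
    a2 <- a + 0.5; b2 <- b + 0.5; c2 <- c + 0.5; d2 <- d + 0.5
  } else {
    a2 <- a; b2 <- b; c2 <- c; d2 <- d
  }
  or <- (a2 * d2) / (b2 * c2)
  se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  p <- chisq.test(matrix(c(a, b, c, d), nrow = 2), correct = FALSE)$p.value
  data.frame(odds_ratio = or,
             ci_low = exp(log(or) - 1.96 * se),
             ci_high = exp(log(or) + 1.96 * se),
             chi2_p = p, adjusted = adjusted)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of tests.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(m >= 1)
  alpha / m
}
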