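#' Per-SNP associations with an outcome, optionally parental-adjusted
#'
#' For each SNP, regresses the (standardized) outcome on the child's dosage
#' plus covariates, with heteroskedasticity-robust standard errors. With
#' `adjust_parental = TRUE` the mother's and father's dosages at the same SNP
#' enter as covariates — the within-family analogue, which removes dynastic
#' and demographic contributions from the SNP-outcome association.
#' Monomorphic SNPs are skipped with a message.
#'
#' @param cohort A genotype-mode `trio_cohort`.
#' @param outcome Outcome column in `cohort$families`.
#' @param covariates Optional covariate columns.
#' @param adjust_parental Adjust for parental genotype at each SNP?
#' @param transform Outcome transform, as in [fit_ols()].
#' @return A tibble `(snp_id, beta_out, se_out, n)`.
#' @export
snp_outcome_assoc <- function(cohort, outcome, covariates = NULL,
                              adjust_parental = FALSE,
                              transform = "standardize") {
  if (is.null(cohort$geno)) abort("cohort was simulated without genotypes")
  fam <- cohort$families
  vars <- c(outcome, covariates)
  ok <- complete.cases(fam[vars])
  fam <- fam[ok, , drop = FALSE]
  y <- fam[[outcome]]
  if (transform == "log1p") y <- log1p(y)
  if (transform %in% c("standardize", "log1p")) y <- (y - mean(y)) / sd(y)
  W <- build_design(fam, covariates)
  dc <- cohort$geno$child[ok, , drop = FALSE]
  dm <- cohort$geno$mother[ok, , drop = FALSE]
  df_ <- cohort$geno$father[ok, , drop = FALSE]
  snp_ids <- colnames(dc)
  res <- vector("list", length(snp_ids))
  skipped <- 0L
  for (j in seq_along(snp_ids)) {
    g <- as.numeric(dc[, j])
    if (sd(g) == 0) { skipped <- skipped + 1L; next }
    X <- cbind(dosage = g, W)
    if (adjust_parental)
      X <- cbind(X, dosage_m = as.numeric(dm[, j]),
                 dosage_f = as.numeric(df_[, j]))
    fit <- ls_core(X, y)
    res[[j]] <- tibble(snp_id = snp_ids[j],
                       beta_out = fit$coef[["dosage"]],
                       se_out = sqrt(fit$vcov["dosage", "dosage"]),
                       n = fit$n)
  }
  if (skipped > 0) inform(sprintf("skipped %d monomorphic SNP(s)", skipped))
  dplyr::bind_rows(res)
}

#' Assemble harmonized SNP summaries for summary-statistic MR
#'
#' Joins per-SNP exposure effects (from a GWAS weight table, `beta`/`se`) with
#' in-cohort outcome associations (from [snp_outcome_assoc()]), then
#' harmonizes orientation: each SNP is flipped so its exposure beta is
#' positive (the MR-Egger convention), negating the outcome beta in step.
#'
#' @param assoc Output of [snp_outcome_assoc()].
#' @param weights Weight table with `snp_id`, `beta`, and `se` columns.
#' @return A tibble `(snp_id, beta_exp, se_exp, beta_out, se_out)`.
#' @export
make_snp_summaries <- function(assoc, weights) {
  if (!"se" %in% names(weights))
    abort("weight table needs an `se` column for summary-statistic MR")
  tb <- dplyr::inner_join(
    dplyr::select(weights, "snp_id", beta_exp = "beta", se_exp = "se"),
    dplyr::select(assoc, "snp_id", "beta_out", "se_out"),
    by = "snp_id")
  harmonize_summaries(tb)
}

harmonize_summaries <- function(summaries) {
  flip <- summaries$beta_exp < 0
  summaries$beta_exp[flip] <- -summaries$beta_exp[flip]
  summaries$beta_out[flip] <- -summaries$beta_out[flip]
  summaries
}

validate_summaries <- function(summaries, min_snps, caller) {
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  miss <- setdiff(need, names(summaries))
  if (length(miss))
    abort(sprintf("%s: summaries are missing column(s) %s", caller,
                  paste(miss, collapse = ", ")))
  if (nrow(summaries) < min_snps)
    abort(sprintf("%s requires at least %d SNPs (got %d)", caller, min_snps,
                  nrow(summaries)))
  if (any(summaries$se_exp <= 0) || any(summaries$se_out <= 0))
    abort(sprintf("%s: standard errors must be positive", caller))
  summaries
}

# shared weighted-regression core for IVW (no intercept) and Egger (free
# intercept): WLS of beta_out on beta_exp with weights 1/se_out^2
weighted_mr_regression <- function(summaries, intercept = FALSE) {
  w <- 1 / summaries$se_out^2
  X <- if (intercept) cbind(`(Intercept)` = 1, slope = summaries$beta_exp)
       else cbind(slope = summaries$beta_exp)
  y <- summaries$beta_out
  sw <- sqrt(w)
  A <- crossprod(X * sw)
  b <- solve(A, crossprod(X * sw, y * sw))
  resid <- y - drop(X %*% b)
  q <- sum(w * resid^2) # Cochran's Q about the fitted line
  list(coef = drop(b), vcov_fixed = solve(A), q = q,
       df = nrow(X) - ncol(X))
}

#' Inverse-variance weighted MR estimate
#'
#' Slope of the SNP-outcome betas on the SNP-exposure betas through the
#' origin, weighted by the inverse outcome variance. Cochran's Q about the
#' fitted slope is reported; with `random_effects = "auto"` (default) the
#' standard error is inflated multiplicatively by `sqrt(Q / (k - 1))` whenever
#' heterogeneity exceeds its degrees of freedom.
#'
#' @param summaries Harmonized SNP summaries (see [make_snp_summaries()]).
#' @param random_effects `"auto"`, `"never"` (fixed-effect), or `"always"`.
#' @return One-row estimate tibble (estimator `"ivw"`) with columns `beta`,
#'   `se`, `ci_low`, `ci_high`, `p`, `n` (SNP count), `Q`.
#' @examples
#' s <- tibble::tibble(beta_exp = c(1, 1), se_exp = 0.01,
#'                     beta_out = c(0.5, 1.0), se_out = c(0.1, 0.2))
#' ivw(s, random_effects = "never")
#' @export
ivw <- function(summaries, random_effects = c("auto", "never", "always")) {
  random_effects <- match.arg(random_effects)
  summaries <- harmonize_summaries(validate_summaries(summaries, 2, "ivw"))
  fit <- weighted_mr_regression(summaries, intercept = FALSE)
  phi <- switch(random_effects,
                never = 1,
                always = sqrt(fit$q / fit$df),
                auto = max(1, sqrt(fit$q / fit$df)))
  se <- sqrt(fit$vcov_fixed[1, 1]) * phi
  summary_estimate_row("slope", fit$coef[["slope"]], se, "ivw",
                       nrow(summaries), fit$q)
}

#' MR-Egger regression
#'
#' Weighted regression of SNP-outcome on SNP-exposure betas with a free
#' intercept: the intercept estimates the average directional (horizontally
#' pleiotropic) effect per SNP, and a non-zero intercept indicates directional
#' pleiotropy; the slope is the pleiotropy-adjusted causal estimate (valid
#' under the InSIDE assumption). Exposure betas must be oriented positive
#' (harmonization is applied; an unharmonizable input errors). Standard errors
#' use multiplicative random-effects scaling `max(1, sqrt(Q / (k - 2)))`.
#'
#' @param summaries Harmonized SNP summaries (at least 3 SNPs).
#' @return Two-row estimate tibble (estimators `"egger_slope"`,
#'   `"egger_intercept"`).
#' @export
egger <- function(summaries) {
  summaries <- harmonize_summaries(validate_summaries(summaries, 3, "egger"))
  if (any(summaries$beta_exp <= 0))
    abort("egger: exposure betas must be strictly positive after harmonization")
  fit <- weighted_mr_regression(summaries, intercept = TRUE)
  phi <- max(1, sqrt(fit$q / fit$df))
  se <- sqrt(diag(fit$vcov_fixed)) * phi
  dplyr::bind_rows(
    summary_estimate_row("slope", fit$coef[["slope"]], se[["slope"]],
                         "egger_slope", nrow(summaries), fit$q),
    summary_estimate_row("intercept", fit$coef[["(Intercept)"]],
                         se[["(Intercept)"]], "egger_intercept",
                         nrow(summaries), fit$q))
}

# summary-statistic estimates are per unit of exposure (1 kg/m^2 when the
# weight-table betas are per-allele kg/m^2); rescale_effect() converts
summary_estimate_row <- function(term, beta, se, estimator, k, q = NA_real_) {
  tibble(term = term, beta = beta, se = se,
         ci_low = beta - qnorm(0.975) * se,
         ci_high = beta + qnorm(0.975) * se,
         p = 2 * pnorm(-abs(beta / se)),
         estimator = estimator, n = k, Q = q, scale = "per1")
}

wald_ratios <- function(summaries) {
  r <- summaries$beta_out / summaries$beta_exp
  se_r <- summaries$se_out / abs(summaries$beta_exp)
  list(r = r, se = se_r, w = 1 / se_r^2)
}

weighted_median_point <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

boot_se <- function(summaries, point_fun, n_boot, seed) {
  set.seed(seed)
  k <- nrow(summaries)
  est <- vapply(seq_len(n_boot), function(b) {
    bs <- summaries
    bs$beta_exp <- rnorm(k, summaries$beta_exp, summaries$se_exp)
    bs$beta_out <- rnorm(k, summaries$beta_out, summaries$se_out)
    point_fun(bs)
  }, numeric(1))
  sd(est)
}

#' Weighted-median MR estimate
#'
#' Weighted median of the per-SNP Wald ratios with inverse-variance weights:
#' consistent as long as SNPs contributing at least half the weight are valid
#' instruments (50% breakdown). The standard error comes from a parametric
#' bootstrap of the summary statistics (default 1,000 replicates, recorded
#' seed).
#'
#' @param summaries Harmonized SNP summaries (at least 3 SNPs).
#' @param n_boot,seed Bootstrap replicate count and seed.
#' @return One-row estimate tibble (estimator `"wmedian"`).
#' @export
weighted_median <- function(summaries, n_boot = 1000, seed = 1) {
  summaries <- harmonize_summaries(validate_summaries(summaries, 3, "weighted_median"))
  point <- function(s) { wr <- wald_ratios(s); weighted_median_point(wr$r, wr$w) }
  se <- boot_se(summaries, point, n_boot, seed)
  summary_estimate_row("slope", point(summaries), se, "wmedian", nrow(summaries))
}

#' Mode-based MR estimate
#'
#' Mode of the smoothed Wald-ratio density: each ratio contributes a normal
#' kernel, with common bandwidth `bandwidth_factor` times the modified
#' Silverman rule `0.9 * min(sd, mad) * k^(-1/5)` applied to the ratios, and
#' kernels weighted by the inverse ratio variance. Consistent when the largest
#' group of SNPs sharing a causal estimate are valid instruments (ZEMPA).
#' As the bandwidth grows the estimate tends to the weighted mean. Standard
#' error by parametric bootstrap.
#'
#' @inheritParams weighted_median
#' @param bandwidth_factor Positive multiplier on the Silverman bandwidth.
#' @return One-row estimate tibble (estimator `"mode"`).
#' @export
mode_based <- function(summaries, bandwidth_factor = 1, n_boot = 1000, seed = 1) {
  if (bandwidth_factor <= 0) abort("bandwidth_factor must be positive")
  summaries <- harmonize_summaries(validate_summaries(summaries, 3, "mode_based"))
  point <- function(s) {
    wr <- wald_ratios(s)
    r <- wr$r; w <- wr$w / sum(wr$w)
    spread <- min(sd(r), mad(r))
    if (spread == 0) return(r[1])
    h <- bandwidth_factor * 0.9 * spread * length(r)^(-1 / 5)
    dens <- function(x) vapply(x, function(xi) sum(w * dnorm(xi, r, h)), numeric(1))
    grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 512)
    x0 <- grid[which.max(dens(grid))]
    stats::optimize(dens, c(x0 - 2 * h, x0 + 2 * h), maximum = TRUE)$maximum
  }
  se <- boot_se(summaries, point, n_boot, seed)
  summary_estimate_row("slope", point(summaries), se, "mode", nrow(summaries))
}

#' Read or write SNP summaries as tab-delimited text
#'
#' @param summaries SNP-summary tibble.
#' @param path File path.
#' @return `read_snp_summaries` returns the tibble; `write_snp_summaries`
#'   returns `path` invisibly.
#' @export
write_snp_summaries <- function(summaries, path) {
  readr::write_tsv(summaries[c("snp_id", "beta_exp", "se_exp", "beta_out", "se_out")],
                   path)
  invisible(path)
}

#' @rdname write_snp_summaries
#' @export
read_snp_summaries <- function(path) {
  validate_summaries(readr::read_tsv(path, show_col_types = FALSE), 1,
                     "read_snp_summaries")
}

#' Spousal assortative-mating diagnostics
#'
#' Regresses every standardized paternal trait on every standardized maternal
#' trait (phenotype x phenotype and score x score grids), optionally adjusted
#' for covariates such as ancestry components, with robust standard errors.
#' Under single-trait assortment the same-trait coefficient recovers the
#' spousal correlation; off-diagonal coefficients indicate cross-trait
#' assortment.
#'
#' @param families Cohort family tibble with paired parents (one couple per
#'   row).
#' @param mother_traits,father_traits Named character vectors mapping trait
#'   labels to columns.
#' @param covariates Optional covariate columns.
#' @return A tibble `(mother_trait, father_trait, beta, se, ci_low, ci_high,
#'   p, n)`.
#' @export
assortment_diagnostics <- function(families,
                                   mother_traits = c(bmi = "bmi_mother",
                                                     symptom = "symptom_mother"),
                                   father_traits = c(bmi = "bmi_father",
                                                     symptom = "symptom_father"),
                                   covariates = NULL) {
  miss <- setdiff(c(mother_traits, father_traits, covariates), names(families))
  if (length(miss))
    abort(sprintf("unpaired or missing parent columns: %s",
                  paste(miss, collapse = ", ")))
  grid <- expand.grid(m = names(mother_traits), f = names(father_traits),
                      stringsAsFactors = FALSE)
  res <- purrr::pmap(grid, function(m, f) {
    d <- families[complete.cases(families[c(mother_traits[[m]],
                                            father_traits[[f]], covariates)]), ]
    d$.x <- as.numeric(scale(d[[mother_traits[[m]]]]))
    d$.y <- as.numeric(scale(d[[father_traits[[f]]]]))
    X <- build_design(d, c(".x", covariates))
    fit <- ls_core(X, d$.y)
    se <- sqrt(fit$vcov[".x", ".x"])
    tibble(mother_trait = m, father_trait = f, beta = fit$coef[[".x"]],
           se = se, ci_low = fit$coef[[".x"]] - qnorm(0.975) * se,
           ci_high = fit$coef[[".x"]] + qnorm(0.975) * se,
           p = 2 * pnorm(-abs(fit$coef[[".x"]] / se)), n = fit$n)
  })
  dplyr::bind_rows(res)
}
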