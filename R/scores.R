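#' Read a GWAS weight table
#'
#' Reads a tab-delimited summary table with a header and (at least) the
#' columns `snp_id`, `chrom`, `pos` (1-based), `effect_allele`,
#' `other_allele`, `beta`, `p_value`; an `se` column is kept when present.
#'
#' @param path Path to the tab-delimited file.
#' @return A validated weight-table tibble.
#' @export
read_weight_table <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  validate_weight_table(tb)
}

validate_weight_table <- function(tb) {
  need <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
            "beta", "p_value")
  miss <- setdiff(need, names(tb))
  if (length(miss))
    abort(sprintf("weight table is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  if (anyDuplicated(tb$snp_id)) abort("weight table has duplicate snp_id values")
  if (any(tb$p_value <= 0 | tb$p_value > 1)) abort("p_value must lie in (0, 1]")
  if (!all(toupper(tb$effect_allele) %in% c("A", "C", "G", "T")) ||
      !all(toupper(tb$other_allele) %in% c("A", "C", "G", "T")))
    abort("alleles must be one of A, C, G, T")
  as_tibble(tb)
}

#' Greedy LD clumping of a GWAS weight table
#'
#' Selects an approximately independent subset of SNPs: candidates are sorted
#' by ascending p-value; a SNP is accepted iff its p-value is below
#' `p_threshold` and its squared dosage correlation in the LD reference with
#' every already-accepted SNP on the same chromosome within `window_kb` is
#' below `r2_threshold`. SNPs absent from the reference are dropped with a
#' message; monomorphic reference SNPs are treated as r^2 = 0 (with a note).
#'
#' The default `r2_threshold = 0.01` mirrors the conventional reading of a
#' printed clumping threshold "r = 0.01" as a squared-correlation threshold;
#' the flag is exposed so either convention can be applied.
#'
#' @param weights Weight-table tibble (see [read_weight_table()]).
#' @param ld_ref A `genotype_matrix` (e.g. from [simulate_founders()])
#'   supplying dosages for LD estimation.
#' @param r2_threshold Squared-correlation threshold (default 0.01).
#' @param window_kb Physical window in kb (default 10,000): SNPs farther apart
#'   are never considered linked.
#' @param p_threshold Significance threshold (default 5e-8).
#' @return The retained subset of `weights` (all columns preserved), ordered
#'   by ascending p-value. Warns (and returns an empty table) when nothing
#'   passes.
#' @export
clump <- function(weights, ld_ref, r2_threshold = 0.01, window_kb = 10000,
                  p_threshold = 5e-8) {
  weights <- validate_weight_table(weights)
  dos <- ld_ref$dosages
  present <- weights$snp_id %in% colnames(dos)
  if (any(!present)) {
    inform(sprintf("excluding %d weight-table SNP(s) not present in the LD reference",
                   sum(!present)))
    weights <- weights[present, , drop = FALSE]
  }
  cand <- weights[weights$p_value < p_threshold, , drop = FALSE]
  cand <- cand[order(cand$p_value), , drop = FALSE]
  if (nrow(cand) == 0) {
    warn("clumping retained no SNPs below the p-value threshold")
    return(cand)
  }
  sds <- apply(dos[, cand$snp_id, drop = FALSE], 2, sd)
  if (any(sds == 0))
    inform(sprintf("%d monomorphic SNP(s) in the LD reference treated as r^2 = 0",
                   sum(sds == 0)))
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in keep) {
      if (cand$chrom[i] != cand$chrom[j]) next
      if (abs(cand$pos[i] - cand$pos[j]) > window_kb * 1000) next
      if (sds[i] == 0 || sds[j] == 0) next # monomorphic: r^2 taken as 0
      r2 <- cor(dos[, cand$snp_id[i]], dos[, cand$snp_id[j]])^2
      if (r2 >= r2_threshold) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  cand[keep, , drop = FALSE]
}

#' Build a polygenic score from a weight table
#'
#' Per individual, the sum over SNPs of the aligned effect-allele dosage times
#' the GWAS beta. Alignment: if the genotype file counts the weight table's
#' `other_allele`, the dosage is flipped to `2 - d`; strand-ambiguous
#' (palindromic A/T, C/G) SNPs and SNPs whose alleles cannot be reconciled by
#' flipping are dropped with a message. Missing dosages are mean-imputed per
#' SNP.
#'
#' @param genotypes A `genotype_matrix`.
#' @param weights Weight-table tibble.
#' @param label Provenance label stored on the result (e.g. `"adult BMI"` or
#'   `"childhood body size"`).
#' @return A tibble `(id, score)` with attributes `n_snps_used` and `label`.
#' @export
build_pgs <- function(genotypes, weights, label = NA_character_) {
  weights <- validate_weight_table(weights)
  snps <- genotypes$snps
  m <- merge(as.data.frame(weights),
             as.data.frame(snps[c("snp_id", "effect_allele", "other_allele")]),
             by = "snp_id", suffixes = c("_w", "_g"))
  if (nrow(m) < nrow(weights))
    inform(sprintf("%d weight-table SNP(s) absent from the genotypes were skipped",
                   nrow(weights) - nrow(m)))
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  pal <- comp[m$effect_allele_w] == m$other_allele_w
  if (any(pal)) {
    inform(sprintf("dropping %d strand-ambiguous (palindromic) SNP(s)", sum(pal)))
    m <- m[!pal, , drop = FALSE]
  }
  same <- m$effect_allele_w == m$effect_allele_g & m$other_allele_w == m$other_allele_g
  flip <- m$effect_allele_w == m$other_allele_g & m$other_allele_w == m$effect_allele_g
  bad <- !(same | flip)
  if (any(bad)) {
    inform(sprintf("dropping %d SNP(s) with irreconcilable alleles", sum(bad)))
    m <- m[!bad, , drop = FALSE]
    same <- same[!bad]; flip <- flip[!bad]
  }
  d <- genotypes$dosages[, m$snp_id, drop = FALSE]
  storage.mode(d) <- "double"
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    for (j in seq_len(ncol(d))) d[is.na(d[, j]), j] <- mu[j]
  }
  if (any(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]
  score <- drop(d %*% m$beta)
  out <- tibble(id = rownames(genotypes$dosages) %||% seq_len(nrow(d)),
                score = score)
  attr(out, "n_snps_used") <- nrow(m)
  attr(out, "label") <- label
  out
}

#' Ancestry principal components from genotype dosages
#'
#' Top-`k` left singular vectors of the column-standardized dosage matrix
#' (monomorphic SNPs dropped), rescaled to unit variance. Deterministic up to
#' sign; the sign is fixed by making each component's largest-magnitude SNP
#' loading positive.
#'
#' @param genotypes A `genotype_matrix`.
#' @param k Number of components.
#' @return A tibble `(id, PC1, ..., PCk)`.
#' @export
ancestry_pcs <- function(genotypes, k) {
  d <- genotypes$dosages
  storage.mode(d) <- "double"
  sds <- apply(d, 2, sd)
  d <- d[, sds > 0, drop = FALSE]
  if (ncol(d) < k)
    abort(sprintf("k = %d exceeds the number of polymorphic SNPs (%d)", k, ncol(d)))
  z <- scale(d)
  sv <- svd(z, nu = k, nv = k)
  if (sv$d[k] <= .Machine$double.eps * sv$d[1])
    abort(sprintf("k = %d exceeds the rank of the standardized dosage matrix (achievable k = %d)",
                  k, sum(sv$d > .Machine$double.eps * sv$d[1])))
  # sign convention: largest-|loading| SNP weight positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) { sv$v[, j] <- -sv$v[, j]; sv$u[, j] <- -sv$u[, j] }
  }
  pcs <- scale(sv$u[, seq_len(k), drop = FALSE])
  colnames(pcs) <- paste0("PC", seq_len(k))
  dplyr::bind_cols(tibble(id = rownames(genotypes$dosages) %||%
                            seq_len(nrow(genotypes$dosages))),
                   as_tibble(pcs))
}

#' Clean anthropometrics and compute BMI
#'
#' Height and weight values more than `sd_limit` standard deviations from the
#' variable mean are treated as outliers and coded to missing, in a single
#' pass using the all-sample mean and SD. Non-positive values are also coded
#' missing. BMI (`weight / height^2`) is returned for complete pairs.
#'
#' @param height Height in metres.
#' @param weight Weight in kg.
#' @param sd_limit Outlier threshold in SDs (default 4).
#' @return A tibble `(height, weight, bmi)` with cleaned values and an
#'   `n_outliers` attribute.
#' @examples
#' clean_anthropometrics(c(1.30, 1.28), c(28, 30))
#' @export
clean_anthropometrics <- function(height, weight, sd_limit = 4) {
  flag <- function(x) {
    bad_pos <- !is.na(x) & x <= 0
    mu <- mean(x, na.rm = TRUE); s <- sd(x, na.rm = TRUE)
    out <- !is.na(x) & abs(x - mu) > sd_limit * s
    x[bad_pos | out] <- NA_real_
    list(x = x, n = sum(out), n_pos = sum(bad_pos))
  }
  h <- flag(height); w <- flag(weight)
  if (h$n_pos + w$n_pos > 0)
    inform(sprintf("%d non-positive height/weight value(s) coded missing",
                   h$n_pos + w$n_pos))
  res <- tibble(height = h$x, weight = w$x, bmi = w$x / h$x^2)
  attr(res, "n_outliers") <- h$n + w$n
  res
}

#' Prorated questionnaire scale score
#'
#' Computes the scale total, prorated for partial response: individuals with
#' at least `min_prop` of item-level information (answered count at least
#' `ceiling(min_prop * n_items)`) get `sum(answered) * n_items / answered`;
#' others are missing.
#'
#' @param item_responses Matrix or data frame of ordinal non-negative integer
#'   item responses (NA = unanswered), one row per respondent.
#' @param n_items Number of items in the full scale (defaults to
#'   `ncol(item_responses)`).
#' @param min_prop Minimum completeness fraction (default 0.8).
#' @param max_category Optional upper bound of the item category range; any
#'   response outside `[0, max_category]` raises an error naming the item.
#' @return Numeric vector of prorated scores (NA where completeness fails).
#' @examples
#' prorate_scale(rbind(c(1, 0, 2, NA), c(NA, NA, 1, 1)), n_items = 4)
#' @export
prorate_scale <- function(item_responses, n_items = ncol(item_responses),
                          min_prop = 0.8, max_category = NULL) {
  x <- as.matrix(item_responses)
  if (any(x < 0 | x != round(x), na.rm = TRUE))
    abort("item responses must be non-negative integers")
  if (!is.null(max_category)) {
    bad <- which(colSums(x > max_category, na.rm = TRUE) > 0)
    if (length(bad))
      abort(sprintf("item(s) out of category range [0, %d]: %s", max_category,
                    paste(colnames(x)[bad] %||% bad, collapse = ", ")))
  }
  answered <- rowSums(!is.na(x))
  need <- ceiling(min_prop * n_items)
  score <- rowSums(x, na.rm = TRUE) * n_items / answered
  score[answered < need] <- NA_real_
  score
}

#' Simulate a GWAS weight table for a cohort's true score
#'
#' Emulates the discovery GWAS behind a polygenic score: for every simulated
#' SNP the true per-allele effect on BMI implied by the cohort's generative
#' model is perturbed with estimation noise at the precision of a GWAS of
#' `n_gwas` individuals (`se = sd(BMI) / (sd(dosage) * sqrt(n_gwas))`), and a
#' two-sided p-value is attached. Larger `n_gwas` gives weights closer to the
#' truth, hence constructed scores more correlated with the true score.
#'
#' @param cohort A genotype-mode `trio_cohort`.
#' @param n_gwas Discovery sample size.
#' @param role Whose generative score scaling to use (default `"child"`).
#' @param seed Optional seed.
#' @return A weight-table tibble (`snp_id`, `chrom`, `pos`, alleles, `beta`,
#'   `se`, `p_value`).
#' @export
simulate_gwas_weights <- function(cohort, n_gwas = 250000, role = "child",
                                  seed = NULL) {
  if (is.null(cohort$geno)) abort("cohort was simulated without genotypes")
  if (!is.null(seed)) set.seed(seed)
  cfg <- cohort$config
  d <- cohort$geno[[role]]
  storage.mode(d) <- "double"
  g_raw <- drop(d %*% cohort$true_effects)
  sdw <- sd(g_raw)
  lam <- cfg$bmi_sd[[role]] * sqrt(cfg[[paste0("pgs_r2_", role)]]) / sdw
  true_beta <- cohort$true_effects * lam
  sd_dos <- pmax(apply(d, 2, sd), 1e-6)
  se <- cfg$bmi_sd[[role]] / (sd_dos * sqrt(n_gwas))
  beta_hat <- rnorm(length(true_beta), true_beta, se)
  dplyr::mutate(cohort$snps[c("snp_id", "chrom", "pos", "effect_allele",
                              "other_allele")],
                beta = beta_hat, se = se,
                p_value = pmax(2 * pnorm(-abs(beta_hat / se)), 1e-300))
}
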