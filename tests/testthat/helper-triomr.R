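# shared fixtures built in code

# wrap a genotype dosage matrix in the container the scoring functions expect
as_geno <- function(dosages, snps, subpop = rep(1L, nrow(dosages))) {
  colnames(dosages) <- snps$snp_id
  structure(list(dosages = dosages, snps = snps, subpop = subpop),
            class = "genotype_matrix")
}

# SNP map with configurable positions, non-palindromic alleles
snp_map <- function(n, chrom = rep(1L, n), pos = seq_len(n) * 1e6L,
                    ea = rep("A", n), oa = rep("G", n)) {
  tibble::tibble(snp_id = sprintf("rs%03d", seq_len(n)), chrom = chrom,
                 pos = pos, effect_allele = ea, other_allele = oa)
}

weight_table <- function(map, beta, p_value, se = NULL) {
  tb <- dplyr::mutate(map, beta = beta, p_value = p_value)
  if (!is.null(se)) tb$se <- se
  tb
}

# quick score-level cohort
quick_cohort <- function(n = 5000, seed = 1, ...) {
  tidy(simulate_trios(sim_config(n_families = n, seed = seed, ...)))
}

# a clean null design: random mating, no confounding, no structural effects
null_config <- function(n, seed, r2 = 0.02, ...) {
  sim_config(n_families = n, seed = seed, spousal_corr = 0,
             confounder_sd = 0, confounder_sd_outcome = 0,
             pgs_r2_child = r2, pgs_r2_mother = r2, pgs_r2_father = r2,
             outcomes = "dep", ...)
}

# summary-level generator for the summary-statistic MR estimators: k SNPs,
# exposure betas drawn positive, outcome betas = slope * beta_exp + pleiotropy
# + estimation noise. Independent of the estimators under test.
make_summaries <- function(k, slope, pleio_mean = 0, pleio_sd = 0,
                           se_exp = 0.002, se_out = 0.01, seed = 1) {
  set.seed(seed)
  bx <- abs(rnorm(k, 0.03, 0.01)) + 0.005
  pleio <- if (pleio_sd > 0 || pleio_mean != 0)
    rnorm(k, pleio_mean, pleio_sd) else 0
  tibble::tibble(
    snp_id = sprintf("rs%03d", seq_len(k)),
    beta_exp = bx + rnorm(k, 0, se_exp),
    se_exp = se_exp,
    beta_out = slope * bx + pleio + rnorm(k, 0, se_out),
    se_out = se_out)
}
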