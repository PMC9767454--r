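#' Simulation configuration for trio cohorts
#'
#' Collects every generative parameter of the trio-cohort simulator in one
#' validated object. Defaults reproduce the study conditions of a large
#' Norwegian birth-cohort trio analysis: 40,949 mother-father-child trios,
#' child BMI at age 8 with mean 16.3 kg/m^2 (SD 2.0), maternal pre-pregnancy
#' BMI 24.0 (4.1), paternal BMI 25.9 (3.2), a polygenic score explaining
#' 1.7%/3.2%/3.0% of BMI variance for child/mother/father, and a spousal BMI
#' correlation of 0.23. All structural effects (causal, dynastic, pleiotropic)
#' default to zero, i.e. the global null.
#'
#' @param n_families Number of trios (one child per family unless
#'   `sibship_prob > 0`).
#' @param n_snps Number of simulated biallelic SNPs (default 954, the size of
#'   an adult-BMI genome-wide-significant instrument set).
#' @param maf_range Interval in (0, 0.5] from which ancestral minor-allele
#'   frequencies are drawn uniformly.
#' @param ld_block_size,ld_rho Founder haplotypes are drawn from a Gaussian
#'   copula with AR(1) correlation `ld_rho` within blocks of `ld_block_size`
#'   adjacent SNPs, then thresholded to alleles; `ld_rho = 0` gives linkage
#'   equilibrium.
#' @param n_subpops,fst Number of ancestral subpopulations and the
#'   Balding-Nichols divergence parameter: subpopulation allele frequencies are
#'   drawn from `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral frequency
#'   `p`. `fst = 0` collapses to a single panmictic population.
#' @param strat_shift_bmi,strat_shift_outcome,strat_shift_score Per-subpopulation
#'   mean shifts (recycled to `n_subpops`), in SD units, applied to BMI, the
#'   outcome liability, and the true polygenic score. Non-zero values create
#'   uncontrolled population stratification.
#' @param pgs_r2_child,pgs_r2_mother,pgs_r2_father Fraction of BMI variance
#'   explained by the true polygenic score for each family role, in `[0, 1)`.
#' @param spousal_corr Target cross-spouse correlation structure over the two
#'   mating traits `{BMI, symptom liability}`: a scalar (same-trait BMI
#'   correlation, the usual case) or a 2x2 matrix with rows = mother traits and
#'   columns = father traits. Matching uses a single latent mating score per
#'   parent, so only rank-1 structures are exactly representable; see
#'   [assortative_pairing()].
#' @param beta_child Causal effect of the child's own BMI on each outcome, in
#'   SD of outcome per 5 kg/m^2.
#' @param alpha_mother,alpha_father Dynastic (genetic-nurture) effects of
#'   maternal and paternal BMI on the child outcome, same units.
#' @param theta_pleio Mean direct (horizontally pleiotropic) effect of the
#'   child's standardized true score on the outcome, in outcome SD.
#' @param confounder_sd Loading (in BMI SD units) of the family-level shared
#'   confounder on every trio member's BMI.
#' @param confounder_sd_outcome Loading (in outcome SD units) of the same
#'   confounder on the child outcome. Jointly non-zero values confound the
#'   BMI-outcome association for non-genetic estimators.
#' @param bmi_mean,bmi_sd Named numeric vectors (`child`, `mother`, `father`)
#'   of BMI means and SDs in kg/m^2.
#' @param outcomes Character vector of outcome liabilities to simulate.
#' @param outcome_items Named list mapping outcome names to
#'   `c(n_items, n_categories)` for optional ordinal questionnaire-item
#'   generation (defaults emulate a 13-item 0-2 depression scale, a 5-item 0-2
#'   anxiety scale, and an 18-item 0-3 ADHD scale, with totals ranging 0-26,
#'   0-10 and 0-54).
#' @param sibship_prob Probability that a family contributes a second child
#'   whose records share the parents' `cluster_id`; used to exercise
#'   cluster-robust standard errors. Default 0 (one child per family,
#'   `cluster_id == family_id`).
#' @param seed Integer seed making the whole simulation reproducible.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_families = 500, seed = 7)
#' cfg$pgs_r2_child
#' @export
sim_config <- function(n_families = 40949,
                       n_snps = 954,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 10,
                       ld_rho = 0,
                       n_subpops = 1,
                       fst = 0,
                       strat_shift_bmi = 0,
                       strat_shift_outcome = 0,
                       strat_shift_score = 0,
                       pgs_r2_child = 0.017,
                       pgs_r2_mother = 0.032,
                       pgs_r2_father = 0.030,
                       spousal_corr = 0.23,
                       beta_child = 0,
                       alpha_mother = 0,
                       alpha_father = 0,
                       theta_pleio = 0,
                       confounder_sd = 0.2,
                       confounder_sd_outcome = 0.2,
                       bmi_mean = c(child = 16.3, mother = 24.0, father = 25.9),
                       bmi_sd = c(child = 2.0, mother = 4.1, father = 3.2),
                       outcomes = c("dep", "anx", "adhd"),
                       outcome_items = list(dep = c(13L, 3L),
                                            anx = c(5L, 3L),
                                            adhd = c(18L, 4L)),
                       sibship_prob = 0,
                       seed = 1L) {
  cfg <- list(
    n_families = as.integer(n_families), n_snps = as.integer(n_snps),
    maf_range = maf_range, ld_block_size = as.integer(ld_block_size),
    ld_rho = ld_rho, n_subpops = as.integer(n_subpops), fst = fst,
    strat_shift_bmi = rep_len(strat_shift_bmi, n_subpops),
    strat_shift_outcome = rep_len(strat_shift_outcome, n_subpops),
    strat_shift_score = rep_len(strat_shift_score, n_subpops),
    pgs_r2_child = pgs_r2_child, pgs_r2_mother = pgs_r2_mother,
    pgs_r2_father = pgs_r2_father,
    spousal_corr = as_spousal_matrix(spousal_corr),
    beta_child = beta_child, alpha_mother = alpha_mother,
    alpha_father = alpha_father, theta_pleio = theta_pleio,
    confounder_sd = confounder_sd,
    confounder_sd_outcome = confounder_sd_outcome,
    bmi_mean = bmi_mean[c("child", "mother", "father")],
    bmi_sd = bmi_sd[c("child", "mother", "father")],
    outcomes = outcomes, outcome_items = outcome_items,
    sibship_prob = sibship_prob, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

as_spousal_matrix <- function(x) {
  traits <- c("bmi", "symptom")
  if (is.matrix(x)) {
    stopifnot(all(dim(x) == c(2, 2)))
    dimnames(x) <- list(mother = traits, father = traits)
    return(x)
  }
  m <- matrix(0, 2, 2, dimnames = list(mother = traits, father = traits))
  m["bmi", "bmi"] <- x
  m
}

cfg_error <- function(field, msg) {
  abort(sprintf("invalid sim_config field `%s`: %s", field, msg),
        class = "triomr_config_error")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_families < 1) cfg_error("n_families", "must be >= 1")
  if (cfg$n_snps < 1) cfg_error("n_snps", "must be >= 1")
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    cfg_error("maf_range", "must be an interval within (0, 0.5]")
  if (cfg$fst < 0 || cfg$fst >= 0.5)
    cfg_error("fst", "must lie in [0, 0.5)")
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1)
    cfg_error("ld_rho", "must lie in [0, 1)")
  for (f in c("pgs_r2_child", "pgs_r2_mother", "pgs_r2_father")) {
    v <- cfg[[f]]
    if (v < 0 || v >= 1) cfg_error(f, "variance fraction must lie in [0, 1)")
  }
  sc <- cfg$spousal_corr
  if (any(abs(sc) > 1)) cfg_error("spousal_corr", "entries must lie in [-1, 1]")
  joint <- rbind(cbind(diag(2), sc), cbind(t(sc), diag(2)))
  if (min(eigen(joint, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    cfg_error("spousal_corr", "implied joint mother/father correlation matrix is not positive semi-definite")
  # residual variances must stay positive once score, confounder and
  # stratification components are carved out of the unit phenotype variance
  strat_var_bmi <- pop_var(cfg$strat_shift_bmi)
  for (role in c("child", "mother", "father")) {
    r2 <- cfg[[paste0("pgs_r2_", role)]]
    resid <- 1 - r2 - cfg$confounder_sd^2 - strat_var_bmi
    if (resid <= 0)
      cfg_error(paste0("pgs_r2_", role),
                sprintf("implied residual BMI variance %.3f is not positive", resid))
  }
  resid_out <- 1 - cfg$confounder_sd_outcome^2 - pop_var(cfg$strat_shift_outcome)
  if (resid_out <= 0)
    cfg_error("confounder_sd_outcome",
              sprintf("implied residual outcome variance %.3f is not positive", resid_out))
  if (cfg$sibship_prob < 0 || cfg$sibship_prob > 1)
    cfg_error("sibship_prob", "must lie in [0, 1]")
  invisible(cfg)
}

# variance of a per-subpop shift over individuals (equal subpop sizes)
pop_var <- function(shifts) {
  if (length(shifts) <= 1) return(0)
  mean((shifts - mean(shifts))^2)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  families: %d  SNPs: %d  subpops: %d (Fst %.3g)\n",
              x$n_families, x$n_snps, x$n_subpops, x$fst))
  cat(sprintf("  PGS R2 (c/m/f): %.3f / %.3f / %.3f\n",
              x$pgs_r2_child, x$pgs_r2_mother, x$pgs_r2_father))
  cat(sprintf("  effects: beta_child=%.3g alpha_mother=%.3g alpha_father=%.3g theta_pleio=%.3g\n",
              x$beta_child, x$alpha_mother, x$alpha_father, x$theta_pleio))
  cat(sprintf("  spousal BMI target: %.3g   seed: %d\n",
              x$spousal_corr["bmi", "bmi"], x$seed))
  invisible(x)
}
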