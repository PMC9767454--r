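#' Generate trio phenotypes from true polygenic scores
#'
#' Builds BMI and outcome liabilities for every trio from a skeleton of true
#' scores. The structural model, per family role `i` in child/mother/father:
#'
#' standardized BMI_i = sqrt(r2_i) * G_i + shift_bmi\[subpop\] + c * C_fam + e_i
#'
#' where `G_i` is the true score scaled to unit within-subpopulation variance,
#' `C_fam` a standard-normal confounder shared by the whole family, and the
#' residual variance is chosen analytically so BMI has unit variance (on the
#' standardized scale) before rescaling to `bmi_mean`/`bmi_sd`. The child
#' outcome liability is
#'
#' y = beta_child * (sd_c/5) z_c + alpha_m * (sd_m/5) z_m + alpha_f * (sd_f/5) z_f +
#'     theta * G_c + shift_out\[subpop\] + c_out * C_fam + covariate effects + eps
#'
#' with `z_i` the standardized BMI values, so `beta_child` and the dynastic
#' effects are expressed as SD of outcome per 5 kg/m^2 of BMI, and the outcome
#' has unit variance under the all-null configuration. Sex and birth-year enter
#' with small fixed loadings (0.1 SD for male sex, 0.02 SD per year) so the
#' standard covariates are relevant but near-negligible.
#'
#' @param skeleton Data frame with one row per family: numeric `g_child`,
#'   `g_mother`, `g_father` (true scores, any scale) and optionally `subpop`,
#'   `confounder`, `cluster_id`.
#' @param config A [sim_config()].
#' @param seed Optional seed (`NULL` continues the current RNG stream).
#' @param items If `TRUE`, also generate ordinal questionnaire items per
#'   outcome scale (see `outcome_items` in [sim_config()]).
#' @return A tibble of families with role-prefixed phenotype columns (`bmi_*`,
#'   `height_*`, `weight_*`, `pgs_*`), covariates (`sex`, `birth_year`),
#'   parental `symptom_*` liabilities, the shared `confounder`, and one column
#'   per outcome.
#' @export
phenotype_model <- function(skeleton, config, seed = NULL, items = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(skeleton)
  s <- if ("subpop" %in% names(skeleton)) as.integer(skeleton$subpop) else rep(1L, n)
  cfam <- if ("confounder" %in% names(skeleton)) skeleton$confounder else rnorm(n)
  g <- list(child = std_score(skeleton$g_child, s),
            mother = std_score(skeleton$g_mother, s),
            father = std_score(skeleton$g_father, s))
  r2 <- c(child = config$pgs_r2_child, mother = config$pgs_r2_mother,
          father = config$pgs_r2_father)
  strat_var <- pop_var(config$strat_shift_bmi)
  z <- lapply(names(g), function(role) {
    resid_sd <- sqrt(1 - r2[[role]] - config$confounder_sd^2 - strat_var)
    sqrt(r2[[role]]) * g[[role]] + config$strat_shift_bmi[s] +
      config$confounder_sd * cfam + rnorm(n, sd = resid_sd)
  })
  names(z) <- names(g)
  fam <- tibble(
    family_id = seq_len(n),
    cluster_id = if ("cluster_id" %in% names(skeleton)) skeleton$cluster_id else seq_len(n),
    subpop = s,
    sex = factor(ifelse(runif(n) < 0.511, "male", "female"),
                 levels = c("female", "male")),
    birth_year = sample(1999:2009, n, replace = TRUE),
    confounder = cfam
  )
  hw <- list(child = c(1.30, 0.06), mother = c(1.67, 0.06), father = c(1.80, 0.07))
  for (role in names(z)) {
    bmi <- config$bmi_mean[[role]] + config$bmi_sd[[role]] * z[[role]]
    height <- rnorm(n, hw[[role]][1], hw[[role]][2])
    fam[[paste0("bmi_", role)]] <- bmi
    fam[[paste0("height_", role)]] <- height
    fam[[paste0("weight_", role)]] <- bmi * height^2
    fam[[paste0("pgs_", role)]] <- g[[role]]
  }
  fam$symptom_mother <- if ("symptom_mother" %in% names(skeleton))
    skeleton$symptom_mother else rnorm(n)
  fam$symptom_father <- if ("symptom_father" %in% names(skeleton))
    skeleton$symptom_father else rnorm(n)
  # parental-education analogue: an observable correlate of both the parental
  # score (genetic-nurture pathway) and the shared family environment, used by
  # the covariate-adjustment sensitivity analysis
  fam$edu_mother <- 0.4 * g$mother + 0.4 * cfam + rnorm(n, sd = sqrt(1 - 0.32))
  fam$edu_father <- 0.4 * g$father + 0.4 * cfam + rnorm(n, sd = sqrt(1 - 0.32))
  sex_eff <- 0.1; by_eff <- 0.02
  resid_out <- 1 - config$confounder_sd_outcome^2 -
    pop_var(config$strat_shift_outcome) -
    sex_eff^2 * 0.511 * (1 - 0.511) - by_eff^2 * 10
  if (resid_out <= 0) cfg_error("confounder_sd_outcome",
                                "implied residual outcome variance is not positive")
  struct <- config$beta_child * (config$bmi_sd[["child"]] / 5) * z$child +
    config$alpha_mother * (config$bmi_sd[["mother"]] / 5) * z$mother +
    config$alpha_father * (config$bmi_sd[["father"]] / 5) * z$father +
    config$theta_pleio * g$child +
    config$strat_shift_outcome[s] +
    config$confounder_sd_outcome * cfam +
    sex_eff * (as.integer(fam$sex == "male") - 0.511) +
    by_eff * (fam$birth_year - 2004)
  for (out in config$outcomes) {
    fam[[out]] <- struct + rnorm(n, sd = sqrt(resid_out))
    if (items) {
      spec <- config$outcome_items[[out]]
      if (!is.null(spec)) {
        it <- ordinal_items(fam[[out]], n_items = spec[1], n_cat = spec[2])
        colnames(it) <- sprintf("%s_item%02d", out, seq_len(ncol(it)))
        fam <- dplyr::bind_cols(fam, as_tibble(it))
      }
    }
  }
  fam
}

# standardize a score to unit pooled within-subpop variance, centered globally,
# preserving between-subpop mean differences (the stratification pathway)
std_score <- function(x, s) {
  if (length(unique(s)) == 1) return(as.numeric(scale(x)))
  wv <- tapply(x, s, var)
  wn <- tapply(x, s, length)
  sdw <- sqrt(sum(wv * (wn - 1)) / sum(wn - 1))
  (x - mean(x)) / sdw
}

# skewed ordinal items loading on a standardized liability; most respondents
# score 0, emulating symptom questionnaires
ordinal_items <- function(y, n_items, n_cat) {
  n <- length(y)
  tail_p <- 0.3 * 0.35^(seq_len(n_cat - 1) - 1) # P(item >= k), geometric decay
  cuts <- qnorm(1 - tail_p)
  lat <- 0.6 * matrix(y, n, n_items) + 0.8 * matrix(rnorm(n * n_items), n, n_items)
  it <- matrix(0L, n, n_items)
  for (k in seq_along(cuts)) it <- it + (lat > cuts[k])
  storage.mode(it) <- "integer"
  it
}

#' Simulate a mother-father-child trio cohort
#'
#' End-to-end forward simulation: founder scores (or genotypes), assortative
#' mate pairing, Mendelian transmission, and the phenotype model of
#' [phenotype_model()]. Two generative paths are available:
#'
#' * `genotypes = FALSE` (default): true polygenic scores are simulated
#'   directly — parental scores standard normal within subpopulation, the
#'   child's score the midparent mean plus segregation noise with half the
#'   population variance. Fast enough for cohorts of tens of thousands of
#'   families and many replicates.
#' * `genotypes = TRUE`: SNP dosages are simulated for founders
#'   (Balding-Nichols structure, copula LD) and transmitted to children; true
#'   scores are dosage-weighted sums with standard-normal per-SNP effects. The
#'   returned object then also carries the dosage matrices and SNP map used by
#'   the scoring functions ([clump()], [build_pgs()], [ancestry_pcs()]).
#'
#' The realized spousal BMI correlation targets `config$spousal_corr`: because
#' the shared family confounder is added to both parents' BMI after matching,
#' the copula target is internally deflated to `(target - c^2) / (1 - c^2)`.
#' A target below the confounder-induced floor `c^2` errors as infeasible.
#'
#' @param config A [sim_config()].
#' @param genotypes Simulate at SNP level? See above.
#' @param items Generate ordinal questionnaire items as well?
#' @return A `trio_cohort`: list with `families` (tibble, one row per trio),
#'   `config`, and for the genotype path `geno` (list of child/mother/father
#'   dosage matrices), `snps`, `subpop_freq` and `true_effects` (per-SNP score
#'   weights). `tidy()` returns the family tibble.
#' @examples
#' coh <- simulate_trios(sim_config(n_families = 300, seed = 1))
#' dplyr::glimpse(tidy(coh)[1:6])
#' @export
simulate_trios <- function(config, genotypes = FALSE, items = FALSE) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_families
  k <- config$n_subpops
  subpop <- rep_len(seq_len(k), n)

  geno <- snps <- true_eff <- subpop_freq <- NULL
  if (genotypes) {
    founders <- simulate_founders(config, seed = NULL)
    dm <- founders$dosages[seq_len(n), , drop = FALSE]
    df <- founders$dosages[n + seq_len(n), , drop = FALSE]
    subpop <- founders$subpop[seq_len(n)]
    true_eff <- rnorm(config$n_snps)
    gm <- drop(dm %*% true_eff)
    gf <- drop(df %*% true_eff)
    snps <- founders$snps
    subpop_freq <- founders$subpop_freq
  } else {
    gm <- rnorm(n) + config$strat_shift_score[subpop]
    gf <- rnorm(n) + config$strat_shift_score[subpop]
  }

  symptom_m <- rnorm(n)
  symptom_f <- rnorm(n)
  # pre-confounder parental BMI used for mate matching
  r2p <- c(mother = config$pgs_r2_mother, father = config$pgs_r2_father)
  strat_var <- pop_var(config$strat_shift_bmi)
  pre <- function(gs, role) {
    resid_sd <- sqrt(1 - r2p[[role]] - config$confounder_sd^2 - strat_var)
    sqrt(r2p[[role]]) * std_score(gs, subpop) + config$strat_shift_bmi[subpop] +
      rnorm(n, sd = resid_sd)
  }
  pre_m <- pre(gm, "mother")
  pre_f <- pre(gf, "father")
  tgt <- deflate_spousal_target(config$spousal_corr, config$confounder_sd)
  couples <- assortative_pairing(
    tibble(bmi = pre_m, symptom = symptom_m),
    tibble(bmi = pre_f, symptom = symptom_f),
    spousal_corr = tgt, seed = NULL, subpop = subpop)
  # reindex fathers so row i of every parental vector refers to couple i
  mo <- couples$mother; fa <- couples$father
  ord <- order(mo)
  mo <- mo[ord]; fa <- fa[ord]
  gf <- gf[fa]; symptom_f <- symptom_f[fa]; pre_f <- pre_f[fa]
  gm <- gm[mo]; symptom_m <- symptom_m[mo]; pre_m <- pre_m[mo]
  subpop <- subpop[mo]
  if (genotypes) { dm <- dm[mo, , drop = FALSE]; df <- df[fa, , drop = FALSE] }

  # sibships: some couples contribute a second trio sharing cluster_id
  cluster <- seq_len(n)
  if (config$sibship_prob > 0) {
    extra <- which(runif(n) < config$sibship_prob)
    idx <- c(seq_len(n), extra)
    cluster <- c(seq_len(n), extra)
    gm <- gm[idx]; gf <- gf[idx]; symptom_m <- symptom_m[idx]
    symptom_f <- symptom_f[idx]; pre_m <- pre_m[idx]; pre_f <- pre_f[idx]
    subpop <- subpop[idx]
    if (genotypes) { dm <- dm[idx, , drop = FALSE]; df <- df[idx, , drop = FALSE] }
  }
  nfam <- length(gm)
  cfam <- rnorm(n)[cluster] # shared within cluster (same couple, same home)

  if (genotypes) {
    dc <- transmit_genotypes(dm, df, seed = NULL)
    gc <- drop(dc %*% true_eff)
  } else {
    seg_sd <- sqrt(0.5) # half the (unit) within-subpop population score variance
    gc <- (gm + gf) / 2 + rnorm(nfam, sd = seg_sd)
  }

  skel <- tibble(g_child = gc, g_mother = gm, g_father = gf, subpop = subpop,
                 confounder = cfam, cluster_id = cluster,
                 symptom_mother = symptom_m, symptom_father = symptom_f)
  fam <- phenotype_model(skel, config, seed = NULL, items = FALSE)
  # overwrite the parental standardized-BMI columns so the matched pre-BMI
  # (which drove pairing) plus the shared confounder is what appears
  for (role in c("mother", "father")) {
    zr <- (if (role == "mother") pre_m else pre_f) + config$confounder_sd * cfam
    fam[[paste0("bmi_", role)]] <- config$bmi_mean[[role]] +
      config$bmi_sd[[role]] * zr
    fam[[paste0("weight_", role)]] <- fam[[paste0("bmi_", role)]] *
      fam[[paste0("height_", role)]]^2
  }
  # outcomes must reflect the (possibly re-matched) parental BMI
  fam <- rebuild_outcomes(fam, config, items = items)

  structure(list(families = fam, config = config, geno =
                   if (genotypes) list(child = dc, mother = dm, father = df),
                 snps = snps, true_effects = true_eff,
                 subpop_freq = subpop_freq),
            class = "trio_cohort")
}

# phenotype_model() simulates parental BMI afresh; after mate matching the
# parental BMI columns are replaced, so outcomes are regenerated from the
# final BMI values with the same structural coefficients
rebuild_outcomes <- function(fam, config, items = FALSE) {
  z <- lapply(c(child = "child", mother = "mother", father = "father"),
              function(role) (fam[[paste0("bmi_", role)]] -
                                config$bmi_mean[[role]]) / config$bmi_sd[[role]])
  sex_eff <- 0.1; by_eff <- 0.02
  resid_out <- 1 - config$confounder_sd_outcome^2 -
    pop_var(config$strat_shift_outcome) -
    sex_eff^2 * 0.511 * (1 - 0.511) - by_eff^2 * 10
  struct <- config$beta_child * (config$bmi_sd[["child"]] / 5) * z$child +
    config$alpha_mother * (config$bmi_sd[["mother"]] / 5) * z$mother +
    config$alpha_father * (config$bmi_sd[["father"]] / 5) * z$father +
    config$theta_pleio * fam$pgs_child +
    config$strat_shift_outcome[fam$subpop] +
    config$confounder_sd_outcome * fam$confounder +
    sex_eff * (as.integer(fam$sex == "male") - 0.511) +
    by_eff * (fam$birth_year - 2004)
  n <- nrow(fam)
  for (out in config$outcomes) {
    fam[[out]] <- struct + rnorm(n, sd = sqrt(resid_out))
    if (items) {
      spec <- config$outcome_items[[out]]
      if (!is.null(spec)) {
        it <- ordinal_items(fam[[out]], n_items = spec[1], n_cat = spec[2])
        cn <- sprintf("%s_item%02d", out, seq_len(ncol(it)))
        fam[cn] <- as_tibble(it, .name_repair = ~cn)
      }
    }
  }
  fam
}

deflate_spousal_target <- function(tgt, c_bmi) {
  if (c_bmi == 0) return(tgt)
  c2 <- c_bmi^2
  if (tgt["bmi", "bmi"] < c2 - 1e-12)
    abort(sprintf(
      "spousal BMI correlation target %.3f is infeasible: the shared family confounder alone induces %.3f",
      tgt["bmi", "bmi"], c2))
  out <- tgt
  out["bmi", "bmi"] <- (tgt["bmi", "bmi"] - c2) / (1 - c2)
  out["bmi", "symptom"] <- tgt["bmi", "symptom"] / sqrt(1 - c2)
  out["symptom", "bmi"] <- tgt["symptom", "bmi"] / sqrt(1 - c2)
  out
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf("<trio_cohort> %d trios, %d subpopulation(s)%s\n",
              nrow(x$families), length(unique(x$families$subpop)),
              if (!is.null(x$geno)) sprintf(", %d SNPs", ncol(x$geno$child)) else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.trio_cohort <- function(x, ...) x$families

#' @exportS3Method tibble::as_tibble
as_tibble.trio_cohort <- function(x, ...) x$families
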