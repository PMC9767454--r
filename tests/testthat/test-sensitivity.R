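test_that("IVW matches the closed-form weighted mean on a worked table", {
  s <- tibble::tibble(snp_id = c("a", "b"), beta_exp = c(1, 1),
                      se_exp = 0.01, beta_out = c(0.5, 1.0),
                      se_out = c(0.1, 0.2))
  fe <- ivw(s, random_effects = "never")
  expect_equal(fe$beta, 0.6, tolerance = 1e-12) # (100*0.5 + 25*1) / 125
  expect_equal(fe$se, 1 / sqrt(125), tolerance = 1e-12)
  expect_equal(fe$Q, 100 * 0.01 + 25 * 0.16, tolerance = 1e-12)
  re <- ivw(s)
  expect_equal(re$se, fe$se * sqrt(fe$Q / 1), tolerance = 1e-12)
})

test_that("exactly proportional summaries give the slope with zero heterogeneity", {
  s <- make_summaries(20, slope = 0.3, se_out = 1e-9, se_exp = 1e-9)
  s$beta_out <- 0.3 * s$beta_exp # exact proportionality
  out <- ivw(s)
  expect_equal(out$beta, 0.3, tolerance = 1e-9)
  expect_lt(out$Q, 1e-6)
})

test_that("Egger equals the hand-computed weighted least squares", {
  s <- tibble::tibble(snp_id = c("a", "b", "c"),
                      beta_exp = c(0.02, 0.04, 0.06), se_exp = 0.001,
                      beta_out = c(0.010, 0.014, 0.026),
                      se_out = c(0.004, 0.005, 0.008))
  e <- egger(s)
  # normal-equations oracle via base weighted lm
  or <- lm(beta_out ~ beta_exp, data = s, weights = 1 / s$se_out^2)
  expect_equal(e$beta[e$term == "slope"], unname(coef(or)[2]),
               tolerance = 1e-10)
  expect_equal(e$beta[e$term == "intercept"], unname(coef(or)[1]),
               tolerance = 1e-10)
  expect_error(egger(s[1:2, ]), "at least 3")
})

test_that("constraining the Egger intercept to zero reproduces IVW exactly", {
  s <- make_summaries(30, slope = 0.25, pleio_sd = 0.005, seed = 3)
  or <- lm(beta_out ~ 0 + beta_exp, data = s, weights = 1 / s$se_out^2)
  expect_equal(ivw(s)$beta, unname(coef(or)), tolerance = 1e-12)
})

test_that("summary estimators recover the true slope absent pleiotropy", {
  betas <- sapply(1:20, function(s) {
    su <- make_summaries(100, slope = 0.3, seed = 200 + s)
    c(ivw(su)$beta, egger(su)$beta[1],
      weighted_median(su, n_boot = 10)$beta,
      mode_based(su, n_boot = 10)$beta)
  })
  means <- rowMeans(betas)
  expect_equal(means, rep(0.3, 4), tolerance = 0.1, ignore_attr = TRUE)
})

test_that("the weighted median has its breakdown and degeneracy properties", {
  s <- tibble::tibble(snp_id = letters[1:3], beta_exp = 1, se_exp = 0.001,
                      beta_out = c(0.2, 0.5, 0.9), se_out = 1)
  expect_equal(weighted_median(s, n_boot = 10)$beta, 0.5)
  # weights concentrating on one SNP pull the median to its ratio
  s2 <- s; s2$se_out <- c(1e-6, 1, 1)
  expect_equal(weighted_median(s2, n_boot = 10)$beta, 0.2, tolerance = 1e-3)
  # 49% invalid SNPs (equal weights) with shifted ratios: the weighted
  # median stays at the valid cluster (50% weight breakdown)
  est <- sapply(1:10, function(r) {
    set.seed(300 + r)
    su <- tibble::tibble(snp_id = sprintf("s%d", 1:100), beta_exp = 0.03,
                         se_exp = 1e-4,
                         beta_out = 0.3 * 0.03 + rnorm(100, 0, 5e-4),
                         se_out = 5e-4)
    bad <- seq_len(49)
    su$beta_out[bad] <- su$beta_out[bad] + 0.5 * su$beta_exp[bad]
    weighted_median(su, n_boot = 10)$beta
  })
  expect_lt(abs(mean(est) - 0.3), 0.15)
  # order invariance and zero-weight duplication invariance
  su <- make_summaries(20, slope = 0.3, seed = 310)
  a <- weighted_median(su, n_boot = 10, seed = 2)$beta
  b <- weighted_median(su[sample.int(20), ], n_boot = 10, seed = 2)$beta
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("the mode-based estimate finds the majority cluster", {
  s <- tibble::tibble(snp_id = letters[1:3], beta_exp = 1, se_exp = 0.001,
                      beta_out = rep(0.4, 3), se_out = 0.05)
  expect_equal(mode_based(s, n_boot = 10)$beta, 0.4, tolerance = 1e-6)
  set.seed(61)
  k <- 30
  s2 <- tibble::tibble(snp_id = sprintf("s%d", 1:k), beta_exp = 1,
                       se_exp = 0.001,
                       beta_out = c(rnorm(20, 0.3, 0.01), rnorm(10, 1.0, 0.01)),
                       se_out = 0.02)
  expect_equal(mode_based(s2, n_boot = 10)$beta, 0.3, tolerance = 0.05)
  # infinite-bandwidth limit tends to the weighted mean
  wm <- weighted.mean(s2$beta_out, 1 / s2$se_out^2)
  expect_equal(mode_based(s2, bandwidth_factor = 1e4, n_boot = 10)$beta, wm,
               tolerance = 0.02)
  expect_error(mode_based(s2, bandwidth_factor = 0), "positive")
})

test_that("per-SNP outcome associations recover generative effects", {
  cfg <- sim_config(n_families = 1500, n_snps = 12, seed = 62,
                    maf_range = c(0.3, 0.5))
  coh <- simulate_trios(cfg, genotypes = TRUE)
  fam <- coh$families
  set.seed(63)
  fam$y_direct <- 0.1 * as.numeric(coh$geno$child[, 1]) + rnorm(nrow(fam), 0, 0.3)
  fam$y_dynastic <- 0.2 * as.numeric(coh$geno$mother[, 2]) + rnorm(nrow(fam), 0, 0.3)
  coh$families <- fam
  direct <- snp_outcome_assoc(coh, "y_direct", transform = "identity")
  expect_lt(abs(direct$beta_out[1] - 0.1), 0.04)
  # a SNP acting only through the mother: association in the child vanishes
  # once parental genotype is adjusted for
  unadj <- snp_outcome_assoc(coh, "y_dynastic", transform = "identity")
  adj <- snp_outcome_assoc(coh, "y_dynastic", transform = "identity",
                           adjust_parental = TRUE)
  expect_gt(unadj$beta_out[2], 0.05) # transmitted correlation ~ 0.1
  expect_lt(abs(adj$beta_out[2]), 0.06)
  expect_gt(unadj$beta_out[2] - adj$beta_out[2], 0.04)
})

test_that("harmonization flips orientation and summaries round-trip to disk", {
  s <- make_summaries(10, slope = 0.3, seed = 64)
  s$beta_exp[1] <- -s$beta_exp[1]; s$beta_out[1] <- -s$beta_out[1]
  h <- triomr:::harmonize_summaries(s)
  expect_true(all(h$beta_exp > 0))
  expect_equal(ivw(h)$beta, ivw(s)$beta, tolerance = 1e-12)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_snp_summaries(s, path)
  back <- read_snp_summaries(path)
  expect_equal(back$beta_out, s$beta_out)
})

test_that("spousal regressions recover configured assortment", {
  fam <- quick_cohort(20000, seed = 65)
  grid <- assortment_diagnostics(fam)
  bmi_row <- grid[grid$mother_trait == "bmi" & grid$father_trait == "bmi", ]
  expect_lt(abs(bmi_row$beta - 0.23), 0.025)
  # random mating: everything near zero
  fam0 <- tidy(simulate_trios(null_config(10000, seed = 66)))
  grid0 <- assortment_diagnostics(fam0)
  expect_true(all(abs(grid0$beta) < 0.05))
  # cross-trait target appears on the off-diagonal
  cfg <- sim_config(n_families = 20000, seed = 67,
                    spousal_corr = matrix(c(0, 0, 0.3, 0), 2, 2),
                    confounder_sd = 0)
  famx <- tidy(simulate_trios(cfg))
  gx <- assortment_diagnostics(famx)
  off <- gx[gx$mother_trait == "bmi" & gx$father_trait == "symptom", ]
  expect_lt(abs(off$beta - 0.3), 0.04)
  expect_error(assortment_diagnostics(fam[, 1:3]), "missing parent")
})
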