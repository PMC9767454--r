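test_that("an exact linear relation is fitted with zero standard error", {
  d <- data.frame(x = 1:10, y = 2 * (1:10))
  f <- fit_ols(d, "y", "x", transform = "identity", exposure_scale = 1)
  expect_equal(tidy(f)$beta, 2, tolerance = 1e-10)
  expect_equal(tidy(f)$se, 0, tolerance = 1e-8)
})

test_that("coefficients match the normal-equations closed form on a toy table", {
  d <- data.frame(x = c(0, 1, 2, 3, 4, 5), w = c(1, 0, 1, 1, 0, 1),
                  y = c(1.2, 0.7, 2.9, 3.1, 3.9, 5.6))
  f <- fit_ols(d, "y", c("x", "w"), transform = "identity",
               exposure_scale = 1)
  X <- cbind(x = d$x, w = d$w, `(Intercept)` = 1)
  oracle <- solve(crossprod(X), crossprod(X, d$y)) # hand normal equations
  expect_equal(tidy(f)$beta, oracle[c("x", "w"), 1], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("robust and cluster-robust covariances agree with the sandwich package", {
  set.seed(51)
  n <- 400
  d <- data.frame(x = rnorm(n), g = sample(40, n, TRUE))
  d$y <- 0.5 * d$x + rnorm(n) * (1 + abs(d$x)) + rnorm(40)[d$g]
  f <- fit_ols(d, "y", "x", transform = "identity", exposure_scale = 1)
  lmfit <- lm(y ~ x, d)
  expect_equal(tidy(f)$se, sqrt(sandwich::vcovHC(lmfit, "HC1")["x", "x"]),
               tolerance = 1e-8)
  fc <- fit_ols(d, "y", "x", cluster = "g", transform = "identity",
                exposure_scale = 1)
  expect_equal(tidy(fc)$se,
               sqrt(sandwich::vcovCL(lmfit, cluster = d$g, type = "HC1",
                                     cadjust = TRUE)["x", "x"]),
               tolerance = 1e-6)
})

test_that("robust and classical errors agree on homoskedastic data", {
  set.seed(52)
  n <- 10000
  d <- data.frame(x = rnorm(n))
  d$y <- 0.3 * d$x + rnorm(n)
  fr <- fit_ols(d, "y", "x", transform = "identity", exposure_scale = 1)
  fcl <- fit_ols(d, "y", "x", transform = "identity", exposure_scale = 1,
                 se_type = "classical")
  expect_equal(tidy(fr)$se, tidy(fcl)$se, tolerance = 0.05)
})

test_that("cluster-robust errors exceed unclustered ones under shared noise", {
  wins <- sapply(1:10, function(s) {
    cfg <- sim_config(n_families = 1500, seed = 6000 + s,
                      sibship_prob = 0.5, confounder_sd_outcome = 0.45)
    fam <- tidy(simulate_trios(cfg))
    # maternal BMI is identical across siblings, so both the regressor and
    # the confounder-driven outcome noise are shared within cluster
    a <- tidy(fit_ols(fam, "dep", "bmi_mother", cluster = "cluster_id"))$se
    b <- tidy(fit_ols(fam, "dep", "bmi_mother"))$se
    a > b
  })
  expect_gt(mean(wins), 0.7)
})

test_that("rank-deficient designs error naming the collinear column", {
  d <- data.frame(x = 1:8, x2 = 2 * (1:8), y = rnorm(8))
  expect_error(fit_ols(d, "y", c("x", "x2"), transform = "identity"),
               "collinear.*x2")
})

test_that("complete-case handling drops and reports missing rows", {
  d <- data.frame(x = c(1:9, NA), y = c(NA, rnorm(9)))
  expect_message(f <- fit_ols(d, "y", "x", transform = "identity",
                              exposure_scale = 1), "dropping 2 of 10")
  expect_equal(f$n, 8)
  expect_equal(f$n_dropped, 2)
})

test_that("2SLS equals the Wald covariance ratio when just-identified", {
  d <- data.frame(z = c(-1, 0, 1), x = c(0, 1, 2), y = c(1, 2, 3))
  f <- fit_2sls(d, "y", "x", "z", transform = "identity", exposure_scale = 1)
  expect_equal(tidy(f)$beta, 1, tolerance = 1e-12)
  d2 <- data.frame(z = 0:3, x = c(1, 1, 2, 4), y = c(2, 1, 4, 6))
  f2 <- fit_2sls(d2, "y", "x", "z", transform = "identity",
                 exposure_scale = 1)
  expect_equal(tidy(f2)$beta, 1.5, tolerance = 1e-12) # 1.875 / 1.25
  # property: equality with cov(z,y)/cov(z,x) on random instances
  for (s in 1:10) {
    set.seed(s)
    n <- 60
    dr <- data.frame(z = rnorm(n))
    dr$x <- 0.6 * dr$z + rnorm(n)
    dr$y <- 0.8 * dr$x + rnorm(n)
    fr <- fit_2sls(dr, "y", "x", "z", transform = "identity",
                   exposure_scale = 1)
    expect_equal(tidy(fr)$beta, cov(dr$z, dr$y) / cov(dr$z, dr$x),
                 tolerance = 1e-10)
  }
})

test_that("under-identified specifications error", {
  d <- data.frame(z = rnorm(10), x1 = rnorm(10), x2 = rnorm(10), y = rnorm(10))
  expect_error(fit_2sls(d, "y", c("x1", "x2"), "z", transform = "identity"),
               "identification")
  expect_error(within_family_mr(d, "y", exposures = c("x1", "x2"),
                                instruments = c("z", "z")),
               "exactly three")
})

test_that("a near-irrelevant instrument triggers the weak-instrument warning", {
  set.seed(53)
  n <- 300
  x <- rnorm(n)
  # sample-orthogonalized plus a sliver of signal: first-stage F far below 1
  z <- residuals(lm(rnorm(n) ~ x)) + 1e-3 * x
  d <- data.frame(x = x, z = z, y = rnorm(n))
  expect_warning(fit_2sls(d, "y", "x", "z", transform = "identity",
                          exposure_scale = 1), "weak instruments")
})

test_that("conditional F satisfies the F-R2 identity in the classic design", {
  set.seed(54)
  n <- 2000
  d <- data.frame(z = rnorm(n))
  d$x <- 0.4 * d$z + rnorm(n)
  cf <- conditional_first_stage(d, "x", "z")
  r2 <- summary(lm(x ~ z, d))$r.squared
  expect_equal(cf$cond_R2, r2, tolerance = 1e-10)
  expect_equal(cf$cond_F, r2 / (1 - r2) * (n - 2), tolerance = 1e-8)
})

test_that("conditioning on parents halves the usable child instrument variance", {
  fam <- tidy(simulate_trios(null_config(30000, seed = 55)))
  marg <- conditional_first_stage(fam, "bmi_child", "pgs_child")
  cond <- conditional_first_stage(fam,
                                  c("bmi_child", "bmi_mother", "bmi_father"),
                                  c("pgs_child", "pgs_mother", "pgs_father"))
  child <- cond$cond_R2[cond$term == "bmi_child"]
  expect_equal(child / marg$cond_R2, 0.5, tolerance = 0.15)
})

test_that("estimator builders label and structure their records", {
  fam <- quick_cohort(2000, seed = 56)
  a <- classic_mr(fam, "dep", covariates = c("sex", "birth_year"),
                  cluster = "cluster_id")
  expect_equal(tidy(a)$estimator, "classic_mr")
  expect_equal(tidy(a)$term, "bmi_child")
  b <- within_family_mr(fam, "dep")
  tb <- tidy(b)
  expect_equal(tb$term, c("bmi_child", "bmi_mother", "bmi_father"))
  expect_true(all(tb$estimator == "within_family_mr"))
  # CI arithmetic and p-value consistency invariants
  expect_equal(tb$ci_low, tb$beta - qnorm(0.975) * tb$se)
  expect_equal(tb$p, 2 * pnorm(-abs(tb$beta / tb$se)))
  expect_equal(glance(b)$n, nrow(fam))
})

test_that("log1p transform standardizes the transformed outcome", {
  set.seed(57)
  d <- data.frame(x = rnorm(500), y = rpois(500, 3))
  f <- fit_2sls(d, "y", "x", "x", transform = "log1p", exposure_scale = 1)
  ylog <- scale(log1p(d$y))
  oracle <- cov(d$x, ylog) / var(d$x)
  expect_equal(tidy(f)$beta, drop(oracle), tolerance = 1e-10)
})
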