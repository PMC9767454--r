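#' @title Least-squares core with robust sandwich covariance
#' @description Internal engine shared by [fit_ols()] and [fit_2sls()].
#'   Coefficients by (instrumented) least squares; covariance by the
#'   heteroskedasticity-robust sandwich with an HC1-style degrees-of-freedom
#'   correction `n/(n-p)`, or the cluster-robust sandwich with the CR1-style
#'   correction `G/(G-1) * (n-1)/(n-p)` when a cluster variable is supplied.
#'   For 2SLS the residuals entering the meat are structural (`y - X b` with
#'   the observed exposures, not second-stage fitted values).
#' @noRd
ls_core <- function(X, y, Z = NULL, cluster = NULL,
                    se_type = c("robust", "classical")) {
  se_type <- match.arg(se_type)
  n <- nrow(X); p <- ncol(X)
  if (!is.null(Z)) {
    if (ncol(Z) < p)
      abort("identification error: fewer instruments (plus covariates) than regressors")
    qz <- qr(Z)
    Xh <- qr.fitted(qz, X)
  } else Xh <- X
  qx <- qr(Xh)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    abort(sprintf("rank-deficient design: collinear column(s) %s",
                  paste(bad, collapse = ", ")))
  }
  b <- qr.coef(qx, y)
  e <- drop(y - X %*% b)
  XtXinv <- chol2inv(chol(crossprod(Xh)))
  if (se_type == "classical") {
    V <- XtXinv * sum(e^2) / (n - p)
  } else {
    u <- Xh * e
    if (!is.null(cluster)) {
      u <- rowsum(u, cluster)
      g <- nrow(u)
      adj <- g / (g - 1) * (n - 1) / (n - p)
    } else {
      adj <- n / (n - p)
    }
    V <- XtXinv %*% crossprod(u) %*% XtXinv * adj
  }
  dimnames(V) <- list(colnames(X), colnames(X))
  list(coef = setNames(drop(b), colnames(X)), vcov = V, residuals = e,
       n = n, p = p, fitted_exposures = if (!is.null(Z)) Xh)
}

# build a numeric design matrix (with intercept) from column names; factors
# expand to treatment contrasts
build_design <- function(data, vars) {
  if (!length(vars)) return(matrix(1, nrow(data), 1,
                                   dimnames = list(NULL, "(Intercept)")))
  model.matrix(stats::reformulate(vars), data = data)
}

prepare_model_frame <- function(data, outcome, exposures, instruments = NULL,
                                covariates = NULL, cluster = NULL,
                                transform = "standardize",
                                exposure_scale = 5) {
  vars <- unique(c(outcome, exposures, instruments, covariates, cluster))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    abort(sprintf("column(s) not found: %s", paste(missing_cols, collapse = ", ")))
  ok <- complete.cases(data[vars])
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    inform(sprintf("dropping %d of %d rows with missing model variables (complete-case analysis)",
                   n_dropped, nrow(data)))
  d <- data[ok, vars, drop = FALSE]
  y <- d[[outcome]]
  if (transform == "log1p") {
    if (any(y < -1)) abort("log1p transform requires outcome >= -1")
    y <- log1p(y)
  }
  if (transform %in% c("standardize", "log1p")) y <- (y - mean(y)) / sd(y)
  for (v in exposures) d[[v]] <- d[[v]] / exposure_scale
  list(data = d, y = y, n_dropped = n_dropped)
}

estimates_table <- function(fit, exposures, estimator, n_dropped,
                            scale_label, diagnostics = NULL) {
  se <- sqrt(diag(fit$vcov))
  tb <- tibble(
    term = exposures,
    beta = unname(fit$coef[exposures]),
    se = unname(se[exposures])
  ) |>
    dplyr::mutate(
      ci_low = .data$beta - qnorm(0.975) * .data$se,
      ci_high = .data$beta + qnorm(0.975) * .data$se,
      p = 2 * pnorm(-abs(.data$beta / .data$se)),
      estimator = estimator, n = fit$n, scale = scale_label
    )
  if (!is.null(diagnostics)) {
    tb <- dplyr::left_join(tb, diagnostics, by = "term")
  } else {
    tb$cond_F <- NA_real_; tb$cond_R2 <- NA_real_
  }
  tb
}

new_mr_fit <- function(estimates, fit, estimator, n_dropped, spec) {
  structure(list(estimates = estimates, coef = fit$coef, vcov = fit$vcov,
                 n = fit$n, n_dropped = n_dropped, estimator = estimator,
                 spec = spec),
            class = "mr_fit")
}

#' Ordinary least squares with robust or cluster-robust standard errors
#'
#' Non-genetic regression of a (standardized, optionally log1p-transformed)
#' outcome on BMI exposures scaled per `exposure_scale` kg/m^2, plus
#' covariates. Coefficients are computed from scratch by least squares;
#' standard errors are heteroskedasticity-robust (HC1-style) or, when
#' `cluster` is given, cluster-robust (CR1-style). Rows with missing model
#' variables are dropped with a message (complete-case analysis).
#'
#' @param data Cohort family tibble.
#' @param outcome Name of the outcome column.
#' @param exposures Character vector of exposure columns (BMI terms); each is
#'   divided by `exposure_scale` so coefficients read SD of outcome per
#'   `exposure_scale` kg/m^2.
#' @param covariates Optional covariate columns (factors allowed).
#' @param cluster Optional cluster-id column for cluster-robust errors.
#' @param transform Outcome transform: `"standardize"` (default), `"log1p"`
#'   (log(score+1) then standardize), or `"identity"`.
#' @param exposure_scale Exposure unit in kg/m^2 (default 5).
#' @param se_type `"robust"` (default) or `"classical"`.
#' @return An `mr_fit`; `tidy()` gives one row per exposure with `beta`, `se`,
#'   normal-theory 95% `ci_low`/`ci_high` and two-sided `p`.
#' @examples
#' coh <- simulate_trios(sim_config(n_families = 500, beta_child = 0.3, seed = 1))
#' tidy(fit_ols(tidy(coh), "dep", "bmi_child", covariates = c("sex", "birth_year")))
#' @export
fit_ols <- function(data, outcome, exposures, covariates = NULL, cluster = NULL,
                    transform = c("standardize", "log1p", "identity"),
                    exposure_scale = 5, se_type = c("robust", "classical")) {
  transform <- match.arg(transform); se_type <- match.arg(se_type)
  mf <- prepare_model_frame(data, outcome, exposures, NULL, covariates,
                            cluster, transform, exposure_scale)
  X <- build_design(mf$data, c(exposures, covariates))
  fit <- ls_core(X, mf$y, cluster = if (!is.null(cluster)) mf$data[[cluster]],
                 se_type = se_type)
  exp_terms <- intersect(colnames(X), exposures)
  est <- estimates_table(fit, exp_terms, "ols", mf$n_dropped,
                         scale_label = sprintf("per%g", exposure_scale))
  est$transform <- transform
  new_mr_fit(est, fit, "ols", mf$n_dropped,
             list(outcome = outcome, exposures = exposures,
                  covariates = covariates, cluster = cluster,
                  transform = transform, exposure_scale = exposure_scale))
}

#' Two-stage least squares instrumental-variable regression
#'
#' From-scratch 2SLS: exposures are projected on the instruments plus
#' covariates, coefficients come from the projected design, and the sandwich
#' covariance uses structural residuals (`y - X b` with observed exposures).
#' Covariates are partialled by inclusion in both stages. Conditional
#' first-stage diagnostics (Sanderson-Windmeijer-style F and incremental R^2
#' per exposure) are computed and attached; a conditional F below 1 triggers a
#' weak-instrument warning.
#'
#' @inheritParams fit_ols
#' @param instruments Character vector of instrument columns; at least as many
#'   instruments as exposures (both study designs here are just-identified).
#' @param estimator Label stored on the estimate rows (`"classic_mr"` or
#'   `"within_family_mr"` when called through the convenience builders).
#' @return An `mr_fit` with `cond_F` and `cond_R2` per exposure.
#' @examples
#' d <- data.frame(z = c(0, 1, 2, 3), x = c(1, 1, 2, 4), y = c(2, 1, 4, 6))
#' tidy(fit_2sls(d, "y", "x", "z", transform = "identity", exposure_scale = 1))
#' @export
fit_2sls <- function(data, outcome, exposures, instruments, covariates = NULL,
                     cluster = NULL,
                     transform = c("standardize", "log1p", "identity"),
                     exposure_scale = 5, estimator = "2sls",
                     se_type = c("robust", "classical")) {
  transform <- match.arg(transform); se_type <- match.arg(se_type)
  if (length(instruments) < length(exposures))
    abort(sprintf("identification error: %d instrument(s) for %d exposure(s)",
                  length(instruments), length(exposures)))
  mf <- prepare_model_frame(data, outcome, exposures, instruments, covariates,
                            cluster, transform, exposure_scale)
  X <- build_design(mf$data, c(exposures, covariates))
  Z <- build_design(mf$data, c(instruments, covariates))
  cl <- if (!is.null(cluster)) mf$data[[cluster]]
  fit <- ls_core(X, mf$y, Z = Z, cluster = cl, se_type = se_type)
  diag_tb <- conditional_first_stage_(mf$data, exposures, instruments,
                                      covariates)
  if (any(diag_tb$cond_F < 1, na.rm = TRUE))
    warn(sprintf("weak instruments: conditional F below 1 for %s",
                 paste(diag_tb$term[diag_tb$cond_F < 1], collapse = ", ")))
  est <- estimates_table(fit, exposures, estimator, mf$n_dropped,
                         scale_label = sprintf("per%g", exposure_scale),
                         diagnostics = diag_tb)
  est$transform <- transform
  new_mr_fit(est, fit, estimator, mf$n_dropped,
             list(outcome = outcome, exposures = exposures,
                  instruments = instruments, covariates = covariates,
                  cluster = cluster, transform = transform,
                  exposure_scale = exposure_scale))
}

#' Conditional first-stage instrument-strength diagnostics
#'
#' For each exposure in a multivariable IV model, residualize it on the other
#' exposures' instrument-predicted values and the covariates, then regress the
#' residual on the instruments (covariates included in every stage). Reported
#' per exposure: the conditional F (numerator degrees of freedom
#' `k_instruments - k_exposures + 1`, Sanderson-Windmeijer-style) and the
#' incremental (partial) R^2 of the instruments in that residual regression.
#' With a single exposure this reduces to the ordinary first-stage F, which
#' satisfies the textbook identity `F = R2/(1-R2) * (n - p - 1)` with `p` the
#' number of non-intercept regressors.
#'
#' @inheritParams fit_2sls
#' @return A tibble with columns `term`, `cond_F`, `cond_R2`.
#' @export
conditional_first_stage <- function(data, exposures, instruments,
                                    covariates = NULL) {
  vars <- unique(c(exposures, instruments, covariates))
  d <- data[complete.cases(data[vars]), vars, drop = FALSE]
  conditional_first_stage_(d, exposures, instruments, covariates)
}

conditional_first_stage_ <- function(d, exposures, instruments, covariates) {
  Z <- build_design(d, c(instruments, covariates))
  W <- build_design(d, covariates)
  qz <- qr(Z); qw <- qr(W)
  Xmat <- as.matrix(d[exposures])
  Xhat <- qr.fitted(qz, Xmat)
  n <- nrow(d); kz <- length(instruments); kx <- length(exposures)
  res <- lapply(seq_along(exposures), function(j) {
    if (kx > 1) {
      A <- cbind(Xhat[, -j, drop = FALSE], W)
      qa <- qr(A)
      r <- qr.resid(qa, Xmat[, j])
    } else {
      r <- Xmat[, j]
    }
    rss1 <- sum(qr.resid(qz, r)^2)
    rss0 <- sum(qr.resid(qw, r)^2)
    df1 <- kz - kx + 1
    df2 <- n - ncol(Z) - if (kx > 1) (kx - 1) else 0
    if (rss0 <= .Machine$double.eps * sum(r^2))
      abort(sprintf("degenerate residual variance for exposure %s", exposures[j]))
    # a perfectly predicted exposure (rss1 = 0) yields an infinite F
    tibble(term = exposures[j],
           cond_F = ((rss0 - rss1) / df1) / (rss1 / df2),
           cond_R2 = (rss0 - rss1) / rss0)
  })
  dplyr::bind_rows(res)
}

#' Classic Mendelian randomization (child instrument only)
#'
#' Convenience builder: 2SLS of the child's outcome on the child's BMI,
#' instrumented by the child's polygenic score alone, without conditioning on
#' parental genotype — the design whose estimates are vulnerable to population
#' stratification, dynastic effects, and assortative mating.
#'
#' @inheritParams fit_2sls
#' @param exposure,instrument Single column names (defaults `bmi_child`,
#'   `pgs_child`).
#' @export
classic_mr <- function(data, outcome, exposure = "bmi_child",
                       instrument = "pgs_child", covariates = NULL,
                       cluster = NULL, transform = "standardize",
                       exposure_scale = 5) {
  fit_2sls(data, outcome, exposure, instrument, covariates, cluster,
           transform, exposure_scale, estimator = "classic_mr")
}

#' Within-family Mendelian randomization (trio instruments)
#'
#' Multivariable 2SLS in which the polygenic scores of all members of a
#' mother-father-child trio instrument the BMI of all three individuals.
#' Conditioning on parental genotype makes the child-BMI estimate robust to
#' population stratification, dynastic effects, and parental assortative
#' mating; the maternal and paternal terms capture dynastic pathways but can
#' still carry biases from earlier generations.
#'
#' @inheritParams fit_2sls
#' @param exposures,instruments Three columns each, child/mother/father order
#'   (defaults `bmi_*` and `pgs_*`).
#' @return An `mr_fit` with three labelled exposure records.
#' @export
within_family_mr <- function(data, outcome,
                             exposures = c("bmi_child", "bmi_mother", "bmi_father"),
                             instruments = c("pgs_child", "pgs_mother", "pgs_father"),
                             covariates = NULL, cluster = NULL,
                             transform = "standardize", exposure_scale = 5) {
  if (length(exposures) != 3 || length(instruments) != 3)
    abort("within-family specification needs exactly three exposures and three instruments")
  fit_2sls(data, outcome, exposures, instruments, covariates, cluster,
           transform, exposure_scale, estimator = "within_family_mr")
}
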