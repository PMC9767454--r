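#' Construct an estimate record from a point estimate and 95% CI
#'
#' Builds a one-row estimate tibble from a published-style `beta (ci_low,
#' ci_high)` triple, recovering the standard error from the normal-theory CI
#' width: `se = (ci_high - ci_low) / (2 * 1.96)`. Useful for comparing against
#' printed results, e.g. with [z_difference()].
#'
#' @param beta Point estimate.
#' @param ci_low,ci_high 95% confidence limits.
#' @param term,estimator Optional labels.
#' @return A one-row tibble with `term`, `beta`, `se`, `ci_low`, `ci_high`,
#'   `p`, `estimator`.
#' @examples
#' estimate_record(0.45, 0.26, 0.64, estimator = "classic_mr")
#' @export
estimate_record <- function(beta, ci_low, ci_high, term = "bmi_child",
                            estimator = NA_character_) {
  se <- (ci_high - ci_low) / (2 * qnorm(0.975))
  tibble(term = term, beta = beta, se = se, ci_low = ci_low, ci_high = ci_high,
         p = 2 * pnorm(-abs(beta / se)), estimator = estimator)
}

#' Z test of difference between two estimates
#'
#' Formal comparison of two coefficient estimates (e.g. classic versus
#' within-family MR for the same term and outcome):
#' `z = (beta_a - beta_b) / sqrt(se_a^2 + se_b^2)` with a two-sided normal
#' p-value. The two estimates are treated as independent; since both designs
#' typically use the same data the estimates are correlated and the p-value is
#' approximate (conservative or anticonservative depending on the sign of the
#' correlation).
#'
#' @param a,b One-row estimate tibbles with `beta` and `se` (from `tidy()` of
#'   an [fit_2sls()] fit, or [estimate_record()]).
#' @return A tibble with columns `z` and `p`.
#' @examples
#' z_difference(estimate_record(0.45, 0.26, 0.64),
#'               estimate_record(0.26, -0.01, 0.52))
#' @export
z_difference <- function(a, b) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  v <- a$se^2 + b$se^2
  if (v <= 0) abort("zero combined variance: cannot form a z statistic")
  z <- (a$beta - b$beta) / sqrt(v)
  tibble(z = z, p = 2 * pnorm(-abs(z)))
}

#' Rescale effect estimates between BMI unit conventions
#'
#' Converts estimate rows among three scalings of the BMI exposure: per
#' 5 kg/m^2 (`"per5"`), per 1 kg/m^2 (`"per1"`), and per SD of BMI
#' (`"per_sd"`, requiring `bmi_sd`). `beta`, `se` and the confidence limits
#' all scale by the same multiplicative factor; `p` is unchanged.
#'
#' @param record Estimate tibble with columns `beta`, `se`, `ci_low`,
#'   `ci_high` and a `scale` column (as produced by `tidy()` on an `mr_fit`).
#' @param to Target scaling.
#' @param bmi_sd SD of the exposure in kg/m^2 (needed to or from `"per_sd"`).
#' @return The rescaled tibble with an updated `scale` column.
#' @examples
#' r <- tibble::tibble(beta = 0.45, se = 0.097, ci_low = 0.26, ci_high = 0.64,
#'                     scale = "per5")
#' rescale_effect(r, "per_sd", bmi_sd = 2.0)
#' @export
rescale_effect <- function(record, to = c("per5", "per1", "per_sd"),
                           bmi_sd = NULL) {
  to <- match.arg(to)
  if (is.null(record[["scale"]])) abort("record has no `scale` column: unknown source scaling")
  kg_per_unit <- function(s) {
    switch(s,
           per5 = 5, per1 = 1,
           per_sd = { if (is.null(bmi_sd)) abort("bmi_sd required for per_sd scaling"); bmi_sd },
           abort(sprintf("unknown scaling `%s`", s)))
  }
  fac <- vapply(record[["scale"]], function(s) kg_per_unit(to) / kg_per_unit(s),
                numeric(1), USE.NAMES = FALSE)
  for (col in c("beta", "se", "ci_low", "ci_high"))
    if (!is.null(record[[col]])) record[[col]] <- record[[col]] * fac
  record$scale <- to
  record
}

#' @exportS3Method generics::tidy
tidy.mr_fit <- function(x, ...) x$estimates

#' @exportS3Method generics::glance
glance.mr_fit <- function(x, ...) {
  tibble(estimator = x$estimator, n = x$n, n_dropped = x$n_dropped,
         n_terms = nrow(x$estimates),
         min_cond_F = suppressWarnings(min(x$estimates$cond_F, na.rm = TRUE)))
}

#' @export
print.mr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<mr_fit> %s, outcome %s, n = %d (%d rows dropped)\n",
              x$estimator, x$spec$outcome, x$n, x$n_dropped))
  print(as.data.frame(x$estimates), digits = digits, row.names = FALSE)
  invisible(x)
}

#' Forest plot of estimate records
#'
#' Draws point estimates with 95% confidence intervals for a tidy estimates
#' table, faceted by outcome when several are present — the standard layout
#' for comparing OLS, classic MR and within-family MR side by side.
#'
#' @param estimates Tidy estimates tibble (rows from `tidy()` on fits,
#'   optionally with an `outcome` column).
#' @return A ggplot object.
#' @export
plot_estimates <- function(estimates) {
  p <- ggplot2::ggplot(estimates,
                       ggplot2::aes(x = .data$beta, y = .data$term,
                                    colour = .data$estimator)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "SD change in outcome per 5 kg/m² BMI", y = NULL) +
    ggplot2::theme_minimal()
  if ("outcome" %in% names(estimates))
    p <- p + ggplot2::facet_wrap(~outcome)
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.mr_fit <- function(object, ...) plot_estimates(tidy(object))
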