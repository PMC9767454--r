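#' Pair mothers and fathers by assortative mating
#'
#' Implements assortment as Gaussian-copula rank matching on a single latent
#' mating score per parent (a weighted combination of the standardized mating
#' traits, here BMI and a symptom liability). Given the 2x2 target matrix of
#' cross-spouse correlations `T` (rows = mother traits, columns = father
#' traits), the latent weights and the copula correlation are taken from the
#' best rank-1 approximation `T ~ rho * u v'`; for the common single-entry
#' targets (e.g. spousal BMI correlation 0.23) this is exact. Matching draws
#' bivariate normal ranks with correlation `rho` and pairs the mother whose
#' latent score has rank `rank(u_i)` with the father whose latent score has
#' rank `rank(v_i)`, within subpopulation (endogamy).
#'
#' For normal traits the realized Pearson cross-spouse correlations converge to
#' the rank-1 targets as n grows. A target that is not rank-1 triggers a
#' warning reporting the approximation actually matched; a leading singular
#' value above 1 is infeasible and raises an error stating the achievable
#' bound.
#'
#' @param mothers,fathers Data frames with numeric columns `bmi` and (optional)
#'   `symptom`; equal row counts, and equal counts per subpopulation when
#'   `subpop` is given.
#' @param spousal_corr Scalar (spousal BMI correlation) or 2x2 matrix, as in
#'   [sim_config()].
#' @param seed Optional integer seed (`NULL` uses the current RNG state).
#' @param subpop Optional integer label per family role; matching is performed
#'   within label.
#' @return A tibble with columns `mother` and `father`: row indices into the
#'   inputs, one row per couple.
#' @examples
#' m <- data.frame(bmi = rnorm(200)); f <- data.frame(bmi = rnorm(200))
#' couples <- assortative_pairing(m, f, spousal_corr = 0.9, seed = 1)
#' cor(m$bmi[couples$mother], f$bmi[couples$father])
#' @export
assortative_pairing <- function(mothers, fathers, spousal_corr, seed = NULL,
                                subpop = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(mothers) != nrow(fathers))
    abort("assortative_pairing needs equal numbers of mothers and fathers")
  n <- nrow(mothers)
  tgt <- as_spousal_matrix(spousal_corr)
  traits <- intersect(colnames(tgt), names(mothers))
  if (!length(traits)) abort("mothers/fathers must contain at least a `bmi` column")
  tgt <- tgt[traits, traits, drop = FALSE]
  dec <- svd(tgt)
  rho <- dec$d[1]
  if (rho > 1 + 1e-10)
    abort(sprintf(
      "spousal correlation target is infeasible: leading singular value %.3f exceeds the achievable bound 1",
      rho))
  if (length(dec$d) > 1 && dec$d[2] > 1e-8)
    warn(sprintf(
      "spousal_corr target is not rank-1; matching its best rank-1 approximation (secondary singular value %.3f dropped)",
      dec$d[2]))
  # orient the leading pair so the dominant weights are positive
  u <- dec$u[, 1]; v <- dec$v[, 1]
  if (u[which.max(abs(u))] < 0) { u <- -u; v <- -v }
  lat_m <- as.matrix(scale(mothers[traits])) %*% u
  lat_f <- as.matrix(scale(fathers[traits])) %*% v
  sp <- if (is.null(subpop)) rep(1L, n) else as.integer(subpop)
  out <- vector("list", length(unique(sp)))
  for (s in seq_along(sort(unique(sp)))) {
    lab <- sort(unique(sp))[s]
    im <- which(sp == lab); iff <- which(sp == lab)
    ns <- length(im)
    uu <- rnorm(ns)
    vv <- if (rho >= 1) uu else rho * uu + sqrt(1 - rho^2) * rnorm(ns)
    # mother with latent rank r is assigned the copula draw with u-rank r
    mo <- im[order(lat_m[im])][rank(uu, ties.method = "first")]
    fa <- iff[order(lat_f[iff])][rank(vv, ties.method = "first")]
    out[[s]] <- tibble(mother = mo, father = fa)
  }
  dplyr::bind_rows(out)
}
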