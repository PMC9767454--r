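#' Inject anthropometric outliers and missingness
#'
#' Corrupts a stated fraction of height/weight entries to exercise the
#' cleaning rules of [clean_anthropometrics()]: outliers are displaced by
#' `magnitude` standard deviations of the corrupted column (far beyond the
#' 4-SD flagging rule), and a further fraction is set missing, emulating the
#' questionnaire attrition that motivates imputation in real trio cohorts.
#'
#' @param families Cohort family tibble (from [simulate_trios()] or
#'   [tidy()] of a `trio_cohort`).
#' @param outlier_rate,missing_rate Fractions in `[0, 1]` of entries to
#'   corrupt, per targeted column. Rates of 0 return the input unchanged.
#' @param magnitude Displacement of outliers, in SDs of the column.
#' @param columns Columns to corrupt (default: all height/weight columns).
#' @param seed Optional seed.
#' @return The corrupted tibble, with a `corruption_log` attribute: a tibble of
#'   `(column, row, kind, original)` records.
#' @export
inject_outliers_and_missingness <- function(families, outlier_rate = 0,
                                            missing_rate = 0, magnitude = 10,
                                            columns = grep("^(height|weight)_",
                                                           names(families),
                                                           value = TRUE),
                                            seed = NULL) {
  stopifnot(outlier_rate >= 0, outlier_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  log <- list()
  for (col in columns) {
    x <- families[[col]]
    n <- length(x)
    n_out <- rbinom(1, n, outlier_rate)
    rows_out <- sample.int(n, n_out)
    if (n_out > 0) {
      shift <- magnitude * sd(x, na.rm = TRUE) * sample(c(-1, 1), n_out, TRUE)
      log[[length(log) + 1]] <- tibble(column = col, row = rows_out,
                                       kind = "outlier", original = x[rows_out])
      x[rows_out] <- x[rows_out] + shift
    }
    remaining <- setdiff(seq_len(n), rows_out)
    n_mis <- rbinom(1, length(remaining), missing_rate)
    rows_mis <- sample(remaining, n_mis)
    if (n_mis > 0) {
      log[[length(log) + 1]] <- tibble(column = col, row = rows_mis,
                                       kind = "missing", original = x[rows_mis])
      x[rows_mis] <- NA_real_
    }
    families[[col]] <- x
  }
  attr(families, "corruption_log") <- if (length(log)) dplyr::bind_rows(log) else
    tibble(column = character(), row = integer(), kind = character(),
           original = numeric())
  families
}

#' Write a simulated cohort to disk
#'
#' Persists a `trio_cohort` as plain text: the family phenotype table as CSV
#' (one row per family, role-prefixed columns), per-role genotype dosage
#' matrices as tab-delimited text (SNPs as rows: snp_id, chrom, 1-based pos,
#' effect and other allele, then one dosage column per individual), and a YAML
#' manifest recording every generative parameter including the seed.
#'
#' @param cohort A `trio_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$families, file.path(dir, "phenotypes.csv"))
  if (!is.null(cohort$geno)) {
    for (role in names(cohort$geno)) {
      d <- cohort$geno[[role]]
      out <- dplyr::bind_cols(cohort$snps[c("snp_id", "chrom", "pos",
                                            "effect_allele", "other_allele")],
                              as_tibble(t(d), .name_repair = ~sprintf(
                                "%s_%05d", role, seq_len(nrow(d)))))
      readr::write_tsv(out, file.path(dir, sprintf("dosages_%s.tsv", role)))
    }
  }
  cfg <- cohort$config
  cfg$spousal_corr <- as.vector(cfg$spousal_corr)
  yaml::write_yaml(lapply(unclass(cfg), function(v)
    if (is.numeric(v)) as.vector(v) else v),
    file.path(dir, "manifest.yaml"))
  invisible(dir)
}
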