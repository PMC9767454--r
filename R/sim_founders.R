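#' Simulate founder (parental) genotypes
#'
#' Draws unphased SNP dosages for the parental generation under a
#' Balding-Nichols model of population structure: each SNP has an ancestral
#' allele frequency drawn uniformly from `maf_range`, and each subpopulation's
#' frequency is drawn from `Beta(p(1-F)/F, (1-p)(1-F)/F)`, which has mean `p`
#' and variance `F p (1-p)`. Within blocks of `ld_block_size` adjacent SNPs,
#' linkage disequilibrium is induced on each of the two haplotypes by a
#' Gaussian copula with AR(1) correlation `ld_rho`, thresholded at the
#' subpopulation allele frequency; the dosage is the sum of the two haplotypes,
#' so Hardy-Weinberg proportions hold within subpopulation.
#'
#' @param config A [sim_config()].
#' @param n_individuals Number of founder rows (default `2 * n_families`:
#'   mothers then fathers).
#' @param seed Optional seed; defaults to `config$seed`. Pass `NULL` to use
#'   the current RNG state (as [simulate_trios()] does).
#' @return A `genotype_matrix`: list with `dosages` (individuals x SNPs integer
#'   matrix in 0/1/2), `snps` (tibble: snp_id, chrom, pos, effect_allele,
#'   other_allele, ancestral maf), `subpop` (integer label per individual), and
#'   `subpop_freq` (SNP x subpop allele frequency matrix).
#' @examples
#' g <- simulate_founders(sim_config(n_families = 50, n_snps = 20, seed = 1))
#' dim(g$dosages)
#' @export
simulate_founders <- function(config, n_individuals = 2L * config$n_families,
                              seed = config$seed) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  m <- config$n_snps
  k <- config$n_subpops
  p_anc <- runif(m, config$maf_range[1], config$maf_range[2])
  if (config$fst > 0 && k > 1) {
    a <- p_anc * (1 - config$fst) / config$fst
    b <- (1 - p_anc) * (1 - config$fst) / config$fst
    freq <- vapply(seq_len(k), function(s) rbeta(m, a, b), numeric(m))
  } else {
    freq <- matrix(p_anc, m, k)
  }
  subpop <- rep_len(seq_len(k), n_individuals)
  dos <- matrix(0L, n_individuals, m)
  blocks <- split(seq_len(m), ceiling(seq_len(m) / config$ld_block_size))
  thresh <- qnorm(freq) # allele present when latent normal < threshold
  for (idx in blocks) {
    tb <- thresh[idx, subpop, drop = FALSE] # block-SNPs x individuals
    h <- 0L
    for (hap in 1:2) {
      z <- ar1_normal(n_individuals, length(idx), config$ld_rho)
      h <- h + (t(z) < tb)
    }
    dos[, idx] <- t(h)
  }
  storage.mode(dos) <- "integer"
  map <- snp_positions(m)
  snps <- tibble(
    snp_id = sprintf("rs%06d", seq_len(m)),
    chrom = map$chrom, pos = map$pos,
    effect_allele = map$ea, other_allele = map$oa,
    maf = p_anc
  )
  rownames(dos) <- sprintf("ind%05d", seq_len(n_individuals))
  colnames(dos) <- snps$snp_id
  structure(list(dosages = dos, snps = snps, subpop = subpop,
                 subpop_freq = freq),
            class = "genotype_matrix")
}

# n x m matrix of standard normals with AR(1) correlation rho along columns
ar1_normal <- function(n, m, rho) {
  z <- matrix(rnorm(n * m), n, m)
  if (rho > 0 && m > 1) {
    s <- sqrt(1 - rho^2)
    for (j in 2:m) z[, j] <- rho * z[, j - 1] + s * z[, j]
  }
  z
}

# deterministic SNP map: ~1 Mb spacing, wrapping to a new chromosome past
# 250 Mb; alleles cycle through non-palindromic pairs (strand-unambiguous)
snp_positions <- function(m) {
  gap <- 1e6
  per_chrom <- 250L
  i <- seq_len(m) - 1L
  chrom <- 1L + i %/% per_chrom
  pos <- 1L + (i %% per_chrom) * as.integer(gap)
  pairs <- matrix(c("A", "C", "A", "G", "T", "C", "T", "G",
                    "C", "A", "G", "A", "C", "T", "G", "T"),
                  ncol = 2, byrow = TRUE)
  sel <- 1L + i %% nrow(pairs)
  list(chrom = chrom, pos = pos, ea = pairs[sel, 1], oa = pairs[sel, 2])
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs, %d subpopulation(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$subpop))))
  invisible(x)
}

#' Mendelian transmission of parental dosages to a child
#'
#' For each SNP the child receives one allele from each parent, drawn
#' independently with probability `dosage/2` (unphased transmission: parental
#' haplotype phase is ignored, so parental LD is not propagated into the child
#' haplotypes; founder LD is all that the clumping step consumes).
#'
#' @param mother,father Integer dosage vectors or matrices (families x SNPs)
#'   with values in `{0, 1, 2}`.
#' @param seed Optional integer seed (`NULL` uses the current RNG state).
#' @return Child dosage object of the same shape.
#' @examples
#' transmit_genotypes(c(2L, 0L, 1L), c(2L, 0L, 1L), seed = 1)
#' @export
transmit_genotypes <- function(mother, father, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  was_vec <- is.null(dim(mother))
  mm <- rbind(mother); ff <- rbind(father)
  if (any(dim(mm) != dim(ff)))
    abort("mother and father dosages must have identical shape")
  if (any(mm != round(mm)) || any(ff != round(ff)) ||
      any(mm < 0 | mm > 2) || any(ff < 0 | ff > 2))
    abort("transmission requires hard calls: parental dosages must be integers in {0,1,2}")
  child <- matrix(rbinom(length(mm), 1L, mm / 2) + rbinom(length(ff), 1L, ff / 2),
                  nrow(mm), ncol(mm), dimnames = dimnames(mm))
  storage.mode(child) <- "integer"
  if (was_vec) drop(child) else child
}
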