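test_that("clumping keeps only the top SNP of a tight LD block", {
  set.seed(41)
  n <- 400
  base <- rbinom(n, 2, 0.4)
  jitter <- function(x) { # strongly correlated variants (r2 ~ 0.8)
    flip <- runif(n) < 0.08
    pmin(pmax(x + ifelse(flip, sample(c(-1, 1), n, TRUE), 0), 0), 2)
  }
  dos <- cbind(base, jitter(base), jitter(base))
  map <- snp_map(3, pos = c(1e6L, 2e6L, 3e6L))
  g <- as_geno(dos, map)
  w <- weight_table(map, beta = c(0.1, 0.1, 0.1),
                    p_value = c(1e-9, 1e-10, 1e-8))
  kept <- clump(w, g, r2_threshold = 0.01, window_kb = 10000)
  expect_equal(kept$snp_id, "rs002") # lowest p wins
})

test_that("SNPs outside the physical window are retained regardless of LD", {
  dos <- cbind(a = rbinom(300, 2, 0.5), b = rbinom(300, 2, 0.5))
  dos[, 2] <- dos[, 1] # perfect LD
  map <- snp_map(2, pos = c(1L, 1L + 20001L * 1000L)) # 20,001 kb apart
  g <- as_geno(dos, map)
  w <- weight_table(map, beta = c(0.1, 0.1), p_value = c(1e-10, 1e-9))
  expect_equal(nrow(clump(w, g, window_kb = 10000)), 2)
})

test_that("the genome-wide significance threshold is strict", {
  dos <- cbind(rbinom(300, 2, 0.5), rbinom(300, 2, 0.5))
  map <- snp_map(2)
  g <- as_geno(dos, map)
  w <- weight_table(map, beta = c(0.1, 0.1), p_value = c(6e-8, 1e-10))
  kept <- clump(w, g, p_threshold = 5e-8)
  expect_equal(kept$snp_id, "rs002")
  w2 <- weight_table(map, beta = c(0.1, 0.1), p_value = c(6e-8, 7e-8))
  expect_warning(out <- clump(w2, g), "no SNPs")
  expect_equal(nrow(out), 0)
})

test_that("clumping satisfies the brute-force pairwise-r2 oracle on random instances", {
  for (s in 1:8) {
    set.seed(s)
    m <- sample(10:50, 1)
    n <- 200
    blocks <- ceiling(seq_len(m) / 5)
    dos <- matrix(0, n, m)
    for (b in unique(blocks)) {
      idx <- which(blocks == b)
      core <- rbinom(n, 2, runif(1, 0.2, 0.5))
      for (j in idx) {
        mix <- runif(1) < 0.5
        dos[, j] <- if (mix) core else rbinom(n, 2, runif(1, 0.2, 0.5))
      }
    }
    map <- snp_map(m, pos = as.integer(sample.int(2e8, m)))
    w <- weight_table(map, beta = rnorm(m), p_value = 10^-runif(m, 5, 12))
    kept <- clump(w, as_geno(dos, map), r2_threshold = 0.01,
                  window_kb = 10000, p_threshold = 1e-5)
    # oracle property 1: every retained pair within the window is below r2
    if (nrow(kept) > 1) {
      for (i in seq_len(nrow(kept) - 1)) for (j in (i + 1):nrow(kept)) {
        if (kept$chrom[i] != kept$chrom[j]) next
        if (abs(kept$pos[i] - kept$pos[j]) > 1e7) next
        r2 <- cor(dos[, match(kept$snp_id[i], map$snp_id)],
                  dos[, match(kept$snp_id[j], map$snp_id)])^2
        expect_lt(r2, 0.01)
      }
    }
    # oracle property 2: every excluded candidate conflicts with a
    # better-ranked retained SNP
    excluded <- setdiff(w$snp_id[w$p_value < 1e-5], kept$snp_id)
    for (sid in excluded) {
      i <- match(sid, map$snp_id)
      better <- kept[kept$p_value < w$p_value[w$snp_id == sid], ]
      conflict <- vapply(better$snp_id, function(kid) {
        j <- match(kid, map$snp_id)
        map$chrom[i] == map$chrom[j] &&
          abs(map$pos[i] - map$pos[j]) <= 1e7 &&
          cor(dos[, i], dos[, j])^2 >= 0.01
      }, logical(1))
      expect_true(any(conflict))
    }
  }
})

test_that("scores are linear in dosage and flip-symmetric", {
  map <- snp_map(1)
  g <- as_geno(matrix(c(0L, 1L, 2L), 3, 1), map)
  w <- weight_table(map, beta = 0.1, p_value = 1e-10)
  expect_equal(build_pgs(g, w)$score, c(0, 0.1, 0.2))
  # genotype file counts the other allele: dosages reflect
  w_flip <- w
  w_flip$effect_allele <- "G"; w_flip$other_allele <- "A"
  expect_equal(build_pgs(g, w_flip)$score, c(0.2, 0.1, 0))
})

test_that("score variance matches the linkage-equilibrium closed form", {
  set.seed(44)
  m <- 300; n <- 4000
  p <- runif(m, 0.1, 0.5)
  dos <- sapply(p, function(pp) rbinom(n, 2, pp))
  map <- snp_map(m, pos = as.integer(seq_len(m) * 2e6))
  beta <- rnorm(m, 0, 0.05)
  w <- weight_table(map, beta = beta, p_value = rep(1e-10, m))
  sc <- build_pgs(as_geno(dos, map), w)
  expect_equal(var(sc$score), sum(2 * p * (1 - p) * beta^2), tolerance = 0.05)
  expect_equal(attr(sc, "n_snps_used"), m)
})

test_that("scoring is invariant to SNP row order and drops palindromic SNPs", {
  set.seed(45)
  m <- 20
  dos <- sapply(runif(m, 0.2, 0.5), function(pp) rbinom(100, 2, pp))
  map <- snp_map(m)
  w <- weight_table(map, beta = rnorm(m), p_value = rep(1e-9, m))
  s1 <- build_pgs(as_geno(dos, map), w)
  s2 <- build_pgs(as_geno(dos, map), w[sample.int(m), ])
  expect_equal(s1$score, s2$score)
  # palindromic SNP: A/T is strand-ambiguous and must be dropped
  w_pal <- w
  w_pal$other_allele[1] <- "T"
  map_pal <- map; map_pal$other_allele[1] <- "T"
  expect_message(s3 <- build_pgs(as_geno(dos, map_pal), w_pal), "palindromic")
  expect_equal(attr(s3, "n_snps_used"), m - 1)
})

test_that("missing dosages are mean-imputed per SNP", {
  map <- snp_map(1)
  d <- matrix(c(0, 2, NA, 2), 4, 1)
  w <- weight_table(map, beta = 1, p_value = 1e-9)
  sc <- build_pgs(as_geno(d, map), w)
  expect_equal(sc$score[3], mean(c(0, 2, 2)))
})

test_that("ancestry components separate simulated subpopulations", {
  coh <- simulate_trios(sim_config(n_families = 300, n_snps = 1000,
                                   n_subpops = 2, fst = 0.1, seed = 46),
                        genotypes = TRUE)
  g <- as_geno(coh$geno$child, coh$snps)
  pcs <- ancestry_pcs(g, 4)
  expect_gt(abs(cor(pcs$PC1, coh$families$subpop)), 0.9)
  # components are orthogonal and unit variance
  cm <- cor(as.matrix(pcs[-1]))
  expect_equal(cm, diag(4), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(apply(as.matrix(pcs[-1]), 2, sd), rep(1, 4),
               tolerance = 1e-8, ignore_attr = TRUE)
  # duplicated individuals get identical rows (determinism incl. sign fix)
  g2 <- as_geno(rbind(coh$geno$child, coh$geno$child[1:5, ]), coh$snps)
  pcs2 <- ancestry_pcs(g2, 2)
  expect_equal(as.matrix(pcs2[301:305, -1]), as.matrix(pcs2[1:5, -1]),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(ancestry_pcs(as_geno(matrix(rbinom(40, 2, .5), 10, 4),
                                    snp_map(4)), 10), "k")
})

test_that("anthropometric cleaning applies the 4-SD rule in one pass", {
  bm <- clean_anthropometrics(1.30, 28)
  expect_equal(bm$bmi, 28 / 1.30^2, tolerance = 1e-6) # 16.57
  set.seed(47)
  h <- rnorm(1000, 1.3, 0.06); w <- rnorm(1000, 28, 3)
  w[1] <- 28 + 12 * sd(w) # 12 SD above the mean
  res <- clean_anthropometrics(h, w)
  expect_true(is.na(res$bmi[1]))
  expect_equal(attr(res, "n_outliers"), 1)
  # all values within 1 SD: nothing flagged
  res2 <- clean_anthropometrics(seq(1.2, 1.4, length.out = 50),
                                seq(25, 30, length.out = 50))
  expect_equal(attr(res2, "n_outliers"), 0)
  expect_false(anyNA(res2$bmi))
})

test_that("scale proration follows the 80% completeness rule", {
  full <- matrix(c(rep(0, 12), 6), 1, 13) # 13 answered, sum 6
  expect_equal(prorate_scale(full, 13), 6)
  part <- full; part[1, 1] <- NA; part[1, 13] <- 6 # 12 of 13, sum 6
  expect_equal(prorate_scale(part, 13), 6 * 13 / 12)
  sparse <- matrix(NA_real_, 1, 13); sparse[1, 1:9] <- 1 # 9 of 13 < 80%
  expect_true(is.na(prorate_scale(sparse, 13)))
  # threshold uses the ceiling: 11 of 13 passes, 10 of 13 does not
  ten <- matrix(NA_real_, 1, 13); ten[1, 1:10] <- 1
  eleven <- matrix(NA_real_, 1, 13); eleven[1, 1:11] <- 1
  expect_true(is.na(prorate_scale(ten, 13)))
  expect_false(is.na(prorate_scale(eleven, 13)))
  expect_error(prorate_scale(matrix(c(1, 5), 1, 2), 2, max_category = 3),
               "category range")
})

test_that("weight tables round-trip through tab-delimited text", {
  path <- withr::local_tempfile(fileext = ".tsv")
  w <- weight_table(snp_map(5), beta = rnorm(5), p_value = rep(1e-9, 5))
  readr::write_tsv(w, path)
  back <- read_weight_table(path)
  expect_equal(back$beta, w$beta)
  bad <- w; bad$p_value[1] <- 0
  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(bad, path2)
  expect_error(read_weight_table(path2), "p_value")
})

test_that("constructed-score fidelity rises with GWAS precision", {
  cfg <- sim_config(n_families = 500, n_snps = 80, seed = 48,
                    pgs_r2_child = 0.3)
  coh <- simulate_trios(cfg, genotypes = TRUE)
  g <- as_geno(coh$geno$child, coh$snps)
  cors <- sapply(c(1e3, 1e5, 1e7), function(ng) {
    w <- simulate_gwas_weights(coh, n_gwas = ng, seed = 49)
    cor(build_pgs(g, w)$score, coh$families$pgs_child)
  })
  expect_true(all(diff(cors) > 0))
  expect_gt(cors[3], 0.95)
})
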