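test_that("GRM matches the naive double loop and flags duplicates", {
  G <- toy_genotypes(n = 5, m = 20, seed = 61)
  K <- compute_grm(G)
  # brute force
  Z <- scale(G$dosage)
  keep <- !is.nan(colSums(Z))
  Z <- Z[, keep, drop = FALSE]
  Kb <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    Kb[i, j] <- sum(Z[i, ] * Z[j, ]) / ncol(Z)
  }
  expect_equal(unname(K), Kb, tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(isSymmetric(unname(K)))

  # duplicated samples give off-diagonal equal to diagonals
  dos <- rbind(G$dosage, G$dosage[1, ])
  G2 <- genotype_matrix(dos, G$variants, c(G$samples, "dup"))
  K2 <- compute_grm(G2)
  expect_equal(K2["s1", "dup"], K2["s1", "s1"], tolerance = 1e-10)
})

test_that("independent samples give near-zero GRM off-diagonals", {
  set.seed(62)
  n <- 40; m <- 5000
  p <- runif(m, 0.1, 0.9)
  dos <- vapply(p, function(pp) rbinom(n, 2, pp), numeric(n))
  G <- genotype_matrix(dos, data.frame(chrom = "1", pos = 100L * (1:m),
                                       id = paste0("v", 1:m),
                                       ref = "A", alt = "G"),
                       paste0("s", 1:n))
  K <- compute_grm(G)
  off <- K[upper.tri(K)]
  expect_lt(mean(abs(off)), 0.05)
  expect_lt(abs(mean(diag(K)) - 1), 0.2)
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)
})

sim_k_pheno <- function(K, h2, seed) {
  # y = g + e with g ~ N(0, h2 K), e ~ N(0, 1 - h2)
  set.seed(seed)
  e <- eigen(K, symmetric = TRUE)
  g <- e$vectors %*% (sqrt(pmax(e$values, 0)) * rnorm(nrow(K)))
  as.numeric(sqrt(h2) * g + rnorm(nrow(K), 0, sqrt(1 - h2)))
}

test_that("null REML prefers the residual component on pure noise", {
  # few SNPs relative to n so K has identifiable structure
  cfg <- sim_config(seed = 63, n_per_cohort = c(200, 10), n_snps = 300,
                    n_chroms = 2, within_block_r = 0.95,
                    block_size_snps = 30)
  G <- simulate_cohorts(cfg)$genotypes$cohort1
  K <- compute_grm(G)
  hits <- vapply(1:20, function(i) {
    set.seed(6300 + i)
    y <- rnorm(length(G$samples))
    f <- fit_null_lmm(y, K)
    f$sigma2_g / max(f$sigma2_e, 1e-12) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("null REML recovers a planted heritability of one half", {
  cfg <- sim_config(seed = 64, n_per_cohort = c(300, 10), n_snps = 2000,
                    n_chroms = 2)
  G <- simulate_cohorts(cfg)$genotypes$cohort1
  K <- compute_grm(G)
  h2 <- vapply(1:20, function(i) {
    y <- sim_k_pheno(K, 0.5, 6400 + i)
    fit_null_lmm(y, K)$h2
  }, numeric(1))
  expect_gte(mean(h2 >= 0.3 & h2 <= 0.7), 0.8)
})

test_that("REML optimum dominates the unit variance ratio", {
  G <- toy_genotypes(n = 50, m = 120, seed = 65)
  K <- compute_grm(G)
  for (i in 1:5) {
    y <- sim_k_pheno(K, runif(1, 0.1, 0.9), 650 + i)
    f <- fit_null_lmm(y, K)
    expect_gte(f$loglik + 1e-6, f$reml_fun(log(1)))
  }
})

test_that("scan pinpoints a planted causal SNP", {
  hits <- vapply(1:20, function(i) {
    cfg <- sim_config(seed = 6600 + i, n_per_cohort = c(300, 10),
                      n_snps = 500, n_chroms = 1, prop_shared = 1,
                      within_block_r = 0.5,
                      causal_spec = data.frame(snp = 250, trait = "glucose",
                                               effect = 1, scope = "shared"),
                      traits = ems_traits()[3, , drop = FALSE])
    sim <- simulate_cohorts(cfg)
    G <- sim$genotypes$cohort1
    ph <- sim$phenotypes[sim$phenotypes$cohort == "cohort1", ]
    y <- prepare_traits(ph)$glucose
    K <- compute_grm(G)
    rec <- lmm_scan(y, G, fit_null_lmm(y, K))
    rec$id[which.min(rec$p)] == "snp00250"
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("null trait p-values are calibrated at the 1e-3 tail", {
  cfg <- sim_config(seed = 67, n_per_cohort = c(300, 10), n_snps = 10000,
                    within_block_r = 0.3)
  G <- simulate_cohorts(cfg)$genotypes$cohort1
  K <- compute_grm(G)
  set.seed(670)
  y <- rnorm(length(G$samples))
  rec <- lmm_scan(y, G, fit_null_lmm(y, K))
  frac <- mean(rec$p < 1e-3)
  expect_gte(frac, 0.0002)
  expect_lte(frac, 0.005)
})

test_that("allele-coding flips negate beta and preserve p", {
  G <- toy_genotypes(n = 60, m = 30, seed = 68)
  set.seed(680)
  y <- rnorm(60)
  K <- compute_grm(G)
  nf <- fit_null_lmm(y, K)
  rec <- lmm_scan(y, G, nf)
  Gf <- G
  Gf$dosage[, 7] <- 2 - Gf$dosage[, 7]
  recf <- lmm_scan(y, Gf, nf)
  expect_equal(recf$beta[7], -rec$beta[7], tolerance = 1e-10)
  expect_equal(recf$p[7], rec$p[7], tolerance = 1e-10)
})

test_that("scan with a zero GRM equals per-SNP ordinary least squares", {
  G <- toy_genotypes(n = 40, m = 25, seed = 69)
  set.seed(690)
  y <- rnorm(40)
  K0 <- matrix(0, 40, 40)
  nf <- fit_null_lmm(y, K0)
  rec <- lmm_scan(y, G, nf)
  for (j in c(1, 10, 25)) {
    ols <- summary(stats::lm(y ~ G$dosage[, j]))$coefficients
    expect_equal(rec$beta[j], ols[2, 1], tolerance = 1e-8)
    expect_equal(rec$se[j], ols[2, 2], tolerance = 1e-8)
    p_wald <- stats::pchisq((ols[2, 1] / ols[2, 2])^2, 1, lower.tail = FALSE)
    expect_equal(rec$p[j], p_wald, tolerance = 1e-8)
  }
})

test_that("duplicated SNP panels halve the effective test count", {
  G <- toy_genotypes(n = 100, m = 30, seed = 70)
  dup <- cbind(G$dosage, G$dosage)
  v <- rbind(G$variants, transform(G$variants,
                                   pos = pos + 1L,
                                   id = paste0(id, "_dup")))
  G2 <- genotype_matrix(dup, v, G$samples)
  # pairs are adjacent after position sorting; one block per pair
  expect_equal(effective_tests(G2, block_size = 2), 30)
})

test_that("independent SNPs keep most of their nominal test count", {
  set.seed(71)
  # sample count well above the block size keeps eigenvalue noise small
  n <- 2000; m <- 400
  p <- runif(m, 0.1, 0.9)
  dos <- vapply(p, function(pp) rbinom(n, 2, pp), numeric(n))
  G <- genotype_matrix(dos, data.frame(chrom = "1", pos = 100L * (1:m),
                                       id = paste0("v", 1:m),
                                       ref = "A", alt = "G"),
                       paste0("s", 1:n))
  expect_gt(effective_tests(G, 200) / m, 0.9)
})

test_that("block method approximates the whole-matrix eigen count", {
  cfg <- sim_config(seed = 72, n_per_cohort = c(1000, 10), n_snps = 200,
                    n_chroms = 1)
  G <- simulate_cohorts(cfg)$genotypes$cohort1
  me_whole <- effective_tests(G, block_size = 10000)
  me_block <- effective_tests(G, block_size = 50)
  expect_lt(abs(me_block - me_whole) / me_whole, 0.1)
})

test_that("effective test count is invariant to coding flips and order", {
  G <- toy_genotypes(n = 80, m = 40, seed = 73)
  me <- effective_tests(G, 40)
  Gf <- G
  Gf$dosage[, c(3, 9)] <- 2 - Gf$dosage[, c(3, 9)]
  expect_equal(effective_tests(Gf, 40), me, tolerance = 1e-8)
})

test_that("threshold arithmetic reproduces the printed values", {
  expect_equal(signif(significance_thresholds(657030)$genome_wide, 3),
               7.61e-8)
  expect_equal(signif(significance_thresholds(307349)$genome_wide, 3),
               1.63e-7)
  th <- significance_thresholds(50)
  expect_equal(th$genome_wide, 1e-3)
  expect_equal(th$suggestive, 1e-5)
})

fake_scan <- function(trait, cohort, pos, p, m_eff = 1000) {
  rec <- data.frame(chrom = "1", pos = pos,
                    id = paste0("v", pos), ref = "A", alt = "G",
                    beta = 0.1, se = 0.05, p = p, n = 100L,
                    stringsAsFactors = FALSE)
  structure(list(trait = trait, cohort = cohort, records = rec,
                 m_effective = m_eff,
                 thresholds = significance_thresholds(m_eff)),
            class = "gwas_scan")
}

test_that("cohort union takes any-scan suggestive SNPs with provenance", {
  pos <- c(100L, 200L, 300L, 400L)
  s_full <- fake_scan("t", "full", pos, c(1e-6, 0.5, 0.5, 1e-9))
  s_ab <- fake_scan("t", "ab", pos, c(0.5, 1e-7, 0.5, 0.5))
  u <- cohort_union(list(s_full, s_ab))
  expect_equal(u$pos, c(100L, 200L, 400L))
  expect_equal(u$suggestive_in[u$pos == 100], "full")
  expect_equal(u$suggestive_in[u$pos == 200], "ab")
  # SNP 400 at 1e-9 beats the full scan genome-wide threshold (5e-5)
  expect_true(u$is_significant[u$pos == 400])
  expect_false(300 %in% u$pos)
})

test_that("union cardinality equals the brute-force set union", {
  set.seed(74)
  pos <- sort(sample(1:10000, 300)) * 10L
  scans <- lapply(1:3, function(k) {
    p <- runif(300)
    p[sample(300, 30)] <- 10^runif(30, -9, -5.01)
    fake_scan("t", paste0("c", k), pos, p)
  })
  u <- cohort_union(scans)
  brute <- sort(unique(unlist(lapply(scans, function(s)
    s$records$pos[s$records$p < 1e-5]))))
  expect_equal(u$pos, brute)
})
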