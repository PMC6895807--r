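test_that("fixed-effects meta matches closed forms", {
  r <- fe_meta(c(1, 1), c(1, 1))
  expect_equal(r$beta, 1)
  expect_equal(r$se, 1 / sqrt(2))
  r0 <- fe_meta(c(0, 0), c(1, 2))
  expect_equal(r0$z, 0)
  expect_equal(r0$p, 1)
  # hand-computed inverse-variance combination
  r2 <- fe_meta(c(0.3, 0.5), c(0.1, 0.2))
  w <- c(1 / 0.01, 1 / 0.04)
  expect_equal(r2$beta, sum(w * c(0.3, 0.5)) / sum(w), tolerance = 1e-12)
  expect_equal(r2$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
  expect_error(fe_meta(c(1, 1), c(1, 0)), "> 0")
  expect_error(fe_meta(1, 2), ">= 2")
})

test_that("k identical studies shrink the standard error by sqrt(k)", {
  for (k in 2:5) {
    r <- fe_meta(rep(0.4, k), rep(0.15, k))
    expect_equal(r$se, 0.15 / sqrt(k), tolerance = 1e-12)
    expect_equal(r$beta, 0.4)
  }
})

test_that("fixed-effects meta agrees with metafor", {
  skip_if_not_installed("metafor")
  set.seed(81)
  for (i in 1:10) {
    b <- rnorm(3); s <- runif(3, 0.05, 0.5)
    r <- fe_meta(b, s)
    m <- metafor::rma(yi = b, sei = s, method = "FE")
    expect_equal(r$beta, as.numeric(m$beta), tolerance = 1e-8)
    expect_equal(r$se, as.numeric(m$se), tolerance = 1e-8)
    d <- dl_tau2(b, s)
    mdl <- metafor::rma(yi = b, sei = s, method = "DL")
    expect_equal(d$tau2, mdl$tau2, tolerance = 1e-6)
    expect_equal(d$Q, as.numeric(mdl$QE), tolerance = 1e-8)
  }
})

test_that("RE2 reduces to the squared FE z-score for homogeneous effects", {
  r <- re2_meta(c(0.5, 0.5), c(0.1, 0.1))
  z <- fe_meta(c(0.5, 0.5), c(0.1, 0.1))$z
  expect_equal(r$stat, z^2, tolerance = 1e-6)
})

test_that("opposite effects produce a huge heterogeneity-driven statistic", {
  r <- re2_meta(c(2, -2), c(0.1, 0.1))
  z2 <- fe_meta(c(2, -2), c(0.1, 0.1))$z^2
  expect_lt(z2, 1)     # FE sees nothing
  expect_gt(r$stat, 100)
})

test_that("RE2 statistic matches dense two-dimensional grid maximization", {
  set.seed(82)
  for (i in 1:12) {
    k <- sample(2:4, 1)
    b <- rnorm(k, sd = sample(c(0.2, 1), 1))
    s <- runif(k, 0.05, 0.5)
    expect_equal(re2_meta(b, s)$stat, re2_oracle(b, s), tolerance = 2e-3)
  }
})

test_that("RE2 dominates the FE chi-square on random inputs", {
  set.seed(83)
  b <- matrix(rnorm(500 * 2, sd = 0.5), 500, 2)
  s <- matrix(runif(500 * 2, 0.05, 0.5), 500, 2)
  re <- re2_meta(b, s)
  fe <- fe_meta(b, s)
  expect_true(all(re$stat >= fe$z^2 - 1e-6))
})

test_that("the asymptotic null mixture is near-nominal and never anticonservative", {
  # at k = 2 the half-half chi-square mixture is known to be conservative
  # (the boundary mass on tau2 > 0 is below one half at finite k), so the
  # null rejection rate sits somewhat below the nominal 5%
  set.seed(84)
  n <- 10000
  s <- matrix(runif(n * 2, 0.05, 0.5), n, 2)
  b <- matrix(rnorm(n * 2), n, 2) * s
  p <- re2_meta(b, s)$p
  frac <- mean(p < 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.07)
})

test_that("allele alignment flips swapped coding and intersects cohorts", {
  s1 <- data.frame(chrom = "1", pos = c(100L, 200L, 300L), id = paste0("v", 1:3),
                   ref = c("A", "A", "A"), alt = c("G", "G", "G"),
                   beta = c(0.1, 0.2, 0.3), se = 0.1, p = 0.5, n = 100L)
  s2 <- data.frame(chrom = "1", pos = c(100L, 200L, 400L), id = paste0("w", 1:3),
                   ref = c("G", "A", "A"), alt = c("A", "G", "G"),
                   beta = c(0.5, -0.2, 0.9), se = 0.1, p = 0.5, n = 90L)
  j <- align_alleles(list(a = s1, b = s2))
  expect_equal(nrow(j), 2L)           # pos 300/400 excluded
  expect_equal(j$beta_b[j$pos == 100], -0.5)  # swapped -> flipped
  expect_equal(j$beta_b[j$pos == 200], -0.2)
  # irreconcilable alleles dropped with count
  s2b <- s2
  s2b$ref[2] <- "C"; s2b$alt[2] <- "T"
  j2 <- align_alleles(list(a = s1, b = s2b))
  expect_equal(nrow(j2), 1L)
  expect_equal(attr(j2, "dropped_alleles"), 1L)
})

test_that("shared/specific fixture joins to exactly the shared rows", {
  set.seed(85)
  mk <- function(pos) data.frame(chrom = "2", pos = pos,
                                 id = paste0("s", pos), ref = "A", alt = "G",
                                 beta = rnorm(length(pos)), se = 0.1,
                                 p = 0.5, n = 50L)
  shared <- sort(sample(1:100000, 100)) * 10L
  only1 <- setdiff(sort(sample(1:100000, 20)) * 10L + 1L, shared)
  only2 <- setdiff(sort(sample(1:100000, 20)) * 10L + 3L, shared)
  j <- align_alleles(list(c1 = mk(c(shared, only1)),
                          c2 = mk(c(shared, only2))))
  expect_equal(nrow(j), 100L)
  expect_equal(sort(j$pos), shared)
})

test_that("meta thresholds use the larger effective count", {
  th <- meta_thresholds(c(306023, 307349))
  expect_equal(th$m_used, 307349)
  expect_equal(signif(th$genome_wide, 3), 1.63e-7)
})

test_that("MA-ROI calls use a strict threshold and allow single SNPs", {
  mk_meta <- function(pos, p) data.frame(chrom = "3", pos = pos, p_re2 = p)
  th <- list(genome_wide = 1.63e-7, suggestive = 1e-5)
  # best p just above the threshold: not an MA-ROI
  r1 <- call_ma_roi(mk_meta(c(1e6, 1.1e6), c(1.7e-7, 5e-6)), th)
  expect_equal(nrow(r1), 1L)
  expect_false(r1$is_ma_roi)
  # single-SNP region below threshold: MA-ROI
  r2 <- call_ma_roi(mk_meta(5e6, 1e-9), th)
  expect_true(r2$is_ma_roi)
  expect_equal(r2$n_suggestive, 1L)
  # boundary equality is not enough (strict inequality)
  r3 <- call_ma_roi(mk_meta(5e6, 1.63e-7), th)
  expect_false(r3$is_ma_roi)
})
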