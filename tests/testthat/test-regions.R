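test_that("gap rule splits and joins suggestive SNP clusters", {
  rec <- data.frame(chrom = "1", pos = c(1000000L, 1300000L, 2500000L),
                    p = c(1e-6, 1e-6, 1e-6))
  reg <- cluster_suggestive_snps(rec, 1e-5, 1e-8)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$min_snp_bp, c(1000000L, 2500000L))
  expect_equal(reg$max_snp_bp, c(1300000L, 2500000L))
})

test_that("ROI requires five suggestive SNPs and one genome-wide hit", {
  pos <- seq(1e6, 1e6 + 4 * 4e5, by = 4e5)
  rec <- data.frame(chrom = "2", pos = as.integer(pos),
                    p = c(1e-6, 1e-6, 1e-9, 1e-6, 1e-6))
  reg <- cluster_suggestive_snps(rec, 1e-5, 1e-8)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$n_suggestive, 5L)
  expect_equal(reg$n_significant, 1L)
  expect_true(reg$is_roi)
  # four suggestive SNPs only: not an ROI even with a genome-wide hit
  reg4 <- cluster_suggestive_snps(rec[-1, ], 1e-5, 1e-8)
  expect_false(reg4$is_roi)
  # five suggestive, none genome-wide: not an ROI
  rec5 <- rec; rec5$p <- rep(1e-6, 5)
  expect_false(cluster_suggestive_snps(rec5, 1e-5, 1e-8)$is_roi)
})

test_that("clustering equals the transitive-closure graph oracle", {
  set.seed(91)
  for (i in 1:5) {
    n <- 60
    rec <- data.frame(
      chrom = sample(c("1", "2"), n, TRUE),
      pos = sample.int(2e7, n),
      p = 10^runif(n, -9, -5.01))
    reg <- cluster_suggestive_snps(rec, 1e-5, 1e-8)
    comps <- cluster_oracle(rec$chrom, rec$pos)
    spans <- t(vapply(comps, range, numeric(2)))
    expect_equal(nrow(reg), length(comps))
    expect_equal(sort(reg$min_snp_bp), sort(as.integer(spans[, 1])))
    expect_equal(sort(reg$max_snp_bp), sort(as.integer(spans[, 2])))
    expect_equal(sum(reg$n_suggestive), n)
  }
})

test_that("fixed boundaries add 500 kb flanks with clipping", {
  fb <- fixed_boundaries(44104129, 45081679)
  expect_equal(fb$start, 43604129L)
  expect_equal(fb$end, 45581679L)
  fb2 <- fixed_boundaries(200000, 600000, chrom_length = 900000)
  expect_equal(fb2$start, 1L)
  expect_equal(fb2$end, 900000L)
  # unclipped width is span + 1 Mb
  set.seed(92)
  lo <- sort(sample.int(1e8, 20)) + 2e6
  hi <- lo + sample.int(1e6, 20)
  fb3 <- fixed_boundaries(lo, hi)
  expect_true(all((fb3$end - fb3$start) == (hi - lo) + 1e6))
})

test_that("pairwise r2 matches the correlation formula", {
  expect_equal(pairwise_r2(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1)
  expect_equal(pairwise_r2(c(0, 0, 2, 2), c(0, 2, 0, 2)), 0)
  expect_true(is.na(pairwise_r2(c(1, 1, 1), c(0, 1, 2))))
  set.seed(93)
  x <- rbinom(500, 2, 0.4)
  y <- ifelse(runif(500) < 0.7, x, rbinom(500, 2, 0.4))
  expect_equal(pairwise_r2(x, y), cor(x, y)^2, tolerance = 1e-12)
  # missing entries: complete pairs only
  x[1:50] <- NA
  ok <- !is.na(x)
  expect_equal(pairwise_r2(x, y), cor(x[ok], y[ok])^2, tolerance = 1e-12)
})

# Designed-LD fixture: SNPs that are exact copies of a base vector are in
# mutual LD (r2 = 1); independent SNPs elsewhere.
ld_fixture <- function(copy_pos, indep_pos, seed = 94, n = 80) {
  set.seed(seed)
  base <- rbinom(n, 2, 0.5)
  while (sd(base) == 0) base <- rbinom(n, 2, 0.5)
  pos <- c(copy_pos, indep_pos)
  dos <- matrix(0, n, length(pos))
  for (j in seq_along(copy_pos)) dos[, j] <- base
  for (j in seq_along(indep_pos)) {
    dos[, length(copy_pos) + j] <- rbinom(n, 2, runif(1, 0.2, 0.8))
  }
  ord <- order(pos)
  genotype_matrix(dos[, ord], data.frame(chrom = "1", pos = sort(pos),
                                         id = paste0("v", seq_along(pos)),
                                         ref = "A", alt = "G"),
                  paste0("s", 1:n))
}

test_that("LD boundaries stop at designed 150 kb gaps", {
  block <- seq(1000000, 1400000, by = 50000)       # 9 copies, 400 kb block
  outliers <- c(850000, 1550000)                    # in LD but beyond gaps
  indep <- c(700000, 905000, 1455000, 1700000)      # not in LD
  G <- ld_fixture(c(block, outliers), indep)
  res <- ld_boundaries(region_pos = c(1150000, 1250000), G, "1")
  expect_equal(res$start, 1000000L)
  expect_equal(res$end, 1400000L)
  expect_equal(res$window_used, 1e6)
})

test_that("window expands by 1 Mb when LD runs past the first window", {
  chain <- seq(1050000, 2580000, by = 90000)  # continuous 90 kb LD ladder
  G <- ld_fixture(c(1000000, chain), c(500000, 2800000, 3000000))
  res <- ld_boundaries(region_pos = c(1000000, 1050000), G, "1",
                       chrom_length = 4e6)
  expect_equal(res$window_used, 2e6)
  expect_gt(res$end, 2050000)   # beyond the first window edge
  expect_equal(res$end, 2580000L)
  expect_equal(res$start, 1000000L)
})

test_that("an isolated single-SNP region degenerates to its own position", {
  G <- ld_fixture(c(5000000), c(4800000, 5200000, 5400000))
  res <- ld_boundaries(5000000, G, "1")
  expect_equal(res$start, 5000000L)
  expect_equal(res$end, 5000000L)
})

test_that("boundaries always contain the SNP span and LD beats fixed on small blocks", {
  cfg <- sim_config(seed = 95, n_per_cohort = c(150, 10), n_snps = 600,
                    n_chroms = 2, block_size_snps = 10,
                    snp_spacing_bp = 5000, within_block_r = 0.9)
  sim <- simulate_cohorts(cfg)
  G <- sim$genotypes$cohort1
  set.seed(950)
  # synthesize regions from arbitrary member SNPs
  for (i in 1:5) {
    j <- sample(nrow(G$variants), 1)
    chrom <- G$variants$chrom[j]
    on_c <- which(G$variants$chrom == chrom)
    members <- G$variants$pos[sort(unique(c(j, sample(on_c[abs(on_c - j) <= 5],
                                                      2))))]
    res <- ld_boundaries(members, G, chrom,
                         chrom_length = sim$chrom_lengths[[chrom]])
    expect_lte(res$start, min(members))
    expect_gte(res$end, max(members))
    fixed <- fixed_boundaries(min(members), max(members),
                              sim$chrom_lengths[[chrom]])
    # LD blocks span ~50 kb, far under the 500 kb flanks
    expect_lt(res$end - res$start, fixed$end - fixed$start)
    res2 <- ld_boundaries(members, G, chrom,
                          chrom_length = sim$chrom_lengths[[chrom]])
    expect_identical(res, res2)
  }
})
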