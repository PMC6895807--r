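test_that("same seed gives identical simulation output", {
  cfg <- sim_config(seed = 9, n_per_cohort = c(40, 40), n_snps = 300,
                    n_chroms = 2)
  s1 <- simulate_cohorts(cfg)
  s2 <- simulate_cohorts(cfg)
  expect_identical(s1$genotypes$cohort1$dosage, s2$genotypes$cohort1$dosage)
  expect_identical(s1$phenotypes, s2$phenotypes)
  d1 <- tempfile(); d2 <- tempfile()
  write_fixture_bundle(s1, d1)
  write_fixture_bundle(s2, d2)
  for (f in c("cohort1.vcf", "cohort2.vcf", "phenotypes.tsv", "truth.tsv",
              "genes.gff3")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("within-block Markov copying controls adjacent-SNP LD", {
  base <- function(r, seed) sim_config(seed = seed, n_per_cohort = c(1000, 10),
                                       n_snps = 400, n_chroms = 1,
                                       block_size_snps = 20,
                                       within_block_r = r,
                                       fst_between_cohorts = 0,
                                       fst_between_sections = 0,
                                       n_sections = 1)
  adj_r2 <- function(hp) {
    H <- hp$haplotypes$cohort1_section1
    blk <- hp$layout$block
    r2 <- vapply(2:ncol(H), function(j) {
      if (blk[j] != blk[j - 1]) return(NA_real_)
      if (sd(H[, j]) == 0 || sd(H[, j - 1]) == 0) return(NA_real_)
      cor(H[, j], H[, j - 1])^2
    }, numeric(1))
    mean(r2, na.rm = TRUE)
  }
  expect_lt(adj_r2(simulate_haplotypes(base(0, 21))), 0.02)
  expect_gt(adj_r2(simulate_haplotypes(base(0.9, 22))), 0.5)
})

test_that("zero Fst leaves cohorts with sampling-only frequency differences", {
  cfg <- sim_config(seed = 5, n_per_cohort = c(400, 400), n_snps = 500,
                    n_chroms = 1, fst_between_cohorts = 0,
                    fst_between_sections = 0, n_sections = 1,
                    prop_shared = 1)
  sim <- simulate_cohorts(cfg)
  p1 <- colMeans(sim$genotypes$cohort1$dosage) / 2
  p2 <- colMeans(sim$genotypes$cohort2$dosage) / 2
  fst <- hudson_fst(p1, p2, 2 * 400, 2 * 400)
  expect_lt(abs(fst), 0.01)
})

test_that("configured between-cohort Fst is recovered by the Hudson estimator", {
  cfg <- sim_config(seed = 6, n_per_cohort = c(300, 300), n_snps = 5000,
                    n_chroms = 2, fst_between_cohorts = 0.1,
                    n_sections = 1, prop_shared = 1,
                    within_block_r = 0)
  sim <- simulate_cohorts(cfg)
  p1 <- colMeans(sim$genotypes$cohort1$dosage) / 2
  p2 <- colMeans(sim$genotypes$cohort2$dosage) / 2
  fst <- hudson_fst(p1, p2, 600, 600)
  # both branches drift with variance F*p0*q0, so pairwise Hudson Fst ~ F
  expect_lt(abs(fst - 0.1) / 0.1, 0.3)
})

test_that("null configuration yields iid-normal traits", {
  cfg <- sim_config(seed = 11, n_per_cohort = c(300, 50), n_snps = 200,
                    covariate_effects = c(sex = 0, age = 0),
                    var_components = c(farm = 0, polygenic = 0, residual = 1),
                    traits = ems_traits()[3, , drop = FALSE])  # glucose
  sim <- simulate_cohorts(cfg)
  y <- sim$phenotypes$glucose[sim$phenotypes$cohort == "cohort1"]
  expect_gt(stats::shapiro.test(y)$p.value, 0.001)
  expect_lt(abs(mean(y)), 0.2)
  expect_lt(abs(sd(y) - 1), 0.2)
})

test_that("trait regression on true genetic values recovers slope one", {
  slopes <- vapply(1:20, function(i) {
    cfg <- sim_config(seed = 100 + i, n_per_cohort = c(150, 10),
                      n_snps = 400, n_chroms = 2,
                      covariate_effects = c(sex = 0, age = 0),
                      var_components = c(farm = 0, polygenic = 1,
                                         residual = 0.05),
                      traits = ems_traits()[3, , drop = FALSE])
    sim <- simulate_cohorts(cfg)
    idx <- sim$phenotypes$cohort == "cohort1"
    stats::coef(stats::lm(sim$phenotypes$glucose[idx] ~
                            sim$truth$genetic[idx, "glucose"]))[2]
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 1), 0.1)
})

test_that("binary trait prevalence matches the liability threshold", {
  cfg <- sim_config(seed = 12, n_per_cohort = c(400, 400), n_snps = 200,
                    liability_threshold = 0.8,
                    traits = ems_traits()[c(3, 12), , drop = FALSE])
  sim <- simulate_cohorts(cfg)
  prev <- mean(sim$phenotypes$laminitis)
  expect_lt(abs(prev - 0.2), 3 * sqrt(0.2 * 0.8 / 800) + 0.01)
})

test_that("causal scope controls which cohort carries the variant", {
  cfg <- sim_config(seed = 13, n_per_cohort = c(50, 50), n_snps = 200,
                    n_chroms = 1,
                    causal_spec = data.frame(
                      snp = c(30, 110), trait = c("glucose", "glucose"),
                      effect = c(1, 1),
                      scope = c("shared", "cohort1_only")),
                    traits = ems_traits()[3, , drop = FALSE])
  sim <- simulate_cohorts(cfg)
  ids <- sprintf("snp%05d", c(30, 110))
  expect_true(all(ids %in% sim$genotypes$cohort1$variants$id))
  expect_true(ids[1] %in% sim$genotypes$cohort2$variants$id)
  expect_false(ids[2] %in% sim$genotypes$cohort2$variants$id)
  # the whole block of the private SNP is private
  blk <- sim$variant_block[110]
  blk_ids <- sprintf("snp%05d", which(sim$variant_block == blk))
  expect_false(any(blk_ids %in% sim$genotypes$cohort2$variants$id))
})

test_that("fixture bundle manifest is complete and regions overlap genes", {
  cfg <- sim_config(seed = 14, n_per_cohort = c(30, 30), n_snps = 150,
                    n_chroms = 2)
  sim <- simulate_cohorts(cfg)
  dir <- tempfile()
  paths <- write_fixture_bundle(sim, dir)
  expect_true(all(file.exists(paths)))
  genes <- read_gff3(paths[["genes"]])
  # toy genes tile at 100 kb spacing with 60 kb length: any >= 100 kb
  # interval in the simulated space overlaps at least one gene
  for (chrom in names(sim$chrom_lengths)) {
    len <- sim$chrom_lengths[[chrom]]
    starts <- seq(1, len - 100000, by = 50000)
    for (s in starts[1:min(5, length(starts))]) {
      cg <- candidate_genes(chrom, s, s + 100000, genes)
      expect_gte(cg$counts[["total"]], 1)
    }
  }
})
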