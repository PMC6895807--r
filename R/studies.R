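#' Null calibration study
#'
#' Runs the full pipeline on repeated fully-null simulations (no causal
#' SNPs, no covariate, farm or polygenic variance: the trait is iid
#' residual noise) and summarizes, per seed: the Kolmogorov-Smirnov
#' uniformity p-value of the scan p-values (thinned to one SNP per
#' simulated LD block, since the KS null assumes independent draws), the
#' number of genome-wide-significant SNPs across both cohorts' full scans,
#' and the number of high-priority regions.
#'
#' @param n_seeds number of independent simulations.
#' @param base_seed seeds used are `base_seed + 1 ... base_seed + n_seeds`.
#' @param n_per_cohort,n_snps study size per simulation.
#' @return data.frame with one row per seed: `seed`, `ks_p`, `n_gw_hits`,
#'   `n_high`.
#' @export
null_calibration_study <- function(n_seeds = 20, base_seed = 1000,
                                   n_per_cohort = 300, n_snps = 10000) {
  res <- lapply(seq_len(n_seeds), function(i) {
    cfg <- sim_config(
      seed = base_seed + i,
      n_per_cohort = c(n_per_cohort, n_per_cohort), n_snps = n_snps,
      causal_spec = NULL,
      covariate_effects = c(sex = 0, age = 0),
      var_components = c(farm = 0, polygenic = 0, residual = 1),
      traits = ems_traits()[ems_traits()$trait == "glucose", , drop = FALSE]
    )
    sim <- simulate_cohorts(cfg)
    run <- run_pipeline(sim, genes = FALSE)
    rec <- run$scans$glucose$cohort1$records
    blk <- sim$variant_block[match(rec$id, sprintf("snp%05d",
                                                   seq_len(cfg$n_snps)))]
    thin <- rec$p[!duplicated(blk)]
    ks <- stats::ks.test(thin, "punif")$p.value
    gw1 <- sum(rec$p < run$scans$glucose$cohort1$thresholds$genome_wide)
    rec2 <- run$scans$glucose$cohort2$records
    gw2 <- sum(rec2$p < run$scans$glucose$cohort2$thresholds$genome_wide)
    data.frame(seed = cfg$seed, ks_p = ks, n_gw_hits = gw1 + gw2,
               n_high = unname(run$tier_counts[["high"]]))
  })
  do.call(rbind, res)
}

#' Planted-SNP recovery study
#'
#' Repeated simulations with two planted common causal variants
#' (per-alt-allele effect 1.0, residual variance 1): one shared between
#' cohorts (on the trait `insulin`) and one private to cohort 1 (on
#' `glucose`, sitting in a cohort-1-specific LD block). Per seed the full
#' pipeline is run and three recovery indicators recorded: whether the
#' shared variant's position is covered by the LD-bound interval of an
#' insulin MA-ROI; whether the private variant yields a medium-tier
#' cohort-1 region covering its position; and whether no glucose MA-ROI
#' falls within 1 Mb of the private variant.
#'
#' @inheritParams null_calibration_study
#' @param effect per-alt-allele causal effect size.
#' @return data.frame with one row per seed: `seed`, `shared_covered`,
#'   `specific_medium`, `specific_no_maroi`.
#' @export
recovery_study <- function(n_seeds = 20, base_seed = 2000,
                           n_per_cohort = 300, n_snps = 10000,
                           effect = 1.0) {
  res <- lapply(seq_len(n_seeds), function(i) {
    seed <- base_seed + i
    base_cfg <- sim_config(seed = seed,
                           n_per_cohort = c(n_per_cohort, n_per_cohort),
                           n_snps = n_snps)
    sf <- sim_site_frequencies(base_cfg)
    pick <- function(chrom) {
      cand <- which(sf$layout$chrom == chrom & abs(sf$freq - 0.5) < 0.15)
      # mid-block, mid-chromosome candidate: take the median-position one
      cand[which.min(abs(cand - stats::median(cand)))]
    }
    shared_snp <- pick("2")
    spec_snp <- pick("4")
    tr <- ems_traits()
    cfg <- sim_config(
      seed = seed, n_per_cohort = c(n_per_cohort, n_per_cohort),
      n_snps = n_snps,
      causal_spec = data.frame(
        snp = c(shared_snp, spec_snp),
        trait = c("insulin", "glucose"),
        effect = c(effect, effect),
        scope = c("shared", "cohort1_only")),
      traits = tr[tr$trait %in% c("insulin", "glucose"), , drop = FALSE]
    )
    sim <- simulate_cohorts(cfg)
    run <- run_pipeline(sim, genes = FALSE)
    shared_pos <- sf$layout$pos[shared_snp]
    spec_pos <- sf$layout$pos[spec_snp]
    ma <- run$ma_regions
    shared_cov <- !is.null(ma) && any(
      ma$trait == "insulin" & ma$is_ma_roi & ma$chrom == "2" &
        ma$ld_start <= shared_pos & ma$ld_end >= shared_pos)
    reg <- run$regions
    spec_med <- nrow(reg) > 0 && any(
      reg$trait == "glucose" & reg$cohort == "cohort1" &
        reg$tier == "medium" & reg$chrom == "4" &
        reg$ld_start <= spec_pos & reg$ld_end >= spec_pos)
    spec_no_ma <- is.null(ma) || !any(
      ma$trait == "glucose" & ma$is_ma_roi & ma$chrom == "4" &
        ma$min_snp_bp <= spec_pos + 1e6 & ma$max_snp_bp >= spec_pos - 1e6)
    data.frame(seed = seed, shared_covered = shared_cov,
               specific_medium = spec_med, specific_no_maroi = spec_no_ma)
  })
  do.call(rbind, res)
}
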