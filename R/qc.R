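#' Alt-allele frequency and MAF of a dosage vector
#'
#' @param dosages numeric vector of 0/1/2 dosages with `NA` for missing.
#' @return list with `alt_freq`, `maf`, `n_nonmissing`.
#' @export
allele_freq <- function(dosages) {
  ok <- !is.na(dosages)
  n <- sum(ok)
  if (n == 0) stop("allele frequency undefined: all dosages missing")
  f <- sum(dosages[ok]) / (2 * n)
  list(alt_freq = f, maf = min(f, 1 - f), n_nonmissing = n)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test: given the observed allele counts, the p-value is
#' the sum of probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count. Monomorphic
#' sites return p = 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total > 0).
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("total genotype count must be > 0")
  n_A <- 2 * n_AA + n_Aa
  n_a <- 2 * n_aa + n_Aa
  if (n_A == 0 || n_a == 0) return(1)
  rare <- min(n_A, n_a)
  # feasible heterozygote counts share the parity of the rare allele count
  het <- seq(rare %% 2, rare, by = 2)
  # log P(het | allele counts) up to a shared constant
  logp <- het * log(2) - lfactorial((n_A - het) / 2) - lfactorial(het) -
    lfactorial((n_a - het) / 2)
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  obs <- prob[match(n_Aa, het)]
  min(1, sum(prob[prob <= obs * (1 + 1e-9)]))
}

#' Default QC thresholds
#'
#' @param sample_call_rate samples kept when call rate exceeds this (> 0.95).
#' @param snp_call_rate SNPs dropped when call rate is below this (< 0.90).
#' @param maf SNPs dropped when MAF is below this (< 0.01).
#' @param hwe_p SNPs dropped when the exact HWE p-value is below this.
#' @return named list of thresholds.
#' @export
qc_thresholds <- function(sample_call_rate = 0.95, snp_call_rate = 0.90,
                          maf = 0.01, hwe_p = 1e-5) {
  list(sample_call_rate = sample_call_rate, snp_call_rate = snp_call_rate,
       maf = maf, hwe_p = hwe_p)
}

#' Genotype quality control
#'
#' Filters are applied in a fixed order: (1) drop samples whose call rate
#' does not exceed the sample threshold; (2) drop SNPs with call rate below
#' the SNP threshold; (3) drop SNPs with MAF below the MAF threshold;
#' (4) drop SNPs with exact HWE p-value below the HWE threshold. Later
#' steps see the data as filtered by earlier steps.
#'
#' @param G a [genotype_matrix()].
#' @param thresholds list from [qc_thresholds()].
#' @return list with `genotypes` (filtered matrix) and `report`
#'   (data.frame of per-step removals, with a `thresholds` attribute).
#' @export
qc_filter <- function(G, thresholds = qc_thresholds()) {
  stopifnot(inherits(G, "genotype_matrix"))
  th <- thresholds
  n0 <- length(G$samples); m0 <- nrow(G$variants)

  sample_cr <- rowMeans(!is.na(G$dosage))
  keep_s <- sample_cr > th$sample_call_rate
  G <- subset_genotypes(G, samples = keep_s)
  rem_sample <- sum(!keep_s)

  snp_cr <- colMeans(!is.na(G$dosage))
  keep1 <- snp_cr >= th$snp_call_rate
  G <- subset_genotypes(G, variants = keep1)
  rem_cr <- sum(!keep1)

  nm <- colSums(!is.na(G$dosage))
  f <- colSums(G$dosage, na.rm = TRUE) / (2 * pmax(nm, 1))
  maf <- pmin(f, 1 - f)
  maf[nm == 0] <- 0
  keep2 <- maf >= th$maf
  G <- subset_genotypes(G, variants = keep2)
  rem_maf <- sum(!keep2)

  hwe_p <- vapply(seq_len(ncol(G$dosage)), function(j) {
    d <- G$dosage[, j]
    hwe_exact_test(sum(d == 0, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
                   sum(d == 2, na.rm = TRUE))
  }, numeric(1))
  keep3 <- hwe_p >= th$hwe_p
  G <- subset_genotypes(G, variants = keep3)
  rem_hwe <- sum(!keep3)

  if (nrow(G$variants) == 0) warning("all SNPs removed by QC")
  report <- data.frame(
    step = c("sample_call_rate", "snp_call_rate", "maf", "hwe"),
    axis = c("sample", "snp", "snp", "snp"),
    removed = c(rem_sample, rem_cr, rem_maf, rem_hwe),
    remaining = c(n0 - rem_sample,
                  m0 - rem_cr,
                  m0 - rem_cr - rem_maf,
                  m0 - rem_cr - rem_maf - rem_hwe),
    stringsAsFactors = FALSE
  )
  attr(report, "thresholds") <- th
  list(genotypes = G, report = report)
}
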