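#' Align per-cohort summary statistics for meta-analysis
#'
#' Joins two or more cohorts' association records on (chrom, pos), keeping
#' only SNPs present in all cohorts. When ref/alt are swapped between
#' cohorts the effect sign is flipped; irreconcilable allele pairs are
#' dropped (count reported in attribute `dropped_alleles`).
#'
#' @param stats_list named list (>= 2) of association record data.frames
#'   (`chrom`, `pos`, `id`, `ref`, `alt`, `beta`, `se`, `p`, `n`).
#' @return data.frame with `chrom`, `pos`, `id`, `ref`, `alt` (first
#'   cohort's orientation) and `beta_<k>`, `se_<k>`, `p_<k>` per cohort.
#' @export
align_alleles <- function(stats_list) {
  stopifnot(length(stats_list) >= 2)
  if (is.null(names(stats_list))) {
    names(stats_list) <- paste0("cohort", seq_along(stats_list))
  }
  base <- stats_list[[1]]
  base$key <- paste(base$chrom, base$pos)
  out <- data.frame(chrom = base$chrom, pos = base$pos, id = base$id,
                    ref = base$ref, alt = base$alt, key = base$key,
                    stringsAsFactors = FALSE)
  nm1 <- names(stats_list)[1]
  out[[paste0("beta_", nm1)]] <- base$beta
  out[[paste0("se_", nm1)]] <- base$se
  out[[paste0("p_", nm1)]] <- base$p
  dropped <- 0L
  for (k in 2:length(stats_list)) {
    nm <- names(stats_list)[k]
    s <- stats_list[[k]]
    s$key <- paste(s$chrom, s$pos)
    m <- match(out$key, s$key)
    keep <- !is.na(m)
    out <- out[keep, , drop = FALSE]
    s <- s[m[keep], , drop = FALSE]
    same <- s$ref == out$ref & s$alt == out$alt
    swap <- s$ref == out$alt & s$alt == out$ref
    bad <- !(same | swap)
    dropped <- dropped + sum(bad)
    out <- out[!bad, , drop = FALSE]
    s <- s[!bad, , drop = FALSE]
    beta <- ifelse(swap[!bad], -s$beta, s$beta)
    out[[paste0("beta_", nm)]] <- beta
    out[[paste0("se_", nm)]] <- s$se
    out[[paste0("p_", nm)]] <- s$p
  }
  out$key <- NULL
  rownames(out) <- NULL
  attr(out, "dropped_alleles") <- dropped
  out
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' @param betas,ses numeric vectors (one study per element) or matrices
#'   (one SNP per row, one study per column).
#' @return list with `beta`, `se`, `z`, `p` (scalars or vectors).
#' @export
fe_meta <- function(betas, ses) {
  b <- rbind_as_matrix(betas); s <- rbind_as_matrix(ses)
  if (ncol(b) < 2) stop("need >= 2 studies")
  if (any(s <= 0) || any(!is.finite(s))) stop("standard errors must be finite and > 0")
  w <- 1 / s^2
  sw <- rowSums(w)
  beta <- rowSums(w * b) / sw
  se <- 1 / sqrt(sw)
  z <- beta / se
  p <- pmin(2 * stats::pnorm(abs(z), lower.tail = FALSE), 1)
  p[p == 0] <- .Machine$double.xmin
  drop_if_scalar(list(beta = beta, se = se, z = z, p = p),
                 is.null(dim(betas)))
}

rbind_as_matrix <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)
drop_if_scalar <- function(lst, scalar) {
  if (scalar) lapply(lst, as.numeric) else lst
}

#' Cochran's Q and DerSimonian-Laird tau-squared
#'
#' Method-of-moments between-study variance, floored at zero (reported
#' alongside the profile-likelihood RE2 test, which maximizes tau-squared
#' independently).
#'
#' @inheritParams fe_meta
#' @return list with `Q` and `tau2`.
#' @export
dl_tau2 <- function(betas, ses) {
  b <- rbind_as_matrix(betas); s <- rbind_as_matrix(ses)
  k <- ncol(b)
  w <- 1 / s^2
  sw <- rowSums(w)
  beta_fe <- rowSums(w * b) / sw
  Q <- rowSums(w * (b - beta_fe)^2)
  denom <- sw - rowSums(w^2) / sw
  tau2 <- pmax((Q - (k - 1)) / denom, 0)
  drop_if_scalar(list(Q = Q, tau2 = tau2), is.null(dim(betas)))
}

#' Random-effects meta-analysis with heterogeneity under the alternative
#'
#' Likelihood-ratio test of `H0: mu = 0, tau2 = 0` against
#' `H1: mu free, tau2 >= 0` in the independent-normals model
#' `beta_i ~ N(mu, se_i^2 + tau2)`. Under the null both the mean effect and
#' the heterogeneity vanish, so the statistic captures association through
#' either a shared effect or between-study heterogeneity. The alternative
#' is maximized by profiling `mu` out analytically and searching `tau2` on
#' a log grid (1e-8 to 10 x max se^2, 200 points, plus tau2 = 0) refined by
#' golden-section search. The p-value uses the asymptotic null mixture
#' `0.5 chi2(1) + 0.5 chi2(2)`.
#'
#' @inheritParams fe_meta
#' @return list with `stat` (the LRT statistic) and `p`.
#' @export
re2_meta <- function(betas, ses) {
  b <- rbind_as_matrix(betas); s <- rbind_as_matrix(ses)
  if (ncol(b) < 2) stop("need >= 2 studies")
  if (any(s <= 0) || any(!is.finite(s)) || any(!is.finite(b))) {
    stop("effects and standard errors must be finite, se > 0")
  }
  v <- s^2
  nsnp <- nrow(b)

  # profile log-likelihood at per-SNP tau2, mu profiled out analytically
  prof_at <- function(tau2_vec) {
    vv <- v + tau2_vec
    w <- 1 / vv
    mu <- rowSums(w * b) / rowSums(w)
    -0.5 * rowSums(log(vv) + w * (b - mu)^2)
  }

  ll0 <- -0.5 * rowSums(log(v) + b^2 / v)
  tau_max <- 10 * apply(v, 1, max) + apply(b, 1, function(x) max(x^2))
  grid <- exp(seq(log(1e-8), log(1), length.out = 200))
  best_ll <- prof_at(rep(0, nsnp))
  best_tau <- rep(0, nsnp)
  for (gfrac in grid) {
    tau <- gfrac * tau_max
    ll <- prof_at(tau)
    upd <- ll > best_ll
    best_ll[upd] <- ll[upd]
    best_tau[upd] <- tau[upd]
  }
  # vectorized golden-section refinement around the best grid point
  gr <- (sqrt(5) - 1) / 2
  lo <- pmax(best_tau * exp(-0.1), 0)
  hi <- ifelse(best_tau == 0, grid[1] * tau_max, best_tau * exp(0.1))
  a <- lo; bb <- hi
  c1 <- bb - gr * (bb - a); c2 <- a + gr * (bb - a)
  f1 <- prof_at(c1); f2 <- prof_at(c2)
  for (it in 1:60) {
    left <- f1 > f2
    bb[left] <- c2[left]
    a[!left] <- c1[!left]
    c1 <- bb - gr * (bb - a); c2 <- a + gr * (bb - a)
    f1 <- prof_at(c1); f2 <- prof_at(c2)
  }
  ref_ll <- pmax(f1, f2)
  upd <- ref_ll > best_ll
  best_ll[upd] <- ref_ll[upd]
  stat <- pmax(2 * (best_ll - ll0), 0)
  p <- 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE) +
    0.5 * stats::pchisq(stat, df = 2, lower.tail = FALSE)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  drop_if_scalar(list(stat = stat, p = p), is.null(dim(betas)))
}

#' Per-SNP meta-analysis table
#'
#' Adds fixed-effects, heterogeneity and RE2 columns to an aligned
#' multi-cohort table.
#'
#' @param aligned output of [align_alleles()].
#' @return the input with columns `beta_fe`, `se_fe`, `z_fe`, `p_fe`, `Q`,
#'   `tau2`, `re2_stat`, `p_re2` appended.
#' @export
meta_analyze <- function(aligned) {
  bcols <- grep("^beta_", names(aligned), value = TRUE)
  scols <- sub("^beta_", "se_", bcols)
  b <- as.matrix(aligned[, bcols, drop = FALSE])
  s <- as.matrix(aligned[, scols, drop = FALSE])
  fe <- fe_meta(b, s)
  ht <- dl_tau2(b, s)
  re <- re2_meta(b, s)
  aligned$beta_fe <- fe$beta
  aligned$se_fe <- fe$se
  aligned$z_fe <- fe$z
  aligned$p_fe <- fe$p
  aligned$Q <- ht$Q
  aligned$tau2 <- ht$tau2
  aligned$re2_stat <- re$stat
  aligned$p_re2 <- re$p
  aligned
}

#' Meta-analysis significance thresholds
#'
#' Genome-wide threshold `alpha / max(M_e per cohort on shared SNPs)`: the
#' larger effective count gives the more conservative threshold.
#'
#' @param m_effective_shared numeric vector: per-cohort effective test
#'   counts computed on the shared SNP set.
#' @param alpha,suggestive threshold parameters.
#' @return list with `genome_wide`, `suggestive`, `m_used`.
#' @export
meta_thresholds <- function(m_effective_shared, alpha = 0.05,
                            suggestive = 1e-5) {
  stopifnot(all(m_effective_shared > 0))
  m <- max(m_effective_shared)
  list(genome_wide = alpha / m, suggestive = suggestive, m_used = m)
}

#' Call meta-analysis regions of interest
#'
#' Clusters suggestive meta-analysis SNPs (RE2 p below the suggestive
#' threshold, 500 kb chaining) and flags a cluster as MA-ROI when at least
#' one SNP lies strictly below the genome-wide threshold. Single-SNP
#' regions are permitted at the meta stage.
#'
#' @param meta data.frame from [meta_analyze()].
#' @param thresholds list from [meta_thresholds()].
#' @param gap_bp chaining distance (default 500 kb).
#' @return data.frame of meta regions with `is_ma_roi`.
#' @export
call_ma_roi <- function(meta, thresholds, gap_bp = 5e5) {
  rec <- data.frame(chrom = meta$chrom, pos = meta$pos, p = meta$p_re2,
                    stringsAsFactors = FALSE)
  reg <- cluster_suggestive_snps(rec, thresholds$suggestive,
                                 thresholds$genome_wide, gap_bp = gap_bp,
                                 min_suggestive_roi = 1L)
  if (nrow(reg) == 0) {
    reg$is_ma_roi <- logical(0)
    return(reg)
  }
  reg$is_ma_roi <- reg$n_significant >= 1L
  reg
}
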