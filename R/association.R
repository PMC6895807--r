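#' Genetic relationship matrix from standardized dosages
#'
#' `K = Z Z' / M` with `Z` the column-standardized dosage matrix (mean 0,
#' variance 1 per SNP). Missing dosages are mean-imputed per SNP for this
#' computation only; zero-variance SNPs are excluded.
#'
#' @param G a [genotype_matrix()] (typically QC'd).
#' @return symmetric n x n matrix with sample ids as dimnames and the SNP
#'   count used as attribute `m_snps`.
#' @export
compute_grm <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  Z <- mean_impute(G$dosage)
  v <- apply(Z, 2, stats::var)
  Z <- Z[, v > 0, drop = FALSE]
  if (ncol(Z) == 0) stop("no polymorphic SNPs available for the GRM")
  Z <- scale(Z)
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(G$samples, G$samples)
  attr(K, "m_snps") <- ncol(Z)
  K
}

mean_impute <- function(dosage) {
  if (!anyNA(dosage)) return(dosage)
  mu <- colMeans(dosage, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(dosage), arr.ind = TRUE)
  dosage[idx] <- mu[idx[, 2]]
  dosage
}

#' REML fit of the null mixed model
#'
#' Fits `y = X beta + g + e`, `g ~ N(0, sigma2_g K)`, `e ~ N(0, sigma2_e I)`
#' by spectral decomposition of `K`: the restricted likelihood is profiled
#' over the variance ratio `delta = sigma2_e / sigma2_g` on a 100-point log
#' grid over [1e-5, 1e5], then refined by golden-section search until
#' successive log-likelihoods differ by < 1e-8. After rotation by the
#' eigenvectors each evaluation is O(n).
#'
#' @param y numeric response (typically a residualized trait).
#' @param K GRM from [compute_grm()].
#' @param X fixed-effect design matrix; default intercept only.
#' @return list of class `null_lmm` with `sigma2_g`, `sigma2_e`, `delta`,
#'   `h2`, `loglik` (restricted, up to an additive constant) and the
#'   eigendecomposition cache used by [lmm_scan()].
#' @export
fit_null_lmm <- function(y, K, X = NULL) {
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  q <- ncol(X)
  eig <- eigen(K, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  if (min(eig$values) < -1e-6 * max(abs(eig$values))) {
    warning("GRM has a noticeably negative eigenvalue; clamped to 0")
  }
  U <- eig$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  logdet_XtX <- determinant(crossprod(X), logarithm = TRUE)$modulus

  reml <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (lambda + delta)
    XtWX <- crossprod(Xt, Xt * w)
    XtWy <- crossprod(Xt, yt * w)
    beta <- solve(XtWX, XtWy)
    r <- yt - Xt %*% beta
    rss <- sum(w * r^2)
    ld_XtWX <- determinant(XtWX, logarithm = TRUE)$modulus
    -0.5 * ((n - q) * log(rss) + sum(log(lambda + delta)) +
              ld_XtWX - logdet_XtX)
  }

  grid <- seq(log(1e-5), log(1e5), length.out = 100)
  vals <- vapply(grid, reml, numeric(1))
  if (any(!is.finite(vals))) stop("non-finite restricted likelihood at delta = ",
                                  signif(exp(grid[which(!is.finite(vals))[1]]), 3))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- reml(c1); f2 <- reml(c2)
  repeat {
    if (abs(f1 - f2) < 1e-8 && abs(b - a) < 1e-6) break
    if (f1 > f2) { b <- c2; c2 <- c1; f2 <- f1
                   c1 <- b - gr * (b - a); f1 <- reml(c1)
    } else { a <- c1; c1 <- c2; f1 <- f2
             c2 <- a + gr * (b - a); f2 <- reml(c2) }
    if (abs(b - a) < 1e-10) break
  }
  log_delta <- if (f1 > f2) c1 else c2
  delta <- exp(log_delta)
  w <- 1 / (lambda + delta)
  XtWX <- crossprod(Xt, Xt * w)
  beta <- solve(XtWX, crossprod(Xt, yt * w))
  r <- yt - Xt %*% beta
  sigma2_g <- sum(w * r^2) / (n - q)
  sigma2_e <- delta * sigma2_g
  structure(list(
    sigma2_g = sigma2_g, sigma2_e = sigma2_e, delta = delta,
    h2 = sigma2_g / (sigma2_g + sigma2_e),
    loglik = max(f1, f2),
    reml_fun = reml,
    eigen = list(values = lambda, vectors = U),
    yt = as.numeric(yt), Xt = Xt
  ), class = "null_lmm")
}

#' Mixed-model association scan
#'
#' EMMAX-style scan: the variance ratio `delta` from the null fit is held
#' fixed across SNPs and each SNP is tested by generalized least squares in
#' the eigenrotated space (intercept + SNP), giving the per-alt-allele
#' effect, its standard error and a 1-df Wald chi-square p-value. Missing
#' dosages are mean-imputed per SNP; zero-variance SNPs are skipped.
#'
#' @param y numeric response, same samples (and order) as `G`.
#' @param G a [genotype_matrix()].
#' @param null_fit a [fit_null_lmm()] result computed from the same `y`.
#' @return data.frame of association records (`chrom`, `pos`, `id`, `ref`,
#'   `alt`, `beta`, `se`, `p`, `n`), one row per testable SNP; skipped SNP
#'   ids are recorded in attribute `skipped`.
#' @export
lmm_scan <- function(y, G, null_fit) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(null_fit, "null_lmm"))
  n <- length(y)
  U <- null_fit$eigen$vectors
  w <- 1 / (null_fit$eigen$values + null_fit$delta)
  Z <- mean_impute(G$dosage)
  v <- matrixStats_colVars(Z)
  testable <- v > 0
  Zt <- crossprod(U, Z[, testable, drop = FALSE])
  ones_t <- crossprod(U, rep(1, n))
  yt <- crossprod(U, y)

  a11 <- sum(w * ones_t^2)
  a12 <- as.numeric(crossprod(Zt * w, ones_t))
  a22 <- colSums(Zt^2 * w)
  b1 <- sum(w * ones_t * yt)
  b2 <- as.numeric(crossprod(Zt * w, yt))
  syy <- sum(w * yt^2)
  det2 <- a11 * a22 - a12^2
  beta <- (a11 * b2 - a12 * b1) / det2
  alpha <- (b1 - a12 * beta) / a11
  rss <- pmax(syy - alpha * b1 - beta * b2, 0)
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 * a11 / det2)
  chi2 <- (beta / se)^2
  p <- pmin(stats::pchisq(chi2, df = 1, lower.tail = FALSE), 1)
  p[p == 0] <- .Machine$double.xmin
  vdf <- G$variants[testable, , drop = FALSE]
  out <- data.frame(chrom = vdf$chrom, pos = vdf$pos, id = vdf$id,
                    ref = vdf$ref, alt = vdf$alt,
                    beta = beta, se = se, p = p, n = n,
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- G$variants$id[!testable]
  out
}

matrixStats_colVars <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}

#' Effective number of independent tests
#'
#' Eigenvalue-based LD correction computed in non-overlapping
#' within-chromosome blocks of `block_size` consecutive SNPs: for each block
#' the eigenvalues of the SNP dosage correlation matrix contribute
#' `1(lambda >= 1) + (lambda - floor(lambda))`, and the total is the sum
#' over blocks. Fully duplicated SNP pairs give exactly M/2; mutually
#' independent SNPs give close to M.
#'
#' @param G a [genotype_matrix()].
#' @param block_size SNPs per block (default 200).
#' @return effective test count `M_e` (<= number of SNPs).
#' @export
effective_tests <- function(G, block_size = 200) {
  stopifnot(inherits(G, "genotype_matrix"))
  Z <- mean_impute(G$dosage)
  total <- 0
  for (chrom in unique(G$variants$chrom)) {
    idx <- which(G$variants$chrom == chrom)
    starts <- seq(1, length(idx), by = block_size)
    for (s in starts) {
      cols <- idx[s:min(s + block_size - 1, length(idx))]
      if (length(cols) < 2) { total <- total + length(cols); next }
      B <- Z[, cols, drop = FALSE]
      v <- matrixStats_colVars(B)
      n_const <- sum(v == 0)
      B <- B[, v > 0, drop = FALSE]
      if (ncol(B) < 2) { total <- total + ncol(B) + n_const; next }
      lam <- eigen(stats::cor(B), symmetric = TRUE, only.values = TRUE)$values
      # guard the floor() against eigenvalues an epsilon below an integer
      lam <- pmax(round(lam, 8), 0)
      total <- total + sum((lam >= 1) + (lam - floor(lam))) + n_const
    }
  }
  min(total, nrow(G$variants))
}

#' Bonferroni thresholds from the effective test count
#'
#' @param m_effective effective number of independent tests (> 0).
#' @param alpha family-wise error rate (default 0.05).
#' @param suggestive fixed suggestive threshold (default 1e-5).
#' @return list with `genome_wide` (= alpha / m_effective) and `suggestive`.
#' @export
significance_thresholds <- function(m_effective, alpha = 0.05,
                                    suggestive = 1e-5) {
  stopifnot(m_effective > 0)
  list(genome_wide = alpha / m_effective, suggestive = suggestive)
}

#' Full single-cohort scan for one trait
#'
#' Convenience wrapper: GRM (optional, reused if given), null REML fit,
#' EMMAX scan, effective-test count and thresholds.
#'
#' @param y residualized trait values aligned with `G`.
#' @param G QC'd [genotype_matrix()].
#' @param trait,cohort labels carried into the result.
#' @param K optional precomputed GRM.
#' @param m_effective optional precomputed effective test count.
#' @param block_size block size for [effective_tests()].
#' @param alpha,suggestive threshold parameters.
#' @return list of class `gwas_scan`: `trait`, `cohort`, `records`,
#'   `m_effective`, `thresholds`, `null_fit` summary.
#' @export
gwas_scan <- function(y, G, trait = "trait", cohort = "cohort", K = NULL,
                      m_effective = NULL, block_size = 200, alpha = 0.05,
                      suggestive = 1e-5) {
  if (is.null(K)) K <- compute_grm(G)
  nf <- fit_null_lmm(y, K)
  rec <- lmm_scan(y, G, nf)
  if (is.null(m_effective)) m_effective <- effective_tests(G, block_size)
  th <- significance_thresholds(m_effective, alpha, suggestive)
  structure(list(trait = trait, cohort = cohort, records = rec,
                 m_effective = m_effective, thresholds = th,
                 h2 = nf$h2, sigma2_g = nf$sigma2_g, sigma2_e = nf$sigma2_e),
            class = "gwas_scan")
}

#' @export
print.gwas_scan <- function(x, ...) {
  cat(sprintf("gwas_scan: %s / %s, %d SNPs, Me = %.1f, gw p < %.3g, h2 = %.2f\n",
              x$trait, x$cohort, nrow(x$records), x$m_effective,
              x$thresholds$genome_wide, x$h2))
  invisible(x)
}

#' Union of suggestive SNPs across nested sub-cohort scans
#'
#' A SNP is in the union when it exceeds the suggestive threshold in any of
#' the scans; flags record the cohorts in which it was suggestive and
#' whether it was genome-wide significant anywhere (each scan judged
#' against its own thresholds). Records are aligned on
#' (chrom, pos, ref, alt); unmatched variants are dropped with a warning.
#'
#' @param scans list of `gwas_scan` objects for the same trait.
#' @return data.frame with `chrom`, `pos`, `id`, `p_min`, `best_cohort`,
#'   `suggestive_in` (comma-separated cohort labels), `is_suggestive`,
#'   `is_significant`; suggestive SNPs only.
#' @export
cohort_union <- function(scans) {
  stopifnot(length(scans) >= 1)
  traits <- unique(vapply(scans, function(s) s$trait, character(1)))
  if (length(traits) > 1) stop("cohort_union requires a single trait; got: ",
                               paste(traits, collapse = ", "))
  keys <- lapply(scans, function(s) {
    with(s$records, paste(chrom, pos, ref, alt))
  })
  all_keys <- unique(unlist(keys))
  in_all <- Reduce(intersect, keys)
  if (length(in_all) < length(all_keys)) {
    warning(length(all_keys) - length(in_all),
            " variant(s) not present in every scan were kept where observed")
  }
  rows <- list()
  for (s in scans) {
    r <- s$records
    r$is_sugg <- r$p < s$thresholds$suggestive
    r$is_sig <- r$p < s$thresholds$genome_wide
    r$cohort <- s$cohort
    rows[[length(rows) + 1]] <-
      r[, c("chrom", "pos", "id", "p", "cohort", "is_sugg", "is_sig")]
  }
  all <- do.call(rbind, rows)
  all$key <- paste(all$chrom, all$pos)
  sugg_keys <- unique(all$key[all$is_sugg])
  if (length(sugg_keys) == 0) {
    return(data.frame(chrom = character(), pos = integer(), id = character(),
                      p_min = numeric(), best_cohort = character(),
                      suggestive_in = character(), is_suggestive = logical(),
                      is_significant = logical(), stringsAsFactors = FALSE))
  }
  sub <- all[all$key %in% sugg_keys, , drop = FALSE]
  agg <- lapply(split(sub, sub$key), function(d) {
    i <- which.min(d$p)
    data.frame(chrom = d$chrom[1], pos = d$pos[1], id = d$id[1],
               p_min = d$p[i], best_cohort = d$cohort[i],
               suggestive_in = paste(sort(unique(d$cohort[d$is_sugg])),
                                     collapse = ","),
               is_suggestive = TRUE,
               is_significant = any(d$is_sig),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(chrom_rank(out$chrom), out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
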