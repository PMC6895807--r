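# Independent brute-force oracles used to cross-check the implementation.

# Exact HWE conditional probability of each heterozygote count, from the
# closed-form hypergeometric-style expression, fully normalized.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_A <- 2 * n_AA + n_Aa
  n_a <- 2 * n_aa + n_Aa
  if (n_A == 0 || n_a == 0) return(1)
  hets <- seq(min(n_A, n_a) %% 2, min(n_A, n_a), by = 2)
  logp <- vapply(hets, function(h) {
    lfactorial(n) - lfactorial((n_A - h) / 2) - lfactorial(h) -
      lfactorial((n_a - h) / 2) + h * log(2) +
      lfactorial(n_A) + lfactorial(n_a) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[hets == n_Aa]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

# Dense two-dimensional grid maximization of the RE2 alternative
# likelihood, independent of the package's profile search.
re2_oracle <- function(b, s, n_mu = 400, n_tau = 400) {
  ll <- function(mu, t2) sum(stats::dnorm(b, mu, sqrt(s^2 + t2), log = TRUE))
  ll0 <- ll(0, 0)
  mu_grid <- seq(-2 * max(abs(b)) - 1, 2 * max(abs(b)) + 1,
                 length.out = n_mu)
  tau_grid <- c(0, exp(seq(log(1e-8), log(10 * max(s^2) + 4 * max(b^2)),
                           length.out = n_tau)))
  best <- -Inf
  for (t2 in tau_grid) {
    vals <- vapply(mu_grid, ll, numeric(1), t2 = t2)
    best <- max(best, max(vals))
  }
  2 * (best - ll0)
}

# Transitive closure of the <= gap_bp adjacency relation among suggestive
# SNPs: connected components by label propagation on sorted positions.
cluster_oracle <- function(chrom, pos, gap_bp = 5e5) {
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]
  n <- length(pos)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (chrom[i] == chrom[j] && abs(pos[i] - pos[j]) <= gap_bp &&
            comp[j] > comp[i]) {
          comp[j] <- comp[i]; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  # return component sizes and spans keyed by component, in genome order
  split(pos, comp)
}

# Hudson Fst estimator averaged over SNPs (ratio of averages).
hudson_fst <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# Small deterministic genotype matrix fixture.
toy_genotypes <- function(n = 6, m = 4, seed = 42, chrom = "1",
                          spacing = 1000L) {
  set.seed(seed)
  dos <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  genotype_matrix(
    dos,
    data.frame(chrom = chrom, pos = spacing * seq_len(m),
               id = paste0("v", seq_len(m)), ref = "A", alt = "G",
               stringsAsFactors = FALSE),
    paste0("s", seq_len(n))
  )
}
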