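#' Cluster suggestive SNPs into regions
#'
#' SNPs below the suggestive threshold are greedily chained along each
#' chromosome: a suggestive SNP joins the current cluster when the gap to
#' the previous suggestive SNP is at most `gap_bp` (default 500 kb).
#' Cluster-level counts of suggestive and genome-wide-significant SNPs are
#' recorded, and a cluster is a region of interest (ROI) when it holds at
#' least `min_suggestive_roi` suggestive SNPs (default 5) and at least one
#' genome-wide-significant SNP.
#'
#' Instead of p-values plus thresholds, precomputed logical columns
#' `is_suggestive` / `is_significant` may be supplied (used for
#' nested-cohort unions where each scan has its own thresholds).
#'
#' @param records data.frame with `chrom`, `pos` and either `p` or the two
#'   logical flag columns; need not be pre-sorted.
#' @param suggestive_p,sig_p thresholds applied to `p` (strict `<`).
#' @param gap_bp chaining distance.
#' @param min_suggestive_roi minimum suggestive SNPs for ROI status.
#' @return data.frame with `chrom`, `min_snp_bp`, `max_snp_bp`,
#'   `n_suggestive`, `n_significant`, `is_roi` and a list column
#'   `snp_pos` of member positions.
#' @export
cluster_suggestive_snps <- function(records, suggestive_p = 1e-5,
                                    sig_p = NULL, gap_bp = 5e5,
                                    min_suggestive_roi = 5L) {
  if (!all(c("is_suggestive", "is_significant") %in% names(records))) {
    stopifnot("p" %in% names(records), !is.null(sig_p))
    records$is_suggestive <- records$p < suggestive_p
    records$is_significant <- records$p < sig_p
  }
  empty <- data.frame(chrom = character(), min_snp_bp = integer(),
                      max_snp_bp = integer(), n_suggestive = integer(),
                      n_significant = integer(), is_roi = logical(),
                      stringsAsFactors = FALSE)
  empty$snp_pos <- list()
  sug <- records[records$is_suggestive, , drop = FALSE]
  if (nrow(sug) == 0) return(empty)
  sug <- sug[order(chrom_rank(sug$chrom), sug$pos), , drop = FALSE]
  new_cluster <- c(TRUE, sug$chrom[-1] != sug$chrom[-nrow(sug)] |
                     diff(sug$pos) > gap_bp)
  cl <- cumsum(new_cluster)
  out <- lapply(split(sug, cl), function(d) {
    r <- data.frame(chrom = d$chrom[1],
                    min_snp_bp = min(d$pos), max_snp_bp = max(d$pos),
                    n_suggestive = nrow(d),
                    n_significant = sum(d$is_significant),
                    stringsAsFactors = FALSE)
    r$is_roi <- r$n_suggestive >= min_suggestive_roi & r$n_significant >= 1L
    r$snp_pos <- list(d$pos)
    r
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fixed-size region boundaries
#'
#' SNP span extended by 500 kb on each side, clipped to [1, chromosome
#' length]; the unclipped width is always span + 1 Mb.
#'
#' @param min_snp_bp,max_snp_bp region SNP span (vectors allowed).
#' @param chrom_length chromosome length(s) in bp (default unbounded).
#' @param flank_bp one-sided extension (default 500 kb).
#' @return data.frame with `start`, `end` (1-based inclusive).
#' @export
fixed_boundaries <- function(min_snp_bp, max_snp_bp, chrom_length = Inf,
                             flank_bp = 5e5) {
  stopifnot(all(min_snp_bp <= max_snp_bp))
  data.frame(start = as.integer(pmax(1, min_snp_bp - flank_bp)),
             end = as.integer(pmin(chrom_length, max_snp_bp + flank_bp)))
}

#' Composite LD between two dosage vectors
#'
#' Squared Pearson correlation of unphased dosages over jointly non-missing
#' samples. Undefined (zero variance or < 2 complete pairs) returns `NA`,
#' treated downstream as not in LD.
#'
#' @param dosage_i,dosage_j numeric dosage vectors of equal length.
#' @return r-squared in [0, 1], or `NA`.
#' @export
pairwise_r2 <- function(dosage_i, dosage_j) {
  ok <- !is.na(dosage_i) & !is.na(dosage_j)
  if (sum(ok) < 2) return(NA_real_)
  x <- dosage_i[ok]; y <- dosage_j[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' LD-bound region boundaries
#'
#' Starting from a window of `window_bp` beyond the region's SNP span,
#' every window SNP is marked in-LD when its maximum r-squared against any
#' of the region's member SNPs exceeds `r2_thresh` (member SNPs are in-LD
#' by definition). The widest contiguous in-LD run (bp extent; ties broken
#' by SNP count, then 5'-most) intersecting the SNP span is then extended
#' outward, absorbing further in-LD SNPs, until a stretch of at least
#' `gap_bp` free of in-LD SNPs is found on each side; the boundaries are
#' the outermost in-LD SNP positions before each gap. If a gap cannot be
#' certified before the window edge the window grows by 1 Mb and the
#' procedure repeats; at the chromosome ends the boundary is clipped with a
#' warning. The returned interval always contains the SNP span.
#'
#' @param region_pos positions of the region's member (suggestive) SNPs.
#' @param G [genotype_matrix()] providing dosages for LD.
#' @param chrom chromosome of the region.
#' @param r2_thresh in-LD threshold, strict `> 0.3` by default.
#' @param gap_bp required LD-free stretch (default 100 kb).
#' @param window_bp initial one-sided window (default 1 Mb).
#' @param chrom_length chromosome length for clipping.
#' @return list with `start`, `end`, `window_used`.
#' @export
ld_boundaries <- function(region_pos, G, chrom, r2_thresh = 0.3,
                          gap_bp = 1e5, window_bp = 1e6,
                          chrom_length = Inf) {
  stopifnot(inherits(G, "genotype_matrix"), length(region_pos) >= 1)
  span_lo <- min(region_pos); span_hi <- max(region_pos)
  on_chrom <- which(G$variants$chrom == chrom)
  if (length(on_chrom) == 0) stop("no SNPs on chromosome ", chrom)
  pos_all <- G$variants$pos[on_chrom]
  member <- on_chrom[pos_all %in% region_pos]
  if (length(member) == 0) stop("region SNPs not present in genotype matrix")
  Dm <- mean_impute(G$dosage[, member, drop = FALSE])

  W <- window_bp
  repeat {
    w_lo <- span_lo - W; w_hi <- span_hi + W
    idx <- on_chrom[pos_all >= w_lo & pos_all <= w_hi]
    pos <- G$variants$pos[idx]
    Dw <- mean_impute(G$dosage[, idx, drop = FALSE])
    r2max <- max_r2_vs(Dw, Dm)
    in_ld <- (!is.na(r2max) & r2max > r2_thresh) | pos %in% region_pos

    ld_pos <- pos[in_ld]
    if (length(ld_pos) == 0) ld_pos <- region_pos
    # contiguous runs of in-LD SNPs in window SNP order
    flag <- in_ld
    run_id <- cumsum(c(TRUE, diff(flag) != 0))
    runs <- lapply(split(seq_along(flag)[flag], run_id[flag]), function(ii) {
      c(first = pos[ii[1]], last = pos[ii[length(ii)]], n = length(ii))
    })
    runs <- do.call(rbind, runs)
    hits <- runs[, "last"] >= span_lo & runs[, "first"] <= span_hi
    cand <- if (any(hits)) runs[hits, , drop = FALSE] else runs
    ext <- cand[, "last"] - cand[, "first"]
    best <- which(ext == max(ext))
    if (length(best) > 1) best <- best[which.max(cand[best, "n"])]
    run_lo <- cand[best, "first"]; run_hi <- cand[best, "last"]

    # absorb outward while the next in-LD SNP is within gap_bp
    lower <- sort(ld_pos[ld_pos < run_lo], decreasing = TRUE)
    b_lo <- run_lo
    for (p in lower) {
      if (b_lo - p <= gap_bp) b_lo <- p else break
    }
    upper <- sort(ld_pos[ld_pos > run_hi])
    b_hi <- run_hi
    for (p in upper) {
      if (p - b_hi <= gap_bp) b_hi <- p else break
    }
    lo_clipped <- w_lo <= 1
    hi_clipped <- w_hi >= chrom_length
    lo_ok <- (b_lo - gap_bp >= w_lo) || lo_clipped
    hi_ok <- (b_hi + gap_bp <= w_hi) || hi_clipped
    if (lo_ok && hi_ok) {
      if ((lo_clipped && b_lo - gap_bp < w_lo) ||
          (hi_clipped && b_hi + gap_bp > w_hi)) {
        warning("LD gap not found before chromosome end; boundary clipped")
      }
      return(list(start = as.integer(min(b_lo, span_lo)),
                  end = as.integer(max(b_hi, span_hi)),
                  window_used = W))
    }
    W <- W + 1e6
  }
}

# max r2 of each column of Dw against any column of Dm (complete data
# assumed after mean imputation); zero-variance columns give NA.
max_r2_vs <- function(Dw, Dm) {
  sd_w <- apply(Dw, 2, stats::sd)
  sd_m <- apply(Dm, 2, stats::sd)
  out <- rep(NA_real_, ncol(Dw))
  okw <- sd_w > 0
  okm <- sd_m > 0
  if (!any(okw) || !any(okm)) return(out)
  r <- stats::cor(Dw[, okw, drop = FALSE], Dm[, okm, drop = FALSE])
  out[okw] <- apply(r^2, 1, max)
  out
}

#' Compute both boundary types for a region table
#'
#' @param regions output of [cluster_suggestive_snps()] (with `snp_pos`).
#' @param G [genotype_matrix()] for LD.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param r2_thresh,gap_bp,window_bp LD-boundary parameters.
#' @return `regions` with `fixed_start`, `fixed_end`, `ld_start`, `ld_end`,
#'   `ld_window_used` columns appended.
#' @export
region_boundaries <- function(regions, G, chrom_lengths = NULL,
                              r2_thresh = 0.3, gap_bp = 1e5,
                              window_bp = 1e6) {
  if (nrow(regions) == 0) {
    for (col in c("fixed_start", "fixed_end", "ld_start", "ld_end",
                  "ld_window_used")) regions[[col]] <- numeric(0)
    return(regions)
  }
  len <- function(chrom) {
    if (is.null(chrom_lengths) || !chrom %in% names(chrom_lengths)) Inf
    else chrom_lengths[[chrom]]
  }
  fb <- fixed_boundaries(regions$min_snp_bp, regions$max_snp_bp,
                         vapply(regions$chrom, len, numeric(1)))
  regions$fixed_start <- fb$start
  regions$fixed_end <- fb$end
  ld <- lapply(seq_len(nrow(regions)), function(i) {
    ld_boundaries(regions$snp_pos[[i]], G, regions$chrom[i],
                  r2_thresh = r2_thresh, gap_bp = gap_bp,
                  window_bp = window_bp, chrom_length = len(regions$chrom[i]))
  })
  regions$ld_start <- vapply(ld, `[[`, numeric(1), "start")
  regions$ld_end <- vapply(ld, `[[`, numeric(1), "end")
  regions$ld_window_used <- vapply(ld, `[[`, numeric(1), "window_used")
  regions
}
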