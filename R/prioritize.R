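#' Detect sharing between regions
#'
#' Regions A and B (of different traits, or of different cohorts) are
#' shared when A's SNP span intersects B's boundary interval or vice versa
#' (symmetric closure). Sharing is computed separately for the fixed-size
#' and LD-bound boundary modes. A strict-containment variant (one SNP span
#' fully inside the other's boundaries) is available via `rule`.
#'
#' @param regions data.frame with `trait`, `cohort`, `chrom`,
#'   `min_snp_bp`, `max_snp_bp` and boundary columns for the chosen mode
#'   (`fixed_start`/`fixed_end` or `ld_start`/`ld_end`).
#' @param mode `"fixed"` or `"ld"`.
#' @param rule `"intersect"` (default) or `"contain"`.
#' @return data.frame of shared pairs (`i`, `j` row indices with i < j,
#'   plus their trait/cohort labels).
#' @export
detect_shared <- function(regions, mode = c("fixed", "ld"),
                          rule = c("intersect", "contain")) {
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  bs <- regions[[paste0(mode, "_start")]]
  be <- regions[[paste0(mode, "_end")]]
  if (is.null(bs) || is.null(be)) stop("boundary columns for mode '", mode,
                                       "' not present")
  n <- nrow(regions)
  pairs <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (regions$chrom[i] != regions$chrom[j]) next
        same_unit <- regions$trait[i] == regions$trait[j] &&
          regions$cohort[i] == regions$cohort[j]
        if (same_unit) next
        if (rule == "intersect") {
          hit <- (regions$min_snp_bp[i] <= be[j] &&
                    regions$max_snp_bp[i] >= bs[j]) ||
                 (regions$min_snp_bp[j] <= be[i] &&
                    regions$max_snp_bp[j] >= bs[i])
        } else {
          hit <- (regions$min_snp_bp[i] >= bs[j] &&
                    regions$max_snp_bp[i] <= be[j]) ||
                 (regions$min_snp_bp[j] >= bs[i] &&
                    regions$max_snp_bp[j] <= be[i])
        }
        if (hit) pairs[[length(pairs) + 1]] <- c(i, j)
      }
    }
  }
  if (length(pairs) == 0) {
    return(data.frame(i = integer(), j = integer(),
                      trait_i = character(), trait_j = character(),
                      cohort_i = character(), cohort_j = character(),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, pairs)
  data.frame(i = m[, 1], j = m[, 2],
             trait_i = regions$trait[m[, 1]], trait_j = regions$trait[m[, 2]],
             cohort_i = regions$cohort[m[, 1]],
             cohort_j = regions$cohort[m[, 2]],
             stringsAsFactors = FALSE)
}

#' Assign a priority tier from evidence flags
#'
#' Tiers follow the prioritization tree: high when the region is an MA-ROI
#' or is shared across traits with ROI support on either side; medium when
#' it is an ROI in at least one cohort (and not high); low when shared
#' across traits without any ROI support; otherwise removed. A region
#' qualifying for several categories takes the highest.
#'
#' @param is_ma_roi,shared_across_traits,is_roi,shared_partner_has_roi,is_roi_any_cohort
#'   logical vectors (recycled to a common length).
#' @return character vector: `"high"`, `"medium"`, `"low"` or `"removed"`.
#' @export
assign_tier <- function(is_ma_roi, shared_across_traits, is_roi,
                        shared_partner_has_roi, is_roi_any_cohort) {
  n <- max(lengths(list(is_ma_roi, shared_across_traits, is_roi,
                        shared_partner_has_roi, is_roi_any_cohort)))
  rec <- function(x) rep_len(x, n)
  is_ma_roi <- rec(is_ma_roi)
  shared_across_traits <- rec(shared_across_traits)
  is_roi <- rec(is_roi)
  shared_partner_has_roi <- rec(shared_partner_has_roi)
  is_roi_any_cohort <- rec(is_roi_any_cohort)
  high <- is_ma_roi | (shared_across_traits & (is_roi | shared_partner_has_roi))
  medium <- !high & is_roi_any_cohort
  low <- !high & !medium & shared_across_traits
  out <- rep("removed", n)
  out[low] <- "low"
  out[medium] <- "medium"
  out[high] <- "high"
  out
}

#' Prioritize the regions of a full study
#'
#' Computes, per region and boundary mode: MA-ROI overlap (the region's
#' boundary interval intersects an MA-ROI SNP span of the same trait),
#' within-cohort across-trait sharing, cross-cohort sharing of the same
#' trait (which can confer ROI-in-any-cohort status), and the resulting
#' tier.
#'
#' @param regions region table with boundaries ([region_boundaries()]) plus
#'   `trait` and `cohort` columns.
#' @param ma_regions meta-analysis region table from [call_ma_roi()] with a
#'   `trait` column, or NULL when no meta-analysis was run.
#' @param mode `"fixed"` or `"ld"` boundary mode used for sharing.
#' @return list with `regions` (flags + `tier` appended), `tier_counts`,
#'   and `n_unique` (regions counted once per within-cohort shared group).
#' @export
prioritize_study <- function(regions, ma_regions = NULL,
                             mode = c("ld", "fixed")) {
  mode <- match.arg(mode)
  n <- nrow(regions)
  if (n == 0) {
    regions$is_ma_roi <- logical(0)
    regions$shared_across_traits <- logical(0)
    regions$shared_partner_has_roi <- logical(0)
    regions$is_roi_any_cohort <- logical(0)
    regions$tier <- character(0)
    return(list(regions = regions,
                tier_counts = c(high = 0L, medium = 0L, low = 0L,
                                removed = 0L),
                n_unique = 0L))
  }
  bs <- regions[[paste0(mode, "_start")]]
  be <- regions[[paste0(mode, "_end")]]

  is_ma_roi <- rep(FALSE, n)
  if (!is.null(ma_regions) && nrow(ma_regions) > 0) {
    ma <- ma_regions[ma_regions$is_ma_roi, , drop = FALSE]
    for (i in seq_len(n)) {
      hit <- ma$trait == regions$trait[i] & ma$chrom == regions$chrom[i] &
        ma$min_snp_bp <= be[i] & ma$max_snp_bp >= bs[i]
      is_ma_roi[i] <- any(hit)
    }
  }

  pairs <- detect_shared(regions, mode = mode)
  shared_traits <- rep(FALSE, n)
  partner_roi <- rep(FALSE, n)
  roi_any <- regions$is_roi
  if (nrow(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$i[r]; j <- pairs$j[r]
      if (pairs$trait_i[r] != pairs$trait_j[r] &&
          pairs$cohort_i[r] == pairs$cohort_j[r]) {
        shared_traits[c(i, j)] <- TRUE
        if (regions$is_roi[j]) partner_roi[i] <- TRUE
        if (regions$is_roi[i]) partner_roi[j] <- TRUE
      }
      if (pairs$trait_i[r] == pairs$trait_j[r] &&
          pairs$cohort_i[r] != pairs$cohort_j[r]) {
        if (regions$is_roi[j]) roi_any[i] <- TRUE
        if (regions$is_roi[i]) roi_any[j] <- TRUE
      }
    }
  }
  regions$is_ma_roi <- is_ma_roi
  regions$shared_across_traits <- shared_traits
  regions$shared_partner_has_roi <- partner_roi
  regions$is_roi_any_cohort <- roi_any
  regions$tier <- assign_tier(is_ma_roi, shared_traits, regions$is_roi,
                              partner_roi, roi_any)
  tier_counts <- vapply(c("high", "medium", "low", "removed"),
                        function(t) sum(regions$tier == t), integer(1))
  # unique region count: within-cohort shared groups counted once
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (nrow(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      if (pairs$cohort_i[r] == pairs$cohort_j[r]) {
        parent[find(pairs$i[r])] <- find(pairs$j[r])
      }
    }
  }
  kept <- which(regions$tier != "removed")
  n_unique <- length(unique(vapply(kept, find, integer(1))))
  list(regions = regions, tier_counts = tier_counts, n_unique = n_unique)
}
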