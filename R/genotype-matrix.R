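#' Construct a genotype matrix
#'
#' The central genotype container: a samples x variants matrix of alt-allele
#' dosages (0, 1, 2 or `NA` for missing) together with a variant table and
#' ordered sample identifiers. Variants are stored sorted by chromosome
#' (autosome number, then "X") and base-pair position; coordinates are
#' 1-based inclusive throughout the package (BED export is the only 0-based
#' surface).
#'
#' @param dosage integer or numeric matrix, samples in rows, variants in
#'   columns; values in \{0, 1, 2, NA\}.
#' @param variants data.frame with columns `chrom` (character), `pos`
#'   (integer, >= 1), `id`, `ref`, `alt`; one row per dosage column.
#' @param samples character vector of sample ids, one per dosage row.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `variants`, `samples`.
#' @export
genotype_matrix <- function(dosage, variants, samples) {
  dosage <- as.matrix(dosage)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "id", "ref", "alt")
  miss <- setdiff(req, names(variants))
  if (length(miss) > 0) {
    stop("variant table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(variants) != ncol(dosage)) {
    stop("variant table has ", nrow(variants), " rows but dosage has ",
         ncol(dosage), " columns")
  }
  if (length(samples) != nrow(dosage)) {
    stop("sample vector length ", length(samples),
         " does not match dosage rows ", nrow(dosage))
  }
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  if (any(variants$pos < 1L)) {
    stop("variant positions must be >= 1 (1-based coordinates)")
  }
  if (any(variants$ref == variants$alt)) {
    stop("ref and alt alleles must differ")
  }
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
  if (anyDuplicated(key)) {
    stop("duplicate (chrom, pos, ref, alt) variant(s): ",
         key[duplicated(key)][1])
  }
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  ord <- order(chrom_rank(variants$chrom), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  dosage <- dosage[, ord, drop = FALSE]
  dimnames(dosage) <- list(samples, variants$id)
  structure(
    list(dosage = dosage, variants = variants, samples = as.character(samples)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$variants), "variants on",
      length(unique(x$variants$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missingness: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

# Sort rank for chromosome labels: autosomes numerically, then "X", then
# anything else lexicographically after that.
chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  rank <- num
  rank[is.na(num) & chrom == "X"] <- 1e6
  other <- is.na(num) & chrom != "X"
  if (any(other)) rank[other] <- 2e6 + as.numeric(factor(chrom[other]))
  rank
}

#' Subset a genotype matrix
#'
#' @param G a `genotype_matrix`.
#' @param samples optional character vector or logical/integer index of
#'   samples to keep.
#' @param variants optional logical/integer index of variants to keep.
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(G, samples = NULL, variants = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  si <- seq_along(G$samples)
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, G$samples) else si[samples]
    if (anyNA(si)) stop("unknown sample id(s)")
  }
  vi <- seq_len(nrow(G$variants))
  if (!is.null(variants)) vi <- vi[variants]
  genotype_matrix(G$dosage[si, vi, drop = FALSE],
                  G$variants[vi, , drop = FALSE],
                  G$samples[si])
}
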