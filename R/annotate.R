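#' Positional candidate genes for an interval
#'
#' A gene is a positional candidate when its interval intersects the region
#' interval by at least 1 bp (adjacency is not overlap). Counts are
#' reported per biotype.
#'
#' @param chrom,start,end region interval (1-based inclusive).
#' @param genes gene table from [read_gff3()].
#' @return list with `genes` (the overlapping rows) and `counts` (named:
#'   protein_coding, rna_gene, pseudogene, total).
#' @export
candidate_genes <- function(chrom, start, end, genes) {
  stopifnot(start >= 1, start <= end)
  if (nrow(genes) == 0) {
    hits <- genes
  } else {
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
    g <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start, genes$end))
    ov <- GenomicRanges::findOverlaps(g, q)
    hits <- genes[unique(S4Vectors::queryHits(ov)), , drop = FALSE]
  }
  counts <- c(protein_coding = sum(hits$biotype == "protein_coding"),
              rna_gene = sum(hits$biotype == "rna_gene"),
              pseudogene = sum(hits$biotype == "pseudogene"))
  counts <- c(counts, total = sum(counts))
  list(genes = hits, counts = counts)
}

#' Annotate a region table with gene counts
#'
#' @param regions data.frame with `chrom` and boundary columns for `mode`.
#' @param genes gene table from [read_gff3()].
#' @param mode `"ld"` or `"fixed"`; selects the boundary columns.
#' @return `regions` with `n_protein_coding`, `n_rna_gene`,
#'   `n_pseudogene`, `n_genes` and a list column `gene_ids`.
#' @export
annotate_regions <- function(regions, genes, mode = c("ld", "fixed")) {
  mode <- match.arg(mode)
  bs <- regions[[paste0(mode, "_start")]]
  be <- regions[[paste0(mode, "_end")]]
  res <- lapply(seq_len(nrow(regions)), function(i) {
    candidate_genes(regions$chrom[i], bs[i], be[i], genes)
  })
  regions$n_protein_coding <- vapply(res, function(r)
    unname(r$counts["protein_coding"]), numeric(1))
  regions$n_rna_gene <- vapply(res, function(r)
    unname(r$counts["rna_gene"]), numeric(1))
  regions$n_pseudogene <- vapply(res, function(r)
    unname(r$counts["pseudogene"]), numeric(1))
  regions$n_genes <- vapply(res, function(r)
    unname(r$counts["total"]), numeric(1))
  regions$gene_ids <- lapply(res, function(r) r$genes$gene_id)
  regions
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of observing `k`
#' query genes in a set of size `K` from a universe of size `N`, with
#' Benjamini-Hochberg adjustment across sets.
#'
#' @param query character vector of query gene ids (subset of universe).
#' @param gene_sets named list of character vectors (each a subset of the
#'   universe), e.g. from [read_gmt()].
#' @param universe character vector of all annotatable gene ids.
#' @return data.frame with `set`, `k`, `K`, `n`, `N`, `p`, `p_adj`.
#' @export
ora_test <- function(query, gene_sets, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0) stop("empty gene universe")
  query <- unique(intersect(query, universe))
  n <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- unique(intersect(gene_sets[[nm]], universe))
    K <- length(set)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
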