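#' Read gene models from a GFF3 file
#'
#' Extracts gene-level features and classifies each into one of three
#' biotypes used for positional candidate-gene tallies: `protein_coding`,
#' `pseudogene` or `rna_gene`. Classification uses, in order, the
#' `biotype`/`gene_biotype` attribute and the GFF3 feature type, via a fixed
#' mapping table: values containing "pseudogene" map to `pseudogene`;
#' RNA-class values (`lncRNA`, `miRNA`, `rRNA`, `tRNA`, `snRNA`, `snoRNA`,
#' `ncRNA`, `misc_RNA`, feature type `ncRNA_gene`) map to `rna_gene`;
#' everything else (including a bare `gene` feature with no biotype
#' attribute) maps to `protein_coding`.
#'
#' @param path GFF3 file path.
#' @return data.frame with columns `gene_id`, `name`, `chrom`, `start`,
#'   `end` (1-based inclusive), `biotype`. Empty (with a warning) when the
#'   file holds no gene-level features.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gff <- ape::read.gff(path, GFF3 = TRUE)
  gene_types <- c("gene", "pseudogene", "ncRNA_gene")
  g <- gff[gff$type %in% gene_types, , drop = FALSE]
  empty <- data.frame(gene_id = character(), name = character(),
                      chrom = character(), start = integer(), end = integer(),
                      biotype = character(), stringsAsFactors = FALSE)
  if (nrow(g) == 0) {
    warning("no gene-level features found in ", path)
    return(empty)
  }
  bad <- is.na(g$start) | is.na(g$end)
  if (any(bad)) {
    warning(sum(bad), " gene feature(s) missing coordinates, skipped")
    g <- g[!bad, , drop = FALSE]
  }
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0("(^|;)\\s*", key, "=[^;]*"), attrs))
    out <- rep(NA_character_, length(attrs))
    hit <- lengths(regmatches(attrs, gregexpr(paste0("(^|;)\\s*", key, "="),
                                              attrs))) > 0
    out[hit] <- sub(paste0(".*", key, "="), "", m)
    out
  }
  gene_id <- attr_get(g$attributes, "ID")
  gene_id[is.na(gene_id)] <- paste0("gene_", seq_len(sum(is.na(gene_id))))
  name <- attr_get(g$attributes, "Name")
  name[is.na(name)] <- gene_id[is.na(name)]
  bt_attr <- attr_get(g$attributes, "biotype")
  bt2 <- attr_get(g$attributes, "gene_biotype")
  bt_attr[is.na(bt_attr)] <- bt2[is.na(bt_attr)]
  biotype <- map_biotype(bt_attr, as.character(g$type))
  data.frame(gene_id = gene_id, name = name,
             chrom = as.character(g$seqid),
             start = as.integer(g$start), end = as.integer(g$end),
             biotype = biotype, stringsAsFactors = FALSE)
}

# Fixed biotype mapping table (documented in ?read_gff3).
map_biotype <- function(attr_value, feature_type) {
  rna_values <- c("lncRNA", "miRNA", "rRNA", "tRNA", "snRNA", "snoRNA",
                  "ncRNA", "misc_RNA", "scRNA", "sRNA", "rna_gene")
  out <- rep("protein_coding", length(attr_value))
  val <- ifelse(is.na(attr_value), "", attr_value)
  out[grepl("pseudogene", val) | feature_type == "pseudogene"] <- "pseudogene"
  out[val %in% rna_values | feature_type == "ncRNA_gene"] <- "rna_gene"
  out
}

#' Write genomic regions as BED6+
#'
#' Internal 1-based inclusive intervals are converted to BED's 0-based
#' half-open convention (`start - 1`, `end`). The name column encodes
#' trait and tier when present. Rows are ordered by (chrom, start).
#'
#' @param regions data.frame with columns `chrom`, `start`, `end` and
#'   optionally `trait`, `tier`, `score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  header <- "# BED6: chrom, start (0-based), end, name, score, strand"
  if (nrow(regions) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (any(regions$start < 1) || any(regions$end < regions$start)) {
    stop("invalid interval(s): need 1 <= start <= end")
  }
  name <- if ("trait" %in% names(regions)) regions$trait else "region"
  if ("tier" %in% names(regions)) name <- paste(name, regions$tier, sep = "|")
  score <- if ("score" %in% names(regions)) regions$score else 0
  ord <- order(chrom_rank(regions$chrom), regions$start)
  lines <- paste(regions$chrom, regions$start - 1L, regions$end,
                 name, score, ".", sep = "\t")[ord]
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a BED6+ file back to 1-based inclusive intervals
#'
#' @param path BED file written by [write_regions_bed()].
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive),
#'   `name`, `score`.
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    chrom = vapply(parts, `[`, character(1), 1),
    start = as.integer(vapply(parts, `[`, character(1), 2)) + 1L,
    end = as.integer(vapply(parts, `[`, character(1), 3)),
    name = vapply(parts, `[`, character(1), 4),
    score = as.numeric(vapply(parts, `[`, character(1), 5)),
    stringsAsFactors = FALSE
  )
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (tab-separated: set id, description, gene ids).
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  sets
}
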