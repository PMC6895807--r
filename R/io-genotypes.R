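#' Read genotypes into a genotype matrix
#'
#' Supported dialects: VCF v4.2 with GT fields (`"vcf"`), PLINK text
#' ped/map (`"plink_text"`, pass the `.ped` path with the `.map` file
#' alongside), and a plain dosage TSV (`"dosage_tsv"`: columns `chrom`,
#' `pos`, `id`, `ref`, `alt` followed by one dosage column per sample,
#' missing coded `NA`). Only biallelic SNPs are retained; multi-allelic VCF
#' records are dropped by default.
#'
#' @param path input file path.
#' @param format one of `"vcf"`, `"plink_text"`, `"dosage_tsv"`.
#' @param drop_multiallelic drop VCF records with more than one alt allele
#'   (default `TRUE`; `FALSE` splits them into one record per alt allele,
#'   heterozygous calls involving other alt alleles become dosage 0/1 on the
#'   retained allele).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path,
                           format = c("vcf", "plink_text", "dosage_tsv"),
                           drop_multiallelic = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         vcf = read_genotypes_vcf(path, drop_multiallelic),
         plink_text = read_genotypes_ped(path),
         dosage_tsv = read_genotypes_tsv(path))
}

read_genotypes_vcf <- function(path, drop_multiallelic) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || nrow(fix) == 0) stop("VCF contains no GT genotype records: ", path)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  keep <- rep(TRUE, nrow(fix))
  if (drop_multiallelic) keep <- !multi
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  # GT like 0/0, 0|1, ./.; dosage counts occurrences of allele "1"
  dose_one <- function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_real_)
    a <- strsplit(g, "[/|]")[[1]]
    if (any(a == ".")) return(NA_real_)
    sum(a == "1")
  }
  dos <- vapply(seq_len(nrow(gt)), function(i) {
    vapply(gt[i, ], dose_one, numeric(1))
  }, numeric(ncol(gt)))
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = ncol(gt))
  alt1 <- vapply(strsplit(fix$ALT, ",", fixed = TRUE), `[`, character(1), 1)
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                     paste0(fix$CHROM, "_", fix$POS), fix$ID),
                         ref = fix$REF, alt = alt1, stringsAsFactors = FALSE)
  snp <- nchar(variants$ref) == 1 & nchar(variants$alt) == 1
  genotype_matrix(dos[, snp, drop = FALSE], variants[snp, , drop = FALSE],
                  colnames(gt))
}

read_genotypes_ped <- function(ped_path) {
  map_path <- sub("\\.ped$", ".map", ped_path)
  if (identical(map_path, ped_path)) map_path <- paste0(ped_path, ".map")
  if (!file.exists(map_path)) stop("map file not found next to ped: ", map_path)
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 4) stop("malformed map file (need 4 columns): ", map_path)
  names(map)[1:4] <- c("chrom", "id", "cm", "pos")
  ped <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE)
  n_meta <- 6L
  n_snp <- nrow(map)
  if (ncol(ped) != n_meta + 2L * n_snp) {
    stop("ped file has ", ncol(ped), " columns; expected ",
         n_meta + 2L * n_snp, " for ", n_snp, " map SNPs")
  }
  a1 <- as.matrix(ped[, n_meta + 2L * seq_len(n_snp) - 1L, drop = FALSE])
  a2 <- as.matrix(ped[, n_meta + 2L * seq_len(n_snp), drop = FALSE])
  dos <- matrix(NA_real_, nrow(ped), n_snp)
  ref <- alt <- character(n_snp)
  for (j in seq_len(n_snp)) {
    al <- c(a1[, j], a2[, j])
    ok <- !(al %in% c("0", "N", "-"))
    lev <- sort(unique(al[ok]))
    if (length(lev) > 2) stop("SNP ", map$id[j], " has >2 alleles in ped")
    if (length(lev) == 0) lev <- c("A", "B")
    if (length(lev) == 1) lev <- c(lev, setdiff(c("A", "C", "G", "T"), lev)[1])
    ref[j] <- lev[1]; alt[j] <- lev[2]
    d <- (a1[, j] == alt[j]) + (a2[, j] == alt[j])
    d[!(a1[, j] %in% lev) | !(a2[, j] %in% lev)] <- NA_real_
    dos[, j] <- d
  }
  variants <- data.frame(chrom = as.character(map$chrom),
                         pos = as.integer(map$pos),
                         id = as.character(map$id), ref = ref, alt = alt,
                         stringsAsFactors = FALSE)
  genotype_matrix(dos, variants, as.character(ped[[2]]))
}

read_genotypes_tsv <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE, showProgress = FALSE)
  req <- c("chrom", "pos", "id", "ref", "alt")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) stop("dosage TSV missing column(s): ",
                             paste(miss, collapse = ", "))
  samp <- setdiff(names(tab), req)
  if (length(samp) == 0) stop("dosage TSV has no sample columns")
  dos <- t(as.matrix(tab[, samp, drop = FALSE]))
  genotype_matrix(dos, tab[, req], samp)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCFv4.2 file with unphased GT fields only (dosage 0 -> 0/0,
#' 1 -> 0/1, 2 -> 1/1, missing -> ./.).
#'
#' @param G a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$samples), collapse = "\t")
  )
  v <- G$variants
  gt <- matrix("./.", nrow(v), length(G$samples))
  for (d in 0:2) gt[t(G$dosage) == d] <- gt_code[[as.character(d)]]
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write a genotype matrix as a dosage TSV
#'
#' @param G a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  tab <- cbind(G$variants, as.data.frame(t(G$dosage)))
  names(tab) <- c(names(G$variants), G$samples)
  data.table::fwrite(tab, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
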