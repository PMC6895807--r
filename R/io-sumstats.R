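#' Write per-SNP association summary statistics
#'
#' Schema (TSV): `chrom`, `pos`, `id`, `ref`, `alt`, `beta`, `se`, `p`, `n`.
#' Values are written at full precision (15 significant digits).
#'
#' @param records data.frame of association records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(records, path) {
  req <- c("chrom", "pos", "id", "ref", "alt", "beta", "se", "p", "n")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0) stop("summary-stat table missing column(s): ",
                             paste(miss, collapse = ", "))
  out <- records[, req, drop = FALSE]
  for (col in c("beta", "se", "p")) {
    out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read per-SNP association summary statistics
#'
#' Validates the schema of [write_sumstats()] and the p-value domain
#' (p must lie in (0, 1]).
#'
#' @param path TSV path.
#' @return data.frame of association records.
#' @export
read_sumstats <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE, showProgress = FALSE)
  req <- c("chrom", "pos", "id", "ref", "alt", "beta", "se", "p", "n")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) stop("summary-stat file missing column(s): ",
                             paste(miss, collapse = ", "))
  tab$chrom <- as.character(tab$chrom)
  if (any(tab$pos < 1)) stop("positions must be >= 1 (1-based coordinates)")
  if (any(tab$p <= 0 | tab$p > 1)) {
    stop("p-values must lie in (0, 1]; offending row ",
         which(tab$p <= 0 | tab$p > 1)[1])
  }
  if (any(tab$se <= 0)) stop("standard errors must be > 0")
  tab
}
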