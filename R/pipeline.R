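#' Run the full two-cohort association pipeline
#'
#' Executes the stages in order: (optional) simulation, phenotype
#' transformation and mixed-model residualization, genotype QC, per-trait
#' mixed-model scans per cohort (with nested sub-cohort scans and their
#' union for the stratified cohort), cross-cohort meta-analysis with
#' MA-ROI calling, region clustering with fixed-size and LD-bound
#' boundaries, tier prioritization, and positional gene annotation.
#'
#' @param input either a [sim_config()] (the study is simulated), a
#'   `sim_study` from [simulate_cohorts()], or a named list of file paths
#'   (`cohort1`, `cohort2` VCFs, `phenotypes` TSV, optional `genes` GFF3).
#' @param out_dir output directory for TSV/BED outputs and the run report;
#'   `NULL` runs in memory only.
#' @param traits trait names to analyze; default all canonical traits
#'   present in the phenotype table.
#' @param transform_mode `"canonical"` or `"auto"` (see [prepare_traits()]).
#' @param union_nested run nested sub-cohort scans (full cohort, then
#'   progressively restricted section subsets) for cohort 1 and use the
#'   union of suggestive SNPs, mirroring stratification handling by nested
#'   GWA; default `TRUE` when section labels are present.
#' @param mode boundary mode used for sharing/prioritization.
#' @param qc QC thresholds ([qc_thresholds()]).
#' @param genes gene table ([read_gff3()]) or GFF3 path; `NULL` with a
#'   simulated input builds the toy tiling annotation; `FALSE` disables
#'   annotation entirely.
#' @param block_size effective-test block size.
#' @param alpha,suggestive significance parameters.
#' @param r2_thresh,gap_bp,window_bp LD-boundary parameters.
#' @return list of class `pipeline_run`: `scans`, `union_records`,
#'   `regions` (with boundaries, flags and tiers), `meta` (per-trait
#'   tables), `ma_regions`, `thresholds`, `tier_counts`, `n_unique`,
#'   `qc_reports`, `annotated` and `out_dir`.
#' @export
run_pipeline <- function(input, out_dir = NULL, traits = NULL,
                         transform_mode = "canonical", union_nested = TRUE,
                         mode = c("ld", "fixed"), qc = qc_thresholds(),
                         genes = NULL, block_size = 200, alpha = 0.05,
                         suggestive = 1e-5, r2_thresh = 0.3, gap_bp = 1e5,
                         window_bp = 1e6) {
  mode <- match.arg(mode)

  # --- stage 0: inputs -------------------------------------------------
  skip_genes <- isFALSE(genes)
  if (skip_genes) genes <- NULL
  chrom_lengths <- NULL
  if (inherits(input, "sim_config")) {
    sim <- simulate_cohorts(input)
    input <- sim
  }
  if (inherits(input, "sim_study")) {
    G1 <- input$genotypes$cohort1
    G2 <- input$genotypes$cohort2
    pheno <- input$phenotypes
    chrom_lengths <- input$chrom_lengths
    if (is.null(genes) && !skip_genes) {
      tmp <- tempfile(fileext = ".gff3")
      write_toy_gff3(chrom_lengths, tmp)
      genes <- read_gff3(tmp)
      unlink(tmp)
    }
  } else if (is.list(input)) {
    need <- c("cohort1", "cohort2", "phenotypes")
    miss <- setdiff(need, names(input))
    if (length(miss) > 0) stop("input list missing element(s): ",
                               paste(miss, collapse = ", "))
    for (f in c(unlist(input[need]), input$genes)) {
      if (!file.exists(f)) stop("input file not found: ", f)
    }
    G1 <- read_genotypes(input$cohort1, format = "vcf")
    G2 <- read_genotypes(input$cohort2, format = "vcf")
    pheno <- as.data.frame(data.table::fread(input$phenotypes,
                                             data.table = FALSE))
    if (!is.null(input$genes)) genes <- read_gff3(input$genes)
  } else {
    stop("unsupported input type")
  }
  if (is.character(genes)) genes <- read_gff3(genes)
  if (is.null(traits)) {
    traits <- intersect(ems_traits()$trait, names(pheno))
  }
  if (is.null(chrom_lengths)) {
    pos_all <- rbind(G1$variants, G2$variants)
    chrom_lengths <- tapply(pos_all$pos, pos_all$chrom, max) + 1e6
  }

  # --- stage 1: phenotype prep per cohort ------------------------------
  panel <- ems_traits()
  panel <- panel[panel$trait %in% traits, , drop = FALSE]
  prep <- lapply(split(pheno, pheno$cohort), prepare_traits,
                 traits = panel, transform_mode = transform_mode)

  # --- stage 2: QC -----------------------------------------------------
  qc1 <- qc_filter(G1, qc)
  qc2 <- qc_filter(G2, qc)
  G1 <- qc1$genotypes; G2 <- qc2$genotypes

  # --- stage 3: scans --------------------------------------------------
  sections <- pheno$section[pheno$cohort == "cohort1"]
  sections <- sections[match(G1$samples, prep$cohort1$sample)]
  do_union <- union_nested && !all(is.na(sections)) &&
    length(unique(stats::na.omit(sections))) > 1
  K1 <- compute_grm(G1); K2 <- compute_grm(G2)
  Me1 <- effective_tests(G1, block_size)
  Me2 <- effective_tests(G2, block_size)

  scan_cohort <- function(G, K, Me, prep_tab, trait, cohort) {
    y <- prep_tab[[trait]][match(G$samples, prep_tab$sample)]
    gwas_scan(y, G, trait = trait, cohort = cohort, K = K,
              m_effective = Me, block_size = block_size, alpha = alpha,
              suggestive = suggestive)
  }

  nested_subsets <- list(seq_along(G1$samples))
  if (do_union) {
    sec_levels <- sort(unique(stats::na.omit(sections)))
    if (length(sec_levels) > 2) {
      nested_subsets <- c(nested_subsets,
                          list(which(sections %in% sec_levels[1:2])))
    }
    nested_subsets <- c(nested_subsets, list(which(sections == sec_levels[1])))
  }

  scans <- list()
  union_records <- list()
  regions_list <- list()
  for (trait in panel$trait) {
    c1_scans <- list()
    for (si in seq_along(nested_subsets)) {
      idx <- nested_subsets[[si]]
      label <- if (si == 1) "cohort1" else paste0("cohort1_sub", si - 1)
      if (si == 1) {
        c1_scans[[label]] <- scan_cohort(G1, K1, Me1, prep$cohort1, trait,
                                         label)
      } else {
        Gs <- subset_genotypes(G1, samples = idx)
        c1_scans[[label]] <- scan_cohort(Gs, compute_grm(Gs), Me1,
                                         prep$cohort1, trait, label)
      }
    }
    s2 <- scan_cohort(G2, K2, Me2, prep$cohort2, trait, "cohort2")
    scans[[trait]] <- c(c1_scans, list(cohort2 = s2))
    u1 <- cohort_union(c1_scans)
    union_records[[trait]] <- u1

    # cohort 1 regions from the union; cohort 2 from its single scan
    r1 <- cluster_suggestive_snps(u1)
    if (nrow(r1) > 0) { r1$trait <- trait; r1$cohort <- "cohort1" }
    rec2 <- s2$records
    r2 <- cluster_suggestive_snps(rec2, s2$thresholds$suggestive,
                                  s2$thresholds$genome_wide)
    if (nrow(r2) > 0) { r2$trait <- trait; r2$cohort <- "cohort2" }
    if (nrow(r1) > 0) r1 <- region_boundaries(r1, G1, chrom_lengths,
                                              r2_thresh, gap_bp, window_bp)
    if (nrow(r2) > 0) r2 <- region_boundaries(r2, G2, chrom_lengths,
                                              r2_thresh, gap_bp, window_bp)
    regions_list[[trait]] <- rbind(if (nrow(r1) > 0) r1,
                                   if (nrow(r2) > 0) r2)
  }
  regions <- do.call(rbind, regions_list[!vapply(regions_list, is.null,
                                                 logical(1))])
  if (is.null(regions)) {
    regions <- cluster_suggestive_snps(
      data.frame(chrom = character(), pos = integer(), p = numeric()),
      1e-5, 1e-8)
    regions$trait <- character(0); regions$cohort <- character(0)
    regions <- region_boundaries(regions, G1, chrom_lengths)
  }
  rownames(regions) <- NULL

  # --- stage 4: meta-analysis on shared SNPs ---------------------------
  shared_key <- intersect(paste(G1$variants$chrom, G1$variants$pos),
                          paste(G2$variants$chrom, G2$variants$pos))
  Me_shared <- c(
    cohort1 = effective_tests(
      subset_genotypes(G1, variants = paste(G1$variants$chrom,
                                            G1$variants$pos) %in% shared_key),
      block_size),
    cohort2 = effective_tests(
      subset_genotypes(G2, variants = paste(G2$variants$chrom,
                                            G2$variants$pos) %in% shared_key),
      block_size))
  mth <- meta_thresholds(Me_shared, alpha, suggestive)
  meta_tabs <- list()
  ma_list <- list()
  for (trait in panel$trait) {
    aligned <- align_alleles(list(cohort1 = scans[[trait]]$cohort1$records,
                                  cohort2 = scans[[trait]]$cohort2$records))
    mt <- meta_analyze(aligned)
    meta_tabs[[trait]] <- mt
    mreg <- call_ma_roi(mt, mth)
    if (nrow(mreg) > 0) {
      mreg$trait <- trait
      # LD-bound interval of each MA-ROI: union of the per-cohort intervals
      ls1 <- ls2 <- vector("list", nrow(mreg))
      for (i in seq_len(nrow(mreg))) {
        cl <- chrom_lengths[[mreg$chrom[i]]]
        p1 <- ld_boundaries(mreg$snp_pos[[i]], G1, mreg$chrom[i], r2_thresh,
                            gap_bp, window_bp, cl)
        p2 <- ld_boundaries(mreg$snp_pos[[i]], G2, mreg$chrom[i], r2_thresh,
                            gap_bp, window_bp, cl)
        ls1[[i]] <- p1; ls2[[i]] <- p2
      }
      mreg$ld_start <- pmin(vapply(ls1, `[[`, numeric(1), "start"),
                            vapply(ls2, `[[`, numeric(1), "start"))
      mreg$ld_end <- pmax(vapply(ls1, `[[`, numeric(1), "end"),
                          vapply(ls2, `[[`, numeric(1), "end"))
      fb <- fixed_boundaries(mreg$min_snp_bp, mreg$max_snp_bp,
                             vapply(mreg$chrom, function(ch)
                               chrom_lengths[[ch]], numeric(1)))
      mreg$fixed_start <- fb$start; mreg$fixed_end <- fb$end
      ma_list[[trait]] <- mreg
    }
  }
  ma_regions <- if (length(ma_list) > 0) do.call(rbind, ma_list) else NULL
  if (!is.null(ma_regions)) rownames(ma_regions) <- NULL

  # --- stage 5: prioritization -----------------------------------------
  prio <- prioritize_study(regions, ma_regions, mode = mode)
  regions <- prio$regions

  # --- stage 6: annotation ---------------------------------------------
  annotated <- NULL
  if (!is.null(genes) && nrow(regions) > 0) {
    keep <- regions$tier != "removed"
    annotated <- annotate_regions(regions[keep, , drop = FALSE], genes, mode)
  }

  run <- structure(list(
    scans = scans, union_records = union_records, regions = regions,
    meta = meta_tabs, ma_regions = ma_regions,
    thresholds = list(cohort1 = scans[[panel$trait[1]]]$cohort1$thresholds,
                      cohort2 = scans[[panel$trait[1]]]$cohort2$thresholds,
                      meta = mth),
    m_effective = list(cohort1 = Me1, cohort2 = Me2, shared = Me_shared),
    tier_counts = prio$tier_counts, n_unique = prio$n_unique,
    qc_reports = list(cohort1 = qc1$report, cohort2 = qc2$report),
    annotated = annotated, out_dir = out_dir
  ), class = "pipeline_run")
  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run:", length(x$scans), "trait(s);",
      nrow(x$regions), "region(s);",
      if (is.null(x$ma_regions)) 0 else sum(x$ma_regions$is_ma_roi),
      "MA-ROI\n")
  cat("  tiers:", paste(names(x$tier_counts), x$tier_counts,
                        sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Flatten list columns and write all run outputs to a directory.
write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  flat <- function(d) {
    for (col in names(d)) {
      if (is.list(d[[col]])) {
        d[[col]] <- vapply(d[[col]], paste, character(1), collapse = ",")
      }
    }
    d
  }
  for (trait in names(run$scans)) {
    for (s in run$scans[[trait]]) {
      write_sumstats(s$records, file.path(
        out_dir, sprintf("sumstats_%s_%s.tsv", trait, s$cohort)))
    }
    data.table::fwrite(flat(run$meta[[trait]]),
                       file.path(out_dir, sprintf("meta_%s.tsv", trait)),
                       sep = "\t", quote = FALSE)
  }
  data.table::fwrite(flat(run$regions),
                     file.path(out_dir, "regions_prioritized.tsv"),
                     sep = "\t", quote = FALSE)
  if (!is.null(run$ma_regions)) {
    data.table::fwrite(flat(run$ma_regions),
                       file.path(out_dir, "ma_regions.tsv"),
                       sep = "\t", quote = FALSE)
  }
  if (!is.null(run$annotated)) {
    data.table::fwrite(flat(run$annotated),
                       file.path(out_dir, "regions_annotated.tsv"),
                       sep = "\t", quote = FALSE)
  }
  for (co in c("cohort1", "cohort2")) {
    data.table::fwrite(run$qc_reports[[co]],
                       file.path(out_dir, sprintf("qc_report_%s.tsv", co)),
                       sep = "\t", quote = FALSE)
  }
  kept <- run$regions[run$regions$tier != "removed", , drop = FALSE]
  if (nrow(kept) > 0) {
    bed <- data.frame(chrom = kept$chrom, start = kept$ld_start,
                      end = kept$ld_end, trait = kept$trait,
                      tier = kept$tier, stringsAsFactors = FALSE)
    write_regions_bed(bed, file.path(out_dir, "regions_ld.bed"))
  } else {
    write_regions_bed(data.frame(chrom = character(), start = integer(),
                                 end = integer()),
                      file.path(out_dir, "regions_ld.bed"))
  }
  rep_lines <- c(
    "pipeline run report",
    sprintf("effective tests: cohort1 = %.1f, cohort2 = %.1f",
            run$m_effective$cohort1, run$m_effective$cohort2),
    sprintf("genome-wide thresholds: cohort1 = %.3g, cohort2 = %.3g, meta = %.3g",
            run$thresholds$cohort1$genome_wide,
            run$thresholds$cohort2$genome_wide,
            run$thresholds$meta$genome_wide),
    sprintf("suggestive threshold: %.3g", run$thresholds$cohort1$suggestive),
    sprintf("regions: %d (high %d, medium %d, low %d, removed %d); unique kept %d",
            nrow(run$regions), run$tier_counts[["high"]],
            run$tier_counts[["medium"]], run$tier_counts[["low"]],
            run$tier_counts[["removed"]], run$n_unique),
    sprintf("MA-ROI: %d",
            if (is.null(run$ma_regions)) 0L else sum(run$ma_regions$is_ma_roi)),
    if (!is.null(run$annotated))
      sprintf("positional candidate genes (kept regions): %d",
              sum(run$annotated$n_genes))
  )
  writeLines(rep_lines, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
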