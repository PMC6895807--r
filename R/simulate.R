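#' Canonical trait panel
#'
#' The twelve metabolic-syndrome traits the pipeline models: eleven
#' quantitative traits with their canonical normalizing transforms
#' (square root for adiponectin, leptin and NEFA; log for insulin, INS-OST,
#' triglycerides and ACTH; identity for glucose, GLU-OST and the two
#' morphometric ratios) plus laminitis status as a binary liability trait.
#'
#' @return data.frame with columns `trait`, `transform`, `type`.
#' @export
ems_traits <- function() {
  data.frame(
    trait = c("insulin", "ins_ost", "glucose", "glu_ost", "nefa", "tg",
              "adiponectin", "leptin", "acth", "nh", "gh", "laminitis"),
    transform = c("log", "log", "identity", "identity", "sqrt", "log",
                  "sqrt", "sqrt", "log", "identity", "identity", "identity"),
    type = c(rep("quantitative", 11), "binary"),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Defines a two-cohort study: cohort 1 emulates a pony population with
#' registry sub-populations ("sections") inducing stratification; cohort 2 a
#' second breed. Genotypes live in fixed-size LD blocks; within a block
#' adjacent haplotype alleles are copied with probability `within_block_r`
#' (first-order Markov LD) and LD is zero across block borders. Population
#' allele frequencies drift from a shared ancestral pool by the
#' Balding-Nichols model with the stated Fst. Each LD block is `shared`,
#' `cohort1` or `cohort2` specific: a cohort is genotyped (and its variants
#' segregate) only at shared blocks plus its own private blocks, emulating
#' breed-private variation. Traits follow
#' `y = sum(causal dosage x effect) + sex + age + farm + polygenic + residual`
#' and quantitative traits are stored on the inverse-transformed scale so
#' the pipeline's canonical forward transform restores normality.
#'
#' @param seed integer RNG seed; a fixed seed gives byte-identical output.
#' @param n_per_cohort integer vector of length 2, samples per cohort.
#' @param n_snps total simulated SNP count across all chromosomes.
#' @param n_chroms number of autosomes (labelled "1", "2", ...).
#' @param block_size_snps SNPs per LD block.
#' @param within_block_r adjacent-SNP haplotype copy probability in [0, 1).
#' @param snp_spacing_bp mean inter-SNP spacing (exponential gaps).
#' @param n_farms farms per cohort (length 2).
#' @param n_sections sub-populations in cohort 1.
#' @param fst_between_cohorts,fst_between_sections Balding-Nichols drift.
#' @param prop_shared proportion of LD blocks genotyped in both cohorts.
#' @param causal_spec data.frame(`snp` global SNP index, `trait`, `effect`
#'   per alt allele, `scope` in shared/cohort1_only/cohort2_only), or NULL.
#' @param covariate_effects named numeric: `sex` (additive male effect) and
#'   `age` (per-year slope) on every trait's latent scale.
#' @param var_components named numeric: `farm`, `polygenic`, `residual`
#'   variances on the latent scale.
#' @param liability_threshold liability quantile above which the binary
#'   trait is 1 (prevalence = 1 - threshold).
#' @param traits trait panel as from [ems_traits()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_per_cohort = c(264L, 287L),
                       n_snps = 10000L,
                       n_chroms = 5L,
                       block_size_snps = 20L,
                       within_block_r = 0.9,
                       snp_spacing_bp = 25000,
                       n_farms = c(28L, 31L),
                       n_sections = 3L,
                       fst_between_cohorts = 0.1,
                       fst_between_sections = 0.03,
                       prop_shared = 0.8,
                       causal_spec = NULL,
                       covariate_effects = c(sex = 0.25, age = 0.02),
                       var_components = c(farm = 0.5, polygenic = 1,
                                          residual = 1),
                       liability_threshold = 0.8,
                       traits = ems_traits()) {
  stopifnot(length(n_per_cohort) == 2, n_snps >= 1, n_chroms >= 1,
            within_block_r >= 0, within_block_r < 1,
            fst_between_cohorts >= 0, fst_between_cohorts < 0.5,
            fst_between_sections >= 0, fst_between_sections < 0.5,
            all(var_components >= 0), var_components[["residual"]] > 0,
            liability_threshold > 0, liability_threshold < 1)
  if (!is.null(causal_spec)) {
    causal_spec <- as.data.frame(causal_spec, stringsAsFactors = FALSE)
    stopifnot(all(c("snp", "trait", "effect", "scope") %in%
                    names(causal_spec)))
    if (any(causal_spec$snp < 1 | causal_spec$snp > n_snps)) {
      stop("causal SNP index out of range 1..n_snps")
    }
    bad <- setdiff(causal_spec$scope,
                   c("shared", "cohort1_only", "cohort2_only"))
    if (length(bad) > 0) stop("unknown causal scope: ", bad[1])
    if (!all(causal_spec$trait %in% traits$trait)) {
      stop("causal trait not in trait panel")
    }
  }
  structure(list(
    seed = as.integer(seed), n_per_cohort = as.integer(n_per_cohort),
    n_snps = as.integer(n_snps), n_chroms = as.integer(n_chroms),
    block_size_snps = as.integer(block_size_snps),
    within_block_r = within_block_r, snp_spacing_bp = snp_spacing_bp,
    n_farms = as.integer(n_farms), n_sections = as.integer(n_sections),
    fst_between_cohorts = fst_between_cohorts,
    fst_between_sections = fst_between_sections,
    prop_shared = prop_shared, causal_spec = causal_spec,
    covariate_effects = covariate_effects, var_components = var_components,
    liability_threshold = liability_threshold, traits = traits
  ), class = "sim_config")
}

# Deterministic genome layout: chromosome assignment, positions, block ids.
# Consumes RNG (positions); call under the config seed.
sim_layout <- function(config) {
  M <- config$n_snps
  per_chrom <- diff(round(seq(0, M, length.out = config$n_chroms + 1)))
  chrom <- rep(as.character(seq_len(config$n_chroms)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(m) {
    cumsum(pmax(1, round(stats::rexp(m, 1 / config$snp_spacing_bp)))) + 10000L
  }), use.names = FALSE)
  # blocks never span chromosome borders
  block <- unlist(lapply(per_chrom, function(m) {
    ceiling(seq_len(m) / config$block_size_snps)
  }), use.names = FALSE)
  block <- cumsum(c(1L, diff(block) != 0 | diff(as.integer(factor(chrom))) != 0))
  chrom_lengths <- tapply(pos, chrom, max) + config$snp_spacing_bp
  list(chrom = chrom, pos = as.integer(pos), block = block,
       chrom_lengths = chrom_lengths[order(as.integer(names(chrom_lengths)))])
}

# Balding-Nichols drifted frequencies.
bn_drift <- function(p0, fst) {
  if (fst == 0) return(p0)
  a <- p0 * (1 - fst) / fst
  b <- (1 - p0) * (1 - fst) / fst
  pmin(pmax(stats::rbeta(length(p0), a, b), 1e-4), 1 - 1e-4)
}

# Draw n_hap haplotypes under first-order Markov copying within blocks.
draw_haplotypes <- function(n_hap, freqs, block, r) {
  M <- length(freqs)
  H <- matrix(0L, n_hap, M)
  H[, 1] <- stats::rbinom(n_hap, 1L, freqs[1])
  if (M == 1) return(H)
  for (j in 2:M) {
    fresh <- stats::rbinom(n_hap, 1L, freqs[j])
    if (block[j] == block[j - 1] && r > 0) {
      copy <- stats::runif(n_hap) < r
      H[, j] <- ifelse(copy, H[, j - 1], fresh)
    } else {
      H[, j] <- fresh
    }
  }
  H
}

#' Simulate population haplotype pools
#'
#' Draws ancestral allele frequencies Uniform(0.05, 0.95), drifts them per
#' population (cohort 2; cohort 1 base plus one extra drift per section) by
#' the Balding-Nichols model, then draws haplotypes with first-order Markov
#' LD within blocks. Pool sizes are 2 x the configured cohort sample sizes,
#' sections splitting cohort 1 evenly.
#'
#' @param config a [sim_config()].
#' @return list with `layout` (chrom/pos/block), `ancestral_freq`,
#'   `pop_freq` (list per population), `haplotypes` (list of 0/1 matrices,
#'   haplotypes x SNPs), and `section_of` mapping cohort-1 pools.
#' @export
simulate_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sim_haplotypes_core(config)
}

sim_haplotypes_core <- function(config) {
  layout <- sim_layout(config)
  M <- config$n_snps
  p0 <- stats::runif(M, 0.05, 0.95)
  c1_base <- bn_drift(p0, config$fst_between_cohorts)
  c2_freq <- bn_drift(p0, config$fst_between_cohorts)
  n_sec <- max(1L, config$n_sections)
  sec_freq <- lapply(seq_len(n_sec), function(s) {
    if (n_sec == 1) c1_base else bn_drift(c1_base, config$fst_between_sections)
  })
  sec_sizes <- diff(round(seq(0, config$n_per_cohort[1],
                              length.out = n_sec + 1)))
  haps <- vector("list", n_sec + 1)
  for (s in seq_len(n_sec)) {
    haps[[s]] <- draw_haplotypes(2L * sec_sizes[s], sec_freq[[s]],
                                 layout$block, config$within_block_r)
  }
  haps[[n_sec + 1]] <- draw_haplotypes(2L * config$n_per_cohort[2], c2_freq,
                                       layout$block, config$within_block_r)
  names(haps) <- c(paste0("cohort1_section", seq_len(n_sec)), "cohort2")
  list(layout = layout, ancestral_freq = p0,
       pop_freq = c(stats::setNames(sec_freq,
                                    paste0("cohort1_section", seq_len(n_sec))),
                    list(cohort2 = c2_freq)),
       haplotypes = haps, section_sizes = sec_sizes)
}

#' Ancestral site frequencies of a configuration
#'
#' Reproduces the ancestral allele frequencies and genome layout that
#' [simulate_cohorts()] will use under the same seed, without drawing
#' haplotypes. Useful for choosing causal SNP indices (e.g. a common variant
#' mid-chromosome) before running the full simulation.
#'
#' @param config a [sim_config()].
#' @return list with `freq` (ancestral alt-allele frequency per SNP) and
#'   `layout`.
#' @export
sim_site_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  layout <- sim_layout(config)
  freq <- stats::runif(config$n_snps, 0.05, 0.95)
  list(freq = freq, layout = layout)
}

#' Simulate a two-cohort genotype/phenotype study
#'
#' Generates genotypes, covariates (sex, age, farm, cohort, section), the
#' full trait panel, and a truth table for recovery tests. Same seed gives
#' byte-identical output.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_study` with elements `genotypes` (list of two
#'   [genotype_matrix()]), `phenotypes` (data.frame of covariates + traits),
#'   `truth` (list: `causal` table, `genetic` per-sample genetic values),
#'   `chrom_lengths`, `variant_scope`, `config`.
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  hp <- sim_haplotypes_core(config)
  layout <- hp$layout
  M <- config$n_snps
  n_blocks <- max(layout$block)

  # block-level cohort membership; causal blocks forced to their scope
  scopes <- sample(c("shared", "cohort1", "cohort2"), n_blocks,
                   replace = TRUE,
                   prob = c(config$prop_shared,
                            (1 - config$prop_shared) / 2,
                            (1 - config$prop_shared) / 2))
  cs <- config$causal_spec
  if (!is.null(cs)) {
    forced <- c(shared = "shared", cohort1_only = "cohort1",
                cohort2_only = "cohort2")
    scopes[layout$block[cs$snp]] <- forced[cs$scope]
  }
  snp_scope <- scopes[layout$block]

  n_sec <- max(1L, config$n_sections)
  geno_from_haps <- function(H) H[c(TRUE, FALSE), , drop = FALSE] +
    H[c(FALSE, TRUE), , drop = FALSE]
  G1_full <- do.call(rbind, lapply(seq_len(n_sec),
                                   function(s) geno_from_haps(hp$haplotypes[[s]])))
  G2_full <- geno_from_haps(hp$haplotypes[[n_sec + 1]])
  section <- rep(paste0("S", seq_len(n_sec)), hp$section_sizes)

  n1 <- config$n_per_cohort[1]; n2 <- config$n_per_cohort[2]
  ids1 <- sprintf("c1_%03d", seq_len(n1))
  ids2 <- sprintf("c2_%03d", seq_len(n2))
  cov <- data.frame(
    sample = c(ids1, ids2),
    cohort = rep(c("cohort1", "cohort2"), c(n1, n2)),
    section = c(section, rep(NA_character_, n2)),
    farm = c(paste0("c1_farm", sample.int(config$n_farms[1], n1, TRUE)),
             paste0("c2_farm", sample.int(config$n_farms[2], n2, TRUE))),
    sex = ifelse(stats::runif(n1 + n2) < 0.3, "M", "F"),
    age = pmin(pmax(round(stats::rnorm(n1 + n2, 12, 3.5), 1), 2), 28),
    stringsAsFactors = FALSE
  )

  G_all <- rbind(G1_full, G2_full)
  in_cohort <- list(cohort1 = snp_scope %in% c("shared", "cohort1"),
                    cohort2 = snp_scope %in% c("shared", "cohort2"))
  cohort_idx <- list(cohort1 = seq_len(n1), cohort2 = n1 + seq_len(n2))

  # latent trait values on the normal scale
  vc <- config$var_components
  ce <- config$covariate_effects
  tr <- config$traits
  latent <- matrix(0, n1 + n2, nrow(tr), dimnames = list(cov$sample, tr$trait))
  genetic <- latent
  farm_levels <- unique(cov$farm)
  for (t in seq_len(nrow(tr))) {
    farm_eff <- stats::setNames(
      stats::rnorm(length(farm_levels), 0, sqrt(vc[["farm"]])), farm_levels)
    y <- ce[["sex"]] * (cov$sex == "M") + ce[["age"]] * cov$age +
      farm_eff[cov$farm]
    g <- numeric(n1 + n2)
    for (co in c("cohort1", "cohort2")) {
      idx <- cohort_idx[[co]]
      vis <- which(in_cohort[[co]])
      if (vc[["polygenic"]] > 0 && length(vis) > 0) {
        Z <- scale(G_all[idx, vis, drop = FALSE])
        Z[is.na(Z) | is.nan(Z)] <- 0
        u <- stats::rnorm(length(vis))
        g[idx] <- as.numeric(Z %*% u) * sqrt(vc[["polygenic"]] / length(vis))
      } else if (vc[["polygenic"]] > 0) {
        g[idx] <- stats::rnorm(length(idx), 0, sqrt(vc[["polygenic"]]))
      }
    }
    causal_part <- numeric(n1 + n2)
    if (!is.null(cs)) {
      rows <- which(cs$trait == tr$trait[t])
      for (r in rows) {
        tgt <- switch(cs$scope[r],
                      shared = seq_len(n1 + n2),
                      cohort1_only = cohort_idx$cohort1,
                      cohort2_only = cohort_idx$cohort2)
        causal_part[tgt] <- causal_part[tgt] +
          G_all[tgt, cs$snp[r]] * cs$effect[r]
      }
    }
    eps <- stats::rnorm(n1 + n2, 0, sqrt(vc[["residual"]]))
    latent[, t] <- y + g + causal_part + eps
    genetic[, t] <- g + causal_part
  }

  # observed scale: invert the canonical transform per trait
  pheno <- cov
  for (t in seq_len(nrow(tr))) {
    y <- latent[, t]
    if (tr$type[t] == "binary") {
      thr1 <- stats::quantile(y[cohort_idx$cohort1],
                              config$liability_threshold)
      thr2 <- stats::quantile(y[cohort_idx$cohort2],
                              config$liability_threshold)
      obs <- as.integer(y > ifelse(cov$cohort == "cohort1", thr1, thr2))
    } else {
      obs <- switch(tr$transform[t],
                    identity = y,
                    log = exp(y),
                    sqrt = (y - min(y) + 0.5)^2)
    }
    pheno[[tr$trait[t]]] <- obs
  }

  variants <- data.frame(
    chrom = layout$chrom, pos = layout$pos,
    id = sprintf("snp%05d", seq_len(M)),
    ref = "A", alt = "G", stringsAsFactors = FALSE
  )
  genotypes <- lapply(c("cohort1", "cohort2"), function(co) {
    vis <- which(in_cohort[[co]])
    genotype_matrix(G_all[cohort_idx[[co]], vis, drop = FALSE],
                    variants[vis, , drop = FALSE],
                    cov$sample[cohort_idx[[co]]])
  })
  names(genotypes) <- c("cohort1", "cohort2")

  causal_truth <- if (is.null(cs)) {
    data.frame(snp = integer(), id = character(), chrom = character(),
               pos = integer(), trait = character(), effect = numeric(),
               scope = character(), stringsAsFactors = FALSE)
  } else {
    data.frame(snp = cs$snp, id = variants$id[cs$snp],
               chrom = variants$chrom[cs$snp], pos = variants$pos[cs$snp],
               trait = cs$trait, effect = cs$effect, scope = cs$scope,
               stringsAsFactors = FALSE)
  }

  structure(list(
    genotypes = genotypes, phenotypes = pheno,
    truth = list(causal = causal_truth, genetic = genetic, latent = latent),
    chrom_lengths = layout$chrom_lengths,
    variant_scope = snp_scope, variant_block = layout$block, config = config
  ), class = "sim_study")
}

#' Write a simulated study as a fixture bundle
#'
#' Emits `cohort1.vcf`, `cohort2.vcf`, `phenotypes.tsv`, `truth.tsv` (the
#' planted-causal table), `truth_samples.tsv` (per-sample genetic values)
#' and `genes.gff3`, a toy annotation tiling every simulated chromosome with
#' genes of cycling biotypes so that every callable region overlaps at
#' least one gene.
#'
#' @param sim a `sim_study` from [simulate_cohorts()].
#' @param dir output directory (created if needed).
#' @param gene_spacing_bp distance between consecutive toy gene starts.
#' @param gene_length_bp toy gene length.
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(sim, dir, gene_spacing_bp = 100000,
                                 gene_length_bp = 60000) {
  stopifnot(inherits(sim, "sim_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    cohort1 = file.path(dir, "cohort1.vcf"),
    cohort2 = file.path(dir, "cohort2.vcf"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    truth = file.path(dir, "truth.tsv"),
    truth_samples = file.path(dir, "truth_samples.tsv"),
    genes = file.path(dir, "genes.gff3")
  )
  write_genotypes_vcf(sim$genotypes$cohort1, paths[["cohort1"]])
  write_genotypes_vcf(sim$genotypes$cohort2, paths[["cohort2"]])
  data.table::fwrite(sim$phenotypes, paths[["phenotypes"]], sep = "\t",
                     na = "NA", quote = FALSE)
  data.table::fwrite(sim$truth$causal, paths[["truth"]], sep = "\t",
                     quote = FALSE)
  gv <- data.frame(sample = rownames(sim$truth$genetic),
                   sim$truth$genetic, check.names = FALSE)
  data.table::fwrite(gv, paths[["truth_samples"]], sep = "\t", quote = FALSE)
  write_toy_gff3(sim$chrom_lengths, paths[["genes"]],
                 gene_spacing_bp, gene_length_bp)
  invisible(paths)
}

# Toy GFF3: genes tile each chromosome at fixed spacing, biotypes cycling
# protein_coding / rna_gene / pseudogene.
write_toy_gff3 <- function(chrom_lengths, path, spacing = 100000,
                           len = 60000) {
  biotypes <- c("protein_coding", "lncRNA", "pseudogene")
  lines <- "##gff-version 3"
  k <- 0L
  for (chrom in names(chrom_lengths)) {
    starts <- seq(1, max(1, chrom_lengths[[chrom]] - len), by = spacing)
    for (s in starts) {
      k <- k + 1L
      bt <- biotypes[(k - 1L) %% 3L + 1L]
      type <- switch(bt, protein_coding = "gene", lncRNA = "ncRNA_gene",
                     pseudogene = "pseudogene")
      lines <- c(lines, paste(
        chrom, "sim", type, s, s + len - 1L, ".", "+", ".",
        sprintf("ID=toygene%05d;Name=TG%05d;biotype=%s", k, k, bt),
        sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
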