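#' Simulation configuration
#'
#' Describes a complete synthetic study: a small genome with gene annotation,
#' a genetic map, a paired multi-population expression experiment, and
#' per-disease GWAS focal-SNP lists with an optional planted enrichment for
#' overlap with differentially expressed (DE) genes.
#'
#' The defaults emulate the designed experiment the pipeline targets: six
#' subjects, each contributing one sample of all six effector-memory T cell
#' populations (three tissues -- peripheral blood, intraepithelial
#' lymphocytes (IEL), lamina propria lymphocytes (LPL) -- crossed with CD4
#' and CD8 lineages), processed in two batches, with additive
#' subject/batch/tissue/cell variance components on the log2 scale.
#'
#' @param n_genes Number of genes to simulate.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param n_subjects Number of paired subjects (>= 2).
#' @param populations Data frame with columns `tissue` and `cell`; one row
#'   per population sampled from every subject.
#' @param n_batches Number of processing batches; subjects are split across
#'   batches so that subject pairs stay within batch.
#' @param variance_components Named fractions (tissue, cell, subject, batch,
#'   residual) of the total log2 variance; must be non-negative and sum to 1.
#' @param total_variance Total per-gene log2 variance distributed across the
#'   components.
#' @param de_effects List of planted differential-expression effects, each a
#'   list with `contrast` (two population labels, `"tissue_cell"`), `log2fc`
#'   (offset added to the first population), and `fraction` of genes affected.
#' @param probes_per_gene Probes per probeset.
#' @param n_background_probes Non-expressed control probes tiling the GC range.
#' @param gene_length_range Min/max gene length in bp.
#' @param overlap_fraction Fraction of genes placed to overlap another gene
#'   (exercises unique-region merging downstream).
#' @param gene_mean_range Range of per-gene baseline log2 expression.
#' @param frac_unexpressed Fraction of genes whose signal sits at the
#'   background level (fail detection).
#' @param background_level Log2 intensity of the non-expressed background.
#' @param affinity_slope Log2 intensity gained per unit GC above 0.5
#'   (probe affinity model).
#' @param affinity_sd SD of the probe-specific affinity offset (log2).
#' @param probe_noise_sd SD of per-observation probe noise (log2).
#' @param map_mode `"uniform"` (constant recombination rate) or `"variable"`.
#' @param map_rate Recombination rate in cM/Mb for the uniform mode and the
#'   mean rate for the variable mode.
#' @param map_anchor_spacing Spacing of genetic-map anchors in bp.
#' @param diseases Character vector of disease/trait labels for SNP lists.
#' @param n_snps_per_disease Number of focal SNPs per disease.
#' @param frac_significant Fraction of SNPs drawn below genome-wide
#'   significance (5e-8); the rest are drawn above it.
#' @param enrichment_odds Planted odds (>= 0, may be `Inf`) that a
#'   significant SNP is placed inside a true DE gene rather than uniformly.
#' @param seed Integer master seed; every generator is a pure function of
#'   (config, seed).
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 100, chrom_lengths = c(chr1 = 1e7), seed = 1)
#' cfg$n_subjects
sim_config <- function(n_genes = 10000,
                       chrom_lengths = c(chr1 = 1e8, chr2 = 1e8, chr3 = 1e8,
                                         chr4 = 1e8, chr5 = 1e8),
                       n_subjects = 6,
                       populations = default_populations(),
                       n_batches = 2,
                       variance_components = c(tissue = 0.5, cell = 0.2,
                                               subject = 0.05, batch = 0.05,
                                               residual = 0.2),
                       total_variance = 0.5,
                       de_effects = list(list(
                         contrast = c("LPL_CD4", "blood_CD4"),
                         log2fc = 1.0, fraction = 0.05)),
                       probes_per_gene = 4,
                       n_background_probes = 500,
                       gene_length_range = c(5e3, 3e4),
                       overlap_fraction = 0.1,
                       gene_mean_range = c(6, 12),
                       frac_unexpressed = 0.05,
                       background_level = 4,
                       affinity_slope = 1.5,
                       affinity_sd = 0.3,
                       probe_noise_sd = 0.2,
                       map_mode = c("uniform", "variable"),
                       map_rate = 1,
                       map_anchor_spacing = 1e6,
                       diseases = "trait_1",
                       n_snps_per_disease = 400,
                       frac_significant = 0.5,
                       enrichment_odds = 0,
                       seed = 1) {
  map_mode <- match.arg(map_mode)
  if (is.list(chrom_lengths)) chrom_lengths <- unlist(chrom_lengths)
  if (is.data.frame(populations)) {
    populations <- as.data.frame(populations, stringsAsFactors = FALSE)
  } else if (is.list(populations)) {
    populations <- do.call(rbind, lapply(populations, function(p) {
      data.frame(tissue = p[[1]], cell = p[[2]], stringsAsFactors = FALSE)
    }))
  }
  if (is.list(variance_components)) {
    variance_components <- unlist(variance_components)
  }
  cfg <- structure(list(
    n_genes = as.integer(n_genes),
    chrom_lengths = chrom_lengths,
    n_subjects = as.integer(n_subjects),
    populations = populations,
    n_batches = as.integer(n_batches),
    variance_components = variance_components,
    total_variance = total_variance,
    de_effects = de_effects,
    probes_per_gene = as.integer(probes_per_gene),
    n_background_probes = as.integer(n_background_probes),
    gene_length_range = as.numeric(gene_length_range),
    overlap_fraction = overlap_fraction,
    gene_mean_range = as.numeric(gene_mean_range),
    frac_unexpressed = frac_unexpressed,
    background_level = background_level,
    affinity_slope = affinity_slope,
    affinity_sd = affinity_sd,
    probe_noise_sd = probe_noise_sd,
    map_mode = map_mode,
    map_rate = map_rate,
    map_anchor_spacing = map_anchor_spacing,
    diseases = as.character(diseases),
    n_snps_per_disease = as.integer(n_snps_per_disease),
    frac_significant = frac_significant,
    enrichment_odds = enrichment_odds,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
}

#' The six default T cell populations
#'
#' Three tissues (blood, IEL, LPL) crossed with two lineages (CD4, CD8).
#' @return Data frame with columns `tissue` and `cell`.
#' @export
default_populations <- function() {
  expand.grid(tissue = c("blood", "IEL", "LPL"), cell = c("CD4", "CD8"),
              stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
}

pop_label <- function(tissue, cell) paste(tissue, cell, sep = "_")

validate_sim_config <- function(cfg) {
  vc <- cfg$variance_components
  needed <- c("tissue", "cell", "subject", "batch", "residual")
  if (!all(needed %in% names(vc))) {
    stopf("variance_components must name all of: %s",
          paste(needed, collapse = ", "))
  }
  if (any(vc < 0) || abs(sum(vc) - 1) > 1e-8) {
    stopf("variance_components must be >= 0 and sum to 1 (got sum %.6f)",
          sum(vc))
  }
  if (length(cfg$chrom_lengths) > 0 &&
      (is.null(names(cfg$chrom_lengths)) || any(cfg$chrom_lengths <= 0))) {
    stopf("chrom_lengths must be a named vector of positive lengths")
  }
  if (cfg$n_subjects < 2) stopf("n_subjects must be >= 2")
  if (cfg$n_genes < 0) stopf("n_genes must be >= 0")
  if (!(cfg$enrichment_odds >= 0)) stopf("enrichment_odds must be >= 0")
  if (cfg$overlap_fraction < 0 || cfg$overlap_fraction > 1) {
    stopf("overlap_fraction must be in [0, 1]")
  }
  if (cfg$frac_significant < 0 || cfg$frac_significant > 1) {
    stopf("frac_significant must be in [0, 1]")
  }
  if (diff(cfg$gene_length_range) < 0 || cfg$gene_length_range[1] <= 0) {
    stopf("gene_length_range must be positive and non-decreasing")
  }
  pops <- pop_label(cfg$populations$tissue, cfg$populations$cell)
  for (eff in cfg$de_effects) {
    bad <- setdiff(eff$contrast, pops)
    if (length(bad)) {
      stopf("de_effects contrast references unknown population(s): %s",
            paste(bad, collapse = ", "))
    }
    if (eff$fraction < 0 || eff$fraction > 1) {
      stopf("de_effects fraction must be in [0, 1]")
    }
  }
  cfg
}

#' Read a simulation configuration from YAML
#'
#' The YAML file mirrors the arguments of [sim_config()]; omitted keys take
#' their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, raw)
}
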