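#' Generate a synthetic gene annotation
#'
#' Places `n_genes` gene spans on the configured chromosomes. A fraction
#' `1 - overlap_fraction` of genes is laid out pairwise-disjoint (gene
#' lengths drawn from `gene_length_range`, gaps by uniform stick-breaking);
#' the remaining genes are each placed to overlap a randomly chosen disjoint
#' gene, so that downstream unique-region merging is exercised.
#'
#' @param config A [sim_config()] object.
#' @return A `gene_annotation`: data frame with columns `gene`, `chrom`,
#'   `start`, `end` (0-based half-open), sorted by chromosome and start.
#' @export
#' @examples
#' ann <- generate_annotation(sim_config(n_genes = 50,
#'   chrom_lengths = c(chr1 = 1e7), seed = 1))
#' head(ann)
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$chrom_lengths) == 0) stopf("chrom_lengths is empty")
  lr <- config$gene_length_range
  if (lr[2] > min(config$chrom_lengths)) {
    stopf("gene length range (max %g bp) exceeds shortest chromosome (%g bp)",
          lr[2], min(config$chrom_lengths))
  }
  n <- config$n_genes
  empty <- data.frame(gene = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("gene_annotation", "data.frame")
  if (n == 0) return(empty)

  with_seed(stage_seed(config$seed, "synthdata", "annotation"), {
    n_over <- round(n * config$overlap_fraction)
    n_seed <- n - n_over
    chroms <- names(config$chrom_lengths)
    lens <- config$chrom_lengths
    counts <- as.vector(stats::rmultinom(1, n_seed, prob = lens))
    pieces <- vector("list", length(chroms))
    for (i in seq_along(chroms)) {
      k <- counts[i]
      if (k == 0) next
      glen <- round(runif(k, lr[1], lr[2]))
      free <- lens[i] - sum(glen)
      if (free < 0) {
        stopf("chromosome %s too short for %d disjoint genes of mean %g bp",
              chroms[i], k, mean(lr))
      }
      cuts <- sort(runif(k, 0, free))
      starts <- floor(cuts + c(0, cumsum(glen))[seq_len(k)])
      pieces[[i]] <- data.frame(chrom = chroms[i], start = starts,
                                end = starts + glen,
                                stringsAsFactors = FALSE)
    }
    ann <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
    if (n_over > 0 && nrow(ann) > 0) {
      host <- sample.int(nrow(ann), n_over, replace = TRUE)
      glen <- round(runif(n_over, lr[1], lr[2]))
      start <- floor(runif(n_over, ann$start[host],
                           pmax(ann$start[host] + 1, ann$end[host] - 1)))
      end <- pmin(start + glen, lens[ann$chrom[host]])
      ann <- rbind(ann, data.frame(chrom = ann$chrom[host], start = start,
                                   end = end, stringsAsFactors = FALSE))
    }
    ann <- ann[order(match(ann$chrom, chroms), ann$start, ann$end), ]
    ann <- data.frame(gene = sprintf("g%05d", seq_len(nrow(ann))),
                      ann, stringsAsFactors = FALSE)
    rownames(ann) <- NULL
    class(ann) <- c("gene_annotation", "data.frame")
    ann
  })
}

#' Generate a synthetic genetic map
#'
#' Produces per-chromosome anchors (bp, cM) with strictly increasing bp and
#' non-decreasing cM. In `"uniform"` mode the map has constant rate
#' `map_rate` cM/Mb so that `cM = bp * rate / 1e6` exactly at every anchor.
#' In `"variable"` mode per-interval rates are drawn from a gamma
#' distribution with mean `map_rate`, with 10% of intervals set to rate 0
#' (recombination plateaus, which exercise the maximally-inclusive inverse
#' interpolation of window construction).
#'
#' @param config A [sim_config()] object.
#' @return A `genetic_map`: data frame with columns `chrom`, `bp` (1-based),
#'   `cM`.
#' @export
generate_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$chrom_lengths) == 0) stopf("chrom_lengths is empty")
  with_seed(stage_seed(config$seed, "synthdata", "map"), {
    pieces <- lapply(names(config$chrom_lengths), function(ch) {
      L <- config$chrom_lengths[[ch]]
      bp <- unique(c(1, seq(config$map_anchor_spacing, L,
                            by = config$map_anchor_spacing), L))
      bp <- sort(bp)
      if (config$map_mode == "uniform") {
        cm <- bp * config$map_rate / 1e6
      } else {
        k <- length(bp) - 1
        rate <- rgamma(k, shape = 2, scale = config$map_rate / 2)
        rate[runif(k) < 0.1] <- 0
        cm <- cumsum(c(0, rate * diff(bp) / 1e6))
      }
      data.frame(chrom = ch, bp = bp, cM = cm, stringsAsFactors = FALSE)
    })
    map <- do.call(rbind, pieces)
    rownames(map) <- NULL
    class(map) <- c("genetic_map", "data.frame")
    map
  })
}

#' Generate a synthetic paired expression experiment
#'
#' Simulates the designed experiment: each subject contributes one sample of
#' every population, and the log2 gene-level signal decomposes additively as
#' gene mean + tissue effect + cell effect + subject effect + batch effect +
#' residual noise, with per-factor variances equal to
#' `variance_components * total_variance`. Genes selected for a planted
#' differential-expression effect additionally receive the configured log2
#' offset in the first population of their contrast. A fraction of genes is
#' non-expressed: their signal sits at the background level.
#'
#' Probe-level linear intensities are `2^(gene signal + affinity + noise)`
#' where affinity = `affinity_slope * (GC - 0.5)` plus a probe-specific
#' offset, constant across samples. Background probes carry affinity-only
#' signal around `background_level` and tile the GC range uniformly, so that
#' every occupied GC bin holds background probes for detection calls.
#'
#' @param config A [sim_config()] object.
#' @param annotation A `gene_annotation` from [generate_annotation()].
#' @param probe_level Also simulate probe-level intensities. `FALSE` skips
#'   them (the gene-level matrix and ground truth are unchanged, as probe
#'   draws come after the gene-level ones), which is convenient for large
#'   calibration sweeps that consume only gene-level truth.
#' @return List with elements `probes` (a `probe_matrix`: linear-scale
#'   probe x sample intensities with probe and sample metadata; `NULL`
#'   when `probe_level = FALSE`), `genes` (an `expression_matrix` holding
#'   the true log2 gene-level signal), and `ground_truth` (planted DE genes
#'   per contrast, true variance fractions, unexpressed genes).
#' @export
generate_expression <- function(config, annotation, probe_level = TRUE) {
  stopifnot(inherits(config, "sim_config"),
            inherits(annotation, "gene_annotation"))
  genes <- annotation$gene
  n <- length(genes)
  pops <- config$populations
  pop_labels <- pop_label(pops$tissue, pops$cell)
  with_seed(stage_seed(config$seed, "synthdata", "expression"), {
    subjects <- sprintf("S%d", seq_len(config$n_subjects))
    batch_of <- sprintf("B%d", ((seq_len(config$n_subjects) - 1) *
                                  config$n_batches) %/% config$n_subjects + 1)
    sample_meta <- do.call(rbind, lapply(seq_len(config$n_subjects),
      function(s) {
        data.frame(sample = paste0(subjects[s], "_", pop_labels),
                   subject = subjects[s], tissue = pops$tissue,
                   cell = pops$cell, batch = batch_of[s],
                   stringsAsFactors = FALSE)
      }))
    S <- nrow(sample_meta)

    sig2 <- config$variance_components * config$total_variance
    tis_lv <- unique(pops$tissue); cel_lv <- unique(pops$cell)
    bat_lv <- unique(batch_of)
    eff <- function(levels, s2) {
      matrix(rnorm(n * length(levels), sd = sqrt(s2)), n,
             dimnames = list(genes, levels))
    }
    tis_eff <- eff(tis_lv, sig2[["tissue"]])
    cel_eff <- eff(cel_lv, sig2[["cell"]])
    sub_eff <- eff(subjects, sig2[["subject"]])
    bat_eff <- eff(bat_lv, sig2[["batch"]])

    mu <- runif(n, config$gene_mean_range[1], config$gene_mean_range[2])
    unexpressed <- genes[runif(n) < config$frac_unexpressed]
    expressed <- setdiff(genes, unexpressed)

    G <- matrix(mu, n, S) +
      tis_eff[, sample_meta$tissue, drop = FALSE] +
      cel_eff[, sample_meta$cell, drop = FALSE] +
      sub_eff[, sample_meta$subject, drop = FALSE] +
      bat_eff[, sample_meta$batch, drop = FALSE] +
      matrix(rnorm(n * S, sd = sqrt(sig2[["residual"]])), n, S)
    dimnames(G) <- list(genes, sample_meta$sample)

    true_de <- list()
    samp_pop <- pop_label(sample_meta$tissue, sample_meta$cell)
    for (effect in config$de_effects) {
      bad <- setdiff(effect$contrast, pop_labels)
      if (length(bad)) {
        stopf("de_effects references unknown population(s): %s",
              paste(bad, collapse = ", "))
      }
      n_de <- round(effect$fraction * n)
      de_genes <- sort(sample(expressed, min(n_de, length(expressed))))
      G[de_genes, samp_pop == effect$contrast[1]] <-
        G[de_genes, samp_pop == effect$contrast[1]] + effect$log2fc
      true_de[[paste(effect$contrast, collapse = "_vs_")]] <- de_genes
    }
    G[unexpressed, ] <- config$background_level

    gt <- structure(list(
      true_de_genes = true_de,
      true_variance_fractions = config$variance_components,
      unexpressed_genes = unexpressed,
      planted_enriched_loci = character(0)
    ), class = "ground_truth")
    detected <- matrix(!(genes %in% unexpressed), n, S,
                       dimnames = dimnames(G))
    if (!probe_level) {
      return(list(probes = NULL,
                  genes = new_expression_matrix(G, detected, sample_meta),
                  ground_truth = gt))
    }

    ppg <- config$probes_per_gene
    probe_gene <- rep(genes, each = ppg)
    probe_ids <- paste0(probe_gene, "_p", rep(seq_len(ppg), n))
    gc_fg <- rbeta(n * ppg, 5, 5)
    nb <- config$n_background_probes
    gc_bg <- runif(nb)
    probe_meta <- data.frame(
      probe = c(probe_ids, sprintf("bg%04d", seq_len(nb))),
      gene = c(probe_gene, rep(NA_character_, nb)),
      gc = c(gc_fg, gc_bg),
      is_background = rep(c(FALSE, TRUE), c(n * ppg, nb)),
      stringsAsFactors = FALSE)
    affinity <- config$affinity_slope * (probe_meta$gc - 0.5) +
      rnorm(nrow(probe_meta), sd = config$affinity_sd)
    base <- rbind(G[probe_gene, , drop = FALSE],
                  matrix(config$background_level, nb, S))
    log2_int <- base + affinity +
      matrix(rnorm(nrow(probe_meta) * S, sd = config$probe_noise_sd),
             nrow(probe_meta), S)
    intensities <- 2^log2_int
    dimnames(intensities) <- list(probe_meta$probe, sample_meta$sample)

    list(
      probes = new_probe_matrix(intensities, probe_meta, sample_meta),
      genes = new_expression_matrix(G, detected, sample_meta),
      ground_truth = gt
    )
  })
}

#' Generate per-disease GWAS focal-SNP lists
#'
#' For each configured disease, draws `n_snps_per_disease` SNPs. A fraction
#' `frac_significant` receives association p-values log-uniform in
#' \[1e-30, 5e-8) (genome-wide significant); the rest log-uniform in
#' \[5e-8, 1\]. Each significant SNP is, with probability
#' `enrichment_odds / (1 + enrichment_odds)`, placed inside a uniformly
#' chosen true DE gene (so its cM window necessarily covers that gene);
#' otherwise (and for all non-significant SNPs) it is placed uniformly on
#' the genome. Targeted significant SNPs are recorded in
#' `ground_truth$planted_enriched_loci`.
#'
#' @param config A [sim_config()] object.
#' @param annotation A `gene_annotation`.
#' @param ground_truth A `ground_truth` from [generate_expression()].
#' @param map A `genetic_map` covering the annotation's chromosomes.
#' @return List with `loci` (named list of `snp_locus_set` data frames, one
#'   per disease: `disease`, `snp_id`, `chrom`, `bp` 1-based, `p`) and an
#'   updated `ground_truth`.
#' @export
generate_snp_lists <- function(config, annotation, ground_truth, map) {
  stopifnot(inherits(config, "sim_config"),
            inherits(annotation, "gene_annotation"),
            inherits(ground_truth, "ground_truth"),
            inherits(map, "genetic_map"))
  missing_ch <- setdiff(unique(annotation$chrom), unique(map$chrom))
  if (length(missing_ch)) {
    stopf("genetic map does not cover chromosome(s): %s",
          paste(missing_ch, collapse = ", "))
  }
  de_genes <- sort(unique(unlist(ground_truth$true_de_genes,
                                 use.names = FALSE)))
  if (config$enrichment_odds > 0 && length(de_genes) == 0) {
    stopf("enrichment planting requested (enrichment_odds = %g) but ground truth has no DE genes",
          config$enrichment_odds)
  }
  de_ann <- annotation[match(de_genes, annotation$gene), , drop = FALSE]
  q <- if (is.infinite(config$enrichment_odds)) 1 else
    config$enrichment_odds / (1 + config$enrichment_odds)

  with_seed(stage_seed(config$seed, "synthdata", "snps"), {
    chroms <- names(config$chrom_lengths)
    lens <- config$chrom_lengths
    planted <- character(0)
    loci <- lapply(config$diseases, function(dz) {
      n <- config$n_snps_per_disease
      if (n == 0) {
        return(snp_locus_set(data.frame(
          disease = character(0), snp_id = character(0),
          chrom = character(0), bp = numeric(0), p = numeric(0),
          stringsAsFactors = FALSE)))
      }
      n_sig <- round(n * config$frac_significant)
      p <- c(10^runif(n_sig, -30, log10(5e-8) - 1e-9),
             10^runif(n - n_sig, log10(5e-8), 0))
      sig <- rep(c(TRUE, FALSE), c(n_sig, n - n_sig))
      targeted <- sig & (runif(n) < q)
      chrom <- sample(chroms, n, replace = TRUE, prob = lens)
      bp <- floor(runif(n, 1, lens[chrom] + 1))
      if (any(targeted)) {
        idx <- sample.int(nrow(de_ann), sum(targeted), replace = TRUE)
        chrom[targeted] <- de_ann$chrom[idx]
        bp[targeted] <- floor(runif(sum(targeted), de_ann$start[idx] + 1,
                                    de_ann$end[idx] + 1))
      }
      ids <- sprintf("%s_rs%05d", dz, seq_len(n))
      planted <<- c(planted, ids[targeted])
      snp_locus_set(data.frame(disease = dz, snp_id = ids, chrom = chrom,
                               bp = bp, p = p, stringsAsFactors = FALSE))
    })
    names(loci) <- config$diseases
    ground_truth$planted_enriched_loci <- planted
    list(loci = loci, ground_truth = ground_truth)
  })
}

snp_locus_set <- function(df) {
  class(df) <- c("snp_locus_set", "data.frame")
  df
}
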