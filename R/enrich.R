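#' @importFrom GenomicRanges GRanges findOverlaps countOverlaps reduce
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

AUTOSOME_RE <- "^(chr)?[0-9]+$"
CHROM_RE <- "^(chr)?([0-9]+|[XYxy]|[Mm][Tt]?)$"

# closed bp window [start_bp, end_bp] -> the integer bases it contains
windows_granges <- function(loci) {
  if (is.null(loci$start_bp)) {
    stopf("loci have no windows; run filter_loci() first")
  }
  GRanges(loci$chrom,
          IRanges(ceiling(loci$start_bp), floor(loci$end_bp)))
}

genes_granges <- function(annotation, genes = NULL) {
  ann <- annotation
  if (!is.null(genes)) {
    idx <- match(genes, ann$gene)
    if (anyNA(idx)) {
      stopf("unknown gene id(s): %s",
            paste(head(genes[is.na(idx)], 5), collapse = ", "))
    }
    ann <- ann[idx, , drop = FALSE]
  }
  # annotation is 0-based half-open; GRanges is 1-based closed
  gr <- GRanges(ann$chrom, IRanges(ann$start + 1, ann$end))
  names(gr) <- ann$gene
  gr
}

#' Filter focal-SNP lists and build their cM windows
#'
#' Drops SNPs that do not reach genome-wide significance
#' (p >= `gws_threshold`) or do not map to an autosome, builds the
#' `window_cm` window around each survivor, and resolves transitively
#' overlapping windows within each disease by keeping only the SNP with the
#' smallest association p-value per overlap group (ties broken by
#' lexicographically smallest snp_id). The result has pairwise-disjoint
#' windows.
#'
#' @param raw A `snp_locus_set` data frame (`disease`, `snp_id`, `chrom`,
#'   `bp`, `p`).
#' @param map A `genetic_map` covering all autosomes present.
#' @param gws_threshold Genome-wide significance threshold; default 5e-8.
#' @param window_cm Window half-width in cM; default 0.2.
#' @return A filtered `snp_locus_set` with `start_bp`, `end_bp` columns and
#'   a `window_cm` attribute.
#' @export
filter_loci <- function(raw, map, gws_threshold = 5e-8, window_cm = 0.2) {
  stopifnot(inherits(map, "genetic_map"))
  bad <- unique(raw$chrom[!grepl(CHROM_RE, raw$chrom)])
  if (length(bad)) {
    stopf("malformed chromosome label(s): %s", paste(bad, collapse = ", "))
  }
  keep <- raw$p < gws_threshold & grepl(AUTOSOME_RE, raw$chrom)
  loci <- raw[keep, , drop = FALSE]
  if (nrow(loci) == 0) {
    loci$start_bp <- numeric(0)
    loci$end_bp <- numeric(0)
    attr(loci, "window_cm") <- window_cm
    return(snp_locus_set(loci))
  }
  missing_ch <- setdiff(unique(loci$chrom), unique(map$chrom))
  if (length(missing_ch)) {
    stopf("genetic map does not cover autosome(s): %s",
          paste(missing_ch, collapse = ", "))
  }
  win <- t(vapply(seq_len(nrow(loci)), function(i) {
    build_window(map, loci$chrom[i], loci$bp[i], window_cm)
  }, numeric(2)))
  loci$start_bp <- win[, 1]
  loci$end_bp <- win[, 2]

  kept <- lapply(split(seq_len(nrow(loci)), loci$disease), function(idx) {
    sub <- loci[idx, , drop = FALSE]
    gr <- windows_granges(sub)
    merged <- reduce(gr, min.gapwidth = 0L)
    grp <- subjectHits(findOverlaps(gr, merged, minoverlap = 1L))
    vapply(split(seq_along(grp), grp), function(g) {
      o <- g[order(sub$p[g], sub$snp_id[g])]
      idx[o[1]]
    }, integer(1))
  })
  out <- loci[sort(unlist(kept, use.names = FALSE)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window_cm") <- window_cm
  snp_locus_set(out)
}

#' Count unique genomic regions covered by a gene list
#'
#' Merges gene spans that share at least one base (transitively, per
#' chromosome) and returns the number of merged regions. This count sizes
#' each draw of the permutation null, so that gene lists dense in clustered
#' loci are not over-weighted.
#'
#' @param genes Character vector of gene ids.
#' @param annotation A `gene_annotation`.
#' @return Integer count of merged regions.
#' @export
unique_regions <- function(genes, annotation) {
  if (length(genes) == 0) return(0L)
  gr <- genes_granges(annotation, genes)
  length(reduce(gr, min.gapwidth = 0L))
}

#' Fraction of loci whose window overlaps a listed gene
#'
#' @param loci A filtered `snp_locus_set` (with windows).
#' @param genes Character vector of gene ids.
#' @param annotation A `gene_annotation`.
#' @return Fraction in \[0,1\]: the share of loci whose closed bp window
#'   shares at least one base with at least one listed gene span.
#' @export
overlap_fraction <- function(loci, genes, annotation) {
  if (nrow(loci) == 0) stopf("no loci to test (n_loci = 0)")
  if (length(genes) == 0) return(0)
  win <- windows_granges(loci)
  gr <- genes_granges(annotation, genes)
  mean(countOverlaps(win, gr, minoverlap = 1L) > 0)
}

# genes x loci sparse incidence: does gene i's span intersect locus j's window
locus_gene_incidence <- function(loci, genes, annotation) {
  win <- windows_granges(loci)
  gr <- genes_granges(annotation, genes)
  hits <- findOverlaps(gr, win, minoverlap = 1L)
  Matrix::sparseMatrix(i = queryHits(hits), j = subjectHits(hits), x = 1,
                       dims = c(length(gr), length(win)))
}

#' Permutation test of locus-gene-list overlap
#'
#' Tests whether the observed fraction of loci overlapping a differential
#' gene list exceeds what random gene lists achieve. Each null iteration
#' draws, uniformly without replacement from the expressed set, as many
#' genes as the differential list has unique genomic regions
#' ([unique_regions()]), and recomputes the overlap fraction. The one-sided
#' empirical p-value is `(1 + #(null >= observed)) / (1 + n_perm)`. When
#' `choose(N, m)` is at most `exhaustive_cap` (and mode is `"auto"` or
#' `"exhaustive"`), all draws are enumerated instead and the exact p-value
#' `#(draws >= observed) / choose(N, m)` is returned.
#'
#' @param loci A filtered `snp_locus_set`.
#' @param de_genes Differential gene ids (subset of `expressed_genes`).
#' @param expressed_genes The expressed sampling frame (subset of the
#'   annotation's genes).
#' @param annotation A `gene_annotation`.
#' @param n_perm Number of Monte-Carlo iterations.
#' @param seed Integer seed for the Monte-Carlo draws.
#' @param mode `"auto"`, `"monte_carlo"`, or `"exhaustive"`.
#' @param exhaustive_cap Maximum number of draws to enumerate exhaustively.
#' @param gene_list Label carried into the result.
#' @param keep_null Keep the full vector of null fractions.
#' @return An `enrichment_result`.
#' @export
permutation_test <- function(loci, de_genes, expressed_genes, annotation,
                             n_perm = 10000, seed = 1,
                             mode = c("auto", "monte_carlo", "exhaustive"),
                             exhaustive_cap = 2e5, gene_list = "de",
                             keep_null = FALSE) {
  mode <- match.arg(mode)
  if (length(setdiff(de_genes, expressed_genes))) {
    stopf("de_genes must be a subset of expressed_genes")
  }
  m <- unique_regions(de_genes, annotation)
  observed <- overlap_fraction(loci, de_genes, annotation)
  N <- length(expressed_genes)
  if (m > N) stopf("unique-region count exceeds expressed-set size")
  n_draws <- choose(N, m)
  if (mode == "auto") {
    mode <- if (n_draws <= exhaustive_cap) "exhaustive" else "monte_carlo"
  }
  if (mode == "exhaustive" && n_draws > exhaustive_cap) {
    stopf("exhaustive mode infeasible: choose(%d, %d) = %g draws > cap %g",
          N, m, n_draws, exhaustive_cap)
  }
  inc <- locus_gene_incidence(loci, expressed_genes, annotation)
  n_loci <- nrow(loci)
  eps <- 1e-12

  if (mode == "exhaustive") {
    draws <- combn(N, m)
    nulls <- null_fractions(inc, draws, n_loci)
    p <- sum(nulls >= observed - eps) / ncol(draws)
    n_used <- ncol(draws)
    used_seed <- NA_integer_
  } else {
    if (n_perm < 1) stopf("n_perm must be >= 1 in monte_carlo mode")
    nulls <- with_seed(seed, {
      draws <- vapply(seq_len(n_perm), function(i) sample.int(N, m),
                      integer(m))
      if (m == 1) draws <- matrix(draws, nrow = 1)
      null_fractions(inc, draws, n_loci)
    })
    p <- (1 + sum(nulls >= observed - eps)) / (1 + n_perm)
    n_used <- n_perm
    used_seed <- seed
  }
  structure(list(
    disease = if (nrow(loci)) loci$disease[1] else NA_character_,
    gene_list = gene_list,
    n_loci = n_loci,
    observed_fraction = observed,
    m_unique_regions = m,
    n_perm = n_used,
    null_mean = mean(nulls),
    null_sd = sd(nulls),
    null_fractions = if (keep_null) nulls else NULL,
    empirical_p = p,
    mode = mode,
    seed = used_seed
  ), class = "enrichment_result")
}

# fraction of loci hit for each draw (columns of a m x n_draws index matrix)
null_fractions <- function(inc, draws, n_loci) {
  n_draws <- ncol(draws)
  m <- nrow(draws)
  sel <- Matrix::sparseMatrix(i = rep(seq_len(n_draws), each = m),
                              j = as.vector(draws), x = 1,
                              dims = c(n_draws, nrow(inc)))
  hits <- sel %*% inc
  Matrix::rowSums(hits > 0) / n_loci
}

#' Run the full disease-by-gene-list enrichment screen
#'
#' @param loci_sets Named list of filtered `snp_locus_set`s, one per
#'   disease.
#' @param gene_lists Named list of differential gene-id vectors.
#' @param expressed_genes The expressed sampling frame.
#' @param annotation A `gene_annotation`.
#' @param n_perm Monte-Carlo iterations per cell.
#' @param seed Master seed; each grid cell derives its own seed with
#'   [stage_seed()].
#' @param mode Passed to [permutation_test()].
#' @param adjust Add a BH-adjusted p-value column across the grid.
#' @param ... Further arguments to [permutation_test()].
#' @return List with `results` (one row per disease x gene list:
#'   `disease`, `gene_list`, `n_loci`, `m_regions`, `observed_fraction`,
#'   `empirical_p`, optionally `p_adj`, `n_perm`, `seed`, `mode`) and
#'   `details` (the `enrichment_result` objects).
#' @export
screen_enrichment <- function(loci_sets, gene_lists, expressed_genes,
                              annotation, n_perm = 10000, seed = 1,
                              mode = "auto", adjust = FALSE, ...) {
  if (anyDuplicated(names(loci_sets))) {
    stopf("duplicated disease labels: %s",
          paste(unique(names(loci_sets)[duplicated(names(loci_sets))]),
                collapse = ", "))
  }
  if (is.null(names(gene_lists)) || anyDuplicated(names(gene_lists))) {
    stopf("gene_lists must have unique names")
  }
  details <- list()
  rows <- list()
  for (dz in names(loci_sets)) {
    for (gl in names(gene_lists)) {
      cell_seed <- stage_seed(seed, "enrich", dz, gl)
      res <- permutation_test(loci_sets[[dz]], gene_lists[[gl]],
                              expressed_genes, annotation, n_perm = n_perm,
                              seed = cell_seed, mode = mode,
                              gene_list = gl, ...)
      res$disease <- dz
      details[[paste(dz, gl, sep = ".")]] <- res
      rows[[length(rows) + 1L]] <- data.frame(
        disease = dz, gene_list = gl, n_loci = res$n_loci,
        m_regions = res$m_unique_regions,
        observed_fraction = res$observed_fraction,
        empirical_p = res$empirical_p, n_perm = res$n_perm,
        seed = res$seed, mode = res$mode, stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  if (adjust) results$p_adj <- bh_adjust(results$empirical_p)
  list(results = results, details = details)
}

#' Annotate loci with overlapping differential genes per population
#'
#' For each filtered locus and each population's differential gene list,
#' reports the (possibly empty) set of genes whose span overlaps the locus
#' window, sorted by genomic start. Loci with no overlap in a population
#' are kept with an empty gene field, mirroring shaded-but-empty cells in a
#' locus-annotation table.
#'
#' @param loci A filtered `snp_locus_set`.
#' @param de_lists Named list (population -> gene-id vector).
#' @param annotation A `gene_annotation`.
#' @return Long data frame `disease`, `snp_id`, `population`, `gene`
#'   (`""` when the set is empty).
#' @export
annotate_loci <- function(loci, de_lists, annotation) {
  if (is.null(names(de_lists))) stopf("de_lists must be named by population")
  win <- windows_granges(loci)
  rows <- list()
  for (pop in names(de_lists)) {
    genes <- de_lists[[pop]]
    if (length(genes)) {
      gr <- genes_granges(annotation, genes)
      hits <- findOverlaps(win, gr, minoverlap = 1L)
      hit_list <- split(subjectHits(hits), queryHits(hits))
    } else {
      hit_list <- list()
    }
    for (i in seq_len(nrow(loci))) {
      js <- hit_list[[as.character(i)]]
      if (is.null(js)) {
        g <- ""
      } else {
        ann_idx <- match(genes[js], annotation$gene)
        g <- genes[js][order(annotation$start[ann_idx])]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        disease = loci$disease[i], snp_id = loci$snp_id[i],
        population = pop, gene = g, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stratified Fisher test of transcription-factor target enrichment at loci
#'
#' Splits the loci into those whose window overlaps a differential gene and
#' those that do not, scores each locus for overlap with at least one gene
#' of a user-supplied target set (e.g. ChIP-derived transcription-factor
#' targets), and tests the 2x2 stratum-by-target table with Fisher's exact
#' test. The odds ratio uses the Haldane +0.5 correction when any cell is
#' zero.
#'
#' @param loci A filtered `snp_locus_set`.
#' @param de_genes Differential gene ids defining the strata.
#' @param annotation A `gene_annotation`.
#' @param target_genes Target-set gene ids.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return List with `table` (2x2), `odds_ratio`, `p`, `alternative`.
#' @export
stratified_fisher <- function(loci, de_genes, annotation, target_genes,
                              alternative = c("two.sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  win <- windows_granges(loci)
  de_hit <- countOverlaps(win, genes_granges(annotation, de_genes),
                          minoverlap = 1L) > 0
  if (all(de_hit) || !any(de_hit)) {
    stopf("a stratum has zero loci (all loci %s a differential gene)",
          if (all(de_hit)) "overlap" else "miss")
  }
  tg_hit <- countOverlaps(win, genes_granges(annotation, target_genes),
                          minoverlap = 1L) > 0
  tab <- table(stratum = factor(de_hit, levels = c(TRUE, FALSE),
                                labels = c("de", "non_de")),
               target = factor(tg_hit, levels = c(TRUE, FALSE),
                               labels = c("hit", "miss")))
  p <- fisher.test(tab, alternative = alternative)$p.value
  m <- tab + if (any(tab == 0)) 0.5 else 0
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  list(table = tab, odds_ratio = unname(or), p = p,
       alternative = alternative)
}
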