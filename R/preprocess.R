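#' Quantile-normalize probe intensities
#'
#' Forces every sample column to share the identical value multiset: the
#' per-rank mean across samples. Tied values within a column receive the
#' mean of the reference values at their ranks.
#'
#' @param probes A `probe_matrix`.
#' @return A `probe_matrix` with normalized intensities.
#' @export
#' @examples
#' pm <- new_probe_matrix(
#'   cbind(a = c(1, 2, 3), b = c(4, 5, 6)),
#'   data.frame(probe = c("p1", "p2", "p3"), gene = "g1", gc = 0.5,
#'              is_background = FALSE),
#'   data.frame(sample = c("a", "b"), subject = "S1",
#'              tissue = c("blood", "LPL"), cell = "CD4", batch = "B1"))
#' quantile_normalize(pm)$intensities
quantile_normalize <- function(probes) {
  stopifnot(inherits(probes, "probe_matrix"))
  x <- probes$intensities
  if (ncol(x) < 2) stopf("quantile normalization needs >= 2 samples")
  if (any(!is.finite(x))) stopf("non-finite intensities in input")
  sorted <- apply(x, 2, sort, method = "radix")
  if (!is.matrix(sorted)) sorted <- matrix(sorted, ncol = ncol(x))
  ref <- rowMeans(sorted)
  out <- apply(x, 2, function(col) {
    res <- numeric(length(col))
    res[order(col)] <- ref
    # tied input values share the mean of their ranks' reference values
    if (anyDuplicated(col)) res <- stats::ave(res, col, FUN = mean)
    res
  })
  if (!is.matrix(out)) out <- matrix(out, ncol = ncol(x))
  dimnames(out) <- dimnames(x)
  probes$intensities <- out
  probes
}

#' Detection-above-background (DABG) calls
#'
#' Compares each probe's signal against non-expressed background probes
#' matched for GC content. Probes are assigned to `gc_bins` equal-width GC
#' bins on \[0,1\]; the probe-level detection p-value in a sample is the
#' empirical upper-tail rank against the background probes of its bin,
#' `(1 + #\{background >= signal\}) / (1 + bin size)`. Per gene and sample,
#' probe p-values are combined by Fisher's method (chi-square with 2k df);
#' the gene is called detected when the combined p is below `alpha`.
#'
#' @param probes A `probe_matrix` (normalized).
#' @param gc_bins Number of equal-width GC bins.
#' @param alpha Detection significance level.
#' @return List with `gene_p` (gene x sample matrix of combined detection
#'   p-values), `calls` (logical matrix, `gene_p < alpha`), and `probe_p`
#'   (probe x sample matrix for the non-background probes).
#' @export
dabg_call <- function(probes, gc_bins = 10, alpha = 0.05) {
  stopifnot(inherits(probes, "probe_matrix"))
  pm <- probes$probe_meta
  if (!any(pm$is_background)) stopf("no background probes present")
  bin <- pmin(floor(pm$gc * gc_bins) + 1L, gc_bins)
  fg <- which(!pm$is_background)
  bg <- which(pm$is_background)
  need <- sort(unique(bin[fg]))
  empty <- setdiff(need, unique(bin[bg]))
  if (length(empty)) {
    stopf("GC bin %s contains probes but no background probes",
          paste(empty, collapse = ", "))
  }
  x <- probes$intensities
  S <- ncol(x)
  probe_p <- matrix(NA_real_, length(fg), S,
                    dimnames = list(pm$probe[fg], colnames(x)))
  for (b in need) {
    fgb <- fg[bin[fg] == b]
    bgb <- bg[bin[bg] == b]
    B <- length(bgb)
    for (s in seq_len(S)) {
      sb <- sort(x[bgb, s])
      # #{background >= signal} via position in the sorted background
      n_lt <- findInterval(x[fgb, s], sb, left.open = TRUE)
      probe_p[match(fgb, fg), s] <- (1 + B - n_lt) / (1 + B)
    }
  }
  gene_of <- pm$gene[fg]
  genes <- unique(gene_of)
  idx <- split(seq_along(gene_of), factor(gene_of, levels = genes))
  lp <- log(probe_p)
  gene_p <- t(vapply(idx, function(i) {
    stat <- -2 * colSums(lp[i, , drop = FALSE])
    pchisq(stat, df = 2 * length(i), lower.tail = FALSE)
  }, numeric(S)))
  dimnames(gene_p) <- list(genes, colnames(x))
  list(gene_p = gene_p, calls = gene_p < alpha, probe_p = probe_p)
}

#' Summarize probes to gene-level log2 expression
#'
#' The gene-level log2 value is the mean of `log2(intensity)` over the
#' gene's probes, per sample. Background probes are dropped.
#'
#' @param probes A normalized `probe_matrix`.
#' @param detection Optional result of [dabg_call()]; its calls are carried
#'   into the output's `detected` slot.
#' @return An `expression_matrix`.
#' @export
summarize_genes <- function(probes, detection = NULL) {
  stopifnot(inherits(probes, "probe_matrix"))
  pm <- probes$probe_meta
  fg <- which(!pm$is_background)
  if (!length(fg)) stopf("no gene-mapped probes to summarize")
  gene_of <- pm$gene[fg]
  genes <- unique(gene_of)
  n_probes <- table(factor(gene_of, levels = genes))
  if (any(n_probes == 0)) {
    stopf("gene(s) with zero probes: %s",
          paste(names(n_probes)[n_probes == 0], collapse = ", "))
  }
  lx <- log2(probes$intensities[fg, , drop = FALSE])
  values <- rowsum(lx, group = gene_of, reorder = FALSE) /
    as.vector(n_probes[unique(gene_of)])
  values <- values[genes, , drop = FALSE]
  detected <- NULL
  if (!is.null(detection)) {
    detected <- detection$calls[genes, , drop = FALSE]
  }
  new_expression_matrix(values, detected, probes$sample_meta)
}

#' Restrict to expressed genes
#'
#' Keeps genes detected in at least `min_fraction` of the samples of at
#' least one population (tissue x cell combination). The surviving genes
#' form the "expressed set" used as the sampling frame of the permutation
#' enrichment null.
#'
#' @param expr An `expression_matrix` with detection calls.
#' @param min_fraction Required detected fraction within a population.
#' @return The filtered `expression_matrix`.
#' @export
filter_expressed <- function(expr, min_fraction = 1.0) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (is.null(expr$detected)) stopf("detection calls are required")
  if (min_fraction < 0 || min_fraction > 1) {
    stopf("min_fraction must be in [0, 1]")
  }
  pop <- population_of(expr$sample_meta)
  keep <- rep(FALSE, nrow(expr$values))
  for (p in unique(pop)) {
    frac <- rowMeans(expr$detected[, pop == p, drop = FALSE])
    keep <- keep | (frac >= min_fraction)
  }
  new_expression_matrix(expr$values[keep, , drop = FALSE],
                        expr$detected[keep, , drop = FALSE],
                        expr$sample_meta)
}

#' Remove additive batch effects
#'
#' Per gene and batch, subtracts the batch mean and adds back the gene's
#' grand mean, so each gene's overall mean is preserved. Intended for the
#' structure diagnostics (variance decomposition, clustering); paired
#' differential expression runs on uncorrected values because subject
#' pairing cancels additive within-batch terms.
#'
#' @param expr An `expression_matrix`.
#' @return The corrected `expression_matrix`.
#' @export
batch_correct <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  batch <- expr$sample_meta$batch
  tab <- table(batch)
  if (length(tab) < 2) stopf("batch correction needs >= 2 batches")
  if (any(tab < 2)) {
    stopf("singleton batch(es): %s (correction would zero their variance)",
          paste(names(tab)[tab < 2], collapse = ", "))
  }
  v <- expr$values
  grand <- rowMeans(v)
  for (b in names(tab)) {
    cols <- batch == b
    v[, cols] <- v[, cols] - rowMeans(v[, cols, drop = FALSE]) + grand
  }
  expr$values <- v
  expr
}
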