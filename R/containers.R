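#' Probe-level intensity container
#'
#' Holds a linear-scale probe x sample intensity matrix together with probe
#' metadata (gene mapping, GC fraction, background flag) and sample metadata
#' (subject, tissue, cell, batch). Every non-background probe must map to
#' exactly one gene.
#'
#' @param intensities Numeric matrix, probes x samples, linear scale, >= 0.
#' @param probe_meta Data frame with columns `probe`, `gene` (NA for
#'   background probes), `gc` in \[0,1\], `is_background`.
#' @param sample_meta Data frame with columns `sample`, `subject`, `tissue`,
#'   `cell`, `batch`, in the column order of `intensities`.
#' @return A `probe_matrix` object.
#' @export
new_probe_matrix <- function(intensities, probe_meta, sample_meta) {
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != nrow(probe_meta)) {
    stopf("intensities rows (%d) != probe_meta rows (%d)",
          nrow(intensities), nrow(probe_meta))
  }
  if (ncol(intensities) != nrow(sample_meta)) {
    stopf("intensities columns (%d) != sample_meta rows (%d)",
          ncol(intensities), nrow(sample_meta))
  }
  if (any(!probe_meta$is_background & is.na(probe_meta$gene))) {
    stopf("every non-background probe must map to a gene")
  }
  if (any(probe_meta$gc < 0 | probe_meta$gc > 1)) {
    stopf("probe GC fractions must lie in [0, 1]")
  }
  structure(list(intensities = intensities, probe_meta = probe_meta,
                 sample_meta = sample_meta),
            class = "probe_matrix")
}

#' Gene-level log2 expression container
#'
#' @param values Numeric matrix, genes x samples, log2 scale.
#' @param detected Logical matrix of detection calls, same shape as
#'   `values`, or `NULL` if detection has not been called yet.
#' @param sample_meta Data frame as in [new_probe_matrix()].
#' @return An `expression_matrix` object.
#' @export
new_expression_matrix <- function(values, detected = NULL, sample_meta) {
  values <- as.matrix(values)
  if (!is.null(detected)) {
    detected <- as.matrix(detected)
    if (!identical(dim(detected), dim(values))) {
      stopf("'detected' must have the same shape as 'values'")
    }
  }
  if (ncol(values) != nrow(sample_meta)) {
    stopf("values columns (%d) != sample_meta rows (%d)",
          ncol(values), nrow(sample_meta))
  }
  structure(list(values = values, detected = detected,
                 sample_meta = sample_meta),
            class = "expression_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("probe_matrix: %d probes (%d background) x %d samples\n",
              nrow(x$intensities), sum(x$probe_meta$is_background),
              ncol(x$intensities)))
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s detection calls)\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$detected)) "no" else "with"))
  invisible(x)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result: %s / %s\n  %d loci, %d unique regions, observed fraction %.4f\n  empirical p = %.4g (%s, n_perm = %d, seed = %s)\n",
    x$disease, x$gene_list, x$n_loci, x$m_unique_regions,
    x$observed_fraction, x$empirical_p, x$mode, x$n_perm,
    as.character(x$seed)))
  invisible(x)
}

population_of <- function(sample_meta) {
  pop_label(sample_meta$tissue, sample_meta$cell)
}
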