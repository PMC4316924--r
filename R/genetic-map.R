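#' Construct a genetic map from anchor data
#'
#' @param df Data frame with columns `chrom`, `bp` (1-based physical
#'   position), `cM` (genetic position). Within each chromosome bp must be
#'   strictly increasing and cM non-decreasing, with at least two anchors.
#' @return A validated `genetic_map`.
#' @export
genetic_map <- function(df) {
  stopifnot(all(c("chrom", "bp", "cM") %in% names(df)))
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (nrow(sub) < 2) stopf("chromosome %s has < 2 map anchors", ch)
    if (any(diff(sub$bp) <= 0)) {
      stopf("bp not strictly increasing on chromosome %s", ch)
    }
    if (any(diff(sub$cM) < 0)) {
      stopf("cM decreasing on chromosome %s", ch)
    }
  }
  df <- df[order(match(df$chrom, unique(df$chrom)), df$bp), ]
  rownames(df) <- NULL
  class(df) <- c("genetic_map", "data.frame")
  df
}

map_chrom <- function(map, chrom) {
  sub <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(sub) == 0) stopf("chromosome '%s' not in genetic map", chrom)
  sub[order(sub$bp), ]
}

#' Interpolate genetic position (cM) at physical positions
#'
#' Piecewise-linear interpolation between the flanking map anchors;
#' positions outside the anchor range are clamped to the terminal anchor's
#' cM.
#'
#' @param map A `genetic_map`.
#' @param chrom Chromosome label.
#' @param bp Numeric vector of 1-based physical positions.
#' @return Numeric vector of cM positions.
#' @export
#' @examples
#' m <- genetic_map(data.frame(chrom = "chr1", bp = c(1, 1e6, 2e6),
#'                             cM = c(0, 0.1, 0.5)))
#' interpolate_cm(m, "chr1", 1.5e6)  # 0.3
interpolate_cm <- function(map, chrom, bp) {
  stopifnot(inherits(map, "genetic_map"))
  sub <- map_chrom(map, chrom)
  approx(sub$bp, sub$cM, xout = bp, rule = 2, ties = "ordered")$y
}

# inverse interpolation of the map, maximally inclusive on plateaus:
# 'lower' gives the smallest bp whose cM >= target, 'upper' the largest bp
# whose cM <= target (so zero-recombination plateaus never shrink a window)
inverse_cm <- function(sub, target, side) {
  bp <- sub$bp
  cm <- sub$cM
  if (side == "lower") {
    if (target <= cm[1]) return(bp[1])
    j <- which(cm >= target)[1]
    if (is.na(j)) return(bp[length(bp)])
    if (cm[j] == target) return(bp[j])
    bp[j - 1] + (target - cm[j - 1]) / (cm[j] - cm[j - 1]) * (bp[j] - bp[j - 1])
  } else {
    if (target >= cm[length(cm)]) return(bp[length(bp)])
    j <- max(which(cm <= target))
    if (cm[j] == target) return(bp[j])
    bp[j] + (target - cm[j]) / (cm[j + 1] - cm[j]) * (bp[j + 1] - bp[j])
  }
}

#' Build the cM window around a focal SNP
#'
#' Converts the SNP position to cM, extends `window_cm` either side, and
#' inverse-interpolates back to physical positions. Endpoints are clamped
#' to the chromosome's anchor range. Within zero-recombination plateaus the
#' inverse takes the outermost bp consistent with the target cM, so the
#' window is maximally inclusive.
#'
#' @param map A `genetic_map`.
#' @param chrom Chromosome label.
#' @param bp Focal SNP position (1-based).
#' @param window_cm Half-width of the window in cM (>= 0); default 0.2.
#' @return Numeric vector `c(start_bp, end_bp)` (closed interval,
#'   start <= bp <= end).
#' @export
#' @examples
#' m <- genetic_map(data.frame(chrom = "chr1", bp = c(1, 1e6, 2e6),
#'                             cM = c(0, 0.1, 0.5)))
#' build_window(m, "chr1", 1.5e6, 0.2)  # c(1e6, 2e6)
build_window <- function(map, chrom, bp, window_cm = 0.2) {
  stopifnot(inherits(map, "genetic_map"))
  if (window_cm < 0) stopf("window_cm must be >= 0")
  sub <- map_chrom(map, chrom)
  center <- approx(sub$bp, sub$cM, xout = bp, rule = 2, ties = "ordered")$y
  start <- inverse_cm(sub, center - window_cm, "lower")
  end <- inverse_cm(sub, center + window_cm, "upper")
  c(start_bp = min(start, bp), end_bp = max(end, bp))
}
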