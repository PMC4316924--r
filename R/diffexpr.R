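#' Define a paired population contrast
#'
#' @param population_a,population_b Population labels `"tissue_cell"` (e.g.
#'   `"LPL_CD4"` vs `"blood_CD4"`); the log2 fold change is a minus b.
#' @return A `contrast` object.
#' @export
contrast <- function(population_a, population_b) {
  structure(list(a = population_a, b = population_b), class = "contrast")
}

contrast_columns <- function(expr, ctr) {
  pop <- population_of(expr$sample_meta)
  subj <- expr$sample_meta$subject
  ia <- which(pop == ctr$a)
  ib <- which(pop == ctr$b)
  if (anyDuplicated(subj[ia]) || anyDuplicated(subj[ib])) {
    stopf("a subject contributes more than one sample to a contrast side")
  }
  shared <- intersect(subj[ia], subj[ib])
  if (length(shared) < 2) {
    stopf("contrast %s vs %s has %d complete subject pair(s); >= 2 required",
          ctr$a, ctr$b, length(shared))
  }
  list(a = ia[match(shared, subj[ia])], b = ib[match(shared, subj[ib])],
       subjects = shared)
}

#' Paired per-gene test between two populations
#'
#' Computes, per gene, the mean over subjects of the paired log2 difference
#' and a two-sided paired t-test p-value on n - 1 degrees of freedom.
#' With `moderate = TRUE`, gene-wise variances are shrunk toward a common
#' prior fitted by moments to the variance distribution
#' (`limma::squeezeVar`); the moderated t uses d0 + n - 1 degrees of
#' freedom.
#'
#' Degenerate genes: zero difference variance with zero mean gives p = 1;
#' zero variance with non-zero mean gives p = 0 (flagged in `degenerate`).
#'
#' @param expr An `expression_matrix` of log2 values.
#' @param ctr A [contrast()].
#' @param moderate Apply empirical-Bayes variance moderation.
#' @return Data frame `gene`, `log2fc`, `p`, `degenerate`.
#' @export
#' @examples
#' # six subjects, constant difference 0.6 plus jitter, single gene
#' sm <- data.frame(sample = paste0("s", 1:12),
#'                  subject = rep(paste0("S", 1:6), 2),
#'                  tissue = rep(c("LPL", "blood"), each = 6),
#'                  cell = "CD4", batch = "B1")
#' v <- rbind(g1 = c(1.6, 1.7, 1.5, 1.65, 1.55, 1.6, 1, 1, 1, 1, 1, 1))
#' paired_test(new_expression_matrix(v, NULL, sm),
#'             contrast("LPL_CD4", "blood_CD4"))
paired_test <- function(expr, ctr, moderate = FALSE) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(ctr, "contrast"))
  cols <- contrast_columns(expr, ctr)
  d <- expr$values[, cols$a, drop = FALSE] -
    expr$values[, cols$b, drop = FALSE]
  n <- length(cols$subjects)
  m <- rowMeans(d)
  s2 <- apply(d, 1, var)
  df <- n - 1
  if (moderate) {
    # zero-variance genes are handled by the degenerate conventions below,
    # so limma's offset warning for them carries no information here
    sq <- suppressWarnings(limma::squeezeVar(s2, df = df))
    s2_use <- sq$var.post
    df_use <- df + sq$df.prior
  } else {
    s2_use <- s2
    df_use <- df
  }
  tstat <- m / sqrt(s2_use / n)
  p <- 2 * pt(abs(tstat), df = df_use, lower.tail = FALSE)
  degenerate <- s2 == 0
  p[degenerate & m == 0] <- 1
  p[degenerate & m != 0] <- 0
  data.frame(gene = rownames(expr$values), log2fc = m, p = p,
             degenerate = degenerate, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: after sorting ascending,
#' `adj_i = min over j >= i of p_j * m / j`, capped at 1, returned in the
#' input order.
#'
#' @param pvalues Numeric vector of p-values in \[0,1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Coefficient-of-variation filter
#'
#' Per gene and population, computes the coefficient of variation (sd/mean)
#' of the linear-scale intensities (`2^log2`) across that population's
#' replicates. A gene passes when its maximum CV over populations is at
#' most `max_cv`.
#'
#' @param expr An `expression_matrix` of log2 values.
#' @param max_cv Maximum allowed within-population CV.
#' @return Character vector of passing gene ids.
#' @export
cv_filter <- function(expr, max_cv = 0.5) {
  stopifnot(inherits(expr, "expression_matrix"))
  pop <- population_of(expr$sample_meta)
  if (any(table(pop) < 2)) {
    stopf("every population needs >= 2 replicates for a CV")
  }
  lin <- 2^expr$values
  max_cv_gene <- rep(-Inf, nrow(lin))
  for (p in unique(pop)) {
    sub <- lin[, pop == p, drop = FALSE]
    mu <- rowMeans(sub)
    if (any(mu <= 0)) stopf("non-positive linear-scale mean encountered")
    cv <- apply(sub, 1, sd) / mu
    max_cv_gene <- pmax(max_cv_gene, cv)
  }
  rownames(expr$values)[max_cv_gene <= max_cv]
}

#' Call differential expression
#'
#' A gene passes when its absolute linear fold change is at least
#' `fc_threshold` and its BH-adjusted p-value is below `alpha`; direction
#' is the sign of the log2 fold change. Up- and downregulated ids are
#' returned separately for the enrichment screens.
#'
#' @param test_result Data frame from [paired_test()].
#' @param fc_threshold Linear fold-change threshold (>= 1); default 1.4.
#' @param alpha Adjusted-p threshold; default 0.05.
#' @return A `de_result`: the input with `p_adj`, `direction`
#'   (`"up"`/`"down"`/`"none"`), `pass`, plus attributes `up` and `down`
#'   holding the passing gene ids.
#' @export
call_de <- function(test_result, fc_threshold = 1.4, alpha = 0.05) {
  if (fc_threshold < 1) stopf("fc_threshold must be >= 1")
  res <- test_result
  res$p_adj <- bh_adjust(res$p)
  res$pass <- 2^abs(res$log2fc) >= fc_threshold & res$p_adj < alpha
  res$direction <- ifelse(!res$pass, "none",
                          ifelse(res$log2fc > 0, "up", "down"))
  attr(res, "up") <- res$gene[res$pass & res$direction == "up"]
  attr(res, "down") <- res$gene[res$pass & res$direction == "down"]
  attr(res, "fc_threshold") <- fc_threshold
  attr(res, "alpha") <- alpha
  class(res) <- c("de_result", "data.frame")
  res
}
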