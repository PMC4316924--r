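#' Principal variance component analysis (PVCA)
#'
#' Estimates the proportion of total expression variance attributable to
#' each experimental factor. Genes are mean-centred (not scaled, so the
#' attribution stays on the natural variance scale), a PCA is taken on the
#' sample-sample covariance, and the smallest set of leading components
#' explaining at least `variance_threshold` of the variance is retained.
#' For each retained component, per-factor variance components are
#' estimated by one-way method-of-moments (between-level mean squares
#' equated to their expectations, negatives truncated at 0), which is
#' unbiased for the balanced crossed designs this pipeline targets. Each
#' component's normalized factor shares are weighted by its raw eigenvalue
#' fraction; the residual absorbs both the within-component remainder and
#' the unretained eigenvalue tail, so the output sums to 1. The default
#' threshold of 0.9 keeps enough components for small factors (around 5%
#' of variance) to remain attributable.
#'
#' @param expr An `expression_matrix` (typically batch-corrected).
#' @param factors Character vector of sample-metadata columns to attribute
#'   variance to.
#' @param variance_threshold Cumulative eigenvalue fraction to retain.
#' @return A `pvca_result`: list with `proportions` (named, includes
#'   `residual`, sums to 1), `n_retained`, `eig_fractions`.
#' @export
pvca <- function(expr, factors = c("tissue", "cell", "subject", "batch"),
                 variance_threshold = 0.9) {
  stopifnot(inherits(expr, "expression_matrix"))
  sm <- expr$sample_meta
  missing_f <- setdiff(factors, names(sm))
  if (length(missing_f)) {
    stopf("unknown factor(s): %s", paste(missing_f, collapse = ", "))
  }
  for (f in factors) {
    if (any(table(sm[[f]]) < 2)) {
      stopf("factor '%s' has level(s) with fewer than 2 samples", f)
    }
  }
  if (length(factors) > 1) {
    for (i in seq_len(length(factors) - 1)) {
      for (j in (i + 1):length(factors)) {
        tab <- table(sm[[factors[i]]], sm[[factors[j]]]) > 0
        if (all(rowSums(tab) == 1) && all(colSums(tab) == 1)) {
          stopf("factors '%s' and '%s' are confounded (identical partition)",
                factors[i], factors[j])
        }
      }
    }
  }
  x <- expr$values
  rsd <- apply(x, 1, sd)
  x <- x[rsd > 0, , drop = FALSE]
  xs <- x - rowMeans(x)
  cv <- crossprod(xs) / (nrow(xs) - 1)
  ev <- eigen(cv, symmetric = TRUE)
  eig_frac <- ev$values / sum(ev$values)
  n_ret <- which(cumsum(eig_frac) >= variance_threshold)[1]
  if (is.na(n_ret)) n_ret <- length(eig_frac)

  solver <- mom_solver(sm, factors)
  out <- setNames(numeric(length(factors) + 1), c(factors, "residual"))
  for (k in seq_len(n_ret)) {
    comps <- solver(ev$vectors[, k])
    denom <- sum(comps)
    if (denom > 0) {
      out <- out + eig_frac[k] * comps / denom
    } else {
      out["residual"] <- out["residual"] + eig_frac[k]
    }
  }
  out["residual"] <- out["residual"] + max(0, 1 - sum(out))
  structure(list(proportions = out / sum(out), n_retained = n_ret,
                 eig_fractions = eig_frac),
            class = "pvca_result")
}

# Joint method-of-moments variance-component solver for one PC score.
#
# For every factor f, the between-level mean square MSB_f = y' A_f y with
# A_f = (P_f - P_1)/(L_f - 1) has expectation sum_g sigma_g tr(A_f G_g) +
# sigma_e tr(A_f), where G_g = Z_g Z_g' for factor g's level-indicator
# matrix. Together with the total variance y'(I - P_1)y/(N - 1) this gives
# a small linear system in (sigma_factors, sigma_residual) whose solution
# handles crossed and nested factors alike (a nested pair, e.g. subjects
# within batches, would double-count under factor-at-a-time estimation).
# Negative solutions are truncated at 0.
mom_solver <- function(sm, factors) {
  N <- nrow(sm)
  proj <- function(groups) {
    z <- stats::model.matrix(~ 0 + factor(groups))
    z %*% solve(crossprod(z)) %*% t(z)
  }
  p1 <- matrix(1 / N, N, N)
  gmats <- lapply(factors, function(f) tcrossprod(
    stats::model.matrix(~ 0 + factor(sm[[f]]))))
  amats <- lapply(factors, function(f) {
    lf <- length(unique(sm[[f]]))
    (proj(sm[[f]]) - p1) / (lf - 1)
  })
  amats <- c(amats, list((diag(N) - p1) / (N - 1)))
  coef <- matrix(0, length(amats), length(factors) + 1)
  for (i in seq_along(amats)) {
    for (j in seq_along(gmats)) {
      coef[i, j] <- sum(amats[[i]] * gmats[[j]])  # tr(A G), both symmetric
    }
    coef[i, length(factors) + 1] <- sum(diag(amats[[i]]))
  }
  function(y) {
    b <- vapply(amats, function(a) drop(crossprod(y, a %*% y)), numeric(1))
    est <- tryCatch(solve(coef, b), error = function(e) {
      stats::lsfit(coef, b, intercept = FALSE)$coefficients
    })
    setNames(pmax(est, 0), c(factors, "residual"))
  }
}

#' @export
print.pvca_result <- function(x, ...) {
  cat(sprintf("pvca_result (%d PCs retained):\n", x$n_retained))
  print(round(x$proportions, 4))
  invisible(x)
}

#' Hierarchical clustering of samples on top-variance genes
#'
#' Selects the `n_top` genes with the greatest variance across samples,
#' computes sample-sample distance as 1 - Pearson correlation of the
#' selected profiles, and clusters with average linkage.
#'
#' @param expr An `expression_matrix`.
#' @param n_top Number of top-variance genes (default 500).
#' @return An `hcluster_result`: list with `hclust`, `order` (leaf order,
#'   sample indices), `labels`, `newick`, `genes_used`.
#' @export
hcluster_samples <- function(expr, n_top = 500) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (n_top < 2) stopf("n_top must be >= 2")
  x <- expr$values
  if (ncol(x) < 3) stopf("need >= 3 samples to cluster")
  if (n_top > nrow(x)) {
    warning(sprintf("n_top (%d) exceeds gene count (%d); using all genes",
                    n_top, nrow(x)), call. = FALSE)
    n_top <- nrow(x)
  }
  v <- apply(x, 1, var)
  top <- order(v, decreasing = TRUE)[seq_len(n_top)]
  d <- stats::as.dist(1 - cor(x[top, , drop = FALSE]))
  hc <- hclust(d, method = "average")
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, order = hc$order, labels = hc$labels,
                 newick = ape::write.tree(phy),
                 genes_used = if (is.null(rownames(x))) top
                              else rownames(x)[top]),
            class = "hcluster_result")
}

#' k-means clustering with discriminant cluster ranking
#'
#' Rows (genes) are mean-centred, then clustered by k-means with k-means++
#' initialization, keeping the best of `n_restarts` runs by total
#' within-cluster sum of squares. Each cluster's discriminance score is the
#' range (max minus min) over the sample groups of the group-mean of its
#' centroid; clusters are ranked by score descending. Intended to run on
#' genes pre-filtered by fold change ([call_de()]) and [cv_filter()].
#'
#' @param expr An `expression_matrix` (typically subset to filtered genes).
#' @param k Number of clusters.
#' @param groups Sample grouping for the score; defaults to the
#'   tissue x cell populations.
#' @param seed Integer seed.
#' @param n_restarts Number of k-means++ restarts.
#' @return A `cluster_result`: list with `assignment` (gene -> cluster id),
#'   `centroids` (cluster x sample), `scores`, `ranking` (cluster ids by
#'   descending score), `score_rank` (rank of each cluster), `sizes`,
#'   `tot_withinss`.
#' @export
kmeans_discriminant <- function(expr, k = 25, groups = NULL, seed = 1,
                                n_restarts = 50) {
  stopifnot(inherits(expr, "expression_matrix"))
  x <- expr$values
  if (k > nrow(x)) {
    stopf("k (%d) exceeds the number of genes (%d)", k, nrow(x))
  }
  if (is.null(groups)) groups <- population_of(expr$sample_meta)
  xc <- x - rowMeans(x)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      centers <- kmeanspp_init(xc, k)
      km <- suppressWarnings(
        kmeans(xc, centers = centers, iter.max = 100))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  cent <- best$centers
  gm <- vapply(unique(groups), function(g) {
    rowMeans(cent[, groups == g, drop = FALSE])
  }, numeric(k))
  if (k == 1) gm <- matrix(gm, nrow = 1)
  scores <- apply(gm, 1, max) - apply(gm, 1, min)
  ranking <- order(scores, decreasing = TRUE)  # ties keep cluster-id order
  structure(list(
    assignment = setNames(best$cluster, rownames(x)),
    centroids = cent, scores = scores, ranking = ranking,
    score_rank = match(seq_len(k), ranking),
    sizes = best$size, tot_withinss = best$tot.withinss
  ), class = "cluster_result")
}

# k-means++ seeding: first center uniform, then each next data point with
# probability proportional to its squared distance to the nearest center
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  if (k == 1) return(centers)
  d2 <- rowSums((x - rep(centers[1, ], each = n))^2)
  for (j in 2:k) {
    if (sum(d2) <= 0) {
      idx <- sample.int(n, 1)
    } else {
      idx <- sample.int(n, 1, prob = d2)
    }
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - rep(centers[j, ], each = n))^2))
  }
  centers
}
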