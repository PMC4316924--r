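# Shared fixtures and independent oracles, all built in code.

tiny_config <- function(...) {
  defaults <- list(n_genes = 200, chrom_lengths = c(chr1 = 2e7, chr2 = 2e7),
                   n_snps_per_disease = 50, seed = 42)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

make_annotation <- function(gene, chrom, start, end) {
  ann <- data.frame(gene = gene, chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

uniform_map <- function(chroms, length_bp = 1e8, rate = 1) {
  df <- do.call(rbind, lapply(chroms, function(ch) {
    bp <- unique(c(1, seq(1e6, length_bp, by = 1e6), length_bp))
    data.frame(chrom = ch, bp = bp, cM = bp * rate / 1e6)
  }))
  genetic_map(df)
}

make_loci <- function(chrom, bp, p = 1e-10, disease = "dz",
                      snp_id = sprintf("rs%03d", seq_along(bp))) {
  df <- data.frame(disease = disease, snp_id = snp_id, chrom = chrom,
                   bp = bp, p = p, stringsAsFactors = FALSE)
  class(df) <- c("snp_locus_set", "data.frame")
  df
}

# expression matrix with the standard 6-subject x 6-population layout
make_design_expr <- function(values, n_subjects = 6) {
  pops <- default_populations()
  sm <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    data.frame(sample = paste0("S", s, "_", pops$tissue, "_", pops$cell),
               subject = paste0("S", s), tissue = pops$tissue,
               cell = pops$cell,
               batch = if (s <= n_subjects / 2) "B1" else "B2",
               stringsAsFactors = FALSE)
  }))
  colnames(values) <- sm$sample
  new_expression_matrix(values, NULL, sm)
}

# ---- independent oracles -------------------------------------------------

# all-pairs closed-interval overlap: does any listed gene share a base with
# the locus window?
brute_overlap_fraction <- function(loci, genes, annotation) {
  ann <- annotation[annotation$gene %in% genes, , drop = FALSE]
  hit <- vapply(seq_len(nrow(loci)), function(i) {
    lo <- ceiling(loci$start_bp[i])
    hi <- floor(loci$end_bp[i])
    any(ann$chrom == loci$chrom[i] &
          (ann$start + 1) <= hi & ann$end >= lo)
  }, logical(1))
  mean(hit)
}

# direct min-over-tail BH definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(o == i)  # rank of p[i]
    adj[i] <- min(1, min(p[o][r:m] * m / seq_len(m)[r:m]))
  }
  adj
}

# exhaustive two-sided Fisher p by hypergeometric enumeration
brute_fisher_two_sided <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
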