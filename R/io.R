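#' @name io
#' @title Readers and writers for the pipeline's plain-text formats
#' @description
#' All tabular outputs are TSV with a header line; files written by the
#' synthetic-data stage carry a `# seed:` comment recording the generator
#' seed. Gene annotation travels as BED6 (0-based half-open), the genetic
#' map as `chrom  bp  cM` (bp 1-based), SNP lists as
#' `disease  snp_id  chrom  bp  p` (bp 1-based), expression matrices as
#' rows-by-samples TSV, gene lists as one id per line, and ground truth as
#' JSON.
NULL

write_tsv_seeded <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, ...)
}

#' @rdname io
#' @param annotation,path,map,loci,genes,con Objects/paths as named.
#' @export
write_annotation_bed <- function(annotation, path) {
  bed <- data.frame(annotation$chrom, format(annotation$start, scientific = FALSE, trim = TRUE),
                    format(annotation$end, scientific = FALSE, trim = TRUE),
                    annotation$gene, 0L, "+")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' @rdname io
#' @export
read_annotation_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stopf("BED file needs >= 4 columns")
  ann <- data.frame(gene = as.character(bed[[4]]), chrom = as.character(bed[[1]]),
                    start = as.numeric(bed[[2]]), end = as.numeric(bed[[3]]),
                    stringsAsFactors = FALSE)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' @rdname io
#' @param seed Optional integer seed recorded in the file header.
#' @export
write_genetic_map <- function(map, path, seed = NULL) {
  write_tsv_seeded(map[, c("chrom", "bp", "cM")], path, seed)
}

#' @rdname io
#' @export
read_genetic_map <- function(path) {
  genetic_map(read_tsv(path))
}

#' @rdname io
#' @export
write_snp_list <- function(loci, path, seed = NULL) {
  write_tsv_seeded(as.data.frame(loci)[, c("disease", "snp_id", "chrom",
                                           "bp", "p")], path, seed)
}

#' @rdname io
#' @export
read_snp_lists <- function(path) {
  df <- read_tsv(path)
  lapply(split(df, df$disease), snp_locus_set)
}

#' @rdname io
#' @param x A matrix (probes or genes by samples).
#' @export
write_matrix_tsv <- function(x, path, seed = NULL) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_seeded(df, path, seed)
}

#' @rdname io
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname io
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
}

#' @rdname io
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' @rdname io
#' @param gt A `ground_truth` object.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA)
}

#' @rdname io
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  gt$true_de_genes <- lapply(gt$true_de_genes, as.character)
  structure(gt, class = "ground_truth")
}
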