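#' Run the full synthetic-to-enrichment pipeline
#'
#' Executes, in order: simulation (annotation, genetic map, expression,
#' SNP lists), preprocessing (quantile normalization, detection calls,
#' gene summarization, expressed-set filtering), paired differential
#' expression for every configured gut-vs-blood style contrast, structure
#' diagnostics (batch correction, PVCA, hierarchical clustering,
#' discriminant k-means), and the permutation enrichment screen. All
#' declared TSV/JSON outputs are written under `outdir`, together with a
#' JSON run manifest holding the configuration snapshot, the master seed,
#' per-file checksums, and timestamps. Re-running with the same
#' configuration reproduces identical data checksums.
#'
#' @param config A [sim_config()]; its `seed` is the master seed.
#' @param outdir Output directory (created if missing).
#' @param window_cm Enrichment window half-width in cM.
#' @param n_perm Permutation count for the enrichment screen.
#' @param fc_threshold,alpha Differential-expression thresholds.
#' @param k,n_top Clustering parameters (k-means clusters; top-variance
#'   gene count for the dendrogram).
#' @param quiet Suppress progress messages (written to `stderr`).
#' @return Invisibly, a list with all stage objects and the manifest.
#' @export
run_pipeline <- function(config, outdir, window_cm = 0.2, n_perm = 1000,
                         fc_threshold = 1.4, alpha = 0.05, k = 25,
                         n_top = 500, quiet = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  tstart <- Sys.time()

  say("simulate: %d genes, %d subjects", config$n_genes, config$n_subjects)
  ann <- generate_annotation(config)
  map <- generate_map(config)
  sim <- generate_expression(config, ann)
  snp <- generate_snp_lists(config, ann, sim$ground_truth, map)
  write_annotation_bed(ann, file.path(outdir, "annotation.bed"))
  write_genetic_map(map, file.path(outdir, "genetic_map.tsv"), config$seed)
  write_matrix_tsv(sim$probes$intensities,
                   file.path(outdir, "probe_intensities.tsv"), config$seed)
  write_tsv_seeded(sim$probes$sample_meta,
                   file.path(outdir, "sample_meta.tsv"))
  write_tsv_seeded(sim$probes$probe_meta,
                   file.path(outdir, "probe_meta.tsv"))
  write_snp_list(do.call(rbind, lapply(snp$loci, as.data.frame)),
                 file.path(outdir, "snp_lists.tsv"), config$seed)
  write_ground_truth(snp$ground_truth,
                     file.path(outdir, "ground_truth.json"))

  say("preprocess: normalize, detect, summarize")
  norm <- quantile_normalize(sim$probes)
  det <- dabg_call(norm)
  expr <- summarize_genes(norm, det)
  expressed <- filter_expressed(expr)
  write_matrix_tsv(expr$values, file.path(outdir, "gene_expression.tsv"))
  write_matrix_tsv(det$gene_p, file.path(outdir, "detection_p.tsv"))
  write_matrix_tsv(det$calls * 1L, file.path(outdir, "detection_calls.tsv"))

  say("diffexpr: %d expressed genes", nrow(expressed$values))
  de_lists_up <- list()
  de_lists_down <- list()
  de_tables <- list()
  for (eff in config$de_effects) {
    ctr <- contrast(eff$contrast[1], eff$contrast[2])
    res <- call_de(paired_test(expressed, ctr), fc_threshold, alpha)
    label <- paste(eff$contrast, collapse = "_vs_")
    de_tables[[label]] <- res
    de_lists_up[[label]] <- attr(res, "up")
    de_lists_down[[label]] <- attr(res, "down")
    out <- res[, c("gene", "log2fc", "p", "p_adj", "direction", "pass")]
    names(out)[2] <- "log2fc"
    write_tsv_seeded(out, file.path(outdir, paste0("de_", label, ".tsv")))
    write_gene_list(attr(res, "up"),
                    file.path(outdir, paste0("de_", label, "_up.txt")))
    write_gene_list(attr(res, "down"),
                    file.path(outdir, paste0("de_", label, "_down.txt")))
  }

  say("structure: batch correction, PVCA, clustering")
  corrected <- batch_correct(expressed)
  pv <- pvca(corrected)
  jsonlite::write_json(as.list(pv$proportions),
                       file.path(outdir, "pvca.json"), auto_unbox = TRUE,
                       digits = NA)
  hc <- hcluster_samples(corrected, n_top = min(n_top,
                                                nrow(corrected$values)))
  writeLines(hc$newick, file.path(outdir, "sample_dendrogram.nwk"))
  fc_genes <- unique(unlist(lapply(de_tables, function(r) {
    r$gene[2^abs(r$log2fc) >= fc_threshold]
  })))
  cv_ok <- cv_filter(corrected, 0.5)
  clus_genes <- intersect(fc_genes, cv_ok)
  km <- NULL
  if (length(clus_genes) >= k) {
    sub <- new_expression_matrix(
      corrected$values[clus_genes, , drop = FALSE],
      NULL, corrected$sample_meta)
    km <- kmeans_discriminant(sub, k = k,
                              seed = stage_seed(config$seed, "kmeans"))
    write_tsv_seeded(data.frame(gene = names(km$assignment),
                                cluster = km$assignment,
                                score_rank = km$score_rank[km$assignment]),
                     file.path(outdir, "kmeans_clusters.tsv"))
  } else {
    say("structure: only %d genes pass clustering filters; k-means skipped",
        length(clus_genes))
  }

  say("enrich: %d diseases x %d gene lists, %d permutations",
      length(snp$loci), length(de_lists_up), n_perm)
  filtered <- lapply(snp$loci, filter_loci, map = map,
                     window_cm = window_cm)
  filtered <- filtered[vapply(filtered, nrow, integer(1)) > 0]
  expressed_ids <- rownames(expressed$values)
  gene_lists <- de_lists_up[vapply(de_lists_up, length, integer(1)) > 0]
  scr <- NULL
  if (length(filtered) && length(gene_lists)) {
    gene_lists <- lapply(gene_lists, intersect, y = expressed_ids)
    scr <- screen_enrichment(filtered, gene_lists, expressed_ids, ann,
                             n_perm = n_perm, seed = config$seed)
    write_tsv_seeded(scr$results, file.path(outdir, "enrichment.tsv"))
    jsonlite::write_json(scr$results, file.path(outdir, "enrichment.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    annot <- annotate_loci(filtered[[1]], de_lists_up, ann)
    write_tsv_seeded(annot, file.path(outdir, "locus_annotation.tsv"))
  }

  files <- list.files(outdir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("temenrich")),
    master_seed = config$seed,
    config = unclass(config)[setdiff(names(unclass(config)),
                                     c("populations", "de_effects"))],
    checksums = as.list(tools::md5sum(files)),
    started = format(tstart, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(annotation = ann, map = map, sim = sim, snp = snp,
                 expression = expr, expressed = expressed,
                 de = de_tables, de_up = de_lists_up, de_down = de_lists_down,
                 pvca = pv, hclust = hc, kmeans = km, screen = scr,
                 manifest = manifest))
}

#' Render a human-readable enrichment report
#'
#' Renders the disease-by-gene-list empirical-p grid and the per-locus
#' annotation table as TSV plus markdown. Loci with no overlapping
#' differential gene in a population keep an explicit empty field.
#'
#' @param screen Result of [screen_enrichment()] (or `NULL` for an empty
#'   grid).
#' @param annotation_table Optional result of [annotate_loci()].
#' @param outdir Directory for `report.md` and `report_grid.tsv`.
#' @return Invisibly, the markdown lines.
#' @export
report <- function(screen, annotation_table = NULL, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  lines <- c("# Enrichment screen", "")
  if (is.null(screen) || nrow(screen$results) == 0) {
    grid <- data.frame(disease = character(0))
    lines <- c(lines, "(no enrichment results)")
  } else {
    res <- screen$results
    diseases <- unique(res$disease)
    lists <- unique(res$gene_list)
    grid <- data.frame(disease = diseases, stringsAsFactors = FALSE)
    for (gl in lists) {
      grid[[gl]] <- vapply(diseases, function(dz) {
        res$empirical_p[res$disease == dz & res$gene_list == gl][1]
      }, numeric(1))
    }
    header <- paste(c("disease", lists), collapse = " | ")
    sep <- paste(rep("---", length(lists) + 1), collapse = " | ")
    body <- apply(grid, 1, function(r) paste(r, collapse = " | "))
    lines <- c(lines, header, sep, body)
  }
  write.table(grid, file.path(outdir, "report_grid.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_table)) {
    lines <- c(lines, "", "## Locus annotation", "",
               paste(names(annotation_table), collapse = " | "),
               paste(rep("---", ncol(annotation_table)), collapse = " | "),
               apply(annotation_table, 1, paste, collapse = " | "))
  }
  writeLines(lines, file.path(outdir, "report.md"))
  invisible(lines)
}
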