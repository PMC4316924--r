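hand_map <- function() {
  genetic_map(data.frame(chrom = "chr1", bp = c(1, 1e6, 2e6),
                         cM = c(0, 0.1, 0.5)))
}

test_that("cM interpolation is linear with terminal clamping", {
  m <- hand_map()
  expect_equal(interpolate_cm(m, "chr1", 1e6), 0.1)    # anchor identity
  expect_equal(interpolate_cm(m, "chr1", 1.5e6), 0.3)  # hand interpolation
  u <- uniform_map("chr1", 1e7)
  expect_equal(interpolate_cm(u, "chr1", 1.5e6), 1.5)
  expect_equal(interpolate_cm(u, "chr1", 2e7), 10)     # clamped to terminal
  expect_error(interpolate_cm(m, "chr9", 1), "not in genetic map")
})

test_that("window construction inverts the map, maximally inclusive", {
  u <- uniform_map("chr1", 1e8)
  expect_equal(unname(build_window(u, "chr1", 1e7, 0)), c(1e7, 1e7))
  expect_equal(unname(build_window(u, "chr1", 1e7, 0.2)), c(9.8e6, 1.02e7))
  m <- hand_map()
  # bp = 1.5 Mb is 0.3 cM; +-0.2 cM -> [0.1, 0.5] -> [1 Mb, 2 Mb]
  expect_equal(unname(build_window(m, "chr1", 1.5e6, 0.2)), c(1e6, 2e6))
  expect_error(build_window(m, "chr1", 1e6, -0.1), ">= 0")

  # zero-recombination plateau: inverse takes the outermost consistent bp
  plat <- genetic_map(data.frame(
    chrom = "chr1", bp = c(1, 1e6, 2e6, 3e6, 4e6),
    cM = c(0, 0.1, 0.1, 0.1, 0.2)))
  w <- build_window(plat, "chr1", 2.5e6, 0)
  expect_equal(unname(w), c(1e6, 3e6))
})

test_that("window endpoints round-trip through the map where unclamped", {
  set.seed(13)
  for (i in 1:20) {
    cfg <- tiny_config(chrom_lengths = c(chr1 = 5e7), map_mode = "variable",
                       seed = i)
    m <- generate_map(cfg)
    total_cm <- max(m$cM)
    if (total_cm < 0.5) next
    bp <- runif(5, 1, 5e7)
    for (b in bp) {
      center <- interpolate_cm(m, "chr1", b)
      if (center < 0.2 || center > total_cm - 0.2) next  # would clamp
      w <- build_window(m, "chr1", b, 0.2)
      expect_equal(interpolate_cm(m, "chr1", w[[1]]), center - 0.2,
                   tolerance = 1e-6)
      expect_equal(interpolate_cm(m, "chr1", w[[2]]), center + 0.2,
                   tolerance = 1e-6)
    }
  }
})

test_that("locus filtering drops weak, non-autosomal and redundant SNPs", {
  u <- uniform_map(c("chr1", "chr2"), 1e8)
  raw <- make_loci(c("chr1", "chr1", "chr1", "chrX", "chr2"),
                   bp = c(1e7, 1.01e7, 3e7, 1e7, 1e7),
                   p = c(1e-10, 1e-9, 1e-7, 1e-12, 1e-9),
                   snp_id = c("rsA", "rsB", "rsC", "rsX", "rsD"))
  out <- filter_loci(raw, u, gws_threshold = 5e-8, window_cm = 0.2)
  # rsC fails significance, rsX is not autosomal, rsB overlaps rsA
  # (0.1 cM apart with 0.2 cM windows) and has the larger p
  expect_setequal(out$snp_id, c("rsA", "rsD"))
  # windows pairwise disjoint within disease
  expect_true(all(out$start_bp <= out$bp & out$bp <= out$end_bp))

  # tie on p -> lexicographically smallest snp_id
  raw_tie <- make_loci("chr1", bp = c(1e7, 1.01e7), p = c(1e-10, 1e-10),
                       snp_id = c("rsZ", "rsA"))
  expect_equal(filter_loci(raw_tie, u)$snp_id, "rsA")

  expect_error(filter_loci(make_loci("weird", 1e6, 1e-10), u), "malformed")
  expect_error(filter_loci(make_loci("chr7", 1e6, 1e-10), u),
               "does not cover")
})

test_that("unique regions merge transitively overlapping spans", {
  ann <- make_annotation(c("A", "B", "C"), "chr1",
                         c(100, 150, 400), c(200, 300, 500))
  expect_equal(unique_regions(c("A", "C"), ann), 2)
  expect_equal(unique_regions(c("A", "B"), ann), 1)
  expect_equal(unique_regions(c("A", "B", "C"), ann), 2)
  expect_equal(unique_regions(character(0), ann), 0L)
  expect_error(unique_regions("nope", ann), "unknown gene")
  # adjacent half-open spans share no base and stay separate
  ann2 <- make_annotation(c("A", "B"), "chr1", c(100, 200), c(200, 300))
  expect_equal(unique_regions(c("A", "B"), ann2), 2)
})

test_that("overlap fraction counts loci whose window touches a listed gene", {
  u <- uniform_map("chr1", 1e8)
  ann <- make_annotation(c("A", "B", "C"), "chr1",
                         c(1.00e7, 3.00e7, 6.00e7),
                         c(1.01e7, 3.01e7, 6.01e7))
  loci <- filter_loci(make_loci("chr1", c(1.005e7, 3.005e7, 8e7)), u)
  expect_equal(overlap_fraction(loci, c("A", "B"), ann), 2 / 3)
  expect_equal(overlap_fraction(loci, character(0), ann), 0)
  expect_equal(overlap_fraction(loci, c("A", "B", "C"), ann), 2 / 3)
  all_loci <- filter_loci(make_loci("chr1", c(1.005e7, 6.005e7)), u)
  expect_equal(overlap_fraction(all_loci, c("A", "B", "C"), ann), 1)
  empty <- filter_loci(make_loci("chr1", 1e7, p = 0.5), u)
  expect_error(overlap_fraction(empty, "A", ann), "n_loci = 0")
})

test_that("interval overlap equals the all-pairs brute-force scan", {
  set.seed(77)
  u <- uniform_map(c("chr1", "chr2"), 1e8)
  for (i in 1:30) {
    n_genes <- sample(20:200, 1)
    ann <- make_annotation(
      sprintf("g%03d", seq_len(n_genes)),
      sample(c("chr1", "chr2"), n_genes, replace = TRUE),
      start <- round(runif(n_genes, 0, 9.9e7)),
      start + round(runif(n_genes, 1e3, 1e6)))
    n_loci <- sample(5:40, 1)
    loci <- filter_loci(make_loci(
      sample(c("chr1", "chr2"), n_loci, replace = TRUE),
      round(runif(n_loci, 1, 1e8)),
      snp_id = sprintf("rs%03d", seq_len(n_loci))), u)
    genes <- sample(ann$gene, sample(seq_len(n_genes), 1))
    expect_equal(overlap_fraction(loci, genes, ann),
                 brute_overlap_fraction(loci, genes, ann))
  }
})

test_that("exhaustive permutation enumerates the micro-instance exactly", {
  u <- uniform_map("chr1", 1e8, rate = 10)  # 0.2 cM = +-20 kb windows
  ann <- make_annotation(c("A", "B", "C", "D"), "chr1",
                         c(1e7, 3e7, 5e7, 7e7), c(1e7, 3e7, 5e7, 7e7) + 1e4)
  loci <- filter_loci(make_loci("chr1", c(1.0005e7, 3.0005e7),
                                snp_id = c("L1", "L2")), u)
  expect_equal(nrow(loci), 2)
  res <- permutation_test(loci, "A", c("A", "B", "C", "D"), ann,
                          mode = "exhaustive")
  # null fractions over the 4 single-gene draws: {1/2, 1/2, 0, 0}
  expect_equal(res$observed_fraction, 0.5)
  expect_equal(res$m_unique_regions, 1)
  expect_equal(res$empirical_p, 0.5)
  expect_equal(res$mode, "exhaustive")

  res_c <- permutation_test(loci, "C", c("A", "B", "C", "D"), ann,
                            mode = "exhaustive")
  expect_equal(res_c$observed_fraction, 0)
  expect_equal(res_c$empirical_p, 1)

  # saturated case: de = expressed, all spans disjoint -> p = 1
  res_all <- permutation_test(loci, c("A", "B", "C", "D"),
                              c("A", "B", "C", "D"), ann,
                              mode = "exhaustive")
  expect_equal(res_all$empirical_p, 1)

  expect_error(permutation_test(loci, "Z", c("A", "B"), ann), "subset")
  expect_error(permutation_test(loci, "A", c("A", "B", "C", "D"), ann,
                                n_perm = 0, mode = "monte_carlo"),
               "n_perm")
})

test_that("Monte-Carlo p-values converge to the exhaustive enumeration", {
  set.seed(55)
  u <- uniform_map("chr1", 1e8, rate = 0.01)
  for (i in 1:10) {
    n_genes <- sample(8:12, 1)
    pos <- sort(sample(seq(1e6, 9.5e7, by = 5e5), n_genes))
    ann <- make_annotation(sprintf("g%02d", seq_len(n_genes)), "chr1",
                           pos, pos + 1e5)
    loci <- filter_loci(make_loci("chr1",
                                  sample(seq(1e6, 9.5e7, by = 1e6), 5),
                                  snp_id = sprintf("rs%d", 1:5)), u)
    de <- sample(ann$gene, sample(2:4, 1))
    ex <- permutation_test(loci, de, ann$gene, ann, mode = "exhaustive")
    mc <- permutation_test(loci, de, ann$gene, ann, mode = "monte_carlo",
                           n_perm = 4000, seed = i)
    se <- sqrt(ex$empirical_p * (1 - ex$empirical_p) / 4000)
    expect_lt(abs(mc$empirical_p - ex$empirical_p), 3 * se + 1 / 4000)
    expect_gte(mc$empirical_p, 1 / 4001)
  }
})

test_that("observed overlap is monotone in window size", {
  set.seed(99)
  cfg <- tiny_config(n_genes = 100, chrom_lengths = c(chr1 = 1e8),
                     map_mode = "variable", seed = 61)
  ann <- generate_annotation(cfg)
  m <- generate_map(cfg)
  raw <- make_loci("chr1", sort(round(runif(20, 1, 1e8))),
                   snp_id = sprintf("rs%02d", 1:20))
  genes <- sample(ann$gene, 30)
  # per-locus windows nest as the half-width grows, so the per-locus hit
  # indicator (hence the overlap fraction over a fixed SNP set) is monotone
  win <- lapply(c(0.05, 0.1, 0.2), function(w) {
    t(vapply(seq_len(nrow(raw)), function(i) {
      build_window(m, raw$chrom[i], raw$bp[i], w)
    }, numeric(2)))
  })
  for (j in 1:2) {
    expect_true(all(win[[j + 1]][, 1] <= win[[j]][, 1] + 1e-9))
    expect_true(all(win[[j + 1]][, 2] >= win[[j]][, 2] - 1e-9))
  }
})

test_that("the screen composes per-cell permutation tests reproducibly", {
  u <- uniform_map("chr1", 1e8)
  set.seed(3)
  pos <- sort(sample(seq(1e6, 9e7, by = 1e6), 40))
  ann <- make_annotation(sprintf("g%02d", 1:40), "chr1", pos, pos + 2e5)
  l1 <- filter_loci(make_loci("chr1", c(2e7, 5e7), disease = "dz1",
                              snp_id = c("a1", "a2")), u)
  l2 <- filter_loci(make_loci("chr1", c(3e7, 7e7), disease = "dz2",
                              snp_id = c("b1", "b2")), u)
  lists <- list(up = sample(ann$gene, 10), down = sample(ann$gene, 5))
  scr <- screen_enrichment(list(dz1 = l1, dz2 = l2), lists, ann$gene, ann,
                           n_perm = 200, seed = 5, mode = "monte_carlo")
  expect_equal(nrow(scr$results), 4)
  scr2 <- screen_enrichment(list(dz1 = l1, dz2 = l2), lists, ann$gene, ann,
                            n_perm = 200, seed = 5, mode = "monte_carlo")
  expect_identical(scr$results, scr2$results)

  # 1 x 1 screen reduces to a direct permutation_test with the derived seed
  solo <- screen_enrichment(list(dz1 = l1), lists["up"], ann$gene, ann,
                            n_perm = 200, seed = 5, mode = "monte_carlo")
  direct <- permutation_test(l1, lists$up, ann$gene, ann, n_perm = 200,
                             seed = stage_seed(5, "enrich", "dz1", "up"),
                             mode = "monte_carlo")
  expect_equal(solo$results$empirical_p, direct$empirical_p)

  expect_error(screen_enrichment(list(dz1 = l1, dz1 = l2), lists,
                                 ann$gene, ann),
               "duplicated")
})

test_that("locus annotation reports per-population overlapping DE genes", {
  u <- uniform_map("chr1", 1e8)
  ann <- make_annotation(c("G1", "G2", "G3"), "chr1",
                         c(1.99e7, 2.01e7, 6e7), c(1.995e7, 2.015e7, 6.1e7))
  loci <- filter_loci(make_loci("chr1", c(2e7, 4e7),
                                snp_id = c("rs1", "rs2")), u)
  tab <- annotate_loci(loci, list(LPL_CD4 = c("G2", "G1"),
                                  IEL_CD4 = "G3"), ann)
  # locus rs1 covers G1 and G2 for LPL_CD4, sorted by genomic start
  lpl <- tab$gene[tab$snp_id == "rs1" & tab$population == "LPL_CD4"]
  expect_equal(lpl, c("G1", "G2"))
  # empty sets preserved as explicit empty strings
  expect_equal(tab$gene[tab$snp_id == "rs2" & tab$population == "LPL_CD4"],
               "")
  expect_equal(tab$gene[tab$snp_id == "rs1" & tab$population == "IEL_CD4"],
               "")
})

test_that("stratified Fisher test matches the hypergeometric oracle", {
  tab <- matrix(c(10, 15, 2, 23), 2, byrow = TRUE)
  expect_equal(fisher.test(tab)$p.value, brute_fisher_two_sided(tab))

  # end-to-end on constructed loci: 6 de-overlapping loci (5 target hits),
  # 6 non-de loci (1 target hit)
  u <- uniform_map("chr1", 1e9)
  pos <- seq(2e7, 24e7, by = 2e7)
  ann_genes <- data.frame(
    gene = c(sprintf("de%d", 1:6), sprintf("tg%d", 1:6)),
    chrom = "chr1",
    start = c(pos[1:6] - 1e5, c(pos[1:5], pos[7]) + 1e4),
    end = c(pos[1:6] - 1e5, c(pos[1:5], pos[7]) + 1e4) + 5e4)
  ann <- make_annotation(ann_genes$gene, ann_genes$chrom, ann_genes$start,
                         ann_genes$end)
  loci <- filter_loci(make_loci("chr1", pos,
                                snp_id = sprintf("rs%02d", 1:12)), u)
  expect_equal(nrow(loci), 12)
  res <- stratified_fisher(loci, sprintf("de%d", 1:6), ann,
                           sprintf("tg%d", 1:6))
  expect_equal(unname(as.vector(res$table)), c(5, 1, 1, 5))
  expect_equal(res$p, brute_fisher_two_sided(res$table))
  expect_gt(res$odds_ratio, 1)

  # zero cell -> finite Haldane-corrected odds ratio
  res1 <- stratified_fisher(loci, sprintf("de%d", 1:6), ann,
                            sprintf("de%d", 1:6))
  expect_true(is.finite(res1$odds_ratio))

  loci_de <- loci[1:6, ]  # every locus overlaps a de gene: empty stratum
  expect_error(stratified_fisher(loci_de, sprintf("de%d", 1:6), ann, "tg1"),
               "stratum")
})
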