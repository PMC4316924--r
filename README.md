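# temenrich

Links differential gene expression in tissue-resident effector-memory
(T_EM) T cell populations to GWAS risk loci. The package is aimed at
immunologists and statistical geneticists who have (i) expression from a
small, paired, designed experiment — here six subjects each contributing
peripheral-blood, intraepithelial (IEL) and lamina-propria (LPL) T_EM
cells in CD4 and CD8 flavours — and (ii) per-disease lists of GWAS focal
SNPs, and who want to know whether risk loci are enriched for genes that
a given cell population regulates.

## The statistic

For a disease with focal SNPs filtered to genome-wide significance
(p < 5×10⁻⁸) and autosomes, each SNP receives a genomic window extending
0.2 centiMorgan either side (piecewise-linear interpolation of a genetic
map; overlapping windows within a disease are reduced to the strongest
SNP). For a differential gene list *D* inside an expressed set *E*, the
observed statistic is

> f_obs = #{loci whose window overlaps ≥ 1 gene of D} / n_loci.

The null redraws, n_perm times, m = (number of merged unique genomic
regions covered by D) genes uniformly without replacement from E and
recomputes the fraction; the one-sided empirical p-value is

> p = (1 + #{f_null ≥ f_obs}) / (1 + n_perm),

or the exact enumeration over all C(|E|, m) draws when that is feasible.
Supporting stages: quantile normalization, detection above background
against GC-matched control probes (Fisher-combined per probeset), paired
t differential expression (≥1.4-fold, BH-adjusted p < 0.05), principal
variance component analysis, top-variance hierarchical clustering,
discriminant-ranked k-means, and a stratified Fisher exact test for
transcription-factor target enrichment at loci. A synthetic-data module
generates the whole study design with known ground truth.

## Worked example

A synthetic study with a planted enrichment (`enrichment_odds = 1.2`
places about half of the significant SNPs inside true differential
genes):

```r
library(temenrich)

cfg <- sim_config(n_genes = 2000, chrom_lengths = c(chr1 = 1e8, chr2 = 1e8),
                  variance_components = c(tissue = 0.15, cell = 0.1,
                                          subject = 0.15, batch = 0.1,
                                          residual = 0.5),
                  total_variance = 0.1,
                  enrichment_odds = 1.2, n_snps_per_disease = 120, seed = 1)
ann <- generate_annotation(cfg)
map <- generate_map(cfg)
sim <- generate_expression(cfg, ann)

norm <- quantile_normalize(sim$probes)
det  <- dabg_call(norm)
expr <- filter_expressed(summarize_genes(norm, det))
nrow(expr$values)
#> [1] 1885                        # expressed set (of 2000 simulated genes)

de <- call_de(paired_test(expr, contrast("LPL_CD4", "blood_CD4")))
sum(de$pass); length(attr(de, "up"))
#> [1] 89                          # differential at >=1.4-fold, adj p < 0.05
#> [1] 78                          # upregulated in LPL CD4

snp  <- generate_snp_lists(cfg, ann, sim$ground_truth, map)
loci <- filter_loci(snp$loci[[1]], map, window_cm = 0.2)
permutation_test(loci, intersect(attr(de, "up"), rownames(expr$values)),
                 rownames(expr$values), ann, n_perm = 10000, seed = 1)
#> enrichment_result: trait_1 / de
#>   47 loci, 78 unique regions, observed fraction 0.4681
#>   empirical p = 9.999e-05 (monte_carlo, n_perm = 10000, seed = 1)

pvca(batch_correct(expr))
#> pvca_result (28 PCs retained):
#>   tissue     cell  subject    batch residual
#>   0.1635   0.1101   0.1876   0.0000   0.5388
```

Reading the output: 47 significant, non-overlapping risk loci were
tested; 46.8% of their 0.2 cM windows contain at least one of the 78
upregulated genes, far more than random draws of 78 expressed regions
achieve, hence the permutation p of about 1e-4. The PVCA proportions
recover the planted variance structure (batch is zero after correction).
`run_pipeline(cfg, outdir)` chains all stages and writes every table plus
a checksummed run manifest; `screen_enrichment()` runs the full
disease-by-gene-list grid.

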