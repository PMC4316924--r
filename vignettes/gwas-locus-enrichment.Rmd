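---
title: "Linking tissue-resident T cell transcriptomes to GWAS risk loci"
author: "temenrich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking tissue-resident T cell transcriptomes to GWAS risk loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temenrich)
```

## The scientific problem

Genome-wide association studies identify risk loci, but a risk locus is a
stretch of correlated variants, not a gene. One way to nominate candidate
genes and effector cell types is to ask whether risk loci are unusually
rich in genes that a particular cell population expresses differentially.
This package implements that question for tissue-resident effector-memory
(T~EM~) T cells: six paired populations per subject — peripheral blood,
intraepithelial lymphocytes (IEL) and lamina propria lymphocytes (LPL),
each split into CD4^+^ and CD8^+^ lineages — profiled on small-n designed
microarrays, with gut populations compared against the subject-matched
blood population.

The core statistic is simple. For each disease, take the focal SNPs (the
strongest association signal per locus), keep those at genome-wide
significance (p < 5×10⁻⁸) on autosomes, and give each a genomic window
extending 0.2 centiMorgan (cM) either side. A cM-defined window adapts its
physical width to the local recombination rate, so it approximates the
region over which a variant plausibly acts on nearby genes. The observed
statistic is the fraction of loci whose window overlaps at least one gene
from a differential list. Its significance comes from a permutation null:
each iteration redraws the same number of *unique genomic regions* from
all transcripts expressed in the data set — regardless of differential
expression — and recomputes the overlap fraction. Sampling from the
expressed set (rather than the genome) controls for the expression
platform; sizing draws by merged unique regions (rather than gene count)
stops clusters of overlapping transcripts from inflating the draw.

The empirical p-value uses the add-one convention,
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_\text{perm})$, so it is
never exactly zero and is one-sided for enrichment. When the draw space
$\binom{N}{m}$ is small (≤ 200{,}000 by default) the package enumerates it
exhaustively and reports the exact tail probability instead.

## Pipeline stages and their parameters

**Detection above background.** Arrays carry non-expressed control probes.
Each probe's detection p-value in a sample is its empirical upper-tail
rank among the background probes of its GC bin (10 equal-width bins on
[0,1] by default): `(1 + #{background ≥ signal}) / (1 + bin size)`.
Per-probeset p-values are combined with Fisher's method; a gene is
detected at `alpha = 0.05`. Genes detected in every sample of at least one
population (min_fraction = 1) form the expressed set — the permutation
sampling frame.

**Normalization and summarization.** Quantile normalization forces every
sample to the common per-rank mean (ties share the mean of their ranks'
reference values); gene-level log2 expression is the mean of log2 probe
intensities. With only a handful of probes per set, a mean of logs is more
stable than a median polish; this is a deliberate departure from RMA-style
summarization.

**Paired differential expression.** Because every subject contributes one
sample of each population, contrasts are paired: per gene, the log2 fold
change is the mean over subjects of the paired difference, tested with a
two-sided paired t on n−1 degrees of freedom. An opt-in empirical-Bayes
path shrinks gene variances toward a moments-fitted prior
(`limma::squeezeVar`) with correspondingly larger degrees of freedom; the
plain t is the default because it is fully specified and directly
checkable against a hand computation. Zero-variance genes follow explicit
conventions (p = 1 when the mean difference is 0, p = 0 otherwise) so
degenerate rows behave monotonically instead of producing NaNs. A gene is
called differential at ≥ 1.4-fold change and Benjamini–Hochberg adjusted
p < 0.05; the 1.4-fold default reflects the usual reliability floor of
expression arrays, with ≥ 2-fold available as a robustness setting. Up-
and downregulated lists are split after two-sided testing, since
enrichment screens run on each direction separately.

**Batch correction** subtracts per-gene batch means and restores the grand
mean. It is applied for the structure diagnostics only: differential
expression runs on uncorrected normalized values because subject pairs lie
within batch, so additive batch terms cancel in the paired differences.

**Principal variance component analysis (PVCA).** Genes are mean-centred
(not variance-scaled: scaling distorts the recovered fractions for factors
with few levels), PCA is taken on the sample–sample covariance, and the
leading components covering 90% of variance are retained. For each
retained component the per-factor variance components are estimated by a
*joint* method of moments: every factor's between-level mean square, plus
the total variance, is equated to its expectation, giving a small linear
system in the factor and residual components (negatives truncated at
zero). The joint system matters because subjects are nested in batches —
factor-at-a-time estimation would count batch variance twice. Per-PC
shares are weighted by eigenvalue fraction; the residual absorbs the
unretained tail. The 90% retention default keeps components carrying small
factors (~5% of variance) inside the attributed set; at the conventional
60% they fall into the discarded tail and the residual is badly
underestimated.

**Clustering.** Sample relationships are summarized by average-linkage
hierarchical clustering on 1 − Pearson correlation over the 500
highest-variance transcripts. Gene modules come from k-means (k = 25
default) on row-centred profiles of genes passing the fold-change and
within-population coefficient-of-variation (CV ≤ 0.5, computed on the
linear scale — log-scale CVs confound location and scale) filters, with
k-means++ initialization, best of 50 restarts. Each cluster's
*discriminance* is the range of its centroid's population-group means;
the top 8 clusters by this score are the headline modules.

## The synthetic-data generator

Every stage is validated against data with known ground truth. The
generator emulates the designed experiment: 6 subjects × 6 populations,
two processing batches split by subject (so pairs stay within batch),
additive log2 variance components (tissue 0.5, cell 0.2, subject 0.05,
batch 0.05, residual 0.2 of a 0.5 total by default — tissue dominant,
interindividual variation small, matching the biology the pipeline
targets), probe-level signal with a GC-dependent affinity
(`1.5·(GC − 0.5)` plus a probe offset, constant across samples),
GC-tiling background probes, and 5% non-expressed genes sitting at
background level. The default genome is 5 × 100 Mb chromosomes carrying
10,000 genes of 5–30 kb (≈ 0.4 Mb windows at the uniform 1 cM/Mb map then
cover ~⅓ of loci at baseline — a non-degenerate operating point). 10% of
genes are placed overlapping a neighbour to exercise unique-region
merging. Four probes per probeset is an arbitrary but configurable
choice.

SNP lists plant enrichment through a single knob: each genome-wide
significant SNP is, with probability `odds/(1 + odds)`, placed inside a
uniformly chosen true differential gene (so its window necessarily covers
it), otherwise uniformly on the genome. Significant association p-values
are drawn log-uniform on [1e-30, 5e-8), the rest on [5e-8, 1], so the
significance filter is exercised from both sides. The power analyses use
`enrichment_odds = 1.2`, chosen from the design geometry: with baseline
per-locus overlap p₀ ≈ 0.35, the targeted-placement probability
q = p₀/(1 − p₀) ≈ 0.55 doubles the expected overlap fraction.

What the generator does *not* emulate: linkage-disequilibrium structure,
realistic human recombination maps, real probe sequences or CEL-level
array artefacts, and correlation between expression and gene location.
Passing tests therefore demonstrate the statistical machinery is correct
and calibrated under the stated model, not that any particular biological
enrichment in real data would replicate.

## Numerical and design choices

- **Genetic-map interpolation** is piecewise linear with terminal
  clamping. Inverse interpolation is *maximally inclusive* on
  zero-recombination plateaus: the window takes the outermost physical
  position consistent with the target cM, so windows never silently
  shrink. Consequently overlap fractions are monotone in the window size.
- **Overlapping loci within a disease** are resolved by keeping the SNP
  with the smallest association p per transitively-overlapping group
  (ties: lexicographically smallest identifier), preserving the strongest
  signal while making windows pairwise disjoint.
- **"Unique genomic regions"** is operationalized as transitive merging of
  gene spans sharing at least one base; an alternative reading (genes
  sharing a SNP window) would change the draw size m and is not
  implemented.
- **SNP coordinates** are 1-based (GWAS-catalog convention) and windows
  closed in bp; gene annotation is 0-based half-open (BED convention)
  internally, converted at the GenomicRanges boundary.
- **Determinism.** Every generator and every Monte-Carlo stage is a pure
  function of (inputs, seed); grid screens derive per-cell seeds from a
  master seed by a stable string hash, and the pipeline writes a manifest
  with checksums so a rerun can be verified byte-for-byte.

## Validation scale and what the tests show

The packaged acceptance checks run, on one CPU in a few minutes: null
calibration of the permutation test over 200 synthetic studies (~200
significant loci, 10,000 genes, 1,000 permutations each; empirical
p-values uniform, 5% rejection within [0.02, 0.09]); power ≥ 90/100
against the two-fold planted excess; Monte-Carlo agreement with exhaustive
enumeration within three binomial standard errors on 50 micro-instances;
exact agreement of interval overlap and BH adjustment with brute-force
oracles; PVCA recovery of planted fractions within ±0.1 per factor over
20 simulations, with batch correction dropping a planted ≥0.2 batch
fraction below 0.05; paired-t error control (raw p uniform under the
null; averaged false-discovery proportion ≤ 0.07 at BH 0.05) and
sensitivity ≥ 0.9 against a one-log2-unit shift at paired-difference
noise sd 0.25 with six pairs; and persistence of planted enrichment when
the window shrinks from 0.2 to 0.1 cM. These sizes are the package's
validation conditions, chosen to make Monte-Carlo tolerances meaningful.

## A worked micro-example

Four disjoint genes A–D; two significant loci whose windows cover only A
and only B; the differential list is {A}.

```{r micro}
map <- genetic_map(data.frame(chrom = "chr1",
                              bp = c(1, seq(1e6, 1e8, by = 1e6)),
                              cM = c(1, seq(1e6, 1e8, by = 1e6)) * 10 / 1e6))
ann <- data.frame(gene = c("A", "B", "C", "D"), chrom = "chr1",
                  start = c(1e7, 3e7, 5e7, 7e7),
                  end = c(1e7, 3e7, 5e7, 7e7) + 1e4)
class(ann) <- c("gene_annotation", "data.frame")
raw <- data.frame(disease = "dz", snp_id = c("L1", "L2"), chrom = "chr1",
                  bp = c(1.0005e7, 3.0005e7), p = 1e-10)
class(raw) <- c("snp_locus_set", "data.frame")
loci <- filter_loci(raw, map)
permutation_test(loci, "A", c("A", "B", "C", "D"), ann,
                 mode = "exhaustive")
```

Half of the single-gene draws (A or B) reach the observed overlap of 1/2,
so the exact p-value is 0.5.

## Known limitations

- The permutation null treats gene positions as exchangeable within the
  expressed set; it does not model linkage disequilibrium between loci or
  chromosomal clustering of co-regulated genes.
- PVCA's method-of-moments estimator targets balanced crossed/nested
  designs; strongly unbalanced designs would warrant a mixed-model fit.
- The detection rule (min_fraction of samples within a population) is a
  declared stand-in for platform-specific filtering; its default keeps
  genes detected in *all* samples of at least one population.
- Transcription-factor target sets for the stratified Fisher test are
  user-supplied gene lists; no ChIP data processing is included.
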