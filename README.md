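# airrkit

Post-analysis of immune repertoire sequencing data in R.

High-throughput sequencing of rearranged T-cell (and B-cell) receptor loci
yields *clonotype tables*: one row per unique rearrangement with its
molecule count, CDR3 nucleotide and amino-acid sequence, V/D/J segment
assignments, and the germline markup of the CDR3 junction. `airrkit` takes
such tables (plus a sample metadata table) and provides the downstream
statistics an immunologist needs to compare repertoires across donors,
conditions and timepoints:

* **Basic statistics & segment usage** — clonotype/molecule counts,
  non-coding clonotype fraction, convergent recombination, CDR3 length
  spectratype, V/J usage profiles and V–J pairing matrices, CDR3 junction
  features (V-germline, J-germline and NDN insert lengths).
* **Diversity** — the count spectrum (abundances \(x_i\), counts-of-counts
  \(f_k\)) feeds the Chao1 lower bound
  \(S_{obs} + f_1^2/2f_2\), the Efron–Thisted alternating-series bound,
  Shannon \(\exp(H)\) and inverse Simpson \(1/\sum p_i^2\) effective
  numbers, multinomial rarefaction
  \(E[S(m)] = S_{obs} - \sum_i \binom{n-x_i}{m}/\binom{n}{m}\) with
  Chao1-anchored extrapolation, and size normalization by seeded
  downsampling (mean of 3 resamples at the smallest sample size).
* **Overlap** — pairwise shared-clonotype sets under nucleotide,
  amino-acid, or batch-robust "amino acid NOT nucleotide" matching, and
  five similarity measures: F (geometric mean of overlapping frequency
  mass), R (log-frequency correlation), D (normalized overlap size),
  Jaccard, Morisita–Horn.
* **Clustering & group statistics** — hierarchical clustering and classical
  MDS of similarity or V-usage distance matrices, a label-permutation test
  for within-group closeness, Fisher's exact test for cluster–group
  association, per-segment t-tests with Benjamini–Hochberg correction,
  Cohen's d, paired log-frequency tests.
* **Tracking** — full outer joins of clonotype tables across timepoints,
  stacked top-N tracking tables ("Not shown" / "Not in overlap"
  bookkeeping rows), persistence summaries.
* **Synthetic cohorts** — a seeded generator of realistic clonotype tables
  (Zipf–Mandelbrot clone sizes, configurable segment usage with
  between-sample noise, germline+insert CDR3 structure, planted group
  effects and twin-pair public-clonotype sharing) so every routine is
  testable without downloads.

## Worked example

Simulate a 24-donor case/control cohort with a planted 1.6-fold expansion
of one V segment in the case group, then recover it:

```r
library(airrkit)

spec <- syntheticSpec(richness = 1500, cloneSizeShift = 250,
                      nMolecules = 8000)
sim <- simulateCohort(spec, c(control = 12, case = 12),
                      groupEffects = list(case = c("TRBV5-6" = 1.6)),
                      seed = 42)
cc <- sim$collection

tt <- segmentUsageTest(cc, "group", tail = "less")
head(tt, 3)
#>   segment  mean1  mean2  fold        p        q
#> 1 TRBV5-6 0.0922 0.1423 0.648 4.57e-05 0.000548
#> 2   TRBV9 0.0817 0.0859 0.951 3.23e-01 0.943738
#> 3 TRBV7-8 0.0824 0.0864 0.954 3.25e-01 0.943738
```

The planted segment is the top Benjamini–Hochberg hit (q = 5e-4): its mean
frequency is 9.2% in controls versus 14.2% in cases, a 1/0.648 ≈ 1.54-fold
realized increase. A permutation test on the V-usage distance matrix
confirms that same-group repertoires sit closer together than random
labelings allow:

```r
dm <- usageDistance(cc, "V")
labels <- setNames(sampleMetadata(cc)$group, names(cc))
withinGroupPermTest(dm, labels, nPerm = 10000, seed = 1)$p
#> [1] 0.00039996
```

Per-sample statistics and diversity, on one sample:

```r
sp <- countSpectrum(cc[["control1"]])
chao1(sp)
#> chao1 (lower-bound): 1453.31
shannonDiversity(sp)
#> shannon (index): 950.208
```

Chao1 estimates the richness of the underlying population (true simulated
richness here: 1500) from the singleton/doubleton counts of an 8000-molecule
sample; the Shannon effective number is smaller because it discounts rare
clones. Repertoire overlap between two samples under the contamination-robust
matching rule:

```r
o <- overlapPair(cc[["control1"]], cc[["control2"]], matchingRule("aa!nt"))
metricF(o)   # geometric mean of the shared frequency mass
#> [1] 0.06540355
```

`readSample()` / `readCollection()` load real tab-delimited clonotype
tables (native dialect, or third-party dialects via `formatSpec()` column
mappings); every analysis above applies unchanged. A thin command-line
wrapper (`inst/scripts/airrkit`) exposes each routine as a subcommand
(`simulate`, `diversity`, `pairwise`, `cluster`, `permtest`, `track`, ...)
writing TSV tables with seed-stamped headers.

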