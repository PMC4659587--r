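---
title: "Methods: repertoire post-analysis with airrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repertoire post-analysis with airrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airrkit)
```

# The data model

A repertoire sample (`RepSample`) is an ordered table of clonotype records:
molecule count, frequency, CDR3 nucleotide and amino-acid sequence, V/D/J
segment names, and a germline markup of the CDR3. Counts are in molecule
units (UMI-collapsed cDNA molecules, each approximating one cell), so
frequency-weighted statistics are cell-population statistics.

Markup coordinates are **0-based, half-open**: `vEnd` is the index one past
the last V-germline base, `jStart` the index of the first J-germline base,
`dStart`/`dEnd` bound the D segment, and −1 means undefined. This
convention was chosen because every junction feature becomes a plain
subtraction: the V-germline length within the CDR3 is `vEnd`, the
J-germline length is `length(cdr3nt) − jStart`, and the NDN (VJ insert)
size is `jStart − vEnd`, so `vGerm + ndn + jGerm = length(cdr3nt)` holds
identically whenever the markup is defined. Clonotypes without V/J markup
are excluded from junction aggregates rather than imputed.

Frequencies are always recomputed as `count / total` on load; a frequency
column in the input that disagrees by more than 1% per row triggers a
warning, not an error, because upstream tools round differently. Duplicate
rows are preserved on read — merging is an explicit, named operation
(`collapseClonotypes()`), never a side effect of parsing. Third-party table
dialects are handled by `formatSpec()` column mappings; only the native
dialect is guaranteed to round-trip bit-exactly.

CDR3 translation (`translateCdr3()`) is single-frame and left-to-right:
an incomplete 3′ codon is rendered as a single `_` marker and codons
containing `N` as `X`. A two-sided convention (translating inwards from
both ends of an out-of-frame junction) exists in the field; the one-frame
rule was chosen because it is deterministic, testable, and sufficient for
the two uses the package makes of translation — amino-acid-level matching
and non-coding detection. A clonotype is *non-coding* when its amino-acid
sequence contains `*` or `_` or its nucleotide length is not divisible
by 3.

# Diversity estimation

All estimators operate on the count spectrum: abundances \(x_i\), total
\(n\), observed richness \(S_{obs}\), and counts-of-counts \(f_k\).

* **Chao1**: \(S_{obs} + f_1^2/(2 f_2)\); when \(f_2 = 0\) the
  bias-corrected fallback \(S_{obs} + f_1 (f_1 - 1)/2\) avoids division by
  zero. Always \(\ge S_{obs}\).
* **Efron–Thisted**: the truncated alternating series
  \(\Delta = \sum_{k=1}^{K} (-1)^{k+1} f_k\) with \(K = \min(20,
  \max_i x_i)\), clamped below at \(S_{obs}\). The Euler-transform
  acceleration of the original estimator is deliberately out of scope; the
  truncated series with clamping is transparent and adequate at repertoire
  scales.
* **Shannon and Simpson** are reported as effective clonotype numbers
  (\(e^H\) and \(1/\sum p_i^2\)) so that all headline values share richness
  units; the raw entropy and probability-of-identity are kept in the
  `details` slot. The Hill-number ordering (inverse Simpson ≤ exp-Shannon ≤
  richness) is enforced by construction and verified property-style in the
  tests.
* **Rarefaction** uses the multinomial model,
  \(E[S(m)] = S_{obs} - \sum_i \binom{n - x_i}{m} / \binom{n}{m}\),
  evaluated via `lchoose` so binomial coefficients survive \(n \sim 10^6\).
  Extrapolation beyond \(n\) follows the Chao1-anchored form whose
  \(m^\ast \to \infty\) asymptote equals the Chao1 estimate exactly — an
  identity the tests exploit as an oracle.

Because rarefaction curves of deep repertoires are far from saturation,
comparing diversity across samples of unequal size is biased;
`normalizedDiversity()` therefore downsamples every sample (multivariate
hypergeometric, without replacement) to the smallest included sample's
molecule count and averages the estimator over 3 independent resamples
(resampling SD is reported in place of analytic variance formulas, which
are out of scope). Samples can be excluded from both the common size and
the results — the intended use is dropping a post-transplantation sample
whose size would drag every other sample down.

Seeding: one integer seed; per-sample streams are derived as `seed +
sample index`, so collection-level results do not depend on iteration
order.

# Overlap and similarity

Clonotype matching has three levels. `nt` and `aa` are straightforward
keys (optionally including the V segment, off by default since segment
assignment conventions differ across pipelines). The pairwise-only
`aa!nt` ("amino acid NOT nucleotide") rule accepts an amino-acid key only
if the two samples' nucleotide-variant sets behind it are **disjoint**:
cross-sample contamination is identical at the nucleotide level, while
genuine convergent sharing between individuals is almost never so. The
strict all-variants-disjoint reading was chosen over subtracting only the
shared-variant mass because it is deterministic and easy to reason about.

The five similarity measures derive from one `OverlapResult`:
F \(= \sqrt{(\sum_{shared} f_1)(\sum_{shared} f_2)}\) with frequencies
relative to the *full* samples (F measures overlapping repertoire mass);
R = Pearson correlation of log10 shared frequencies (log scale because
clonotype frequencies span orders of magnitude; R is undefined, and
propagated as missing rather than zero, below 3 shared keys);
D \(= d_{12}/(S_1 S_2)\) (scale-dependent — clustering on D assumes
comparable richness); Jaccard; and Morisita–Horn with squared-count sums
over all clonotypes of each sample. Missing matrix entries are never
imputed; a matrix with more than 20% undefined pairs is refused with
advice to change rule or metric.

# Clustering and group statistics

Similarity matrices map to distances as \(d = 1 - s\) (or \((1 - R)/2\)
for the correlation measure). Agglomerative clustering (average linkage
by default) and classical Torgerson MDS do the embedding; samples are
sorted lexicographically before clustering so tie-breaking is
deterministic. When fewer positive eigenvalues than requested dimensions
exist, MDS coordinates are zero-padded with a warning.

The within-group permutation test asks whether same-group samples sit
closer together than random labelings allow. The statistic is the mean
pairwise Euclidean distance among same-group pairs, computed on the 2-D
MDS plane by default (a raw-distance mode is a flag); the p-value uses the
add-one rule \(p = (1 + \#\{perm \le obs\})/(1 + N)\), so ties count as
extreme, p is never 0, and the test is exactly calibrated — the
acceptance suite verifies a 5% type-I error over 1000 null datasets.

Segment-usage group tests are per-segment t-tests on frequency-weighted
usage with Benjamini–Hochberg correction across segments. Welch's
unequal-variance t-test is the default (a pooled-variance option exists
for matching legacy outputs). The one-tailed direction must be supplied
explicitly — a one-sided test is only defensible with an a-priori
hypothesis, so there is no silent default. Fold changes against an absent
segment are reported as infinite, flagged rather than dropped. Fisher's
exact test evaluates cluster–group association after cutting the
dendrogram at k = 2 (two groups are compared; larger k is allowed but
recall is only reported for k = 2).

# Clonotype tracking

`joinSamples()` is a full outer join on match keys with deterministic row
order (descending mean frequency, then key). `trackTop()` keeps the top-N
rows and aggregates the remainder into "Not shown" (observed in ≥ 2
samples, below top-N) and "Not in overlap" (private to one sample); the
occurrence-≥2 rule is the N-sample generalization of the two-sample
wording. Every sample column of a tracking table sums to 1 within 1e-6 —
a conservation law the tests check exactly.

# The synthetic cohort generator

The generator emulates the statistical structure the analyses assume,
not the biology of recombination:

* **Clone sizes** follow a Zipf–Mandelbrot law, \(p_i \propto (i +
  q)^{-\alpha}\) with \(\alpha = 1.5\) and \(q = 20\) by default. The
  heavy tail keeps rarefaction curves far from saturation (as in real
  repertoires); the shift \(q\) tempers the head so top clones carry a few
  percent of the mass — a pure Zipf law would put ~40% of molecules in the
  single top clone, which real blood repertoires do not show.
* **CDR3s** are assembled as trimmed synthetic V stub + uniform-ACGT
  insert of geometric length (mean 6 nt, the typical NDN scale) + trimmed
  J stub, with consistent half-open markup. Segment stubs are
  deterministic synthetic strings, not real IMGT sequences — biological
  realism is unnecessary for algorithmic testing. 90% of clones are
  constrained to in-frame length, mimicking selection for productive
  rearrangements.
* **Usage noise**: per-sample lognormal multiplicative noise on the
  segment-usage probabilities with CV 20%, a realistic inter-individual
  spread and the cohort condition under which the planted-effect power
  properties are stated. On top of this, clone-level sampling adds noise
  that shrinks with the effective clone count; power checks on planted
  usage folds therefore use a flattened, larger repertoire (shift 250,
  richness 1500, 8000 molecules) so the realized between-sample CV is the
  stated 20% rather than being dominated by clone-sampling noise.
* **Planted structure**: per-group usage fold multipliers (renormalized),
  and twin pairs drawing a fixed fraction (0.2 in the benchmark design:
  3 twin pairs, so 3 twin and 12 unrelated pairs among 6 samples) of
  their repertoire frequency from a pair-specific public clone pool.
  Unrelated samples still share some amino-acid keys by chance — short
  inserts recur, as public clonotypes do in reality — so the twin
  discrimination check is a genuine signal-versus-background comparison.

What the generator does **not** emulate: D-segment markup (vd/dj insert
statistics are exercised with handcrafted fixtures), somatic hypermutation,
sequencing error, selection against stop codons inside the insert (the
simulated non-coding fraction is therefore higher than in real mRNA-based
data), and realistic germline sequence content. Passing tests demonstrate
the correctness and calibration of the algorithms under controlled
conditions, not biological fidelity of any particular dataset.

Reproducibility: identical spec + seed give byte-identical tables.
Per-sample seeds are `seed + index`, pool seeds `seed + 100000 + pair`.

# Problem sizes and numerical choices

The validation suite runs at desk scale by design: toy spectra (tens of
molecules) where exhaustive enumeration is possible, simulated samples of
500–8000 molecules, cohorts of 6–24 samples, 100 cohort replicates for
power/discrimination properties, 1000 datasets × 500 permutations for
type-I calibration, and all 46,376 2×2 tables with total ≤ 30 for the
Fisher-exact enumeration check. Binomial coefficients are computed in
log-space; permutation p-values use the add-one correction; BH q-values
come from the standard step-up; degenerate inputs (empty samples,
zero-variance groups, constant paired differences, singleton permutation
groups) are reported as missing, p = 1 conventions, or warnings as
documented on each function — never silently dropped.

# Known limitations

* The `aa!nt` rule discards genuinely shared clonotypes that happen to
  share one nucleotide variant; this is the price of contamination
  robustness.
* D metric diagonals (1/S) are reported but should not be clustered on
  when sample richness differs widely.
* Efron–Thisted is the truncated series, not the Euler-accelerated
  version, and can be conservative when \(f_k\) oscillates strongly.
* The CLI writes tables only; figures are left to the user (the matrices
  and long-format TSVs are plot-ready).
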