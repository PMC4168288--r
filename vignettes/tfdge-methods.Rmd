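---
title: "Methods: modelling differential expression from differential TF binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling differential expression from differential TF binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfdge)
```

# Scope and model

`tfdge` asks how much of the change in gene expression between two related
cell types is explained by the change in binding of a panel of transcription
factors assayed in both. The data model is: per (TF, cell type) sample a set
of ChIP-Seq peak calls and read intervals (BED, 0-based half-open), per gene
a pair of fpkm values with an externally supplied differential-expression
flag, and optionally genomic sequence plus position weight matrices for
motif content.

The response and predictors are pseudocounted log ratios with cell type B in
the numerator:

* per gene, `delta_ge = log2((fpkm_B + c) / (fpkm_A + c))`;
* per region and TF, `delta_tf = log2((cov_B + c) / (cov_A + c))` on
  coverage normalised per 10 million reads, then averaged over the regions
  assigned to a gene in which the TF has a called peak.

The exact algebraic form of these contrasts is a design choice of this
package: the log-of-ratio form with a shared pseudocount `c = 1` (default,
configurable) is standard practice, is antisymmetric under swapping the cell
types, and leaves correlation-based results invariant to the shared sign
convention. Alternatives (difference of logs of pseudocounted values,
normalised differences) differ only in tail behaviour at near-zero coverage.

Two model classes link them:

* **Linear** (`fit_delta_lm`): OLS of `delta_ge` on the per-TF `delta_tf`
  vector over genes bound by at least `min_tfs` TFs. Accuracy is training
  R² and tenfold cross-validated R², where each fold's R² is the squared
  Pearson correlation between held-out observed and predicted values and
  the summary is the mean over folds (`1 - RSS/TSS` on the held-out fold is
  reported alongside, since the two diverge when predictions are biased).
* **Additive** (`fit_delta_gam`): Gaussian GAM with identity link,
  `delta_ge ~ sum_i s(delta_tf_i)` plus, optionally, one interaction-only
  tensor-product smooth `ti(delta_tf_i, delta_tf_j)` per unordered TF pair
  (45 pairs for 10 TFs). Smoothing parameters are selected by REML via
  `mgcv`; accuracy is adjusted R²,
  `1 - (RSS / (n - edf)) / (TSS / (n - 1))`. The default `min_tfs = 2`
  reflects that genes bound by a single TF carry no information about
  pairwise interactions.

# Pipeline rules and their edge cases

**Interval convention.** All coordinates are BED-style 0-based half-open;
two intervals overlap iff they share at least one base, so book-ended
intervals (`[10,20)`, `[20,30)`) do not merge and do not co-occupy.
Chromosome names are matched exactly; reads on chromosomes absent from the
atlas are excluded with a warning rather than silently renamed.

**Peak merging and coverage.** All samples' peaks are merged transitively at
≥ 1 bp overlap; a read counts toward a region if it overlaps it by ≥ 1 bp
(no fractional-overlap threshold); normalisation is `raw * 1e7 /
library_size`, so doubling the library size exactly halves every entry.
Whether "coverage" should be read counts or peak-caller scores is not fully
determined by the upstream tooling conventions; read counting is the
primary mode here because it is self-contained and linear in sequencing
depth.

**Sample correlation.** Pearson correlation between coverage columns, with
hierarchical clustering on `1 - r`. No linkage is canonical for this
heatmap-style summary; average linkage is the default and the argument is
exposed. Constant columns make correlation undefined and raise an error
naming the sample.

**Gene assignment.** Precedence: (1) overlap with the closed ±1 kb TSS
window or the gene body assigns the region to that gene — to *all* such
genes when several overlap, with the TSS-window rule recorded when both
apply to the same gene; (2) otherwise the nearest gene per side within
50 kb (gap measured edge-to-edge; both sides may assign, giving at most two
entries for an intergenic region; equidistant same-side ties break to the
smaller gene id for determinism); (3) otherwise unassigned. Enlarging
either window can only grow the assigned set, and bound-gene sets are
nested in the bound-TF threshold — both properties are tested.

**Expression categories.** Category IV (not expressed) requires both fpkm
below 2; categories II/III (cell-type-specific) require the external
significance flag plus fold change ≥ 4 and take precedence over category I
(comparable expression). The floor/fold thresholds are arguments. At the
boundary fpkm = 2 exactly, the record counts as expressed; the
published rule set is ambiguous there and this package resolves it in
favour of expression.

**Unbound encoding.** A TF that does not bind a gene contributes an exact 0
to that gene's `delta_tf` vector rather than a missing value; this matches
the design implied by thresholding on bound-TF counts, keeps the design
matrix complete, and makes the invariant "`delta_tf == 0` iff unbound"
testable. TFs bound in fewer than 10 genes of the filtered set are dropped
from the design with a warning, because their coefficient/smooth would rest
on a handful of observations.

# Numerical choices

* **CV folds**: one uniform shuffle under the run seed, contiguous blocks,
  remainder rows spread one per fold from the first fold; folds partition
  the rows exactly. A fold with constant observed or predicted values makes
  the squared correlation undefined and raises an error carrying the fold
  index.
* **Spline bases**: cubic regression splines with basis dimension 10 per
  univariate smooth; interaction smooths are `ti()` tensor products with
  marginal dimension 4 (9 coefficients each), keeping the 45-pair design
  tractable while leaving main effects identifiable in their own terms.
  Both dimensions are arguments.
* **REML**: `mgcv`'s Newton optimiser with its defaults; `method` is
  exposed (`"GCV.Cp"` as fallback) and `sp` can be fixed, which is how the
  heavy-smoothing limit is verified — as all smoothing parameters grow, the
  cubic-spline fits collapse onto their linear null space and the GAM's
  fitted values converge to the OLS fit (tested to max abs difference
  < 1e-3, observed ~1e-7).
* **Chi-square**: Pearson's test without continuity correction (df = 1),
  appropriate at the gene-set sizes involved; zero margins raise an error
  rather than returning a degenerate statistic. The implementation is
  checked against the closed form `n(ad-bc)² / (r₁r₂c₁c₂)` and for type-I
  calibration under an independent null.
* **PWM scanning**: motifs are probability matrices after a 0.5 pseudocount
  per count cell; scores are log₂-odds against a uniform background
  (sequence-derived backgrounds can be supplied), computed at every offset
  on both strands, with windows containing `N` skipped. The default hit
  threshold is 80% of the motif's maximum achievable score. Scanning of
  known motifs replaces de-novo discovery and motif-to-motif matching,
  which are outside this package's scope; content fractions are therefore
  comparable across categories within a run but only approximately
  comparable to discovery-based fractions.

# The synthetic-data generator

The generator emulates the statistical structure the models assume, with
ground truth recorded in a `synthetic_truth` object:

* **Genome/genes**: non-overlapping gene bodies with uniform strands on
  uniform-base sequence.
* **Peaks/reads**: per TF, candidate locations on non-overlapping slots
  biased towards TSSs (exponential decay, 10 kb scale); a controllable
  fraction of locations is shared between cell types, the rest split into
  A-only/B-only. Each location carries a target `delta_tf ~ N(0, dtf_sd²)`
  realised by placing `round(cov * library_size / 1e7)` fixed-length reads
  with log-normal base coverage (median 50), so realised per-region scores
  track the targets at r ≥ 0.9 (tested).
* **Expression**: `delta_ge = Σ f_i(delta_tf_i) + Σ γ_ij delta_tf_i
  delta_tf_j + ε`, `ε ~ N(0, σ²)`; fpkm pairs are back-solved as
  `base · 2^(∓delta_ge/2)` with log-normal base expression — exact for
  pseudocount 0, slightly compressed otherwise. Significance flags are
  `|delta_ge| > 0.5` (an external differential test is out of scope);
  H3K27ac flags have their odds multiplied by a configurable odds ratio for
  genes with `|ε| ≤ σ`, linking the mark to predictability.
* **Population R²**: with standard-normal predictors the signal variance is
  `Σβ² + Σ var(f_i) + Σγ²`, so `population_r2 = signal / (signal + σ²)`;
  supplying `population_r2` back-solves `σ`. Analytic variances are used
  for smooth effects (e.g. `var(sin 2X) = (1 - e⁻⁸)/2`).

Default study conditions used by the verification suite: parameter recovery
runs 200 replicates at n = 5000 genes, 10 TFs, β = 0.5 each, population
R² = 0.5; model-class separation uses n = 2000 with a planted `sin(2x)`
smooth (2 TFs) and a planted pairwise product (4 TFs, γ = 0.8); the GAM
limit uses n = 500; chi-square calibration uses 500 replicates of n = 2000.
These sizes give stable statistics at desk scale while exercising every
code path; the `paper_shaped` preset of `simulate_study()` scales the same
generator towards a 10-TF, thousands-of-genes study.

What passing these tests shows — and does not. The generator draws
independent predictors, Gaussian noise, and well-separated peaks; real
ChIP-Seq has correlated TF binding, heteroscedastic coverage, overlapping
peaks, and mapping artefacts. Recovery of planted parameters therefore
validates the pipeline's arithmetic and the estimators' correctness, not
the biological adequacy of the linear/GAM model class on any particular
dataset.

# Known limitations

* Gene-level `delta_tf` averages only peak-bearing assigned regions
  (all-regions averaging is not offered); with no bound region the gene
  scores exactly 0.
* Transcript collapsing keeps the transcript with the largest summed fpkm
  (`"max"`, default) or averages (`"mean"`); other collapsing schemes are
  not implemented.
* Read positions are consumed as BED intervals; BAM/SAM and full GFF/GTF
  parsing are out of scope, as are peak calling, differential-expression
  testing, and de-novo motif discovery.
* The interfaces are R functions (`pipeline_features()` drives the full
  chain); there is no shell executable.
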