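---
title: "Methods: rank-bin integration of label-free proteomes across datasets"
author: "binatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-bin integration of label-free proteomes across datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binatlas)
```

## The integration model

Label-free iBAQ intensities from independently acquired datasets differ by
large multiplicative factors (instrument response, loading, acquisition
depth) and by which proteins are detected at all. `binatlas` integrates
such datasets under two commitments:

* **Each dataset is processed independently** through filtering, FOT
  normalization and gene mapping. Nothing pooled enters a per-dataset
  result, so adding a dataset later leaves earlier per-dataset outputs
  byte-identical — a practical requirement for an atlas that grows over
  time.
* **Datasets are compared only through within-run ranks.** Per MS run, the
  detected ppb values are cut into `n_bins` equal-frequency bins. Any
  strictly increasing transform of a run's intensities — in particular a
  global batch factor — leaves the bins unchanged, which is the entire
  robustness argument: no cross-dataset normalization model is fitted, and
  none has to be believed.

### Filtering and normalization

Groups flagged as decoys or potential contaminants, and groups with fewer
than 2 PSMs (`min_psm`, configurable), are removed first; a row failing
several criteria is counted once (decoy > contaminant > low PSM) so the
removal report balances exactly. FOT normalization then rescales each run:
`ppb = ibaq / sum(ibaq) * 1e9` over detected values. The denominator is
computed *after* filtering so that contaminant signal does not distort the
scale; the order is configurable in principle but the filtered denominator
is the default because a run dominated by keratins would otherwise
compress every genuine ppb value.

### Gene mapping

A protein group maps to the set of distinct gene identifiers of its
majority protein IDs. Isoform accessions of one gene collapse to that
gene; groups spanning several genes are excluded into a side table
(reason `multi-gene`) rather than guessed; unmapped accessions exclude the
group (reason `unmapped`). When several groups map to one gene, the gene's
per-run value is the median of the groups' non-missing ppb values —
dropping missing values before the median is the least destructive rule
when one group is detected and another is not, though it does mean a
gene's value can be carried by a single isoform group in sparse runs.
Summing instead of taking the median is deliberately not offered: summed
isoform aggregation behaves poorly when isoform coverage differs between
runs.

### Binning and the missing-value rules

Within a run with `m` detected proteins, the protein with (average) rank
`r` gets bin `ceiling((r - 0.5) * n_bins / m)`: the equal-frequency slice
of `1..m` containing the rank's midpoint. Ties share the average rank and
hence a single bin. The midpoint convention was chosen over
`ceiling(r * n_bins / m)` because it treats tied groups consistently with
untied ones and coincides with it whenever `n_bins` divides `m`;
equal-width binning on ppb is not offered at all, since abundances span
about five orders of magnitude and equal-width bins would put nearly
everything in bin 1. When a sample comprises several runs, the sample bin
is the median run bin rounded half up.

Missingness is resolved per *batch* — all samples of one tissue within one
dataset: a gene undetected in every sample of the batch is `NA` there
(absent as far as that batch can tell), while a gene detected in some
samples gets bin 1 in the remaining ones (present in the material, below
the detection limit of that sample). The distinction matters downstream:
`NA` counts as 0 in the specificity mean, so absence elsewhere strengthens
enrichment, whereas bin 1 is evidence of broad low expression.

Three-level bins for categorical-atlas comparison are recomputed from ppb
with the same algorithm (`rebin(..., method = "recompute")`), keeping the
definition self-consistent; collapsing 5-level bins as {1,2}/{3,4}/{5} is
available as `method = "collapse"`.

### Specificity classification

For each gene, per-organ bins are the rounded-half-up median over the
organ's samples. The gene's mean bin is taken across **all** organs,
including the candidate and with `NA` as 0; the enrichment threshold is
twice that mean, compared inclusively (`>=`). One organ at or above the
threshold makes the gene organ-enriched, 2–7 group-enriched, anything else
mixed; a gene with no detected organ is mixed with flag `undetected`. The
excluded-candidate variant (mean over the *other* organs) and strict
comparison are available as toggles (`exclude_self`, `inclusive`), since
both readings of "twofold above the mean" exist in the atlas literature.

Two arithmetic consequences are worth knowing. A gene expressed at a
similar level everywhere can never be enriched: for a constant profile the
threshold `2b` exceeds the largest bin. And with `NA` counted as 0, a gene
detected at equal bin `b` in `k` of 6 organs satisfies `b >= 2kb/6` only
for `k <= 3` — so group-enrichment across 4–7 organs is only detectable
when the gene is *also* expressed (at lower bins) in the remaining organs.
On synthetic data this caps group-enriched recall near 40% while
organ-enriched recall is essentially complete; the same asymmetry should
be expected on real data.

### Cross-dataset FDR

Decoy hits surviving in the unfiltered tables estimate the error of the
aggregated protein list as a function of reproducibility:
`FDR(k) = D(k) / T(k)` with `T(k)`/`D(k)` the targets/decoys detected in
at least `k` datasets. Spurious matches recur across independent searches
far less often than genuine proteins, so the curve falls steeply in `k`;
on the default synthetic study it drops from about 3% at `k = 1` to below
1% at `k = 3`. Identity across datasets is the sorted majority-ID set of
the group — decoys carry no gene mapping, so the FDR is computed at the
protein-group level.

### Atlas comparison statistics

Categorical reference levels map to 1/2/3 (low/medium/high), `NA` for
"not detected", and 1 for the ascending/descending/not-representative
annotations; rows with reliability "uncertain" are dropped. Agreement with
the pipeline's three-level organ profile is quantified by the randomized
edit distance difference: pairs with `NA` on either side are removed, the
true mean absolute bin difference is subtracted from its average under
`n_perm` protein-wise permutations of the reference. Permutation (not
resampling) is the default null because it preserves the reference's bin
composition; resampling with replacement is available. The default
`n_perm = 10` mirrors common practice for this statistic; tests use
thousands of replicates where convergence to the enumerable exact value is
asserted. Continuous references are compared per organ by Pearson
correlation of log2 gene medians, dropping non-positive and missing values
pairwise and skipping organs with fewer than 3 usable genes.

### QC conventions

Sample-sample correlations are Pearson on pairwise-complete bin vectors
(`NA` if fewer than 3 complete pairs or a constant vector). Clustering is
agglomerative on Euclidean distances between correlation rows; the linkage
method is complete (configurable — only the distance is canonical) and
rows are pre-sorted by sample id so leaf order is deterministic under
ties. PCA keeps genes quantified in at least half the samples
(`min_fraction`), imputes remaining `NA` as 0 — undetected approximates
lowest signal on the bin scale — or optionally as the gene mean, centers
genes, and decomposes by SVD.

## The synthetic study

The generator (`sim_config()`, `generate_truth()`, `simulate_dataset()`)
emulates the inputs the pipeline is built for, with known ground truth so
that every stage has a known-answer test.

* **Abundance**: log10 iBAQ baselines are normal with sd 1.0 (about five
  orders of magnitude across genes), per-measurement log10 noise sd 0.1.
* **Batch structure**: a per-dataset global factor (log10 sd 0.3) and a
  per-run depth factor (log10 sd 0.1), both multiplicative — exactly the
  distortions rank binning is meant to cancel.
* **Dropout**: detection is Bernoulli with logistic probability in log10
  intensity, midpoint at the run's 30th abundance percentile and slope 25
  per log10 unit (detection rises 10%→90% over ~0.2 orders of magnitude —
  a sharp detection limit). Tying the midpoint to the run's own quantile
  makes detection depth-invariant, so batch factors do not leak into
  missingness.
* **Specificity structure**: organ-enriched genes have one organ with an
  8-fold abundance effect, group-enriched 2–7 such organs, mixed none.
  Enriched genes are modeled as tissue-restricted: their out-of-organ
  baseline sits in a narrow band just below the detection limit (log10
  baseline 1.25–1.45 sd below the population mean), and the fold lifts
  them above it in their organs. This is the regime in which a bin-based
  twofold classifier is informative — a gene expressed mid-range
  everywhere cannot be called enriched on a bounded bin scale (see above)
  — and it matches the biology of organ-specific proteins, which are
  near-undetectable outside their tissue. The band is placed relative to
  the *mixture* quantile of the abundance distribution, since concentrating
  ~20% of genes in a low band itself shifts the run-level detection
  midpoint.
* **Nuisance rows**: decoys (10% of genes) and planted false targets draw
  intensities from the bottom half of the target distribution, but whether
  they appear in a dataset at all is an independent Bernoulli event
  (probability 0.4): spurious search matches are dataset-level artifacts,
  not reproducible signal, which is what makes `FDR(k)` fall with `k`.
  Contaminants are few (5) and high-abundance. A configurable fraction of
  target groups (5%) is forced below 2 PSMs to exercise the filter, and
  10% of multi-isoform genes split their isoforms over two protein groups
  to exercise median aggregation.
* **Reference atlases**: the categorical atlas is the per-organ tercile
  discretization of the true organ abundances, with each level resampled
  uniformly with probability `noise_rate`; the continuous atlas is the
  true abundance with log-normal noise. At `noise_rate = 1` the
  categorical atlas carries no signal, so the randomized edit distance
  difference against it vanishes within Monte-Carlo error.

Randomness uses R's default Mersenne-Twister with inversion sampling;
every dataset derives its stream from the study seed and its index, so a
study extended by one dataset reproduces the earlier ones bit for bit.

What the generator does **not** emulate: peptide-level identity and shared
peptides across genes (protein grouping is taken as given), correlated
biological replicates, compositional distortion of FOT by a few dominant
proteins, instrument-specific intensity nonlinearities, and real annotation
churn in accession-to-gene maps. Passing tests therefore validate the
pipeline's arithmetic and its robustness to rank-preserving batch effects
and abundance-dependent dropout — not the biological fidelity of any
particular public dataset.

## Problem sizes and numerical choices

The default study simulates 2,000 genes over 3 datasets × 6 organs × 2
tissues × 2 samples (72 runs), which keeps an end-to-end run in a few
seconds while leaving ~1,500 genes per organ pair for the comparison
statistics; unit tests use 200-gene studies. FOT conservation is asserted
to a relative 1e-9; ties in binning are resolved by average rank
(deterministic); medians of bins round half up, biasing toward the higher
bin rather than dropping evidence of expression; permutation statistics
take an explicit seed and restore the caller's RNG state.

## Known limitations

* The classifier inherits the bounded-scale blind spots described above
  (no enrichment calls for uniformly expressed genes; weak recall for
  broad groups).
* FDR(k) treats datasets symmetrically; a single deep dataset contributes
  the same reproducibility evidence as a shallow one.
* The pipeline assumes one quantification column per run and a complete
  run-to-sample map; fractionated designs are handled only through the
  median-of-run-bins rule.
* Excluded multi-gene groups are reported, not rescued; quantifying them
  would require peptide-level evidence that `proteinGroups.txt` does not
  carry.
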