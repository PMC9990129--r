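# binatlas

Cross-dataset integration of label-free proteomics abundances through
rank bins.

## The problem

Public label-free proteomics datasets are searched and quantified one at a
time, and their iBAQ intensities are not comparable across studies:
instruments, acquisition depth and sample handling impose strong
multiplicative batch effects, and low-abundance proteins drop out of
detection in a depth-dependent way. Building a baseline protein-abundance
atlas across organs from many such datasets therefore needs an
integration scheme that is robust to monotone distortions of intensity and
explicit about missing values.

`binatlas` implements that post-search pipeline for MaxQuant-style
`proteinGroups.txt` tables, for anyone assembling or auditing a multi-study
organ atlas:

1. **Filtering** — remove decoy hits, potential contaminants, and protein
   groups with fewer than 2 PSMs.
2. **FOT normalization** — scale each protein's iBAQ intensity by the total
   signal of its MS run: `ppb_i = ibaq_i / Σ_j ibaq_j × 1e9` (parts per
   billion).
3. **Gene mapping** — collapse protein groups to canonical genes via their
   majority protein IDs; isoform groups collapse to one gene, ambiguous
   (multi-gene) groups are set aside, and groups sharing a gene aggregate
   by the per-run median.
4. **Rank binning** — per MS run, detected ppb values are ranked and cut
   into five equal-frequency bins (bin 1 = lowest). Within each *batch*
   (all samples of one tissue in one dataset), a protein undetected in
   every sample is `NA`, while one detected in only some samples gets bin 1
   in the others. Because bins depend on ranks alone, any monotone batch
   effect cancels.
5. **Organ specificity** — per-organ median bins classify each gene as
   *organ-enriched* (one organ with bin ≥ 2 × the mean bin across all
   organs, `NA` counting as 0), *group-enriched* (2–7 such organs), or
   *mixed*.
6. **QC** — cross-dataset decoy FDR (`FDR(k) = decoys/targets detected in
   ≥ k datasets`), pairwise-complete Pearson correlations of bins,
   hierarchical clustering, PCA on genes quantified in ≥ 50% of samples.
7. **Atlas comparison** — against categorical references (levels
   low/medium/high → 1/2/3, after re-binning to three levels) via the
   *randomized edit distance difference* — mean absolute bin difference
   under protein-wise permutation minus the observed one; ≈ 0 for noise,
   positive for concordant signal — and against continuous references via
   per-organ Pearson correlation of log2 gene medians.

A synthetic multi-dataset generator with planted ground truth
(organ-enrichment structure, batch effects, abundance-dependent dropout,
decoys, contaminants, isoform groups) makes every stage testable end to
end; see the methods vignette (`vignettes/binatlas-methods.Rmd`).

## Worked example

```r
library(binatlas)
run <- run_pipeline(pipeline_config(seed = 1), out_dir = "atlas_out")
print(run)
#> binatlas pipeline run -> atlas_out
#>   datasets: 3  genes quantified: 1749  samples: 72
#>   specificity: group-enriched: 93  mixed: 1411  organ-enriched: 245
#>   decoy FDR < 1% from k = 3 datasets on
```

Three simulated datasets (6 organs × 2 tissues × 2 samples each) quantify
1,749 of 2,000 genes after filtering and gene mapping. 245 genes come out
organ-enriched — the 200 planted ones are recovered at 100% here, plus
low-abundance genes detected in a single organ by chance. Decoy
accounting shows why multi-dataset evidence matters: proteins detected in
at least 3 datasets carry a decoy-estimated FDR below 1%, while single
dataset detections sit near 3%.

```r
summary(run)          # per-dataset counts, FDR table, per-organ edit distances
run$compare$edit      # randomized edit distance difference per organ (> 0:
                      # pipeline bins agree with the reference atlas)
```

The artifact directory contains every stage as TSV (`ppb_<dataset>.tsv`,
`bins5.tsv`, `organ_profile.tsv`, `specificity.tsv`, `fdr.tsv`, ...) plus a
JSON manifest; outputs are byte-identical across reruns with the same
configuration and seed. A thin CLI over the same functions lives at
`inst/scripts/atlas-pipeline.R` (`simulate` and `run-all` subcommands).

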