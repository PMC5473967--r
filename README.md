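# dualtrans

Comparative analysis of transcription and translation around the 24-h day
from paired ribosome-profiling (RPF-seq) and RNA-seq time series in two
organs.

## The scientific problem

Ribosome profiling measures protein synthesis by sequencing ~26–35 nt
ribosome-protected mRNA fragments (RPFs); paired RNA-seq measures mRNA
abundance. Sampling two organs (kidney, liver) every 2 h across the day —
2 organs × 2 assays × 12 timepoints × 2 replicates = 96 libraries — lets one
ask where gene expression output diverges between tissues and how much of
that divergence is set at the level of translation rather than mRNA
abundance. `dualtrans` provides the statistical machinery for this design:

- **Translation efficiency (TE).** Counts are scaled by upper-quartile
  effective library sizes (75th percentile of positive gene counts, factors
  rescaled to geometric mean 1), converted to
  RPKM = count / (length/10³) / (effective size/10⁶), and
  TE = RPF-RPKM / RNA-RPKM per gene and sample.
- **Differential TE between organs.** Per gene, a two-sided Wilcoxon
  signed-rank test on paired log TE across the 24 samples, Benjamini–Hochberg
  FDR, and a call requiring q < 0.01 **and** ≥ 1.5-fold TE difference.
- **Translational compensation.** Per sample, cross-organ Spearman ρ over
  genes at the RNA and at the RPF level; paired t-test on Fisher
  z-transformed coefficients. Compensation shows as footprints agreeing
  better across organs than mRNAs.
- **Rhythm detection.** Per gene, least squares
  y = m + a·cos(2πt/24) + b·sin(2πt/24) versus the flat model on log2
  expression, AIC model selection, peak phase φ = (24/2π)·atan2(b, a) mod 24,
  and a peak-to-trough amplitude gate 2^(2√(a²+b²)) ≥ 1.5.
- **Phase lags.** RPF-minus-RNA peak differences wrapped into (−12, 12] h,
  a KS-statistic permutation test between lag distributions, the
  Watson–Wheeler circular test for phase-distribution homogeneity, and lagged
  cross-correlation of RPF against RNA profiles (negative lag ⇔ RPF leads).
- **uORF analysis.** AUG-initiated upstream ORFs of ≥ 18 nt to the first
  in-frame stop, composite merging of overlapping uORFs, translation calls
  from A-site reading-frame bias (one-sided exact binomial against ⅓) plus
  > 10% positional coverage, and uORF-level TE.
- **Isoform divergence.** Hellinger distance
  H = (1/√2)·√Σ(√p_L − √p_K)² between a gene's isoform-proportion vectors in
  the two organs (0 = identical usage, 1 = disjoint), feature attribution
  (5′UTR / CDS / 3′UTR) and Kozak-context scoring (consensus GccA/GccAUGG,
  +3/+1 scheme, maximum 13).
- **Profile clustering.** Per-gene 4×4 Euclidean dissimilarities between the
  kidney/liver × RNA/RPF time courses, weighted fusion over genes, and
  average-linkage hierarchical clustering with Newick export.

A fully truth-tracked synthetic-data generator (`simulation_config()`,
`simulate_dataset()`, `simulate_footprints()`) emulates the complete study —
negative-binomial counts, planted rhythms and RPF-leads-RNA lags,
anticorrelated organ-level RNA/TE shifts, 3-periodic footprints, planted
uORFs — so every stage is testable end to end without external data.

## Worked example

```r
library(dualtrans)

cfg <- simulation_config(seed = 8, n_genes = 1000)
sim <- simulate_dataset(cfg)
sim
#> translatome_simulation: 1000 genes, 4 strata x 24 libraries (seed 8)
#>   planted: 100 RNA-rhythmic, 20 TE-rhythmic, 200 uORF genes

r <- lapply(sim$counts, rpkm)
compensation_test(r$kidney_RNA, r$liver_RNA, r$kidney_RPF, r$liver_RPF)
#> cross-organ compensation: mean Spearman rho RPF 0.805 vs RNA 0.733
#>   paired t on Fisher z: t = 86.78, p = 1.9e-30 (n = 24 samples, 1000 genes)

fits_rna <- call_rhythms(r$kidney_RNA)
fits_rpf <- call_rhythms(r$kidney_RPF)
sum(fits_rna$rhythmic); sum(fits_rpf$rhythmic)
#> [1] 101
#> [1] 117

pd <- phase_differences(fits_rpf, fits_rna)
attr(pd, "mean_delta")      # planted kidney RPF-RNA lag is -2 h
#> [1] -1.95

fit_harmonic(rep(seq(0, 22, 2), each = 2),
             5 + 0.5 * cos(2 * pi * (rep(seq(0, 22, 2), each = 2) - 8) / 24))
#> 24-h harmonic fit
#>   mesor 5.000, half-amplitude 0.500 (log2), peak phase ZT8.00
#>   peak-to-trough fold 2.000; AIC harmonic -1097.24 vs flat -45.91
#>   rhythmic (fold >= 1.50): TRUE
```

The compensation readout shows the planted effect: organ-level TE
differences anticorrelated with mRNA differences make footprint abundances
more similar across organs (ρ 0.805) than mRNA abundances (ρ 0.733). The
rhythm caller recovers the planted 10% RNA rhythms, and the mean phase
difference recovers the planted −2 h kidney lag (footprints peak before
mRNA).

`run_pipeline(cfg, out_dir)` executes every stage in order (simulate →
quantify → differential TE → compensation → rhythms → lags → uORFs →
Hellinger → clustering) and writes all tables, BED/Newick outputs and a
manifest with configuration, seeds and file hashes.

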