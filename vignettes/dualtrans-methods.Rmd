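---
title: "Methods: dual-organ around-the-clock translatome analysis"
author: "dualtrans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-organ around-the-clock translatome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualtrans)
```

# The design and the models

`dualtrans` analyses a paired ribosome-profiling (RPF-seq) and RNA-seq time
course in two organs: 12 Zeitgeber timepoints (ZT0–ZT22, 2-h steps) in
duplicate, giving 24 libraries per organ × assay stratum and 96 in total.
Each library is identified by the 4-tuple (organ, assay, timepoint,
replicate), encoded in column names as `organ_assay_ZTxx_repN`. Throughout,
coordinates on transcripts are 0-based and half-open; genome coordinates are
never needed because footprints arrive transcript-mapped.

## Normalization, RPKM and translation efficiency

Library scaling uses upper-quartile normalization: per library the factor is
the 75th percentile of the counts of genes with a positive count, divided by
the raw library size; factors are rescaled to geometric mean 1, and the
effective size is raw size × factor. RPKM is
count / (length/10³) / (effective size/10⁶), computed on CDS counts against
CDS lengths, with no mappable-length correction. Translation efficiency is
the per-gene, per-sample ratio RPF-RPKM / RNA-RPKM; it is undefined (NA,
gene retained) wherever the RNA RPKM is zero. Two invariances pin the
arithmetic down and are enforced by tests: RPKM is invariant under global
depth rescaling of any library, and TE under joint rescaling of the RPF and
RNA libraries.

The phrase defining the RPKM denominator admits two readings (per-sample
effective sizes with geometric-mean-1 factors, versus dividing by a single
geometric mean across samples). We use the former: it keeps RPKM a
per-library quantity, reduces to the textbook definition when all factors
are 1, and differs from the alternative only by a global constant that
cancels in every downstream ratio (TE, organ ratios) and in Spearman
correlations.

## Replicate measurement error

To compare technical reproducibility of RPF and RNA data, genes are binned
into ten deciles of overall expression — the fourth root of the product of
the four stratum means (liver RNA × liver RPF × kidney RNA × kidney RPF of
normalised counts) — and within each bin, per organ × assay and timepoint,
the measurement error is mean over genes of (log x₁ − log x₂)²/2 for the two
replicates, with the 12 timepoints providing the spread. Logs are natural
logs of (normalised count + 0.5); the pseudo-count handles zeros and is the
conventional half-count. A filter flag excludes genes whose mean expression
ratio between any two strata exceeds 2 at every timepoint, for the variant
restricted to comparably expressed genes.

## Differential translation efficiency

Per gene, paired log TE differences across the 24 samples are tested with
the two-sided Wilcoxon signed-rank test. Zero differences are dropped (the
standard convention). For ≤ 25 untied pairs the exact null is used; the
all-positive/all-negative boundary is exact under the sign-flip null
regardless of tied magnitudes (only one of the 2ⁿ sign assignments reaches
it, so p = 2/2ⁿ); otherwise a normal approximation with continuity and tie
correction applies. P-values are Benjamini–Hochberg adjusted across genes
and a gene is called differential only when q < 0.01 **and** the inter-organ
TE ratio (of medians) is at least 1.5-fold. The fold gate makes the
procedure conservative: on null simulations the fraction of calls stays
below 2%.

## Translational compensation

For each of the 24 timepoint × replicate pairs, the cross-organ Spearman
correlation over genes is computed at the RNA and the RPF level; the two
coefficient sets are Fisher z-transformed and compared by a paired two-sided
t-test. Average ranks handle ties. If organ-specific TE counteracts
organ-specific mRNA abundance, footprints agree better across organs than
mRNAs (mean ρ\_RPF > mean ρ\_RNA).

## Rhythm detection and phase statistics

Rhythmicity is decided per gene by AIC model selection between the flat
model y = m and the single 24-h harmonic
y = m + a·cos(2πt/24) + b·sin(2πt/24), fitted by least squares on
log2(RPKM + 0.05) with both replicates entering as independent observations.
The model space is deliberately restricted to the fundamental harmonic; with
12 distinct timepoints this is the robust choice and higher harmonics would
mostly fit noise. The peak phase is φ = (24/2π)·atan2(b, a) mod 24 and the
peak-to-trough fold change 2^(2√(a²+b²)) (values are log2, so √(a²+b²) is
the log2 half-amplitude). A gene is rhythmic when the harmonic AIC is lower
**and** the fold reaches 1.5. Numerically, the Gaussian AIC is computed from
the residual sum of squares floored at n·10⁻²⁰ so noiseless series stay
finite, and a constant series — perfect under both models — resolves to the
flat model through the parameter penalty. On noiseless planted cosines the
estimator is exact: phase to within floating-point error (tests require
±0.25 h at any phase) and fold exactly 2^(2A).

Phase differences (RPF peak − RNA peak) are wrapped into (−12, 12] with the
boundary mapping to +12; negative values mean footprints peak before mRNA.
Two lag distributions are compared by a permutation test whose statistic is
the two-sample Kolmogorov–Smirnov distance, with the null built by pooling
and re-splitting at the original sizes and the add-one estimator
p = (1 + #{perm ≥ obs}) / (n_perm + 1), which makes p-values valid and never
zero. Homogeneity of peak-time distributions across groups uses the
Watson–Wheeler rank-based circular test (angles h·2π/24, average circular
ranks on ties, χ² with 2(k−1) df). Cross-correlation of the
replicate-averaged RPF profile against the RNA profile uses overall means
and population SDs with truncation at the series ends (a circular variant is
available behind a flag); with RPF as the shifted series, negative lags
correspond to RPF leading RNA, and planted −2/−4/−6 h lags are recovered as
the argmax lag on noiseless profiles.

The screen for genes rhythmic in translation only — a defined substitute for
model-based translational-rhythm detection — requires (i) RPF called
rhythmic, (ii) RNA not rhythmic and RNA fold below the amplitude gate, and
(iii) TE varying across the 12 ZT groups by Kruskal–Wallis at BH FDR < α
(default 0.05). Condition (iii) plays the role of a dedicated
rhythmic-translation model by demanding significant time-dependent TE
variation rather than merely a rhythmic-looking footprint fit. Note that
with 2 replicates per ZT the Kruskal–Wallis p-value cannot go below ≈ 0.02,
which bounds the resolution of condition (iii) at this design size.

## uORF detection and translation calling

Candidate uORFs are AUG-initiated spans in the 5′UTR extending to the first
in-frame stop, retained when the coding span (AUG through the last codon
before the stop, boundary included) is at least 18 nt. A uORF without an
in-frame stop before the CDS overlaps the CDS: in the same frame it is
discarded; in a different frame it is kept but only its 5′UTR-specific part
is countable. Overlapping uORFs on one 5′UTR are merged into a composite
counting unit spanning their union, with the 5′-most AUG defining the frame.
A-site positions are footprint 5′ ends plus a length-dependent offset
(default +14 nt for 26–30 nt reads, +15 nt for 31–35 nt; the table is
config-exposed since protocols differ). A uORF is called translated when the
A-sites in its countable span show significant bias toward its frame
(one-sided exact binomial, k frame-0 A-sites out of n against rate ⅓,
α = 0.05) **and** more than 10% of countable positions carry at least one
A-site. Coverage is counted at single-nucleotide resolution by default
(per-codon behind a flag; the choice matters because an all-frame-0 signal
can cover at most ⅓ of nucleotide positions). The calling is monotone:
adding frame-0 reads can only move a record toward a translated call. uORF
TE divides span RPF by span RNA counts, each scaled by its effective library
size.

## Isoform divergence, Kozak context and transcript features

A gene's isoform usage in two organs is compared by the Hellinger distance
H = (1/√2)·√Σᵢ(√p_L^i − √p_K^i)² over its protein-coding isoform proportion
vectors, built on the shared transcript universe (absent isoform ⇒ 0). H is
0 exactly for identical usage and 1 exactly for disjoint support; it is a
bounded metric (symmetry and the triangle inequality are property-tested).
Feature attribution compares the 5′UTR/CDS/3′UTR sequences of all expressed
isoforms: `5'UTR-only` (CDS and 3′UTR identical), `CDS-only`, `3'UTR-only`,
`5'UTR-identical` (5′UTR shared, CDS and/or 3′UTR differ), `identical-set`,
or `mixed`. Kozak contexts are scored against GccA/GccAUGG: +3 for the
highly conserved positions (G at −6, A/G at −3, G at +4), +1 for the common
C at −5, −4, −2, −1, maximum 13; when the 5′UTR is shorter than 6 nt the
missing positions are padded and score 0 (scoring stays on the transcript
sequence). The feature table reports lengths and GC per region and accepts
an externally computed 5′UTR minimum-free-energy column; structure
prediction itself is out of scope.

## Profile clustering

For each gene of interest the 4×4 matrix of Euclidean distances between its
four replicate-averaged 12-point log2 time courses (kidney/liver ×
RNA/RPF) is computed; matrices are fused as an elementwise weighted mean
(weights default to equal — the natural uninformative choice since no
weighting scheme is prescribed — and are caller-settable), and the fused
matrix is clustered by average linkage. Profiles are log2(RPKM + 0.05)
without standardisation by default (a z-score flag exists), so mesor
differences contribute to the distances — intentionally, since cross-organ
level convergence is part of the compensation signal. Agglomeration ties
are broken by lexicographic leaf label, making the tree deterministic.

# The synthetic-data generator

`simulation_config()` / `simulate_dataset()` emulate the study with known
ground truth. Per gene g, organ o and time t the RNA log2 abundance is

> m_g ± Δ_g/2 + A_g·cos(2π(t − φ_g)/24)

and the RPF log2 abundance adds the log2 TE: an organ-shared baseline, an
organ shift anticorrelated with the RNA shift, and — for RNA-rhythmic
genes — the same oscillation phase-shifted by the organ's planted RPF−RNA
lag. Mean counts are scaled per library to a total drawn from
`library_size_range` (exercising normalization) and drawn negative binomial
with a gene-shared dispersion, the field-standard overdispersion model for
sequencing counts; dispersion 0 degenerates to deterministic rounded means,
which the noiseless tests rely on. Phase lags are planted as deterministic
shifts of the cosine argument — a phenomenological stand-in for the
post-transcriptional kinetics that create such lags in vivo.

Scale defaults are fixed once from the magnitudes such dual-organ data
exhibit: baseline log2 SD 2.25 (a > 500-fold within-organ mRNA range),
cross-organ RNA log-fold SD 1.75 (95% of genes within a ~114-fold ratio
range), cross-organ TE log-fold SD 0.40 (95% within threefold), within-organ
TE baseline SD 0.85 (about a tenfold TE range), compensation correlation
−0.6, 10% RNA-rhythmic and 2% TE-rhythmic genes, planted log2
half-amplitudes 0.3–1.0, kidney RPF−RNA lag −2 h (liver 0). With these
values the emitted data reproduce cross-organ Spearman correlations near
0.73 (RNA) and 0.79 (RPF) without further adjustment. The NB dispersion
default of 0.02 is a calibration choice — no quantitative noise magnitude is
prescribed by the design — and tests that depend on noise level set it
explicitly.

Sequences are generated with constrained alphabets so ground truth is exact:
5′UTR filler and uORF bodies use adenine-free codons (no AUG and no stop can
arise in any frame, including across codon boundaries), planted uORFs are
AUG + body + TAG, and CDSs are AUG + sense codons + stop. This makes the
planted uORF the only uORF on the transcript, at the cost of unrealistic
UTR base composition — acceptable because no downstream statistic depends on
UTR composition beyond AUG/stop placement. Footprints are placed so that a
configurable fraction `f_frame` (default 0.85) of A-sites falls in frame 0
of the CDS and of each planted translated uORF; non-translated uORFs get
sparse frame-uniform or zero coverage. Multi-isoform genes (20% by default)
carry 2–3 isoforms differing in 5′UTR length, with organ proportion vectors
whose divergence increases with the gene's TE organ shift
(`isoform_te_coupling`), so the association between isoform divergence and
differential TE is plantable.

What the generator does **not** emulate: alignment artefacts, rRNA
contamination, position-dependent coverage biases, length-dependent TE,
realistic UTR base composition, isoform diversity beyond 5′UTR variation,
and gene-specific dispersions. Passing tests therefore demonstrate the
statistical machinery is correct under the stated generative model, not that
the thresholds are optimal for any particular real dataset.

# Numerical choices and problem sizes

Determinism: a single seed drives each simulated dataset; footprint
simulation derives its stream from seed + 1; rerunning any configuration is
byte-identical. The permutation test seeds its own stream when asked.
Degenerate inputs are defined, not accidental: constant series select the
flat model; zero-variance profiles make cross-correlation NA with a
warning; zero A-sites give an NA frame-bias p and a negative translation
call; all-zero libraries and invalid proportion vectors are errors.

The shipped tests and the acceptance script run simulations of 150–2000
genes — large enough that decile binning, FDR calibration (≤ 2% null calls),
power (≥ 80% sensitivity for 2-fold TE shifts at dispersion 0.05), rhythm
recovery (≥ 90% sensitivity for half-amplitudes ≥ 0.5) and the clustering
topologies are stable, while a full run stays in the minutes range on one
core. The clustering acceptance scenario sets the TE organ-shift scale equal
to the RNA scale with ρ = −0.95: compensation can only cancel RNA divergence
in the footprint profiles when the TE effect has comparable magnitude, so
this is the regime in which the "RPF profiles merge first across organs"
topology is the planted truth; with ρ = 0 at default scales the within-organ
RNA/RPF pair is closest instead.

# Known limitations

- The rhythm model space is flat-vs-fundamental only; ultradian or
  multi-harmonic shapes are declared non-goals.
- The translation-only screen is a defined substitute, not a reimplementation
  of a joint RPF/RNA generative model, and its third condition is resolution-
  limited at 2 replicates per timepoint.
- Isoform proportions are consumed as input; isoform abundance estimation is
  upstream and out of scope, as are structure prediction, miRNA-site and
  GO-term analyses.
- Non-AUG uORF initiation is not considered, biasing uORF counts downward.
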