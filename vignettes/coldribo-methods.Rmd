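---
title: "Methods: quantifying ribosome complexes, riboproteome composition and cold-acclimation transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying ribosome complexes, riboproteome composition and cold-acclimation transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldribo)
```

`coldribo` analyses three data layers of a cold-acclimation study of plant
ribosome biogenesis: sucrose-gradient absorbance profiles, fraction-wise
riboproteome LFQ tables, and expression matrices. This vignette describes
the models and procedures, the parameters that matter, the numerical
choices, and what the synthetic generators do and do not emulate.

## 1. Gradient profiles

### Model

An A254 trace is an ordered series of (position, absorbance) pairs along
one gradient. Positions are normalized to [0, 1] with 0 at the gradient top
(low sucrose), so complexes appear in sedimentation order
40S < 60S < 80S < polysomes. Each centrifugation run carries a non-sample
control gradient whose trace captures the sucrose/buffer baseline; analysis
always starts by interpolating that blank linearly onto the sample grid and
subtracting it. Traces from different runs are compared only after each has
been corrected by its own run's blank.

Peak regions are delimited by valley detection: the boundary between two
adjacent complexes is the absorbance minimum between their expected centre
("anchor") positions. The anchor positions are configuration, because peak
positions drift slightly between runs; in practice they are read off a
wild-type profile or auto-located as the tallest local maxima in expected
order. For a flat stretch (no distinct valley) the tie-break is the anchor
midpoint. Everything denser than the 80S right boundary is the polysome
region, up to the configured trace end; the reported `total` is the sum of
the 40S, 60S, 80S and polysome areas. Whether a printed "total" should stop
at the low-oligomer peaks is ambiguous in practice; this package includes
the full region beyond 80S and documents that choice here.

Areas are trapezoidal integrals over each region. Negative post-subtraction
absorbance is clipped to 0 before integration because areas are physical
quantities; by default no clipping is applied to the corrected trace itself
(`floor = NULL` in `subtract_blank()`), so the clipping decision sits at the
integration step only. On a planted Gaussian of amplitude $A$ and width
$\sigma$ the closed-form area is $A\sigma\sqrt{2\pi}$; the pipeline recovers
planted areas within 2% when recording noise is at or below 1% of the peak
amplitude. Residual error comes from region truncation (Gaussian tails
falling outside the valley boundaries) and baseline noise, not from the
integration rule.

Comparisons between genotypes are log2 ratios of areas at the same
timepoint, which makes the table antisymmetric under swapping mutant and
reference; a zero reference area yields a flagged undefined entry rather
than a silently dropped row. Correlations between complexes across all
(mutant, timepoint) measurements use Pearson's r, assuming a linear trend.
KCl sensitivity of the monosome pool is
$(a_{80S}^{200\,mM} - a_{80S}^{400\,mM}) / a_{80S}^{200\,mM}$ on paired
technical replicates, with the sign contract that a KCl-sensitive
(non-translating) pool loses 80S while 40S and 60S gain. Half-mer shoulders
between the 80S and first polysome peak are flagged qualitatively only
(`flag_halfmer()`); no attempt is made to quantify them.

Equal-material loading (fresh weight) is assumed to have happened upstream;
the module never rescales one sample to another.

### Key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `anchors` | 0.20 / 0.32 / 0.47 / 0.63 | gradient position | centres of the default synthetic peaks; supply per-run values for real data |
| `noise_sd` | 0.002 | absorbance | ~0.2% of the 80S amplitude, typical of a clean detector |
| `floor` | none | absorbance | keep the corrected trace honest; clip only at integration |
| `n_points` | 400 | — | ~10 points per peak width, matching a continuous recorder downsampled to ~40 fractions |

## 2. Riboproteome composition

### Fraction identity

Sampled fractions are aligned by content, not position: each fraction is
scored by its summed LFQ abundances of 40S, 60S and organellar 30S/50S RPs
and by pre-60S marker content (the eIF6A/TIF6 and NMD3 homolog entries of
the annotation catalog). Labels (30S/40S, 50S, 60S, 60S/80S, polysome) are
assigned by a dynamic program that maximizes the summed class-profile score
subject to sedimentation order: labels are non-decreasing in fraction
index, each non-polysome label is used at most once, and any fraction past
the 60S/80S region is polysome. Fractions holding a marker's abundance
maximum are eligible only for the 60S and 60S/80S labels, since those
markers ride on immature pre-60S particles. A table without any detected
RPs is an error, not a guess.

### Normalization, filtering, calling

Compositional normalization divides each protein's abundance in a fraction
by the summed abundance of the reference RP class detected there (60S RPs
for the 60S/60S-80S fractions, 40S RPs for the 30S/40S fraction), so
reference shares sum to 1 per fraction and every downstream call is
invariant to per-fraction rescaling. 40S RPs are excluded from the 60S
compartment and vice versa. Combining the 60S and 60S/80S fractions uses
the mean of the two normalized shares, with absence in one fraction
contributing 0 and the divisor kept at 2 — a sum would double-weight
proteins detected in both fractions. This choice is deliberate and
switchable in code; a per-fraction comparison is the natural alternative.

Because compositional normalization can make co-purified proteins look like
complex components, a change is only considered when the *non-normalized*
abundance peaks where the complex sediments: for the 60S compartment the
raw-abundance maximum must lie in the 60S or 60S/80S fraction (ties resolve
against inclusion), and for the 40S compartment the protein must be
strictly more abundant in the 30S/40S than in the 60S fraction. In the 40S
report, organellar RPs and a configurable contaminant list are additionally
excluded (they co-purify without being complex components), while eIF3
subunits are retained as genuine 43S preinitiation constituents.

Detection is binary at LFQ > 0: presence in the mutant with absence in the
wild type is accumulation (`+`), the reverse is decrease (`−`), and doubly
detected proteins get a log2 fold change classified at |log2-FC| = 1
(strong/weak, up/down; the exact-zero boundary is classed `weak_up` by
convention). No statistical test is applied in this module — selection is
purely the shared-direction rule: a change is reported when both paired
experiments agree in direction at 10 °C, and in the stringent mode also at
20 °C with the same direction as in the cold. A numeric call with log2-FC
exactly 0 has no direction and never enters shared selection; this matters
only for noise-free synthetic data, where unchanged proteins would
otherwise be counted as changes.

One consequence of compositional closure is worth noting: planting (or
observing) a change in a reference-class RP changes the reference sum and
therefore genuinely shifts every other protein's share in that fraction.
Exactness tests for planted-truth recovery therefore plant effects on
non-reference-class proteins (biogenesis factors, eIF3 subunits,
contaminants); effects on reference RPs are still recovered in direction,
but they are never side-effect-free.

### Transcript association

Protein calls and gene-level differential expression join on the gene
model; unmatched rows from either side are retained with a null partner.
Concordance requires matching direction and transcript P < 0.05. Note that
protein entries without paralog-specific peptide evidence are family-level
calls, so a one-to-one transcript match is not always meaningful — the join
keeps them, flagged by the catalog's `paralog_specific` column.

## 3. Transcriptome statistics

Expression values are treated as log2 after quantile normalization (a flag
handles linear input). Quantile normalization delegates to
`limma::normalizeQuantiles(ties = TRUE)`: rank r in every column is
replaced by the mean of the columns' r-th order statistics, ties sharing
the mean of the quantile means they span; the operation is idempotent.
Redundant probes are averaged per gene before enrichment analyses.

Differential expression per condition is the difference of group means with
the Welch (heteroscedastic) test. Welch is the right choice when replicate
variances differ between genotypes, but at n = 3 per group it is genuinely
conservative: the Welch–Satterthwaite approximation yields an empirical
type-I error of ≈ 0.034 at a nominal α = 0.05 (measured here with 2 × 10^5
null replicates; n = 4 gives ≈ 0.041, n = 5 ≈ 0.044). Calibration tests
that expect the nominal rate at n = 3 will therefore flag it; downstream
screens built on P < 0.05 are slightly conservative, not anti-conservative.

The two-factor genotype × time ANOVA uses type-II sums of squares
(`car::Anova`); with the balanced 3 genotypes × 3 timepoints × 3 replicates
design, types I/II/III coincide, so the choice is immaterial there. The
degenerate all-equal response returns F = 0, P = 1 rather than NaN.

PAGE compares a gene set's mean log2-FC $\bar S_m$ against the global
distribution: $z = (\bar S_m - \mu)\sqrt{m}/\delta$. Sets need at least 10
genes present in the fold-change vector; smaller sets are skipped with a
note. P values are two-sided by default because both activation and
repression are of interest; the original method's one-sided variant is
available (`sided = "one"`). FDR adjustment (Benjamini–Hochberg) is applied
across all tested sets within one condition, matching per-condition
significance marking; significance is adjusted P < 0.05. A planted shift of
+0.5 log2 in a 50-gene set at global SD 1 yields an expected z near
$0.5\sqrt{50} \approx 3.54$; the mean over simulations sits slightly below
(≈ 3.43) because the planted genes themselves pull the global mean up and
widen δ — an inherent property of the statistic, not an implementation
artifact.

The constitutive screen selects genes with P < 0.05 *and* a consistent
fold-change direction in every one of the six comparisons (two mutant
genotypes × three timepoints). The direction requirement is deliberate:
"constitutively accumulated" implies one sign throughout, and dropping it
would admit genes that flip direction while staying individually
significant.

## 4. What the synthetic generators emulate — and what they do not

The generators define the study conditions used by the tests:

- **Traces** are Gaussian mixtures over a linearly drifting baseline with
  additive Gaussian recording noise; the blank shares the baseline with
  independent noise. The study-level generator
  (`simulate_profile_study()`) plants multiplicative amplitude effects per
  genotype × timepoint emulating the characteristic pattern: roughly
  two-fold 40S/60S over-accumulation before cold shift, relaxation at day
  1, re-accumulation later, strong (up to four-fold) 80S depletion in
  double mutants in the cold, with log-normal jitter (SD 0.15 log2 units)
  for gradient-to-gradient variation. Real traces additionally contain
  asymmetric peaks, half-mer shoulders, detector drift and fraction-pump
  artifacts, none of which are simulated — so passing tests demonstrate
  correctness of the integration rules, not robustness to every
  real-world trace pathology.
- **LFQ tables** draw per-protein base abundances from a log-normal
  (median 10^7 LFQ units, GSD e), spread across six fractions by smooth
  per-class profiles, apply planted multiplicative mutant effects
  (including 0 = absent and ∞ = mutant-only), multiplicative log-normal
  noise (CV 0.2 by default), and hard censoring to 0 below a detection
  threshold. Real LFQ data have peptide-level missingness, shared-peptide
  ambiguity and intensity-dependent variance, which are not simulated;
  the generator's censoring is value-thresholded, which is the dominant
  mechanism but not the only one.
- **Expression matrices** are gene baselines plus a shared cold response
  (SD 0.5 log2 at cold timepoints), planted gene-set shifts, planted
  constitutive effects, and i.i.d. residual noise (SD 0.25 log2 — typical
  between-replicate scatter for arrays after normalization). Probe-level
  redundancy shares the gene signal. Array-specific intensity biases and
  probe cross-hybridization are not simulated; the quantile-normalization
  test surface is therefore about the algorithm, not about rescuing bad
  arrays.

Problem sizes in the shipped tests and acceptance script — 400-point
traces, a 25-pair profile study, an ~80-protein catalog over six fractions,
1,500–2,000 genes with 10–10,000 simulated sets, 10^4 null replicates for
calibration — were chosen as the smallest sizes at which the planted
effects are comfortably identifiable and Monte-Carlo error is well below
the tested tolerances.

## 5. Known limitations

- The packaged annotation catalog covers only the proteins named in the
  underlying figures; real analyses need a complete RP family/paralog
  catalog supplied by the user.
- Fraction identity assignment assumes the sampled fractions actually span
  the 30S/40S → polysome range; a table of, say, two polysome cuts will be
  labeled by best effort.
- Shared-change selection is a direction rule without error control, by
  design; it inherits the false-positive behaviour of presence/absence
  coding near the detection limit.
- Welch calibration at n = 3 is conservative (see above).
- The pipeline performs relative quantification only; no molar units, no
  polysome-to-monosome interpretation.
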