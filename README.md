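# coldribo

Quantitative analysis of plant ribosome biogenesis during cold acclimation.

When *Arabidopsis* seedlings are shifted into the cold, ribosome biogenesis
mutants (such as double knockouts of the cytosolic maturation factors of the
REIL family) reorganize their pools of ribosome complexes: free 40S and 60S
subunits over-accumulate, non-translating 80S monosomes are depleted, and
immature pre-60S particles carrying maturation factors (eIF6A/TIF6 and NMD3
homologs) build up in the non-translating fractions. `coldribo` implements
the quantitative core of this kind of study as a tested, reusable pipeline
for three data layers:

1. **Gradient profiles** — A254 absorbance traces from sucrose density
   gradients: blank (non-sample control) subtraction, valley-based peak
   segmentation at anchor positions, trapezoidal peak integration, log2
   fold changes of complex abundances versus wild type, inter-complex
   Pearson correlations, and the KCl-sensitivity of the 80S monosome pool
   (non-translating monosomes dissociate into subunits at 400 mM KCl).
2. **Riboproteomes** — protein × fraction LFQ tables of non-translating
   40S/60S fractions: fraction identity assignment from ribosomal-protein
   (RP) class sums and pre-60S markers, compositional normalization to the
   summed 60S (or 40S) RP abundance per fraction, an abundance-maximum
   filter against co-purification artifacts, presence/absence (`+` / `−`)
   and log2-FC change calling with classification at |log2-FC| = 1, and
   selection of changes shared between two paired experiments (optionally
   at both growth temperatures).
3. **Transcriptomes** — probe × sample expression matrices: quantile
   normalization, probe averaging, Welch (heteroscedastic) tests, two-factor
   genotype × time ANOVA, parametric gene set enrichment (PAGE) with
   Benjamini–Hochberg FDR, and a screen for constitutive changes
   (P < 0.05 with consistent direction in both mutants at every timepoint).

A synthetic-data generator plants known ground truth (peak areas, paralog
shifts, biogenesis-factor accumulation, detection-limit censoring, gene-set
shifts, constitutive genes) so every stage is testable without downloads.
It is intended for researchers analysing polysome profiles and
fraction-resolved ribo-proteomes, and as a transparent reference
implementation of the analysis rules above.

## The core statistics

- Peak areas: a complex's abundance is the trapezoidal integral of the
  background-corrected trace over its valley-delimited interval; a planted
  Gaussian peak of amplitude *A* and width *σ* has closed-form area
  *A·σ·√(2π)*, which the pipeline recovers within 2% at 1% recording noise.
- Compositional shares: within each fraction, protein abundance is divided
  by the summed abundance of the reference RP class, so the reference
  shares sum to 1 and calls are invariant to per-fraction rescaling.
- PAGE: for a gene set of size *m* with mean log2-FC *S̄*, against a global
  fold-change mean *μ* and SD *δ*, the enrichment statistic is
  *z = (S̄ − μ)·√m / δ*, with normal P values (two-sided by default) and
  BH-FDR across all tested sets (minimum set size 10, significance at
  adjusted P < 0.05).

## Worked example

```r
library(coldribo)

# a synthetic wild-type gradient trace with known peak areas
g <- generate_trace(trace_config(seed = 42), label = "wild-type")
corrected <- subtract_blank(g$sample, g$blank)
anchors <- c("40S" = 0.20, "60S" = 0.32, "80S" = 0.47, "polysome" = 0.63)
areas <- integrate_complexes(corrected, segment_peaks(corrected, anchors))
print(areas, digits = 3)
#>      sample  complex   area
#> 1 wild-type      40S 0.0178
#> 2 wild-type      60S 0.0302
#> 3 wild-type      80S 0.0627
#> 4 wild-type polysome 0.0377
#> 5 wild-type    total 0.1483

# a cold-shifted double mutant: subunits doubled, 80S depleted
mut <- generate_trace(trace_config(peaks = within(trace_config()$peaks,
         amplitude <- amplitude * c(2, 2, 0.3, 0.8, 0.8)), seed = 43), "dko 1d")
mcorr <- subtract_blank(mut$sample, mut$blank)
mareas <- integrate_complexes(mcorr, segment_peaks(mcorr, anchors))
print(relative_abundance(mareas, areas), digits = 3)
#>    complex log2_fc undefined
#> 1      40S  0.9900     FALSE
#> 2      60S  1.0044     FALSE
#> 3      80S -1.7400     FALSE
#> 4 polysome -0.3260     FALSE
#> 5    total -0.0353     FALSE
```

The log2 fold changes recover the planted effects: the doubled free
subunits read out as FC ≈ +1 ("two-fold"), the depleted monosome pool as a
strong negative FC, while the total stays near wild type.

The full pipeline (profiles, riboproteome, transcriptome) runs from one
seed with `run_pipeline(list(seed = 1), "out/")`, writing provenance-headed
TSVs and a JSON run report.

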