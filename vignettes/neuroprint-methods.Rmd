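---
title: "Twin heritability and transcriptomic decoding of brain-fingerprints: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin heritability and transcriptomic decoding of brain-fingerprints: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroprint)
```

## Scope

`neuroprint` implements an inference chain for studying the genetic basis
of individual variability in resting-state neurophysiology:

1. **Brain-fingerprinting.** Per-subject spectral profiles (power spectral
   density across cortical parcels and frequency bins) are compared across
   recording sessions by Pearson correlation; a subject is *differentiated*
   when their own other-session profile is their nearest match, and twin
   siblings are *matched* when each other's profiles are mutually nearest
   among all other participants.
2. **Saliency and heritability maps.** One-way intraclass correlation
   (ICC) over subjects × sessions quantifies, per parcel and frequency
   band, how stable a trait is within a person relative to the cohort;
   Falconer's formula \(H^2 = 2\,(r_{MZ} - r_{DZ})\) applied to cross-twin
   cross-session correlations gives a genetic-contribution map, with
   significance from zygosity-label permutations.
3. **Transcriptomic decoding.** Partial least squares (PLS) correlation
   between parcel-wise gene expression and the band-wise ICC map, with
   spatial-autocorrelation-preserving spin permutations for significance,
   bootstrap intervals, distance-based cross-validation, cell-type gene-set
   enrichment, and developmental gene-score trajectories.

Every stage is validated by parameter recovery on synthetic cohorts with
planted ground truth; the generator is a first-class part of the package.

## The twin model in the generator

For subject \(s\), parcel \(p\) and frequency bin \(f\), `simulateProfiles()`
draws the latent trait

\[
T_{spf} = \sqrt{h^2}\,g + \sqrt{c^2}\,c + \sqrt{1 - h^2 - c^2}\,e ,
\]

where monozygotic co-twins share \(g\) exactly, dizygotic co-twins share it
with correlation \(0.5\) (bivariate construction, which makes Falconer
recovery exact in expectation), pair members share \(c\), and \(e\) is
unique. Observed power is

\[
y_{stpf} = b_f + A_{pf}\,T_{spf} + \sigma_{ses}\,\varepsilon_{stpf},
\qquad
A_{pf} = \max\!\big(0.2,\; 1 + w_{b(f)}\,\ell_p\big),
\]

with a 1/f-like baseline \(b_f\) shared by all subjects, session noise
\(\sigma_{ses}\) (default 0.3 relative to unit trait variance — spectral
profiles are empirically very stable across sessions), and an amplitude
surface \(A\) that embeds the planted cortical gradient \(\ell\) (zero
mean, unit variance, spatially smooth) weighted per band by \(w\). The
expected cross-twin correlations are
\(r_{MZ} = (h^2+c^2)\,a\) and \(r_{DZ} = (h^2/2+c^2)\,a\) with attenuation
\(a = A^2/(A^2+\sigma_{ses}^2)\), so \(2(r_{MZ}-r_{DZ}) \to h^2 a\). The
same amplitude surface makes the ICC saliency map and the heritability map
spatially coupled, as both increase with \(A\).

**Global trait factors.** A fraction (default 0.7) of the trait variance is
routed through a small number (default 8) of global factors — smooth
patterns over frequency and cortex, each with the same \(h^2/c^2\)
decomposition. Real spectral profiles are dominated by a few subject-level
factors (overall power, alpha-peak amplitude, spectral slope); without
them, an independent-features model concentrates between-subject profile
correlations so sharply that twin matching saturates at 100% for both
zygosities. With the factor structure, MZ matching is high, DZ matching
low, and randomly paired unrelated subjects match at about 1–2% — the
qualitative regime observed in real twin cohorts. Per-feature twin
correlations, and hence Falconer algebra, are unchanged by construction.

**Band weights.** The default planted band weights
`c(0.10, 0.15, 0.50, 0.40, 0.25, 0.15)` are all positive with alpha/beta
dominant: trait-variance gradients in real cohorts are co-oriented across
bands and strongest in the alpha/beta range. (With mixed-sign weights the
ICC map's band gradients can anti-orient the recovered PLS signature,
because narrow bands average fewer bins and are noisier, hence carry
*steeper* ICC gradients than their amplitude weight suggests; a planted
directional developmental trend would then be ill-posed.)

**Mock noise profiles.** `simulateNoiseProfiles()` emulates empty-room
control recordings: session-varying source spectra shared by all subjects
pass through a participant-specific mixing across parcels (squared, to a
power-like quantity). The mixing is largely redrawn per session
(`mixInstability = 0.85`), leaving only weak subject-specific structure:
differentiation from mock profiles stays above the exact \(1/N\) floor but
around 4–8%, an order of magnitude below planted profiles, at both the
20-parcel test scale and the 200-parcel study scale. Setting
`mixInstability = 1` yields exactly session-independent profiles, the
clean chance-floor condition.

## Atlas geometry and the spin null

`makeAtlas()` produces a bilateral parcellation in *spherical-registration*
coordinates: each hemisphere occupies a full unit sphere (as in
surface-based registration), with the right hemisphere stored mirrored
into register so that homotopic parcels nearly coincide on the common
reference sphere. All spatial kernels, parcel distances and spin rotations
act on these coordinates. This matters for the spin test: rotations of a
full sphere have no boundary, so the Hungarian reassignment of rotated to
original parcels displaces each parcel by about half the inter-parcel
spacing. If hemispheres occupied half-spheres instead, rotations would
push parcels across the hemispheric boundary and the reassignment would
destroy map smoothness, making the null anti-conservative.

Two practical consequences, verified by the calibration tests:

- Spin p-values are well calibrated for *differentiable* (Gaussian-kernel)
  fields whose autocorrelation length is comfortably above the parcel
  spacing; `simulateSmoothMaps()` (default Gaussian kernel, length 0.6 in
  chord distance) generates such fields for calibration studies.
- Calibration improves with parcel density. At 200 parcels the pairwise
  spin test runs marginally liberal (≈7% rejection at the 5% level over
  many map pairs); at 400 parcels it is within the binomial band of the
  nominal level. This resolution-dependence is intrinsic to parcel-level
  spin tests, not specific to this implementation.

Rotations are drawn exactly uniformly (QR of a Gaussian matrix with sign
fix and determinant +1); the assignment minimises total chord distance via
the Hungarian algorithm (`clue::solve_LSAP`).

## Spectral profiles

`welchPsd()` averages Hann-tapered, mean-removed, 50%-overlapping segment
periodograms; with the default 2-s window the grid has 0.5 Hz resolution,
giving the canonical 301-bin 0–150 Hz profile. Returned values are power
per bin, so the summed spectrum of a zero-mean series approximates its
variance. Band membership is half-open \([lo, hi)\), so the six canonical
bands (delta 1–4, theta 4–8, alpha 8–13, beta 13–30, gamma 30–50, high
gamma 50–150 Hz) partition the 1–150 Hz axis; a band whose upper edge
equals the top of the grid includes that edge, which makes the
concatenated band bins exactly the broadband bin set (299 of the 301
bins — DC and 0.5 Hz are outside every band).

Fingerprinting uses per-bin features (the full band-limited profile);
cortical ICC and heritability maps use band means (one value per parcel
and band). Power is used in linear units; a log transform is deliberately
not applied by default.

## Estimators and conventions

- **ICC**: one-way random-effects ICC(1),
  \((MS_B - MS_W)/(MS_B + (k-1)MS_W)\). Twin-aware saliency maps average
  the ICC over 100 random subsamples keeping one twin per pair; on
  twin-free cohorts the subsample mean is the full-cohort map by
  construction.
- **Cross-twin correlation**: all 3×3 session pairings per pair are pooled
  and double-entered (both twin orderings), removing twin-order
  arbitrariness; the default estimator is Pearson on the pooled pairings,
  with a one-way ANOVA-ICC variant (pairs as groups) available — the two
  produce near-identical heritability maps.
- **Falconer estimates** are clipped to \([0, 1]\) for mapping; raw values
  are preserved, since sampling noise at realistic pair counts routinely
  crosses the bounds. Permutation significance shuffles zygosity labels
  across pairs, preserving pair structure; p-values carry the +1
  correction and are BH-FDR adjusted across parcels within band.
- **Ties** in any nearest-neighbour argmax count as failures
  (conservative); exact ties occur with probability zero for continuous
  data but matter for degenerate inputs.
- **PLS**: columns z-scored; \(\mathrm{Cov} = X_z^\top Y_z/(n-1)\)
  decomposed by SVD. Each component's score covariance equals its singular
  value and is therefore non-negative automatically; the remaining joint
  sign indeterminacy is fixed by requiring a non-negative sum of the
  Y-weight vector (falling back to a positive largest-magnitude entry when
  the sum is zero), which keeps the recovered signature orientation stable
  across refits and permutations. Loadings are Pearson correlations of
  each variable's parcel map with the *opposite* block's score pattern.
  Out-of-sample projection in the distance-based cross-validation uses
  training-set means and standard deviations only (no leakage); only
  component 1 is cross-validated and carried downstream.
- **Enrichment**: two-tailed permutation p-values are twice the smaller
  tail probability, capped at 1, with the +1 correction; being discrete
  and tie-inclusive they are conservative at small set sizes. The
  background is the set of genes that entered the PLS after the
  differential-stability filter (default cutoff 0.1).
- **Developmental slopes**: ordinary least squares against equally spaced
  integer stage indices; the default test is one-tailed (directional
  strengthening), with a two-tailed variant by flag. The null refits the
  PLS on spin-permuted trait maps and propagates the null gene weights
  through the same projection.

## Expression generator

`simulateExpression()` plants a rank-1 gene–gradient signal
(`geneWeights ⊗ latentMap`) plus, by default, eight donor-shared nuisance
gradients (smooth cortical map × random gene weights, total sd 0.7):
cortical transcriptomes contain many competing spatial gradients, and
without them the planted direction is so dominant that even spin-permuted
trait maps recover it, degenerating the developmental null. Donor noise is
a half-spatial (exponential kernel, length 0.3), half-white mixture with
marginal sd 0.5 per donor; six donors are averaged, and differential
stability (mean pairwise Spearman correlation of regional profiles across
donors) is computed per gene. With zero noise all donors are identical
and every gene's stability is exactly 1.

A note on recovery: through the full chain (profiles → ICC → PLS), the
planted *gene* weights are recovered with correlation above 0.9, but the
planted *band* weights only weakly (≈0.5) — ICC is a saturating, nonlinear
function of the planted amplitude, and narrower bands have noisier band
means. Band-weight recovery is therefore assessed on directly constructed
rank-1 trait maps, and through the chain the loadings' sign structure is
what is checked.

## Problem sizes

The test-suite and the acceptance script run at sizes chosen to make the
Monte Carlo assertions stable while keeping a laptop-scale footprint: a
200-parcel atlas with the 89-subject reference cohort (17 MZ pairs, 11 DZ
pairs, 33 unrelated) and 1000 genes for the end-to-end chain; 100+100
pairs at 10 parcels for Falconer recovery; 400 parcels for the spin-test
calibration study; 200–500 spins and permutations per null. Structural
unit tests use a reduced 61-bin frequency grid where the 301-bin grid is
not the point.

## What the synthetic data do and do not establish

The generator emulates: twin-structured trait covariance with
session-stable traits, global spectral factors, spatially autocorrelated
cortical maps, a planted low-rank gene–trait covariance with nuisance
gradients, planted cell-type enrichment and developmental slopes, and weak
participant-specific structure in noise controls. It does not emulate MEG
physics (no forward model, beamforming or sensor noise), donor-level
microarray probe structure, realistic gene–gene co-expression beyond
low-rank gradients, unevenly spaced developmental stages, or age/sex
structure in the cohort. Passing recovery tests therefore establishes
correctness of the estimators and calibration of the null procedures under
the stated generative assumptions — not that real MEG or expression data
satisfy those assumptions. Headline numbers from real cohorts (e.g.
differentiation or matching percentages) are not desk-reproducible from
restricted data and are not targets of the synthetic runs.

## Known limitations

- Parcel-level spin tests are mildly liberal at coarse parcellations
  (see above); map-level conclusions at 200 parcels should treat p-values
  near the threshold with care.
- Falconer's formula is a method-of-moments estimator; no ACE/SEM
  variance-component modelling is provided, by design.
- The per-cell cross-twin correlation at realistic pair counts is noisy
  and, under the global-factor structure, spatially correlated; map means
  are unbiased but single-parcel estimates have wide sampling bands.
- The pipeline's configuration runner executes stages sequentially in one
  process; no workflow-manager integration is provided.
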