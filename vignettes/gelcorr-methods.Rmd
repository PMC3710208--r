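---
title: "Pixel-by-pixel correlation analysis of 2D gel stacks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pixel-by-pixel correlation analysis of 2D gel stacks: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Two-dimensional gel electrophoresis (2DE) separates proteins by isoelectric
point and molecular weight. A protein with many isoforms and
post-translational modifications — p53 is the canonical example — appears
not as one spot but as a chain of loosely connected spots, ladders of
ubiquitinated forms, and smears whose shapes and positions change with the
biological state. Spot-detection software struggles exactly where this
information is richest: spots appear and disappear, overlap, and deform.

gelcorr takes the complementary, pixel-based route. Given a stack of $n$
aligned and normalized gel images $I_1, \dots, I_n$ and a per-sample
external variable $v = (v_1, \dots, v_n)$ (hours after irradiation, dose,
survival, an ordered category...), it computes for every pixel coordinate
$(x, y)$ the Spearman rank correlation of the *pixel column*
$(I_1(x,y), \dots, I_n(x,y))$ with $v$. The result is an image of
correlations — a *biosignature* — showing which parts of the protein's gel
region rise or fall with the external variable, regardless of spot shape.

## The statistics

**Correlation.** $\rho(x,y)$ is the Pearson correlation of the
average-ranked (midranks for ties) pixel column against the ranked
variable. With no ties this equals $1 - 6\sum d_i^2 / (n(n^2-1))$. Rank
correlation is invariant under strictly monotone transforms of either
side, which is what makes ordered categories legitimate after encoding as
consecutive integers (any monotone encoding gives identical maps; the test
suite asserts this bit-for-bit).

**Variability.** The "variance" factor $\sigma_{\mathrm{norm}}(x,y)$ is the
per-pixel sample standard deviation (divisor $n-1$) of the *normalized*
intensities, divided by the maximum over all valid pixels, so it lies in
$[0,1]$. No standard definition exists for this quantity in the pixel-based
gel literature; this scaled-sd form was chosen because it makes the
composite products below dimensionless and bounded. A coefficient-of-
variation alternative (`kind = "cv"` / `variance_kind = "cv"`) is provided
for users who prefer relative change; it is scaled the same way.
$\sigma$ is computed *after* normalization (the order is unspecified in
prior descriptions of the method; computing it after keeps the factor
comparable across gels with different exposure).

**Significance.** Two tests are offered per pixel, both two-sided (both
activation and suppression are biologically meaningful):

* *correlation t-test*: $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ with $n-2$
  degrees of freedom;
* *permutation test*: the variable is permuted; when $n! \le$
  `exhaustive_limit` (default $8! = 40320$) all $n!$ orderings are
  enumerated and $p = \#\{|\rho_{\pi}| \ge |\rho_{\mathrm{obs}}|\}/n!$ is
  exact. Otherwise $m$ = `n_permutations` random orderings are drawn under
  the run seed and $p = (b+1)/(m+1)$, which includes the observed ordering
  and can never report zero. Midranks are recomputed per permutation, so
  ties travel with the permuted values.

The typical gel time course ($n = 5$) has only $120$ orderings, so its
permutation p-values are exact and discrete: the smallest attainable
two-sided p is $2/120 \approx 0.017$. p-values are clamped to
$[\varepsilon, 1]$ (smallest positive double) so the products below never
saturate from rounding alone. No multiple-testing correction is applied in
the core maps — each pixel carries its raw p, as the method traditionally
reports — but `adjust_pvalues()` provides a clearly-labelled
Benjamini–Hochberg q-map.

**Composite products.** With significance $s = 1 - p$ (default; the
$-\log_{10} p$ alternative is selectable but unbounded), the shipped
products are $CS = \rho s$, $CV = \rho\,\sigma_{\mathrm{norm}}$, and the
biosignature $CSD = \rho\, s\, \sigma_{\mathrm{norm}}$. The $\sigma$ factor
suppresses pixels that correlate perfectly but barely move in intensity;
the $s$ factor suppresses pixels whose correlation could easily arise by
chance.

## Normalization

Gel-to-gel intensity variability (membrane handling, exposure) is removed
per image: divide by the image mean, divide by the image median (the
default — robust to the strong-spot upper tail, and generally the most
suitable for gel images), or z-score (subtract the mean, divide by the
population standard deviation, divisor $N$; the $N$ vs $N-1$ choice is a
documented convention). Statistics are computed over *valid* pixels only,
because post-alignment off-canvas pixels would otherwise corrupt them.
Outputs are not rescaled to any grand reference — division (or centering)
only. Background correction is deliberately not implemented: no defensible
procedure is established for chemiluminescent gel images in this pipeline's
scope, and a silent heuristic would inject exactly the kind of technical
artefact the method tries to avoid.

## Alignment

Gels shift, rotate and stretch slightly between runs. Alignment is
restricted to the 4-parameter similarity family — rotation, uniform scale,
translation — deliberately excluding warping: non-rigid registration can
manufacture or destroy the local intensity changes the correlation is
supposed to detect. Conventions, fixed and tested:

* pixel coordinates are 0-based, origin top-left, $+x$ right (columns),
  $+y$ down (rows);
* the transform acts about the image center $((W-1)/2, (H-1)/2)$:
  $q = s\,R(\theta)(p - c) + c + t$, scale with rotation first, translation
  last; rotation is counter-clockwise as displayed. Any pivot/order
  convention is expressible in any other by re-parameterization; fixing one
  makes transform files portable;
* resampling is done once, by inverse mapping, bilinear by default
  (nearest-neighbor available where exactness matters);
* output pixels that sample outside the source footprint become *missing
  data* (masked), never zeros — border zeros would fabricate
  anti-correlations;
* transforms estimated on fluorescent standard images are applied
  unchanged to the signal images (same camera geometry), so that protein
  expression itself cannot bias the alignment.

`estimate_from_landmarks()` provides a headless parameter source: the
closed-form least-squares similarity fit through complex regression,
globally optimal for the landmark RMS (tested against a local grid
search). Alignment quality is inspected via exported overlay blends
(`render_overlay`, `gelcorr align-check`) instead of an interactive fade.

## The synthetic generator

Because real immunoblot stacks are not redistributable, every pipeline
stage is exercised against `synthetic_stack_spec()` stacks with known
ground truth: anisotropic Gaussian spot chains whose amplitudes are linear
in the covariate (optionally appearing/disappearing at covariate
thresholds), single-row streaks emulating ubiquitination ladders, constant
background, per-image global intensity jitter, additive Gaussian noise,
and known per-image misalignments. The `p53_timecourse` preset mimics a
5-gel irradiation time course (covariate 0, 2, 4, 6, 8 hours, 96×96
pixels): a five-spot chain whose right three spots respond strongly, a
developing high-PI "long tail", a spot appearing mid-course, weak lower
isoform spots, ladder streaks, per-gel scale jitter 0.85–1.25, noise at
about 5% of the covariate-driven amplitude range, and misalignments of up
to 2° rotation, 2% scale and ~3 px translation.

What the generator does *not* emulate — irregular spot shapes, spatially
structured background, saturation, warping-type distortions — bounds what
green tests mean: they validate the statistics and the geometry handling,
not robustness to every artefact of real membranes.

Two rendering details deserve a note:

* *Noise stage.* By default noise is added after the per-image scale
  (a fixed camera/readout floor). Under strong scale jitter such a floor
  shifts each image's median by $\approx z_q\,\sigma_{\mathrm{noise}}/s_i$,
  leaving a small monotone residual that *no* per-image rescaling can
  remove — an instructive fact about normalization, but not the regime the
  jitter demonstration is about. The `scale_jitter` preset therefore uses
  `noise_stage = "pre_scale"` (noise scales with the image), in which
  mean/median normalization cancels the jitter exactly.
* *Sample sizes and the null law of $|\rho|$.* Under independence the
  exhaustive Spearman null at $n = 5$ has $E|\rho| = 0.42$ (exact, by
  enumeration of the 120 orderings) and $0.371$ at $n = 6$. Background
  pixels of any noisy stack at $n = 5$ therefore *must* average
  $|\rho| \approx 0.42$ — a law of the statistic, not a defect of a
  pipeline. Checks of "no background correlation" consequently use the
  signed mean (near 0) plus agreement of mean $|\rho|$ with its exact null
  value; and the jitter demonstration uses $n = 24$ images (jitter
  spanning 1–16 geometrically), where
  $E|\rho| \approx \sqrt{2/\pi(n-1)} \approx 0.165$, small enough that
  "mean $|\rho| \le 0.2$ after normalization" is a meaningful bound.

## Problem sizes and determinism

The shipped tests and the acceptance script use 96×96×5 stacks for the
time-course properties, 64×64×24 for the jitter demonstration, 40×40×6
i.i.d. noise for permutation calibration (attainable-level comparison
against an independent enumeration of all 720 orderings), and 8×8×6 stacks
for oracle equivalence — sizes chosen so the whole suite runs in seconds
while keeping every estimate well inside its binomial error budget. All
randomness flows through explicit seeds; two runs of `gelcorr analyze`
with the same config and seed produce byte-identical text outputs (tested).

## Degenerate inputs and numerical choices

* Constant pixel columns (rank correlation undefined) are masked, not
  forced to 0; pixels with fewer than `min_valid` valid samples (default:
  all $n$, relaxable to 3) are masked.
* Images whose normalization scale is 0, or z-score spread is 0, raise
  errors naming the offending samples.
* Permutation-count comparisons use a $10^{-12}$ tolerance on
  $|\rho_\pi| \ge |\rho_{\mathrm{obs}}|$ so float jitter cannot drop a
  tied permutation from the count.
* 8- vs 16-bit PNGs are *not* rescaled to a common range at load (0..255
  and 0..65535 stay distinct); per-image normalization handles scale, and
  raw units remain inspectable. Color PNGs are averaged to gray with a
  logged warning.
* Map and ROI text exports print 17 significant digits, so re-imported
  values are bit-identical.

## Known limitations

* Alignment parameters must come from landmarks or files; there is no
  automatic intensity-based registration.
* The similarity family cannot correct local gel distortions — by design.
* Raw per-pixel p-values are not corrected for multiplicity in the core
  maps; use `adjust_pvalues()` when pixel-level discovery claims are made.
* With $n = 5$ samples the exact permutation p cannot go below $2/120$;
  strong claims need more samples, not more pixels.
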