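---
title: "Quantifying arrayed MYTH screens: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying arrayed MYTH screens: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mythquant)
```

## The measurement model

An arrayed MYTH screen converts protein–protein interaction strength
into colony growth. The package's quantitative model has three layers.

**Density.** The growth readout of a test-plate spot is its *density*:
the integrated above-background intensity over the spot's grid window.
We chose integration (rather than mean intensity or thresholded area)
because it is monotone in both colony footprint and opacity — matching
how growth strength is read by eye — and because it is linear: a colony
rendered with twice the true density integrates to twice the measured
value, which makes the synthetic ground-truth oracle exact. Background
is estimated per spot from the annulus between the integration disc
(radius 0.40 × pitch) and the grid cell boundary (median, so shoulder
bleed from bright neighbours is ignored), which also removes smooth
illumination gradients locally. Negative integrals clamp to zero:
densities are physically non-negative.

**Mating normalization.** Diploid colony areas measure mating success,
not interaction. Areas are extracted by a single global Otsu threshold
per diploid plate, min–max normalized over the whole screen (all plates
of one bait pooled — one normalization per screen; a per-plate mode is
available via `per_plate`), and test densities are divided by the
normalized area. The min–max map sends the smallest colony to exactly 0,
where the division is undefined; wells below `epsilon` (default 0.05)
are therefore flagged `failed_mating` and excluded from calling rather
than divided. An absolute floor (`min_area_px`, default 20 px) covers
the degenerate case in which *every* diploid is absent and min–max
normalization collapses to all-ones: absence of a diploid is a failed
mating, never evidence of no interaction.

**Calling.** The positive cutoff is the 25th percentile of the
"weak"-labeled densities from a manually categorized colony set, using
the linear-interpolation quantile convention (`stats::quantile` type 7;
the convention is not dictated by the recipe itself, so we document it
here and test the fixed example {4, 8, 12, 16} → 7). A prey is positive
when at least half of its technical-replicate spots exceed the cutoff
*strictly* — ties count as below — and `2 · n_above ≥ n_spots` is the
reading used for odd replicate counts. Reported mean densities average
*all* usable replicates, including sub-cutoff ones.

Two consequences of this calling rule are worth stating because they
bound what any implementation can achieve. First, by construction a
quarter of genuinely weak spots fall below the cutoff, so a weak prey in
quadruplicate is called with probability
P(Binomial(4, 0.75) ≥ 2) ≈ 0.949 even under perfect quantification.
Second, dividing all four replicates of a prey by one shared diploid
area correlates them, which pushes the weak-prey call rate slightly
below the binomial value. Sensitivity of the end-to-end pipeline is
therefore dominated by the weak share of the interactor population, not
by image-analysis error.

## Calibration lives on the normalized scale

Manual labeling happens on colonies of the screen itself, so labeled
densities are on the same scale as the values being thresholded. The
synthetic end-to-end flow mirrors this: `label_colonies_from_truth()`
samples measured, *normalized* densities (evenly spaced per
ground-truth class) and labels them with the true class. The
truth-scale generator `simulate_labeled_colonies()` exists for testing
the calibration arithmetic itself. A single cutoff is applied to the
whole screen (all baits screened simultaneously); per-screen
recalibration is available simply by calibrating per table.

## What the synthetic generator emulates

`simulate_screen()` produces, per source plate, a 96-spot diploid plate
and a 384-spot test plate with contiguous 2×2 technical quadruplicates —
the standard replicate-pinning geometry, chosen because the expansion
convention is not otherwise fixed and adjacent quadruplicates match how
pinned plates photograph. Rendered colonies are flat-top discs with
Gaussian shoulders whose integrals equal their true densities exactly
before noise; plates get a low-order polynomial illumination gradient
and additive Gaussian noise.

Defaults are on a 16-bit-photography intensity scale and were fixed
once, from first principles:

- background 500 a.u., noise SD 2, gradient amplitude 50 (10% of
  background). With a ~450 px integration window, the propagated density
  error is ~100 a.u., two orders of magnitude below the class scale, so
  measured densities correlate with truth at r ≥ 0.99 — the regime the
  pipeline is designed for.
- class densities log-normal with ordered medians 900 (negative; barely
  visible background growth, amplitude ≈ 2.5 × noise SD), 9000 (weak),
  36000 (medium), 120000 (strong). Colony densities are positive and
  right-skewed, spanning orders of magnitude on real plates.
- interactor fraction 377/1037 ≈ 0.36, the hit fraction of screen-scale
  MYTH data; class mixture weak 0.25 / medium 0.40 / strong 0.35. With
  ~100 interactors among 288 preys this makes realized sensitivity a
  stable statistic while keeping the intrinsic weak-class miss rate
  (above) visible in results.
- mating failure (dropout) probability 0.02; dropouts render no diploid
  colony and zero growth on the test plate.

Not emulated: colony texture, agar artifacts, plate edges/barcodes,
camera nonlinearity, contamination, or spatially correlated growth
effects. Passing recovery tests therefore demonstrates correctness of
the quantification logic under the stated optical model, not robustness
to every pathology of real plate photography.

## The nuclear-envelope pipeline

`nuclei_pipeline()` follows the canonical confocal recipe: maximum
projection, rolling-ball background subtraction (radius 20 px), Gaussian
blur (sigma 2 px — the blur width is acquisition-dependent and
configurable), automatic threshold, particle filter (area 4–12 µm²,
circularity ≥ 0.3), then per-nucleus mean intensity on the *sum*
projection of the original stack. Conventions we fixed:

- **Rolling ball** is realized as grayscale morphological opening with a
  flat disc of the stated radius (van Herk sliding min/max over the
  disc's chord decomposition). Radius semantics are preserved: flat
  backgrounds vanish exactly, discs much smaller than the radius are
  preserved, and a broad gradient leaves a residual below 5% of its
  amplitude at radius 20 on a 512 px field.
- **"Default" automatic threshold** is iterative intermeans (IsoData).
  A constant image yields an empty mask.
- **Connectivity** is 8-connected; labels are assigned in raster order.
- **Perimeter** uses crack-length counting corrected by π/4, which makes
  digitized discs measure 2πr so disc circularity → 1 from below;
  circularity is clamped at 1. Circularity cutoffs are
  convention-sensitive, hence the explicit choice.
- **Pixel size** must be supplied (0.1 µm/px in all synthetic fixtures,
  making the area gate 400–1200 px); the z geometry default is 21 planes
  at 0.3 µm — a 6.3 µm range under the inclusive fencepost, documented
  as a convention.

`render_nuclear_stack()` draws each nucleus as a spherical shell
(envelope-enriched fluorescence) on an anisotropic voxel grid with
sub-plane slab averaging. Its maximum projection is a flat-top disc
(clean to segment); its sum projection shows the limb-brightened ring of
real envelope staining. Ground truth uses the *half-maximum support*
convention: the truth mask contains the pixels whose noiseless
maximum-projection value reaches half that object's peak, and the truth
mean is the noiseless sum-projection mean (background included) over
that mask, with amplitudes scaled so the target mean holds exactly. A
global threshold sits somewhat below each object's half-maximum, so
measured masks run ~30% larger in area than the geometric disc;
in-range nuclei are therefore drawn at geometric areas 4.5–6.5 µm²
(realistic fission-yeast nuclei) so measured areas land inside the
4–12 µm² gate, and distractors at 0.8–1.2 µm², 18–22 µm², and 15 µm
rods so theirs land outside it. Measured means agree with truth to
within 2% at zero noise; the residual is the sum-projection tail
included by the slightly larger measured mask.

## Comparison-layer conventions

- Shared hits between replicates are intersection over union — the only
  simple reading under which a printed shared/total pair reproduces its
  printed percentage.
- Replicate Pearson correlation uses raw (not log) mean densities over
  preys positive in at least one replicate, zero-filling non-hits; the
  plotted-population choice is not uniquely determined, so log and
  hits-only variants are deliberately easy to compute from the returned
  tables.
- Fold enrichment compares a bait's density to the *maximum* over other
  baits; a zero denominator counts as enriched. At fold ≥ 2 enrichment
  sets are provably disjoint when all densities are positive.
- The Bonferroni divisor is the number of terms with at least one
  annotated hit (terms with none get p = 1 and are not counted),
  matching list-enrichment practice against a fixed library background.
  No ontology propagation is performed: term lists are taken as given.
- Row clustering is Euclidean distance with complete linkage — the
  common heatmap default — and is deterministic; distance ties resolve
  to the lower merge index via `stats::hclust`.

## Problem sizes and determinism

The shipped tests and the acceptance script use a three-plate screen
(288 preys, 1152 quadruplicate spots, 384-spot test plates at 30 px
pitch) and 512 × 512 × 21 nuclear stacks with 20 in-range nuclei and 5
distractors — sizes chosen so a full run of every stage completes in
seconds while leaving every statistic well-determined. All generators
are pure functions of (configuration, seed): identical inputs give
bit-identical images, truth tables and downstream calls.

## Known limitations

- The original plugin's density definition is not published; agreement
  is demonstrated against synthetic ground truth, not against the
  original implementation.
- Grid fitting assumes an approximately axis-aligned lattice;
  significant plate rotation is out of scope (a manual
  `nominal_grid()` override exists for hard cases).
- The min–max/epsilon normalization intrinsically inflates densities of
  wells with small diploids; this is faithful to the published recipe
  and is the main residual source of false calls near the cutoff.
- Real micrograph intensities are arbitrary-unit; the nuclei module's
  accuracy statements are defined only with respect to the synthetic
  ground-truth conventions above.
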