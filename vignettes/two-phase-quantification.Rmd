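---
title: "Quantifying the two-phase cytoplasm: methods and design notes"
author: "cytophase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the two-phase cytoplasm: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytophase)
```

# The scientific setting

Sequential detergent fractionation splits cultured cells into three
compartments: the cytosol (viscous fluid, extracted with a nonionic
detergent in a mild isotonic KCl buffer), the cytomatrix (CMX; the
detergent- and salt-resistant elastic solid, released by a stringent
LiCl buffer), and the core nucleus. This package implements the
computations layered on that protocol: the ionic arithmetic that keeps
the buffers isotonic, the high-content imaging readout of ribosome
biogenesis (nucleolar hypertrophy), the fraction-level quantification
statistics, and the downstream transcriptome/translatome enrichment and
concordance analysis. None of the wet-lab chemistry is modelled; values
enter as numbers, images, or gene tables.

# Buffer design: the ionic-replacement relation

Replacing sodium in isotonic saline by another monovalent cation while
preserving the ionic environment around proteins uses

$$C_r = \frac{18}{R_i},$$

with $R_i$ the relative (solvation-shell) ionic radius in picometres and
$C_r$ in mol/L; the constant 18 is empirical and carries units
mol·pm/L. We treat 18 as a given constant — whether it was originally
fitted so that sodium's radius reproduces standard saline is not
something the arithmetic needs. With the tabulated radii (Li 90, Na 116,
K 152 pm):

```{r}
sapply(ionicRadii(), function(r) replacingConcentration(r) * 1000)  # mM
```

Practical recipes round to the nearest 10 mM (`recipeConcentration()`),
reproducing 200 mM LiCl and 120 mM KCl. For sodium the same rule gives
160 mM, *not* 154 mM: standard saline is an external reference solution,
and we deliberately do not force the equation's output to match it.
Osmolarity bookkeeping (`osmolarity()`) assumes ideal complete
dissociation — a 1:1 salt contributes twice its molarity, so 154 mM NaCl
is 308 mOsm/L — with no osmotic coefficient, matching the arithmetic the
recipes were designed with.

# The synthetic microscopy generator

`generateField()` emulates a 40× high-content acquisition: a single
nuclear-stain (DAPI) plane and an 11-plane spot-channel (GFP) z-stack at
1 µm spacing. The stated stack extent ("10 µm at 1 µm increments") is
ambiguous about endpoints; we take 11 planes (inclusive) and make it
configurable. No magnification or pixel size is given for the
acquisition, so the default calibration of 0.16 µm/px is a plausible
40× value and is flagged as arbitrary.

The scene model is:

* **Nuclei**: filled ellipses with semi-major axis 4.5–6 µm (9–12 µm
  diameter, typical of adherent carcinoma cells) and mild eccentricity
  (axis ratio uniform in [0.7, 1]), placed disjointly by rejection
  sampling on bounding circles with a retry cap, fully inside the field.
* **Nucleoli**: a Poisson number of spots per nucleus (default rate 2),
  rendered as isotropic 2-D Gaussians with σ = radius/2 truncated at
  3σ, amplitude additive over the nucleus background. Spot centres are
  sampled uniformly in a shrunken copy of the parent ellipse, and spots
  within one nucleus are kept disjoint when space allows — real nucleoli
  do not interpenetrate, and overlapping synthetic spots would conflate
  generator artefacts with detector merging errors.
* **Defocus**: the focal plane is rendered sharp; every other plane is
  blurred with a Gaussian kernel of standard deviation
  `defocus_blur_um_per_um × |z − z_focal|` (default 0.5 µm of blur per
  µm of defocus), converted to pixels.
* **Noise**: Poisson shot noise at a configurable photon gain
  (default 1), then additive Gaussian read noise (default SD 10),
  clamped at zero — the standard fluorescence camera model.
  `photon_gain = Inf` disables shot noise for noise-free renderings.

A single integer seed drives one pseudo-random stream per generator
call; equal (config, seed) gives bit-identical pixels and truth, and all
ground-truth draws precede pixel draws so `generateFieldTruth()`
reproduces the identical truth without rendering. On disk
(`writeField()`) images are 16-bit unsigned TIFF, clipped with a
saturation warning, and the JSON ground truth uses 0-based coordinates
with x = column, y = row. In memory the package uses R's native 1-based
indexing throughout, including the focal-plane index.

What the generator does **not** emulate: uneven illumination, spectral
bleed-through, nucleolar substructure, cell-to-cell intensity
variability, mitotic figures, debris, and out-of-plane nucleoli
(detection operates on the single best-focused plane, as does the
method under test). Passing tests therefore show that the algorithmic
chain is correct under its own assumptions, not that it is robust to
every artefact of real plates.

# The nucleolar-hypertrophy pipeline

**Nuclei segmentation** (`segmentNuclei()`): Gaussian smoothing
(σ = 2 px) → global Otsu threshold on the normalised plane → hole
filling → removal of objects below `min_nucleus_area_px` → Euclidean
distance transform → markers at distance-map maxima with minimum
separation $\sqrt{\mathrm{min\_area}/\pi}$ → marker-controlled watershed
on the negated distance map restricted to the foreground → optional
removal of border-touching nuclei (on by default; partial nuclei bias
counts) → consecutive relabelling. The distance map is lightly smoothed
(σ = 2 px) before peak finding: boundary aliasing otherwise creates
twin ridge maxima on eccentric nuclei, and the smoothing merges them
without affecting well-separated markers. Thresholding and marker
choice operate on relative structure only, so label maps are invariant
to adding a constant to the image.

**Best-focus selection** (`selectBestFocusPlane()`): the plane
maximising the normalised variance of the Laplacian
($\mathrm{var}(\nabla^2 I)/\bar I^2$). The focus functional is not
specified by the original description; this one is standard, strictly
decreasing under Gaussian blurring of a structured image, and
illumination-normalised. Ties break to the lowest index.

**Nucleolus detection** (`detectNucleoli()`): white top-hat with a disc
of radius `tophat_radius_px` (default 11 px ≈ 2× the expected nucleolus
radius at the default calibration) isolates bright structures smaller
than the disc; the H-maxima transform with depth `h_depth` suppresses
maxima shallower than `h`; its regional maxima seed a marker-controlled
watershed of the negated top-hat image restricted to pixels with
top-hat value ≥ `h` (plus the seed plateaus), which turns maxima —
which underestimate object extent — into contiguous spot areas. The
default depth is 10% of the focused plane's robust dynamic range
(1st–99.9th percentile), making detection invariant to additive
offsets. Objects below `min_spot_area_px` are dropped, and each object
is assigned to the nucleus containing its centroid (simple,
deterministic, and adequate for well-separated nuclei); orphan objects
are discarded. Raw mean intensities and top-hat (background-corrected)
means are both reported, since whether the original implementation
background-subtracted is unknown.

Two default thresholds deliberately reflect the geometry rather than
minimal values: `min_nucleus_area_px = 1500` (true nuclei are
1700–4300 px² at the default calibration, and the marker-separation
rule derives from this area) and `min_spot_area_px = 20`. The latter
matters: discretisation of the nucleus boundary produces one- to
two-pixel top-hat artefacts of full background height — no proportional
depth threshold removes them — but they span only 4–6 px while true
spots cover ≥ 60 px, so a modest area floor separates the two cleanly.

The H-maxima machinery itself (grayscale reconstruction by dilation,
exact plateau regional maxima, priority-flood marker-controlled
watershed with FIFO tie-breaking) is implemented in compiled code with
8-connectivity throughout, since general-purpose image packages provide
tolerance-based rather than marker-controlled watersheds.

**Morphometry and comparison**: `summarizePerNucleus()` reports, per
nucleus, the nucleolus count and mean nucleolus area/intensity (absent,
not zero, for nucleolus-free nuclei). `aggregatePlate()` pools nuclei
across the fields of a well; counts average over all nuclei, areas and
intensities over nucleoli-bearing nuclei. Wells — not cells — are the
replicate unit passed to `compareTreatments()`: treating single cells
as replicates would pseudo-replicate, while well-level repetition
matches how such plates are actually laid out.

# Fraction statistics

`fractionPercentages()` divides each fraction by the per-replicate
total, so percentages sum to 100 within every replicate by
construction; means, SDs and SEs across replicates are all reported
(figure captions in this literature use SE, methods sections SD — both
are provided, labelled). `percentChange()` uses group means (the
bar-plot arithmetic), giving −20 for a 0.8× effect and +50 for a 1.5×
effect; it is antisymmetric on the multiplicative scale. Significance
thresholds are never baked into return values.

`oneWayAnova()` is the classic fixed-effects decomposition
$F = \mathrm{MSB}/\mathrm{MSW}$ with df $(k-1, N-k)$, delegated to
`stats::oneway.test(var.equal = TRUE)` after explicit handling of the
degenerate corners: zero within-group variance with separated means
gives $F = \infty$, $p = 0$ with a warning; all-identical data are an
error. The two-group statistic equals the squared pooled t. The t-test
(`welchTTest()`) defaults to Welch with Welch–Satterthwaite degrees of
freedom — the description names only "t-tests", and Welch is the robust
default under unequal variances — with the pooled variant behind a
flag.

Assay presets (`assayPreset()`) freeze the study conditions: the
`pp242-incorporation` preset carries multipliers 0.80 (cytosol) and
1.50 (CMX) with n = 5 and CV 0.05; `fraction-split` carries true shares
(0.70, 0.15, 0.15) with n = 6 and CV 0.03; `18S-ratio` carries a true
cytosol:CMX ratio of 1.8 with n = 3 and CV 0.05. Values are drawn as
mean × multiplier × (1 + ε), ε ~ N(0, CV); non-positive draws are
redrawn rather than clipped, because clipping would bias the means the
estimators are judged against. The baseline means themselves (10⁴ cpm
cytosol, 3 × 10³ cpm CMX, 1000 µg total protein) are arbitrary scale
choices; every downstream estimator is scale-free.

# Enrichment and concordance

`callDegs()` applies the strict rule: up requires $2^{\log_2 FC} >$
1.5 and FDR $< 0.05$ (both strict, both configurable). The universe for
over-representation analysis is an explicit required input — a
hypergeometric p-value is meaningless without a declared universe — and
gene sets are intersected with it before sizing, with dropped ids
reported. The upper-tail probability comes from `stats::phyper`;
adjustment is Benjamini–Hochberg step-up (the standard referent of
"FDR-adjusted"), applied across all sets of a collection. Up- and
down-regulated queries are analysed separately, mirroring how such
results are presented.

`vennConcordance()` computes the two-set region counts and the share of
transcriptionally upregulated genes without a ribosome-footprint call.
The exact denominator behind a printed "15–16% not translated" summary
is ambiguous, so the function exposes it: `|rna_up|` by default, the
union size as an alternative; an empty denominator returns 0 with a
warning.

# Numerical choices and degenerate inputs

* Equal (inputs, parameters) always give identical outputs; all
  stochastic stages take explicit seeds, and the watershed flood breaks
  priority ties FIFO so even plateau partitions are deterministic.
* A constant image segments to an empty label map; a constant plane has
  focus score 0; a blank stack is rejected; detection on a constant
  image returns no objects.
* Raising the H-maxima depth never increases the detected object count.
* 16-bit TIFF export quantises to one intensity unit on the fixed
  0–65535 scale; label maps round-trip exactly.

# Problem sizes used in the checks

The test suite validates the imaging chain on 256 × 256 px fields with
five nuclei each (about twenty fields for the detection-recovery check,
≈ 100 nuclei), one full-pipeline 2-treatment × 4-well plate of
512 × 512 px fields with 24 nuclei per field for effect-size recovery,
and 500 ground-truth-level plates for the null calibration of the
well-level ANOVA. The null calibration deliberately measures the
statistical stage on ground-truth summaries: its subject is the ANOVA's
type-I rate, which rendered pixels would only add variance to, and the
imaging stages are validated separately against rendered ground truth.
Monte-Carlo assay checks use 200–500 repetitions, enough to pin the
estimator means an order of magnitude tighter than the acceptance
tolerances.

# Known limitations

* Detection operates on one best-focused plane; nucleoli sharp only in
  other planes are invisible by design, as in the method emulated.
* Centroid-containment assignment can misattribute a spot whose
  centroid falls just outside a concave segmentation boundary; with
  well-separated convex nuclei this is negligible.
* The ANOVA and t-tests assume approximately Gaussian well-level
  summaries; with very few nuclei per well the Poisson skew of counts
  propagates to the F-test.
* The ionic-replacement relation is an empirical design rule, not a
  thermodynamic model: no activity coefficients, no osmotic
  coefficients, no detergent micellisation.
* Synthetic fields are far cleaner than real plates (see the generator
  section); performance numbers on them are upper bounds.
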