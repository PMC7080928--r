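---
title: "Quantifying gamma-H2AX foci and internal dose: models and choices"
author: "focidose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gamma-H2AX foci and internal dose: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focidose)
```

# The problem

After systemic administration of a radionuclide such as
^111^InCl~3~, tissues are irradiated continuously from within. An early,
countable marker of the resulting DNA double-strand breaks is the
phosphorylated histone H2AX (gamma-H2AX), which forms discrete
intranuclear foci visible by immunofluorescence and confocal laser
scanning microscopy (CLSM). `focidose` implements the full analysis chain
for such experiments:

1. a data model for two-channel (DAPI / gamma-H2AX) confocal z-stacks;
2. a synthetic ground-truth generator for liver- and testis-like fields;
3. DAPI-based nucleus segmentation (liver protocol) and manual-ROI support
   (testis protocol);
4. plateau-aware 3D foci detection with per-focus shell backgrounds;
5. per-nucleus count statistics (group summaries, zero-foci fractions,
   histograms, one-way ANOVA + Tukey HSD);
6. a MIRD-style self-dose chain from organ biokinetics to absorbed dose.

# Image model and conventions

Volumes use axis order `(z, y, x)` with `dim = c(nz, ny, nx)`; voxel
geometry defaults to a 1024 x 1024 lateral matrix at 140 nm pixel width
and 581 nm z-steps over 10 optical sections — a typical high-NA
acquisition. All radii and size thresholds are expressed in voxel-index
units, deliberately ignoring the ~4.15x z anisotropy, because the
protocol's thresholds (8 / 20 voxels, 6-voxel background radius) are voxel
counts; a physical-distance shell is available via
`foci_params(shell_mode = ...)` plumbing if needed. Intensities are
non-negative integers (8- or 16-bit storage), with all computation in
doubles.

# Nucleus segmentation (liver protocol)

The mask pipeline operates on the 2D maximum-intensity projection (MIP) of
the DAPI channel, in this fixed order:

1. **Automatic threshold.** Otsu's criterion over the integer histogram —
   the split maximizing the between-class variance
   $\omega_0\omega_1(\mu_0-\mu_1)^2$. The returned level is the *midpoint*
   between the two classes at the optimal split (so a two-valued image
   thresholds strictly between its values), multiplied by a user
   adjustment factor (`threshold_adjust`, default 1) that mirrors an
   operator nudging an automatic threshold.
2. **Binary median filter**, radius-2 Euclidean disk (13 pixels,
   centre-inclusive). Edge pixels use the in-bounds neighbourhood only; on
   binary input the median is a strict majority vote, and the exact tie
   possible in even-sized edge neighbourhoods resolves to background.
   The filter is applied to the mask, not the grayscale MIP.
3. **Distance-transform watershed** (EBImage `distmap` + `watershed`,
   tolerance 1 px by default) to separate touching nuclei. A single convex
   nucleus stays one region; two disks overlapping at 1.5 radii split in
   two.
4. **Fill holes**: every background component not connected to the image
   border becomes foreground (background connectivity 4, the complement of
   8-connected foreground); filled pixels inherit the dominant adjacent
   label.
5. **Minimum area** (default 50 px) and **border policy** (default:
   exclude nuclei touching the border, since partially imaged nuclei bias
   per-nucleus counts).
6. Consecutive relabelling; per-label features (area, centroid, perimeter,
   circularity, elongation, mean DAPI, heterochromatin contrast =
   0.9-quantile / median).

The 2D outlines are extruded unchanged across z (`extrude_labels_to_3d`),
defining the 3D regions in which foci are counted. Note the perimeter
estimator (boundary-pixel based, from EBImage) makes digital circularity
exceed 1 for compact shapes; the classifier thresholds account for that.

Cell-class assignment is **manual by default** (the field's protocol:
classes are assigned by an operator from morphology and staining). The
`auto` rule is a convenience for synthetic benchmarks: hepatocyte iff
round, large and heterochromatin-speckled; non-hepatocyte iff elongated
(`elongation >= 1.5`); otherwise unassigned. On the generator's default
morphologies it agrees with ground truth for >= 90% of nuclei.

# Foci detection

A focus is a coherent region with exactly one local-maximum centre:

* **Maxima** are maximal connected sets of equal-intensity voxels whose
  outside neighbours are all strictly lower (plateau-aware; border voxels
  compare in-bounds neighbours only). A plateau at the global minimum is
  never a maximum — there is no lower intensity for its surroundings to
  take, so the constant volume has none.
* **Background** per maximum: the mean (or median) intensity over the
  voxels at index-space Euclidean distance `6 +- 0.5` from the maximum
  centroid, clipped to the volume (a filled-ball alternative is a config
  switch).
* **Region growth**: the connected component, containing the maximum, of
  voxels at or above `background + alpha (peak - background)` with
  `alpha = 0.5` by default. The protocol fixes the size filter, the
  single-maximum rule and the background shell but not the region
  criterion; half-prominence is the natural choice and `alpha` is exposed
  and recorded in provenance.
* **Single-maximum rule.** Under the default `split` policy every voxel is
  first assigned to the basin of the maximum its steepest-ascent path
  terminates in (an intensity watershed seeded at all maxima; saddle
  plateaus resolve towards an equal-or-greater neighbour's basin). A
  focus region is then the connected part of its own basin above its
  growth threshold, so no region ever contains a second maximum, and
  shot-noise maxima fragment into sub-threshold pieces instead of
  percolating into large false regions. The stricter `reject` policy
  grows regions without basin restriction and discards any region holding
  more than one maximum.
* **Size filter**: strictly more than `min_voxels` voxels (8 for the liver
  protocol, 20 for testis), matching a "larger than" reading exactly.

Per-focus backgrounds are one-pass (a shell may overlap a neighbouring
focus); there is no iterative re-estimation. In liver mode, detection and
growth are restricted to the extruded nucleus labels and a focus belongs
to the nucleus whose label its maximum carries; zero-count nuclei are
reported (they carry the zero-foci fractions). In testis mode
(`foci_per_nucleus_roi`) foci are detected across the whole manual-ROI
volume of the gamma-H2AX channel and the result is total foci divided by
the operator-supplied nucleus count.

# Synthetic ground truth

The generator emulates two liver morphologies — large round
hepatocyte nuclei (semi-axes 18-24 px, ~2.5-3.4 um, with 4-8 bright
heterochromatin speckles) and smaller elongated homogeneous
non-hepatocyte nuclei (elongation 1.8-2.4) — plus round
spermatogonium/spermatocyte classes for testis-like fields. Per-nucleus
focus counts follow a zero-inflated Poisson (ZIP) law, the natural model
for count histograms with excess zeros; `pi0 = 0` recovers plain Poisson,
and `zip_pi0_for_zero_fraction()` solves the inflation for a target zero
fraction (the default emulates an exposed-liver condition: `mu = 5` with
a true zero fraction of 0.26).

Foci render as isotropic Gaussians in index space (sigma 1.2-1.5 voxels,
the scale of a diffraction-limited focus at 140 nm pixels), so that the
voxel-count size thresholds are exercised directly. Focus centres keep a
minimum pairwise separation of 5 voxels: at these widths closer pairs are
not two-point resolvable, and the ground truth is defined as the set of
*microscopically resolvable* foci — sub-resolution merging is an optical
limit, not a property of the counting pipeline.

Noise is Poisson shot noise on expected photons (with a configurable
gain) plus additive Gaussian read noise. The default photon backgrounds
are near-black (0.01 counts outside and inside nuclei beyond a faint
nuclear term, read noise SD 0.1): the imagery this emulates is acquired
with detector settings tuned until foci stand out on an essentially black
offset-subtracted background. This matters quantitatively: the
half-prominence growth rule admits, for a noise maximum of peak $p$ over
background $b$, every voxel above $(p+b)/2$ — and for integer Poisson
data with an appreciable background rate some intensity level always
sits above the 3D percolation threshold, producing spurious
above-size-limit regions no size filter can remove. High-SNR acquisition
is therefore a *precondition* of the counting protocol, and the generator
defaults reflect it. What passing tests show is that the pipeline
recovers truth under these (favourable, but protocol-faithful)
conditions; they do not certify behaviour on dim, high-background or
strongly autofluorescent real tissue, nor do they model PSF blur,
spectral bleed-through or intensity calibration.

The scaled-down default geometry (256 x 256 x 10) keeps desk-scale runs
fast; all sizes in physical units are unchanged. End-to-end checks use
~36 such stacks (~500 nuclei), the scale at which the 99% sampling
intervals of the ZIP mean and zero fraction are tight enough to be
informative.

# Count statistics

Summaries treat the **animal as the experimental unit** by default:
per-animal means are computed first and group means +- SD are taken over
animal means (n = 4 animals per group in the emulated design, giving
ANOVA df = (2, 9) for three groups). Pooling over nuclei is available but
not the default; SDs over animals are what "mean +- SD" refers to
throughout. One-way ANOVA is the classic fixed-effects decomposition
(fitted via `lm`); zero within-group variance with nonzero between-group
variance reports an infinite F with p = 0 and a degeneracy flag. Tukey
HSD uses the studentized range with the Tukey-Kramer standard error for
unbalanced groups; no further multiplicity correction is applied.

# Dosimetry

The self-dose chain assumes instantaneous uptake and mono-exponential
elimination: organ activity $A(t) = A_0 e^{-\lambda_{eff} t}$, with
$\lambda_{eff}$ from a two-point closed form (or log-linear least squares
for more points), $T_{eff} = \ln 2 / \lambda_{eff}$, residence time
$\tau_h = (1 - e^{-\lambda_{eff} h})/\lambda_{eff}$ up to horizon $h$
($1/\lambda_{eff}$ at infinity), and mean absorbed dose

$$\bar D_h = A_0 \cdot \tau_h \cdot S_{\text{self dose}}.$$

Cross-organ dose is deliberately out of scope. The physical half-life
constant for ^111^In is 67.32 h. S values and organ masses are user
configuration; the bundled `sfactors_synthetic.yaml` is an *illustrative
synthetic* table back-derived from tabulated dose-rate anchors with
nominal organ masses (testis 0.1 g, liver 1.5 g) — replace it with
phantom-derived Monte Carlo values for real work.
`dose_per_injected_activity()` bypasses S and mass entirely by anchoring
on a known dose rate, which lets a tabulated
biokinetics row be reproduced without either quantity.

Two cautions the package surfaces rather than hides. First, an effective
half-life *longer than the physical half-life* (the liver row of the
bundled reference table, `dose_reference_table.csv`: 167.9 h vs 67.32 h) implies the underlying activity values were
decay-corrected, i.e. describe biological retention; the chain accepts
either convention but cannot resolve which was used. Second, that liver
reference row is not internally consistent under a single
mono-exponential (the anchored chain gives ~45 mGy/MBq at 25 h against a
tabulated 49.6, and the infinite-horizon value is far below the naive
extrapolation); quantitative validation therefore anchors on the testis
row, and liver results from `scripts/acceptance.R` are reported as
computed, discrepancy included.

```{r dosimetry-example}
fit <- fit_monoexponential(c(4, 25), c(0.36, 0.28))
fit$T_eff
dose_per_injected_activity(4.6, 4, fit$T_eff, 25, 63)   # mGy/MBq at 25 h
dose_per_injected_activity(4.6, 4, fit$T_eff, Inf, 63)  # mGy/MBq, infinity
```

# Numerical choices and degenerate inputs

* Otsu on a constant image is an error (degenerate histogram); an empty
  segmentation result is a valid zero-label map with a warning.
* Median-filter ties (even edge neighbourhoods) resolve to background;
  interior neighbourhoods are odd-sized so ties cannot occur.
* A maximum whose background shell lies entirely outside the volume is
  skipped with a warning; a focus with peak below its background is
  dropped.
* `lambda = 0` (constant kinetics) is flagged; residence time then
  requires a finite horizon and diverges at infinity by design.
* Steepest-ascent ties (several equally bright greater neighbours) break
  deterministically by neighbour enumeration order; results are exactly
  reproducible for a fixed seed and config.
* TIFF intensities above the declared bit depth are an error rather than
  silently clipped.

# Known limitations

* Nucleus segmentation is 2D (MIP-based) with z-extrusion, per the liver
  protocol; overlapping nuclei in z are not separated.
* The foci picker reports voxel-resolution maxima (plateau centroids);
  there is no sub-voxel localization or intensity-to-DSB calibration.
* The ZIP generator draws counts independently per nucleus; spatial
  correlation of damage between neighbouring cells is not modelled.
* The dosimetry chain is organ-level: no voxel or small-scale tissue
  dosimetry, no cross-dose.
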