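# focidose

Quantitative analysis of radiation-induced DNA double-strand breaks in
tissue, for researchers studying the biological effects of internally
administered radionuclides (nuclear-medicine dosimetry, radiobiology).
After systemic exposure to a radionuclide such as ¹¹¹InCl₃, the
phosphorylated histone H2AX (γ-H2AX) marks double-strand-break sites as
discrete intranuclear foci visible by confocal laser scanning microscopy.
`focidose` turns two-channel (DAPI / γ-H2AX) confocal z-stacks into
per-nucleus foci counts and group statistics, and links them to the
absorbed dose via a MIRD-style self-dose chain.

## What it computes

**Image side.** Nuclei are delineated on the 2D maximum-intensity
projection of the DAPI channel (Otsu threshold with user adjustment →
radius-2 binary median filter → distance-transform watershed → fill
holes), and the outlines are extruded across z. γ-H2AX foci are detected
in 3D as coherent regions with a single local-maximum centre (a voxel or
an equal-intensity plateau), a per-focus background taken from the voxels
at a 6-voxel radius around the maximum, a region grown to
`background + α·(peak − background)` (α = 0.5), and a strict size filter
(> 8 voxels for liver, > 20 for testis). Counts are aggregated per
nucleus (zero-count nuclei included), summarized per animal group
(mean ± SD over animal means), and compared by one-way ANOVA with Tukey
HSD. A synthetic generator renders liver/testis-like fields with known
ground truth (zero-inflated Poisson foci counts), so the whole pipeline
is testable without any imaging data.

**Dose side.** From organ biokinetics (activity or %IA/g at sacrifice
times): mono-exponential elimination λ_eff, effective half-life
T_eff = ln 2 / λ_eff, residence time τ_h = (1 − e^(−λ_eff·h))/λ_eff, and
mean absorbed dose

```
D̄_h = A₀ · τ_h · S_selfdose
```

plus dose rates and dose-per-injected-activity at arbitrary horizons
(4 h, 25 h, ∞).

## Worked example

```r
library(focidose)

# a liver-like field with known ground truth
cfg   <- generator_config(seed = 7)        # 256x256x10, 8 hepatocytes + 6 others
scene <- build_scene(cfg)
stack <- render_stack(scene)

res <- analyze_liver_stack(stack, classify = "auto")
max(res$labelmap$labels)       # 14  (all 14 simulated nuclei segmented)
nrow(res$fociset$foci)         # 52  (52 true foci in this scene)
head(res$counts)
#> # A tibble: 6 x 3
#>   nucleus_id n_foci cell_class
#>        <int>  <int> <chr>
#> 1          1      2 hepatocyte
#> 2          2      6 hepatocyte
#> 3          3      0 hepatocyte
#> ...

# dosimetry: testis biokinetics, 63 MBq injected
fit <- fit_monoexponential(c(4, 25), c(0.36, 0.28))   # %IA/g at 4 h and 25 h
fit$T_eff
#> [1] 57.91984                     # effective half-life, hours
dose_per_injected_activity(4.6, 4, fit$T_eff, 25, 63)
#> [1] 1.655001                     # mGy/MBq accumulated by 25 h
dose_per_injected_activity(4.6, 4, fit$T_eff, Inf, 63)
#> [1] 6.400422                     # mGy/MBq if never sacrificed
```

The first block says: 14 nuclei were segmented and classified, and 52
foci were detected and assigned to them; `res$counts` is the per-nucleus
table that feeds `summarize_groups()`, `zero_foci_fraction()`,
`count_histogram()`, `one_way_anova()` and `tukey_hsd()`. The second
block says: testis activity falls with an effective half-life of ~58 h,
so an animal sacrificed at 25 h accumulated ~1.66 mGy per injected MBq
(~0.10 Gy at 63 MBq), and ~6.4 mGy/MBq (~0.40 Gy) would have accrued
over a full decay.

A thin command-line wrapper with `simulate` / `segment` / `foci` /
`quantify` / `dose` / `convert` subcommands is in
`inst/cli/focidose.R`. The methods vignette
(`vignettes/focidose-methods.Rmd`) documents the models, parameter
defaults and design choices.

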