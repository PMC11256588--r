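# cbss — CSF-based spatial statistics for low-b diffusion MRI

`cbss` quantifies the *pseudodiffusivity* of cerebrospinal fluid — the
apparent diffusivity D\* fitted from diffusion MRI at low b-values
(≤ 200 s/mm²), where signal attenuation is dominated by incoherent bulk
CSF motion (the IVIM effect) rather than thermal diffusion — and runs the
regional statistics a cohort study of CSF dynamics needs. It is aimed at
neuroimaging researchers studying CSF circulation, glymphatic function,
aging and cognitive impairment.

The pipeline:

1. **Tissue fractions & CSF mask** — free-water fraction as the CSF
   proxy, a deterministic two-class split of corrected FA into WM
   fraction, GM = 1 − CSF − WM, a pseudo-T2 contrast (GM:CSF mixed 1:2),
   and the CSF mask (free-water ≥ 0.8 ∧ ventricular/subarachnoid label).
2. **CSF parcellation** — every subarachnoid voxel takes the label of its
   nearest gray-matter atlas landmark in Euclidean mm (anisotropic voxels
   honoured, exact ties to the lowest code); ventricles keep their
   anatomical labels.
3. **Pseudodiffusivity** — per voxel, OLS of log S on b over all volumes
   with b ≤ 200 fits S(b) = S(0)·e^(−b·D\*); per region, the **median
   pseudodiffusivity (MPD)**, with left/right medians averaged weighted by
   volume.
4. **Fine mapping** — lateral and third ventricles split into 5-mm
   distance zones from the start of the third ventricle (the overlap of
   the 3-voxel-dilated lateral ventricles with the third ventricle).
5. **Statistics** — voxel-subsampling reproducibility (CoV), inter-regional
   Pearson correlation with Benjamini–Hochberg control and a cohort
   bootstrap aggregated by the Cauchy association test (ACAT),
   covariate-adjusted associations of MPD with cognition/age/sex/CBF, and
   per-subject MPD–CBF profile correlations.
6. **Digital phantom** — a procedural head phantom with known regional
   D\*, planted covariate effects, Rician noise and realistic covariates,
   so the full chain is testable without patient data.

## Worked example

Generate a 12-subject synthetic cohort and run the full pipeline:

```r
library(cbss)
library(dplyr)

spec <- phantom_spec(n_subjects = 12, seed = 2026)
run  <- run_cbss(cbss_config(phantom = spec, seed = 2026))

run$frame |>
  select(subject, age, STM, mpd_third_ventricle, mpd_lateral_ventricle) |>
  head(4)
#> # A tibble: 4 × 5
#>   subject   age   STM mpd_third_ventricle mpd_lateral_ventricle
#>     <int> <dbl> <dbl>               <dbl>                 <dbl>
#> 1       1  68.5 13.4              0.00262               0.00324
#> 2       2  75.7 12.7              0.00272               0.00290
#> 3       3  63.9  4.60             0.00244               0.00307
#> 4       4  71.7  8.09             0.00186               0.00345
```

MPD is in mm²/s: ventricular CSF sits near 3 × 10⁻³ mm²/s, well above the
thermal diffusivity of water, because bulk motion dominates at low b. The
association layer reports standardized slopes of each region's MPD on a
cognitive score, adjusted for age, sex and education, BH-corrected across
regions:

```r
run$stats$associations |> filter(outcome == "STM") |> arrange(p) |> head(3)
#> # A tibble: 3 × 8
#>   predictor               outcome  slope    se      r     p     n p_adj
#>   <chr>                   <chr>    <dbl> <dbl>  <dbl> <dbl> <int> <dbl>
#> 1 mpd_central_sulcus      STM     -0.370 0.204 -0.414 0.113    12 0.445
#> 2 mpd_third_ventricle     STM      0.285 0.193  0.294 0.183    12 0.445
#> 3 mpd_suprasellar_cistern STM      0.260 0.221  0.254 0.278    12 0.445
```

With 12 unplanted subjects nothing survives correction — as it should.
Planting an effect (`phantom_spec(effects = tibble(region =
"third_ventricle_zone1", covariate = "STM", slope = 0.4), ...)`) makes the
zone-1 association recoverable; the acceptance script below does exactly
that. Results carry broom-style accessors (`tidy()`, `glance()`) and
ggplot2 `autoplot()` methods; `plot_zone_profile(run$zone_tables)` shows
the ventricular MPD gradient.

A thin command-line wrapper ships in `inst/cli/cbss`
(`cbss phantom`, `cbss run`, `cbss stats`).

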