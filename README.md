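# angiokinetics

Pixel-by-pixel kinetic analysis of video fluorescein angiography in R.

Snapshot angiography answers "is there leakage?" almost as a yes/no
question. A 30 Hz video of the dye transit contains far more: when each
pixel fills, how fast it washes out, and how much fluorescence it retains.
`angiokinetics` turns a registered image stack into per-pixel kinetic
parameters and statistical maps of abnormality, for laboratory (rodent
fundus camera) or any comparable dynamic contrast sequence. It was built
around the laser-photocoagulation use case: localizing and sizing focal
blood–retinal-barrier lesions from their prolonged dye retention.

For every pixel's intensity profile *y(t)* (time zero = infusion start,
baseline *b* = pre-arrival mean, peak *p*):

- **half-rise** — first crossing of *b + (p − b)/2* on the rising limb;
- **half-fall** — first crossing of *offset + (p − offset)/2* after the
  peak; profiles that never decay that far are **capped** at the nominal
  duration (e.g. 60 s);
- **offset amplitude** — mean of the last recorded second, as % of peak.

Abnormality is scored within the same eye as z = (x − µ)/σ per pixel
(µ, σ over an explicit included region, e.g. the capillary/choroid field),
thresholded at 1–4 SD, and summarized as abnormal area and connected
components. The pipeline: **register** (translational cross-correlation) →
**filter** (PCA reconstruction, or 3-point moving median for
high-variance injury data) → **extract** → **regions** (vessel class ×
quadrant × eccentricity zone, mean ± SEM) → **anomaly**. A synthetic
phantom generator with exact ground truth (vessel geometry, class
kinetics, leak lesions, frame jitter, noise) makes every stage testable
without recorded data.

## Worked example

Simulate a laser-injury acquisition (60 s at 30 Hz, four leak lesions),
register it, filter with the moving median, extract kinetics, and map
abnormal offset amplitude:

```r
library(angiokinetics)

ph  <- render_phantom(default_injury_spec(seed = 1))
ref <- choose_reference(ph$seq)               # frame 295 (~9.8 s, vessels full)
reg <- apply_shifts(ph$seq, estimate_shifts(ph$seq, ref))
maps <- extract_maps(moving_median3(reg))
#> kinetics: 7744 valid, 0 flat, 25 capped pixels
print(maps)
#> Kinetic parameter maps: 96 x 96 px, 7744 valid (25 capped)
#>   half_rise_s  median 7.85 [7.61, 8.62]
#>   half_fall_s  median 11.10 [10.53, 13.60]
#>   offset_pct   median 35.84 [32.27, 54.65]

cap <- maps$valid_mask & ph$truth$class_map == 0   # capillary/choroid field
am  <- zscore_map(ifelse(cap, maps$offset_pct, NA), cap, parameter = "offset")
print(am)
#> Anomaly map of offset: mu = 38.14, sigma = 11.93 (6421 included px, positive tail)
#>   >= 1 SD: 320 px
#>   >= 2 SD: 320 px
#>   >= 3 SD: 320 px
#>   >= 4 SD: 160 px
abnormality_indices(am, ph$seq$meta)
#>   threshold_sd n_pixels area_um2 n_components largest_component_um2
#> 1            1      320   307520            4                 76880
#> 2            2      320   307520            4                 76880
#> 3            3      320   307520            4                 76880
#> 4            4      160   153760            2                 76880
```

Reading the output: half-rise times cluster near 7.6–8.6 s (arteries
first, veins ~1 s later) and the healthy field's offset sits near 36% of
peak. At the 2 SD threshold the offset map recovers exactly the four
injected lesions as four 8-connected components totalling ≈0.31 mm²; the
two continuous-rise lesions reach ≥4 SD. `run_pipeline(pipeline_config(...))`
performs the same flow from a TIFF stack on disk and writes every artifact
(registered/filtered stacks, parameter maps, region summary CSV, z and
level maps, indices CSV, manifest with hashes); `inst/cli/angiokin`
exposes the stages as shell subcommands.

## Layout

- `R/` — implementation (I/O, phantom, registration, filtering, kinetics,
  regions, anomaly, pipeline)
- `tests/testthat/` — unit, property, and end-to-end suites
- `vignettes/angiokinetics-methods.Rmd` — model, conventions, design
  decisions, limitations
- `scripts/acceptance.R`, `inst/cli/angiokin` — reproduction script and
  CLI front end
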