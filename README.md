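# retmorph

Geometry-corrected retinal vessel morphometry and OCT cohort analysis for
ultra-widefield-style fundus imaging.

## What problem this solves

Studies of neurodegenerative disease increasingly measure the retina as a
window on the central nervous system: peripapillary retinal nerve fibre
layer (RNFL) thickness and macular volume from OCT, and — more recently —
the calibre of blood vessels in the retinal *periphery* from
ultra-widefield scanning laser ophthalmoscopy (UWF-SLO). Comparing vessel
widths between a disease group and healthy volunteers only works if pixel
measurements are converted to millimetres of curved retina at a
standardised retinal location; otherwise projection distortion and vessel
taper swamp group effects of a few micrometres.

`retmorph` implements the full chain for researchers running such cohorts:

- **Projection geometry.** A conformal stereographic model of the eye
  (sphere of radius *R*, fovea at the tangent point): planar radius
  `rho = 2 R tan(theta/2)`, per-pixel scale `cos^2(theta/2) / s` mm/px.
  Corrected polyline lengths agree with on-sphere geodesics to a small
  fraction of a percent.
- **Vessel morphometry.** Otsu segmentation (seeded, semi-automatic),
  Zhang–Suen centerlines with distance-transform widths and sub-pixel
  perpendicular-profile refinement, quadrant demarcation from the
  disc–fovea axis, measurement restricted to the 6.5–8.5 disc-radii
  annulus, and the 8-vessel selection protocol (one artery + one vein per
  quadrant).
- **OCT cohort handling.** Strict CSV loading of per-visit RNFL/macular
  records, the study exclusion rules (retinal pathology / high myopia,
  optic-neuritis history in the disease group, quality score < 25,
  pregnancy visits dropped from follow-up only) with a conserving filter
  report, and annualised per-subject rates of change for irregular visit
  schedules.
- **Statistics.** Pooled two-sample t-tests with CIs and star codes,
  disease-coefficient OLS with an adjusted-R²-and-significance confounder
  rule (age, then sex), Cook's-distance (3× mean) robustness refits,
  residual diagnostics, and report tables per outcome and eye.
- **Synthetic ground truth.** An eye/vessel-tree/fundus renderer and a
  two-group cohort generator with configurable effect sizes, so every
  stage is validated against known truth.

## Worked example

```r
library(retmorph)

eye   <- eye_model()                      # 12 mm right eye, disc 15° nasal
tree  <- grow_vessel_tree(eye, seed = 7)  # 1 artery + 1 vein per quadrant
scene <- render_fundus(eye, tree, resolution = 1024)
res   <- measure_scene(scene)
res$measurements[, c("vessel_id", "quadrant", "vessel_type",
                     "mean_width_mm", "n_pixels", "true_annulus_mean_mm")]
```

```
    vessel_id quadrant vessel_type mean_width_mm n_pixels true_annulus_mean_mm
1 NI_artery_1       NI      artery    0.07045698       95           0.07013907
2   NI_vein_1       NI        vein    0.08181305      110           0.08263084
3 NS_artery_1       NS      artery    0.08263305       87           0.08275634
4   NS_vein_1       NS        vein    0.09000812       80           0.09035371
5 TI_artery_1       TI      artery    0.09529766       83           0.09488964
6   TI_vein_1       TI        vein    0.10980849       98           0.10937732
7 TS_artery_1       TS      artery    0.10143659       85           0.10108983
8   TS_vein_1       TS        vein    0.11737211       85           0.11731290
```

Eight vessels selected (one artery and one vein in each quadrant); the
measured annulus-mean widths in mm sit within ~1% of the generator's
analytic ground truth. The same functions accept real images plus a
landmarks JSON (`read_landmarks`) and operator seed/type annotations.

A full statistical round trip on synthetic data:

```r
cfg    <- cohort_config(seed = 1)          # 72 MS / 80 HV, study-scale effects
ch     <- simulate_cohort(cfg)
vis    <- simulate_visits(ch, cfg)
filt   <- apply_exclusions(vis, ch$subjects)
rates  <- rates_table(filt$records)
report <- analyze_cohort(ch$baseline, rates, ch$subjects)
subset(report$baseline_regression, outcome == "rnfl_global",
       select = c(eye, included, disease_coef, disease_p, stars))
```

```
  eye        included disease_coef    disease_p stars
1  OD disease+age+sex   -10.847981 1.653312e-08   ***
2  OS disease+age+sex    -9.671149 1.047472e-06   ***
```

The fitted disease coefficients recover the configured −10 µm global-RNFL
effect, with age kept by the confounder rule.

See `vignettes/retinal-morphometry.Rmd` for the models, parameter
defaults, numerical choices, and limitations.

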