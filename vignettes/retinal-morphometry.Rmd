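---
title: "Geometry-corrected retinal vessel morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry-corrected retinal vessel morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retmorph)
```

## The measurement problem

Ultra-widefield scanning laser ophthalmoscopy images most of the retina in
a single capture, which makes the peripheral vasculature accessible to
quantitative measurement. But the retina is (to a good approximation) the
inner surface of a sphere, and a flat image of it necessarily distorts
lengths: a vessel-width measured in pixels means different things in
different parts of the image. Cohort studies comparing vessel calibre
between groups -- for example people with multiple sclerosis (MS) and
healthy volunteers (HV) -- need widths in millimetres of retina, measured
at a standardised retinal location, or group differences of a few
micrometres will drown in projection artefacts.

`retmorph` implements that measurement chain and the statistical analysis
that typically follows it, together with a synthetic data generator that
provides ground truth for every stage.

## The projection model

The eye is modelled as a sphere of radius $R$ (default 12 mm, an
emmetropic globe) with the fovea at the posterior pole, which is also the
tangent point of the image. The image is a stereographic projection from
the antipodal point: a retinal point at eccentricity $\theta$ (angular
distance from the tangent point) and meridian $\phi$ maps to the planar
point at radius

$$\rho = 2R\tan(\theta/2)$$

millimetres from the image centre, at the same polar angle $\phi$, scaled
by $s$ px/mm. Stereographic projection is conformal -- it preserves angles
exactly -- and its length distortion is purely radial and known in closed
form: one pixel at eccentricity $\theta$ covers

$$\frac{\cos^2(\theta/2)}{s} \ \text{mm of retina,}$$

isotropically. This gives the per-pixel millimetre conversion used by
every width and length measurement. A polyline traced on the image is
converted to an on-retina length by summing planar segment lengths times
the local scale at each segment midpoint (midpoints rather than endpoints
for second-order accuracy). On densely sampled test arcs within 100
degrees of eccentricity the relative error of this corrected length
against the closed-form geodesic is of order $10^{-3}$ percent (the
contract we test against is 2%), and it converges to the geodesic as the
sampling density increases.

The scanner maker's proprietary re-mapping is not public; the package's
contract is therefore the accuracy of geometric measurement on the
ideal-sphere model, not bit-compatibility with any device. Axial-length
personalisation of $R$ is out of scope, though any positive radius is
accepted.

## The morphometry pipeline

1. **Segmentation** (`segment_vessels`). Vessels are the darker phase of
   the (red-channel) image; Otsu's threshold separates them. With operator
   seed points, only components touching a seed are kept -- the
   semi-automatic mode matching how a grader selects vessels.
2. **Centerlines and widths** (`extract_centerlines`). The binary map is
   thinned with the Zhang-Suen algorithm. Junctions are detected by the
   *crossing number* (the number of connected runs of skeleton neighbours
   around a pixel), not the raw neighbour count, which over-detects on
   8-connected skeletons; short spur branches -- rasterisation artefacts --
   are pruned (default: shorter than about 1.5 vessel widths). The raw
   width at a centerline point is twice the Euclidean distance-transform
   value there.
3. **Sub-pixel refinement** (`profile_widths`, the default). The
   distance-transform width is quantised by the pixel grid; on vessels
   only 5-10 px wide this quantisation does not average out along a
   straight vessel and can reach 8-10% of the width. The default
   measurement therefore samples the image along the perpendicular of
   each centerline point (bilinear interpolation, 0.25 px steps) and
   places each edge at the half-intensity crossing between vessel core and
   background, interpolated to sub-pixel precision. Setting
   `width_method = "dt"` restores the raw distance-transform width.
4. **Quadrants and annulus** (`demarcate_quadrants`, `annulus_filter`).
   The line from the optic-disc centre to the fovea, and its perpendicular
   through the disc centre, split the image into temporal-superior (TS),
   temporal-inferior (TI), nasal-superior (NS) and nasal-inferior (NI)
   quadrants; temporal is the fovea side, superior is image-up (fundus
   images are assumed displayed anatomically upright), and laterality
   (OD/OS) makes labels mirror-consistent between eyes. Because vessels
   taper with distance from the disc, widths are only measured where a
   centerline point lies between 6.5 and 8.5 disc radii (planar distance,
   in units of the annotated disc radius) from the disc centre -- bounds
   inclusive, a measure-zero convention fixed for determinism.
5. **Selection and measurement** (`select_vessels`, `measure_width`). At
   most 8 vessels are analysed per image: one artery and one vein per
   quadrant. A segment's quadrant is the majority vote of its in-annulus
   centerline points (ties: the point nearest 7.5 disc radii). Among
   candidates of a (quadrant, type) pair, the segment with the most
   in-annulus points wins (ties: larger mean width, then lexicographic
   id); artery/vein identity is an *input* (ground truth or operator
   annotation), as automated artery-vein classification is out of scope.
   The reported quantity is the mean over in-annulus centerline points of
   width in px times the local mm-per-px scale.

Distances in disc radii are computed on the projected plane, matching how
an operator would mark them on the image; computing them on the sphere
instead would shift the annulus by well under its own width at these
eccentricities.

## The synthetic retina and cohort generator

Because the patient data behind studies of this kind are not public, the
package ships a generator whose outputs have known ground truth, and the
test suite measures the pipeline against it.

* **Vessel trees** (`grow_vessel_tree`): unbranched artery/vein
  centerlines per quadrant, built as wobbling radial curves in the
  projected plane, lifted to the sphere. Widths taper strictly
  monotonically with on-sphere arc length (linear by default, exponential
  optionally) towards quadrant- and type-specific annulus targets in the
  0.07-0.12 mm range -- arteries narrower than veins, nasal narrower than
  temporal. Each vessel records its analytic annulus-mean width.
* **Rendering** (`render_fundus`): anti-aliased stamping of each vessel
  into a square image (default 1024 px across a 22 mm planar field, i.e.
  about 47 px/mm centrally), dark vessels on a bright background, optional
  additive Gaussian noise, plus a per-pixel vessel label map and the
  landmarks JSON (disc centre and radius, fovea, laterality) the
  measurement stage consumes.
* **Cohorts** (`cohort_config`, `simulate_cohort`, `simulate_visits`):
  subjects in two groups (default 72 MS / 80 HV, ages 20-79 and 23-73,
  about three-quarters female, MS subtypes roughly 87/3/10%
  RRMS/PPMS/SPMS); each baseline outcome is
  $\beta_0 + \beta_d \mathbb{1}[\text{MS}] + \beta_a\,\text{age} +
  \beta_s \mathbb{1}[\text{F}] + \varepsilon$, drawn independently for the
  two eyes (eyes share covariates, not noise; no interocular correlation
  parameter by default, since the analysis keeps eyes separate). Default
  effects are at the magnitudes reported for MS retinal morphometry: for
  example $\beta_d = -10\ \mu m$ for global peripapillary RNFL thickness,
  $-0.0079$ mm for nasal-inferior artery width, $-0.29\ \text{mm}^3$ for
  macular volume; age slopes of about $-0.2\ \mu m$/yr globally; residual
  SDs of roughly 11-26 um for RNFL regions, 0.36 mm^3 for macular volume
  and 0.018 mm for vessel widths (back-computed from group standard
  errors at n = 80). Follow-up visits (1-5 for MS, 1-3 for HV) place the
  baseline-to-final span uniformly in 196-672 days (MS) or 227-802 days
  (HV) -- the span, not the individual gaps, is the quantity the study
  design constrains -- with intermediate visits uniform within the span,
  day resolution; outcomes evolve linearly at group-specific annual
  slopes (division by 365.25 days/yr) with visit-level measurement noise
  (2 um RNFL, 0.05 mm^3 macular volume, typical device repeatability).
  An occasional healthy-volunteer pregnancy flags one follow-up visit.
  Quality scores are Gaussian around 32 (SD 4), so a few percent of
  records fall below the 25-point inclusion floor and exercise the
  exclusion rules.

What the generator does *not* emulate: vessel branching and crossings
within the annulus, central reflex and calibre pulsation, eyelash and lid
artefacts, media opacity, inter-visit registration error, and
pathology-driven focal changes. Passing tests therefore validate the
geometry, bookkeeping and statistics of the pipeline -- not segmentation
robustness on real scanner images.

## OCT records, exclusions, rates

OCT summary records (seven peripapillary RNFL sectors in um, macular
volume in mm^3, quality score, ART averaging count, visit date) are read
from CSV with strict parsing: missing cells become `NA`, malformed dates
or numbers fail loudly with the row number. Exclusions follow a fixed
order, each record attributed to the first rule that removes it:

1. retinal pathology or high myopia (refractive error $\le -10$ D) --
   subject-level;
2. history of optic neuritis in MS subjects -- subject-level;
3. quality score below 25 (a *minimum of 25* means 25 itself is kept);
4. pregnancy-flagged visits are retained for baseline but excluded from
   rate-of-change analyses (pregnancy transiently thickens the RNFL).

The filter report satisfies removed + surviving = input by construction
and is idempotent. Annualised rates are per-subject-per-eye OLS slopes of
outcome against years since first usable visit (with two visits this is
the difference quotient); subjects with fewer than two usable visits
contribute nothing. ART values are stored as metadata only -- the study
settings are 100 (peripapillary) and 12 (posterior pole), but no cut-off
is defined on them.

## The statistical stage

Baseline group differences use the pooled-variance (not Welch) unpaired
Student's t-test with 95% CIs, and significance stars at p < 0.05 / 0.01 /
0.001 (strict inequalities). Disease effects come from OLS regressions of
each outcome on *disease* (always included) plus *age* and *sex* as
candidate confounders. The inclusion rule evaluates candidates in the
fixed order age-then-sex: a candidate stays only if it strictly increases
the **adjusted** R-squared *and* its coefficient is significant at 0.05;
the audit trail records both numbers for every candidate. Adjusted (rather
than plain) R-squared is used because plain R-squared never decreases
under addition and would make the first clause vacuous.

Robustness is assessed by a single non-iterative refit after removing all
observations with Cook's distance above 3 times the mean Cook's distance;
if removal would leave fewer observations than coefficients plus one, an
error is raised and nothing is removed. Cook's distance uses the standard
leverage form, which the tests verify against explicit leave-one-out
refits at $10^{-10}$. Residual diagnostics report the five-number summary,
histogram counts, normal-quantile pairs, skewness, excess kurtosis and a
Shapiro-Wilk p-value -- a quantitative proxy for the visual normality
checks such studies describe. Eyes are analysed separately throughout; no
multiple-testing correction is applied by default (matching exploratory
practice in this literature), but `fdr = TRUE` adds Benjamini-Hochberg
adjusted p-values.

## Numerical and design choices

* Angles are radians internally; degrees only at constructor boundaries.
* The `2*dt` width: EBImage's distance transform measures to the nearest
  *background pixel centre* (~0.5 px beyond the true boundary), while the
  skeleton pixel sits up to ~0.5 px off the true centerline; the two
  quantisations cancel on average, and on rasterised bands of known width
  `2*dt` is empirically unbiased to under 0.2 px, where the
  half-pixel-"corrected" `2*dt - 1` is about 1 px low. The profile
  refinement then removes the remaining grid quantisation; it was made
  the default after the distance-transform width alone proved unable to
  meet the 5% recovery contract on 5-8 px vessels.
* Degenerate inputs fail early with messages: antipodal projection
  points, fovea coincident with the disc, singular regression designs
  (naming the collinear columns), leverage-1 observations (infinite
  Cook's distance, with a warning), sub-minimal group sizes.
* Determinism: every stochastic routine takes or derives from an integer
  seed and restores the caller's RNG state; identical seeds give
  bit-identical trees, rasters, cohorts and reports.

## Validation problem sizes

The shipped test suite validates width recovery on 512 and 2048 px
renders of an 8-vessel scene with 0.25 mm annulus widths (so the coarse
render still has >5 px vessels, within the estimator's validity domain);
type-I calibration of the group test and disease coefficient with 500
null-generator replicates at n = 30 per group; and effect recovery
(global RNFL -10 um, NI artery -0.0079 mm, global rate -0.98 um/yr,
macular-volume rate -0.047 mm^3/yr) over 500 replicates at n = 70 per
group, asserting the mean fitted coefficient lies within two Monte-Carlo
standard errors of the configured truth. A two-standard-error band is a
5%-false-alarm check per target by construction, so the replicate count
is kept high enough that a systematic bias of scientific magnitude would
dominate the Monte-Carlo noise. Recovery fits use the full
disease + age + sex model: the two groups have different age ranges, so a
model that dropped age would bias the disease coefficient by more than
the acceptance band.

## Known limitations

* Artery/vein identity must be supplied; there is no colour-based A/V
  classification.
* The annulus is planar; no on-sphere disc-radii variant is provided.
* Quadrant assignment of vessels that straddle a boundary uses majority
  vote -- a proxy for an operator decision that real protocols leave
  implicit.
* Linear per-subject rates assume no plateau over the observation window;
  mixed-effects models for interocular correlation are deliberately out
  of scope.
* The generator's Gaussian additive noise cannot represent segmentation
  failure modes of real images (central reflex splitting, crossing
  artefacts), so real-data performance claims require real annotated
  images.

## A worked example

```{r, eval = FALSE}
eye <- eye_model()                           # 12 mm OD eye
tree <- grow_vessel_tree(eye, seed = 7)      # 8 vessels, known widths
scene <- render_fundus(eye, tree, resolution = 1024)
res <- measure_scene(scene)
res$measurements[, c("vessel_id", "quadrant", "vessel_type",
                     "mean_width_mm", "true_annulus_mean_mm")]

cfg <- cohort_config(seed = 1)               # study-scale cohort
ch <- simulate_cohort(cfg)
vis <- simulate_visits(ch, cfg)
filt <- apply_exclusions(vis, ch$subjects)
rates <- rates_table(filt$records)
report <- analyze_cohort(ch$baseline, rates, ch$subjects)
report$baseline_regression[report$baseline_regression$outcome ==
                           "rnfl_global", ]
```
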