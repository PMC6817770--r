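---
title: "Distinguishing cerebral arterioles from venules by lumen-to-wall area ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing cerebral arterioles from venules by lumen-to-wall area ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselmorph)
```

## The measurement problem

Small parenchymal vessels of the brain are notoriously hard to classify.
Arterioles and venules both carry a single layer of intramural cells (smooth
muscle cells and pericytes) inside the endothelial basement membrane, both
express the same immunohistochemical markers, and both are rarely circular in
section. The traditional criterion — the ratio of lumen diameter to wall
thickness, $R_D = D_L / T_W$ — fails for the smallest vessels because the two
classes' $R_D$ ranges overlap heavily: a small venule and an arteriole of
similar caliber can produce the same number.

The ratio of lumen *area* to wall *area*,

$$R_A = \frac{A_L}{A_W},$$

measured on a transverse cross-section segmented into lumen and wall, behaves
much better. Venule walls are thin relative to their lumen ($R_A$ roughly 1.9
to 11 in reference data), arteriole walls are thick ($R_A$ roughly 0.27 to
1.6), and the two observed ranges do not overlap. `vesselmorph` implements
this morphometric pipeline end to end: calibrated 3-label masks in, areas,
diameters, thicknesses, classifications and rank tests out — together with a
synthetic cross-section generator that provides exact analytic ground truth
for every estimator, since the original electron micrographs behind the
published ranges are not publicly deposited.

## Vessel masks and what is measured

A vessel enters the pipeline as a `segmented_vessel`: an integer label grid
(0 background, 1 lumen, 2 wall) plus a calibration in micrometers per pixel.
The wall label covers everything between lumen and parenchyma — endothelium,
basement membrane, intramural cells and, where present, leptomeninges — as a
single closed region. Pixel centers sit at integer coordinates and a pixel
belongs to the region containing its center, so areas are exact pixel counts
times the squared calibration and `total_area = lumen_area + wall_area` holds
identically.

From one mask, `measure()` assembles:

* `lumen_area` ($A_L$), `wall_area` ($A_W$), `total_area`, in $\mu m^2$;
* `area_ratio` $R_A = A_L / A_W$;
* `equiv_diameter` $D_L = 2\sqrt{A_L/\pi}$, the area-equivalent circular
  diameter. Because small vessels are rarely smoothly circumscribed, a single
  caliper width is ill-defined; the area-equivalent diameter is reproducible
  and is the default. Maximum and minimum Feret diameters are available via
  `lumen_diameter(v, "feret_max" | "feret_min")` for users who want an
  explicit caliper measurement.
* `mean_thickness` $T_W$: the mean, over (by default) 360 equally spaced rays
  cast from the lumen centroid, of the distance from the lumen/wall crossing
  to the wall/background crossing. Rays that do not cross each boundary
  exactly once are dropped and the valid fraction is reported. If the
  centroid falls outside a strongly non-convex lumen, the estimator falls
  back (with a warning) to a distance-transform form: twice the mean
  distance-to-boundary over the wall's medial-axis pixels. Setting
  `thickness_check = TRUE` computes both and warns when they disagree by more
  than 10%.
* `diameter_ratio` $R_D = D_L / T_W$.

Both ratios are invariant under any change of calibration, since areas scale
with the square and lengths with the first power of microns-per-pixel.

### Exclusion rules

`measure()` flags, in order of precedence: vessels with wall-altering
pathology noted at acquisition (`pathology`), sections that are not transverse
(`not_transverse`), and vessels whose **total** cross-sectional area is
strictly below 70 $\mu m^2$ (`too_small`) — the floor that keeps capillaries
and post-capillary venules out of the analysis. "Surface area" here means the
whole vessel (lumen plus wall), and the boundary is a strict less-than: a
vessel of exactly 70 $\mu m^2$ is kept. Excluded vessels are still measured
and carried through the output with their reason, never silently dropped, so
every batch is fully accounted for.

## Classification

`classify_area_ratio()` applies the empirical decision ranges: $R_A \le 1.57$
is an arteriole, $R_A \ge 1.89$ a venule. The open interval between the two
observed ranges maps to an explicit `indeterminate` class rather than to an
invented cut point — the separation claim is only supported outside the
observed ranges. Users who require binary output can pass a `binary_cutoff`
(a conventional choice is the geometric midpoint of the gap,
$\sqrt{1.57 \times 1.89} \approx 1.723$).

`classify_diameter_ratio()` is deliberately weak, encoding the negative
result for the traditional criterion: at or above its threshold a vessel is
called a venule; below it no call is made, because both classes populate that
region. Two published values exist for the arteriole-group mean diameter
ratio that anchors this threshold — 4.348 in the results text and 4.97 in the
subgroup analysis. Both are exported (`DIAMETER_RATIO_GROUP2_MEAN`,
`DIAMETER_RATIO_SUBGROUP_THRESHOLD`); the package does not resolve which is
correct and defaults to 4.97, the value the subgroup re-test used.

`range_overlap()` quantifies the separability argument directly: it
intersects the $[\min, \max]$ envelopes of the two groups for any metric.

## The rank test

Group differences are tested with a Mann–Whitney U test written from scratch
(`mann_whitney_u()`), two-sided throughout (the sidedness convention of
common statistical packages). $U$ is computed from rank sums with midranks
for ties. For pooled sizes $n_1 + n_2 \le 16$ (or on request) the p-value is
exact: a generating-function recursion counts, conditional on the observed
tie pattern, how many of the $\binom{n}{n_1}$ group-label arrangements reach
each rank sum, and the two-sided p doubles the smaller tail (capped at 1).
Otherwise a normal approximation with tie-corrected variance

$$\sigma_U^2 = \frac{n_1 n_2}{12}\Big(n + 1 - \frac{\sum_j (t_j^3 - t_j)}{n(n-1)}\Big)$$

and a continuity correction of $1/2$ is used. If every pooled value is
identical the test is degenerate and returns $p = 1$ with a warning. A
reported "p = 0.000" in reference results is read as $p < 0.001$ (a display
convention), never as literal zero. `below_threshold_retest()` restricts both
groups to diameter ratios strictly below a threshold before re-testing, and
raises an error naming the offending group when a restricted sample is empty.

## The synthetic generator

Because the source micrographs are unavailable, validation rests on synthetic
cross-sections whose geometry is known exactly. A vessel is built in polar
coordinates about its lumen center:

* lumen boundary: a polar ellipse with semi-axes $(a, b)$, modulated by a
  low-order Fourier perturbation
  $\rho_L(\theta) = r_e(\theta)\,(1 + \sum_{k=2}^{4} c_k \cos(k\theta + \phi_k))$
  with total amplitude $\sum_k c_k \le 0.2$;
* wall: a radial offset band
  $\rho_{out}(\theta) = \rho_L(\theta) + t_0\,(1 + m \cos(2\theta + \phi_t))$
  with modulation amplitude $m \le 0.5$.

Star-shaped construction guarantees the boundaries never self-intersect and
the wall is always a topologically closed annulus — the discontinuity of the
venule's intramural cell layer is a cell-scale feature inside the wall, not a
hole in it. Truth areas and thickness come from trapezoidal quadrature of the
boundary curves on 4096 angular nodes (spectrally accurate for these smooth
periodic functions), never from the raster, so rasterization error is
measurable. Wall area is exactly quadratic in $t_0$,
$A_W = \alpha t_0 + \beta t_0^2$ with
$\alpha = \oint \rho_L (1 + m\cos(2\theta+\phi_t))\,d\theta$ and
$\beta = \pi(1 + m^2/2)$, so given a lumen and a target area ratio the base
thickness has a closed-form solution and every generated vessel hits its
sampled ratio to quadrature precision (about $10^{-12}$ relative).

### Population defaults: the study conditions

`population_spec()` defaults encode the reference study: 81 venule-like and
31 arteriole-like vessels, rasterized at 0.05 $\mu m$/px. True area ratios
are drawn from scaled Beta distributions on the published supports with the
published means: group 1 is Beta(1, 3.405) on $[1.89, 10.96]$ (mean 3.9489)
— right-skewed, matching the observation that the ratio rises steeply for
the largest vessels, with positive density at the lower edge so that the
expected sample minimum over 81 draws sits near the published range edge;
group 2 is Beta(1.037, 1) on $[0.27, 1.57]$ (mean 0.9317).

The published data give no absolute size distribution beyond the 70 $\mu m^2$
floor, so sizes are a generator decision: venule lumen equivalent radii span
4.5–12.5 $\mu m$ and correlate positively with the ratio (the largest vessels
carry the largest ratios); arteriole radii are uniform on 4–9 $\mu m$. These
choices keep every default vessel above the exclusion floor, as in the
reference data where all 112 analyzed vessels passed it.

Shape diversity is where the generator earns the diameter-ratio overlap that
real vessels show. With an area-equivalent diameter and a mean radial
thickness, $R_D$ is close to a monotone function of $R_A$ for near-circular
vessels, so disjoint $R_A$ supports would imply nearly disjoint $R_D$ ranges
— contrary to what is observed on real tissue, where single-location width
and thickness measurements scatter widely. The generator restores the
overlap through a physiologically motivated mechanism, venule collapse: a
collapsing venule loses lumen area while its wall is conserved, so a *low*
area ratio co-occurs with a flattened, slit-like lumen (polar-ellipse aspect
up to about 6.5) and with apposed-wall thickening (thickness modulation
0.2–0.5 phased onto the flattened sides). Arteriole-like vessels stay rounder
(aspect up to 2.5) with free-phase wall asymmetry. Under these defaults the
area-ratio ranges of the two groups remain disjoint while their
diameter-ratio ranges overlap in essentially every seed — the qualitative
signature the package is meant to reproduce.

What the generator does **not** emulate: electron-micrograph texture,
cell-scale wall substructure, oblique sections (`transverse_plane = FALSE`
masks can be ingested but receive no geometric correction), and the extreme
low end of published venule diameter ratios (a published minimum of 1.58
reflects single-location manual measurements that area-based estimators
cannot produce; synthetic venule $R_D$ bottoms out around 6). Consequently
the default populations contain no venules below the 4.97 subgroup
threshold, and the below-threshold re-test on default synthetic data reports
"not applicable" in the pipeline rather than reproducing the published
subgroup p-value — a known, documented divergence between the synthetic
conditions and the real data. Passing tests on synthetic data therefore
demonstrate estimator correctness and the separability structure, not
photorealism.

Reproducibility: per-vessel seeds derive from the master seed by a counter
scheme, so a vessel's geometry is stable under changes of population size,
identical `(spec, seed)` pairs give identical rasters and truth records, and
identical run configurations give byte-identical output files.

## Numerical choices

* Quadrature: 4096 angular nodes; trapezoidal rule on a periodic smooth
  integrand converges faster than any polynomial order, so truth values are
  exact to roughly machine precision.
* Rasterization: pixel-center membership, no anti-aliasing — unambiguous
  pixel counting. At the default 0.05 $\mu m$/px, measured areas sit within
  about 0.1–0.7% of truth, and area ratios within about 0.15%.
* Ray casting: 360 rays, samples every 0.25 px, boundary crossings placed at
  sample midpoints; constant-thickness rings are recovered within 2% at
  0.05 $\mu m$/px.
* The distance-transform fallback estimates thickness as
  $2\,\overline{d}_{medial} - 1$ pixel, correcting the half-pixel offset of
  pixel-center distances at each side.
* Exact rank-test enumeration is selected automatically up to $n_1 + n_2 =
  16$ (12,870 arrangements at worst); beyond that the tie-corrected normal
  approximation differs from the exact value by well under 0.02 for balanced
  samples of 8.
* Tie-breaking at the decision boundaries is inclusive ($\le$ arteriole,
  $\ge$ venule), so vessels measured exactly on a published range edge are
  classified into that range.

## A complete run

```{r, eval = FALSE}
cfg <- run_config(mode = "synthetic", master_seed = 11,
                  output_dir = "run_seed11")
report <- run_pipeline(cfg)
print(report)
#> vesselmorph run report
#>   vessels: 112 input, 0 excluded, 112 classified
#>   area-ratio classes: arteriole = 31, venule = 81
#>   area-ratio rank test: U = 2511, p = 3.31e-16
```

The run writes `measurements.csv`, `classifications.csv`, `truth.csv`,
`group_summaries.csv`, `tests.json` and a `manifest.json` carrying the config
hash, seed and the excluded-vessel accounting
(`n_input = n_excluded + n_classified`).

The test suite exercises the default conditions across 20 seeds (a few
minutes of compute); the per-example tests use coarser calibrations
(0.1–0.2 $\mu m$/px) and small populations, which the estimators' convergence
behavior makes representative.

## Known limitations

* Oblique-section correction is out of scope; non-transverse masks are
  excluded, not corrected.
* The classifier is a fixed empirical rule, not a trained model; its decision
  ranges come from one reference dataset (one aged beagle brain) and should
  be re-derived before use on other species or imaging modalities.
* The wall is one compartment; endothelium, basement membrane and intramural
  cells are not measured separately.
* Synthetic diameter-ratio distributions match real data qualitatively
  (overlap, venule tail to high values) but not in their published extremes,
  as discussed above.
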