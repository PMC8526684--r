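---
title: "Foveal pit morphometry from OCT segmentation maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Foveal pit morphometry from OCT segmentation maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foveametry)
```

## Scope and model

`foveametry` measures the central retina of macaque eyes from per-B-scan
semantic segmentation maps (vitreous / retina / choroid / sclera, one label
per pixel). The upstream segmentation network is explicitly out of scope:
the package's contract starts at label maps and ends at a per-eye record of
21 morphometric parameters plus the reference-database statistics over a
cohort of such records.

### Scan geometry

The default geometry mirrors a 20°×20° macular raster: 25 B-scans 221 µm
apart, 512 columns over 5.3 mm (10.352 µm/column), 512 rows after
nearest-neighbor rescale of the exported 512×496 px maps. The axial scale
defaults to 3.9 µm/row: published per-eye extremes on this protocol
quantize at 3.9 µm (e.g. 179.4 = 46 × 3.9), identifying the working scale
of the measurement software, while the nominal 1.9 mm / 496 rows would give
≈3.83. The scale is configurable (`scan_geometry()`), and every axial-mode
thickness the package emits is by construction an integer multiple of it.

Label maps are rescaled by center-aligned nearest-neighbor index mapping —
labels are categorical and must never be interpolated. The map is the
identity at the target size, so rescaling is idempotent.

### Artifact removal

In a clean map each compartment forms one large 4-connected region.
Non-maximal regions of a label are artifacts; a region whose entire
8-neighborhood carries exactly one other label is relabeled to that label,
and the pass iterates to a fixpoint so nested artifacts resolve. Three
choices here are deliberate, since raster connectivity and boundary
behavior are not dictated by the problem:

* **4-connectivity for regions, 8-neighborhood for enclosure.** Diagonal
  contact does not merge regions, but a diagonal leak cannot defeat
  enclosure either — the conservative pairing.
* **Largest region per label** rather than the four largest regions
  overall: equivalent when each compartment has a single dominant region
  (always the case here), and still well defined when a label is absent.
* **Regions touching the image border or bordered by ≥2 labels are left
  unchanged** and surfaced in a diagnostic count; removal is only defined
  for fully enclosed artifacts.

### Surfaces and smoothing

Per column of an artifact-removed map, the ILM is the first retina row
scanning downward and the outer retinal boundary the last; columns without
retina are missing. The per-B-scan ILM rows form a 25×512 surface that is
smoothed by an unweighted moving average over an 11-column × 5-B-scan
window. Windows truncate at raster edges and around missing cells and
renormalize by the number of cells actually present: padding would bias
depth exactly where the outermost thickness readings (T1/T9) sit. A
constant surface is preserved to machine precision, an interior impulse of
+55 spreads to exactly +1 (55/(11×5)), and linear ramps pass through the
symmetric window unchanged — these closed forms are asserted at 1e-12 in
the tests.

### Nulla localization

The nulla — the objective foveal-center landmark — is the deepest point of
the smoothed ILM (largest row index). Lowest points are identified at the
voxel grid's depth resolution: every cell within half a row (`depth_tol =
0.5`) of the maximal depth belongs to the tied set, whose unweighted center
of mass is rounded to the nearest cell (an exact half rounds toward the
lower index, a documented deterministic tie-break). This matters
quantitatively: with a ~10.35 µm lateral pitch and a 3.9 µm axial quantum,
the discretized floor of a realistic foveal pit (depth ≈ 140 µm, lateral
σ ≈ 300 µm) is flat to under 0.4 rows across roughly ±4 columns. An argmax
at float resolution would wander on that plateau under any boundary jitter,
whereas the plateau's center of mass is stable; on noiseless phantoms it
recovers the true center exactly for any grid center. The search region
defaults to the full raster; an optional central ROI exists for degraded
inputs but is off by default.

### Thicknesses and areas

On the central (nulla) B-scan, thickness columns sit at
`round(offset / 10.352)` columns from the nulla: ±48 columns per 500 µm
step, ±10 for the 100 µm umbo offsets, T1 nasal-most through T9
temporal-most. Two conventions are explicit because the source material
does not fix them:

* **Axial thickness is an inclusive row count** (`rpe − ilm + 1`) times the
  axial scale. The exclusive alternative differs by exactly one row and is
  a configuration away; the phantom's analytic truth uses the same
  convention so exact equality is assertable.
* **Display orientation** (which image side is nasal) flips between OD and
  OS and is device- and workflow-specific. The default — OD image-left =
  temporal, OS image-left = nasal — is an explicit, overridable
  `orientation_convention()`, never an assumption baked into the code. If a
  data source uses the mirrored convention, T1↔T9, TUn↔TUt and the area
  labels mirror accordingly.

The default mode measures along the A-scan (axial) direction: the printed
3.9 µm quantization of reference extremes is incompatible with oblique
measurement lines, and at the near-horizontal macular RPE an RPE-orthogonal
line coincides with the axial one. The `rpe_normal` mode implements the
orthogonal reading literally (local least-squares RPE tangent over ±250 µm,
inward normal to the ILM crossing, plus one axial quantum to keep the
inclusive convention) for users who want it.

Areas count retina pixels over half-open column intervals
(`A4 = [T4col, T5col)`, `A5 = [T5col, T6col)`, `AUn = [TUn, nulla)`,
`AUt = [nulla, TUt)`), scaled by the ≈40.37 µm² pixel footprint. Half-open
intervals tile: `area(a,b) + area(b,c) = area(a,c)` exactly. Two
discretization facts follow and are asserted in tests rather than smoothed
over: the rounded 500 µm step makes two of the eight spans 49 columns
instead of 48, and mirroring a half-open interval swaps one endpoint
column, so even a perfectly symmetric pit yields `A4 − A5 = (T6 − T5) ×
10.352 µm²`.

## The phantom: what it emulates, what it does not

`phantom_spec()` builds four stacked compartments with a Gaussian ILM
depression: `ilm(b,c) = base + round(depth_px · exp(−d²/2σ²))`, `d` the
physical distance to the pit center across columns and B-scans. Defaults —
peripheral thickness 351 µm (90 rows), pit depth 140 µm, σ = 300 µm — put
the central thickness near 210 µm rising past 280 µm at 500 µm
eccentricity, the scale of a cynomolgus macula. The analytic truth
(`PhantomTruth` record) is discretized with exactly the measurement rules
above, so on noiseless input the pipeline must reproduce it bit-for-bit,
and the acceptance suite checks precisely that on ten random centers and
depths (110–170 µm, spanning the plausible range of pit depths).

Noise is integer row jitter on the ILM only, independent per (B-scan,
column) — the smoothing stage exists to handle ILM raggedness, and the RPE
is left clean. Under 1-px jitter the recovered nulla stays within ±2
columns on the exact B-scan, and T5 within 2 axial pixels in the great
majority of replicates; a single-column jitter excursion of 3 rows (≈0.3 %
probability per eye) can push an individual T5 reading to 11.7 µm, which is
the expected tail of the rounded unit-sigma jitter rather than a pipeline
error.

Artifact injection places 4-connected discs of a wrong label wholly inside
a host compartment, with the disc's entire 8-neighborhood kept in the host
label — by construction exactly the class of artifacts the removal step is
defined on, so removal inverts injection pixel-exactly; a brute-force
flood-fill oracle, implemented independently in the test suite, agrees
with the removal operator on 200 randomized small maps.

The phantom does **not** emulate speckle or reflectivity (it starts at
labels), vascular shadowing, RPE curvature or tilt beyond an optional
per-column RPE row, pathology, or spatially correlated CNN failure modes.
Passing phantom tests therefore demonstrates the geometry and arithmetic of
the pipeline, not robustness to every real-world segmentation failure;
enclosed-blob artifacts are the only artifact class handled by design.

## Cohort statistics

The battery operates on tibbles of measurement records, one eye per row,
keyed `(eye_id, side)`:

* **Summaries** per side × sex × origin: mean, min, max, sample SD (n−1
  denominator), and boxplot statistics with type-7 quantiles. Whiskers
  follow the strict rule: the upper whisker is the last datum *smaller
  than* Q3 + 1.5 IQR (lower mirrored), data beyond whiskers are outliers;
  in a degenerate all-equal group the whiskers fall back to the quartiles
  and nothing is an outlier.
* **Pearson correlations** over all 21 coefficients, left and right eyes
  combined by default; zero-variance columns are rejected by name.
* **PCA** of T1–T9 on the **covariance** matrix of raw µm values, per eye
  side (paired eyes would correlate a pooled sample). Reference loading
  tables on this protocol print values around 5–12 — the thickness scale,
  far above unit-norm eigenvector entries — so loadings are reported as
  eigenvector × √eigenvalue, with PC1's sign fixed to a positive mean
  loading (an overall-thickness factor); the remaining components' signs
  are mathematically arbitrary.
* **MANOVA**: additive two-way (sex + origin, no interaction term in the
  model), Type II SSCP — the conventional choice for additive models on
  unbalanced data: each factor's hypothesis matrix is the residual
  cross-product of the model without it minus that of the full model.
  Wilks' Λ = det(E)/det(E+H); p-values via Rao's F approximation. Rows
  with unknown sex or origin are excluded before fitting.
* **ANOVA** per coefficient, same model and Type II tests, raw p-values
  plus significance categories at 0.001/9, 0.01/9, 0.05/9, 0.1/9 —
  Bonferroni division by the nine tests.
* **Multivariate outliers**: the upstream reference analysis removed one
  right-eye outlier identified from unshown diagnostic plots; as a declared,
  reproducible stand-in this package flags rows by Mahalanobis distance on
  T1–T9 against the χ²₉ 0.999 quantile. Removal is opt-in
  (`remove_outliers = TRUE` / `remove_multivariate_outliers()`) and logged.

`simulate_cohort()` generates records directly on the table scale for
exercising this battery: per-eye Gaussian-pit profiles with between-animal
variation, a center-thickness origin effect, an edge-thickness sex effect,
axial-quantized noise, and areas derived from adjacent thicknesses — which
reproduces the strong thickness–area and umbo–T5 correlations of real
cohorts. It makes no claim to reproduce any published cohort's numbers; it
exists so that effect detection, exclusion handling, and the engine's
oracles can be tested with known ground truth.

## Numerical choices and degenerate inputs

* Offsets snap to columns via `round()`; the half-down rule
  (`ceiling(x − 0.5)`) is used only where a deterministic tie-break is
  required (center-of-mass coordinates at exact halves).
* Smoothing windows must be odd; a 1×1 window is the identity; an
  all-missing neighborhood stays missing.
* A sampling plan that would leave the B-scan (nulla closer than 2000 µm
  to a lateral edge) errors naming the offending offset; partial records
  are never emitted.
* Wilks' Λ errors on a singular error matrix or a single-level factor;
  PCA requires more rows than variables; correlations require ≥3 rows.
* Measurement CSVs write thicknesses with one decimal (exact under the
  3.9 µm quantum) and areas with up to eight decimals (exact under the
  default pixel footprint, whose decimal expansion terminates).

## Problem sizes in the test and acceptance runs

The shipped suites validate at desk scale, chosen as the package's own
test design: 10 noiseless + 20 noisy phantom eyes end-to-end, 200
randomized 64×64 artifact maps against the brute-force oracle, a 374-eye
simulated cohort for the statistics battery, 300–1000 null simulations for
the ANOVA type-I rate (the observed rejection rate sits inside the binomial
95 % band around 0.05/9), and closed-form smoothing checks at 1e-12.

## Known limitations

* Only the inner and outer retinal boundaries are extracted; no
  intraretinal layer segmentation, choroidal surfaces, ETDRS-grid
  averages, en-face maps, or axial-length/refraction correction.
* The nasal/temporal orientation of exported B-scans must be supplied; a
  wrong convention mirrors the T/A labels silently (values are unaffected).
* The artifact remover only acts on regions fully enclosed by one label;
  border-touching or multi-label-bordered regions pass through (counted in
  diagnostics).
* BMP support covers the uncompressed 24-bit flavor; PNG is the preferred
  interchange format.
* Statistical replication of a published cohort requires that cohort's
  measurement table as CSV (`read_measurements()`); it is not distributed
  with the package.
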