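---
title: "Methods: GPS-weighted exposure, spirometry QC and wristband chemistry in elfpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GPS-weighted exposure, spirometry QC and wristband chemistry in elfpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

elfpipe implements the analytic chain of a week-long personal exposure
study in which each participant carries a GPS-enabled phone, wears a fresh
silicone wristband every 24 h to integrate PAH (polycyclic aromatic
hydrocarbon) exposure, and performs triplicate spirometry three times a
day. The package turns those three raw streams — plus a set of
environmental layers — into one quality-controlled record per participant
per day, and ships a fully seeded synthetic-cohort generator so every stage
can be validated against known ground truth.

# Time-weighted exposure from GPS traces

The central quantity is the time-weighted daily average of a per-fix
spatial exposure estimate. For a trace with fixes at times $t_1 < \dots <
t_n$ and a per-fix metric $v_i$,

$$\bar v \;=\; \frac{\sum_i w_i\, v_i}{\sum_i w_i},
\qquad w_i = \min(t_{i+1} - t_i,\; g_{\max}),$$

with two conventions the data force us to choose:

* **Last fix.** The final fix has no following interval; it inherits the
  previous (capped) interval, or $g_{\max}$ for a single-fix trace. This
  preserves total wear-time mass without inventing future data.
* **Gaps.** The cap $g_{\max}$ (`max_gap_s`, default 3600 s) treats
  hour-plus holes in a nominally 15-minute schedule as phone-off periods:
  a fix contributes at most one hour of representativeness, and the
  excess time joins no denominator. Missing per-fix values (e.g. a fix
  outside the raster extent) drop both the value and its weight.

The per-fix estimators are:

* **PM2.5** — the hourly value of the great-circle-nearest monitor at the
  hour containing the fix (floored). An absent hour falls back to the
  nearest available hour within ±3 h (ties to the earlier hour); monitor
  distance ties resolve to the lowest monitor id. These tie-breaks are
  arbitrary but documented and deterministic.
* **Point-source emissions** — the inverse-distance-weighted sum
  $\sum_s E_s / \max(d_s, d_0)^p$ over all emission sources. The exponent
  $p$ (`idw_power`, default 1) and floor $d_0$ (`idw_floor_m`, default
  10 m) are exposed in the configuration; the floor keeps a fix standing
  on a facility finite. A normalized variant (dividing by
  $\sum_s \max(d_s,d_0)^{-p}$) is available behind `idw_normalized`
  because the weighting's exact form is a modelling choice, not a law; the
  unnormalized sum is the default because it preserves additivity over
  sources.
* **Road length** — the total length of highway/expressway geometry
  clipped to a 100 m disc about the fix, a standard proxy for
  traffic-related air pollution. Clipping happens in a local azimuthal
  equidistant projection centred on each fix, so buffer distances are
  metre-true at any latitude; segment–disc intersection is closed-form.
* **NDVI by land class** — the sum of NDVI over raster cells whose
  *centres* fall within 250 m of the fix and whose land-cover class
  matches (urban, hay, grass, trees, wetlands, crops). Pixel-centre
  inclusion is chosen because it matches a brute-force pixel loop exactly,
  which is how the operation is tested.
* **Smoke density** — plume polygons carry a low/medium/high class mapped
  to 5/16/17 µg/m³. Containment beats proximity; a fix inside overlapping
  plumes takes the *highest* class (conservative exposure assignment). A
  fix outside all plumes takes the nearest plume's value within a
  configurable distance (default 50 km), else 0.
* **Wildfire distance** — great-circle distance to the nearest active fire
  point. Whether the daily summary should be the minimum or the
  time-weighted mean is a genuinely open choice, so both are emitted
  (`fire_km_min`, `fire_km_mean`).
* **Chronic NO2 / PM2.5** — nearest-cell extraction from annual surfaces
  at the *residence*, with a half-open (floor) pixel convention on cell
  boundaries.
* **Driving** — an interval counts as driving when its speed exceeds
  `driving_speed_ms` (default 8 m/s, comfortably above cycling) on at
  least two consecutive intervals; a single fast interval is treated as
  GPS jitter. Unobserved intervals (beyond the gap cap) break runs and
  join no denominator.

All spherical math uses a sphere of radius 6371.0088 km; bearings for the
local projection are computed with the spherical initial-bearing formula
so they are exactly consistent with the haversine distances.

# Day definition and joining

Days are local calendar days in the configured time zone. The exposure day
for a participant-day is the wristband wear interval when a band exists
(the band is the physical 24-h integrator, so its window is what the
chemistry measured); a calendar-day mode is provided for sensitivity
analysis (`day_alignment = "calendar"`). Overlapping wear intervals for
one participant are rejected. A record keeps its location and spirometry
fields even when the band was non-compliant; only the chemistry fields go
missing.

# Spirometry

Sessions are triplicate blows; QC follows the printed wording of the
protocol's rules, which fixes the bound directions:

* blow duration **≥ 6 s** ("minimum six second test" — inclusive);
* FEV1/FVC **< 1.00** (strict: "below");
* two largest FEV1 (and FVC) values within **≤ 0.150 L** (inclusive:
  "within") — applied to the full blow set when more than three blows
  exist, with the per-blow checks evaluated on the blows contributing the
  two largest FEV1 values;
* calibration: three 3 L-syringe strokes each within **± 0.15 L**
  (2.85–3.15 L). A 2.5 % rule (bound 3.075 L) is also printed for the
  same instrument; the two are inconsistent, so both are computed and
  reported and the overall pass follows the absolute rule, which is the
  one stated as the acceptance range.

The best value of a valid session is the largest FEV1; invalid sessions
yield a missing value rather than a downgraded one. Percent-predicted FEV1
is $100 \times \mathrm{FEV1}_{test} / \mathrm{FEV1}_{pred}$ with the
predicted value from the NHANES III reference polynomial
$b_0 + b_1\,\mathrm{age} + b_2\,\mathrm{age}^2 + b_{h}\,\mathrm{height}^2$,
keyed by sex, ethnicity group and age band (males split at 20 y, females
at 18 y). The coefficients are embedded as a versioned data table
(`hankinson_coefficients()`); tests assert properties (determinism, height
monotonicity, agreement with direct evaluation of the table) rather than
coefficient values, so the table can be swapped for another reference
without touching code. The afternoon slot is retained even though refined
protocols often drop it; slots are data, not code.

# Wristband chemistry

A band is compliant when worn 24 ± 8 h (16–32 h, bounds inclusive, from
the "± 8 h" wording), both on/off timestamps recorded, worn singly, and
returned in an air-tight seal; reason codes enumerate every failed rule so
`compliant ⇔ no reasons` holds by construction.

Concentration processing per analyte:

1. **Nondetect substitution** — a raw value below the instrumental LOD (or
   the `ND` token) becomes LOD/2. A value exactly at the LOD is a
   detection ("below" is strict).
2. **Background correction** — detected values have the batch blank level
   (mean of detected blank values per analyte; median available) removed,
   floored at 0; a corrected value that falls under the LOD is re-flagged
   and re-substituted at LOD/2.
3. **Surrogate correction** — division by the band's surrogate recovery
   fraction.

The additive (blank) correction precedes the multiplicative (recovery)
one; the exact published forms live in the cited laboratory methods, so
the implemented forms are flagged as conventions in the QC report and the
pipeline is built to be idempotent — re-running it on its own output
changes nothing. Detection status is decided on raw vs LOD and is
invariant under both corrections; summaries (detection counts, per-analyte
medians including the LOD/2 entries, the log10 participant-day × analyte
matrix) rely on that invariance. CCV batches pass when ≥ 80 % of the
62-analyte panel is within 20 % of truth, both bounds inclusive.

The panel registry ships 62 PAH names with default LODs that decrease with
molecular weight; the nine analytes historically detected in every band
are mandatory, the rest are configurable.

# Compliance table and correlation structure

The compliance report mirrors the study's feasibility metrics: wristbands
returned, returned bands compliant, sessions performed (of 3/day),
sessions in triplicate, sessions fully valid, and activity logs filled
daily. Raw fractions are kept alongside integer display percentages. The
expected study length is inferred from bands deployed per participant
(robust to wear-time drift across calendar dates) and can be overridden.

Correlations between daily location variables are pairwise-complete
Pearson coefficients over participant-days (the method is a reporting
choice; participant-week aggregation can be obtained by averaging records
before calling `correlation_matrix()`). The display ordering comes from
average-linkage hierarchical clustering on $1 - r$, which places blocks of
same-sign correlation contiguously; zero-variance variables are dropped
with a warning.

# The synthetic cohort

`generate_study()` emulates the full study at its native size — 10
participants × 7 days, a 15-minute GPS schedule (97 fixes per day, the
last fix held just before midnight so traces stay strictly increasing),
62-analyte chemistry, triplicate spirometry three times daily — inside a
40 × 40 km town on real WGS84 coordinates so the projection code paths are
exercised exactly as with real data. All randomness flows from one root
seed through a documented stream-splitting hash (`sub_seed(root, labels…)`),
so any participant-day or assay stream can be regenerated in isolation and
two runs with the same seed are byte-identical down to the output files.

Planted structure, recorded as ground truth:

* **Sessions** — a 6 % invalid rate (so ~94 % of sessions pass QC, the
  study's observed validity), planted either as short blows or as an
  inflated top FEV1; valid sessions are valid *by construction* (blow
  shortfalls ≤ 0.05 L, a session-level FEV1/FVC ratio with a clamped
  per-blow jitter keeping the FVC spread inside 0.150 L), so label
  recovery is exact, not statistical. Seven percent of scheduled sessions
  are skipped, matching the observed 93 % protocol compliance.
* **Bands** — a 10 % non-compliance rate (mostly wear-window violations,
  as observed), one expected lost band per 70, sequential wear intervals
  that never overlap.
* **Chemistry** — 9 core analytes always detected, 22 variably detected,
  the rest below LOD; the generator records exactly which draws fell
  below the LOD, so the substitution set is checkable exactly. Blanks are
  mostly nondetects (6 analytes with low detected levels), CCVs run every
  10 samples with planted failing batches, recoveries near 1.
* **Environment** — AR(1) hourly PM2.5 around 8 µg/m³ at two in-town
  monitors plus one ~40 km south; 5–20 log-normal emission sources; a
  highway grid; a blocky six-class land-cover raster at ~30 m with an
  NDVI surface; 0–3 smoke plumes and 0–2 fires (≥ 25 km out) per day;
  smooth chronic surfaces.
* **Correlation** — four latent daily location factors drawn from a
  planted correlation matrix with +0.9 blocks anti-correlated at −0.9.
  The draw uses an in-sample-exact multivariate normal
  (`MASS::mvrnorm(empirical = TRUE)`), so the planted structure holds
  exactly at the generated sample size and recovery checks measure the
  correlation/ordering code rather than Monte-Carlo noise.
* **Constant-environment mode** — every field spatially and temporally
  constant (constant monitors and rasters, one domain-wide medium plume,
  no sources, no highways, no fires). In this mode the daily truth values
  are known scalars and the pipeline must reproduce them to numerical
  precision; metrics whose fix-level value varies even in a constant
  field (IDW, road length, fire distance) are instead validated against
  explicit loop oracles.

What the generator does **not** emulate: atmospheric dispersion,
behaviourally rich mobility (only home/commute/workplace states),
instrument drift, or spatially correlated GPS error. Passing tests
therefore demonstrate the correctness of the estimators and QC logic
under the stated conventions, not the realism of any exposure level.

# Numerical choices and problem sizes

Degenerate inputs are handled explicitly: empty traces give all-missing
records (never zeros), all-missing values give missing averages, empty
source/road/fire layers give 0/0/missing respectively, and a single fix
carries one `max_gap_s` of weight. Test and validation sizes are chosen to
keep full runs quick while exercising the real geometry: oracle checks use
100 random 20-fix traces (tolerance 1e-9), 50 random chord offsets
(1e-6 of the radius), and 20 random rasters (exact); recovery runs use the
full 10 × 7 cohort; determinism uses a 3 × 3 cohort with a coarser
(~330 m) raster, since raster resolution affects runtime but no asserted
quantity.

# Known limitations

* The chronic surfaces are consumed, not fitted; no land-use regression is
  estimated.
* GeoJSON vectors and ASCII-grid rasters are the interchange formats; the
  package does not read projected CRSs — all coordinates are WGS84
  degrees.
* The cohort is far too small for exposure–health inference; the package
  deliberately stops at descriptive integration (records, compliance,
  correlations) and computes no health-effect estimates.
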