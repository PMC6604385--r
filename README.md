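# elfpipe

Analysis pipeline for week-long personal exposure studies that pair three
data streams per participant: a GPS time-activity trace from a carried
phone, a daily silicone wristband that passively absorbs polycyclic
aromatic hydrocarbons (PAHs), and triplicate hand-held spirometry three
times a day. It is written for exposure scientists and environmental
epidemiologists who need to turn those raw streams — plus public
environmental layers (monitor series, emission inventories, roads, land
cover/NDVI, smoke plumes, wildfire points, chronic pollutant surfaces) —
into quality-controlled participant-day records.

## What it computes

**Exposure.** For each GPS fix the package evaluates: nearest-monitor
hourly PM2.5; inverse-distance-weighted point-source emissions
`sum(E_s / max(d_s, d_0)^p)`; highway length clipped to a 100 m buffer (in
a metre-true local azimuthal equidistant projection); NDVI summed by land
class within 250 m (pixel-centre rule); wildfire smoke density from plume
polygons mapped low/medium/high → 5/16/17 µg/m³; and distance to the
nearest active fire. Daily values are time-weighted averages,

```
v̄ = Σ w_i v_i / Σ w_i,   w_i = min(t_{i+1} − t_i, max_gap)
```

so each fix counts for the time it represents, capped so phone-off gaps
don't leak into the denominator. A sustained-speed rule (two consecutive
fast intervals) classifies driving time.

**Lung function.** ATS-style session QC — blows ≥ 6 s, FEV1/FVC < 1.00,
two largest FEV1/FVC within 0.150 L, triplicate — plus 3 L-syringe
calibration checks (±0.15 L and 2.5 % rules). Valid sessions contribute
their largest FEV1, normalised to percent-predicted FEV1,
`100 × FEV1_test / FEV1_pred`, using embedded NHANES III reference
equations (sex × ethnicity-group × age-band polynomials in age and
height²).

**Wristband chemistry.** Compliance filtering (worn 24 ± 8 h, timestamps
recorded, worn singly, sealed), half-LOD substitution of nondetects,
blank (background) subtraction with re-substitution, surrogate-recovery
division, CCV batch QC (pass when ≥ 80 % of the 62-analyte panel is
within 20 % of truth), and detection summaries including the log-scale
participant-day × analyte matrix.

**Integration.** One record per participant-day (exposure day = wristband
wear interval), a study compliance table, a location-variable correlation
matrix ordered so same-sign blocks sit together, and activity-log
summaries.

**Synthetic cohort.** `generate_study()` produces a complete seeded
synthetic study (default 10 participants × 7 days, 15-min GPS schedule,
62-analyte panel) with recorded ground truth for every planted quantity —
invalid sessions, non-compliant bands, nondetect sets, constant-field
exposures, correlation structure — so the whole pipeline is testable
end-to-end. Same seed, byte-identical output.

## Worked example

```r
library(elfpipe)

cfg   <- study_config(seed = 1)
study <- generate_study(sim_config(), seed = 1, cfg = cfg)   # 10 x 7 cohort
res   <- run_study(study, cfg)

res$compliance[, c("metric", "numerator", "denominator", "percent_display")]
#>   metric                    numerator denominator percent_display
#> 1 wristbands_returned              70          70             100
#> 2 wristbands_compliant             63          70              90
#> 3 spiro_sessions_performed        195         210              93
#> 4 spiro_sessions_triplicate       195         195             100
#> 5 spiro_sessions_valid            184         195              94
#> 6 activity_log_days                69          70              99

sum(res$detections$per_analyte$detection_frequency > 0)
#> [1] 31        # analytes seen at least once across the cohort
median(res$records$band_detections, na.rm = TRUE)
#> [1] 20        # PAHs detected per compliant band
```

Reading the table: 195 of the 210 expected spirometry sessions (10
participants × 7 days × 3 slots) were performed, and 94 % of performed
sessions met every validity rule; 63 of the 70 deployed wristbands passed
the wear protocol, so 63 participant-days carry chemistry. Each
participant-day row in `res$records` holds the daily exposure metrics
(`pm25`, `tri_idw`, `road_m`, `ndvi_*`, `smoke`, `fire_km_min`,
`driving_fraction`, chronic values), per-slot `best_fev1_*`/`pct_pred_*`,
and band detection counts; `res$correlation` is the sorted correlation
matrix of the location variables.

The same pipeline runs from files: `read_study_bundle(dir)` reads the
CSV/GeoJSON/ASCII-grid file set that `simulate_study(dir, seed)` writes,
and `run_study(dir, cfg, out_dir = "out")` writes `daily_records.csv`,
`band_values.csv`, `compliance_report.csv` and
`correlation_matrix.csv`. A thin CLI wraps the same functions:

```sh
Rscript inst/cli/elf.R simulate --seed 17 --out study/
Rscript inst/cli/elf.R run --data study/ --out study_out/
Rscript inst/cli/elf.R qc-spiro --data study/ --out spiro_qc.csv
Rscript inst/cli/elf.R qc-bands --data study/ --out band_qc.csv
```

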