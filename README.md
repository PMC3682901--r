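# rtrecur

Pattern-of-failure analysis for radiotherapy: where did the recurrence
grow, and how much dose did it receive?

After (chemo)radiation of an abdominal tumor, local recurrences seen on
follow-up CT are the evidence base for adjusting target-volume margins and
dose prescriptions. Evaluating one case means registering the follow-up
scan to the planning CT, carrying the delineated recurrence into the
planning frame, computing its dose-volume histogram and descriptive dose
statistics against each treatment plan, and classifying its location
relative to the boost volume, the boost expanded by 1 / 1.5 / 2 cm, and
the 80% isodose volume. `rtrecur` implements that workflow end to end for
radiation oncology researchers working with DICOM-RT data — and ships a
geometric phantom generator with closed-form expected values, so the whole
toolchain is testable without any clinical data.

## What it computes

For each case (patient) with a planning CT, one or more follow-up CTs,
structure sets and per-plan dose grids:

* **Rigid registration** `T = (t_x,t_y,t_z,\ rp_x,rp_y,rp_z,\ r_x,r_y,r_z)`
  (translation, rotation point, intrinsic z–y–x Euler angles in degrees) of
  the follow-up CT to the planning CT by mutual-information maximization
  over a 3-level pyramid, with deterministic pre-initialization (intensity
  centroids + optional axial-angle hint) for oblique acquisitions rotated
  20–60°. Seeded and bit-reproducible; a manual override transform bypasses
  it.
* **Subvoxel voxelization** of contour structures: per-slice even-odd
  rasterization on refining subgrids (factors 1–8) until the volume changes
  < 0.5% between levels.
* **DVH and dose statistics** of the recurrence against each plan
  separately (sequential base + boost): `D_min`, `D_max`, volume-weighted
  median, recurrence volume, volume within the 80% isodose of the plan's
  prescription, with out-of-grid dose reported as "undefined" rather than
  silently zeroed. Composite sum-plan dose files are flagged and skipped,
  never mis-attributed.
* **Location classification**: coverage fraction and containment flag for
  boost, boost+1 cm, +1.5 cm, +2 cm (Euclidean margin expansion with
  anisotropic spacing), outfield volume, and the maximal extension beyond
  the boost surface in cm — 3D and the clinical worst-axial-slice variant.
* **Reports** in CSV and JSON (2-decimal ml/Gy, explicit nulls), DVH
  export, transform serialization with its convention stated.

## Worked example

A complete phantom case: a planning scene observed at follow-up under a
known 40° oblique acquisition with a 12 mm shift, and a recurrence
protruding 12 mm beyond the boost surface.

```r
library(rtrecur)

spec <- phantom_spec(transform = rigid_transform(12, -8, 6, rz = 40), seed = 1)
fx <- make_recurrence_fixture(
  boost_radius_mm = spec$boost_radius, extension_mm = 12,
  center = spec$target_center,
  z_planes = spec$origin[3] + (seq_len(spec$shape[3]) - 1) * spec$spacing[3])
make_phantom(spec, "phantom_case", recurrence = fx)

cfg <- case_config(list(
  patient_id = "phantom-01",
  planning_ct = "planning_ct", followup_ct = "followup_ct",
  structures = list(planning = "rtstruct.dcm",
                    followup = "rtstruct_followup.dcm"),
  plans = list(
    list(label = "base",  dose = "dose_base.dcm",  fractions = 25,
         prescribed_gy = 44.5),
    list(label = "boost", dose = "dose_boost.dcm", fractions = 5,
         prescribed_gy = 9)),
  registration = list(hint_deg = 40, seed = 0)
), base_dir = "phantom_case")

report <- run_case(cfg)
print(report)
```

```
<RecurrenceReport> patient phantom-01
  transform: automatic
  plan base  : vol 36.47 ml | in isodose 36.47 ml (100%) | min/med/max 44.50/44.50/44.50 Gy
  plan boost : vol 36.47 ml | in isodose 35.05 ml (96%) | min/med/max 3.06/9.00/9.00 Gy
<LocationClassification>
  boost        coverage   91.0%
  boost+10mm   coverage   99.8%  [within]
  boost+15mm   coverage  100.0%  [within]
  boost+20mm   coverage  100.0%  [within]
  outfield volume 0.00 ml; max extension 1.25 cm (3D), 1.25 cm (worst axial slice)
```

Reading it: registration recovered the 40° acquisition automatically (the
transform is in the report); the recurrence (36.47 ml, closed form
36.55 ml) received the full 44.5 Gy base prescription, 96% of it lies in
the boost plan's 80% isodose, and geometrically it is not contained in the
boost (91% coverage, below the 0.95 containment threshold) but is
contained from the +1 cm shell on, protruding 1.25 cm — the fixture was
built with a 1.2 cm protrusion. `write_report(report, "report.csv")`
serializes the row; `plot(report$plans$base$dvh)` draws the cumulative
DVH.

A thin command-line wrapper is installed with the package
(`system.file("cli/rtrecur", package = "rtrecur")`) with subcommands
`analyze`, `make-phantom`, `dvh` and `register` over YAML case files.

## Package layout

```
R/                  implementation (I/O, geometry, registration,
                    voxelization, DVH, metrics, phantoms, pipeline)
inst/cli/rtrecur    command-line entry point
tests/testthat/     unit, property and acceptance tests
scripts/acceptance.R  recomputes the headline numbers
vignettes/          methods vignette (models, conventions, limitations)
```
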