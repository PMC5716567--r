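# skindose

Skin (surface) dose estimation for external-beam radiotherapy.

## The problem

Epidemiologic studies of second cancers and other late effects after
radiotherapy need the dose to the skin at arbitrary body locations — often
decades after treatment, from records that contain little more than the
machine type, field size, whether a block tray was used, and the prescribed
Dmax ("given") dose. Treatment-planning systems model the skin poorly (the
buildup region is steep and planning CT voxels are too coarse), and they
cannot be rerun for historical cobalt and early linac treatments anyway.

`skindose` implements a general dosimetry system for exactly this setting.
It deliberately trades patient-specific accuracy for broad applicability:
every input is something a historical chart provides, and the target local
accuracy is the ±30% typical of general peripheral-dose systems. It is
aimed at dose reconstructionists and medical physicists supporting
epidemiology, not at treatment planning.

## The model

All surface doses `Ds` are expressed as a percent of the Dmax dose `Dm`.
With `FS` the equivalent-square field size (cm, isocenter plane), `TF = 1`
when a block tray is present (0 otherwise), and `x` the distance from the
jaw-projected field edge (cm, clamped at 12):

| Point | Megavoltage | Cobalt-60 |
|---|---|---|
| In-field, entrance | `6.63 + 0.926·FS + 0.5·FS·TF` | `12.9 + 1.85·FS` (tray has no effect) |
| 2 cm outside field, entrance | `−0.686 + 0.557·FS + 0.27·FS·TF` | `−1.17 + 0.894·FS` |
| Under a block, entrance | same as 2 cm outside | same as 2 cm outside |
| 0–2 cm outside, entrance | linear between the in-field and 2 cm values | idem |
| Beyond 2 cm, entrance | `(Ds/Dd)·Dd` with ratio `(FS+10)(x/150) + FS/100 + 1` | ratio `FS·x/85 + (FS−3)/10 + 1` |
| In-field, exit | `PDD(exit depth) × 0.85` | idem |
| Under a block, exit | `100 × 0.08 × 0.85 = 6.8` | idem |
| Outside field, exit | `Dd × 0.85` (or half the in-field exit dose on the diverged edge) | idem |
| Tangential surface | `65` | `65` |

`Dd` is the out-of-field dose at depth at the same distance from the field
edge, taken from user-supplied generic peripheral-dose tables or from a
built-in exponential fallback anchored at 1% of Dmax at 10 cm and 0.05% at
50 cm from the edge. `PDD` comes from a user-supplied percent-depth-dose
table. All nominal MV energies share one model; cobalt-60 is separate.
Every constant is overridable through `model_coefficients()` or a config
file.

## Worked example

An opposed-pair 6 MV mantle treatment, 30×30 cm fields with lung blocks on
a tray, 2 Gy given dose per beam, evaluated at the anterior field center:

```r
library(skindose)

beams <- list(
  beam_spec("ant",  "6MV", jaw_x = 30, jaw_y = 30, tray = TRUE,
            dmax_dose_gy = 2, exit_thickness_cm = 22),
  beam_spec("post", "6MV", jaw_x = 30, jaw_y = 30, tray = TRUE,
            dmax_dose_gy = 2, exit_thickness_cm = 22)
)
pt <- point_spec("chest_center",
  ant  = point_location("in_field", "entrance"),
  post = point_location("in_field", "exit", depth_cm = 22))
pdd <- read_pdd_table(system.file("extdata", "pdd_mv6_synthetic.tsv",
                                  package = "skindose"))
plan_dose(beams, pt, pdd = pdd)
```

```
Per-beam surface doses:
        point beam             rule percent_of_dmax dose_gy clamped
 chest_center  ant entrance_infield              49  0.9882   FALSE
 chest_center post     exit_surface              35  0.7004   FALSE

Totals per point (Gy):
        point total_gy
 chest_center   1.6886
```

The anterior beam deposits 49% of its 2 Gy Dmax dose at the entrance skin
(49.41% before report rounding); the posterior beam exits through the same
point, contributing its depth dose at 22 cm reduced by the 0.85 backscatter
deficit. The point receives about 1.69 Gy per 2 Gy fraction pair.

The two phantom validation scenarios bundled with the package rerun with

```r
run_validation("table3")   # pediatric phantom, 15x15 cobalt
run_validation("table4")   # adult phantom, 30x30 6 MV mantle
```

and report mean local differences of 22% and 21% against the TLD
measurements (mean absolute differences 2.7 and 4.8% of Dmax). The same
scenarios are available from the shell:

```sh
inst/cli/skindose validate table3
inst/cli/skindose compute plan.yaml -o out.csv
inst/cli/skindose coeffs --dump
```

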