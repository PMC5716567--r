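---
title: "The skindose surface-dose model: assumptions, parameters, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The skindose surface-dose model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skindose)
```

## Why a general model

Skin dose is the quantity that drives basal-cell carcinoma and other
skin-surface late effects, yet it is the quantity radiotherapy records
document worst. The dose at the basal layer (about 0.07 mm deep) sits in
the steepest part of the buildup curve, where treatment-planning systems
are unreliable and where historical treatments — cobalt-60 units, early
linacs, mantle fields — were never planned volumetrically at all. Dose
reconstruction for epidemiology therefore needs a model whose inputs are
only what a chart reliably contains: beam class, field size, block tray,
prescribed Dmax dose, and roughly where on the body the point of interest
lies relative to each field.

`skindose` implements such a system. Its design point is deliberate: local
accuracy of roughly ±30% (the accuracy class of general peripheral-dose
systems), in exchange for applicability to essentially any photon
treatment since the cobalt era.

## The model and its assumptions

All doses are percentages of the Dmax dose of the beam in question.
Absolute dose is `percent/100 × dmax_dose_gy`, summed over beams.

**Beam classes.** Surface dose varies little across nominal megavoltage
energies (6–18 MV), so all MV beams share one fit; cobalt-60, with its much
softer spectrum and shorter buildup, gets its own. `beam_class()` maps any
energy label onto the two classes.

**In-field entrance dose** grows linearly with the equivalent-square field
size `FS`: more collimator scatter and electron contamination reach the
skin from larger apertures. A block tray adds contaminant electrons in
proportion to field size — the tray factor term `0.5·FS` for MV beams. For
cobalt the tray term is a structural no-op: measurements show no effect
(if anything slightly negative), so `entrance_infield("cobalt", ...)`
ignores `tray` for every rule. Rectangular fields are reduced with the
Sterling rule `FS = 4·Area/Perimeter`; the validation geometries are
square, so this convention is unconstrained by them and is simply the
field-standard choice. For blocked fields `FS` is the *unblocked*
jaw-defined size, matching how the validation scenarios were computed.

**Under a block (entrance)** the point sees scatter but not primary beam,
which turns out to resemble the dose 2 cm outside the field edge; the
model reuses the near-field line. A published TLD measurement of 20–23% of
Dmax under a block brackets what the near-field line predicts for a
comparable field (about 20% at `FS = 25` with tray), which is the main
external support for this rule.

**Near field (0–2 cm outside the edge)** interpolates linearly between the
in-field value at the edge and the 2-cm fitted line. The fitted near-field
lines have negative intercepts; for fields below about 2 cm they predict
negative doses, which the package clamps to zero (flagged in the result).
The fit was never intended for such fields.

**Far out-of-field (beyond 2 cm)** doses are built multiplicatively: the
out-of-field dose at depth `Dd` (a quantity that generic peripheral-dose
compilations tabulate well) times a surface-to-depth ratio `Ds/Dd` that
captures how much hotter the surface is than depth outside the beam. The
ratio grows with field size and with distance from the edge up to 12 cm,
beyond which it is constant — hence the hard clamp `x = min(distance, 12)`.
The cobalt ratio formula dips below 1 for fields under 3 cm; the package
floors it at 1, since the surface cannot receive less than the underlying
depth dose in this regime.

One known internal tension: the cobalt ratio formula evaluated at
`FS = 40, x = 12` gives about 10.3, while the prose accompanying the model
states a cobalt maximum of about 7. The formula, not the prose, reproduces
the cobalt validation scenario (ratio 3.96 at `FS = 15, x = 10` matching
the 7.9% far-field cell), so the package implements the formula and
documents the discrepancy here rather than resolving it.

**Exit side.** The missing backscatter beyond the exit surface costs about
15% of the dose, so every exit rule multiplies by 0.85: the percent depth
dose at the exit depth in-field, `100 × 0.08` under a block (8% block
transmission, depth-independent), and `Dd` outside the field. A point on
the *diverged* edge of the exit-side field — the geometry opposed-beam
setups create, where a point 2 cm outside the entrance field sits exactly
on the exit field's edge — receives half the in-field exit dose.

**Tangential surfaces** (beam grazing the skin at 90° obliquity) are
assigned a flat 65% of Dmax for both classes. Obliquity is binary in this
model: a surface is either normal or tangential, and intermediate angles
are rejected rather than silently approximated, because chart records
cannot support an angle-resolved rule and the 65% value already
overestimates large-but-non-orthogonal angles.

**Legacy cobalt tray separation.** Old cobalt units had variable
tray-to-skin distance `h`; the electron-contamination dose follows
`0.25·h^(−0.44)·r^(0.72)` (a fraction of Dmax, adopted as a fraction since
that is how the quantity is described), with `r` the equivalent-circle
radius. The equal-area convention `r = s/√π` is the default
(`equivalent_circle_radius()`); equal-perimeter is available as an option.
Modern fixed-tray linacs never need this rule.

## Parameters

Every constant lives in `model_coefficients()` and can be overridden
there, or from a flat YAML/JSON file (`read_coefficients()`, or the
`model:` section of a plan config). Defaults are the published fits:

```{r}
model_coefficients()
```

Entrance slopes are %/cm of equivalent square; `exit_backscatter_deficit`
and `block_transmission` are dimensionless fractions;
`tangential_fraction` is % of Dmax; `ratio_distance_clamp` is cm. The
fitted range is `FS` up to 40 cm — larger fields compute with a warning.

## What the model does not compute itself

Two quantities come from outside the dose rules:

* **PDD at the exit depth**, from machine commissioning data
  (`pdd_table()` / `read_pdd_table()`, linear interpolation, no
  extrapolation).
* **Out-of-field dose at depth `Dd`**, from generic peripheral-dose
  compilations (`oof_model()` with a user table), or from a built-in
  exponential fallback `A·e^(−b·x)` with `b = ln(20)/40 ≈ 0.0749 cm⁻¹`
  and `A = 20^{1/4} ≈ 2.115`, the unique exponential through the two
  general anchor levels of 1% of Dmax at 10 cm and 0.05% at 50 cm from
  the field edge. The fallback carries no field-size dependence (its
  anchors carry none) and refuses distances of 2 cm or less, where the
  near-field rules apply instead.

## The bundled validation scenarios and the synthetic tables

`fixture_table3()` and `fixture_table4()` encode the two anthropomorphic
phantom irradiations used to validate the system — a pediatric phantom in
a 15×15 cm cobalt field and an adult phantom in opposed 30×30 cm 6 MV
mantle fields, both with block trays — together with the published
measured and calculated doses. `run_validation()` recomputes every cell
with the current model; with default coefficients it reproduces the
published calculated column cell-for-cell and the agreement statistics
(mean |local difference| 22% and 21%, mean |absolute difference| 2.7 and
4.8% of Dmax).

The per-beam region assignments in these fixtures are hand-assigned, as
the original validation did: the point "2 cm outside" the anterior field
lies *on the diverged edge* of the posterior field, and the 5 cm / 15 cm
points sit at slightly different distances from the two opposed fields
(4.6 and 15.4 cm on the posterior side). The package takes such per-beam
locations as explicit inputs rather than ray-tracing 3D geometry — a
deliberate scope decision, since chart-based reconstruction assigns
regions by hand anyway.

The PDD and out-of-field tables under `inst/extdata/` are **synthetic**.
The original validation used commissioning PDDs and generic
peripheral-dose data that are not distributed; the shipped tables are
smooth, physically plausible curves *calibrated so the scenarios reproduce
the published calculated cells* (for example, cobalt PDD 45.9% at the
16 cm exit depth, and an out-of-field depth dose of 2.0% of Dmax at 10 cm
from the edge of the cobalt field — twice the fallback's generic 1%,
which is within the spread of published peripheral-dose datasets). What
passing these fixtures shows is therefore that the *rule arithmetic and
dispatch* are correct, not that the bundled tables predict any particular
machine. Users doing real reconstruction must supply their own tables;
only the equation-level cells (in-field, near-field, under-block entrance,
under-block exit, tangential) are reproducible from package defaults
alone.

## Numerical choices

* Full floating-point precision everywhere internally; rounding to
  reporting precision only at the reporting boundary (`report_round()`):
  integers at ≥10% of Dmax, one decimal below 10, half away from zero —
  the convention the validation tables print.
* Percent outputs clamp to [0, 100]; exceeding 100% warns and caps (a
  surface cannot plausibly exceed the Dmax dose under this model), and
  every clamp is flagged in the result.
* Table lookups are linear and refuse extrapolation; asking for a depth or
  distance outside a table is an error, not a guess.
* Dispatch is total over valid locations: every (region, side) pair maps
  to exactly one rule, and a missing depth model fails with an error
  naming the gap rather than substituting the fallback silently.
* Output row order is deterministic (points, then beams, in input order),
  so identical configs produce byte-identical reports.

## Known limitations

* No couch, immobilization device, gown, wedge, SSD, or off-axis
  corrections: all deliberately out of scope, as they are rarely
  documented in historical records. Beams through a couch or mask can
  raise skin dose substantially; such plans need case-by-case judgment.
* Obliquity is binary; doses to surfaces at large non-orthogonal angles
  are overestimated by the 65% tangential rule.
* The fitted coefficients extend to 40×40 cm fields; beyond that the
  package extrapolates with a warning.
* Penumbra and MLC-shaped apertures are not modelled; the field edge is
  the jaw projection.
* The cobalt far-field ratio inconsistency described above.
* The bundled depth tables are illustrative stand-ins, not beam data.
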