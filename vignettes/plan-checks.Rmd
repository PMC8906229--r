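---
title: "Per-fraction plan checks for adaptive MR-guided radiotherapy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-fraction plan checks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apart)
```

## Why check the input, not the dose

In online-adaptive MR-guided radiotherapy the plan delivered today is not
the plan that was commissioned weeks ago: targets and organs at risk are
recontoured on the day's image, GTV→CTV→PTV margins are re-expanded, the
electron-density map may receive manual overrides, and the plan is
re-optimized — with the patient on the table and the clock running. The
standard safeguard, a secondary dose calculation, recomputes dose from the
same structures and densities the planning system used. It therefore
cannot see a deleted contour slice, a skipped margin expansion, or a
physically implausible override: garbage in, consistent garbage out.

This package implements a complementary, purely input-side check battery.
It consumes the four DICOM files of a fraction (original and adapted
RT Plan + RT Structure Set), compares them, and condenses the findings into
weighted alerts and a traffic light. The philosophy is deliberately
sensitivity-first: thresholds are low, false alarms are accepted, and the
light is advisory — a red fraction may be treated after review, but never
unreviewed.

## The checks and their parameters

**Identity.** Patient name, patient ID and plan name (RTPlanLabel) are
compared case-sensitively after whitespace normalization. A patient
mismatch (name *or* ID) and a plan-name mismatch each weigh 10 — either
alone pushes the light to red, as adapting the wrong plan is never
acceptable. RTPlanName is also read; the label is compared because it is
the field the operator sees.

**Volumes.** A structure's volume is the slice-prism sum
$V = \sum_z A(z)\,\Delta z$, where $A(z)$ is the net shoelace area of the
slice's polygons (a polygon nested inside another at even-odd depth is a
hole and is subtracted — standard structure-set semantics) and $\Delta z$
the slice spacing inferred per structure as the mode of its consecutive
z-differences (ties resolved to the smallest; adapted sets may be cropped,
so no global constant is trusted). No end-cap correction is applied; the
discretization bias cancels almost entirely in the *relative* volume
change, which is what the checks consume. A relative change beyond 30%
raises a weight-3 alert *per structure* — a fraction with three large OAR
changes accumulates 9. The 30% default is a deliberately broad,
organ-agnostic limit; it flags what deserves a second look, not what is
necessarily wrong.

**Gaps.** For each adapted structure the nominal spacing (mode of
z-differences) is computed and any consecutive jump above 1.5× that
spacing reports the intermediate missing positions (weight 5). The 1.5
factor is robust to float jitter yet catches every single-slice deletion.
Gaps are checked on the adapted set: that is where on-table recontouring
can lose slices. Intentional gaps alert too — by design; the clinical
record shows intentional and accidental gaps are indistinguishable without
review.

**Target chains.** Names matching `GTV/CTV/PTV` with a shared suffix
(`GTV2`–`CTV2`–`PTV2`; the pattern is a configurable regex) form a chain.
A chain is inconsistent (weight 2) if any of:

* **(a) sign rule** — the PTV change and the GTV change (CTV standing in
  when no GTV exists) have opposite signs, in either direction;
* **(b) spread rule** — the relative changes of any two members differ by
  more than 10 percentage points. The limit is read as a
  percentage-*point* spread: comparing raw cc changes across a 4 cc GTV
  and a 14 cc PTV would be meaningless;
* **(c) frozen-PTV rule** — GTV or CTV changed by more than 0.5
  percentage points while the PTV stayed within 0.5 points of unchanged.
  This is the signature of a skipped or misdirected margin expansion:
  GTVs are recontoured every fraction, so a PTV that does not move at all
  while its GTV does is suspect. The 0.5-point tolerance keeps float noise
  and trivial recontouring from triggering it; the same tolerance defines
  "a change" for the sign rule. Note the rule intentionally fires even for
  small inner changes (e.g. GTV −1%, CTV −2%, PTV exactly 0%): that exact
  pattern occurred clinically when the wrong GTV was edited and the stale
  PTV went through unnoticed.

For reassurance the sphere-equivalent margin
$m = (3V_\mathrm{PTV}/4\pi)^{1/3} - (3V_\mathrm{inner}/4\pi)^{1/3}$
is reported for both plans; on sphere fixtures with 1 mm slicing it
recovers a constructed margin to well within 5%.

One labeling subtlety: the severity table names this row "target volume
differences consistent", while the surrounding description alerts on
*inconsistency*. The weight is implemented on inconsistency — a consistent
chain raising an alert would be nonsensical — and the discrepancy is
documented here rather than silently papered over.

**Density overrides.** Informational, no weight: every override with its
relative electron density and priority, sorted by priority. Values at or
below 0 or above 3 are flagged as extreme (an override of 0.0 means
"vacuum", which even an air cavity is not). DICOM has no standard
override-priority attribute; the fixture writer encodes it in
ROIObservationLabel (`DENSITY_PRIORITY:n`) and the reader falls back to
observation order when the label is absent.

**Modulation complexity.** The machine's double-stack MLC (two opposed
leaf banks offset by half a leaf width; default geometry 34 pairs of
8.3 mm with a 4.15 mm offset, configurable) is collapsed to an artificial
single stack: the y-range covered by both stacks is partitioned at every
leaf boundary of either stack — half-leaf-pitch rows — and each row's
opening is $[\max(l_A, l_B), \min(r_A, r_B)]$, the *minimum united
opening*. Half-leaf pitch is the finest structure the geometry defines,
and the physical field is open only where both stacks are. On these rows:

* segment area (row widths × heights), subsegment count (connected
  components of open rows, adjacency requiring positive x-overlap),
* per-beam union area by interval merging,
* effective MU per beam $i$:
  $\mathrm{effMU}_i = \sum_j \mathrm{MU}_{ij}\,AA_{ij} \,/\, U(AA_{ij})$.
  The denominator is the union area of the beam's segment apertures; with
  any other reading the quantity would carry units of MU·cm⁴ and the name
  "effective MU" would be meaningless. effMU equals the beam MU exactly
  when every aperture fills the union and drops as modulation rises.
* Plan statistics: if more than 10% of segments are under 1 cm², an alert
  with formula weight (fraction% − 10) is raised; if more than 5% deliver
  under 5 MU, a weight-1 alert. The severity table splits the two
  thresholds this way (10% for area, 5% for MU) even though the prose
  description merges them into one sentence; the table is implemented.
  Machine delivery uncertainty rises sharply for sub-1 cm², sub-5 MU
  segments, which is why the smallest-area and smallest-MU segments are
  reported with their partner quantity for both plans.
* Total MU difference beyond 10% weighs |Δ%| − 10, using the absolute
  value: the table says "difference", and both directions matter.
  Subsegment totals are compared but carry no weight.

Formula weights are kept as real numbers — the table gives arithmetic
expressions and no rounding rule, and the fractional weights are what make
totals such as 10.1 (red) or 0.1 (orange) possible.

**Traffic light.** Weights are summed: 0 → green; above 9 → red;
everything in between → orange. The written rule says orange covers "1 to
9", but a formula weight can produce a positive total below 1 (an MU
difference of 10.1% weighs 0.1), and a raised alert must be visible — so
any positive total is at least orange. This is a deliberate
interpretation in favor of sensitivity.

## Reading the DICOM files

No R DICOM package is available in this stack, so the package carries a
minimal explicit-VR little-endian codec covering exactly the RT Plan and
RT Structure Set attributes the checks need (structure sets: ROI names and
numbers, planar contours, physical-property overrides; plans: beam
limiting devices, control points, leaf positions, cumulative meterset
weights, beam metersets). Per-segment MU is reconstructed as the
cumulative-weight difference times the beam meterset, with leaf positions
taken at the start control point of each segment — the step-and-shoot
dialect these machines use. The two MLC stacks are identified by their
leaf-boundary positions: the device whose first boundary is smaller is
stack A, a deterministic rule that needs no vendor-specific naming.
Written fixtures are verified against pydicom (an independent DICOM
implementation) in the test suite.

## The synthetic-data generator

`fixture_spec()`/`generate_pair()` build a valid original/adapted pair
from analytic solids — spheres, cylinders, boxes sampled to planar
polygons (72 vertices, 1 mm slicing by default) — plus target chains
realized as concentric spheres with analytically expanded radii, and
step-and-shoot beams whose rectangular apertures have exact areas on the
half-leaf row grid. Output is deterministic for a fixed spec: UIDs derive
from the seed and no timestamps are written.

The adapted pair differs from the original by benign recontouring noise —
OAR volumes scaled uniformly within ±2%, each chain's GTV by exactly ±2%
(random sign) with margins re-applied — and by whatever faults are
injected. The ±2% default is small against the ±50% intentional changes
seen clinically; it is chosen so that injected faults remain isolable in
tests while the no-change tolerances still face realistic jitter. Volume
scaling acts on in-plane dimensions where a z-extent change would add or
drop whole slices (a 10% discontinuity that has nothing to do with the
fault under test). Eleven fault kinds map one-to-one onto expected alerts,
from `delete_slice` → structure gap to `scale_total_mu` → MU difference;
`incident_suite()` packages nine of them into regressions of clinically
observed failure patterns, including the four margin incidents with their
reconstructed volume changes (+32/+16/−21; −55 with ≈+20; +19/+10 against
a frozen PTV; −1/−2 against a frozen PTV).

What the generator does *not* emulate: real anatomy (no concavities,
no touching structures, no deformable-registration artifacts), imaging,
dose. Passing tests therefore demonstrate that the checks compute what
they claim on known geometry and detect every injected fault class — not
that the clinical alert *rates* of any institution would be reproduced.
Clinical rates depend on patient mix and contouring practice and are
outside what synthetic data can validate.

## Numerical choices

* Contours are validated as simple polygons (vectorized proper-crossing
  test); self-intersection is an error, fewer than 3 points is a skipped
  contour with a warning, recorded in the read report.
* Slice grouping and spacing inference round z to 1 µm; DS attributes are
  written with 8 significant digits, so coordinates and MUs round-trip to
  well under the 10⁻⁶ mm/MU tolerance the domain model asserts.
* A row is "open" only if its interval length exceeds 10⁻⁹ mm; touching
  intervals (zero overlap) do not connect subsegments.
* Zero original volume makes a relative change undefined: the entry is
  flagged and alerts rather than dividing by zero. A zero union area makes
  effMU undefined: reported as such with a warning, no alert.
* Degenerate target chains (single member, undefined volumes) are noted
  in the report and excluded from consistency rules rather than guessed.

## Problem sizes in the tests

The suite exercises sphere/prism fixtures of 20–60 slices with 40–72-gon
contours, checks volumes against a 0.5 mm voxelization oracle (1%),
aperture and union areas against 0.1 mm rasterization (0.5%), subsegment
counts against an exact flood-fill partition, and runs the full pipeline
over 20 randomized fixtures per fault kind plus 50 fault-free controls
(100% sensitivity, 100% specificity required). The acceptance script uses
ten fixtures per fault kind and thirty controls. A single fraction check
on these fixtures completes in about a second.

## Known limitations

* Volume computation assumes planar, z-aligned contours; oblique
  reslicing is out of scope.
* The gap check keys on the per-structure modal spacing; a structure
  contoured at deliberately mixed spacings could mask a gap.
* Chain grouping is name-based. Exotic target naming conventions need a
  custom `target_patterns` regex in the configuration.
* The severity weights encode one institution's risk analysis; they are
  configuration, not truth, and transfer to other clinics only after
  local review.
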