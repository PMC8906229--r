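# apart

Automated per-fraction plan checks for online-adaptive MR-guided
radiotherapy.

## The problem

On an MR-Linac, the treatment plan is re-optimized daily while the patient
lies on the couch: targets and organs at risk (OARs) are recontoured on the
day's MR image, margins are re-expanded, density overrides may be edited,
and the plan is re-optimized — all under time pressure, and without any
possibility of a pre-treatment measurement. The vendor's secondary dose
calculation verifies that the dose of the adapted plan was *computed*
correctly, but it is blind to errors in its own input: a deleted contour
slice, a forgotten margin expansion, an implausible density override or an
excessively modulated plan all pass a secondary dose calculation unnoticed,
because the calculation is internally consistent with the wrong input.

`apart` fills that gap. It compares the original and the on-table-adapted
plan (a DICOM RT Plan + RT Structure Set pair each) and runs a battery of
checks on the *inputs* to dose calculation:

* **identity** — patient name, patient ID and plan name must match;
* **structure integrity** — deleted structures, missing slices within a
  structure (gaps), per-structure volume differences beyond a threshold
  (default 30%);
* **target-chain consistency** — GTV → CTV → PTV margin expansions must
  move together: opposite-sign changes of PTV vs GTV, a spread of more
  than 10 percentage points between chain members, or an unchanged PTV
  while GTV/CTV moved (the signature of a skipped expansion) are flagged;
  sphere-equivalent expansion radii
  `r(V) = (3V/4π)^{1/3}` are reported for reassurance;
* **density overrides** — every relative-electron-density override with
  its priority, implausible values flagged;
* **modulation complexity** — the double-stack MLC is collapsed into an
  artificial single-stack aperture (per half-leaf row, the intersection of
  both stacks' openings); from it: segment areas, subsegment counts, the
  fraction of segments below 1 cm² or 5 MU, the total-MU difference, and
  per beam *i* the effective monitor units

  &nbsp;&nbsp;&nbsp;&nbsp; effMU<sub>i</sub> = Σ<sub>j</sub> MU<sub>ij</sub>·AA<sub>ij</sub> / U(AA<sub>ij</sub>)

  where AA<sub>ij</sub> is the area of segment *j* and U(AA<sub>ij</sub>)
  the union area of the beam's segments — an open-field-equivalent MU that
  drops as modulation rises.

Every finding carries a severity weight (wrong patient or plan 10, deleted
structure 5, structure gap 5, volume difference 3, target inconsistency 2,
low-MU segments 1; MU difference |Δ%|−10 and small-segment fraction
frac%−10 as formula weights). The weights are summed into a traffic light:
**green** (0), **orange** (0 < total ≤ 9, review), **red** (> 9, strong
irregularity). The light is advisory: it directs the physicist's attention,
it does not decide.

Because no clinical data ship with the package, a fixture module generates
valid, deterministic DICOM pairs — spheres, cylinders and boxes sampled to
planar contours, rectangular MLC segments with exact areas — with eleven
injectable fault kinds, each mapped to the alert it must raise.

## Worked example

Reproduce the modulation incident from the regression suite — a plan whose
total MU rose by 10.1% and which contains one 0.66 cm² segment carrying
302.6 MU among five segments:

```r
library(apart)

suite <- incident_suite()
p <- generate_pair(suite$modulation_incident)
rep <- run_check(p$paths$original_plan, p$paths$original_rs,
                 p$paths$adapted_plan, p$paths$adapted_rs)
print(rep)
```

```
TRAFFIC LIGHT: RED (total alert weight 10.1)
Patient: FIXTURE^PATIENT [APT-0001]  Plan: AdaptFx01

Alerts:
  [SMALL_SEGMENTS      w= 10.0] 20.0% of segments are smaller than 1 cm2 (limit 10%); smallest: 0.66 cm2 at 302.6 MU
  [MU_DIFF             w=  0.1] total MU changed by +10.1% (2995.0 -> 3297.5 MU, limit 10%)

Volumes [cc]:
  Liver               33.45 ->    33.45  (  +0.0%)
  Stomach             11.30 ->    11.30  (  +0.0%)
  Bowel                9.07 ->     9.07  (  +0.0%)
  GTV1                 4.17 ->     4.17  (  +0.0%)
  CTV1                 7.22 ->     7.22  (  +0.0%)
  PTV1                14.10 ->    14.10  (  +0.0%)

Target chain '1': consistent (sphere margin 5.00 -> 5.00 mm)

MU: 2995.0 -> 3297.5 (+10.1%), subsegments 4 -> 5
Smallest segment: 0.66 cm2 at 302.6 MU; lowest-MU segment: 302.6 MU at 0.66 cm2
  beam 1: effMU 2544.3 (union 25.0 cm2, 5 segments, 3297.5 MU)
```

One of five segments is under 1 cm² (20%), so the small-segment alert
carries weight 20 − 10 = 10; the MU difference of +10.1% adds 0.1. The
total of 10.1 crosses the red threshold (> 9): the fraction must be
reviewed before treatment. `glance(rep)` gives the one-row summary,
`tidy(rep, "volumes")` the volume table, `autoplot(rep)` a volume-change
plot, and `render_report(rep, "json")` the full machine-readable report.

A shell entry point wraps the same pipeline
(`inst/cli/apart check --original-plan … --adapted-rs …`; exit code 0 =
green, 1 = orange, 2 = red, ≥ 3 = error).

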