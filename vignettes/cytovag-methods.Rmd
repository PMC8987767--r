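---
title: "Standardized determination of canine vaginal cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardized determination of canine vaginal cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytovag)
```

## The problem

Exfoliative vaginal cytology is a routine tool for estrous-cycle staging in
the bitch: epithelial cells shed from the vaginal mucosa are swabbed,
stained and classified, and the mix of cell types tracks the estrogen-driven
maturation of the epithelium. The practical difficulty is that published
definitions of the cell types disagree — diameter ranges, what counts as
cornification, and how the nucleus should look differ from author to
author — and inter-rater agreement on cell calls is correspondingly weak.
`cytovag` implements a fully quantitative, deterministic determination
procedure so that two evaluators (or one evaluator and a computer) given the
same measurements always produce the same call, together with the
statistical machinery to *measure* agreement and to *derive* the thresholds
from data.

## The flowchart classifier

Every cell is reduced to four features: the diameter (maximum caliper, µm),
the number of cornification lines (angular folds, a proxy for the grade of
cornification), the nucleus area (µm²) and a categorical nucleus state
(absent / eroded / demarcated). Classification walks a fixed decision path:

1. **Diameter.** A cell whose diameter does not exceed 20 µm is a
   **parabasal** cell, full stop. Only larger cells proceed.
2. **Grade of cornification.** Fewer than two cornification lines counts as
   "none or slight" and leads to the nuclear-area step; two or more lines
   ("moderate to significant") skip straight to nucleus visibility.
3. **Nuclear area** (non-cornified cells only). A nucleus of 79.5 µm² or
   larger makes the cell **intermediate**; smaller nuclei fall through to
   the visibility step.
4. **Nucleus visibility.** No visible nucleus → **squamous**.
5. **Nucleus degeneration.** A definable, demarcated nucleus with clear
   color difference from the cytoplasm → **superficial**; an eroded, only
   just visible nucleus → **squamous**.

Basal cells are deliberately not an output: they form the lowest epithelial
layer and are not collected by a normal swab, so a "basal" call on a smear
is treated as an evaluation artifact.

Three choices in this scheme deserve comment, because the sources leave them
open:

* **The 20 µm boundary is inclusive.** Only cells that *exceed* 20.0 µm
  leave the parabasal box, so a cell at exactly 20.0 µm is parabasal.
* **The nuclear-area threshold is the single value 79.5 µm².** Stated to
  one decimal, the exit rules "79.4 µm² or smaller" and "79.5 µm² or
  larger" leave the open interval (79.4, 79.5) formally unassigned for
  continuous measurements; we treat ≥ 79.5 as intermediate and everything
  below as not intermediate, which reproduces both printed rules exactly.
* **A large, non-cornified cell with no visible nucleus** has no measurable
  nuclear area, so the area step cannot be evaluated; we route such cells
  directly to the visibility step, where they become squamous. This is an
  interpretation — the flowchart's sources never describe this cell.

A cell at or below 20 µm that nevertheless shows cornification lines or an
altered nucleus is still classified parabasal, but the decision trace
carries a warning: in the validation of the diameter rule (200 measured
small cells) no such cell was observed, so one appearing in real data is
worth a second look. Every call records its complete trace (`step`,
`outcome` rows), which makes the classifier auditable cell by cell.

All three thresholds live in `classifier_config()` and can be overridden
programmatically or from YAML/JSON.

## Threshold calibration

The 79.5 µm² value is not arbitrary: it is the 95th percentile of nucleus
areas measured on cornified cells with a definable, demarcated nucleus
(i.e. superficial cells), a sample with mean 57.7 µm² and SD 13.8 µm².
`percentile_threshold()` reproduces this derivation on any sample: select
the measurable cells (at least two cornification lines, demarcated
nucleus), take the q-th percentile, report mean, SD, and threshold.

Numerical choices:

* **Percentile estimator.** Linear interpolation between closest ranks
  (R's `type = 7`, the default of `quantile()`), chosen because it is the
  most widespread convention and deterministic; the estimator type is an
  argument, so users can compare (the source of the published value is not
  stated).
* **SD convention.** Sample SD with the n−1 denominator. The published
  "±13.8 µm²" is taken to be an SD rather than a standard error: with
  n = 200 the SEM would be ≈ 1 µm², inconsistent with the visible spread of
  the published histogram.

Under a Normal(57.7, 13.8²) model truncated at zero the analytic 95th
percentile is ≈ 80.4 µm², bracketing the published 79.5; the acceptance
script recomputes this on 100,000 generated draws.

`validate_parabasal_rule()` implements the companion check for the 20 µm
rule: among cells measured below the cut-off, count those showing any
cornification or a non-demarcated nucleus. On the study's own material that
fraction was exactly zero; the function reports the fraction, so drift from
zero on new material is visible immediately.

## Inter-rater agreement

Agreement between `n` raters assigning `N` subjects to `k` categories is
measured by Fleiss' kappa. With `n_ij` raters placing subject `i` in
category `j`:

$$P_i = \frac{1}{n(n-1)} \sum_j n_{ij}(n_{ij}-1), \qquad
\bar P = \frac{1}{N}\sum_i P_i, \qquad
p_j = \frac{1}{Nn}\sum_i n_{ij}, \qquad
\bar P_e = \sum_j p_j^2,$$

$$\kappa = \frac{\bar P - \bar P_e}{1 - \bar P_e}.$$

`fleiss_kappa()` returns every intermediate quantity, not just κ, because
the per-subject agreement values `P_i` show *which* cells divide raters —
in the motivating survey, a single cell split 9/6/1 across intermediate /
parabasal / basal gives `P_i = 102/240 = 0.425`, immediately flagging it as
contentious. The test suite checks the closed-form `P_i` against a
brute-force count of agreeing rater pairs on a thousand random matrices.

Interpretation bands follow the conventional reading: κ below 0.40 is poor
agreement, above 0.75 good, 1.0 perfect, and everything from 0.40 to 0.75
(inclusive at both ends, since the quoted rule is strict on both sides)
moderate. Note that by this rule a kappa of 0.412 is (just) moderate, even
though such values are sometimes loosely described as poor; we implement the
explicit rule, which is the only operational definition available. Negative
kappa (worse than chance) is reported as-is and banded poor. When all
ratings fall in a single category the expected agreement is 1 and kappa is
undefined; this raises a classed error whose message still reports the
observed agreement.

Confidence intervals, weighted kappa and Cohen's two-rater kappa are out of
scope.

## The synthetic smear generator

There is no deposited image or measurement dataset to test against, so the
package carries its own data model: `generate_cell_table()` draws labeled
cells whose feature distributions encode what the literature and the
measurements above say about each class, and `render_smear()` turns a table
into an image with a ground-truth mask. This makes the entire chain —
generation, rendering, measurement, classification, staging — exercisable
end to end with known truth.

Feature priors (all configurable through `generator_config()`):

* **Diameters** uniform over the literature ranges: parabasal 10–20 µm,
  intermediate 20–50 µm, superficial and squamous 30–75 µm.
* **Nucleus areas** truncated normal: superficial mean 57.7 / SD 13.8 µm²
  (the measured distribution), truncated at 0; intermediate mean 95 µm²
  (consistent with the ">90 µm²" intermediate nucleus and the 38.5–95.0 µm²
  diameter-to-area conversion of the 7–11 µm range), SD 15, truncated below
  at the 79.5 µm² threshold; parabasal mean 60 / SD 10; squamous eroded
  remnants mean 30 / SD 8, truncated at 12 µm² (invented — squames carry at
  most the remains of a disintegrated nucleus).
* **Cornification lines**: parabasal none (the validated small-cell rule
  found not one cornified small cell); intermediate 0 or 1; superficial and
  squamous uniform 2–5.
* **Nucleus state**: demarcated everywhere except squamous cells, which are
  anuclear with probability 0.85 and otherwise eroded.

The distributional *forms* (uniform diameters, truncated normal areas) are
assumptions: only the superficial-area mean/SD and the range endpoints are
data-backed. Stage mixtures are likewise package defaults chosen to satisfy
the respective literature staging criteria rather than measured
compositions: anestrus 70/30/0/0 (parabasal/intermediate/superficial/
squamous), proestrus 20/40/35/5, estrus 0/0/30/70, early diestrus
20/40/30/10 with a high neutrophil rate. The estrus mixture together with
the 0.85 anuclear probability yields an expected anuclear fraction of
≈ 0.6, comfortably above the ">50 % anuclear squames" estrus criterion at
n = 200; none of these invented numbers is load-bearing, and all are
configurable.

A **margin buffer** (default 1 µm at the diameter boundary, 4 µm² at the
area threshold) keeps draws away from the decision boundaries, so that with
the default margin every generated cell is recovered exactly by
`classify_cells()` — the round trip is a package invariant, tested at
n = 5000. With the margin set to zero, draws can land on the boundary side
the label did not anticipate only through floating-point ties, so accuracy
stays ≥ 95 %.

### Rendering

Cells are drawn on a bright background (0.95) as filled regions whose
maximum caliper equals the recorded diameter: smooth rotated ellipses for
non-cornified cells, angular 8–12-vertex polygons (evenly spaced vertex
angles with bounded jitter, radial jitter 0.82–1.0) for cornified ones. The
jitter bounds keep the polygon star-shaped with a healthy inradius so the
nucleus disk always fits inside. Demarcated nuclei are dark disks
(intensity 0.20) of exactly the recorded area; eroded nuclei are the same
disks at low contrast (0.08 below the cytoplasm); cornification lines are
thin dark chords (intensity 0.35) parallel to a per-cell fold axis, placed
clear of the nucleus and spaced widely enough that measurement-side
blurring cannot merge them. Erythrocytes (6.5 µm pale discoids) and
neutrophils (3–4 small dark lobes) are drawn as clutter without mask
entries. Placement is rejection sampling of non-overlapping bounding
circles — overlapping cells are not generated by default because measurable
cells in practice are exactly the non-overlapped ones; the canvas auto-sizes
to ≈ 25 % packing when not specified. Gaussian pixel noise (SD 0.02) is
added last. Identical inputs and seed give byte-identical rasters.

The renderer is a geometric sketch, not a stain simulation: no Diff-Quick
color, no texture, no focus blur, no debris other than the two distractor
types. Passing the round-trip tests therefore shows that the measurement
code is correct *on this image model*, not that it is robust to real
stained smears.

## Morphometry

`measure_smear()` inverts the renderer: background estimation by the image
median, foreground where intensity drops 0.1 below it, connected-component
labelling, then per-region measurement. Exclusion rules mirror the usual
inclusion criteria for measurable cells: regions smaller than an 8 µm disk
are debris (this removes both distractor types by construction), regions
touching the border cannot be measured completely, and regions with convex
solidity below 0.8 are taken as overlapping cells. Each exclusion is
logged with its reason.

Per-region measurements:

* **Diameter** is the maximum Feret (caliper) diameter of the pixel set
  (+1 px for pixel extent), matching how a ruler or ocular scale is used on
  elongated cornified cells; an equivalent-circle option exists. The
  sources never define "diameter" geometrically — Feret is our convention
  and is documented as such.
* **Nucleus**: candidate pixels are those at least 0.06 below the
  cytoplasm level (the 75th intensity percentile of the region) after a
  σ = 1 px Gaussian blur; a morphological opening with a 5 px disc brush
  removes thin creases, and the largest remaining blob with area ≥ 10 µm²
  *and* PCA roundness ≥ 0.4 is accepted. The roundness condition matters:
  shallow blurred creases can survive the opening as elongated slabs, and
  without it an anuclear cell can grow a phantom nucleus. The final area is
  re-thresholded on the *unblurred* image at the mid-level between nucleus
  and cytoplasm — on the blurred image the half-contrast contour of a
  convex disk sits ≈ σ²/(2r) inside the true boundary, a bias of ≈ 1 µm²
  at these nucleus sizes that the raw-image refinement removes. On 100
  rendered superficial cells the mean measured area is within 2 % of truth.
* **Nucleus state**: absent if no blob qualifies; otherwise eroded or
  demarcated by Michelson contrast between the nucleus and cytoplasm
  levels against a 0.2 threshold. This operationalizes the qualitative
  "color difference between nucleus and cytoplasm" criterion and is only
  meaningful for this package's renderer.
* **Cornification lines**: thin dark components (0.15 below cytoplasm,
  outside the dilated nucleus blob) kept if their length reaches 25 % of
  the cell's Feret diameter, then merged when collinear (orientation within
  15°, lateral offset under 2.5 px). The length floor suppresses noise
  specks; the merge repairs creases split by occlusion.

The eroded/absent distinction is the least reliable measurement (shallow
remnants at low contrast), but it is also immaterial for classification:
both routes end in the squamous box. The full
generate → render → measure → classify loop recovers ≥ 90 % of labels at
n = 200 with default settings (in practice ≈ 98–100 %); residual errors are
dominated by intermediate cells whose measured nucleus area lands on the
wrong side of 79.5 µm² and by occasional spurious/missed creases.

## Cycle staging

`smear_profile()` aggregates a classified table into composition fractions;
`call_estrus()` evaluates one of three literature rule sets, with the
printed inequalities applied strictly:

* **antonov**: 100 % superficial (including anuclear squamous) cells *and*
  more than 80 % of cells with pyknotic or absent nuclei;
* **feldman90**: more than 90 % superficial keratinized epithelial cells;
* **kustritz**: 100 % cornification with more than 50 % anuclear squames.

The sources define these criteria differently and no adjudication exists,
so the package exposes all three and never declares one canonical — a smear
at exactly 90 % superficial cells is estrus-negative under `feldman90`
because the rule says "more than". "Pyknotic" has no separate flag in the
feature model; it is proxied by a demarcated nucleus with area below the
intermediate threshold, which is documented as a proxy, not an equivalent.

`call_diestrus_onset()` compares two consecutive smears: onset is called
when the superficial-plus-squamous proportion drops by at least 20 — read
as absolute percentage points, the conventional application — *and*
neutrophils are present in the current smear. A relative-decline mode is
available behind a flag because the wording is genuinely ambiguous.
Neutrophil presence is defined as a neutrophil-to-epithelial-cell ratio of
at least 0.05, a package choice.

Every call returns each criterion with its observed value and pass/fail, so
a verdict is never detached from its evidence.

## Problem sizes and reproducibility

The shipped tests generate all fixtures in code. Simulation sizes were
chosen to make the checks sharp but quick: 10,000 draws for mixture and
threshold distributional checks, 100,000 for the percentile calibration
(Monte-Carlo error ≈ 0.1 µm² at the 95th percentile), 200-cell smears for
full imaging-chain checks, 1,000 random matrices for the kappa oracle and
N = 2000 for the null-kappa check. All randomness flows from explicit
seeds; rendering is deterministic given table, config and seed.
`scripts/acceptance.R` recomputes the headline quantities from scratch with
a single user seed.

## Known limitations

* The published headline kappas of the motivating survey (0.412 for 16
  survey raters; 0.533 for the experienced subgroup; 0.858 for five raters
  using the flowchart) cannot be recomputed here because the underlying
  rating matrices were never published numerically; the package reproduces
  the *machinery* and its worked per-subject values, not those totals.
* The renderer and morphometry are calibrated to each other; no claim is
  made about real stained smears, whole-slide formats, or stain-specific
  color effects (eosinophilia under Papanicolaou/Shorr staining is out of
  scope).
* Staging rules are implemented as configurable literature rule sets; the
  flowchart itself was validated for cell determination, not staging, and
  ovulation-timing questions are explicitly beyond what composition rules
  can answer.
* Basal cells are not modeled at all, by design.
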