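---
title: "Quantitative CT aeration analysis for PEEP titration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CT aeration analysis for PEEP titration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peepct)
```

## The problem

In supine mechanically ventilated subjects with intra-abdominal hypertension
(IAH, sustained intra-abdominal pressure ≥ 12 mmHg), the cephalad shift of
the diaphragm collapses the dependent (dorsal) lung. Raising positive
end-expiratory pressure (PEEP) re-aerates that tissue, but the same pressure
acts on the non-dependent (ventral) lung, where it produces alveolar
overdistension. Quantitative CT resolves this trade-off regionally: each
voxel's Hounsfield-unit (HU) value measures the local gas/tissue mix, so the
proportion of collapsed and overdistended lung can be followed across a PEEP
titration, compartment by compartment. This package implements that analysis
chain — voxel classification, volumetric quantification, pressure–volume
(PV) curve modeling, and bedside titration-target selection — together with
a synthetic phantom generator so the whole chain is testable without animal
or patient data.

## Aeration compartments and quantification

Lung voxels are classified into four compartments by CT density:
overdistended (−1000 to −901 HU), normally aerated (−900 to −501 HU),
poorly aerated (−500 to −101 HU) and non-aerated, atelectatic tissue
(−100 to 200 HU). Internally the bins are half-open with lower-inclusive
edges at −900/−500/−100, which reproduces those integer ranges exactly and
stays well defined for interpolated, non-integer HU. In-mask voxels outside
\[−1000, 200\] are excluded from the compartment fractions but reported, so
compartment volumes plus the excluded volume always equal the mask volume.
Whether boundary values were rounded up or down in any particular clinical
software is generally unknowable; the half-open convention is this package's
fixed choice.

Gas and tissue are quantified with the standard linear mixture: voxel gas
fraction $\max(0, \min(1, -HU/1000))$, tissue volume fraction one minus the
gas fraction (so gas plus tissue volume equals the included volume exactly),
and tissue density $\min(1.2, \max(0, (HU+1000)/1000))$ g/mL — the 1.2 g/mL
cap keeps rare dense voxels near the +200 HU edge from inflating mass. No HU
smoothing or partial-volume correction is applied. Lung segmentation is
upstream: the package consumes masks, it does not create them.

For regional analysis the mask's bounding extent along the dependent axis is
cut into three equal-thickness slabs (ventral, medial, dorsal); remainder
voxels go to the ventral-most slabs first, so a 31-voxel extent splits
11/10/10. Equal thickness (rather than equal volume) is the simplest
reproducible rule and the one implemented. Sides are split left/right at the
mask's bounding-box midline. The dependent axis is fixed by convention as
the third array axis, index 1 most ventral; one fixed convention avoids
silent orientation flips between the generator and the analysis.

## Pressure–volume models, inflection points, optimal range

Each compartment's volume across the PEEP ladder is fitted with three
competing models:

* the four-parameter sigmoid $V(P) = a + b/(1 + e^{-(P-c)/d})$, with $a$ the
  lower asymptote, $b$ the signed span (negative for compartments that
  shrink with pressure, such as atelectasis), $c$ the true inflection
  pressure and $d > 0$ the width;
* the saturating exponential $V(P) = a + b(1 - e^{-P/\tau})$, the standard
  saturating respiratory PV form, chosen here as the fixed exponential
  family;
* the straight line $V(P) = a + bP$.

The best model is the converged fit with the smallest root mean square
between observed and fitted volumes — raw RMS, no degrees-of-freedom
penalty, which is a known bias toward the richer families and is documented
rather than corrected. Exact ties resolve to the more expressive family.

Fitting a four-parameter sigmoid to a five-point titration is weakly
identified, so the sigmoid is fitted by bounded Levenberg–Marquardt from a
deterministic multi-start grid: $c$ started at five equally spaced pressures
over the observed range, $d$ at 1, 3 and 6 cmH2O, $a$/$b$ from the volume
extremes; the best converged start is kept. Deterministic starts make the
fit reproducible without random restarts. $d$ is bounded to (0.1, 50) cmH2O
to exclude step-function and quasi-linear degeneracies at either extreme;
$c$ is loosely bounded to the observed range ± two range-widths. A fit whose
optimum pins a parameter to a bound, or whose $|b|$ collapses to zero, is
flagged *degenerate* and excluded from model selection — this is what makes
near-linear data fall through to the linear family instead of being claimed
by a sigmoid with an absurd width.

The tangent to the sigmoid at $P = c$ has slope $b/(4d)$ and meets the two
asymptotes at the lower and upper inflection (corner) pressures $c - 2d$ and
$c + 2d$. The **optimal CT inflation PEEP range** is the interval between
the lower inflection point of the atelectatic compartment's curve (above it,
most recruitable lung has been recruited) and the lower inflection point of
the overdistended compartment's curve (below it, the steep part of
overdistension has not begun). The bounds are reported in that fixed order
and flagged `well_formed = FALSE` when they cross — they are never silently
swapped. Fits are run on raw volumes by default; fractional rescaling of the
trajectory between the lowest and highest PEEP is available as an option and
leaves $c$ and $d$ unchanged (the rescaling is affine).

## Respiratory mechanics and titration targets

Static elastances use the two-point method: respiratory-system elastance
$E_{rs} = (P_{aw,insp} - P_{aw,exp})/V_T$ from plateau and total
end-expiratory airway pressure, chest-wall elastance
$E_W = (P_{es,insp} - P_{es,exp})/V_T$ from the esophageal pressures, and
lung elastance $E_L = E_{rs} - E_W$, so the partition holds exactly by
construction. Total end-expiratory airway pressure is set PEEP plus
intrinsic PEEP when the latter was measured, else set PEEP; whether
intrinsic PEEP should enter is a genuine ambiguity of two-point elastance
and the package simply uses the total pressure it is given.
$P/F$ is $PaO_2/FiO_2$ (mmHg); lung injury is present when $P/F < 300$
(strict inequality).

Best-PEEP selection takes the descending-limb values only (physiology and CT
are measured on the descending limb of the titration), summarizes multiple
subjects by the median per PEEP level, and returns the argmax or argmin over
the protocol's PEEP set. Exact ties resolve to the lowest tied PEEP — the
clinically conservative choice — and are flagged. Hysteresis is the
descending-minus-ascending difference per cell, summarized by median and
IQR.

Missing cells are imputed from average relative differences: a subject's
missing value at a cell is the mean of the other subjects' values there,
multiplied by the subject's mean ratio to the others across the cells where
it was observed. The averaging is per endpoint (not pooled across
endpoints): endpoints live on different scales, and per-endpoint ratios make
the rule scale-equivariant endpoint by endpoint. Cells with no donors or no
observable ratio are left missing and reported, never guessed.

## The synthetic phantom

The generator builds an ellipsoidal lung inside the grid (identical mask at
every PEEP) and assigns each voxel an opening pressure that rises linearly
with normalized depth $h$ along the dependent axis and with the transmitted
fraction of IAP:

$$g(h, P) = g_{min} + (g_{max} - g_{min})\,
  \sigma\!\left(\frac{P - P_{open}(h)}{w}\right),
  \qquad P_{open}(h) = \theta_0 + \theta_1 h + k_{iap}\,IAP,$$

with HU $= -1000\,g$ plus seeded Gaussian noise (default SD 30 HU — typical
scanner-noise magnitude, and sufficient for recovery tests). The defaults
are the study conditions used throughout the tests: PEEP levels 5, 12, 17,
22, 27 cmH2O; IAP 27 cmH2O with transmission $k_{iap} = 0.5$ (about half of
abdominal pressure reaches the pleural space, a literature-typical
transmission); $\theta_0 = -12$ cmH2O, $\theta_1 = 50$ cmH2O per unit depth,
$w = 3$ cmH2O, $g \in [0.03, 0.905]$; a 64×64×56 grid of 3 mm voxels giving
a ≈1.7 L lung. The `injury` flag lowers the achievable gas fraction and
steepens the opening-pressure slope in the dependent half only ($h > 0.5$),
mirroring the dorsal dominance of injury-related collapse.

Two properties of this model are worth stating plainly. First, it has the
right *directions* by construction: for fixed depth the gas fraction rises
strictly with PEEP, and for fixed PEEP it falls with depth, so atelectasis
shrinks and overdistension grows monotonically across the titration — the
qualitative behaviour the analysis is meant to detect. Second, its
*magnitudes* are not calibrated to any animal: because a single
$(g_{min}, g_{max})$ span drives every voxel through the same sigmoid, the
model cannot simultaneously reproduce a mild atelectasis decline and a
small overdistension fraction at realistic pressure scales. The chosen
defaults represent a severely collapsed lung (atelectatic fraction falling
from roughly 85% to 27% over the ladder, overdistension appearing only
above PEEP ≈ 17 and reaching roughly 11%). Passing tests on these phantoms
therefore demonstrate correctness of the analysis chain — conservation,
classification, monotone response, parameter recovery — not fidelity to any
particular species' regional mechanics. The phantom also deliberately omits
perfusion, gas exchange, heterogeneous tissue density, registration error
and scanner artefacts; physiology tables are statistical fixtures
(median × lognormal noise, optional phase offset), not hemodynamic
simulations.

## Numerical choices and degenerate inputs

* Nonlinear fits: Levenberg–Marquardt with box bounds, `ftol`/`ptol`
  1e−13, 200 iterations per start; deterministic start grids as above.
* RMS uses the $1/n$ (not $1/(n-p)$) denominator, matching its use as a raw
  goodness-of-fit comparator across families with different $p$.
* Constant-volume data: the sigmoid converges to $b \approx 0$ with $c$, $d$
  unidentifiable; this is flagged degenerate, and selection falls to the
  line.
* Fewer than 4 distinct pressures: the sigmoid is refused (under-determined)
  with an explicit error; the exponential needs 3, the line 2.
* Conservation identities (compartments + excluded = mask volume; gas +
  tissue = included volume) hold to floating-point accuracy; tests allow one
  voxel volume.
* All randomness (phantom noise, PV noise, physiology noise) flows from
  explicit seeds, and generators restore the caller's RNG state.
* Pressures are cmH2O everywhere; file readers accept mmHg with an explicit
  unit flag (1 mmHg = 1.36 cmH2O) and convert on read.

## Problem sizes used in the tests

Structural tests run on 20×20×18 phantoms; the study-condition checks
(conservation, monotone aeration across the ladder) use the default
64×64×56 noiseless phantom; corner-pressure recovery uses 200 simulated
five-point titrations with noise at 2% of the volume span. These sizes give
stable statistics while keeping the full suite under half a minute. The
acceptance script (`scripts/acceptance.R`) re-runs the best-PEEP selector on
the packaged median titration table, the full phantom→aeration→PV-fit
pipeline, and the recovery simulation, writing every quantity it computes to
JSON.

## Known limitations

* The segment partition is thickness-based, not volume-based; dorsal slabs
  of an ellipsoid contain less volume than medial ones.
* Model selection by raw RMS favours the sigmoid whenever it converges
  cleanly; the exponential and linear families mostly act as fallbacks for
  degenerate trajectories.
* The imputation rule assumes a multiplicative subject effect; endpoints
  that cross zero would need an additive variant, which is not provided.
* The best-PEEP selector optimizes one endpoint at a time; it does not
  combine targets into a composite score.
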