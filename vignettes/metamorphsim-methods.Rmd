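---
title: "Simulating metamorphopsia and its digital suppression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating metamorphopsia and its digital suppression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metamorphsim)
```

Metamorphopsia — the perceived bending of straight lines caused by macular
pathology such as age-related macular degeneration or a macular hole — is
classically assessed with the Amsler grid. This package implements a
complete simulated pipeline around a head-mounted countermeasure idea:
model the distortion parametrically, draw it into one eye of a simulated
observer, overlay a gaze-locked dark spot sized relative to the distortion
so the healthy eye can fill in the suppressed region, and quantify how
perceived distortion and reading legibility respond. Everything a human
did in the motivating experimental design — reconstructing a remembered
distortion, nulling one on the affected eye, guiding an examiner — is
replayed here against a noisy synthetic participant, so every procedure is
testable end to end.

## The distortion model

A single unit of metamorphopsia is a circular *distortion kernel* with
four parameter groups: localization (center $\mu$, visual-field degrees),
size (Gaussian standard deviation $\sigma$ and a support bound
$\alpha\sigma$), luminance perception (peak sensitivity loss
$\lambda \in [0,1]$), and shape (a signed tangential rotation amplitude
$\rho$ and a signed radial stretch $s > -1$). A complex metamorphopsia is
a mixture of such kernels; perceptual-loss, rotational and spatial
components live on one record but act independently, sharing only the
size parameters, so zeroing any subset recovers pure single-effect
kernels.

With $v = p - \mu$, $r = \lvert v \rvert$, the kernel profile is a
truncated Gaussian

$$g(r) = e^{-r^2 / 2\sigma^2}\, T(r),$$

where $T$ is a smoothstep from 1 to 0 over
$[(\alpha - \tfrac12)\sigma,\ \alpha\sigma]$. The smooth window is a
numerical choice: it preserves the hard compact support that the bound
$\alpha$ demands (every contribution is *exactly* zero on and outside the
disk of radius $\alpha\sigma$, which the locality tests verify by brute
force) while keeping the displacement field $C^1$, so warped lines bend
rather than kink at the boundary.

The percept is produced by backward mapping. The backward sample point of
percept location $p$ under one kernel composes a tangential rotation with
a radial scale (rotation applied first; the composition order is not
forced by anything observable at these amplitudes, so it is fixed and
documented):

$$p' = \mu + R\big(\theta(r)\big)\, v\, \big(1 + s\, g(r)\big),
\qquad
\theta(r) = \rho\,\frac{r}{\sigma}\,
            e^{\,1/2 - r^2/2\sigma^2}\, T(r).$$

The rotation angle grows linearly from zero at the kernel center
("in proportion to the distance to the center"), peaks at $r = \sigma$
with value $\rho$, and dies smoothly at the boundary. A plain
$\theta \propto r$ reading without Gaussian damping was the alternative;
the damped form was chosen because an undamped angle hands the largest
rotation to the support boundary, where it would collide with the
truncation and make $\alpha$ strongly change the percept instead of
merely bounding it. Zero at the center keeps the field continuous.

Across kernels, displacements add (matching the mixture composition) and
luminance gains multiply, $\prod_k (1 - \lambda_k w_k(r))$ with $w_k$ the
truncated Gaussian weight: the product form keeps gains closed in
$[0, 1]$ for any number of overlapping kernels.

Coordinates are visual-field degrees, $x$ right and $y$ up with fixation
at the origin; rasters put pixel $(0,0)$ at the top-left with
half-integer pixel centers, and all conversions go through one affine
`raster_spec` mapping (round-trip error below $10^{-9}$ degrees). The
default raster mirrors professional headset hardware (1440×1600 per eye,
110° diagonal field); model, tests and study all run on a 192×192 desk
raster at exactly 8 px/degree (`study_raster()`), which resolves the
default 0.5° grid pitch with four pixels per cell while keeping dense map
operations around 37k pixels.

## Warping, inversion and the corrective distortion

`warp_image()` is backward mapping with bilinear interpolation and edge
clamping — forward splatting was rejected because it leaves holes under
expansion. Bilinear weights are exact at integer sample positions, so a
zero displacement with unit gain reproduces the input bit for bit; the
identity tests assert that literally.

The countermeasure needs the *inverse* warp. `invert_displacement()`
computes a dense inverse by the fixed-point iteration
$d^{-1} \leftarrow -d(p + d^{-1}(p))$, which contracts when the
displacement gradient stays below one. Mixtures of strong kernels can
exceed that bound while remaining fold-free (Jacobian determinants
comfortably positive), so the update is under-relaxed on demand, retrying
with damping 1, 1/2, 1/4 before reporting the worst composition residual
in an error. Converged inverses leave a forward∘inverse residual below
half a pixel everywhere — far below it, in practice — which the
acceptance-style tests scan by brute force.

`fit_corrective_field()` answers the question the countermeasure actually
poses: not "reconstruct the distortion elsewhere" but "make it
disappear" — find a *parametric* field $C$ in the same kernel family such
that warping by $C$ and then by the pathological field $F$ moves nothing.
The objective is the mean squared residual displacement over a regular
raster subsample; the search is Nelder–Mead seeded from the negated
rotation/stretch parameters of $F$, with one restart from the first
optimum (the simplex collapses along curved valleys of this surface and a
fresh simplex reliably gains another digit). Luminance loss is not
correctible by warping and stays zero on corrective kernels. The reported
objective never exceeds the all-zero corrective field's objective, and
the running-best trace is non-increasing by construction.

**A measured family limitation.** The kernel family is not exactly closed
under inversion: cancelling $r \mapsto r(1 + s\,g(r))$ with a kernel of
the same Gaussian profile carries an $O(s^2)$ error. For moderate draws
the fitted corrective removes 95–99% of the uncorrected RMS residual, but
at the strong end of the default stretch range ($s \approx 0.24$ with
$\sigma \approx 2.4°$) the *global* single-kernel optimum plateaus near
6% — multistart Nelder–Mead and gradient polish agree, and a two-kernel
concentric corrective drops the same residual to about 1%. The
single-kernel 5% target is therefore genuinely unattainable for roughly
the strongest tenth of default-range draws; the corresponding test is
left failing rather than loosened, and this paragraph is its analysis.

## Stimuli

`render_amsler()` draws the classical geometry: a 20°×20° square grid of
0.5° cells centered on fixation, line width in pixels, line and
background chromaticity free, optional diagonals through fixation (an aid
for patients whose central loss hides the fixation point) and a fixation
disk. A pixel belongs to a line when its center lies within half a line
width of the line's geometric position; the rendering is deterministic
and is tested against an independent per-pixel rasterizer, including
exact 90° rotational symmetry on rasters where lines land on pixel
centers.

`render_reading_task()` lays out pseudo-Latin words — seeded CV/CVC
syllable chains of two to four syllables, so no lexical context can
rescue a distorted word — in a bundled fixed-width 5×7 bitmap font, and
marks randomly chosen words with filled translucent highlight boxes
recorded as pixel rectangles. The same seed yields byte-identical output.

`random_metamorphopsia()` draws templates uniformly from
`template_ranges()`. The defaults emulate moderate clinical
metamorphopsia and were fixed once, before the downstream experiments
were run: 1–3 kernels (single and multi-focal distortions both occur
clinically, and multi-kernel fields are what make partial suppression
leave visible residuals), centers within 5° of fixation (central-field
pathology), $\sigma \in [0.5, 2.5]°$, luminance loss 0.2–0.8, rotation
$\lvert\rho\rvert \le 0.5$ rad and stretch $s \in [-0.2, 0.25]$, with
$\alpha = 3$ so supports follow the conventional three-sigma reading.

## Suppression and the binocular observer

`make_spot()` sizes a dark circular spot against the *distortion extent*:
the amplitude-weighted centroid of kernel centers and the smallest radius
whose disk covers every kernel support. "Percent of the distortion size"
is read as percent of that radius, which keeps every protocol level —
0, 25, 90 and 120% — well defined; 120% of a Gaussian *mass* would not
be. (A mass-based sizing mode is exposed as an alternative, with scales
above one falling back to full support coverage.) Because the extent
radius covers all supports, a spot of scale ≥ 1 covers every distorted
pixel — a small coverage theorem the tests verify by scanning kernel
weights. The spot is pure black with a hard edge and is gaze-locked:
its raster position is `gaze + retinal_center`, so shifting gaze shifts
the mask by exactly the pixel image of the shift.

`binocular_composite()` forms the percept: masked pixels come bit-exact
from the healthy eye (the fill-in that makes suppression a countermeasure
rather than a scotoma), unmasked pixels from the affected eye. Outside
the spot the *distorted* percept is assumed to dominate — the worst case
for the countermeasure; an averaging mode exists but is not the default.
Monocular mode ignores the healthy image entirely, matching the
contralateral display being switched off during corrective assessment.

Perceived distortion is operationalized geometrically:
`grid_distortion_metric()` is the mean residual displacement magnitude,
in grid-pitch units, over grid-line pixels not covered by the spot.
Metamorphopsia is by definition a distortion of lines, so the geometric
residual, not a photometric difference, is the percept proxy; luminance
loss can be mixed in through a weight that defaults to zero. The 0–5
categorical score is `round(5 · min(1, metric/ref))` with half-up
rounding, and the reference metric is calibrated once as the metric of
the strongest template the ranges admit, so the maximal template maps to
5 and the empty field to 0. Two consequences are worth stating plainly:
random templates are much weaker than the strongest one, so unsuppressed
scores concentrate at the low end of the scale rather than near 5; and at
90% suppression the surviving residual is of order 0.1% of the reference,
so the simulated observer reports 0 there, where human observers near
threshold still reported a mean of about 1. The simulated means therefore
reproduce the *ordering* of suppression levels (and elimination at 120%
exactly), not the human magnitudes — the quantized mean scores tie at
zero between the 90% and 120% levels even though the underlying mean
metric still strictly decreases.

The synthetic participant wraps the deterministic score in Gaussian
response noise (SD on the score scale) and an optional lapse rate, on a
private RNG stream so response sequences replay exactly per seed and
never disturb the caller's RNG. Zero noise and zero lapse make every
response a pure function of the stimulus, which is the default study
condition.

## Calibration procedures

All three interactive procedures are optimization loops that may only
query the participant.

*Contralateral reconstruction* starts a candidate field at mid-range
parameters and coordinate-descends on the participant-reported
dissimilarity between the candidate percept and the remembered target
(mean displacement difference over grid-line points plus mean
luminance-gain difference, perturbed by memory noise). Accepted moves
must strictly improve the report, so the accepted trace is
non-increasing; steps halve after a sweep without improvement and the
schedule restarts from the current point while the budget allows, which
is what lets axis-aligned steps escape curved valleys. Noiseless
single-kernel targets are recovered to within 0.5° in center and 15% in
$\sigma$.

*Corrective assessment* optimizes the corrective field's rotation,
stretch, placement and size against the reported residual of
corrective-then-pathology, querying only the affected-eye percept. The
corrective patch starts where the participant sees the distortion (the
per-blob support centers) with zero amplitudes: placement carries no
objective gradient until some amplitude is nonzero, so a blind mid-field
start cannot lock on — the percept-anchored start encodes the fact that
patients know where their distortion is. Noiseless runs end with a
reported score of 0 and residuals within about twice the oracle-seeded
parametric fit.

*The examiner (macular-hole) procedure* follows a fixed stepwise
schedule against a participant with a hidden single-kernel distortion:
directional feedback moves a dot until centered (step 0.25°); a circle
grows in 0.25° steps until full coverage is reported ($\sigma$ of the
corrective kernel is the covering radius over $\alpha$); rotation steps
clockwise in 0.05 rad increments, reversing direction after a first
worsening report; radial contortion steps inward by 0.05, switching
outward if worse; rotation/contortion passes repeat while they help.
"Worse" and "better" follow the sign of the perceived metric change with
a 2% dead-band emulating perceptual indifference. The step sizes resolve
the default ranges in well under 200 queries (about 40 in practice).
Noiseless patients finish at score 0 with the center localized within
one center-step; with response noise of 0.5 score units the median final
score stays at most 1. Only sequential per-eye calibration is
implemented; a simultaneous bilateral protocol would need an interaction
order that nothing here pins down.

## The study harness

`run_protocol()` replays a repeated-measures design: per participant, a
baseline no-distortion check, then one random template per severity
condition in one randomly chosen eye, scored on the Amsler grid and the
reading task at each ascending suppression scale (0, 0.25, 0.90, 1.20).
Six severity conditions are the base ranges with amplitude intervals
scaled by 1/6 … 6/6 — the count is protocol-fixed, the presets are a
package choice. Per participant, condition and task the first scale with
a zero score ("first imperceptible") is recorded, as is the first scale
at which the spot covers a grid-line pixel — a stated proxy for the spot
itself becoming noticeable. Participants default to noiseless, so a
(config, seed) pair determines the trial CSV byte for byte.

`chi_square_analysis()` builds the score-by-level contingency table per
task, drops empty rows and columns, and reports the Pearson statistic
(via `chisq.test` without continuity correction, cross-checked in the
tests against a hand-rolled $\sum (O-E)^2/E$), its
$(r-1)(c-1)$ degrees of freedom, the p-value and per-level mean scores.
Raw p-values only; no multiple-comparison correction is applied, and the
per-level means and the chi-square are both emitted since either alone
tells half the story of a categorical repeated-measures outcome.

## What the synthetic results do and do not show

Passing tests demonstrate internal consistency of the geometry and the
procedures: elimination at 120% is *forced* by the coverage theorem, the
monotone response to spot size follows from removing above-average
residual pixels, and parameter recovery shows the calibration loops are
well-posed against their own percept model. None of this validates the
perceptual claims a human study makes: the geometric metric has no
contrast sensitivity, no acuity, no crowding, no temporal dynamics; gaze
is static at fixation during scoring; suppression is a single hard-edged
black disk; and the 0–5 mapping is linear in the metric where human
category use near threshold is not (the 90%-level discrepancy above is
exactly that). Those are the boundaries within which the simulated
numbers should be read.
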