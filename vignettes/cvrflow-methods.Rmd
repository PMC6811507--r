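---
title: "Quantifying cerebrovascular reactivity from 4D flow MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cerebrovascular reactivity from 4D flow MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

Cerebrovascular reactivity (CVR) is the capacity of the cerebral circulation
to increase flow when arterial CO2 rises. A hypercapnic challenge raises
end-tidal CO2 (ETCO2, the breath-by-breath surrogate for arterial CO2) in
steps — room air, then 4 % and 6 % inspired CO2 — while velocity-encoded
(4D flow) phase-contrast MRI measures blood velocity in all three directions
across a volume covering the major intracranial arteries: both internal
carotids (ICA), both middle cerebral arteries (MCA, M1 segment) and the
basilar artery (BA).

Because hypercapnia also raises blood pressure, flow is converted to
cerebrovascular conductance

$$\mathrm{CVC} = \frac{\mathrm{flow}}{\mathrm{MAP}} \times 100
\quad \left[\tfrac{\mathrm{mL/min}}{\mathrm{mmHg}} \times 100\right],$$

and CVR is the ordinary least-squares slope of CVC against ETCO2 across the
conditions, per vessel and globally (global flow = left ICA + right ICA +
BA). A brain-volume-corrected variant divides global flow by the subject's
GM + WM volume (liters) before the fit. Because the MCA may dilate under
CO2 — which biases any velocity-only technique — the pipeline also reports
vessel cross-sectional area (CSA) and its change between normocapnia and
the top condition.

`cvrflow` implements the full chain from decoded velocity volumes to these
statistics, and — because no public reference dataset accompanies this kind
of study — ships a synthetic flow phantom whose ground truth is analytic,
so that every stage is verifiable end to end.

# The phantom

Vessels are tubes (polyline centerlines, radius $R$) carrying laminar
Poiseuille flow: the velocity $v(r) = 2\bar v\,(1-(r/R)^2)$ along the local
tangent, so that volumetric flow is exactly $\bar v \pi R^2 \times 60$
mL/min and CSA is $\pi R^2$. Fields are rendered directly in image space on
an isotropic grid (0-based voxel indices, voxel-center convention, world
position = index × voxel size); each voxel is supersampled 4× per axis and
averaged, which reproduces partial-volume blur at the lumen wall. Radial
k-space acquisition is not simulated: the analysis consumes reconstructed
volumes, so the phantom produces them directly.

The acquisition model is phase-contrast encoding per axis,
$\phi = \pi v / \mathrm{Venc}$ wrapped into $[-\pi, \pi)$ with Venc = 80
cm/s, optional smooth background phase offsets
$\phi_{bg} = a_0 + a_1 x + a_2 y + a_3 z$ (the artifact that eddy-current
correction removes), and independent complex Gaussian noise added to the
signal $m e^{i\phi}$ of each encoding, with SNR defined on the vessel
magnitude (vessel = 1, static tissue 0.3 by default). Decoding
($v = \mathrm{Venc}\,\phi/\pi$) then yields volumes carrying exactly the
artifacts the preprocessing stage must remove: wrap-around aliasing where
$|v| > \mathrm{Venc}$, spatially smooth velocity offsets, and noise with
per-component standard deviation $\mathrm{Venc}/(\pi\,\mathrm{SNR}\,m)$.
Steady flow is the default; an optional sinusoidal modulation over the
cardiac phases (time-average equal to $\bar v$) models pulsatility, since
all analysis here is of time-averaged quantities.

The simulated hypercapnia study fixes the physiology at the young-adult
protocol values: ETCO2 40 / 47 / 49 mmHg and MAP 94 / 93 / 96 mmHg across
normocapnia / 4 % / 6 % CO2 (HR 53 / 56 / 58 bpm, SpO2 98 %). Values the
protocol does not pin down were chosen once as physiologically typical and
are not tuned: normocapnic global flow 640 mL/min split 37.5 % per ICA and
25 % BA, each MCA carrying 23.44 % of global flow; ICA radius 0.20 cm, BA
radius 0.16 cm, MCA CSA 0.069 cm² (radius 0.148 cm); SNR 20; grid
60×60×48 at 0.036 cm isotropic, which puts ≥ 8 voxels across the MCA
diameter. Per-condition vessel flows are set so that true CVC lies exactly
on a programmed line against ETCO2 (default slope 5 CVC-units/mmHg); since
each vessel carries a fixed fraction of global flow, per-vessel CVC lines
are exact as well. At the top condition the MCA radius is scaled so CSA
rises 4.35 % (0.069 → 0.072 cm²). The truth ledger records every flow,
CSA and slope analytically.

```{r}
library(cvrflow)
study <- simulateCVRStudy(studySpec(trueSlope = 5, seed = 1L))
res <- analyzeStudy(study, params = list(gm = 0.72, wm = 0.48))
res$cvr
```

# Preprocessing

**Aliasing.** Velocities beyond Venc wrap by $2\,\mathrm{Venc}$. Two
complementary detectors correct whole wraps:

* a *voxel rule* — a voxel whose component differs from the median of its
  26-neighborhood by more than Venc is shifted one wrap toward the median —
  which handles isolated aliased voxels; and
* a *region rule* — connected regions bounded by 6-neighbor velocity jumps
  exceeding Venc are shifted by the whole number of wraps that minimizes
  the mean jump across their boundary.

The region rule exists because a deeply aliased jet core is *smooth
inside*: only its rim is visible to any local detector, and local
correction stalls where corrected and uncorrected neighbors differ by just
under Venc. Treating the core as one region recovers it wholesale; on the
90 cm/s jet at Venc 80 the decoded field is restored to machine precision.
Corrections are single-region, whole-wrap shifts, and both stages leave
alias-free data untouched, so the operation is idempotent. Velocities with
more than one unresolved wrap level inside a single smooth region would
need the boundary-jump quotient to exceed 1.5 wraps and are out of scope
(at Venc 80 cm/s intracranial flow does not approach 3×Venc).

**Background/eddy-current offsets.** Static tissue is detected as voxels
with magnitude at or above the 5th percentile and (component-wise
box-smoothed) velocity norm below 5 % of Venc; smoothing the components
before the norm matters because rectified noise otherwise inflates the
norm far above the threshold at realistic SNR. A first-order 3-D polynomial
(constant + linear, matching eddy-current phenomenology; order 2
available) is fitted per axis to the static voxels by least squares and
subtracted everywhere. Offsets are reported in decoded-velocity units.

# Geometry: angiogram, segmentation, centerlines

The PC-MRA angiogram is the standard product, time-averaged magnitude ×
velocity norm. Segmentation is thresholding plus removal of 26-connected
components under 27 voxels. Four threshold rules are available, and the
choice is consequential on fading-edge (Poiseuille) tubes:

* `otsu` — the classical two-class criterion. On an angiogram whose tube
  intensity falls linearly to zero at the wall, the between-class optimum
  sits near 2/3 of the peak, truncating the lumen to about two thirds of
  its area and clipping ~10 % of the flux. It remains available (and is
  the op's default) but is not what the study pipeline uses.
* `background` — $k\hat\sigma$ (default $k = 3$), with $\hat\sigma$ the
  noise floor estimated from the image median via the $\chi_3$ median
  (velocity-norm noise has three Gaussian components). This keeps slow
  near-wall flow while staying above the percolation regime of the noise;
  it is the study pipeline's default.
* `relmax` — a fraction of the maximum intensity (default 2 %), the
  noise-free analogue of `background`, used by the validation phantoms.
* `percentile` / `fixed` — explicit alternatives.

Centerlines are extracted by medialness-weighted geodesics rather than
topological thinning: within each component, Dijkstra paths between
automatically detected tips are traced with edge cost proportional to step
length divided by the squared distance-transform value, which pins the
path to the lumen axis; branch paths are added while some voxel lies
farther from the centerline than the local radius explains, with a
deliberately generous margin and a minimum branch length so that noise
blobs attached to a vessel cannot spawn false branches (a false branch
cuts the through-vessel at a false junction); path ends running through
near-zero-radius mask (noise tails above threshold) are pruned. Sequential
voxel-peeling thinning was evaluated first and rejected: on even-width
tubes its deletion order "zips" along two-voxel-wide ladders and collapses
whole segments, and subfield variants leave endpoint spurs; the geodesic
formulation is deterministic, centered by construction, and robust on
tubes and bifurcations, which is the geometry this pipeline measures.

Labels are assigned from user seed points (world cm): each label takes the
skeleton branch (component after cutting at junctions) nearest its seed,
ordered from the branch end nearest the seed. Tangents are central
differences of the moving-average-smoothed path (window 5 nodes).
Measurement nodes exclude: nodes within k = 2 steps of a junction, within
m = 3 steps of an endpoint (both configurable; the removal is stated
practice, its extent is this package's choice), nodes whose local
distance-transform radius falls below 75 % of the vessel median (such
nodes sit where the lumen is truncated — vessel ends and mask tails — not
in open tube), and nodes on path stretches whose tangent opposes the
path's mean direction (a path that folded back over an attached noise
blob). The last two guards matter at realistic SNR: a single folded tail
of two or three reversed-flux sections otherwise biases a vessel's mean
flow by > 10 %.

# Quantification

Each measurement node gets a square plane perpendicular to its tangent
(side 4× local radius, pixel = half a voxel). Mask and velocity are
interpolated trilinearly; lumen pixels are interpolated mask ≥ 0.5; flux is
$\sum_\mathrm{lumen} (\mathbf v \cdot \hat n)\,\mathrm{d}A \times 60$
(mL/min, sign positive along increasing node order from the seed) and CSA
is lumen pixel count × pixel area. Planes that leave the grid, contain no
lumen pixel, or touch the mask territory of another label (mask voxels are
assigned to the label of the nearest centerline node) are skipped — the
overlap test prevents double counting where a neighboring vessel crosses
the plane. Vessel flow and CSA are unweighted means over sections
(node spacing is nearly uniform, so length weighting would change little;
the choice is documented rather than inferred).

Known numerical biases, quantified on noise-free tubes at 10 voxels per
diameter: trilinear interpolation under-reads the concave Poiseuille
profile by ~2 % of flux (the bias scales with voxel²), and the lumen cut
at the wall costs up to ~2 % of CSA. Both are resolution-dependent
discretization effects, not tuning targets; the validation suite asserts
flow within 3 % and CSA within 5 % of the closed forms across radii
0.10–0.25 cm and mean velocities 20–60 cm/s, obliquity changing flow by
< 3 %.

Sub-voxel CSA *changes* deserve a caveat: an axis-aligned tube's voxel
lattice is identical in every slice, so a 2 % radius change can leave the
thresholded mask literally unchanged — the dilation is invisible no matter
how many sections are averaged. Real vessels are oblique and curved, which
staggers the wall's sub-voxel phase along the vessel; the dilation
validation therefore uses slightly oblique tubes (direction ≈ (0.1, 0.05, 1))
at 0.024 cm voxels, where the programmed 4.35 % MCA CSA increase is
recovered within 1.5 percentage points as the mean of left/right vessels.

# CVR and statistics

CVC, the CVR line fit, brain-volume correction and CSA change are direct
formula implementations. The fit supports both reported readings of the
protocol — `all_conditions` (default; the truth-ledger CVC is collinear
across all three conditions, so on synthetic truth both modes agree
exactly) and `hypercapnic_only` (drop the normocapnic point) — because the
source methods are ambiguous between them; the mode is recorded in every
output row.

The group battery delegates classical machinery to base R and `car`:
one-way ANOVA (`oneway.test`, pooled), two-way ANOVA with Type-III sums of
squares and sum-to-zero contrasts (`car::Anova`), mixed
(between × repeated) ANOVA via `aov` with an `Error(subject)` stratum (no
sphericity correction — a documented limitation), paired/unpaired
two-tailed t tests (pooled variance by default so that F = t² holds
exactly against the one-way ANOVA; Welch by flag), and Brown–Forsythe as a
one-way ANOVA on absolute deviations from group medians. The Holm–Šidák
step-down is implemented directly (no equivalent in `p.adjust`): the k-th
smallest of m p values is adjusted to $1-(1-p)^{m-k+1}$, enforced monotone,
rejecting sequentially until the first failure. All five test families
hold their nominal 5 % type-I error within ±1.5 points on 2,000-replicate
null simulations.

# Problem sizes and determinism

The verification suite runs noise-free tube phantoms at 10–12 voxels per
diameter on grids of roughly 30–80 voxels per side, the simulated study at
60×60×48, slope recovery over 20 noisy studies at SNR 20, and the
statistical calibration at 2,000 replicates — sizes chosen so the whole
suite completes in minutes on a laptop while every tolerance retains a
clear safety margin. All randomness flows from explicit seeds
(`withr::with_seed`); a fixed seed reproduces every output byte.

# What passing tests do and do not show

The phantom establishes *numerical* correctness: conservation of the
analytic flux through encoding, artifact injection, correction, geometry
and integration. It does not model pulsatile waveform shape beyond a
sinusoid, non-Newtonian or secondary flow at bends, wall motion, k-space
undersampling artifacts, inflow-dependent magnitude contrast, or
anatomical variation in vessel course — so passing tests certify the
pipeline's measurement chain, not the physiological fidelity of any real
scan. Group-level inferences on real cohorts additionally depend on
between-subject variability that the single-subject phantom does not
emulate; the statistics module is calibrated on simulated nulls instead.
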