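---
title: "Models and methods behind spnmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spnmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spnmorph)
```

`spnmorph` implements a processing and modelling chain for striatal
projection neuron (SPN) morphologies: standardisation of SWC
reconstructions, repair of slice-cut dendrites, quantitative morphometry, a
sigmoid spine-density model with a membrane-area correction, a passive
branched-cable simulator with glutamatergic synapses, and a calibrated
synthetic-morphology generator. This vignette explains each model, its
assumptions, the tunable parameters, and the design choices that were
genuinely open.

## Reconstructions and their standardisation

A reconstruction is a rooted tree of 3D points with radii (`spn_recon`).
Standardisation (`standardize()`) replaces a multi-point soma with a single
sphere (centre = mean of the soma points; radius = their mean distance from
the centre), translates the cell so the soma centre is the origin, and
multiplies z coordinates by a shrinkage factor (1.7 for ProLong-mounted
tissue, 1 for glycerol; x and y are never corrected). A z-jump repair hook
is exposed (`z_jump_fix`) but ships as a pass-through: no published
algorithm exists for it and reconstruction-specific fixes belong to the
caller.

Two conventions matter downstream:

* **The soma edge carries no cable.** The edge from the soma centre to the
  first dendritic node is bookkeeping, not dendrite; dendritic length and
  path distance start at the first dendritic node. This keeps total length
  independent of soma size.
* **Radii are stored; diameters are reported.** Every user-facing quantity
  is a diameter (`2r`).

`resample()` re-parameterises each segment by arc length at a fixed step
(3 µm default), preserving branch points, terminals and the soma attachment
point exactly; interior points are regenerated and radii interpolated
linearly in arc length. Chord sampling shortens curved paths, so
coordinates are then scaled about the soma by 1.01. The upscale applies to
coordinates only — it exists to recover length, and rescaling diameters
would corrupt the taper statistics. On smooth test curves the combined
operation changes total length by < 1.5 %; on an already-straight polyline
the +1 % overshoot is the worst case.

## Segments, orders, breadths

Morphometry works on *segments*: portions of dendrite between structural
points (soma, branch point, tip). Each segment has a centrifugal **order**
(primary dendrite = 1, incremented at each branch point) and a centripetal
**breadth** (number of terminal tips distal to it; terminal = 1; a
segment's breadth is the sum of its daughters'). `partition_segments()`
also records arc length, base/end/arc-weighted-mean diameters, the path
distance of the segment base from the soma, and the inclusive subtree
length used by the diameter law.

Taper fits (`fit_taper()`) pool (arc-position, diameter) samples per class:
primary = order-1 non-terminal, terminal = breadth-1, intermediate =
everything else; non-bifurcating primary dendrites (simultaneously primary
and terminal) are excluded, matching the reporting convention for SPN
dendrites. Exponential fits use `d(s) = d_end + (d_base − d_end)·e^{−s/rate}`
via Levenberg–Marquardt; the constant fit is the mean diameter.

The subtree law (`fit_subtree_law()`) regresses mean segment diameter on
the total dendritic length `L` distal to the segment's base. `L` includes
the measuring segment itself by default (`inclusive = TRUE`), because the
subtree "originating from" a segment naturally contains it; the exclusive
variant is one switch away.

Sholl profiles use Euclidean radial distance from the soma centre with
10 µm steps — the standard convention — counting sign changes of
`(‖p‖ − r)` along each dendritic edge with linear interpolation.

The mean branching ratio is daughters-per-bifurcation by default (2 for
binary trees); terminals-per-primary is exposed as an alternative because
the phrase is used both ways in the morphometry literature.

Feret diameters of a 2D soma contour use the exact maximal point-pair
distance for the maximum and a dense angular scan (0.5°) of projection
widths for the minimum and mean caliper. Rotating-calipers exactness is
unnecessary at the noise level of traced outlines; the scan's worst-case
error on the minimum width is far below reconstruction uncertainty.

## Repair of slice-cut dendrites

Cells filled in 150–300 µm sections lose the dendrites nearest the cut
face. The repair model assumes: (i) cut points are terminal nodes within a
band below the maximal z of the reconstruction (20 µm for mouse material,
10 µm for human, reflecting section quality); (ii) the dendritic field is
spherically symmetric on average, so the intact lower half of the cell
predicts whole-cell morphometry once mirrored through the soma plane
(`predict_morphometry()`); (iii) intact branches from any cell of the
cohort — including the damaged cell itself — are valid donor material.

`repair_reconstruction()` generates `n_candidates` independent repairs. For
every cut terminal a donor branch is drawn (with replacement) and a node of
the same centrifugal order as the cut terminal is chosen as the attachment
point; the donor's distal material is copied, rotated so its initial
direction continues the cut terminal's last-3 µm tangent (orientation is
not constrained by any published procedure; tangent continuation is the
least-commitment choice), translated onto the cut node, and its diameters
scaled by (arc-weighted mean diameter of the cut segment)/(donor diameter
at the attachment). A graft is rejected when a scaled *terminal* diameter
leaves the species bounds ([0.376, 0.876] µm mouse, [0.59, 1.26] µm human,
the ranges of intact terminal diameters) — the bounds describe terminal
calibre, so they are enforced where they are defined.

Candidates are scored by the summed |Z| of six features — total length,
terminal count, maximal order, bifurcation count, maximal breadth, mean
terminal length — against the mirror prediction, with SDs taken from the
intact cohort; ties break on candidate index. The selection metric is not
prescribed anywhere, so this transparent aggregate was chosen and is
reported with the result. The winning candidate is resampled (3 µm, +1 %).

One practical caveat: automatic cut detection on an *intact* cell still
flags its topmost terminals (some terminal always attains the maximal z).
Detection is therefore meaningful only for cells known to be sliced;
`repair_reconstruction()` accepts a curated `cut_report` for other cases,
and the tests verify exact ground-truth recovery with a tight band on
synthetically sliced cells.

## Spine model

Spine density along an SPN dendrite is near zero over the first ~25 µm,
rises to a plateau by ~50 µm and stays there:

$$S(x) = \frac{a}{1 + e^{(b-x)/c}}$$

with plateau `a` (1.6 spines/µm mouse, 0.7 human), half-rise `b` and scale
`c`. The numeric `b` and `c` are not published in machine-readable form;
the presets adopt `b = 35` µm, `c = 8` µm, consistent with the qualitative
description, and both are ordinary fit parameters everywhere else.
`fit_spine_density()` fits binned densities (counts per dendritic length,
10 µm half-open bins anchored at the soma) by weighted nonlinear least
squares; the weights are the dendritic length per bin — bins that sample
more dendrite constrain the fit more — since no weighting scheme is
prescribed. Initial values: `a` = maximal binned density, `b` = first bin
at half maximum, `c` = 10 µm.

Spines enlarge the membrane. For a dendrite with spine area `A_spines` on
shaft area `A_shaft`, `F_spines = (A_spines + A_shaft)/A_shaft`. A
compartmental model without explicit spines compensates by scaling the
membrane at path distance `x`:

$$F(x) = 1 + (F_{\mathrm{spines}} - 1)\,\frac{S(x)}{a},\qquad
  c_m(x) = C_m F(x),\quad r_m(x) = R_m / F(x).$$

Simulations use `a = 1` (shape only) and `F_spines = 2`, so corrected
capacitance runs from 1 up to 2 µF/cm². The product `r_m c_m` — the local
membrane time constant — is invariant under the correction by
construction; note that voltage transients in a *branched* tree also
involve axial charge redistribution, which the correction does not (and
should not) preserve.

Expected spine counts integrate `S(x)` in closed form along every segment
(the sigmoid has an elementary antiderivative, so no quadrature error);
sampling for simulation-facing inventories uses an inhomogeneous Poisson
process at rate `S(x)`, realised by thinning a homogeneous process at the
plateau rate.

## Passive cable model

`build_cable_model()` discretises each segment into compartments no longer
than min(0.1 λ_local, 10 µm), with λ the local space constant
`sqrt(R_m d / 4 R_a)`; the soma sphere is one isopotential compartment of
area 4πr². Terminals are sealed ends; axial coupling is symmetric. Passive
constants: `C_m = 1` µF/cm² before spine correction, `R_a = 150` Ω·cm,
rest at −86 mV, 35 °C stored for reference.

`R_m` is deliberately a **calibration constant** per species (mouse
6 800 Ω·cm², human 20 000 Ω·cm²): absolute membrane resistivities for these
cells are not published, only the facts that the terminal decay time
constant is larger in human and that terminal *electrotonic* lengths
`L = l/λ` are similar across species despite very different physical
lengths. The presets reproduce both: the generator's terminal lengths
differ ~2.6-fold while mean terminal `L` agrees within ~20 %, and measured
local τ orders mouse < human. Absolute τ magnitudes are not asserted
anywhere.

The solver is backward Euler on the passive system (the matrix
`C/dt + G` is inverted once), with synaptic and injected currents entering
explicitly at the previous step's voltage. Rest is an exact fixed point
(drift < 1 µV over 1 s in the tests); the isopotential step response
recovers τ = R_m·C_m within 1 % at dt = 0.01 ms; steady-state attenuation
on a sealed cylinder matches `cosh((l−x)/λ)/cosh(l/λ)` within 2 %; halving
dt moves a peak EPSP by < 0.5 %. Default dt is 0.025 ms for synaptic
protocols, 0.05–0.1 ms for slow ones.

Synapses are dual-exponential conductances: AMPA 0.2/1.7 ms, NMDA
2/100 ms, reversal 0 mV, with the Jahr–Stevens magnesium block
`B(V) = 1/(1 + ([Mg]/3.57 mM)·e^{−0.062V})` at 1 mM Mg. Base AMPA
conductance is 0.5 nS; the human variant multiplies the synaptic
conductance by 1.37, proportional to the mean spine-area ratio
(4.263/3.118), applied to AMPA and NMDA alike since no component-specific
statement exists. The NMDA:AMPA peak-conductance ratio defaults to **3**:
with a ratio of 1 the clustered-input protocol cannot produce a
regenerative plateau at all — the local depolarisation never reaches the
magnesium-unblocking range, so blocking NMDA barely changes the response,
contradicting the well-documented NMDA dependence of SPN plateau
potentials. A ratio of 3 sits inside the range used by detailed SPN
dendrite models and restores the phenomenology (tens of millivolts locally,
an order smaller at the soma, duration collapsing by more than half when
NMDA is off). All kinetic constants are exposed in `synapse_params()`.

Active conductances (fast Na⁺, fast/slow A-type K⁺, T-type Ca²⁺) are a
plug-in surface only: `build_cable_model()` accepts distance-dependent
density profiles and stores them per compartment, but no kinetics ship —
the supported simulation surface is passive + synaptic, and reversal
potentials (+53.34 / −105.9 mV) are stored for the plug-in interface.

`measure_tau()` fits the *late tail* of the decay after a brief pulse
(between 0.5 % and 5 % of the peak): early decay at a dendritic location is
dominated by charge redistribution along the tree, and the slowest mode is
the quantity with a clean membrane interpretation. Local τ measured at
branched terminals therefore sits below R_m·C_m; only its cross-species
ordering is meaningful.

`rescale_species()` implements the cross-species geometry swap: dendritic
diameters ×1.7 and terminal arc lengths ×2 carry a mouse cell to human
proportions (0.6 and 0.5 for the reverse); terminal stretching is a
homothety about the terminal's base node so branch points stay fixed, and
spherical somata are swapped. At matched distributed synaptic drive the
enlarged cell depolarises less at the soma and the shrunken cell more,
which is the passive-membrane core of the observation that rescaled
morphologies behave like the other species.

## Synthetic cohorts and their calibration

`sample_morphology()` grows cells recursively: the number of primaries is
drawn from species-specific integer distributions (mouse 3–8, median 5;
human 3–9, median 6); each branch draws its breadth from the empirical
per-breadth branch counts of the two datasets (mouse
{1:8, 2:4, 3:6, 4:9, 5:6, 6:4, 7:4, 8:4, 13:1}; human
{1:4, 2:4, 3:9, 4:6, 5:2, 6:5, 7:1, 8:2, 15:1, 21:1}); a random binary
topology realises the breadth (uniform split at each branch point); segment
lengths are lognormal per class; diameters follow `d = k·L_subtree`
(`k = 0.002` µm/µm) floored at the species terminal diameter (0.6/1.0 µm),
which simultaneously produces tapering proximal dendrites and
constant-diameter terminals. Embedding is a persistent random walk
(direction jitter σ = 0.12 per 5 µm step, branch divergence σ = 0.55) from
uniformly random primary directions — enough to give plausible, roughly
spherical Sholl profiles; the walk parameters are aesthetic and not
validated quantitatively.

**Length calibration.** Primary and intermediate length means are
25/20–25 µm (similar primaries across species, slightly longer
intermediates in human). Terminal means are then *solved*, not tuned: with
breadth counts giving `E[B]` terminals and `E[B−1]` internal segments per
branch, the expected terminal-length fraction is
`E[B]·l_t / (E[B]·l_t + n_p·l_p + n_i·l_i)`; setting this to the published
84 % (mouse) and 92 % (human) yields `l_t = 85.5` µm and `225.4` µm. Cohorts
of 25 cells reproduce the targets within the tested 3 %. The terminal spine
fractions (≈90 %/95 %) then *emerge* from geometry — proximal segments sit
in the sigmoid's dead zone — rather than being fitted.

Spine areas are lognormal at the species mean (3.118/4.263 µm²) with
CV 0.6 (only means are published; 0.6 is typical for spine-size
distributions). Head area is a Beta-distributed fraction (~60 %) of the
total, neck length ~1 µm and neck diameter ~0.2 µm lognormal — plausible
inventory fields, not calibrated claims.

`slice_cut()` places the soma 30–50 µm below the upper slice face (40 µm
default), removes everything above the face and truncates crossing paths at
it, recording the ground-truth cut set. At the defaults roughly two thirds
of the arbour survives, matching the reported loss for slice-filled cells.

**What the generator does not emulate:** tortuosity and diameter noise of
real dendrites, z-anisotropy of optical reconstruction, spine clustering,
inter-animal variability, and any correlation between branch topology and
diameter beyond the subtree law. Passing tests on synthetic cohorts
therefore validate the *pipeline's* correctness and internal consistency,
not biological claims about new tissue.

## Problem sizes and determinism

Every stochastic stage takes an explicit seed; cohorts derive per-cell
seeds from one master stream, so regeneration is bit-identical. The shipped
tests and the acceptance script use the cohort sizes of the underlying
study where they are meaningful (25 cells, 20 dendrites, 400 spines) and
small cohorts (5–8 cells, 10–20 repair candidates) for the end-to-end
repair and simulation property checks, which behave identically at larger
sizes. Simulation protocols in tests run 0.4–1 s of model time at
dt = 0.025–0.05 ms.

## Known limitations

* The repair donor search is rejection-based; with very small donor pools
  and strict diameter bounds many candidates can be rejected (the result
  reports how many).
* The solver treats synaptic conductances explicitly; extremely large
  conductance clusters (≫20 nS on one thin compartment) would need a
  smaller dt. The dt-halving test guards the regimes used here.
* `measure_tau` on active (non-monotone) responses is rejected rather than
  fitted.
* Sholl uses Euclidean radii; path-distance Sholl is not implemented.
* The CLI layer is deliberately thin: `run_pipeline()` plus the acceptance
  script are the batch entry points; there is no shell subcommand suite.
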