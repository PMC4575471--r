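---
title: "Models and methods behind dbacsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dbacsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dbacsim is a desk-scale simulation of a circumferential HIFU cuff that
finds arterial bleeders deep inside a limb and cauterizes them under
closed-loop control. This vignette explains the models each module
implements, the assumptions and tunable parameters behind them, the
numerical choices, and what the synthetic data do and do not establish
about a physical system.

## The treatment problem

A limb is modelled as a tissue cylinder (7.5--25 cm diameter, matching the
cuff's minimum and maximum radius of curvature) containing an arterial
tree; a *bleeder* is a vented branch that ducts flow out of the artery, as
in a puncture wound. A polygonal cuff of 4--7 rigid panels surrounds the
limb across a ~1-cm water coupling jacket. Each panel carries three
therapy tiles (Tx; 52 x 52 mm, 4608 elements at 1 MHz, electronically
steerable to 60 deg azimuth / 45 deg elevation) and one 3D imaging probe
(Ix; 2.5 MHz pyramidal sector). Treatment has two phases, each started by
a single command: detection & localization (D&L) of the bleeders from
compounded power-Doppler volumes, then therapy -- tile recruitment, beam
targeting correction, and a thermometry-controlled 30-s dose that must
raise an 8-mm therapeutic sphere (MTV) by 33--58 deg C without exceeding a
20 deg C skin rise.

## Synthetic phantoms (`make_limb_phantom`)

Vascular trees are recursive binary branchings from a femoral-scale root
(5 mm lumen): child radii follow a Murray-type law
$r_p^{2.5} = r_1^{2.5} + r_2^{2.5}$, branching half-angles scale linearly
with limb diameter so small limbs have the narrow branch angles that make
junction localization genuinely harder, and every polyline wanders gently
so centerline extraction is exercised on curved vessels. Bleeders are
straight vented stubs of at least 30 mm replacing one child at the deepest
junctions (so at least one bleeder is deeper than a quarter diameter),
steered away from their sibling branch so neighbouring lumens stay
resolvable, and carrying a thermocouple marker 20 mm downstream of the
junction. The smallest representable vessel diameter is 0.6 mm, the
system's minimum-structure-resolution target.

Flow waveforms are one cardiac cycle of a stereotyped arterial pulse. The
resistive index RI = (V_systole - V_diastole)/V_systole is set *by
construction*: intact branches draw RI in [0.82, 0.95], vented branches in
[0.55, 0.70] (venting lowers distal resistance and raises diastolic
flow), and the `irregular-slow` profile produces slow (<= 4 cm/s)
non-periodic traces whose cycle-to-cycle extrema are unreliable -- the
regime in which RI-based classification demonstrably degrades, mirroring
the known low-flow failure mode. Mean velocities scale with the square
root of the radius ratio and are floored at 3 cm/s, the minimum
detectable velocity (MDV).

## Doppler observation model (`render_power_doppler`)

Rendering is geometric, not an RF simulation: the lumen is rasterized
into voxels (voxel size at most half the smallest lumen diameter -- the
0.3-mm default resolves the 0.6-mm vessel), each probe contributes
intensity scaled by the Doppler angle factor |cos theta| between its beam
direction and the local flow direction, views are compounded by taking
the per-voxel maximum across probes, flow below the MDV returns no
signal, and seeded additive Gaussian noise is applied last. Probes are
staggered axially panel-to-panel, as on the physical cuff, so
predominantly axial flow is seen at a usable angle from somewhere on the
circumference; with two facing probes only, both orthogonal to the flow,
the compounded lumen stays at background -- the contralateral blind spot.
Spectral-Doppler gates return the branch waveform with multiplicative
speckle-like noise when placed within a capture radius (2 mm beyond the
lumen) of a centerline, and a distinguishable no-signal outcome
otherwise.

This fidelity level exercises every decision the D&L logic makes
(thresholding, connectivity, angles, gate capture) but says nothing about
speckle statistics, wall filters, or aliasing in a real scanner.

## Detection & localization

Segmentation is Otsu's threshold on the nonzero intensities, a 1-voxel
morphological closing (noise pinholes otherwise become spurious skeleton
tunnels), and removal of connected components under 20 voxels.
Centerlines come from 3D topological thinning, ordered by a 3-4-5 chamfer
distance transform and preserving curve endpoints; the skeleton becomes a
graph whose nodes are junctions and endpoints and whose edges are
polylines with distance-transform radii. Cleanup operates at graph level:
junction nodes closer than 1.5 mm are merged, short parallel double edges
(thinning leaves loops around thick junctions) are contracted, degree-2
nodes are dissolved, and terminal spurs are pruned when shorter than 2 mm
or much thinner (< 0.55 x) than the vessel they attach to while still
short -- a genuine thin branch is long and survives. The 2-mm spur and
1.5-mm merge radii sit safely below the 3-mm targeting tolerance.

At each bifurcation three spectral gates are placed 5 mm along each
incident branch (branch midpoint, flagged, when shorter); the upstream
branch is `proximal`, taken from the generating tree's flow direction --
the simulation stand-in for directional Doppler. Classification is the
strict rule bleeder iff RI < 0.75; an undefined RI (non-positive
systole) is unclassifiable. The gate distance of 5 mm is a package
default: only "a prescribed distance" is specified by the source system
concept, and 5 mm keeps gates clear of junction flow disturbance while
staying on short branches.

`run_dl` chains the whole pipeline, records per-phase wall-clock times
(reported, never gated -- simulation timing is not comparable to imaging
hardware), and reports each bleeder's target coordinate at its gate
location.

## Therapy planning and power equalization

For a target, a tile is *available* when the target is inside its
steering cone and focal range (30--160 mm) and no bone blocks the path.
Its transport efficiency is
$\eta = \eta_{ea} \cdot D(az, el) \cdot e^{-2 \alpha f d_{tissue}}$,
with electroacoustic conversion $\eta_{ea} = 0.5$ (the arrays' measured
>50% ratio), a steering directivity LUT fit as separable cosine powers to
coherent element sums on a 5-degree grid, and two-way amplitude (one-way
intensity) attenuation along the tissue chord. The absorbed-power
capacity of a tile over the d0 = 8 mm therapeutic sphere is
$Q = Q_0\,\eta\,(1 - e^{-2 \alpha d_0})$. Candidates are ranked by
achievable Q; for each group size k in [minTx, maxTx] the top-k group is
*equalized* -- every member throttled to the k-th largest Q so all
contribute equally, hence weights $w = Q_{(k)}/Q_i \le 1$ -- and the
group with the greatest total $k\,Q_{(k)}$ wins. Equalization is
interpreted as equal absorbed contribution set by the weakest member's
capacity: the only reading consistent with weights bounded by 1 and with
comparing group totals. Defaults minTx = 2, maxTx = 6 bracket the 2--4
tiles used per dose in practice.

Dither patterns spread the focus laterally across the MTV: 12 points in a
double ring for depths <= 7 cm, 9 points in a 3x3 grid deeper (corners
scaled to stay inside the sphere), switched at up to 10 kHz. Only the
counts and the 7-cm depth rule are normative; the point geometry is this
package's choice.

## Acoustic fields and deposition

Beam fields are monochromatic coherent sums over the element grid with
focusing delays, spherical spreading and a baffled-cosine element factor
-- linear propagation only, by design: the treatment concept restricts
itself to linear thermal dosing. For deposition the element grid may be
grouped 2x in azimuth (grouped pitch 1.08 mm, still below the 1.5-mm
wavelength, so no grating lobes); elevation is never grouped, because a
2x elevation group reaches 2.17 mm > lambda and injects spurious lobes.
Dithering is applied as a time-averaged superposition of focus-translated
field copies, valid for the few-mm spans used. Volumetric heating is
$q = 2\alpha f I$ with per-voxel attenuation along the tissue chord, and
each tile's field is calibrated so the power absorbed inside the MTV
sphere equals its equalized plan contribution.

One bookkeeping subtlety deserves emphasis: the planning capacity
$Q = Q_0 \eta (1 - e^{-2\alpha d_0})$ treats the *entire* arriving beam
as crossing the therapeutic sphere. With 3-dB focal widths of 1--3.7 mm
dithered across an 8-mm sphere, an appreciable fraction of the arriving
power physically passes outside the strict sphere, so the planning figure
overstates strict in-sphere absorption substantially (a factor of about
1.5--2 at the default beam and dither geometry). The package calibrates
deposition to the strict in-sphere definition (the `DepositionMap`
contract) and `power_for_min_dose` reports on that scale; readers
comparing against planning-style "absorbed power at the target" figures
should expect the planning number to be correspondingly larger. The
skin-intensity consequence of this calibration is conservative: skin
temperatures computed from MTV-calibrated maps overstate the true
per-watt skin exposure, which is safe for a limit check.

## Bioheat solver and thermal dose

The Pennes equation
$\rho c_p \partial_t \Delta T = k_t \nabla^2 \Delta T - \rho_b c_b w_b \Delta T + q$
is solved explicitly on a regular grid (7-point Laplacian, Dirichlet
$\Delta T = 0$ at the outer water boundary), with the sink term treated
implicitly so arbitrarily strong local sinks (the vessel-lumen advective
surrogate) remain unconditionally stable. The explicit step is capped at
90% of $h^2 \rho c_p / (6 k_t)$; an over-long request is rejected with
the bound. Default phantom properties are documented soft-tissue
surrogates -- rho 1050 kg/m^3, c_p 3600 J/(kg K), k_t 0.55 W/(m K),
sound speed 1515 m/s, attenuation 0.05 Np/cm/MHz, zero perfusion -- all
configurable via `tissue_properties()`. Verified behaviours: exact
adiabatic heating for uniform sources, agreement with the Green-kernel
convolution for compact sources (median voxelwise error under 3% at
0.5-mm resolution), enthalpy conservation within 1%, linearity in the
source, and <5% change under grid refinement at the default resolutions.

Fine target-region solves and coarse whole-limb solves (for skin maxima)
are separate runs on single regular grids rather than one composite
two-resolution grid: at these problem sizes a composite solver buys
nothing and adds interface error.

`mtv_stats` evaluates end-of-dose minimum/mean/maximum over the 8-mm
sphere; `skin_peak` the running maximum over skin-surface voxels;
`cem43` the Sapareto--Dewey dose $\sum \Delta t\, R^{43-T}$ with R = 0.5
above 43 deg C and 0.25 below. The lateral containment check (MTTD)
operationalizes "no significant heating" beyond 1 cm lateral of the
target as less than 20% of the mean MTV rise -- no number is specified
anywhere, so the threshold is a documented package decision.
`power_for_min_dose` exploits source linearity: one reference solve, an
exact scaling to the 33 deg C minimum, and a verification solve at the
returned power -- the same root a bisection would find.

## Closed-loop targeting

A low-power test pulse heats a thin volume along the beam; apparent
thermal strain is lambda x temperature rise (lambda drawn near
0.0012 / deg C per phantom) plus spatially correlated noise. Focus
localization segments super-threshold voxels, fits a strain-weighted
total-least-squares line (the beam axis), and projects the peak-strain
voxel onto it. Correction applies the full negative measured offset each
iteration (no damping; a damping factor is exposed). Convergence is
declared on the measured offset with a noise margin -- below
max(tol/2, tol - 3 sigma) rather than the bare 3-mm tolerance -- so a
measurement that noise happens to pull just under the tolerance cannot
stop the loop while the true offset is still outside it; trials declared
converged then genuinely end inside the tolerance.
Radiation-force (ARFI-style) and thermal-strain localization are unified
in one segment/line-fit/peak operator, since both produce a beam-shaped
scalar volume. For statistical experiments the measurement can be the
direct Gaussian noise model (sigma = 0.5 mm per axis); the strain-volume
route is exercised separately.

## Acoustic thermometry and closed-loop dosing

The simulated echo features at the target are: apparent thermal strain
with a soft knee -- linear to 10 deg C, half slope above, so a linear
readout under-reads a 30 deg C rise by about a third, matching the
documented bias magnitude of strain-only thermometry (a calibration to
the reported behaviour, not derived physics); radiation-force
displacement proportional to applied power; a monotone backscatter
change; and an inter-frame correlation that falls with heating rate. The
TSI estimator divides strain by lambda through a cubic calibration
(identity by default). The recurrent estimator is an echo-state network:
a fixed, seeded 32-unit reservoir over all four features with a
ridge-regression readout -- deterministic under seed and trained in
seconds on a synthetic corpus of 250 first-order heating ramps (the
corpus scale mirrors the training-set size used in practice), with mean
absolute error reported on a held-out fifth, overall and in the 0--10 and
11--30 deg C bands. On saturating streams the recurrent estimator beats
the linear readout precisely because displacement and backscatter remain
informative where strain saturates.

The dosing controller steps the bioheat solver in 0.5-s frames, forms the
spatial-average (plain voxel mean) temperature estimate over the MTV, and
cuts power when the estimate reaches the threshold or at the 30-s limit,
recording the cause. With the vessel-lumen sink enabled, the cold lumen
inside the averaging sphere drags the estimate down, the trip comes late,
and the true wall temperature at shut-off overshoots the threshold --
reproducing the documented spatial-averaging bias anomaly. The lumen sink
is an equivalent-perfusion surrogate for advective cooling, not a flow
solve.

## Time-of-flight registration

Each array face carries five 3 x 3 mm sub-apertures (four corners and the
center -- the count is a package default; only the sub-aperture size is
specified). Arrival times between pairs on distinct arrays within 72
degrees of both face normals are
$t = L_w/c_w + L_t/c_t + \varepsilon$, the straight two-segment split at
the known limb cylinder, with Gaussian jitter (default one carrier period
at 2.5 MHz, 0.4 us; no noise figure is specified). Snell bending is
neglected on both forward and inverse sides: at the water/tissue contrast
used it is under half a degree, and modelling it on one side only would
inject bias. The as-worn ground truth is the nominal polygon perturbed
per-array (2 mm, 1 deg SD) -- a flexible cuff never sits exactly on its
nominal frame -- while the solver initializes from the unperturbed
polygon prior, playing the role of the calibration file.

The solve alternates: (i) the two slownesses by linear least squares on
$t = L_w u_w + L_t u_t$ at fixed geometry; (ii) each sub-aperture
position by a small Gauss--Newton step on its incident measurements
(numeric Jacobian, scaled normal equations) with a weak prior pull toward
the polygon to pin the six-dimensional rigid gauge. Array poses are rigid
(Kabsch) fits of the nominal five-point layout to the solved positions;
the square layout is symmetric under an in-plane 180-degree flip that
negates the face normal, so the branch facing like the prior is chosen.
The panel count is identified by clustering tile-normal azimuths with a
10-degree gap. Registration errors are reported after best-fit rigid
alignment to truth and are invariant to any global rigid transform of the
estimate.

## Orchestration

`run_config` + `start_dl` + `start_therapy` (or `run_all`) execute the
two-command sequence unattended: D&L, then per-bleeder recruitment,
targeting correction, deposition and controlled dose, with per-bleeder
failures recorded rather than fatal, pass/fail reported against the
33--58 deg C target window, the skin limit and the 3-mm tolerance, and
JSON reports persisted when an output directory is configured. A thin
command-line wrapper (`inst/cli/dbac.R`) exposes phantom/cuff
construction, ToF calibration and the two buttons. Volumes persist as
RDS payloads; trees, cuffs, plans, poses and reports as JSON; waveforms,
ToF sets and thermocouple logs as CSV.

## Problem sizes and determinism

All results in the test-suite and the acceptance script are computed at
desk scale, chosen for a single CPU: D&L phantoms of 5--8 cm length at
0.25--0.5 mm voxels (a few million voxels), deposition grids of 0.75--1 mm
around the target and 2--2.5 mm for whole-limb skin runs, 50-trial
targeting ensembles, and ToF sets of a few thousand measurements. Every
stochastic step takes an explicit seed and identical seeds give identical
results; the scoped RNG never disturbs the caller's random state.

## Known limitations

Doppler rendering is geometric (no RF, speckle or aliasing physics); the
beam model is monochromatic and linear with no tissue motion, cavitation
or property change on coagulation; the lumen sink is not a flow solve;
the recurrent thermometry is trained and evaluated on the package's own
synthetic feature model, so its accuracy numbers characterize the
estimator architecture, not performance on real echo data; and simulated
timings say nothing about imaging-hardware acquisition budgets. Passing
tests establish internal consistency of the pipeline and its numerics,
not clinical performance.
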