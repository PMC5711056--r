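---
title: "Backscatter underdose in multilumen balloon brachytherapy: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backscatter underdose in multilumen balloon brachytherapy: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Accelerated partial breast irradiation (APBI) with a multilumen balloon
applicator delivers 340 cGy per fraction, prescribed to points 1 cm beyond
the balloon surface, from an Ir-192 high-dose-rate source stepping through
five lumens. Conventional treatment planning systems compute dose with the
TG-43 formalism, which assumes an unbounded homogeneous water medium. When
the balloon sits close to the skin, the air beyond the patient returns
almost no scattered photons, so the delivered dose at the prescription
point falls short of the planned dose. This package quantifies that
shortfall with the dose modification factor

DMF = D(full scatter) / D(finite tissue),

the ratio of the dose rate at the reference point 1 cm from the balloon
surface in unbounded water to the dose rate with a finite tissue thickness
beyond that point. `100 * (DMF - 1)` is the percent underdose committed by
a homogeneous-water planning system. Everything the package computes is a
relative dose or a dose ratio; absolute calibration (air-kerma strength,
dose-rate constant) is deliberately out of scope.

## Geometry

The applicator model is a 2.2 cm-radius spherical balloon centred at the
origin with its axis along +z. The central lumen is the axis; the four
outer lumens are circular arcs in axial planes at cardinal azimuths, pinned
to the balloon poles and offset 0.5 cm from the axis at the equator (the
device's quoted maximum central-to-outer separation). Each lumen holds 7
dwell positions at a 0.5 cm step measured as arc length and centred on the
equator — 35 source cylinders of 0.5 cm length and 0.017 cm radius, the
most each lumen can hold without a dwell protruding from the balloon.
Because step length equals source length, the dwells in a lumen form a
contiguous column. The exact dwell placement along each lumen and the arc
curvature are modelling choices; only the 5 mm apex offset and the 7 x 5 mm
filling are fixed by the device description.

Four reference points sit at the lumen azimuths in the equatorial plane,
3.2 cm from the centre (1 cm beyond the surface); the +y point is the
asymmetry/measurement point, covered by a 0.17 cm-radius spherical detector.
Phantoms are water: a cuboid 40 x (23.2 + d) x 40 cm with 20 cm of water
behind the balloon centre, or a sphere of radius (3.2 + d) cm, where d is
the tissue depth beyond the reference point; both sit in a 100 cm cube of
air. The full-scatter reference is a sphere with a 30 cm margin beyond the
detector; extending the margin to 40 cm moves the tally by less than 0.2 %
(verified by a paired-seed run in the test suite). Balloon wall, catheters
and balloon interior are water.

## Transport physics

The engine is an analog photon Monte Carlo with exact ray tracing of the
sphere/box/cylinder surfaces and optical-depth bookkeeping across material
boundaries (no random numbers are consumed at boundary crossings, which
keeps paired-geometry runs maximally correlated). Physics choices, all
switchable where noted:

* **Source spectrum** — discrete Ir-192 gamma and K x-ray lines (26 lines
  above 60 keV, 2.30 photons per decay, mean 0.355 MeV) from standard decay
  tables, shipped as a plain-text fixture.
* **Interactions** — incoherent scattering on free electrons (Klein-Nishina,
  sampled with Kahn's composition-rejection method) and photoelectric
  absorption; pair production from the minor lines above 1.022 MeV is folded
  into absorption. Bound-electron (incoherent scattering function)
  corrections are omitted: they are negligible above ~100 keV, where nearly
  all of the emission lies.
* **Coherent (Rayleigh) scattering** — off by default; a Thomson-shaped
  coherent channel can be enabled. The test suite asserts that toggling it
  moves the detector tally by less than the statistical resolution.
* **Cross sections** — standard-reference mass attenuation and mass
  energy-absorption grids for water, air and steel, embedded as commented
  text fixtures with log-log interpolation (exact at nodes, monotone between
  them). The "without coherent" transport column is assembled as analytic
  Klein-Nishina plus an embedded photoelectric term. The iridium table used
  for source self-absorption is an approximation built from analytic
  Klein-Nishina plus a photoelectric term scaled from the lead grid; the
  fixture headers document provenance.
* **Source self-absorption** — dwell cylinders are attenuating iridium by
  default. This matters: a bare emission volume has no end-on self-absorption
  and produces unphysical polar hot lobes in the 3-D dose grid. With
  attenuation on, the derived single-dwell kernel shows the familiar ~0.55 to
  0.75 end-on anisotropy of real HDR sources, most of the polar shadow being
  refilled by in-water scatter.
* **Cutoff** — photons falling below 2 keV are terminated; sub-cutoff
  transport is irrelevant at centimetre scales in water.
* **Kerma approximation** — no electron transport. Secondary-electron ranges
  at these energies are below ~2 mm in water, small against the 1 cm
  prescription distance, and the DMF ratio cancels most of the residual.

Dose is scored per source photon with a track-length kerma estimator over
the detector sphere (score = track length x E x muen/rho(E) / volume), with
a collision-density estimator always scored alongside as an independent
cross-check; the two agree within statistics in the suite. Uncertainties
come from 100 history batches; each dwell has its own deterministic random
stream (xoshiro256++ seeded per dwell and batch), so per-dwell sub-tallies
are independent and a run can be re-weighted under any dwell plan after the
fact — exactly the equal-particles-per-dwell, weight-multiplied scheme the
study design calls for. Runs are bit-reproducible given (seed, config,
geometry).

## The planning-system surrogate

The TG-43 stand-in is a single-dwell dose kernel in effectively unbounded
water (50 cm sphere), tabulated on a log-spaced radial grid over
0.25–20 cm by a 5 degree polar grid and normalized to 1 at (r = 1 cm,
theta = 90 deg). It is scored with the collision-density estimator binned in
(r, theta), so it shares the exact transport physics of the engine; it is
deliberately not the published consensus table of any commercial source
model, keeping the package self-contained (a loader accepts user tables in
the same layout for cross-checks). Plan doses are superpositions of the
kernel over the 35 dwells — like any TG-43 system this ignores
inter-source shadowing, which the full transport engine does model.
Interpolation is bilinear in (log r, cos theta) of the log kernel value;
the inner cutoff is 0.25 cm and no clinical point lies inside it. The 3-D
dose grid uses the planning-system convention: 40 cm extent, 0.25 cm
resolution, inclusive endpoints (161 nodes per axis), node-centred voxels
of 0.25^3 cm^3 for volume metrics.

Kernel fidelity is tested by comparing kernel-superposed doses at several
radii against direct Monte Carlo tallies of the same plan (agreement within
combined statistics), and kernel-vs-grid interpolation consistency is held
to 1 % at the prescription distance.

## Plans, asymmetry and dose-volume limits

The symmetric plan puts equal weight on all 35 dwells, scaled so the mean
of the four cardinal point doses equals the prescription. The asymmetric
plan operationalizes manual forward planning deterministically: the central
lumen and the lumen nearest the spared point get zero weight, weights are
equal within each remaining lumen, and the three per-lumen scales solve a
3 x 3 linear system holding the other three points exactly at prescription.
Plan quality is summarized by the dose asymmetry — the percent difference
between the mean of the three held points and the spared point — and by
V150 and V200, the tissue volumes receiving at least 150 % and 200 % of
prescription, counted on the dose grid excluding the balloon interior
(switchable, since the clinical convention is not universal) and compared
with the RTOG 0413 limits of 50 cc and 10 cc.

Two aspects deserve honesty. First, the per-lumen-equal construction yields
an asymmetry of about 7.5–8 % in this geometry. An exhaustive enumeration of
the basic solutions of the corresponding linear program (minimize the
spared-point dose over all 21 per-dwell weights subject to the three held
points, weights nonnegative) bounds the achievable asymmetry at about 11.5 %,
so substantially larger values reported for the physical device cannot be
reached by any nonnegative weighting of this applicator model; they reflect
CT-derived lumen geometry and hand-tuned per-dwell times that are not
published, and the bound itself is the more informative model statement.
Second, V150/V200 of the asymmetric plan evaluate to roughly 38 cc and
10.5 cc here: the dwell columns span 3.5 cm inside a 4.4 cm balloon, so
their ends sit ~0.45 cm from the balloon poles and the polar caps just
outside the balloon exceed 150 % of prescription under any superposition
that lacks inter-source shadowing. A full-transport dose grid (with the
iridium columns shadowing each other) would shrink these polar volumes
substantially, but the volume metrics are defined on the planning-system
surrogate, as they are clinically.

## The scenario generator

The study matrix is generated deterministically from a master seed:
{cuboid, spherical} phantoms x tissue depths 0–10 cm in 1 cm steps x
{symmetric, asymmetric} plans (44 finite-depth records), one full-scatter
reference per plan, wire-on variants of the cuboid symmetric sweep and a
wire-on reference. Per-scenario seeds derive from the master seed; the
manifest is a pure function of (master seed, scale). The scale parameter
expresses histories per scenario as a fraction of the full-study 5 x 10^7;
the desk default of 0.02 (10^6 histories) targets a few percent relative
standard error at the detector, and the full scale is available by flag.

What the generator emulates is the study design, not patient data: perfect
spheres and boxes of pure water, a geometrically ideal applicator, and a
point-symmetric dwell loading. Passing tests therefore demonstrate the
internal consistency and physics fidelity of the pipeline under these
idealized conditions — not performance on CT-derived anatomy, heterogeneous
tissue, or real afterloader dwell times.

## Statistical and numerical choices

* Detector tallies at 10^6 histories carry ~4–5 % relative standard error;
  the headline underdose numbers use 2.6–3 x 10^7 histories per run, and the
  batch-estimated error scales as 1/sqrt(n) (fitted slope −0.5 ± 0.05 over a
  100x range in the suite). In configurations that are exactly 4-fold
  symmetric (full-scatter or spherical phantom with a symmetric plan) the
  reference-point dose is estimated as the average over the four equivalent
  cardinal detectors — a pure estimator-efficiency choice that roughly
  halves the error; a single 0.17 cm detector converges to ~0.6 % rse at the
  full 5 x 10^7 scale, the averaged estimate to ~0.3 %.
* Sub-percent comparisons (symmetric vs asymmetric DMF, the steel-wire
  effect) use common random numbers: identical seeds, and where only the
  weights differ, literally the same per-dwell sub-tallies re-weighted.
* The steel wire is modelled as type-304 (iron-grid coefficients at
  8.0 g/cm^3), radius 0.045 cm, running along each active lumen from the
  balloon entry pole up to the bottom of the occupied dwell span -- the
  cable trails the source train rather than enclosing it, which both matches
  the delivery geometry and preserves the common-random-numbers pairing of
  wire-on/off runs (a wire overlaying every source would perturb every
  history). The device description gives no dimensions, so these sit in the
  config.
* Boundary crossings push positions by 10^-6 cm; ray tracing is validated
  against a 1 micrometre membership-marching oracle to 10^-4 cm, and traced
  segments partition world chords to 10^-3 cm.
* Kernel nodes that collect no collisions at desk scale (far corner bins)
  are floored to a tiny positive value so log-interpolation stays defined;
  the provenance records how many, and a warning is recorded whenever any
  node exceeds 1 % statistical error.
* Problem sizes used by the reproduction script: 2 x 10^7 histories for each
  underdose run, 1.6 x 10^7 for the kernel, 5 x 10^6 per depth for the
  paired sweeps, chosen so each quantity's statistical error is small
  against its physical effect.

## Known limitations

* Kerma-only scoring, free-electron Compton, no bound-electron or Doppler
  corrections, approximate coherent channel: adequate for ratios at Ir-192
  energies, not for absolute low-energy dosimetry.
* The iridium table is a documented approximation assembled from analytic
  Compton and scaled photoelectric terms, not a standard-reference grid.
* The kernel superposition, like any TG-43-style system, ignores
  inter-source and applicator shadowing; the transport engine models them.
* The applicator is geometrically ideal; elliptical balloon fills, the
  4.5–6 cm device size, and CT-derived patient geometry are out of scope,
  as are heterogeneity-aware (TG-186-style) dose algorithms.
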