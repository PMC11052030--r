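---
title: "Coarse-grained cell mechanics with cytomech: model, assays, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained cell mechanics with cytomech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytomech)
```

## The model

`cytomech` builds a mechanical model of a suspended cell from dissipative
particle dynamics (DPD).  Every component is a set of particles of unit
mass in reduced units (energy scale `kBT = 1`, cell radius 8).  Non-bonded
particles interact through the three standard DPD pair forces inside a
cutoff `r_c`: a soft conservative repulsion `a_ij (1 - r/r_c) r_hat`, a
dissipative force `-gamma w_D(r) (v_ij . r_hat) r_hat` with
`w_D = (1 - r/r_c)^2`, and a random force `sigma w_R(r) eps/sqrt(dt) r_hat`
with `w_R = sqrt(w_D)`.  The fluctuation-dissipation relation
`sigma^2 = 2 gamma kBT` is enforced structurally: `sigma` is always derived
from `gamma`, never stored.  Momentum is conserved exactly because every
pair term (including the random one, which uses a single shared normal
deviate per pair) is antisymmetric.

**Membrane.**  A closed icosphere triangulation whose vertices are DPD
particles and whose edges are worm-like-chain (WLC) bonds with a power-law
(POW) repulsion `kp / l^m`.  The bond energy is supplemented by a cosine
dihedral bending term across every edge, harmonic global area and volume
constraints, and a local per-face area constraint (constants
`ka = kv = 7.5e3`, `kd = 300`).  The membrane's viscosity is modelled by
dissipative and random forces on the bonds themselves, with a central and
a tangential channel, each paired with matched noise
(`sigma^2 = 2 gamma kBT` per channel).  The tangential channel matters:
with central-only bond friction the transverse membrane modes are
essentially undamped and tracer motion stays inertial across the whole
observable window.

The user-facing stiffness knob is the WLC shear modulus `mu0`.  Given
(`mu0`, `x0 = l0/lmax`, `l0`, `m`) the persistence length `p` and the POW
constant `kp` are obtained in closed form from two conditions: the printed
shear-modulus expression evaluates to `mu0`, and the net bond force
vanishes at `l0`.  Both conditions are linear in `1/p` after substitution,
so calibration is exact (`calibrate_wlc()`), and `shear_modulus()` returns
the target to rounding error.

Defaults the underlying study leaves open, fixed here once:
`x0 = 0.45` (so the 2 l0 rupture length lies below the contour length
`l0/x0`, without which the rupture criterion could never fire),
`m = 2` (common POW exponent), `mu0 = 100` and `kbending = 65` (the
mid-range of the values the indentation study sweeps), and spontaneous
dihedral angles equal to the built icosphere's own dihedrals (a relaxed
sphere is stress-free).

**Cytoskeleton.**  Filaments are straight chains of particles at 0.25
spacing joined by stiff harmonic bonds (`U = k (r - r0)^2`, printed
convention without the 1/2, `k = 8e4`) and straightening angles
(`k = 350`, rest angle pi).  Actin cross-linking proteins (ACPs) are free
particles that bind up to two filament particles each (a filament particle
carries at most one ACP link); membrane-filament links form by the same
rule.  Binding and unbinding follow the Bell law
`k = k0 exp(-sigma (l - l0)^2 / (2 kBT))` converted to per-interval
probabilities `P = 1 - exp(-k dt)`; binding is attempted below `d_on`,
unbinding at or beyond `d_off`.  Cross-linked junctions additionally carry
a four-body cosine twist term (`kb = 550`) whose rest angle is the
dihedral at formation.  The shipped table also names a torsion constant
`kt = 470`; since the twist term is the only printed four-body form, `kt`
is stored but unused.

Network assembly is staged: generate non-intersecting filaments (minimum
clearance of one bond length), scatter ACPs, cross-link to saturation,
form membrane-filament links, then activate junction dihedrals at their
formation geometry and relax.  "Saturation" is realised as a
capacity-respecting greedy matching over all eligible pairs within `d_on`,
seed-shuffled for determinism: it is the fixed point the stochastic rule
converges to, reached directly instead of waiting out the slow shipped
rates (`k0 = 26e-4`).

## Integration and time steps

A DPD-modified velocity-Verlet scheme with velocity-prediction factor
`lambda = 0.5` advances the system; frozen particles exert forces but move
only under prescribed motion (rigid probes, plates, pipettes).  Forces are
evaluated once per step; a Verlet pair list built on a cell grid with a
0.3 skin is refreshed every five steps.

Three time steps are used, set by stability rather than taste: 0.005 for
plain fluids (the generic soft-DPD choice), 0.001 for membrane systems
(about six viscous bonds per vertex give an effective friction near 270,
and the thermostat is accurate only for `gamma dt` well below 1), and
2e-4 wherever filaments are present (the `k = 8e4` springs oscillate at
about 566 rad per time unit).  The temperature tests pin these choices:
an equilibrated solvent cube and a relaxed free membrane both hold
`kBT = 1` within 2%.

Determinism: a single 64-bit generator seeded from the run configuration
drives every stochastic term, so identical seeds give bit-identical
trajectories on one thread.  Initial velocities additionally have their
net linear and angular momentum removed (`remove_rigid_drift()`): DPD pair
forces are central, so an isolated body would otherwise rotate coherently
forever and contaminate tracer statistics.

## Assay 1: particle-tracking microrheology of the membrane

`membrane_microrheology()` equilibrates a free membrane, records unwrapped
trajectories of 40 vertices, and forms the multi-origin mean-square
displacement (lags up to a quarter of the run).  The generalized
Stokes-Einstein conversion
`|G*(s)| = kBT / (pi a <dr^2(1/s)> Gamma[1 + chi(s)])` with
`G' = |G*| cos(pi chi/2)`, `G'' = |G*| sin(pi chi/2)` uses the local
log-log slope `chi`, fitted by a second-degree polynomial in a sliding
one-decade window.  The tracer radius `a` defaults to half the membrane
bond length (the tracked "particles" are membrane vertices; no radius is
stated for them).

Two analysis guards are part of the assay's definition, not afterthoughts:
the conversion is meaningful only in the overdamped regime, so lags whose
slope exceeds 1 (inertia-dominated short times) are excluded; and the
"high-frequency" power-law exponent is fitted over the top decade of the
remaining Laplace frequencies, evaluated at the window midpoint.  The
reduced assay runs an icosphere at subdivision level 3 (642 vertices,
2e5 production steps at dt 0.001); at that size the whole pipeline takes
about a minute on one CPU.

## Assay 2: two-plate oscillatory shear of the network

`build_network_slab()` makes a fully periodic cross-linked network.  The
box is sized so the mesh size `sqrt(V / total contour length)` is about
twice the binding distance; much sparser networks simply do not form ACP
bridges (the same generator at the full cell's interior density yields a
handful of cross-links and no percolation).  Relaxation is quenched in
stages -- random placement releases overlap energy at startup, and the
velocities are rescaled to the energy scale between stages so production
starts cold.  During long driven runs a weak background Langevin bath
(friction 0.05, three orders below the pair friction, applied
impulse-equivalently every ten steps) absorbs the slow numerical heating
a sparsely-contacted stiff network otherwise accumulates.

`run_oscillatory_shear()` freezes the bottom and top 5% z-slabs (selected
by z-quantiles; through the periodic wrap the two slabs are contiguous
and act as one rheometer wall).  Bonded terms internal to that wall are
excluded exactly like frozen pair terms -- otherwise the plates are
spring-coupled to each other and the "modulus" is just the filament
spring constant.  The top plate is driven as
`s(t) = gamma0 h sin(2 pi fs t)` with `gamma0 = 0.02`; the stress is the
shear force the sample exerts per box cross-section, read from both
plates (equal and opposite below the inertial regime, independent thermal
noise) and averaged over each sampling interval.  After discarding two of
the ten cycles, a least-squares sinusoid at the drive frequency (with a
linear drift regressor absorbing slow network wander) gives amplitude and
phase, and `|G*| = |tau|/gamma0`, `G' = |G*| cos(phi)`,
`G'' = |G*| sin(phi)`.

The shipped sweep uses six frequencies `0.05 * 2^(0:5)`: low enough that
the bottom of the band sits on the network's elastic plateau and the
G''/G' crossover falls inside the band, high enough that ten-cycle runs
at the stability-limited time step stay within desk budgets.  The
high-frequency exponent is fitted on `|G*|` over the top decade with the
same polynomial convention as the MSD slope.

A scaled-down caveat belongs here rather than in fine print: the
weak sublinear high-frequency exponent reported for cross-linked actin
(around 3/4) arises from single-filament transverse bending fluctuations
between cross-links.  At this network's prescribed reduced size the
strands between cross-links are only one to three bonds long, so that
fluctuation spectrum is structurally absent, and the measured top-decade
exponent lands on the viscous side (about 0.9-1.1 across seeds) above a
clearly present G''/G' crossover.  The crossover and the qualitative
plateau-to-fluid transition reproduce; the exponent's precise value does
not at this scale.

## Assay 3: conical indentation with Sneddon fitting

A rigid cone (half-angle 18 degrees from the indentation axis, surface
particle spacing 0.18 so the wall has no gaps at the 0.25 interaction
cutoff) approaches the cell resting on a fixed substrate at constant
speed.  After settling, the basal membrane patch in contact with the
substrate is anchored -- the experimental dish is coated with an adhesive
polymer, and without that anchor a reduced cell simply recoils and bounces
against the probe.  The load is the axial force the cell exerts on the
probe, interval-averaged; the contact point is the first sustained
excursion of the smoothed load above three pre-contact noise standard
deviations.

`sneddon_fit()` inverts `F = (2/pi) (E/(1-nu^2)) tan(alpha) delta^2` over
a depth window (default 0.4 to 0.8 from contact) by the two-point method
on a moving-average-smoothed curve (a least-squares variant is provided);
`nu = 0.5` treats the cell as incompressible.  On synthetic Sneddon
curves the round trip is exact to 1e-10 for any admissible
`(E, alpha, nu)`.  The parameter sweep repeats the assay across
`mu0 = 5, 50, 100, 300` and bending stiffnesses with a shared seed, and
checks that the fitted modulus increases with `mu0` while sweeping `lmax`
at fixed `l0` leaves the curves within a noise band.

## Assay 4: microinjection with rupture detection and strain analysis

The microinjection environment holds the cell against a holding pipette
by a simplified aspiration force field (a constant body force toward the
mouth on membrane particles inside a capture cylinder), advances an
injection needle along the y axis at constant speed, checks every
membrane bond each step, and halts at the first bond longer than twice
its rest length, exporting the full state.

Reduced scale makes four geometric choices necessary; all were forced by
observed failure modes of the literal full-scale setup, and all are
recorded here because they define what the desk-scale assay does and does
not show:

* the **needle is cone-tipped** (`make_injection_needle()`).  A blunt
  open tube of realistic bore either swallows a coarse membrane through
  its mouth or is wrapped like fabric without any bond ever doubling; a
  sharp tip wedges one triangle open with geometric amplification, which
  is how a bevelled micropipette punctures.
* **pipette walls have two particle layers.**  DPD wall potentials are
  soft (`a = 100`, and only 30 against the holding pipette); a single
  layer is penetrable under assay loads.
* the **membrane mesh must be finer than the tools.**  Per-vertex forces
  from the area/volume constraints scale with `l0^2`; on a coarse mesh
  they exceed the wall barrier and the membrane presses through the
  needle surface before any bond reaches the rupture length.  Injection
  cells therefore use subdivision level 3 at their reduced radius.
* after aspiration stabilises (tongue length varying by less than 1% of
  the bore radius between check windows, with the field magnitude
  auto-calibrated toward a tongue of about one bore radius), the captured
  membrane cap is **anchored** for the injection stage: the body-force
  field cannot resist the lateral torque of the advancing needle on a
  reduced cell, which otherwise escapes as a rigid body.

The checkpointed post-aspiration state is the strain reference, so the
measured field is injection-induced deformation only.  Strain follows the
local-affine construction: per particle, the least-squares deformation
gradient over a neighbourhood (radius 1.5 times the mean spacing), right
polar decomposition `J = R U`, strain `E = U - I`, scalar strain the
diagonal element along the injection axis.  The estimator is exact for
affine motion, frame-indifferent, and flags rank-deficient
neighbourhoods instead of inverting them.  Histograms use bins of width
0.05 on [-1, 1]; the comparison metrics are the histogram
intersection-over-union (Jaccard), the Bhattacharyya distance
`-ln sum sqrt(p q)`, and the Jensen-Shannon divergence with natural
logarithm (the printed experimental values do not state the log base; the
natural log keeps the [0, ln 2] range).

The reduced speed family {0.25, 0.75, 1.25} preserves the 1:3:5 ratio of
the study's injection speeds; no physical-to-reduced speed mapping is
stated anywhere, so the micrometre-per-second labels are carried as
metadata only.

## What the synthetic systems do and do not show

The generators used by the tests and the acceptance analyses emulate an
equilibrated DPD fluid, a closed relaxed membrane, a percolating
cross-linked slab, and point clouds under known affine maps.  They
reproduce the model's own statistical mechanics -- thermostat accuracy,
constraint maintenance, binding-capacity invariants, exact
affine-strain recovery -- and the qualitative mechanics the paper reports
(power-law rheology, stiffness ordering under indentation, rate-dependent
rupture).  They do not contain a zona pellucida, nucleus, solvent
hydrodynamics, or any experimental imaging noise, so quantitative
agreement with wet-lab values beyond the reproduced summary statistics is
outside what passing tests demonstrate.

Problem sizes used throughout (level-3 membranes, ~800-particle slabs,
radius-2.5 injection cells, 3 seeds for orderings) are the package's
reduced-scale defaults; they were chosen so each assay completes in
minutes while keeping the mesh-versus-tool and band-versus-resonance
hierarchies described above intact.

## Known limitations

* The cytoskeletal slab's modulus has large seed-to-seed variability at
  800 particles, and its high-frequency exponent sits near 1 (viscous)
  rather than the sublinear semiflexible value, for the structural reason
  given in the assay-2 section.
* Plate-force rheometry cannot reach the elastic plateau at very low
  frequency within desk budgets, and is invalid above the shear-wave
  resonance; the usable band is roughly 1.5 decades.
* The aspiration field is a body-force surrogate: it reproduces holding
  and tongue formation but not intra-pipette flow.
* Bond rupture is evaluated only during microinjection, per the protocol;
  free equilibration assumes intact bonds and errors if a WLC bond
  reaches its contour length.
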