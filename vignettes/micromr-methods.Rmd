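---
title: "Models and methods behind micromr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind micromr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

micromr is a desk-scale, self-contained implementation of the molecular
replacement and iterative model-rebuilding workflow of macromolecular
crystallography: a homologous template is edited to the target sequence,
placed in the unit cell against observed structure-factor amplitudes, and the
placed model is then improved by alternating density modification,
density-guided fragment rebuilding, real-space refinement, and R-factor-driven
iteration. Every stage runs on synthetic toy crystals generated by the
package itself, so the entire chain of reasoning — from amplitudes to an
improved model — is verifiable offline. This vignette explains the models
and the numerical choices; it states no result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The crystallographic model

Atoms are points with an element, an occupancy and an isotropic displacement
parameter B (Å²). The calculated structure factor of a model is

    F(h) = sum_ops sum_atoms f_el(s) * occ * exp(-B s^2 / 4) * exp(2 pi i h . x)

with `s = 1/d` and 4-Gaussian-plus-constant scattering factors packaged for
C, N, O and S — the only elements the toy models contain. Two independent
routes compute F: direct summation (`sf_direct`, exact, used as the oracle)
and an FFT route (`sf_fft`) that samples atom Gaussians on a grid of roughly
d_min/3 per axis. The FFT route adds an anti-aliasing smearing B (default
30 Å²) during sampling and divides it out exactly afterwards, which keeps the
sharpest Gaussian terms representable on the grid; with this trick the two
routes agree to an amplitude R of about 1e-4 on the standard fixture, far
inside the 0.005 band the tests enforce.

Observed-vs-calculated agreement is the classical R factor after fitting one
overall scale k and one overall B by least squares on the working set;
cross-validation flags mark about 5% of reflections (one per block of ~20,
so the realized fraction is tightly controlled) and are never touched by any
model-improvement step.

Maps are plain 2Fo−Fc syntheses with model phases and overall k/B scaling —
not sigma-A-weighted coefficients. This is a deliberate fidelity limit:
error-dependent weighting would add machinery without changing the control
flow the package exists to demonstrate, and all map-quality claims in the
tests are made relative (improvement over a starting map), where the
weighting scheme cancels to first order.

## Search: rotations, translations and copy numbers

The search target is the Pearson correlation between squared observed and
squared calculated amplitudes — the classic correlation translation
function. Orientations are enumerated on a deduplicated zyz Euler grid
(default 15°; the examples and tests use 30–45°, which the recovery
tolerances in the tests are stated against). For each orientation the
translation scan is exact and fast: the calculated intensity at every
fractional offset is assembled from per-symmetry-operator structure factors
and precomputed phase shifts, so the grid scan costs one complex matrix
multiply rather than one structure-factor calculation per point.

Two identifiability facts shape the tests. In P1 with a single copy and no
fixed model, amplitudes are invariant under any global translation: the
translation function is flat, and the package reports the lexicographically
first grid point — the origin — as the canonical representative. Translation
recovery is therefore demonstrated where it is physically defined: in P21
(x and z determined modulo the 1/2-cell origin choices) and in P1 with a
fixed second molecule, whose cross terms break the invariance. Copy numbers
come from the Matthews relation (`solvent = 1 − 1.23/Vm`, admissible window
0.20–0.80, ranked by closeness to 50% solvent); when the copy count is known
it can be given directly, which is also what the pipeline examples do,
because the deliberately loosely-packed toy cells (see below) make the
Matthews ranking prefer overfilled cells. Solutions are rescored under a
common criterion — amplitude correlation after one shared B inflation — the
package's stand-in for rescoring all solutions under one assumed template
error.

## Density modification and NCS averaging

Density modification is classical solvent flattening with phase
recombination: per cycle, the solvent mask (points more than 4 Å from the
model, trimmed or grown by density ranking to the target solvent fraction)
is flattened to its mean, non-crystallographic symmetry is averaged in when
operators are present, and the map is resynthesized from amplitudes reset to
the observed values with phases `arg(0.5 F_mod + 0.5 F_start)`. The
modification is phase-only by construction — work and free amplitudes are
treated identically — and five cycles is the default.

NCS operators are detected from chain pairs with matching sequence (≥ 90%
identity over shared numbering) by CA superposition, discarding pairs above
2.0 Å. Averaging uses the *invariant core* region: grid points within 5 Å of
the reference copy whose images under every operator stay clear of all other
copies' neighborhoods, so no point mixes two molecular environments. Sampling
is tricubic with periodic wrap, and — a subtle point worth recording — the
back-mapping of a grid point through an operator uses its *unwrapped*
coordinates relative to the copy it belongs to: a lattice translation is not
an NCS symmetry, so wrapping before rotating would land the preimage in the
wrong place. Written copy regions are dilated by the interpolation support
and overlap is resolved by nearest-copy ownership, which together make the
operation idempotent to within interpolation error (region correlation
> 0.999 on the exact-NCS fixture) and reduce independent noise by close to
the theoretical 1/sqrt(n).

## The combined score and rebuilding

Model quality during rebuilding is a single scalar:

    score = w_dens * fit - w_geom * (bond_dev + angle_dev/50 + clash + 2 * rama_out)

where `fit` is the occupancy-weighted mean map value at atom centers
(residue-averaged, on a standardized map), `bond_dev`/`angle_dev` are rms
deviations from ideal values, `clash` counts non-bonded pairs under 2.4 Å
and `rama_out` is the fraction of residues outside broad allowed torsion
regions. Unbuilt gap residues contribute zero to the density mean, so
completing the model is rewarded the way added correct atoms lower an R
factor. The default weights are `w_dens = 1`, `w_geom = 4`: the geometry
weight was set so that a correct ideal-geometry model is a stationary point
of the score in its own map on the standard fixture — with a weaker weight
the density term alone pulls atoms measurably into series-termination
ripples, which would make "refinement leaves a correct model alone"
false.

Rebuilding is Metropolis Monte Carlo over fragment proposals: a random
3-residue window (9-residue in long segments) or an unbuilt gap of up to 8
residues is re-grown with torsions drawn from the packaged fragment library
(canonical helix / strand / polyproline / turn / loop archetypes plus
seeded ±10° jitter, ~200 entries, generated deterministically in code and
serializable to JSON). Internal windows must close onto the downstream
anchor: proposals are closed by cyclic coordinate descent over the window's
phi/psi pivots, accepted only if the residual is at or below 0.5 Å (1.0 Å
for gap loops, whose anchors are themselves imperfect), and the residual is
then distributed linearly along the stretch. The temperature (default 0.4,
annealed linearly to a tenth over the trajectory) was tuned once for roughly
30% acceptance on the standard fixture; annealing makes end-of-trajectory
models near-locally-optimal, which matters because the operation's
contract returns end-of-trajectory states, not best-seen states. Desk-scale defaults are 20
trajectories of 300 steps — an explicit scale-down from the thousands of
models a production structure-modeling run would generate; the tests use
6–8 trajectories of 100–150 steps and state their sizes where they do.

With several NCS copies, one reference copy is rebuilt and the best result
is replicated through every operator, giving exact (idealized) NCS — the
inter-copy rmsd of the output is numerically zero regardless of input
asymmetry.

## Real-space refinement

Reciprocal-space refinement is approximated by real-space refinement against
the current density-modified 2Fo−Fc map plus the overall k/B fit. Two
stages: a rigid-body fit (Nelder-Mead over 6 parameters; geometry-invariant,
so any accepted move is pure density gain — accepted only above a small
material-gain threshold so the stage does not chase the tiny
series-termination offset of the density optimum at convergence), then
gradient ascent over all coordinates with analytic gradients for the density
and bond/angle terms, a backtracking line search on the *true* combined
score (so clash and torsion terms participate through acceptance), a hard
0.5 Å per-iteration cap on any atom's shift, and a guarantee that the score
never decreases. The objective is evaluated on a 3× band-limited Fourier
upsampling of the map: on the raw synthesis grid the trilinear score
landscape has its maxima at grid nodes, which would lock atoms to the grid.

## The autobuild loop and the pipeline

One autobuild cycle is: structure factors → k/B scaling and R → 2Fo−Fc →
density modification → Monte-Carlo rebuild of the worst-fitting 20% of
residues → real-space refinement → pruning of residues fitting worse than
(mean − 2 sd). Iteration stops when R_work changes by less than 0.005
(the package's reading of "no substantial change"), when R has risen three
cycles in a row, or at the cycle cap; the lowest-R model and its map are
returned. The full pipeline wraps this in an outer loop (default 3 cycles)
over refinement + density modification, NCS-aware rebuilding with top-model
selection (default: top 2 by amplitude correlation; maps from the top 4
models are averaged when available), and autobuilding. Refinement inside the
pipeline is R-driven in the usual sense: each refinement runs at the default
geometry weight and, when the working R does not drop, once more at a third
of it, keeping the lower-R model (the stiff default that protects correct
models also immobilizes marginal ones in their own biased maps). The best
model by R_work is tracked across *all* stages — a stage whose output is
worse than its input is logged but never carried forward — and a first cycle that
cannot improve its own starting R is treated as evidence of a fixed point
and terminates the run, which is exactly the observed behavior when the
true structure is supplied as the placed model. All randomness derives from
the single configuration seed through a fixed per-stage offset scheme, so
identical configurations reproduce identical histories bit for bit.

The optional pre-search stage emulates structure optimization without
diffraction data by running the same Monte-Carlo machinery with the density
weight set to zero: only the geometry surrogate drives acceptance, and the
best-scoring model proceeds to the search.

## The synthetic crystals, and what they do not show

`fixture_spec()` defaults define the standard study conditions: a
30-residue helix-turn-helix in P1, one copy, 2.5 Å data with 5% relative
Gaussian amplitude noise, and homolog templates at 30% sequence identity
perturbed to 1.5 Å main-chain rmsd — the marginal-template regime in which
density-guided rebuilding is decisive rather than cosmetic. Perturbation is
a smooth low-frequency torsion-space field rebuilt through ideal-geometry
chain extension and rescaled to the target rmsd (±10%), so template error
is spatially correlated, as homolog divergence is, rather than i.i.d.
atomic noise that rigid placement would average away. Homologs carry random
substitutions plus 0–2 short deletions that become loop-building targets.
Amplitude noise is relative Gaussian without counting statistics; under the
R-factor definition used here, 5% noise yields R ≈ 0.04 for the generating
model, which the tests verify by simulation.

Known departures from real data, and hence limits on what green tests
mean: the toy chains are backbone-plus-CB only (side chains beyond CB exist
only during template editing), cells are loosely packed (solvent fractions
of 70–85% rather than ~50%, because an isolated short helix cannot fill a
box the way a packed lattice does — this is why the pipeline examples state
the copy number instead of trusting the Matthews ranking), B factors are
uniform, there is no bulk solvent, no measurement-error model beyond
relative noise, and map-correlation figures are plain Pearson correlations
on the asymmetric grid rather than any weighted-region convention. The
mechanisms demonstrated — placement degrading smoothly with template error,
density modification and map averaging clearing model bias, rebuild cycles
lowering R while moving the model toward the truth — are the phenomena
this package demonstrates at toy scale; absolute numbers from real
structure determinations are out of reach without real diffraction data and
a full force field, and the package does not claim them.

## Degenerate inputs and tie-breaks

Alternate locations collapse to the highest-occupancy conformer (ties by
altloc letter); insertion codes are rejected with a line number. Flat
translation functions (P1, single copy) resolve to the lexicographically
first grid point. Equal search scores break by grid order. Systematically
absent reflections are excluded at generation and verified to compute to
zero. Maps with zero variance are rejected wherever a correlation or
standardization is requested. The translation grid is guarded at 64^3
points, and space groups beyond P1, P21 and P212121 must be supplied as
explicit operator lists.
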