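---
title: "Statistical mechanics of protofilament peeling: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical mechanics of protofilament peeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A shrinking GDP-rich microtubule sheds its wall as outward-curled
protofilaments ("ram's horns"). `mtpeel` models one protofilament as a
discrete worm-like chain of `N` rigid subunits of length `b = 8` nm (a
tubulin dimer), clamped at the minus end along the tube axis, interacting
with a rigid straight neighbor through one breakable Hookean spring per
subunit:

- lateral bond: `E_s(l) = ks/2 (l - l0)^2` for `l < lmax`, constant
  `E_ms = ks/2 (lmax - l0)^2` beyond — a bond stretched past `lmax = 1.2 l0`
  is broken but re-forms, history-free, whenever the distance drops back
  below `lmax`;
- bending: `E_b(theta) = kb (1 - cos(theta - theta0))` per longitudinal
  bond, with preferred angle `theta0 = theta_D = 0.4` rad for GDP subunits
  (intrinsic curl radius `rc = b/theta_D = 20` nm) and `theta_T = 0` for
  GTP subunits, which is what makes a GTP cap stabilizing;
- `E_mb = kb (1 - cos theta_D)` is the bending strain a straightened GDP
  bond stores inside the lattice.

The single control parameter of the stability "power struggle" is
`delta_E = E_ms - E_mb`. The reaction coordinate is the tip position
`Rx = L - x_N` (`L = N b`): `Rx ~ 0` is the tubular state, `Rx -> L` fully
peeled. Energies are in kBT, lengths in nm, angles in rad; temperature
enters only through a dimensionless scaling factor whose limit 0 is the
zero-temperature theory.

Geometry conventions the data structures rely on:

- node `k` sits at `node[k-1] + b (cos Theta_k, sin Theta_k)` with
  `Theta_k` the cumulative bond angle (the clamp angle of subunit 1 is the
  first entry and is held at 0 during sampling, but still stores bending
  strain);
- the rigid neighbor runs parallel to the axis at offset `-l0`, and the
  spring of subunit `i` connects its distal node to the fixed point
  `(i b, -l0)`, so the straight chain has every bond exactly at rest length
  and the preferred curl peels *away* from the neighbor (the mirror image
  of the same construction with the neighbor at `+l0`);
- the peeled count `Nc` counts contiguous broken bonds from the tip inward;
  an interior broken bond behind intact tip bonds does not contribute to
  the peeled length `Lc = Nc b`.

Whether the lateral distance is taken node-to-node or center-to-center is
not fixed by the physics; the node convention is used throughout. This
choice (like any attachment-point convention) shifts the entropy balance
of peeling by a few tenths of kBT, which is worth keeping in mind when
comparing absolute `delta_E` values across implementations; see
"Placement of the stability transition" below.

### Discreteness and the arc relation

A fully peeled segment of arc length `Lc` relaxed onto its intrinsic curl
obeys, in the continuum limit, `Rx0(Lc) = Lc - rc sin(Lc/rc)` — flat
wherever the arc closes full circles (`Lc` a multiple of `2 pi rc ~ 125.66`
nm), which is where peel states pile up and the free energy develops its
interior minima. The discrete chain itself satisfies the exact closed form
`x_N = b [sin(N theta + theta/2) - sin(theta/2)] / (2 sin(theta/2))` for a
uniform bond angle `theta`; this differs from the continuum relation by up
to `~b/2` depending on where `N theta` sits on the circle (0.06 nm at
`N = 16`, up to several nm elsewhere). Tests therefore pin the geometry to
the exact discrete form and treat the continuum relation as an
approximation valid to within one rod length; all landscape structure
(minima spacing, the `~125` nm state) is insensitive to this.

## Sampling

`run_chain()` is a pivot-move Metropolis sampler: one randomly chosen
movable bond angle is incremented by a uniform draw in ±1.5 rad, the distal
segment rotates rigidly, and the move is accepted with probability
`min(1, exp(-beta dE))`. At the standard parameters acceptance lands in the
few-percent range. The wide ±1.5 rad proposal is deliberately kept: it lets
a single move form or break a bond outright, which is what carries the
chain across the lateral-bond barriers.

Because direct sampling mixes slowly across the multi-minima landscape,
`sample_landscape()` uses harmonic umbrella windows on `Rx` (default
spacing 10 nm, stiffness 0.1 kBT/nm², each seeded from a partially peeled
configuration near its center) recombined by self-consistent histogram
reweighting (`wham_combine()`, convergence when the window free-energy
shifts move by less than 1e-8 kBT). The umbrella bias is the standard
harmonic form; the recombination makes no assumption about the bias shape
beyond its tabulated values on the shared 2-nm bins. A split-half
diagnostic (`split_half_rms()`) recombines the first and second halves of
every window separately and reports the RMS discrepancy of the two
free-energy estimates.

Default problem sizes were chosen so a full landscape (27 windows,
1e7 steps each) completes in about two minutes on one core while holding
the split-half RMS well under 0.3 kBT in the regimes studied; production
curves simply scale `n_steps` up. Burn-in defaults to 10% of the run and
recording to every 100 steps; both are configurable and, with the pivot
move's short correlation time at few-percent acceptance, uncontroversial.

## From landscape to kinetics

`free_energy_from_distribution()` sets `F = -ln P` on the occupied bins
(empty interior bins are interpolated with a warning, never silently
extrapolated beyond the sampled support). All consumers are invariant to
the additive constant.

Mean first-passage times use the double integral for diffusion on `F(Rx)`
with a reflecting boundary at the start `A` and an absorbing boundary at
the target, evaluated by cumulative trapezoids on a 20001-point grid over
the cubic-spline interpolant; both integration orders agree to better than
1e-6 relative and the flat-landscape closed form `(B-A)^2/2D` is
reproduced to 1e-3. The boundary choice (reflecting at `A`) is stated
explicitly because it is not forced by the integral's notation. The tip
diffusion coefficient is Stokes-Einstein, `D = kBT/(6 pi eta a)` with
`eta = 0.001` Pa s and `a = 40` nm (the circle a curled GDP protofilament
makes) — about `5.46e6` nm²/s at 298 K; both inputs are configurable.
States A, B, C sit at `Rx = 0`, one curl circumference (125 nm) and two
(250 nm); the unzippering velocities are `v_AB = 125 nm / tau_AB`,
`v_AC = 250 nm / tau_AC`.

Minima detection smooths `F` with a 4-nm Gaussian first (raw `F` is always
used for kinetics), then keeps local minima whose depth below the lower of
the two barriers closing the well off — the highest point on each side — is
at least 1 kBT ("prominent"). A landscape with no interior maximum reports
no minima, but a well at the support edge behind a genuine barrier still
counts: the tubular state at `Rx ~ 0` is such a well. This side-maximum
reading of the flanking barrier is deliberately permissive; the stricter
key-saddle (topographic) prominence would rate the shallow well near the
fully peeled end at `delta_E = 1.2` just below 1 kBT.

## Shrinkage dynamics

`simulate_shrinkage()` couples overdamped Euler-Maruyama dynamics of the
tip on the landscape (`dRx = -D F' dt + sqrt(2 D dt) xi`, default
`dt = 1e-7` s, mirror reflection at both support ends, drift-per-step
checked against the bin width at start-up) to a Poisson dissociation
process active only while `Rx` exceeds a gate (default one subunit,
8 nm — subunits do not leave the tubular state). Each event removes the
terminal subunit: the observable length drops by `b` and the tip is
remapped through the arc geometry, `Rx -> Rx0(Lc(Rx) - b)`, implementing
the switch to a similar-but-shorter landscape without resampling. The
dissociation rate `k_off` is an explicit tunable (default 75 /s, so that
`b k_off ~ 0.6` um/s brackets the observed GDP shrinkage scale) and is
surfaced in every report, as is the geometric factor `l_d` (default 1)
relating tip excursion to observable length,
`L(t) = L(0) - Rx(t) l_d - b Nd(t)` — an identity that holds exactly at
every recorded sample.

Ram's-horn observables: an unzippering event is a maximal excursion with
`Rx > 10` nm; excursions or gaps shorter than ten sample intervals are
merged before computing the mean lifetime `Tu` and event rate `Nu` (with
no events, `Nu = 0` and `Tu` is reported missing, not zero). A pulling
force tilts the landscape exactly, `F(Rx, f) = F(Rx, 0) + f Rx` with
`1 kBT/nm = 4.114 pN` at 298 K.

## Three protofilaments

`build_3pf()` places three chains whose minus-end nodes form an
equilateral triangle of side `l0` (so the straight tube has every lateral
bond at rest; this is the unique side length giving a strain-free ground state). Each chain
fluctuates only in the plane spanned by the tube axis and its own radial
direction; subunit `i` of protofilament `alpha` bonds to subunit `i` of
`alpha+1` cyclically, distances taken in 3-D between distal nodes with the
same breakable spring. Freezing protofilaments implements the `p = 1, 2, 3`
bendable cases; the effective lateral energy per bendable protofilament is
`2 E_bond` (p = 1), `3 E_bond / 2` (p = 2) and `E_bond` (p = 3).
`destabilization_threshold()` bisects the per-subunit bending strain for
the smallest value at which the bendable protofilaments' mean tip position
reaches `L/2` (at `L = 15 b` and 4 kBT per bond), to a ±0.25 kBT bracket.
Here `p` always counts the bendable protofilaments (descriptions of this
setup sometimes index the cases by the number of stabilized neighbors
instead; the two conventions are easy to confuse).

## Semi-analytic reference

`semi_analytic_p()` approximates the tip distribution as a mixture over
peeled counts: weight `exp(-delta_E Nc)` at position `Rx0(Nc b)` with a
Gaussian of width `sigma0 sqrt(Nc)` (default `sigma0 = 2` nm — thermal
width grows with the free arc length; no closed form is available, and
only the peak *positions*, which are geometry-driven, feed any assertion).
The folding of `Rx0` near multiples of `2 pi rc` concentrates many `Nc`
values at nearly the same `Rx`, reproducing the multi-peak structure of
the sampled distribution. At `delta_E = 0` the zero-temperature reference
is degenerate and is returned as a flagged missing value rather than an
arbitrary state.

## What the simulations do and do not emulate

All inputs are model parameters; there is no external data. The sampler
generates equilibrium conformations of the mechanical model — it emulates
thermal fluctuations of real protofilaments only through the three energy
scales above, with no polymerization, no hydrolysis kinetics, no
13-protofilament lattice (three suffice for the closed cross-section), no
excluded volume, and no solvent hydrodynamics beyond the scalar tip
diffusion coefficient. Passing tests therefore certify the statistical
mechanics of this model class, not tubulin biochemistry.

### Placement of the stability transition

Within this model the tubular-to-peeled transition of an all-GDP chain
sits near `delta_E* ~ 1.2` (L = 19b) to `~1.4` kBT (L = 32b): peeling is
driven by the configurational entropy of the freed arc, worth roughly
1.2-1.4 kBT per subunit at these stiffnesses. Consequences worth knowing:

- at `delta_E = 1.4` the landscape is tilted gently toward the tube, and
  combined Langevin/dissociation runs fluctuate around a mean tip position
  of ~50 nm with excursions beyond 240 nm and shrink at a few hundred nm/s
  — the regime where unzippering and dissociation cooperate;
- the unzippering velocity `v_AC` crosses the observed ~0.5 um/s scale
  near `delta_E ~ 1.45`, about 0.4 kBT above where a description with a
  lower-entropy peel would put it. The absolute placement of `delta_E*` is
  sensitive at the few-tenths-of-kBT level to the attachment-point
  convention; ratios, shifts and minima positions are not;
- a single GTP cap subunit shifts the transition midpoint by
  `E_mb / N ~ 0.4` kBT at `L = 19 b` and erects an `~E_mb` wall at
  `Rx ~ 0`; the first-passage delay it causes is enormous (orders of
  magnitude) on the tubular side of the transition and modest below it.

## Numerical choices

- Histogram bins 2 nm; umbrella spacing 10 nm; bias 0.1 kBT/nm².
- WHAM tolerance 1e-8 kBT on the shifts; disconnected windows are an
  error naming the gap, never silently bridged.
- MFPT quadrature: 20001-point trapezoid grid, mid-range shift of `F`
  before exponentiation to avoid overflow.
- Langevin `dt = 1e-7` s; the start-up check requires the worst-case
  drift per step to stay under one histogram bin.
- Minima: 4-nm Gaussian smoothing with reflect-padding; prominence 1 kBT.
- Seeds: every sampler takes an explicit integer seed; umbrella windows,
  sweep points and ensemble trajectories advance it deterministically, so
  identical configurations are bit-reproducible.
- Degenerate inputs: `lmax = l0` or `theta_D = 0` with a nonzero target
  energy, empty distributions, out-of-support evaluation and non-bracketing
  bisections all raise errors rather than guessing.

## Known limitations

- Rescue, polymerization and attachment of new subunits are out of scope.
- The dissociation rate and the `l_d` geometric factor are tunables, not
  predictions.
- The post-dissociation remap assumes the landscape keeps its shape as the
  filament shortens, which is accurate while the remaining length stays
  well above the peeled segment.
- Alternative bond potentials (Lennard-Jones/Morse lateral forms,
  quadratic bending) behave equivalently near the minima and are not
  implemented.
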