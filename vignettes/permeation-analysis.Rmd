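---
title: "Methods: free-energy, pore and permeability analysis with permeakit"
author: "permeakit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-energy, pore and permeability analysis with permeakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permeakit)
```

# Scope

`permeakit` implements the post-simulation analysis stack used in
computational studies of ion-channel permeation — here motivated by
work on the plant vacuolar two-pore channel TPC1, a weakly selective
cation channel whose apparent Ca^2+^ permeability has long been
debated.  The package covers five analyses:

1. **Umbrella sampling / WHAM**: plan restraint windows along a pulled
   coordinate, combine biased histograms into a potential of mean force
   (PMF), anchor it to bulk, attach block-wise errors, and extract
   barrier/minimum features.
2. **Pore-radius profiling**: largest-inscribed-sphere (HOLE-style)
   radius along the membrane normal, replica averaging, and Kabsch RMSD
   for conformational comparison.
3. **Hydration counting**: first-shell water-oxygen counts per frame
   and their block-averaged profiles along the coordinate.
4. **Permeation counting**: hysteresis counting of complete passages
   through a selectivity-filter slab, flux summaries, and the
   field/voltage/conductance arithmetic used to set expectations for
   field-driven simulations.
5. **GHK analysis**: Goldman–Hodgkin–Katz fluxes, reversal potentials,
   and bi-ionic relative-permeability ratios — plus a single-file
   lattice model that shows where the GHK independence assumption
   breaks down.

Because cluster-scale molecular dynamics cannot run at one's desk, a
first-class synthetic-data module generates every input with known
ground truth, so each stage is verified against analytic or scheduled
values rather than against irreproducible trajectories.

# The synthetic-data generators

## Brownian sampling on analytic landscapes

The reference landscape is a sum of Gaussians,
$U(\xi) = o + \sum_i A_i e^{-(\xi - c_i)^2 / 2w_i^2}$, whose energy and
gradient are exact (`potential_spec()`, `eval_potential()`).  Sampling
uses overdamped (Brownian) Euler–Maruyama dynamics:

$$\xi' = \xi - \frac{\Delta t}{\gamma}\frac{d(U+W)}{d\xi}
       + \sqrt{\frac{2 k_B T \Delta t}{\gamma}}\,\eta, \qquad
  \eta \sim N(0,1),$$

with restraints $W$ of three shapes (harmonic, flat-bottom,
lower-bound) matching the restraint types used in biased MD protocols.
An overdamped integrator is sufficient because every downstream
analysis consumes *configurational* statistics only; inertial dynamics
would add parameters without changing any stationary property.

Parameter choices (all overridable):

* `kT` defaults to $k_B \cdot 300\,\mathrm{K} = 0.5962$ kcal/mol.
  Temperature is a free parameter of the generator.
* `timestep` $10^{-3}$ ns and `friction` $\gamma = 0.5$
  kcal mol^-1^ Å^-2^ ns.  These are reduced, not physical, units; they
  are chosen so that a "10 ns" umbrella window is $10^4$–$10^5$ steps
  and the Euler stability parameter $k\,\Delta t/\gamma$ stays below
  0.05 for force constants up to ~20 kcal mol^-1^ Å^-2^ (the stationary
  variance of a harmonic window is then biased by under 2%).
* every generator takes an integer `seed`; identical seeds reproduce
  trajectories bit for bit.

The generator's fidelity is tested two ways: the stationary variance
under a pure harmonic restraint equals $k_BT/k$ (equipartition), and
the histogram of a long unbiased run on a confined double well matches
$e^{-(U+W)/k_BT}/Z$ computed by quadrature (chi-square on subsampled
frames).  For the chi-square check the friction is lowered to 0.1 and
frames are subsampled every 2000 steps: at the default friction the
well-to-well exchange (a Kramers hopping process) keeps even distant
frames correlated, and a multinomial test on correlated draws
over-rejects for reasons that have nothing to do with the sampler's
correctness.

## Steered pulls

`steered_pull()` drags the coordinate with a harmonic restraint whose
center follows a monotone schedule, exactly as steered MD seeds
umbrella windows.  On a flat landscape the trajectory lags the moving
center by $\gamma v / k_{pull}$ at steady state, which the tests verify
against that closed form.  Pull velocity is exposed as a free
parameter: published protocols often pull over ~0.1 ns of MD time, far
faster than the surrogate's diffusive time scales, so reproducing those
literal durations would be meaningless here.

## Crossing, pore, and hydration fixtures

* `make_crossing_trajectories()` builds per-ion $z(t)$ series from a
  schedule of (direction, time window) crossings, with clamped Gaussian
  noise (±3 SD) and resting baselines placed far enough beyond the slab
  that the scheduled counts are *exactly* countable — scheduled
  crossings of one ion must alternate direction, since a repeat without
  a return is physically impossible.  Optional wrapping into
  $[0, L_z)$ exercises the unwrapping path.
* `make_pore_geometry()` builds rings of spheres whose inner accessible
  radius equals a supplied radius profile exactly at each ring; ring
  spacing of 0.25 Å keeps the between-ring bulge below 0.002 Å for the
  radii used in the tests.
* `make_hydration_snapshot()` places water oxygens at exact shell
  distances in random directions, so any cutoff between the shells
  returns the scheduled coordination number.

## The single-file lattice pore

`simulate_single_file()` runs fixed-step Monte Carlo on an
`n_sites`-site lattice: species A and B enter at either end with
configurable rates, hop symmetrically, and (optionally) obey
single-file exclusion — at most one particle per site, no passing.  A
*crossing* is a full traversal (entered one end, exited the other).
Per-step probabilities are $1 - e^{-r\,\Delta t}$.

The model is deliberately minimal and its rates are illustrative — it
makes no kinetic claim about any real channel.  Its purpose is the
qualitative contrast at the heart of the permeability discussion:
without exclusion, opposing species sustain independent fluxes (the GHK
picture, and the tests verify the independent-walker closed form that a
walker entering an $M$-site lattice exits the far side with probability
$1/(M+1)$); with exclusion at high occupancy the opposing fluxes block
each other almost completely.  The standard drive used in the tests —
A fed at the left and B at the right at 300 ns^-1^, hopping at
100 ns^-1^ on 8 sites — fills the pore to ~0.8 occupancy and suppresses
both fluxes by well over 50% relative to the exclusion-off run with the
same seeds.

# WHAM

## Planning and binning

`plan_windows()` reproduces the pull-protocol arithmetic: windows at
$\mathrm{start} + i\cdot\mathrm{spacing}$, $i = 1..n$, with
$n = \mathrm{round}(\mathrm{span}/\mathrm{spacing})$.  The convention
that the starting frame is not itself a window is a documented choice
(protocol descriptions rarely say); with 0.5 Å spacing over a 50 Å
pull it yields 100 windows, and dropping a terminal 15 Å stretch — a
gate region that is not part of the permeation coordinate proper —
retains 70.  The drop is a flag, so full-span profiles remain
producible.  `bin_window()` discards a configurable number of leading
equilibration frames (e.g. the first 3 ns of a 10 ns window) before
histogramming.

## The estimator

`wham_solve()` iterates the standard self-consistent equations

$$P(\xi_b) = \frac{\sum_j n_j(\xi_b)}
  {\sum_j N_j \exp[(f_j - w_j(\xi_b))/k_BT]},\qquad
  f_j = -k_BT \ln \sum_b P(\xi_b)\, e^{-w_j(\xi_b)/k_BT},$$

with $w_j(\xi) = \tfrac12 k_j (\xi - \xi_j)^2$, defaults of 300 bins
and a convergence tolerance of $10^{-7}$ on
$\max_j |\Delta f_j|$ — the tolerance is interpreted in kcal/mol, the
natural unit of the $f_j$.  The gauge freedom is fixed by $f_1 = 0$.
Only the 1D window restraint enters the weights: auxiliary restraints
used during sampling (in-plane flat-bottom containment, ion-exclusion
distance restraints) act on coordinates orthogonal to the reaction
coordinate and are excluded from $w_j$.  Bins never visited carry a
`+Inf` sentinel and are excluded from shifting and feature extraction;
windows that share no histogram bins with the rest raise a
"disconnected coverage" error rather than silently producing profiles
with undetermined offsets.

Implementation notes: the bias Boltzmann factors
$A_{bj} = e^{-w_j(\xi_b)/k_BT}$ are precomputed once, making each
iteration two matrix–vector products; far-window entries underflow to
zero harmlessly.  On degenerate input (one window, zero force constant)
the estimator reduces exactly to direct Boltzmann inversion of the
histogram, and on small problems it matches an independently coded
brute-force alternation to $10^{-8}$ — both are tested.

## Anchoring, errors, features

`shift_profile()` subtracts the mean free energy of the first and last
`bulk_points` (default 10) bins — the bulk-solution ends of the
coordinate — leaving the shape untouched; it is idempotent.
`block_error()` re-solves WHAM and re-shifts per contiguous block
(default unit: the frames of one nanosecond) and reports the per-bin
SEM across block profiles with the $n-1$ denominator, the same
convention used for hydration profiles.  Trailing frames that do not
fill a block are dropped and recorded.

`extract_features()` reports the maximum free energy inside a
selectivity-filter interval, the global minimum and its position, and
the *luminal-to-cytosolic barrier*, implemented as the largest forward
climb $\max_\xi [G(\xi) - \min_{\xi' \le \xi} G(\xi')]$.  For the
canonical well-then-barrier profile this equals barrier minus well
depth (a $-4.1$ kcal/mol well before a $2.8$ kcal/mol barrier gives
$6.9$); for a profile without a well it reduces to the barrier height
itself.  The naive alternative — "maximum past the global minimum" —
is unstable for well-free profiles, whose nominal global minimum is
bulk noise and can sit at the cytosolic end, leaving nothing "past" it.
The filter interval is a required user input in real analyses (no
universally correct z-bounds exist); it defaults to the 10% of the
covered coordinate nearest the luminal end.

## What the recovery tests show — and what they don't

The pipeline test samples 20 windows ($k = 10$ kcal mol^-1^ Å^-2^,
0.5 Å spacing) on a double-Gaussian landscape with a $-1.5$ kcal/mol
well and a $3$ kcal/mol barrier, 50,000 retained frames per window
after a 10,000-frame discard, and requires the shifted profile to match
the analytic landscape to an RMSE below 0.3 kcal/mol over covered bins
(typical observed values are ~0.05–0.08).  A block-error coverage check
requires at least 95% of bins to lie within three SEM of truth, and a
mutant-versus-wildtype pair (well removed, barrier raised) must
reproduce the qualitative feature contrast: without the well, the
luminal-to-cytosolic climb collapses onto the bare barrier height.

Two caveats found while validating are worth recording.  First,
duplicating a window is *not* an exact no-op for WHAM — the duplicate
re-weights the likelihood unless the window's histogram already equals
its reweighted reconstruction — so the tests assert near-invariance
(0.05 kcal/mol) rather than identity.  Second, with contiguous
Brownian frames the profile error is dominated by slowly accumulating
window-to-window drift; sample-size comparisons are therefore run on
frames thinned 10×, mirroring how MD trajectories are actually saved,
where "more sampling is better" holds in ~9 of 10 paired repeats.
These are properties of the estimator itself, not of this
implementation.

None of this demonstrates recovery of any *real* channel's PMF: the
synthetic landscape has no orthogonal degrees of freedom, no slow
conformational gating, and its noise model is exactly the one the
estimator assumes.

# Pore profiling

`pore_radius_profile()` maximizes, per z-slice, the inscribed-sphere
radius $f(x, y) = \min_i(|p - a_i| - r_i)$ over the in-plane center by
Nelder–Mead with random restarts, seeding each slice from the previous
slice's optimum so the center path is continuous through connected
pores.  Two robustness choices matter:

* $f$ is unbounded away from the structure, so a restart placed outside
  the pore walls runs off to infinity; the profiler keeps the best
  optimum *below* the radius cap (default 15 Å) and declares a slice
  open only when every start escapes.  Simulated annealing (the
  original HOLE approach) is unnecessary because the fixtures verify
  exactness directly.
* van der Waals radii come from a Bondi element table by default, or
  per-atom from the PDB occupancy column (the convention the fixture
  writer uses).  Waters and other HETATM records are excluded unless
  requested.  The reported quantity is a radius; diameter plots are
  $2r$ at the reporting layer.

On fixtures the profiler returns a 5 Å cylinder to machine precision
and locates an hourglass constriction within one slice.  Note a piece
of genuine geometry: for sloped walls the inscribed sphere touches
neighbouring rings, so the recovered radius at steep slices is slightly
below the slice's nominal profile value, and dilating the wall by
$\delta$ increases the recovered radius by marginally less than
$\delta$ (a wall-slope cosine factor).  Invariance tests therefore use
gently sloped fixtures.

`kabsch_rmsd()` implements least-squares superposition via SVD with the
determinant-sign correction enforcing a proper rotation; it is checked
against a brute-force rotation search and an independent package
implementation.

# Permeation counting and expectations

`count_crossings()` uses a two-plane hysteresis machine: an event fires
only when an ion last seen strictly below the lower plane is next seen
strictly above the upper plane, or vice versa.  Oscillation between the
planes produces nothing; after an event the ion must traverse the full
slab again before an opposite event can fire (and that return, when it
happens, is itself a countable event — what is counted are *events*,
not unique ions; per-ion event tables make either summary derivable).
With a periodic box the trajectory is unwrapped by minimum-image
increments first, and the slab recurs every box length: passages
through any periodic image are counted by indexing the gaps between
successive slab images, so an ion that circles the box cannot be
mistaken for (or hidden as) a filter passage.  Time-reversing a
trajectory exactly swaps the two direction counts, and the net count
equals a brute-force winding tracker on random fixtures — both are
tested on 100 scheduled fixtures.

`summarize_flux()` reports mean ± SD ($n-1$), range, and median of
per-replica counts, the reporting style of field-driven permeation
tables.  `field_to_voltage()` converts a uniform field in
kcal mol^-1^ Å^-1^ e^-1^ across a box of length $L_z$ to volts
(1 kcal mol^-1^ e^-1^ = 4184/F ≈ 0.0434 V); a 0.180 field over a
~128 Å box is ~1 V.  `expected_crossings()` evaluates the ohmic
expectation $N = G\,\Delta V\,\Delta t/(|z|e)$: an 80 pS channel at 1 V
for 500 ns passes ~250 monovalent ions — the yardstick against which
observed counts in field-driven simulations are judged.

# GHK analysis

`ghk_flux()` evaluates the constant-field charge-weighted flux

$$\Phi = P z^2 \frac{FV}{RT}
  \frac{[X]_{cyt} - [X]_{lum} e^{-zFV/RT}}{1 - e^{-zFV/RT}},$$

switching to a series expansion for $|zFV/RT| < 10^{-6}$ so the
$V \to 0$ limit $\Phi \to P z([X]_{cyt} - [X]_{lum})$ is reached
continuously.  The total current is $F \sum_s \Phi_s$ (each $\Phi_s$
already carries its $z_s^2$ — the standard GHK current equation), the
voltage convention is $V = \varphi_{cyt} - \varphi_{lum}$ throughout,
temperature defaults to 298.15 K, and concentrations are used as
activities, as is universal in applications of the equation.  The full
flux expression handles mono- and divalent mixtures uniformly, so no
bi-ionic special case is needed; the closed-form $V = 0$ limit serves
as an internal cross-check.

`reversal_potential()` finds the zero of the (monotone) current–voltage
relation by Brent search; `bi_ionic_permeability_ratio()` solves the
zero-current condition for $P_B/P_A$ at a measured reversal potential.
The canonical worked example: 150 mM K^+^ on the cytosolic side against
15 mM Ca^2+^ on the luminal side, reversing at 0 mV, yields
$P_{Ca}/P_{K} = (z_K [K]_{cyt})/(z_{Ca} [Ca]_{lum}) = 5$ — the textbook
"5:1 Ca^2+^ preference".  Literature reports of a contrary ~1:10 ratio
under other solutions exist, but the concentrations for that condition
are not available here, so it is noted without a corresponding test.
The package's point, carried by the lattice contrast above, is that for
a single-file pore such ratios do not measure permeation at all: at the
bi-ionic reversal the GHK model balances two large opposing charge
fluxes, while a single-file pore at the same drive simply blocks.

# Hydration

`count_shell()` counts water oxygens (oxygens only — counting whole
waters differs only in bookkeeping and is not standard) within a cutoff
of the ion, with minimum-image distances when a periodic box is given.
Default cutoffs are the usual first minima of ion–oxygen radial
distribution functions: K^+^ 3.5 Å, Na^+^/Ca^2+^ 3.2 Å; the cutoff used
is recorded in every output row.  `hydration_profile()` applies the
same block convention as the WHAM errors (block means, then mean ± SEM
with $n-1$ across blocks).

# Problem sizes and runtime

All defaults are desk-scale by design: the WHAM recovery runs 20
windows × 60,000 steps (about a second of compute including the
5-block error analysis), the generator fidelity checks use $10^6$-step
runs, the lattice contrast 2 × 10^5^ steps, and the full test suite
completes in well under a minute.  The acceptance script
(`scripts/acceptance.R`) recomputes every headline quantity from
scratch in a few seconds.

# Known limitations

* The Brownian surrogate has a single degree of freedom; it cannot
  exhibit hidden-variable hysteresis, pulling-rate artifacts, or
  force-field error — the dominant failure modes of real
  umbrella-sampling studies.
* WHAM here is strictly 1D with harmonic window weights; no MBAR, no
  2D coordinates, and block SEM is the only error model (no
  autocorrelation analysis).
* The pore profiler assumes a z-aligned pore axis and optimizes
  in-plane only, like the classical profile tools it mirrors.
* The lattice model is a cartoon: no electrostatics, no voltage
  dependence, no binding-site chemistry.  It demonstrates a mechanism,
  not a channel.
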