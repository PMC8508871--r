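# permeakit

Analysis toolkit for ion-channel permeation studies built on molecular
simulation: umbrella-sampling free-energy profiles via WHAM,
HOLE-style pore-radius profiling, hydration-shell counting,
permeation-event counting under applied electric fields, and
Goldman–Hodgkin–Katz (GHK) relative-permeability analysis.

The package is aimed at computational biophysicists analysing channel
permeation — the motivating system is the plant vacuolar two-pore
channel TPC1, a weakly selective cation channel whose "relative
Ca²⁺ permeability" from GHK analysis of reversal potentials has long
conflicted with structural and kinetic evidence.  Every analysis stage
is paired with a synthetic-data generator (Brownian dynamics on
analytic landscapes, scripted crossing trajectories, geometric pore
fixtures, a single-file lattice pore) so the whole stack is verifiable
against exact ground truth without running all-atom MD.

## The core methods

**WHAM.**  Biased histograms $n_j(\xi)$ from harmonic umbrella windows
($w_j(\xi) = \tfrac12 k_j(\xi-\xi_j)^2$) are combined by
self-consistent iteration of

$$P(\xi_b) = \frac{\sum_j n_j(\xi_b)}{\sum_j N_j\,
  e^{(f_j - w_j(\xi_b))/k_BT}}, \qquad
  f_j = -k_BT \ln \sum_b P(\xi_b)\, e^{-w_j(\xi_b)/k_BT},$$

(default 300 bins, tolerance $10^{-7}$ kcal/mol on
$\max_j|\Delta f_j|$), giving $G(\xi) = -k_BT\ln P(\xi)$ anchored so
the mean over the bulk bins at both ends is zero.  Errors are SEMs
across per-block (per-nanosecond) WHAM solutions; features reported
are the selectivity-filter barrier, the global minimum, and the
luminal-to-cytosolic barrier (largest forward climb of the profile).

**Pore profiling.**  Per z-slice, the in-plane center maximizing the
inscribed-sphere radius $\min_i(|p-a_i| - r_i)$ is found by
multi-start Nelder–Mead with continuation along z; replica profiles
are averaged with SEM.  `kabsch_rmsd()` superposes conformations by
the SVD solution with the proper-rotation correction.

**Permeation counting.**  A two-plane hysteresis machine counts only
complete passages through the selectivity-filter slab (periodic
trajectories are unwrapped first), with Table-style summaries
(mean ± SD, range, median across replicas) and the conversions
field → voltage ($\Delta V = E\,L_z\cdot 0.0434$ V per
kcal mol⁻¹ e⁻¹) and conductance → expected counts
($N = G\,\Delta V\,\Delta t/|z|e$).

**GHK.**  Constant-field fluxes
$\Phi = Pz^2 (FV/RT)\,\frac{[X]_{cyt}-[X]_{lum}e^{-zFV/RT}}{1-e^{-zFV/RT}}$,
total current $F\sum_s\Phi_s$, reversal potentials by root search, and
bi-ionic permeability ratios from measured reversal voltages.  A
single-file exclusion lattice shows why such ratios mislead for
narrow pores: opposing fluxes block each other instead of compensating
electrically.

## Worked example

Bi-ionic GHK arithmetic and the ohmic expectation for a field-driven
simulation:

```r
library(permeakit)
k  <- ion_species("K",  1, conc_cyt = 150, conc_lum = 0)
ca <- ion_species("Ca", 2, conc_cyt = 0,   conc_lum = 15)
bi_ionic_permeability_ratio(k, ca, v_rev = 0)
#> [1] 5
expected_crossings(80, 1, 500, valence = 1)$expected
#> [1] 249.6604
```

A 150 mM K⁺ (cytosol) vs 15 mM Ca²⁺ (lumen) condition reversing at
0 mV yields the textbook P_Ca:P_K = 5 — and an 80 pS channel at 1 V
would be expected to pass ~250 monovalent ions in 500 ns.

Umbrella sampling on a known landscape, recovered by WHAM:

```r
truth <- potential_spec(c(-1.5, 3), c(4, 7), c(1, 1))  # well + barrier
centers <- plan_windows(10, 0.5)$centers
plan_windows(50, 0.5, drop_terminal = 15)
#> window plan: 100 windows at 0.5 A spacing; 30 terminal window(s) dropped, 70 retained

windows <- lapply(seq_along(centers), function(j) {
  cfg <- langevin_config(6e4, seed = 100 + j, initial_position = centers[j])
  umbrella_window(centers[j], 10,
                  simulate_overdamped(truth, harmonic_bias(centers[j], 10), cfg),
                  n_discard = 1e4, block_length = 1e4)
})
pmf <- shift_profile(wham_solve(windows, wham_config(range = c(0.3, 10.2))), 10)
pmf
#> PMF profile: 300 bins over [ 0.3165 , 10.18 ] A; 300 covered
#> converged in 1946 iterations (residual 9.97e-08 kcal/mol); bulk-shifted by 1.613 kcal/mol
extract_features(pmf, sf_region = c(6, 8))
#> PMF features: SF barrier 3.05 kcal/mol; minimum -1.61 at xi = 3.85 A; luminal-to-cytosolic barrier 4.66 kcal/mol
```

The recovered profile matches the analytic landscape to
0.119 kcal/mol RMSE here (ground truth: a −1.5 kcal/mol well at 4 Å, a
3 kcal/mol barrier at 7 Å, hence a true luminal-to-cytosolic climb of
4.5 kcal/mol); the barrier and well read off within the block-SEM
uncertainty.

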