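---
title: "Density-matrix extrapolation on the Grassmann manifold for Born-Oppenheimer dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-matrix extrapolation on the Grassmann manifold for Born-Oppenheimer dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtrgext)
```

## The problem

Born-Oppenheimer molecular dynamics (BOMD) solves a self-consistent field
(SCF) problem at every nuclear configuration along the trajectory. The SCF is
a fixed-point iteration, and its cost is measured in iterations: a good
initial-guess density can cut the per-step cost by a factor of two or more
over tens of thousands of steps. The catch is that converged one-particle
density matrices are rank-N orthogonal projectors,

$$D = C C^\top, \qquad C^\top C = I_N, \qquad D^2 = D,$$

so they live on (a manifold isomorphic to) the Grassmann manifold
$\mathrm{Gr}(N, n)$, not in a vector space: a linear combination of previous
densities is not a density. This package implements guess generation by
*linear extrapolation in the tangent space* of that manifold, together with
the baselines against which such schemes are judged, and a self-contained toy
electronic-structure model plus NVE driver so that the whole pipeline can be
measured end to end.

## Tangent-space extrapolation

All densities are handled in the Löwdin-orthonormalized basis
($\tilde C = S^{1/2} C$, handled by `lowdin_factor()` and
`orthonormalize()`). A reference frame $C_0$ is fixed at the first converged
density of a run. The two maps between the manifold and the tangent space at
$C_0$ are computed with thin SVDs:

* `grassmann_log()`: with $L = (I - C_0 C_0^\top)\, C\, (C_0^\top C)^{-1}$
  and $L = U \Sigma V^\top$, the tangent representative is
  $\Gamma = U \arctan(\Sigma)\, V^\top$;
* `grassmann_exp()`: with $\Gamma = U \Sigma V^\top$, the density is built
  from the orthonormal frame $(C_0 V \cos\Sigma + U \sin\Sigma) V^\top$.

Because the frame is orthonormal by construction, **every** output of the
exponential is an exact projector, whatever the input tangent; this is why
extrapolated guesses never need purification. The logarithm is gauge
invariant (it depends on the subspace, not the frame chosen for $D$) and the
two maps are mutually inverse within the injectivity domain; the test suite
checks both to $10^{-10}$ over hundreds of random tangents. Tangents are
stored in the economical $n \times N$ form; linear combinations stay tangent.

The reference is never re-centered during a run. If a trajectory wanders far
enough that $C_0^\top C$ becomes ill-conditioned the logarithm raises an
error rather than silently re-referencing; at that point the caller should
restart with a fresh reference.

## The quasi time-reversible scheme

Geometries are encoded by the Coulomb-matrix descriptor (`coulomb_matrix()`):
off-diagonal entries $z_k z_l / \|R_k - R_l\|$, diagonal $0.5\, z_k^{2.4}$,
vectorized over the lower triangle (length $N_{QM}(N_{QM}+1)/2$). It is
invariant under rigid motions, cheap, and smooth in the nuclear coordinates.

Given the $q$ previous converged tangents $\Gamma_{n-1}, \dots, \Gamma_{n-q}$
and descriptors $d_{n-1}, \dots, d_{n-q}$, the guess tangent for step $n$ is
the symmetric combination

$$\tilde\Gamma_n = \sum_{i=1}^{\tilde q} \alpha_i\,
  (\Gamma_{n-i} + \Gamma_{n-q+i}) - \Gamma_{n-q},
  \qquad \tilde q = \lfloor q/2 \rfloor,$$

whose coefficients solve the Tikhonov-regularized least-squares problem with
data matrix columns $d_{n-i} + d_{n-q+i}$ and right-hand side
$d_n + d_{n-q}$, implemented in stacked form (`build_ls_system()` appends the
$\epsilon I_{\tilde q}$ block; `solve_tikhonov()` solves by QR). Two
properties motivate the structure:

* *Linear exactness*: if the descriptor-to-tangent map happens to be linear
  and the system is solvable, the guess is exact. The suite verifies this on
  synthetic linear maps to $10^{-8}$.
* *Quasi time-reversal symmetry*: each pair $\Gamma_{n-i}, \Gamma_{n-q+i}$
  enters with the same weight, so the combination treats the history window
  symmetrically in time up to the single trailing $-\Gamma_{n-q}$ term. This
  suppresses the systematic bias that plain extrapolation feeds into the
  dynamics. Substituting the engine's own emitted guess tangent for
  $\Gamma_{n-q}$ gives the fully time-reversible variant
  (`fully_tr_tangent()`), which is exactly reversible in exact arithmetic
  but known to accumulate noise-driven errors in iteration counts; it is
  provided as a baseline, bootstrapped through the quasi scheme until its
  own guesses reach age $q$.

The $\epsilon$ block is absolute (the objective is
$\|A\alpha - b\|^2 + \epsilon^2\|\alpha\|^2$), not scaled by $\|A\|$: the
standard grid values are meaningful only under this convention, and the
descriptor scale therefore matters when transferring $(q, \epsilon)$ between
systems — see the calibration section.

## Baselines

* **Plain Grassmann extrapolation** (`gext_guess()`): tangent
  $\sum_{i=1}^q \alpha_i \Gamma_{n-i}$ with $\alpha$ fitted to reproduce
  $d_n$ from past descriptors, $\epsilon = 0.01$. Accurate, but the
  one-sided fit biases the guess and, at loose SCF thresholds, the bias
  leaks into forces and shows up as energy drift.
* **Dissipative extended-Lagrangian propagation** (`xlbo_step()`): an
  auxiliary density $P$ follows a Verlet-like update pulled toward the
  converged density with $\kappa = 1.86$ and damped by the 8-term
  dissipative kernel $c = 0.0016$,
  $\alpha = (-36, 99, -88, 11, 32, -25, 8, -1)$ (the $\alpha_k$ sum to zero,
  so a stationary history is an exact fixed point). The raw guess is not
  idempotent; by default it is McWeeny-purified (`mcweeny_purify()`) before
  being handed to the SCF so that iteration counts are comparable across
  engines — whether purification is applied in published XLBO runs varies,
  so a flag (`purify_xlbo`) disables it.
* **Previous-density and core guesses** complete the ladder for sanity
  checks: iteration counts must not improve when the guess gets worse.

## Choosing q and epsilon

The history depth and regularization are chosen per system by replaying the
extrapolation over a stored trajectory of (tangent, descriptor) snapshots for
every pair on the grids $q \in \{3, \dots, 20\}$ and
$\epsilon \in \{0.001, 0.002, 0.005, 0.01, 0.02, 0.05\}$ and picking the pair
with the smallest mean tangent-prediction error, ties broken toward smaller
$q$ then smaller $\epsilon$ (`select_parameters()`;
`calibrate_parameters()` wraps the warm-up run plus the search). Errors that
reach the floating-point floor are treated as exact ties, so degenerate
fixtures resolve deterministically.

For solvated quantum-chemistry systems the reported good values are
$(5, 0.005)$ at an SCF threshold of $10^{-5}$ and $(4, 0.001)$ at $10^{-7}$,
and those are this package's defaults (`default_config()`). On the toy
fixture below the calibration picks smaller $\epsilon$ — its descriptor
entries (unit charges, distances of a few Bohr) are an order of magnitude
smaller than those of heavy-atom systems, so the same absolute $\epsilon$
regularizes harder. This is exactly why the selection step is part of the
method rather than a constant.

## The toy electronic-structure model

The stand-in for a quantum-chemistry backend is a charge-self-consistent
tight-binding model (`toy_model_spec()`): one basis function per atom,
hopping $-t_0 e^{-r/r_0}$, overlap $s_0 e^{-r/r_0}$ (so the Löwdin machinery
is genuinely exercised), and a Hubbard-style on-site term
$F(D) = h_0 + U\,\mathrm{diag}(D)$ that makes the Fock operator depend on its
own density. The SCF (`scf_solve()`) diagonalizes, occupies the $N$ lowest
levels, linearly mixes the next input (default mixing 0.8 — deliberately
*not* an accelerated solver, because acceleration would mask the
guess-quality differences we want to measure), and converges on the RMS
change $\|D_k - D_{k-1}\|_F / n$ between successive aufbau densities, so an
exact-fixed-point guess converges in one iteration and any $U = 0$ problem in
two. Aufbau occupation raises a hard error when the HOMO-LUMO gap closes;
fixtures are built gapped.

The electronic band energy alone is attractive at all distances, so the model
adds a short-range Born-Mayer pair repulsion
$a_{rep} e^{-r/\rho_{rep}}$ — the standard tight-binding construction — to
give geometries a bound minimum. The default parameters
($t_0 = 0.8$, $r_0 = 1.5$, $U = 0.15$, $s_0 = 0.1$, $a_{rep} = 3.5$,
$\rho_{rep} = 0.5$, all atomic units) put the equilibrium bond near 2.35 Bohr
with a bond stiffness of about 0.1 Ha/Bohr², i.e. stretch periods of roughly
15-30 fs for unit masses. That matches the regime the 0.5 fs production time
step is designed for (a few tens of integrator steps per vibrational period,
as for X-H stretches). An earlier, much softer parameterization (~60 fs
periods) made the trajectory so smooth relative to the time step that any
history-based propagator looked artificially good; the stiff regime is the
honest one.

Forces (`forces()`) are central finite differences (displacement $10^{-4}$
Bohr) of the total energy evaluated at the *frozen* converged density — the
fixed-density gradient. At exact SCF convergence this equals the full
gradient by variational stationarity; at a finite threshold its error is
first order in the SCF residual, which is how production codes behave and
what lets guess bias reach the dynamics at all. (Re-converging the SCF at
every displaced geometry was considered and rejected: the central difference
then cancels the residual error to second order and the energy-drift
diagnostics lose their subject.)

## Dynamics, units, and diagnostics

`run_bomd()` integrates NVE dynamics with velocity Verlet: per step, guess →
SCF → frozen-density forces → position update, with the converged tangent and
descriptor appended to the engine history (only converged densities ever
enter it; an SCF failure aborts the run with partial logs). Units are Bohr,
fs, amu; energies are in Hartree, converted through the single constant
$1\,\mathrm{Ha} = 0.9376\,\mathrm{amu\,Bohr^2/fs^2}$, and
Maxwell-Boltzmann velocities (`init_velocities()`) remove the
center-of-mass momentum but not angular momentum (runs are short). An
equipartition test pins the unit conversion.

Stability is summarized exactly as in the BOMD literature
(`stability_report()`):

* **STF** — mean of the RMS energy fluctuation over consecutive,
  non-overlapping 50 fs windows anchored at the first logged time (trailing
  partial window dropped);
* **LTD** — the OLS slope of total energy against time;
* **iteration statistics** — mean and *population* standard deviation of the
  per-step SCF iteration count, discarding the first $q$ steps and every
  cold-start step (the trajectory is the population of interest, hence no
  $n-1$ correction).

## A worked comparison

```{r comparison, eval = FALSE}
fx <- chain_fixture(10, seed = 1)

# per-system calibration at the production threshold
cal <- calibrate_parameters(fx$geometry, fx$masses, fx$spec,
                            threshold = 1e-5, seed = 1)

runs <- lapply(c(qtr = "qtr", gext = "gext", xlbo = "xlbo"), function(s) {
  cfg <- md_config(n_steps = 2000, threshold = 1e-5, strategy = s, seed = 1,
                   q = cal$q, epsilon = if (s == "gext") 0.01 else cal$epsilon)
  run_bomd(fx$geometry, fx$masses, fx$spec, cfg)
})
compare_report(runs)
```

The README shows the numbers this prints. The problem sizes used throughout
the package's own validation (10 atoms, 2000 steps of 0.5 fs, three velocity
seeds) were chosen as the smallest trajectory on which windowed energy
statistics and iteration averages are meaningful.

## What the toy model does and does not show

The synthetic apparatus reproduces the *mechanics* of the method faithfully:
manifold geometry, the least-squares structure, warm-up logistics,
SCF-iteration response to guess quality, and time-reversal diagnostics. Two
caveats matter when extrapolating conclusions to real solvated systems:

* The toy trajectory is noiseless and nearly harmonic, and the toy Fock
  operator couples to the density only through its diagonal, so SCF
  iteration counts race solely on the 10-entry charge vector. Under those
  two conditions the per-entry temporal tracking of the dissipative
  extended-Lagrangian propagator is unrealistically strong: in this
  package's own comparison runs XLBO reaches convergence in *fewer* mean
  iterations than QTR, even though QTR's guess densities are closer to the
  converged ones in Frobenius norm. The iteration advantage of QTR over
  XLBO reported for solvated quantum-chemistry systems arises under
  environmental noise the toy deliberately lacks; what the toy does
  reproduce robustly is QTR's advantage over the biased one-sided
  extrapolation (G-Ext) and the time-reversal retrace ordering.
* Total-energy drift at these scales is dominated by the $O(dt^2)$
  integrator error (|LTD| of a few $10^{-9}$ Ha/fs at *every* SCF threshold,
  three orders of magnitude below the STF). That the guess engines add no
  measurable drift on top is the property of interest; differences *between*
  engines' LTD values at the same threshold are below the noise floor and
  should not be over-interpreted.

## Numerical choices and degenerate inputs

* Overlap matrices with an eigenvalue below $10^{-10}$ raise a
  linear-dependence error naming the eigenvalue; `frame_from_density()`
  rejects any eigenvalue in $[0.1, 0.9]$ as a corrupted density.
* `grassmann_log()` requires $\mathrm{cond}(C_0^\top C) < 10^8$.
* McWeeny purification requires spectrum inside $(-0.3, 1.3)$ and stops at
  $\|P^2 - P\|_{\max} < 10^{-12}$ or 50 iterations.
* Cold starts reuse the last converged density (the backend default at step
  0); those steps are flagged and excluded from statistics.
* SVD sign/ordering ambiguity is harmless: all downstream quantities are
  gauge invariant, and tests only ever compare densities or tangency
  residuals, never raw factors.
* CSV logs are written at 17 significant digits so that re-analysis of a
  saved log reproduces the report bit for bit.

## Known limitations

Restricted, integer-occupation densities only (no fractional occupations, no
spin polarization, no complex orbitals); no automatic reference re-centering;
no thermostats or barostats; no periodic boundary conditions; the optional
adapter to a real SCF backend is an extension point, not part of the core.
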