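# qtrgext

Quasi time-reversible Grassmann extrapolation of SCF density matrices for
Born-Oppenheimer molecular dynamics (BOMD).

## The problem

Every step of a BOMD simulation converges a self-consistent field (SCF)
calculation, and the iteration count — hence the cost — depends on the quality
of the initial-guess density. Converged one-particle densities are rank-N
orthogonal projectors, `D = C Cᵀ` with `CᵀC = I`, points on (a manifold
isomorphic to) the Grassmann manifold: linear combinations of previous
densities leave the manifold, so naive extrapolation produces unphysical
guesses. Worse, biased extrapolation schemes feed a systematic error into the
forces that shows up as a drift of the total energy in NVE simulations.

This package is for people who study or prototype SCF guess-propagation
schemes. It implements:

* the **Grassmann machinery**: Löwdin orthonormalization, gauge-invariant
  SVD-based `Log`/`Exp` maps between densities and a fixed tangent space
  (`grassmann_log()`, `grassmann_exp()`), so that extrapolated guesses are
  exact projectors by construction;
* the **quasi time-reversible extrapolation** (QTR): the symmetric tangent
  combination
  `Γ̃ₙ = Σᵢ αᵢ (Γₙ₋ᵢ + Γₙ₋q₊ᵢ) − Γₙ₋q`, `q̃ = ⌊q/2⌋`,
  with coefficients fitted to Coulomb-matrix descriptors by
  Tikhonov-regularized least squares (`qtr_guess()`), plus the per-system
  grid search for `(q, ε)` (`select_parameters()`,
  `calibrate_parameters()`);
* the **baselines**: plain Grassmann extrapolation (`gext_guess()`,
  ε = 0.01), the fully time-reversible variant, and the dissipative
  extended-Lagrangian propagator XLBO (`xlbo_step()`, κ = 1.86, c = 0.0016,
  α = (−36, 99, −88, 11, 32, −25, 8, −1)) with optional McWeeny
  purification;
* a **toy electronic-structure model** (charge-self-consistent tight
  binding with overlap and a Born-Mayer repulsion) and an **NVE velocity
  Verlet driver** (`run_bomd()`, `reverse_run()`), so that iteration savings
  and energy conservation are measurable end to end without external
  quantum-chemistry software;
* the standard **stability diagnostics**: short-time fluctuation (windowed
  RMS of the total energy), long-time drift (OLS slope), SCF iteration
  statistics and moving averages (`stability_report()`,
  `compare_report()`).

See the vignette (`vignettes/grassmann-extrapolation.Rmd`) for the model,
its assumptions, and all numerical choices.

## Worked example

Compare guess engines on the built-in 10-atom chain fixture: calibrate
`(q, ε)` with the prescribed grid search, then run 1 ps of NVE dynamics
(2000 steps, 0.5 fs) per engine at an SCF threshold of 1e-5.

```r
library(qtrgext)
fx <- chain_fixture(10, seed = 1)

cal <- calibrate_parameters(fx$geometry, fx$masses, fx$spec,
                            threshold = 1e-5, seed = 1)
#> calibrated: q = 4, epsilon = 0.001

runs <- lapply(c(qtr = "qtr", gext = "gext", xlbo = "xlbo"), function(s) {
  cfg <- md_config(n_steps = 2000, threshold = 1e-5, strategy = s, seed = 1,
                   q = cal$q, epsilon = if (s == "gext") 0.01 else cal$epsilon)
  run_bomd(fx$geometry, fx$masses, fx$spec, cfg)
})
compare_report(runs)
#> strategy            STF         LTD/fs     k_mean     k_sd    steps
#> qtr          1.7762e-04    -5.1351e-09      1.752    0.438     2000
#> gext         1.7762e-04    -5.1269e-09      2.131    0.437     2000
#> xlbo         1.7762e-04    -5.1354e-09      1.139    0.443     2000
```

Reading the table: `k_mean`/`k_sd` are the mean and population standard
deviation of SCF iterations per step after discarding warm-up; the quasi
time-reversible scheme needs ~18% fewer iterations than the plain Grassmann
extrapolation. `STF` (Hartree) is the windowed 50 fs RMS energy fluctuation
— set by the integrator time step and identical across engines — and
`LTD` (Hartree/fs) is the drift slope, here at the integrator noise floor
(~5e-9 Ha/fs, three orders of magnitude below STF) for every engine: none of
the schemes injects measurable bias into this trajectory. On this noiseless
toy the dissipative XLBO propagator converges fastest of all — see the
vignette for why that ordering is specific to the toy regime. The
time-reversal retrace error (`reverse_run()`), which isolates guess-induced
force bias, ranks the engines as expected: QTR 6.7e-7 ≤ fully-TR 1.0e-6 ≤
G-Ext 1.5e-6 Bohr over 200 steps at threshold 1e-5.

A thin command-line front end with `simulate`, `analyze`, `compare` and
`select-params` subcommands is installed at `inst/cli/qtrgext.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/qtrgext.R", package="qtrgext"))')" \
    simulate --config run.json --out outdir/
```

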