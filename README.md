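# stoichTumour

Simulation and dynamical analysis of a stoichiometric tumour–immune
model in a potassium-limited environment, together with its discrete
exponential-map analogue.

## The problem and who this is for

Epidemiological studies have suggested a protective role of dietary
potassium against cancer risk, but there is no cell-biology data to test
the idea directly. One way to explore it theoretically is to put the
tumour–immune interaction inside a *closed potassium budget* and ask how
the dynamics respond to the total potassium available. This package is
for mathematical-biology researchers who want a tested, reproducible
implementation of that model class: a predator–prey system (immune cells
prey on tumour cells) whose growth laws are constrained by ecological
stoichiometry.

## The model

Tumour biomass `x` and immune biomass `y` (carbon units) evolve as

    dx/dt = b·x·min(1 − x/L, 1 − q/Q(x,y)) − f(x)·y
    dy/dt = e·min(1, Q/θ)·f(x)·y − l·x·y − d·y + u

with `f(x) = c·x/(a + x)` the Monod functional response. The tumour's
potassium:carbon quota `Q` follows a Droop growth law with floor `q` and
is closed against the fixed total `K_t = Q·x + θ·y + K_f` through a
quasi-steady-state expression; `θ` is the immune cells' fixed quota,
`−l·x·y` is coercion of immune cells by the tumour, and `u` is a
constant immune influx (treatment surrogate). Freezing per-capita rates
over unit intervals gives the discrete analogue
`x' = x·exp(g_x)`, `y' = y·exp(g_y)`, which shares its fixed points with
the ODE but not its stability or chaos properties.

The package provides: parameter handling and the θ-free scaled form;
trajectory simulation (deSolve) and orbit iteration; equilibrium
location; stability classification (eigenvalues, Jury criterion,
nullcline slopes, Ω-regions); a forward-invariance audit of the
trapezoid `{0 < x < k, 0 < y, s·x + y < p}`; immunoediting phase
classification (elimination / equilibrium / escape); and bifurcation
sweeps with period detection and maximal Lyapunov exponents.

## Worked example

```r
library(stoichTumour)

p <- reference_parameters(L = 1.0, l = 0.2, u = 0.05, K_t = 0.045)
boundary_equilibrium(p)                       # tumour-free state (0, u/d)
classify_equilibrium("continuous", boundary_equilibrium(p), p)
find_equilibria(p, include_boundary = FALSE)
invariance_check(p)
classify_phase(p, t_end = 1500)
```

prints

    continuous-model stability at (0, 0.2) [boundary, Omega1]
    eigenvalues:  0.538131, -0.250000
    verdict: saddle
    internal equilibrium at (x, y) = (0.077909104, 0.4479437)
    residuals: continuous 2.61e-12, discrete 2.61e-12
    Invariance audit of Delta: k = 1, p = 1.5, s = 0.126667 (trapezoid)
    minimum inward flux: 8.8992e-10 on edge 'right' at (1, 1.373e-09)
    verdict: invariant
    Immunoediting phase: escape ( oscillatory coexistence )
    E1 = (0, u/d): saddle
    internal E2 at (0.077909, 0.44794): unstable focus

Read: under this treatment setting the tumour-free state is a saddle
(the tumour can invade), the unique coexistence equilibrium is an
unstable focus, and trajectories settle into a bounded oscillation —
the "escape" immunoediting phase — while remaining inside the
potassium-feasible trapezoid. Raising `K_t` or the influx `u` moves the
system toward coexistence or elimination; `phase_scan()` maps this out.

Bifurcation sweeps reproduce the two headline figures of the model
class: an `L`-sweep at `K_t = 0.045` vs `0.06` (protective potassium
effect) and a `b`-sweep of the discrete map at `L = 1.6` showing a
period-doubling route to chaos while the ODE converges:

```r
run_scenario("fig1A", out_dir = "out")   # CSV of attractor samples
run_scenario("fig2B", out_dir = "out")
```

## Layout

- `R/` — implementation (parameters, response, continuous model,
  discrete map, equilibria/stability, invariance, phases, bifurcation,
  scenarios)
- `tests/testthat/` — unit, property and acceptance tests with
  independently coded oracles in `helper-oracles.R`
- `vignettes/stoichiometric-tumour-immune.Rmd` — methods notes: model
  derivation, closures, numerical choices, limitations
- `inst/cli/stoichtumour.R` — thin command-line front end
- `scripts/acceptance.R` — reproducibility script (above)
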