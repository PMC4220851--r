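---
title: "A stoichiometric tumour-immune model and its discrete analogue: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stoichiometric tumour-immune model and its discrete analogue: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoichTumour)
```

## The model

`stoichTumour` simulates and analyses a predator-prey model of tumour
(prey, biomass $x$) and cytotoxic immune cells (predator, biomass $y$)
whose interaction is constrained by ecological stoichiometry: the system
is closed for potassium, with total mass $K_t$ split between the tumour
pool ($Q\,x$, where $Q$ is the tumour's variable potassium:carbon quota),
the immune pool ($\theta\,y$, with a fixed quota $\theta$) and the free
pool $K_f$ in the surroundings. Biomass is measured in carbon units.

The continuous model is

$$\frac{dx}{dt} = b\,x\,\min\!\Big(1-\frac{x}{L},\; 1-\frac{q}{Q(x,y)}\Big)
  - f(x)\,y,$$
$$\frac{dy}{dt} = e\,\min\!\Big(1,\frac{Q(x,y)}{\theta}\Big) f(x)\,y
  - l\,x\,y - d\,y + u,$$

where the first minimum is Liebig's law over carbon-limited (logistic)
and potassium-limited (Droop, $\mu(Q)=\mu_m(1-q/Q)$ with quota floor
$q$) per-capita growth; $f(x) = c\,x/(a+x)$ is the Monod functional
response of the immune cells; the recruitment efficiency $e$ is reduced
by the factor $Q/\theta$ when the tumour is potassium-poor
($Q<\theta$); $-l\,x\,y$ is coercion of immune cells into a
tumour-promoting role; and $u$ is a constant immune influx (a treatment
surrogate). With $l=u=0$ the system is exactly the classic
stoichiometric producer-grazer (KHE) model, reinterpreted; the package
tests verify this reduction against an independently coded oracle.

### The quota closure

The quota kinetics $dQ/dt = \alpha K_f - \mu_m (1-q/Q)\,Q$ are fast
relative to biomass growth; their quasi-steady state combined with the
closed budget $K_f = K_t - Qx - \theta y$ gives

$$Q(x,y) = \frac{q\,\mu_m/\alpha + K_t - \theta y}{\mu_m/\alpha + x}.$$

This `qss` closure is the package default. The limit
$\alpha \to \infty$, in which the free pool is instantaneously absorbed
($Q = (K_t-\theta y)/x$), is provided as the `lke` closure; it makes
the scaled algebra exact (the region boundary $Q=\theta$ becomes the
line $x+y=p$ in scaled coordinates) and is the form under which the
carrying-capacity reading $b\,x\,(1 - x/\min(L,(K_t-\theta y)/q))$ and
the per-capita-minimum reading used here are algebraically identical.
Under `qss` the two readings differ in shape but share the same zero
set; the per-capita minimum is taken as canonical. At $x=0$ the `lke`
quota is $+\infty$ and all quota-limited factors are defined by their
saturating limits, which keeps the vector field continuous on the
$y$-axis.

Both closures satisfy the potassium mass balance
$K_c + K_i + K_f = K_t$ identically, and under `qss` the free pool is
nonnegative exactly on the trapezoid $q\,x + \theta\,y \le K_t$ — the
same set that the invariance audit checks.

### Scaling out the immune quota

With $p = K_t/\theta$ (the maximal immune density the potassium pool
can support) and $s = q/\theta$, the immune quota is a pure gauge: the
package exposes both parameterizations (`scale_params`,
`model_rhs_scaled`) and tests that rebuilding the model with any
$\theta' > 0$ reproduces the same vector field to machine precision.

### The discrete analogue

Freezing the per-capita growth rates over unit time intervals and
integrating gives the exponential map

$$x' = x\,e^{g_x(x,y)}, \qquad y' = y\,e^{g_y(x,y)},$$

with $g_x = b\min(1-x/L, 1-q/Q) - P(x)\,y$, $P(x)=f(x)/x$
(extended by $P(0)=f'(0)$), and
$g_y = e\min(1,Q/\theta)f(x) - l\,x - d + u/y$. The treatment influx is
frozen per capita ($u/y$ inside the exponent), which is the literal
reading of the piecewise-constant-rates construction; an
exact-integration variant
$y' = y\,e^{g} + u\,(e^{g}-1)/g$ (with $g$ the frozen linear part) is
available via `map_step(..., influx = "exact")`. Both share their fixed
points with the ODE — the exponents vanish exactly where the per-capita
rates do — and the map Jacobian at a fixed point is $I + J_{\rm cont}$,
which is why stability thresholds of the two models line up the way
they do.

## Analysis toolkit

**Equilibria.** The boundary equilibrium is $(0, u/d)$ (both models);
in the $l=u=0$ reduction the boundary set is $\{(0,0), (k,0)\}$ with
$k=\min(L, K_t/q)$. Internal equilibria are located by seeding a damped
Newton solve of $(F,G)=0$ (or of the map's fixed-point residual) from a
grid over the trapezoid, with dedupe radius $10^{-6}$ and residual
tolerance $10^{-10}$. The Jacobians used by Newton and by the
classifier are analytic; they are cross-validated against central
differences in the tests, away from the two switch surfaces (Liebig
branch tie; $Q=\theta$), where only one-sided derivatives exist and the
classifier flags the point instead.

**Stability.** Continuous equilibria are classified from eigenvalue
real parts (saddle iff $\det J < 0$); discrete fixed points by the Jury
inequalities $|\mathrm{tr}\,M| < 1 + \det M < 2$, cross-checked against
eigenvalue moduli. Reports carry the nullcline slopes $-F_x/F_y$ and
$-G_x/G_y$ and flag the slope-comparison clauses: at an internal
equilibrium a flatter immune nullcline ($-G_x/G_y < -F_x/F_y$) forces a
continuous saddle / discrete instability, and the opposite comparison
together with the spectral condition gives local asymptotic stability.
Eigenvalues within $10^{-9}$ of criticality are reported
non-hyperbolic, not classified.

**Invariant region.** The candidate forward-invariant set is the open
trapezoid $\Delta = \{0<x<k,\ 0<y,\ s x + y < p\}$, a triangle when
$L \ge p/s$. Instead of a closed-form bound on $u$, the package audits
the boundary numerically: the inward normal component of the vector
field at edge samples (the $x=0$ axis is itself invariant and noted),
plus a free-potassium sign audit on interior samples.
`max_invariant_influx` recovers the largest invariance-preserving $u$
by bisection. This numeric surrogate is also how the E1-stability
thresholds in $(u, K_t)$ are recovered: the boundary state's nontrivial
eigenvalue $b\min(1, 1-q/Q(0,u/d)) - f'(0)\,u/d$ is monotone
decreasing in $u$ and increasing in $K_t$, which the tests check
directly.

**Immunoediting phases.** `classify_phase` combines equilibrium
analysis with trajectories from five deterministic starts spread over
$\Delta$: *elimination* when $(0,u/d)$ is stable and every trajectory
drives the tumour below $10^{-6}$ sustained over the last tenth of the
horizon (the threshold is a package choice; the model itself never
reaches $x=0$ in finite time); *equilibrium* for convergence to a
stable internal coexistence state; *escape* otherwise, with subcases
for the $(k,0)$ attractor of the $l=u=0$ reduction, for sustained
oscillation, and for an immune-collapse state. The collapse subcase is
a deliberate extension of the taxonomy: a stable internal equilibrium
with the immune population within 5% of its tumour-free floor $u/d$
and the tumour above $0.75\,k$ is the continuation of the $(k,0)$
boundary attractor to $l,u>0$ — the tumour persists near its resource
ceiling and the immune pool is sustained by treatment alone — and is
reported as escape rather than as benign coexistence. Without this
refinement the letter of the stable-equilibrium definition would label
the tumour-winning state at high $L$ and low $K_t$ as "equilibrium
phase", inverting the intended reading of the potassium effect.

**Bifurcation sweeps.** One-parameter sweeps record post-transient
attractor samples per value (continuous protocol: 500 days discarded,
samples over the next 200 days; discrete: 2000 iterates discarded, 300
kept — configurable), warm-starting each value from the last state of
the previous one by default. Periods are detected as the smallest lag
under which the sample sequence repeats within tolerance; maximal
Lyapunov exponents propagate a tangent vector through the analytic map
Jacobian with per-step renormalization. The sweep protocol sizes are
conventional choices; the acceptance checks in
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R` use 15
values for the carrying-capacity sweeps and 28 for the growth-rate
sweep, with longer discrete burn-ins (3000) where attractors are
reached slowly.

## Reference setting and scenarios

The built-in reference parameter set (`reference_parameters`) is

```{r}
print(reference_parameters(L = 1.0))
```

with $L$ free in 0.25-2.0. The coercion rate $l$ and influx $u$ are
scenario-specific and default to 0 (the KHE reduction); the shipped
scenarios use $l=0.2, u=0.05$ for the carrying-capacity sweeps
(`fig1A`-`fig1H`, at $K_t = 0.045$ and $0.06$) and
$l=0.009, u=0.02, L=1.6$ for the growth-rate sweeps (`fig2A`,
`fig2B`). The growth-rate sweep range $b \in [0.8, 3.5]$ is a package
choice bracketing the regime where the ODE still settles to a point
while the map period-doubles into chaos. Units are kept abstract
("biomass", "per day"); the tumour death rate is treated as absorbed
into the net growth rate $b$, which is why $b$ and $\mu_m$ are separate
parameters ($\mu_m$ enters only the quota closure).

## What the simulations show

Three headline behaviours, all recomputed by the acceptance script:

```{r, eval = FALSE}
# protective role of potassium: at the high-L end of an L-sweep the
# long-run minimum immune biomass rises when K_t goes 0.045 -> 0.06
p45 <- reference_parameters(L = 1.0, l = 0.2, u = 0.05, K_t = 0.045)
bifurcation_sweep("continuous", "L", seq(0.25, 2, length.out = 15), p45)

# discrete chaos: period-doubling route along a b-sweep at L = 1.6
p2 <- reference_parameters(L = 1.6, l = 0.009, u = 0.02)
bifurcation_sweep("discrete", "b", seq(0.8, 3.5, length.out = 28), p2)

# all three immunoediting phases on a (u, K_t) grid
phase_scan(reference_parameters(L = 1.0, l = 0.2),
           u_values = c(0.02, 0.05, 0.12),
           K_t_values = c(0.025, 0.045))
```

## Numerical choices and degenerate inputs

* Integration uses `deSolve::ode` (lsoda) with `rtol = 1e-8`,
  `atol = 1e-10`. The vector field is continuous with kinks only, so no
  event location is needed; branch crossings are logged post hoc from
  the output grid. Output components more negative than the tolerance
  stop the run; smaller negatives are clipped to zero and counted.
* The infeasible half-plane $\theta y \ge K_t$ (immune potassium demand
  exceeding the total pool) is a hard error, not a silent clamp: the
  model's derivation assumes a nonnegative free pool.
* The map's exponents are capped at $\pm 50$ with a diagnostic —
  chaotic sweeps can transiently produce enormous frozen rates — and
  `map_step` refuses $y=0$ with $u>0$, where the frozen per-capita
  influx is undefined.
* Central-difference cross-checks of the Jacobians are only meaningful
  when the difference stencil does not straddle a switch-surface kink,
  and (for the map) away from tiny $y$ with $u>0$ where $e^{u/y}$ makes
  the truncation error itself large; the tests sample accordingly.
* Newton steps that leave the feasible cone, meet a singular Jacobian,
  or fail to reduce the residual under damping are abandoned; the grid
  seeding makes the search robust to these local failures.

## What the generator emulates, and limits

All inputs are self-contained simulations from the reference set or
multiplicative jitter around it (20% log-uniform, keeping $q<\theta$
and $e\le 1$); there is no patient or laboratory data anywhere in the
pipeline, and the reference values themselves mimic stoichiometric
plankton experiments rather than any clinical situation. Passing tests
therefore demonstrate internal mathematical consistency (reductions,
shared fixed points, invariance, stability theory, the direction of the
potassium effect) — not clinical validity. Oscillatory escape dynamics
have no solid-tumour counterpart, and the chaos of the discrete map is
a property of the discretization, not an observed phenomenon. The
package deliberately omits: stochastic or spatial extensions, delay
effects, a dynamic quota ODE (only its closure), parameter fitting,
sigmoidal functional responses, two-parameter bifurcation surfaces and
rigorous chaos verification.
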