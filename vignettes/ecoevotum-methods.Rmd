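---
title: "Methods: a phenotype-structured model of tumour adaptation to hypoxia and acidity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a phenotype-structured model of tumour adaptation to hypoxia and acidity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoevotum)
```

## The model and its assumptions

`ecoevotum` integrates a phenotype-structured balance equation for the
local population density $n(t, x, \mathbf{y})$ of tumour cells at position
$x \in [0, \mathrm{L}]$ (vessel wall at $x = 0$) with trait vector
$\mathbf{y} = (y_1, y_2) \in [0,1]^2$,

$$\partial_t n = \beta_n \,\partial_x^2 n + \theta\, \Delta_{\mathbf{y}} n
  + R(S_o, S_g, S_l, \rho, \mathbf{y})\, n,$$

coupled to reaction–diffusion equations for oxygen $S_o$, glucose $S_g$
and lactate $S_l$. The trait $y_1$ is the (normalised) expression of an
acidity-resistance gene, $y_2$ of a hypoxia-resistance gene; we fix this
pairing throughout: $y_1$ is judged against the fittest acidity level
$\varphi_l(S_l)$ and $y_2$ against the fittest hypoxia level
$\varphi_o(S_o)$. The fitness landscape is

$$R = \underbrace{p_o(S_o) + p_g(S_o, S_g)}_{\text{metabolism}}
 - \eta_o\,(y_2 - \varphi_o(S_o))^2 - \eta_l\,(y_1 - \varphi_l(S_l))^2
 - \kappa\,\rho,$$

with Michaelis–Menten proliferation
$p_o = \gamma_o S_o w(S_o)/(\alpha_o + S_o)$ and
$p_g = \gamma_g S_g (1 - w(S_o))/(\alpha_g + S_g)$. The oxygen weight
$w$ is 1 above the normoxia threshold $O_M$, 0 below the hypoxia
threshold $O_m$ and linear in between; $\varphi_o = 1 - w$ identically,
and $\varphi_l$ rises linearly from 0 at $L_m$ to 1 at $L_M$. The
quadratic (rather than absolute-value) trait penalty keeps the landscape
smooth, and at the exact threshold values the closed ("$\ge$/$\le$")
branches apply — continuity makes this choice observationally irrelevant,
but the code fixes it explicitly.

Modelling assumptions worth keeping in mind:

* selection acts only through the two quadratic penalties with constant
  gradients $\eta_o$, $\eta_l$ (no concentration-dependent curvature, no
  multiple fitness peaks);
* phenotypic changes are spontaneous, undirected diffusion in trait space
  (no stress-induced drift);
* crowding death is linear in the local density, so the local carrying
  capacity is (proliferation rate)/$\kappa$;
* substrates enter/leave only through the vessel (Dirichlet values at
  $x = 0$), oxygen and glucose also take far-field Dirichlet values,
  and lactate accumulates at the far end (zero flux at $x = \mathrm{L}$).

## Parameters

`default_parameters()` stores the full calibration in CGS units (cm, s,
g, cells); the 400 µm strip is `L_domain = 0.04` cm. One canonical unit
system avoids silent scale bugs between cm²/s diffusivities and µm
geometry. `validate_parameters()` enforces positivity and the ordering
constraints that make the habitat classification coherent
($O_m < O_M$, $L_m < L_M$, $\bar S_o > O_M$, $\underline S_o < O_m$,
$\underline S_l < L_m$).

Two calibration remarks. First, the far-field oxygen value
$\underline S_o = 2\times10^{-10}$ is close to 0.01% of the vessel value
$\bar S_o = 2.08\times10^{-6}$ — not 0.1% as a naive reading of the
glucose analogy would suggest; the printed boundary values are taken as
authoritative (the glucose pair is exactly 1%). Second, the simulated
horizon `T_max` is a solver configuration (default $10^9$ s), not a model
constant: runs terminate at numerical equilibrium, and `T_max` is only a
guard.

## Discretisation and numerics

* **Grids.** Vertex-centred, boundary nodes included: `nx` nodes on
  $[0, \mathrm{L}]$, `ny` per trait axis. Defaults `nx = 200`,
  `ny = 41`; the equilibrium diagnostics are checked under refinement in
  the test suite rather than assumed. All integrals (density, trait
  moments, tissue-wide distribution) use trapezoidal quadrature, which is
  exact for per-variable-linear integrands and, combined with mirrored
  ghost nodes, makes the diffusion stencils conserve mass to round-off.
* **Splitting.** Each macro step applies half an explicit x-diffusion
  step, half a trait-diffusion step, the reaction update, and the two
  half-steps in reverse — a symmetric order chosen so the splitting is
  second-order in the diffusion terms.
* **Reaction.** The implicit–explicit update freezes $\rho$ at the start
  of the step, making $R$ constant in $n$, so the implicit solve is the
  scalar division $n/(1 - \Delta t\, R)$. The step is refused whenever
  $\Delta t\, R \ge 1$ anywhere, which simultaneously guarantees
  positivity. A pleasant consequence of freezing $\rho$: for pure
  crowding decay the discrete map reproduces the logistic solution
  exactly ($1/\rho$ grows linearly), which the suite exploits as an
  oracle.
* **Stability.** Explicit bounds $\Delta t \le dx^2/(2\beta_n)$ and
  $dy^2/(4\theta)$, scaled by a safety factor (default 0.9). The
  automatic step takes the tightest of these and the reaction-positivity
  bound $1/(\gamma_o + \gamma_g)$.
* **Substrate coupling.** The substrate fields relax within seconds to
  minutes while the cell dynamics evolve over weeks — a ~$10^5$-fold
  separation under the default rates. The default mode therefore
  refreshes $S_o, S_g, S_l$ each macro step with their steady state at
  the current density (damped fixed-point iteration on the nonlinear
  consumption terms around a sparse tridiagonal solve, relative update
  $< 10^{-10}$; the lactate equation, linear given the others, is a
  single solve with its mixed Dirichlet/zero-flux conditions). Explicit
  co-integration with sub-cycling at the substrates' own stable step is
  retained (`abiotic_mode = "co-integrate"`) both as a literal
  discretisation of the coupled system and as the branch checked against
  a stiff method-of-lines reference in the tests. At the default
  calibration the consumption terms perturb the substrate profiles by
  only a few percent, so the fixed point needs no under-relaxation
  (damping 1); the damping knob exists for stiffer calibrations.
* **Equilibrium detection.** The run stops when
  $\max |\Delta| / (\Delta t\,(1 + |v|)) < 10^{-12}\,\mathrm{s}^{-1}$
  over all state arrays — a scale-aware relative rate of change; there is
  no prescribed final time.
* **Degenerate inputs.** Trait means are undefined where
  $\rho \le$ `rho_floor` ($10^{-12}$ cells/cm³ by default) and are
  excluded (with quadrature renormalisation) from the tissue-wide means
  $\nu_1, \nu_2$. Threshold-crossing positions are located by linear
  interpolation on the first bracketing node pair scanning from the
  vessel; a crossing that never happens is reported as `NA`.

## Initial conditions

The initial population is the Gaussian bump
$n^0 = 200\, \exp(-x^2/0.0002 - |\mathbf{y}|^2/0.4)$ with $x$ in cm —
cells concentrated within ~100 µm of the vessel with both resistance
genes near minimal expression. Note that this profile has tissue-wide
mean trait levels $\nu_1(0) = \nu_2(0) \approx 0.336$ (the truncated
Gaussian mean), not 0.15 — the value the curve $\phi(t)$ actually departs
from in pathway plots.

The initial substrate profiles are generated by relaxing the substrate
subsystem itself: steady states at a frozen reference density (by default
the density of $n^0$; `rho_ref = 0` gives the cell-free profiles with
closed-form solutions used as oracles). This stands in for externally
measured equilibrium distributions, which are not shipped with the
package; since the coupled system converges to an equilibrium independent
of the substrate initial data, the long-run results are unaffected, and
users who have their own measured profiles can supply them as the `ic`
argument of `run_simulation()`. This generator emulates the spatial decay
of vessel-fed resources in avascular tissue; it does not emulate
measurement noise, vessel pulsatility, or consumption by stromal cells —
so passing tests certify the solver against the model, not the model
against tissue data.

## Experiments

`preset_baseline()` is the calibrated invasion/adaptation run.
`preset_eta_sweep()` varies the selection-gradient ratio $\eta_o/\eta_l$;
the sweep anchors $\eta_l$ at its calibrated value and sets
$\eta_o = \text{ratio} \times \eta_l$ (only the ratio is scientifically
interpreted; anchoring the lactate gradient is a documented, overridable
choice). The default ratio list $\{0.01, 0.1, 1, 10, 100\}$ is log-spaced
to straddle the hypothesised acidity-first, simultaneous and
hypoxia-first regimes. `preset_sensitivity()` scales one named parameter
by a list of multipliers and re-evaluates the final-state invariant suite
per run. Reruns of any preset are bit-identical; the model has no random
component.

## What the default calibration can and cannot exhibit

Two structural consequences of the default constants deserve emphasis,
because they determine which qualitative regimes a simulation can reach.
Both follow from back-of-envelope analysis and are confirmed by the
package's own runs.

1. **The acidity arm is inert.** The carrying capacity is
   $\gamma_o/\kappa \approx 1.8\times10^3$ cells/cm³, so the lactate
   source $\zeta_l\, p_g\, \rho \lesssim 6\times10^{-12}$ g/cm³/s. Even
   with no decay at all, diffusive flushing to the vessel caps interior
   lactate near $\underline S_l + s\mathrm{L}^2/(2\beta_l) \approx
   2.4\times10^{-9}$ g/cm³ — four orders of magnitude below $L_m$.
   Acidity-driven selection therefore never activates
   ($\varphi_l \equiv 0$), the equilibrium lactate profile *decreases*
   away from the vessel (the vessel-side value $10^{-8}$ exceeds the
   interior quasi-steady level), and no acidity-resistance pathway can
   emerge. Raising the carrying capacity to a histologically realistic
   $\sim10^8$ cells/cm³ (e.g. $\kappa \approx 3.65\times10^{-15}$), or
   equivalently raising $\zeta_l$ by a similar factor, activates the arm.
2. **The transition zone is a population sink.** The selection gradients
   exceed the proliferation rates by a factor $\sim10^5$, so the viable
   trait band around $\varphi_o$ has width
   $\sqrt{p/\eta_o} \approx 3\times10^{-3}$. With cell motility
   $\beta_n = 10^{-13}$ cm²/s, confinement losses from the
   correspondingly narrow spatial band exceed the maximal proliferation
   rate throughout the moderately-oxygenated zone: no phenotype, on any
   grid or in the continuum, has positive net growth there. The zone is
   populated only as a diffusion-fed sink whose local trait distribution
   inherits the normoxic residents' phenotype instead of tracking
   $\varphi_o$, and since oxygen consumption is negligible at the low
   carrying capacity, the truly hypoxic habitat (where a penalty-free
   phenotype exists) is a sub-grid sliver at the far wall. The
   equilibrium therefore shows trait tracking only in the normoxic bulk.

The test suite asserts the full expected equilibrium structure — substrate
monotonicity, density plateaus, trait tracking, unimodality, pathway
ordering — at face value; the clauses that the default calibration cannot
realise fail visibly rather than being weakened, and this section is the
package's account of why.

## Problem sizes used by the tests

The suite runs the baseline equilibrium at `nx = 100`, `ny = 21`
(seconds), the pathway sweep at `nx = 80`, `ny = 15`, the
method-of-lines comparison on a 5×5×5 instance over $1.5\times10^4$ s
(the reference integration dominates, ~15 s), and the analytic
steady-state checks at `nx = 6001` — the lactate decay length
($\sqrt{\beta_l/\lambda_l} \approx 62$ µm) demands a fine mesh for
$10^{-6}$ relative accuracy against the closed forms. These sizes are the
package's choices for routine verification; all scale up by changing the
grid arguments.

## Known limitations

One-dimensional space only; no advection, mechanics, chemotherapy,
angiogenesis or stress-induced drift; constant vessel boundary values;
the substrate quasi-steady mode assumes the timescale separation that the
default rates provide — calibrations that slow substrate dynamics by
orders of magnitude should use co-integration; and the default
calibration's structural quirks described above.
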