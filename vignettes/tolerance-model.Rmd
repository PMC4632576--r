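---
title: "An inertial/elastic model of T-cell tolerance and elimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An inertial/elastic model of T-cell tolerance and elimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcelltol)
```

## The model and its assumptions

`tcelltol` simulates the population dynamics of an activated effector
T-cell clone and the target population (pathogen, tumour, or any
antigen-carrying cell population) that drives it:

$$T''(t) = -k\,T(t) + \lambda P(t), \qquad
  P'(t) = \alpha P(t) - \beta\,T(t)\,P(t).$$

The second-order form is the point. A first-order growth law for $T$ cannot
produce *inertia* — the empirically conspicuous continuation of clonal
expansion after the antigen is gone — whereas a Newtonian balance of two
forces can: an antigenic force $\lambda P$ proportional to target abundance,
and a Hooke's-law elastic force $-kT$ pulling the population back toward its
baseline. The target grows exponentially at rate $\alpha$ and is cleared by
mass-action encounters $\beta T P$.

The model's assumptions, made explicit:

* it describes the response **from the instant of activation to the end of
  clonal contraction** — nothing before (naive-cell dynamics, activation
  thresholds) and nothing after (memory formation, re-infection,
  exhaustion) is modelled;
* the target grows at a constant per-capita rate and has a minimum
  infective population size `p_min`;
* all parameters are constant during one response; there is no saturation
  in either force term, so the state variables are trusted only on the
  modelled time span;
* the raw ODE can drive $T$ negative after contraction; we therefore
  terminate integration at the contraction-end event rather than clamping.

## Events and outcome classification

Two zero-crossings structure every run:

* **`PATHOGEN_CONTROLLED`** — $P$ crosses `p_min` downward. The infection
  is no longer self-sustaining. This event is *recorded but not terminal*:
  the response itself continues, which is precisely the model's account of
  delayed contraction (the peak of $T$ falls after this time in acute
  runs).
* **`CONTRACTION_END`** — total $T$ returns to its baseline $T_0$ with
  negative slope, *after* having exceeded $T_0 +$ `peak_guard_eps`. The
  guard prevents the trivial detection at $t = 0$ where $T = T_0$ by
  construction. This event terminates the run: the model is not valid
  beyond it.

A run is classified `ELIMINATION` if control occurred before contraction
ended, `TOLERANCE` if contraction ended with residual target above
`p_min` (tolerance by early contraction), and `UNRESOLVED` if the horizon
`t_max` arrived first. `UNRESOLVED` is a first-class label, not an error,
so parameter sweeps never abort.

## Non-dimensionalization

With $\tau = \sqrt{k}\,t$, $x = Tk/(\lambda P_0)$ and $y = P/P_0$ the
system becomes

$$x'' = -x + y, \qquad y' = \alpha^* y - \beta^* x y, \qquad y(0) = 1,$$

with $\alpha^* = \alpha/\sqrt{k}$ and $\beta^* = \beta\lambda P_0/k^{3/2}$.
This is the unique two-parameter reduction that fixes $y(0) = 1$ and
absorbs $k$ and $\lambda$ into the state scales. It reads $\alpha^*$ as the
target growth rate *relative to the clone's elastic frequency* and
$\beta^*$ as a composite clearance strength: affinity, clearance rate and
initial load enter tolerance only through this one number. Other reductions
differing by constant factors are possible; this one is fixed throughout
the package and verified by a property test (integrate-then-reduce equals
reduce-then-integrate on randomly drawn parameter sets).

## Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| `t_max` | reduced time | 200 | ≈ 30 elastic periods; events in practice occur before $t \approx 10$, so the horizon only matters as an `UNRESOLVED` guard |
| `p_min` | fraction of $P_0$ | 0.05 | minimum infective population; well above integrator noise, well below typical residuals |
| `peak_guard_eps` | reduced $T$ units | 1e-6 | arms contraction detection; far below any physical excursion, far above `abs_tol` |
| `rel_tol`, `abs_tol` | — | 1e-8, 1e-10 | event times then carry ~8 significant digits; cheap at this problem size |
| `dt_out` | reduced time | 0.01 | dense output for peak statistics; peaks have curvature $O(1)$, so peak-time error is $O(10^{-2})$ and peak-height error $O(10^{-4})$ |

All rates are in arbitrary consistent units; the underlying study calibrates
nothing to physical time, and neither do we.

## Numerical choices

Integration uses `deSolve`'s `lsodar` with compiled C right-hand sides and
root functions. Because the contraction-end root needs memory (it must not
fire before the excursion above baseline), runs are integrated as a short
sequence of memoryless phases: watch for {control, arming}, then {control,
baseline return}, with each phase's thresholds encoded in the parameter
vector. A fixed-step classical RK4 integrator (also C) with sign-change +
linear-interpolation event location serves as an independent cross-check;
the test suite requires the two to agree to $10^{-4}$ relative max-norm on
a ten-preset suite spanning both outcome labels (observed agreement is
~$10^{-9}$), and verifies the RK4's $O(h^4)$ convergence on the analytic
limits. If both events fall in one integration step, pathogen control wins
— a fixed tie-break that keeps phase-diagram classification deterministic.

Degenerate inputs: $P_0 \le$ `p_min` is a configuration error (the run
would be "controlled" at $t=0$); $\lambda = 0$ or $\beta = 0$ are accepted
solely to expose the analytic limits (harmonic oscillator; pure exponential
growth with the closed-form forced solution) that anchor the solver tests;
pathogen overflow (|P| > 1e15) is a numerical error, which sweeps record
per-cell as `UNRESOLVED` rather than aborting.

`critical_alpha` bisects on the outcome *label* (the outcome is a step
function of $\alpha$ at fixed clone), to a default bracket width of 1e-4,
and post-verifies that labels flip across the returned midpoint. Smooth
root-finders are deliberately not used: there is no continuous objective
whose sign encodes the outcome without re-deriving the event structure.

## The preset registry and what it does (not) show

The model's own study conditions are qualitative regimes, not measured
parameter sets, so the registry pins one frozen configuration per regime,
found by coarse grid search over the reduced plane and then never moved:

* `acute` ($\alpha^*=2, \beta^*=1$) — elimination with the T-peak after
  control (delayed contraction);
* `tolerated` ($\alpha^*=0.5, \beta^*=1$) — same clone, slower target:
  contraction ends with ~6.4% residual load. The pair straddles the
  bisection threshold $\alpha^*_c(\beta^*{=}1) = 0.7895$;
* ten `suite-*` presets spanning both labels, on which the two integrators
  must agree;
* `two-clone` / `three-clone` — multi-clone sets for the compensation and
  immunodominance experiments;
* `affinity-sweep`, `straddle` — the default threshold-curve and
  acute-versus-tolerated configurations.

Because the generator of "data" here is the model itself, passing tests
show internal consistency (solver correctness, event logic, the predicted
orderings), not agreement with any measured immune response. In particular
the model omits saturation of clonal expansion, stochastic extinction at
low pathogen numbers, antigen presentation dynamics and regulatory
populations; real response curves share the qualitative shape, not the
numbers.

## Design decisions where the design was open

* **Multi-clone coupling.** "Clones interact in proportion to their
  abundances" is implemented minimally: each clone is driven independently
  ($\lambda_i P$) and clearance contributions add
  ($P' = \alpha P - P\sum_i \beta_i T_i$). An alternative would share
  antigenic stimulation among clones (a normalized $T_i/\sum T_j$
  weighting); the minimal form already yields immunodominance ordering and
  compensatory expansion, and introduces no extra parameters. Contraction
  end for several clones is defined on the *total* effector population.
* **Tolerance band geometry.** Near the largest $\beta^*$ that admits any
  tolerance ($\beta^* \approx 1$ at default `p_min`), the tolerance band in
  $\alpha^*$ detaches from the $\alpha^* = 0$ axis: a very slowly growing
  target is eliminated because 20-fold decay (to `p_min` $= 0.05$)
  completes before contraction does, while a somewhat faster grower
  replenishes itself enough to survive the response. Each phase-diagram row
  still contains a single contiguous tolerance band with exactly one
  tolerance-to-elimination transition, which is what the structure tests
  assert; they do not assert that the band touches the axis. Consequently
  `threshold_vs_affinity` marks an affinity undefined when no *tolerated
  low endpoint* exists for its bracket, which first happens near
  $\lambda \approx 1$ in the default sweep ($k = \beta = P_0 = 1$).
* **Problem sizes.** The default phase diagram is the full 60×50 grid of
  the reduced plane ($\alpha^*$ 0.05–3 by 0.05, $\beta^*$ 0.1–5 by 0.1);
  property tests use thinned subgrids since cells are independent. The
  commute and oracle checks use 5 random parameter sets and 10 presets
  respectively — enough to cover both outcome regimes without redundancy.

## Known limitations

* At most 64 clones (a fixed buffer in the compiled code); the experiments
  of interest use 2–3.
* Event times inherit the integrator tolerances; classifications within
  ~1e-8 of the tolerance boundary are resolved by the tie-break rule, not
  by the model.
* The phase diagram's single-transition row structure is asserted on the
  default grid only; it is not a theorem, and oscillatory clearance could
  in principle produce re-entrant bands elsewhere in parameter space.
* No parameter fitting: the framework predicts regimes and orderings, and
  provides no likelihood for time-course data.
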