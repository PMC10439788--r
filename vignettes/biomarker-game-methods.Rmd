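---
title: "The biomarker game: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The biomarker game: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biomarkergame)
```

## The model

Many cancer biomarkers are not passive readouts: the molecule whose blood
concentration the clinic monitors can itself speed proliferation, sharpen
competition between tumour cells, buy resistance to chemotherapy — and, when
a therapy against the marker exists, paint a target on the cell producing
it. `biomarkergame` treats per-cell biomarker production $v > 0$ as a
heritable quantitative trait of cancer cells and couples its evolution to
the population dynamics it shapes.

The ecological backbone is Lotka–Volterra competition. A monomorphic
population with trait $u$ and density $C$ experiences, and a rare variant
with trait $v$ inside it has per-capita growth rate given by the
fitness-generating function

$$G(v, u, C) = r(v)\Bigl(1 - \frac{a(v, u)\,C}{K}\Bigr) - \delta(v)
  - E_C(v)\,\tau_C - E_T(v)\,\tau_T,$$

with components

* growth benefit $r(v) = r_0 (v/v_0)^{\beta_r}$ — production speeds
  proliferation;
* survival cost $\delta(v) = \delta_0 e^{\beta_\delta (v - v_0)}$ —
  production is metabolically expensive;
* competition $a(v, u) = a_{\max} e^{x} / (a_{\max} + e^{x} - 1)$ with
  $x = \beta_a (u - v)$ — a logistic-type kernel, scaled so
  $a(v, v) = 1$: the competition a cell experiences *falls* as its own
  production rises and *rises* with its competitor's production (higher
  producers are better competitors, e.g. through motility or resource
  acquisition);
* chemotherapy $E_C(v) = \zeta_C e^{-m_C (v - v_0)}$, an added death rate
  that decays with the trait (production confers resistance);
* targeted therapy $E_T(v) = \zeta_T (v/v_0)^{m_T}$, an added death rate
  that grows steeply with the trait (the therapy attacks the marker).

$\tau_C, \tau_T \in \{0, 1\}$ are treatment indicators. Population and
trait evolve together:

$$\frac{dC}{dt} = G(v, v, C)\,C, \qquad
  \frac{dv}{dt} = k\,\frac{\partial G}{\partial v}\Big|_{v = u},$$

the second line being the Fisher-process form in which the evolvability
$k$ (heritable-variation scale) converts the selection gradient into a
rate of trait change. The gradient is implemented analytically; the
self-derivative of the competition kernel at equal traits is the closed
form $-\beta_a (a_{\max} - 1) / a_{\max}$.

A note on the competition kernel's argument order. Written with exponent
$\beta_a(v - u)$ the kernel would *reward* the focal cell for producing
less, contradict the verbal description of competitiveness increasing in
production, and fail to reproduce the known ESS ordering. The package
therefore fixes the exponent as $\beta_a(u - v)$; with that convention the
three ESS values below follow from the equations, which we treat as the
deciding evidence.

## Equilibria and evolutionarily stable strategies

With the resident at its own ecological equilibrium, $G(v,v,C) = 0$ gives
the closed form $C^*(v) = K\,(1 - (\delta(v) + E(v)) / r(v))$, clamped at
0 when the death load exceeds growth (so harsh-therapy sweeps remain
well defined). Without therapy $C^*$ is maximal at the baseline trait
$v_0$ — the *group optimum*.

An ESS solves $G = 0$ and $\partial G/\partial v|_{v=u} = 0$
simultaneously. Because $a(v,v) = 1$, substituting $C^*(v)$ into the
gradient reduces the problem to one dimension; `solve_ess()` brackets the
root on $[0.1, 5]$, polishes it with Newton steps until both residuals are
below $10^{-12}$–$10^{-10}$, and verifies the second-order condition (the
reduced gradient changes sign from $+$ to $-$). At the default parameters

```{r ess}
ess_table(model_params())
```

the ESS ordering `targeted < none < chemo` quantifies the selective push
of each environment, and the no-therapy ESS ($\approx 1.48$) sits above
the group optimum $v_0 = 1$: competition drives production past the level
that would maximise the population — a cellular tragedy of the commons,
visible in `equilibrium_curve()` as the gap between $C^*(v_{ESS})$ and the
curve's maximum. `pip_grid()` renders the same information as a pairwise
invasibility plot; residents whose equilibrium is zero cannot define an
invasion environment and are flagged `NA` rather than skipped.

## Parameters

Defaults of `model_params()` (dimensionless density, abstract model time):

| field | default | role |
|---|---|---|
| `K` | 1 | carrying capacity |
| `r0` | 0.05 | growth rate at `v0` (per time unit) |
| `beta_r` | 1 | growth benefit exponent |
| `v0` | 1 | baseline trait, anchor of all four rate functions |
| `delta0` | 0.02 | death rate at `v0` |
| `beta_delta` | 1 | death cost coefficient |
| `a_max` | 2 | competition ceiling (must exceed 1) |
| `beta_a` | 0.5 | competitive benefit coefficient |
| `zeta_C`, `m_C` | 0.03, 1 | chemotherapy intensity and resistance slope |
| `zeta_T`, `m_T` | 0.01, 5 | targeted intensity and sensitivity exponent |
| `k` | 0.01 | evolvability |

All fields are validated strictly positive (`k` may be 0: frozen trait;
`a_max` must exceed 1 for the kernel to be monotone).

## Time units and the week conversion

Model time is abstract. Protocol durations are stated in weeks and convert
at `time_units_per_week` (default 100). The choice rescales *speed only* —
equilibria, ESS values and the balance point are invariant — but it decides
what a "16-week phase" contains. At the default, a therapy block spans
1600 time units, long enough for both the ecological relaxation
(rates $\sim 0.03$–$0.1$ per unit) and the trait displacement
($dv/dt = k\,\partial G/\partial v \sim 10^{-3}$–$10^{-4}$ per unit) that
the trap and adaptive protocols rely on. Much smaller conversions freeze
the trait within phases and reduce every protocol to fixed kill phases.

## Numerical choices

* **Log-density integration.** The monomorphic system is integrated in
  $(\log C, v)$ with `deSolve::lsoda` (rtol $10^{-8}$, atol $10^{-10}$).
  Trap protocols push the density tens of orders of magnitude down; in
  natural scale anything below the absolute tolerance is noise (and
  underflows to 0), while in log scale the relative tolerance applies at
  every depth and positivity is automatic. The polymorphic system stays in
  natural scale because types may legitimately sit at density 0.
* **Discontinuities.** Treatment switches restart the integrator at each
  schedule breakpoint; no discontinuity is integrated across.
* **Root-finding.** Bracketed `uniroot` plus a short Newton polish, both
  for the ESS and for the chemo–targeted balance point
  $E_C(v_b) = E_T(v_b)$ (residual $\le 10^{-12}$).
* **Tie-break.** Adaptive rules give chemotherapy at exact threshold
  equality (the "below" branch) — a measure-zero event fixed for
  determinism.
* **Degenerate inputs.** Zero-equilibrium residents are flagged in PIP
  grids; protocols whose treatment never switches between therapies are
  flagged `degenerate`; negative equilibria clamp to 0; a zero initial
  density is rejected (extinct stays extinct).

## Therapy protocols

Fixed presets follow an 8-week untreated pre-diagnosis period:
`chemo_16wk` and `targeted_16wk` (8 + 16 weeks) and the
`sequential_trap` (8 none, 16 chemotherapy, 16 targeted). Adaptive
protocols re-decide weekly at physician visits, after the same 8-week
lead-in: the total-marker rule gives chemotherapy while $vC \le T$ and
targeted therapy above; the mean-marker rule compares $v$ with $M$.
Preset thresholds are $T \in \{0.4, 0.5, 0.6\}$ and
$M \in \{0.8, 1.2, 1.6\}$. Decisions change only at visits; at most one
therapy is ever active; an optional withhold-below mode exists but no
preset uses it. Switches are counted between successive visit decisions —
the onset of therapy at diagnosis is not a switch.

## The packaged experiments and what they show

**Efficacy bias** (`efficacy_bias()`): across the therapy window,
compares the population ratio $C_{end}/C_{start}$ with the total-marker
ratio $(vC)_{end}/(vC)_{start}$. Chemotherapy selects the trait upward, so
total marker shrinks less than the population: a marker-based readout
*underestimates* efficacy. Targeted therapy selects downward:
*overestimation*. With $k = 0$ the two ratios agree exactly — the bias is
purely evolutionary.

**Trap evaluation** (`trap_evaluation()`): full-trajectory minima of the
two monotherapies and the sequential protocol from a common start. The
chemotherapy phase drives the trait toward the chemotherapy ESS, which
maximises $E_T$; the following targeted phase then crashes the population
far below either monotherapy's minimum. Survivors relax toward the
targeted ESS.

**Threshold sweeps** (`threshold_sweep()`): per-threshold population
minima and switch counts of the adaptive protocols. Minima are measured
from diagnosis onward — the shared untreated growth phase starts at the
common initial density and would otherwise clip every protocol's minimum
to that density, masking the comparison. Thresholds near the
chemo–targeted balance point `balance_point()` ($\approx 1.20$ at
defaults) produce frequent switching and tight control; thresholds far
from it on either side leave time for traps and produce much deeper
minima. Runs without a single switch are flagged and excluded from the
admissible set.

**Sensitivity sweeps** (`sensitivity_sweep()`): trap-protocol minima as a
function of the competitive benefit $\beta_a$ or the evolvability $k$, at
low ($\zeta_C = 0.03, \zeta_T = 0.01$) or high
($\zeta_C = 0.12, \zeta_T = 0.04$) intensity, full-horizon minima. Two
regimes are worth spelling out, because they follow from the rate
arithmetic rather than from tuning:

* At **low intensity** the chemotherapy load at the baseline trait is
  exactly marginal ($r_0 - \delta_0 - \zeta_C = 0$), so the slow-evolution
  limit survives chemotherapy at a bounded level, and the evolvability
  trade-off — faster evolution digs a deeper trap, but also escapes it
  faster — is realised as an *interior* minimum of the nadir-versus-$k$
  curve: evolvability is double-edged, and an intermediate $k$ is worst
  for the tumour. Larger $\beta_a$ likewise deepens the trap by pushing
  the pre-trap trait higher.
* At **high intensity** the baseline-trait load under chemotherapy is
  deeply negative ($0.05 - 0.02 - 0.12 = -0.09$ per time unit), so the
  kill accumulated before the trait escapes grows like $1/k$ and the
  slow-evolution limit is always the deepest point: the curve is monotone
  in $k$ and no interior optimum exists under these equations. The
  package reports this regime as it is; the double-edged-sword
  demonstration is the low-intensity sweep.

## What the model does and does not emulate

There are no data inputs: the model *is* the study system, and the
experiment drivers generate every trajectory from the parameter set. The
deterministic ODE cannot go extinct, so "near-extinction" is a continuous
minimum with no threshold applied; minima like $10^{-8}$ should be read
as relative comparisons between protocols, not cell counts. Traits are
clonal means (no standing polymorphism in the monomorphic system; the
polymorphic system carries fixed types with no mutation); therapy acts as
an additive death rate with no pharmacokinetics, no dosing structure, no
inter-drug interaction; decision delays at visits are fixed at zero.
Parameter values are order-of-magnitude plausible rather than calibrated
to any patient series, so passing tests demonstrate internal consistency
of the mechanism — trap ordering, bias directions, threshold shapes — and
say nothing quantitative about a clinical population.

## Problem sizes used in the test suite

ESS solving and PIP grids are essentially instant (the 200×200 grids take
seconds). Dynamic checks integrate horizons of 2000–60 000 time units with
output steps of 0.25–20 units; the sweep-based checks use 12–18 thresholds
or 13 log-spaced evolvability values at 108-week adaptive horizons or
40-week fixed protocols. The full suite runs in about a minute on one
core.
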