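---
title: "Immune trade-offs in an age-structured life history: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune trade-offs in an age-structured life history: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunodem)
```

`immunodem` implements an eco-immunological life-history model in three
layers: two within-age immunological trade-offs, an age-structured
demographic embedding, and a stochastic two-generation extension with immune
memory and maternal antibody transfer. This vignette is the package's own
account of the model, its assumptions, its tunable parameters, and the
numerical choices behind the implementation. It states no empirical result
beyond what the package's tests and acceptance script themselves compute.

## 1. The within-age model

### Discrimination

Because pathogens are selected to mimic host molecules, the distributions of
self and non-self traits overlap and detection is a
receiver-operating-characteristic problem. The package adopts the one-parameter
ROC family

$$s_e = 1 - e^{-\gamma (1 - s_p)},$$

where $s_e$ is sensitivity (probability of responding to a true infection),
$s_p$ specificity (probability of staying quiet without infection), and
$\gamma > 0$ the discrimination power. The family is concave through
$(0, 0)$ in the $(1-s_p,\, s_e)$ plane and saturates at the attainable
ceiling $1 - e^{-\gamma}$; `sensitivity_from_specificity()` and its inverse
implement the link, with sensitivities at or above the ceiling rejected as
infeasible.

### Competing hazards

Each age class faces four mortality routes, combined as summed hazards:

$$s_x = \exp\!\big\{-\big[\mu_b + (1-i_x)\,\mu_i\,(1-s_p)
 + i_x\,\mu_d\,e^{-\gamma(1-s_p)} + i_x\,\mu_{id}\,(1-e^{-\gamma(1-s_p)})\big]\big\}$$

| parameter | meaning | unit | default |
|---|---|---|---|
| $\mu_b$ | baseline hazard | per year | 1/60 |
| $\mu_d$ | hazard of an undetected infection | per year | 1 |
| $\mu_i$ | immunopathology hazard, false positives | per year | $e^{-\eta\mu_d}$ |
| $\mu_{id}$ | immune damage during detected infection | per year | $\rho\,\mu_i$ |
| $i_x$ | infection probability at age $x$ | probability | scenario-dependent |
| $\gamma$ | discrimination power | — | 4 |
| $\eta$ | effector trade-off shape | — | 0.8 |
| $\rho$ | infected-damage fraction | — | 0.01 |

The hazards are phenomenological: no cell populations or cytokine dynamics
are modelled, and $\mu_d$ doubles as the *inverse* index of effector
magnitude through the exponential trade-off $\mu_i = e^{-\eta \mu_d}$,
$\mu_{id} = \rho\,\mu_i$ (a strong response controls infection but is
autoreactive). A linear variant $\mu_i = \max(0,\, 1 - \eta\mu_d)$ is
provided to show that the qualitative results do not hinge on the
exponential shape; only the exponential closure is used for closed-form
optima.

### Optima and the survival landscape

`optimal_specificity()` and `optimal_mud()` implement the closed-form
within-age optima (the roots of the survival derivatives, certified maxima
by their negative second derivatives). Both expressions can leave the
feasible region, and the implementation clamps them — $s_p^*$ to $[0,1]$,
$\mu_d^*$ to $[0,\infty)$ — because probabilities and hazards are
constrained; the boundary cases are certified against the grid argmax in the
tests. Degenerate incidence is handled explicitly rather than passed to the
logarithms: $i_x = 0$ gives $s_p^* = 1$ (nothing to detect) and $i_x = 1$
gives $s_p^* = 0$ (false positives impossible). Baseline mortality scales
survival uniformly and so never moves the within-age optimum.

`optimal_strategy_numeric()` is the independent brute-force route used to
certify the closed forms: a coarse global grid (at least 512 points per
axis) followed by golden-section refinement to $10^{-8}$ on the argument.
The global scan matters because the combined landscape is bimodal — a purely
local optimiser could climb the wrong peak. `survival_landscape()`
evaluates the surface over $(s_e, \mu_d)$ with the trade-off active and
reports all strict local maxima under 8-connectivity (plateaus contain no
peaks; boundary cells compare over their existing neighbours).

### The discrimination-response map

The ratio $R = \mu_i/(\mu_d - \mu_{id})$ indexes how damaging the response
is relative to the net cost of missing an infection. At an interior optimum
$s_e^* = 1 - (1-i_x)R/(\gamma i_x)$, so reducing allocation towards $R$
*always* selects for increased sensitivity. The response to reduced
discrimination $\gamma$ is context-dependent, and the map of that response
over the $(\gamma, R)$ plane is computed numerically: each cell locates the
optimum at $\gamma$ and at $0.99\gamma$ and records the responses of both
$s_p^*$ and $s_e^*$. We do not trust any closed form for the dividing line;
the boundary $R_b(\gamma) = \gamma i_x / (e\,(1-i_x))$ is derived
independently (by setting $d s_p^*/d\gamma = 0$ in the closed-form optimum)
and *checked against* the numeric sign change.

A genuinely open point is which "sensitivity" the sign change refers to: the
interior $s_e^*$ is monotone in $\gamma$, so no sign change exists for it;
the specificity optimum $s_p^*$ does change its response direction across
$R_b$. The package therefore classifies cells by the $s_p^*$ response
(increased specificity = reduced sensitivity) and records both derivatives
per cell, leaving the choice inspectable. Cells whose optimum clamps to the
feasibility boundary in either evaluation are marked indeterminate (sign 0).
Since no canonical axis ranges exist for the map, defaults
($\gamma \in [1, 6]$, $R$ log-spaced over roughly $[0.02, 1.3]$ for
$i_x = 0.15$) were chosen to display both regions.

## 2. The demographic embedding

Ages are 1-based, one age class per time step; with $\mu_b = 1/60$ the step
is read as a year of a long-lived vertebrate's life. `build_leslie()` places
per-age survival $s_x$ (from the within-age model, with each age's $i_x$,
$\mu_{b}$ and an optional $\mu_d$ multiplier) on the subdiagonal and the
fertility schedule on the first row. `eigen_summary()` returns the dominant
eigenvalue $\lambda$ (the fitness proxy), the stable age structure $w$, and
reproductive values $v$, scaled so that $\langle w, v \rangle = 1$; under
that scaling

$$\frac{\delta\lambda}{\delta s_x} = v_{x+1}\, w_x$$

in the package's 1-based indexing (survival out of age $x$ occupies matrix
entry $(x{+}1, x)$; the finite-difference tests are the arbiter of the
indexing convention). Chain-rule derivatives with respect to shared
parameters ($s_p$, $\mu_d$) combine these sensitivities with the survival
derivatives. The reported $w$ is additionally normalised to sum to one for
readability; that normalisation is cosmetic and never enters a sensitivity.

`optimize_lifespan_sensitivity()` finds the single lifespan-constant
strategy maximising $\lambda$ (coarse grid of at least 256 points, then
golden-section to $10^{-7}$). The two sexes are evaluated as separate
one-sex models, i.e. mates are assumed non-limiting; no marriage function,
density dependence, or stochastic environment is modelled.

**Defaults.** $A = 60$ age classes, maturity $m = 15$, constant
$i_x = 0.15$, constant fertility $f = 1.272$ from maturity — calibrated once
so that the baseline schedule at its optimal strategy has $\lambda \approx 1$
(a stationary population), which keeps scenario-induced changes in $\lambda$
interpretable as fitness costs.

## 3. Scenarios

`scenario_spec()`/`make_schedule()` generate the age-schedule perturbations
that stand in for sex differences in reproductive investment. All claims
made about them in the tests are directional, not magnitude-based, because
no canonical boost sizes exist; the defaults are $\times 2$ boosts over the
window from maturity to the last age class, and an early/late pivot at the
age of maturity.

* `infection_boost` — $i_x$ multiplied inside the window (capped at 1 with a
  warning).
* `infection_mortality_boost` — a $\mu_d$ multiplier inside the window,
  infection probability unchanged. Multiplicative (rather than additive)
  action was chosen since either reading is defensible; the boost factor is
  a config knob, so the choice is easy to vary.
* `background_mortality_boost` — $\mu_b$ multiplied inside the window.
* `fertility_rising_with_age` — a linear fertility ramp holding *total*
  fertility at the baseline amount, isolating the schedule effect from the
  amount effect.
* `fertility_sensitivity_penalty` — fertility scaled by $1 - c\,s_e$ at
  evaluation time (the penalty depends on the strategy under evaluation, so
  it cannot be baked into the schedule). The multiplicative-linear form is
  the simplest monotone coupling of fertility loss to sensitivity.
* `infection_early` / `infection_late` — total infection mass conserved and
  concentrated before/after the pivot.

## 4. The maternal-immunity simulation

The two-generation simulation makes discrimination mechanistic: self traits
are Normal(0, 1), pathogen traits Normal(2, 1) (unit-scale distributions
separated by two scale units, overlapping as the ROC framing requires), and
the host responds to any molecule above a threshold $t$ — low threshold,
high sensitivity. `roc_from_threshold()` computes $(s_e, s_p)$ from the
distribution functions without sampling.

Structural choices, made where the conceptual description leaves the design
open and flagged here because results could depend on them:

* **Within-year averaging.** A year contains many independent exposures, so
  the mother's yearly hazard is the *expectation* of the competing hazards
  given her current memory state; only memory accrual (one potential
  infection event per year), death, and offspring pathogen draws are
  stochastic. With memory and transfer disabled this makes the Monte-Carlo
  age-specific survival converge exactly to the closed-form $s_x$ at the
  threshold's $(s_e, s_p)$ — the convergence check in the tests.
* **Memory.** The trait axis is discretised into 32 bins on $[-4, 6]$; a
  pathogen is "previously seen" when its bin is in the memory set. This
  gives memory finite specificity without a full strain model. Remembered
  pathogens elicit $\mu_{id}$ discounted by `memory_discount`.
* **Naive offspring.** First-year offspring cannot detect pathogens
  themselves; maternal antibodies are their only first-year protection, and
  their own reactivity contributes immunopathology scaled by
  `offspring_immunopathology` (default 0). An offspring infected by a
  pathogen whose bin its mother remembers has $\mu_d$ reduced by the factor
  `transfer_efficacy` (and optionally the transferred response's $\mu_{id}$
  damage likewise). Transfer is therefore *memory-dependent*: a more
  sensitive mother accumulates broader memory and transfers more protection.
  This is the key structural assumption; a fixed endowment would decouple
  transfer from the mother's strategy entirely.
* **Fitness proxy.** Lifetime reproduction weighted by offspring first-year
  survival — a two-generation proxy rather than a full multi-generation
  currency.

`optimal_threshold()` sweeps the threshold grid twice (transfer off/on)
with common random numbers: the draw order inside `simulate_lineage()` is
fixed and threshold-independent, so arms and thresholds share their noise
and paired comparisons remove it. Standard errors of the optimal sensitivity
come from block-wise optima (10 blocks of the replicate set), paired across
arms.

**Defaults** (chosen once as a plausible long-lived host with a severe
unchecked pathogen, and not revisited): 20 maternal age classes, maturity 5,
yearly infection probability 0.15, $\mu_b = 0.02$, $\mu_d = 1.5$,
$\mu_i = 0.45$, $\mu_{id} = 0.5$, offspring first-year infection
probability 0.8 (naive newborns are heavily exposed), transfer efficacy
0.9, 20,000 replicates. The mandatory seed makes every run reproducible
bit-for-bit.

## 5. Numerical choices

* Finite differences are central, step $h = 10^{-6}\max(1, |\theta|)$ for
  first derivatives of survival; eigenvalue derivatives are validated at
  $h = 10^{-4}$, balancing truncation against eigen-solver roundoff.
* The eigen-solver is the dense general solver with selection of the
  largest real eigenvalue; the Euler–Lotka characteristic root (solved by
  bisection-based `uniroot`) is the independent cross-check.
* Golden-section search uses a fixed shrink factor, so reruns are
  bit-identical.
* Ties in grid argmaxes resolve to the first (lowest-index) cell; peak
  lists are ordered by descending survival, then row, then column.
* ROC inversion rejects $s_e \ge 1 - e^{-\gamma}$ as infeasible rather than
  clamping, since such a request is a modelling error, not a boundary case.

## 6. What the synthetic scenarios do and do not show

The scenario generator produces the *study conditions*: piecewise-constant
schedules, multiplicative boosts, conserved totals. Real vertebrate
schedules have high early and late mortality, age-varying fertility, and
infection hazards that are none of these clean shapes, and the trait-axis
distributions of the maternal model are stylised unimodal families. Passing
tests therefore demonstrate the *directional logic* of the model — which
way each reproductive-investment feature pushes the optimal strategy, and
that those directions are robust to the trade-off's functional form — not
quantitative predictions for any particular species. Known limitations
beyond scope: no two-sex coupling, no density dependence, no
within-pregnancy plasticity, no multi-generation evolutionary dynamics, and
hazards that are phenomenological throughout.

## 7. Problem sizes used by the tests and acceptance script

Closed-form-vs-oracle comparisons use 200 random draws; landscapes
$200 \times 200$ cells; the boundary map 8 values of $\gamma$ by 60
log-spaced values of $R$; eigen validation 50 random Leslie fixtures of
30–60 age classes; scenario optimisations the full 60-age default schedule;
the maternal comparison 20,000 replicates over a 25-point threshold grid in
both arms. These sizes keep every check comfortably reproducible on a
single CPU while leaving the Monte-Carlo margins (e.g. the $>2$ standard
error transfer shift) wide.
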