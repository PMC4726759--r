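---
title: "Derivation and numerics of the stochastic kinetics engines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Derivation and numerics of the stochastic kinetics engines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmekit)
```

cmekit derives microscopic (SSA, FSP), mesoscopic (moment equations,
system size expansion, conditional moments) and macroscopic (reaction rate
equations) descriptions of a stochastic reaction network from one model
definition. This vignette records the mathematics each engine implements,
the numerical choices behind it, and the limits of what the test suite
demonstrates.

## The model class

A network is `n_s` species with integer counts `x`, `n_r` reactions with
stoichiometric change vectors `nu_j` and propensities `a_j(x, t)`, a flat
positive parameter vector `theta`, optional time-dependent inputs (inlined
into propensities before any derivation), observables, and compartments.
Counts are the canonical unit; a compartment volume `Omega` is a
dimensionless system size, not a physical litre — it is the expansion
parameter of the system size expansion and the scale for concentration
output (`concentration = count / Omega`).

Mass-action propensities follow the combinatorial convention
`a_j(x) = c_j * prod_i choose(x_i, r_ij)`, so a dimerization `2X -> 0` with
stochastic rate constant `c` has propensity `c x (x-1) / 2`. This is stated
prominently because silent factor-of-two discrepancies between conventions
are a classic source of wrong variances. General (non-mass-action)
propensities are accepted verbatim; engines that need polynomials
(moments, SSE, MCM) require a Taylor polynomialization first
(`taylor_expand_propensity()`), with the expansion center kept symbolic —
centering at the running mean is the only choice that keeps moment systems
autonomous. The truncation order of that expansion is exposed as an option
with the moment order as its default.

## The generator as the single source of truth

Everything mesoscopic follows from the action of the master-equation
generator on polynomial test functions,

$$\mathcal{A}f(x,t) = \sum_{j=1}^{n_r} a_j(x,t)\,\big(f(x+\nu_j)-f(x)\big),$$

implemented exactly over a sparse multivariate polynomial ring whose
coefficients are symbolic expressions in parameters and time. Probability
conservation (`A 1 = 0`) and linearity hold structurally, not just
numerically, and are asserted as such in the tests.

## Stochastic simulation

Three exact path samplers share one propensity evaluator:

* **direct**: exponential waiting time with rate `a_0 = sum_j a_j`,
  reaction index drawn proportional to `a_j`;
* **next reaction**: per-reaction absolute tentative firing times with the
  Gibson–Bruck rescaling rule for unfired reactions;
* **modified next reaction**: internal-time formulation; reaction `j`
  fires when its consumed internal time `int a_j dt` reaches a
  unit-exponential budget. With a user-supplied closed-form antiderivative
  the firing-time equation is solved exactly (to root-finding tolerance
  `1e-12`); otherwise adaptive quadrature with absolute tolerance `1e-10`
  controls the error. Fixed delays enter a completion queue and apply the
  full state change at firing time + delay.

Simultaneous tentative firing times are broken toward the lowest reaction
index (a measure-zero event; determinism matters more than the choice).
Each path draws from its own L'Ecuyer-CMRG substream derived from the
master seed, so ensembles are bit-reproducible regardless of execution
order, and the per-path RNG states are stored with the ensemble. Output is
zero-order-hold sampling on the requested grid; full event sequences are
optional (`record_events`), keeping memory bounded for 10^4-path ensembles.

## Finite state projection

The CME restricted to an enumerated truncated space is a sparse linear ODE
`dp/dt = A(t) p` with `A[y, x] = a_j(x)` for in-space transitions and
diagonal `-sum_j a_j(x)` including out-of-space flow. Lost mass is tracked
only through the defect `1 - sum p` (no explicit sink row — an equivalent
bound with a smaller matrix), which is simultaneously the certified
approximation error and the renormalization constant for FSP moments.
Truncation geometry is hyper-rectangles intersected with the nonnegative
integer conservation laws detected from the left null space of the
stoichiometry matrix (a conserved promoter pair contributes 2 states, not
4); bounds are user-supplied, and moments are renormalized by `1 - defect`
with the defect reported so consumers can judge the bias. Integration uses
the sparse stiff solver (`deSolve::lsodes`); time-dependent propensities
re-evaluate the matrix per solver callback on a fixed sparsity skeleton.

## Moment equations and closures

For each multi-index `I` up to order `m`, `d<x^I>/dt = <A x^I>` with
monomial expectations replaced by moment symbols — exact but unclosed:
with maximum propensity degree `d`, right-hand sides reference moments up
to `m + d - 1`. The central representation (means + central moments) is
obtained by exact symbolic change of variables and is the default for
integration; the raw representation is retained because closures are most
natural there and because the two must agree (they are interconvertible,
and the suite checks trajectory-level agreement). At order 4 the raw form
is numerically fragile — raw moments span many decades and variances come
from catastrophic cancellation — which is why central is the default.

Closures eliminate the higher symbols:

* **low dispersion**: central moments above `m` set to zero;
* **mean field**: a higher raw moment factorizes by peeling one unit of
  the lexicographically first species in its index. The literature leaves
  this split under-determined; the peel rule is fixed and documented so
  results are reproducible (anyone comparing numerically against another
  toolbox's "mean field" should check its split first);
* **zero cumulants**: cumulants above `m` vanish; higher raw moments come
  from the multivariate moment–cumulant recursion;
* **derivative matching**: a higher raw moment is a product of powers of
  lower moments with exponents solving the binomial moment-matching linear
  system (solved once per index and order). The resulting right-hand sides
  contain real powers, so positivity of moments is required along the
  trajectory — divergence is a known and expected behavior of this
  closure on some models and is *reported*, never masked;
* **user**: an explicit substitution map; unresolved symbols are an error
  naming the symbol.

For the three polynomial closures, substitution happens inside the
polynomial ring, and the Jacobian of the closed system is emitted by
formal differentiation — on the 69-state order-4 system of the gene
expression fixture this analytic Jacobian (together with folding numeric
parameter values into the compiled code) cuts integration from minutes to
seconds. Compiled right-hand sides go through common-subexpression
elimination before lowering, since derived moment systems share many
subterms.

Initial conditions are deterministic counts (all central moments zero),
with an option to supply initial moments. Concentration-unit output is an
exact post-scaling (the moment of `x/Omega` is the count moment divided by
`Omega^|I|`); all four closure schemes are scale-invariant, so this is
identical to deriving in concentration units while keeping a single
derivation path.

## System size expansion

With the ansatz `x = Omega*phi + sqrt(Omega)*xi` and macroscopic rates
`f_j`, the engine derives one nested ODE system:

* `RRE`: `dphi/dt = S f(phi)`;
* `LNA`: fluctuation covariance `dC/dt = A C + C A' + S diag(f) S'`, with
  `A` the RRE Jacobian;
* `EMRE`: mean shift `dh/dt = A h + (1/2) A'' : C + S g`, where `g`
  collects the sub-leading parts of mass-action propensities (the `-1` in
  `x(x-1)`), so the discreteness correction lands in the correction term
  and the RRE remains the strict macroscopic limit;
* `IOS`: the leading third cumulant `T` of the fluctuations and the
  order-`1/Omega` covariance correction `Z`, whose equations couple `A`,
  its second and third derivatives, the derivative tensors of
  `S diag(f) S'`, and `g`.

Corrections never feed back into lower blocks; reading the LNA block out
of an IOS run reproduces a standalone LNA run to integration tolerance,
which is the main structural test of the derivation (the IOS term set is
verified through such nesting and large-volume limits rather than
formula-by-formula, since its published forms vary in notation). Count
output: mean `Omega*phi (+ h)`, covariance `Omega*C (+ Z)`. Across
volumes, mass-action rate constants scale as `Omega^(1-order)`; general
kinetics are taken as already macroscopic term by term — a documented
assumption, adequate for the shipped fixtures, wrong for a hand-written
propensity that secretly encodes combinatorial corrections.

One empirical note: on the dimerization fixture the EMRE shift is
*positive* (the stationary law is sub-Poissonian, so `E[x(x-1)]` falls
below `E[x]^2` and the true mean sits above the RRE mean). Intuition that
bimolecular depletion should push the correction negative fails here; the
ordering that actually matters — EMRE closer to the FSP than the RRE — is
what the tests assert.

## Method of conditional moments

Species are partitioned into low-copy modes `y` (automatic rule: provably
finite range from a conservation law, at most 2 states by default — e.g.
promoter occupancy; everything else needs a manual partition) and
high-copy species `z`. Applying the generator to `1{y = y0} z^I` gives
exact equations for the weighted moments `w_{y,I} = p(y) E[z^I | y]`.
Because gain and loss terms of mode-switching reactions attach to
different modes, the weighted system references conditional moments up to
`m + deg_z(a)` (no leading-order cancellation), closed per mode by the
same closure engine with conditional moments `w/(p + eps)`; the
regularization `eps = 1e-10` avoids 0/0 at modes of vanishing probability
and is separate from the reporting threshold (conditional moments are
shown only where `p(y) > 1e-10`, `NA` otherwise). The probability
sub-system sums to zero structurally, so total probability is conserved to
integrator tolerance.

The weighted form is a plain ODE and is the primary integration path; the
normalized DAE view (probabilities and conditional moments, with
probability-weighted mass rows) is retained and solved with the implicit
solver `deSolve::daspk` — it requires strictly positive initial mode
probabilities for consistent initialization, so the point-mass default
initial condition uses the weighted form. Degenerate partitions are the
strongest correctness checks and are tested: empty high-copy reduces the
MCM to the FSP over the modes; empty low-copy reduces it to the plain
moment equations. Unconditional moments come from the laws of total
expectation and variance; low-copy moments from the marginal itself.
Propensities jointly involving `y` and `z` are handled by evaluating `y`
exactly (mode by mode) and treating only the `z` dependence polynomially;
any Taylor expansion is therefore in `z` only.

## Sensitivities

Forward: the augmented system carries `n (1 + n_theta)` states at order 1
— exactly, which the tests assert — and the symmetric second-order block
adds `n n_theta (n_theta + 1) / 2`. DAE bases replicate their mass matrix
blockwise. Adjoint (ODE bases only — the DAE case is deliberately
unsupported and errors toward the forward path): `dlambda/dt = -J'lambda`
integrated backward segment-wise between measurement times with jump
updates at each datum (no delta smoothing — exact for discrete-time
data), the state co-integrated backward alongside and re-anchored on the
stored forward solution at every measurement so no interpolation error
enters. The gradient assembles the quadrature `int lambda' f_theta dt`,
the initial-condition term, and direct observable terms. Finite
differences use central steps at relative `1e-6` with an absolute floor
`1e-8`. The adjoint state dimension is `n` regardless of `n_theta`; the
structural scaling (not wall-clock ratios, which are hardware-dependent)
is what the suite checks.

## Numerical defaults

Integration: `lsoda` (ODE) / `radau` with constant mass matrix (DAE) /
`lsodes` (FSP), relative tolerance `1e-8`, absolute `1e-10` — moment
systems are stiff and downstream comparisons are made at the `1e-6` level.
Gradient computations tighten to `1e-10`/`1e-12`. Covariance positivity is
flagged (minimum eigenvalue carried on the trajectory), never clipped.
Degenerate inputs are handled explicitly: a single-time grid returns the
initial state, zero propensities freeze paths and zero the generator, a
zero-variance entry yields `NA` correlations (not 0), and a singular
covariance yields absent partial correlations with a diagnostic.

## What the fixtures do and do not show

The shipped study systems are: a linear birth–death unit (every moment
description is exact — the primary calibration), a dimerization unit
(nonlinear, sub-Poissonian), a three-stage gene expression model with
positive feedback (promoter switching `k_on = 0.05`, `k_off = 0.1`,
feedback `k_fb = 0.01` per protein, transcription `k_m = 5`, translation
`k_p = 2`, degradation `gamma_m = 1`, `gamma_p = 0.5`; chosen to mix a
2-state low-copy promoter with mRNA around 2–5 and protein around 10–20
copies so that FSP reference solves stay at ~3500 states), a
time-dependent birth process `a(t) = 5 (1 + sin t)` (inhomogeneous
Poisson, analytic law), and a two-compartment phosphorylation–dimerization–
nuclear-export chain with a pulse input `u(t) = t e^{-0.25 t}` and five
intermediate nuclear species (delayed export as a linear chain). Rate
constants for the gene expression and signaling fixtures are this
package's documented defaults, selected for the copy-number regimes above.

This parameterization of the gene-expression model is strongly bimodal
with slow switching — deliberately hard. Low-order moment closures
genuinely diverge there (order 2 low-dispersion and zero-cumulants) or
wander to absurd values while remaining finite (order 2 mean field);
derivative matching diverges at several orders. The benchmark harness
reports all of this as `failed`/large rather than smoothing it over, and
the conditional-moment hybrid — which treats the bimodality exactly —
stays within 2% (order 2) and 0.2% (order 3) of the FSP protein mean.
Passing tests on these fixtures demonstrate correctness of the
derivations and solvers at desk scale; they do not certify closure
accuracy on other networks (closure quality is model-specific, which is
the reason a comparison harness exists), nor SSA performance at
genome-scale reaction counts, nor SBML coverage beyond core constructs
(no events, rules, or hierarchical models).

Problem sizes used throughout the suite — 10^3–10^4 SSA paths, FSP spaces
up to ~3.5k states, moment orders up to 4 — are the package's chosen
desk-scale study conditions: large enough that sampling error bars
(4 standard errors) and truncation defects (~1e-6) are far below the
effects being tested.
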