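# cmekit

Stochastic chemical kinetics from a single model definition.

Cellular reaction networks — gene expression, signal transduction — run on
molecule counts small enough that random timing of individual reaction
events shapes the biology. The exact description is the chemical master
equation (CME): for a network of `n_s` species and `n_r` reactions with
propensities `a_j(x, t)` and state-change vectors `nu_j`, the probability
`p(x|t)` of count state `x` evolves as

```
dp(x|t)/dt = sum_j [ a_j(x - nu_j, t) p(x - nu_j|t) - a_j(x, t) p(x|t) ]
```

The CME is rarely solvable directly, so practitioners juggle a hierarchy of
descriptions. cmekit derives all of them from one declarative network
definition, so their accuracy can be compared on equal footing:

- **SSA** — exact sample paths (direct, next-reaction, and modified
  next-reaction methods; the last handles time-dependent propensities and
  fixed delays exactly when closed-form antiderivatives are available);
- **FSP** — the finite state projection: the CME restricted to a truncated
  state space, with the lost probability mass `1 - sum_x p(x|t)` reported
  as a certified error bound; the package's reference oracle;
- **MM** — moment equations of arbitrary order `m` with selectable closures
  (low dispersion, mean field, zero cumulants, derivative matching, or
  user-supplied), in raw or central representation;
- **SSE** — the system size expansion in the inverse volume `1/Omega`:
  reaction rate equations (RRE), linear noise approximation (LNA),
  effective mesoscopic rate equation (EMRE, mean correction), and the
  inverse-omega-square covariance correction (IOS), as one nested system;
- **MCM** — the method of conditional moments: exact marginal probabilities
  for low-copy species (e.g. promoter states) coupled to closed conditional
  moments of high-copy species (mRNA, protein);
- **sensitivities** — first- and second-order forward sensitivity systems
  for any derived ODE/DAE description, and adjoint sensitivities for ODE
  descriptions, feeding gradients of weighted least-squares objectives.

Models are defined in R, read from a YAML schema
(`inst/schema/network.schema.json`), or imported from SBML.

## A worked example

The three-stage gene expression model — a promoter switching between off
and on states with protein-mediated positive feedback, transcription,
translation, and first-order degradation — is built in:

```r
library(cmekit)

net <- make_fixture("three_stage_gene_expression")
net
#> <ck_network> three_stage_gene_expression: 4 species, 7 reactions, 7 parameters

## reference solution: FSP on a truncated space (promoter conservation
## detected automatically; ~3500 states, mass defect ~ 2e-6 at t = 100)
sol  <- solve_fsp(net, c(M = 22, P = 75), seq(0, 100, by = 5))
ref  <- fsp_moments(sol, 2)
ref$mean[21, ]
#>     G_off      G_on         M         P
#> 0.5664244 0.4335756 2.1678653 8.6713366

## hybrid description: exact promoter marginals + conditional moments
part <- partition_species(net)         # low = {G_off, G_on}, high = {M, P}
mcm  <- derive_mcm(net, part, order = 3)
res  <- simulate_mcm(mcm, seq(0, 100, by = 5))
ov   <- reconstruct_overall_moments(res)
abs(ov$mean[21, "P"] - ref$mean[21, "P"]) / ref$mean[21, "P"]
#> [1] 0.001925058
```

The reconstructed protein mean of the order-3 conditional-moment system
lands within 0.2% of the FSP reference, at 20 state variables instead of
~3500. The same comparison for every description is one call:

```r
bm <- closure_benchmark(net, "P", t_star = 100, orders = 2:4,
                        bounds = c(M = 22, P = 75))
subset(bm, quantity == "mean" & status == "ok")[, c("order", "closure", "rel_error")]
#>     order        closure  rel_error
#> P1      2     mean_field 3.19e+07      # exploded, finite -> reported as is
#> P4      3 low_dispersion 1.16e-01
#> P5      3     mean_field 3.82e-01
#> P8      4 low_dispersion 4.44e-02
#> P9      4     mean_field 1.24e-02
#> P10     4 zero_cumulants 9.20e-02
```

Runs that diverge (derivative matching here, and the order-2 closures on
this strongly bimodal parameterization) are reported with status
`"failed"`, never as a number.

A thin command-line wrapper over the same functions ships in
`inst/cli/cmekit` (`derive`, `simulate`, `compare`, `gradient`
subcommands).

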