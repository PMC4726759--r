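# Shared fixtures and cached reference solutions for the test suite.
# Expensive oracles (FSP reference runs) are computed once per session.

.oracle_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.oracle_cache[[key]])) .oracle_cache[[key]] <- force(expr)
  .oracle_cache[[key]]
}

# FSP reference for the three-stage gene expression fixture on [0, 100]
# (bounds chosen so the mass defect stays ~ 2e-6).
three_stage_reference <- function() {
  cached("three_stage_fsp", {
    net <- make_fixture("three_stage_gene_expression")
    space <- enumerate_states(net, c(M = 22, P = 75))
    sol <- solve_fsp(net, space, seq(0, 100, by = 5))
    list(net = net, space = space, sol = sol,
         moments = fsp_moments(sol, 2L),
         promoter = marginalize_fsp(sol, c("G_off", "G_on")))
  })
}

dimerization_reference <- function() {
  cached("dimer_fsp", {
    net <- make_fixture("dimerization")
    sol <- solve_fsp(net, c(X = 200), c(0, 10))
    list(net = net, sol = sol, moments = fsp_moments(sol, 2L))
  })
}

# exact birth-death moments: Poisson(mu(t)) with mu(t) = k/gamma (1 - e^-gt)
bd_mean <- function(t, k = 10, gamma = 1) k / gamma * (1 - exp(-gamma * t))

# two-sample z statistic on ensemble means
z_stat <- function(m1, se1, m2, se2) abs(m1 - m2) / sqrt(se1^2 + se2^2)

# evaluate an expression on random integer states, for symbolic-equivalence
# checks by numeric sampling
eval_on_states <- function(expr, net, n = 25, seed = 99, t_max = 10) {
  set.seed(seed)
  sn <- species_names <- vapply(net$species, `[[`, character(1L), "name")
  vapply(seq_len(n), function(i) {
    env <- c(setNames(as.list(sample(0:30, length(sn), TRUE)), sn),
             as.list(net$parameters),
             list(t = runif(1, 0, t_max), pi = pi))
    eval(expr, env)
  }, numeric(1L))
}
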