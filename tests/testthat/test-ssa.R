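test_that("ensembles are bit-identical for a given (seed, method, n_paths)", {
  net <- make_fixture("birth_death")
  for (m in c("direct", "next_reaction", "modified_next_reaction")) {
    e1 <- simulate_ssa(net, c(0, 1, 2), 50L, seed = 42L, method = m)
    e2 <- simulate_ssa(net, c(0, 1, 2), 50L, seed = 42L, method = m)
    expect_identical(e1$paths, e2$paths, info = m)
  }
  # a single path is still a valid ensemble
  e <- simulate_ssa(net, c(0, 1), 1L, seed = 7L, method = "next_reaction")
  expect_equal(dim(e$paths), c(1L, 2L, 1L))
})

test_that("paths never contain negative counts and absorb at zero propensity", {
  net <- make_fixture("dimerization")
  ens <- simulate_ssa(net, seq(0, 5, by = 0.5), 200L, seed = 3L)
  expect_true(all(ens$paths >= 0L))
  # all-zero propensities freeze the path: pure death from 0
  dead <- reaction_network(
    species = list(species("X", initial = 0)),
    reactions = list(reaction(reactants = c(X = 1), rate = "g",
                              kinetics = "mass_action")),
    parameters = c(g = 1))
  ens0 <- simulate_ssa(dead, c(0, 1, 5), 20L, seed = 1L)
  expect_true(all(ens0$paths == 0L))
})

test_that("first event of a pure-death unit follows the exponential law", {
  dead <- reaction_network(
    species = list(species("X", initial = 1)),
    reactions = list(reaction(reactants = c(X = 1), rate = "g",
                              kinetics = "mass_action")),
    parameters = c(g = 2))
  ens <- simulate_ssa(dead, c(0, 20), 2000L, seed = 11L, record_events = TRUE)
  ft <- vapply(ens$events, function(ev) ev$time[1L], numeric(1L))
  expect_false(anyNA(ft))
  # mean within 4 standard errors of 1/g
  expect_lt(abs(mean(ft) - 0.5), 4 * sd(ft) / sqrt(length(ft)))
})

test_that("all three simulators agree with the analytic mean and each other", {
  net <- make_fixture("birth_death")
  mu1 <- bd_mean(1)
  ests <- lapply(c("direct", "next_reaction", "modified_next_reaction"),
                 function(m) {
    ens <- simulate_ssa(net, c(0, 1), 3000L, seed = 5L, method = m)
    est <- ensemble_moments(ens)
    list(mean = est$mean[2L, 1L], se = est$se_mean[2L, 1L])
  })
  for (e in ests) expect_lt(abs(e$mean - mu1), 4 * e$se)
  # pairwise two-sample z-tests at alpha = 0.001
  zcrit <- qnorm(1 - 0.001 / 2)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_lt(z_stat(ests[[i]]$mean, ests[[i]]$se, ests[[j]]$mean, ests[[j]]$se),
              zcrit)
  }
})

test_that("time-dependent propensities integrate to the inhomogeneous Poisson law", {
  net <- make_fixture("timedep_birth")
  ens <- simulate_ssa(net, c(0, 2 * pi), 3000L, seed = 9L,
                      method = "modified_next_reaction",
                      antiderivatives = list("b0 * (t - cos(omega * t) / omega)"))
  est <- ensemble_moments(ens)
  # X(2*pi) ~ Poisson(10*pi): mean within 4 SE, Fano close to 1
  expect_lt(abs(est$mean[2L, 1L] - 10 * pi), 4 * est$se_mean[2L, 1L])
  expect_lt(abs(est$variance[2L, 1L] / est$mean[2L, 1L] - 1), 0.1)
  # quadrature fallback (no antiderivative) matches the exact inversion
  ens2 <- simulate_ssa(net, c(0, 2 * pi), 400L, seed = 13L,
                       method = "modified_next_reaction")
  est2 <- ensemble_moments(ens2)
  expect_lt(z_stat(est$mean[2L, 1L], est$se_mean[2L, 1L],
                   est2$mean[2L, 1L], est2$se_mean[2L, 1L]),
            qnorm(1 - 0.001 / 2))
})

test_that("fixed delays postpone the state change to firing + delay", {
  dnet <- reaction_network(
    species = list(species("X", initial = 0)),
    reactions = list(reaction(products = c(X = 1), rate = "k", delay = 2)),
    parameters = c(k = 5))
  ens <- simulate_ssa(dnet, c(0, 1, 1.99, 2.5, 4), 300L, seed = 2L,
                      method = "modified_next_reaction")
  expect_true(all(ens$paths[, 1:3, 1L] == 0L))    # nothing completes before t = 2
  est <- ensemble_moments(ens)
  # by t = 4, completions cover initiations from [0, 2): mean ~ k * 2
  expect_lt(abs(est$mean[5L, 1L] - 10), 4 * est$se_mean[5L, 1L])
  # direct method refuses delayed/time-dependent models
  expect_error(simulate_ssa(dnet, c(0, 1), 5L, seed = 1L, method = "direct"),
               "modified_next_reaction")
  expect_error(simulate_ssa(make_fixture("timedep_birth"), c(0, 1), 5L,
                            seed = 1L, method = "next_reaction"),
               "modified_next_reaction")
})

test_that("ensemble moment estimates behave like the estimators they claim to be", {
  net <- make_fixture("birth_death")
  # degenerate ensemble: constant paths at the initial state
  frozen <- make_fixture("birth_death", overrides = list(k = 0, gamma = 0))
  frozen$species[[1L]]$initial <- 7L
  ens7 <- simulate_ssa(frozen, c(0, 1), 40L, seed = 1L)
  est7 <- ensemble_moments(ens7)
  expect_equal(unname(est7$mean[2L, 1L]), 7)
  expect_equal(unname(est7$variance[2L, 1L]), 0)
  expect_equal(unname(est7$se_mean[2L, 1L]), 0)
  # pooling two half-ensembles reproduces the weighted mean
  e1 <- simulate_ssa(net, c(0, 1), 100L, seed = 21L)
  e2 <- simulate_ssa(net, c(0, 1), 100L, seed = 22L)
  pooled <- e1
  arr <- array(0L, dim = c(200L, 2L, 1L))
  arr[1:100, , ] <- e1$paths
  arr[101:200, , ] <- e2$paths
  pooled$paths <- arr
  mp <- ensemble_moments(pooled)$mean[2L, 1L]
  m1 <- ensemble_moments(e1)$mean[2L, 1L]
  m2 <- ensemble_moments(e2)$mean[2L, 1L]
  expect_equal(mp, (m1 + m2) / 2, tolerance = 1e-12)
  # near-stationary birth-death is Poisson: Fano factor within [0.9, 1.1]
  ens <- simulate_ssa(net, c(0, 6), 3000L, seed = 31L)
  est <- ensemble_moments(ens)
  expect_gt(est$variance[2L, 1L] / est$mean[2L, 1L], 0.9)
  expect_lt(est$variance[2L, 1L] / est$mean[2L, 1L], 1.1)
})

test_that("empirical distributions are normalized, marginal-consistent, and near-Poisson", {
  net <- make_fixture("birth_death")
  ens <- cached("bd_ens_t6", simulate_ssa(net, c(0, 6), 3000L, seed = 31L))
  d <- empirical_distribution(ens, 6)
  expect_equal(sum(d$probability), 1)
  pois <- dpois(d$X, bd_mean(6))
  tv <- 0.5 * (sum(abs(d$probability - pois)) + (1 - sum(pois)))
  expect_lt(tv, 0.05)
  expect_error(empirical_distribution(ens, 3.14), "not on the ensemble")
  # marginalizing a joint histogram equals the directly computed marginal
  casc <- reaction_network(
    species = list(species("A", initial = 0), species("B", initial = 0)),
    reactions = list(
      reaction(products = c(A = 1), rate = "k1", kinetics = "mass_action"),
      reaction(reactants = c(A = 1), rate = "g1", kinetics = "mass_action"),
      reaction(products = c(B = 1), rate = "k2", kinetics = "mass_action"),
      reaction(reactants = c(B = 1), rate = "g2", kinetics = "mass_action")),
    parameters = c(k1 = 3, g1 = 1, k2 = 5, g2 = 1))
  ens2 <- simulate_ssa(casc, c(0, 4), 500L, seed = 8L)
  joint <- empirical_distribution(ens2, 4)
  margA <- empirical_distribution(ens2, 4, "A")
  agg <- tapply(joint$probability, joint$A, sum)
  expect_equal(as.numeric(agg[as.character(margA$A)]), margA$probability,
               tolerance = 1e-12)
})

test_that("ensembles persist to CSV with seeds and metadata", {
  net <- make_fixture("birth_death")
  ens <- simulate_ssa(net, c(0, 1), 10L, seed = 4L)
  d <- withr::local_tempdir()
  write_ensemble_csv(ens, d)
  expect_true(all(file.exists(file.path(d, c("paths.csv", "seeds.csv",
                                             "metadata.csv")))))
  paths <- read.csv(file.path(d, "paths.csv"))
  expect_equal(nrow(paths), 20L)
  expect_equal(paths$X[paths$path == 3 & paths$time == 1],
               as.integer(ens$paths[3L, 2L, 1L]))
})
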