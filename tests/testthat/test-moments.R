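test_that("moment state counts match the combinatorial formula", {
  for (n_s in 1:4) for (m in 1:4) {
    expect_equal(moment_state_count(n_s, m), choose(n_s + m, m) - 1L)
    net <- switch(n_s, make_fixture("birth_death"), NULL, NULL,
                  make_fixture("three_stage_gene_expression"))
    if (!is.null(net)) {
      msys <- derive_moment_equations(net, m, kind = "raw")
      expect_length(msys$states, moment_state_count(n_s, m))
    }
  }
})

test_that("the reaction rate equations are the macroscopic limit", {
  bd <- make_fixture("birth_death")
  rre <- derive_rre(bd)
  expect_equal(eval(rre$rhs[[1L]], list(X = 3, k = 10, gamma = 1)), 7)
  # dimerization: dphi/dt = k1 - 2 k2 phi^2 (leading term of k2 x (x-1))
  dm <- derive_rre(make_fixture("dimerization"))
  for (x in c(0, 2.5, 14)) {
    expect_equal(eval(dm$rhs[[1L]], list(X = x, k1 = 4, k2 = 0.01)),
                 4 - 2 * 0.01 * x^2, tolerance = 1e-12)
  }
  # zero-propensity network: dphi/dt = 0
  z <- derive_rre(make_fixture("birth_death", overrides = list(k = 0, gamma = 0)))
  expect_equal(eval(z$rhs[[1L]], list(X = 5, k = 0, gamma = 0)), 0)
})

test_that("raw and central birth-death equations match the hand derivation", {
  bd <- make_fixture("birth_death")
  raw <- derive_moment_equations(bd, 2L, kind = "raw")
  # d<m1> = k - g m1 ; d<m2> = k + (2k + g) m1 - 2 g m2
  env <- list(mom_1 = 3.2, mom_2 = 15.7, k = 10, gamma = 1)
  expect_equal(eval(cmekit:::p_to_expr(raw$rhs_polys[["mom_1"]]), env),
               10 - 3.2, tolerance = 1e-12)
  expect_equal(eval(cmekit:::p_to_expr(raw$rhs_polys[["mom_2"]]), env),
               10 + 21 * 3.2 - 2 * 15.7, tolerance = 1e-12)
  # central: d sigma^2 = k + g mu - 2 g sigma^2
  cen <- derive_moment_equations(bd, 2L)
  envc <- list(mom_1 = 3.2, cen_2 = 4.4, k = 10, gamma = 1)
  expect_equal(eval(cmekit:::p_to_expr(cen$rhs_polys[["cen_2"]]), envc),
               10 + 3.2 - 2 * 4.4, tolerance = 1e-12)
})

test_that("linear networks are exact at every order and closure", {
  bd <- make_fixture("birth_death")
  tt <- c(0, 0.5, 1, 5, 30)
  mu <- bd_mean(tt[-1L])
  for (m in 1:4) {
    msys <- derive_moment_equations(bd, m)
    expect_length(msys$unclosed, 0L)   # degree-1 propensities close exactly
    for (cl in c("low_dispersion", "mean_field", "zero_cumulants",
                 "derivative_matching")) {
      tr <- simulate_moments(apply_closure(msys, cl), tt)
      expect_lt(max(abs(tr$mean[-1L, 1L] - mu) / mu), 1e-6)
      if (m >= 2L) {
        expect_lt(max(abs(moment_variance(tr, "X")[-1L] - mu) / mu), 1e-6)
      }
    }
  }
})

test_that("raw and central representations yield the same trajectories", {
  nd <- make_fixture("dimerization")
  for (cl in c("low_dispersion", "zero_cumulants")) {
    tr_raw <- simulate_moments(apply_closure(
      derive_moment_equations(nd, 3L, kind = "raw"), cl), c(0, 2, 10))
    tr_cen <- simulate_moments(apply_closure(
      derive_moment_equations(nd, 3L), cl), c(0, 2, 10))
    expect_equal(tr_raw$mean, tr_cen$mean, tolerance = 1e-6)
    expect_equal(moment_variance(tr_raw, "X"), moment_variance(tr_cen, "X"),
                 tolerance = 1e-5)
  }
})

test_that("closure rules reproduce their defining identities", {
  ring <- c("mom_1", "mom_2", "mom_3")
  # zero cumulants at m = 2: <x^3> = 3 mu sigma^2 + mu^3 = 3 m1 m2 - 2 m1^3
  zc <- cmekit:::close_raw_map(1L, 2L, 3L, "zero_cumulants", ring)
  env <- list(mom_1 = 2.5, mom_2 = 9.1)
  expect_equal(eval(zc$exprs$mom_3, env),
               3 * 2.5 * 9.1 - 2 * 2.5^3, tolerance = 1e-12)
  # derivative matching at m = 2: <x^3> = m2^3 / m1^3
  dm <- cmekit:::close_raw_map(1L, 2L, 3L, "derivative_matching", ring)
  expect_equal(eval(dm$exprs$mom_3, env), 9.1^3 / 2.5^3, tolerance = 1e-12)
  # mean field peels the lexicographically first species
  ring2 <- vapply(cmekit:::moment_indices(2L, 3L), cmekit:::mom_sym, character(1L))
  mf <- cmekit:::close_raw_map(2L, 2L, 3L, "mean_field", ring2)
  env2 <- list(mom_1_0 = 2, mom_0_1 = 3, mom_1_1 = 7, mom_2_0 = 5, mom_0_2 = 10)
  expect_equal(eval(mf$exprs$mom_2_1, env2), 2 * 7)   # peel one unit of species 1
  expect_equal(eval(mf$exprs$mom_0_3, env2), 3 * 10)
  # low dispersion zeroes central moments above m
  ld <- cmekit:::close_raw_map(1L, 2L, 3L, "low_dispersion", ring)
  # <x^3> with third central moment 0: 3 m1 m2 - 2 m1^3 (same as Gaussian)
  expect_equal(eval(ld$exprs$mom_3, env), 3 * 2.5 * 9.1 - 2 * 2.5^3,
               tolerance = 1e-12)
  # user maps must resolve every higher symbol
  msys <- derive_moment_equations(make_fixture("dimerization"), 2L)
  expect_error(apply_closure(msys, "user", user_map = list()), "mom_3")
  ok <- apply_closure(msys, "user", user_map = list(mom_3 = "3*mom_1*mom_2 - 2*mom_1^3"))
  expect_length(ok$unclosed, 0L)
})

test_that("second-order moments track the FSP oracle on the dimerization model", {
  ref <- dimerization_reference()
  tr <- simulate_moments(apply_closure(
    derive_moment_equations(ref$net, 2L), "low_dispersion"), c(0, 10))
  rel_mean <- abs(tr$mean[2L, 1L] - ref$moments$mean[2L, 1L]) /
    ref$moments$mean[2L, 1L]
  expect_lt(rel_mean, 0.05)
  rel_var <- abs(moment_variance(tr, "X")[2L] - ref$moments$cov[2L, 1L, 1L]) /
    ref$moments$cov[2L, 1L, 1L]
  expect_lt(rel_var, 0.1)
  # k = 0 from an empty state keeps every moment at zero
  z <- make_fixture("dimerization", overrides = list(k1 = 0))
  trz <- simulate_moments(apply_closure(derive_moment_equations(z, 2L),
                                        "low_dispersion"), c(0, 5))
  expect_equal(max(abs(trz$mean)), 0)
  expect_equal(max(abs(trz$cov)), 0)
})

test_that("non-polynomial propensities are rejected with Taylor guidance", {
  hill <- reaction_network(
    species = list(species("X", initial = 0)),
    reactions = list(reaction(products = c(X = 1), rate = ~v * X / (K + X))),
    parameters = c(v = 5, K = 2))
  expect_error(derive_moment_equations(hill, 2L), "Taylor")
})

test_that("correlation and partial-correlation maps have the documented conventions", {
  # diagonal covariance -> identity correlation
  traj <- cmekit:::new_moments(
    times = 0, species = c("A", "B"),
    mean = matrix(c(1, 2), 1), cov = array(diag(c(2, 3)), c(1, 2, 2)),
    method = "MM", order = 2L, closure = "none", units = "molecule_numbers")
  cm <- correlation_maps(traj)[[1L]]
  expect_equal(unname(cm$correlation), diag(2))
  # 2-species case: partial correlation equals the correlation
  cv <- matrix(c(2, 1.2, 1.2, 3), 2)
  traj2 <- cmekit:::new_moments(
    times = 0, species = c("A", "B"),
    mean = matrix(c(1, 2), 1), cov = array(cv, c(1, 2, 2)),
    method = "MM", order = 2L, closure = "none", units = "molecule_numbers")
  cm2 <- correlation_maps(traj2)[[1L]]
  expect_equal(cm2$partial["A", "B"], cm2$correlation["A", "B"],
               tolerance = 1e-12)
  # zero variance -> NA, not zero; singular covariance -> diagnosed
  cv0 <- matrix(c(0, 0, 0, 3), 2)
  traj0 <- cmekit:::new_moments(
    times = 0, species = c("A", "B"),
    mean = matrix(c(1, 2), 1), cov = array(cv0, c(1, 2, 2)),
    method = "MM", order = 2L, closure = "none", units = "molecule_numbers")
  cm0 <- correlation_maps(traj0)[[1L]]
  expect_true(is.na(cm0$correlation["A", "B"]))
  expect_false(is.null(attr(cm0$partial, "diagnostic")))
})

test_that("transcription and translation are positively correlated", {
  ref <- three_stage_reference()
  lna <- simulate_sse(derive_sse(ref$net, "LNA"), c(0, 10))
  cm <- correlation_maps(lna)[[2L]]
  expect_gt(cm$correlation["M", "P"], 0)
  # same sign in the exact FSP covariance
  expect_gt(ref$moments$cov[3L, "M", "P"], 0)
})

test_that("concentration units rescale moments by compartment volume", {
  net <- make_fixture("birth_death")
  net$compartments[[1L]]$volume <- 4
  tr_n <- simulate_moments(derive_moment_equations(net, 2L), c(0, 30))
  tr_c <- simulate_moments(derive_moment_equations(net, 2L,
                                                   units = "concentrations"),
                           c(0, 30))
  expect_equal(tr_c$mean[2L, 1L], tr_n$mean[2L, 1L] / 4, tolerance = 1e-10)
  expect_equal(moment_variance(tr_c, "X")[2L],
               moment_variance(tr_n, "X")[2L] / 16, tolerance = 1e-10)
})
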