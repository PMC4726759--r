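test_that("forward sensitivities match the closed form on birth-death", {
  rre <- derive_rre(make_fixture("birth_death"))
  sens <- derive_forward_sensitivities(rre, "k")
  tr <- integrate_system(sens$system, c(0, 1, 2), c(k = 10, gamma = 1))
  # ds/dt = -gamma s + 1, s(0) = 0  =>  s(t) = (1 - e^{-gamma t}) / gamma
  expect_equal(unname(tr[, "sn_X_k"]), (1 - exp(-c(0, 1, 2))), tolerance = 1e-7)
  # a parameter absent from rhs and x0 has identically zero sensitivity
  sens0 <- derive_forward_sensitivities(
    symbolic_system("X", list(quote(k - gamma * X)), list(0),
                    c("k", "gamma", "unused")), "unused")
  tr0 <- integrate_system(sens0$system, c(0, 2), c(k = 10, gamma = 1, unused = 3))
  expect_equal(max(abs(tr0[, "sn_X_unused"])), 0)
})

test_that("the augmented system has exactly n(1 + n_theta) states at order 1", {
  # constructed 5-state linear system with 3 parameters
  sts <- paste0("x", 1:5)
  rhs <- lapply(1:5, function(i) str2lang(sprintf("a * x%d - b * x%d + c", max(1, i - 1), i)))
  sys <- symbolic_system(sts, rhs, as.list(rep(0, 5)), c("a", "b", "c"))
  aug <- derive_forward_sensitivities(sys, c("a", "b", "c"))
  expect_length(aug$system$state_symbols, 5L * (1L + 3L))
  # order 2 adds n * n_theta (n_theta + 1) / 2 states
  aug2 <- derive_forward_sensitivities(sys, c("a", "b", "c"), order = 2L)
  expect_length(aug2$system$state_symbols, 20L + 5L * 6L)
  # the base block of the augmented rhs is the base rhs itself
  expect_identical(aug$system$rhs[seq_len(5L)], sys$rhs)
})

test_that("second-order sensitivities are symmetric in the parameter pair", {
  rre <- derive_rre(make_fixture("birth_death"))
  s2 <- derive_forward_sensitivities(rre, c("k", "gamma"), order = 2L)
  theta <- c(k = 10, gamma = 1)
  tr <- integrate_system(s2$system, c(0, 2), theta)
  # cross-check s2_{k,gamma} against central differences of first-order runs
  s1 <- derive_forward_sensitivities(rre, c("k", "gamma"))
  h <- 1e-5
  sk_at <- function(th) {
    integrate_system(s1$system, c(0, 2), th, rtol = 1e-11,
                     atol = 1e-13)[2L, "sn_X_k"]
  }
  sg_at <- function(th) {
    integrate_system(s1$system, c(0, 2), th, rtol = 1e-11,
                     atol = 1e-13)[2L, "sn_X_gamma"]
  }
  dk_dg <- (sk_at(c(k = 10, gamma = 1 + h)) - sk_at(c(k = 10, gamma = 1 - h))) / (2 * h)
  dg_dk <- (sg_at(c(k = 10 + h, gamma = 1)) - sg_at(c(k = 10 - h, gamma = 1))) / (2 * h)
  expect_equal(unname(dk_dg), unname(dg_dk), tolerance = 1e-5)  # symmetry
  expect_equal(unname(tr[2L, "sn2_X_gamma_k"]), unname(dk_dg), tolerance = 1e-4)
})

test_that("forward, adjoint and finite differences agree on a least-squares objective", {
  rre <- derive_rre(make_fixture("birth_death"))
  obj <- objective_function(list(yX = quote(X)), times = c(0.5, 1, 2),
                            data = matrix(c(4, 6, 8), ncol = 1),
                            weights = c(1, 2, 1))
  gf <- objective_gradient(obj, rre, c(k = 10, gamma = 1), "forward")
  ga <- objective_gradient(obj, rre, c(k = 10, gamma = 1), "adjoint")
  gd <- objective_gradient(obj, rre, c(k = 10, gamma = 1), "finite_differences")
  expect_equal(ga$value, gf$value, tolerance = 1e-8)
  expect_lt(max(abs(gf$gradient - ga$gradient) / abs(gf$gradient)), 1e-6)
  expect_lt(max(abs(gf$gradient - gd$gradient) / abs(gf$gradient)), 1e-4)
  # 5-point-style oracle on a single parameter
  f <- function(k) objective_gradient(obj, rre, c(k = k, gamma = 1),
                                      "forward")$value
  h <- 1e-4
  oracle <- (-f(10 + 2 * h) + 8 * f(10 + h) - 8 * f(10 - h) + f(10 - 2 * h)) / (12 * h)
  expect_equal(unname(gf$gradient["k"]), oracle, tolerance = 1e-6)
})

test_that("a zero-residual fit sits at a stationary point", {
  rre <- derive_rre(make_fixture("birth_death"))
  tt <- c(0.5, 1, 2)
  truth <- integrate_system(rre, c(0, tt), c(k = 10, gamma = 1),
                            rtol = 1e-12, atol = 1e-14)[-1L, 1L]
  obj <- objective_function(list(yX = quote(X)), tt, matrix(truth, ncol = 1))
  g <- objective_gradient(obj, rre, c(k = 10, gamma = 1), "forward")
  expect_lt(g$value, 1e-12)
  expect_lt(sqrt(sum(g$gradient^2)), 1e-6)
})

test_that("the adjoint refuses DAE bases and scales independently of n_theta", {
  dae <- symbolic_system(c("x", "z"), list(quote(-a * x), quote(x - z)),
                         list(1, 1), c("a"),
                         mass_matrix = diag(c(1, 0)), kind = "dae")
  obj <- objective_function(list(y = quote(x)), 1, matrix(0.5))
  expect_error(derive_adjoint(dae, obj), "forward")
  # structural scaling: adjoint state dimension = n for any parameter count
  rre <- derive_rre(make_fixture("two_compartment_chain"))
  ad <- derive_adjoint(rre, objective_function(list(y = quote(pSd)), 10,
                                               matrix(1)))
  expect_length(ad$adjoint_states, length(rre$state_symbols))
  # forward augmentation grows affinely with the parameter count
  n <- length(rre$state_symbols)
  for (np in 1:3) {
    aug <- derive_forward_sensitivities(rre, names(
      make_fixture("two_compartment_chain")$parameters)[seq_len(np)])
    expect_length(aug$system$state_symbols, n * (1L + np))
  }
})

test_that("DAE bases propagate the mass matrix to every sensitivity block", {
  dae <- symbolic_system(c("x", "z"), list(quote(-a * x), quote(x - z)),
                         list(1, 1), "a",
                         mass_matrix = diag(c(1, 0)), kind = "dae")
  aug <- derive_forward_sensitivities(dae, "a")
  M <- aug$system$mass_matrix
  expect_equal(dim(M), c(4L, 4L))
  expect_equal(diag(M), c(1, 0, 1, 0))
  expect_identical(aug$system$kind, "dae")
})

test_that("gradient reports tabulate all methods consistently", {
  rre <- derive_rre(make_fixture("birth_death"))
  obj <- objective_function(list(yX = quote(X)), c(1, 2), matrix(c(6, 8), ncol = 1))
  f <- withr::local_tempfile(fileext = ".csv")
  rep <- gradient_report(obj, rre, c(k = 10, gamma = 1), path = f)
  expect_true(file.exists(f))
  expect_equal(nrow(rep), 6L)   # 2 parameters x 3 methods
  spread <- tapply(rep$gradient, rep$parameter, function(v) diff(range(v)))
  expect_lt(max(spread / abs(tapply(rep$gradient, rep$parameter, mean))), 1e-4)
})
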