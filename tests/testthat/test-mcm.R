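test_that("automatic partition finds conserved low-copy species or demands manual input", {
  net3 <- make_fixture("three_stage_gene_expression")
  part <- partition_species(net3)
  expect_setequal(part$low, c("G_off", "G_on"))
  expect_setequal(part$high, c("M", "P"))
  # no finite-range species in birth-death
  expect_error(partition_species(make_fixture("birth_death")), "manual")
  # manual override with an explicit bound enumerates 2 * 21 modes
  partM <- partition_species(net3, "manual", low_copy = c("G_off", "G_on", "M"),
                             low_bounds = c(M = 20))
  mcm <- derive_mcm(net3, partM, order = 1L)
  expect_equal(nrow(mcm$modes), 2L * 21L)
})

test_that("MCM state counts follow modes x (1 + conditional moments)", {
  net3 <- make_fixture("three_stage_gene_expression")
  part <- partition_species(net3)
  # 2 modes x (1 prob + 2 cond means + 3 cond second moments) = 12
  expect_length(derive_mcm(net3, part, order = 2L)$states, 12L)
  # order 3: 2 x (1 + C(2+3,3) - 1) = 20
  expect_length(derive_mcm(net3, part, order = 3L)$states, 20L)
})

test_that("an empty high-copy partition reduces the MCM to the FSP", {
  net3 <- make_fixture("three_stage_gene_expression")
  part <- partition_species(net3, "manual",
                            low_copy = c("G_off", "G_on", "M", "P"),
                            low_bounds = c(M = 8, P = 12))
  mcm <- derive_mcm(net3, part, order = 1L)
  res <- simulate_mcm(mcm, c(0, 2))
  space <- enumerate_states(net3, c(M = 8, P = 12))
  fsol <- solve_fsp(net3, space, c(0, 2))
  keyM <- apply(mcm$modes[, colnames(space$states)], 1L, paste, collapse = ",")
  keyF <- apply(space$states, 1L, paste, collapse = ",")
  expect_lt(max(abs(res$p[2L, match(keyF, keyM)] - fsol$p[2L, ])), 1e-8)
})

test_that("an empty low-copy partition reduces the MCM to the moment equations", {
  nd <- make_fixture("dimerization")
  part <- partition_species(nd, "manual", low_copy = character(0L))
  for (cl in c("low_dispersion", "zero_cumulants")) {
    res <- simulate_mcm(derive_mcm(nd, part, order = 2L, closure = cl), c(0, 10))
    ov <- reconstruct_overall_moments(res)
    mm <- simulate_moments(apply_closure(derive_moment_equations(nd, 2L), cl),
                           c(0, 10))
    expect_lt(abs(ov$mean[2L, 1L] - mm$mean[2L, 1L]), 1e-6)
    expect_lt(abs(ov$cov[2L, 1L, 1L] - mm$cov[2L, 1L, 1L]), 1e-5)
  }
})

test_that("mode probabilities stay normalized and match the FSP marginal", {
  ref <- three_stage_reference()
  part <- partition_species(ref$net)
  res <- cached("mcm2_run", simulate_mcm(derive_mcm(ref$net, part, order = 2L),
                                         seq(0, 100, by = 5)))
  expect_lt(max(abs(rowSums(res$p) - 1)), 1e-6)
  gon_fsp <- ref$promoter$p[, which(ref$promoter$states[, "G_on"] == 1L)]
  gon_mcm <- res$p[, grep("G_on=1", colnames(res$p))]
  expect_lt(max(abs(gon_mcm - gon_fsp)), 0.01)
  # initial condition: point mass on the initial mode, zero conditional spread
  expect_equal(unname(res$p[1L, grep("G_off=1", colnames(res$p))]), 1)
  cm0 <- res$conditional[[grep("G_off=1", colnames(res$p))]][1L, ]
  expect_equal(unname(cm0["2_0"] - cm0["1_0"]^2), 0)   # conditional var of M
})

test_that("reconstructed moments track the FSP and improve with order", {
  ref <- three_stage_reference()
  part <- partition_species(ref$net)
  res2 <- cached("mcm2_run", simulate_mcm(derive_mcm(ref$net, part, order = 2L),
                                          seq(0, 100, by = 5)))
  res3 <- cached("mcm3_run", simulate_mcm(derive_mcm(ref$net, part, order = 3L),
                                          seq(0, 100, by = 5)))
  fsp_mean <- ref$moments$mean[, "P"]
  rel2 <- abs(reconstruct_overall_moments(res2)$mean[, "P"] - fsp_mean) /
    pmax(fsp_mean, 1e-8)
  rel3 <- abs(reconstruct_overall_moments(res3)$mean[, "P"] - fsp_mean) /
    pmax(fsp_mean, 1e-8)
  expect_lt(max(rel2[-1L]), 0.02)
  expect_lt(max(rel3[-1L]), 0.02)
  # higher conditional order is at least as accurate near steady state
  expect_lte(rel3[21L], rel2[21L])
})

test_that("total-variance decomposition identities hold in reconstruction", {
  ref <- three_stage_reference()
  part <- partition_species(ref$net)
  res <- cached("mcm2_run", simulate_mcm(derive_mcm(ref$net, part, order = 2L),
                                         seq(0, 100, by = 5)))
  ov <- reconstruct_overall_moments(res)
  k <- 11L
  # unconditional mean = sum_y p(y) E[z|y]
  manual <- 0
  for (mi in 1:2) {
    manual <- manual + res$p[k, mi] * res$conditional[[mi]][k, "0_1"]
  }
  expect_equal(unname(ov$mean[k, "P"]), unname(manual), tolerance = 1e-9)
  # law of total variance for the protein
  within <- between <- 0
  for (mi in 1:2) {
    cmean <- res$conditional[[mi]][k, "0_1"]
    cvar <- res$conditional[[mi]][k, "0_2"] - cmean^2
    within <- within + res$p[k, mi] * cvar
    between <- between + res$p[k, mi] * (cmean - ov$mean[k, "P"])^2
  }
  expect_equal(unname(ov$cov[k, "P", "P"]), unname(within + between),
               tolerance = 1e-9)
})

test_that("a frozen active promoter reduces conditional to plain moments", {
  net <- make_fixture("three_stage_gene_expression",
                      overrides = list(k_on = 0, k_off = 0, k_fb = 0))
  net$species[[1L]]$initial <- 0L   # start in the on state
  net$species[[2L]]$initial <- 1L
  part <- partition_species(net)
  res <- simulate_mcm(derive_mcm(net, part, order = 2L), c(0, 10))
  on_col <- grep("G_on=1", colnames(res$p))
  expect_equal(unname(res$p[2L, on_col]), 1, tolerance = 1e-9)
  # reduced network: constitutive transcription of M, translation to P
  reduced <- reaction_network(
    species = list(species("M", initial = 0), species("P", initial = 0)),
    reactions = list(
      reaction(products = c(M = 1), rate = "k_m", kinetics = "mass_action"),
      reaction(reactants = c(M = 1), products = c(M = 1, P = 1),
               rate = "k_p", kinetics = "mass_action"),
      reaction(reactants = c(M = 1), rate = "gamma_m", kinetics = "mass_action"),
      reaction(reactants = c(P = 1), rate = "gamma_p", kinetics = "mass_action")),
    parameters = net$parameters[c("k_m", "k_p", "gamma_m", "gamma_p")])
  mm <- simulate_moments(derive_moment_equations(reduced, 2L), c(0, 10))
  cond <- res$conditional[[on_col]]
  expect_equal(unname(cond[2L, "1_0"]), unname(mm$mean[2L, "M"]), tolerance = 1e-6)
  expect_equal(unname(cond[2L, "0_1"]), unname(mm$mean[2L, "P"]), tolerance = 1e-6)
  expect_equal(unname(cond[2L, "0_2"] - cond[2L, "0_1"]^2),
               unname(mm$cov[2L, "P", "P"]), tolerance = 1e-5)
})

test_that("the normalized DAE view agrees with the weighted ODE form", {
  net3 <- make_fixture("three_stage_gene_expression")
  part <- partition_species(net3)
  mcm <- derive_mcm(net3, part, order = 2L)
  resW <- simulate_mcm(mcm, c(0, 5, 20), p0 = c(0.5, 0.5))
  resD <- simulate_mcm(mcm, c(0, 5, 20), p0 = c(0.5, 0.5),
                       form = "normalized_dae")
  expect_lt(max(abs(resW$weighted - resD$weighted)), 1e-5)
  # the DAE view needs strictly positive initial mode probabilities
  expect_error(simulate_mcm(mcm, c(0, 5), form = "normalized_dae"), "positive")
})

test_that("conditional moments are reported only where the mode has mass", {
  net3 <- make_fixture("three_stage_gene_expression")
  part <- partition_species(net3)
  res <- simulate_mcm(derive_mcm(net3, part, order = 2L), c(0, 5))
  off_col <- grep("G_on=1", colnames(res$p))
  # at t = 0 the on-mode has zero probability: conditional moments absent
  expect_true(all(is.na(res$conditional[[off_col]][1L, ])))
  expect_false(anyNA(res$conditional[[off_col]][2L, ]))
  # export table carries mode labels and quantities
  tab <- mcm_to_table(res)
  expect_setequal(unique(tab$quantity),
                  c("probability", paste0("cond_moment_",
                                          colnames(res$conditional[[1L]]))))
})
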