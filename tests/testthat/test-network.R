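test_that("all built-in fixtures validate cleanly and have the documented shape", {
  shapes <- list(birth_death = c(1L, 2L), dimerization = c(1L, 2L),
                 three_stage_gene_expression = c(4L, 7L),
                 timedep_birth = c(1L, 1L), two_compartment_chain = c(8L, 8L))
  for (fx in names(shapes)) {
    net <- make_fixture(fx)
    expect_equal(nrow(validate_network(net)), 0L, info = fx)
    expect_equal(dim(stoichiometry_matrix(net)), shapes[[fx]], info = fx)
  }
  # the chain fixture carries 5 intermediate species and a time-dependent input
  chain <- make_fixture("two_compartment_chain")
  expect_length(grep("^npS", vapply(chain$species, `[[`, character(1L), "name")), 5L)
  expect_length(chain$inputs, 1L)
  expect_true("t" %in% all.vars(chain$inputs[[1L]]$expression))
  expect_error(make_fixture("no_such_model"))
})

test_that("validation reports one diagnostic per violation instead of erroring", {
  net <- reaction_network(
    species = list(species("X", initial = -1)),
    reactions = list(reaction(products = c(X = 1), rate = ~k * q)),
    parameters = c(k = 1))
  d <- validate_network(net)
  expect_s3_class(d, "data.frame")
  expect_equal(nrow(d), 2L)
  expect_true(any(grepl("q", d$message)))          # undeclared symbol named
  expect_true(any(grepl("negative", d$message)))   # negative initial amount
})

test_that("stoichiometry columns are products minus reactants", {
  bd <- make_fixture("birth_death")
  expect_identical(unname(stoichiometry_matrix(bd)), matrix(c(1L, -1L), 1L))
  dim_net <- make_fixture("dimerization")
  expect_identical(unname(stoichiometry_matrix(dim_net)[1L, ]), c(1L, -2L))
  # promoter conservation: G_off + G_on unchanged by every reaction
  S3 <- stoichiometry_matrix(make_fixture("three_stage_gene_expression"))
  expect_true(all(S3["G_off", ] + S3["G_on", ] == 0L))
})

test_that("mass-action propensities follow the combinatorial convention", {
  # 2X -> 0 with stochastic constant c gives c * x * (x-1) / 2
  rxn <- reaction(reactants = c(X = 2), rate = "c", kinetics = "mass_action")
  net <- reaction_network(species = list(species("X", initial = 5)),
                          reactions = list(rxn), parameters = c(c = 3))
  a <- cmekit:::propensity_expr(net, 1L)
  for (x in 0:6) {
    expect_equal(eval(a, list(X = x, c = 3)), 3 * choose(x, 2))
  }
})

test_that("parameter overrides replace fixture defaults and reject unknowns", {
  net <- make_fixture("birth_death", overrides = list(k = 2.5))
  expect_equal(unname(net$parameters["k"]), 2.5)
  expect_equal(unname(net$parameters["gamma"]), 1)
  expect_error(make_fixture("birth_death", overrides = list(zeta = 1)),
               "unknown fixture parameter")
})

test_that("native YAML configuration round-trips the model definition", {
  net <- make_fixture("two_compartment_chain")
  f <- withr::local_tempfile(fileext = ".yaml")
  write_network_config(net, f)
  net2 <- read_network_config(f)
  expect_identical(stoichiometry_matrix(net2), stoichiometry_matrix(net))
  expect_equal(net2$parameters[names(net$parameters)], net$parameters)
  for (j in seq_along(net$reactions)) {
    a1 <- eval_on_states(cmekit:::propensity_expr(net, j), net)
    a2 <- eval_on_states(cmekit:::propensity_expr(net2, j), net)
    expect_equal(a2, a1, tolerance = 1e-12)
  }
})

test_that("SBML export/import round-trips stoichiometry and propensity values", {
  for (fx in c("birth_death", "timedep_birth", "three_stage_gene_expression")) {
    net <- make_fixture(fx)
    f <- withr::local_tempfile(fileext = ".xml")
    export_sbml(net, f)
    net2 <- import_sbml(f)
    expect_identical(unname(stoichiometry_matrix(net2)),
                     unname(stoichiometry_matrix(net)), info = fx)
    for (j in seq_len(length(net$reactions))) {
      a1 <- eval_on_states(cmekit:::propensity_expr(net, j), net, n = 100)
      a2 <- eval_on_states(cmekit:::propensity_expr(net2, j), net2, n = 100)
      expect_equal(a2, a1, tolerance = 1e-9, info = paste(fx, j))
    }
  }
})

test_that("reversible SBML reactions split into an irreversible pair", {
  rev_xml <- paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="m"><listOfCompartments>',
    '<compartment id="cell" size="1" constant="true"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="A" compartment="cell" initialAmount="5" hasOnlySubstanceUnits="true" boundaryCondition="false" constant="false"/>',
    '<species id="B" compartment="cell" initialAmount="0" hasOnlySubstanceUnits="true" boundaryCondition="false" constant="false"/>',
    '</listOfSpecies><listOfParameters>',
    '<parameter id="kf" value="2" constant="true"/>',
    '<parameter id="kr" value="1" constant="true"/>',
    '</listOfParameters><listOfReactions>',
    '<reaction id="r1" reversible="true">',
    '<listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B" stoichiometry="1" constant="true"/></listOfProducts>',
    '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<apply><minus/><apply><times/><ci>kf</ci><ci>A</ci></apply>',
    '<apply><times/><ci>kr</ci><ci>B</ci></apply></apply>',
    '</math></kineticLaw></reaction></listOfReactions></model></sbml>')
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(rev_xml, f)
  net <- import_sbml(f)
  S <- stoichiometry_matrix(net)
  expect_equal(ncol(S), 2L)
  expect_identical(unname(S[, 1L]), -unname(S[, 2L]))  # opposite state changes
  # a reaction without kineticLaw is an unsupported model, named in the error
  f2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(sub("<kineticLaw>.*</kineticLaw>", "", rev_xml), f2)
  expect_error(import_sbml(f2), "no kinetic law")
  # garbage is a parse failure
  f3 <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model", f3)
  expect_error(import_sbml(f3), "parse failure")
})
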