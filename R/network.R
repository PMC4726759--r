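#' Define a compartment
#'
#' Compartments carry the system-size parameter Omega used by the system size
#' expansion: the volume is a dimensionless scale, not a physical litre.
#'
#' @param name compartment identifier (a syntactic R name)
#' @param volume positive real; system size Omega for the species it contains
#' @return a `ck_compartment` object
#' @export
compartment <- function(name, volume = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  structure(list(name = name, volume = volume), class = "ck_compartment")
}

#' Define a chemical species
#'
#' @param name species identifier; becomes the symbol used in propensity and
#'   observable expressions
#' @param compartment name of the compartment the species lives in
#' @param initial initial molecule count (nonnegative integer)
#' @param copy_class abundance class hint for the method of conditional
#'   moments partition: `"low_copy"`, `"high_copy"` or `"auto"`
#' @return a `ck_species` object
#' @export
species <- function(name, compartment = "cell", initial = 0,
                    copy_class = c("auto", "low_copy", "high_copy")) {
  copy_class <- match.arg(copy_class)
  structure(list(name = name, compartment = compartment,
                 initial = initial, copy_class = copy_class),
            class = "ck_species")
}

#' Define a reaction
#'
#' Mass-action reactions take `rate` as the stochastic rate constant `c`; the
#' propensity is generated with the combinatorial convention
#' `a(x) = c * prod_i choose(x_i, r_i)`, so `2X -> 0` yields `c*x*(x-1)/2`.
#' General reactions take `rate` as an explicit propensity expression in the
#' species, parameters, inputs and time `t`.
#'
#' @param reactants named integer vector of reactant stoichiometries
#' @param products named integer vector of product stoichiometries
#' @param rate rate constant name (mass action) or propensity expression
#'   (general); character, formula or language
#' @param kinetics `"mass_action"` or `"general"`
#' @param delay fixed completion delay (time units); the state change is
#'   applied `delay` after the firing time (modified next-reaction method only)
#' @param name optional reaction label
#' @return a `ck_reaction` object
#' @export
reaction <- function(reactants = c(), products = c(), rate,
                     kinetics = c("general", "mass_action"), delay = 0,
                     name = NULL) {
  kinetics <- match.arg(kinetics)
  as_sto <- function(v) {
    if (length(v) == 0L) return(integer(0L))
    stopifnot(!is.null(names(v)), all(v == round(v)), all(v >= 0))
    storage.mode(v) <- "integer"
    v[v > 0L]
  }
  structure(list(reactants = as_sto(reactants), products = as_sto(products),
                 rate = as_lang(rate), kinetics = kinetics,
                 delay = delay, name = name),
            class = "ck_reaction")
}

#' Define a time-dependent input signal
#'
#' Inputs describe experimental conditions as scalar functions of time `t`
#' and the parameters; input names may be referenced inside propensities and
#' are inlined before any derivation.
#'
#' @param name input identifier
#' @param expression expression in `t` and parameters
#' @return a `ck_input` object
#' @export
input_signal <- function(name, expression) {
  structure(list(name = name, expression = as_lang(expression)),
            class = "ck_input")
}

#' Define an observable
#'
#' @param name observable identifier
#' @param expression expression in species amounts and parameters
#' @return a `ck_observable` object
#' @export
observable <- function(name, expression) {
  structure(list(name = name, expression = as_lang(expression)),
            class = "ck_observable")
}

#' Assemble a reaction network
#'
#' The single model definition from which every downstream description (SSA,
#' FSP, moment equations, system size expansion, conditional moments,
#' sensitivities) is derived.
#'
#' @param species list of [species()] objects (defines the state ordering)
#' @param reactions list of [reaction()] objects
#' @param parameters named numeric vector of default parameter values
#' @param compartments list of [compartment()] objects; a default unit-volume
#'   `"cell"` compartment is created if missing
#' @param inputs list of [input_signal()] objects
#' @param observables list of [observable()] objects
#' @param name network label
#' @return a `ck_network` object
#' @export
reaction_network <- function(species, reactions, parameters = c(),
                             compartments = NULL, inputs = list(),
                             observables = list(), name = "network") {
  if (is.null(compartments)) compartments <- list(compartment("cell", 1))
  net <- structure(list(name = name,
                        species = species, reactions = reactions,
                        parameters = parameters, compartments = compartments,
                        inputs = inputs, observables = observables),
                   class = "ck_network")
  net
}

species_names <- function(net) vapply(net$species, `[[`, character(1L), "name")
n_species <- function(net) length(net$species)
n_reactions <- function(net) length(net$reactions)

initial_state <- function(net) {
  x0 <- vapply(net$species, `[[`, numeric(1L), "initial")
  names(x0) <- species_names(net)
  x0
}

#' @export
print.ck_network <- function(x, ...) {
  cat("<ck_network> ", x$name, ": ", n_species(x), " species, ",
      n_reactions(x), " reactions, ", length(x$parameters), " parameters\n",
      sep = "")
  invisible(x)
}

# Mass-action propensity c * prod choose(x_i, r_i), expanded to a polynomial
# expression (falling factorial over factorial).
mass_action_propensity <- function(rate, reactants) {
  prop <- rate
  for (sp in names(reactants)) {
    r <- reactants[[sp]]
    for (k in 0:(r - 1L)) {
      fac <- if (k == 0L) as.symbol(sp) else call("-", as.symbol(sp), k)
      prop <- e_mul(prop, fac)
    }
    if (r > 1L) prop <- e_div(prop, factorial(r))
  }
  prop
}

# Propensity expression of reaction j with input signals inlined.
propensity_expr <- function(net, j) {
  rxn <- net$reactions[[j]]
  prop <- if (rxn$kinetics == "mass_action") {
    mass_action_propensity(rxn$rate, rxn$reactants)
  } else {
    rxn$rate
  }
  inline_inputs(prop, net)
}

inline_inputs <- function(e, net) {
  if (length(net$inputs) == 0L) return(e)
  map <- lapply(net$inputs, `[[`, "expression")
  names(map) <- vapply(net$inputs, `[[`, character(1L), "name")
  fold_expr(subst_expr(e, map))
}

# All symbols a model expression may legally reference.
declared_symbols <- function(net) {
  c(species_names(net), names(net$parameters),
    vapply(net$inputs, `[[`, character(1L), "name"),
    vapply(net$compartments, `[[`, character(1L), "name"),
    "t", "pi")
}

#' Validate a reaction network
#'
#' Checks the structural invariants of the model definition and returns one
#' diagnostic per violation instead of raising errors, so a whole definition
#' can be vetted in one pass.
#'
#' @param net a `ck_network`
#' @return a data frame with columns `element` and `message`; zero rows iff
#'   the network is well formed
#' @export
validate_network <- function(net) {
  bad <- list()
  note <- function(element, message) {
    bad[[length(bad) + 1L]] <<- data.frame(element = element, message = message)
  }
  sn <- species_names(net)
  if (anyDuplicated(sn)) note("species", "duplicated species names")
  if (length(net$species) < 1L) note("species", "network needs at least one species")
  if (length(net$reactions) < 1L) note("reactions", "network needs at least one reaction")
  cn <- vapply(net$compartments, `[[`, character(1L), "name")
  if (anyDuplicated(cn)) note("compartments", "duplicated compartment names")
  for (cm in net$compartments) {
    if (!is.numeric(cm$volume) || cm$volume <= 0) {
      note(cm$name, "compartment volume must be positive")
    }
  }
  for (sp in net$species) {
    if (!(sp$compartment %in% cn)) {
      note(sp$name, paste0("unknown compartment '", sp$compartment, "'"))
    }
    if (sp$initial < 0) note(sp$name, "negative initial amount")
    if (sp$initial != round(sp$initial)) note(sp$name, "non-integer initial amount")
    if (make.names(sp$name) != sp$name) note(sp$name, "species name is not a syntactic name")
    if (sp$name %in% c("t", "pi")) note(sp$name, "species name shadows a reserved symbol")
  }
  ok_syms <- declared_symbols(net)
  for (j in seq_along(net$reactions)) {
    rxn <- net$reactions[[j]]
    lab <- if (is.null(rxn$name)) paste0("reaction ", j) else rxn$name
    for (sp in c(names(rxn$reactants), names(rxn$products))) {
      if (!(sp %in% sn)) note(lab, paste0("unknown species '", sp, "' in stoichiometry"))
    }
    unknown <- setdiff(all.vars(propensity_expr(net, j)), ok_syms)
    if (length(unknown)) {
      note(lab, paste0("propensity references undeclared symbol(s): ",
                       paste(unknown, collapse = ", ")))
    }
    if (rxn$delay < 0) note(lab, "negative delay")
  }
  for (ob in net$observables) {
    unknown <- setdiff(all.vars(ob$expression), ok_syms)
    if (length(unknown)) {
      note(ob$name, paste0("observable references undeclared symbol(s): ",
                           paste(unknown, collapse = ", ")))
    }
  }
  for (ip in net$inputs) {
    unknown <- setdiff(all.vars(ip$expression), c(names(net$parameters), "t", "pi"))
    if (length(unknown)) {
      note(ip$name, paste0("input references undeclared symbol(s): ",
                           paste(unknown, collapse = ", ")))
    }
  }
  if (length(bad) == 0L) {
    return(data.frame(element = character(0L), message = character(0L)))
  }
  do.call(rbind, bad)
}

#' Stoichiometry matrix
#'
#' @param net a `ck_network`
#' @return integer matrix (`n_s` x `n_r`); column `j` is the state-change
#'   vector of reaction `j` (products minus reactants)
#' @export
stoichiometry_matrix <- function(net) {
  sn <- species_names(net)
  S <- matrix(0L, nrow = length(sn), ncol = n_reactions(net),
              dimnames = list(sn, NULL))
  for (j in seq_along(net$reactions)) {
    rxn <- net$reactions[[j]]
    for (sp in names(rxn$reactants)) S[sp, j] <- S[sp, j] - rxn$reactants[[sp]]
    for (sp in names(rxn$products)) S[sp, j] <- S[sp, j] + rxn$products[[sp]]
  }
  S
}

# Conservation laws: rows w (nonnegative, integer up to scale) with w'S = 0,
# from the left null space of the stoichiometry matrix.
conservation_laws <- function(net, tol = 1e-9) {
  S <- stoichiometry_matrix(net)
  M <- t(S)                               # left null space of S = null(t(S))
  sv <- svd(M, nv = ncol(M))
  d_full <- c(sv$d, rep(0, ncol(M) - length(sv$d)))
  null_idx <- which(d_full < tol * max(d_full, 1))
  W <- sv$v[, null_idx, drop = FALSE]
  laws <- list()
  for (k in seq_len(ncol(W))) {
    w <- W[, k]
    w[abs(w) < tol] <- 0
    if (all(w <= tol)) w <- -w
    if (any(w < -tol)) next            # keep only nonnegative laws (bounds)
    nz <- w[w > tol]
    if (length(nz) == 0L) next
    w <- w / min(nz)
    if (max(abs(w - round(w))) > 1e-6) next
    w <- round(w)
    laws[[length(laws) + 1L]] <- list(coef = w,
                                      total = sum(w * initial_state(net)))
  }
  laws
}

#' Built-in model fixtures
#'
#' Returns one of the documented study networks. Defaults:
#' \describe{
#'   \item{birth_death}{`0 -> X` at `k = 10`; `X -> 0` at `gamma*x`,
#'     `gamma = 1`; `X(0) = 0`. Linear, Poisson stationary law.}
#'   \item{dimerization}{`0 -> X` at `k1 = 4`; `2X -> 0` with propensity
#'     `k2*x*(x-1)`, `k2 = 0.01` (mass action with stochastic constant
#'     `2*k2`). Nonlinear test case.}
#'   \item{three_stage_gene_expression}{promoter switching
#'     `G_off <-> G_on`, protein-induced activation `G_off + P -> G_on + P`,
#'     transcription `G_on -> G_on + M`, translation `M -> M + P`, and
#'     first-order degradation of `M` and `P`; `G_off(0) = 1`.}
#'   \item{timedep_birth}{`0 -> X` with time-dependent propensity
#'     `b0*(1 + sin(omega*t))`, `b0 = 5`, `omega = 1` (inhomogeneous Poisson
#'     counting process).}
#'   \item{two_compartment_chain}{cytoplasmic activation of `S_c` driven by a
#'     time-dependent input `u(t)`, dimerization of the activated form,
#'     nuclear import, a 5-step linear chain `npS1 ... npS5` modelling
#'     delayed export, and export back to the cytoplasm as monomers.}
#' }
#'
#' @param name fixture name
#' @param overrides named list/vector of parameter overrides
#' @return a validated `ck_network`
#' @export
make_fixture <- function(name = c("birth_death", "dimerization",
                                  "three_stage_gene_expression",
                                  "timedep_birth", "two_compartment_chain"),
                         overrides = NULL) {
  name <- match.arg(name)
  net <- switch(name,
    birth_death = reaction_network(
      name = "birth_death",
      species = list(species("X", initial = 0)),
      reactions = list(
        reaction(products = c(X = 1), rate = "k", kinetics = "mass_action"),
        reaction(reactants = c(X = 1), rate = "gamma", kinetics = "mass_action")),
      parameters = c(k = 10, gamma = 1)),
    dimerization = reaction_network(
      name = "dimerization",
      species = list(species("X", initial = 0)),
      reactions = list(
        reaction(products = c(X = 1), rate = "k1", kinetics = "mass_action"),
        # stochastic constant 2*k2 with the choose(x,2) convention gives the
        # documented propensity k2*x*(x-1)
        reaction(reactants = c(X = 2), rate = ~2 * k2, kinetics = "mass_action")),
      parameters = c(k1 = 4, k2 = 0.01)),
    three_stage_gene_expression = reaction_network(
      name = "three_stage_gene_expression",
      species = list(species("G_off", initial = 1, copy_class = "low_copy"),
                     species("G_on", initial = 0, copy_class = "low_copy"),
                     species("M", initial = 0),
                     species("P", initial = 0)),
      reactions = list(
        reaction(reactants = c(G_off = 1), products = c(G_on = 1),
                 rate = "k_on", kinetics = "mass_action"),
        reaction(reactants = c(G_off = 1, P = 1), products = c(G_on = 1, P = 1),
                 rate = "k_fb", kinetics = "mass_action"),
        reaction(reactants = c(G_on = 1), products = c(G_off = 1),
                 rate = "k_off", kinetics = "mass_action"),
        reaction(reactants = c(G_on = 1), products = c(G_on = 1, M = 1),
                 rate = "k_m", kinetics = "mass_action"),
        reaction(reactants = c(M = 1), products = c(M = 1, P = 1),
                 rate = "k_p", kinetics = "mass_action"),
        reaction(reactants = c(M = 1), rate = "gamma_m", kinetics = "mass_action"),
        reaction(reactants = c(P = 1), rate = "gamma_p", kinetics = "mass_action")),
      parameters = c(k_on = 0.05, k_fb = 0.01, k_off = 0.1,
                     k_m = 5, k_p = 2, gamma_m = 1, gamma_p = 0.5)),
    timedep_birth = reaction_network(
      name = "timedep_birth",
      species = list(species("X", initial = 0)),
      reactions = list(
        reaction(products = c(X = 1), rate = ~b0 * (1 + sin(omega * t)),
                 kinetics = "general")),
      parameters = c(b0 = 5, omega = 1)),
    two_compartment_chain = reaction_network(
      name = "two_compartment_chain",
      compartments = list(compartment("cytoplasm", 1), compartment("nucleus", 1)),
      species = list(species("S_c", "cytoplasm", initial = 50),
                     species("pS", "cytoplasm", initial = 0),
                     species("pSd", "cytoplasm", initial = 0),
                     species("npS1", "nucleus", initial = 0),
                     species("npS2", "nucleus", initial = 0),
                     species("npS3", "nucleus", initial = 0),
                     species("npS4", "nucleus", initial = 0),
                     species("npS5", "nucleus", initial = 0)),
      inputs = list(input_signal("u", ~t * exp(-0.25 * t))),
      reactions = list(
        reaction(reactants = c(S_c = 1), products = c(pS = 1),
                 rate = ~k1 * u * S_c, kinetics = "general"),
        reaction(reactants = c(pS = 2), products = c(pSd = 1),
                 rate = ~2 * k2, kinetics = "mass_action"),
        reaction(reactants = c(pSd = 1), products = c(npS1 = 1),
                 rate = "k3", kinetics = "mass_action"),
        reaction(reactants = c(npS1 = 1), products = c(npS2 = 1),
                 rate = "k4", kinetics = "mass_action"),
        reaction(reactants = c(npS2 = 1), products = c(npS3 = 1),
                 rate = "k4", kinetics = "mass_action"),
        reaction(reactants = c(npS3 = 1), products = c(npS4 = 1),
                 rate = "k4", kinetics = "mass_action"),
        reaction(reactants = c(npS4 = 1), products = c(npS5 = 1),
                 rate = "k4", kinetics = "mass_action"),
        reaction(reactants = c(npS5 = 1), products = c(S_c = 2),
                 rate = "k4", kinetics = "mass_action")),
      parameters = c(k1 = 0.04, k2 = 0.05, k3 = 0.2, k4 = 0.3),
      observables = list(observable("pSd_obs", ~pSd))))
  if (!is.null(overrides)) {
    overrides <- unlist(overrides)
    unknown <- setdiff(names(overrides), names(net$parameters))
    if (length(unknown)) stop("unknown fixture parameter(s): ",
                              paste(unknown, collapse = ", "))
    net$parameters[names(overrides)] <- overrides
  }
  net
}
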