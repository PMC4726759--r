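# SBML Level 2/3 core import and export over xml2.  Scope: compartments,
# species (amount-based), global + reaction-local parameters, irreversible
# and reversible reactions with kinetic laws in a MathML subset
# (+ - * / ^, elementary functions, <ci>, <cn>, the time <csymbol>).
# Events, rules and hierarchical composition are out of scope.  Reversible
# reactions are split into a forward/backward pair by the top-level
# difference of their kinetic law; local parameters are promoted to global
# parameters with reaction-prefixed names so that a single flat parameter
# vector feeds the sensitivity machinery.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

## ---- MathML <-> R expressions ---------------------------------------------

mathml_to_expr <- function(node) {
  name <- xml2::xml_name(node)
  if (name == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1L) stop("malformed <math> element")
    return(mathml_to_expr(kids[[1L]]))
  }
  if (name == "ci") return(as.symbol(trimws(xml2::xml_text(node))))
  if (name == "cn") {
    kids <- xml2::xml_children(node)
    if (length(kids) > 0L && any(xml2::xml_name(kids) == "sep")) {
      txt <- strsplit(trimws(xml2::xml_text(node)), "[[:space:]]+")[[1L]]
      return(as.numeric(txt[1L]) * 10^as.numeric(txt[2L]))
    }
    return(as.numeric(trimws(xml2::xml_text(node))))
  }
  if (name == "csymbol") {
    url <- xml2::xml_attr(node, "definitionURL")
    if (!is.na(url) && grepl("time", url)) return(as.symbol("t"))
    return(as.symbol(trimws(xml2::xml_text(node))))
  }
  if (name == "pi") return(pi)
  if (name == "exponentiale") return(exp(1))
  if (name != "apply") stop("unsupported MathML element <", name, ">")
  kids <- xml2::xml_children(node)
  op <- xml2::xml_name(kids[[1L]])
  args <- lapply(kids[-1L], mathml_to_expr)
  fold <- function(fun, args) Reduce(function(a, b) call(fun, a, b), args)
  switch(op,
    plus = if (length(args) == 0L) 0 else fold("+", args),
    times = if (length(args) == 0L) 1 else fold("*", args),
    minus = if (length(args) == 1L) call("-", args[[1L]]) else fold("-", args),
    divide = fold("/", args),
    power = fold("^", args),
    sin = call("sin", args[[1L]]),
    cos = call("cos", args[[1L]]),
    tan = call("tan", args[[1L]]),
    exp = call("exp", args[[1L]]),
    ln = call("log", args[[1L]]),
    log = if (length(args) == 1L) call("log", args[[1L]], 10) else
      stop("unsupported MathML log with explicit base"),
    root = call("sqrt", args[[length(args)]]),
    abs = call("abs", args[[1L]]),
    stop("unsupported MathML operator <", op, ">"))
}

expr_to_mathml <- function(e, parent) {
  if (is_num1(e)) {
    xml2::xml_add_child(parent, "cn", format(e, digits = 17))
    return(invisible())
  }
  if (is.symbol(e)) {
    if (identical(as.character(e), "t")) {
      cs <- xml2::xml_add_child(parent, "csymbol", "t", encoding = "text",
        definitionURL = "http://www.sbml.org/sbml/symbols/time")
    } else if (identical(as.character(e), "pi")) {
      xml2::xml_add_child(parent, "pi")
    } else {
      xml2::xml_add_child(parent, "ci", as.character(e))
    }
    return(invisible())
  }
  if (!is.call(e)) stop("cannot serialize '", deparse_one(e), "' to MathML")
  op <- as.character(e[[1L]])
  args <- as.list(e)[-1L]
  if (op == "(") return(expr_to_mathml(args[[1L]], parent))
  tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                "/" = "divide", "^" = "power", sin = "sin", cos = "cos",
                tan = "tan", exp = "exp", log = "ln", sqrt = "root",
                abs = "abs",
                stop("cannot serialize function '", op, "' to MathML"))
  ap <- xml2::xml_add_child(parent, "apply")
  xml2::xml_add_child(ap, tag)
  for (a in args) expr_to_mathml(a, ap)
  invisible()
}

## ---- export ----------------------------------------------------------------

#' Export a reaction network to SBML
#'
#' Writes SBML Level 3 Version 1 core.  Mass-action propensities are
#' expanded to their combinatorial polynomial form and input signals are
#' inlined, so the kinetic laws are self-contained; on re-import all
#' reactions come back with general kinetics (the canonical SBML round-trip
#' preserves the stoichiometry and the propensity values, not the
#' mass-action tagging).
#'
#' @param net a `ck_network`
#' @param path output file
#' @return `path`, invisibly
#' @export
export_sbml <- function(net, path) {
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS, level = "3", version = "1")
  model <- xml2::xml_add_child(doc, "model", id = make.names(net$name))
  lc <- xml2::xml_add_child(model, "listOfCompartments")
  for (cm in net$compartments) {
    xml2::xml_add_child(lc, "compartment", id = cm$name,
                        size = format(cm$volume, digits = 17),
                        spatialDimensions = "3", constant = "true")
  }
  ls <- xml2::xml_add_child(model, "listOfSpecies")
  for (sp in net$species) {
    xml2::xml_add_child(ls, "species", id = sp$name,
                        compartment = sp$compartment,
                        initialAmount = format(sp$initial, digits = 17),
                        hasOnlySubstanceUnits = "true",
                        boundaryCondition = "false", constant = "false")
  }
  lp <- xml2::xml_add_child(model, "listOfParameters")
  for (pn in names(net$parameters)) {
    xml2::xml_add_child(lp, "parameter", id = pn,
                        value = format(net$parameters[[pn]], digits = 17),
                        constant = "true")
  }
  lr <- xml2::xml_add_child(model, "listOfReactions")
  for (j in seq_len(n_reactions(net))) {
    rxn <- net$reactions[[j]]
    rid <- if (is.null(rxn$name)) paste0("reaction_", j) else make.names(rxn$name)
    rnode <- xml2::xml_add_child(lr, "reaction", id = rid,
                                 reversible = "false")
    if (length(rxn$reactants)) {
      lre <- xml2::xml_add_child(rnode, "listOfReactants")
      for (sp in names(rxn$reactants)) {
        xml2::xml_add_child(lre, "speciesReference", species = sp,
                            stoichiometry = as.character(rxn$reactants[[sp]]),
                            constant = "true")
      }
    }
    if (length(rxn$products)) {
      lpr <- xml2::xml_add_child(rnode, "listOfProducts")
      for (sp in names(rxn$products)) {
        xml2::xml_add_child(lpr, "speciesReference", species = sp,
                            stoichiometry = as.character(rxn$products[[sp]]),
                            constant = "true")
      }
    }
    kl <- xml2::xml_add_child(rnode, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math", xmlns = MATHML_NS)
    expr_to_mathml(propensity_expr(net, j), math)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

## ---- import ----------------------------------------------------------------

#' Import a reaction network from SBML
#'
#' Reads SBML Level 2 or 3 core models with kinetic laws.  Reversible
#' reactions are split into two irreversible reactions using the top-level
#' difference of their kinetic law; reaction-local parameters are promoted
#' to global parameters named `<reaction id>_<parameter id>`; non-integer
#' initial amounts are rounded with a warning.
#'
#' @param path SBML file
#' @return a `ck_network`
#' @export
import_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("SBML parse failure in '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) stop("SBML parse failure: no <model> element")
  comps <- lapply(xml2::xml_find_all(model, ".//listOfCompartments/compartment"),
                  function(nd) {
    size <- xml2::xml_attr(nd, "size")
    compartment(xml2::xml_attr(nd, "id"),
                if (is.na(size)) 1 else as.numeric(size))
  })
  if (length(comps) == 0L) comps <- list(compartment("cell", 1))
  comp_sizes <- vapply(comps, `[[`, numeric(1L), "volume")
  names(comp_sizes) <- vapply(comps, `[[`, character(1L), "name")
  sps <- lapply(xml2::xml_find_all(model, ".//listOfSpecies/species"),
                function(nd) {
    id <- xml2::xml_attr(nd, "id")
    cmp <- xml2::xml_attr(nd, "compartment")
    if (is.na(cmp)) cmp <- names(comp_sizes)[1L]
    amt <- xml2::xml_attr(nd, "initialAmount")
    if (is.na(amt)) {
      conc <- xml2::xml_attr(nd, "initialConcentration")
      amt <- if (is.na(conc)) 0 else as.numeric(conc) * comp_sizes[[cmp]]
    } else {
      amt <- as.numeric(amt)
    }
    if (abs(amt - round(amt)) > 1e-9) {
      warning("rounding non-integer initial amount of species '", id,
              "' (", amt, ") to ", round(amt))
    }
    species(id, compartment = cmp, initial = round(amt))
  })
  pars <- c()
  for (nd in xml2::xml_find_all(model, ".//listOfParameters/parameter")) {
    # global parameters only: local ones sit under kineticLaw
    if (length(xml2::xml_find_first(nd, "ancestor::kineticLaw")) > 0 &&
        !inherits(xml2::xml_find_first(nd, "ancestor::kineticLaw"), "xml_missing")) next
    v <- xml2::xml_attr(nd, "value")
    pars[[xml2::xml_attr(nd, "id")]] <- if (is.na(v)) 0 else as.numeric(v)
  }
  rxns <- list()
  for (nd in xml2::xml_find_all(model, ".//listOfReactions/reaction")) {
    rid <- xml2::xml_attr(nd, "id")
    sto <- function(xpath) {
      refs <- xml2::xml_find_all(nd, xpath)
      out <- integer(0L)
      for (rf in refs) {
        s <- xml2::xml_attr(rf, "stoichiometry")
        s <- if (is.na(s)) 1L else as.integer(round(as.numeric(s)))
        sp <- xml2::xml_attr(rf, "species")
        out[sp] <- (if (sp %in% names(out)) out[[sp]] else 0L) + s
      }
      out
    }
    reactants <- sto("./listOfReactants/speciesReference")
    products <- sto("./listOfProducts/speciesReference")
    kl <- xml2::xml_find_first(nd, "./kineticLaw")
    if (inherits(kl, "xml_missing")) {
      stop("unsupported SBML model: reaction '", rid, "' has no kinetic law")
    }
    math <- xml2::xml_find_first(kl, "./math")
    if (inherits(math, "xml_missing")) {
      stop("unsupported SBML model: reaction '", rid,
           "' has a kinetic law without <math>")
    }
    rate <- mathml_to_expr(math)
    # promote local parameters with reaction-prefixed names
    locals <- xml2::xml_find_all(kl, ".//parameter | .//localParameter")
    if (length(locals)) {
      ren <- list()
      for (lp in locals) {
        lid <- xml2::xml_attr(lp, "id")
        v <- xml2::xml_attr(lp, "value")
        gname <- paste0(rid, "_", lid)
        pars[[gname]] <- if (is.na(v)) 0 else as.numeric(v)
        ren[[lid]] <- as.symbol(gname)
      }
      rate <- subst_expr(rate, ren)
    }
    reversible <- identical(xml2::xml_attr(nd, "reversible"), "true")
    if (reversible) {
      if (!(is.call(rate) && identical(as.character(rate[[1L]]), "-") &&
            length(rate) == 3L)) {
        stop("unsupported SBML model: reversible reaction '", rid,
             "' has a kinetic law that is not a top-level difference; ",
             "cannot split into irreversible pair")
      }
      rxns[[length(rxns) + 1L]] <- reaction(reactants, products,
                                            rate = rate[[2L]],
                                            name = paste0(rid, "_fwd"))
      rxns[[length(rxns) + 1L]] <- reaction(products, reactants,
                                            rate = rate[[3L]],
                                            name = paste0(rid, "_rev"))
    } else {
      rxns[[length(rxns) + 1L]] <- reaction(reactants, products, rate = rate,
                                            name = rid)
    }
  }
  mid <- xml2::xml_attr(model, "id")
  net <- reaction_network(species = sps, reactions = rxns, parameters = pars,
                          compartments = comps,
                          name = if (is.na(mid)) "sbml_model" else mid)
  diag <- validate_network(net)
  if (nrow(diag) > 0L) {
    stop("imported SBML model is invalid:\n",
         paste0("  ", diag$element, ": ", diag$message, collapse = "\n"))
  }
  net
}
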