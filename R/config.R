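# Native declarative model definition: a YAML (or JSON) document with
# compartments, species, parameters, inputs, reactions and observables.
# The schema shipped under inst/schema/network.schema.json documents the
# format; read_network_config()/write_network_config() round-trip it.

#' Read a reaction network from a YAML/JSON configuration file
#'
#' @param path configuration file (YAML; JSON is valid YAML)
#' @return a `ck_network`
#' @export
read_network_config <- function(path) {
  doc <- yaml::read_yaml(path)
  network_from_list(doc)
}

network_from_list <- function(doc) {
  stopifnot(!is.null(doc$species), !is.null(doc$reactions))
  comps <- if (is.null(doc$compartments)) {
    list(compartment("cell", 1))
  } else {
    lapply(doc$compartments, function(cm) {
      compartment(cm$name, if (is.null(cm$volume)) 1 else cm$volume)
    })
  }
  sps <- lapply(doc$species, function(sp) {
    species(sp$name,
            compartment = if (is.null(sp$compartment)) comps[[1L]]$name else sp$compartment,
            initial = if (is.null(sp$initial)) 0 else sp$initial,
            copy_class = if (is.null(sp$copy_class)) "auto" else sp$copy_class)
  })
  rxns <- lapply(doc$reactions, function(rx) {
    reaction(reactants = unlist(rx$reactants),
             products = unlist(rx$products),
             rate = rx$rate,
             kinetics = if (is.null(rx$kinetics)) "general" else rx$kinetics,
             delay = if (is.null(rx$delay)) 0 else rx$delay,
             name = rx$name)
  })
  inputs <- lapply(doc$inputs, function(ip) input_signal(ip$name, ip$expression))
  observables <- lapply(doc$observables, function(ob) observable(ob$name, ob$expression))
  net <- reaction_network(species = sps, reactions = rxns,
                          parameters = unlist(doc$parameters),
                          compartments = comps, inputs = inputs,
                          observables = observables,
                          name = if (is.null(doc$name)) "network" else doc$name)
  diag <- validate_network(net)
  if (nrow(diag) > 0L) {
    stop("configuration defines an invalid network:\n",
         paste0("  ", diag$element, ": ", diag$message, collapse = "\n"))
  }
  net
}

#' Write a reaction network to a YAML configuration file
#'
#' @param net a `ck_network`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_network_config <- function(net, path) {
  doc <- list(
    name = net$name,
    compartments = lapply(net$compartments, function(cm) {
      list(name = cm$name, volume = cm$volume)
    }),
    species = lapply(net$species, function(sp) {
      list(name = sp$name, compartment = sp$compartment,
           initial = sp$initial, copy_class = sp$copy_class)
    }),
    parameters = as.list(net$parameters),
    inputs = lapply(net$inputs, function(ip) {
      list(name = ip$name, expression = deparse_one(ip$expression))
    }),
    reactions = lapply(net$reactions, function(rx) {
      out <- list(rate = deparse_one(rx$rate), kinetics = rx$kinetics)
      if (length(rx$reactants)) out$reactants <- as.list(rx$reactants)
      if (length(rx$products)) out$products <- as.list(rx$products)
      if (rx$delay > 0) out$delay <- rx$delay
      if (!is.null(rx$name)) out$name <- rx$name
      out
    }),
    observables = lapply(net$observables, function(ob) {
      list(name = ob$name, expression = deparse_one(ob$expression))
    }))
  yaml::write_yaml(doc, path)
  invisible(path)
}
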