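# Optional SBML import path for the clock stage. A minimal reader for SBML
# Level 3 reaction networks: species, global/local parameters, reactions
# with MathML kinetic laws (plus, minus, times, divide, power, exp, ln) and
# rate rules. Models using events, assignment rules, function definitions
# or compartment volumes other than 1 are outside the supported subset and
# raise an error where detected.

mathml_to_lang <- function(node) {
  name <- xml2::xml_name(node)
  if (name == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (name == "cn") {
    kids <- xml2::xml_children(node)
    if (length(kids) && any(xml2::xml_name(kids) == "sep")) {
      parts <- strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]]
      return(as.numeric(parts[1]) * 10^as.numeric(parts[2]))
    }
    return(as.numeric(trimws(xml2::xml_text(node))))
  }
  if (name == "csymbol") return(as.name("t"))
  if (name == "math") {
    return(mathml_to_lang(xml2::xml_child(node)))
  }
  if (name == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- lapply(kids[-1], mathml_to_lang)
    fun <- switch(op,
                  plus = "+", minus = "-", times = "*", divide = "/",
                  power = "^", exp = "exp", ln = "log",
                  abort(paste0("Unsupported MathML operator: ", op)))
    if (op == "minus" && length(args) == 1) {
      return(call("-", args[[1]]))
    }
    if (op %in% c("exp", "ln")) return(as.call(c(as.name(fun), args)))
    return(Reduce(function(a, b) call(fun, a, b), args))
  }
  abort(paste0("Unsupported MathML node: ", name))
}

xattr <- function(node, attrib, default = NA) {
  v <- xml2::xml_attr(node, attrib)
  if (is.na(v)) default else v
}

parse_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  for (bad in c("event", "assignmentRule", "functionDefinition")) {
    if (length(xml2::xml_find_all(doc, paste0("//", bad)))) {
      abort(paste0("SBML construct not supported: ", bad))
    }
  }
  sp_nodes <- xml2::xml_find_all(doc, "//listOfSpecies/species")
  species <- tibble(
    id = xml2::xml_attr(sp_nodes, "id"),
    initial = as.numeric(vapply(sp_nodes, function(s) {
      xattr(s, "initialConcentration", xattr(s, "initialAmount", "0"))
    }, "")),
    boundary = vapply(sp_nodes, function(s)
      identical(xattr(s, "boundaryCondition", "false"), "true"), TRUE)
  )
  par_nodes <- xml2::xml_find_all(doc, "//model/listOfParameters/parameter")
  params <- setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                     xml2::xml_attr(par_nodes, "id"))
  reactions <- lapply(xml2::xml_find_all(doc, "//listOfReactions/reaction"),
                      function(rx) {
    refs <- function(xp) {
      nodes <- xml2::xml_find_all(rx, xp)
      setNames(as.numeric(vapply(nodes, xattr, "", "stoichiometry",
                                 default = "1")),
               xml2::xml_attr(nodes, "species"))
    }
    kl <- xml2::xml_find_first(rx, "./kineticLaw")
    if (inherits(kl, "xml_missing")) {
      abort("Every reaction needs a kineticLaw in the supported subset.")
    }
    loc_nodes <- xml2::xml_find_all(
      kl, "./listOfLocalParameters/localParameter | ./listOfParameters/parameter")
    locals <- setNames(as.numeric(xml2::xml_attr(loc_nodes, "value")),
                       xml2::xml_attr(loc_nodes, "id"))
    list(reactants = refs("./listOfReactants/speciesReference"),
         products = refs("./listOfProducts/speciesReference"),
         rate = mathml_to_lang(xml2::xml_find_first(kl, "./math")),
         locals = locals)
  })
  rate_rules <- lapply(xml2::xml_find_all(doc, "//listOfRules/rateRule"),
                       function(rr) {
    list(variable = xml2::xml_attr(rr, "variable"),
         rate = mathml_to_lang(xml2::xml_find_first(rr, "./math")))
  })
  list(species = species, params = params, reactions = reactions,
       rate_rules = rate_rules)
}

sbml_derivatives <- function(model) {
  function(t, state, parms) {
    env <- list2env(as.list(c(state, model$params)))
    assign("t", t, envir = env)
    dx <- setNames(numeric(length(state)), names(state))
    for (rx in model$reactions) {
      e <- if (length(rx$locals)) {
        le <- list2env(as.list(rx$locals), parent = env)
        le
      } else env
      v <- eval(rx$rate, e)
      for (s in names(rx$reactants)) dx[s] <- dx[s] - rx$reactants[s] * v
      for (s in names(rx$products)) dx[s] <- dx[s] + rx$products[s] * v
    }
    for (rr in model$rate_rules) {
      dx[rr$variable] <- dx[rr$variable] + eval(rr$rate, env)
    }
    dx[model$species$boundary[match(names(state), model$species$id)]] <- 0
    list(dx)
  }
}

#' Drive the clock stage from an SBML model
#'
#' Reads a (subset of) SBML Level 3, integrates the reaction network with
#' `deSolve::ode`, and exposes the six clock regulator roles through a
#' declared species mapping so the result can be used anywhere a surrogate
#' clock trajectory can.
#'
#' @param path SBML file.
#' @param species_map Named character vector mapping every role in
#'   [clock_species()] to an SBML species id, e.g.
#'   `c(LHY_CCA1 = "cLm", ..., EC = "cEC")`.
#' @param duration Simulation length in hours (>= 48).
#' @param step Output grid step in hours (must divide 24).
#' @param genotype A [genotype()] applied to the mapped trajectory
#'   (knockouts zero a role; modifiers scale it).
#' @param regime Light regime metadata attached to the result (the
#'   supported SBML subset has no light forcing; default constant light).
#' @return A `cbf_clock` tibble with columns `time_h` and the six roles.
#' @export
read_sbml_clock <- function(path, species_map, duration = 72, step = 0.5,
                            genotype = cbfclock::genotype(),
                            regime = light_regime(24)) {
  if (duration < 48) abort("`duration` must be at least 48 h.")
  if (step <= 0 || abs(24 / step - round(24 / step)) > 1e-9) {
    abort("`step` must be positive and divide 24 h evenly.")
  }
  miss <- setdiff(clock_species(), names(species_map))
  if (length(miss)) {
    abort(paste0("`species_map` must map every role; missing: ",
                 toString(miss)))
  }
  model <- parse_sbml(path)
  bad <- setdiff(unname(species_map), model$species$id)
  if (length(bad)) abort(paste0("Mapped species not in the model: ",
                                toString(bad)))
  y0 <- setNames(model$species$initial, model$species$id)
  times <- seq(0, duration, by = step)
  sol <- deSolve::ode(y = y0, times = times, func = sbml_derivatives(model),
                      parms = NULL, method = "lsoda")
  if (attr(sol, "istate")[1] < 0) abort("SBML integration failed.")
  sol <- as.data.frame(sol)
  if (min(as.matrix(sol[unname(species_map)])) < -1e-6) {
    abort("SBML solution has substantially negative abundances.")
  }
  out <- tibble(time_h = sol$time)
  for (role in clock_species()) {
    out[[role]] <- pmax(0, sol[[species_map[[role]]]])
  }
  traj <- new_clock_trajectory(out, as_regime(regime),
                               cbfclock::genotype(), NULL)
  apply_genotype(traj, genotype)
}
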