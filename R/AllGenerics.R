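#' @rdname StoichiometricModel-class
#' @param x,object a \linkS4class{StoichiometricModel}.
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' @rdname StoichiometricModel-class
#' @export
setGeneric("metabolites", function(x) standardGeneric("metabolites"))

#' @rdname StoichiometricModel-class
#' @export
setGeneric("exchangeables", function(x) standardGeneric("exchangeables"))

#' Stoichiometric and exchange matrices
#'
#' Returns the stoichiometric matrix S (metabolites x reactions) and the
#' exchange selector E, an identity-like 0/1 matrix with one unit column per
#' exchangeable metabolite, so that steady state reads `S v - E e = 0`.
#'
#' @param model a \linkS4class{StoichiometricModel}.
#' @return list with elements `S` and `E`.
#' @export
setGeneric("stoichiometricMatrix",
           function(model) standardGeneric("stoichiometricMatrix"))

#' @rdname FluxSolution-class
#' @param object a \linkS4class{FluxSolution}.
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))

#' @rdname FluxSolution-class
#' @export
setGeneric("exchangeFluxes",
           function(object) standardGeneric("exchangeFluxes"))

#' @rdname FluxSolution-class
#' @export
setGeneric("solutionStatus", function(object) standardGeneric("solutionStatus"))

#' @rdname FluxSolution-class
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))

#' Net exchange balance of one metabolite
#'
#' For an optimal solution, the net production (positive) or consumption
#' (negative) of a metabolite across the system boundary: the exchange flux
#' if the metabolite was open in the scenario, and 0 for a closed metabolite
#' (whose internal production and consumption cancel at steady state).
#'
#' @param sol a \linkS4class{FluxSolution}.
#' @param met metabolite id.
#' @return a single number.
#' @export
setGeneric("metaboliteBalance",
           function(sol, met) standardGeneric("metaboliteBalance"))

#' @rdname ScenarioReport-class
#' @param object a \linkS4class{ScenarioReport}.
#' @export
setGeneric("growthRate", function(object) standardGeneric("growthRate"))

#' @rdname ScenarioReport-class
#' @export
setGeneric("fluxBalances", function(object) standardGeneric("fluxBalances"))
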