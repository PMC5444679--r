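#' @import methods
NULL

## Box bound used by the LP layer to represent "unbounded" fluxes.  Solutions
## touching the box are flagged as effectively unbounded (see FluxSolution).
.BIG_BOUND <- 1e6

## Feasibility / optimality tolerances used throughout the engine.
.TOL_RESIDUAL <- 1e-9
.TOL_OBJECTIVE <- 1e-7
.TOL_FLUX <- 1e-6

#' Biomass drain specification
#'
#' Coefficients (per unit growth flux) with which the growth pseudo-reaction
#' drains precursor metabolites and cofactors.  Positive values are consumed;
#' a negative value (conventionally for NADH) is produced during biosynthesis.
#' The `provenance` label records where the coefficient set came from
#' (`"standin"` for the packaged synthetic set, `"standin:<seed>"` after
#' perturbation, or a user-supplied label).
#'
#' @slot drains named numeric vector of drain coefficients; names are
#'   metabolite ids of the model the spec is embedded into.
#' @slot provenance single character label.
#' @export
setClass("BiomassSpec",
         slots = c(drains = "numeric", provenance = "character"))

setValidity("BiomassSpec", function(object) {
    d <- object@drains
    if (is.null(names(d)) || any(!nzchar(names(d))))
        return("all drains must be named")
    if (anyDuplicated(names(d)))
        return("duplicated drain names")
    bad <- setdiff(names(d)[d < 0], c("NADH", "NAD"))
    if (length(bad))
        return(sprintf("negative drain for '%s': only NADH/NAD may be produced",
                       bad[[1L]]))
    for (must in c("ATP", "NADPH"))
        if (!must %in% names(d) || d[[must]] <= 0)
            return(sprintf("drain '%s' must be present and > 0", must))
    TRUE
})

#' Stoichiometric model
#'
#' A single-compartment metabolic reconstruction: metabolites, reactions with
#' bounds and reversibility, the stoichiometric matrix, and the set of
#' metabolites that may cross the system boundary (the non-zero columns of the
#' exchange selector matrix E).
#'
#' @slot metabolites data.frame with columns `id`, `name`, `isCofactor`,
#'   `defaultExchangeable`.
#' @slot reactions data.frame with columns `id`, `metacycId`, `index`,
#'   `reversible`, `lb`, `ub`.
#' @slot stoich numeric matrix, metabolites x reactions, dimnames set.
#' @slot exchangeable character vector of metabolite ids that may carry an
#'   exchange flux under some policy.
#' @slot constants named list of model constants (`poRatio`, `uptakeBound`).
#' @slot biomass the [BiomassSpec-class] embedded in the growth reaction.
#' @export
setClass("StoichiometricModel",
         slots = c(metabolites = "data.frame",
                   reactions = "data.frame",
                   stoich = "matrix",
                   exchangeable = "character",
                   constants = "list",
                   biomass = "BiomassSpec"))

setValidity("StoichiometricModel", function(object) {
    met <- object@metabolites
    rxn <- object@reactions
    S <- object@stoich
    if (anyDuplicated(met$id)) return("duplicated metabolite ids")
    if (anyDuplicated(rxn$id)) return("duplicated reaction ids")
    if (!identical(dim(S), c(nrow(met), nrow(rxn))))
        return("stoichiometric matrix dimensions inconsistent with tables")
    if (!identical(rownames(S), met$id) || !identical(colnames(S), rxn$id))
        return("stoichiometric matrix dimnames inconsistent with tables")
    if (any(colSums(S != 0) == 0))
        return("reaction with empty stoichiometry")
    if (any(!object@exchangeable %in% met$id))
        return("exchangeable set references unknown metabolite")
    bad <- !rxn$reversible & rxn$lb < 0
    if (any(bad))
        return(sprintf("irreversible reaction '%s' has negative lower bound",
                       rxn$id[bad][[1L]]))
    if (any(rxn$lb > rxn$ub)) return("reaction with lb > ub")
    TRUE
})

#' Exchange policy
#'
#' Per-metabolite boundary modes for one simulation.  Modes are `"closed"`
#' (no exchange flux), `"accumulate"` (export only, e >= 0), `"uptake"`
#' (e <= 0, finite lower bound), `"free"`, and `"fixed"` (e pinned to the
#' value in `uptakeBounds`, used when a saturated carbon uptake is part of
#' the experimental premise).  Metabolites of the model's exchangeable set
#' that are absent from `modes` are closed.
#'
#' @slot modes named character vector of modes.
#' @slot uptakeBounds named numeric vector of (negative) lower bounds for
#'   metabolites in `"uptake"` mode; defaults to the LP box bound.
#' @export
setClass("ExchangePolicy",
         slots = c(modes = "character", uptakeBounds = "numeric"))

setValidity("ExchangePolicy", function(object) {
    ok <- c("closed", "accumulate", "uptake", "free", "fixed")
    if (any(!object@modes %in% ok))
        return(sprintf("unknown exchange mode '%s'",
                       setdiff(object@modes, ok)[[1L]]))
    if (is.null(names(object@modes)) && length(object@modes))
        return("modes must be named by metabolite id")
    if (length(object@uptakeBounds) &&
        any(object@uptakeBounds > 0))
        return("uptake bounds must be <= 0")
    TRUE
})

#' Linear objective over fluxes
#'
#' Weights over reaction fluxes and/or exchange fluxes; the engine always
#' maximises.
#'
#' @slot reactionWeights named numeric vector (may be empty).
#' @slot exchangeWeights named numeric vector (may be empty).
#' @export
setClass("FluxObjective",
         slots = c(reactionWeights = "numeric", exchangeWeights = "numeric"))

setValidity("FluxObjective", function(object) {
    n <- length(object@reactionWeights) + length(object@exchangeWeights)
    if (n == 0L) return("objective must have at least one weight")
    TRUE
})

#' Assembled flux LP
#'
#' Internal container for one assembled linear programme
#' \eqn{\max c'x,\; Ax = b,\; l \le x \le u} whose variables are the reaction
#' fluxes v followed by the open exchange fluxes e.
#'
#' @slot A constraint matrix (one equality row per metabolite).
#' @slot b right-hand side.
#' @slot lb,ub variable bounds.
#' @slot cvec objective coefficients.
#' @slot varId variable identifiers (reaction or metabolite ids).
#' @slot varKind `"v"` or `"e"` per variable.
#' @slot metIds row identifiers.
#' @export
setClass("FluxLP",
         slots = c(A = "matrix", b = "numeric", lb = "numeric", ub = "numeric",
                   cvec = "numeric", varId = "character",
                   varKind = "character", metIds = "character"))

#' Flux solution
#'
#' @slot status `"optimal"`, `"infeasible"` or `"unbounded"`.
#' @slot objectiveValue objective at the reported point (NA unless optimal).
#' @slot v named reaction fluxes.
#' @slot e named exchange fluxes (open exchangeables only); positive values
#'   are net export/accumulation, negative values net uptake.
#' @slot residual maximal mass-balance residual of the reported point.
#' @slot atBox ids of variables whose solution value touches the LP box bound
#'   (effectively unbounded directions).
#' @export
setClass("FluxSolution",
         slots = c(status = "character", objectiveValue = "numeric",
                   v = "numeric", e = "numeric", residual = "numeric",
                   atBox = "character", mets = "character"))

#' Flux variability ranges
#'
#' Per-variable minimum and maximum flux attainable while holding the
#' objective at its optimum.
#'
#' @slot ranges data.frame with columns `id`, `kind`, `min`, `max`, `status`.
#' @export
setClass("FluxRange", slots = c(ranges = "data.frame"))

#' Scenario configuration
#'
#' The algebra that turns the reference model into one figure-style
#' simulation: carbon source, aerobiosis, deactivated reactions, cofactor
#' swaps, exchange policy and objective.
#'
#' @slot name scenario label (e.g. `"fig3"`).
#' @slot carbonSource `"glucose"` or `"xylose"`.
#' @slot aerobic logical.
#' @slot inactiveReactions reaction ids whose bounds are forced to zero.
#' @slot cofactorSwaps list of `list(reaction=, from=c(ox, red), to=c(ox, red))`.
#' @slot exchangePolicy an [ExchangePolicy-class].
#' @slot objective a [FluxObjective-class].
#' @export
setClass("ScenarioConfig",
         slots = c(name = "character", carbonSource = "character",
                   aerobic = "logical", inactiveReactions = "character",
                   cofactorSwaps = "list", exchangePolicy = "ExchangePolicy",
                   objective = "FluxObjective"))

setValidity("ScenarioConfig", function(object) {
    if (!object@carbonSource %in% c("glucose", "xylose"))
        return("carbonSource must be 'glucose' or 'xylose'")
    if (!object@aerobic &&
        identical(unname(object@exchangePolicy@modes["O2"]), "uptake"))
        return("anaerobic scenario must close the O2 exchange")
    TRUE
})

#' Scenario report
#'
#' @slot config the [ScenarioConfig-class] that was run.
#' @slot solution the parsimony-refined [FluxSolution-class].
#' @slot ranges the [FluxRange-class] from FVA (may be empty).
#' @slot balances named numeric exchange balances for the headline
#'   metabolites (ATP, NADH, NADPH, glycerol, ethanol, xylitol, acetate,
#'   CO2, O2).
#' @slot growth growth flux (flux of the biomass reaction).
#' @slot cycleAudit list of detected internal cycles that carry removable
#'   flux in the reported solution (empty for a sound solution).
#' @export
setClass("ScenarioReport",
         slots = c(config = "ScenarioConfig", solution = "FluxSolution",
                   ranges = "FluxRange", balances = "numeric",
                   growth = "numeric", cycleAudit = "list"))

#' Random model generator specification
#'
#' @slot nMetabolites,nReactions sizes (kept small so the vertex-enumeration
#'   oracle stays tractable).
#' @slot reversibleFraction fraction of side reactions made reversible.
#' @slot boundMagnitude box bound for all fluxes.
#' @slot seed integer RNG seed.
#' @export
setClass("GeneratorSpec",
         slots = c(nMetabolites = "integer", nReactions = "integer",
                   reversibleFraction = "numeric", boundMagnitude = "numeric",
                   seed = "integer"))

setValidity("GeneratorSpec", function(object) {
    if (object@nMetabolites < 3L || object@nMetabolites > 8L)
        return("nMetabolites must be in 3..8")
    if (object@nReactions < object@nMetabolites - 1L ||
        object@nReactions > 12L)
        return("nReactions must allow the planted pathway and be <= 12")
    if (object@reversibleFraction < 0 || object@reversibleFraction > 1)
        return("reversibleFraction must be in [0,1]")
    if (object@boundMagnitude <= 0)
        return("boundMagnitude must be positive")
    TRUE
})
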