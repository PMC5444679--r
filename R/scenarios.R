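## The scenario suite: each figure-style simulation of the study encoded as
## a ScenarioConfig, the runner that turns one into a ScenarioReport, and
## derived quantities (balances, condition comparisons, expression fold
## changes).

## Cofactor pairing used by exchange semantics: letting the high-energy /
## reduced form accumulate only makes stoichiometric sense if the partner
## can flow back (the boundary then stands for unmodelled hydrolysis or
## re-oxidation); acetyl export likewise returns free CoA.
.PARTNER <- c(ATP = "ADP", NADPH = "NADP", NADH = "NAD", ACCOA = "COA")

## Reactions that only exist to complete known substrate cycles; figure
## simulations deactivate them unless the figure explicitly studies the
## cycle (malic enzyme in the anaerobic scenario).  PEP synthase and PEP
## carboxylase/carboxykinase close ATP-dissipating pyruvate/PEP cycles; the
## malic-enzyme cycle (with pyruvate carboxylase and malate dehydrogenase)
## hydrolyses ATP while converting NADH to NADPH.
.CYCLE_BLOCKERS <- c("PPS", "PPC", "PCK")
.AEROBIC_EXTRA_BLOCKERS <- c("MAE")

#' Default exchange policy for a figure-style simulation
#'
#' Boundary semantics: the carbon source is uptake-only at the model's
#' uptake bound (-10); O2 is uptake-only when aerobic, closed otherwise;
#' CO2, water and orthophosphate are free; the fermentation products
#' (ethanol, glycerol, acetate, xylitol, ethyl acetate) and biomass may
#' accumulate; everything else is closed unless opened through `accumulate`
#' or `free`.  Letting a cofactor accumulate opens its partner for uptake
#' (see the package vignette).
#'
#' @param model a \linkS4class{StoichiometricModel}.
#' @param carbonSource `"glucose"` or `"xylose"`.
#' @param aerobic logical.
#' @param accumulate metabolite ids allowed to accumulate (export-only).
#' @param free metabolite ids exchanged freely (e.g. all cofactors in the
#'   NADPH-maximisation scenarios).
#' @param fixedUptake pin the carbon uptake to exactly the uptake bound
#'   (saturated transporter) instead of bounding it.
#' @return an \linkS4class{ExchangePolicy}.
#' @export
standardExchangePolicy <- function(model, carbonSource,
                                   aerobic = TRUE,
                                   accumulate = character(),
                                   free = character(),
                                   fixedUptake = FALSE) {
    stopifnot(carbonSource %in% c("glucose", "xylose"))
    carbon <- if (carbonSource == "glucose") "GLC" else "XYL"
    modes <- c(CO2 = "free", H2O = "free", PI = "free",
               ETOH = "accumulate", GLYC = "accumulate", AC = "accumulate",
               XYLT = "accumulate", ETAC = "accumulate",
               BIOMASS = "accumulate")
    modes[carbon] <- if (fixedUptake) "fixed" else "uptake"
    if (aerobic) modes["O2"] <- "uptake"
    for (m in free) modes[m] <- "free"
    for (m in accumulate) {
        modes[m] <- "accumulate"
        p <- .PARTNER[m]
        if (!is.na(p) && is.na(modes[p])) modes[p] <- "uptake"
    }
    keep <- intersect(names(modes), model@exchangeable)
    newExchangePolicy(modes[keep],
                      uptakeBounds =
                          stats::setNames(-model@constants$uptakeBound, carbon))
}

#' Precursor metabolites drained by the growth reaction
#'
#' @param model a \linkS4class{StoichiometricModel}.
#' @return character vector of non-cofactor metabolites consumed by vGrowth.
#' @export
biomassPrecursors <- function(model) {
    S <- model@stoich
    if (!"vGrowth" %in% colnames(S)) return(character())
    drained <- rownames(S)[S[, "vGrowth"] < 0]
    setdiff(drained, model@metabolites$id[model@metabolites$isCofactor])
}

#' Figure-scenario registry
#'
#' Returns the configuration of each published simulation:
#' \describe{
#'   \item{fig1/fig2}{growth maximisation on glucose / xylose, aerobic, ATP
#'     allowed to accumulate.}
#'   \item{fig3}{xylose, all cofactor exchanges free, FBP active; maximise
#'     NADPH production (complete cyclic PPP).}
#'   \item{fig4}{as fig3 with FBP inactive; maximise NADPH plus
#'     glyceraldehyde-3-phosphate export 1:1 (incomplete cycling).}
#'   \item{fig5}{xylose growth, biomass precursors + ATP + NADPH may
#'     accumulate, PFK inactive / FBP active.}
#'   \item{fig6}{as fig5 with the NADPH balance closed.}
#'   \item{fig7}{xylose growth, precursors + NADPH may accumulate, ATP
#'     balance closed, FBP inactive / PFK active.}
#'   \item{fig8}{as fig7 with FBP and PFK both active.}
#'   \item{fig9}{xylose growth, glucose-6-phosphate dehydrogenase swapped
#'     from NADP+ to NAD+, precursors + NADPH + ATP may accumulate, FBP
#'     active / PFK inactive.}
#'   \item{fig10}{as fig9 with PFK active / FBP inactive.}
#'   \item{fig11}{xylose, anaerobic, precursors + NADPH + ATP may
#'     accumulate, FBP and PFK active, malic enzyme active.}
#' }
#' Known ATP-dissipating substrate cycles not under study are blocked by
#' deactivating their enabling reactions (PEP synthase, PEP carboxylase,
#' PEP carboxykinase always; malic enzyme in the aerobic figures).
#'
#' @param figId one of `"fig1"` ... `"fig11"`.
#' @param model the model the scenario will run on (used for precursor and
#'   exchangeable sets).
#' @return a \linkS4class{ScenarioConfig}.
#' @export
scenarioRegistry <- function(figId, model = buildReferenceModel()) {
    figs <- paste0("fig", 1:11)
    if (!figId %in% figs)
        stop("unknown scenario '", figId, "'; expected one of ",
             paste(figs, collapse = ", "))
    pre <- biomassPrecursors(model)
    cof <- c("ATP", "ADP", "NAD", "NADH", "NADP", "NADPH")
    growth <- newFluxObjective(reactions = c(vGrowth = 1))
    blocked <- c(.CYCLE_BLOCKERS, .AEROBIC_EXTRA_BLOCKERS)
    cfg <- switch(figId,
        fig1 = list(carbon = "glucose", aerobic = TRUE,
                    accumulate = "ATP", free = character(),
                    inactive = blocked, swaps = list(), objective = growth),
        fig2 = list(carbon = "xylose", aerobic = TRUE,
                    accumulate = "ATP", free = character(),
                    inactive = blocked, swaps = list(), objective = growth),
        fig3 = list(carbon = "xylose", aerobic = TRUE,
                    accumulate = character(), free = cof,
                    inactive = blocked, swaps = list(),
                    objective = newFluxObjective(exchanges = c(NADPH = 1))),
        fig4 = list(carbon = "xylose", aerobic = TRUE,
                    accumulate = "GAP", free = cof,
                    inactive = c(blocked, "FBP"), swaps = list(),
                    objective = newFluxObjective(
                        exchanges = c(NADPH = 1, GAP = 1))),
        fig5 = list(carbon = "xylose", aerobic = TRUE,
                    accumulate = c(pre, "ATP", "NADPH"), free = character(),
                    inactive = c(blocked, "PFK"), swaps = list(),
                    objective = growth),
        fig6 = list(carbon = "xylose", aerobic = TRUE,
                    accumulate = c(pre, "ATP"), free = character(),
                    inactive = c(blocked, "PFK"), swaps = list(),
                    objective = growth),
        fig7 = list(carbon = "xylose", aerobic = TRUE,
                    accumulate = c(pre, "NADPH"), free = character(),
                    inactive = c(blocked, "FBP"), swaps = list(),
                    objective = growth),
        fig8 = list(carbon = "xylose", aerobic = TRUE,
                    accumulate = c(pre, "NADPH"), free = character(),
                    inactive = blocked, swaps = list(), objective = growth),
        fig9 = list(carbon = "xylose", aerobic = TRUE,
                    accumulate = c(pre, "NADPH", "ATP"), free = character(),
                    inactive = c(blocked, "PFK"),
                    swaps = list(list(reaction = "G6PDH",
                                      from = c("NADP", "NADPH"),
                                      to = c("NAD", "NADH"))),
                    objective = growth),
        fig10 = list(carbon = "xylose", aerobic = TRUE,
                    accumulate = c(pre, "NADPH", "ATP"), free = character(),
                    inactive = c(blocked, "FBP"),
                    swaps = list(list(reaction = "G6PDH",
                                      from = c("NADP", "NADPH"),
                                      to = c("NAD", "NADH"))),
                    objective = growth),
        fig11 = list(carbon = "xylose", aerobic = FALSE,
                    accumulate = c(pre, "NADPH", "ATP"), free = character(),
                    inactive = .CYCLE_BLOCKERS, swaps = list(),
                    objective = growth))
    pol <- standardExchangePolicy(model, cfg$carbon, cfg$aerobic,
                                  accumulate = cfg$accumulate,
                                  free = cfg$free)
    new("ScenarioConfig", name = figId, carbonSource = cfg$carbon,
        aerobic = cfg$aerobic, inactiveReactions = cfg$inactive,
        cofactorSwaps = cfg$swaps, exchangePolicy = pol,
        objective = cfg$objective)
}

#' Activate or deactivate a reaction in a scenario
#'
#' Deactivation forces both flux bounds to zero; re-activation restores the
#' model bounds.  Configurations are immutable; a modified copy is returned.
#'
#' @param config a \linkS4class{ScenarioConfig}.
#' @param reaction reaction id.
#' @param active logical.
#' @param model model used to check the reaction exists.
#' @return a new \linkS4class{ScenarioConfig}.
#' @export
setReactionActivity <- function(config, reaction, active,
                                model = buildReferenceModel()) {
    if (!reaction %in% model@reactions$id)
        stop("unknown reaction '", reaction, "'")
    inact <- config@inactiveReactions
    inact <- if (active) setdiff(inact, reaction) else union(inact, reaction)
    initialize(config, inactiveReactions = inact)
}

#' Swap the redox cofactor pair of a reaction
#'
#' Transfers the stoichiometric coefficients of an oxidised/reduced cofactor
#' pair to another pair, leaving all other coefficients untouched (e.g.
#' glucose-6-phosphate dehydrogenase from NADP+/NADPH to NAD+/NADH).
#' Swapping twice returns the original model.
#'
#' @param model a \linkS4class{StoichiometricModel}.
#' @param reaction reaction id or MetaCyc id.
#' @param from length-2 character, the present (oxidised, reduced) pair.
#' @param to length-2 character, the replacement pair.
#' @return the modified model.
#' @export
swapCofactor <- function(model, reaction, from, to) {
    rxn <- model@reactions
    j <- match(reaction, rxn$id)
    if (is.na(j)) j <- match(reaction, rxn$metacycId)
    if (is.na(j)) stop("unknown reaction '", reaction, "'")
    stopifnot(length(from) == 2L, length(to) == 2L)
    S <- model@stoich
    if (any(!from %in% rownames(S)) || any(!to %in% rownames(S)))
        stop("cofactor ids not in model")
    if (all(S[from, j] == 0))
        stop("reaction '", reaction, "' does not use the ",
             paste(from, collapse = "/"), " pair")
    for (k in 1:2) {
        S[to[k], j] <- S[to[k], j] + S[from[k], j]
        S[from[k], j] <- 0
    }
    model@stoich <- S
    model
}

.applyScenarioModel <- function(model, config) {
    for (sw in config@cofactorSwaps)
        model <- swapCofactor(model, sw$reaction, sw$from, sw$to)
    model
}

.inactiveEdits <- function(ids) {
    stats::setNames(rep(list(c(0, 0)), length(ids)), ids)
}

#' Run one scenario
#'
#' Applies cofactor swaps and reaction deactivations, assembles and solves
#' the LP, refines the solution parsimoniously, optionally runs FVA, audits
#' internal-cycle flux and computes the headline exchange balances.  The
#' whole pipeline is deterministic.
#'
#' @param model a \linkS4class{StoichiometricModel}.
#' @param config a \linkS4class{ScenarioConfig}.
#' @param fva run flux variability analysis (slower).
#' @param audit audit the refined solution against detected internal cycles.
#' @return a \linkS4class{ScenarioReport}.  Infeasible scenarios carry the
#'   status in the solution and empty balances.
#' @export
runScenario <- function(model, config, fva = TRUE, audit = TRUE) {
    model2 <- .applyScenarioModel(model, config)
    lp <- assembleFluxLP(model2, config@exchangePolicy, config@objective,
                         .inactiveEdits(config@inactiveReactions))
    sol <- solveFBA(lp)
    if (sol@status != "optimal")
        return(new("ScenarioReport", config = config, solution = sol,
                   ranges = new("FluxRange", ranges = data.frame()),
                   balances = numeric(), growth = NA_real_,
                   cycleAudit = list()))
    ref <- parsimoniousRefine(lp, sol@objectiveValue)
    ranges <- if (fva) fluxVariability(lp, sol@objectiveValue)
              else new("FluxRange", ranges = data.frame())
    watch <- c("ATP", "NADH", "NADPH", "GLYC", "ETOH", "XYLT", "AC",
               "CO2", "O2")
    balances <- vapply(watch, function(m) metaboliteBalance(ref, m),
                       numeric(1))
    auditRes <- if (audit) {
        cyc <- detectInternalCycles(model2,
                                    inactive = config@inactiveReactions)
        auditCycleFlux(model2, ref, cyc, config@exchangePolicy@modes)
    } else list()
    new("ScenarioReport", config = config, solution = ref, ranges = ranges,
        balances = balances,
        growth = if ("vGrowth" %in% names(ref@v))
                     unname(ref@v[["vGrowth"]]) else NA_real_,
        cycleAudit = auditRes)
}

#' Limited malic-enzyme probe of the anaerobic scenario
#'
#' Re-runs the anaerobic xylose scenario with a saturated (pinned) xylose
#' uptake and the malic-enzyme flux capped at a fraction of its
#' unrestricted value.  With the uptake saturated, restricting the cycle
#' forces part of the entering carbon out as xylitol.
#'
#' @param model a \linkS4class{StoichiometricModel}.
#' @param fraction cap as a fraction of the unrestricted malic-enzyme flux.
#' @param fva forwarded to [runScenario()].
#' @return list with the unrestricted `reference` report and the `limited`
#'   report.
#' @export
limitedMalicEnzymeProbe <- function(model = buildReferenceModel(),
                                    fraction = 0.5, fva = FALSE) {
    cfg <- scenarioRegistry("fig11", model)
    pol <- standardExchangePolicy(model, "xylose", aerobic = FALSE,
                                  accumulate = c(biomassPrecursors(model),
                                                 "NADPH", "ATP"),
                                  fixedUptake = TRUE)
    cfg <- initialize(cfg, exchangePolicy = pol)
    refReport <- runScenario(model, cfg, fva = FALSE, audit = FALSE)
    maeFlux <- fluxes(refReport)[["MAE"]]
    lp <- assembleFluxLP(model, pol, cfg@objective,
                         c(.inactiveEdits(cfg@inactiveReactions),
                           list(MAE = c(0, fraction * maeFlux))))
    sol <- solveFBA(lp)
    limited <- if (sol@status == "optimal")
        parsimoniousRefine(lp, sol@objectiveValue) else sol
    list(reference = refReport, limited = limited)
}

#' Compare scenario reports
#'
#' Tabulates growth and the headline balances across reports, with ratios
#' relative to the first report, and flags reactions whose flux direction
#' flips between any two reports (such as glucose-6-phosphate isomerase
#' between the glucose and xylose media).
#'
#' @param reports list of \linkS4class{ScenarioReport}s (>= 2).
#' @param tol flux threshold for the direction-flip flags.
#' @return list with `values` (quantity x scenario data.frame), `ratios`
#'   (relative to the first report) and `flips` (data.frame of reaction
#'   direction flips).
#' @export
compareConditions <- function(reports, tol = .TOL_FLUX) {
    stopifnot(length(reports) >= 2L)
    nm <- vapply(reports, function(r) r@config@name, "")
    qty <- rbind(growth = vapply(reports, growthRate, numeric(1)),
                 vapply(reports, fluxBalances,
                        numeric(length(fluxBalances(reports[[1L]])))))
    colnames(qty) <- nm
    ratios <- qty / qty[, 1L]
    ratios[!is.finite(ratios)] <- NA_real_
    flips <- data.frame(reaction = character(), from = character(),
                        to = character(), fluxFrom = numeric(),
                        fluxTo = numeric())
    for (a in seq_along(reports)) for (b in seq_along(reports)) {
        if (a >= b) next
        va <- fluxes(reports[[a]]); vb <- fluxes(reports[[b]])
        common <- intersect(names(va), names(vb))
        flip <- common[va[common] > tol & vb[common] < -tol |
                       va[common] < -tol & vb[common] > tol]
        if (length(flip))
            flips <- rbind(flips,
                data.frame(reaction = flip, from = nm[a], to = nm[b],
                           fluxFrom = unname(va[flip]),
                           fluxTo = unname(vb[flip])))
    }
    list(values = as.data.frame(qty), ratios = as.data.frame(ratios),
         flips = flips)
}
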