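## Core model construction: reaction-equation parsing, the model constructor,
## matrix extraction, structural validation, accessors and show methods.

#' Parse a reaction equation string
#'
#' Equations use the dialect `"2 A + B -> C"` (irreversible) or
#' `"A <-> B"` (reversible).  Coefficients are positive decimals; omitted
#' coefficients are 1.
#'
#' @param equation a single equation string.
#' @return list with `stoich` (named numeric, substrates negative) and
#'   `reversible` (logical).
#' @examples
#' parseEquation("2 ATP + PYR -> PEP + 2 ADP + PI")
#' @export
parseEquation <- function(equation) {
    stopifnot(is.character(equation), length(equation) == 1L)
    reversible <- grepl("<->", equation, fixed = TRUE)
    arrow <- if (reversible) "<->" else "->"
    sides <- strsplit(equation, arrow, fixed = TRUE)[[1L]]
    if (length(sides) != 2L)
        stop("equation must contain exactly one '", arrow, "': ", equation)
    parseSide <- function(side, sign) {
        side <- trimws(side)
        if (!nzchar(side)) stop("empty side in equation: ", equation)
        terms <- trimws(strsplit(side, " + ", fixed = TRUE)[[1L]])
        out <- numeric(0)
        for (term in terms) {
            m <- regmatches(term,
                regexec("^([0-9]*\\.?[0-9]+[ ]+)?([A-Za-z][A-Za-z0-9_]*)$",
                        term))[[1L]]
            if (length(m) == 0L)
                stop("cannot parse term '", term, "' in equation: ", equation)
            coef <- if (nzchar(trimws(m[[2L]]))) as.numeric(trimws(m[[2L]])) else 1
            id <- m[[3L]]
            out[id] <- (if (is.na(out[id])) 0 else out[id]) + sign * coef
        }
        out
    }
    lhs <- parseSide(sides[[1L]], -1)
    rhs <- parseSide(sides[[2L]], +1)
    stoich <- lhs
    for (id in names(rhs))
        stoich[id] <- (if (id %in% names(stoich)) stoich[[id]] else 0) + rhs[[id]]
    stoich <- stoich[stoich != 0]
    list(stoich = stoich, reversible = reversible)
}

#' Write a stoichiometry back to an equation string
#'
#' Inverse of [parseEquation()] up to term order (substrates and products are
#' emitted in the metabolite order given).
#'
#' @param stoich named numeric stoichiometry (substrates negative).
#' @param reversible logical.
#' @return equation string.
#' @export
deparseEquation <- function(stoich, reversible) {
    fmtCoef <- function(x) {
        if (isTRUE(all.equal(x, 1))) return("")
        paste0(format(x, scientific = FALSE, trim = TRUE, digits = 12), " ")
    }
    term <- function(ids, coefs)
        paste(mapply(function(i, k) paste0(fmtCoef(k), i), ids, coefs),
              collapse = " + ")
    sub <- stoich < 0
    lhs <- term(names(stoich)[sub], -stoich[sub])
    rhs <- term(names(stoich)[!sub], stoich[!sub])
    paste(lhs, if (reversible) "<->" else "->", rhs)
}

#' Construct a stoichiometric model
#'
#' @param metabolites data.frame with columns `id`, `name`, `isCofactor`,
#'   `defaultExchangeable`.
#' @param reactions data.frame with columns `id`, `metacycId`, `index`,
#'   `equation`, `reversible`, `lb`, `ub`.  `lb`/`ub` may be `-Inf`/`Inf`;
#'   the LP layer boxes them.
#' @param constants named list; `poRatio` and `uptakeBound` default to 2.5
#'   and 10.
#' @param biomass a [BiomassSpec-class] (recorded; the growth reaction itself
#'   must be part of `reactions`).
#' @return a \linkS4class{StoichiometricModel}.  The exchangeable set is the
#'   union of the default-exchangeable metabolites, the cofactor species and
#'   the non-cofactor precursors drained by a reaction named `vGrowth` (so
#'   that scenario policies can open any of them).
#' @export
newStoichiometricModel <- function(metabolites, reactions,
                                   constants = list(),
                                   biomass = NULL) {
    metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
    reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
    S <- matrix(0, nrow(metabolites), nrow(reactions),
                dimnames = list(metabolites$id, reactions$id))
    for (j in seq_len(nrow(reactions))) {
        parsed <- parseEquation(reactions$equation[[j]])
        unknown <- setdiff(names(parsed$stoich), metabolites$id)
        if (length(unknown))
            stop("reaction '", reactions$id[[j]],
                 "' references undeclared metabolite '", unknown[[1L]], "'")
        if (!identical(parsed$reversible, reactions$reversible[[j]]))
            stop("reaction '", reactions$id[[j]],
                 "': arrow in equation contradicts the reversible flag")
        S[names(parsed$stoich), j] <- parsed$stoich
    }
    if (!reactions$reversible[1] %in% c(TRUE, FALSE))
        stop("reversible column must be logical")
    bad <- !reactions$reversible & reactions$lb < 0
    if (any(bad))
        stop("irreversible reaction '", reactions$id[bad][[1L]],
             "' has a negative lower bound")
    constants <- utils::modifyList(list(poRatio = 2.5, uptakeBound = 10),
                                   constants)
    if (is.null(biomass))
        biomass <- new("BiomassSpec", drains = c(ATP = 1, NADPH = 1),
                       provenance = "unused")
    exch <- metabolites$id[metabolites$defaultExchangeable |
                           metabolites$isCofactor]
    if ("vGrowth" %in% reactions$id) {
        drained <- rownames(S)[S[, "vGrowth"] < 0]
        drained <- setdiff(drained,
                           metabolites$id[metabolites$isCofactor])
        exch <- union(exch, drained)
    }
    exch <- metabolites$id[metabolites$id %in% exch]  # model order
    rxnTab <- reactions[, c("id", "metacycId", "index", "reversible",
                            "lb", "ub")]
    rownames(rxnTab) <- NULL
    new("StoichiometricModel", metabolites = metabolites,
        reactions = rxnTab, stoich = S, exchangeable = exch,
        constants = constants, biomass = biomass)
}

#' @rdname StoichiometricModel-class
#' @export
setMethod("reactions", "StoichiometricModel", function(x) x@reactions)

#' @rdname StoichiometricModel-class
#' @export
setMethod("metabolites", "StoichiometricModel", function(x) x@metabolites)

#' @rdname StoichiometricModel-class
#' @export
setMethod("exchangeables", "StoichiometricModel", function(x) x@exchangeable)

#' @export
setMethod("stoichiometricMatrix", "StoichiometricModel", function(model) {
    S <- model@stoich
    E <- matrix(0, nrow(S), length(model@exchangeable),
                dimnames = list(rownames(S), model@exchangeable))
    for (m in model@exchangeable) E[m, m] <- 1
    list(S = S, E = E)
})

#' Structural validation of a model
#'
#' Returns findings rather than raising: orphan metabolites (in no reaction),
#' dead-end non-exchangeable metabolites (only produced or only consumed,
#' hence necessarily flux-less at steady state), and bound violations.
#'
#' @param model a \linkS4class{StoichiometricModel}.
#' @return data.frame with columns `class`, `id`, `message` (zero rows for a
#'   clean model).
#' @export
validateModel <- function(model) {
    S <- model@stoich
    rxn <- model@reactions
    findings <- list()
    add <- function(class, id, message)
        findings[[length(findings) + 1L]] <<-
            data.frame(class = class, id = id, message = message)
    for (m in rownames(S)) {
        nuse <- sum(S[m, ] != 0)
        if (nuse == 0L) {
            add("orphan", m, sprintf("metabolite '%s' occurs in no reaction", m))
            next
        }
        if (m %in% model@exchangeable) next
        ## a reversible reaction can both produce and consume
        rev <- rxn$reversible
        canProduce <- any(S[m, ] > 0 | (S[m, ] != 0 & rev))
        canConsume <- any(S[m, ] < 0 | (S[m, ] != 0 & rev))
        if (!canProduce || !canConsume)
            add("dead_end", m,
                sprintf("non-exchangeable metabolite '%s' is only %s", m,
                        if (canProduce) "produced" else "consumed"))
    }
    bad <- which(rxn$lb > rxn$ub)
    for (j in bad)
        add("bound_violation", rxn$id[[j]],
            sprintf("reaction '%s' has lb > ub", rxn$id[[j]]))
    bad <- which(!rxn$reversible & rxn$lb < 0)
    for (j in bad)
        add("bound_violation", rxn$id[[j]],
            sprintf("irreversible reaction '%s' has negative lower bound",
                    rxn$id[[j]]))
    if (length(findings)) do.call(rbind, findings)
    else data.frame(class = character(), id = character(),
                    message = character())
}

setMethod("show", "StoichiometricModel", function(object) {
    cat("StoichiometricModel:", nrow(object@metabolites), "metabolites,",
        nrow(object@reactions), "reactions,",
        length(object@exchangeable), "exchangeable\n")
    cat("  biomass set:", object@biomass@provenance,
        " P/O:", object@constants$poRatio,
        " carbon uptake bound:", object@constants$uptakeBound, "\n")
})

setMethod("show", "FluxSolution", function(object) {
    cat("FluxSolution:", object@status)
    if (object@status == "optimal")
        cat(", objective", format(object@objectiveValue, digits = 6),
            ", max residual", format(object@residual, digits = 3))
    cat("\n")
    if (length(object@atBox))
        cat("  at box bound (effectively unbounded):",
            paste(object@atBox, collapse = ", "), "\n")
})

setMethod("show", "ScenarioReport", function(object) {
    cat("ScenarioReport", object@config@name, "(",
        object@config@carbonSource,
        if (object@config@aerobic) "aerobic" else "anaerobic", ")\n")
    cat("  status:", object@solution@status,
        " growth:", format(object@growth, digits = 4), "\n")
    if (length(object@balances)) {
        cat("  balances:\n")
        print(round(object@balances, 4))
    }
    if (length(object@cycleAudit))
        cat("  WARNING:", length(object@cycleAudit),
            "removable internal cycle(s) carry flux\n")
})

#' @rdname FluxSolution-class
#' @export
setMethod("fluxes", "FluxSolution", function(object) object@v)

#' @rdname FluxSolution-class
#' @export
setMethod("exchangeFluxes", "FluxSolution", function(object) object@e)

#' @rdname FluxSolution-class
#' @export
setMethod("solutionStatus", "FluxSolution", function(object) object@status)

#' @rdname FluxSolution-class
#' @export
setMethod("objectiveValue", "FluxSolution",
          function(object) object@objectiveValue)

#' @export
setMethod("metaboliteBalance", c("FluxSolution", "character"),
          function(sol, met) {
    stopifnot(length(met) == 1L)
    if (length(sol@mets) && !met %in% sol@mets)
        stop("unknown metabolite '", met, "'")
    if (met %in% names(sol@e)) unname(sol@e[[met]]) else 0
})

#' @rdname ScenarioReport-class
#' @export
setMethod("growthRate", "ScenarioReport", function(object) object@growth)

#' @rdname ScenarioReport-class
#' @export
setMethod("fluxBalances", "ScenarioReport", function(object) object@balances)

#' @rdname ScenarioReport-class
#' @export
setMethod("fluxes", "ScenarioReport", function(object) object@solution@v)
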