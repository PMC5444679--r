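## LP assembly and solution of S v - E e = 0, parsimonious tie-breaking,
## flux variability analysis and internal substrate-cycle detection.

#' Construct an exchange policy
#'
#' @param modes named character vector over metabolite ids with values
#'   `"closed"`, `"accumulate"`, `"uptake"` or `"free"`.
#' @param uptakeBounds named numeric vector of lower bounds (<= 0) for
#'   metabolites in uptake mode; any uptake metabolite without an entry gets
#'   the LP box bound.
#' @return an \linkS4class{ExchangePolicy}.
#' @export
newExchangePolicy <- function(modes, uptakeBounds = numeric()) {
    new("ExchangePolicy", modes = modes, uptakeBounds = uptakeBounds)
}

#' Construct a flux objective
#'
#' @param reactions named numeric weights over reaction ids.
#' @param exchanges named numeric weights over exchangeable metabolite ids.
#' @return a \linkS4class{FluxObjective} (always maximised).
#' @export
newFluxObjective <- function(reactions = numeric(), exchanges = numeric()) {
    new("FluxObjective", reactionWeights = reactions,
        exchangeWeights = exchanges)
}

#' Assemble the flux LP
#'
#' Builds `max c'x` subject to one steady-state equality per metabolite,
#' `S v - E e = 0`, with reaction bounds from the model (overridden by
#' `edits`, applied last) and exchange bounds from the policy.  Upper bounds
#' left unconstrained in the model are boxed at the package's LP box bound.
#'
#' @param model a \linkS4class{StoichiometricModel}.
#' @param policy an \linkS4class{ExchangePolicy}.
#' @param objective a \linkS4class{FluxObjective}.
#' @param edits named list of `c(lb, ub)` overrides by reaction id.
#' @return a \linkS4class{FluxLP}.
#' @export
assembleFluxLP <- function(model, policy, objective, edits = list()) {
    S <- model@stoich
    rxn <- model@reactions
    unknownPol <- setdiff(names(policy@modes), model@exchangeable)
    if (length(unknownPol))
        stop("policy references non-exchangeable metabolite '",
             unknownPol[[1L]], "'")
    lbv <- pmax(rxn$lb, -.BIG_BOUND)
    ubv <- pmin(rxn$ub, .BIG_BOUND)
    for (id in names(edits)) {
        j <- match(id, rxn$id)
        if (is.na(j)) stop("edit references unknown reaction '", id, "'")
        lbv[j] <- max(edits[[id]][[1L]], -.BIG_BOUND)
        ubv[j] <- min(edits[[id]][[2L]], .BIG_BOUND)
    }
    openMets <- names(policy@modes)[policy@modes != "closed"]
    ne <- length(openMets)
    A <- cbind(S, matrix(0, nrow(S), ne,
                         dimnames = list(NULL, openMets)))
    lbe <- numeric(ne); ube <- numeric(ne)
    for (k in seq_len(ne)) {
        met <- openMets[[k]]
        A[met, ncol(S) + k] <- -1
        mode <- policy@modes[[met]]
        if (mode == "accumulate") { lbe[k] <- 0; ube[k] <- .BIG_BOUND }
        else if (mode == "uptake") {
            lbe[k] <- if (met %in% names(policy@uptakeBounds))
                          max(policy@uptakeBounds[[met]], -.BIG_BOUND)
                      else -.BIG_BOUND
            ube[k] <- 0
        } else if (mode == "fixed") {
            if (!met %in% names(policy@uptakeBounds))
                stop("fixed exchange for '", met, "' needs an uptakeBounds entry")
            lbe[k] <- ube[k] <- policy@uptakeBounds[[met]]
        } else { lbe[k] <- -.BIG_BOUND; ube[k] <- .BIG_BOUND }
    }
    cvec <- numeric(ncol(S) + ne)
    for (id in names(objective@reactionWeights)) {
        j <- match(id, rxn$id)
        if (is.na(j)) stop("objective references unknown reaction '", id, "'")
        cvec[j] <- objective@reactionWeights[[id]]
    }
    for (id in names(objective@exchangeWeights)) {
        k <- match(id, openMets)
        if (is.na(k))
            stop("objective references closed or unknown exchange '", id, "'")
        cvec[ncol(S) + k] <- objective@exchangeWeights[[id]]
    }
    new("FluxLP", A = A, b = numeric(nrow(S)),
        lb = c(lbv, lbe), ub = c(ubv, ube), cvec = cvec,
        varId = c(rxn$id, openMets),
        varKind = c(rep("v", ncol(S)), rep("e", ne)),
        metIds = rownames(S))
}

.lpToSolution <- function(lp, res) {
    isv <- lp@varKind == "v"
    v <- res$x[isv]; names(v) <- lp@varId[isv]
    e <- res$x[!isv]; names(e) <- lp@varId[!isv]
    atBox <- lp@varId[abs(res$x) >= .BIG_BOUND * (1 - 1e-6)]
    new("FluxSolution", status = res$status,
        objectiveValue = if (res$status == "optimal") res$objective
                         else NA_real_,
        v = v, e = e,
        residual = if (is.na(res$residual)) NA_real_ else res$residual,
        atBox = atBox, mets = lp@metIds)
}

#' Solve a flux LP
#'
#' @param lp a \linkS4class{FluxLP} from [assembleFluxLP()].
#' @return a \linkS4class{FluxSolution}; infeasible and unbounded problems
#'   are reported through the status, never as silent zeros.
#' @export
solveFBA <- function(lp) {
    res <- lpSolveBounded(lp@A, lp@b, lp@cvec, lp@lb, lp@ub, maximize = TRUE)
    if (res$status == "maxiter")
        stop("LP solver failed to converge")
    .lpToSolution(lp, res)
}

## Split-variable LP minimising sum |x_j| over the selected variables while
## holding linear constraints; shared by pFBA and cycle-support extraction.
.minAbsSolve <- function(A, b, lb, ub, penalise, extraRow = NULL,
                         extraRhs = NULL) {
    n <- ncol(A)
    splitIdx <- which(lb < 0)
    ## x = xplus - xminus with xplus in [max(lb,0), max(ub,0)] and
    ## xminus in [max(-ub,0), -lb]; exact also for pinned negative bounds
    A2 <- cbind(A, -A[, splitIdx, drop = FALSE], deparse.level = 0)
    lb2 <- c(pmax(lb, 0), pmax(-ub[splitIdx], 0))
    ub2 <- c(pmax(ub, 0), -lb[splitIdx])
    if (!is.null(extraRow)) {
        A2 <- rbind(A2, c(extraRow, -extraRow[splitIdx]), deparse.level = 0)
        b <- c(b, extraRhs)
    }
    cpen <- numeric(ncol(A2))
    cpen[seq_len(n)][penalise] <- -1
    cpen[n + seq_along(splitIdx)][penalise[splitIdx]] <- -1
    res <- lpSolveBounded(A2, b, cpen, lb2, ub2, maximize = TRUE)
    if (res$status == "optimal") {
        x <- res$x[seq_len(n)]
        x[splitIdx] <- x[splitIdx] - res$x[n + seq_along(splitIdx)]
        res$x <- x
    }
    res
}

#' Parsimonious refinement of an optimal solution
#'
#' Among the alternate optima of a solved LP, returns the flux distribution
#' minimising the total absolute reaction flux (pFBA-style tie-breaking)
#' with the objective pinned to the optimum.  Reported scenario solutions
#' always pass through this refinement, which strips gratuitous internal
#' circulations.
#'
#' @param lp the assembled \linkS4class{FluxLP}.
#' @param optimum objective value returned by [solveFBA()].
#' @return a \linkS4class{FluxSolution} with `objectiveValue = optimum`.
#' @export
parsimoniousRefine <- function(lp, optimum) {
    stopifnot(is.finite(optimum))
    res <- .minAbsSolve(lp@A, lp@b, lp@lb, lp@ub,
                        penalise = lp@varKind == "v",
                        extraRow = lp@cvec, extraRhs = optimum)
    if (res$status != "optimal")
        stop("parsimonious refinement failed: ", res$status)
    sol <- .lpToSolution(lp, res)
    sol@objectiveValue <- sum(lp@cvec * res$x)
    sol@status <- "optimal"
    sol
}

#' Flux variability analysis
#'
#' Per-variable minimum and maximum subject to the original constraints plus
#' the objective held at its optimum (fraction 1.0).
#'
#' @param lp the assembled \linkS4class{FluxLP}.
#' @param optimum objective value returned by [solveFBA()].
#' @param vars optional variable ids to restrict to.
#' @return a \linkS4class{FluxRange}.
#' @export
fluxVariability <- function(lp, optimum, vars = NULL) {
    A <- rbind(lp@A, lp@cvec, deparse.level = 0)
    b <- c(lp@b, optimum)
    idx <- seq_along(lp@varId)
    if (!is.null(vars)) idx <- which(lp@varId %in% vars)
    out <- data.frame(id = lp@varId[idx], kind = lp@varKind[idx],
                      min = NA_real_, max = NA_real_,
                      status = "ok", stringsAsFactors = FALSE)
    for (r in seq_along(idx)) {
        k <- idx[[r]]
        cv <- numeric(length(lp@cvec)); cv[k] <- 1
        up <- lpSolveBounded(A, b, cv, lp@lb, lp@ub, maximize = TRUE)
        dn <- lpSolveBounded(A, b, cv, lp@lb, lp@ub, maximize = FALSE)
        if (up$status == "optimal") out$max[r] <- up$objective
        if (dn$status == "optimal") out$min[r] <- dn$objective
        if (up$status != "optimal" || dn$status != "optimal")
            out$status[r] <- paste(dn$status, up$status, sep = "/")
    }
    new("FluxRange", ranges = out)
}

#' Detect internal substrate cycles
#'
#' Finds minimal sets of reactions able to carry a non-zero circulation with
#' every exchange closed — the substrate cycles ("futile cycles") whose net
#' effect is pure cofactor turnover (e.g. ATP hydrolysis by the
#' FBP/PFK pair) and which could otherwise reach unbounded flux.  Balance
#' rows of the cofactor species (and water) are relaxed, matching the
#' defining property that a substrate cycle converts no carbon and only
#' turns cofactors over; the net cofactor conversion of each cycle is
#' reported.
#'
#' @param model a \linkS4class{StoichiometricModel}.
#' @param inactive reaction ids treated as shut off.
#' @param tol flux threshold above which a circulation counts.
#' @return list of cycles, each a list with `reactions` (ids), `mode` (a
#'   representative unit circulation) and `net` (named net conversion of the
#'   relaxed species).
#' @export
detectInternalCycles <- function(model, inactive = character(),
                                 tol = .TOL_FLUX) {
    S <- model@stoich
    rxn <- model@reactions
    relax <- model@metabolites$id[model@metabolites$isCofactor]
    relax <- union(relax, "H2O")
    keep <- setdiff(rownames(S), relax)
    A <- S[keep, , drop = FALSE]
    lb <- pmax(rxn$lb, -.BIG_BOUND)
    ub <- pmin(rxn$ub, .BIG_BOUND)
    off <- rxn$id %in% inactive
    lb[off] <- 0; ub[off] <- 0
    cycles <- list(); seen <- character()
    covered <- logical(nrow(rxn))
    for (j in seq_len(nrow(rxn))) {
        if (covered[j] || (ub[j] <= tol && lb[j] >= -tol)) next
        for (dir in c(1, -1)) {
            if (dir > 0 && ub[j] <= tol) next
            if (dir < 0 && lb[j] >= -tol) next
            cv <- numeric(ncol(A)); cv[j] <- dir
            res <- lpSolveBounded(A, numeric(nrow(A)), cv, lb, ub,
                                  maximize = TRUE)
            if (res$status != "optimal" || res$objective < .BIG_BOUND * 1e-3)
                next
            ## minimal support: unit flux through j, least total |v|
            lb2 <- lb; ub2 <- ub; lb2[j] <- dir; ub2[j] <- dir
            sup <- .minAbsSolve(A, numeric(nrow(A)), lb2, ub2,
                                penalise = rep(TRUE, ncol(A)))
            if (sup$status != "optimal") next
            mode <- sup$x
            support <- which(abs(mode) > tol)
            key <- paste(sort(rxn$id[support]), collapse = "+")
            if (!key %in% seen) {
                seen <- c(seen, key)
                net <- as.numeric(S[relax, , drop = FALSE] %*% mode)
                names(net) <- relax
                names(mode) <- rxn$id
                cycles[[length(cycles) + 1L]] <-
                    list(reactions = rxn$id[support],
                         mode = mode[support],
                         net = net[abs(net) > tol])
            }
            covered[support] <- TRUE
            break
        }
    }
    cycles
}

#' Audit a refined solution for removable cycle flux
#'
#' Checks, for each detected internal cycle, whether the reported solution
#' carries a circulation along it that could be subtracted without changing
#' the objective or violating any balance (i.e. flux that only chases the
#' cycle).  Parsimonious refinement guarantees an empty audit; a cycle that
#' is *required* to close a cofactor balance (such as the FBP/PFK pair under
#' a closed ATP balance) is not flagged.
#'
#' @param model the model the scenario ran on.
#' @param sol a refined \linkS4class{FluxSolution}.
#' @param cycles output of [detectInternalCycles()].
#' @param policyModes named modes vector of the scenario's exchange policy.
#' @param tol flux tolerance.
#' @return list of flagged cycles (empty when sound).
#' @export
auditCycleFlux <- function(model, sol, cycles, policyModes,
                           tol = .TOL_FLUX) {
    flagged <- list()
    S <- model@stoich
    for (cy in cycles) {
        lam <- suppressWarnings(min(sol@v[cy$reactions] / cy$mode))
        if (!is.finite(lam) || lam <= tol) next
        ## removing lam * mode changes only the relaxed (cofactor) balances:
        ## feasible only if every affected balance row is an open exchange
        ## able to absorb the change
        full <- numeric(nrow(S)); names(full) <- rownames(S)
        full[names(cy$net)] <- cy$net
        affected <- names(full)[abs(full) > tol]
        removable <- TRUE
        for (met in affected) {
            mode <- policyModes[met]
            if (is.na(mode) || mode == "closed") { removable <- FALSE; break }
            eNew <- metaboliteBalance(sol, met) - lam * full[[met]]
            okLow <- if (mode == "accumulate") eNew >= -tol else TRUE
            okHigh <- if (mode == "uptake") eNew <= tol else TRUE
            if (!okLow || !okHigh) { removable <- FALSE; break }
        }
        if (removable) flagged[[length(flagged) + 1L]] <- cy
    }
    flagged
}
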