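## Generators and oracles: random small models with a planted pathway, an
## independent vertex-enumeration LP optimum, and biomass-coefficient
## perturbation.  These make every engine property testable without any
## external data and keep the oracle free of any code shared with the
## simplex solver.

#' Specification for a random small model
#'
#' @param nMetabolites,nReactions sizes (<= 8 and <= 12: the enumeration
#'   oracle must stay tractable).
#' @param reversibleFraction fraction of side reactions made reversible.
#' @param boundMagnitude box bound applied to every flux.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return a \linkS4class{GeneratorSpec}.
#' @export
generatorSpec <- function(nMetabolites = 5L, nReactions = 7L,
                          reversibleFraction = 0.3, boundMagnitude = 10,
                          seed = 1L) {
    new("GeneratorSpec", nMetabolites = as.integer(nMetabolites),
        nReactions = as.integer(nReactions),
        reversibleFraction = reversibleFraction,
        boundMagnitude = boundMagnitude, seed = as.integer(seed))
}

#' Generate a random small model
#'
#' Plants a linear uptake-to-export pathway M1 -> M2 -> ... -> Mk (so a
#' non-trivial feasible flux always exists), then adds random side
#' reactions with coefficients in \{-2, -1, 1, 2\}.  The first metabolite
#' is exchangeable for uptake, the last for export.
#'
#' @param spec a \linkS4class{GeneratorSpec}.
#' @return a \linkS4class{StoichiometricModel}.
#' @export
randomSmallModel <- function(spec) {
    v <- validObject(spec, test = TRUE)
    if (!isTRUE(v)) stop(v)
    set.seed(spec@seed)
    k <- spec@nMetabolites
    mets <- paste0("M", seq_len(k))
    metTab <- data.frame(id = mets, name = mets,
                         isCofactor = FALSE,
                         defaultExchangeable = seq_len(k) %in% c(1L, k),
                         stringsAsFactors = FALSE)
    eqs <- character(); rev <- logical()
    for (i in seq_len(k - 1L)) {
        eqs <- c(eqs, paste(mets[i], "->", mets[i + 1L]))
        rev <- c(rev, FALSE)
    }
    nSide <- spec@nReactions - (k - 1L)
    for (s in seq_len(nSide)) {
        nsub <- sample(1:2, 1L); npro <- sample(1:2, 1L)
        sub <- sample(mets, nsub)
        pro <- sample(setdiff(mets, sub), npro)
        coefTxt <- function(ids) paste(
            vapply(ids, function(i) {
                cf <- sample(1:2, 1L)
                if (cf == 1L) i else paste(cf, i)
            }, ""), collapse = " + ")
        isRev <- stats::runif(1) < spec@reversibleFraction
        eqs <- c(eqs, paste(coefTxt(sub), if (isRev) "<->" else "->",
                            coefTxt(pro)))
        rev <- c(rev, isRev)
    }
    n <- length(eqs)
    rxnTab <- data.frame(id = sprintf("R%02d", seq_len(n)),
                         metacycId = sprintf("SYN-RXN-%02d", seq_len(n)),
                         index = seq_len(n), reversible = rev,
                         equation = eqs,
                         lb = ifelse(rev, -spec@boundMagnitude, 0),
                         ub = spec@boundMagnitude,
                         stringsAsFactors = FALSE)
    newStoichiometricModel(metTab, rxnTab,
                           constants = list(uptakeBound =
                                                spec@boundMagnitude / 2))
}

#' Uptake/export policy for a generated model
#'
#' @param model a model from [randomSmallModel()].
#' @return an \linkS4class{ExchangePolicy} taking the first metabolite up
#'   (bounded by the generator's uptake constant) and exporting the last.
#' @export
generatorPolicy <- function(model) {
    mets <- model@metabolites$id
    first <- mets[[1L]]; last <- mets[[length(mets)]]
    newExchangePolicy(stats::setNames(c("uptake", "accumulate"),
                                      c(first, last)),
                      uptakeBounds = stats::setNames(
                          -model@constants$uptakeBound, first))
}

#' Independent LP optimum by vertex enumeration
#'
#' Enumerates every basic solution of the equality system `S v - E e = 0`
#' (all combinations of basic variable sets with the nonbasic variables at
#' either bound), keeps the feasible ones, and returns the maximal
#' objective.  This is an exhaustive oracle that shares no code with the
#' simplex solver; it refuses problems beyond its enumeration budget rather
#' than approximating.
#'
#' @param model a small fully box-bounded \linkS4class{StoichiometricModel}.
#' @param policy an \linkS4class{ExchangePolicy}.
#' @param objective a \linkS4class{FluxObjective}.
#' @param enumLimit maximal number of basic solutions to enumerate.
#' @return list with `status` (`"optimal"` or `"infeasible"`) and `value`.
#' @export
bruteForceOptimum <- function(model, policy, objective, enumLimit = 3e5) {
    ## independent construction of the constraint data from the model
    S <- model@stoich
    rxn <- model@reactions
    open <- names(policy@modes)[policy@modes != "closed"]
    n <- ncol(S) + length(open)
    A <- matrix(0, nrow(S), n)
    A[, seq_len(ncol(S))] <- S
    lb <- numeric(n); ub <- numeric(n); cvec <- numeric(n)
    lb[seq_len(ncol(S))] <- rxn$lb
    ub[seq_len(ncol(S))] <- rxn$ub
    for (k in seq_along(open)) {
        met <- open[[k]]
        A[match(met, rownames(S)), ncol(S) + k] <- -1
        mode <- policy@modes[[met]]
        ## exchange bounds follow the engine's documented semantics,
        ## including the package box bound for unbounded directions
        if (mode == "accumulate") {
            lb[ncol(S) + k] <- 0; ub[ncol(S) + k] <- .BIG_BOUND
        } else if (mode == "uptake") {
            lb[ncol(S) + k] <- if (met %in% names(policy@uptakeBounds))
                policy@uptakeBounds[[met]] else -.BIG_BOUND
            ub[ncol(S) + k] <- 0
        } else if (mode == "fixed") {
            lb[ncol(S) + k] <- ub[ncol(S) + k] <- policy@uptakeBounds[[met]]
        } else {
            lb[ncol(S) + k] <- -.BIG_BOUND; ub[ncol(S) + k] <- .BIG_BOUND
        }
    }
    if (any(!is.finite(lb)) || any(!is.finite(ub)))
        stop("oracle requires a fully box-bounded problem")
    for (id in names(objective@reactionWeights))
        cvec[match(id, rxn$id)] <- objective@reactionWeights[[id]]
    for (id in names(objective@exchangeWeights))
        cvec[ncol(S) + match(id, open)] <- objective@exchangeWeights[[id]]
    ## reduce to independent rows; validate candidates on the full system
    qrA <- qr(t(A))
    rank <- qrA$rank
    rows <- sort(qrA$pivot[seq_len(rank)])
    A2 <- A[rows, , drop = FALSE]
    nb <- n - rank
    nBases <- choose(n, rank) * 2^nb
    if (nBases > enumLimit)
        stop("enumeration budget exceeded (", format(nBases, big.mark = ","),
             " basic solutions); refuse rather than approximate")
    best <- -Inf; feasible <- FALSE
    tol <- 1e-6 * max(1, max(abs(rxn$ub)))
    basesIdx <- utils::combn(n, rank)
    ## bound patterns for the nonbasic variables
    for (ci in seq_len(ncol(basesIdx))) {
        B <- basesIdx[, ci]
        N <- setdiff(seq_len(n), B)
        AB <- A2[, B, drop = FALSE]
        if (abs(det(AB)) < 1e-10) next
        ABi <- solve(AB)
        AN <- A2[, N, drop = FALSE]
        ## all 2^nb assignments of nonbasic vars to lb/ub
        if (nb > 0L) {
            patt <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), nb)))
            XN <- matrix(lb[N], nb, nrow(patt)) * t(!patt) +
                  matrix(ub[N], nb, nrow(patt)) * t(patt)
        } else XN <- matrix(0, 0L, 1L)
        XB <- -ABi %*% AN %*% XN            # b = 0
        okB <- XB >= lb[B] - tol & XB <= ub[B] + tol
        ok <- colSums(!okB) == 0L
        if (!any(ok)) next
        feasible <- TRUE
        vals <- as.numeric(crossprod(cvec[B], XB[, ok, drop = FALSE])) +
                as.numeric(crossprod(cvec[N], XN[, ok, drop = FALSE]))
        best <- max(best, vals)
    }
    if (!feasible) {
        ## a bounded non-empty polytope has a vertex; none feasible means
        ## the system is infeasible (checked on the reduced rows; dropped
        ## rows are linear combinations and hold automatically at b = 0)
        return(list(status = "infeasible", value = NA_real_))
    }
    list(status = "optimal", value = best)
}

#' Perturb a biomass coefficient set
#'
#' Multiplies every drain by an independent factor uniform in
#' `[1 - relativeNoise, 1 + relativeNoise]`; deterministic per seed.  Used
#' to show that the qualitative scenario outcomes do not hinge on the exact
#' coefficient values.
#'
#' @param spec a [BiomassSpec-class].
#' @param relativeNoise in `[0, 0.5]`.
#' @param seed integer seed.
#' @return a [BiomassSpec-class] with provenance `"standin:<seed>"`.
#' @export
perturbBiomass <- function(spec, relativeNoise, seed) {
    stopifnot(relativeNoise >= 0, relativeNoise <= 0.5)
    set.seed(as.integer(seed))
    f <- stats::runif(length(spec@drains),
                      1 - relativeNoise, 1 + relativeNoise)
    new("BiomassSpec", drains = spec@drains * f,
        provenance = paste0("standin:", as.integer(seed)))
}
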