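## Plain-text model exchange: a two-table TSV dialect and a JSON mirror.
##
## metabolites table: id, name, is_cofactor, default_exchangeable
## reactions table:   id, metacyc_id, index, equation, reversible, lb, ub
##
## Equations use the dialect of parseEquation(); "inf"/"-inf" spell
## unbounded flux bounds.  Reading then writing any valid model reproduces
## it (same ids, stoichiometry, bounds and exchangeable set).

.fmtBound <- function(x)
    ifelse(is.infinite(x), ifelse(x > 0, "inf", "-inf"),
           format(x, scientific = FALSE, trim = TRUE, digits = 15))

.parseBound <- function(s) {
    out <- suppressWarnings(as.numeric(s))
    out[s == "inf"] <- Inf
    out[s == "-inf"] <- -Inf
    out
}

#' Write a model to the tabular format
#'
#' @param model a \linkS4class{StoichiometricModel}.
#' @param basePath path prefix; `<basePath>_metabolites.tsv` and
#'   `<basePath>_reactions.tsv` are written.
#' @return invisibly, the two file paths.
#' @export
writeModelTable <- function(model, basePath) {
    met <- model@metabolites
    metOut <- data.frame(id = met$id, name = met$name,
                         is_cofactor = met$isCofactor,
                         default_exchangeable = met$defaultExchangeable)
    rxn <- model@reactions
    S <- model@stoich
    eqs <- vapply(seq_len(nrow(rxn)), function(j) {
        st <- S[, j]; deparseEquation(st[st != 0], rxn$reversible[[j]])
    }, "")
    rxnOut <- data.frame(id = rxn$id, metacyc_id = rxn$metacycId,
                         index = rxn$index, equation = eqs,
                         reversible = rxn$reversible,
                         lb = .fmtBound(rxn$lb), ub = .fmtBound(rxn$ub))
    paths <- paste0(basePath, c("_metabolites.tsv", "_reactions.tsv"))
    utils::write.table(metOut, paths[[1L]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(rxnOut, paths[[2L]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(paths)
}

#' Read a model from the tabular format
#'
#' Parse errors carry the offending line number of the reactions table.
#' The exchangeable set is reconstituted by the same rule used at
#' construction (default-exchangeables, cofactors, growth precursors).
#'
#' @param basePath path prefix as in [writeModelTable()].
#' @param constants optional constants list override.
#' @param biomass optional [BiomassSpec-class] to attach.
#' @return a \linkS4class{StoichiometricModel}.
#' @export
readModelTable <- function(basePath, constants = list(), biomass = NULL) {
    paths <- paste0(basePath, c("_metabolites.tsv", "_reactions.tsv"))
    for (p in paths) if (!file.exists(p)) stop("missing model file: ", p)
    met <- utils::read.table(paths[[1L]], sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = c("character", "character",
                                            "logical", "logical"))
    rxnRaw <- utils::read.table(paths[[2L]], sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE,
                                colClasses = "character")
    names(met) <- c("id", "name", "isCofactor", "defaultExchangeable")
    if (anyDuplicated(rxnRaw$id)) {
        dup <- rxnRaw$id[duplicated(rxnRaw$id)][[1L]]
        line <- which(rxnRaw$id == dup)[2L] + 1L
        stop("duplicate reaction id '", dup, "' at line ", line,
             " of ", paths[[2L]])
    }
    rxn <- data.frame(id = rxnRaw$id, metacycId = rxnRaw$metacyc_id,
                      index = as.integer(rxnRaw$index),
                      reversible = as.logical(rxnRaw$reversible),
                      equation = rxnRaw$equation,
                      lb = .parseBound(rxnRaw$lb),
                      ub = .parseBound(rxnRaw$ub),
                      stringsAsFactors = FALSE)
    bad <- which(!rxn$reversible & rxn$lb < 0)
    if (length(bad))
        stop("irreversible reaction '", rxn$id[bad[[1L]]],
             "' with negative lower bound at line ", bad[[1L]] + 1L,
             " of ", paths[[2L]])
    ## surface parse errors with their table line number
    for (j in seq_len(nrow(rxn))) {
        parsed <- tryCatch(parseEquation(rxn$equation[[j]]),
                           error = function(e) e)
        if (inherits(parsed, "error"))
            stop("line ", j + 1L, " of ", paths[[2L]], ": ",
                 conditionMessage(parsed))
        unknown <- setdiff(names(parsed$stoich), met$id)
        if (length(unknown))
            stop("line ", j + 1L, " of ", paths[[2L]],
                 ": reaction '", rxn$id[[j]],
                 "' references undeclared metabolite '", unknown[[1L]], "'")
    }
    newStoichiometricModel(met, rxn, constants = constants,
                           biomass = biomass)
}

#' Write a model as JSON
#'
#' Mirror of the tabular format with identical field names, for
#' programmatic use.
#'
#' @param model a \linkS4class{StoichiometricModel}.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeModelJSON <- function(model, path) {
    met <- model@metabolites
    rxn <- model@reactions
    S <- model@stoich
    eqs <- vapply(seq_len(nrow(rxn)), function(j) {
        st <- S[, j]; deparseEquation(st[st != 0], rxn$reversible[[j]])
    }, "")
    obj <- list(
        metabolites = data.frame(id = met$id, name = met$name,
                                 is_cofactor = met$isCofactor,
                                 default_exchangeable =
                                     met$defaultExchangeable),
        reactions = data.frame(id = rxn$id, metacyc_id = rxn$metacycId,
                               index = rxn$index, equation = eqs,
                               reversible = rxn$reversible,
                               lb = .fmtBound(rxn$lb),
                               ub = .fmtBound(rxn$ub)),
        constants = model@constants)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' Read a model from JSON
#'
#' @param path file written by [writeModelJSON()].
#' @param biomass optional [BiomassSpec-class] to attach.
#' @return a \linkS4class{StoichiometricModel}.
#' @export
readModelJSON <- function(path, biomass = NULL) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    met <- obj$metabolites
    names(met) <- c("id", "name", "isCofactor", "defaultExchangeable")
    rxn <- data.frame(id = obj$reactions$id,
                      metacycId = obj$reactions$metacyc_id,
                      index = as.integer(obj$reactions$index),
                      reversible = obj$reactions$reversible,
                      equation = obj$reactions$equation,
                      lb = .parseBound(obj$reactions$lb),
                      ub = .parseBound(obj$reactions$ub),
                      stringsAsFactors = FALSE)
    newStoichiometricModel(met, rxn, constants = obj$constants,
                           biomass = biomass)
}

#' Write a flux solution to TSV
#'
#' @param sol a \linkS4class{FluxSolution}.
#' @param model the model it was solved on (for MetaCyc ids).
#' @param path output file; a `#`-prefixed header records status and
#'   objective.
#' @return invisibly, `path`.
#' @export
writeFluxTSV <- function(sol, model, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# status: %s", sol@status), con)
    writeLines(sprintf("# objective: %.12g", sol@objectiveValue), con)
    rxn <- model@reactions
    df <- data.frame(id = c(rxn$id, names(sol@e)),
                     metacyc_id = c(rxn$metacycId,
                                    rep("exchange", length(sol@e))),
                     flux = c(unname(sol@v[rxn$id]), unname(sol@e)))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
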