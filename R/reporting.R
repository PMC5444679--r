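## Reporting front end: flux-map graph export, the all-figures runner and
## its reproducibility manifest.

#' Export a flux map as a graph file
#'
#' Writes a bipartite metabolite/reaction graph in GraphML or DOT.  Every
#' reaction of the model appears (zero-flux reactions with weight 0); edge
#' weights are absolute fluxes, reaction nodes carry the flux and its
#' fraction of the largest flux in the simulation (the greyscale of the
#' published maps), and metabolite nodes are annotated as consumed,
#' produced, accumulated or balanced from the exchange fluxes.
#'
#' @param report an optimal \linkS4class{ScenarioReport}.
#' @param model the model the scenario ran on.
#' @param path output file; format chosen by extension (`.graphml` or
#'   `.dot`/`.gv`).
#' @return invisibly, `path`.
#' @export
exportFluxGraph <- function(report, model, path) {
    if (report@solution@status != "optimal")
        stop("cannot export a non-optimal report")
    v <- report@solution@v
    e <- report@solution@e
    S <- model@stoich
    vmax <- max(abs(v), 1e-12)
    metStatus <- vapply(rownames(S), function(m) {
        if (m %in% names(e)) {
            if (e[[m]] > .TOL_FLUX) "accumulated"
            else if (e[[m]] < -.TOL_FLUX) "consumed"
            else "balanced"
        } else "balanced"
    }, "")
    nodes <- data.frame(
        name = c(rownames(S), colnames(S)),
        type = c(rep("metabolite", nrow(S)), rep("reaction", ncol(S))),
        status = c(metStatus, rep(NA_character_, ncol(S))),
        flux = c(rep(NA_real_, nrow(S)), unname(v[colnames(S)])),
        fluxFraction = c(rep(NA_real_, nrow(S)),
                         unname(abs(v[colnames(S)]) / vmax)),
        stringsAsFactors = FALSE)
    edges <- do.call(rbind, lapply(colnames(S), function(j) {
        mets <- rownames(S)[S[, j] != 0]
        ## substrates point into the reaction, products out of it, for the
        ## net forward direction; reversed flux flips roles
        coef <- S[mets, j]
        fwd <- v[[j]] >= 0
        from <- ifelse(xor(coef < 0, !fwd), mets, j)
        to <- ifelse(xor(coef < 0, !fwd), j, mets)
        data.frame(from = from, to = to, weight = abs(v[[j]]),
                   stringsAsFactors = FALSE)
    }))
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = nodes)
    fmt <- if (grepl("\\.(dot|gv)$", path)) "dot" else "graphml"
    igraph::write_graph(g, path, format = fmt)
    invisible(path)
}

#' Run the full figure suite and write its outputs
#'
#' Runs the selected figure scenarios against the reference model (or a
#' supplied model), writing per-scenario flux TSVs, JSON reports and a
#' machine-readable manifest sufficient to reproduce the outputs
#' bit-identically (package version, model digest, scenario list,
#' tolerances).  Unknown scenario names are rejected before anything is
#' solved.
#'
#' @param outDir output directory (created if needed).
#' @param scenarios scenario ids, by default all of fig1..fig11.
#' @param model a \linkS4class{StoichiometricModel}.
#' @param fva run FVA per scenario (slower).
#' @param verbose print progress to stderr.
#' @return invisibly, named list of \linkS4class{ScenarioReport}s.
#' @export
runFigures <- function(outDir, scenarios = paste0("fig", 1:11),
                       model = buildReferenceModel(), fva = TRUE,
                       verbose = FALSE) {
    bad <- setdiff(scenarios, paste0("fig", 1:11))
    if (length(bad)) stop("unknown scenario '", bad[[1L]], "'")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    reports <- list()
    for (fig in scenarios) {
        if (verbose) message("running ", fig)
        cfg <- scenarioRegistry(fig, model)
        rep <- runScenario(model, cfg, fva = fva)
        reports[[fig]] <- rep
        if (rep@solution@status == "optimal") {
            writeFluxTSV(rep@solution, .applyScenarioModel(model, cfg),
                         file.path(outDir, paste0(fig, "_fluxes.tsv")))
        }
        jsonlite::write_json(.reportToList(rep),
                             file.path(outDir, paste0(fig, "_report.json")),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    manifest <- list(
        package = "marxFBA",
        version = as.character(utils::packageVersion("marxFBA")),
        scenarios = scenarios,
        biomassProvenance = model@biomass@provenance,
        constants = model@constants,
        nReactions = nrow(model@reactions),
        tolerances = list(residual = .TOL_RESIDUAL,
                          objective = .TOL_OBJECTIVE, flux = .TOL_FLUX),
        lpBoxBound = .BIG_BOUND)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(reports)
}

.reportToList <- function(rep) {
    sol <- rep@solution
    out <- list(scenario = rep@config@name,
                carbonSource = rep@config@carbonSource,
                aerobic = rep@config@aerobic,
                inactiveReactions = rep@config@inactiveReactions,
                status = sol@status)
    if (sol@status == "optimal") {
        out$objective <- sol@objectiveValue
        out$growth <- rep@growth
        out$balances <- as.list(rep@balances)
        out$fluxes <- as.list(sol@v)
        out$exchangeFluxes <- as.list(sol@e)
        out$cycleAuditClean <- length(rep@cycleAudit) == 0L
        if (nrow(rep@ranges@ranges))
            out$fva <- rep@ranges@ranges
    }
    out
}
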