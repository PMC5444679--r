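test_that("the registry encodes the figure captions", {
    mod <- buildReferenceModel()
    f9 <- scenarioRegistry("fig9", mod)
    expect_length(f9@cofactorSwaps, 1)
    sw <- f9@cofactorSwaps[[1]]
    expect_equal(sw$reaction, "G6PDH")
    expect_equal(sw$from, c("NADP", "NADPH"))
    expect_equal(sw$to, c("NAD", "NADH"))
    f11 <- scenarioRegistry("fig11", mod)
    expect_false(f11@aerobic)
    expect_false("O2" %in% names(f11@exchangePolicy@modes))
    expect_false("MAE" %in% f11@inactiveReactions)
    f7 <- scenarioRegistry("fig7", mod)
    expect_false("ATP" %in% names(f7@exchangePolicy@modes))  # closed
    expect_equal(unname(f7@exchangePolicy@modes["GLYC"]), "accumulate")
    expect_true("FBP" %in% f7@inactiveReactions)
    ## the carbon source is taken up at the model bound
    expect_equal(unname(f7@exchangePolicy@uptakeBounds["XYL"]), -10)
    expect_error(scenarioRegistry("fig99", mod), "unknown scenario")
})

test_that("reaction activity edits are immutable and effective", {
    mod <- buildReferenceModel()
    cfg <- scenarioRegistry("fig5", mod)
    cfg2 <- setReactionActivity(cfg, "PFK", TRUE, mod)
    expect_true("PFK" %in% cfg@inactiveReactions)     # original untouched
    expect_false("PFK" %in% cfg2@inactiveReactions)
    rep <- runScenario(mod, cfg, fva = FALSE, audit = FALSE)
    expect_equal(fluxes(rep)[["PFK"]], 0)
    cfg3 <- setReactionActivity(cfg, "vGrowth", FALSE, mod)
    rep3 <- runScenario(mod, cfg3, fva = FALSE, audit = FALSE)
    expect_equal(objectiveValue(rep3@solution), 0, tolerance = 1e-9)
    expect_error(setReactionActivity(cfg, "NOPE", FALSE, mod),
                 "unknown reaction")
})

test_that("cofactor swapping transfers coefficients and is an involution", {
    mod <- buildReferenceModel()
    sw <- swapCofactor(mod, "G6PDH", c("NADP", "NADPH"), c("NAD", "NADH"))
    expect_equal(unname(sw@stoich["NADH", "G6PDH"]), 1)
    expect_equal(unname(sw@stoich["NADPH", "G6PDH"]), 0)
    expect_equal(unname(sw@stoich["NAD", "G6PDH"]), -1)
    back <- swapCofactor(sw, "GLU6PDEHYDROG-RXN", c("NAD", "NADH"),
                         c("NADP", "NADPH"))
    expect_equal(max(abs(back@stoich - mod@stoich)), 0)
    expect_error(swapCofactor(mod, "PGI", c("NADP", "NADPH"),
                              c("NAD", "NADH")), "does not use")
})

test_that("glucose-6-phosphate isomerase flips direction from glucose to xylose", {
    mod <- buildReferenceModel()
    r1 <- runFig(mod, "fig1")
    r2 <- runFig(mod, "fig2")
    expect_gt(fluxes(r1)[["PGI"]], 0)   # glycolytic on glucose
    expect_lt(fluxes(r2)[["PGI"]], 0)   # gluconeogenic on xylose
    cmp <- compareConditions(list(r1, r2))
    expect_true("PGI" %in% cmp$flips$reaction)
    ## ATP overproduction is larger on xylose
    expect_gt(cmp$values["ATP", "fig2"], cmp$values["ATP", "fig1"])
    ## identical reports: unit ratios and no flips
    same <- compareConditions(list(r2, r2))
    expect_true(all(abs(na.omit(unlist(same$ratios)) - 1) < 1e-9))
    expect_equal(nrow(same$flips), 0)
})

test_that("expression fold changes reproduce the published table", {
    fc <- expressionFoldChange(kmExpression())
    expect_equal(round(fc$foldChange[fc$gene == "FBP1"], 2), 27.34)
    expect_equal(round(fc$foldChange[fc$gene == "PFK1"], 2), 0.21)
    expect_equal(round(fc$foldChange[fc$gene == "PFK2"], 2), 0.21)
    ## equal FPKM gives unit fold change; zero denominators are flagged NA
    eq <- expressionFoldChange(data.frame(gene = "X", fpkmGlucose = 5,
                                          fpkmXylose = 5))
    expect_equal(eq$foldChange, 1)
    z <- expressionFoldChange(data.frame(gene = "Z", fpkmGlucose = 0,
                                         fpkmXylose = 3))
    expect_true(is.na(z$foldChange) && z$undefined)
    expect_error(expressionFoldChange(data.frame(gene = "N",
        fpkmGlucose = -1, fpkmXylose = 1)), "non-negative")
})

test_that("scenario reports expose balances, growth and accessors", {
    mod <- buildReferenceModel()
    rep <- runFig(mod, "fig2", fva = TRUE)
    expect_s4_class(rep, "ScenarioReport")
    expect_equal(growthRate(rep), objectiveValue(rep@solution),
                 tolerance = 1e-9)
    b <- fluxBalances(rep)
    expect_true(all(c("ATP", "NADPH", "GLYC", "O2") %in% names(b)))
    expect_equal(unname(b["NADPH"]), 0)          # closed balance
    expect_lt(unname(b["O2"]), 0)                # net uptake
    expect_equal(metaboliteBalance(rep@solution, "NADH"), 0)
    expect_error(metaboliteBalance(rep@solution, "NOPE"), "unknown")
    ## the refined solution sits inside its own FVA ranges
    fr <- rep@ranges@ranges
    all2 <- c(fluxes(rep), exchangeFluxes(rep@solution))
    ok <- vapply(seq_len(nrow(fr)), function(r)
        all2[[fr$id[r]]] >= fr$min[r] - 1e-6 &&
        all2[[fr$id[r]]] <= fr$max[r] + 1e-6, NA)
    expect_true(all(ok))
})

test_that("graph export writes every reaction with its flux weight", {
    mod <- buildReferenceModel()
    rep <- runFig(mod, "fig3")
    path <- tempfile(fileext = ".graphml")
    exportFluxGraph(rep, mod, path)
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- igraph::vertex_attr(g, "name")
    expect_true(all(reactions(mod)$id %in% nodes))
    ## complete PPP cycling runs through fructose-bisphosphatase
    fbpFlux <- igraph::vertex_attr(g, "flux")[match("FBP", nodes)]
    expect_gt(fbpFlux, 0)
    ## ATP is annotated as accumulated in the xylose reference scenario
    rep2 <- runFig(mod, "fig2")
    path2 <- tempfile(fileext = ".graphml")
    exportFluxGraph(rep2, mod, path2)
    g2 <- igraph::read_graph(path2, format = "graphml")
    n2 <- igraph::vertex_attr(g2, "name")
    expect_equal(igraph::vertex_attr(g2, "status")[match("ATP", n2)],
                 "accumulated")
    ## zero-flux reactions stay in the graph with weight 0
    zero <- igraph::vertex_attr(g2, "flux")[match("ICL", n2)]
    expect_equal(zero, 0)
})

test_that("the figure runner writes fluxes, reports and a manifest", {
    outDir <- tempfile()
    reports <- runFigures(outDir, scenarios = c("fig2", "fig3"),
                          fva = FALSE)
    expect_true(file.exists(file.path(outDir, "fig2_fluxes.tsv")))
    expect_true(file.exists(file.path(outDir, "fig3_report.json")))
    man <- jsonlite::read_json(file.path(outDir, "manifest.json"))
    expect_equal(man$package, "marxFBA")
    expect_equal(man$nReactions, 56L)
    expect_equal(man$tolerances$residual, 1e-9)
    rep3 <- jsonlite::read_json(file.path(outDir, "fig3_report.json"))
    expect_equal(rep3$exchangeFluxes$NADPH, 90, tolerance = 1e-6)
    expect_error(runFigures(outDir, scenarios = "fig99"), "unknown")
})
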