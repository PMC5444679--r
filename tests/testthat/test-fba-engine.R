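test_that("a linear chain carries its uptake bound to the export", {
    mod <- makeChainModel()
    lp <- assembleFluxLP(mod, chainPolicy(mod, uptake = 10),
                         exportObjective())
    sol <- solveFBA(lp)
    expect_equal(solutionStatus(sol), "optimal")
    expect_equal(objectiveValue(sol), 10, tolerance = 1e-9)
    expect_equal(unname(fluxes(sol)), c(10, 10), tolerance = 1e-9)
    expect_lt(sol@residual, 1e-9)
})

test_that("closing every exchange forces the null flux", {
    mod <- buildReferenceModel()
    pol <- newExchangePolicy(setNames(character(), character()))
    lp <- assembleFluxLP(mod, pol, newFluxObjective(
        reactions = c(vGrowth = 1)))
    sol <- solveFBA(lp)
    ref <- parsimoniousRefine(lp, sol@objectiveValue)
    expect_equal(objectiveValue(sol), 0, tolerance = 1e-9)
    expect_lt(max(abs(fluxes(ref))), 1e-6)
})

test_that("zero carbon uptake means zero growth", {
    mod <- buildReferenceModel()
    pol <- standardExchangePolicy(mod, "glucose", accumulate = "ATP")
    pol@uptakeBounds["GLC"] <- 0
    lp <- assembleFluxLP(mod, pol, newFluxObjective(
        reactions = c(vGrowth = 1)))
    expect_equal(objectiveValue(solveFBA(lp)), 0, tolerance = 1e-9)
})

test_that("infeasible problems are reported as such, never as zeros", {
    ## a forced internal flux into a closed dead end cannot balance
    mets <- data.frame(id = c("A", "B"), name = c("A", "B"),
                       isCofactor = FALSE,
                       defaultExchangeable = c(TRUE, FALSE))
    rxns <- data.frame(id = "R1", metacycId = "X", index = 1L,
                       reversible = FALSE, equation = "A -> B",
                       lb = 1, ub = 10)
    mod <- newStoichiometricModel(mets, rxns)
    pol <- newExchangePolicy(c(A = "uptake"), uptakeBounds = c(A = -10))
    lp <- assembleFluxLP(mod, pol, newFluxObjective(reactions = c(R1 = 1)))
    sol <- solveFBA(lp)
    expect_equal(solutionStatus(sol), "infeasible")
    expect_true(is.na(objectiveValue(sol)))
    oracle <- bruteForceOptimum(mod, pol,
                                newFluxObjective(reactions = c(R1 = 1)))
    expect_equal(oracle$status, "infeasible")
})

test_that("parsimonious refinement strips gratuitous loop flux", {
    mod <- makeLoopModel()
    lp <- assembleFluxLP(mod, chainPolicy(mod), exportObjective())
    sol <- solveFBA(lp)
    expect_equal(objectiveValue(sol), 10, tolerance = 1e-9)
    ref <- parsimoniousRefine(lp, objectiveValue(sol))
    expect_equal(objectiveValue(ref), objectiveValue(sol), tolerance = 1e-9)
    expect_equal(unname(fluxes(ref)[c("L1", "L2")]), c(0, 0),
                 tolerance = 1e-9)
})

test_that("FVA pins a fully determined chain and exposes free loops", {
    mod <- makeChainModel()
    lp <- assembleFluxLP(mod, chainPolicy(mod), exportObjective())
    opt <- objectiveValue(solveFBA(lp))
    fr <- fluxVariability(lp, opt)@ranges
    expect_equal(fr$min, fr$max, tolerance = 1e-7)
    ## the loop model at the same optimum has unbounded loop ranges,
    ## flagging the cycle, and every refined flux lies inside its range
    mod2 <- makeLoopModel()
    lp2 <- assembleFluxLP(mod2, chainPolicy(mod2), exportObjective())
    opt2 <- objectiveValue(solveFBA(lp2))
    ref2 <- parsimoniousRefine(lp2, opt2)
    fr2 <- fluxVariability(lp2, opt2)@ranges
    loop <- fr2[fr2$id %in% c("L1", "L2"), ]
    expect_true(all(loop$max >= 1e5))
    all2 <- c(fluxes(ref2), exchangeFluxes(ref2))
    for (r in seq_len(nrow(fr2)))
        expect_true(all2[[fr2$id[r]]] >= fr2$min[r] - 1e-6 &&
                    all2[[fr2$id[r]]] <= fr2$max[r] + 1e-6)
})

test_that("the optimum is homogeneous in the carbon-uptake bound", {
    mod <- buildReferenceModel()
    base <- NULL
    for (k in c(1, 0.5, 2, 5)) {
        pol <- standardExchangePolicy(mod, "xylose", accumulate = "ATP")
        pol@uptakeBounds["XYL"] <- -10 * k
        lp <- assembleFluxLP(mod, pol,
                             newFluxObjective(reactions = c(vGrowth = 1)))
        opt <- objectiveValue(solveFBA(lp))
        if (k == 1) base <- opt
        expect_equal(opt, base * k, tolerance = 1e-6)
    }
})

test_that("deactivation never helps and opening an exchange never hurts", {
    mod <- buildReferenceModel()
    cfg <- scenarioRegistry("fig2", mod)
    base <- growthRate(runScenario(mod, cfg, fva = FALSE, audit = FALSE))
    set.seed(7)
    for (rid in sample(setdiff(reactions(mod)$id, "vGrowth"), 6)) {
        cfg2 <- setReactionActivity(cfg, rid, FALSE, mod)
        rep2 <- runScenario(mod, cfg2, fva = FALSE, audit = FALSE)
        g2 <- if (rep2@solution@status == "optimal") growthRate(rep2) else 0
        expect_lte(g2, base + 1e-7)
    }
    ## opening the acetate exchange to free uptake can only help
    pol <- cfg@exchangePolicy
    pol@modes["AC"] <- "free"
    cfg3 <- initialize(cfg, exchangePolicy = pol)
    g3 <- growthRate(runScenario(mod, cfg3, fva = FALSE, audit = FALSE))
    expect_gte(g3, base - 1e-7)
})

test_that("mass-balance residuals stay below 1e-9 across the figure suite", {
    mod <- buildReferenceModel()
    for (fig in c("fig1", "fig2", "fig3", "fig7", "fig11")) {
        rep <- runFig(mod, fig)
        expect_equal(rep@solution@status, "optimal", info = fig)
        expect_lt(rep@solution@residual, 1e-9)
    }
})
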