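test_that("model generation is deterministic and structurally sound", {
    sp <- generatorSpec(6, 8, 0.4, 10, 42)
    m1 <- randomSmallModel(sp)
    m2 <- randomSmallModel(sp)
    expect_identical(m1@stoich, m2@stoich)
    expect_identical(m1@reactions, m2@reactions)
    ## no fatal findings by construction
    f <- validateModel(m1)
    expect_false(any(f$class == "bound_violation"))
    expect_false(any(f$class == "orphan"))
    expect_true(all(c("M1", "M6") %in% exchangeables(m1)))
})

test_that("the planted pathway alone carries the uptake to the export", {
    sp <- generatorSpec(5, 4, 0, 10, 1)   # chain only, no side reactions
    m <- randomSmallModel(sp)
    lp <- assembleFluxLP(m, generatorPolicy(m),
                         newFluxObjective(exchanges = c(M5 = 1)))
    ## unit-yield chain: export optimum equals the uptake bound
    expect_equal(objectiveValue(solveFBA(lp)), m@constants$uptakeBound,
                 tolerance = 1e-9)
})

test_that("the LP optimum matches vertex enumeration on 50 seeded models", {
    worst <- 0
    for (seed in 1:50) {
        nMet <- 4L + seed %% 3L
        sp <- generatorSpec(nMet, nMet + seed %% 3L, 0.3, 10, seed)
        m <- randomSmallModel(sp)
        pol <- generatorPolicy(m)
        obj <- newFluxObjective(exchanges = setNames(
            1, paste0("M", sp@nMetabolites)))
        s <- solveFBA(assembleFluxLP(m, pol, obj))
        o <- bruteForceOptimum(m, pol, obj)
        expect_equal(solutionStatus(s), o$status, info = paste("seed", seed))
        if (o$status == "optimal")
            worst <- max(worst, abs(objectiveValue(s) - o$value))
    }
    expect_lt(worst, 1e-7)
})

test_that("the oracle refuses problems beyond its enumeration budget", {
    m <- randomSmallModel(generatorSpec(8, 12, 0.5, 10, 3))
    pol <- generatorPolicy(m)
    obj <- newFluxObjective(exchanges = c(M8 = 1))
    expect_error(bruteForceOptimum(m, pol, obj, enumLimit = 10),
                 "budget exceeded")
})

test_that("biomass perturbation is seeded, bounded and labelled", {
    base <- biomassSpec()
    expect_identical(perturbBiomass(base, 0, 1)@drains, base@drains)
    p1 <- perturbBiomass(base, 0.2, 7)
    p2 <- perturbBiomass(base, 0.2, 7)
    expect_identical(p1@drains, p2@drains)
    expect_equal(p1@provenance, "standin:7")
    expect_true(all(abs(p1@drains / base@drains - 1) <= 0.2 + 1e-12))
    ## multiplicative noise preserves drain signs up to the maximal noise
    p3 <- perturbBiomass(base, 0.5, 11)
    pre <- setdiff(names(base@drains), "NADH")
    expect_true(all(p3@drains[pre] > 0))
    expect_error(perturbBiomass(base, 0.7, 1))
})
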