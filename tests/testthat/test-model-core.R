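test_that("reference model has the documented structure", {
    mod <- buildReferenceModel()
    rxn <- reactions(mod)
    expect_equal(nrow(rxn), 56)
    expect_setequal(rxn$index, 1:56)
    expect_equal(anyDuplicated(rxn$index), 0L)
    SE <- stoichiometricMatrix(mod)
    expect_equal(ncol(SE$S), 56)
    ## E is an identity-like selector: one unit entry per column
    expect_true(all(colSums(SE$E != 0) == 1))
    expect_true(all(SE$E[SE$E != 0] == 1))
    ## every irreversible reaction is constrained below by exactly zero
    expect_true(all(rxn$lb[!rxn$reversible] == 0))
    ## cofactors participate in at least two reactions
    cof <- metabolites(mod)$id[metabolites(mod)$isCofactor]
    expect_true(all(rowSums(SE$S[cof, ] != 0) >= 2))
    expect_equal(mod@constants$poRatio, 2.5)
    expect_equal(mod@constants$uptakeBound, 10)
})

test_that("fructose-bisphosphatase is transcribed correctly", {
    mod <- buildReferenceModel()
    rxn <- reactions(mod)
    j <- which(rxn$metacycId == "F16BDEPHOS-RXN")
    expect_equal(rxn$index[j], 19L)
    expect_false(rxn$reversible[j])
    col <- mod@stoich[, j]
    expect_equal(unname(col["F16BP"]), -1)
    expect_equal(unname(col["H2O"]), -1)
    expect_equal(unname(col["F6P"]), 1)
    expect_equal(unname(col["PI"]), 1)
    expect_equal(sum(col != 0), 4)
})

test_that("the FBP/PFK pair nets pure ATP hydrolysis", {
    mod <- buildReferenceModel()
    S <- mod@stoich
    net <- S[, "FBP"] + S[, "PFK"]
    ## all sugar phosphates cancel; only the ATP <-> ADP + Pi (+ water)
    ## conversion remains
    expect_equal(unname(net["ATP"]), -1)
    expect_equal(unname(net["ADP"]), 1)
    expect_equal(unname(net["PI"]), 1)
    expect_equal(unname(net["H2O"]), -1)
    expect_equal(sum(net != 0), 4)
})

test_that("the validator is clean on the reference model and finds defects", {
    mod <- buildReferenceModel()
    f <- validateModel(mod)
    expect_equal(nrow(f), 0)
    ## a metabolite only produced and not exchangeable is a dead end
    mets <- data.frame(id = c("A", "B"), name = c("A", "B"),
                       isCofactor = FALSE,
                       defaultExchangeable = c(TRUE, FALSE))
    rxns <- data.frame(id = "R1", metacycId = "X", index = 1L,
                       reversible = FALSE, equation = "A -> B",
                       lb = 0, ub = 10)
    bad <- newStoichiometricModel(mets, rxns)
    f <- validateModel(bad)
    expect_true("dead_end" %in% f$class)
    expect_true(any(grepl("'B'", f$message)))
})

test_that("removing the growth reaction orphans the biomass metabolite", {
    mod <- buildReferenceModel()
    base <- tempfile()
    writeModelTable(mod, base)
    rxnFile <- paste0(base, "_reactions.tsv")
    lines <- readLines(rxnFile)
    writeLines(lines[!grepl("^vGrowth\t", lines)], rxnFile)
    edited <- readModelTable(base)
    f <- validateModel(edited)
    expect_true(any(f$class == "orphan" & f$id == "BIOMASS"))
})

test_that("biomass specs are validated", {
    expect_s4_class(biomassSpec(), "BiomassSpec")
    expect_error(buildReferenceModel(
        new("BiomassSpec", drains = c(G6P = 1, NADPH = 1),
            provenance = "broken")), "ATP")
    ## a negative precursor drain is named in the failure
    expect_error(validObject(
        new("BiomassSpec",
            drains = c(G6P = -1, ATP = 1, NADPH = 1),
            provenance = "broken")), "G6P")
})
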