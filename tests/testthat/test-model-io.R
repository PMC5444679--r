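test_that("equation strings round-trip through the parser", {
    cases <- list("2 A + B -> C", "A <-> B", "0.5 O2 + NADH -> NAD + H2O",
                  "PYR + 2 ATP + H2O -> PEP + 2 ADP + PI")
    for (eq in cases) {
        p <- parseEquation(eq)
        expect_equal(parseEquation(deparseEquation(p$stoich, p$reversible)),
                     p, info = eq)
    }
    expect_error(parseEquation("A -> "), "empty side")
    expect_error(parseEquation("A + -> B"), "cannot parse")
})

test_that("the tabular format round-trips the reference model", {
    mod <- buildReferenceModel()
    base <- tempfile()
    writeModelTable(mod, base)
    m2 <- readModelTable(base, constants = mod@constants)
    expect_identical(m2@reactions$id, mod@reactions$id)
    expect_identical(m2@reactions$metacycId, mod@reactions$metacycId)
    expect_identical(m2@reactions$lb, mod@reactions$lb)
    expect_identical(m2@reactions$ub, mod@reactions$ub)
    expect_identical(m2@metabolites, mod@metabolites)
    expect_identical(m2@exchangeable, mod@exchangeable)
    expect_equal(max(abs(m2@stoich - mod@stoich)), 0)
})

test_that("the JSON mirror round-trips and ships as extdata", {
    mod <- buildReferenceModel()
    path <- tempfile(fileext = ".json")
    writeModelJSON(mod, path)
    m2 <- readModelJSON(path)
    expect_equal(max(abs(m2@stoich - mod@stoich)), 0)
    expect_identical(m2@constants$poRatio, mod@constants$poRatio)
    shipped <- system.file("extdata", "kmarx_central_reactions.tsv",
                           package = "marxFBA")
    expect_true(nzchar(shipped))
    m3 <- readModelTable(sub("_reactions\\.tsv$", "", shipped))
    expect_equal(max(abs(m3@stoich - mod@stoich)), 0)
})

test_that("parse errors carry the metabolite and line number", {
    mod <- buildReferenceModel()
    base <- tempfile()
    writeModelTable(mod, base)
    rxnFile <- paste0(base, "_reactions.tsv")
    lines <- readLines(rxnFile)
    lines[3] <- sub("X5P", "NOSUCHMET", lines[3])
    writeLines(lines, rxnFile)
    expect_error(readModelTable(base), "NOSUCHMET")
    expect_error(readModelTable(base), "line 3")
})

test_that("duplicate ids and bad bounds are rejected on read", {
    mod <- buildReferenceModel()
    base <- tempfile()
    writeModelTable(mod, base)
    rxnFile <- paste0(base, "_reactions.tsv")
    lines <- readLines(rxnFile)
    writeLines(c(lines, lines[2]), rxnFile)
    expect_error(readModelTable(base), "duplicate reaction id")
    ## irreversible with a negative lower bound is a validation error
    writeLines(sub("\tFALSE\t0\t", "\tFALSE\t-5\t", lines), rxnFile)
    expect_error(readModelTable(base), "negative lower bound")
})

test_that("flux solutions serialize to TSV with a status header", {
    mod <- makeChainModel()
    lp <- assembleFluxLP(mod, chainPolicy(mod), exportObjective())
    sol <- solveFBA(lp)
    path <- tempfile(fileext = ".tsv")
    writeFluxTSV(sol, mod, path)
    lines <- readLines(path)
    expect_match(lines[1], "status: optimal")
    expect_match(lines[2], "objective: 10")
    tab <- read.table(path, sep = "\t", header = TRUE, comment.char = "#")
    expect_true(all(c("R1", "R2", "A", "C") %in% tab$id))
})
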