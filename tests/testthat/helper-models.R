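## Small hand-built models used across the engine tests.

## linear uptake -> export chain: A -> B -> C
makeChainModel <- function(boundMagnitude = 100) {
    mets <- data.frame(id = c("A", "B", "C"),
                       name = c("A", "B", "C"),
                       isCofactor = FALSE,
                       defaultExchangeable = c(TRUE, FALSE, TRUE))
    rxns <- data.frame(id = c("R1", "R2"),
                       metacycId = c("CHAIN-1", "CHAIN-2"),
                       index = 1:2, reversible = FALSE,
                       equation = c("A -> B", "B -> C"),
                       lb = 0, ub = boundMagnitude)
    newStoichiometricModel(mets, rxns,
                           constants = list(uptakeBound = 10))
}

## chain A -> B -> C with a gratuitous internal loop B <-> D
makeLoopModel <- function(boundMagnitude = 100) {
    mets <- data.frame(id = c("A", "B", "C", "D"),
                       name = c("A", "B", "C", "D"),
                       isCofactor = FALSE,
                       defaultExchangeable = c(TRUE, FALSE, TRUE, FALSE))
    rxns <- data.frame(id = c("R1", "R2", "L1", "L2"),
                       metacycId = paste0("LOOP-", 1:4),
                       index = 1:4, reversible = FALSE,
                       equation = c("A -> B", "B -> C", "B -> D", "D -> B"),
                       lb = 0, ub = c(boundMagnitude, boundMagnitude,
                                      Inf, Inf))
    newStoichiometricModel(mets, rxns,
                           constants = list(uptakeBound = 10))
}

chainPolicy <- function(model, uptake = 10)
    newExchangePolicy(c(A = "uptake", C = "accumulate"),
                      uptakeBounds = c(A = -uptake))

exportObjective <- function(met = "C") newFluxObjective(exchanges =
                                                            setNames(1, met))

## run one registry scenario on a model, without the slow extras
runFig <- function(model, fig, fva = FALSE, audit = FALSE)
    runScenario(model, scenarioRegistry(fig, model), fva = fva,
                audit = audit)
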