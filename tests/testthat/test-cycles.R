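cycleKeys <- function(cycles)
    vapply(cycles, function(cy) paste(sort(cy$reactions), collapse = "+"), "")

test_that("the FBP/PFK substrate cycle is detected with its net conversion", {
    mod <- buildReferenceModel()
    cyc <- detectInternalCycles(mod)
    keys <- cycleKeys(cyc)
    expect_true("FBP+PFK" %in% keys)
    fbp <- cyc[[match("FBP+PFK", keys)]]
    expect_equal(unname(fbp$net["ATP"]), -1, tolerance = 1e-6)
    expect_equal(unname(fbp$net["ADP"]), 1, tolerance = 1e-6)
    ## deactivating one member removes the cycle
    cyc2 <- detectInternalCycles(mod, inactive = "FBP")
    expect_false("FBP+PFK" %in% cycleKeys(cyc2))
})

test_that("the malic-enzyme cycle hydrolyses ATP and converts NADH to NADPH", {
    mod <- buildReferenceModel()
    cyc <- detectInternalCycles(mod)
    keys <- cycleKeys(cyc)
    expect_true("MAE+MDH+PYC" %in% keys)
    mal <- cyc[[match("MAE+MDH+PYC", keys)]]
    expect_equal(unname(mal$net["ATP"]), -1, tolerance = 1e-6)
    expect_equal(unname(mal$net["NADH"]), -1, tolerance = 1e-6)
    expect_equal(unname(mal$net["NADPH"]), 1, tolerance = 1e-6)
})

test_that("refined figure solutions carry no removable cycle flux", {
    mod <- buildReferenceModel()
    for (fig in c("fig2", "fig8", "fig11")) {
        rep <- runFig(mod, fig, audit = TRUE)
        expect_length(rep@cycleAudit, 0)
    }
})

test_that("the deliberate FBP/PFK cycle of the closed-ATP scenario is kept", {
    ## with the ATP balance closed the cycle is the ATP sink: it carries
    ## flux yet is not flagged, because removing it would break the balance
    mod <- buildReferenceModel()
    rep <- runFig(mod, "fig8", audit = TRUE)
    v <- fluxes(rep)
    expect_gt(v[["FBP"]], 1)
    expect_gt(v[["PFK"]], 1)
    expect_length(rep@cycleAudit, 0)
})
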