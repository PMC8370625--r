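test_that("tolerance check follows the relative-deviation rule", {
    expect_true(withinTolerance(1.0, 1.0, 0.01))
    ## a 3% relative deviation sits above 2.5% and 1%, below 5%
    expect_true(withinTolerance(1.0, 0.97, 0.05))
    expect_false(withinTolerance(1.0, 0.97, 0.025))
    expect_false(withinTolerance(1.0, 0.97, 0.01))
    ## degenerate kinetic rate: no drift only if both are zero
    expect_true(withinTolerance(0, 0, 0.01))
    expect_false(withinTolerance(0, 0.5, 0.01))
    expect_error(withinTolerance(1, 1, 0), "tol")
})

test_that("solve frequency spans its limit cases and is monotone in tol", {
    phys <- refPhys(); parts <- refParts(); kin <- refKin(); net <- refNet()
    sc <- ScenarioConfig(tEnd = 150, tol = 0.01)

    ## tol -> infinity: exactly the initial solve
    one <- runDFBA(phys, parts, kin, net, sc, tol = 1e9)
    expect_equal(one@meta$solveCount, 1L)

    ## tol -> 0+: one solve per step (the upper bound)
    all <- runDFBA(phys, parts, kin, net, sc, tol = 1e-12)
    expect_equal(all@meta$solveCount, 150L)

    counts <- vapply(c(0.10, 0.01, 0.001), function(tl)
        runDFBA(phys, parts, kin, net, sc, tol = tl)@meta$solveCount,
        integer(1))
    expect_true(all(diff(counts) >= 0))
    expect_true(all(counts <= 150L))
})

test_that("held fluxes drive the ODE and the audit log records each solve", {
    cts <- baselineRun()
    expect_gt(cts@meta$solveCount, 10)
    expect_lte(cts@meta$solveCount, 1000)
    log <- cts@meta$solveLog
    expect_equal(nrow(log), cts@meta$solveCount)
    expect_true(all(log$trigger %in% c("initial", "dose", "adh", "aldh2")))
    ## held-rate safety: the liver route advances no faster than the held
    ## bound over any reporting step
    inc <- diff(cts@routeTotals[, "liver_adh"])
    held <- approx(log$time, log$vLiverADH, xout = head(cts@times, -1),
                   method = "constant", rule = 2)$y
    expect_true(all(inc <= held * diff(cts@times) + 1e-9))
    ## log export is delimited text
    f <- tempfile(fileext = ".tsv")
    writeSolveLog(cts, f)
    expect_true(any(grepl("^# ", readLines(f))))
})

test_that("dFBA approaches the standalone PBPK model on the liver-only network", {
    phys <- refPhys(); parts <- refParts()
    kinL <- refKin()
    kinL@clUrine <- 0; kinL@clSweat <- 0; kinL@clCatalase <- 0
    netL <- buildEthanolNetwork(routeConstraints(liverOnly = TRUE))
    sc <- ScenarioConfig(tEnd = 300, tol = 0.001, dt = 0.5)
    setup <- list(physiology = phys, partitions = parts, kinetics = kinL,
                  network = netL, scenario = sc)
    tab <- toleranceSweep(setup, c(0.10, 0.001))
    ## accuracy-cost trade-off: tighter tolerance, more solves, less deviation
    expect_gt(tab$solveCount[2], tab$solveCount[1])
    expect_lt(tab$aucDeviation[2], tab$aucDeviation[1])
    ## consistency limit: < 1% AUC deviation at tol 0.1%
    expect_lt(tab$aucDeviation[2], 0.01)
    ## an independent trapezoid AUC reproduces the tabulated deviation
    ref <- simulatePBPK(phys, parts, kinL, sc@regimen, sc@tEnd, sc@dt)
    dfba <- runDFBA(phys, parts, kinL, netL, sc, tol = 0.001)
    trap <- function(s) sum(diff(s$time) *
                            (head(s$conc, -1) + tail(s$conc, -1)) / 2)
    dev <- abs(trap(concSeries(dfba, "blood", "ethanol")) -
               trap(concSeries(ref, "blood", "ethanol"))) /
        trap(concSeries(ref, "blood", "ethanol"))
    expect_equal(dev, tab$aucDeviation[2], tolerance = 0.15)
})

test_that("every reported trajectory respects nonnegativity and route order",
{
    cts <- baselineRun()
    expect_true(all(cts@conc >= 0))
    expect_true(all(apply(cts@routeTotals, 2, function(z)
        all(diff(z) >= -1e-9))))
    expect_true(validObject(cts))
})
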