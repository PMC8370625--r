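test_that("absorption correlation interpolates its anchors", {
    an <- absorptionCorrelation()
    ## anchor identity
    k <- absorptionParams(5.1)
    expect_equal(unname(k[["kStom"]]), an$k_stom[an$strength_wv == 5.1])
    expect_false(attr(k, "extrapolated"))
    ## interior interpolation is bracketed by the neighbouring anchors
    mid <- absorptionParams(8)
    expect_gt(mid[["kSI"]], an$k_si[1]); expect_lt(mid[["kSI"]], an$k_si[2])
    ## extrapolation flagged with a warning
    expect_warning(k40 <- absorptionParams(40), "extrapolat")
    expect_true(attr(k40, "extrapolated"))
    expect_true(all(k40 > 0))
    expect_error(absorptionParams(0), "> 0")
})

test_that("isoform table scales only the aldehyde dehydrogenase", {
    base <- KineticParameters()
    expect_identical(applyIsoform(base, "ALDH2.1"), base)
    mu <- applyIsoform(base, "ALDH2.2")
    expect_equal(mu@vmaxALDH2 / base@vmaxALDH2, 0.015)
    expect_equal(mu@vmaxALDH2Colon / base@vmaxALDH2Colon, 0.015)
    expect_equal(mu@vmaxADH, base@vmaxADH)
    fin <- applyIsoform(base, "ALDH2.7")
    expect_equal(fin@vmaxALDH2 / base@vmaxALDH2, 0.23)
    expect_error(applyIsoform(base, "ALDH2.99"), "ALDH2.1")
    expect_error(applyIsoform(base, "ALDH2.1/ALDH2.2"), "heterozygous")
    ## table invariants
    tab <- aldh2Isoforms()
    expect_equal(tab$activity_pct[tab$isoform == "ALDH2.1"], 100)
    expect_true(all(tab$activity_pct > 0 & tab$activity_pct <= 100))
})

test_that("disulfiram inhibition is anchored, bounded and monotone", {
    expect_equal(disulfiramActivity(0), 1)
    lv <- seq(0, 10, by = 0.5)
    act <- vapply(lv, disulfiramActivity, numeric(1))
    expect_true(all(act > 0 & act <= 1))
    expect_true(all(diff(act) < 0))
    expect_lt(disulfiramActivity(8), disulfiramActivity(2))
    ## the fitted curve reproduces the shipped anchor table
    an <- disulfiramCorrelation()
    fit <- vapply(an$disulfiram_uM * 296.54 / 1000, disulfiramActivity,
                  numeric(1))
    expect_lt(max(abs(fit - an$relative_activity)), 0.05)
    expect_error(disulfiramActivity(-1), ">= 0")
})

test_that("exposure metrics match their closed forms", {
    ## constant concentration
    expect_equal(auc(data.frame(time = 0:20, conc = rep(2, 21)), 0, 20), 40)
    ## exponential decay to infinity: AUC = C0/k within 0.1%
    k <- 0.05; tt <- seq(0, 200, by = 1)
    s <- data.frame(time = tt, conc = 3 * exp(-k * tt))
    expect_lt(abs(auc(s, 0, Inf) - 3 / k) / (3 / k), 0.001)
    ## beyond-span guard
    expect_error(auc(s, 0, 500), "Inf")
    expect_error(auc(s, 10, 10), "t0")

    expect_equal(mae(data.frame(time = 1:3, conc = c(2, 0, 4)),
                     data.frame(time = 1:3, conc = c(1, 1, 1))), 5 / 3)
    expect_equal(mae(s, s), 0)
    expect_error(mae(s[0, ], s), "empty")
})

test_that("absorption fitting recovers noiseless generating parameters", {
    r <- fitRecovery()
    expect_true(r$fit$converged)
    got <- c(r$fit$kStom, r$fit$kSI, r$fit$kStomSI)
    expect_true(all(abs(got - r$truth) / r$truth < 0.01))
    expect_lt(r$fit$mae, 0.01)
    expect_error(fitAbsorption(data.frame(time = 1:3, conc = 1:3),
                               refKin(), refInd()), "5")
})

test_that("multi-dose regimens accumulate acetaldehyde while ethanol cycles", {
    phys <- refPhys(); parts <- refParts(); net <- refNet()
    kin <- loadKinetics(20)
    reg <- suppressWarnings(doseRegimen(seq(0, 240, by = 60), 0.25, 20))
    sc <- ScenarioConfig(regimen = reg, tEnd = 400, tol = 0.01)
    cts <- runDFBA(phys, parts, kin, net, sc)

    ba <- concSeries(cts, "blood", "acetaldehyde")
    win <- ba[ba$time >= 10 & ba$time <= 290, ]
    ## no inter-dose acetaldehyde decline during the dosing window
    expect_true(all(diff(win$conc) >= -1e-4))
    ## ethanol oscillates between doses
    be <- concSeries(cts, "blood", "ethanol")
    dips <- sum(diff(sign(diff(be$conc[be$time < 290]))) > 0)
    expect_gte(dips, 3)

    ## one dose reduces to the single-dose simulation
    one <- multiDoseRun(ScenarioConfig(regimen = suppressWarnings(
        doseRegimen(0, 0.25, 20)), tEnd = 200, tol = 0.01),
        kinetics = kin)
    single <- runScenario(ScenarioConfig(regimen = suppressWarnings(
        doseRegimen(0, 0.25, 20)), tEnd = 200, tol = 0.01),
        kinetics = kin)
    expect_equal(one$cts@conc, single@conc, tolerance = 1e-12)
    expect_equal(nrow(one$aucs), 14)
})

test_that("expression sweep reproduces the compensation structure", {
    ## cached runs at expression scales 1, 0.5, 0.25
    tots <- lapply(c(1, 0.5, 0.25), function(s) routeTotals(expressionRun(s)))
    auxMmol <- vapply(tots, function(z) z[["urine_ex"]] + z[["sweat_ex"]],
                      numeric(1))
    ## halving expression strictly increases sweat+urine cumulative mmol
    expect_true(all(diff(auxMmol) > 0))
    ## each route stays within its coupling cap relative to the liver
    for (z in tots) {
        expect_lte(z[["urine_ex"]], (0.10 / 0.90) * z[["liver_adh"]] + 1e-6)
        expect_lte(z[["sweat_ex"]], (0.10 / 0.90) * z[["liver_adh"]] + 1e-6)
    }
    ## ethanol exposure rises as the liver is impaired
    eth <- vapply(c(1, 0.5, 0.25), function(s)
        auc(expressionRun(s), 0, 1000, "blood", "ethanol"), numeric(1))
    expect_true(all(diff(eth) > 0))
    ## shut-off limit: zero expression leaves only auxiliary elimination
    zero <- runDFBA(refPhys(), refParts(), refKin(), refNet(),
                    ScenarioConfig(expressionScale = 0, tEnd = 120,
                                   tol = 0.01))
    z <- routeTotals(zero)
    expect_equal(unname(z[["liver_adh"]]), 0)
})

test_that("scenario engine wires individual, kinetics and network together", {
    cfg <- ScenarioConfig(tEnd = 60, tol = 0.01)
    cts <- runScenario(cfg)
    expect_s4_class(cts, "ConcentrationTimeSeries")
    expect_equal(max(simTimes(cts)), 60)
    expect_gt(max(concSeries(cts, "blood", "ethanol")$conc), 0.5)
})
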