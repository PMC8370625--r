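test_that("Michaelis-Menten rate honours its limits and contracts", {
    expect_equal(michaelisMentenRate(0, 2.2, 0.4), 0)
    expect_equal(michaelisMentenRate(0.4, 2.2, 0.4), 1.1)
    expect_lt(abs(michaelisMentenRate(1000 * 0.4, 2.2, 0.4) - 2.2) / 2.2,
              0.001 + 1e-12)
    expect_true(all(michaelisMentenRate(c(0, 1, 10), 2, 0.5) <
                    2 + 1e-12))
    expect_error(michaelisMentenRate(-1, 2.2, 0.4), ">= 0")
    expect_error(michaelisMentenRate(1, 2.2, 0), "Km")
})

test_that("dose events convert grams to stomach-lumen mmol and volume", {
    ind <- refInd()
    y0 <- setNames(numeric(34), ethanolWBM:::.stateNames())
    lum <- c(stomach_lumen = 0, si_lumen = 0.5, li_lumen = 0.5)

    r0 <- applyDose(y0, data.frame(time = 0, dose = 0, strength = 12.5),
                    ind, lum)
    expect_identical(r0$state, y0)
    expect_equal(r0$mmolAdded, 0)

    r <- applyDose(y0, data.frame(time = 0, dose = 0.25, strength = 12.5),
                   ind, lum)
    expect_equal(r$mmolAdded, 0.25 * 74.5 / 46.07 * 1000, tolerance = 1e-12)
    expect_equal(r$mmolAdded, 404.3, tolerance = 1e-3)

    ## same grams at different strengths: same mmol, different volume and
    ## hence initial concentration
    rWeak <- applyDose(y0, data.frame(time = 0, dose = 0.25, strength = 5.1),
                       ind, lum)
    rStrong <- applyDose(y0, data.frame(time = 0, dose = 0.25,
                                        strength = 20), ind, lum)
    expect_equal(rWeak$mmolAdded, rStrong$mmolAdded)
    expect_gt(rWeak$lumenVolumes[["stomach_lumen"]],
              rStrong$lumenVolumes[["stomach_lumen"]])
    expect_lt(rWeak$state[["stomach_lumen.ethanol"]],
              rStrong$state[["stomach_lumen.ethanol"]])
})

test_that("stomach-lumen decay matches the analytic exponential", {
    kin <- refKin()
    cts <- simulatePBPK(refPhys(), refParts(), kin,
                        doseRegimen(0, 0.25, 12.5), tEnd = 120)
    sl <- concSeries(cts, "stomach_lumen", "ethanol")
    k <- kin@kStom + kin@kStomSI
    expected <- sl$conc[1] * exp(-k * sl$time)
    expect_lt(max(abs(sl$conc - expected) / expected[1]), 1e-6)
})

test_that("a closed system conserves total moles", {
    ## all reaction and excretion terms disabled
    kin <- KineticParameters(vmaxADH = 0, vmaxALDH2 = 0, vmaxALDH2Colon = 0)
    phys <- refPhys()
    cts <- simulatePBPK(phys, refParts(), kin, doseRegimen(0, 0.25, 12.5),
                        tEnd = 200, dt = 2)
    V <- organVolumes(phys)
    V[names(cts@meta$lumenVolumes)] <- cts@meta$lumenVolumes
    organs <- sub("\\.ethanol$", "",
                  grep("ethanol", colnames(cts@conc), value = TRUE))
    total <- cts@conc[, paste0(organs, ".ethanol")] %*% V[organs]
    expect_lt(max(abs(total - total[1])) / total[1], 1e-6)
    ## and the rest state stays at rest
    z <- simulatePBPK(phys, refParts(), kin, doseRegimen(0, 0, 12.5),
                      tEnd = 30)
    expect_true(all(z@conc == 0))
})

test_that("the split integrator matches an independent stiff ODE solver", {
    skip_if_not_installed("deSolve")
    ind <- refInd(); phys <- refPhys(); parts <- refParts(); kin <- refKin()
    ## strength chosen so the drink volume equals the reference lumen volume
    y0 <- setNames(numeric(34), ethanolWBM:::.stateNames())
    r <- applyDose(y0, data.frame(time = 0, dose = 0.25, strength = 7.45),
                   ind, c(stomach_lumen = 0, si_lumen = 0.5, li_lumen = 0.5))
    f <- assembleDerivatives(phys, parts, kin, "mm",
                             lumenVolumes = r$lumenVolumes)
    out <- deSolve::ode(y = r$state, times = seq(0, 240, 1),
                        func = function(t, y, p) list(f(t, y)),
                        parms = NULL, rtol = 1e-8, atol = 1e-10)
    cts <- simulatePBPK(phys, parts, kin, doseRegimen(0, 0.25, 7.45), 240)
    be <- concSeries(cts, "blood", "ethanol")
    ref <- out[, "blood.ethanol"]
    expect_lt(max(abs(be$conc - ref)), 0.02)
    aref <- sum(diff(out[, 1]) * (head(ref, -1) + tail(ref, -1)) / 2)
    expect_lt(abs(auc(be, 0, 240) - aref) / aref, 0.005)
    ## stiff metabolite: quasi-steady acetaldehyde agrees at its peak
    ba <- concSeries(cts, "blood", "acetaldehyde")
    expect_lt(abs(max(ba$conc) - max(out[, "blood.acetaldehyde"])) /
              max(out[, "blood.acetaldehyde"]), 0.1)
})

test_that("halving the sub-step changes the blood-ethanol AUC by < 0.5%", {
    kin <- refKin()
    a8 <- auc(simulatePBPK(refPhys(), refParts(), kin,
                           doseRegimen(0, 0.25, 12.5), 300, nSub = 8L),
              0, 300)
    a16 <- auc(simulatePBPK(refPhys(), refParts(), kin,
                            doseRegimen(0, 0.25, 12.5), 300, nSub = 16L),
               0, 300)
    expect_lt(abs(a8 - a16) / a16, 0.005)
})

test_that("blood ethanol declines linearly when saturated, curvilinear below", {
    kin <- refKin()
    cts <- simulatePBPK(refPhys(), refParts(), kin,
                        doseRegimen(0, 0.75, 20), tEnd = 700, dt = 1)
    be <- concSeries(cts, "blood", "ethanol")
    ## saturated (Widmark) segment: C >> Km, decline is near zero order
    ## (start past the distribution phase, ~1 h after the peak)
    seg <- be[be$conc > 10 & be$time > be$time[which.max(be$conc)] + 60, ]
    fit <- lm(conc ~ time, data = seg)
    expect_gt(summary(fit)$r.squared, 0.999)
    slopeSat <- -coef(fit)[["time"]]
    ## low-concentration segment declines slower than the zero-order slope
    low <- be[be$conc < 2 & be$conc > 0.3, ]
    slopeLow <- mean(-diff(low$conc) / diff(low$time))
    expect_lt(slopeLow, 0.7 * slopeSat)
})

test_that("topology construction rejects a missing compartment", {
    phys <- refPhys()
    broken <- phys
    broken@organs <- phys@organs[phys@organs$organ != "kidney", ]
    expect_error(assembleDerivatives(broken, refParts(), refKin()),
                 "kidney")
})

test_that("trajectory export round-trips through delimited text", {
    cts <- simulatePBPK(refPhys(), refParts(), refKin(),
                        doseRegimen(0, 0.25, 12.5), tEnd = 60)
    f <- tempfile(fileext = ".tsv"); rf <- tempfile(fileext = ".tsv")
    writeTrajectory(cts, f, rf)
    back <- read.delim(f, comment.char = "#", check.names = FALSE)
    expect_equal(back$time, cts@times)
    expect_equal(as.matrix(back[, -1]), cts@conc, tolerance = 1e-8,
                 ignore_attr = TRUE)
    routes <- read.delim(rf, comment.char = "#")
    expect_equal(nrow(routes), length(cts@times))
})
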