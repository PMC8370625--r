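## Shared fixtures and independent oracles. Expensive coupled runs are
## cached per session so acceptance and property tests can share them.

test_cache <- new.env(parent = emptyenv())

getCached <- function(key, fn) {
    if (is.null(test_cache[[key]])) assign(key, fn(), envir = test_cache)
    test_cache[[key]]
}

refInd <- function() referenceMale()
refPhys <- function() getCached("phys", function() buildPhysiology(refInd()))
refParts <- function() getCached("parts", function() buildPartitions(refPhys()))
refKin <- function() getCached("kin", function() loadKinetics(12.5))
refNet <- function() getCached("net", function() buildEthanolNetwork())

## Baseline coupled run: reference male, 0.25 g/kg, 1000 min, default
## couplings (the enzyme-expression study conditions).
baselineRun <- function() getCached("base1000", function()
    runDFBA(refPhys(), refParts(), refKin(), refNet(),
            ScenarioConfig(tEnd = 1000, tol = 0.01)))

## Coupled runs at reduced liver enzyme expression (same conditions).
expressionRun <- function(scale) getCached(paste0("expr", scale), function()
    runDFBA(refPhys(), refParts(), refKin(), refNet(),
            ScenarioConfig(expressionScale = scale, tEnd = 1000, tol = 0.01)))

## Isoform runs over 500 min (exposure-window study conditions).
isoformRun <- function(iso) getCached(paste0("iso", iso), function()
    runDFBA(refPhys(), refParts(), refKin(), refNet(),
            ScenarioConfig(isoform = iso, tEnd = 500, tol = 0.01)))

## Mitchell-style beverage arm (0.5 g/kg, fitted Vmax 1.5 mM/min).
mitchellInd <- function() Individual(37.8, "male", 177.1, 82.66, 0.20)
mitchellRun <- function(strength) getCached(paste0("mitch", strength),
    function() {
        phys <- buildPhysiology(mitchellInd())
        parts <- buildPartitions(phys)
        kin <- loadKinetics(strength)
        kin@vmaxADH <- 1.5
        runDFBA(phys, parts, kin, refNet(),
                ScenarioConfig(regimen = suppressWarnings(
                    doseRegimen(0, 0.5, strength)), tEnd = 600, tol = 0.01))
    })

## Disulfiram runs to full elimination (AUC_0-inf study conditions).
disulfiramRun <- function(level) getCached(paste0("dsf", level), function()
    runDFBA(refPhys(), refParts(), refKin(), refNet(),
            ScenarioConfig(disulfiramLevel = level, tEnd = 2500, dt = 2,
                           tol = 0.01)))

## Noiseless absorption-parameter recovery (shared by the calibration tests
## and the acceptance property suite).
fitRecovery <- function() getCached("fitRecovery", function() {
    kin <- refKin()
    truth <- c(kStom = 0.035, kSI = 0.12, kStomSI = 0.06)
    cts <- simulatePBPK(refPhys(), refParts(), kin,
                        doseRegimen(0, 0.5, 12.5), 320, dt = 2)
    s <- concSeries(cts, "blood", "ethanol")
    obs <- s[s$time %in% seq(20, 300, by = 40), ]
    fit <- fitAbsorption(obs, kin, refInd(), dose = 0.5, strength = 12.5,
                         start = c(kStom = 0.05, kSI = 0.09,
                                   kStomSI = 0.04))
    list(fit = fit, truth = truth)
})

## ---------------------------------------------------------------------------
## Independent LP oracle: exhaustive vertex enumeration.
## Builds its own constraint representation straight from the model slots
## (equalities: S v = 0 plus any lb == ub pins; inequalities: bounds and
## couplings) and enumerates basic feasible points.
## ---------------------------------------------------------------------------

vertexOptimum <- function(model, bigM = 1e5) {
    rx <- model@reactions
    n <- nrow(rx)
    obj <- match(model@objective, rx$id)
    unit <- function(i) { r <- numeric(n); r[i] <- 1; r }

    Aeq <- model@smatrix
    beq <- rep(0, nrow(Aeq))
    pinned <- which(abs(rx$ub - rx$lb) < 1e-12)
    for (i in pinned) { Aeq <- rbind(Aeq, unit(i)); beq <- c(beq, rx$lb[i]) }

    Ain <- NULL; bin <- NULL
    for (i in setdiff(seq_len(n), pinned)) {
        if (rx$ub[i] < bigM) { Ain <- rbind(Ain, unit(i)); bin <- c(bin, rx$ub[i]) }
        Ain <- rbind(Ain, -unit(i)); bin <- c(bin, -rx$lb[i])
    }
    if (nrow(model@couplings))
        for (i in seq_len(nrow(model@couplings))) {
            cp <- model@couplings[i, ]
            j <- match(cp$id, rx$id)
            if (j %in% pinned) next
            r <- unit(j); r[obj] <- r[obj] - cp$cmax
            Ain <- rbind(Ain, r); bin <- c(bin, 0)
            if (cp$cmin > 0) {
                r <- -unit(j); r[obj] <- r[obj] + cp$cmin
                Ain <- rbind(Ain, r); bin <- c(bin, 0)
            }
        }

    nFree <- n - nrow(Aeq)
    if (nFree < 0) stop("over-determined oracle system")
    best <- -Inf; bestV <- NULL
    combs <- utils::combn(nrow(Ain), nFree)
    for (k in seq_len(ncol(combs))) {
        A <- rbind(Aeq, Ain[combs[, k], , drop = FALSE])
        b <- c(beq, bin[combs[, k]])
        v <- tryCatch(solve(A, b), error = function(e) NULL)
        if (is.null(v) || anyNA(v)) next
        if (any(Ain %*% v > bin + 1e-7)) next
        if (v[obj] > best) { best <- v[obj]; bestV <- v }
    }
    list(objective = unname(best), v = bestV)
}
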