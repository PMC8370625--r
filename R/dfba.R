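## Dynamic FBA: hold the last flux solution constant in the ODE system until
## the held rates drift from the current Michaelis-Menten rates beyond a
## relative tolerance, then re-solve (solve -> hold -> check loop; the check
## runs before each step on start-of-step concentrations).

#' Relative-deviation tolerance check between kinetic and held FBA rates
#'
#' TRUE iff \code{|rMM - rFBA| / rMM < tol}. A zero kinetic rate with a
#' nonzero held rate counts as a violation (re-solve rather than eliminate
#' mass from an empty compartment); both zero counts as no drift.
#'
#' @param rMM current Michaelis-Menten rate (any consistent unit).
#' @param rFBA held FBA rate, same unit.
#' @param tol relative tolerance (> 0), e.g. 0.01 for 1\%.
#' @return logical.
#' @examples
#' withinTolerance(1.0, 0.97, 0.05)  # TRUE (3% deviation < 5%)
#' withinTolerance(1.0, 0.97, 0.01)  # FALSE
#' @export
withinTolerance <- function(rMM, rFBA, tol) {
    if (tol <= 0) stop("tol must be > 0")
    if (is.null(rFBA)) return(FALSE)
    if (rMM == 0) return(rFBA == 0)
    abs(rMM - rFBA) / abs(rMM) < tol
}

## Held-rate provider bound to a coupler environment.
.dfbaProvider <- function(sys, network, kinetics, physiology, scenario, dt,
                          env) {
    V <- sys$V
    tissueEthCols <- paste(.TISSUES, "ethanol", sep = ".")
    tissueVols <- V[.TISSUES]

    function(t, state, dosedNow = FALSE) {
        liverEth <- state[["liver.ethanol"]]
        liverAc <- state[["liver.acetaldehyde"]]
        rADH <- sys$sExpr *
            michaelisMentenRate(liverEth, kinetics@vmaxADH, kinetics@kmADH) *
            V[["liver"]]
        rALDH2 <- sys$sExpr * sys$sIso * sys$sDsf *
            michaelisMentenRate(liverAc, kinetics@vmaxALDH2,
                                kinetics@kmALDH2) * V[["liver"]]
        trigger <- NULL
        if (is.null(env$held)) trigger <- "initial"
        else if (dosedNow) trigger <- "dose"
        else if (!withinTolerance(rADH, env$heldADH, env$tol)) trigger <- "adh"
        else if (!withinTolerance(rALDH2, env$heldALDH2, env$tol))
            trigger <- "aldh2"

        if (!is.null(trigger)) {
            pool <- sum(state[tissueEthCols] * tissueVols)
            avail <- max(pool, 0) / dt
            sol <- tryCatch({
                m <- setBounds(network, liverEth, liverAc, kinetics,
                               physiology, scenario,
                               bloodCEthanol = state[["blood.ethanol"]],
                               colonCEthanol =
                                   state[["large_intestine.ethanol"]],
                               availability = avail)
                solveFBA(m)
            }, fbaInfeasible = function(e) e)
            if (inherits(sol, "fbaInfeasible")) {
                env$failStreak <- env$failStreak + 1L
                if (env$failStreak >= 3L)
                    stop(sprintf(
                        "dynamic FBA aborted at t = %g min after repeated LP infeasibility (last: %s)",
                        t, conditionMessage(sol)), call. = FALSE)
            } else {
                env$failStreak <- 0L
                v <- fluxes(sol)
                env$held <- c(
                    liver_adh = v[["Liver_ALCD2if"]],
                    breath_ex = v[["EX_etoh_[br]"]],
                    urine_ex = v[["EX_etoh[u]"]],
                    sweat_ex = v[["EX_etoh[sw]"]],
                    feces_ex = v[["Excretion_EX_etoh[fe]"]],
                    colon_catalase = v[["Colon_CAT2p"]])
                env$heldADH <- v[["Liver_ALCD2if"]]
                env$heldALDH2 <- v[["Liver_ALDH2x"]]
                env$solveCount <- env$solveCount + 1L
                env$log[[length(env$log) + 1L]] <- data.frame(
                    time = t, trigger = trigger,
                    rateADH = rADH, rateALDH2 = rALDH2,
                    vLiverADH = env$heldADH, vLiverALDH2 = env$heldALDH2,
                    vUrine = env$held[["urine_ex"]],
                    vSweat = env$held[["sweat_ex"]],
                    vBreath = env$held[["breath_ex"]],
                    vCatalase = env$held[["colon_catalase"]])
            }
        }
        env$held
    }
}

#' Run the coupled PBPK / dynamic-FBA simulation
#'
#' At each reporting step the ethanol elimination rates in the ODE system
#' are the held whole-body fluxes of the last FBA solution (converted to
#' concentration units per host organ). Before every step the liver alcohol-
#' and aldehyde-dehydrogenase Michaelis-Menten rates at the current
#' concentrations are compared with the held fluxes; a relative deviation
#' beyond \code{tol} (or a dose event) triggers a re-solve at the current
#' state. Acetaldehyde elimination itself is always kinetic (see the methods
#' vignette for the rationale); its FBA counterpart sets the production
#' throttle via the stoichiometric closure of the acetaldehyde species.
#'
#' @param physiology a \linkS4class{PhysiologyParameters}.
#' @param partitions from \code{\link{buildPartitions}}.
#' @param kinetics a \linkS4class{KineticParameters}.
#' @param network from \code{\link{buildEthanolNetwork}}.
#' @param scenario a \linkS4class{ScenarioConfig}; supplies the regimen,
#'   horizon, step and tolerance unless overridden.
#' @param regimen,tEnd,dt,tol overrides of the scenario values.
#' @param nSub integrator sub-steps per reporting step.
#' @return A \linkS4class{ConcentrationTimeSeries} whose \code{meta} carries
#'   \code{solveCount} and the per-solve audit log (\code{solveLog}).
#' @examples
#' \donttest{
#' phys <- buildPhysiology(referenceMale())
#' parts <- buildPartitions(phys)
#' cfg <- ScenarioConfig(tEnd = 120)
#' cts <- runDFBA(phys, parts, KineticParameters(), buildEthanolNetwork(),
#'                cfg)
#' cts@meta$solveCount
#' }
#' @export
runDFBA <- function(physiology, partitions, kinetics, network,
                    scenario = ScenarioConfig(), regimen = scenario@regimen,
                    tEnd = scenario@tEnd, dt = scenario@dt,
                    tol = scenario@tol, nSub = 8L) {
    if (tol <= 0) stop("tol must be > 0")
    sys <- .pbpkSystem(physiology, partitions, kinetics, scenario)
    env <- new.env(parent = emptyenv())
    env$held <- NULL; env$heldADH <- NULL; env$heldALDH2 <- NULL
    env$solveCount <- 0L; env$failStreak <- 0L; env$tol <- tol
    env$log <- list()
    provider <- .dfbaProvider(sys, network, kinetics, physiology, scenario,
                              dt, env)
    cts <- .integrate(sys, physiology@individual, regimen, tEnd, dt,
                      holdProvider = provider, nSub = nSub)
    cts@meta$solveCount <- env$solveCount
    cts@meta$solveLog <- if (length(env$log)) do.call(rbind, env$log) else
        data.frame()
    cts@meta$tol <- tol
    cts@meta$scenario <- scenario
    cts
}

#' Cumulative route fractions of total ethanol elimination
#'
#' @param cts a \linkS4class{ConcentrationTimeSeries}.
#' @return Named numeric: each ethanol route's share of the cumulative mmol
#'   eliminated over the whole trajectory.
#' @export
cumulativeRouteFractions <- function(cts) {
    tot <- routeTotals(cts)
    routes <- c("liver_adh", "breath_ex", "urine_ex", "sweat_ex", "feces_ex",
                "colon_catalase")
    tot <- tot[routes]
    tot / sum(tot)
}

#' Write the per-solve coupler log as delimited text
#'
#' @param cts a dFBA \linkS4class{ConcentrationTimeSeries}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeSolveLog <- function(cts, file) {
    con <- file(file, "w")
    writeLines(c("# ethanolWBM dFBA solve log",
                 sprintf("# tol: %g, solves: %d", cts@meta$tol,
                         cts@meta$solveCount)), con)
    utils::write.table(cts@meta$solveLog, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    invisible(file)
}

#' Tolerance sweep: re-solve frequency vs accuracy
#'
#' Runs the coupled simulation at each tolerance and reports the FBA solve
#' count and the relative deviation of the blood-ethanol AUC from the
#' standalone (pure Michaelis-Menten) PBPK reference.
#'
#' @param setup list with elements \code{physiology}, \code{partitions},
#'   \code{kinetics}, \code{network}, \code{scenario}.
#' @param tols positive tolerances, sorted decreasing or increasing.
#' @return data.frame with columns \code{tol}, \code{solveCount},
#'   \code{aucDeviation}.
#' @export
toleranceSweep <- function(setup, tols) {
    if (any(tols <= 0)) stop("tolerances must be > 0")
    sc <- setup$scenario
    ref <- simulatePBPK(setup$physiology, setup$partitions, setup$kinetics,
                        sc@regimen, sc@tEnd, sc@dt, scenario = sc)
    refAUC <- auc(concSeries(ref, "blood", "ethanol"), 0, sc@tEnd)
    rows <- lapply(tols, function(tl) {
        cts <- runDFBA(setup$physiology, setup$partitions, setup$kinetics,
                       setup$network, sc, tol = tl)
        a <- auc(concSeries(cts, "blood", "ethanol"), 0, sc@tEnd)
        data.frame(tol = tl, solveCount = cts@meta$solveCount,
                   aucDeviation = abs(a - refAUC) / refAUC)
    })
    do.call(rbind, rows)
}
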