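## PBPK core: the 34-state ODE system (ethanol + acetaldehyde in 14 tissues
## and 3 lumina), its fixed-step split integrator, dosing, and the
## mass-balance audit.
##
## Topology (single pooled venous blood compartment):
##   tissues <- arterial blood (lung outflow); venous returns pool in blood;
##   blood perfuses the lung (lung mixing point: the full cardiac output);
##   portal organs (stomach, intestines, pancreas, spleen) drain into the
##   liver, whose inflow is hepatic artery + portal flows (liver mixing
##   point). Lumina exchange only by first-order absorption/transit.
## Saturable reaction sinks are advanced analytically within a Strang split
## so that the near-zero-Km aldehyde dehydrogenase term does not constrain
## the explicit transport step.

.METS <- c("ethanol", "acetaldehyde")
.ROUTES <- c("liver_adh", "breath_ex", "urine_ex", "sweat_ex", "feces_ex",
             "colon_catalase", "liver_aldh2", "colon_aldh2")

#' Michaelis-Menten rate
#'
#' @param C substrate concentration, mM (vectorised, must be >= 0).
#' @param Vmax maximal rate, mM/min (>= 0).
#' @param Km half-saturation constant, mM (> 0).
#' @return Rate \code{Vmax * C / (Km + C)} in mM/min, in \code{[0, Vmax)}.
#' @examples
#' michaelisMentenRate(0.4, 2.2, 0.4)  # half saturation -> Vmax/2
#' @export
michaelisMentenRate <- function(C, Vmax, Km) {
    if (any(C < 0)) stop("concentration must be >= 0")
    if (Km <= 0) stop("Km must be > 0")
    if (any(Vmax < 0)) stop("Vmax must be >= 0")
    Vmax * C / (Km + C)
}

## Exact advance of dC/dt = -Vmax*C/(Km+C) over time h (implicit one-step
## solve of the integrated MM relation Km*log(C0/C1) + (C0 - C1) = Vmax*h).
.mmDecay <- function(C0, Vmax, Km, h) {
    if (C0 <= 0 || Vmax <= 0 || h <= 0) return(max(C0, 0))
    target <- Vmax * h
    f <- function(C1) Km * log(C0 / C1) + (C0 - C1) - target
    lo <- C0 * 1e-15
    if (f(lo) <= 0) return(lo)  # essentially fully depleted
    C1 <- max(C0 - target * C0 / (Km + C0), lo)
    for (i in 1:60) {
        fv <- Km * log(C0 / C1) + (C0 - C1) - target
        if (abs(fv) < 1e-13 * max(Km, C0)) break
        deriv <- -Km / C1 - 1
        C1new <- C1 - fv / deriv
        if (!is.finite(C1new) || C1new <= lo) C1new <- C1 / 2
        if (C1new > C0) C1new <- (C1 + C0) / 2
        C1 <- C1new
    }
    C1
}

## ---------------------------------------------------------------------------
## System construction
## ---------------------------------------------------------------------------

.TISSUES <- c("lung", "liver", "stomach", "small_intestine",
              "large_intestine", "pancreas", "spleen", "kidney", "skin",
              "muscle", "adipose", "brain", "heart", "blood")
.LUMINA <- c("stomach_lumen", "si_lumen", "li_lumen")

.stateNames <- function() {
    organs <- c(.TISSUES, .LUMINA)
    as.vector(vapply(.METS, function(m) paste(organs, m, sep = "."),
                     character(length(organs))))
}

## Internal system object: precomputed indices and parameters.
.pbpkSystem <- function(physiology, partitions, kinetics, scenario = NULL) {
    org <- physiology@organs
    missing <- setdiff(c(.TISSUES, .LUMINA), org$organ)
    if (length(missing))
        stop(sprintf("physiology is missing compartment(s): %s",
                     paste(missing, collapse = ", ")))
    organs <- c(.TISSUES, .LUMINA)
    row <- match(organs, org$organ)
    V <- org$volume[row]
    Q <- org$flow[row]
    names(V) <- names(Q) <- organs

    K <- lapply(partitions, function(k) k[organs])
    if (!all(c("ethanol", "acetaldehyde") %in% names(K)))
        stop("partitions must cover ethanol and acetaldehyde")

    idx <- function(organ, met) {
        (match(met, .METS) - 1L) * length(organs) + match(organ, organs)
    }
    portal <- organs[which(org$portal[row] == 1)]
    systemic <- setdiff(.TISSUES, c("lung", "blood", "liver", portal))

    sIso <- 1; sDsf <- 1; sExpr <- 1
    if (!is.null(scenario)) {
        sExpr <- scenario@expressionScale
        sIso <- isoformActivity(scenario@isoform) / 100
        sDsf <- disulfiramActivity(scenario@disulfiramLevel)
    }

    lumenVol <- new.env(parent = emptyenv())
    lumenVol$stomach_lumen <- V[["stomach_lumen"]]
    lumenVol$si_lumen <- V[["si_lumen"]]
    lumenVol$li_lumen <- V[["li_lumen"]]

    audit <- new.env(parent = emptyenv())
    audit$clampCount <- 0L
    audit$maxDeficit <- 0

    list(organs = organs, V = V, Q = Q, K = K, CO = physiology@cardiacOutput,
         QlivTot = Q[["liver"]] + sum(Q[portal]),
         portal = portal, systemic = systemic,
         kin = kinetics, idx = idx,
         sExpr = sExpr, sIso = sIso, sDsf = sDsf,
         lumenVol = lumenVol, audit = audit,
         physiology = physiology)
}

## Transport derivative for one metabolite block (concentration units).
## `x` is the 17-vector of that metabolite's compartment concentrations.
.dTransport <- function(sys, x, K, lumenEthanol) {
    V <- sys$V; Q <- sys$Q
    d <- numeric(length(x))
    names(d) <- sys$organs
    cb <- x[["blood"]]
    cart <- x[["lung"]] / K[["lung"]]

    for (o in sys$systemic)
        d[o] <- Q[[o]] / V[[o]] * (cart - x[[o]] / K[[o]])
    for (o in sys$portal)
        d[o] <- Q[[o]] / V[[o]] * (cart - x[[o]] / K[[o]])
    ## liver mixing point: hepatic artery + portal venous inflow
    inflow <- Q[["liver"]] * cart +
        sum(vapply(sys$portal, function(p) Q[[p]] * x[[p]] / K[[p]],
                   numeric(1)))
    d["liver"] <- (inflow - sys$QlivTot * x[["liver"]] / K[["liver"]]) /
        V[["liver"]]
    ## lung mixing point: full cardiac output from the venous pool
    d["lung"] <- sys$CO / V[["lung"]] * (cb - x[["lung"]] / K[["lung"]])
    ## venous pool: all systemic returns, liver returns its total inflow
    returns <- sys$QlivTot * x[["liver"]] / K[["liver"]] +
        sum(vapply(sys$systemic, function(o) Q[[o]] * x[[o]] / K[[o]],
                   numeric(1)))
    d["blood"] <- (returns - sys$CO * cb) / V[["blood"]]

    if (lumenEthanol) {
        kin <- sys$kin
        vst <- sys$lumenVol$stomach_lumen
        vsi <- sys$lumenVol$si_lumen
        vli <- sys$lumenVol$li_lumen
        ast <- x[["stomach_lumen"]] * vst   # mmol
        asi <- x[["si_lumen"]] * vsi
        ali <- x[["li_lumen"]] * vli
        d["stomach_lumen"] <- if (vst > 0)
            -(kin@kStom + kin@kStomSI) * x[["stomach_lumen"]] else 0
        d["si_lumen"] <- (kin@kStomSI * ast - (kin@kSI + kin@kSILI) * asi) / vsi
        d["li_lumen"] <- (kin@kSILI * asi - kin@kLI * ali) / vli
        d["stomach"] <- d[["stomach"]] + kin@kStom * ast / V[["stomach"]]
        d["small_intestine"] <- d[["small_intestine"]] +
            kin@kSI * asi / V[["small_intestine"]]
        d["large_intestine"] <- d[["large_intestine"]] +
            kin@kLI * ali / V[["large_intestine"]]
    }
    d
}

## Full instantaneous derivative (transport + reactions), used by
## assembleDerivatives() and the deSolve cross-checks. Reaction rates are
## either "mm" (closed-form kinetics, standalone PBPK mode) or a named held
## flux vector in mmol/min (dFBA mode).
.dFull <- function(sys, state, reactionRates) {
    n <- length(sys$organs)
    eth <- state[seq_len(n)]
    ac <- state[n + seq_len(n)]
    names(eth) <- names(ac) <- sys$organs
    dEth <- .dTransport(sys, eth, sys$K$ethanol, lumenEthanol = TRUE)
    dAc <- .dTransport(sys, ac, sys$K$acetaldehyde, lumenEthanol = FALSE)

    rate <- .reactionRates(sys, eth, ac, reactionRates)   # mmol/min, by role
    V <- sys$V
    dEth["liver"] <- dEth[["liver"]] - rate[["liver_adh"]] / V[["liver"]]
    dEth["lung"] <- dEth[["lung"]] - rate[["breath_ex"]] / V[["lung"]]
    dEth["kidney"] <- dEth[["kidney"]] - rate[["urine_ex"]] / V[["kidney"]]
    dEth["skin"] <- dEth[["skin"]] - rate[["sweat_ex"]] / V[["skin"]]
    dEth["large_intestine"] <- dEth[["large_intestine"]] -
        rate[["colon_catalase"]] / V[["large_intestine"]]
    if (sys$lumenVol$li_lumen > 0)
        dEth["li_lumen"] <- dEth[["li_lumen"]] -
            rate[["feces_ex"]] / sys$lumenVol$li_lumen
    dAc["liver"] <- dAc[["liver"]] +
        (rate[["liver_adh"]] - rate[["liver_aldh2"]]) / V[["liver"]]
    dAc["large_intestine"] <- dAc[["large_intestine"]] +
        (rate[["colon_catalase"]] - rate[["colon_aldh2"]]) /
        V[["large_intestine"]]
    c(dEth, dAc)
}

## Role-wise reaction rates in mmol/min given current concentrations.
.reactionRates <- function(sys, eth, ac, reactionRates) {
    kin <- sys$kin
    V <- sys$V
    mmALDH2 <- sys$sExpr * sys$sIso * sys$sDsf *
        michaelisMentenRate(ac[["liver"]], kin@vmaxALDH2, kin@kmALDH2) *
        V[["liver"]]
    mmALDH2col <- sys$sIso * sys$sDsf *
        michaelisMentenRate(ac[["large_intestine"]], kin@vmaxALDH2Colon,
                            kin@kmALDH2Colon) * V[["large_intestine"]]
    if (is.character(reactionRates) && identical(reactionRates, "mm")) {
        r <- c(liver_adh = sys$sExpr *
                   michaelisMentenRate(eth[["liver"]], kin@vmaxADH,
                                       kin@kmADH) * V[["liver"]],
               breath_ex = 0, urine_ex = 0, sweat_ex = 0, feces_ex = 0,
               colon_catalase = 0,
               liver_aldh2 = mmALDH2, colon_aldh2 = mmALDH2col)
    } else {
        r <- c(liver_adh = 0, breath_ex = 0, urine_ex = 0, sweat_ex = 0,
               feces_ex = 0, colon_catalase = 0,
               liver_aldh2 = mmALDH2, colon_aldh2 = mmALDH2col)
        held <- reactionRates
        r[names(held)[names(held) %in% names(r)]] <-
            held[names(held) %in% names(r)]
    }
    r
}

#' Assemble the instantaneous derivative function of the ODE system
#'
#' Returns \code{function(t, state)} giving d(concentration)/dt (mM/min) for
#' the 34 named states. \code{reactionRates} selects the metabolic mode:
#' \code{"mm"} uses closed-form Michaelis-Menten kinetics in the liver and
#' colon (standalone PBPK mode); a named numeric vector of whole-body fluxes
#' (mmol/min, names among the elimination roles) holds those rates constant,
#' as between dynamic-FBA solves. Aldehyde dehydrogenase elimination is
#' always kinetic.
#'
#' @param physiology a \linkS4class{PhysiologyParameters} covering all 17
#'   compartments (a missing compartment is a construction-time error).
#' @param partitions partition coefficients from \code{\link{buildPartitions}}.
#' @param kinetics a \linkS4class{KineticParameters}.
#' @param reactionRates \code{"mm"} or a named flux vector (mmol/min).
#' @param scenario optional \linkS4class{ScenarioConfig} whose expression /
#'   isoform / disulfiram scales apply to the enzyme terms.
#' @param lumenVolumes optional named numeric overriding the reference lumen
#'   volumes (L), e.g. to match the drink volume set by a dose event.
#' @return derivative function \code{function(t, state)}.
#' @export
assembleDerivatives <- function(physiology, partitions, kinetics,
                                reactionRates = "mm", scenario = NULL,
                                lumenVolumes = NULL) {
    sys <- .pbpkSystem(physiology, partitions, kinetics, scenario)
    for (nm in names(lumenVolumes)) assign(nm, lumenVolumes[[nm]],
                                           envir = sys$lumenVol)
    function(t, state) .dFull(sys, state, reactionRates)
}

## ---------------------------------------------------------------------------
## Dosing
## ---------------------------------------------------------------------------

.MAX_STOMACH_VOLUME <- 1.0  # L

#' Apply a dose event to a model state
#'
#' The dose (g ethanol per kg body weight) is converted to mmol via the
#' molecular weight of ethanol and added to the stomach lumen. The drink
#' volume is \code{grams / (strength * 10)} litres (\%w/v = g/100 mL); the
#' lumen volume grows by that amount up to a 1 L ceiling, so the same dose
#' taken as a stronger drink yields the same mmol in a smaller volume and
#' hence a higher initial lumen concentration.
#'
#' @param state named concentration vector (34 states, mM).
#' @param event one-row data.frame with \code{time}, \code{dose},
#'   \code{strength} (see \code{\link{doseRegimen}}).
#' @param individual an \linkS4class{Individual}.
#' @param lumenVolumes named numeric with current lumen volumes (L);
#'   element \code{stomach_lumen} is updated.
#' @return list with \code{state}, \code{lumenVolumes}, \code{mmolAdded}.
#' @export
applyDose <- function(state, event, individual, lumenVolumes) {
    if (event$dose < 0) stop("dose must be >= 0")
    if (event$dose == 0)
        return(list(state = state, lumenVolumes = lumenVolumes, mmolAdded = 0))
    mw <- defaultMetabolites()$ethanol@molecularWeight
    grams <- event$dose * individual@weight
    mmol <- grams / mw * 1000
    vDrink <- grams / (event$strength * 10)
    v0 <- lumenVolumes[["stomach_lumen"]]
    a0 <- state[["stomach_lumen.ethanol"]] * v0
    v1 <- min(v0 + vDrink, .MAX_STOMACH_VOLUME)
    ## first dose into an empty reference lumen: the drink defines the volume
    if (a0 <= 0) v1 <- min(max(vDrink, 0.05), .MAX_STOMACH_VOLUME)
    state[["stomach_lumen.ethanol"]] <- (a0 + mmol) / v1
    lumenVolumes[["stomach_lumen"]] <- v1
    list(state = state, lumenVolumes = lumenVolumes, mmolAdded = mmol)
}

## ---------------------------------------------------------------------------
## Integrator
## ---------------------------------------------------------------------------

## One transport RK4 step of size h on the full state (both metabolites).
.rk4Transport <- function(sys, state, h) {
    n <- length(sys$organs)
    f <- function(s) {
        eth <- s[seq_len(n)]; ac <- s[n + seq_len(n)]
        names(eth) <- names(ac) <- sys$organs
        c(.dTransport(sys, eth, sys$K$ethanol, TRUE),
          .dTransport(sys, ac, sys$K$acetaldehyde, FALSE))
    }
    k1 <- f(state)
    k2 <- f(state + h / 2 * k1)
    k3 <- f(state + h / 2 * k2)
    k4 <- f(state + h * k3)
    out <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    neg <- out < 0
    if (any(neg)) {
        sys$audit$maxDeficit <- max(sys$audit$maxDeficit, -min(out[neg]))
        if (any(out[neg] < -1e-9)) sys$audit$clampCount <-
            sys$audit$clampCount + sum(out[neg] < -1e-9)
        out[neg] <- 0
    }
    out
}

## Backward-Euler step for dC/dt = p - Vmax*C/(Km+C) (constant production p
## over the sub-step). A-stable, so the near-zero-Km aldehyde sink relaxes
## to its quasi-steady state C* = Km*p/(Vmax-p) instead of being wiped out
## by a sequential exact-decay split. Returns the new concentration.
.mmProdStep <- function(C0, p, Vmax, Km, h) {
    a <- C0 + h * p
    if (Vmax <= 0) return(a)
    b <- Km - a + h * Vmax
    c <- Km * a
    (-b + sqrt(b * b + 4 * c)) / 2
}

## Reaction half/full step of size h: ethanol sinks (kinetic in "mm" mode,
## held constant-rate fluxes with availability clamping in dFBA mode),
## stoichiometric 1:1 acetaldehyde generation in the producing compartment,
## and kinetic aldehyde-dehydrogenase elimination solved jointly with the
## production term. Updates route totals (mmol) and returns the state.
.reactionStep <- function(sys, state, h, mode, held, totals) {
    kin <- sys$kin; V <- sys$V
    iE <- function(o) paste(o, "ethanol", sep = ".")
    iA <- function(o) paste(o, "acetaldehyde", sep = ".")
    prodLiver <- 0   # mM over the sub-step
    prodColon <- 0

    ## --- ethanol sinks ---
    if (identical(mode, "mm")) {
        c0 <- state[[iE("liver")]]
        c1 <- .mmDecay(c0, sys$sExpr * kin@vmaxADH, kin@kmADH, h)
        prodLiver <- c0 - c1
        state[iE("liver")] <- c1
        totals["liver_adh"] <- totals[["liver_adh"]] +
            prodLiver * V[["liver"]]
    } else {
        sinks <- c(liver_adh = "liver", breath_ex = "lung",
                   urine_ex = "kidney", sweat_ex = "skin",
                   colon_catalase = "large_intestine")
        for (role in names(sinks)) {
            v <- held[[role]]
            if (is.null(v) || v <= 0) next
            o <- sinks[[role]]
            dC <- v / V[[o]] * h
            avail <- state[[iE(o)]]
            if (dC > avail) { dC <- avail; sys$audit$clampCount <-
                sys$audit$clampCount + 1L }
            state[iE(o)] <- state[[iE(o)]] - dC
            totals[role] <- totals[[role]] + dC * V[[o]]
            if (role == "liver_adh") prodLiver <- dC
            if (role == "colon_catalase") prodColon <- dC
        }
        vfe <- held[["feces_ex"]]
        if (!is.null(vfe) && vfe > 0 && sys$lumenVol$li_lumen > 0) {
            dC <- min(vfe / sys$lumenVol$li_lumen * h,
                      state[["li_lumen.ethanol"]])
            state["li_lumen.ethanol"] <- state[["li_lumen.ethanol"]] - dC
            totals["feces_ex"] <- totals[["feces_ex"]] +
                dC * sys$lumenVol$li_lumen
        }
    }

    ## --- acetaldehyde: production + kinetic elimination, jointly ---
    c0 <- state[[iA("liver")]]
    c1 <- .mmProdStep(c0, prodLiver / h,
                      sys$sExpr * sys$sIso * sys$sDsf * kin@vmaxALDH2,
                      kin@kmALDH2, h)
    state[iA("liver")] <- c1
    totals["liver_aldh2"] <- totals[["liver_aldh2"]] +
        (c0 + prodLiver - c1) * V[["liver"]]

    c0 <- state[[iA("large_intestine")]]
    c1 <- .mmProdStep(c0, prodColon / h,
                      sys$sIso * sys$sDsf * kin@vmaxALDH2Colon,
                      kin@kmALDH2Colon, h)
    state[iA("large_intestine")] <- c1
    totals["colon_aldh2"] <- totals[["colon_aldh2"]] +
        (c0 + prodColon - c1) * V[["large_intestine"]]

    list(state = state, totals = totals)
}

## Core fixed-step engine with Strang splitting. `holdProvider`, if given, is
## called at the start of every reporting step with (t, state, env) and must
## return the held flux vector (mmol/min) for that step; NULL means pure
## Michaelis-Menten mode.
.integrate <- function(sys, individual, regimen, tEnd, dt, holdProvider,
                       nSub = 8L) {
    stopifnot(tEnd > 0, dt > 0)
    ## explicit-transport stability: the stiffest perfusion eigenvalue is
    ## ~CO/(V*K) at the lung (~17/min), so cap the sub-step at 0.125 min
    nSub <- max(as.integer(nSub), ceiling(dt / 0.125))
    nm <- .stateNames()
    state <- stats::setNames(numeric(length(nm)), nm)
    totals <- stats::setNames(numeric(length(.ROUTES)), .ROUTES)
    times <- seq(0, tEnd, by = dt)
    conc <- matrix(0, length(times), length(nm), dimnames = list(NULL, nm))
    routeMat <- matrix(0, length(times), length(totals),
                       dimnames = list(NULL, names(totals)))
    lumenVolumes <- c(stomach_lumen = sys$lumenVol$stomach_lumen,
                      si_lumen = sys$lumenVol$si_lumen,
                      li_lumen = sys$lumenVol$li_lumen)
    dosed <- 0
    mode <- if (is.null(holdProvider)) "mm" else "held"
    held <- NULL
    h <- dt / nSub

    ## each dose fires at the first grid time >= its event time
    doseStep <- if (nrow(regimen))
        vapply(regimen$time, function(tt) match(TRUE, times >= tt - 1e-9),
               integer(1)) else integer(0)

    for (k in seq_along(times)) {
        t <- times[k]
        due <- which(doseStep == k)
        for (j in due) {
            r <- applyDose(state, regimen[j, ], individual, lumenVolumes)
            state <- r$state
            lumenVolumes <- r$lumenVolumes
            sys$lumenVol$stomach_lumen <- lumenVolumes[["stomach_lumen"]]
            dosed <- dosed + r$mmolAdded
        }
        conc[k, ] <- state
        routeMat[k, ] <- totals
        if (k == length(times)) break

        if (mode == "held")
            held <- holdProvider(t, state, dosedNow = length(due) > 0)

        for (s in seq_len(nSub)) {
            r <- .reactionStep(sys, state, h / 2, mode, held, totals)
            state <- r$state; totals <- r$totals
            state <- .rk4Transport(sys, state, h)
            r <- .reactionStep(sys, state, h / 2, mode, held, totals)
            state <- r$state; totals <- r$totals
        }
    }

    meta <- list(dosedMmol = dosed, clampCount = sys$audit$clampCount,
                 maxDeficit = sys$audit$maxDeficit,
                 lumenVolumes = lumenVolumes,
                 individual = individual, mode = mode)
    new("ConcentrationTimeSeries", times = times, conc = conc,
        routeTotals = routeMat, meta = meta)
}

#' Simulate the standalone PBPK model (pure Michaelis-Menten mode)
#'
#' Liver alcohol dehydrogenase, liver aldehyde dehydrogenase and colon
#' aldehyde dehydrogenase run on closed-form kinetics; the auxiliary
#' excretion routes (breath, urine, sweat, feces, catalase) are inactive in
#' this mode — they belong to the flux-balance layer
#' (\code{\link{runDFBA}}).
#'
#' @param physiology a \linkS4class{PhysiologyParameters}.
#' @param partitions from \code{\link{buildPartitions}}.
#' @param kinetics a \linkS4class{KineticParameters}.
#' @param regimen dose regimen (see \code{\link{doseRegimen}}).
#' @param tEnd simulation horizon, min.
#' @param dt reporting step, min (default 1).
#' @param scenario optional \linkS4class{ScenarioConfig} supplying enzyme
#'   scales.
#' @param nSub sub-steps per reporting step (default 8).
#' @return A \linkS4class{ConcentrationTimeSeries}.
#' @examples
#' \donttest{
#' ind <- referenceMale()
#' phys <- buildPhysiology(ind)
#' parts <- buildPartitions(phys)
#' cts <- simulatePBPK(phys, parts, KineticParameters(),
#'                     doseRegimen(0, 0.25, 12.5), tEnd = 300)
#' head(concSeries(cts, "blood", "ethanol"))
#' }
#' @export
simulatePBPK <- function(physiology, partitions, kinetics, regimen,
                         tEnd, dt = 1, scenario = NULL, nSub = 8L) {
    if (nrow(regimen) && any(regimen$time >= tEnd))
        stop("all dose times must fall before tEnd")
    sys <- .pbpkSystem(physiology, partitions, kinetics, scenario)
    .integrate(sys, physiology@individual, regimen, tEnd, dt,
               holdProvider = NULL, nSub = nSub)
}

## ---------------------------------------------------------------------------
## Audit and export
## ---------------------------------------------------------------------------

#' Mass-balance audit of a simulated trajectory
#'
#' Checks dose = body burden + lumen residue + route eliminations for
#' ethanol, and production = body burden + eliminations for acetaldehyde.
#'
#' @param cts a \linkS4class{ConcentrationTimeSeries}.
#' @param physiology the physiology used for the simulation.
#' @return list with \code{ethanolRelError}, \code{acetaldehydeRelError}
#'   (relative to total dose / total production) and the audited components.
#' @export
massBalance <- function(cts, physiology) {
    org <- physiology@organs
    V <- stats::setNames(org$volume, org$organ)
    lum <- cts@meta$lumenVolumes
    V[names(lum)] <- lum
    final <- cts@conc[nrow(cts@conc), ]
    tot <- routeTotals(cts)

    burden <- function(met) {
        cols <- paste(c(.TISSUES, .LUMINA), met, sep = ".")
        sum(final[cols] * V[c(.TISSUES, .LUMINA)])
    }
    dosed <- cts@meta$dosedMmol
    ethOut <- sum(tot[c("liver_adh", "breath_ex", "urine_ex", "sweat_ex",
                        "feces_ex", "colon_catalase")])
    ethErr <- if (dosed > 0)
        (dosed - burden("ethanol") - ethOut) / dosed else 0

    produced <- sum(tot[c("liver_adh", "colon_catalase")])
    acOut <- sum(tot[c("liver_aldh2", "colon_aldh2")])
    acErr <- if (produced > 0)
        (produced - burden("acetaldehyde") - acOut) / produced else 0

    list(ethanolRelError = ethErr, acetaldehydeRelError = acErr,
         dosedMmol = dosed, ethanolBody = burden("ethanol"),
         ethanolEliminated = ethOut, acetaldehydeProduced = produced,
         acetaldehydeEliminated = acOut)
}

#' Write a trajectory (and route totals) as delimited text
#'
#' @param cts a \linkS4class{ConcentrationTimeSeries}.
#' @param file output path for the concentration table (TSV; metadata lines
#'   prefixed with \code{#}).
#' @param routeFile optional output path for the cumulative route-total
#'   table (mmol).
#' @return \code{file}, invisibly.
#' @export
writeTrajectory <- function(cts, file, routeFile = NULL) {
    con <- file(file, "w")
    writeLines(c("# ethanolWBM trajectory export",
                 sprintf("# states: %d, t_end: %g min, units: mM",
                         ncol(cts@conc), max(cts@times)),
                 sprintf("# dosed_mmol: %.6g", cts@meta$dosedMmol)), con)
    utils::write.table(data.frame(time = cts@times, cts@conc,
                                  check.names = FALSE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    if (!is.null(routeFile)) {
        con <- file(routeFile, "w")
        writeLines("# ethanolWBM cumulative route totals (mmol)", con)
        utils::write.table(data.frame(time = cts@times, cts@routeTotals,
                                      check.names = FALSE),
                           con, sep = "\t", quote = FALSE, row.names = FALSE)
        close(con)
    }
    invisible(file)
}
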