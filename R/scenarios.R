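## Scenario engines and calibration utilities: drink-strength absorption,
## ALDH2 isoforms, disulfiram inhibition, enzyme-expression sweeps,
## multi-dose regimens, and the AUC / MAE exposure metrics.

#' ALDH2 isoform table (homozygous genotypes)
#'
#' @return data.frame with columns \code{isoform}, \code{mutation},
#'   \code{allelic_frequency_pct}, \code{major_ethnicity},
#'   \code{activity_pct} (in-vitro activity as \% of wild type).
#' @export
aldh2Isoforms <- function() {
    .cached("isoforms", function() .readTsv(.extdata("aldh2_isoforms.tsv")))
}

#' Scale ALDH2 kinetics by isoform activity
#'
#' Multiplies the liver and colon ALDH2 Vmax by \code{activity/100}; all
#' other parameters are untouched. Only homozygous genotypes are supported.
#'
#' @param kinetics a \linkS4class{KineticParameters}.
#' @param isoform isoform id from \code{\link{aldh2Isoforms}}.
#' @param table isoform table (defaults to the shipped one).
#' @return Scaled \linkS4class{KineticParameters}.
#' @examples
#' k <- applyIsoform(KineticParameters(), "ALDH2.2")
#' k@vmaxALDH2 / KineticParameters()@vmaxALDH2  # 0.015
#' @export
applyIsoform <- function(kinetics, isoform, table = aldh2Isoforms()) {
    if (grepl("/", isoform, fixed = TRUE))
        stop("heterozygous genotypes are not supported; supply one of the ",
             "homozygous isoform ids: ",
             paste(table$isoform, collapse = ", "))
    i <- match(isoform, table$isoform)
    if (is.na(i))
        stop(sprintf("unknown ALDH2 isoform '%s'; valid ids: %s", isoform,
                     paste(table$isoform, collapse = ", ")))
    s <- table$activity_pct[i] / 100
    kinetics@vmaxALDH2 <- kinetics@vmaxALDH2 * s
    kinetics@vmaxALDH2Colon <- kinetics@vmaxALDH2Colon * s
    kinetics
}

#' Shipped disulfiram inhibition anchors
#'
#' @return data.frame with columns \code{disulfiram_uM},
#'   \code{relative_activity}.
#' @export
disulfiramCorrelation <- function() {
    .cached("disulfiram", function()
        .readTsv(.extdata("disulfiram_anchors_synthetic.tsv")))
}

.DISULFIRAM_MW <- 296.54  # g/mol

.disulfiramLambda <- function(correlation) {
    key <- "disulfiramLambda"
    if (is.null(.pkgCache[[key]])) {
        fit <- stats::optimize(function(l)
            sum((exp(-l * correlation$disulfiram_uM) -
                 correlation$relative_activity)^2),
            interval = c(1e-4, 2))
        assign(key, fit$minimum, envir = .pkgCache)
    }
    .pkgCache[[key]]
}

#' Relative ALDH2 activity at a constant blood disulfiram level
#'
#' A single-parameter exponential inhibition curve
#' \code{activity = exp(-lambda * level_uM)} fitted by least squares to the
#' shipped in-vitro anchor table; the blood level in mg/L is converted to
#' micromolar via the molecular weight of disulfiram (296.54 g/mol).
#'
#' @param level blood disulfiram, mg/L (>= 0).
#' @param correlation anchor table (defaults to the shipped one).
#' @return Activity fraction in (0, 1]; exactly 1 at level 0; strictly
#'   decreasing in level.
#' @examples
#' disulfiramActivity(0)  # 1
#' disulfiramActivity(8) < disulfiramActivity(2)  # TRUE
#' @export
disulfiramActivity <- function(level, correlation = disulfiramCorrelation()) {
    if (any(level < 0)) stop("disulfiram level must be >= 0")
    uM <- level / .DISULFIRAM_MW * 1000
    exp(-.disulfiramLambda(correlation) * uM)
}

## ---------------------------------------------------------------------------
## Drink-strength absorption correlation
## ---------------------------------------------------------------------------

#' Shipped drink-strength absorption anchors
#'
#' @return data.frame with columns \code{strength_wv}, \code{k_stom},
#'   \code{k_si}, \code{k_stomsi} (1/min), anchored at 5.1, 12.5 and
#'   20 \%w/v.
#' @export
absorptionCorrelation <- function() {
    .cached("absorption", function()
        .readTsv(.extdata("absorption_anchors_synthetic.tsv")))
}

#' Absorption and transit rates for a drink strength
#'
#' Monotone piecewise-linear interpolation through the calibrated anchors;
#' outside the calibrated [5.1, 20] \%w/v range the edge segment is
#' extended linearly, a warning is issued, and the result carries
#' \code{attr(, "extrapolated") = TRUE}.
#'
#' @param strength drink strength, \%w/v (> 0).
#' @param correlation anchor table (defaults to the shipped one).
#' @return Named numeric \code{c(kStom, kSI, kStomSI)} (1/min).
#' @examples
#' absorptionParams(5.1)
#' @export
absorptionParams <- function(strength, correlation = absorptionCorrelation()) {
    if (strength <= 0) stop("drink strength must be > 0")
    x <- correlation$strength_wv
    extrap <- strength < min(x) || strength > max(x)
    interp1 <- function(y) {
        if (strength <= min(x)) {
            s <- (y[2] - y[1]) / (x[2] - x[1])
            max(y[1] + s * (strength - x[1]), 1e-4)
        } else if (strength >= max(x)) {
            n <- length(x)
            s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
            max(y[n] + s * (strength - x[n]), 1e-4)
        } else stats::approx(x, y, xout = strength)$y
    }
    out <- c(kStom = interp1(correlation$k_stom),
             kSI = interp1(correlation$k_si),
             kStomSI = interp1(correlation$k_stomsi))
    if (extrap) {
        warning(sprintf(
            "strength %.3g %%w/v is outside the calibrated [%.3g, %.3g] range; rates are extrapolated",
            strength, min(x), max(x)))
        attr(out, "extrapolated") <- TRUE
    } else attr(out, "extrapolated") <- FALSE
    out
}

#' Default kinetic parameters from the shipped hepatic parameter file
#'
#' Hepatic Michaelis-Menten constants come from the shipped parameter file
#' (or a user replacement with the same schema); absorption/transit rates
#' come from the drink-strength correlation.
#'
#' @param strength drink strength used to set absorption rates (\%w/v).
#' @param path optional path to an alternative hepatic parameter file.
#' @return A \linkS4class{KineticParameters}.
#' @export
loadKinetics <- function(strength = 12.5, path = NULL) {
    tab <- if (is.null(path))
        .cached("umulisKin", function()
            .readTsv(.extdata("kinetics_umulis_synthetic.tsv")))
    else .readTsv(path)
    p <- stats::setNames(tab$value, tab$parameter)
    ka <- suppressWarnings(absorptionParams(strength))
    KineticParameters(vmaxADH = p[["vmax_adh"]], kmADH = p[["km_adh"]],
                      vmaxALDH2 = p[["vmax_aldh2"]],
                      kmALDH2 = p[["km_aldh2"]],
                      vmaxALDH2Colon = p[["vmax_aldh2_colon"]],
                      kmALDH2Colon = p[["km_aldh2_colon"]],
                      kStom = ka[["kStom"]], kSI = ka[["kSI"]],
                      kStomSI = ka[["kStomSI"]])
}

## ---------------------------------------------------------------------------
## Exposure metrics
## ---------------------------------------------------------------------------

#' Area under a concentration-time curve
#'
#' Trapezoidal integration between \code{t0} and \code{t1}. With
#' \code{t1 = Inf} the integral is extended beyond the observed span by a
#' log-linear terminal phase fitted to the last declining points
#' (\code{AUC_tail = C_last / lambda_z}).
#'
#' @param series data.frame with columns \code{time} (min) and \code{conc}
#'   (mM), e.g. from \code{\link{concSeries}}, or a
#'   \linkS4class{ConcentrationTimeSeries} (then \code{compartment} and
#'   \code{metabolite} select the curve).
#' @param t0,t1 integration limits, min; \code{t1 = Inf} for extrapolation.
#'   A finite \code{t1} beyond the series span is an error.
#' @param compartment,metabolite used when \code{series} is a trajectory
#'   object.
#' @param nTail points used for the terminal log-linear fit (default 5).
#' @return AUC in mM*min (multiply by 1000 for uM*min).
#' @examples
#' auc(data.frame(time = 0:10, conc = rep(2, 11)), 0, 10)  # 20
#' @export
auc <- function(series, t0 = NULL, t1 = NULL, compartment = "blood",
                metabolite = "ethanol", nTail = 5) {
    if (is(series, "ConcentrationTimeSeries"))
        series <- concSeries(series, compartment, metabolite)
    tt <- series$time; cc <- series$conc
    if (is.null(t0)) t0 <- min(tt)
    if (is.null(t1)) t1 <- max(tt)
    if (t0 >= t1) stop("t0 must be < t1")
    if (t0 < min(tt)) stop("t0 precedes the series span")
    tail <- 0
    if (is.infinite(t1)) {
        n <- length(tt)
        sel <- which(cc > 0)
        sel <- sel[sel > max(1, n - 3 * nTail)]
        sel <- utils::tail(sel, nTail)
        if (length(sel) < 3)
            stop("too few positive terminal points for extrapolation")
        fit <- stats::lm(log(cc[sel]) ~ tt[sel])
        lambda <- -stats::coef(fit)[[2]]
        if (lambda <= 0)
            stop("terminal phase is not declining; cannot extrapolate to infinity")
        tail <- cc[length(cc)] / lambda
        t1 <- max(tt)
    } else if (t1 > max(tt) + 1e-9) {
        stop("t1 lies beyond the series span; use t1 = Inf for extrapolation")
    }
    grid <- unique(sort(c(t0, t1, tt[tt > t0 & tt < t1])))
    cg <- stats::approx(tt, cc, xout = grid)$y
    sum(diff(grid) * (utils::head(cg, -1) + utils::tail(cg, -1)) / 2) + tail
}

#' Mean absolute error between predicted and observed curves
#'
#' The predicted curve is interpolated onto the observed time points.
#'
#' @param predicted data.frame with \code{time}, \code{conc}.
#' @param observed data.frame with \code{time}, \code{conc}.
#' @return Mean absolute residual, same units as the inputs.
#' @examples
#' mae(data.frame(time = 1:3, conc = c(2, 0, 4)),
#'     data.frame(time = 1:3, conc = c(1, 1, 1)))  # 5/3
#' @export
mae <- function(predicted, observed) {
    if (!nrow(observed) || !nrow(predicted)) stop("empty input series")
    p <- stats::approx(predicted$time, predicted$conc, xout = observed$time,
                       rule = 2)$y
    mean(abs(p - observed$conc))
}

## ---------------------------------------------------------------------------
## Absorption-parameter fitting
## ---------------------------------------------------------------------------

#' Fit gut absorption/transit rates to an observed blood-ethanol curve
#'
#' Least-squares fit of (kStom, kSI, kStomSI) on the log scale, holding the
#' hepatic kinetics fixed, using the standalone PBPK model for prediction
#' (gut absorption was calibrated on the PBPK layer before network
#' coupling).
#'
#' @param observed data.frame with \code{time} (min), \code{conc} (mM blood
#'   ethanol); at least 5 time points.
#' @param kinetics fixed \linkS4class{KineticParameters} (its absorption
#'   slots provide the starting values unless \code{start} is given).
#' @param individual an \linkS4class{Individual}.
#' @param dose,strength dose (g/kg) and drink strength (\%w/v) of the arm.
#' @param start optional named start values \code{c(kStom, kSI, kStomSI)}.
#' @param dt,nSub integrator settings for the repeated predictions.
#' @return list with \code{kStom}, \code{kSI}, \code{kStomSI}, \code{mae},
#'   \code{converged}, \code{iterations}, \code{message}.
#' @export
fitAbsorption <- function(observed, kinetics, individual, dose = 0.5,
                          strength = 12.5, start = NULL, dt = 2, nSub = 4L) {
    if (nrow(observed) < 5)
        stop("need at least 5 observed time points")
    phys <- buildPhysiology(individual)
    parts <- buildPartitions(phys)
    tEnd <- max(observed$time) + dt
    regimen <- suppressWarnings(doseRegimen(0, dose, strength))
    if (is.null(start))
        start <- c(kStom = kinetics@kStom, kSI = kinetics@kSI,
                   kStomSI = kinetics@kStomSI)
    predict1 <- function(k) {
        kin <- kinetics
        kin@kStom <- k[[1]]; kin@kSI <- k[[2]]; kin@kStomSI <- k[[3]]
        cts <- simulatePBPK(phys, parts, kin, regimen, tEnd, dt = dt,
                            nSub = nSub)
        concSeries(cts, "blood", "ethanol")
    }
    resid <- function(logk) {
        pred <- predict1(exp(logk))
        stats::approx(pred$time, pred$conc, xout = observed$time,
                      rule = 2)$y - observed$conc
    }
    fit <- minpack.lm::nls.lm(par = log(unlist(start)), fn = resid,
                              control = minpack.lm::nls.lm.control(
                                  maxiter = 60, ftol = 1e-10, ptol = 1e-10))
    k <- exp(fit$par)
    pred <- predict1(k)
    out <- list(kStom = unname(k[1]), kSI = unname(k[2]),
                kStomSI = unname(k[3]),
                mae = mae(pred, observed),
                converged = fit$info %in% 1:4,
                iterations = fit$niter, message = fit$message)
    if (!out$converged)
        stop(structure(class = c("fitNonConvergence", "error", "condition"),
                       list(message = sprintf(
                           "absorption fit did not converge (%s); best-so-far kStom=%.4g kSI=%.4g kStomSI=%.4g, MAE=%.4g",
                           fit$message, out$kStom, out$kSI, out$kStomSI,
                           out$mae),
                           call = sys.call(), best = out)))
    out
}

## ---------------------------------------------------------------------------
## Scenario engines
## ---------------------------------------------------------------------------

#' Run one complete coupled scenario
#'
#' Convenience wrapper: builds physiology and partitions for the individual,
#' takes hepatic kinetics from the shipped parameter file, absorption rates
#' from the drink-strength correlation (first regimen entry), applies the
#' scenario's isoform to the kinetics, builds the ethanol network and runs
#' the coupled simulation.
#'
#' @param config a \linkS4class{ScenarioConfig}.
#' @param individual an \linkS4class{Individual}.
#' @param kinetics optional \linkS4class{KineticParameters} override.
#' @param constraints route-fraction table (default \code{\link{routeConstraints}()}).
#' @param nSub integrator sub-steps.
#' @return A \linkS4class{ConcentrationTimeSeries}.
#' @export
runScenario <- function(config, individual = referenceMale(),
                        kinetics = NULL,
                        constraints = routeConstraints(), nSub = 8L) {
    phys <- buildPhysiology(individual)
    parts <- buildPartitions(phys)
    if (is.null(kinetics))
        kinetics <- loadKinetics(strength = config@regimen$strength[1])
    net <- buildEthanolNetwork(constraints)
    runDFBA(phys, parts, kinetics, net, config, nSub = nSub)
}

#' Enzyme-expression sweep
#'
#' Re-runs the coupled scenario over a set of liver enzyme-expression
#' scales (scaling the alcohol- and aldehyde-dehydrogenase capacities
#' jointly) and tabulates the cumulative mmol eliminated per route and the
#' blood exposure metrics.
#'
#' @param scales positive expression scales (1 = normal).
#' @param setup list with \code{physiology}, \code{partitions},
#'   \code{kinetics}, \code{network}, \code{scenario}.
#' @param nSub integrator sub-steps.
#' @return data.frame: \code{scale}, per-route cumulative mmol
#'   (\code{liver}, \code{urine}, \code{sweat}, \code{breath},
#'   \code{catalase}, \code{feces}), \code{liverShare},
#'   \code{ethanolAUC} (mM*min) and \code{acetaldehydeAUC} (uM*min).
#' @export
enzymeExpressionSweep <- function(scales, setup, nSub = 8L) {
    if (any(scales < 0)) stop("expression scales must be >= 0")
    rows <- lapply(scales, function(s) {
        sc <- setup$scenario
        sc@expressionScale <- s
        cts <- runDFBA(setup$physiology, setup$partitions, setup$kinetics,
                       setup$network, sc, nSub = nSub)
        tot <- routeTotals(cts)
        ethTot <- sum(tot[c("liver_adh", "urine_ex", "sweat_ex", "breath_ex",
                            "feces_ex", "colon_catalase")])
        data.frame(scale = s,
                   liver = tot[["liver_adh"]], urine = tot[["urine_ex"]],
                   sweat = tot[["sweat_ex"]], breath = tot[["breath_ex"]],
                   catalase = tot[["colon_catalase"]],
                   feces = tot[["feces_ex"]],
                   liverShare = if (ethTot > 0)
                       tot[["liver_adh"]] / ethTot else NA_real_,
                   ethanolAUC = auc(cts, 0, sc@tEnd, "blood", "ethanol"),
                   acetaldehydeAUC = 1000 *
                       auc(cts, 0, sc@tEnd, "blood", "acetaldehyde"))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Multi-dose scenario run
#'
#' @param config a \linkS4class{ScenarioConfig} whose regimen holds the
#'   repeated doses (all dose times must precede \code{tEnd}).
#' @param individual an \linkS4class{Individual}.
#' @param kinetics optional kinetics override.
#' @param nSub integrator sub-steps.
#' @return list with the trajectory (\code{cts}) and \code{aucs}, a
#'   data.frame of per-compartment AUCs over the full horizon
#'   (\code{ethanolAUC} mM*min, \code{acetaldehydeAUC} uM*min).
#' @export
multiDoseRun <- function(config, individual = referenceMale(),
                         kinetics = NULL, nSub = 8L) {
    if (nrow(config@regimen) && any(config@regimen$time >= config@tEnd))
        stop("all dose times must precede tEnd")
    cts <- runScenario(config, individual, kinetics, nSub = nSub)
    comps <- c(.TISSUES)
    aucs <- do.call(rbind, lapply(comps, function(o) {
        data.frame(compartment = o,
                   ethanolAUC = auc(cts, 0, config@tEnd, o, "ethanol"),
                   acetaldehydeAUC = 1000 *
                       auc(cts, 0, config@tEnd, o, "acetaldehyde"))
    }))
    list(cts = cts, aucs = aucs)
}
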