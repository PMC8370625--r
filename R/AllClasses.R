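#' @import methods
NULL

## ---------------------------------------------------------------------------
## Individual
## ---------------------------------------------------------------------------

#' Anthropometric description of a simulated individual
#'
#' Holds the inputs from which organ volumes, blood flows and cardiac output
#' are derived: age, sex, height, weight and body-fat fraction.
#'
#' @slot age numeric, years.
#' @slot sex character, \code{"male"} or \code{"female"}.
#' @slot height numeric, cm.
#' @slot weight numeric, kg.
#' @slot bodyFat numeric, fraction of body mass in (0, 1).
#' @export
setClass("Individual",
    representation(age = "numeric", sex = "character", height = "numeric",
                   weight = "numeric", bodyFat = "numeric"))

## Documented validity range of the shipped anthropometric correlation table.
.individualRange <- list(age = c(18, 80), height = c(140, 210),
                         weight = c(40, 150), bodyFat = c(0.05, 0.60))

setValidity("Individual", function(object) {
    msgs <- character(0)
    for (f in c("age", "height", "weight", "bodyFat")) {
        v <- slot(object, f)
        if (length(v) != 1L || !is.finite(v) || v <= 0)
            msgs <- c(msgs, sprintf("'%s' must be a single positive number", f))
    }
    if (!(object@sex %in% c("male", "female")))
        msgs <- c(msgs, "'sex' must be \"male\" or \"female\"")
    if (length(object@bodyFat) == 1L && is.finite(object@bodyFat) &&
        (object@bodyFat <= 0 || object@bodyFat >= 1))
        msgs <- c(msgs, "'bodyFat' must lie in (0, 1)")
    if (length(msgs)) msgs else TRUE
})

#' Construct an Individual
#'
#' @param age age in years.
#' @param sex \code{"male"} or \code{"female"}.
#' @param height height in cm.
#' @param weight weight in kg.
#' @param bodyFat body-fat mass fraction, in (0, 1).
#' @return An \linkS4class{Individual}.
#' @examples
#' referenceMale()
#' Individual(30, "male", 175, 70, 0.18)
#' @export
Individual <- function(age, sex, height, weight, bodyFat) {
    new("Individual", age = as.numeric(age), sex = as.character(sex),
        height = as.numeric(height), weight = as.numeric(weight),
        bodyFat = as.numeric(bodyFat))
}

#' Reference male used throughout the bundled studies
#'
#' A 25.6-year-old, 74.5 kg, 180 cm male with 20\% body fat.
#' @return An \linkS4class{Individual}.
#' @export
referenceMale <- function() Individual(25.6, "male", 180, 74.5, 0.20)

setMethod("show", "Individual", function(object) {
    cat(sprintf("Individual: %s, %.1f y, %.1f cm, %.1f kg, %.0f%% body fat\n",
                object@sex, object@age, object@height, object@weight,
                100 * object@bodyFat))
})

## ---------------------------------------------------------------------------
## Metabolite
## ---------------------------------------------------------------------------

#' Physicochemical record for a tracked metabolite
#'
#' @slot name character.
#' @slot molecularWeight numeric, g/mol.
#' @slot lipophilicity numeric, log10 octanol:water partition.
#' @slot fractionUnbound numeric in (0, 1], unbound fraction in plasma.
#' @export
setClass("Metabolite",
    representation(name = "character", molecularWeight = "numeric",
                   lipophilicity = "numeric", fractionUnbound = "numeric"))

setValidity("Metabolite", function(object) {
    msgs <- character(0)
    if (object@molecularWeight <= 0)
        msgs <- c(msgs, "'molecularWeight' must be > 0")
    if (object@fractionUnbound <= 0 || object@fractionUnbound > 1)
        msgs <- c(msgs, "'fractionUnbound' must lie in (0, 1]")
    if (length(msgs)) msgs else TRUE
})

#' Construct a Metabolite
#' @param name metabolite name.
#' @param molecularWeight g/mol, positive.
#' @param lipophilicity log10 partition coefficient.
#' @param fractionUnbound unbound plasma fraction in (0, 1].
#' @return A \linkS4class{Metabolite}.
#' @export
Metabolite <- function(name, molecularWeight, lipophilicity, fractionUnbound) {
    new("Metabolite", name = name, molecularWeight = as.numeric(molecularWeight),
        lipophilicity = as.numeric(lipophilicity),
        fractionUnbound = as.numeric(fractionUnbound))
}

setMethod("show", "Metabolite", function(object) {
    cat(sprintf("Metabolite '%s': MW %.2f g/mol, logP %.2f, fu %.2f\n",
                object@name, object@molecularWeight, object@lipophilicity,
                object@fractionUnbound))
})

## ---------------------------------------------------------------------------
## PhysiologyParameters
## ---------------------------------------------------------------------------

#' Per-organ volumes, blood flows and tissue composition
#'
#' Produced by \code{\link{buildPhysiology}}. The \code{organs} table has one
#' row per model compartment (14 tissues and 3 lumina) with columns
#' \code{organ}, \code{volume} (L), \code{flow} (L/min), \code{water},
#' \code{nlipid}, \code{plipid}, \code{is_lumen}, \code{portal}.
#'
#' @slot organs data.frame as described above.
#' @slot cardiacOutput numeric, L/min.
#' @slot plasma numeric, named water/nlipid/plipid composition of the plasma
#'   reference phase.
#' @slot individual the \linkS4class{Individual} the parameters derive from.
#' @export
setClass("PhysiologyParameters",
    representation(organs = "data.frame", cardiacOutput = "numeric",
                   plasma = "numeric", individual = "Individual"))

setValidity("PhysiologyParameters", function(object) {
    org <- object@organs
    msgs <- character(0)
    need <- c("organ", "volume", "flow", "water", "nlipid", "plipid",
              "is_lumen", "portal")
    if (!all(need %in% names(org)))
        return(sprintf("organs table must have columns: %s",
                       paste(need, collapse = ", ")))
    if (any(org$volume <= 0)) msgs <- c(msgs, "all organ volumes must be > 0")
    if (any(org$flow < 0)) msgs <- c(msgs, "organ flows must be >= 0")
    tissue <- org[org$is_lumen == 0, ]
    bad <- tissue$water + tissue$nlipid + tissue$plipid > 1 + 1e-9
    if (any(bad))
        msgs <- c(msgs, "tissue composition fractions must sum to <= 1")
    ## Flow conservation at the lung mixing point: systemic flows = CO.
    systemic <- tissue[!(tissue$organ %in% c("lung", "blood")), ]
    if (abs(sum(systemic$flow) - object@cardiacOutput) >
        1e-6 * object@cardiacOutput)
        msgs <- c(msgs, "systemic organ flows must sum to cardiac output")
    if (length(msgs)) msgs else TRUE
})

#' @describeIn PhysiologyParameters-class named vector of organ volumes (L).
#' @param object,x a \code{PhysiologyParameters}.
#' @export
organVolumes <- function(x) {
    stats::setNames(x@organs$volume, x@organs$organ)
}

#' @describeIn PhysiologyParameters-class named vector of organ blood flows
#'   (L/min); lumina carry zero flow.
#' @export
organFlows <- function(x) {
    stats::setNames(x@organs$flow, x@organs$organ)
}

#' @describeIn PhysiologyParameters-class cardiac output (L/min).
#' @export
cardiacOutput <- function(x) x@cardiacOutput

setMethod("show", "PhysiologyParameters", function(object) {
    cat(sprintf("PhysiologyParameters: %d compartments, CO %.2f L/min\n",
                nrow(object@organs), object@cardiacOutput))
    cat(sprintf("  total tissue volume %.1f L (body weight %.1f kg)\n",
                sum(object@organs$volume[object@organs$is_lumen == 0]),
                object@individual@weight))
})

## ---------------------------------------------------------------------------
## KineticParameters
## ---------------------------------------------------------------------------

#' Enzyme, absorption, transport and clearance constants
#'
#' Michaelis-Menten constants are expressed per litre of host organ
#' (mM/min and mM); absorption/transit rates are first order (1/min);
#' auxiliary-route clearances are apparent clearances (L/min) that generate
#' the concentration-driven proposals for the urine, sweat and colon-catalase
#' routes inside their whole-body flux-fraction bands.
#'
#' @slot vmaxADH,kmADH liver alcohol dehydrogenase, mM/min and mM.
#' @slot vmaxALDH2,kmALDH2 liver aldehyde dehydrogenase, mM/min and mM.
#' @slot vmaxALDH2Colon,kmALDH2Colon colon aldehyde dehydrogenase.
#' @slot kStom,kSI first-order lumen absorption rates, 1/min.
#' @slot kStomSI gastric emptying (stomach to small-intestine lumen), 1/min.
#' @slot kSILI small- to large-intestine lumen transit, 1/min.
#' @slot kLI first-order absorption from the large-intestine lumen, 1/min.
#' @slot clUrine,clSweat,clCatalase apparent route clearances, L/min.
#' @export
setClass("KineticParameters",
    representation(vmaxADH = "numeric", kmADH = "numeric",
                   vmaxALDH2 = "numeric", kmALDH2 = "numeric",
                   vmaxALDH2Colon = "numeric", kmALDH2Colon = "numeric",
                   kStom = "numeric", kSI = "numeric", kStomSI = "numeric",
                   kSILI = "numeric", kLI = "numeric",
                   clUrine = "numeric", clSweat = "numeric",
                   clCatalase = "numeric"))

setValidity("KineticParameters", function(object) {
    msgs <- character(0)
    for (f in slotNames("KineticParameters")) {
        v <- slot(object, f)
        if (length(v) != 1L || !is.finite(v) || v < 0)
            msgs <- c(msgs, sprintf("'%s' must be a single nonnegative number", f))
    }
    for (f in c("kmADH", "kmALDH2", "kmALDH2Colon")) {
        if (slot(object, f) <= 0)
            msgs <- c(msgs, sprintf("'%s' must be > 0", f))
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct kinetic parameters
#'
#' Defaults are the shipped hepatic parameter set (see
#' \code{system.file("extdata", "kinetics_umulis_synthetic.tsv",
#' package = "ethanolWBM")}) plus mid-strength absorption rates and the
#' auxiliary-route clearances documented in the methods vignette.
#'
#' @param vmaxADH,kmADH,vmaxALDH2,kmALDH2,vmaxALDH2Colon,kmALDH2Colon
#'   Michaelis-Menten constants (mM/min, mM).
#' @param kStom,kSI,kStomSI,kSILI first-order lumen rates (1/min).
#' @param clUrine,clSweat,clCatalase apparent route clearances (L/min).
#' @return A \linkS4class{KineticParameters}.
#' @export
KineticParameters <- function(vmaxADH = 2.2, kmADH = 0.4,
                              vmaxALDH2 = 2.7, kmALDH2 = 0.0012,
                              vmaxALDH2Colon = 0.5, kmALDH2Colon = 0.0012,
                              kStom = 0.035, kSI = 0.12, kStomSI = 0.06,
                              kSILI = 0.01, kLI = 0.05,
                              clUrine = 0.04, clSweat = 0.04,
                              clCatalase = 0.01) {
    new("KineticParameters", vmaxADH = vmaxADH, kmADH = kmADH,
        vmaxALDH2 = vmaxALDH2, kmALDH2 = kmALDH2,
        vmaxALDH2Colon = vmaxALDH2Colon, kmALDH2Colon = kmALDH2Colon,
        kStom = kStom, kSI = kSI, kStomSI = kStomSI, kSILI = kSILI, kLI = kLI,
        clUrine = clUrine, clSweat = clSweat, clCatalase = clCatalase)
}

setMethod("show", "KineticParameters", function(object) {
    cat(sprintf(paste0("KineticParameters: ADH Vmax %.2f mM/min (Km %.2f mM), ",
                       "ALDH2 Vmax %.2f mM/min (Km %.4g mM)\n"),
                object@vmaxADH, object@kmADH, object@vmaxALDH2, object@kmALDH2))
    cat(sprintf("  absorption kStom %.3f, kSI %.3f, kStomSI %.3f 1/min\n",
                object@kStom, object@kSI, object@kStomSI))
})

## ---------------------------------------------------------------------------
## StoichiometricModel & FluxSolution
## ---------------------------------------------------------------------------

#' Reduced whole-body ethanol/acetaldehyde stoichiometric network
#'
#' @slot smatrix numeric matrix, internal metabolites x reactions.
#' @slot reactions data.frame with columns \code{id}, \code{role},
#'   \code{lb}, \code{ub} (mmol/min, whole-body flux).
#' @slot metabolites character, internal metabolite ids (rows of
#'   \code{smatrix}); boundary species are implicit.
#' @slot objective character, id of the maximised reaction.
#' @slot couplings data.frame (possibly empty) with columns \code{id},
#'   \code{cmin}, \code{cmax}: linear couplings
#'   \code{cmin * v_objective <= v_id <= cmax * v_objective} encoding the
#'   whole-body route-fraction constraints.
#' @export
setClass("StoichiometricModel",
    representation(smatrix = "matrix", reactions = "data.frame",
                   metabolites = "character", objective = "character",
                   couplings = "data.frame"),
    prototype(couplings = data.frame(id = character(0), cmin = numeric(0),
                                     cmax = numeric(0))))

setValidity("StoichiometricModel", function(object) {
    msgs <- character(0)
    rx <- object@reactions
    if (!all(c("id", "role", "lb", "ub") %in% names(rx)))
        return("reactions table must have columns id, role, lb, ub")
    if (ncol(object@smatrix) != nrow(rx))
        msgs <- c(msgs, "S-matrix columns must match reactions")
    if (nrow(object@smatrix) != length(object@metabolites))
        msgs <- c(msgs, "S-matrix rows must match metabolites")
    if (anyDuplicated(rx$id))
        msgs <- c(msgs, "reaction ids must be unique")
    if (!(object@objective %in% rx$id))
        msgs <- c(msgs, "objective reaction id must exist")
    if (any(rx$lb > rx$ub + 1e-12))
        msgs <- c(msgs, "lower bounds must not exceed upper bounds")
    if (length(object@metabolites) &&
        any(rowSums(abs(object@smatrix)) == 0))
        msgs <- c(msgs, "every metabolite must participate in >= 1 reaction")
    if (length(msgs)) msgs else TRUE
})

#' @describeIn StoichiometricModel-class the reactions table.
#' @param x a \code{StoichiometricModel}.
#' @export
reactions <- function(x) x@reactions

#' @describeIn StoichiometricModel-class the stoichiometric matrix.
#' @export
stoichiometry <- function(x) x@smatrix

setMethod("show", "StoichiometricModel", function(object) {
    cat(sprintf("StoichiometricModel: %d reactions, %d internal metabolites\n",
                nrow(object@reactions), length(object@metabolites)))
    cat(sprintf("  objective: maximise '%s'\n", object@objective))
})

#' Flux-balance solution
#'
#' @slot fluxes named numeric, mmol/min per reaction.
#' @slot objectiveValue numeric.
#' @slot status character: \code{"optimal"}, \code{"infeasible"} or
#'   \code{"unbounded"}.
#' @export
setClass("FluxSolution",
    representation(fluxes = "numeric", objectiveValue = "numeric",
                   status = "character"))

#' @describeIn FluxSolution-class named flux vector (mmol/min).
#' @param x a \code{FluxSolution}.
#' @export
fluxes <- function(x) x@fluxes

setMethod("show", "FluxSolution", function(object) {
    cat(sprintf("FluxSolution (%s): objective %.4g mmol/min\n",
                object@status, object@objectiveValue))
})

## ---------------------------------------------------------------------------
## ScenarioConfig
## ---------------------------------------------------------------------------

#' Everything that perturbs bounds and kinetics in a simulation scenario
#'
#' @slot expressionScale numeric >= 0, liver enzyme expression relative to
#'   normal (scales the ADH and ALDH2 capacities jointly).
#' @slot isoform character, one of the ALDH2 isoform ids
#'   (see \code{\link{aldh2Isoforms}}).
#' @slot disulfiramLevel numeric >= 0, constant blood disulfiram (mg/L).
#' @slot regimen data.frame of dose events (\code{time} min, \code{dose}
#'   g ethanol/kg, \code{strength} \%w/v), see \code{\link{doseRegimen}}.
#' @slot tol numeric > 0, dFBA re-solve tolerance (relative deviation).
#' @slot tEnd,dt numeric, simulation horizon and reporting step (min).
#' @export
setClass("ScenarioConfig",
    representation(expressionScale = "numeric", isoform = "character",
                   disulfiramLevel = "numeric", regimen = "data.frame",
                   tol = "numeric", tEnd = "numeric", dt = "numeric"))

setValidity("ScenarioConfig", function(object) {
    msgs <- character(0)
    if (object@expressionScale < 0)
        msgs <- c(msgs, "'expressionScale' must be >= 0")
    if (object@disulfiramLevel < 0)
        msgs <- c(msgs, "'disulfiramLevel' must be >= 0")
    if (object@tol <= 0) msgs <- c(msgs, "'tol' must be > 0")
    if (object@tEnd <= 0 || object@dt <= 0)
        msgs <- c(msgs, "'tEnd' and 'dt' must be > 0")
    if (nrow(object@regimen) &&
        any(object@regimen$time >= object@tEnd))
        msgs <- c(msgs, "dose times must fall before 'tEnd'")
    if (length(msgs)) msgs else TRUE
})

#' Construct a dosing regimen
#'
#' @param times dose times, min (>= 0).
#' @param doses grams of ethanol per kg body weight per dose.
#' @param strengths drink strength, \%w/v ethanol. A warning is issued
#'   outside the calibrated 5.1-20 range.
#' @return data.frame with columns \code{time}, \code{dose}, \code{strength}.
#' @examples
#' doseRegimen(0, 0.25, 12.5)
#' doseRegimen(seq(0, 240, by = 60), 0.25, 20)
#' @export
doseRegimen <- function(times, doses, strengths) {
    df <- data.frame(time = as.numeric(times), dose = as.numeric(doses),
                     strength = as.numeric(strengths))
    if (any(df$time < 0)) stop("dose times must be >= 0")
    if (any(df$dose < 0)) stop("doses must be >= 0")
    if (any(df$strength <= 0)) stop("drink strength must be > 0")
    if (any(df$strength < 5.1 | df$strength > 20))
        warning("drink strength outside the calibrated 5.1-20 %w/v range")
    df[order(df$time), , drop = FALSE]
}

#' Construct a ScenarioConfig
#'
#' @param expressionScale liver enzyme expression scale (1 = normal).
#' @param isoform ALDH2 isoform id (default wild type \code{"ALDH2.1"}).
#' @param disulfiramLevel constant blood disulfiram, mg/L.
#' @param regimen dose regimen from \code{\link{doseRegimen}}.
#' @param tol dFBA re-solve tolerance (default 0.01, i.e. 1\%).
#' @param tEnd simulation horizon, min.
#' @param dt reporting/FBA-hold step, min.
#' @return A \linkS4class{ScenarioConfig}.
#' @export
ScenarioConfig <- function(expressionScale = 1, isoform = "ALDH2.1",
                           disulfiramLevel = 0,
                           regimen = doseRegimen(0, 0.25, 12.5),
                           tol = 0.01, tEnd = 500, dt = 1) {
    new("ScenarioConfig", expressionScale = as.numeric(expressionScale),
        isoform = isoform, disulfiramLevel = as.numeric(disulfiramLevel),
        regimen = regimen, tol = as.numeric(tol), tEnd = as.numeric(tEnd),
        dt = as.numeric(dt))
}

setMethod("show", "ScenarioConfig", function(object) {
    cat(sprintf(paste0("ScenarioConfig: expression %.2f, %s, disulfiram ",
                       "%.1f mg/L, %d dose(s), tol %.3g, %g min\n"),
                object@expressionScale, object@isoform,
                object@disulfiramLevel, nrow(object@regimen), object@tol,
                object@tEnd))
})

## ---------------------------------------------------------------------------
## ConcentrationTimeSeries
## ---------------------------------------------------------------------------

#' Simulated concentration trajectories and route totals
#'
#' @slot times numeric, strictly increasing sampling times (min).
#' @slot conc numeric matrix, time x (compartment.metabolite), mM.
#' @slot routeTotals numeric matrix, time x route, cumulative mmol eliminated.
#' @slot meta list: dosing audit, clamp log, FBA solve log, lumen volumes,
#'   solver statistics.
#' @export
setClass("ConcentrationTimeSeries",
    representation(times = "numeric", conc = "matrix",
                   routeTotals = "matrix", meta = "list"))

setValidity("ConcentrationTimeSeries", function(object) {
    msgs <- character(0)
    if (length(object@times) != nrow(object@conc))
        msgs <- c(msgs, "times and conc rows must match")
    if (any(diff(object@times) <= 0))
        msgs <- c(msgs, "times must be strictly increasing")
    if (any(object@conc < -1e-9))
        msgs <- c(msgs, "concentrations must be nonnegative")
    if (nrow(object@routeTotals) &&
        any(apply(object@routeTotals, 2, function(z) any(diff(z) < -1e-6))))
        msgs <- c(msgs, "route totals must be nondecreasing")
    if (length(msgs)) msgs else TRUE
})

#' @describeIn ConcentrationTimeSeries-class sampling times (min).
#' @param x a \code{ConcentrationTimeSeries}.
#' @export
simTimes <- function(x) x@times

#' Extract one compartment's concentration series
#'
#' @param x a \linkS4class{ConcentrationTimeSeries}.
#' @param compartment compartment name, e.g. \code{"blood"}.
#' @param metabolite \code{"ethanol"} or \code{"acetaldehyde"}.
#' @return data.frame with columns \code{time} (min) and \code{conc} (mM).
#' @export
concSeries <- function(x, compartment = "blood", metabolite = "ethanol") {
    col <- paste(compartment, metabolite, sep = ".")
    if (!(col %in% colnames(x@conc)))
        stop(sprintf("no compartment/metabolite column '%s'", col))
    data.frame(time = x@times, conc = x@conc[, col])
}

#' @describeIn ConcentrationTimeSeries-class cumulative route totals (mmol)
#'   at the final time point.
#' @export
routeTotals <- function(x) {
    if (!nrow(x@routeTotals)) return(numeric(0))
    x@routeTotals[nrow(x@routeTotals), ]
}

setMethod("show", "ConcentrationTimeSeries", function(object) {
    n <- length(object@times)
    cat(sprintf("ConcentrationTimeSeries: %d time points over %.0f min, %d states\n",
                n, if (n) max(object@times) else 0, ncol(object@conc)))
    if (!is.null(object@meta$solveCount))
        cat(sprintf("  dFBA solves: %d\n", object@meta$solveCount))
})
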