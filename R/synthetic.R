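## Synthetic clinical-study generator: emulates beverage-arm absorption
## studies (blood ethanol) and paired ethanol/acetaldehyde curves so that
## every fitting test is self-contained. Truth curves come from the
## standalone PBPK layer; observation noise is multiplicative log-normal.

#' Synthetic clinical study
#'
#' @slot observations long-format data.frame: \code{arm}, \code{subject},
#'   \code{time} (min), \code{metabolite}, \code{true} and \code{obs}
#'   (mM for ethanol, uM for acetaldehyde).
#' @slot design the design list the study was generated from.
#' @slot noiseSigma multiplicative log-normal sigma.
#' @slot seed integer seed; the same seed reproduces the same study.
#' @export
setClass("SyntheticStudy",
    representation(observations = "data.frame", design = "list",
                   noiseSigma = "numeric", seed = "numeric"))

setMethod("show", "SyntheticStudy", function(object) {
    cat(sprintf("SyntheticStudy: %d arms, %d subjects/arm, %d observations (seed %d)\n",
                length(unique(object@observations$arm)),
                object@design$n, nrow(object@observations),
                as.integer(object@seed)))
})

#' Generate a synthetic beverage-arm study
#'
#' Per-subject anthropometrics are drawn around the reference male
#' (log-normal weight sd 10\%, height sd 4\%, uniform age 20-40 y and body
#' fat 15-25\%), each subject's truth curve is simulated with the standalone
#' PBPK layer, and observations are the truth times mean-one multiplicative
#' log-normal noise \code{exp(sigma*Z - sigma^2/2)}. Fully determined by
#' \code{seed}.
#'
#' @param kinetics a \linkS4class{KineticParameters} used for every arm
#'   (its absorption slots are the generating truth), or \code{NULL} to take
#'   per-arm absorption rates from \code{\link{absorptionCorrelation}}.
#' @param design list with elements \code{arms} (data.frame with
#'   \code{strength} \%w/v and \code{dose} g/kg), \code{n} subjects per arm,
#'   \code{times} observation times (min), and optionally
#'   \code{acetaldehyde = TRUE} to also observe blood acetaldehyde (uM) and
#'   \code{dt}/\code{nSub} integrator settings.
#' @param noiseSigma log-normal sigma (0 gives noise-free observations).
#' @param seed integer seed.
#' @return A \linkS4class{SyntheticStudy}.
#' @examples
#' \donttest{
#' des <- list(arms = data.frame(strength = 12.5, dose = 0.5), n = 3,
#'             times = c(30, 60, 90, 120, 180))
#' st <- generateSyntheticStudy(NULL, des, noiseSigma = 0.1, seed = 7)
#' head(st@observations)
#' }
#' @export
generateSyntheticStudy <- function(kinetics, design, noiseSigma, seed) {
    stopifnot(is.list(design), !is.null(design$arms), !is.null(design$n),
              !is.null(design$times))
    if (noiseSigma < 0) stop("noiseSigma must be >= 0")
    oldSeed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(oldSeed))
            assign(".Random.seed", oldSeed, envir = globalenv())
    })
    set.seed(as.integer(seed))

    dt <- if (is.null(design$dt)) 2 else design$dt
    nSub <- if (is.null(design$nSub)) 4L else design$nSub
    tEnd <- max(design$times) + dt
    ref <- referenceMale()
    wantAc <- isTRUE(design$acetaldehyde)

    rows <- list()
    for (a in seq_len(nrow(design$arms))) {
        strength <- design$arms$strength[a]
        dose <- design$arms$dose[a]
        kin <- if (is.null(kinetics)) {
            ka <- suppressWarnings(absorptionParams(strength))
            k0 <- loadKinetics(strength)
            k0
        } else kinetics
        for (s in seq_len(design$n)) {
            ind <- Individual(
                age = stats::runif(1, 20, 40), sex = "male",
                height = min(max(ref@height * exp(stats::rnorm(1, 0, 0.04)),
                                 150), 205),
                weight = min(max(ref@weight * exp(stats::rnorm(1, 0, 0.10)),
                                 45), 140),
                bodyFat = stats::runif(1, 0.15, 0.25))
            phys <- buildPhysiology(ind)
            parts <- buildPartitions(phys)
            cts <- simulatePBPK(phys, parts, kin,
                                suppressWarnings(doseRegimen(0, dose,
                                                             strength)),
                                tEnd, dt = dt, nSub = nSub)
            eth <- concSeries(cts, "blood", "ethanol")
            truth <- stats::approx(eth$time, eth$conc,
                                   xout = design$times)$y
            noise <- if (noiseSigma > 0)
                exp(stats::rnorm(length(truth), 0, noiseSigma) -
                    noiseSigma^2 / 2) else rep(1, length(truth))
            rows[[length(rows) + 1L]] <- data.frame(
                arm = strength, subject = s, time = design$times,
                metabolite = "ethanol", true = truth,
                obs = pmax(truth * noise, 0))
            if (wantAc) {
                ac <- concSeries(cts, "blood", "acetaldehyde")
                truthA <- 1000 * stats::approx(ac$time, ac$conc,
                                               xout = design$times)$y
                noiseA <- if (noiseSigma > 0)
                    exp(stats::rnorm(length(truthA), 0, noiseSigma) -
                        noiseSigma^2 / 2) else rep(1, length(truthA))
                rows[[length(rows) + 1L]] <- data.frame(
                    arm = strength, subject = s, time = design$times,
                    metabolite = "acetaldehyde", true = truthA,
                    obs = pmax(truthA * noiseA, 0))
            }
        }
    }
    new("SyntheticStudy", observations = do.call(rbind, rows),
        design = design, noiseSigma = noiseSigma, seed = as.numeric(seed))
}

#' Arm-mean observed curve from a synthetic study
#'
#' @param study a \linkS4class{SyntheticStudy}.
#' @param arm arm identifier (drink strength).
#' @param metabolite \code{"ethanol"} or \code{"acetaldehyde"}.
#' @return data.frame with \code{time}, \code{conc} (mean over subjects).
#' @export
armMeanCurve <- function(study, arm, metabolite = "ethanol") {
    obs <- study@observations
    obs <- obs[obs$arm == arm & obs$metabolite == metabolite, ]
    if (!nrow(obs)) stop(sprintf("no observations for arm '%s'", arm))
    agg <- stats::aggregate(obs$obs, by = list(time = obs$time), FUN = mean)
    data.frame(time = agg$time, conc = agg$x)
}
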