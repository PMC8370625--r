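## Physiology: anthropometrics -> organ volumes, blood flows, partition
## coefficients. The per-organ reference table ships as delimited text so it
## can be swapped for an alternative parameterisation without touching code.

.extdata <- function(file) {
    path <- system.file("extdata", file, package = "ethanolWBM")
    if (!nzchar(path)) stop(sprintf("shipped data file '%s' not found", file))
    path
}

.readTsv <- function(path) {
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

.pkgCache <- new.env(parent = emptyenv())

.cached <- function(key, fn) {
    if (is.null(.pkgCache[[key]])) assign(key, fn(), envir = .pkgCache)
    .pkgCache[[key]]
}

#' Read the shipped reference physiology table
#'
#' One row per organ: reference volume (L, for the 73 kg / 20\% fat reference
#' male), fraction of cardiac output, and water / neutral-lipid /
#' phospholipid composition. The \code{plasma_reference} row defines the
#' partitioning reference phase.
#'
#' @param path optional path to an alternative table with the same columns.
#' @return data.frame.
#' @export
readPhysiologyTable <- function(path = NULL) {
    if (is.null(path)) {
        .cached("physTable", function() .readTsv(.extdata("physiology_male.tsv")))
    } else .readTsv(path)
}

#' Shipped metabolite records
#'
#' @return Named list of \linkS4class{Metabolite} objects for ethanol and
#'   acetaldehyde.
#' @export
defaultMetabolites <- function() {
    .cached("metabolites", function() {
        tab <- .readTsv(.extdata("metabolites.tsv"))
        out <- lapply(seq_len(nrow(tab)), function(i) {
            Metabolite(tab$name[i], tab$molecular_weight[i],
                       tab$lipophilicity[i], tab$fraction_unbound[i])
        })
        names(out) <- tab$name
        out
    })
}

## Reference anthropometrics the shipped volume table was tabulated at.
.REF_WEIGHT <- 73
.REF_FAT <- 0.20
.ADIPOSE_DENSITY <- 0.916  # kg/L

.checkRange <- function(value, field) {
    r <- .individualRange[[field]]
    if (value < r[1] || value > r[2])
        stop(sprintf(
            "'%s' = %g is outside the validity range [%g, %g] of the shipped anthropometric correlation table",
            field, value, r[1], r[2]), call. = FALSE)
    invisible(value)
}

#' Derive organ volumes and blood flows from anthropometrics
#'
#' Non-adipose organ volumes scale with lean body mass relative to the
#' reference male of the shipped table; adipose volume is
#' \code{weight * bodyFat / 0.916}. Cardiac output scales allometrically as
#' \code{6.3 * (weight/73)^0.75} L/min and is distributed over the systemic
#' organs by the shipped flow fractions, which sum to one, so flow conserves
#' exactly at the lung mixing point; the liver additionally receives the
#' portal venous outflow of the stomach, intestines, pancreas and spleen at
#' the liver mixing point. Lumina carry no blood flow.
#'
#' @param individual an \linkS4class{Individual}.
#' @param table optional alternative physiology table
#'   (see \code{\link{readPhysiologyTable}}).
#' @return A \linkS4class{PhysiologyParameters}.
#' @examples
#' phys <- buildPhysiology(referenceMale())
#' organVolumes(phys)["liver"]
#' @export
buildPhysiology <- function(individual, table = readPhysiologyTable()) {
    stopifnot(is(individual, "Individual"))
    validObject(individual)
    for (f in c("age", "height", "weight", "bodyFat"))
        .checkRange(slot(individual, f), f)

    tab <- table[table$organ != "plasma_reference", ]
    plasmaRow <- table[table$organ == "plasma_reference", ]
    if (nrow(plasmaRow) != 1L)
        stop("physiology table must contain one 'plasma_reference' row")

    lean <- individual@weight * (1 - individual@bodyFat)
    refLean <- .REF_WEIGHT * (1 - .REF_FAT)
    vol <- tab$ref_volume_L * (lean / refLean)
    vol[tab$organ == "adipose"] <-
        individual@weight * individual@bodyFat / .ADIPOSE_DENSITY
    ## Lumen reference volumes are anatomical defaults, not lean-scaled.
    vol[tab$is_lumen == 1] <- tab$ref_volume_L[tab$is_lumen == 1]

    co <- 6.3 * (individual@weight / .REF_WEIGHT)^0.75
    flow <- tab$flow_frac * co
    flow[tab$organ %in% c("lung", "blood")] <- 0
    flow[tab$is_lumen == 1] <- 0

    organs <- data.frame(organ = tab$organ, volume = vol, flow = flow,
                         water = tab$water, nlipid = tab$nlipid,
                         plipid = tab$plipid, is_lumen = tab$is_lumen,
                         portal = tab$portal, stringsAsFactors = FALSE)
    new("PhysiologyParameters", organs = organs, cardiacOutput = co,
        plasma = c(water = plasmaRow$water, nlipid = plasmaRow$nlipid,
                   plipid = plasmaRow$plipid),
        individual = individual)
}

#' Tissue:plasma partition coefficient from tissue composition
#'
#' Implements the standard composition-based partition equation for a
#' non-ionised solute: with \eqn{P = 10^{logP}},
#' \deqn{K = f_u \frac{P (NL_t + 0.3 PL_t) + (W_t + 0.7 PL_t)}
#'                    {P (NL_p + 0.3 PL_p) + (W_p + 0.7 PL_p)}}
#' where \eqn{W}, \eqn{NL}, \eqn{PL} are the water, neutral-lipid and
#' phospholipid fractions of tissue (t) and plasma (p). Phospholipid is
#' treated as 30\% lipid-like and 70\% water-like.
#'
#' @param metabolite a \linkS4class{Metabolite}.
#' @param composition named numeric (\code{water}, \code{nlipid},
#'   \code{plipid}) or a one-row data.frame with those columns.
#' @param plasma reference-phase composition, same format (defaults to the
#'   shipped plasma reference).
#' @return Positive scalar K (mM tissue per mM plasma).
#' @examples
#' eth <- defaultMetabolites()$ethanol
#' partitionCoefficient(eth, c(water = 0.76, nlipid = 0.022, plipid = 0.0072))
#' @export
partitionCoefficient <- function(metabolite, composition,
                                 plasma = NULL) {
    stopifnot(is(metabolite, "Metabolite"))
    validObject(metabolite)
    if (metabolite@fractionUnbound == 0)
        stop("fractionUnbound must be nonzero for partitioning")
    comp <- unlist(composition)[c("water", "nlipid", "plipid")]
    if (anyNA(comp)) stop("composition must supply water, nlipid, plipid")
    if (is.null(plasma)) {
        tab <- readPhysiologyTable()
        pr <- tab[tab$organ == "plasma_reference", ]
        plasma <- c(water = pr$water, nlipid = pr$nlipid, plipid = pr$plipid)
    }
    pl <- unlist(plasma)[c("water", "nlipid", "plipid")]
    P <- 10^metabolite@lipophilicity
    num <- P * (comp["nlipid"] + 0.3 * comp["plipid"]) +
        (comp["water"] + 0.7 * comp["plipid"])
    den <- P * (pl["nlipid"] + 0.3 * pl["plipid"]) +
        (pl["water"] + 0.7 * pl["plipid"])
    unname(metabolite@fractionUnbound * num / den)
}

#' Partition coefficients for all model compartments
#'
#' Blood is the reference compartment (K = 1); lumina hold bulk fluid and
#' also carry K = 1 (their exchange is by explicit absorption terms, not
#' perfusion equilibrium).
#'
#' @param physiology a \linkS4class{PhysiologyParameters}.
#' @param metabolites named list of \linkS4class{Metabolite}s (default the
#'   shipped ethanol/acetaldehyde pair).
#' @return Named list (per metabolite) of named numeric K vectors (per organ).
#' @export
buildPartitions <- function(physiology, metabolites = defaultMetabolites()) {
    stopifnot(is(physiology, "PhysiologyParameters"))
    org <- physiology@organs
    lapply(metabolites, function(m) {
        k <- vapply(seq_len(nrow(org)), function(i) {
            if (org$organ[i] == "blood" || org$is_lumen[i] == 1) return(1)
            partitionCoefficient(
                m, c(water = org$water[i], nlipid = org$nlipid[i],
                     plipid = org$plipid[i]),
                plasma = physiology@plasma)
        }, numeric(1))
        stats::setNames(k, org$organ)
    })
}
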