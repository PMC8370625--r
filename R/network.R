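## Reduced whole-body ethanol/acetaldehyde stoichiometric network and its
## flux-balance solver. The network mirrors the ethanol subsystem of an
## organ-resolved whole-body reconstruction: one circulating ethanol species,
## liver and colon acetaldehyde species closed by aldehyde dehydrogenase
## (acetaldehyde leaves the steady-state network only through ALDH2), and
## exchange reactions for diet intake and breath/urine/sweat/feces excretion.
## Whole-body fluxes are in mmol/min.

.BIGBOUND <- 1e6

#' Construct a stoichiometric model
#'
#' @param smatrix internal-metabolites x reactions matrix (boundary species
#'   are implicit, the usual exchange convention).
#' @param reactions data.frame with columns \code{id}, \code{role},
#'   \code{lb}, \code{ub} (mmol/min).
#' @param objective id of the reaction maximised by \code{\link{solveFBA}}.
#' @param couplings optional data.frame (\code{id}, \code{cmin}, \code{cmax})
#'   of couplings \code{cmin * v_obj <= v_id <= cmax * v_obj}.
#' @return A \linkS4class{StoichiometricModel}.
#' @export
stoichiometricModel <- function(smatrix, reactions, objective,
                                couplings = NULL) {
    if (is.null(couplings))
        couplings <- data.frame(id = character(0), cmin = numeric(0),
                                cmax = numeric(0))
    if (any(reactions$lb < 0))
        stop("reversible reactions (lb < 0) are not supported")
    colnames(smatrix) <- reactions$id
    new("StoichiometricModel", smatrix = smatrix, reactions = reactions,
        metabolites = rownames(smatrix), objective = objective,
        couplings = couplings)
}

#' Whole-body route-fraction constraints for ethanol elimination
#'
#' Fractions of total ethanol elimination per route: breath exactly 0.05\%,
#' urine and sweat 3-10\% each, feces 0, liver 90-95\%, colon catalase
#' 0-2\%, colon/adipose alcohol dehydrogenase 0.
#'
#' @param liverOnly logical; if TRUE all auxiliary routes are pinned to zero
#'   (used for the consistency-limit comparison against the standalone PBPK
#'   model).
#' @return data.frame with columns \code{role}, \code{fmin}, \code{fmax}.
#' @export
routeConstraints <- function(liverOnly = FALSE) {
    rc <- data.frame(
        role = c("liver_ADH", "breath_ex", "urine_ex", "sweat_ex",
                 "feces_ex", "colon_catalase", "colon_ADH", "adipose_ADH"),
        fmin = c(0.90, 0.0005, 0.03, 0.03, 0, 0,    0, 0),
        fmax = c(0.95, 0.0005, 0.10, 0.10, 0, 0.02, 0, 0),
        stringsAsFactors = FALSE)
    if (liverOnly) {
        rc$fmin[rc$role != "liver_ADH"] <- 0
        rc$fmax[rc$role != "liver_ADH"] <- 0
        rc$fmin[rc$role == "liver_ADH"] <- 1
        rc$fmax[rc$role == "liver_ADH"] <- 1
    }
    rc
}

#' Build the reduced ethanol/acetaldehyde network
#'
#' Twelve reactions: diet intake (sole ethanol source), liver alcohol
#' dehydrogenase, colon catalase, colon and adipose alcohol dehydrogenase
#' (structurally present, bounds fixed at zero), the four excretion
#' exchanges, and liver/colon aldehyde dehydrogenase closing the
#' acetaldehyde species. Auxiliary-route fraction constraints are attached
#' as couplings relative to the liver flux, rescaled so the liver share of
#' total elimination can lie in its 90-95\% window:
#' \code{f'min = fmin/0.95}, \code{f'max = fmax/0.90}.
#'
#' @param constraints route-fraction table from \code{\link{routeConstraints}}.
#' @return A \linkS4class{StoichiometricModel} (bounds not yet state-scaled;
#'   see \code{\link{setBounds}}).
#' @examples
#' net <- buildEthanolNetwork()
#' reactions(net)$id
#' @export
buildEthanolNetwork <- function(constraints = routeConstraints()) {
    mets <- c("etoh[bc]", "acald[liv]", "acald[col]")
    rx <- data.frame(
        id = c("Diet_EX_etoh[d]", "Liver_ALCD2if", "Colon_CAT2p",
               "Colon_ALCD2if", "Adipocytes_ALCD2if", "Adipocytes_ALCD2yf",
               "EX_etoh_[br]", "EX_etoh[u]", "EX_etoh[sw]",
               "Excretion_EX_etoh[fe]", "Liver_ALDH2x", "Colon_ALDH2x"),
        role = c("diet_input", "liver_ADH", "colon_catalase", "colon_ADH",
                 "adipose_ADH", "adipose_ADH", "breath_ex", "urine_ex",
                 "sweat_ex", "feces_ex", "liver_ALDH2", "colon_ALDH2"),
        lb = 0,
        ub = c(.BIGBOUND, .BIGBOUND, .BIGBOUND, 0, 0, 0,
               .BIGBOUND, .BIGBOUND, .BIGBOUND, 0, .BIGBOUND, .BIGBOUND),
        stringsAsFactors = FALSE)
    S <- matrix(0, length(mets), nrow(rx),
                dimnames = list(mets, rx$id))
    S["etoh[bc]", ] <- c(1, -1, -1, -1, -1, -1, -1, -1, -1, -1, 0, 0)
    S["acald[liv]", "Liver_ALCD2if"] <- 1
    S["acald[liv]", "Liver_ALDH2x"] <- -1
    S["acald[col]", c("Colon_CAT2p", "Colon_ALCD2if")] <- 1
    S["acald[col]", "Colon_ALDH2x"] <- -1

    aux <- constraints[constraints$role != "liver_ADH", ]
    liv <- constraints[constraints$role == "liver_ADH", ]
    coup <- do.call(rbind, lapply(seq_len(nrow(aux)), function(i) {
        ids <- rx$id[rx$role == aux$role[i]]
        data.frame(id = ids,
                   cmin = aux$fmin[i] / liv$fmax,
                   cmax = if (liv$fmin > 0) aux$fmax[i] / liv$fmin else 0,
                   stringsAsFactors = FALSE)
    }))
    ## zero-flux roles need no coupling rows
    coup <- coup[coup$cmax > 0 | coup$cmin > 0, , drop = FALSE]
    stoichiometricModel(S, rx, objective = "Liver_ALCD2if", couplings = coup)
}

#' ALDH2 isoform activity lookup
#'
#' @param isoform isoform id, e.g. \code{"ALDH2.2"}.
#' @return activity as \% of wild type.
#' @export
isoformActivity <- function(isoform) {
    tab <- aldh2Isoforms()
    i <- match(isoform, tab$isoform)
    if (is.na(i))
        stop(sprintf("unknown ALDH2 isoform '%s'; valid ids: %s", isoform,
                     paste(tab$isoform, collapse = ", ")))
    tab$activity_pct[i]
}

#' Set state-dependent flux bounds on the ethanol network
#'
#' The liver alcohol-dehydrogenase upper bound is the Michaelis-Menten rate
#' at the current liver ethanol concentration times the liver volume and the
#' enzyme-expression scale. The aldehyde-dehydrogenase bounds are saturation
#' capacities \code{Vmax * V} scaled by expression, isoform activity and
#' disulfiram inhibition (their Km is in the low micromolar range, so the
#' saturable factor is ~1 whenever these bounds can bind; see the methods
#' vignette). Auxiliary excretion routes receive concentration-driven
#' physiological proposals (apparent clearance times blood or colon ethanol
#' concentration) clipped into their route-fraction coupling band around a
#' provisional liver flux obtained from a preliminary solve; diet intake is
#' bounded by the available ethanol supply.
#'
#' @param model network from \code{\link{buildEthanolNetwork}}.
#' @param liverCEthanol,liverCAcald liver concentrations, mM (>= 0).
#' @param kinetics a \linkS4class{KineticParameters}.
#' @param physiology a \linkS4class{PhysiologyParameters}.
#' @param scenario a \linkS4class{ScenarioConfig} (expression scale, isoform,
#'   disulfiram level); negative scales are an error.
#' @param bloodCEthanol,colonCEthanol blood / colon-tissue ethanol (mM) for
#'   the auxiliary-route proposals.
#' @param availability ethanol supply available to the network, mmol/min.
#' @return The model with numeric bounds set.
#' @export
setBounds <- function(model, liverCEthanol, liverCAcald, kinetics,
                      physiology, scenario = ScenarioConfig(),
                      bloodCEthanol = 0, colonCEthanol = 0,
                      availability = Inf) {
    if (liverCEthanol < 0 || liverCAcald < 0)
        stop("concentrations must be >= 0")
    sExpr <- scenario@expressionScale
    if (sExpr < 0) stop("expression scale must be >= 0")
    sIso <- isoformActivity(scenario@isoform) / 100
    sDsf <- disulfiramActivity(scenario@disulfiramLevel)

    V <- organVolumes(physiology)
    rx <- model@reactions
    ub <- stats::setNames(rx$ub, rx$id)
    lb <- stats::setNames(rx$lb, rx$id)

    ubADH <- sExpr * michaelisMentenRate(liverCEthanol, kinetics@vmaxADH,
                                         kinetics@kmADH) * V[["liver"]]
    ub["Liver_ALCD2if"] <- ubADH
    ub["Liver_ALDH2x"] <- sExpr * sIso * sDsf * kinetics@vmaxALDH2 *
        V[["liver"]]
    ub["Colon_ALDH2x"] <- sIso * sDsf * kinetics@vmaxALDH2Colon *
        V[["large_intestine"]]
    ub["Diet_EX_etoh[d]"] <- min(availability, .BIGBOUND)

    model@reactions$ub <- unname(ub[rx$id])
    model@reactions$lb <- unname(lb[rx$id])

    if (nrow(model@couplings) == 0)
        return(model)

    ## provisional liver flux from a coupling-only solve
    pre <- solveFBA(model, tieBreak = FALSE)
    Lhat <- pre@fluxes[["Liver_ALCD2if"]]

    prop <- c("EX_etoh[u]" = kinetics@clUrine * bloodCEthanol,
              "EX_etoh[sw]" = kinetics@clSweat * bloodCEthanol,
              "Colon_CAT2p" = kinetics@clCatalase * colonCEthanol)
    coup <- model@couplings
    for (id in names(prop)) {
        i <- match(id, coup$id)
        if (is.na(i)) next
        lo <- coup$cmin[i] * Lhat
        hi <- coup$cmax[i] * Lhat
        model@reactions$lb[model@reactions$id == id] <-
            min(max(prop[[id]], lo), hi)
    }
    ## keep the raised lower bounds feasible against the supply bound
    for (tries in 1:30) {
        ok <- tryCatch({ solveFBA(model, tieBreak = FALSE); TRUE },
                       error = function(e) FALSE)
        if (ok) break
        aux <- model@reactions$id %in% names(prop)
        model@reactions$lb[aux] <- model@reactions$lb[aux] * 0.5
        if (all(model@reactions$lb[aux] < 1e-12))
            model@reactions$lb[aux] <- 0
    }
    model
}

## ---------------------------------------------------------------------------
## LP solve
## ---------------------------------------------------------------------------

.AUX_ROLES <- c("breath_ex", "urine_ex", "sweat_ex", "feces_ex",
                "colon_catalase", "colon_ADH", "adipose_ADH")

#' Solve the flux-balance linear program
#'
#' Maximises the objective reaction subject to steady state
#' (\code{S v = 0}), numeric bounds and the route-fraction couplings. Ties
#' in the auxiliary fluxes are broken lexicographically by minimising the
#' total auxiliary flux at the fixed optimum, so solutions do not depend on
#' solver pivot order.
#'
#' @param model a bounded \linkS4class{StoichiometricModel}.
#' @param tieBreak logical, apply the secondary minimisation (default TRUE).
#' @return A \linkS4class{FluxSolution}.
#' @examples
#' net <- buildEthanolNetwork()
#' net@reactions$ub[net@reactions$id == "Liver_ALCD2if"] <- 2
#' sol <- solveFBA(net)
#' fluxes(sol)[["Liver_ALCD2if"]]
#' @export
solveFBA <- function(model, tieBreak = TRUE) {
    validObject(model)
    rxFull <- model@reactions
    nFull <- nrow(rxFull)
    zeroSol <- function() {
        v <- stats::setNames(numeric(nFull), rxFull$id)
        new("FluxSolution", fluxes = v, objectiveValue = 0,
            status = "optimal")
    }
    ## preprocessing: variables with ub ~ 0 are fixed at zero; if the
    ## objective itself is fixed, the couplings and the ethanol balance pin
    ## the whole network to zero (feasible iff no positive lower bound).
    fixed <- rxFull$ub <= 1e-12
    if (any(rxFull$lb > 1e-12 & fixed))
        stop(structure(class = c("fbaInfeasible", "error", "condition"),
                       list(message = paste0(
                           "flux balance LP infeasible; binding constraints: ",
                           paste(paste0("lb>ub:", rxFull$id[rxFull$lb > 1e-12 &
                                                            fixed]),
                                 collapse = ", ")),
                            call = sys.call())))
    if (fixed[match(model@objective, rxFull$id)]) return(zeroSol())
    keep <- which(!fixed)
    rx <- rxFull[keep, , drop = FALSE]
    n <- nrow(rx)
    obj <- match(model@objective, rx$id)

    A1 <- NULL; b1 <- NULL   # <=
    A2 <- NULL; b2 <- NULL   # >=
    A3 <- model@smatrix[, keep, drop = FALSE]
    liveRows <- rowSums(abs(A3)) > 0
    A3 <- A3[liveRows, , drop = FALSE]
    b3 <- rep(0, nrow(A3))   # ==
    rowNames1 <- character(0); rowNames2 <- character(0)
    rowNames3 <- paste0("balance:", model@metabolites[liveRows])

    addRow <- function(kind, row, rhs, label) {
        if (kind == 1) { A1 <<- rbind(A1, row); b1 <<- c(b1, rhs)
            rowNames1 <<- c(rowNames1, label) }
        else if (kind == 2) { A2 <<- rbind(A2, row); b2 <<- c(b2, rhs)
            rowNames2 <<- c(rowNames2, label) }
        else { A3 <<- rbind(A3, row); b3 <<- c(b3, rhs)
            rowNames3 <<- c(rowNames3, label) }
    }

    for (i in seq_len(n)) {
        if (is.finite(rx$ub[i]) && rx$ub[i] < .BIGBOUND)
            addRow(1, .unitRow(n, i), rx$ub[i], paste0("ub:", rx$id[i]))
        if (rx$lb[i] > 0)
            addRow(2, .unitRow(n, i), rx$lb[i], paste0("lb:", rx$id[i]))
    }
    if (nrow(model@couplings)) {
        for (i in seq_len(nrow(model@couplings))) {
            cp <- model@couplings[i, ]
            j <- match(cp$id, rx$id)
            if (is.na(j)) next   # coupled reaction fixed at zero
            if (abs(cp$cmax - cp$cmin) < 1e-12) {
                row <- .unitRow(n, j); row[obj] <- -cp$cmin
                addRow(3, row, 0, paste0("couple:", cp$id))
            } else {
                row <- .unitRow(n, j); row[obj] <- -cp$cmax
                addRow(1, row, 0, paste0("couple-ub:", cp$id))
                if (cp$cmin > 0) {
                    row <- .unitRow(n, j); row[obj] <- -cp$cmin
                    addRow(2, row, 0, paste0("couple-lb:", cp$id))
                }
            }
        }
    }

    a <- numeric(n); a[obj] <- 1
    res <- .lpSolve(a = a, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                    A3 = A3, b3 = b3, maximize = TRUE)
    if (res$solved == -1)
        stop(structure(class = c("fbaInfeasible", "error", "condition"),
                       list(message = paste0(
                           "flux balance LP infeasible; constraint set: ",
                           paste(c(rowNames1, rowNames2, rowNames3),
                                 collapse = ", ")),
                            call = sys.call())))
    v <- res$soln[seq_len(n)]
    objVal <- unname(res$value)

    if (tieBreak) {
        auxIdx <- which(rx$role %in% .AUX_ROLES)
        if (length(auxIdx)) {
            ## hold the primary objective at its optimum (>= row; the
            ## original constraints already cap it from above) and minimise
            ## the total auxiliary flux
            row <- numeric(n); row[obj] <- 1
            A2b <- rbind(A2, row)
            b2b <- c(b2, objVal * (1 - 1e-9))
            a2 <- numeric(n); a2[auxIdx] <- 1
            res2 <- .lpSolve(a = a2, A1 = A1, b1 = b1, A2 = A2b,
                             b2 = b2b, A3 = A3, b3 = b3, maximize = FALSE)
            if (res2$solved == 1L &&
                !anyNA(res2$soln)) v <- res2$soln[seq_len(n)]
        }
    }
    vFull <- stats::setNames(numeric(nFull), rxFull$id)
    vFull[rx$id] <- v
    vFull[abs(vFull) < 1e-11] <- 0
    new("FluxSolution", fluxes = vFull, objectiveValue = objVal,
        status = "optimal")
}

.unitRow <- function(n, i) { r <- numeric(n); r[i] <- 1; r }

#' Per-role fractions of total ethanol elimination
#'
#' @param solution a \linkS4class{FluxSolution}.
#' @param model the solved \linkS4class{StoichiometricModel}.
#' @return Named numeric of fractions summing to 1 over the elimination
#'   roles, with attribute \code{defined = TRUE}; if total elimination is
#'   zero, a vector of \code{NA}s with \code{defined = FALSE}.
#' @export
fluxFractions <- function(solution, model) {
    rolesOf <- stats::setNames(model@reactions$role, model@reactions$id)
    elim <- c("liver_ADH", "colon_ADH", "adipose_ADH", "colon_catalase",
              "breath_ex", "urine_ex", "sweat_ex", "feces_ex")
    v <- solution@fluxes
    byRole <- vapply(elim, function(r)
        sum(v[names(v)[rolesOf[names(v)] == r]]), numeric(1))
    total <- sum(byRole)
    if (total <= 1e-12) {
        out <- stats::setNames(rep(NA_real_, length(elim)), elim)
        attr(out, "defined") <- FALSE
        return(out)
    }
    out <- byRole / total
    attr(out, "defined") <- TRUE
    out
}

## ---------------------------------------------------------------------------
## Serialisation
## ---------------------------------------------------------------------------

.stoichString <- function(model, j) {
    col <- model@smatrix[, j]
    side <- function(sel) {
        if (!any(sel)) return("")
        paste(vapply(which(sel), function(i) {
            co <- abs(col[i])
            if (abs(co - 1) < 1e-12) model@metabolites[i]
            else paste(format(co), model@metabolites[i])
        }, character(1)), collapse = " + ")
    }
    paste(side(col < 0), "->", side(col > 0))
}

#' Export the network as a delimited table
#'
#' Columns: reaction id, stoichiometry string (exchange convention: boundary
#' species implicit), lb, ub, role; couplings are emitted as comment
#' metadata lines.
#'
#' @param model a \linkS4class{StoichiometricModel}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
exportNetworkTable <- function(model, file) {
    con <- file(file, "w")
    writeLines(c("# ethanolWBM network export",
                 sprintf("# objective\t%s", model@objective),
                 sprintf("# metabolites\t%s",
                         paste(model@metabolites, collapse = ","))), con)
    if (nrow(model@couplings))
        writeLines(sprintf("# coupling\t%s\t%.10g\t%.10g",
                           model@couplings$id, model@couplings$cmin,
                           model@couplings$cmax), con)
    df <- data.frame(id = model@reactions$id,
                     stoichiometry = vapply(seq_len(nrow(model@reactions)),
                                            function(j) .stoichString(model, j),
                                            character(1)),
                     lb = model@reactions$lb, ub = model@reactions$ub,
                     role = model@reactions$role)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    invisible(file)
}

#' Read a network table written by \code{\link{exportNetworkTable}}
#'
#' @param file path to the table.
#' @return A \linkS4class{StoichiometricModel}.
#' @export
readNetworkTable <- function(file) {
    lines <- readLines(file)
    meta <- lines[startsWith(lines, "#")]
    objective <- sub("^# objective\t", "",
                     meta[startsWith(meta, "# objective")])
    mets <- strsplit(sub("^# metabolites\t", "",
                         meta[startsWith(meta, "# metabolites")]), ",")[[1]]
    coupLines <- meta[startsWith(meta, "# coupling")]
    couplings <- if (length(coupLines)) {
        parts <- do.call(rbind, strsplit(sub("^# coupling\t", "", coupLines),
                                         "\t"))
        data.frame(id = parts[, 1], cmin = as.numeric(parts[, 2]),
                   cmax = as.numeric(parts[, 3]), stringsAsFactors = FALSE)
    } else NULL
    df <- utils::read.delim(textConnection(lines[!startsWith(lines, "#")]),
                            stringsAsFactors = FALSE)
    S <- matrix(0, length(mets), nrow(df), dimnames = list(mets, df$id))
    for (j in seq_len(nrow(df))) {
        sides <- strsplit(df$stoichiometry[j], "->", fixed = TRUE)[[1]]
        parseSide <- function(s, sign) {
            s <- trimws(s)
            if (!nzchar(s)) return()
            for (term in trimws(strsplit(s, "+", fixed = TRUE)[[1]])) {
                toks <- strsplit(term, " ", fixed = TRUE)[[1]]
                if (length(toks) == 2) {
                    S[toks[2], j] <<- S[toks[2], j] + sign * as.numeric(toks[1])
                } else S[term, j] <<- S[term, j] + sign
            }
        }
        parseSide(sides[1], -1)
        if (length(sides) > 1) parseSide(sides[2], +1)
    }
    stoichiometricModel(S, data.frame(id = df$id, role = df$role, lb = df$lb,
                                      ub = df$ub, stringsAsFactors = FALSE),
                        objective = objective, couplings = couplings)
}

#' Export the network as an SBML document with flux bounds
#'
#' Writes an SBML level-3 document: internal species, reactions with
#' reactant/product stoichiometry, and per-reaction flux bounds and role
#' stored as parameters in the \code{fbc} style
#' (\code{lb_<index>}/\code{ub_<index>}).
#'
#' @param model a \linkS4class{StoichiometricModel}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
exportNetworkSBML <- function(model, file) {
    doc <- xml2::xml_new_root("sbml",
        xmlns = "http://www.sbml.org/sbml/level3/version1/core",
        level = "3", version = "1")
    mdl <- xml2::xml_add_child(doc, "model", id = "ethanolWBM_network",
                               name = "reduced ethanol/acetaldehyde network")
    san <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
    los <- xml2::xml_add_child(mdl, "listOfSpecies")
    for (m in model@metabolites)
        xml2::xml_add_child(los, "species", id = san(m), name = m,
                            boundaryCondition = "false",
                            hasOnlySubstanceUnits = "true")
    lop <- xml2::xml_add_child(mdl, "listOfParameters")
    for (j in seq_len(nrow(model@reactions))) {
        xml2::xml_add_child(lop, "parameter", id = sprintf("lb_%d", j),
                            value = format(model@reactions$lb[j], digits = 15),
                            constant = "true")
        xml2::xml_add_child(lop, "parameter", id = sprintf("ub_%d", j),
                            value = format(model@reactions$ub[j], digits = 15),
                            constant = "true")
    }
    lor <- xml2::xml_add_child(mdl, "listOfReactions")
    for (j in seq_len(nrow(model@reactions))) {
        col <- model@smatrix[, j]
        rxn <- xml2::xml_add_child(lor, "reaction",
                                   id = san(model@reactions$id[j]),
                                   name = model@reactions$id[j],
                                   reversible = "false")
        xml2::xml_set_attr(rxn, "metaid", model@reactions$role[j])
        if (any(col < 0)) {
            lre <- xml2::xml_add_child(rxn, "listOfReactants")
            for (i in which(col < 0))
                xml2::xml_add_child(lre, "speciesReference",
                                    species = san(model@metabolites[i]),
                                    stoichiometry = format(-col[i]))
        }
        if (any(col > 0)) {
            lpr <- xml2::xml_add_child(rxn, "listOfProducts")
            for (i in which(col > 0))
                xml2::xml_add_child(lpr, "speciesReference",
                                    species = san(model@metabolites[i]),
                                    stoichiometry = format(col[i]))
        }
    }
    xml2::xml_set_attr(mdl, "metaid", model@objective)
    xml2::write_xml(doc, file)
    invisible(file)
}

#' Read a network SBML document written by \code{\link{exportNetworkSBML}}
#'
#' @param file path to the SBML file.
#' @return A \linkS4class{StoichiometricModel} (couplings are not part of
#'   the SBML representation; re-attach via \code{\link{routeConstraints}}
#'   if needed).
#' @export
readNetworkSBML <- function(file) {
    doc <- xml2::read_xml(file)
    ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
    mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
    objective <- xml2::xml_attr(mdl, "metaid")
    spNodes <- xml2::xml_find_all(doc, ".//s:species", ns)
    mets <- xml2::xml_attr(spNodes, "name")
    sanToName <- stats::setNames(mets, xml2::xml_attr(spNodes, "id"))
    rxNodes <- xml2::xml_find_all(doc, ".//s:reaction", ns)
    ids <- xml2::xml_attr(rxNodes, "name")
    roles <- xml2::xml_attr(rxNodes, "metaid")
    pNodes <- xml2::xml_find_all(doc, ".//s:parameter", ns)
    pv <- stats::setNames(as.numeric(xml2::xml_attr(pNodes, "value")),
                          xml2::xml_attr(pNodes, "id"))
    S <- matrix(0, length(mets), length(ids), dimnames = list(mets, ids))
    lb <- ub <- numeric(length(ids))
    for (j in seq_along(rxNodes)) {
        for (sr in xml2::xml_find_all(rxNodes[[j]],
                                      "./s:listOfReactants/s:speciesReference",
                                      ns))
            S[sanToName[[xml2::xml_attr(sr, "species")]], j] <-
                -as.numeric(xml2::xml_attr(sr, "stoichiometry"))
        for (sr in xml2::xml_find_all(rxNodes[[j]],
                                      "./s:listOfProducts/s:speciesReference",
                                      ns))
            S[sanToName[[xml2::xml_attr(sr, "species")]], j] <-
                as.numeric(xml2::xml_attr(sr, "stoichiometry"))
        lb[j] <- pv[[sprintf("lb_%d", j)]]
        ub[j] <- pv[[sprintf("ub_%d", j)]]
    }
    stoichiometricModel(S, data.frame(id = ids, role = roles, lb = lb,
                                      ub = ub, stringsAsFactors = FALSE),
                        objective = objective)
}
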