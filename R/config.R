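## Structured-text scenario configuration (YAML) with a versioned schema.
## Unknown keys are errors so typos in scenario names cannot silently
## produce a default run.

.SCHEMA <- list(
    top = c("schema_version", "individual", "regimen", "scenario",
            "numerics"),
    individual = c("age", "sex", "height", "weight", "body_fat"),
    regimen = c("times", "dose_g_per_kg", "strength_wv"),
    scenario = c("expression_scale", "isoform", "disulfiram_mg_l"),
    numerics = c("t_end", "dt", "tol", "n_sub"))

.checkKeys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra))
        stop(sprintf("unknown key(s) in %s: %s (allowed: %s)", where,
                     paste(extra, collapse = ", "),
                     paste(allowed, collapse = ", ")), call. = FALSE)
}

#' Read a scenario configuration file
#'
#' YAML schema (version 1): \code{individual} (age, sex, height, weight,
#' body_fat), \code{regimen} (times, dose_g_per_kg, strength_wv),
#' \code{scenario} (expression_scale, isoform, disulfiram_mg_l) and
#' \code{numerics} (t_end, dt, tol, n_sub). Unknown keys are errors.
#'
#' @param path path to the YAML file.
#' @return list with elements \code{individual} (an
#'   \linkS4class{Individual}), \code{config} (a
#'   \linkS4class{ScenarioConfig}) and \code{nSub}.
#' @export
readScenarioConfig <- function(path) {
    if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
    y <- yaml::read_yaml(path)
    .checkKeys(y, .SCHEMA$top, "config")
    if (is.null(y$schema_version) || y$schema_version != 1)
        stop("config schema_version must be 1")
    for (sect in c("individual", "regimen"))
        if (is.null(y[[sect]]))
            stop(sprintf("config section '%s' is required", sect))
    .checkKeys(y$individual, .SCHEMA$individual, "individual")
    .checkKeys(y$regimen, .SCHEMA$regimen, "regimen")
    if (!is.null(y$scenario)) .checkKeys(y$scenario, .SCHEMA$scenario,
                                         "scenario")
    if (!is.null(y$numerics)) .checkKeys(y$numerics, .SCHEMA$numerics,
                                         "numerics")
    ind <- Individual(y$individual$age, y$individual$sex,
                      y$individual$height, y$individual$weight,
                      y$individual$body_fat)
    num <- y$numerics
    sc <- y$scenario
    regimen <- doseRegimen(y$regimen$times, y$regimen$dose_g_per_kg,
                           y$regimen$strength_wv)
    config <- ScenarioConfig(
        expressionScale = if (is.null(sc$expression_scale)) 1 else
            sc$expression_scale,
        isoform = if (is.null(sc$isoform)) "ALDH2.1" else sc$isoform,
        disulfiramLevel = if (is.null(sc$disulfiram_mg_l)) 0 else
            sc$disulfiram_mg_l,
        regimen = regimen,
        tol = if (is.null(num$tol)) 0.01 else num$tol,
        tEnd = if (is.null(num$t_end)) 500 else num$t_end,
        dt = if (is.null(num$dt)) 1 else num$dt)
    list(individual = ind, config = config,
         nSub = if (is.null(num$n_sub)) 8L else as.integer(num$n_sub))
}
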