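# Structured-text (YAML) configuration loading with strict validation:
# unknown keys are rejected, defaults are filled and echoed so the run
# manifest records the effective configuration.

verr <- function(...) {
  stop(structure(class = c("adasim_validation_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    verr("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "))
}

#' Load and validate drug / trial / population configurations
#'
#' Reads YAML configuration files, rejects unknown keys, enforces
#' units/ranges and fills documented defaults (ADA threshold 100
#' ng/mL, alpha 0.05, population size 250). The filled defaults are
#' returned in `$effective` so they can be echoed to the run manifest.
#'
#' Schema (keys carry units): `drug:` `name`,
#' `molecular_weight_g_per_mol`, `clearance_L_per_h`, `clearance_cv`,
#' `route`, `bioavailability`, `ka_per_h`, `infusion_duration_h`,
#' `dc_uptake`, `naive_t_fraction`; `trial:` `regimen` (`dose_mg` or
#' `dose_mg_per_kg`, `interval_h`, `n_doses`, `dose_times_h`),
#' `schedule` (`ada_times_h`, `pk_times_h`, `final_time_h`),
#' `ada_threshold_ng_per_ml`, `alpha`, `mtx` (`dose_mg`, `interval_h`,
#' `n_doses`, `start_h`); `population:` `n`, `distributions` (per
#' parameter `mean`, `cv`).
#'
#' @param drug,trial,population paths to the respective YAML files
#'   (any may be `NULL`).
#' @param epitopes optional list of epitopes attached to the drug.
#' @return list with validated objects (`drug`, `regimen`, `schedule`,
#'   `threshold_ng_per_ml`, `alpha`, `n`, `distributions`, `mtx`) and
#'   `effective` (defaults that were filled in).
#' @export
load_configs <- function(drug = NULL, trial = NULL, population = NULL,
                         epitopes = list()) {
  out <- list(effective = list())
  for (p in c(drug, trial, population))
    if (!is.null(p) && !file.exists(p)) verr("config file not found: ", p)

  if (!is.null(drug)) {
    y <- yaml::read_yaml(drug)
    check_keys(y, "drug", drug)
    d <- y$drug
    if (is.null(d)) verr("missing 'drug' section in ", drug)
    allowed <- c("name", "molecular_weight_g_per_mol", "clearance_L_per_h",
                 "clearance_cv", "route", "bioavailability", "ka_per_h",
                 "infusion_duration_h", "dc_uptake", "naive_t_fraction")
    check_keys(d, allowed, "drug config")
    for (k in c("name", "molecular_weight_g_per_mol", "clearance_L_per_h"))
      if (is.null(d[[k]])) verr("missing required drug key: ", k)
    if (is.null(d$route)) {
      d$route <- "IV_bolus"
      out$effective$route <- "IV_bolus"
    }
    if (is.null(d$clearance_cv)) {
      d$clearance_cv <- 0
      out$effective$clearance_cv <- 0
    }
    if (is.null(d$dc_uptake)) {
      d$dc_uptake <- 1
      out$effective$dc_uptake <- 1
    }
    if (is.null(d$naive_t_fraction)) {
      d$naive_t_fraction <- 1e-5
      out$effective$naive_t_fraction <- 1e-5
    }
    out$drug <- tryCatch(
      drug_parameters(name = d$name,
                      molecular_weight = d$molecular_weight_g_per_mol,
                      clearance_mean = d$clearance_L_per_h,
                      clearance_cv = d$clearance_cv,
                      route = d$route,
                      bioavailability = d$bioavailability,
                      ka = d$ka_per_h,
                      infusion_duration = d$infusion_duration_h,
                      dc_uptake = d$dc_uptake,
                      naive_t_fraction = d$naive_t_fraction,
                      epitopes = epitopes),
      error = function(e) verr("drug config: ", conditionMessage(e)))
  }

  if (!is.null(trial)) {
    y <- yaml::read_yaml(trial)
    check_keys(y, "trial", trial)
    tr <- y$trial
    if (is.null(tr)) verr("missing 'trial' section in ", trial)
    check_keys(tr, c("regimen", "schedule", "ada_threshold_ng_per_ml",
                     "alpha", "mtx"), "trial config")
    rg <- tr$regimen
    if (is.null(rg)) verr("trial config needs a regimen section")
    check_keys(rg, c("dose_mg", "dose_mg_per_kg", "interval_h", "n_doses",
                     "dose_times_h"), "trial regimen")
    mtx <- NULL
    if (!is.null(tr$mtx)) {
      check_keys(tr$mtx, c("dose_mg", "interval_h", "n_doses", "start_h"),
                 "mtx co-regimen")
      mtx <- tryCatch(
        mtx_regimen(tr$mtx$dose_mg,
                    interval = tr$mtx$interval_h %||% 168,
                    n_doses = tr$mtx$n_doses %||% 1,
                    start = tr$mtx$start_h %||% 0),
        error = function(e) verr("mtx config: ", conditionMessage(e)))
    }
    amount <- rg$dose_mg %||% rg$dose_mg_per_kg
    if (is.null(amount)) verr("regimen needs dose_mg or dose_mg_per_kg")
    out$regimen <- tryCatch(
      regimen(amount,
              dose_unit = if (is.null(rg$dose_mg)) "mg_per_kg" else "mg",
              interval = rg$interval_h, n_doses = rg$n_doses %||% 1,
              times = rg$dose_times_h, mtx = mtx),
      error = function(e) verr("regimen config: ", conditionMessage(e)))
    sc <- tr$schedule
    if (is.null(sc) || is.null(sc$ada_times_h))
      verr("trial config needs schedule$ada_times_h")
    check_keys(sc, c("ada_times_h", "pk_times_h", "final_time_h"),
               "trial schedule")
    out$schedule <- tryCatch(
      sampling_schedule(sc$ada_times_h,
                        pk_times = sc$pk_times_h %||% sc$ada_times_h,
                        final_time = sc$final_time_h),
      error = function(e) verr("schedule config: ", conditionMessage(e)))
    if (is.null(tr$ada_threshold_ng_per_ml)) {
      tr$ada_threshold_ng_per_ml <- 100
      out$effective$ada_threshold_ng_per_ml <- 100
    }
    if (tr$ada_threshold_ng_per_ml <= 0) verr("ada threshold must be > 0")
    out$threshold_ng_per_ml <- tr$ada_threshold_ng_per_ml
    if (is.null(tr$alpha)) {
      tr$alpha <- 0.05
      out$effective$alpha <- 0.05
    }
    out$alpha <- tr$alpha
  }

  if (!is.null(population)) {
    y <- yaml::read_yaml(population)
    check_keys(y, "population", population)
    pp <- y$population
    if (is.null(pp)) verr("missing 'population' section in ", population)
    check_keys(pp, c("n", "distributions"), "population config")
    if (is.null(pp$n)) {
      pp$n <- 250
      out$effective$n <- 250
    }
    if (pp$n < 1) verr("population n must be >= 1")
    out$n <- pp$n
    dists <- default_physiology_distributions()
    if (!is.null(pp$distributions)) {
      check_keys(pp$distributions, names(dists), "population distributions")
      for (k in names(pp$distributions)) {
        check_keys(pp$distributions[[k]], c("mean", "cv"),
                   paste0("distribution ", k))
        dists[[k]] <- modifyList(dists[[k]], pp$distributions[[k]])
        if (dists[[k]]$cv < 0) verr("negative CV for ", k)
        if (dists[[k]]$mean <= 0) verr("non-positive mean for ", k)
      }
    }
    out$distributions <- dists
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' Records package version, master seed, config-file MD5 hashes,
#' effective (defaulted) configuration values, per-stage wall-clock
#' seconds and warnings, as `manifest.json` in the output directory.
#'
#' @param dir output directory.
#' @param seed master seed of the run.
#' @param config_paths character vector of config files used.
#' @param stage label of the pipeline stage.
#' @param effective named list of filled-in default values.
#' @param timings named numeric vector of per-stage seconds.
#' @param warnings character vector.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(dir, seed, config_paths = character(0),
                           stage = "run", effective = list(),
                           timings = numeric(0),
                           warnings = character(0)) {
  config_paths <- config_paths[file.exists(config_paths)]
  manifest <- list(
    package = "adasim",
    version = as.character(utils::packageVersion("adasim")),
    stage = stage,
    seed = seed,
    configs = if (length(config_paths)) lapply(config_paths, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))) else list(),
    effective_defaults = effective,
    timings_s = as.list(timings),
    warnings = warnings)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
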