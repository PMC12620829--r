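#' Simulate one virtual subject
#'
#' Integrates the coupled PBPK + immune system (or the PBPK model alone)
#' for a single subject over a requested output grid. Bolus doses are
#' handled by integrating between dose events and applying state jumps,
#' so a sampling time that coincides with a dose time (> 0) reports the
#' pre-dose (trough) concentration; infusions are zero-order inputs over
#' the infusion duration; SC doses enter a first-order depot carrying
#' the bioavailable fraction.
#'
#' When the immune module is off, the epitope list is empty, or
#' `dc_uptake` is zero, the immune cascade cannot leave its initial
#' state and the drug dynamics decouple exactly; this limit is
#' integrated through the identical PK-only code path so the equality is
#' exact rather than approximate.
#'
#' @param drug [drug_parameters()].
#' @param physiology [physiology_parameters()].
#' @param regimen [regimen()]; its `$mtx` co-regimen (if any) modulates
#'   T-cell proliferation.
#' @param time_grid strictly increasing output times, h, starting at or
#'   after 0.
#' @param immune_on logical switch for the immune module.
#' @param rates [immune_rates()].
#' @param clearance subject-level clearance, L/h; defaults to
#'   `clearance_mean * clearance_multiplier`.
#' @param genotype optional character vector of HLA allele names carried
#'   by the subject, used to restrict epitope elution ranks.
#' @param control list of solver settings (`rtol`, `atol`, `maxsteps`,
#'   `engine` = `"compiled"` or `"R"`).
#' @param subject_id identifier used in error messages.
#' @return object of class `subject_trajectory`.
#' @export
simulate_subject <- function(drug, physiology, regimen, time_grid,
                             immune_on = TRUE,
                             rates = immune_rates(),
                             clearance = NULL,
                             genotype = NULL,
                             control = list(),
                             subject_id = NULL) {
  stopifnot(inherits(drug, "drug_parameters"),
            inherits(physiology, "physiology_parameters"),
            inherits(regimen, "regimen"))
  if (is.unsorted(time_grid, strictly = TRUE))
    stop("time_grid must be strictly increasing")
  if (any(time_grid < 0)) stop("time_grid must be >= 0")
  ctrl <- modifyList(list(rtol = 1e-8, atol = 1e-10, maxsteps = 50000,
                          engine = "compiled"), control)
  if (is.null(clearance))
    clearance <- drug$clearance_mean * physiology$clearance_multiplier
  if (clearance < 0) stop("clearance must be >= 0")

  horizon <- max(time_grid)
  if (any(regimen$times > horizon))
    stop("configuration error: dose times must lie within [0, last output time]")

  weights <- epitope_weights(drug$epitopes, genotype)
  coupled <- immune_on && length(weights) > 0 && any(weights > 0) &&
    drug$dc_uptake > 0
  mode <- if (immune_on) "full" else "pk_only"

  # per-dose molar amount
  amount_mg <- regimen$dose_amount *
    if (regimen$dose_unit == "mg_per_kg") physiology$body_weight else 1
  dose_nmol <- mg_to_nmol(amount_mg, drug$molecular_weight)

  inf_dur <- if (drug$route == "IV_infusion") drug$infusion_duration else 0
  inf_ends <- if (inf_dur > 0) pmin(regimen$times + inf_dur, horizon) else numeric(0)

  boundaries <- sort(unique(c(0, regimen$times, inf_ends, horizon)))
  grid0 <- sort(unique(c(0, time_grid)))

  y <- initial_state(drug, rates)
  pv <- pack_parms(drug, physiology, rates, clearance,
                   immune_on = coupled, weights = weights,
                   mtx = regimen$mtx)

  apply_dose <- function(y) {
    switch(drug$route,
           SC = { y["depot"] <- y["depot"] + drug$bioavailability * dose_nmol; y },
           IV_bolus = { y["plasma"] <- y["plasma"] + dose_nmol; y },
           IV_infusion = y)
  }

  out <- matrix(NA_real_, nrow = length(grid0), ncol = 18,
                dimnames = list(NULL, STATE_NAMES))
  if (grid0[1] == 0) {
    if (0 %in% regimen$times) y <- apply_dose(y)
    out[1, ] <- y
  }

  for (k in seq_len(length(boundaries) - 1)) {
    a <- boundaries[k]; b <- boundaries[k + 1]
    if (k > 1 && a %in% regimen$times) y <- apply_dose(y)
    # zero-order infusion active on this segment?
    pv[13] <- if (inf_dur > 0 &&
                  any(regimen$times <= a & a < regimen$times + inf_dur))
      dose_nmol / inf_dur else 0
    inner <- grid0[grid0 > a & grid0 <= b]
    times <- unique(c(a, inner, b))
    sol <- tryCatch(
      if (ctrl$engine == "compiled")
        deSolve::lsoda(y, times, func = "adasim_deriv", parms = pv,
                       dllname = "adasim", initfunc = "adasim_init",
                       rtol = ctrl$rtol, atol = ctrl$atol,
                       maxsteps = ctrl$maxsteps)
      else
        deSolve::lsoda(y, times, func = adasim_rhs_R, parms = pv,
                       rtol = ctrl$rtol, atol = ctrl$atol,
                       maxsteps = ctrl$maxsteps),
      warning = function(w) stop("solver failure",
                                 if (!is.null(subject_id))
                                   paste0(" for subject ", subject_id),
                                 ": ", conditionMessage(w), call. = FALSE))
    y <- stats::setNames(sol[nrow(sol), -1], STATE_NAMES)
    if (length(inner))
      out[match(inner, grid0), ] <- sol[match(inner, times), -1, drop = FALSE]
  }

  keep <- match(time_grid, grid0)
  traj <- pmax(out[keep, , drop = FALSE], 0)

  Vp <- physiology$V_plasma
  conc <- cbind(
    plasma = traj[, "plasma"] / Vp,
    lymph_node = traj[, "lymph"] / physiology$V_lymph_node,
    tissue_vascular = traj[, "tisv"] / physiology$V_tissue_vascular,
    tissue_endosomal = traj[, "tise"] / physiology$V_tissue_endosomal,
    tissue_interstitial = traj[, "tisi"] / physiology$V_tissue_interstitial)

  structure(list(
    times = time_grid,
    conc_nM = conc,
    amounts_nmol = traj[, 1:6, drop = FALSE],
    immune = traj[, 7:16, drop = FALSE],
    ada_free_nM = traj[, "ADA"],
    complex_nM = traj[, "CPLX"],
    ada_total_nM = traj[, "ADA"] + traj[, "CPLX"],
    mode = mode,
    subject_id = subject_id,
    drug_name = drug$name
  ), class = "subject_trajectory")
}

#' PK-only simulation (immune system deactivated)
#'
#' Runs the minimal PBPK model alone for a subject, i.e. the same
#' parameter set with the immune response switched off. Used as the
#' paired no-ADA reference for the [ADA]:[Drug] metric.
#'
#' @inheritParams simulate_subject
#' @return `subject_trajectory` with mode `"pk_only"`; all immune and
#'   ADA states are identically zero.
#' @export
simulate_pk_only <- function(drug, physiology, regimen, time_grid,
                             clearance = NULL, control = list(),
                             subject_id = NULL) {
  tr <- simulate_subject(drug, physiology, regimen, time_grid,
                         immune_on = FALSE, clearance = clearance,
                         control = control, subject_id = subject_id)
  tr$immune[] <- 0
  tr$ada_free_nM[] <- 0
  tr$complex_nM[] <- 0
  tr$ada_total_nM[] <- 0
  tr
}

#' @export
print.subject_trajectory <- function(x, ...) {
  cat(sprintf("<subject_trajectory> %s run, %d time points over %.0f h\n",
              x$mode, length(x$times), max(x$times)))
  cat(sprintf("  final free plasma drug: %.4g nM; peak total ADA: %.4g nM\n",
              x$conc_nM[nrow(x$conc_nM), "plasma"], max(x$ada_total_nM)))
  invisible(x)
}

# Per-epitope presentation weights w_e = sum over the subject's
# expressed allele set of (100/EL_rank - 1)^2. Homozygous loci
# contribute an allele once (allele-set semantics); (epitope, allele)
# pairs absent from the rank table contribute nothing (EL_rank 100).
epitope_weights <- function(epitopes, genotype = NULL) {
  vapply(epitopes, function(ep) {
    r <- ep$ranks
    if (!is.null(genotype)) r <- r[names(r) %in% unique(genotype)]
    if (!length(r)) return(0)
    if (any(r <= 0 | r > 100)) stop("EL_rank must be in (0, 100]")
    sum((100 / r - 1)^2)
  }, 0)
}
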