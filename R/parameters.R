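#' Compound-specific drug parameters
#'
#' Container for the pharmacokinetic and immunogenicity inputs of one
#' protein therapeutic: molecular weight, linear plasma clearance (mean
#' and between-subject CV), administration route, absorption parameters
#' for subcutaneous dosing, the dendritic-cell uptake scalar multiplying
#' antigen concentration, the drug-specific fraction of the naive CD4+
#' T-cell repertoire, and the list of selected T-cell epitopes.
#'
#' @param name drug label.
#' @param molecular_weight g/mol, > 0.
#' @param clearance_mean mean plasma clearance, L/h, > 0.
#' @param clearance_cv between-subject coefficient of variation of
#'   clearance (fraction, >= 0).
#' @param route one of `"IV_bolus"`, `"IV_infusion"`, `"SC"`.
#' @param bioavailability SC bioavailability (fraction in (0, 1]); SC only.
#' @param ka first-order SC absorption rate, 1/h; SC only.
#' @param infusion_duration infusion length in hours; IV_infusion only.
#' @param dc_uptake dimensionless dendritic-cell uptake scalar, >= 0.
#' @param naive_t_fraction fraction of the T-cell repertoire specific
#'   for the drug (fraction, >= 0).
#' @param epitopes list of epitopes as returned by [select_epitopes()],
#'   each with `peptide`, `start` and per-allele elution `ranks`.
#' @return object of class `drug_parameters`.
#' @export
drug_parameters <- function(name,
                            molecular_weight,
                            clearance_mean,
                            clearance_cv = 0,
                            route = c("IV_bolus", "IV_infusion", "SC"),
                            bioavailability = NULL,
                            ka = NULL,
                            infusion_duration = NULL,
                            dc_uptake = 1,
                            naive_t_fraction = 1e-5,
                            epitopes = list()) {
  route <- match.arg(route)
  if (!is.numeric(molecular_weight) || molecular_weight <= 0)
    stop("molecular_weight must be > 0 (g/mol)")
  if (!is.numeric(clearance_mean) || clearance_mean <= 0)
    stop("clearance_mean must be > 0 (L/h)")
  if (!is.numeric(clearance_cv) || clearance_cv < 0)
    stop("clearance_cv must be >= 0")
  if (!is.numeric(dc_uptake) || dc_uptake < 0)
    stop("dc_uptake must be >= 0")
  if (!is.numeric(naive_t_fraction) || naive_t_fraction < 0)
    stop("naive_t_fraction must be >= 0")
  if (route == "SC") {
    if (is.null(bioavailability) || bioavailability <= 0 || bioavailability > 1)
      stop("SC route requires bioavailability in (0, 1]")
    if (is.null(ka) || ka <= 0)
      stop("SC route requires ka > 0 (1/h)")
  }
  if (route == "IV_infusion" &&
      (is.null(infusion_duration) || infusion_duration <= 0))
    stop("IV_infusion route requires infusion_duration > 0 (h)")
  structure(list(
    name = name,
    molecular_weight = molecular_weight,
    clearance_mean = clearance_mean,
    clearance_cv = clearance_cv,
    route = route,
    bioavailability = bioavailability,
    ka = ka,
    infusion_duration = infusion_duration,
    dc_uptake = dc_uptake,
    naive_t_fraction = naive_t_fraction,
    epitopes = epitopes
  ), class = "drug_parameters")
}

#' Subject physiology for the minimal PBPK model
#'
#' Volumes and flows of the minimal PBPK structure: plasma, lymph node
#' and a lumped tissue split into vascular, endosomal and interstitial
#' sub-compartments. Transcapillary transport is convective lymph flow
#' with vascular reflection coefficient `sigma_vascular`; the endosomal
#' space exchanges with the tissue vascular space at first-order rates
#' (structural only -- elimination is linear plasma clearance).
#'
#' Defaults describe a 70 kg healthy adult and are package assumptions
#' (volumes/flows of this granularity are not identifiable from typical
#' mAb plasma data); they can be overridden per argument.
#'
#' @param body_weight kg.
#' @param V_plasma,V_lymph_node,V_tissue_vascular,V_tissue_endosomal,V_tissue_interstitial
#'   compartment volumes, L.
#' @param Q_blood plasma flow between plasma and tissue vascular space, L/h.
#' @param Q_lymph lymph flow, L/h; must be < `Q_blood`.
#' @param sigma_vascular vascular reflection coefficient in [0, 1].
#' @param k_endosomal_uptake,k_endosomal_return first-order exchange
#'   rates between tissue vascular and endosomal space, 1/h.
#' @param clearance_multiplier dimensionless subject-level multiplier on
#'   drug clearance, > 0.
#' @return object of class `physiology_parameters`.
#' @export
physiology_parameters <- function(body_weight = 70,
                                  V_plasma = 3.0,
                                  V_lymph_node = 0.28,
                                  V_tissue_vascular = 2.6,
                                  V_tissue_endosomal = 0.45,
                                  V_tissue_interstitial = 15.6,
                                  Q_blood = 120,
                                  Q_lymph = 0.121,
                                  sigma_vascular = 0.95,
                                  k_endosomal_uptake = 0.05,
                                  k_endosomal_return = 0.05,
                                  clearance_multiplier = 1) {
  vols <- c(V_plasma, V_lymph_node, V_tissue_vascular, V_tissue_endosomal,
            V_tissue_interstitial)
  if (any(!is.finite(vols)) || any(vols <= 0))
    stop("all compartment volumes must be > 0 (L)")
  if (Q_blood <= 0 || Q_lymph <= 0) stop("flows must be > 0 (L/h)")
  if (Q_lymph >= Q_blood) stop("Q_lymph must be < Q_blood")
  if (sigma_vascular < 0 || sigma_vascular > 1)
    stop("sigma_vascular must be in [0, 1]")
  if (clearance_multiplier <= 0) stop("clearance_multiplier must be > 0")
  structure(list(
    body_weight = body_weight,
    V_plasma = V_plasma,
    V_lymph_node = V_lymph_node,
    V_tissue_vascular = V_tissue_vascular,
    V_tissue_endosomal = V_tissue_endosomal,
    V_tissue_interstitial = V_tissue_interstitial,
    Q_blood = Q_blood,
    Q_lymph = Q_lymph,
    sigma_vascular = sigma_vascular,
    k_endosomal_uptake = k_endosomal_uptake,
    k_endosomal_return = k_endosomal_return,
    clearance_multiplier = clearance_multiplier
  ), class = "physiology_parameters")
}

#' Methotrexate PK/PD parameters
#'
#' Two-compartment disposition with first-order oral absorption, and an
#' inhibitory Emax pharmacodynamic model on the T-cell proliferation
#' rate. The default IC50 of 283 nM reproduces the reported reduction of
#' ADA incidence under methotrexate co-medication; PK defaults are
#' literature-typical low-dose oral methotrexate values (assumed).
#'
#' @param ka_mtx absorption rate, 1/h.
#' @param CL_mtx central clearance, L/h.
#' @param Q_mtx inter-compartmental clearance, L/h.
#' @param V1_mtx,V2_mtx central and peripheral volumes, L.
#' @param F_mtx oral bioavailability (fraction).
#' @param imax maximal fractional inhibition, in (0, 1].
#' @param ic50 concentration of half-maximal inhibition, nM, > 0.
#' @return object of class `mtx_parameters`.
#' @export
mtx_parameters <- function(ka_mtx = 1.0,
                           CL_mtx = 6.0,
                           Q_mtx = 0.4,
                           V1_mtx = 15,
                           V2_mtx = 5,
                           F_mtx = 0.7,
                           imax = 1,
                           ic50 = 283) {
  if (ic50 <= 0) stop("ic50 must be > 0 (nM)")
  if (imax <= 0 || imax > 1) stop("imax must be in (0, 1]")
  if (any(c(ka_mtx, CL_mtx, Q_mtx, V1_mtx, V2_mtx) <= 0))
    stop("methotrexate PK parameters must be > 0")
  if (F_mtx <= 0 || F_mtx > 1) stop("F_mtx must be in (0, 1]")
  structure(list(ka_mtx = ka_mtx, CL_mtx = CL_mtx, Q_mtx = Q_mtx,
                 V1_mtx = V1_mtx, V2_mtx = V2_mtx, F_mtx = F_mtx,
                 imax = imax, ic50 = ic50),
            class = "mtx_parameters")
}

#' Immune-response rate constants
#'
#' Rate table for the dendritic-cell / T / B / plasma-cell lineages, ADA
#' secretion and ADA-drug binding. The lineage structure follows
#' published mechanistic humoral-response models; the numeric defaults
#' are assumed stand-ins (not from a single source) chosen so that a
#' strongly presented epitope set seroconverts a typical subject within
#' about four weeks of repeat dosing while a weakly presented set does
#' not. `k_ag_n` is the half-maximal activation constant of the
#' presented-antigen signal; see [calibrate_k_ag_n()] to refit it
#' against observed incidences.
#'
#' All rates are 1/h; `kon` is 1/nM/h; `q_SP`/`q_LP` are nmol IgG per
#' cell per hour; capacities and pool sizes are cell counts.
#'
#' @param ... named overrides of any default listed in the function
#'   signature, e.g. `immune_rates(k_ic = 0.1)`.
#' @return object of class `immune_rates`.
#' @export
immune_rates <- function(...) {
  def <- list(
    # presented-antigen half-activation constant (dimensionless signal)
    k_ag_n = 4e7,
    # dendritic cells
    id_i0 = 1e4, k_dc_death = 0.01, k_dc_mat = 0.1, k_dc_mat0 = 0.001,
    k_dcm_death = 0.05,
    # T lineage; t_repertoire scales naive_t_fraction to a cell count
    t_repertoire = 1e6,
    k_act_T = 0.1, rho_AT = 0.2, at_cap = 1e6, s_prolif_ratio = 0.75,
    k_AT_death = 0.085, k_AT_mem = 0.005, k_MT_death = 1e-4, f_recall = 0.5,
    # B lineage: a trace of cognate help suffices for activation
    # (k_T_help) but clonal expansion needs an expanded T compartment
    # (k_T_prol)
    nb0 = 8500, k_act_B = 0.001, k_T_help = 0.1, k_T_prol = 1000,
    k_B_ag = 5, rho_AB = 0.08, ab_cap = 3.6e4,
    k_AB_death = 0.01, k_AB_sp = 0.01, k_AB_lp = 2e-3, k_AB_mem = 0.002,
    k_MB_death = 1e-4,
    # plasma cells and ADA
    k_SP_death = 0.008, k_LP_death = 0.002,
    q_SP = 2.9e-5, q_LP = 2.9e-5,
    k_ADA_elim = log(2) / (7 * 24),
    kon = 0.036, koff = 0.0036, k_ic = 0.003
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(def))
    if (length(bad)) stop("unknown immune rate(s): ", paste(bad, collapse = ", "))
    def[names(ov)] <- ov
  }
  num <- unlist(def)
  if (any(!is.finite(num)) || any(num < 0))
    stop("immune rates must be finite and >= 0")
  if (def$kon <= 0 || def$koff <= 0) stop("kon and koff must be > 0")
  if (def$k_ag_n <= 0) stop("k_ag_n must be > 0")
  structure(def, class = "immune_rates")
}
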