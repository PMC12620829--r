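# Parameter packing shared by the compiled and the reference R
# right-hand sides. Index layout must match src/adasim.c exactly.

N_PARMS <- 224L
MAX_MTX <- 160L
MAX_EPITOPES <- 5L

STATE_NAMES <- c("depot", "plasma", "lymph", "tisv", "tise", "tisi",
                 "IDi", "IDm", "NT", "AT", "MT",
                 "NB", "AB", "MB", "SP", "LP", "ADA", "CPLX")

pack_parms <- function(drug, physiology, rates, clearance,
                       immune_on, weights = numeric(0),
                       inf_rate = 0, mtx = NULL) {
  n_epi <- length(weights)
  if (n_epi > MAX_EPITOPES)
    stop("at most ", MAX_EPITOPES, " epitopes are supported per drug")
  pv <- numeric(N_PARMS)
  pv[1:13] <- c(physiology$V_plasma, physiology$V_lymph_node,
                physiology$V_tissue_vascular, physiology$V_tissue_endosomal,
                physiology$V_tissue_interstitial,
                physiology$Q_blood, physiology$Q_lymph,
                physiology$sigma_vascular,
                physiology$k_endosomal_uptake, physiology$k_endosomal_return,
                clearance,
                if (drug$route == "SC") drug$ka else 0,
                inf_rate)
  pv[14] <- as.numeric(immune_on)
  pv[15] <- drug$dc_uptake
  pv[16] <- rates$k_ag_n
  pv[17] <- n_epi
  if (n_epi) pv[18:(17 + n_epi)] <- weights
  pv[23:53] <- c(rates$k_dc_death * rates$id_i0, rates$k_dc_death,
                 rates$k_dc_mat, rates$k_dc_mat0, rates$k_dcm_death,
                 rates$k_act_T, rates$rho_AT, rates$at_cap,
                 rates$k_AT_death, rates$k_AT_mem, rates$k_MT_death,
                 rates$f_recall,
                 rates$k_act_B, rates$k_T_help, rates$k_T_prol,
                 rates$k_B_ag, rates$rho_AB, rates$ab_cap,
                 rates$k_AB_death, rates$k_AB_sp, rates$k_AB_lp,
                 rates$k_AB_mem, rates$k_MB_death,
                 rates$k_SP_death, rates$k_LP_death,
                 rates$q_SP, rates$q_LP, rates$k_ADA_elim,
                 rates$kon, rates$koff, rates$k_ic)
  # clonal-expansion gate scales with the activation constant
  pv[54] <- rates$s_prolif_ratio * rates$k_ag_n
  if (!is.null(mtx) && mtx$dose_mg > 0) {
    if (length(mtx$times) > MAX_MTX)
      stop("at most ", MAX_MTX, " methotrexate doses are supported")
    terms <- mtx_exp_terms(mtx$params, mg_to_nmol(mtx$dose_mg, MTX_MW))
    pv[55:57] <- c(mtx$params$imax, mtx$params$ic50, length(mtx$times))
    pv[58:60] <- terms$lambda
    pv[61:63] <- terms$coef
    pv[64:(63 + length(mtx$times))] <- mtx$times
  }
  pv
}

initial_state <- function(drug, rates) {
  y <- stats::setNames(numeric(18), STATE_NAMES)
  y["IDi"] <- rates$id_i0
  y["NT"] <- drug$naive_t_fraction * rates$t_repertoire
  y["NB"] <- rates$nb0
  y
}

# Reference right-hand side in plain R, mirroring src/adasim.c term by
# term. Used by the test suite to cross-check the compiled code and
# available as a fallback engine.
adasim_rhs_R <- function(t, y, pv) {
  y <- pmax(y, 0)
  Vp <- pv[1]; Vln <- pv[2]; Vv <- pv[3]; Vi <- pv[5]
  Qb <- pv[6]; Ql <- pv[7]; sig <- pv[8]; kup <- pv[9]; kret <- pv[10]
  CL <- pv[11]; ka <- pv[12]; inf_rate <- pv[13]
  immune_on <- pv[14] > 0.5

  Cp <- y[2] / Vp; Cln <- y[3] / Vln; Cv <- y[4] / Vv; Ci <- y[6] / Vi
  bind <- if (immune_on) pv[51] * Cp * y[17] - pv[52] * y[18] else 0

  d <- numeric(18)
  d[1] <- -ka * y[1]
  d[2] <- ka * y[1] + inf_rate - CL * Cp - Qb * Cp +
    (Qb - Ql) * Cv + Ql * Cln - bind * Vp
  d[3] <- Ql * Ci - Ql * Cln
  d[4] <- Qb * Cp - (Qb - Ql) * Cv - Ql * (1 - sig) * Cv -
    kup * y[4] + kret * y[5]
  d[5] <- kup * y[4] - kret * y[5]
  d[6] <- Ql * (1 - sig) * Cv - Ql * Ci

  if (!immune_on) return(list(d))

  u <- pv[15]; K <- pv[16]; n_epi <- pv[17]
  w <- if (n_epi > 0) pv[18:(17 + n_epi)] else numeric(0)
  AgVS <- Cv
  Ttot <- y[9] + y[10] + y[11]
  frac <- if (y[8] + Ttot > 0) y[8] / (y[8] + Ttot) else 0
  S <- u * AgVS * w
  S_tot <- sum(S)
  D_sum <- frac * sum(ifelse(S > 0, S / (S + K), 0))
  stim <- if (S_tot > 0) S_tot / (S_tot + K) else 0
  stim_p <- if (S_tot > 0) S_tot^2 / (S_tot^2 + pv[54]^2) else 0

  f_mtx <- 1
  if (pv[57] > 0) {
    td <- pv[64:(63 + pv[57])]
    dt <- t - td[td <= t]
    cm <- if (length(dt))
      max(0, sum(vapply(dt, function(x) sum(pv[61:63] * exp(pv[58:60] * x)), 0)))
    else 0
    f_mtx <- 1 - pv[55] * cm / (pv[56] + cm)
  }

  mat <- (pv[25] * stim + pv[26]) * y[7]
  d[7] <- pv[23] - pv[24] * y[7] - mat
  d[8] <- mat - pv[27] * y[8]

  actT <- pv[28] * D_sum * y[9]
  recall <- pv[34] * pv[28] * D_sum * y[11]
  prolT <- pv[29] * f_mtx * stim_p * y[10] * (1 - y[10] / pv[30])
  d[9] <- -actT
  d[10] <- actT + recall + prolT - (pv[31] + pv[32]) * y[10]
  d[11] <- pv[32] * y[10] - pv[33] * y[11] - recall

  help_act <- y[10] / (y[10] + pv[36])
  help_prol <- y[10] / (y[10] + pv[37])
  stimB <- Cp / (Cp + pv[38])
  actB <- pv[35] * y[12] * stimB * help_act
  prolB <- pv[39] * stimB * help_prol * y[13] * (1 - y[13] / pv[40])
  d[12] <- -actB
  d[13] <- actB + prolB - (pv[41] + pv[42] + pv[43] + pv[44]) * y[13]
  d[14] <- pv[44] * y[13] - pv[45] * y[14]
  d[15] <- pv[42] * y[13] - pv[46] * y[15]
  d[16] <- pv[43] * y[13] - pv[47] * y[16]

  sec <- (pv[48] * y[15] + pv[49] * y[16]) / Vp
  d[17] <- sec - bind - pv[50] * y[17]
  d[18] <- bind - pv[53] * y[18]
  list(d)
}
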