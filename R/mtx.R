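#' Methotrexate central concentration
#'
#' Two-compartment disposition with first-order oral absorption, solved
#' in closed form by eigen-decomposition of the linear rate matrix and
#' superposed over doses. Used as a time-dependent forcing on the
#' T-cell proliferation rate; methotrexate itself carries no immune
#' states.
#'
#' @param params [mtx_parameters()].
#' @param mtx_regimen [mtx_regimen()]; its `$params` are ignored in
#'   favour of `params`.
#' @param t times (h), >= 0.
#' @return central methotrexate concentration, nM, at each `t`.
#' @export
mtx_concentration <- function(params, mtx_regimen, t) {
  stopifnot(inherits(params, "mtx_parameters"),
            inherits(mtx_regimen, "mtx_regimen"))
  if (any(t < 0)) stop("t must be >= 0")
  if (mtx_regimen$dose_mg == 0) return(rep(0, length(t)))
  terms <- mtx_exp_terms(params, mg_to_nmol(mtx_regimen$dose_mg, MTX_MW))
  vapply(t, function(ti) {
    dt <- ti - mtx_regimen$times
    dt <- dt[dt >= 0]
    if (!length(dt)) return(0)
    max(0, sum(vapply(dt, function(d) sum(terms$coef * exp(terms$lambda * d)),
                      0)))
  }, 0)
}

# Exponential terms of the central-compartment solution for one oral
# dose: C1(t) = sum_j coef[j] * exp(lambda[j] * t), nM, t since dose.
mtx_exp_terms <- function(params, dose_nmol) {
  k10 <- params$CL_mtx / params$V1_mtx
  k12 <- params$Q_mtx / params$V1_mtx
  k21 <- params$Q_mtx / params$V2_mtx
  M <- rbind(c(-params$ka_mtx, 0, 0),
             c(params$ka_mtx, -(k10 + k12), k21),
             c(0, k12, -k21))
  eg <- eigen(M)
  if (any(abs(Im(eg$values)) > 1e-12))
    stop("unexpected complex eigenvalues in methotrexate PK matrix")
  lambda <- Re(eg$values)
  if (min(abs(outer(lambda, lambda, "-")[lower.tri(diag(3))])) < 1e-10)
    stop("degenerate methotrexate PK eigenvalues; perturb ka_mtx")
  V <- Re(eg$vectors)
  x0 <- c(params$F_mtx * dose_nmol, 0, 0)
  coef_amount <- V[2, ] * drop(solve(V, x0))
  list(lambda = lambda, coef = coef_amount / params$V1_mtx)
}
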