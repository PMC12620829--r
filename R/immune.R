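#' Per-epitope T-cell activation signal
#'
#' Activation of drug-specific naive T cells by one presented epitope:
#' a dendritic-cell availability fraction multiplied by a saturating
#' function of the presented-antigen signal,
#' \deqn{D = \frac{ID_m}{ID_m + T_{tot}} \cdot \frac{S}{S + K_{Ag,N}},
#'   \quad S = DC_{uptake} \cdot AgVS \cdot
#'   \sum_{alleles} (100 / EL_{rank} - 1)^2,}
#' where `AgVS` is the drug concentration in the tissue vascular space
#' (nM) and the sum runs over the elution ranks of the epitope for the
#' alleles expressed by the subject. An allele at the maximum rank of
#' 100 contributes nothing; lower (stronger) ranks contribute more.
#'
#' @param inputs list with fields `ID_m`, `Ttot` (cell counts),
#'   `dc_uptake` (>= 0), `AgVS` (nM, >= 0), `elution_ranks` (numeric in
#'   (0, 100]), `K_Ag_N` (> 0).
#' @return dimensionless activation signal in [0, 1]; 0 when
#'   `ID_m + Ttot` is 0.
#' @examples
#' epitope_activation_signal(list(ID_m = 100, Ttot = 300, dc_uptake = 1,
#'                                AgVS = 1, elution_ranks = 10,
#'                                K_Ag_N = 81))  # 0.125
#' @export
epitope_activation_signal <- function(inputs) {
  stopifnot(is.list(inputs))
  with(inputs, {
    if (any(elution_ranks <= 0 | elution_ranks > 100))
      stop("EL_rank must be in (0, 100]")
    if (K_Ag_N <= 0) stop("K_Ag_N must be > 0")
    if (dc_uptake < 0 || AgVS < 0 || ID_m < 0 || Ttot < 0)
      stop("ID_m, Ttot, dc_uptake and AgVS must be >= 0")
    if (ID_m + Ttot == 0) return(0)
    S <- dc_uptake * AgVS * sum((100 / elution_ranks - 1)^2)
    if (S == 0) return(0)
    ID_m / (ID_m + Ttot) * S / (S + K_Ag_N)
  })
}

#' Methotrexate inhibition factor on T-cell proliferation
#'
#' Inhibitory Emax model: the T-cell proliferation rate is multiplied by
#' `1 - imax * c / (ic50 + c)`. With the default `ic50` of 283 nM and
#' `imax` of 1, inhibition is half-maximal at 283 nM.
#'
#' @param c_mtx central methotrexate concentration, nM (>= 0).
#' @param params [mtx_parameters()].
#' @return multiplicative factor in (0, 1]; strictly decreasing in
#'   `c_mtx` and tending to `1 - imax`.
#' @export
mtx_proliferation_factor <- function(c_mtx, params = mtx_parameters()) {
  stopifnot(inherits(params, "mtx_parameters"))
  if (any(c_mtx < 0)) stop("c_mtx must be >= 0")
  1 - params$imax * c_mtx / (params$ic50 + c_mtx)
}

#' Build the coupled PBPK + immune simulator for one subject
#'
#' Returns a closure running the joint system for a given regimen and
#' output grid: immune activation is summed over the drug's selected
#' epitopes restricted to the subject's genotype, ADA is secreted into
#' plasma, binds free drug 1:1 and the complex is cleared; the drug
#' mass balance reflects the loss to complex. With no epitopes (or zero
#' uptake) the system decouples and reproduces [simulate_pk_only()]
#' exactly.
#'
#' @inheritParams simulate_subject
#' @return function `(regimen, time_grid, immune_on = TRUE)` returning
#'   a `subject_trajectory`.
#' @export
build_coupled_system <- function(drug, physiology, rates = immune_rates(),
                                 genotype = NULL, clearance = NULL,
                                 control = list(), subject_id = NULL) {
  force(drug); force(physiology); force(rates); force(genotype)
  function(regimen, time_grid, immune_on = TRUE) {
    simulate_subject(drug, physiology, regimen, time_grid,
                     immune_on = immune_on, rates = rates,
                     clearance = clearance, genotype = genotype,
                     control = control, subject_id = subject_id)
  }
}

#' Calibrate the half-maximal activation constant K_Ag_N
#'
#' Bound-constrained scalar calibration of `k_ag_n` minimising the root
#' mean square error between simulated and observed immunogenicity
#' incidences over a set of drug configurations, mirroring how the
#' constant is fitted against clinical incidence data. The search works
#' on a log10 scale: a fixed grid is evaluated first (also used to flag
#' an insensitive objective), then refined with [stats::optimize()];
#' every evaluation must be deterministic for a fixed seed, which is the
#' caller's responsibility inside `simulate_incidence`.
#'
#' @param targets list of `list(config = <drug or scenario object>,
#'   observed = <incidence %>)`.
#' @param simulate_incidence function `(config, k_ag_n)` returning the
#'   simulated ADA incidence in percent.
#' @param bounds length-2 positive numeric search interval for
#'   `k_ag_n`.
#' @param n_grid number of log-spaced pre-screen points.
#' @param tol relative tolerance of the 1-D optimisation (on log10 k).
#' @return object of class `k_ag_n_fit` with elements `k_ag_n`, `rmse`,
#'   `insensitive`, and the table of `evaluations`.
#' @export
calibrate_k_ag_n <- function(targets, simulate_incidence,
                             bounds = c(1e2, 1e8), n_grid = 7,
                             tol = 0.01) {
  if (!length(targets)) stop("at least one calibration target is required")
  if (length(bounds) != 2 || any(bounds <= 0) || bounds[1] >= bounds[2])
    stop("bounds must be positive and increasing")
  obs <- vapply(targets, `[[`, 0, "observed")

  evals <- new.env(parent = emptyenv())
  incidences <- function(k) {
    key <- sprintf("%.15g", k)
    if (!is.null(evals[[key]])) return(evals[[key]])
    v <- vapply(targets, function(tg) simulate_incidence(tg$config, k), 0)
    evals[[key]] <- v
    v
  }
  rmse <- function(k) sqrt(mean((incidences(k) - obs)^2))

  grid <- 10^seq(log10(bounds[1]), log10(bounds[2]), length.out = n_grid)
  grid_inc <- lapply(grid, incidences)
  insensitive <- all(vapply(seq_along(obs), function(i) {
    v <- vapply(grid_inc, `[[`, 0, i)
    diff(range(v)) == 0
  }, NA))

  refined <- numeric(0)
  if (!insensitive) {
    # the objective is stepwise in k (finite virtual cohorts), so a
    # plain golden-section search can stall on a plateau; zoom in with
    # a second grid around the best pre-screen point, then polish
    grid_rmse <- vapply(grid_inc, function(v) sqrt(mean((v - obs)^2)), 0)
    # plateaus tie frequently; bracket every tied minimum plus a
    # neighbour on each side
    tie <- which(grid_rmse <= min(grid_rmse) + 1e-9)
    lo <- log10(grid[max(1, min(tie) - 1)])
    hi <- log10(grid[min(n_grid, max(tie) + 1)])
    zoom <- 10^seq(lo, hi, length.out = 17)
    zoom_rmse <- vapply(zoom, rmse, 0)
    z <- which.min(zoom_rmse)
    o <- stats::optimize(function(lk) rmse(10^lk),
                         interval = log10(zoom[c(max(1, z - 1),
                                                 min(length(zoom), z + 1))]),
                         tol = tol)
    refined <- c(zoom, 10^o$minimum)
  }
  ks <- sort(unique(c(grid, refined)))
  rs <- vapply(ks, rmse, 0)
  best <- which(rs <= min(rs) + 1e-12)[1]  # tie -> smallest k

  structure(list(k_ag_n = ks[best], rmse = rs[best],
                 insensitive = insensitive,
                 evaluations = data.frame(k_ag_n = ks, rmse = rs)),
            class = "k_ag_n_fit")
}

#' @export
print.k_ag_n_fit <- function(x, ...) {
  if (x$insensitive)
    cat("<k_ag_n_fit> objective insensitive over the search range;",
        "returning", format(x$k_ag_n), "\n")
  else
    cat(sprintf("<k_ag_n_fit> k_ag_n = %.6g (RMSE %.3f%% over %d evaluations)\n",
                x$k_ag_n, x$rmse, nrow(x$evaluations)))
  invisible(x)
}
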