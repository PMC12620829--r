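#' Dosing regimen
#'
#' Repeat-dose regimen for the therapeutic: either a regular pattern
#' (`interval`, `n_doses`) or an explicit list of dose times (which
#' overrides the pattern, e.g. for loading doses). Doses are mass based
#' and converted to molar amounts at the simulation boundary.
#'
#' @param dose_amount dose per administration.
#' @param dose_unit `"mg"` or `"mg_per_kg"` (scaled by subject body
#'   weight).
#' @param interval dosing interval, h (> 0).
#' @param n_doses number of doses (>= 1).
#' @param times optional explicit dose times (h); overrides
#'   `interval`/`n_doses`.
#' @param mtx optional methotrexate co-regimen from [mtx_regimen()].
#' @return object of class `regimen` with derived `$times`.
#' @export
regimen <- function(dose_amount, dose_unit = c("mg", "mg_per_kg"),
                    interval = NULL, n_doses = 1, times = NULL,
                    mtx = NULL) {
  dose_unit <- match.arg(dose_unit)
  if (!is.numeric(dose_amount) || dose_amount <= 0)
    stop("configuration error: dose_amount must be > 0")
  if (is.null(times)) {
    if (is.null(interval)) {
      if (n_doses > 1) stop("interval required when n_doses > 1")
      interval <- 1
    }
    if (interval <= 0) stop("interval must be > 0 (h)")
    if (n_doses < 1) stop("n_doses must be >= 1")
    times <- (seq_len(n_doses) - 1) * interval
  } else {
    if (any(times < 0) || is.unsorted(times, strictly = TRUE))
      stop("explicit dose times must be strictly increasing and >= 0")
    n_doses <- length(times)
  }
  structure(list(dose_amount = dose_amount, dose_unit = dose_unit,
                 interval = interval, n_doses = n_doses, times = times,
                 mtx = mtx),
            class = "regimen")
}

#' Methotrexate co-medication regimen
#'
#' @param dose_mg oral methotrexate dose, mg.
#' @param interval dosing interval, h (typically 168 for weekly dosing).
#' @param n_doses number of doses.
#' @param start time of first dose, h.
#' @param params PK/PD parameters from [mtx_parameters()].
#' @return object of class `mtx_regimen`.
#' @export
mtx_regimen <- function(dose_mg, interval = 168, n_doses = 1, start = 0,
                        params = mtx_parameters()) {
  if (!is.numeric(dose_mg) || dose_mg < 0)
    stop("configuration error: dose_mg must be >= 0")
  if (interval <= 0) stop("interval must be > 0")
  if (n_doses < 1) stop("n_doses must be >= 1")
  stopifnot(inherits(params, "mtx_parameters"))
  structure(list(dose_mg = dose_mg, interval = interval,
                 n_doses = n_doses, start = start,
                 times = start + (seq_len(n_doses) - 1) * interval,
                 params = params),
            class = "mtx_regimen")
}

#' Trial sampling schedule
#'
#' Times at which ADA and drug concentrations are "assayed" in the
#' virtual trial. The ADA positivity rule and the [ADA]:[Drug] metric
#' only look at these sampled times; `final_time` is the joint final
#' PK/ADA assessment time and must be present in both lists.
#'
#' @param ada_times ADA sampling times, h.
#' @param pk_times drug concentration sampling times, h.
#' @param final_time final joint assessment time, h; defaults to the
#'   last common time of `ada_times` and `pk_times`.
#' @return object of class `sampling_schedule`.
#' @export
sampling_schedule <- function(ada_times, pk_times = ada_times,
                              final_time = NULL) {
  if (any(ada_times < 0) || any(pk_times < 0))
    stop("sampling times must be >= 0")
  ada_times <- sort(unique(ada_times))
  pk_times <- sort(unique(pk_times))
  if (is.null(final_time)) {
    common <- intersect(ada_times, pk_times)
    if (!length(common))
      stop("no common ADA/PK sampling time to use as final_time")
    final_time <- max(common)
  }
  if (!(final_time %in% ada_times) || !(final_time %in% pk_times))
    stop("final_time must be present in both ada_times and pk_times")
  structure(list(ada_times = ada_times, pk_times = pk_times,
                 final_time = final_time),
            class = "sampling_schedule")
}
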