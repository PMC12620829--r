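#' Classify ADA positivity from a trajectory
#'
#' A subject is ADA positive if total ADA (free plus complexed),
#' converted to ng/mL with the assumed ADA molecular weight, strictly
#' exceeds the assay threshold at one or more ADA sampling times.
#' Values between sampling times are ignored, mimicking a sparse
#' clinical assay. The default threshold is the FDA minimum recommended
#' assay sensitivity of 100 ng/mL, applied when a study-specific
#' threshold is not supplied.
#'
#' @param trajectory `subject_trajectory` from the full simulation.
#' @param ada_times ADA sampling times (must be in the trajectory
#'   grid).
#' @param threshold_ng_per_ml positivity threshold, ng/mL, > 0.
#' @param ada_mw assumed ADA molecular weight, g/mol.
#' @return logical flag.
#' @export
classify_ada <- function(trajectory, ada_times,
                         threshold_ng_per_ml = 100,
                         ada_mw = ADA_MW_DEFAULT) {
  stopifnot(inherits(trajectory, "subject_trajectory"))
  if (threshold_ng_per_ml <= 0) stop("threshold must be > 0 (ng/mL)")
  idx <- match(ada_times, trajectory$times)
  if (anyNA(idx)) stop("ada_times must be a subset of the trajectory times")
  any(nM_to_ng_per_ml(trajectory$ada_total_nM[idx], ada_mw) >
        threshold_ng_per_ml)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration p-value for small tie-free samples, otherwise the
#' normal approximation with tie-corrected variance and continuity
#' correction (the standard [stats::wilcox.test()] behaviour, to which
#' this delegates). Degenerate all-tied comparisons return p = 1.
#'
#' @param x,y numeric samples (each non-empty).
#' @return two-sided p-value in (0, 1].
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  p <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL,
                                           correct = TRUE)$p.value)
  if (is.nan(p) || is.na(p)) p <- 1  # zero rank variance: no evidence
  min(p, 1)
}

#' [ADA]:[Drug] molar ratio for one subject
#'
#' The maximum total ADA concentration (nM, full simulation, over the
#' ADA sampling times) divided by the free plasma drug concentration
#' (nM) that the same subject would have had in the absence of ADA
#' (paired PK-only run) at the final ADA sampling time. Returns 0 when
#' ADA never forms; +Inf (with attribute `flag = "zero_drug"`) when the
#' PK-only drug concentration at the final time is 0.
#'
#' @param full,pk_only paired `subject_trajectory` objects for the same
#'   subject.
#' @param schedule [sampling_schedule()].
#' @return non-negative ratio.
#' @export
ada_drug_ratio <- function(full, pk_only, schedule) {
  stopifnot(inherits(full, "subject_trajectory"),
            inherits(pk_only, "subject_trajectory"),
            inherits(schedule, "sampling_schedule"))
  idx <- match(schedule$ada_times, full$times)
  if (anyNA(idx)) stop("ada_times must be in the trajectory grid")
  max_ada <- max(full$ada_total_nM[idx])
  if (max_ada == 0) return(0)
  fidx <- match(schedule$final_time, pk_only$times)
  drug <- unname(pk_only$conc_nM[fidx, "plasma"])
  if (drug == 0) {
    r <- Inf
    attr(r, "flag") <- "zero_drug"
    return(r)
  }
  max_ada / drug
}

#' Exposure-impact verdict from a trial result
#'
#' Compares free plasma drug concentration at the final sampling time
#' between ADA-positive and ADA-negative subjects with a two-sided
#' Wilcoxon rank-sum test. The verdict is `"impact"` only when p <
#' alpha *and* the ADA-positive median is lower (a significant increase
#' is not an exposure loss); `"not_assessable"` when fewer than
#' `min_group` ADA-positive subjects exist (or no ADA-negative
#' subjects).
#'
#' @param result `ada_trial` object from [run_trial()].
#' @param alpha significance level.
#' @param min_group minimum assessable ADA-positive group size.
#' @return list with `verdict`, `p_value`, and group medians.
#' @export
compare_pk <- function(result, alpha = 0.05, min_group = 2) {
  stopifnot(inherits(result, "ada_trial"))
  d <- result$subjects
  pos <- d$free_drug_final_full[d$ada_positive]
  neg <- d$free_drug_final_full[!d$ada_positive]
  if (length(pos) < min_group || length(neg) < 1)
    return(list(verdict = "not_assessable", p_value = NA_real_,
                median_pos = if (length(pos)) stats::median(pos) else NA_real_,
                median_neg = if (length(neg)) stats::median(neg) else NA_real_))
  p <- wilcoxon_rank_sum(pos, neg)
  verdict <- if (p < alpha && stats::median(pos) < stats::median(neg))
    "impact" else "no_impact"
  list(verdict = verdict, p_value = p,
       median_pos = stats::median(pos), median_neg = stats::median(neg))
}

#' Run a virtual clinical trial
#'
#' For every virtual subject, runs the full coupled simulation and a
#' paired PK-only simulation on the identical parameter set, classifies
#' ADA positivity at the sampled ADA times, computes the [ADA]:[Drug]
#' molar ratio and the percent reduction in free trough drug versus the
#' PK-only run, and tests whether ADA positivity is associated with
#' lower free drug at the final sampling time. Subjects whose solver
#' run fails are flagged and excluded from the statistics.
#'
#' @param population [generate_population()] result.
#' @param drug [drug_parameters()].
#' @param regimen [regimen()].
#' @param schedule [sampling_schedule()].
#' @param seed master seed recorded in the result (the simulation
#'   itself is deterministic given the population).
#' @param threshold_ng_per_ml ADA positivity threshold (default: FDA
#'   minimum recommended sensitivity, 100 ng/mL).
#' @param alpha significance level of the exposure comparison.
#' @param rates [immune_rates()].
#' @param ada_mw assumed ADA molecular weight, g/mol.
#' @param immune_on master switch; `FALSE` gives a PK-only trial (0%
#'   incidence by construction).
#' @param control solver control list, see [simulate_subject()].
#' @return object of class `ada_trial` with per-subject results
#'   (`$subjects` data.frame), incidence (%), the exposure comparison
#'   and metadata.
#' @export
run_trial <- function(population, drug, regimen, schedule, seed = 1,
                      threshold_ng_per_ml = 100, alpha = 0.05,
                      rates = immune_rates(), ada_mw = ADA_MW_DEFAULT,
                      immune_on = TRUE, control = list()) {
  stopifnot(inherits(population, "virtual_population"),
            inherits(drug, "drug_parameters"),
            inherits(regimen, "regimen"),
            inherits(schedule, "sampling_schedule"))
  grid <- sort(unique(c(schedule$ada_times, schedule$pk_times)))
  grid <- grid[grid > 0]

  rows <- vector("list", population$n)
  failed <- integer(0)
  for (s in population$subjects) {
    res <- tryCatch({
      full <- simulate_subject(drug, s$physiology, regimen, grid,
                               immune_on = immune_on, rates = rates,
                               clearance = s$clearance,
                               genotype = s$genotype, control = control,
                               subject_id = s$id)
      pk <- simulate_pk_only(drug, s$physiology, regimen, grid,
                             clearance = s$clearance, control = control,
                             subject_id = s$id)
      aidx <- match(schedule$ada_times, grid)
      fidx <- match(schedule$final_time, grid)
      max_ada <- max(full$ada_total_nM[aidx])
      ratio <- ada_drug_ratio(full, pk, schedule)
      f_full <- unname(full$conc_nM[fidx, "plasma"])
      f_pk <- unname(pk$conc_nM[fidx, "plasma"])
      data.frame(
        id = s$id,
        ada_positive = classify_ada(full, schedule$ada_times,
                                    threshold_ng_per_ml, ada_mw),
        max_ada_nM = max_ada,
        max_ada_ng_per_ml = nM_to_ng_per_ml(max_ada, ada_mw),
        ratio = as.numeric(ratio),
        free_drug_final_full = f_full,
        free_drug_final_pkonly = f_pk,
        pct_reduction = if (f_pk > 0) 100 * (1 - f_full / f_pk) else NA_real_)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("subject ", s$id, " excluded: ", conditionMessage(res))
      failed <- c(failed, s$id)
    } else {
      rows[[s$id]] <- res
    }
  }
  subjects <- do.call(rbind, rows)
  result <- structure(list(
    subjects = subjects,
    n = nrow(subjects),
    n_failed = length(failed),
    failed_ids = failed,
    incidence = 100 * mean(subjects$ada_positive),
    threshold_ng_per_ml = threshold_ng_per_ml,
    alpha = alpha,
    seed = seed,
    schedule = schedule,
    drug_name = drug$name
  ), class = "ada_trial")
  result$comparison <- compare_pk(result, alpha = alpha)
  result
}

#' Dose-adjustment scan of the [ADA]:[Drug] ratio
#'
#' Runs three trials on the same population and sampling schedule: the
#' study regimen, twice the dose amount at the same interval
#' (`2xDose`), and the same dose at half the interval (`2xFreq`), and
#' reports the fraction of subjects whose [ADA]:[Drug] ratio exceeds 1
#' under each -- the model-informed screen for managing ADA by dose
#' adjustment.
#'
#' @inheritParams run_trial
#' @param base_regimen the study [regimen()].
#' @return data.frame with columns `regimen` (`"Study Dose"`,
#'   `"2xDose"`, `"2xFreq"`) and `fraction_ratio_gt_1`, with the three
#'   `ada_trial` objects attached as attribute `trials`.
#' @export
dose_adjustment_scan <- function(population, drug, base_regimen, schedule,
                                 seed = 1, ...) {
  stopifnot(inherits(base_regimen, "regimen"))
  double_dose <- regimen(base_regimen$dose_amount * 2,
                         base_regimen$dose_unit,
                         interval = base_regimen$interval,
                         n_doses = base_regimen$n_doses,
                         times = base_regimen$times, mtx = base_regimen$mtx)
  if (is.null(base_regimen$interval))
    stop("2xFreq scan requires an interval-based regimen")
  double_freq <- regimen(base_regimen$dose_amount, base_regimen$dose_unit,
                         interval = base_regimen$interval / 2,
                         n_doses = base_regimen$n_doses * 2,
                         mtx = base_regimen$mtx)
  regs <- list("Study Dose" = base_regimen, "2xDose" = double_dose,
               "2xFreq" = double_freq)
  trials <- lapply(regs, function(r)
    run_trial(population, drug, r, schedule, seed = seed, ...))
  out <- data.frame(
    regimen = names(regs),
    fraction_ratio_gt_1 = vapply(trials, function(tr)
      mean(tr$subjects$ratio > 1), 0),
    row.names = NULL)
  attr(out, "trials") <- trials
  out
}

#' @export
print.ada_trial <- function(x, ...) {
  cat(sprintf("<ada_trial> %s: %d subjects (%d failed)\n",
              x$drug_name, x$n, x$n_failed))
  cat(sprintf("  ADA incidence: %.1f%% (threshold %g ng/mL)\n",
              x$incidence, x$threshold_ng_per_ml))
  cat(sprintf("  exposure impact: %s (Wilcoxon p = %s)\n",
              x$comparison$verdict,
              ifelse(is.na(x$comparison$p_value), "NA",
                     format.pval(x$comparison$p_value, digits = 3))))
  cat(sprintf("  max [ADA]:[Drug] ratio: %.3g\n", max(x$subjects$ratio)))
  invisible(x)
}

#' @export
summary.ada_trial <- function(object, ...) {
  d <- object$subjects
  out <- list(
    drug = object$drug_name,
    n = object$n,
    n_failed = object$n_failed,
    incidence_pct = object$incidence,
    verdict = object$comparison$verdict,
    p_value = object$comparison$p_value,
    median_free_drug_pos = object$comparison$median_pos,
    median_free_drug_neg = object$comparison$median_neg,
    ratio_quantiles = stats::quantile(d$ratio, c(0, .25, .5, .75, 1)),
    fraction_ratio_gt_1 = mean(d$ratio > 1),
    seed = object$seed)
  class(out) <- "summary.ada_trial"
  out
}

#' @export
print.summary.ada_trial <- function(x, ...) {
  cat(sprintf("Virtual trial of %s (n = %d, %d solver failures)\n",
              x$drug, x$n, x$n_failed))
  cat(sprintf("  ADA incidence:        %.1f%%\n", x$incidence_pct))
  cat(sprintf("  exposure verdict:     %s (p = %s)\n", x$verdict,
              ifelse(is.na(x$p_value), "NA", format(x$p_value, digits = 3))))
  cat(sprintf("  median free drug:     ADA+ %.3g / ADA- %.3g nM\n",
              x$median_free_drug_pos, x$median_free_drug_neg))
  cat(sprintf("  [ADA]:[Drug] > 1:     %.1f%% of subjects\n",
              100 * x$fraction_ratio_gt_1))
  cat("  ratio quantiles:\n")
  print(signif(x$ratio_quantiles, 3))
  invisible(x)
}

#' Fingerprint plot of an ada_trial
#'
#' Free plasma drug at the final sampling time against the
#' [ADA]:[Drug] ratio (log-log axes); ADA-positive subjects in red,
#' negative in blue, and the paired PK-only concentrations in grey.
#' The dashed line marks a ratio of 1.
#'
#' @param x `ada_trial` object.
#' @param ratio_floor ratios below this are plotted as one group at the
#'   floor value.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ada_trial <- function(x, ratio_floor = 1e-3, ...) {
  d <- x$subjects
  r <- pmax(d$ratio, ratio_floor)
  col <- ifelse(d$ada_positive, "firebrick", "steelblue")
  graphics::plot(r, d$free_drug_final_full, log = "xy", col = col,
                 xlab = "[ADA]:[Drug] (molar)",
                 ylab = "free plasma drug at final time (nM)",
                 main = x$drug_name, ...)
  graphics::points(r, d$free_drug_final_pkonly, col = "grey60", pch = 3)
  graphics::abline(v = 1, lty = 2, col = "grey40")
  invisible(x)
}
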