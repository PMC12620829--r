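#' Aggregate HLA allele/haplotype frequencies across studies
#'
#' Weighted average of per-study allele (DRB1) or haplotype (DQ, DP)
#' frequencies with weights equal to study sample sizes, followed by a
#' per-locus renormalisation so that the listed specificities sum to 1.
#' An allele reported in one study but absent from another is treated
#' as frequency 0 in the study that omits it, with a warning.
#'
#' @param studies data.frame with columns `locus`, `allele`,
#'   `study_id`, `sample_size`, `frequency`.
#' @return object of class `hla_frequency_table`: a list with `loci`
#'   (named list of data.frames `allele`, `frequency`) and
#'   `provenance` (`study_id`, `sample_size`).
#' @export
aggregate_allele_frequencies <- function(studies) {
  stopifnot(is.data.frame(studies))
  need <- c("locus", "allele", "study_id", "sample_size", "frequency")
  miss <- setdiff(need, names(studies))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(studies$sample_size <= 0)) stop("sample sizes must be > 0")
  if (any(studies$frequency < 0 | studies$frequency > 1))
    stop("frequencies must be in [0, 1]")

  loci <- lapply(split(studies, studies$locus), function(d) {
    alleles <- unique(d$allele)
    sids <- unique(d$study_id)
    n_by_study <- vapply(sids, function(s)
      d$sample_size[match(s, d$study_id)], 0)
    raw <- vapply(alleles, function(a) {
      f <- vapply(sids, function(s) {
        v <- d$frequency[d$allele == a & d$study_id == s]
        if (!length(v)) NA_real_ else v[1]
      }, 0)
      if (anyNA(f) && length(sids) > 1)
        warning("allele ", a, " absent from some studies; treated as 0")
      f[is.na(f)] <- 0
      sum(f * n_by_study) / sum(n_by_study)
    }, 0)
    if (sum(raw) <= 0) stop("all-zero frequencies for a locus")
    data.frame(allele = alleles, frequency = raw / sum(raw),
               row.names = NULL)
  })
  structure(list(
    loci = loci,
    provenance = unique(studies[c("study_id", "sample_size")])
  ), class = "hla_frequency_table")
}

#' Sample HLA class II genotypes
#'
#' Two independent draws per locus per subject (with replacement, so
#' homozygosity is allowed) according to the table frequencies.
#'
#' @param table [aggregate_allele_frequencies()] result or
#'   [make_default_hla_table()].
#' @param n number of subjects (>= 1).
#' @param seed integer RNG seed.
#' @return data.frame with two columns per locus (`<locus>_1`,
#'   `<locus>_2`), one row per subject.
#' @export
sample_genotypes <- function(table, n, seed) {
  stopifnot(inherits(table, "hla_frequency_table"), n >= 1)
  if (!length(table$loci)) stop("frequency table has no loci")
  set.seed(seed)
  cols <- list()
  for (locus in names(table$loci)) {
    d <- table$loci[[locus]]
    if (!nrow(d)) stop("empty locus: ", locus)
    draws <- matrix(sample(d$allele, 2 * n, replace = TRUE,
                           prob = d$frequency), ncol = 2)
    cols[[paste0(locus, "_1")]] <- draws[, 1]
    cols[[paste0(locus, "_2")]] <- draws[, 2]
  }
  as.data.frame(cols, stringsAsFactors = FALSE)
}

#' Default lognormal physiology distributions
#'
#' Means mirror [physiology_parameters()] defaults; coefficients of
#' variation are modest between-subject values typical of healthy-adult
#' PBPK populations (assumed). Used by [generate_population()]; any
#' entry can be overridden, and `clearance_L_per_h` is usually supplied
#' from the drug configuration.
#'
#' @param clearance_mean,clearance_cv drug clearance distribution.
#' @return named list of `list(mean, cv)` entries.
#' @export
default_physiology_distributions <- function(clearance_mean = 0.01,
                                             clearance_cv = 0.3) {
  list(
    body_weight = list(mean = 70, cv = 0.15),
    V_plasma = list(mean = 3.0, cv = 0.1),
    V_lymph_node = list(mean = 0.28, cv = 0.1),
    V_tissue_vascular = list(mean = 2.6, cv = 0.1),
    V_tissue_endosomal = list(mean = 0.45, cv = 0.1),
    V_tissue_interstitial = list(mean = 15.6, cv = 0.1),
    Q_blood = list(mean = 120, cv = 0.1),
    Q_lymph = list(mean = 0.121, cv = 0.15),
    clearance_L_per_h = list(mean = clearance_mean, cv = clearance_cv)
  )
}

#' Monte Carlo sampling of lognormal physiological parameters
#'
#' Each parameter is drawn from a lognormal distribution parameterised
#' so that the arithmetic mean equals the configured mean and the
#' coefficient of variation equals the configured CV (`sdlog^2 =
#' log(1 + cv^2)`, `meanlog = log(mean) - sdlog^2 / 2`); a CV of 0
#' yields the mean deterministically.
#'
#' @param distributions named list of `list(mean, cv)`; see
#'   [default_physiology_distributions()].
#' @param n number of subjects.
#' @param seed integer RNG seed.
#' @return list with `physiology` (list of [physiology_parameters()])
#'   and `clearance` (numeric vector, L/h).
#' @export
sample_physiology <- function(distributions, n, seed) {
  set.seed(seed)
  draws <- lapply(distributions, function(dpar) {
    if (dpar$mean <= 0) stop("distribution means must be > 0")
    if (dpar$cv < 0) stop("negative CV")
    if (dpar$cv == 0) return(rep(dpar$mean, n))
    sdlog <- sqrt(log(1 + dpar$cv^2))
    stats::rlnorm(n, meanlog = log(dpar$mean) - sdlog^2 / 2, sdlog = sdlog)
  })
  phys_fields <- setdiff(names(distributions), "clearance_L_per_h")
  physiology <- lapply(seq_len(n), function(i) {
    args <- lapply(draws[phys_fields], `[[`, i)
    # guard the Q_lymph < Q_blood invariant under independent sampling
    if (!is.null(args$Q_lymph) && !is.null(args$Q_blood) &&
        args$Q_lymph >= args$Q_blood)
      args$Q_lymph <- 0.9 * args$Q_blood
    do.call(physiology_parameters, args)
  })
  clearance <- if ("clearance_L_per_h" %in% names(distributions))
    draws$clearance_L_per_h else rep(NA_real_, n)
  list(physiology = physiology, clearance = clearance)
}

#' Generate a virtual population
#'
#' Samples `n` virtual subjects with independent physiology, drug
#' clearance and HLA class II genotype, plus a derived per-subject RNG
#' seed for downstream stochastic steps. Regenerating with the same
#' master seed reproduces the population element-wise.
#'
#' @param n number of subjects; the default trial size is 250.
#' @param table HLA frequency table.
#' @param distributions physiology/clearance distributions, see
#'   [default_physiology_distributions()].
#' @param seed master integer seed.
#' @return object of class `virtual_population`: list of subjects, each
#'   with `id`, `physiology`, `clearance`, `genotype` (character vector
#'   of 6 allele names), `genotype_by_locus`, `rng_seed`.
#' @export
generate_population <- function(n = 250, table = make_default_hla_table(),
                                distributions = default_physiology_distributions(),
                                seed = 1) {
  if (n < 1) stop("n must be >= 1")
  geno <- sample_genotypes(table, n, seed = seed)
  ph <- sample_physiology(distributions, n, seed = seed + 1L)
  set.seed(seed + 2L)
  sub_seeds <- sample.int(.Machine$integer.max, n)
  loci <- names(table$loci)
  subjects <- lapply(seq_len(n), function(i) {
    by_locus <- lapply(loci, function(l)
      c(geno[[paste0(l, "_1")]][i], geno[[paste0(l, "_2")]][i]))
    names(by_locus) <- loci
    if (!is.na(ph$clearance[i]) && ph$clearance[i] <= 0)
      stop("non-positive clearance draw")
    list(id = i,
         physiology = ph$physiology[[i]],
         clearance = ph$clearance[i],
         genotype = unlist(by_locus, use.names = FALSE),
         genotype_by_locus = by_locus,
         rng_seed = sub_seeds[i])
  })
  structure(list(subjects = subjects, n = n, seed = seed),
            class = "virtual_population")
}

#' @export
print.virtual_population <- function(x, ...) {
  cat(sprintf("<virtual_population> %d subjects (master seed %s)\n",
              x$n, format(x$seed)))
  invisible(x)
}

#' @export
as.data.frame.virtual_population <- function(x, ...) {
  do.call(rbind, lapply(x$subjects, function(s) {
    g <- unlist(s$genotype_by_locus)
    data.frame(id = s$id, body_weight = s$physiology$body_weight,
               V_plasma = s$physiology$V_plasma,
               clearance_L_per_h = s$clearance,
               t(g), stringsAsFactors = FALSE, check.names = FALSE)
  }))
}

#' Read an allele-frequency TSV and aggregate it
#'
#' Expects columns `locus`, `allele`, `study_id`, `sample_size`,
#' `frequency`.
#'
#' @param path TSV path.
#' @return `hla_frequency_table`.
#' @export
read_hla_table <- function(path) {
  aggregate_allele_frequencies(utils::read.delim(path, stringsAsFactors = FALSE))
}
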