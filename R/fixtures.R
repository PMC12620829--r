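#' Synthetic toy proteome
#'
#' Reproducible random amino-acid FASTA records standing in for a
#' self-proteome in tests and examples (the real human reference
#' proteome is an external download). A given 15-mer can be spiked into
#' a chosen record to exercise the self-filter.
#'
#' @param n_records number of records (>= 0).
#' @param record_length residues per record.
#' @param seed integer RNG seed.
#' @param spike optional 15-mer to embed.
#' @param spike_into index of the record receiving the spike.
#' @return named character vector of sequences.
#' @export
make_toy_proteome <- function(n_records, record_length = 80, seed = 1,
                              spike = NULL, spike_into = 1) {
  if (n_records < 0) stop("n_records must be >= 0")
  if (!is.null(spike) && record_length < nchar(spike))
    stop("record_length too short for the requested spike")
  if (n_records == 0) return(stats::setNames(character(0), character(0)))
  set.seed(seed)
  seqs <- vapply(seq_len(n_records), function(i)
    paste(sample(AA_CODES, record_length, replace = TRUE), collapse = ""), "")
  if (!is.null(spike)) {
    s <- seqs[spike_into]
    at <- sample.int(nchar(s) - nchar(spike) + 1, 1)
    substr(s, at, at + nchar(spike) - 1) <- spike
    seqs[spike_into] <- s
  }
  stats::setNames(seqs, sprintf("SYNPROT%03d", seq_len(n_records)))
}

#' Synthetic elution-rank table
#'
#' Complete (peptide x allele) table of percentile elution ranks for a
#' named risk scenario: `high_risk` ranks lie in (0.1, 2] (strong
#' predicted presentation), `low_risk` ranks in [20, 100] (weak
#' presentation). Within each band the table is allele-structured, as
#' real class II predictions are: a minority of "presenter" alleles
#' carry the strongest ranks of the band for most peptides while the
#' remaining alleles sit near its weak end, so a subject's predicted
#' presentation load depends on which alleles they carry.
#'
#' @param peptides,alleles non-empty character vectors.
#' @param scenario `"high_risk"` or `"low_risk"`.
#' @param seed integer RNG seed.
#' @param presenter_fraction fraction of alleles drawn as strong
#'   presenters of the band.
#' @return data.frame with columns `peptide`, `allele`, `el_rank`.
#' @export
make_rank_table <- function(peptides, alleles,
                            scenario = c("high_risk", "low_risk"),
                            seed = 1, presenter_fraction = 0.3) {
  scenario <- match.arg(scenario)
  if (!length(peptides) || !length(alleles))
    stop("peptides and alleles must be non-empty")
  set.seed(seed)
  presenter <- stats::runif(length(alleles)) < presenter_fraction
  names(presenter) <- alleles
  g <- expand.grid(peptide = peptides, allele = alleles,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(g)
  pres <- presenter[g$allele]
  if (scenario == "high_risk") {
    base <- ifelse(pres,
                   10^stats::runif(n, log10(0.112), log10(0.25)),
                   10^stats::runif(n, log10(1.45), log10(1.95)))
    g$el_rank <- pmin(pmax(base * stats::runif(n, 0.92, 1.08), 0.101), 2)
  } else {
    base <- ifelse(pres, stats::runif(n, 20, 28), stats::runif(n, 55, 100))
    g$el_rank <- pmin(pmax(base + stats::runif(n, -4, 4), 20), 100)
  }
  g
}

#' Default HLA class II locus definition
#'
#' Placeholder frequency table mirroring the structure of the IEDB HLA
#' class II reference set: 11 DRB1 alleles, 6 DQ and 6 DP haplotypes,
#' with synthetic per-locus frequencies summing to 1. Names follow
#' standard nomenclature shape but the frequencies are seeded
#' placeholders, not population estimates; supply a real
#' allele-frequency TSV via [read_hla_table()] for population work.
#'
#' @param seed integer RNG seed for the placeholder frequencies.
#' @return `hla_frequency_table`.
#' @export
make_default_hla_table <- function(seed = 20250) {
  drb1 <- paste0("DRB1*", c("01:01", "03:01", "04:01", "04:05", "07:01",
                            "08:02", "09:01", "11:01", "12:01", "13:02",
                            "15:01"))
  dq <- c("DQA1*05:01-DQB1*02:01", "DQA1*05:01-DQB1*03:01",
          "DQA1*03:01-DQB1*03:02", "DQA1*04:01-DQB1*04:02",
          "DQA1*01:01-DQB1*05:01", "DQA1*01:02-DQB1*06:02")
  dp <- c("DPA1*02:01-DPB1*01:01", "DPA1*01:03-DPB1*02:01",
          "DPA1*01:03-DPB1*04:01", "DPA1*03:01-DPB1*04:02",
          "DPA1*02:01-DPB1*05:01", "DPA1*02:01-DPB1*14:01")
  set.seed(seed)
  mk <- function(alleles) {
    w <- stats::rgamma(length(alleles), shape = 2)
    data.frame(allele = alleles, frequency = w / sum(w), row.names = NULL)
  }
  structure(list(
    loci = list(DRB1 = mk(drb1), DQ = mk(dq), DP = mk(dp)),
    provenance = data.frame(study_id = "synthetic_placeholder",
                            sample_size = 1000)
  ), class = "hla_frequency_table")
}

#' Named synthetic drug scenarios
#'
#' Fully self-contained, seeded end-to-end inputs standing in for
#' compound-specific study packages: a synthetic antibody sequence, toy
#' self-proteome, elution-rank table, HLA frequency table, drug
#' configuration with epitopes selected through the sequence pipeline,
#' dosing regimen and sampling schedule.
#'
#' * `high_risk_drug`: strongly presented epitopes (all best ranks
#'   <= 2), 100 mg SC every two weeks.
#' * `low_risk_drug`: weakly presented epitopes (best ranks >= 20),
#'   300 mg SC every two weeks (a high-exposure regimen).
#' * `no_epitope_drug`: empty epitope list; never seroconverts.
#'
#' @param name scenario name (`"high_risk_drug"`, `"low_risk_drug"`,
#'   `"no_epitope_drug"`; the shorthand forms without `_drug` are also
#'   accepted).
#' @param seed integer seed controlling the synthetic sequence and rank
#'   draws.
#' @return list with `drug`, `regimen`, `schedule`, `hla_table`,
#'   `rank_table`, `proteome`, `sequence`, `name`.
#' @export
fixture_scenario <- function(name = c("high_risk_drug", "low_risk_drug",
                                      "no_epitope_drug", "high_risk",
                                      "low_risk", "no_epitope"),
                             seed = 101) {
  name <- match.arg(name)
  name <- sub("_drug$", "", name)
  set.seed(seed)
  sequence <- paste(sample(AA_CODES, 89, replace = TRUE), collapse = "")
  proteome <- make_toy_proteome(20, 80, seed = seed + 1)
  hla <- make_default_hla_table()
  alleles <- unlist(lapply(hla$loci, function(d) d$allele), use.names = FALSE)

  cand <- filter_self(enumerate_candidates(sequence = sequence), proteome)
  rank_scn <- if (name == "low_risk") "low_risk" else "high_risk"
  # strongly presented epitopes are restricted to few alleles; weak
  # presentation is spread over more of the reference set
  rank_table <- make_rank_table(cand$peptide, alleles, rank_scn,
                                seed = seed + 2,
                                presenter_fraction =
                                  if (rank_scn == "high_risk") 0.13 else 0.3)
  epitopes <- if (name == "no_epitope") list() else
    select_epitopes(cand, rank_table, max_n = 5)

  drug <- switch(name,
    high_risk = drug_parameters(
      name = "synthetic high-risk mAb", molecular_weight = 150000,
      clearance_mean = 0.010, clearance_cv = 0.3, route = "SC",
      bioavailability = 0.70, ka = 0.012, dc_uptake = 1,
      naive_t_fraction = 1e-5, epitopes = epitopes),
    low_risk = drug_parameters(
      name = "synthetic low-risk mAb", molecular_weight = 149000,
      clearance_mean = 0.008, clearance_cv = 0.3, route = "SC",
      bioavailability = 0.75, ka = 0.012, dc_uptake = 1,
      naive_t_fraction = 5e-5, epitopes = epitopes),
    no_epitope = drug_parameters(
      name = "synthetic non-immunogenic mAb", molecular_weight = 150000,
      clearance_mean = 0.010, clearance_cv = 0.3, route = "SC",
      bioavailability = 0.70, ka = 0.012, dc_uptake = 1,
      naive_t_fraction = 1e-5, epitopes = list()))

  dose <- if (name == "low_risk") 300 else 100
  reg <- regimen(dose, "mg", interval = 336, n_doses = 6)
  sched <- sampling_schedule(ada_times = seq(336, 2016, by = 336))

  list(name = paste0(name, "_drug"), drug = drug, regimen = reg,
       schedule = sched, hla_table = hla, rank_table = rank_table,
       proteome = proteome, sequence = sequence)
}

#' Write a ready-to-run scenario directory
#'
#' Materialises a [fixture_scenario()] as plain-text files: FASTA
#' sequence and proteome, TSV rank and HLA tables, YAML drug/trial/
#' population configs, plus a run manifest.
#'
#' @param name scenario name, see [fixture_scenario()].
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return `dir`, invisibly.
#' @export
write_scenario_dir <- function(name, dir, seed = 101) {
  scn <- fixture_scenario(name, seed = seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(stats::setNames(scn$sequence, "synthetic_drug_sequence"),
              file.path(dir, "sequence.fasta"))
  write_fasta(scn$proteome, file.path(dir, "proteome.fasta"))
  # a drug without epitopes ships no rank table: the simulate/scan
  # commands derive the epitope list from sequence + ranks when present
  if (length(scn$drug$epitopes))
    write_table_stable(scn$rank_table, file.path(dir, "ranks.tsv"),
                       sep = "\t")
  hla_rows <- do.call(rbind, lapply(names(scn$hla_table$loci), function(l) {
    d <- scn$hla_table$loci[[l]]
    data.frame(locus = l, allele = d$allele,
               study_id = "synthetic_placeholder", sample_size = 1000,
               frequency = d$frequency)
  }))
  write_table_stable(hla_rows, file.path(dir, "hla.tsv"), sep = "\t")
  d <- scn$drug
  yaml::write_yaml(list(drug = list(
    name = d$name, molecular_weight_g_per_mol = d$molecular_weight,
    clearance_L_per_h = d$clearance_mean, clearance_cv = d$clearance_cv,
    route = d$route, bioavailability = d$bioavailability,
    ka_per_h = d$ka, dc_uptake = d$dc_uptake,
    naive_t_fraction = d$naive_t_fraction
  )), file.path(dir, "drug.yaml"))
  yaml::write_yaml(list(trial = list(
    regimen = list(dose_mg = scn$regimen$dose_amount,
                   interval_h = scn$regimen$interval,
                   n_doses = scn$regimen$n_doses),
    schedule = list(ada_times_h = scn$schedule$ada_times,
                    pk_times_h = scn$schedule$pk_times,
                    final_time_h = scn$schedule$final_time),
    ada_threshold_ng_per_ml = 100, alpha = 0.05
  )), file.path(dir, "trial.yaml"))
  yaml::write_yaml(list(population = list(n = 250)),
                   file.path(dir, "population.yaml"))
  write_manifest(dir, seed = seed,
                 config_paths = file.path(dir, c("drug.yaml", "trial.yaml",
                                                 "population.yaml")),
                 stage = "fixtures")
  invisible(dir)
}

#' Virtual population matched to a fixture scenario
#'
#' Convenience wrapper generating a [generate_population()] for a
#' scenario: the scenario's HLA table and physiology defaults with the
#' drug's clearance distribution.
#'
#' @param scenario list from [fixture_scenario()].
#' @param n number of subjects.
#' @param seed master seed.
#' @return `virtual_population`.
#' @export
scenario_population <- function(scenario, n = 250, seed = 1) {
  generate_population(
    n = n, table = scenario$hla_table,
    distributions = default_physiology_distributions(
      clearance_mean = scenario$drug$clearance_mean,
      clearance_cv = scenario$drug$clearance_cv),
    seed = seed)
}
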