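test_that("epitope activation signal matches hand arithmetic and limits", {
  base <- list(ID_m = 100, Ttot = 300, dc_uptake = 1, AgVS = 1,
               elution_ranks = 10, K_Ag_N = 81)
  expect_equal(epitope_activation_signal(base), 0.125)
  expect_equal(epitope_activation_signal(modifyList(base, list(AgVS = 0))), 0)
  expect_equal(epitope_activation_signal(
    modifyList(base, list(elution_ranks = c(100, 100)))), 0)
  expect_equal(epitope_activation_signal(
    modifyList(base, list(ID_m = 0, Ttot = 0))), 0)
  expect_error(epitope_activation_signal(
    modifyList(base, list(elution_ranks = 0))), "EL_rank")
  expect_error(epitope_activation_signal(
    modifyList(base, list(elution_ranks = 101))), "EL_rank")
  expect_error(epitope_activation_signal(
    modifyList(base, list(K_Ag_N = 0))), "K_Ag_N")
})

test_that("activation signal is bounded and monotone (randomised)", {
  set.seed(7)
  for (i in 1:50) {
    inp <- list(ID_m = runif(1, 0, 1e4), Ttot = runif(1, 0, 1e4),
                dc_uptake = runif(1, 0, 5), AgVS = runif(1, 0, 500),
                elution_ranks = runif(sample(1:6, 1), 0.1, 100),
                K_Ag_N = 10^runif(1, 0, 8))
    d0 <- epitope_activation_signal(inp)
    expect_gte(d0, 0); expect_lte(d0, 1)
    up <- epitope_activation_signal(modifyList(inp, list(AgVS = inp$AgVS * 2)))
    expect_gte(up, d0)
    upu <- epitope_activation_signal(
      modifyList(inp, list(dc_uptake = inp$dc_uptake * 2)))
    expect_gte(upu, d0)
    worse <- epitope_activation_signal(modifyList(inp, list(
      elution_ranks = pmin(inp$elution_ranks * 1.5, 100))))
    expect_lte(worse, d0 + 1e-12)
  }
})

test_that("allele sets collapse homozygous loci and ignore missing ranks", {
  ep <- list(peptide = strrep("A", 15), start = 1,
             ranks = c("DRB1*01:01" = 10, "DRB1*15:01" = 50),
             best_rank = 10)
  w_het <- adasim:::epitope_weights(list(ep),
                                    c("DRB1*01:01", "DRB1*15:01"))
  w_hom <- adasim:::epitope_weights(list(ep),
                                    c("DRB1*01:01", "DRB1*01:01"))
  expect_equal(w_hom, (100 / 10 - 1)^2)
  expect_equal(w_het, (100 / 10 - 1)^2 + (100 / 50 - 1)^2)
  # allele with no tabulated rank contributes nothing
  w_missing <- adasim:::epitope_weights(list(ep), c("DQB1*06:02"))
  expect_equal(w_missing, 0)
})

test_that("system decouples exactly without epitopes or uptake", {
  sc <- hi_scenario()
  s <- hi_subject()
  tg <- seq(24, 2016, 48)
  pk <- simulate_pk_only(sc$drug, s$physiology, sc$regimen, tg,
                         clearance = s$clearance)
  d0 <- sc$drug; d0$epitopes <- list()
  full0 <- simulate_subject(d0, s$physiology, sc$regimen, tg,
                            clearance = s$clearance, genotype = s$genotype)
  expect_identical(full0$conc_nM, pk$conc_nM)
  expect_true(all(full0$ada_total_nM == 0))
  # immune states stay at their initial conditions
  expect_true(all(full0$immune[, "NT"] == full0$immune[1, "NT"]))
  du <- sc$drug; du$dc_uptake <- 0
  fullu <- simulate_subject(du, s$physiology, sc$regimen, tg,
                            clearance = s$clearance, genotype = s$genotype)
  expect_identical(fullu$conc_nM, pk$conc_nM)
})

test_that("immune-off switch reproduces the PK-only run bit for bit", {
  sc <- hi_scenario()
  s <- hi_subject()
  tg <- seq(24, 2016, 48)
  off <- simulate_subject(sc$drug, s$physiology, sc$regimen, tg,
                          immune_on = FALSE, clearance = s$clearance,
                          genotype = s$genotype)
  pk <- simulate_pk_only(sc$drug, s$physiology, sc$regimen, tg,
                         clearance = s$clearance)
  expect_identical(off$conc_nM, pk$conc_nM)
})

test_that("a huge activation constant suppresses ADA toward the PK-only limit", {
  sc <- hi_scenario()
  s <- hi_subject()
  tg <- seq(24, 2016, 48)
  pk <- simulate_pk_only(sc$drug, s$physiology, sc$regimen, tg,
                         clearance = s$clearance)
  big <- simulate_subject(sc$drug, s$physiology, sc$regimen, tg,
                          clearance = s$clearance, genotype = s$genotype,
                          rates = immune_rates(k_ag_n = 1e12))
  expect_lt(max(abs(big$conc_nM[, "plasma"] / pk$conc_nM[, "plasma"] - 1)),
            1e-3)
})

test_that("free drug plus complex is conserved without clearance", {
  sc <- hi_scenario()
  s <- hi_subject()
  tg <- seq(24, 2016, 24)
  tr <- simulate_subject(sc$drug, s$physiology, sc$regimen, tg,
                         clearance = 0, genotype = s$genotype,
                         rates = immune_rates(k_ic = 0))
  expect_gt(max(tr$complex_nM), 0)  # binding actually occurred
  total <- rowSums(tr$amounts_nmol) +
    tr$complex_nM * s$physiology$V_plasma
  # running total must equal the amount administered so far
  dose_amt <- sc$drug$bioavailability * mg_to_nmol(100, 150000)
  # sampling at a dose time is pre-dose, so count doses strictly before
  n_given <- vapply(tg, function(t) sum(sc$regimen$times < t), 0L)
  expect_lt(max(abs(total / (n_given * dose_amt) - 1)), 1e-6)
})

test_that("methotrexate co-medication never increases total ADA", {
  sc <- hi_scenario()
  s <- hi_subject()
  tg <- seq(24, 2016, 48)
  reg_mtx <- regimen(100, "mg", interval = 336, n_doses = 6,
                     mtx = mtx_regimen(15, 168, 12))
  t0 <- simulate_subject(sc$drug, s$physiology, sc$regimen, tg,
                         clearance = s$clearance, genotype = s$genotype)
  tm <- simulate_subject(sc$drug, s$physiology, reg_mtx, tg,
                         clearance = s$clearance, genotype = s$genotype)
  expect_true(all(tm$ada_total_nM <= t0$ada_total_nM * (1 + 1e-8) + 1e-12))
})

test_that("compiled and R reference right-hand sides agree", {
  sc <- hi_scenario()
  s <- hi_subject()
  tg <- seq(24, 2016, 48)
  reg <- regimen(100, "mg", interval = 336, n_doses = 6,
                 mtx = mtx_regimen(15, 168, 12))
  tC <- simulate_subject(sc$drug, s$physiology, reg, tg,
                         clearance = s$clearance, genotype = s$genotype)
  tR <- simulate_subject(sc$drug, s$physiology, reg, tg,
                         clearance = s$clearance, genotype = s$genotype,
                         control = list(engine = "R"))
  rel <- function(a, b) max(abs(a - b) / (abs(a) + 1e-9))
  expect_lt(rel(tC$conc_nM[, "plasma"], tR$conc_nM[, "plasma"]), 1e-6)
  expect_lt(rel(tC$ada_total_nM, tR$ada_total_nM), 1e-6)
  expect_lt(rel(tC$immune[, "AT"], tR$immune[, "AT"]), 1e-5)
})

test_that("build_coupled_system returns a working subject simulator", {
  sc <- hi_scenario()
  s <- hi_subject()
  sim <- build_coupled_system(sc$drug, s$physiology,
                              genotype = s$genotype,
                              clearance = s$clearance)
  tr <- sim(sc$regimen, seq(336, 2016, 336))
  expect_s3_class(tr, "subject_trajectory")
  pk <- sim(sc$regimen, seq(336, 2016, 336), immune_on = FALSE)
  expect_true(all(pk$ada_total_nM == 0))
})
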