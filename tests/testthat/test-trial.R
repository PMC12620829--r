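test_that("ADA positivity requires a strict exceedance at a sampled time", {
  times <- c(100, 200, 300)
  # exactly at threshold at samples, higher only between them
  tr <- make_traj(c(times, 250), plasma_nM = rep(10, 4),
                  ada_total_nM = c(ng_per_ml_to_nM(100, 150000),
                                   ng_per_ml_to_nM(100, 150000),
                                   ng_per_ml_to_nM(100, 150000),
                                   ng_per_ml_to_nM(150, 150000)))
  expect_false(classify_ada(tr, times))
  tr2 <- make_traj(times, rep(10, 3),
                   ng_per_ml_to_nM(c(90, 150, 80), 150000))
  expect_true(classify_ada(tr2, times))
  tr0 <- make_traj(times, rep(10, 3), rep(0, 3))
  expect_false(classify_ada(tr0, times))
  expect_error(classify_ada(tr2, times, threshold_ng_per_ml = 0), "> 0")
  expect_error(classify_ada(tr2, c(times, 999)), "subset")
})

test_that("rank-sum p-values match enumeration and handle degenerate input", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(wilcoxon_rank_sum(rep(5, 4), rep(5, 3)), 1.0)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")

  # exact p equals full permutation enumeration for all n_total <= 10
  set.seed(42)
  for (i in 1:12) {
    n <- sample(1:5, 1); m <- sample(1:5, 1)
    x <- sample(seq(0, 1, by = 1e-4), n)
    y <- sample(seq(2, 3, by = 1e-4), m) - runif(1, 0, 2.5)
    expect_equal(wilcoxon_rank_sum(x, y), perm_rank_sum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("the molar ADA to drug ratio converts units correctly", {
  times <- c(336, 672)
  sched <- sampling_schedule(times)
  # equal molar: 150 ug/mL ADA (150 kDa) vs 150 ug/mL drug
  full <- make_traj(times, rep(1, 2),
                    c(0, ug_per_ml_to_nM(150, 150000)))
  pk <- make_traj(times, rep(ug_per_ml_to_nM(150, 150000), 2), rep(0, 2),
                  mode = "pk_only")
  expect_equal(ada_drug_ratio(full, pk, sched), 1.0)

  # 30 ug/mL at 150 kDa (200 nM) vs 10 ug/mL at 100 kDa (100 nM) -> 2
  full2 <- make_traj(times, rep(1, 2), c(0, ug_per_ml_to_nM(30, 150000)))
  pk2 <- make_traj(times, rep(ug_per_ml_to_nM(10, 100000), 2), rep(0, 2))
  expect_equal(ada_drug_ratio(full2, pk2, sched), 2.0)

  # zero ADA -> 0; zero PK-only drug -> Inf with a flag
  full0 <- make_traj(times, rep(1, 2), rep(0, 2))
  expect_equal(ada_drug_ratio(full0, pk, sched), 0)
  pk0 <- make_traj(times, rep(0, 2), rep(0, 2))
  r <- ada_drug_ratio(full2, pk0, sched)
  expect_true(is.infinite(r))
  expect_equal(attr(r, "flag"), "zero_drug")
})

test_that("exposure-impact verdicts follow the group rules", {
  mk <- function(pos_vals, neg_vals) make_trial(data.frame(
    ada_positive = c(rep(TRUE, length(pos_vals)),
                     rep(FALSE, length(neg_vals))),
    free_drug_final_full = c(pos_vals, neg_vals)))
  expect_equal(compare_pk(mk(numeric(0), 1:10))$verdict, "not_assessable")
  expect_equal(compare_pk(mk(5, 1:10))$verdict, "not_assessable")
  expect_equal(compare_pk(mk(1:10, 1:10))$verdict, "no_impact")
  # extreme shift: positives at 1% of negative values
  set.seed(1)
  neg <- rlnorm(230, log(100), 0.2)
  pos <- 0.01 * sample(neg, 20)
  out <- compare_pk(mk(pos, neg))
  expect_equal(out$verdict, "impact")
  expect_lt(out$p_value, 1e-10)
  # a significant INCREASE is not an impact
  out2 <- compare_pk(mk(neg * 100, neg))
  expect_equal(out2$verdict, "no_impact")
})

test_that("trials pair full and PK-only runs on identical parameters", {
  sc <- hi_scenario()
  pop <- small_population(sc, n = 8)
  tr <- run_trial(pop, sc$drug, sc$regimen, sc$schedule, seed = 1)
  expect_equal(nrow(tr$subjects), 8)
  s <- pop$subjects[[3]]
  pk <- simulate_pk_only(sc$drug, s$physiology, sc$regimen,
                         sort(unique(c(sc$schedule$ada_times,
                                       sc$schedule$pk_times))),
                         clearance = s$clearance)
  fidx <- match(sc$schedule$final_time, pk$times)
  expect_equal(tr$subjects$free_drug_final_pkonly[3],
               unname(pk$conc_nM[fidx, "plasma"]))
  # every ADA-positive subject exceeded the threshold by construction
  pos <- tr$subjects[tr$subjects$ada_positive, ]
  expect_true(all(pos$max_ada_ng_per_ml > tr$threshold_ng_per_ml))
})

test_that("disabling the immune module gives zero incidence and zero ratios", {
  sc <- hi_scenario()
  pop <- small_population(sc, n = 6)
  tr <- run_trial(pop, sc$drug, sc$regimen, sc$schedule, immune_on = FALSE)
  expect_equal(tr$incidence, 0)
  expect_true(all(tr$subjects$ratio == 0))
  expect_equal(tr$comparison$verdict, "not_assessable")
  scan <- dose_adjustment_scan(pop, sc$drug, sc$regimen, sc$schedule,
                               immune_on = FALSE)
  expect_equal(scan$fraction_ratio_gt_1, rep(0, 3))
})

test_that("dose scans report exactly three labelled regimens", {
  sc <- hi_scenario()
  pop <- small_population(sc, n = 6)
  scan <- dose_adjustment_scan(pop, sc$drug, sc$regimen, sc$schedule)
  expect_equal(scan$regimen, c("Study Dose", "2xDose", "2xFreq"))
  expect_true(all(scan$fraction_ratio_gt_1 >= 0 &
                    scan$fraction_ratio_gt_1 <= 1))
  trials <- attr(scan, "trials")
  expect_length(trials, 3)
  # 2xDose doubles the per-dose amount; 2xFreq halves the interval
  expect_equal(trials[["2xDose"]]$n, 6)
})

test_that("trial results are reproducible and summarise cleanly", {
  sc <- hi_scenario()
  pop <- small_population(sc, n = 6)
  t1 <- run_trial(pop, sc$drug, sc$regimen, sc$schedule, seed = 4)
  t2 <- run_trial(pop, sc$drug, sc$regimen, sc$schedule, seed = 4)
  expect_identical(t1$subjects, t2$subjects)
  s <- summary(t1)
  expect_s3_class(s, "summary.ada_trial")
  expect_output(print(t1), "ADA incidence")
  expect_output(print(s), "exposure verdict")
  tf <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tf); plot(t1); grDevices::dev.off()
  expect_true(file.exists(tf))
})

test_that("sampling schedules validate their final time", {
  expect_error(sampling_schedule(c(100, 200), final_time = 150), "final_time")
  sch <- sampling_schedule(c(200, 100))
  expect_equal(sch$ada_times, c(100, 200))
  expect_equal(sch$final_time, 200)
  expect_error(sampling_schedule(c(-5, 10)), ">= 0")
})
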