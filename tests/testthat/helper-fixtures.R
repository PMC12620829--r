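# Shared fixtures: scenarios and small populations are built once per
# test run; heavier trial results are memoised on first use.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

hi_scenario <- function() cached("hi", fixture_scenario("high_risk_drug"))
lo_scenario <- function() cached("lo", fixture_scenario("low_risk_drug"))

small_population <- function(scenario, n = 12, seed = 1) {
  cached(paste0("pop_", scenario$name, "_", n, "_", seed),
         scenario_population(scenario, n = n, seed = seed))
}

# one high-risk subject (a strong responder) and its simulation inputs
hi_subject <- function(i = 2) {
  sc <- hi_scenario()
  pop <- small_population(sc)
  pop$subjects[[i]]
}

# brute-force two-sided rank-sum p-value by enumerating all group
# assignments (independent oracle for the Wilcoxon test)
perm_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  idx <- utils::combn(length(pooled), n)
  stats <- apply(idx, 2, function(i) sum(r[i]))
  obs <- sum(r[seq_len(n)])
  mu <- n * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}

# minimal subject_trajectory for unit tests of trial metrics
make_traj <- function(times, plasma_nM, ada_total_nM,
                      mode = "full") {
  conc <- cbind(plasma = plasma_nM, lymph_node = 0, tissue_vascular = 0,
                tissue_endosomal = 0, tissue_interstitial = 0)
  structure(list(times = times, conc_nM = conc,
                 amounts_nmol = matrix(0, length(times), 6),
                 immune = matrix(0, length(times), 10),
                 ada_free_nM = ada_total_nM,
                 complex_nM = rep(0, length(times)),
                 ada_total_nM = ada_total_nM,
                 mode = mode, subject_id = 1, drug_name = "test"),
            class = "subject_trajectory")
}

# fake ada_trial carrying only the per-subject table (for compare_pk)
make_trial <- function(subjects) {
  structure(list(subjects = subjects), class = "ada_trial")
}
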