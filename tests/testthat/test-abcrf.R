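# Small shared fixtures: an indistinguishable pair (same generating process
# under two labels) and a separable pair (panmixia vs deep split).
same_pair_reftable <- function(n = 250, seed = 30) {
  mk <- function(lab) scenario(lab, list(A = deme(800, 6), B = deme(800, 6)),
                               list(ev_merge(400, "B", "A")))
  build_reference_table(list(mk("twin1"), mk("twin2")),
                        prior_set(list(dummy = prior_unif(0, 1))),
                        n, sumstat_schema(c("A", "B")), n_loci = 100,
                        seed = seed)
}

separable_reftable <- function(n = 400, seed = 31) {
  pan <- scenario("panmixia", list(A = deme(1000, 6), B = deme(1000, 6)),
                  list(ev_merge(0.001, "B", "A")))
  deep <- scenario("deepsplit", list(A = deme(1000, 6), B = deme(1000, 6)),
                   list(ev_merge(4000, "B", "A")))
  list(rt = build_reference_table(list(pan, deep),
                                  prior_set(list(dummy = prior_unif(0, 1))),
                                  n, sumstat_schema(c("A", "B")),
                                  n_loci = 100, seed = seed),
       pan = pan, deep = deep)
}

test_that("indistinguishable scenarios give chance-level OOB error and split votes", {
  rt <- same_pair_reftable()
  clf <- train_model_choice(rt, n_trees = 500, seed = 32)
  expect_true(abs(clf$oob_error - 0.5) < 0.05)
  twin <- scenario("twin1", list(A = deme(800, 6), B = deme(800, 6)),
                   list(ev_merge(400, "B", "A")))
  pm <- scenario_popmap(twin)
  sch <- sumstat_schema(c("A", "B"))
  fracs <- withr::with_seed(33, vapply(1:10, function(i) {
    obs <- summary_vector(simulate_snps(twin, n_loci = 100, maf_min = 0.05),
                          pm, sch)
    res <- classify_observed(clf, obs)
    expect_equal(sum(res$votes), 500)
    expect_true(res$posterior_prob >= 0 && res$posterior_prob <= 1)
    res$votes[1] / 500
  }, numeric(1)))
  # vote symmetry holds on average over observed datasets
  expect_lt(abs(mean(fracs) - 0.5), 0.1)
})

test_that("separable scenarios are learned: low OOB error, stable in trees, self-consistent", {
  sep <- separable_reftable()
  errs <- vapply(c(100, 500, 1000), function(nt)
    train_model_choice(sep$rt, n_trees = nt, seed = 34)$oob_error, numeric(1))
  expect_lt(errs[3], 0.05)
  expect_true(all(diff(errs) <= 0.02))   # non-increasing within tolerance
  clf <- train_model_choice(sep$rt, n_trees = 500, seed = 35)
  pm <- scenario_popmap(sep$deep)
  sch <- sumstat_schema(c("A", "B"))
  hits <- 0
  withr::with_seed(36, {
    for (r in 1:100) {
      obs <- summary_vector(simulate_snps(sep$deep, n_loci = 100,
                                          maf_min = 0.05), pm, sch)
      res <- classify_observed(clf, obs)
      hits <- hits + (res$selected == "deepsplit")
    }
  })
  expect_gte(hits, 90)
  expect_error(train_model_choice(
    structure(list(labels = rep("only", 10),
                   stats = matrix(rnorm(20), 10)), class = "reference_table")),
    "2 scenarios")
})

test_that("the advancement rule is strictly more-than-average", {
  votes <- c(S1 = 207, S2 = 66, S3 = 89, S4 = 65, S5 = 379, S6 = 194)
  expect_setequal(advance_scenarios(votes, 1000), c("S1", "S5", "S6"))
  expect_equal(advance_scenarios(c(a = 501, b = 499), 1000), "a")
  expect_equal(advance_scenarios(c(a = 500, b = 500), 1000), character(0))
})

test_that("a single-round tournament reduces to plain classification", {
  sep <- separable_reftable(n = 200, seed = 37)
  clf_cache <- new.env()
  pm <- scenario_popmap(sep$pan)
  obs <- summary_vector(simulate_snps(sep$pan, n_loci = 100, maf_min = 0.05,
                                      seed = 38), pm,
                        sumstat_schema(c("A", "B")))
  tour <- run_tournament(tournament_plan(list(c("panmixia", "deepsplit"))),
                         sep$rt, obs, n_trees = 300, seed = 39,
                         cache = clf_cache)
  direct <- classify_observed(clf_cache[["deepsplit|panmixia"]], obs)
  expect_identical(tour$result$votes, direct$votes)
  expect_equal(tour$selected, "panmixia")
  expect_equal(length(tour$audit), 1)
})

test_that("regression adjustment collapses onto an exactly matching reference row", {
  fs <- founding_scenario(n_samples = 6)
  rt <- build_reference_table(list(fs$scenario), fs$priors, 400, fs$schema,
                              n_loci = 80, seed = 40)
  obs <- rt$stats[123, ]
  post <- estimate_parameters(rt, obs, fs$priors, tolerance = 2 / 400)
  # the matching row has distance zero and the largest weight
  expect_equal(post$distance[1], 0)
  expect_lt(abs(post$parameters$t$adjusted[1] - rt$params$t[123]), 2)
  # all adjusted draws inside prior bounds
  expect_true(all(post$parameters$Nf$adjusted >= 5 &
                    post$parameters$Nf$adjusted <= 500))
  expect_true(all(post$parameters$t$adjusted >= 38 &
                    post$parameters$t$adjusted <= 45))
  # quantiles ordered
  for (p in post$parameters)
    expect_true(p$q05 <= p$median && p$median <= p$q95)
  expect_error(estimate_parameters(rt, obs, fs$priors, tolerance = 1 / 1000),
               "1/tolerance")
})

test_that("model checking is calibrated under the truth and detects misfit", {
  fs <- founding_scenario(n_samples = 6)
  rt <- build_reference_table(list(fs$scenario), fs$priors, 600, fs$schema,
                              n_loci = 100, seed = 41)
  pm <- scenario_popmap(fs$scenario)
  obs <- summary_vector(simulate_snps(fs$scenario, list(t = 40, Nf = 8, db = 3),
                                      n_loci = 100, seed = 42), pm, fs$schema)
  post <- estimate_parameters(rt, obs, fs$priors, tolerance = 0.05)
  mc <- model_check(fs$scenario, post, obs, fs$schema, n_loci = 100,
                    n_sims = 150, seed = 43)
  expect_true(all(mc$table$p >= 0 & mc$table$p <= 1))
  expect_equal(mc$n_stats, sumstat_length(fs$schema))
  # p-values invariant to statistic order (recompute from permuted obs)
  mc2 <- model_check(fs$scenario, post, obs[sample(length(obs))], fs$schema,
                     n_loci = 100, n_sims = 150, seed = 43)
  expect_equal(mc$table$p, mc2$table$p)
  # observed from a grossly different history: most statistics flagged
  far <- scenario("far", list(NAT = deme(1000, 6), INV = deme(30, 6)),
                  list(ev_merge(3000, "INV", "NAT")))
  obs_far <- summary_vector(simulate_snps(far, n_loci = 100, seed = 44),
                            pm, fs$schema)
  mc_far <- model_check(fs$scenario, post, obs_far, fs$schema, n_loci = 100,
                        n_sims = 150, seed = 45)
  expect_gt(mc_far$n_significant / mc_far$n_stats, 0.5)
  expect_error(model_check(fs$scenario, post, obs, fs$schema, n_loci = 100,
                           n_sims = 50), "100")
})
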