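test_that("scenario validation names the broken rule", {
  expect_silent(validate_scenario(
    instantiate_scenario(scenario("one", list(A = deme(100, 2))))))
  # deme referenced after it merged away
  bad <- scenario("bad", list(A = deme(100, 2), B = deme(100, 2)),
                  list(ev_merge(5, "B", "A"), ev_admix(10, "B", "A", 0.5)))
  expect_error(validate_scenario(instantiate_scenario(bad)), "inactive")
  # unknown deme
  orphan <- scenario("o", list(A = deme(100, 2)),
                     list(ev_merge(5, "Z", "A")))
  expect_error(validate_scenario(instantiate_scenario(orphan)), "orphan")
  # admixture rate outside [0, 1]
  ra <- scenario("r", list(A = deme(100, 2), B = deme(100, 2)),
                 list(ev_admix(5, "B", "A", 1.5), ev_merge(9, "B", "A")))
  expect_error(validate_scenario(instantiate_scenario(ra)), "\\[0,1\\]")
  # two demes that never share an ancestor
  split <- scenario("s", list(A = deme(100, 2), B = deme(100, 2)))
  expect_error(validate_scenario(instantiate_scenario(split)), "single ancestral")
  # negative time
  neg <- scenario("n", list(A = deme(100, 2), B = deme(100, 2)),
                  list(ev_merge(-3, "B", "A")))
  expect_error(validate_scenario(instantiate_scenario(neg)), "non-negative")
})

test_that("simulated loci are biallelic, polymorphic and seed-deterministic", {
  sc <- scenario("one", list(A = deme(1000, 5)))
  gm <- simulate_snps(sc, n_loci = 100, maf_min = 0, seed = 6)
  expect_equal(nrow(gm$genotypes), 100)
  p <- rowSums(gm$genotypes) / (2 * ncol(gm$genotypes))
  expect_true(all(p > 0 & p < 1))       # every locus carries its mutation
  gm2 <- simulate_snps(sc, n_loci = 100, maf_min = 0, seed = 6)
  expect_identical(gm$genotypes, gm2$genotypes)
  # MAF conditioning honoured
  gm3 <- simulate_snps(sc, n_loci = 200, maf_min = 0.1, seed = 7)
  expect_true(all(site_maf(gm3) >= 0.1))
})

test_that("a split at time zero leaves no differentiation", {
  sc <- scenario("s0", list(A = deme(500, 5), B = deme(500, 5)),
                 list(ev_merge(1e-4, "B", "A")))
  gm <- simulate_snps(sc, n_loci = 2000, maf_min = 0.05, seed = 8)
  fst <- pairwise_fst(gm, scenario_popmap(sc), "WC84")["A", "B"]
  expect_lt(abs(fst), 0.01)
})

test_that("mean FST is self-consistent across simulation scales", {
  sc <- scenario("deep", list(A = deme(500, 5), B = deme(500, 5)),
                 list(ev_merge(2000, "B", "A")))
  pm <- scenario_popmap(sc)
  f1 <- pairwise_fst(simulate_snps(sc, n_loci = 2000, maf_min = 0.05,
                                   seed = 9), pm, "WC84")["A", "B"]
  f2 <- pairwise_fst(simulate_snps(sc, n_loci = 20000, maf_min = 0.05,
                                   seed = 10), pm, "WC84")["A", "B"]
  expect_lt(abs(f1 - f2), 0.02)
})

test_that("relabeling demes consistently leaves statistics invariant", {
  mk <- function(a, b) scenario("s", stats::setNames(
    list(deme(400, 6), deme(900, 4)), c(a, b)),
    list(ev_merge(800, b, a)))
  g1 <- simulate_snps(mk("A", "B"), n_loci = 400, maf_min = 0.05, seed = 13)
  g2 <- simulate_snps(mk("X", "Y"), n_loci = 400, maf_min = 0.05, seed = 13)
  s1 <- summary_vector(g1, scenario_popmap(mk("A", "B")),
                       sumstat_schema(c("A", "B")))
  s2 <- summary_vector(g2, scenario_popmap(mk("X", "Y")),
                       sumstat_schema(c("X", "Y")))
  expect_equal(unname(s1), unname(s2))
})

test_that("prior draws respect bounds, distribution and constraints", {
  pr <- prior_set(list(t_EAU = prior_unif(38, 45),
                       t_WAU = prior_unif(8, 10)),
                  constraints = "t_EAU > t_WAU")
  d <- draw_parameters(pr, 10000, seed = 14)
  expect_true(all(d$t_EAU >= 38 & d$t_EAU <= 45))
  expect_true(all(d$t_EAU > d$t_WAU))
  ks <- stats::ks.test((d$t_EAU - 38) / 7, "punif")
  expect_gt(ks$p.value, 0.001)
  expect_identical(draw_parameters(pr, 5, seed = 3),
                   draw_parameters(pr, 5, seed = 3))
  # integer rounding flag
  pri <- prior_set(list(n = prior_unif(1, 9, integer = TRUE)))
  expect_true(all(draw_parameters(pri, 200, seed = 1)$n %% 1 == 0))
  # unsatisfiable constraint detected
  bad <- prior_set(list(a = prior_unif(0, 1), b = prior_unif(2, 3)),
                   constraints = "a > b")
  expect_error(draw_parameters(bad, 1, seed = 1), "99.9%")
})

test_that("reference tables have exact bookkeeping and reproduce under a seed", {
  s1 <- scenario("const", list(A = deme(800, 4), B = deme(800, 4)),
                 list(ev_merge(60, "B", "A")))
  s2 <- scenario("bneck", list(A = deme(800, 4), B = deme(800, 4)),
                 list(ev_size(30, "B", 10), ev_merge(60, "B", "A")))
  pr <- prior_set(list(dummy = prior_unif(0, 1)))
  sch <- sumstat_schema(c("A", "B"))
  rt <- build_reference_table(list(s1, s2), pr, 100, sch, n_loci = 60,
                              seed = 15)
  expect_equal(table(rt$labels), table(rep(c("const", "bneck"), each = 100)))
  expect_equal(nrow(rt$stats), 200)
  expect_equal(ncol(rt$stats), sumstat_length(sch))
  rt2 <- build_reference_table(list(s1, s2), pr, 100, sch, n_loci = 60,
                               seed = 15)
  expect_identical(rt$stats, rt2$stats)
  # founder bottleneck lowers He in the bottlenecked deme's columns
  he_b <- rt$stats[, "mean_He_B"]
  tt <- stats::t.test(he_b[rt$labels == "bneck"], he_b[rt$labels == "const"],
                      alternative = "less")
  expect_lt(tt$p.value, 0.01)
})

test_that("the sequencing layer reproduces its depth model and exercises thinning", {
  sc <- scenario("one", list(A = deme(1000, 10)))
  gm <- simulate_snps(sc, n_loci = 5000, maf_min = 0.05, seed = 16)
  seq_gm <- add_sequencing_layer(gm, depth_mean = 22, depth_shape = 7,
                                 seed = 17)
  # 5000 x 10 = 5e4 genotypes; double for a second draw
  seq_gm2 <- add_sequencing_layer(gm, depth_mean = 22, depth_shape = 7,
                                  seed = 18)
  frac_low <- mean(c(seq_gm$depth, seq_gm2$depth) < 5)
  expect_lt(abs(frac_low - stats::pnbinom(4, mu = 22, size = 7)), 0.01)
  # allele depths consistent with genotypes
  expect_true(all(seq_gm$ad_alt[gm$genotypes == 0L] == 0))
  expect_true(all(seq_gm$ad_ref[gm$genotypes == 2L] == 0))
  expect_true(all(seq_gm$ad_ref + seq_gm$ad_alt == seq_gm$depth))
  # linked duplicates: thinning recovers exactly n_loci sites
  small <- simulate_snps(sc, n_loci = 50, maf_min = 0.05, seed = 19)
  linked <- add_sequencing_layer(small, depth_mean = 50, depth_shape = 50,
                                 n_extra_snps_per_locus = 3, seed = 20)
  expect_equal(nrow(linked$genotypes), 200)
  expect_equal(nrow(thin_one_per_locus(linked, seed = 1)$genotypes), 50)
  expect_error(add_sequencing_layer(small, missing_rate = 1.2), "\\[0, 1\\]")
})

test_that("YAML configuration round-trips scenarios and priors", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "priors:",
    "  t: {dist: unif, min: 38, max: 45}",
    "  Nf: {dist: logunif, min: 5, max: 500}",
    "scenarios:",
    "  - label: founding",
    "    demes:",
    "      NAT: {Ne: 1000, samples: 4}",
    "      INV: {Ne: 1000, samples: 4}",
    "    events:",
    "      - {type: size, time: t - 2, pop: INV, Ne: Nf}",
    "      - {type: merge, time: t, child: INV, parent: NAT}"), path)
  cfg <- read_scenario_config(path)
  expect_length(cfg$scenarios, 1)
  expect_s3_class(cfg$priors, "prior_set")
  gm <- simulate_snps(cfg$scenarios[[1]], list(t = 40, Nf = 8),
                      n_loci = 20, seed = 21)
  expect_equal(nrow(gm$genotypes), 20)
})
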