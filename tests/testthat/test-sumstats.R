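make_gm <- function(geno, groups) {
  geno <- as.matrix(geno)
  samples <- paste0("s", seq_len(ncol(geno)))
  gm <- genotype_matrix(geno, samples,
                        data.frame(locus = paste0("L", seq_len(nrow(geno))),
                                   pos = 1L, ref = "A", alt = "T"))
  list(gm = gm, pm = population_map(samples, groups))
}

test_that("diversity matches hand-enumerated values on one site", {
  # genotypes 0/0, 0/1, 1/1: 6 alleles, p = 0.5
  x <- make_gm(matrix(c(0L, 1L, 2L), 1, 3), rep("A", 3))
  d <- diversity(x$gm, x$pm)
  expect_equal(d$Ho, 1 / 3)
  expect_equal(d$He, 0.5)
  expect_equal(d$FIS, 1 - (1 / 3) / 0.5)   # = 1/3
  expect_equal(d$pi, 0.6)                  # 9 mismatching of 15 allele pairs
})

test_that("an all-heterozygote site forces Ho=1, He=0.5, FIS=-1", {
  x <- make_gm(matrix(1L, 1, 4), rep("A", 4))
  d <- diversity(x$gm, x$pm)
  expect_equal(d$Ho, 1)
  expect_equal(d$He, 0.5)
  expect_equal(d$FIS, -1)
})

test_that("a monomorphic group has zero diversity", {
  x <- make_gm(matrix(0L, 5, 4), rep("A", 4))
  d <- diversity(x$gm, x$pm)
  expect_equal(d$polymorphic_fraction, 0)
  expect_equal(d$He, 0)
  expect_equal(d$pi, 0)
})

test_that("He >= Ho exactly when FIS >= 0 (per-site estimator)", {
  for (seed in 1:20) {
    inst <- random_instance(seed)
    d <- suppressWarnings(diversity(inst$gm, inst$pm, fis_per_site = FALSE))
    ok <- d$He > 0   # FIS undefined for a group monomorphic everywhere
    expect_equal((d$FIS >= 0)[ok], (d$He >= d$Ho)[ok])
  }
})

test_that("private alleles follow observation across groups", {
  # site 1: A has alleles {0,1}, B only {0} -> A:1, B:0
  x <- make_gm(matrix(c(1L, 0L, 0L, 0L), 1, 4), c("A", "A", "B", "B"))
  pa <- private_alleles(x$gm, x$pm)
  expect_equal(unname(pa), c(1L, 0L))
  # identical allele sets everywhere -> all zeros
  y <- make_gm(matrix(c(1L, 1L, 1L, 1L), 2, 4), c("A", "A", "B", "B"))
  expect_equal(unname(private_alleles(y$gm, y$pm)), c(0L, 0L))
  # allele observed in one sample of one group, missing elsewhere
  g <- matrix(c(2L, NA, 0L, 0L), 1, 4)
  z <- make_gm(g, c("A", "A", "B", "B"))
  expect_equal(unname(private_alleles(z$gm, z$pm))[1], 1L)
  expect_error(private_alleles(x$gm, population_map(x$pm$sample,
                                                    rep("A", 4))),
               "2 groups")
})

test_that("maximal and null differentiation hit the estimator bounds", {
  fixed <- make_gm(rbind(c(0L, 0L, 2L, 2L), c(0L, 0L, 2L, 2L)),
                   c("A", "A", "B", "B"))
  for (est in c("WC84", "PhiST", "FST_std"))
    expect_equal(unname(pairwise_fst(fixed$gm, fixed$pm, est)["A", "B"]), 1)
  # two identical copies of the same genotype table; the estimator's exact
  # zero arises when the within-group heterozygote correction cancels the
  # between-group term (all-heterozygote sites), and for general duplicate
  # tables the finite-sample bias is O(1/n)
  het <- make_gm(matrix(1L, 3, 4), c("A", "A", "B", "B"))
  expect_lt(abs(pairwise_fst(het$gm, het$pm, "WC84")["A", "B"]), 1e-12)
  one <- simulate_snps(scenario("p", list(P = deme(1000, 30))),
                       n_loci = 400, maf_min = 0.05, seed = 77)
  dup <- genotype_matrix(cbind(one$genotypes, one$genotypes),
                         c(paste0("a", 1:30), paste0("b", 1:30)), one$loci)
  pm_dup <- population_map(dup$samples, rep(c("A", "B"), each = 30))
  expect_lt(abs(pairwise_fst(dup, pm_dup, "WC84")["A", "B"]), 0.05)
  # no variation anywhere -> flagged undefined, not zero
  mono <- make_gm(matrix(0L, 3, 4), c("A", "A", "B", "B"))
  expect_true(is.na(pairwise_fst(mono$gm, mono$pm, "WC84")["A", "B"]))
})

test_that("Nei's D matches the closed form and flags non-overlap", {
  # p1 = 0.8, p2 = 0.6 at a single site
  x <- make_gm(matrix(c(2L, 2L, 2L, 1L, 1L,  2L, 2L, 1L, 1L, 0L), 1, 10),
               rep(c("A", "B"), each = 5))
  jx <- 0.8^2 + 0.2^2; jy <- 0.6^2 + 0.4^2; jxy <- 0.8 * 0.6 + 0.2 * 0.4
  expect_equal(unname(nei_distance(x$gm, x$pm)["A", "B"]),
               -log(jxy / sqrt(jx * jy)))
  ident <- make_gm(rbind(c(1L, 1L, 1L, 1L)), c("A", "A", "B", "B"))
  expect_equal(unname(nei_distance(ident$gm, ident$pm)["A", "B"]), 0)
  opp <- make_gm(rbind(c(0L, 0L, 2L, 2L)), c("A", "A", "B", "B"))
  expect_equal(unname(nei_distance(opp$gm, opp$pm)["A", "B"]), Inf)
})

test_that("f3 is negative for an admixed target and ~0 under panmixia", {
  # pT = (p1+p2)/2 with sources far apart: planted frequencies
  # A (src1) p=0.9, B (src2) p=0.1, T p=0.5, 5 diploids each
  geno <- matrix(c(2L, 2L, 2L, 2L, 1L,   # p=0.9
                   0L, 0L, 0L, 0L, 1L,   # p=0.1
                   1L, 1L, 1L, 1L, 1L),  # p=0.5
                 1, 15)
  x <- make_gm(geno, rep(c("A", "B", "T"), each = 5))
  expect_lt(f3_admixture(x$gm, x$pm, "T", "A", "B"), -0.1)
  # one panmictic deme relabeled into three groups: f3 ~ 0
  sc <- scenario("pan", list(P = deme(1000, 15)))
  gm <- simulate_snps(sc, n_loci = 2000, maf_min = 0.05, seed = 11)
  pm <- population_map(gm$samples, rep(c("T", "A", "B"), each = 5))
  expect_lt(abs(f3_admixture(gm, pm, "T", "A", "B")), 0.005)
  # target a copy of src1 (same deme), src2 diverged: never strongly negative
  sc2 <- scenario("two", list(P = deme(1000, 10), Q = deme(1000, 5)),
                  list(ev_merge(1500, "Q", "P")))
  gm2 <- simulate_snps(sc2, n_loci = 2000, maf_min = 0.05, seed = 12)
  pm2 <- population_map(gm2$samples,
                        c(rep(c("T", "A"), each = 5), rep("B", 5)))
  expect_gt(f3_admixture(gm2, pm2, "T", "A", "B"), -0.005)
  expect_error(f3_admixture(gm2, pm2, "T", "T", "B"), "distinct")
})

test_that("the summary vector has schema length and is order-invariant", {
  sch5 <- sumstat_schema(paste0("G", 1:5))
  expect_equal(sumstat_length(sch5), 70L)
  inst <- random_instance(3, max_groups = 3, max_samples = 9)
  sch <- sumstat_schema(levels(inst$grp))
  v1 <- summary_vector(inst$gm, inst$pm, sch)
  expect_equal(length(v1), sumstat_length(sch))
  # permuting sample order leaves the vector unchanged
  perm <- sample(seq_along(inst$gm$samples))
  gm_p <- gm_subset(inst$gm, samples = perm)
  v2 <- summary_vector(gm_p, inst$pm, sch)
  expect_equal(v1, v2)
  # determinism
  expect_identical(v1, summary_vector(inst$gm, inst$pm, sch))
  expect_error(summary_vector(inst$gm, inst$pm, sumstat_schema(c("G1", "ZZ"))),
               "absent")
})

test_that("statistics are invariant to site order", {
  inst <- random_instance(8, max_groups = 3)
  perm <- sample(nrow(inst$gm$genotypes))
  gm_p <- gm_subset(inst$gm, sites = perm)
  expect_equal(pairwise_fst(inst$gm, inst$pm, "WC84"),
               pairwise_fst(gm_p, inst$pm, "WC84"))
  expect_equal(diversity(inst$gm, inst$pm)$He, diversity(gm_p, inst$pm)$He)
})

test_that("FST grows with divergence time in two-deme simulations", {
  mean_fst <- vapply(c(50, 500, 3000), function(t) {
    sc <- scenario("s", list(A = deme(500, 8), B = deme(500, 8)),
                   list(ev_merge(t, "B", "A")))
    gm <- simulate_snps(sc, n_loci = 1000, maf_min = 0.05, seed = 100 + t)
    pairwise_fst(gm, scenario_popmap(sc), "WC84")["A", "B"]
  }, numeric(1))
  expect_true(all(diff(mean_fst) > 0))
})
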