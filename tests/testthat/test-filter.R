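test_that("planted violations are removed stage by stage with exact counts", {
  gm <- toy_filter_gm()
  res <- filter_cascade(gm, seed = 1)
  st <- res$report$stages
  expect_equal(st$stage,
               c("sample_missingness_pre", "depth_mask",
                 "biallelic_missingness_maf", "thin_one_per_locus",
                 "sample_missingness_post"))
  expect_equal(st$samples_in, c(6, 5, 5, 5, 5))
  expect_equal(st$samples_out, c(5, 5, 5, 5, 5))
  expect_equal(st$sites_in, c(10, 10, 10, 6, 3))
  expect_equal(st$sites_out, c(10, 10, 6, 3, 3))
  # totals reconcile: input = output + removed at each stage
  expect_true(all(st$sites_in - st$sites_out >= 0))
  expect_true(all(st$samples_in - st$samples_out >= 0))
  out <- res$gm
  expect_equal(length(out$samples), 5)
  expect_equal(nrow(out$genotypes), 3)
  expect_setequal(unique(out$loci$locus), c("L1", "L2", "L3"))
  # every retained site satisfies the stage predicates
  expect_true(all(site_maf(out) > 0.05))
  expect_true(all(rowMeans(is.na(out$genotypes)) < 0.2))
  expect_true(all(colMeans(is.na(out$genotypes)) <= 0.5))
})

test_that("the cascade is a no-op on clean data and idempotent", {
  sc <- scenario("one", list(A = deme(500, 6)))
  gm <- simulate_snps(sc, n_loci = 40, maf_min = 0.06, seed = 2)
  gm <- add_sequencing_layer(gm, depth_mean = 50, depth_shape = 50, seed = 3)
  res <- filter_cascade(gm, seed = 1)
  expect_equal(res$gm$genotypes, gm$genotypes)
  twice <- filter_cascade(res$gm, seed = 1)
  expect_identical(twice$gm$genotypes, res$gm$genotypes)
  expect_identical(twice$gm$loci, res$gm$loci)
})

test_that("identical seeds give bitwise-identical output and report", {
  gm <- add_sequencing_layer(
    simulate_snps(scenario("one", list(A = deme(500, 6))),
                  n_loci = 30, maf_min = 0.05, seed = 4),
    depth_mean = 22, missing_rate = 0.05, n_extra_snps_per_locus = 2,
    seed = 5)
  a <- filter_cascade(gm, seed = 42)
  b <- filter_cascade(gm, seed = 42)
  expect_identical(a$gm, b$gm)
  expect_identical(a$report$stages, b$report$stages)
})

test_that("the cascade errors loudly instead of returning empty output", {
  geno <- matrix(0L, 4, 4)  # all monomorphic: nothing survives stage 3
  gm <- genotype_matrix(geno, paste0("s", 1:4),
                        data.frame(locus = paste0("L", 1:4), pos = 1,
                                   ref = "A", alt = "T"))
  expect_error(filter_cascade(gm), "empty after stage 3")
})

test_that("thinning keeps exactly one site per locus, uniformly at random", {
  gm <- toy_filter_gm()
  loci_sizes <- table(gm$loci$locus)
  thin <- thin_one_per_locus(gm, seed = 9)
  expect_equal(nrow(thin$genotypes), length(loci_sizes))
  expect_equal(sort(unique(thin$loci$locus)), sort(names(loci_sizes)))
  # already thinned -> identity
  expect_identical(thin_one_per_locus(thin, seed = 1)$loci, thin$loci)
  # missing locus ids -> instructive error
  gm_noloc <- gm
  gm_noloc$loci$locus <- NA
  expect_error(thin_one_per_locus(gm_noloc), "locus_id_rule")
})

test_that("thinning selects each site of a locus with equal frequency", {
  # one locus with 4 sites; selection frequencies over 10,000 seeds
  geno <- matrix(rep(c(0L, 1L, 2L, 1L), each = 4), 4, 4, byrow = FALSE)
  gm <- genotype_matrix(geno, paste0("s", 1:4),
                        data.frame(locus = "L1", pos = 1:4,
                                   ref = "A", alt = "T"))
  picks <- vapply(1:10000, function(s)
    thin_one_per_locus(gm, seed = s)$loci$pos, integer(1))
  freq <- tabulate(picks, 4) / 10000
  expect_true(all(abs(freq - 0.25) < 0.02))
})
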