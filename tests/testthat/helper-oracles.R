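# Brute-force oracles, written independently of the package's vectorized
# implementations: explicit per-site, per-population loops following the
# textbook definitions.

# Weir-Cockerham (1984) theta over all sites, loop form. geno: sites x
# samples matrix of alt-allele counts; grp: factor over samples.
oracle_wc84 <- function(geno, grp) {
  grp <- droplevels(factor(grp))
  num <- den <- 0
  for (s in seq_len(nrow(geno))) {
    g <- geno[s, ]
    pops <- levels(grp)
    n <- p <- h <- numeric(length(pops))
    for (k in seq_along(pops)) {
      gk <- g[grp == pops[k]]
      gk <- gk[!is.na(gk)]
      n[k] <- length(gk)
      if (n[k] == 0) next
      p[k] <- sum(gk) / (2 * n[k])
      h[k] <- sum(gk == 1) / n[k]
    }
    use <- n > 0
    r <- sum(use)
    if (r < 2) next
    n <- n[use]; p <- p[use]; h <- h[use]
    nbar <- mean(n)
    if (nbar <= 1) next
    nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    pbar <- sum(n * p) / sum(n)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / sum(n)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  if (den == 0) NA_real_ else num / den
}

# AMOVA Phi-ST from explicit pairwise squared-difference sums, loop form.
oracle_phist <- function(geno, grp) {
  grp <- droplevels(factor(grp))
  N <- ncol(geno); G <- nlevels(grp)
  dist2 <- function(i, j) {
    ok <- !is.na(geno[, i]) & !is.na(geno[, j])
    sum((geno[ok, i] - geno[ok, j])^2)
  }
  ss_total <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) ss_total <- ss_total + dist2(i, j)
  ss_total <- ss_total / N
  ss_within <- 0
  for (g in levels(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2) next
    acc <- 0
    for (a in seq_along(idx)[-length(idx)])
      for (b in (a + 1):length(idx)) acc <- acc + dist2(idx[a], idx[b])
    ss_within <- ss_within + acc / length(idx)
  }
  ss_among <- ss_total - ss_within
  df_a <- G - 1; df_w <- N - G
  sigma_w <- ss_within / df_w
  n_g <- as.numeric(table(grp))
  n_prime <- (N - sum(n_g^2) / N) / df_a
  sigma_a <- (ss_among / df_a - sigma_w) / n_prime
  sigma_a / (sigma_a + sigma_w)
}

# Random small genotype-matrix instance for oracle comparisons.
random_instance <- function(seed, max_groups = 4, max_samples = 8,
                            max_sites = 10) {
  withr::with_seed(seed, {
    G <- sample(2:max_groups, 1)
    szs <- 2:max(2, max_samples %/% G)
    n_per <- szs[sample.int(length(szs), G, replace = TRUE)]
    n <- sum(n_per)
    n_sites <- sample(2:max_sites, 1)
    repeat {
      geno <- matrix(sample(0:2, n_sites * n, replace = TRUE), n_sites, n)
      # keep instances with variation so theta is defined
      if (any(rowSums(geno) > 0 & rowSums(geno) < 2 * n)) break
    }
    grp <- factor(rep(paste0("G", seq_len(G)), n_per))
    samples <- paste0("s", seq_len(n))
    gm <- genotype_matrix(geno, samples,
                          data.frame(locus = paste0("L", seq_len(n_sites)),
                                     pos = 1L, ref = "A", alt = "T"))
    pm <- population_map(samples, as.character(grp))
    list(gm = gm, pm = pm, geno = geno, grp = grp)
  })
}

# Toy genotype matrix with one planted violation of every filter stage.
# Layout (10 sites, 6 samples S1..S6):
#   - S6 missing at every site                    -> stage 1 drops S6
#   - site 1: depth 3 at S1 (masked at stage 2, raising missingness to
#     1/5 = 20%, not < 20%)                        -> stage 3 drops site 1
#   - site 2: multiallelic                         -> stage 3 drops site 2
#   - sites 3, 4: monomorphic (MAF 0 <= 0.05)      -> stage 3 drops both
#   - sites 5,6 on locus L1; site 7 on L2; sites 8,9,10 on L3
#                                                  -> stage 4 keeps 3 of 6
#   - no sample exceeds 50% missingness afterwards -> stage 5 keeps 5
toy_filter_gm <- function() {
  polym <- c(0L, 1L, 2L, 1L, 0L)   # MAF 0.4, no missing
  geno <- rbind(
    c(0L, 1L, 1L, 0L, 1L),  # site 1 (depth violation at S1)
    c(0L, 1L, 0L, 1L, 1L),  # site 2 (multiallelic)
    rep(0L, 5),             # site 3 monomorphic ref
    rep(2L, 5),             # site 4 monomorphic alt
    polym, polym, polym, polym, polym, polym) # sites 5-10
  geno <- cbind(geno, NA_integer_)  # S6 all missing
  depth <- matrix(20L, 10, 6)
  depth[1, 1] <- 3L
  loci <- data.frame(
    locus = c("L1", "L2", "L3", "L4", "L1", "L1", "L2", "L3", "L3", "L3"),
    pos = c(1L, 1L, 1L, 1L, 2L, 3L, 2L, 2L, 3L, 4L),
    ref = "A", alt = c("T", "T,G", rep("T", 8)),
    multiallelic = c(FALSE, TRUE, rep(FALSE, 8)))
  genotype_matrix(geno, paste0("S", 1:6), loci, depth = depth)
}

toy_popmap <- function(gm) population_map(gm$samples,
                                          rep("P1", length(gm$samples)))
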