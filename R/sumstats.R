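# Per-group per-site counts used by every statistic: number of called
# diploid genotypes, alternate-allele frequency, observed-heterozygote
# proportion. Columns follow levels(groups).
group_site_counts <- function(gm, groups) {
  g <- gm$genotypes
  lev <- levels(groups)
  n <- p <- ho <- matrix(NA_real_, nrow(g), length(lev),
                         dimnames = list(NULL, lev))
  for (k in seq_along(lev)) {
    sub <- g[, groups == lev[k], drop = FALSE]
    if (ncol(sub) == 0) stop("group with zero samples: ", lev[k])
    n[, k] <- rowSums(!is.na(sub))
    p[, k] <- rowSums(sub, na.rm = TRUE) / (2 * n[, k])
    ho[, k] <- rowSums(sub == 1L, na.rm = TRUE) / n[, k]
  }
  list(n = n, p = p, ho = ho, levels = lev)
}

se_mean <- function(x) stats::sd(x) / sqrt(length(x))

#' Per-group diversity statistics
#'
#' For each region group: private allele count, fraction of polymorphic
#' sites, mean observed heterozygosity (Ho), mean expected heterozygosity
#' (gene diversity, He), the inbreeding coefficient FIS, and nucleotide
#' diversity at SNP sites (pi), each with a standard error. Per-site values
#' are averaged over sites and the SE is the site-wise standard error of the
#' mean (FIS, a ratio of means, uses a leave-one-site-out jackknife SE).
#'
#' He defaults to the naive gene diversity 1 - sum(p^2); pi uses the
#' sample-size-corrected average pairwise difference 2n/(2n-1) * 2p(1-p).
#' FIS is reported as 1 - mean(Ho)/mean(He) over sites; `fis_per_site = TRUE`
#' averages per-site FIS at polymorphic sites instead.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap a [population_map()] covering all samples of `gm`.
#' @param unbiased_he apply the 2n/(2n-1) small-sample correction to He.
#' @param fis_per_site average per-site FIS instead of the ratio of means.
#' @return data.frame, one row per group, of class `diversity_table`.
#' @export
diversity <- function(gm, popmap, unbiased_he = FALSE, fis_per_site = FALSE) {
  groups <- gm_groups(gm, popmap)
  cs <- group_site_counts(gm, groups)
  if (any(cs$n == 0))
    stop("some group has zero called genotypes at some site")
  priv <- if (length(cs$levels) >= 2) private_alleles(gm, popmap) else
    stats::setNames(rep(NA_integer_, length(cs$levels)), cs$levels)
  rows <- lapply(seq_along(cs$levels), function(k) {
    p <- cs$p[, k]; n <- cs$n[, k]; ho <- cs$ho[, k]
    he <- 2 * p * (1 - p)
    if (unbiased_he) he <- he * (2 * n) / (2 * n - 1)
    pi_site <- 2 * p * (1 - p) * (2 * n) / (2 * n - 1)
    poly <- p > 0 & p < 1
    mean_he <- mean(he)
    fis <- if (fis_per_site) {
      f <- 1 - ho[poly] / he[poly]
      c(mean(f), se_mean(f))
    } else {
      point <- 1 - mean(ho) / mean_he
      jack <- vapply(seq_along(ho), function(i)
        1 - mean(ho[-i]) / mean(he[-i]), numeric(1))
      m <- length(ho)
      c(point, sqrt((m - 1) / m * sum((jack - mean(jack))^2)))
    }
    data.frame(group = cs$levels[k],
               private_alleles = priv[[cs$levels[k]]],
               polymorphic_fraction = mean(poly),
               Ho = mean(ho), Ho_se = se_mean(ho),
               He = mean_he, He_se = se_mean(he),
               FIS = fis[1], FIS_se = fis[2],
               pi = mean(pi_site), pi_se = se_mean(pi_site),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("diversity_table", "data.frame"))
}

#' Private allele counts per group
#'
#' An allele is private to a group when it is observed (in at least one
#' called genotype) in that group and in no other group; counts are summed
#' over sites.
#'
#' @inheritParams diversity
#' @return named integer vector of private-allele counts per group.
#' @export
private_alleles <- function(gm, popmap) {
  groups <- gm_groups(gm, popmap)
  if (nlevels(groups) < 2) stop("private alleles need at least 2 groups")
  cs <- group_site_counts(gm, groups)
  # allele observed: ref if p < 1 (given calls), alt if p > 0
  called <- cs$n > 0
  has_ref <- called & cs$p < 1
  has_alt <- called & cs$p > 0
  priv_count <- function(has) {
    tot <- rowSums(has)
    (tot == 1) * has   # site x group indicator of private allele
  }
  counts <- colSums(priv_count(has_ref)) + colSums(priv_count(has_alt))
  stats::setNames(as.integer(counts), cs$levels)
}

# Weir & Cockerham (1984) per-site variance components a, b, c for a set of
# populations, vectorized over sites. Sites where fewer than 2 populations
# have calls, or n_bar <= 1, contribute NA components.
wc84_components <- function(cs) {
  n <- cs$n; p <- cs$p; h <- cs$ho
  r <- rowSums(n > 0)
  n_tot <- rowSums(n)
  n_bar <- n_tot / r
  n_c <- (n_tot - rowSums(n^2) / n_tot) / (r - 1)
  p_bar <- rowSums(n * p) / n_tot
  s2 <- rowSums(n * (p - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- rowSums(n * h) / n_tot
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  bad <- r < 2 | n_bar <= 1
  a[bad] <- b[bad] <- cc[bad] <- NA_real_
  list(a = a, b = b, c = cc)
}

wc84_theta <- function(cs) {
  comp <- wc84_components(cs)
  ok <- !is.na(comp$a)
  den <- sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
  if (!any(ok) || den == 0) return(NA_real_)
  sum(comp$a[ok]) / den
}

# AMOVA Phi-ST on squared differences of alternate-allele counts, two-level
# (among groups / among individuals within groups). Distances use
# pairwise-complete sites. x: sites x individuals genotype matrix.
amova_phist <- function(x, grp) {
  grp <- droplevels(factor(grp))
  N <- ncol(x); G <- nlevels(grp)
  d <- matrix(0, N, N)
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    ok <- !is.na(x[, i]) & !is.na(x[, j])
    d[i, j] <- d[j, i] <- sum((x[ok, i] - x[ok, j])^2)
  }
  ss_total <- sum(d[upper.tri(d)]) / N
  n_g <- tabulate(grp)
  ss_within <- sum(vapply(seq_len(G), function(k) {
    idx <- which(as.integer(grp) == k)
    dk <- d[idx, idx, drop = FALSE]
    sum(dk[upper.tri(dk)]) / length(idx)
  }, numeric(1)))
  ss_among <- ss_total - ss_within
  df_a <- G - 1; df_w <- N - G
  if (df_w <= 0) return(NA_real_)
  sigma_w <- ss_within / df_w
  n_prime <- (N - sum(n_g^2) / N) / df_a
  sigma_a <- (ss_among / df_a - sigma_w) / n_prime
  tot <- sigma_a + sigma_w
  if (tot == 0) return(NA_real_)
  sigma_a / tot
}

#' Pairwise population differentiation matrix
#'
#' Computes one of three estimators between every pair of region groups:
#' \describe{
#'   \item{WC84}{Weir-Cockerham theta, the multi-site ratio of sums of the
#'     among-population variance component to the total.}
#'   \item{PhiST}{AMOVA-based Phi-ST: the among-group fraction of molecular
#'     variance, with the inter-individual distance taken as the squared
#'     difference of alternate-allele counts summed over sites.}
#'   \item{FST_std}{standardized FST: WC84 theta divided by its maximum
#'     attainable value given the mean within-group gene diversity
#'     (Hedrick-style maximum standardization).}
#' }
#' Pairs with no variation anywhere have an undefined value and are returned
#' as `NA` rather than 0.
#'
#' @inheritParams diversity
#' @param estimator one of `"WC84"`, `"PhiST"`, `"FST_std"`.
#' @return symmetric group x group matrix with zero diagonal.
#' @export
pairwise_fst <- function(gm, popmap, estimator = c("WC84", "PhiST", "FST_std")) {
  estimator <- match.arg(estimator)
  groups <- gm_groups(gm, popmap)
  lev <- levels(groups)
  if (length(lev) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  cs <- group_site_counts(gm, groups)
  out <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_along(lev)[-length(lev)]) for (j in (i + 1):length(lev)) {
    keep <- groups %in% lev[c(i, j)]
    val <- switch(estimator,
      WC84 = wc84_theta(lapply(cs[c("n", "p", "ho")],
                               function(m) m[, c(i, j), drop = FALSE])),
      PhiST = amova_phist(gm$genotypes[, keep, drop = FALSE],
                          droplevels(groups[keep])),
      FST_std = {
        sub <- lapply(cs[c("n", "p", "ho")],
                      function(m) m[, c(i, j), drop = FALSE])
        theta <- wc84_theta(sub)
        hs <- mean(2 * sub$p * (1 - sub$p))
        theta_max <- (2 - 1) * (1 - hs) / (2 - 1 + hs)
        if (is.na(theta) || theta_max == 0) NA_real_ else theta / theta_max
      })
    out[i, j] <- out[j, i] <- val
  }
  out
}

#' Nei's standard genetic distance between groups
#'
#' D = -ln( Jxy / sqrt(Jx * Jy) ) with the gene identities J averaged over
#' sites before taking the ratio. Pairs with zero shared identity return
#' `Inf` (flagged, not an error).
#'
#' @inheritParams diversity
#' @return symmetric group x group matrix with zero diagonal.
#' @export
nei_distance <- function(gm, popmap) {
  groups <- gm_groups(gm, popmap)
  cs <- group_site_counts(gm, groups)
  lev <- cs$levels
  p <- cs$p
  out <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_along(lev)[-length(lev)]) for (j in (i + 1):length(lev)) {
    jx <- mean(p[, i]^2 + (1 - p[, i])^2)
    jy <- mean(p[, j]^2 + (1 - p[, j])^2)
    jxy <- mean(p[, i] * p[, j] + (1 - p[, i]) * (1 - p[, j]))
    out[i, j] <- out[j, i] <- if (jxy == 0) Inf else -log(jxy / sqrt(jx * jy))
  }
  out
}

#' f3 admixture statistic
#'
#' f3(target; src1, src2) = mean over sites of
#' (pT - p1)(pT - p2) - pT(1 - pT)/(2 nT - 1), the last term removing the
#' sampling-variance bias of the target allele frequency. Strongly negative
#' values indicate that the target is admixed between populations related to
#' the two sources.
#'
#' @inheritParams diversity
#' @param target,src1,src2 three distinct group labels.
#' @return a single numeric value.
#' @export
f3_admixture <- function(gm, popmap, target, src1, src2) {
  trio <- c(target, src1, src2)
  if (anyDuplicated(trio)) stop("target and sources must be distinct groups")
  groups <- gm_groups(gm, popmap)
  if (!all(trio %in% levels(groups)))
    stop("unknown group(s): ", paste(setdiff(trio, levels(groups)), collapse = ", "))
  cs <- group_site_counts(gm, groups)
  f3_stat(cs, target, src1, src2)
}

#' Fixed-order summary-statistic vector for ABC
#'
#' Concatenates, in a deterministic order fixed by the schema's group list:
#' per group \{mean He, variance of He across sites, proportion of
#' monomorphic sites, mean Ho\}; per unordered group pair \{Weir-Cockerham
#' FST, Nei's D\}; per group trio, the three f3 statistics obtained by
#' letting each member of the trio be the target. Length is
#' 4G + 2*C(G,2) + 3*C(G,3).
#'
#' @inheritParams diversity
#' @param schema a [sumstat_schema()] naming the group list (and version).
#' @return named numeric vector; identical inputs give identical vectors.
#' @export
summary_vector <- function(gm, popmap, schema) {
  stopifnot(inherits(schema, "sumstat_schema"))
  groups <- gm_groups(gm, popmap)
  missing_g <- setdiff(schema$groups, levels(groups))
  if (length(missing_g))
    stop("schema group(s) absent from data: ", paste(missing_g, collapse = ", "))
  cs <- group_site_counts(gm, groups)
  gsel <- match(schema$groups, cs$levels)
  out <- c()
  for (k in gsel) {
    p <- cs$p[, k]
    he <- 2 * p * (1 - p)
    g <- cs$levels[k]
    out <- c(out, stats::setNames(
      c(mean(he), stats::var(he), mean(p == 0 | p == 1), mean(cs$ho[, k])),
      paste0(c("mean_He_", "var_He_", "prop_mono_", "mean_Ho_"), g)))
  }
  G <- length(schema$groups)
  if (G >= 2) {
    for (i in seq_len(G - 1)) for (j in (i + 1):G) {
      a <- gsel[i]; b <- gsel[j]
      theta <- wc84_theta(lapply(cs[c("n", "p", "ho")],
                                 function(m) m[, c(a, b), drop = FALSE]))
      jx <- mean(cs$p[, a]^2 + (1 - cs$p[, a])^2)
      jy <- mean(cs$p[, b]^2 + (1 - cs$p[, b])^2)
      jxy <- mean(cs$p[, a] * cs$p[, b] + (1 - cs$p[, a]) * (1 - cs$p[, b]))
      nei <- if (jxy == 0) Inf else -log(jxy / sqrt(jx * jy))
      pr <- paste0(schema$groups[i], "_", schema$groups[j])
      out <- c(out, stats::setNames(c(theta, nei),
                                    paste0(c("fst_", "neiD_"), pr)))
    }
  }
  if (G >= 3) {
    trios <- utils::combn(seq_len(G), 3)
    for (t in seq_len(ncol(trios))) {
      tri <- schema$groups[trios[, t]]
      for (tg in 1:3) {
        tgt <- tri[tg]; srcs <- tri[-tg]
        out <- c(out, stats::setNames(
          f3_stat(cs, tgt, srcs[1], srcs[2]),
          paste0("f3_", tgt, ".", srcs[1], "_", srcs[2])))
      }
    }
  }
  structure(out, schema = schema$version)
}

# f3 from precomputed group counts (avoids re-deriving them per trio)
f3_stat <- function(cs, target, src1, src2) {
  pT <- cs$p[, target]; nT <- cs$n[, target]
  p1 <- cs$p[, src1]; p2 <- cs$p[, src2]
  ok <- nT > 0 & cs$n[, src1] > 0 & cs$n[, src2] > 0 & (2 * nT) > 1
  mean(((pT - p1) * (pT - p2) - pT * (1 - pT) / (2 * nT - 1))[ok])
}

#' Summary-statistic schema
#'
#' Fixes the group list (and therefore the order and length) of
#' [summary_vector()] outputs, so that observed data and simulated reference
#' tables are guaranteed to use the same statistics.
#'
#' @param groups character vector of region-group labels, in order.
#' @param version schema version identifier.
#' @return an object of class `sumstat_schema`.
#' @export
sumstat_schema <- function(groups, version = "v1") {
  structure(list(groups = as.character(groups), version = version),
            class = "sumstat_schema")
}

#' Length of the statistic vector implied by a schema
#' @param schema a [sumstat_schema()].
#' @return integer: 4G + 2*C(G,2) + 3*C(G,3).
#' @export
sumstat_length <- function(schema) {
  G <- length(schema$groups)
  as.integer(4 * G + 2 * choose(G, 2) + 3 * choose(G, 3))
}
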