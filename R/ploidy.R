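#' Extract per-individual allele balances from a genotype matrix
#'
#' The allele balance at a site is alt_reads / (ref_reads + alt_reads).
#' Sites qualify for an individual when the summed allele coverage
#' (ref + alt reads) is at least `min_cov` and the within-individual minor
#' allele fraction is at least `maf_min`; under ploidy m the qualifying
#' balances concentrate at k/m, so their modes reveal the ploidy.
#'
#' @param gm a [genotype_matrix()] with allele depths (AD).
#' @param min_cov minimum summed allele coverage per site (default 10).
#' @param maf_min minimum within-individual minor allele fraction
#'   (default 0.2).
#' @return an `allele_balance_set`: named list of balance vectors, one per
#'   sample, with the thresholds recorded as attributes.
#' @export
extract_allele_balance <- function(gm, min_cov = 10, maf_min = 0.2) {
  if (is.null(gm$ad_ref) || is.null(gm$ad_alt))
    stop("genotype matrix has no allele depths (AD)")
  out <- lapply(seq_along(gm$samples), function(j) {
    ref <- gm$ad_ref[, j]; alt <- gm$ad_alt[, j]
    cov <- ref + alt
    b <- alt / cov
    keep <- !is.na(cov) & cov >= min_cov & pmin(b, 1 - b) >= maf_min
    unname(b[keep])
  })
  names(out) <- gm$samples
  structure(out, min_cov = min_cov, maf_min = maf_min,
            class = "allele_balance_set")
}

# EM for a free Gaussian mixture (free means, per-component sd, truncated
# to the balance window) plus one uniform noise component over the window.
# sd bounds keep the mixture away from point-mass degeneracies and from
# flat pseudo-noise components.
balance_mixture_em <- function(x, means = c(0.3, 0.5, 0.7), lo = 0.2,
                               hi = 0.8, sd_init = 0.05, noise_weight = 0.1,
                               sd_floor = 0.01, sd_cap = 0.15,
                               max_iter = 3000, tol = 1e-8) {
  n <- length(x); k <- length(means)
  sds <- rep(sd_init, k)
  w <- rep((1 - noise_weight) / k, k)
  wn <- noise_weight
  nd <- 1 / (hi - lo)
  ll_old <- -Inf; converged <- FALSE; resp <- NULL
  for (iter in seq_len(max_iter)) {
    zs <- pmax(stats::pnorm(hi, means, sds) - stats::pnorm(lo, means, sds),
               1e-10)
    dens <- vapply(seq_len(k), function(j)
      w[j] * stats::dnorm(x, means[j], sds[j]) / zs[j], numeric(n))
    dens <- cbind(dens, rep(wn * nd, n))
    tot <- pmax(rowSums(dens), 1e-300)
    ll <- sum(log(tot))
    resp <- dens / tot
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) {
      converged <- TRUE; break
    }
    ll_old <- ll
    nk <- colSums(resp)
    w <- nk[seq_len(k)] / n
    wn <- nk[k + 1] / n
    means <- vapply(seq_len(k), function(j)
      sum(resp[, j] * x) / max(nk[j], 1e-12), numeric(1))
    sds <- vapply(seq_len(k), function(j)
      sqrt(sum(resp[, j] * (x - means[j])^2) / max(nk[j], 1e-12)), numeric(1))
    sds <- pmin(pmax(sds, sd_floor), sd_cap)
  }
  list(loglik = ll, means = means, sds = sds, weights = w,
       noise_weight = wn, resp = resp, converged = converged)
}

#' Remove noise sites from an allele-balance vector
#'
#' Fits a three-component free-mean Gaussian mixture plus a uniform noise
#' component over the balance window by EM and drops the sites whose
#' largest responsibility belongs to the noise component (mismapping and
#' other artefacts produce a flat background under the ploidy peaks).
#'
#' Two guards return the input unfiltered (with a warning and
#' `converged = FALSE`): non-convergence of the EM, and a fit that would
#' discard more than half the sites - on strongly discrete balance
#' distributions (low, integer read depths) the flat component can soak up
#' the mass between depth atoms, which is a mis-specification of the noise
#' model rather than evidence of contamination.
#'
#' @param balances numeric vector of allele balances (>= 50).
#' @param lo,hi the balance window imposed by the extraction thresholds
#'   (defaults 0.2 and 0.8, matching `maf_min = 0.2`); the noise component
#'   is uniform over this window.
#' @param max_iter EM iteration cap.
#' @return list with `balances` (retained), `retained_fraction`, and
#'   `converged`.
#' @export
denoise <- function(balances, lo = 0.2, hi = 0.8, max_iter = 3000) {
  if (length(balances) < 50) stop("denoise needs at least 50 balances")
  fit <- balance_mixture_em(balances, lo = lo, hi = hi, max_iter = max_iter)
  if (!fit$converged) {
    warning("denoise EM did not converge; returning input unfiltered")
    return(list(balances = balances, retained_fraction = 1, converged = FALSE))
  }
  keep <- max.col(fit$resp) != ncol(fit$resp)
  if (mean(keep) < 0.5) {
    warning("denoise would discard over half the sites (noise model ",
            "mis-specified for this balance distribution); returning input ",
            "unfiltered")
    return(list(balances = balances, retained_fraction = 1, converged = FALSE))
  }
  list(balances = balances[keep],
       retained_fraction = mean(keep), converged = TRUE)
}

ploidy_models <- list(diploid = 1 / 2, triploid = c(1 / 3, 2 / 3),
                      tetraploid = c(1 / 4, 2 / 4, 3 / 4))

# Log-likelihood of a truncated-Gaussian mixture on [lo, hi] with shared sd.
tmix_loglik <- function(x, means, sd, weights, lo, hi) {
  sd <- max(sd, 1e-4)
  z <- stats::pnorm(hi, means, sd) - stats::pnorm(lo, means, sd)
  z <- pmax(z, 1e-12)
  dens <- vapply(seq_along(means), function(j)
    weights[j] * stats::dnorm(x, means[j], sd) / z[j], numeric(length(x)))
  tot <- if (is.matrix(dens)) rowSums(dens) else sum(dens)
  sum(log(pmax(tot, 1e-300)))
}

softmax <- function(l) { e <- exp(l - max(l)); e / sum(e) }

# Maximize the truncated-mixture likelihood by direct numerical
# optimization (Nelder-Mead over log-sd, weight logits and, for the free
# model, logit-window means). Returns the best of the supplied starts; the
# value can only improve on each start's likelihood.
fit_tmix <- function(x, means, lo, hi, free_means = FALSE,
                     sd_start = 0.08, weight_start = NULL) {
  k <- length(means)
  if (is.null(weight_start)) weight_start <- rep(1 / k, k)
  to_mean <- function(m) lo + (hi - lo) * stats::plogis(m)
  from_mean <- function(mu) stats::qlogis(pmin(pmax((mu - lo) / (hi - lo),
                                                    1e-6), 1 - 1e-6))
  obj <- function(par) {
    s <- exp(par[1])
    wl <- if (k > 1) c(0, par[2:k]) else 0
    mu <- if (free_means) to_mean(par[(k + 1):(2 * k)]) else means
    -tmix_loglik(x, mu, s, softmax(wl), lo, hi)
  }
  par0 <- c(log(sd_start),
            if (k > 1) log(pmax(weight_start[-1], 1e-8) /
                             pmax(weight_start[1], 1e-8)),
            if (free_means) from_mean(means))
  fit <- stats::optim(par0, obj, method = if (length(par0) > 1)
    "Nelder-Mead" else "Brent",
    lower = if (length(par0) == 1) -12 else -Inf,
    upper = if (length(par0) == 1) 3 else Inf,
    control = list(maxit = 2000))
  s <- exp(fit$par[1])
  wl <- if (k > 1) c(0, fit$par[2:k]) else 0
  mu <- if (free_means) to_mean(fit$par[(k + 1):(2 * k)]) else means
  list(loglik = -fit$value, means = mu, sd = s, weights = softmax(wl))
}

#' Maximum-likelihood ploidy call from allele balances
#'
#' Fits one truncated-Gaussian mixture per fixed ploidy model (component
#' means pinned at k/m: diploid \{1/2\}, triploid \{1/3, 2/3\}, tetraploid
#' \{1/4, 1/2, 3/4\}; free weights, one shared free standard deviation) and
#' a free model (three components with free means), all truncated to the
#' balance window \[`lo`, `hi`\] imposed by the extraction thresholds.
#' The free model is additionally started from each fixed model's optimum,
#' so its log-likelihood can never fall below any fixed model's.
#'
#' The per-model gap is (lnL_free - lnL_fixed)/|lnL_free|. The call is the
#' lowest ploidy among the models whose gap is within 1% (relative) of the
#' smallest gap - nested fixed models (a tetraploid mixture can empty its
#' outer components onto the diploid model) make parsimony the only
#' defensible tie-break - and the fit is flagged ambiguous whenever more
#' than one model falls inside that band.
#'
#' @param balances numeric vector of (denoised) allele balances (>= 100).
#' @param lo,hi balance window from the extraction thresholds
#'   (defaults 0.2, 0.8).
#' @return a `ploidy_fit` with per-model log-likelihoods, gaps, the call and
#'   the ambiguity flag.
#' @export
call_ploidy <- function(balances, lo = 0.2, hi = 0.8) {
  if (length(balances) < 100)
    stop("ploidy call needs at least 100 balances")
  fixed <- lapply(ploidy_models, function(m)
    fit_tmix(balances, m, lo, hi, free_means = FALSE))
  starts <- c(
    lapply(fixed, function(f)
      list(means = rep(f$means, length.out = 3), sd = f$sd,
           weights = {
             w <- rep(f$weights, length.out = 3); w / sum(w)
           })),
    list(list(means = c(0.3, 0.5, 0.7), sd = 0.08, weights = rep(1 / 3, 3))))
  free_fits <- lapply(starts, function(st)
    fit_tmix(balances, st$means, lo, hi, free_means = TRUE,
             sd_start = st$sd, weight_start = st$weights))
  free <- free_fits[[which.max(vapply(free_fits, `[[`, numeric(1), "loglik"))]]
  ll_fixed <- vapply(fixed, `[[`, numeric(1), "loglik")
  # nesting guard: the free model contains every fixed model
  if (free$loglik < max(ll_fixed)) {
    best_fixed <- fixed[[which.max(ll_fixed)]]
    free <- list(loglik = best_fixed$loglik,
                 means = rep(best_fixed$means, length.out = 3),
                 sd = best_fixed$sd, weights = rep(1 / 3, 3))
  }
  gaps <- (free$loglik - ll_fixed) / max(abs(free$loglik), 1)
  gaps <- pmax(gaps, 0)
  gmin <- min(gaps)
  in_band <- (gaps - gmin) <= 0.01
  call <- names(ploidy_models)[which(in_band)[1]]
  structure(list(loglik_fixed = ll_fixed, loglik_free = free$loglik,
                 gaps = gaps, call = call,
                 ambiguous = sum(in_band) > 1, free_means = free$means,
                 n_balances = length(balances)),
            class = "ploidy_fit")
}

#' @exportS3Method base::print
print.ploidy_fit <- function(x, ...) {
  cat(sprintf("ploidy call: %s%s (n = %d balances)\n", x$call,
              if (x$ambiguous) " [ambiguous]" else "", x$n_balances))
  for (m in names(x$loglik_fixed))
    cat(sprintf("  %s: lnL %.1f, gap %.4g\n", m, x$loglik_fixed[[m]],
                x$gaps[[m]]))
  cat(sprintf("  free: lnL %.1f (means %s)\n", x$loglik_free,
              paste(sprintf("%.3f", sort(x$free_means)), collapse = ", ")))
  invisible(x)
}

#' Simulate allele balances for a known ploidy (synthetic)
#'
#' Synthetic generator for testing the ploidy caller: per site, a true
#' allele dosage k of m is drawn uniformly over 1..(m-1), the read depth
#' from Poisson(`depth_mean`), and the alternate-read count from
#' Binomial(depth, k/m); a fraction `noise_rate` of sites is replaced by
#' uniform noise. The extraction thresholds (coverage, minor fraction) are
#' then applied as in [extract_allele_balance()].
#'
#' @param ploidy 2, 3 or 4.
#' @param n_sites sites to simulate before filtering.
#' @param depth_mean mean read depth (default 30).
#' @param noise_rate fraction of noise sites (default 0).
#' @param min_cov,maf_min extraction thresholds (defaults 10 and 0.2).
#' @param seed integer seed.
#' @return numeric vector of allele balances passing the thresholds.
#' @export
simulate_allele_balances <- function(ploidy, n_sites, depth_mean = 30,
                                     noise_rate = 0, min_cov = 10,
                                     maf_min = 0.2, seed = NULL) {
  stopifnot(ploidy %in% 2:4)
  run <- function() {
    k <- sample(seq_len(ploidy - 1), n_sites, replace = TRUE)
    dp <- stats::rpois(n_sites, depth_mean)
    alt <- stats::rbinom(n_sites, dp, k / ploidy)
    b <- alt / dp
    noisy <- stats::runif(n_sites) < noise_rate
    b[noisy] <- stats::runif(sum(noisy))
    keep <- !is.na(b) & dp >= min_cov & pmin(b, 1 - b) >= maf_min
    b[keep]
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}
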