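# Shared feature preparation: drop constant columns (warning), clamp the
# rare infinite statistic (e.g. a Nei distance between fixed groups) to a
# large finite sentinel so the forests can split on it.
prep_features <- function(stats, keep = NULL) {
  x <- as.matrix(stats)
  if (anyNA(x)) stop("summary statistics contain NA")
  if (any(!is.finite(x))) x[] <- pmax(pmin(x, 1e6), -1e6)
  if (is.null(keep)) {
    v <- apply(x, 2, stats::var)
    keep <- v > 0
    if (any(!keep))
      warning("dropping constant statistic column(s): ",
              paste(colnames(x)[!keep], collapse = ", "))
  }
  list(x = x[, keep, drop = FALSE], keep = keep)
}

#' Train an ABC-RF scenario classifier
#'
#' Fits a classification random forest to a reference table's summary
#' statistics with the scenario label as response, optionally augmented by
#' the linear discriminant axes of the statistics (fit on the scenario
#' labels). The out-of-bag (OOB) misclassification rate is the ABC-RF prior
#' error rate. A companion regression forest on the OOB misclassification
#' indicator supports the posterior-probability estimate of
#' [classify_observed()].
#'
#' @param reftable a `reference_table` from [build_reference_table()] (>= 2
#'   scenarios).
#' @param n_trees number of trees (default 1000).
#' @param use_lda append LDA axes of the statistics as extra features.
#' @param seed integer seed for forest construction.
#' @return a `scenario_classifier` with elements `forest`, `post_forest`,
#'   `oob_error`, `n_trees`, `scenarios`, `use_lda`.
#' @export
train_model_choice <- function(reftable, n_trees = 1000, use_lda = TRUE,
                               seed = 1L) {
  y <- factor(reftable$labels)
  if (nlevels(y) < 2) stop("model choice needs at least 2 scenarios")
  pf <- prep_features(reftable$stats)
  lda_fit <- NULL
  feats <- pf$x
  if (use_lda) {
    lda_fit <- MASS::lda(pf$x, grouping = y)
    feats <- cbind(feats, stats::predict(lda_fit, pf$x)$x)
  }
  df <- data.frame(feats, check.names = FALSE)
  df$.scenario <- y
  forest <- ranger::ranger(
    dependent.variable.name = ".scenario", data = df,
    num.trees = n_trees, mtry = floor(sqrt(ncol(feats))),
    seed = as.integer(seed), num.threads = 1)
  oob_pred <- forest$predictions
  ok <- !is.na(oob_pred)
  miss <- as.numeric(oob_pred[ok] != y[ok])
  df2 <- data.frame(feats[ok, , drop = FALSE], check.names = FALSE)
  df2$.miss <- miss
  post_forest <- ranger::ranger(
    dependent.variable.name = ".miss", data = df2,
    num.trees = n_trees, mtry = max(1L, floor(ncol(feats) / 3)),
    seed = as.integer(seed) + 1L, num.threads = 1)
  structure(list(forest = forest, post_forest = post_forest, lda = lda_fit,
                 keep = pf$keep, stat_names = colnames(reftable$stats),
                 oob_error = forest$prediction.error,
                 n_trees = n_trees, scenarios = levels(y),
                 use_lda = use_lda),
            class = "scenario_classifier")
}

#' @exportS3Method base::print
print.scenario_classifier <- function(x, ...) {
  cat(sprintf("ABC-RF scenario classifier: %s; %d trees; OOB prior error %.3f\n",
              paste(x$scenarios, collapse = " vs "), x$n_trees, x$oob_error))
  invisible(x)
}

classifier_features <- function(clf, observed) {
  obs <- rbind(observed)
  if (!identical(colnames(obs), clf$stat_names)) {
    if (is.null(colnames(obs)) || !all(clf$stat_names %in% colnames(obs)))
      stop("observed statistics do not match the reference schema")
    obs <- obs[, clf$stat_names, drop = FALSE]
  }
  obs[!is.finite(obs)] <- pmax(pmin(obs[!is.finite(obs)], 1e6), -1e6)
  x <- obs[, clf$keep, drop = FALSE]
  if (clf$use_lda) x <- cbind(x, stats::predict(clf$lda, x)$x)
  data.frame(x, check.names = FALSE)
}

#' Classify an observed dataset among competing scenarios
#'
#' Drops the observed summary-statistic vector down the trained forest and
#' tallies the per-tree votes. The posterior probability of the selected
#' scenario is 1 minus the local OOB misclassification rate predicted by the
#' companion regression forest at the observed statistics, clipped to
#' \[0, 1\].
#'
#' @param clf a `scenario_classifier` from [train_model_choice()].
#' @param observed a named statistic vector from [summary_vector()] using
#'   the reference schema.
#' @return a `model_choice_result` with `votes` (named, summing to
#'   `n_trees`), `selected`, `posterior_prob`, `oob_error`, `n_trees`.
#' @export
classify_observed <- function(clf, observed) {
  newdata <- classifier_features(clf, observed)
  pred <- stats::predict(clf$forest, data = newdata, predict.all = TRUE,
                         num.threads = 1)
  tree_classes <- as.vector(pred$predictions)
  votes <- tabulate(tree_classes, nbins = length(clf$scenarios))
  names(votes) <- clf$scenarios
  sel <- clf$scenarios[which.max(votes)]
  loc_err <- stats::predict(clf$post_forest, data = newdata,
                            num.threads = 1)$predictions
  structure(list(votes = votes, selected = sel,
                 posterior_prob = min(max(1 - loc_err, 0), 1),
                 oob_error = clf$oob_error, n_trees = clf$n_trees,
                 use_lda = clf$use_lda),
            class = "model_choice_result")
}

#' @exportS3Method base::print
print.model_choice_result <- function(x, ...) {
  cat("ABC-RF model choice:", x$n_trees, "trees\n")
  print(x$votes)
  cat(sprintf("selected: %s (posterior probability %.2f; OOB prior error %.3f)\n",
              x$selected, x$posterior_prob, x$oob_error))
  invisible(x)
}

#' Scenarios advancing from a round of the sequential tournament
#'
#' A scenario advances when its vote count strictly exceeds the round
#' average `n_trees / k` for `k` scenarios in the round ("more than the
#' average number of votes"); a tie with the threshold does not advance.
#'
#' @param votes named integer vector of votes in the round.
#' @param n_trees total trees (votes sum).
#' @return character vector of advancing scenario labels.
#' @export
advance_scenarios <- function(votes, n_trees) {
  names(votes)[votes > n_trees / length(votes)]
}

#' Tournament plan for sequential scenario comparison
#'
#' Preliminary rounds each compare an explicit scenario subset; the final
#' round compares the union of all scenarios that advanced (vote count
#' strictly above trees/k in their round). With a single round the
#' tournament degenerates to one [classify_observed()] call.
#'
#' @param rounds list of character vectors (scenario labels per preliminary
#'   round); with `length(rounds) == 1` that round is final.
#' @return a `tournament_plan`.
#' @export
tournament_plan <- function(rounds) {
  stopifnot(length(rounds) >= 1, all(lengths(rounds) >= 1))
  structure(list(rounds = lapply(rounds, as.character)),
            class = "tournament_plan")
}

#' Run a sequential scenario-choice tournament
#'
#' For each preliminary round, trains a classifier on the reference rows of
#' that round's scenarios, records votes for the observed data and advances
#' scenarios with strictly more than trees/k votes (if none, the top-voted
#' scenario advances with a warning). The final round compares all
#' advancers and decides.
#'
#' @param plan a [tournament_plan()] covering every scenario of interest.
#' @param reftable a `reference_table` holding rows for every scenario in
#'   the plan.
#' @param observed named statistic vector.
#' @param n_trees trees per round (default 1000).
#' @param use_lda append LDA axes (default TRUE).
#' @param seed integer seed.
#' @param cache optional environment to reuse per-subset classifiers across
#'   repeated calls with the same reference table.
#' @return list with `result` (final `model_choice_result`), `selected`, and
#'   `audit` (per-round votes, threshold and advancement).
#' @export
run_tournament <- function(plan, reftable, observed, n_trees = 1000,
                           use_lda = TRUE, seed = 1L, cache = NULL) {
  stopifnot(inherits(plan, "tournament_plan"))
  get_clf <- function(subset) {
    subset <- sort(unique(subset))
    key <- paste(subset, collapse = "|")
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    rows <- reftable$labels %in% subset
    sub <- reftable
    sub$labels <- reftable$labels[rows]
    sub$params <- reftable$params[rows, , drop = FALSE]
    sub$stats <- reftable$stats[rows, , drop = FALSE]
    clf <- suppressWarnings(train_model_choice(sub, n_trees = n_trees,
                                               use_lda = use_lda, seed = seed))
    if (!is.null(cache)) cache[[key]] <- clf
    clf
  }
  audit <- list()
  rounds <- plan$rounds
  prelim <- if (length(rounds) > 1) rounds[-length(rounds)] else list()
  explicit_final <- if (length(rounds) > 1) rounds[[length(rounds)]] else rounds[[1]]
  advanced <- character(0)
  for (r in seq_along(prelim)) {
    subset <- prelim[[r]]
    if (length(subset) < 2) { advanced <- c(advanced, subset); next }
    res <- classify_observed(get_clf(subset), observed)
    adv <- advance_scenarios(res$votes, res$n_trees)
    if (!length(adv)) {
      warning("no scenario exceeded the round threshold; advancing the top-voted")
      adv <- names(res$votes)[which.max(res$votes)]
    }
    audit[[length(audit) + 1]] <- list(
      round = r, scenarios = subset, votes = res$votes,
      threshold = res$n_trees / length(subset), advanced = adv)
    advanced <- c(advanced, adv)
  }
  final_set <- unique(c(explicit_final, advanced))
  if (length(final_set) < 2) {
    res <- structure(list(votes = stats::setNames(n_trees, final_set),
                          selected = final_set, posterior_prob = NA_real_,
                          oob_error = NA_real_, n_trees = n_trees,
                          use_lda = use_lda), class = "model_choice_result")
  } else {
    res <- classify_observed(get_clf(final_set), observed)
  }
  audit[[length(audit) + 1]] <- list(
    round = length(prelim) + 1, scenarios = final_set, votes = res$votes,
    threshold = res$n_trees / length(final_set),
    advanced = res$selected, final = TRUE)
  list(result = res, selected = res$selected, audit = audit)
}

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- (cumsum(w) - w / 2) / sum(w)
  stats::approx(cw, x, xout = probs, rule = 2, ties = "ordered")$y
}

#' Regression-adjusted ABC parameter estimation
#'
#' Selects the fraction `tolerance` of reference simulations closest to the
#' observed statistics (Euclidean distance on statistics standardized by
#' reference-table median absolute deviation), logit-transforms each
#' parameter to its prior bounds, adjusts the accepted draws by weighted
#' local-linear regression on the statistics (Epanechnikov weights), and
#' back-transforms, which guarantees the adjusted draws respect the prior
#' bounds.
#'
#' @param reftable a `reference_table` restricted to the selected scenario
#'   (single label).
#' @param observed named statistic vector.
#' @param priors the [prior_set()] the table was simulated from; supplies
#'   the logit bounds per parameter.
#' @param tolerance accepted fraction of reference rows (default 0.01);
#'   the table must hold at least `1/tolerance` rows.
#' @param params parameters to estimate (default: all columns of the
#'   table's parameter draws).
#' @return a `parameter_posterior`: per parameter the accepted raw and
#'   adjusted draws, importance weights, point estimates (weighted mean and
#'   median) and 5%/50%/95% quantiles; plus the tolerance and transform
#'   record.
#' @export
estimate_parameters <- function(reftable, observed, priors, tolerance = 0.01,
                                params = NULL, ridge = 0.01) {
  if (length(unique(reftable$labels)) != 1)
    warning("reference table holds several scenarios; estimating over all rows")
  n <- nrow(reftable$stats)
  if (n < 1 / tolerance)
    stop("reference table smaller than 1/tolerance rows")
  if (is.null(params)) params <- colnames(reftable$params)
  pf <- prep_features(reftable$stats)
  obs <- rbind(observed)[, clf_names <- colnames(reftable$stats), drop = FALSE]
  obs <- obs[, pf$keep, drop = FALSE]
  med <- apply(pf$x, 2, stats::median)
  mad_ <- apply(pf$x, 2, stats::mad)
  usable <- mad_ > 0
  xs <- sweep(sweep(pf$x[, usable, drop = FALSE], 2, med[usable]), 2,
              mad_[usable], "/")
  os <- (obs[, usable, drop = FALSE] - med[usable]) / mad_[usable]
  d <- sqrt(rowSums(sweep(xs, 2, as.numeric(os))^2))
  n_keep <- max(2L, ceiling(tolerance * n))
  sel <- order(d)[seq_len(n_keep)]
  dmax <- max(d[sel])
  w <- if (dmax == 0) rep(1, n_keep) else 1 - (d[sel] / dmax)^2
  w[w <= 0] <- min(w[w > 0], 1e-8)
  X <- sweep(xs[sel, , drop = FALSE], 2, as.numeric(os))
  post <- list()
  for (p in params) {
    pr <- priors$priors[[p]]
    if (is.null(pr)) stop("no prior recorded for parameter ", p)
    a <- pr$min; b <- pr$max
    theta <- reftable$params[[p]][sel]
    log_scale <- pr$dist == "logunif"
    th <- if (log_scale) log(theta) else theta
    lo <- if (log_scale) log(a) else a
    hi <- if (log_scale) log(b) else b
    eps <- 1e-6 * (hi - lo)
    thc <- pmin(pmax(th, lo + eps), hi - eps)
    z <- log((thc - lo) / (hi - thc))
    # weighted local-linear solve with a light ridge penalty on the slopes
    # (stabilizes the adjustment when the accepted sample is small relative
    # to the statistic dimension); the intercept is unpenalized
    Xd <- cbind(1, X)
    A <- crossprod(Xd * w, Xd)
    pen <- diag(c(0, rep(ridge * mean(diag(A)[-1]), ncol(X))))
    beta_all <- tryCatch(solve(A + pen, crossprod(Xd * w, z)),
                         error = function(e) NULL)
    if (is.null(beta_all) || anyNA(beta_all)) {
      warning("singular local regression for ", p,
              "; falling back to rejection-only posterior")
      z_adj <- z
    } else {
      beta <- beta_all[-1]
      z_adj <- z - as.numeric(X %*% beta)
    }
    adj <- lo + (hi - lo) * stats::plogis(z_adj)
    if (log_scale) adj <- exp(adj)
    q <- weighted_quantile(adj, w, c(0.05, 0.5, 0.95))
    post[[p]] <- list(
      raw = theta, adjusted = adj, weights = w,
      mean = sum(w * adj) / sum(w), median = q[2],
      q05 = q[1], q95 = q[3],
      transform = list(type = if (log_scale) "log-logit" else "logit",
                       lower = a, upper = b))
  }
  structure(list(parameters = post, tolerance = tolerance,
                 n_accepted = n_keep, distance = d[sel]),
            class = "parameter_posterior")
}

#' @exportS3Method base::print
print.parameter_posterior <- function(x, ...) {
  cat(sprintf("ABC posterior (tolerance %g, %d accepted draws)\n",
              x$tolerance, x$n_accepted))
  for (p in names(x$parameters)) {
    pp <- x$parameters[[p]]
    cat(sprintf("  %s: mean %.3g, median %.3g, 5%%-95%% [%.3g, %.3g]\n",
                p, pp$mean, pp$median, pp$q05, pp$q95))
  }
  invisible(x)
}

#' Posterior-predictive model check
#'
#' Simulates `n_sims` datasets under the selected scenario with parameters
#' resampled from the adjusted posterior, recomputes the summary statistics
#' and, for each statistic, reports the two-tailed empirical p-value
#' 2 min(F(obs), 1 - F(obs)) of the observed value within the simulated
#' distribution, plus the count significant at `alpha` (overall and on an
#' optional held-out subset of statistics not used upstream).
#'
#' @param spec the selected [scenario()].
#' @param posterior a `parameter_posterior` from [estimate_parameters()].
#' @param observed named statistic vector.
#' @param schema the [sumstat_schema()] in force.
#' @param n_loci SNP loci per simulated dataset (match the observed data).
#' @param n_sims posterior-predictive simulations (>= 100).
#' @param alpha significance level (default 0.05).
#' @param holdout character vector of statistic names held out upstream.
#' @param maf_min per-locus MAF rejection threshold (default 0.05).
#' @param seed integer seed.
#' @return a `model_check_report`: per-statistic table plus significant
#'   counts.
#' @export
model_check <- function(spec, posterior, observed, schema, n_loci, n_sims,
                        alpha = 0.05, holdout = NULL, maf_min = 0.05,
                        seed = 1L) {
  if (n_sims < 100) stop("n_sims below 100 gives unstable tail p-values")
  pm <- scenario_popmap(spec)
  draws <- posterior_draw_frame(posterior)
  w <- posterior$parameters[[1]]$weights
  sims <- withr::with_seed(as.integer(seed), {
    idx <- sample.int(nrow(draws), n_sims, replace = TRUE, prob = w)
    t(vapply(idx, function(i) {
      gm <- simulate_snps(spec, draws[i, , drop = FALSE], n_loci = n_loci,
                          maf_min = maf_min)
      summary_vector(gm, pm, schema)
    }, numeric(sumstat_length(schema))))
  })
  obs <- rbind(observed)[1, colnames(sims)]
  pvals <- vapply(seq_along(obs), function(j) {
    f <- mean(sims[, j] <= obs[j])
    min(1, 2 * min(f, 1 - f))
  }, numeric(1))
  tab <- data.frame(stat = colnames(sims), observed = as.numeric(obs),
                    sim_quantile = vapply(seq_along(obs), function(j)
                      mean(sims[, j] <= obs[j]), numeric(1)),
                    p = pvals, significant = pvals < alpha,
                    holdout = colnames(sims) %in% (holdout %||% character()),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, alpha = alpha,
                 n_significant = sum(tab$significant),
                 n_stats = nrow(tab),
                 n_significant_holdout = sum(tab$significant & tab$holdout),
                 n_holdout = sum(tab$holdout),
                 n_sims = n_sims),
            class = "model_check_report")
}

posterior_draw_frame <- function(posterior) {
  as.data.frame(lapply(posterior$parameters, `[[`, "adjusted"))
}

#' @exportS3Method base::print
print.model_check_report <- function(x, ...) {
  cat(sprintf("model check: %d of %d statistics significant at alpha=%g (%d sims)\n",
              x$n_significant, x$n_stats, x$alpha, x$n_sims))
  if (x$n_holdout > 0)
    cat(sprintf("  held-out subset: %d of %d significant\n",
                x$n_significant_holdout, x$n_holdout))
  invisible(x)
}
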