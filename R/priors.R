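#' Prior distributions for scenario parameters
#'
#' `prior_unif` and `prior_logunif` describe uniform and log-uniform priors
#' with finite bounds; `integer = TRUE` rounds draws to whole numbers.
#' `prior_set` bundles named priors with optional cross-parameter
#' constraints, written as character expressions in the parameter names
#' (e.g. `"t_EAU > t_WAU"`), enforced by rejection sampling.
#'
#' @param min,max finite bounds.
#' @param integer round draws to integers.
#' @return a `prior` / `prior_set` object.
#' @export
prior_unif <- function(min, max, integer = FALSE) {
  stopifnot(is.finite(min), is.finite(max), min < max)
  structure(list(dist = "unif", min = min, max = max, integer = integer),
            class = "prior")
}

#' @rdname prior_unif
#' @export
prior_logunif <- function(min, max, integer = FALSE) {
  stopifnot(is.finite(min), is.finite(max), 0 < min, min < max)
  structure(list(dist = "logunif", min = min, max = max, integer = integer),
            class = "prior")
}

#' @rdname prior_unif
#' @param priors named list of `prior` objects.
#' @param constraints character vector of constraint expressions.
#' @export
prior_set <- function(priors, constraints = character()) {
  stopifnot(is.list(priors), length(names(priors)) == length(priors))
  stopifnot(all(vapply(priors, inherits, logical(1), "prior")))
  structure(list(priors = priors, constraints = constraints),
            class = "prior_set")
}

draw_one <- function(pr) {
  x <- switch(pr$dist,
              unif = stats::runif(1, pr$min, pr$max),
              logunif = exp(stats::runif(1, log(pr$min), log(pr$max))))
  if (pr$integer) round(x) else x
}

#' Draw parameter values from a prior set
#'
#' Draws respect bounds, integer rounding and all constraints (by rejection
#' sampling). If more than 99.9% of proposals are rejected the constraints
#' are considered unsatisfiable in practice and an error is raised.
#'
#' @param priors a [prior_set()].
#' @param n number of joint draws.
#' @param seed optional integer seed.
#' @return data.frame with `n` rows, one column per parameter.
#' @export
draw_parameters <- function(priors, n = 1, seed = NULL) {
  stopifnot(inherits(priors, "prior_set"))
  run <- function() {
    out <- vector("list", n)
    tries <- 0L; got <- 0L
    while (got < n) {
      draw <- lapply(priors$priors, draw_one)
      tries <- tries + 1L
      ok <- all(vapply(priors$constraints, function(cn)
        isTRUE(eval(parse(text = cn), envir = draw)), logical(1)))
      if (ok) { got <- got + 1L; out[[got]] <- draw }
      if (tries >= 1000L && got / tries < 0.001)
        stop("constraint rejection rate above 99.9%; revise the priors")
    }
    as.data.frame(do.call(rbind, lapply(out, function(d)
      unlist(d, use.names = TRUE))))
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Build an ABC reference table
#'
#' For each scenario, draws `n_per_scenario` parameter vectors from the
#' priors, simulates a SNP dataset per draw and computes the fixed-order
#' summary-statistic vector. All scenarios must sample the same deme names
#' (the schema's group list).
#'
#' @param scenarios list of [scenario()] objects (>= 2 for model choice).
#' @param priors a [prior_set()] shared by all scenarios (each scenario uses
#'   the parameters it references).
#' @param n_per_scenario simulated datasets per scenario.
#' @param schema a [sumstat_schema()]; its groups must be the sampled demes.
#' @param n_loci SNP loci per simulated dataset.
#' @param maf_min per-locus overall-MAF rejection threshold (default 0.05).
#' @param seed integer seed governing the whole table.
#' @return a `reference_table`: list with `labels` (scenario per row),
#'   `params` (data.frame of draws), `stats` (rows x statistics matrix) and
#'   `provenance` (seed, schema version, n per scenario, n_loci).
#' @export
build_reference_table <- function(scenarios, priors, n_per_scenario, schema,
                                  n_loci, maf_min = 0.05, seed = 1L) {
  labs <- vapply(scenarios, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop("duplicate scenario labels")
  for (sc in scenarios) {
    pm <- scenario_popmap(sc)
    if (!setequal(unique(pm$group), schema$groups))
      stop("scenario ", sc$label, " samples demes ",
           paste(unique(pm$group), collapse = ","),
           " but schema expects ", paste(schema$groups, collapse = ","))
  }
  withr::with_seed(as.integer(seed), {
    rows_lab <- character(0)
    rows_par <- list()
    rows_stat <- list()
    for (sc in scenarios) {
      pm <- scenario_popmap(sc)
      draws <- draw_parameters(priors, n_per_scenario)
      for (i in seq_len(n_per_scenario)) {
        gm <- simulate_snps(sc, draws[i, , drop = FALSE], n_loci = n_loci,
                            maf_min = maf_min)
        rows_stat[[length(rows_stat) + 1L]] <- summary_vector(gm, pm, schema)
      }
      rows_lab <- c(rows_lab, rep(sc$label, n_per_scenario))
      rows_par[[length(rows_par) + 1L]] <- draws
    }
    structure(list(
      labels = rows_lab,
      params = do.call(rbind, rows_par),
      stats = do.call(rbind, rows_stat),
      provenance = list(seed = as.integer(seed), schema = schema$version,
                        groups = schema$groups,
                        n_per_scenario = n_per_scenario, n_loci = n_loci,
                        maf_min = maf_min)),
      class = "reference_table")
  })
}

#' @exportS3Method base::print
print.reference_table <- function(x, ...) {
  cat(sprintf("reference_table: %d rows (%s), %d statistics, %d loci each\n",
              length(x$labels),
              paste(unique(x$labels), collapse = ", "),
              ncol(x$stats), x$provenance$n_loci))
  invisible(x)
}

#' Write / read a reference table as TSV plus a JSON provenance sidecar
#' @param reftable a `reference_table`.
#' @param path base path; writes `<path>.tsv` and `<path>.provenance.json`.
#' @export
write_reference_table <- function(reftable, path) {
  df <- data.frame(scenario = reftable$labels, reftable$params,
                   reftable$stats, check.names = FALSE)
  utils::write.table(df, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(reftable$provenance, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate a ddRADseq-like sequencing layer over perfect genotypes
#'
#' Adds, per genotype, a negative-binomial total read depth (mean
#' `depth_mean`, dispersion `depth_shape`: variance = mu + mu^2/shape),
#' allele depths consistent with the genotype (heterozygotes draw
#' alternate-allele reads as Binomial(DP, 1/2)), random genotype missingness
#' at rate `missing_rate`, and optionally `n_extra_snps_per_locus` perfectly
#' linked copies of each SNP within its RAD locus, so that the
#' one-SNP-per-locus thinning stage has work to do.
#'
#' @param gm a [genotype_matrix()] from [simulate_snps()].
#' @param depth_mean mean per-genotype read depth (default 22, emulating the
#'   ~22x mean RAD-locus coverage of typical ddRADseq runs).
#' @param depth_shape negative-binomial size parameter (default 7, giving an
#'   SD near 9.5 at mean 22).
#' @param missing_rate per-genotype missingness probability in \[0, 1\].
#' @param n_extra_snps_per_locus linked duplicate SNPs added per locus.
#' @param seed integer seed.
#' @return a [genotype_matrix()] with depth and allele-depth matrices.
#' @export
add_sequencing_layer <- function(gm, depth_mean = 22, depth_shape = 7,
                                 missing_rate = 0, n_extra_snps_per_locus = 0L,
                                 seed = NULL) {
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must be in [0, 1]")
  run <- function() {
    geno <- gm$genotypes
    loci <- gm$loci
    if (n_extra_snps_per_locus > 0) {
      reps <- rep(seq_len(nrow(geno)), each = 1L + n_extra_snps_per_locus)
      geno <- geno[reps, , drop = FALSE]
      loci <- loci[reps, , drop = FALSE]
      loci$pos <- stats::ave(loci$pos, rep(seq_len(nrow(gm$loci)),
                                           each = 1L + n_extra_snps_per_locus),
                             FUN = seq_along)
    }
    n <- length(geno)
    dp <- matrix(stats::rnbinom(n, mu = depth_mean, size = depth_shape),
                 nrow(geno))
    alt <- matrix(0L, nrow(geno), ncol(geno))
    alt[geno == 2L] <- dp[geno == 2L]
    het <- which(geno == 1L)
    alt[het] <- stats::rbinom(length(het), dp[het], 0.5)
    ref <- dp - alt
    if (missing_rate > 0) {
      drop <- matrix(stats::runif(n) < missing_rate, nrow(geno))
      geno[drop] <- NA_integer_
    }
    genotype_matrix(geno, gm$samples, loci, depth = dp,
                    ad_ref = ref, ad_alt = alt)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}
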