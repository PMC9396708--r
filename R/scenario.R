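#' Define a demographic scenario
#'
#' A scenario is a set of named demes (with diploid effective size and
#' diploid sample count) plus a list of events stated backwards in time:
#' [ev_size()] changes a deme's Ne, [ev_merge()] moves a child deme's
#' lineages into its parent (the forward-time founding of the child), and
#' [ev_admix()] moves each of a recipient's lineages to a donor with a given
#' probability (the forward-time admixture proportion contributed by the
#' donor). Ghost populations are demes with zero samples. Any numeric field
#' may instead be a character expression in prior parameter names (e.g.
#' `time = "t_inv - db"`), resolved by [instantiate_scenario()].
#'
#' @param label scenario identifier.
#' @param demes named list of [deme()] entries.
#' @param events list of [ev_size()], [ev_merge()], [ev_admix()] entries.
#' @return an object of class `scenario_spec`.
#' @export
scenario <- function(label, demes, events = list()) {
  if (is.null(names(demes)) || any(names(demes) == ""))
    stop("demes must be a named list")
  structure(list(label = label, demes = demes, events = events),
            class = "scenario_spec")
}

#' @rdname scenario
#' @param Ne diploid effective size (number or parameter expression).
#' @param samples diploid sample count (0 for a ghost deme).
#' @export
deme <- function(Ne, samples = 0L) list(Ne = Ne, samples = as.integer(samples))

#' @rdname scenario
#' @param time event time in generations before sampling.
#' @param pop,child,parent,recipient,donor deme names.
#' @param rate admixture proportion received from `donor`, in \[0, 1\].
#' @export
ev_size <- function(time, pop, Ne)
  list(type = "size", time = time, a = pop, b = NA, par = Ne)

#' @rdname scenario
#' @export
ev_merge <- function(time, child, parent)
  list(type = "merge", time = time, a = child, b = parent, par = NA)

#' @rdname scenario
#' @export
ev_admix <- function(time, recipient, donor, rate)
  list(type = "admix", time = time, a = recipient, b = donor, par = rate)

#' @exportS3Method base::print
print.scenario_spec <- function(x, ...) {
  cat("scenario", x$label, "-", length(x$demes), "demes,",
      length(x$events), "events\n")
  for (nm in names(x$demes))
    cat(sprintf("  %s: Ne=%s, samples=%d%s\n", nm,
                format(x$demes[[nm]]$Ne), x$demes[[nm]]$samples,
                if (x$demes[[nm]]$samples == 0) " (ghost)" else ""))
  for (e in x$events)
    cat(sprintf("  t=%s %s %s%s\n", format(e$time), e$type, e$a,
                if (!is.na(e$b)) paste0(" -> ", e$b) else ""))
  invisible(x)
}

# Evaluate a field that may be numeric or a parameter expression.
resolve_field <- function(x, params) {
  if (is.numeric(x)) return(x)
  v <- tryCatch(eval(parse(text = x), envir = as.list(params)),
                error = function(e) stop("cannot resolve scenario field '", x,
                                         "': ", conditionMessage(e)))
  as.numeric(v)
}

#' Bind prior parameter values into a scenario
#'
#' Replaces every parameter expression in deme sizes and events by its value
#' under `params`, returning a fully numeric scenario sorted by event time
#' (ties keep the stated order).
#'
#' @param spec a [scenario()].
#' @param params named list or single-row data.frame of parameter values.
#' @return a numeric `scenario_spec`.
#' @export
instantiate_scenario <- function(spec, params = list()) {
  params <- as.list(params)
  demes <- lapply(spec$demes, function(d)
    list(Ne = resolve_field(d$Ne, params), samples = d$samples))
  events <- lapply(spec$events, function(e) {
    e$time <- resolve_field(e$time, params)
    if (e$type %in% c("size", "admix")) e$par <- resolve_field(e$par, params)
    e
  })
  if (length(events)) {
    ord <- order(vapply(events, `[[`, numeric(1), "time"))
    events <- events[ord]
  }
  out <- scenario(spec$label, demes, events)
  attr(out, "instantiated") <- TRUE
  out
}

#' Validate a (numeric) scenario
#'
#' Checks that every event references a deme that is still active at the
#' event's time, that times are non-negative and admixture rates lie in
#' \[0, 1\], that ghost demes carry no samples by construction, and that
#' after all events exactly one deme remains active, so that every sampled
#' lineage reaches a common ancestor.
#'
#' @param spec an instantiated [scenario()] (see [instantiate_scenario()]).
#' @return the spec, invisibly, on success; otherwise an error naming the
#'   violated rule.
#' @export
validate_scenario <- function(spec) {
  nm <- names(spec$demes)
  for (d in nm) {
    dd <- spec$demes[[d]]
    if (!is.numeric(dd$Ne) || dd$Ne <= 0)
      stop("deme ", d, ": Ne must be a positive number (instantiate first?)")
    if (dd$samples < 0) stop("deme ", d, ": negative sample count")
  }
  active <- stats::setNames(rep(TRUE, length(nm)), nm)
  last_t <- 0
  for (e in spec$events) {
    if (!is.numeric(e$time) || e$time < 0)
      stop("event times must be non-negative numbers")
    if (e$time < last_t) stop("events not in time order after instantiation")
    last_t <- e$time
    for (d in c(e$a, if (!is.na(e$b)) e$b)) {
      if (!d %in% nm) stop("orphan deme in event: ", d)
      if (!active[[d]]) stop("deme inactive at event time: ", d,
                             " (t=", e$time, ")")
    }
    if (e$type == "admix" && (e$par < 0 || e$par > 1))
      stop("admixture rate outside [0,1]: ", e$par)
    if (e$type == "size" && e$par <= 0)
      stop("size change to non-positive Ne")
    if (e$type == "merge") active[[e$a]] <- FALSE
  }
  if (sum(active) != 1 && length(nm) > 1)
    stop("scenario does not funnel to a single ancestral deme (",
         sum(active), " demes still active)")
  invisible(spec)
}

#' Sample-to-population map implied by a scenario's sample configuration
#'
#' @param spec a [scenario()].
#' @return a [population_map()] with samples named `<deme>_<i>`.
#' @export
scenario_popmap <- function(spec) {
  sampled <- names(spec$demes)[vapply(spec$demes, `[[`, integer(1),
                                      "samples") > 0]
  samp <- unlist(lapply(sampled, function(d)
    paste0(d, "_", seq_len(spec$demes[[d]]$samples))))
  pop <- unlist(lapply(sampled, function(d)
    rep(d, spec$demes[[d]]$samples)))
  population_map(samp, pop)
}

#' Simulate unlinked biallelic SNP loci under a scenario
#'
#' One coalescent genealogy per locus; a single mutation placed uniformly on
#' the total branch length; the locus is redrawn while the overall-sample
#' minor allele frequency is below `maf_min`. Diploid genotypes are formed
#' by pairing consecutive sampled lineages within each deme (equivalent to
#' random pairing by exchangeability).
#'
#' @param spec a [scenario()].
#' @param params named parameter values bound into the scenario (see
#'   [instantiate_scenario()]); ignored fields already numeric.
#' @param n_loci number of SNP loci.
#' @param maf_min minimum overall minor allele frequency per locus
#'   (default 0.05, matching the data filter); 0 disables the rejection.
#' @param seed integer seed.
#' @param max_redraw redraw cap per locus before erroring (default 10000).
#' @return a [genotype_matrix()] (complete genotypes, no depths); the
#'   matching popmap is available via [scenario_popmap()].
#' @export
simulate_snps <- function(spec, params = list(), n_loci, maf_min = 0.05,
                          seed = NULL, max_redraw = 10000L) {
  inst <- if (isTRUE(attr(spec, "instantiated"))) spec else
    instantiate_scenario(spec, params)
  validate_scenario(inst)
  nm <- names(inst$demes)
  samples_per <- vapply(inst$demes, `[[`, integer(1), "samples")
  if (sum(samples_per) < 1) stop("scenario samples no deme")
  lineage_demes <- unlist(lapply(seq_along(nm), function(k)
    rep(k - 1L, 2L * samples_per[k])))
  ev <- inst$events
  type_code <- c(size = 1L, merge = 2L, admix = 3L)
  run <- function() .sim_snp_loci_cpp(
    as.integer(n_loci), as.integer(lineage_demes),
    vapply(inst$demes, function(d) as.numeric(d$Ne), numeric(1)),
    vapply(ev, function(e) type_code[[e$type]], integer(1)),
    vapply(ev, function(e) as.numeric(e$time), numeric(1)),
    vapply(ev, function(e) match(e$a, nm) - 1L, integer(1)),
    vapply(ev, function(e) if (is.na(e$b)) -1L else match(e$b, nm) - 1L,
           integer(1)),
    vapply(ev, function(e) if (is.na(e$par)) 0 else as.numeric(e$par),
           numeric(1)),
    as.numeric(maf_min), as.integer(max_redraw))
  hap <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  # pair consecutive lineages into diploids
  odd <- seq(1, ncol(hap), by = 2)
  geno <- hap[, odd, drop = FALSE] + hap[, odd + 1, drop = FALSE]
  pm <- scenario_popmap(inst)
  genotype_matrix(geno, pm$sample,
                  data.frame(locus = paste0("locus_", seq_len(n_loci)),
                             pos = 1L, ref = "A", alt = "T",
                             multiallelic = FALSE))
}
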