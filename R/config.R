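#' Read a scenario / prior configuration file
#'
#' The configuration is YAML with three top-level keys:
#' \preformatted{
#' priors:
#'   t_inv: {dist: unif, min: 38, max: 45}
#'   Nf:    {dist: logunif, min: 5, max: 500}
#' constraints: ["t_EAU > t_WAU"]
#' scenarios:
#'   - label: direct
#'     demes:
#'       NAT: {Ne: 1000, samples: 10}
#'       INV: {Ne: 1000, samples: 10}
#'     events:
#'       - {type: size,  time: t_inv - db, pop: INV, Ne: Nf}
#'       - {type: merge, time: t_inv, child: INV, parent: NAT}
#' }
#' Numeric fields may be parameter expressions (strings); `dist` is `unif`
#' or `logunif` with optional `integer: true`.
#'
#' @param path path to the YAML file.
#' @return list with elements `scenarios` (list of [scenario()]) and
#'   `priors` (a [prior_set()]).
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenarios)) stop("config has no 'scenarios' key")
  pr <- lapply(cfg$priors, function(p) {
    f <- switch(p$dist, unif = prior_unif, logunif = prior_logunif,
                stop("unknown prior dist: ", p$dist))
    f(p$min, p$max, integer = isTRUE(p$integer))
  })
  priors <- prior_set(pr, constraints = as.character(cfg$constraints %||% character()))
  scenarios <- lapply(cfg$scenarios, function(sc) {
    demes <- lapply(sc$demes, function(d) deme(d$Ne, d$samples %||% 0L))
    events <- lapply(sc$events %||% list(), function(e) {
      switch(e$type,
             size = ev_size(e$time, e$pop, e$Ne),
             merge = ev_merge(e$time, e$child, e$parent),
             admix = ev_admix(e$time, e$recipient, e$donor, e$rate),
             stop("unknown event type: ", e$type))
    })
    scenario(sc$label, demes, events)
  })
  list(scenarios = scenarios, priors = priors)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
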