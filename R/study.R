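#' Canonical invasion scenario set: direct, ghost-source, admixed bridgehead
#'
#' Three competing introduction histories for an invading plant sampled in
#' its native range (NAT) and two introduced ranges (EAU, then WAU),
#' mirroring the classic questions of invasion genetics: did each invasion
#' come directly from the sampled native range, from an unsampled ghost
#' population, or did the second invasion use the first as a bridgehead
#' (with admixture from the native range)?
#'
#' \describe{
#'   \item{direct}{EAU founded from NAT `t_EAU` generations ago and WAU
#'     founded from NAT `t_WAU` generations ago, each through a founder
#'     bottleneck (size `Nf_*` for `db_*` generations).}
#'   \item{ghost}{an unsampled ghost population split from NAT `t_ghost`
#'     generations ago; both EAU and WAU were founded from the ghost.}
#'   \item{bridgehead}{EAU founded from NAT; WAU founded from EAU with an
#'     admixture fraction `ra` contributed by NAT at the founding.}
#' }
#'
#' Priors: introduction times are uniform, `t_EAU` ~ U(38, 45) and `t_WAU`
#' ~ U(8, 10) generations (first records of the two invasions, at 3 years
#' per generation); founder sizes are log-uniform on (5, 500) diploids;
#' bottleneck durations uniform on (1, 5) generations; the ghost split time
#' uniform on (500, 1500) generations, well before the invasions, so that
#' ghost ancestry is distinguishable from direct native ancestry;
#' admixture fraction uniform on (0.1, 0.9). Sampled population sizes are
#' fixed at Ne = 1000 diploids.
#'
#' @param n_samples diploid samples per sampled deme (default 10).
#' @param ne effective size of the sampled demes and the ghost
#'   (default 1000).
#' @return list with `scenarios` (list of three [scenario()] objects),
#'   `priors` (a [prior_set()]) and `schema` (the [sumstat_schema()] over
#'   NAT, EAU, WAU).
#' @export
invasion_scenarios <- function(n_samples = 10, ne = 1000) {
  direct <- scenario("direct",
    demes = list(NAT = deme(ne, n_samples), EAU = deme(ne, n_samples),
                 WAU = deme(ne, n_samples)),
    events = list(
      ev_size("t_WAU - db_WAU", "WAU", "Nf_WAU"),
      ev_merge("t_WAU", "WAU", "NAT"),
      ev_size("t_EAU - db_EAU", "EAU", "Nf_EAU"),
      ev_merge("t_EAU", "EAU", "NAT")))
  ghost <- scenario("ghost",
    demes = list(NAT = deme(ne, n_samples), EAU = deme(ne, n_samples),
                 WAU = deme(ne, n_samples), GHOST = deme(ne, 0)),
    events = list(
      ev_size("t_WAU - db_WAU", "WAU", "Nf_WAU"),
      ev_merge("t_WAU", "WAU", "GHOST"),
      ev_size("t_EAU - db_EAU", "EAU", "Nf_EAU"),
      ev_merge("t_EAU", "EAU", "GHOST"),
      ev_merge("t_ghost", "GHOST", "NAT")))
  bridgehead <- scenario("bridgehead",
    demes = list(NAT = deme(ne, n_samples), EAU = deme(ne, n_samples),
                 WAU = deme(ne, n_samples)),
    events = list(
      ev_size("t_WAU - db_WAU", "WAU", "Nf_WAU"),
      ev_admix("t_WAU", "WAU", "NAT", "ra"),
      ev_merge("t_WAU", "WAU", "EAU"),
      ev_size("t_EAU - db_EAU", "EAU", "Nf_EAU"),
      ev_merge("t_EAU", "EAU", "NAT")))
  priors <- prior_set(
    list(t_EAU = prior_unif(38, 45), t_WAU = prior_unif(8, 10),
         Nf_EAU = prior_logunif(5, 500), Nf_WAU = prior_logunif(5, 500),
         db_EAU = prior_unif(1, 5), db_WAU = prior_unif(1, 5),
         t_ghost = prior_unif(500, 1500), ra = prior_unif(0.1, 0.9)),
    constraints = "t_EAU > t_WAU")
  list(scenarios = list(direct, ghost, bridgehead), priors = priors,
       schema = sumstat_schema(c("NAT", "EAU", "WAU")))
}

#' Founding-bottleneck scenario for parameter estimation
#'
#' A two-deme scenario - a native source (NAT) and an introduced deme (INV)
#' founded `t` generations ago through a founder bottleneck of effective
#' size `Nf` lasting `db` generations - with the priors used for the
#' introduction-time / founder-size recovery analyses: `t` ~ U(38, 45)
#' generations, `Nf` ~ log-uniform(5, 500) diploids, `db` ~ U(1, 5)
#' generations.
#'
#' @inheritParams invasion_scenarios
#' @return list with `scenario`, `priors` and `schema` (NAT, INV).
#' @export
founding_scenario <- function(n_samples = 10, ne = 1000) {
  sc <- scenario("founding",
    demes = list(NAT = deme(ne, n_samples), INV = deme(ne, n_samples)),
    events = list(
      ev_size("t - db", "INV", "Nf"),
      ev_merge("t", "INV", "NAT")))
  priors <- prior_set(list(t = prior_unif(38, 45),
                           Nf = prior_logunif(5, 500),
                           db = prior_unif(1, 5)))
  list(scenario = sc, priors = priors,
       schema = sumstat_schema(c("NAT", "INV")))
}
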