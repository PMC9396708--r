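---
title: "Inferring invasion history from ddRADseq SNPs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring invasion history from ddRADseq SNPs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

invadeR reconstructs the introduction history of an invasive plant from
reduced-representation (ddRADseq) SNP genotypes. The pipeline has five
stages, each exercisable on synthetic data: SNP filtering, population
diversity and differentiation statistics, coalescent simulation of
competing demographic scenarios, ABC random-forest scenario choice with
regression-based parameter estimation, and ploidy / genome-size
estimation. This vignette records the models, the tunable parameters, and
the numerical and design choices behind each stage.

## The SNP filter cascade

Raw genotype calls pass five stages, in a fixed order and with strict
inequalities throughout:

1. samples with more than 90% missing genotypes are removed;
2. genotype calls with read depth below 5 are set to missing;
3. biallelic sites with less than 20% missing genotypes and minor allele
   frequency above 0.05 are retained, MAF being computed over non-missing
   calls *after* the depth masking of stage 2;
4. one SNP is kept per RAD locus, chosen uniformly at random under an
   explicit seed (default 1) that the filter report records, so a filtered
   dataset is exactly reproducible;
5. samples with more than 50% missing genotypes are removed.

Because stage 5 removes whole samples it can, in principle, push a site's
missingness back above the stage-3 bound; the cascade follows the stated
stage order rather than iterating, and the report notes when this happens.
Multi-allelic records are carried through reading and removed at stage 3.
The cascade is idempotent on its own output (stage 4 finds one SNP per
locus already).

## Diversity and differentiation statistics

Per-site statistics are averaged over sites; standard errors are site-wise
SEs of the mean. Defaults and variants:

* **He** is the naive gene diversity $1 - \sum_a p_a^2$; an unbiased
  $2n/(2n-1)$ variant is available behind `unbiased_he = TRUE`. Which
  small-sample variant a given upstream caller uses is rarely documented,
  so both are provided.
* **FIS** is reported as $1 - \bar{H}_o/\bar{H}_e$ (ratio of means over
  sites, jackknife SE), which keeps the sign stable when many sites are
  weakly polymorphic; a per-site mean variant sits behind
  `fis_per_site = TRUE`.
* **pi** is the sample-size-corrected average pairwise difference
  $\frac{2n}{2n-1} 2p(1-p)$ at SNP sites only. Without invariant sites a
  per-locus nucleotide diversity is not computable from a SNP matrix; this
  per-SNP pi is therefore *not* comparable to locus-length-normalized
  values from assembly-aware callers.
* **Weir–Cockerham FST** uses the 1984 variance components with the
  multi-site ratio-of-sums. Note that the estimator is unbiased around
  zero rather than zero-valued on literal duplicate tables: two groups
  that are exact copies of each other give a small negative estimate of
  order $-1/(2n)$, with an exact zero only when the heterozygote
  correction cancels (e.g. all-heterozygote sites).
* **Phi-ST** is the two-level AMOVA among-group variance fraction with the
  inter-individual distance taken as the squared difference of
  alternate-allele counts summed over pairwise-complete sites. A
  haplotype-level AMOVA is not possible from unphased biallelic SNPs.
* **Standardized FST** divides Weir–Cockerham theta by its Hedrick-style
  maximum $(k-1)(1-H_S)/(k-1+H_S)$ given the mean within-group gene
  diversity.
* **f3(target; A, B)** is the site-mean of $(p_T-p_A)(p_T-p_B)$ minus the
  estimated sampling variance of $\hat p_T$, i.e.
  $\hat p_T(1-\hat p_T)/(2n_T-1)$; strongly negative values indicate an
  admixed target.

The ABC summary-statistic vector (schema `v1`) concatenates, in an order
fixed by the schema's group list: per group {mean He, variance of He
across sites, proportion of monomorphic sites, mean Ho}; per pair
{Weir–Cockerham FST, Nei's D}; per trio the three f3 statistics. For $G$
groups the length is $4G + 2\binom{G}{2} + 3\binom{G}{3}$. The schema is
versioned so alternative statistic sets can be added without invalidating
stored reference tables.

## Coalescent scenario simulator

Scenarios are sets of demes (diploid effective size, diploid sample
count; ghost populations are demes with zero samples) plus events stated
backwards in time: size changes, merges (forward-time foundings) and
admixture pulses (each recipient lineage moves to the donor with the
admixture fraction as probability). Any numeric field may be an
expression in prior parameter names (`"t_inv - db"`), so founder
bottlenecks are expressed as a size change to $N_f$ at $t - d_b$ followed
by the merge at $t$.

Each locus is an independent genealogy under the structured coalescent
without migration (pair coalescence rate $1/(2N_e)$ per generation per
deme). One mutation is placed uniformly on the total branch length —
every simulated locus is a biallelic SNP, matching the one-SNP-per-locus
data the filter cascade produces. Loci whose overall-sample minor allele
frequency falls below `maf_min` (default 0.05, matching the data filter)
are redrawn, with a cap of 10,000 redraws per locus. Diploids are formed
by pairing consecutive sampled lineages within a deme, which is
equivalent to random pairing by exchangeability. The per-locus simulator
is compiled (Rcpp) and uses R's RNG, so everything is reproducible from a
single seed. There is no recombination within loci, no selection, and no
mutation model beyond the single biallelic mutation.

Time is counted in generations. For calendar conversions the package's
demonstration scenarios assume 3 years per generation, so the
introduction-time priors U(38, 45) and U(8, 10) generations correspond to
first records roughly 110–130 and 25–30 years before sampling.

Priors are uniform or log-uniform with finite bounds, an optional
integer-rounding flag, and cross-parameter constraints enforced by
rejection (an error is raised if more than 99.9% of proposals are
rejected). Defaults in the demonstration set: founder sizes log-uniform
on (5, 500) diploids — the lower bound is the smallest founding
population worth distinguishing from zero propagule pressure; bottleneck
durations uniform on (1, 5) generations; the ghost split time uniform on
(500, 1500) generations, long enough that ghost ancestry is
distinguishable from direct native ancestry at the simulated drift rates;
sampled deme sizes fixed at $N_e = 1000$.

The sequencing layer (`add_sequencing_layer`) emulates ddRADseq noise on
perfect genotypes: negative-binomial read depth (default mean 22,
dispersion 7, giving an SD near 9.5 — the coverage regime typical of
ddRADseq experiments), allele depths binomial at the heterozygote
expectation 1/2, uniform genotype missingness, and optional perfectly
linked duplicate SNPs within a RAD locus so the thinning stage has work
to do. It does not emulate allele dropout, reference bias, paralog
collapse or batch effects; filter-cascade tests passing on this generator
therefore validate bookkeeping and thresholds, not robustness to those
artefacts.

## ABC random-forest scenario choice

The reference table holds, per scenario, parameter draws from the priors
and the summary-statistic vector of one simulated dataset per draw. Model
choice trains a classification random forest (default 1000 trees,
`mtry = floor(sqrt(d))`, unlimited depth, single-threaded for
reproducibility) on the statistics plus, by default, the LDA axes of the
statistics fit on the scenario labels. The out-of-bag misclassification
rate is the prior error rate. The posterior probability of the selected
scenario is estimated by a companion regression forest trained on the
OOB misclassification indicator, evaluated at the observed statistics and
clipped to [0, 1] — a reconstruction of the standard ABC-RF construction.

The sequential tournament compares scenario subsets in preliminary
rounds; a scenario advances when its votes strictly exceed the round
average (trees / scenarios-in-round) — a tie does not advance. The final
round pools all advancers and decides. If no scenario clears a round's
threshold the top-voted one advances with a prominent warning rather than
aborting, which keeps tournaments runnable on noisy, small reference
tables.

## Parameter estimation and model checking

Posteriors come from rejection plus local-linear adjustment: statistics
are standardized by reference-table median absolute deviation (robust to
the heavy tails simulation can produce), the closest `tolerance` fraction
(default 1%) by Euclidean distance is accepted, and each parameter is
logit-transformed to its prior bounds (log-scale first for log-uniform
priors), adjusted by weighted linear regression on the centered
statistics with Epanechnikov weights, and back-transformed — so adjusted
draws respect the prior bounds by construction. The regression uses a
light ridge penalty on the slopes (default 0.01 of the mean Gram
diagonal): with a few hundred accepted draws and a ten-plus-dimensional
statistic vector the unpenalized solve overfits and produces badly
under-dispersed posteriors (credible-interval coverage near 55% in our
calibration runs, against 85% with the penalty). A singular penalized
system falls back to the rejection-only posterior with a warning.

Model checking simulates datasets from the adjusted posterior and reports,
per statistic, the two-tailed empirical p-value
$2\min(F(\mathrm{obs}), 1-F(\mathrm{obs}))$ plus the count significant at
$\alpha$, optionally on a held-out statistic subset. Raw p-values are
used with no multiple-testing correction — the count of flagged
statistics is a descriptive misfit measure, not a family-wise test. At
least 100 simulations are required; tail estimates are unstable below
that.

## Ploidy from allele balance

Per individual, allele balances (alt reads over total) are collected at
sites with summed allele coverage at least 10 and within-individual minor
fraction at least 0.2. That window truncates the balance distribution to
[0.2, 0.8], which matters numerically: at 30x coverage the binomial SD
around a tetraploid 1/4 component is about 0.08, so a substantial part of
that component is clipped. The fixed diploid {1/2}, triploid {1/3, 2/3}
and tetraploid {1/4, 1/2, 3/4} models and the free three-component model
are therefore mixtures of *truncated* Gaussians on the window, with free
weights and one shared free SD, fitted by direct likelihood maximization
(Nelder–Mead on log-SD, weight logits and, for the free model,
logit-window means). The free model is started from each fixed optimum as
well as a generic start, which guarantees
$\ln L_{\mathrm{free}} \ge \ln L_{\mathrm{fixed}}$ exactly.

The fixed models are nested: with free weights the tetraploid model can
empty its outer components and reproduce the diploid model. The call is
therefore the *lowest* ploidy among models whose normalized gap
$(\ln L_{\mathrm{free}} - \ln L_{\mathrm{fixed}})/|\ln L_{\mathrm{free}}|$
is within 0.01 of the smallest — a parsimony tie-break — and the fit is
flagged ambiguous whenever more than one model falls in that band. In
practice clean diploid samples are called diploid-with-ambiguity (the
tetraploid model fits equally well by nesting), which mirrors how
fixed-model ploidy tools behave on real diploid data.

`denoise` fits a free Gaussian mixture (three components, per-component
SDs bounded to [0.01, 0.15]) plus a uniform noise component over the
balance window by EM, and removes sites whose largest responsibility is
the noise component. Two guards return the input unfiltered with a
warning: EM non-convergence, and a fit that would discard more than half
the sites. The latter occurs on strongly discrete balance distributions —
at integer depths near 30 the balances form atoms, and the flat component
can "explain" the mass between atoms; that is a mis-specification of the
noise model, not contamination. Denoising is aimed at flat mismapping
backgrounds under smooth peaks and should be read as optional on clean
high-quality data.

## Flow-cytometry 2C and genome size

Events are gated at FSC-H ≥ 80,000 and FL2-H ≥ 600 to exclude debris. The
G1 peak of the gated FL2-H distribution is the mode of a kernel density
(Silverman bandwidth) — gating alone does not isolate G1 — and the G1
population is taken as events within ±20% of that mode, summarized by
geometric mean and CV (SD/mean). Then
$2C_{\mathrm{sample}} = 2C_{\mathrm{ref}} \times
\mathrm{GM}_{\mathrm{sample}} / \mathrm{GM}_{\mathrm{ref}}$ with the
tomato standard (1.96 pg) as default reference, and
$1C\,[\mathrm{Mbp}] = (2C/2) \times 978$. The estimate is invariant to
jointly rescaling all fluorescence values; sample and reference peaks
within 1.1x of each other trigger a resolvability warning. Cell-cycle
(S/G2) modeling and spectral compensation are out of scope; the synthetic
event generator produces a single lognormal G1 peak plus sub-gate debris,
and a single-G1-peak assumption is built into the mode detection.

## Problem sizes used by the test suite and analyses

The packaged analyses run at desk scale, chosen once as the smallest
sizes at which each property is comfortably measurable: scenario choice
uses 1000 reference simulations per scenario of 500 SNP loci with
500-tree forests and 50 pseudo-observed datasets per scenario;
the posterior calibration study uses a 20,000-row reference table at 300
loci, tolerance 1%, and 100 pseudo-observed replicates; the bottleneck
signature is averaged over 200 replicates of 200 loci; ploidy recovery
uses 60 individuals at 2000 sites and 30x depth. Sampled deme sizes are
10 diploids per deme throughout.

## Known limitations

* Summary statistics are a reconstruction of a generic SNP statistic set
  (per-group diversity, pairwise differentiation, trio f3), versioned as
  schema `v1`; they are not a byte-level match to any particular
  simulation package's statistic list.
* The simulator's loci are unlinked with exactly one SNP each; linkage
  exists only in the synthetic sequencing layer.
* Per-SNP pi and SEs over sites are not directly comparable to
  locus-based estimates that include invariant sites.
* The posterior-probability estimator and the denoise/ambiguity rules are
  reconstructions of published tool behaviour, validated here by
  property-based tests (calibration, self-consistency, symmetry) rather
  than against the original implementations.
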