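#include <Rcpp.h>
using namespace Rcpp;

// Structured-coalescent simulator for unlinked biallelic SNP loci.
//
// Each locus: one genealogy of all sampled haploid lineages under a
// piecewise-constant multi-deme demography (no migration; lineages change
// deme only at merge/admixture events, processed backwards in time), one
// mutation placed uniformly on the total branch length, locus redrawn while
// the overall-sample minor allele frequency is below maf_min.
//
// Events are passed pre-sorted by time (ascending, stable):
//   type 1 size_change: deme a -> Ne par
//   type 2 merge:       lineages of child a move to parent b; a inactive
//   type 3 admixture:   each lineage in recipient a moves to donor b w.p. par
// Times are generations; deme sizes are diploid Ne, so a pair of lineages
// in a deme of size Ne coalesces at rate 1/(2 Ne).

// [[Rcpp::export(name = ".sim_snp_loci_cpp")]]
IntegerMatrix sim_snp_loci_cpp(int n_loci,
                               IntegerVector sample_demes,
                               NumericVector deme_sizes,
                               IntegerVector ev_type,
                               NumericVector ev_time,
                               IntegerVector ev_a,
                               IntegerVector ev_b,
                               NumericVector ev_par,
                               double maf_min,
                               int max_redraw) {
  const int n = sample_demes.size();
  const int n_demes = deme_sizes.size();
  const int n_ev = ev_type.size();
  if (n < 2) stop("need at least 2 sampled lineages");
  IntegerMatrix out(n_loci, n);

  const int n_nodes = 2 * n - 1;
  std::vector<int> parent(n_nodes);
  std::vector<double> ntime(n_nodes);
  std::vector<int> lin_node;   // active lineage -> node id
  std::vector<int> lin_deme;   // active lineage -> deme
  std::vector<double> sizes(n_demes);
  std::vector<int> k(n_demes); // active lineage count per deme
  std::vector<double> rate(n_demes);

  for (int locus = 0; locus < n_loci; ++locus) {
    int redraws = 0;
    for (;;) {
      // reset state
      lin_node.assign(n, 0);
      lin_deme.assign(n, 0);
      for (int i = 0; i < n; ++i) { lin_node[i] = i; lin_deme[i] = sample_demes[i]; }
      for (int i = 0; i < n_nodes; ++i) { parent[i] = -1; ntime[i] = 0.0; }
      for (int d = 0; d < n_demes; ++d) sizes[d] = deme_sizes[d];
      int n_active = n;
      int next_node = n;
      int eidx = 0;
      double t = 0.0;

      while (n_active > 1) {
        std::fill(k.begin(), k.end(), 0);
        for (int i = 0; i < n_active; ++i) k[lin_deme[i]]++;
        double total = 0.0;
        for (int d = 0; d < n_demes; ++d) {
          rate[d] = (k[d] >= 2) ? k[d] * (k[d] - 1.0) / (4.0 * sizes[d]) : 0.0;
          total += rate[d];
        }
        double dt = (total > 0.0) ? R::exp_rand() / total : R_PosInf;
        if (eidx < n_ev && t + dt >= ev_time[eidx]) {
          t = ev_time[eidx];
          int a = ev_a[eidx], b = ev_b[eidx];
          switch (ev_type[eidx]) {
          case 1: sizes[a] = ev_par[eidx]; break;
          case 2:
            for (int i = 0; i < n_active; ++i)
              if (lin_deme[i] == a) lin_deme[i] = b;
            break;
          case 3:
            for (int i = 0; i < n_active; ++i)
              if (lin_deme[i] == a && unif_rand() < ev_par[eidx]) lin_deme[i] = b;
            break;
          default: stop("unknown event type");
          }
          ++eidx;
          continue;
        }
        if (!R_FINITE(dt))
          stop("lineages cannot coalesce: no rate and no remaining events");
        t += dt;
        // pick deme proportional to rate, then an unordered pair in it
        double u = unif_rand() * total, acc = 0.0;
        int d = n_demes - 1;
        for (int dd = 0; dd < n_demes; ++dd) { acc += rate[dd]; if (u <= acc) { d = dd; break; } }
        int i1 = -1, i2 = -1;
        int pick1 = (int)std::floor(unif_rand() * k[d]);
        int pick2 = (int)std::floor(unif_rand() * (k[d] - 1));
        int seen = 0;
        for (int i = 0; i < n_active && (i1 < 0 || i2 < 0); ++i) {
          if (lin_deme[i] != d) continue;
          if (seen == pick1) i1 = i;
          ++seen;
        }
        seen = 0;
        for (int i = 0; i < n_active && i2 < 0; ++i) {
          if (lin_deme[i] != d || i == i1) continue;
          if (seen == pick2) i2 = i;
          ++seen;
        }
        int node = next_node++;
        ntime[node] = t;
        parent[lin_node[i1]] = node;
        parent[lin_node[i2]] = node;
        lin_node[i1] = node;                 // i1 becomes the merged lineage
        lin_node[i2] = lin_node[n_active - 1];
        lin_deme[i2] = lin_deme[n_active - 1];
        --n_active;
      }

      // place one mutation uniformly on total branch length
      double total_len = 0.0;
      for (int i = 0; i < n_nodes; ++i)
        if (parent[i] >= 0) total_len += ntime[parent[i]] - ntime[i];
      double target = unif_rand() * total_len, acc2 = 0.0;
      int mut_node = -1;
      for (int i = 0; i < n_nodes; ++i) {
        if (parent[i] < 0) continue;
        acc2 += ntime[parent[i]] - ntime[i];
        if (target <= acc2) { mut_node = i; break; }
      }
      if (mut_node < 0) mut_node = n_nodes - 2;

      // derived leaves = leaves whose path to the root passes mut_node
      int n_derived = 0;
      for (int leaf = 0; leaf < n; ++leaf) {
        int v = leaf;
        int hit = 0;
        while (v >= 0) {
          if (v == mut_node) { hit = 1; break; }
          v = parent[v];
        }
        out(locus, leaf) = hit;
        n_derived += hit;
      }
      double f = (double)n_derived / n;
      if (std::min(f, 1.0 - f) >= maf_min) break;
      if (++redraws > max_redraw)
        stop("locus redraw cap exceeded (maf_min too strict for this scenario)");
    }
  }
  return out;
}
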