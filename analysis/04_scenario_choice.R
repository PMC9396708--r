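#!/usr/bin/env Rscript

# ABC random-forest scenario choice for the synthetic invasion: simulate a
# reference table under the three competing histories (direct, ghost,
# bridgehead), train a 500-tree classifier with LDA axes, and run the
# sequential tournament on the observed (filtered) dataset: preliminary
# round direct-vs-ghost, winner(s) against bridgehead in the final.
# The observed data is thinned to the reference locus count so observed and
# simulated statistics share their sampling scale.

library(invadeR)

n_ref <- 600; n_loci <- 500; n_trees <- 500
st <- invasion_scenarios()
gm <- read_vcf("results/synthetic/filtered.vcf", locus_id_rule = "chrom")
pm <- read_popmap("results/synthetic/popmap.tsv")

set.seed(404)
keep <- sort(sample(nrow(gm$genotypes), n_loci))
obs <- summary_vector(gm_subset(gm, sites = keep), pm, st$schema)

message("building reference table (", n_ref, " sims/scenario x ",
        n_loci, " loci) ...")
rt <- build_reference_table(st$scenarios, st$priors, n_ref, st$schema,
                            n_loci = n_loci, seed = 405)
write_reference_table(rt, "results/reference_table")

plan <- tournament_plan(list(c("direct", "ghost"), "bridgehead"))
out <- run_tournament(plan, rt, obs, n_trees = n_trees, seed = 406)
print(out$result)
for (rd in out$audit)
  message(sprintf("round %d [%s]: votes %s; threshold %.1f; advanced: %s",
                  rd$round, paste(rd$scenarios, collapse = ", "),
                  paste(sprintf("%s=%d", names(rd$votes), rd$votes),
                        collapse = " "),
                  rd$threshold, paste(rd$advanced, collapse = ", ")))

jsonlite::write_json(
  list(selected = out$selected,
       posterior_probability = out$result$posterior_prob,
       oob_prior_error = out$result$oob_error,
       audit = lapply(out$audit, function(r)
         list(scenarios = r$scenarios, votes = as.list(r$votes),
              threshold = r$threshold, advanced = r$advanced))),
  "results/scenario_choice.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
message("selected scenario: ", out$selected,
        " (true history of the synthetic data: ghost)")
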