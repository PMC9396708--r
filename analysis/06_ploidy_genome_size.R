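#!/usr/bin/env Rscript

# Ploidy and genome size of the synthetic invader. (1) Allele-balance
# ploidy inference per sample from the raw VCF's AD field (coverage >= 10,
# within-individual minor fraction >= 0.2; denoise; fixed diploid /
# triploid / tetraploid models against a free mixture). (2) Flow-cytometry
# 2C DNA content against the tomato internal standard (2C = 1.96 pg) from
# synthetic gated events, converted to a 1C genome size in Mbp.

library(invadeR)

gm <- read_vcf("results/synthetic/raw.vcf", locus_id_rule = "chrom")
ab <- extract_allele_balance(gm, min_cov = 10, maf_min = 0.2)

rows <- lapply(names(ab), function(ind) {
  b <- ab[[ind]]
  if (length(b) < 100)
    return(data.frame(sample = ind, n_sites = length(b), call = NA,
                      ambiguous = NA, gap_diploid = NA))
  d <- suppressWarnings(denoise(b))
  f <- call_ploidy(d$balances)
  data.frame(sample = ind, n_sites = length(d$balances), call = f$call,
             ambiguous = f$ambiguous,
             gap_diploid = round(f$gaps[["diploid"]], 5))
})
ploidy <- do.call(rbind, rows)
utils::write.table(ploidy, "results/ploidy_calls.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("%d of %d samples called diploid (%d ambiguous)",
                sum(ploidy$call == "diploid", na.rm = TRUE), nrow(ploidy),
                sum(ploidy$ambiguous, na.rm = TRUE)))

# flow cytometry: co-stained sample + tomato reference, 3 replicates
reps <- lapply(1:3, function(r) {
  s <- simulate_cytometry_events(10000, g1_mean = 6000 * 1.587, cv = 0.05,
                                 debris_frac = 0.1, seed = 600 + r)
  ref <- simulate_cytometry_events(10000, g1_mean = 6000, cv = 0.05,
                                   debris_frac = 0.1, seed = 650 + r,
                                   role = "reference", ref_2c_pg = 1.96)
  est <- estimate_2c(gate_events(s), gate_events(ref))
  data.frame(replicate = r, c2_pg = est$c2_pg,
             cv_sample = est$cv_sample, cv_reference = est$cv_reference,
             genome_size_1c_mbp = genome_size_mbp(est$c2_pg))
})
cyto <- do.call(rbind, reps)
print(cyto, digits = 4)
utils::write.table(cyto, "results/cytometry.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("2C = %.3f +/- %.3f pg; 1C = %.0f Mbp",
                mean(cyto$c2_pg), stats::sd(cyto$c2_pg),
                mean(cyto$genome_size_1c_mbp)))
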