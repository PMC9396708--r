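#!/usr/bin/env Rscript

# Apply the post-calling SNP filter cascade to the raw synthetic VCF:
# drop samples >90% missing, mask genotype calls with depth <5, keep
# biallelic sites with <20% missing and MAF >0.05, thin to one SNP per RAD
# locus, drop samples >50% missing. Writes the filtered VCF and the
# per-stage filter report.

library(invadeR)

raw <- read_vcf("results/synthetic/raw.vcf", locus_id_rule = "chrom")
res <- filter_cascade(raw, seed = 1)

print(res$report)
write_vcf(res$gm, "results/synthetic/filtered.vcf")
write_filter_report(res$report, "results/synthetic/filter_report.tsv")
message(sprintf("retained %d of %d sites, %d of %d samples",
                nrow(res$gm$genotypes), nrow(raw$genotypes),
                length(res$gm$samples), length(raw$samples)))
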