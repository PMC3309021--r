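#!/usr/bin/env Rscript
# Generate the study-shaped synthetic dataset used by all downstream
# analysis steps: 262 individuals, 22 populations, 5 regional lineages
# (A-E), 1248 aligned mtDNA sites evolved under HKY+Gamma on a
# structured coalescent with the empirical lineage sizes and split
# order. Writes FASTA + sample table + true genealogy + truth record.

library(phylodemog)

seed <- 20260928
out <- "results/data"
cat("Simulating the study-shaped dataset (seed ", seed, ") ...\n", sep = "")
d <- generate_dataset(scenario_preset("multiple_refugia"), seed = seed,
                      out_dir = out)

print(d$aln)
cat("\nGround truth written to ", file.path(out, "truth.tsv"), ":\n", sep = "")
print(d$truth, row.names = FALSE)
cat("\nThe alignment collapses to", length(d$aln$haplotype_id),
    "haplotypes; the study's real data had 63. No haplotype is shared",
    "across regional lineages, matching the empirical pattern.\n")
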