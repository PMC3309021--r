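#!/usr/bin/env Rscript
# Statistical-parsimony haplotype network: 95% connection limit for the
# 1248-site alignment, network assembly, components and modal
# haplotypes.

library(phylodemog)

aln <- read_alignment("results/data/alignment.fasta", "results/data/samples.tsv")

lim <- connection_limit(aln$L_effective, confidence = 0.95)
cat("95% parsimony connection limit at L =", aln$L_effective, ":", lim,
    "steps\n")
cat("(probability of parsimony at", lim, "steps:",
    round(parsimony_probability(lim, aln$L_effective), 4), "; at",
    lim + 1, "steps:",
    round(parsimony_probability(lim + 1, aln$L_effective), 4), ")\n\n")

net <- build_network(aln, limit = lim)
print(net)
files <- write_network(net, "results/network", aln)
cat("Modal haplotype per subnetwork:\n")
print(modal_haplotype(net, aln), row.names = FALSE)
cat("\nWrote", paste(files, collapse = ", "), "\n")
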