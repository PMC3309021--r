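#!/usr/bin/env Rscript
# Mismatch-distribution analysis per lineage: sudden-expansion fit,
# bootstrap goodness-of-fit, neutrality tests, and expansion-time
# conversion (Table-2 shape). Bootstrap/simulation counts are reduced
# from the study's 1000 to keep this driver quick; the package accepts
# the full counts.

library(phylodemog)

aln <- read_alignment("results/data/alignment.fasta", "results/data/samples.tsv")
rates <- rate_params(0.036, 2.5, aln$L_effective)
n_boot <- 100
n_sims <- 200
seeds <- derive_seeds(42, c("boot", "neutrality"))

rows <- list()
for (g in unique(aln$samples$group)) {
  keep <- aln$samples$group == g
  ex <- expand_alignment(aln)
  sub <- haplotype_alignment(ex$seqs[keep, , drop = FALSE], ex$samples[keep, 1:3])
  fit <- fit_sudden_expansion(mismatch_distribution(sub), tau_step = 0.1)
  fit <- bootstrap_fit_pvalues(sub, fit, n_boot = n_boot,
                               seed = seeds[["boot"]], tau_step = 0.25)
  fs <- fu_fs(sub, n_sims = n_sims, seed = seeds[["neutrality"]])
  td <- tajimas_d(sub, n_sims = n_sims, seed = seeds[["neutrality"]])
  rows[[g]] <- data.frame(
    lineage = g, tau = round(fit$tau, 3),
    ssd = round(fit$ssd, 5), p_ssd = fit$p_ssd,
    raggedness = round(fit$raggedness, 5), p_rag = fit$p_rag,
    expansion_mya = expansion_time(fit$tau, rates)$mya,
    fu_fs = round(fs$statistic, 5), p_fs = round(fs$p_low, 3),
    tajima_d = round(td$statistic, 5), p_d = round(td$p_low, 3))
}
tab <- do.call(rbind, rows)
write.table(tab, "results/mismatch_demography.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Per-lineage expansion inference (results/mismatch_demography.tsv):\n")
print(tab, row.names = FALSE)

# published tau values -> expansion dates with the study clock
conv <- data.frame(lineage = c("E", "D", "A2"), tau = c(4.738, 4.375, 2.209))
conv$mya <- vapply(conv$tau,
                   function(t) expansion_time(t, rate_params(0.036, 2.5, 1248))$mya,
                   numeric(1))
write.table(conv, "results/expansion_times_published_tau.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nPublished tau converted by t = tau/(2u), u = 0.036e-6 * 1248 per year:\n")
print(conv, row.names = FALSE)
cat("\nThese reproduce the published dates 0.053 / 0.049 / 0.025 Mya.\n")
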