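test_that("identical sequences collapse to haplotypes with summed counts", {
  aln <- toy_alignment(c("ACGT", "ACGT", "ACGA", "ACGA"),
                       population = c("p1", "p1", "p2", "p2"))
  expect_length(aln$haplotype_id, 2)
  expect_equal(n_individuals(aln), 4)
  expect_equal(sum(aln$counts), 4)
  expect_equal(aln$haplotype_id, c("H1", "H2"))  # first-appearance order

  mono <- toy_alignment(rep("ACGTACGT", 5))
  expect_length(mono$haplotype_id, 1)
  expect_equal(segregating_sites(mono), 0)
})

test_that("columns with N or gaps are excluded everywhere (complete deletion)", {
  aln <- toy_alignment(c("ACNT-A", "ACGTGA", "TCGTGA"))
  expect_equal(aln$L_original, 6)
  expect_equal(aln$L_effective, 4)  # cols 3 and 5 dropped
  # only col 1 varies among retained sites
  expect_equal(segregating_sites(aln), 1)
  # individuals identical on retained sites collapse even if they
  # differed at a dropped site
  aln2 <- toy_alignment(c("ANGT", "AcGT"))
  expect_length(aln2$haplotype_id, 1)
})

test_that("alignment errors are reported", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACG"), fa)
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("individual\tpopulation\tgroup", "a\tp\tg", "b\tp\tg"), tsv)
  expect_error(read_alignment(fa, tsv), "not aligned")

  writeLines(c(">a", "ACGT", ">zzz", "ACGA"), fa)
  expect_error(read_alignment(fa, tsv), "missing from sample table")

  bad <- data.frame(individual = c("a", "a"), population = "p", group = "g")
  expect_error(phylodemog:::validate_sample_table(bad), "duplicated")
  bad2 <- data.frame(individual = c("a", "b"), population = c("p", "p"),
                     group = c("g1", "g2"))
  expect_error(phylodemog:::validate_sample_table(bad2), "more than one group")
})

test_that("segregating sites equal a naive per-column scan and ignore frequencies", {
  set.seed(42)
  for (rep in 1:5) {
    seqs <- random_seqs(8, 40)
    samples <- data.frame(individual = rownames(seqs), population = "p",
                          group = "g")
    aln <- haplotype_alignment(seqs, samples)
    expect_equal(segregating_sites(aln), brute_segsites(seqs))
    # duplicating a sequence (changing frequencies) leaves S unchanged
    seqs2 <- rbind(seqs, seqs[c(1, 1, 2), ])
    rownames(seqs2) <- paste0("ind", seq_len(nrow(seqs2)))
    samples2 <- data.frame(individual = rownames(seqs2), population = "p",
                           group = "g")
    expect_equal(segregating_sites(haplotype_alignment(seqs2, samples2)),
                 segregating_sites(aln))
  }
})

test_that("collapse then expand preserves downstream statistics", {
  set.seed(7)
  seqs <- random_seqs(10, 30)[c(1:6, 1, 2, 2, 3), ]  # force duplicates
  rownames(seqs) <- paste0("ind", 1:10)
  samples <- data.frame(individual = rownames(seqs),
                        population = rep(c("p1", "p2"), each = 5),
                        group = "g")
  aln <- haplotype_alignment(seqs, samples)
  ex <- expand_alignment(aln)
  aln2 <- haplotype_alignment(ex$seqs, ex$samples[, 1:3])
  expect_equal(diversity_stats(aln2)[c("n", "k", "h", "pi", "theta_w")],
               diversity_stats(aln)[c("n", "k", "h", "pi", "theta_w")])
  expect_equal(mismatch_distribution(aln2)$counts,
               mismatch_distribution(aln)$counts)
})

test_that("FASTA round-trip through files reproduces the generator's haplotype count", {
  d <- generate_dataset(scenario_preset("constant", L = 300), seed = 11,
                        out_dir = td <- tempfile())
  aln <- read_alignment(file.path(td, "alignment.fasta"),
                        file.path(td, "samples.tsv"))
  truth <- read_truth(file.path(td, "truth.tsv"))
  k_truth <- as.integer(truth$value[truth$field == "n_haplotypes"])
  expect_equal(length(aln$haplotype_id), k_truth)
  expect_equal(length(d$aln$haplotype_id), k_truth)
  expect_equal(sort(haplotype_counts(aln)), sort(haplotype_counts(d$aln)),
               ignore_attr = TRUE)
})
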