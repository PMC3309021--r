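test_that("degenerate and hand-computed diversity values are exact", {
  mono <- toy_alignment(c("ACGT", "ACGT"))
  st <- diversity_stats(mono)
  expect_equal(st$h, 0)
  expect_equal(st$pi, 0)
  expect_equal(st$theta_w, 0)

  expect_error(diversity_stats(toy_alignment("ACGT")), "at least 2")

  # n = 4, S = 3, L = 100: theta_W = 3 / ((1 + 1/2 + 1/3) * 100)
  base <- strsplit(paste(rep("A", 100), collapse = ""), "")[[1]]
  s2 <- base; s2[1] <- "C"
  s3 <- base; s3[2] <- "G"
  s4 <- base; s4[3] <- "T"
  aln <- toy_alignment(vapply(list(base, s2, s3, s4), paste, "", collapse = ""))
  st <- diversity_stats(aln)
  expect_equal(st$S, 3)
  expect_equal(st$theta_w, 3 / ((1 + 1/2 + 1/3) * 100), tolerance = 1e-12)
  # h for 4 singleton haplotypes: (4/3) * (1 - 4 * (1/4)^2)
  expect_equal(st$h, (4 / 3) * (1 - 4 * 0.25^2), tolerance = 1e-12)
})

test_that("theta -> Ne conversion is linear and generation-time reciprocal", {
  r <- rate_params(0.036, 2.5, 1248)
  expect_equal(ne_from_theta(0, r), 0)
  th <- c(0.001, 0.004, 0.02)
  expect_equal(ne_from_theta(2 * th, r, round = FALSE),
               2 * ne_from_theta(th, r, round = FALSE))
  r2 <- rate_params(0.036, 5, 1248)
  expect_equal(ne_from_theta(th, r2, round = FALSE),
               ne_from_theta(th, r, round = FALSE) / 2)
})

test_that("Tajima's D matches a textbook-constants hand computation", {
  # fixed 10-sequence alignment with 5 segregating sites
  set.seed(3)
  L <- 50
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  seqs <- matrix(rep(base, 10), nrow = 10, byrow = TRUE)
  # five mutations on distinct sites, various sharing patterns
  seqs[1:3, 5] <- "A"; seqs[4:10, 5] <- "C"
  seqs[1, 12] <- "G"; seqs[2:10, 12] <- "T"
  seqs[1:5, 20] <- "T"; seqs[6:10, 20] <- "A"
  seqs[8, 33] <- "C"; seqs[-8, 33] <- "G"
  seqs[9:10, 41] <- "A"; seqs[1:8, 41] <- "G"
  rownames(seqs) <- paste0("ind", 1:10)
  aln <- haplotype_alignment(seqs, data.frame(individual = rownames(seqs),
                                              population = "p", group = "g"))
  st <- diversity_stats(aln)
  expect_equal(st$S, 5)

  n <- 10; S <- 5
  # independent pi: direct pairwise loop over rows
  pi_hand <- 0
  for (i in 1:9) for (j in (i + 1):10) pi_hand <- pi_hand + sum(seqs[i, ] != seqs[j, ])
  pi_hand <- pi_hand / choose(10, 2)
  a1 <- sum(1 / 1:9); a2 <- sum(1 / (1:9)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  D_hand <- (pi_hand - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))

  td <- tajimas_d(aln, n_sims = 50, seed = 1)
  expect_equal(td$statistic, D_hand, tolerance = 1e-12)
  expect_true(td$p_low >= 0 && td$p_low <= 1)
})

test_that("Ewens haplotype-count distribution is exact and normalized", {
  # normalization across a grid
  for (n in c(2, 5, 10, 20)) for (theta in c(0.1, 1, 10)) {
    expect_equal(sum(ewens_k_dist(n, theta)), 1, tolerance = 1e-12)
  }
  # exact permutation-cycle enumeration oracle
  for (n in c(4, 5, 6)) for (theta in c(0.5, 2)) {
    expect_equal(ewens_k_dist(n, theta), ewens_perm_oracle(n, theta),
                 tolerance = 1e-12)
  }
  # S' for n = 5, theta = 2, k_obs = 3 against the oracle tail sum
  oracle_tail <- sum(ewens_perm_oracle(5, 2)[3:5])
  expect_equal(sum(ewens_k_dist(5, 2)[3:5]), oracle_tail, tolerance = 1e-12)
})

test_that("Fu's Fs is negative under expansion and its S' uses the Ewens tail", {
  d <- generate_dataset(scenario_preset("expansion", L = 500), seed = 31)
  fs <- fu_fs(d$aln, n_sims = 100, seed = 5)
  st <- diversity_stats(d$aln)
  sp_hand <- sum(ewens_k_dist(st$n, st$pi_seq)[st$k:st$n])
  expect_equal(fs$statistic, log(sp_hand / (1 - sp_hand)), tolerance = 1e-10)
  expect_lt(fs$statistic, 0)   # haplotype excess from growth
  expect_error(fu_fs(toy_alignment(c("AA", "AA", "AA"))), "no segregating")
})

test_that("neutrality-test P-values are reproducible under a fixed seed", {
  d <- generate_dataset(scenario_preset("constant", L = 400), seed = 8)
  t1 <- tajimas_d(d$aln, n_sims = 100, seed = 99)
  t2 <- tajimas_d(d$aln, n_sims = 100, seed = 99)
  expect_identical(t1$p_low, t2$p_low)
  f1 <- fu_fs(d$aln, n_sims = 100, seed = 99)
  f2 <- fu_fs(d$aln, n_sims = 100, seed = 99)
  expect_identical(f1$p_low, f2$p_low)
})

test_that("two divergent sub-lineages inflate pi relative to a single lineage", {
  # secondary-contact signature: mixture of two deep lineages
  set.seed(12)
  m <- demographic_model(
    data.frame(id = c("R", "X", "Y"), parent = c(NA, "R", "R"),
               ne = c(20000, 10000, 10000)),
    c(R = 500000), 2.5, c(X = 10, Y = 10), label = "two_lineages")
  mut <- mutation_model(rate = 9e-8, kappa = 4, gamma_shape = 0.5)
  mix <- overlay_mutations(simulate_genealogy(m, seed = 1), mut, 800, seed = 2)
  single <- overlay_mutations(
    simulate_genealogy(demographic_model(
      data.frame(id = "X", parent = NA, ne = 10000),
      numeric(0), 2.5, c(X = 20)), seed = 3), mut, 800, seed = 4)
  expect_gt(diversity_stats(mix)$pi, diversity_stats(single)$pi)
})
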