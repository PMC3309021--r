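test_that("mismatch counts follow hand enumeration and sum to C(n,2)", {
  mono <- toy_alignment(rep("ACGTAC", 4))
  mm <- mismatch_distribution(mono)
  expect_equal(mm$counts, choose(4, 2))  # all mass at 0

  # 2 haplotypes (counts 2,2) differing at 5 sites: {0:2, 5:4}
  aln <- toy_alignment(c("AAAAAA", "AAAAAA", "CCCCCA", "CCCCCA"))
  mm <- mismatch_distribution(aln)
  expect_equal(mm$counts, c(2, 0, 0, 0, 0, 4))
  expect_equal(sum(mm$counts), choose(4, 2))

  set.seed(9)
  seqs <- random_seqs(12, 25)
  aln <- haplotype_alignment(seqs, data.frame(individual = rownames(seqs),
                                              population = "p", group = "g"))
  expect_equal(sum(mismatch_distribution(aln)$counts), choose(12, 2))
})

test_that("raggedness matches Harpending's sum with the trailing-zero convention", {
  expect_equal(raggedness(c(0.2, 0.5, 0.3)), 0.22)
  expect_equal(raggedness(1), 1)          # all pairs identical
  # smooth distribution is less ragged than a spiky one
  expect_lt(raggedness(dpois(0:15, 5)), raggedness(c(0.5, 0, 0.5, rep(0, 13))))
})

test_that("sudden-expansion expected curve has the right limits", {
  jmax <- 30
  eq <- function(th) th^(0:jmax) / (1 + th)^(1:(jmax + 1))
  # tau = 0: still at the old equilibrium
  expect_equal(expected_mismatch(0, 1, 50, jmax), eq(1), tolerance = 1e-12)
  # tau large: converged to the new equilibrium
  expect_equal(expected_mismatch(500, 1, 5, jmax), eq(5), tolerance = 1e-8)
  # probabilities: non-negative, at most 1 in total over the window
  f <- expected_mismatch(6, 0.5, 80, jmax)
  expect_true(all(f >= 0) && sum(f) <= 1 + 1e-12)
})

test_that("fitting model-generated frequencies recovers the parameters", {
  jmax <- 40
  truth <- list(tau = 5, theta0 = 1, theta1 = 60)
  f <- expected_mismatch(truth$tau, truth$theta0, truth$theta1, jmax)
  mm <- structure(list(counts = f * 1000, freqs = f, total_pairs = 1000,
                       d_max = jmax, n = 50, L = 600),
                  class = "mismatch_distribution")
  fit <- fit_sudden_expansion(mm)
  expect_lt(fit$ssd, 1e-6)
  expect_equal(fit$tau, truth$tau, tolerance = 0.1)
  # optimum is at least as good as nearby grid evaluations
  for (tau in c(2, 4, 5, 6, 10)) {
    expect_lte(fit$ssd,
               phylodemog:::mismatch_ssd(f, tau, truth$theta0, truth$theta1) + 1e-12)
  }
})

test_that("fit refuses degenerate input and bootstrap is seed-reproducible", {
  mono <- toy_alignment(rep("ACGT", 3))
  expect_error(fit_sudden_expansion(mismatch_distribution(mono)), "identical")

  d <- generate_dataset(scenario_preset("expansion", L = 300), seed = 14)
  mm <- mismatch_distribution(d$aln)
  fit <- fit_sudden_expansion(mm, tau_step = 0.1)
  b1 <- bootstrap_fit_pvalues(d$aln, fit, n_boot = 12, seed = 5, tau_step = 0.25)
  b2 <- bootstrap_fit_pvalues(d$aln, fit, n_boot = 12, seed = 5, tau_step = 0.25)
  expect_identical(b1$p_ssd, b2$p_ssd)
  expect_identical(b1$p_rag, b2$p_rag)
  expect_true(b1$p_ssd >= 0 && b1$p_ssd <= 1)
})

test_that("expansion-simulated data give a unimodal fit; lineage mixtures are rejected", {
  d <- generate_dataset(scenario_preset("expansion", L = 600), seed = 77)
  mm <- mismatch_distribution(d$aln)
  fit <- fit_sudden_expansion(mm)
  # smooth relative to its own expected curve
  expect_lt(fit$raggedness, 0.1)

  # deep unequal two-lineage mixture: bimodal mismatch, poor fit of the
  # sudden-expansion curve -> small bootstrap P for the SSD
  m <- demographic_model(
    data.frame(id = c("R", "X", "Y"), parent = c(NA, "R", "R"),
               ne = c(3000, 3000, 3000)),
    c(R = 1200000), 2.5, c(X = 10, Y = 4), label = "mixture")
  mut <- mutation_model(rate = 9e-8, kappa = 4, gamma_shape = 0.5)
  mix <- overlay_mutations(simulate_genealogy(m, seed = 2), mut, 600, seed = 3)
  fit_mix <- fit_sudden_expansion(mismatch_distribution(mix), tau_step = 0.1)
  fit_mix <- bootstrap_fit_pvalues(mix, fit_mix, n_boot = 40, seed = 9,
                                   tau_step = 0.25)
  expect_lt(fit_mix$p_ssd, 0.1)
  # and it is far more ragged than the expansion data
  expect_gt(fit_mix$raggedness, 3 * fit$raggedness)
})

test_that("expansion-time conversion is linear in tau and reciprocal in L", {
  r <- rate_params(0.036, 2.5, 1248)
  expect_equal(expansion_time(0, r)$years, 0)
  expect_equal(expansion_time(4, r)$years, 2 * expansion_time(2, r)$years)
  r2 <- rate_params(0.036, 2.5, 624)
  expect_equal(expansion_time(2, r2)$years, 2 * expansion_time(2, r)$years)
})
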