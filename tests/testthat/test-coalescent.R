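test_that("model construction validates structure", {
  br <- data.frame(id = c("R", "X", "Y"), parent = c(NA, "R", "R"),
                   ne = c(1000, 1000, 1000))
  expect_error(demographic_model(br, c(R = 100), 2.5, c(R = 2)),
               "leaf branches")
  expect_error(demographic_model(br, numeric(0), 2.5, c(X = 2)),
               "split time")
  m <- demographic_model(br, c(R = 100), 2.5, c(X = 2, Y = 2))
  expect_s3_class(m, "demographic_model")
})

test_that("genealogies are binary, ultrametric, and respect split times", {
  m <- demographic_model(
    data.frame(id = c("R", "X", "Y"), parent = c(NA, "R", "R"),
               ne = c(2000, 2000, 2000)),
    c(R = 50000), 2.5, c(X = 4, Y = 3))
  gen <- simulate_genealogy(m, seed = 2)
  n <- gen$n_tips
  expect_equal(n, 7)
  expect_equal(sum(gen$node_time > 0), n - 1)      # n-1 coalescences
  # node times increase root-ward along every edge
  for (v in (n + 1):(2 * n - 1)) {
    expect_true(all(gen$node_time[v] > gen$node_time[gen$children[v, ]]))
  }
  ph <- ape::as.phylo(gen)
  expect_true(ape::is.ultrametric(ph, tol = 1e-6))
  expect_true(ape::is.binary(ph))
  # cross-population TMRCA cannot predate the split (20000 generations)
  t_split <- 50000 / 2.5
  for (s in 1:25) {
    g2 <- simulate_genealogy(m)
    # any X tip and any Y tip only meet above the split
    expect_gte(tmrca(g2), t_split)
  }
})

test_that("single-population pair TMRCA matches the analytic haploid expectation", {
  m <- demographic_model(data.frame(id = "P", parent = NA, ne = 5000),
                         numeric(0), 2.5, c(P = 2))
  set.seed(10)
  tm <- replicate(600, tmrca(simulate_genealogy(m)))
  expect_equal(mean(tm), 5000, tolerance = 0.1)    # E[T2] = Ne generations
})

test_that("mutation overlay is calibrated and deterministic", {
  m <- demographic_model(data.frame(id = "P", parent = NA, ne = 10000),
                         numeric(0), 2.5, c(P = 2))
  # rate 0: identical sequences
  g <- simulate_genealogy(m, seed = 7)
  a0 <- overlay_mutations(g, mutation_model(rate = 0), 100, seed = 1)
  expect_length(a0$haplotype_id, 1)
  # fixed seed: identical alignment
  mut <- mutation_model(rate = 1e-5, kappa = 4, gamma_shape = 0.5)
  a1 <- overlay_mutations(g, mut, 200, seed = 3)
  a2 <- overlay_mutations(g, mut, 200, seed = 3)
  expect_identical(a1$seqs, a2$seqs)
  # Jukes-Cantor closed form in the symmetric no-heterogeneity limit
  mmjc <- mutation_model(rate = 1e-5, kappa = 1, gamma_shape = Inf)
  set.seed(5)
  obs <- expd <- numeric(20)
  for (i in 1:20) {
    gi <- simulate_genealogy(m)
    ai <- overlay_mutations(gi, mmjc, 4000)
    obs[i] <- segregating_sites(ai) / 4000
    expd[i] <- 0.75 * (1 - exp(-4 / 3 * 1e-5 * 2 * tmrca(gi)))
  }
  expect_equal(mean(obs), mean(expd), tolerance = 0.05)
})

test_that("simulate + mutate closes the loop with theta = 2 Ne mu", {
  ne <- 8000; mu <- 2e-6; L <- 400
  m <- demographic_model(data.frame(id = "P", parent = NA, ne = ne),
                         numeric(0), 2.5, c(P = 8))
  mut <- mutation_model(rate = mu, kappa = 1, gamma_shape = Inf)
  set.seed(6)
  pis <- replicate(300, diversity_stats(
    overlay_mutations(simulate_genealogy(m), mut, L))$pi)
  expect_equal(mean(pis), 2 * ne * mu, tolerance = 0.1)
})

test_that("per-branch size epochs change the coalescent rate", {
  # 100-fold growth at 50 kyr: pair coalescence piles up just beyond it
  pre <- scenario_preset("expansion")
  m <- pre$model
  set.seed(8)
  tm <- replicate(300, tmrca(simulate_genealogy(m)))
  t_exp <- 50000 / 2.5
  # most pairs coalesce after the boundary but soon after (Ne drops to 1000)
  expect_gt(mean(tm > t_exp), 0.7)
  expect_lt(median(tm[tm > t_exp]) - t_exp, 10 * 1000)
})

test_that("the two refugia models carry the empirical sizes and times", {
  models <- paper_models()
  single <- models$single_refugium
  multiple <- models$multiple_refugia
  ne <- setNames(single$branches$ne, single$branches$id)
  expect_equal(unname(ne[c("C", "D", "E")]), c(32333, 14889, 27944))
  expect_equal(unname(ne["ANC"]), 32333 + 14889 + 27944)
  # daughter sizes are proportional shares of the empirical total
  expect_equal(unname(ne["ANC"]), 75611, tolerance = 0.01)
  # 640 000 yr at 2.5 yr/generation = 256 000 generations
  expect_equal(multiple$split_times[["ANC"]] / multiple$generation_time, 256000)
  # model (b) root is older than model (a) root
  expect_gt(max(multiple$split_times), max(single$split_times))
})
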