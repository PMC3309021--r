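test_that("parsimony probability is monotone and pinned regression values hold", {
  expect_gt(parsimony_probability(1, 1248), 0.95)  # single step always safe
  p <- parsimony_probability(1:20, 1248)
  expect_true(all(diff(p) < 0))                     # decreasing in steps
  # frozen regression values from this implementation
  expect_equal(connection_limit(400), 8)
  expect_equal(connection_limit(658), 11)
  # limit never decreases with sequence length
  lims <- vapply(c(200, 400, 800, 1248, 2000), connection_limit, integer(1))
  expect_true(all(diff(lims) >= 0))
})

test_that("a triangle of mutually 1-step haplotypes reports a loop", {
  # three states at one site: every pair differs by exactly one step
  aln <- toy_alignment(c("AA", "CA", "GA"),
                       population = c("p1", "p2", "p3"))
  net <- build_network(aln, limit = 3)
  expect_equal(net$n_components, 1)
  expect_equal(nrow(net$loops), 1)                 # forced homoplasy
  expect_equal(net$loops$steps, 1)
})

test_that("multi-step connections insert intermediate nodes", {
  aln <- toy_alignment(c("AAAA", "CCAA"))          # distance 2
  net <- build_network(aln, limit = 5)
  inter <- net$nodes[net$nodes$type == "intermediate", ]
  expect_equal(nrow(inter), 1)
  expect_equal(inter$id, "m1")
  expect_equal(nrow(net$edges), 2)                 # H1-m1, m1-H2
  # every edge spans exactly one step: path length H1..H2 = 2
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE)
  expect_equal(as.numeric(igraph::distances(g, "H1", "H2")), 2)
})

test_that("components respect the connection limit and lineage structure", {
  d <- study_data()
  net <- build_network(d$aln)   # limit 15 at L = 1248
  expect_equal(net$connection_limit, 15)
  # inter-lineage distances far exceed the limit, so components can
  # never span lineages; deep within-lineage structure may subdivide a
  # lineage, so the component count is bounded below by the 5 groups
  expect_gte(net$n_components, 5)
  # real nodes partition the haplotypes
  expect_equal(sum(net$nodes$type == "haplotype"), length(d$aln$haplotype_id))
  # within a component, all haplotypes connected by single-step edges
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  memb <- igraph::components(g)$membership
  for (cc in unique(net$nodes$component)) {
    ids <- net$nodes$id[net$nodes$component == cc]
    expect_length(unique(memb[ids]), 1)
  }
  # raising the limit never increases the number of components
  net20 <- build_network(d$aln, limit = 20)
  expect_lte(net20$n_components, net$n_components)
  # components map onto the true groups: haplotypes of one component
  # never span two regional lineages
  grp_of_pop <- with(unique(d$aln$samples[, c("population", "group")]),
                     setNames(group, population))
  hap_grp <- apply(d$aln$counts > 0, 1,
                   function(r) unique(grp_of_pop[colnames(d$aln$counts)[r]])[1])
  hn <- net$nodes[net$nodes$type == "haplotype", ]
  expect_true(all(tapply(hap_grp[hn$id], hn$component,
                         function(g) length(unique(g))) == 1))
  expect_setequal(unique(hap_grp[hn$id]), c("A", "B", "C", "D", "E"))
})

test_that("shallow lineages separated beyond the limit give one component each", {
  # three lineages with tiny within-lineage diversity and deep splits:
  # the component count equals the lineage count exactly
  m <- demographic_model(
    data.frame(id = c("R", "YZ", "X", "Y", "Z"),
               parent = c(NA, "R", "R", "YZ", "YZ"),
               ne = c(500, 500, 500, 500, 500)),
    c(R = 3e6, YZ = 2e6), 2.5, c(X = 10, Y = 10, Z = 10))
  mut <- mutation_model(rate = 9e-8, kappa = 4, gamma_shape = 0.5)
  aln <- overlay_mutations(simulate_genealogy(m, seed = 6), mut, 1248, seed = 7)
  net <- build_network(aln)
  expect_equal(net$n_components, 3)
})

test_that("modal haplotype picks frequency, then connectivity, then id", {
  aln <- toy_alignment(c(rep("AAAA", 5), "CAAA"),
                       population = rep("p1", 6))
  net <- build_network(aln, limit = 3)
  expect_equal(modal_haplotype(net, aln)$haplotype, "H1")

  # tie on counts (3 vs 3): the star centre has more connections
  aln2 <- toy_alignment(c(rep("AAAA", 3), rep("CAAA", 3), "ACAA", "AACA"),
                        population = rep("p1", 8))
  net2 <- build_network(aln2, limit = 3)
  md <- modal_haplotype(net2, aln2)
  expect_equal(md$haplotype, "H1")   # H1 degree 3 beats H2 degree 1
})

test_that("star-like expansion clusters centre on the modal haplotype", {
  d <- generate_dataset(scenario_preset("expansion", L = 800), seed = 41)
  net <- build_network(d$aln)
  md <- modal_haplotype(net, d$aln)
  # the modal haplotype should be far more connected than average
  expect_gte(max(net$degree[md$haplotype]), 2)
})

test_that("network writers produce readable files", {
  aln <- toy_alignment(c("AAAA", "CAAA", "CCAA", "TTTT"))
  net <- build_network(aln, limit = 2)
  base <- file.path(tempfile(), "net")
  dir.create(dirname(base), recursive = TRUE)
  files <- write_network(net, base, aln)
  expect_true(all(file.exists(files)))
  g <- igraph::read_graph(files[1], format = "gml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
})
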