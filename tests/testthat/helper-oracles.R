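# Independent oracles and small fixture builders, written against the
# definitions rather than the package's code paths.

# Build a haplotype_alignment from a character vector of sequence
# strings, with optional population/group labels per individual.
toy_alignment <- function(seq_strings, population = NULL, group = NULL) {
  n <- length(seq_strings)
  seqs <- do.call(rbind, strsplit(seq_strings, ""))
  rownames(seqs) <- paste0("ind", seq_len(n))
  population <- population %||% rep("p1", n)
  samples <- data.frame(individual = rownames(seqs),
                        population = population,
                        group = group %||% population,
                        stringsAsFactors = FALSE)
  haplotype_alignment(seqs, samples)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# random aligned sequences (no N/gaps)
random_seqs <- function(n, L) {
  matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE,
                prob = c(0.4, 0.2, 0.2, 0.2)),
         nrow = n, dimnames = list(paste0("ind", seq_len(n)), NULL))
}

# naive per-column segregating-site count on an individual-level matrix
brute_segsites <- function(seqs) {
  sum(apply(seqs, 2, function(col) length(unique(col)) > 1))
}

# Sankoff dynamic programme with unit costs: exact minimum number of
# state changes over all internal assignments, on a genealogy object.
sankoff_s <- function(gen) {
  pops <- unique(gen$tip_pop)
  ns <- length(pops)
  if (ns < 2) return(0L)
  n <- gen$n_tips
  big <- 1e9
  cost <- matrix(big, 2L * n - 1L, ns)
  for (i in seq_len(n)) cost[i, match(gen$tip_pop[i], pops)] <- 0
  for (v in (n + 1):(2L * n - 1L)) {
    for (s in seq_len(ns)) {
      tot <- 0
      for (child in gen$children[v, ]) {
        tot <- tot + min(cost[child, ] + (seq_len(ns) != s))
      }
      cost[v, s] <- tot
    }
  }
  as.integer(min(cost[2L * n - 1L, ]))
}

# random coalescent genealogy with tips assigned to populations
random_genealogy <- function(n, n_pops) {
  m <- demographic_model(data.frame(id = "P", parent = NA, ne = 1000),
                         numeric(0), 1, c(P = n))
  gen <- simulate_genealogy(m)
  gen$tip_pop <- sample(paste0("pop", seq_len(n_pops)), n, replace = TRUE)
  # ensure at least two populations present
  if (length(unique(gen$tip_pop)) < 2) {
    gen$tip_pop[1] <- "pop1"; gen$tip_pop[2] <- "pop2"
  }
  gen
}

# Brute-force three-level AMOVA from first principles: sums of squared
# deviations by explicit double loops over individuals.
brute_amova <- function(d2, pop, grp_of_pop) {
  N <- length(pop)
  grp <- grp_of_pop[pop]
  pops <- names(grp_of_pop)
  groups <- unique(grp_of_pop)
  ss_pairs <- function(idx) {
    s <- 0
    if (length(idx) < 2) return(0)
    for (i in seq_along(idx)[-length(idx)]) for (j in (i + 1):length(idx)) {
      s <- s + d2[idx[i], idx[j]]
    }
    s
  }
  ss_tot <- ss_pairs(seq_len(N)) / N
  ss_wp <- sum(vapply(pops, function(p) {
    idx <- which(pop == p)
    if (length(idx)) ss_pairs(idx) / length(idx) else 0
  }, numeric(1)))
  ss_wg <- sum(vapply(groups, function(g) {
    idx <- which(grp == g)
    if (length(idx)) ss_pairs(idx) / length(idx) else 0
  }, numeric(1)))
  G <- length(groups); P <- length(pops)
  n_p <- vapply(pops, function(p) sum(pop == p), numeric(1))
  N_g <- vapply(groups, function(g) sum(grp == g), numeric(1))
  msd_ag <- (ss_tot - ss_wg) / (G - 1)
  msd_ap <- (ss_wg - ss_wp) / (P - G)
  msd_wp <- ss_wp / (N - P)
  sum_np2_over_Ng <- sum(vapply(groups, function(g) {
    sum(n_p[grp_of_pop == g]^2) / N_g[g]
  }, numeric(1)))
  n1 <- (N - sum_np2_over_Ng) / (P - G)
  n2 <- (sum_np2_over_Ng - sum(n_p^2) / N) / (G - 1)
  n3 <- (N - sum(N_g^2) / N) / (G - 1)
  sc <- msd_wp
  sb <- (msd_ap - sc) / n1
  sa <- (msd_ag - sc - n2 * sb) / n3
  list(sigma = c(a = sa, b = sb, c = sc),
       phi_ct = sa / (sa + sb + sc),
       phi_sc = sb / (sb + sc),
       phi_st = (sa + sb) / (sa + sb + sc))
}

# Exact Ewens K distribution by enumerating all permutations of n and
# counting cycles (P(K=k) proportional to #perms with k cycles * theta^k).
ewens_perm_oracle <- function(n, theta) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  count_cycles <- function(p) {
    seen <- rep(FALSE, length(p)); k <- 0L
    for (s in seq_along(p)) {
      if (seen[s]) next
      k <- k + 1L; cur <- s
      while (!seen[cur]) { seen[cur] <- TRUE; cur <- p[cur] }
    }
    k
  }
  cyc <- vapply(perms(seq_len(n)), count_cycles, integer(1))
  w <- theta^cyc
  p <- tapply(w, factor(cyc, levels = 1:n), sum) / sum(w)
  p[is.na(p)] <- 0
  as.numeric(p)
}

# shared synthetic study-shape dataset, generated once per test run
study_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(scenario_preset("multiple_refugia"), seed = 20260928)
    }
    cache
  }
})

# Exact Ewens K distribution via integer partitions and Cauchy's
# cycle-type count: #perms of n with cycle type (1^m1 2^m2 ...) =
# n! / prod(j^mj * mj!). Independent of the CRP recurrence.
ewens_partition_oracle <- function(n, theta) {
  parts <- list()
  gen <- function(rest, maxpart, acc) {
    if (rest == 0) { parts[[length(parts) + 1]] <<- acc; return(invisible()) }
    for (p in seq_len(min(rest, maxpart))) gen(rest - p, p, c(acc, p))
  }
  gen(n, n, integer(0))
  w <- numeric(n)
  for (lam in parts) {
    mj <- table(lam)
    count <- factorial(n) / prod(as.numeric(names(mj))^mj * factorial(mj))
    k <- length(lam)
    w[k] <- w[k] + count * theta^k
  }
  w / sum(w)
}
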