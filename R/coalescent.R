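#' Define a demographic model (population tree with sizes and split times)
#'
#' Populations are branches of a rooted tree. Each branch has a haploid
#' effective size Ne (mtDNA convention, theta = 2 Ne mu); an internal
#' branch comes into existence (looking backwards in time) at its split
#' time, when its daughter branches merge into it. Split times are in
#' years before present and must increase root-ward. Samples are taken
#' only in leaf branches. A branch may additionally carry size epochs
#' (e.g. a recent expansion): \code{epochs} is a named list mapping a
#' branch id to a data.frame with columns \code{from_yr} (epoch start,
#' years BP) and \code{ne}, applying backwards in time; times before the
#' first epoch use the branch's base \code{ne}.
#'
#' @param branches data.frame with columns \code{id}, \code{parent} (NA
#'   for the root), \code{ne} (haploid effective size).
#' @param split_times named numeric vector, years BP, one entry per
#'   internal branch id.
#' @param generation_time years per generation.
#' @param sample_sizes named integer vector, tips per leaf population.
#' @param epochs optional named list of per-branch size epochs.
#' @param label optional model label.
#' @return object of class \code{demographic_model}.
#' @export
demographic_model <- function(branches, split_times, generation_time,
                              sample_sizes, epochs = NULL, label = "model") {
  stopifnot(all(c("id", "parent", "ne") %in% names(branches)),
            generation_time > 0, all(branches$ne > 0))
  branches$id <- as.character(branches$id)
  branches$parent <- as.character(branches$parent)
  root <- branches$id[is.na(branches$parent)]
  if (length(root) != 1) stop("model must have exactly one root branch", call. = FALSE)
  is_leaf <- !(branches$id %in% branches$parent)
  leaves <- branches$id[is_leaf]
  internals <- setdiff(branches$id, leaves)
  if (!all(internals %in% names(split_times))) {
    stop("every internal branch needs a split time", call. = FALSE)
  }
  if (!all(names(sample_sizes) %in% leaves)) {
    stop("samples can only be placed in leaf branches", call. = FALSE)
  }
  # start time of a branch = 0 for leaves, its split time for internals;
  # end time = parent's split time (Inf for the root)
  start <- stats::setNames(rep(0, nrow(branches)), branches$id)
  start[internals] <- split_times[internals]
  endt <- stats::setNames(rep(Inf, nrow(branches)), branches$id)
  for (b in branches$id) {
    p <- branches$parent[branches$id == b]
    if (!is.na(p)) endt[b] <- split_times[[p]]
  }
  if (any(endt < start - 1e-9)) {
    stop("split times must increase root-ward", call. = FALSE)
  }
  structure(list(branches = branches, split_times = split_times,
                 start = start, end = endt, leaves = leaves, root = root,
                 generation_time = generation_time,
                 sample_sizes = sample_sizes, epochs = epochs,
                 label = label),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Demographic model '", x$label, "': ", length(x$leaves),
      " leaf population(s), ", sum(x$sample_sizes), " samples, generation time ",
      x$generation_time, " yr\n", sep = "")
  invisible(x)
}

# Ne of branch b at time t_gen (generations BP), honouring size epochs.
branch_ne_at <- function(model, b, t_gen) {
  ne <- model$branches$ne[model$branches$id == b]
  ep <- model$epochs[[b]]
  if (!is.null(ep)) {
    t_yr <- t_gen * model$generation_time
    hit <- ep$from_yr <= t_yr
    if (any(hit)) ne <- ep$ne[max(which(hit))]
  }
  ne
}

# next epoch boundary (generations) strictly after t_gen within branch b
next_epoch_boundary <- function(model, b, t_gen) {
  ep <- model$epochs[[b]]
  if (is.null(ep)) return(Inf)
  bd <- ep$from_yr / model$generation_time
  bd <- bd[bd > t_gen + 1e-12]
  if (length(bd)) min(bd) else Inf
}

#' Simulate a genealogy under the structured coalescent
#'
#' Standard n-coalescent within each branch of the population tree: a
#' lineage pair in branch b coalesces at rate 1/Ne_b per generation
#' (haploid scaling, consistent with theta = 2 Ne mu). At a split time
#' (converted to generations), all lineages of the daughter branches
#' move into the parent branch; the root branch extends indefinitely
#' until the last coalescence.
#'
#' @param model a [demographic_model()].
#' @param seed optional RNG seed.
#' @return object of class \code{genealogy}: tips 1..n labelled by
#'   population, internal nodes in coalescence order, children matrix,
#'   node times (generations BP). Convert with [as.phylo.genealogy()].
#' @export
simulate_genealogy <- function(model, seed = NULL) {
  with_seed(seed, {
    n <- sum(model$sample_sizes)
    n_nodes <- 2L * n - 1L
    children <- matrix(0L, n_nodes, 2)
    node_time <- numeric(n_nodes)
    tip_pop <- rep(names(model$sample_sizes), model$sample_sizes)

    gen <- model$generation_time
    start_gen <- model$start / gen
    end_gen <- model$end / gen

    lineages <- split(seq_len(n), tip_pop)        # active lineages per branch
    for (b in setdiff(model$branches$id, names(lineages))) lineages[[b]] <- integer(0)
    active_branch <- function() names(lineages)[lengths(lineages) > 0]

    t_now <- 0
    nxt <- n
    repeat {
      act <- active_branch()
      total_lin <- sum(lengths(lineages[act]))
      if (total_lin == 1) break
      # candidate coalescent waiting time per branch currently alive at t_now
      alive <- act[start_gen[act] <= t_now + 1e-12]
      rates <- vapply(alive, function(b) {
        k <- length(lineages[[b]])
        if (k < 2) 0 else k * (k - 1) / 2 / branch_ne_at(model, b, t_now)
      }, numeric(1))
      total_rate <- sum(rates)
      # next structural boundary: earliest branch end or epoch change
      boundaries <- c(end_gen[alive],
                      vapply(alive, function(b) next_epoch_boundary(model, b, t_now),
                             numeric(1)))
      t_bound <- min(boundaries)
      wait <- if (total_rate > 0) stats::rexp(1, total_rate) else Inf
      if (t_now + wait < t_bound) {
        t_now <- t_now + wait
        b <- if (length(alive) == 1) alive else sample(alive, 1, prob = rates)
        lin <- lineages[[b]]
        pick <- sample.int(length(lin), 2)
        nxt <- nxt + 1L
        children[nxt, ] <- lin[pick]
        node_time[nxt] <- t_now
        lineages[[b]] <- c(lin[-pick], nxt)
      } else {
        if (!is.finite(t_bound)) stop("coalescent stalled: no rate and no boundary")
        t_now <- t_bound
        # move lineages of branches ending here into their parents
        for (b in alive[abs(end_gen[alive] - t_bound) < 1e-9]) {
          p <- model$branches$parent[model$branches$id == b]
          lineages[[p]] <- c(lineages[[p]], lineages[[b]])
          lineages[[b]] <- integer(0)
        }
      }
    }
    structure(list(n_tips = n, children = children, node_time = node_time,
                   tip_pop = tip_pop, model_label = model$label),
              class = "genealogy")
  })
}

#' Convert a genealogy to an ape phylo tree
#'
#' Branch lengths are in generations; tips are labelled
#' "<population>_<index>".
#'
#' @param x a \code{genealogy}.
#' @param ... unused.
#' @return an \code{ape::phylo} object.
#' @method as.phylo genealogy
#' @export
as.phylo.genealogy <- function(x, ...) {
  n <- x$n_tips
  n_nodes <- 2L * n - 1L
  # ape numbering: tips 1..n, root n+1, internals in preorder
  new_id <- integer(n_nodes)
  new_id[1:n] <- 1:n
  counter <- n
  order_stack <- n_nodes            # root = last created
  preorder <- integer(0)
  while (length(order_stack)) {
    v <- order_stack[1]; order_stack <- order_stack[-1]
    preorder <- c(preorder, v)
    kids <- x$children[v, ]
    order_stack <- c(kids[kids > n], order_stack)
  }
  for (v in preorder) { counter <- counter + 1L; new_id[v] <- counter }
  edge <- matrix(0L, n_nodes - 1L, 2)
  elen <- numeric(n_nodes - 1L)
  e <- 0L
  for (v in (n + 1):n_nodes) {
    for (child in x$children[v, ]) {
      e <- e + 1L
      edge[e, ] <- c(new_id[v], new_id[child])
      elen[e] <- x$node_time[v] - x$node_time[child]
    }
  }
  tr <- list(edge = edge, edge.length = elen,
             tip.label = paste0(x$tip_pop, "_", seq_len(n)),
             Nnode = n - 1L)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' TMRCA of a genealogy (generations)
#' @param gen a \code{genealogy}.
#' @return time of the root node in generations BP.
#' @export
tmrca <- function(gen) max(gen$node_time)

#' HKY+Gamma mutation model
#'
#' @param rate substitutions/site/generation (expected, i.e. the rate
#'   matrix is normalized to mean rate 1 at the stationary frequencies).
#' @param kappa transition/transversion rate ratio.
#' @param gamma_shape shape of the per-site Gamma rate multipliers
#'   (mean 1); \code{Inf} disables rate heterogeneity.
#' @param base_freqs stationary base frequencies (A, C, G, T).
#' @return object of class \code{mutation_model} with the eigendecomposed
#'   rate matrix attached.
#' @export
mutation_model <- function(rate, kappa = 4, gamma_shape = 0.5,
                           base_freqs = rep(0.25, 4)) {
  stopifnot(rate >= 0, kappa > 0, gamma_shape > 0,
            length(base_freqs) == 4, abs(sum(base_freqs) - 1) < 1e-8,
            all(base_freqs > 0))
  bases <- c("A", "C", "G", "T")
  names(base_freqs) <- bases
  Q <- matrix(0, 4, 4, dimnames = list(bases, bases))
  transitions <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  for (i in bases) for (j in bases) {
    if (i == j) next
    Q[i, j] <- base_freqs[j] *
      if (any(transitions[, 1] == i & transitions[, 2] == j)) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  mean_rate <- -sum(base_freqs * diag(Q))
  Q <- Q / mean_rate
  # reversible: symmetrize with pi^(1/2) for a stable eigendecomposition
  sq <- sqrt(base_freqs)
  Sm <- diag(sq) %*% Q %*% diag(1 / sq)
  eig <- eigen((Sm + t(Sm)) / 2, symmetric = TRUE)
  V <- diag(1 / sq) %*% eig$vectors
  Vinv <- t(eig$vectors) %*% diag(sq)
  structure(list(rate = rate, kappa = kappa, gamma_shape = gamma_shape,
                 base_freqs = base_freqs, Q = Q,
                 eigenvalues = eig$values, V = V, Vinv = Vinv),
            class = "mutation_model")
}

# P(t)[parent -> child] rows for a vector of per-site distances d:
# returns an L x 4 matrix of transition probabilities for a fixed parent
# base; vectorized over sites.
hky_child_probs <- function(mut, parent_base_idx, d) {
  E <- exp(outer(d, mut$eigenvalues))            # L x 4
  P <- matrix(0, length(d), 4)
  for (jcol in 1:4) {
    w <- mut$V[parent_base_idx, ] * mut$Vinv[, jcol]
    P[, jcol] <- as.numeric(E %*% w)
  }
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Overlay finite-sites HKY+Gamma mutations on a genealogy
#'
#' The root sequence is drawn from the stationary base frequencies;
#' per-site Gamma(alpha, alpha) rate multipliers are drawn once; each
#' branch then evolves every site by the HKY transition probabilities
#' for its length (in generations) times the site rate times the model
#' rate.
#'
#' @param gen a \code{genealogy}.
#' @param mut a [mutation_model()].
#' @param L number of sites.
#' @param seed optional RNG seed.
#' @return a \code{haplotype_alignment} of the simulated tip sequences
#'   (individual ids "<population>_<i>", populations from the
#'   genealogy's tip labels, one group per population).
#' @export
overlay_mutations <- function(gen, mut, L, seed = NULL) {
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    n <- gen$n_tips
    n_nodes <- 2L * n - 1L
    site_rate <- if (is.finite(mut$gamma_shape)) {
      stats::rgamma(L, shape = mut$gamma_shape, rate = mut$gamma_shape)
    } else rep(1, L)
    seq_idx <- matrix(0L, n_nodes, L)
    seq_idx[n_nodes, ] <- sample.int(4, L, replace = TRUE, prob = mut$base_freqs)
    for (v in n_nodes:(n + 1)) {
      for (child in gen$children[v, ]) {
        blen <- gen$node_time[v] - gen$node_time[child]
        d <- mut$rate * site_rate * blen
        child_seq <- integer(L)
        for (pb in 1:4) {
          at <- which(seq_idx[v, ] == pb)
          if (!length(at)) next
          if (mut$rate * blen == 0) { child_seq[at] <- pb; next }
          P <- hky_child_probs(mut, pb, d[at])
          u <- stats::runif(length(at))
          cs <- 1L + (u > P[, 1]) + (u > P[, 1] + P[, 2]) +
            (u > P[, 1] + P[, 2] + P[, 3])
          child_seq[at] <- cs
        }
        seq_idx[child, ] <- child_seq
      }
    }
    seqs <- matrix(bases[seq_idx[1:n, ]], nrow = n)
    rownames(seqs) <- paste0(gen$tip_pop, "_", seq_len(n))
    samples <- data.frame(individual = rownames(seqs),
                          population = gen$tip_pop,
                          group = gen$tip_pop,
                          stringsAsFactors = FALSE)
    haplotype_alignment(seqs, samples)
  })
}

#' The two glacial-refugia demographic models
#'
#' Builds the competing single-refugium and multiple-refugia models for
#' the eastern (C), northwestern (D) and central (E) plateau lineages.
#' (a) Single refugium: one ancestral population containing the total
#' empirical Ne splits into C, D and E at the end of the last glacial
#' maximum (18 000 yr BP). (b) Multiple refugia: C diverges from (D,E)
#' at 640 000 yr BP and D from E at 360 000 yr BP. Leaf Ne values come
#' from the empirical per-lineage Watterson theta via
#' [ne_from_theta()]; ancestral branches default to the sum of their
#' daughters (conserving the total, which matches the empirical total
#' estimate).
#'
#' @param theta named numeric vector of per-site theta for C, D, E
#'   (defaults to the empirical estimates 0.00582, 0.00268, 0.00503).
#' @param rates a [rate_params()] object.
#' @param sample_sizes named vector of tips per lineage.
#' @param t_single,t_split_c,t_split_de split times in years BP.
#' @return list with \code{single_refugium} and \code{multiple_refugia}
#'   [demographic_model()]s.
#' @export
paper_models <- function(theta = c(C = 0.00582, D = 0.00268, E = 0.00503),
                         rates = rate_params(),
                         sample_sizes = c(C = 50, D = 30, E = 120),
                         t_single = 18000, t_split_c = 640000,
                         t_split_de = 360000) {
  ne <- vapply(theta, ne_from_theta, numeric(1), rates = rates)
  single <- demographic_model(
    branches = data.frame(
      id = c("ANC", "DE", "C", "D", "E"),
      parent = c(NA, "ANC", "ANC", "DE", "DE"),
      ne = c(sum(ne), ne[["D"]] + ne[["E"]], ne[["C"]], ne[["D"]], ne[["E"]])),
    split_times = c(ANC = t_single, DE = t_single),
    generation_time = rates$generation_time,
    sample_sizes = sample_sizes,
    label = "single_refugium")
  multiple <- demographic_model(
    branches = data.frame(
      id = c("ANC", "DE", "C", "D", "E"),
      parent = c(NA, "ANC", "ANC", "DE", "DE"),
      ne = c(sum(ne), ne[["D"]] + ne[["E"]], ne[["C"]], ne[["D"]], ne[["E"]])),
    split_times = c(ANC = t_split_c, DE = t_split_de),
    generation_time = rates$generation_time,
    sample_sizes = sample_sizes,
    label = "multiple_refugia")
  list(single_refugium = single, multiple_refugia = multiple)
}
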