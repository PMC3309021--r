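#' Slatkin-Maddison minimum number of sorting events
#'
#' The minimum number of population-state changes needed to explain the
#' distribution of population labels over the tips of a genealogy:
#' Fitch small-parsimony count treating the population as an unordered
#' multistate character on the rooted binary tree. Small S relative to
#' a panmictic expectation indicates deep population subdivision
#' (lineage sorting).
#'
#' @param gen a \code{genealogy} (from [simulate_genealogy()]) or an
#'   \code{ape::phylo} rooted binary tree.
#' @param labels for a phylo input, a named character vector mapping
#'   tip labels to populations; ignored for \code{genealogy} input
#'   (tip populations are embedded).
#' @return integer minimum sorting-event count.
#' @export
slatkin_s <- function(gen, labels = NULL) {
  if (inherits(gen, "genealogy")) {
    n <- gen$n_tips
    pops <- unique(gen$tip_pop)
    if (length(pops) < 2) return(0L)
    state <- lapply(seq_len(2L * n - 1L), function(i) integer(0))
    for (i in seq_len(n)) state[[i]] <- match(gen$tip_pop[i], pops)
    changes <- 0L
    for (v in (n + 1):(2L * n - 1L)) {       # children always precede parents
      a <- state[[gen$children[v, 1]]]
      b <- state[[gen$children[v, 2]]]
      inter <- intersect(a, b)
      if (length(inter)) state[[v]] <- inter
      else { state[[v]] <- union(a, b); changes <- changes + 1L }
    }
    return(changes)
  }
  if (!inherits(gen, "phylo")) stop("need a genealogy or phylo tree", call. = FALSE)
  if (!ape::is.binary(gen) || !ape::is.rooted(gen)) {
    stop("tree must be rooted and binary", call. = FALSE)
  }
  if (is.null(labels)) stop("tip labels -> population mapping required", call. = FALSE)
  pop <- labels[gen$tip.label]
  if (anyNA(pop)) stop("unlabeled tip(s): ",
                       paste(utils::head(gen$tip.label[is.na(pop)], 5), collapse = ", "),
                       call. = FALSE)
  pops <- unique(pop)
  if (length(pops) < 2) return(0L)
  n <- length(gen$tip.label)
  tr <- ape::reorder.phylo(gen, "postorder")
  state <- vector("list", n + gen$Nnode)
  for (i in seq_len(n)) state[[i]] <- match(pop[i], pops)
  changes <- 0L
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  # in postorder, an internal node first appears as a parent only after
  # all its descendant internal nodes have, so this order is children-first
  for (v in unique(tr$edge[, 1])) {
    ab <- kids[[as.character(v)]]
    a <- state[[ab[1]]]; b <- state[[ab[2]]]
    inter <- intersect(a, b)
    if (length(inter)) state[[v]] <- inter
    else { state[[v]] <- union(a, b); changes <- changes + 1L }
  }
  changes
}

#' Null distribution of the sorting-event statistic under a model
#'
#' Simulates \code{n_sims} genealogies under the demographic model and
#' records the Slatkin-Madison S of each (tips labelled by their
#' population of origin).
#'
#' @param model a [demographic_model()].
#' @param n_sims number of simulated genealogies (study default 1000).
#' @param seed optional RNG seed.
#' @return integer vector of S values, with attribute \code{model}.
#' @export
null_distribution <- function(model, n_sims = 1000, seed = NULL) {
  s <- with_seed(seed, vapply(seq_len(n_sims), function(i) {
    slatkin_s(simulate_genealogy(model))
  }, integer(1)))
  attr(s, "model") <- model$label
  s
}

#' Test an observed S against a simulated null distribution
#'
#' The 95% confidence interval is the empirical 2.5th and 97.5th
#' percentile of the null S values (linear-interpolation quantiles,
#' R type 7). The demographic model is rejected when the observed S
#' falls outside the interval; both tail positions are reported.
#'
#' @param observed_s observed minimum sorting-event count.
#' @param null_s vector of simulated S values (from
#'   [null_distribution()]).
#' @param model_label optional label for reporting.
#' @return object of class \code{refugia_test}: observed_s, ci95,
#'   decision ("reject"/"fail-to-reject"), tail ("low"/"high"/"inside"),
#'   null_s.
#' @export
test_hypothesis <- function(observed_s, null_s, model_label = NULL) {
  stopifnot(length(null_s) >= 1)
  ci <- stats::quantile(null_s, c(0.025, 0.975), type = 7, names = FALSE)
  outside <- observed_s < ci[1] | observed_s > ci[2]
  structure(list(
    model_label = model_label %||% attr(null_s, "model"),
    observed_s = observed_s,
    ci95 = ci,
    decision = if (outside) "reject" else "fail-to-reject",
    tail = if (observed_s < ci[1]) "low" else if (observed_s > ci[2]) "high" else "inside",
    null_s = as.integer(null_s)
  ), class = "refugia_test")
}

#' @export
print.refugia_test <- function(x, ...) {
  cat(sprintf("Refugia test vs '%s': observed S = %d, null 95%% CI [%.1f, %.1f] -> %s\n",
              x$model_label %||% "model", x$observed_s, x$ci95[1], x$ci95[2],
              x$decision))
  invisible(x)
}

#' Run the refugia hypothesis test for a set of candidate models
#'
#' For each demographic model, simulates the null distribution of S and
#' compares the observed genealogy's S against it.
#'
#' @param gen observed genealogy (\code{genealogy} or \code{phylo}).
#' @param models named list of [demographic_model()]s.
#' @param labels tip -> population mapping (phylo input only).
#' @param n_sims simulated genealogies per model.
#' @param seed optional seed (one sub-seed per model).
#' @return named list of \code{refugia_test} results.
#' @export
refugia_test <- function(gen, models, labels = NULL, n_sims = 1000, seed = NULL) {
  s_obs <- slatkin_s(gen, labels)
  seeds <- if (is.null(seed)) rep(list(NULL), length(models))
           else as.list(derive_seeds(seed, names(models)))
  out <- Map(function(m, s) {
    test_hypothesis(s_obs, null_distribution(m, n_sims = n_sims, seed = s),
                    model_label = m$label)
  }, models, seeds)
  out
}
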