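# truncated power-series helpers (coefficients of x^0..x^(n-1))
series_mul <- function(a, b) {
  n <- length(a)
  r <- numeric(n)
  for (i in seq_len(n)) if (a[i] != 0) r[i:n] <- r[i:n] + a[i] * b[1:(n - i + 1)]
  r
}
series_pow <- function(a, p, n) {
  r <- numeric(n); r[1] <- 1
  while (p > 0) {
    if (p %% 2 == 1) r <- series_mul(r, a)
    a <- series_mul(a, a)
    p <- p %/% 2
  }
  r
}

#' Probability of parsimony for haplotypes j steps apart
#'
#' Probability that j observed differences between two sequences of
#' length L reflect a parsimonious connection, i.e. that no
#' parsimony-defeating superimposed change occurred. Computed from a
#' coalescent model for a sequence pair: the total substitution count H
#' separating the pair is geometric with mean set to j (the coalescent
#' pair distribution), substitutions fall uniformly over the L sites,
#' and a site hit k times shows a difference with probability
#' 3/4 (1 - (-1/3)^k) (four-state symmetric change). A site hit more
#' than once defeats parsimony with weight w (default 1/2, pinned to
#' the reference TCS program's published connection limit of 15 steps
#' at L = 1248). The probability is
#' P_j = P(no defeated site, D = j) / P(D = j), D the observed
#' difference count.
#'
#' @param j number of observed differences (steps); vectorized.
#' @param L sequence length in sites.
#' @param w violation weight for a multiply-hit site.
#' @return numeric vector of probabilities.
#' @export
parsimony_probability <- function(j, L, w = 0.5) {
  vapply(j, function(jj) parsprob_one(jj, L, w), numeric(1))
}

parsprob_one <- function(j, m, w, h_extra = 30L) {
  stopifnot(j >= 1, m >= 1, j <= m)
  hmax <- j + h_extra
  n <- hmax + 1L
  k <- 0:hmax
  lf <- lgamma(k + 1)
  ex <- exp(-lf)                                   # x^k/k! coefficients of e^x
  pk <- 0.75 * (1 - (-1 / 3)^k)                     # visibility after k hits
  A <- pk * ex                                      # visible sites, any k >= 1
  B <- ex - A                                       # no visible difference
  A2 <- A; A2[2] <- 0                               # visible, k >= 2
  I2 <- (ex - A); I2[1] <- 0; I2[2] <- 0            # invisible, k >= 2

  theta <- j
  h <- 0:hmax
  prH <- exp(h * log(theta / (1 + theta)) - log(1 + theta))

  lc <- lgamma(m + 1) - lgamma(j + 1) - lgamma(m - j + 1)
  coefs <- function(S) {
    out <- exp(lgamma(h + 1) - h * log(m) + lc + log(pmax(S, 0)))
    out[S <= 0] <- 0
    out
  }
  den <- sum(prH * coefs(series_mul(series_pow(A, j, n), series_pow(B, m - j, n))))
  # allowed per-site series: a visible single hit, or a multiply-hit site
  # surviving with probability (1 - w)
  V <- numeric(n); V[2] <- 1
  V <- V + (1 - w) * A2
  U <- numeric(n); U[1] <- 1
  U <- U + (1 - w) * I2
  num <- sum(prH * coefs(series_mul(series_pow(V, j, n), series_pow(U, m - j, n))))
  num / den
}

#' Statistical-parsimony connection limit
#'
#' The largest number of mutational steps j whose probability of
#' parsimony ([parsimony_probability()]) is at least \code{confidence};
#' haplotype pairs farther apart than this are not connected in the
#' network (the TCS 95% criterion).
#'
#' @param L sequence length in sites.
#' @param confidence parsimony confidence level (default 0.95).
#' @return integer connection limit (0 if even one step fails).
#' @export
connection_limit <- function(L, confidence = 0.95) {
  stopifnot(L >= 1, confidence > 0, confidence < 1)
  j <- 0L
  while (j < L && parsprob_one(j + 1L, L, 0.5) >= confidence) j <- j + 1L
  j
}

#' Build a statistical-parsimony haplotype network
#'
#' Agglomerative TCS-style assembly: haplotype pairs are connected in
#' order of increasing mutational distance up to the connection limit.
#' Ties at equal distance are processed connecting higher-frequency
#' haplotypes first (an approximation of TCS's ancestral-weighting
#' heuristic, pinned by tests). A connection of d steps inserts d-1
#' synthetic intermediate ("missing") nodes labelled m1, m2, ... in
#' insertion order. A pair whose components were distinct
#' at the start of its distance level but merged within it is an
#' alternative connection and is recorded as a loop, not discarded
#' (their absence in real data is a reportable result).
#'
#' @param aln a \code{haplotype_alignment}.
#' @param limit connection limit in steps; default
#'   \code{connection_limit(aln$L_effective)}.
#' @return object of class \code{haplotype_network}: nodes and edges
#'   data.frames, loops data.frame, components, connection_limit.
#' @export
build_network <- function(aln, limit = NULL) {
  if (is.null(limit)) limit <- connection_limit(aln$L_effective)
  if (limit < 1) stop("connection limit must be >= 1", call. = FALSE)
  D <- hap_distances(aln)
  haps <- aln$haplotype_id
  k <- length(haps)
  cnt <- haplotype_counts(aln)

  comp <- seq_len(k)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }

  pairs <- which(upper.tri(D), arr.ind = TRUE)
  pd <- D[upper.tri(D)]
  keep <- pd >= 1 & pd <= limit
  pairs <- pairs[keep, , drop = FALSE]
  pd <- pd[keep]
  # frequency-weighted tie-break within a distance level
  wt <- cnt[pairs[, 1]] + cnt[pairs[, 2]]
  ord <- order(pd, -wt, pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  pd <- pd[ord]

  edges <- list()
  loops <- list()
  inter_n <- 0L
  inter_host <- integer(0)   # a haplotype index in the intermediate's component
  degree <- stats::setNames(integer(k), haps)
  comp_at_level_start <- comp

  add_edge <- function(a, b) edges[[length(edges) + 1L]] <<- c(a, b)

  prev_d <- -1L
  for (e in seq_along(pd)) {
    d <- pd[e]
    if (d != prev_d) {
      comp_at_level_start <- vapply(seq_len(k), find, integer(1))
      prev_d <- d
    }
    i <- pairs[e, 1]; j <- pairs[e, 2]
    ci <- find(i); cj <- find(j)
    if (ci != cj) {
      # connect through d-1 intermediates
      chain <- haps[i]
      if (d > 1) {
        for (s in seq_len(d - 1)) {
          inter_n <- inter_n + 1L
          inter_host[inter_n] <- i
          nm <- paste0(".m", inter_n)
          add_edge(chain, nm)
          chain <- nm
        }
      }
      add_edge(chain, haps[j])
      degree[i] <- degree[i] + 1L; degree[j] <- degree[j] + 1L
      comp[ci] <- cj
    } else if (comp_at_level_start[i] != comp_at_level_start[j]) {
      loops[[length(loops) + 1L]] <- data.frame(from = haps[i], to = haps[j],
                                                steps = d)
    }
  }

  comp_id <- vapply(seq_len(k), find, integer(1))
  comp_labels <- match(comp_id, unique(comp_id))
  names(comp_labels) <- haps

  # intermediates keep global insertion-order ids (unique across components)
  inter_comp <- comp_labels[inter_host]
  new_names <- if (inter_n) paste0("m", seq_len(inter_n)) else character(0)
  tmp_names <- paste0(".m", seq_len(inter_n))
  edges <- if (length(edges)) {
    data.frame(from = vapply(edges, `[`, character(1), 1),
               to = vapply(edges, `[`, character(1), 2))
  } else data.frame(from = character(0), to = character(0))
  fix <- function(x) {
    idx <- match(x, tmp_names)
    ifelse(is.na(idx), x, new_names[idx])
  }
  edges$from <- fix(edges$from); edges$to <- fix(edges$to)

  nodes <- data.frame(
    id = c(haps, new_names),
    type = c(rep("haplotype", k), rep("intermediate", inter_n)),
    count = c(unname(cnt), rep(0L, inter_n)),
    component = c(unname(comp_labels), unname(inter_comp))
  )
  structure(list(nodes = nodes, edges = edges,
                 loops = if (length(loops)) do.call(rbind, loops)
                         else data.frame(from = character(0), to = character(0),
                                         steps = integer(0)),
                 n_components = length(unique(comp_labels)),
                 connection_limit = limit,
                 degree = degree),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("Statistical-parsimony network: limit", x$connection_limit, "steps,",
      x$n_components, "component(s),",
      sum(x$nodes$type == "haplotype"), "haplotypes,",
      sum(x$nodes$type == "intermediate"), "inferred intermediates\n")
  cat(if (nrow(x$loops)) paste(nrow(x$loops), "alternative connection(s) (loops) observed\n")
      else "No alternative connections (loops) observed\n")
  invisible(x)
}

#' Modal haplotype of each network component
#'
#' The highest-frequency haplotype per component; ties are broken by
#' the larger number of network connections, then by lexical id. In
#' star-like expansion clusters this picks the putative ancestral
#' haplotype at the star's centre.
#'
#' @param net a \code{haplotype_network}.
#' @param aln the \code{haplotype_alignment} it was built from.
#' @return data.frame: component, modal haplotype, count.
#' @export
modal_haplotype <- function(net, aln) {
  hn <- net$nodes[net$nodes$type == "haplotype", ]
  out <- lapply(split(hn, hn$component), function(df) {
    o <- order(-df$count, -net$degree[df$id], df$id)
    data.frame(component = df$component[1], haplotype = df$id[o[1]],
               count = df$count[o[1]])
  })
  do.call(rbind, out)
}

#' Write a network as GML and edge-list/component TSVs
#' @param net a \code{haplotype_network}.
#' @param basename output path prefix (writes .gml, _edges.tsv,
#'   _components.tsv).
#' @param aln alignment for the component summary (optional).
#' @return invisibly, the file paths.
#' @export
write_network <- function(net, basename, aln = NULL) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  gml <- paste0(basename, ".gml")
  igraph::write_graph(g, gml, format = "gml")
  ef <- paste0(basename, "_edges.tsv")
  utils::write.table(net$edges, ef, sep = "\t", quote = FALSE, row.names = FALSE)
  cf <- paste0(basename, "_components.tsv")
  hn <- net$nodes[net$nodes$type == "haplotype", ]
  summ <- do.call(rbind, lapply(split(hn, hn$component), function(df) {
    data.frame(component = df$component[1], n_haplotypes = nrow(df),
               n_copies = sum(df$count))
  }))
  if (!is.null(aln)) summ$modal <- modal_haplotype(net, aln)$haplotype
  utils::write.table(summ, cf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(gml, ef, cf))
}
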