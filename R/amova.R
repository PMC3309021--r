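# Core three-level AMOVA decomposition from a haplotype distance matrix
# (treated as squared distances, Arlequin's "pairwise difference"
# convention), haplotype index per individual, population per
# individual, and group per population. Returns sums of squares,
# variance components and Phi-statistics. Excoffier et al. (1992)
# weighted decomposition.
amova_components <- function(D, hap_idx, pop, grp_of_pop) {
  N <- length(hap_idx)
  pops <- names(grp_of_pop)
  pop <- factor(pop, levels = pops)
  grp <- factor(grp_of_pop[as.character(pop)], levels = unique(grp_of_pop))
  G <- nlevels(grp); P <- nlevels(pop)

  # pair sums of (squared) distances via haplotype count vectors
  k <- nrow(D)
  cvec <- function(idx) tabulate(hap_idx[idx], k)
  pair_sum <- function(cv) as.numeric(cv %*% D %*% cv) / 2

  n_p <- tabulate(pop, P)
  ss_tot <- pair_sum(cvec(seq_len(N))) / N
  ss_wp <- 0
  for (p in seq_len(P)) {
    if (n_p[p] > 0) ss_wp <- ss_wp + pair_sum(cvec(which(as.integer(pop) == p))) / n_p[p]
  }
  ss_wg <- 0
  N_g <- numeric(G)
  for (g in seq_len(G)) {
    idx <- which(as.integer(grp) == g)
    N_g[g] <- length(idx)
    if (N_g[g] > 0) ss_wg <- ss_wg + pair_sum(cvec(idx)) / N_g[g]
  }
  ss_ag <- ss_tot - ss_wg
  ss_ap <- ss_wg - ss_wp

  df_ag <- G - 1; df_ap <- P - G; df_wp <- N - P
  ms_wp <- ss_wp / df_wp
  ms_ap <- if (df_ap > 0) ss_ap / df_ap else NA_real_
  ms_ag <- if (df_ag > 0) ss_ag / df_ag else NA_real_

  # coefficients of the expected mean squares
  sum_np2_over_Ng <- 0
  for (g in seq_len(G)) {
    pset <- which(grp_of_pop == levels(grp)[g])
    if (N_g[g] > 0) sum_np2_over_Ng <- sum_np2_over_Ng + sum(n_p[pset]^2) / N_g[g]
  }
  n1 <- if (df_ap > 0) (N - sum_np2_over_Ng) / df_ap else NA_real_
  n2 <- if (df_ag > 0) (sum_np2_over_Ng - sum(n_p^2) / N) / df_ag else NA_real_
  n3 <- if (df_ag > 0) (N - sum(N_g^2) / N) / df_ag else NA_real_

  sig_c <- ms_wp
  sig_b <- if (df_ap > 0) (ms_ap - sig_c) / n1 else 0
  sig_a <- if (df_ag > 0) (ms_ag - sig_c - n2 * sig_b) / n3 else 0
  total <- sig_a + sig_b + sig_c

  list(ss = c(among_groups = ss_ag, among_pops_within = ss_ap, within_pops = ss_wp),
       df = c(df_ag, df_ap, df_wp),
       sigma = c(a = sig_a, b = sig_b, c = sig_c),
       pct = 100 * c(sig_a, sig_b, sig_c) / total,
       phi_ct = sig_a / total,
       phi_sc = sig_b / (sig_b + sig_c),
       phi_st = (sig_a + sig_b) / total,
       total = total)
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Three-level AMOVA (among groups / among populations within groups /
#' within populations) on pairwise nucleotide difference distances, with
#' Phi-statistics and permutation P-values. Permutation schemes follow
#' Excoffier et al. (1992): Phi_CT permutes whole populations among
#' groups, Phi_SC permutes individuals among populations within their
#' group, Phi_ST permutes individuals among populations. P-values are
#' (count{perm >= obs} + 1) / (n_perm + 1). Negative variance components
#' are reported as-is with a flag, keeping the percentages additive.
#'
#' @param aln a \code{haplotype_alignment}.
#' @param grouping named character vector population -> group; defaults
#'   to the groups in the alignment's sample table.
#' @param n_perm number of permutations (study default 1000).
#' @param seed optional RNG seed.
#' @param label optional grouping label for reports.
#' @return object of class \code{amova_result}.
#' @export
amova <- function(aln, grouping = NULL, n_perm = 1000, seed = NULL,
                  label = "groups") {
  samples <- aln$samples
  if (is.null(grouping)) {
    pg <- unique(samples[, c("population", "group")])
    grouping <- stats::setNames(pg$group, pg$population)
  }
  pops <- names(grouping)
  if (!all(samples$population %in% pops)) {
    stop("grouping does not cover all populations", call. = FALSE)
  }
  if (length(pops) < 2) stop("AMOVA needs at least 2 populations", call. = FALSE)
  D <- hap_distances(aln)
  hap_idx <- match(samples$haplotype, aln$haplotype_id)
  pop <- samples$population

  obs <- amova_components(D, hap_idx, pop, grouping)
  degenerate <- !is.finite(obs$total) || obs$total <= 0
  G <- length(unique(grouping))

  p_ct <- p_sc <- p_st <- NA_real_
  if (!degenerate && n_perm > 0) {
    perms <- with_seed(seed, {
      ct <- sc <- st <- 0L
      pop_f <- factor(pop, levels = pops)
      grp_sizes <- table(factor(grouping, levels = unique(grouping)))
      for (b in seq_len(n_perm)) {
        if (G > 1) {
          g_perm <- stats::setNames(sample(grouping), pops)       # pops among groups
          r <- amova_components(D, hap_idx, pop, g_perm)
          if (is.finite(r$phi_ct) && r$phi_ct >= obs$phi_ct - 1e-12) ct <- ct + 1L
        }
        # individuals among pops within groups
        idx_sc <- seq_along(hap_idx)
        for (g in unique(grouping)) {
          members <- which(grouping[pop] == g)
          idx_sc[members] <- members[sample.int(length(members))]
        }
        r <- amova_components(D, hap_idx[idx_sc], pop, grouping)
        if (is.finite(r$phi_sc) && r$phi_sc >= obs$phi_sc - 1e-12) sc <- sc + 1L
        # individuals among pops, ignoring groups
        r <- amova_components(D, hap_idx[sample.int(length(hap_idx))], pop, grouping)
        if (is.finite(r$phi_st) && r$phi_st >= obs$phi_st - 1e-12) st <- st + 1L
      }
      list(ct = ct, sc = sc, st = st)
    })
    if (G > 1) p_ct <- (perms$ct + 1) / (n_perm + 1)
    p_sc <- (perms$sc + 1) / (n_perm + 1)
    p_st <- (perms$st + 1) / (n_perm + 1)
  }

  structure(list(
    grouping_label = label, grouping = grouping,
    df = obs$df, ss = obs$ss,
    var_among_groups = obs$sigma[["a"]],
    var_among_pops_within = obs$sigma[["b"]],
    var_within_pops = obs$sigma[["c"]],
    pct_variation = obs$pct,
    phi_ct = obs$phi_ct, phi_sc = obs$phi_sc, phi_st = obs$phi_st,
    p_ct = p_ct, p_sc = p_sc, p_st = p_st,
    n_perm = n_perm,
    degenerate = degenerate,
    negative_components = any(obs$sigma < 0)
  ), class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (", x$grouping_label, ")\n", sep = "")
  if (x$degenerate) {
    cat("  degenerate: no molecular variance in the data\n")
    return(invisible(x))
  }
  lab <- c("Among groups", "Among populations within groups", "Within populations")
  for (i in 1:3) cat(sprintf("  %-33s %6.2f%%\n", lab[i], x$pct_variation[i]))
  cat(sprintf("  Phi_CT = %.5f (P = %.4g), Phi_SC = %.5f (P = %.4g), Phi_ST = %.5f (P = %.4g)\n",
              x$phi_ct, x$p_ct, x$phi_sc, x$p_sc, x$phi_st, x$p_st))
  if (x$negative_components) cat("  note: negative variance component(s) reported as-is\n")
  invisible(x)
}

#' Compare candidate groupings by their among-group fixation index
#'
#' Runs [amova()] for each candidate population-to-group assignment and
#' ranks them by Phi_CT; the arg-max is declared the most probable
#' geographical subdivision (the criterion of maximizing the
#' among-group component of the total variance).
#'
#' @param aln a \code{haplotype_alignment}.
#' @param groupings named list of named character vectors
#'   (population -> group).
#' @param n_perm permutations per grouping.
#' @param seed optional RNG seed (one sub-seed per grouping).
#' @return data.frame sorted by descending Phi_CT, with a \code{best}
#'   flag; the full \code{amova_result}s are in attribute
#'   \code{results}.
#' @export
compare_groupings <- function(aln, groupings, n_perm = 1000, seed = NULL) {
  stopifnot(length(groupings) >= 2)
  if (is.null(names(groupings))) names(groupings) <- paste0("grouping", seq_along(groupings))
  seeds <- if (is.null(seed)) rep(list(NULL), length(groupings))
           else as.list(derive_seeds(seed, names(groupings)))
  res <- Map(function(g, lab, s) amova(aln, g, n_perm = n_perm, seed = s, label = lab),
             groupings, names(groupings), seeds)
  df <- data.frame(
    grouping = names(groupings),
    n_groups = vapply(groupings, function(g) length(unique(g)), integer(1)),
    phi_ct = vapply(res, `[[`, numeric(1), "phi_ct"),
    phi_sc = vapply(res, `[[`, numeric(1), "phi_sc"),
    phi_st = vapply(res, `[[`, numeric(1), "phi_st"),
    pct_among_groups = vapply(res, function(r) r$pct_variation[1], numeric(1)),
    p_ct = vapply(res, `[[`, numeric(1), "p_ct"),
    row.names = NULL
  )
  df <- df[order(-df$phi_ct), ]
  df$best <- seq_len(nrow(df)) == 1
  attr(df, "results") <- res
  df
}
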