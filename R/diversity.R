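#' Rate parameters for molecular-clock conversions
#'
#' @param subs_rate substitution rate in substitutions/site/Myr.
#' @param generation_time generation time in years.
#' @param L sequence length in sites.
#' @return object of class \code{rate_params}.
#' @export
rate_params <- function(subs_rate = 0.036, generation_time = 2.5, L = 1248) {
  stopifnot(subs_rate > 0, generation_time > 0, L >= 1)
  structure(list(subs_rate = subs_rate, generation_time = generation_time,
                 L = as.integer(L)),
            class = "rate_params")
}

harmonic_sum <- function(n, power = 1) sum(1 / seq_len(n - 1)^power)

#' Basic diversity statistics for a haplotype alignment
#'
#' Haplotype diversity h = n/(n-1) (1 - sum p_i^2); nucleotide diversity
#' pi = mean pairwise differences per site over all sequence pairs
#' (count-weighted); Watterson's theta = S / (a_n L) with
#' a_n = sum_{i<n} 1/i. pi and theta are per site over the retained
#' length.
#'
#' @param aln a \code{haplotype_alignment} with at least 2 sequences.
#' @return list of class \code{diversity_stats}: n, k, h, pi, theta_w,
#'   S, L (retained sites), pi_seq (mean pairwise differences per
#'   sequence).
#' @export
diversity_stats <- function(aln) {
  n <- n_individuals(aln)
  if (n < 2) stop("diversity statistics need at least 2 sequences", call. = FALSE)
  cnt <- haplotype_counts(aln)
  p <- cnt / n
  h <- n / (n - 1) * (1 - sum(p^2))
  d <- hap_distances(aln)
  pairs <- n * (n - 1) / 2
  pi_seq <- as.numeric(cnt %*% d %*% cnt / 2) / pairs
  S <- segregating_sites(aln)
  L <- aln$L_effective
  structure(list(n = n, k = length(cnt), h = h, pi = pi_seq / L,
                 theta_w = S / (harmonic_sum(n) * L), S = S, L = L,
                 pi_seq = pi_seq),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf("n = %d, k = %d haplotypes, S = %d segregating sites\n", x$n, x$k, x$S))
  cat(sprintf("h = %.5f, pi = %.6f /site, theta_W = %.6f /site\n", x$h, x$pi, x$theta_w))
  invisible(x)
}

#' Convert per-site Watterson's theta to effective population size
#'
#' Uses theta = 2 Ne mu for maternally inherited haploid loci, with
#' mu = subs_rate * 1e-6 * generation_time (per site per generation).
#' The returned Ne is rounded half-up to an integer for reporting.
#'
#' @param theta_w per-site theta estimate (>= 0).
#' @param rates a [rate_params()] object.
#' @param round round to integer (default TRUE).
#' @return effective population size in individuals.
#' @export
ne_from_theta <- function(theta_w, rates = rate_params(), round = TRUE) {
  stopifnot(all(theta_w >= 0))
  mu_gen <- rates$subs_rate * 1e-6 * rates$generation_time
  ne <- theta_w / (2 * mu_gen)
  if (round) round_half_up(ne) else ne
}

# Tajima (1989) normalizing constants.
tajima_constants <- function(n) {
  a1 <- harmonic_sum(n)
  a2 <- harmonic_sum(n, 2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# One neutral constant-size coalescent replicate under the infinite-sites
# model, in coalescent units where a lineage pair coalesces at rate 1 and
# mutations fall at rate theta/2 per lineage. Returns the summaries the
# neutrality tests need: S, mean pairwise differences per sequence, and
# the number of distinct haplotypes.
sim_neutral_sample <- function(n, theta) {
  n_nodes <- 2L * n - 1L
  left <- right <- integer(n_nodes)
  blen <- numeric(n_nodes)        # branch above each node
  ndesc <- integer(n_nodes); ndesc[1:n] <- 1L
  active <- 1:n
  t_now <- 0
  nxt <- n
  birth <- numeric(n_nodes)       # time the node was created
  for (k in n:2) {
    t_now <- t_now + stats::rexp(1, rate = k * (k - 1) / 2)
    pick <- sample.int(k, 2)
    a <- active[pick[1]]; b <- active[pick[2]]
    nxt <- nxt + 1L
    left[nxt] <- a; right[nxt] <- b
    blen[a] <- t_now - birth[a]; blen[b] <- t_now - birth[b]
    birth[nxt] <- t_now
    ndesc[nxt] <- ndesc[a] + ndesc[b]
    active <- c(active[-pick], nxt)
  }
  total_len <- sum(blen)
  S <- stats::rpois(1, theta / 2 * total_len)
  if (S == 0) {
    return(list(S = 0L, pi_seq = 0, k = 1L, n = n))
  }
  mut_branch <- sample.int(n_nodes, S, replace = TRUE, prob = blen)
  i <- ndesc[mut_branch]
  pi_seq <- sum(i * (n - i)) / (n * (n - 1) / 2)
  # haplotype classes: tips connected through mutation-free branches
  parent <- integer(n_nodes)
  parent[left[(n + 1):n_nodes]] <- (n + 1):n_nodes
  parent[right[(n + 1):n_nodes]] <- (n + 1):n_nodes
  has_mut <- tabulate(mut_branch, n_nodes) > 0
  comp <- seq_len(n_nodes)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  for (v in seq_len(n_nodes - 1L)) {   # root has no parent edge
    if (!has_mut[v] && parent[v] > 0) {
      comp[find(v)] <- find(parent[v])
    }
  }
  k_hap <- length(unique(vapply(1:n, find, integer(1))))
  list(S = S, pi_seq = pi_seq, k = k_hap, n = n)
}

#' Tajima's D with a coalescent P-value
#'
#' D = (pi - S/a1) / sqrt(e1 S + e2 S (S-1)) with Tajima's (1989)
#' constants, pi in per-sequence units. The P-value is obtained by
#' simulating \code{n_sims} constant-size neutral coalescent samples
#' conditioned on n and theta-hat = S/a1, computing D for each
#' (replicates with S = 0 contribute D = 0), and reporting the lower
#' tail p_low = Pr(D_sim <= D_obs) together with the two-sided
#' convention p_two = 2 min(p_low, 1 - p_low). Significantly negative D
#' indicates demographic expansion.
#'
#' @param aln a \code{haplotype_alignment} with S >= 1 and n >= 4.
#' @param n_sims number of null simulations.
#' @param seed optional RNG seed.
#' @return list of class \code{neutrality_test}: statistic, p_low,
#'   p_two, null (simulated statistics).
#' @export
tajimas_d <- function(aln, n_sims = 1000, seed = NULL) {
  st <- diversity_stats(aln)
  if (st$S < 1) stop("Tajima's D undefined with no segregating sites", call. = FALSE)
  if (st$n < 4) stop("Tajima's D needs n >= 4", call. = FALSE)
  cst <- tajima_constants(st$n)
  d_of <- function(pi_seq, S) {
    if (S == 0) return(0)
    (pi_seq - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  }
  D <- d_of(st$pi_seq, st$S)
  theta_hat <- st$S / cst$a1
  null <- with_seed(seed, vapply(seq_len(n_sims), function(i) {
    s <- sim_neutral_sample(st$n, theta_hat)
    d_of(s$pi_seq, s$S)
  }, numeric(1)))
  p_low <- mean(null <= D)
  structure(list(statistic = D, p_low = p_low,
                 p_two = min(1, 2 * min(p_low, 1 - p_low)),
                 null = null, method = "Tajima's D"),
            class = "neutrality_test")
}

#' Ewens sampling distribution of the number of haplotypes
#'
#' P(K = k | theta, n) for the Ewens sampling formula, computed by the
#' Chinese-restaurant recurrence
#' P_{n+1}(k) = n/(theta+n) P_n(k) + theta/(theta+n) P_n(k-1),
#' which is numerically stable at any n (equivalent to the Stirling
#' number form |s(n,k)| theta^k / theta^(n rising)).
#'
#' @param n sample size.
#' @param theta scaled mutation parameter (per sequence), > 0.
#' @return numeric vector p[k], k = 1..n, summing to 1.
#' @export
ewens_k_dist <- function(n, theta) {
  stopifnot(n >= 1, theta > 0)
  p <- 1   # n = 1: K = 1
  if (n == 1) return(p)
  for (m in 1:(n - 1)) {
    p <- c(p * m, 0) / (theta + m) + c(0, p) * theta / (theta + m)
  }
  p
}

#' Fu's Fs with a coalescent P-value
#'
#' Fs = ln(S' / (1 - S')) with S' = P(K >= k_obs | theta_pi, n) from the
#' Ewens sampling formula, theta_pi the mean pairwise difference per
#' sequence (the plug-in Fu 1997 and Arlequin use). The P-value is the
#' fraction of \code{n_sims} constant-size neutral replicates
#' (conditioned on n and theta_pi) whose Fs, computed from their own
#' simulated k and theta_pi, is <= the observed Fs; replicates with
#' S = 0 are skipped. Large negative Fs indicates an excess of rare
#' haplotypes, the signature of demographic expansion. Arlequin's
#' convention deems Fs significant at P < 0.02; the study literature
#' often reads P < 0.05 -- both verdicts are reported.
#'
#' @param aln a \code{haplotype_alignment} with S >= 1 and n >= 3.
#' @param n_sims number of null simulations.
#' @param seed optional RNG seed.
#' @return list of class \code{neutrality_test}: statistic, p_low,
#'   s_prime, significant_0.02, significant_0.05, null.
#' @export
fu_fs <- function(aln, n_sims = 1000, seed = NULL) {
  st <- diversity_stats(aln)
  if (st$S < 1) stop("Fu's Fs undefined with no segregating sites", call. = FALSE)
  if (st$n < 3) stop("Fu's Fs needs n >= 3", call. = FALSE)
  fs_of <- function(k, theta, n) {
    if (theta <= 0) return(NA_real_)
    sp <- sum(ewens_k_dist(n, theta)[k:n])
    if (sp <= 0) { warning("S' underflowed to 0; Fs reported as -Inf"); return(-Inf) }
    if (sp >= 1) { return(Inf) }
    log(sp / (1 - sp))
  }
  Fs <- fs_of(st$k, st$pi_seq, st$n)
  null <- with_seed(seed, {
    out <- numeric(0)
    for (i in seq_len(n_sims)) {
      s <- sim_neutral_sample(st$n, st$pi_seq)
      if (s$S == 0) next
      out <- c(out, fs_of(s$k, s$pi_seq, s$n))
    }
    out
  })
  p_low <- mean(null <= Fs)
  structure(list(statistic = Fs, p_low = p_low,
                 s_prime = 1 / (1 + exp(-Fs)),
                 significant_0.02 = is.finite(Fs) && Fs < 0 && p_low < 0.02,
                 significant_0.05 = is.finite(Fs) && Fs < 0 && p_low < 0.05,
                 null = null, method = "Fu's Fs"),
            class = "neutrality_test")
}

#' @export
print.neutrality_test <- function(x, ...) {
  cat(sprintf("%s = %.5f (P = %.3f one-tailed low)\n", x$method, x$statistic, x$p_low))
  invisible(x)
}
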