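#' Mismatch distribution of an alignment
#'
#' Histogram of pairwise differences over all unordered sequence pairs,
#' haplotypes expanded by their copy numbers. Unimodal, roughly Poisson
#' shaped distributions are the signature of a sudden demographic
#' expansion; multimodal ("ragged") ones indicate stationarity or
#' admixed divergent lineages.
#'
#' @param aln a \code{haplotype_alignment} with n >= 2.
#' @return object of class \code{mismatch_distribution}: counts (index
#'   j = 0..d_max), freqs, total_pairs, d_max, n, L.
#' @export
mismatch_distribution <- function(aln) {
  n <- n_individuals(aln)
  if (n < 2) stop("mismatch distribution needs n >= 2", call. = FALSE)
  d <- hap_distances(aln)
  cnt <- haplotype_counts(aln)
  d_max <- max(d)
  counts <- numeric(d_max + 1)
  counts[1] <- sum(cnt * (cnt - 1) / 2)                  # identical pairs
  k <- length(cnt)
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      counts[d[i, j] + 1] <- counts[d[i, j] + 1] + cnt[i] * cnt[j]
    }
  }
  total <- n * (n - 1) / 2
  structure(list(counts = counts, freqs = counts / total, total_pairs = total,
                 d_max = d_max, n = n, L = aln$L_effective),
            class = "mismatch_distribution")
}

#' Expected mismatch probabilities under the sudden-expansion model
#'
#' Rogers-Harpending infinite-sites model of a population at mutational
#' equilibrium theta0 that grew instantaneously to theta1 at tau
#' mutational time units before present:
#' F_j(tau, theta0, theta1) = F^eq_j(theta1) +
#'   exp(-tau (theta1+1)/theta1) * sum_{i=0}^{j} tau^i/i! *
#'   (F^eq_{j-i}(theta0) - F^eq_{j-i}(theta1)),
#' with equilibrium F^eq_j(theta) = theta^j / (1+theta)^{j+1}.
#'
#' @param tau expansion age in mutational units (>= 0).
#' @param theta0,theta1 pre-/post-expansion theta per sequence,
#'   0 <= theta0 <= theta1.
#' @param jmax highest difference count to evaluate.
#' @return numeric vector F_j, j = 0..jmax.
#' @export
expected_mismatch <- function(tau, theta0, theta1, jmax) {
  j <- 0:jmax
  feq <- function(th) if (th <= 0) c(1, rep(0, jmax)) else exp(j * log(th) - (j + 1) * log1p(th))
  f1 <- feq(theta1)
  if (theta1 <= 0) return(f1)
  f0 <- feq(theta0)
  if (tau <= 0) return(f0)
  pois <- exp(j * log(tau) - lgamma(j + 1))       # tau^i / i!
  delta <- f0 - f1
  conv <- vapply(j, function(jj) sum(pois[1:(jj + 1)] * delta[(jj + 1):1]), numeric(1))
  f1 + exp(-tau * (theta1 + 1) / theta1) * conv
}

#' Harpending's raggedness index
#'
#' r = sum_{j=1}^{d+1} (x_j - x_{j-1})^2 over the observed mismatch
#' frequencies x_0..x_d, with the convention x_{d+1} = 0 (a trailing
#' zero class closes the sum).
#'
#' @param freqs normalized mismatch frequencies (x_0..x_d).
#' @return raggedness index.
#' @export
raggedness <- function(freqs) sum(diff(c(freqs, 0))^2)

# SSD between observed freqs and model, over j = 0..d_max.
mismatch_ssd <- function(freqs, tau, theta0, theta1) {
  sum((freqs - expected_mismatch(tau, theta0, theta1, length(freqs) - 1))^2)
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Minimizes the sum of squared deviations (SSD) between observed and
#' expected mismatch frequencies over (tau, theta0, theta1) by a coarse
#' grid search (tau in steps of \code{tau_step} up to 2 d_max; theta0 up
#' to the mean pairwise difference; theta1 log-spaced up to 10 d_max, a
#' proxy for an effectively infinite post-expansion size) refined by
#' Nelder-Mead. Grid ties are broken toward the smallest tau.
#'
#' @param mm a \code{mismatch_distribution}.
#' @param tau_step grid step for tau (default 0.05).
#' @return object of class \code{mismatch_fit}: tau, theta0, theta1,
#'   ssd, raggedness, plus the observed distribution.
#' @export
fit_sudden_expansion <- function(mm, tau_step = 0.05) {
  freqs <- mm$freqs
  d_max <- mm$d_max
  if (d_max < 1) stop("all sequence pairs identical; nothing to fit", call. = FALSE)
  pi_seq <- sum((0:d_max) * freqs)
  jj <- 0:d_max

  taus <- seq(0, 2 * d_max, by = tau_step)
  th0s <- unique(c(0, pi_seq * c(0.1, 0.25, 0.5, 0.75, 1)))
  th1s <- unique(pmax(exp(seq(log(max(d_max / 2, 1)), log(10 * d_max), length.out = 6)), 1e-3))

  best <- list(ssd = Inf, tau = 0, theta0 = 0, theta1 = th1s[1])
  # vectorized over the tau grid: F(tau) = f1 + e^{-c tau} T %*% M with
  # T[t, i+1] = tau_t^i/i! and M the upper-triangular Toeplitz of (f0-f1)
  lt <- outer(log(pmax(taus, 1e-300)), jj) - rep(lgamma(jj + 1), each = length(taus))
  Tm <- exp(lt); Tm[taus == 0, ] <- c(1, rep(0, d_max))
  for (th1 in th1s) {
    f1 <- expected_mismatch(0, th1, th1, d_max)
    ec <- exp(-taus * (th1 + 1) / th1)
    for (th0 in th0s[th0s <= th1]) {
      f0 <- expected_mismatch(0, th0, th0, d_max)
      delta <- f0 - f1
      M <- matrix(0, d_max + 1, d_max + 1)
      for (i in jj) M[i + 1, (i + 1):(d_max + 1)] <- delta[1:(d_max + 1 - i)]
      Fm <- ec * (Tm %*% M) + rep(f1, each = length(taus))
      ssd <- rowSums((Fm - rep(freqs, each = length(taus)))^2)
      m <- which(ssd < best$ssd - 1e-15 |
                   (abs(ssd - best$ssd) <= 1e-15 & taus < best$tau))
      if (length(m)) {
        m <- m[which.min(ssd[m])]
        best <- list(ssd = ssd[m], tau = taus[m], theta0 = th0, theta1 = th1)
      }
    }
  }
  # local refinement on a log/logit-free parameterization with box penalty
  obj <- function(p) {
    tau <- p[1]; th0 <- p[2]; th1 <- p[3]
    if (tau < 0 || th0 < 0 || th1 < th0 || th1 > 20 * d_max) return(1e6)
    mismatch_ssd(freqs, tau, th0, th1)
  }
  opt <- stats::optim(c(best$tau, best$theta0, best$theta1), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  if (opt$value < best$ssd) {
    best <- list(ssd = opt$value, tau = opt$par[1], theta0 = opt$par[2],
                 theta1 = opt$par[3])
  }
  structure(list(tau = best$tau, theta0 = best$theta0, theta1 = best$theta1,
                 ssd = best$ssd, raggedness = raggedness(freqs),
                 observed = mm),
            class = "mismatch_fit")
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat(sprintf("Sudden-expansion fit: tau = %.3f, theta0 = %.3f, theta1 = %.3f\n",
              x$tau, x$theta0, x$theta1))
  cat(sprintf("SSD = %.5f, raggedness = %.5f\n", x$ssd, x$raggedness))
  if (!is.null(x$p_ssd)) {
    cat(sprintf("P_SSD = %.3f, P_rag = %.3f (%d bootstrap replicates)\n",
                x$p_ssd, x$p_rag, length(x$null_ssd)))
  }
  invisible(x)
}

# Coalescent sample under the fitted two-epoch (sudden expansion)
# demography, finite-sites mutation at L sites. Time is scaled to the
# current (post-expansion) population: a lineage pair coalesces at rate
# 1 until tau/theta1, and at rate theta1/theta0 before that; mutations
# fall at theta1/2 per lineage per unit time, uniformly over sites, each
# changing the base to one of the other three. Returns the pairwise
# difference counts directly.
sim_expansion_mismatch <- function(n, L, tau, theta0, theta1) {
  t_exp <- if (theta1 > 0) tau / theta1 else Inf
  ratio <- if (theta0 > 1e-8) theta1 / theta0 else Inf
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes); blen <- numeric(n_nodes)
  birth <- numeric(n_nodes)
  active <- 1:n; t_now <- 0; nxt <- n
  for (k in n:2) {
    rate_mult <- if (t_now >= t_exp) ratio else 1
    if (is.finite(rate_mult)) {
      wait <- stats::rexp(1, rate = k * (k - 1) / 2 * rate_mult)
      if (t_now < t_exp && t_now + wait > t_exp) {
        # crossed the expansion boundary: redraw in the ancient epoch
        if (is.finite(ratio)) {
          wait <- (t_exp - t_now) + stats::rexp(1, rate = k * (k - 1) / 2 * ratio)
        } else wait <- t_exp - t_now
      }
      t_now <- t_now + wait
    } else {
      t_now <- max(t_now, t_exp)   # star collapse: theta0 ~ 0
    }
    pick <- sample.int(k, 2)
    a <- active[pick[1]]; b <- active[pick[2]]
    nxt <- nxt + 1L
    parent[a] <- nxt; parent[b] <- nxt
    blen[a] <- t_now - birth[a]; blen[b] <- t_now - birth[b]
    birth[nxt] <- t_now
    active <- c(active[-pick], nxt)
  }
  n_mut <- stats::rpois(1, theta1 / 2 * sum(blen))
  seqs <- matrix(rep(sample(c("A", "C", "G", "T"), L, replace = TRUE), n_nodes),
                 nrow = n_nodes, byrow = TRUE)
  if (n_mut > 0) {
    mb <- sample.int(n_nodes, n_mut, replace = TRUE, prob = blen)
    ms <- sample.int(L, n_mut, replace = TRUE)
    # apply mutations root-ward first so descendants inherit them
    ord <- order(match(mb, n_nodes:1))
    desc_cache <- NULL
    # precompute descendant tip sets per node
    desc <- vector("list", n_nodes)
    for (v in 1:n) desc[[v]] <- v
    for (v in (n + 1):n_nodes) desc[[v]] <- integer(0)
    ch <- split(seq_len(n_nodes - 1L), parent[seq_len(n_nodes - 1L)])
    collect <- function(v) {
      kids <- ch[[as.character(v)]]
      if (is.null(kids)) return(desc[[v]])
      out <- integer(0)
      for (kd in kids) out <- c(out, if (kd <= n) kd else collect(kd))
      out
    }
    for (idx in ord) {
      v <- mb[idx]; s <- ms[idx]
      tips <- if (v <= n) v else collect(v)
      cur <- seqs[tips[1], s]
      newb <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
      seqs[tips, s] <- newb
    }
  }
  tip_seqs <- seqs[1:n, , drop = FALSE]
  d <- matrix(0L, n, n)
  for (i in 1:(n - 1)) {
    block <- tip_seqs[(i + 1):n, , drop = FALSE] != rep(tip_seqs[i, ], each = n - i)
    d[i, (i + 1):n] <- as.integer(rowSums(block))
  }
  d[upper.tri(d)]
}

#' Parametric bootstrap P-values for the sudden-expansion fit
#'
#' Simulates \code{n_boot} coalescent samples of the same size and
#' length under the fitted expansion demography (finite-sites mutation,
#' matching how real data arise), refits the model to each, and reports
#' P = Pr(simulated statistic >= observed) for SSD and raggedness
#' separately -- small P rejects the sudden-expansion null, matching
#' Arlequin's direction.
#'
#' @param aln the \code{haplotype_alignment} the fit came from.
#' @param fit a \code{mismatch_fit}.
#' @param n_boot bootstrap replicates (study default 1000).
#' @param seed optional RNG seed.
#' @param tau_step grid step passed to the per-replicate refits.
#' @return the fit, augmented with p_ssd, p_rag, null_ssd, null_rag.
#' @export
bootstrap_fit_pvalues <- function(aln, fit, n_boot = 1000, seed = NULL,
                                  tau_step = 0.1) {
  n <- n_individuals(aln); L <- aln$L_effective
  sims <- with_seed(seed, {
    null_ssd <- null_rag <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      dd <- sim_expansion_mismatch(n, L, fit$tau, fit$theta0, fit$theta1)
      cnts <- tabulate(dd + 1, max(dd) + 1)
      mm_b <- structure(list(counts = c(cnts, numeric(0)),
                             freqs = cnts / length(dd),
                             total_pairs = length(dd), d_max = max(dd),
                             n = n, L = L),
                        class = "mismatch_distribution")
      null_rag[b] <- raggedness(mm_b$freqs)
      if (mm_b$d_max < 1) { null_ssd[b] <- 0; next }
      fb <- fit_sudden_expansion(mm_b, tau_step = tau_step)
      null_ssd[b] <- fb$ssd
    }
    list(ssd = null_ssd, rag = null_rag)
  })
  fit$p_ssd <- mean(sims$ssd >= fit$ssd)
  fit$p_rag <- mean(sims$rag >= fit$raggedness)
  fit$null_ssd <- sims$ssd
  fit$null_rag <- sims$rag
  fit
}

#' Convert tau to an absolute expansion time
#'
#' tau = 2 u t with u the per-sequence per-year mutation rate
#' (subs_rate * 1e-6 * L), so t = tau / (2u) years. Generation time does
#' not enter this conversion. The Mya value is rounded to 3 decimals for
#' reporting.
#'
#' @param tau mismatch expansion parameter (>= 0).
#' @param rates a [rate_params()] object (uses subs_rate and L).
#' @return list with years and mya (3-decimal).
#' @export
expansion_time <- function(tau, rates = rate_params()) {
  stopifnot(all(tau >= 0))
  u <- rates$subs_rate * 1e-6 * rates$L
  years <- tau / (2 * u)
  list(years = years, mya = round(years / 1e6, 3))
}
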