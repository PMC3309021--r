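#' Configuration for a full analysis run
#'
#' Defaults follow the study settings: substitution rate 0.036
#' subs/site/Myr, generation time 2.5 yr, and 1000
#' permutations/bootstrap replicates/simulations. A single top-level
#' seed deterministically derives one sub-seed per stage so that one
#' number reproduces the whole report bundle.
#'
#' @param subs_rate substitutions/site/Myr.
#' @param generation_time years.
#' @param n_perm AMOVA permutations.
#' @param n_boot mismatch bootstrap replicates.
#' @param n_sims neutrality-test and refugia-test simulations.
#' @param seed top-level integer seed.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(subs_rate = 0.036, generation_time = 2.5,
                       n_perm = 1000, n_boot = 1000, n_sims = 1000,
                       seed = 1L) {
  stopifnot(n_perm >= 1, n_boot >= 1, n_sims >= 1)
  structure(list(subs_rate = subs_rate, generation_time = generation_time,
                 n_perm = n_perm, n_boot = n_boot, n_sims = n_sims,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full phylogeographic analysis pipeline
#'
#' Orchestrates, on one haplotype alignment: per-group diversity
#' statistics with Ne conversion (Table-1 shape), mismatch-expansion
#' fits with bootstrap P-values, expansion times and neutrality tests
#' per group (Table-2 shape), AMOVA over candidate groupings, the
#' statistical-parsimony network, and (when demographic models and an
#' observed genealogy are supplied) the minimum-sorting-events refugia
#' test. Every stochastic stage gets its own seed derived from the
#' config seed, recorded in the manifest.
#'
#' @param aln a \code{haplotype_alignment}.
#' @param config a [run_config()].
#' @param groupings named list of candidate groupings for AMOVA
#'   (default: the sample table's groups).
#' @param genealogy optional observed genealogy (\code{genealogy} or
#'   \code{phylo}) for the refugia test.
#' @param models optional named list of [demographic_model()]s to test.
#' @param tree_labels tip -> population mapping when \code{genealogy}
#'   is a phylo object.
#' @param out_dir if non-NULL, writes TSV tables and a JSON manifest.
#' @return list of class \code{pipeline_result} with elements
#'   \code{diversity}, \code{demography}, \code{amova}, \code{network},
#'   \code{refugia}, \code{manifest}.
#' @export
run_pipeline <- function(aln, config = run_config(), groupings = NULL,
                         genealogy = NULL, models = NULL,
                         tree_labels = NULL, out_dir = NULL) {
  stages <- c("neutrality", "mismatch", "amova", "refugia")
  seeds <- derive_seeds(config$seed, stages)
  rates <- rate_params(config$subs_rate, config$generation_time,
                       aln$L_effective)
  groups <- unique(aln$samples$group)

  sub_aln <- function(g) {
    keep <- aln$samples$group == g
    ex <- expand_alignment(aln)
    haplotype_alignment(ex$seqs[keep, , drop = FALSE], ex$samples[keep, ])
  }
  alns <- c(stats::setNames(lapply(groups, sub_aln), groups), list(Total = aln))

  # Table-1 shape: diversity + Ne per group
  diversity <- do.call(rbind, Map(function(a, g) {
    st <- diversity_stats(a)
    data.frame(group = g, n = st$n, haplotypes = st$k, S = st$S,
               h = st$h, pi = st$pi, theta_w = st$theta_w,
               ne = ne_from_theta(st$theta_w, rates))
  }, alns, names(alns)))

  # Table-2 shape: mismatch fit + expansion time + neutrality per group
  demography <- do.call(rbind, Map(function(a, g) {
    if (n_individuals(a) < 4 || segregating_sites(a) < 1) {
      return(data.frame(group = g, tau = NA, ssd = NA, p_ssd = NA,
                        raggedness = NA, p_rag = NA, expansion_mya = NA,
                        fu_fs = NA, p_fs = NA, tajima_d = NA, p_d = NA))
    }
    mm <- mismatch_distribution(a)
    fit <- fit_sudden_expansion(mm)
    fit <- bootstrap_fit_pvalues(a, fit, n_boot = config$n_boot,
                                 seed = seeds[["mismatch"]])
    fs <- fu_fs(a, n_sims = config$n_sims, seed = seeds[["neutrality"]])
    td <- tajimas_d(a, n_sims = config$n_sims, seed = seeds[["neutrality"]])
    data.frame(group = g, tau = fit$tau, ssd = fit$ssd, p_ssd = fit$p_ssd,
               raggedness = fit$raggedness, p_rag = fit$p_rag,
               expansion_mya = expansion_time(fit$tau, rates)$mya,
               fu_fs = fs$statistic, p_fs = fs$p_low,
               tajima_d = td$statistic, p_d = td$p_low)
  }, alns, names(alns)))

  amova_tab <- NULL
  if (length(groups) >= 2 && ncol(aln$counts) >= 2) {
    if (is.null(groupings)) {
      pg <- unique(aln$samples[, c("population", "group")])
      groupings <- list(lineages = stats::setNames(pg$group, pg$population))
    }
    amova_tab <- if (length(groupings) >= 2) {
      compare_groupings(aln, groupings, n_perm = config$n_perm,
                        seed = seeds[["amova"]])
    } else {
      r <- amova(aln, groupings[[1]], n_perm = config$n_perm,
                 seed = seeds[["amova"]], label = names(groupings)[1])
      data.frame(grouping = r$grouping_label,
                 n_groups = length(unique(r$grouping)),
                 phi_ct = r$phi_ct, phi_sc = r$phi_sc, phi_st = r$phi_st,
                 pct_among_groups = r$pct_variation[1], p_ct = r$p_ct,
                 best = TRUE)
    }
  }

  net <- build_network(aln)

  refugia <- NULL
  if (!is.null(genealogy) && !is.null(models)) {
    refugia <- refugia_test(genealogy, models, labels = tree_labels,
                            n_sims = config$n_sims, seed = seeds[["refugia"]])
  }

  manifest <- list(package = "phylodemog",
                   version = as.character(utils::packageVersion("phylodemog")),
                   seed = config$seed, stage_seeds = as.list(seeds),
                   config = unclass(config),
                   n_individuals = n_individuals(aln),
                   n_haplotypes = length(aln$haplotype_id),
                   L = aln$L_effective,
                   connection_limit = net$connection_limit)

  out <- structure(list(diversity = diversity, demography = demography,
                        amova = amova_tab, network = net, refugia = refugia,
                        manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, f) utils::write.table(df, file.path(out_dir, f),
                                            sep = "\t", quote = FALSE,
                                            row.names = FALSE)
    w(diversity, "diversity.tsv")
    w(demography, "demography.tsv")
    if (!is.null(amova_tab)) w(as.data.frame(amova_tab), "amova.tsv")
    write_network(net, file.path(out_dir, "network"), aln)
    if (!is.null(refugia)) {
      w(do.call(rbind, lapply(refugia, function(r) {
        data.frame(model = r$model_label, observed_s = r$observed_s,
                   ci_low = r$ci95[1], ci_high = r$ci95[2],
                   decision = r$decision)
      })), "refugia.tsv")
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result:", x$manifest$n_individuals, "individuals,",
      x$manifest$n_haplotypes, "haplotypes, seed", x$manifest$seed, "\n")
  cat("Stages: diversity,", "demography,",
      if (!is.null(x$amova)) "amova,", "network",
      if (!is.null(x$refugia)) ", refugia", "\n")
  invisible(x)
}
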