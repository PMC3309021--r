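# Fixed study-shaped sampling design: 262 individuals, 22 populations,
# 5 regional groups. Table of population, group and sample size; the
# allocation is deterministic (the real per-site sample sizes are not
# part of the public record, so a fixed plausible allocation is used).
study_design <- function() {
  data.frame(
    population = c("A1p", "A2p1", "A2p2", "A2p3",
                   "Bp",
                   "Cp1", "Cp2", "Cp3",
                   "Dp1", "Dp2",
                   paste0("Ep", 1:12)),
    group = c(rep("A", 4), "B", rep("C", 3), rep("D", 2), rep("E", 12)),
    n = c(20, 10, 10, 10,
          12,
          15, 20, 15,
          20, 10,
          rep(10, 12)),
    stringsAsFactors = FALSE
  )
}

#' Scenario presets for study-shaped synthetic data
#'
#' Named presets bundling a demographic model, a mutation model, sample
#' sizes and sequence length, so every pipeline stage can be exercised
#' on data with known ground truth:
#' \describe{
#'   \item{study_shape / multiple_refugia}{5 regional lineages (A..E),
#'     22 populations, 262 individuals, L = 1248 sites. Lineage splits
#'     at 2.44, 2.01, 0.64 and 0.36 Mya (the empirical divergence
#'     order); populations within a lineage split 100 kyr ago. Lineage
#'     Ne for C, D, E from the empirical theta estimates; A and B set
#'     to 30000 and 8000.}
#'   \item{single_refugium}{only C, D, E, all derived from one
#'     ancestral population 18 kyr ago (the competing LGM scenario).}
#'   \item{expansion}{a single population grown 100-fold at 50 kyr BP
#'     (sudden-expansion signature: unimodal mismatch, negative Fs).}
#'   \item{constant}{a single stationary population (neutral null).}
#' }
#'
#' @param name preset name.
#' @param L sites (default 1248).
#' @param rates a [rate_params()] object; the per-generation mutation
#'   rate is subs_rate * 1e-6 * generation_time.
#' @param kappa,gamma_shape HKY+Gamma mutation parameters.
#' @return object of class \code{scenario_preset}.
#' @export
scenario_preset <- function(name = c("study_shape", "multiple_refugia",
                                     "single_refugium", "expansion", "constant"),
                            L = 1248, rates = rate_params(),
                            kappa = 4, gamma_shape = 0.5) {
  name <- match.arg(name)
  mu_gen <- rates$subs_rate * 1e-6 * rates$generation_time
  mut <- mutation_model(rate = mu_gen, kappa = kappa, gamma_shape = gamma_shape)
  gt <- rates$generation_time

  if (name %in% c("study_shape", "multiple_refugia")) {
    des <- study_design()
    grp_ne <- c(A = 30000, B = 8000,
                C = ne_from_theta(0.00582, rates),
                D = ne_from_theta(0.00268, rates),
                E = ne_from_theta(0.00503, rates))
    pop_split <- 100000
    br <- data.frame(id = character(0), parent = character(0), ne = numeric(0))
    add <- function(id, parent, ne) br <<- rbind(br, data.frame(id = id, parent = parent, ne = ne))
    # lineage backbone: (A, (B, (C, (D, E)))) with the empirical split order
    add("ROOT", NA, sum(grp_ne))
    add("Ag", "ROOT", grp_ne[["A"]]); add("BCDE", "ROOT", sum(grp_ne[-1]))
    add("Bg", "BCDE", grp_ne[["B"]]); add("CDE", "BCDE", sum(grp_ne[3:5]))
    add("Cg", "CDE", grp_ne[["C"]]); add("DEg", "CDE", grp_ne[["D"]] + grp_ne[["E"]])
    add("Dg", "DEg", grp_ne[["D"]]); add("Eg", "DEg", grp_ne[["E"]])
    splits <- c(ROOT = 2440000, BCDE = 2010000, CDE = 640000, DEg = 360000)
    # populations hang off their lineage branch via a star split
    for (g in unique(des$group)) {
      pops <- des$population[des$group == g]
      lin <- paste0(g, "g")
      if (length(pops) == 1) {
        # rename: single population is the lineage branch itself
        br$id[br$id == lin] <- pops
        br$parent[br$parent == lin] <- pops
      } else {
        for (p in pops) add(p, lin, grp_ne[[g]] / length(pops))
        splits[lin] <- pop_split
      }
    }
    samples <- stats::setNames(des$n, des$population)
    model <- demographic_model(br, splits, gt, samples, label = name)
    truth_groups <- stats::setNames(des$group, des$population)
  } else if (name == "single_refugium") {
    models <- paper_models(rates = rates)
    model <- models$single_refugium
    truth_groups <- c(C = "C", D = "D", E = "E")
  } else if (name == "expansion") {
    br <- data.frame(id = "P1", parent = NA, ne = 100000)
    model <- demographic_model(br, split_times = numeric(0), gt,
                               sample_sizes = c(P1 = 50),
                               epochs = list(P1 = data.frame(from_yr = 50000, ne = 1000)),
                               label = "expansion")
    truth_groups <- c(P1 = "P1")
  } else {
    br <- data.frame(id = "P1", parent = NA, ne = 20000)
    model <- demographic_model(br, split_times = numeric(0), gt,
                               sample_sizes = c(P1 = 50), label = "constant")
    truth_groups <- c(P1 = "P1")
  }
  structure(list(name = name, model = model, mutation = mut, L = as.integer(L),
                 rates = rates, groups = truth_groups),
            class = "scenario_preset")
}

#' Generate a study-shaped synthetic dataset
#'
#' Simulates a genealogy under the preset's demographic model, overlays
#' HKY+Gamma mutations, and returns the alignment together with a
#' ground-truth record (the genealogy, the true model label, distinct
#' sequence count, per-group TMRCAs). Identical seeds give identical
#' output.
#'
#' @param preset a [scenario_preset()] (or preset name).
#' @param seed RNG seed (required for reproducibility).
#' @param out_dir if non-NULL, writes FASTA, sample TSV, genealogy
#'   newick and truth TSV there.
#' @return list: \code{aln} (a \code{haplotype_alignment}),
#'   \code{genealogy}, \code{truth} (data.frame).
#' @export
generate_dataset <- function(preset, seed, out_dir = NULL) {
  if (is.character(preset)) preset <- scenario_preset(preset)
  seeds <- derive_seeds(seed, c("genealogy", "mutations"))
  gen <- simulate_genealogy(preset$model, seed = seeds[["genealogy"]])
  aln <- overlay_mutations(gen, preset$mutation, preset$L,
                           seed = seeds[["mutations"]])
  # attach the true group labels
  aln$samples$group <- unname(preset$groups[aln$samples$population])
  tip_group <- preset$groups[gen$tip_pop]
  grp_tmrca <- vapply(unique(tip_group), function(g) {
    tips <- which(tip_group == g)
    if (length(tips) == 1) return(0)
    subtree_tmrca(gen, tips)
  }, numeric(1))
  truth <- data.frame(
    field = c("scenario", "seed", "n_individuals", "n_haplotypes",
              "L", "tmrca_generations",
              paste0("tmrca_", names(grp_tmrca))),
    value = c(preset$name, seed, n_individuals(aln), length(aln$haplotype_id),
              preset$L, format(tmrca(gen), digits = 10),
              format(grp_tmrca, digits = 10)),
    stringsAsFactors = FALSE
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ex <- expand_alignment(aln)
    write_fasta(ex$seqs, file.path(out_dir, "alignment.fasta"))
    utils::write.table(ex$samples[, c("individual", "population", "group")],
                       file.path(out_dir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ape::write.tree(as.phylo(gen), file.path(out_dir, "genealogy.nwk"))
    truth_report(truth, file.path(out_dir, "truth.tsv"))
  }
  list(aln = aln, genealogy = gen, truth = truth)
}

# TMRCA (generations) of a tip subset: oldest node on paths joining them.
subtree_tmrca <- function(gen, tips) {
  n <- gen$n_tips
  parent <- integer(2L * n - 1L)
  for (v in (n + 1):(2L * n - 1L)) parent[gen$children[v, ]] <- v
  # mark ancestors of the first tip, then walk up from the others
  anc_sets <- lapply(tips, function(tp) {
    path <- tp
    while (parent[tp] != 0) { tp <- parent[tp]; path <- c(path, tp) }
    path
  })
  common <- Reduce(intersect, anc_sets)   # shared internal ancestors; root always present
  min(gen$node_time[common])
}

#' Write / read a ground-truth record
#' @param truth truth data.frame from [generate_dataset()].
#' @param path TSV path.
#' @return invisibly \code{path} (write); data.frame (read).
#' @export
truth_report <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname truth_report
#' @export
read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}
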