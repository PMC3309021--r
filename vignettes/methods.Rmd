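---
title: "Models and methods in phylodemog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in phylodemog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

phylodemog implements the analysis chain of a range-wide mtDNA
phylogeography study: diversity and effective size, neutrality tests,
mismatch-distribution expansion inference, hierarchical AMOVA,
statistical-parsimony networks, and a structured-coalescent test of
competing refugia scenarios. This vignette records the models, the
conventions, and the design decisions a user or reviewer needs to
interpret the output.

## Data model and conventions

The basic container is the haplotype alignment: equal-length DNA
sequences collapsed to distinct haplotypes, each carrying
per-population copy numbers, plus the population-to-regional-group
table. Two conventions apply throughout:

* **Complete deletion.** Any column containing an `N` or a gap in any
  sequence is dropped before anything is counted. This gives one
  unambiguous effective length L for all per-site scaling (the target
  data class — protein-coding mtDNA without indels — loses essentially
  nothing, and it avoids pairwise-deletion inconsistencies between
  statistics).
* **Haploid N_e.** Mitochondrial inheritance means every conversion
  uses θ = 2N_e·μ, not 4N_e·μ. The coalescent engine is scaled the same
  way (a lineage pair coalesces at rate 1/N_e per generation), so sizes
  estimated by `ne_from_theta()` plug directly into simulations.
  Diploid-autosomal users must halve/double accordingly.

Haplotypes are labelled H1..Hk in order of first appearance, so ids are
stable across reruns of the same input.

## Diversity and neutrality tests

`diversity_stats()` computes h, π (per site, count-weighted over all
sequence pairs) and Watterson's θ_W = S/(a_n·L). `ne_from_theta()`
converts with μ = rate·10⁻⁶·generation-time per site per generation and
rounds half-up for reporting (75611.1 prints as 75611). Defaults
(0.036 substitutions/site/Myr; 2.5-year generations) are the clock of
the motivating study and should be replaced for other taxa.

Tajima's D uses the 1989 constants with π in per-sequence units. Fu's
F_S = ln(S'/(1−S')) with S' = P(K ≥ k_obs | θ_π, n) from the Ewens
sampling formula; θ_π (mean pairwise differences per sequence) is the
plug-in, following Fu (1997) and Arlequin practice. The Ewens
probabilities are computed by the Chinese-restaurant recurrence
P_{n+1}(k) = n/(θ+n)·P_n(k) + θ/(θ+n)·P_n(k−1), which is exactly the
Stirling-number form but stable at any n. Both tests draw their
P-values from constant-size neutral coalescent replicates conditioned
on n and the observed θ̂ (θ_W for D, θ_π for F_S); the reported P is the
lower tail Pr(sim ≤ obs). Null replicates that happen to carry no
segregating site contribute D = 0 and are skipped for F_S (they carry
no information about either statistic). Two significance conventions
circulate for F_S — Arlequin's P < 0.02 and the more common P < 0.05 —
so `fu_fs()` reports both verdicts and leaves the choice to the user.

## Mismatch distributions and sudden expansion

The observed mismatch distribution is the histogram of pairwise
differences over all C(n,2) pairs (haplotypes expanded by their
counts). The sudden-expansion model is the Rogers–Harpending
infinite-sites solution

F_j(τ, θ₀, θ₁) = F̂_j(θ₁) + e^{−τ(θ₁+1)/θ₁} Σ_{i≤j} (τ^i/i!)·(F̂_{j−i}(θ₀) − F̂_{j−i}(θ₁)),

with equilibrium F̂_j(θ) = θ^j/(1+θ)^{j+1}. Fitting minimizes the SSD
over observed difference classes 0..d_max by a vectorized grid search —
τ in steps of 0.05 up to 2·d_max, θ₀ up to the observed mean pairwise
difference, θ₁ log-spaced up to 10·d_max (a finite proxy for Arlequin's
effectively infinite post-expansion size; an unbounded θ₁ is not
identifiable) — refined by Nelder–Mead, with grid ties broken toward
the smallest τ. Harpending's raggedness is summed with a trailing zero
class, r = Σ_{j=1}^{d+1}(x_j − x_{j−1})², x_{d+1} = 0.

Goodness-of-fit P-values are parametric bootstrap: samples of the same
n and L are simulated under the *fitted* two-epoch coalescent with
finite-sites mutation (matching how real data arise, even though the
fitted curve is infinite-sites), each is refitted, and
P = Pr(sim ≥ obs) — small P rejects sudden expansion, Arlequin's
direction. Expansion time uses τ = 2ut with u per sequence per *year*
(rate·10⁻⁶·L), so generation time does not enter; this is the
convention that converts τ = 4.738 at L = 1248 into 0.053 Myr.

A caveat the tests exercise deliberately: for strongly bimodal
mixtures of divergent lineages the SSD surface often prefers τ = 0
(a stationary curve). The SSD bootstrap still rejects, but the
raggedness bootstrap then compares against stationary simulations,
which are themselves ragged, and loses power. Rejection of expansion
for admixed data should therefore be read from P_SSD.

## AMOVA

Three-level AMOVA follows the Excoffier–Quattro–Smouse decomposition
on pairwise difference counts used as squared distances (Arlequin's
default for haplotypic data; no substitution-model correction).
Negative variance components are reported as-is with a flag so the
percentages stay additive. Permutation schemes: Φ_CT permutes whole
populations among groups; Φ_SC permutes individuals among populations
within their group; Φ_ST permutes individuals among populations.
P = (count{perm ≥ obs}+1)/(n_perm+1), so P is never exactly zero. Note
that Φ_CT resolution is limited by the number of distinct population
partitions: with few populations the smallest achievable P is large no
matter how many permutations are drawn. `compare_groupings()` ranks
candidate groupings by Φ_CT and flags the arg-max, the
"optimal geographical subdivision" criterion.

## Statistical-parsimony networks

The connection limit is the largest step count j whose probability of
parsimony is at least 0.95. That probability is computed from a
coalescent model of a sequence pair: the total number of substitutions
H separating the pair is geometric (the coalescent-pair distribution)
with mean set to the observed difference count j; substitutions land
uniformly on the L sites; a site hit k times shows a difference with
probability 3/4·(1 − (−1/3)^k) (four-state symmetric change); and a
multiply-hit site defeats parsimony with weight w. The reported
P_j = P(no defeated site | j observed differences) is evaluated by
exact truncated power series, not simulation. The single weight
w = 1/2 sits between the two analytic extremes (counting every
multiple hit as fatal gives a limit of 11 at L = 1248; counting only
hidden back-mutations gives 19) and is pinned so the procedure
reproduces the reference TCS program's published limit of 15 steps at
1248 sites; the regression tests freeze 8 steps at L = 400 and 11 at
L = 658 from the same calculation.

Network assembly is agglomerative in increasing distance, connecting
components only, with ties at a distance level processed
higher-frequency-haplotypes-first (an approximation to TCS's
ancestral-weighting heuristic, pinned by tests). Multi-step
connections insert synthetic intermediate nodes m1, m2, … (insertion
order). A pair whose components were distinct at the start of its
distance level but merged within it is an alternative connection and
is recorded as a loop rather than discarded — the absence of loops in
a real dataset is itself a reportable result. Modal (putative
ancestral) haplotypes per component are chosen by highest frequency,
then most connections, then lexical id.

## Structured coalescent and mutation overlay

`simulate_genealogy()` runs the standard n-coalescent inside each
branch of a population tree: within a branch of size N_e, k lineages
coalesce at rate k(k−1)/(2N_e) per generation, with exponential
waiting times (no discrete-generation approximation); at each split
time (years, converted by the generation time) daughter lineages merge
into the parent branch; the root branch extends until the final
coalescence. Branches may carry size epochs (step changes backwards in
time), which is how the sudden-expansion preset is expressed.
Ancestral branch sizes in the refugia models default to the sum of
their daughters, conserving the total empirical size — the paper trail
for those models fixes the leaf sizes and the total but is silent on
ancestral partitioning.

`overlay_mutations()` draws the root from the stationary base
frequencies, per-site Gamma(α, α) rate multipliers once, and evolves
each branch by exact HKY transition probabilities (closed-form via the
symmetrized eigendecomposition) — no per-branch event simulation, so
long branches cost the same as short ones. Defaults κ = 4, α = 0.5,
uniform frequencies are unexceptional mtDNA values; none of the
fixed-value results depend on them. The engine's calibration is
test-pinned: pair TMRCA = N_e generations analytically, and
simulate-plus-mutate closes the loop with θ = 2N_eμ within sampling
error.

## Refugia test

The Slatkin–Maddison statistic S is the Fitch small-parsimony count of
the population character on the rooted binary genealogy (an exact
Sankoff dynamic programme is kept in the tests as the oracle).
Polytomous trees are refused rather than resolved silently. The null
distribution simulates genealogies under each demographic model; the
95% interval is the empirical 2.5/97.5 percentile pair
(linear-interpolation quantiles, R type 7), and a model is rejected
when the observed S falls outside, either tail. Whether the historical
Mesquite workflow counted Fitch changes or deep coalescences is not
documented in the sources this package follows; Fitch counting is
implemented, as in the original S definition, and for the fixed
species-tree association used here the two orderings agree in the
deep-split regime the test discriminates.

## Synthetic data: what it does and does not establish

`scenario_preset("study_shape")` reproduces the study's design
constants exactly — 262 individuals, 22 populations, 5 regional
lineages, 1248 sites — with the empirical lineage sizes for C/D/E,
lineage splits in the empirical order (2.44/2.01/0.64/0.36 Mya), a
fixed within-lineage population split at 100 kyr, and a fixed
deterministic allocation of individuals to populations (the real
per-site sample sizes are not in the public record). Generated data
reproduce the qualitative empirical fingerprints: haplotypes are
private to their regional lineage, the five-lineage grouping maximizes
Φ_CT, and networks never join lineages. They are *not* a surrogate for
the real sequences: haplotype counts and within-lineage depths drift
with the seed (60–80 distinct haplotypes rather than exactly 63), and
within-lineage diversity can exceed the 15-step limit so a lineage may
split into several subnetworks, which the real data did not. Tests
that pass on synthetic data validate the machinery and its
calibration, not the biological conclusions.

## Problem sizes and numerical choices in the test-suite

The suite favours exactness where exactness is available (hand-counted
fixtures; Sankoff, brute-SSD, and permutation-cycle oracles; frozen
regression values) and keeps stochastic checks at sizes that make them
sharp but quick: 2000 replicates for the pair-TMRCA calibration (±5%),
1000 neutral replicates for the mean-D check (±0.15), 20 replicates
for τ recovery (±30% on the median), 100 datasets × 200 permutations
for the Φ_CT type-I rate, and 50 end-to-end refugia replicates at 200
null simulations each (≥80% correct model choice). Seeds are fixed in
every stochastic test, so the suite is deterministic.

## Known limitations

* No migration, recombination or serial sampling in the coalescent
  engine; population trees only.
* Ambiguity codes other than N are rejected rather than resolved.
* The mismatch machinery covers the demographic (sudden) expansion
  model, not the spatial-expansion variant.
* Standard errors for h and π are not reported.
* The parsimony-probability weight is a calibrated model constant (see
  above), not a first-principles derivation of the historical TCS
  code, which is no longer readily available.
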