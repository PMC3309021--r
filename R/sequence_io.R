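#' Read a sample table
#'
#' The sample table maps each sequenced individual to a population and,
#' optionally, a regional group (mtDNA lineage). Tab-separated with a
#' header line \code{individual<TAB>population<TAB>group}; the
#' \code{group} column may be omitted, in which case each population is
#' treated as its own group.
#'
#' @param path path to a TSV file.
#' @return data.frame with columns \code{individual}, \code{population},
#'   \code{group}.
#' @export
read_sample_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character")
  validate_sample_table(tab)
}

validate_sample_table <- function(tab) {
  if (!all(c("individual", "population") %in% names(tab))) {
    stop("sample table needs 'individual' and 'population' columns", call. = FALSE)
  }
  if (is.null(tab$group)) tab$group <- tab$population
  if (anyDuplicated(tab$individual)) {
    stop("duplicated individual ids in sample table", call. = FALSE)
  }
  pg <- unique(tab[, c("population", "group")])
  if (anyDuplicated(pg$population)) {
    stop("a population maps to more than one group", call. = FALSE)
  }
  tab[, c("individual", "population", "group")]
}

#' Build a haplotype alignment from sequences and sample metadata
#'
#' Collapses individual sequences into distinct haplotypes. Columns
#' containing an N or a gap in any sequence are excluded from all
#' downstream site counts (complete deletion); individuals identical at
#' the retained sites collapse to one haplotype with summed
#' per-population counts. Haplotypes are labelled H1..Hk in order of
#' first appearance.
#'
#' @param seqs character matrix, rows = individuals (rownames = ids),
#'   columns = aligned sites, entries in \code{A,C,G,T,N,-} (case
#'   insensitive).
#' @param samples sample table (data.frame as from
#'   [read_sample_table()]); every rowname of \code{seqs} must appear in
#'   \code{samples$individual}.
#' @return object of class \code{haplotype_alignment}: a list with
#'   \item{haplotype_id}{H1..Hk}
#'   \item{seqs}{k x L_effective character matrix of haplotype sequences}
#'   \item{counts}{k x n_population integer matrix of per-population copies}
#'   \item{samples}{the sample table, with a \code{haplotype} column added}
#'   \item{L_original, L_effective}{site counts before/after complete deletion}
#' @export
haplotype_alignment <- function(seqs, samples) {
  samples <- validate_sample_table(samples)
  if (is.null(rownames(seqs))) stop("sequence matrix must have rownames", call. = FALSE)
  missing_ids <- setdiff(rownames(seqs), samples$individual)
  if (length(missing_ids)) {
    stop("sequence ids missing from sample table: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  seqs[] <- toupper(seqs)
  bad <- !(seqs %in% c("A", "C", "G", "T", "N", "-"))
  if (any(bad)) stop("unexpected characters in alignment", call. = FALSE)
  L_original <- ncol(seqs)
  keep <- colSums(seqs == "N" | seqs == "-") == 0
  seqs <- seqs[, keep, drop = FALSE]

  key <- apply(seqs, 1, paste, collapse = "")
  first <- !duplicated(key)
  hap_of <- match(key, key[first])
  k <- sum(first)
  hap_ids <- paste0("H", seq_len(k))

  samples <- samples[match(rownames(seqs), samples$individual), ]
  samples$haplotype <- hap_ids[hap_of]
  pops <- unique(samples$population)
  counts <- table(factor(hap_of, levels = seq_len(k)),
                  factor(samples$population, levels = pops))
  counts <- matrix(as.integer(counts), nrow = k,
                   dimnames = list(hap_ids, pops))

  structure(list(
    haplotype_id = hap_ids,
    seqs = structure(seqs[first, , drop = FALSE], dimnames = list(hap_ids, NULL)),
    counts = counts,
    samples = samples,
    L_original = L_original,
    L_effective = ncol(seqs)
  ), class = "haplotype_alignment")
}

#' Read an aligned FASTA plus sample table into a haplotype alignment
#'
#' @param fasta_path pre-aligned FASTA of individual sequences.
#' @param sample_table_path TSV sample table (see [read_sample_table()]).
#' @return a \code{haplotype_alignment}; see [haplotype_alignment()].
#' @export
read_alignment <- function(fasta_path, sample_table_path) {
  dna <- ape::read.FASTA(fasta_path)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1) {
    stop("sequences are not aligned (unequal lengths)", call. = FALSE)
  }
  seqs <- toupper(do.call(rbind, as.character(dna)))
  rownames(seqs) <- names(dna)
  haplotype_alignment(seqs, read_sample_table(sample_table_path))
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat("Haplotype alignment:", n_individuals(x), "individuals,",
      length(x$haplotype_id), "haplotypes,", ncol(x$counts), "populations\n")
  cat("Sites:", x$L_effective, "retained of", x$L_original,
      "| segregating:", segregating_sites(x), "\n")
  invisible(x)
}

#' Number of individuals in an alignment
#' @param aln a \code{haplotype_alignment}.
#' @return integer.
#' @export
n_individuals <- function(aln) sum(aln$counts)

#' Haplotype copy numbers (over all populations)
#' @param aln a \code{haplotype_alignment}.
#' @return named integer vector.
#' @export
haplotype_counts <- function(aln) rowSums(aln$counts)

#' Number of segregating (polymorphic) sites
#'
#' Counts retained columns with two or more observed states among the
#' distinct haplotypes; haplotype frequencies do not enter.
#'
#' @param aln a \code{haplotype_alignment}.
#' @return integer.
#' @export
segregating_sites <- function(aln) {
  if (length(aln$haplotype_id) < 2) return(0L)
  ref <- aln$seqs[1, ]
  sum(colSums(aln$seqs != rep(ref, each = nrow(aln$seqs))) > 0)
}

#' Pairwise difference matrix between haplotypes
#'
#' Raw number of differing retained sites for every haplotype pair
#' (Arlequin's "pairwise difference" distance).
#'
#' @param aln a \code{haplotype_alignment}.
#' @return k x k symmetric integer matrix.
#' @export
hap_distances <- function(aln) {
  k <- nrow(aln$seqs)
  d <- matrix(0L, k, k, dimnames = list(aln$haplotype_id, aln$haplotype_id))
  if (k < 2) return(d)
  for (i in seq_len(k - 1)) {
    block <- aln$seqs[(i + 1):k, , drop = FALSE] != rep(aln$seqs[i, ], each = k - i)
    d[i, (i + 1):k] <- d[(i + 1):k, i] <- as.integer(rowSums(block))
  }
  d
}

#' Expand a haplotype alignment back to one row per individual
#'
#' Inverse of the collapse step: repeats each haplotype sequence by its
#' per-population count. Downstream statistics are invariant to
#' collapsing, which the tests exercise through this function.
#'
#' @param aln a \code{haplotype_alignment}.
#' @return list with \code{seqs} (matrix, one row per individual) and
#'   \code{samples} (the sample table).
#' @export
expand_alignment <- function(aln) {
  idx <- match(aln$samples$haplotype, aln$haplotype_id)
  seqs <- aln$seqs[idx, , drop = FALSE]
  rownames(seqs) <- aln$samples$individual
  list(seqs = seqs, samples = aln$samples)
}

#' Write the haplotype table (haplotype, sequence, per-population counts)
#' @param aln a \code{haplotype_alignment}.
#' @param path output TSV path.
#' @return invisibly, the data.frame written.
#' @export
write_haplotype_table <- function(aln, path) {
  df <- data.frame(haplotype = aln$haplotype_id,
                   sequence = apply(aln$seqs, 1, paste, collapse = ""),
                   as.data.frame(aln$counts, optional = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write sequences to FASTA
#' @param seqs character matrix of sequences (rownames = ids).
#' @param path output path.
#' @return invisibly \code{path}.
#' @export
write_fasta <- function(seqs, path) {
  lines <- character(2L * nrow(seqs))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(seqs))
  lines[c(FALSE, TRUE)] <- apply(seqs, 1, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}
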