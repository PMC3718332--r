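# Core-genome divergence and molecular-clock dating.
#
# Single-copy ubiquitous ortholog families supply a concatenated
# nucleotide alignment; pairwise divergence (raw or Jukes-Cantor corrected)
# feeds a neighbour-joining tree with column-bootstrap supports, and split
# times follow t = d / (2 mu) with the hyperthermophile clock rate
# mu = 4.66e-9 substitutions per site per year (divergence accrues on both
# lineages).

#' Hyperthermophile molecular clock rate (substitutions/site/year)
#' @export
HYPERTHERMOPHILE_CLOCK_RATE <- 4.66e-9

#' Concatenated single-copy core-gene alignment
#'
#' Takes every ubiquitous family with exactly one member per genome,
#' aligns the members (equal-length members are stacked; members within
#' 20% length discordance are globally aligned to the longest one;
#' families above that are dropped with a message) and concatenates the
#' blocks.
#'
#' @param families Output of [build_ortholog_families()].
#' @param gene_sequences Named list (genome id -> named character vector of
#'   CDS nucleotide sequences, names matching family member protein ids).
#' @param max_length_discordance Drop threshold (default 0.2).
#' @return List of class `CoreAlignment`: `genomes`, `sequences` (named,
#'   equal length), `blocks` (family_id, start, end).
#' @export
core_gene_alignment <- function(families, gene_sequences,
                                max_length_discordance = 0.2) {
  genomes <- names(gene_sequences)
  if (length(genomes) < 2) stop("need >= 2 genomes")
  single <- families[families$category == "ubiquitous" &
                       families$n_members == length(genomes), , drop = FALSE]
  if (nrow(single) == 0) stop("no usable single-copy ubiquitous family")
  aligned <- stats::setNames(rep(list(character()), length(genomes)), genomes)
  blocks <- list()
  at <- 0L
  for (i in seq_len(nrow(single))) {
    mem <- single$members[[i]]
    seqs <- vapply(genomes, function(g) {
      pid <- mem$protein[mem$genome == g]
      gene_sequences[[g]][[pid]]
    }, "")
    lens <- nchar(seqs)
    if ((max(lens) - min(lens)) / max(lens) > max_length_discordance) {
      message("dropping length-discordant family ", single$family_id[i])
      next
    }
    if (length(unique(lens)) > 1) {
      ref <- seqs[which.max(lens)]
      seqs <- vapply(seqs, function(s) {
        if (nchar(s) == nchar(ref)) return(s)
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(s), Biostrings::DNAString(ref),
          type = "global")
        as.character(Biostrings::alignedPattern(aln))
      }, "")
      w <- max(nchar(seqs))
      seqs <- vapply(seqs, function(s)
        if (nchar(s) < w) paste0(s, strrep("-", w - nchar(s))) else s, "")
    }
    for (g in genomes) aligned[[g]] <- c(aligned[[g]], seqs[[g]])
    blocks[[length(blocks) + 1L]] <- data.frame(
      family_id = single$family_id[i], start = at + 1L,
      end = at + nchar(seqs[[1]]), stringsAsFactors = FALSE)
    at <- at + nchar(seqs[[1]])
  }
  if (length(blocks) == 0) stop("no usable single-copy ubiquitous family")
  sequences <- vapply(aligned, paste, "", collapse = "")
  structure(list(genomes = genomes, sequences = sequences,
                 blocks = do.call(rbind, blocks)),
            class = "CoreAlignment")
}

#' Pairwise divergence from a core alignment
#'
#' @param alignment A `CoreAlignment` (or named character vector of
#'   equal-length aligned sequences).
#' @param correction `"raw"` (mismatches / compared columns, gap columns
#'   excluded pairwise) or `"jukes_cantor"` (`-3/4 log(1 - 4p/3)`,
#'   undefined and reported `NA` when `p >= 0.75`).
#' @return Symmetric numeric distance matrix.
#' @export
pairwise_divergence <- function(alignment,
                                correction = c("raw", "jukes_cantor")) {
  correction <- match.arg(correction)
  seqs <- if (inherits(alignment, "CoreAlignment")) alignment$sequences
          else alignment
  if (length(seqs) < 2) stop("alignment must hold >= 2 sequences")
  if (length(unique(nchar(seqs))) != 1) stop("unequal aligned lengths")
  mats <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  ids <- names(seqs)
  d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    a <- mats[[i]]; b <- mats[[j]]
    ok <- a != "-" & b != "-" & a != "N" & b != "N"
    p <- sum(a[ok] != b[ok]) / sum(ok)
    val <- if (correction == "raw") p else {
      if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
    }
    d[i, j] <- d[j, i] <- val
  }
  d
}

#' Neighbour-joining tree with column-bootstrap support
#'
#' Standard NJ ([ape::nj()]); when an alignment is supplied, bootstrap
#' replicates resample alignment columns, and supports are the fraction of
#' replicates recovering each internal bipartition.
#'
#' @param distances Symmetric distance matrix.
#' @param alignment Optional `CoreAlignment` for bootstrapping.
#' @param bootstrap Replicate count (default 100; 0 disables).
#' @param seed RNG seed for the resampling.
#' @param correction Distance correction used in replicates.
#' @return An [ape::phylo] tree; `node.label` carries supports (%) when
#'   bootstrapped.
#' @export
build_nj_tree <- function(distances, alignment = NULL, bootstrap = 100L,
                          seed = 1L, correction = "raw") {
  if (!isSymmetric(unname(as.matrix(distances)))) {
    stop("validation error: non-symmetric distance matrix")
  }
  if (nrow(as.matrix(distances)) < 3) stop("need >= 3 taxa")
  tree <- ape::nj(as.dist(distances))
  if (!is.null(alignment) && bootstrap > 0) {
    mats <- do.call(rbind, lapply(alignment$sequences,
                                  function(s) strsplit(s, "")[[1]]))
    ncol_aln <- ncol(mats)
    set.seed(seed)
    reps <- vector("list", bootstrap)
    for (r in seq_len(bootstrap)) {
      cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
      sub <- apply(mats[, cols, drop = FALSE], 1, paste, collapse = "")
      dd <- pairwise_divergence(stats::setNames(sub, rownames(mats)),
                                correction = correction)
      reps[[r]] <- ape::nj(as.dist(dd))
    }
    counts <- ape::prop.clades(tree, reps, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    tree$node.label <- round(100 * counts / bootstrap)
  }
  tree
}

#' Date a split from divergence under the molecular clock
#'
#' `t = d / (2 mu)`: the observed per-site divergence accumulates along
#' both descendant lineages.
#'
#' @param d Substitutions per site (pairwise divergence), >= 0.
#' @param mu Clock rate in substitutions/site/year (default
#'   [HYPERTHERMOPHILE_CLOCK_RATE]).
#' @return Split time in years.
#' @export
date_divergence <- function(d, mu = HYPERTHERMOPHILE_CLOCK_RATE) {
  if (any(d < 0)) stop("validation error: negative divergence")
  if (mu <= 0) stop("validation error: non-positive rate")
  d / (2 * mu)
}
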