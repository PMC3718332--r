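# Pan-genome ortholog families from reciprocal-best-hit clustering.
#
# All-vs-all local protein alignment (Smith-Waterman, BLOSUM62, affine
# gaps 11/1 - the de facto protein-search defaults), best hit per query per
# ordered genome pair above identity/coverage floors, reciprocal best hits
# as edges, families as connected components (single linkage). Categories:
# ubiquitous (>= 1 member in every genome, the core genome), singleton
# (exactly one member in one genome), shared (everything else, including
# multi-copy strain-confined families, which are flagged).

#' Best-hit protein similarity between two proteomes
#'
#' Local alignment of every query against every subject; at most the single
#' best-scoring subject passing the thresholds is kept per query
#' (deterministic tie-break: lexicographically smallest subject id).
#' Identity is computed over the aligned region; coverage is aligned length
#' over the shorter sequence.
#'
#' @param proteome_a,proteome_b Named character vectors of amino-acid
#'   sequences. Shared names are treated as the same protein and never
#'   compared with themselves.
#' @param min_identity Percent identity floor (default 30).
#' @param min_coverage Coverage floor, fraction of the shorter sequence
#'   (default 0.5).
#' @param min_score Alignment score floor (default 75); with BLOSUM62 and
#'   affine 11/1 gaps this corresponds to a roughly BLAST-significant local
#'   alignment and suppresses the short compositional matches that raw
#'   identity floors let through.
#' @return Data frame: query, subject, identity, coverage, score.
#' @export
pairwise_protein_similarity <- function(proteome_a, proteome_b,
                                        min_identity = 30,
                                        min_coverage = 0.5,
                                        min_score = 75) {
  if (length(proteome_a) == 0 || length(proteome_b) == 0) {
    stop("validation error: empty proteome")
  }
  subj_names <- sort(names(proteome_b))   # lexicographic tie-break
  out <- list()
  pat_set <- Biostrings::AAStringSet(proteome_a)
  for (sn in subj_names) {
    aln <- Biostrings::pairwiseAlignment(
      pat_set, Biostrings::AAString(proteome_b[[sn]]), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      scoreOnly = FALSE)
    ident <- 100 * Biostrings::nmatch(aln) /
      pmax(1L, Biostrings::nmatch(aln) + Biostrings::nmismatch(aln))
    cov <- (Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)) /
      pmin(nchar(proteome_a), nchar(proteome_b[[sn]]))
    out[[sn]] <- data.frame(query = names(proteome_a), subject = sn,
                            identity = ident, coverage = cov,
                            score = Biostrings::score(aln),
                            stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, out)
  all <- all[all$query != all$subject, , drop = FALSE]
  all <- all[all$identity >= min_identity & all$coverage >= min_coverage &
               all$score >= min_score, , drop = FALSE]
  if (nrow(all) == 0) return(all)
  # best per query: max score, tie-break smallest subject id
  all <- all[order(all$query, -all$score, all$subject), , drop = FALSE]
  all <- all[!duplicated(all$query), , drop = FALSE]
  rownames(all) <- NULL
  all
}

#' All-direction best-hit lists for a set of proteomes
#'
#' @param proteomes Named list of named character vectors (genome id ->
#'   proteins). Protein ids must be unique across genomes.
#' @param min_identity,min_coverage See [pairwise_protein_similarity()].
#' @param within_genome Also compute self-pair best hits (paralog edges,
#'   default TRUE).
#' @return Named list of hit data frames, keys `"A->B"`.
#' @export
pangenome_similarity <- function(proteomes, min_identity = 30,
                                 min_coverage = 0.5, min_score = 75,
                                 within_genome = TRUE) {
  ids <- names(proteomes)
  all_ids <- unlist(lapply(proteomes, names), use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    stop("validation error: protein ids must be unique across genomes")
  }
  hits <- list()
  for (a in ids) for (b in ids) {
    if (a == b && !within_genome) next
    if (a == b && length(proteomes[[a]]) < 2) next
    hits[[paste0(a, "->", b)]] <- pairwise_protein_similarity(
      proteomes[[a]], proteomes[[b]], min_identity, min_coverage, min_score)
  }
  hits
}

#' Build ortholog families from reciprocal best hits
#'
#' Reciprocal best hits (in any genome pair, including within-genome
#' paralog pairs) form edges; families are the connected components.
#' Proteins with no edge become one-member families. Total membership
#' always equals the total protein count.
#'
#' @param hits Output of [pangenome_similarity()].
#' @param proteomes The proteome list the hits were computed from.
#' @return Data frame (one row per family): family_id, n_members,
#'   n_genomes, category (`ubiquitous`/`shared`/`singleton`),
#'   multi_copy_single_genome flag, plus a `members` list-column of
#'   data.frames (genome, protein) and a `copy_counts` list-column.
#' @export
build_ortholog_families <- function(hits, proteomes) {
  genome_of <- rep(names(proteomes), times = lengths(proteomes))
  names(genome_of) <- unlist(lapply(proteomes, names), use.names = FALSE)
  all_prot <- names(genome_of)
  for (h in hits) {
    unknown <- setdiff(unique(c(h$query, h$subject)), all_prot)
    if (length(unknown) > 0) {
      stop("validation error: hit references unknown protein ",
           unknown[1])
    }
  }
  # best-hit map per direction key
  edges <- list()
  keys <- names(hits)
  for (key in keys) {
    ab <- strsplit(key, "->", fixed = TRUE)[[1]]
    rev_key <- paste0(ab[2], "->", ab[1])
    h <- hits[[key]]; hr <- hits[[rev_key]]
    if (is.null(hr) || nrow(h) == 0 || nrow(hr) == 0) next
    back <- stats::setNames(hr$subject, hr$query)
    rbh <- h[!is.na(back[h$subject]) & back[h$subject] == h$query, ,
             drop = FALSE]
    if (nrow(rbh) > 0) {
      edges[[key]] <- rbh[, c("query", "subject")]
    }
  }
  g <- igraph::graph_from_data_frame(
    if (length(edges) > 0) do.call(rbind, edges) else
      data.frame(query = character(), subject = character()),
    directed = FALSE, vertices = data.frame(name = all_prot))
  comp <- igraph::components(g)$membership
  fam_ids <- split(names(comp), comp)
  # deterministic family order: by smallest member id
  fam_ids <- fam_ids[order(vapply(fam_ids, min, ""))]
  n_genomes_total <- length(proteomes)
  rows <- lapply(seq_along(fam_ids), function(i) {
    prots <- sort(fam_ids[[i]])
    gms <- genome_of[prots]
    cc <- table(factor(gms, levels = names(proteomes)))
    n_gen <- sum(cc > 0)
    category <- if (length(prots) == 1) "singleton"
      else if (n_gen == n_genomes_total) "ubiquitous"
      else "shared"
    list(family_id = sprintf("FAM_%05d", i), n_members = length(prots),
         n_genomes = n_gen, category = category,
         multi_copy_single_genome = n_gen == 1 && length(prots) > 1,
         members = data.frame(genome = unname(gms), protein = prots,
                              stringsAsFactors = FALSE),
         copy_counts = as.integer(cc) |> stats::setNames(names(cc)))
  })
  fam <- data.frame(
    family_id = vapply(rows, `[[`, "", "family_id"),
    n_members = vapply(rows, `[[`, 0L, "n_members"),
    n_genomes = vapply(rows, `[[`, 0L, "n_genomes"),
    category = vapply(rows, `[[`, "", "category"),
    multi_copy_single_genome = vapply(rows, `[[`, TRUE,
                                      "multi_copy_single_genome"),
    stringsAsFactors = FALSE)
  fam$members <- lapply(rows, `[[`, "members")
  fam$copy_counts <- lapply(rows, `[[`, "copy_counts")
  fam
}

#' Classify families into core / shared / singleton counts
#'
#' @param families Output of [build_ortholog_families()].
#' @return Named integer vector: n_families, ubiquitous, shared, singleton.
#' @export
classify_families <- function(families) {
  c(n_families = nrow(families),
    ubiquitous = sum(families$category == "ubiquitous"),
    shared = sum(families$category == "shared"),
    singleton = sum(families$category == "singleton"))
}

#' Three-strain family overlap (7-cell Venn)
#'
#' @param families Output of [build_ortholog_families()].
#' @param trio Character vector of exactly three genome ids.
#' @return Named integer vector of the 7 cells (`A_only`, ..., `ABC`),
#'   names prefixed by the genome ids.
#' @export
shared_family_venn <- function(families, trio) {
  stopifnot(length(trio) == 3)
  known <- unique(unlist(lapply(families$members, function(m) m$genome)))
  all_known <- unique(c(known, names(families$copy_counts[[1]])))
  if (!all(trio %in% all_known)) {
    stop("validation error: genome id(s) not in family set: ",
         paste(setdiff(trio, all_known), collapse = ", "))
  }
  pres <- t(vapply(families$members, function(m)
    trio %in% m$genome, logical(3)))
  colnames(pres) <- trio
  pres <- pres[rowSums(pres) > 0, , drop = FALSE]
  key <- apply(pres, 1, function(r) paste(trio[r], collapse = "&"))
  cells <- c(trio, paste(trio[c(1, 1, 2)], trio[c(2, 3, 3)], sep = "&"),
             paste(trio, collapse = "&"))
  out <- stats::setNames(integer(length(cells)), cells)
  tb <- table(key)
  out[names(tb)] <- as.integer(tb)
  out
}
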