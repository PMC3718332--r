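# Integrated mobile genetic elements: viral/plasmid-homolog window
# enrichment, tRNA-linked attachment-site scanning, clusters of atypical
# codon usage (CAG), IS elements and MITEs.

#' Annotate genes by best viral/plasmid database hit
#'
#' Local-alignment best hit per gene against a labelled mobile-genetic-
#' element protein database; one record per gene with a passing hit.
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param mge_db Either a FASTA path whose headers carry `class=virus` or
#'   `class=plasmid` tags, or a data frame with columns `id`, `class`,
#'   `sequence`.
#' @param min_identity Percent identity floor (default 30).
#' @param min_coverage Coverage floor on the shorter sequence (default 0.5).
#' @return Data frame: gene, subject, class, identity, coverage, score.
#' @export
annotate_mge_homologs <- function(proteins, mge_db, min_identity = 30,
                                  min_coverage = 0.5, min_score = 75) {
  db <- load_protein_db(mge_db)
  if (nrow(db) == 0) stop("validation error: empty MGE database")
  if (any(is.na(db$class) | !db$class %in% c("virus", "plasmid"))) {
    stop("validation error: unlabeled MGE database entry (need class=virus|plasmid)")
  }
  hits <- pairwise_protein_similarity(
    proteins, stats::setNames(db$sequence, db$id),
    min_identity, min_coverage, min_score)
  if (nrow(hits) == 0) {
    return(data.frame(gene = character(), subject = character(),
                      class = character(), identity = numeric(),
                      coverage = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  hits$class <- db$class[match(hits$subject, db$id)]
  names(hits)[names(hits) == "query"] <- "gene"
  hits[, c("gene", "subject", "class", "identity", "coverage", "score")]
}

load_protein_db <- function(x) {
  if (is.data.frame(x)) return(x)
  ss <- Biostrings::readAAStringSet(x)
  hdr <- names(ss)
  cls <- regmatches(hdr, regexpr("class=\\S+", hdr))
  cls_vec <- rep(NA_character_, length(hdr))
  has <- grepl("class=", hdr)
  cls_vec[has] <- sub("class=", "", regmatches(hdr, regexpr("class=\\S+", hdr)))
  data.frame(id = sub("\\s.*$", "", hdr), class = cls_vec,
             sequence = as.character(ss), stringsAsFactors = FALSE)
}

#' Window scan for clusters of viral/plasmid homologs
#'
#' Tests a window of `window_bp` anchored at the start of every annotated
#' gene; windows with at least `min_hits` annotated genes are retained and
#' overlapping retained windows merged. Anchoring at hit-gene starts is
#' exactly equivalent to sliding a window over every base pair: any per-bp
#' window holding k hits can be slid right until its left edge touches the
#' first hit without losing any of them. Wraps the circular junction.
#'
#' @param annotations Output of [annotate_mge_homologs()].
#' @param genome `GenomeRecord` whose CDS features carry the annotated ids.
#' @param window_bp Window size (default 20000).
#' @param min_hits Minimum annotated genes per window (default 5).
#' @return Data frame of merged candidates: start, end, n_hits, genes
#'   (comma-separated), evidence = `window_enrichment`.
#' @export
scan_homolog_windows <- function(annotations, genome, window_bp = 20000L,
                                 min_hits = 5L) {
  empty <- data.frame(start = integer(), end = integer(), n_hits = integer(),
                      genes = character(), evidence = character(),
                      stringsAsFactors = FALSE)
  if (nrow(annotations) == 0) return(empty)
  f <- genome$features
  cds <- f[f$kind == "CDS" & !duplicated(f$id), , drop = FALSE]
  hit <- cds[cds$id %in% annotations$gene, , drop = FALSE]
  if (nrow(hit) == 0) return(empty)
  hit <- hit[order(hit$start), , drop = FALSE]
  L <- nchar(genome$sequence)
  circ <- genome$topology == "circular"
  s <- hit$start
  s_ext <- if (circ) c(s, s + L) else s
  id_ext <- if (circ) rep(hit$id, 2) else hit$id
  retained <- list()
  for (i in seq_along(s)) {
    inw <- which(s_ext >= s[i] & s_ext <= s[i] + window_bp - 1L)
    if (length(inw) >= min_hits) {
      retained[[length(retained) + 1L]] <-
        c(start = s[i], end = s[i] + window_bp - 1L)
    }
  }
  if (length(retained) == 0) return(empty)
  w <- do.call(rbind, retained)
  w <- w[order(w[, 1]), , drop = FALSE]
  grp <- cumsum(c(TRUE, w[-1, 1] > cummax(w[-nrow(w), 2])[
    seq_len(nrow(w) - 1L)]))
  out <- lapply(split(seq_len(nrow(w)), grp), function(ii) {
    ws <- min(w[ii, 1]); we <- max(w[ii, 2])
    inw <- which(s_ext >= ws & s_ext <= we)
    genes <- unique(id_ext[inw])
    rows <- hit[hit$id %in% genes, , drop = FALSE]
    sp_start <- min(rows$start); sp_end <- max(rows$end)
    data.frame(start = sp_start, end = sp_end, n_hits = length(genes),
               genes = paste(genes, collapse = ","),
               evidence = "window_enrichment", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  # merge candidates whose gene spans overlap after trimming to genes
  res <- res[order(res$start), , drop = FALSE]
  if (nrow(res) > 1) {
    grp2 <- cumsum(c(TRUE, res$start[-1] > cummax(res$end[-nrow(res)])[
      seq_len(nrow(res) - 1L)]))
    res <- do.call(rbind, lapply(split(res, grp2), function(d) {
      genes <- unique(unlist(strsplit(d$genes, ",")))
      data.frame(start = min(d$start), end = max(d$end),
                 n_hits = length(genes),
                 genes = paste(genes, collapse = ","),
                 evidence = "window_enrichment", stringsAsFactors = FALSE)
    }))
  }
  rownames(res) <- NULL
  res
}

#' Scan tRNA genes for attachment-site-delimited integrated elements
#'
#' Site-specific integrases recombine with the 3' end of a tRNA gene,
#' duplicating an attachment (att) sequence that then flanks the element as
#' a direct repeat: one copy (attL) overlaps the tRNA 3' end, the distal
#' copy (attR) sits up to tens of kb away. For each tRNA the 3'-terminal
#' subsequence (longest first, `max_att` down to `min_att`) is searched in
#' the downstream window for a second copy at `min_att_identity` or better.
#'
#' @param genome `GenomeRecord` with tRNA features.
#' @param window_bp Search window beyond the tRNA 3' end (default 50000).
#' @param min_att,max_att att length bounds (defaults 15, 50).
#' @param min_att_identity Identity floor for the distal copy (default 0.8).
#' @param annotations Optional [annotate_mge_homologs()] output; candidate
#'   rows then carry the count of viral/plasmid homolog genes inside.
#' @param min_distance Minimum attL-attR separation (default 100 bp).
#' @return Data frame: trna_id, start, end, att_length, att_identity,
#'   attL_start, attL_end, attR_start, attR_end, n_mge_hits, evidence.
#' @export
trna_integration_scan <- function(genome, window_bp = 50000L,
                                  min_att = 15L, max_att = 50L,
                                  min_att_identity = 0.8,
                                  annotations = NULL,
                                  min_distance = 100L) {
  f <- genome$features
  trnas <- f[f$kind == "tRNA", , drop = FALSE]
  trnas <- trnas[!duplicated(trnas$id), , drop = FALSE]
  if (nrow(trnas) == 0) stop("validation error: no tRNA features")
  seq <- genome$sequence
  L <- nchar(seq)
  out <- list()
  for (i in seq_len(nrow(trnas))) {
    tr <- trnas[i, ]
    plus <- tr$strand == "+"
    found <- NULL
    for (la in seq(min(max_att, tr$end - tr$start + 1L), min_att)) {
      if (plus) {
        attL <- c(tr$end - la + 1L, tr$end)
        win <- c(tr$end + 1L, min(L, tr$end + window_bp))
      } else {
        attL <- c(tr$start, tr$start + la - 1L)
        win <- c(max(1L, tr$start - window_bp), tr$start - 1L)
      }
      if (win[2] - win[1] + 1L < la) next
      pat <- substr(seq, attL[1], attL[2])
      mm_budget <- floor((1 - min_att_identity) * la)
      h <- hamming_hits(substr(seq, win[1], win[2]), pat, mm_budget,
                        both_strands = FALSE)
      if (nrow(h) == 0) next
      h$start <- h$start + win[1] - 1L
      h$end <- h$end + win[1] - 1L
      h <- if (plus) h[h$start >= tr$end + min_distance, , drop = FALSE]
           else h[h$end <= tr$start - min_distance, , drop = FALSE]
      if (nrow(h) == 0) next
      h <- h[order(h$mismatches, -abs(h$start - tr$end)), , drop = FALSE]
      # refine the att boundary: among suffixes of the aligned pair
      # (length min_att..la; the tRNA 3'-anchored end is fixed) take the
      # one maximizing identity, preferring the longest on ties
      hit <- substr(seq, h$start[1], h$end[1])
      mv <- strsplit(pat, "")[[1]] == strsplit(hit, "")[[1]]
      # anchor at the tRNA 3' end: genome-coordinate right end on "+",
      # left end on "-"
      if (plus) mv <- rev(mv)
      cum <- cumsum(mv)   # matches in the suffix of length k
      ks <- seq(min_att, la)
      ident_k <- cum[ks] / ks
      best <- ks[which(ident_k == max(ident_k))]
      lb <- best[length(best)]
      if (cum[lb] / lb < min_att_identity) next
      if (plus) {
        attL_f <- c(tr$end - lb + 1L, tr$end)
        attR_f <- c(h$end[1] - lb + 1L, h$end[1])
      } else {
        attL_f <- c(tr$start, tr$start + lb - 1L)
        attR_f <- c(h$start[1], h$start[1] + lb - 1L)
      }
      found <- list(la = lb, attL = attL_f, attR = attR_f,
                    ident = cum[lb] / lb)
      break
    }
    if (is.null(found)) next
    span <- range(c(found$attL, found$attR))
    n_hits <- NA_integer_
    if (!is.null(annotations)) {
      cds <- f[f$kind == "CDS" & f$id %in% annotations$gene, , drop = FALSE]
      n_hits <- sum(cds$start >= span[1] & cds$end <= span[2])
    }
    out[[length(out) + 1L]] <- data.frame(
      trna_id = tr$id, start = span[1], end = span[2],
      att_length = found$la, att_identity = found$ident,
      attL_start = found$attL[1], attL_end = found$attL[2],
      attR_start = found$attR[1], attR_end = found$attR[2],
      n_mge_hits = n_hits, evidence = "trna_linked",
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(trna_id = character(), start = integer(),
                      end = integer(), att_length = integer(),
                      att_identity = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# --- codon usage ------------------------------------------------------------

sense_codons <- function(translation_table = 11L) {
  code <- Biostrings::getGeneticCode(as.character(translation_table))
  names(code)[code != "*"]
}

#' Per-gene codon-usage atypicality scores
#'
#' For each CDS, codon frequencies over the 61 sense codons are compared
#' with the genome-wide frequencies F by the chi-square distance
#' `d_g = sum_i (f_gi - F_i)^2 / F_i` (over codons with `F_i > 0`). Genes
#' are ranked by `d_g` descending and cut into deciles; decile score 1
#' marks the most atypical tenth, 10 the least.
#'
#' @param genome `GenomeRecord` with at least 10 CDS.
#' @param translation_table NCBI code id (default 11); only sets the stop
#'   codons excluded from the sense set.
#' @return Data frame in gene order: gene, start, end, n_codons, d,
#'   decile, low_confidence (< 30 codons).
#' @export
codon_usage_scores <- function(genome, translation_table = 11L) {
  f <- genome$features
  cds_ids <- unique(f$id[f$kind == "CDS"])
  if (length(cds_ids) < 10) {
    stop("validation error: need >= 10 CDS for decile scoring")
  }
  sense <- sense_codons(translation_table)
  count1 <- function(fid) {
    nt <- feature_nt_sequence(genome, fid, kind = "CDS")
    nt <- substr(nt, 1, nchar(nt) - nchar(nt) %% 3)
    cc <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAString(nt), width = 3, step = 3)
    cc[sense]
  }
  counts <- t(vapply(cds_ids, count1, numeric(length(sense))))
  total <- colSums(counts)
  F_glob <- total / sum(total)
  supported <- F_glob > 0
  n_cod <- rowSums(counts)
  fg <- counts / pmax(1, n_cod)
  d <- vapply(seq_along(cds_ids), function(i) {
    sum((fg[i, supported] - F_glob[supported])^2 / F_glob[supported])
  }, 0)
  ord <- order(-d, cds_ids)
  decile <- integer(length(d))
  decile[ord] <- ceiling(seq_along(ord) * 10 / length(ord))
  starts <- vapply(cds_ids, function(id)
    min(f$start[f$id == id & f$kind == "CDS"]), 0L)
  ends <- vapply(cds_ids, function(id)
    max(f$end[f$id == id & f$kind == "CDS"]), 0L)
  out <- data.frame(gene = cds_ids, start = starts, end = ends,
                    n_codons = as.integer(n_cod), d = d, decile = decile,
                    low_confidence = n_cod < 30, stringsAsFactors = FALSE)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect clusters of atypical genes (CAG)
#'
#' A CAG is a maximal run of consecutive genes (in genome order) whose
#' decile score is at most `max_score`, containing at least one seed gene
#' (score <= `seed_score`), tolerating up to `interruptions` intervening
#' typical genes, and holding at least `min_genes` member genes.
#'
#' Because decile scores are a forced uniform partition (a tenth of all
#' genes per decile), a permissive member ceiling floods the scan with
#' chance runs: with a ceiling of 7, 70% of genes qualify and runs of five
#' arise everywhere by chance. The defaults therefore restrict members to
#' the two most atypical deciles and seeds to the first.
#'
#' @param profiles Output of [codon_usage_scores()] (gene order).
#' @param min_genes Minimum member genes (default 5).
#' @param max_score Decile ceiling for members (default 2).
#' @param seed_score Decile ceiling for the required seed (default 1).
#' @param interruptions Allowed interior interruptions (default 1).
#' @return Data frame: cag_id, start, end, n_genes, min_score, max_score,
#'   genes, scores (comma-separated).
#' @export
detect_cags <- function(profiles, min_genes = 5L, max_score = 2L,
                        seed_score = 1L, interruptions = 1L) {
  atyp <- profiles$decile <= max_score
  n <- nrow(profiles)
  regions <- list()
  i <- 1L
  while (i <= n) {
    if (!atyp[i]) { i <- i + 1L; next }
    j <- i
    used_int <- 0L
    last_good <- i
    while (j < n) {
      nxt <- j + 1L
      if (atyp[nxt]) { j <- nxt; last_good <- nxt; next }
      if (used_int < interruptions && nxt < n && atyp[nxt + 1L]) {
        used_int <- used_int + 1L
        j <- nxt + 1L
        last_good <- j
        next
      }
      break
    }
    members <- which(atyp[i:last_good]) + i - 1L
    if (length(members) >= min_genes &&
        any(profiles$decile[members] <= seed_score)) {
      regions[[length(regions) + 1L]] <- members
    }
    i <- last_good + 1L
  }
  if (length(regions) == 0) {
    return(data.frame(cag_id = character(), start = integer(),
                      end = integer(), n_genes = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, lapply(seq_along(regions), function(k) {
    m <- regions[[k]]
    data.frame(cag_id = sprintf("CAG%d", k),
               start = min(profiles$start[m]), end = max(profiles$end[m]),
               n_genes = length(m),
               min_score = min(profiles$decile[m]),
               max_score = max(profiles$decile[m]),
               genes = paste(profiles$gene[m], collapse = ","),
               scores = paste(profiles$decile[m], collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

# --- ORFs, IS elements, MITEs ----------------------------------------------

# Longest ORF (start codon .. stop codon, inclusive, nt) on both strands.
longest_orf <- function(seq, starts = c("ATG", "GTG", "TTG"),
                        stops = c("TAA", "TAG", "TGA")) {
  best <- 0L
  for (s in c(seq, revcomp(seq))) {
    n <- nchar(s)
    for (frame in 0:2) {
      cs <- seq.int(1L + frame, n - 2L, by = 3L)
      if (length(cs) == 0) next
      cods <- substring(s, cs, cs + 2L)
      stop_at <- which(cods %in% stops)
      seg_bounds <- c(0L, stop_at, length(cods) + 1L)
      for (k in seq_len(length(seg_bounds) - 1L)) {
        from <- seg_bounds[k] + 1L
        to <- seg_bounds[k + 1L]
        if (to > length(cods)) next    # open segment: no stop, not an ORF
        st <- which(cods[from:to] %in% starts)
        if (length(st) == 0) next
        len <- (to - (from + st[1] - 1L) + 1L) * 3L
        if (len > best) best <- len
      }
    }
  }
  best
}

#' Detect IS elements from a family library
#'
#' Library matches are seeded by the consensus termini (first/last 30 bp,
#' 20% mismatch budget) paired within 0.3-1.2 of the consensus length, on
#' both strands; each candidate is validated by the best reverse-complement
#' terminal repeat pair (ITR), and the transposase is called intact when
#' the longest internal ORF reaches `intact_frac` of the family reference
#' ORF length. Truncated copies are mobilizable in trans when an intact
#' same-family copy exists elsewhere in the genome.
#'
#' @param genome `GenomeRecord` or DNA string.
#' @param is_library Data frame: family, sequence (consensus), ref_len
#'   (reference transposase ORF length in nt).
#' @param min_identity Identity floor over the aligned region (default 0.8).
#' @param itr_max_offset ITR search offset from element ends (default 50).
#' @param min_itr Minimum ITR length (default 10).
#' @param intact_frac Intactness threshold (default 0.8).
#' @return Data frame: family, start, end, strand, identity, itr_length,
#'   itr_mismatches, transposase (`intact`/`truncated`/`absent`),
#'   mobilizable_in_trans.
#' @export
detect_is_elements <- function(genome, is_library, min_identity = 0.8,
                               itr_max_offset = 50L, min_itr = 10L,
                               intact_frac = 0.8) {
  seq <- if (inherits(genome, "GenomeRecord")) genome$sequence else genome
  if (is.null(is_library) || nrow(is_library) == 0) {
    stop("validation error: empty IS library")
  }
  if (!"ref_len" %in% names(is_library) || any(is.na(is_library$ref_len))) {
    stop("validation error: IS library entry without reference length")
  }
  out <- list()
  for (i in seq_len(nrow(is_library))) {
    fam <- is_library$family[i]
    cons <- toupper(is_library$sequence[i])
    cl <- nchar(cons)
    seed_len <- min(30L, cl %/% 3L)
    for (strand in c("+", "-")) {
      cs <- if (strand == "+") cons else revcomp(cons)
      sl <- substr(cs, 1, seed_len)
      sr <- substr(cs, cl - seed_len + 1L, cl)
      hl <- hamming_hits(seq, sl, floor(0.2 * seed_len))
      hr <- hamming_hits(seq, sr, floor(0.2 * seed_len))
      hl <- hl[hl$strand == "+", , drop = FALSE]
      hr <- hr[hr$strand == "+", , drop = FALSE]
      if (nrow(hl) == 0 || nrow(hr) == 0) next
      for (a in seq_len(nrow(hl))) {
        len_to <- hr$end - hl$start[a] + 1L
        ok <- which(len_to >= 0.3 * cl & len_to <= 1.2 * cl)
        if (length(ok) == 0) next
        b <- ok[which.min(abs(len_to[ok] - cl))]
        el_start <- hl$start[a]; el_end <- hr$end[b]
        el <- substr(seq, el_start, el_end)
        if (strand == "-") el <- revcomp(el)
        # gap-tolerant global alignment: an internal deletion (truncated
        # transposase) must not destroy the identity estimate, so gaps are
        # cheap to extend; identity is over aligned (non-gap) columns
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(el), Biostrings::DNAString(cons),
          type = "global",
          substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
            match = 2, mismatch = -2),
          gapOpening = 10, gapExtension = 0.25)
        ident <- Biostrings::nmatch(aln) /
          max(1L, Biostrings::nmatch(aln) + Biostrings::nmismatch(aln))
        if (ident < min_identity) next
        itr <- best_itr(el, itr_max_offset, min_itr)
        orf <- longest_orf(el)
        status <- if (is.null(itr)) "no_itr"
          else if (orf >= intact_frac * is_library$ref_len[i]) "intact"
          else if (orf > 0) "truncated" else "absent"
        out[[length(out) + 1L]] <- data.frame(
          family = fam, start = el_start, end = el_end, strand = strand,
          identity = ident,
          itr_length = if (is.null(itr)) NA_integer_ else itr$len,
          itr_mismatches = if (is.null(itr)) NA_integer_ else itr$mm,
          transposase = status, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(family = character(), start = integer(),
                      end = integer(), strand = character(),
                      identity = numeric(), itr_length = integer(),
                      itr_mismatches = integer(), transposase = character(),
                      mobilizable_in_trans = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  res <- res[!duplicated(paste(res$start, res$end)), , drop = FALSE]
  res$mobilizable_in_trans <- vapply(seq_len(nrow(res)), function(k) {
    res$transposase[k] == "truncated" &&
      any(res$family == res$family[k] & res$transposase == "intact")
  }, TRUE)
  rownames(res) <- NULL
  res
}

# Best reverse-complement terminal repeat pair near element ends.
best_itr <- function(el, max_offset = 50L, min_len = 10L, max_len = 40L,
                     mismatch_frac = 0.2) {
  n <- nchar(el)
  rc <- revcomp(el)   # revcomp of suffix at offset o2 = prefix of rc at o2
  for (len in seq(min(max_len, n %/% 3L), min_len)) {
    for (o1 in 0:min(max_offset, n - 2L * len)) {
      a <- substr(el, 1L + o1, o1 + len)
      for (o2 in 0:min(max_offset, n - 2L * len - o1)) {
        b_rc <- substr(rc, o2 + 1L, o2 + len)
        mm <- hamming(a, b_rc)
        if (mm <= floor(mismatch_frac * len)) {
          return(list(len = len, mm = mm, offset5 = o1, offset3 = o2))
        }
      }
    }
  }
  NULL
}

#' Detect MITEs by class consensus or de novo structure
#'
#' Consensus mode reports Hamming matches of each labelled class consensus
#' at `min_identity` or better, on both strands. De novo mode searches for
#' the structural signature alone: a terminal inverted repeat (TIR) pair
#' spanning 50-400 bp, flanked by a short target-site duplication (TSD),
#' with no internal ORF of 100+ codons.
#'
#' @param genome `GenomeRecord` or DNA string.
#' @param consensi Optional data frame `class`, `sequence` for consensus
#'   mode.
#' @param min_identity Consensus-mode identity floor (default 0.9).
#' @param denovo Run the structural scan (default `is.null(consensi)`).
#' @param tir_min,tir_max TIR length bounds (defaults 12, 30).
#' @param tsd_min,tsd_max TSD length bounds (defaults 3, 9).
#' @param len_min,len_max Element length bounds (defaults 50, 400).
#' @return Data frame: class (or `denovo`), start, end, strand, length,
#'   identity, tir_length, tsd_length, tsd.
#' @export
detect_mites <- function(genome, consensi = NULL, min_identity = 0.9,
                         denovo = is.null(consensi),
                         tir_min = 12L, tir_max = 30L,
                         tsd_min = 3L, tsd_max = 9L,
                         len_min = 50L, len_max = 400L) {
  seq <- if (inherits(genome, "GenomeRecord")) genome$sequence else genome
  out <- list()
  if (!is.null(consensi)) {
    for (i in seq_len(nrow(consensi))) {
      cons <- toupper(consensi$sequence[i])
      mm <- floor((1 - min_identity) * nchar(cons))
      h <- hamming_hits(seq, cons, mm, both_strands = TRUE)
      if (nrow(h) == 0) next
      h$class <- consensi$class[i]
      h$length <- nchar(cons)
      h$identity <- 1 - h$mismatches / nchar(cons)
      h$tir_length <- NA_integer_; h$tsd_length <- NA_integer_
      h$tsd <- NA_character_
      out[[length(out) + 1L]] <-
        h[, c("class", "start", "end", "strand", "length", "identity",
              "tir_length", "tsd_length", "tsd")]
    }
  }
  if (denovo) {
    dn <- mite_denovo_scan(seq, tir_min, tir_max, tsd_min, tsd_max,
                           len_min, len_max)
    if (nrow(dn) > 0) out[[length(out) + 1L]] <- dn
  }
  if (length(out) == 0) {
    return(data.frame(class = character(), start = integer(),
                      end = integer(), strand = character(),
                      length = integer(), identity = numeric(),
                      tir_length = integer(), tsd_length = integer(),
                      tsd = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

mite_denovo_scan <- function(seq, tir_min, tir_max, tsd_min, tsd_max,
                             len_min, len_max) {
  n <- nchar(seq)
  k <- as.integer(tir_min)
  empty <- data.frame(class = character(), start = integer(),
                      end = integer(), strand = character(),
                      length = integer(), identity = numeric(),
                      tir_length = integer(), tsd_length = integer(),
                      tsd = character(), stringsAsFactors = FALSE)
  if (n < len_min + 2L * tsd_min) return(empty)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  pos <- split(starts, kmers)
  cand <- list()
  nm <- names(pos)
  rcs <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(nm)))
  idx <- match(rcs, nm)
  sel <- which(!is.na(idx) & rcs > nm)   # each kmer/revcomp pair once
  for (t in sel) {
    # both orders: an element may start with this kmer and end with its
    # reverse complement, or the reverse (same structure seen from the
    # other terminus)
    for (ij in list(c(t, idx[t]), c(idx[t], t))) {
      for (i in pos[[ij[1]]]) for (j in pos[[ij[2]]]) {
        total <- j + k - i
        if (total < len_min || total > len_max) next
        cand[[length(cand) + 1L]] <- c(i, j + k - 1L)
      }
    }
  }
  if (length(cand) == 0) return(empty)
  m <- unique(do.call(rbind, cand))
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  keep <- list()
  claimed_to <- 0L
  for (r in seq_len(nrow(m))) {
    st <- m[r, 1]; en <- m[r, 2]
    if (st <= claimed_to) next
    el <- substr(seq, st, en)
    # extend TIR inward up to tir_max
    tl <- k
    while (tl < tir_max && tl * 2L < nchar(el) &&
           substr(el, tl + 1L, tl + 1L) ==
             revcomp(substr(el, nchar(el) - tl, nchar(el) - tl))) {
      tl <- tl + 1L
    }
    tsd <- NA_character_
    for (t in seq(tsd_max, tsd_min)) {
      if (st - t < 1L || en + t > n) next
      left <- substr(seq, st - t, st - 1L)
      right <- substr(seq, en + 1L, en + t)
      if (left == right) { tsd <- left; break }
    }
    if (is.na(tsd)) next
    if (longest_orf(el) >= 300L) next
    keep[[length(keep) + 1L]] <- data.frame(
      class = "denovo", start = st, end = en, strand = "+",
      length = en - st + 1L, identity = NA_real_, tir_length = tl,
      tsd_length = nchar(tsd), tsd = tsd, stringsAsFactors = FALSE)
    claimed_to <- en
  }
  if (length(keep) == 0) return(empty)
  do.call(rbind, keep)
}
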