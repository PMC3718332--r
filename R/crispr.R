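# CRISPR repeat-spacer arrays: de novo detection, repeat-driven scans,
# spacer/protospacer matching and PAM inference.
#
# An array is a maximal chain of near-identical direct repeats (20-50 bp)
# separated by unique spacers. Mismatch handling is Hamming throughout (no
# indels), which keeps every scan equivalent to an exhaustive per-position
# oracle. A kilobase-scale segment sitting between two complete repeats is
# kept as an "anomalous" spacer (pseudo-spacer), the hallmark of an element
# integrated into the array.

new_crispr_array <- function(locus_id, copies, genome_seq, strand = "+",
                             anomaly_threshold = 200L, family = NA_character_) {
  copies <- copies[order(copies$start), , drop = FALSE]
  cons <- consensus_string(substring(genome_seq, copies$start, copies$end))
  copies$mismatches <- vapply(seq_len(nrow(copies)), function(i)
    hamming(substr(genome_seq, copies$start[i], copies$end[i]), cons), 0L)
  n <- nrow(copies)
  spacers <- data.frame(array_id = character(), index = integer(),
                        start = integer(), end = integer(),
                        length = integer(), sequence = character(),
                        anomalous = logical(), stringsAsFactors = FALSE)
  if (n >= 2) {
    s_start <- copies$end[-n] + 1L
    s_end <- copies$start[-1] - 1L
    len <- s_end - s_start + 1L
    spacers <- data.frame(
      array_id = locus_id, index = seq_len(n - 1L),
      start = s_start, end = s_end, length = len,
      sequence = substring(genome_seq, s_start, s_end),
      anomalous = len > anomaly_threshold, stringsAsFactors = FALSE)
  }
  structure(list(locus_id = locus_id, start = min(copies$start),
                 end = max(copies$end), repeat_consensus = cons,
                 copies = copies, spacers = spacers, strand = strand,
                 orientation = "unknown", family = family),
            class = "CrisprArray")
}

#' @export
print.CrisprArray <- function(x, ...) {
  cat(sprintf("CrisprArray %s %d..%d (%s): repeat %s, %d copies, %d spacers%s\n",
              x$locus_id, x$start, x$end, x$strand, x$repeat_consensus,
              nrow(x$copies), nrow(x$spacers),
              if (any(x$spacers$anomalous))
                sprintf(" (%d anomalous)", sum(x$spacers$anomalous)) else ""))
  invisible(x)
}

#' Locate CRISPR arrays built from a known repeat
#'
#' Finds all Hamming matches of `repeat_seq` on both strands within
#' `max_mismatch`, drops overlapping matches (best mismatch count wins),
#' clusters copies separated by at most `anomalous_gap`, and extracts the
#' intervening spacers.
#'
#' @param genome `GenomeRecord` or DNA string.
#' @param repeat_seq Repeat sequence, 15-60 bp.
#' @param max_mismatch Per-copy mismatch budget (default 20% of length).
#' @param min_copies Minimum repeat copies per array (default 3).
#' @param anomalous_gap Maximum spacer gap in bp before an array is split
#'   (default 2500); gaps above the usual spacer length but below this cap
#'   become anomalous spacers.
#' @param anomaly_threshold Spacer length above which it is flagged
#'   anomalous (default 200).
#' @param region Optional `c(start, end)` restricting the scan.
#' @param locus_prefix Prefix for array ids.
#' @return List of `CrisprArray` objects, ordered by start.
#' @export
find_arrays_by_repeat <- function(genome, repeat_seq,
                                  max_mismatch = NULL, min_copies = 3L,
                                  anomalous_gap = 2500L,
                                  anomaly_threshold = 200L, region = NULL,
                                  locus_prefix = "CRISPR") {
  seq <- if (inherits(genome, "GenomeRecord")) genome$sequence else genome
  rl <- nchar(repeat_seq)
  if (rl < 15 || rl > 60) stop("repeat length must be 15-60 bp")
  if (length(unique(strsplit(repeat_seq, "")[[1]])) == 1) {
    warning("degenerate (homopolymer) repeat")
  }
  if (is.null(max_mismatch)) max_mismatch <- floor(0.2 * rl)
  offset <- 0L
  if (!is.null(region)) {
    offset <- region[1] - 1L
    seq <- substr(seq, region[1], region[2])
  }
  hits <- hamming_hits(seq, repeat_seq, max_mismatch, both_strands = TRUE)
  arrays <- list()
  for (strand in unique(hits$strand)) {
    h <- hits[hits$strand == strand, , drop = FALSE]
    h <- drop_overlaps(h)
    if (nrow(h) < min_copies) next
    gap <- h$start[-1] - h$end[-nrow(h)] - 1L
    grp <- cumsum(c(TRUE, gap > anomalous_gap | gap < 15L))
    for (g in split(h, grp)) {
      if (nrow(g) < min_copies) next
      arrays[[length(arrays) + 1L]] <- new_crispr_array(
        "tmp", g[, c("start", "end")], seq, strand = strand,
        anomaly_threshold = anomaly_threshold)
    }
  }
  arrays <- shift_and_name(arrays, offset, locus_prefix)
  arrays
}

drop_overlaps <- function(h) {
  if (nrow(h) <= 1) return(h)
  h <- h[order(h$mismatches, h$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    if (!keep[i]) next
    ov <- which(keep & seq_len(nrow(h)) > i &
                  h$start <= h$end[i] & h$end >= h$start[i])
    keep[ov] <- FALSE
  }
  h <- h[keep, , drop = FALSE]
  h[order(h$start), , drop = FALSE]
}

shift_and_name <- function(arrays, offset, prefix) {
  if (length(arrays) == 0) return(arrays)
  ord <- order(vapply(arrays, `[[`, 0L, "start"))
  arrays <- arrays[ord]
  for (i in seq_along(arrays)) {
    a <- arrays[[i]]
    a$locus_id <- sprintf("%s_%d", prefix, i)
    a$start <- a$start + offset; a$end <- a$end + offset
    a$copies$start <- a$copies$start + offset
    a$copies$end <- a$copies$end + offset
    if (nrow(a$spacers) > 0) {
      a$spacers$array_id <- a$locus_id
      a$spacers$start <- a$spacers$start + offset
      a$spacers$end <- a$spacers$end + offset
    }
    arrays[[i]] <- a
  }
  arrays
}

#' De novo CRISPR array detection
#'
#' Seed stage: exact k-mers recurring with a period inside
#' `period_range` nominate candidate repeats. Refinement stage: the repeat
#' boundary is grown around the seed while the copies stay column-conserved,
#' giving a consensus which is then handed to [find_arrays_by_repeat()].
#' Arrays sharing a consensus (same repeat family) are reported together;
#' overlapping candidates are de-duplicated.
#'
#' @param genome `GenomeRecord` or DNA string (length >= 200).
#' @param repeat_len_range Allowed repeat length (default `c(23, 50)`).
#' @param period_range Allowed repeat-start period, i.e. repeat + spacer
#'   (default `c(44, 120)`).
#' @param min_copies Minimum repeat copies (default 3).
#' @param mismatch_frac Per-copy mismatch budget as a fraction of repeat
#'   length (default 0.2).
#' @param anomalous_gap,anomaly_threshold See [find_arrays_by_repeat()].
#' @param seed_k Exact seed length (default 12).
#' @return List of `CrisprArray`, ordered by start; repeat families are
#'   labelled by consensus (`family` field).
#' @export
detect_crispr_arrays <- function(genome, repeat_len_range = c(23L, 50L),
                                 period_range = c(44L, 120L),
                                 min_copies = 3L, mismatch_frac = 0.2,
                                 anomalous_gap = 2500L,
                                 anomaly_threshold = 200L, seed_k = 12L) {
  seq <- if (inherits(genome, "GenomeRecord")) genome$sequence else genome
  n <- nchar(seq)
  if (n < 200) stop("genome too short for array detection")
  k <- as.integer(seed_k)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  pos_by_kmer <- split(starts, kmers)
  pos_by_kmer <- pos_by_kmer[lengths(pos_by_kmer) >= min_copies &
                               !grepl("N", names(pos_by_kmer), fixed = TRUE)]
  # candidate = kmer with >= min_copies-1 consecutive periodic gaps
  cand <- list()
  for (km in names(pos_by_kmer)) {
    p <- pos_by_kmer[[km]]
    d <- diff(p)
    periodic <- d >= period_range[1] & d <= period_range[2]
    r <- rle(periodic)
    if (any(r$values & r$lengths >= (min_copies - 1L))) {
      ends <- cumsum(r$lengths)
      sel <- which(r$values & r$lengths >= (min_copies - 1L))[1]
      i0 <- if (sel == 1) 1L else ends[sel - 1L] + 1L
      cand[[length(cand) + 1L]] <- list(kmer = km,
                                        pos = p[i0:(ends[sel] + 1L)])
    }
  }
  if (length(cand) == 0) return(list())
  cand <- cand[order(vapply(cand, function(x) x$pos[1], 0L))]

  arrays <- list()
  covered <- integer(0)  # starts of spans already claimed, as c(start,end) rows
  span_taken <- function(s, e) {
    if (length(covered) == 0) return(FALSE)
    any(covered[, 1] <= e & covered[, 2] >= s)
  }
  for (cd in cand) {
    p0 <- cd$pos[1]
    if (span_taken(p0, p0 + k)) next
    cons <- refine_repeat_consensus(seq, cd$pos, k, repeat_len_range)
    if (is.null(cons)) next
    mm <- floor(mismatch_frac * nchar(cons))
    found <- find_arrays_by_repeat(seq, cons, max_mismatch = mm,
                                   min_copies = min_copies,
                                   anomalous_gap = anomalous_gap,
                                   anomaly_threshold = anomaly_threshold,
                                   locus_prefix = "tmp")
    for (a in found) {
      if (span_taken(a$start, a$end)) next
      a$family <- a$repeat_consensus
      arrays[[length(arrays) + 1L]] <- a
      covered <- rbind(covered, c(a$start, a$end))
    }
  }
  shift_and_name(arrays, 0L, "CRISPR")
}

# Grow repeat boundaries around an exact seed shared by periodic copies.
# Columns are kept while the modal base covers >= 75% of copies; result is
# trimmed into the allowed length range (NULL if impossible).
refine_repeat_consensus <- function(seq, pos, k, repeat_len_range,
                                    col_conserved = 0.75) {
  n <- nchar(seq)
  max_ext <- repeat_len_range[2]
  col_ok <- function(delta) {
    at <- pos + delta
    if (any(at < 1 | at > n)) return(FALSE)
    b <- substring(seq, at, at)
    max(table(b)) / length(b) >= col_conserved
  }
  left <- 0L
  while (left < max_ext && col_ok(-(left + 1L))) left <- left + 1L
  right <- k - 1L
  while (right - (-left) + 1L < max_ext && col_ok(right + 1L))
    right <- right + 1L
  len <- right + left + 1L
  if (len < max(15L, repeat_len_range[1] - 3L)) return(NULL)
  copies <- substring(seq, pos - left, pos + right)
  cons <- consensus_string(copies)
  if (nchar(cons) > repeat_len_range[2]) {
    cons <- substr(cons, 1, repeat_len_range[2])
  }
  cons
}

#' Collect spacers from arrays
#'
#' @param arrays List of `CrisprArray`.
#' @param include_anomalous Keep anomalous (pseudo-)spacers (default FALSE).
#' @return One data frame of spacers across arrays.
#' @export
collect_spacers <- function(arrays, include_anomalous = FALSE) {
  sp <- do.call(rbind, lapply(arrays, `[[`, "spacers"))
  if (is.null(sp)) {
    return(data.frame(array_id = character(), index = integer(),
                      start = integer(), end = integer(), length = integer(),
                      sequence = character(), anomalous = logical(),
                      stringsAsFactors = FALSE))
  }
  if (!include_anomalous) sp <- sp[!sp$anomalous, , drop = FALSE]
  rownames(sp) <- NULL
  sp
}

#' Match spacers against target sequences (protospacer search)
#'
#' Scans both strands of every target, reporting every position within the
#' mismatch budget (not only the best). Matching is Hamming; the accelerated
#' fixed-pattern scan is exactly equivalent to a naive per-position scan.
#'
#' @param spacers Spacer data frame ([collect_spacers()]).
#' @param targets Named character vector / `DNAStringSet` / path to a FASTA.
#' @param max_mismatch Budget, <= 5 (default 3).
#' @return Data frame: array_id, spacer_index, spacer_length, target_id,
#'   start, end, strand, mismatches, class (`perfect`/`imperfect`).
#' @export
match_spacers <- function(spacers, targets, max_mismatch = 3L) {
  stopifnot(max_mismatch <= 5)
  targets <- load_sequences(targets)
  if (length(targets) == 0) stop("validation error: empty target set")
  out <- list()
  for (i in seq_len(nrow(spacers))) {
    sp <- spacers[i, ]
    for (tid in names(targets)) {
      h <- hamming_hits(targets[[tid]], sp$sequence, max_mismatch,
                        both_strands = TRUE)
      if (nrow(h) == 0) next
      h$array_id <- sp$array_id
      h$spacer_index <- sp$index
      h$spacer_length <- sp$length
      h$target_id <- tid
      out[[length(out) + 1L]] <- h
    }
  }
  if (length(out) == 0) {
    return(data.frame(array_id = character(), spacer_index = integer(),
                      spacer_length = integer(), target_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      mismatches = integer(), class = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$class <- ifelse(res$mismatches == 0, "perfect", "imperfect")
  res <- res[, c("array_id", "spacer_index", "spacer_length", "target_id",
                 "start", "end", "strand", "mismatches", "class")]
  res <- res[order(res$target_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Accepts a named character vector, DNAStringSet, or FASTA path; returns a
# named character vector of uppercase sequences.
load_sequences <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    ss <- Biostrings::readDNAStringSet(x)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))
    return(toupper(out))
  }
  if (methods::is(x, "DNAStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(toupper(out))
  }
  if (is.character(x)) {
    if (length(x) == 0) return(stats::setNames(character(), character()))
    if (is.null(names(x))) names(x) <- paste0("target", seq_along(x))
    return(toupper(x))
  }
  stop("cannot interpret target set")
}

#' Infer PAM matrices from protospacer flanks
#'
#' Collects the 10 nt immediately 5' and 3' of every protospacer match, on
#' the protospacer strand (minus-strand matches are reverse-complemented
#' first), builds positional base-frequency matrices and calls a consensus
#' per position: a single base when its frequency passes
#' `single_threshold`, a two-base call (e.g. `[T/A]`) when the top two pass
#' `pair_threshold` together and each exceeds 0.25, else `.`.
#'
#' @param matches Output of [match_spacers()].
#' @param targets Same target set used for matching.
#' @param flank Flank width (default 10).
#' @param single_threshold Frequency for a single-base call (default 0.7).
#' @param pair_threshold Joint frequency for a two-base call (default 0.85).
#' @return List with `five_prime` / `three_prime` matrices (rows ACGT,
#'   columns positions -10..-1 / +1..+10), `n` usable flanks each, and
#'   `consensus` character vectors.
#' @export
infer_pam <- function(matches, targets, flank = 10L,
                      single_threshold = 0.7, pair_threshold = 0.85) {
  if (nrow(matches) == 0) stop("no protospacer matches supplied")
  targets <- load_sequences(targets)
  five <- character(); three <- character()
  skipped <- 0L
  for (i in seq_len(nrow(matches))) {
    m <- matches[i, ]
    tseq <- targets[[m$target_id]]
    if (is.null(tseq)) stop("unknown target id ", m$target_id)
    if (m$strand == "+") {
      up <- c(m$start - flank, m$start - 1L)
      dn <- c(m$end + 1L, m$end + flank)
      if (up[1] < 1 || dn[2] > nchar(tseq)) { skipped <- skipped + 1L; next }
      five <- c(five, substr(tseq, up[1], up[2]))
      three <- c(three, substr(tseq, dn[1], dn[2]))
    } else {
      up <- c(m$end + 1L, m$end + flank)      # 5' flank on protospacer strand
      dn <- c(m$start - flank, m$start - 1L)
      if (dn[1] < 1 || up[2] > nchar(tseq)) { skipped <- skipped + 1L; next }
      five <- c(five, revcomp(substr(tseq, up[1], up[2])))
      three <- c(three, revcomp(substr(tseq, dn[1], dn[2])))
    }
  }
  if (skipped > 0) warning(skipped, " flank(s) truncated at target ends; skipped")
  if (length(five) == 0) stop("zero usable flanks")
  build <- function(flanks, side) {
    m <- do.call(rbind, strsplit(flanks, ""))
    freq <- apply(m, 2, function(col) {
      tb <- table(factor(col, levels = DNA_BASES))
      if (sum(tb) == 0) rep(NA_real_, 4) else as.numeric(tb) / sum(tb)
    })
    rownames(freq) <- DNA_BASES
    colnames(freq) <- if (side == "5prime") as.character(seq(-flank, -1L))
                      else paste0("+", seq_len(flank))
    freq
  }
  consensus_call <- function(freq) {
    vapply(seq_len(ncol(freq)), function(j) {
      f <- sort(freq[, j], decreasing = TRUE)
      if (f[1] >= single_threshold) return(names(f)[1])
      if (f[1] + f[2] >= pair_threshold && f[2] > 0.25) {
        return(paste0("[", names(f)[1], "/", names(f)[2], "]"))
      }
      "."
    }, "")
  }
  fp <- build(five, "5prime"); tp <- build(three, "3prime")
  list(five_prime = fp, three_prime = tp, n = length(five),
       consensus = list(five_prime = stats::setNames(consensus_call(fp),
                                                     colnames(fp)),
                        three_prime = stats::setNames(consensus_call(tp),
                                                      colnames(tp))))
}

#' Report anomalous (pseudo-)spacers
#'
#' Spacers longer than `threshold`, each with its flanking repeat copies and
#' whether both flanks are complete (mismatch-free against the array
#' consensus).
#'
#' @param arrays List of `CrisprArray`.
#' @param threshold Length threshold in bp (default 200).
#' @return Data frame: array_id, index, start, end, length, left/right
#'   repeat spans and their mismatch counts, flanks_complete.
#' @export
flag_anomalous_spacers <- function(arrays, threshold = 200L) {
  out <- list()
  for (a in arrays) {
    sp <- a$spacers
    long <- which(sp$length > threshold)
    for (i in long) {
      out[[length(out) + 1L]] <- data.frame(
        array_id = a$locus_id, index = sp$index[i], start = sp$start[i],
        end = sp$end[i], length = sp$length[i],
        left_repeat_start = a$copies$start[i],
        left_repeat_end = a$copies$end[i],
        left_repeat_mismatches = a$copies$mismatches[i],
        right_repeat_start = a$copies$start[i + 1],
        right_repeat_end = a$copies$end[i + 1],
        right_repeat_mismatches = a$copies$mismatches[i + 1],
        flanks_complete = a$copies$mismatches[i] == 0 &
          a$copies$mismatches[i + 1] == 0,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(array_id = character(), index = integer(),
                      start = integer(), end = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
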