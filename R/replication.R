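# Replication-origin prediction from cumulative nucleotide-disparity curves.
#
# The Z-curve decomposes a DNA walk into three cumulative components:
#   x_n = (A+G) - (C+T)   purine vs pyrimidine
#   y_n = (A+C) - (G+T)   amino vs keto
#   z_n = (A+T) - (G+C)   weak vs strong
# In Sulfolobales the polarity of the disparity curves flips at replication
# origins; extrema of the smoothed curves are therefore origin candidates,
# assigned to oriC labels through the nearby cdc6/whiP initiator genes. A
# second, independent signal is the cumulative forward-minus-reverse bias of
# the tetramer ACCA.

#' Cumulative disparity (Z-curve) and ACCA-bias curves
#'
#' @param genome `GenomeRecord` or DNA string.
#' @param step Sampling interval in bp (default 100).
#' @return List of class `SkewCurves`: `positions`, `x`, `y`, `z`, `acca`,
#'   `step`, `length`. Curves start at 0 (position 0).
#' @export
compute_skew_curves <- function(genome, step = 100L) {
  seq <- if (inherits(genome, "GenomeRecord")) genome$sequence else genome
  n <- nchar(seq)
  if (n == 0) stop("validation error: empty genome")
  b <- strsplit(seq, "")[[1]]
  xi <- (b == "A" | b == "G") - (b == "C" | b == "T")
  yi <- (b == "A" | b == "C") - (b == "G" | b == "T")
  zi <- (b == "A" | b == "T") - (b == "G" | b == "C")
  grid <- unique(c(seq(0L, n, by = as.integer(step)), n))
  cx <- cumsum(xi); cy <- cumsum(yi); cz <- cumsum(zi)
  at <- function(cs, i) ifelse(i == 0, 0, cs[pmax(i, 1)])
  # ACCA bias: forward ACCA minus forward TGGT (= reverse-strand ACCA)
  acca_fwd <- gregexpr("ACCA", seq, fixed = TRUE)[[1]]
  acca_rev <- gregexpr("TGGT", seq, fixed = TRUE)[[1]]
  acca_fwd <- acca_fwd[acca_fwd > 0]
  acca_rev <- acca_rev[acca_rev > 0]
  acca <- vapply(grid, function(p)
    sum(acca_fwd <= p) - sum(acca_rev <= p), 0)
  structure(list(positions = grid, x = at(cx, grid), y = at(cy, grid),
                 z = at(cz, grid), acca = acca,
                 step = as.integer(step), length = n),
            class = "SkewCurves")
}

#' Call replication origins from skew extrema
#'
#' Smooths the selected curves with a centred moving average, takes extrema
#' where the sign of the smoothed first difference flips and persists for at
#' least `persist` bp, merges calls across curves, and links each call to
#' the nearest candidate initiator gene (cdc6/whiP) within `link_cap`.
#'
#' @param curves A `SkewCurves` object.
#' @param candidate_genes Optional data frame with columns `id`, `start`,
#'   `end` of cdc6/whiP genes; may be empty.
#' @param link_cap Max distance (bp) for gene linkage (default 10000).
#' @param smooth_bp Moving-average window in bp (default 10000).
#' @param persist Minimum persistence of the new slope sign in bp (default
#'   5000).
#' @param use Curve names to scan (default `c("z", "acca")`).
#' @param merge_bp Calls closer than this across curves are merged (default
#'   5000; this only needs to unify co-located calls from different
#'   curves, and a large radius would chain distinct extrema together).
#' @return Data frame: position, curve, extremum (`min`/`max`), linked_gene,
#'   distance, label.
#' @export
call_origins <- function(curves, candidate_genes = NULL, link_cap = 10000L,
                         smooth_bp = 10000L, persist = 5000L,
                         use = c("z", "acca"), merge_bp = 5000L) {
  stopifnot(inherits(curves, "SkewCurves"))
  step <- curves$step
  k <- max(1L, round(smooth_bp / step))
  persist_pts <- max(1L, round(persist / step))
  calls <- list()
  for (cv in use) {
    vals <- curves[[cv]]
    sm <- as.numeric(stats::filter(vals, rep(1 / k, k), sides = 2))
    npts <- length(sm)
    w <- persist_pts
    hit_max <- logical(npts); hit_min <- logical(npts)
    for (i in seq_len(npts)) {
      lo <- i - w; hi <- i + w
      if (lo < 1 || hi > npts) next
      win <- sm[lo:hi]
      if (anyNA(win)) next
      if (sm[i] >= max(win) && sm[i] > sm[lo] && sm[i] > sm[hi]) {
        hit_max[i] <- TRUE
      } else if (sm[i] <= min(win) && sm[i] < sm[lo] && sm[i] < sm[hi]) {
        hit_min[i] <- TRUE
      }
    }
    for (kind in c("max", "min")) {
      hits <- which(if (kind == "max") hit_max else hit_min)
      if (length(hits) == 0) next
      grp <- cumsum(c(TRUE, diff(hits) > 1))
      centers <- vapply(split(hits, grp), function(ii)
        curves$positions[round(mean(ii))], 0)
      for (p in centers) {
        calls[[length(calls) + 1L]] <- data.frame(
          position = p, curve = cv, extremum = kind,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(calls) == 0) {
    return(data.frame(position = integer(), curve = character(),
                      extremum = character(), linked_gene = character(),
                      distance = integer(), label = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, calls)
  out <- out[order(out$position), , drop = FALSE]
  # merge nearby calls (across curves) into one, keep the first curve's call
  grp <- cumsum(c(TRUE, diff(out$position) > merge_bp))
  out <- do.call(rbind, lapply(split(out, grp), function(d) {
    d$position <- round(mean(d$position))
    d[1, , drop = FALSE]
  }))
  out$linked_gene <- NA_character_
  out$distance <- NA_integer_
  out$label <- "unassigned"
  if (!is.null(candidate_genes) && nrow(candidate_genes) > 0) {
    mid <- (candidate_genes$start + candidate_genes$end) / 2
    for (i in seq_len(nrow(out))) {
      dd <- abs(mid - out$position[i])
      j <- which.min(dd)
      if (dd[j] <= link_cap) {
        out$linked_gene[i] <- candidate_genes$id[j]
        out$distance[i] <- as.integer(round(dd[j]))
      }
    }
    linked <- which(!is.na(out$linked_gene))
    if (length(linked) > 0) {
      out$label[linked] <- paste0("oriC", seq_along(linked))
    }
  }
  rownames(out) <- NULL
  out
}

#' Map origin-associated motifs (ORB/nORB/UCM/C2/C3)
#'
#' Finds all occurrences of each consensus on both strands within its
#' mismatch budget (Hamming, no indels).
#'
#' @param genome `GenomeRecord` or DNA string.
#' @param motifs Data frame with columns `id`, `consensus`, `max_mismatch`.
#' @param origins Optional origin-call data frame; hits get a
#'   `nearest_origin` distance column when given.
#' @return Data frame: motif_id, start, end, strand, mismatches
#'   (+ nearest_origin_bp).
#' @export
map_origin_motifs <- function(genome, motifs, origins = NULL) {
  seq <- if (inherits(genome, "GenomeRecord")) genome$sequence else genome
  if (is.null(motifs) || nrow(motifs) == 0) stop("motif set is empty")
  hits <- list()
  for (i in seq_len(nrow(motifs))) {
    h <- hamming_hits(seq, motifs$consensus[i], motifs$max_mismatch[i],
                      both_strands = TRUE)
    if (nrow(h) > 0) {
      h$motif_id <- motifs$id[i]
      hits[[length(hits) + 1L]] <- h
    }
  }
  if (length(hits) == 0) {
    return(data.frame(motif_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)[, c("motif_id", "start", "end", "strand",
                                  "mismatches")]
  if (!is.null(origins) && nrow(origins) > 0) {
    out$nearest_origin_bp <- vapply(out$start, function(s)
      as.integer(min(abs(origins$position - s))), 0L)
  }
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All Hamming matches of `pattern` in `subject` within `max_mismatch`.
# Backed by Biostrings fixed-pattern matching (no indels); strand "-" rows
# report the match span on the forward coordinate system.
hamming_hits <- function(subject, pattern, max_mismatch,
                         both_strands = FALSE) {
  scan1 <- function(pat, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat),
                                  Biostrings::DNAString(subject),
                                  max.mismatch = max_mismatch,
                                  with.indels = FALSE, fixed = TRUE)
    if (length(m) == 0) {
      return(data.frame(start = integer(), end = integer(),
                        strand = character(), mismatches = integer(),
                        stringsAsFactors = FALSE))
    }
    mm <- vapply(as.character(m), function(s) {
      sum(strsplit(s, "")[[1]] != strsplit(pat, "")[[1]])
    }, 0L, USE.NAMES = FALSE)
    data.frame(start = Biostrings::start(m), end = Biostrings::end(m),
               strand = strand, mismatches = mm, stringsAsFactors = FALSE)
  }
  out <- scan1(pattern, "+")
  if (both_strands) {
    rc <- revcomp(pattern)
    if (rc != pattern) out <- rbind(out, scan1(rc, "-"))
  }
  out[order(out$start), , drop = FALSE]
}
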