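#' Genome record: sequence plus typed features of one replicon
#'
#' A `GenomeRecord` bundles a single DNA sequence (chromosome or plasmid),
#' its topology, and an ordered feature table. All coordinates are 1-based
#' inclusive, the GenBank/GFF3 convention; features crossing the circular
#' junction are stored as two spans sharing one feature `id`.
#'
#' @param id Accession or name of the replicon.
#' @param sequence DNA string over `{A,C,G,T,N}` (lowercase is normalized).
#' @param topology `"circular"` or `"linear"`.
#' @param features Data frame with columns `kind` (one of CDS, tRNA, rRNA,
#'   repeat_region, misc), `start`, `end`, `strand` (`+`/`-`), `id`, and an
#'   optional list-column `qualifiers` of named character vectors
#'   (product, translation, codon_start, ...).
#' @return An object of class `GenomeRecord`.
#' @export
genome_record <- function(id, sequence, topology = c("linear", "circular"),
                          features = empty_features()) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) stop("validation error: zero-length sequence")
  check_dna(sequence)
  features <- as_feature_table(features, nchar(sequence))
  structure(list(id = id, sequence = sequence, topology = topology,
                 features = features),
            class = "GenomeRecord")
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("GenomeRecord %s: %s bp (%s), %d features (%d CDS, %d tRNA)\n",
              x$id, format(nchar(x$sequence), big.mark = ","), x$topology,
              nrow(x$features), sum(x$features$kind == "CDS"),
              sum(x$features$kind == "tRNA")))
  invisible(x)
}

FEATURE_KINDS <- c("CDS", "tRNA", "rRNA", "repeat_region", "misc")

empty_features <- function() {
  data.frame(kind = character(), start = integer(), end = integer(),
             strand = character(), id = character(),
             stringsAsFactors = FALSE)
}

as_feature_table <- function(features, genome_len) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  need <- c("kind", "start", "end", "strand", "id")
  missing <- setdiff(need, names(features))
  if (length(missing) > 0) {
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!"qualifiers" %in% names(features)) {
    features$qualifiers <- replicate(nrow(features), character(),
                                     simplify = FALSE)
  }
  if (nrow(features) == 0) return(features)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$kind <- ifelse(features$kind %in% FEATURE_KINDS,
                          features$kind, "misc")
  bad <- which(features$start < 1 | features$end > genome_len |
                 features$start > features$end)
  if (length(bad) > 0) {
    stop(sprintf("validation error: feature '%s' has coordinates %d..%d outside [1, %d]",
                 features$id[bad[1]], features$start[bad[1]],
                 features$end[bad[1]], genome_len))
  }
  if (!all(features$strand %in% c("+", "-"))) {
    stop("validation error: feature strand must be '+' or '-'")
  }
  features[order(features$start, features$end, features$id), , drop = FALSE] |>
    (\(d) {rownames(d) <- NULL; d})()
}

#' Read a genome with annotation
#'
#' Reads FASTA (optionally with a GFF3 annotation file) or a GenBank flat
#' file into a [genome_record()]. The GenBank reader is a minimal parser for
#' LOCUS topology, CDS/tRNA/rRNA/repeat_region features (join/complement
#' locations, origin-crossing spans split at the junction) and the
#' product/translation/codon_start/locus_tag qualifiers.
#'
#' @param path Path to the sequence file.
#' @param format `"fasta"` or `"genbank"`.
#' @param annotation_path Optional GFF3 file (1-based) when `format="fasta"`.
#' @param topology Topology override for FASTA input.
#' @return A `GenomeRecord`.
#' @export
read_genome <- function(path, format = c("fasta", "genbank"),
                        annotation_path = NULL,
                        topology = c("linear", "circular")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("I/O error: cannot read ", path)
  if (format == "genbank") return(read_genbank(path))
  topology <- match.arg(topology)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("I/O error: no sequence in ", path)
  seq_id <- sub("\\s.*$", "", names(ss)[1])
  features <- empty_features()
  if (!is.null(annotation_path)) {
    gr <- rtracklayer::import(annotation_path)
    seqn <- as.character(GenomicRanges::seqnames(gr))
    if (length(gr) > 0 && !any(seqn == seq_id)) {
      stop("validation error: GFF3 sequence IDs do not match FASTA header '",
           seq_id, "'")
    }
    gr <- gr[seqn == seq_id]
    if (length(gr) > 0) {
      mc <- S4Vectors::mcols(gr)
      ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else
        paste0("feat", seq_along(gr))
      ids[is.na(ids)] <- paste0("feat", which(is.na(ids)))
      strand <- as.character(GenomicRanges::strand(gr))
      strand[strand == "*"] <- "+"
      features <- data.frame(
        kind = as.character(mc$type), start = GenomicRanges::start(gr),
        end = GenomicRanges::end(gr), strand = strand, id = ids,
        stringsAsFactors = FALSE)
    }
  }
  genome_record(seq_id, as.character(ss[[1]]), topology, features)
}

#' Write a feature table as GFF3
#'
#' @param genome A `GenomeRecord`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genome, path) {
  f <- genome$features
  gr <- GenomicRanges::GRanges(
    seqnames = genome$id,
    ranges = IRanges::IRanges(start = f$start, end = f$end),
    strand = f$strand)
  S4Vectors::mcols(gr)$type <- f$kind
  S4Vectors::mcols(gr)$ID <- f$id
  S4Vectors::mcols(gr)$source <- "plasticome"
  S4Vectors::mcols(gr)$phase <- ifelse(f$kind == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# --- minimal GenBank flat-file reader ---------------------------------------

read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)[1]
  topology <- if (grepl("circular", locus, ignore.case = TRUE))
    "circular" else "linear"
  id <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1]][1]

  ori <- grep("^ORIGIN", lines)[1]
  if (is.na(ori)) stop("I/O error: no ORIGIN section in ", path)
  seq_lines <- lines[(ori + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  fstart <- grep("^FEATURES", lines)[1]
  features <- empty_features()
  features$qualifiers <- list()
  if (!is.na(fstart)) {
    block <- lines[(fstart + 1L):(ori - 1L)]
    feats <- parse_genbank_features(block, nchar(sequence))
    features <- feats
  }
  genome_record(id, sequence, topology, features)
}

parse_genbank_features <- function(block, genome_len) {
  # feature headers start at column 6; qualifier/continuation lines at 22
  hdr <- grepl("^ {5}\\S", block)
  idx <- which(hdr)
  out <- list()
  counter <- 0L
  for (i in seq_along(idx)) {
    from <- idx[i]
    to <- if (i < length(idx)) idx[i + 1] - 1L else length(block)
    ln <- block[from:to]
    kind <- trimws(substr(ln[1], 6, 21))
    if (kind == "source") next
    body <- trimws(c(substr(ln[1], 22, nchar(ln[1])), ln[-1]))
    is_qual <- grepl("^/[A-Za-z_]+", body)
    qual_at <- which(is_qual)
    loc_lines <- if (length(qual_at) > 0) body[seq_len(qual_at[1] - 1L)] else body
    loc <- gsub("\\s", "", paste(loc_lines, collapse = ""))
    quals <- list()
    if (length(qual_at) > 0) {
      grp <- cumsum(is_qual)[qual_at[1]:length(body)]
      chunks <- split(body[qual_at[1]:length(body)], grp)
      quals <- parse_genbank_qualifiers(
        vapply(chunks, paste, "", collapse = ""))
    }
    counter <- counter + 1L
    fid <- quals[["locus_tag"]] %||% sprintf("gbfeat_%04d", counter)
    spans <- parse_genbank_location(loc, genome_len)
    if (is.null(spans)) next
    kind_std <- if (kind %in% FEATURE_KINDS) kind else "misc"
    for (s in seq_len(nrow(spans))) {
      out[[length(out) + 1L]] <- list(kind = kind_std,
                                      start = spans$start[s],
                                      end = spans$end[s],
                                      strand = spans$strand[s],
                                      id = fid, qualifiers = quals)
    }
  }
  if (length(out) == 0) return(empty_features())
  data.frame(
    kind = vapply(out, `[[`, "", "kind"),
    start = vapply(out, `[[`, 0L, "start"),
    end = vapply(out, `[[`, 0L, "end"),
    strand = vapply(out, `[[`, "", "strand"),
    id = vapply(out, `[[`, "", "id"),
    stringsAsFactors = FALSE
  ) |> (\(d) {d$qualifiers <- lapply(out, `[[`, "qualifiers"); d})()
}

parse_genbank_qualifiers <- function(parts) {
  quals <- character()
  for (p in parts) {
    kv <- regmatches(p, regexec("^/([A-Za-z_]+)=?\"?([^\"]*)\"?", p))[[1]]
    if (length(kv) == 3) quals[kv[2]] <- kv[3]
  }
  as.list(quals)
}

parse_genbank_location <- function(loc, genome_len) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  loc <- sub("^order\\((.*)\\)$", "\\1", loc)
  pieces <- strsplit(loc, ",")[[1]]
  starts <- integer(); ends <- integer()
  for (p in pieces) {
    p <- gsub("[<>]", "", p)
    m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", p))[[1]]
    if (length(m) == 3) {
      starts <- c(starts, as.integer(m[2])); ends <- c(ends, as.integer(m[3]))
    } else if (grepl("^\\d+$", p)) {
      starts <- c(starts, as.integer(p)); ends <- c(ends, as.integer(p))
    } else {
      return(NULL)   # remote/fuzzy locations are skipped
    }
  }
  data.frame(start = starts, end = ends, strand = strand,
             stringsAsFactors = FALSE)
}

# --- genome statistics ------------------------------------------------------

#' Headline genome statistics
#'
#' Computes the usual genome-table numbers: length, GC content (N excluded
#' from numerator and denominator), coding percentage (union of CDS spans),
#' CDS count and mean size, tRNA count, and the mean intergenic gap between
#' consecutive annotated features around the circle.
#'
#' @param genome A `GenomeRecord`.
#' @return A list of class `GenomeStats`.
#' @export
genome_stats <- function(genome) {
  stopifnot(inherits(genome, "GenomeRecord"))
  n <- nchar(genome$sequence)
  if (n == 0) stop("validation error: zero-length genome")
  counts <- Biostrings::alphabetFrequency(Biostrings::DNAString(genome$sequence))
  acgt <- sum(counts[DNA_BASES])
  gc <- if (acgt > 0) 100 * sum(counts[c("G", "C")]) / acgt else NA_real_

  f <- genome$features
  cds <- f[f$kind == "CDS", , drop = FALSE]
  cds_ids <- unique(cds$id)
  n_cds <- length(cds_ids)
  coding_bp <- 0L
  if (nrow(cds) > 0) {
    coding_bp <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(cds$start, cds$end))))
  }
  total_cds_bp <- sum(cds$end - cds$start + 1L)
  mean_cds <- if (n_cds > 0) round(total_cds_bp / n_cds) else NA_integer_

  mean_intergenic <- NA_integer_
  if (nrow(f) > 0) {
    red <- IRanges::reduce(IRanges::IRanges(f$start, f$end))
    st <- IRanges::start(red); en <- IRanges::end(red)
    if (length(red) >= 1) {
      gaps <- if (length(red) == 1) integer() else st[-1] - en[-length(en)] - 1L
      if (genome$topology == "circular") {
        gaps <- c(gaps, (n - en[length(en)]) + (st[1] - 1L))
      } else if (length(gaps) == 0) {
        gaps <- integer()
      }
      gaps <- gaps[gaps > 0]
      if (length(gaps) > 0) mean_intergenic <- round(mean(gaps))
    }
  }

  structure(list(
    length_bp = n,
    gc_percent = gc,
    coding_percent = 100 * coding_bp / n,
    n_cds = n_cds,
    mean_cds_bp = mean_cds,
    n_trna = length(unique(f$id[f$kind == "tRNA"])),
    mean_intergenic_bp = mean_intergenic
  ), class = "GenomeStats")
}

#' @export
print.GenomeStats <- function(x, ...) {
  cat(sprintf(paste0("GenomeStats: %s bp, GC %.1f%%, coding %.1f%%, ",
                     "%d CDS (mean %d bp), %d tRNA, mean intergenic %s bp\n"),
              format(x$length_bp, big.mark = ","), x$gc_percent,
              x$coding_percent, x$n_cds, x$mean_cds_bp, x$n_trna,
              x$mean_intergenic_bp))
  invisible(x)
}

# Extract the spliced, strand-corrected nucleotide sequence of one feature id.
feature_nt_sequence <- function(genome, fid, kind = NULL) {
  f <- genome$features
  rows <- f[f$id == fid & (is.null(kind) | f$kind == kind), , drop = FALSE]
  if (nrow(rows) == 0) stop("unknown feature id: ", fid)
  rows <- rows[order(rows$start), , drop = FALSE]
  nt <- paste(substring(genome$sequence, rows$start, rows$end), collapse = "")
  if (rows$strand[1] == "-") nt <- revcomp(nt)
  nt
}

#' Extract proteins from annotated CDS features
#'
#' One protein per CDS id. A stored `translation` qualifier wins; otherwise
#' the spliced, strand-corrected CDS is translated with the
#' bacterial/archaeal code (transl_table 11 by default), honouring
#' `codon_start`. A CDS whose length is not a codon multiple is truncated to
#' frame with a warning; internal stop codons are reported in the
#' `internal_stops` attribute, not dropped.
#'
#' @param genome A `GenomeRecord` with CDS features.
#' @param translation_table NCBI genetic code id (default 11).
#' @return Named character vector of amino-acid sequences (names = CDS ids),
#'   with attribute `internal_stops` listing ids containing internal stops.
#' @export
extract_proteins <- function(genome, translation_table = 11L) {
  f <- genome$features
  cds_ids <- unique(f$id[f$kind == "CDS"])
  if (length(cds_ids) == 0) stop("validation error: no CDS features present")
  code <- Biostrings::getGeneticCode(as.character(translation_table))
  prots <- character(length(cds_ids))
  names(prots) <- cds_ids
  internal <- character()
  for (fid in cds_ids) {
    rows <- f[f$id == fid & f$kind == "CDS", , drop = FALSE]
    q <- rows$qualifiers[[1]]
    tr <- if ("translation" %in% names(q)) q[["translation"]] else NULL
    if (!is.null(tr) && nzchar(tr)) {
      prots[fid] <- tr
      next
    }
    nt <- feature_nt_sequence(genome, fid, kind = "CDS")
    cs <- suppressWarnings(as.integer(
      if ("codon_start" %in% names(q)) q[["codon_start"]] else "1"))
    if (is.na(cs)) cs <- 1L
    if (cs > 1L) nt <- substr(nt, cs, nchar(nt))
    if (nchar(nt) %% 3 != 0) {
      warning(sprintf("CDS %s length %d not divisible by 3; truncating to frame",
                      fid, nchar(nt)))
      nt <- substr(nt, 1, nchar(nt) - nchar(nt) %% 3)
    }
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(nt), genetic.code = code,
      if.fuzzy.codon = "solve", no.init.codon = TRUE))
    aa <- sub("\\*$", "", aa)
    if (grepl("\\*", aa)) internal <- c(internal, fid)
    prots[fid] <- aa
  }
  attr(prots, "internal_stops") <- internal
  prots
}
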