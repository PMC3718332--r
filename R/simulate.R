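# Deterministic synthetic genomes with planted, truth-tracked features.
#
# The generator lays down an i.i.d. background at a target GC with a
# gene/intergenic architecture drawn from a genome-wide codon model, then
# plants CRISPR arrays (with optional kilobase pseudo-spacers), shifted
# codon-usage gene clusters, IS elements, MITEs, tRNA-integrated elements
# delimited by attachment-site direct repeats, viral/plasmid-homolog gene
# clusters, and replication-origin skew polarity switches. Every planted
# feature is recorded in a truth table, so each detector can be scored
# exactly. Everything is reproducible from a single integer seed.

# Genome-wide codon model at a target GC: codon probability proportional
# to the product of base probabilities, stop codons excluded.
make_codon_model <- function(gc, translation_table = 11L) {
  pb <- stats::setNames(c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2),
                        DNA_BASES)
  sense <- sense_codons(translation_table)
  w <- vapply(sense, function(cd) {
    prod(pb[strsplit(cd, "")[[1]]])
  }, 0)
  probs <- w / sum(w)
  code <- Biostrings::getGeneticCode(as.character(translation_table))
  aa <- code[sense]
  list(codons = sense, probs = probs, aa = aa, gc = gc)
}

# A codon model with extreme synonymous preferences: for each amino acid
# all mass goes to its (globally) least-preferred codon. Used to plant
# clusters of atypical genes with a large, tunable chi-square distance.
shift_codon_model <- function(model, magnitude = 1) {
  probs <- model$probs
  for (a in unique(model$aa)) {
    idx <- which(model$aa == a)
    if (length(idx) < 2) next
    target <- idx[which.min(model$probs[idx])]
    mass <- sum(model$probs[idx])
    p <- model$probs[idx] * (1 - magnitude)
    p[idx == target] <- p[idx == target] + mass * magnitude
    probs[idx] <- p * (mass / sum(p))
  }
  model$probs <- probs / sum(probs)
  model
}

random_dna <- function(n, gc) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_gene <- function(n_codons, model) {
  body <- sample(model$codons, n_codons, replace = TRUE, prob = model$probs)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

# Re-encode a coding sequence under another synonymous-preference model,
# preserving the protein exactly.
reencode_gene <- function(nt, model) {
  nt <- substr(nt, 1, nchar(nt) - nchar(nt) %% 3)
  cs <- seq.int(1L, nchar(nt) - 2L, by = 3L)
  cods <- substring(nt, cs, cs + 2L)
  out <- vapply(cods, function(cd) {
    i <- match(cd, model$codons)
    if (is.na(i)) return(cd)           # stop or N-containing codon
    syn <- which(model$aa == model$aa[i])
    p <- model$probs[syn]
    model$codons[syn[sample.int(length(syn), 1L, prob = p / sum(p))]]
  }, "", USE.NAMES = FALSE)
  paste(out, collapse = "")
}

#' Generate an i.i.d. background genome with gene architecture
#'
#' Bases are i.i.d. at the target GC; protein-coding genes alternate with
#' intergenic gaps, gene bodies drawn from a genome-wide codon model
#' consistent with the GC target.
#'
#' @param length Target genome length (>= 10000).
#' @param gc GC fraction in (0, 1).
#' @param seed Integer seed (mandatory).
#' @param mean_cds_bp Mean CDS length (default 800).
#' @param mean_intergenic_bp Mean intergenic gap (default 190).
#' @param topology Genome topology (default circular).
#' @return A `GenomeRecord` with CDS features; the codon model is attached
#'   as attribute `codon_model`.
#' @export
generate_background <- function(length, gc, seed, mean_cds_bp = 800L,
                                mean_intergenic_bp = 190L,
                                topology = "circular") {
  if (length < 10000) stop("validation error: length must be >= 10000")
  if (gc <= 0 || gc >= 1) stop("validation error: gc must be in (0,1)")
  set.seed(as.integer(seed))
  model <- make_codon_model(gc)
  parts <- character(); feats <- list()
  pos <- 1L; gi <- 0L
  while (pos < length) {
    ig <- max(30L, stats::rpois(1, mean_intergenic_bp))
    parts[[length(parts) + 1L]] <- random_dna(ig, gc)
    pos <- pos + ig
    if (pos >= length) break
    nc <- max(40L, stats::rpois(1, round((mean_cds_bp - 6) / 3)))
    gseq <- random_gene(nc, model)
    gl <- nchar(gseq)
    if (pos + gl > length) {
      parts[[length(parts) + 1L]] <- random_dna(length - pos + 1L, gc)
      pos <- length + 1L
      break
    }
    strand <- if (stats::runif(1) < 0.7) "+" else "-"
    gi <- gi + 1L
    feats[[gi]] <- data.frame(
      kind = "CDS", start = pos, end = pos + gl - 1L, strand = strand,
      id = sprintf("g%04d", gi), stringsAsFactors = FALSE)
    parts[[length(parts) + 1L]] <- if (strand == "+") gseq else revcomp(gseq)
    pos <- pos + gl
  }
  seq <- paste(parts, collapse = "")
  g <- genome_record("simgenome", seq, topology,
                     do.call(rbind, feats))
  attr(g, "codon_model") <- model
  g
}

#' Default simulation plan mirroring the study architecture
#'
#' The reference scenario plants, on a 300 kb background at GC 0.35:
#' five CRISPR arrays totalling 285 spacers (two family-I arrays sharing a
#' 24 bp repeat, one carrying a 1.9 kb pseudo-spacer; three family-III
#' arrays), three shifted-codon-usage clusters of 26/10/7 genes, four
#' viral/plasmid-homolog gene clusters, two tRNA-integrated elements with
#' 22 bp attachment duplications, three IS copies (intact / truncated /
#' ITR-destroyed) plus MITEs of two classes, and three origin skew
#' switches.
#'
#' @return A plan list for [plant_features()].
#' @export
reference_plan <- function() {
  repI <- "GCTAATCTACTATAGAATTGAAAG"
  repIII <- "GTAACAACACAAAGAAACTAAAAC"
  list(
    crispr = list(
      list(pos = 30000, repeat_seq = repI, n_spacers = 86),
      list(pos = 50000, repeat_seq = repI, n_spacers = 113,
           pseudo_spacer = 1900L, pseudo_index = 40L),
      list(pos = 80000, repeat_seq = repIII, n_spacers = 31),
      list(pos = 90000, repeat_seq = repIII, n_spacers = 25),
      list(pos = 100000, repeat_seq = repIII, n_spacers = 30)),
    # clusters of database-matched genes are kept > 20 kb apart so the
    # default homolog-window scan cannot bridge two planted elements
    homolog_elements = list(
      list(pos = 120000, n_genes = 6, class = "virus"),
      list(pos = 180000, n_genes = 8, class = "plasmid"),
      list(pos = 240000, n_genes = 10, class = "virus"),
      list(pos = 285000, n_genes = 13, class = "plasmid")),
    trna_elements = list(
      list(pos = 150000, att_len = 22L, n_genes = 3, element_len = 6000L),
      list(pos = 210000, att_len = 22L, n_genes = 2, element_len = 4000L)),
    is_elements = list(
      list(pos = 106000, family = "ISC1058like", length = 1200L,
           itr_len = 25L, status = "intact"),
      list(pos = 108500, family = "ISC1058like", length = 1200L,
           itr_len = 25L, status = "truncated"),
      list(pos = 262000, family = "ISC1225like", length = 1100L,
           itr_len = 22L, status = "truncated")),
    mites = list(
      list(pos = 111000, class = "SM3Alike", length = 164L, identity = 0.95),
      list(pos = 113000, class = "SM3Alike", length = 164L, identity = 0.95),
      list(pos = 115000, class = "SM3Alike", length = 164L, identity = 1.0),
      list(pos = 117000, class = "SMN1like", length = 320L, identity = 1.0)),
    # CAG gene runs sit in stretches free of inserted CDS clusters (so the
    # planted genes stay consecutive in overall gene order) and well away
    # from planted origins, whose skew extrema a 10-30 kb block of
    # composition-shifted genes would otherwise mask
    cags = list(
      list(pos = 296000, n_genes = 26),
      list(pos = 160000, n_genes = 10),
      list(pos = 222000, n_genes = 7)),
    origins = list(positions = c(20000, 140000, 260000), amplitude = 0.9,
                   acca_rate = 0.04)
  )
}

#' Plant features into a background genome
#'
#' Executes a plan (see [reference_plan()]) on a [generate_background()]
#' genome. Insertions are placed in the intergenic gap nearest the
#' requested position; codon-usage clusters re-encode existing background
#' genes in place; origin skew switches post-process intergenic bases
#' only. Every planted feature is recorded in the returned truth table.
#'
#' @param genome Background `GenomeRecord` (with `codon_model` attribute).
#' @param plan Plan list; any component may be absent.
#' @param seed Integer seed (mandatory).
#' @return List: `genome` (with planted features), `truth` (list of truth
#'   records), `mge_db` (labelled protein database covering the planted
#'   homolog genes), `is_library`, `mite_consensi`, `origin_genes`
#'   (candidate initiator-gene table).
#' @export
plant_features <- function(genome, plan = reference_plan(), seed) {
  set.seed(derive_seed(seed, 1L))
  model <- attr(genome, "codon_model")
  if (is.null(model)) model <- make_codon_model(0.35)
  gc <- model$gc
  state <- list(seq = genome$sequence, features = genome$features,
                claimed = NULL)
  truth <- list()
  mge_db <- list()
  is_library <- list()
  mite_consensi <- list()

  # ---- build insertion payloads (ordered by requested position) -----------
  ins_specs <- list()
  add_ins <- function(pos, seq, feats, truth_entry) {
    ins_specs[[length(ins_specs) + 1L]] <<- list(
      pos = pos, seq = seq, feats = feats, truth = truth_entry)
  }

  for (cr in plan$crispr %||% list()) {
    built <- build_crispr_insert(cr, gc)
    add_ins(cr$pos, built$seq, built$feats, built$truth)
  }
  hid <- 0L
  for (he in plan$homolog_elements %||% list()) {
    hid <- hid + 1L
    built <- build_gene_cluster(he$n_genes, model, gc,
                                prefix = sprintf("mge%d", hid))
    for (k in seq_along(built$proteins)) {
      mge_db[[length(mge_db) + 1L]] <- data.frame(
        id = sprintf("db_%s_%s", he$class, names(built$proteins)[k]),
        class = he$class, sequence = built$proteins[[k]],
        stringsAsFactors = FALSE)
    }
    add_ins(he$pos, built$seq, built$feats,
            list(type = "homolog_element", class = he$class,
                 genes = built$feats$id, n_genes = he$n_genes))
  }
  tid <- 0L
  for (te in plan$trna_elements %||% list()) {
    tid <- tid + 1L
    built <- build_trna_element(te, model, gc, sprintf("tel%d", tid))
    for (k in seq_along(built$proteins)) {
      mge_db[[length(mge_db) + 1L]] <- data.frame(
        id = sprintf("db_virus_%s", names(built$proteins)[k]),
        class = "virus", sequence = built$proteins[[k]],
        stringsAsFactors = FALSE)
    }
    add_ins(te$pos, built$seq, built$feats, built$truth)
  }
  fam_cons <- list()
  for (ie in plan$is_elements %||% list()) {
    if (is.null(fam_cons[[ie$family]])) {
      fam_cons[[ie$family]] <- build_is_consensus(ie, gc, model)
      is_library[[ie$family]] <- data.frame(
        family = ie$family, sequence = fam_cons[[ie$family]]$seq,
        ref_len = fam_cons[[ie$family]]$orf_len, stringsAsFactors = FALSE)
    }
    built <- build_is_copy(fam_cons[[ie$family]], ie)
    add_ins(ie$pos, built$seq, NULL, built$truth)
  }
  for (mi in plan$mites %||% list()) {
    if (is.null(mite_consensi[[mi$class]])) {
      mite_consensi[[mi$class]] <- build_mite_consensus(mi$class, mi$length, gc)
    }
    built <- build_mite_copy(mite_consensi[[mi$class]], mi, gc)
    add_ins(mi$pos, built$seq, NULL, built$truth)
  }

  # ---- apply insertions ascending, tracking realized coordinates ----------
  ord <- order(vapply(ins_specs, `[[`, 0, "pos"))
  for (sp in ins_specs[ord]) {
    state <- insert_payload(state, sp)
    truth[[length(truth) + 1L]] <- state$last_truth
  }

  # ---- CAG re-encoding (in place) -----------------------------------------
  shifted <- shift_codon_model(model, magnitude = 0.95)
  cid <- 0L
  for (cg in plan$cags %||% list()) {
    cid <- cid + 1L
    res <- plant_cag(state, cg, shifted, sprintf("CAGT%d", cid))
    state <- res$state
    truth[[length(truth) + 1L]] <- res$truth
  }

  # ---- origin skew polarity (intergenic bases only) -----------------------
  origin_genes <- NULL
  if (!is.null(plan$origins)) {
    res <- plant_origin_skew(state, plan$origins, gc)
    state <- res$state
    truth[[length(truth) + 1L]] <- res$truth
    origin_genes <- res$origin_genes
  }

  out_genome <- genome_record(genome$id, state$seq, genome$topology,
                              state$features)
  attr(out_genome, "codon_model") <- model
  list(genome = out_genome, truth = truth,
       mge_db = if (length(mge_db) > 0) do.call(rbind, mge_db) else NULL,
       is_library = if (length(is_library) > 0)
         do.call(rbind, is_library) else NULL,
       mite_consensi = if (length(mite_consensi) > 0)
         data.frame(class = names(mite_consensi),
                    sequence = unlist(mite_consensi),
                    stringsAsFactors = FALSE) else NULL,
       origin_genes = origin_genes)
}

# Insert one payload into the nearest intergenic gap >= its requested pos.
insert_payload <- function(state, sp) {
  f <- state$features
  n <- nchar(state$seq)
  # gap positions: after each feature end, before next feature start
  bounds <- sort(unique(c(1L, f$end + 1L)))
  occupied <- function(p) any(f$start <= p & f$end >= p)
  p <- NA_integer_
  cand <- bounds[bounds >= 1 & bounds <= n]
  cand <- cand[order(abs(cand - sp$pos))]
  for (b in cand) if (!occupied(b)) { p <- b; break }
  if (is.na(p)) stop("no intergenic insertion point available")
  L <- nchar(sp$seq)
  state$seq <- paste0(substr(state$seq, 1L, p - 1L), sp$seq,
                      substr(state$seq, p, n))
  shift <- f$start >= p
  f$start[shift] <- f$start[shift] + L
  f$end[shift] <- f$end[shift] + L
  if (!is.null(sp$feats)) {
    nf <- sp$feats[, c("kind", "start", "end", "strand", "id")]
    nf$start <- nf$start + p - 1L
    nf$end <- nf$end + p - 1L
    nf$qualifiers <- replicate(nrow(nf), character(), simplify = FALSE)
    f <- rbind(f[, c("kind", "start", "end", "strand", "id", "qualifiers")],
               nf)
  }
  state$features <- f[order(f$start, f$end), , drop = FALSE]
  # planted spans already placed lie left of p (ascending order) and are
  # unaffected by the shift
  state$claimed <- rbind(state$claimed, c(p, p + L - 1L))
  tr <- sp$truth
  tr$start <- p
  tr$end <- p + L - 1L
  if (!is.null(tr$rel)) {   # relative coordinate sub-records
    for (nm in names(tr$rel)) tr[[nm]] <- tr$rel[[nm]] + p - 1L
    tr$rel <- NULL
  }
  state$last_truth <- tr
  state
}

build_crispr_insert <- function(cr, gc, spacer_len_range = c(35L, 45L)) {
  n_sp <- cr$n_spacers
  rep_seq <- cr$repeat_seq
  spacer_lens <- sample(seq(spacer_len_range[1], spacer_len_range[2]),
                        n_sp, replace = TRUE)
  pseudo_at <- cr$pseudo_index %||% NA_integer_
  if (!is.na(pseudo_at)) spacer_lens[pseudo_at] <- cr$pseudo_spacer
  parts <- character(); at <- 0L
  copy_starts <- integer(); spacer_starts <- integer()
  for (i in seq_len(n_sp + 1L)) {
    copy_starts <- c(copy_starts, at + 1L)
    parts <- c(parts, rep_seq)
    at <- at + nchar(rep_seq)
    if (i <= n_sp) {
      spacer_starts <- c(spacer_starts, at + 1L)
      parts <- c(parts, random_dna(spacer_lens[i], gc))
      at <- at + spacer_lens[i]
    }
  }
  list(seq = paste(parts, collapse = ""), feats = NULL,
       truth = list(type = "crispr", repeat_seq = rep_seq,
                    n_spacers = n_sp, spacer_lengths = spacer_lens,
                    pseudo_spacer = cr$pseudo_spacer %||% NA_integer_,
                    pseudo_index = pseudo_at,
                    rel = list(copy_starts = copy_starts,
                               spacer_starts = spacer_starts)))
}

build_gene_cluster <- function(n_genes, model, gc, prefix) {
  parts <- character(); feats <- list(); prots <- list()
  at <- 0L
  for (k in seq_len(n_genes)) {
    ig <- random_dna(60L, gc)
    parts <- c(parts, ig); at <- at + 60L
    nc <- max(40L, stats::rpois(1, 150))
    gseq <- random_gene(nc, model)
    id <- sprintf("%s_g%02d", prefix, k)
    feats[[k]] <- data.frame(kind = "CDS", start = at + 1L,
                             end = at + nchar(gseq), strand = "+",
                             id = id, stringsAsFactors = FALSE)
    prots[[id]] <- as.character(Biostrings::translate(
      Biostrings::DNAString(gseq),
      genetic.code = Biostrings::getGeneticCode("11"),
      no.init.codon = TRUE)) |> sub(pattern = "\\*$", replacement = "")
    parts <- c(parts, gseq); at <- at + nchar(gseq)
  }
  parts <- c(parts, random_dna(60L, gc))
  list(seq = paste(parts, collapse = ""), feats = do.call(rbind, feats),
       proteins = prots)
}

build_trna_element <- function(te, model, gc, prefix) {
  att_len <- te$att_len
  trna_len <- 75L
  trna_seq <- random_dna(trna_len, gc)
  att <- substr(trna_seq, trna_len - att_len + 1L, trna_len)
  cluster <- build_gene_cluster(te$n_genes, model, gc, prefix)
  pad <- max(0L, te$element_len - nchar(cluster$seq) - att_len)
  interior <- paste0(cluster$seq, random_dna(pad, gc))
  # the base just before the distal att copy must differ from the base
  # just before the tRNA-borne copy, so the realized duplication length
  # equals att_len exactly
  guard <- substr(trna_seq, trna_len - att_len, trna_len - att_len)
  if (substr(interior, nchar(interior), nchar(interior)) == guard) {
    interior <- paste0(substr(interior, 1, nchar(interior) - 1L),
                       setdiff(DNA_BASES, guard)[1])
  }
  seq <- paste0(trna_seq, interior, att)
  feats <- rbind(
    data.frame(kind = "tRNA", start = 1L, end = trna_len, strand = "+",
               id = paste0(prefix, "_trna"), stringsAsFactors = FALSE),
    within(cluster$feats, {start <- start + trna_len; end <- end + trna_len}))
  list(seq = seq, feats = feats[, c("kind", "start", "end", "strand", "id")],
       proteins = cluster$proteins,
       truth = list(type = "trna_element", att_len = att_len,
                    trna_id = paste0(prefix, "_trna"),
                    genes = cluster$feats$id,
                    rel = list(attL_start = trna_len - att_len + 1L,
                               attL_end = trna_len,
                               attR_start = nchar(seq) - att_len + 1L,
                               attR_end = nchar(seq))))
}

build_is_consensus <- function(ie, gc, model) {
  itr <- random_dna(ie$itr_len, gc)
  n_cod <- max(60L, (ie$length - 2L * ie$itr_len - 60L) %/% 3L - 2L)
  orf <- random_gene(n_cod, model)
  pad <- ie$length - 2L * ie$itr_len - nchar(orf)
  pad_l <- max(0L, pad %/% 2L); pad_r <- max(0L, pad - pad_l)
  seq <- paste0(itr, random_dna(pad_l, gc), orf, random_dna(pad_r, gc),
                revcomp(itr))
  list(seq = seq, orf_len = nchar(orf), itr = itr,
       orf_at = ie$itr_len + pad_l + 1L)
}

build_is_copy <- function(cons, ie) {
  seq <- cons$seq
  status <- ie$status
  if (status == "truncated") {
    # delete the middle 60% of the transposase ORF
    del_from <- cons$orf_at + round(0.2 * cons$orf_len)
    del_to <- cons$orf_at + round(0.8 * cons$orf_len)
    seq <- paste0(substr(seq, 1, del_from - 1L),
                  substr(seq, del_to + 1L, nchar(seq)))
  } else if (status == "no_itr") {
    n <- nchar(seq)
    seq <- paste0(substr(seq, 1, n - nchar(cons$itr)),
                  sample_scramble(cons$itr))
  }
  list(seq = seq, truth = list(type = "is_element", family = ie$family,
                               status = status, itr_len = nchar(cons$itr)))
}

sample_scramble <- function(x) {
  paste(sample(strsplit(x, "")[[1]]), collapse = "")
}

build_mite_consensus <- function(class, len, gc, tir_len = 15L,
                                 max_orf = 240L) {
  repeat {
    tir <- random_dna(tir_len, gc)
    body <- random_dna(len - 2L * tir_len, gc)
    seq <- paste0(tir, body, revcomp(tir))
    if (longest_orf(seq) < max_orf) return(seq)
  }
}

build_mite_copy <- function(cons, mi, gc, tsd_len = 5L) {
  seq <- cons
  if (mi$identity < 1) {
    b <- strsplit(seq, "")[[1]]
    n_mut <- round((1 - mi$identity) * length(b))
    # keep terminal inverted repeats untouched so structure survives
    interior <- 16:(length(b) - 16L)
    at <- sample(interior, n_mut)
    b[at] <- vapply(b[at], function(x)
      sample(setdiff(DNA_BASES, x), 1), "")
    seq <- paste(b, collapse = "")
  }
  tsd <- random_dna(tsd_len, gc)
  list(seq = paste0(tsd, seq, tsd),
       truth = list(type = "mite", class = mi$class,
                    identity = mi$identity, tsd = tsd,
                    length = nchar(seq),
                    rel = list(element_start = tsd_len + 1L,
                               element_end = tsd_len + nchar(seq))))
}

plant_cag <- function(state, cg, shifted_model, cag_id) {
  f <- state$features
  bg <- f[f$kind == "CDS" & grepl("^g\\d+$", f$id), , drop = FALSE]
  bg <- bg[order(bg$start), , drop = FALSE]
  i0 <- which.min(abs(bg$start - cg$pos))
  if (i0 + cg$n_genes - 1L > nrow(bg)) i0 <- nrow(bg) - cg$n_genes + 1L
  rows <- bg[i0:(i0 + cg$n_genes - 1L), , drop = FALSE]
  seq <- state$seq
  for (r in seq_len(nrow(rows))) {
    nt <- substr(seq, rows$start[r], rows$end[r])
    fwd <- if (rows$strand[r] == "+") nt else revcomp(nt)
    re <- reencode_gene(fwd, shifted_model)
    if (rows$strand[r] == "-") re <- revcomp(re)
    stopifnot(nchar(re) == nchar(nt))
    seq <- paste0(substr(seq, 1, rows$start[r] - 1L), re,
                  substr(seq, rows$end[r] + 1L, nchar(seq)))
  }
  state$seq <- seq
  list(state = state,
       truth = list(type = "cag", cag_id = cag_id, genes = rows$id,
                    n_genes = cg$n_genes, start = min(rows$start),
                    end = max(rows$end)))
}

# Impose skew polarity switches at planted origins on intergenic bases:
# between an origin and the next terminus (midpoint to the next origin),
# C is converted to G and A to T with probability `amplitude` ("+"
# polarity) and the reverse in "-" regions, giving the amino-keto (y)
# disparity a maximum at each origin that dominates the residual
# composition trends of gene blocks; the ACCA bias is planted the same way
# with extra ACCA/TGGT words at `acca_rate` per intergenic base.
plant_origin_skew <- function(state, org, gc) {
  seq_b <- strsplit(state$seq, "")[[1]]
  n <- length(seq_b)
  pos <- sort(org$positions)
  amp <- org$amplitude %||% 0.5
  acca_rate <- org$acca_rate %||% 0.02
  f <- state$features
  inter <- rep(TRUE, n)
  for (i in seq_len(nrow(f))) inter[f$start[i]:f$end[i]] <- FALSE
  if (!is.null(state$claimed)) {
    for (i in seq_len(nrow(state$claimed))) {
      inter[state$claimed[i, 1]:state$claimed[i, 2]] <- FALSE
    }
  }
  # polarity: +1 just right of an origin, flipping at midpoints (termini)
  term <- (pos + c(diff(pos), n - pos[length(pos)] + pos[1]) / 2) %% n
  cuts <- sort(c(pos, round(term)))
  k <- findInterval(seq_len(n), cuts)
  k[k == 0] <- length(cuts)             # wrap: before the first cut
  polarity <- ifelse(cuts[k] %in% pos, 1, -1)
  conv <- stats::runif(n) < amp & inter
  plus <- polarity > 0
  cg <- conv & plus & seq_b == "C"
  gc_ <- conv & !plus & seq_b == "G"
  at <- conv & plus & seq_b == "A"
  ta <- conv & !plus & seq_b == "T"
  seq_b[cg] <- "G"; seq_b[gc_] <- "C"
  seq_b[at] <- "T"; seq_b[ta] <- "A"
  # plant ACCA (plus regions) / TGGT (minus regions) words
  slots <- which(inter & seq_len(n) %% 25 == 0 & seq_len(n) < n - 4L)
  slots <- slots[stats::runif(length(slots)) < acca_rate * 25]
  for (s in slots) {
    if (!all(inter[s:(s + 3L)])) next
    seq_b[s:(s + 3L)] <- strsplit(if (polarity[s] > 0) "ACCA" else "TGGT",
                                  "")[[1]]
  }
  state$seq <- paste(seq_b, collapse = "")
  # nearest background gene to each origin becomes the initiator candidate
  cds <- f[f$kind == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) {
    state$seq <- paste(seq_b, collapse = "")
    return(list(state = state,
                truth = list(type = "origins", positions = pos,
                             amplitude = amp),
                origin_genes = NULL))
  }
  og <- do.call(rbind, lapply(seq_along(pos), function(k) {
    j <- which.min(abs((cds$start + cds$end) / 2 - pos[k]))
    data.frame(id = cds$id[j], start = cds$start[j], end = cds$end[j],
               origin = pos[k], stringsAsFactors = FALSE)
  }))
  list(state = state,
       truth = list(type = "origins", positions = pos, amplitude = amp),
       origin_genes = og)
}

#' Evolve strains along a tree under a molecular clock
#'
#' Independent point substitutions per branch with expected density
#' `mu * years` per site (Jukes-Cantor kernel: the substituted base is
#' uniform over the other three). Substitution-only, so coordinates and
#' annotation are preserved on every leaf.
#'
#' @param genome Root `GenomeRecord`.
#' @param tree An [ape::phylo] tree (or newick string) with branch lengths
#'   in years; leaves >= 2.
#' @param mu Clock rate (default [HYPERTHERMOPHILE_CLOCK_RATE]).
#' @param seed Integer seed.
#' @return List: `genomes` (named list of `GenomeRecord`), `expected_d`
#'   (matrix of expected pairwise divergence `mu * path-years`),
#'   `realized_d` (observed raw divergence matrix).
#' @export
evolve_strains <- function(genome, tree, mu = HYPERTHERMOPHILE_CLOCK_RATE,
                           seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (ape::Ntip(tree) < 2) stop("validation error: tree needs >= 2 leaves")
  if (any(tree$edge.length < 0)) {
    stop("validation error: negative branch length")
  }
  set.seed(derive_seed(seed, 7L))
  n <- nchar(genome$sequence)
  root_b <- strsplit(genome$sequence, "")[[1]]
  nnode <- ape::Ntip(tree) + tree$Nnode
  seqs <- vector("list", nnode)
  root <- ape::Ntip(tree) + 1L
  seqs[[root]] <- root_b
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    yrs <- ord$edge.length[e]
    b <- seqs[[parent]]
    p_sub <- min(0.75, mu * yrs)
    k <- stats::rbinom(1, n, p_sub)
    if (k > 0) {
      at <- sample.int(n, k)
      b[at] <- vapply(b[at], function(x)
        sample(setdiff(DNA_BASES, x), 1), "", USE.NAMES = FALSE)
    }
    seqs[[child]] <- b
  }
  tips <- tree$tip.label
  genomes <- stats::setNames(lapply(seq_along(tips), function(i) {
    g <- genome_record(tips[i], paste(seqs[[i]], collapse = ""),
                       genome$topology, genome$features)
    attr(g, "codon_model") <- attr(genome, "codon_model")
    g
  }), tips)
  pd <- ape::cophenetic.phylo(tree)[tips, tips]
  expected_d <- mu * pd
  realized_d <- matrix(0, length(tips), length(tips),
                       dimnames = list(tips, tips))
  for (i in seq_along(tips)) for (j in seq_along(tips)) {
    if (j <= i) next
    realized_d[i, j] <- realized_d[j, i] <-
      mean(seqs[[i]] != seqs[[j]])
  }
  list(genomes = genomes, expected_d = expected_d, realized_d = realized_d)
}

#' Write a simulated dataset to disk
#'
#' FASTA + GFF3 per genome, truth JSON and a plan echo; re-reading with
#' [read_genome()] reproduces the in-memory records.
#'
#' @param genomes Named list of `GenomeRecord`.
#' @param truth Truth list from [plant_features()] (may be `NULL`).
#' @param outdir Output directory (created).
#' @param plan Optional plan echo.
#' @return Invisibly, the vector of written paths.
#' @export
emit_dataset <- function(genomes, truth, outdir, plan = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(genomes)) {
    g <- genomes[[nm]]
    fa <- file.path(outdir, paste0(nm, ".fasta"))
    ss <- Biostrings::DNAStringSet(stats::setNames(g$sequence, g$id))
    Biostrings::writeXStringSet(ss, fa, width = 80L)
    gff <- file.path(outdir, paste0(nm, ".gff3"))
    write_gff3(g, gff)
    paths <- c(paths, fa, gff)
  }
  if (!is.null(truth)) {
    tj <- file.path(outdir, "truth.json")
    jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, tj)
  }
  if (!is.null(plan)) {
    pj <- file.path(outdir, "plan.json")
    jsonlite::write_json(plan, pj, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, pj)
  }
  invisible(paths)
}

#' Run the shipped reference scenario
#'
#' Background of 300 kb at GC 0.35 with the [reference_plan()] features.
#' This is the package's core regression scenario: every detector must
#' recover its planted features at default parameters.
#'
#' @param seed Integer seed.
#' @param length Background length (default 300000).
#' @param gc GC fraction (default 0.35).
#' @return The [plant_features()] result list.
#' @export
simulate_reference <- function(seed, length = 300000L, gc = 0.35) {
  bg <- generate_background(length, gc, seed = derive_seed(seed, 11L))
  plant_features(bg, reference_plan(), seed = derive_seed(seed, 13L))
}
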