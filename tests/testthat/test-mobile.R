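# Mobile-element detectors: homolog windows, tRNA att scan, CAGs, IS, MITEs.

test_that("MGE homolog annotation hits planted proteins, not shuffled ones", {
  p <- rand_protein(150, 301)
  db <- data.frame(id = "v1", class = "virus", sequence = p,
                   stringsAsFactors = FALSE)
  ann <- annotate_mge_homologs(c(geneA = p), db)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$identity, 100)
  expect_equal(ann$class, "virus")
  # shuffled database: no annotation at defaults
  set.seed(302)
  shuf <- paste(sample(strsplit(p, "")[[1]]), collapse = "")
  ann0 <- annotate_mge_homologs(c(geneA = p),
                                data.frame(id = "v1", class = "virus",
                                           sequence = shuf))
  expect_equal(nrow(ann0), 0)
  expect_error(annotate_mge_homologs(c(geneA = p),
                                     data.frame(id = "v1",
                                                class = NA_character_,
                                                sequence = p)),
               "unlabeled")
})

# A feature-table-only genome: hit positions are what matters, so the
# annotation table is constructed directly rather than via alignment.
window_fixture <- function(gene_starts, hit_idx, L = 60000) {
  feats <- data.frame(kind = "CDS", start = gene_starts,
                      end = gene_starts + 599L, strand = "+",
                      id = sprintf("g%03d", seq_along(gene_starts)))
  g <- genome_record("w", rand_dna(L, 303), "circular", feats)
  ann <- data.frame(gene = feats$id[hit_idx], subject = "v", class = "virus",
                    identity = 100, coverage = 1, score = 500,
                    stringsAsFactors = FALSE)
  list(genome = g, ann = ann)
}

test_that("gene-anchored window scan equals the per-bp oracle", {
  fx <- window_fixture(gene_starts = seq(1000, 59000, by = 1200),
                       hit_idx = c(3:8, 25:30, 44))
  got <- scan_homolog_windows(fx$ann, fx$genome, window_bp = 8000,
                              min_hits = 5)
  expect_equal(nrow(got), 2)
  oracle_ids <- {
    f <- fx$genome$features
    hits <- f[f$id %in% fx$ann$gene, ]
    s <- hits$start
    keep <- list()
    for (x in seq_len(60000 - 1)) {
      inw <- which(s >= x & s <= x + 7999)
      if (length(inw) >= 5) keep[[length(keep) + 1L]] <- c(x, x + 7999)
    }
    w <- do.call(rbind, keep)
    grp <- cumsum(c(TRUE, w[-1, 1] > cummax(w[-nrow(w), 2])[
      seq_len(nrow(w) - 1)]))
    lapply(split(seq_len(nrow(w)), grp), function(ii) {
      lo <- min(w[ii, 1]); hi <- max(w[ii, 2])
      sort(hits$id[hits$start >= lo & hits$start <= hi])
    })
  }
  got_ids <- lapply(strsplit(got$genes, ","), sort)
  expect_equal(unname(got_ids), unname(oracle_ids))
})

test_that("window scan respects density thresholds and degeneracies", {
  # hits every ~12 kb: nothing at min 5 per 20 kb
  fx <- window_fixture(gene_starts = seq(1000, 59000, by = 1200),
                       hit_idx = seq(1, 48, by = 10))
  expect_equal(nrow(scan_homolog_windows(fx$ann, fx$genome)), 0)
  # min_hits 1: every annotated gene seeds a candidate; merged count equals
  # the number of hit clusters separated by > window
  got <- scan_homolog_windows(fx$ann, fx$genome, window_bp = 2000,
                              min_hits = 1)
  expect_equal(nrow(got), length(seq(1, 48, by = 10)))
})

trna_fixture <- function(att_len = 22, ident = 1, seed = 310,
                         with_element = TRUE) {
  set.seed(seed)
  trna <- rand_dna(75, seed + 1)
  att <- substr(trna, 75 - att_len + 1, 75)
  attR <- if (ident < 1) {
    n_mut <- round((1 - ident) * att_len)
    mutate_dna(att, round(seq(2, att_len - 1, length.out = n_mut)),
               seed = seed + 2)
  } else att
  interior <- rand_dna(3000, seed + 3)
  # guard the boundary bases so the realized duplication is exactly att_len
  pre <- substr(trna, 75 - att_len, 75 - att_len)
  if (substr(interior, 3000, 3000) == pre) {
    interior <- paste0(substr(interior, 1, 2999),
                       setdiff(c("A", "C", "G", "T"), pre)[1])
  }
  body <- if (with_element) paste0(trna, interior, attR)
          else paste0(trna, interior)
  seqs <- paste0(rand_dna(2000, seed + 4), body, rand_dna(3000, seed + 5))
  feats <- data.frame(kind = "tRNA", start = 2001, end = 2075, strand = "+",
                      id = "trnaX")
  genome_record("t", seqs, "linear", feats)
}

test_that("tRNA att scan recovers an exact planted duplication", {
  g <- trna_fixture()
  res <- trna_integration_scan(g)
  expect_equal(nrow(res), 1)
  expect_equal(res$att_length, 22)
  expect_equal(res$att_identity, 1)
  expect_equal(res$start, 2075 - 22 + 1)
  expect_equal(res$end, 2075 + 3000 + 22)
  # no distal copy: no candidate
  g0 <- trna_fixture(with_element = FALSE, seed = 311)
  expect_equal(nrow(trna_integration_scan(g0)), 0)
  expect_error(trna_integration_scan(genome_record("x", rand_dna(1000, 1))),
               "no tRNA")
})

test_that("att identity floor separates degraded duplications", {
  g <- trna_fixture(att_len = 30, ident = 0.7, seed = 312)
  strict <- trna_integration_scan(g, min_att_identity = 0.8)
  loose <- trna_integration_scan(g, min_att_identity = 0.65)
  expect_equal(nrow(strict), 0)
  expect_equal(nrow(loose), 1)
})

test_that("codon usage distance is zero iff gene matches genome frequencies", {
  # ten identical genes: every per-gene frequency equals the genome-wide one
  gene <- "ATGGCTAAAGGTTTAGCTAAAGGTTAA"
  feats <- data.frame(kind = "CDS",
                      start = 1 + (0:9) * nchar(gene),
                      end = (1:10) * nchar(gene), strand = "+",
                      id = sprintf("g%02d", 1:10))
  g <- genome_record("c", strrep(gene, 10), features = feats)
  prof <- codon_usage_scores(g)
  expect_true(all(prof$d == 0))
  expect_equal(sort(unique(prof$decile)), 1:10)  # still a valid partition
  expect_error(codon_usage_scores(genome_record("c", gene,
    features = feats[1, ])), ">= 10 CDS")
})

test_that("decile scores form an exact 10-way partition", {
  sim <- ref_sim()
  prof <- codon_usage_scores(sim$genome)
  sizes <- table(prof$decile)
  expect_length(sizes, 10)
  expect_lte(max(sizes) - min(sizes), 1)
})

test_that("CAG run rules respond to thresholds", {
  prof <- data.frame(gene = sprintf("g%02d", 1:20),
                     start = (1:20) * 1000, end = (1:20) * 1000 + 800,
                     n_codons = 200, d = 1,
                     decile = c(rep(9, 5), 1, 2, 1, 2, rep(8, 6),
                                1, 1, 2, 1, 9),
                     low_confidence = FALSE)
  # 4-gene atypical run: nothing at min 5, one region at min 4
  expect_equal(nrow(detect_cags(prof, min_genes = 5, interruptions = 0)), 0)
  got <- detect_cags(prof, min_genes = 4, interruptions = 0)
  expect_equal(nrow(got), 2)
  expect_equal(got$n_genes, c(4, 4))
})

is_fixture <- function() {
  cached("is_fixture", {
    bg <- generate_background(40000, 0.35, seed = 77)
    plan <- list(is_elements = list(
      list(pos = 8000, family = "FAMA", length = 1000L, itr_len = 25L,
           status = "intact"),
      list(pos = 18000, family = "FAMA", length = 1000L, itr_len = 25L,
           status = "truncated"),
      list(pos = 28000, family = "FAMB", length = 900L, itr_len = 20L,
           status = "truncated"),
      list(pos = 34000, family = "FAMB", length = 900L, itr_len = 20L,
           status = "no_itr")))
    plant_features(bg, plan, seed = 78)
  })
}

test_that("IS elements classify as intact/truncated and mobilizable in trans", {
  fx <- is_fixture()
  got <- detect_is_elements(fx$genome, fx$is_library)
  types <- vapply(fx$truth, `[[`, "", "type")
  tr <- fx$truth[types == "is_element"]
  tr_by_start <- tr[order(vapply(tr, `[[`, 0L, "start"))]
  found <- vapply(tr_by_start, function(t) {
    any(got$start == t$start & got$end == t$end)
  }, TRUE)
  # the ITR-destroyed copy is excluded from the structurally valid set
  expect_equal(found[1:3], rep(TRUE, 3), ignore_attr = TRUE)
  m <- function(t) got[got$start == t$start & got$end == t$end, ]
  expect_equal(m(tr_by_start[[1]])$transposase, "intact")
  expect_equal(m(tr_by_start[[2]])$transposase, "truncated")
  expect_true(m(tr_by_start[[2]])$mobilizable_in_trans)
  expect_equal(m(tr_by_start[[3]])$transposase, "truncated")
  expect_false(m(tr_by_start[[3]])$mobilizable_in_trans)
  destroyed <- got[got$start == tr_by_start[[4]]$start &
                     got$end == tr_by_start[[4]]$end, ]
  expect_true(nrow(destroyed) == 0 || is.na(destroyed$itr_length))
  expect_error(detect_is_elements(fx$genome,
                                  data.frame(family = "x", sequence = "ACGT",
                                             ref_len = NA)),
               "reference length")
})

test_that("MITE consensus mode and de novo mode complement each other", {
  sim <- ref_sim()
  types <- vapply(sim$truth, `[[`, "", "type")
  tr <- sim$truth[types == "mite"]
  cons <- detect_mites(sim$genome, consensi = sim$mite_consensi)
  for (t in tr) {
    expect_true(any(cons$start == t$element_start &
                      cons$end == t$element_end &
                      abs(cons$identity - t$identity) < 0.02))
  }
  # de novo finds the same copies (within 2 bp) without any consensus
  dn <- detect_mites(sim$genome)
  for (t in tr) {
    expect_true(any(abs(dn$start - t$element_start) <= 2 &
                      abs(dn$end - t$element_end) <= 2))
  }
})

test_that("a diverged copy escapes consensus mode but not the de novo scan", {
  set.seed(330)
  cons <- ref_sim()$mite_consensi
  sm3a <- cons$sequence[cons$class == "SM3Alike"]
  # 85% identity copy: interior mutations, TIRs preserved
  copy <- mutate_dna(sm3a, sample(17:(nchar(sm3a) - 17), 25), seed = 331)
  tsd <- "GATTC"
  g <- paste0(rand_dna(4000, 332), tsd, copy, tsd, rand_dna(4000, 333))
  hit_cons <- detect_mites(g, consensi = cons, denovo = FALSE)
  expect_false(any(hit_cons$start == 4006))
  hit_dn <- detect_mites(g)
  expect_true(any(abs(hit_dn$start - 4006) <= 2))
})

test_that("de novo MITE false positives stay below 1 per 100 kb", {
  g <- rand_dna(300000, 340, gc = 0.35)
  dn <- detect_mites(g)
  expect_lt(nrow(dn) / 3, 1)
})
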