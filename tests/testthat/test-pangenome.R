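# Ortholog families from reciprocal best hits.

# Smith-Waterman score oracle: plain dynamic programming with BLOSUM62 and
# affine gaps (open 11, extend 1), independent of the aligner under test.
sw_score_oracle <- function(a, b) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- BLOSUM62
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1)   # best ending in a match
  X <- matrix(-Inf, n + 1, m + 1) # gap in b
  Y <- matrix(-Inf, n + 1, m + 1) # gap in a
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    sc <- S[av[i - 1], bv[j - 1]]
    M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1],
                   Y[i - 1, j - 1]) + sc
    X[i, j] <- max(M[i - 1, j] - 12, X[i - 1, j] - 1)
    Y[i, j] <- max(M[i, j - 1] - 12, Y[i, j - 1] - 1)
    best <- max(best, M[i, j])
  }
  best
}

test_that("identical proteins give one full-coverage perfect hit", {
  p <- rand_protein(100, 71)
  h <- pairwise_protein_similarity(c(q = p), c(s = p))
  expect_equal(nrow(h), 1)
  expect_equal(h$identity, 100)
  expect_equal(h$coverage, 1.0)
})

test_that("alignment scores agree with a quadratic DP oracle on short pairs", {
  for (k in 1:6) {
    a <- rand_protein(25, 700 + k)
    b <- if (k <= 3) {
      # 50%-point-mutated copy
      set.seed(800 + k)
      av <- strsplit(a, "")[[1]]
      at <- sample(25, 12)
      av[at] <- vapply(av[at], function(x)
        sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], x), 1), "")
      paste(av, collapse = "")
    } else rand_protein(28, 900 + k)
    h <- pairwise_protein_similarity(c(q = a), c(s = b), min_identity = 0,
                                     min_coverage = 0, min_score = -Inf)
    expect_equal(h$score, sw_score_oracle(a, b))
  }
})

test_that("a half-mutated protein aligns near 50% identity", {
  a <- rand_protein(100, 75)
  set.seed(76)
  av <- strsplit(a, "")[[1]]
  at <- sample(100, 50)
  av[at] <- vapply(av[at], function(x)
    sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], x), 1), "")
  b <- paste(av, collapse = "")
  h <- pairwise_protein_similarity(c(q = a), c(s = b), min_identity = 0,
                                   min_coverage = 0, min_score = 0)
  expect_gt(h$identity, 35)
  expect_lt(h$identity, 70)
})

test_that("unrelated random proteins produce no hit at default thresholds", {
  pa <- stats::setNames(lapply(1:8, function(i) rand_protein(120, 400 + i)),
                        paste0("a", 1:8))
  pb <- stats::setNames(lapply(1:8, function(i) rand_protein(120, 500 + i)),
                        paste0("b", 1:8))
  h <- pairwise_protein_similarity(unlist(pa), unlist(pb))
  expect_equal(nrow(h), 0)
})

make_trio <- function(n_core = 20, n_unique = 5, seed = 90) {
  genomes <- c("G1", "G2", "G3")
  core <- lapply(seq_len(n_core), function(i) rand_protein(90, seed + i))
  proteomes <- list()
  for (gi in seq_along(genomes)) {
    ps <- character()
    for (i in seq_len(n_core)) {
      # light strain-specific mutation, orthologs stay near-identical
      set.seed(seed * 100 + gi * 1000 + i)
      pv <- strsplit(core[[i]], "")[[1]]
      at <- sample(90, 3)
      pv[at] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 3,
                       replace = TRUE)
      ps[sprintf("%s_core%02d", genomes[gi], i)] <- paste(pv, collapse = "")
    }
    for (u in seq_len(n_unique)) {
      ps[sprintf("%s_uniq%02d", genomes[gi], u)] <-
        rand_protein(90, seed + 5000 + gi * 100 + u)
    }
    proteomes[[genomes[gi]]] <- ps
  }
  proteomes
}

trio_fixture <- function() {
  cached("trio_fixture", {
    proteomes <- make_trio()
    hits <- pangenome_similarity(proteomes)
    list(proteomes = proteomes, hits = hits,
         fam = build_ortholog_families(hits, proteomes))
  })
}

test_that("planted trio resolves into core + singleton families", {
  fx <- trio_fixture()
  proteomes <- fx$proteomes
  hits <- fx$hits
  fam <- fx$fam
  counts <- classify_families(fam)
  expect_equal(unname(counts["ubiquitous"]), 20)
  expect_equal(unname(counts["singleton"]), 15)
  # conservation: total membership = total protein count
  expect_equal(sum(fam$n_members), sum(lengths(proteomes)))
  # one-genome degenerate case: every family ubiquitous or singleton
  one <- list(G1 = proteomes$G1)
  fam1 <- build_ortholog_families(pangenome_similarity(one), one)
  expect_true(all(fam1$n_genomes == 1))

  # connected components match a brute-force union-find oracle
  edges <- do.call(rbind, lapply(names(hits), function(key) {
    ab <- strsplit(key, "->", fixed = TRUE)[[1]]
    h <- hits[[key]]; hr <- hits[[paste0(ab[2], "->", ab[1])]]
    if (is.null(hr) || nrow(h) == 0 || nrow(hr) == 0) return(NULL)
    back <- stats::setNames(hr$subject, hr$query)
    h[!is.na(back[h$subject]) & back[h$subject] == h$query,
      c("query", "subject")]
  }))
  oracle <- brute_components(unlist(lapply(proteomes, names),
                                    use.names = FALSE), edges)
  oracle_sets <- sort(vapply(oracle, function(x)
    paste(sort(x), collapse = "|"), ""))
  got_sets <- sort(vapply(fam$members, function(m)
    paste(sort(m$protein), collapse = "|"), ""))
  expect_equal(got_sets, unname(oracle_sets))

  # family construction is invariant under genome input order
  rev_prot <- rev(proteomes)
  fam_rev <- build_ortholog_families(pangenome_similarity(rev_prot),
                                     rev_prot)
  got_rev <- sort(vapply(fam_rev$members, function(m)
    paste(sort(m$protein), collapse = "|"), ""))
  expect_equal(got_rev, got_sets)
})

test_that("three-strain overlap cells sum and place families correctly", {
  fam <- trio_fixture()$fam
  venn <- shared_family_venn(fam, c("G1", "G2", "G3"))
  expect_equal(unname(venn[["G1&G2&G3"]]), 20)
  expect_equal(unname(venn[["G1"]]), 5)
  expect_equal(unname(venn[["G2"]]), 5)
  expect_equal(unname(venn[["G3"]]), 5)
  expect_equal(sum(venn), nrow(fam))
  expect_error(shared_family_venn(fam, c("G1", "G2", "NOPE")), "genome id")
})
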