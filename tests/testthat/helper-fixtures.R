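# Shared fixtures and independent oracles.

# Cache expensive objects across test files (one process per run).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# The shipped reference scenario (fixed seed: this is the regression
# dataset every detector must recover).
ref_sim <- function() cached("ref_sim", simulate_reference(42))

ref_truth_of <- function(type) {
  sim <- ref_sim()
  sim$truth[vapply(sim$truth, `[[`, "", "type") == type]
}

ref_arrays <- function() cached("ref_arrays",
                                detect_crispr_arrays(ref_sim()$genome))

ref_proteins <- function() cached("ref_proteins",
                                  extract_proteins(ref_sim()$genome))

ref_annotations <- function() cached(
  "ref_annotations",
  annotate_mge_homologs(ref_proteins(), ref_sim()$mge_db))

# ---- independent oracles ---------------------------------------------------

# Naive per-position Hamming scan: every start where pattern matches the
# subject within max_mm mismatches, both strands.
naive_hamming_scan <- function(subject, pattern, max_mm) {
  sb <- strsplit(subject, "")[[1]]
  scan1 <- function(pat, strand) {
    pl <- nchar(pat)
    pb <- strsplit(pat, "")[[1]]
    np <- length(sb) - pl + 1L
    mm <- integer(np)
    for (o in seq_len(pl)) {           # mismatch count at every start
      mm <- mm + (sb[o:(o + np - 1L)] != pb[o])
    }
    hit <- which(mm <= max_mm)
    data.frame(start = hit, end = hit + pl - 1L,
               strand = rep(strand, length(hit)), mismatches = mm[hit],
               stringsAsFactors = FALSE)
  }
  out <- scan1(pattern, "+")
  rc <- plasticome::revcomp(pattern)
  if (rc != pattern) out <- rbind(out, scan1(rc, "-"))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

rand_dna <- function(n, seed, gc = 0.5) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rand_protein <- function(n, seed) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

# Mutate a fraction of positions of a DNA string at fixed positions.
mutate_dna <- function(x, at, seed = 1) {
  set.seed(seed)
  b <- strsplit(x, "")[[1]]
  b[at] <- vapply(b[at], function(ch)
    sample(setdiff(c("A", "C", "G", "T"), ch), 1), "")
  paste(b, collapse = "")
}

# Brute-force connected components from an undirected edge list over a
# fixed vertex set (label-propagation union-find oracle).
brute_components <- function(vertices, edges) {
  comp <- stats::setNames(seq_along(vertices), vertices)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(names(comp), comp)
}
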