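# CRISPR array detection, spacer matching, PAM inference.

REP24 <- "GCTAATCTACTATAGAATTGAAAG"

build_array_genome <- function(n_spacers, seed, repeat_seq = REP24,
                               pad = 3000, pseudo = NULL, pseudo_at = NULL) {
  set.seed(seed)
  parts <- list(rand_dna(pad, seed))
  for (i in seq_len(n_spacers + 1)) {
    parts <- c(parts, repeat_seq)
    if (i <= n_spacers) {
      len <- if (!is.null(pseudo) && i == pseudo_at) pseudo
             else sample(35:45, 1)
      parts <- c(parts, rand_dna(len, seed * 1000 + i))
    }
  }
  paste(c(parts, rand_dna(pad, seed + 7)), collapse = "")
}

test_that("a constructed repeat-spacer-repeat instance yields one array", {
  g <- build_array_genome(2, 51)
  arr <- find_arrays_by_repeat(g, REP24)
  expect_length(arr, 1)
  expect_equal(nrow(arr[[1]]$copies), 3)
  expect_equal(nrow(arr[[1]]$spacers), 2)
  expect_equal(arr[[1]]$repeat_consensus, REP24)
  # de novo detection agrees
  da <- detect_crispr_arrays(g)
  expect_length(da, 1)
  expect_equal(nrow(da[[1]]$spacers), 2)
  # spacer count = copies - 1 always
  expect_equal(nrow(da[[1]]$spacers), nrow(da[[1]]$copies) - 1)
})

test_that("mismatched repeat copies are found within budget (Hamming oracle)", {
  g <- build_array_genome(4, 52)
  # mutate copies 2 and 4 (2 mismatches each)
  arr0 <- find_arrays_by_repeat(g, REP24)[[1]]
  st <- arr0$copies$start
  g2 <- mutate_dna(g, c(st[2] + c(3, 11), st[4] + c(5, 17)), seed = 3)
  arr <- find_arrays_by_repeat(g2, REP24, max_mismatch = 3)
  expect_length(arr, 1)
  expect_equal(nrow(arr[[1]]$copies), 5)
  oracle <- naive_hamming_scan(g2, REP24, 3)
  expect_equal(arr[[1]]$copies$start, oracle$start[oracle$strand == "+"])
  # absent repeat: empty result
  expect_length(find_arrays_by_repeat(rand_dna(5000, 53), REP24), 0)
})

test_that("arrays mirror under reverse complement of the genome", {
  g <- build_array_genome(3, 54)
  n <- nchar(g)
  a <- detect_crispr_arrays(g)[[1]]
  b <- detect_crispr_arrays(revcomp(g))[[1]]
  expect_equal(nrow(b$spacers), nrow(a$spacers))
  expect_equal(b$start, n - a$end + 1)
  expect_equal(b$end, n - a$start + 1)
})

test_that("array detection is invariant under genome rotation", {
  g <- build_array_genome(3, 55)
  n <- nchar(g)
  off <- 1500
  rot <- paste0(substr(g, off + 1, n), substr(g, 1, off))
  a <- detect_crispr_arrays(g)[[1]]
  b <- detect_crispr_arrays(rot)[[1]]
  expect_equal(b$start, a$start - off)
  expect_equal(nrow(b$spacers), nrow(a$spacers))
})

test_that("anomalous (pseudo-)spacers are flagged with complete flanks", {
  g <- build_array_genome(6, 56, pseudo = 1500, pseudo_at = 3)
  arr <- detect_crispr_arrays(g)
  expect_length(arr, 1)
  an <- flag_anomalous_spacers(arr)
  expect_equal(nrow(an), 1)
  expect_equal(an$length, 1500)
  expect_equal(an$index, 3)
  expect_true(an$flanks_complete)
  # uniform-length arrays yield nothing
  g2 <- build_array_genome(5, 57)
  expect_equal(nrow(flag_anomalous_spacers(detect_crispr_arrays(g2))), 0)
})

test_that("spacer matching equals the naive Hamming scan and classifies hits", {
  target <- rand_dna(20000, 61)
  # a spacer equal to a target substring: one perfect match at the offset
  sp1 <- data.frame(array_id = "A", index = 1L,
                    sequence = substr(target, 5001, 5038),
                    length = 38L, anomalous = FALSE)
  m <- match_spacers(sp1, c(tgt = target), max_mismatch = 0)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 5001)
  expect_equal(m$class, "perfect")

  # random spacers at budget 3: identical output to the naive scan
  set.seed(62)
  sp <- do.call(rbind, lapply(1:50, function(i) {
    st <- sample(1:(20000 - 38), 1)
    seq <- substr(target, st, st + 37)
    if (i %% 2 == 0) seq <- mutate_dna(seq, sample(38, 2), seed = i)
    data.frame(array_id = "A", index = i, sequence = seq, length = 38L,
               anomalous = FALSE)
  }))
  m <- match_spacers(sp, c(tgt = target), max_mismatch = 3)
  for (i in sample(1:50, 10)) {
    oracle <- naive_hamming_scan(target, sp$sequence[i], 3)
    got <- m[m$spacer_index == i, c("start", "end", "strand", "mismatches")]
    rownames(got) <- rownames(oracle) <- NULL
    expect_equal(got, oracle[, c("start", "end", "strand", "mismatches")])
  }
  expect_error(match_spacers(sp1, character(0)), "empty target")
})

test_that("PAM inference recovers planted flank motifs on both strands", {
  set.seed(63)
  # 40 protospacers, each preceded by NNNNNNNACCN-style flank with CC at
  # (-3,-2) and followed by random 3' flank
  five_fix <- function() paste0(rand_dna(7, sample(1e6, 1)), "CC",
                                rand_dna(1, sample(1e6, 1)))
  spacers <- list(); targets <- character()
  for (i in 1:40) {
    sp <- rand_dna(38, 7000 + i)
    tgt <- paste0(rand_dna(30, 8000 + i), five_fix(), sp,
                  rand_dna(12, 9000 + i))
    if (i %% 3 == 0) {  # embed on the minus strand
      tgt <- revcomp(tgt)
    }
    targets[paste0("t", i)] <- tgt
    spacers[[i]] <- data.frame(array_id = "A", index = i, sequence = sp,
                               length = 38L, anomalous = FALSE)
  }
  m <- match_spacers(do.call(rbind, spacers), targets, max_mismatch = 0)
  expect_equal(nrow(m), 40)
  pam <- infer_pam(m, targets)
  expect_equal(unname(pam$consensus$five_prime[c("-3", "-2")]), c("C", "C"))
  expect_equal(pam$five_prime["C", "-3"], 1.0)
  expect_equal(pam$five_prime["C", "-2"], 1.0)
  # two-base calls: plant T/A split at -4
  targets2 <- character(); spacers2 <- list()
  for (i in 1:40) {
    sp <- rand_dna(38, 17000 + i)
    base <- if (i <= 20) "T" else "A"
    flank5 <- paste0(rand_dna(6, 18000 + i), base, "GT",
                     rand_dna(1, 18500 + i))
    targets2[paste0("u", i)] <- paste0(rand_dna(15, 19000 + i), flank5, sp,
                                       rand_dna(12, 19500 + i))
    spacers2[[i]] <- data.frame(array_id = "A", index = i, sequence = sp,
                                length = 38L, anomalous = FALSE)
  }
  m2 <- match_spacers(do.call(rbind, spacers2), targets2, max_mismatch = 0)
  pam2 <- infer_pam(m2, targets2)
  expect_true(pam2$consensus$five_prime[["-4"]] %in%
                c("[T/A]", "[A/T]"))
  expect_equal(unname(pam2$consensus$five_prime[c("-3", "-2")]), c("G", "T"))
})

test_that("PAM frequencies on shuffled flanks stay near uniform", {
  set.seed(64)
  targets <- character(); spacers <- list()
  for (i in 1:60) {
    sp <- rand_dna(38, 27000 + i)
    targets[paste0("s", i)] <- paste0(rand_dna(15, 28000 + i), sp,
                                      rand_dna(15, 29000 + i))
    spacers[[i]] <- data.frame(array_id = "A", index = i, sequence = sp,
                               length = 38L, anomalous = FALSE)
  }
  m <- match_spacers(do.call(rbind, spacers), targets, max_mismatch = 0)
  pam <- infer_pam(m, targets)
  dev <- max(abs(pam$five_prime - 0.25))
  expect_lt(dev, 3 / sqrt(pam$n))
})
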