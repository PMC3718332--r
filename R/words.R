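# Exceptional-word statistics under maximal-order Markov models.
#
# For a word w of length l, the order-(l-2) Markov expectation is
#   E(w) = N(w[1..l-1]) * N(w[2..l]) / N(w[2..l-1]),
# the classical maximal-order estimator; the Gaussian variance follows the
# matching large-sequence approximation. Scores z = (N - E)/sqrt(V) rank
# words by exceptionality; overrepresentation of repeat-borne words and
# avoidance of restriction-site palindromes are the typical signals.

#' Count overlapping words of fixed length
#'
#' Overlapping occurrences of all `len`-mers. In circular mode the
#' `len - 1` junction-spanning positions are counted too. Strand mode
#' `"both"` adds reverse-complement-strand counts. Words containing `N`
#' are never counted.
#'
#' @param sequence DNA string, or a `GenomeRecord` (its topology then sets
#'   the default for `circular`).
#' @param len Word length, 2..12.
#' @param strand `"forward"` or `"both"`.
#' @param circular Count across the origin junction?
#' @return Named integer vector over all 4^len words (zeros included).
#' @export
count_words <- function(sequence, len, strand = c("forward", "both"),
                        circular = FALSE) {
  strand <- match.arg(strand)
  if (inherits(sequence, "GenomeRecord")) {
    if (missing(circular)) circular <- sequence$topology == "circular"
    sequence <- sequence$sequence
  }
  stopifnot(len >= 2, len <= 12)
  if (len > nchar(sequence)) stop("word length exceeds sequence length")
  seq_use <- if (circular) paste0(sequence, substr(sequence, 1, len - 1L))
             else sequence
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(seq_use), width = len)
  if (strand == "both") {
    counts <- counts + Biostrings::oligonucleotideFrequency(
      Biostrings::reverseComplement(Biostrings::DNAString(seq_use)),
      width = len)
  }
  counts
}

#' Markov expected count of one word
#'
#' Maximal-order (`m = l - 2`) expectation from sub-word counts:
#' `E(w) = N(prefix) * N(suffix) / N(core)`. For `l = 2` the order-0 form
#' `E = N(w1) * N(w2) / L'` is used, `L'` being the number of counted
#' positions.
#'
#' @param word The word.
#' @param counts_l1 Named counts of length `l-1` words (same counting mode).
#' @param counts_l2 Named counts of length `l-2` words; for `l = 2` pass
#'   single-base counts as `counts_l1` and the position total as `positions`.
#' @param positions Number of counted positions (needed for `l = 2`).
#' @return Expected count (numeric), or `NA` with a warning on a zero
#'   denominator.
#' @export
markov_expected <- function(word, counts_l1, counts_l2 = NULL,
                            positions = NULL) {
  l <- nchar(word)
  if (l == 2) {
    if (is.null(positions)) stop("positions required for length-2 words")
    return(unname(counts_l1[substr(word, 1, 1)] *
                    counts_l1[substr(word, 2, 2)] / positions))
  }
  pre <- substr(word, 1, l - 1L)
  suf <- substr(word, 2, l)
  core <- substr(word, 2, l - 1L)
  if (is.na(counts_l2[core]) || counts_l2[core] == 0) {
    warning("zero denominator for word ", word, "; expectation undefined")
    return(NA_real_)
  }
  unname(counts_l1[pre] * counts_l1[suf] / counts_l2[core])
}

#' Rank all words of one length by exceptionality
#'
#' Computes observed counts, maximal-order Markov expectations, a variance
#' estimate and the z-score `(N - E)/sqrt(V)` for every word of length
#' `len`, ranked by `|z|` descending (ties by word). `variance = "gaussian"`
#' uses the maximal-order approximation
#' `V = E * (N(core)-N(prefix)) * (N(core)-N(suffix)) / N(core)^2`;
#' `"poisson"` uses `V = E`.
#'
#' @param sequence DNA string or `GenomeRecord`.
#' @param len Word length 2..8.
#' @param strand,circular Counting mode, as [count_words()].
#' @param variance `"gaussian"` or `"poisson"`.
#' @return Data frame: word, observed, expected, variance, z, palindrome
#'   (reverse complement equals self), rank.
#' @export
word_exceptionality <- function(sequence, len, strand = c("forward", "both"),
                                circular = FALSE,
                                variance = c("gaussian", "poisson")) {
  strand <- match.arg(strand)
  variance <- match.arg(variance)
  if (inherits(sequence, "GenomeRecord")) {
    if (missing(circular)) circular <- sequence$topology == "circular"
    sequence <- sequence$sequence
  }
  stopifnot(len >= 2, len <= 8, nchar(sequence) >= 16)
  nl <- count_words(sequence, len, strand, circular)
  n1 <- count_words_any(sequence, len - 1L, strand, circular)
  words <- names(nl)
  pre <- substr(words, 1, len - 1L)
  suf <- substr(words, 2, len)
  if (len == 2) {
    total <- sum(n1)
    e <- n1[pre] * n1[suf] / total
    ncore <- rep(total, length(words))
  } else {
    n2 <- count_words_any(sequence, len - 2L, strand, circular)
    core <- substr(words, 2, len - 1L)
    ncore <- n2[core]
    e <- ifelse(ncore > 0, n1[pre] * n1[suf] / ncore, NA_real_)
  }
  v <- if (variance == "poisson") e else
    e * (ncore - n1[pre]) * (ncore - n1[suf]) / ncore^2
  z <- ifelse(!is.na(v) & v > 0, (nl - e) / sqrt(v), NA_real_)
  pal <- words == as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(words)))
  out <- data.frame(word = words, observed = as.integer(nl),
                    expected = as.numeric(e), variance = as.numeric(v),
                    z = as.numeric(z), palindrome = pal,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$z), out$word, na.last = TRUE), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# count_words for lengths down to 1 (count_words proper enforces >= 2).
count_words_any <- function(sequence, len, strand, circular) {
  if (len >= 2) return(count_words(sequence, len, strand, circular))
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(sequence), width = 1L)[DNA_BASES]
  if (strand == "both") {
    counts <- counts + Biostrings::oligonucleotideFrequency(
      Biostrings::reverseComplement(Biostrings::DNAString(sequence)),
      width = 1L)[DNA_BASES]
  }
  counts
}

#' Palindrome avoidance summary
#'
#' Compares mean z-scores of reverse-complement palindromic words with
#' non-palindromic words of the same length; a negative difference is the
#' avoidance signature typical of restriction-modification carriers.
#'
#' @param records Output of [word_exceptionality()] for an even word length.
#' @return List: `len`, `mean_z_palindrome`, `mean_z_other`, `difference`,
#'   `n_palindromes`.
#' @export
palindrome_report <- function(records) {
  len <- nchar(records$word[1])
  if (len %% 2 == 1 || !any(records$palindrome)) {
    stop("validation error: no reverse-complement palindromes at odd length ",
         len)
  }
  zp <- records$z[records$palindrome]
  zo <- records$z[!records$palindrome]
  list(len = len,
       mean_z_palindrome = mean(zp, na.rm = TRUE),
       mean_z_other = mean(zo, na.rm = TRUE),
       difference = mean(zp, na.rm = TRUE) - mean(zo, na.rm = TRUE),
       n_palindromes = sum(records$palindrome))
}
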