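# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin character-in/character-out wrapper around
#' [Biostrings::reverseComplement()]; `N` is preserved.
#'
#' @param x A single DNA string over `{A,C,G,T,N}`.
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Hamming distance between two equal-length strings (byte comparison).
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming() requires equal-length strings")
  sum(charToRaw(a) != charToRaw(b))
}

# Circular substring: 1-based start, wraps past the end. len <= nchar(seq).
substr_circ <- function(seq, start, len) {
  n <- nchar(seq)
  start <- ((start - 1L) %% n) + 1L
  end <- start + len - 1L
  if (end <= n) return(substr(seq, start, end))
  paste0(substr(seq, start, n), substr(seq, 1L, end - n))
}

# Deterministic seed derivation: combine a base seed with a small offset,
# staying inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + k) %% 2147483647)
}

# Validate a DNA string: uppercase over ACGTN.
check_dna <- function(x, what = "sequence") {
  bad <- gsub("[ACGTN]", "", x)
  if (nchar(bad) > 0) {
    stop(sprintf("%s contains unknown residue symbol(s): %s", what,
                 paste(unique(strsplit(bad, "")[[1]]), collapse = ",")))
  }
  invisible(x)
}

# Majority base per column over equal-length strings; ties broken by
# alphabetical order (deterministic).
consensus_string <- function(strings) {
  m <- do.call(rbind, strsplit(strings, ""))
  apply(m, 2, function(col) {
    tb <- table(factor(col, levels = DNA_BASES))
    names(tb)[which.max(tb)]
  }) |> paste(collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
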