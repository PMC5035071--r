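#' All k-mer words in lexicographic order
#'
#' @param k Word length.
#' @return Character vector of the `4^k` words over A, C, G, T with A < C <
#'   G < T, most-significant position first.
#' @export
kmer_words <- function(k) {
  stopifnot(k >= 1)
  args <- rep(list(c("A", "C", "G", "T")), k)
  grid <- do.call(expand.grid,
                  c(rev(args), list(stringsAsFactors = FALSE)))
  # expand.grid varies the first factor fastest; reverse to make the first
  # sequence position most significant
  do.call(paste0, rev(grid))
}

#' Lexicographic index of a k-mer
#'
#' @param word Character vector of k-mers over A, C, G, T, all of length `k`.
#' @param k Word length (defaults to the width of the first word).
#' @return Integer vector of 0-based indices in `[0, 4^k)`; `"AAAAA"` is 0
#'   and `"TTTTT"` is `4^5 - 1`.
#' @export
kmer_index <- function(word, k = nchar(word[1])) {
  if (any(nchar(word) != k)) abort("all words must have length k")
  base <- c(A = 0, C = 1, G = 2, T = 3)
  mat <- matrix(base[unlist(strsplit(word, "", fixed = TRUE))],
                ncol = k, byrow = TRUE)
  if (anyNA(mat)) abort("words must contain only A, C, G, T")
  as.integer(mat %*% 4^((k - 1):0))
}

#' Encode DNA sequences as normalized k-mer count vectors
#'
#' Every overlapping window of length `k` consisting solely of A/C/G/T is
#' counted; windows containing N (or any other ambiguity code) are skipped.
#' Counts are normalized to sum to 1, making vectors comparable across
#' sequence lengths.  A sequence with no valid window yields an all-zero row
#' flagged invalid.
#'
#' @param seqs Character vector (or [Biostrings::DNAStringSet]) of sequences.
#' @param k Word length; 5 by default (1,024 features).
#' @param canonical If `TRUE`, collapse each word with its reverse complement
#'   (strand-symmetric encoding); columns are then the lexicographically
#'   smaller word of each pair.
#' @return Numeric matrix, one row per sequence, columns named by k-mer,
#'   with attribute `"valid"` (logical vector marking rows whose counts sum
#'   to 1).
#' @examples
#' x <- encode_kmers(c("AAAAAA", "ACGTACGTAC"), k = 2)
#' rowSums(x)
#' @export
encode_kmers <- function(seqs, k = 5, canonical = FALSE) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  counts <- Biostrings::oligonucleotideFrequency(seqs, width = k)
  if (canonical) {
    words <- colnames(counts)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(words)))
    keep <- words <= rc
    partner <- counts[, match(rc[keep], words), drop = FALSE]
    partner[, words[keep] == rc[keep]] <- 0  # palindromes counted once
    counts <- counts[, keep, drop = FALSE] + partner
    colnames(counts) <- words[keep]
  }
  tot <- rowSums(counts)
  valid <- tot > 0
  out <- counts / ifelse(tot > 0, tot, 1)
  rownames(out) <- names(seqs)
  attr(out, "valid") <- valid
  out
}

#' GC content of sequences
#'
#' @param seqs Character vector (or [Biostrings::DNAStringSet]).
#' @return `(G + C) / (A + C + G + T)` per sequence, in `[0, 1]`; `NA` for a
#'   sequence with no unambiguous base.  Errors on empty sequences.
#' @export
gc_content <- function(seqs) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  if (any(Biostrings::width(seqs) == 0)) abort("empty sequence")
  f <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
  den <- rowSums(f)
  ifelse(den > 0, (f[, "C"] + f[, "G"]) / den, NA_real_)
}
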