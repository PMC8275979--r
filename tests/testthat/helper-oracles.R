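# Independent oracles and fixture builders used across the suite. These
# stay deliberately naive (string slicing, exhaustive enumeration) so they
# never share code with the implementation paths they check.

# Brute-force k-mer counter: plain substring slicing into a table.
oracleKmerCounts <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(integer(0))
  km <- vapply(seq_len(L - k + 1L), function(i) substr(s, i, i + k - 1L),
               character(1))
  tb <- table(km)
  out <- as.integer(tb)
  names(out) <- names(tb)
  out[order(names(out))]
}

# Named count vectors considered equal as multisets of labelled counts.
sameCounts <- function(a, b) {
  a <- a[order(names(a))]
  b <- b[order(names(b))]
  identical(names(a), names(b)) && all(a == b)
}

# All distinct permutations of a character multiset (exhaustive, for short
# strings only).
multisetPermutations <- function(chars) {
  if (length(chars) <= 1L) return(paste(chars, collapse = ""))
  out <- character(0)
  for (u in unique(chars)) {
    rest <- chars[-match(u, chars)]
    out <- c(out, paste0(u, multisetPermutations(rest)))
  }
  unique(out)
}

# Brute-force set of all rearrangements of s with identical k-mer counts.
oracleValidShuffles <- function(s, k) {
  target <- oracleKmerCounts(s, k)
  perms <- multisetPermutations(strsplit(s, "")[[1]])
  perms[vapply(perms, function(p) sameCounts(oracleKmerCounts(p, k), target),
               logical(1))]
}

# Random sequence over a given alphabet.
randomSeq <- function(L, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

# Random IUPAC alphabets of assorted sizes, always containing A and C so
# two-letter alphabets are possible.
randomAlphabet <- function(size) {
  iupac <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "N")
  unique(c("A", "C", sample(iupac, max(size - 2L, 0L))))
}

# A pool guaranteed to cover every 1% GC bin: for each bin b, sequences of
# length 100 with exactly b G/C residues (GC bin is then exactly b).
saturatedPool <- function(perBin = 3L, len = 100L) {
  seqs <- character(0)
  for (b in 0:100) {
    gc <- round(b * len / 100)
    for (r in seq_len(perBin)) {
      chars <- c(sample(c("G", "C"), gc, replace = TRUE),
                 sample(c("A", "T"), len - gc, replace = TRUE))
      seqs <- c(seqs, paste(sample(chars), collapse = ""))
    }
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("pool%d", seq_along(out))
  out
}
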