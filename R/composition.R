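#' GC fraction of sequences
#'
#' Fraction of residues that are G, C or the IUPAC strong code S; the
#' denominator is the full sequence length. Other ambiguity codes (R, Y, K,
#' M, N, ...) do not contribute fractionally: the policy is conservative,
#' unambiguous, and reduces to the standard definition on ACGT-only
#' sequences.
#'
#' @param x sequences (character vector, [Biostrings::DNAString] or
#'   [Biostrings::DNAStringSet]).
#' @return numeric vector of fractions in [0, 1], one per sequence.
#' @examples
#' gcFraction(c("GGCC", "AATT", "ACGN", "SSWW"))
#' @export
gcFraction <- function(x) {
  x <- .asSet(x)
  counts <- .gcCounts(x)
  as.numeric(counts) / Biostrings::width(x)
}

# Integer G+C+S counts per sequence.
.gcCounts <- function(x) {
  lf <- Biostrings::letterFrequency(x, letters = c("G", "C", "S"))
  as.integer(rowSums(lf))
}

# 1% GC bin per sequence, computed in integer arithmetic so the floor rule
# floor(100 * gc / L) is exact (no floating-point edge cases); gc == L maps
# to bin 100.
.gcBins <- function(x) {
  x <- .asSet(x)
  gc <- .gcCounts(x)
  L <- Biostrings::width(x)
  as.integer((100 * as.numeric(gc)) %/% L)
}

#' Exact k-mer profile of one sequence
#'
#' Counts every overlapping length-k substring. K-mers containing IUPAC
#' ambiguity codes are counted as literal strings over the extended
#' alphabet (no expansion into ACGT possibilities), preserving the exact
#' count semantics the k-let shuffler conserves.
#'
#' @param x a single sequence (character scalar, DNAString, or length-1
#'   DNAStringSet).
#' @param k k-mer order, a positive integer. `k` longer than the sequence
#'   yields an empty profile with total 0.
#' @return a [KmerProfile-class] object.
#' @examples
#' kmerProfile("ACGCG", 2)
#' @export
kmerProfile <- function(x, k) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  s <- .asSingleString(x)
  L <- nchar(s)
  n <- L - k + 1L
  if (n < 1L) {
    counts <- integer(0)
    total <- 0L
  } else {
    tb <- table(substring(s, 1:n, k:L))
    counts <- as.integer(tb)
    names(counts) <- names(tb)
    total <- n
  }
  new("KmerProfile", k = k, counts = counts, total = total)
}

#' @describeIn kmerProfile named counts of a profile (sorted by k-mer).
#' @param profile a [KmerProfile-class].
#' @export
kmerCounts <- function(profile) profile@counts

#' @describeIn kmerProfile total number of k-mer positions counted.
#' @export
kmerTotal <- function(profile) profile@total

#' Sliding-window %GC profile
#'
#' Windows of width `windowSize` start at offsets 0, S, 2S, ... while
#' offset + W <= L (0-based, half-open); trailing partial windows are not
#' emitted so per-window values stay comparable. A sequence shorter than
#' the window is profiled as a single whole-sequence window.
#'
#' @param x a single sequence.
#' @param windowSize window width W in bp (default 100).
#' @param step window step S in bp (default 50).
#' @return a [GCWindowProfile-class].
#' @examples
#' gcWindowProfile("GGGGAAAA", windowSize = 4, step = 4)
#' @export
gcWindowProfile <- function(x, windowSize = 100L, step = 50L) {
  W <- as.integer(windowSize)
  S <- as.integer(step)
  if (W < 1L || S < 1L) stop("windowSize and step must be >= 1")
  s <- .asSingleString(x)
  L <- nchar(s)
  if (L < W) {
    values <- 100 * gcFraction(s)
  } else {
    offs <- seq.int(0L, L - W, by = S)
    v <- Biostrings::Views(Biostrings::DNAString(s),
                           start = offs + 1L, end = offs + W)
    gcc <- rowSums(Biostrings::letterFrequency(v, letters = c("G", "C", "S")))
    values <- 100 * as.numeric(gcc) / W
  }
  new("GCWindowProfile", values = values, windowSize = W, step = S)
}

#' @describeIn gcWindowProfile the per-window %GC values.
#' @param profile a [GCWindowProfile-class].
#' @export
profileValues <- function(profile) profile@values

#' @describeIn gcWindowProfile arithmetic mean of the window values.
#' @export
profileMean <- function(profile) mean(profile@values)

#' @describeIn gcWindowProfile population (divide-by-n) standard deviation
#'   of the window values.
#' @export
profileSD <- function(profile) {
  v <- profile@values
  sqrt(mean((v - mean(v))^2))
}
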