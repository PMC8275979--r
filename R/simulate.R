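# Synthetic fixture generators: foreground sets with controllable %GC and
# synthetic genomes with patterned GC and assembly-gap (N) stretches. All
# output is fully determined by the seed.

# One random sequence of length L with per-position GC probability p
# (recycled to length L). GC positions become G or C with equal
# probability, the rest A or T.
.simSeq <- function(L, p) {
  p <- rep_len(p, L)
  isGC <- stats::runif(L) < p
  strong <- sample(c("G", "C"), L, replace = TRUE)
  weak <- sample(c("A", "T"), L, replace = TRUE)
  paste(ifelse(isGC, strong, weak), collapse = "")
}

#' Simulate a foreground sequence set
#'
#' Generates random DNA with controllable \%GC. Exactly one of three
#' composition modes applies:
#' \itemize{
#'   \item `gcTarget`: every position has the same GC probability;
#'   \item `gcRange`: each sequence draws its own GC level uniformly from
#'     the range, giving a set that spreads across GC bins;
#'   \item `gcGradient`: the GC probability ramps linearly from
#'     `gcGradient[1]` to `gcGradient[2]` along each sequence, producing
#'     within-sequence \%GC heterogeneity that exercises the windowed
#'     models.
#' }
#' When none is given, `gcTarget = 0.41` (a typical mammalian genome-wide
#' level) is used.
#'
#' @param n number of sequences.
#' @param lengthRange inclusive length range in bp; each sequence's length
#'   is uniform over it (default c(100, 500)).
#' @param gcTarget,gcRange,gcGradient composition controls, see above.
#' @param seed optional integer seed; same seed, same FASTA bytes.
#' @param prefix identifier prefix (default "fg").
#' @return a named [Biostrings::DNAStringSet].
#' @examples
#' simulateForeground(3, c(50, 60), gcTarget = 0.6, seed = 1)
#' @export
simulateForeground <- function(n, lengthRange = c(100L, 500L),
                               gcTarget = NULL, gcRange = NULL,
                               gcGradient = NULL, seed = NULL,
                               prefix = "fg") {
  modes <- !vapply(list(gcTarget, gcRange, gcGradient), is.null, logical(1))
  if (sum(modes) > 1L)
    stop("give at most one of gcTarget, gcRange, gcGradient")
  if (sum(modes) == 0L) gcTarget <- 0.41
  .withSeed(seed, function() {
    lens <- if (lengthRange[1] == lengthRange[2]) rep(lengthRange[1], n)
            else sample(lengthRange[1]:lengthRange[2], n, replace = TRUE)
    seqs <- vapply(seq_len(n), function(i) {
      L <- lens[i]
      p <- if (!is.null(gcTarget)) gcTarget
           else if (!is.null(gcRange)) stats::runif(1, gcRange[1], gcRange[2])
           else seq(gcGradient[1], gcGradient[2], length.out = L)
      .simSeq(L, p)
    }, character(1))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- sprintf("%s%d synthetic length=%d", prefix, seq_len(n), lens)
    out
  })
}

#' Simulate a synthetic genome
#'
#' Long random contigs built from blocks of distinct GC level (emulating
#' isochore-like GC patterning) with optional runs of N emulating assembly
#' gaps — the inputs the genome partitioner is designed for.
#'
#' @param nContigs number of contigs.
#' @param contigLength length of each contig in bp.
#' @param blockSize length of each constant-GC block (default 1000).
#' @param gcBlockRange each block's GC level is uniform over this range
#'   (default c(0.25, 0.65)).
#' @param nGapsPerContig number of N gaps inserted per contig.
#' @param nGapLength length of each N gap in bp.
#' @param seed optional integer seed.
#' @return a named [Biostrings::DNAStringSet] of contigs.
#' @export
simulateGenome <- function(nContigs = 2L, contigLength = 20000L,
                           blockSize = 1000L, gcBlockRange = c(0.25, 0.65),
                           nGapsPerContig = 2L, nGapLength = 300L,
                           seed = NULL) {
  .withSeed(seed, function() {
    seqs <- vapply(seq_len(nContigs), function(i) {
      nBlocks <- ceiling(contigLength / blockSize)
      p <- rep(stats::runif(nBlocks, gcBlockRange[1], gcBlockRange[2]),
               each = blockSize)[seq_len(contigLength)]
      chars <- strsplit(.simSeq(contigLength, p), "")[[1L]]
      if (nGapsPerContig > 0L && nGapLength > 0L &&
          contigLength > nGapLength) {
        starts <- sample.int(contigLength - nGapLength, nGapsPerContig)
        for (st in starts) chars[st:(st + nGapLength - 1L)] <- "N"
      }
      paste(chars, collapse = "")
    }, character(1))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- sprintf("contig%d synthetic", seq_len(nContigs))
    out
  })
}
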