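#' Partition a genome into fixed-size bins
#'
#' Tiles every contig of a genome into non-overlapping bins of `binSize`
#' bp (0-based, half-open coordinates), building the background pools the
#' genomic matching models draw from. Bins whose fraction of N residues
#' exceeds `maxNFraction` are discarded, so assembly gaps do not flood the
#' low-GC bins. Tiling is non-overlapping (step = bin size): a background
#' pool should not contain near-duplicate sequences. Only the forward
#' strand is emitted, \%GC being strand-symmetric.
#'
#' @param genome [Biostrings::DNAStringSet] of contigs (e.g. from
#'   [readFasta()]).
#' @param binSize bin width in bp; common published pool sizes are 100,
#'   250, 500, 750 and 1000.
#' @param maxNFraction maximum tolerated N fraction per bin (default 0.1).
#' @param dropRemainder drop the final short bin of each contig (default
#'   TRUE); with `FALSE` the remainder is emitted too (subject to the N
#'   filter), so that with `maxNFraction = 1` the bins of a contig
#'   concatenate back to the contig exactly.
#' @return a [Biostrings::DNAStringSet] of bins named "contig:start-end"
#'   (0-based half-open), with contig/start/end also in `mcols()`; empty
#'   (with a warning) when no bin survives.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 300), collapse = "")))
#' partitionGenome(g, binSize = 500)
#' @export
partitionGenome <- function(genome, binSize, maxNFraction = 0.1,
                            dropRemainder = TRUE) {
  genome <- .asSet(genome)
  if (length(genome) == 0L) stop("genome is empty")
  binSize <- as.integer(binSize)
  if (binSize < 1L) stop("binSize must be >= 1")
  contigs <- seqIds(genome)
  seqs <- character(0)
  contig <- character(0)
  bstart <- integer(0)
  bend <- integer(0)
  for (i in seq_along(genome)) {
    L <- Biostrings::width(genome)[i]
    nb <- L %/% binSize
    starts <- if (nb > 0L) (seq_len(nb) - 1L) * binSize else integer(0)
    ends <- starts + binSize
    if (!dropRemainder && L %% binSize > 0L) {
      starts <- c(starts, nb * binSize)
      ends <- c(ends, L)
    }
    if (length(starts) == 0L) next
    v <- Biostrings::Views(genome[[i]], start = starts + 1L, end = ends)
    nfrac <- as.numeric(Biostrings::letterFrequency(v, "N")) /
      Biostrings::width(v)
    keep <- nfrac <= maxNFraction
    if (!any(keep)) next
    seqs <- c(seqs, as.character(Biostrings::DNAStringSet(v))[keep])
    contig <- c(contig, rep(contigs[i], sum(keep)))
    bstart <- c(bstart, starts[keep])
    bend <- c(bend, ends[keep])
  }
  out <- Biostrings::DNAStringSet(seqs)
  if (length(out) == 0L)
    warning("no bin passed the size and N-fraction filters; ",
            "empty partition returned")
  else
    names(out) <- sprintf("%s:%d-%d", contig, bstart, bend)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    contig = contig, start = bstart, end = bend)
  out
}

#' BED3 coordinates of a partition
#'
#' @param bins output of [partitionGenome()].
#' @return data.frame with chrom/start/end columns (0-based half-open, the
#'   BED convention).
#' @export
binsToBed <- function(bins) {
  mc <- S4Vectors::mcols(bins)
  data.frame(chrom = as.character(mc$contig),
             start = as.integer(mc$start),
             end = as.integer(mc$end),
             stringsAsFactors = FALSE)
}

#' @describeIn binsToBed write the coordinates as a BED3 file.
#' @param path output path.
#' @export
writeBed <- function(bins, path) {
  bed <- binsToBed(bins)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(nrow(bed))
}
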