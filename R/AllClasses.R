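#' @import methods
NULL

#' Exact k-mer count profile of a sequence
#'
#' Counts of every overlapping length-\code{k} substring of a sequence over
#' its observed alphabet. Substrings containing IUPAC ambiguity codes are
#' counted as literal strings over the extended alphabet; they are never
#' expanded into their ACGT possibilities, so the counts are exact and
#' suitable as the conservation contract of the k-let shuffler.
#'
#' @slot k k-mer order (positive integer).
#' @slot counts named integer vector, one entry per distinct k-mer observed.
#' @slot total sum of counts; equals \code{L - k + 1} for a sequence of
#'   length \code{L >= k}, else 0.
#'
#' @seealso [kmerProfile()]
#' @exportClass KmerProfile
setClass("KmerProfile",
  representation(k = "integer", counts = "integer", total = "integer"))

setValidity("KmerProfile", function(object) {
  if (length(object@k) != 1L || object@k < 1L)
    return("k must be a single positive integer")
  if (length(object@counts) && is.null(names(object@counts)))
    return("counts must be named")
  if (length(object@counts) && any(nchar(names(object@counts)) != object@k))
    return("every k-mer label must have length k")
  if (sum(object@counts) != object@total)
    return("total must equal sum(counts)")
  TRUE
})

#' Sliding-window %GC profile of a sequence
#'
#' The \%GC value of each sliding window of a sequence, used both by the
#' windowed shuffling model and by windowed genomic matching. Windows start
#' at offsets 0, S, 2S, ... and only full-width windows are emitted; a
#' sequence shorter than the window is profiled as one whole-sequence
#' window. The standard deviation is the population (divide-by-n) form:
#' the windows are the complete profile, not a sample.
#'
#' @slot values \%GC per window, each in [0, 100], in genomic order.
#' @slot windowSize window width W in bp.
#' @slot step window step S in bp.
#'
#' @seealso [gcWindowProfile()], [profileMean()], [profileSD()]
#' @exportClass GCWindowProfile
setClass("GCWindowProfile",
  representation(values = "numeric", windowSize = "integer", step = "integer"))

setValidity("GCWindowProfile", function(object) {
  if (length(object@values) < 1L) return("profile must have at least one window")
  if (any(object@values < 0 | object@values > 100))
    return("window %GC values must lie in [0, 100]")
  if (object@windowSize < 1L || object@step < 1L)
    return("windowSize and step must be positive")
  TRUE
})

#' Background pool indexed by 1% GC bins
#'
#' A background sequence pool partitioned into 101 integer \%GC bins
#' (0..100). A record with GC fraction f lives in bin floor(100 f), except
#' f = 1 which lives in bin 100.
#'
#' @slot pool the indexed [Biostrings::DNAStringSet].
#' @slot bins list of 101 integer vectors; element b + 1 holds the pool
#'   indices assigned to bin b.
#'
#' @seealso [buildGCIndex()], [matchGCBin()]
#' @exportClass GCBinIndex
setClass("GCBinIndex",
  representation(pool = "DNAStringSet", bins = "list"))

setValidity("GCBinIndex", function(object) {
  if (length(object@bins) != 101L) return("bins must have 101 elements (0..100)")
  idx <- unlist(object@bins, use.names = FALSE)
  if (length(idx) != length(object@pool))
    return("every pool record must be indexed exactly once")
  if (length(idx) && !setequal(idx, seq_along(object@pool)))
    return("bin contents must be a partition of the pool indices")
  TRUE
})

#' Result of matching one foreground sequence to a background
#'
#' @slot foregroundId identifier of the foreground sequence.
#' @slot poolIndex index of the selected pool record (NA when unmatched).
#' @slot background length-0 or length-1 [Biostrings::DNAStringSet] holding
#'   the selected record.
#' @slot binDistance distance (in 1\% GC bins) between the foreground bin
#'   and the bin the background was drawn from; 0 means an exact-bin match.
#' @slot accepted whether a background was found.
#'
#' @seealso [matchGCBin()], [matchWindowed()]
#' @exportClass MatchResult
setClass("MatchResult",
  representation(foregroundId = "character", poolIndex = "integer",
                 background = "DNAStringSet", binDistance = "integer",
                 accepted = "logical"))

setValidity("MatchResult", function(object) {
  if (object@accepted != (length(object@background) == 1L))
    return("background must be present iff accepted")
  TRUE
})

#' Foreground-vs-background quality-control report
#'
#' The four distribution comparisons (per-sequence \%GC density, IUPAC
#' dinucleotide content, ACGT-only dinucleotide content, sequence-length
#' histogram), each scored with the mean absolute error and three
#' goodness-of-fit statistics: Pearson's chi-squared, the G statistic
#' (log-likelihood ratio) and the Cressie-Read power divergence.
#'
#' @slot metrics data.frame with one row per comparison and the four metric
#'   columns plus the Cressie-Read lambda used.
#' @slot tables named list of per-comparison data.frames (label, counts and
#'   frequencies for both sets) sufficient to regenerate the QC plots.
#' @slot flagged named list of labels where the goodness-of-fit statistics
#'   were undefined (expected 0 with observed > 0); empty when all defined.
#'
#' @seealso [buildQCReport()]
#' @exportClass QCReport
setClass("QCReport",
  representation(metrics = "data.frame", tables = "list", flagged = "list"))

setMethod("show", "KmerProfile", function(object) {
  cat("KmerProfile: k =", object@k, "|", length(object@counts),
      "distinct k-mers |", object@total, "total\n")
})

setMethod("show", "GCWindowProfile", function(object) {
  cat(sprintf("GCWindowProfile: %d windows (W=%d, S=%d) | mean %.2f%% | sd %.2f\n",
              length(object@values), object@windowSize, object@step,
              profileMean(object), profileSD(object)))
})

setMethod("show", "GCBinIndex", function(object) {
  occ <- sum(lengths(object@bins) > 0L)
  cat("GCBinIndex:", length(object@pool), "pool sequences in", occ,
      "occupied 1% GC bins\n")
})

setMethod("show", "MatchResult", function(object) {
  if (object@accepted)
    cat(sprintf("MatchResult: %s -> pool #%d (bin distance %d)\n",
                object@foregroundId, object@poolIndex, object@binDistance))
  else
    cat("MatchResult:", object@foregroundId, "-> unmatched\n")
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport: 4 comparisons x 4 metrics\n")
  print(object@metrics, row.names = FALSE)
  if (length(object@flagged))
    cat("flagged (undefined GOF) comparisons:",
        paste(names(object@flagged), collapse = ", "), "\n")
})
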