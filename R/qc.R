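# Quality control: four foreground-vs-background distribution comparisons
# (%GC density, IUPAC dinucleotides, ACGT dinucleotides, lengths), each
# scored with MAE, Pearson chi-squared, the G statistic and the
# Cressie-Read power divergence.

#' Per-sequence %GC density over 1% bins
#'
#' Relative frequency of sequences per integer GC bin 0..100 (one
#' observation per sequence, not per residue).
#'
#' @param x non-empty [Biostrings::DNAStringSet].
#' @return named numeric vector of length 101 summing to 1.
#' @export
binGCDensity <- function(x) {
  x <- .asSet(x)
  if (length(x) == 0L) stop("no sequences to bin")
  .gcBinCountsVec(x) / length(x)
}

# Integer counts per 1% GC bin, names "0".."100".
.gcBinCountsVec <- function(x) {
  b <- .gcBins(x)
  out <- tabulate(b + 1L, nbins = 101L)
  names(out) <- as.character(0:100)
  out
}

# Pooled dinucleotide counts across records (overlapping, never across
# record boundaries).
.dinucCounts <- function(x, alphabet = c("iupac", "acgt")) {
  alphabet <- match.arg(alphabet)
  x <- .asSet(x)
  if (length(x) == 0L) stop("no sequences to count")
  acc <- integer(0)
  for (s in as.character(x)) {
    L <- nchar(s)
    if (L < 2L) next
    tb <- table(substring(s, 1:(L - 1L), 2:L))
    cnt <- as.integer(tb)
    names(cnt) <- names(tb)
    all <- union(names(acc), names(cnt))
    merged <- integer(length(all))
    names(merged) <- all
    merged[names(acc)] <- acc
    merged[names(cnt)] <- merged[names(cnt)] + cnt
    acc <- merged
  }
  if (alphabet == "acgt")
    acc <- acc[grepl("^[ACGT]{2}$", names(acc))]
  if (length(acc) == 0L || sum(acc) == 0L)
    stop("no valid dinucleotides under alphabet mode '", alphabet, "'")
  acc[order(names(acc))]
}

#' Pooled dinucleotide frequencies
#'
#' Overlapping dinucleotide counts pooled across all records (never
#' counting across record boundaries), normalized to relative frequencies.
#' In `"acgt"` mode dinucleotides containing any ambiguity code are
#' excluded before normalization; in `"iupac"` mode every observed
#' dinucleotide over the extended alphabet is a category.
#'
#' @param x non-empty [Biostrings::DNAStringSet].
#' @param alphabet `"iupac"` or `"acgt"`.
#' @return named numeric vector summing to 1 over the active label set.
#' @export
dinucleotideFrequencies <- function(x, alphabet = c("iupac", "acgt")) {
  cnt <- .dinucCounts(x, alphabet)
  cnt / sum(cnt)
}

#' Sequence-length histogram
#'
#' Relative frequency of records per half-open length bin
#' [i w, (i+1) w).
#'
#' @param x non-empty [Biostrings::DNAStringSet].
#' @param binWidth length bin width in bp (default 10).
#' @return named numeric vector (labels "lo-hi") summing to 1.
#' @export
lengthDistribution <- function(x, binWidth = 10L) {
  x <- .asSet(x)
  if (length(x) == 0L) stop("no sequences")
  cnt <- .lengthBinCounts(x, binWidth)
  cnt / sum(cnt)
}

.lengthBinCounts <- function(x, binWidth = 10L) {
  w <- as.integer(binWidth)
  b <- Biostrings::width(x) %/% w
  tb <- table(b)
  cnt <- as.integer(tb)
  lo <- as.integer(names(tb)) * w
  names(cnt) <- sprintf("%d-%d", lo, lo + w)
  cnt[order(lo)]
}

#' Mean absolute error between two aligned distributions
#'
#' @param observed,expected numeric vectors over the same label set (when
#'   named, labels are aligned and must agree as sets).
#' @return mean of the per-label absolute differences.
#' @export
meanAbsoluteError <- function(observed, expected) {
  al <- .alignLabels(observed, expected)
  mean(abs(al$o - al$e))
}

# Align two per-label vectors on the union of their labels (absent = 0).
.alignLabels <- function(observed, expected) {
  if (is.null(names(observed)) || is.null(names(expected))) {
    if (length(observed) != length(expected))
      stop("unnamed vectors must have equal length")
    return(list(o = as.numeric(observed), e = as.numeric(expected)))
  }
  labs <- union(names(observed), names(expected))
  o <- stats::setNames(numeric(length(labs)), labs)
  e <- o
  o[names(observed)] <- observed
  e[names(expected)] <- expected
  list(o = o, e = e, labels = labs)
}

#' Goodness-of-fit statistics between observed and expected counts
#'
#' Computes Pearson's chi-squared, the G statistic (log-likelihood ratio)
#' and the Cressie-Read power divergence
#' \deqn{CR(\lambda) = \frac{2}{\lambda(\lambda+1)}
#'   \sum_i O_i\left[(O_i/E_i)^\lambda - 1\right],}
#' a one-parameter family containing Pearson's statistic (\eqn{\lambda=1})
#' and the G statistic (\eqn{\lambda \to 0}). The default
#' \eqn{\lambda = 2/3} is the exponent recommended in the Cressie-Read
#' framework. Statistics are reported raw, without p-values: after pooling
#' sparse bins the degrees of freedom are ill-defined, and these are QC
#' metrics, not hypothesis tests.
#'
#' @param observed,expected non-negative per-label vectors; labels present
#'   in only one vector count as 0 in the other.
#' @param lambda Cressie-Read exponent (not 0 or -1).
#' @param rescale rescale `expected` to the observed total first (default
#'   TRUE; the three divergences require matched totals).
#' @return list with `pearson_chi2`, `g_statistic`, `cressie_read`,
#'   `lambda`.
#' @examples
#' gofStatistics(c(10, 20), c(15, 15))
#' @export
gofStatistics <- function(observed, expected, lambda = 2 / 3, rescale = TRUE) {
  if (lambda == 0 || lambda == -1)
    stop("lambda must differ from 0 and -1 (use a small lambda for the G limit)")
  al <- .alignLabels(observed, expected)
  o <- al$o
  e <- al$e
  if (any(o < 0) || any(e < 0)) stop("counts must be non-negative")
  if (rescale && sum(e) > 0) e <- e * sum(o) / sum(e)
  drop <- o == 0 & e == 0
  o <- o[!drop]
  e <- e[!drop]
  offending <- e == 0 & o > 0
  if (any(offending))
    stop("goodness of fit undefined: expected 0 with observed > 0 at label(s) ",
         paste(names(o)[offending], collapse = ", "))
  ratio <- o / e
  g_terms <- ifelse(o > 0, o * log(ratio), 0)
  list(
    pearson_chi2 = sum((o - e)^2 / e),
    g_statistic = 2 * sum(g_terms),
    cressie_read = 2 / (lambda * (lambda + 1)) * sum(o * (ratio^lambda - 1)),
    lambda = lambda)
}

# Merge labels whose expected count is below `minExpected` into one pooled
# cell so sparse categories do not leave the statistics undefined.
.poolSparse <- function(o, e, minExpected = 5) {
  sparse <- e < minExpected
  if (!any(sparse)) return(list(o = o, e = e))
  op <- c(o[!sparse], "(pooled)" = sum(o[sparse]))
  ep <- c(e[!sparse], "(pooled)" = sum(e[sparse]))
  list(o = op, e = ep)
}

#' Build the full foreground-vs-background QC report
#'
#' Runs the four comparisons (per-sequence \%GC density over 1\% bins,
#' pooled dinucleotide content over the IUPAC and the ACGT alphabets,
#' sequence-length histogram) and applies the four metrics to each.
#' Goodness-of-fit statistics are computed on counts with the background
#' rescaled to the foreground total; the MAE is computed on the normalized
#' frequencies. Labels where the expected count is zero but the observed is
#' positive make the three divergence statistics undefined: by default such
#' comparisons get NA statistics and the offending labels are flagged in
#' the report; with `poolSparse = TRUE` cells with expected count below
#' `minExpected` are merged into one pooled cell first.
#'
#' @param foregrounds,backgrounds non-empty [Biostrings::DNAStringSet]s.
#' @param lambda Cressie-Read exponent (default 2/3).
#' @param lengthBinWidth bin width of the length histogram (default 10 bp).
#' @param poolSparse merge sparse cells before the statistics?
#' @param minExpected pooling threshold (expected count, default 5).
#' @return a [QCReport-class].
#' @export
buildQCReport <- function(foregrounds, backgrounds, lambda = 2 / 3,
                          lengthBinWidth = 10L, poolSparse = FALSE,
                          minExpected = 5) {
  fg <- .asSet(foregrounds)
  bg <- .asSet(backgrounds)
  if (length(fg) == 0L || length(bg) == 0L)
    stop("both foreground and background sets must be non-empty")

  comparisons <- list(
    gc_density = list(o = .gcBinCountsVec(fg), e = .gcBinCountsVec(bg)),
    dinucleotide_iupac = list(o = .dinucCounts(fg, "iupac"),
                              e = .dinucCounts(bg, "iupac")),
    dinucleotide_acgt = list(o = .dinucCounts(fg, "acgt"),
                             e = .dinucCounts(bg, "acgt")),
    length = list(o = .lengthBinCounts(fg, lengthBinWidth),
                  e = .lengthBinCounts(bg, lengthBinWidth)))

  rows <- list()
  tables <- list()
  flagged <- list()
  for (nm in names(comparisons)) {
    al <- .alignLabels(comparisons[[nm]]$o, comparisons[[nm]]$e)
    o <- al$o
    e <- al$e
    eScaled <- if (sum(e) > 0) e * sum(o) / sum(e) else e
    tables[[nm]] <- data.frame(
      label = names(o), fg_count = as.numeric(o), bg_count = as.numeric(e),
      bg_expected = as.numeric(eScaled),
      fg_freq = as.numeric(o) / sum(o), bg_freq = as.numeric(e) / sum(e),
      stringsAsFactors = FALSE)
    mae <- meanAbsoluteError(o / sum(o), e / sum(e))
    oo <- o
    ee <- eScaled
    keep <- !(oo == 0 & ee == 0)
    oo <- oo[keep]
    ee <- ee[keep]
    if (poolSparse) {
      pooled <- .poolSparse(oo, ee, minExpected)
      oo <- pooled$o
      ee <- pooled$e
    }
    off <- ee == 0 & oo > 0
    if (any(off)) {
      flagged[[nm]] <- names(oo)[off]
      gof <- list(pearson_chi2 = NA_real_, g_statistic = NA_real_,
                  cressie_read = NA_real_)
    } else {
      gof <- gofStatistics(oo, ee, lambda = lambda, rescale = FALSE)
    }
    rows[[nm]] <- data.frame(
      comparison = nm, mae = mae, pearson_chi2 = gof$pearson_chi2,
      g_statistic = gof$g_statistic, cressie_read = gof$cressie_read,
      lambda = lambda, stringsAsFactors = FALSE)
  }
  new("QCReport", metrics = do.call(rbind, c(rows, make.row.names = FALSE)),
      tables = tables, flagged = flagged)
}

#' @describeIn buildQCReport the 4-comparison x 4-metric table.
#' @param report a [QCReport-class].
#' @export
qcMetrics <- function(report) report@metrics

#' @describeIn buildQCReport the per-comparison plot-data tables.
#' @export
qcTables <- function(report) report@tables

#' @describeIn buildQCReport labels with undefined statistics, per
#'   comparison.
#' @export
qcFlagged <- function(report) report@flagged

#' @describeIn buildQCReport write the report as JSON metrics plus one TSV
#'   of plot data per comparison under `dir`.
#' @param dir output directory (created if missing).
#' @export
writeQCReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(
    list(metrics = report@metrics, flagged = report@flagged),
    file.path(dir, "qc_metrics.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(report@tables))
    utils::write.table(report@tables[[nm]],
                       file.path(dir, paste0("qc_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, "qc_metrics.json"))
}
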