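# Genomic background models: global 1%-GC-bin matching and windowed
# %GC-distribution matching against a pool of real genomic sequences.

#' Index a background pool by 1% GC bins
#'
#' Assigns every pool sequence to one of 101 integer \%GC bins (0..100):
#' bin floor(100 f) for GC fraction f, with f = 1 in bin 100.
#'
#' @param pool non-empty [Biostrings::DNAStringSet] of background
#'   candidates (e.g. the output of [partitionGenome()]).
#' @return a [GCBinIndex-class].
#' @export
buildGCIndex <- function(pool) {
  pool <- .asSet(pool)
  if (length(pool) == 0L)
    stop("background pool is empty: no background sequences available")
  b <- .gcBins(pool)
  bins <- unname(split(seq_along(pool), factor(b, levels = 0:100)))
  new("GCBinIndex", pool = pool, bins = bins)
}

#' @describeIn buildGCIndex number of indexed pool records.
#' @param index a [GCBinIndex-class].
#' @export
poolSize <- function(index) length(index@pool)

#' @describeIn buildGCIndex integer vector of per-bin record counts
#'   (names "0".."100").
#' @export
binCounts <- function(index) {
  out <- lengths(index@bins)
  names(out) <- as.character(0:100)
  out
}

# Draw one pool index for a foreground in bin b: the exact bin first, then
# an expanding ring search over bins at distance 1, 2, ... <= maxDist,
# pooling bin b-d and bin b+d before sampling so ties are broken uniformly.
.drawFromBins <- function(bins, b, maxDist) {
  for (d in 0:maxDist) {
    lo <- b - d
    hi <- b + d
    cand <- integer(0)
    if (lo >= 0L) cand <- bins[[lo + 1L]]
    if (d > 0L && hi <= 100L) cand <- c(cand, bins[[hi + 1L]])
    if (length(cand))
      return(list(idx = cand[sample.int(length(cand), 1L)], dist = d))
  }
  list(idx = NA_integer_, dist = NA_integer_)
}

.matchResult <- function(fgId, pool, idx, dist) {
  if (is.na(idx))
    new("MatchResult", foregroundId = fgId, poolIndex = NA_integer_,
        background = Biostrings::DNAStringSet(),
        binDistance = NA_integer_, accepted = FALSE)
  else
    new("MatchResult", foregroundId = fgId, poolIndex = as.integer(idx),
        background = pool[idx], binDistance = as.integer(dist),
        accepted = TRUE)
}

#' Match a foreground sequence to a background from the same 1% GC bin
#'
#' Returns a uniformly random member of the foreground's GC bin. When that
#' bin is empty the search expands ring-wise to bins at distance 1, 2, ...
#' up to `maxBinDistance`, and the distance used is reported so match
#' quality can be audited; failure is expressed as `accepted = FALSE`,
#' never as an error.
#'
#' @param foreground a single foreground sequence.
#' @param index a [GCBinIndex-class] built from the pool.
#' @param maxBinDistance furthest bin distance searched (default 100,
#'   effectively unbounded).
#' @param seed optional integer seed.
#' @return a [MatchResult-class].
#' @export
matchGCBin <- function(foreground, index, maxBinDistance = 100L, seed = NULL) {
  fg <- .asSet(foreground)
  if (length(fg) != 1L) stop("foreground must be a single sequence")
  b <- .gcBins(fg)
  .withSeed(seed, function() {
    hit <- .drawFromBins(index@bins, b, as.integer(maxBinDistance))
    .matchResult(seqIds(fg), index@pool, hit$idx, hit$dist)
  })
}

# Logical acceptance vector for windowed matching: candidate i is accepted
# when every window %GC of its profile lies within the foreground band
# [mean - m*sd, mean + m*sd]. A tiny epsilon absorbs float noise so the
# sd = 0 degenerate band still accepts exact-equality candidates.
.windowedAccept <- function(fgProfile, poolProfiles, sdMultiplier) {
  m <- profileMean(fgProfile)
  s <- profileSD(fgProfile)
  lo <- m - sdMultiplier * s - 1e-9
  hi <- m + sdMultiplier * s + 1e-9
  vapply(poolProfiles, function(p) all(p >= lo & p <= hi), logical(1))
}

#' Which pool candidates fall inside a foreground's %GC band?
#'
#' The acceptance rule of the windowed genomic model, exposed on its own:
#' a candidate is accepted when all of its sliding-window \%GC values lie
#' within the foreground's mean +/- `sdMultiplier` * sd band. Acceptance is
#' monotone in `sdMultiplier`.
#'
#' @inheritParams matchWindowed
#' @return logical vector, one element per pool sequence.
#' @export
windowedCandidates <- function(foreground, pool, sdMultiplier = 2.6,
                               windowSize = 100L, step = 50L) {
  fg <- .asSet(foreground)
  if (length(fg) != 1L) stop("foreground must be a single sequence")
  pool <- .asSet(pool)
  P <- gcWindowProfile(fg, windowSize, step)
  profs <- lapply(seq_along(pool), function(i)
    profileValues(gcWindowProfile(pool[[i]], windowSize, step)))
  .windowedAccept(P, profs, sdMultiplier)
}

#' Match a foreground sequence by sliding-window %GC distribution
#'
#' Computes the foreground's sliding-window \%GC profile and accepts a pool
#' candidate when every one of the candidate's window values lies within
#' the foreground band mean +/- `sdMultiplier` * sd (population sd over the
#' foreground windows; default multiplier 2.6). The returned background is
#' a uniformly random accepted candidate.
#'
#' @param foreground a single foreground sequence.
#' @param pool non-empty [Biostrings::DNAStringSet] of candidates.
#' @param sdMultiplier width of the acceptance band in foreground sds.
#' @param windowSize,step sliding-window parameters (defaults 100/50 bp).
#' @param seed optional integer seed.
#' @return a [MatchResult-class]; `accepted = FALSE` when no candidate
#'   qualifies.
#' @export
matchWindowed <- function(foreground, pool, sdMultiplier = 2.6,
                          windowSize = 100L, step = 50L, seed = NULL) {
  pool <- .asSet(pool)
  if (length(pool) == 0L) stop("background pool is empty")
  acc <- which(windowedCandidates(foreground, pool, sdMultiplier,
                                  windowSize, step))
  fg <- .asSet(foreground)
  .withSeed(seed, function() {
    if (length(acc) == 0L)
      .matchResult(seqIds(fg), pool, NA_integer_, NA_integer_)
    else
      .matchResult(seqIds(fg), pool, acc[sample.int(length(acc), 1L)], 0L)
  })
}

#' Generate a genomic background set matched to a foreground set
#'
#' Batch driver for the two genomic models. Mode `"global"` draws from the
#' foreground's 1\% GC bin (with ring fallback); mode `"windowed"` applies
#' the sliding-window band criterion. Sampling is with replacement by
#' default, since pools pre-binned at one size can be smaller than the
#' foreground set; `withReplacement = FALSE` removes each chosen record so
#' no pool sequence is emitted twice.
#'
#' @param foregrounds [Biostrings::DNAStringSet] of foreground sequences.
#' @param pool non-empty [Biostrings::DNAStringSet] of candidates.
#' @param mode `"global"` or `"windowed"`.
#' @param sdMultiplier,windowSize,step windowed-mode parameters.
#' @param maxBinDistance global-mode ring-search limit.
#' @param withReplacement may one pool record serve several foregrounds?
#' @param seed optional integer seed; selection is deterministic given it.
#' @return list with `backgrounds` (a DNAStringSet whose headers encode the
#'   source pool record and the matched foreground), `results` (one row per
#'   foreground: ids, bin distance, acceptance), and `unmatched` (ids of
#'   foregrounds with no acceptable background).
#' @export
generateMatchedSet <- function(foregrounds, pool,
                               mode = c("global", "windowed"),
                               sdMultiplier = 2.6, windowSize = 100L,
                               step = 50L, maxBinDistance = 100L,
                               withReplacement = TRUE, seed = NULL) {
  mode <- match.arg(mode)
  foregrounds <- .asSet(foregrounds)
  pool <- .asSet(pool)
  if (length(pool) == 0L)
    stop("background pool is empty: no background sequences available")
  n <- length(foregrounds)
  fgIds <- seqIds(foregrounds)
  poolIds <- seqIds(pool)

  chosen <- rep(NA_integer_, n)
  dist <- rep(NA_integer_, n)

  if (mode == "global") {
    bins <- buildGCIndex(pool)@bins
    fgBins <- .gcBins(foregrounds)
    for (i in seq_len(n)) {
      hit <- .withSeed(.deriveSeed(seed, i), function()
        .drawFromBins(bins, fgBins[i], as.integer(maxBinDistance)))
      chosen[i] <- hit$idx
      dist[i] <- hit$dist
      if (!withReplacement && !is.na(hit$idx)) {
        b <- .gcBins(pool[hit$idx]) + 1L
        bins[[b]] <- bins[[b]][bins[[b]] != hit$idx]
      }
    }
  } else {
    W <- as.integer(windowSize)
    S <- as.integer(step)
    poolProfs <- lapply(seq_along(pool), function(i)
      profileValues(gcWindowProfile(pool[[i]], W, S)))
    available <- rep(TRUE, length(pool))
    for (i in seq_len(n)) {
      P <- gcWindowProfile(foregrounds[[i]], W, S)
      acc <- which(.windowedAccept(P, poolProfs, sdMultiplier) & available)
      if (length(acc)) {
        chosen[i] <- .withSeed(.deriveSeed(seed, i), function()
          acc[sample.int(length(acc), 1L)])
        dist[i] <- 0L
        if (!withReplacement) available[chosen[i]] <- FALSE
      }
    }
  }

  ok <- !is.na(chosen)
  bg <- pool[chosen[ok]]
  if (length(bg)) {
    names(bg) <- .makeHeader(
      sprintf("%s_bg_for_%s", poolIds[chosen[ok]], fgIds[ok]),
      sprintf("model=%s source=%s matched_to=%s bin_distance=%d",
              if (mode == "global") "g" else "c",
              poolIds[chosen[ok]], fgIds[ok], dist[ok]))
  }
  list(
    backgrounds = bg,
    results = data.frame(
      foreground_id = fgIds,
      background_id = ifelse(ok, poolIds[chosen], NA_character_),
      bin_distance = dist,
      accepted = ok,
      stringsAsFactors = FALSE),
    unmatched = fgIds[!ok])
}
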