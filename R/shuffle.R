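# Synthetic background models: global k-let shuffling and sliding-window
# k-let shuffling. The shuffle is the Euler-path construction on the de
# Bruijn multigraph of (k-1)-lets: every output conserves the input's exact
# k-let counts (and hence all j-let counts for j <= k).

# Shuffle a character vector of residues preserving exact k-let counts.
# k >= length returns the input unchanged (a single k-let, or none, admits
# no rearrangement). Ambiguity codes are ordinary alphabet symbols.
.kletShuffleChars <- function(chars, k) {
  L <- length(chars)
  if (k >= L) return(chars)
  if (k == 1L) return(chars[sample.int(L)])

  # Vertices are the (k-1)-lets at positions 1..m; edges are the k-lets,
  # edge i going vertex i -> vertex i+1 and emitting chars[i + k - 1].
  s <- paste(chars, collapse = "")
  m <- L - k + 2L
  vlab <- substring(s, 1:m, (k - 1L):L)
  vf <- factor(vlab)
  vid <- as.integer(vf)
  nv <- nlevels(vf)
  ne <- m - 1L
  eto <- vid[2:m]
  echar <- chars[k:L]
  root <- vid[m]

  outList <- vector("list", nv)
  sp <- split(seq_len(ne), vid[1:ne])
  outList[as.integer(names(sp))] <- sp

  # Uniformly random arborescence toward the root via Wilson's algorithm
  # (loop-erased random walk, successor drawn uniformly over the out-edge
  # multiset). Every non-root vertex can reach the root along the original
  # walk, so the chain is absorbed with probability 1.
  inTree <- logical(nv)
  inTree[root] <- TRUE
  nxt <- integer(nv)
  for (u in seq_len(nv)) {
    x <- u
    while (!inTree[x]) {
      es <- outList[[x]]
      e <- es[sample.int(length(es), 1L)]
      nxt[x] <- e
      x <- eto[e]
    }
    x <- u
    while (!inTree[x]) {
      inTree[x] <- TRUE
      x <- eto[nxt[x]]
    }
  }

  # Per-vertex edge order: non-tree edges in random order, the tree edge
  # last (the root's edges are all randomly ordered). The Eulerian walk
  # from the first (k-1)-let then consumes every edge exactly once.
  ordering <- vector("list", nv)
  for (u in seq_len(nv)) {
    es <- outList[[u]]
    if (is.null(es)) next
    if (u == root) {
      ordering[[u]] <- es[sample.int(length(es))]
    } else {
      rest <- es[-match(nxt[u], es)]
      if (length(rest) > 1L) rest <- rest[sample.int(length(rest))]
      ordering[[u]] <- c(rest, nxt[u])
    }
  }

  ptr <- rep.int(1L, nv)
  cur <- vid[1L]
  emitted <- character(ne)
  for (i in seq_len(ne)) {
    e <- ordering[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    emitted[i] <- echar[e]
    cur <- eto[e]
  }
  c(chars[seq_len(k - 1L)], emitted)
}

#' Shuffle a sequence preserving its exact k-let composition
#'
#' For k >= 2 a uniformly random arborescence toward the terminal
#' (k-1)-let fixes the last exit edge of every vertex of the de Bruijn
#' multigraph, remaining out-edges are randomly ordered, and the Eulerian
#' walk from the first (k-1)-let spells the output; for k = 1 the residues
#' are uniformly permuted. The output has the same length and exactly the
#' same j-let counts as the input for every j <= k; its first and last
#' (k-1)-lets equal the input's.
#'
#' @param x sequence(s): character vector, [Biostrings::DNAString], or
#'   [Biostrings::DNAStringSet] (shuffled element-wise).
#' @param k k-let order; `k` greater than a sequence's length leaves that
#'   sequence unchanged.
#' @param seed optional integer seed for reproducibility.
#' @return same type as `x`.
#' @examples
#' kletShuffle("ACGTACGTAA", k = 2, seed = 1)
#' @export
kletShuffle <- function(x, k, seed = NULL) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  .withSeed(seed, function() {
    if (is.character(x))
      return(vapply(x, function(s)
        paste(.kletShuffleChars(strsplit(s, "")[[1L]], k), collapse = ""),
        character(1), USE.NAMES = FALSE))
    if (is(x, "XString"))
      return(Biostrings::DNAString(paste(
        .kletShuffleChars(strsplit(as.character(x), "")[[1L]], k),
        collapse = "")))
    xs <- .asSet(x)
    out <- vapply(as.character(xs), function(s)
      paste(.kletShuffleChars(strsplit(s, "")[[1L]], k), collapse = ""),
      character(1), USE.NAMES = FALSE)
    res <- Biostrings::DNAStringSet(out)
    names(res) <- names(xs)
    res
  })
}

# Windowed shuffle over a character vector. Windows are visited left to
# right and shuffled IN PLACE, so regions covered by several windows are
# re-shuffled by each later window; local k-let counts are therefore only
# guaranteed for the last window touching a region, while global 1-let
# counts are conserved exactly. Residues past the last full window are
# shuffled as a short tail window (unchanged if shorter than k).
.windowShuffleChars <- function(chars, k, W, S) {
  L <- length(chars)
  if (L <= W) return(.kletShuffleChars(chars, k))
  offs <- seq.int(0L, L - W, by = S)
  for (o in offs) {
    idx <- (o + 1L):(o + W)
    chars[idx] <- .kletShuffleChars(chars[idx], k)
  }
  lastOff <- offs[length(offs)]
  if (lastOff + W < L) {
    ts <- lastOff + S
    idx <- (ts + 1L):L
    chars[idx] <- .kletShuffleChars(chars[idx], k)
  }
  chars
}

#' Shuffle a sequence within a sliding window
#'
#' Conserves local k-let composition: each window of width `windowSize`
#' (default 100 bp), advancing by `step` (default 50 bp), is k-let-shuffled
#' in place in the current, partially shuffled sequence. A sequence no
#' longer than the window is equivalent to a global [kletShuffle()].
#' Global mononucleotide counts are always conserved exactly.
#'
#' @inheritParams kletShuffle
#' @param windowSize window width W in bp; must be >= k.
#' @param step window step S in bp.
#' @return same type as `x`.
#' @export
windowShuffle <- function(x, k, windowSize = 100L, step = 50L, seed = NULL) {
  k <- as.integer(k)
  W <- as.integer(windowSize)
  S <- as.integer(step)
  if (k < 1L) stop("k must be >= 1")
  if (W < k) stop("windowSize must be >= k so every window can be shuffled")
  if (S < 1L) stop("step must be >= 1")
  .withSeed(seed, function() {
    shuf1 <- function(s)
      paste(.windowShuffleChars(strsplit(s, "")[[1L]], k, W, S), collapse = "")
    if (is.character(x))
      return(vapply(x, shuf1, character(1), USE.NAMES = FALSE))
    if (is(x, "XString"))
      return(Biostrings::DNAString(shuf1(as.character(x))))
    xs <- .asSet(x)
    res <- Biostrings::DNAStringSet(
      vapply(as.character(xs), shuf1, character(1), USE.NAMES = FALSE))
    names(res) <- names(xs)
    res
  })
}

#' Generate a shuffled background set
#'
#' Batch driver for the two synthetic models: emits `replicates` shuffled
#' background sequences per foreground sequence, with provenance recorded
#' in the FASTA description. Each record is shuffled under its own
#' sub-stream derived from `seed` and the record's position, so output is
#' deterministic given the seed.
#'
#' @param x foreground [Biostrings::DNAStringSet].
#' @param k k-let order.
#' @param mode `"global"` ([kletShuffle()]) or `"windowed"`
#'   ([windowShuffle()]).
#' @param windowSize,step windowed-mode parameters.
#' @param replicates background sequences per foreground sequence.
#' @param seed optional integer seed.
#' @return a [Biostrings::DNAStringSet] of `replicates * length(x)`
#'   records; identifiers are the input identifier plus a replicate suffix.
#' @export
generateShuffledSet <- function(x, k, mode = c("global", "windowed"),
                                windowSize = 100L, step = 50L,
                                replicates = 1L, seed = NULL) {
  mode <- match.arg(mode)
  x <- .asSet(x)
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("replicates must be >= 1")
  ids <- seqIds(x)
  n <- length(x)
  out <- character(n * replicates)
  hdr <- character(n * replicates)
  j <- 0L
  for (i in seq_len(n)) {
    s <- as.character(x[[i]])
    for (r in seq_len(replicates)) {
      j <- j + 1L
      sub <- .deriveSeed(seed, j)
      out[j] <- if (mode == "global")
        kletShuffle(s, k, seed = sub)
      else
        windowShuffle(s, k, windowSize = windowSize, step = step, seed = sub)
      hdr[j] <- .makeHeader(
        sprintf("%s_shuffled_%d", ids[i], r),
        sprintf("model=%s k=%d%s source=%s",
                if (mode == "global") "k" else "w", k,
                if (mode == "windowed")
                  sprintf(" W=%d S=%d", as.integer(windowSize), as.integer(step))
                else "",
                ids[i]))
    }
  }
  res <- Biostrings::DNAStringSet(out)
  names(res) <- hdr
  res
}
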