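# Build a sequence from %GC-per-window specs: each window is `width` bp
# with exactly gc G residues, so its window %GC is 100*gc/width.
seqFromWindowGC <- function(gcPerWindow, width = 10L) {
  paste(vapply(gcPerWindow, function(g)
    paste(c(rep("G", g), rep("A", width - g)), collapse = ""),
    character(1)), collapse = "")
}

test_that("buildGCIndex assigns records by the floor(100*gc) rule", {
  pool <- Biostrings::DNAStringSet(c(s1 = "AATT", s2 = "ACGT", s3 = "GGCC"))
  idx <- buildGCIndex(pool)
  cnt <- binCounts(idx)
  expect_equal(unname(cnt[c("0", "50", "100")]), c(1L, 1L, 1L))
  expect_equal(sum(cnt), 3L)
  expect_equal(poolSize(idx), 3L)

  # gc fraction 0.505 (101 GC in 200) -> bin 50, not 51
  s <- paste(c(rep("G", 101), rep("A", 99)), collapse = "")
  idx2 <- buildGCIndex(Biostrings::DNAStringSet(c(x = s)))
  expect_equal(unname(binCounts(idx2)["50"]), 1L)

  # all-identical pool collapses into one bin
  idx3 <- buildGCIndex(Biostrings::DNAStringSet(rep("ACGT", 5)))
  expect_equal(unname(binCounts(idx3)["50"]), 5L)

  expect_error(buildGCIndex(Biostrings::DNAStringSet()), "empty")
})

test_that("matchGCBin draws from the exact bin when available", {
  pool <- Biostrings::DNAStringSet(c(only = "ACGTACGT"))
  idx <- buildGCIndex(pool)
  res <- matchGCBin("TGCA", idx, seed = 1)
  expect_true(res@accepted)
  expect_equal(res@binDistance, 0L)
  expect_equal(seqIds(res@background), "only")
})

test_that("empty bins trigger an expanding ring search with distance audit", {
  # pool occupies bin 52 only; foreground in bin 50 must fall back there
  pool <- Biostrings::DNAStringSet(
    c(far = paste(c(rep("G", 52), rep("A", 48)), collapse = "")))
  idx <- buildGCIndex(pool)
  res <- matchGCBin("ACGTACGTAC", idx, seed = 1)  # bin 50
  expect_true(res@accepted)
  expect_equal(res@binDistance, 2L)

  # search range exhausted -> accepted = FALSE, never an error
  res0 <- matchGCBin("ACGTACGTAC", idx, maxBinDistance = 1, seed = 1)
  expect_false(res0@accepted)
  expect_length(res0@background, 0)
})

test_that("every distance-0 match shares the foreground's GC bin", {
  set.seed(3)
  pool <- saturatedPool(perBin = 2)
  idx <- buildGCIndex(pool)
  fg <- simulateForeground(60, c(100, 100), gcRange = c(0.05, 0.95), seed = 8)
  for (i in seq_along(fg)) {
    res <- matchGCBin(fg[i], idx, seed = 100 + i)
    expect_true(res@accepted)
    expect_equal(res@binDistance, 0L)
    expect_equal(floor(100 * gcFraction(res@background)),
                 floor(100 * gcFraction(fg[i])))
  }
})

test_that("windowed band acceptance follows the mean +/- m*sd rule", {
  # foreground windows 40/50/60 %GC: mean 50, population sd sqrt(200/3),
  # band at m = 2.6 is [28.77, 71.23]
  fg <- seqFromWindowGC(c(4, 5, 6))
  pool <- Biostrings::DNAStringSet(c(
    inband = seqFromWindowGC(c(3, 7)),    # windows 30, 70 -> accepted
    outband = seqFromWindowGC(c(2, 5))))  # window 20 below the band
  acc <- windowedCandidates(fg, pool, sdMultiplier = 2.6,
                            windowSize = 10, step = 10)
  expect_equal(unname(acc), c(TRUE, FALSE))

  res <- matchWindowed(fg, pool, sdMultiplier = 2.6, windowSize = 10,
                       step = 10, seed = 1)
  expect_true(res@accepted)
  expect_equal(seqIds(res@background), "inband")
  expect_equal(res@binDistance, 0L)
})

test_that("the sd = 0 degenerate band accepts only exact-mean candidates", {
  fg <- seqFromWindowGC(c(5, 5, 5))  # every window 50% -> sd 0
  pool <- Biostrings::DNAStringSet(c(
    exact = seqFromWindowGC(c(5, 5)),
    off = seqFromWindowGC(c(5, 6))))
  acc <- windowedCandidates(fg, pool, sdMultiplier = 2.6,
                            windowSize = 10, step = 10)
  expect_equal(unname(acc), c(TRUE, FALSE))
})

test_that("a foreground always accepts itself as candidate", {
  set.seed(15)
  for (i in 1:5) {
    fg <- simulateForeground(1, c(150, 300), gcGradient = c(0.3, 0.7),
                             seed = i)
    res <- matchWindowed(fg, fg, windowSize = 50, step = 25, seed = i)
    expect_true(res@accepted)
  }
})

test_that("windowed acceptance is monotone in the sd multiplier", {
  set.seed(23)
  for (i in 1:10) {
    fg <- simulateForeground(1, c(200, 400), gcGradient = c(0.35, 0.65),
                             seed = 2 * i)
    pool <- simulateForeground(30, c(200, 400), gcRange = c(0.2, 0.8),
                               seed = 2 * i + 1)
    m <- sort(runif(2, 0.1, 5))
    a1 <- windowedCandidates(fg, pool, sdMultiplier = m[1],
                             windowSize = 50, step = 25)
    a2 <- windowedCandidates(fg, pool, sdMultiplier = m[2],
                             windowSize = 50, step = 25)
    expect_true(all(a2[a1]))  # accepted at m1 => accepted at m2 >= m1
  }
})

test_that("generateMatchedSet matches every foreground and is deterministic", {
  set.seed(2)
  pool <- saturatedPool(perBin = 2)
  fg <- simulateForeground(25, c(100, 100), gcRange = c(0.1, 0.9), seed = 3)
  res <- generateMatchedSet(fg, pool, mode = "global", seed = 7)
  expect_length(res$backgrounds, 25)
  expect_length(res$unmatched, 0)
  expect_true(all(res$results$bin_distance == 0))
  again <- generateMatchedSet(fg, pool, mode = "global", seed = 7)
  expect_identical(as.character(res$backgrounds),
                   as.character(again$backgrounds))
  # headers encode source pool record and matched foreground
  expect_match(seqDescs(res$backgrounds)[1], "matched_to=fg1")
})

test_that("without replacement no pool record is emitted twice", {
  pool <- Biostrings::DNAStringSet(
    stats::setNames(rep("ACGTACGT", 5), sprintf("p%d", 1:5)))
  fg <- Biostrings::DNAStringSet(
    stats::setNames(rep("TGCATGCA", 8), sprintf("f%d", 1:8)))
  res <- generateMatchedSet(fg, pool, mode = "global",
                            withReplacement = FALSE, maxBinDistance = 0,
                            seed = 4)
  expect_length(res$backgrounds, 5)
  expect_length(res$unmatched, 3)
  used <- res$results$background_id[res$results$accepted]
  expect_false(any(duplicated(used)))

  # windowed mode honors the same exhaustion rule
  resW <- generateMatchedSet(fg, pool, mode = "windowed",
                             withReplacement = FALSE, seed = 4)
  usedW <- resW$results$background_id[resW$results$accepted]
  expect_false(any(duplicated(usedW)))
  expect_length(resW$backgrounds, 5)
})

test_that("a GC-disjoint pool with no fallback leaves all unmatched", {
  pool <- Biostrings::DNAStringSet(c(p1 = "GGGGGGGG"))
  fg <- Biostrings::DNAStringSet(c(f1 = "AAAAAAAA", f2 = "AATTAATT"))
  res <- generateMatchedSet(fg, pool, mode = "global", maxBinDistance = 0,
                            seed = 1)
  expect_length(res$backgrounds, 0)
  expect_setequal(res$unmatched, c("f1", "f2"))
  expect_error(generateMatchedSet(fg, Biostrings::DNAStringSet()), "empty")
})
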