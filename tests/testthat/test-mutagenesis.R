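test_that("mutant scan differentials are exact under an additive oracle", {
  sc <- demoScaffold()
  gt <- linearOracle(sc, sd = 0.1)
  obj <- designObjective("activity")
  set.seed(60)
  s <- sampleSequence(sc, 1L)
  prof <- singleMutantScan(s, oracleScorer(gt), obj, scaffold = sc)
  codes <- match(strsplit(s, "")[[1L]], c("A", "C", "G", "T"))
  w <- gt@positionWeights
  for (p in c(1L, 5L, 50L, 109L)) {
    for (b in seq_len(4L)[-codes[p]]) {
      expect_equal(prof@diffs[b, p], w[b, p] - w[codes[p], p],
                   tolerance = 1e-12)
    }
    expect_true(is.na(prof@diffs[codes[p], p]))
    # position score is the largest predicted loss
    expect_equal(prof@positionScore[p],
                 max(-(prof@diffs[, p]), na.rm = TRUE),
                 tolerance = 1e-12)
  }
  # constant oracle: all differentials zero
  flat <- function(seqs) rep(1.5, length(seqs))
  prof0 <- singleMutantScan(s, flat, obj, scaffold = sc)
  expect_true(all(prof0@diffs[!is.na(prof0@diffs)] == 0))
  expect_true(all(prof0@positionScore == 0))
})

test_that("positionImportance normalizes mean scores to a max of one", {
  sc <- demoScaffold()
  gt <- linearOracle(sc, sd = 0.1)
  obj <- designObjective("activity")
  set.seed(61)
  profs <- lapply(sampleSequence(sc, 4L), singleMutantScan,
                  model = oracleScorer(gt), objective = obj,
                  scaffold = sc)
  imp <- positionImportance(profs)
  expect_equal(max(imp$importance), 1)
  expect_true(all(imp$importance >= 0 & imp$importance <= 1))
  # invariant under uniform rescaling of the oracle
  gt2 <- GroundTruthModel(gt@positionWeights * 3)
  profs2 <- lapply(vapply(profs, function(p) p@sequence, ""),
                   singleMutantScan, model = oracleScorer(gt2),
                   objective = obj, scaffold = sc)
  expect_equal(positionImportance(profs2)$importance, imp$importance,
               tolerance = 1e-9)
  # single profile: normalized copy of its own (floored) position scores
  one <- positionImportance(profs[1L])
  ps <- pmax(profs[[1L]]@positionScore, 0)
  expect_equal(one$importance, ps / max(ps))
})

test_that("lowScoreBlocks finds planted loss motifs and obeys the quantile", {
  sc <- LibraryScaffold("flat", list(randomSegment(100L)))
  # planted 10-bp strong-loss region, flat elsewhere
  planted <- function(strength) {
    function(seqs) {
      vapply(seqs, function(s) {
        ch <- strsplit(s, "")[[1L]]
        sum(ch[41:50] == "A") * strength
      }, 1, USE.NAMES = FALSE)
    }
  }
  obj <- designObjective("activity")
  s <- paste0(strrep("C", 40L), strrep("A", 10L), strrep("C", 50L))
  prof <- singleMutantScan(s, planted(0.5), obj, scaffold = sc)
  res <- lowScoreBlocks(list(prof), minLen = 6L, selectFraction = 0.10)
  expect_length(res$blocks[[1L]], 1L)
  expect_equal(IRanges::start(res$blocks[[1L]]), 41L)
  expect_equal(IRanges::end(res$blocks[[1L]]), 50L)
  # flat profile yields no blocks
  profFlat <- singleMutantScan(s, function(x) rep(0, length(x)), obj,
                               scaffold = sc)
  resFlat <- lowScoreBlocks(list(profFlat), selectFraction = 0.05)
  expect_length(resFlat$blocks[[1L]], 0L)

  # threshold selects ~ the requested fraction; brute-force run scan
  gt <- linearOracle(sc, sd = 0.2, seed = 13L)
  set.seed(62)
  profs <- lapply(sampleSequence(sc, 5L), singleMutantScan,
                  model = oracleScorer(gt), objective = obj,
                  scaffold = sc)
  res2 <- lowScoreBlocks(profs, minLen = 3L, selectFraction = 0.05)
  vals <- unlist(lapply(profs, function(p)
    apply(p@diffs, 2L, min, na.rm = TRUE)))
  frac <- mean(vals < res2$threshold)
  expect_lte(abs(frac - 0.05), 1 / 100 + 1e-9)
  bruteRuns <- function(below, minLen) {
    r <- rle(below)
    ends <- cumsum(r$lengths)
    keep <- r$values & r$lengths >= minLen
    cbind(start = (ends - r$lengths + 1L)[keep], end = ends[keep])
  }
  for (i in seq_along(profs)) {
    below <- apply(profs[[i]]@diffs, 2L, min, na.rm = TRUE) <
      res2$threshold
    want <- bruteRuns(below, 3L)
    got <- res2$blocks[[i]]
    expect_identical(IRanges::start(got), unname(want[, "start"]))
    expect_identical(IRanges::end(got), unname(want[, "end"]))
  }
})

test_that("repeatDifferential locates TA repeats and recovers their effect", {
  sc <- demoScaffold()
  gt <- demoGroundTruth(sc)      # +0.10 per overlapping TATATA
  obj <- designObjective("activity")
  # regex oracle for the longest repeat
  base <- strrep("C", 40L)
  s6 <- paste0("TATATA", strrep("C", 34L))
  hit <- PromoterForge:::.longestRepeat(s6, "TA")
  expect_equal(c(IRanges::start(hit), IRanges::width(hit)), c(1L, 6L))
  # partial trailing unit ignored: TATATAT -> 6 bases
  hit2 <- PromoterForge:::.longestRepeat(paste0("TATATAT",
                                                strrep("C", 33L)), "TA")
  expect_equal(IRanges::width(hit2), 6L)

  mk <- function(spacer) {
    set.seed(63)
    rest <- substr(sampleSequence(sc, 1L), 41L, 110L)
    paste0(spacer, rest)
  }
  seqs <- c(mk(paste0(strrep("C", 10L), "TATATA", strrep("C", 24L))),
            mk(paste0(strrep("A", 6L), "TATATATA", strrep("C", 26L))),
            mk(base))                      # no repeat: baseline only
  profs <- lapply(seqs, singleMutantScan, model = oracleScorer(gt),
                  objective = obj, scaffold = sc)
  res <- repeatDifferential(profs, sc)
  expect_identical(res$byLength$length, c(6L, 8L))
  # mutations inside repeats lose the planted bonus: medians below
  # the non-repeat baseline
  expect_true(all(res$byLength$median < res$baseline))
  expect_identical(res$perSequence$length, c(6L, 8L, 0L))
})

test_that("siteExtensionDifferential separates GCTA extensions", {
  sc <- demoScaffold()
  gt <- demoGroundTruth(sc)      # +0.15 for GCGTGGGCGGCTA
  obj <- designObjective("activity")
  st <- segmentTable(sc)
  site <- st[st$kind == "constant" & st$sequence == "GCGTGGGCG", ]
  set.seed(64)
  tmpl <- sampleSequence(sc, 2L)
  withExt <- tmpl[1L]
  substr(withExt, site$end + 1L, site$end + 4L) <- "GCTA"
  without <- tmpl[2L]
  substr(without, site$end + 1L, site$end + 4L) <- "CCCC"
  profs <- lapply(c(withExt, without), singleMutantScan,
                  model = oracleScorer(gt), objective = obj,
                  scaffold = sc)
  res <- siteExtensionDifferential(profs, sc)
  expect_identical(nrow(res), 2L)
  medExt <- res$median[res$extension]
  medNon <- res$median[!res$extension]
  expect_lt(medExt, medNon)      # extension mutations lose the bonus
  expect_lt(medExt, 0)
  # classification agrees with direct string comparison
  expect_identical(res$n[res$extension], 1L)
})

test_that("frequencyMatrix counts bases per column", {
  seqs <- rep("ACGT", 5L)
  fm <- frequencyMatrix(seqs)
  expect_equal(unname(fm), diag(4L) * 5L)
  expect_true(all(colSums(fm) == 5L))
  set.seed(65)
  rnd <- vapply(1:300, function(i)
    paste(sample(c("A", "C", "G", "T"), 10L, TRUE), collapse = ""), "")
  fm2 <- frequencyMatrix(rnd)
  expect_true(all(colSums(fm2) == 300L))
  expect_gt(chisq.test(fm2[, 1L])$p.value, 1e-4)
  fmr <- frequencyMatrix(rnd, region = c(2L, 4L))
  expect_identical(ncol(fmr), 3L)
  expect_equal(fmr, fm2[, 2:4])
})
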