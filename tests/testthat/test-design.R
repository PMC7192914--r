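# a transparent linear stand-in model: score = sum of per-position
# weights, computable in closed form for any scaffold
test_that("scoreSequences matches a closed-form linear oracle", {
  sc <- tinyScaffold()
  gt <- linearOracle(sc, sd = 0.3)
  obj <- designObjective("activity", threshold = 0)
  set.seed(50)
  seqs <- sampleSequence(sc, 20L)
  got <- scoreSequences(oracleScorer(gt), seqs, obj)
  want <- vapply(seqs, function(s) {
    codes <- match(strsplit(s, "")[[1L]], c("A", "C", "G", "T"))
    sum(gt@positionWeights[cbind(codes, seq_along(codes))])
  }, 1, USE.NAMES = FALSE)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("screening acceptance matches the analytic tail probability", {
  sc <- LibraryScaffold("one", list(randomSegment(1L)))
  w <- c(A = 0, C = 1, G = 2, T = 3)
  model <- function(seqs) w[seqs]
  # threshold -Inf accepts everything that passes constraints
  objAll <- designObjective("activity", threshold = -1e9)
  set.seed(51)
  d0 <- screenDesigns(sc, model, objAll, nTarget = 50L,
                      batchSize = 50L,
                      constraints = designConstraints(bsai = FALSE))
  expect_identical(nrow(d0), 50L)
  expect_identical(attr(d0, "examined"), 50L)
  # unreachable threshold accepts nothing
  objNone <- designObjective("activity", threshold = 4)
  expect_warning(
    dN <- screenDesigns(sc, model, objNone, nTarget = 5L,
                        maxIter = 300L, constraints =
                          designConstraints(bsai = FALSE)),
    "cap")
  expect_identical(nrow(dN), 0L)
  # single-base space: P(score >= 2) = 1/2; Monte-Carlo within 3 SE
  obj2 <- designObjective("activity", threshold = 2)
  set.seed(52)
  expect_warning(
    d2 <- screenDesigns(sc, model, obj2, nTarget = 10000L,
                        maxIter = 4000L, batchSize = 4000L,
                        constraints = designConstraints(bsai = FALSE)),
    "cap")
  acc <- nrow(d2) / attr(d2, "examined")
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("evolution reaches the optimum of a small search space", {
  sc <- LibraryScaffold("small", list(
    constantSegment("AC"), randomSegment(3L), constantSegment("GT")))
  gt <- linearOracle(sc, sd = 0.5, seed = 7L)
  best <- max(vapply(
    do.call(paste0,
            expand.grid(rep(list(c("A", "C", "G", "T")), 3L))),
    function(mid) {
      s <- paste0("AC", mid, "GT")
      trueActivity(gt, s)[1, 1]
    }, 1))
  obj <- designObjective("activity", threshold = best - 1e-9)
  set.seed(53)
  res <- evolveDesign(sc, oracleScorer(gt), obj,
                      schedule = evolutionSchedule(30L, c(2L, 1L), 50L),
                      constraints = designConstraints(bsai = FALSE))
  expect_true(res$accepted)
  expect_equal(res$score, best, tolerance = 1e-9)
  # constant regions intact
  expect_identical(substr(res$sequence, 1, 2), "AC")
  expect_identical(substr(res$sequence, 6, 7), "GT")
  # cycle log is recorded
  expect_true(nrow(attr(res, "cycles")) >= 1L)
})

test_that("mutation never introduces zero-frequency bases", {
  sc <- LibraryScaffold("nog", list(randomSegment(30L,
                                                  c(.4, .3, 0, .3))))
  set.seed(54)
  s <- sampleSequence(sc, 1L)
  for (i in 1:50) {
    s <- PromoterForge:::.mutateSequence(s, sc, 5L)
    expect_false(grepl("G", s))
  }
})

test_that("adjustThreshold steps in fixed increments", {
  # runner succeeding only strictly below 0.5, downward from 0.6
  runner <- function(t) t < 0.5 - 1e-9
  got <- adjustThreshold(runner, 0.6, "down", increment = 0.05)
  expect_equal(got, 0.45, tolerance = 1e-9)   # first success
  # upward mode returns the last achievable threshold
  up <- adjustThreshold(function(t) t <= 1.2 + 1e-9, 1.0, "up",
                        increment = 0.05)
  expect_equal(up, 1.2, tolerance = 1e-9)
  # always-succeeding runner is stopped by the iteration cap
  capped <- adjustThreshold(function(t) TRUE, 0, "up",
                            increment = 0.05, maxSteps = 10L)
  expect_equal(capped, 0.5, tolerance = 1e-9)
  expect_true(is.na(adjustThreshold(function(t) FALSE, 0, "down",
                                    maxSteps = 5L)))
})

test_that("ensemble input gradients match finite differences", {
  sc <- demoScaffold()
  enc <- encoderConfig(sc)
  arch <- architectureConfig("small", fcUnits = c(8L, 8L))
  net <- PromoterForge:::.netConfig(arch, enc$frame)
  set.seed(55)
  subs <- lapply(1:2, function(i)
    list(params = PromoterForge:::.initParams(arch, enc$frame),
         net = net, arch = arch))
  ens <- new("EnsembleModel", submodels = subs, testIdx = integer(0),
             folds = list(), encoder = enc, arch = arch,
             mergeMode = "mean")
  s <- sampleSequence(sc, 1L)
  X <- encodeBatch(s, "demo", enc)
  for (mode in c("mean", "mean_minus_sd")) {
    g <- PromoterForge:::.ensembleInputGrad(ens, X, 1, mode)
    score <- function(Xc) {
      preds <- vapply(subs, function(sub)
        PromoterForge:::cnn_predict_cpp(sub$params, net, Xc)[1, 1], 1)
      if (mode == "mean") mean(preds)
      else mean(preds) - sqrt(mean(preds^2) - mean(preds)^2)
    }
    eps <- 1e-4
    for (probe in list(c(1, 30), c(3, 80))) {
      Xp <- X; Xp[probe[1], probe[2], 1] <- Xp[probe[1], probe[2], 1] + eps
      Xm <- X; Xm[probe[1], probe[2], 1] <- Xm[probe[1], probe[2], 1] - eps
      fd <- (score(Xp) - score(Xm)) / (2 * eps)
      # single-precision forward pass: allow a few percent of slack
      expect_lt(abs(unname(g[probe[1], probe[2], 1]) - fd),
                0.05 * max(abs(fd), 0.01))
    }
  }
})

test_that("gradient ascent produces valid sequences and improves score", {
  sc <- demoScaffold()
  gt <- linearOracle(sc, sd = 0.1)
  set.seed(56)
  seqs <- sampleSequence(sc, 400L)
  y <- trueActivity(gt, seqs)[, "uninduced"]
  enc <- encoderConfig(sc)
  arch <- architectureConfig("small", fcUnits = c(16L, 16L))
  cfg <- trainConfig("small", maxEpochs = 8L, batchSize = 64L)
  set.seed(57)
  ens <- trainEnsemble(seqs, "demo", y, enc, arch, cfg, k = 1L,
                       seed = 57L)
  obj <- designObjective("activity", threshold = 1e9)  # never reached
  set.seed(58)
  res <- gradientAscentDesign(sc, ens, obj, steps = 30L, stepSize = 0.3)
  expect_false(res$accepted)
  # constant regions byte-identical, no zero-frequency bases introduced
  expect_true(filterConstantRegions(res$sequence, sc))
  utr <- segmentTable(sc); utr <- utr[utr$label == "utr", ]
  expect_false(grepl("G", substr(res$sequence, utr$start, utr$end)))
  tr <- attr(res, "trace")
  expect_gte(max(tr), tr[1L])          # ascent improves over the start
  # zero step size never changes the sequence
  set.seed(59)
  frozen <- gradientAscentDesign(sc, ens, obj, steps = 5L, stepSize = 0)
  trF <- attr(frozen, "trace")
  expect_identical(length(unique(trF)), 1L)
})
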