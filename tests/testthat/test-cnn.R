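test_that("encoding embeds, pads and shifts sequences consistently", {
  scA <- demoScaffold()
  enc <- encoderConfig(scA)
  set.seed(40)
  s <- sampleSequence(scA, 1L)
  X0 <- encodeBatch(s, "demo", enc, shift = 0L)
  X7 <- encodeBatch(s, "demo", enc, shift = 7L)
  expect_identical(dim(X0), dim(X7))
  expect_true(all(apply(X0[, , 1L], 2L, sum) == 1))
  # shifted frame is the same content displaced by 7 positions
  F <- enc$frame
  expect_equal(X0[, 1:(F - 7L), 1L], X7[, 8:F, 1L])
  # round trip: the insert region decodes to the original sequence
  rng <- PromoterForge:::.insertRange("demo", enc)
  expect_identical(decodeOneHot(X0[, rng[1L]:rng[2L], 1L]), s)

  # two libraries of different lengths share one encoded frame
  scB <- keyedScaffold(tail = 30L)   # 79 bp vs 110 bp
  enc2 <- encoderConfig(list(demo = scA, keyed = scB))
  sB <- sampleSequence(scB, 1L)
  XA <- encodeBatch(s, "demo", enc2)
  XB <- encodeBatch(sB, "keyed", enc2)
  expect_identical(dim(XA), dim(XB))
  rngB <- PromoterForge:::.insertRange("keyed", enc2)
  expect_identical(decodeOneHot(XB[, rngB[1L]:rngB[2L], 1L]), sB)
})

test_that("huberLoss switches from quadratic to linear at delta", {
  expect_equal(huberLoss(1, 1), 0)
  expect_equal(huberLoss(0.1, 0), 0.005)
  expect_equal(huberLoss(0.3, 0), 0.15 * (0.3 - 0.075))
  expect_equal(huberLoss(0.3, 0), 0.03375)
  expect_error(huberLoss(1, 1, delta = 0), "delta")
})

test_that("makePartitions yields disjoint covering folds and a shared test", {
  p <- makePartitions(100L, k = 9L, seed = 5L)
  expect_length(p$test, 10L)
  expect_identical(unname(lengths(p$folds)), rep(10L, 9L))
  all_ <- c(p$test, unlist(p$folds))
  expect_identical(sort(all_), 1:100)     # disjoint + covering
  p2 <- makePartitions(100L, k = 9L, seed = 5L)
  expect_identical(p, p2)                 # deterministic
  p3 <- makePartitions(103L, k = 9L, seed = 5L)
  expect_lte(diff(range(lengths(p3$folds))), 1L)
  expect_error(makePartitions(5L, k = 9L), "at least")
})

test_that("training reduces loss and early stopping returns best weights", {
  sc <- demoScaffold()
  gt <- linearOracle(sc)
  set.seed(41)
  seqs <- sampleSequence(sc, 300L)
  y <- trueActivity(gt, seqs)[, "uninduced"]
  enc <- encoderConfig(sc)
  arch <- architectureConfig("small", fcUnits = c(16L, 16L))
  cfg <- trainConfig("small", maxEpochs = 6L, batchSize = 64L)
  set.seed(42)
  sub <- trainSubmodel(seqs, "demo", y, enc, arch, cfg, 1:240, 241:300)
  h <- sub$history
  expect_lt(h$train[nrow(h)], h$train[1L])          # loss decreases
  expect_identical(sub$bestEpoch, which.min(h$val)) # best-epoch weights
  expect_lte(nrow(h), 6L)
  # patience: stop follows the first patience-long non-improving run
  bad <- cumsum(seq_len(nrow(h)) > sub$bestEpoch)
  if (nrow(h) < 6L) expect_gte(max(bad), cfg$patience)
})

test_that("prediction merging follows the mean and mean-minus-sd rules", {
  mk <- function(v) list(pred = v)
  # synthetic submodel predictions (B=2, 1 output, k=2)
  preds <- list(matrix(c(0, 1), 2L), matrix(c(1, 1), 2L))
  mn <- PromoterForge:::.mergePreds(preds, "mean")
  expect_equal(mn, matrix(c(0.5, 1), 2L))
  ms <- PromoterForge:::.mergePreds(preds, "mean_minus_sd")
  expect_equal(ms, matrix(c(0, 1), 2L))   # population SD, divisor k
  expect_true(all(ms <= mn))
  one <- PromoterForge:::.mergePreds(list(matrix(1, 1L)), "mean_minus_sd")
  expect_equal(one[1L], 1)
})

test_that("activationRatio converts log differences to fold changes", {
  expect_equal(activationRatio(1, 1)$fold, 1)
  r <- activationRatio(1.33, 0.04)       # the measured library medians
  expect_equal(r$logRatio, 1.29)
  expect_equal(r$fold, 10^1.29, tolerance = 1e-12)
  expect_equal(round(r$fold, 1), 19.5)
  expect_true(activationRatio(2, 0)$fold > activationRatio(1, 0)$fold)
})

test_that("dual-output targets supervise both outputs for single labels", {
  y <- c(0.1, 0.2)
  Y <- PromoterForge:::.targetMatrix(y, 2L)
  expect_equal(Y, matrix(c(0.1, 0.1, 0.2, 0.2), 2L))
  Ym <- PromoterForge:::.targetMatrix(cbind(un = c(0, 1), in_ = c(1, 2)),
                                      2L)
  expect_equal(Ym, matrix(c(0, 1, 1, 2), 2L))
})

test_that("network parameter gradients match finite differences", {
  set.seed(77)
  sc <- demoScaffold()
  enc <- encoderConfig(sc)
  arch <- architectureConfig("small", fcUnits = c(8L, 8L))
  net <- PromoterForge:::.netConfig(arch, enc$frame)
  P <- PromoterForge:::.initParams(arch, enc$frame)
  X <- encodeBatch(sampleSequence(sc, 8L), "demo", enc, 0L)
  Y <- matrix(rnorm(8L, 0, 0.2), 1L)
  out <- PromoterForge:::cnn_loss_grads_cpp(P, net, X, Y, 0.15)
  lossAt <- function(P)
    PromoterForge:::cnn_loss_grads_cpp(P, net, X, Y, 0.15)$loss
  eps <- 1e-3
  # probe the largest-gradient entry of every layer type: conv weights,
  # batchnorm gamma/beta (training statistics), dense and output layers
  for (pi in c(1L, 2L, 3L, 6L, 11L, 13L, 16L, 17L)) {
    g <- out$grads[[pi]]
    ij <- arrayInd(which.max(abs(g)), dim(g))
    Pp <- P; Pp[[pi]][ij] <- Pp[[pi]][ij] + eps
    Pm <- P; Pm[[pi]][ij] <- Pm[[pi]][ij] - eps
    fd <- (lossAt(Pp) - lossAt(Pm)) / (2 * eps)
    expect_lt(abs(g[ij] - fd), 0.02 * max(abs(fd), 1e-4))
  }
})

test_that("a dual-output model learns both activity channels", {
  sc <- demoScaffold()
  gt <- demoGroundTruth(sc)          # induced = uninduced + 1.2
  set.seed(80)
  seqs <- sampleSequence(sc, 600L)
  y <- trueActivity(gt, seqs)        # two columns
  enc <- encoderConfig(sc)
  arch <- architectureConfig("small", nOutputs = 2L,
                             fcUnits = c(32L, 32L))
  cfg <- trainConfig("small", maxEpochs = 12L, batchSize = 128L)
  set.seed(81)
  sub <- trainSubmodel(seqs, "demo", y, enc, arch, cfg, 1:480, 481:540)
  pred <- predictSubmodel(sub, seqs[541:600], "demo", enc)
  expect_identical(dim(pred), c(60L, 2L))
  expect_true(all(is.finite(pred)))
  # the constant induction offset is learned early
  gap <- mean(pred[, 2L] - pred[, 1L])
  expect_lt(abs(gap - 1.2), 0.25)
  # ratio objective scores merged induced minus merged uninduced
  ens <- new("EnsembleModel", submodels = list(sub), testIdx = 1L,
             folds = list(), encoder = enc, arch = arch,
             mergeMode = "mean")
  r <- scoreSequences(ens, seqs[1:5], designObjective("ratio"), "demo")
  expect_equal(r, pred0 <- {
    p <- predictSubmodel(sub, seqs[1:5], "demo", enc)
    p[, 2L] - p[, 1L]
  }, tolerance = 1e-6)
})
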