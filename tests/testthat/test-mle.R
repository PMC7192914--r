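test_that("normalizeCounts rescales reads by cells per read", {
  r <- matrix(c(2, 0), 1L)
  A <- normalizeCounts(r, cellsSorted = c(100, 100),
                       totalReads = c(50, 200))
  expect_equal(A, matrix(c(4, 0), 1L))
  # C == R leaves counts unchanged
  r2 <- matrix(1:6, 2L)
  expect_equal(normalizeCounts(r2, colSums(r2)), r2 + 0)
  # column sums equal cells x column read share (independent recompute)
  set.seed(30)
  raw <- matrix(rpois(60, 20), 10L)
  C <- c(500, 800, 300, 900, 100, 250)
  A3 <- normalizeCounts(raw, C)
  expect_equal(colSums(A3), C * (colSums(raw) / colSums(raw)))
  expect_error(normalizeCounts(matrix(-1, 1L), 1), "nonnegative")
})

test_that("binProb is a proper mixture over bins", {
  lay <- defaultBinLayout()
  # contaminant-only limit
  expect_equal(binProb(0, 0.2, 1, lay), rep(1 / 12, 12L))
  # interior bin mass against the normal CDF
  lay3 <- BinLayout(c(-2, -1, 0, 2))
  expect_equal(binProb(0, 1, 0, lay3)[2L], pnorm(0) - pnorm(-1),
               tolerance = 1e-12)
  # sums to one for arbitrary parameters
  set.seed(31)
  for (i in 1:20) {
    p <- binProb(runif(1, -1, 1), runif(1, 0.05, 0.5), runif(1),
                 lay)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0))
  }
  expect_error(binProb(0, -1, 0, lay), "sigma")
})

test_that("loglikMatrix columns are log mixture probabilities", {
  lay <- defaultBinLayout()
  mu <- seq(-0.5, 0.5, by = 0.1)
  W <- loglikMatrix(lay, mu, 0.15, 0.01)
  expect_equal(dim(W), c(12L, length(mu)))
  expect_equal(colSums(exp(W)), rep(1, length(mu)), tolerance = 1e-9)
  # spot-check entries against direct evaluation
  set.seed(32)
  for (k in 1:5) {
    i <- sample(12L, 1L); j <- sample(length(mu), 1L)
    expect_equal(W[i, j], log(binProb(mu[j], 0.15, 0.01, lay)[i]),
                 tolerance = 1e-12)
  }
})

test_that("fitMeans equals a direct per-sequence likelihood loop", {
  lay <- defaultBinLayout()
  mu <- defaultMuGrid(lay)
  W <- loglikMatrix(lay, mu, 0.15, 0.01)
  set.seed(33)
  A <- matrix(rpois(200 * 12, 5), 200L)
  A[1L, ] <- 0      # all-zero row is flagged
  fit <- fitMeans(A, mu, W)
  expect_identical(fit$flag[1L], "no_reads")
  expect_true(is.na(fit$muHat[1L]))
  # naive per-sequence loop, exact equality
  for (s in 2:50) {
    ll <- vapply(seq_along(mu), function(j) sum(A[s, ] * W[, j]), 1)
    expect_identical(fit$muHat[s], mu[which.max(ll)])
    expect_equal(fit$loglik[s], max(ll), tolerance = 1e-12)
  }
  # counts proportional to binProb(mu*) recover the nearest grid value
  target <- 0.1234
  A2 <- matrix(binProb(target, 0.15, 0.01, lay) * 1000, 1L)
  fit2 <- fitMeans(A2, mu, W)
  expect_lte(abs(fit2$muHat - target), 0.005 / 2 + 1e-9)
  # single-bin counts at eps 0: estimate inside that bin
  A3 <- matrix(0, 1L, 12L); A3[1L, 6L] <- 50
  W0 <- loglikMatrix(lay, mu, 0.15, 0)
  fit3 <- fitMeans(A3, mu, W0)
  expect_gte(fit3$muHat, lay@breaks[6L])
  expect_lte(fit3$muHat, lay@breaks[7L])
})

test_that("gridSearch recovers the generating hyperparameters", {
  lay <- defaultBinLayout()
  # single-point grids return that point
  A <- matrix(rpois(12, 10), 1L)
  g1 <- gridSearch(A, lay, sigmaGrid = 0.2, epsilonGrid = 0.05)
  expect_equal(c(g1$sigma, g1$epsilon), c(0.2, 0.05))

  set.seed(34)
  truthMu <- runif(300, -0.5, 0.5)
  cfg <- SortConfig(lay, sigmaCell = 0.15, epsilon = 0.03,
                    cellsPerSequence = 500)
  counts <- simulateSort(truthMu, cfg)
  g <- gridSearch(counts, lay, sigmaGrid = seq(0.10, 0.20, 0.01),
                  epsilonGrid = seq(0, 0.08, 0.01))
  expect_lte(abs(g$sigma - 0.15), 0.01 + 1e-9)
  expect_lte(abs(g$epsilon - 0.03), 0.01 + 1e-9)
  # score surface invariant to sequence order
  g2 <- gridSearch(counts[rev(seq_len(nrow(counts))), ], lay,
                   sigmaGrid = seq(0.10, 0.20, 0.01),
                   epsilonGrid = seq(0, 0.08, 0.01))
  expect_equal(g2$surface, g$surface)
})

test_that("combineReplicates averages and flags discordant pairs", {
  m <- rbind(c(0.10, 0.10), c(0.0, 0.25), c(0.0, 0.20), c(NA, 0.1))
  out <- combineReplicates(m)
  expect_equal(out$mu[1:3], c(0.10, 0.125, 0.10))
  expect_identical(out$flag,
                   c("ok", "replicate_discordant", "ok",
                     "missing_replicate"))
})

test_that("extreme-bin and read-threshold filters apply the stated rules", {
  r <- matrix(0, 4L, 12L)
  r[1L, 12L] <- 30          # only highest bin -> flagged
  r[2L, 11:12] <- c(3, 9)   # two bins -> kept
  r[3L, 1L] <- 5            # only lowest bin -> flagged
  r[4L, 5:7] <- 2
  expect_identical(extremeBinFilter(r), c(TRUE, FALSE, TRUE, FALSE))

  tot <- cbind(c(10, 9, 50), c(10, 50, 50))
  expect_identical(readThresholdFilter(tot, 10), c(TRUE, FALSE, TRUE))
  expect_true(all(readThresholdFilter(tot, 0)))
})

test_that("rescaleBinEdges recovers affine maps between conditions", {
  set.seed(35)
  a <- rnorm(2000, 0, 0.3)
  expect_equal(rescaleBinEdges(a, a),
               c(slope = 1, intercept = 0), tolerance = 1e-9)
  b <- 2 * a + 0.3
  expect_equal(rescaleBinEdges(a, b),
               c(slope = 2, intercept = 0.3), tolerance = 1e-6)
  # order invariance (sorting happens inside)
  expect_equal(rescaleBinEdges(sample(a), sample(b)),
               rescaleBinEdges(a, b), tolerance = 1e-9)
  # unequal sizes interpolate
  fit <- rescaleBinEdges(a, (2 * a + 0.3)[1:1500])
  expect_equal(unname(fit["slope"]), 2, tolerance = 0.05)
  expect_error(rescaleBinEdges(rep(1, 5), rnorm(5)), "variance")
})

test_that("more cells per sequence tightens the activity estimates", {
  lay <- defaultBinLayout()
  mu <- defaultMuGrid(lay)
  W <- loglikMatrix(lay, mu, 0.15, 0.01)
  set.seed(36)
  truth <- runif(200, -0.4, 0.4)
  err <- vapply(c(50, 200, 800), function(cells) {
    cfg <- SortConfig(lay, 0.15, 0.01, cellsPerSequence = cells)
    counts <- simulateSort(truth, cfg)
    fit <- fitMeans(counts, mu, W)
    median(abs(fit$muHat - truth), na.rm = TRUE)
  }, 1)
  expect_true(all(diff(err) < 0))
})
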