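#' Cell-normalize raw read counts
#'
#' Converts raw per-bin read counts into estimated cell counts: the
#' count in bin `i` is multiplied by `C_i / R_i`, where `C_i` is the
#' number of cells collected in the bin and `R_i` the total reads
#' observed in it. Bins with zero reads contribute zero (with a
#' warning). Fractional values are kept; the likelihood is linear in
#' counts, so no rounding is applied.
#'
#' @param rawReads S x N matrix of raw reads per sequence per bin.
#' @param cellsSorted Length-N vector of cells collected per bin.
#' @param totalReads Length-N vector of total reads per bin (default:
#'   column sums of `rawReads`).
#' @return S x N numeric matrix `A` of estimated cells.
#' @export
normalizeCounts <- function(rawReads, cellsSorted,
                            totalReads = colSums(rawReads)) {
  rawReads <- as.matrix(rawReads)
  if (any(rawReads < 0) || any(cellsSorted < 0) || any(totalReads < 0))
    stop("counts must be nonnegative")
  fac <- ifelse(totalReads > 0, cellsSorted / totalReads, 0)
  if (any(totalReads == 0 & colSums(rawReads) > 0))
    stop("totalReads is zero in a bin that has reads")
  if (any(totalReads == 0))
    warning("bins with zero total reads contribute nothing")
  sweep(rawReads, 2L, fac, `*`)
}

#' Mixture bin probabilities
#'
#' Probability that a cell with mean activity `mu` lands in each sort
#' bin: normal mass between the bin edges times `1 - epsilon`, plus a
#' uniform contaminant share `epsilon / N`. With `unboundedOuter` the
#' outermost edges are taken as -Inf/+Inf (the gates cover the full
#' activity range, so out-of-range cells land in the end bins and the
#' probabilities sum to exactly 1).
#'
#' @param mu Mean activity (scalar or vector).
#' @param sigma Shared cell-level SD (> 0).
#' @param epsilon Contaminant fraction in `[0, 1]`.
#' @param layout A [BinLayout-class].
#' @param unboundedOuter Treat outer edges as infinite (default TRUE).
#' @return Length-N probability vector, or N x M matrix for vector `mu`.
#' @export
binProb <- function(mu, sigma, epsilon, layout, unboundedOuter = TRUE) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0, 1]")
  br <- layout@breaks
  N <- length(br) - 1L
  if (unboundedOuter) {
    br[1L] <- -Inf
    br[N + 1L] <- Inf
  }
  # tail-stable normal mass: use the upper-tail CDF for bins right of mu
  # (the naive difference of lower-tail CDFs cancels to exactly 0 there)
  lo <- outer(br, mu, function(b, m) pnorm(b, m, sigma))
  up <- outer(br, mu, function(b, m) pnorm(b, m, sigma,
                                           lower.tail = FALSE))
  massLo <- lo[-1L, , drop = FALSE] - lo[-(N + 1L), , drop = FALSE]
  massUp <- up[-(N + 1L), , drop = FALSE] - up[-1L, , drop = FALSE]
  rightOfMu <- outer(br[-(N + 1L)], mu, `>=`)
  mass <- ifelse(rightOfMu, massUp, massLo)
  P <- pmax(mass, 0) * (1 - epsilon) + epsilon / N
  if (length(mu) == 1L) P[, 1L] else P
}

#' Log bin-probability matrix over a candidate activity grid
#'
#' @param layout A [BinLayout-class].
#' @param muGrid Length-M vector of candidate mean activities.
#' @param sigma,epsilon Mixture hyperparameters.
#' @param unboundedOuter See [binProb()].
#' @return N x M matrix `W` with `W[i, j] = log P(bin i | mu_j)`.
#' @export
loglikMatrix <- function(layout, muGrid, sigma, epsilon,
                         unboundedOuter = TRUE) {
  if (!length(muGrid)) stop("muGrid must be nonempty")
  P <- binProb(muGrid, sigma, epsilon, layout, unboundedOuter)
  # floor keeps zero-count x log(0) products finite in the A %*% W step
  log(pmax(P, 1e-300))
}

#' Maximum-likelihood mean activities from binned counts
#'
#' The matrix product `A %*% W` gives, for every sequence, the
#' log-likelihood of each candidate activity; the estimate is the
#' argmax over the grid (ties broken toward the smallest value).
#' All-zero count rows get `NA` and are flagged.
#'
#' @param A S x N matrix of (cell-normalized) counts.
#' @param muGrid Length-M candidate grid.
#' @param W N x M log-probability matrix from [loglikMatrix()].
#' @return data.frame with `muHat`, `loglik`, `flag` per sequence.
#' @export
fitMeans <- function(A, muGrid, W) {
  A <- as.matrix(A)
  if (ncol(A) != nrow(W)) stop("A columns must match W rows")
  LL <- A %*% W
  j <- max.col(LL, ties.method = "first")   # first = smallest mu
  muHat <- muGrid[j]
  loglik <- LL[cbind(seq_len(nrow(A)), j)]
  empty <- rowSums(A) == 0
  muHat[empty] <- NA_real_
  loglik[empty] <- NA_real_
  data.frame(muHat = muHat, loglik = loglik,
             flag = ifelse(empty, "no_reads", "ok"),
             stringsAsFactors = FALSE)
}

#' Hyperparameter grid search for the mixture model
#'
#' For every (sigma, epsilon) pair the per-sequence maximum
#' log-likelihoods are summed; the pair maximizing this total score is
#' returned together with the full score surface for sensitivity
#' reporting.
#'
#' @param A S x N count matrix.
#' @param layout A [BinLayout-class].
#' @param sigmaGrid,epsilonGrid Candidate hyperparameter values.
#' @param muGrid Candidate activity grid (default [defaultMuGrid()]).
#' @param unboundedOuter See [binProb()].
#' @return List with `sigma`, `epsilon`, `surface` (sigma x epsilon
#'   score matrix) and `fit` (the [fitMeans()] table at the optimum).
#' @export
gridSearch <- function(A, layout, sigmaGrid = seq(0.05, 0.40, by = 0.01),
                       epsilonGrid = seq(0, 0.20, by = 0.01),
                       muGrid = defaultMuGrid(layout),
                       unboundedOuter = TRUE) {
  if (!length(sigmaGrid) || !length(epsilonGrid))
    stop("hyperparameter grids must be nonempty")
  A <- as.matrix(A)
  surface <- matrix(NA_real_, length(sigmaGrid), length(epsilonGrid),
                    dimnames = list(sigmaGrid, epsilonGrid))
  best <- list(score = -Inf)
  for (si in seq_along(sigmaGrid)) {
    for (ei in seq_along(epsilonGrid)) {
      W <- loglikMatrix(layout, muGrid, sigmaGrid[si], epsilonGrid[ei],
                        unboundedOuter)
      fit <- fitMeans(A, muGrid, W)
      sc <- sum(fit$loglik, na.rm = TRUE)
      surface[si, ei] <- sc
      if (sc > best$score)
        best <- list(score = sc, sigma = sigmaGrid[si],
                     epsilon = epsilonGrid[ei], fit = fit)
    }
  }
  list(sigma = best$sigma, epsilon = best$epsilon, surface = surface,
       fit = best$fit)
}

#' Default candidate activity grid
#'
#' Bin range extended by one bin width on each side, step 0.005 log10
#' units.
#'
#' @param layout A [BinLayout-class].
#' @param step Grid step.
#' @export
defaultMuGrid <- function(layout, step = 0.005) {
  br <- layout@breaks
  w <- mean(diff(br))
  seq(min(br) - w, max(br) + w, by = step)
}

#' Combine replicate activity estimates
#'
#' Final estimate is the mean across replicates; sequences whose
#' replicate estimates differ by more than `maxDiff` (strict
#' inequality: exactly 0.2 apart is kept) are flagged as discordant,
#' and sequences with any missing replicate are flagged missing.
#'
#' @param muMatrix S x k matrix of per-replicate estimates.
#' @param maxDiff Largest tolerated pairwise difference.
#' @return data.frame with `mu`, `flag`.
#' @export
combineReplicates <- function(muMatrix, maxDiff = 0.2) {
  muMatrix <- as.matrix(muMatrix)
  mu <- rowMeans(muMatrix)
  rng <- apply(muMatrix, 1L, function(x) diff(range(x)))
  flag <- rep("ok", nrow(muMatrix))
  flag[rng > maxDiff] <- "replicate_discordant"
  miss <- apply(muMatrix, 1L, anyNA)
  flag[miss] <- "missing_replicate"
  mu[miss] <- NA_real_
  data.frame(mu = mu, flag = flag, stringsAsFactors = FALSE)
}

#' Extreme-bin outlier filter
#'
#' Flags sequences whose reads all fall in the lowest bin or all in the
#' highest bin — their activities lie at or beyond the gate limits and
#' cannot be estimated reliably. Apply per condition/replicate and
#' combine with `|` for the inducible-library rule (flag if extreme in
#' either condition).
#'
#' @param rawReads S x N count matrix (one condition/replicate).
#' @return Logical vector, `TRUE` for flagged sequences.
#' @export
extremeBinFilter <- function(rawReads) {
  rawReads <- as.matrix(rawReads)
  N <- ncol(rawReads)
  tot <- rowSums(rawReads)
  lo <- rawReads[, 1L] == tot & tot > 0
  hi <- rawReads[, N] == tot & tot > 0
  lo | hi
}

#' Minimum read-count filter
#'
#' `TRUE` iff the sequence has at least `minReads` total reads in every
#' supplied replicate/condition (boundary inclusive).
#'
#' @param totals S x k matrix (or vector) of total reads per
#'   replicate/condition.
#' @param minReads Threshold.
#' @return Logical vector.
#' @export
readThresholdFilter <- function(totals, minReads) {
  if (minReads < 0) stop("minReads must be >= 0")
  totals <- as.matrix(totals)
  apply(totals >= minReads, 1L, all)
}

#' Affine rescaling between instrument conditions
#'
#' Matches approximately corresponding cells of two samples by sorting
#' their per-cell activities, interpolates the larger sample onto the
#' smaller one's quantile grid, and fits ordinary least squares,
#' returning the affine map from condition A to condition B. Used to
#' convert bin edges measured under one set of cytometer settings to a
#' reference condition, and to rescale estimated means against
#' validation measurements.
#'
#' @param activitiesA,activitiesB Per-cell activity samples.
#' @return Named vector `c(slope, intercept)` with `B ~ slope * A +
#'   intercept`.
#' @export
rescaleBinEdges <- function(activitiesA, activitiesB) {
  a <- sort(activitiesA)
  b <- sort(activitiesB)
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  if (var(a) == 0 || var(b) == 0) stop("zero-variance input")
  n <- min(length(a), length(b))
  grid <- seq(0, 1, length.out = n)
  qa <- if (length(a) == n) a else
    approx(seq(0, 1, length.out = length(a)), a, grid)$y
  qb <- if (length(b) == n) b else
    approx(seq(0, 1, length.out = length(b)), b, grid)$y
  co <- coef(lm(qb ~ qa))
  c(slope = unname(co[2L]), intercept = unname(co[1L]))
}

#' Estimate activities for a count matrix (full pipeline step)
#'
#' Grid-searches the mixture hyperparameters, then fits per-sequence
#' means at the optimum.
#'
#' @inheritParams gridSearch
#' @return List as from [gridSearch()], plus `muGrid`.
#' @export
estimateActivities <- function(A, layout,
                               sigmaGrid = seq(0.05, 0.40, by = 0.01),
                               epsilonGrid = seq(0, 0.20, by = 0.01),
                               muGrid = defaultMuGrid(layout)) {
  res <- gridSearch(A, layout, sigmaGrid, epsilonGrid, muGrid)
  res$muGrid <- muGrid
  res
}
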