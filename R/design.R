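#' Design objective
#'
#' @param target `"activity"` (single-output models),
#'   `"induced"` or `"ratio"` (two-output models; the ratio is the
#'   difference of induced and uninduced log10 activities).
#' @param mergeMode Ensemble merge mode used when scoring.
#' @param threshold Acceptance threshold on the score scale.
#' @return List objective.
#' @export
designObjective <- function(target = c("activity", "induced", "ratio"),
                            mergeMode = "mean", threshold = 0) {
  target <- match.arg(target)
  stopifnot(is.finite(threshold),
            mergeMode %in% c("mean", "mean_minus_sd"))
  list(target = target, mergeMode = mergeMode, threshold = threshold)
}

# per-output weights defining the scored linear combination
.objectiveWeights <- function(objective, nOut) {
  switch(objective$target,
    activity = { stopifnot(nOut == 1L); 1 },
    induced  = { stopifnot(nOut == 2L); c(0, 1) },
    ratio    = { stopifnot(nOut == 2L); c(-1, 1) })
}

#' Score sequences under an objective
#'
#' For an [EnsembleModel-class], submodel predictions are merged per
#' the objective's merge mode; the ratio objective scores merged
#' induced minus merged uninduced. Any plain function
#' `f(seqs) -> vector/matrix` (e.g. a ground-truth oracle) can stand in
#' as the model.
#'
#' @param model An [EnsembleModel-class] or a scoring function.
#' @param seqs Character vector of sequences.
#' @param objective From [designObjective()].
#' @param library Library label (ensemble models).
#' @return Numeric score vector.
#' @export
scoreSequences <- function(model, seqs, objective, library = NULL) {
  if (is(model, "EnsembleModel")) {
    pred <- predictMerge(model, seqs, library, objective$mergeMode)
    w <- .objectiveWeights(objective, ncol(pred))
  } else {
    pred <- model(seqs)
    if (!is.matrix(pred)) pred <- matrix(pred, ncol = 1L)
    w <- .objectiveWeights(objective, ncol(pred))
  }
  drop(pred %*% w)
}

#' Constraint set for accepted designs
#'
#' @param gc Apply the 20-bp GC-window constraint ([gcWindowOk()]).
#' @param bsai Reject sequences with BsaI sites (always recommended;
#'   such sequences interfere with assembly).
#' @export
designConstraints <- function(gc = FALSE, bsai = TRUE) {
  list(gc = gc, bsai = bsai)
}

.passesConstraints <- function(seq, constraints) {
  if (constraints$bsai && containsBsaI(seq)) return(FALSE)
  if (constraints$gc && !gcWindowOk(seq)) return(FALSE)
  TRUE
}

.designResult <- function(sequence, score, strategy, accepted, log = NULL) {
  data.frame(sequence = sequence, score = score, strategy = strategy,
             accepted = accepted, stringsAsFactors = FALSE)
}

#' Screening design strategy
#'
#' Samples random library members from the scaffold and keeps those
#' that pass the constraints with score at or above the threshold,
#' until `nTarget` designs are found or the iteration cap is hit
#' (partial results are returned with a warning).
#'
#' @param scaffold A [LibraryScaffold-class].
#' @param model Ensemble or scoring function.
#' @param objective From [designObjective()].
#' @param nTarget Number of designs wanted.
#' @param constraints From [designConstraints()].
#' @param maxIter Cap on candidate sequences examined.
#' @param batchSize Candidates scored per round.
#' @param library Library label for ensemble scoring.
#' @return data.frame of accepted designs (`sequence`, `score`,
#'   `strategy`), with attribute `examined`.
#' @export
screenDesigns <- function(scaffold, model, objective, nTarget,
                          constraints = designConstraints(),
                          maxIter = 100000L, batchSize = 200L,
                          library = NULL) {
  stopifnot(nTarget >= 1L)
  kept <- NULL
  examined <- 0L
  while (examined < maxIter && (is.null(kept) || nrow(kept) < nTarget)) {
    nb <- min(batchSize, maxIter - examined)
    cand <- sampleSequence(scaffold, nb)
    examined <- examined + nb
    sc <- scoreSequences(model, cand, objective, library)
    ok <- sc >= objective$threshold
    ok <- ok & vapply(cand, .passesConstraints, TRUE,
                      constraints = constraints, USE.NAMES = FALSE)
    if (any(ok))
      kept <- rbind(kept, .designResult(cand[ok], sc[ok], "screening",
                                        TRUE))
  }
  if (is.null(kept))
    kept <- .designResult(character(0), numeric(0), character(0),
                          logical(0))
  if (nrow(kept) < nTarget)
    warning("screening cap reached with ", nrow(kept), "/", nTarget,
            " designs")
  kept <- head(kept, nTarget)
  attr(kept, "examined") <- examined
  kept
}

#' Evolution schedule
#'
#' Variants per cycle and a non-increasing per-cycle mutation count;
#' by default the mutation count decays 8, 4, 2, 1 over quartiles of
#' the cycle budget.
#'
#' @param variantsPerCycle Variants generated each cycle.
#' @param mutations Mutation counts over cycle quartiles
#'   (non-increasing).
#' @param maxCycles Cycle cap.
#' @export
evolutionSchedule <- function(variantsPerCycle = 100L,
                              mutations = c(8L, 4L, 2L, 1L),
                              maxCycles = 200L) {
  stopifnot(all(mutations >= 1L), all(diff(mutations) <= 0))
  list(variantsPerCycle = as.integer(variantsPerCycle),
       mutations = as.integer(mutations),
       maxCycles = as.integer(maxCycles))
}

.mutationsAt <- function(schedule, cycle) {
  q <- ceiling(cycle / schedule$maxCycles * length(schedule$mutations))
  schedule$mutations[min(max(q, 1L), length(schedule$mutations))]
}

# mutate m randomized positions; new base redrawn from the segment's
# base frequencies excluding the current base (zero-frequency bases can
# never be introduced)
.mutateSequence <- function(seq, scaffold, m) {
  mask <- which(randomizedMask(scaffold))
  segIdx <- rep(seq_along(scaffold@segments),
                vapply(scaffold@segments, function(s) s@length, 1L))
  pos <- sample(mask, min(m, length(mask)))
  ch <- strsplit(seq, "")[[1L]]
  for (p in pos) {
    freqs <- scaffold@segments[[segIdx[p]]]@baseFreqs
    cur <- match(ch[p], DNA_BASES)
    w <- freqs
    w[cur] <- 0
    if (sum(w) > 0) ch[p] <- sample(DNA_BASES, 1L, prob = w)
  }
  paste(ch, collapse = "")
}

#' In silico evolution design strategy
#'
#' From a random parent, each cycle generates a set of mutants (only
#' randomized positions mutate; the mutation count follows the
#' schedule) and passes the highest-scoring variant to the next cycle.
#' The run stops as soon as the current sequence scores at or above
#' the threshold and passes the constraints.
#'
#' @inheritParams screenDesigns
#' @param schedule From [evolutionSchedule()].
#' @param hillClimb Keep the parent when no variant beats it (default
#'   FALSE: the best variant always becomes the parent).
#' @return One-row data.frame (`accepted` FALSE carries best-so-far),
#'   with attribute `cycles` (per-cycle score log).
#' @export
evolveDesign <- function(scaffold, model, objective,
                         schedule = evolutionSchedule(),
                         constraints = designConstraints(),
                         hillClimb = FALSE, library = NULL) {
  parent <- sampleSequence(scaffold, 1L)
  parentScore <- scoreSequences(model, parent, objective, library)
  log <- data.frame(cycle = 0L, score = parentScore)
  best <- list(seq = parent, score = parentScore)
  for (cycle in seq_len(schedule$maxCycles)) {
    if (parentScore >= objective$threshold &&
        .passesConstraints(parent, constraints))
      return(structure(.designResult(parent, parentScore, "evolution",
                                     TRUE), cycles = log))
    m <- .mutationsAt(schedule, cycle)
    vars <- vapply(seq_len(schedule$variantsPerCycle), function(i)
      .mutateSequence(parent, scaffold, m), "")
    sc <- scoreSequences(model, vars, objective, library)
    top <- which.max(sc)
    if (!hillClimb || sc[top] > parentScore) {
      parent <- vars[top]
      parentScore <- sc[top]
    }
    if (parentScore > best$score)
      best <- list(seq = parent, score = parentScore)
    log <- rbind(log, data.frame(cycle = cycle, score = parentScore))
  }
  if (parentScore >= objective$threshold &&
      .passesConstraints(parent, constraints))
    return(structure(.designResult(parent, parentScore, "evolution",
                                   TRUE), cycles = log))
  structure(.designResult(best$seq, best$score, "evolution", FALSE),
            cycles = log)
}

#' Gradient ascent design strategy
#'
#' Maintains a continuous relaxation of the one-hot input and
#' iteratively adds the input gradient of the objective at randomized
#' positions (constant columns and zero-frequency bases stay frozen).
#' After every update the relaxation is rounded by per-column argmax to
#' a valid sequence, which is scored; the run stops when the rounded
#' sequence reaches the threshold and passes the constraints. Requires
#' an [EnsembleModel-class] (the gradient flows through the network;
#' with the extrapolation penalty the exact gradient of mean - SD is
#' used).
#'
#' @inheritParams screenDesigns
#' @param steps Step cap.
#' @param stepSize Gradient step on the relaxed input.
#' @return One-row data.frame with attribute `trace` (per-step rounded
#'   scores).
#' @export
gradientAscentDesign <- function(scaffold, model, objective, steps = 500L,
                                 stepSize = 0.1,
                                 constraints = designConstraints(),
                                 library = NULL) {
  stopifnot(is(model, "EnsembleModel"))
  enc <- model@encoder
  if (is.null(library)) library <- names(enc$libraries)[1L]
  w <- .objectiveWeights(objective, model@arch$n_out)
  if (length(w) == 1L) w <- as.numeric(w)
  rng <- .insertRange(library, enc)
  mask <- randomizedMask(scaffold)
  freeCols <- rng[1L]:rng[2L]
  freeCols <- freeCols[mask]
  # per-column allowed bases (zero-frequency bases never introduced)
  segIdx <- rep(seq_along(scaffold@segments),
                vapply(scaffold@segments, function(s) s@length, 1L))
  allowed <- matrix(TRUE, 4L, scaffoldLength(scaffold))
  for (p in which(mask))
    allowed[, p] <- scaffold@segments[[segIdx[p]]]@baseFreqs > 0
  seq0 <- sampleSequence(scaffold, 1L)
  X <- encodeBatch(seq0, library, enc, 0L)
  relax <- X
  best <- list(seq = seq0, score = -Inf)
  trace <- numeric(0)
  for (st in seq_len(steps)) {
    g <- .ensembleInputGrad(model, relax, w, objective$mergeMode)
    relax[, freeCols, 1L] <- relax[, freeCols, 1L] +
      stepSize * g[, freeCols, 1L]
    seqCur <- .roundRelaxation(relax[, rng[1L]:rng[2L], 1L], mask,
                               allowed, seq0)
    # rounded sequence re-embedded so flanks/constants stay exact
    relax[, rng[1L]:rng[2L], 1L][, !mask] <-
      oneHot(seqCur)[, !mask, drop = FALSE]
    sc <- scoreSequences(model, seqCur, objective, library)
    trace <- c(trace, sc)
    if (sc > best$score) best <- list(seq = seqCur, score = sc)
    if (sc >= objective$threshold &&
        .passesConstraints(seqCur, constraints))
      return(structure(.designResult(seqCur, sc, "gradient_ascent",
                                     TRUE), trace = trace))
  }
  structure(.designResult(best$seq, best$score, "gradient_ascent",
                          FALSE), trace = trace)
}

# argmax rounding restricted to allowed bases; constant positions keep
# the scaffold's bases
.roundRelaxation <- function(relaxCols, mask, allowed, template) {
  vals <- relaxCols
  vals[!allowed] <- -Inf
  ch <- DNA_BASES[max.col(t(vals), ties.method = "first")]
  tmpl <- strsplit(template, "")[[1L]]
  ch[!mask] <- tmpl[!mask]
  paste(ch, collapse = "")
}

# gradient of the merged objective wrt the relaxed input
.ensembleInputGrad <- function(ensemble, X, w, mergeMode) {
  k <- length(ensemble@submodels)
  grads <- lapply(ensemble@submodels, function(s)
    cnn_input_grad_cpp(s$params, s$net, X, w))
  if (mergeMode == "mean" || k == 1L)
    return(Reduce(`+`, grads) / k)
  scores <- vapply(ensemble@submodels, function(s)
    sum(cnn_predict_cpp(s$params, s$net, X)[, 1L] * w), 1)
  mn <- mean(scores)
  sdp <- sqrt(mean(scores^2) - mn^2)
  gMean <- Reduce(`+`, grads) / k
  if (sdp < 1e-12) return(gMean)
  # d(mean - sd)/dx = mean_i g_i - sum_i (s_i - mean) g_i / (k * sd)
  gSd <- Reduce(`+`, Map(function(g, s) (s - mn) * g, grads,
                         as.list(scores))) / (k * sdp)
  gMean - gSd
}

#' Produce a full design set with one strategy
#'
#' @inheritParams screenDesigns
#' @param strategy `"screening"`, `"evolution"` or `"gradient_ascent"`.
#' @param n Number of accepted designs wanted.
#' @param ... Passed to the strategy function.
#' @return data.frame of accepted designs.
#' @export
designSet <- function(scaffold, model, objective, n,
                      strategy = c("screening", "evolution",
                                   "gradient_ascent"),
                      constraints = designConstraints(), library = NULL,
                      maxAttempts = 5L * n, ...) {
  strategy <- match.arg(strategy)
  if (strategy == "screening")
    return(screenDesigns(scaffold, model, objective, n,
                         constraints = constraints, library = library,
                         ...))
  out <- NULL
  attempts <- 0L
  while ((is.null(out) || nrow(out) < n) && attempts < maxAttempts) {
    attempts <- attempts + 1L
    res <- if (strategy == "evolution")
      evolveDesign(scaffold, model, objective, constraints = constraints,
                   library = library, ...)
    else
      gradientAscentDesign(scaffold, model, objective,
                           constraints = constraints, library = library,
                           ...)
    if (res$accepted) out <- rbind(out, res)
  }
  if (is.null(out) || nrow(out) < n)
    warning("design attempts exhausted with ",
            if (is.null(out)) 0L else nrow(out), "/", n, " designs")
  out
}

#' Adjust a design threshold in fixed increments
#'
#' Downward mode lowers the threshold by `increment` until the runner
#' first succeeds (used when a strategy cannot reach the initial
#' threshold); upward mode raises it until the runner first fails and
#' returns the last achievable threshold. Budgets are iteration counts
#' for determinism.
#'
#' @param runner Function `f(threshold) -> logical` (whether a full
#'   design set could be produced).
#' @param initial Starting threshold.
#' @param direction `"down"` or `"up"`.
#' @param increment Step (0.05 score units).
#' @param maxSteps Iteration cap.
#' @return The final threshold (`NA` if downward mode never succeeds).
#' @export
adjustThreshold <- function(runner, initial, direction = c("down", "up"),
                            increment = 0.05, maxSteps = 100L) {
  direction <- match.arg(direction)
  stopifnot(increment > 0)
  # thresholds form an exact arithmetic sequence (no accumulated drift)
  if (direction == "down") {
    for (i in 0:(maxSteps - 1L)) {
      t <- initial - i * increment
      if (runner(t)) return(t)
    }
    return(NA_real_)
  }
  if (!runner(initial)) return(NA_real_)
  t <- initial
  for (i in seq_len(maxSteps)) {
    cand <- initial + i * increment
    if (!runner(cand)) return(t)
    t <- cand
  }
  t
}

#' Pairwise alignment-distance diversity of a design set
#'
#' Mean pairwise Needleman-Wunsch distance within a set of sequences,
#' used as a sequence-diversity proxy when comparing strategies.
#'
#' @param seqs Character vector.
#' @param maxPairs Subsample cap on pairs.
#' @export
designDiversity <- function(seqs, maxPairs = 2000L) {
  n <- length(seqs)
  if (n < 2L) return(NA_real_)
  pairs <- t(combn(n, 2L))
  if (nrow(pairs) > maxPairs)
    pairs <- pairs[sample.int(nrow(pairs), maxPairs), , drop = FALSE]
  mean(nwDistance(seqs[pairs[, 1L]], seqs[pairs[, 2L]]))
}
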