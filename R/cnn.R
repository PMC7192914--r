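#' Sequence encoder configuration
#'
#' Library members are embedded in their scaffold's vector-context
#' flanks, padded with at least `pad` bp on each side, and pad lengths
#' are equalized across libraries so that every encoded example shares
#' one length. A frame of `shiftMax` extra positions allows the
#' training-time shift augmentation: the encoded sequence is displaced
#' by 0..`shiftMax` positions within the frame (prediction always uses
#' shift 0).
#'
#' @param scaffolds Named list of [LibraryScaffold-class] objects (one
#'   per library).
#' @param pad Minimum pad on each side (bp).
#' @param shiftMax Largest augmentation shift (bp).
#' @return List config used by [encodeBatch()] and the trainers.
#' @export
encoderConfig <- function(scaffolds, pad = 25L, shiftMax = 7L) {
  if (is(scaffolds, "LibraryScaffold"))
    scaffolds <- setNames(list(scaffolds), scaffoldName(scaffolds))
  lens <- vapply(scaffolds, scaffoldLength, 1L)
  target <- max(lens) + 2L * pad       # common padded length, pre-shift
  libs <- lapply(scaffolds, function(sc) {
    L <- scaffoldLength(sc)
    extra <- target - L                 # total pad for this library
    pad5 <- extra %/% 2L
    pad3 <- extra - pad5
    need5 <- pad5 + shiftMax
    need3 <- pad3 + shiftMax
    f5 <- .cycleTo(sc@flank5, need5, fromEnd = TRUE)
    f3 <- .cycleTo(sc@flank3, need3, fromEnd = FALSE)
    list(scaffold = sc, pad5 = pad5, pad3 = pad3, flank5 = f5,
         flank3 = f3, length = L)
  })
  list(libraries = libs, pad = as.integer(pad),
       shiftMax = as.integer(shiftMax),
       frame = as.integer(target + shiftMax))
}

# recycle a flank string to exactly n bases (taking the end nearest the
# insert); empty flanks fall back to 'A' padding
.cycleTo <- function(flank, n, fromEnd) {
  if (n == 0L) return("")
  if (!nchar(flank)) flank <- "A"
  reps <- strrep(flank, ceiling(n / nchar(flank)))
  if (fromEnd) substr(reps, nchar(reps) - n + 1L, nchar(reps))
  else substr(reps, 1L, n)
}

# integer base-code matrix (frame x B) for a batch at given shifts
.encodeCodes <- function(seqs, library, enc, shift) {
  lib <- enc$libraries[[library]]
  if (is.null(lib)) stop("unknown library '", library, "'")
  shift <- rep_len(as.integer(shift), length(seqs))
  if (any(shift < 0L | shift > enc$shiftMax))
    stop("shift must be in [0, shiftMax]")
  if (any(nchar(seqs) != lib$length))
    stop("sequence length does not match the library scaffold")
  F <- enc$frame
  ext <- paste0(lib$flank5, seqs, lib$flank3)   # frame + shiftMax long
  out <- matrix(0L, F, length(seqs))
  for (i in seq_along(seqs)) {
    start <- enc$shiftMax - shift[i] + 1L       # shift displaces content
    out[, i] <- match(strsplit(substr(ext[i], start, start + F - 1L),
                               "")[[1L]], DNA_BASES)
  }
  if (anyNA(out)) stop("non-ACGT character in sequence or flank")
  out
}

# column range (within the frame) occupied by the insert at shift 0
.insertRange <- function(library, enc) {
  lib <- enc$libraries[[library]]
  start <- lib$pad5 + 1L
  c(start, start + lib$length - 1L)
}

#' One-hot encode a batch of library members
#'
#' @param seqs Character vector of sequences from one library.
#' @param library Library name (must match the encoder config).
#' @param enc Config from [encoderConfig()].
#' @param shift Displacement within the frame, scalar or per-sequence.
#' @return 4 x frame x B numeric array.
#' @export
encodeBatch <- function(seqs, library, enc, shift = 0L) {
  codes <- .encodeCodes(seqs, library, enc, shift)
  F <- nrow(codes)
  B <- ncol(codes)
  arr <- array(0, dim = c(4L, F, B))
  arr[cbind(as.vector(codes),
            rep(seq_len(F), times = B),
            rep(seq_len(B), each = F))] <- 1
  arr
}

#' Huber loss
#'
#' Quadratic within `delta` of zero error, linear beyond:
#' `e^2/2` if `|e| <= delta`, else `delta * (|e| - delta/2)`.
#'
#' @param y,yHat Observed and predicted values (vectorized).
#' @param delta Transition point (default 0.15 log10 units).
#' @export
huberLoss <- function(y, yHat, delta = 0.15) {
  if (delta <= 0) stop("delta must be > 0")
  e <- abs(y - yHat)
  ifelse(e <= delta, e^2 / 2, delta * (e - delta / 2))
}

#' Partition examples into a shared test set and validation folds
#'
#' Deterministic given `seed`: 10% (by default) of examples form a test
#' set shared by all submodels; the rest is split into `k` near-equal
#' disjoint folds, one per submodel, used for validation.
#'
#' @param n Number of examples.
#' @param k Number of folds/submodels.
#' @param testFraction Held-out fraction.
#' @param seed Integer seed.
#' @return List with `test` (integer vector) and `folds` (list of k
#'   integer vectors).
#' @export
makePartitions <- function(n, k = 9L, testFraction = 0.1, seed = 1L) {
  if (n < k + 1L) stop("need at least k + 1 examples")
  set.seed(seed)
  perm <- sample.int(n)
  nTest <- round(testFraction * n)
  test <- sort(perm[seq_len(nTest)])
  rest <- perm[-seq_len(nTest)]
  folds <- split(rest, rep(seq_len(k), length.out = length(rest)))
  list(test = test, folds = unname(lapply(folds, sort)))
}

#' Model architecture configuration
#'
#' The `paper` preset is the full-size model: 6 conv blocks of width 8
#' with 128 channels (batch normalization before each ReLU, max-pooling
#' of stride 2 after each block), two 128-unit dense layers, L2 weight
#' 1e-4. The `small` preset (2 blocks, 16 channels) is sized for
#' desk-scale experiments and tests.
#'
#' @param preset `"small"` or `"paper"`.
#' @param nOutputs 1 (single activity) or 2 (uninduced + induced).
#' @param convBlocks,kernel,channels,fcUnits,l2 Overrides.
#' @return List config.
#' @export
architectureConfig <- function(preset = c("small", "paper"), nOutputs = 1L,
                               convBlocks = NULL, kernel = 8L,
                               channels = NULL, fcUnits = NULL,
                               l2 = 1e-4) {
  preset <- match.arg(preset)
  if (is.null(convBlocks)) convBlocks <- if (preset == "paper") 6L else 2L
  if (is.null(channels)) channels <- if (preset == "paper") 128L else 16L
  if (is.null(fcUnits))
    fcUnits <- c(128L, 128L)
  stopifnot(nOutputs %in% 1:2)
  list(n_blocks = as.integer(convBlocks), kernel = as.integer(kernel),
       channels = as.integer(channels), fc = as.integer(fcUnits),
       n_out = as.integer(nOutputs), l2 = l2)
}

#' Training configuration
#'
#' The full-size settings are Adam at learning rate 1e-5 with Huber
#' delta 0.15 and early stopping after 5 epochs without validation
#' improvement; the `small` preset raises the learning rate and the
#' patience to suit the reduced architecture and desk-scale data.
#' When the validation loss plateaus for `lrPatience` epochs the
#' learning rate is multiplied by `lrDecay` (set `lrDecay = 1` to
#' disable).
#'
#' @param preset `"small"` or `"paper"`.
#' @param learningRate,batchSize,maxEpochs,patience,delta Overrides.
#' @param lrDecay Plateau decay factor for the learning rate.
#' @param lrPatience Epochs without improvement before decaying.
#' @return List config.
#' @export
trainConfig <- function(preset = c("small", "paper"), learningRate = NULL,
                        batchSize = 256L, maxEpochs = NULL, patience = NULL,
                        delta = 0.15, lrDecay = 0.7, lrPatience = 5L) {
  preset <- match.arg(preset)
  if (is.null(learningRate))
    learningRate <- if (preset == "paper") 1e-5 else 8e-3
  if (is.null(maxEpochs)) maxEpochs <- if (preset == "paper") 500L else 120L
  if (is.null(patience)) patience <- if (preset == "paper") 5L else 12L
  stopifnot(patience >= 1L)
  list(learning_rate = learningRate, batch_size = as.integer(batchSize),
       max_epochs = as.integer(maxEpochs), patience = as.integer(patience),
       delta = delta, lr_decay = lrDecay,
       lr_patience = as.integer(lrPatience))
}

# architecture + frame -> config list consumed by the C++ core
.netConfig <- function(arch, frame) {
  c(arch[c("n_blocks", "kernel", "channels", "fc", "n_out")],
    list(frame = as.integer(frame)))
}

# He-style initialization; uses R's RNG
.initParams <- function(arch, frame) {
  P <- list()
  L <- frame
  cin <- 4L
  C <- arch$channels
  K <- arch$kernel
  for (b in seq_len(arch$n_blocks)) {
    fan <- cin * K
    P <- c(P, list(matrix(rnorm(C * fan, sd = sqrt(2 / fan)), C, fan),
                   matrix(1, C, 1L), matrix(0, C, 1L),
                   matrix(0, C, 1L), matrix(1, C, 1L)))
    L <- L %/% 2L
    cin <- C
  }
  inDim <- C * L
  for (u in arch$fc) {
    P <- c(P, list(matrix(rnorm(u * inDim, sd = sqrt(2 / inDim)), u, inDim),
                   matrix(1, u, 1L), matrix(0, u, 1L),
                   matrix(0, u, 1L), matrix(1, u, 1L)))
    inDim <- u
  }
  P <- c(P, list(matrix(rnorm(arch$n_out * inDim, sd = sqrt(1 / inDim)),
                        arch$n_out, inDim),
                 matrix(0, arch$n_out, 1L)))
  P
}

.zeroLike <- function(P) lapply(P, function(m) m * 0)

#' Train one convolutional submodel
#'
#' Trains with Adam on Huber loss; every epoch re-encodes the training
#' examples at a fresh uniform shift in `[0, shiftMax]` (validation
#' uses shift 0). Training stops after `patience` consecutive epochs
#' without improvement in validation loss, and the weights from the
#' best validation epoch are returned.
#'
#' @param seqs Character vector of training sequences.
#' @param libraries Library label per sequence.
#' @param y Numeric vector (or 1/2-column matrix) of target activities.
#'   With a two-output model, single-activity examples supervise both
#'   outputs.
#' @param enc Encoder config ([encoderConfig()]).
#' @param arch Architecture config ([architectureConfig()]).
#' @param cfg Training config ([trainConfig()]).
#' @param trainIdx,valIdx Disjoint index vectors.
#' @return List with `params`, `history` (per-epoch train/val loss),
#'   `bestEpoch`, `arch`, `net`.
#' @export
trainSubmodel <- function(seqs, libraries, y, enc, arch, cfg,
                          trainIdx, valIdx) {
  if (!length(trainIdx) || !length(valIdx)) stop("empty train or val set")
  if (length(intersect(trainIdx, valIdx)))
    stop("train and validation sets overlap")
  libraries <- rep_len(libraries, length(seqs))
  Y <- .targetMatrix(y, arch$n_out)
  net <- .netConfig(arch, enc$frame)
  P <- .initParams(arch, enc$frame)
  M <- .zeroLike(P)
  V <- .zeroLike(P)
  step <- 0L
  Xval <- .encodeMixed(seqs[valIdx], libraries[valIdx], enc, 0L)
  Yval <- Y[, valIdx, drop = FALSE]
  hist <- data.frame(epoch = integer(0), train = numeric(0),
                     val = numeric(0))
  best <- list(loss = Inf, params = P, epoch = 0L)
  bad <- 0L
  lr <- cfg$learning_rate
  lrDecay <- if (is.null(cfg$lr_decay)) 1 else cfg$lr_decay
  lrPatience <- if (is.null(cfg$lr_patience)) 3L else cfg$lr_patience
  for (epoch in seq_len(cfg$max_epochs)) {
    shifts <- sample(0:enc$shiftMax, length(trainIdx), replace = TRUE)
    Xtr <- .encodeMixed(seqs[trainIdx], libraries[trainIdx], enc, shifts)
    ord <- sample.int(length(trainIdx)) - 1L
    up <- cnn_train_epoch_cpp(P, M, V, step, net, Xtr,
                              Y[, trainIdx, drop = FALSE], ord,
                              cfg$batch_size, lr,
                              cfg$delta, arch$l2)
    P <- up$params; M <- up$m; V <- up$v; step <- up$step
    valPred <- cnn_predict_cpp(P, net, Xval)
    valLoss <- mean(huberLoss(Yval, valPred, cfg$delta))
    hist <- rbind(hist, data.frame(epoch = epoch, train = up$loss,
                                   val = valLoss))
    if (valLoss < best$loss) {
      best <- list(loss = valLoss, params = P, epoch = epoch)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= cfg$patience) break
      if (lrDecay < 1 && bad %% lrPatience == 0L) lr <- lr * lrDecay
    }
  }
  list(params = best$params, history = hist, bestEpoch = best$epoch,
       arch = arch, net = net)
}

.targetMatrix <- function(y, nOut) {
  if (is.matrix(y)) {
    if (ncol(y) == nOut) return(unname(t(y)))
    if (ncol(y) == 1L) y <- y[, 1L]
    else stop("target has wrong number of columns")
  }
  # single targets supervise every output
  matrix(rep(y, each = nOut), nrow = nOut)
}

# encode a batch that may mix libraries (groups by library internally)
.encodeMixed <- function(seqs, libraries, enc, shift) {
  libraries <- rep_len(libraries, length(seqs))
  shift <- rep_len(shift, length(seqs))
  arr <- array(0, dim = c(4L, enc$frame, length(seqs)))
  for (lib in unique(libraries)) {
    sel <- which(libraries == lib)
    arr[, , sel] <- encodeBatch(seqs[sel], lib, enc, shift[sel])
  }
  arr
}

#' Train a model ensemble
#'
#' Trains `k` submodels sharing one held-out test set; submodel `j` is
#' validated on fold `j` and trained on the remaining folds.
#'
#' @inheritParams trainSubmodel
#' @param k Number of submodels (9 at full scale).
#' @param nFolds Number of validation partitions of the non-test data
#'   (default `k`). The full-size design always uses nine partitions;
#'   a reduced ensemble can train fewer submodels while keeping the
#'   nine-fold partition structure (`k = 3, nFolds = 9`), so each
#'   submodel still trains on 8/9 of the non-test data.
#' @param testFraction Shared held-out fraction.
#' @param seed Seed for partitioning and initialization.
#' @param mergeMode Default prediction merge mode.
#' @return An [EnsembleModel-class].
#' @export
trainEnsemble <- function(seqs, libraries, y, enc, arch, cfg, k = 9L,
                          nFolds = NULL, testFraction = 0.1, seed = 1L,
                          mergeMode = "mean") {
  n <- length(seqs)
  if (is.null(nFolds)) nFolds <- k
  stopifnot(k <= nFolds)
  parts <- makePartitions(n, nFolds, testFraction, seed)
  libraries <- rep_len(libraries, n)
  subs <- vector("list", k)
  for (j in seq_len(k)) {
    trainIdx <- sort(unlist(parts$folds[-j]))
    if (nFolds == 1L) { # degenerate single 80/10/10 model
      fold <- parts$folds[[1L]]
      nv <- max(1L, round(length(fold) / 9))
      valIdx <- fold[seq_len(nv)]
      trainIdx <- setdiff(fold, valIdx)
    } else {
      valIdx <- parts$folds[[j]]
    }
    subs[[j]] <- trainSubmodel(seqs, libraries, y, enc, arch, cfg,
                               trainIdx, valIdx)
  }
  new("EnsembleModel", submodels = subs, testIdx = as.integer(parts$test),
      folds = parts$folds[seq_len(k)], encoder = enc, arch = arch,
      mergeMode = mergeMode)
}

#' Predict activities with a submodel
#'
#' @param submodel A trained submodel (from [trainSubmodel()]).
#' @param seqs,libraries,enc As in [trainSubmodel()]; prediction uses
#'   shift 0.
#' @return B x nOutputs matrix of predictions.
#' @export
predictSubmodel <- function(submodel, seqs, libraries, enc) {
  X <- .encodeMixed(seqs, libraries, enc, 0L)
  t(cnn_predict_cpp(submodel$params, submodel$net, X))
}

#' Merged ensemble predictions
#'
#' `mean` averages the submodels; `mean_minus_sd` subtracts the
#' population-form standard deviation (divisor k) to penalize
#' sequences on which the submodels disagree (extrapolation penalty).
#'
#' @param ensemble An [EnsembleModel-class].
#' @param seqs Character vector of sequences.
#' @param libraries Library label(s).
#' @param mergeMode `"mean"` or `"mean_minus_sd"` (default: the
#'   ensemble's mode).
#' @return B x nOutputs matrix of merged predictions.
#' @export
predictMerge <- function(ensemble, seqs, libraries = NULL,
                         mergeMode = NULL) {
  if (is.null(mergeMode)) mergeMode <- ensemble@mergeMode
  if (is.null(libraries))
    libraries <- names(ensemble@encoder$libraries)[1L]
  preds <- lapply(ensemble@submodels, predictSubmodel, seqs = seqs,
                  libraries = libraries, enc = ensemble@encoder)
  .mergePreds(preds, mergeMode)
}

.mergePreds <- function(preds, mergeMode) {
  k <- length(preds)
  d <- dim(preds[[1L]])
  arr <- array(unlist(preds), dim = c(d, k))  # B x nOut x k
  mn <- apply(arr, c(1L, 2L), mean)
  if (mergeMode == "mean") return(mn)
  sdp <- apply(arr, c(1L, 2L), function(x)
    sqrt(mean(x^2) - mean(x)^2))           # population form, divisor k
  mn - sdp
}

#' Activation ratio from predicted activities
#'
#' @param induced,uninduced Predicted log10 activities.
#' @return data.frame with `logRatio` (difference on the log10 scale)
#'   and `fold` (10^logRatio).
#' @export
activationRatio <- function(induced, uninduced) {
  lr <- induced - uninduced
  data.frame(logRatio = lr, fold = 10^lr)
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` of predictions against observations.
#'
#' @param pred,obs Numeric vectors.
#' @export
rSquared <- function(pred, obs) {
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}
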