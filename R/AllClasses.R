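#' @import methods
#' @importFrom stats approx dnorm lm median pnorm quantile rbinom rmultinom
#'   rnorm rpois runif sd setNames var coef
#' @importFrom utils read.delim write.table head tail combn
#' @importFrom tools md5sum
#' @useDynLib PromoterForge, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

DNA_BASES <- c("A", "C", "G", "T")

.validDna <- function(x) {
  all(grepl("^[ACGT]+$", x))
}

#' Segment of a promoter scaffold
#'
#' A scaffold segment is either a constant motif (an explicit DNA string,
#' e.g. a transcription-factor binding site or TATA box) or a randomized
#' spacer of fixed length whose bases are drawn independently from a
#' per-segment base-frequency vector over A, C, G, T.
#'
#' @slot kind `"constant"` or `"randomized"`.
#' @slot sequence DNA string (constant segments only).
#' @slot length Segment length in bp.
#' @slot baseFreqs Probability 4-vector over A, C, G, T (randomized only).
#' @slot label Free-text label (e.g. `"RAP1"`, `"core"`).
#' @export
setClass("Segment",
  representation(kind = "character", sequence = "character",
                 length = "integer", baseFreqs = "numeric",
                 label = "character"))

setValidity("Segment", function(object) {
  msg <- NULL
  if (!object@kind %in% c("constant", "randomized"))
    msg <- c(msg, "kind must be 'constant' or 'randomized'")
  if (object@length < 1L) msg <- c(msg, "length must be >= 1")
  if (object@kind == "constant") {
    if (!.validDna(object@sequence))
      msg <- c(msg, "constant sequence must contain only A,C,G,T")
    if (nchar(object@sequence) != object@length)
      msg <- c(msg, "length must equal nchar(sequence)")
  } else {
    if (length(object@baseFreqs) != 4L)
      msg <- c(msg, "baseFreqs must have length 4")
    else {
      if (any(object@baseFreqs < 0))
        msg <- c(msg, "baseFreqs must be nonnegative")
      if (abs(sum(object@baseFreqs) - 1) > 1e-9)
        msg <- c(msg, "baseFreqs must sum to 1 (tolerance 1e-9)")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Promoter library scaffold
#'
#' Ordered arrangement of constant and randomized segments that defines a
#' promoter library design, together with the vector context flanking the
#' promoter on either side (used to pad model inputs).
#'
#' @slot name Scaffold name.
#' @slot segments List of [Segment-class] objects, 5' to 3'.
#' @slot flank5,flank3 Vector context DNA strings (5' and 3').
#' @export
setClass("LibraryScaffold",
  representation(name = "character", segments = "list",
                 flank5 = "character", flank3 = "character"))

setValidity("LibraryScaffold", function(object) {
  msg <- NULL
  if (!length(object@segments)) msg <- c(msg, "at least one segment required")
  if (!all(vapply(object@segments, is, TRUE, class2 = "Segment")))
    msg <- c(msg, "segments must all be Segment objects")
  for (fl in c(object@flank5, object@flank3))
    if (nchar(fl) && !.validDna(fl))
      msg <- c(msg, "flanks must contain only A,C,G,T")
  if (is.null(msg)) TRUE else msg
})

#' Contiguous FACS sort-bin layout
#'
#' `N` contiguous, strictly increasing activity bins on the log10
#' GFP:mCherry scale; bin `i` has edges `breaks[i]`, `breaks[i+1]`.
#'
#' @slot breaks Numeric vector of N+1 strictly increasing bin edges.
#' @export
setClass("BinLayout", representation(breaks = "numeric"))

setValidity("BinLayout", function(object) {
  if (length(object@breaks) < 3L)
    return("at least 2 bins (3 breaks) required")
  if (any(diff(object@breaks) <= 0))
    return("breaks must be strictly increasing")
  TRUE
})

#' Additive sequence-to-activity ground truth
#'
#' Deterministic generative model used by the synthetic-data module: the
#' log10 activity of a sequence is `baseline` plus per-position per-base
#' additive weights plus a weight for every (possibly overlapping) match of
#' each planted motif; the induced channel adds `inducedOffset`.
#'
#' @slot baseline Baseline log10 activity.
#' @slot positionWeights 4 x L numeric matrix (rows A,C,G,T).
#' @slot motifWeights data.frame with columns `motif`, `weight`.
#' @slot inducedOffset Offset added for the induced channel.
#' @export
setClass("GroundTruthModel",
  representation(baseline = "numeric", positionWeights = "matrix",
                 motifWeights = "data.frame", inducedOffset = "numeric"))

setValidity("GroundTruthModel", function(object) {
  msg <- NULL
  if (nrow(object@positionWeights) != 4L)
    msg <- c(msg, "positionWeights must have 4 rows (A,C,G,T)")
  if (nrow(object@motifWeights) &&
      !all(c("motif", "weight") %in% names(object@motifWeights)))
    msg <- c(msg, "motifWeights needs columns 'motif' and 'weight'")
  if (is.null(msg)) TRUE else msg
})

#' FACS sort simulation settings
#'
#' @slot layout A [BinLayout-class].
#' @slot sigmaCell Cell-to-cell SD of log10 activity (shared by sequences).
#' @slot epsilon Uniform-across-bins contaminant fraction.
#' @slot cellsPerSequence Expected sorted cells per sequence.
#' @slot outOfRange `"clamp"` (out-of-range cells go to the nearest end
#'   bin) or `"discard"`.
#' @export
setClass("SortConfig",
  representation(layout = "BinLayout", sigmaCell = "numeric",
                 epsilon = "numeric", cellsPerSequence = "numeric",
                 outOfRange = "character"))

setValidity("SortConfig", function(object) {
  msg <- NULL
  if (object@sigmaCell <= 0) msg <- c(msg, "sigmaCell must be > 0")
  if (object@epsilon < 0 || object@epsilon > 1)
    msg <- c(msg, "epsilon must be in [0, 1]")
  if (!object@outOfRange %in% c("clamp", "discard"))
    msg <- c(msg, "outOfRange must be 'clamp' or 'discard'")
  if (is.null(msg)) TRUE else msg
})

#' Read simulation settings
#'
#' @slot substitutionRate Per-base substitution error probability.
#' @slot meanDepth Expected counting reads per sorted cell ratio unit
#'   (reads per sequence per bin scale with bin cell counts).
#' @slot meanIdDepth Expected full-length identification reads per sequence.
#' @slot keyLength Length of the fully randomized 5' identifier (bp).
#' @export
setClass("ReadSimConfig",
  representation(substitutionRate = "numeric", meanDepth = "numeric",
                 meanIdDepth = "numeric", keyLength = "integer"))

setValidity("ReadSimConfig", function(object) {
  msg <- NULL
  if (object@substitutionRate < 0 || object@substitutionRate >= 0.5)
    msg <- c(msg, "substitutionRate must be in [0, 0.5)")
  if (object@keyLength < 1L) msg <- c(msg, "keyLength must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Ensemble of convolutional sequence-to-activity models
#'
#' `k` submodels sharing one held-out test set; submodel `j` is validated
#' on fold `j` and trained on the remaining folds. Predictions are merged
#' by their mean, or mean minus (population) standard deviation to
#' penalize extrapolation.
#'
#' @slot submodels List of trained submodels (parameters + history).
#' @slot testIdx Integer indices of the shared held-out test examples.
#' @slot folds List of integer validation-fold indices, one per submodel.
#' @slot encoder Encoder configuration (see [encoderConfig()]).
#' @slot arch Architecture configuration (see [architectureConfig()]).
#' @slot mergeMode Default merge mode, `"mean"` or `"mean_minus_sd"`.
#' @export
setClass("EnsembleModel",
  representation(submodels = "list", testIdx = "integer", folds = "list",
                 encoder = "list", arch = "list", mergeMode = "character"))

setValidity("EnsembleModel", function(object) {
  msg <- NULL
  if (!length(object@submodels)) msg <- c(msg, "no submodels")
  if (!object@mergeMode %in% c("mean", "mean_minus_sd"))
    msg <- c(msg, "mergeMode must be 'mean' or 'mean_minus_sd'")
  fo <- unlist(object@folds)
  if (length(fo) && anyDuplicated(fo))
    msg <- c(msg, "validation folds must be disjoint")
  if (length(intersect(fo, object@testIdx)))
    msg <- c(msg, "test set must be disjoint from validation folds")
  if (is.null(msg)) TRUE else msg
})

#' Saturation-mutagenesis profile of one sequence
#'
#' Signed score differentials (mutant minus original) for all single-base
#' substitutions of a sequence under a model scorer, plus the derived
#' per-position mutagenesis score, defined as the largest predicted loss:
#' `max over the three mutants of (original - mutant)`.
#'
#' @slot sequence The scanned DNA sequence.
#' @slot originalScore Model score of the unmutated sequence.
#' @slot diffs 4 x L matrix of signed differentials; `NA` at each
#'   position's original base.
#' @slot positionScore Numeric length-L vector of position scores.
#' @slot mask Logical length-L vector, `TRUE` at randomized positions.
#' @export
setClass("MutagenesisProfile",
  representation(sequence = "character", originalScore = "numeric",
                 diffs = "matrix", positionScore = "numeric",
                 mask = "logical"))

setValidity("MutagenesisProfile", function(object) {
  L <- nchar(object@sequence)
  msg <- NULL
  if (ncol(object@diffs) != L) msg <- c(msg, "diffs must have L columns")
  if (length(object@positionScore) != L)
    msg <- c(msg, "positionScore must have length L")
  if (length(object@mask) != L) msg <- c(msg, "mask must have length L")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "LibraryScaffold", function(object) {
  kinds <- vapply(object@segments, function(s) s@kind, "")
  cat("LibraryScaffold '", object@name, "': ", scaffoldLength(object),
      " bp, ", sum(kinds == "randomized"), " randomized / ",
      length(kinds), " segments (",
      round(100 * mean(randomizedMask(object))), "% of positions)\n",
      sep = "")
})

setMethod("show", "BinLayout", function(object) {
  n <- length(object@breaks) - 1L
  cat("BinLayout: ", n, " bins on [", min(object@breaks), ", ",
      max(object@breaks), "]\n", sep = "")
})

setMethod("show", "EnsembleModel", function(object) {
  cat("EnsembleModel: ", length(object@submodels), " submodels, ",
      length(object@testIdx), " shared test examples, merge mode '",
      object@mergeMode, "'\n", sep = "")
})

setMethod("show", "MutagenesisProfile", function(object) {
  cat("MutagenesisProfile: ", nchar(object@sequence),
      " bp, original score ", signif(object@originalScore, 4), "\n",
      sep = "")
})
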