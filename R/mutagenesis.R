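#' In silico saturation mutagenesis of one sequence
#'
#' Scores all 3L single-base substitutions of a sequence under a model
#' scorer and records signed score differentials (mutant minus
#' original; negative means the mutation is predicted to lose
#' activity). The per-position mutagenesis score is the greatest
#' predicted loss, `max over the three mutants of (original - mutant)`.
#'
#' @param seq DNA string.
#' @param model An [EnsembleModel-class] or scoring function
#'   `f(seqs) -> vector/matrix`.
#' @param objective From [designObjective()]; selects the scored
#'   output and merge mode.
#' @param scaffold Optional [LibraryScaffold-class]; its randomized
#'   mask is attached (constant positions are reported but flagged).
#' @param library Library label for ensemble scoring.
#' @return A [MutagenesisProfile-class].
#' @export
singleMutantScan <- function(seq, model, objective, scaffold = NULL,
                             library = NULL) {
  codes <- .baseCodes(seq)
  L <- length(codes)
  muts <- character(3L * L)
  idx <- 1L
  slots <- matrix(0L, 2L, 3L * L)  # row 1: position, row 2: base code
  for (p in seq_len(L)) {
    for (b in seq_len(4L)[-codes[p]]) {
      s <- seq
      substr(s, p, p) <- DNA_BASES[b]
      muts[idx] <- s
      slots[, idx] <- c(p, b)
      idx <- idx + 1L
    }
  }
  all <- scoreSequences(model, c(seq, muts), objective, library)
  orig <- all[1L]
  diffs <- matrix(NA_real_, 4L, L, dimnames = list(DNA_BASES, NULL))
  diffs[cbind(slots[2L, ], slots[1L, ])] <- all[-1L] - orig
  posScore <- apply(diffs, 2L, function(d) max(orig - (orig + d),
                                               na.rm = TRUE))
  mask <- if (is.null(scaffold)) rep(TRUE, L) else
    randomizedMask(scaffold)
  new("MutagenesisProfile", sequence = seq, originalScore = orig,
      diffs = diffs, positionScore = posScore, mask = mask)
}

#' Position-importance profile across sequences
#'
#' Per-position mutagenesis scores are averaged across sequences and
#' normalized to the largest mean, yielding importance values in
#' `[0, 1]` with maximum exactly 1.
#'
#' @param profiles List of [MutagenesisProfile-class] (same length).
#' @return data.frame with `position`, `importance`, `randomized`.
#' @export
positionImportance <- function(profiles) {
  if (!length(profiles)) stop("no profiles")
  Ls <- vapply(profiles, function(p) length(p@positionScore), 1L)
  if (length(unique(Ls)) != 1L) stop("profiles have unequal lengths")
  # negative position scores (all three mutants improve the score) are
  # floored at zero so the importance track stays in [0, 1]
  m <- rowMeans(vapply(profiles, function(p) pmax(p@positionScore, 0),
                       numeric(Ls[1L])))
  mx <- max(m)
  data.frame(position = seq_along(m),
             importance = if (mx > 0) m / mx else m,
             randomized = profiles[[1L]]@mask)
}

# per-position strongest predicted loss (most negative differential)
.minDiffs <- function(profile) {
  apply(profile@diffs, 2L, min, na.rm = TRUE)
}

#' Candidate motif blocks with strong predicted loss
#'
#' Pools the per-position minimal signed differentials over all
#' randomizable positions of all profiles, takes the quantile that
#' selects `selectFraction` of them (the most negative tail), and
#' reports maximal runs of at least `minLen` consecutive
#' below-threshold randomizable positions in each sequence.
#'
#' @param profiles List of [MutagenesisProfile-class].
#' @param minLen Minimum block length (6 bp).
#' @param selectFraction Fraction of randomizable bases selected
#'   (0.05).
#' @return List with `threshold` and `blocks` (list of
#'   [IRanges::IRanges] per profile).
#' @export
lowScoreBlocks <- function(profiles, minLen = 6L, selectFraction = 0.05) {
  stopifnot(selectFraction > 0, selectFraction < 1)
  vals <- unlist(lapply(profiles, function(p) .minDiffs(p)[p@mask]))
  thr <- quantile(vals, selectFraction, names = FALSE)
  blocks <- lapply(profiles, function(p) {
    below <- .minDiffs(p) < thr & p@mask
    r <- IRanges::reduce(IRanges::IRanges(which(below), width = 1L))
    r[IRanges::width(r) >= minLen]
  })
  list(threshold = thr, blocks = blocks)
}

# longest (TA)+ run, in bases, whole units only
.longestRepeat <- function(seq, unit = "TA") {
  hits <- gregexpr(paste0("(", unit, ")+"), seq)[[1L]]
  if (hits[1L] == -1L) return(IRanges::IRanges())
  lens <- attr(hits, "match.length")
  lens <- lens - lens %% nchar(unit)   # drop partial trailing unit
  top <- which.max(lens)
  IRanges::IRanges(start = as.integer(hits[top]), width = lens[top])
}

#' TA-repeat score differentials
#'
#' For each sequence, locates the longest TA dinucleotide repeat within
#' `region` (default: the first randomized segment, the 5' spacer) and
#' computes the median signed differential over all single mutations
#' inside it. Sequences whose longest repeat is shorter than `minLen`
#' contribute only to the baseline, which pools differentials at region
#' positions outside any qualifying repeat.
#'
#' @param profiles List of [MutagenesisProfile-class].
#' @param scaffold The design scaffold (defines the 5' spacer region).
#' @param unit Repeat unit (default `"TA"`).
#' @param minLen Minimum qualifying repeat length in bases.
#' @param region Optional explicit `c(start, end)` region.
#' @return List with `byLength` (repeat length, n, median of
#'   per-sequence medians), `baseline` (median differential outside
#'   repeats) and `perSequence`.
#' @export
repeatDifferential <- function(profiles, scaffold = NULL, unit = "TA",
                               minLen = 6L, region = NULL) {
  if (is.null(region)) {
    if (is.null(scaffold)) stop("give scaffold or region")
    st <- segmentTable(scaffold)
    sp <- st[st$kind == "randomized", ][1L, ]
    region <- c(sp$start, sp$end)
  }
  perSeq <- lapply(profiles, function(p) {
    sub <- substr(p@sequence, region[1L], region[2L])
    rep_ <- .longestRepeat(sub, unit)
    if (length(rep_) && IRanges::width(rep_) >= minLen) {
      pos <- (region[1L] - 1L + IRanges::start(rep_)):
             (region[1L] - 1L + IRanges::end(rep_))
      data.frame(length = IRanges::width(rep_),
                 median = median(p@diffs[, pos], na.rm = TRUE))
    } else {
      data.frame(length = 0L, median = NA_real_)
    }
  })
  perSeq <- do.call(rbind, perSeq)
  qual <- perSeq[perSeq$length >= minLen, , drop = FALSE]
  byLength <- if (nrow(qual)) {
    agg <- split(qual$median, qual$length)
    data.frame(length = as.integer(names(agg)),
               n = lengths(agg),
               median = vapply(agg, median, 1))
  } else {
    data.frame(length = integer(0), n = integer(0), median = numeric(0))
  }
  # baseline: differentials at region positions outside the repeat
  base <- unlist(lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    pos <- region[1L]:region[2L]
    if (perSeq$length[i] >= minLen) {
      sub <- substr(p@sequence, region[1L], region[2L])
      rep_ <- .longestRepeat(sub, unit)
      inRep <- (region[1L] - 1L + IRanges::start(rep_)):
               (region[1L] - 1L + IRanges::end(rep_))
      pos <- setdiff(pos, inRep)
    }
    as.vector(p@diffs[, pos])
  }))
  list(byLength = byLength,
       baseline = median(base, na.rm = TRUE),
       perSequence = perSeq)
}

#' Binding-site-extension score differentials
#'
#' For each occurrence of `siteMotif` among the scaffold's constant
#' segments, classifies the following 4-mer of each sequence as
#' extension (`GCTA`) or not, and reports the median signed
#' differential over those four positions, grouped by site index and
#' class.
#'
#' @param profiles List of [MutagenesisProfile-class].
#' @param scaffold The design scaffold.
#' @param siteMotif Constant binding-site motif (ZEV site by default).
#' @param extension Extension tetramer.
#' @return data.frame with `site`, `extension`, `n`, `median`.
#' @export
siteExtensionDifferential <- function(profiles, scaffold,
                                      siteMotif = "GCGTGGGCG",
                                      extension = "GCTA") {
  st <- segmentTable(scaffold)
  sites <- st[st$kind == "constant" & st$sequence == siteMotif, ,
              drop = FALSE]
  if (!nrow(sites)) {
    warning("site motif not found among constant segments")
    return(data.frame(site = integer(0), extension = logical(0),
                      n = integer(0), median = numeric(0)))
  }
  extLen <- nchar(extension)
  rows <- list()
  for (si in seq_len(nrow(sites))) {
    pos <- (sites$end[si] + 1L):(sites$end[si] + extLen)
    meds <- vapply(profiles, function(p)
      median(p@diffs[, pos], na.rm = TRUE), 1)
    isExt <- vapply(profiles, function(p)
      substr(p@sequence, pos[1L], pos[extLen]) == extension, TRUE)
    for (cls in unique(isExt)) {
      sel <- isExt == cls
      rows[[length(rows) + 1L]] <- data.frame(
        site = si, extension = cls, n = sum(sel),
        median = median(meds[sel]))
    }
  }
  do.call(rbind, rows)
}

#' Per-column base counts of aligned sequences
#'
#' Count matrix underlying a sequence logo (rendering itself is out of
#' scope): one column per position, rows A, C, G, T; column sums equal
#' the number of sequences.
#'
#' @param seqs Equal-length character vector.
#' @param region Optional `c(start, end)` restriction.
#' @return 4 x width integer matrix.
#' @export
frequencyMatrix <- function(seqs, region = NULL) {
  if (!is.null(region))
    seqs <- substr(seqs, region[1L], region[2L])
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences (or region) must have equal length")
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs))
  out <- matrix(0L, 4L, nchar(seqs[1L]), dimnames = list(DNA_BASES, NULL))
  common <- intersect(rownames(cm), DNA_BASES)
  out[common, ] <- cm[common, , drop = FALSE]
  out
}
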