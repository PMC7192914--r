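#' Needleman-Wunsch alignment distance
#'
#' Minimal global-alignment cost with match cost 0, mismatch cost
#' `mismatch` and per-base gap cost `gap` (distance semantics: 0 iff the
#' strings are identical, symmetric). Vectorized over pairs.
#'
#' @param s1,s2 Character vectors of equal length (aligned pairwise).
#' @param gap Gap penalty (default 5).
#' @param mismatch Mismatch penalty (default 1).
#' @return Integer vector of distances.
#' @export
nwDistance <- function(s1, s2, gap = 5L, mismatch = 1L) {
  stopifnot(length(s1) == length(s2), all(nchar(s1) > 0),
            all(nchar(s2) > 0))
  nw_distance_cpp(as.character(s1), as.character(s2),
                  as.integer(gap), as.integer(mismatch))
}

#' Single sort-and-compare clustering pass
#'
#' Reads are sorted lexicographically (byte order, locale-independent)
#' and each read is compared with the one following it by
#' Needleman-Wunsch distance; a cluster is a maximal run of consecutive
#' sorted reads in which every adjacent pair is within `cutoff`. The
#' result partitions the input.
#'
#' @param reads Character vector of reads.
#' @param cutoff Maximum adjacent distance within a cluster.
#' @param gap,mismatch Alignment penalties.
#' @return List of integer vectors of read indices (into `reads`).
#' @export
clusterPass <- function(reads, cutoff = 10L, gap = 5L, mismatch = 1L) {
  n <- length(reads)
  if (n == 0L) return(list())
  ord <- order(reads, method = "radix")
  if (n == 1L) return(list(ord))
  d <- nw_adjacent_cpp(reads[ord], as.integer(gap), as.integer(mismatch))
  grp <- cumsum(c(1L, as.integer(d > cutoff)))
  unname(split(ord, grp))
}

#' Merge forward- and reverse-pass clusterings
#'
#' Sorting-based clustering misses mutations near the start of a read,
#' so the pass is repeated on reversed strings; each read then belongs
#' to one cluster per pass, and clusters sharing reads are merged
#' (connected components of the bipartite overlap graph).
#'
#' @param forward,reverse Lists of integer index vectors partitioning
#'   the same read universe.
#' @return List of integer vectors (sorted), a partition of all reads.
#' @export
mergePasses <- function(forward, reverse) {
  uf <- sort(unlist(forward))
  ur <- sort(unlist(reverse))
  if (!identical(uf, ur))
    stop("forward and reverse passes cover different read sets")
  n <- length(uf)
  # union-find over reads; union every read with its cluster head
  parent <- seq_len(max(uf, 0L))
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (cl in c(forward, reverse)) {
    h <- find(cl[1L])
    for (x in cl[-1L]) {
      r <- find(x)
      if (r != h) parent[r] <- h
    }
  }
  roots <- vapply(uf, find, 1L)
  unname(lapply(split(uf, roots), sort))
}

#' Majority-vote consensus of a read cluster
#'
#' Votes only among reads of the modal length (a per-position vote is
#' undefined across unequal lengths); the call at each position is the
#' unique strict-plurality base. Clusters of one read are rejected as
#' singletons; ties in modal length or at any position reject the
#' cluster as `no_majority`.
#'
#' @param seqs Character vector of member reads.
#' @return List with `consensus` (string or `NA`) and `reason`
#'   (`"none"`, `"singleton"` or `"no_majority"`).
#' @export
consensusCall <- function(seqs) {
  if (!length(seqs)) stop("empty cluster")
  if (length(seqs) == 1L)
    return(list(consensus = NA_character_, reason = "singleton"))
  lens <- nchar(seqs)
  tl <- table(lens)
  mode_ <- as.integer(names(tl)[tl == max(tl)])
  if (length(mode_) > 1L)
    return(list(consensus = NA_character_, reason = "no_majority"))
  members <- seqs[lens == mode_]
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(members))
  cm <- cm[DNA_BASES, , drop = FALSE]
  best <- apply(cm, 2L, max)
  nbest <- colSums(cm == rep(best, each = 4L))
  if (any(nbest > 1L))
    return(list(consensus = NA_character_, reason = "no_majority"))
  list(consensus = paste(DNA_BASES[apply(cm, 2L, which.max)],
                         collapse = ""),
       reason = "none")
}

#' Cluster error-bearing reads and call consensus sequences
#'
#' Runs the forward and reverse sort-and-compare passes, merges them,
#' and reduces every cluster to a majority-vote consensus. The result
#' is independent of input read order.
#'
#' @param reads Character vector of full-length reads.
#' @param cutoff Adjacent-distance cutoff.
#' @param gap,mismatch Alignment penalties.
#' @return List with `consensus` (character vector of accepted
#'   consensi) and `report` (data.frame: cluster id, size, reason).
#' @export
clusterReads <- function(reads, cutoff = 10L, gap = 5L, mismatch = 1L) {
  fwd <- clusterPass(reads, cutoff, gap, mismatch)
  revReads <- .reverseStrings(reads)
  rev_ <- clusterPass(revReads, cutoff, gap, mismatch)
  clusters <- mergePasses(fwd, rev_)
  # deterministic order: by smallest member's read string
  keyOrd <- order(vapply(clusters, function(cl) min(reads[cl]), ""),
                  method = "radix")
  clusters <- clusters[keyOrd]
  calls <- lapply(clusters, function(cl) consensusCall(reads[cl]))
  report <- data.frame(
    cluster = seq_along(clusters),
    size = lengths(clusters),
    reason = vapply(calls, `[[`, "", "reason"),
    stringsAsFactors = FALSE)
  list(consensus = unlist(lapply(calls, function(x)
         if (x$reason == "none") x$consensus else NULL)),
       report = report, clusters = clusters)
}

.reverseStrings <- function(x) {
  as.character(Biostrings::reverse(Biostrings::BStringSet(x)))
}

#' Link counting reads to consensus sequences via the 5' identifier
#'
#' Each short counting read is matched to a consensus by exact identity
#' of its first `keyLength` bases; the first `keyLength` bases of each
#' library member are fully randomized and act as a unique identifier.
#' Reads matching no consensus, and consensi sharing an identifier
#' (excluded with a warning), are dropped and tallied.
#'
#' @param consensi Character vector of full-length consensus sequences.
#' @param countingReads data.frame with columns `read`, `bin`.
#' @param nBins Number of sort bins.
#' @param keyLength Identifier length (default 35).
#' @return Matrix (length(consensi) x nBins) of counts, with a
#'   `dropped` attribute (reads not assigned) and `excluded` attribute
#'   (indices of ambiguous consensi).
#' @export
linkCounts <- function(consensi, countingReads, nBins, keyLength = 35L) {
  if (any(nchar(consensi) < keyLength))
    stop("all consensi must be at least keyLength long")
  keys <- substr(consensi, 1L, keyLength)
  dupKeys <- unique(keys[duplicated(keys)])
  excluded <- which(keys %in% dupKeys)
  if (length(excluded))
    warning(length(excluded),
            " consensi share a 5' identifier and were excluded")
  usable <- setdiff(seq_along(consensi), excluded)
  counts <- matrix(0L, length(consensi), nBins)
  m <- match(substr(countingReads$read, 1L, keyLength), keys[usable])
  hit <- !is.na(m)
  if (any(hit)) {
    tt <- table(factor(usable[m[hit]], levels = seq_along(consensi)),
                factor(countingReads$bin[hit], levels = seq_len(nBins)))
    counts <- counts + unclass(tt)
  }
  dimnames(counts) <- NULL
  attr(counts, "dropped") <- sum(!hit)
  attr(counts, "excluded") <- excluded
  counts
}

#' Check constant regions of reconstructed sequences
#'
#' `TRUE` iff the sequence has the scaffold's length and matches every
#' constant segment verbatim; sequences with mutations in designed
#' constant regions are removed from downstream tables.
#'
#' @param seqs Character vector of sequences.
#' @param scaffold A [LibraryScaffold-class].
#' @return Logical vector.
#' @export
filterConstantRegions <- function(seqs, scaffold) {
  L <- scaffoldLength(scaffold)
  mask <- randomizedMask(scaffold)
  template <- strsplit(constantTemplate(scaffold), "")[[1L]]
  constPos <- which(!mask)
  vapply(seqs, function(s) {
    if (nchar(s) != L) return(FALSE)
    ch <- strsplit(s, "")[[1L]]
    all(ch[constPos] == template[constPos])
  }, TRUE, USE.NAMES = FALSE)
}
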