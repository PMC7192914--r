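#' Create a constant scaffold segment
#'
#' @param sequence DNA string held constant in every library member.
#' @param label Optional label.
#' @return A [Segment-class].
#' @export
constantSegment <- function(sequence, label = "const") {
  new("Segment", kind = "constant", sequence = as.character(sequence),
      length = nchar(sequence), baseFreqs = numeric(0), label = label)
}

#' Create a randomized scaffold segment
#'
#' @param length Segment length in bp.
#' @param baseFreqs Probability 4-vector over A, C, G, T. A zero entry
#'   excludes that base (e.g. no G downstream of the TSS, to avoid
#'   premature ATG start codons).
#' @param label Optional label.
#' @return A [Segment-class].
#' @export
randomSegment <- function(length, baseFreqs = rep(0.25, 4),
                          label = "spacer") {
  new("Segment", kind = "randomized", sequence = NA_character_,
      length = as.integer(length), baseFreqs = as.numeric(baseFreqs),
      label = label)
}

#' Assemble a library scaffold
#'
#' @param name Scaffold name.
#' @param segments List of [Segment-class] objects, 5' to 3'.
#' @param flank5,flank3 Vector-context DNA flanking the library insert.
#' @return A [LibraryScaffold-class].
#' @export
LibraryScaffold <- function(name, segments, flank5 = "", flank3 = "") {
  new("LibraryScaffold", name = name, segments = segments,
      flank5 = flank5, flank3 = flank3)
}

#' Total scaffold length in bp
#' @param scaffold A [LibraryScaffold-class].
#' @export
scaffoldLength <- function(scaffold) {
  sum(vapply(scaffold@segments, function(s) s@length, 1L))
}

#' @rdname scaffoldLength
#' @export
scaffoldName <- function(scaffold) scaffold@name

#' Mask of randomized positions
#'
#' Logical vector with one entry per scaffold position (0-based intervals
#' internally; returned vector is position-ordered 5' to 3'), `TRUE` where
#' the position lies in a randomized segment. Design and mutagenesis use
#' this mask to protect constant regions.
#'
#' @param scaffold A [LibraryScaffold-class].
#' @return Logical vector of length `scaffoldLength(scaffold)`.
#' @export
randomizedMask <- function(scaffold) {
  unlist(lapply(scaffold@segments, function(s)
    rep(s@kind == "randomized", s@length)), use.names = FALSE)
}

#' Segment table of a scaffold
#'
#' @param scaffold A [LibraryScaffold-class].
#' @return data.frame with one row per segment (start/end are 1-based
#'   inclusive coordinates).
#' @export
segmentTable <- function(scaffold) {
  lens <- vapply(scaffold@segments, function(s) s@length, 1L)
  ends <- cumsum(lens)
  data.frame(
    label = vapply(scaffold@segments, function(s) s@label, ""),
    kind = vapply(scaffold@segments, function(s) s@kind, ""),
    start = ends - lens + 1L, end = ends,
    sequence = vapply(scaffold@segments, function(s) s@sequence, ""),
    stringsAsFactors = FALSE)
}

#' Constant backbone with randomized positions as N
#' @param scaffold A [LibraryScaffold-class].
#' @export
constantTemplate <- function(scaffold) {
  paste(vapply(scaffold@segments, function(s) {
    if (s@kind == "constant") s@sequence else strrep("N", s@length)
  }, ""), collapse = "")
}

#' Sample random library members from a scaffold
#'
#' Constant segments appear verbatim; each randomized position is drawn
#' independently from its segment's base frequencies. Uses R's RNG
#' (seed with [set.seed()] for reproducibility).
#'
#' @param scaffold A [LibraryScaffold-class].
#' @param n Number of sequences.
#' @return Character vector of length `n`.
#' @export
sampleSequence <- function(scaffold, n = 1L) {
  parts <- lapply(scaffold@segments, function(s) {
    if (s@kind == "constant") {
      rep(s@sequence, n)
    } else {
      draws <- sample(DNA_BASES, n * s@length, replace = TRUE,
                      prob = s@baseFreqs)
      apply(matrix(draws, nrow = n), 1L, paste, collapse = "")
    }
  })
  do.call(paste0, parts)
}

#' One-hot encode a DNA sequence
#'
#' Rows are ordered A, C, G, T (fixed throughout the package); every
#' column sums to exactly 1.
#'
#' @param seq DNA string (A/C/G/T only).
#' @return 4 x L binary matrix with rownames A,C,G,T.
#' @export
oneHot <- function(seq) {
  codes <- .baseCodes(seq)
  L <- length(codes)
  m <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(DNA_BASES, NULL))
  m[cbind(codes, seq_len(L))] <- 1L
  m
}

#' @rdname oneHot
#' @param mat A 4 x L one-hot matrix.
#' @export
decodeOneHot <- function(mat) {
  stopifnot(nrow(mat) == 4L)
  paste(DNA_BASES[max.col(t(mat), ties.method = "first")], collapse = "")
}

# integer codes 1..4 for A,C,G,T; errors on anything else
.baseCodes <- function(seq) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1L]], DNA_BASES)
  if (anyNA(codes)) stop("sequence contains non-ACGT characters")
  codes
}

#' Sliding-window GC synthesizability check
#'
#' A sequence passes iff every window of `window` bp has GC fraction
#' within `[lo, hi]` (inclusive bounds: exactly 25% or 80% GC passes).
#' Sequences shorter than `window` pass vacuously.
#'
#' @param seq DNA string, or character vector of them.
#' @param window Window width in bp.
#' @param lo,hi Inclusive GC-fraction bounds.
#' @return Logical vector, one entry per sequence.
#' @export
gcWindowOk <- function(seq, window = 20L, lo = 0.25, hi = 0.80) {
  vapply(seq, function(s) {
    codes <- .baseCodes(s)
    L <- length(codes)
    if (L < window) return(TRUE)
    gc <- cumsum(codes == 2L | codes == 3L)
    wins <- gc[window:L] - c(0, gc)[seq_len(L - window + 1L)]
    all(wins >= lo * window - 1e-12 & wins <= hi * window + 1e-12)
  }, TRUE, USE.NAMES = FALSE)
}

#' BsaI restriction-site screen
#'
#' `TRUE` iff the BsaI recognition site GGTCTC, or its reverse complement
#' GAGACC, occurs in the sequence. BsaI sites interfere with Golden Gate
#' assembly, so designs containing them are removed.
#'
#' @param seq DNA string or character vector.
#' @return Logical vector.
#' @export
containsBsaI <- function(seq) {
  grepl("GGTCTC", seq, fixed = TRUE) | grepl("GAGACC", seq, fixed = TRUE)
}

#' Read or write scaffold files
#'
#' The scaffold file is a tab-separated table with columns `scaffold`,
#' `label`, `kind`, `sequence`, `length`, `freq_A`, `freq_C`, `freq_G`,
#' `freq_T`. `kind` is `constant`, `randomized`, `flank5` or `flank3`;
#' flank rows carry vector-context sequence.
#'
#' @param file Path to a scaffold TSV.
#' @param name Scaffold to extract (default: the only one present).
#' @return `readScaffold`: a [LibraryScaffold-class].
#' @export
readScaffold <- function(file, name = NULL) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  if (is.null(name)) {
    name <- unique(tab$scaffold)
    if (length(name) != 1L)
      stop("file contains several scaffolds; give 'name'")
  }
  tab <- tab[tab$scaffold == name, , drop = FALSE]
  if (!nrow(tab)) stop("scaffold '", name, "' not found")
  f5 <- tab$sequence[tab$kind == "flank5"]
  f3 <- tab$sequence[tab$kind == "flank3"]
  body <- tab[tab$kind %in% c("constant", "randomized"), , drop = FALSE]
  segs <- lapply(seq_len(nrow(body)), function(i) {
    r <- body[i, ]
    if (r$kind == "constant") constantSegment(r$sequence, r$label)
    else randomSegment(r$length,
                       c(r$freq_A, r$freq_C, r$freq_G, r$freq_T), r$label)
  })
  LibraryScaffold(name, segs,
                  flank5 = if (length(f5)) f5 else "",
                  flank3 = if (length(f3)) f3 else "")
}

#' @rdname readScaffold
#' @param scaffold A [LibraryScaffold-class] to write.
#' @export
writeScaffold <- function(scaffold, file) {
  rows <- lapply(scaffold@segments, function(s) {
    data.frame(scaffold = scaffold@name, label = s@label, kind = s@kind,
               sequence = ifelse(is.na(s@sequence), "", s@sequence),
               length = s@length,
               freq_A = if (s@kind == "randomized") s@baseFreqs[1] else NA,
               freq_C = if (s@kind == "randomized") s@baseFreqs[2] else NA,
               freq_G = if (s@kind == "randomized") s@baseFreqs[3] else NA,
               freq_T = if (s@kind == "randomized") s@baseFreqs[4] else NA)
  })
  tab <- do.call(rbind, rows)
  for (fl in c("flank5", "flank3")) {
    s <- slot(scaffold, fl)
    if (nchar(s))
      tab <- rbind(tab, data.frame(scaffold = scaffold@name, label = fl,
                                   kind = fl, sequence = s,
                                   length = nchar(s), freq_A = NA,
                                   freq_C = NA, freq_G = NA, freq_T = NA))
  }
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Bundled promoter scaffolds
#'
#' Returns one of the two library designs shipped with the package: the
#' final constitutive P_GPD-style scaffold (312 bp, 83% of positions
#' randomized; Rap1p/Gcr1p sites, TATA box and TSS motif held constant,
#' T-rich core-promoter spacer, no G after the TSS) or the inducible
#' P_ZEV design-4-style scaffold (246 bp, 79% randomized; three ZEV
#' artificial-transcription-factor sites GCGTGGGCG, 37-bp internal
#' spacers, 18-bp TATA region). The exact constant-region strings are
#' synthetic stand-ins with the documented motif content and the printed
#' segment totals; the file `extdata/scaffolds.tsv` is editable.
#'
#' @param name `"PGPD-final"` or `"PZEV-design4"`.
#' @return A [LibraryScaffold-class].
#' @export
builtinScaffold <- function(name = c("PGPD-final", "PZEV-design4")) {
  name <- match.arg(name)
  file <- system.file("extdata", "scaffolds.tsv", package = "PromoterForge",
                      mustWork = TRUE)
  readScaffold(file, name)
}

#' Export the scaffold backbone as FASTA
#'
#' Writes the constant backbone with randomized positions as `N`,
#' suitable for primer design or record keeping.
#'
#' @param scaffold A [LibraryScaffold-class].
#' @param file Output FASTA path.
#' @export
scaffoldToFasta <- function(scaffold, file) {
  x <- Biostrings::DNAStringSet(constantTemplate(scaffold))
  names(x) <- scaffoldName(scaffold)
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}
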