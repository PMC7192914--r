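#' Construct an additive ground-truth model
#'
#' @param positionWeights 4 x L matrix of additive per-position per-base
#'   weights on log10 activity (rows A,C,G,T).
#' @param motifWeights data.frame with columns `motif` (DNA string) and
#'   `weight`; every (overlapping) occurrence adds its weight.
#' @param baseline Baseline log10 activity.
#' @param inducedOffset Added to form the induced activity channel.
#' @return A [GroundTruthModel-class].
#' @export
GroundTruthModel <- function(positionWeights,
                             motifWeights = data.frame(motif = character(0),
                                                       weight = numeric(0)),
                             baseline = 0, inducedOffset = 0) {
  rownames(positionWeights) <- DNA_BASES
  new("GroundTruthModel", baseline = baseline,
      positionWeights = positionWeights, motifWeights = motifWeights,
      inducedOffset = inducedOffset)
}

# all (overlapping) occurrence count of a fixed motif
.countMotif <- function(seq, motif) {
  hits <- gregexpr(paste0("(?=", motif, ")"), seq, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) 0L else length(hits)
}

#' True activity of sequences under a ground-truth model
#'
#' Additive score: baseline + per-position weights + motif weights over
#' all overlapping motif occurrences. Deterministic.
#'
#' @param model A [GroundTruthModel-class].
#' @param seqs Character vector of DNA sequences (length must match the
#'   position-weight matrix).
#' @return Matrix with columns `uninduced`, `induced`.
#' @export
trueActivity <- function(model, seqs) {
  L <- ncol(model@positionWeights)
  vals <- vapply(seqs, function(s) {
    codes <- .baseCodes(s)
    if (length(codes) != L) stop("sequence length does not match model")
    a <- model@baseline +
      sum(model@positionWeights[cbind(codes, seq_len(L))])
    if (nrow(model@motifWeights)) {
      for (i in seq_len(nrow(model@motifWeights)))
        a <- a + model@motifWeights$weight[i] *
          .countMotif(s, model@motifWeights$motif[i])
    }
    a
  }, 1, USE.NAMES = FALSE)
  cbind(uninduced = vals, induced = vals + model@inducedOffset)
}

#' Bin layout constructors
#'
#' `BinLayout` wraps a strictly increasing break vector;
#' `defaultBinLayout` builds the default sort layout: `n` equal-width
#' bins spanning `range` on the log10 GFP:mCherry scale (the default
#' range resembles the measured constitutive-library activity span).
#'
#' @param breaks Numeric vector of bin edges.
#' @export
BinLayout <- function(breaks) new("BinLayout", breaks = as.numeric(breaks))

#' @rdname BinLayout
#' @param n Number of bins.
#' @param range Activity range covered by the sort gates.
#' @export
defaultBinLayout <- function(n = 12L, range = c(-0.6, 0.6)) {
  BinLayout(seq(range[1L], range[2L], length.out = n + 1L))
}

#' @rdname BinLayout
#' @param layout A [BinLayout-class].
#' @export
nBins <- function(layout) length(layout@breaks) - 1L

#' Sort simulation settings
#'
#' Defaults emulate the study structure: 12 equal-width bins over
#' \[-0.6, 0.6\], per-cell SD 0.15 log10 units, contaminant fraction
#' 0.01, 200 sorted cells expected per sequence.
#'
#' @param layout A [BinLayout-class].
#' @param sigmaCell Cell-to-cell SD of log10 activity.
#' @param epsilon Uniform contaminant fraction.
#' @param cellsPerSequence Expected sorted cells per sequence.
#' @param outOfRange `"clamp"` or `"discard"`.
#' @return A [SortConfig-class].
#' @export
SortConfig <- function(layout = defaultBinLayout(), sigmaCell = 0.15,
                       epsilon = 0.01, cellsPerSequence = 200,
                       outOfRange = "clamp") {
  new("SortConfig", layout = layout, sigmaCell = sigmaCell,
      epsilon = epsilon, cellsPerSequence = cellsPerSequence,
      outOfRange = outOfRange)
}

#' Read simulation settings
#' @param substitutionRate Per-base substitution probability.
#' @param meanDepth Expected counting reads per sequence per bin, scaled
#'   by the bin's share of that sequence's cells.
#' @param meanIdDepth Expected full-length identification reads per
#'   sequence.
#' @param keyLength 5' identifier length (bp).
#' @return A [ReadSimConfig-class].
#' @export
ReadSimConfig <- function(substitutionRate = 0.005, meanDepth = 20,
                          meanIdDepth = 10, keyLength = 35L) {
  new("ReadSimConfig", substitutionRate = substitutionRate,
      meanDepth = meanDepth, meanIdDepth = meanIdDepth,
      keyLength = as.integer(keyLength))
}

#' Simulate a FACS sort of a sequence library
#'
#' Each sequence's cells are multinomial across bins with the mixture
#' probabilities assumed by the activity estimator ([binProb()]): normal
#' around the sequence mean with shared SD, a uniform contaminant
#' fraction, and out-of-range mass assigned to the end bins (`"clamp"`)
#' or dropped (`"discard"`). Cell totals are Poisson around
#' `cellsPerSequence`.
#'
#' @param activities Numeric vector of per-sequence mean activities.
#' @param cfg A [SortConfig-class].
#' @return Integer matrix, sequences x bins.
#' @export
simulateSort <- function(activities, cfg) {
  N <- nBins(cfg@layout)
  S <- length(activities)
  counts <- matrix(0L, S, N)
  totals <- rpois(S, cfg@cellsPerSequence)
  for (s in seq_len(S)) {
    if (totals[s] == 0L) next
    p <- binProb(activities[s], cfg@sigmaCell, cfg@epsilon, cfg@layout,
                 unboundedOuter = cfg@outOfRange == "clamp")
    if (cfg@outOfRange == "discard") {
      p <- c(p, max(0, 1 - sum(p)))
      draw <- rmultinom(1L, totals[s], p)[seq_len(N), 1L]
    } else {
      draw <- rmultinom(1L, totals[s], p)[, 1L]
    }
    counts[s, ] <- draw
  }
  counts
}

# apply iid per-base substitutions to replicated reads of one sequence
.mutateReads <- function(seq, n, rate) {
  if (n == 0L) return(character(0))
  codes <- .baseCodes(seq)
  L <- length(codes)
  m <- matrix(rep(codes, n), nrow = n, byrow = TRUE)
  hit <- which(matrix(runif(n * L) < rate, nrow = n))
  if (length(hit)) {
    # substitute with one of the three other bases, uniformly
    m[hit] <- ((m[hit] - 1L + sample(1:3, length(hit), TRUE)) %% 4L) + 1L
  }
  apply(matrix(DNA_BASES[m], nrow = n), 1L, paste, collapse = "")
}

#' Simulate sequencing reads for one library member
#'
#' Counting reads are emitted per bin with Poisson depth proportional to
#' the bin's cell count; identification reads are full-length and
#' bin-less. All reads carry iid per-base substitution errors.
#'
#' @param seq The true sequence.
#' @param counts Per-bin cell counts for this sequence.
#' @param cfg A [ReadSimConfig-class].
#' @param cellsPerSequence Expected cells per sequence (depth scaling).
#' @param countingReadLength Length of the short counting reads.
#' @return List with `counting` (data.frame `read`, `bin`) and
#'   `identification` (character vector of full-length reads).
#' @export
simulateReads <- function(seq, counts, cfg, cellsPerSequence = 200,
                          countingReadLength = 75L) {
  nb <- length(counts)
  nReads <- rpois(nb, cfg@meanDepth * counts / cellsPerSequence)
  reads <- character(0)
  bins <- integer(0)
  for (i in seq_len(nb)) {
    if (nReads[i] == 0L) next
    r <- .mutateReads(seq, nReads[i], cfg@substitutionRate)
    reads <- c(reads, substr(r, 1L, countingReadLength))
    bins <- c(bins, rep(i, nReads[i]))
  }
  idn <- rpois(1L, cfg@meanIdDepth)
  list(counting = data.frame(read = reads, bin = bins,
                             stringsAsFactors = FALSE),
       identification = .mutateReads(seq, idn, cfg@substitutionRate))
}

#' Demonstration scaffold and ground truth for desk-scale fixtures
#'
#' `demoScaffold()` is a 110-bp miniature of the library designs: a 40-bp
#' fully randomized 5' spacer (doubling as the unique identifier), one
#' ZEV-type binding site, a TATA box, a T-rich core spacer, a TSS motif
#' and a no-G 5' UTR. `demoGroundTruth()` plants recoverable signal in
#' it: small per-position weights at randomized positions, a TA-repeat
#' bonus and a GCTA binding-site-extension bonus, so mutagenesis and
#' design analyses have known answers.
#'
#' @return A [LibraryScaffold-class].
#' @export
demoScaffold <- function() {
  LibraryScaffold("demo", list(
    randomSegment(40L, label = "id_spacer"),
    constantSegment("GCGTGGGCG", "ZEV"),
    randomSegment(20L, label = "spacer1"),
    constantSegment("CTATAAATA", "TATA"),
    randomSegment(15L, c(0.30, 0.15, 0.12, 0.43), "core"),
    constantSegment("ACAAAC", "TSS"),
    randomSegment(11L, c(0.40, 0.25, 0, 0.35), "utr")),
    flank5 = "TTCTAGAACGGTCATGAACGGCATACTTCTTGAGCAACTG",
    flank3 = "ATGTCTAAAGGTGAAGAATTATTCACTGGTGTTGTCCCAA")
}

#' @rdname demoScaffold
#' @param scaffold The scaffold the model applies to.
#' @param weightSd SD of the per-position weights.
#' @param taWeight Weight per overlapping TATATA occurrence.
#' @param gctaWeight Weight of the extended ZEV site GCGTGGGCGGCTA.
#' @param inducedOffset Induced-channel offset.
#' @param seed Seed for drawing the position weights.
#' @return A [GroundTruthModel-class].
#' @export
demoGroundTruth <- function(scaffold = demoScaffold(), weightSd = 0.025,
                            taWeight = 0.10, gctaWeight = 0.15,
                            inducedOffset = 1.2, seed = 1L) {
  L <- scaffoldLength(scaffold)
  mask <- randomizedMask(scaffold)
  set.seed(seed)
  pw <- matrix(0, 4L, L, dimnames = list(DNA_BASES, NULL))
  pw[, mask] <- rnorm(4L * sum(mask), sd = weightSd)
  # center each free column so weights are identified relative to the mean
  pw[, mask] <- sweep(pw[, mask, drop = FALSE], 2L,
                      colMeans(pw[, mask, drop = FALSE]))
  GroundTruthModel(pw,
    motifWeights = data.frame(motif = c("TATATA", "GCGTGGGCGGCTA"),
                              weight = c(taWeight, gctaWeight)),
    baseline = 0, inducedOffset = inducedOffset)
}

#' Generate a complete synthetic FACS-seq fixture on disk
#'
#' Writes ground-truth sequences (FASTA), true activities (TSV),
#' per-replicate cell-count matrices (TSV), bin layout with sorted-cell
#' totals (TSV), optional per-bin reads (FASTQ + counting-read TSV), and
#' a JSON manifest of all parameters and file checksums. Rerunning with
#' the same seed reproduces byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param scaffold A [LibraryScaffold-class].
#' @param nSequences Library size.
#' @param model A [GroundTruthModel-class].
#' @param sortCfg A [SortConfig-class].
#' @param readCfg A [ReadSimConfig-class] or `NULL` to skip reads.
#' @param replicates Number of sort replicates (the constitutive
#'   experiment was performed in duplicate).
#' @param conditions `"uninduced"` or both conditions.
#' @param seed Integer seed controlling all randomness.
#' @return Invisibly, the manifest list.
#' @export
makeFixture <- function(dir, scaffold = demoScaffold(), nSequences = 1000L,
                        model = demoGroundTruth(scaffold),
                        sortCfg = SortConfig(), readCfg = NULL,
                        replicates = 2L, conditions = "uninduced",
                        seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  seqs <- if (nSequences > 0L) sampleSequence(scaffold, nSequences)
          else character(0)
  ids <- sprintf("seq%05d", seq_len(nSequences))
  act <- trueActivity(model, seqs)
  fasta <- file.path(dir, "truth.fasta")
  Biostrings::writeXStringSet(
    setNames(Biostrings::DNAStringSet(seqs), ids), fasta)
  actFile <- file.path(dir, "activities.tsv")
  write.table(data.frame(id = ids, act), actFile, sep = "\t",
              quote = FALSE, row.names = FALSE)
  files <- c(fasta, actFile)
  layTab <- NULL
  for (cond in conditions) {
    mu <- act[, cond]
    for (r in seq_len(replicates)) {
      counts <- simulateSort(mu, sortCfg)
      f <- file.path(dir, sprintf("cellcounts_%s_rep%d.tsv", cond, r))
      write.table(data.frame(id = ids, counts), f, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      files <- c(files, f)
      layTab <- rbind(layTab, data.frame(
        condition = cond, replicate = r, bin = seq_len(ncol(counts)),
        a = head(sortCfg@layout@breaks, -1L),
        b = tail(sortCfg@layout@breaks, -1L),
        cells_sorted = colSums(counts)))
      if (!is.null(readCfg)) {
        allCount <- NULL
        idReads <- character(0)
        for (s in seq_len(nSequences)) {
          rd <- simulateReads(seqs[s], counts[s, ], readCfg,
                              sortCfg@cellsPerSequence)
          allCount <- rbind(allCount, rd$counting)
          idReads <- c(idReads, rd$identification)
        }
        cf <- file.path(dir, sprintf("counting_%s_rep%d.tsv", cond, r))
        write.table(allCount, cf, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        idf <- file.path(dir, sprintf("idreads_%s_rep%d.fasta", cond, r))
        Biostrings::writeXStringSet(setNames(
          Biostrings::DNAStringSet(idReads),
          sprintf("read%06d", seq_along(idReads))), idf)
        files <- c(files, cf, idf)
      }
    }
  }
  layFile <- file.path(dir, "layout.tsv")
  write.table(layTab, layFile, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, layFile)
  manifest <- list(
    seed = seed, n_sequences = nSequences,
    scaffold = scaffoldName(scaffold), replicates = replicates,
    conditions = as.list(conditions),
    sort = list(sigma = sortCfg@sigmaCell, epsilon = sortCfg@epsilon,
                cells_per_sequence = sortCfg@cellsPerSequence,
                breaks = sortCfg@layout@breaks),
    reads = if (is.null(readCfg)) NULL else
      list(substitution_rate = readCfg@substitutionRate,
           mean_depth = readCfg@meanDepth,
           mean_id_depth = readCfg@meanIdDepth,
           key_length = readCfg@keyLength),
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
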