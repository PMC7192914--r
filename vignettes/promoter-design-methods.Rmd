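---
title: "Model-guided promoter design from sort-seq data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-guided promoter design from sort-seq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PromoterForge)
```

PromoterForge implements a complete model-guided promoter engineering
pipeline for *Saccharomyces cerevisiae*: promoter libraries built from
scaffolds of constant motifs and randomized spacers are characterized by
a binned FACS sort plus sequencing (sort-seq), per-variant activities are
inferred by maximum likelihood, a convolutional ensemble learns the
sequence-to-activity map, and new promoters are designed against the
model under synthesizability constraints. This vignette explains the
models, the tunable parameters, and the design choices made where the
problem left genuine freedom. Every empirical number quoted here is
computed by the package's test suite or by `scripts/acceptance.R`.

## Scaffolds

A `LibraryScaffold` is an ordered list of segments, each either a
constant DNA string (transcription-factor binding sites such as Rap1p,
Gcr1p or the ZEV artificial-transcription-factor site `GCGTGGGCG`, the
TATA box, the TSS motif) or a randomized spacer of fixed length with a
per-segment base-frequency vector. Two composition rules matter
biologically: the core-promoter spacer between TATA box and TSS is
T-rich, and G is excluded downstream of the TSS so that randomization
cannot create premature ATG start codons. The first 35 or more bases of
each design are fully randomized and double as a unique identifier
linking short counting reads to full-length variants.

Two bundled scaffolds reproduce the original libraries' design geometry: the final
constitutive P~GPD~-style design (312 bp, 83% of positions randomized)
and the inducible P~ZEV~ design 4 (246 bp, 79% randomized; three ZEV
sites, 37-bp internal spacers, 18-bp TATA region). The *exact*
constant-region strings of the tested designs are not given at
single-base resolution in the main text, so the bundled file
`extdata/scaffolds.tsv` carries synthetic stand-in motifs with the
documented content and the exact printed totals; it is a plain TSV and
is meant to be edited when the true sequences are available. Coordinates
are handled 0-based half-open internally; user-facing tables are
1-based inclusive, as is conventional in R/Bioconductor.

## Synthetic data: what it emulates and what it does not

The `synthetic_data` functions generate complete fixtures with known
ground truth so that every downstream stage is testable without any
download. The generative model mirrors the assumptions of the
estimator:

* each sequence has a true mean activity (log10 GFP:mCherry);
* single-cell activities are normal around that mean with a shared
  standard deviation `sigmaCell` (default **0.15** log10 units);
* with probability `epsilon` (default **0.01**) a cell is a
  contaminant and falls into a uniformly random bin;
* cells are sorted into **12** equal-width bins spanning
  **[-0.6, 0.6]**, a range resembling the measured constitutive
  library span (about -0.52 to 0.56); out-of-range cells are assigned
  to the nearest end bin because the sort gates are set to cover the
  library's activity range (a `"discard"` switch exists for
  sensitivity analysis);
* about **200** cells are sorted per sequence, and the sort is
  performed in **duplicate**, as the constitutive experiment was;
* reads carry independent per-base substitution errors (default
  0.5%).

The ground-truth activity is additive: a baseline plus per-position
per-base weights (SD 0.025 per position across ~86 free positions,
giving a library activity SD near 0.19) plus motif bonuses. Two motifs
are planted deliberately so attribution analyses have recoverable
signal with a known sign: +0.10 per (overlapping) `TATATA` occurrence
and +0.15 for the extended ZEV site `GCGTGGGCGGCTA`. Because
overlapping occurrences each count, longer TA repeats both score higher
and are more robust to any single mutation — qualitatively matching the
repeat-length effect the attribution analysis is expected to find.

What the generator does **not** emulate: PCR amplification bias,
cytometer optics, doublets, epistasis (an optional interaction term can
be added through the motif table), or replicate-specific batch effects.
Tests passing on these fixtures therefore demonstrate correctness of
the inference and design machinery under the model's own assumptions,
not performance on real sort-seq data.

## Activity inference

For a cell with mean activity $\mu$, shared SD $\sigma$ and contaminant
fraction $\varepsilon$, the probability of landing in bin $i$ with
edges $(a_i, b_i)$ is

$$P_{\mu,\sigma,\varepsilon}(i) =
  \left[F_{\mu,\sigma}(b_i) - F_{\mu,\sigma}(a_i)\right]
  (1-\varepsilon) + \varepsilon/N,$$

with $F$ the normal CDF. Given per-bin counts $r_i$ the log-likelihood
of $\mu$ is $\sum_i r_i \log P(i)$, evaluated for all sequences at once
as the matrix product $AW$, where $A$ holds cell-normalized counts
(reads scaled by cells-per-read, $C_i/R_i$) and
$W_{ij} = \log P_{\mu_j}(i)$ over a candidate grid of means.
`fitMeans()` takes the per-row argmax; a dedicated test proves the
matrix route exactly equals a per-sequence loop.

Numerical choices worth knowing:

* The outermost bin edges are treated as $-\infty/+\infty$ so the
  distribution normalizes (the gates cover the library's range); a
  switch restores finite edges for sensitivity analysis.
* Normal bin masses are computed with upper-tail CDFs for bins right
  of $\mu$: the naive difference of lower-tail CDFs cancels to exactly
  zero in double precision a few dozen SDs out, and a zero probability
  would turn zero-count bins into `0 * log(0) = NaN` in the matrix
  product. Probabilities are floored at `1e-300` before the log.
* Grids: $\mu$ over the bin range extended by one bin width, step
  0.005; $\sigma$ over 0.05–0.40 step 0.01; $\varepsilon$ over 0–0.20
  step 0.01. The grids used at full experimental scale are not published; these
  are configurable defaults.
* Argmax ties break toward the smallest $\mu$, making outputs
  deterministic.

Hyperparameters $(\sigma, \varepsilon)$ are chosen by grid search,
scoring each pair by the summed per-sequence maximum log-likelihood,
independently per replicate, as at full scale. Estimates from
replicates are averaged; pairs differing by more than 0.2 log10 units
are flagged as discordant outliers, sequences observed only in an
extreme bin are flagged, and a minimum-read filter (10 reads per
replicate for the constitutive data, 20 for the inducible data) gates
model-training tables.

A note on precision: with $\sigma = 0.15$ and 200 cells per sequence, a
single replicate cannot beat an RMSE of about
$\sigma/\sqrt{200} \approx 0.0106$ (the information bound; binning
loses slightly more). The pipeline's accuracy statement — RMSE at or
below 0.01 — therefore refers to the duplicate design whose mean is
the final estimate, which the acceptance suite measures at about
0.008 with $R^2 > 0.99$ and exact recovery of $(\sigma, \varepsilon)$
on the default grid.

## Read reconstruction

Full-length variant sequences are recovered from error-bearing reads by
sort-and-compare clustering: reads are sorted lexicographically (byte
order, locale-independent) and each read is compared to the next by
Needleman–Wunsch distance (gap 5, mismatch 1, match 0); a cluster is a
maximal run with adjacent distance at or below a cutoff (default 10 —
the cutoff was chosen per experiment at full scale and its value is
not published).
Because sorting hides errors near the read start, the pass is repeated
on reversed reads and clusters sharing reads are merged (connected
components via union-find; a test checks this against igraph). Each
cluster is reduced by a per-position vote among reads of the modal
length: votes across unequal lengths are undefined, so minority-length
members are ignored, and "majority" is implemented as a unique strict
plurality — exact ties reject the cluster, as do singletons. Counting
reads are then linked to consensi by exact match of the first 35 bases;
error-bearing keys are indistinguishable from other members, so no
mismatch tolerance is applied, and duplicated identifiers exclude all
sequences involved.

## The convolutional ensemble

Sequences are one-hot encoded (rows A, C, G, T), embedded in their
vector-context flanks with at least 25 bp of padding, and pad lengths
are equalized across libraries so constitutive and inducible examples
share one input length. Training augments each example with a fresh
uniform shift of 0–7 positions inside the frame each epoch; validation,
test and design always use shift 0.

The network follows the original architecture, fully parameterized:
blocks of width-8 convolutions (same padding) with batch normalization
before each ReLU and max-pooling of stride 2, two dense layers with
batch normalization and ReLU, and a linear output with one unit
(constitutive activity) or two (uninduced and induced, losses weighted
equally; constitutive examples supervise both outputs when data sets
are merged). L2 regularization (weight $10^{-4}$) applies to all
weight matrices except the output layer. Training uses Adam on Huber
loss with $\delta = 0.15$ and early stopping after a patience of
epochs without validation improvement, returning the best-validation
weights. The ensemble trains $k$ submodels sharing one held-out test
set (10%); the remainder is split into $k$ equal folds and submodel
$j$ validates on fold $j$. Predictions merge by the mean, or by mean
minus the population standard deviation (divisor $k$) — the
extrapolation penalty that damps sequences the submodels disagree on.

No deep-learning framework is involved: the forward and backward
passes, batch normalization, Adam and the input-gradient computation
are implemented in single-precision RcppArmadillo inside the package,
and the input gradient is verified against finite differences in the
tests. The full-size preset (6 blocks, 128 channels, $k = 9$,
learning rate $10^{-5}$) reflects the original configuration and is
impractical on a laptop-scale CPU; the `small` preset used by the
tests and the acceptance script keeps the structure (2 blocks, 16
channels, $k = 3$ submodels over the same nine-fold partition of the
non-test data, so each submodel still trains on 8/9 of it) and adapts
the optimizer to desk scale (learning rate $8 \times 10^{-3}$, batch
256, patience 12, up to 120 epochs, multiplying the rate by 0.7 after
every 5 stagnant epochs). Problem sizes in the
acceptance runs — 5,000 training sequences of a 110-bp demonstration
scaffold, 1,000 sequences for inference, 500 for read reconstruction —
were chosen as the smallest at which the statistical claims are
comfortably testable.

## Sequence design

Three strategies maximize a model-scored objective (constitutive
activity, induced activity, or activation ratio = induced minus
uninduced on the log scale; whether the original implementation used
the log difference or a delogged ratio is not documented — the log difference is the default
and a config alternative exists):

* **Screening** samples scaffold-conformant sequences and keeps those
  at or above a score threshold.
* **Evolution** mutates only randomized positions of a parent (bases
  redrawn from the segment's own frequencies, so excluded bases can
  never appear), scores a set of variants per cycle, and passes the
  best variant on — even when worse than the parent, which is the
  literal reading of the original procedure; a hill-climb mode is a
  config switch. The per-cycle mutation count decays 8, 4, 2, 1 over
  quartiles of the cycle budget (the original procedure is documented
  only as a count decreasing over time).
* **Gradient ascent** maintains a continuous relaxation of the one-hot
  input, adds the input gradient of the objective at randomized
  positions only (for the extrapolation penalty the exact gradient of
  mean − SD is used), and after each step rounds by per-column argmax
  — restricted to bases with nonzero scaffold frequency — to a valid
  sequence that is then scored. Default step size 0.1 with a 500-step
  cap (not documented for the original runs; iteration counts replace
  wall-clock budgets for determinism).

Accepted designs must reach the threshold and pass the constraint set:
no 20-bp window with GC below 25% or above 80% (inclusive bounds — the
text rejects "below/above") when the GC constraint is on, and never a
BsaI site (`GGTCTC`/`GAGACC`), which would break Golden Gate assembly.
Constraints are checked at acceptance time, matching the original post-hoc
filter; per-cycle checking is available.
`adjustThreshold()` implements the two threshold-calibration modes:
lowering by 0.05 until a set can be produced (screening) and raising by
0.05 until production fails (the elevated-threshold designs).

## In silico mutagenesis

For each designed sequence all $3L$ single-base mutants are scored.
Two sign conventions are in circulation for such scans and are fixed
here explicitly: the *signed differential* is mutant minus original
(negative = predicted loss), and the *position score* is the greatest
predicted loss, $\max(\text{original} - \text{mutant}) \ge 0$ for
beneficial positions. Position importance averages position scores
across sequences and normalizes to the maximum; negative position
scores (possible on non-optimized sequences where mutants improve the
score) are floored at zero so the track stays in $[0, 1]$. Candidate
motif blocks are maximal runs of at least 6 randomizable positions
whose minimal signed differential falls strictly below the quantile
selecting 5% of randomizable bases — applied to signed differentials
rather than position scores because the blocks are meant to capture
loss-of-function motifs; both views are computable. TA-repeat analysis
finds the longest whole-unit TA run in the 5' spacer per sequence and
reports the median differential inside it, grouped by repeat length,
against a baseline of 5'-spacer positions outside any qualifying
repeat; the ZEV-site extension analysis classifies the 4-mer after
each constant ZEV site as `GCTA` or not and compares median
differentials over those four positions per site.

## Known limitations

The acceptance-scale model is trained on noise-free ground-truth
activities of a miniature scaffold; real libraries add measurement
noise, length-scale effects and epistasis, so held-out accuracy there
does not predict accuracy on the deposited experimental data, whose
headline numbers (test $R^2$ of 0.79–0.84 at 675,000 + 327,000
sequences) require the full-size configuration and days of GPU-scale
compute. Consensus calling ignores base qualities. Paired-end merging
and transcription-factor database enrichment are out of scope by
design; the pipeline starts from merged reads and stops at frequency
matrices and score tables.
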