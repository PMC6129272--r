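#' One-hot encoded DNA sequence
#'
#' A 4 x L matrix representation of a DNA sequence with rows in the fixed
#' order A, C, G, T. Columns always sum to 1. A natural (unmutated) sequence
#' is strictly one-hot; after a GC-background mutation (see
#' [applyBackgroundMutation()]) mutated columns hold fractional values in
#' [0, 1].
#'
#' @slot id character(1), sequence identifier.
#' @slot mat real 4 x L matrix, rows A, C, G, T.
#' @seealso [oneHotEncode()], [oneHotDecode()]
#' @export
setClass("OneHotSequence",
  representation(id = "character", mat = "matrix"))

setValidity("OneHotSequence", function(object) {
  m <- object@mat
  if (length(object@id) != 1L) return("id must be a single string")
  if (nrow(m) != 4L) return("matrix must have 4 rows (A, C, G, T)")
  if (ncol(m) < 1L) return("sequence must be non-empty")
  if (!identical(rownames(m), .BASES)) return("rownames must be A, C, G, T")
  if (any(!is.finite(m))) return("matrix entries must be finite")
  if (any(m < -1e-12 | m > 1 + 1e-12)) return("entries must lie in [0, 1]")
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-9)) return("every column must sum to 1")
  TRUE
})

#' A nucleotide or motif feature in a sequence
#'
#' A feature locus is either a single (base, position) nucleotide feature,
#' e.g. a single-nucleotide variant, or a contiguous (subsequence, span)
#' motif feature. Positions are 1-based; only the plus strand is supported
#' (score reverse-complement features by constructing them explicitly).
#'
#' @slot sequenceId character(1), id of the sequence the locus refers to
#'   ("" when detached).
#' @slot kind "nucleotide" or "motif".
#' @slot positions ordered integer positions (single position for a
#'   nucleotide, contiguous ascending span for a motif).
#' @slot bases character vector of observed bases, one per position.
#' @slot strand "+" only.
#' @seealso [featureLocus()], [readFeatureBed()]
#' @export
setClass("FeatureLocus",
  representation(sequenceId = "character", kind = "character",
    positions = "integer", bases = "character", strand = "character"))

setValidity("FeatureLocus", function(object) {
  p <- object@positions
  if (length(p) < 1L) return("locus must cover at least one position")
  if (any(p < 1L)) return("positions must be >= 1")
  if (length(object@bases) != length(p))
    return("bases must have one entry per position")
  if (!all(object@bases %in% .BASES)) return("bases must be A, C, G or T")
  if (!identical(object@strand, "+")) return("only the + strand is supported")
  if (length(p) == 1L) {
    if (object@kind != "nucleotide") return("single position must be kind 'nucleotide'")
  } else {
    if (object@kind != "motif") return("multi-position locus must be kind 'motif'")
    if (!identical(p, seq(p[1L], p[length(p)])))
      return("motif span must be contiguous and ascending")
  }
  TRUE
})

#' Per-nucleotide importance (attribution) matrix
#'
#' The 4 x L matrix of contribution scores of every nucleotide at every
#' position of one sequence, produced by an attribution backend. For the
#' gradient-times-input backend on a one-hot sequence, entries at
#' non-observed bases are exactly zero.
#'
#' @slot scores real 4 x L matrix.
#' @slot sequenceId character(1).
#' @slot backend "gradInput" or "refDiff".
#' @slot referenceSpec list describing the reference construction for
#'   reference-based backends (empty for gradInput).
#' @seealso [importanceMatrix()], [importanceOfLocus()]
#' @export
setClass("ImportanceMatrix",
  representation(scores = "matrix", sequenceId = "character",
    backend = "character", referenceSpec = "list"))

setValidity("ImportanceMatrix", function(object) {
  if (nrow(object@scores) != 4L) return("scores must have 4 rows")
  if (any(!is.finite(object@scores))) return("scores must be finite")
  TRUE
})

#' Attribution backend
#'
#' A named attribution method plus its configuration and an evaluation
#' counter. The counter records how many importance matrices the backend
#' has produced, which makes the linear, O(F), cost of interaction maps
#' directly observable (see [backendCalls()]).
#'
#' @slot name "gradInput" or "refDiff".
#' @slot refSpec list of reference parameters (refDiff only).
#' @slot counter environment holding the evaluation count.
#' @seealso [gradInputBackend()], [refDiffBackend()]
#' @export
setClass("ImportanceBackend",
  representation(name = "character", refSpec = "list", counter = "environment"))

#' Virtual parent for models satisfying the sequence-model contract
#'
#' A model exposes scalar predictions Y (the regression output, or for a
#' classifier the pre-sigmoid logit) via [modelPredict()] and exact input
#' gradients dY/dX via [inputGradient()], both accepting batches and
#' fractional (non one-hot) columns. Multi-task models select one output
#' through `taskIndex`.
#'
#' @slot taskIndex integer(1), the output scored by predict/gradient.
#' @export
setClass("SequenceModel", representation("VIRTUAL", taskIndex = "integer"))

#' Linear sequence model fixture
#'
#' `Y = sum(weights * X) + bias`, gradient identically equal to `weights`.
#' A linear model encodes no interactions, so every FIS and every pairwise
#' in-silico-mutagenesis interaction on it is exactly zero -- the package's
#' principal analytic test fixture.
#'
#' @slot weights 4 x L matrix. @slot bias numeric(1).
#' @seealso [wrapLinearModel()]
#' @export
setClass("LinearSequenceModel", contains = "SequenceModel",
  representation(weights = "matrix", bias = "numeric"))

#' Small convolutional sequence classifier
#'
#' One convolutional layer (ReLU), windowed (or global) max pooling, one
#' ReLU dense hidden layer and a linear multi-task output (logits).
#' Implemented
#' in-package with exact analytic backpropagation for both parameter and
#' input gradients.
#'
#' @slot params list(Wc, bc, Wh, bh, Wo, bo, w, pool) of parameters,
#'   filter width and pooling window width.
#' @slot trainingLog data.frame of per-epoch loss and validation accuracy.
#' @seealso [trainBenchmarkCnn()], [convSequenceModel()]
#' @export
setClass("ConvSequenceModel", contains = "SequenceModel",
  representation(params = "list", trainingLog = "data.frame"))

#' Dense (fully connected) sequence regressor
#'
#' A multilayer perceptron on the flattened one-hot encoding, ReLU hidden
#' layers and a linear output; used for short fixed-length inputs such as
#' motif-flank libraries.
#'
#' @slot params list(W = list, b = list) of layer weights and biases.
#' @slot inputDim integer(2): c(4, L) expected input shape.
#' @slot trainingLog data.frame of per-epoch loss and validation R^2.
#' @seealso [trainFlankModel()], [denseSequenceModel()]
#' @export
setClass("DenseSequenceModel", contains = "SequenceModel",
  representation(params = "list", inputDim = "integer",
    trainingLog = "data.frame"))

#' Gaussian null model for FIS significance
#'
#' Gaussian (mu, sigma) fitted by maximum likelihood to FIS scores computed
#' on dinucleotide-shuffled input sequences.
#'
#' @slot mu numeric(1). @slot sigma positive numeric(1).
#' @slot nNull integer(1), number of null scores used in the fit.
#' @seealso [buildNull()], [fisSignificance()]
#' @export
setClass("NullModel",
  representation(mu = "numeric", sigma = "numeric", nNull = "integer"))

setValidity("NullModel", function(object) {
  if (!is.finite(object@mu)) return("mu must be finite")
  if (!is.finite(object@sigma) || object@sigma <= 0)
    return("sigma must be a positive real")
  if (object@nNull < 1L) return("nNull must be positive")
  TRUE
})

#' Per-sequence deep feature interaction map
#'
#' L x L matrix whose (s, t) entry is the maximal FIS of target position t
#' with source position s, maximised over the three mutant bases at s under
#' the chosen policy. The diagonal (t == s) is undefined and masked as NA:
#' mutating s changes the observed base at s, so the score is ill-posed
#' there.
#'
#' @slot sequenceId character(1). @slot scores L x L matrix, NA on masked
#'   entries. @slot policy "abs" or "signed". @slot backend backend name.
#' @seealso [dfimMap()]
#' @export
setClass("DFIMMap",
  representation(sequenceId = "character", scores = "matrix",
    policy = "character", backend = "character"))

#' Cross-sequence aggregate interaction map
#'
#' Matrix of aggregate FIS statistics with rows indexed by (source
#' position, source base) and columns by (target position, target base),
#' with per-cell sequence counts. Cells whose (source base, target base,
#' positions) context matched no sequence are NA with count 0.
#'
#' @slot values numeric matrix of aggregate scores.
#' @slot counts integer matrix of contributing-sequence counts.
#' @slot statistic e.g. "max_mutant_mean_abs".
#' @seealso [marginalizedAggregateMap()], [aggregateFis()]
#' @export
setClass("AggregateMap",
  representation(values = "matrix", counts = "matrix", statistic = "character"))

#' Labeled synthetic benchmark dataset
#'
#' Sequences with binary labels and a ground-truth table of planted motif
#' embeddings. Positive sequences contain at least one ELF1 and one SIX5
#' instance; negatives contain only one of the two.
#'
#' @slot sequences named character vector of DNA strings.
#' @slot labels integer vector of 0/1 labels, parallel to sequences.
#' @slot truth data.frame(sequence_id, motif, start, end) of planted spans
#'   (1-based, closed).
#' @slot config list of generator settings (n per set, L, fGC, motifs,
#'   seed, ...).
#' @seealso [simulateBenchmark()]
#' @export
setClass("BenchmarkDataset",
  representation(sequences = "character", labels = "integer",
    truth = "data.frame", config = "list"))

setValidity("BenchmarkDataset", function(object) {
  if (length(object@sequences) != length(object@labels))
    return("labels must be parallel to sequences")
  if (is.null(names(object@sequences))) return("sequences must be named")
  if (!all(object@labels %in% c(0L, 1L))) return("labels must be 0/1")
  TRUE
})
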