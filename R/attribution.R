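#' Gradient-times-input attribution backend
#'
#' Importance scores are the pointwise product of the gradient of the model
#' output with the one-hot input: a first-order Taylor decomposition of the
#' output. On a one-hot sequence only observed nucleotides can have
#' non-zero importance. One forward+backward pass per sequence.
#'
#' @return an [ImportanceBackend-class].
#' @seealso [refDiffBackend()], [importanceMatrix()]
#' @export
gradInputBackend <- function() {
  cnt <- new.env(parent = emptyenv())
  cnt$n <- 0L
  new("ImportanceBackend", name = "gradInput", refSpec = list(), counter = cnt)
}

#' Reference-based attribution backend (integrated gradients)
#'
#' Contribution scores relative to neutral reference sequences: the
#' integrated-gradients path integral from each reference to the input
#' (midpoint rule with `nSteps` interpolation steps), multiplied elementwise
#' by (input - reference) and averaged over the references. Two reference
#' modes are supported:
#'
#' * `"dinuc_shuffle"`: `nReferences` dinucleotide-shuffled versions of the
#'   input sequence, regenerated from `shuffleSeed` at every call so that a
#'   mutated sequence gets its own references from the same seed stream --
#'   the mutation, not reference resampling, drives score differences.
#' * `"fixed_gc"`: a single constant fractional reference with C/G rows at
#'   `fGC / 2` and A/T rows at `(1 - fGC) / 2`; appropriate when sequences
#'   were generated on a fixed-GC background.
#'
#' External attribution implementations (e.g. DeepLIFT) can be plugged in
#' through the same [importanceMatrix()] signature via
#' [registerImportanceBackend()].
#'
#' @param nReferences number of references (dinuc_shuffle mode).
#' @param nSteps interpolation steps of the path integral.
#' @param mode "dinuc_shuffle" or "fixed_gc".
#' @param shuffleSeed mandatory integer seed for reference generation
#'   (dinuc_shuffle mode).
#' @param fGC background G+C fraction (fixed_gc mode).
#' @return an [ImportanceBackend-class].
#' @export
refDiffBackend <- function(nReferences = 10L, nSteps = 50L,
    mode = c("dinuc_shuffle", "fixed_gc"), shuffleSeed = 1L, fGC = NULL) {
  mode <- match.arg(mode)
  if (nReferences < 1L) .input_error("nReferences must be >= 1")
  if (nSteps < 1L) .input_error("nSteps must be >= 1")
  if (mode == "fixed_gc") {
    if (is.null(fGC) || fGC <= 0 || fGC >= 1)
      .input_error("fixed_gc mode requires fGC in (0, 1)")
    nReferences <- 1L
  }
  cnt <- new.env(parent = emptyenv())
  cnt$n <- 0L
  new("ImportanceBackend", name = "refDiff",
    refSpec = list(nReferences = as.integer(nReferences),
      nSteps = as.integer(nSteps), mode = mode,
      shuffleSeed = as.integer(shuffleSeed), fGC = fGC),
    counter = cnt)
}

.backend_registry <- new.env(parent = emptyenv())

#' Register a plug-in attribution backend
#'
#' A plug-in is a function `fun(model, x)` returning a finite 4 x L score
#' matrix; it becomes available as `customBackend(name)` and must satisfy
#' the [ImportanceMatrix-class] contract.
#'
#' @param name backend name.
#' @param fun scoring function.
#' @export
registerImportanceBackend <- function(name, fun) {
  if (!is.function(fun)) .input_error("fun must be a function(model, x)")
  assign(name, fun, envir = .backend_registry)
  invisible(name)
}

#' @rdname registerImportanceBackend
#' @return `customBackend` returns an [ImportanceBackend-class] dispatching
#'   to the registered function.
#' @export
customBackend <- function(name) {
  if (!exists(name, envir = .backend_registry))
    .input_error("no registered backend named '", name, "'")
  cnt <- new.env(parent = emptyenv())
  cnt$n <- 0L
  new("ImportanceBackend", name = name, refSpec = list(), counter = cnt)
}

#' Number of importance evaluations performed by a backend
#'
#' Each computed importance matrix counts as one evaluation, which is the
#' unit in which interaction-map complexity is stated: an all-pairs map of
#' a length-L sequence costs exactly 3L + 1 evaluations, and F pre-specified
#' source features cost F + 1.
#'
#' @param backend an [ImportanceBackend-class].
#' @return integer count.
#' @export
backendCalls <- function(backend) backend@counter$n

#' @rdname backendCalls
#' @export
resetBackendCalls <- function(backend) {
  backend@counter$n <- 0L
  invisible(backend)
}

setMethod("show", "ImportanceBackend", function(object) {
  cat("ImportanceBackend '", object@name, "'", sep = "")
  if (length(object@refSpec))
    cat(" (", object@refSpec$mode, ", n_ref = ", object@refSpec$nReferences,
      ", steps = ", object@refSpec$nSteps, ")", sep = "")
  cat("; evaluations:", object@counter$n, "\n")
})

.fixed_gc_reference <- function(L, fGC) {
  ref <- matrix((1 - fGC) / 2, 4L, L, dimnames = list(.BASES, NULL))
  ref[c("C", "G"), ] <- fGC / 2
  ref
}

.make_references <- function(m, spec) {
  if (spec$mode == "fixed_gc")
    return(list(.fixed_gc_reference(ncol(m), spec$fGC)))
  ## shuffle the argmax-decoded string (deterministic first-row tie-break
  ## for fractional columns); regenerated identically at each call
  s <- paste(.BASES[.observed_rows(m)], collapse = "")
  lapply(seq_len(spec$nReferences), function(k)
    ohMatrix(oneHotEncode(dinucleotideShuffle(s, seed = spec$shuffleSeed + k - 1L))))
}

#' Compute the importance matrix of a sequence under a backend
#'
#' Dispatches to the backend's attribution rule and increments its
#' evaluation counter by one. Scores must be finite; a model returning
#' non-finite gradients violates the contract and raises an error.
#'
#' @param backend an [ImportanceBackend-class].
#' @param model a [SequenceModel-class].
#' @param x a [OneHotSequence-class] or 4 x L matrix (fractional columns
#'   allowed).
#' @return an [ImportanceMatrix-class].
#' @export
importanceMatrix <- function(backend, model, x) {
  m <- .as_oh(x)
  scores <- switch(backend@name,
    gradInput = {
      g <- inputGradient(model, m)
      if (any(!is.finite(g)))
        .contract_error("model produced non-finite gradients")
      g * m
    },
    refDiff = .ref_diff_scores(backend, model, m),
    {
      fun <- get(backend@name, envir = .backend_registry)
      fun(model, m)
    })
  if (any(!is.finite(scores)))
    .contract_error("backend '", backend@name, "' produced non-finite scores")
  backend@counter$n <- backend@counter$n + 1L
  new("ImportanceMatrix", scores = scores, sequenceId = .oh_id(x),
    backend = backend@name, referenceSpec = backend@refSpec)
}

.ref_diff_scores <- function(backend, model, m) {
  spec <- backend@refSpec
  refs <- .make_references(m, spec)
  for (r in refs)
    if (!identical(dim(r), dim(m)))
      .input_error("reference length does not match the input sequence")
  msteps <- spec$nSteps
  total <- matrix(0, 4L, ncol(m), dimnames = list(.BASES, NULL))
  for (r in refs) {
    diff <- m - r
    pts <- lapply(seq_len(msteps), function(k)
      r + (k - 0.5) / msteps * diff)
    gs <- inputGradient(model, pts)
    if (any(vapply(gs, function(g) any(!is.finite(g)), logical(1))))
      .contract_error("model produced non-finite gradients")
    gbar <- Reduce(`+`, gs) / msteps
    total <- total + gbar * diff
  }
  total / length(refs)
}

#' Summed importance of a feature locus
#'
#' The importance of a motif (or nucleotide) feature is the sum of the
#' importance scores of its observed (base, position) pairs.
#'
#' @param C an [ImportanceMatrix-class].
#' @param locus a [FeatureLocus-class].
#' @return numeric(1).
#' @export
importanceOfLocus <- function(C, locus) {
  s <- C@scores
  if (max(locus@positions) > ncol(s) || min(locus@positions) < 1L)
    .input_error("locus out of range for importance matrix of length ", ncol(s))
  sum(s[cbind(match(locus@bases, .BASES), locus@positions)])
}

#' @rdname ImportanceMatrix-class
#' @export
setMethod("importanceScores", "ImportanceMatrix", function(x) x@scores)

setMethod("show", "ImportanceMatrix", function(object) {
  cat("ImportanceMatrix '", object@sequenceId, "' (", object@backend,
    "): L = ", ncol(object@scores), ", |score| range [",
    sprintf("%.3g", min(abs(object@scores))), ", ",
    sprintf("%.3g", max(abs(object@scores))), "]\n", sep = "")
})
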