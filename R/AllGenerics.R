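#' Predict scalar model outputs for one or more sequences
#'
#' Returns the model's scalar output Y for each input: the regression value,
#' or for classifiers the pre-sigmoid logit (never the probability -- the
#' sigmoid saturates and would crush gradients). Accepts a single 4 x L
#' matrix, a [OneHotSequence-class], or a list of either; fractional
#' (non one-hot) columns are allowed. Batched and unbatched calls return
#' identical numbers.
#'
#' @param model a [SequenceModel-class].
#' @param x input sequence(s).
#' @return numeric vector of scalar outputs, one per input.
#' @export
setGeneric("modelPredict", function(model, x) standardGeneric("modelPredict"))

#' Exact gradient of the model output with respect to the input
#'
#' Returns dY/dX evaluated at `x`, as a 4 x L matrix (or list of matrices
#' for a batch). Must agree with central finite differences of
#' [modelPredict()] to a relative tolerance of 1e-3 (see [gradientCheck()]).
#'
#' @inheritParams modelPredict
#' @return 4 x L gradient matrix, or a list of them for list input.
#' @export
setGeneric("inputGradient", function(model, x) standardGeneric("inputGradient"))

#' Number of outputs (tasks) of a model
#' @param model a [SequenceModel-class].
#' @return integer(1).
#' @export
setGeneric("numTasks", function(model) standardGeneric("numTasks"))

#' Extract one task of a multi-task model as a single-output model
#'
#' The clone's predictions and input gradients are identical to the parent
#' model evaluated with `taskIndex = task`.
#'
#' @param model a multi-task [SequenceModel-class].
#' @param task integer task index.
#' @return a single-output model of the same class.
#' @export
setGeneric("cloneTask", function(model, task) standardGeneric("cloneTask"))

#' @rdname OneHotSequence-class
#' @param x a OneHotSequence.
#' @return `ohMatrix` returns the 4 x L matrix; `seqId` the identifier;
#'   `seqLength` the length L.
#' @export
setGeneric("ohMatrix", function(x) standardGeneric("ohMatrix"))

#' @rdname OneHotSequence-class
#' @export
setGeneric("seqId", function(x) standardGeneric("seqId"))

#' @rdname OneHotSequence-class
#' @export
setGeneric("seqLength", function(x) standardGeneric("seqLength"))

#' @rdname ImportanceMatrix-class
#' @param x an ImportanceMatrix.
#' @return the 4 x L score matrix.
#' @export
setGeneric("importanceScores", function(x) standardGeneric("importanceScores"))
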