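## normalise predict/gradient input to a list of 4 x L matrices
.as_batch <- function(x) {
  if (is(x, "OneHotSequence")) return(list(x@mat))
  if (is.matrix(x)) return(list(.as_oh(x)))
  if (is.list(x)) return(lapply(x, .as_oh))
  .input_error("expected a OneHotSequence, a 4 x L matrix, or a list of them")
}

.check_finite_pred <- function(y) {
  if (any(!is.finite(y)))
    .contract_error("model produced non-finite predictions")
  y
}

#' Wrap a weight matrix as an analytic linear model
#'
#' `predict(X) = sum(weights * X) + bias` with input gradient identically
#' `weights`. Because a linear model encodes no feature interactions, every
#' interaction score computed on it is exactly zero -- the package's
#' analytic null fixture.
#'
#' @param weights finite 4 x L matrix.
#' @param bias scalar.
#' @return a [LinearSequenceModel-class].
#' @examples
#' m <- wrapLinearModel(matrix(1, 4, 8, dimnames = list(c("A","C","G","T"), NULL)))
#' modelPredict(m, oneHotEncode("ACGTACGT"))  # 8
#' @export
wrapLinearModel <- function(weights, bias = 0) {
  if (!is.matrix(weights) || nrow(weights) != 4L || any(!is.finite(weights)))
    .input_error("weights must be a finite 4 x L matrix")
  if (is.null(rownames(weights))) rownames(weights) <- .BASES
  new("LinearSequenceModel", weights = weights, bias = as.numeric(bias),
    taskIndex = 1L)
}

#' @describeIn modelPredict linear model: `sum(weights * X) + bias`.
#' @export
setMethod("modelPredict", "LinearSequenceModel", function(model, x) {
  xs <- .as_batch(x)
  y <- vapply(xs, function(m) {
    if (!identical(dim(m), dim(model@weights)))
      .input_error("input shape ", paste(dim(m), collapse = "x"),
        " does not match model weights ",
        paste(dim(model@weights), collapse = "x"))
    sum(model@weights * m) + model@bias
  }, numeric(1))
  .check_finite_pred(y)
})

#' @describeIn inputGradient linear model: the constant `weights` matrix.
#' @export
setMethod("inputGradient", "LinearSequenceModel", function(model, x) {
  xs <- .as_batch(x)
  out <- lapply(xs, function(m) {
    if (!identical(dim(m), dim(model@weights)))
      .input_error("input shape does not match model weights")
    model@weights
  })
  if (length(out) == 1L && !is.list(x)) out[[1L]] else out
})

setMethod("numTasks", "LinearSequenceModel", function(model) 1L)

setMethod("show", "LinearSequenceModel", function(object) {
  cat("LinearSequenceModel: L =", ncol(object@weights),
    "bias =", object@bias, "\n")
})

#' Construct a convolutional sequence model from explicit parameters
#'
#' Architecture: one convolutional layer (`nFilters` filters of width `w`,
#' ReLU), max pooling over position windows of width `pool` (global when
#' `pool` is missing or infinite), one ReLU dense hidden layer, and a
#' linear multi-task output whose values are logits.
#'
#' @param params list with elements `Wc` (nFilters x 4w), `bc` (nFilters),
#'   `Wh` (nHidden x nFilters * nWindows), `bh` (nHidden), `Wo`
#'   (nTasks x nHidden), `bo` (nTasks), `w` (filter width) and optional
#'   `pool` (pooling window width).
#' @param taskIndex output selected by predict/gradient (default 1).
#' @param trainingLog optional data.frame of training history.
#' @return a [ConvSequenceModel-class].
#' @export
convSequenceModel <- function(params, taskIndex = 1L,
    trainingLog = data.frame()) {
  need <- c("Wc", "bc", "Wh", "bh", "Wo", "bo", "w")
  if (!all(need %in% names(params)))
    .input_error("params must contain ", paste(need, collapse = ", "))
  if (ncol(params$Wc) != 4L * params$w)
    .input_error("Wc must have 4 * w columns")
  if (taskIndex < 1L || taskIndex > nrow(params$Wo))
    .input_error("taskIndex out of range")
  new("ConvSequenceModel", params = params, taskIndex = as.integer(taskIndex),
    trainingLog = trainingLog)
}

#' @describeIn modelPredict convolutional model: logit of `taskIndex`.
#'   Sequences are evaluated one at a time internally so that results are
#'   bit-identical whether or not calls are batched.
#' @export
setMethod("modelPredict", "ConvSequenceModel", function(model, x) {
  xs <- .as_batch(x)
  y <- vapply(xs, function(m)
    .cnn_forward(model@params, list(m))$Y[model@taskIndex, 1L], numeric(1))
  .check_finite_pred(y)
})

#' @describeIn inputGradient convolutional model: exact backpropagated
#'   gradient of the selected logit; bit-identical across batchings.
#' @export
setMethod("inputGradient", "ConvSequenceModel", function(model, x) {
  xs <- .as_batch(x)
  out <- lapply(xs, function(m)
    .cnn_input_grad(model@params, list(m), model@taskIndex)[[1L]])
  if (length(out) == 1L && !is.list(x)) out[[1L]] else out
})

setMethod("numTasks", "ConvSequenceModel", function(model) nrow(model@params$Wo))

#' @describeIn cloneTask convolutional model: keeps one output row.
#' @export
setMethod("cloneTask", "ConvSequenceModel", function(model, task) {
  task <- as.integer(task)
  if (task < 1L || task > numTasks(model)) .input_error("task out of range")
  p <- model@params
  p$Wo <- p$Wo[task, , drop = FALSE]
  p$bo <- p$bo[task]
  convSequenceModel(p, taskIndex = 1L, trainingLog = model@trainingLog)
})

setMethod("show", "ConvSequenceModel", function(object) {
  p <- object@params
  cat("ConvSequenceModel:", nrow(p$Wc), "filters x width", p$w, "->",
    nrow(p$Wh), "hidden ->", nrow(p$Wo), "task(s); taskIndex =",
    object@taskIndex, "\n")
  if (nrow(object@trainingLog) > 0) {
    last <- object@trainingLog[nrow(object@trainingLog), ]
    cat("  trained", nrow(object@trainingLog), "epochs; final val accuracy",
      sprintf("%.4f", last$valAccuracy), "\n")
  }
})

#' Construct a dense (MLP) sequence model from explicit parameters
#'
#' @param params list(W = list of weight matrices, b = list of bias
#'   vectors); ReLU after every layer except the last (linear output).
#' @param inputDim integer(2), expected input shape c(4, L).
#' @param taskIndex output row selected by predict/gradient.
#' @param trainingLog optional data.frame of training history.
#' @return a [DenseSequenceModel-class].
#' @export
denseSequenceModel <- function(params, inputDim, taskIndex = 1L,
    trainingLog = data.frame()) {
  if (!is.list(params$W) || !is.list(params$b) ||
      length(params$W) != length(params$b))
    .input_error("params must be list(W = list, b = list) of equal length")
  if (ncol(params$W[[1L]]) != prod(inputDim))
    .input_error("first layer must accept ", prod(inputDim), " inputs")
  new("DenseSequenceModel", params = params,
    inputDim = as.integer(inputDim), taskIndex = as.integer(taskIndex),
    trainingLog = trainingLog)
}

.mlp_stack <- function(model, xs) {
  d <- prod(model@inputDim)
  X <- matrix(0, d, length(xs))
  for (i in seq_along(xs)) {
    if (!identical(dim(xs[[i]]), model@inputDim))
      .input_error("input shape ", paste(dim(xs[[i]]), collapse = "x"),
        " does not match model input ", paste(model@inputDim, collapse = "x"))
    X[, i] <- as.vector(xs[[i]])
  }
  X
}

#' @describeIn modelPredict dense model: linear output of `taskIndex`;
#'   evaluated per sequence so results are bit-identical across batchings.
#' @export
setMethod("modelPredict", "DenseSequenceModel", function(model, x) {
  xs <- .as_batch(x)
  y <- vapply(xs, function(m) {
    X <- .mlp_stack(model, list(m))
    .mlp_forward(model@params, X)$Y[model@taskIndex, 1L]
  }, numeric(1))
  .check_finite_pred(y)
})

#' @describeIn inputGradient dense model: exact backpropagated gradient;
#'   bit-identical across batchings.
#' @export
setMethod("inputGradient", "DenseSequenceModel", function(model, x) {
  xs <- .as_batch(x)
  out <- lapply(xs, function(m) {
    X <- .mlp_stack(model, list(m))
    G <- .mlp_input_grad(model@params, X, model@taskIndex)
    matrix(G[, 1L], 4L, model@inputDim[2L], dimnames = list(.BASES, NULL))
  })
  if (length(out) == 1L && !is.list(x)) out[[1L]] else out
})

setMethod("numTasks", "DenseSequenceModel",
  function(model) nrow(model@params$W[[length(model@params$W)]]))

#' @describeIn cloneTask dense model: keeps one output row.
#' @export
setMethod("cloneTask", "DenseSequenceModel", function(model, task) {
  task <- as.integer(task)
  if (task < 1L || task > numTasks(model)) .input_error("task out of range")
  p <- model@params
  nl <- length(p$W)
  p$W[[nl]] <- p$W[[nl]][task, , drop = FALSE]
  p$b[[nl]] <- p$b[[nl]][task]
  denseSequenceModel(p, model@inputDim, taskIndex = 1L,
    trainingLog = model@trainingLog)
})

setMethod("show", "DenseSequenceModel", function(object) {
  sizes <- vapply(object@params$W, nrow, integer(1))
  cat("DenseSequenceModel: input", paste(object@inputDim, collapse = "x"),
    "-> layers", paste(sizes, collapse = ", "), "\n")
})

#' Check a model's analytic input gradient against finite differences
#'
#' Computes the central finite difference of [modelPredict()] for every
#' entry of the input and returns the maximum relative discrepancy
#' `|fd - analytic| / (|analytic| + 1e-8)` against [inputGradient()].
#' Values below 1e-3 on random inputs are required by the model contract;
#' analytic-exact models (e.g. linear) give ~0.
#'
#' @param model a [SequenceModel-class].
#' @param x a single input sequence.
#' @param epsilon step size, in (0, 0.1].
#' @return numeric(1), the maximum relative error.
#' @export
gradientCheck <- function(model, x, epsilon = 0.01) {
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon > 0.1)
    .input_error("epsilon must be in (0, 0.1]")
  m <- .as_oh(x)
  g <- inputGradient(model, m)
  if (any(!is.finite(g)))
    .contract_error("model produced non-finite gradients")
  n <- length(m)
  batch <- vector("list", 2L * n)
  for (k in seq_len(n)) {
    up <- m; up[k] <- up[k] + epsilon
    dn <- m; dn[k] <- dn[k] - epsilon
    batch[[2L * k - 1L]] <- up
    batch[[2L * k]] <- dn
  }
  y <- modelPredict(model, batch)
  fd <- (y[seq(1L, 2L * n, by = 2L)] - y[seq(2L, 2L * n, by = 2L)]) /
    (2 * epsilon)
  max(abs(fd - as.vector(g)) / (abs(as.vector(g)) + 1e-8))
}
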