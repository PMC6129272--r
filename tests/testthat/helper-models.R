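## Shared model fixtures.

## random small CNN (not trained): enough nonlinearity for oracle tests
randomConvModel <- function(seed, nFilters = 8L, w = 5L, nHidden = 12L,
    nTasks = 1L) {
  set.seed(seed)
  p <- list(
    Wc = matrix(rnorm(nFilters * 4L * w, 0, 0.4), nFilters, 4L * w),
    bc = rnorm(nFilters, 0, 0.1),
    Wh = matrix(rnorm(nHidden * nFilters, 0, 0.4), nHidden, nFilters),
    bh = rnorm(nHidden, 0, 0.1),
    Wo = matrix(rnorm(nTasks * nHidden, 0, 0.4), nTasks, nHidden),
    bo = rnorm(nTasks, 0, 0.1),
    w = as.integer(w))
  convSequenceModel(p, taskIndex = 1L)
}

randomLinearModel <- function(seed, L) {
  set.seed(seed)
  wrapLinearModel(matrix(rnorm(4L * L), 4L, L,
    dimnames = list(c("A", "C", "G", "T"), NULL)), bias = rnorm(1))
}

## linear model with dyadic-rational weights: sums are exact in binary
## floating point, so additivity cancellations are exactly zero
dyadicLinearModel <- function(seed, L) {
  set.seed(seed)
  w <- matrix(sample(seq(-2, 2, by = 1 / 16), 4L * L, replace = TRUE), 4L, L,
    dimnames = list(c("A", "C", "G", "T"), NULL))
  wrapLinearModel(w, bias = 0.5)
}

randomSeq <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

## analytic toy model Y = X[A, 1] * X[A, 2]: the minimal model with a pure
## pairwise interaction, with hand-computable gradients
setClass("ProductToyModel", contains = "SequenceModel")

productToyModel <- function() new("ProductToyModel", taskIndex = 1L)

setMethod("modelPredict", "ProductToyModel", function(model, x) {
  xs <- if (is.list(x)) x else list(x)
  vapply(xs, function(m) {
    m <- if (is(m, "OneHotSequence")) ohMatrix(m) else m
    m["A", 1L] * m["A", 2L]
  }, numeric(1))
})

setMethod("inputGradient", "ProductToyModel", function(model, x) {
  grad1 <- function(m) {
    m <- if (is(m, "OneHotSequence")) ohMatrix(m) else m
    g <- m * 0
    g["A", 1L] <- m["A", 2L]
    g["A", 2L] <- m["A", 1L]
    g
  }
  if (is.list(x)) lapply(x, grad1) else grad1(x)
})

## model violating the contract (non-finite output/gradient)
setClass("BrokenModel", contains = "SequenceModel")

brokenModel <- function() new("BrokenModel", taskIndex = 1L)

setMethod("modelPredict", "BrokenModel", function(model, x) {
  n <- if (is.list(x)) length(x) else 1L
  rep(NaN, n)
})

setMethod("inputGradient", "BrokenModel", function(model, x) {
  bad <- function(m) {
    m <- if (is(m, "OneHotSequence")) ohMatrix(m) else m
    m * NaN
  }
  if (is.list(x)) lapply(x, bad) else bad(x)
})
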