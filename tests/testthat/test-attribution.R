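test_that("gradient-times-input reproduces the linear Taylor decomposition", {
  lmod <- randomLinearModel(21, 12)
  x <- oneHotEncode(randomSeq(12))
  b <- gradInputBackend()
  C <- importanceMatrix(b, lmod, x)
  expect_identical(importanceScores(C), lmod@weights * ohMatrix(x))
  ## exactly three zeros per column on one-hot input
  expect_true(all(colSums(importanceScores(C) == 0) >= 3))
  expect_equal(backendCalls(b), 1L)
})

test_that("non-finite gradients violate the backend contract", {
  x <- oneHotEncode(randomSeq(8))
  expect_error(importanceMatrix(gradInputBackend(), brokenModel(), x),
    class = "dfimContractError")
})

test_that("reference backend is exact for linear models, any step count", {
  lmod <- randomLinearModel(22, 16)
  x <- oneHotEncode(randomSeq(16))
  for (m in c(5L, 50L)) {
    b <- refDiffBackend(nReferences = 4, nSteps = m, shuffleSeed = 3)
    C <- importanceScores(importanceMatrix(b, lmod, x))
    ## references regenerate identically from the seed stream
    refs <- lapply(1:4, function(k) ohMatrix(oneHotEncode(
      dinucleotideShuffle(oneHotDecode(x), seed = 3 + k - 1))))
    meanRef <- Reduce(`+`, refs) / 4
    expect_equal(C, lmod@weights * (ohMatrix(x) - meanRef), tolerance = 1e-12)
  }
})

test_that("a reference equal to the input gives an all-zero matrix", {
  ## every dinucleotide shuffle of a homopolymer is the sequence itself
  x <- oneHotEncode("AAAAAAAA")
  b <- refDiffBackend(nReferences = 1, nSteps = 10, shuffleSeed = 1)
  C <- importanceScores(importanceMatrix(b, randomConvModel(30), x))
  expect_true(all(C == 0))
})

test_that("fixed-GC reference has the documented composition", {
  ref <- dfim:::.fixed_gc_reference(6, 0.46)
  expect_equal(unname(ref[, 1]), c(0.27, 0.23, 0.23, 0.27))
  expect_equal(colSums(ref), rep(1, 6))
  b <- refDiffBackend(mode = "fixed_gc", fGC = 0.46, nSteps = 20)
  x <- oneHotEncode(randomSeq(20))
  C <- importanceMatrix(b, randomConvModel(31), x)
  expect_true(all(is.finite(importanceScores(C))))
})

test_that("the path-integral completeness gap shrinks with more steps", {
  cnn <- randomConvModel(33)
  x <- oneHotEncode(randomSeq(40))
  gap <- function(m) {
    b <- refDiffBackend(nReferences = 3, nSteps = m, shuffleSeed = 5)
    C <- importanceScores(importanceMatrix(b, cnn, x))
    refs <- lapply(1:3, function(k) ohMatrix(oneHotEncode(
      dinucleotideShuffle(oneHotDecode(x), seed = 5 + k - 1))))
    yref <- mean(vapply(refs, function(r) modelPredict(cnn, r), numeric(1)))
    abs(sum(C) - (modelPredict(cnn, x) - yref))
  }
  expect_lt(gap(200), gap(20) + 1e-12)
})

test_that("locus importance sums the observed entries", {
  sc <- matrix(0, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  x <- oneHotEncode("ACGTACGT")
  sc[cbind(dfim:::.observed_rows(ohMatrix(x)), 1:8)] <- 0.5
  C <- new("ImportanceMatrix", scores = sc, sequenceId = "s",
    backend = "gradInput", referenceSpec = list())
  expect_equal(importanceOfLocus(C, featureLocus(3, "G")), 0.5)
  expect_equal(importanceOfLocus(C, featureLocus(2:5, "CGTA")), 2.0)
  expect_error(importanceOfLocus(C, featureLocus(7:10, "GTAC")), "out of range")
})

test_that("plug-in backends register and count like built-ins", {
  registerImportanceBackend("toy_unit", function(model, x) x * 2)
  b <- customBackend("toy_unit")
  x <- oneHotEncode("ACGT")
  C <- importanceMatrix(b, randomConvModel(1), x)
  expect_equal(importanceScores(C), ohMatrix(x) * 2)
  expect_equal(backendCalls(b), 1L)
  expect_error(customBackend("never_registered"), "no registered backend")
})
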