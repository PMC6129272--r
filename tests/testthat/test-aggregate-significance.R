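## helper: minimal single-nucleotide record table
rec <- function(id, sPos, sBase, mut, tPos, tBase, score,
    backend = "gradInput") {
  data.table::data.table(sequence_id = id, source_start = sPos,
    source_end = sPos, source_bases = sBase, mutant = mut,
    target_start = tPos, target_end = tPos, target_bases = tBase,
    score = score, abs_score = abs(score), backend = backend)
}

test_that("aggregation averages within identical feature contexts", {
  r <- rbind(
    rec("s1", 2, "A", "C", 5, "G", 0.2),
    rec("s2", 2, "A", "C", 5, "G", 0.4),
    rec("s3", 2, "T", "C", 5, "G", 9))   # different source base: own cell
  agg <- aggregateFis(r, statistic = "mean")
  cell <- agg[agg$source_base == "A", ]
  expect_equal(cell$value, 0.3)
  expect_equal(cell$n, 2L)
  expect_equal(agg[agg$source_base == "T", ]$n, 1L)
  ## mean |FIS| differs from mean FIS on sign-mixed scores
  r2 <- rbind(rec("a", 1, "A", "C", 3, "T", -0.5),
    rec("b", 1, "A", "C", 3, "T", 0.5))
  expect_equal(aggregateFis(r2, "mean")$value, 0)
  expect_equal(aggregateFis(r2, "meanAbs")$value, 0.5)
  ## mixed backends are rejected
  r3 <- rbind(rec("a", 1, "A", "C", 3, "T", 1),
    rec("b", 1, "A", "C", 3, "T", 1, backend = "refDiff"))
  expect_error(aggregateFis(r3), "mix")
})

test_that("marginalised map takes the max over mutants and flags empty cells", {
  ## single context, three mutants: marginalisation = max of per-mutant means
  r <- rbind(
    rec("s1", 1, "A", "C", 2, "G", 0.1),
    rec("s1", 1, "A", "G", 2, "G", -0.7),
    rec("s1", 1, "A", "T", 2, "G", 0.3))
  mp <- marginalizedAggregateMap(r)
  expect_s4_class(mp, "AggregateMap")
  expect_equal(mp@values["1:A", "2:G"], 0.7)   # abs of the G mutant
  expect_equal(mp@counts["1:A", "2:G"], 1L)
  ## unmatched contexts are NA with count 0
  expect_true(is.na(mp@values["1:C", "2:G"]))
  expect_equal(mp@counts["1:C", "2:G"], 0L)
  ## all-zero scores give an all-zero (populated) map
  rz <- rbind(rec("s1", 1, "A", "C", 2, "G", 0),
    rec("s1", 2, "G", "A", 1, "A", 0))
  mz <- marginalizedAggregateMap(rz)
  expect_true(all(mz@values[!is.na(mz@values)] == 0))
  top <- topAggregateCell(mp)
  expect_identical(top$source, "1:A")
  expect_identical(top$target, "2:G")
})

test_that("interaction maps round-trip through TSV", {
  r <- rbind(rec("s1", 1, "A", "C", 2, "G", 0.25),
    rec("s1", 2, "G", "A", 1, "A", -0.5))
  mp <- marginalizedAggregateMap(r)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeInteractionMap(mp, f)
  back <- readInteractionMap(f)
  expect_equal(back, mp@values)
})

test_that("Gaussian null fit recovers known parameters and rejects degeneracy", {
  set.seed(91)
  z <- rnorm(1e5)
  nm <- fitNullModel(z)
  expect_lt(abs(nm@mu - 0), 0.01)
  expect_lt(abs(nm@sigma - 1), 0.01)
  expect_equal(nm@nNull, 100000L)
  expect_error(fitNullModel(rep(0, 5000)), "degenerate")
  expect_error(fitNullModel(rnorm(10)), "at least")
})

test_that("two-sided p-values and BH q-values follow the definitions", {
  nm <- new("NullModel", mu = 0, sigma = 1, nNull = 1000L)
  r <- rec("s", 1, "A", "C", 2, "G", 1.959964)
  ann <- fisSignificance(r, nm)
  expect_equal(ann$p, 0.05, tolerance = 1e-3)
  ## score at the null mean: p = 1, never significant
  ann0 <- fisSignificance(rec("s", 1, "A", "C", 2, "G", 0), nm)
  expect_equal(ann0$p, 1)
  expect_false(ann0$significant)
  ## BH step-up on a hand-computed list
  rr <- do.call(rbind, lapply(1:4, function(i)
    rec("s", i, "A", "C", i + 4, "G", 0)))
  rr$score <- -qnorm(c(0.01, 0.02, 0.03, 0.04) / 2)   # p = .01 .02 .03 .04
  ann4 <- fisSignificance(rr, nm)
  expect_equal(ann4$q, rep(0.04, 4), tolerance = 1e-12)
  expect_error(fisSignificance(rr[0, ], nm), "empty")
})

test_that("q-values are monotone in sorted p, bounded, and at least p", {
  nm <- new("NullModel", mu = 0, sigma = 1, nNull = 1000L)
  set.seed(92)
  rr <- do.call(rbind, lapply(1:200, function(i)
    rec("s", i, "A", "C", i + 300, "G", rnorm(1, 0, 2))))
  ann <- fisSignificance(rr, nm)
  o <- order(ann$p)
  expect_true(all(diff(ann$q[o]) >= -1e-15))
  expect_true(all(ann$q >= ann$p - 1e-15))
  expect_true(all(ann$q >= 0 & ann$q <= 1))
})

test_that("the realised false-positive rate under the null is calibrated", {
  set.seed(93)
  nm <- fitNullModel(rnorm(2e4, 0.3, 0.8))
  draws <- rnorm(1e4, nm@mu, nm@sigma)
  p <- 2 * pnorm(-abs(draws - nm@mu) / nm@sigma)
  fpr <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / 1e4)
  expect_lte(fpr, 0.05 + 3 * se)
})

test_that("buildNull pools shuffled-sequence FIS and errors on degenerate nulls", {
  cnn <- randomConvModel(94)
  xs <- lapply(1:2, function(i) oneHotEncode(randomSeq(30), id = paste0("s", i)))
  b <- gradInputBackend()
  nm <- buildNull(cnn, b, xs, nShuffles = 2, seed = 5,
    scope = list(type = "nucleotide", nSources = 5), minN = 100L)
  expect_s4_class(nm, "NullModel")
  expect_gt(nm@sigma, 0)
  expect_gte(nm@nNull, 100L)
  ## reproducible from the seed
  b2 <- gradInputBackend()
  nm2 <- buildNull(cnn, b2, xs, nShuffles = 2, seed = 5,
    scope = list(type = "nucleotide", nSources = 5), minN = 100L)
  expect_identical(c(nm@mu, nm@sigma), c(nm2@mu, nm2@sigma))
  ## a linear model's null FIS is identically zero: degenerate sigma
  lmod <- randomLinearModel(95, 30)
  expect_error(
    buildNull(lmod, gradInputBackend(), xs, nShuffles = 2, seed = 5,
      scope = list(type = "nucleotide", nSources = 5), minN = 100L),
    "degenerate")
})
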