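test_that("point mutation changes exactly one column and is pure", {
  x <- oneHotEncode("ACGT")
  before <- ohMatrix(x)
  y <- applyPointMutation(x, 1, "C")
  expect_identical(oneHotDecode(y), "CCGT")
  expect_identical(ohMatrix(x), before)               # input untouched
  expect_identical(ohMatrix(y)[, 2:4], before[, 2:4]) # other columns bit-identical
  ## involution: mutating back restores the original exactly
  z <- applyPointMutation(y, 1, "A")
  expect_identical(ohMatrix(z), before)
  ## order independence at two distinct positions
  ab <- applyPointMutation(applyPointMutation(x, 1, "G"), 3, "T")
  ba <- applyPointMutation(applyPointMutation(x, 3, "T"), 1, "G")
  expect_identical(ohMatrix(ab), ohMatrix(ba))
  expect_error(applyPointMutation(x, 5, "A"), "out of range")
  expect_error(applyPointMutation(x, 2, "C"), "must differ")
})

test_that("GC-background mutation sets the documented composition", {
  x <- oneHotEncode("ACGTACGT")
  y <- applyBackgroundMutation(x, 3L, fGC = 0.46)
  expect_equal(unname(ohMatrix(y)[, 3]), c(0.27, 0.23, 0.23, 0.27))
  expect_equal(sum(ohMatrix(y)[c("C", "G"), 3]), 0.46)
  expect_identical(ohMatrix(y)[, -3], ohMatrix(x)[, -3])
  u <- applyBackgroundMutation(x, 2:5, fGC = 0.5)
  expect_true(all(ohMatrix(u)[, 2:5] == 0.25))
  expect_equal(colSums(ohMatrix(u)), rep(1, 8))
  expect_identical(ohMatrix(x), ohMatrix(oneHotEncode("ACGTACGT")))  # pure
  expect_error(applyBackgroundMutation(x, integer(0), 0.4), "at least one")
  expect_error(applyBackgroundMutation(x, 1:2, 1.2), "fGC")
})

test_that("dinucleotide shuffle preserves the 16-count table and endpoints", {
  expect_identical(dinucleotideShuffle("AAAA", seed = 1), "AAAA")
  set.seed(42)
  for (i in 1:50) {
    s <- randomSeq(sample(10:120, 1))
    sh <- dinucleotideShuffle(s)
    expect_identical(dinucleotideCounts(sh), dinucleotideCounts(s))
    expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
    L <- nchar(s)
    expect_identical(substr(sh, L, L), substr(s, L, L))
  }
})

test_that("shuffling explores exactly the brute-force enumerable arrangements", {
  ## brute-force oracle: all permutations (first character fixed by the
  ## algorithm's endpoint guarantee) with an identical dinucleotide table
  bruteArrangements <- function(s) {
    ch <- strsplit(s, "")[[1]]
    tab <- function(x) paste(sort(paste0(x[-length(x)], x[-1])), collapse = ",")
    target <- tab(ch)
    found <- character(0)
    rec <- function(prefix, remaining) {
      if (!length(remaining)) {
        if (tab(prefix) == target)
          found <<- union(found, paste(prefix, collapse = ""))
        return(invisible())
      }
      for (u in unique(remaining))
        rec(c(prefix, u), remaining[-match(u, remaining)])
    }
    rec(ch[1], sort(ch[-1]))
    found
  }
  s <- "AACAGTAC"
  valid <- bruteArrangements(s)     # 6 arrangements for this string
  expect_gte(length(valid), 2L)
  outs <- unique(vapply(1:500, function(k) dinucleotideShuffle(s, seed = k),
    character(1)))
  expect_gte(length(outs), 2L)
  expect_true(all(outs %in% valid))
  ## a sequence whose dinucleotide table forces a unique walk shuffles to
  ## itself: every A is followed by C, every C by G, every G by T
  rigid <- "ACGTACGTACGT"
  expect_identical(bruteArrangements(rigid), rigid)
  for (k in 1:20) expect_identical(dinucleotideShuffle(rigid, seed = k), rigid)
})

test_that("a given seed makes the shuffle reproducible without touching the RNG", {
  s <- randomSeq(60)
  a <- dinucleotideShuffle(s, seed = 7)
  set.seed(99)
  before <- .Random.seed
  b <- dinucleotideShuffle(s, seed = 7)
  expect_identical(.Random.seed, before)
  expect_identical(a, b)
})
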