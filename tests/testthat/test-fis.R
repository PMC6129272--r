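test_that("every interaction score is exactly zero on a linear model", {
  set.seed(51)
  L <- 25L
  lmod <- dyadicLinearModel(52, L)
  x <- oneHotEncode(randomSeq(L))
  b <- gradInputBackend()
  C0 <- importanceMatrix(b, lmod, x)
  obs <- strsplit(oneHotDecode(x), "")[[1]]
  for (i in 1:40) {
    s <- sample(L, 1)
    t <- sample(setdiff(seq_len(L), s), 1)
    g <- sample(setdiff(c("A", "C", "G", "T"), obs[s]), 1)
    expect_identical(fisNucleotide(lmod, b, x, s, g, t, C0 = C0), 0)
    src <- featureLocus(s, obs[s])
    tgt <- featureLocus(t, obs[t])
    expect_identical(pairwiseIsmInteraction(lmod, x,
      list(locus = src, mutant = g),
      list(locus = tgt, mutant = setdiff(c("A", "C", "G", "T"), obs[t])[1])), 0)
  }
  ## motif-resolution scores vanish too
  tgtm <- featureLocus(10:13, paste(obs[10:13], collapse = ""))
  expect_identical(fisMotifTarget(lmod, b, x, 2, setdiff(c("A","C","G","T"),
    obs[2])[1], tgtm, C0 = C0), 0)
  srcm <- featureLocus(18:21, paste(obs[18:21], collapse = ""))
  expect_identical(fisMotifMotif(lmod, b, x, srcm, tgtm, fGC = 0.46, C0 = C0), 0)
  ## and the whole map is zero off the masked diagonal
  mp <- dfimMap(lmod, gradInputBackend(), x)
  expect_true(all(mp@scores[!is.na(mp@scores)] == 0))
  expect_true(all(is.na(diag(mp@scores))))
})

test_that("the product toy model gives the hand-computed scores", {
  toy <- productToyModel()
  x <- oneHotEncode("AA")
  b <- gradInputBackend()
  ## C_X0[A,2] = 1; after A1 -> C, gradient at [A,2] is 0: FIS = 1 - 0 = 1
  expect_equal(fisNucleotide(toy, b, x, 1, "C", 2), 1)
  ## ISM(joint) = 1, ISM(source) = ISM(target) = 1: interaction = 1 - 2 = -1
  expect_equal(pairwiseIsmInteraction(toy, x,
    list(locus = featureLocus(1, "A"), mutant = "C"),
    list(locus = featureLocus(2, "A"), mutant = "C")), -1)
})

test_that("engine FIS equals the definitional two-call oracle, bit-exactly", {
  set.seed(61)
  hits <- 0L
  for (case in 1:100) {
    L <- sample(12:30, 1)
    cnn <- randomConvModel(600 + case, nFilters = 6L, w = 5L, nHidden = 8L)
    s0 <- randomSeq(L)
    x <- oneHotEncode(s0)
    obs <- strsplit(s0, "")[[1]]
    s <- sample(L, 1)
    t <- sample(setdiff(seq_len(L), s), 1)
    g <- sample(setdiff(c("A", "C", "G", "T"), obs[s]), 1)
    b <- gradInputBackend()
    engine <- fisNucleotide(cnn, b, x, s, g, t)
    ## oracle: build the mutant by string surgery, score both sequences
    ## independently, subtract the observed-target entries
    ms <- obs; ms[s] <- g
    x1 <- oneHotEncode(paste(ms, collapse = ""))
    ob <- gradInputBackend()
    c0 <- importanceScores(importanceMatrix(ob, cnn, x))
    c1 <- importanceScores(importanceMatrix(ob, cnn, x1))
    oracle <- unname(c0[obs[t], t] - c1[obs[t], t])
    expect_identical(engine, oracle)
    if (engine != 0) hits <- hits + 1L
  }
  expect_gt(hits, 10L)   # the cases genuinely exercise non-zero interactions
})

test_that("fis profiles match per-target calls and cost at most 2 evaluations", {
  cnn <- randomConvModel(70)
  L <- 18L
  set.seed(700)
  x <- oneHotEncode(randomSeq(L))
  b <- gradInputBackend()
  obs <- strsplit(oneHotDecode(x), "")[[1]]
  g4 <- setdiff(c("A", "C", "G", "T"), obs[4])[2]
  D <- fisProfile(cnn, b, x, 4, g4)
  expect_equal(backendCalls(b), 2L)
  C0 <- importanceMatrix(b, cnn, x)
  for (t in setdiff(seq_len(L), 4L))
    expect_identical(unname(D[obs[t], t]),
      fisNucleotide(cnn, b, x, 4, g4, t, C0 = C0))
  expect_true(all(is.na(D[, 4])))
  ## cached C0 drops the cost to one evaluation per profile
  b2 <- gradInputBackend()
  C0b <- importanceMatrix(b2, cnn, x)
  fisProfile(cnn, b2, x, 4, g4, C0 = C0b)
  expect_equal(backendCalls(b2), 2L)
})

test_that("maxFis policies select the documented mutant and break ties alphabetically", {
  cnn <- randomConvModel(71)
  L <- 16L
  x <- oneHotEncode(randomSeq(L))
  b <- gradInputBackend()
  obs <- strsplit(oneHotDecode(x), "")[[1]]
  C0 <- importanceMatrix(b, cnn, x)
  s <- 3L; t <- 9L
  cand <- setdiff(c("A", "C", "G", "T"), obs[s])
  vals <- vapply(cand, function(g)
    fisNucleotide(cnn, b, x, s, g, t, C0 = C0), numeric(1))
  sg <- maxFis(cnn, b, x, s, t, policy = "signed", C0 = C0)
  expect_identical(sg$score, unname(vals[which.max(vals)]))
  expect_identical(sg$mutant, cand[which.max(vals)])
  ab <- maxFis(cnn, b, x, s, t, policy = "abs", C0 = C0)
  expect_identical(ab$score, unname(vals[which.max(abs(vals))]))
  ## signed max dominates every per-mutant score
  expect_true(all(sg$score >= vals))
  ## alphabetical tie-break on the all-zero linear fixture
  lmod <- randomLinearModel(72, L)
  lz <- maxFis(lmod, gradInputBackend(), x, 1, 5, policy = "signed")
  expect_identical(lz$mutant, setdiff(c("A", "C", "G", "T"), obs[1])[1])
  expect_identical(lz$score, 0)
})

test_that("interaction maps are consistent, directional and cost 3L + 1", {
  cnn <- randomConvModel(73)
  L <- 14L
  x <- oneHotEncode(randomSeq(L))
  b <- gradInputBackend()
  mp <- dfimMap(cnn, b, x, policy = "abs")
  expect_equal(backendCalls(b), 3L * L + 1L)
  expect_true(all(is.na(diag(mp@scores))))
  ## row s equals the per-target abs-max over the three mutant profiles
  obs <- strsplit(oneHotDecode(x), "")[[1]]
  b2 <- gradInputBackend()
  C0 <- importanceMatrix(b2, cnn, x)
  for (s in c(2L, 7L)) {
    cand <- setdiff(c("A", "C", "G", "T"), obs[s])
    vals <- sapply(cand, function(g) {
      D <- fisProfile(cnn, b2, x, s, g, C0 = C0)
      D[cbind(match(obs, c("A", "C", "G", "T")), seq_len(L))]
    })
    expected <- vapply(seq_len(L), function(t) {
      if (t == s) return(NA_real_)
      v <- vals[t, ]
      v[[which.max(abs(v))]]
    }, numeric(1))
    expect_equal(unname(mp@scores[s, ]), expected)
  }
  ## no symmetrisation: FIS(t|s) and FIS(s|t) generally differ
  off <- abs(mp@scores - t(mp@scores))
  expect_gt(max(off, na.rm = TRUE), 0)
})

test_that("motif-target FIS is the sum of per-position nucleotide FIS", {
  toy <- randomConvModel(74)
  L <- 20L
  x <- oneHotEncode(randomSeq(L))
  obs <- strsplit(oneHotDecode(x), "")[[1]]
  b <- gradInputBackend()
  C0 <- importanceMatrix(b, toy, x)
  tgt <- featureLocus(8:10, paste(obs[8:10], collapse = ""))
  whole <- fisMotifTarget(toy, b, x, 2, "G", tgt, C0 = C0)
  parts <- sum(vapply(8:10, function(t)
    fisNucleotide(toy, b, x, 2, "G", t, C0 = C0), numeric(1)))
  expect_identical(whole, parts)
  expect_error(fisMotifTarget(toy, b, x, 9, "G", tgt), "inside the target")
  ## product toy, 3-mer target vs two-call oracle
  ptoy <- productToyModel()
  px <- oneHotEncode("AAAA")
  ptgt <- featureLocus(2:4, "AAA")
  eng <- fisMotifTarget(ptoy, gradInputBackend(), px, 1, "C", ptgt)
  ob <- gradInputBackend()
  c0 <- importanceScores(importanceMatrix(ob, ptoy, px))
  c1 <- importanceScores(importanceMatrix(ob, ptoy, oneHotEncode("CAAA")))
  idx <- cbind(rep(1L, 3), 2:4)
  expect_identical(eng, sum(c0[idx]) - sum(c1[idx]))
})

test_that("motif-motif FIS uses one background mutant and two evaluations", {
  cnn <- randomConvModel(75)
  L <- 24L
  x <- oneHotEncode(randomSeq(L))
  obs <- strsplit(oneHotDecode(x), "")[[1]]
  src <- featureLocus(3:6, paste(obs[3:6], collapse = ""))
  tgt <- featureLocus(15:18, paste(obs[15:18], collapse = ""))
  b <- gradInputBackend()
  sc <- fisMotifMotif(cnn, b, x, src, tgt, fGC = 0.46)
  expect_equal(backendCalls(b), 2L)
  ## consistency with explicit importance sums on both matrices
  b2 <- gradInputBackend()
  C0 <- importanceMatrix(b2, cnn, x)
  C1 <- importanceMatrix(b2, cnn, applyBackgroundMutation(x, src, 0.46))
  expect_identical(sc,
    importanceOfLocus(C0, tgt) - importanceOfLocus(C1, tgt))
  overlap <- featureLocus(5:9, paste(obs[5:9], collapse = ""))
  expect_error(fisMotifMotif(cnn, b, x, src, overlap, fGC = 0.46), "overlap")
})

test_that("pairwise ISM interaction is symmetric and magnitude-matches FIS on the toy", {
  cnn <- randomConvModel(76)
  L <- 20L
  set.seed(77)
  for (i in 1:20) {
    x <- oneHotEncode(randomSeq(L))
    obs <- strsplit(oneHotDecode(x), "")[[1]]
    s <- sample(L, 1); t <- sample(setdiff(seq_len(L), s), 1)
    a <- list(locus = featureLocus(s, obs[s]),
      mutant = sample(setdiff(c("A", "C", "G", "T"), obs[s]), 1))
    bsp <- list(locus = featureLocus(t, obs[t]),
      mutant = sample(setdiff(c("A", "C", "G", "T"), obs[t]), 1))
    expect_identical(pairwiseIsmInteraction(cnn, x, a, bsp),
      pairwiseIsmInteraction(cnn, x, bsp, a))
  }
  toy <- productToyModel()
  px <- oneHotEncode("AA")
  fis <- fisNucleotide(toy, gradInputBackend(), px, 1, "C", 2)
  ism <- pairwiseIsmInteraction(toy, px,
    list(locus = featureLocus(1, "A"), mutant = "C"),
    list(locus = featureLocus(2, "A"), mutant = "C"))
  expect_equal(abs(fis), abs(ism))
  expect_error(pairwiseIsmInteraction(toy, px,
    list(locus = featureLocus(1, "A"), mutant = "C"),
    list(locus = featureLocus(1, "A"), mutant = "G")), "overlap")
})

test_that("pre-specified sources cost F + 1 evaluations", {
  cnn <- randomConvModel(78)
  L <- 40L
  x <- oneHotEncode(randomSeq(L))
  obs <- strsplit(oneHotDecode(x), "")[[1]]
  spans <- list(1:4, 9:12, 17:20, 25:28, 33:36)
  loci <- lapply(spans, function(p)
    featureLocus(p, paste(obs[p], collapse = "")))
  sources <- lapply(loci, function(l) list(locus = l, fGC = 0.46))
  b <- gradInputBackend()
  recs <- fisForSources(cnn, b, x, sources, loci)
  expect_equal(backendCalls(b), length(sources) + 1L)
  ## 5 sources x 4 non-overlapping targets each
  expect_equal(nrow(recs), 20L)
  expect_true(all(recs$abs_score == abs(recs$score)))
})

test_that("self-interaction and same-base mutants are rejected", {
  cnn <- randomConvModel(79)
  x <- oneHotEncode(randomSeq(10))
  b <- gradInputBackend()
  expect_error(fisNucleotide(cnn, b, x, 3, "A", 3), "undefined")
  obs <- substr(oneHotDecode(x), 2, 2)
  expect_error(fisNucleotide(cnn, b, x, 2, obs, 5), "must differ")
})
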