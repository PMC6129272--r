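## Motif-flank library emulation: short fixed-length sequences (the
## variable nucleotides flanking a fixed core binding site) with a
## real-valued response generated from a planted mono- plus dinucleotide
## energy function, and a dense regressor trained on them. Used to show
## that the marginalised aggregate interaction map recovers a planted
## pairwise energy term.

#' Energy specification for the flank library
#'
#' Mononucleotide energies are a fixed 4 x (2 * flankLen) coefficient
#' matrix (drawn once from N(0, 0.3) under an internal fixed seed, so the
#' spec is a constant of the package); the planted interaction is a single
#' strong pairwise term between T at flank position -1 and A at +1
#' (coefficient 1.5, i.e. 5 standard deviations of the mononucleotide
#' coefficients).
#'
#' @param flankLen flank length per side (default 5).
#' @param planted include the pairwise term (set FALSE for a purely
#'   additive, interaction-free energy).
#' @param pairCoef coefficient of the planted pair.
#' @return list(mono, pairs, posLabels).
#' @export
flankEnergySpec <- function(flankLen = 5L, planted = TRUE, pairCoef = 1.5) {
  P <- 2L * flankLen
  mono <- .with_seed(104729L, function()
    matrix(rnorm(4L * P, 0, 0.3), 4L, P, dimnames = list(.BASES, NULL)))
  posLabels <- c(paste0("-", flankLen:1), paste0("+", 1:flankLen))
  pairs <- if (planted)
    data.frame(sPos = flankLen, sBase = "T", tPos = flankLen + 1L,
      tBase = "A", coef = pairCoef, stringsAsFactors = FALSE)
  else
    data.frame(sPos = integer(), sBase = character(), tPos = integer(),
      tBase = character(), coef = numeric(), stringsAsFactors = FALSE)
  list(mono = mono, pairs = pairs, posLabels = posLabels)
}

#' Simulate a motif-flank library with a planted pairwise energy
#'
#' Random uniform flank sequences of length `2 * flankLen` with responses
#' `energy(sequence) + N(0, noiseSd)`; the energy is the sum of the
#' mononucleotide terms plus any pairwise terms of the spec. Identical
#' seeds reproduce responses bit-exactly.
#'
#' @param n number of sequences.
#' @param flankLen flank length per side.
#' @param energySpec a [flankEnergySpec()] list.
#' @param noiseSd response noise standard deviation.
#' @param seed integer seed.
#' @return list(sequences, responses, spec, posLabels).
#' @export
simulateFlankLibrary <- function(n = 5000L, flankLen = 5L,
    energySpec = flankEnergySpec(flankLen), noiseSd = 0.1, seed = 1L) {
  P <- 2L * flankLen
  .with_seed(seed, function() {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(.BASES, P, replace = TRUE), collapse = ""), character(1))
    names(seqs) <- sprintf("flank_%05d", seq_len(n))
    resp <- vapply(seqs, function(s) {
      chars <- strsplit(s, "", fixed = TRUE)[[1L]]
      e <- sum(energySpec$mono[cbind(match(chars, .BASES), seq_len(P))])
      pr <- energySpec$pairs
      for (j in seq_len(nrow(pr)))
        if (chars[pr$sPos[j]] == pr$sBase[j] && chars[pr$tPos[j]] == pr$tBase[j])
          e <- e + pr$coef[j]
      e
    }, numeric(1))
    resp <- resp + rnorm(n, 0, noiseSd)
    list(sequences = seqs, responses = unname(resp), spec = energySpec,
      posLabels = energySpec$posLabels)
  })
}

#' Train the dense flank-library regressor
#'
#' Multilayer perceptron on the flattened one-hot flanks (ReLU hidden
#' layers, linear output), trained with Adam on mean squared error. The
#' validation R^2 must clear `r2Gate`: interaction maps read off a poorly
#' fitted model are not meaningful.
#'
#' @param library a [simulateFlankLibrary()] result.
#' @param hidden hidden layer sizes (default c(64, 32)).
#' @param lr Adam learning rate. @param epochs training epochs.
#' @param batchSize minibatch size. @param valFraction held-out fraction.
#' @param r2Gate minimum validation R^2 (default 0.9).
#' @param seed integer seed.
#' @return a [DenseSequenceModel-class] with per-epoch trainingLog.
#' @export
trainFlankModel <- function(library, hidden = c(64L, 32L), lr = 0.003,
    epochs = 120L, batchSize = 64L, valFraction = 0.1, r2Gate = 0.9,
    seed = 1L) {
  P <- nchar(library$sequences[[1L]])
  n <- length(library$sequences)
  X <- matrix(0, 4L * P, n)
  for (i in seq_len(n))
    X[, i] <- as.vector(ohMatrix(oneHotEncode(library$sequences[[i]])))
  yresp <- library$responses
  .with_seed(seed, function() {
    valIdx <- sort(sample.int(n, max(1L, round(valFraction * n))))
    trIdx <- setdiff(seq_len(n), valIdx)
    sizes <- c(4L * P, hidden, 1L)
    nl <- length(sizes) - 1L
    p <- list(W = vector("list", nl), b = vector("list", nl))
    for (k in seq_len(nl)) {
      p$W[[k]] <- matrix(rnorm(sizes[k + 1L] * sizes[k], 0,
        sqrt(2 / sizes[k])), sizes[k + 1L], sizes[k])
      p$b[[k]] <- rep(0, sizes[k + 1L])
    }
    m <- .zero_like(p)
    v <- .zero_like(p)
    tstep <- 0L
    log <- list()
    for (epoch in seq_len(epochs)) {
      ord <- sample(trIdx)
      eloss <- 0
      nb <- 0L
      for (b in split(ord, ceiling(seq_along(ord) / batchSize))) {
        tstep <- tstep + 1L
        g <- .mlp_param_grad(p, X[, b, drop = FALSE], yresp[b], task = 1L)
        upd <- .adam_update(p, g$grads, m, v, tstep, lr)
        p <- upd$p
        m <- upd$m
        v <- upd$v
        eloss <- eloss + g$loss
        nb <- nb + 1L
      }
      yhat <- .mlp_forward(p, X[, valIdx, drop = FALSE])$Y[1L, ]
      r2 <- 1 - mean((yhat - yresp[valIdx])^2) /
        mean((yresp[valIdx] - mean(yresp[valIdx]))^2)
      log[[epoch]] <- data.frame(epoch = epoch, loss = eloss / nb, valR2 = r2)
    }
    tl <- do.call(rbind, log)
    finalR2 <- tl$valR2[nrow(tl)]
    if (finalR2 < r2Gate)
      .contract_error(sprintf(
        "validation R^2 %.3f below the %.2f gate; the regressor does not fit ",
        finalR2, r2Gate), "the library well enough to interpret")
    attr(tl, "valIndices") <- valIdx
    denseSequenceModel(p, inputDim = c(4L, P), taskIndex = 1L,
      trainingLog = tl)
  })
}

#' All-pairs FIS records across a flank library
#'
#' Runs [fisAllPairs()] on a (seeded) subsample of the library under the
#' given backend and concatenates the records; feed the result to
#' [marginalizedAggregateMap()] with the library's position labels.
#'
#' @param model a trained [DenseSequenceModel-class].
#' @param library a [simulateFlankLibrary()] result.
#' @param nSequences number of sequences to score (default 600).
#' @param backend attribution backend (default [gradInputBackend()]).
#' @param seed subsample seed.
#' @return a data.table of FIS records.
#' @export
flankFisRecords <- function(model, library, nSequences = 600L,
    backend = gradInputBackend(), seed = 1L) {
  n <- length(library$sequences)
  sel <- .with_seed(seed, function()
    if (n > nSequences) sort(sample.int(n, nSequences)) else seq_len(n))
  recs <- lapply(sel, function(i)
    fisAllPairs(model, backend,
      oneHotEncode(library$sequences[[i]], id = names(library$sequences)[i])))
  data.table::rbindlist(recs)
}
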