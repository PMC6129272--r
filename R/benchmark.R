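## Synthetic motif-interaction benchmark: random fixed-GC background
## sequences with planted transcription-factor consensus motifs, a binary
## label that is positive exactly when both ELF1 and SIX5 are present, and
## a small trainable CNN. The benchmark validates the interaction scorer,
## not the classifier: ELF1-SIX5 pairs are the only motif pairs whose
## interaction the model must learn, while AP1/TAL1 embeddings are
## label-irrelevant decoys.

#' Benchmark motif consensus strings
#'
#' Consensus approximations of the highest-affinity sequences of the
#' published ELF1, SIX5, AP1 and TAL1 position weight matrices. Shipped as
#' configuration data: the benchmark validates the interaction scorer, so
#' any fixed, mutually distinct strings serve.
#'
#' @return named character vector.
#' @export
benchmarkMotifs <- function() {
  c(ELF1 = "ACCCGGAAGT", SIX5 = "GTGTCAGGTT",
    AP1 = "TGACTCA", TAL1 = "AACAGATGGT")
}

## place motifs into a background string without overlap; rejection sampling
.place_motifs <- function(L, lens, maxTries = 1000L) {
  if (sum(lens) > L)
    .input_error("cannot place motifs of total length ", sum(lens),
      " in a sequence of length ", L, " without overlap")
  starts <- integer(length(lens))
  occupied <- logical(L)
  for (i in seq_along(lens)) {
    len <- lens[i]
    ok <- FALSE
    for (try in seq_len(maxTries)) {
      st <- sample.int(L - len + 1L, 1L)
      if (!any(occupied[st:(st + len - 1L)])) {
        starts[i] <- st
        occupied[st:(st + len - 1L)] <- TRUE
        ok <- TRUE
        break
      }
    }
    if (!ok)
      .input_error("could not place ", length(lens), " motifs of total length ",
        sum(lens), " in a sequence of length ", L, " without overlap")
  }
  starts
}

#' Simulate the three-set motif-interaction benchmark
#'
#' Generates `3 * nPerSet` random sequences with i.i.d. background
#' composition P(C) = P(G) = fGC / 2, P(A) = P(T) = (1 - fGC) / 2. Set 1
#' sequences carry 1 or 2 planted ELF1 consensus instances, Set 2 carries 1
#' or 2 SIX5 instances, and Set 3 (the positive class) carries 1 or 2 of
#' each. Independently, each sequence carries 0 or 1 AP1 and 0 or 1 TAL1
#' instance (probability `pAccessory` each) -- label-irrelevant decoys.
#' Embedding positions are uniform among placements keeping all planted
#' motifs non-overlapping; every planted span is recorded in the truth
#' table. Fully reproducible from `seed`.
#'
#' @param nPerSet sequences per set (benchmark default 2000; the original
#'   design uses 20000).
#' @param L sequence length (default 200).
#' @param fGC background G+C fraction (default 0.46).
#' @param motifs named motif consensus strings (default [benchmarkMotifs()]).
#' @param pAccessory probability of embedding each of AP1/TAL1.
#' @param seed integer seed.
#' @return a [BenchmarkDataset-class].
#' @export
simulateBenchmark <- function(nPerSet = 2000L, L = 200L, fGC = 0.46,
    motifs = benchmarkMotifs(), pAccessory = 0.5, seed = 1L) {
  if (fGC <= 0 || fGC >= 1) .input_error("fGC must be in (0, 1)")
  need <- c("ELF1", "SIX5", "AP1", "TAL1")
  if (!all(need %in% names(motifs)))
    .input_error("motifs must name ", paste(need, collapse = ", "))
  bgProb <- c((1 - fGC) / 2, fGC / 2, fGC / 2, (1 - fGC) / 2)
  .with_seed(seed, function() {
    n <- 3L * nPerSet
    seqs <- character(n)
    ids <- character(n)
    labels <- integer(n)
    truth <- vector("list", n)
    k <- 0L
    for (set in 1:3) {
      for (i in seq_len(nPerSet)) {
        k <- k + 1L
        ids[k] <- sprintf("set%d_%05d", set, i)
        labels[k] <- as.integer(set == 3L)
        plant <- character(0)
        if (set != 2L) plant <- c(plant, rep("ELF1", sample(1:2, 1L)))
        if (set != 1L) plant <- c(plant, rep("SIX5", sample(1:2, 1L)))
        if (runif(1) < pAccessory) plant <- c(plant, "AP1")
        if (runif(1) < pAccessory) plant <- c(plant, "TAL1")
        chars <- sample(.BASES, L, replace = TRUE, prob = bgProb)
        lens <- nchar(motifs[plant])
        starts <- .place_motifs(L, lens)
        for (j in seq_along(plant)) {
          mseq <- strsplit(motifs[[plant[j]]], "", fixed = TRUE)[[1L]]
          chars[starts[j]:(starts[j] + lens[j] - 1L)] <- mseq
        }
        seqs[k] <- paste(chars, collapse = "")
        truth[[k]] <- data.frame(sequence_id = ids[k], motif = plant,
          start = starts, end = starts + lens - 1L,
          stringsAsFactors = FALSE)
      }
    }
    names(seqs) <- ids
    new("BenchmarkDataset", sequences = seqs, labels = labels,
      truth = do.call(rbind, truth),
      config = list(nPerSet = nPerSet, L = L, fGC = fGC,
        motifs = as.list(motifs), pAccessory = pAccessory, seed = seed))
  })
}

setMethod("show", "BenchmarkDataset", function(object) {
  cat("BenchmarkDataset:", length(object@sequences), "sequences of length",
    object@config$L, "(", sum(object@labels), "positive );",
    nrow(object@truth), "planted motifs\n")
})

#' Empirical G+C fraction over background (non-planted) positions
#'
#' @param dataset a [BenchmarkDataset-class].
#' @return list(fraction, nPositions).
#' @export
backgroundGcFraction <- function(dataset) {
  gc <- 0
  tot <- 0
  truth <- dataset@truth
  for (id in names(dataset@sequences)) {
    chars <- strsplit(dataset@sequences[[id]], "", fixed = TRUE)[[1L]]
    keep <- rep(TRUE, length(chars))
    tr <- truth[truth$sequence_id == id, , drop = FALSE]
    for (j in seq_len(nrow(tr))) keep[tr$start[j]:tr$end[j]] <- FALSE
    bg <- chars[keep]
    gc <- gc + sum(bg %in% c("C", "G"))
    tot <- tot + length(bg)
  }
  list(fraction = gc / tot, nPositions = tot)
}

#' Export a benchmark dataset as FASTA plus labels and truth tables
#'
#' Writes `sequences.fa` (80-column wrap), `labels.tsv` and `truth.tsv`
#' (0-based half-open coordinates) into `dir`. Identical dataset and seed
#' produce byte-identical files.
#'
#' @param dataset a [BenchmarkDataset-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the file paths.
#' @export
exportBenchmark <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "sequences.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(dataset@sequences),
    filepath = fa, width = 80L)
  lab <- file.path(dir, "labels.tsv")
  data.table::fwrite(data.table::data.table(
    sequence_id = names(dataset@sequences), label = dataset@labels),
    lab, sep = "\t", quote = FALSE)
  tru <- file.path(dir, "truth.tsv")
  tt <- data.table::as.data.table(dataset@truth)
  tt$start <- tt$start - 1L    # 0-based half-open on disk
  data.table::fwrite(tt, tru, sep = "\t", quote = FALSE)
  invisible(c(fasta = fa, labels = lab, truth = tru))
}

#' Train the benchmark convolutional classifier
#'
#' One convolutional layer (ReLU), windowed max pooling, one ReLU dense
#' hidden layer and a linear logit, trained with Adam on binary
#' cross-entropy over a random 90/10 train/validation split. Training
#' stops once validation accuracy reaches `targetAccuracy`; a final best
#' validation accuracy below `accuracyGate` is an error, because
#' interaction scores are only meaningful for models that predict
#' essentially perfectly on this benchmark. Pooling is windowed (not
#' global) so that multiple instances of one motif remain separately
#' visible to the dense layer -- with global pooling a redundant second
#' instance is invisible and the network cannot represent its buffering.
#'
#' @param dataset a [BenchmarkDataset-class].
#' @param nFilters,filterWidth,nHidden architecture (defaults 16, 15, 32).
#' @param poolSize max-pooling window width over conv positions (default
#'   25); `Inf` gives global pooling, which generalises better on very
#'   small training sets at the cost of hiding redundant motif copies.
#' @param lr initial Adam learning rate. @param lrDecay per-epoch geometric
#'   learning-rate decay factor. @param weightDecay decoupled weight decay
#'   on the weight matrices (not biases); shrinks weights serving
#'   label-irrelevant sequence content toward zero.
#' @param batchSize minibatch size.
#' @param maxEpochs epoch budget. @param valFraction held-out fraction.
#' @param accuracyGate minimum acceptable validation accuracy (default
#'   0.95). @param targetAccuracy early-stopping accuracy (default 0.999).
#' @param seed integer seed controlling the split, initialisation and
#'   minibatch order; identical seeds give identical training curves.
#' @param verbose print per-epoch progress.
#' @return a [ConvSequenceModel-class]; `trainingLog` has per-epoch loss
#'   and validation accuracy, with the held-out indices as attribute
#'   `valIndices`.
#' @export
trainBenchmarkCnn <- function(dataset, nFilters = 16L, filterWidth = 15L,
    nHidden = 32L, poolSize = 25L, lr = 0.005, lrDecay = 0.97,
    weightDecay = 0.3, batchSize = 64L, maxEpochs = 90L,
    valFraction = 0.1, accuracyGate = 0.95, targetAccuracy = 0.999,
    seed = 1L, verbose = FALSE) {
  xs <- lapply(dataset@sequences, function(s) ohMatrix(oneHotEncode(s)))
  ylab <- dataset@labels
  n <- length(xs)
  P <- dataset@config$L - filterWidth + 1L
  nw <- length(.pool_windows(P, poolSize))
  .with_seed(seed, function() {
    valIdx <- sort(sample.int(n, max(1L, round(valFraction * n))))
    trIdx <- setdiff(seq_len(n), valIdx)
    p <- list(
      Wc = matrix(rnorm(nFilters * 4L * filterWidth, 0,
        sqrt(2 / (4 * filterWidth))), nFilters, 4L * filterWidth),
      bc = rep(0, nFilters),
      Wh = matrix(rnorm(nHidden * nFilters * nw, 0, sqrt(2 / (nFilters * nw))),
        nHidden, nFilters * nw),
      bh = rep(0, nHidden),
      Wo = matrix(rnorm(nHidden, 0, sqrt(1 / nHidden)), 1L, nHidden),
      bo = 0,
      w = as.integer(filterWidth),
      pool = if (is.finite(poolSize)) as.integer(poolSize) else Inf)
  trainable <- c("Wc", "bc", "Wh", "bh", "Wo", "bo")
    m <- .zero_like(p[trainable])
    v <- .zero_like(p[trainable])
    tstep <- 0L
    log <- list()
    valAcc <- 0
    for (epoch in seq_len(maxEpochs)) {
      ord <- sample(trIdx)
      eloss <- 0
      nb <- 0L
      lrE <- lr * lrDecay^(epoch - 1L)
      for (b in split(ord, ceiling(seq_along(ord) / batchSize))) {
        tstep <- tstep + 1L
        g <- .cnn_param_grad(p, xs[b], ylab[b], task = 1L)
        upd <- .adam_update(p[trainable], g$grads, m, v, tstep, lrE)
        p[trainable] <- upd$p
        m <- upd$m
        v <- upd$v
        if (weightDecay > 0)
          for (nm in c("Wc", "Wh", "Wo"))
            p[[nm]] <- p[[nm]] * (1 - lrE * weightDecay)
        eloss <- eloss + g$loss
        nb <- nb + 1L
      }
      valAcc <- .cnn_accuracy(p, xs, ylab, valIdx)
      log[[epoch]] <- data.frame(epoch = epoch, loss = eloss / nb,
        valAccuracy = valAcc)
      if (verbose)
        message(sprintf("epoch %d: loss %.4f, val accuracy %.4f",
          epoch, eloss / nb, valAcc))
      if (valAcc >= targetAccuracy) break
    }
    if (valAcc < accuracyGate)
      .contract_error(sprintf(
        "validation accuracy %.3f below the %.2f gate after %d epochs; ",
        valAcc, accuracyGate, length(log)),
        "interaction scores require a near-perfect benchmark model")
    tl <- do.call(rbind, log)
    attr(tl, "valIndices") <- valIdx
    convSequenceModel(p, taskIndex = 1L, trainingLog = tl)
  })
}

.cnn_accuracy <- function(p, xs, ylab, idx, chunk = 256L) {
  correct <- 0L
  for (b in split(idx, ceiling(seq_along(idx) / chunk))) {
    y <- .cnn_forward(p, xs[b])$Y[1L, ]
    correct <- correct + sum((y > 0) == (ylab[b] == 1L))
  }
  correct / length(idx)
}

#' Held-out accuracy of a trained benchmark model
#'
#' Recomputes classification accuracy on the validation indices stored in
#' the model's training log.
#'
#' @param model a trained [ConvSequenceModel-class].
#' @param dataset the [BenchmarkDataset-class] it was trained on.
#' @return numeric(1) accuracy in [0, 1].
#' @export
heldOutAccuracy <- function(model, dataset) {
  valIdx <- attr(model@trainingLog, "valIndices")
  if (is.null(valIdx)) .input_error("model has no recorded validation split")
  xs <- lapply(dataset@sequences[valIdx], function(s) ohMatrix(oneHotEncode(s)))
  .cnn_accuracy(model@params, xs, dataset@labels[valIdx], seq_along(xs))
}

#' Motif-pair interaction scores on the benchmark's positive class
#'
#' For each positive sequence (optionally subsampled), computes the
#' motif-resolution FIS of every ordered pair of distinct planted motif
#' instances, using the GC-background source mutation at the generator's
#' `fGC`. Pairs between an ELF1 and a SIX5 instance are the ground-truth
#' interactions ("true"); pairs involving AP1 or TAL1 are decoys; pairs of
#' two instances of the same motif are homotypic and excluded from the
#' separation statistic. Reports the AUC of |FIS| for true vs decoy pairs
#' and, when `withSignificance`, annotates all pairs against a
#' dinucleotide-shuffle null built at the same span coordinates.
#'
#' @param model a trained [ConvSequenceModel-class].
#' @param dataset the [BenchmarkDataset-class].
#' @param backend attribution backend; default is the fixed-GC
#'   reference-difference backend, matching the fixed-GC background of the
#'   generator. Pass [gradInputBackend()] to replicate with plain gradient
#'   saliency.
#' @param nSequences number of positive sequences to score (default 300).
#' @param seed seed for the subsample and the null shuffles.
#' @param withSignificance run the empirical-null significance layer.
#' @param nullSequences,nullShuffles null-construction sizes.
#' @param alpha significance level (default 0.05).
#' @param minNull minimum pooled null size.
#' @return list(records, auc, trueSigFraction, decoySigFraction, null).
#' @export
evaluateMotifPairFis <- function(model, dataset, backend = NULL,
    nSequences = 300L, seed = 1L, withSignificance = TRUE,
    nullSequences = 75L, nullShuffles = 2L, alpha = 0.05, minNull = 500L) {
  fGC <- dataset@config$fGC
  if (is.null(backend))
    backend <- refDiffBackend(mode = "fixed_gc", fGC = fGC)
  pos <- which(dataset@labels == 1L)
  if (!length(pos)) .input_error("dataset has no positive sequences")
  sel <- .with_seed(seed, function()
    if (length(pos) > nSequences) sort(sample(pos, nSequences)) else pos)
  truth <- dataset@truth
  recs <- list()
  pairsBySeq <- list()
  seqList <- list()
  for (i in sel) {
    id <- names(dataset@sequences)[i]
    x <- oneHotEncode(dataset@sequences[[i]], id = id)
    tr <- truth[truth$sequence_id == id, , drop = FALSE]
    if (nrow(tr) < 2L) next
    loci <- lapply(seq_len(nrow(tr)), function(j)
      .locus_from_span(x, tr$start[j], tr$end[j]))
    sources <- lapply(loci, function(l) list(locus = l, fGC = fGC))
    r <- fisForSources(model, backend, x, sources, loci)
    ## map spans back to motif names
    key <- setNames(tr$motif, tr$start)
    r$source_motif <- key[as.character(r$source_start)]
    r$target_motif <- key[as.character(r$target_start)]
    r$pair_class <- ifelse(
      r$source_motif != r$target_motif &
        r$source_motif %in% c("ELF1", "SIX5") &
        r$target_motif %in% c("ELF1", "SIX5"), "true",
      ifelse(r$source_motif == r$target_motif, "homotypic", "decoy"))
    recs[[length(recs) + 1L]] <- r
    seqList[[length(seqList) + 1L]] <- x
    pairsBySeq[[length(pairsBySeq) + 1L]] <- {
      prs <- list()
      for (a in seq_along(loci)) for (b in seq_along(loci)) {
        if (a == b) next
        if (length(intersect(loci[[a]]@positions, loci[[b]]@positions))) next
        prs[[length(prs) + 1L]] <- list(source = loci[[a]], target = loci[[b]])
      }
      prs
    }
  }
  records <- data.table::rbindlist(recs)
  if (nrow(records) == 0L) .input_error("no motif pairs found to score")
  het <- records[records$pair_class != "homotypic", ]
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = factor(het$pair_class, levels = c("decoy", "true")),
    predictor = het$abs_score, levels = c("decoy", "true"),
    direction = "<", quiet = TRUE)))
  nullModel <- NULL
  trueSig <- decoySig <- NA_real_
  if (withSignificance) {
    nNull <- min(nullSequences, length(seqList))
    nullModel <- buildNull(model, backend, seqList[seq_len(nNull)],
      nShuffles = nullShuffles, seed = seed,
      scope = list(type = "motif", pairs = pairsBySeq[seq_len(nNull)],
        fGC = fGC),
      minN = minNull)
    records <- fisSignificance(records, nullModel, alpha = alpha)
    trueSig <- mean(records$significant[records$pair_class == "true"])
    decoySig <- mean(records$significant[records$pair_class == "decoy"])
  }
  list(records = records, auc = auc, trueSigFraction = trueSig,
    decoySigFraction = decoySig, null = nullModel)
}
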