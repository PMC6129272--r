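## Empirical-null significance for FIS scores: a Gaussian is fitted to FIS
## computed on dinucleotide-shuffled versions of the input sequences, and
## observed scores receive two-sided Gaussian p-values with
## Benjamini-Hochberg correction.

#' Fit a Gaussian null model to a vector of null FIS scores
#'
#' Maximum-likelihood fit (mean and population standard deviation). A
#' degenerate spread (all null scores equal, e.g. from a linear model whose
#' FIS is identically zero) is an error advising more shuffles.
#'
#' @param scores numeric vector of null scores.
#' @param minN minimum acceptable number of null scores (default 1000).
#' @return a [NullModel-class].
#' @export
fitNullModel <- function(scores, minN = 1000L) {
  scores <- scores[is.finite(scores)]
  n <- length(scores)
  if (n < minN)
    .input_error("only ", n, " null scores; need at least ", minN,
      " (increase shuffles or scope, or lower minN)")
  mu <- mean(scores)
  sigma <- sqrt(mean((scores - mu)^2))
  if (sigma <= 1e-12)
    .input_error("degenerate null (sigma = 0): all null scores identical; ",
      "increase the number of shuffles or widen the scope")
  new("NullModel", mu = mu, sigma = sigma, nNull = as.integer(n))
}

setMethod("show", "NullModel", function(object) {
  cat(sprintf("NullModel: mu = %.4g, sigma = %.4g (n = %d)\n",
    object@mu, object@sigma, object@nNull))
})

#' Build an empirical FIS null from dinucleotide-shuffled sequences
#'
#' Each input sequence is dinucleotide-shuffled `nShuffles` times (so the
#' base and dinucleotide composition of the null matches the data while any
#' planted features are destroyed), FIS is computed on the shuffled
#' sequences over the requested scope, and a Gaussian is fitted to the
#' pooled scores.
#'
#' Scopes:
#' * `list(type = "nucleotide", nSources = 50)` -- for each shuffled
#'   sequence, FIS of all targets is computed for `nSources` randomly
#'   sampled source positions (all three mutant bases). `nSources = Inf`
#'   gives the full all-pairs null, which is quadratic in sequence length;
#'   the subsample is the tractable default.
#' * `list(type = "motif", pairs = ...)` -- `pairs` is a list parallel to
#'   `sequences`; each element is a list of `list(source =, target =)`
#'   motif-locus pairs whose coordinates are re-scored on the shuffled
#'   sequence (the shuffle destroys the motif content at those spans),
#'   with `fGC` for the background source mutation given in the scope.
#'
#' @param model a [SequenceModel-class].
#' @param backend an [ImportanceBackend-class].
#' @param sequences list of [OneHotSequence-class].
#' @param nShuffles shuffles per sequence (default 10).
#' @param seed integer seed for the shuffles.
#' @param scope scoring scope, see Details.
#' @param minN minimum pooled null size passed to [fitNullModel()].
#' @return a [NullModel-class].
#' @export
buildNull <- function(model, backend, sequences, nShuffles = 10L, seed = 1L,
    scope = list(type = "nucleotide", nSources = 50L), minN = 1000L) {
  if (nShuffles < 1L) .input_error("nShuffles must be >= 1")
  if (is(sequences, "OneHotSequence")) sequences <- list(sequences)
  scores <- .with_seed(seed, function() {
    out <- list()
    for (i in seq_along(sequences)) {
      x <- sequences[[i]]
      s0 <- oneHotDecode(x)
      for (k in seq_len(nShuffles)) {
        xs <- oneHotEncode(dinucleotideShuffle(s0), id = seqId(x))
        out[[length(out) + 1L]] <- switch(scope$type,
          nucleotide = .null_scores_nucleotide(model, backend, xs, scope),
          motif = .null_scores_motif(model, backend, xs, scope$pairs[[i]],
            scope$fGC),
          .input_error("unknown null scope type '", scope$type, "'"))
      }
    }
    unlist(out)
  })
  fitNullModel(scores, minN = minN)
}

.null_scores_nucleotide <- function(model, backend, xs, scope) {
  L <- seqLength(xs)
  nSrc <- if (is.infinite(scope$nSources)) L else min(scope$nSources, L)
  srcs <- if (nSrc == L) seq_len(L) else sort(sample.int(L, nSrc))
  m <- ohMatrix(xs)
  obs <- .observed_rows(m)
  C0 <- importanceMatrix(backend, model, xs)
  vals <- list()
  for (s in srcs) {
    for (g in setdiff(.BASES, .BASES[obs[s]])) {
      D <- fisProfile(model, backend, xs, s, g, C0 = C0)
      v <- D[cbind(obs, seq_len(L))]
      vals[[length(vals) + 1L]] <- v[-s]
    }
  }
  unlist(vals)
}

.null_scores_motif <- function(model, backend, xs, pairs, fGC) {
  if (!length(pairs)) return(numeric(0))
  C0 <- importanceMatrix(backend, model, xs)
  m <- ohMatrix(xs)
  vapply(pairs, function(pr) {
    ## re-anchor the loci on the shuffled sequence's observed bases
    src <- .locus_from_span(xs, pr$source@positions[1L],
      pr$source@positions[length(pr$source@positions)])
    tgt <- .locus_from_span(xs, pr$target@positions[1L],
      pr$target@positions[length(pr$target@positions)])
    fisMotifMotif(model, backend, xs, src, tgt, fGC, C0 = C0)
  }, numeric(1))
}

#' Annotate FIS records with null p-values, BH q-values and significance
#'
#' Two-sided Gaussian p-values against the fitted null,
#' `p = 2 * pnorm(-|score - mu| / sigma)`, corrected by the
#' Benjamini-Hochberg step-up procedure over all records in the call (the
#' call defines the correction family; batch records accordingly). A record
#' is significant when `q <= alpha`.
#'
#' @param records data.table/data.frame with a `score` column.
#' @param null a [NullModel-class].
#' @param alpha significance level (default 0.05).
#' @return the records with columns `p`, `q`, `significant` appended.
#' @export
fisSignificance <- function(records, null, alpha = 0.05) {
  records <- data.table::as.data.table(records)
  if (nrow(records) == 0L) .input_error("empty record set: nothing to test")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    .input_error("alpha must be in (0, 1)")
  z <- abs(records$score - null@mu) / null@sigma
  records$p <- 2 * pnorm(-z)
  records$q <- p.adjust(records$p, method = "BH")
  records$significant <- records$q <= alpha
  records[]
}
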