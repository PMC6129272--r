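#' Point-mutate one position of a one-hot sequence
#'
#' Returns a copy of `x` whose column `s` is one-hot at the mutant base
#' `gamma`; every other column is bit-identical to the input. The input
#' object is never modified. Mutating back restores the original matrix
#' exactly.
#'
#' @param x a [OneHotSequence-class] (strictly one-hot at `s`).
#' @param s 1-based position to mutate.
#' @param gamma mutant base, must differ from the observed base at `s`.
#' @return a new [OneHotSequence-class].
#' @examples
#' oneHotDecode(applyPointMutation(oneHotEncode("ACGT"), 1, "C"))  # "CCGT"
#' @export
applyPointMutation <- function(x, s, gamma) {
  m <- .as_oh(x)
  s <- as.integer(s)
  if (length(s) != 1L || s < 1L || s > ncol(m))
    .input_error("position s = ", s, " out of range [1, ", ncol(m), "]")
  gamma <- toupper(gamma)
  gi <- match(gamma, .BASES)
  if (is.na(gi)) .input_error("mutant base must be one of A, C, G, T")
  col <- m[, s]
  if (!(sum(col == 1) == 1 && sum(col == 0) == 3))
    .input_error("column ", s, " is not strictly one-hot; point mutation undefined")
  alpha <- .BASES[which(col == 1)]
  if (alpha == gamma)
    .input_error("mutant base gamma (", gamma,
      ") must differ from the observed base at position ", s)
  m2 <- m
  m2[, s] <- 0
  m2[gi, s] <- 1
  new("OneHotSequence", id = .oh_id(x), mat = m2)
}

#' Replace a motif span by the background GC composition
#'
#' Every column in the span is set to the expected background base
#' frequencies for G+C content `fGC`: rows C and G each get `fGC / 2`,
#' rows A and T each get `(1 - fGC) / 2`, so mutated columns still sum to 1
#' and their total C+G mass equals `fGC`. Columns outside the span are
#' untouched; the input object is never modified. This is the source
#' perturbation used for motif-to-motif interaction scores, where a single
#' mutant sequence replaces the combinatorially many point mutations of the
#' span.
#'
#' @param x a [OneHotSequence-class].
#' @param span a motif [FeatureLocus-class], or an integer vector of
#'   contiguous positions.
#' @param fGC background G+C fraction, in (0, 1). Always explicit -- there
#'   is no default in the library core.
#' @return a new [OneHotSequence-class] with fractional columns in the span.
#' @export
applyBackgroundMutation <- function(x, span, fGC) {
  m <- .as_oh(x)
  pos <- if (is(span, "FeatureLocus")) span@positions else as.integer(span)
  if (length(pos) < 1L) .input_error("span must cover at least one position")
  if (min(pos) < 1L || max(pos) > ncol(m))
    .input_error("span out of range [1, ", ncol(m), "]")
  if (!is.numeric(fGC) || length(fGC) != 1L || fGC <= 0 || fGC >= 1)
    .input_error("fGC must be a single value in (0, 1)")
  m2 <- m
  m2[c("C", "G"), pos] <- fGC / 2
  m2[c("A", "T"), pos] <- (1 - fGC) / 2
  new("OneHotSequence", id = .oh_id(x), mat = m2)
}

#' Dinucleotide-preserving shuffle of a DNA string
#'
#' Produces a random permutation of `seq` with exactly the same table of all
#' 16 dinucleotide counts, using the Euler-path (Altschul-Erickson)
#' algorithm: the shuffle is a random Eulerian walk on the multigraph whose
#' edges are the observed dinucleotides. A consequence of the method is
#' that the first and last nucleotides are always preserved -- the shuffle
#' is not a full randomisation.
#'
#' @param seq DNA string (length >= 2).
#' @param seed optional integer; when given, the caller's RNG state is left
#'   untouched.
#' @return a shuffled DNA string.
#' @export
dinucleotideShuffle <- function(seq, seed = NULL) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 2L) .input_error("sequence must have length >= 2 to shuffle")
  if (!all(chars %in% .BASES)) .input_error("sequence must contain only A/C/G/T")
  .with_seed(seed, function() .dinuc_shuffle_impl(chars, n))
}

.dinuc_shuffle_impl <- function(chars, n) {
  verts <- unique(chars)
  if (length(verts) == 1L) return(paste(chars, collapse = ""))
  last <- chars[n]
  ## out-edge multiset per origin vertex
  edges <- split(chars[-1L], factor(chars[-n], levels = verts))
  ## choose a random "last out-edge" per non-terminal vertex such that the
  ## chosen edges form an arborescence into `last` (guarantees an Eulerian
  ## walk that consumes every edge)
  repeat {
    lastEdge <- vapply(verts, function(v) {
      if (v == last) NA_character_
      else edges[[v]][sample.int(length(edges[[v]]), 1L)]
    }, character(1))
    names(lastEdge) <- verts
    ok <- TRUE
    for (v in verts) {
      if (v == last) next
      cur <- v
      seen <- character(0)
      while (cur != last && !(cur %in% seen)) {
        seen <- c(seen, cur)
        cur <- lastEdge[[cur]]
      }
      if (cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  ## per-vertex: shuffle the remaining out-edges, append the reserved one
  adj <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (v == last) return(e[sample.int(length(e))])
    i <- match(lastEdge[[v]], e)
    rest <- e[-i]
    if (length(rest) > 1L) rest <- rest[sample.int(length(rest))]
    c(rest, lastEdge[[v]])
  })
  names(adj) <- verts
  ## Eulerian walk from the original first character
  out <- character(n)
  out[1L] <- chars[1L]
  ptr <- setNames(rep(1L, length(verts)), verts)
  cur <- chars[1L]
  for (i in 2:n) {
    nxt <- adj[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Table of the 16 dinucleotide counts of a DNA string
#'
#' @param seq DNA string.
#' @return named integer vector of length 16 (AA, AC, ..., TT).
#' @export
dinucleotideCounts <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  lv <- as.vector(outer(.BASES, .BASES, paste0))
  n <- length(chars)
  if (n < 2L) return(setNames(integer(16), lv))
  di <- paste0(chars[-n], chars[-1L])
  table(factor(di, levels = lv))
}
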