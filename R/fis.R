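## ---- Feature Interaction Score engine ----
##
## FIS(target | source mutation) = C_X0[target] - C_X0'[target], where X0'
## is X0 with the source feature mutated and C are backend importance
## matrices. Directional by construction: FIS(t|s) and FIS(s|t) are
## computed independently and no symmetrisation is ever applied.

.obs_base_at <- function(m, t) .BASES[.observed_rows(m)[t]]

#' Nucleotide-resolution feature interaction score
#'
#' Change in the importance of the observed target nucleotide (beta, t)
#' when the observed source nucleotide (alpha, s) is mutated to `gamma`,
#' with all other positions held fixed. The self pair t == s is undefined
#' (mutating s changes the observed base at s) and raises an error.
#'
#' @param model a [SequenceModel-class].
#' @param backend an [ImportanceBackend-class].
#' @param x a strictly one-hot [OneHotSequence-class].
#' @param s source position. @param gamma mutant base (must differ from the
#'   observed base at `s`). @param t target position (t != s).
#' @param C0 optional cached [ImportanceMatrix-class] of the unperturbed
#'   sequence; saves one backend evaluation.
#' @return signed numeric score.
#' @export
fisNucleotide <- function(model, backend, x, s, gamma, t, C0 = NULL) {
  m <- .as_oh(x)
  t <- as.integer(t)
  if (length(t) != 1L || t < 1L || t > ncol(m))
    .input_error("target position t = ", t, " out of range")
  if (t == as.integer(s))
    .input_error("self-interaction (t == s) is undefined: mutating the ",
      "source changes the observed target base at that position")
  if (is.null(C0)) C0 <- importanceMatrix(backend, model, x)
  xm <- applyPointMutation(x, s, gamma)
  C1 <- importanceMatrix(backend, model, xm)
  bi <- .observed_rows(m)[t]
  unname(C0@scores[bi, t] - C1@scores[bi, t])
}

#' FIS of every target position with respect to one source mutation
#'
#' Computes the full 4 x L matrix of importance differences for a single
#' source mutation. The values at (observed base, t) for t != s are the
#' nucleotide FIS scores; the source column is NA. Consumes exactly two
#' backend evaluations, or one when `C0` is supplied from a prior call.
#'
#' @inheritParams fisNucleotide
#' @return 4 x L matrix of differences; column `s` is NA.
#' @export
fisProfile <- function(model, backend, x, s, gamma, C0 = NULL) {
  if (is.null(C0)) C0 <- importanceMatrix(backend, model, x)
  xm <- applyPointMutation(x, s, gamma)
  C1 <- importanceMatrix(backend, model, xm)
  D <- C0@scores - C1@scores
  D[, as.integer(s)] <- NA_real_
  D
}

#' Maximal FIS over the three possible mutant bases
#'
#' Marginalises the nucleotide FIS of target `t` with source `s` over the
#' three mutant bases gamma != alpha. Under `policy = "signed"` the maximum
#' signed score is returned; under `policy = "abs"` the score of largest
#' magnitude (sign retained). Ties are broken by alphabetical order of the
#' mutant base.
#'
#' @inheritParams fisNucleotide
#' @param policy "abs" (default; magnitude is what interaction maps
#'   display) or "signed" (the literal maximum).
#' @return list(score, mutant).
#' @export
maxFis <- function(model, backend, x, s, t, policy = c("abs", "signed"),
    C0 = NULL) {
  policy <- match.arg(policy)
  m <- .as_oh(x)
  alpha <- .obs_base_at(m, as.integer(s))
  if (is.null(C0)) C0 <- importanceMatrix(backend, model, x)
  cand <- setdiff(.BASES, alpha)
  scores <- vapply(cand, function(g)
    fisNucleotide(model, backend, x, s, g, t, C0 = C0), numeric(1))
  key <- if (policy == "abs") abs(scores) else scores
  i <- which.max(key)   # first max: candidates are in alphabetical order
  list(score = scores[[i]], mutant = cand[[i]])
}

#' Per-sequence deep feature interaction map
#'
#' For every source position s, the three mutant profiles are computed and
#' each target position t receives the policy-maximal FIS; the diagonal is
#' masked. Importance matrices for the unperturbed sequence are computed
#' once and cached, so the whole map costs exactly 3L + 1 backend
#' evaluations.
#'
#' @inheritParams maxFis
#' @return a [DFIMMap-class].
#' @export
dfimMap <- function(model, backend, x, policy = c("abs", "signed")) {
  policy <- match.arg(policy)
  m <- .as_oh(x)
  L <- ncol(m)
  obs <- .observed_rows(m)
  C0 <- importanceMatrix(backend, model, x)
  out <- matrix(NA_real_, L, L)
  for (s in seq_len(L)) {
    alpha <- .BASES[obs[s]]
    cand <- setdiff(.BASES, alpha)
    vals <- matrix(0, 3L, L)
    for (k in seq_along(cand)) {
      D <- fisProfile(model, backend, x, s, cand[k], C0 = C0)
      vals[k, ] <- D[cbind(obs, seq_len(L))]
    }
    key <- if (policy == "abs") abs(vals) else vals
    pick <- max.col(t(key), ties.method = "first")
    row <- vals[cbind(pick, seq_len(L))]
    row[s] <- NA_real_
    out[s, ] <- row
  }
  new("DFIMMap", sequenceId = .oh_id(x), scores = out, policy = policy,
    backend = backend@name)
}

setMethod("show", "DFIMMap", function(object) {
  s <- object@scores
  cat("DFIMMap '", object@sequenceId, "': ", nrow(s), " x ", ncol(s),
    " (", object@policy, ", ", object@backend, "); max |score| = ",
    sprintf("%.4g", max(abs(s), na.rm = TRUE)), "\n", sep = "")
})

#' FIS of a target motif with a nucleotide source mutation
#'
#' The difference of the summed importance of the target motif's
#' nucleotides between the original and the point-mutated sequence;
#' identical to the sum of the per-position nucleotide FIS over the motif.
#' The natural score for asking which motif a regulatory single-nucleotide
#' variant acts on.
#'
#' @inheritParams fisNucleotide
#' @param targetMotif a motif [FeatureLocus-class]; must not contain `s`.
#' @return signed numeric score.
#' @export
fisMotifTarget <- function(model, backend, x, s, gamma, targetMotif,
    C0 = NULL) {
  if (as.integer(s) %in% targetMotif@positions)
    .input_error("source position ", s, " lies inside the target motif span")
  .check_locus(x, targetMotif)
  if (is.null(C0)) C0 <- importanceMatrix(backend, model, x)
  xm <- applyPointMutation(x, s, gamma)
  C1 <- importanceMatrix(backend, model, xm)
  importanceOfLocus(C0, targetMotif) - importanceOfLocus(C1, targetMotif)
}

#' FIS of a target motif with a source motif (GC-background mutation)
#'
#' The source motif span is replaced by the expected background GC
#' composition in a single mutant sequence (see
#' [applyBackgroundMutation()]), and the score is the difference of the
#' target motif's summed importance between the original and mutant
#' sequences. Exactly two backend evaluations (one if `C0` is supplied).
#' Overlapping spans are rejected: the score is undefined there.
#'
#' @inheritParams fisNucleotide
#' @param sourceMotif,targetMotif disjoint motif [FeatureLocus-class]
#'   objects.
#' @param fGC background G+C fraction in (0, 1), always explicit.
#' @return signed numeric score.
#' @export
fisMotifMotif <- function(model, backend, x, sourceMotif, targetMotif, fGC,
    C0 = NULL) {
  if (length(intersect(sourceMotif@positions, targetMotif@positions)) > 0L)
    .input_error("source and target motif spans overlap; the score is undefined")
  .check_locus(x, targetMotif)
  if (is.null(C0)) C0 <- importanceMatrix(backend, model, x)
  xm <- applyBackgroundMutation(x, sourceMotif, fGC)
  C1 <- importanceMatrix(backend, model, xm)
  importanceOfLocus(C0, targetMotif) - importanceOfLocus(C1, targetMotif)
}

## mutation spec -> mutated sequence (shared by ISM and fisForSources)
.apply_spec <- function(x, spec) {
  if (is(spec, "FeatureLocus"))
    .input_error("a bare locus is ambiguous; supply list(locus =, mutant =) ",
      "for a point mutation or list(locus =, fGC =) for background mutation")
  if (!is.null(spec$mutant))
    applyPointMutation(x, spec$locus@positions[1L], spec$mutant)
  else if (!is.null(spec$fGC))
    applyBackgroundMutation(x, spec$locus, spec$fGC)
  else .input_error("mutation spec needs either $mutant (point) or $fGC (background)")
}

.spec_positions <- function(spec) spec$locus@positions

.spec_mutant_label <- function(spec) {
  if (!is.null(spec$mutant)) spec$mutant
  else sprintf("GC%.3g", spec$fGC)
}

#' Pairwise in-silico-mutagenesis interaction score
#'
#' The ISM score of a feature f is `Y(x) - Y(mutate(x, f))`. The pairwise
#' interaction of two disjoint features is the ISM score of the joint
#' mutation minus the sum of the two individual ISM scores; it is symmetric
#' in its arguments and zero for any additive (linear) model. Used as the
#' forward-propagation comparison oracle for FIS: it needs one forward pass
#' per feature pair, whereas FIS needs only one attribution pass per
#' feature.
#'
#' @param model a [SequenceModel-class].
#' @param x a strictly one-hot [OneHotSequence-class].
#' @param source,target mutation specs: `list(locus =, mutant =)` for a
#'   point mutation or `list(locus =, fGC =)` for a GC-background motif
#'   mutation; the loci must not overlap.
#' @return signed numeric score.
#' @export
pairwiseIsmInteraction <- function(model, x, source, target) {
  if (length(intersect(.spec_positions(source), .spec_positions(target))) > 0L)
    .input_error("source and target features overlap; interaction undefined")
  xs <- .apply_spec(x, source)
  xt <- .apply_spec(x, target)
  xst <- .apply_spec(xs, target)
  y <- modelPredict(model, list(.as_oh(x), .as_oh(xs), .as_oh(xt), .as_oh(xst)))
  ## (Y0 - Yst) - (Y0 - Ys) - (Y0 - Yt)
  (y[1L] - y[4L]) - (y[1L] - y[2L]) - (y[1L] - y[3L])
}

#' FIS records for pre-specified source features against target features
#'
#' Computes the unperturbed importance matrix once, then one mutant
#' importance matrix per source feature, scoring every non-overlapping
#' target feature against each source: F sources cost exactly F + 1 backend
#' evaluations, the linear-in-features complexity that distinguishes this
#' approach from quadratic pairwise in-silico mutagenesis.
#'
#' @inheritParams pairwiseIsmInteraction
#' @param backend an [ImportanceBackend-class].
#' @param sources list of mutation specs (see [pairwiseIsmInteraction()]).
#' @param targets list of target [FeatureLocus-class] objects.
#' @return a data.table of FIS records (one row per source-target pair);
#'   columns sequence_id, source_start, source_end, source_bases, mutant,
#'   target_start, target_end, target_bases, score, abs_score, backend.
#' @export
fisForSources <- function(model, backend, x, sources, targets) {
  C0 <- importanceMatrix(backend, model, x)
  rows <- list()
  for (src in sources) {
    xm <- .apply_spec(x, src)
    C1 <- importanceMatrix(backend, model, xm)
    spos <- .spec_positions(src)
    for (tg in targets) {
      if (length(intersect(spos, tg@positions)) > 0L) next
      sc <- importanceOfLocus(C0, tg) - importanceOfLocus(C1, tg)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        sequence_id = .oh_id(x),
        source_start = spos[1L], source_end = spos[length(spos)],
        source_bases = paste(src$locus@bases, collapse = ""),
        mutant = .spec_mutant_label(src),
        target_start = tg@positions[1L],
        target_end = tg@positions[length(tg@positions)],
        target_bases = paste(tg@bases, collapse = ""),
        score = sc, abs_score = abs(sc), backend = backend@name)
    }
  }
  if (!length(rows)) return(.empty_records())
  data.table::rbindlist(rows)
}

.empty_records <- function() data.table::data.table(
  sequence_id = character(), source_start = integer(), source_end = integer(),
  source_bases = character(), mutant = character(), target_start = integer(),
  target_end = integer(), target_bases = character(), score = numeric(),
  abs_score = numeric(), backend = character())

#' All-pairs nucleotide FIS records for one sequence
#'
#' One record per (source position, mutant base, target position) triple,
#' scored at the observed target base. Costs 3L + 1 backend evaluations.
#'
#' @inheritParams dfimMap
#' @return a data.table of FIS records (single-position source and target).
#' @export
fisAllPairs <- function(model, backend, x) {
  m <- .as_oh(x)
  L <- ncol(m)
  obs <- .observed_rows(m)
  obase <- .BASES[obs]
  C0 <- importanceMatrix(backend, model, x)
  rows <- vector("list", 3L * L)
  k <- 0L
  for (s in seq_len(L)) {
    cand <- setdiff(.BASES, obase[s])
    for (g in cand) {
      D <- fisProfile(model, backend, x, s, g, C0 = C0)
      vals <- D[cbind(obs, seq_len(L))]
      tt <- setdiff(seq_len(L), s)
      k <- k + 1L
      rows[[k]] <- data.table::data.table(
        sequence_id = .oh_id(x),
        source_start = s, source_end = s, source_bases = obase[s],
        mutant = g,
        target_start = tt, target_end = tt, target_bases = obase[tt],
        score = vals[tt], abs_score = abs(vals[tt]), backend = backend@name)
    }
  }
  data.table::rbindlist(rows)
}
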