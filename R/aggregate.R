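## Cross-sequence aggregation of nucleotide-resolution FIS records.

#' Aggregate FIS records over sequences sharing a feature context
#'
#' Groups single-nucleotide FIS records by their (source position, source
#' base, mutant base, target position, target base) context -- i.e. over
#' the subset of sequences with identical source and target nucleotides at
#' those positions -- and returns the mean FIS or mean absolute FIS per
#' context with the number of contributing records. Records must come from
#' a single backend.
#'
#' @param records data.table of single-position FIS records (as from
#'   [fisAllPairs()], possibly concatenated over sequences).
#' @param statistic "mean" or "meanAbs".
#' @return data.table with columns source_pos, source_base, mutant,
#'   target_pos, target_base, value, n.
#' @export
aggregateFis <- function(records, statistic = c("mean", "meanAbs")) {
  statistic <- match.arg(statistic)
  records <- data.table::as.data.table(records)
  if (nrow(records) == 0L) .input_error("no records to aggregate")
  if (length(unique(records$backend)) > 1L)
    .input_error("records mix attribution backends: ",
      paste(unique(records$backend), collapse = ", "))
  if (any(records$source_start != records$source_end) ||
      any(records$target_start != records$target_end))
    .input_error("aggregation is defined for single-nucleotide records")
  val <- if (statistic == "meanAbs") abs(records$score) else records$score
  dt <- data.table::data.table(
    source_pos = records$source_start, source_base = records$source_bases,
    mutant = records$mutant,
    target_pos = records$target_start, target_base = records$target_bases,
    v = val)
  out <- dt[, list(value = mean(v), n = .N),
    by = c("source_pos", "source_base", "mutant", "target_pos", "target_base")]
  data.table::setorder(out, source_pos, source_base, mutant, target_pos,
    target_base)
  out[]
}

#' Marginalised aggregate interaction map
#'
#' Builds the (4 * P) x (4 * P) aggregate map over a fixed-length
#' collection: for each (source base, source position, target base, target
#' position) cell, the mean absolute FIS is computed per mutant base over
#' the sequences matching that context, then the maximum over the three
#' mutant bases is recorded. Rows are (source position, source base),
#' columns (target position, target base); cells whose context matched no
#' sequence are NA with count 0. Same-position blocks are structurally
#' empty because the score is undefined at t == s.
#'
#' @param records single-nucleotide FIS records over sequences of one
#'   common length.
#' @param posLabels optional character labels for the positions (e.g.
#'   `c("-5", ..., "-1", "+1", ..., "+5")` for a motif-flank library).
#' @return an [AggregateMap-class].
#' @export
marginalizedAggregateMap <- function(records, posLabels = NULL) {
  agg <- aggregateFis(records, statistic = "meanAbs")
  P <- max(agg$source_pos, agg$target_pos)
  if (is.null(posLabels)) posLabels <- as.character(seq_len(P))
  if (length(posLabels) != P)
    .input_error("need ", P, " position labels, got ", length(posLabels))
  ## max over the 3 mutant bases of the per-mutant mean |FIS|
  marg <- agg[, list(value = max(value), n = n[which.max(value)]),
    by = c("source_pos", "source_base", "target_pos", "target_base")]
  labs <- as.vector(t(outer(posLabels, .BASES, paste, sep = ":")))
  idx <- function(pos, base) (pos - 1L) * 4L + match(base, .BASES)
  vals <- matrix(NA_real_, 4L * P, 4L * P, dimnames = list(labs, labs))
  cnts <- matrix(0L, 4L * P, 4L * P, dimnames = list(labs, labs))
  ri <- idx(marg$source_pos, marg$source_base)
  ci <- idx(marg$target_pos, marg$target_base)
  vals[cbind(ri, ci)] <- marg$value
  cnts[cbind(ri, ci)] <- marg$n
  new("AggregateMap", values = vals, counts = cnts,
    statistic = "max_mutant_mean_abs")
}

#' Strongest cell of an aggregate map
#'
#' @param map an [AggregateMap-class].
#' @return list(source, target, value) naming the row and column labels of
#'   the largest non-missing cell.
#' @export
topAggregateCell <- function(map) {
  v <- map@values
  if (all(is.na(v))) .input_error("aggregate map is empty")
  i <- which(v == max(v, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  list(source = rownames(v)[i[1L]], target = colnames(v)[i[2L]],
    value = v[i[1L], i[2L]])
}

setMethod("show", "AggregateMap", function(object) {
  cat("AggregateMap (", object@statistic, "): ", nrow(object@values), " x ",
    ncol(object@values), "; ", sum(!is.na(object@values)),
    " populated cells\n", sep = "")
  if (any(!is.na(object@values))) {
    top <- topAggregateCell(object)
    cat("  top cell: ", top$source, " -> ", top$target, " = ",
      sprintf("%.4g", top$value), "\n", sep = "")
  }
})

#' Write / read an aggregate or per-sequence interaction map as TSV
#'
#' Maps are stored as labelled tab-separated matrices (row labels in the
#' first column).
#'
#' @param map an [AggregateMap-class] or [DFIMMap-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeInteractionMap <- function(map, path) {
  m <- if (is(map, "AggregateMap")) map@values else map@scores
  if (is.null(rownames(m))) {
    rownames(m) <- as.character(seq_len(nrow(m)))
    colnames(m) <- as.character(seq_len(ncol(m)))
  }
  dt <- data.table::data.table(label = rownames(m))
  for (j in seq_len(ncol(m))) dt[[colnames(m)[j]]] <- m[, j]
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname writeInteractionMap
#' @return `readInteractionMap` returns the labelled numeric matrix.
#' @export
readInteractionMap <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1L])
  rownames(m) <- dt[[1L]]
  m
}
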