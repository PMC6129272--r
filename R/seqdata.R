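#' One-hot encode a DNA string
#'
#' Encodes a DNA string into a 4 x L matrix with row order A, C, G, T:
#' column p carries a single 1 in the row of the base at position p.
#' Case-insensitive. Ambiguity codes (including N) are rejected rather than
#' imputed -- attribution scores on imputed bases would be silently wrong.
#'
#' @param seq character(1), DNA string over A/C/G/T.
#' @param id sequence identifier.
#' @return a [OneHotSequence-class].
#' @examples
#' x <- oneHotEncode("ACGT")
#' ohMatrix(x)          # the 4 x 4 identity matrix
#' oneHotDecode(x)      # "ACGT"
#' @export
oneHotEncode <- function(seq, id = "seq") {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    .input_error("seq must be a single non-empty DNA string")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  row <- match(chars, .BASES)
  if (anyNA(row)) {
    p <- which(is.na(row))[1L]
    .input_error("non-ACGT character '", chars[p], "' at position ", p,
      " in sequence '", id, "'")
  }
  L <- length(chars)
  m <- matrix(0, 4L, L, dimnames = list(.BASES, NULL))
  m[cbind(row, seq_len(L))] <- 1
  new("OneHotSequence", id = as.character(id), mat = m)
}

#' Decode a strictly one-hot sequence back to a DNA string
#'
#' Defined only for strictly one-hot input: decoding a background-mutated
#' (fractional) column is undefined and raises an error.
#'
#' @param x a [OneHotSequence-class] or 4 x L matrix.
#' @return character(1) DNA string.
#' @export
oneHotDecode <- function(x) {
  m <- .as_oh(x)
  onehot <- colSums(m == 1) == 1 & colSums(m == 0) == 3
  if (!all(onehot))
    .input_error("column ", which(!onehot)[1L],
      " is fractional; decoding is only defined for strictly one-hot sequences")
  paste(.BASES[max.col(t(m), ties.method = "first")], collapse = "")
}

## accept OneHotSequence or bare matrix everywhere in the engine
.as_oh <- function(x) {
  if (is(x, "OneHotSequence")) return(x@mat)
  if (is.matrix(x)) {
    if (nrow(x) != 4L) .input_error("matrix input must have 4 rows (A,C,G,T)")
    if (is.null(rownames(x))) rownames(x) <- .BASES
    return(x)
  }
  .input_error("expected a OneHotSequence or a 4 x L matrix")
}

.oh_id <- function(x) if (is(x, "OneHotSequence")) x@id else "seq"

## observed base index per column (first max for fractional ties)
.observed_rows <- function(m) max.col(t(m), ties.method = "first")

#' @rdname OneHotSequence-class
#' @export
setMethod("ohMatrix", "OneHotSequence", function(x) x@mat)

#' @rdname OneHotSequence-class
#' @export
setMethod("seqId", "OneHotSequence", function(x) x@id)

#' @rdname OneHotSequence-class
#' @export
setMethod("seqLength", "OneHotSequence", function(x) ncol(x@mat))

setMethod("show", "OneHotSequence", function(object) {
  L <- ncol(object@mat)
  frac <- sum(!(colSums(object@mat == 1) == 1))
  cat("OneHotSequence '", object@id, "': L = ", L,
    if (frac > 0) paste0(" (", frac, " fractional columns)"), "\n", sep = "")
})

#' Construct a feature locus
#'
#' @param positions integer positions (1-based); a single position gives a
#'   nucleotide feature, a contiguous ascending span a motif feature.
#' @param bases observed base(s): one character per position, or a single
#'   string of length equal to the span.
#' @param sequenceId optional id of the sequence the locus belongs to.
#' @return a [FeatureLocus-class].
#' @examples
#' featureLocus(5, "C")              # a nucleotide feature
#' featureLocus(2:5, "ACGT")         # a 4-bp motif feature
#' @export
featureLocus <- function(positions, bases, sequenceId = "") {
  positions <- as.integer(positions)
  if (length(bases) == 1L && nchar(bases) == length(positions) &&
      length(positions) > 1L)
    bases <- strsplit(toupper(bases), "", fixed = TRUE)[[1L]]
  bases <- toupper(as.character(bases))
  kind <- if (length(positions) == 1L) "nucleotide" else "motif"
  new("FeatureLocus", sequenceId = as.character(sequenceId), kind = kind,
    positions = positions, bases = bases, strand = "+")
}

## locus from a span of an encoded sequence, bases read off the sequence
.locus_from_span <- function(x, start, end) {
  m <- .as_oh(x)
  if (start < 1L || end > ncol(m) || end < start)
    .input_error("span [", start, ", ", end, "] out of range for sequence '",
      .oh_id(x), "' of length ", ncol(m))
  pos <- seq.int(start, end)
  featureLocus(pos, .BASES[.observed_rows(m)[pos]], sequenceId = .oh_id(x))
}

## check locus bases match the sequence's observed bases
.check_locus <- function(x, locus) {
  m <- .as_oh(x)
  if (max(locus@positions) > ncol(m))
    .input_error("locus positions exceed sequence length ", ncol(m))
  obs <- .BASES[.observed_rows(m)[locus@positions]]
  if (!all(obs == locus@bases))
    .input_error("locus bases (", paste(locus@bases, collapse = ""),
      ") do not match the sequence's observed bases (",
      paste(obs, collapse = ""), ")")
  invisible(TRUE)
}

setMethod("show", "FeatureLocus", function(object) {
  cat("FeatureLocus [", object@kind, "] ",
    if (nzchar(object@sequenceId)) paste0(object@sequenceId, ":"),
    object@positions[1L], "-", object@positions[length(object@positions)],
    " ", paste(object@bases, collapse = ""), " (+)\n", sep = "")
})

#' Read a multi-record FASTA file as one-hot sequences
#'
#' Lowercase input is accepted and uppercased. Duplicate ids, empty records
#' and ambiguity codes (N) are rejected with messages naming the offending
#' record (and offset, for bad characters).
#'
#' @param path FASTA file path.
#' @return named list of [OneHotSequence-class] objects.
#' @export
readFastaOneHot <- function(path) {
  if (!file.exists(path)) .input_error("FASTA file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  ids <- names(set)
  if (anyDuplicated(ids))
    .input_error("duplicate FASTA ids: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(set) == 0L))
    .input_error("empty FASTA record: ", ids[Biostrings::width(set) == 0L][1L])
  out <- vector("list", length(set))
  for (i in seq_along(set))
    out[[i]] <- oneHotEncode(as.character(set[[i]]), id = ids[i])
  names(out) <- ids
  out
}

#' Write one-hot sequences to FASTA (80-column wrap)
#'
#' @param seqs list of [OneHotSequence-class] (strictly one-hot).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeFastaOneHot <- function(seqs, path) {
  if (is(seqs, "OneHotSequence")) seqs <- list(seqs)
  strings <- vapply(seqs, oneHotDecode, character(1))
  names(strings) <- vapply(seqs, seqId, character(1))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(strings),
    filepath = path, width = 80L)
  invisible(path)
}

#' Read feature loci from a BED file
#'
#' BED3+ with 0-based half-open intervals; the chrom field must match a
#' sequence id in `seqs`. Bases are filled in from the referenced sequence;
#' single-base intervals become nucleotide features, longer intervals motif
#' features. The optional BED name column is attached as the `motif`
#' attribute of each locus.
#'
#' @param path BED file path.
#' @param seqs named list of [OneHotSequence-class] (as from
#'   [readFastaOneHot()]).
#' @return list of [FeatureLocus-class].
#' @export
readFeatureBed <- function(path, seqs) {
  if (!file.exists(path)) .input_error("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  for (i in which(keep)) {
    f <- strsplit(lines[i], "[\t ]+")[[1L]]
    if (length(f) < 3L || is.na(suppressWarnings(as.integer(f[2L]))) ||
        is.na(suppressWarnings(as.integer(f[3L]))))
      .input_error("malformed BED line ", i, " in ", path, ": '", lines[i], "'")
  }
  gr <- rtracklayer::import(path, format = "BED")
  ids <- vapply(seqs, seqId, character(1))
  names(seqs) <- ids
  out <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    chrom <- as.character(GenomicRanges::seqnames(gr)[i])
    if (!chrom %in% ids)
      .input_error("BED interval ", i, ": unknown sequence id '", chrom, "'")
    x <- seqs[[chrom]]
    loc <- .locus_from_span(x, GenomicRanges::start(gr)[i],
      GenomicRanges::end(gr)[i])
    nm <- gr$name
    attr(loc, "motif") <- if (!is.null(nm) && !is.na(nm[i])) nm[i] else NA_character_
    out[[i]] <- loc
  }
  out
}
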