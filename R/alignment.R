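#' Construct a multiple sequence alignment object
#'
#' An `msa` is a named character vector of equal-length gapped rows (gap
#' character `-`), normalized to uppercase, with class `msa`. Ungapping any
#' row recovers its source sequence exactly.
#'
#' @param rows Character vector of gapped sequences.
#' @param ids Row labels; defaults to `names(rows)`.
#' @return An `msa` object.
#' @export
msa <- function(rows, ids = names(rows)) {
  stopifnot(is.character(rows), length(rows) >= 1L)
  if (is.null(ids)) ids <- paste0("seq", seq_along(rows))
  if (length(ids) != length(rows)) stop("msa: ids/rows length mismatch", call. = FALSE)
  rows <- toupper(rows)
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) {
    bad <- ids[lens != lens[1L]][1L]
    stop(sprintf("msa: ragged alignment, record '%s' has a different length", bad),
         call. = FALSE)
  }
  if (any(grepl("[^ACGTN-]", rows))) {
    stop("msa: rows contain characters outside {A,C,G,T,N,-}", call. = FALSE)
  }
  structure(stats::setNames(rows, ids), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d rows x %d columns\n", length(x), msa_length(x)))
  invisible(x)
}

#' Number of columns of an alignment
#' @param x An `msa`.
#' @return Integer column count.
#' @export
msa_length <- function(x) nchar(unclass(x)[[1L]])

#' Alignment as a character matrix (rows x columns)
#' @param x An `msa`.
#' @return Character matrix with rownames = ids.
#' @export
msa_matrix <- function(x) {
  m <- do.call(rbind, strsplit(unclass(x), "", fixed = TRUE))
  rownames(m) <- names(x)
  m
}

#' Remove gaps from one alignment row
#' @param row Gapped sequence string.
#' @return Ungapped sequence.
#' @export
ungap <- function(row) gsub("-", "", row, fixed = TRUE)

#' Read an aligned FASTA file
#'
#' @param path Path to aligned FASTA.
#' @return An [msa]. Ragged inputs raise an error naming the offending record.
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("read_alignment: no records in file", call. = FALSE)
  msa(as.character(ss), ids = sub("\\s.*$", "", names(ss)))
}

#' Write an alignment as aligned FASTA
#'
#' @param x An [msa].
#' @param path Output path.
#' @export
write_alignment <- function(x, path) {
  ss <- Biostrings::BStringSet(unclass(x))
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Alignment scoring scheme
#'
#' Affine-gap scoring: a gap run of length `g` costs
#' `gap_open + g * gap_extend` (both supplied as negative numbers).
#'
#' @param match Match score (default `2`).
#' @param mismatch Mismatch score (default `-1`).
#' @param gap_open Gap opening score (default `-4`).
#' @param gap_extend Per-base gap extension score (default `-1`).
#' @return Named list of class `align_scoring`.
#' @export
align_scoring <- function(match = 2, mismatch = -1, gap_open = -4, gap_extend = -1) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment (via Biostrings) with the affine gap
#' model of [align_scoring]. `N` scores as a mismatch against any base.
#' Intended for desk-scale sequences; genome-scale alignments should be
#' produced externally and ingested with [read_alignment].
#'
#' @param a,b Nucleotide strings (or [genome_record]s).
#' @param scoring An [align_scoring]; defaults match +2 / mismatch -1 /
#'   open -4 / extend -1.
#' @param ids Row labels for the result (default `c("a", "b")`).
#' @param max_cells Refuse alignments with `|a| * |b|` above this cap
#'   (default 1e8) and direct the user to an external aligner.
#' @return A `pairwise_alignment`: an [msa] with two rows, a `score`
#'   attribute, and the scoring scheme as attribute `scoring`.
#' @export
#' @examples
#' aln <- global_align("ACGTA", "ACTA")
#' attr(aln, "score")
global_align <- function(a, b, scoring = align_scoring(), ids = c("a", "b"),
                         max_cells = 1e8) {
  if (inherits(a, "genome_record")) { if (ids[1] == "a") ids[1] <- a$accession; a <- a$sequence }
  if (inherits(b, "genome_record")) { if (ids[2] == "b") ids[2] <- b$accession; b <- b$sequence }
  stopifnot(nchar(a) >= 1L, nchar(b) >= 1L)
  if (as.numeric(nchar(a)) * nchar(b) > max_cells) {
    stop("global_align: sequence product exceeds the cell cap; ",
         "align externally and supply the result via read_alignment()",
         call. = FALSE)
  }
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                                 mismatch = scoring$mismatch,
                                                 baseOnly = FALSE)
  # make N score as a plain mismatch rather than an averaged ambiguity score
  sm["N", ] <- scoring$mismatch
  sm[, "N"] <- scoring$mismatch
  pa <- Biostrings::pairwiseAlignment(toupper(a), toupper(b), type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = -scoring$gap_open,
                                      gapExtension = -scoring$gap_extend)
  out <- msa(c(as.character(Biostrings::alignedPattern(pa)),
               as.character(Biostrings::alignedSubject(pa))),
             ids = ids)
  attr(out, "score") <- Biostrings::score(pa)
  attr(out, "scoring") <- scoring
  class(out) <- c("pairwise_alignment", "msa")
  out
}

#' Extract one pair of rows from a multiple alignment as a pairwise alignment
#'
#' Columns gapped in both selected rows are removed, so the result satisfies
#' the pairwise-alignment invariant that no column is all-gap.
#'
#' @param x An [msa].
#' @param i,j Row ids or indices.
#' @return A `pairwise_alignment` (without a score attribute).
#' @export
msa_pair <- function(x, i, j) {
  ri <- unclass(x)[[i]]
  rj <- unclass(x)[[j]]
  ids <- names(unclass(x)[c(i, j)])
  ci <- strsplit(ri, "", fixed = TRUE)[[1L]]
  cj <- strsplit(rj, "", fixed = TRUE)[[1L]]
  keep <- !(ci == "-" & cj == "-")
  out <- msa(c(paste(ci[keep], collapse = ""), paste(cj[keep], collapse = "")),
             ids = ids)
  class(out) <- c("pairwise_alignment", "msa")
  out
}
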