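#' Create a genome record
#'
#' A `genome_record` holds one circular (by default) nucleotide sequence
#' together with its accession and host-species metadata. Sequences are
#' restricted to the alphabet `A`, `C`, `G`, `T`, `N` and stored uppercase.
#'
#' @param sequence Single nucleotide string.
#' @param accession Accession or other unique identifier.
#' @param host_species Host species name (optional).
#' @param circular Logical; is the molecule circular? Default `TRUE`.
#' @return An object of class `genome_record` with fields `accession`,
#'   `host_species`, `sequence`, `circular`.
#' @export
#' @examples
#' g <- genome_record("ACGTACGT", "toy1")
#' genome_stats(g)
genome_record <- function(sequence, accession, host_species = NA_character_,
                          circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) {
    stop("genome_record: sequence must be non-empty", call. = FALSE)
  }
  if (grepl("[^ACGTN]", sequence)) {
    stop("genome_record: sequence contains characters outside {A,C,G,T,N}",
         call. = FALSE)
  }
  structure(
    list(accession = as.character(accession),
         host_species = as.character(host_species),
         sequence = sequence,
         circular = isTRUE(circular)),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%s), %s bp, %s\n", x$accession,
              ifelse(is.na(x$host_species), "host unknown", x$host_species),
              format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read genomes from a FASTA file
#'
#' @param path Path to a (multi-)FASTA file.
#' @param hosts Optional named character vector mapping record ids to host
#'   species.
#' @param circular Logical, applied to every record.
#' @return Named list of [genome_record] objects (names = FASTA ids, first
#'   whitespace-delimited token).
#' @export
read_genomes <- function(path, hosts = NULL, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  out <- lapply(seq_along(ss), function(i) {
    host <- if (!is.null(hosts) && ids[i] %in% names(hosts)) hosts[[ids[i]]] else NA_character_
    genome_record(as.character(ss[[i]]), ids[i], host, circular)
  })
  names(out) <- ids
  out
}

#' Write genomes to a FASTA file
#'
#' @param genomes List of [genome_record] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genomes <- function(genomes, path) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  seqs <- Biostrings::DNAStringSet(vapply(genomes, function(g) g$sequence, ""))
  names(seqs) <- vapply(genomes, function(g) g$accession, "")
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Genome length and GC content
#'
#' Length is the raw sequence length; GC percent is `100 * (G + C)` over the
#' number of non-`N` bases, so ambiguity positions do not dilute the ratio.
#' Rounding is left to the presentation layer.
#'
#' @param record A [genome_record].
#' @return List with `length` (bp) and `gc_percent`.
#' @export
genome_stats <- function(record) {
  stopifnot(inherits(record, "genome_record"))
  counts <- base_counts(record$sequence)
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0L) {
    stop("genome_stats: GC content undefined for an all-N sequence", call. = FALSE)
  }
  list(length = nchar(record$sequence),
       gc_percent = 100 * sum(counts[c("G", "C")]) / denom)
}

base_counts <- function(sequence) {
  tab <- table(factor(strsplit(sequence, "", fixed = TRUE)[[1]],
                      levels = c("A", "C", "G", "T", "N")))
  stats::setNames(as.integer(tab), names(tab))
}

#' Tabulate genome statistics
#'
#' @param genomes List of [genome_record] objects.
#' @return `data.frame` with columns `accession`, `host`, `length_bp`,
#'   `gc_percent`.
#' @export
genome_stats_table <- function(genomes) {
  rows <- lapply(genomes, function(g) {
    s <- genome_stats(g)
    data.frame(accession = g$accession, host = g$host_species,
               length_bp = s$length, gc_percent = s$gc_percent,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a genome statistics table as TSV
#'
#' GC percent is rounded to one decimal in the exported file.
#'
#' @param genomes List of [genome_record] objects.
#' @param path Output TSV path.
#' @export
write_genome_stats <- function(genomes, path) {
  tab <- genome_stats_table(genomes)
  tab$gc_percent <- round(tab$gc_percent, 1)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Circularly rotate a genome
#'
#' Returns the record with sequence `s[offset..] + s[..offset]` (0-based
#' offset), i.e. the new origin is placed `offset` bases downstream of the
#' old one. Offsets are normalized modulo the genome length.
#'
#' @param record A circular [genome_record].
#' @param offset Shift in bp.
#' @return Rotated [genome_record].
#' @export
rotate_genome <- function(record, offset) {
  stopifnot(inherits(record, "genome_record"))
  if (!record$circular) stop("rotate_genome: record is not circular", call. = FALSE)
  L <- nchar(record$sequence)
  offset <- ((as.integer(offset) %% L) + L) %% L
  if (offset == 0L) return(record)
  record$sequence <- paste0(substr(record$sequence, offset + 1L, L),
                            substr(record$sequence, 1L, offset))
  record
}

revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Detect the rotation of one circular genome relative to another
#'
#' Finds the circular shift `offset` (and strand) such that rotating the
#' query by `-offset` (after reverse-complementing when strand is `"-"`)
#' places the position homologous to the reference start at the origin, i.e.
#' the query reads as the reference rotated by `offset`. Anchor
#' k-mers from the reference that are unique within the reference are located
#' in the query (both strands); on repeated misses up to `max_anchors`
#' successive anchors are tried, and for genomes up to `exhaustive_max` bp an
#' exhaustive scoring of all rotations (minimum Hamming distance on the
#' forward strand, then reverse complement) is the final fallback.
#'
#' @param reference,query Circular [genome_record] objects.
#' @param anchor_k Anchor k-mer size, at least 11 (default 31).
#' @param max_anchors Number of successive anchors to try before falling back.
#' @param exhaustive_max Maximum length for the exhaustive fallback.
#' @return List with `offset` (bp, in `[0, L)`) and `strand` (`"+"`/`"-"`).
#' @export
detect_rotation <- function(reference, query, anchor_k = 31L,
                            max_anchors = 50L, exhaustive_max = 50000L) {
  stopifnot(inherits(reference, "genome_record"), inherits(query, "genome_record"))
  if (!reference$circular || !query$circular) {
    stop("detect_rotation: both genomes must be circular", call. = FALSE)
  }
  anchor_k <- as.integer(anchor_k)
  if (anchor_k < 11L) stop("detect_rotation: anchor_k must be >= 11", call. = FALSE)
  ref <- reference$sequence
  qry <- query$sequence
  Lr <- nchar(ref)
  Lq <- nchar(qry)
  if (Lr < anchor_k || Lq < anchor_k) {
    stop("detect_rotation: sequences shorter than anchor_k", call. = FALSE)
  }
  # doubled circles so anchors spanning the origin are still found; the
  # reverse strand is searched on the doubled reverse complement of the
  # query circle so reported offsets refer to that circle
  wrap <- min(anchor_k - 1L, Lq)
  qry2 <- paste0(qry, substr(qry, 1L, wrap))
  qrc <- revcomp(qry)
  qrc2 <- paste0(qrc, substr(qrc, 1L, wrap))
  tried <- 0L
  for (p in seq_len(Lr - anchor_k + 1L)) {
    anchor <- substr(ref, p, p + anchor_k - 1L)
    if (grepl("N", anchor, fixed = TRUE)) next
    if (count_fixed(ref, anchor) != 1L) next
    tried <- tried + 1L
    q <- find_fixed(qry2, anchor)
    if (length(q) >= 1L) {
      off <- (((p - 1L) - (q[1L] - 1L)) %% Lq + Lq) %% Lq
      return(list(offset = off, strand = "+"))
    }
    qr <- find_fixed(qrc2, anchor)
    if (length(qr) >= 1L) {
      off <- (((p - 1L) - (qr[1L] - 1L)) %% Lq + Lq) %% Lq
      return(list(offset = off, strand = "-"))
    }
    if (tried >= max_anchors) break
  }
  if (Lq <= exhaustive_max && Lr <= exhaustive_max) {
    return(rotation_by_exhaustion(ref, qry))
  }
  stop("detect_rotation: no anchor k-mer found on either strand (unalignable)",
       call. = FALSE)
}

count_fixed <- function(haystack, needle) {
  length(find_fixed(haystack, needle))
}

find_fixed <- function(haystack, needle) {
  hits <- gregexpr(needle, haystack, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) integer(0) else as.integer(hits)
}

# Exhaustive rotation scoring: Hamming distance over min(Lr, Lq) leading
# positions for every rotation of the query, forward then reverse strand.
# The returned offset follows the anchor convention: rotating the (strand-
# adjusted) query by -offset aligns it with the reference.
rotation_by_exhaustion <- function(ref, qry) {
  best <- best_rotation_hamming(ref, qry)
  best_rc <- best_rotation_hamming(ref, revcomp(qry))
  if (best_rc$score < best$score) {
    list(offset = best_rc$offset, strand = "-")
  } else {
    list(offset = best$offset, strand = "+")
  }
}

best_rotation_hamming <- function(ref, qry) {
  n <- min(nchar(ref), nchar(qry))
  Lq <- nchar(qry)
  r <- strsplit(substr(ref, 1L, n), "", fixed = TRUE)[[1L]]
  q2 <- strsplit(paste0(qry, qry), "", fixed = TRUE)[[1L]]
  ri <- match(r, c("A", "C", "G", "T"))
  qi <- match(q2, c("A", "C", "G", "T"))
  scores <- vapply(0:(Lq - 1L), function(r0) {
    m <- ri != qi[r0 + seq_len(n)]
    m[is.na(m)] <- TRUE  # N counts as mismatch
    sum(m)
  }, 0)
  r0 <- which.min(scores) - 1L  # rotate(qry, r0) best matches ref
  list(offset = ((-r0) %% Lq + Lq) %% Lq, score = scores[r0 + 1L])
}
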