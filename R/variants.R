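#' Call SNPs and INDEL regions from a pairwise alignment
#'
#' A SNP is an alignment column where both rows carry unequal unambiguous
#' bases (`A`, `C`, `G`, `T`); columns with `N` in either row are ignored.
#' An INDEL region is a maximal run of contiguous gap columns in one row
#' ("continuous INDELs" counted as one event); its `inserted_in` label is
#' the row that carries the bases. Gap runs in opposite rows are never
#' merged across the row switch. Terminal gap runs - typically artifacts of
#' aligning circular genomes whose starts were not normalized - are excluded
#' by default.
#'
#' @param aln A `pairwise_alignment` (2-row [msa], no all-gap columns).
#' @param include_terminal_gaps Keep gap runs touching either alignment end
#'   (default `FALSE`).
#' @return A `variant_set` list: `snps` (data.frame `column` (0-based),
#'   `base_a`, `base_b`), `indel_regions` (data.frame `start` (0-based
#'   column), `length`, `inserted_in`), `ids`, `genome_a_len`,
#'   `genome_b_len`.
#' @export
#' @examples
#' aln <- msa(c(a = "ACG-TA", b = "ACGCTA"))
#' call_variants(aln)
call_variants <- function(aln, include_terminal_gaps = FALSE) {
  m <- msa_matrix(aln)
  if (nrow(m) != 2L) stop("call_variants: need exactly two rows", call. = FALSE)
  L <- ncol(m)
  a <- m[1L, ]
  b <- m[2L, ]
  if (any(a == "-" & b == "-")) {
    stop("call_variants: column gapped in both rows; not a pairwise alignment",
         call. = FALSE)
  }
  ids <- rownames(m)
  ai <- match(a, c("A", "C", "G", "T"))
  bi <- match(b, c("A", "C", "G", "T"))
  is_snp <- !is.na(ai) & !is.na(bi) & ai != bi
  snps <- data.frame(column = which(is_snp) - 1L,
                     base_a = a[is_snp], base_b = b[is_snp],
                     stringsAsFactors = FALSE)
  regions <- rbind(gap_runs(a, ids[2L]), gap_runs(b, ids[1L]))
  if (nrow(regions) > 0L) {
    regions <- regions[order(regions$start), , drop = FALSE]
    if (!include_terminal_gaps) {
      keep <- regions$start > 0L & (regions$start + regions$length) < L
      regions <- regions[keep, , drop = FALSE]
    }
    rownames(regions) <- NULL
  }
  structure(list(snps = snps, indel_regions = regions, ids = ids,
                 genome_a_len = sum(a != "-"), genome_b_len = sum(b != "-")),
            class = "variant_set")
}

gap_runs <- function(row_chars, carrier_id) {
  r <- rle(row_chars == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based starts
  gap <- r$values
  data.frame(start = starts[gap], length = r$lengths[gap],
             inserted_in = rep(carrier_id, sum(gap)),
             stringsAsFactors = FALSE)
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> %s vs %s: %d SNPs, %d INDEL region(s) (%d gap bp)\n",
              x$ids[1L], x$ids[2L], nrow(x$snps), nrow(x$indel_regions),
              sum(x$indel_regions$length)))
  invisible(x)
}

#' Summarize a variant set
#'
#' Percentages use the shorter of the two ungapped genome lengths as the
#' default denominator; `"alignment"` uses the alignment column count
#' instead. `indel_bp` is the total number of gap columns across INDEL
#' regions. Values are unrounded; round only for presentation.
#'
#' @param vs A `variant_set`.
#' @param denominator `"shorter_genome"` (default) or `"alignment"`.
#' @return List with `n_snps`, `snp_percent`, `n_indel_regions`, `indel_bp`,
#'   `indel_percent`, `denominator`.
#' @export
summarize_variants <- function(vs, denominator = c("shorter_genome", "alignment")) {
  denominator <- match.arg(denominator)
  denom <- switch(denominator,
                  shorter_genome = min(vs$genome_a_len, vs$genome_b_len),
                  alignment = {
                    # alignment length = ungapped length + gaps in the other row
                    vs$genome_a_len + sum(vs$indel_regions$length[
                      vs$indel_regions$inserted_in == vs$ids[2L]])
                  })
  if (denom == 0L) stop("summarize_variants: zero denominator", call. = FALSE)
  indel_bp <- sum(vs$indel_regions$length)
  list(n_snps = nrow(vs$snps),
       snp_percent = 100 * nrow(vs$snps) / denom,
       n_indel_regions = nrow(vs$indel_regions),
       indel_bp = indel_bp,
       indel_percent = 100 * indel_bp / denom,
       denominator = denom)
}

#' Per-window SNP and INDEL-region counts
#'
#' Uses the same window grid as [sliding_pi]: starts `0, step, ...` with
#' `start + window <= L`. A SNP is counted in every window containing its
#' column; an INDEL region is counted in every window containing its start
#' column (so a region spanning a window boundary is counted once per
#' window, at its start).
#'
#' @param aln A `pairwise_alignment`.
#' @param window,step Window width and step in columns (defaults 500/200).
#' @param ... Passed to [call_variants].
#' @return data.frame `start`, `end`, `snp_count`, `indel_region_count`.
#' @export
windowed_variant_counts <- function(aln, window = 500L, step = 200L, ...) {
  L <- msa_length(aln)
  window <- as.integer(window)
  step <- as.integer(step)
  if (window > L) stop("windowed_variant_counts: window exceeds alignment length",
                       call. = FALSE)
  vs <- call_variants(aln, ...)
  starts <- seq.int(0L, L - window, by = step)
  count_in <- function(pos) {
    vapply(starts, function(s) sum(pos >= s & pos < s + window), 0L)
  }
  data.frame(start = starts, end = starts + window,
             snp_count = count_in(vs$snps$column),
             indel_region_count = count_in(vs$indel_regions$start))
}

#' Export a variant set as VCF-like TSV and/or BED
#'
#' The TSV has columns CHROM (fixed label "alignment"), POS (1-based
#' alignment column), REF, ALT, TYPE (`SNP`/`INDEL`), LEN. INDEL regions can
#' also be written as BED3 with the carrier row in the name column.
#'
#' @param vs A `variant_set`.
#' @param path Output path.
#' @param format `"tsv"` or `"bed"` (BED of INDEL regions only).
#' @export
write_variants <- function(vs, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    snp <- if (nrow(vs$snps)) {
      data.frame(CHROM = "alignment", POS = vs$snps$column + 1L,
                 REF = vs$snps$base_a, ALT = vs$snps$base_b,
                 TYPE = "SNP", LEN = 1L)
    }
    ind <- if (nrow(vs$indel_regions)) {
      data.frame(CHROM = "alignment", POS = vs$indel_regions$start + 1L,
                 REF = ".", ALT = vs$indel_regions$inserted_in,
                 TYPE = "INDEL", LEN = vs$indel_regions$length)
    }
    out <- rbind(snp, ind)
    if (is.null(out)) {
      out <- data.frame(CHROM = character(0), POS = integer(0),
                        REF = character(0), ALT = character(0),
                        TYPE = character(0), LEN = integer(0))
    }
    out <- out[order(out$POS), , drop = FALSE]
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    bed <- data.frame(chrom = "alignment", start = vs$indel_regions$start,
                      end = vs$indel_regions$start + vs$indel_regions$length,
                      name = vs$indel_regions$inserted_in)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
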