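#' Minimum repeat-count thresholds for SSR detection
#'
#' One minimum repeat count per unit size 1-10. The defaults are the
#' smallest thresholds consistent with SSR total lengths of (mostly) 10 bp
#' or more: mono >= 10 repeats, di >= 5, tri >= 4, tetra >= 3, penta/hexa
#' >= 2 (two units is the "potential" class), hepta-deca >= 2.
#'
#' @return Named integer vector of length 10.
#' @export
ssr_thresholds <- function() {
  stats::setNames(c(10L, 5L, 4L, 3L, 2L, 2L, 2L, 2L, 2L, 2L),
                  c("mono", "di", "tri", "tetra", "penta",
                    "hexa", "hepta", "octa", "nona", "deca"))
}

#' Classify an SSR by unit size and repeat count
#'
#' Classes follow the three-class scheme: unit sizes 1-6 meeting their
#' length thresholds are `"normal"`, except that exactly two units of a 5-
#' or 6-bp motif are `"potential"`; unit sizes 7-10 are `"extended"`.
#' Combinations below threshold are not SSRs and return `NA_character_`.
#'
#' @param unit_len Unit size(s), 1-10.
#' @param repeat_count Repeat count(s), >= 2.
#' @param thresholds Minimum repeat counts per unit size ([ssr_thresholds]).
#' @return Character vector of `"normal"`, `"potential"`, `"extended"`, or
#'   `NA_character_` for below-threshold combinations.
#' @export
#' @examples
#' classify_ssr(5, 2)  # "potential"
#' classify_ssr(5, 3)  # "normal"
#' classify_ssr(7, 2)  # "extended"
classify_ssr <- function(unit_len, repeat_count, thresholds = ssr_thresholds()) {
  stopifnot(all(unit_len >= 1L & unit_len <= 10L), all(repeat_count >= 2L))
  n <- max(length(unit_len), length(repeat_count))
  unit_len <- rep_len(as.integer(unit_len), n)
  repeat_count <- rep_len(as.integer(repeat_count), n)
  out <- rep(NA_character_, n)
  ok <- repeat_count >= thresholds[unit_len]
  out[ok & unit_len >= 7L] <- "extended"
  out[ok & unit_len %in% 5:6 & repeat_count == 2L] <- "potential"
  out[ok & unit_len %in% 5:6 & repeat_count >= 3L] <- "normal"
  out[ok & unit_len <= 4L] <- "normal"
  out
}

# Smallest period of a string (== nchar(u) iff u is primitive).
primitive_period <- function(u) {
  k <- nchar(u)
  for (p in seq_len(k - 1L)) {
    if (k %% p == 0L && u == strrep(substr(u, 1L, p), k %/% p)) return(p)
  }
  k
}

#' Canonical form of a repeat unit
#'
#' The lexicographically smallest rotation of the unit; used as the grouping
#' key so that the same motif observed in different phases compares equal.
#'
#' @param unit Nucleotide string(s).
#' @return Canonical rotation(s).
#' @export
canonical_unit <- function(unit) {
  vapply(unit, function(u) {
    k <- nchar(u)
    if (k <= 1L) return(u)
    d <- paste0(u, u)
    min(vapply(seq_len(k), function(i) substr(d, i, i + k - 1L), ""))
  }, "", USE.NAMES = FALSE)
}

#' Find perfect tandem repeats (SSRs) in a genome
#'
#' Scans every unit size 1-10 for maximal perfect tandem runs of primitive
#' units meeting the per-class thresholds. For each maximal periodic region
#' the run is reported from its leftmost position with
#' `floor(region_length / unit_len)` repeats; runs whose unit is itself a
#' repetition of a shorter motif are covered at the smaller unit size and
#' not re-reported. With `circular_scan`, runs crossing the origin are also
#' detected (repeat counts capped at `floor(L / unit_len)`); coordinates of
#' origin-spanning SSRs keep `start < L` with `end` extending past `L`.
#'
#' @param record A [genome_record] (or plain nucleotide string).
#' @param thresholds Minimum repeat counts per unit size ([ssr_thresholds]).
#' @param circular_scan Join runs across the origin (default `FALSE`).
#' @return data.frame with columns `genome_id`, `start`, `end` (0-based
#'   half-open bp), `unit` (genomic phase), `unit_len`, `repeat_count`,
#'   `total_len`, `ssr_class`, sorted by `start`.
#' @export
#' @examples
#' find_ssrs(genome_record("GGATATATATATCC", "toy"))
find_ssrs <- function(record, thresholds = ssr_thresholds(),
                      circular_scan = FALSE) {
  if (is.character(record)) record <- genome_record(record, "seq")
  s <- record$sequence
  L <- nchar(s)
  scan_len <- L
  if (circular_scan && record$circular && L >= 2L) {
    # append one wrap (minus 1 so a fully periodic circle is not re-counted
    # beyond one full turn per starting phase)
    s <- paste0(s, substr(s, 1L, L - 1L))
    scan_len <- nchar(s)
  }
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  res <- list()
  for (k in 1:10) {
    if (scan_len < 2L * k) next
    eq <- ch[seq_len(scan_len - k)] == ch[(k + 1L):scan_len]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values & r$lengths >= k)) {
      st <- starts[i]
      if (circular_scan && st > L) next  # same run, later phase of the wrap
      period_len <- r$lengths[i] + k
      reps <- period_len %/% k
      if (circular_scan) reps <- min(reps, L %/% k)
      if (reps < thresholds[k]) next
      unit <- substr(s, st, st + k - 1L)
      if (anyNA(match(strsplit(unit, "")[[1L]], c("A", "C", "G", "T")))) next
      if (primitive_period(unit) != k) next
      cls <- classify_ssr(k, reps, thresholds)
      if (is.na(cls)) next
      res[[length(res) + 1L]] <- data.frame(
        genome_id = record$accession, start = st - 1L,
        end = st - 1L + reps * k, unit = unit, unit_len = k,
        repeat_count = reps, total_len = reps * k, ssr_class = cls,
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) {
    return(data.frame(genome_id = character(0), start = integer(0),
                      end = integer(0), unit = character(0),
                      unit_len = integer(0), repeat_count = integer(0),
                      total_len = integer(0), ssr_class = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  if (circular_scan) {
    # drop linear runs wholly contained in an origin-spanning run of the
    # same canonical unit
    cu <- canonical_unit(out$unit)
    wrapped <- out$end > L
    drop <- rep(FALSE, nrow(out))
    for (w in which(wrapped)) {
      cover <- cu == cu[w] & !wrapped &
        (out$start >= out$start[w] | out$end <= out$end[w] - L)
      drop <- drop | cover
    }
    out <- out[!drop, , drop = FALSE]
  }
  out <- out[order(out$start, out$unit_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-genome SSR count table with dispersion statistics
#'
#' Counts SSRs by unit-size type (mono..deca) and class for each genome and
#' reports, per type and in total, the across-genome mean, sample standard
#' deviation, and coefficient of variation `CV = 100 * SD / mean`. With a
#' single genome the SD and CV are reported as `NA`.
#'
#' @param records_by_genome Named list of SSR data.frames ([find_ssrs]).
#' @return List with `counts` (genome x type data.frame, plus `total` and
#'   per-class columns) and `dispersion` (type, mean, sd, cv).
#' @export
ssr_summary <- function(records_by_genome) {
  stopifnot(length(records_by_genome) >= 1L)
  types <- names(ssr_thresholds())
  classes <- c("normal", "potential", "extended")
  counts <- lapply(records_by_genome, function(df) {
    by_type <- table(factor(types[df$unit_len], levels = types))
    by_class <- table(factor(df$ssr_class, levels = classes))
    c(as.integer(by_type), as.integer(by_class), nrow(df))
  })
  tab <- as.data.frame(do.call(rbind, counts))
  names(tab) <- c(types, classes, "total")
  tab <- cbind(genome = names(records_by_genome), tab)
  rownames(tab) <- NULL
  single <- nrow(tab) < 2L
  disp <- do.call(rbind, lapply(c(types, classes, "total"), function(ty) {
    v <- tab[[ty]]
    m <- mean(v)
    s <- if (single) NA_real_ else stats::sd(v)
    data.frame(type = ty, mean = m, sd = s,
               cv = if (!single && m > 0) 100 * s / m else NA_real_)
  }))
  list(counts = tab, dispersion = disp)
}

#' Export SSR records as TSV or BED6
#'
#' @param ssrs data.frame from [find_ssrs].
#' @param path Output path.
#' @param format `"tsv"` (all columns) or `"bed"` (BED6: genome, start, end,
#'   unit x repeats, repeat count as score, `+` strand).
#' @export
write_ssrs <- function(ssrs, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(ssrs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    bed <- data.frame(chrom = ssrs$genome_id, start = ssrs$start,
                      end = ssrs$end,
                      name = paste0("(", ssrs$unit, ")x", ssrs$repeat_count),
                      score = ssrs$repeat_count, strand = "+")
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
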