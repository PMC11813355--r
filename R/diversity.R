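#' Nei-Li nucleotide diversity of an alignment
#'
#' Computes pi as the mean, over all unordered row pairs, of the proportion
#' of differing sites among compared sites. Under the default
#' pairwise-deletion policy a site is compared for a pair when both rows
#' carry an unambiguous base (`A`, `C`, `G`, `T`) in that column; gaps and
#' `N` are excluded per pair. Under complete deletion only columns where
#' every row carries an unambiguous base are used for all pairs.
#'
#' @param x An [msa] with at least two rows, or a character matrix as from
#'   [msa_matrix].
#' @param gap_policy `"pairwise"` (default) or `"complete"` deletion.
#' @return Nucleotide diversity (nonnegative scalar).
#' @export
#' @examples
#' nucleotide_diversity(msa(c(a = "AAAA", b = "AATT")))  # 0.5
nucleotide_diversity <- function(x, gap_policy = c("pairwise", "complete")) {
  gap_policy <- match.arg(gap_policy)
  m <- if (is.matrix(x)) x else msa_matrix(x)
  if (nrow(m) < 2L) stop("nucleotide_diversity: need at least 2 rows", call. = FALSE)
  b <- matrix(match(m, c("A", "C", "G", "T")), nrow = nrow(m))  # NA = gap or N
  if (gap_policy == "complete") {
    keep <- colSums(is.na(b)) == 0L
    b <- b[, keep, drop = FALSE]
  }
  n <- nrow(b)
  pairs <- utils::combn(n, 2L)
  props <- apply(pairs, 2L, function(p) {
    bi <- b[p[1L], ]
    bj <- b[p[2L], ]
    comp <- !is.na(bi) & !is.na(bj)
    ncomp <- sum(comp)
    if (ncomp == 0L) {
      stop(sprintf("nucleotide_diversity: rows '%s' and '%s' share no comparable sites",
                   rownames(m)[p[1L]], rownames(m)[p[2L]]), call. = FALSE)
    }
    sum(bi[comp] != bj[comp]) / ncomp
  })
  mean(props)
}

#' Sliding-window nucleotide diversity
#'
#' Evaluates [nucleotide_diversity] on consecutive column windows of the
#' alignment. Window coordinates are alignment columns (0-based, half-open);
#' only full windows are emitted, so the window starts are
#' `0, step, 2*step, ...` with `start + window_size <= length`.
#'
#' @param x An [msa].
#' @param window_size Window width in columns (default 500).
#' @param step Step between window starts (default 200).
#' @inheritParams nucleotide_diversity
#' @return A `window_series`: data.frame with columns `start`, `end`, `pi`
#'   and attributes `window_size`, `step`.
#' @export
sliding_pi <- function(x, window_size = 500L, step = 200L,
                       gap_policy = c("pairwise", "complete")) {
  gap_policy <- match.arg(gap_policy)
  m <- msa_matrix(x)
  L <- ncol(m)
  window_size <- as.integer(window_size)
  step <- as.integer(step)
  stopifnot(window_size >= 1L, step >= 1L)
  if (window_size > L) {
    stop("sliding_pi: window_size exceeds alignment length", call. = FALSE)
  }
  starts <- seq.int(0L, L - window_size, by = step)
  pi <- vapply(starts, function(s) {
    nucleotide_diversity(m[, (s + 1L):(s + window_size), drop = FALSE],
                         gap_policy = gap_policy)
  }, 0)
  window_series(data.frame(start = starts, end = starts + window_size, pi = pi),
                window_size = window_size, step = step)
}

window_series <- function(df, window_size, step) {
  stopifnot(all(c("start", "end", "pi") %in% names(df)))
  structure(df, window_size = as.integer(window_size), step = as.integer(step),
            class = c("window_series", "data.frame"))
}

#' Segment a diversity profile into homogeneous regions
#'
#' Recursive binary mean-shift segmentation: each segment is split at the
#' boundary that maximally reduces the within-segment sum of squared
#' deviations; a split is accepted only when the cost reduction exceeds
#' `penalty` and both sides keep at least `min_segment_windows` windows.
#' The default penalty is a BIC-style `2 * sigma2 * log(n)` with the noise
#' variance `sigma2` estimated robustly from first differences of the
#' series, which keeps the procedure deterministic and scale-aware.
#'
#' @param series A `window_series` (or data.frame with a `pi` column).
#' @param min_segment_windows Minimum windows per segment (default 10).
#' @param penalty Cost-reduction threshold for accepting a split; `NULL`
#'   (default) uses the BIC-style rule above.
#' @return A `region_segmentation` list with `boundaries` (column indices at
#'   segment starts, excluding 0), `boundary_windows` (window indices,
#'   1-based), `segment_means`, and `segments` (data.frame with window and
#'   column extents and mean pi).
#' @export
segment_regions <- function(series, min_segment_windows = 10L, penalty = NULL) {
  pi <- series$pi
  n <- length(pi)
  min_segment_windows <- as.integer(min_segment_windows)
  if (n < 2L * min_segment_windows) {
    stop("segment_regions: need at least 2 * min_segment_windows windows",
         call. = FALSE)
  }
  if (is.null(penalty)) {
    # noise SD from robust first differences; when windows overlap (step <
    # window) adjacent values share data and lag-1 differences understate
    # the noise, so difference at the smallest overlap-free lag instead
    lag <- 1L
    w <- attr(series, "window_size"); st <- attr(series, "step")
    if (!is.null(w) && !is.null(st) && st < w) lag <- ceiling(w / st)
    lag <- min(lag, max(1L, n - min_segment_windows))
    d <- pi[(lag + 1L):n] - pi[seq_len(n - lag)]
    sigma <- stats::median(abs(d)) / (0.6745 * sqrt(2))
    penalty <- 2 * max(sigma^2, .Machine$double.eps) * log(n)
  }
  cuts <- integer(0)
  recurse <- function(lo, hi) {
    len <- hi - lo + 1L
    if (len < 2L * min_segment_windows) return(invisible())
    seg <- pi[lo:hi]
    best <- best_single_split(seg, min_segment_windows)
    if (is.null(best) || best$gain <= penalty) return(invisible())
    cut <- lo + best$k - 1L  # last window index of the left part
    cuts <<- c(cuts, cut)
    recurse(lo, cut)
    recurse(cut + 1L, hi)
  }
  recurse(1L, n)
  cuts <- sort(cuts)
  seg_start <- c(1L, cuts + 1L)
  seg_end <- c(cuts, n)
  means <- vapply(seq_along(seg_start),
                  function(i) mean(pi[seg_start[i]:seg_end[i]]), 0)
  segs <- data.frame(
    first_window = seg_start, last_window = seg_end,
    start = series$start[seg_start], end = series$end[seg_end],
    mean_pi = means)
  structure(list(boundaries = series$start[cuts + 1L],
                 boundary_windows = cuts + 1L,
                 segment_means = means,
                 segments = segs),
            class = "region_segmentation")
}

# Optimal single split of a numeric vector into a prefix/suffix, by
# within-segment SSE reduction. Returns NULL when no admissible split.
best_single_split <- function(x, min_len) {
  n <- length(x)
  ks <- min_len:(n - min_len)
  if (length(ks) == 0L || ks[1L] > ks[length(ks)]) return(NULL)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  total <- cs2[n] - cs[n]^2 / n
  sse <- vapply(ks, function(k) {
    left <- cs2[k] - cs[k]^2 / k
    right <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
    left + right
  }, 0)
  i <- which.min(sse)
  list(k = ks[i], gain = total - sse[i])
}

#' @export
print.region_segmentation <- function(x, ...) {
  cat(sprintf("<region_segmentation> %d segment(s)\n", length(x$segment_means)))
  print(x$segments)
  invisible(x)
}

#' Detect diversity peaks in a window series
#'
#' Windows with `pi > mean + z_threshold * SD` (population SD by default)
#' are marked; runs of marked windows separated by at most `merge_gap`
#' unmarked windows are merged into one peak. A zero-variance series yields
#' no peaks.
#'
#' @param series A `window_series`.
#' @param z_threshold Threshold in SD units above the mean (default 2).
#' @param merge_gap Maximum unmarked windows bridged when merging (default 1).
#' @param sd_type `"population"` (divide by n, default) or `"sample"`.
#' @return data.frame of peaks with columns `start`, `end` (columns),
#'   `first_window`, `last_window`, `max_pi`, `annotation` (empty string,
#'   filled by [annotate_intervals]).
#' @export
detect_peaks <- function(series, z_threshold = 2, merge_gap = 1L,
                         sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  pi <- series$pi
  n <- length(pi)
  if (n == 0L) stop("detect_peaks: empty series", call. = FALSE)
  mu <- mean(pi)
  s <- stats::sd(pi)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  empty <- data.frame(start = integer(0), end = integer(0),
                      first_window = integer(0), last_window = integer(0),
                      max_pi = numeric(0), annotation = character(0))
  if (is.na(s) || s == 0) return(empty)
  marked <- pi > mu + z_threshold * s
  if (!any(marked)) return(empty)
  idx <- which(marked)
  grp <- cumsum(c(1L, diff(idx) > merge_gap + 1L))
  rows <- lapply(split(idx, grp), function(w) {
    data.frame(start = series$start[min(w)], end = series$end[max(w)],
               first_window = min(w), last_window = max(w),
               max_pi = max(pi[min(w):max(w)]), annotation = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read genome features from a GFF3 file
#'
#' Thin wrapper over `rtracklayer::import` returning the minimal feature
#' table consumed by [annotate_intervals]. Feature names are taken from the
#' `Name` attribute, falling back to `gene`, `ID`, then type.
#'
#' @param path GFF3 file path.
#' @param types Feature types to keep (default `"gene"`; `NULL` keeps all).
#' @return data.frame with columns `name`, `start`, `end` (1-based closed,
#'   reference coordinates), sorted by `start`.
#' @export
read_features <- function(path, types = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_features requires the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(path)
  if (!is.null(types)) gr <- gr[as.character(gr$type) %in% types]
  md <- as.data.frame(gr)
  nm <- md$Name
  if (is.null(nm)) nm <- rep(NA_character_, nrow(md))
  for (alt in c("gene", "ID", "type")) {
    if (alt %in% names(md)) nm <- ifelse(is.na(nm), as.character(md[[alt]]), nm)
  }
  out <- data.frame(name = nm, start = md$start, end = md$end,
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' Map alignment columns to one row's ungapped coordinates
#'
#' @param x An [msa].
#' @param row Row id or index used as the reference.
#' @return Integer vector of length `msa_length(x)`: for each column, the
#'   1-based position in the ungapped reference row, or `NA` where the
#'   reference has a gap.
#' @export
column_map_from_row <- function(x, row) {
  ch <- strsplit(unclass(x)[[row]], "", fixed = TRUE)[[1L]]
  pos <- cumsum(ch != "-")
  pos[ch == "-"] <- NA_integer_
  as.integer(pos)
}

#' Annotate peak intervals with overlapping or flanking features
#'
#' Each peak's alignment-column interval is mapped to reference coordinates
#' through `column_map`; features overlapping the mapped interval are listed
#' in genomic order, joined by `","`. Peaks falling between two features are
#' annotated with both flanking names joined by `"-"` (the style used for
#' intergenic diversity peaks); intervals with no mapped columns are
#' annotated `"unplaced"`.
#'
#' @param peaks data.frame from [detect_peaks] (columns `start`, `end`).
#' @param features data.frame as from [read_features] (`name`, `start`,
#'   `end`, 1-based closed).
#' @param column_map Integer vector mapping alignment columns to reference
#'   positions ([column_map_from_row]); must be monotone over non-`NA`
#'   entries.
#' @return `peaks` with the `annotation` column filled.
#' @export
annotate_intervals <- function(peaks, features, column_map) {
  nn <- column_map[!is.na(column_map)]
  if (is.unsorted(nn)) {
    stop("annotate_intervals: column_map must be monotone", call. = FALSE)
  }
  if (nrow(peaks) == 0L) return(peaks)
  ann <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    cols <- (peaks$start[i] + 1L):peaks$end[i]
    cols <- cols[cols >= 1L & cols <= length(column_map)]
    mapped <- column_map[cols]
    mapped <- mapped[!is.na(mapped)]
    if (length(mapped) == 0L) { ann[i] <- "unplaced"; next }
    lo <- min(mapped); hi <- max(mapped)
    if (nrow(features) == 0L) { ann[i] <- ""; next }
    hit <- features$start <= hi & features$end >= lo
    if (any(hit)) {
      ann[i] <- paste(features$name[hit][order(features$start[hit])],
                      collapse = ",")
    } else {
      left <- features$name[features$end < lo]
      right <- features$name[features$start > hi]
      lname <- if (length(left)) left[length(left)] else NA_character_
      rname <- if (length(right)) right[1L] else NA_character_
      ann[i] <- paste(stats::na.omit(c(lname, rname)), collapse = "-")
    }
  }
  peaks$annotation <- ann
  peaks
}

#' Export a window series as TSV or BED4
#'
#' BED intervals are in alignment space (0-based half-open), with pi as the
#' BED name/score column.
#'
#' @param series A `window_series`.
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @param track_name Chrom/track label used in the BED first column.
#' @export
write_window_series <- function(series, path, format = c("tsv", "bed"),
                                track_name = "alignment") {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(series), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    bed <- data.frame(chrom = track_name, start = series$start,
                      end = series$end, name = signif(series$pi, 6))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
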