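#' Extract the flanking sequences of an SSR
#'
#' Returns the `flank_len` bases ending at the SSR start and the
#' `flank_len` bases from the SSR end. On circular genomes flanks wrap
#' through the origin; on linear genomes too short for a full flank the
#' flank is truncated with a warning.
#'
#' @param record The [genome_record] the SSR was found in.
#' @param ssr One-row data.frame (or list) with at least `start`, `end`,
#'   `unit`, `repeat_count`, `ssr_class` as produced by [find_ssrs].
#' @param flank_len Flank length in bp (default 60).
#' @return A `flanked_ssr` list: `ssr`, `left_flank`, `right_flank`,
#'   `genome_id`.
#' @export
extract_flanks <- function(record, ssr, flank_len = 60L) {
  stopifnot(inherits(record, "genome_record"))
  flank_len <- as.integer(flank_len)
  L <- nchar(record$sequence)
  start <- as.integer(ssr$start)
  end <- as.integer(ssr$end)
  if (start < 0L || end > L + start || end < start) {
    stop("extract_flanks: SSR does not lie in the record", call. = FALSE)
  }
  take <- function(positions) {
    if (length(positions) == 0L) return("")
    paste(substring(record$sequence, positions, positions), collapse = "")
  }
  if (record$circular) {
    left_pos <- ((start - flank_len):(start - 1L)) %% L + 1L
    right_pos <- (end:(end + flank_len - 1L)) %% L + 1L
    left <- if (flank_len) take(left_pos) else ""
    right <- if (flank_len) take(right_pos) else ""
  } else {
    lo <- max(0L, start - flank_len)
    hi <- min(L, end + flank_len)
    left <- substr(record$sequence, lo + 1L, start)
    right <- substr(record$sequence, end + 1L, hi)
    if (nchar(left) < flank_len || nchar(right) < flank_len) {
      warning("extract_flanks: linear record too short, flank truncated")
    }
  }
  structure(list(ssr = as.list(ssr), left_flank = left, right_flank = right,
                 genome_id = record$accession),
            class = "flanked_ssr")
}

#' Flank all SSRs of one genome
#'
#' @param record A [genome_record].
#' @param ssrs data.frame from [find_ssrs] for that record.
#' @inheritParams extract_flanks
#' @return List of `flanked_ssr` objects.
#' @export
extract_all_flanks <- function(record, ssrs, flank_len = 60L) {
  lapply(seq_len(nrow(ssrs)), function(i)
    extract_flanks(record, ssrs[i, , drop = FALSE], flank_len))
}

#' Compare the flanks of two SSRs
#'
#' Each side is globally aligned ([global_align]); identity is
#' matches / alignment columns and coverage is the number of columns where
#' both flanks carry a base, divided by the nominal flank length. The pair
#' matches when identity and coverage on both sides all reach their
#' thresholds (inclusive, i.e. a value of exactly 0.90 passes the default).
#'
#' @param a,b `flanked_ssr` objects.
#' @param min_identity,min_coverage Thresholds in `[0, 1]` (defaults 0.90).
#' @param flank_len Nominal flank length used in the coverage denominator
#'   (default: the longer of the observed flank lengths).
#' @param scoring [align_scoring] used for the flank alignments.
#' @return List `match` (logical), `left_identity`, `right_identity`,
#'   `left_coverage`, `right_coverage`.
#' @export
flanks_match <- function(a, b, min_identity = 0.9, min_coverage = 0.9,
                         flank_len = NULL, scoring = align_scoring()) {
  side <- function(fa, fb) {
    if (nchar(fa) == 0L || nchar(fb) == 0L) {
      stop("flanks_match: empty flank", call. = FALSE)
    }
    nominal <- if (is.null(flank_len)) max(nchar(fa), nchar(fb)) else flank_len
    aln <- global_align(fa, fb, scoring = scoring)
    m <- msa_matrix(aln)
    ncols <- ncol(m)
    both <- m[1L, ] != "-" & m[2L, ] != "-"
    ident <- sum(both & m[1L, ] == m[2L, ]) / ncols
    cover <- sum(both) / nominal
    c(ident, cover)
  }
  l <- side(a$left_flank, b$left_flank)
  r <- side(a$right_flank, b$right_flank)
  list(match = l[1L] >= min_identity && r[1L] >= min_identity &&
         l[2L] >= min_coverage && r[2L] >= min_coverage,
       left_identity = l[1L], right_identity = r[1L],
       left_coverage = l[2L], right_coverage = r[2L])
}

#' Group SSRs across genomes by flanking-sequence similarity
#'
#' Builds a graph over all flanked SSRs with an edge wherever both flanks
#' match at the identity/coverage thresholds; groups are the connected
#' components (an order-independent closure of the pairwise relation). Only
#' SSRs with identical canonical repeat units are eligible for an edge.
#' Components with a single member are "unique SSRs".
#'
#' @param flanked_by_genome Named list (one element per genome) of lists of
#'   `flanked_ssr` objects ([extract_all_flanks]).
#' @inheritParams flanks_match
#' @return List with `groups` (list of `ssr_group`: `members` data.frame,
#'   `shared_in`, `same_unit`, `repeat_counts`, `repeat_variation`) and
#'   `members` (flat data.frame with a `group_id` column).
#' @export
group_ssrs <- function(flanked_by_genome, min_identity = 0.9,
                       min_coverage = 0.9, scoring = align_scoring()) {
  stopifnot(length(flanked_by_genome) >= 1L)
  flat <- unlist(flanked_by_genome, recursive = FALSE, use.names = FALSE)
  n <- length(flat)
  if (n == 0L) return(list(groups = list(), members = empty_group_members()))
  meta <- data.frame(
    genome = vapply(flat, function(f) f$genome_id, ""),
    start = vapply(flat, function(f) as.integer(f$ssr$start), 0L),
    unit = vapply(flat, function(f) as.character(f$ssr$unit), ""),
    unit_len = vapply(flat, function(f) as.integer(f$ssr$unit_len), 0L),
    repeats = vapply(flat, function(f) as.integer(f$ssr$repeat_count), 0L),
    class = vapply(flat, function(f) as.character(f$ssr$ssr_class), ""),
    stringsAsFactors = FALSE)
  meta$canonical <- canonical_unit(meta$unit)
  edges <- matrix(integer(0), ncol = 2L)
  # canonical-unit pre-filter: identical motifs only, a documented
  # efficiency choice with results identical to post-filtering
  for (key in unique(meta$canonical)) {
    idx <- which(meta$canonical == key)
    if (length(idx) < 2L) next
    cmb <- utils::combn(idx, 2L)
    for (c_i in seq_len(ncol(cmb))) {
      i <- cmb[1L, c_i]; j <- cmb[2L, c_i]
      fm <- flanks_match(flat[[i]], flat[[j]], min_identity, min_coverage,
                         scoring = scoring)
      if (fm$match) edges <- rbind(edges, c(i, j))
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  meta$group_id <- comp
  groups <- lapply(sort(unique(comp)), function(gid) {
    mem <- meta[meta$group_id == gid, , drop = FALSE]
    structure(list(
      members = mem[, c("genome", "start", "unit", "unit_len", "repeats", "class")],
      shared_in = length(unique(mem$genome)),
      same_unit = length(unique(mem$canonical)) == 1L,
      repeat_counts = mem$repeats,
      repeat_variation = length(unique(mem$repeats)) > 1L),
      class = "ssr_group")
  })
  list(groups = groups, members = meta)
}

empty_group_members <- function() {
  data.frame(genome = character(0), start = integer(0), unit = character(0),
             unit_len = integer(0), repeats = integer(0), class = character(0),
             canonical = character(0), group_id = integer(0),
             stringsAsFactors = FALSE)
}

#' Summarize SSR groups by sharing level
#'
#' Tabulates, per number of genomes represented, how many groups are unique
#' (one genome) or shared, plus the number of groups with repeat-number
#' variation. When `hosts` is given the table is additionally computed per
#' host species over that host's genomes.
#'
#' @param grouping Result of [group_ssrs].
#' @param hosts Optional named character vector mapping genome id to host.
#' @return List with `by_sharing` (data.frame `shared_in`, `n_groups`,
#'   `n_repeat_variation`) and, when `hosts` is given, `by_host`.
#' @export
ssr_group_summary <- function(grouping, hosts = NULL) {
  gs <- grouping$groups
  shared <- vapply(gs, function(g) g$shared_in, 0L)
  rv <- vapply(gs, function(g) g$repeat_variation, FALSE)
  by_sharing <- do.call(rbind, lapply(sort(unique(shared)), function(s) {
    data.frame(shared_in = s, n_groups = sum(shared == s),
               n_repeat_variation = sum(rv[shared == s]))
  }))
  if (is.null(by_sharing)) {
    by_sharing <- data.frame(shared_in = integer(0), n_groups = integer(0),
                             n_repeat_variation = integer(0))
  }
  out <- list(by_sharing = by_sharing)
  if (!is.null(hosts)) {
    rows <- lapply(gs, function(g) {
      hs <- unique(hosts[g$members$genome])
      data.frame(host = if (length(hs) == 1L) hs else "multiple",
                 shared_in = g$shared_in, repeat_variation = g$repeat_variation)
    })
    tab <- do.call(rbind, rows)
    out$by_host <- do.call(rbind, lapply(split(tab, tab$host), function(d) {
      data.frame(host = d$host[1L],
                 unique_ssrs = sum(d$shared_in == 1L),
                 shared_groups = sum(d$shared_in > 1L),
                 repeat_variation_groups = sum(d$repeat_variation))
    }))
    rownames(out$by_host) <- NULL
  }
  out
}

#' Export SSR groups as TSV
#'
#' One row per member with its group id, sharing level and repeat-variation
#' flag.
#'
#' @param grouping Result of [group_ssrs].
#' @param path Output path.
#' @export
write_ssr_groups <- function(grouping, path) {
  meta <- grouping$members
  shared <- vapply(grouping$groups, function(g) g$shared_in, 0L)
  rv <- vapply(grouping$groups, function(g) g$repeat_variation, FALSE)
  meta$shared_in <- shared[meta$group_id]
  meta$repeat_variation <- rv[meta$group_id]
  cols <- c("group_id", "genome", "start", "unit", "repeats", "class",
            "shared_in", "repeat_variation")
  utils::write.table(meta[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
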