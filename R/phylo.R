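#' Tamura-Nei (TN93) distance between two gapped rows
#'
#' Distance under the Tamura-Nei 1993 model, distinguishing purine
#' transitions, pyrimidine transitions and transversions with empirical
#' base frequencies, computed from the sites where both rows carry an
#' unambiguous base (pairwise deletion). Saturated pairs, where a logarithm
#' argument becomes nonpositive and the distance is undefined, are reported
#' as `max_distance` with a warning.
#'
#' @param row_a,row_b Gapped or ungapped nucleotide strings.
#' @param max_distance Value substituted on saturation (default 10).
#' @return TN93 distance (nonnegative scalar).
#' @export
tn93_distance <- function(row_a, row_b, max_distance = 10) {
  d <- tn93_matrix(msa(c(a = row_a, b = row_b)), max_distance = max_distance)
  d["a", "b"]
}

#' TN93 distance matrix of an alignment
#'
#' @param x An [msa].
#' @param max_distance Value substituted for saturated pairs (default 10).
#' @return Symmetric numeric matrix with zero diagonal, labelled by row ids.
#' @export
tn93_matrix <- function(x, max_distance = 10) {
  m <- msa_matrix(x)
  bin <- ape::as.DNAbin(tolower(m))
  d <- as.matrix(ape::dist.dna(bin, model = "TN93", pairwise.deletion = TRUE))
  bad <- !is.finite(d)
  if (any(bad)) {
    warning("tn93_matrix: saturated pair(s) set to max_distance")
    d[bad] <- max_distance
    diag(d) <- 0
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining; on an additive matrix the generating
#' topology is recovered with exact branch lengths.
#'
#' @param d Symmetric distance matrix (or `dist`) with at least 3 labels.
#' @return Unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("nj_tree: need at least 3 labels", call. = FALSE)
  if (is.null(rownames(d))) stop("nj_tree: matrix must be labelled", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8) {
    stop("nj_tree: matrix is not symmetric", call. = FALSE)
  }
  ape::nj(stats::as.dist(d))
}

#' Neighbor-joining tree straight from an alignment
#'
#' Convenience wrapper: TN93 distances ([tn93_matrix]) followed by
#' [nj_tree]. Also used to build a host tree from a marker-gene (e.g. COI)
#' alignment when no externally estimated host tree is supplied.
#'
#' @param x An [msa].
#' @param max_distance Passed to [tn93_matrix].
#' @return Unrooted `phylo`.
#' @export
nj_from_alignment <- function(x, max_distance = 10) {
  nj_tree(tn93_matrix(x, max_distance = max_distance))
}

#' Nontrivial bipartitions of a tree
#'
#' Each internal edge of the unrooted tree defines a bipartition of the tip
#' set; bipartitions are canonicalized (the side not containing the
#' alphabetically first tip, tips sorted and joined by `"|"`) so they can
#' be compared across trees with `%in%`.
#'
#' @param tree A `phylo`.
#' @return Character vector of canonical split keys.
#' @export
tree_splits <- function(tree) {
  if (ape::Ntip(tree) < 4L) return(character(0))  # no nontrivial splits
  tree <- ape::unroot(tree)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  anchor <- sort(labs)[1L]
  keys <- vapply(pp, function(s) {
    tips <- labs[s]
    if (length(tips) <= 1L || length(tips) >= length(labs) - 1L) return(NA_character_)
    if (anchor %in% tips) tips <- setdiff(labs, tips)
    paste(sort(tips), collapse = "|")
  }, "")
  unique(keys[!is.na(keys)])
}

#' Robinson-Foulds distance between two trees
#'
#' Number of nontrivial bipartitions present in exactly one of the two
#' trees (unrooted). Zero iff the topologies are identical.
#'
#' @param t1,t2 `phylo` trees over the same tip set.
#' @return Integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("rf_distance: trees have different tip sets", call. = FALSE)
  }
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement `replicates` times
#' (seeded, reproducible); for every internal bipartition of the full-data
#' NJ/TN93 tree the support is the percentage of replicate trees containing
#' that bipartition. Edges below `collapse_below` (percent) can optionally
#' be collapsed into polytomies.
#'
#' @param x An [msa] with at least 4 rows.
#' @param replicates Number of pseudoreplicates (>= 1; the full-scale
#'   analysis convention is 5,000).
#' @param seed Integer seed for the resampling.
#' @param max_distance Passed to [tn93_matrix].
#' @param collapse_below Support threshold in percent below which internal
#'   edges are collapsed; `NULL` (default) keeps the full topology.
#' @return List of class `support_tree`: `tree` (`phylo` with support
#'   percentages as `node.label`, `NA` on trivial nodes), `support` (named
#'   vector, split key -> percent), `replicates`.
#' @export
bootstrap_support <- function(x, replicates = 100L, seed = 1L,
                              max_distance = 10, collapse_below = NULL) {
  replicates <- as.integer(replicates)
  stopifnot(replicates >= 1L)
  m <- msa_matrix(x)
  if (nrow(unique(t(m))) < 2L) {
    stop("bootstrap_support: fewer than 2 distinct columns, supports undefined",
         call. = FALSE)
  }
  full <- nj_tree(tn93_matrix(x, max_distance = max_distance))
  keys <- tree_splits(full)
  counts <- stats::setNames(numeric(length(keys)), keys)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  for (b in seq_len(replicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    xb <- msa(apply(m[, cols, drop = FALSE], 1L, paste, collapse = ""))
    tb <- suppressWarnings(nj_tree(tn93_matrix(xb, max_distance = max_distance)))
    hit <- keys %in% tree_splits(tb)
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / replicates
  full$node.label <- node_support_labels(full, support)
  if (!is.null(collapse_below)) {
    full <- collapse_unsupported(full, support, collapse_below)
  }
  structure(list(tree = full, support = support, replicates = replicates),
            class = "support_tree")
}

# Map split supports onto internal-node labels of a phylo tree.
node_support_labels <- function(tree, support) {
  tree2 <- ape::unroot(tree)
  pp <- ape::prop.part(tree2)
  labs <- attr(pp, "labels")
  anchor <- sort(labs)[1L]
  vapply(seq_along(pp), function(i) {
    tips <- labs[pp[[i]]]
    if (length(tips) <= 1L || length(tips) >= length(labs) - 1L) return(NA_real_)
    if (anchor %in% tips) tips <- setdiff(labs, tips)
    key <- paste(sort(tips), collapse = "|")
    unname(support[key])
  }, 0)
}

# Collapse internal edges whose child-clade split support is below the
# threshold (percent) into polytomies.
collapse_unsupported <- function(tree, support, threshold) {
  tree <- ape::unroot(tree)
  repeat {
    labels <- node_support_labels(tree, support)
    weak <- which(!is.na(labels) & labels < threshold)
    if (length(weak) == 0L) return(tree)
    node <- weak[1L] + ape::Ntip(tree)
    edge_i <- which(tree$edge[, 2L] == node)
    if (length(edge_i) == 0L) return(tree)
    tree$edge.length[edge_i] <- 0
    tree <- ape::di2multi(tree, tol = 1e-12)
  }
}

#' @export
print.support_tree <- function(x, ...) {
  cat(sprintf("<support_tree> %d tips, %d replicates\n",
              ape::Ntip(x$tree), x$replicates))
  invisible(x)
}

#' Root a tree on an outgroup for presentation
#'
#' @param tree A `phylo`.
#' @param outgroup Tip label.
#' @return Rooted `phylo`.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) {
    stop(sprintf("root_on_outgroup: tip '%s' not in tree", outgroup), call. = FALSE)
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Host-symbiont congruence report
#'
#' Checks (1) whether the symbiont genomes of each host with more than one
#' genome are monophyletic (form a bipartition of the unrooted symbiont
#' tree); (2) condenses the symbiont tree to one representative tip per
#' host (alphabetically first accession; hosts violating monophyly are
#' flagged but still condensed); (3) reports the Robinson-Foulds distance
#' between the condensed symbiont tree and the host tree; and (4) lists the
#' hosts involved in conflicting bipartitions.
#'
#' @param symbiont_tree `phylo` over symbiont genome ids.
#' @param host_tree `phylo` over host species names.
#' @param tip_map Named character vector: symbiont tip -> host species.
#' @return List: `monophyly` (data.frame `host`, `n_genomes`,
#'   `monophyletic`), `condensed_tree`, `rf_distance`, `max_rf`,
#'   `conflicting_hosts`, `congruent` (logical).
#' @export
compare_topologies <- function(symbiont_tree, host_tree, tip_map) {
  tips <- symbiont_tree$tip.label
  unmapped <- setdiff(tips, names(tip_map))
  if (length(unmapped) > 0L) {
    stop(sprintf("compare_topologies: unmapped symbiont tip(s): %s",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  }
  hosts <- tip_map[tips]
  splits <- tree_splits(symbiont_tree)
  anchor <- sort(tips)[1L]
  multi <- names(which(table(hosts) > 1L))
  monophyly <- do.call(rbind, lapply(multi, function(h) {
    set <- sort(tips[hosts == h])
    mono <- if (length(set) >= length(tips) - 1L) TRUE else {
      key_set <- if (anchor %in% set) sort(setdiff(tips, set)) else set
      paste(key_set, collapse = "|") %in% splits
    }
    data.frame(host = h, n_genomes = length(set), monophyletic = mono,
               stringsAsFactors = FALSE)
  }))
  if (is.null(monophyly)) {
    monophyly <- data.frame(host = character(0), n_genomes = integer(0),
                            monophyletic = logical(0))
  }
  # condense: one representative per host, relabelled to the host name
  keep <- vapply(split(tips, hosts), function(v) sort(v)[1L], "")
  condensed <- ape::keep.tip(symbiont_tree, unname(keep))
  condensed$tip.label <- names(keep)[match(condensed$tip.label, keep)]
  missing_hosts <- setdiff(condensed$tip.label, host_tree$tip.label)
  if (length(missing_hosts) > 0L) {
    stop(sprintf("compare_topologies: host tree lacks: %s",
                 paste(missing_hosts, collapse = ", ")), call. = FALSE)
  }
  host_tree <- ape::keep.tip(host_tree, condensed$tip.label)
  s_sym <- tree_splits(condensed)
  s_host <- tree_splits(host_tree)
  conflict <- c(setdiff(s_sym, s_host), setdiff(s_host, s_sym))
  conflicting_hosts <- sort(unique(unlist(lapply(conflict, function(k) {
    side <- strsplit(k, "|", fixed = TRUE)[[1L]]
    if (length(side) <= length(condensed$tip.label) / 2) side
    else setdiff(condensed$tip.label, side)
  }))))
  rf <- length(conflict)
  n <- length(condensed$tip.label)
  list(monophyly = monophyly, condensed_tree = condensed,
       rf_distance = rf, max_rf = 2L * max(n - 3L, 0L),
       conflicting_hosts = conflicting_hosts,
       pairing = data.frame(symbiont = tips, host = unname(hosts),
                            stringsAsFactors = FALSE),
       congruent = rf == 0L && all(monophyly$monophyletic))
}

#' Write a congruence report as TSV plus a pairing list
#'
#' @param report Result of [compare_topologies].
#' @param path Output TSV path for the monophyly table; a plain-text
#'   summary (RF distance, conflicting hosts, and the symbiont-host
#'   pairing list) is written to `paste0(path, ".txt")`.
#' @export
write_congruence_report <- function(report, path) {
  utils::write.table(report$monophyly, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  txt <- c(sprintf("rf_distance\t%d", report$rf_distance),
           sprintf("max_rf\t%d", report$max_rf),
           sprintf("congruent\t%s", report$congruent),
           sprintf("conflicting_hosts\t%s",
                   paste(report$conflicting_hosts, collapse = ",")),
           "",
           sprintf("%s -- %s", report$pairing$symbiont, report$pairing$host))
  writeLines(txt, paste0(path, ".txt"))
  invisible(path)
}
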