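BASES <- c("A", "C", "G", "T")

#' Simulation configuration for synthetic genome sets
#'
#' Describes an ancestral circular genome and its evolution along a rooted
#' tree: an HKY substitution process whose rate is scaled per region of a
#' three-region (in general, k-region) mosaic, geometric-length indels,
#' tandem repeats planted into the ancestor before evolution (so that
#' descendants can diverge in repeat number through slippage events), and a
#' random circular rotation of every tip sequence. Defaults emulate a
#' low-GC endosymbiont genome set at desk scale.
#'
#' @param genome_length Ancestor length in bp before SSR planting
#'   (default 20000).
#' @param gc_target GC fraction in (0, 1) of the ancestor (default 0.25).
#' @param region_breaks Strictly increasing fractional positions in (0, 1)
#'   delimiting the rate mosaic (default `c(1/3, 2/3)`, a three-region
#'   structure).
#' @param region_rate_multipliers One positive multiplier per region
#'   (`length(region_breaks) + 1`; default `c(1, 3, 1.5)`).
#' @param tree Rooted tree with branch lengths in expected
#'   substitutions/site: a `phylo` or Newick string. Default: four tips in
#'   two cherries.
#' @param kappa HKY transition/transversion rate ratio (default 2).
#' @param indel_rate Indel events per site per unit branch length
#'   (default 0.05, roughly the SNP:INDEL-region ratio seen in
#'   endosymbiont genome pairs).
#' @param indel_mean_length Mean of the geometric indel-length
#'   distribution (default 3).
#' @param indel_max_length Truncation of indel lengths (default 50).
#' @param ssr_plants data.frame with columns `unit`, `count`, `position`
#'   (fractional position in (0,1)); units must be primitive, counts >= 2.
#'   `NULL` disables planting; the default plants four repeats of unit
#'   sizes 1, 2, 3 and 5.
#' @param slippage_prob Probability per planted SSR per branch of a +/-1
#'   unit repeat-number change (default 0.1).
#' @param rotate Randomly rotate each tip sequence (default `TRUE`).
#' @param hosts Optional named character vector tip -> host species.
#' @param seed Integer seed (default 1).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 20000L,
                       gc_target = 0.25,
                       region_breaks = c(1 / 3, 2 / 3),
                       region_rate_multipliers = c(1, 3, 1.5),
                       tree = "((t1:0.02,t2:0.02):0.01,(t3:0.02,t4:0.02):0.01);",
                       kappa = 2,
                       indel_rate = 0.05,
                       indel_mean_length = 3,
                       indel_max_length = 50L,
                       ssr_plants = default_ssr_plants(),
                       slippage_prob = 0.1,
                       rotate = TRUE,
                       hosts = NULL,
                       seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.null(tree) || !inherits(tree, "phylo") || ape::Ntip(tree) < 1L) {
    stop("sim_config: tree must be a non-empty rooted phylo/Newick", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("sim_config: tree must have branch lengths", call. = FALSE)
  }
  genome_length <- as.integer(genome_length)
  if (genome_length < 1L) stop("sim_config: zero-length genome", call. = FALSE)
  if (!(gc_target > 0 && gc_target < 1)) {
    stop("sim_config: gc_target must lie in (0, 1)", call. = FALSE)
  }
  if (length(region_breaks) > 0L) {
    if (any(diff(region_breaks) <= 0) || any(region_breaks <= 0) ||
        any(region_breaks >= 1)) {
      stop("sim_config: region_breaks must be strictly increasing within (0, 1)",
           call. = FALSE)
    }
  }
  if (length(region_rate_multipliers) != length(region_breaks) + 1L) {
    stop("sim_config: need one rate multiplier per region", call. = FALSE)
  }
  if (any(region_rate_multipliers <= 0)) {
    stop("sim_config: rate multipliers must be positive", call. = FALSE)
  }
  if (indel_rate < 0 || slippage_prob < 0 || kappa <= 0) {
    stop("sim_config: rates must be nonnegative and kappa positive", call. = FALSE)
  }
  if (!is.null(ssr_plants) && nrow(ssr_plants) > 0L) {
    for (i in seq_len(nrow(ssr_plants))) {
      u <- toupper(ssr_plants$unit[i])
      if (grepl("[^ACGT]", u)) {
        stop("sim_config: SSR plant units must be DNA over {A,C,G,T}", call. = FALSE)
      }
      if (primitive_period(u) != nchar(u)) {
        stop(sprintf("sim_config: plant unit '%s' is not primitive", u), call. = FALSE)
      }
      if (ssr_plants$count[i] < 2L) {
        stop("sim_config: plant repeat counts must be >= 2", call. = FALSE)
      }
    }
    ssr_plants$unit <- toupper(ssr_plants$unit)
  }
  structure(list(genome_length = genome_length, gc_target = gc_target,
                 region_breaks = region_breaks,
                 region_rate_multipliers = region_rate_multipliers,
                 tree = tree, kappa = kappa, indel_rate = indel_rate,
                 indel_mean_length = indel_mean_length,
                 indel_max_length = as.integer(indel_max_length),
                 ssr_plants = ssr_plants, slippage_prob = slippage_prob,
                 rotate = isTRUE(rotate), hosts = hosts,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default SSR plants of the simulator
#' @return data.frame with columns `unit`, `count`, `position`.
#' @export
default_ssr_plants <- function() {
  data.frame(unit = c("A", "AT", "AAT", "ACGTG"),
             count = c(12L, 7L, 5L, 3L),
             position = c(0.12, 0.37, 0.62, 0.85),
             stringsAsFactors = FALSE)
}

#' Read a simulation configuration from YAML
#'
#' Scalar fields as in [sim_config]; `tree` as a Newick string;
#' `ssr_plants` as a list of `{unit, count, position}` mappings.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$ssr_plants)) {
    y$ssr_plants <- do.call(rbind, lapply(y$ssr_plants, function(p)
      data.frame(unit = p$unit, count = as.integer(p$count),
                 position = p$position, stringsAsFactors = FALSE)))
  }
  do.call(sim_config, y)
}

#' Insert a perfect tandem repeat into a sequence
#'
#' @param sequence Nucleotide string.
#' @param unit Primitive repeat unit over `{A,C,G,T}`.
#' @param count Repeat count, >= 2.
#' @param position 0-based insertion index (`0` prepends).
#' @return Sequence with `unit` repeated `count` times inserted at
#'   `position`; the length grows by `count * nchar(unit)`.
#' @export
#' @examples
#' plant_ssr("GGGGGG", "AT", 5, 3)  # "GGGATATATATATGGG"
plant_ssr <- function(sequence, unit, count, position) {
  unit <- toupper(unit)
  if (grepl("[^ACGT]", unit)) {
    stop("plant_ssr: unit must be DNA over {A,C,G,T}", call. = FALSE)
  }
  if (primitive_period(unit) != nchar(unit)) {
    stop("plant_ssr: unit is not primitive", call. = FALSE)
  }
  count <- as.integer(count)
  if (count < 2L) stop("plant_ssr: count must be >= 2", call. = FALSE)
  position <- as.integer(position)
  L <- nchar(sequence)
  if (position < 0L || position > L) stop("plant_ssr: position out of range", call. = FALSE)
  paste0(substr(sequence, 1L, position), strrep(unit, count),
         substr(sequence, position + 1L, L))
}

# HKY transition-probability matrix at time t (expected substitutions/site),
# computed by eigendecomposition of the frequency-scaled rate matrix.
hky_pmatrix <- function(t, freqs, kappa) {
  Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  transitions <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    rate <- freqs[j]
    if (any(transitions[, 1] == BASES[i] & transitions[, 2] == BASES[j])) {
      rate <- rate * kappa
    }
    Q[i, j] <- rate
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))  # mean rate, normalized to 1 sub/site/unit time
  Q <- Q / mu
  e <- eigen(Q)
  P <- Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate a genome set with known ground truth
#'
#' Builds a random ancestor at the target GC, plants the configured SSRs,
#' then evolves the genome down the configured tree: HKY substitutions with
#' per-region rate multipliers, indel events of geometric length, and
#' repeat-slippage events on planted SSRs; finally each tip is randomly
#' rotated when `rotate` is on. The same config and seed always produce
#' byte-identical output.
#'
#' @param config A [sim_config].
#' @return List with `genomes` (named list of [genome_record], one per tip)
#'   and `truth`: `tree`, `ancestor` (string), `rotations` (named bp
#'   offsets such that rotating a tip by `-offset` restores the unrotated
#'   frame), `variant_events` (data.frame `branch`, `position` (0-based, in
#'   the evolving sequence at event time), `type`
#'   (`substitution`/`insertion`/`deletion`/`slippage`), `detail`,
#'   `region`), `planted_ssrs` (ancestor coordinates), `tip_ssrs`
#'   (per-tip state of every planted SSR: final repeat count, whether still
#'   intact, start in the emitted sequence), `region_intervals` (ancestor
#'   coordinates with multipliers).
#' @export
simulate_genome_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  gc <- config$gc_target
  freqs <- stats::setNames(c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2), BASES)
  anc <- sample.int(4L, config$genome_length, replace = TRUE, prob = freqs)

  # plant SSRs (largest position first so earlier insertions do not shift
  # later insertion points), then record final ancestor coordinates
  plants <- config$ssr_plants
  planted <- data.frame(ssr_id = integer(0), start = integer(0),
                        unit = character(0), count = integer(0))
  if (!is.null(plants) && nrow(plants) > 0L) {
    ord <- order(plants$position, decreasing = TRUE)
    starts <- integer(nrow(plants))
    for (i in ord) {
      pos <- as.integer(round(plants$position[i] * length(anc)))
      pos <- max(0L, min(length(anc), pos))
      ins <- match(strsplit(strrep(plants$unit[i], plants$count[i]), "")[[1L]], BASES)
      anc <- append(anc, ins, after = pos)
      starts[i] <- pos
      shifted <- ord[seq_len(which(ord == i) - 1L)]
      starts[shifted] <- starts[shifted] + length(ins)
    }
    planted <- data.frame(ssr_id = seq_len(nrow(plants)), start = starts,
                          unit = plants$unit, count = as.integer(plants$count),
                          stringsAsFactors = FALSE)
    # break the repeat periodicity just outside each plant so the planted
    # run is recovered with its exact start and repeat count
    other_base <- function(avoid) {
      pool <- setdiff(1:4, avoid)
      pool[sample.int(length(pool), 1L)]
    }
    for (i in seq_len(nrow(planted))) {
      k <- nchar(planted$unit[i])
      s <- planted$start[i]                 # 0-based start
      e <- s + k * planted$count[i]         # 0-based end (exclusive)
      if (s >= 1L && anc[s] == anc[s + k]) anc[s] <- other_base(anc[s + k])
      if (e + 1L <= length(anc) && anc[e + 1L] == anc[e + 1L - k]) {
        anc[e + 1L] <- other_base(anc[e + 1L - k])
      }
    }
  }

  L0 <- length(anc)
  breaks <- unique(pmin(L0, pmax(0L, as.integer(round(config$region_breaks * L0)))))
  bounds <- c(0L, breaks, L0)
  region <- rep(seq_len(length(bounds) - 1L), times = diff(bounds))
  region_intervals <- data.frame(start = bounds[-length(bounds)],
                                 end = bounds[-1L],
                                 multiplier = config$region_rate_multipliers)

  pmat_cache <- new.env(parent = emptyenv())
  pmat <- function(t) {
    key <- sprintf("%.12g", t)
    if (is.null(pmat_cache[[key]])) pmat_cache[[key]] <- hky_pmatrix(t, freqs, config$kappa)
    pmat_cache[[key]]
  }

  events <- list()
  record_events <- function(df) if (nrow(df) > 0L) events[[length(events) + 1L]] <<- df

  tree <- ape::reorder.phylo(config$tree, "cladewise")
  ntip <- ape::Ntip(tree)
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label)) tree$node.label
              else paste0("node", seq_len(tree$Nnode)))
  planted$intact <- rep(TRUE, nrow(planted))
  root_state <- list(seq = anc, region = region, ssrs = planted)
  planted$intact <- NULL
  states <- vector("list", ntip + tree$Nnode)
  states[[ntip + 1L]] <- root_state
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    b <- tree$edge.length[e]
    res <- evolve_branch(states[[parent]], b, config, pmat, labels[child])
    states[[child]] <- res$state
    record_events(res$events)
  }

  variant_events <- if (length(events)) do.call(rbind, events) else
    data.frame(branch = character(0), position = integer(0),
               type = character(0), detail = character(0), region = integer(0),
               stringsAsFactors = FALSE)
  rownames(variant_events) <- NULL

  genomes <- list()
  rotations <- stats::setNames(integer(ntip), tree$tip.label)
  tip_ssrs <- list()
  for (i in seq_len(ntip)) {
    st <- states[[i]]
    L <- length(st$seq)
    off <- 0L
    if (config$rotate) off <- sample.int(L, 1L) - 1L
    rotations[[tree$tip.label[i]]] <- off
    seq_chr <- paste(BASES[st$seq], collapse = "")
    host <- if (!is.null(config$hosts)) config$hosts[[tree$tip.label[i]]] else NA_character_
    rec <- genome_record(seq_chr, tree$tip.label[i], host, circular = TRUE)
    if (off > 0L) rec <- rotate_genome(rec, off)
    genomes[[tree$tip.label[i]]] <- rec
    ss <- st$ssrs
    if (nrow(ss) > 0L) {
      ss$start_unrotated <- ss$start
      ss$start <- (ss$start - off) %% L
      ss$genome <- tree$tip.label[i]
    }
    tip_ssrs[[tree$tip.label[i]]] <- ss
  }

  list(genomes = genomes,
       truth = list(tree = tree, ancestor = paste(BASES[anc], collapse = ""),
                    rotations = rotations, variant_events = variant_events,
                    planted_ssrs = planted,
                    tip_ssrs = do.call(rbind, tip_ssrs),
                    region_intervals = region_intervals))
}

# One branch of evolution: substitutions (region-scaled HKY), indels,
# then repeat slippage on still-intact planted SSRs.
evolve_branch <- function(state, b, config, pmat, branch_label) {
  seqv <- state$seq
  region <- state$region
  ssrs <- state$ssrs
  ev <- list()
  push <- function(position, type, detail, reg) {
    ev[[length(ev) + 1L]] <<- data.frame(
      branch = branch_label, position = as.integer(position), type = type,
      detail = detail, region = as.integer(reg), stringsAsFactors = FALSE)
  }

  if (b > 0) {
    # substitutions
    for (r in unique(region)) {
      t_eff <- b * config$region_rate_multipliers[r]
      P <- pmat(t_eff)
      idx <- which(region == r)
      cur <- seqv[idx]
      new <- cur
      for (base in 1:4) {
        sel <- which(cur == base)
        if (length(sel)) {
          new[sel] <- sample.int(4L, length(sel), replace = TRUE, prob = P[base, ])
        }
      }
      ch <- which(new != cur)
      if (length(ch)) {
        pos <- idx[ch]
        for (m in seq_along(ch)) {
          push(pos[m] - 1L, "substitution",
               sprintf("%s>%s", BASES[cur[ch[m]]], BASES[new[ch[m]]]), r)
        }
        seqv[pos] <- new[ch]
        if (nrow(ssrs) > 0L) {
          for (k in seq_len(nrow(ssrs))) {
            if (!ssrs$intact[k]) next
            s0 <- ssrs$start[k]
            s1 <- s0 + nchar(ssrs$unit[k]) * ssrs$count[k]
            if (any(pos - 1L >= s0 & pos - 1L < s1)) ssrs$intact[k] <- FALSE
          }
        }
      }
    }
    # indels
    n_indel <- stats::rpois(1L, config$indel_rate * length(seqv) * b)
    gc <- config$gc_target
    freqs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    for (j in seq_len(n_indel)) {
      L <- length(seqv)
      len <- min(1L + stats::rgeom(1L, prob = 1 / config$indel_mean_length),
                 config$indel_max_length)
      pos0 <- sample.int(L, 1L) - 1L  # 0-based
      if (stats::runif(1L) < 0.5) {
        ins <- sample.int(4L, len, replace = TRUE, prob = freqs)
        reg_src <- region[max(1L, pos0)]
        seqv <- append(seqv, ins, after = pos0)
        region <- append(region, rep(reg_src, len), after = pos0)
        push(pos0, "insertion", sprintf("+%d", len), reg_src)
        ssrs <- shift_ssrs(ssrs, pos0, len)
      } else {
        last <- min(L, pos0 + len)
        if (last <= pos0) next
        del_idx <- (pos0 + 1L):last
        reg_src <- region[del_idx[1L]]
        push(pos0, "deletion", sprintf("-%d", length(del_idx)), reg_src)
        ssrs <- shift_ssrs(ssrs, pos0, -(length(del_idx)))
        seqv <- seqv[-del_idx]
        region <- region[-del_idx]
      }
    }
  }
  # slippage
  if (nrow(ssrs) > 0L && config$slippage_prob > 0) {
    for (k in seq_len(nrow(ssrs))) {
      if (!ssrs$intact[k]) next
      if (stats::runif(1L) >= config$slippage_prob) next
      ulen <- nchar(ssrs$unit[k])
      delta <- sample(c(-1L, 1L), 1L)
      if (ssrs$count[k] + delta < 2L) delta <- 1L
      end0 <- ssrs$start[k] + ulen * ssrs$count[k]  # 0-based end
      if (delta > 0L) {
        unit_int <- match(strsplit(ssrs$unit[k], "")[[1L]], BASES)
        seqv <- append(seqv, unit_int, after = end0)
        region <- append(region, rep(region[max(1L, end0)], ulen), after = end0)
        if (nrow(ssrs) > 1L) {
          ssrs[-k, ] <- shift_ssrs(ssrs[-k, , drop = FALSE], end0, ulen)
        }
      } else {
        del_idx <- (end0 - ulen + 1L):end0
        seqv <- seqv[-del_idx]
        region <- region[-del_idx]
        if (nrow(ssrs) > 1L) {
          ssrs[-k, ] <- shift_ssrs(ssrs[-k, , drop = FALSE], end0 - ulen, -ulen)
        }
      }
      ssrs$count[k] <- ssrs$count[k] + delta
      push(ssrs$start[k], "slippage",
           sprintf("ssr%d:%+d", ssrs$ssr_id[k], delta), region[max(1L, ssrs$start[k])])
    }
  }
  list(state = list(seq = seqv, region = region, ssrs = ssrs),
       events = if (length(ev)) do.call(rbind, ev) else
         data.frame(branch = character(0), position = integer(0),
                    type = character(0), detail = character(0),
                    region = integer(0), stringsAsFactors = FALSE))
}

# Shift planted-SSR coordinates after an indel of signed length `len`
# applied just after 0-based position `pos0`; SSRs overlapped by a deletion
# are marked not intact.
shift_ssrs <- function(ssrs, pos0, len) {
  if (nrow(ssrs) == 0L) return(ssrs)
  for (k in seq_len(nrow(ssrs))) {
    s0 <- ssrs$start[k]
    s1 <- s0 + nchar(ssrs$unit[k]) * ssrs$count[k]
    if (len > 0L) {
      if (pos0 <= s0) {
        ssrs$start[k] <- s0 + len
      } else if (pos0 < s1) {
        ssrs$intact[k] <- FALSE  # insertion inside the repeat
      }
    } else {
      d0 <- pos0; d1 <- pos0 - len  # deleted interval [d0, d1)
      if (d1 <= s0) {
        ssrs$start[k] <- s0 + len
      } else if (d0 < s1) {
        ssrs$intact[k] <- FALSE  # deletion overlaps the repeat
      }
    }
  }
  ssrs
}

#' Write a simulated genome set and its truth tables
#'
#' Emits `genomes.fasta`, `tree.nwk`, `rotations.tsv`, `variants.tsv`,
#' `planted_ssrs.tsv`, `tip_ssrs.tsv`, `region_intervals.tsv` and
#' `config.yaml` into `dir`.
#'
#' @param sim Result of [simulate_genome_set].
#' @param dir Output directory (created if missing).
#' @param config The [sim_config] used (optional, for `config.yaml`).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, config = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_genomes(sim$genomes, file.path(dir, "genomes.fasta"))
  ape::write.tree(sim$truth$tree, file.path(dir, "tree.nwk"))
  wt <- function(df, name) utils::write.table(df, file.path(dir, name),
                                              sep = "\t", quote = FALSE,
                                              row.names = FALSE)
  wt(data.frame(tip = names(sim$truth$rotations),
                offset = as.integer(sim$truth$rotations)), "rotations.tsv")
  wt(sim$truth$variant_events, "variants.tsv")
  wt(sim$truth$planted_ssrs, "planted_ssrs.tsv")
  if (!is.null(sim$truth$tip_ssrs)) wt(sim$truth$tip_ssrs, "tip_ssrs.tsv")
  wt(sim$truth$region_intervals, "region_intervals.tsv")
  if (!is.null(config)) {
    y <- config[setdiff(names(config), c("tree", "ssr_plants", "hosts"))]
    y$tree <- ape::write.tree(config$tree)
    if (!is.null(config$ssr_plants)) {
      y$ssr_plants <- lapply(seq_len(nrow(config$ssr_plants)), function(i)
        as.list(config$ssr_plants[i, ]))
    }
    yaml::write_yaml(y, file.path(dir, "config.yaml"))
  }
  invisible(dir)
}
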