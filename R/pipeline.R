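#' Pipeline run configuration
#'
#' Exactly one of `genomes` (path to a multi-FASTA) or `simulation` (a
#' [sim_config]) must be given. Analysis parameters default to the
#' full-scale study conventions: 500/200 bp diversity windows, 60-bp SSR
#' flanks at 0.90 identity/coverage, TN93 distances with NJ and bootstrap
#' resampling.
#'
#' @param genomes Path to input genomes (FASTA), or `NULL`.
#' @param simulation A [sim_config], or `NULL`.
#' @param alignment Optional path to an externally produced aligned FASTA
#'   of the (rotation-normalized) genomes. When absent, equal-length
#'   genome sets (e.g. indel-free simulations) are treated as trivially
#'   aligned; with `aligner = "mafft"` a system `mafft` is invoked for
#'   desk-scale inputs.
#' @param aligner `"none"` (default) or `"mafft"`.
#' @param hosts Named character vector genome id -> host species (used for
#'   within-host variant pairs and congruence).
#' @param host_tree Optional Newick path or `phylo` of the host species.
#' @param outgroup Optional genome id used to root the symbiont tree at
#'   presentation.
#' @param rotate_to Rotation reference: `"longest"` (default), a genome id,
#'   or `NA` to skip rotation normalization.
#' @param window,step Diversity window size and step in columns.
#' @param z_threshold,merge_gap Peak detection parameters ([detect_peaks]).
#' @param min_segment_windows,penalty Segmentation parameters
#'   ([segment_regions]).
#' @param ssr_thresholds Minimum repeat counts ([ssr_thresholds]).
#' @param flank_len,min_identity,min_coverage SSR grouping parameters.
#' @param bootstrap_replicates NJ bootstrap pseudoreplicates (default 200
#'   at desk scale; the full-scale convention is 5000).
#' @param features Optional GFF3 path for peak annotation.
#' @param annotation_reference Row id whose coordinates anchor feature
#'   annotation (default: first row).
#' @param seed Integer seed for all stochastic stages.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(genomes = NULL, simulation = NULL, alignment = NULL,
                       aligner = c("none", "mafft"), hosts = NULL,
                       host_tree = NULL, outgroup = NULL,
                       rotate_to = "longest", window = 500L, step = 200L,
                       z_threshold = 2, merge_gap = 1L,
                       min_segment_windows = 10L, penalty = NULL,
                       ssr_thresholds = symbiovar::ssr_thresholds(),
                       flank_len = 60L, min_identity = 0.9,
                       min_coverage = 0.9, bootstrap_replicates = 200L,
                       features = NULL, annotation_reference = NULL,
                       seed = 1L) {
  aligner <- match.arg(aligner)
  if (is.null(genomes) == is.null(simulation)) {
    stop("run_config: exactly one of genomes/simulation must be given",
         call. = FALSE)
  }
  for (p in c(genomes, alignment, features,
              if (is.character(host_tree)) host_tree)) {
    if (!file.exists(p)) stop(sprintf("run_config: file not found: %s", p),
                              call. = FALSE)
  }
  structure(list(genomes = genomes, simulation = simulation,
                 alignment = alignment, aligner = aligner, hosts = hosts,
                 host_tree = host_tree, outgroup = outgroup,
                 rotate_to = rotate_to, window = as.integer(window),
                 step = as.integer(step), z_threshold = z_threshold,
                 merge_gap = as.integer(merge_gap),
                 min_segment_windows = as.integer(min_segment_windows),
                 penalty = penalty, ssr_thresholds = ssr_thresholds,
                 flank_len = as.integer(flank_len),
                 min_identity = min_identity, min_coverage = min_coverage,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 features = features,
                 annotation_reference = annotation_reference,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write a fully defaulted pipeline configuration as YAML
#'
#' Every analysis parameter appears explicitly with its default so a run
#' can be reproduced from the file alone.
#'
#' @param path Output YAML path.
#' @export
write_default_config <- function(path) {
  cfg <- list(
    genomes = "genomes.fasta", alignment = NULL, aligner = "none",
    rotate_to = "longest", window = 500L, step = 200L, z_threshold = 2,
    merge_gap = 1L, min_segment_windows = 10L,
    ssr_thresholds = as.list(ssr_thresholds()), flank_len = 60L,
    min_identity = 0.9, min_coverage = 0.9, bootstrap_replicates = 5000L,
    seed = 1L)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML path as written by [write_default_config].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$ssr_thresholds)) {
    y$ssr_thresholds <- stats::setNames(as.integer(unlist(y$ssr_thresholds)),
                                        names(y$ssr_thresholds))
  }
  if (!is.null(y$hosts)) y$hosts <- unlist(y$hosts)
  do.call(run_config, y)
}

#' Run the comparative-genomics pipeline end to end
#'
#' Stages, in order: load or simulate genomes; rotation-normalize circular
#' starts against the reference; align or ingest an alignment; sliding
#' nucleotide diversity with segmentation and peak detection; pairwise
#' SNP/INDEL calling (within-host pairs when hosts are known, otherwise all
#' pairs); SSR detection; cross-genome SSR grouping; NJ/TN93 phylogeny with
#' bootstrap (and host congruence when a host tree is available); report.
#' All stage outputs are written under `output_dir` and a JSON manifest
#' with parameters and file digests is returned (identical config and seed
#' give identical digests).
#'
#' @param config A [run_config].
#' @param output_dir Output directory (created).
#' @return The manifest, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config, output_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  outputs <- character(0)
  emit <- function(path) { outputs <<- c(outputs, path); path }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # -- genomes ---------------------------------------------------------
  sim <- NULL
  genomes <- stage("genomes", {
    if (!is.null(config$simulation)) {
      sim <- simulate_genome_set(config$simulation)
      write_simulation(sim, file.path(output_dir, "simulation"),
                       config$simulation)
      emit(file.path(output_dir, "simulation", "genomes.fasta"))
      sim$genomes
    } else {
      read_genomes(config$genomes, hosts = config$hosts)
    }
  })
  stage("stats", {
    write_genome_stats(genomes, emit(file.path(output_dir, "genome_stats.tsv")))
  })

  # -- rotation --------------------------------------------------------
  genomes <- stage("rotate", {
    if (length(genomes) < 2L || is.na(config$rotate_to)) genomes else {
      lens <- vapply(genomes, function(g) nchar(g$sequence), 0L)
      ref_id <- if (identical(config$rotate_to, "longest"))
        names(genomes)[which.max(lens)] else config$rotate_to
      ref <- genomes[[ref_id]]
      rot <- lapply(genomes, function(g) {
        if (g$accession == ref_id) return(g)
        r <- detect_rotation(ref, g)
        if (r$strand == "-") g$sequence <- revcomp(g$sequence)
        rotate_genome(g, -r$offset)
      })
      write_genomes(rot, emit(file.path(output_dir, "genomes_rotated.fasta")))
      rot
    }
  })

  # -- alignment -------------------------------------------------------
  aln <- stage("align", {
    if (!is.null(config$alignment)) {
      read_alignment(config$alignment)
    } else if (config$aligner == "mafft") {
      mafft_align(genomes, output_dir)
    } else {
      lens <- vapply(genomes, function(g) nchar(g$sequence), 0L)
      if (length(unique(lens)) != 1L) {
        stop("genomes are not equal length; supply an external alignment ",
             "or set aligner = 'mafft'")
      }
      msa(vapply(genomes, function(g) g$sequence, ""))
    }
  })
  stage("write_alignment", {
    write_alignment(aln, emit(file.path(output_dir, "alignment.fasta")))
  })

  # -- diversity -------------------------------------------------------
  series <- segments <- peaks <- NULL
  stage("diversity", {
    series <- sliding_pi(aln, config$window, config$step)
    write_window_series(series, emit(file.path(output_dir, "diversity.tsv")))
    write_window_series(series, emit(file.path(output_dir, "diversity.bed")),
                        format = "bed")
    if (nrow(series) >= 2L * config$min_segment_windows) {
      segments <- segment_regions(series, config$min_segment_windows,
                                   config$penalty)
      utils::write.table(segments$segments,
                         emit(file.path(output_dir, "regions.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    peaks <- detect_peaks(series, config$z_threshold, config$merge_gap)
    if (!is.null(config$features)) {
      ref_row <- if (is.null(config$annotation_reference)) 1L else
        config$annotation_reference
      peaks <- annotate_intervals(peaks, read_features(config$features),
                                   column_map_from_row(aln, ref_row))
    }
    utils::write.table(peaks, emit(file.path(output_dir, "peaks.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # -- variants --------------------------------------------------------
  variant_summaries <- stage("variants", {
    ids <- names(genomes)
    host_of <- vapply(genomes, function(g) g$host_species, "")
    pairs <- utils::combn(ids, 2L, simplify = FALSE)
    if (any(!is.na(host_of)) && length(unique(stats::na.omit(host_of))) > 1L) {
      pairs <- Filter(function(p) !is.na(host_of[[p[1L]]]) &&
                        identical(host_of[[p[1L]]], host_of[[p[2L]]]), pairs)
    }
    rows <- lapply(pairs, function(p) {
      vs <- call_variants(msa_pair(aln, p[1L], p[2L]))
      write_variants(vs, emit(file.path(
        output_dir, sprintf("variants_%s_%s.tsv", p[1L], p[2L]))))
      sm <- summarize_variants(vs)
      data.frame(genome_a = p[1L], genome_b = p[2L], n_snps = sm$n_snps,
                 snp_percent = sm$snp_percent,
                 n_indel_regions = sm$n_indel_regions,
                 indel_bp = sm$indel_bp, indel_percent = sm$indel_percent)
    })
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(genome_a = character(0), genome_b = character(0))
    utils::write.table(tab, emit(file.path(output_dir, "variant_summary.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tab
  })

  # -- SSRs ------------------------------------------------------------
  ssrs <- stage("ssr", {
    per_genome <- lapply(genomes, find_ssrs, thresholds = config$ssr_thresholds)
    for (id in names(per_genome)) {
      write_ssrs(per_genome[[id]],
                 emit(file.path(output_dir, sprintf("ssr_%s.tsv", id))))
    }
    summ <- ssr_summary(per_genome)
    utils::write.table(summ$counts, emit(file.path(output_dir, "ssr_counts.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summ$dispersion,
                       emit(file.path(output_dir, "ssr_dispersion.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    per_genome
  })

  grouping <- stage("ssr_compare", {
    flanked <- lapply(names(genomes), function(id)
      extract_all_flanks(genomes[[id]], ssrs[[id]], config$flank_len))
    names(flanked) <- names(genomes)
    gr <- group_ssrs(flanked, config$min_identity, config$min_coverage)
    write_ssr_groups(gr, emit(file.path(output_dir, "ssr_groups.tsv")))
    gr
  })

  # -- phylogeny -------------------------------------------------------
  phylo_out <- stage("phylo", {
    if (length(genomes) < 3L) return(NULL)
    bs <- bootstrap_support(aln, config$bootstrap_replicates,
                            seed = config$seed)
    tree <- bs$tree
    if (!is.null(config$outgroup) && config$outgroup %in% tree$tip.label) {
      tree <- root_on_outgroup(tree, config$outgroup)
    }
    ape::write.tree(tree, emit(file.path(output_dir, "nj_tree.nwk")))
    res <- list(support = bs)
    host_of <- vapply(genomes, function(g) g$host_species, "")
    if (!is.null(config$host_tree) && all(!is.na(host_of))) {
      ht <- if (inherits(config$host_tree, "phylo")) config$host_tree else
        ape::read.tree(config$host_tree)
      res$congruence <- compare_topologies(bs$tree, ht, host_of)
      write_congruence_report(res$congruence,
                              emit(file.path(output_dir, "congruence.tsv")))
    }
    res
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("symbiovar")),
    seed = config$seed,
    parameters = config[c("window", "step", "z_threshold", "merge_gap",
                          "min_segment_windows", "flank_len", "min_identity",
                          "min_coverage", "bootstrap_replicates")],
    n_genomes = length(genomes),
    input_digest = if (!is.null(config$genomes))
      unname(tools::md5sum(config$genomes)) else "simulated",
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# Desk-scale alignment through a system mafft, when available.
mafft_align <- function(genomes, output_dir) {
  if (Sys.which("mafft") == "") {
    stop("aligner = 'mafft' requested but mafft is not on the PATH")
  }
  fa <- file.path(output_dir, "genomes_for_alignment.fasta")
  write_genomes(genomes, fa)
  out <- file.path(output_dir, "mafft_alignment.fasta")
  status <- system2("mafft", c("--auto", "--quiet", shQuote(fa)),
                    stdout = out)
  if (status != 0L) stop("mafft failed")
  read_alignment(out)
}
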