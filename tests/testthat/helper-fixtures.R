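# Shared fixture builders (all data generated in code, no files).

# Wrap a numeric pi vector as a window_series on a unit grid so the
# segmentation/peak operations can be exercised directly.
window_series_for_test <- function(pi, window = 1L, step = 1L) {
  starts <- (seq_along(pi) - 1L) * step
  symbiovar:::window_series(
    data.frame(start = starts, end = starts + window, pi = pi),
    window_size = window, step = step)
}

# A tiny genome carrying one known SSR with fixed flanks, for grouping
# tests: flanks are shared across "genomes" unless mutated.
ssr_test_genome <- function(id, repeats = 5L, unit = "ACT",
                            left = NULL, right = NULL, seed = 99) {
  set.seed(seed)
  pad <- random_dna(70)
  if (is.null(left)) left <- random_dna(60)
  if (is.null(right)) right <- random_dna(60)
  genome_record(paste0(pad, left, strrep(unit, repeats), right, random_dna(70)),
                id)
}
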