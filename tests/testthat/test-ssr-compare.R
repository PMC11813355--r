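test_that("flank extraction uses half-open coordinates with circular wrap", {
  set.seed(61)
  seq200 <- random_dna(200)
  g <- genome_record(seq200, "g", circular = TRUE)
  ssr <- list(start = 60L, end = 70L, unit = "ACGTG", unit_len = 5L,
              repeat_count = 2L, ssr_class = "potential")
  f <- extract_flanks(g, ssr, 60)
  expect_equal(f$left_flank, substr(seq200, 1, 60))
  expect_equal(f$right_flank, substr(seq200, 71, 130))
  expect_equal(nchar(f$left_flank), 60L)

  # left flank wraps through the origin
  g100 <- genome_record(random_dna(100), "g100", circular = TRUE)
  ssr2 <- list(start = 10L, end = 20L, unit = "AATCG", unit_len = 5L,
               repeat_count = 2L, ssr_class = "potential")
  f2 <- extract_flanks(g100, ssr2, 60)
  expect_equal(f2$left_flank,
               paste0(substr(g100$sequence, 51, 100), substr(g100$sequence, 1, 10)))

  # zero-length flanks are allowed
  f0 <- extract_flanks(g, ssr, 0)
  expect_equal(f0$left_flank, "")

  # linear record too short: truncated with a warning
  lin <- genome_record(random_dna(40), "lin", circular = FALSE)
  ssr3 <- list(start = 5L, end = 15L, unit = "AATCG", unit_len = 5L,
               repeat_count = 2L, ssr_class = "potential")
  expect_warning(f3 <- extract_flanks(lin, ssr3, 60), "truncated")
  expect_equal(nchar(f3$left_flank), 5L)
})

test_that("flank matching applies inclusive 0.90 thresholds to identity and coverage", {
  set.seed(62)
  base <- random_dna(60)
  right <- random_dna(60)
  mk <- function(left) {
    structure(list(ssr = list(start = 0, end = 10, unit = "AT", unit_len = 2,
                              repeat_count = 5, ssr_class = "normal"),
                   left_flank = left, right_flank = right, genome_id = "g"),
              class = "flanked_ssr")
  }
  mutate_n <- function(s, n) {
    ch <- strsplit(s, "")[[1]]
    idx <- seq_len(n)
    ch[idx] <- vapply(ch[idx], function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
    paste(ch, collapse = "")
  }
  same <- flanks_match(mk(base), mk(base))
  expect_true(same$match)
  expect_equal(same$left_identity, 1.0)
  expect_equal(same$left_coverage, 1.0)

  # 5 mismatches of 60: identity 55/60 = 0.9167 >= 0.9 -> match
  m5 <- flanks_match(mk(base), mk(mutate_n(base, 5)))
  expect_true(m5$match)
  expect_equal(m5$left_identity, 55 / 60)

  # 10 mismatches of 60: identity 50/60 = 0.833 < 0.9 -> no match
  m10 <- flanks_match(mk(base), mk(mutate_n(base, 10)))
  expect_false(m10$match)
  expect_equal(m10$left_identity, 50 / 60)

  # exactly 6 mismatches: identity 54/60 = 0.90 passes the inclusive rule
  m6 <- flanks_match(mk(base), mk(mutate_n(base, 6)))
  expect_true(m6$match)
  expect_equal(m6$left_identity, 0.9)
})

test_that("grouping yields shared, unique and repeat-variant groups", {
  set.seed(63)
  left <- random_dna(60)
  right <- random_dna(60)
  pad_l <- random_dna(30)
  pad_r <- random_dna(30)
  build <- function(id, repeats) {
    genome_record(paste0(pad_l, left, strrep("ACG", repeats), right, pad_r), id)
  }
  genomes <- list(g1 = build("g1", 5), g2 = build("g2", 5), g3 = build("g3", 5))
  flanked <- lapply(genomes, function(g) {
    ss <- find_ssrs(g)
    ss <- ss[canonical_unit(ss$unit) == "ACG", , drop = FALSE]
    extract_all_flanks(g, ss, 60)
  })
  gr <- group_ssrs(flanked)
  expect_equal(length(gr$groups), 1L)
  expect_equal(gr$groups[[1]]$shared_in, 3L)
  expect_true(gr$groups[[1]]$same_unit)
  expect_false(gr$groups[[1]]$repeat_variation)

  # one genome with a different repeat count -> same group, variation flag
  genomes$g3 <- build("g3", 6)
  flanked$g3 <- local({
    ss <- find_ssrs(genomes$g3)
    ss <- ss[canonical_unit(ss$unit) == "ACG", , drop = FALSE]
    extract_all_flanks(genomes$g3, ss, 60)
  })
  gr2 <- group_ssrs(flanked)
  expect_equal(length(gr2$groups), 1L)
  expect_true(gr2$groups[[1]]$repeat_variation)
  expect_equal(sort(gr2$groups[[1]]$repeat_counts), c(5L, 5L, 6L))

  # an SSR whose flanks match nothing is a unique singleton group
  lone <- genome_record(paste0(random_dna(60), strrep("TTAGC", 3), random_dna(60)),
                        "lone")
  fl <- extract_all_flanks(lone, find_ssrs(lone), 60)
  fl <- Filter(function(f) f$ssr$unit_len == 5, fl)
  gr3 <- group_ssrs(c(flanked, list(lone = fl)))
  shared <- vapply(gr3$groups, function(g) g$shared_in, 0L)
  expect_true(any(shared == 1L))
  # member count conservation across groups
  expect_equal(sum(vapply(gr3$groups, function(g) nrow(g$members), 0L)),
               sum(vapply(c(flanked, list(lone = fl)), length, 0L)))
})

test_that("grouping is invariant under genome input order", {
  set.seed(64)
  left <- random_dna(60); right <- random_dna(60)
  build <- function(id, unit, reps) {
    genome_record(paste0(random_dna(20), left, strrep(unit, reps), right,
                         random_dna(20)), id)
  }
  genomes <- list(a = build("a", "AC", 6), b = build("b", "AC", 6),
                  c = build("c", "AC", 7))
  flanked <- lapply(genomes, function(g) {
    ss <- find_ssrs(g)
    extract_all_flanks(g, ss[canonical_unit(ss$unit) == "AC", , drop = FALSE], 60)
  })
  sig <- function(gr) {
    keys <- vapply(gr$groups, function(g) {
      paste(sort(paste(g$members$genome, g$members$start)), collapse = ";")
    }, "")
    sort(keys)
  }
  expect_equal(sig(group_ssrs(flanked)), sig(group_ssrs(rev(flanked))))
  expect_equal(sig(group_ssrs(flanked)), sig(group_ssrs(flanked[c(2, 1, 3)])))
})

test_that("zero-rate simulated tips form full-shared groups; slippage drives repeat variation", {
  # zero-length branches give a zero substitution rate; slippage is drawn
  # per branch regardless of branch length
  cfg <- sim_config(genome_length = 4000,
                    tree = "((t1:0,t2:0):0,(t3:0,t4:0):0);",
                    region_breaks = numeric(0), region_rate_multipliers = 1,
                    indel_rate = 0, slippage_prob = 0.5, rotate = FALSE,
                    seed = 29)
  sim <- simulate_genome_set(cfg)
  slips <- sim$truth$variant_events[sim$truth$variant_events$type == "slippage", ]
  expect_gt(nrow(slips), 0L)  # slippage did occur at this seed
  truth_counts <- sim$truth$tip_ssrs
  flanked <- lapply(sim$genomes, function(g) {
    ss <- find_ssrs(g)
    pl <- sim$truth$planted_ssrs
    keep <- vapply(seq_len(nrow(ss)), function(i)
      any(canonical_unit(ss$unit[i]) == canonical_unit(pl$unit)), TRUE)
    extract_all_flanks(g, ss[keep, , drop = FALSE], 60)
  })
  gr <- group_ssrs(flanked)
  full <- Filter(function(g) g$shared_in == 4L, gr$groups)
  group_key <- function(mem) paste(sort(paste(mem$genome, mem$start)), collapse = ";")
  truth_keys <- vapply(sim$truth$planted_ssrs$ssr_id, function(pid) {
    tt <- truth_counts[truth_counts$ssr_id == pid, ]
    group_key(data.frame(genome = tt$genome, start = tt$start))
  }, "")
  matched <- match(vapply(full, function(g) group_key(g$members), ""), truth_keys)
  expect_setequal(stats::na.omit(matched), seq_along(truth_keys))
  for (i in which(!is.na(matched))) {
    pid <- sim$truth$planted_ssrs$ssr_id[matched[i]]
    tc <- truth_counts$count[truth_counts$ssr_id == pid]
    expect_equal(full[[i]]$repeat_variation, length(unique(tc)) > 1L,
                 info = paste("planted SSR", pid))
    expect_equal(sort(full[[i]]$repeat_counts), sort(tc),
                 info = paste("planted SSR", pid))
  }
})

test_that("group summaries cross-foot and export cleanly", {
  set.seed(66)
  left <- random_dna(60); right <- random_dna(60)
  build <- function(id, reps) {
    genome_record(paste0(random_dna(25), left, strrep("GAT", reps), right,
                         random_dna(25)), id)
  }
  genomes <- list(x = build("x", 4), y = build("y", 4))
  flanked <- lapply(genomes, function(g) {
    ss <- find_ssrs(g)
    extract_all_flanks(g, ss[canonical_unit(ss$unit) == "ATG", , drop = FALSE], 60)
  })
  gr <- group_ssrs(flanked)
  sm <- ssr_group_summary(gr, hosts = c(x = "hostA", y = "hostA"))
  expect_equal(sum(sm$by_sharing$n_groups), length(gr$groups))
  expect_equal(sm$by_host$host, "hostA")
  tsv <- tempfile(fileext = ".tsv")
  write_ssr_groups(gr, tsv)
  tab <- utils::read.delim(tsv)
  expect_equal(nrow(tab), sum(vapply(gr$groups, function(g) nrow(g$members), 0L)))
})
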