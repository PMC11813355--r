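test_that("plant_ssr inserts verbatim repeats and rejects bad units", {
  expect_equal(plant_ssr("GGGGGG", "AT", 5, 3), "GGGATATATATATGGG")
  expect_equal(plant_ssr("TTTT", "ACGTG", 2, 0), "ACGTGACGTGTTTT")
  expect_equal(nchar(plant_ssr("GGGGGG", "AT", 5, 3)), 6 + 10)
  expect_error(plant_ssr("TTTT", "ATAT", 3, 0), "primitive")
  expect_error(plant_ssr("TTTT", "AT", 1, 0), ">= 2")
  expect_error(plant_ssr("TTTT", "AU", 2, 0), "DNA")
  expect_error(plant_ssr("TTTT", "AC", 2, 9), "position")
})

test_that("configuration invariants are validated", {
  expect_error(sim_config(genome_length = 0), "zero-length")
  expect_error(sim_config(gc_target = 1.2), "gc_target")
  expect_error(sim_config(region_breaks = c(0.5, 0.3)), "increasing")
  expect_error(sim_config(region_breaks = c(0.5),
                          region_rate_multipliers = c(1, 2, 3)),
               "multiplier")
  expect_error(sim_config(region_rate_multipliers = c(1, -1, 2)), "positive")
  expect_error(sim_config(tree = NULL), "tree")
  expect_error(sim_config(ssr_plants = data.frame(unit = "ATAT", count = 3,
                                                  position = 0.5)),
               "primitive")
  expect_error(sim_config(ssr_plants = data.frame(unit = "AXT", count = 3,
                                                  position = 0.5)),
               "DNA")
})

test_that("zero rates give tips identical to the ancestor and no events", {
  cfg <- sim_config(genome_length = 2000, tree = "((a:0,b:0):0,c:0);",
                    indel_rate = 0, slippage_prob = 0, rotate = FALSE, seed = 2)
  sim <- simulate_genome_set(cfg)
  expect_equal(length(sim$genomes), 3L)
  for (g in sim$genomes) expect_equal(g$sequence, sim$truth$ancestor)
  expect_equal(nrow(sim$truth$variant_events), 0L)
})

test_that("identical config and seed give byte-identical FASTA", {
  cfg <- sim_config(genome_length = 3000, seed = 12)
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(simulate_genome_set(cfg), d1, cfg)
  write_simulation(simulate_genome_set(cfg), d2, cfg)
  f1 <- file.path(d1, "genomes.fasta"); f2 <- file.path(d2, "genomes.fasta")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # and a different seed changes the output
  cfg3 <- sim_config(genome_length = 3000, seed = 13)
  d3 <- tempfile()
  write_simulation(simulate_genome_set(cfg3), d3, cfg3)
  expect_false(identical(unname(tools::md5sum(f1)),
                         unname(tools::md5sum(file.path(d3, "genomes.fasta")))))
})

test_that("pairwise divergence matches the closed-form expectation", {
  cfg <- sim_config(genome_length = 10000, region_breaks = numeric(0),
                    region_rate_multipliers = 1, tree = "(a:0.01,b:0.01);",
                    indel_rate = 0, ssr_plants = NULL, slippage_prob = 0,
                    rotate = FALSE, seed = 5)
  sim <- simulate_genome_set(cfg)
  p_obs <- mean(strsplit(sim$genomes$a$sequence, "")[[1]] !=
                strsplit(sim$genomes$b$sequence, "")[[1]])
  p_exp <- oracle_jc_p(0.02)
  sd3 <- 3 * sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(p_obs - p_exp), sd3 + 0.001)
})

test_that("substitution events per region recover the rate multipliers", {
  cfg <- sim_config(genome_length = 30000, region_breaks = c(1 / 3, 2 / 3),
                    region_rate_multipliers = c(1, 3, 1.5),
                    tree = "(a:0.02,b:0.02);", indel_rate = 0,
                    ssr_plants = NULL, slippage_prob = 0, rotate = FALSE,
                    seed = 9)
  sim <- simulate_genome_set(cfg)
  ev <- sim$truth$variant_events
  ev <- ev[ev$type == "substitution", ]
  expect_gt(nrow(ev), 500)
  ri <- sim$truth$region_intervals
  lens <- ri$end - ri$start
  counts <- as.integer(table(factor(ev$region, levels = seq_len(nrow(ri)))))
  rates <- counts / lens
  ratios <- rates / rates[1]
  for (r in 2:3) {
    se <- ratios[r] * sqrt(1 / counts[r] + 1 / counts[1])
    # 3 SE Poisson band plus a small allowance for multiple-hit shrinkage
    expect_lt(abs(ratios[r] - ri$multiplier[r]),
              3 * se + 0.08 * ri$multiplier[r])
  }
})

test_that("indel events follow the configured rate and lengths stay truncated", {
  cfg <- sim_config(genome_length = 20000, region_breaks = numeric(0),
                    region_rate_multipliers = 1, tree = "(a:0.05,b:0.05);",
                    indel_rate = 0.02, indel_mean_length = 3,
                    indel_max_length = 10, ssr_plants = NULL,
                    slippage_prob = 0, rotate = FALSE, seed = 19)
  sim <- simulate_genome_set(cfg)
  ev <- sim$truth$variant_events
  ind <- ev[ev$type %in% c("insertion", "deletion"), ]
  lens <- abs(as.integer(sub("^[+-]", "", ind$detail)))
  expect_true(all(lens >= 1 & lens <= 10))
  lam <- 0.02 * 20000 * 0.1  # both branches combined
  expect_lt(abs(nrow(ind) - lam), 4 * sqrt(lam))
  # tips differ in length once indels act
  expect_false(nchar(sim$genomes$a$sequence) == nchar(sim$genomes$b$sequence) &&
                 identical(sim$genomes$a$sequence, sim$genomes$b$sequence))
})

test_that("rotations are recorded exactly and reversible", {
  cfg <- sim_config(genome_length = 3000, tree = "((a:0,b:0):0,c:0);",
                    indel_rate = 0, slippage_prob = 0, rotate = TRUE, seed = 3)
  sim <- simulate_genome_set(cfg)
  for (id in names(sim$genomes)) {
    off <- sim$truth$rotations[[id]]
    expect_true(off >= 0 && off < nchar(sim$genomes[[id]]$sequence))
    expect_equal(rotate_genome(sim$genomes[[id]], -off)$sequence,
                 sim$truth$ancestor)
  }
})

test_that("simulation truth tables and config round-trip through files", {
  cfg <- sim_config(genome_length = 2500, seed = 8)
  sim <- simulate_genome_set(cfg)
  d <- tempfile()
  write_simulation(sim, d, cfg)
  expect_true(all(file.exists(file.path(
    d, c("genomes.fasta", "tree.nwk", "rotations.tsv", "variants.tsv",
         "planted_ssrs.tsv", "region_intervals.tsv", "config.yaml")))))
  cfg2 <- read_sim_config(file.path(d, "config.yaml"))
  expect_equal(cfg2$genome_length, cfg$genome_length)
  expect_equal(cfg2$ssr_plants$unit, cfg$ssr_plants$unit)
  expect_equal(ape::write.tree(cfg2$tree), ape::write.tree(cfg$tree))
  sim2 <- simulate_genome_set(cfg2)
  expect_identical(sim2$genomes[[1]]$sequence, sim$genomes[[1]]$sequence)
  back <- read_genomes(file.path(d, "genomes.fasta"))
  expect_equal(back[[1]]$sequence, sim$genomes[[1]]$sequence)
})
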