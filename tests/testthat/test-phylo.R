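test_that("TN93 distances match the closed-form formula", {
  expect_equal(tn93_distance("ACGTACGT", "ACGTACGT"), 0)
  set.seed(71)
  for (i in 1:10) {
    a <- random_dna(400, c(A = .35, C = .15, G = .15, T = .35))
    ch <- strsplit(a, "")[[1]]
    idx <- sample(400, 25)
    ch[idx] <- vapply(ch[idx], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    b <- paste(ch, collapse = "")
    expect_equal(tn93_distance(a, b), oracle_tn93(a, b), tolerance = 1e-8)
  }
  # single A<->G difference in 100 sites
  a <- paste0(strrep("A", 50), strrep("C", 25), strrep("G", 15), strrep("T", 10))
  b <- paste0(strrep("A", 49), "G", strrep("C", 25), strrep("G", 15), strrep("T", 10))
  expect_equal(tn93_distance(a, b), oracle_tn93(a, b), tolerance = 1e-8)
})

test_that("TN93 never shrinks below the observed p-distance and handles saturation", {
  set.seed(72)
  for (i in 1:10) {
    d_frac <- runif(1, 0.01, 0.3)
    a <- random_dna(500)
    ch <- strsplit(a, "")[[1]]
    idx <- sample(500, round(d_frac * 500))
    ch[idx] <- vapply(ch[idx], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    b <- paste(ch, collapse = "")
    p <- mean(strsplit(a, "")[[1]] != ch)
    expect_gte(tn93_distance(a, b) + 1e-12, p)
  }
  # ~75% random difference saturates the correction
  a <- strrep("A", 400)
  b <- random_dna(400)
  expect_warning(d <- tn93_distance(a, b, max_distance = 12), "saturated")
  expect_equal(d, 12)
})

test_that("gapped sites are pairwise-deleted in the distance", {
  a <- "ACGTACGTAC"
  b <- "-CGTACGTAC"
  expect_equal(tn93_distance(a, b), 0)
})

test_that("NJ recovers quartets and triplets with exact branch lengths", {
  d <- matrix(3, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 2
  d["C", "D"] <- d["D", "C"] <- 2
  diag(d) <- 0
  tr <- nj_tree(d)
  expect_equal(tree_splits(tr), "C|D")  # the AB|CD split
  internal <- tr$edge.length[tr$edge[, 2] > ape::Ntip(tr)]
  expect_equal(internal, 1)
  expect_equal(sort(tr$edge.length), c(1, 1, 1, 1, 1))
  # least-squares quartet oracle prefers the same pairing
  rss <- vapply(list(c(1, 2), c(1, 3), c(1, 4)),
                function(p) oracle_ls_rss_quartet(d, p), 0)
  expect_equal(which.min(rss), 1L)

  d3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(d3)
  # three-point formulas: x=(3+5-6)/2=1, y=(3+6-5)/2=2, z=(5+6-3)/2=4
  bl <- stats::setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(bl[c("x", "y", "z")], c(x = 1, y = 2, z = 4))

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2,
                              dimnames = list(c("a", "b"), c("a", "b")))),
               "at least 3")
  dd <- d; dd["A", "B"] <- 5
  expect_error(nj_tree(dd), "symmetric")
})

test_that("NJ reproduces random additive trees exactly", {
  set.seed(73)
  for (i in 1:10) {
    n <- sample(5:8, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    d <- ape::cophenetic.phylo(tr)
    rec <- nj_tree(d)
    expect_equal(rf_distance(rec, tr), 0L)
    expect_equal(ape::cophenetic.phylo(rec)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
  }
})

test_that("RF distance is a metric consistent with an independent implementation", {
  set.seed(74)
  for (i in 1:10) {
    t1 <- ape::rtree(7)
    t2 <- ape::rtree(7, tip.label = t1$tip.label)
    expect_equal(rf_distance(t1, t2),
                 as.integer(phangorn::RF.dist(t1, t2)))
    expect_equal(rf_distance(t1, t1), 0L)
    expect_equal(rf_distance(t1, t2), rf_distance(t2, t1))
  }
})

test_that("bootstrap support is reproducible and saturates on unanimous signal", {
  set.seed(75)
  # 200 sites in which every variable column is congruent with split AB|CD
  base <- random_dna(200)
  other <- local({
    ch <- strsplit(base, "")[[1]]
    idx <- sample(200, 40)
    ch[idx] <- vapply(ch[idx], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(ch, collapse = "")
  })
  x <- msa(c(A = base, B = base, C = other, D = other))
  bs <- bootstrap_support(x, replicates = 100, seed = 42)
  expect_equal(unname(bs$support["C|D"]), 100)
  bs2 <- bootstrap_support(x, replicates = 100, seed = 42)
  expect_identical(bs$support, bs2$support)
  bs3 <- bootstrap_support(x, replicates = 100, seed = 43)
  expect_identical(names(bs3$support), names(bs$support))

  one <- bootstrap_support(x, replicates = 1, seed = 7)
  expect_true(all(one$support %in% c(0, 100)))
})

test_that("congruence comparison flags monophyly breaks and conflicting hosts", {
  sym <- ape::read.tree(text = "((s1:1,s2:1):1,((s3:1,s4:1):1,(s5:1,s6:1):1):1);")
  host <- ape::read.tree(text = "((h1:1,h2:1):1,h3:1);")
  map <- c(s1 = "h1", s2 = "h1", s3 = "h2", s4 = "h2", s5 = "h3", s6 = "h3")
  rep0 <- compare_topologies(sym, host, map)
  expect_true(all(rep0$monophyly$monophyletic))
  expect_equal(rep0$rf_distance, 0L)
  expect_true(rep0$congruent)

  # two same-host genomes placed apart break monophyly
  map2 <- c(s1 = "h1", s3 = "h1", s2 = "h2", s4 = "h2", s5 = "h3", s6 = "h3")
  rep1 <- compare_topologies(sym, host, map2)
  expect_false(all(rep1$monophyly$monophyletic))
  expect_false(rep1$congruent)

  expect_error(compare_topologies(sym, host, map[-1]), "s1")
})

test_that("swapping tips across cherries gives RF 2 with both hosts implicated", {
  t1 <- ape::read.tree(text = "((a:1,b:1):1,((c:1,d:1):1,e:1):1);")
  t2 <- ape::read.tree(text = "((a:1,c:1):1,((b:1,d:1):1,e:1):1);")
  expect_equal(rf_distance(t1, t2), 4L)  # both nontrivial splits differ
  # hand enumeration: t1 has {a,b} and {c,d}; t2 has {a,c} and {b,d}
  expect_equal(sort(tree_splits(t1)), sort(c("c|d", "c|d|e")))
  map <- stats::setNames(paste0("H", letters[1:5]), letters[1:5])
  host <- t2
  host$tip.label <- unname(map[host$tip.label])
  rep <- compare_topologies(t1, host, map)
  expect_equal(rep$rf_distance, 4L)
  expect_true(all(c("Ha", "Hb", "Hc", "Hd") %in% rep$conflicting_hosts) ||
                length(rep$conflicting_hosts) >= 2)
})

test_that("congruence reports export with pairing list", {
  sym <- ape::read.tree(text = "((s1:1,s2:1):1,(s3:1,s4:1):1);")
  host <- ape::read.tree(text = "(h1:1,h2:1);")
  map <- c(s1 = "h1", s2 = "h1", s3 = "h2", s4 = "h2")
  rep <- compare_topologies(sym, host, map)
  expect_equal(nrow(rep$pairing), 4L)
  f <- tempfile(fileext = ".tsv")
  write_congruence_report(rep, f)
  expect_true(file.exists(f))
  txt <- readLines(paste0(f, ".txt"))
  expect_true(any(grepl("rf_distance", txt)))
  expect_true(any(grepl("s1 -- h1", txt)))
})
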