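# Independent oracles used to verify package operations. Each is written
# directly from the defining formula or by exhaustion, never by calling the
# code path it checks.

# Affine-gap global alignment score by an independent Gotoh-style
# three-state recursion (match/insert/delete layers), no traceback.
# Gap run of length g costs open + g * extend (both negative).
oracle_align_score <- function(a, b, match = 2, mismatch = -1,
                               gap_open = -4, gap_extend = -1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # last move diagonal
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consume a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consume b)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- gap_open + i * gap_extend
  for (j in seq_len(m)) Y[1, j + 1] <- gap_open + j * gap_extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j] && A[i] %in% c("A", "C", "G", "T")) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_extend,
                             X[i, j + 1] + gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_extend,
                             Y[i + 1, j] + gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Exhaustive SSR scan: for every unit size and start position, count
# repeats by direct substring comparison; keep maximal (non-left-extendable)
# primitive runs meeting the thresholds. Returns start0/unit/repeats rows.
oracle_find_ssrs <- function(s, thresholds = symbiovar::ssr_thresholds()) {
  L <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  rows <- list()
  for (k in 1:10) {
    for (i in seq_len(max(0, L - 2 * k + 1))) {
      # maximal: position i-1 must not extend the periodicity leftwards
      if (i > 1 && i + k - 1 <= L && ch[i - 1] == ch[i - 1 + k]) next
      unit <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", unit)) next
      # primitivity by direct definition
      prim <- TRUE
      for (p in seq_len(k - 1)) {
        if (k %% p == 0 && unit == strrep(substr(unit, 1, p), k / p)) {
          prim <- FALSE; break
        }
      }
      if (!prim) next
      reps <- 1
      while (i + (reps + 1) * k - 1 <= L &&
             substr(s, i + reps * k, i + (reps + 1) * k - 1) == unit) {
        reps <- reps + 1
      }
      # a trailing partial period can still absorb whole extra units only
      # via the while above; reps is the full-unit count
      if (reps >= max(2, thresholds[k])) {
        cls <- symbiovar::classify_ssr(k, reps, thresholds)
        if (!is.na(cls)) {
          rows[[length(rows) + 1]] <- data.frame(
            start = i - 1, unit = unit, unit_len = k, repeat_count = reps,
            ssr_class = cls, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), unit = character(0),
                      unit_len = integer(0), repeat_count = integer(0),
                      ssr_class = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$unit_len), , drop = FALSE]
}

# Jukes-Cantor expected p-distance at total divergence d subs/site.
oracle_jc_p <- function(d) 0.75 * (1 - exp(-4 * d / 3))

# Closed-form TN93 distance from two ungapped-comparable rows.
oracle_tn93 <- function(a, b) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  keep <- A %in% c("A", "C", "G", "T") & B %in% c("A", "C", "G", "T")
  A <- A[keep]; B <- B[keep]
  n <- length(A)
  f <- (table(factor(A, levels = c("A", "C", "G", "T"))) +
        table(factor(B, levels = c("A", "C", "G", "T")))) / (2 * n)
  gA <- f[["A"]]; gC <- f[["C"]]; gG <- f[["G"]]; gT <- f[["T"]]
  gR <- gA + gG; gY <- gC + gT
  P1 <- mean((A == "A" & B == "G") | (A == "G" & B == "A"))
  P2 <- mean((A == "C" & B == "T") | (A == "T" & B == "C"))
  Q <- mean(A != B) - P1 - P2
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gC * gT / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY)
  w1 <- 1 - P1 / k1 - Q / (2 * gR)
  w2 <- 1 - P2 / k2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(NA_real_)
  -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
}

# Minimum-Hamming rotation by direct exhaustion over all offsets of the
# query circle; returns the offset in the detect_rotation convention
# (query reads as the reference rotated by `offset`).
oracle_rotation <- function(ref, qry) {
  L <- nchar(qry)
  best <- Inf; best_r <- 0
  for (r in 0:(L - 1)) {
    rot <- paste0(substr(qry, r + 1, L), substr(qry, 1, r))
    n <- min(nchar(ref), L)
    h <- sum(strsplit(substr(ref, 1, n), "")[[1]] !=
             strsplit(substr(rot, 1, n), "")[[1]])
    if (h < best) { best <- h; best_r <- r }
  }
  (-best_r) %% L
}

# Exhaustive best single split of a series by within-segment SSE.
oracle_single_split <- function(x, min_len) {
  n <- length(x)
  best_k <- NA; best_sse <- Inf
  for (k in min_len:(n - min_len)) {
    sse <- sum((x[1:k] - mean(x[1:k]))^2) +
      sum((x[(k + 1):n] - mean(x[(k + 1):n]))^2)
    if (sse < best_sse) { best_sse <- sse; best_k <- k }
  }
  best_k
}

# Least-squares branch lengths for a fixed 4-taxon unrooted topology
# ((1,2),(3,4)) given a distance matrix ordered to that topology; returns
# the residual sum of squares (5-parameter OLS fit).
oracle_ls_rss_quartet <- function(d, pair) {
  others <- setdiff(1:4, pair)
  o <- c(pair, others)
  # design: rows = 6 pairwise distances, cols = a,b,c,d,e
  labs <- combn(4, 2)
  X <- matrix(0, 6, 5)
  y <- numeric(6)
  for (r in 1:6) {
    i <- o[labs[1, r]]; j <- o[labs[2, r]]
    y[r] <- d[i, j]
    X[r, labs[1, r]] <- 1
    X[r, labs[2, r]] <- 1
    same_side <- (labs[1, r] <= 2) == (labs[2, r] <= 2)
    if (!same_side) X[r, 5] <- 1
  }
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

random_dna <- function(n, freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}
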