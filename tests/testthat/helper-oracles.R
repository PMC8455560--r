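# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (and, where possible, the
# libraries) used by the package functions.

# All motif occurrence starts (0-based) by naive substring comparison.
oracle_motif_starts <- function(genome, motif) {
  n <- nchar(genome); w <- nchar(motif)
  if (n < w) return(integer(0))
  starts <- integer(0)
  for (i in seq_len(n - w + 1L)) {
    if (substr(genome, i, i + w - 1L) == motif) starts <- c(starts, i - 1L)
  }
  starts
}

# Fragment table by naive scanning (boundaries at motif starts, tiling).
oracle_digest <- function(genome, primary = "GATC", secondary = "CATG",
                          min_length = 20L) {
  cuts <- oracle_motif_starts(genome, primary)
  bounds <- sort(unique(c(0L, cuts)))
  bounds <- bounds[bounds < nchar(genome)]
  starts <- bounds
  ends <- c(bounds[-1], nchar(genome))
  sec <- oracle_motif_starts(genome, secondary)
  w <- nchar(secondary)
  has_sec <- vapply(seq_along(starts), function(k)
    any(sec >= starts[k] & sec + w <= ends[k]), logical(1))
  data.frame(start = starts, end = ends,
             valid = has_sec & (ends - starts) >= min_length)
}

# Exact PWM p-value by enumerating all 4^L k-mers on the integer grid.
oracle_pwm_pvalue <- function(x, score) {
  L <- x$width
  kmers <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- rowSums(matrix(x$int_scores[cbind(as.vector(kmers),
                                          rep(seq_len(L), each = nrow(kmers)))],
                       nrow = nrow(kmers)))
  pr <- apply(kmers, 1, function(k) prod(x$background[k]))
  s_int <- round(score / x$grid)
  sum(pr[sc >= s_int])
}

# Distribution of the rank sum of group 1 by recursive counting:
# N[k, s] = number of k-subsets of {1..n} with sum s.
oracle_ranksum_counts <- function(n, n1) {
  maxs <- sum((n - n1 + 1):n)
  N <- matrix(0, nrow = n1 + 1L, ncol = maxs + 1L)  # [k+1, s+1]
  N[1, 1] <- 1
  for (v in seq_len(n)) {
    for (k in rev(seq_len(min(v, n1)))) {
      s_idx <- which(N[k, ] > 0)
      for (s in rev(s_idx)) {
        if (s - 1 + v <= maxs) N[k + 1L, s + v] <- N[k + 1L, s + v] + N[k, s]
      }
    }
  }
  N[n1 + 1L, ]
}

# Exact two-tailed Mann-Whitney p via the recursive rank-sum distribution.
oracle_mw_pvalue <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  rx <- sum(r[seq_len(n1)])
  U <- n1 * n2 - (rx - n1 * (n1 + 1) / 2)
  counts <- oracle_ranksum_counts(n, n1)
  total <- choose(n, n1)
  sums <- which(counts > 0) - 1L
  u_vals <- n1 * n2 - (sums - n1 * (n1 + 1) / 2)
  cnt <- counts[counts > 0]
  p_le <- sum(cnt[u_vals <= U]) / total
  p_ge <- sum(cnt[u_vals >= U]) / total
  min(1, 2 * min(p_le, p_ge))
}

# Naive per-position window identity on a 2-sequence alignment, mirroring
# the stated rule: clamped windows of `wl` reference positions, reference
# gap columns inside the span count as mismatches.
oracle_window_identity <- function(aln, wl) {
  ref <- strsplit(aln[1], "", fixed = TRUE)[[1]]
  oth <- strsplit(aln[2], "", fixed = TRUE)[[1]]
  cols <- which(ref != "-")
  R <- length(cols)
  out <- numeric(R)
  for (i in seq_len(R)) {
    lo <- max(1L, i - wl %/% 2L)
    hi <- min(R, lo + wl - 1L)
    lo <- max(1L, hi - wl + 1L)
    span <- cols[lo]:cols[hi]
    m <- sum(ref[span] != "-" & oth[span] != "-" & ref[span] == oth[span])
    out[i] <- 100 * m / length(span)
  }
  out
}

# Optimal global alignment score by exhaustive recursion (tiny strings
# only). Affine gaps: each maximal gap of length L costs open + ext * L.
oracle_global_score <- function(a, b, match = 1, mismatch = -1,
                                gap_open = 2, gap_extend = 1) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  rec <- function(i, j, state) {
    # state: 0 none/substitution, 1 gap in b (a consumed), 2 gap in a
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, 0L))
    }
    if (i <= length(av)) {
      cost <- gap_extend + if (state == 1L) 0 else gap_open
      best <- max(best, -cost + rec(i + 1L, j, 1L))
    }
    if (j <= length(bv)) {
      cost <- gap_extend + if (state == 2L) 0 else gap_open
      best <- max(best, -cost + rec(i, j + 1L, 2L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# Expected fraction of differing sites after t substitutions/site (JC69).
jc_expected_diff <- function(t) 0.75 * (1 - exp(-4 * t / 3))

# Random PWM count matrix of the given width.
random_pwm_counts <- function(width, seed) {
  set.seed(seed)
  matrix(sample(0:50, 4 * width, replace = TRUE) +
           rep(sample(0:30, width, replace = TRUE), each = 4),
         nrow = 4, dimnames = list(c("A", "C", "G", "T"), NULL))
}

# Fraction of differing aligned sites between two equal-length strings.
seq_diff_frac <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  mean(av != bv)
}
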