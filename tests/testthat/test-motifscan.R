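# PWM construction, exact p-values, scanning, site overlaps, conserved
# columns and the mutagenesis design/verification loop.

consensus_counts_test <- function(consensus, major = 90, minor = 0) {
  b <- strsplit(consensus, "", fixed = TRUE)[[1]]
  m <- matrix(minor, 4, length(b), dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(b, c("A", "C", "G", "T")), seq_along(b))] <- major
  m
}

test_that("pwm construction validates inputs and derives log-odds", {
  counts <- random_pwm_counts(5, 201)
  p <- pwm(counts, id = "m")
  expect_identical(p$width, 5L)
  expect_equal(dim(p$log_odds), c(4L, 5L))
  # deterministic re-derivation
  expect_identical(p$log_odds, pwm(counts, id = "m")$log_odds)

  bad <- counts; bad[, 3] <- 0
  expect_error(pwm(bad), "degenerate")
  expect_error(pwm(counts, background = c(0.3, 0.3, 0.3, 0.3)), "sum")
  expect_error(pwm(counts[1:3, , drop = FALSE]), "4 rows")
})

test_that("score_to_pvalue equals exhaustive enumeration", {
  # 1-column PWM: p is the background mass of bases scoring >= threshold
  p1 <- pwm(matrix(c(10, 5, 3, 1), 4, dimnames = list(c("A", "C", "G", "T"),
                                                      NULL)))
  d_scores <- sort(p1$int_scores[, 1] * p1$grid)
  for (s in d_scores) {
    expect_equal(score_to_pvalue(p1, s),
                 sum(0.25 * (p1$int_scores[, 1] * p1$grid >= s - 1e-9)))
  }

  # 4-column PWM, uniform background, all 256 4-mers: probe a spread of
  # achievable scores
  p4 <- pwm(random_pwm_counts(4, 202))
  set.seed(203)
  probe <- quantile(replicate(50, sum(vapply(1:4, function(j)
    sample(p4$int_scores[, j], 1), numeric(1)))), probs = seq(0, 1, 0.1))
  for (s in unique(round(probe))) {
    expect_lt(abs(score_to_pvalue(p4, s * p4$grid) -
                    oracle_pwm_pvalue(p4, s * p4$grid)), 1e-9)
  }

  # unique optimum: p(max) = 0.25^L
  popt <- pwm(consensus_counts_test("GATC"), id = "opt")
  smax <- sum(apply(popt$int_scores, 2, max)) * popt$grid
  expect_equal(score_to_pvalue(popt, smax), 0.25^4)

  # monotone non-increasing in score
  pv <- score_to_pvalue(p4, sort(probe) * p4$grid)
  expect_true(all(diff(pv) <= 1e-12))
})

test_that("property: exact p-values match enumeration for random PWMs", {
  for (k in 1:20) {
    w <- sample(2:6, 1)
    x <- pwm(random_pwm_counts(w, 400 + k), id = paste0("r", k))
    set.seed(500 + k)
    kmer <- sample(1:4, w, replace = TRUE)
    s <- sum(x$int_scores[cbind(kmer, seq_len(w))]) * x$grid
    expect_lt(abs(score_to_pvalue(x, s) - oracle_pwm_pvalue(x, s)), 1e-9)
  }
})

test_that("scan_pwm finds planted sites on both strands", {
  gli <- example_gli_pwm()
  g <- make_genome(500, 0.5, seed = 211, name = "s")
  pl <- plant_motifs(g[[1]], list(gli),
                     data.frame(pwm = 1, offset = 37, strand = "+"))
  hits <- scan_pwm(pl$sequence, gli, 0.01)
  expect_true(any(hits$start == 37 & hits$strand == "+"))

  pl2 <- plant_motifs(g[[1]], list(gli),
                      data.frame(pwm = 1, offset = 37, strand = "-"))
  hits2 <- scan_pwm(pl2$sequence, gli, 0.01)
  expect_true(any(hits2$start == 37 & hits2$strand == "-"))

  expect_error(scan_pwm("ACGT", gli), "shorter")
})

test_that("scan hit set reflects under reverse complementation", {
  gli <- example_gli_pwm(); hox <- example_hox13_pwm()
  g <- make_genome(2000, 0.5, seed = 221, name = "s")
  pl <- plant_motifs(g[[1]], list(gli, hox),
                     data.frame(pwm = c(1, 2), offset = c(300, 900),
                                strand = c("+", "-")))
  s <- pl$sequence
  L <- nchar(s)
  h_fwd <- scan_pwms(s, list(gli, hox), 0.01)
  h_rc <- scan_pwms(revcomp(s), list(gli, hox), 0.01)
  # reflect the RC hits back into forward coordinates
  refl <- data.frame(motif = h_rc$motif, start = L - h_rc$end,
                     end = L - h_rc$start,
                     strand = ifelse(h_rc$strand == "+", "-", "+"),
                     score = h_rc$score)
  o1 <- h_fwd[order(h_fwd$start, h_fwd$motif, h_fwd$strand),
              c("motif", "start", "end", "strand", "score")]
  o2 <- refl[order(refl$start, refl$motif, refl$strand), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("background hit counts follow the binomial expectation", {
  gli <- example_gli_pwm()
  g <- make_genome(1e5, 0.5, seed = 231, name = "bg")[[1]]
  hits <- scan_pwm(g, gli, 0.01)
  n_win <- nchar(g) - gli$width + 1
  # the realised per-window significance level under the discrete score
  # distribution (largest achievable p below 0.01)
  d <- crmkit:::pwm_score_distribution(gli)
  alpha <- max(d$cum_ge[d$cum_ge < 0.01])
  expected <- 2 * n_win * alpha
  expect_lt(abs(nrow(hits) - expected), 4 * sqrt(2 * n_win * alpha))
})

test_that("overlap_sites merges intersecting hit pairs", {
  a <- data.frame(start = c(10, 50, 100), end = c(19, 59, 109))
  b <- data.frame(start = c(200, 300), end = c(209, 309))
  expect_identical(nrow(overlap_sites(a, b)), 0L)

  # three planted overlapping pairs -> exactly 3 regions
  b2 <- data.frame(start = c(15, 55, 105), end = c(24, 64, 114))
  ov <- overlap_sites(a, b2)
  expect_identical(nrow(ov), 3L)
  expect_equal(ov$start, c(10, 50, 100))
  expect_equal(ov$end, c(24, 64, 114))

  # containment yields one region spanning the union
  ov2 <- overlap_sites(data.frame(start = 10, end = 30),
                       data.frame(start = 15, end = 20))
  expect_equal(ov2, data.frame(start = 10, end = 30, n_pairs = 1))
})

test_that("conserved_columns requires full identity and no gaps", {
  msa <- c(s1 = "ACGTACGT", s2 = "ACGTACGT", s3 = "ACGTACGT")
  expect_identical(conserved_columns(msa), 1:8)

  msa2 <- msa; substr(msa2["s2"], 3, 3) <- "T"
  expect_identical(conserved_columns(msa2), setdiff(1:8, 3L))

  msa3 <- msa; substr(msa3["s3"], 5, 5) <- "-"
  expect_identical(conserved_columns(msa3), setdiff(1:8, 5L))
})

test_that("design_mutations produces verified-clean plans", {
  gli <- example_gli_pwm(); hox <- example_hox13_pwm()
  g <- make_genome(400, 0.5, seed = 241, name = "e")
  pl <- plant_motifs(g[[1]], list(gli, hox),
                     data.frame(pwm = c(1, 2), offset = c(80, 250),
                                strand = c("+", "-")))
  plan <- design_mutations(pl$sequence, list(gli, hox))
  expect_true(plan$accepted)
  expect_gte(nrow(plan$edits), 1L)
  # edits applied to the original reproduce the mutant, refs match
  m <- plan$original
  for (k in seq_len(nrow(plan$edits))) {
    off <- plan$edits$offset[k] + 1L
    expect_identical(substr(plan$original, off, off), plan$edits$ref[k])
    substr(m, off, off) <- plan$edits$alt[k]
  }
  expect_identical(m, plan$mutant)
  # fixed point: a second pass has nothing to do
  plan2 <- design_mutations(plan$mutant, list(gli, hox))
  expect_identical(nrow(plan2$edits), 0L)
  expect_identical(plan2$mutant, plan$mutant)

  # no hits -> empty plan, unchanged sequence
  quiet <- design_mutations(strrep("ACGT", 30), list(gli, hox))
  expect_identical(quiet$mutant, strrep("ACGT", 30))
  expect_identical(nrow(quiet$edits), 0L)
})

test_that("a reverted edit brings back exactly one site", {
  gli <- example_gli_pwm(); hox <- example_hox13_pwm()
  g <- make_genome(300, 0.5, seed = 251, name = "e")
  pl <- plant_motifs(g[[1]], list(gli),
                     data.frame(pwm = 1, offset = 120, strand = "+"))
  plan <- design_mutations(pl$sequence, list(gli, hox))
  expect_true(plan$accepted)
  # revert the edit inside the planted site
  in_site <- which(plan$edits$offset >= 120 &
                     plan$edits$offset < 120 + gli$width)
  expect_gte(length(in_site), 1L)
  mut <- plan$mutant
  k <- in_site[1]
  substr(mut, plan$edits$offset[k] + 1L, plan$edits$offset[k] + 1L) <-
    plan$edits$ref[k]
  rep2 <- verify_mutagenesis(mut, list(gli, hox), original_hits = plan$report$hits)
  expect_false(rep2$clean)
  expect_true(all(rep2$hits$start < 120 + gli$width &
                    rep2$hits$end > 120))
})

test_that("the adversarial opposite-strand trap still verifies clean", {
  gli <- example_gli_pwm(); hox <- example_hox13_pwm()
  # AT-rich background where the naive single edit (highest-IC column to
  # the lowest log-odds base) creates a de-novo minus-strand Hox site
  g <- make_genome(60, 0.25, seed = 3128, name = "e")
  pl <- plant_motifs(g[[1]], list(hox),
                     data.frame(pwm = 1, offset = 25, strand = "+"))
  h0 <- scan_pwms(pl$sequence, list(gli, hox), 0.01)
  expect_identical(nrow(h0), 1L)
  expect_identical(h0$strand, "+")
  naive <- pl$sequence
  substr(naive, 26, 26) <- "A"  # the naive greedy edit
  h1 <- scan_pwms(naive, list(gli, hox), 0.01)
  expect_true(any(h1$strand == "-"))  # the trap springs
  plan <- design_mutations(pl$sequence, list(gli, hox))
  expect_true(plan$accepted)
  expect_true(verify_mutagenesis(plan$mutant, list(gli, hox))$clean)
})

test_that("verify_mutagenesis splits residual and de-novo hits", {
  gli <- example_gli_pwm()
  g <- make_genome(300, 0.5, seed = 261, name = "e")
  pl <- plant_motifs(g[[1]], list(gli),
                     data.frame(pwm = 1, offset = 100, strand = "+"))
  orig_hits <- scan_pwms(pl$sequence, list(gli), 0.01)
  rep0 <- verify_mutagenesis(pl$sequence, list(gli), original_hits = orig_hits)
  expect_false(rep0$clean)
  expect_gte(nrow(rep0$residual), 1L)
  expect_identical(nrow(rep0$de_novo), 0L)
})
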