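# In-silico digestion, primer filtering, read assignment, exclusion masks,
# sliding-window RPM and subtraction, and the binned RPKM track.

test_that("digest places boundaries at motif starts and flags validity", {
  lib <- digest(c(chr1 = "AAAA"))
  expect_identical(nrow(lib$fragments), 1L)
  expect_identical(lib$fragments$start, 0L)
  expect_identical(lib$fragments$end, 4L)
  expect_false(lib$fragments$valid)

  lib2 <- digest(c(chr1 = "AAGATCCATGAAGATCAA"))
  f <- lib2$fragments
  expect_identical(f$start, c(0L, 2L, 12L))
  expect_identical(f$end, c(2L, 12L, 18L))
  expect_identical(f$has_secondary, c(FALSE, TRUE, FALSE))
  # the CATG-containing fragment is still invalid: 10 bp < 20 bp
  expect_false(any(f$valid))

  expect_error(digest(c(chr1 = "ACGT"), primary_motif = "GANC"), "ambiguous")
})

test_that("digestion agrees with a brute-force scan and tiles the genome", {
  for (s in 1:30) {
    g <- make_genome(sample(500:3000, 1), runif(1, 0.3, 0.7),
                     seed = 500 + s)[[1]]
    lib <- digest(c(chr1 = g))
    f <- lib$fragments
    o <- oracle_digest(g)
    expect_identical(f$start, as.integer(o$start))
    expect_identical(f$end, as.integer(o$end))
    expect_identical(f$valid, o$valid)
    expect_identical(sum(f$length), nchar(g))
    expect_identical(f$end[-nrow(f)], f$start[-1])  # exact tiling
  }
})

test_that("fragment validity is monotone in min_length", {
  g <- make_genome(5000, 0.5, seed = 77)[[1]]
  lens <- c(5L, 20L, 50L, 200L)
  vsets <- lapply(lens, function(L) digest(c(chr1 = g), min_length = L)$fragments$valid)
  for (k in seq_along(lens)[-1]) {
    # raising min_length never turns an invalid fragment valid
    expect_true(all(vsets[[k]] <= vsets[[k - 1]]))
  }
})

test_that("filter_primer_reads keeps, trims and tallies correctly", {
  r <- filter_primer_reads(c("ACGTACGTACTTTT", "AGGTACGTACTTTT", "ACG"),
                           "ACGTACGTAC")
  expect_identical(r$kept, "TTTT")
  expect_identical(r$n_discarded, 1L)
  expect_identical(r$n_short, 1L)

  r2 <- filter_primer_reads(c("AGGTACGTACTTTT"), "ACGTACGTAC", max_mismatch = 1)
  expect_identical(r2$kept, "TTTT")
  expect_error(filter_primer_reads("AAAA", ""), "non-empty")
})

test_that("assign_reads uses fragment boundaries on both ends", {
  g <- make_genome(20000, 0.5, seed = 41)
  lib <- digest(g)
  f <- lib$fragments
  vi <- which(f$valid & f$length >= 30)[3]
  # forward read from the fragment start boundary
  rd_fwd <- substr(g[[1]], f$start[vi] + 1, f$start[vi] + 25)
  # reverse-oriented read from the fragment end boundary
  rd_rev <- revcomp(substr(g[[1]], f$end[vi] - 24, f$end[vi]))
  a <- assign_reads(c(rd_fwd, rd_rev), lib)
  expect_identical(a$counts[vi], 2L)
  expect_identical(sum(a$counts), 2L)

  # read from an invalid fragment is unassigned
  ii <- which(!f$valid & f$length >= 30)[1]
  rd_bad <- substr(g[[1]], f$start[ii] + 1, f$start[ii] + 25)
  b <- assign_reads(rd_bad, lib)
  expect_identical(sum(b$counts), 0L)
  expect_identical(b$n_unassigned, 1L)

  # read matching nowhere
  c2 <- assign_reads(strrep("ACGT", 8), lib)
  expect_identical(c2$n_unassigned + c2$n_ambiguous >= 1L, TRUE)
})

test_that("simulated reads are recovered exactly with no decoys", {
  g <- make_genome(40000, 0.5, seed = 51)
  lib <- digest(g)
  vp_pos <- 20000L
  primer <- substr(g[[1]], vp_pos + 1, vp_pos + 20)
  vp <- viewpoint_spec("chr1", vp_pos, primer, exclusion_radius = 2000)
  sim <- simulate_4c_reads(lib, vp, alpha = 1, n_reads = 5000, seed = 52)
  kept <- filter_primer_reads(sim$reads, primer)$kept
  a <- assign_reads(kept, lib)
  expect_identical(a$counts, as.integer(sim$truth$count))
  expect_identical(a$n_ambiguous, 0L)
})

test_that("informative_mask applies all exclusion rules", {
  g <- make_genome(30000, 0.5, seed = 61)
  lib <- digest(g)
  f <- lib$fragments
  primer <- substr(g[[1]], 15001, 15020)
  # radius 0: only the viewpoint fragment and its two neighbours drop out
  vp0 <- viewpoint_spec("chr1", 15000, primer, exclusion_radius = 0)
  m0 <- informative_mask(lib, vp0)
  vp_row <- which(f$start <= 15000 & f$end > 15000)
  expect_false(any(m0[(vp_row - 1):(vp_row + 1)]))
  dropped <- which(f$valid & !m0)
  expect_true(all(dropped %in% (vp_row - 1):(vp_row + 1)))

  # radius 10 kb: every fragment intersecting [pos - 10k, pos + 10k) excluded
  vp1 <- viewpoint_spec("chr1", 15000, primer, exclusion_radius = 10000)
  m1 <- informative_mask(lib, vp1)
  inside <- interval_ov <- pmax(0, pmin(f$end, 25000) - pmax(f$start, 5000)) > 0
  expect_false(any(m1[inside]))
  expect_true(all(m1[f$valid & !inside]))

  # analysis interval restriction
  vp2 <- viewpoint_spec("chr1", 15000, primer, exclusion_radius = 1000,
                        analysis_interval = list(chrom = "chr1",
                                                 start = 10000, end = 20000))
  m2 <- informative_mask(lib, vp2)
  expect_false(any(m2[f$end <= 10000 | f$start >= 20000]))

  # degenerate: nothing informative
  tiny <- digest(c(chr1 = strrep("A", 100)))
  expect_error(informative_mask(tiny,
                                viewpoint_spec("chr1", 50, strrep("ACGT", 3))),
               "no informative")
})

test_that("smooth_rpm matches hand-computed window means", {
  g <- make_genome(30000, 0.5, seed = 71)
  lib <- digest(g)
  primer <- substr(g[[1]], 15001, 15020)
  vp <- viewpoint_spec("chr1", 15000, primer, exclusion_radius = 500)
  mask <- informative_mask(lib, vp)
  idx <- which(mask)

  # constant counts: every informative value is c * 1e6 / total
  counts <- integer(nrow(lib$fragments)); counts[idx] <- 4L
  prof <- viewpoint_profile(lib, vp, counts, 5)
  expect_equal(unique(prof$rpm[mask]), 4 * 1e6 / sum(counts))

  # impulse: [0,0,10,0,0] at the first five informative fragments, window 5
  counts2 <- integer(nrow(lib$fragments)); counts2[idx[3]] <- 10L
  prof2 <- viewpoint_profile(lib, vp, counts2, 5)
  expect_equal(prof2$rpm[idx[3]], 2 * 1e6 / 10)
  # edge shrink: first fragment sees only itself (window shrinks to 1)
  expect_equal(prof2$rpm[idx[1]], 0)

  # window 1 returns scaled raw counts
  prof3 <- smooth_rpm(prof2, 1)
  expect_equal(prof3$rpm[mask], counts2[mask] * 1e6 / 10)

  expect_error(smooth_rpm(prof2, 4), "odd")
  zero <- counts2; zero[] <- 0L
  expect_error(viewpoint_profile(lib, vp, zero), "zero")
})

test_that("profile subtraction is exact, antisymmetric and guarded", {
  g <- make_genome(30000, 0.5, seed = 81)
  lib <- digest(g)
  primer <- substr(g[[1]], 15001, 15020)
  vp <- viewpoint_spec("chr1", 15000, primer, exclusion_radius = 500)
  mask <- informative_mask(lib, vp)
  set.seed(82)
  ca <- integer(nrow(lib$fragments)); ca[mask] <- rpois(sum(mask), 5)
  cb <- integer(nrow(lib$fragments)); cb[mask] <- rpois(sum(mask), 5)
  pa <- viewpoint_profile(lib, vp, ca)
  pb <- viewpoint_profile(lib, vp, cb)
  expect_true(all(subtract_profiles(pa, pa)[mask] == 0))
  expect_equal(subtract_profiles(pa, pb)[mask], -subtract_profiles(pb, pa)[mask])

  other <- digest(make_genome(30000, 0.5, seed = 83))
  po <- viewpoint_profile(other,
                          viewpoint_spec("chr1", 15000,
                                         substr(other$genomes[[1]], 15001, 15020),
                                         exclusion_radius = 500),
                          {x <- integer(nrow(other$fragments))
                           x[informative_mask(other,
                             viewpoint_spec("chr1", 15000,
                               substr(other$genomes[[1]], 15001, 15020),
                               exclusion_radius = 500))] <- 1L; x})
  expect_error(subtract_profiles(pa, po), "different")
})

test_that("atac_rpkm implements the binned end-count formula", {
  # 2 fragments, all 4 ends inside one 10-bp bin
  fr <- data.frame(start = c(2, 5), end = c(8, 9))
  tr <- atac_rpkm(fr, bin_size = 10)
  expect_identical(tr$library_size, 4L)
  expect_equal(tr$bins$rpkm[1], 4 / (4 * 10) * 1e9)
  expect_equal(tr$bins$rpkm[1], 1e8)

  # uniform ends across bins give equal RPKM; doubling counts changes nothing
  ends <- rep(seq(5, 95, by = 10), each = 2)
  t1 <- atac_rpkm(ends, 10)
  expect_equal(length(unique(round(t1$bins$rpkm, 9))), 1L)
  t2 <- atac_rpkm(c(ends, ends), 10)
  expect_equal(t1$bins$rpkm, t2$bins$rpkm)

  expect_error(atac_rpkm(data.frame(start = numeric(0), end = numeric(0))),
               "no input")
})
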