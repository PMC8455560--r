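# Synthetic-data generators. Every pipeline input can be produced from a
# single integer seed with known ground truth: random genomes with realistic
# restriction-site spacing, CRM ortholog families diverged along a tree,
# planted motif instances, 4C reads with distance-decaying capture
# probability, and replicate-level Cq tables.

#' Generate a random genome sequence
#'
#' Bases are drawn i.i.d. with \eqn{P(G) + P(C) = } \code{gc}; at the
#' default GC content of 0.5 a 4-bp restriction motif such as GATC occurs
#' every ~256 bp on average, which mimics the fragment-size scale of a
#' DpnII digest.
#'
#' @param length genome length in bp (>= 1).
#' @param gc GC fraction in [0, 1].
#' @param seed integer seed; fixes the output bit-for-bit.
#' @param name sequence name.
#' @return named character vector of length 1 (the genome sequence).
#' @export
make_genome <- function(length, gc = 0.5, seed = 1L, name = "chr1") {
  if (!is.numeric(length) || length < 1) stop("genome length must be >= 1")
  if (gc < 0 || gc > 1) stop("gc must lie in [0, 1]")
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  setNames(paste(sample(DNA_BASES, length, replace = TRUE, prob = p),
                 collapse = ""), name)
}

# Evolve one sequence along a branch of t expected substitutions per site
# under Jukes-Cantor; optional geometric-length indels.
evolve_branch <- function(seq, t, indel_rate = 0) {
  if (t < 0) stop("branch length must be >= 0")
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(bases)
  if (t > 0) {
    # JC69: P(end in specific different base) = (1/4)(1 - exp(-4t/3))
    p_each <- (1 - exp(-4 * t / 3)) / 4
    u <- runif(n)
    idx <- match(bases, DNA_BASES)
    # map u into one of the three alternative bases or keep
    changed <- u < 3 * p_each
    if (any(changed)) {
      slot <- pmax(1L, ceiling(u[changed] / p_each))  # 1..3
      alts <- t(vapply(idx[changed], function(i) DNA_BASES[-i], character(3)))
      bases[changed] <- alts[cbind(seq_along(slot), slot)]
    }
  }
  if (indel_rate > 0 && t > 0) {
    n_ev <- rbinom(1, n, pmin(1, indel_rate * t))
    if (n_ev > 0) {
      pos <- sort(sample.int(n, n_ev))
      for (p0 in rev(pos)) {  # right-to-left so positions stay valid
        len <- 1L + stats::rgeom(1, 0.5)
        if (runif(1) < 0.5) {  # deletion
          keep <- setdiff(seq_along(bases), p0:min(length(bases), p0 + len - 1L))
          bases <- bases[keep]
        } else {               # insertion
          ins <- sample(DNA_BASES, len, replace = TRUE)
          bases <- append(bases, ins, after = p0)
        }
      }
    }
  }
  paste(bases, collapse = "")
}

#' Evolve a CRM sequence along a rooted tree
#'
#' Per-site substitution follows the Jukes-Cantor model: along a branch of
#' length \eqn{b} the expected number of substitutions per site is
#' \code{rate * b}, and the probability that a site differs from its
#' ancestor is \eqn{\frac{3}{4}(1 - e^{-4 rate\, b/3})}. Indels are off by
#' default; a small indel rate is available for orthology stress tests.
#'
#' @param ancestor ancestral sequence (non-empty string).
#' @param tree an \pkg{ape} \code{phylo} object with branch lengths, or a
#'   Newick string.
#' @param rate expected substitutions per site per unit branch length.
#' @param seed integer seed.
#' @param indel_rate indel events per site per unit branch length.
#' @return named character vector with one descendant sequence per leaf.
#' @export
evolve_crm <- function(ancestor, tree, rate = 1, seed = 1L, indel_rate = 0) {
  if (!is.character(ancestor) || nchar(ancestor) < 1)
    stop("ancestor sequence must be non-empty")
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object or Newick string")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  set.seed(seed)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- vector("list", max(tree$edge))
  seqs[[root]] <- ancestor
  # edges in ape preorder-compatible order after reorder()
  tree <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1]; child <- tree$edge[k, 2]
    seqs[[child]] <- evolve_branch(seqs[[par]], rate * tree$edge.length[k],
                                   indel_rate = indel_rate)
  }
  setNames(unlist(seqs[seq_len(n_tip)]), tree$tip.label)
}

#' Simulate 4C-seq reads from a fragment library
#'
#' Captured fragments are drawn with probability proportional to
#' \eqn{(1 + |d|)^{-\alpha}} where \eqn{d} is the distance from the
#' fragment midpoint to the viewpoint, restricted to informative fragments
#' (valid, inside the analysis interval, outside the exclusion zone).
#' Each read consists of the viewpoint primer followed by fragment
#' sequence starting at one of the two primary-enzyme boundaries of the
#' captured fragment (reads from the downstream boundary run inward on
#' the reverse strand). A configurable fraction of decoy reads carries a
#' non-matching primer. Ligation-junction chimeras are not modelled;
#' reads stay within their fragment.
#'
#' @param library a [fragment_library] built from the simulated genome.
#' @param viewpoint a [viewpoint_spec].
#' @param alpha distance-decay exponent (> 0).
#' @param n_reads total number of reads, decoys included.
#' @param seed integer seed.
#' @param read_length read length after the primer, in bp.
#' @param decoy_fraction expected fraction of reads with a corrupted
#'   primer.
#' @return list of class \code{sim4c} with \code{reads} (character
#'   vector), and \code{truth}: per-fragment capture probabilities
#'   (\code{prob}, summing to 1 over informative fragments), true capture
#'   counts (\code{count}), and \code{n_decoy}.
#' @export
simulate_4c_reads <- function(library, viewpoint, alpha = 1, n_reads = 10000L,
                              seed = 1L, read_length = 40L,
                              decoy_fraction = 0) {
  stopifnot(inherits(library, "fragment_library"),
            inherits(viewpoint, "viewpoint_spec"))
  if (alpha <= 0) stop("alpha must be > 0")
  mask <- informative_mask(library, viewpoint)
  frags <- library$fragments
  if (sum(mask) < 10L) stop("library has fewer than 10 informative fragments")
  set.seed(seed)
  mid <- (frags$start + frags$end) / 2
  d <- abs(mid - viewpoint$position)
  w <- ifelse(mask, (1 + d)^(-alpha), 0)
  prob <- w / sum(w)
  n_decoy <- rbinom(1L, n_reads, decoy_fraction)
  n_real <- n_reads - n_decoy
  counts <- as.vector(rmultinom(1L, n_real, prob))
  genome <- library$genomes[[viewpoint$chrom]]

  frag_read <- function(i, upstream) {
    s <- frags$start[i]; e <- frags$end[i]
    if (upstream) {
      substr(genome, s + 1L, min(s + read_length, e))
    } else {
      revcomp(substr(genome, max(s + 1L, e - read_length + 1L), e))
    }
  }
  reads <- character(0)
  hit_idx <- which(counts > 0)
  for (i in hit_idx) {
    up <- runif(counts[i]) < 0.5
    pre <- frag_read(i, TRUE); suf <- frag_read(i, FALSE)
    reads <- c(reads, paste0(viewpoint$primer, ifelse(up, pre, suf)))
  }
  if (n_decoy > 0) {
    # corrupt the first primer base (cyclic shift guarantees a mismatch)
    bad_primer <- viewpoint$primer
    substr(bad_primer, 1L, 1L) <- chartr("ACGT", "CGTA",
                                         substr(bad_primer, 1L, 1L))
    di <- sample(which(mask), n_decoy, replace = TRUE, prob = prob[mask])
    dreads <- vapply(di, function(i)
      paste0(bad_primer, frag_read(i, runif(1) < 0.5)), character(1))
    reads <- c(reads, dreads)
  }
  reads <- sample(reads)  # shuffle read order
  structure(list(reads = reads,
                 truth = list(prob = prob, count = counts, n_decoy = n_decoy,
                              mask = mask)),
            class = "sim4c")
}

#' Simulate a replicate-level Cq table
#'
#' Target-gene Cq values are \code{baseline - log2(expression) + noise}
#' where expression is the group fold change; the reference gene is
#' independent of group. With zero noise the recovered 2^-ddCq fold
#' changes equal the specified ones exactly.
#'
#' @param group_sizes named integer vector of replicates per group; the
#'   first group is the control unless \code{control_group} is given.
#' @param fold_changes named numeric vector (> 0) of true expression fold
#'   changes per group relative to control (control is 1).
#' @param noise_sd Gaussian noise SD in cycles, applied to each Cq
#'   measurement.
#' @param seed integer seed.
#' @param target_gene,reference_gene gene labels written to the table.
#' @param baseline_target,baseline_reference baseline Cq of the two genes
#'   in the control group.
#' @return data.frame with columns sample, group, gene, Cq, replicate.
#' @export
simulate_cq <- function(group_sizes, fold_changes, noise_sd = 0.2, seed = 1L,
                        target_gene = "target", reference_gene = "reference",
                        baseline_target = 22, baseline_reference = 18) {
  if (any(group_sizes < 1)) stop("group sizes must be positive")
  if (any(fold_changes <= 0)) stop("fold changes must be > 0")
  groups <- names(group_sizes)
  if (is.null(groups)) stop("group_sizes must be named")
  if (!all(groups %in% names(fold_changes)))
    stop("fold_changes must name every group")
  set.seed(seed)
  recs <- lapply(groups, function(g) {
    n <- group_sizes[[g]]
    fc <- fold_changes[[g]]
    cq_t <- baseline_target - log2(fc) + rnorm(n, 0, noise_sd)
    cq_r <- baseline_reference + rnorm(n, 0, noise_sd)
    samp <- sprintf("%s_rep%d", g, seq_len(n))
    rbind(
      data.frame(sample = samp, group = g, gene = target_gene, Cq = cq_t,
                 replicate = seq_len(n), stringsAsFactors = FALSE),
      data.frame(sample = samp, group = g, gene = reference_gene, Cq = cq_r,
                 replicate = seq_len(n), stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Plant motif instances in a background sequence
#'
#' Writes the consensus (top-count base per column) of each supplied PWM
#' at the requested offsets and strands, overwriting the background.
#'
#' @param sequence background sequence.
#' @param pwms list of [pwm] objects.
#' @param plant data.frame with columns \code{pwm} (index or id),
#'   \code{offset} (0-based), \code{strand} ("+"/"-").
#' @return list with the modified \code{sequence} and the realised
#'   \code{plant} table (with planted substrings).
#' @export
plant_motifs <- function(sequence, pwms, plant) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  ids <- vapply(pwms, function(p) p$id, character(1))
  planted <- character(nrow(plant))
  for (k in seq_len(nrow(plant))) {
    p <- plant$pwm[k]
    pw <- if (is.numeric(p)) pwms[[p]] else pwms[[match(p, ids)]]
    cons <- pwm_consensus(pw)
    if (plant$strand[k] == "-") cons <- revcomp(cons)
    off <- plant$offset[k]
    if (off < 0 || off + nchar(cons) > nchar(sequence))
      stop("planted motif exceeds sequence bounds")
    substr(sequence, off + 1L, off + nchar(cons)) <- cons
    planted[k] <- cons
  }
  plant$planted <- planted
  list(sequence = sequence, plant = plant)
}
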