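# Umbrella configuration and the end-to-end synthetic pipeline run.

default_config <- function() {
  list(
    seed = 1L,
    out_dir = "crmkit_run",
    # synthetic genome
    genome_length = 60000L,
    gc_fraction = 0.5,
    # digestion / 4C
    primary_motif = "GATC",
    secondary_motif = "CATG",
    min_frag_length = 20L,
    window_width = 5L,
    exclusion_radius = 2000L,
    viewpoint_fraction = 0.5,   # viewpoint position as fraction of genome
    primer_length = 20L,
    decay_alpha = 1,
    n_reads = 20000L,
    decoy_fraction = 0.05,
    read_length = 40L,
    # orthology
    evalue_max = 1e-5,
    word_size = 11L,
    substitution_rate = 0.1,
    crm_length = 600L,
    # conservation
    conservation_window = 100L,
    conservation_threshold = 70,
    # motifs
    p_threshold = 0.01,
    pseudocount = 0.1,
    # qPCR
    group_sizes = c(wild_type = 7L, mutant = 7L),
    fold_changes = c(wild_type = 1, mutant = 0.5),
    cq_noise_sd = 0.2
  )
}

#' Build a validated pipeline configuration
#'
#' Starts from the package defaults and overrides the supplied fields;
#' unknown keys are rejected before any work happens. The resolved
#' configuration is written next to the outputs of every [run_pipeline]
#' call.
#'
#' @param ... named overrides of the default parameters.
#' @return named list of class \code{run_config}.
#' @export
run_config <- function(...) {
  over <- list(...)
  base <- default_config()
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("all configuration overrides must be named")
    unknown <- setdiff(names(over), names(base))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    base[names(over)] <- over
  }
  structure(base, class = "run_config")
}

write_config <- function(config, path) {
  flat <- vapply(config, function(v)
    paste(format(v, scientific = FALSE, trim = TRUE), collapse = ","),
    character(1))
  writeLines(paste0(names(config), "\t", flat), path)
  invisible(path)
}

#' Run the full synthetic pipeline from one seed
#'
#' Generates a genome, digests it, simulates two 4C genotypes (the
#' variant with one fragment's capture weight doubled), writes profiles
#' and their subtraction, evolves a CRM ortholog into a second genome and
#' runs BBH detection, plants motif sites and designs verified
#' mutations, and simulates plus analyses a Cq table. All outputs are
#' plain text; a manifest with md5 checksums makes reruns comparable.
#'
#' @param config a [run_config].
#' @param out_dir output directory (defaults to \code{config$out_dir}).
#' @return invisibly, the manifest data.frame (file, md5).
#' @export
run_pipeline <- function(config = run_config(), out_dir = config$out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_config(config, p("config.tsv"))

  # --- genome + digestion -------------------------------------------------
  genome <- make_genome(config$genome_length, config$gc_fraction,
                        seed = split_seed(config$seed, 1L))
  write_fasta(genome, p("genome.fa"))
  lib <- digest(genome, config$primary_motif, config$secondary_motif,
                config$min_frag_length)
  frags <- lib$fragments
  write_bed(data.frame(chrom = frags$chrom, start = frags$start,
                       end = frags$end,
                       name = sprintf("frag%05d", seq_len(nrow(frags))),
                       score = as.integer(frags$valid)),
            p("fragments.bed"))

  # --- 4C: two genotypes + subtraction ------------------------------------
  vp_pos <- floor(config$genome_length * config$viewpoint_fraction)
  primer <- substr(genome[[1]], vp_pos + 1L, vp_pos + config$primer_length)
  vp <- viewpoint_spec(names(genome)[1], vp_pos, primer,
                       exclusion_radius = config$exclusion_radius)
  sims <- lapply(c(a = 2L, b = 3L), function(s)
    simulate_4c_reads(lib, vp, alpha = config$decay_alpha,
                      n_reads = config$n_reads,
                      seed = split_seed(config$seed, s),
                      read_length = config$read_length,
                      decoy_fraction = config$decoy_fraction))
  profiles <- lapply(sims, function(sim) {
    kept <- filter_primer_reads(sim$reads, primer)$kept
    counts <- assign_reads(kept, lib)$counts
    viewpoint_profile(lib, vp, counts, config$window_width)
  })
  write_fastq(sims[[1]]$reads, p("reads_a.fastq"))
  write_bedgraph(profile_bedgraph(profiles[[1]]), p("profile_a.bedgraph"))
  write_bedgraph(profile_bedgraph(profiles[[2]]), p("profile_b.bedgraph"))
  delta <- subtract_profiles(profiles[[1]], profiles[[2]])
  write_bedgraph(profile_bedgraph(profiles[[1]], delta),
                 p("subtraction_a_minus_b.bedgraph"))

  # --- orthology ----------------------------------------------------------
  crm_start <- floor(config$genome_length * 0.2)
  crm <- list(chrom = names(genome)[1], start = crm_start,
              end = crm_start + config$crm_length, name = "CRM_sim")
  crm_seq <- substr(genome[[1]], crm$start + 1L, crm$end)
  diverged <- evolve_branch_seeded(crm_seq, config$substitution_rate,
                                   split_seed(config$seed, 4L))
  target <- make_genome(config$genome_length, config$gc_fraction,
                        seed = split_seed(config$seed, 5L), name = "t_chr1")
  ins <- floor(config$genome_length * 0.6)
  substr(target[[1]], ins + 1L, ins + nchar(diverged)) <- diverged
  write_fasta(target, p("target_genome.fa"))
  params <- search_params(evalue_max = config$evalue_max,
                          word_size = config$word_size)
  orth <- bbh_detect(crm, genome, target, params)
  orth_df <- data.frame(
    crm = orth$crm_id, genome = names(target)[1], status = orth$status,
    forward = if (is.null(orth$forward_hit)) NA else
      sprintf("%s:%d-%d", orth$forward_hit$t_chrom, orth$forward_hit$t_start,
              orth$forward_hit$t_end),
    forward_evalue = if (is.null(orth$forward_hit)) NA else
      orth$forward_hit$evalue,
    overlap_bp = orth$overlap_bp)
  write.table(orth_df, p("orthology.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  aln <- global_align(crm_seq, diverged)
  cons <- conservation_windows(aln, config$conservation_window,
                               config$conservation_threshold)
  write_bedgraph(data.frame(chrom = crm$name, start = cons$identity$pos,
                            end = cons$identity$pos + 1,
                            value = cons$identity$identity),
                 p("conservation.bedgraph"))
  if (nrow(cons$calls))
    write_bed(data.frame(chrom = crm$name, start = cons$calls$start,
                         end = cons$calls$end), p("conserved_calls.bed"))

  # --- motifs -------------------------------------------------------------
  gli <- example_gli_pwm(pseudocount = config$pseudocount)
  hox <- example_hox13_pwm(pseudocount = config$pseudocount)
  enh <- make_genome(1500L, config$gc_fraction, seed = split_seed(config$seed, 6L),
                     name = "enhancer")
  planted <- plant_motifs(enh[[1]], list(gli, hox),
                          data.frame(pwm = c(1, 2, 1), offset = c(200, 600, 1000),
                                     strand = c("+", "-", "+")))
  hits <- scan_pwms(planted$sequence, list(gli, hox), config$p_threshold,
                    seq_id = "enhancer")
  write_bed(data.frame(chrom = hits$seq_id, start = hits$start, end = hits$end,
                       name = hits$motif,
                       score = round(-log10(hits$pvalue), 4),
                       strand = hits$strand),
            p("motif_hits.bed"))
  plan <- design_mutations(planted$sequence, list(gli, hox),
                           p_threshold = config$p_threshold)
  write.table(plan$edits, p("mutagenesis_edits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("accepted\t%s", plan$accepted),
               sprintf("rounds\t%d", plan$rounds),
               sprintf("n_edits\t%d", nrow(plan$edits))),
             p("mutagenesis_report.txt"))

  # --- qPCR ---------------------------------------------------------------
  cq <- simulate_cq(config$group_sizes, config$fold_changes,
                    noise_sd = config$cq_noise_sd,
                    seed = split_seed(config$seed, 7L))
  write_cq_table(cq, p("cq_table.tsv"))
  fc <- ddcq_fold_change(cq, control_group = names(config$group_sizes)[1])
  write.table(fc$summary, p("qpcr_summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # --- manifest -----------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir), "manifest.tsv"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir, files))),
                         stringsAsFactors = FALSE)
  write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(manifest)
}

# Seeded single-branch evolution helper used by the pipeline and tests.
evolve_branch_seeded <- function(seq, t, seed, indel_rate = 0) {
  set.seed(seed)
  evolve_branch(seq, t, indel_rate = indel_rate)
}

#' Example Gli-like PWM
#'
#' A high-information 9-column count matrix modelled on the GLI-family
#' consensus GACCACCCA; a stand-in for a ChIP-derived Gli matrix, used by
#' the synthetic pipeline and the test-suite.
#'
#' @param pseudocount pseudocount passed to [pwm].
#' @return a [pwm] object with id \code{"Gli_like"}.
#' @export
example_gli_pwm <- function(pseudocount = 0.1) {
  cons <- "GACCACCCA"
  counts <- consensus_counts(cons, major = 85, minor = 5)
  pwm(counts, pseudocount = pseudocount, id = "Gli_like")
}

#' Example Hox13-like PWM
#'
#' An 8-column count matrix modelled on the posterior-Hox AT-rich
#' consensus TTTTATGG (HOXD13-style); a synthetic stand-in used by the
#' pipeline and tests.
#'
#' @param pseudocount pseudocount passed to [pwm].
#' @return a [pwm] object with id \code{"Hox13_like"}.
#' @export
example_hox13_pwm <- function(pseudocount = 0.1) {
  cons <- "TTTTATGG"
  counts <- consensus_counts(cons, major = 82, minor = 6)
  pwm(counts, pseudocount = pseudocount, id = "Hox13_like")
}

# Count matrix with `major` counts on the consensus base per column and
# `minor` on the others.
consensus_counts <- function(consensus, major = 85, minor = 5) {
  b <- strsplit(consensus, "", fixed = TRUE)[[1]]
  counts <- matrix(minor, nrow = 4, ncol = length(b),
                   dimnames = list(DNA_BASES, NULL))
  counts[cbind(match(b, DNA_BASES), seq_along(b))] <- major
  counts
}
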