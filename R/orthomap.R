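# CRM orthology detection across genomes: a built-in seed-and-extend local
# search engine with Karlin-Altschul E-values, the modified
# bidirectional-best-hit (BBH) procedure, Gblocks-style alignment column
# trimming, and VISTA-style windowed conservation calling.

#' Parameters for the local search engine
#'
#' Defaults follow common nucleotide-search practice: 11-nt words,
#' match +1 / mismatch -2 scoring, and the Karlin-Altschul constants for
#' that scoring (lambda ~ 1.28 nats, K ~ 0.46). The E-value of a hit of
#' score S against a query of length m and database of length n is
#' \eqn{E = K m n e^{-\lambda S}}.
#'
#' @param evalue_max E-value cap; only hits below it are reported.
#' @param word_size seed word length in nt (>= 4).
#' @param match,mismatch match reward and mismatch penalty.
#' @param xdrop ungapped extension stops when the running score falls
#'   this far below the best score seen.
#' @param karlin_lambda,karlin_k Karlin-Altschul statistics constants.
#' @return list of class \code{search_params}.
#' @export
search_params <- function(evalue_max = 1e-5, word_size = 11L, match = 1,
                          mismatch = -2, xdrop = 20,
                          karlin_lambda = 1.28, karlin_k = 0.46) {
  if (evalue_max <= 0) stop("evalue_max must be > 0")
  if (word_size < 4L) stop("word_size must be >= 4")
  structure(list(evalue_max = evalue_max, word_size = as.integer(word_size),
                 match = match, mismatch = mismatch, xdrop = xdrop,
                 karlin_lambda = karlin_lambda, karlin_k = karlin_k),
            class = "search_params")
}

# Ungapped seed-and-extend search of a query against one strand of one
# chromosome. qvec/tvec are integer-encoded sequences.
search_one_strand <- function(qseq, qvec, tseq, tvec, params) {
  w <- params$word_size
  nq <- length(qvec); nt <- length(tvec)
  if (nq < w || nt < w) return(NULL)
  twords <- substring(tseq, seq_len(nt - w + 1L), seq_len(nt - w + 1L) + w - 1L)
  qwords <- substring(qseq, seq_len(nq - w + 1L), seq_len(nq - w + 1L) + w - 1L)
  pos_by_word <- split(seq_along(twords), twords)
  hit_lists <- pos_by_word[qwords]
  seeds_q <- rep(seq_along(qwords), lengths(hit_lists))
  seeds_t <- unlist(hit_lists, use.names = FALSE)
  if (length(seeds_q) == 0L) return(NULL)
  diag <- seeds_t - seeds_q
  ord <- order(diag, seeds_q)
  seeds_q <- seeds_q[ord]; seeds_t <- seeds_t[ord]; diag <- diag[ord]
  hsps <- list()
  covered_hi <- -Inf; covered_diag <- NA
  for (k in seq_along(seeds_q)) {
    qs <- seeds_q[k]; ts <- seeds_t[k]; dg <- diag[k]
    if (!is.na(covered_diag) && dg == covered_diag && qs <= covered_hi) next
    # extend left from (qs, ts) and right from seed end
    sc <- ifelse(qvec[qs:(qs + w - 1L)] == tvec[ts:(ts + w - 1L)],
                 params$match, params$mismatch)
    score <- sum(sc)
    best <- score; bl <- 0L; br <- 0L
    # leftward
    i <- qs - 1L; j <- ts - 1L; run <- score; ext <- 0L
    while (i >= 1L && j >= 1L) {
      run <- run + if (qvec[i] == tvec[j]) params$match else params$mismatch
      ext <- ext + 1L
      if (run > best) { best <- run; bl <- ext }
      if (run < best - params$xdrop) break
      i <- i - 1L; j <- j - 1L
    }
    # rightward from the best-left extension state
    run <- best
    i <- qs + w; j <- ts + w; ext <- 0L
    while (i <= nq && j <= nt) {
      run <- run + if (qvec[i] == tvec[j]) params$match else params$mismatch
      ext <- ext + 1L
      if (run > best) { best <- run; br <- ext }
      if (run < best - params$xdrop) break
      i <- i + 1L; j <- j + 1L
    }
    q1 <- qs - bl; q2 <- qs + w - 1L + br
    hsps[[length(hsps) + 1L]] <-
      c(qstart = q1, qend = q2, tstart = ts - bl, tend = ts + w - 1L + br,
        score = best)
    covered_diag <- dg; covered_hi <- q2
  }
  do.call(rbind, hsps)
}

#' Local similarity search (seed-and-extend)
#'
#' Finds ungapped local alignments of a query in a target genome on both
#' strands, scores them with match/mismatch rewards, assigns
#' Karlin-Altschul E-values and returns hits below the E-value cap sorted
#' by ascending E. The engine signature is intentionally minimal so an
#' external search tool can be swapped in (see \code{engine} in
#' [bbh_detect]).
#'
#' @param query query sequence (length >= 2 * word_size).
#' @param target_genome named character vector of chromosome sequences.
#' @param params a [search_params] object.
#' @return data.frame of hits: q_start, q_end (0-based half-open in the
#'   query), t_chrom, t_start, t_end (target, forward coordinates),
#'   strand, score, evalue. Zero rows when nothing passes the cap.
#' @export
local_search <- function(query, target_genome, params = search_params()) {
  stopifnot(is.character(query), length(query) == 1L)
  if (is.null(names(target_genome)) && length(target_genome) == 1L)
    names(target_genome) <- "chr1"
  if (any(!nzchar(target_genome))) stop("empty target genome sequence")
  if (nchar(query) < 2L * params$word_size)
    stop("query shorter than 2 * word_size")
  m <- nchar(query)
  n_total <- sum(nchar(target_genome))
  qvec_f <- encode_dna(query)
  qrc <- revcomp(query)
  qvec_r <- encode_dna(qrc)
  out <- list()
  for (chrom in names(target_genome)) {
    tseq <- target_genome[[chrom]]
    tvec <- encode_dna(tseq)
    nt <- length(tvec)
    for (strand in c("+", "-")) {
      qs <- if (strand == "+") query else qrc
      qv <- if (strand == "+") qvec_f else qvec_r
      h <- search_one_strand(qs, qv, tseq, tvec, params)
      if (is.null(h)) next
      h <- as.data.frame(h)
      # map query coordinates of minus-strand hits back to the original frame
      if (strand == "-") {
        q1 <- m - h$qend + 1L
        q2 <- m - h$qstart + 1L
        h$qstart <- q1; h$qend <- q2
      }
      out[[length(out) + 1L]] <- data.frame(
        q_start = h$qstart - 1L, q_end = h$qend,
        t_chrom = chrom, t_start = h$tstart - 1L, t_end = h$tend,
        strand = strand, score = h$score,
        evalue = params$karlin_k * m * n_total *
          exp(-params$karlin_lambda * h$score),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(q_start = integer(0), q_end = integer(0),
                      t_chrom = character(0), t_start = integer(0),
                      t_end = integer(0), strand = character(0),
                      score = numeric(0), evalue = numeric(0)))
  hits <- do.call(rbind, out)
  # drop duplicated intervals (same HSP reached from several seeds)
  hits <- hits[!duplicated(hits[, c("t_chrom", "t_start", "t_end", "strand")]), ]
  hits <- hits[hits$evalue < params$evalue_max, , drop = FALSE]
  hits <- hits[order(hits$evalue, -hits$score, hits$t_start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Bidirectional-best-hit orthology detection for one CRM
#'
#' Implements the modified BBH procedure: (1) search the CRM sequence in
#' the target genome and keep hits with E below the cap; (2) for the
#' top-scoring hit, extract the target interval of the alignment extended
#' by the unaligned query flank lengths and a further 20 nt per side to
#' accommodate indels, clipped to the chromosome; (3) search that extract
#' back against the source genome; (4) the orthologous region is
#' \emph{detected} iff some reciprocal hit below the cap overlaps the
#' original CRM interval by at least 1 bp.
#'
#' @param crm list or single-row data.frame with \code{chrom},
#'   \code{start}, \code{end} (0-based half-open) and optionally
#'   \code{name}.
#' @param source_genome,target_genome named character vectors of
#'   chromosome sequences.
#' @param params a [search_params].
#' @param engine search function with the signature of [local_search];
#'   replaceable by an external tool wrapper.
#' @param flank_extension nt added to each side of the extracted target
#'   region (default 20).
#' @return object of class \code{orthology_result}: status
#'   ("detected"/"not_detected"), the forward hit, the extracted target
#'   interval, the best overlapping reciprocal hit and \code{overlap_bp}.
#' @export
bbh_detect <- function(crm, source_genome, target_genome,
                       params = search_params(), engine = local_search,
                       flank_extension = 20L) {
  if (is.data.frame(crm)) crm <- as.list(crm[1, ])
  chrom <- crm$chrom
  if (!chrom %in% names(source_genome)) stop("CRM chromosome not in source genome")
  src_len <- nchar(source_genome[[chrom]])
  if (crm$start < 0 || crm$end > src_len || crm$start >= crm$end)
    stop("CRM interval invalid in source genome")
  qseq <- substr(source_genome[[chrom]], crm$start + 1L, crm$end)
  qlen <- nchar(qseq)
  res <- list(crm_id = crm$name %||% sprintf("%s:%d-%d", chrom, crm$start, crm$end),
              status = "not_detected", forward_hit = NULL,
              extract_interval = NULL, reciprocal_hit = NULL, overlap_bp = 0L)
  fwd <- engine(qseq, target_genome, params)
  if (nrow(fwd) == 0L) return(structure(res, class = "orthology_result"))
  best <- fwd[1, ]
  res$forward_hit <- best
  # unaligned query flanks, swapped for minus-strand hits
  left_q <- best$q_start
  right_q <- qlen - best$q_end
  if (best$strand == "-") { tmp <- left_q; left_q <- right_q; right_q <- tmp }
  tchrom_len <- nchar(target_genome[[best$t_chrom]])
  lo <- max(0L, best$t_start - left_q - flank_extension)
  hi <- min(tchrom_len, best$t_end + right_q + flank_extension)
  res$extract_interval <- list(chrom = best$t_chrom, start = lo, end = hi)
  extract <- substr(target_genome[[best$t_chrom]], lo + 1L, hi)
  rec <- engine(extract, source_genome, params)
  if (nrow(rec) == 0L) return(structure(res, class = "orthology_result"))
  # only the best reciprocal hit decides: a paralog more similar to the
  # extract than the original CRM therefore breaks the reciprocity test
  best_rec <- rec[1, ]
  res$reciprocal_hit <- best_rec
  ov <- if (best_rec$t_chrom == chrom)
    interval_overlap(best_rec$t_start, best_rec$t_end, crm$start, crm$end)
  else 0
  if (ov >= 1) {
    res$status <- "detected"
    res$overlap_bp <- as.integer(ov)
  }
  structure(res, class = "orthology_result")
}

#' @export
print.orthology_result <- function(x, ...) {
  cat("orthology_result:", x$crm_id, "->", x$status)
  if (x$status == "detected")
    cat(sprintf(" (reciprocal overlap %d bp, E = %.3g)", x$overlap_bp,
                x$reciprocal_hit$evalue))
  cat("\n")
  invisible(x)
}

#' Gblocks-style trimming of a multiple sequence alignment
#'
#' Removes alignment columns whose gap fraction exceeds
#' \code{max_gap_fraction} (default 50\%), then drops surviving runs of
#' consecutive columns shorter than \code{min_block_length} (default 10).
#'
#' @param alignment named character vector of >= 2 equal-length aligned
#'   sequences (gaps '-').
#' @param max_gap_fraction maximum tolerated per-column gap fraction.
#' @param min_block_length minimum length of a retained column block.
#' @return object of class \code{trimmed_msa}: the trimmed
#'   \code{alignment}, the 1-based \code{kept_columns} map into the input
#'   and the parameters.
#' @export
trim_msa <- function(alignment, max_gap_fraction = 0.5, min_block_length = 10L) {
  if (length(alignment) < 2L) stop("alignment needs >= 2 sequences")
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) stop("aligned sequences have unequal lengths")
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-")
  keep <- gap_frac <= max_gap_fraction
  r <- rle(keep)
  r$values[r$values & r$lengths < min_block_length] <- FALSE
  keep <- inverse.rle(r)
  kept_columns <- which(keep)
  trimmed <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  if (length(kept_columns) == 0L)
    trimmed <- setNames(rep("", length(alignment)), names(alignment))
  structure(list(alignment = setNames(trimmed, names(alignment)),
                 kept_columns = kept_columns,
                 max_gap_fraction = max_gap_fraction,
                 min_block_length = as.integer(min_block_length)),
            class = "trimmed_msa")
}

#' Global pairwise alignment with affine gaps
#'
#' A thin wrapper around Needleman-Wunsch global alignment (Biostrings)
#' under match/mismatch scoring with affine gap penalties
#' (\code{gap_open + gap_extend * length} per gap). Intended for
#' desk-scale sequences (<= 50 kb).
#'
#' @param a,b sequences to align.
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_extend affine gap penalty components (positive
#'   costs).
#' @return object of class \code{pairwise_alignment}: gapped strings
#'   \code{a}, \code{b} and the alignment \code{score}.
#' @export
global_align <- function(a, b, match = 1, mismatch = -1,
                         gap_open = 2, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  if (nchar(a) > 50000 || nchar(b) > 50000)
    stop("global_align is limited to sequences <= 50 kb")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  structure(list(a = as.character(Biostrings::alignedPattern(al)),
                 b = as.character(Biostrings::alignedSubject(al)),
                 score = Biostrings::score(al)),
            class = "pairwise_alignment")
}

#' VISTA-style windowed conservation calling on a pairwise alignment
#'
#' Percent identity is computed in a sliding window of
#' \code{window_length} reference positions (windows are clamped at the
#' sequence ends). Alignment columns where the reference carries a gap do
#' not advance the reference coordinate but count as mismatches inside
#' the window span. Reference positions with identity at or above
#' \code{threshold} are merged into conserved-region calls; calls shorter
#' than \code{min_call_length} are dropped.
#'
#' @param alignment a [pairwise_alignment], or a character vector of two
#'   equal-length gapped sequences.
#' @param window_length window size in reference bp (default 100).
#' @param threshold percent identity threshold for calls (default 70).
#' @param min_call_length minimum call length in reference bp; defaults
#'   to \code{window_length}.
#' @param reference which sequence (1 or 2) provides the coordinates.
#' @return object of class \code{conservation_track}: \code{identity}
#'   data.frame (pos: 0-based reference coordinate, identity: percent)
#'   and \code{calls} data.frame (start, end, 0-based half-open).
#' @export
conservation_windows <- function(alignment, window_length = 100L,
                                 threshold = 70, min_call_length = window_length,
                                 reference = 1L) {
  if (inherits(alignment, "pairwise_alignment"))
    alignment <- c(alignment$a, alignment$b)
  stopifnot(length(alignment) == 2L, nchar(alignment[1]) == nchar(alignment[2]))
  if (reference == 2L) alignment <- rev(alignment)
  ref <- strsplit(alignment[1], "", fixed = TRUE)[[1]]
  oth <- strsplit(alignment[2], "", fixed = TRUE)[[1]]
  ref_pos_cols <- which(ref != "-")
  R <- length(ref_pos_cols)
  if (R == 0L) stop("reference sequence is all gaps")
  if (window_length > R) stop("window longer than the reference sequence")
  is_match <- ref != "-" & oth != "-" & ref == oth
  cs_match <- cumsum(c(0L, as.integer(is_match)))
  wl <- as.integer(window_length)
  i <- seq_len(R)
  lo <- pmax(1L, i - wl %/% 2L)
  hi <- pmin(R, lo + wl - 1L)
  lo <- pmax(1L, hi - wl + 1L)
  col_lo <- ref_pos_cols[lo]
  col_hi <- ref_pos_cols[hi]
  span <- col_hi - col_lo + 1L  # includes reference-gap (insertion) columns
  matches <- cs_match[col_hi + 1L] - cs_match[col_lo]
  identity <- 100 * matches / span
  above <- identity >= threshold
  r <- rle(above)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  sel <- r$values & r$lengths >= min_call_length
  calls <- data.frame(start = starts_i[sel] - 1L, end = ends_i[sel])
  structure(list(identity = data.frame(pos = i - 1L, identity = identity),
                 calls = calls, window_length = wl, threshold = threshold,
                 min_call_length = as.integer(min_call_length)),
            class = "conservation_track")
}

#' @export
print.conservation_track <- function(x, ...) {
  cat("conservation_track:", nrow(x$identity), "reference positions,",
      nrow(x$calls), "conserved call(s) at >=", x$threshold, "% identity\n")
  invisible(x)
}
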