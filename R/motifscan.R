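# PWM binding-site identification with exact score-distribution p-values,
# overlap detection between motif sets, MSA conservation marks, and
# disruptive mutagenesis design with de-novo site verification.

#' Position weight matrix with exact p-value machinery
#'
#' Builds a log-odds PWM from a count matrix: per-column probabilities
#' are \code{(count + pseudocount * background) / (colsum + pseudocount)}
#' and log-odds are \code{log2(p / background)}. Scores are discretised
#' on a fixed grid so that the exact distribution of the score of a
#' random background sequence can be computed by dynamic programming over
#' columns (see [score_to_pvalue]).
#'
#' @param counts 4 x L numeric matrix of base counts, rows A, C, G, T
#'   (row names optional but, when present, must be ACGT in some order).
#' @param background base frequencies (A, C, G, T), summing to 1.
#' @param pseudocount pseudocount mass added per column.
#' @param id motif identifier.
#' @param grid score discretisation width in log-odds units.
#' @return object of class \code{pwm}.
#' @export
pwm <- function(counts, background = rep(0.25, 4), pseudocount = 0.1,
                id = "motif", grid = 1e-3) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A, C, G, T)")
  if (!is.null(rownames(counts))) {
    if (!setequal(rownames(counts), DNA_BASES))
      stop("count matrix row names must be A, C, G, T")
    counts <- counts[DNA_BASES, , drop = FALSE]
  } else {
    rownames(counts) <- DNA_BASES
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(colSums(counts) <= 0)) stop("degenerate PWM column (all zeros)")
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  if (any(background <= 0)) stop("background frequencies must be positive")
  background <- setNames(as.numeric(background), DNA_BASES)
  probs <- sweep(counts + pseudocount * background, 2,
                 colSums(counts) + pseudocount, "/")
  log_odds <- log2(sweep(probs, 1, background, "/"))
  int_scores <- round(log_odds / grid)
  storage.mode(int_scores) <- "integer"
  obj <- structure(list(id = id, counts = counts, background = background,
                        pseudocount = pseudocount, grid = grid,
                        probs = probs, log_odds = log_odds,
                        int_scores = int_scores,
                        width = ncol(counts),
                        cache = new.env(parent = emptyenv())),
                   class = "pwm")
  obj
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm:", x$id, "-", x$width, "positions, pseudocount", x$pseudocount, "\n")
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM (top-count base per column)
#' @param x a [pwm].
#' @return consensus string; count ties resolve alphabetically.
#' @export
pwm_consensus <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste(DNA_BASES[apply(x$counts, 2, which.max)], collapse = "")
}

# Exact distribution of the integer-grid score of a random background
# k-mer: DP convolution over columns. Returns list(support, prob, cum_ge)
# with cum_ge[i] = P(score >= support[i]).
pwm_score_distribution <- function(x) {
  if (!is.null(x$cache$dist)) return(x$cache$dist)
  lo_col <- apply(x$int_scores, 2, min)
  hi_col <- apply(x$int_scores, 2, max)
  offset <- sum(lo_col)
  width_total <- sum(hi_col - lo_col)
  p <- numeric(width_total + 1L)  # index k+1 = P(score == offset + k)
  p[1] <- 1
  cur_hi <- 0L
  for (j in seq_len(x$width)) {
    newp <- numeric(width_total + 1L)
    sh <- x$int_scores[, j] - lo_col[j]
    idx <- seq_len(cur_hi + 1L)
    for (b in 1:4) {
      tgt <- idx + sh[b]
      newp[tgt] <- newp[tgt] + p[idx] * x$background[b]
    }
    p <- newp
    cur_hi <- cur_hi + (hi_col[j] - lo_col[j])
  }
  support <- offset + seq(0L, width_total)
  keep <- p > 0
  support <- support[keep]; prob <- p[keep]
  cum_ge <- rev(cumsum(rev(prob)))
  dist <- list(support = support, prob = prob, cum_ge = cum_ge)
  assign("dist", dist, envir = x$cache)
  dist
}

#' Exact p-value of a PWM score
#'
#' Returns \eqn{P(S \ge s)} where S is the log-odds score of a random
#' i.i.d. background sequence of motif length, computed exactly by
#' dynamic programming over the discretised per-column score
#' distributions. Monotone non-increasing in the score.
#'
#' @param x a [pwm].
#' @param score log-odds score (must lie within the achievable range, up
#'   to one grid step of tolerance).
#' @return p-value in (0, 1].
#' @export
score_to_pvalue <- function(x, score) {
  stopifnot(inherits(x, "pwm"))
  d <- pwm_score_distribution(x)
  s_int <- round(score / x$grid)
  if (any(s_int < min(d$support) - 1L) || any(s_int > max(d$support) + 1L))
    stop("score outside the achievable range of this PWM")
  vapply(s_int, function(s) {
    k <- which(d$support >= s)
    if (length(k) == 0L) d$cum_ge[length(d$cum_ge)] else d$cum_ge[k[1]]
  }, numeric(1))
}

# Smallest integer score whose exact p-value is < p (strict); NULL when no
# achievable score is that significant.
score_threshold_int <- function(x, p) {
  d <- pwm_score_distribution(x)
  k <- which(d$cum_ge < p)
  if (length(k) == 0L) return(NULL)
  d$support[k[1]]
}

#' Scan a sequence for PWM binding sites
#'
#' Reports every window whose exact p-value is below \code{p_threshold},
#' on the requested strands. Coordinates are always on the forward frame;
#' a minus-strand hit at \code{[start, end)} means the reverse complement
#' of that window matches the motif.
#'
#' @param sequence sequence to scan (>= motif length).
#' @param x a [pwm].
#' @param p_threshold p-value cutoff (default 0.01, strict inequality).
#' @param strands "both", "+" or "-".
#' @param seq_id sequence identifier carried into the hit table.
#' @return data.frame of hits: seq_id, motif, start, end (0-based
#'   half-open), strand, score (log-odds), pvalue; sorted by start.
#' @export
scan_pwm <- function(sequence, x, p_threshold = 0.01, strands = "both",
                     seq_id = "seq") {
  stopifnot(inherits(x, "pwm"))
  L <- nchar(sequence); w <- x$width
  if (L < w) stop("sequence shorter than the motif")
  thr <- score_threshold_int(x, p_threshold)
  empty <- data.frame(seq_id = character(0), motif = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      pvalue = numeric(0))
  if (is.null(thr)) return(empty)
  code <- encode_dna(sequence)
  n_win <- L - w + 1L
  win_scores <- function(code) {
    s <- integer(n_win)
    ok <- rep(TRUE, n_win)
    for (j in seq_len(w)) {
      b <- code[j:(j + n_win - 1L)]
      bad <- is.na(b)
      ok <- ok & !bad
      b[bad] <- 1L
      s <- s + x$int_scores[cbind(b, j)]
    }
    s[!ok] <- NA_integer_
    s
  }
  hits <- list()
  if (strands %in% c("both", "+")) {
    s <- win_scores(code)
    sel <- which(!is.na(s) & s >= thr)
    if (length(sel))
      hits[["+"]] <- data.frame(seq_id = seq_id, motif = x$id,
                                start = sel - 1L, end = sel - 1L + w,
                                strand = "+", score = s[sel] * x$grid,
                                pvalue = score_to_pvalue(x, s[sel] * x$grid),
                                stringsAsFactors = FALSE)
  }
  if (strands %in% c("both", "-")) {
    rc <- encode_dna(revcomp(sequence))
    s <- win_scores(rc)
    sel <- which(!is.na(s) & s >= thr)
    if (length(sel)) {
      # window i (1-based) on the RC maps to forward start L - i - w + 1
      fstart <- L - (sel - 1L) - w
      hits[["-"]] <- data.frame(seq_id = seq_id, motif = x$id,
                                start = fstart, end = fstart + w,
                                strand = "-", score = s[sel] * x$grid,
                                pvalue = score_to_pvalue(x, s[sel] * x$grid),
                                stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Scan with several PWMs at once
#' @param sequence sequence to scan.
#' @param pwms list of [pwm] objects.
#' @inheritParams scan_pwm
#' @return combined hit data.frame (see [scan_pwm]).
#' @export
scan_pwms <- function(sequence, pwms, p_threshold = 0.01, strands = "both",
                      seq_id = "seq") {
  out <- do.call(rbind, lapply(pwms, function(p)
    scan_pwm(sequence, p, p_threshold, strands, seq_id)))
  out <- out[order(out$start, out$motif), ]
  rownames(out) <- NULL
  out
}

#' Overlapping-site regions between two motif hit sets
#'
#' Finds pairs of hits (one from each set) whose intervals intersect by
#' at least 1 bp, strand-agnostic, and merges the paired spans into
#' maximal regions.
#'
#' @param hits_a,hits_b hit data.frames from [scan_pwm] on the same
#'   sequence.
#' @return data.frame of merged regions (start, end, n_pairs).
#' @export
overlap_sites <- function(hits_a, hits_b) {
  empty <- data.frame(start = integer(0), end = integer(0), n_pairs = integer(0))
  if (nrow(hits_a) == 0L || nrow(hits_b) == 0L) return(empty)
  regions <- list()
  for (i in seq_len(nrow(hits_a))) {
    ov <- interval_overlap(hits_a$start[i], hits_a$end[i],
                           hits_b$start, hits_b$end)
    for (j in which(ov >= 1)) {
      regions[[length(regions) + 1L]] <-
        c(min(hits_a$start[i], hits_b$start[j]),
          max(hits_a$end[i], hits_b$end[j]))
    }
  }
  if (length(regions) == 0L) return(empty)
  m <- do.call(rbind, regions)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out <- list(); cur <- m[1, ]; n_pairs <- 1L
  if (nrow(m) > 1L) for (k in 2:nrow(m)) {
    if (m[k, 1] < cur[2]) {  # overlap >= 1 bp with the open region
      cur[2] <- max(cur[2], m[k, 2]); n_pairs <- n_pairs + 1L
    } else {
      out[[length(out) + 1L]] <- c(cur, n_pairs)
      cur <- m[k, ]; n_pairs <- 1L
    }
  }
  out[[length(out) + 1L]] <- c(cur, n_pairs)
  res <- as.data.frame(do.call(rbind, out))
  names(res) <- c("start", "end", "n_pairs")
  res
}

#' Fully conserved MSA columns
#'
#' Returns the columns where every sequence carries the same base and no
#' sequence has a gap - the positions that would be marked with an
#' asterisk under an alignment.
#'
#' @param msa named character vector of equal-length aligned sequences.
#' @return integer vector of 1-based column indices.
#' @export
conserved_columns <- function(msa) {
  if (length(msa) == 0L) stop("empty alignment")
  if (length(unique(nchar(msa))) != 1L) stop("aligned lengths differ")
  mat <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  same <- apply(mat, 2, function(col) length(unique(col)) == 1L && col[1] != "-")
  which(same)
}

# Lowest log-odds replacement base at PWM column j, excluding `current`;
# ties resolve alphabetically (log_odds rows are in ACGT order).
worst_base <- function(x, j, current) {
  lo <- x$log_odds[, j]
  cand <- setdiff(DNA_BASES, current)
  cand[which.min(lo[cand])]
}

# Choose one disruptive edit for a hit on `mutant`. Columns are tried in
# decreasing information content (ties left to right) and bases in
# increasing log-odds (ties alphabetical) - the greedy
# highest-IC/lowest-log-odds rule - but a candidate is committed only if,
# after the substitution, no PWM hit covers the edited position (this is
# what prevents an edit from silently creating a de-novo site, e.g. on the
# opposite strand of an AT-rich motif). If no candidate is locally clean,
# the primary greedy edit is applied anyway and later rounds continue.
choose_edit <- function(mutant, hit, x, pwms, p_threshold, maxw) {
  ic <- apply(x$probs, 2, function(p) 2 + sum(p * log2(p)))
  ord <- order(-ic, seq_along(ic))
  fallback <- NULL
  for (j in ord) {
    pos <- if (hit$strand == "+") hit$start + j else hit$end - j + 1L
    cur <- substr(mutant, pos, pos)
    cur_m <- if (hit$strand == "+") cur else chartr("ACGT", "TGCA", cur)
    cand_m <- setdiff(DNA_BASES, cur_m)
    cand_m <- cand_m[order(x$log_odds[cand_m, j], cand_m)]
    cand_f <- if (hit$strand == "+") cand_m else chartr("ACGT", "TGCA", cand_m)
    # fallback: first substitution (IC order) that strictly lowers the score,
    # so repeated rounds keep making progress instead of re-editing column 1
    if (is.null(fallback) &&
        x$log_odds[cand_m[1], j] < x$log_odds[cur_m, j])
      fallback <- list(pos = pos, alt = cand_f[1])
    for (alt in cand_f) {
      trial <- mutant
      substr(trial, pos, pos) <- alt
      lo <- max(1L, pos - maxw + 1L)
      hi <- min(nchar(trial), pos + maxw - 1L)
      fit <- pwms[vapply(pwms, function(p) p$width, integer(1)) <= hi - lo + 1L]
      loc <- scan_pwms(substr(trial, lo, hi), fit, p_threshold)
      covered <- nrow(loc) > 0L &&
        any(loc$start + lo - 1L <= pos - 1L & loc$end + lo - 1L >= pos)
      if (!covered) return(list(pos = pos, alt = alt))
    }
  }
  # no column can lower the score further (already minimal): greedy edit of
  # the most informative column
  fallback %||% {
    j <- ord[1]
    pos <- if (hit$strand == "+") hit$start + j else hit$end - j + 1L
    cur <- substr(mutant, pos, pos)
    cur_m <- if (hit$strand == "+") cur else chartr("ACGT", "TGCA", cur)
    alt_m <- worst_base(x, j, cur_m)
    list(pos = pos,
         alt = if (hit$strand == "+") alt_m else chartr("ACGT", "TGCA", alt_m))
  }
}

#' Design disruptive mutations for PWM binding sites
#'
#' Greedy mutagenesis loop: for every target site, the
#' highest-information-content PWM column is substituted with the base of
#' lowest log-odds (ties alphabetical; for minus-strand hits the edit is
#' the complement at the corresponding forward position). The full mutant
#' is then rescanned with every PWM on both strands; residual or de-novo
#' hits are repaired the same way until a rescan is clean or
#' \code{max_rounds} is exhausted (then an error lists the surviving
#' hits).
#'
#' @param sequence original sequence.
#' @param pwms list of [pwm] objects (all are rescanned each round).
#' @param target_sites optional hit data.frame to disrupt; defaults to a
#'   fresh scan of \code{sequence} with all \code{pwms}.
#' @param p_threshold p-value cutoff defining a binding site.
#' @param max_rounds maximum design/verify rounds.
#' @return object of class \code{mutagenesis_plan}: \code{original},
#'   \code{mutant}, \code{edits} (offset, ref, alt; 0-based),
#'   \code{rounds}, \code{report} (see [verify_mutagenesis]) and
#'   \code{accepted} (TRUE iff the final rescan is clean).
#' @export
design_mutations <- function(sequence, pwms, target_sites = NULL,
                             p_threshold = 0.01, max_rounds = 10L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  ids <- vapply(pwms, function(p) p$id, character(1))
  if (is.null(names(pwms))) names(pwms) <- ids
  hits <- target_sites %||% scan_pwms(sequence, pwms, p_threshold)
  original <- sequence
  mutant <- sequence
  rounds <- 0L
  while (nrow(hits) > 0L) {
    if (rounds >= max_rounds) {
      stop("mutagenesis did not converge after ", max_rounds,
           " rounds; surviving hits: ",
           paste(sprintf("%s@%d(%s)", hits$motif, hits$start, hits$strand),
                 collapse = ", "))
    }
    rounds <- rounds + 1L
    maxw <- max(vapply(pwms, function(p) p$width, integer(1)))
    for (i in seq_len(nrow(hits))) {
      x <- pwms[[match(hits$motif[i], ids)]]
      # an earlier edit this round may already have killed this site
      win <- substr(mutant, hits$start[i] + 1L, hits$end[i])
      frame <- if (hits$strand[i] == "-") revcomp(win) else win
      code <- encode_dna(frame)
      if (anyNA(code)) next
      sc <- sum(x$int_scores[cbind(code, seq_len(x$width))])
      if (score_to_pvalue(x, sc * x$grid) >= p_threshold) next
      ed <- choose_edit(mutant, hits[i, ], x, pwms, p_threshold, maxw)
      substr(mutant, ed$pos, ed$pos) <- ed$alt
    }
    hits <- scan_pwms(mutant, pwms, p_threshold)
  }
  report <- verify_mutagenesis(mutant, pwms, p_threshold,
                               original_hits = target_sites)
  ov <- strsplit(original, "", fixed = TRUE)[[1]]
  mv <- strsplit(mutant, "", fixed = TRUE)[[1]]
  ed <- which(ov != mv)
  edits <- data.frame(offset = ed - 1L, ref = ov[ed], alt = mv[ed],
                      stringsAsFactors = FALSE)
  structure(list(original = original, mutant = mutant, edits = edits,
                 rounds = rounds, report = report,
                 accepted = report$clean),
            class = "mutagenesis_plan")
}

#' @export
print.mutagenesis_plan <- function(x, ...) {
  cat("mutagenesis_plan:", nrow(x$edits), "edit(s) in", x$rounds,
      "round(s);", if (x$accepted) "verified clean" else "NOT clean", "\n")
  invisible(x)
}

#' Verify a mutated sequence against all motifs
#'
#' Full both-strand rescan of the mutant with every PWM. The report is
#' \emph{clean} iff no hit remains; when the original hit set is
#' supplied, surviving hits are split into residual (overlapping an
#' original site) and de-novo.
#'
#' @param mutant mutated sequence.
#' @param pwms list of [pwm] objects.
#' @param p_threshold p-value cutoff.
#' @param original_hits optional original hit table for the
#'   residual/de-novo split.
#' @return object of class \code{verification_report}: \code{clean},
#'   \code{hits}, \code{residual}, \code{de_novo}.
#' @export
verify_mutagenesis <- function(mutant, pwms, p_threshold = 0.01,
                               original_hits = NULL) {
  hits <- scan_pwms(mutant, pwms, p_threshold)
  residual <- hits[0, ]; de_novo <- hits
  if (!is.null(original_hits) && nrow(hits) > 0L) {
    is_res <- vapply(seq_len(nrow(hits)), function(i)
      any(interval_overlap(hits$start[i], hits$end[i],
                           original_hits$start, original_hits$end) >= 1),
      logical(1))
    residual <- hits[is_res, ]; de_novo <- hits[!is_res, ]
  }
  structure(list(clean = nrow(hits) == 0L, hits = hits,
                 residual = residual, de_novo = de_novo),
            class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  if (x$clean) cat("verification_report: clean (no residual or de-novo sites)\n")
  else cat("verification_report: NOT clean -", nrow(x$residual), "residual,",
           nrow(x$de_novo), "de-novo site(s)\n")
  invisible(x)
}
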