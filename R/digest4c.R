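# 4C-seq computation: in-silico double digestion, valid-fragment filtering,
# primer filtering, exact-match read assignment, exclusion zones, sliding
# window RPM normalisation, genotype subtraction, and the ATAC-style binned
# RPKM track.

#' In-silico double restriction digestion
#'
#' Cuts every chromosome at each occurrence of the primary motif (DpnII
#' GATC by default). Because GATC and CATG are palindromic, scanning the
#' forward strand alone finds every site. A fragment is \emph{valid} -
#' retained for 4C counting - iff it contains at least one secondary-motif
#' site (NlaIII CATG) and is at least \code{min_length} bp long.
#'
#' @param genome named character vector of chromosome sequences (a single
#'   unnamed string is treated as chromosome \code{"chr1"}).
#' @param primary_motif primary (fragmenting) enzyme recognition sequence.
#' @param secondary_motif secondary enzyme site required inside a valid
#'   fragment.
#' @param min_length minimum valid fragment length in bp.
#' @return object of class \code{fragment_library}: a list with
#'   \code{fragments} (data.frame: chrom, start, end, length,
#'   has_secondary, valid, index), the source \code{genomes}, and the
#'   digestion parameters.
#' @examples
#' lib <- digest(c(chr1 = "AAGATCCATGAAGATCAA"))
#' lib$fragments[, c("start", "end", "valid")]
#' @export
digest <- function(genome, primary_motif = "GATC", secondary_motif = "CATG",
                   min_length = 20L) {
  if (is.null(names(genome)) && length(genome) == 1L) names(genome) <- "chr1"
  stopifnot(is.character(genome), all(nzchar(genome)))
  check_dna_motif(primary_motif, "primary_motif")
  check_dna_motif(secondary_motif, "secondary_motif")
  per_chrom <- lapply(names(genome), function(chrom) {
    s <- Biostrings::DNAString(genome[[chrom]])
    n <- length(s)
    cuts <- Biostrings::start(Biostrings::matchPattern(primary_motif, s)) - 1L
    bounds <- unique(c(0L, cuts, n))
    bounds <- sort(bounds[bounds < n])
    starts <- bounds
    ends <- c(bounds[-1], n)
    sec <- Biostrings::start(Biostrings::matchPattern(secondary_motif, s)) - 1L
    w <- nchar(secondary_motif)
    # a fragment contains the site iff some occurrence lies fully inside it
    has_sec <- vapply(seq_along(starts), function(k)
      any(sec >= starts[k] & sec + w <= ends[k]), logical(1))
    len <- ends - starts
    data.frame(chrom = chrom, start = starts, end = ends, length = len,
               has_secondary = has_sec,
               valid = has_sec & len >= min_length,
               index = seq_along(starts), stringsAsFactors = FALSE)
  })
  frags <- do.call(rbind, per_chrom)
  rownames(frags) <- NULL
  structure(list(fragments = frags, genomes = genome,
                 primary_motif = primary_motif,
                 secondary_motif = secondary_motif,
                 min_length = as.integer(min_length)),
            class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat("fragment_library:", nrow(x$fragments), "fragments on",
      length(x$genomes), "chromosome(s)\n")
  cat("  primary/secondary motif:", x$primary_motif, "/", x$secondary_motif,
      " min valid length:", x$min_length, "bp\n")
  cat("  valid fragments:", sum(x$fragments$valid), "\n")
  invisible(x)
}

#' Viewpoint specification for 4C analysis
#'
#' @param chrom chromosome name.
#' @param position viewpoint position (0-based bp).
#' @param primer viewpoint primer sequence (>= 10 nt).
#' @param exclusion_radius bp excluded on both sides of the viewpoint
#'   (default 10 kb, matching the standard 4C practice of masking the
#'   strong self-ligation signal around the viewpoint).
#' @param analysis_interval optional region restriction: a
#'   \code{"chrom:start-end"} string (1-based inclusive, as in genome
#'   browsers) or a list with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open). NULL profiles the whole chromosome.
#' @return object of class \code{viewpoint_spec}.
#' @export
viewpoint_spec <- function(chrom, position, primer, exclusion_radius = 10000L,
                           analysis_interval = NULL) {
  if (nchar(primer) < 10L) stop("primer must be at least 10 nt")
  check_dna_motif(primer, "primer")
  if (is.character(analysis_interval))
    analysis_interval <- parse_region(analysis_interval)
  if (!is.null(analysis_interval)) {
    if (analysis_interval$chrom != chrom)
      stop("analysis_interval chromosome differs from viewpoint chromosome")
    if (position < analysis_interval$start || position >= analysis_interval$end)
      stop("viewpoint position must lie inside the analysis interval")
  }
  structure(list(chrom = chrom, position = position, primer = primer,
                 exclusion_radius = exclusion_radius,
                 analysis_interval = analysis_interval),
            class = "viewpoint_spec")
}

#' Primer filtering of raw 4C reads
#'
#' A read is kept iff its prefix matches the viewpoint primer with at most
#' \code{max_mismatch} mismatches; the primer is trimmed from kept reads.
#' Reads shorter than the primer are discarded and counted separately.
#'
#' @param reads character vector of read sequences.
#' @param primer primer sequence.
#' @param max_mismatch maximum allowed prefix mismatches (default 0).
#' @return list with \code{kept} (trimmed reads), \code{n_discarded}
#'   (primer mismatch) and \code{n_short} (shorter than the primer).
#' @export
filter_primer_reads <- function(reads, primer, max_mismatch = 0L) {
  if (!nzchar(primer)) stop("primer must be non-empty")
  np <- nchar(primer)
  short <- nchar(reads) < np
  cand <- reads[!short]
  if (max_mismatch == 0L) {
    ok <- startsWith(cand, primer)
  } else {
    pv <- strsplit(primer, "", fixed = TRUE)[[1]]
    ok <- vapply(substr(cand, 1L, np), function(s) {
      sum(strsplit(s, "", fixed = TRUE)[[1]] != pv) <= max_mismatch
    }, logical(1), USE.NAMES = FALSE)
  }
  list(kept = substring(cand[ok], np + 1L),
       n_discarded = sum(!ok), n_short = sum(short))
}

#' Assign primer-trimmed reads to valid restriction fragments
#'
#' Each read is located in the genome by exact matching. A read is
#' assigned to the valid fragment one of whose primary-enzyme boundaries
#' coincides with the read's match: forward-strand matches must start at a
#' fragment start boundary, reverse-strand matches must end at a fragment
#' end boundary (both ends of a fragment are eligible because 4C reads run
#' from a ligated DpnII site into the captured fragment). Reads matching
#' nowhere, not at a boundary, or only on invalid fragments are tallied as
#' unassigned; reads matching more than one valid boundary are counted as
#' ambiguous and excluded.
#'
#' @param reads primer-trimmed reads.
#' @param library a [fragment_library].
#' @return list with \code{counts} (integer per row of
#'   \code{library$fragments}), \code{n_unassigned}, \code{n_ambiguous}.
#' @export
assign_reads <- function(reads, library) {
  stopifnot(inherits(library, "fragment_library"))
  frags <- library$fragments
  counts <- integer(nrow(frags))
  n_unassigned <- 0L; n_ambiguous <- 0L
  tab <- table(reads)
  useqs <- names(tab)
  subjects <- lapply(library$genomes, Biostrings::DNAString)
  # boundary lookup keyed by chrom: start -> row, end -> row (valid only)
  vrows <- which(frags$valid)
  key_start <- paste0(frags$chrom[vrows], ":", frags$start[vrows])
  key_end <- paste0(frags$chrom[vrows], ":", frags$end[vrows])
  for (u in seq_along(useqs)) {
    rd <- useqs[u]
    n <- as.integer(tab[[u]])
    if (!nzchar(rd)) { n_unassigned <- n_unassigned + n; next }
    hits <- integer(0)
    matched_any <- FALSE
    for (chrom in names(subjects)) {
      fwd <- Biostrings::matchPattern(rd, subjects[[chrom]])
      if (length(fwd)) {
        matched_any <- TRUE
        k <- match(paste0(chrom, ":", Biostrings::start(fwd) - 1L), key_start)
        hits <- c(hits, vrows[k[!is.na(k)]])
      }
      rev <- Biostrings::matchPattern(revcomp(rd), subjects[[chrom]])
      if (length(rev)) {
        matched_any <- TRUE
        k <- match(paste0(chrom, ":", Biostrings::end(rev)), key_end)
        hits <- c(hits, vrows[k[!is.na(k)]])
      }
    }
    hits <- unique(hits)
    if (length(hits) == 1L) {
      counts[hits] <- counts[hits] + n
    } else if (length(hits) > 1L) {
      n_ambiguous <- n_ambiguous + n
    } else {
      n_unassigned <- n_unassigned + n
    }
  }
  list(counts = counts, n_unassigned = n_unassigned, n_ambiguous = n_ambiguous)
}

#' Informative-fragment mask for a viewpoint
#'
#' Marks the fragments that enter RPM normalisation: valid fragments
#' overlapping the analysis interval, excluding the viewpoint fragment,
#' its two immediately adjacent fragments (undigested neighbours), and any
#' fragment overlapping \code{viewpoint +/- exclusion_radius}.
#'
#' @param library a [fragment_library].
#' @param viewpoint a [viewpoint_spec].
#' @return logical vector over the rows of \code{library$fragments}.
#' @export
informative_mask <- function(library, viewpoint) {
  stopifnot(inherits(library, "fragment_library"),
            inherits(viewpoint, "viewpoint_spec"))
  frags <- library$fragments
  on_chrom <- frags$chrom == viewpoint$chrom
  if (!any(on_chrom & frags$start <= viewpoint$position &
             frags$end > viewpoint$position))
    stop("viewpoint position not covered by the fragment library")
  mask <- frags$valid & on_chrom
  ai <- viewpoint$analysis_interval
  if (!is.null(ai))
    mask <- mask & interval_overlap(frags$start, frags$end, ai$start, ai$end) > 0
  vp_row <- which(on_chrom & frags$start <= viewpoint$position &
                    frags$end > viewpoint$position)[1]
  vp_idx <- frags$index[vp_row]
  mask[on_chrom & abs(frags$index - vp_idx) <= 1L] <- FALSE
  if (viewpoint$exclusion_radius > 0) {
    lo <- viewpoint$position - viewpoint$exclusion_radius
    hi <- viewpoint$position + viewpoint$exclusion_radius
    mask[on_chrom & interval_overlap(frags$start, frags$end, lo, hi) > 0] <- FALSE
  }
  if (!any(mask))
    stop("no informative fragments remain after exclusion")
  mask
}

#' Build a 4C viewpoint profile
#'
#' Combines per-fragment raw counts with the informative mask and the
#' sliding-window RPM normalisation (see [smooth_rpm]).
#'
#' @param library a [fragment_library].
#' @param viewpoint a [viewpoint_spec].
#' @param counts integer vector of raw counts per fragment row (e.g. from
#'   [assign_reads]).
#' @param window_width odd number of informative fragments per smoothing
#'   window (default 5).
#' @return object of class \code{viewpoint_profile} with fields
#'   \code{counts}, \code{mask}, \code{rpm} (NA off-mask),
#'   \code{total_mapped}, \code{window_width}.
#' @export
viewpoint_profile <- function(library, viewpoint, counts, window_width = 5L) {
  stopifnot(inherits(library, "fragment_library"),
            length(counts) == nrow(library$fragments))
  mask <- informative_mask(library, viewpoint)
  prof <- structure(list(library = library, viewpoint = viewpoint,
                         counts = as.numeric(counts), mask = mask,
                         total_mapped = sum(counts[mask]),
                         window_width = as.integer(window_width),
                         rpm = rep(NA_real_, length(counts))),
                    class = "viewpoint_profile")
  smooth_rpm(prof, window_width)
}

#' Sliding-window RPM smoothing of a 4C profile
#'
#' The value at informative fragment i is the mean raw count over a
#' window of \code{window_width} informative fragments centred on i
#' (the window shrinks symmetrically at the profile edges), scaled to
#' reads per million: \code{1e6 / total_mapped}, where
#' \code{total_mapped} is the raw-count sum over informative fragments.
#'
#' @param profile a [viewpoint_profile].
#' @param window_width odd window width in informative fragments.
#' @return the profile with its \code{rpm} field recomputed.
#' @export
smooth_rpm <- function(profile, window_width = profile$window_width) {
  stopifnot(inherits(profile, "viewpoint_profile"))
  w <- as.integer(window_width)
  if (w < 1L || w %% 2L == 0L) stop("window_width must be odd and >= 1")
  idx <- which(profile$mask)
  cnt <- profile$counts[idx]
  total <- sum(cnt)
  if (total == 0) stop("total mapped count over informative fragments is zero")
  m <- length(idx)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, cnt))
  i <- seq_len(m)
  h <- pmin(half, i - 1L, m - i)  # symmetric shrink at the edges
  sm <- (cs[i + h + 1L] - cs[i - h]) / (2L * h + 1L)
  rpm <- rep(NA_real_, length(profile$counts))
  rpm[idx] <- sm * 1e6 / total
  profile$rpm <- rpm
  profile$total_mapped <- total
  profile$window_width <- w
  profile
}

#' @export
print.viewpoint_profile <- function(x, ...) {
  cat("viewpoint_profile:", sum(x$mask), "informative fragments,",
      x$total_mapped, "mapped reads, window", x$window_width, "\n")
  invisible(x)
}

#' Subtract one normalised 4C profile from another
#'
#' Computes RPM(a) - RPM(b) per informative fragment (positive = gain in
#' a). Both profiles must come from the same fragment library, viewpoint
#' mask and window; subtraction operates on normalised values so that
#' libraries of different depth are comparable.
#'
#' @param a,b [viewpoint_profile] objects sharing a library and mask.
#' @return numeric vector over fragment rows (NA off-mask).
#' @export
subtract_profiles <- function(a, b) {
  stopifnot(inherits(a, "viewpoint_profile"), inherits(b, "viewpoint_profile"))
  if (!identical(a$library$fragments, b$library$fragments))
    stop("profiles use different fragment libraries")
  if (!identical(a$mask, b$mask))
    stop("profiles use different informative masks")
  a$rpm - b$rpm
}

#' Export a profile or subtraction as a bedGraph data.frame
#'
#' One record per informative fragment, 0-based half-open.
#'
#' @param profile a [viewpoint_profile].
#' @param values optional numeric vector over fragment rows (defaults to
#'   the profile's smoothed RPM; pass a [subtract_profiles] result for a
#'   subtraction track).
#' @return data.frame with chrom, start, end, value.
#' @export
profile_bedgraph <- function(profile, values = profile$rpm) {
  frags <- profile$library$fragments
  keep <- profile$mask & !is.na(values)
  data.frame(chrom = frags$chrom[keep], start = frags$start[keep],
             end = frags$end[keep], value = values[keep],
             stringsAsFactors = FALSE)
}

#' ATAC-style binned RPKM track
#'
#' Counts both 5'-ends of each fragment into fixed-width bins; the
#' per-bin value is \code{count / (library_size * bin_size) * 1e9}
#' (reads per kilobase per million), where \code{library_size} is the sum
#' of all bin counts.
#'
#' @param fragments data.frame with \code{start}, \code{end} (0-based
#'   half-open) and optionally \code{chrom}; alternatively a numeric
#'   vector of pre-extracted 5'-end positions.
#' @param bin_size bin width in bp (default 10).
#' @return object of class \code{binned_track}: data.frame \code{bins}
#'   (start, end, count, rpkm) plus \code{bin_size}, \code{library_size}.
#' @export
atac_rpkm <- function(fragments, bin_size = 10L) {
  if (bin_size < 1L) stop("bin_size must be >= 1")
  if (is.data.frame(fragments)) {
    if (nrow(fragments) == 0L) stop("no input fragments")
    # plus-strand 5' end = start, minus-strand 5' end = last base (end - 1)
    ends <- c(fragments$start, fragments$end - 1L)
  } else {
    if (length(fragments) == 0L) stop("no input end positions")
    ends <- as.numeric(fragments)
  }
  bin <- floor(ends / bin_size)
  rng <- range(bin)
  all_bins <- seq(rng[1], rng[2])
  count <- tabulate(bin - rng[1] + 1L, nbins = length(all_bins))
  library_size <- sum(count)
  rpkm <- count / (library_size * bin_size) * 1e9
  structure(list(bins = data.frame(start = all_bins * bin_size,
                                   end = (all_bins + 1) * bin_size,
                                   count = count, rpkm = rpkm),
                 bin_size = as.integer(bin_size),
                 library_size = library_size),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat("binned_track:", nrow(x$bins), "bins of", x$bin_size, "bp,",
      x$library_size, "fragment ends\n")
  invisible(x)
}
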