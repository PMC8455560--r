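# Shared low-level helpers: sequence handling, seed splitting, coordinates.

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T, case preserved as
#'   upper case).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    comp <- chartr("ACGTacgt", "TGCAtgca", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Encode a DNA string as integers 1..4 (A,C,G,T); other characters -> NA.
encode_dna <- function(s) {
  match(strsplit(toupper(s), "", fixed = TRUE)[[1]], DNA_BASES)
}

check_dna_motif <- function(motif, what = "motif") {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) < 1L)
    stop(what, " must be a single non-empty string")
  if (grepl("[^ACGT]", motif))
    stop(what, " contains ambiguous (non-ACGT) characters: ", motif)
  invisible(motif)
}

#' Derive a stream-specific seed from a global seed
#'
#' All generators in the package split one global integer seed into
#' independent per-stream seeds so stages can be re-run in isolation while
#' remaining bit-reproducible end to end.
#'
#' @param seed global integer seed.
#' @param stream small integer identifying the consumer stream.
#' @return an integer seed below 2^31.
#' @export
split_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(stream) * 10007 + 17) %%
               2147483647)
}

#' Parse a UCSC-style region string to 0-based half-open coordinates
#'
#' Region strings such as \code{"chr2:113326224-113894862"} follow the
#' 1-based inclusive browser convention; internally all coordinates are
#' 0-based half-open, so the parsed interval is
#' \code{[start - 1, end)} and its width is \code{end - start + 1}.
#' An en dash is accepted in place of the hyphen.
#'
#' @param region a single region string \code{"chrom:start-end"}.
#' @return list with \code{chrom}, \code{start} (0-based), \code{end}
#'   (exclusive).
#' @examples
#' r <- parse_region("chr2:113326224-113894862")
#' r$end - r$start  # 568639 bp
#' @export
parse_region <- function(region) {
  stopifnot(is.character(region), length(region) == 1L)
  region <- gsub("–", "-", region)
  region <- gsub(",", "", region)
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L)
    stop("cannot parse region string: ", region)
  start1 <- as.numeric(m[3]); end1 <- as.numeric(m[4])
  if (end1 < start1) stop("region end before start: ", region)
  list(chrom = m[2], start = start1 - 1, end = end1)
}

# 0-based half-open interval overlap in bp (0 if disjoint).
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}
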