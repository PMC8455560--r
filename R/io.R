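# File format support: FASTA/FASTQ via Biostrings, BED/bedGraph/JASPAR/Cq
# tables as plain tab-delimited text. All genomic records written by this
# package are 0-based half-open.

#' Read a FASTA file into a named character vector
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences as FASTA
#'
#' Sequences are wrapped at 60 characters per line so that
#' \code{write_fasta(read_fasta(f), f2)} is byte-identical for canonical
#' inputs.
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    starts <- seq(1L, n, by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, n)), con)
  }
  invisible(path)
}

#' Read a FASTQ file (sequences only)
#'
#' @param path path to an uncompressed FASTQ file.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Write reads as FASTQ with constant quality
#'
#' @param reads character vector of read sequences; names become read ids
#'   (defaults to \code{read1..readN}).
#' @param path output path.
#' @param quality_char single quality character applied to every base.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  if (is.null(names(reads))) ids <- paste0("read", seq_along(reads))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(reads)) {
    writeLines(c(paste0("@", ids[i]), reads[[i]], "+",
                 strrep(quality_char, nchar(reads[[i]]))), con)
  }
  invisible(path)
}

#' Read a BED file (3-6 columns, 0-based half-open)
#'
#' @param path path to a tab-delimited BED file without header.
#' @return data.frame with columns chrom, start, end and, when present,
#'   name, score, strand.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) stop("no records in BED file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- length(fields[[1]])
  if (ncol < 3L) stop("BED line 1 has fewer than 3 fields")
  cols <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(ncol, 6L))]
  df <- as.data.frame(do.call(rbind, lapply(fields, function(f) f[seq_along(cols)])),
                      stringsAsFactors = FALSE)
  names(df) <- cols
  df$start <- suppressWarnings(as.numeric(df$start))
  df$end <- suppressWarnings(as.numeric(df$end))
  bad <- which(is.na(df$start) | is.na(df$end) | df$start >= df$end)
  if (length(bad))
    stop("malformed BED record (start >= end or non-numeric) at line ",
         bad[1], " of ", path)
  if ("score" %in% names(df)) df$score <- suppressWarnings(as.numeric(df$score))
  if ("strand" %in% names(df) && any(!df$strand %in% c("+", "-", ".")))
    stop("invalid strand in BED file: ", path)
  df
}

#' Write a BED file
#'
#' @param df data.frame with columns chrom, start, end and optionally
#'   name, score, strand.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (any(df$start >= df$end)) stop("BED record with start >= end")
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(df))
  out <- df[, cols, drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a 4-column bedGraph track
#'
#' @param df data.frame with columns chrom, start, end, value.
#' @param path output path.
#' @param track_name optional track line name; omitted when NULL.
#' @export
write_bedgraph <- function(df, path, track_name = NULL) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(df)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track_name))
    writeLines(sprintf("track type=bedGraph name=\"%s\"", track_name), con)
  writeLines(sprintf("%s\t%d\t%d\t%g", df$chrom, as.integer(df$start),
                     as.integer(df$end), df$value), con)
  invisible(path)
}

#' Read a JASPAR-format count matrix
#'
#' Parses the standard JASPAR text layout: a \code{>ID name} header line
#' followed by four rows \code{A [ 1 2 ... ]}, \code{C [...]}, \code{G},
#' \code{T}. Bracket-less whitespace-separated rows are accepted too.
#'
#' @param path path to the matrix file.
#' @inheritParams pwm
#' @return a [pwm] object.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.1) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (length(hdr) != 1L || hdr != 1L)
    stop("expected exactly one '>' header as the first line of ", path)
  id <- sub("^>\\s*", "", lines[1])
  id <- strsplit(id, "\\s+")[[1]][1]
  rows <- lines[-1]
  if (length(rows) != 4L)
    stop("expected 4 matrix rows (A/C/G/T) in ", path, ", found ", length(rows))
  parse_row <- function(r, i) {
    base <- sub("^([ACGT]).*", "\\1", r)
    if (!base %in% DNA_BASES) {
      base <- DNA_BASES[i]  # rows without a base label, positional order
      nums <- r
    } else {
      nums <- sub("^[ACGT]", "", r)
    }
    nums <- gsub("\\[|\\]", " ", nums)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
    if (any(is.na(vals))) stop("non-numeric count in matrix row: ", r)
    list(base = base, vals = vals)
  }
  parsed <- lapply(seq_along(rows), function(i) parse_row(rows[i], i))
  lens <- vapply(parsed, function(p) length(p$vals), integer(1))
  if (length(unique(lens)) != 1L) stop("matrix rows have unequal lengths in ", path)
  counts <- do.call(rbind, lapply(parsed, `[[`, "vals"))
  rownames(counts) <- vapply(parsed, `[[`, character(1), "base")
  counts <- counts[DNA_BASES, , drop = FALSE]
  pwm(counts, background = background, pseudocount = pseudocount, id = id)
}

#' Write a pwm object in JASPAR text format
#' @param x a [pwm] object.
#' @param path output path.
#' @export
write_jaspar <- function(x, path) {
  stopifnot(inherits(x, "pwm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", x$id), con)
  for (b in DNA_BASES)
    writeLines(sprintf("%s [ %s ]", b,
                       paste(format(x$counts[b, ], trim = TRUE), collapse = " ")), con)
  invisible(path)
}

#' Read an aligned FASTA file (MSA)
#'
#' @param path path to an aligned FASTA file; all records must have equal
#'   aligned length. Gaps are '-'.
#' @return named character vector of aligned sequences.
#' @export
read_aligned_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  seqs <- setNames(toupper(as.character(x)), names(x))
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned FASTA records have unequal lengths: ", path)
  seqs
}

#' Read a tab-delimited Cq table
#'
#' Expected header: \code{sample  group  gene  Cq} (a \code{replicate}
#' column is optional).
#'
#' @param path path to the table.
#' @return data.frame of Cq records.
#' @export
read_cq_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample", "group", "gene", "Cq")
  if (!all(need %in% names(df)))
    stop("Cq table must have columns ", paste(need, collapse = ", "))
  if (any(!is.finite(df$Cq)) || any(df$Cq <= 0))
    stop("Cq values must be finite and positive")
  df
}

#' Write a Cq table as tab-delimited text
#' @param df Cq data.frame (columns sample, group, gene, Cq, ...).
#' @param path output path.
#' @export
write_cq_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
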