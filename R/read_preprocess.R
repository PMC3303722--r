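#' Trim a 3' sequencing adapter from a read
#'
#' Looks for the adapter (or an adapter prefix of at least
#' \code{min_overlap} nt reaching the read's 3' end) and returns the insert
#' preceding its leftmost occurrence. A read with no adapter evidence
#' returns \code{NULL}: only reads in which the adapter was actually seen
#' and removed count as clean, so adapterless reads are discarded upstream.
#'
#' @param read Read sequence (character scalar).
#' @param adapter Adapter sequence; matching is exact, no mismatches.
#' @param min_overlap Minimum adapter prefix length that counts as evidence
#'   when the adapter runs off the read's 3' end (default 6).
#' @return The insert sequence, possibly empty, or \code{NULL}.
#' @export
trim_adapter <- function(read, adapter, min_overlap = 6L) {
  stopifnot(nzchar(adapter), min_overlap >= 1L)
  # full internal adapter occurrence
  hit <- regexpr(adapter, read, fixed = TRUE)
  if (hit > 0L) {
    return(substr(read, 1L, as.integer(hit) - 1L))
  }
  # adapter prefix anchored at the read's 3' end
  n <- nchar(read)
  max_ov <- min(nchar(adapter) - 1L, n)
  ov <- max_ov
  while (ov >= min_overlap) {
    if (substr(read, n - ov + 1L, n) == substr(adapter, 1L, ov)) {
      return(substr(read, 1L, n - ov))
    }
    ov <- ov - 1L
  }
  NULL
}

#' Collapse clean reads to unique reads and apply length/count filters
#'
#' Reads are filtered to the mature-miRNA length envelope (18-25 nt by
#' default), grouped into unique sequences with tabulated counts, and unique
#' reads seen fewer than \code{min_count} times are dropped. Filtering order
#' is length first, then count, so counts are tallied over length-passed
#' reads only.
#'
#' @param clean_reads Character vector of adapter-trimmed reads, or a
#'   two-column data.frame (sequence, count) of pre-collapsed reads.
#' @param name Library name.
#' @param min_len,max_len Inclusive length bounds (nt).
#' @param min_count Minimum count of a unique read.
#' @param total_raw Optional raw read number before adapter trimming, kept
#'   in the totals for bookkeeping.
#' @return A list of class \code{smallrna_library}: \code{name},
#'   \code{reads} (data.frame sequence/count, count-descending),
#'   \code{total_raw}, \code{total_clean}, \code{total_used}.
#' @export
collapse_and_filter <- function(clean_reads, name = "lib",
                                min_len = 18L, max_len = 25L,
                                min_count = 2L, total_raw = NA_integer_) {
  if (is.data.frame(clean_reads)) {
    df <- data.frame(sequence = as.character(clean_reads[[1L]]),
                     count = as.integer(clean_reads[[2L]]),
                     stringsAsFactors = FALSE)
    # re-collapse in case sequences repeat
    agg <- tapply(df$count, df$sequence, sum)
    df <- data.frame(sequence = names(agg), count = as.integer(agg),
                     stringsAsFactors = FALSE)
  } else {
    if (length(clean_reads) == 0L) {
      warning("empty read input for library '", name, "'")
      df <- data.frame(sequence = character(0), count = integer(0))
    } else {
      tab <- table(clean_reads)
      df <- data.frame(sequence = names(tab), count = as.integer(tab),
                       stringsAsFactors = FALSE)
    }
  }
  total_clean <- sum(df$count)
  len <- nchar(df$sequence)
  df <- df[len >= min_len & len <= max_len, , drop = FALSE]
  df <- df[df$count >= min_count, , drop = FALSE]
  df <- df[order(-df$count, df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(name = name, reads = df,
                 total_raw = if (is.na(total_raw)) total_clean else as.integer(total_raw),
                 total_clean = total_clean,
                 total_used = sum(df$count)),
            class = "smallrna_library")
}

#' @export
print.smallrna_library <- function(x, ...) {
  cat("small-RNA library '", x$name, "': ", nrow(x$reads),
      " unique reads, ", x$total_used, " reads used (",
      x$total_clean, " clean, ", x$total_raw, " raw)\n", sep = "")
  invisible(x)
}

#' Read a small-RNA library from FASTA, FASTQ or collapsed TSV
#'
#' FASTA/FASTQ inputs are treated as raw clean reads (quality scores
#' ignored) and collapsed; a two-column TSV (sequence, count; header
#' optional) is taken as pre-collapsed and bypasses adapter handling.
#' Sequences are normalized to the RNA alphabet.
#'
#' @inheritParams collapse_and_filter
#' @param path Input file.
#' @param adapter Optional 3' adapter to trim from FASTA/FASTQ reads; reads
#'   without adapter evidence are discarded as non-clean.
#' @param min_overlap Passed to [trim_adapter()].
#' @return A \code{smallrna_library} (see [collapse_and_filter()]).
#' @export
read_library <- function(path, name = basename(path), adapter = NULL,
                         min_overlap = 6L, min_len = 18L, max_len = 25L,
                         min_count = 2L) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">") || startsWith(first, "@")) {
    fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
    set <- Biostrings::readBStringSet(path, format = fmt)
    reads <- as.character(set)
    total_raw <- length(reads)
    if (!is.null(adapter)) {
      reads <- lapply(reads, trim_adapter, adapter = adapter,
                      min_overlap = min_overlap)
      reads <- unlist(reads[!vapply(reads, is.null, logical(1))])
      if (is.null(reads)) reads <- character(0)
    }
    reads <- reads[nzchar(reads)]
    if (length(reads) > 0) reads <- normalize_rna(reads)
    collapse_and_filter(reads, name = name, min_len = min_len,
                        max_len = max_len, min_count = min_count,
                        total_raw = total_raw)
  } else {
    df <- utils::read.delim(path, header = is_tsv_header(first),
                            stringsAsFactors = FALSE)
    df[[1L]] <- normalize_rna(as.character(df[[1L]]))
    collapse_and_filter(df[, 1:2], name = name, min_len = min_len,
                        max_len = max_len, min_count = min_count)
  }
}

is_tsv_header <- function(first_line) {
  fields <- strsplit(first_line, "\t", fixed = TRUE)[[1L]]
  length(fields) >= 2L && is.na(suppressWarnings(as.numeric(fields[2L])))
}

#' Write a collapsed library to TSV (sequence, count)
#' @param lib A \code{smallrna_library}.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_library_tsv <- function(lib, path) {
  utils::write.table(lib$reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
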