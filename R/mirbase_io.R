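#' Read pre-miRNA hairpin sequences from FASTA
#'
#' Reads a miRBase-dialect hairpin FASTA (the first whitespace-delimited
#' header token is the record ID, e.g. \code{hsa-mir-423}). Sequences may be
#' in DNA or RNA alphabet and any case; they are upper-cased and T is
#' normalized to U so the canonical internal alphabet is RNA.
#'
#' @param path Path to a FASTA file of hairpin (pre-miRNA) sequences.
#' @return A data.frame with columns \code{id}, \code{sequence} (RNA,
#'   uppercase) and \code{length} (nt), one row per record.
#' @export
read_hairpins <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("no FASTA records found in '", path, "'")
  }
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate hairpin ID(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- normalize_rna(as.character(set), ids)
  data.frame(id = ids, sequence = seqs, length = nchar(seqs),
             stringsAsFactors = FALSE)
}

# Upper-case, T->U, validate alphabet. `ids` only labels error messages.
normalize_rna <- function(seqs, ids = seq_along(seqs)) {
  seqs <- chartr("t", "u", toupper(seqs))
  seqs <- chartr("T", "U", seqs)
  bad <- regexpr("[^ACGU]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("non-nucleotide character in record '", ids[i],
         "' at position ", bad[i])
  }
  if (any(!nzchar(seqs))) {
    i <- which(!nzchar(seqs))[1L]
    stop("empty sequence in record '", ids[i], "'")
  }
  seqs
}

#' Assign a mature span to the 5p or 3p arm of its hairpin
#'
#' A mature miRNA whose span midpoint lies strictly upstream of the hairpin
#' midpoint sits on the 5p arm, otherwise on the 3p arm. The hairpin midpoint
#' is (length + 1) / 2, so on odd-length hairpins a span centered exactly on
#' the middle base is called 3p; such exact ties are rare and flagged with a
#' warning because the call is conventional, not biological.
#'
#' @param start,end 1-based inclusive mature coordinates on the hairpin.
#' @param hairpin_length Hairpin length in nt.
#' @param warn_tie Warn when the midpoints coincide exactly.
#' @return "5p" or "3p".
#' @export
assign_arm <- function(start, end, hairpin_length, warn_tie = TRUE) {
  mid_mature <- (start + end) / 2
  mid_hairpin <- (hairpin_length + 1) / 2
  if (warn_tie && any(mid_mature == mid_hairpin)) {
    warning("mature span centered exactly on the hairpin midpoint; ",
            "arm call '3p' is conventional")
  }
  ifelse(mid_mature < mid_hairpin, "5p", "3p")
}

#' Locate mature miRNAs within their hairpins
#'
#' Mature sequences supplied as FASTA are located by exact substring search
#' in the hairpin whose ID is a prefix of the mature ID (miRBase convention:
#' mature \code{hsa-miR-423-5p} belongs to hairpin \code{hsa-mir-423}, with
#' the miR/mir case difference ignored). A TSV with explicit coordinates
#' bypasses the search and is authoritative.
#'
#' @param hairpins data.frame from [read_hairpins()].
#' @param matures Either a path to a mature FASTA / annotation TSV, or a
#'   data.frame already holding annotation columns.
#' @return Annotation data.frame with columns \code{premirna_id},
#'   \code{mature_id}, \code{start}, \code{end} (1-based inclusive),
#'   \code{arm} ("5p"/"3p") and \code{source}.
#' @export
locate_matures <- function(hairpins, matures) {
  if (is.data.frame(matures)) {
    return(validate_annotations(matures, hairpins))
  }
  if (is_fasta_file(matures)) {
    set <- Biostrings::readBStringSet(matures)
    if (length(set) == 0L) stop("no mature records found in '", matures, "'")
    ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1L)
    seqs <- normalize_rna(as.character(set), ids)
    ann <- do.call(rbind, lapply(seq_along(ids), function(i) {
      locate_one_mature(ids[i], seqs[i], hairpins)
    }))
    rownames(ann) <- NULL
    return(validate_annotations(ann, hairpins))
  }
  validate_annotations(read_annotation_tsv(matures), hairpins)
}

locate_one_mature <- function(mature_id, mature_seq, hairpins) {
  # miRBase mature IDs extend the hairpin ID; match the longest hairpin-ID
  # prefix, case-insensitively (miR vs mir).
  lid <- tolower(mature_id)
  cand <- hairpins[startsWith(lid, tolower(hairpins$id)), , drop = FALSE]
  if (nrow(cand) == 0L) {
    stop("no hairpin whose ID prefixes mature '", mature_id, "'")
  }
  cand <- cand[which.max(nchar(cand$id)), , drop = FALSE]
  hits <- find_occurrences(mature_seq, cand$sequence)
  if (length(hits) == 0L) {
    stop("mature '", mature_id, "' not found in hairpin '", cand$id, "'")
  }
  if (length(hits) > 1L) {
    stop("mature '", mature_id, "' occurs ", length(hits),
         " times in hairpin '", cand$id,
         "'; supply an annotation TSV to disambiguate")
  }
  start <- hits[1L]
  end <- start + nchar(mature_seq) - 1L
  if (nchar(mature_seq) == cand$length) {
    stop("mature '", mature_id, "' spans the whole hairpin '", cand$id,
         "'; arm undefined")
  }
  data.frame(premirna_id = cand$id, mature_id = mature_id,
             start = start, end = end,
             arm = assign_arm(start, end, cand$length),
             source = "mirbase", stringsAsFactors = FALSE)
}

validate_annotations <- function(ann, hairpins) {
  need <- c("premirna_id", "mature_id", "start", "end", "arm", "source")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0L) {
    stop("annotation table missing column(s): ", paste(miss, collapse = ", "))
  }
  ann <- ann[, need]
  ann$start <- as.integer(ann$start)
  ann$end <- as.integer(ann$end)
  idx <- match(ann$premirna_id, hairpins$id)
  if (anyNA(idx)) {
    stop("annotation references unknown hairpin(s): ",
         paste(unique(ann$premirna_id[is.na(idx)]), collapse = ", "))
  }
  len <- hairpins$length[idx]
  bad <- ann$start < 1L | ann$start > ann$end | ann$end > len
  if (any(bad)) {
    stop("invalid mature coordinates for '", ann$mature_id[which(bad)[1L]], "'")
  }
  if (!all(ann$arm %in% c("5p", "3p"))) stop("arm must be '5p' or '3p'")
  rownames(ann) <- NULL
  ann
}

is_fasta_file <- function(path) {
  first <- readLines(path, n = 1L)
  length(first) == 1L && startsWith(first, ">")
}

#' Read / write a mature-annotation TSV
#'
#' Columns: premirna_id, mature_id, start, end, arm, source; header required.
#' Coordinates are 1-based inclusive on the hairpin.
#'
#' @param path File path.
#' @param ann Annotation data.frame (for writing).
#' @return The annotation data.frame (reader) or `path`, invisibly (writer).
#' @export
read_annotation_tsv <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  ann$start <- as.integer(ann$start)
  ann$end <- as.integer(ann$end)
  ann
}

#' @rdname read_annotation_tsv
#' @export
write_annotation_tsv <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# All start positions (1-based) of exact occurrences of `pattern` in
# `subject`; overlapping occurrences included.
find_occurrences <- function(pattern, subject) {
  hits <- integer(0)
  from <- 1L
  repeat {
    i <- regexpr(pattern, substr(subject, from, nchar(subject)), fixed = TRUE)
    if (i < 0L) break
    pos <- from + as.integer(i) - 1L
    hits <- c(hits, pos)
    from <- pos + 1L
    if (from > nchar(subject) - nchar(pattern) + 1L) break
  }
  hits
}

#' Parse a compact arm-location string
#'
#' Annotation location strings encode one or two mature spans on a hairpin,
#' e.g. \code{"5p:17-39;3p:53-75"}, \code{"3p:80-101"} for a single
#' annotated arm, or \code{"MA:14-36;mi:51-72"} where MA/mi mark the
#' annotated major and minor product. When arms are labelled MA/mi, the span
#' that starts first is the 5p arm. Returns one row per span with the arm,
#' coordinates, and whether the database calls it the major product (for
#' single-arm annotations the annotated arm is the major one).
#'
#' @param location Character vector of location strings.
#' @return data.frame with columns \code{location}, \code{arm},
#'   \code{start}, \code{end}, \code{major} (logical).
#' @export
parse_location <- function(location) {
  out <- lapply(location, function(loc) {
    parts <- strsplit(loc, ";", fixed = TRUE)[[1L]]
    m <- regmatches(parts, regexec("^(5p|3p|MA|mi):(\\d+)-(\\d+)$", parts))
    if (any(lengths(m) != 4L)) stop("cannot parse location '", loc, "'")
    lab <- vapply(m, `[`, character(1), 2L)
    start <- as.integer(vapply(m, `[`, character(1), 3L))
    end <- as.integer(vapply(m, `[`, character(1), 4L))
    if (all(lab %in% c("MA", "mi"))) {
      arm <- ifelse(rank(start) == 1L, "5p", "3p")
      major <- lab == "MA"
    } else {
      arm <- lab
      major <- rep(length(parts) == 1L, length(parts))
      if (length(parts) == 2L) {
        # two explicit 5p/3p spans carry no major call
        major <- c(NA, NA)
      }
    }
    data.frame(location = loc, arm = arm, start = start, end = end,
               major = major, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Major arm named by the annotation database, from a location string
#'
#' @param location Character vector of location strings (see
#'   [parse_location()]).
#' @return Character vector over \code{"5p"}, \code{"3p"},
#'   \code{"both-undetermined"}.
#' @export
mirbase_major_arm <- function(location) {
  vapply(location, function(loc) {
    p <- parse_location(loc)
    if (anyNA(p$major)) return("both-undetermined")
    mj <- p$arm[p$major]
    if (length(mj) == 1L) mj else "both-undetermined"
  }, character(1), USE.NAMES = FALSE)
}
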