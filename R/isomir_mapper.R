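#' Map one read onto hairpins with iterative 3'-end trimming
#'
#' The read is matched against every hairpin as an exact substring (no
#' mismatches anywhere). If the full-length read has no exact hit in any
#' hairpin, its 3'-terminal nucleotide is removed and matching retried,
#' repeating while the trimmed read stays at least \code{min_trim_len} nt
#' long; trimming stops at the first length that yields one or more hits
#' anywhere in the reference. The removed suffix is recorded as the
#' trimmed fragment — operationally these are the 3' non-templated addition
#' fragments, since a terminal base matching the template is never trimmed.
#'
#' @param read Read sequence (RNA alphabet).
#' @param hairpins Hairpin data.frame from [read_hairpins()].
#' @param min_trim_len Minimum post-trim read length (default 18).
#' @return data.frame with columns \code{premirna_id}, \code{map_start},
#'   \code{map_end} (1-based inclusive hairpin coordinates) and
#'   \code{trimmed_fragment} (possibly empty string); zero rows if the read
#'   is unmappable at every allowed length.
#' @export
map_read <- function(read, hairpins, min_trim_len = 18L) {
  n <- nchar(read)
  len <- n
  while (len >= min_trim_len) {
    core <- substr(read, 1L, len)
    hits <- lapply(seq_len(nrow(hairpins)), function(i) {
      pos <- find_occurrences(core, hairpins$sequence[i])
      if (length(pos) == 0L) return(NULL)
      data.frame(premirna_id = hairpins$id[i], map_start = pos,
                 map_end = pos + len - 1L,
                 trimmed_fragment = substr(read, len + 1L, n),
                 stringsAsFactors = FALSE)
    })
    hits <- do.call(rbind, hits)
    if (!is.null(hits) && nrow(hits) > 0L) {
      rownames(hits) <- NULL
      return(hits)
    }
    len <- len - 1L
  }
  data.frame(premirna_id = character(0), map_start = integer(0),
             map_end = integer(0), trimmed_fragment = character(0),
             stringsAsFactors = FALSE)
}

#' Map a whole collapsed library onto the hairpin reference
#'
#' Runs [map_read()] for every unique read. A read hitting k loci
#' contributes its full count to each locus by default; with
#' \code{split_multihits = TRUE} the count is divided by k (useful to keep
#' per-locus sums additive in paralog-rich references).
#'
#' @param lib A \code{smallrna_library}.
#' @param hairpins Hairpin data.frame.
#' @param min_trim_len Minimum post-trim length.
#' @param split_multihits Divide a read's count across its loci.
#' @return List with \code{mapped} (data.frame sequence, count,
#'   premirna_id, map_start, map_end, trimmed_fragment, n_loci) and
#'   \code{unmapped} (data.frame sequence, count).
#' @export
map_library <- function(lib, hairpins, min_trim_len = 18L,
                        split_multihits = FALSE) {
  reads <- lib$reads
  res <- vector("list", nrow(reads))
  unmapped <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    m <- map_read(reads$sequence[i], hairpins, min_trim_len = min_trim_len)
    if (nrow(m) == 0L) {
      unmapped[i] <- TRUE
      next
    }
    k <- nrow(m)
    m$sequence <- reads$sequence[i]
    m$count <- if (split_multihits) reads$count[i] / k else reads$count[i]
    m$n_loci <- k
    res[[i]] <- m
  }
  mapped <- do.call(rbind, res)
  if (is.null(mapped)) {
    mapped <- data.frame(premirna_id = character(0), map_start = integer(0),
                         map_end = integer(0), trimmed_fragment = character(0),
                         sequence = character(0), count = numeric(0),
                         n_loci = integer(0), stringsAsFactors = FALSE)
  }
  mapped <- mapped[, c("sequence", "count", "premirna_id", "map_start",
                       "map_end", "trimmed_fragment", "n_loci")]
  rownames(mapped) <- NULL
  list(mapped = mapped,
       unmapped = reads[unmapped, c("sequence", "count"), drop = FALSE])
}

#' Assign mapped reads to mature miRNAs as isomiRs
#'
#' A mapped read becomes an isomiR of a mature annotation on the same
#' hairpin when its start offset (map_start - mature start) is within
#' \code{max_start_offset} and its end offset (map_end - mature end) within
#' \code{max_end_offset} in absolute value; these windows exclude random
#' matches elsewhere on the hairpin. A read inside the windows of two
#' annotations goes to the one with the smaller |start offset| (ties:
#' smaller |end offset|, then the 5p arm) with a warning. Reads failing
#' every annotation's windows are returned as unassigned — candidates for
#' opposite-arm detection.
#'
#' @param mapped \code{mapped} data.frame from [map_library()].
#' @param annotations Annotation data.frame (see [locate_matures()]).
#' @param max_start_offset,max_end_offset Acceptance windows (defaults 2, 5).
#' @return List with \code{isomirs} (data.frame mature_id, premirna_id,
#'   start_offset, end_offset, count) aggregated per distinct offset pair,
#'   and \code{unassigned} (rows of \code{mapped}).
#' @export
assign_isomirs <- function(mapped, annotations,
                           max_start_offset = 2L, max_end_offset = 5L) {
  if (nrow(mapped) == 0L) {
    return(list(isomirs = empty_isomirs(), unassigned = mapped))
  }
  pick <- vector("list", nrow(mapped))
  ambiguous <- 0L
  for (i in seq_len(nrow(mapped))) {
    ann <- annotations[annotations$premirna_id == mapped$premirna_id[i], ,
                       drop = FALSE]
    if (nrow(ann) == 0L) next
    so <- mapped$map_start[i] - ann$start
    eo <- mapped$map_end[i] - ann$end
    ok <- abs(so) <= max_start_offset & abs(eo) <= max_end_offset
    if (!any(ok)) next
    if (sum(ok) > 1L) ambiguous <- ambiguous + 1L
    ann <- ann[ok, , drop = FALSE]
    so <- so[ok]; eo <- eo[ok]
    ord <- order(abs(so), abs(eo), ann$arm != "5p")
    j <- ord[1L]
    pick[[i]] <- data.frame(mature_id = ann$mature_id[j],
                            premirna_id = ann$premirna_id[j],
                            start_offset = so[j], end_offset = eo[j],
                            count = mapped$count[i],
                            stringsAsFactors = FALSE)
  }
  if (ambiguous > 0L) {
    warning(ambiguous, " read(s) satisfied the offset windows of more than ",
            "one annotation; assigned by smallest |start offset|")
  }
  assigned <- !vapply(pick, is.null, logical(1))
  iso <- do.call(rbind, pick[assigned])
  if (is.null(iso)) iso <- empty_isomirs()
  iso <- aggregate_isomirs(iso)
  list(isomirs = iso, unassigned = mapped[!assigned, , drop = FALSE])
}

empty_isomirs <- function() {
  data.frame(mature_id = character(0), premirna_id = character(0),
             start_offset = integer(0), end_offset = integer(0),
             count = numeric(0), stringsAsFactors = FALSE)
}

aggregate_isomirs <- function(iso) {
  if (nrow(iso) == 0L) return(iso)
  key <- paste(iso$mature_id, iso$start_offset, iso$end_offset, sep = "\r")
  agg <- rowsum(iso$count, key)
  first <- iso[!duplicated(key), , drop = FALSE]
  first <- first[order(match(paste(first$mature_id, first$start_offset,
                                   first$end_offset, sep = "\r"),
                             rownames(agg))), , drop = FALSE]
  out <- first
  out$count <- agg[, 1L]
  out <- out[order(out$mature_id, out$start_offset, out$end_offset), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect an additional mature miRNA on an unannotated arm
#'
#' On hairpins annotated on one arm only, unassigned mapped reads falling
#' on the opposite (unannotated) arm — by the span-midpoint rule — are
#' clustered; the most abundant read's span (ties: smaller start, then
#' smaller end) defines a detected mature annotation, provided its count
#' reaches \code{min_count}. Deeper sequencing routinely reveals such
#' opposite-arm products missing from the reference database.
#'
#' @param unassigned \code{unassigned} data.frame from [assign_isomirs()].
#' @param annotations Current annotation data.frame.
#' @param hairpins Hairpin data.frame.
#' @param min_count Minimum count of the cluster-defining read (default 2).
#' @return Annotation data.frame with \code{source = "detected"} and mature
#'   IDs of the form \code{<hairpin>-<arm>.detected}; zero rows if nothing
#'   is detectable.
#' @export
detect_opposite_arm <- function(unassigned, annotations, hairpins,
                                min_count = 2L) {
  out <- list()
  for (hid in unique(unassigned$premirna_id)) {
    ann_arms <- unique(annotations$arm[annotations$premirna_id == hid])
    if (length(ann_arms) != 1L) next    # both arms annotated, or none known
    target_arm <- setdiff(c("5p", "3p"), ann_arms)
    hlen <- hairpins$length[hairpins$id == hid]
    u <- unassigned[unassigned$premirna_id == hid, , drop = FALSE]
    arm <- assign_arm(u$map_start, u$map_end, hlen, warn_tie = FALSE)
    u <- u[arm == target_arm, , drop = FALSE]
    if (nrow(u) == 0L) next
    u <- u[order(-u$count, u$map_start, u$map_end), , drop = FALSE]
    if (u$count[1L] < min_count) next
    out[[hid]] <- data.frame(
      premirna_id = hid,
      mature_id = paste0(hid, "-", target_arm, ".detected"),
      start = u$map_start[1L], end = u$map_end[1L],
      arm = target_arm, source = "detected", stringsAsFactors = FALSE)
  }
  det <- do.call(rbind, out)
  if (is.null(det)) {
    det <- data.frame(premirna_id = character(0), mature_id = character(0),
                      start = integer(0), end = integer(0),
                      arm = character(0), source = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(det) <- NULL
  det
}

#' Cross-tabulate opposite-arm detections between two libraries
#'
#' Runs [detect_opposite_arm()] independently in each library's unassigned
#' pool, reports which hairpin arms were detected exclusively in library A,
#' exclusively in library B, or in both, and consolidates one annotation
#' per detected arm (when both libraries detect it, the span comes from the
#' library whose defining read is more abundant) for re-assignment.
#'
#' @param unassigned_a,unassigned_b Unassigned pools of the two libraries.
#' @inheritParams detect_opposite_arm
#' @return List with \code{annotations} (consolidated, source "detected"),
#'   and \code{crosstab} (premirna_id, arm, in_a, in_b, category).
#' @export
detect_opposite_arms_paired <- function(unassigned_a, unassigned_b,
                                        annotations, hairpins,
                                        min_count = 2L) {
  det_a <- detect_opposite_arm(unassigned_a, annotations, hairpins, min_count)
  det_b <- detect_opposite_arm(unassigned_b, annotations, hairpins, min_count)
  keys <- union(det_a$mature_id, det_b$mature_id)
  crosstab <- data.frame(
    premirna_id = sub("-(5p|3p)\\.detected$", "", keys),
    arm = sub("^.*-(5p|3p)\\.detected$", "\\1", keys),
    in_a = keys %in% det_a$mature_id,
    in_b = keys %in% det_b$mature_id, stringsAsFactors = FALSE)
  crosstab$category <- ifelse(crosstab$in_a & crosstab$in_b, "shared",
                              ifelse(crosstab$in_a, "a_only", "b_only"))
  defining_count <- function(det, unassigned) {
    vapply(seq_len(nrow(det)), function(i) {
      u <- unassigned[unassigned$premirna_id == det$premirna_id[i] &
                      unassigned$map_start == det$start[i] &
                      unassigned$map_end == det$end[i], , drop = FALSE]
      if (nrow(u) == 0L) 0 else max(u$count)
    }, numeric(1))
  }
  cons <- list()
  for (k in keys) {
    a <- det_a[det_a$mature_id == k, , drop = FALSE]
    b <- det_b[det_b$mature_id == k, , drop = FALSE]
    if (nrow(a) > 0L && nrow(b) > 0L) {
      ca <- defining_count(a, unassigned_a)
      cb <- defining_count(b, unassigned_b)
      cons[[k]] <- if (ca >= cb) a else b
    } else {
      cons[[k]] <- if (nrow(a) > 0L) a else b
    }
  }
  ann <- do.call(rbind, cons)
  if (is.null(ann)) ann <- det_a[0L, , drop = FALSE]
  rownames(ann) <- NULL
  list(annotations = ann, crosstab = crosstab)
}

#' Per-miRNA expression from isomiR counts
#'
#' The expression of a mature miRNA is the sum of the read counts of all
#' its isomiRs; the number of distinct isomiR types is reported alongside.
#'
#' @param isomirs isomiR data.frame from [assign_isomirs()].
#' @return data.frame mature_id, premirna_id, expression, n_isomir_types.
#' @export
expression_table <- function(isomirs) {
  if (nrow(isomirs) == 0L) {
    return(data.frame(mature_id = character(0), premirna_id = character(0),
                      expression = numeric(0), n_isomir_types = integer(0),
                      stringsAsFactors = FALSE))
  }
  sp <- split(isomirs, isomirs$mature_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(mature_id = d$mature_id[1L], premirna_id = d$premirna_id[1L],
               expression = sum(d$count), n_isomir_types = nrow(d),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$mature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge per-library isomiR tables into one wide table
#'
#' @param isomirs_a,isomirs_b isomiR data.frames of libraries A and B.
#' @return data.frame mature_id, premirna_id, start_offset, end_offset,
#'   count_a, count_b (union of offset pairs; absent counts are 0).
#' @export
isomir_table <- function(isomirs_a, isomirs_b) {
  key <- function(d) paste(d$mature_id, d$start_offset, d$end_offset,
                           sep = "\r")
  all <- rbind(isomirs_a, isomirs_b)
  all <- all[!duplicated(key(all)), c("mature_id", "premirna_id",
                                      "start_offset", "end_offset")]
  ka <- key(isomirs_a); kb <- key(isomirs_b); ku <- paste(
    all$mature_id, all$start_offset, all$end_offset, sep = "\r")
  all$count_a <- ifelse(ku %in% ka, isomirs_a$count[match(ku, ka)], 0)
  all$count_b <- ifelse(ku %in% kb, isomirs_b$count[match(ku, kb)], 0)
  all <- all[order(all$mature_id, all$start_offset, all$end_offset), ,
             drop = FALSE]
  rownames(all) <- NULL
  all
}

#' Per-hairpin per-arm expression totals
#'
#' Sums isomiR counts by hairpin arm (annotated plus detected matures), the
#' input to arm-selection ratio analysis.
#'
#' @param isomirs isomiR data.frame.
#' @param annotations Annotation data.frame covering the mature IDs.
#' @return data.frame premirna_id, arm, expression.
#' @export
arm_expression <- function(isomirs, annotations) {
  if (nrow(isomirs) == 0L) {
    return(data.frame(premirna_id = character(0), arm = character(0),
                      expression = numeric(0), stringsAsFactors = FALSE))
  }
  arm <- annotations$arm[match(isomirs$mature_id, annotations$mature_id)]
  key <- paste(isomirs$premirna_id, arm, sep = "\r")
  agg <- rowsum(isomirs$count, key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  out <- data.frame(premirna_id = vapply(parts, `[`, character(1), 1L),
                    arm = vapply(parts, `[`, character(1), 2L),
                    expression = agg[, 1L], stringsAsFactors = FALSE)
  out <- out[order(out$premirna_id, out$arm), , drop = FALSE]
  rownames(out) <- NULL
  out
}
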