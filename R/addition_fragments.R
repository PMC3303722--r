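#' Tabulate 3'-end addition fragments removed during trim-rescue mapping
#'
#' Reads rescued by iterative 3' trimming carry a nonempty trimmed
#' fragment — operationally the non-templated nucleotides appended to the
#' mature miRNA's 3' end (an appended base that matches the template is
#' never trimmed, so templated extensions are invisible here; see the
#' methods vignette). Counts are read counts (unique-read counts weighted
#' by abundance), tallied once per unique read even when it maps to several
#' loci. Percentages are per-fragment shares of all addition events; the
#' number of distinct fragment kinds and the addition rate (fraction of
#' mapped reads carrying an addition) are reported alongside.
#'
#' @param mapped \code{mapped} data.frame from [map_library()].
#' @return List of class \code{addition_table}: \code{fragments}
#'   (data.frame fragment, count, pct; descending pct, ties lexicographic),
#'   \code{n_kinds}, \code{added_reads}, \code{mapped_reads},
#'   \code{addition_rate} (fraction in [0,1]).
#' @export
tabulate_additions <- function(mapped) {
  # one row per unique read (multi-locus hits share one fragment)
  u <- mapped[!duplicated(mapped$sequence), , drop = FALSE]
  total_mapped <- sum(u$count)
  added <- u[nzchar(u$trimmed_fragment), , drop = FALSE]
  if (nrow(added) == 0L) {
    warning("no trim-rescued reads; addition table is empty")
    frags <- data.frame(fragment = character(0), count = numeric(0),
                        pct = numeric(0), stringsAsFactors = FALSE)
    return(structure(list(fragments = frags, n_kinds = 0L, added_reads = 0,
                          mapped_reads = total_mapped, addition_rate = 0),
                     class = "addition_table"))
  }
  stopifnot(all(grepl("^[ACGU]+$", added$trimmed_fragment)))
  agg <- rowsum(added$count, added$trimmed_fragment)
  frags <- data.frame(fragment = rownames(agg), count = agg[, 1L],
                      stringsAsFactors = FALSE)
  frags$pct <- 100 * frags$count / sum(frags$count)
  frags <- frags[order(-frags$pct, frags$fragment), , drop = FALSE]
  rownames(frags) <- NULL
  structure(list(fragments = frags, n_kinds = nrow(frags),
                 added_reads = sum(added$count),
                 mapped_reads = total_mapped,
                 addition_rate = sum(added$count) / total_mapped),
            class = "addition_table")
}

#' @export
print.addition_table <- function(x, ...) {
  cat(sprintf("3' addition fragments: %d kinds, %s added reads (%.1f%% of %s mapped)\n",
              x$n_kinds, format(x$added_reads, big.mark = ","),
              100 * x$addition_rate,
              format(x$mapped_reads, big.mark = ",")))
  print(utils::head(transform(x$fragments, pct = round_half_up(pct, 2L)), 10L))
  invisible(x)
}

#' Write a two-library addition-fragment table to TSV
#'
#' @param tab_a,tab_b \code{addition_table}s of the two libraries.
#' @param path Output TSV (fragment, count_libA, pct_libA, count_libB,
#'   pct_libB).
#' @return `path`, invisibly.
#' @export
write_addition_tsv <- function(tab_a, tab_b, path) {
  frags <- union(tab_a$fragments$fragment, tab_b$fragments$fragment)
  get <- function(tab, col) {
    v <- tab$fragments[[col]][match(frags, tab$fragments$fragment)]
    ifelse(is.na(v), 0, v)
  }
  out <- data.frame(fragment = frags,
                    count_libA = get(tab_a, "count"),
                    pct_libA = round_half_up(get(tab_a, "pct"), 2L),
                    count_libB = get(tab_b, "count"),
                    pct_libB = round_half_up(get(tab_b, "pct"), 2L),
                    stringsAsFactors = FALSE)
  out <- out[order(-pmax(out$pct_libA, out$pct_libB), out$fragment), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
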