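#' Round half away from zero at a fixed number of decimals
#'
#' Report-time rounding used for ratio tables (base R's round() rounds half
#' to even, which does not match the conventional half-up presentation).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' 5p/3p arm-selection ratios and between-library fold changes
#'
#' For each hairpin with per-arm expression in two libraries (named N and T
#' after the normal/tumor design this analysis comes from), computes the
#' within-library 5p:3p ratio (Ratio_N53p = N5p/N3p, Ratio_T53p = T5p/T3p)
#' and the fold change between the two ratios, defined as
#' max(ratio)/min(ratio) so it is >= 1 and symmetric in the libraries.
#' Within-library ratios are computed on raw counts: any monotone
#' per-library scaling cancels in the ratio, so no between-library
#' normalization is needed here. A hairpin is examined only when all four
#' arm counts reach \code{min_count} (default 10), and called significant
#' when it additionally exceeds the empirical fold-change threshold
#' (default 3). Ratios with a zero denominator are infinite and never
#' significant.
#'
#' @param counts data.frame with columns premirna_id, N5p, N3p, T5p, T3p
#'   (per-arm expression in libraries A = "N" and B = "T").
#' @param min_count Minimum of all four counts to pass the filter.
#' @param fc_threshold Fold-change threshold (strict >).
#' @return data.frame of class \code{arm_ratio_table}: the input counts
#'   plus ratio_a, ratio_b, fold_change (full precision),
#'   passes_count_filter, significant.
#' @export
arm_ratios <- function(counts, min_count = 10, fc_threshold = 3) {
  out <- counts[, c("premirna_id", "N5p", "N3p", "T5p", "T3p")]
  out$ratio_a <- out$N5p / out$N3p
  out$ratio_b <- out$T5p / out$T3p
  out$fold_change <- pmax(out$ratio_a, out$ratio_b) /
    pmin(out$ratio_a, out$ratio_b)
  out$passes_count_filter <-
    pmin(out$N5p, out$N3p, out$T5p, out$T3p) >= min_count
  out$significant <- out$passes_count_filter &
    is.finite(out$fold_change) & out$fold_change > fc_threshold
  class(out) <- c("arm_ratio_table", "data.frame")
  out
}

#' Format an arm-ratio table at report precision
#'
#' Ratios half-up rounded to 4 decimals and fold changes to 2, matching the
#' conventional presentation; the unrounded table should be used for any
#' further computation.
#'
#' @param records An \code{arm_ratio_table}.
#' @return data.frame with rounded ratio/fold-change columns.
#' @export
format_arm_ratios <- function(records) {
  out <- as.data.frame(records)
  out$ratio_a <- round_half_up(out$ratio_a, 4L)
  out$ratio_b <- round_half_up(out$ratio_b, 4L)
  out$fold_change <- round_half_up(out$fold_change, 2L)
  out
}

#' Compare observed major arms against the database annotation
#'
#' The observed major arm in each library is the arm with strictly larger
#' expression. The database's major arm comes from the annotation: for
#' two-arm annotations the product marked major, for single-arm annotations
#' the annotated arm itself (detecting the opposite arm at higher
#' expression then contradicts the annotation). The exchange label collects
#' the codes of the libraries ("N" for A, "T" for B) whose observed major
#' arm contradicts the database; a tied library contributes no code.
#'
#' @param counts data.frame with premirna_id, N5p, N3p, T5p, T3p.
#' @param mirbase_major Character vector (recycled) of the database major
#'   arm per hairpin: "5p", "3p" or "both-undetermined"; alternatively a
#'   \code{location} column in \code{counts} is parsed with
#'   [mirbase_major_arm()].
#' @return data.frame premirna_id, major_arm_a, major_arm_b,
#'   mirbase_major_arm, exch_label, tissue_switch.
#' @export
mirbase_consistency <- function(counts, mirbase_major = NULL) {
  if (is.null(mirbase_major)) {
    if (!"location" %in% names(counts)) {
      stop("supply mirbase_major or a 'location' column")
    }
    mirbase_major <- mirbase_major_arm(counts$location)
  }
  mirbase_major <- rep_len(mirbase_major, nrow(counts))
  major <- function(x5, x3) ifelse(x5 > x3, "5p", ifelse(x3 > x5, "3p", "tie"))
  ma <- major(counts$N5p, counts$N3p)
  mb <- major(counts$T5p, counts$T3p)
  if (any(ma == "tie" | mb == "tie")) {
    message(sum(ma == "tie") + sum(mb == "tie"),
            " tied arm count(s); tied libraries contribute no exchange code")
  }
  code <- function(obs, lib_code) {
    ifelse(obs != "tie" & mirbase_major %in% c("5p", "3p") &
             obs != mirbase_major, lib_code, "")
  }
  ca <- code(ma, "N"); cb <- code(mb, "T")
  exch <- ifelse(nzchar(ca) & nzchar(cb), paste(ca, cb, sep = ";"),
                 paste0(ca, cb))
  data.frame(premirna_id = counts$premirna_id,
             major_arm_a = ma, major_arm_b = mb,
             mirbase_major_arm = mirbase_major,
             exch_label = exch,
             tissue_switch = ma != "tie" & mb != "tie" & ma != mb,
             stringsAsFactors = FALSE)
}

#' Arm-preference switches between the two libraries
#'
#' A hairpin switches arm preference when its strictly-major arm differs
#' between the libraries (e.g. 5p-dominant in normal tissue but 3p-dominant
#' in tumor). Ties in either library yield no switch call.
#'
#' @param counts data.frame with premirna_id, N5p, N3p, T5p, T3p.
#' @return data.frame premirna_id, major_arm_a, major_arm_b, tissue_switch.
#' @export
tissue_switch_calls <- function(counts) {
  cc <- mirbase_consistency(counts, mirbase_major = "both-undetermined")
  cc[, c("premirna_id", "major_arm_a", "major_arm_b", "tissue_switch")]
}
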