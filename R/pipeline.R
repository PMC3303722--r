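#' Run the full two-library isomiR / arm-selection pipeline
#'
#' Maps both libraries onto the hairpin reference (exact match with
#' iterative 3' trimming), assigns isomiRs within the offset acceptance
#' windows, detects opposite-arm miRNAs from the unassigned pools,
#' quantifies per-miRNA and per-arm expression, computes arm-selection
#' ratios with between-library fold changes, tabulates 3' addition
#' fragments, screens isomiR distribution patterns with the categorical KS
#' comparison, and fits the between-library normalization model.
#'
#' @param hairpins Hairpin data.frame ([read_hairpins()]).
#' @param annotations Mature annotation data.frame ([locate_matures()]).
#' @param lib_a,lib_b \code{smallrna_library} objects, or data.frames of
#'   collapsed reads (sequence, count) which are then passed through the
#'   length/count filters.
#' @param min_len,max_len,min_count Collapse filters for data.frame input.
#' @param min_trim_len Minimum post-trim read length for mapping.
#' @param max_start_offset,max_end_offset isomiR acceptance windows.
#' @param detect_opposite Detect opposite-arm miRNAs on one-arm hairpins.
#' @param min_detect_count Minimum defining-read count for a detection.
#' @param split_multihits Split multi-locus read counts across loci.
#' @param ks_min_types,ks_min_reads,ks_alpha KS screen parameters.
#' @param ratio_min_count,ratio_fc_threshold Arm-ratio filter parameters.
#' @return List of class \code{isomirarm_result} with elements
#'   \code{isomirs} (wide table), \code{isomirs_a}, \code{isomirs_b},
#'   \code{expression_a}, \code{expression_b}, \code{arm_counts} (N5p/N3p/
#'   T5p/T3p per hairpin), \code{arm_ratio} (arm-ratio records),
#'   \code{consistency} (exchange and switch calls), \code{additions_a},
#'   \code{additions_b}, \code{ks} (screen table), \code{detected}
#'   (opposite-arm annotations), \code{opposite_arm_crosstab},
#'   \code{norm_model} (or NULL if unfittable), \code{conservation}.
#' @export
run_pipeline <- function(hairpins, annotations, lib_a, lib_b,
                         min_len = 18L, max_len = 25L, min_count = 2L,
                         min_trim_len = 18L,
                         max_start_offset = 2L, max_end_offset = 5L,
                         detect_opposite = TRUE, min_detect_count = 2L,
                         split_multihits = FALSE,
                         ks_min_types = 8L, ks_min_reads = 1000,
                         ks_alpha = 0.001,
                         ratio_min_count = 10, ratio_fc_threshold = 3) {
  as_lib <- function(x, name) {
    if (inherits(x, "smallrna_library")) x
    else collapse_and_filter(x, name = name, min_len = min_len,
                             max_len = max_len, min_count = min_count)
  }
  lib_a <- as_lib(lib_a, "A")
  lib_b <- as_lib(lib_b, "B")

  map_a <- map_library(lib_a, hairpins, min_trim_len = min_trim_len,
                       split_multihits = split_multihits)
  map_b <- map_library(lib_b, hairpins, min_trim_len = min_trim_len,
                       split_multihits = split_multihits)
  asg_a <- assign_isomirs(map_a$mapped, annotations,
                          max_start_offset, max_end_offset)
  asg_b <- assign_isomirs(map_b$mapped, annotations,
                          max_start_offset, max_end_offset)
  iso_a <- asg_a$isomirs; un_a <- asg_a$unassigned
  iso_b <- asg_b$isomirs; un_b <- asg_b$unassigned

  detected <- annotations[0L, , drop = FALSE]
  crosstab <- NULL
  if (detect_opposite) {
    det <- detect_opposite_arms_paired(un_a, un_b, annotations, hairpins,
                                       min_count = min_detect_count)
    detected <- det$annotations
    crosstab <- det$crosstab
    if (nrow(detected) > 0L) {
      re_a <- assign_isomirs(un_a, detected, max_start_offset,
                             max_end_offset)
      re_b <- assign_isomirs(un_b, detected, max_start_offset,
                             max_end_offset)
      iso_a <- aggregate_isomirs(rbind(iso_a, re_a$isomirs))
      iso_b <- aggregate_isomirs(rbind(iso_b, re_b$isomirs))
      un_a <- re_a$unassigned
      un_b <- re_b$unassigned
    }
  }
  ann_all <- rbind(annotations, detected)

  expr_a <- expression_table(iso_a)
  expr_b <- expression_table(iso_b)

  arm_a <- arm_expression(iso_a, ann_all)
  arm_b <- arm_expression(iso_b, ann_all)
  ids <- unique(c(arm_a$premirna_id, arm_b$premirna_id))
  pull <- function(arm_df, arm) {
    v <- arm_df$expression[match(paste(ids, arm),
                                 paste(arm_df$premirna_id, arm_df$arm))]
    ifelse(is.na(v), 0, v)
  }
  arm_counts <- data.frame(premirna_id = ids,
                           N5p = pull(arm_a, "5p"), N3p = pull(arm_a, "3p"),
                           T5p = pull(arm_b, "5p"), T3p = pull(arm_b, "3p"),
                           stringsAsFactors = FALSE)
  ratio <- arm_ratios(arm_counts, min_count = ratio_min_count,
                      fc_threshold = ratio_fc_threshold)
  consistency <- tissue_switch_calls(arm_counts)

  additions_a <- suppressWarnings(tabulate_additions(map_a$mapped))
  additions_b <- suppressWarnings(tabulate_additions(map_b$mapped))
  wide <- isomir_table(iso_a, iso_b)
  ks <- if (nrow(wide) > 0L) {
    screen_all(wide, min_types = ks_min_types, min_reads = ks_min_reads,
               alpha = ks_alpha)
  } else NULL
  norm_model <- tryCatch(fit_normalization(expr_a, expr_b),
                         error = function(e) NULL)

  conservation <- rbind(
    conservation_row("A", lib_a, map_a, un_a, iso_a),
    conservation_row("B", lib_b, map_b, un_b, iso_b))

  structure(list(isomirs = wide, isomirs_a = iso_a, isomirs_b = iso_b,
                 expression_a = expr_a, expression_b = expr_b,
                 arm_counts = arm_counts, arm_ratio = ratio,
                 consistency = consistency,
                 additions_a = additions_a, additions_b = additions_b,
                 ks = ks, detected = detected,
                 opposite_arm_crosstab = crosstab,
                 norm_model = norm_model, conservation = conservation,
                 lib_a = lib_a, lib_b = lib_b),
            class = "isomirarm_result")
}

# Read-level conservation: every used read is exactly one of assigned /
# mapped-but-unassigned / unmapped (counts tallied once per unique read).
conservation_row <- function(name, lib, map_res, unassigned, isomirs) {
  un_seqs <- unique(unassigned$sequence)
  mapped_seqs <- unique(map_res$mapped$sequence)
  assigned_seqs <- setdiff(mapped_seqs, un_seqs)
  cnt <- function(seqs) sum(lib$reads$count[lib$reads$sequence %in% seqs])
  data.frame(library = name,
             assigned = cnt(assigned_seqs),
             unassigned = cnt(un_seqs),
             unmapped = sum(map_res$unmapped$count),
             isomir_total = sum(isomirs$count),
             total_used = lib$total_used,
             stringsAsFactors = FALSE)
}

#' @export
print.isomirarm_result <- function(x, ...) {
  cat("isomiR / arm-selection pipeline result\n")
  cat(sprintf("  libraries: %s (%g reads used), %s (%g reads used)\n",
              x$lib_a$name, x$lib_a$total_used,
              x$lib_b$name, x$lib_b$total_used))
  cat(sprintf("  isomiR types: %d across %d mature miRNAs\n",
              nrow(x$isomirs), length(unique(x$isomirs$mature_id))))
  cat(sprintf("  opposite-arm detections: %d\n", nrow(x$detected)))
  cat(sprintf("  hairpins passing arm-ratio count filter: %d (significant: %d)\n",
              sum(x$arm_ratio$passes_count_filter),
              sum(x$arm_ratio$significant)))
  if (!is.null(x$ks)) {
    cat(sprintf("  KS screen: %d eligible, %d significant\n",
                attr(x$ks, "n_eligible"), attr(x$ks, "n_significant")))
  }
  invisible(x)
}

#' Bundled gastric normal/tumor reference tables
#'
#' Loads the published per-hairpin worked-example tables from the gastric
#' normal (N) / tumor (T) paired-library study this package reimplements:
#' \code{"arm_ratio"} (per-hairpin arm counts with printed ratios and fold
#' changes), \code{"exchange"} (hairpins whose observed major arm
#' contradicts the database annotation, with printed exchange labels),
#' \code{"switch"} (hairpins whose major arm differs between tissues) and
#' \code{"additions"} (the 3' addition-fragment abundance spectrum, in %).
#'
#' @param table One of "arm_ratio", "exchange", "switch", "additions".
#' @return The table as a data.frame.
#' @export
gastric_reference <- function(table = c("arm_ratio", "exchange", "switch",
                                        "additions")) {
  table <- match.arg(table)
  file <- c(arm_ratio = "gastric_arm_ratio.tsv",
            exchange = "gastric_arm_exchange.tsv",
            switch = "gastric_arm_switch.tsv",
            additions = "gastric_addition_fragments.tsv")[[table]]
  path <- system.file("extdata", file, package = "isomirarm",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
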