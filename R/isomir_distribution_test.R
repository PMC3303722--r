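#' Build the isomiR type table for one mature miRNA across two libraries
#'
#' The isomiR types of a mature miRNA are the union of the (start offset,
#' end offset) pairs observed in either library, ordered 5' to 3'
#' (ascending start offset, then ascending end offset) and numbered with
#' consecutive type IDs 1..K along that order. Relative abundances are
#' computed within each library; a type absent from one library has
#' abundance zero there. The canonical order is what makes a
#' Kolmogorov-Smirnov comparison along the type axis well defined.
#'
#' @param isomirs_a,isomirs_b isomiR data.frames for one mature miRNA
#'   (columns start_offset, end_offset, count), from the two libraries.
#' @param mature_id Mature miRNA identifier (taken from the data when
#'   present).
#' @return List of class \code{isomir_type_table}: \code{mature_id},
#'   \code{types} (data.frame type_id, start_offset, end_offset, count_a,
#'   count_b, rel_a, rel_b), \code{n_a}, \code{n_b}.
#' @export
build_type_table <- function(isomirs_a, isomirs_b, mature_id = NULL) {
  if (is.null(mature_id)) {
    mature_id <- c(isomirs_a$mature_id, isomirs_b$mature_id)[1L]
  }
  if (nrow(isomirs_a) + nrow(isomirs_b) == 0L) {
    stop("no isomiRs in either library for '", mature_id, "'")
  }
  key <- function(d) paste(d$start_offset, d$end_offset, sep = "\r")
  uni <- rbind(isomirs_a[, c("start_offset", "end_offset")],
               isomirs_b[, c("start_offset", "end_offset")])
  uni <- uni[!duplicated(key(uni)), , drop = FALSE]
  uni <- uni[order(uni$start_offset, uni$end_offset), , drop = FALSE]
  ku <- key(uni)
  ca <- isomirs_a$count[match(ku, key(isomirs_a))]
  cb <- isomirs_b$count[match(ku, key(isomirs_b))]
  ca[is.na(ca)] <- 0; cb[is.na(cb)] <- 0
  n_a <- sum(ca); n_b <- sum(cb)
  types <- data.frame(type_id = seq_len(nrow(uni)),
                      start_offset = uni$start_offset,
                      end_offset = uni$end_offset,
                      count_a = ca, count_b = cb,
                      rel_a = if (n_a > 0) ca / n_a else rep(0, length(ca)),
                      rel_b = if (n_b > 0) cb / n_b else rep(0, length(cb)),
                      stringsAsFactors = FALSE)
  rownames(types) <- NULL
  structure(list(mature_id = mature_id, types = types, n_a = n_a, n_b = n_b),
            class = "isomir_type_table")
}

#' Asymptotic two-sample Kolmogorov p-value
#'
#' Evaluates the Kolmogorov distribution tail
#' Q(lambda) = 2 * sum_{j>=1} (-1)^(j-1) exp(-2 j^2 lambda^2) at
#' lambda = (sqrt(n_e) + 0.12 + 0.11/sqrt(n_e)) * D with effective sample
#' size n_e = n_a n_b / (n_a + n_b).
#'
#' @param d KS statistic D in [0, 1].
#' @param n_a,n_b Sample sizes of the two groups.
#' @return p-value in [0, 1].
#' @export
ks_pvalue <- function(d, n_a, n_b) {
  if (d <= 0) return(1)
  ne <- n_a * n_b / (n_a + n_b)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * d
  if (lambda < 1e-3) return(1)
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Categorical two-sample KS comparison of isomiR distributions
#'
#' D is the maximum absolute difference between the two cumulative
#' relative-abundance vectors taken along the canonical type order; because
#' the axis is categorical, the order matters and is fixed by
#' [build_type_table()]. The p-value treats reads as the sample units
#' (sample sizes n_a, n_b are total read counts), using the asymptotic
#' Kolmogorov distribution. Eligibility requires more than
#' \code{min_types} isomiR types and more than \code{min_reads} reads in
#' each library — low-expression miRNAs present too few types for the
#' comparison to be meaningful.
#'
#' @param table An \code{isomir_type_table}.
#' @param min_types,min_reads Eligibility floors (strict >; defaults 8 and
#'   1000).
#' @param alpha Significance level on the raw p-value (default 0.001).
#' @return List of class \code{ks_result}: mature_id, d_stat, p_value,
#'   n_a, n_b, n_effective, k_types, eligible, significant.
#' @export
ks_compare <- function(table, min_types = 8L, min_reads = 1000,
                       alpha = 0.001) {
  cdf_a <- cumsum(table$types$rel_a)
  cdf_b <- cumsum(table$types$rel_b)
  d <- max(abs(cdf_a - cdf_b))
  p <- ks_pvalue(d, table$n_a, table$n_b)
  k <- nrow(table$types)
  eligible <- k > min_types && table$n_a > min_reads && table$n_b > min_reads
  structure(list(mature_id = table$mature_id, d_stat = d, p_value = p,
                 n_a = table$n_a, n_b = table$n_b,
                 n_effective = table$n_a * table$n_b /
                   (table$n_a + table$n_b),
                 k_types = k, eligible = eligible,
                 significant = eligible && p < alpha),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("%s: K = %d types, n = (%g, %g), D = %.4f, p = %.3g%s\n",
              x$mature_id, x$k_types, x$n_a, x$n_b, x$d_stat, x$p_value,
              if (!x$eligible) " [ineligible]"
              else if (x$significant) " *" else ""))
  invisible(x)
}

#' Screen all miRNAs for differing isomiR distribution patterns
#'
#' Builds the per-miRNA type table from a wide isomiR table and applies the
#' categorical KS comparison to every mature miRNA, flagging eligibility
#' and significance. No multiple-testing correction is applied by default
#' (the screen uses a raw p < alpha criterion); \code{bonferroni = TRUE}
#' divides alpha by the number of eligible tests.
#'
#' @param wide Wide isomiR table from [isomir_table()].
#' @inheritParams ks_compare
#' @param bonferroni Apply a Bonferroni-adjusted alpha.
#' @return data.frame mature_id, k_types, n_a, n_b, d_stat, p_value,
#'   eligible, significant, with attributes \code{n_eligible} and
#'   \code{n_significant}.
#' @export
screen_all <- function(wide, min_types = 8L, min_reads = 1000,
                       alpha = 0.001, bonferroni = FALSE) {
  sp <- split(wide, wide$mature_id)
  res <- lapply(sp, function(d) {
    a <- data.frame(mature_id = d$mature_id, start_offset = d$start_offset,
                    end_offset = d$end_offset, count = d$count_a)
    b <- data.frame(mature_id = d$mature_id, start_offset = d$start_offset,
                    end_offset = d$end_offset, count = d$count_b)
    ks_compare(build_type_table(a, b), min_types = min_types,
               min_reads = min_reads, alpha = alpha)
  })
  out <- do.call(rbind, lapply(res, function(r) {
    data.frame(mature_id = r$mature_id, k_types = r$k_types,
               n_a = r$n_a, n_b = r$n_b, d_stat = r$d_stat,
               p_value = r$p_value, eligible = r$eligible,
               significant = r$significant, stringsAsFactors = FALSE)
  }))
  if (bonferroni) {
    m <- sum(out$eligible)
    out$significant <- out$eligible & out$p_value < alpha / max(m, 1L)
  }
  out <- out[order(out$p_value, out$mature_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_eligible") <- sum(out$eligible)
  attr(out, "n_significant") <- sum(out$significant)
  out
}

#' Paired isomiR-distribution comparison plot
#'
#' Per-library relative-abundance bars over type IDs with the cumulative
#' curves and the KS D annotation; purely presentational.
#'
#' @param table An \code{isomir_type_table}.
#' @param result The matching \code{ks_result}.
#' @param file Output file (device chosen from the extension).
#' @param lib_names Display names of the two libraries.
#' @return `file`, invisibly.
#' @export
comparison_plot <- function(table, result, file,
                            lib_names = c("library A", "library B")) {
  t <- table$types
  df <- data.frame(type_id = rep(t$type_id, 2L),
                   library = rep(lib_names, each = nrow(t)),
                   rel = c(t$rel_a, t$rel_b),
                   cdf = c(cumsum(t$rel_a), cumsum(t$rel_b)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = type_id)) +
    ggplot2::geom_col(ggplot2::aes(y = rel), width = 0.8) +
    ggplot2::geom_step(ggplot2::aes(y = cdf), direction = "hv") +
    ggplot2::facet_wrap(~library, ncol = 1L) +
    ggplot2::labs(title = table$mature_id,
                  subtitle = sprintf("KS D = %.4f, p = %.3g",
                                     result$d_stat, result$p_value),
                  x = "isomiR type ID", y = "relative abundance") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file, p, width = 6, height = 6)
  invisible(file)
}
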