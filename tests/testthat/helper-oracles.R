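# Independent brute-force oracles and fixture builders used across tests.

# Exhaustive mapper oracle: scan every substring of every hairpin at every
# trim length, longest first; stops at the first length with any hit.
brute_map <- function(read, hairpins, min_len = 18L) {
  n <- nchar(read)
  for (len in seq(n, min_len)) {
    core <- substr(read, 1L, len)
    rows <- list()
    for (i in seq_len(nrow(hairpins))) {
      hs <- hairpins$sequence[i]
      last <- nchar(hs) - len + 1L
      if (last < 1L) next
      for (p in seq_len(last)) {
        if (substr(hs, p, p + len - 1L) == core) {
          rows[[length(rows) + 1L]] <- data.frame(
            premirna_id = hairpins$id[i], map_start = p,
            map_end = p + len - 1L,
            trimmed_fragment = substr(read, len + 1L, n),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows) > 0L) return(do.call(rbind, rows))
  }
  data.frame(premirna_id = character(0), map_start = integer(0),
             map_end = integer(0), trimmed_fragment = character(0),
             stringsAsFactors = FALSE)
}

# Brute-force adapter scan: leftmost position where the adapter (or an
# adapter prefix of >= min_overlap nt reaching the read end) occurs.
brute_trim <- function(read, adapter, min_overlap = 6L) {
  n <- nchar(read); la <- nchar(adapter)
  for (i in seq_len(n)) {
    take <- min(la, n - i + 1L)
    full <- take == la
    if (!full && take < min_overlap) next
    if (!full && (i + take - 1L) != n) next
    if (substr(read, i, i + take - 1L) == substr(adapter, 1L, take)) {
      return(substr(read, 1L, i - 1L))
    }
  }
  NULL
}

# Direct evaluation of the asymptotic two-sample Kolmogorov tail.
ks_series_p <- function(d, n_a, n_b, terms = 200L) {
  ne <- n_a * n_b / (n_a + n_b)
  lam <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * d
  j <- seq_len(terms)
  min(max(2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lam^2)), 0), 1)
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Tiny deterministic two-hairpin reference for hand-checkable cases.
toy_reference <- function() {
  set.seed(404)
  h1 <- random_rna(80)
  h2 <- random_rna(90)
  hairpins <- data.frame(id = c("toy-mir-1", "toy-mir-2"),
                         sequence = c(h1, h2), length = c(80L, 90L),
                         stringsAsFactors = FALSE)
  ann <- data.frame(
    premirna_id = c("toy-mir-1", "toy-mir-1", "toy-mir-2"),
    mature_id = c("toy-mir-1-5p", "toy-mir-1-3p", "toy-mir-2-3p"),
    start = c(5L, 52L, 60L), end = c(26L, 73L, 81L),
    arm = c("5p", "3p", "3p"), source = "mirbase",
    stringsAsFactors = FALSE)
  list(hairpins = hairpins, annotations = ann)
}

# Synthetic KS screening cohort: `n_null` miRNAs share one generating
# distribution in both libraries; `n_shifted` move >= 15 percentage points
# of mass to later types in library B. Returns a wide isomiR table.
make_ks_cohort <- function(n_null = 50L, n_shifted = 10L, n_reads = 5000L,
                           seed = 11L) {
  set.seed(seed)
  k <- 12L
  p0 <- c(0.25, 0.20, 0.15, 0.10, 0.08, 0.06, 0.05, 0.04, 0.03, 0.02,
          0.01, 0.01)
  p_shift <- p0
  p_shift[1:2] <- p_shift[1:2] - c(0.10, 0.05)
  p_shift[7:8] <- p_shift[7:8] + c(0.10, 0.05)
  rows <- list()
  add <- function(name, pa, pb) {
    ca <- stats::rmultinom(1L, n_reads, pa)[, 1L]
    cb <- stats::rmultinom(1L, n_reads, pb)[, 1L]
    rows[[length(rows) + 1L]] <<- data.frame(
      mature_id = name, premirna_id = name, start_offset = 0L,
      end_offset = seq_len(k), count_a = ca, count_b = cb,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_null)) add(sprintf("null-%02d", i), p0, p0)
  for (i in seq_len(n_shifted)) add(sprintf("shift-%02d", i), p0, p_shift)
  do.call(rbind, rows)
}
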