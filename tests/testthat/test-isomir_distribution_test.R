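iso_df <- function(offsets, counts, id = "m") {
  data.frame(mature_id = id, premirna_id = "h",
             start_offset = vapply(offsets, `[`, integer(1), 1L),
             end_offset = vapply(offsets, `[`, integer(1), 2L),
             count = counts, stringsAsFactors = FALSE)
}

test_that("type tables take the offset union in canonical 5'->3' order", {
  a <- iso_df(list(c(0L, 0L), c(1L, 0L)), c(90, 10))
  b <- iso_df(list(c(0L, 0L), c(0L, -1L)), c(50, 50))
  tt <- build_type_table(a, b)
  expect_equal(nrow(tt$types), 3L)
  expect_equal(tt$types$start_offset, c(0L, 0L, 1L))
  expect_equal(tt$types$end_offset, c(-1L, 0L, 0L))
  expect_equal(tt$types$type_id, 1:3)
  expect_equal(tt$types$rel_a, c(0, 0.9, 0.1))
  expect_equal(tt$types$rel_b, c(0.5, 0.5, 0))
  expect_equal(sum(tt$types$rel_a), 1, tolerance = 1e-9)
  expect_error(build_type_table(a[0, ], b[0, ]), "no isomiRs")
})

test_that("identical libraries give D = 0, p = 1; disjoint give D = 1", {
  a <- iso_df(list(c(0L, 0L), c(0L, 1L)), c(70, 30))
  tt <- build_type_table(a, a)
  r <- ks_compare(tt)
  expect_equal(r$d_stat, 0)
  expect_equal(r$p_value, 1)
  b <- iso_df(list(c(0L, 1L)), 5000)
  a2 <- iso_df(list(c(0L, 0L)), 5000)
  r <- ks_compare(build_type_table(a2, b))
  expect_equal(r$d_stat, 1)
  expect_lt(r$p_value, 1e-12)
})

test_that("D and p agree with the Kolmogorov series oracle to 1e-6", {
  a <- iso_df(list(c(0L, 0L), c(0L, 1L)), c(1000, 1000))
  b <- iso_df(list(c(0L, 0L), c(0L, 1L)), c(200, 1800))
  r <- ks_compare(build_type_table(a, b))
  expect_equal(r$d_stat, 0.4)
  expect_equal(r$p_value, ks_series_p(0.4, 2000, 2000), tolerance = 1e-6)
  # moderate D where the p-value is non-degenerate
  for (d in c(0.02, 0.035, 0.05)) {
    expect_equal(ks_pvalue(d, 1500, 2500), ks_series_p(d, 1500, 2500),
                 tolerance = 1e-6)
  }
})

test_that("D matches stats::ks.test on read-expanded samples", {
  set.seed(81)
  for (i in 1:5) {
    ka <- sample(3:6, 1)
    ca <- stats::rmultinom(1, 300, stats::runif(ka) + 0.2)[, 1]
    cb <- stats::rmultinom(1, 400, stats::runif(ka) + 0.2)[, 1]
    offs <- lapply(seq_len(ka), function(k) c(0L, k))
    tt <- build_type_table(iso_df(offs, ca), iso_df(offs, cb))
    r <- ks_compare(tt)
    ref <- suppressWarnings(stats::ks.test(rep(seq_len(ka), ca),
                                           rep(seq_len(ka), cb)))
    expect_equal(r$d_stat, unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("D is invariant under per-library count scaling", {
  a <- iso_df(list(c(0L, 0L), c(0L, 1L), c(1L, 1L)), c(10, 30, 60))
  b <- iso_df(list(c(0L, 0L), c(0L, 1L), c(1L, 1L)), c(40, 40, 20))
  d1 <- ks_compare(build_type_table(a, b))$d_stat
  a$count <- a$count * 17
  d2 <- ks_compare(build_type_table(a, b))$d_stat
  expect_equal(d1, d2)
})

test_that("p decreases monotonically in D at fixed sample sizes", {
  d <- seq(0.01, 0.5, by = 0.01)
  p <- vapply(d, ks_pvalue, numeric(1), n_a = 2000, n_b = 2000)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("eligibility floors are strict", {
  offs8 <- lapply(1:8, function(k) c(0L, k))
  a <- iso_df(offs8, rep(200, 8)); b <- iso_df(offs8, rep(200, 8))
  expect_false(ks_compare(build_type_table(a, b))$eligible)   # K = 8 exactly
  offs9 <- lapply(1:9, function(k) c(0L, k))
  a <- iso_df(offs9, c(rep(111, 8), 112))                     # n_a = 1000
  b <- iso_df(offs9, rep(200, 9))
  expect_false(ks_compare(build_type_table(a, b))$eligible)
  a$count <- a$count + 1                                       # n_a = 1009
  expect_true(ks_compare(build_type_table(a, b))$eligible)
})

test_that("screening recovers planted pattern shifts with few false calls", {
  wide <- make_ks_cohort(n_null = 50, n_shifted = 10, n_reads = 5000,
                         seed = 11)
  res <- screen_all(wide)
  shifted <- grepl("^shift", res$mature_id)
  expect_true(all(res$eligible))
  expect_true(all(res$significant[shifted]))
  expect_lte(sum(res$significant[!shifted]), 2L)
  expect_equal(attr(res, "n_eligible"), 60L)
})

test_that("the canonical order is deterministic across shuffles", {
  a <- iso_df(list(c(0L, 0L), c(-1L, 2L), c(1L, -3L), c(0L, 1L)),
              c(10, 20, 30, 40))
  b <- iso_df(list(c(1L, -3L), c(0L, 0L)), c(5, 5))
  t1 <- build_type_table(a, b)
  t2 <- build_type_table(a[sample(nrow(a)), ], b[sample(nrow(b)), ])
  expect_identical(t1$types, t2$types)
})

test_that("comparison plots are written with the D annotation", {
  a <- iso_df(list(c(0L, 0L), c(0L, 1L)), c(60, 40))
  b <- iso_df(list(c(0L, 0L), c(0L, 1L)), c(30, 70))
  tt <- build_type_table(a, b)
  r <- ks_compare(tt)
  f <- withr::local_tempfile(fileext = ".png")
  suppressMessages(comparison_plot(tt, r, f))
  expect_true(file.exists(f))
  expect_gt(file.size(f), 0)
})
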