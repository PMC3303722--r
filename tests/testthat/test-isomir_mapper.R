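test_that("exact reads map without trimming; mismatched tails are trimmed", {
  ref <- toy_reference()
  h1 <- ref$hairpins$sequence[1]
  read <- substr(h1, 47, 67)
  m <- map_read(read, ref$hairpins)
  expect_equal(nrow(m), 1L)
  expect_equal(m$map_start, 47L)
  expect_equal(m$map_end, 67L)
  expect_equal(m$trimmed_fragment, "")

  # single-step trim: appended base differs from the next templated base
  nxt <- substr(h1, 31, 31)
  bad <- setdiff(c("A", "C", "G", "U"), nxt)[1]
  m <- map_read(paste0(substr(h1, 10, 30), bad), ref$hairpins)
  expect_equal(m$map_start, 10L)
  expect_equal(m$map_end, 30L)
  expect_equal(m$trimmed_fragment, bad)

  # unmappable at every allowed length
  expect_equal(nrow(map_read(strrep("AC", 10), ref$hairpins)), 0L)
})

test_that("mapper agrees with the brute-force all-substrings oracle", {
  sim <- simulate_libraries(sim_config(n_hairpins = 8,
                                       library_depth = c(800, 800),
                                       seed = 51))
  reads <- sim$lib_a$sequence
  set.seed(52)
  # mix in unmappable and truncated reads
  reads <- c(sample(reads, min(250, length(reads))),
             vapply(1:20, function(i) random_rna(20), character(1)))
  for (r in reads) {
    got <- map_read(r, sim$hairpins)
    want <- brute_map(r, sim$hairpins)
    got <- got[order(got$premirna_id, got$map_start), ]
    want <- want[order(want$premirna_id, want$map_start), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("mapped spans re-extract the post-trim read exactly", {
  sim <- simulate_libraries(sim_config(n_hairpins = 5,
                                       library_depth = c(500, 500),
                                       seed = 53))
  lib <- collapse_and_filter(sim$lib_a, min_count = 1L)
  mp <- map_library(lib, sim$hairpins)
  expect_gt(nrow(mp$mapped), 0L)
  for (i in seq_len(nrow(mp$mapped))) {
    row <- mp$mapped[i, ]
    hseq <- sim$hairpins$sequence[sim$hairpins$id == row$premirna_id]
    core <- substr(row$sequence, 1,
                   nchar(row$sequence) - nchar(row$trimmed_fragment))
    expect_identical(substr(hseq, row$map_start, row$map_end), core)
    expect_gte(nchar(core), 18L)
  }
})

test_that("isomiR assignment enforces the offset acceptance windows", {
  ref <- toy_reference()
  ann <- ref$annotations[1, , drop = FALSE]   # 5..26 on toy-mir-1
  mk <- function(s, e) data.frame(sequence = "x", count = 5,
                                  premirna_id = "toy-mir-1", map_start = s,
                                  map_end = e, trimmed_fragment = "",
                                  n_loci = 1L, stringsAsFactors = FALSE)
  # reference form
  r <- assign_isomirs(mk(5L, 26L), ann)
  expect_equal(r$isomirs$start_offset, 0L)
  expect_equal(r$isomirs$end_offset, 0L)
  # extreme accepted corner (+2, -5)
  r <- assign_isomirs(mk(7L, 21L), ann)
  expect_equal(r$isomirs$start_offset, 2L)
  expect_equal(r$isomirs$end_offset, -5L)
  # start offset +3 is rejected
  r <- assign_isomirs(mk(8L, 26L), ann)
  expect_equal(nrow(r$isomirs), 0L)
  expect_equal(nrow(r$unassigned), 1L)
})

test_that("no emitted isomiR violates the windows on simulated data", {
  sim <- simulate_libraries(sim_config(n_hairpins = 10,
                                       library_depth = c(2000, 2000),
                                       seed = 54))
  res <- run_pipeline(sim$hairpins, sim$annotations, sim$lib_a, sim$lib_b)
  expect_true(all(abs(res$isomirs$start_offset) <= 2))
  expect_true(all(abs(res$isomirs$end_offset) <= 5))
})

test_that("ambiguous two-annotation reads go to the smaller start offset", {
  ref <- toy_reference()
  ann <- data.frame(premirna_id = "toy-mir-1",
                    mature_id = c("m5", "m3"),
                    start = c(20L, 24L), end = c(41L, 45L),
                    arm = c("5p", "3p"), source = "mirbase",
                    stringsAsFactors = FALSE)
  mapped <- data.frame(sequence = "x", count = 1, premirna_id = "toy-mir-1",
                       map_start = 22L, map_end = 43L, trimmed_fragment = "",
                       n_loci = 1L, stringsAsFactors = FALSE)
  expect_warning(r <- assign_isomirs(mapped, ann), "more than one")
  # offsets are (+2,+2) on m5 and (-2,-2) on m3: |start| and |end| both tie,
  # so the 5p annotation wins the final tie-break
  expect_equal(r$isomirs$mature_id, "m5")
})

test_that("opposite-arm miRNAs are detected at the planted span", {
  sim <- simulate_libraries(sim_config(n_hairpins = 10,
                                       library_depth = c(3000, 3000),
                                       unannotated_arm_fraction = 0.5,
                                       seed = 55))
  hidden <- setdiff(sim$annotations_full$mature_id,
                    sim$annotations$mature_id)
  expect_gt(length(hidden), 0L)
  res <- run_pipeline(sim$hairpins, sim$annotations, sim$lib_a, sim$lib_b)
  expect_gt(nrow(res$detected), 0L)
  truth <- sim$annotations_full
  for (i in seq_len(nrow(res$detected))) {
    d <- res$detected[i, ]
    t <- truth[truth$premirna_id == d$premirna_id & truth$arm == d$arm, ]
    # detected span is the most abundant read's span: it must sit inside the
    # planted mature's offset neighbourhood
    expect_lte(abs(d$start - t$start), 2L)
    expect_lte(abs(d$end - t$end), 5L)
  }
  # both-arms-annotated hairpins yield no detection
  expect_false(any(res$detected$premirna_id %in%
                     sim$annotations$premirna_id[
                       duplicated(sim$annotations$premirna_id)]))
  expect_true(all(res$opposite_arm_crosstab$category %in%
                    c("a_only", "b_only", "shared")))
})

test_that("expression is the sum of isomiR counts", {
  iso <- data.frame(mature_id = "m", premirna_id = "h",
                    start_offset = c(0L, 1L, 0L), end_offset = c(0L, 0L, -1L),
                    count = c(10, 7, 3), stringsAsFactors = FALSE)
  et <- expression_table(iso)
  expect_equal(et$expression, 20)
  expect_equal(et$n_isomir_types, 3L)
  expect_equal(nrow(expression_table(iso[0, ])), 0L)
})

test_that("read counts are conserved through mapping and assignment", {
  for (seed in c(61, 62)) {
    sim <- simulate_libraries(sim_config(n_hairpins = 8,
                                         library_depth = c(1500, 1500),
                                         unannotated_arm_fraction = 0.25,
                                         seed = seed))
    res <- run_pipeline(sim$hairpins, sim$annotations, sim$lib_a, sim$lib_b,
                        min_count = 1)
    cons <- res$conservation
    expect_equal(cons$assigned + cons$unassigned + cons$unmapped,
                 cons$total_used)
    # with unambiguous mapping the isomiR total equals the assigned total
    expect_equal(cons$isomir_total, cons$assigned)
  }
})
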