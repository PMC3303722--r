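test_that("identical seed and config give byte-identical outputs", {
  cfg <- sim_config(n_hairpins = 4, library_depth = c(500, 500), seed = 91)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(simulate_libraries(cfg), d1)
  write_simulation(simulate_libraries(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  # a different seed changes the reads
  cfg2 <- sim_config(n_hairpins = 4, library_depth = c(500, 500), seed = 92)
  sim2 <- simulate_libraries(cfg2)
  sim1 <- simulate_libraries(cfg)
  expect_false(identical(sim1$lib_a, sim2$lib_a))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(100)
  before <- stats::runif(1)
  set.seed(100)
  invisible(simulate_libraries(sim_config(n_hairpins = 2,
                                          library_depth = c(50, 50))))
  expect_identical(stats::runif(1), before)
})

test_that("infeasible configurations are rejected before generation", {
  expect_error(sim_config(mature_length = c(19L, 19L)), "18 nt mapping floor")
  expect_error(sim_config(mature_length = c(23L, 23L)), "25 nt length filter")
  expect_error(sim_config(hairpin_length = c(40L, 50L)), "two mature spans")
  op <- default_offset_probs(); op$prob[1] <- op$prob[1] + 0.1
  expect_error(sim_config(isomir_offset_probs = op), "sum to 1")
  op <- default_offset_probs(); op$start_offset[1] <- 3L
  expect_error(sim_config(isomir_offset_probs = op), "mapper windows")
})

test_that("zero depth yields empty read sets but a valid reference", {
  sim <- simulate_libraries(sim_config(n_hairpins = 2,
                                       library_depth = c(0, 0)))
  expect_equal(nrow(sim$lib_a), 0L)
  expect_equal(nrow(sim$lib_b), 0L)
  expect_equal(nrow(sim$hairpins), 2L)
  expect_equal(nrow(sim$annotations_full), 4L)
})

test_that("every emitted read's origin re-extracts from its hairpin", {
  sim <- simulate_libraries(sim_config(n_hairpins = 6,
                                       library_depth = c(800, 800),
                                       seed = 93))
  gt <- sim$ground_truth$reads_a
  ann <- sim$annotations_full
  for (i in seq_len(nrow(gt))) {
    a <- ann[ann$premirna_id == gt$premirna_id[i] & ann$arm == gt$arm[i], ]
    hseq <- sim$hairpins$sequence[sim$hairpins$id == gt$premirna_id[i]]
    core <- substr(hseq, a$start + gt$start_offset[i],
                   a$end + gt$end_offset[i])
    expect_identical(gt$sequence[i], paste0(core, gt$fragment[i]))
  }
})

test_that("hairpins share no 18-mer, making mapping unambiguous", {
  sim <- simulate_libraries(sim_config(n_hairpins = 12, seed = 94,
                                       library_depth = c(0, 0)))
  env <- asNamespace("isomirarm")
  all_kmers <- unlist(lapply(sim$hairpins$sequence, env$kmers))
  expect_false(anyDuplicated(all_kmers) > 0)
})

test_that("the mapper recovers at least 99% of simulated origins", {
  sim <- simulate_libraries(sim_config(n_hairpins = 10,
                                       library_depth = c(2000, 2000),
                                       seed = 95))
  lib <- collapse_and_filter(sim$lib_a, min_count = 1L)
  mp <- map_library(lib, sim$hairpins)
  gt <- sim$ground_truth$reads_a
  ann <- sim$annotations_full
  gt_key <- paste(gt$premirna_id,
                  ann$start[match(paste(gt$premirna_id, gt$arm),
                                  paste(ann$premirna_id, ann$arm))] +
                    gt$start_offset,
                  gt$fragment)
  got_key <- paste(mp$mapped$premirna_id, mp$mapped$map_start,
                   mp$mapped$trimmed_fragment)
  ok <- got_key[match(gt$sequence, mp$mapped$sequence)] == gt_key
  expect_gte(mean(ok, na.rm = TRUE), 0.99)
  expect_lte(mean(is.na(ok)), 0.01)
})

test_that("planted arm ratios and switches are recovered end-to-end", {
  cfg <- sim_config(n_hairpins = 8, library_depth = c(10000, 10000),
                    arm_ratio_a = 2, arm_ratio_b = 0.5, seed = 96)
  sim <- simulate_libraries(cfg)
  res <- run_pipeline(sim$hairpins, sim$annotations, sim$lib_a, sim$lib_b)
  # every hairpin switches from 5p-major to 3p-major
  expect_true(all(res$consistency$tissue_switch))
  rep <- recovery_report(sim, res)
  ratios <- rep[grepl("arm_ratio", rep$metric), ]
  expect_true(all(ratios$pass))
  expect_true(all(rep$pass[rep$metric %in% c("isomir_tv_a", "isomir_tv_b")]))
})
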