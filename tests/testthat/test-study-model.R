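test_that("study design validates phase structure and ordering", {
  d <- study_design(2, c("A", "B"), day_grid = c(9, 11, 14, 20, 24, 30))
  expect_s3_class(d, "study_design")
  expect_identical(phase_of(d, c(9, 14, 23, 24)),
                   c("pre", "treatment", "treatment", "post"))
  expect_error(study_design(2, "A", day_grid = c(9, 9, 14, 24)),
               "strictly increasing")
  expect_error(study_design(2, "A", day_grid = c(9, 11, 24),
                            treatment_start = 14, treatment_end = 23),
               "empty.*treatment")
  expect_error(study_design(2, "A", day_grid = c(14, 20, 24),
                            baseline_day = 15, treatment_start = 14),
               "baseline_day < treatment_start")
})

test_that("read_counts parses valid TSVs and reports offending cells", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_counts(f)
  ct <- read_counts(f)
  expect_identical(ct$total_reads, c(10L, 20L, 30L))
  expect_identical(ct$taxa, c("taxA", "taxB"))
  expect_identical(ct$sample_id, c("s1", "s2", "s3"))

  # header only -> zero samples
  writeLines("sample_id\ttaxA\ttaxB", f)
  expect_identical(nrow(read_counts(f)$counts), 0L)

  write_tiny_counts(f, rows = c("s1\t4\t-1"))
  expect_error(read_counts(f), "s1.*taxB")
  write_tiny_counts(f, rows = c("s1\t4\t2.5"))
  expect_error(read_counts(f), "non-integer")
  write_tiny_counts(f, rows = c("s1\t4\t6", "s1\t1\t2"))
  expect_error(read_counts(f), "duplicate sample_id")
})

test_that("counts round-trip through write/read exactly", {
  sim <- simulate_study(synthetic_config(seed = 3))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_counts(sim$counts, f)
  back <- read_counts(f)
  expect_identical(back$counts, sim$counts$counts)
})

test_that("read_metadata enforces integer days and unique (mouse, day)", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_metadata(f, rows = c("s1\tm1\t9", "s2\tm1\t11"))
  meta <- read_metadata(f)
  expect_identical(nrow(meta), 2L)
  expect_type(meta$day, "integer")

  write_tiny_metadata(f, rows = c("s1\tm1\t9", "s2\tm1\t9"))
  expect_error(read_metadata(f), "duplicate \\(mouse_id, day\\)")
  write_tiny_metadata(f, rows = c("s1\tm1\t9.5"))
  expect_error(read_metadata(f), "not an integer day")
  writeLines(c("sample_id\tday", "s1\t9"), f)
  expect_error(read_metadata(f), "missing column.*mouse_id")
})

test_that("filter_min_reads drops strictly-below-threshold samples in order", {
  m <- matrix(c(5000L, 3999L, 4000L), ncol = 1,
              dimnames = list(c("s1", "s2", "s3"), "taxA"))
  ct <- count_table(m)
  kept <- filter_min_reads(ct, 4000)
  expect_identical(kept$sample_id, c("s1", "s3"))
  expect_identical(filter_min_reads(ct, 0)$sample_id, ct$sample_id)
  expect_identical(nrow(filter_min_reads(ct, 1e6)$counts), 0L)
})

test_that("to_relative normalizes rows and refuses zero-depth samples", {
  m <- matrix(c(2L, 2L, 0L, 5L), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("A", "B")))
  ab <- to_relative(count_table(m))
  expect_equal(ab$abundance["s1", ], c(A = 0.5, B = 0.5))
  expect_equal(ab$abundance["s2", ], c(A = 0, B = 1))
  expect_equal(unname(rowSums(ab$abundance)), c(1, 1), tolerance = 1e-9)

  mz <- matrix(c(0L, 0L), nrow = 1, dimnames = list("s1", c("A", "B")))
  expect_error(to_relative(count_table(mz)), "filter_min_reads")
})

test_that("filtered tables never divide by zero for threshold >= 1", {
  sim <- simulate_study(synthetic_config(seed = 11, depth_mean = 50,
                                         depth_dispersion = 0.5))
  ab <- to_relative(filter_min_reads(sim$counts, threshold = 1))
  expect_false(anyNA(ab$abundance))
  expect_equal(unname(rowSums(ab$abundance)), rep(1, nrow(ab$abundance)),
               tolerance = 1e-9)
})

test_that("extract_series uses available-case means over mice", {
  m <- matrix(c(20L, 80L, 40L, 60L, 30L, 70L), nrow = 3, byrow = TRUE,
              dimnames = list(c("a9", "b9", "a11"), c("A", "B")))
  ab <- to_relative(count_table(m))
  meta <- data.frame(sample_id = c("a9", "b9", "a11"),
                     mouse_id = c("m1", "m2", "m1"), day = c(9L, 9L, 11L))
  mean_ts <- extract_series(ab, meta, "A", "mean")
  expect_equal(mean_ts$value, c((0.2 + 0.4) / 2, 0.3))
  expect_equal(mean_ts$day, c(9L, 11L))
  # day 11 has only mouse m1 -> the mean equals m1's value
  m1_ts <- extract_series(ab, meta, "A", "m1")
  expect_equal(mean_ts$value[2], m1_ts$value[2])
  expect_error(extract_series(ab, meta, "nope", "mean"), "unknown taxon")
  expect_error(extract_series(ab, meta, "A", "m9"), "unknown mouse")
})

test_that("mean series equals the single-mouse series when n_mice = 1", {
  cfg <- synthetic_config(design = study_design(1, c("A", "B", "C"),
                                                day_grid = c(9, 11, 14, 20, 24, 30)),
                          baseline_composition = c(0.5, 0.3, 0.2),
                          templates = list(), seed = 5)
  sim <- simulate_study(cfg)
  ab <- to_relative(sim$counts)
  expect_equal(extract_series(ab, sim$metadata, "B", "mean")$value,
               extract_series(ab, sim$metadata, "B", "m1")$value)
})

test_that("design YAML reading applies defaults for missing keys", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("treatment_start: 10", "min_reads: 2000"), f)
  cfg <- read_design_config(f)
  expect_identical(cfg$treatment_start, 10L)
  expect_identical(cfg$min_reads, 2000L)
  expect_identical(cfg$baseline_day, 9L)
  expect_identical(cfg$end_day, 37L)
})
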