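test_that("the default design encodes the 37-day intervention study", {
  d <- default_study_design()
  expect_identical(d$n_mice, 6L)
  expect_length(d$taxa, 25L)
  expect_identical(d$baseline_day, 9L)
  expect_identical(d$treatment_end - d$treatment_start + 1L, 10L)
  expect_identical(d$end_day, 37L)
  # every-two-days backbone plus daily sampling around onset and offset
  expect_true(all(c(13:16, 22:26) %in% d$day_grid))
  expect_true(all(seq(9, 37, by = 2) %in% d$day_grid))
})

test_that("response templates validate their windows", {
  expect_error(response_template("early_transient", onset_day = 20,
                                 offset_day = 14), "offset_day > onset_day")
  expect_error(response_template("persistent"), "onset_day")
  tpl <- response_template("null")
  expect_identical(tpl$log2_effect, 0)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- synthetic_config(seed = 99)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$metadata, s2$metadata)
})

test_that("row sums of simulated counts equal the drawn depths", {
  sim <- simulate_study(synthetic_config(seed = 4))
  expect_identical(sim$counts$total_reads,
                   as.integer(rowSums(sim$counts$counts)))
  expect_true(all(sim$counts$total_reads > 0))
})

test_that("zero noise and large depth recover the configured composition", {
  cfg <- synthetic_config(noise_sigma = 0, templates = list(),
                          depth_mean = 1e6, depth_dispersion = 1e9, seed = 8)
  sim <- simulate_study(cfg)
  ab <- to_relative(sim$counts)
  target <- cfg$baseline_composition
  err <- sweep(ab$abundance, 2, target)
  expect_lt(max(abs(err)), 1e-2)
})

test_that("expected composition reflects planted effects exactly", {
  cfg <- synthetic_config(seed = 1)
  base <- expected_composition(cfg, 9)
  expect_equal(sum(base), 1, tolerance = 1e-12)
  expect_equal(unname(base), unname(cfg$baseline_composition),
               tolerance = 1e-12)
  # early transient at +2: unnormalized level x4 on effect days
  during <- expected_composition(cfg, 15)
  u_ratio <- (during[["Escherichia_coli"]] / base[["Escherichia_coli"]])
  # ratio of relative abundances is 4 / renormalization; recompute directly
  u <- cfg$baseline_composition
  u["Escherichia_coli"] <- u["Escherichia_coli"] * 4
  u["Clostridium_ramosum"] <- u["Clostridium_ramosum"] * 4
  u["Bacteroides_vulgatus"] <- u["Bacteroides_vulgatus"] / 4
  u["Bacteroides_fragilis"] <- u["Bacteroides_fragilis"] / 4
  u["Enterococcus_faecalis"] <- u["Enterococcus_faecalis"] / 4
  u["Klebsiella_oxytoca"] <- u["Klebsiella_oxytoca"] * 4
  u["Proteus_mirabilis"] <- u["Proteus_mirabilis"] / 4
  expect_equal(unname(during), unname(u / sum(u)), tolerance = 1e-12)
})

test_that("ground truth lists the planted changepoint days and calls", {
  sim <- simulate_study(synthetic_config(seed = 1))
  tr <- sim$truth
  early <- tr[tr$taxon == "Escherichia_coli", ]
  expect_identical(early$changepoint_days[[1]], c(14L, 20L))
  expect_identical(early$n_response, 1L)
  expect_identical(early$n_recovery, 1L)
  expect_identical(early$direction, "up")
  pers <- tr[tr$kind == "persistent", ]
  expect_true(all(pers$n_recovery == 0L) && all(pers$n_response == 1L))
  nulls <- tr[tr$kind == "null", ]
  expect_true(all(nulls$n_response == 0L) && all(nulls$direction == "none"))
})

test_that("templates referencing unknown taxa are rejected", {
  expect_error(
    synthetic_config(templates = list(
      not_a_taxon = response_template("persistent", onset_day = 14))),
    "unknown taxa")
})

test_that("dropout removes scheduled samples but never the baseline day", {
  cfg <- synthetic_config(dropout_prob = 0.3, seed = 21)
  sim <- simulate_study(cfg)
  n_sched <- cfg$design$n_mice * length(cfg$design$day_grid)
  expect_lt(nrow(sim$metadata), n_sched)
  base <- sim$metadata[sim$metadata$day == cfg$design$baseline_day, ]
  expect_identical(nrow(base), cfg$design$n_mice)
})

sim_truth_row <- function(cfg, tx) {
  tpl <- cfg$templates[[tx]]
  kind <- if (is.null(tpl)) "null" else tpl$kind
  list(n_response = if (kind == "null") 0L else 1L,
       n_recovery = if (kind %in% c("early_transient", "late_transient"))
         1L else 0L)
}

test_that("classification of noise-free mean series matches ground truth", {
  cfg <- synthetic_config(seed = 1)
  design <- cfg$design
  for (i in seq_along(design$taxa)) {
    tx <- design$taxa[i]
    vals <- vapply(design$day_grid,
                   function(d) expected_composition(cfg, d)[[tx]], numeric(1))
    ts <- structure(data.frame(day = design$day_grid, value = vals),
                    class = c("taxon_series", "data.frame"),
                    taxon = tx, mouse = "mean")
    res <- microresil:::call_one_series(ts, NULL, 2L, 0.5, 0.005)
    tr <- sim_truth_row(cfg, tx)
    expect_identical(res$call$n_response, tr$n_response, label = tx)
    expect_identical(res$call$n_recovery, tr$n_recovery, label = tx)
  }
})

test_that("write_study emits readable counts, metadata and truth files", {
  dir <- withr::local_tempdir()
  sim <- simulate_study(synthetic_config(seed = 2))
  write_study(sim, dir)
  expect_identical(read_counts(file.path(dir, "counts.tsv"))$counts,
                   sim$counts$counts)
  expect_identical(read_metadata(file.path(dir, "metadata.tsv"))$sample_id,
                   sim$metadata$sample_id)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_length(truth, 25L)
})
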