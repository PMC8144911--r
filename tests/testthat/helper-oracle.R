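# Exhaustive-enumeration oracle for K-segment least-squares segmentation.
# Enumerates all C(n-1, K-1) placements of K-1 boundaries and scores each
# candidate directly from segment means — independent of the DP under test.
brute_force_segmentation <- function(y, K, min_seg_len = 1L) {
  n <- length(y)
  seg_ss <- function(s, e) {
    v <- y[s:e]
    sum((v - mean(v))^2)
  }
  if (K == 1) {
    return(list(cost = seg_ss(1, n), changepoints = integer(0)))
  }
  best <- Inf
  best_cps <- NULL
  splits <- utils::combn(n - 1, K - 1)
  for (ci in seq_len(ncol(splits))) {
    b <- splits[, ci]
    starts <- c(1L, b + 1L)
    ends <- c(b, n)
    if (any(ends - starts + 1L < min_seg_len)) next
    cost <- sum(mapply(seg_ss, starts, ends))
    if (cost < best) {
      best <- cost
      best_cps <- b + 1L  # first index of each new segment
    }
  }
  list(cost = best, changepoints = best_cps)
}

# Small deterministic 3-sample x 2-taxon counts TSV.
write_tiny_counts <- function(path, rows = NULL) {
  if (is.null(rows)) {
    rows <- c("s1\t4\t6", "s2\t12\t8", "s3\t10\t20")
  }
  writeLines(c("sample_id\ttaxA\ttaxB", rows), path)
}

write_tiny_metadata <- function(path, rows = NULL) {
  if (is.null(rows)) {
    rows <- c("s1\tm1\t9", "s2\tm1\t11", "s3\tm1\t14")
  }
  writeLines(c("sample_id\tmouse_id\tday", rows), path)
}

# Small two-mouse study whose composition steps 0.8/0.2 -> 0.4/0.6 during
# treatment: Bray-Curtis distance to baseline is exactly 0.4 in-treatment.
step_study <- function() {
  design <- study_design(n_mice = 2, taxa = c("dom", "rest"),
                         day_grid = c(9, 11, 14, 20, 24, 30),
                         baseline_day = 9, treatment_start = 14,
                         treatment_end = 23, end_day = 37)
  comp <- function(day) if (day >= 14 && day <= 23) c(0.4, 0.6) else c(0.8, 0.2)
  rows <- list()
  meta <- list()
  for (m in c("m1", "m2")) {
    for (d in design$day_grid) {
      sid <- paste0(m, "_d", d)
      rows[[sid]] <- as.integer(comp(d) * 1000)
      meta[[sid]] <- data.frame(sample_id = sid, mouse_id = m, day = d)
    }
  }
  counts <- do.call(rbind, rows)
  dimnames(counts) <- list(names(rows), design$taxa)
  list(design = design, counts = count_table(counts),
       metadata = do.call(rbind, meta))
}
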