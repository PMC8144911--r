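#' Classify a segmentation into response/recovery counts
#'
#' The pre-treatment level is the first segment's mean, `m1`. Walking the
#' changepoints in order, a changepoint is a *response* when the new segment
#' moves away from (or ties with) the current distance to `m1`
#' (`|m[k+1] - m1| >= |m[k] - m1|`), and a *recovery* when it moves back
#' toward `m1`. The direction is the sign of the first shift (`m2 - m1`),
#' matching the single arrow reported per series. A single-segment
#' (degenerate) input yields 0/0 with direction "none".
#'
#' @param seg a `segmentation` (see [best_segmentation()]), or any list with
#'   a `segment_means` element.
#' @return an object of class `response_recovery_call`: list with
#'   `n_response`, `n_recovery`, `direction` (`"up"`, `"down"` or `"none"`)
#'   and `formatted` (e.g. `"1/1 (↑)"`).
#' @examples
#' classify_segmentation(list(segment_means = c(0.1, 0.4, 0.12)))  # 1/1 up
#' @export
classify_segmentation <- function(seg) {
  m <- seg$segment_means
  K <- length(m)
  n_response <- 0L
  n_recovery <- 0L
  if (K >= 2) {
    dev <- abs(m - m[1])
    for (k in seq_len(K - 1)) {
      if (dev[k + 1] >= dev[k]) n_response <- n_response + 1L
      else n_recovery <- n_recovery + 1L
    }
  }
  direction <- if (K < 2 || m[2] == m[1]) "none"
               else if (m[2] > m[1]) "up" else "down"
  if (n_response == 0L) direction <- "none"
  new_rr_call(n_response, n_recovery, direction)
}

new_rr_call <- function(n_response, n_recovery, direction,
                        flag = NA_character_) {
  arrow <- switch(direction, up = " (\u2191)", down = " (\u2193)", "")
  structure(
    list(n_response = as.integer(n_response),
         n_recovery = as.integer(n_recovery),
         direction = direction,
         formatted = sprintf("%d/%d%s", n_response, n_recovery, arrow),
         flag = flag),
    class = "response_recovery_call"
  )
}

#' @export
print.response_recovery_call <- function(x, ...) {
  cat(x$formatted, "\n")
  invisible(x)
}

#' Merge biologically negligible mean shifts
#'
#' Knee-selected segmentations can include statistically real but tiny mean
#' shifts — compositional spill-over from other taxa's responses, or small
#' wiggles split off a genuine segment. Before classification these are
#' collapsed: adjacent segments whose means differ by less than a floor are
#' merged (smallest difference first, means recombined length-weighted) until
#' every remaining shift clears the floor. The floor is
#' `max(min_rel_change * |m1|, min_abs_change)` with `m1` the pre-treatment
#' (first-segment) mean, so calls require a shift of biologically meaningful
#' size relative to the taxon's own baseline level.
#'
#' @param seg a `segmentation`.
#' @param min_rel_change floor as a fraction of the pre-treatment level
#'   (default 0.5, i.e. a 1.5-fold deviation).
#' @param min_abs_change absolute floor on the relative-abundance scale
#'   (default 0.005).
#' @return a list with `segment_means`, `changepoints` (indices retained from
#'   `seg`) and `K` after merging.
#' @export
merge_small_shifts <- function(seg, min_rel_change = 0.5,
                               min_abs_change = 0.005) {
  m <- seg$segment_means
  len <- segment_lengths(seg)
  cps <- seg$changepoints
  floor_abs <- max(min_rel_change * abs(m[1]), min_abs_change)
  while (length(m) > 1) {
    d <- abs(diff(m))
    if (all(d >= floor_abs)) break
    k <- which.min(d)  # merge the most negligible boundary first
    m[k] <- (m[k] * len[k] + m[k + 1] * len[k + 1]) / (len[k] + len[k + 1])
    len[k] <- len[k] + len[k + 1]
    m <- m[-(k + 1)]
    len <- len[-(k + 1)]
    cps <- cps[-k]
  }
  list(segment_means = m, changepoints = cps, K = length(m))
}

#' Per-series response/recovery report
#'
#' Runs the full changepoint workflow — [detect_changepoints()], optional
#' [merge_small_shifts()], [classify_segmentation()] — for every taxon in
#' every mouse plus the across-mouse mean series, and lays the calls out as
#' one row per taxon with one column per mouse and a final `Mean` column,
#' each cell formatted `"n/m (↑|↓)"`. Series too short for knee
#' selection are reported as `0/0` with an `insufficient_data` flag.
#'
#' @param ab an `abundance_table`.
#' @param meta metadata data.frame.
#' @param design a [study_design()].
#' @param taxa taxa to report (default: all in `ab`).
#' @param K_max,min_seg_len passed to [detect_changepoints()].
#' @param min_rel_change,min_abs_change effect-size floor for
#'   [merge_small_shifts()]; set `min_rel_change = 0` and
#'   `min_abs_change = 0` to disable merging.
#' @return an object of class `response_report`: list with `table` (the
#'   formatted taxon x mouse data.frame) and `calls` (long data.frame with
#'   one row per taxon x series: n_response, n_recovery, direction, K_opt,
#'   changepoint days, degenerate and flag columns).
#' @export
response_report <- function(ab, meta, design, taxa = NULL, K_max = NULL,
                            min_seg_len = 2L, min_rel_change = 0.5,
                            min_abs_change = 0.005) {
  stopifnot(inherits(ab, "abundance_table"), inherits(design, "study_design"))
  if (is.null(taxa)) taxa <- ab$taxa
  mice <- unique(meta$mouse_id[meta$sample_id %in% ab$sample_id])
  series_ids <- c(mice, "mean")

  calls <- list()
  for (tx in taxa) {
    for (sid in series_ids) {
      ts <- extract_series(ab, meta, tx, mouse = sid)
      res <- call_one_series(ts, K_max, min_seg_len, min_rel_change,
                             min_abs_change)
      calls[[length(calls) + 1]] <- data.frame(
        taxon = tx, series = sid,
        n_response = res$call$n_response, n_recovery = res$call$n_recovery,
        direction = res$call$direction, formatted = res$call$formatted,
        K_opt = res$K_opt, degenerate = res$degenerate,
        changepoint_days = paste(res$changepoint_days, collapse = ","),
        flag = res$flag
      )
    }
  }
  calls <- do.call(rbind, calls)
  wide <- data.frame(taxon = taxa)
  for (sid in series_ids) {
    col <- if (sid == "mean") "Mean" else sid
    wide[[col]] <- calls$formatted[match(paste(taxa, sid),
                                         paste(calls$taxon, calls$series))]
  }
  structure(list(table = wide, calls = calls), class = "response_report")
}

call_one_series <- function(ts, K_max, min_seg_len, min_rel_change,
                            min_abs_change) {
  n <- nrow(ts)
  k_need <- if (is.null(K_max)) 4L else as.integer(K_max)
  if (n < k_need * min_seg_len || n < 4L * min_seg_len) {
    return(list(call = new_rr_call(0L, 0L, "none", flag = "insufficient_data"),
                K_opt = NA_integer_, degenerate = NA,
                changepoint_days = integer(0), flag = "insufficient_data"))
  }
  det <- detect_changepoints(ts, K_max = K_max, min_seg_len = min_seg_len)
  seg <- det$segmentation
  cps_days <- det$changepoint_days
  if (!det$elbow$degenerate &&
      (min_rel_change > 0 || min_abs_change > 0)) {
    merged <- merge_small_shifts(seg, min_rel_change, min_abs_change)
    keep <- match(merged$changepoints, seg$changepoints)
    cps_days <- cps_days[keep]
    seg <- merged
  }
  cl <- classify_segmentation(seg)
  if (cl$n_response == 0L) cps_days <- integer(0)
  list(call = cl, K_opt = det$elbow$K_opt, degenerate = det$elbow$degenerate,
       changepoint_days = cps_days, flag = NA_character_)
}

#' @export
print.response_report <- function(x, ...) {
  cat("Response/recovery report (cells: n_response/n_recovery (direction))\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
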