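#' Bray-Curtis dissimilarity between two compositions
#'
#' `sum(|x_i - y_i|) / sum(x_i + y_i)`: 0 for identical vectors, 1 for
#' disjoint support. The workhorse of community-level resilience analysis —
#' each sample is compared against the same mouse's pre-treatment baseline.
#'
#' @param x,y non-negative numeric vectors of equal length, not both all-zero.
#' @return dissimilarity in \[0, 1\].
#' @examples
#' bray_curtis(c(0.8, 0.2), c(0.6, 0.4))  # 0.2
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have the same length", call. = FALSE)
  }
  if (any(x < 0) || any(y < 0)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both vectors are all-zero", call. = FALSE)
  sum(abs(x - y)) / tot
}

#' Distance-to-baseline resilience trajectory
#'
#' For every mouse, computes the Bray-Curtis distance of each sample to that
#' mouse's own baseline-day sample, then summarizes each day across mice by
#' the mean, the standard error of the mean (`sd / sqrt(n)`, reported only for
#' `n >= 2`), and a two-sided paired t-test of the day's distances against
#' each mouse's mean distance over the remaining pre-treatment days. The
#' paired-against-pre construction avoids the degenerate one-sample test
#' against zero (distances are non-negative by construction).
#'
#' @param ab an `abundance_table` (see [to_relative()]).
#' @param meta metadata data.frame (`sample_id`, `mouse_id`, `day`).
#' @param design a [study_design()].
#' @param adjust_p apply Benjamini-Hochberg correction across days
#'   (default `FALSE`).
#' @return an object of class `distance_trajectory`: list with `distances`
#'   (data.frame: mouse_id, day, distance) and `summary` (data.frame: day,
#'   n, mean, sem, p_value, and `p_adj` if requested).
#' @export
baseline_distance_trajectory <- function(ab, meta, design, adjust_p = FALSE) {
  stopifnot(inherits(ab, "abundance_table"), inherits(design, "study_design"))
  meta <- meta[match(ab$sample_id, meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) {
    stop("metadata is missing sample(s) present in the abundance table",
         call. = FALSE)
  }
  mice <- unique(meta$mouse_id)
  base_row <- vapply(mice, function(m) {
    hit <- which(meta$mouse_id == m & meta$day == design$baseline_day)
    if (length(hit) == 0) {
      stop("mouse '", m, "' has no sample at baseline day ",
           design$baseline_day, call. = FALSE)
    }
    hit[1]
  }, integer(1))

  dist <- vapply(seq_len(nrow(ab$abundance)), function(i) {
    b <- base_row[[meta$mouse_id[i]]]
    bray_curtis(ab$abundance[i, ], ab$abundance[b, ])
  }, numeric(1))
  distances <- data.frame(mouse_id = meta$mouse_id, day = meta$day,
                          distance = dist)
  distances <- distances[order(distances$mouse_id, distances$day), ]
  rownames(distances) <- NULL

  pre_days <- setdiff(design$day_grid[phase_of(design, design$day_grid) == "pre"],
                      design$baseline_day)
  days <- sort(unique(distances$day))
  summ <- do.call(rbind, lapply(days, function(d) {
    dd <- distances[distances$day == d, ]
    n <- nrow(dd)
    m <- mean(dd$distance)
    sem <- if (n >= 2) stats::sd(dd$distance) / sqrt(n) else NA_real_
    ref_days <- setdiff(pre_days, d)
    ref <- vapply(dd$mouse_id, function(ms) {
      r <- distances$distance[distances$mouse_id == ms &
                                distances$day %in% ref_days]
      if (length(r) == 0) NA_real_ else mean(r)
    }, numeric(1))
    p <- paired_pvalue(dd$distance, ref)
    data.frame(day = d, n = n, mean = m, sem = sem, p_value = p)
  }))
  if (adjust_p) summ$p_adj <- stats::p.adjust(summ$p_value, method = "BH")
  rownames(summ) <- NULL
  structure(list(distances = distances, summary = summ),
            class = "distance_trajectory")
}

# two-sided paired t-test p-value with degenerate-case handling
paired_pvalue <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  d <- a[ok] - b[ok]
  if (length(d) < 2) return(NA_real_)
  if (all(d == 0)) return(1)
  if (stats::sd(d) == 0) return(0)
  stats::t.test(d)$p.value
}

#' @export
print.distance_trajectory <- function(x, ...) {
  cat("Bray-Curtis distance-to-baseline trajectory:",
      length(unique(x$distances$mouse_id)), "mice,",
      length(unique(x$distances$day)), "days\n")
  print(utils::head(x$summary, 5))
  if (nrow(x$summary) > 5) cat("  ...", nrow(x$summary) - 5, "more days\n")
  invisible(x)
}
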