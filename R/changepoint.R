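#' Within-segment sum of squared deviations
#'
#' The least-squares cost of fitting one constant mean to `series[i..j]`:
#' `sum((y_t - mean(y_i..y_j))^2)`. This is the cost the segmentation
#' minimizes, the canonical criterion for detecting changes in means. Inside
#' the dynamic program it is evaluated in O(1) from prefix sums of `y` and
#' `y^2`; this exported form recomputes the prefixes per call.
#'
#' @param series numeric vector.
#' @param i,j 1-based inclusive segment bounds, `i <= j`.
#' @return non-negative scalar cost.
#' @examples
#' segment_cost(c(3, 3, 3), 1, 3)  # 0
#' segment_cost(c(0, 2), 1, 2)     # 2
#' @export
segment_cost <- function(series, i, j) {
  n <- length(series)
  stopifnot(i >= 1, j <= n)
  if (i > j) stop("segment start i must not exceed end j", call. = FALSE)
  cs <- prefix_sums(as.numeric(series))
  seg_cost_prefix(cs, i, j)
}

prefix_sums <- function(y) {
  list(s1 = c(0, cumsum(y)), s2 = c(0, cumsum(y * y)))
}

seg_cost_prefix <- function(cs, i, j) {
  s <- cs$s1[j + 1] - cs$s1[i]
  q <- cs$s2[j + 1] - cs$s2[i]
  # clamp tiny negative round-off
  pmax(q - s * s / (j - i + 1), 0)
}

# Bellman dynamic program over segment counts 1..k_max.
# Jm[k, j] = minimal cost of splitting y[1..j] into k segments of length
# >= min_seg_len; arg[k, j] = start index of the k-th segment at the optimum
# (first minimum, i.e. earliest feasible changepoint on ties).
dp_engine <- function(y, k_max, min_seg_len) {
  n <- length(y)
  cs <- prefix_sums(y)
  Jm <- matrix(Inf, nrow = k_max, ncol = n)
  arg <- matrix(NA_integer_, nrow = k_max, ncol = n)
  for (j in seq_len(n)) {
    if (j >= min_seg_len) Jm[1, j] <- seg_cost_prefix(cs, 1, j)
  }
  if (k_max >= 2) {
    for (k in 2:k_max) {
      jmin <- k * min_seg_len
      if (jmin > n) break
      for (j in jmin:n) {
        i <- ((k - 1) * min_seg_len + 1):(j - min_seg_len + 1)
        tot <- Jm[k - 1, i - 1] + seg_cost_prefix(cs, i, j)
        b <- which.min(tot)  # first minimum -> earliest changepoint
        Jm[k, j] <- tot[b]
        arg[k, j] <- i[b]
      }
    }
  }
  list(J = Jm, arg = arg, cs = cs, n = n)
}

dp_backtrack <- function(dp, k) {
  cps <- integer(0)
  j <- dp$n
  if (k >= 2) {
    for (kk in k:2) {
      i <- dp$arg[kk, j]
      cps <- c(i, cps)
      j <- i - 1
    }
  }
  starts <- c(1L, cps)
  ends <- c(cps - 1L, dp$n)
  means <- (dp$cs$s1[ends + 1] - dp$cs$s1[starts]) / (ends - starts + 1)
  list(changepoints = as.integer(cps), segment_means = as.numeric(means),
       cost = Jm_cost(dp, k))
}

Jm_cost <- function(dp, k) dp$J[k, dp$n]

#' Optimal K-segment mean-shift segmentation
#'
#' Finds the globally cost-minimal partition of a series into exactly `K`
#' contiguous segments, where each segment is scored by its within-segment sum
#' of squared deviations from the segment mean ([segment_cost()]). The
#' optimum is found by the Bellman dynamic-programming recursion
#' `J(k, j) = min_i { J(k-1, i-1) + cost(i, j) }` in `O(K n^2)` time. Ties in
#' cost resolve to the earliest feasible changepoint positions, so output is
#' deterministic.
#'
#' @param series numeric vector (or `taxon_series`).
#' @param K number of segments (>= 1).
#' @param min_seg_len minimum points per segment (default 2; a one-point
#'   spike is not a segment).
#' @return an object of class `segmentation`: list with `K`, `changepoints`
#'   (1-based index of the first point of each new segment, length `K - 1`),
#'   `segment_means`, `cost`, `n` and `min_seg_len`.
#' @examples
#' best_segmentation(c(1, 1, 1, 9, 9, 9), K = 2)
#' @export
best_segmentation <- function(series, K, min_seg_len = 2L) {
  y <- as_series_values(series)
  n <- length(y)
  K <- as.integer(K)
  min_seg_len <- as.integer(min_seg_len)
  stopifnot(K >= 1L, min_seg_len >= 1L)
  if (K * min_seg_len > n) {
    stop(sprintf("infeasible segmentation: K * min_seg_len = %d exceeds series length %d",
                 K * min_seg_len, n), call. = FALSE)
  }
  dp <- dp_engine(y, K, min_seg_len)
  bt <- dp_backtrack(dp, K)
  new_segmentation(K, bt$changepoints, bt$segment_means, bt$cost, n,
                   min_seg_len)
}

new_segmentation <- function(K, changepoints, segment_means, cost, n,
                             min_seg_len) {
  structure(
    list(K = as.integer(K), changepoints = as.integer(changepoints),
         segment_means = segment_means, cost = as.numeric(cost),
         n = as.integer(n), min_seg_len = as.integer(min_seg_len)),
    class = "segmentation"
  )
}

#' @export
print.segmentation <- function(x, ...) {
  cat("Segmentation: K =", x$K, "segments over", x$n, "points; cost =",
      signif(x$cost, 6), "\n")
  if (x$K > 1) cat("  changepoints at positions:",
                   paste(x$changepoints, collapse = ", "), "\n")
  cat("  segment means:", paste(signif(x$segment_means, 4), collapse = ", "),
      "\n")
  invisible(x)
}

segment_lengths <- function(seg) {
  diff(c(1L, seg$changepoints, seg$n + 1L))
}

as_series_values <- function(series) {
  if (inherits(series, "taxon_series")) as.numeric(series$value)
  else as.numeric(series)
}

#' Knee-point selection of the number of segments
#'
#' Computes the elbow curve `J(K)` of minimal segmentation costs for
#' `K = 1..K_max` and selects the knee `K_opt` as the maximum-curvature point,
#' with curvature approximated by the central second difference
#' `D2(K) = J(K-1) - 2 J(K) + J(K+1)`. The search range is `K` in
#' `[2, K_max - 1]` (`J(1)` only anchors the central difference at `K = 2`);
#' curvature ties resolve to the smallest `K`. A series whose one-segment
#' cost is (numerically) zero carries no changepoint information and is
#' flagged degenerate.
#'
#' @inheritParams best_segmentation
#' @param K_max largest segment count to score (>= 4 so the knee search range
#'   is non-degenerate).
#' @return an object of class `elbow_selection`: list with `costs` (`J(K)`,
#'   `K = 1..K_max`), `curvature` (`D2(K)`, `K = 2..K_max-1`, named), `K_opt`
#'   (`NA` when degenerate) and `degenerate` (logical).
#' @examples
#' y <- rep(c(1, 9, 1), each = 5)
#' elbow_select(y, K_max = 6, min_seg_len = 2)$K_opt  # 3
#' @export
elbow_select <- function(series, K_max, min_seg_len = 2L) {
  y <- as_series_values(series)
  n <- length(y)
  K_max <- as.integer(K_max)
  min_seg_len <- as.integer(min_seg_len)
  stopifnot(min_seg_len >= 1L)
  if (K_max < 4L) stop("K_max must be at least 4", call. = FALSE)
  if (K_max * min_seg_len > n) {
    stop(sprintf("series too short (n = %d) for K_max = %d with min_seg_len = %d; reduce K_max",
                 n, K_max, min_seg_len), call. = FALSE)
  }
  dp <- dp_engine(y, K_max, min_seg_len)
  costs <- vapply(seq_len(K_max), function(k) Jm_cost(dp, k), numeric(1))
  ks <- 2:(K_max - 1)
  curvature <- costs[ks - 1] - 2 * costs[ks] + costs[ks + 1]
  names(curvature) <- ks
  tol <- 1e-12 * (1 + sum(y * y))
  degenerate <- costs[1] <= tol
  K_opt <- if (degenerate) NA_integer_ else ks[which.max(curvature)]
  structure(
    list(costs = costs, curvature = curvature, K_opt = K_opt,
         degenerate = degenerate, K_max = K_max, min_seg_len = min_seg_len),
    class = "elbow_selection"
  )
}

#' @export
print.elbow_selection <- function(x, ...) {
  if (x$degenerate) {
    cat("Elbow selection: degenerate series, no change detected\n")
  } else {
    cat("Elbow selection: K_opt =", x$K_opt, "(K_max =", x$K_max, ")\n")
  }
  cat("  J(K):", paste(signif(x$costs, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Detect changepoints in a taxon's time series
#'
#' Runs [elbow_select()] to pick the number of segments, then
#' [best_segmentation()] at `K_opt`. Changepoint positions are reported both
#' as 1-based indices and as days (the day of the first sample of the new
#' segment) when the input is a `taxon_series` carrying days. A degenerate
#' (flat) series yields the single-segment result with no changepoints.
#'
#' @param series a `taxon_series` (see [extract_series()]) or numeric vector.
#' @param K_max largest segment count scored; default
#'   `min(8, floor(n / min_seg_len))`.
#' @param min_seg_len minimum points per segment (default 2).
#' @return list with elements `elbow` (an `elbow_selection`), `segmentation`
#'   (at `K_opt`, or `K = 1` when degenerate) and `changepoint_days` (integer
#'   days; `NA` when the series has no day information).
#' @export
detect_changepoints <- function(series, K_max = NULL, min_seg_len = 2L) {
  y <- as_series_values(series)
  n <- length(y)
  min_seg_len <- as.integer(min_seg_len)
  if (is.null(K_max)) K_max <- min(8L, n %/% min_seg_len)
  K_max <- as.integer(K_max)
  if (K_max < 4L || K_max * min_seg_len > n) {
    stop(sprintf("series too short (n = %d) for knee selection with K_max = %d, min_seg_len = %d; use a smaller K_max or min_seg_len",
                 n, K_max, min_seg_len), call. = FALSE)
  }
  elbow <- elbow_select(y, K_max = K_max, min_seg_len = min_seg_len)
  seg <- if (elbow$degenerate) {
    best_segmentation(y, K = 1L, min_seg_len = min_seg_len)
  } else {
    best_segmentation(y, K = elbow$K_opt, min_seg_len = min_seg_len)
  }
  days <- if (inherits(series, "taxon_series")) as.integer(series$day)
          else rep(NA_integer_, n)
  list(elbow = elbow, segmentation = seg,
       changepoint_days = days[seg$changepoints])
}
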