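#' Per-mouse phase means of a taxon
#'
#' Averages one taxon's relative abundance over each mouse's samples within
#' each of the three a-priori phases (pre / treatment / post, taken from the
#' study design's treatment boundaries).
#'
#' @param ab an `abundance_table`.
#' @param meta metadata data.frame.
#' @param design a [study_design()].
#' @param taxon taxon label.
#' @return data.frame with one row per mouse and columns `mouse_id`, `pre`,
#'   `treatment`, `post`.
#' @export
interval_means <- function(ab, meta, design, taxon) {
  stopifnot(inherits(ab, "abundance_table"), inherits(design, "study_design"))
  if (!taxon %in% ab$taxa) stop("unknown taxon: ", taxon, call. = FALSE)
  meta <- meta[match(ab$sample_id, meta$sample_id), , drop = FALSE]
  phase <- phase_of(design, meta$day)
  vals <- ab$abundance[, taxon]
  mice <- unique(meta$mouse_id)
  out <- do.call(rbind, lapply(mice, function(m) {
    row <- list(mouse_id = m)
    for (ph in c("pre", "treatment", "post")) {
      v <- vals[meta$mouse_id == m & phase == ph]
      if (length(v) == 0) {
        stop("mouse '", m, "' has no sample in phase '", ph, "'",
             call. = FALSE)
      }
      row[[ph]] <- mean(v)
    }
    as.data.frame(row)
  }))
  rownames(out) <- NULL
  out
}

#' Paired t-test between two phases
#'
#' Two-sided paired t-test on per-mouse differences, the built-in stand-in
#' differential-abundance test for pipeline runs without external verdicts.
#' Degenerate inputs follow a fixed contract: identical vectors give
#' statistic 0 and p = 1; a constant non-zero difference (zero variance)
#' gives p = 0 with a `zero_variance` flag and is reported significant.
#'
#' @param means_a,means_b numeric vectors of per-mouse phase means, same mice
#'   in the same order, length >= 2.
#' @param alpha significance threshold (default 0.05).
#' @return list with `statistic`, `p_value`, `significant` and
#'   `zero_variance`.
#' @export
paired_interval_test <- function(means_a, means_b, alpha = 0.05) {
  if (length(means_a) != length(means_b)) {
    stop("phase mean vectors must cover the same mice", call. = FALSE)
  }
  if (length(means_a) < 2) {
    stop("need at least 2 mice for a paired test", call. = FALSE)
  }
  d <- means_a - means_b
  if (all(d == 0)) {
    return(list(statistic = 0, p_value = 1, significant = FALSE,
                zero_variance = FALSE))
  }
  if (stats::sd(d) == 0) {
    return(list(statistic = sign(d[1]) * Inf, p_value = 0,
                significant = TRUE, zero_variance = TRUE))
  }
  tt <- stats::t.test(d)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       significant = tt$p.value <= alpha, zero_variance = FALSE)
}

#' Two-of-three consensus over method verdicts
#'
#' A taxon is called significantly changed when at least two of the three
#' differential-abundance methods agree.
#'
#' @param verdicts logical vector of exactly three method verdicts.
#' @return single logical.
#' @examples
#' combine_consensus(c(TRUE, TRUE, FALSE))   # TRUE
#' combine_consensus(c(TRUE, FALSE, FALSE))  # FALSE
#' @export
combine_consensus <- function(verdicts) {
  if (length(verdicts) != 3 || !is.logical(verdicts) || anyNA(verdicts)) {
    stop("verdicts must be exactly three non-missing logicals", call. = FALSE)
  }
  sum(verdicts) >= 2
}

phase_pairs <- function() {
  list(c("pre", "treatment"), c("treatment", "post"), c("pre", "post"))
}

#' Predefined-window interval comparisons
#'
#' For every taxon and every phase pair (pre-vs-treatment, treatment-vs-post,
#' pre-vs-post), computes per-mouse phase means and the built-in paired
#' t-test ([paired_interval_test()]). The `method` column labels these rows
#' `"paired_t (stand-in)"` to make explicit that they substitute for external
#' differential-abundance tools only in self-contained runs.
#'
#' @inheritParams interval_means
#' @param taxa taxa to test (default: all).
#' @param alpha per-test significance threshold (default 0.05).
#' @return data.frame with columns `taxon`, `pair`, `mean_a`, `mean_b`,
#'   `statistic`, `p_value`, `significant`, `method`.
#' @export
interval_tests <- function(ab, meta, design, taxa = NULL, alpha = 0.05) {
  if (is.null(taxa)) taxa <- ab$taxa
  out <- list()
  for (tx in taxa) {
    pm <- interval_means(ab, meta, design, tx)
    for (pr in phase_pairs()) {
      res <- paired_interval_test(pm[[pr[1]]], pm[[pr[2]]], alpha = alpha)
      out[[length(out) + 1]] <- data.frame(
        taxon = tx, pair = paste(pr, collapse = "-vs-"),
        mean_a = mean(pm[[pr[1]]]), mean_b = mean(pm[[pr[2]]]),
        statistic = res$statistic, p_value = res$p_value,
        significant = res$significant, method = "paired_t (stand-in)"
      )
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read external method verdicts
#'
#' The three external differential-abundance methods (negative-binomial GLM,
#' voom-style linear model, compositional log-ratio test) are run outside
#' this package; their boolean verdicts enter as a TSV with columns `taxon`,
#' `pair`, `method`, `significant` (TRUE/FALSE).
#'
#' @param path path to the verdicts TSV.
#' @return data.frame with those four columns, `significant` logical.
#' @export
read_verdicts <- function(path) {
  if (!file.exists(path)) stop("verdicts file not found: ", path,
                               call. = FALSE)
  v <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("taxon", "pair", "method", "significant")
  miss <- setdiff(need, names(v))
  if (length(miss) > 0) {
    stop("verdicts TSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  v$significant <- as.logical(v$significant)
  if (anyNA(v$significant)) stop("verdicts must be TRUE/FALSE", call. = FALSE)
  v
}

#' Consensus calls per taxon and phase pair
#'
#' Combines three method verdicts per (taxon, pair) with the at-least-2-of-3
#' rule. Verdicts come either from an external table ([read_verdicts()]) or,
#' when none is supplied, from the built-in stand-in test replicated as the
#' sole method — in which case the output's `methods` column marks the run as
#' stand-in-only and the consensus equals that single verdict.
#'
#' @inheritParams interval_tests
#' @param verdicts optional data.frame from [read_verdicts()]; must contain
#'   exactly three methods per (taxon, pair).
#' @return data.frame with columns `taxon`, `pair`, `n_significant`,
#'   `consensus`, `methods`.
#' @export
consensus_calls <- function(ab, meta, design, taxa = NULL, verdicts = NULL,
                            alpha = 0.05) {
  if (is.null(taxa)) taxa <- ab$taxa
  if (is.null(verdicts)) {
    own <- interval_tests(ab, meta, design, taxa = taxa, alpha = alpha)
    out <- own[, c("taxon", "pair")]
    out$n_significant <- as.integer(own$significant)
    out$consensus <- own$significant
    out$methods <- "paired_t (stand-in only)"
    return(out)
  }
  keys <- unique(verdicts[, c("taxon", "pair")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- verdicts$taxon == keys$taxon[i] & verdicts$pair == keys$pair[i]
    v <- verdicts$significant[sel]
    if (length(v) != 3) {
      stop("need exactly three method verdicts for taxon '", keys$taxon[i],
           "', pair '", keys$pair[i], "'; got ", length(v), call. = FALSE)
    }
    data.frame(taxon = keys$taxon[i], pair = keys$pair[i],
               n_significant = sum(v), consensus = combine_consensus(v),
               methods = paste(sort(verdicts$method[sel]), collapse = ","))
  }))
  rownames(out) <- NULL
  out
}
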