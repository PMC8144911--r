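#' Describe a longitudinal perturbation study
#'
#' A study design captures the skeleton of a longitudinal intervention
#' experiment: which taxa are profiled, on which days samples are scheduled,
#' and where the treatment window sits. Days are integers; the experiment is
#' split into three phases: "pre" (`day < treatment_start`), "treatment"
#' (`treatment_start <= day <= treatment_end`) and "post"
#' (`day > treatment_end`). The baseline day anchors distance-to-baseline
#' trajectories and must fall in the pre phase.
#'
#' @param n_mice number of animals (>= 1).
#' @param taxa character vector of taxon labels (column order of count tables).
#' @param day_grid strictly increasing integer days on which sampling is
#'   scheduled.
#' @param baseline_day reference day for distance trajectories (default 9).
#' @param treatment_start first day of the intervention (default 14).
#' @param treatment_end last day of the intervention (default 23).
#' @param end_day last day of the experiment (default 37).
#' @return an object of class `study_design`.
#' @examples
#' d <- study_design(2, c("A", "B"), day_grid = c(9, 11, 14, 20, 24, 30))
#' phase_of(d, c(9, 14, 30))
#' @export
study_design <- function(n_mice, taxa, day_grid,
                         baseline_day = 9L, treatment_start = 14L,
                         treatment_end = 23L, end_day = 37L) {
  n_mice <- as.integer(n_mice)
  day_grid <- as.integer(day_grid)
  stopifnot(n_mice >= 1L, length(taxa) >= 1L, !anyDuplicated(taxa))
  if (any(diff(day_grid) <= 0L)) {
    stop("day_grid must be strictly increasing", call. = FALSE)
  }
  baseline_day <- as.integer(baseline_day)
  treatment_start <- as.integer(treatment_start)
  treatment_end <- as.integer(treatment_end)
  end_day <- as.integer(end_day)
  if (!(baseline_day < treatment_start && treatment_start < treatment_end &&
        treatment_end < end_day)) {
    stop("need baseline_day < treatment_start < treatment_end < end_day",
         call. = FALSE)
  }
  phases <- c("pre", "treatment", "post")
  got <- table(factor(phase_days(day_grid, treatment_start, treatment_end),
                      levels = phases))
  if (any(got == 0L)) {
    stop("every phase needs at least one scheduled day; empty: ",
         paste(phases[got == 0L], collapse = ", "), call. = FALSE)
  }
  if (!baseline_day %in% day_grid) {
    stop("baseline_day ", baseline_day, " is not on the day grid", call. = FALSE)
  }
  structure(
    list(n_mice = n_mice, taxa = as.character(taxa), day_grid = day_grid,
         baseline_day = baseline_day, treatment_start = treatment_start,
         treatment_end = treatment_end, end_day = end_day),
    class = "study_design"
  )
}

phase_days <- function(days, treatment_start, treatment_end) {
  ifelse(days < treatment_start, "pre",
         ifelse(days <= treatment_end, "treatment", "post"))
}

#' @rdname study_design
#' @param design a `study_design`.
#' @param day integer day(s).
#' @return `phase_of()`: character vector in `c("pre", "treatment", "post")`.
#' @export
phase_of <- function(design, day) {
  stopifnot(inherits(design, "study_design"))
  phase_days(as.integer(day), design$treatment_start, design$treatment_end)
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", x$n_mice, "mice,", length(x$taxa), "taxa,",
      length(x$day_grid), "scheduled days (", min(x$day_grid), "-",
      max(x$day_grid), ")\n")
  cat("  baseline day", x$baseline_day, "; treatment days",
      x$treatment_start, "-", x$treatment_end, "; end day", x$end_day, "\n")
  invisible(x)
}

#' Sample-by-taxon count table
#'
#' Thin container for a non-negative integer count matrix with samples as rows
#' (named by sample id) and taxa as columns. `total_reads` is the row sum and
#' is the quantity thresholded by [filter_min_reads()].
#'
#' @param counts integer matrix, samples x taxa, with row and column names.
#' @return an object of class `count_table` with elements `counts` (matrix),
#'   `sample_id`, `taxa` and `total_reads`.
#' @export
count_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("counts must have taxon column names",
                                      call. = FALSE)
  if (nrow(counts) > 0 && is.null(rownames(counts))) {
    stop("counts must have sample ids as row names", call. = FALSE)
  }
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("counts must be non-negative integers; offending cell: sample '%s', taxon '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample_id: ",
         rownames(counts)[duplicated(rownames(counts))][1], call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  structure(
    list(counts = counts, sample_id = rownames(counts),
         taxa = colnames(counts), total_reads = as.integer(rowSums(counts))),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat("Count table:", nrow(x$counts), "samples x", ncol(x$counts), "taxa;",
      "read depth", if (nrow(x$counts) > 0)
        paste0("[", min(x$total_reads), ", ", max(x$total_reads), "]")
      else "[]", "\n")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Read and write count tables
#'
#' Counts travel as plain TSV: a header row with `sample_id` followed by one
#' column per taxon, then one row per sample with integer cells. Missing taxa
#' are 0 counts, never NA.
#'
#' @param path path to a tab-separated file.
#' @return `read_counts()`: a [count_table()].
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           sep = "\t")
  if (ncol(raw) < 1 || names(raw)[1] != "sample_id") {
    stop("counts TSV must have 'sample_id' as its first column", call. = FALSE)
  }
  taxa <- names(raw)[-1]
  if (nrow(raw) == 0) {
    m <- matrix(integer(0), nrow = 0, ncol = length(taxa),
                dimnames = list(NULL, taxa))
    return(count_table(m))
  }
  cells <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-integer or negative count '%s' at sample '%s', taxon '%s'",
                 cells[bad[1, 1], bad[1, 2]], raw$sample_id[bad[1, 1]],
                 taxa[bad[1, 2]]), call. = FALSE)
  }
  dimnames(num) <- list(raw$sample_id, taxa)
  count_table(num)
}

#' @rdname read_counts
#' @param table a [count_table()].
#' @return `write_counts()`: the path, invisibly.
#' @export
write_counts <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(sample_id = table$sample_id, table$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write per-sample metadata
#'
#' Metadata is a TSV with columns `sample_id`, `mouse_id` and `day`. Days are
#' integers (sampling happens on whole days); fractional days are rejected.
#' The pair (`mouse_id`, `day`) must be unique.
#'
#' @param path path to a tab-separated file.
#' @return `read_metadata()`: a data.frame with columns `sample_id`,
#'   `mouse_id` (character) and `day` (integer).
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           sep = "\t")
  need <- c("sample_id", "mouse_id", "day")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  day <- suppressWarnings(as.numeric(raw$day))
  bad <- which(is.na(day) | day != round(day))
  if (length(bad) > 0) {
    stop(sprintf("day '%s' for sample '%s' is not an integer day",
                 raw$day[bad[1]], raw$sample_id[bad[1]]), call. = FALSE)
  }
  meta <- data.frame(sample_id = raw$sample_id, mouse_id = raw$mouse_id,
                     day = as.integer(day), stringsAsFactors = FALSE)
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id: ",
         meta$sample_id[duplicated(meta$sample_id)][1], call. = FALSE)
  }
  key <- paste(meta$mouse_id, meta$day)
  if (anyDuplicated(key)) {
    stop("duplicate (mouse_id, day): ", key[duplicated(key)][1], call. = FALSE)
  }
  meta
}

#' @rdname read_metadata
#' @param meta a metadata data.frame.
#' @return `write_metadata()`: the path, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta[, c("sample_id", "mouse_id", "day")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a study configuration from YAML
#'
#' Recognized keys: `baseline_day`, `treatment_start`, `treatment_end`,
#' `end_day`, `min_reads`. Missing keys fall back to the defaults of the
#' 37-day design (9 / 14 / 23 / 37, 4000 reads).
#'
#' @param path path to a YAML file.
#' @return named list with the five keys above, integer-valued.
#' @export
read_design_config <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  defaults <- list(baseline_day = 9L, treatment_start = 14L,
                   treatment_end = 23L, end_day = 37L, min_reads = 4000L)
  for (k in names(defaults)) {
    if (!is.null(cfg[[k]])) defaults[[k]] <- as.integer(cfg[[k]])
  }
  defaults
}

#' Drop shallow samples
#'
#' Samples whose total read count is strictly below the threshold are removed;
#' everything at or above it is retained, in the original order. The default
#' threshold of 4000 reads is the depth below which per-sample compositions
#' are too noisy to trust.
#'
#' @param table a [count_table()].
#' @param threshold minimum total reads to keep a sample (default 4000).
#' @return a [count_table()] containing only the retained samples.
#' @export
filter_min_reads <- function(table, threshold = 4000L) {
  stopifnot(inherits(table, "count_table"), threshold >= 0)
  keep <- table$total_reads >= threshold
  count_table(table$counts[keep, , drop = FALSE])
}

#' Convert counts to relative abundances
#'
#' Divides every row by its total so rows sum to one. Zero-depth samples have
#' no defined composition; filter them out first (see [filter_min_reads()]).
#'
#' @param table a [count_table()].
#' @return an object of class `abundance_table`: same shape as the input, with
#'   numeric fractional values.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "count_table"))
  zero <- which(table$total_reads == 0L)
  if (length(zero) > 0) {
    stop("sample '", table$sample_id[zero[1]],
         "' has zero reads; apply filter_min_reads() before to_relative()",
         call. = FALSE)
  }
  ab <- table$counts / table$total_reads
  structure(
    list(abundance = ab, sample_id = table$sample_id, taxa = table$taxa),
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("Abundance table:", nrow(x$abundance), "samples x", ncol(x$abundance),
      "taxa (rows sum to 1)\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$abundance)

#' Extract one taxon's time series
#'
#' Pulls the (day, value) series of a single taxon, either for one mouse or as
#' the across-mouse mean. The mean is available-case: each day is averaged
#' over the mice that actually have a sample on that day, and days with no
#' samples are dropped (no imputation or interpolation).
#'
#' @param ab an `abundance_table` (see [to_relative()]).
#' @param meta metadata data.frame as returned by [read_metadata()].
#' @param taxon taxon label.
#' @param mouse a mouse id, or `"mean"` (default) for the across-mouse mean.
#' @return an object of class `taxon_series`: a data.frame with columns `day`
#'   and `value`, ordered by day, with attributes `taxon` and `mouse`.
#' @export
extract_series <- function(ab, meta, taxon, mouse = "mean") {
  stopifnot(inherits(ab, "abundance_table"))
  if (!taxon %in% ab$taxa) stop("unknown taxon: ", taxon, call. = FALSE)
  meta <- meta[match(ab$sample_id, meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) {
    stop("metadata is missing sample(s): ",
         ab$sample_id[which(is.na(meta$sample_id))[1]], call. = FALSE)
  }
  vals <- ab$abundance[, taxon]
  if (identical(mouse, "mean")) {
    agg <- tapply(vals, meta$day, mean)
    out <- data.frame(day = as.integer(names(agg)), value = as.numeric(agg))
  } else {
    if (!mouse %in% meta$mouse_id) stop("unknown mouse: ", mouse, call. = FALSE)
    sel <- meta$mouse_id == mouse
    out <- data.frame(day = meta$day[sel], value = as.numeric(vals[sel]))
  }
  out <- out[order(out$day), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("taxon_series", "data.frame"),
            taxon = taxon, mouse = mouse)
}
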