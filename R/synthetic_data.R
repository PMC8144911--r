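#' Per-taxon response template
#'
#' Describes how one taxon's unnormalized abundance reacts to the
#' intervention. Effects are piecewise-constant: the taxon's baseline level is
#' multiplied by `2^log2_effect` on days in `[onset_day, offset_day)`; with no
#' `offset_day` the effect persists to the end of the experiment. Four shapes
#' cover the dynamics seen in perturbation studies of defined communities:
#'
#' * `"null"` — no effect;
#' * `"early_transient"` — a shift shortly after treatment onset, reverting
#'   before or around treatment end (response + recovery);
#' * `"late_transient"` — a shift after treatment ends, reverting before the
#'   end of the experiment (response + recovery);
#' * `"persistent"` — a shift with no reversal inside the observation window
#'   (response, no recovery).
#'
#' @param kind one of `"null"`, `"early_transient"`, `"late_transient"`,
#'   `"persistent"`.
#' @param onset_day first day the effect applies.
#' @param offset_day first day the effect no longer applies (`NA` for
#'   persistent / null).
#' @param log2_effect signed log2 fold-change of the unnormalized abundance.
#' @return an object of class `response_template`.
#' @export
response_template <- function(kind = c("null", "early_transient",
                                       "late_transient", "persistent"),
                              onset_day = NA_integer_,
                              offset_day = NA_integer_,
                              log2_effect = 0) {
  kind <- match.arg(kind)
  if (kind == "null") {
    onset_day <- NA_integer_; offset_day <- NA_integer_; log2_effect <- 0
  } else {
    onset_day <- as.integer(onset_day)
    if (is.na(onset_day)) stop("non-null templates need an onset_day",
                               call. = FALSE)
    if (kind == "persistent") {
      offset_day <- NA_integer_
    } else {
      offset_day <- as.integer(offset_day)
      if (is.na(offset_day) || offset_day <= onset_day) {
        stop("transient templates need offset_day > onset_day", call. = FALSE)
      }
    }
  }
  structure(list(kind = kind, onset_day = onset_day, offset_day = offset_day,
                 log2_effect = log2_effect),
            class = "response_template")
}

effect_on_day <- function(template, day) {
  if (template$kind == "null") return(0)
  active <- day >= template$onset_day &
    (is.na(template$offset_day) | day < template$offset_day)
  ifelse(active, template$log2_effect, 0)
}

#' The default 37-day gnotobiotic study design
#'
#' Six singly-housed gnotobiotic mice colonized with a 25-member defined
#' community, sampled every two days from the day-9 baseline to day 37, with
#' daily sampling around treatment onset (days 13-16) and treatment offset
#' (days 22-26). The ten-day intervention spans days 14-23 and is followed by
#' a 14-day recovery phase.
#'
#' @return a [study_design()].
#' @examples
#' d <- default_study_design()
#' d$treatment_end - d$treatment_start + 1  # ten dosing days
#' @export
default_study_design <- function() {
  grid <- sort(unique(c(seq(9L, 37L, by = 2L), 13:16, 22:26)))
  study_design(n_mice = 6L, taxa = default_taxa(), day_grid = grid,
               baseline_day = 9L, treatment_start = 14L,
               treatment_end = 23L, end_day = 37L)
}

#' @rdname default_study_design
#' @return `default_taxa()`: character vector of the 25 community members
#'   (human-origin gut commensals; *Bacteroides ovatus* is the dominant
#'   colonizer).
#' @export
default_taxa <- function() {
  c("Bacteroides_ovatus", "Bacteroides_vulgatus", "Bacteroides_fragilis",
    "Parabacteroides_distasonis", "Parabacteroides_merdae",
    "Prevotella_copri", "Escherichia_coli", "Klebsiella_oxytoca",
    "Proteus_mirabilis", "Clostridium_ramosum", "Clostridium_hiranonis",
    "Clostridium_scindens", "Enterococcus_faecalis", "Lactobacillus_reuteri",
    "Lactobacillus_plantarum", "Akkermansia_muciniphila",
    "Bifidobacterium_longum", "Blautia_producta", "Collinsella_aerofaciens",
    "Dorea_formicigenerans", "Eubacterium_rectale",
    "Faecalibacterium_prausnitzii", "Roseburia_intestinalis",
    "Ruminococcus_bromii", "Veillonella_parvula")
}

#' Default response templates for the simulated study
#'
#' Plants the three dynamic classes observed in short-term perturbation
#' studies onto the default community, leaving the dominant colonizer and the
#' remaining taxa unperturbed:
#'
#' * early transients (effect days 14-19, during treatment) on five taxa,
#'   mixed directions;
#' * late transients (effect days 24-30, after treatment offset) on three;
#' * persistent shifts (onset day 14 or 24, no offset) on three.
#'
#' All effect magnitudes default to |log2 fold-change| = 2 (4-fold).
#'
#' @param log2_effect absolute effect size on the log2 scale (default 2).
#' @return named list of [response_template()]s for the non-null taxa.
#' @export
default_templates <- function(log2_effect = 2) {
  e <- abs(log2_effect)
  list(
    Escherichia_coli      = response_template("early_transient", 14, 20,  e),
    Clostridium_ramosum   = response_template("early_transient", 14, 20,  e),
    Bacteroides_vulgatus  = response_template("early_transient", 14, 20, -e),
    Bacteroides_fragilis  = response_template("early_transient", 14, 20, -e),
    Enterococcus_faecalis = response_template("early_transient", 14, 20, -e),
    Akkermansia_muciniphila = response_template("late_transient", 24, 31,  e),
    Clostridium_hiranonis   = response_template("late_transient", 24, 31,  e),
    Lactobacillus_reuteri   = response_template("late_transient", 24, 31, -e),
    Klebsiella_oxytoca         = response_template("persistent", 14, NA,  e),
    Proteus_mirabilis          = response_template("persistent", 14, NA, -e),
    Parabacteroides_distasonis = response_template("persistent", 24, NA, -e)
  )
}

#' Configuration of the synthetic count simulator
#'
#' Bundles everything [simulate_study()] needs: the study design, the
#' baseline composition, the planted response templates, the noise and
#' sequencing-depth model, the dropout rate and the seed. The default baseline
#' composition puts the dominant taxon (first in the design's taxon order) at
#' 0.8 relative abundance and spreads the remaining 0.2 evenly.
#'
#' @param design a [study_design()] (default [default_study_design()]).
#' @param baseline_composition numeric vector over `design$taxa` summing to 1,
#'   or `NULL` for the dominant-taxon default.
#' @param templates named list of [response_template()]s; taxa not listed are
#'   null. Default [default_templates()].
#' @param noise_sigma standard deviation of the Gaussian noise on log
#'   unnormalized abundance (logistic-normal model; default 0.15).
#' @param depth_mean,depth_dispersion mean and dispersion (negative-binomial
#'   `size`) of the per-sample read depth; defaults 30000 and 5.
#' @param dropout_prob probability that a scheduled non-baseline sample is
#'   missing (default 0).
#' @param seed integer seed governing all randomness.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(design = default_study_design(),
                             baseline_composition = NULL,
                             templates = default_templates(),
                             noise_sigma = 0.15,
                             depth_mean = 30000, depth_dispersion = 5,
                             dropout_prob = 0, seed = 1L) {
  stopifnot(inherits(design, "study_design"), noise_sigma >= 0,
            depth_mean > 0, depth_dispersion > 0,
            dropout_prob >= 0, dropout_prob < 1)
  p <- length(design$taxa)
  if (is.null(baseline_composition)) {
    baseline_composition <- c(0.8, rep(0.2 / (p - 1), p - 1))
  }
  stopifnot(length(baseline_composition) == p, all(baseline_composition >= 0))
  if (abs(sum(baseline_composition) - 1) > 1e-9) {
    stop("baseline_composition must sum to 1", call. = FALSE)
  }
  names(baseline_composition) <- design$taxa
  unknown <- setdiff(names(templates), design$taxa)
  if (length(unknown) > 0) {
    stop("templates reference unknown taxa: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ok <- vapply(templates, inherits, logical(1), "response_template")
  if (length(templates) > 0 && (!all(ok) || is.null(names(templates)))) {
    stop("templates must be a named list of response_template objects",
         call. = FALSE)
  }
  structure(
    list(design = design, baseline_composition = baseline_composition,
         templates = templates, noise_sigma = noise_sigma,
         depth_mean = depth_mean, depth_dispersion = depth_dispersion,
         dropout_prob = dropout_prob, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

template_for <- function(config, taxon) {
  tpl <- config$templates[[taxon]]
  if (is.null(tpl)) response_template("null") else tpl
}

#' Noise-free expected composition on a given day
#'
#' The composition the simulator targets before noise and sequencing:
#' baseline levels scaled by the active effects and renormalized. Because the
#' data are compositional, an effect on one taxon slightly shifts every other
#' taxon's relative abundance as well.
#'
#' @param config a [synthetic_config()].
#' @param day integer day.
#' @return named numeric vector over taxa, summing to 1.
#' @export
expected_composition <- function(config, day) {
  u <- vapply(config$design$taxa, function(tx) {
    config$baseline_composition[[tx]] *
      2^effect_on_day(template_for(config, tx), day)
  }, numeric(1))
  u / sum(u)
}

#' Simulate a longitudinal defined-community sequencing study
#'
#' For each mouse and scheduled day (minus dropouts) the generator draws a
#' sample in three stages: (1) unnormalized abundance
#' `u_i = baseline_i * 2^log2_effect_i(day) * exp(eps)` with
#' `eps ~ Normal(0, noise_sigma^2)` independently per taxon and sample
#' (logistic-normal compositional noise); (2) the composition `p = u / sum(u)`;
#' (3) a read depth from a negative binomial and counts from
#' `Multinomial(depth, p)`. The same seed yields bit-identical output. The
#' baseline day is never dropped, so every mouse anchors its own
#' distance-to-baseline trajectory.
#'
#' @param config a [synthetic_config()].
#' @return a list with elements `counts` (a [count_table()]), `metadata`
#'   (data.frame: sample_id, mouse_id, day) and `truth` (a data.frame of
#'   planted ground truth per taxon: kind, effect window, changepoint days,
#'   expected response/recovery counts and direction; identical across mice).
#' @examples
#' sim <- simulate_study(synthetic_config(seed = 7))
#' sim$counts
#' subset(sim$truth, kind != "null")[, c("taxon", "n_response", "n_recovery")]
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  design <- config$design
  taxa <- design$taxa
  p <- length(taxa)
  set.seed(config$seed)

  log2eff <- vapply(design$day_grid, function(d) {
    vapply(taxa, function(tx) effect_on_day(template_for(config, tx), d),
           numeric(1))
  }, numeric(p))  # taxa x days

  rows <- list(); ids <- character(0)
  meta <- list()
  for (m in seq_len(design$n_mice)) {
    mouse_id <- sprintf("m%d", m)
    for (di in seq_along(design$day_grid)) {
      day <- design$day_grid[di]
      if (day != design$baseline_day && config$dropout_prob > 0 &&
          stats::runif(1) < config$dropout_prob) next
      eps <- stats::rnorm(p, 0, config$noise_sigma)
      u <- config$baseline_composition * 2^log2eff[, di] * exp(eps)
      prob <- u / sum(u)
      depth <- stats::rnbinom(1, size = config$depth_dispersion,
                              mu = config$depth_mean)
      cnt <- as.integer(stats::rmultinom(1, size = depth, prob = prob))
      sid <- sprintf("%s_d%02d", mouse_id, day)
      rows[[sid]] <- cnt
      meta[[sid]] <- data.frame(sample_id = sid, mouse_id = mouse_id,
                                day = day)
    }
  }
  mat <- do.call(rbind, rows)
  dimnames(mat) <- list(names(rows), taxa)
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL

  truth <- do.call(rbind, lapply(taxa, function(tx) {
    tpl <- template_for(config, tx)
    cps <- switch(tpl$kind,
                  null = integer(0),
                  persistent = tpl$onset_day,
                  c(tpl$onset_day, tpl$offset_day))
    data.frame(
      taxon = tx, kind = tpl$kind,
      onset_day = tpl$onset_day, offset_day = tpl$offset_day,
      log2_effect = tpl$log2_effect,
      changepoint_days = I(list(as.integer(cps))),
      n_response = if (tpl$kind == "null") 0L else 1L,
      n_recovery = if (tpl$kind %in% c("early_transient", "late_transient"))
        1L else 0L,
      direction = if (tpl$kind == "null") "none"
                  else if (tpl$log2_effect > 0) "up" else "down"
    )
  }))
  rownames(truth) <- NULL

  list(counts = count_table(mat), metadata = metadata, truth = truth)
}

#' Write a simulated study to disk
#'
#' Writes `counts.tsv`, `metadata.tsv` and `truth.json` into a directory, in
#' the same plain-text formats the analysis functions read back.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  write_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
  truth <- sim$truth
  truth$changepoint_days <- lapply(truth$changepoint_days, as.integer)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
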