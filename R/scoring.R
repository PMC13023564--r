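#' Classify memory errors by shared cues
#'
#' Keeps only incorrect recall trials and flags, for every error and every
#' cue, whether the chosen face shares that cue with the true speaker
#' (a within-category error for that cue). Correct trials are uninformative
#' for categorization and are dropped; the dropped count is recorded.
#'
#' @param trials A trial-record tibble (see [simulate_wsw_cohort()] or
#'   [read_trials()]).
#' @param design A [wsw_design()].
#' @param quiet Suppress the message reporting how many correct trials were
#'   dropped.
#'
#' @return A tibble with one row per error: the trial identifiers plus one
#'   logical `<cue>_match` column per cue and `any_overlap` (shares at least
#'   one cue). The number of dropped correct trials is stored in the
#'   `n_correct_dropped` attribute.
#'
#' @examples
#' cohort <- simulate_wsw_cohort(wsw_config(n_participants = 10, seed = 1))
#' classify_errors(cohort$trials, cohort$design)
#' @export
classify_errors <- function(trials, design, quiet = TRUE) {
  validate_wsw_design(design)
  check_trials(trials)
  err <- trials[!trials$correct, , drop = FALSE]
  n_dropped <- nrow(trials) - nrow(err)
  if (!quiet) {
    rlang::inform(sprintf("Dropped %d correct trials; %d errors retained.",
                          n_dropped, nrow(err)))
  }
  codes <- cue_code_matrix(design)
  it <- face_index(design, err$true_face_id, "true_face_id")
  ic <- face_index(design, err$chosen_face_id, "chosen_face_id")
  flags <- codes[it, , drop = FALSE] == codes[ic, , drop = FALSE]
  dimnames(flags) <- NULL
  out <- tibble::as_tibble(err)
  cn <- cue_names(design)
  for (j in seq_along(cn)) out[[paste0(cn[j], "_match")]] <- flags[, j]
  out$any_overlap <- rowSums(flags) > 0
  attr(out, "n_correct_dropped") <- n_dropped
  out
}

#' Per-participant proportional categorization scores
#'
#' For each participant and each cue, counts within-category and
#' between-category errors and computes the proportional categorization
#' score `(within - between) / total errors`. Scores for different cues are
#' computed on the same error pool and are not mutually exclusive.
#' Participants with zero errors have no defined score: their rows are kept
#' with `NA` scores and are excluded from downstream aggregates and fits,
#' never imputed as zero.
#'
#' @inheritParams classify_errors
#'
#' @return A tibble of class `wsw_scores`: `participant_id`, `n_errors`,
#'   and per cue `<cue>_within`, `<cue>_between`, `<cue>_score`. The
#'   analytic chance score (`-1/7` in the 2 x 2 x 2 design, see
#'   [expected_random_score()]) is stored in the `chance_score` attribute
#'   for balanced factorial designs.
#'
#' @examples
#' cohort <- simulate_wsw_cohort(wsw_config(n_participants = 10, seed = 1))
#' categorization_scores(cohort$trials, cohort$design)
#' @export
categorization_scores <- function(trials, design, quiet = TRUE) {
  validate_wsw_design(design)
  check_trials(trials)
  errors <- classify_errors(trials, design, quiet = quiet)
  cn <- cue_names(design)
  ids <- sort(unique(trials$participant_id))
  pid <- factor(errors$participant_id, levels = ids)
  n_errors <- as.integer(table(pid))
  flags <- as.matrix(errors[, paste0(cn, "_match")]) + 0
  within <- matrix(0, nrow = length(ids), ncol = length(cn))
  if (nrow(flags) > 0) {
    # rowsum drops empty groups; reindex so error-free participants keep 0 rows
    rs <- rowsum(flags, as.integer(pid))
    within[as.integer(rownames(rs)), ] <- rs
  }
  out <- tibble::tibble(participant_id = ids, n_errors = n_errors)
  for (j in seq_along(cn)) {
    w <- within[, j]
    b <- n_errors - w
    s <- ifelse(n_errors > 0, (w - b) / n_errors, NA_real_)
    out[[paste0(cn[j], "_within")]] <- as.integer(w)
    out[[paste0(cn[j], "_between")]] <- as.integer(b)
    out[[paste0(cn[j], "_score")]] <- s
  }
  if (is_factorial_design(design)) {
    attr(out, "chance_score") <- as.numeric(expected_random_score(design))
  }
  attr(out, "cues") <- cn
  attr(out, "n_zero_error") <- sum(n_errors == 0)
  class(out) <- c("wsw_scores", class(tibble::tibble()))
  out
}

#' One-sample t-test with Cohen's d
#'
#' Two-sided one-sample t-test of `values` against `mu0`, reported with the
#' standardized mean difference `d = (mean - mu0) / sd`.
#'
#' @param values Numeric vector (at least two finite values; `NA` dropped).
#' @param mu0 Null value.
#'
#' @return A one-row tibble: `n`, `mean`, `sd`, `statistic` (t), `df`,
#'   `p.value`, `cohens_d`.
#'
#' @examples
#' one_sample_test(c(0.1, 0.3, 0.5), mu0 = 0)
#' @export
one_sample_test <- function(values, mu0 = 0) {
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    abort_wsw("Need at least two finite values.", "test")
  }
  s <- stats::sd(values)
  if (s == 0) {
    abort_wsw("Values are constant; the t-test is undefined.", "test")
  }
  tt <- stats::t.test(values, mu = mu0)
  tibble::tibble(
    n = length(values),
    mean = unname(tt$estimate),
    sd = s,
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = tt$p.value,
    cohens_d = (mean(values) - mu0) / s
  )
}

#' Cue-level summary of categorization strength
#'
#' One-sample tests of each cue's participant-level categorization scores
#' against `mu0` (zero by default, following standard WSW reporting; the
#' uniform-guessing expectation is shown in `chance_score` for reference).
#'
#' @param scores A [categorization_scores()] table.
#' @param mu0 Null value for the per-cue tests.
#'
#' @return A tibble with one row per cue: `cue`, `n`, `mean`, `sd`,
#'   `statistic`, `df`, `p.value`, `cohens_d`, `chance_score`.
#' @export
cue_summary <- function(scores, mu0 = 0) {
  cn <- attr(scores, "cues")
  if (is.null(cn)) {
    cn <- sub("_score$", "", grep("_score$", names(scores), value = TRUE))
  }
  chance <- attr(scores, "chance_score")
  purrr::map_dfr(cn, function(cue) {
    res <- one_sample_test(scores[[paste0(cue, "_score")]], mu0 = mu0)
    dplyr::bind_cols(
      tibble::tibble(cue = cue),
      res,
      tibble::tibble(chance_score = if (is.null(chance)) NA_real_ else chance)
    )
  })
}

#' Shared-feature overlap analysis of memory errors
#'
#' Tests whether errors land on faces sharing at least one cue with the
#' true speaker more often than uniform guessing predicts (6/7 in the
#' balanced 2 x 2 x 2 design). Two complementary analyses are run: a
#' participant-level one-sample t-test of each participant's overlap
#' proportion against the baseline (with Cohen's d), and a pooled
#' trial-level exact binomial test.
#'
#' @inheritParams classify_errors
#' @param baseline Chance probability of sharing at least one cue; defaults
#'   to [feature_overlap_probability()] of the design.
#' @param alternative Alternative hypothesis for the binomial test. The
#'   default `"greater"` asks for elevation above chance; `"two.sided"` is
#'   available. The t-test is always two-sided.
#'
#' @return A list of class `wsw_overlap`: `participant` (per-participant
#'   overlap proportions), `by_participant` (t-test summary or `NULL` with
#'   fewer than two scored participants), `pooled` (counts, proportion and
#'   binomial p-value), and `baseline`.
#'
#' @examples
#' cohort <- simulate_wsw_cohort(wsw_config(n_participants = 30, seed = 1))
#' overlap_statistics(cohort$trials, cohort$design)
#' @export
overlap_statistics <- function(trials, design, baseline = NULL,
                               alternative = c("greater", "two.sided")) {
  validate_wsw_design(design)
  alternative <- match.arg(alternative)
  if (is.null(baseline)) baseline <- as.numeric(feature_overlap_probability(design))
  if (baseline <= 0 || baseline >= 1) {
    abort_wsw("`baseline` must be strictly between 0 and 1.", "test")
  }
  errors <- classify_errors(trials, design)
  if (nrow(errors) == 0) {
    return(structure(
      list(participant = tibble::tibble(), by_participant = NULL,
           pooled = NULL, baseline = baseline),
      class = "wsw_overlap"
    ))
  }
  participant <- errors |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_errors = dplyr::n(),
      n_overlap = sum(.data$any_overlap),
      proportion = mean(.data$any_overlap),
      .groups = "drop"
    )
  by_participant <- NULL
  if (nrow(participant) >= 2 && stats::sd(participant$proportion) > 0) {
    by_participant <- one_sample_test(participant$proportion, mu0 = baseline)
  }
  pooled <- overlap_from_counts(sum(errors$any_overlap), nrow(errors),
                                baseline, alternative)$pooled
  structure(
    list(
      participant = participant,
      by_participant = by_participant,
      pooled = pooled,
      baseline = baseline
    ),
    class = "wsw_overlap"
  )
}

#' Pooled overlap test from raw counts
#'
#' Exact binomial test of a pooled overlap count against the chance
#' baseline, for when only the aggregated counts are available.
#'
#' @param n_overlap Number of errors sharing at least one cue.
#' @param n_total Total number of errors.
#' @param baseline Chance probability (e.g. 6/7 for the 2 x 2 x 2 design).
#' @param alternative Passed to [stats::binom.test()]; default `"greater"`.
#'
#' @return A `wsw_overlap` object with only the `pooled` component filled.
#'
#' @examples
#' overlap_from_counts(4593, 5143, 6 / 7)
#' @export
overlap_from_counts <- function(n_overlap, n_total, baseline,
                                alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_overlap > n_total) abort_wsw("`n_overlap` cannot exceed `n_total`.", "test")
  bt <- stats::binom.test(n_overlap, n_total, p = baseline,
                          alternative = alternative)
  structure(
    list(
      participant = NULL,
      by_participant = NULL,
      pooled = list(
        n_overlap = n_overlap,
        n_total = n_total,
        proportion = n_overlap / n_total,
        p.value = bt$p.value,
        alternative = alternative
      ),
      baseline = baseline
    ),
    class = "wsw_overlap"
  )
}

#' @export
print.wsw_overlap <- function(x, ...) {
  cat("<wsw_overlap>\n")
  cat(sprintf("  chance baseline: %.4f\n", x$baseline))
  if (!is.null(x$by_participant)) {
    bp <- x$by_participant
    cat(sprintf(
      "  participant-mean overlap: %.3f (SD %.3f), t(%d) = %.2f, p = %.3g, d = %.2f\n",
      bp$mean, bp$sd, bp$df, bp$statistic, bp$p.value, bp$cohens_d
    ))
  }
  if (!is.null(x$pooled)) {
    cat(sprintf(
      "  pooled: %d of %d errors (%.1f%%) share a cue; exact binomial p = %.3g (%s)\n",
      x$pooled$n_overlap, x$pooled$n_total, 100 * x$pooled$proportion,
      x$pooled$p.value, x$pooled$alternative
    ))
  }
  invisible(x)
}
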