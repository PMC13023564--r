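#' Resample error choices under the constrained null
#'
#' Replaces the chosen face of every error trial with a uniform draw over
#' the `2^k - 1` incorrect alternatives, leaving correct trials — and hence
#' each participant's error count — untouched. This preserves the zero-sum
#' constraints of the task while destroying any cue-based structure in the
#' error choices; it is the resampling step of the shared-error-pool null.
#'
#' @param trials Trial records (with a `correct` flag).
#' @param design A [wsw_design()].
#'
#' @return The trial table with resampled `chosen_face_id` on error trials
#'   (`correct` recomputed; resampled choices are never the true face, so
#'   every error stays an error). Uses the current RNG stream.
#' @export
resample_errors <- function(trials, design) {
  validate_wsw_design(design)
  check_trials(trials)
  err <- which(!trials$correct)
  if (length(err) == 0) return(trials)
  n_faces <- nrow(design)
  rank_true <- face_index(design, trials$true_face_id[err], "true_face_id")
  u <- sample.int(n_faces - 1L, length(err), replace = TRUE)
  idx <- u + (u >= rank_true)  # uniform over the alternatives, skipping the true face
  trials$chosen_face_id[err] <- design$face_id[idx]
  trials
}

#' Add-one-corrected empirical tail probability
#'
#' Monte-Carlo p-value of an observed statistic against null replicates:
#' `p = (1 + #extreme) / (1 + R)`. The add-one correction counts the
#' observed value as one more replicate and never reports exactly zero.
#' Modes: `"magnitude"` counts `|x| >= |observed|` (two-sided on size, the
#' default for coefficients), `"signed"` counts the tail on the observed
#' side, `"upper"` counts `x >= observed` (used for R-squared).
#'
#' @param samples Numeric vector of null replicate values.
#' @param observed Observed statistic.
#' @param mode Tail mode; see Details.
#' @param correction Apply the add-one correction (default `TRUE`); the raw
#'   proportion is returned when `FALSE`.
#'
#' @return A probability in `(0, 1]` (or `[0, 1]` uncorrected).
#'
#' @examples
#' tail_probability(rnorm(5000), 3, mode = "magnitude")
#' @export
tail_probability <- function(samples, observed,
                             mode = c("magnitude", "signed", "upper"),
                             correction = TRUE) {
  mode <- match.arg(mode)
  samples <- samples[is.finite(samples)]
  if (length(samples) == 0) abort_wsw("`samples` must be non-empty.", "nullsim")
  extreme <- switch(mode,
    magnitude = sum(abs(samples) >= abs(observed)),
    signed = if (observed < 0) sum(samples <= observed) else sum(samples >= observed),
    upper = sum(samples >= observed)
  )
  if (correction) (1 + extreme) / (1 + length(samples)) else extreme / length(samples)
}

#' Empirical quantile of null replicates
#'
#' Order-statistic quantile with linear interpolation between closest ranks
#' (type-7 convention, the fixed convention used throughout the package).
#'
#' @param samples Numeric vector (non-empty).
#' @param q Probabilities strictly between 0 and 1.
#'
#' @return Quantile value(s).
#'
#' @examples
#' empirical_quantile(1:5, 0.5)
#' @export
empirical_quantile <- function(samples, q) {
  samples <- samples[is.finite(samples)]
  if (length(samples) == 0) abort_wsw("`samples` must be non-empty.", "nullsim")
  if (any(q <= 0 | q >= 1)) abort_wsw("`q` must be strictly between 0 and 1.", "nullsim")
  stats::quantile(samples, probs = q, type = 7, names = FALSE)
}

#' Constrained resampling null for the interaction regression
#'
#' Builds the empirical null distribution of the cue-interdependence
#' regression under the shared-error-pool constraint. Each replicate
#' resamples every error trial's chosen face uniformly over the incorrect
#' alternatives ([resample_errors()]), recomputes categorization scores
#' with [categorization_scores()] and refits the interaction model with
#' [fit_interaction_model()] — the identical code paths used for the
#' observed data, so observed and null values are strictly comparable. Any
#' structure in the null replicates reflects mechanical constraints alone
#' (scores for different cues share one finite error pool and trade off);
#' observed statistics beyond the null indicate genuine cue-based encoding.
#'
#' @param trials Observed trial records.
#' @param design A [wsw_design()].
#' @param n_replicates Number of null replicates (5000 for a full analysis;
#'   smaller values for exploration).
#' @param seed Optional integer seed; the run is reproducible given the
#'   seed and the caller's RNG stream is restored afterwards.
#' @param outcome,predictors Model specification passed to
#'   [fit_interaction_model()].
#' @param quantile_probs Probabilities for the reported null quantiles.
#' @param tail_mode Tail mode for coefficient p-values (`"magnitude"` by
#'   default, matching "comparable magnitude or greater"); R-squared always
#'   uses the upper tail.
#'
#' @return An object of class `wsw_nullsim`: `replicates` (tibble with one
#'   row per successful replicate: `replicate`, `r2`, `b_intercept`,
#'   `b_<predictor1>`, `b_<predictor2>`, `b_interaction`), `observed`,
#'   `quantiles`, `tails` (add-one-corrected tail probabilities),
#'   `n_replicates`, `n_failed`, `seed`, `tail_mode`.
#'
#' @examples
#' cohort <- simulate_wsw_cohort(wsw_config(n_participants = 80, seed = 1))
#' ns <- run_null_simulation(cohort$trials, cohort$design,
#'                           n_replicates = 50, seed = 2)
#' glance(ns)
#' @export
run_null_simulation <- function(trials, design, n_replicates = 5000L,
                                seed = NULL, outcome = "scar",
                                predictors = c("race", "sex"),
                                quantile_probs = c(0.5, 0.9, 0.95, 0.99, 0.999),
                                tail_mode = c("magnitude", "signed")) {
  validate_wsw_design(design)
  check_trials(trials)
  tail_mode <- match.arg(tail_mode)
  if (n_replicates < 1) abort_wsw("`n_replicates` must be at least 1.", "nullsim")

  extract_stats <- function(tr) {
    sc <- categorization_scores(tr, design)
    fit <- fit_interaction_model(sc, outcome = outcome, predictors = predictors)
    cf <- unname(stats::coef(fit$model))
    c(r2 = summary(fit$model)$r.squared,
      b_intercept = cf[1], b_p1 = cf[2], b_p2 = cf[3], b_interaction = cf[4])
  }
  observed <- extract_stats(trials)

  draws <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      tryCatch(extract_stats(resample_errors(trials, design)),
               error = function(e) NULL)
    })
  })
  failed <- vapply(draws, is.null, logical(1))
  if (all(failed)) abort_wsw("Every null replicate failed to fit.", "nullsim")
  mat <- do.call(rbind, draws[!failed])
  stat_names <- c("r2", "b_intercept", paste0("b_", predictors), "b_interaction")
  colnames(mat) <- stat_names
  names(observed) <- stat_names
  replicates <- dplyr::bind_cols(
    tibble::tibble(replicate = which(!failed)),
    tibble::as_tibble(mat)
  )

  quantiles <- tidyr::expand_grid(statistic = stat_names, q = quantile_probs) |>
    dplyr::mutate(
      value = purrr::map2_dbl(.data$statistic, .data$q,
                              function(s, p) empirical_quantile(mat[, s], p))
    )
  tails <- tibble::tibble(
    statistic = stat_names,
    observed = unname(observed[stat_names]),
    mode = c("upper", rep(tail_mode, 4L)),
    p.value = purrr::map_dbl(seq_along(stat_names), function(i) {
      tail_probability(mat[, i], observed[[i]],
                       mode = if (i == 1L) "upper" else tail_mode)
    })
  )
  structure(
    list(
      replicates = replicates,
      observed = as.list(observed),
      quantiles = quantiles,
      tails = tails,
      n_replicates = as.integer(n_replicates),
      n_failed = sum(failed),
      seed = seed,
      tail_mode = tail_mode,
      quantile_convention = "type 7 (linear interpolation between order statistics)"
    ),
    class = "wsw_nullsim"
  )
}

#' @rdname run_null_simulation
#' @param x,object A `wsw_nullsim`.
#' @param ... Unused.
#' @export
tidy.wsw_nullsim <- function(x, ...) {
  dplyr::left_join(
    x$tails,
    tidyr::pivot_wider(x$quantiles, names_from = "q", values_from = "value",
                       names_prefix = "q"),
    by = "statistic"
  )
}

#' @rdname run_null_simulation
#' @export
glance.wsw_nullsim <- function(x, ...) {
  r2q <- x$quantiles[x$quantiles$statistic == "r2" & x$quantiles$q == 0.999, ]
  tibble::tibble(
    n_replicates = x$n_replicates,
    n_failed = x$n_failed,
    observed_r2 = x$observed$r2,
    null_r2_q999 = if (nrow(r2q) == 1) r2q$value else NA_real_,
    p_r2 = x$tails$p.value[x$tails$statistic == "r2"],
    p_interaction = x$tails$p.value[x$tails$statistic == "b_interaction"]
  )
}

#' @export
print.wsw_nullsim <- function(x, ...) {
  cat("<wsw_nullsim>\n")
  cat(sprintf("  %d replicates (%d failed), seed: %s\n",
              x$n_replicates, x$n_failed,
              if (is.null(x$seed)) "<none>" else x$seed))
  print(tidy(x))
  invisible(x)
}
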