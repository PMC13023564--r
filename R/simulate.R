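#' Configuration for a simulated WSW cohort
#'
#' Collects the generative settings for [simulate_wsw_cohort()]. Each
#' participant has a latent memory accuracy (the probability that a recall
#' trial is answered correctly) drawn from a Beta distribution, and a latent
#' weight per cue (a log-odds bonus for choosing an error face that shares
#' that cue with the true speaker) drawn from a multivariate normal.
#'
#' @param n_participants Cohort size. Default 500, the scale of a typical
#'   online WSW sample.
#' @param trials_per_participant Recall trials per participant; must equal
#'   the number of statements in the encoding plan (24 in the classic
#'   8-face, 3-statements-per-face design).
#' @param accuracy_shape1,accuracy_shape2 Beta shape parameters for the
#'   accuracy distribution. The default Beta(6, 4) has mean 0.6, i.e. about
#'   10 errors in 24 trials.
#' @param weight_means Named numeric vector of cue-weight means, one per
#'   cue. The default `c(sex = 1, race = 0.15, scar = -0.15)` mirrors the
#'   qualitative ordering seen in WSW data: strong sex-based confusion, weak
#'   race-based confusion, and a weak contrastive scar pattern.
#' @param weight_cov Covariance matrix of the cue weights across
#'   participants (symmetric positive semidefinite). Default: identity
#'   (unit variances, independent cues).
#' @param seed Optional integer seed; the whole cohort is reproducible
#'   given the seed.
#'
#' @return A list of class `wsw_config`.
#'
#' @examples
#' wsw_config(n_participants = 50, seed = 1)
#' @export
wsw_config <- function(n_participants = 500L,
                       trials_per_participant = 24L,
                       accuracy_shape1 = 6,
                       accuracy_shape2 = 4,
                       weight_means = c(sex = 1, race = 0.15, scar = -0.15),
                       weight_cov = NULL,
                       seed = NULL) {
  if (n_participants < 1) abort_wsw("`n_participants` must be positive.", "config")
  if (accuracy_shape1 <= 0 || accuracy_shape2 <= 0) {
    abort_wsw("Beta shape parameters must be positive.", "config")
  }
  k <- length(weight_means)
  if (is.null(weight_cov)) weight_cov <- diag(k)
  weight_cov <- as.matrix(weight_cov)
  if (!identical(dim(weight_cov), c(k, k))) {
    abort_wsw("`weight_cov` must be k x k for k cue weights.", "config")
  }
  if (!isTRUE(all.equal(weight_cov, t(weight_cov))) ||
      any(eigen(weight_cov, symmetric = TRUE, only.values = TRUE)$values < -1e-8)) {
    abort_wsw("`weight_cov` must be a symmetric positive semidefinite matrix.", "config")
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      trials_per_participant = as.integer(trials_per_participant),
      accuracy_shape1 = accuracy_shape1,
      accuracy_shape2 = accuracy_shape2,
      weight_means = weight_means,
      weight_cov = weight_cov,
      seed = seed
    ),
    class = "wsw_config"
  )
}

#' @export
print.wsw_config <- function(x, ...) {
  cat("<wsw_config>\n")
  cat(sprintf("  participants: %d x %d trials\n",
              x$n_participants, x$trials_per_participant))
  cat(sprintf("  accuracy ~ Beta(%g, %g)\n", x$accuracy_shape1, x$accuracy_shape2))
  cat(sprintf("  weight means: %s\n",
              paste(sprintf("%s=%g", names(x$weight_means), x$weight_means),
                    collapse = ", ")))
  cat(sprintf("  seed: %s\n", if (is.null(x$seed)) "<none>" else x$seed))
  invisible(x)
}

# One 8 x 8 match matrix per cue: M[[c]][t, f] = 1 iff faces t and f share cue c.
match_matrices <- function(design) {
  codes <- cue_code_matrix(design)
  lapply(seq_len(ncol(codes)), function(c) {
    outer(codes[, c], codes[, c], FUN = "==") + 0
  })
}

# Row-normalized error-choice probabilities for one participant:
# P[t, f] over f != t, softmax in the number of shared cues weighted by w.
choice_prob_matrix <- function(weights, mats) {
  u <- 0
  for (c in seq_along(mats)) u <- u + weights[c] * mats[[c]]
  p <- exp(u - apply(u, 1, max))  # guard against overflow at large weights
  diag(p) <- 0
  p / rowSums(p)
}

#' Error-choice probabilities under the cue-match softmax model
#'
#' Given a participant's latent cue weights and the true speaker, returns
#' the probability of choosing each of the `2^k - 1` incorrect alternatives:
#' `P(f) proportional to exp(sum_c w_c * match_c(f, true))`. All-zero
#' weights give uniform guessing (1/7 each in the 8-face design); a large
#' weight on one cue concentrates the mass on the alternatives sharing that
#' cue.
#'
#' @param weights Numeric vector of cue weights, in design cue order (or
#'   named by cue).
#' @param true_face_id The true speaker's face id.
#' @param design A [wsw_design()].
#'
#' @return A tibble with columns `face_id` and `probability`, one row per
#'   incorrect alternative; probabilities sum to 1.
#'
#' @examples
#' choice_probabilities(c(sex = log(2), race = 0, scar = 0), 0, wsw_design())
#' @export
choice_probabilities <- function(weights, true_face_id, design) {
  validate_wsw_design(design)
  weights <- align_weights(weights, design)
  it <- face_index(design, true_face_id, "true_face_id")
  p <- choice_prob_matrix(weights, match_matrices(design))[it, ]
  tibble::tibble(face_id = design$face_id[-it], probability = unname(p[-it]))
}

align_weights <- function(weights, design) {
  cn <- cue_names(design)
  if (!is.null(names(weights)) && all(cn %in% names(weights))) {
    weights <- weights[cn]
  }
  if (length(weights) != length(cn)) {
    abort_wsw("`weights` must supply one value per cue.", "config")
  }
  unname(weights)
}

#' Simulate one participant's recall phase
#'
#' Presents every statement of the encoding plan in random order. With
#' probability `accuracy` the true face is selected; otherwise an error face
#' is drawn from [choice_probabilities()]. Uses the current RNG stream.
#'
#' @param accuracy Probability in `[0, 1]` of a correct recall.
#' @param weights Cue weights (see [choice_probabilities()]).
#' @param plan An [encoding_plan()].
#' @param design A [wsw_design()].
#' @param participant_id Id stamped on the returned records.
#'
#' @return A tibble of trial records: `participant_id`, `trial_index`,
#'   `statement_id`, `true_face_id`, `chosen_face_id`, `correct`.
#'
#' @examples
#' design <- wsw_design()
#' plan <- encoding_plan(design, seed = 1)
#' set.seed(2)
#' simulate_recall(0.5, c(sex = 2, race = 0, scar = 0), plan, design)
#' @export
simulate_recall <- function(accuracy, weights, plan, design, participant_id = 1L) {
  validate_wsw_design(design)
  if (accuracy < 0 || accuracy > 1) abort_wsw("`accuracy` must be in [0, 1].", "config")
  weights <- align_weights(weights, design)
  pmat <- choice_prob_matrix(weights, match_matrices(design))
  recall_one(participant_id, accuracy, pmat, plan, design)
}

# Hot path shared by simulate_recall() and simulate_wsw_cohort().
recall_one <- function(participant_id, accuracy, pmat, plan, design) {
  n_trials <- nrow(plan)
  order_idx <- sample.int(n_trials)
  true_idx <- face_index(design, plan$face_id[order_idx], "plan face_id")
  correct <- stats::runif(n_trials) < accuracy
  chosen_idx <- true_idx
  err <- which(!correct)
  if (length(err) > 0) {
    # draw all errors with the same true face in one multinomial call
    for (t in unique(true_idx[err])) {
      rows <- err[true_idx[err] == t]
      chosen_idx[rows] <- sample.int(nrow(design), length(rows),
                                     replace = TRUE, prob = pmat[t, ])
    }
  }
  tibble::tibble(
    participant_id = as.integer(participant_id),
    trial_index = seq_len(n_trials),
    statement_id = plan$statement_id[order_idx],
    true_face_id = design$face_id[true_idx],
    chosen_face_id = design$face_id[chosen_idx],
    correct = correct
  )
}

#' Simulate a full WSW cohort with known latent structure
#'
#' Draws per-participant accuracies and cue weights from the configured
#' distributions, then simulates every participant's recall phase. The
#' latent parameters are returned alongside the trial records so that
#' downstream scoring can be checked against the planted structure
#' (parameter recovery).
#'
#' @param config A [wsw_config()].
#' @param design A [wsw_design()]; its cues must match `config$weight_means`.
#' @param plan Optional [encoding_plan()]; generated from the cohort's RNG
#'   stream when omitted.
#'
#' @return A list of class `wsw_cohort` with elements `trials` (one row per
#'   recall trial), `latents` (one row per participant: `participant_id`,
#'   `accuracy`, `w_<cue>` columns), `design`, `plan`, and `config`.
#'
#' @examples
#' cohort <- simulate_wsw_cohort(wsw_config(n_participants = 20, seed = 1))
#' cohort$trials
#' @export
simulate_wsw_cohort <- function(config, design = wsw_design(), plan = NULL) {
  if (!inherits(config, "wsw_config")) {
    abort_wsw("`config` must be a `wsw_config` object.", "config")
  }
  validate_wsw_design(design)
  cn <- cue_names(design)
  if (length(config$weight_means) != length(cn)) {
    abort_wsw("`config$weight_means` must supply one mean per design cue.", "config")
  }
  with_seed(config$seed, {
    if (is.null(plan)) {
      per_face <- config$trials_per_participant / nrow(design)
      if (per_face != as.integer(per_face)) {
        abort_wsw("`trials_per_participant` must be a multiple of the number of faces.",
                  "config")
      }
      plan <- encoding_plan(design, per_face = as.integer(per_face))
    }
    if (nrow(plan) != config$trials_per_participant) {
      abort_wsw("`trials_per_participant` must equal the number of planned statements.",
                "config")
    }
    n <- config$n_participants
    accuracy <- stats::rbeta(n, config$accuracy_shape1, config$accuracy_shape2)
    w <- MASS::mvrnorm(n, mu = unname(config$weight_means), Sigma = config$weight_cov)
    w <- matrix(w, nrow = n)
    mats <- match_matrices(design)
    trials <- vector("list", n)
    for (i in seq_len(n)) {
      pmat <- choice_prob_matrix(w[i, ], mats)
      trials[[i]] <- recall_one(i, accuracy[i], pmat, plan, design)
    }
    latents <- tibble::tibble(
      participant_id = seq_len(n),
      accuracy = accuracy
    )
    for (j in seq_along(cn)) latents[[paste0("w_", cn[j])]] <- w[, j]
    structure(
      list(
        trials = dplyr::bind_rows(trials),
        latents = latents,
        design = design,
        plan = plan,
        config = config
      ),
      class = "wsw_cohort"
    )
  })
}

#' @export
print.wsw_cohort <- function(x, ...) {
  cat("<wsw_cohort>\n")
  cat(sprintf("  %d participants x %d trials (%d records)\n",
              x$config$n_participants, x$config$trials_per_participant,
              nrow(x$trials)))
  cat(sprintf("  errors: %d (%.1f%% of trials)\n",
              sum(!x$trials$correct), 100 * mean(!x$trials$correct)))
  invisible(x)
}
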