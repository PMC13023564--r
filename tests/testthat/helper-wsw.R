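# Shared fixtures, all built in code.

default_design <- wsw_design()

# Hand-built trial table; `true` and `chosen` are face ids, one participant
# per element of `pid`.
make_trials <- function(pid, true, chosen) {
  tibble::tibble(
    participant_id = as.integer(pid),
    trial_index = stats::ave(pid, pid, FUN = seq_along),
    statement_id = seq_along(pid) - 1L,
    true_face_id = as.integer(true),
    chosen_face_id = as.integer(chosen),
    correct = true == chosen
  )
}

# Trials for one participant whose e errors all go to `chosen`, plus
# (n_trials - e) correct trials on face `true`.
make_participant_trials <- function(pid, true, chosen, e, n_trials = 24) {
  make_trials(
    rep(pid, n_trials),
    rep(true, n_trials),
    c(rep(chosen, e), rep(true, n_trials - e))
  )
}

# Cohort where every participant has exactly e errors with uniformly random
# error choices (accuracy degenerate, used for null-regime comparisons).
make_fixed_error_cohort <- function(n, e, design = default_design, n_trials = 24) {
  trials <- purrr::map_dfr(seq_len(n), function(i) {
    true <- design$face_id[(seq_len(n_trials) - 1L) %% nrow(design) + 1L]
    err_rows <- sample.int(n_trials, e)
    chosen <- true
    for (r in err_rows) {
      alts <- setdiff(design$face_id, true[r])
      chosen[r] <- sample(alts, 1L)
    }
    tibble::tibble(
      participant_id = i,
      trial_index = seq_len(n_trials),
      statement_id = seq_len(n_trials) - 1L,
      true_face_id = true,
      chosen_face_id = chosen,
      correct = chosen == true
    )
  })
  trials
}

# Scores tibble generated exactly from interaction-model coefficients
# (no noise) over a grid of predictor values.
make_exact_scores <- function(b, n_grid = 7) {
  grid <- tidyr::expand_grid(
    race_score = seq(-0.9, 0.9, length.out = n_grid),
    sex_score = seq(-0.8, 1, length.out = n_grid)
  )
  dplyr::mutate(
    grid,
    scar_score = b[1] + b[2] * race_score + b[3] * sex_score +
      b[4] * race_score * sex_score,
    participant_id = dplyr::row_number()
  )
}

# Rescale a vector to an exact target mean and sd.
with_mean_sd <- function(x, m, s) {
  as.numeric(scale(x)) * s + m
}
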