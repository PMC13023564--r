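test_that("errors are classified by shared cues, correct trials dropped", {
  d <- default_design
  # true (male, White, scar) = 111 -> 7; chosen (male, Black, scar) = 101 -> 5
  trials <- make_trials(c(1, 1, 1), c(7, 7, 3), c(5, 0, 3))
  errors <- classify_errors(trials, d)
  expect_equal(nrow(errors), 2)
  expect_equal(attr(errors, "n_correct_dropped"), 1)
  expect_equal(errors$sex_match, c(TRUE, FALSE))
  expect_equal(errors$race_match, c(FALSE, FALSE))
  expect_equal(errors$scar_match, c(TRUE, FALSE))
  # 7 -> 0 is the full complement: no overlap at all
  expect_equal(errors$any_overlap, c(TRUE, FALSE))
  expect_message(classify_errors(trials, d, quiet = FALSE), "Dropped 1 correct")
})

test_that("a perfectly accurate cohort yields an empty error table", {
  d <- default_design
  plan <- encoding_plan(d, seed = 2)
  set.seed(1)
  trials <- simulate_recall(1, c(0, 0, 0), plan, d)
  errors <- classify_errors(trials, d)
  expect_equal(nrow(errors), 0)
  expect_equal(attr(errors, "n_correct_dropped"), 24)
})

test_that("categorization scores hit their bounds and symmetry point", {
  d <- default_design
  # 10 errors all to a same-sex face (7 -> 5): sex score +1
  all_within <- make_participant_trials(1, true = 7, chosen = 5, e = 10)
  sc <- categorization_scores(all_within, d)
  expect_equal(sc$sex_score, 1)
  expect_equal(sc$race_score, -1)  # race never shared on 7 -> 5
  # 5 same-sex and 5 different-sex errors: sex score 0
  mixed <- dplyr::bind_rows(
    make_participant_trials(1, true = 7, chosen = 5, e = 5)[1:5, ],
    make_participant_trials(1, true = 7, chosen = 0, e = 5)
  )
  mixed$trial_index <- seq_len(nrow(mixed))
  expect_equal(categorization_scores(mixed, d)$sex_score, 0)
})

test_that("within + between = n_errors for every participant and cue", {
  cohort <- simulate_wsw_cohort(wsw_config(n_participants = 60, seed = 12))
  sc <- categorization_scores(cohort$trials, cohort$design)
  for (cue in c("sex", "race", "scar")) {
    expect_equal(sc[[paste0(cue, "_within")]] + sc[[paste0(cue, "_between")]],
                 sc$n_errors)
  }
  expect_true(all(abs(sc$sex_score) <= 1, na.rm = TRUE))
})

test_that("scores agree with a brute-force per-error recount", {
  cohort <- simulate_wsw_cohort(wsw_config(n_participants = 15, seed = 13))
  d <- cohort$design
  sc <- categorization_scores(cohort$trials, d)
  # oracle: recount every participant/cue from raw trials via match_vector
  for (pid in sc$participant_id) {
    tr <- dplyr::filter(cohort$trials, .data$participant_id == pid, !.data$correct)
    for (cue in c("sex", "race", "scar")) {
      within <- sum(vapply(seq_len(nrow(tr)), function(i) {
        match_vector(d, tr$true_face_id[i], tr$chosen_face_id[i])[[cue]]
      }, logical(1)))
      expect_equal(sc[[paste0(cue, "_within")]][sc$participant_id == pid], within)
      if (nrow(tr) > 0) {
        expect_equal(sc[[paste0(cue, "_score")]][sc$participant_id == pid],
                     (2 * within - nrow(tr)) / nrow(tr))
      }
    }
  }
})

test_that("zero-error participants are flagged, not imputed", {
  d <- default_design
  trials <- dplyr::bind_rows(
    make_participant_trials(1, true = 7, chosen = 5, e = 4),
    make_participant_trials(2, true = 7, chosen = 7, e = 0)
  )
  sc <- categorization_scores(trials, d)
  expect_equal(sc$n_errors, c(4L, 0L))
  expect_true(is.na(sc$sex_score[2]))
  expect_equal(attr(sc, "n_zero_error"), 1L)
  # excluded from aggregates: cue_summary must use n = 1... which is below the
  # t-test minimum, so add a third scored participant with mixed errors
  trials <- dplyr::bind_rows(
    trials,
    make_trials(rep(3, 24), rep(7, 24), c(rep(3, 3), rep(0, 3), rep(7, 18)))
  )
  summary_tbl <- cue_summary(categorization_scores(trials, d))
  expect_equal(unique(summary_tbl$n), 2L)
})

test_that("one-sample test reproduces textbook values and invariances", {
  set.seed(4)
  vals <- with_mean_sd(rnorm(486), 0.29, 0.44)
  res <- one_sample_test(vals, mu0 = 0)
  expect_equal(res$mean, 0.29)
  expect_equal(res$sd, 0.44)
  expect_equal(round(res$cohens_d, 2), 0.66)
  expect_equal(res$df, 485)
  # shift invariance
  shifted <- one_sample_test(vals + 0.5, mu0 = 0.5)
  expect_equal(shifted$statistic, res$statistic)
  expect_equal(shifted$p.value, res$p.value)
  expect_equal(shifted$cohens_d, res$cohens_d)
  # symmetric two-point case
  sym <- one_sample_test(c(-1, 1), mu0 = 0)
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p.value, 1)
  expect_error(one_sample_test(c(2, 2, 2)), class = "wsw_error_test")
  expect_error(one_sample_test(c(1)), class = "wsw_error_test")
})

test_that("pooled overlap from counts matches the printed-count arithmetic", {
  res <- overlap_from_counts(4593, 5143, 6 / 7)
  expect_equal(round(100 * res$pooled$proportion, 1), 89.3)
  expect_lt(res$pooled$p.value, 0.001)
  # all errors overlapping: one-sided binomial p collapses to p0^n
  all_over <- overlap_from_counts(20, 20, 6 / 7)
  expect_equal(all_over$pooled$p.value, (6 / 7)^20)
  expect_error(overlap_from_counts(21, 20, 6 / 7), class = "wsw_error_test")
})

test_that("uniform-guessing cohorts sit at the 6/7 overlap baseline", {
  cfg <- wsw_config(n_participants = 200,
                    weight_means = c(sex = 0, race = 0, scar = 0),
                    weight_cov = diag(c(0, 0, 0)), seed = 14)
  cohort <- simulate_wsw_cohort(cfg)
  ov <- overlap_statistics(cohort$trials, cohort$design)
  expect_equal(ov$baseline, 6 / 7)
  expect_lt(abs(ov$by_participant$mean - 6 / 7), 0.02)
  expect_lt(abs(ov$by_participant$statistic), 2.5)
  expect_gt(ov$by_participant$p.value, 0.01)
})

test_that("overlap statistics flag empty and degenerate inputs", {
  d <- default_design
  no_errors <- make_participant_trials(1, true = 7, chosen = 7, e = 0)
  ov <- overlap_statistics(no_errors, d)
  expect_null(ov$pooled)
  expect_null(ov$by_participant)
  expect_error(overlap_statistics(no_errors, d, baseline = 1.2),
               class = "wsw_error_test")
})
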