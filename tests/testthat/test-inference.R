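# printed coefficients of the canonical interaction model, reused across tests
b_canonical <- c(-0.11, -0.32, -0.15, -0.51)

test_that("noise-free scores are interpolated exactly (R^2 = 1)", {
  scores <- make_exact_scores(b_canonical)
  fit <- fit_interaction_model(scores)
  expect_equal(unname(coef(fit)), b_canonical, tolerance = 1e-12)
  expect_equal(glance(fit)$r.squared, 1, tolerance = 1e-12)
})

test_that("pure-noise outcomes give near-zero R^2 at large n", {
  set.seed(41)
  scores <- tibble::tibble(
    participant_id = 1:4000,
    race_score = rnorm(4000),
    sex_score = rnorm(4000),
    scar_score = rnorm(4000)
  )
  g <- glance(fit_interaction_model(scores))
  expect_lt(g$r.squared, 0.01)
  expect_gt(g$p.value, 0.001)
})

test_that("OLS matches the frozen normal-equations solution on a fixed n = 8 set", {
  scores <- tibble::tibble(
    participant_id = 1:8,
    race_score = c(-0.8, -0.4, -0.2, 0, 0.1, 0.3, 0.6, 0.9),
    sex_score = c(0.5, -0.3, 0.2, -0.6, 0.4, 0, -0.2, 0.7),
    scar_score = c(0.2, -0.1, 0.05, -0.3, 0, 0.15, -0.25, 0.4)
  )
  fit <- fit_interaction_model(scores)
  # frozen from solve(X'X, X'y) on this exact data
  expect_equal(unname(coef(fit)),
               c(-0.021856655782, -0.076926300941, 0.435474459362, 0.254279457284),
               tolerance = 1e-9)
  expect_equal(glance(fit)$r.squared, 0.819252381660, tolerance = 1e-9)
  expect_equal(tidy(fit)$std.error,
               c(0.047878929123, 0.127628379676, 0.116583034109, 0.247072533777),
               tolerance = 1e-9)
})

test_that("OLS agrees with a normal-equations oracle on random small designs", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(8:20, 1)
    scores <- tibble::tibble(
      participant_id = seq_len(n),
      race_score = round(runif(n, -1, 1), 3),
      sex_score = round(runif(n, -1, 1), 3),
      scar_score = round(runif(n, -1, 1), 3)
    )
    fit <- fit_interaction_model(scores)
    X <- cbind(1, scores$race_score, scores$sex_score,
               scores$race_score * scores$sex_score)
    y <- scores$scar_score
    b <- solve(t(X) %*% X, t(X) %*% y)
    res <- y - X %*% b
    v <- as.numeric(crossprod(res) / (n - 4)) * solve(t(X) %*% X)
    expect_equal(unname(coef(fit)), as.numeric(b), tolerance = 1e-8)
    expect_equal(vcov(fit), v, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(glance(fit)$r.squared,
                 1 - sum(res^2) / sum((y - mean(y))^2), tolerance = 1e-8)
  }
})

test_that("degenerate model inputs raise fit errors", {
  scores <- make_exact_scores(b_canonical)
  expect_error(fit_interaction_model(scores, outcome = "scar",
                                     predictors = c("scar", "sex")),
               class = "wsw_error_fit")
  expect_error(fit_interaction_model(scores[1:3, ]), class = "wsw_error_fit")
  const <- dplyr::mutate(scores, race_score = 0.5)
  expect_error(fit_interaction_model(const), class = "wsw_error_fit")
  expect_error(fit_interaction_model(dplyr::rename(scores, foo = "race_score")),
               class = "wsw_error_fit")
})

test_that("simple slopes satisfy their algebraic identities exactly", {
  set.seed(43)
  scores <- tibble::tibble(
    participant_id = 1:60,
    race_score = rnorm(60),
    sex_score = rnorm(60),
    scar_score = rnorm(60)
  )
  fit <- fit_interaction_model(scores)
  cf <- coef(fit)
  v <- vcov(fit)
  levels <- c(low = -0.7, mid = 0.1, high = 1.3)
  sl <- simple_slopes(fit, moderator = "sex", levels = levels)
  expect_equal(sl$estimate,
               unname(cf["race_score"] + cf["race_score:sex_score"] * levels))
  expect_equal(
    sl$std.error,
    unname(sqrt(v["race_score", "race_score"] +
                  levels^2 * v["race_score:sex_score", "race_score:sex_score"] +
                  2 * levels * v["race_score", "race_score:sex_score"]))
  )
  # v = 0 reduces to the focal coefficient itself
  at0 <- simple_slopes(fit, moderator = "sex", levels = c(zero = 0))
  expect_equal(at0$estimate, unname(cf["race_score"]))
  expect_equal(at0$std.error, unname(sqrt(v["race_score", "race_score"])))
  expect_equal(at0$statistic, tidy(fit)$statistic[2])
  # default levels are mean and mean +/- 1 SD of the moderator
  dflt <- simple_slopes(fit, moderator = "sex")
  m <- mean(scores$sex_score)
  s <- sd(scores$sex_score)
  expect_equal(dflt$moderator_value, c(m - s, m, m + s))
  expect_error(simple_slopes(fit, moderator = "scar"), class = "wsw_error_fit")
})

test_that("slope contrasts equal the interaction effect scaled by the level gap", {
  scores <- make_exact_scores(b_canonical)
  noisy <- dplyr::mutate(scores,
                         scar_score = scar_score + with_mean_sd(sin(1:49), 0, 0.05))
  fit <- fit_interaction_model(noisy)
  ct <- slope_contrast(fit, "sex", -0.5, 0.8)
  b3 <- coef(fit)[["race_score:sex_score"]]
  expect_equal(ct$estimate, b3 * 1.3)
  # contrast t == interaction t in magnitude, for any level pair
  expect_equal(abs(ct$statistic), abs(tidy(fit)$statistic[4]), tolerance = 1e-12)
  ct2 <- slope_contrast(fit, "sex", 0.1, 0.2)
  expect_equal(abs(ct2$statistic), abs(ct$statistic), tolerance = 1e-12)
  # antisymmetry under swapped levels
  swapped <- slope_contrast(fit, "sex", 0.8, -0.5)
  expect_equal(swapped$estimate, -ct$estimate)
  expect_equal(swapped$std.error, ct$std.error)
  expect_error(slope_contrast(fit, "sex", 0.3, 0.3), class = "wsw_error_contrast")
})

test_that("nested model comparison matches the RSS-based oracle", {
  set.seed(44)
  n <- 120
  scores <- tibble::tibble(
    participant_id = seq_len(n),
    race_score = rnorm(n),
    sex_score = rnorm(n),
    scar_score = rnorm(n)
  )
  covars <- tibble::tibble(
    participant_id = seq_len(n),
    z1 = rnorm(n),
    z2 = rnorm(n)
  )
  reduced <- fit_covariate_model(scores, covars,
                                 formula = scar_score ~ race_score * sex_score)
  full <- fit_covariate_model(scores, covars)
  cmp <- nested_model_comparison(full, reduced)
  oracle <- stats::anova(reduced$model, full$model)
  expect_equal(cmp$statistic, oracle$F[2], tolerance = 1e-10)
  expect_equal(cmp$p.value, oracle$`Pr(>F)`[2], tolerance = 1e-10)
  expect_equal(cmp$df1, oracle$Df[2])
  # identical models compare as a null change
  self <- nested_model_comparison(full, full)
  expect_equal(self$delta.r.squared, 0)
  expect_equal(self$statistic, 0)
  expect_equal(self$p.value, 1)
  expect_error(nested_model_comparison(reduced, full), class = "wsw_error_comparison")
})

test_that("delta-F over pure-noise covariates is calibrated to its F null", {
  set.seed(45)
  pvals <- purrr::map_dbl(1:150, function(r) {
    n <- 40
    scores <- tibble::tibble(
      participant_id = seq_len(n),
      race_score = rnorm(n),
      sex_score = rnorm(n),
      scar_score = rnorm(n)
    )
    covars <- tibble::tibble(participant_id = seq_len(n),
                             z1 = rnorm(n), z2 = rnorm(n))
    full <- fit_covariate_model(scores, covars)
    reduced <- fit_covariate_model(scores, covars,
                                   formula = scar_score ~ race_score * sex_score)
    nested_model_comparison(full, reduced)$p.value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(pvals < 0.5) - 0.5), 0.15)
})

test_that("covariate models join, dummy-code, subset, and recover planted effects", {
  cohort <- simulate_wsw_cohort(wsw_config(n_participants = 400, seed = 46))
  scores <- categorization_scores(cohort$trials, cohort$design)
  set.seed(47)
  covars <- tibble::tibble(
    participant_id = scores$participant_id,
    exposure_frequency = sample(1:5, nrow(scores), replace = TRUE),
    acquaintance = sample(c("none", "family", "coworker"), nrow(scores),
                          replace = TRUE, prob = c(0.6, 0.2, 0.2)),
    age = sample(18:65, nrow(scores), replace = TRUE)
  )
  # plant a linear exposure effect on the outcome
  planted <- 0.05
  scores$scar_score <- scores$scar_score + planted * covars$exposure_frequency
  fit <- fit_covariate_model(scores, covars)
  est <- tidy(fit)
  row <- est[est$term == "exposure_frequency", ]
  expect_lt(abs(row$estimate - planted), 2.5 * row$std.error)
  # modal category is the dummy reference: no "none" level among terms
  expect_false(any(grepl("acquaintancenone", est$term)))
  # constant covariates reduce to the core interaction model
  const <- tibble::tibble(participant_id = scores$participant_id, c1 = 1)
  expect_message(fit_const <- fit_covariate_model(scores, const), "constant")
  core <- fit_interaction_model(scores)
  expect_equal(coef(fit_const), coef(core))
  # subsetting by covariate value
  older <- fit_covariate_model(scores, covars, subset = age >= 30)
  expect_equal(older$n, sum(covars$age >= 30 & scores$n_errors > 0))
  # join diagnostics
  expect_error(
    fit_covariate_model(scores, dplyr::mutate(covars, participant_id = participant_id + 10000)),
    class = "wsw_error_join"
  )
  partial <- fit_covariate_model(scores, covars[1:200, ])
  expect_equal(partial$n_unmatched, nrow(scores) - 200L)
})
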