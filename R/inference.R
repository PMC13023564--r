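#' Fit the cue-interdependence interaction regression
#'
#' Ordinary least squares of one cue's categorization score on two other
#' cues' scores and their product, on uncentered scores:
#' `outcome ~ b0 + b1 * predictor1 + b2 * predictor2 + b3 * predictor1:predictor2`.
#' The canonical analysis regresses scar-based categorization on race- and
#' sex-based categorization to ask whether anomaly-based grouping shrinks
#' when the dominant social cues are strongly encoded. Participants with
#' undefined scores (zero errors) are dropped listwise.
#'
#' @param scores A [categorization_scores()] table (or any data frame with
#'   `<cue>_score` columns and `participant_id`).
#' @param outcome Outcome cue name (default `"scar"`).
#' @param predictors Character vector of the two predictor cues; the second
#'   is the conventional moderator for [simple_slopes()]. Default
#'   `c("race", "sex")`.
#'
#' @return An object of class `wsw_fit` wrapping the [stats::lm] fit, with
#'   [generics::tidy()] and [generics::glance()] methods.
#'
#' @examples
#' cohort <- simulate_wsw_cohort(wsw_config(n_participants = 200, seed = 1))
#' scores <- categorization_scores(cohort$trials, cohort$design)
#' fit <- fit_interaction_model(scores)
#' tidy(fit)
#' glance(fit)
#' @export
fit_interaction_model <- function(scores, outcome = "scar",
                                  predictors = c("race", "sex")) {
  if (length(predictors) != 2 || outcome %in% predictors) {
    abort_wsw("`predictors` must be two cues distinct from `outcome`.", "fit")
  }
  cols <- paste0(c(outcome, predictors), "_score")
  missing <- setdiff(cols, names(scores))
  if (length(missing) > 0) {
    abort_wsw(paste0("Missing score column(s): ", paste(missing, collapse = ", ")),
              "fit")
  }
  dat <- scores[stats::complete.cases(scores[, cols]), , drop = FALSE]
  n_dropped <- nrow(scores) - nrow(dat)
  if (nrow(dat) < 5) {
    abort_wsw("Need at least 5 complete rows to fit the interaction model.", "fit")
  }
  f <- stats::as.formula(paste0(cols[1], " ~ ", cols[2], " * ", cols[3]))
  fit_wsw_lm(f, dat, outcome, predictors, n_dropped)
}

# shared constructor for interaction and covariate models
fit_wsw_lm <- function(formula, dat, outcome, predictors, n_dropped) {
  model <- stats::lm(formula, data = dat)
  if (model$rank < length(stats::coef(model)) || anyNA(stats::coef(model))) {
    abort_wsw("Rank-deficient design (constant or collinear predictors).", "fit")
  }
  structure(
    list(
      model = model,
      formula = formula,
      outcome = outcome,
      predictors = predictors,
      data = dat,
      n = nrow(dat),
      n_dropped = n_dropped
    ),
    class = "wsw_fit"
  )
}

#' Fit the interaction model with participant-level covariates
#'
#' Extends [fit_interaction_model()] with covariates joined on
#' `participant_id` (for instance exposure frequency, acquaintance type,
#' self-scar status, or age). Character covariates are dummy-coded with the
#' modal category as reference. Rows with missing covariates are deleted
#' listwise, with counts recorded on the returned object.
#'
#' @inheritParams fit_interaction_model
#' @param covariates Data frame keyed by `participant_id`.
#' @param formula Optional model formula overriding the default
#'   `<outcome>_score ~ <p1>_score * <p2>_score + <each covariate>`; use it
#'   for alternative structures such as `scar_score ~ age * exposure_frequency`.
#' @param subset Optional unquoted logical expression evaluated in the
#'   joined data (e.g. `age >= 30`) selecting the analysis rows.
#'
#' @return A `wsw_fit` (see [fit_interaction_model()]); `n_unmatched`
#'   records participants in `scores` without covariate rows.
#' @export
fit_covariate_model <- function(scores, covariates, outcome = "scar",
                                predictors = c("race", "sex"),
                                formula = NULL, subset = NULL) {
  if (!"participant_id" %in% names(covariates)) {
    abort_wsw("`covariates` must contain `participant_id`.", "join")
  }
  if (anyDuplicated(covariates$participant_id)) {
    abort_wsw("`covariates` must have one row per participant.", "join")
  }
  unmatched <- setdiff(scores$participant_id, covariates$participant_id)
  if (length(unmatched) == nrow(scores)) {
    abort_wsw("No participants in `scores` match `covariates`.", "join")
  }
  dat <- dplyr::inner_join(
    tibble::as_tibble(scores), tibble::as_tibble(covariates),
    by = "participant_id"
  )
  subset_quo <- rlang::enquo(subset)
  if (!rlang::quo_is_null(subset_quo)) {
    keep <- rlang::eval_tidy(subset_quo, data = dat)
    dat <- dat[!is.na(keep) & keep, , drop = FALSE]
  }
  cov_cols <- setdiff(names(covariates), "participant_id")
  # a constant covariate carries no information and would only break the fit
  constant <- cov_cols[vapply(cov_cols, function(col) {
    length(unique(dat[[col]][!is.na(dat[[col]])])) < 2
  }, logical(1))]
  if (length(constant) > 0 && is.null(formula)) {
    rlang::inform(paste0("Dropping constant covariate(s): ",
                         paste(constant, collapse = ", ")))
    cov_cols <- setdiff(cov_cols, constant)
  }
  for (col in cov_cols) {
    if (is.character(dat[[col]]) || is.factor(dat[[col]])) {
      x <- as.character(dat[[col]])
      modal <- names(sort(table(x), decreasing = TRUE))[1]
      dat[[col]] <- stats::relevel(factor(x), ref = modal)
    }
  }
  if (is.null(formula)) {
    cols <- paste0(c(outcome, predictors), "_score")
    formula <- stats::as.formula(
      paste0(cols[1], " ~ ", cols[2], " * ", cols[3],
             if (length(cov_cols) > 0) paste0(" + ", paste(cov_cols, collapse = " + ")) else "")
    )
  }
  used <- all.vars(formula)
  complete <- stats::complete.cases(dat[, intersect(used, names(dat)), drop = FALSE])
  n_dropped <- sum(!complete)
  dat <- dat[complete, , drop = FALSE]
  if (nrow(dat) < 5) abort_wsw("Need at least 5 complete rows.", "fit")
  fit <- fit_wsw_lm(formula, dat, outcome, predictors, n_dropped)
  fit$n_unmatched <- length(unmatched)
  fit
}

#' @export
print.wsw_fit <- function(x, ...) {
  g <- generics::glance(x)
  cat("<wsw_fit> ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  n = %d, R^2 = %.3f, F(%d, %d) = %.2f, p = %.3g\n",
              g$nobs, g$r.squared, g$df, g$df.residual, g$statistic, g$p.value))
  print(generics::tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_interaction_model
#' @param x,object A `wsw_fit`.
#' @param ... Unused.
#' @export
tidy.wsw_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = unname(s[, "Estimate"]),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' @rdname fit_interaction_model
#' @export
glance.wsw_fit <- function(x, ...) {
  s <- summary(x$model)
  fstat <- s$fstatistic
  tibble::tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    statistic = unname(fstat["value"]),
    df = as.integer(fstat["numdf"]),
    df.residual = as.integer(fstat["dendf"]),
    p.value = unname(stats::pf(fstat["value"], fstat["numdf"], fstat["dendf"],
                               lower.tail = FALSE)),
    nobs = x$n,
    n_dropped = x$n_dropped
  )
}

#' @export
coef.wsw_fit <- function(object, ...) stats::coef(object$model)

#' @export
vcov.wsw_fit <- function(object, ...) stats::vcov(object$model)

# coefficient bookkeeping for slope machinery
slope_terms <- function(fit, moderator) {
  if (!moderator %in% fit$predictors) {
    abort_wsw(sprintf("`%s` is not a predictor of this model.", moderator), "fit")
  }
  focal <- setdiff(fit$predictors, moderator)
  focal_term <- paste0(focal, "_score")
  mod_term <- paste0(moderator, "_score")
  cf <- stats::coef(fit$model)
  int_term <- intersect(
    c(paste0(focal_term, ":", mod_term), paste0(mod_term, ":", focal_term)),
    names(cf)
  )
  if (length(int_term) != 1) {
    abort_wsw("Model does not contain the focal-by-moderator interaction term.", "fit")
  }
  list(focal = focal, focal_term = focal_term, mod_term = mod_term,
       int_term = int_term)
}

#' Simple slopes of the focal predictor at moderator levels
#'
#' Conditional slope of the focal cue at fixed values of the moderator:
#' `slope(v) = b_focal + b_interaction * v`, with delta-method standard
#' error `sqrt(Var(b1) + v^2 Var(b3) + 2 v Cov(b1, b3))` from the
#' coefficient covariance and t-tests on the residual degrees of freedom.
#' Default levels are the moderator's mean and mean +/- 1 SD in the fitted
#' data (raw, uncentered values).
#'
#' @param fit A `wsw_fit` from [fit_interaction_model()].
#' @param moderator Name of the moderating cue (default: the second
#'   predictor).
#' @param levels Optional numeric vector of moderator values; names are
#'   used as level labels.
#'
#' @return A tibble of class `wsw_slopes`: `level`, `moderator_value`,
#'   `estimate`, `std.error`, `statistic`, `p.value`; all pairwise level
#'   contrasts are in the `contrasts` attribute (see [slope_contrast()]).
#'
#' @examples
#' cohort <- simulate_wsw_cohort(wsw_config(n_participants = 200, seed = 1))
#' scores <- categorization_scores(cohort$trials, cohort$design)
#' fit <- fit_interaction_model(scores)
#' simple_slopes(fit)
#' @export
simple_slopes <- function(fit, moderator = NULL, levels = NULL) {
  if (is.null(moderator)) moderator <- fit$predictors[2]
  st <- slope_terms(fit, moderator)
  if (is.null(levels)) {
    modcol <- fit$data[[st$mod_term]]
    m <- mean(modcol)
    s <- stats::sd(modcol)
    levels <- c("-1 SD (Low)" = m - s, "Mean" = m, "+1 SD (High)" = m + s)
  }
  if (is.null(names(levels))) {
    names(levels) <- sprintf("%.3g", levels)
  }
  cf <- stats::coef(fit$model)
  v <- stats::vcov(fit$model)
  b1 <- cf[st$focal_term]
  b3 <- cf[st$int_term]
  var1 <- v[st$focal_term, st$focal_term]
  var3 <- v[st$int_term, st$int_term]
  cov13 <- v[st$focal_term, st$int_term]
  df <- stats::df.residual(fit$model)
  slope <- unname(b1 + b3 * levels)
  se <- sqrt(var1 + levels^2 * var3 + 2 * levels * cov13)
  tval <- slope / se
  out <- tibble::tibble(
    level = names(levels),
    moderator_value = unname(levels),
    estimate = slope,
    std.error = unname(se),
    statistic = unname(tval),
    p.value = 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  )
  contrasts <- NULL
  if (length(levels) >= 2) {
    pairs <- utils::combn(seq_along(levels), 2)
    contrasts <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]
      b <- pairs[2, j]
      res <- slope_contrast(fit, moderator, levels[a], levels[b])
      dplyr::bind_cols(
        tibble::tibble(contrast = paste(names(levels)[a], names(levels)[b], sep = " ~ ")),
        res
      )
    })
  }
  structure(
    out,
    contrasts = contrasts,
    moderator = moderator,
    focal = st$focal,
    class = c("wsw_slopes", class(tibble::tibble()))
  )
}

#' Contrast between two simple slopes
#'
#' Difference between the focal predictor's slopes at two moderator values:
#' `estimate = b_interaction * (level_b - level_a)` with
#' `SE = |level_b - level_a| * SE(b_interaction)`. The t statistic
#' therefore equals the interaction coefficient's t in magnitude for every
#' pair of distinct levels.
#'
#' @inheritParams simple_slopes
#' @param level_a,level_b Two distinct moderator values.
#'
#' @return A one-row tibble: `estimate`, `std.error`, `statistic`,
#'   `p.value`, `level_a`, `level_b`.
#' @export
slope_contrast <- function(fit, moderator = NULL, level_a, level_b) {
  if (is.null(moderator)) moderator <- fit$predictors[2]
  st <- slope_terms(fit, moderator)
  if (isTRUE(all.equal(level_a, level_b))) {
    abort_wsw("`level_a` and `level_b` must differ.", "contrast")
  }
  b3 <- stats::coef(fit$model)[st$int_term]
  se3 <- sqrt(stats::vcov(fit$model)[st$int_term, st$int_term])
  est <- unname(b3 * (level_b - level_a))
  se <- abs(level_b - level_a) * se3
  tval <- est / se
  df <- stats::df.residual(fit$model)
  tibble::tibble(
    estimate = est,
    std.error = unname(se),
    statistic = unname(tval),
    p.value = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
    level_a = unname(level_a),
    level_b = unname(level_b)
  )
}

#' @export
print.wsw_slopes <- function(x, ...) {
  cat(sprintf("Simple slopes of %s at levels of %s\n",
              attr(x, "focal"), attr(x, "moderator")))
  NextMethod()
  cat("\nSlope contrasts:\n")
  print(attr(x, "contrasts"))
  invisible(x)
}

#' Nested OLS model comparison
#'
#' Incremental-fit F-test between two nested fits of the same outcome on
#' the same rows:
#' `dF = ((R2_full - R2_reduced) / q) / ((1 - R2_full) / df_resid_full)`,
#' where `q` is the number of added parameters. Identical models give
#' `dR2 = 0`, `dF = 0`, `p = 1`.
#'
#' @param fit_full,fit_reduced `wsw_fit` objects; the reduced model's terms
#'   must be a subset of the full model's.
#'
#' @return A one-row tibble: `delta.r.squared`, `statistic` (delta F),
#'   `df1`, `df2`, `p.value`.
#' @export
nested_model_comparison <- function(fit_full, fit_reduced) {
  if (!identical(fit_full$outcome, fit_reduced$outcome)) {
    abort_wsw("Models must share the same outcome.", "comparison")
  }
  if (fit_full$n != fit_reduced$n) {
    abort_wsw("Models must be fitted on the same rows.", "comparison")
  }
  terms_full <- attr(stats::terms(fit_full$model), "term.labels")
  terms_red <- attr(stats::terms(fit_reduced$model), "term.labels")
  if (!all(terms_red %in% terms_full)) {
    abort_wsw("Models are not nested (reduced terms not a subset of full terms).",
              "comparison")
  }
  r2_full <- summary(fit_full$model)$r.squared
  r2_red <- summary(fit_reduced$model)$r.squared
  q <- length(stats::coef(fit_full$model)) - length(stats::coef(fit_reduced$model))
  df2 <- stats::df.residual(fit_full$model)
  if (q == 0) {
    return(tibble::tibble(delta.r.squared = 0, statistic = 0,
                          df1 = 0L, df2 = df2, p.value = 1))
  }
  dr2 <- r2_full - r2_red
  f <- (dr2 / q) / ((1 - r2_full) / df2)
  tibble::tibble(
    delta.r.squared = dr2,
    statistic = f,
    df1 = as.integer(q),
    df2 = as.integer(df2),
    p.value = stats::pf(f, q, df2, lower.tail = FALSE)
  )
}
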