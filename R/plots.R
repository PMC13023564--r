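#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the null distribution of a statistic
#'
#' Histogram of the null replicates with the observed value marked, in the
#' style of a permutation-test figure: if the observed line sits beyond the
#' bulk of the null, the statistic exceeds what shared-error-pool
#' constraints alone produce.
#'
#' @param object A [run_null_simulation()] result.
#' @param statistic Which tracked statistic to show (default `"r2"`).
#' @param bins Histogram bins.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.wsw_nullsim <- function(object, statistic = "r2", bins = 50, ...) {
  if (!statistic %in% names(object$replicates)) {
    abort_wsw(sprintf("Unknown statistic `%s`.", statistic), "nullsim")
  }
  obs <- object$observed[[statistic]]
  ggplot2::ggplot(object$replicates, ggplot2::aes(x = .data[[statistic]])) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = obs, colour = "red", linewidth = 0.8) +
    ggplot2::labs(
      x = statistic,
      y = "null replicates",
      title = sprintf("Constrained null distribution of %s", statistic),
      subtitle = sprintf("observed = %.3f (red), %d replicates",
                         obs, nrow(object$replicates))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_simple_slopes
#' @export
autoplot.wsw_slopes <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$moderator_value, y = .data$estimate)
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(
        ymin = .data$estimate - 1.96 * .data$std.error,
        ymax = .data$estimate + 1.96 * .data$std.error
      )
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("%s-based categorization (moderator level)", attr(object, "moderator")),
      y = sprintf("slope of %s-based categorization", attr(object, "focal")),
      title = "Simple slopes"
    ) +
    ggplot2::theme_minimal()
}

#' Interaction plot of predicted outcome lines at moderator levels
#'
#' Predicted outcome score as a function of the focal cue, one line per
#' moderator level, with pointwise 95% confidence ribbons from the fitted
#' model.
#'
#' @param fit A [fit_interaction_model()] result.
#' @param moderator Moderating cue (default: the model's second predictor).
#' @param levels Moderator values (default mean and mean +/- 1 SD).
#' @param n_grid Points along the focal axis.
#' @param object A `wsw_slopes` object (for the `autoplot` method).
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
plot_simple_slopes <- function(fit, moderator = NULL, levels = NULL, n_grid = 50) {
  if (is.null(moderator)) moderator <- fit$predictors[2]
  st <- slope_terms(fit, moderator)
  if (is.null(levels)) {
    modcol <- fit$data[[st$mod_term]]
    m <- mean(modcol)
    s <- stats::sd(modcol)
    levels <- c("-1 SD (Low)" = m - s, "Mean" = m, "+1 SD (High)" = m + s)
  }
  if (is.null(names(levels))) names(levels) <- sprintf("%.3g", levels)
  focal_range <- range(fit$data[[st$focal_term]])
  grid <- tidyr::expand_grid(
    focal = seq(focal_range[1], focal_range[2], length.out = n_grid),
    level = names(levels)
  )
  grid$moderator <- unname(levels[grid$level])
  newdata <- stats::setNames(
    data.frame(grid$focal, grid$moderator),
    c(st$focal_term, st$mod_term)
  )
  pred <- stats::predict(fit$model, newdata = newdata, interval = "confidence")
  grid <- dplyr::bind_cols(grid, tibble::as_tibble(pred))
  ggplot2::ggplot(
    grid,
    ggplot2::aes(x = .data$focal, y = .data$fit, colour = .data$level,
                 fill = .data$level)
  ) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lwr, ymax = .data$upr),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = sprintf("%s-based categorization", st$focal),
      y = sprintf("predicted %s-based categorization", fit$outcome),
      colour = sprintf("%s level", moderator),
      fill = sprintf("%s level", moderator)
    ) +
    ggplot2::theme_minimal()
}

#' Mean categorization strength per cue
#'
#' Bar chart of participant-mean categorization scores with +/- 1 SE error
#' bars and the uniform-guessing chance line.
#'
#' @param object A [categorization_scores()] table.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.wsw_scores <- function(object, ...) {
  summary_tbl <- cue_summary(object)
  chance <- attr(object, "chance_score")
  p <- ggplot2::ggplot(
    summary_tbl,
    ggplot2::aes(x = .data$cue, y = .data$mean)
  ) +
    ggplot2::geom_col(fill = "grey70", colour = "grey40") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd / sqrt(.data$n),
                   ymax = .data$mean + .data$sd / sqrt(.data$n)),
      width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "mean categorization score (+/- SE)") +
    ggplot2::theme_minimal()
  if (!is.null(chance)) {
    p <- p + ggplot2::geom_hline(yintercept = chance, linetype = "dashed",
                                 colour = "red")
  }
  p
}
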