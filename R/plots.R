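#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_line
#'   geom_errorbar geom_hline facet_wrap facet_grid labs position_dodge
#'   theme_minimal
#' @export
ggplot2::autoplot

#' Plot observed versus fitted count frequencies
#'
#' Compares the observed frequency of each count value with the frequency
#' implied by the fitted model (averaging each observation's fitted pmf),
#' the standard graphical check for zero-inflation and dispersion misfit.
#'
#' @param object A converged `count_fit`.
#' @param max_count Largest count value displayed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.count_fit <- function(object, max_count = NULL, ...) {
  if (!object$converged) abort("cannot plot a non-converged fit.")
  y <- object$y
  max_count <- max_count %||% max(y)
  counts <- 0:max_count
  mu <- exp(drop(object$X %*% object$coefficients$count))
  phi <- if (.has_phi(object$family)) {
    .zero_prob(drop(object$Z %*% object$coefficients$zero), object$zero_link)
  } else {
    rep(0, length(y))
  }
  alpha <- object$coefficients$alpha
  fitted_freq <- vapply(counts, function(k) {
    base <- if (.has_alpha(object$family)) {
      exp(.nb_logpmf(k, mu, 1 / alpha))
    } else {
      dpois(k, mu)
    }
    mean((1 - phi) * base + phi * (k == 0))
  }, numeric(1))
  df <- tibble::tibble(
    count = rep(counts, 2),
    frequency = c(as.numeric(table(factor(y, levels = counts))) / length(y),
                  fitted_freq),
    source = rep(c("observed", "fitted"), each = length(counts))
  )
  ggplot(df, aes(x = .data$count, y = .data$frequency, fill = .data$source)) +
    geom_col(position = position_dodge(), width = 0.8) +
    labs(title = sprintf("%s fit: observed vs fitted count frequencies",
                         toupper(object$family)),
         x = "count", y = "relative frequency", fill = NULL) +
    theme_minimal()
}

#' Plot scenario summaries of a simulation study
#'
#' Shows a chosen metric (mean AIC by default) against sample size, one
#' line per fitted model, faceted by the generating family's dispersion
#' and zero-proportion factors where present.
#'
#' @param object A `count_study`.
#' @param metric One of `"mean_aic"`, `"mean_bic"`, `"mean_mae"`,
#'   `"convergence_rate"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.count_study <- function(object, metric = "mean_aic", ...) {
  metric <- match.arg(metric, c("mean_aic", "mean_bic", "mean_mae",
                                "convergence_rate"))
  s <- object$summaries
  p <- ggplot(s, aes(x = .data$n, y = .data[[metric]],
                     colour = .data$model, group = .data$model)) +
    geom_line() + geom_point() +
    labs(x = "sample size", y = metric, colour = "fitted model") +
    theme_minimal()
  has_d <- "dispersion" %in% names(s) && !all(is.na(s$dispersion))
  has_z <- "zero_prop" %in% names(s) && !all(is.na(s$zero_prop))
  if (has_d && has_z) {
    p <- p + facet_grid(dispersion ~ zero_prop, labeller = "label_both")
  } else if (has_d) {
    p <- p + facet_wrap(~dispersion, labeller = "label_both")
  } else if (has_z) {
    p <- p + facet_wrap(~zero_prop, labeller = "label_both")
  }
  p
}

#' Plot count-part coefficients across compared models
#'
#' Forest-style plot of the count-part estimates with 95% Wald intervals,
#' one colour per model, highlighting how overdispersion widens NB/ZINB
#' intervals relative to Poisson/ZIP.
#'
#' @param object A `count_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.count_comparison <- function(object, ...) {
  cc <- dplyr::filter(object$coefficients, .data$part == "count",
                      .data$term != "(Intercept)")
  ggplot(cc, aes(x = .data$estimate, y = .data$term, colour = .data$model)) +
    geom_point(position = position_dodge(width = 0.6)) +
    geom_errorbar(aes(xmin = .data$estimate - 1.96 * .data$std.error,
                      xmax = .data$estimate + 1.96 * .data$std.error),
                  position = position_dodge(width = 0.6), width = 0.2) +
    geom_hline(yintercept = 0, linetype = 0) +
    labs(x = "count-part estimate (log scale)", y = NULL, colour = "model") +
    theme_minimal()
}
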