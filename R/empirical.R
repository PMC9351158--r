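#' Descriptive summary of a count-outcome table
#'
#' Summarizes the outcome (n, mean, variance, SD, zero fraction, range) and
#' every categorical covariate (frequency and percentage per level), and
#' flags a variance well above the mean as an overdispersion signal.
#'
#' @param data A data frame.
#' @param outcome Name of the count outcome column.
#' @return A list of class `count_descriptives` with elements `outcome`
#'   (one-row tibble), `categories` (long tibble: variable, level, n,
#'   percent) and `overdispersed` (logical, variance > mean).
#' @examples
#' describe_counts(sim_los(300, seed = 1), "los")
#' @export
describe_counts <- function(data, outcome) {
  data <- tibble::as_tibble(data)
  if (!outcome %in% names(data)) abort(sprintf("column '%s' not found.", outcome))
  y <- data[[outcome]]
  .check_counts(y, arg = outcome)
  out <- tibble::tibble(
    variable = outcome, n = length(y), mean = mean(y),
    variance = stats::var(y), sd = stats::sd(y),
    zero_fraction = mean(y == 0), min = min(y), max = max(y)
  )
  cat_cols <- names(data)[vapply(data, function(x) is.character(x) || is.factor(x),
                                 logical(1))]
  categories <- purrr::map_dfr(cat_cols, function(v) {
    tab <- table(data[[v]])
    tibble::tibble(variable = v, level = names(tab), n = as.integer(tab),
                   percent = 100 * as.integer(tab) / length(y))
  })
  structure(list(outcome = out, categories = categories,
                 overdispersed = out$variance > out$mean),
            class = "count_descriptives")
}

#' @export
print.count_descriptives <- function(x, ...) {
  o <- x$outcome
  cat(sprintf("%s: n = %d, mean = %.2f, variance = %.2f (SD %.2f), %.1f%% zeros, range %d-%d\n",
              o$variable, o$n, o$mean, o$variance, o$sd,
              100 * o$zero_fraction, o$min, o$max))
  if (x$overdispersed) {
    cat("variance exceeds mean: overdispersion signal (Poisson equidispersion violated)\n")
  }
  if (nrow(x$categories) > 0) print(x$categories, n = Inf)
  invisible(x)
}

#' Fit and compare the four count regression models on one table
#'
#' Fits Poisson, NB, ZIP and ZINB regressions of a count outcome on the
#' same covariates (categoricals dummy-coded against declared reference
#' levels; for ZIP/ZINB the same predictors enter the count model and the
#' logistic zero model), and assembles a comparison report: the per-model
#' coefficient table with Wald inference, and per-model fit statistics
#' (log-likelihood, AIC, BIC, Pearson dispersion) ranked by AIC.
#' Non-converged fits are flagged in the report, never dropped silently;
#' separation in the zero part yields a converged-with-boundary flag with
#' the resulting large standard errors reported as-is.
#'
#' @param data A data frame.
#' @param outcome Name of the count outcome column.
#' @param covariates Character vector of covariate column names.
#' @param reference_levels Named character vector mapping categorical
#'   covariates to their reference level (defaults match a hospital
#'   length-of-stay analysis: male sex, self-pay insurance, urgent
#'   admission).
#' @param families Models to fit (default all four).
#' @param zero_link Zero-part link for the zero-inflated models.
#' @return An object of class `count_comparison`: list with `coefficients`
#'   (long tibble with a `model` column), `fit_stats` (one row per model,
#'   AIC-ranked), `fits` (the `count_fit` objects) and `descriptives`.
#' @examples
#' los <- sim_los(400, seed = 5)
#' cmp <- compare_count_models(los, "los", c("age", "sex"))
#' cmp$fit_stats
#' @export
compare_count_models <- function(data, outcome, covariates,
                                 reference_levels = c(sex = "male",
                                                      insurance = "self_pay",
                                                      admission_type = "urgent"),
                                 families = c("poisson", "nb", "zip", "zinb"),
                                 zero_link = "logit") {
  data <- as.data.frame(data)
  if (!outcome %in% names(data)) abort(sprintf("column '%s' not found.", outcome))
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov) > 0) {
    abort(sprintf("covariate column(s) not found: %s.", paste(missing_cov, collapse = ", ")))
  }
  covariates <- sort(covariates)  # report invariant to covariate order
  for (v in covariates) {
    if (is.character(data[[v]]) || is.factor(data[[v]])) {
      data[[v]] <- factor(data[[v]])
      ref <- reference_levels[[v]]
      if (!is.null(ref) && !is.na(ref)) {
        if (!ref %in% levels(data[[v]])) {
          abort(sprintf("reference level '%s' not present in '%s'.", ref, v))
        }
        data[[v]] <- stats::relevel(data[[v]], ref = ref)
      }
    }
  }
  fml <- stats::reformulate(covariates, response = outcome)
  zf <- stats::reformulate(covariates)
  fits <- purrr::map(setNames(families, families), function(fam) {
    fit_count(data, fml, family = fam,
              zero = if (.has_phi(fam)) zf else ~1, zero_link = zero_link)
  })
  coefs <- purrr::map_dfr(fits, function(f) {
    if (!f$converged) return(tibble::tibble())
    dplyr::mutate(tidy(f), model = f$family, significant = .data$p.value < 0.05,
                  .before = 1)
  })
  stats_tab <- purrr::map_dfr(fits, glance) |>
    dplyr::mutate(pearson_dispersion = purrr::map_dbl(fits, function(f) {
      if (f$converged) pearson_dispersion(f) else NA_real_
    })) |>
    dplyr::arrange(dplyr::desc(.data$converged), .data$AIC)
  structure(list(coefficients = coefs, fit_stats = stats_tab, fits = fits,
                 descriptives = describe_counts(data, outcome),
                 outcome = outcome, covariates = covariates),
            class = "count_comparison")
}

#' @export
print.count_comparison <- function(x, ...) {
  cat(format_comparison(x), sep = "\n")
  invisible(x)
}

#' Human-readable rendering of a model comparison report
#'
#' @param report A `count_comparison`.
#' @return A character vector of report lines.
#' @export
format_comparison <- function(report) {
  stopifnot(inherits(report, "count_comparison"))
  lines <- c(
    sprintf("Count-model comparison for '%s' on %s (n = %d)",
            report$outcome, paste(report$covariates, collapse = ", "),
            report$descriptives$outcome$n),
    "",
    "Model fit (AIC-ranked):",
    sprintf("  %-8s logLik %10.2f  AIC %10.2f  BIC %10.2f  Pearson disp %7.4f%s",
            report$fit_stats$family, report$fit_stats$logLik,
            report$fit_stats$AIC, report$fit_stats$BIC,
            report$fit_stats$pearson_dispersion,
            ifelse(report$fit_stats$converged, "", "  [NOT CONVERGED]")),
    ""
  )
  for (m in unique(report$coefficients$model)) {
    cc <- dplyr::filter(report$coefficients, .data$model == m)
    lines <- c(lines, sprintf("%s coefficients:", toupper(m)),
               sprintf("  %-11s %-22s % 10.4f (%.4g)  p = %s%s",
                       cc$part, cc$term, cc$estimate, cc$std.error,
                       ifelse(is.na(cc$p.value), "  --  ",
                              formatC(cc$p.value, digits = 4, format = "f")),
                       ifelse(!is.na(cc$significant) & cc$significant, " *", "")),
               "")
  }
  lines
}

#' Write a comparison report to disk
#'
#' Writes the long coefficient table as CSV and, optionally, the
#' human-readable rendering as a text file.
#'
#' @param report A `count_comparison`.
#' @param csv_path Path for the coefficient CSV.
#' @param text_path Optional path for the text rendering.
#' @return `csv_path`, invisibly.
#' @export
write_comparison <- function(report, csv_path, text_path = NULL) {
  stopifnot(inherits(report, "count_comparison"))
  readr::write_csv(report$coefficients, csv_path)
  if (!is.null(text_path)) {
    writeLines(format_comparison(report), text_path)
  }
  invisible(csv_path)
}
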