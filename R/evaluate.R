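#' Mean absolute error between true and fitted conditional means
#'
#' `MAE = sum(|E(y_i | x_i) - E(yhat_i | x_i)|) / n`, the mean absolute
#' deviation between the data-generating process's conditional mean and the
#' fitted model's conditional mean. The reference is the *true* conditional
#' mean (the formula compares two expectations, not residuals); pass the
#' observed counts as `true_mean` to get the residual-based alternative.
#'
#' @param true_mean Numeric vector of true conditional means (or observed
#'   counts for the residual variant).
#' @param predicted_mean Numeric vector of fitted conditional means.
#' @return A nonnegative length-one numeric.
#' @examples
#' mae(c(1, 2, 3), c(1, 2, 6))
#' @export
mae <- function(true_mean, predicted_mean) {
  if (length(true_mean) != length(predicted_mean)) {
    abort("`true_mean` and `predicted_mean` must have equal lengths.")
  }
  if (length(true_mean) == 0) abort("inputs must be non-empty.")
  mean(abs(true_mean - predicted_mean))
}

#' Convergence rate of a set of replication records
#'
#' @param records A data frame with a logical `converged` column (one row
#'   per replication), e.g. the `records` element of [run_study()].
#' @return Percentage of converged replications, in `[0, 100]`.
#' @examples
#' convergence_rate(data.frame(converged = c(TRUE, TRUE, TRUE, FALSE)))
#' @export
convergence_rate <- function(records) {
  if (is.data.frame(records)) records <- records$converged
  if (is.null(records) || length(records) == 0) {
    abort("`records` must contain at least one replication.")
  }
  100 * mean(records)
}

#' Summarize replication records into per-scenario performance rows
#'
#' Aggregates a replication log into the row type of the simulation-study
#' tables: per (scenario, model) the convergence rate and the means of AIC,
#' BIC and MAE *computed over converged replications only* (non-converged
#' fits contribute solely to the convergence rate). Replication-level
#' standard errors of the means are included so Monte Carlo uncertainty is
#' visible.
#'
#' @param records A tibble with columns `scenario_id`, `model`,
#'   `converged`, `aic`, `bic`, `mae` (and optionally the scenario factors
#'   `family`, `n`, `dispersion`, `zero_prop`, which are carried through).
#' @return A tibble with one row per scenario x model: `convergence_rate`,
#'   `n_converged`, `n_replications`, `mean_aic`, `mean_bic`, `mean_mae`
#'   and their standard errors.
#' @export
summarize_replications <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("`records` must be a non-empty data frame.")
  }
  keys <- intersect(
    c("scenario_id", "family", "n", "dispersion", "zero_prop", "model"),
    names(records)
  )
  mse <- function(x) stats::sd(x) / sqrt(length(x))
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_replications = dplyr::n(),
      n_converged = sum(.data$converged),
      convergence_rate = 100 * mean(.data$converged),
      mean_aic = mean(.data$aic[.data$converged]),
      mean_bic = mean(.data$bic[.data$converged]),
      mean_mae = mean(.data$mae[.data$converged]),
      se_aic = mse(.data$aic[.data$converged]),
      se_bic = mse(.data$bic[.data$converged]),
      se_mae = mse(.data$mae[.data$converged]),
      .groups = "drop"
    )
}
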