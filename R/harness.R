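#' Configuration of a Monte Carlo count-model comparison study
#'
#' Defines the factorial simulation grid: data-generating families, sample
#' sizes, NB-type dispersion levels, structural-zero proportions, the
#' number of replications per cell, the true count-part coefficients, and
#' the roster of models fitted to every replication. Dispersion levels
#' apply only to the `nb`/`zinb` generating families and zero proportions
#' only to `zip`/`zinb`, so the default grid has 4 Poisson cells, 16 NB
#' cells, 16 ZIP cells and 64 ZINB cells.
#'
#' @param families Generating families to include.
#' @param sizes Sample sizes per cell.
#' @param dispersions NB2 dispersion levels (`alpha`).
#' @param zero_props Structural-zero proportions (`phi`).
#' @param replications Replications per cell (the full study uses 1000).
#' @param base_seed Integer seed from which every per-replication seed is
#'   derived deterministically.
#' @param beta True count-part coefficients (intercept, `x1`, `x2`).
#' @param roster Models fitted to each replication.
#' @param zero_model `"intercept"` fits ZIP/ZINB with an intercept-only
#'   zero part (the generating mixture weight is constant);
#'   `"covariates"` uses the count-part covariates in the zero part too.
#' @param out_dir Optional directory for per-cell record CSVs; when set,
#'   [run_study()] is resumable (completed cells are re-read, not re-run).
#' @return A list of class `study_config`.
#' @export
study_config <- function(families = c("poisson", "nb", "zip", "zinb"),
                         sizes = c(50, 200, 600, 1000),
                         dispersions = c(0.01, 1, 5, 10),
                         zero_props = c(0.1, 0.3, 0.5, 0.7),
                         replications = 1000,
                         base_seed = 20220804,
                         beta = c(2.1, -0.001, 0.03),
                         roster = c("poisson", "nb", "zip", "zinb"),
                         zero_model = c("intercept", "covariates"),
                         out_dir = NULL) {
  families <- vapply(families, .check_family, character(1), USE.NAMES = FALSE)
  roster <- vapply(roster, .check_family, character(1), USE.NAMES = FALSE)
  if (length(sizes) == 0 || length(dispersions) == 0 || length(zero_props) == 0) {
    abort("`sizes`, `dispersions` and `zero_props` must be non-empty.")
  }
  if (any(sizes < 1 | sizes != floor(sizes))) abort("`sizes` must be positive integers.")
  if (any(dispersions <= 0)) abort("`dispersions` must be > 0.")
  if (any(zero_props < 0 | zero_props >= 1)) abort("`zero_props` must lie in [0, 1).")
  if (length(replications) != 1 || replications < 1) abort("`replications` must be >= 1.")
  structure(list(
    families = families, sizes = sizes, dispersions = dispersions,
    zero_props = zero_props, replications = as.integer(replications),
    base_seed = as.integer(base_seed), beta = beta, roster = roster,
    zero_model = match.arg(zero_model), out_dir = out_dir
  ), class = "study_config")
}

#' Build the scenario grid of a study configuration
#'
#' Expands the configuration into one row per simulation cell, in a
#' deterministic order (family, then sample size, then dispersion, then
#' zero proportion). Each cell carries a `scenario_id` and an integer
#' `scenario_key` from which per-replication seeds are derived, so a cell's
#' data stream does not depend on which other cells are in the grid.
#'
#' @param config A [study_config()].
#' @return A tibble with columns `scenario_id`, `family`, `n`,
#'   `dispersion`, `zero_prop`, `replications`, `scenario_key`.
#' @examples
#' nrow(build_grid(study_config(families = "zinb")))  # 64 cells
#' @export
build_grid <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cells <- purrr::map_dfr(config$families, function(fam) {
    tidyr::expand_grid(
      family = fam,
      n = sort(config$sizes),
      dispersion = if (.has_alpha(fam)) sort(config$dispersions) else NA_real_,
      zero_prop = if (.has_phi(fam)) sort(config$zero_props) else NA_real_
    )
  })
  fam_idx <- match(cells$family, .families)
  cells |>
    dplyr::mutate(
      scenario_id = paste0(
        .data$family, "_n", .data$n,
        ifelse(is.na(.data$dispersion), "", paste0("_d", .data$dispersion)),
        ifelse(is.na(.data$zero_prop), "", paste0("_z", .data$zero_prop))
      ),
      replications = config$replications,
      scenario_key = fam_idx * 100000000 + .data$n * 10000 +
        round(dplyr::coalesce(.data$dispersion, 0) * 100) * 10 +
        round(dplyr::coalesce(.data$zero_prop, 0) * 10)
    ) |>
    dplyr::relocate("scenario_id")
}

#' Run the Monte Carlo comparison study
#'
#' For every cell of the scenario grid and every replication: generate one
#' dataset from the cell's process, fit every roster model, and record the
#' convergence flag, AIC, BIC and MAE (fitted vs true conditional mean).
#' Individual fit failures are captured as non-converged records and never
#' abort the study. The run is fully reproducible from `base_seed`, and
#' when `out_dir` is set it is resumable: cells whose record file already
#' exists are re-read instead of re-run.
#'
#' @param config A [study_config()].
#' @param grid Optional subset of [build_grid()] rows to run.
#' @param verbose Print one progress line per cell.
#' @return An object of class `count_study`: a list with `records` (one row
#'   per cell x replication x model), `summaries`
#'   (via [summarize_replications()]) and `config`.
#' @export
run_study <- function(config, grid = build_grid(config), verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  if (!is.null(config$out_dir) && !dir.exists(config$out_dir)) {
    ok <- dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory '%s'.", config$out_dir))
  }
  records <- purrr::map(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    cache <- if (!is.null(config$out_dir)) {
      file.path(config$out_dir, paste0("records_", cell$scenario_id, ".csv"))
    }
    if (!is.null(cache) && file.exists(cache)) {
      if (verbose) message("cell ", cell$scenario_id, ": cached")
      return(.read_records(cache))
    }
    t0 <- Sys.time()
    rec <- .run_cell(cell, config)
    if (!is.null(cache)) readr::write_csv(rec, cache)
    if (verbose) {
      message(sprintf("cell %s: %d reps x %d models in %.1fs",
                      cell$scenario_id, cell$replications, length(config$roster),
                      as.numeric(Sys.time() - t0, units = "secs")))
    }
    rec
  })
  records <- dplyr::bind_rows(records)
  structure(list(records = records,
                 summaries = summarize_replications(records),
                 config = config),
            class = "count_study")
}

# re-read a cached per-cell record file with stable column types
.read_records <- function(path) {
  readr::read_csv(
    path, progress = FALSE, na = "NA",
    col_types = readr::cols(
      scenario_id = "c", family = "c", n = "d", dispersion = "d",
      zero_prop = "d", replication = "i", model = "c", converged = "l",
      reason = "c", loglik = "d", aic = "d", bic = "d", mae = "d", seed = "i"
    )
  )
}

# one grid cell: replications x roster fits, minimal overhead
.run_cell <- function(cell, config) {
  roster <- config$roster
  reps <- cell$replications
  nrec <- reps * length(roster)
  conv <- logical(nrec); aic <- bic <- mm <- ll <- rep(NA_real_, nrec)
  reason <- character(nrec); seed_used <- integer(nrec)
  ctl <- count_control()
  r_i <- 0L
  for (r in seq_len(reps)) {
    seed <- mix_seed(config$base_seed, cell$scenario_key, r)
    dat <- sim_counts(
      family = cell$family, beta = config$beta,
      alpha = if (.has_alpha(cell$family)) cell$dispersion,
      phi = if (.has_phi(cell$family)) cell$zero_prop,
      n = cell$n, seed = seed, scenario_id = cell$scenario_id
    )
    X <- cbind(`(Intercept)` = 1, x1 = dat$x1, x2 = dat$x2)
    for (m in roster) {
      r_i <- r_i + 1L
      Z <- if (.has_phi(m)) {
        if (config$zero_model == "covariates") X else
          matrix(1, cell$n, 1, dimnames = list(NULL, "(Intercept)"))
      }
      fit <- tryCatch(.fit_engine(dat$y, X, Z, m, "logit", ctl),
                      error = function(e) NULL)
      seed_used[r_i] <- seed
      if (is.null(fit)) {
        reason[r_i] <- "fit_error"
        next
      }
      conv[r_i] <- fit$converged
      reason[r_i] <- if (fit$converged) "" else fit$reason
      if (fit$converged) {
        aic[r_i] <- fit$aic
        bic[r_i] <- fit$bic
        ll[r_i] <- fit$loglik
        muhat <- exp(drop(X %*% fit$coefficients$count))
        if (.has_phi(m)) {
          phihat <- .zero_prob(drop(Z %*% fit$coefficients$zero), "logit")
          muhat <- muhat * (1 - phihat)
        }
        mm[r_i] <- mae(dat$true_mean, muhat)
      }
    }
  }
  tibble::tibble(
    scenario_id = cell$scenario_id, family = cell$family, n = cell$n,
    dispersion = cell$dispersion, zero_prop = cell$zero_prop,
    replication = rep(seq_len(reps), each = length(roster)),
    model = rep(roster, times = reps),
    converged = conv, reason = reason, loglik = ll,
    aic = aic, bic = bic, mae = mm, seed = seed_used
  )
}

#' Render study summaries as wide per-family tables
#'
#' Produces, per generating family, one table per metric (convergence rate,
#' mean AIC, mean BIC, mean MAE) with one row per scenario (sample size x
#' dispersion x zero proportion) and one column per fitted model, the
#' layout of the simulation-study report tables. Incomplete cells appear as
#' `NA`.
#'
#' @param summaries The `summaries` tibble of a `count_study` (or any
#'   output of [summarize_replications()]).
#' @param dir Optional directory; when given, each table is written as
#'   `<family>_<metric>.csv`.
#' @return A named list of tibbles, names `<family>_<metric>`.
#' @export
render_tables <- function(summaries, dir = NULL) {
  metrics <- c(convergence = "convergence_rate", aic = "mean_aic",
               bic = "mean_bic", mae = "mean_mae")
  keys <- intersect(c("n", "dispersion", "zero_prop"), names(summaries))
  out <- list()
  for (fam in unique(summaries$family)) {
    fam_rows <- dplyr::filter(summaries, .data$family == fam)
    for (mname in names(metrics)) {
      tab <- fam_rows |>
        dplyr::select(dplyr::all_of(keys), "model", value = dplyr::all_of(metrics[[mname]])) |>
        dplyr::select(dplyr::where(~ !all(is.na(.x))) | dplyr::any_of(c("model", "value"))) |>
        tidyr::pivot_wider(names_from = "model", values_from = "value") |>
        dplyr::arrange(dplyr::across(dplyr::any_of(keys)))
      out[[paste0(fam, "_", mname)]] <- tab
    }
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(out)) {
      readr::write_csv(out[[nm]], file.path(dir, paste0(nm, ".csv")))
    }
  }
  out
}

#' @export
print.count_study <- function(x, ...) {
  cat(sprintf("<count_study> %d cells, %d replications each, roster: %s\n",
              dplyr::n_distinct(x$records$scenario_id),
              x$config$replications, paste(x$config$roster, collapse = ", ")))
  print(x$summaries, n = 20)
  invisible(x)
}
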