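# Statistics reported by the study that produced the packaged tables, used
# only for side-by-side comparison in the reproduction report.
study_reference <- list(
  correlations = tibble::tibble(
    feature = c("cf_ch7", "pse_ch7", "cf_ch10", "pse_ch10"),
    reference_r = c(0.84, 0.61, 0.37, 0.71),
    reference_p = c(2.5e-7, 0.0016, 0.076, 1.0e-4)
  ),
  coefficients = tibble::tibble(
    term = c("(Intercept)", "cf_ch7", "pse_ch7", "pse_ch10"),
    reference = c(-0.04, 0.86, 0.06, 0.15)
  ),
  alpha = 0.1,
  cv_error = 0.36,
  r_pred_actual = 0.83
)

#' Load the packaged study tables
#'
#' Twelve participants completed five Stroop-task sets; mean reaction times,
#' Stroop effects and FSS ratings for the first and fifth sets, and the
#' matching channel-7/channel-10 spectral features, are packaged as
#' plain-text tables. This function joins them into one record per
#' subject-session and verifies the Stroop-effect arithmetic identity
#' (`stroop_effect_ms == incongruent_ms - congruent_ms`) on every row.
#'
#' Participant 4's fifth set had a negative Stroop effect and is flagged
#' `excluded`; see [apply_exclusions()].
#'
#' @return A tibble of 24 rows: `subject`, `session` (1 or 5),
#'   `congruent_ms`, `incongruent_ms`, `stroop_effect_ms`, `fss`, `cf_ch7`,
#'   `cf_ch10`, `pse_ch7`, `pse_ch10`, `excluded`.
#' @export
#' @examples
#' study <- load_study()
#' nrow(study)
load_study <- function() {
  path <- function(f) system.file("extdata", f, package = "fatiguebrake",
                                  mustWork = TRUE)
  stroop <- readr::read_csv(path("table2_stroop.csv"), show_col_types = FALSE)
  feats <- readr::read_csv(path("table3_features.csv"), show_col_types = FALSE)
  records <- dplyr::inner_join(stroop, feats, by = c("subject", "session"))
  if (nrow(records) != 24) {
    abort("Packaged study tables are inconsistent: expected 24 joined rows.")
  }
  identity_ok <- records$stroop_effect_ms ==
    records$incongruent_ms - records$congruent_ms
  if (!all(identity_ok)) {
    abort("Stroop-effect identity fails on packaged rows; data corrupted.")
  }
  bad_fss <- records$fss < 0 | records$fss > 4 |
    (records$fss * 2) %% 1 != 0
  if (any(bad_fss)) {
    abort("FSS scores must lie on the half-point grid in [0, 4].")
  }
  dplyr::mutate(records,
                excluded = .data$subject == 4 & .data$session == 5)
}

#' The five-point Fatigue Severity Scale
#'
#' @return A tibble with columns `score` (0-4) and `description`.
#' @export
fss_scale <- function() {
  readr::read_csv(
    system.file("extdata", "table1_fss.csv", package = "fatiguebrake",
                mustWork = TRUE),
    show_col_types = FALSE
  )
}

#' Apply the study's exclusion rule
#'
#' Participant 4 produced negative Stroop effects (faster incongruent than
#' congruent responses); the flagged fifth set was discarded from model
#' construction in the original analysis. Three variants are supported:
#' `"session"` (default) drops only flagged rows (22 + 1 = 23 remain),
#' `"subject"` drops every row of any subject with a flagged row (22
#' remain), and `"none"` keeps all rows — recomputation shows the published
#' feature-FSS correlations match the unfiltered 24-row table.
#'
#' @param records A tibble from [load_study()] (or any table with `subject`
#'   and `excluded` columns).
#' @param mode `"session"`, `"subject"` or `"none"`.
#' @return The filtered tibble.
#' @export
#' @examples
#' nrow(apply_exclusions(load_study(), "subject"))  # 22
apply_exclusions <- function(records, mode = c("session", "subject", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(records)
  if (!all(c("subject", "excluded") %in% names(records))) {
    abort("`records` needs `subject` and `excluded` columns.")
  }
  if (mode == "session") {
    dplyr::filter(records, !.data$excluded)
  } else {
    bad_subjects <- unique(records$subject[records$excluded])
    dplyr::filter(records, !.data$subject %in% bad_subjects)
  }
}

#' Reproduce the full study analysis
#'
#' Runs the complete analysis chain on the packaged tables: feature-FSS
#' Pearson correlations (under every exclusion variant), the analytic ridge
#' fit at the stated regularization under both the standardized and
#' raw-scale conventions and both exclusion variants, k-fold
#' cross-validation errors (MSE, MAE and RMSE, averaged over `n_cv_seeds`
#' fold shuffles), and the correlation between predicted and actual fatigue
#' scores (in-sample and cross-validated). Every recomputed quantity is
#' tabulated next to the value originally reported for these data.
#'
#' @param correlation_mode Exclusion variant for the correlation table
#'   (default `"none"`, which reproduces the published values most
#'   closely).
#' @param model_mode Exclusion variant for model construction (default
#'   `"session"`, the rule stated with the original tables).
#' @param alpha Ridge regularization parameter (default 0.1, the published
#'   choice).
#' @param k Folds for cross-validation (default 5).
#' @param n_cv_seeds Number of fold-shuffle seeds to average over (default
#'   100).
#' @param seed Master seed for the fold shuffles.
#'
#' @return An object of class `study_report`; print it for the side-by-side
#'   comparison. Components: `correlations`, `correlations_by_mode`,
#'   `coefficients`, `models` (named list of `fatigue_model`s), `cv_errors`,
#'   `pred_actual`, `alpha_grid`, and the settings used.
#' @export
#' @examples
#' report <- reproduce_study(n_cv_seeds = 10, seed = 1)
#' report
reproduce_study <- function(correlation_mode = "none",
                            model_mode = "session",
                            alpha = 0.1, k = 5,
                            n_cv_seeds = 100, seed = 1) {
  study <- load_study()
  modes <- c("none", "session", "subject")

  correlations_by_mode <- purrr::map(modes, function(m) {
    dplyr::bind_cols(tibble::tibble(mode = m),
                     correlate_features(apply_exclusions(study, m)))
  }) |>
    dplyr::bind_rows()
  correlations <- correlations_by_mode |>
    dplyr::filter(.data$mode == correlation_mode) |>
    dplyr::left_join(study_reference$correlations, by = "feature")

  fit_modes <- c("session", "subject")
  models <- list()
  coef_tbl <- study_reference$coefficients
  for (m in fit_modes) {
    dat <- apply_exclusions(study, m)
    fit <- ridge_fit(dat, alpha = alpha, standardize = TRUE)
    models[[paste0("standardized_", m)]] <- fit
    coef_tbl[[paste0("standardized_", m)]] <-
      tidy(fit)$estimate[match(coef_tbl$term, tidy(fit)$term)]
  }
  raw_fit <- ridge_fit(apply_exclusions(study, model_mode),
                       alpha = alpha, standardize = FALSE)
  models$raw <- raw_fit
  coef_tbl$raw_scale <-
    tidy(raw_fit)$estimate_raw[match(coef_tbl$term, tidy(raw_fit)$term)]

  set.seed(as.integer(seed))
  cv_seeds <- sample.int(.Machine$integer.max - 1L, n_cv_seeds)
  cv_errors <- tidyr::expand_grid(mode = fit_modes,
                                  metric = c("mse", "mae", "rmse")) |>
    dplyr::mutate(error = purrr::map2_dbl(.data$mode, .data$metric, function(m, met) {
      dat <- apply_exclusions(study, m)
      mean(purrr::map_dbl(cv_seeds, function(s) {
        as.numeric(kfold_cv(dat, alpha = alpha, k = k, metric = met, seed = s))
      }))
    }))

  pred_actual <- purrr::map(fit_modes, function(m) {
    dat <- apply_exclusions(study, m)
    fit <- models[[paste0("standardized_", m)]]
    r_cv <- mean(purrr::map_dbl(cv_seeds, function(s) {
      cp <- cv_predictions(dat, alpha = alpha, k = k, seed = s)
      cor(cp$predicted, cp$actual)
    }))
    tibble::tibble(mode = m, variant = c("in_sample", "cross_validated"),
                   r = c(fit$r_insample, r_cv))
  }) |>
    dplyr::bind_rows()

  sel <- select_alpha(apply_exclusions(study, model_mode),
                      grid = c(0.001, 0.01, 0.1, 1, 10), k = k,
                      seed = cv_seeds[1])

  structure(
    list(
      correlations = correlations,
      correlations_by_mode = correlations_by_mode,
      coefficients = coef_tbl,
      models = models,
      cv_errors = cv_errors,
      pred_actual = pred_actual,
      alpha_selected = as.numeric(sel),
      alpha_grid_mse = attr(sel, "cv_mse"),
      reference = study_reference,
      settings = list(correlation_mode = correlation_mode,
                      model_mode = model_mode, alpha = alpha, k = k,
                      n_cv_seeds = n_cv_seeds, seed = seed)
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  s <- x$settings
  cat("== Study reproduction report ==\n")
  cat(sprintf("alpha = %g, %d-fold CV over %d shuffle seeds\n\n",
              s$alpha, s$k, s$n_cv_seeds))
  cat(sprintf("-- Feature-FSS correlations (exclusion: %s, n = %d) --\n",
              s$correlation_mode, x$correlations$n[1]))
  print(as.data.frame(x$correlations[, c("feature", "r", "p",
                                         "reference_r", "reference_p")]),
        digits = 3, row.names = FALSE)
  cat(sprintf("\n-- Ridge coefficients at alpha = %g --\n", s$alpha))
  print(as.data.frame(x$coefficients), digits = 3, row.names = FALSE)
  cat(sprintf("   reported reference vector: FSS = %.2f CF_ch7 + %.2f PSE_ch7 + %.2f PSE_ch10 %+.2f\n",
              0.86, 0.06, 0.15, -0.04))
  cat(sprintf("\n-- Cross-validated error (reference: %.2f) --\n",
              x$reference$cv_error))
  print(as.data.frame(tidyr::pivot_wider(x$cv_errors,
                                         names_from = "metric",
                                         values_from = "error")),
        digits = 3, row.names = FALSE)
  cat(sprintf("\n-- Predicted vs actual correlation (reference: %.2f) --\n",
              x$reference$r_pred_actual))
  print(as.data.frame(x$pred_actual), digits = 3, row.names = FALSE)
  cat(sprintf("\n-- Alpha selected on MSE grid: %g (reference: %g) --\n",
              x$alpha_selected, x$reference$alpha))
  invisible(x)
}
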