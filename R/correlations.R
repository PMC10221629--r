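#' Pearson correlation with a t-distribution p-value
#'
#' Sample Pearson correlation between two paired vectors, with the usual
#' two-tailed p-value from \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on `n - 2`
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return A one-row tibble with columns `r`, `p`, `n`.
#' @export
#' @examples
#' pearson(1:10, (1:10)^2)
pearson <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Need at least 3 paired observations.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation is undefined for a constant input.")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlations between spectral features and fatigue scores
#'
#' For a study table (see [load_study()]) computes the Pearson correlation
#' of each spectral feature column with the FSS score.
#'
#' @param records A data frame with columns `fss` and the feature columns.
#' @param features Character vector of feature column names.
#' @return A tibble with one row per feature: `feature`, `r`, `p`, `n`.
#' @export
#' @examples
#' correlate_features(apply_exclusions(load_study(), "none"))
correlate_features <- function(records,
                               features = c("cf_ch7", "pse_ch7",
                                            "cf_ch10", "pse_ch10")) {
  missing_cols <- setdiff(c("fss", features), names(records))
  if (length(missing_cols)) {
    abort(paste("Missing columns:", paste(missing_cols, collapse = ", ")))
  }
  purrr::map(features, function(f) {
    dplyr::bind_cols(tibble::tibble(feature = f),
                     pearson(records[[f]], records$fss))
  }) |>
    dplyr::bind_rows()
}

#' Full pairwise correlation matrix
#'
#' All pairwise Pearson correlations (and p-values) among a set of columns,
#' e.g. the four spectral features plus the FSS score. The `r` matrix is
#' symmetric with unit diagonal.
#'
#' @param data A data frame.
#' @param vars Character vector of numeric column names (default: the four
#'   feature columns plus `fss`).
#' @return A list with square matrices `r` and `p` (dimnames = `vars`) and
#'   the sample size `n`.
#' @export
correlation_matrix <- function(data,
                               vars = c("cf_ch7", "pse_ch7", "cf_ch10",
                                        "pse_ch10", "fss")) {
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    abort(paste("Missing columns:", paste(missing_cols, collapse = ", ")))
  }
  k <- length(vars)
  r <- diag(1, k)
  p <- matrix(0, k, k)
  dimnames(r) <- dimnames(p) <- list(vars, vars)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      res <- pearson(data[[vars[i]]], data[[vars[j]]])
      r[i, j] <- r[j, i] <- res$r
      p[i, j] <- p[j, i] <- res$p
    }
  }
  list(r = r, p = p, n = nrow(data))
}

#' Correlation heatmap
#'
#' Displays a pairwise correlation structure with correlation coefficients
#' in the lower-left triangle and p-values in the upper-right.
#'
#' @param cm A list with matrices `r` and `p`, as from
#'   [correlation_matrix()].
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(cm) {
  vars <- rownames(cm$r)
  k <- length(vars)
  grid <- tidyr::expand_grid(row = seq_len(k), col = seq_len(k))
  grid <- dplyr::mutate(
    grid,
    value = ifelse(.data$row >= .data$col,
                   cm$r[cbind(.data$row, .data$col)],
                   cm$p[cbind(.data$row, .data$col)]),
    fill = cm$r[cbind(.data$row, .data$col)],
    label = ifelse(.data$row >= .data$col,
                   sprintf("%.2f", .data$value),
                   sprintf("%.1e", .data$value))
  )
  ggplot2::ggplot(grid, ggplot2::aes(
    x = factor(.data$col, labels = vars),
    y = factor(.data$row, levels = rev(seq_len(k)), labels = rev(vars)),
    fill = .data$fill
  )) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  limits = c(-1, 1), name = "r") +
    ggplot2::labs(x = NULL, y = NULL,
                  subtitle = "lower: r, upper: p-value") +
    ggplot2::theme_minimal()
}
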