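#' Tidy a wavelet decomposition into a coefficient tibble
#'
#' One row per coefficient: `band` (`w1..wJ`, `approx`), `level`, `index`
#' (0-based within the band) and `value`. Works for both decimated and
#' redundant decompositions; for the latter every band has the original
#' length.
#'
#' @param x A `wavelet_decomposition`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy wavelet_decomposition
#' @export
tidy.wavelet_decomposition <- function(x, ...) {
  bands <- c(x$detail_coeffs, list(x$approx_coeffs))
  labels <- c(paste0("w", seq_len(x$levels)), "approx")
  levels <- c(seq_len(x$levels), x$levels)
  purrr::map_dfr(seq_along(bands), function(i) {
    tibble::tibble(
      band = labels[i],
      level = as.integer(levels[i]),
      index = seq_along(bands[[i]]) - 1L,
      value = bands[[i]]
    )
  })
}

#' @rdname tidy.wavelet_decomposition
#' @method glance wavelet_decomposition
#' @export
glance.wavelet_decomposition <- function(x, ...) {
  tibble::tibble(
    kind = if (inherits(x, "decimated_decomposition")) "dwt" else "rdwt",
    filterbank = x$filterbank_name,
    levels = x$levels,
    original_length = x$original_length,
    n_coefficients = sum(lengths(x$detail_coeffs)) + length(x$approx_coeffs),
    coefficient_energy = sum(vapply(x$detail_coeffs, function(d) sum(d^2), numeric(1))) +
      sum(x$approx_coeffs^2)
  )
}

#' Tidy and summarize a shift-sensitivity report
#'
#' `tidy()` returns the per-band table (band, estimated TV period, distinct
#' spectral pattern count, max equivariance deviation); `glance()` a one-row
#' summary with the LTI/LTV verdict.
#'
#' @param x A `shift_sensitivity_report` from [lti_check()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy shift_sensitivity_report
#' @export
tidy.shift_sensitivity_report <- function(x, ...) {
  x$per_band
}

#' @rdname tidy.shift_sensitivity_report
#' @method glance shift_sensitivity_report
#' @export
glance.shift_sensitivity_report <- function(x, ...) {
  tibble::tibble(
    transform = x$transform_label,
    filterbank = x$filterbank_name,
    levels = x$levels,
    n_shifts = length(x$tested_shifts),
    max_deviation = max(x$per_band$max_equivariance_deviation),
    verdict = x$verdict
  )
}

#' @method autoplot wavelet_decomposition
#' @export
autoplot.wavelet_decomposition <- function(object, ...) {
  df <- tidy(object)
  df$band <- factor(df$band, levels = unique(df$band))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$band), scales = "free") +
    ggplot2::labs(x = "coefficient index", y = "value") +
    ggplot2::theme_minimal()
}

#' @method autoplot shift_sensitivity_report
#' @export
autoplot.shift_sensitivity_report <- function(object, ...) {
  df <- tidy_deviations(object)
  df$band <- factor(df$band, levels = unique(object$per_band$band))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$shift), y = pmax(.data$deviation, 1e-17))) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$band)) +
    ggplot2::labs(
      x = "input shift (samples)", y = "max equivariance deviation",
      title = sprintf("%s: %s", toupper(object$transform_label), object$verdict)
    ) +
    ggplot2::theme_minimal()
}
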