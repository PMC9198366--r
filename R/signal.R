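#' Construct a discrete signal
#'
#' A `discrete_signal` is a finite real-valued sample sequence together with
#' its sampling rate. It is the common currency of the package: transforms,
#' diagnostics and generators all consume and produce this type.
#'
#' @param samples Numeric vector of finite values, length at least 2.
#' @param sampling_rate Sampling rate in samples per second (Hz), positive.
#'
#' @return An object of class `discrete_signal`: a list with elements
#'   `samples` and `sampling_rate`.
#' @examples
#' x <- discrete_signal(sin(2 * pi * 5 * (0:199) / 100), sampling_rate = 100)
#' x
#' @export
discrete_signal <- function(samples, sampling_rate) {
  if (!is.numeric(samples) || length(samples) < 2) {
    sw_abort("`samples` must be a numeric vector of length >= 2.", "invalid_argument")
  }
  if (!all(is.finite(samples))) {
    sw_abort("`samples` must contain only finite values.", "invalid_argument")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    sw_abort("`sampling_rate` must be a single positive number.", "invalid_argument")
  }
  structure(
    list(samples = as.double(samples), sampling_rate = as.double(sampling_rate)),
    class = "discrete_signal"
  )
}

#' @export
print.discrete_signal <- function(x, ...) {
  cat(sprintf(
    "<discrete_signal> N = %d samples at %g Hz (%.4g s)\n",
    length(x$samples), x$sampling_rate, length(x$samples) / x$sampling_rate
  ))
  cat("  head:", format(head(x$samples, 6), digits = 4), "\n")
  invisible(x)
}

#' @export
length.discrete_signal <- function(x) length(x$samples)

#' @rdname discrete_signal
#' @param x A `discrete_signal`.
#' @param ... Unused.
#' @method tidy discrete_signal
#' @export
tidy.discrete_signal <- function(x, ...) {
  n <- length(x$samples)
  tibble::tibble(
    index = seq_len(n) - 1L,
    time_s = (seq_len(n) - 1) / x$sampling_rate,
    value = x$samples
  )
}

#' Circularly shift a signal to the right
#'
#' "Shift by `s`" throughout the package means a circular right shift:
#' sample `n` moves to position `(n + s) mod N`. This single convention is
#' shared by the transforms, the generators and every diagnostic, so that
#' shift-equivariance statements are unambiguous.
#'
#' @param x A `discrete_signal`.
#' @param s Integer shift, any value (reduced modulo the signal length).
#' @return The shifted `discrete_signal` (same sampling rate, same energy).
#' @examples
#' d <- delta_impulse(8, 2)
#' shift_signal(d, 3)$samples # impulse now at index 5
#' @export
shift_signal <- function(x, s) {
  stopifnot(inherits(x, "discrete_signal"))
  if (!is.numeric(s) || length(s) != 1 || s != round(s)) {
    sw_abort("`s` must be a single integer.", "invalid_argument")
  }
  discrete_signal(circ_shift(x$samples, s), x$sampling_rate)
}

# circular right shift of a bare numeric vector
circ_shift <- function(v, s) {
  n <- length(v)
  s <- ((s %% n) + n) %% n
  if (s == 0) return(v)
  v[((seq_len(n) - 1 - s) %% n) + 1]
}

# circular convolution y(k) = sum_m h[m] x((k - m) mod N), via the FFT;
# h may be longer than x (it is wrapped)
circ_conv <- function(x, h) {
  n <- length(x)
  hp <- numeric(n)
  idx <- ((seq_along(h) - 1) %% n) + 1
  for (i in seq_along(h)) hp[idx[i]] <- hp[idx[i]] + h[i]
  Re(fft(fft(x) * fft(hp), inverse = TRUE)) / n
}

#' @method autoplot discrete_signal
#' @export
autoplot.discrete_signal <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "amplitude") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
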