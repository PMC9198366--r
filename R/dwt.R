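#' Decimated discrete wavelet transform (analysis pyramid)
#'
#' Iterated two-channel analysis with downsampling by 2: at each stage the
#' current approximation is circularly convolved with the analysis lowpass
#' and highpass filters and every second sample is kept (even indices,
#' offset 0). Level-`j` detail has `N / 2^j` coefficients and the final
#' approximation `N / 2^J`, so the total coefficient count equals `N`.
#' Boundary handling is periodic (circular), which makes the transform an
#' exact orthogonal map: coefficient energy equals signal energy and the
#' round trip through [dwt_reconstruct()] is exact to machine precision.
#'
#' @param x A [discrete_signal()]. Its length must be divisible by
#'   `2^levels`.
#' @param fb A [daubechies_filterbank()] (or compatible orthonormal bank).
#' @param levels Number of decomposition levels `J >= 1`.
#'
#' @return A `decimated_decomposition`: list with `levels`, `detail_coeffs`
#'   (list of J vectors), `approx_coeffs`, `original_length`,
#'   `sampling_rate`, `filterbank_name`.
#' @seealso [dwt_reconstruct()], [dwt_subspaces()], [rdwt_decompose()]
#' @examples
#' x <- delta_impulse(64, 32)
#' dec <- dwt_decompose(x, daubechies_filterbank(2), levels = 3)
#' lengths(dec$detail_coeffs) # 32 16 8
#' @export
dwt_decompose <- function(x, fb, levels) {
  check_transform_args(x, fb, levels)
  n <- length(x$samples)
  if (n %% 2^levels != 0) {
    sw_abort(
      sprintf("signal length %d is not divisible by 2^levels = %d.", n, 2^levels),
      "divisibility"
    )
  }
  h <- fb$analysis_lowpass
  g <- fb$analysis_highpass
  a <- x$samples
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    even <- seq(1, length(a), by = 2)
    details[[j]] <- circ_conv(a, g)[even]
    a <- circ_conv(a, h)[even]
  }
  structure(
    list(
      levels = as.integer(levels),
      detail_coeffs = details,
      approx_coeffs = a,
      original_length = n,
      sampling_rate = x$sampling_rate,
      filterbank_name = fb$name
    ),
    class = c("decimated_decomposition", "wavelet_decomposition")
  )
}

#' Inverse decimated wavelet transform (synthesis pyramid)
#'
#' Iterated two-channel synthesis: coefficients are upsampled by zero
#' insertion, circularly convolved with the synthesis filters, summed, and
#' the filter group delay (`Ltap - 1` samples) is unwound so the composition
#' with [dwt_decompose()] is the identity.
#'
#' @param dec A `decimated_decomposition`.
#' @param fb The filter bank the decomposition was produced with (matched by
#'   name).
#' @return The reconstructed [discrete_signal()].
#' @export
dwt_reconstruct <- function(dec, fb) {
  check_decomposition(dec, fb, "decimated_decomposition")
  a <- dec$approx_coeffs
  for (j in rev(seq_len(dec$levels))) {
    a <- idwt_step(a, dec$detail_coeffs[[j]], fb)
  }
  discrete_signal(a, dec$sampling_rate)
}

# one synthesis stage; output length is twice the coefficient length
idwt_step <- function(a, d, fb) {
  n <- 2 * length(a)
  ua <- numeric(n); ua[seq(1, n, by = 2)] <- a
  ud <- numeric(n); ud[seq(1, n, by = 2)] <- d
  y <- circ_conv(ua, fb$synthesis_lowpass) + circ_conv(ud, fb$synthesis_highpass)
  circ_shift(y, -(length(fb$synthesis_lowpass) - 1))
}

#' Full-length wavelet subspaces of a decimated decomposition
#'
#' Subspace `w_j` is the reconstruction with every band except level-`j`
#' detail zeroed; the last element is the approximation subspace
#' `w_{J+1}`. By linearity the subspaces sum to the original signal. Each is
#' returned full length, which is what the translation-variability
#' diagnostics compare across input shifts.
#'
#' @inheritParams dwt_reconstruct
#' @return A named list of `J + 1` [discrete_signal()]s:
#'   `w1, ..., wJ, approx`.
#' @examples
#' x <- delta_impulse(64, 32)
#' fb <- daubechies_filterbank(2)
#' ws <- dwt_subspaces(dwt_decompose(x, fb, 2), fb)
#' names(ws)
#' @export
dwt_subspaces <- function(dec, fb) {
  check_decomposition(dec, fb, "decimated_decomposition")
  J <- dec$levels
  out <- vector("list", J + 1)
  for (b in seq_len(J + 1)) {
    z <- dec
    for (j in seq_len(J)) if (j != b) z$detail_coeffs[[j]][] <- 0
    if (b != J + 1) z$approx_coeffs[] <- 0
    out[[b]] <- dwt_reconstruct(z, fb)
  }
  names(out) <- c(paste0("w", seq_len(J)), "approx")
  out
}

check_transform_args <- function(x, fb, levels) {
  if (!inherits(x, "discrete_signal")) {
    sw_abort("`x` must be a discrete_signal.", "invalid_argument")
  }
  if (!inherits(fb, "wavelet_filterbank")) {
    sw_abort("`fb` must be a wavelet_filterbank.", "invalid_argument")
  }
  if (!is.numeric(levels) || length(levels) != 1 || levels != round(levels) ||
      levels < 1) {
    sw_abort("`levels` must be a single integer >= 1.", "invalid_argument")
  }
}

check_decomposition <- function(dec, fb, class) {
  if (!inherits(dec, class)) {
    sw_abort(sprintf("`dec` must be a %s.", class), "invalid_argument")
  }
  if (!inherits(fb, "wavelet_filterbank")) {
    sw_abort("`fb` must be a wavelet_filterbank.", "invalid_argument")
  }
  if (!identical(dec$filterbank_name, fb$name)) {
    sw_abort(
      sprintf("decomposition was built with '%s' but `fb` is '%s'.",
              dec$filterbank_name, fb$name),
      "incompatible"
    )
  }
  if (inherits(dec, "decimated_decomposition")) {
    want <- dec$original_length / 2^seq_len(dec$levels)
    if (!identical(unname(lengths(dec$detail_coeffs)), as.integer(want)) ||
        length(dec$approx_coeffs) != dec$original_length / 2^dec$levels) {
      sw_abort("coefficient lengths are inconsistent with original_length.", "structural")
    }
  } else {
    if (any(lengths(dec$detail_coeffs) != dec$original_length) ||
        length(dec$approx_coeffs) != dec$original_length) {
      sw_abort("redundant bands must all have the original length.", "structural")
    }
  }
  invisible(TRUE)
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  kind <- if (inherits(x, "decimated_decomposition")) "decimated" else "redundant"
  cat(sprintf(
    "<%s_decomposition> %s, J = %d, N = %d; band lengths: %s + %d (approx)\n",
    kind, x$filterbank_name, x$levels, x$original_length,
    paste(lengths(x$detail_coeffs), collapse = ", "), length(x$approx_coeffs)
  ))
  invisible(x)
}
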