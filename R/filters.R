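#' Construct an orthonormal Daubechies filter bank
#'
#' Builds the four-filter set (analysis/synthesis, low/high pass) for the
#' Daubechies wavelet of the given order by spectral factorization of the
#' maxflat half-band polynomial. The analysis lowpass is the minimum-phase
#' (extremal-phase) solution: all zeros of the factored polynomial are taken
#' inside the unit circle. Order `p` gives `2p` taps and `p` vanishing
#' moments in the highpass filter.
#'
#' Conventions, fixed once and used everywhere in the package:
#' filters are stored causally (tap indices `0..2p-1`) and applied by
#' circular convolution; the analysis highpass is the alternating-flip
#' quadrature mirror of the lowpass, `g[n] = (-1)^n h[2p-1-n]`; synthesis
#' filters are the time-reverses of the analysis filters (orthogonal bank).
#'
#' @param order Integer in 1..20. Order 1 is Haar; order 8 ("db8") is the
#'   default basis used by the diagnostic experiments.
#'
#' @return A `wavelet_filterbank`: list with `name` (e.g. `"db8"`) and the
#'   four tap vectors `analysis_lowpass`, `analysis_highpass`,
#'   `synthesis_lowpass`, `synthesis_highpass`.
#' @examples
#' fb <- daubechies_filterbank(8)
#' sum(fb$analysis_lowpass) - sqrt(2) # ~ 0
#' @export
daubechies_filterbank <- function(order) {
  if (!is.numeric(order) || length(order) != 1 || !is.finite(order) ||
      order != round(order) || order < 1) {
    sw_abort("`order` must be a single integer >= 1.", "invalid_argument")
  }
  if (order > 20) {
    sw_abort(
      "`order` > 20 is not supported: spectral factorization of the maxflat polynomial is ill-conditioned beyond order 20.",
      "unsupported_order"
    )
  }
  h <- daub_lowpass(as.integer(order))
  new_filterbank(paste0("db", order), h)
}

# minimum-phase Daubechies scaling filter by spectral factorization.
# |H(w)|^2 = 2 cos^{2p}(w/2) P(sin^2(w/2)) with P the degree p-1 maxflat
# polynomial; roots of P are mapped to reciprocal z-pairs and the in-circle
# root of each pair is kept.
daub_lowpass <- function(p) {
  if (p == 1) return(c(1, 1) / sqrt(2))
  k <- 0:(p - 1)
  maxflat <- choose(p - 1 + k, k)        # ascending coefficients of P(y)
  yroots <- polyroot(maxflat)
  h <- choose(p, 0:p)                    # (1 + z^-1)^p factor
  for (y in yroots) {
    # y = (2 - z - 1/z)/4  =>  z^2 - (2 - 4y) z + 1 = 0; roots reciprocal
    b <- 2 - 4 * y
    disc <- sqrt(as.complex(b * b - 4))
    z1 <- (b + disc) / 2
    z <- if (Mod(z1) < 1) z1 else (b - disc) / 2
    h <- c(h, 0) - z * c(0, h)           # multiply by (1 - z z^-1)
  }
  h <- Re(h)
  h * sqrt(2) / sum(h)
}

new_filterbank <- function(name, h) {
  structure(
    list(
      name = name,
      analysis_lowpass = h,
      analysis_highpass = qmf_highpass(h),
      synthesis_lowpass = rev(h),
      synthesis_highpass = rev(qmf_highpass(h))
    ),
    class = "wavelet_filterbank"
  )
}

# alternating-flip quadrature mirror: g[n] = (-1)^n h[L-1-n]
qmf_highpass <- function(h) {
  L <- length(h)
  (-1)^(seq_len(L) - 1) * rev(h)
}

#' @export
print.wavelet_filterbank <- function(x, ...) {
  cat(sprintf(
    "<wavelet_filterbank> %s: %d taps, sum(h) - sqrt(2) = %.2e\n",
    x$name, length(x$analysis_lowpass), sum(x$analysis_lowpass) - sqrt(2)
  ))
  invisible(x)
}

#' Validate a wavelet filter bank
#'
#' Evaluates every defining property of an orthonormal two-channel bank and
#' reports one row per check with its numerical residual: lowpass
#' normalization (sum = sqrt(2)), unit energy, double-shift orthogonality,
#' the alternating-flip quadrature-mirror relation, synthesis-equals-reversed
#' -analysis, the two-channel perfect-reconstruction condition
#' (sum over even lags of the low+high autocorrelations equals 2 at lag 0,
#' 0 elsewhere), and vanishing moments of the highpass (residuals scaled by
#' the moment's absolute-term magnitude so the check is meaningful at high
#' order).
#'
#' @param fb A `wavelet_filterbank`.
#' @param tolerance Residual above which a check is marked as failed
#'   (default `1e-10`).
#' @return A tibble with columns `check`, `residual`, `pass`.
#' @examples
#' validate_filterbank(daubechies_filterbank(4))
#' @export
validate_filterbank <- function(fb, tolerance = 1e-10) {
  if (!inherits(fb, "wavelet_filterbank")) {
    sw_abort("`fb` must be a wavelet_filterbank.", "invalid_argument")
  }
  taps <- fb[c("analysis_lowpass", "analysis_highpass",
               "synthesis_lowpass", "synthesis_highpass")]
  len <- lengths(taps)
  if (length(unique(len)) != 1 || len[1] %% 2 != 0) {
    sw_abort("all four filters must have equal, even length.", "structural")
  }
  h <- fb$analysis_lowpass
  g <- fb$analysis_highpass
  L <- length(h)

  res <- c(
    lowpass_sum_sqrt2 = abs(sum(h) - sqrt(2)),
    unit_energy = abs(sum(h^2) - 1),
    double_shift_orthogonality = max(vapply(
      seq_len(L / 2 - 1),
      function(k) abs(sum(h[seq_len(L - 2 * k)] * h[seq_len(L - 2 * k) + 2 * k])),
      numeric(1)
    ), 0),
    qmf_alternating_flip = max(abs(g - qmf_highpass(h))),
    synthesis_time_reversal = max(
      abs(fb$synthesis_lowpass - rev(h)),
      abs(fb$synthesis_highpass - rev(g))
    ),
    perfect_reconstruction = pr_residual(h, g),
    vanishing_moments = vanishing_moment_residual(g, L / 2)
  )
  tibble::tibble(
    check = names(res),
    residual = unname(res),
    pass = unname(res) < tolerance
  )
}

# two-channel PR on the even-lag autocorrelations:
# sum_n h[n]h[n+2k] + g[n]g[n+2k] = 2*delta(k)
pr_residual <- function(h, g) {
  L <- length(h)
  lag_sum <- function(f, l) {
    if (l >= L) return(0)
    sum(f[seq_len(L - l)] * f[seq_len(L - l) + l])
  }
  lags <- seq(0, L - 2, by = 2)
  target <- ifelse(lags == 0, 2, 0)
  max(abs(vapply(lags, function(l) lag_sum(h, l) + lag_sum(g, l), numeric(1)) - target))
}

# p-th moments of the highpass, relative to the scale of their terms
vanishing_moment_residual <- function(g, order) {
  n <- seq_along(g) - 1
  max(vapply(0:(order - 1), function(p) {
    terms <- n^p * g
    abs(sum(terms)) / max(sum(abs(terms)), .Machine$double.eps)
  }, numeric(1)))
}

#' Write or read a filter bank as JSON
#'
#' Taps are serialized with 17 significant digits, so the round trip is
#' lossless in double precision.
#'
#' @param fb A `wavelet_filterbank`.
#' @param path File path.
#' @return `write_filterbank_json` returns `path` invisibly;
#'   `read_filterbank_json` returns the `wavelet_filterbank`.
#' @export
write_filterbank_json <- function(fb, path) {
  stopifnot(inherits(fb, "wavelet_filterbank"))
  jsonlite::write_json(
    list(
      name = fb$name,
      analysis_lowpass = fb$analysis_lowpass,
      analysis_highpass = fb$analysis_highpass,
      synthesis_lowpass = fb$synthesis_lowpass,
      synthesis_highpass = fb$synthesis_highpass
    ),
    path,
    auto_unbox = TRUE, digits = I(17)
  )
  invisible(path)
}

#' @rdname write_filterbank_json
#' @export
read_filterbank_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("name", "analysis_lowpass", "analysis_highpass",
            "synthesis_lowpass", "synthesis_highpass")
  if (!all(need %in% names(obj))) {
    sw_abort("filter-bank JSON is missing required fields.", "format")
  }
  structure(obj[need], class = "wavelet_filterbank")
}
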