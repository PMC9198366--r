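#' Discrete delta impulse
#'
#' The unit impulse `d(n - l)`: one sample equal to 1 at 0-based index `l`,
#' all others 0. Shifted deltas are the canonical probe for translation
#' variability: the decomposition of a delta reads out the system's response
#' at that alignment, so comparing decompositions of shifted deltas isolates
#' the effect of the decimation grid.
#'
#' @param n Signal length `N >= 2`.
#' @param l Impulse index, 0-based, in `[0, N)`.
#' @param sampling_rate Sampling rate in Hz (default 1000, the rate used by
#'   the delta experiments).
#' @return A [discrete_signal()].
#' @examples
#' delta_impulse(1000, 500) # the baseline probe of the delta experiments
#' @export
delta_impulse <- function(n, l, sampling_rate = 1000) {
  if (!is.numeric(n) || length(n) != 1 || n != round(n) || n < 2) {
    sw_abort("`n` must be a single integer >= 2.", "invalid_argument")
  }
  if (!is.numeric(l) || length(l) != 1 || l != round(l) || l < 0 || l >= n) {
    sw_abort("`l` must be an integer in [0, n).", "invalid_argument")
  }
  s <- numeric(n)
  s[l + 1] <- 1
  discrete_signal(s, sampling_rate)
}

#' Family of circularly shifted copies of a signal
#'
#' Circular right-shifts of `x` by each requested amount, in order. Energy
#' is preserved member-wise (a circular shift permutes samples). Shifts must
#' already lie in `[0, N)`: out-of-range values are an error rather than
#' being wrapped silently.
#'
#' @param x A [discrete_signal()].
#' @param shifts Integer vector of right shifts in `[0, N)`.
#' @return A list of [discrete_signal()]s, one per shift.
#' @examples
#' fam <- shifted_family(delta_impulse(1000, 500), 0:3)
#' vapply(fam, function(s) which(s$samples == 1) - 1, numeric(1)) # 500..503
#' @export
shifted_family <- function(x, shifts) {
  if (!inherits(x, "discrete_signal")) {
    sw_abort("`x` must be a discrete_signal.", "invalid_argument")
  }
  n <- length(x$samples)
  if (length(shifts) == 0 || any(shifts != round(shifts)) ||
      any(shifts < 0) || any(shifts >= n)) {
    sw_abort("`shifts` must be integers in [0, N).", "invalid_argument")
  }
  purrr::map(as.integer(shifts), function(s) shift_signal(x, s))
}

#' Parameters for the EEG surrogate generator
#'
#' Defaults emulate a short ictal-like scalp recording sampled at 200 Hz:
#' the four conventional rhythms (delta 0.5-4 Hz, theta 4-8 Hz, alpha
#' 8-13 Hz, beta 13-30 Hz) as band-limited stochastic oscillations with
#' amplitudes decreasing with frequency, a 1/f background, and sparse
#' spike-wave-like transients whose high-frequency content is what the
#' translation-variability diagnostics distort most visibly. Energy is
#' concentrated in the low band (>= 80% below 40 Hz under the defaults), as
#' in anti-alias-filtered clinical recordings.
#'
#' @param duration_s Duration in seconds (default 10).
#' @param sampling_rate Sampling rate in Hz (default 200).
#' @param rhythms Tibble/data frame with columns `band`, `low_hz`, `high_hz`,
#'   `amplitude` (relative RMS of each band-limited component).
#' @param one_over_f_exponent Spectral slope of the background noise
#'   (power ~ 1/f^a, default 1).
#' @param one_over_f_amplitude Relative RMS of the background (default 0.4).
#' @param transient_rate_hz Mean rate of spike-wave transients per second
#'   (default 0.5).
#' @param transient_amplitude Peak amplitude of each transient relative to
#'   unit rhythm RMS (default 3).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments including the seed.
#' @return A list of class `eeg_surrogate_params`.
#' @export
eeg_surrogate_params <- function(duration_s = 10,
                                 sampling_rate = 200,
                                 rhythms = tibble::tibble(
                                   band = c("delta", "theta", "alpha", "beta"),
                                   low_hz = c(0.5, 4, 8, 13),
                                   high_hz = c(4, 8, 13, 30),
                                   amplitude = c(1, 0.6, 0.45, 0.25)
                                 ),
                                 one_over_f_exponent = 1,
                                 one_over_f_amplitude = 0.4,
                                 transient_rate_hz = 0.5,
                                 transient_amplitude = 3,
                                 seed = 1L) {
  if (duration_s <= 0 || sampling_rate <= 0) {
    sw_abort("`duration_s` and `sampling_rate` must be positive.", "invalid_argument")
  }
  if (any(rhythms$high_hz >= sampling_rate / 2) ||
      any(rhythms$low_hz >= rhythms$high_hz) || any(rhythms$low_hz < 0)) {
    sw_abort("rhythm band edges must satisfy 0 <= low < high < Nyquist.", "invalid_argument")
  }
  if (any(rhythms$amplitude < 0) || all(rhythms$amplitude == 0)) {
    sw_abort("rhythm amplitudes must be >= 0 with at least one positive.", "invalid_argument")
  }
  if (one_over_f_exponent < 0 || transient_rate_hz < 0) {
    sw_abort("`one_over_f_exponent` and `transient_rate_hz` must be >= 0.", "invalid_argument")
  }
  structure(
    list(
      duration_s = duration_s, sampling_rate = sampling_rate,
      rhythms = tibble::as_tibble(rhythms),
      one_over_f_exponent = one_over_f_exponent,
      one_over_f_amplitude = one_over_f_amplitude,
      transient_rate_hz = transient_rate_hz,
      transient_amplitude = transient_amplitude,
      seed = as.integer(seed)
    ),
    class = "eeg_surrogate_params"
  )
}

#' Generate an EEG-like surrogate signal
#'
#' Deterministic given the seed in `params`. Each rhythm is seeded white
#' noise bandpassed in the frequency domain (bins outside the band zeroed)
#' and scaled to its relative RMS; the background is white noise shaped to a
#' 1/f^a amplitude profile; transients are Mexican-hat (Ricker) pulses of
#' ~40 ms width at Poisson-drawn times. The surrogate reproduces the gross
#' spectral shape of ictal recordings (low-frequency concentration plus
#' sparse sharp transients); it makes no claim of physiological realism.
#'
#' @param params An [eeg_surrogate_params()] object.
#' @return A [discrete_signal()] of `duration_s * sampling_rate` samples.
#' @examples
#' x <- synth_eeg(eeg_surrogate_params(seed = 42))
#' length(x) # 2000
#' @export
synth_eeg <- function(params = eeg_surrogate_params()) {
  if (!inherits(params, "eeg_surrogate_params")) {
    sw_abort("`params` must come from eeg_surrogate_params().", "invalid_argument")
  }
  fs <- params$sampling_rate
  n <- as.integer(round(params$duration_s * fs))
  withr::with_seed(params$seed, {
    freqs <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * fs / n
    x <- numeric(n)
    for (i in seq_len(nrow(params$rhythms))) {
      amp <- params$rhythms$amplitude[i]
      if (amp == 0) next
      keep <- abs(freqs) >= params$rhythms$low_hz[i] &
        abs(freqs) <= params$rhythms$high_hz[i]
      spec <- fft(rnorm(n))
      spec[!keep] <- 0
      comp <- Re(fft(spec, inverse = TRUE)) / n
      x <- x + amp * comp / stats::sd(comp)
    }
    if (params$one_over_f_amplitude > 0) {
      shape <- c(0, 1 / abs(freqs[-1])^(params$one_over_f_exponent / 2))
      spec <- fft(rnorm(n)) * shape
      bg <- Re(fft(spec, inverse = TRUE)) / n
      x <- x + params$one_over_f_amplitude * bg / stats::sd(bg)
    }
    if (params$transient_rate_hz > 0) {
      k <- rpois(1, params$transient_rate_hz * params$duration_s)
      if (k > 0) {
        centers <- sort(runif(k, 0, params$duration_s))
        width <- 0.02 # Ricker width parameter (s): ~40 ms main lobe
        t <- (seq_len(n) - 1) / fs
        for (tc in centers) {
          u <- (t - tc) / width
          x <- x + params$transient_amplitude * (1 - u^2) * exp(-u^2 / 2)
        }
      }
    }
    discrete_signal(x, fs)
  })
}
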