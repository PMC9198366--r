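#' One-sided FFT magnitude spectrum
#'
#' Magnitude of the discrete Fourier transform at bins `0..floor(N/2)`, with
#' the frequency axis in Hz derived from the sampling rate. Magnitude (not
#' complex) spectra are what the shift-sensitivity diagnostics compare:
#' the magnitude spectrum is invariant under circular shifts, so two shifted
#' inputs whose subspace spectra differ reveal genuine translation
#' variability rather than a pure delay.
#'
#' @param x A [discrete_signal()].
#' @return A tibble with columns `freq_hz` and `magnitude`.
#' @examples
#' fft_magnitude_spectrum(delta_impulse(16, 3)) # flat: DFT of a delta
#' @export
fft_magnitude_spectrum <- function(x) {
  if (!inherits(x, "discrete_signal")) {
    sw_abort("`x` must be a discrete_signal.", "invalid_argument")
  }
  n <- length(x$samples)
  bins <- 0:(n %/% 2)
  tibble::tibble(
    freq_hz = bins * x$sampling_rate / n,
    magnitude = Mod(fft(x$samples))[bins + 1]
  )
}

#' Count distinct spectral patterns
#'
#' Number of equivalence classes among magnitude spectra under the relation
#' `max|a - b| <= rel_tolerance * max|a|`, with classes built greedily in
#' input order against class representatives (deterministic). The default
#' tolerance separates the machine-precision congruence of redundant
#' subspaces from the order-one discrepancies of decimated ones by more than
#' six orders of magnitude.
#'
#' @param spectra A list of magnitude spectra: numeric vectors, or tibbles
#'   from [fft_magnitude_spectrum()] (the `magnitude` column is used). All
#'   must have the same length.
#' @param rel_tolerance Positive relative tolerance (default `1e-8`).
#' @return The number of distinct patterns (positive integer).
#' @export
count_distinct_patterns <- function(spectra, rel_tolerance = 1e-8) {
  if (!is.list(spectra) || length(spectra) == 0) {
    sw_abort("`spectra` must be a non-empty list.", "invalid_argument")
  }
  if (!is.numeric(rel_tolerance) || length(rel_tolerance) != 1 || rel_tolerance <= 0) {
    sw_abort("`rel_tolerance` must be a single positive number.", "invalid_argument")
  }
  mags <- purrr::map(spectra, function(s) {
    if (is.data.frame(s)) s$magnitude else as.double(s)
  })
  if (length(unique(lengths(mags))) != 1) {
    sw_abort("all spectra must have the same length.", "structural")
  }
  reps <- list()
  for (m in mags) {
    matched <- FALSE
    for (r in reps) {
      if (max(abs(r - m)) <= rel_tolerance * max(abs(r))) {
        matched <- TRUE
        break
      }
    }
    if (!matched) reps[[length(reps) + 1]] <- m
  }
  length(reps)
}

# band-isolated full-length subspaces as bare numeric vectors
transform_subspaces <- function(transform, x, fb, levels) {
  transform <- match.arg(transform, c("dwt", "rdwt"))
  ws <- if (transform == "dwt") {
    dwt_subspaces(dwt_decompose(x, fb, levels), fb)
  } else {
    rdwt_subspaces(rdwt_decompose(x, fb, levels), fb)
  }
  purrr::map(ws, "samples")
}

#' Estimate the translation-variability period of a subspace
#'
#' The TV period of band `j` is the smallest input shift `p >= 1` for which
#' the band's subspace output is exactly the `p`-shifted copy of the
#' baseline output (circular comparison, within `tolerance`). The search is
#' exhaustive over `1..max_period`, which is its own oracle at these problem
#' sizes. For the decimated transform the detail band `j` has period `2^j`
#' and the approximation band period `2^J`; every redundant band has
#' period 1 (exact shift invariance).
#'
#' @param transform `"dwt"` or `"rdwt"`.
#' @param x Baseline input signal.
#' @param fb Filter bank.
#' @param levels Decomposition depth `J`.
#' @param band Band index `j` in `1..J+1` (`J+1` is the approximation).
#' @param max_period Largest period searched (default `2^(levels+1)`).
#' @param tolerance Absolute comparison tolerance (default `1e-10`).
#' @return The smallest period found, or `max_period + 1` as a sentinel when
#'   no shift up to `max_period` restores equivariance.
#' @examples
#' fb <- daubechies_filterbank(2)
#' x <- delta_impulse(256, 128)
#' estimate_tv_periodicity("dwt", x, fb, levels = 2, band = 1) # 2
#' @export
estimate_tv_periodicity <- function(transform, x, fb, levels, band,
                                    max_period = 2^(levels + 1),
                                    tolerance = 1e-10) {
  if (!is.numeric(band) || length(band) != 1 || band != round(band) ||
      band < 1 || band > levels + 1) {
    sw_abort("`band` must be an integer in 1..levels+1.", "invalid_argument")
  }
  if (max_period > length(x$samples)) {
    sw_abort("`max_period` must not exceed the signal length.", "invalid_argument")
  }
  base <- transform_subspaces(transform, x, fb, levels)[[band]]
  for (p in seq_len(max_period)) {
    shifted <- transform_subspaces(transform, shift_signal(x, p), fb, levels)[[band]]
    if (max(abs(shifted - circ_shift(base, p))) < tolerance) return(as.integer(p))
  }
  as.integer(max_period + 1)
}

#' Linear time-invariance check of a decomposition
#'
#' For each band and each tested shift `s`, computes the equivariance
#' deviation `max | band(shift(x, s)) - shift(band(x), s) |` (the baseline
#' output is shifted, per the package's single circular-shift convention).
#' The verdict is LTI when every deviation is below `tolerance`; otherwise
#' LTV. The report also counts distinct magnitude-spectrum patterns across
#' the tested shifts and estimates each band's TV period.
#'
#' @inheritParams estimate_tv_periodicity
#' @param shifts Integer vector of shifts in `0..N-1` to test.
#' @param rel_tolerance Relative tolerance for spectral pattern counting.
#' @return A `shift_sensitivity_report`; see [tidy.shift_sensitivity_report()].
#' @examples
#' fb <- daubechies_filterbank(2)
#' x <- delta_impulse(256, 128)
#' lti_check("rdwt", x, fb, levels = 2, shifts = 0:7)$verdict # "LTI"
#' @export
lti_check <- function(transform, x, fb, levels, shifts,
                      tolerance = 1e-10, rel_tolerance = 1e-8) {
  if (length(shifts) == 0) {
    sw_abort("`shifts` must be a non-empty integer vector.", "invalid_argument")
  }
  n <- length(x$samples)
  if (any(shifts != round(shifts)) || any(shifts < 0) || any(shifts >= n)) {
    sw_abort("`shifts` must be integers in 0..N-1.", "invalid_argument")
  }
  transform <- match.arg(transform, c("dwt", "rdwt"))
  base <- transform_subspaces(transform, x, fb, levels)
  band_names <- names(base)
  fs <- x$sampling_rate

  dev <- matrix(NA_real_, nrow = length(base), ncol = length(shifts))
  spectra <- purrr::map(seq_along(base), function(b) vector("list", length(shifts)))
  for (si in seq_along(shifts)) {
    ws <- transform_subspaces(transform, shift_signal(x, shifts[si]), fb, levels)
    for (b in seq_along(base)) {
      dev[b, si] <- max(abs(ws[[b]] - circ_shift(base[[b]], shifts[si])))
      spectra[[b]][[si]] <- Mod(fft(ws[[b]]))[1:(n %/% 2 + 1)]
    }
  }

  per_band <- tibble::tibble(
    band = band_names,
    band_index = seq_along(base),
    estimated_period = purrr::map_int(
      seq_along(base),
      function(b) estimate_tv_periodicity(transform, x, fb, levels, b,
                                          tolerance = tolerance)
    ),
    distinct_pattern_count = purrr::map_int(
      spectra,
      function(sp) as.integer(count_distinct_patterns(sp, rel_tolerance))
    ),
    max_equivariance_deviation = apply(dev, 1, max)
  )
  structure(
    list(
      transform_label = transform,
      per_band = per_band,
      deviations = dev,
      tested_shifts = as.integer(shifts),
      tolerance = tolerance,
      rel_tolerance = rel_tolerance,
      verdict = if (max(dev) < tolerance) "LTI" else "LTV",
      filterbank_name = fb$name,
      levels = as.integer(levels),
      sampling_rate = fs
    ),
    class = "shift_sensitivity_report"
  )
}

#' @export
print.shift_sensitivity_report <- function(x, ...) {
  cat(sprintf(
    "<shift_sensitivity_report> %s (%s, J = %d): verdict %s over shifts {%s}\n",
    toupper(x$transform_label), x$filterbank_name, x$levels, x$verdict,
    paste(x$tested_shifts, collapse = ", ")
  ))
  print(x$per_band)
  invisible(x)
}

#' Theoretical spectral passing band of a wavelet subspace
#'
#' Detail band `j` nominally occupies `[fs / 2^(j+1), fs / 2^j]`; the
#' approximation band (`j = J + 1`) occupies the complementary low band
#' `[0, fs / 2^(J+1)]`. The diagnostics exist precisely because decimated
#' subspaces only conditionally respect these bands.
#'
#' @param band Band index `j` in `1..J+1`.
#' @param levels Decomposition depth `J`.
#' @param fs Sampling rate in Hz.
#' @return A one-row tibble with `low_hz`, `high_hz`.
#' @examples
#' theoretical_spb(1, 3, 1000) # 250..500 Hz
#' @export
theoretical_spb <- function(band, levels, fs) {
  if (!is.numeric(band) || length(band) != 1 || band != round(band) ||
      band < 1 || band > levels + 1) {
    sw_abort("`band` must be an integer in 1..levels+1.", "invalid_argument")
  }
  if (band == levels + 1) {
    tibble::tibble(low_hz = 0, high_hz = fs / 2^(levels + 1))
  } else {
    tibble::tibble(low_hz = fs / 2^(band + 1), high_hz = fs / 2^band)
  }
}

#' Empirical spectral passing band
#'
#' Smallest contiguous frequency interval containing at least
#' `energy_fraction` of the one-sided spectral energy of the signal; ties
#' are broken toward lower frequency. Comparing this against
#' [theoretical_spb()] quantifies how far a subspace leaks outside its
#' nominal band.
#'
#' @param subspace A nonzero [discrete_signal()] (typically one subspace
#'   from [dwt_subspaces()] / [rdwt_subspaces()]).
#' @param energy_fraction Fraction of total one-sided energy in `(0, 1]`.
#' @return A one-row tibble with `low_hz`, `high_hz`.
#' @export
empirical_spb <- function(subspace, energy_fraction = 0.9) {
  if (!is.numeric(energy_fraction) || length(energy_fraction) != 1 ||
      energy_fraction <= 0 || energy_fraction > 1) {
    sw_abort("`energy_fraction` must be in (0, 1].", "invalid_argument")
  }
  spec <- fft_magnitude_spectrum(subspace)
  p <- spec$magnitude^2
  total <- sum(p)
  if (total == 0) {
    sw_abort("the signal is identically zero; no passing band exists.", "degenerate_input")
  }
  target <- energy_fraction * total
  nb <- length(p)
  best <- c(lo = 1L, hi = nb)
  best_w <- nb
  # two-pointer sweep over contiguous bin windows
  lo <- 1L
  acc <- 0
  hi <- 0L
  while (lo <= nb) {
    while (acc < target && hi < nb) {
      hi <- hi + 1L
      acc <- acc + p[hi]
    }
    if (acc < target) break
    w <- hi - lo + 1L
    if (w < best_w) { # strict: ties keep the earlier (lower-frequency) window
      best_w <- w
      best <- c(lo = lo, hi = hi)
    }
    acc <- acc - p[lo]
    lo <- lo + 1L
  }
  tibble::tibble(
    low_hz = spec$freq_hz[best["lo"]],
    high_hz = spec$freq_hz[best["hi"]]
  )
}
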