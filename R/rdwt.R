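#' Redundant (undecimated) discrete wavelet transform
#'
#' The a trous scheme: the same filter bank as [dwt_decompose()] with the
#' down/upsampling removed. At level `j` the analysis filters are dilated by
#' inserting `2^(j-1) - 1` zeros between taps and applied by circular
#' convolution, with no decimation, so every band keeps the full input
#' length `N` and the expansion is overcomplete (`(J+1) * N` coefficients).
#' The sqrt(2)-normalized filters are kept at every level (the inverse
#' compensates with a factor 1/2 per level), which preserves the
#' subsampling identity: the decimated level-`j` detail equals the redundant
#' level-`j` detail taken at indices `0, 2^j, 2*2^j, ...`. Under circular
#' boundaries the redundant transform is exactly shift-invariant: shifting
#' the input circularly shifts every band by the same amount.
#'
#' @inheritParams dwt_decompose
#' @return A `redundant_decomposition` with the same fields as a
#'   `decimated_decomposition` but every band of length `N`.
#' @seealso [rdwt_reconstruct()], [rdwt_subspaces()]
#' @examples
#' x <- delta_impulse(64, 32)
#' dec <- rdwt_decompose(x, daubechies_filterbank(2), levels = 3)
#' lengths(dec$detail_coeffs) # 64 64 64
#' @export
rdwt_decompose <- function(x, fb, levels) {
  check_transform_args(x, fb, levels)
  n <- length(x$samples)
  if (n %% 2^levels != 0) {
    sw_abort(
      sprintf("signal length %d is not divisible by 2^levels = %d.", n, 2^levels),
      "divisibility"
    )
  }
  a <- x$samples
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    hd <- dilate_filter(fb$analysis_lowpass, 2^(j - 1))
    gd <- dilate_filter(fb$analysis_highpass, 2^(j - 1))
    details[[j]] <- circ_conv(a, gd)
    a <- circ_conv(a, hd)
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
    class = c("redundant_decomposition", "wavelet_decomposition")
  )
}

# insert (factor - 1) zeros between taps
dilate_filter <- function(f, factor) {
  if (factor == 1) return(f)
  out <- numeric((length(f) - 1) * factor + 1)
  out[seq(1, length(out), by = factor)] <- f
  out
}

#' Inverse redundant wavelet transform
#'
#' Per-level inverse averaging the redundant polyphase branches: with
#' analysis bands `A = H x`, `D = G x` (circular filtering), the orthonormal
#' quadrature-mirror pair satisfies `|H|^2 + |G|^2 = 2` pointwise on the
#' frequency grid, so `x = (H* A + G* D) / 2`. Applied level by level with
#' the dilated filters; exact to machine precision.
#'
#' @param dec A `redundant_decomposition`.
#' @param fb The filter bank the decomposition was produced with.
#' @return The reconstructed [discrete_signal()].
#' @export
rdwt_reconstruct <- function(dec, fb) {
  check_decomposition(dec, fb, "redundant_decomposition")
  n <- dec$original_length
  a <- dec$approx_coeffs
  for (j in rev(seq_len(dec$levels))) {
    hf <- fft(pad_to(dilate_filter(fb$analysis_lowpass, 2^(j - 1)), n))
    gf <- fft(pad_to(dilate_filter(fb$analysis_highpass, 2^(j - 1)), n))
    a <- Re(fft((Conj(hf) * fft(a) + Conj(gf) * fft(dec$detail_coeffs[[j]])) / 2,
                inverse = TRUE)) / n
  }
  discrete_signal(a, dec$sampling_rate)
}

# pad (wrapping) a filter to length n for frequency-domain use
pad_to <- function(f, n) {
  out <- numeric(n)
  idx <- ((seq_along(f) - 1) %% n) + 1
  for (i in seq_along(f)) out[idx[i]] <- out[idx[i]] + f[i]
  out
}

#' Full-length wavelet subspaces of a redundant decomposition
#'
#' Band-isolated reconstructions, as in [dwt_subspaces()]: subspace `j` is
#' [rdwt_reconstruct()] with all other bands zeroed. Subspaces sum to the
#' input, and each is circular-shift-equivariant with it — the property that
#' makes the redundant transform a linear time-invariant system.
#'
#' @inheritParams rdwt_reconstruct
#' @return A named list of `J + 1` full-length [discrete_signal()]s.
#' @export
rdwt_subspaces <- function(dec, fb) {
  check_decomposition(dec, fb, "redundant_decomposition")
  J <- dec$levels
  out <- vector("list", J + 1)
  for (b in seq_len(J + 1)) {
    z <- dec
    for (j in seq_len(J)) if (j != b) z$detail_coeffs[[j]][] <- 0
    if (b != J + 1) z$approx_coeffs[] <- 0
    out[[b]] <- rdwt_reconstruct(z, fb)
  }
  names(out) <- c(paste0("w", seq_len(J)), "approx")
  out
}
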