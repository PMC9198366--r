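test_that("coefficient lengths follow the dyadic pyramid", {
  x <- random_signal(1000)
  dec <- dwt_decompose(x, daubechies_filterbank(8), levels = 3)
  expect_identical(unname(lengths(dec$detail_coeffs)), c(500L, 250L, 125L))
  expect_length(dec$approx_coeffs, 125)
})

test_that("highpass annihilates constants; Haar delta has two half-power taps", {
  fb <- daubechies_filterbank(1)
  const <- discrete_signal(rep(3, 8), 8)
  dec <- dwt_decompose(const, fb, 1)
  expect_equal(dec$detail_coeffs[[1]], rep(0, 4), tolerance = 1e-14)
  expect_equal(dec$approx_coeffs, rep(3 * sqrt(2), 4), tolerance = 1e-13)

  # delta at index 0: circular convolution + even-index decimation puts
  # exactly one 1/sqrt(2) in each branch
  dec2 <- dwt_decompose(delta_impulse(8, 0, 8), fb, 1)
  expect_equal(sum(dec2$detail_coeffs[[1]] != 0), 1)
  expect_equal(sum(dec2$approx_coeffs != 0), 1)
  expect_equal(max(abs(dec2$detail_coeffs[[1]])), 1 / sqrt(2), tolerance = 1e-14)
  expect_equal(max(abs(dec2$approx_coeffs)), 1 / sqrt(2), tolerance = 1e-14)
})

test_that("round trip is exact and energy is conserved (property sweep)", {
  for (case in 1:25) {
    n <- sample(c(64, 256, 512), 1)
    p <- sample(1:10, 1)
    J <- sample(1:3, 1)
    x <- random_signal(n, seed = 100 + case)
    fb <- daubechies_filterbank(p)
    dec <- dwt_decompose(x, fb, J)
    energy <- sum(vapply(dec$detail_coeffs, function(d) sum(d^2), numeric(1))) +
      sum(dec$approx_coeffs^2)
    expect_lt(abs(energy - sum(x$samples^2)), 1e-10)
    xr <- dwt_reconstruct(dec, fb)
    expect_lt(max(abs(xr$samples - x$samples)), 1e-10)
  }
})

test_that("all-zero coefficients reconstruct to the zero signal", {
  fb <- daubechies_filterbank(4)
  dec <- dwt_decompose(random_signal(128), fb, 2)
  for (j in seq_len(dec$levels)) dec$detail_coeffs[[j]][] <- 0
  dec$approx_coeffs[] <- 0
  expect_equal(max(abs(dwt_reconstruct(dec, fb)$samples)), 0)
})

test_that("subspaces are full length, additive, and detail-free for constants", {
  fb <- daubechies_filterbank(8)
  x <- random_signal(256)
  dec <- dwt_decompose(x, fb, 3)
  ws <- dwt_subspaces(dec, fb)
  expect_named(ws, c("w1", "w2", "w3", "approx"))
  expect_true(all(vapply(ws, length, integer(1)) == 256))
  expect_lt(max(abs(subspace_sum(ws) - x$samples)), 1e-10)

  const <- discrete_signal(rep(2.5, 64), 1000)
  wsc <- dwt_subspaces(dwt_decompose(const, fb, 2), fb)
  expect_lt(max(abs(wsc$w1$samples)), 1e-10)
  expect_lt(max(abs(wsc$w2$samples)), 1e-10)
})

test_that("delta subspace spectra concentrate in their theoretical bands", {
  fb <- daubechies_filterbank(8)
  x <- delta_impulse(1000, 500, 1000)
  ws <- dwt_subspaces(dwt_decompose(x, fb, 3), fb)
  for (j in 1:3) {
    spec <- fft_magnitude_spectrum(ws[[j]])
    band <- theoretical_spb(j, 3, 1000)
    inside <- spec$freq_hz >= band$low_hz & spec$freq_hz <= band$high_hz
    frac <- sum(spec$magnitude[inside]^2) / sum(spec$magnitude^2)
    expect_gte(frac, 0.6)
  }
})

test_that("decimated transform is translation-variant but 2^J-shift equivariant", {
  fb <- daubechies_filterbank(8)
  x <- delta_impulse(1000, 500, 1000)
  J <- 3
  base <- dwt_subspaces(dwt_decompose(x, fb, J), fb)

  # one-sample shift visibly distorts the finest subspace (LTV witness)
  shifted1 <- dwt_subspaces(dwt_decompose(shift_signal(x, 1), fb, J), fb)
  dev1 <- max(abs(shifted1$w1$samples - shift_vec(base$w1$samples, 1)))
  expect_gt(dev1, 0.01 * max(abs(base$w1$samples)))

  # a 2^J shift commutes with the whole pyramid, coefficient for coefficient
  dec0 <- dwt_decompose(x, fb, J)
  dec8 <- dwt_decompose(shift_signal(x, 2^J), fb, J)
  for (j in seq_len(J)) {
    expect_lt(max(abs(dec8$detail_coeffs[[j]] - shift_vec(dec0$detail_coeffs[[j]], 2^(J - j)))), 1e-12)
  }
  expect_lt(max(abs(dec8$approx_coeffs - shift_vec(dec0$approx_coeffs, 1))), 1e-12)
})

test_that("preconditions are enforced", {
  fb <- daubechies_filterbank(2)
  x <- random_signal(100) # 100 not divisible by 8
  expect_error(dwt_decompose(x, fb, 3), "divisible", class = "shiftwave_error_divisibility")
  expect_error(dwt_decompose(x, fb, 0), class = "shiftwave_error_invalid_argument")

  dec <- dwt_decompose(random_signal(64), fb, 2)
  expect_error(dwt_reconstruct(dec, daubechies_filterbank(3)),
               class = "shiftwave_error_incompatible")
  broken <- dec
  broken$detail_coeffs[[1]] <- broken$detail_coeffs[[1]][-1]
  expect_error(dwt_reconstruct(broken, fb), class = "shiftwave_error_structural")
})
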