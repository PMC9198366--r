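test_that("magnitude spectrum: delta is flat, tones are single-bin, shifts invisible", {
  d <- delta_impulse(64, 10, 64)
  spec <- fft_magnitude_spectrum(d)
  expect_equal(nrow(spec), 33)
  expect_lt(max(abs(spec$magnitude - 1)), 1e-12)
  expect_equal(spec$freq_hz, 0:32)

  n <- 128; fs <- 128
  tone <- discrete_signal(sin(2 * pi * 10 * (0:(n - 1)) / fs), fs)
  st <- fft_magnitude_spectrum(tone)
  expect_equal(st$freq_hz[which.max(st$magnitude)], 10)
  expect_gt(max(st$magnitude), 100 * sort(st$magnitude, decreasing = TRUE)[2])

  x <- random_signal(256)
  for (s in c(1, 13, 200)) {
    expect_lt(max(abs(fft_magnitude_spectrum(shift_signal(x, s))$magnitude -
                        fft_magnitude_spectrum(x)$magnitude)), 1e-10)
  }
})

test_that("distinct-pattern counting is deterministic and tolerance-driven", {
  a <- c(1, 2, 3); b <- a + 1e-12; c1 <- c(5, 5, 5)
  expect_identical(count_distinct_patterns(list(a, a, a, a)), 1L)
  expect_identical(count_distinct_patterns(list(a, b, c1, a)), 2L)
  expect_identical(count_distinct_patterns(list(a, c1, b, c1)), 2L)
  # below tolerance everything collapses
  expect_identical(count_distinct_patterns(list(a, c1), rel_tolerance = 10), 1L)
  expect_error(count_distinct_patterns(list(a, c(1, 2))),
               class = "shiftwave_error_structural")
})

test_that("TV periodicity law: 2^j for details, 2^J for approximation, 1 for RDWT", {
  for (p in c(2, 8)) {
    fb <- daubechies_filterbank(p)
    for (setup in list(list(n = 256, J = 2), list(n = 1000, J = 3))) {
      x <- delta_impulse(setup$n, setup$n / 2, 1000)
      for (j in seq_len(setup$J)) {
        expect_identical(
          estimate_tv_periodicity("dwt", x, fb, setup$J, j),
          as.integer(2^j),
          info = sprintf("db%d N=%d J=%d band=%d", p, setup$n, setup$J, j)
        )
      }
      expect_identical(
        estimate_tv_periodicity("dwt", x, fb, setup$J, setup$J + 1),
        as.integer(2^setup$J)
      )
      expect_identical(estimate_tv_periodicity("rdwt", x, fb, setup$J, 1), 1L)
      expect_identical(estimate_tv_periodicity("rdwt", x, fb, setup$J, setup$J + 1), 1L)
    }
  }
})

test_that("periodicity also holds on random (non-impulse) inputs", {
  fb <- daubechies_filterbank(4)
  x <- random_signal(256)
  expect_identical(estimate_tv_periodicity("dwt", x, fb, 2, 1), 2L)
  expect_identical(estimate_tv_periodicity("dwt", x, fb, 2, 2), 4L)
  expect_identical(estimate_tv_periodicity("rdwt", x, fb, 2, 2), 1L)
})

test_that("lti_check separates the two transforms and is self-consistent", {
  fb <- daubechies_filterbank(8)
  x <- delta_impulse(1000, 500, 1000)

  rep_rdwt <- lti_check("rdwt", x, fb, 3, shifts = 0:15)
  expect_identical(rep_rdwt$verdict, "LTI")
  expect_lt(max(rep_rdwt$per_band$max_equivariance_deviation), 1e-10)
  expect_true(all(rep_rdwt$per_band$distinct_pattern_count == 1L))
  expect_true(all(rep_rdwt$per_band$estimated_period == 1L))

  rep_dwt <- lti_check("dwt", x, fb, 3, shifts = 0:15)
  expect_identical(rep_dwt$verdict, "LTV")
  w1 <- rep_dwt$per_band[rep_dwt$per_band$band == "w1", ]
  expect_gt(w1$max_equivariance_deviation, rep_dwt$tolerance)
  expect_gt(w1$distinct_pattern_count, 1L)

  # shifts that are multiples of 2^J pass the per-shift equivariance check
  rep_mult <- lti_check("dwt", x, fb, 3, shifts = c(0, 8, 16, 24))
  expect_identical(rep_mult$verdict, "LTI")
  expect_lt(max(rep_mult$per_band$max_equivariance_deviation), 1e-10)
  expect_true(all(rep_mult$per_band$distinct_pattern_count == 1L))

  # glance/tidy expose the same content
  expect_identical(tidy(rep_dwt), rep_dwt$per_band)
  expect_identical(glance(rep_dwt)$verdict, "LTV")
  expect_error(lti_check("dwt", x, fb, 3, shifts = integer(0)),
               class = "shiftwave_error_invalid_argument")
})

test_that("theoretical passing bands follow the dyadic formula", {
  b1 <- theoretical_spb(1, 3, 1000)
  expect_equal(c(b1$low_hz, b1$high_hz), c(250, 500))
  b3 <- theoretical_spb(3, 3, 200)
  expect_equal(c(b3$low_hz, b3$high_hz), c(12.5, 25))
  ba <- theoretical_spb(4, 3, 1000)
  expect_equal(c(ba$low_hz, ba$high_hz), c(0, 62.5))
  expect_error(theoretical_spb(5, 3, 1000), class = "shiftwave_error_invalid_argument")
})

test_that("empirical passing band finds constructed concentrations", {
  n <- 2000; fs <- 200
  # bandpass noise synthesized in 8..12 Hz
  freqs <- c(0:(n / 2), -((n / 2 - 1):1)) * fs / n
  spec <- withr::with_seed(7, fft(rnorm(n)))
  spec[abs(freqs) < 8 | abs(freqs) > 12] <- 0
  bp <- discrete_signal(Re(fft(spec, inverse = TRUE)) / n, fs)
  band <- empirical_spb(bp, 0.9)
  expect_gte(band$low_hz, 6)
  expect_lte(band$high_hz, 14)

  tone <- discrete_signal(cos(2 * pi * 25 * (0:(n - 1)) / fs), fs)
  bt <- empirical_spb(tone, 0.9)
  expect_lte(bt$high_hz - bt$low_hz, 3 * fs / n)
  expect_lte(bt$low_hz, 25)
  expect_gte(bt$high_hz, 25)

  bd <- empirical_spb(delta_impulse(64, 5, 64), 1.0)
  expect_equal(c(bd$low_hz, bd$high_hz), c(0, 32))

  expect_error(empirical_spb(discrete_signal(rep(0, 16), 16), 0.9),
               class = "shiftwave_error_degenerate_input")
})
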