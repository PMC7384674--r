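test_that("waveform sampling matches the shape definitions", {
  s <- stim_signal("rectangular", amplitude = 1, pulse_width = 60e-6,
                   repetition_rate = 130)
  expect_equal(sample_signal(s, 30e-6), 1)
  expect_equal(sample_signal(s, 100e-6), 0)
  # periodic: one full period later, same values
  expect_equal(sample_signal(s, 30e-6 + 1 / 130), 1)
  tri <- stim_signal("centered_triangular", pulse_width = 60e-6)
  expect_equal(sample_signal(tri, 30e-6), 1)        # apex
  expect_equal(sample_signal(tri, 15e-6), 0.5)      # half way up
  rmp <- stim_signal("ramp", pulse_width = 60e-6)
  expect_equal(sample_signal(rmp, 30e-6), 0.5)
  # in-period phase shift moves the pulse
  sh <- stim_signal("rectangular", pulse_width = 60e-6, phase_shift = 1e-3)
  expect_equal(sample_signal(sh, 30e-6), 0)
  expect_equal(sample_signal(sh, 1e-3 + 30e-6), 1)
})

test_that("signal constructor rejects invalid parameters", {
  expect_error(stim_signal(pulse_width = 1 / 100, repetition_rate = 130),
               "pulse_width")
  expect_error(stim_signal(repetition_rate = 0), "repetition_rate")
})

test_that("Fourier coefficients: DC term, linearity, empty spectrum", {
  s <- stim_signal("rectangular", amplitude = 1, pulse_width = 60e-6,
                   repetition_rate = 130)
  sp <- fourier_coefficients(s, 1e6)
  expect_equal(Re(sp$coefficients[1]), 1 * 60e-6 * 130, tolerance = 1e-12)
  expect_equal(sp$frequencies[1:3], c(0, 130, 260))
  s3 <- stim_signal("rectangular", amplitude = 3, pulse_width = 60e-6,
                    repetition_rate = 130)
  sp3 <- fourier_coefficients(s3, 1e6)
  expect_equal(sp3$coefficients, 3 * sp$coefficients, tolerance = 1e-12)
  expect_error(fourier_coefficients(s, 100), "empty")
  # triangular and ramp DC terms are the pulse means
  expect_equal(Re(fourier_coefficients(
    stim_signal("centered_triangular"), 1e4)$coefficients[1]),
    0.5 * 60e-6 * 130)
  expect_equal(Re(fourier_coefficients(
    stim_signal("ramp"), 1e4)$coefficients[1]), 0.5 * 60e-6 * 130)
})

test_that("band-limited reconstruction converges to the waveform", {
  # avoid sampling exactly at the jump discontinuities
  t <- seq(0, 1 / 130, length.out = 1500)
  t <- t + 0.37 * diff(t)[1]
  for (shape in c("rectangular", "centered_triangular", "ramp")) {
    s <- stim_signal(shape, amplitude = 1, pulse_width = 60e-6)
    sp <- fourier_coefficients(s, 1e6)
    rec <- reconstruct_time_course(sp, 1 + 0i, t)
    rms <- sqrt(mean((rec - sample_signal(s, t))^2))
    expect_lt(rms, 0.02)
    # Parseval: band-limited spectral power never exceeds the analytic
    # signal power, and approaches it from below
    power <- sum(ifelse(sp$frequencies == 0, 1, 2) * Mod(sp$coefficients)^2)
    ana <- if (shape == "rectangular") 60e-6 * 130 else 60e-6 * 130 / 3
    expect_lte(power, ana * (1 + 1e-9))
    expect_gt(power, 0.98 * ana)
  }
})

test_that("truncation schemes select the documented harmonics", {
  s <- stim_signal("rectangular")
  sp <- fourier_coefficients(s, 2000)
  seqt <- truncate_spectrum(sp, truncation_scheme("sequential",
                                                  n_components = 3))
  expect_equal(seqt$frequencies, c(0, 130, 260))
  mag <- truncate_spectrum(sp, truncation_scheme("magnitude_ranked",
                                                 n_components = 1))
  expect_equal(mag$frequencies,
               sp$frequencies[which.max(Mod(sp$coefficients))])
  expect_warning(truncate_spectrum(sp, truncation_scheme(
    "sequential", n_components = 1000)), "clamp")
  # octave band starting above f_max: identity mapping
  oct <- truncate_spectrum(sp, truncation_scheme(
    "octave_band", octave_start_frequency = 5000))
  expect_equal(oct$rep_index, seq_along(sp$frequencies))
  expect_equal(solve_frequencies(oct), sp$frequencies)
})

test_that("octave-band truncation shares solves but keeps coefficients", {
  s <- stim_signal("rectangular")
  sp <- fourier_coefficients(s, 2e4)
  oct <- truncate_spectrum(sp, truncation_scheme(
    "octave_band", octave_start_frequency = 1000))
  expect_lt(length(solve_frequencies(oct)), length(sp$frequencies))
  expect_equal(oct$coefficients, sp$coefficients)
  # identity transfer: reconstruction identical to the untruncated one
  t <- seq(0, 1 / 130, length.out = 400)
  expect_equal(reconstruct_time_course(oct, 1 + 0i, t),
               reconstruct_time_course(sp, 1 + 0i, t), tolerance = 1e-12)
})

test_that("magnitude-ranked truncation error is monotone in n", {
  s <- stim_signal("rectangular")
  sp <- fourier_coefficients(s, 5e4)
  t <- seq(0, 1 / 130, length.out = 600) + 1e-7
  ref <- sample_signal(s, t)
  errs <- vapply(c(5, 20, 80, 200), function(n) {
    tr <- truncate_spectrum(sp, truncation_scheme("magnitude_ranked",
                                                  n_components = n))
    sqrt(mean((reconstruct_time_course(tr, 1 + 0i, t) - ref)^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("reconstruction handles degenerate transfers and errors", {
  sp <- fourier_coefficients(stim_signal("rectangular"), 1e4)
  t <- seq(0, 1 / 130, length.out = 50)
  expect_equal(reconstruct_time_course(sp, 0 + 0i, t), rep(0, 50))
  expect_error(reconstruct_time_course(sp, complex(5), t), "transfer")
})

test_that("low-pass transfer matches the analytic RC response", {
  s <- stim_signal("rectangular", amplitude = 1, pulse_width = 60e-6,
                   repetition_rate = 130)
  sp <- fourier_coefficients(s, 1e6)
  fc <- 3000
  H <- 1 / (1 + 1i * sp$frequencies / fc)
  t <- seq(0, 1 / 130, length.out = 1200) + 1e-8
  rec <- reconstruct_time_course(sp, H, t)
  # closed-form steady-state RC response to the periodic pulse
  tau <- 1 / (2 * pi * fc); Tp <- 1 / 130; w <- 60e-6
  v0 <- (1 - exp(-w / tau)) * exp(-(Tp - w) / tau) / (1 - exp(-Tp / tau))
  v1 <- 1 + (v0 - 1) * exp(-w / tau)
  ana <- ifelse(t < w, 1 + (v0 - 1) * exp(-t / tau),
                v1 * exp(-(t - w) / tau))
  expect_lt(sqrt(mean((rec - ana)^2)), 0.02)
})

test_that("spectrum CSV round trip preserves coefficients", {
  sp <- fourier_coefficients(stim_signal("ramp"), 5000)
  f <- tempfile(fileext = ".csv")
  write_spectrum_csv(sp, f)
  sp2 <- read_spectrum_csv(f)
  expect_equal(sp2$frequencies, sp$frequencies)
  expect_equal(sp2$coefficients, sp$coefficients, tolerance = 1e-12)
  unlink(f)
})
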