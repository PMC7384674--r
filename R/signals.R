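# Stimulus waveforms, their Fourier-series representation, spectrum
# truncation schemes, and reconstruction of time courses from per-frequency
# field solutions (the Fourier-FEM signal path).

#' Stimulus signal description
#'
#' @param shape one of `"rectangular"`, `"centered_triangular"`, `"ramp"`.
#' @param amplitude pulse amplitude (V in voltage mode, A in current mode).
#' @param pulse_width pulse width, seconds.
#' @param repetition_rate pulse repetition rate, Hz.
#' @param phase_shift in-period shift of the pulse onset, seconds.
#' @param mode `"voltage"` or `"current"`.
#' @return an object of class `stim_signal`.
#' @export
stim_signal <- function(shape = c("rectangular", "centered_triangular", "ramp"),
                        amplitude = 1, pulse_width = 60e-6,
                        repetition_rate = 130, phase_shift = 0,
                        mode = c("voltage", "current")) {
  shape <- match.arg(shape)
  mode <- match.arg(mode)
  if (repetition_rate <= 0) stop("repetition_rate must be > 0")
  if (!is.finite(amplitude)) stop("amplitude must be finite")
  if (pulse_width <= 0 || pulse_width >= 1 / repetition_rate)
    stop("pulse_width must lie in (0, 1/repetition_rate)")
  structure(list(shape = shape, amplitude = amplitude,
                 pulse_width = pulse_width,
                 repetition_rate = repetition_rate,
                 phase_shift = phase_shift, mode = mode),
            class = "stim_signal")
}

#' Sample a stimulus waveform
#'
#' Evaluates the periodic waveform at the given times. The rectangular
#' pulse equals `amplitude` on `[phase_shift, phase_shift + pulse_width)`
#' within each period and 0 elsewhere; the centered triangular pulse ramps
#' linearly to its apex at the pulse centre; the ramp rises linearly from 0
#' to `amplitude` over the pulse and drops back.
#'
#' @param signal a [stim_signal].
#' @param times numeric vector of times, seconds.
#' @return numeric vector of waveform values.
#' @export
sample_signal <- function(signal, times) {
  stopifnot(inherits(signal, "stim_signal"))
  T <- 1 / signal$repetition_rate
  u <- (times - signal$phase_shift) %% T   # time since pulse onset
  w <- signal$pulse_width
  A <- signal$amplitude
  inside <- u < w
  switch(signal$shape,
    rectangular = ifelse(inside, A, 0),
    centered_triangular = ifelse(inside, A * (1 - abs(2 * u / w - 1)), 0),
    ramp = ifelse(inside, A * u / w, 0),
    stop("unsupported signal shape: ", signal$shape))
}

#' Fourier-series coefficients of a stimulus signal
#'
#' Computes the complex Fourier-series coefficients
#' `c_k = (1/T) \int_T s(t) exp(-j 2 pi k f0 t) dt` of the periodic signal
#' at the harmonics `k * repetition_rate`, DC included, up to `f_max`.
#' Closed forms are used for the three supported shapes. The spectrum is
#' stored one-sided; reconstruction applies weight 1 to DC and 2 to k > 0
#' (conjugate symmetry of the real signal).
#'
#' @param signal a [stim_signal].
#' @param f_max highest retained frequency, Hz (default 1 MHz, truncated to
#'   the nearest harmonic below).
#' @return an object of class `spectrum` with fields `frequencies`,
#'   `coefficients`, `f0`, `f_max`, `rep_index` (per-harmonic index of the
#'   representative solve frequency; identity before truncation).
#' @export
fourier_coefficients <- function(signal, f_max = 1e6) {
  stopifnot(inherits(signal, "stim_signal"))
  f0 <- signal$repetition_rate
  if (f_max < f0) stop("empty spectrum: f_max below the repetition rate")
  kmax <- floor(f_max / f0 + 1e-9)
  k <- 0:kmax
  w <- signal$pulse_width
  A <- signal$amplitude
  s <- signal$phase_shift
  th <- 2 * pi * k * f0                    # angular frequency per harmonic
  sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(x) / x)
  coeff <- switch(signal$shape,
    rectangular =
      A * f0 * w * sinc(th * w / 2) * exp(-1i * th * (s + w / 2)),
    centered_triangular =
      A * f0 * (w / 2) * sinc(th * w / 4)^2 * exp(-1i * th * (s + w / 2)),
    ramp = {
      # (A/w) * (1/T) * int_0^w u exp(-j th u) du, shifted by s
      cc <- complex(length.out = length(k))
      for (i in seq_along(k)) {
        if (k[i] == 0) { cc[i] <- A * f0 * w / 2; next }
        p <- -1i * th[i]
        cc[i] <- (A * f0 / w) * (exp(p * w) * (w / p - 1 / p^2) + 1 / p^2) *
          exp(-1i * th[i] * s)
      }
      cc
    },
    stop("unsupported signal shape: ", signal$shape))
  structure(list(frequencies = k * f0, coefficients = coeff,
                 f0 = f0, f_max = kmax * f0,
                 rep_index = seq_along(k)),
            class = "spectrum")
}

#' Spectrum truncation scheme
#'
#' @param method `"sequential"` (first `n_components` harmonics),
#'   `"magnitude_ranked"` (`n_components` largest-magnitude harmonics) or
#'   `"octave_band"` (all harmonics below `octave_start_frequency` solved
#'   individually; above it one representative harmonic per geometric
#'   octave band `[f, 2f)` carries the field solution for every band
#'   member, whose own coefficients are retained).
#' @param n_components number of retained harmonics (first two methods).
#' @param octave_start_frequency band start frequency, Hz (octave method).
#' @return an object of class `truncation_scheme`.
#' @export
truncation_scheme <- function(method = c("sequential", "magnitude_ranked",
                                         "octave_band"),
                              n_components = NULL,
                              octave_start_frequency = NULL) {
  method <- match.arg(method)
  if (method %in% c("sequential", "magnitude_ranked")) {
    if (is.null(n_components) || n_components < 1)
      stop("n_components >= 1 required for method '", method, "'")
  } else if (is.null(octave_start_frequency) || octave_start_frequency <= 0) {
    stop("octave_start_frequency required for octave_band truncation")
  }
  structure(list(method = method, n_components = n_components,
                 octave_start_frequency = octave_start_frequency),
            class = "truncation_scheme")
}

#' Truncate a spectrum
#'
#' Applies a [truncation_scheme]. For the sequential and magnitude-ranked
#' methods the returned spectrum holds only the retained harmonics. For the
#' octave-band method every harmonic (and its coefficient) is kept, but
#' `rep_index` maps each harmonic above the band start onto the band's
#' representative harmonic, so that one field solve per band is shared by
#' all band members.
#'
#' @param spec a `spectrum`.
#' @param scheme a [truncation_scheme].
#' @return a `spectrum`; `solve_frequencies(spec)` lists the frequencies
#'   that actually require a field solve.
#' @export
truncate_spectrum <- function(spec, scheme) {
  stopifnot(inherits(spec, "spectrum"), inherits(scheme, "truncation_scheme"))
  n_avail <- length(spec$frequencies)
  if (scheme$method %in% c("sequential", "magnitude_ranked")) {
    n <- scheme$n_components
    if (n > n_avail) {
      warning("n_components clamped to the ", n_avail, " available harmonics")
      n <- n_avail
    }
    keep <- if (scheme$method == "sequential") seq_len(n)
            else sort(order(Mod(spec$coefficients), decreasing = TRUE)[1:n])
    out <- spec
    out$frequencies <- spec$frequencies[keep]
    out$coefficients <- spec$coefficients[keep]
    out$rep_index <- seq_along(keep)
    return(out)
  }
  # octave_band: representatives below the start frequency are the
  # harmonics themselves; geometric bands [f, 2f) above it.
  f <- spec$frequencies
  fs <- scheme$octave_start_frequency
  rep_index <- seq_along(f)
  above <- which(f >= fs & f > 0)
  if (length(above)) {
    band <- floor(log2(f[above] / fs))            # octave band number
    for (b in unique(band)) {
      members <- above[band == b]
      centre <- fs * 2^b * sqrt(2)                # geometric band centre
      repm <- members[which.min(abs(f[members] - centre))]
      rep_index[members] <- repm
    }
  }
  out <- spec
  out$rep_index <- rep_index
  out
}

#' Frequencies that require a field solve
#' @param spec a `spectrum` (possibly truncated).
#' @return numeric vector of unique representative frequencies.
#' @export
solve_frequencies <- function(spec) {
  spec$frequencies[sort(unique(spec$rep_index))]
}

#' Reconstruct a time course from spectrum and transfer values
#'
#' Computes `v(t) = sum_k w_k Re( c_k H(f_rep(k)) exp(j 2 pi f_k t) )`
#' with one-sided weights `w_0 = 1`, `w_k = 2` for k > 0. `transfer` gives
#' the complex transfer value H at every solve frequency (a harmonic above
#' an octave-band start reuses its band representative's transfer).
#'
#' @param spec a `spectrum` (possibly truncated).
#' @param transfer complex vector of transfer values, either of length
#'   `length(solve_frequencies(spec))` (per solve frequency) or of length
#'   `length(spec$frequencies)` (per harmonic), or a single value recycled.
#' @param times numeric vector of times, seconds.
#' @return numeric vector, the reconstructed real time course.
#' @export
reconstruct_time_course <- function(spec, transfer, times) {
  stopifnot(inherits(spec, "spectrum"))
  nf <- length(spec$frequencies)
  reps <- sort(unique(spec$rep_index))
  H <- if (length(transfer) == 1) rep(as.complex(transfer), nf)
  else if (length(transfer) == length(reps)) {
    as.complex(transfer)[match(spec$rep_index, reps)]
  } else if (length(transfer) == nf) {
    as.complex(transfer)[match(spec$rep_index, seq_len(nf))]
  } else {
    stop("transfer must have one value per solve frequency (",
         length(reps), ") or per harmonic (", nf, ")")
  }
  if (anyNA(H)) {
    bad <- spec$frequencies[which(is.na(H))[1]]
    stop("missing transfer value for frequency ", bad, " Hz")
  }
  wts <- ifelse(spec$frequencies == 0, 1, 2)
  ck <- spec$coefficients * H * wts
  vapply(times, function(t)
    sum(Re(ck * exp(1i * 2 * pi * spec$frequencies * t))), numeric(1))
}

#' Export a spectrum as CSV
#' @param spec a `spectrum`.
#' @param path output CSV path (`frequency_hz, coeff_real, coeff_imag`).
#' @export
write_spectrum_csv <- function(spec, path) {
  utils::write.csv(data.frame(frequency_hz = spec$frequencies,
                              coeff_real = Re(spec$coefficients),
                              coeff_imag = Im(spec$coefficients)),
                   path, row.names = FALSE)
}

#' Read a spectrum from CSV
#' @param path CSV written by [write_spectrum_csv].
#' @return a `spectrum` (identity representative mapping).
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path)
  f <- d$frequency_hz
  structure(list(frequencies = f,
                 coefficients = complex(real = d$coeff_real,
                                        imaginary = d$coeff_imag),
                 f0 = if (length(f) > 1) diff(f)[1] else f[1],
                 f_max = max(f), rep_index = seq_along(f)),
            class = "spectrum")
}
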