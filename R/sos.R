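# Butterworth band-pass design as cascaded second-order sections (biquads).
#
# High-order narrow band-pass filters at low normalized frequencies are
# numerically fragile in transfer-function form (the pole polynomial is
# ill-conditioned); the cascade form keeps each section second order and
# preserves linearity of the zero-phase filter to near machine precision.
# Design: analog Butterworth prototype poles, low-pass-to-band-pass
# transform, bilinear map; zeros land at z = +/-1 (one pair per section) and
# the overall gain is normalized to 1 at the warped center frequency.
butter_bandpass_sos <- function(order, low, high, fs) {
  if (!(low > 0 && high > low && high < fs / 2))
    stop_invalid("band edges must satisfy 0 < low < high < fs/2")
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  B <- w2 - w1
  W0 <- sqrt(w1 * w2)
  k <- seq_len(order)
  p_proto <- exp(1i * (pi / 2 + pi * (2 * k - 1) / (2 * order)))
  s_all <- unlist(lapply(p_proto, function(p) {
    t1 <- p * B / 2
    rad <- sqrt(t1^2 - W0^2)
    c(t1 + rad, t1 - rad)
  }))
  s_up <- s_all[Im(s_all) > 1e-12 * Mod(s_all)]
  if (length(s_up) != order)
    stop("unexpected pole configuration in band-pass design", call. = FALSE)
  zp <- (fs2 + s_up) / (fs2 - s_up)          # bilinear transform of poles
  sos <- t(vapply(zp, function(z)
    c(1, 0, -1, -2 * Re(z), Mod(z)^2), numeric(5)))
  fc <- atan(W0 / fs2) * fs / pi             # warped center frequency (Hz)
  g <- Mod(sos_response(sos, fc, fs))
  sos[, 1:3] <- sos[, 1:3] * (1 / g)^(1 / nrow(sos))
  sos
}

# Complex frequency response of an SOS cascade at frequencies f (Hz).
sos_response <- function(sos, f, fs) {
  e1 <- exp(-1i * 2 * pi * f / fs)
  e2 <- e1^2
  H <- rep(1 + 0i, length(f))
  for (s in seq_len(nrow(sos))) {
    H <- H * (sos[s, 1] + sos[s, 2] * e1 + sos[s, 3] * e2) /
      (1 + sos[s, 4] * e1 + sos[s, 5] * e2)
  }
  H
}

# Zero-phase band-pass of a samples x series matrix.
bandpass_zero_phase <- function(x, low, high, fs, order = 4) {
  .filtfilt_sos(butter_bandpass_sos(order, low, high, fs), x)
}
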