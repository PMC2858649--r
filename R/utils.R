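#' Number of samples covering a time window
#'
#' Sample count of a post-stimulus analysis window of duration `dur_s` at
#' sampling rate `sfreq_hz`, counting the pulse sample (t = 0) as the first
#' sample. 250 ms at 725 Hz gives 182 samples, the per-channel denominator
#' used by the Divergence Index.
#'
#' @param dur_s window duration in seconds.
#' @param sfreq_hz sampling rate in Hz.
#' @return integer sample count, `ceiling(dur_s * sfreq_hz)`.
#' @examples
#' n_window_samples(0.250, 725)  # 182
#' @export
n_window_samples <- function(dur_s, sfreq_hz) {
  stopifnot(dur_s > 0, sfreq_hz > 0)
  as.integer(ceiling(dur_s * sfreq_hz))
}

# Deterministic stage-seed derivation: every source of randomness in the
# package is seeded from a single master seed plus a stage tag, so a run is
# reproducible end to end from one integer. Values stay below 2^31 - 1.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647  # 2^31 - 1
  h <- (abs(seed) %% m)
  for (b in utf8ToInt(as.character(tag))) {
    h <- (h * 48271 + b) %% m
  }
  as.integer(max(1, h))
}

# withr-free local RNG: run expr with its own seed, restore global state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# 1/f ("pink") noise via spectral shaping: white Gaussian spectrum scaled by
# f^(-1/2) above a 1 Hz floor, inverse FFT, normalized to unit rms. The floor
# keeps the (high-pass-filtered in real amplifiers) near-DC region bounded.
pink_noise <- function(n, sfreq_hz) {
  nf <- n %/% 2L
  f <- seq_len(nf) * sfreq_hz / n
  shape <- 1 / sqrt(pmax(f, 1))
  re <- stats::rnorm(nf) * shape
  im <- stats::rnorm(nf) * shape
  spec <- complex(real = re, imaginary = im)
  full <- complex(length.out = n)
  full[2:(nf + 1L)] <- spec
  # Hermitian symmetry for a real signal
  full[n:(n - nf + 2L)] <- Conj(spec[seq_len(nf - 1L)])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# Mean one-sided power spectral density over a frequency band, Hann-tapered
# periodogram. x in volts; returns density in the square of `unit_scale`
# (pass 1e-6 to get uV^2/Hz from volts).
band_psd <- function(x, sfreq_hz, band_hz, unit_scale = 1e-6) {
  n <- length(x)
  stopifnot(n > 8)
  x <- (x - mean(x)) / unit_scale
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))  # Hann
  X <- stats::fft(x * w)
  nf <- n %/% 2L
  f <- seq_len(nf) * sfreq_hz / n
  # one-sided density normalized by the taper power
  psd <- 2 * Mod(X[2:(nf + 1L)])^2 / (sfreq_hz * sum(w^2))
  sel <- f >= band_hz[1] & f <= band_hz[2]
  if (!any(sel)) stop("band [", band_hz[1], ", ", band_hz[2], "] Hz outside spectrum")
  mean(psd[sel])
}
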