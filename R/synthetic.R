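#' Configuration for a synthetic TMS-EEG session
#'
#' Describes one stimulation session: target site (Brodmann area), stimulator
#' intensity (percent of maximal output), coil angle, recording day, and the
#' noise/artifact model. Defaults emulate the acquisition regime the analysis
#' assumes: ~200 single pulses, 60 EEG channels plus one vertical EOG,
#' 1450 Hz sampling, -250..+250 ms epochs.
#'
#' Intensity drives a multiplicative evoked gain `(intensity_pct/50)^2`
#' (quadratic in the usual 40-75% working range, so a +10-point step is a
#' clearly supra-noise amplitude change) and a small latency shift; the site
#' selects a fixed spatial amplitude map; the coil angle offsets component
#' phases and partially remixes the maps.
#'
#' @param site stimulation target, one of `"BA6"`, `"BA7"`, `"BA19"`.
#' @param intensity_pct stimulator output percentage (1-100).
#' @param angle_deg coil angle in degrees: 0, 45 or 90.
#' @param day session day (1 = reference day; other days add drift).
#' @param n_trials number of TMS pulses (epochs).
#' @param sfreq_hz acquisition sampling rate, Hz.
#' @param epoch_pre_s,epoch_post_s epoch spans before/after the pulse, s.
#' @param channel_names EEG channel labels; must be a subset of
#'   [tep_montage()] and include `"F8"`. An EOG channel is appended
#'   automatically.
#' @param noise list: `pink_uv` (per-channel 1/f background rms, uV),
#'   `white_uv` (sensor noise rms, uV), `eog_noise_uv` (EOG background rms,
#'   uV), `amp_jitter` (sd of the multiplicative trial amplitude factor),
#'   `latency_jitter_ms` (sd of the trial latency shift, ms).
#' @param artifacts list: `blink_rate` (per-trial blink probability),
#'   `blink_uv` (blink amplitude on EOG, uV), `muscle_rate` (per-trial
#'   probability of a >25 Hz muscle burst on F8), `muscle_uv` (burst rms, uV).
#' @param session_drift sd of the multiplicative per-channel perturbation of
#'   the evoked amplitude maps applied on days other than day 1 (a few
#'   percent emulates one-week test-retest drift).
#' @param seed integer; the session is bit-reproducible from (config, seed).
#' @return object of class `tep_config`.
#' @export
session_config <- function(site = c("BA19", "BA6", "BA7"),
                           intensity_pct = 50,
                           angle_deg = 0,
                           day = 1L,
                           n_trials = 200L,
                           sfreq_hz = 1450,
                           epoch_pre_s = 0.250,
                           epoch_post_s = 0.250,
                           channel_names = tep_montage()$label,
                           noise = list(),
                           artifacts = list(),
                           session_drift = 0.03,
                           seed = 1L) {
  site <- match.arg(site)
  noise_def <- list(pink_uv = 9, white_uv = 2, eog_noise_uv = 6,
                    amp_jitter = 0.10, latency_jitter_ms = 1.0)
  art_def <- list(blink_rate = 0.08, blink_uv = 180,
                  muscle_rate = 0.05, muscle_uv = 35)
  noise <- utils::modifyList(noise_def, noise)
  artifacts <- utils::modifyList(art_def, artifacts)

  if (!angle_deg %in% c(0, 45, 90)) stop("angle_deg must be 0, 45 or 90")
  if (intensity_pct <= 0 || intensity_pct > 100)
    stop("intensity_pct must be in (0, 100]")
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (sfreq_hz <= 0) stop("sfreq_hz must be positive")
  if (epoch_pre_s <= 0 || epoch_post_s <= 0) stop("epoch spans must be positive")
  rates <- c(artifacts$blink_rate, artifacts$muscle_rate)
  if (any(rates < 0 | rates > 1)) stop("artifact rates must be in [0, 1]")
  amps <- c(noise$pink_uv, noise$white_uv, noise$eog_noise_uv, noise$amp_jitter,
            noise$latency_jitter_ms, artifacts$blink_uv, artifacts$muscle_uv,
            session_drift)
  if (any(amps < 0)) stop("noise/artifact amplitudes must be >= 0")
  montage_positions(channel_names)  # errors on unknown labels
  if (!"F8" %in% channel_names)
    stop("channel_names must include F8 (muscle-artifact monitor channel)")

  structure(list(site = site, intensity_pct = intensity_pct,
                 angle_deg = angle_deg, day = as.integer(day),
                 n_trials = as.integer(n_trials), sfreq_hz = sfreq_hz,
                 epoch_pre_s = epoch_pre_s, epoch_post_s = epoch_post_s,
                 channel_names = as.character(channel_names),
                 noise = noise, artifacts = artifacts,
                 session_drift = session_drift, seed = as.integer(seed)),
            class = "tep_config")
}

# ---- evoked model -----------------------------------------------------------
# The evoked response is a sum of K = 3 damped sinusoids per channel (alpha /
# low-beta / high-beta bands, all inside the 2-80 Hz analysis band), each with
# a smooth bipolar spatial amplitude map anchored at the stimulated site.
# Maps are deterministic per site (fixed internal seeds), independent of the
# session seed, so "same site" always means "same topography".

evoked_params <- function(site, angle_deg) {
  freq_hz <- c(10, 22, 33)
  tau_s <- c(0.090, 0.050, 0.035)
  amp_uv <- c(15, 10, 6)
  centers0 <- switch(site,
    BA6  = c(-0.75, 1.2),
    BA7  = c(-0.75, -2.4),
    BA19 = c(-0.75, -3.6))
  k <- length(freq_hz)
  # fixed site-keyed draws: per-component center offset, width, dipole axis,
  # dipole spatial frequency, phase origin, angle-remix direction
  site_draw <- with_seed(derive_seed(74210, site), {
    list(center_off = matrix(stats::rnorm(2 * k, sd = 0.45), k, 2),
         sigma = 1.5 + abs(stats::rnorm(k, sd = 0.35)),
         axis = {
           a <- matrix(stats::rnorm(2 * k), k, 2)
           a / sqrt(rowSums(a^2))
         },
         beta = 0.9 + abs(stats::rnorm(k, sd = 0.4)),
         theta = stats::runif(k, -pi, pi),
         remix = matrix(stats::rnorm(2 * k, sd = 0.55), k, 2))
  })
  # angle: component phase offsets plus a partial shift of the map centers
  phase <- angle_deg * pi / 180 * c(0.5, 1.0, 1.5)
  centers <- sweep(site_draw$center_off, 2, centers0, "+") +
    (angle_deg / 90) * site_draw$remix
  list(freq_hz = freq_hz, tau_s = tau_s, amp_uv = amp_uv, phase = phase,
       centers = centers, sigma = site_draw$sigma, axis = site_draw$axis,
       beta = site_draw$beta, theta = site_draw$theta)
}

# channels x K amplitude maps in uV (EEG channels only)
evoked_maps <- function(pos, p) {
  k <- length(p$freq_hz)
  maps <- matrix(0, nrow(pos), k)
  for (i in seq_len(k)) {
    d2 <- (pos[, 1] - p$centers[i, 1])^2 + (pos[, 2] - p$centers[i, 2])^2
    proj <- (pos[, 1] - p$centers[i, 1]) * p$axis[i, 1] +
            (pos[, 2] - p$centers[i, 2]) * p$axis[i, 2]
    maps[, i] <- p$amp_uv[i] * exp(-d2 / (2 * p$sigma[i]^2)) *
      cos(p$theta[i] + p$beta[i] * proj)
  }
  maps
}

intensity_gain <- function(intensity_pct) (intensity_pct / 50)^2

# Onset latency: >= 8 ms always (amplifier guarantee); higher intensities
# recruit slightly earlier.
onset_latency_s <- function(intensity_pct) {
  (8 + 2 * max(0, 70 - intensity_pct) / 30) / 1000
}

#' Noise-free evoked template of a session configuration
#'
#' The deterministic per-channel evoked response (EEG channels only, no EOG)
#' implied by a configuration: K damped sinusoids with site-specific bipolar
#' amplitude maps, angle-dependent phases/topography, intensity gain and
#' latency. Zero before the onset latency.
#'
#' @param config a [session_config()].
#' @param drift_mult optional channels x K multiplicative map perturbation
#'   (used internally for between-day drift).
#' @return list: `template` (channels x samples matrix, volts), `times`
#'   (seconds, pulse at 0), `maps` (channels x K, uV), `onset_latency_s`,
#'   `gain`.
#' @export
evoked_template <- function(config, drift_mult = NULL) {
  stopifnot(inherits(config, "tep_config"))
  sf <- config$sfreq_hz
  n_pre <- as.integer(ceiling(config$epoch_pre_s * sf))
  n_post <- as.integer(floor(config$epoch_post_s * sf))
  n <- n_pre + 1L + n_post
  times <- (seq_len(n) - 1L - n_pre) / sf

  p <- evoked_params(config$site, config$angle_deg)
  pos <- montage_positions(config$channel_names)
  maps <- evoked_maps(pos, p)
  if (!is.null(drift_mult)) maps <- maps * drift_mult
  gain <- intensity_gain(config$intensity_pct)
  t0 <- onset_latency_s(config$intensity_pct)

  tpl <- matrix(0, nrow(pos), n)
  act <- times >= t0
  ta <- times[act] - t0
  for (i in seq_along(p$freq_hz)) {
    wav <- sin(2 * pi * p$freq_hz[i] * ta + p$phase[i]) * exp(-ta / p$tau_s[i])
    tpl[, act] <- tpl[, act] + maps[, i] %o% wav
  }
  list(template = gain * tpl * 1e-6, times = times, maps = maps,
       onset_latency_s = t0, gain = gain, onset_sample = n_pre)
}

# smooth spatially correlated pink background: n_src 1/f sources mixed onto
# channels with a Gaussian spatial kernel, rows normalized so every channel
# has unit-rms colored noise before scaling by pink_uv
noise_mixing <- function(pos, n_src = 12) {
  gx <- seq(-3, 3, length.out = 4)
  gy <- seq(-3.5, 3.5, length.out = 3)
  src <- as.matrix(expand.grid(x = gx, y = gy))
  W <- exp(-(outer(pos[, 1], src[, 1], "-")^2 +
             outer(pos[, 2], src[, 2], "-")^2) / (2 * 1.5^2))
  W / sqrt(rowSums(W^2))
}

# stereotyped ~300 ms biphasic blink transient, peak amplitude ~1 (unitless)
blink_waveform <- function(times, t_center) {
  exp(-(times - t_center)^2 / (2 * 0.045^2)) -
    0.4 * exp(-(times - t_center - 0.110)^2 / (2 * 0.075^2))
}

#' Generate one synthetic epoched TMS-EEG session
#'
#' Each trial is the configuration's evoked template scaled by the intensity
#' gain and a multiplicative amplitude jitter, time-shifted by a latency
#' jitter, plus spatially correlated pink background noise and white sensor
#' noise. The appended EOG channel carries background noise plus
#' Bernoulli-drawn blink transients (with frontal leakage onto EEG
#' channels); channel F8 additionally receives Bernoulli-drawn band-limited
#' (>25 Hz) muscle bursts. Output is bit-identical for identical
#' (config, seed).
#'
#' @param config a [session_config()].
#' @return an [eeg_session()]; data in volts, EOG appended as last channel.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "tep_config"))
  sf <- config$sfreq_hz

  drift_mult <- NULL
  if (config$day != 1L && config$session_drift > 0) {
    drift_mult <- with_seed(
      derive_seed(config$seed, paste0("drift_day", config$day)),
      matrix(1 + stats::rnorm(length(config$channel_names) * 3,
                              sd = config$session_drift),
             ncol = 3))
  }
  ev <- evoked_template(config, drift_mult = drift_mult)
  tpl <- ev$template                       # volts, EEG channels x samples
  n_eeg <- nrow(tpl)
  n <- ncol(tpl)
  n_tr <- config$n_trials
  nz <- config$noise
  ar <- config$artifacts
  pos <- montage_positions(config$channel_names)
  W <- noise_mixing(pos)
  n_src <- ncol(W)
  f8 <- match("F8", config$channel_names)

  data <- array(0, dim = c(n_tr, n_eeg + 1L, n))
  with_seed(config$seed, {
    amp_fac <- 1 + stats::rnorm(n_tr, sd = nz$amp_jitter)
    lat_shift <- as.integer(round(stats::rnorm(n_tr, sd = nz$latency_jitter_ms)
                                  * sf / 1000))
    blink_on <- stats::runif(n_tr) < ar$blink_rate
    blink_t <- stats::runif(n_tr, min(ev$times) + 0.08, max(ev$times) - 0.12)
    muscle_on <- stats::runif(n_tr) < ar$muscle_rate
    muscle_t0 <- stats::runif(n_tr, 0, max(0, n - as.integer(0.15 * sf) - 1))

    # precompute band-pass for muscle bursts (25 Hz up to near Nyquist)
    b_mus <- signal::butter(4, c(25, min(150, 0.45 * sf)) / (sf / 2),
                            type = "pass")

    for (k in seq_len(n_tr)) {
      sig <- tpl * amp_fac[k]
      if (lat_shift[k] != 0L) {
        shifted <- matrix(0, n_eeg, n)
        if (lat_shift[k] > 0L) {
          shifted[, (1L + lat_shift[k]):n] <- sig[, 1L:(n - lat_shift[k])]
        } else {
          s <- -lat_shift[k]
          shifted[, 1L:(n - s)] <- sig[, (1L + s):n]
        }
        sig <- shifted
      }
      if (nz$pink_uv > 0) {
        src <- matrix(0, n_src, n)
        for (j in seq_len(n_src)) src[j, ] <- pink_noise(n, sf)
        sig <- sig + nz$pink_uv * 1e-6 * (W %*% src)
      } else {
        # keep the RNG stream aligned across noise settings is not required;
        # determinism only holds for identical configs
      }
      if (nz$white_uv > 0)
        sig <- sig + nz$white_uv * 1e-6 * matrix(stats::rnorm(n_eeg * n), n_eeg, n)

      eog <- numeric(n)
      if (nz$eog_noise_uv > 0)
        eog <- eog + nz$eog_noise_uv * 1e-6 * pink_noise(n, sf) +
          0.3 * nz$eog_noise_uv * 1e-6 * stats::rnorm(n)
      if (blink_on[k] && ar$blink_uv > 0) {
        bw <- blink_waveform(ev$times, blink_t[k])
        eog <- eog + ar$blink_uv * 1e-6 * bw
        # frontal leakage, decaying with distance from the eyes
        leak <- pmax(0, (pos[, 2] - 2) / 2) * 0.15
        sig <- sig + (leak * ar$blink_uv * 1e-6) %o% bw
      }
      if (muscle_on[k] && ar$muscle_uv > 0) {
        len <- as.integer(0.15 * sf)
        burst <- signal::filtfilt(b_mus, stats::rnorm(len + 40L))
        burst <- burst[21:(20 + len)]
        burst <- burst / max(stats::sd(burst), 1e-12) * ar$muscle_uv * 1e-6
        env <- 0.5 - 0.5 * cos(2 * pi * seq(0, len - 1) / (len - 1))
        i0 <- as.integer(muscle_t0[k]) + 1L
        idx <- i0:min(n, i0 + len - 1L)
        sig[f8, idx] <- sig[f8, idx] + (burst * env)[seq_along(idx)]
      }
      data[k, seq_len(n_eeg), ] <- sig
      data[k, n_eeg + 1L, ] <- eog
    }
  })

  eeg_session(
    data, sfreq_hz = sf, onset_sample = ev$onset_sample,
    channel_names = c(config$channel_names, "EOG"),
    eog_index = n_eeg,  # 0-based
    meta = list(site = config$site, intensity_pct = config$intensity_pct,
                angle_deg = config$angle_deg, day = config$day,
                seed = config$seed))
}

#' Generate a pair of sessions differing in at most one stimulation parameter
#'
#' Mirrors the change / no-change (C / NC) design: the second session is
#' identical to the first except for the named parameter. `change = "none"`
#' differs only in the noise realization (and in between-day drift when
#' `day_b` is not day 1 and `session_drift > 0`).
#'
#' @param config base [session_config()] for the first session.
#' @param change `"none"`, `"site"`, `"intensity"` or `"angle"`.
#' @param magnitude for `"site"`: the new site label; for `"intensity"`: the
#'   change in percentage points (default +10, the I% vs I%+10% design); for
#'   `"angle"`: the new coil angle in degrees (45 or 90).
#' @param seeds integer pair: seeds of the two sessions.
#' @param day_b recording day of the second session (default: same day).
#' @return list with elements `a` and `b`, both [eeg_session()] objects.
#' @export
make_comparison_pair <- function(config, change = "none", magnitude = NULL,
                                 seeds = c(1L, 2L), day_b = NULL) {
  stopifnot(inherits(config, "tep_config"), length(seeds) == 2L)
  if (!change %in% c("none", "site", "intensity", "angle"))
    stop("unknown change label: ", change)
  cfg_a <- config
  cfg_a$seed <- as.integer(seeds[1])
  cfg_b <- config
  cfg_b$seed <- as.integer(seeds[2])
  if (!is.null(day_b)) cfg_b$day <- as.integer(day_b)
  if (change == "site") {
    if (is.null(magnitude)) stop("change = 'site' needs the new site as magnitude")
    if (!magnitude %in% c("BA6", "BA7", "BA19")) stop("unknown site: ", magnitude)
    if (identical(magnitude, config$site)) stop("site change names the same site")
    cfg_b$site <- magnitude
  } else if (change == "intensity") {
    if (is.null(magnitude)) magnitude <- 10
    cfg_b$intensity_pct <- config$intensity_pct + magnitude
    if (cfg_b$intensity_pct <= 0 || cfg_b$intensity_pct > 100)
      stop("intensity change leaves (0, 100]")
  } else if (change == "angle") {
    if (is.null(magnitude)) stop("change = 'angle' needs the new angle as magnitude")
    if (!magnitude %in% c(0, 45, 90)) stop("angle must be 0, 45 or 90")
    if (magnitude == config$angle_deg) stop("angle change names the same angle")
    cfg_b$angle_deg <- magnitude
  }
  list(a = generate_session(cfg_a), b = generate_session(cfg_b))
}
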