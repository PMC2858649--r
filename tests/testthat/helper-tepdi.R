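# Shared fixtures, all generated in code.

# Small quiet config: few trials, artifacts off unless asked for.
quiet_config <- function(n_trials = 12, seed = 1, site = "BA19", ...) {
  session_config(site = site, n_trials = n_trials, seed = seed,
                 artifacts = list(blink_rate = 0, muscle_rate = 0), ...)
}

noise_free <- list(pink_uv = 0, white_uv = 0, eog_noise_uv = 0,
                   amp_jitter = 0, latency_jitter_ms = 0)

# Hand-built session: deterministic array, EOG last, includes F8.
manual_session <- function(n_trials = 8, n_samples = 120, sfreq = 200,
                           onset = 60, channels = c("F3", "F8", "Cz", "EOG"),
                           fill = 0) {
  arr <- array(fill, dim = c(n_trials, length(channels), n_samples))
  eeg_session(arr, sfreq_hz = sfreq, onset_sample = onset,
              channel_names = channels, eog_index = length(channels) - 1L,
              meta = list(), require_spans = FALSE)
}

# Trials x channels x samples of iid Gaussian noise plus a fixed waveform,
# for null-calibration style checks at the array level.
noise_trials <- function(n_trials, n_channels, n_samples, sd_v = 2e-6,
                         template = NULL) {
  a <- array(stats::rnorm(n_trials * n_channels * n_samples, sd = sd_v),
             dim = c(n_trials, n_channels, n_samples))
  if (!is.null(template)) a <- sweep(a, 3, template, "+")
  a
}

# Exhaustive trial-mixing null for tiny groups: enumerates every partition
# of the pooled trials into a group of size n_a, averages that group, and
# returns the exact max-statistic distribution and threshold. Independent of
# build_null (direct enumeration).
exhaustive_null <- function(A, B, alpha) {
  n_a <- dim(A)[1]
  pool <- rbind(matrix(A, nrow = dim(A)[1]), matrix(B, nrow = dim(B)[1]))
  sets <- utils::combn(nrow(pool), n_a)
  mixed <- t(apply(sets, 2, function(ix) colMeans(pool[ix, , drop = FALSE])))
  delta <- colMeans(mixed)
  centered <- abs(sweep(mixed, 2, delta))
  max_stats <- apply(centered, 1, max)
  k <- ceiling((1 - alpha) * length(max_stats))
  list(max_stats = sort(max_stats), G = sort(max_stats)[k], delta = delta)
}
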