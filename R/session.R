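#' Epoched TMS-EEG session
#'
#' Container for single-pulse epoched EEG: a trials x channels x samples
#' voltage array (volts) with its sampling rate, pulse-onset index, channel
#' labels, EOG channel index and stimulation metadata. Sample indexing is
#' 0-based in the stored fields (`onset_sample`, `eog_index`) to match the
#' on-disk format; time t = 0 s is at `onset_sample`.
#'
#' @param data numeric array, trials x channels x samples, volts.
#' @param sfreq_hz sampling rate in Hz.
#' @param onset_sample 0-based index of the TMS pulse sample.
#' @param channel_names character vector, one label per channel.
#' @param eog_index 0-based index of the vertical EOG channel, or `NA` if
#'   the session carries no EOG.
#' @param meta named list of stimulation metadata (`subject`, `day`, `site`,
#'   `intensity_pct`, `angle_deg`, free-form extras).
#' @param require_spans validate that at least 250 ms of pre- and
#'   post-stimulus data are present (half-sample tolerance). The statistical
#'   pipeline requires both spans; set `FALSE` only for intermediate objects.
#' @return object of class `eeg_session`.
#' @export
eeg_session <- function(data, sfreq_hz, onset_sample, channel_names,
                        eog_index = NA_integer_, meta = list(),
                        require_spans = TRUE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3-D array (trials x channels x samples)")
  if (!all(is.finite(data))) stop("data contains non-finite samples")
  d <- dim(data)
  if (length(channel_names) != d[2])
    stop("channel_names length (", length(channel_names),
         ") != channels (", d[2], ")")
  if (sfreq_hz <= 0) stop("sfreq_hz must be positive")
  onset_sample <- as.integer(onset_sample)
  if (onset_sample < 0L || onset_sample >= d[3])
    stop("onset_sample (", onset_sample, ") out of range [0, ", d[3] - 1L, "]")
  if (!is.na(eog_index)) {
    eog_index <- as.integer(eog_index)
    if (eog_index < 0L || eog_index >= d[2])
      stop("eog_index (", eog_index, ") out of range [0, ", d[2] - 1L, "]")
  }
  s <- structure(
    list(data = data, sfreq_hz = sfreq_hz, onset_sample = onset_sample,
         channel_names = as.character(channel_names),
         eog_index = eog_index, meta = meta),
    class = "eeg_session")
  if (require_spans) validate_spans(s, 0.250, 0.250)
  s
}

# Pre/post spans in seconds; tolerance of half a sample so that a symmetric
# -250..+250 ms epoch (e.g. 726 samples at 1450 Hz) validates.
validate_spans <- function(session, pre_s, post_s) {
  n <- dim(session$data)[3]
  sf <- session$sfreq_hz
  tol <- 0.5 / sf + 1e-12
  pre <- session$onset_sample / sf
  post <- (n - 1L - session$onset_sample) / sf
  if (pre < pre_s - tol)
    stop(sprintf("epoch too short: pre-stimulus span %.1f ms < required %.0f ms",
                 1000 * pre, 1000 * pre_s))
  if (post < post_s - tol)
    stop(sprintf("epoch too short: post-stimulus span %.1f ms < required %.0f ms",
                 1000 * post, 1000 * post_s))
  invisible(session)
}

#' @export
print.eeg_session <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_session> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sfreq_hz))
  cat(sprintf("  onset_sample %d (t in [%.1f, %.1f] ms), EOG index %s\n",
              x$onset_sample, -1000 * x$onset_sample / x$sfreq_hz,
              1000 * (d[3] - 1 - x$onset_sample) / x$sfreq_hz,
              ifelse(is.na(x$eog_index), "none", x$eog_index)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Time axis of a session or evoked potential
#'
#' @param x an `eeg_session` or `evoked_tep`.
#' @return numeric vector of times in seconds relative to the TMS pulse.
#' @export
tep_times <- function(x) {
  n <- if (inherits(x, "eeg_session")) dim(x$data)[3] else ncol(x$data)
  (seq_len(n) - 1L - x$onset_sample) / x$sfreq_hz
}

# 1-based column indices of the post-stimulus analysis window:
# `n_window_samples(dur_s, sfreq)` samples starting at the pulse sample.
post_window_idx <- function(onset_sample, n_samples, sfreq_hz, dur_s = 0.250) {
  k <- n_window_samples(dur_s, sfreq_hz)
  idx <- (onset_sample + 1L):(onset_sample + k)
  if (max(idx) > n_samples)
    stop(sprintf("post-stimulus window needs %d samples after the pulse, only %d available",
                 k, n_samples - onset_sample))
  idx
}

# 1-based column indices of the pre-stimulus baseline window (dur_s seconds
# immediately before the pulse sample).
baseline_window_idx <- function(onset_sample, sfreq_hz, dur_s = 0.250) {
  k <- min(onset_sample, as.integer(floor(dur_s * sfreq_hz)) + 1L)
  if (k < 8L) stop("baseline window too short (", k, " samples)")
  (onset_sample - k + 1L):onset_sample
}

# EEG (non-EOG) channel indices, 1-based.
eeg_channel_idx <- function(session) {
  idx <- seq_len(dim(session$data)[2])
  if (!is.na(session$eog_index)) idx <- idx[idx != session$eog_index + 1L]
  idx
}
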