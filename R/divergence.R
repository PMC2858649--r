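#' Equalize pre-stimulus baseline distributions of two trial sets
#'
#' Before mixing trials from two sessions, their 250 ms pre-stimulus
#' baselines must be exchangeable. Each trial is summarized as the mean over
#' EEG channels of its mean absolute baseline voltage; a Wilcoxon rank-sum
#' test (normal approximation with tie correction) compares the two groups
#' of summaries. While P <= `p_floor`, the single trial whose summary lies
#' farthest from the pooled median is removed from its group and the test is
#' repeated. Removal is capped at `max_removed_frac` of the pooled trials;
#' if equivalence is not reached within the cap, an error asks for manual
#' inspection.
#'
#' @param a,b [eeg_session()] objects with identical channels and sampling.
#' @param p_floor rank-sum P value above which the baselines are accepted.
#' @param max_removed_frac maximum fraction of pooled trials removable.
#' @param baseline_s baseline duration before the pulse, seconds.
#' @return list: `a`, `b` (trimmed sessions), `n_removed`,
#'   `removed` (list of trial indices removed from each session, original
#'   numbering), `p_value` (final rank-sum P).
#' @export
equalize_baselines <- function(a, b, p_floor = 0.05, max_removed_frac = 0.05,
                               baseline_s = 0.250) {
  stopifnot(inherits(a, "eeg_session"), inherits(b, "eeg_session"))
  if (!identical(a$channel_names, b$channel_names))
    stop("sessions have different channel sets")
  if (a$sfreq_hz != b$sfreq_hz) stop("sessions have different sampling rates")

  summarize <- function(s) {
    idx <- baseline_window_idx(s$onset_sample, s$sfreq_hz, baseline_s)
    ch <- eeg_channel_idx(s)
    apply(abs(s$data[, ch, idx, drop = FALSE]), 1, mean)
  }
  sa <- summarize(a)
  sb <- summarize(b)
  keep_a <- seq_along(sa)
  keep_b <- seq_along(sb)
  cap <- floor(max_removed_frac * (length(sa) + length(sb)))
  n_removed <- 0L
  removed <- list(a = integer(), b = integer())

  repeat {
    if (length(keep_a) < 2L || length(keep_b) < 2L)
      stop("baseline equalization removed too many trials from one group")
    p <- stats::wilcox.test(sa[keep_a], sb[keep_b], exact = FALSE,
                            correct = TRUE)$p.value
    if (p > p_floor) break
    if (n_removed >= cap)
      stop(sprintf(paste0("baseline distributions still differ (P = %.3g) after ",
                          "removing %d trials (%.0f%% cap); inspect the recordings"),
                   p, n_removed, 100 * max_removed_frac))
    pooled <- c(sa[keep_a], sb[keep_b])
    med <- stats::median(pooled)
    dev_a <- abs(sa[keep_a] - med)
    dev_b <- abs(sb[keep_b] - med)
    if (max(dev_a) >= max(dev_b)) {
      i <- keep_a[which.max(dev_a)]
      removed$a <- c(removed$a, i)
      keep_a <- setdiff(keep_a, i)
    } else {
      i <- keep_b[which.max(dev_b)]
      removed$b <- c(removed$b, i)
      keep_b <- setdiff(keep_b, i)
    }
    n_removed <- n_removed + 1L
  }

  a$data <- a$data[keep_a, , , drop = FALSE]
  b$data <- b$data[keep_b, , , drop = FALSE]
  list(a = a, b = b, n_removed = n_removed, removed = removed, p_value = p)
}

as_trial_array <- function(x) {
  if (inherits(x, "eeg_session")) x$data
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("trials must be an eeg_session or a trials x channels x samples array")
}

#' Trial-mixing permutation null with max-statistic correction over time
#'
#' Pools the single trials of two sessions and, `n_perm` times, randomly
#' re-partitions them (without replacement) into two groups of the original
#' sizes; the average of the first re-formed group is one "mixed" evoked
#' potential. Per channel and time sample, the center of the mixed-average
#' distribution is the centralization profile delta(t); per channel, the
#' (1-alpha)100th percentile of the distribution of max-over-time absolute
#' centered mixed averages gives the family-wise significance threshold G
#' for the whole window. No correction is applied across channels.
#'
#' @param trials_a,trials_b preprocessed trials: [eeg_session()] objects or
#'   trials x channels x samples arrays on a common time axis.
#' @param n_perm number of random re-partitions (default 1000).
#' @param alpha family-wise false-positive probability per channel over the
#'   analysis window. No default is assumed silently elsewhere: it is logged
#'   in every report.
#' @param seed integer seed; the null is fully reproducible from it.
#' @param window 1-based sample (column) indices of the analysis window; for
#'   an `eeg_session` input it defaults to the 250 ms post-stimulus window.
#' @param keep_ensemble keep the n_perm x channels x window mixed-average
#'   ensemble in the result (memory-heavy; diagnostics only).
#' @return object of class `perm_null`: `delta` (channels x window, volts),
#'   `G` (per-channel threshold, volts), `max_stats` (n_perm x channels),
#'   `n_perm`, `alpha`, `seed`, `window`, group sizes, optionally `mixed`.
#' @export
build_null <- function(trials_a, trials_b, n_perm = 1000, alpha = 0.05,
                       seed = 1L, window = NULL, keep_ensemble = FALSE) {
  A <- as_trial_array(trials_a)
  B <- as_trial_array(trials_b)
  if (!identical(dim(A)[-1], dim(B)[-1]))
    stop("trial sets differ in channels/samples: ",
         paste(dim(A)[-1], collapse = "x"), " vs ",
         paste(dim(B)[-1], collapse = "x"))
  if (is.null(window)) {
    if (!inherits(trials_a, "eeg_session"))
      stop("window must be given for array input")
    window <- post_window_idx(trials_a$onset_sample, dim(A)[3],
                              trials_a$sfreq_hz)
  }
  n_a <- dim(A)[1]; n_b <- dim(B)[1]
  if (n_a < 2L || n_b < 2L) stop("need at least 2 trials per group")
  if (n_perm < 100) warning("n_perm < 100: percentile threshold is unstable")
  n_ch <- dim(A)[2]
  n_s <- length(window)

  # pooled trials x (channel-major flattened window)
  pool <- rbind(matrix(A[, , window, drop = FALSE], nrow = n_a),
                matrix(B[, , window, drop = FALSE], nrow = n_b))
  n_pool <- n_a + n_b

  sel <- with_seed(seed, {
    S <- matrix(0, n_pool, n_perm)
    for (p in seq_len(n_perm)) S[sample.int(n_pool, n_a), p] <- 1
    S
  })
  mixed <- crossprod(sel, pool) / n_a            # n_perm x (n_ch * n_s)
  delta_flat <- colMeans(mixed)
  centered <- sweep(mixed, 2, delta_flat)

  # columns are channel-major within each sample block: col = ch + (s-1)*n_ch
  max_stats <- matrix(0, n_perm, n_ch)
  for (s in seq_len(n_s)) {
    blk <- abs(centered[, (s - 1L) * n_ch + seq_len(n_ch), drop = FALSE])
    max_stats <- pmax(max_stats, blk)
  }
  k <- as.integer(ceiling((1 - alpha) * n_perm))
  G <- apply(max_stats, 2, function(v) sort(v)[k])

  out <- structure(
    list(delta = matrix(delta_flat, n_ch, n_s),
         G = G, max_stats = max_stats,
         n_perm = as.integer(n_perm), alpha = alpha, seed = as.integer(seed),
         window = as.integer(window), n_a = n_a, n_b = n_b),
    class = "perm_null")
  if (keep_ensemble)
    out$mixed <- aperm(array(t(mixed), dim = c(n_ch, n_s, n_perm)), c(3, 1, 2))
  out
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("<perm_null> %d permutations, alpha = %g, %d channels x %d samples\n",
              x$n_perm, x$alpha, nrow(x$delta), ncol(x$delta)))
  cat(sprintf("  G range [%.3g, %.3g] V, groups %d + %d trials, seed %d\n",
              min(x$G), max(x$G), x$n_a, x$n_b, x$seed))
  invisible(x)
}

#' Significance mask of two evoked potentials against a permutation null
#'
#' A (channel, time) cell is significant when at least one of the two evoked
#' potentials lies strictly beyond the significance boundaries
#' `delta(t) - G` and `delta(t) + G` of that channel. Values exactly on a
#' boundary are not flagged.
#'
#' @param evoked_a,evoked_b `evoked_tep` objects or channels x samples
#'   matrices. Full-axis inputs are cut to the null's window; inputs already
#'   restricted to the window are used as is.
#' @param null a [build_null()] result.
#' @return logical channels x window-samples matrix.
#' @export
significance_mask <- function(evoked_a, evoked_b, null) {
  stopifnot(inherits(null, "perm_null"))
  cut <- function(e) {
    m <- if (inherits(e, "evoked_tep")) e$data else as.matrix(e)
    if (ncol(m) == ncol(null$delta)) m
    else if (ncol(m) >= max(null$window)) m[, null$window, drop = FALSE]
    else stop("evoked has ", ncol(m), " samples; null needs window up to ",
              max(null$window))
  }
  a <- cut(evoked_a)
  b <- cut(evoked_b)
  if (!identical(dim(a), dim(null$delta)) || !identical(dim(b), dim(null$delta)))
    stop("shape mismatch with null: evoked ", paste(dim(a), collapse = "x"),
         " vs null ", paste(dim(null$delta), collapse = "x"))
  lo <- null$delta - null$G
  hi <- null$delta + null$G
  (a < lo | a > hi) | (b < lo | b > hi)
}

#' Divergence Index of a significance mask
#'
#' The DI is the percentage of significantly different spatio-temporal
#' samples over all retained channels and the post-stimulus analysis window
#' (250 ms, 182 samples per channel at 725 Hz). Sub-window DIs are computed
#' over disjoint latency ranges (half-open in ms, last window closed) that
#' partition the total window, so the total DI is their cell-count-weighted
#' mean.
#'
#' @param mask logical channels x samples matrix; column k (1-based) is the
#'   post-stimulus sample at t = (k-1)/sfreq_hz.
#' @param sfreq_hz sampling rate of the mask's time axis.
#' @param windows_ms list of `c(lo, hi)` latency windows in ms.
#' @return object of class `divergence_result`: `di_total` (percent),
#'   `di_windows` (named percent vector), `n_flagged`, `n_channels`,
#'   `n_samples`, `mask`.
#' @export
divergence_index <- function(mask, sfreq_hz = 725,
                             windows_ms = list(c(0, 60), c(60, 120), c(120, 250))) {
  if (!is.matrix(mask) || !is.logical(mask)) stop("mask must be a logical matrix")
  if (length(mask) == 0L) stop("empty mask")
  n_ch <- nrow(mask); n_s <- ncol(mask)
  t_ms <- (seq_len(n_s) - 1L) / sfreq_hz * 1000
  di <- function(cols) {
    if (!length(cols)) return(NA_real_)
    100 * sum(mask[, cols, drop = FALSE]) / (n_ch * length(cols))
  }
  last <- length(windows_ms)
  dw <- vapply(seq_along(windows_ms), function(i) {
    w <- windows_ms[[i]]
    cols <- if (i == last) which(t_ms >= w[1] & t_ms <= w[2])
            else which(t_ms >= w[1] & t_ms < w[2])
    di(cols)
  }, numeric(1))
  names(dw) <- vapply(windows_ms, function(w) paste0(w[1], "-", w[2]), "")
  structure(list(di_total = di(seq_len(n_s)), di_windows = dw,
                 n_flagged = sum(mask), n_channels = n_ch, n_samples = n_s,
                 mask = mask),
            class = "divergence_result")
}

#' @export
print.divergence_result <- function(x, ...) {
  cat(sprintf("<divergence_result> DI = %.2f%% (%d of %d cells; %d channels x %d samples)\n",
              x$di_total, x$n_flagged, x$n_channels * x$n_samples,
              x$n_channels, x$n_samples))
  cat("  windows (ms):", paste(sprintf("%s: %.2f%%", names(x$di_windows),
                                       x$di_windows), collapse = ", "), "\n")
  invisible(x)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Full pairwise comparison of two TMS-EEG sessions
#'
#' Runs the complete chain on two epoched sessions: automatic trial
#' rejection, symmetric bad-channel exclusion, baseline equalization,
#' trial-level preprocessing (band-pass, downsample, common average
#' reference), trial-mixing permutation null, significance mask and
#' Divergence Index. All stage seeds derive from one master seed.
#'
#' @param a,b [eeg_session()] objects (raw, with EOG).
#' @param comparison_id identifier written into the report row.
#' @param alpha family-wise false-positive level per channel (logged).
#' @param n_perm permutations for the null (default 1000).
#' @param seed master seed.
#' @param parameter label of the changed parameter (`"site"`,
#'   `"intensity"`, `"angle"`, `"same-day"`, `"one-week"`); inferred from
#'   session metadata when `NULL`.
#' @param bad_channels labels excluded from both sessions.
#' @param eog_uv,beta_uv2_per_hz trial-rejection thresholds.
#' @param band_hz,target_sfreq_hz,min_trials preprocessing
#'   parameters (see [preprocess_evoked()]).
#' @param p_floor,max_removed_frac baseline-equalization parameters.
#' @param windows_ms DI latency windows (ms).
#' @param window_s post-stimulus analysis span, seconds.
#' @return object of class `comparison_result`: `record` (one-row
#'   data.frame in the report schema), `di` ([divergence_index()] result),
#'   `null` (without the mixed ensemble), `evoked_a`, `evoked_b`,
#'   `rejection` (per-session reports), `baseline` (removal summary).
#' @export
compare_sessions <- function(a, b, comparison_id = "cmp",
                             alpha = 0.05, n_perm = 1000, seed = 1L,
                             parameter = NULL, bad_channels = character(),
                             eog_uv = 70, beta_uv2_per_hz = 0.9,
                             band_hz = c(2, 80), target_sfreq_hz = 725,
                             min_trials = 150,
                             p_floor = 0.05, max_removed_frac = 0.05,
                             windows_ms = list(c(0, 60), c(60, 120), c(120, 250)),
                             window_s = 0.250) {
  stopifnot(inherits(a, "eeg_session"), inherits(b, "eeg_session"))
  ra <- stage("rejection", reject_trials_auto(a, eog_uv, beta_uv2_per_hz))
  rb <- stage("rejection", reject_trials_auto(b, eog_uv, beta_uv2_per_hz))
  dd <- stage("bad-channels", drop_bad_channels(ra$session, rb$session,
                                                bad_channels))
  eq <- stage("baseline-equalization",
              equalize_baselines(dd$a, dd$b, p_floor, max_removed_frac))
  for (s in list(eq$a, eq$b)) {
    n_tr <- dim(s$data)[1]
    if (n_tr < min_trials)
      stop("[trial-floor] only ", n_tr, " artifact-free trials; the evoked ",
           "average requires at least ", min_trials, call. = FALSE)
  }
  pa <- stage("preprocess", preprocess_trials(eq$a, band_hz, target_sfreq_hz))
  pb <- stage("preprocess", preprocess_trials(eq$b, band_hz, target_sfreq_hz))
  ev_a <- apply(pa$data, c(2, 3), mean)
  ev_b <- apply(pb$data, c(2, 3), mean)
  window <- post_window_idx(pa$onset_sample, dim(pa$data)[3],
                            target_sfreq_hz, window_s)
  null <- stage("permutation",
                build_null(pa$data, pb$data, n_perm = n_perm, alpha = alpha,
                           seed = derive_seed(seed, "perm"), window = window))
  mask <- stage("mask", significance_mask(ev_a[, window, drop = FALSE],
                                          ev_b[, window, drop = FALSE], null))
  di <- stage("divergence-index",
              divergence_index(mask, target_sfreq_hz, windows_ms))

  if (is.null(parameter)) parameter <- infer_parameter(a$meta, b$meta)
  label <- if (parameter %in% c("site", "intensity", "angle")) "C" else "NC"
  record <- data.frame(
    comparison_id = comparison_id, label = label, parameter_changed = parameter,
    DI_total = di$di_total, DI_0_60 = di$di_windows[[1]],
    DI_60_120 = di$di_windows[[2]], DI_120_250 = di$di_windows[[3]],
    alpha = alpha, n_permutations = as.integer(n_perm), seed = as.integer(seed),
    stringsAsFactors = FALSE)

  structure(list(record = record, di = di, null = null,
                 evoked_a = ev_a, evoked_b = ev_b, window = window,
                 sfreq_hz = target_sfreq_hz,
                 rejection = list(a = ra$report, b = rb$report),
                 baseline = eq[c("n_removed", "removed", "p_value")],
                 n_trials = c(a = dim(pa$data)[1], b = dim(pb$data)[1])),
            class = "comparison_result")
}

infer_parameter <- function(ma, mb) {
  get <- function(m, f) if (is.null(m[[f]])) NA else m[[f]]
  diffs <- c(
    site = !identical(get(ma, "site"), get(mb, "site")),
    intensity = !isTRUE(all.equal(get(ma, "intensity_pct"), get(mb, "intensity_pct"))),
    angle = !isTRUE(all.equal(get(ma, "angle_deg"), get(mb, "angle_deg"))))
  diffs[is.na(diffs)] <- FALSE
  changed <- names(diffs)[diffs]
  if (length(changed) > 1L)
    stop("sessions differ in more than one stimulation parameter: ",
         paste(changed, collapse = ", "))
  if (length(changed) == 1L) return(changed)
  da <- get(ma, "day"); db <- get(mb, "day")
  if (!is.na(da) && !is.na(db) && !identical(as.integer(da), as.integer(db)))
    "one-week" else "same-day"
}

#' @export
print.comparison_result <- function(x, ...) {
  r <- x$record
  cat(sprintf("<comparison_result> %s [%s/%s]: DI = %.2f%% (0-60: %.2f, 60-120: %.2f, 120-250: %.2f)\n",
              r$comparison_id, r$label, r$parameter_changed, r$DI_total,
              r$DI_0_60, r$DI_60_120, r$DI_120_250))
  cat(sprintf("  alpha %g, %d permutations, seed %d, %d + %d trials\n",
              r$alpha, r$n_permutations, r$seed, x$n_trials[1], x$n_trials[2]))
  invisible(x)
}
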