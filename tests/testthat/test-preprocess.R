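test_that("EOG rule rejects exactly the blink-contaminated trials", {
  s <- manual_session(n_trials = 20)
  eog <- s$eog_index + 1L
  bad <- c(3L, 7L, 15L)
  for (k in bad) s$data[k, eog, 40:70] <- 100 * 1e-6   # 100 uV blink
  out <- reject_trials_auto(s)
  expect_identical(out$report$rejected_eog, bad)
  expect_identical(out$report$n_rejected_eog, 3L)
  expect_identical(out$report$n_rejected_beta, 0L)
  expect_identical(dim(out$session$data)[1], 17L)
})

test_that("EOG threshold is strict: exactly 70 uV peak-to-peak is kept", {
  s <- manual_session(n_trials = 3)
  eog <- s$eog_index + 1L
  s$data[1, eog, 10] <- 70 * 1e-6     # p2p exactly at the threshold
  s$data[2, eog, 10] <- 70.5 * 1e-6   # just beyond
  out <- reject_trials_auto(s, eog_uv = 70)
  expect_identical(out$report$rejected_eog, 2L)
})

test_that("F8 fast-beta rule rejects muscle-contaminated trials, attributed after EOG", {
  s <- manual_session(n_trials = 10)
  f8 <- match("F8", s$channel_names)
  t <- seq_len(dim(s$data)[3]) / s$sfreq_hz
  for (k in c(2L, 9L)) s$data[k, f8, ] <- 50e-6 * sin(2 * pi * 40 * t)
  # trial 2 also gets a blink: first-failing rule (EOG) takes it
  s$data[2, s$eog_index + 1L, 30] <- 200e-6
  out <- reject_trials_auto(s)
  expect_identical(out$report$rejected_eog, 2L)
  expect_identical(out$report$rejected_beta, 9L)

  # all-zero session: nothing rejected
  z <- reject_trials_auto(manual_session(n_trials = 5))
  expect_identical(z$report$n_rejected_eog + z$report$n_rejected_beta, 0L)

  no_f8 <- manual_session(channels = c("F3", "Cz", "EOG"))
  expect_error(reject_trials_auto(no_f8), "F8")

  all_bad <- manual_session(n_trials = 3)
  all_bad$data[, all_bad$eog_index + 1L, 5] <- 300e-6
  expect_error(reject_trials_auto(all_bad), "all trials rejected")
})

test_that("band-pass attenuation at 100 Hz matches the filter-design oracle", {
  sf <- 1450
  n <- 726
  t <- (seq_len(n) - 1) / sf
  s <- manual_session(n_trials = 1, n_samples = n, sfreq = sf, onset = 363)
  x <- sin(2 * pi * 100 * t)
  s$data[1, 1, ] <- 1e-5 * x      # F3
  s$data[1, 2, ] <- -1e-5 * x     # F8: CAR mean stays ~0
  ev <- preprocess_evoked(s, min_trials = 1)
  mid <- 60:300                    # away from filter edge transients
  amp_out <- sqrt(2) * stats::sd(ev$data[1, mid])
  att_db <- -20 * log10(amp_out / 1e-5)

  # oracle: squared magnitude (forward-backward) of the high-pass/low-pass
  # Butterworth cascade the chain uses
  hp <- signal::butter(3, 2 / (sf / 2), type = "high")
  lp <- signal::butter(5, 80 / (sf / 2), type = "low")
  H1 <- function(b, f) {
    z <- exp(-1i * 2 * pi * f / sf)
    sum(b$b * z^(0:(length(b$b) - 1))) / sum(b$a * z^(0:(length(b$a) - 1)))
  }
  att_oracle <- -20 * log10(Mod(H1(hp, 100))^2 * Mod(H1(lp, 100))^2)
  expect_equal(att_db, att_oracle, tolerance = 0.05)
  expect_gte(att_db, 20)
})

test_that("common-average reference zeroes the channel mean and is idempotent", {
  s <- generate_session(quiet_config(n_trials = 6, seed = 2))
  ev <- preprocess_evoked(s, min_trials = 1)
  scale <- max(abs(ev$data))
  expect_lt(max(abs(colMeans(ev$data))), 1e-12 * scale)
  again <- sweep(ev$data, 2, colMeans(ev$data))
  expect_equal(again, ev$data, tolerance = 1e-14)
})

test_that("filtering and decimation commute with trial averaging", {
  s <- generate_session(quiet_config(n_trials = 6, seed = 3))
  ev_direct <- preprocess_evoked(s, min_trials = 1)
  tr <- preprocess_trials(s)
  ev_from_trials <- apply(tr$data, c(2, 3), mean)
  expect_equal(ev_from_trials, ev_direct$data, tolerance = 1e-10)
  expect_identical(tr$onset_sample, ev_direct$onset_sample)
  expect_identical(tr$sfreq_hz, 725)
})

test_that("evoked preprocessing enforces the trial floor and rate divisibility", {
  s <- generate_session(quiet_config(n_trials = 4, seed = 4))
  expect_error(preprocess_evoked(s, min_trials = 150), "at least 150")
  expect_error(preprocess_evoked(s, target_sfreq_hz = 700, min_trials = 1),
               "integer divisor")
  z <- manual_session(n_trials = 2, n_samples = 726, sfreq = 1450, onset = 363)
  ev <- preprocess_evoked(z, min_trials = 1)
  expect_true(all(ev$data == 0))
  # pulse sample survives decimation: time axis still crosses 0
  expect_identical(ev$onset_sample, 181L)
})

test_that("bad channels are removed symmetrically from both sessions", {
  a <- manual_session(n_trials = 2)
  b <- manual_session(n_trials = 3)
  same <- drop_bad_channels(a, b)
  expect_identical(same$a$channel_names, a$channel_names)

  out <- drop_bad_channels(a, b, bad = "F8")
  expect_identical(out$a$channel_names, c("F3", "Cz", "EOG"))
  expect_identical(out$a$channel_names, out$b$channel_names)
  expect_identical(out$a$eog_index, 2L)  # re-indexed after removal

  expect_error(drop_bad_channels(a, b, bad = "Pz"), "not present")
  expect_error(drop_bad_channels(a, b, bad = c("F3", "F8", "Cz")),
               "no EEG channel")
})

test_that("variance screening flags a grossly noisy channel as a candidate", {
  s <- generate_session(quiet_config(n_trials = 8, seed = 6))
  expect_identical(suggest_bad_channels(s), character(0))
  i <- match("C3", s$channel_names)
  s$data[, i, ] <- s$data[, i, ] * 40
  expect_identical(suggest_bad_channels(s), "C3")
})
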