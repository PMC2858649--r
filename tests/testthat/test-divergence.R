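# array-level session helper for statistics tests
stat_session <- function(nt, seed, shift = 0, sd_v = 5e-6, offs = NULL,
                         off_v = 40e-6) {
  set.seed(seed)
  a <- array(stats::rnorm(nt * 2 * 60, sd = sd_v), dim = c(nt, 2, 60)) + shift
  if (!is.null(offs)) for (k in offs) a[k, , 1:30] <- a[k, , 1:30] + off_v
  eeg_session(a, sfreq_hz = 120, onset_sample = 30,
              channel_names = c("F3", "Cz"), meta = list(),
              require_spans = FALSE)
}

test_that("matched baselines need no trial removal", {
  # identical trial sets: distributions equal by construction
  A <- stat_session(15, seed = 1)
  eq <- equalize_baselines(A, A)
  expect_identical(eq$n_removed, 0L)
  expect_gt(eq$p_value, 0.05)

  # same generator, independent draws: removal should be rare; the rank-sum
  # has size ~0.05, so zero removals in the vast majority of seeded runs
  zero <- vapply(1:50, function(s) {
    eq <- tryCatch(
      equalize_baselines(stat_session(18, seed = 100 + s),
                         stat_session(18, seed = 200 + s)),
      error = function(e) NULL)
    !is.null(eq) && eq$n_removed == 0L
  }, logical(1))
  expect_gte(sum(zero), 45)

  # a handful of grossly contaminated trials do not shift the rank-sum:
  # equalization leaves the sets alone (per-trial outliers are the
  # rejection stage's job, not the equalization loop's)
  B <- stat_session(20, seed = 3, offs = c(4, 11, 17))
  eq2 <- equalize_baselines(stat_session(20, seed = 2), B)
  expect_identical(eq2$n_removed, 0L)
})

test_that("a moderate global baseline shift engages removal and stays within the cap", {
  A <- stat_session(30, seed = 2)
  B <- stat_session(30, seed = 12, shift = 2e-6)
  # frozen fixture: the loop removes the most deviant trials and terminates
  eq <- equalize_baselines(A, B)
  expect_identical(eq$n_removed, 3L)
  expect_gt(eq$p_value, 0.05)
  expect_lte(eq$n_removed, floor(0.05 * 60))
  expect_identical(dim(eq$a$data)[1] + dim(eq$b$data)[1], 57L)

  # an unrepairable shift errors at the cap with an inspection hint
  B2 <- stat_session(30, seed = 11, shift = 2.5e-6)
  expect_error(equalize_baselines(A, B2), "inspect")
})

test_that("degenerate null of constant trials gives G = 0 and an empty mask", {
  A <- array(rep(3e-6, 3 * 1 * 10), dim = c(3, 1, 10))
  null <- suppressWarnings(
    build_null(A, A, n_perm = 200, alpha = 0.05, seed = 1, window = 1:10))
  expect_equal(max(abs(null$G)), 0)
  expect_equal(null$delta, matrix(3e-6, 1, 10))
  ev <- matrix(3e-6, 1, 10)
  expect_false(any(significance_mask(ev, ev, null)))
})

test_that("the family-wise threshold is monotone in alpha", {
  set.seed(4)
  A <- noise_trials(10, 3, 40)
  B <- noise_trials(10, 3, 40)
  g05 <- build_null(A, B, n_perm = 400, alpha = 0.05, seed = 9, window = 1:40)$G
  g01 <- build_null(A, B, n_perm = 400, alpha = 0.01, seed = 9, window = 1:40)$G
  expect_true(all(g01 >= g05))
})

test_that("permutation null converges to the exhaustive 20-partition oracle", {
  set.seed(7)
  A <- array(stats::rnorm(3 * 1 * 2), dim = c(3, 1, 2))
  B <- array(stats::rnorm(3 * 1 * 2, mean = 0.3), dim = c(3, 1, 2))
  ex <- exhaustive_null(A, B, alpha = 0.05)      # all C(6,3) = 20 partitions
  n_perm <- 20000
  null <- build_null(A, B, n_perm = n_perm, alpha = 0.05, seed = 5,
                     window = 1:2, keep_ensemble = TRUE)
  # delta is estimated from the sampled ensemble, so every statistic carries
  # O(sd / sqrt(n_perm)) centering noise; derive the tolerance from the
  # exhaustive ensemble itself
  pool <- rbind(matrix(A, 3), matrix(B, 3))
  mixed_ex <- t(apply(utils::combn(6, 3), 2,
                      function(ix) colMeans(pool[ix, , drop = FALSE])))
  tol <- 4 * max(apply(mixed_ex, 2, stats::sd)) / sqrt(n_perm)
  expect_equal(as.numeric(null$delta), ex$delta, tolerance = 10 * tol)
  # G lands within the percentile's sampling tolerance: between the order
  # statistics adjacent to the exact (1 - alpha) quantile of the 20 atoms
  k <- ceiling(0.95 * 20)
  expect_gte(null$G, ex$max_stats[k] - tol)
  expect_lte(null$G, ex$max_stats[20] + tol)
  # with the exact centering, the sampled max-stat distribution matches the
  # exhaustive one (pure multinomial sampling => small KS distance)
  stats_aligned <- apply(abs(sweep(null$mixed[, 1, ], 2, ex$delta)), 1, max)
  f_ex <- stats::ecdf(ex$max_stats)   # handles tied atoms correctly
  # evaluate just above each atom: summation order differs between the
  # sampled (crossprod) and enumerated (colMeans) averages by ~1e-16
  at <- ex$max_stats + 1e-9
  ks <- max(abs(stats::ecdf(stats_aligned)(at) - f_ex(at)))
  expect_lt(ks, 0.02)
})

test_that("significance mask flags exactly the cells pushed beyond the boundaries", {
  set.seed(11)
  A <- noise_trials(20, 4, 30)
  B <- noise_trials(20, 4, 30)
  null <- build_null(A, B, n_perm = 500, alpha = 0.05, seed = 2, window = 1:30)
  # evoked potentials at the center of the null: nothing flagged
  evA <- null$delta
  evB <- null$delta
  expect_false(any(significance_mask(evA, evB, null)))

  # push 5 known cells of B far beyond the boundary: exactly those flagged
  cells <- cbind(ch = c(1, 2, 3, 4, 2), t = c(3, 8, 15, 22, 29))
  evB2 <- evB
  evB2[cells] <- evB[cells] + 10 * null$G[cells[, "ch"]]
  m <- significance_mask(evA, evB2, null)
  expect_identical(sum(m), 5L)
  expect_true(all(m[cells]))

  # a value exactly on the boundary is not flagged (strict "beyond")
  evB3 <- evB
  evB3[2, 10] <- null$delta[2, 10] + null$G[2]
  expect_false(any(significance_mask(evA, evB3, null)))

  # label swap cannot change the mask (the rule is symmetric in A and B)
  expect_identical(significance_mask(evA, evB2, null),
                   significance_mask(evB2, evA, null))

  expect_error(significance_mask(evA[, 1:10], evB[, 1:10], null),
               "samples")
  expect_error(significance_mask(evA[1:2, ], evB[1:2, ], null), "mismatch")
})

test_that("the Divergence Index is the flagged-cell percentage, additive over windows", {
  m <- matrix(FALSE, 60, 182)
  expect_equal(divergence_index(m)$di_total, 0)
  expect_equal(divergence_index(!m)$di_total, 100)

  set.seed(3)
  m[sample.int(length(m), 546)] <- TRUE   # 546 / 10920 cells
  di <- divergence_index(m)
  expect_equal(di$di_total, 5.0)
  expect_identical(di$n_flagged, 546L)

  # total = cell-count-weighted mean of the window DIs; windows partition 182
  t_ms <- (0:181) / 725 * 1000
  n_w <- c(sum(t_ms < 60), sum(t_ms >= 60 & t_ms < 120),
           sum(t_ms >= 120 & t_ms <= 250))
  expect_identical(sum(n_w), 182L)
  expect_equal(sum(di$di_windows * n_w) / 182, di$di_total)
  expect_true(all(di$di_windows >= 0 & di$di_windows <= 100))

  expect_error(divergence_index(matrix(logical(0), 0, 0)), "empty")
})

test_that("comparing a session with itself yields a near-zero DI", {
  cfg <- quiet_config(n_trials = 24, seed = 21)
  s <- generate_session(cfg)
  res <- compare_sessions(s, s, "self", n_perm = 200, min_trials = 10, seed = 5)
  expect_lt(res$record$DI_total, 1)
  expect_identical(res$record$label, "NC")
  expect_identical(res$record$parameter_changed, "same-day")
})

test_that("the changed parameter is inferred from session metadata", {
  cfg <- quiet_config(n_trials = 24, seed = 31)
  p <- make_comparison_pair(cfg, "intensity", 10, seeds = c(31, 32))
  res <- compare_sessions(p$a, p$b, "int", n_perm = 150, min_trials = 10,
                          seed = 6)
  expect_identical(res$record$label, "C")
  expect_identical(res$record$parameter_changed, "intensity")
  expect_identical(res$record$alpha, 0.05)
  expect_identical(res$record$n_permutations, 150L)

  pw <- make_comparison_pair(cfg, "none", seeds = c(33, 34), day_b = 8)
  resw <- compare_sessions(pw$a, pw$b, "wk", n_perm = 150, min_trials = 10,
                           seed = 7)
  expect_identical(resw$record$parameter_changed, "one-week")

  # two parameters changed at once is a design error
  bad_b <- pw$b
  bad_b$meta$site <- "BA6"
  bad_b$meta$intensity_pct <- 60
  expect_error(compare_sessions(pw$a, bad_b, n_perm = 150, min_trials = 10),
               "more than one")
})
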