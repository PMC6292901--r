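test_that("steps rebinning yields equal-count levels with stable ties", {
  tab <- data.frame(steps = c(0, 0, 1, 1, 2, 2, 3, 3))
  expect_equal(rebin_steps(tab), c(1, 1, 2, 2, 3, 3, 4, 4))
  set.seed(41)
  sp <- subject_spec(1, 4)
  tab <- generate_trial_table(sp)
  lv <- rebin_steps(tab)
  expect_equal(as.integer(table(lv)), rep(30L, 4))
  # increasing in steps: every trial in a higher bin has steps >= any lower bin
  expect_true(max(tab$steps[lv == 1]) <= min(tab$steps[lv == 3]))
  # ties split deterministically by trial order
  tab2 <- data.frame(steps = c(2, 2, 2, 2, 2, 5, 5, 5))
  b <- rebin_steps(tab2)
  expect_equal(b, c(1, 1, 2, 2, 3, 3, 4, 4))
  expect_identical(rebin_steps(tab2), b)
  expect_error(rebin_steps(data.frame(steps = rep(3, 8))), "degenerate")
  expect_error(rebin_steps(data.frame(steps = 1:3)), "4 trials")
})

test_that("condition regressors cover the level's delay events only", {
  set.seed(42)
  sp <- subject_spec(1, 4)
  tab <- generate_trial_table(sp)
  hrf <- hrf_model()
  x <- build_condition_regressor(tab, "set_size", 2, hrf, run = 1)
  expect_length(x, 254L)
  expect_lt(abs(mean(x)), 1e-12)
  # a level with no trials in the run errors
  tab_empty <- tab
  tab_empty$level[tab_empty$run == 1 & tab_empty$level == 3] <- 2L
  expect_error(build_condition_regressor(tab_empty, "set_size", 3, hrf, run = 1),
               "no trials")
  # single-level table: regressor equals the demeaned unmodulated delay
  tab1 <- tab[tab$run == 1, ]
  tab1$level <- 1L
  x1 <- build_condition_regressor(tab1, "set_size", 1, hrf, run = 1)
  delay <- wmnet:::.convolve_events(tab1$onset_delay, rep(5, nrow(tab1)),
                                    rep(1, nrow(tab1)), hrf, 254, 2)
  expect_equal(x1, delay - mean(delay), tolerance = 1e-12)
})

test_that("cPPI equals the naive joint-residualization oracle", {
  set.seed(43)
  for (rep in 1:5) {
    n_vol <- 20; n_node <- 3
    ts <- matrix(rnorm(n_vol * n_node), n_vol, n_node)
    psych <- rnorm(n_vol)
    nuis <- matrix(rnorm(n_vol * 2), n_vol, 2)
    fast <- wmnet:::.cppi_run(ts, psych, nuis)
    slow <- naive_cppi(ts, psych, nuis)
    expect_equal(fast[upper.tri(fast)], slow[upper.tri(slow)],
                 tolerance = 1e-10)
  }
})

test_that("cPPI matrices are symmetric, bounded, and run-order invariant", {
  set.seed(44)
  sp <- subject_spec(1, 4)
  tab <- simulate_behavior(generate_trial_table(sp), behavior_params(), sp)
  b <- simulate_timeseries(tab, ground_truth(n_rois = 50), sp)
  psych <- lapply(1:4, function(r) {
    build_condition_regressor(tab, "set_size", 1, hrf_model(), run = r)
  })
  m <- cppi_matrix(b, 1:20, psych)
  expect_true(isSymmetric(unname(m), tol = 1e-12))
  off <- m[upper.tri(m)]
  expect_true(all(is.finite(off)))
  expect_true(all(off >= -1 & off <= 1))
  # permuting run order leaves the Fisher-z average unchanged
  b2 <- b
  ord <- c(3, 1, 4, 2)
  b2$signal <- b$signal[ord]
  b2$confounds <- b$confounds[ord]
  m2 <- cppi_matrix(b2, 1:20, psych[ord])
  expect_equal(m, m2, tolerance = 1e-12)
})

test_that("cPPI separates task-locked coupling from independent noise", {
  set.seed(45)
  hrf <- hrf_model()
  n_vol <- 254
  onsets <- seq(10, 480, by = 16)
  shape <- wmnet:::.convolve_events(onsets, rep(5, length(onsets)),
                                    rep(1, length(onsets)), hrf, n_vol, 2)
  psych <- shape - mean(shape)
  pos <- neg <- 0
  null_r <- c()
  for (rep in 1:20) {
    # per-event shared gain: two nodes co-fluctuate only during task events
    shared <- sapply(seq_along(onsets), function(i) {
      wmnet:::.convolve_events(onsets[i], 5, 1, hrf, n_vol, 2)
    }) %*% rnorm(length(onsets), 0, 1.2)
    ts <- cbind(shared + rnorm(n_vol, 0, 0.6),
                shared + rnorm(n_vol, 0, 0.6),
                rnorm(n_vol))   # third node: independent noise
    nuis <- matrix(rnorm(n_vol * 2, 0, 0.1), n_vol, 2)
    m <- wmnet:::.cppi_run(ts, psych, nuis)
    if (m[1, 2] > 0) pos <- pos + 1 else neg <- neg + 1
    null_r <- c(null_r, m[1, 3], m[2, 3])
  }
  expect_gte(pos, 18)                 # task-locked covariance survives
  # independent node: signed entries average out near zero across seeds,
  # and single-run estimates stay within sampling noise of zero
  expect_lt(abs(mean(null_r)), 0.05)
  expect_lt(mean(abs(null_r)), 0.08)
})

test_that("condition tensors contain all 8 level matrices", {
  set.seed(46)
  sp <- subject_spec(2, 3)
  tab <- simulate_behavior(generate_trial_table(sp), behavior_params(), sp)
  b <- simulate_timeseries(tab, ground_truth(n_rois = 50), sp)
  ct <- condition_tensor(b, 1:46, tab)
  expect_named(ct$matrices,
               c(paste0("set_size_", 1:4), paste0("steps_", 1:4)))
  expect_true(all(vapply(ct$matrices, function(m) all(dim(m) == 46L),
                         logical(1))))
  expect_equal(unname(ct$trial_counts), rep(30L, 8))
})
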