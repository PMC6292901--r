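test_that("trial tables satisfy the task design invariants", {
  set.seed(21)
  sp <- subject_spec(1, 4)
  tab <- generate_trial_table(sp)
  expect_equal(nrow(tab), 120L)
  expect_equal(as.integer(table(tab$level)), rep(30L, 4))
  expect_equal(as.integer(table(tab$run)), rep(30L, 4))
  pr <- table(tab$probe_type)
  expect_equal(pr[["valid"]], 48L)
  expect_equal(pr[["invalid"]], 48L)
  expect_equal(pr[["new"]], 24L)
  expect_equal(tab$set_size, sp$starting_set_size + tab$level - 1L)
  for (r in 1:4) {
    tt <- tab[tab$run == r, ]
    expect_true(all(diff(tt$onset_array) > 0))
    expect_true(max(tt$onset_probe) + 4 <= 254 * 2)
    expect_true(all(tt$iti[-30] >= 2 - 1e-9 & tt$iti[-30] <= 10 + 1e-9))
  }
  # letters consistent with recorded steps
  idx <- sample(nrow(tab), 10)
  expect_equal(tab$steps[idx],
               vapply(tab$letters[idx], min_sorting_steps, integer(1),
                      USE.NAMES = FALSE))
  # same seed reproduces the identical table
  set.seed(21)
  sp2 <- subject_spec(1, 4)
  expect_identical(generate_trial_table(sp2), tab)
})

test_that("behavior simulation reproduces the coefficient arithmetic", {
  set.seed(22)
  sp <- subject_spec(1, 4)
  sp$re_logit <- c(0, 0, 0)
  sp$re_rt <- c(0, 0, 0)
  params <- behavior_params(nonresponse_rate = 0, rt_sd = 350)
  n <- 6000
  tab <- data.frame(level = 1, steps = 0)[rep(1, n), ]
  out <- simulate_behavior(tab, params, sp)
  # inverse-logit(4.10 - 0.94) = 0.9595
  expect_lt(abs(mean(out$correct) - 0.9595), 0.01)
  # mean RT 1129.17 + 284.36 = 1413.5 ms before truncation
  expect_lt(abs(mean(out$rt) - 1413.5), 20)
  tab4 <- data.frame(level = 4, steps = 7)[rep(1, n), ]
  out4 <- simulate_behavior(tab4, params, sp)
  # inverse-logit(4.10 - 3.76 - 3.43 + 3.08) = 0.498
  expect_lt(abs(mean(out4$correct) - 0.498), 0.015)
  expect_true(all(out$rt <= 4000))
})

test_that("default cohort matches the study dimensions", {
  ch <- default_cohort()
  expect_equal(nrow(ch$trials), 4920L)
  expect_equal(length(ch$subjects), 41L)
  starts <- vapply(ch$subjects, `[[`, integer(1), "starting_set_size")
  expect_equal(as.integer(table(factor(starts, levels = 3:6))),
               c(12L, 19L, 9L, 1L))
  nr <- mean(!ch$trials$responded)
  expect_gt(nr, 0.008)
  expect_lt(nr, 0.026)
  expect_true(all(is.na(ch$trials$rt[!ch$trials$responded])))
  # per-subject criteria lie between the Easy and Medium sizes
  crit <- vapply(ch$subjects, `[[`, numeric(1), "criterion_set_size")
  expect_true(all(crit > starts + 1 & crit < starts + 2))
  # reproducibility under the master seed
  ch2 <- generate_cohort(seed = ch$seed)
  expect_identical(ch2$trials, ch$trials)
})

test_that("timeseries generator conserves configured noise SD", {
  set.seed(23)
  sp <- subject_spec(1, 4)
  tab <- simulate_behavior(generate_trial_table(sp), behavior_params(), sp)
  truth <- ground_truth(n_rois = 50, amp_delay = 0, amp_set = 0,
                        amp_steps = 0, w_maint = 0, w_manip = 0,
                        cross_jitter = 0, stable_sd = 0, confound_mix = 0,
                        noise_sd = 1.3)
  b <- simulate_timeseries(tab, truth, sp)
  expect_equal(length(b$signal), 4L)
  expect_equal(dim(b$signal[[1]]), c(254L, 50L))
  emp_sd <- mean(vapply(b$signal, function(Y) mean(apply(Y, 2, sd)),
                        numeric(1)))
  expect_lt(abs(emp_sd - 1.3) / 1.3, 0.05)
  expect_true(all(vapply(b$confounds, ncol, integer(1)) == 8L))
})

test_that("structural matrices separate within from between blocks", {
  truth <- ground_truth()
  set.seed(24)
  fa_list <- replicate(29, generate_structural_matrix(truth), simplify = FALSE)
  expect_true(all(vapply(fa_list, function(m) {
    v <- m[upper.tri(m)]
    all(v >= 0 & v <= 1)
  }, logical(1))))
  expect_true(isSymmetric(unname(fa_list[[1]]), tol = 1e-12))
  res <- validate_structure(fa_list, truth_partition())
  expect_true(res$t_maint > 0 && res$p_maint < 0.001)
  expect_true(res$t_manip > 0 && res$p_manip < 0.001)
  # zero margin: paired differences centered near zero
  truth0 <- ground_truth(fa_within = 0.4, fa_between = 0.4)
  set.seed(25)
  fa0 <- replicate(29, generate_structural_matrix(truth0), simplify = FALSE)
  r0 <- validate_structure(fa0, truth_partition())
  expect_lt(abs(mean(r0$within_maint - r0$between)), 0.005)
})

test_that("cohort writer produces self-describing plain-text outputs", {
  dir <- tempfile("cohort")
  ch <- generate_cohort(n_subjects = 2, seed = 5)
  write_cohort(ch, dir)
  expect_true(file.exists(file.path(dir, "trials.tsv")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$n_subjects, 2L)
  expect_equal(man$n_trials, 240L)
  expect_equal(man$seed, 5L)
  tt <- read.delim(file.path(dir, "trials.tsv"))
  expect_equal(nrow(tt), 240L)
  ev <- events_table(ch$trials[ch$trials$subject == 1, ], run = 1)
  expect_equal(nrow(ev), 90L)  # 30 trials x 3 events
  expect_true(all(diff(ev$onset[ev$trial_type == "array"]) > 0))
  unlink(dir, recursive = TRUE)
})
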