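make_block_matrix <- function(k, within_m, within_p, between, noise = 0,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * k
  m <- matrix(between, n, n)
  m[1:k, 1:k] <- within_m
  m[(k + 1):n, (k + 1):n] <- within_p
  if (noise > 0) {
    e <- matrix(rnorm(n * n, 0, noise), n, n)
    e[lower.tri(e)] <- t(e)[lower.tri(e)]
    m <- m + e
  }
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- NA
  m
}

test_that("within/between means match block construction and a brute oracle", {
  part <- truth_partition(5)
  m <- make_block_matrix(5, 0.3, 0.3, -0.1)
  wb <- within_between_means(m, part)
  expect_equal(wb$z_within_maint, 0.3)
  expect_equal(wb$z_within_manip, 0.3)
  expect_equal(wb$z_between, -0.1)
  # random symmetric matrix: equals explicit pair enumeration
  m <- make_block_matrix(5, 0, 0, 0, noise = 0.5, seed = 61)
  wb <- within_between_means(m, part)
  w_pairs <- b_pairs <- c()
  for (i in 1:9) for (j in (i + 1):10) {
    v <- m[i, j]
    if ((i <= 5) == (j <= 5)) w_pairs <- c(w_pairs, v) else b_pairs <- c(b_pairs, v)
  }
  expect_equal(wb$z_between, mean(b_pairs), tolerance = 1e-12)
  expect_equal((wb$z_within_maint + wb$z_within_manip) / 2,
               mean(w_pairs), tolerance = 1e-12)
  expect_error(within_between_means(make_block_matrix(1, 0, 0, 0),
                                    truth_partition(1)), "within")
})

test_that("segregation identities hold exactly", {
  expect_equal(segregation(0.2, 0.2), 0)
  expect_equal(segregation(0.2, 0.0), 1)
  expect_equal(segregation(0.25, -0.05), 1.2)
  expect_warning(s <- segregation(0, 0.1), "undefined")
  expect_true(is.na(s))
  # node-level variant agrees on homogeneous blocks
  part <- truth_partition(5)
  m <- make_block_matrix(5, 0.3, 0.2, -0.1)
  ns <- node_segregation(m, part)
  expect_equal(ns$maint, (0.3 - (-0.1)) / 0.3, tolerance = 1e-12)
  expect_equal(ns$manip, (0.2 - (-0.1)) / 0.2, tolerance = 1e-12)
})

test_that("reconfiguration matches its defining identities", {
  part <- truth_partition(6)
  m <- make_block_matrix(6, 0, 0, 0, noise = 0.3, seed = 62)
  states <- list(m, m, m, m)
  for (sub in c("between", "within_maintenance", "within_manipulation")) {
    expect_equal(reconfiguration(states, part, sub)$value, 0, tolerance = 1e-12)
  }
  # two states: value = 1 - mean offdiagonal spearman (oracle check)
  m2 <- make_block_matrix(6, 0, 0, 0, noise = 0.3, seed = 63)
  rec <- reconfiguration(list(m, m2), part, "between")
  v1 <- as.numeric(m[1:6, 7:12]); v2 <- as.numeric(m2[1:6, 7:12])
  expect_equal(rec$value, 1 - cor(v1, v2, method = "spearman"),
               tolerance = 1e-12)
  expect_error(reconfiguration(list(m), part), "2 states")
  # monotone transform invariance (rank correlation property)
  states2 <- list(m, m2, make_block_matrix(6, 0, 0, 0, noise = 0.3, seed = 64),
                  make_block_matrix(6, 0, 0, 0, noise = 0.3, seed = 65))
  r1 <- reconfiguration(states2, part, "between")$value
  r2 <- reconfiguration(lapply(states2, function(x) exp(3 * x)),
                        part, "between")$value
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("independent random states reconfigure to about 1", {
  part <- truth_partition(15)
  set.seed(66)
  vals <- replicate(20, {
    states <- lapply(1:4, function(i) make_block_matrix(15, 0, 0, 0, noise = 1))
    reconfiguration(states, part, "between")$value
  })
  expect_lt(abs(mean(vals) - 1), 0.05)
})

test_that("behavior correlation and its comparison behave canonically", {
  set.seed(67)
  x <- rnorm(20)
  bc <- behavior_correlation(x, x)
  expect_equal(bc$r, 1)
  expect_error(behavior_correlation(rep(1, 10), rnorm(10)), "variance")
  expect_error(behavior_correlation(rnorm(3), rnorm(3)), "4 subjects")
  # Fisher comparison of a correlation with itself is zero
  y <- rnorm(20)
  bc2 <- behavior_correlation(x, y, x2 = x)
  expect_equal(bc2$z_diff, 0, tolerance = 1e-12)
  expect_equal(bc2$p_diff, 1, tolerance = 1e-12)
  # null calibration: |r| exceeds the alpha = .05 cutoff about 5% of the time
  set.seed(68)
  n <- 41
  crit_r <- 0.308
  hits <- mean(replicate(1000, abs(cor(rnorm(n), rnorm(n))) > crit_r))
  expect_gt(hits, 0.03)
  expect_lt(hits, 0.08)
})

test_that("difficulty trend detects linear effects and stays flat on nulls", {
  # constant metric per subject -> no level effect
  df <- data.frame(subject = rep(1:10, each = 4), level = rep(1:4, 10),
                   metric = rep(rnorm(10), each = 4))
  tr <- difficulty_trend(df)
  expect_equal(tr$chisq, 0, tolerance = 1e-6)
  # metric = level + noise -> strong positive trend
  set.seed(69)
  df2 <- df
  df2$metric <- df2$level + rnorm(40, 0, 0.5) + rep(rnorm(10), each = 4)
  tr2 <- difficulty_trend(df2)
  expect_true(tr2$converged)
  expect_gt(tr2$slope, 0)
  expect_lt(tr2$p, 0.001)
  # null calibration of the LRT
  set.seed(70)
  ps <- replicate(60, {
    dfn <- data.frame(subject = rep(1:8, each = 4), level = rep(1:4, 8),
                      metric = rnorm(32) + rep(rnorm(8), each = 4))
    difficulty_trend(dfn)$p
  })
  expect_gt(mean(ps < 0.05), 0.0)
  expect_lt(mean(ps < 0.05), 0.15)
})
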