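test_that("letter array validation enforces the stimulus constraints", {
  expect_equal(as_letter_array("CAB"), c("C", "A", "B"))
  expect_error(as_letter_array("CA"), "length")
  expect_error(as_letter_array("BCDFGHJKLM"), "length")
  expect_error(as_letter_array("CAA"), "duplicate")
  expect_error(as_letter_array("CAE", consonants_only = TRUE), "consonants")
  expect_equal(as_letter_array("CAE"), c("C", "A", "E"))
  expect_error(count_steps("CAB", "bogosort"), "arg")
})

test_that("step counts match the worked examples and counting rules", {
  expect_equal(count_steps("BCD", "selection"), 0L)
  expect_equal(count_steps("CAB", "selection"), 2L)
  expect_equal(count_steps("CAB", "insertion"), 2L)
  expect_equal(count_steps("BACD", "selection"), 1L)
  expect_equal(min_sorting_steps("BCD"), 0L)
  expect_equal(min_sorting_steps("DCB"), 1L)
  expect_equal(min_sorting_steps("CAB"), 2L)
  for (alg in c("insertion", "selection", "merge_insertion", "merge_selection")) {
    expect_equal(count_steps("CAB", alg), 2L)
  }
})

test_that("closed-form oracles match their examples and BFS for n <= 5", {
  expect_equal(oracle_min_steps("BCD", "transposition"), 0L)
  expect_equal(oracle_min_steps("CAB", "transposition"), 2L)
  expect_equal(oracle_min_steps("CAB", "remove_reinsert"), 1L)
  set.seed(42)
  for (n in 3:5) {
    bfs_t <- bfs_distances(n, transposition_neighbors)
    bfs_r <- bfs_distances(n, remove_reinsert_neighbors)
    for (p in perms_of(n)) {
      arr <- letters_for_perm(p)
      k <- paste(p, collapse = "")
      expect_identical(oracle_min_steps(arr, "transposition"), bfs_t[[k]])
      expect_identical(oracle_min_steps(arr, "remove_reinsert"), bfs_r[[k]])
    }
  }
})

test_that("selection equals the transposition oracle exhaustively for n <= 6", {
  set.seed(43)
  for (n in 3:6) {
    for (p in perms_of(n)) {
      arr <- letters_for_perm(p)
      expect_identical(count_steps(arr, "selection"),
                       oracle_min_steps(arr, "transposition"))
    }
  }
})

test_that("exhaustive invariants hold for all permutations of n <= 6", {
  set.seed(44)
  algs <- c("insertion", "selection", "merge_insertion", "merge_selection")
  for (n in c(3L, 5L, 6L)) {
    for (p in perms_of(n)) {
      arr <- letters_for_perm(p)
      counts <- vapply(algs, function(a) count_steps(arr, a), integer(1))
      ms <- min_sorting_steps(arr)
      expect_identical(ms, min(counts))
      expect_true(ms >= 0L && ms <= n - 1L)
      sorted <- identical(arr, sort(arr))
      expect_identical(all(counts == 0L), sorted)
      expect_identical(ms == 0L, sorted)
      expect_true(counts["insertion"] <= n - 1L)
      expect_true(counts["selection"] <= n - 1L)
      # fused fast path agrees with the public counting rules
      expect_identical(wmnet:::.min_steps_perm(rank(match(arr, LETTERS))), ms)
    }
  }
})

test_that("monotone relabeling of letters leaves all counts unchanged", {
  set.seed(45)
  algs <- c("insertion", "selection", "merge_insertion", "merge_selection")
  for (i in 1:25) {
    n <- sample(3:8, 1)
    idx <- sort(sample(seq_len(20), n))  # room to shift up by one consonant
    arr1 <- wmnet:::CONSONANTS[idx][sample.int(n)]
    arr2 <- wmnet:::CONSONANTS[idx + 1L][rank(match(arr1, wmnet:::CONSONANTS))]
    for (a in algs) expect_identical(count_steps(arr1, a), count_steps(arr2, a))
    expect_identical(min_sorting_steps(arr1), min_sorting_steps(arr2))
  }
})

test_that("array generation is seeded, stratified, and in range", {
  set.seed(7); a1 <- generate_array(3)
  set.seed(7); a2 <- generate_array(3)
  expect_identical(a1, a2)
  expect_error(generate_array(2), "size")
  expect_error(generate_array(10), "size")
  a9 <- generate_array(9)
  expect_length(unique(a9), 9L)
  expect_true(all(a9 %in% wmnet:::CONSONANTS))

  set.seed(8); s1 <- generate_stimulus_set(c(3, 5), 4)
  set.seed(8); s2 <- generate_stimulus_set(c(3, 5), 4)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 8L)
  expect_equal(sum(s1$set_size == 3), 4L)
})

test_that("min-steps distribution has an interior mode and widens with size", {
  set.seed(9)
  s5 <- replicate(4000, wmnet:::.min_steps_perm(sample.int(5)))
  tab <- tabulate(s5 + 1L, nbins = 5)
  mode_at <- which.max(tab)
  expect_true(mode_at > 1 && mode_at < 5)  # interior mode for n = 5
  s3 <- replicate(2000, wmnet:::.min_steps_perm(sample.int(3)))
  s8 <- replicate(2000, wmnet:::.min_steps_perm(sample.int(8)))
  expect_true(sd(s8) > sd(s3))
})
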