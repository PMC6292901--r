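# The 21 uppercase consonants; vowels are excluded from stimuli so that
# letter arrays cannot be chunked into pronounceable units.
CONSONANTS <- setdiff(LETTERS, c("A", "E", "I", "O", "U"))

SORT_ALGORITHMS <- c("insertion", "selection", "merge_insertion", "merge_selection")

#' Validate a letter array
#'
#' A letter array is a vector of 3--9 distinct uppercase letters. Accepts
#' either a character vector of single letters or a single string such as
#' \code{"CAB"}. Step counting is defined on any distinct letters; the
#' stimulus generators additionally restrict themselves to consonants
#' (vowels are excluded from generated stimuli to prevent chunking), which
#' \code{consonants_only = TRUE} enforces.
#'
#' @param letters character vector of single letters, or one string.
#' @param consonants_only reject vowels (the stimulus constraint).
#' @return The array as a character vector of single letters (invisibly
#'   validated).
#' @export
as_letter_array <- function(letters, consonants_only = FALSE) {
  if (length(letters) == 1L && nchar(letters[1L]) > 1L) {
    letters <- strsplit(letters, "")[[1L]]
  }
  letters <- toupper(as.character(letters))
  n <- length(letters)
  if (n < 3L || n > 9L) {
    stop("letter array length must be in [3, 9], got ", n, call. = FALSE)
  }
  if (anyDuplicated(letters)) {
    stop("letter array must not contain duplicate letters", call. = FALSE)
  }
  pool <- if (consonants_only) CONSONANTS else LETTERS
  if (any(!letters %in% pool)) {
    bad <- setdiff(letters, pool)
    stop("letter array must contain only ",
         if (consonants_only) "consonants" else "uppercase letters",
         "; offending: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  letters
}

# Sorting permutation: p[i] = alphabetical rank of the letter at position i.
# The array is alphabetized iff p is the identity.
.sort_perm <- function(letters) rank(match(letters, LETTERS))

# number of cycles of a permutation
.n_cycles <- function(p) {
  n <- length(p)
  seen <- logical(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!seen[i]) {
      k <- k + 1L
      j <- i
      while (!seen[j]) {
        seen[j] <- TRUE
        j <- p[j]
      }
    }
  }
  k
}

# length of the longest increasing subsequence (n <= 9, quadratic DP is fine)
.lis_length <- function(p) {
  n <- length(p)
  best <- rep(1L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (p[j] < p[i] && best[j] + 1L > best[i]) best[i] <- best[j] + 1L
    }
  }
  max(best)
}

# insertion count on a rank vector: one step per element that is not a
# left-to-right running maximum (such elements must be extracted and
# reinserted into the sorted prefix; running maxima are already in place).
.steps_insertion <- function(p) {
  runmax <- cummax(p)
  sum(p != runmax)
}

# selection count: one step per executed swap; equals n - #cycles.
.steps_selection <- function(p) {
  length(p) - .n_cycles(p)
}

# merge combine cost: merging the two sorted halves costs one step for each
# element taken from the second half while the first half is non-empty.
# Inputs must already be sorted ascending.
.merge_cost <- function(a, b) {
  i <- 1L
  cost <- 0L
  for (x in b) {
    while (i <= length(a) && a[i] < x) i <- i + 1L
    if (i <= length(a)) cost <- cost + 1L
  }
  cost
}

# merge variants: split at ceiling(n/2), count steps inside each half with
# the base rule applied to the half's relative order, then add the combine
# cost of merging the two sorted halves.
.steps_merge <- function(p, base) {
  n <- length(p)
  h <- ceiling(n / 2)
  left <- p[seq_len(h)]
  right <- p[(h + 1L):n]
  base(rank(left)) + base(rank(right)) +
    .merge_cost(sort(left), sort(right))
}

#' Count sorting steps under one algorithm
#'
#' Counts the number of reordering steps needed to alphabetize a letter
#' array under one of four counting rules: \code{insertion} (one step per
#' element that must be extracted and reinserted into the growing sorted
#' prefix), \code{selection} (one step per executed swap placing the
#' alphabetically earliest remaining letter; equal to n minus the number of
#' permutation cycles), and \code{merge_insertion} / \code{merge_selection}
#' (split at the midpoint, apply the base rule within each half, plus one
#' step per element of the second half merged in while the first half is
#' non-empty).
#'
#' @param letters a letter array (string or character vector), see
#'   [as_letter_array()].
#' @param algorithm one of \code{"insertion"}, \code{"selection"},
#'   \code{"merge_insertion"}, \code{"merge_selection"}.
#' @return integer step count; 0 iff the array is already alphabetized.
#' @examples
#' count_steps("CAB", "selection")   # 2
#' count_steps("BCD", "insertion")   # 0
#' @export
count_steps <- function(letters, algorithm) {
  letters <- as_letter_array(letters)
  algorithm <- match.arg(algorithm, SORT_ALGORITHMS)
  p <- .sort_perm(letters)
  switch(algorithm,
    insertion = .steps_insertion(p),
    selection = .steps_selection(p),
    merge_insertion = .steps_merge(p, .steps_insertion),
    merge_selection = .steps_merge(p, .steps_selection)
  )
}

#' Minimum sorting steps over the four algorithms
#'
#' The manipulation-demand measure of a trial: the minimum number of
#' reordering steps to alphabetize the array, taken over insertion,
#' selection, merge-insertion and merge-selection counting rules (the most
#' efficient strategy is assumed).
#'
#' @inheritParams count_steps
#' @return integer; 0 iff the array is already alphabetized.
#' @export
min_sorting_steps <- function(letters) {
  letters <- as_letter_array(letters)
  p <- .sort_perm(letters)
  min(.steps_insertion(p),
      .steps_selection(p),
      .steps_merge(p, .steps_insertion),
      .steps_merge(p, .steps_selection))
}

#' Closed-form oracles for minimum reordering distance
#'
#' Independent verification oracles. Under the \code{transposition}
#' primitive (swap any two letters) the minimum number of moves to sort a
#' permutation is n minus its number of cycles. Under \code{remove_reinsert}
#' (remove one letter and reinsert it anywhere) it is n minus the length of
#' the longest increasing subsequence.
#'
#' @inheritParams count_steps
#' @param primitive \code{"transposition"} or \code{"remove_reinsert"}.
#' @return integer minimal move count.
#' @export
oracle_min_steps <- function(letters, primitive = c("transposition", "remove_reinsert")) {
  letters <- as_letter_array(letters)
  primitive <- match.arg(primitive)
  p <- .sort_perm(letters)
  n <- length(p)
  switch(primitive,
    transposition = n - .n_cycles(p),
    remove_reinsert = n - .lis_length(p)
  )
}

# fast internal path: minimum steps of a rank permutation, no validation.
# Fused implementation of the four counting rules (hot loop of the
# stimulus generator); equivalence with count_steps is asserted in tests.
.min_steps_perm <- function(p) {
  n <- length(p)
  ins <- sum(p != cummax(p))
  seen <- logical(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!seen[i]) {
      k <- k + 1L
      j <- i
      while (!seen[j]) {
        seen[j] <- TRUE
        j <- p[j]
      }
    }
  }
  sel <- n - k
  best <- if (ins < sel) ins else sel
  h <- (n + 1L) %/% 2L
  left <- p[seq_len(h)]
  right <- p[(h + 1L):n]
  # relative ranks without rank()'s tie handling; reuse the orderings
  ol <- order(left); orr <- order(right)
  rl <- integer(h); rl[ol] <- seq_len(h)
  rr <- integer(n - h); rr[orr] <- seq_len(n - h)
  ins_l <- sum(rl != cummax(rl)); ins_r <- sum(rr != cummax(rr))
  cyc <- function(q) {
    m <- length(q); s <- logical(m); c <- 0L
    for (i in seq_len(m)) {
      if (!s[i]) {
        c <- c + 1L
        j <- i
        while (!s[j]) { s[j] <- TRUE; j <- q[j] }
      }
    }
    c
  }
  sel_l <- h - cyc(rl); sel_r <- (n - h) - cyc(rr)
  mc <- .merge_cost(left[ol], right[orr])
  m_ins <- ins_l + ins_r + mc
  m_sel <- sel_l + sel_r + mc
  if (m_ins < best) best <- m_ins
  if (m_sel < best) best <- m_sel
  best
}

#' Generate a random letter array
#'
#' Draws \code{size} distinct consonants uniformly at random and returns
#' them in random order. Uses the current RNG state, so results are
#' reproducible under [set.seed()].
#'
#' @param size array length, in \code{[3, 9]}.
#' @return character vector of \code{size} distinct consonants.
#' @export
generate_array <- function(size) {
  size <- as.integer(size)
  if (is.na(size) || size < 3L || size > 9L) {
    stop("array size must be in [3, 9]", call. = FALSE)
  }
  sample(CONSONANTS, size)
}

#' Generate a stratified stimulus set
#'
#' Draws \code{per_size} random arrays for each requested set size and
#' records each array's minimum sorting steps.
#'
#' @param sizes integer vector of set sizes, each in \code{[3, 9]}.
#' @param per_size number of arrays per size.
#' @return data.frame with columns \code{set_size}, \code{letters}
#'   (collapsed string) and \code{steps}.
#' @export
generate_stimulus_set <- function(sizes, per_size) {
  if (per_size < 1L) stop("per_size must be >= 1", call. = FALSE)
  sizes <- as.integer(sizes)
  if (any(sizes < 3L | sizes > 9L)) stop("sizes must lie in [3, 9]", call. = FALSE)
  out <- vector("list", length(sizes) * per_size)
  k <- 0L
  for (s in sizes) {
    for (i in seq_len(per_size)) {
      arr <- generate_array(s)
      k <- k + 1L
      out[[k]] <- data.frame(
        set_size = s,
        letters = paste(arr, collapse = ""),
        steps = min_sorting_steps(arr),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
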