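# Shared test fixtures and independent oracle implementations.

# all permutations of 1..n (n small)
perms_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms_of(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# breadth-first search distances from the identity permutation over a move
# set; returns an environment keyed by permutation string
bfs_distances <- function(n, neighbors) {
  dist <- new.env(hash = TRUE)
  key <- function(p) paste(p, collapse = "")
  id <- seq_len(n)
  assign(key(id), 0L, envir = dist)
  frontier <- list(id)
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- list()
    for (p in frontier) {
      for (q in neighbors(p)) {
        k <- key(q)
        if (is.null(dist[[k]])) {
          assign(k, d, envir = dist)
          nxt[[length(nxt) + 1L]] <- q
        }
      }
    }
    frontier <- nxt
  }
  dist
}

transposition_neighbors <- function(p) {
  n <- length(p)
  out <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    q <- p; q[c(i, j)] <- q[c(j, i)]
    out[[length(out) + 1L]] <- q
  }
  out
}

remove_reinsert_neighbors <- function(p) {
  n <- length(p)
  out <- list()
  for (i in seq_len(n)) {
    rest <- p[-i]
    for (pos in 0:(n - 1L)) {
      q <- append(rest, p[i], after = pos)
      if (!identical(q, p)) out[[length(out) + 1L]] <- q
    }
  }
  out
}

# letters whose sorting permutation is p
letters_for_perm <- function(p) {
  sort(sample(wmnet:::CONSONANTS, length(p)))[p]
}

# naive cPPI partial correlation: per pair, joint residualization on the
# full nuisance set, then plain correlation of the residuals
naive_cppi <- function(ts, psych, nuisance) {
  n <- ncol(ts)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      di <- ts[, i] - mean(ts[, i])
      dj <- ts[, j] - mean(ts[, j])
      pc <- psych - mean(psych)
      ppi_i <- di * pc
      ppi_j <- dj * pc
      Z <- cbind(1, psych, ts[, i], ts[, j], as.matrix(nuisance))
      ri <- stats::lm.fit(Z, ppi_i)$residuals
      rj <- stats::lm.fit(Z, ppi_j)$residuals
      out[i, j] <- out[j, i] <- stats::cor(ri, rj)
    }
  }
  out
}

# ground-truth partition over a (maint, manip)-ordered node set
truth_partition <- function(k = 23L) {
  structure(list(maintenance = seq_len(k), manipulation = k + seq_len(k),
                 fraction = 0.05, k = k), class = "network_partition")
}

# memoized default 41-subject behavior-only cohort shared across tests
default_cohort <- local({
  cache <- new.env()
  function(seed = 20260924L) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) cache[[key]] <- generate_cohort(seed = seed)
    cache[[key]]
  }
})
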