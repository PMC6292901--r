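# Task-state connectivity by correlational psychophysiological interaction
# (cPPI): for each node pair (i, j), the partial correlation of the PPI
# terms PPI_i and PPI_j (demeaned timecourse x demeaned convolved
# psychological regressor) controlling for the psychological regressor, the
# raw timecourses of i and j, and nuisance signals (6 motion + WM + CSF).
# Estimated per run, combined across runs by Fisher-z averaging.

#' Rebin sorting steps to four equal-count levels
#'
#' Within-subject quartile assignment of trials by their sorting-steps
#' value so that connectivity at each steps level is estimated from (as
#' near as possible) equal trial counts. Ties across a quartile boundary
#' are broken by trial order (earlier trials fill the lower bin).
#'
#' @param table a trial table (one subject).
#' @return integer vector of steps levels 1--4, aligned with the table's
#'   rows.
#' @export
rebin_steps <- function(table) {
  steps <- table$steps
  n <- length(steps)
  if (n < 4L) stop("need at least 4 trials to rebin", call. = FALSE)
  if (length(unique(steps)) < 2L) {
    stop("degenerate steps distribution: all trials share one value",
         call. = FALSE)
  }
  ord <- order(steps, seq_len(n))  # stable: ties by trial order
  bins <- rep(1:4, diff(round(seq(0, n, length.out = 5L))))
  out <- integer(n)
  out[ord] <- bins
  out
}

#' Psychological regressor for one condition level
#'
#' Unmodulated (weight 1) delay-period events of the trials at one level of
#' one demand type, HRF-convolved and mean-adjusted.
#'
#' @param table trial table (one subject).
#' @param demand \code{"set_size"} (relative level) or \code{"steps"}
#'   (rebinned steps level).
#' @param level level 1--4.
#' @param hrf an [hrf_model()].
#' @param run run number.
#' @param tr,n_vol acquisition timing.
#' @return numeric vector (one value per volume), mean zero.
#' @export
build_condition_regressor <- function(table, demand = c("set_size", "steps"),
                                      level, hrf = hrf_model(), run = 1L,
                                      tr = 2, n_vol = 254L) {
  demand <- match.arg(demand)
  lev <- switch(demand, set_size = table$level, steps = rebin_steps(table))
  sel <- table$run == run & lev == level
  if (!any(sel)) {
    stop("no trials at ", demand, " level ", level, " in run ", run,
         call. = FALSE)
  }
  x <- .convolve_events(table$onset_delay[sel], rep(5, sum(sel)),
                        rep(1, sum(sel)), hrf, n_vol, tr)
  x - mean(x)
}

# Vectorized cPPI for one run. ts: n_vol x nodes matrix; psych: length
# n_vol; nuisance: matrix of confound columns. Returns the partial
# correlation matrix over all node pairs.
.cppi_run <- function(ts, psych, nuisance) {
  n <- ncol(ts)
  tsd <- sweep(ts, 2, colMeans(ts))
  ppi <- tsd * (psych - mean(psych))
  # common nuisance: intercept + psych + confounds; node timecourses are
  # partialled pairwise below (Frisch-Waugh: residualize everything on the
  # common set first)
  Z <- cbind(1, psych, as.matrix(nuisance))
  qz <- qr(Z)
  P <- ppi - Z %*% qr.coef(qz, ppi)
  X <- tsd - Z %*% qr.coef(qz, tsd)
  PtP <- crossprod(P)
  XtX <- crossprod(X)
  XtP <- crossprod(X, P)
  a <- diag(XtX)
  A <- matrix(a, n, n)        # A[i,j] = x_i' x_i
  C <- t(A)                   # C[i,j] = x_j' x_j
  B <- XtX                    # B[i,j] = x_i' x_j
  det <- A * C - B^2
  det[det < 1e-300] <- NA     # constant/duplicated timecourses -> flagged
  # g_k = (x_i' p_k, x_j' p_k) for k in {i, j}
  gi1 <- matrix(diag(XtP), n, n)      # x_i' p_i
  gi2 <- t(XtP)                        # [i,j] = x_j' p_i
  gj1 <- XtP                           # [i,j] = x_i' p_j
  gj2 <- t(matrix(diag(XtP), n, n))    # x_j' p_j
  # M^{-1} = 1/det [[C, -B], [-B, A]]
  quad <- function(u1, u2, v1, v2) {
    (u1 * (C * v1 - B * v2) + u2 * (-B * v1 + A * v2)) / det
  }
  cov_ij <- PtP - quad(gi1, gi2, gj1, gj2)
  var_i <- matrix(diag(PtP), n, n) - quad(gi1, gi2, gi1, gi2)
  var_j <- t(matrix(diag(PtP), n, n)) - quad(gj1, gj2, gj1, gj2)
  r <- cov_ij / sqrt(pmax(var_i, 0) * pmax(var_j, 0))
  r[var_i <= 1e-300 | var_j <= 1e-300] <- NA
  r <- (r + t(r)) / 2  # symmetrize numerical asymmetry
  diag(r) <- NA_real_
  r
}

.fisher_z <- function(r) atanh(pmax(pmin(r, 1 - 1e-12), -1 + 1e-12))

#' cPPI connectivity matrix for one condition
#'
#' Computes the partial-correlation cPPI matrix over the partition's nodes
#' for one psychological regressor, per run, and averages runs via Fisher
#' z. The nuisance set removed from each pair's PPI terms comprises the
#' psychological regressor, the raw timecourses of both nodes, and the
#' run's confound columns (6 motion + WM + CSF).
#'
#' @param bundle a \code{roi_bundle} (see [simulate_timeseries()]).
#' @param nodes integer vector of node (ROI) indices to include.
#' @param psych list of per-run psychological regressors, or a single
#'   vector applied to every run.
#' @return symmetric matrix (nodes x nodes), \code{NA} diagonal, entries in
#'   \code{[-1, 1]}.
#' @export
cppi_matrix <- function(bundle, nodes, psych) {
  n_runs <- length(bundle$signal)
  if (!is.list(psych)) psych <- rep(list(psych), n_runs)
  zsum <- 0
  for (ri in seq_len(n_runs)) {
    ts <- bundle$signal[[ri]][, nodes, drop = FALSE]
    r <- .cppi_run(ts, psych[[ri]], bundle$confounds[[ri]])
    zsum <- zsum + .fisher_z(r)
  }
  out <- tanh(zsum / n_runs)
  dimnames(out) <- list(nodes, nodes)
  out
}

#' Per-condition connectivity tensor
#'
#' The 8 cPPI matrices of one subject: one per relative set-size level
#' (1--4) and one per rebinned sorting-steps level (1--4), each estimated
#' from that level's unmodulated delay regressor.
#'
#' @param bundle a \code{roi_bundle}.
#' @param nodes node indices (e.g. the union of a partition's networks).
#' @param table the subject's trial table.
#' @param hrf an [hrf_model()].
#' @param demands demand types to compute (default both).
#' @return list of class \code{cppi_tensor}: matrices named
#'   \code{set_size_1..4}, \code{steps_1..4}, plus \code{trial_counts}.
#' @export
condition_tensor <- function(bundle, nodes, table, hrf = hrf_model(),
                             demands = c("set_size", "steps")) {
  n_runs <- length(bundle$signal)
  out <- list()
  counts <- list()
  runs <- sort(unique(table$run))
  for (dm in demands) {
    lev_codes <- switch(dm, set_size = table$level, steps = rebin_steps(table))
    for (lv in 1:4) {
      # a run may hold no trials of this level (especially after steps
      # rebinning); estimate from the runs that do and Fisher-average
      have <- which(vapply(runs, function(r) {
        any(table$run == r & lev_codes == lv)
      }, logical(1)))
      if (length(have) == 0L) {
        stop("no trials at ", dm, " level ", lv, call. = FALSE)
      }
      psych <- lapply(runs[have], function(ri) {
        build_condition_regressor(table, dm, lv, hrf, run = ri,
                                  tr = bundle$tr, n_vol = bundle$n_vol)
      })
      sub <- bundle
      sub$signal <- bundle$signal[have]
      sub$confounds <- bundle$confounds[have]
      nm <- paste0(dm, "_", lv)
      out[[nm]] <- cppi_matrix(sub, nodes, psych)
      counts[[nm]] <- sum(lev_codes == lv)
    }
  }
  structure(list(matrices = out, trial_counts = unlist(counts),
                 nodes = nodes), class = "cppi_tensor")
}
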