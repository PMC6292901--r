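# First-level GLM machinery: canonical double-gamma HRF, event convolution
# on a microtime grid, design matrices with concurrent parametric delay
# modulators (mean-centered, then orthogonalized to the unmodulated delay
# regressor after convolution), per-ROI OLS, fixed-effects run combination,
# group random-effects z maps, and VIF collinearity diagnostics.

#' Canonical double-gamma HRF model
#'
#' @param peak_delay time-to-peak of the positive gamma (s).
#' @param undershoot_delay time-to-peak of the undershoot gamma (s).
#' @param undershoot_ratio amplitude ratio of undershoot to peak.
#' @param length kernel support (s).
#' @param dt microtime resolution (s).
#' @return object of class \code{hrf_model}.
#' @export
hrf_model <- function(peak_delay = 6, undershoot_delay = 16,
                      undershoot_ratio = 1 / 6, length = 32, dt = 0.1) {
  stopifnot(peak_delay > 0, undershoot_delay > 0, length > 0, dt > 0)
  t <- seq(0, length, by = dt)
  h <- stats::dgamma(t, shape = peak_delay, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_delay, rate = 1)
  h <- h / sum(h)  # unit-sum kernel; integrates to a positive value
  structure(list(kernel = h, dt = dt, peak_delay = peak_delay,
                 undershoot_delay = undershoot_delay,
                 undershoot_ratio = undershoot_ratio, length = length),
            class = "hrf_model")
}

#' @export
print.hrf_model <- function(x, ...) {
  cat(sprintf(
    "Double-gamma HRF: peak %gs, undershoot %gs (ratio %.3f), %gs @ dt=%gs\n",
    x$peak_delay, x$undershoot_delay, x$undershoot_ratio, x$length, x$dt))
  invisible(x)
}

# Place weighted boxcar events on the microtime grid, convolve with the HRF
# kernel, and sample at volume onsets. onsets/durations in seconds.
.convolve_events <- function(onsets, durations, weights, hrf,
                             n_vol, tr) {
  dt <- hrf$dt
  n_micro <- ceiling(n_vol * tr / dt)
  u <- numeric(n_micro)
  for (i in seq_along(onsets)) {
    if (onsets[i] + durations[i] > n_vol * tr + 1e-9) {
      stop("event at ", onsets[i], " s exceeds run end (", n_vol * tr, " s)",
           call. = FALSE)
    }
    a <- floor(onsets[i] / dt) + 1L
    b <- min(n_micro, ceiling((onsets[i] + durations[i]) / dt))
    u[a:b] <- u[a:b] + weights[i]
  }
  conv <- stats::convolve(u, rev(hrf$kernel), type = "open")[seq_len(n_micro)]
  idx <- pmin(n_micro, floor((seq_len(n_vol) - 1L) * tr / dt) + 1L)
  conv[idx]
}

# residualize y against columns of X (with intercept)
.residualize <- function(y, X) {
  X <- cbind(1, X)
  y - X %*% qr.coef(qr(X), y)
}

#' Build first-level design matrices
#'
#' One design per run. Task regressors: array presentation (3 s boxcar),
#' unmodulated delay (5 s), two parametric delay modulators (relative set
#' size and sorting steps; mean-centered across the run's correct trials
#' before convolution and residualized against the convolved unmodulated
#' delay regressor afterwards), and a response regressor with duration equal
#' to the reaction time. Incorrect and non-response trials are modeled by
#' separate duplicate array/delay/response regressors and carry no
#' parametric weight.
#'
#' @param table a trial table (one subject), see [generate_trial_table()].
#' @param hrf an [hrf_model()].
#' @param confounds optional list (per run) of confound matrices appended
#'   unaltered as nuisance columns.
#' @param n_vol volumes per run.
#' @param tr repetition time (s).
#' @return list of class \code{wm_design}: per run a list with \code{task}
#'   (matrix of convolved task regressors), \code{confounds},
#'   \code{parametric} (names of the modulator columns).
#' @export
build_design <- function(table, hrf = hrf_model(), confounds = NULL,
                         n_vol = 254L, tr = 2) {
  runs <- sort(unique(table$run))
  out <- vector("list", length(runs))
  names(out) <- paste0("run", runs)
  for (ri in seq_along(runs)) {
    tt <- table[table$run == runs[ri], , drop = FALSE]
    ok <- tt$correct & tt$responded
    err <- !ok
    cols <- list()
    cols$array <- .convolve_events(tt$onset_array[ok], rep(3, sum(ok)),
                                   rep(1, sum(ok)), hrf, n_vol, tr)
    delay <- .convolve_events(tt$onset_delay[ok], rep(5, sum(ok)),
                              rep(1, sum(ok)), hrf, n_vol, tr)
    cols$delay <- delay
    w_set <- tt$level[ok] - mean(tt$level[ok])
    w_steps <- tt$steps[ok] - mean(tt$steps[ok])
    mod_set <- .convolve_events(tt$onset_delay[ok], rep(5, sum(ok)),
                                w_set, hrf, n_vol, tr)
    mod_steps <- .convolve_events(tt$onset_delay[ok], rep(5, sum(ok)),
                                  w_steps, hrf, n_vol, tr)
    cols$delay_x_set <- as.numeric(.residualize(mod_set, cbind(delay)))
    cols$delay_x_steps <- as.numeric(.residualize(mod_steps, cbind(delay)))
    rt_s <- pmin(tt$rt[ok], 4000) / 1000
    cols$response <- .convolve_events(tt$onset_probe[ok], rt_s,
                                      rep(1, sum(ok)), hrf, n_vol, tr)
    if (any(err)) {
      cols$err_array <- .convolve_events(tt$onset_array[err], rep(3, sum(err)),
                                         rep(1, sum(err)), hrf, n_vol, tr)
      cols$err_delay <- .convolve_events(tt$onset_delay[err], rep(5, sum(err)),
                                         rep(1, sum(err)), hrf, n_vol, tr)
      rt_e <- ifelse(tt$responded[err], pmin(tt$rt[err], 4000) / 1000, 4)
      cols$err_response <- .convolve_events(tt$onset_probe[err], rt_e,
                                            rep(1, sum(err)), hrf, n_vol, tr)
    }
    task <- do.call(cbind, cols)
    degenerate <- apply(task, 2, function(x) all(abs(x) < 1e-12))
    if (any(degenerate)) {
      warning("degenerate all-zero design column(s): ",
              paste(colnames(task)[degenerate], collapse = ", "))
      task <- task[, !degenerate, drop = FALSE]
    }
    out[[ri]] <- list(
      task = task,
      confounds = if (is.null(confounds)) NULL else confounds[[ri]],
      parametric = intersect(c("delay_x_set", "delay_x_steps"),
                             colnames(task)),
      n_vol = n_vol, tr = tr)
  }
  class(out) <- "wm_design"
  out
}

#' Fit the per-ROI GLM
#'
#' Ordinary least squares per ROI and run on \code{[intercept | task |
#' confounds]}; runs are combined by fixed-effects inverse-variance
#' averaging of each coefficient.
#'
#' @param bundle list with element \code{signal}: per-run TR x ROI matrices
#'   (see [simulate_timeseries()]); or a single matrix for one run.
#' @param design a \code{wm_design} from [build_design()].
#' @return list of class \code{wm_glm}: \code{coef} and \code{se} (task
#'   column x ROI matrices, run-combined), plus per-run detail.
#' @export
fit_glm <- function(bundle, design) {
  sig <- if (is.matrix(bundle)) list(bundle) else bundle$signal
  if (length(sig) != length(design)) {
    stop("signal and design run counts differ", call. = FALSE)
  }
  # combine only columns present in every run (error-trial regressors may
  # be absent from runs without error trials)
  task_names <- Reduce(intersect, lapply(design, function(d) colnames(d$task)))
  nroi <- ncol(sig[[1]])
  runs <- vector("list", length(sig))
  for (ri in seq_along(sig)) {
    Y <- sig[[ri]]
    d <- design[[ri]]
    if (nrow(Y) != nrow(d$task)) {
      stop("design and signal share no common volume count", call. = FALSE)
    }
    X <- cbind(intercept = 1, d$task)
    if (!is.null(d$confounds)) X <- cbind(X, as.matrix(d$confounds))
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      keep <- qx$pivot[seq_len(qx$rank)]
      bad <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
      stop("rank-deficient design; collinear column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    beta <- qr.coef(qx, Y)
    res <- Y - X %*% beta
    dfres <- nrow(X) - ncol(X)
    sigma2 <- colSums(res^2) / dfres
    xtx_inv_diag <- diag(solve(crossprod(X)))
    se <- sqrt(outer(xtx_inv_diag, sigma2))
    rownames(se) <- colnames(X)
    runs[[ri]] <- list(coef = beta, se = se, df = dfres)
  }
  comb_coef <- matrix(0, length(task_names), nroi,
                      dimnames = list(task_names, colnames(sig[[1]])))
  comb_se <- comb_coef
  for (cn in task_names) {
    b <- matrix(vapply(runs, function(r) r$coef[cn, ], numeric(nroi)),
                nroi, length(runs))
    v <- matrix(vapply(runs, function(r) r$se[cn, ]^2, numeric(nroi)),
                nroi, length(runs))
    w <- 1 / v
    comb_coef[cn, ] <- rowSums(b * w) / rowSums(w)
    comb_se[cn, ] <- sqrt(1 / rowSums(w))
  }
  structure(list(coef = comb_coef, se = comb_se, runs = runs),
            class = "wm_glm")
}

#' Group-level parametric map
#'
#' One-sample t test across subjects of each ROI's modulator coefficient,
#' converted to a z statistic (capped at +/-38 to avoid infinities from
#' zero-variance degenerate inputs).
#'
#' @param coef_list list (per subject) of \code{wm_glm} fits, or a list of
#'   named lists with per-effect coefficient vectors.
#' @param effects task columns to map (default the two modulators).
#' @param z_cap cap on |z|.
#' @return data.frame of class \code{parametric_map} with columns
#'   \code{roi}, \code{z_set}, \code{z_steps} (one z column per effect).
#' @export
group_parametric_map <- function(coef_list,
                                 effects = c("delay_x_set", "delay_x_steps"),
                                 z_cap = 38) {
  if (length(coef_list) < 3L) {
    stop("group map needs at least 3 subjects", call. = FALSE)
  }
  nroi <- ncol(coef_list[[1]]$coef)
  out <- data.frame(roi = seq_len(nroi))
  for (ef in effects) {
    B <- t(sapply(coef_list, function(f) f$coef[ef, ]))
    n <- nrow(B)
    m <- colMeans(B)
    s <- apply(B, 2, stats::sd)
    tstat <- m / (s / sqrt(n))
    tstat[s == 0] <- sign(m[s == 0]) * Inf
    # tail-safe t -> z conversion (work in the nearer tail, log scale)
    lp <- stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE, log.p = TRUE)
    z <- -sign(tstat) * stats::qnorm(lp, log.p = TRUE)
    z[!is.finite(z)] <- sign(tstat[!is.finite(z)]) * z_cap
    z <- pmax(pmin(z, z_cap), -z_cap)
    nm <- sub("delay_x_", "z_", ef)
    out[[nm]] <- z
  }
  class(out) <- c("parametric_map", "data.frame")
  out
}

#' Variance inflation factors for design columns
#'
#' VIF of a column is 1 / (1 - R^2) from regressing it on all other task
#' columns (plus an intercept); per-run VIFs are averaged across runs.
#'
#' @param design a \code{wm_design}.
#' @param columns columns to diagnose (default the parametric modulators).
#' @return named numeric vector of run-averaged VIFs.
#' @export
compute_vif <- function(design, columns = NULL) {
  if (is.null(columns)) columns <- design[[1]]$parametric
  vifs <- matrix(NA_real_, length(design), length(columns),
                 dimnames = list(NULL, columns))
  for (ri in seq_along(design)) {
    X <- design[[ri]]$task
    for (ci in seq_along(columns)) {
      cn <- columns[ci]
      if (!cn %in% colnames(X)) stop("no design column ", cn, call. = FALSE)
      y <- X[, cn]
      others <- X[, setdiff(colnames(X), cn), drop = FALSE]
      r <- .residualize(y, others)
      ssr <- sum((y - mean(y))^2)
      if (ssr < 1e-300) stop("column ", cn, " is constant", call. = FALSE)
      r2 <- 1 - sum(r^2) / ssr
      if (r2 > 1 - 1e-12) {
        warning("perfect collinearity for column ", cn)
        vifs[ri, ci] <- Inf
      } else {
        vifs[ri, ci] <- 1 / (1 - r2)
      }
    }
  }
  colMeans(vifs)
}
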