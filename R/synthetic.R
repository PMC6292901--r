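# Synthetic cohort generator: trial tables with the scanned task's timing
# and demand codes, behavioral outcomes from the mixed-model coefficient
# structure, ROI-level BOLD timeseries with two ground-truth task networks
# (positive within-network coupling, difficulty-scaled negative
# between-network coupling), confounds, and structural (FA) matrices.

#' Default behavioral model parameters
#'
#' Fixed-effect coefficients of the trial-level accuracy (logit) and
#' reaction-time (ms) models, the RT residual SD, random-effect SDs, and
#' the non-response rate. The fixed effects default to the fitted values of
#' the study design the generator emulates: accuracy logit
#' 4.10 - 0.94*level - 0.49*steps + 0.11*level*steps; RT (ms)
#' 1129.17 + 284.36*level + 89.22*steps - 29.14*level*steps.
#'
#' @param logit intercept/level/steps/interaction logit coefficients.
#' @param rt intercept/level/steps/interaction RT coefficients (ms).
#' @param rt_sd RT residual SD (ms).
#' @param re_sd_logit random-effect SDs (intercept, level slope, steps
#'   slope) of the accuracy model.
#' @param re_sd_rt random-effect SDs of the RT model (ms).
#' @param nonresponse_rate fraction of trials with no response within the
#'   4 s window.
#' @return list of class \code{behavior_params}.
#' @export
behavior_params <- function(logit = c(intercept = 4.10, level = -0.94,
                                      steps = -0.49, interaction = 0.11),
                            rt = c(intercept = 1129.17, level = 284.36,
                                   steps = 89.22, interaction = -29.14),
                            rt_sd = 350,
                            re_sd_logit = c(0.60, 0.15, 0.10),
                            re_sd_rt = c(150, 40, 20),
                            nonresponse_rate = 0.016) {
  structure(list(logit = logit, rt = rt, rt_sd = rt_sd,
                 re_sd_logit = re_sd_logit, re_sd_rt = re_sd_rt,
                 nonresponse_rate = nonresponse_rate),
            class = "behavior_params")
}

#' Ground-truth network structure for the BOLD generator
#'
#' Two disjoint node communities among \code{n_rois} abstract ROIs: a
#' maintenance network whose delay activation scales with relative set size
#' and a manipulation network scaling with sorting steps. Within-network
#' coupling is carried by a per-network latent series with positive
#' loadings; the mean between-network coupling by the correlation of the
#' two networks' per-trial latent innovations, \code{rho_level = rho0 -
#' delta * (level - 1)}, negative at every level and more negative at
#' harder levels. A subject's reconfiguration gain scales a level-specific
#' coupling-pattern component (\code{cross_jitter}) that reorganizes the
#' edge pattern across difficulty states without moving the level means.
#'
#' @param n_rois number of ROIs (default 471).
#' @param n_nodes nodes per network (default 23).
#' @param amp_delay unmodulated delay amplitude of network nodes.
#' @param amp_set per-level parametric amplitude of maintenance nodes.
#' @param amp_steps per-step parametric amplitude of manipulation nodes.
#' @param w_maint,w_manip latent coupling weight per network.
#' @param loading_jitter multiplicative SD of per-node latent loadings.
#' @param rho0 between-network innovation correlation at level 1.
#' @param delta per-level decrement of the between-network correlation.
#' @param cross_jitter SD of the gain-scaled, level-specific coupling
#'   pattern (drives gain-dependent network reconfiguration without
#'   shifting the mean coupling at any level).
#' @param stable_sd SD of the signed node loadings on a global latent
#'   series: a stable, level-independent edge pattern (zero mean across
#'   edges) shared by all difficulty states.
#' @param noise_sd idiosyncratic noise SD.
#' @param ar1 AR(1) coefficient of the idiosyncratic noise.
#' @param confound_mix SD of the per-node confound mixing weights.
#' @param fa_within,fa_between,fa_sd structural (FA) block means and noise.
#' @return list of class \code{ground_truth}.
#' @export
ground_truth <- function(n_rois = 471L, n_nodes = 23L,
                         amp_delay = 0.15, amp_set = 0.25, amp_steps = 0.20,
                         w_maint = 0.95, w_manip = 0.60,
                         loading_jitter = 0.25,
                         rho0 = -0.15, delta = 0.20, cross_jitter = 0.8,
                         stable_sd = 0.6,
                         noise_sd = 1, ar1 = 0.3,
                         confound_mix = 0.05,
                         fa_within = 0.45, fa_between = 0.35, fa_sd = 0.03) {
  stopifnot(n_rois >= 2L * n_nodes, n_nodes >= 2L)
  maint <- seq_len(n_nodes)
  manip <- n_nodes + seq_len(n_nodes)
  structure(list(
    n_rois = as.integer(n_rois), n_nodes = as.integer(n_nodes),
    maintenance_nodes = maint, manipulation_nodes = manip,
    amp_delay = amp_delay, amp_set = amp_set, amp_steps = amp_steps,
    w_maint = w_maint, w_manip = w_manip, loading_jitter = loading_jitter,
    rho0 = rho0, delta = delta, cross_jitter = cross_jitter,
    stable_sd = stable_sd, noise_sd = noise_sd, ar1 = ar1,
    confound_mix = confound_mix,
    fa_within = fa_within, fa_between = fa_between, fa_sd = fa_sd),
    class = "ground_truth")
}

#' Subject specification
#'
#' Per-subject design and generative parameters: the titrated starting set
#' size, the continuous criterion (set size at 82% fitted accuracy, which
#' lies between the Easy and Medium sizes), behavioral random effects, and
#' the reconfiguration gain scaling the level dependence of between-network
#' coupling.
#'
#' @param subject_id integer id.
#' @param starting_set_size Very Easy set size, in \code{[3, 6]}.
#' @param params a [behavior_params()] (random effects are drawn from its
#'   SDs).
#' @param criterion_link slope tying the reconfiguration gain to the
#'   subject's criterion (0 = no link).
#' @param gain_noise SD of the residual gain variation.
#' @return list of class \code{subject_spec}.
#' @export
subject_spec <- function(subject_id, starting_set_size,
                         params = behavior_params(),
                         criterion_link = 0.6, gain_noise = 0.25) {
  starting_set_size <- as.integer(starting_set_size)
  if (starting_set_size < 3L || starting_set_size > 6L) {
    stop("starting_set_size must lie in [3, 6]", call. = FALSE)
  }
  criterion <- starting_set_size + 1 + stats::runif(1)
  gain <- max(0, 1 + criterion_link * (criterion - 5.5) +
                stats::rnorm(1, 0, gain_noise))
  structure(list(
    subject_id = subject_id,
    starting_set_size = starting_set_size,
    criterion_set_size = criterion,
    re_logit = stats::rnorm(3, 0, params$re_sd_logit),
    re_rt = stats::rnorm(3, 0, params$re_sd_rt),
    reconfiguration_gain = gain),
    class = "subject_spec")
}

# Trial stimulus selection: difficulty-standardized sampling. Draw `m`
# candidate arrays and keep the one whose min-steps is closest to a target
# drawn around a mean that rises with the relative level and is shifted
# down for higher-starting (higher-ability) subjects, compensating the
# larger achievable step range of their bigger arrays. This emulates a
# titrated design in which manipulation difficulty per level is comparable
# across subjects: sorting steps track relative difficulty more than
# absolute array size, which keeps the pooled set-size/steps correlation
# moderate while per-run demand codes stay substantially collinear.
.draw_stimulus <- function(size, level, start, m = 16L,
                           target_base = 1.0, target_slope = 1.0,
                           target_start_comp = 1.6, target_sd = 2.0) {
  target <- stats::rnorm(1, target_base + target_slope * level -
                           target_start_comp * (start - 4), target_sd)
  best_p <- NULL
  best_d <- Inf
  for (i in seq_len(m)) {
    p <- sample.int(size)
    s <- .min_steps_perm(p)
    d <- abs(s - target)
    if (d < best_d) { best_d <- d; best_p <- p }
  }
  letters <- sort(sample(CONSONANTS, size))[best_p]
  list(letters = letters, steps = .min_steps_perm(best_p))
}

# truncated exponential on [lo, hi] with approximate mean `mean_s`
.draw_iti <- function(n, mean_s = 5, lo = 2, hi = 10) {
  out <- numeric(n)
  k <- 0L
  while (k < n) {
    x <- stats::rexp(n, 1 / (mean_s - lo)) + lo
    x <- x[x <= hi]
    take <- min(length(x), n - k)
    if (take > 0) out[(k + 1L):(k + take)] <- x[seq_len(take)]
    k <- k + take
  }
  out
}

#' Generate one subject's trial table
#'
#' 4 runs x 30 trials; equal numbers of trials per relative level (30 each),
#' probe mix 48 valid / 48 invalid / 24 new, pseudorandomized across runs.
#' Within a run, trials are array (3 s) + delay (5 s) + probe window (4 s)
#' separated by truncated-exponential ITIs (mean ~5 s on [2, 10] s) after a
#' 2 s lead-in; ITIs are scaled down if the last probe would overrun the
#' 508 s run. Letters are drawn by the stimulus-selection policy and the
#' minimum sorting steps recorded per trial.
#'
#' @param spec a [subject_spec()].
#' @param n_runs,trials_per_run task dimensions.
#' @param tr,n_vol acquisition timing (run length = \code{n_vol * tr}).
#' @return data.frame trial table with columns \code{subject}, \code{run},
#'   \code{trial}, \code{level}, \code{set_size}, \code{letters},
#'   \code{steps}, \code{probe_type}, \code{onset_array},
#'   \code{onset_delay}, \code{onset_probe}, \code{iti} plus behavioral
#'   columns filled by [simulate_behavior()].
#' @export
generate_trial_table <- function(spec, n_runs = 4L, trials_per_run = 30L,
                                 tr = 2, n_vol = 254L) {
  n_trials <- n_runs * trials_per_run
  if (n_trials %% 4L != 0L) stop("trial count must be divisible by 4")
  levels <- sample(rep(1:4, n_trials / 4L))
  probe_pool <- c(rep("valid", round(0.4 * n_trials)),
                  rep("invalid", round(0.4 * n_trials)))
  probe_pool <- c(probe_pool, rep("new", n_trials - length(probe_pool)))
  probes <- sample(probe_pool)
  run_dur <- n_vol * tr
  v_run <- v_trial <- v_level <- v_size <- v_steps <- integer(n_trials)
  v_letters <- character(n_trials)
  v_onset <- v_iti <- numeric(n_trials)
  k <- 0L
  for (r in seq_len(n_runs)) {
    iti <- .draw_iti(trials_per_run - 1L)
    lead_in <- 2
    # event time per trial: 3 s array + 5 s delay + 4 s probe window
    total <- lead_in + trials_per_run * 12 + sum(iti)
    if (total > run_dur) {
      iti <- iti * (run_dur - lead_in - trials_per_run * 12) / sum(iti)
    }
    onset <- lead_in
    for (i in seq_len(trials_per_run)) {
      k <- k + 1L
      lev <- levels[k]
      size <- spec$starting_set_size + lev - 1L
      stim <- .draw_stimulus(size, lev, spec$starting_set_size)
      v_run[k] <- r; v_trial[k] <- i; v_level[k] <- lev; v_size[k] <- size
      v_letters[k] <- paste(stim$letters, collapse = "")
      v_steps[k] <- stim$steps
      v_onset[k] <- onset
      v_iti[k] <- if (i < trials_per_run) iti[i] else NA_real_
      onset <- onset + 12 + (if (i < trials_per_run) iti[i] else 0)
    }
  }
  data.frame(
    subject = spec$subject_id, run = v_run, trial = v_trial,
    level = v_level, set_size = v_size, letters = v_letters,
    steps = v_steps, probe_type = probes,
    onset_array = v_onset, onset_delay = v_onset + 3,
    onset_probe = v_onset + 8, iti = v_iti,
    correct = NA, rt = NA_real_, responded = NA,
    stringsAsFactors = FALSE)
}

#' Simulate trial-level behavior
#'
#' Accuracy is Bernoulli with logit \code{(b0+u0) + (b1+u1)*level +
#' (b2+u2)*steps + b3*level*steps}; RT is the linear model plus Gaussian
#' residual, truncated at the 4000 ms response window. A random
#' \code{nonresponse_rate} fraction of trials is marked unanswered
#' (excluded from all analyses downstream).
#'
#' @param table trial table from [generate_trial_table()].
#' @param params a [behavior_params()].
#' @param spec the [subject_spec()] carrying the random effects.
#' @return the table with \code{correct}, \code{rt}, \code{responded}
#'   filled in.
#' @export
simulate_behavior <- function(table, params = behavior_params(), spec) {
  b <- params$logit; u <- spec$re_logit
  eta <- (b[1] + u[1]) + (b[2] + u[2]) * table$level +
    (b[3] + u[3]) * table$steps + b[4] * table$level * table$steps
  if (any(abs(eta) > 30)) {
    warning("logit predictor overflow; clamping")
    eta <- pmax(pmin(eta, 30), -30)
  }
  p <- 1 / (1 + exp(-eta))
  table$correct <- stats::runif(nrow(table)) < p
  g <- params$rt; v <- spec$re_rt
  mu <- (g[1] + v[1]) + (g[2] + v[2]) * table$level +
    (g[3] + v[3]) * table$steps + g[4] * table$level * table$steps
  rt <- mu + stats::rnorm(nrow(table), 0, params$rt_sd)
  table$rt <- pmax(150, pmin(rt, 4000))
  table$responded <- stats::runif(nrow(table)) >= params$nonresponse_rate
  table$rt[!table$responded] <- NA_real_
  table$correct[!table$responded] <- FALSE
  table
}

# AR(1) noise matrix (n x k), unit innovation scaling to sd `sd`
.ar1_noise <- function(n, k, phi, sd) {
  e <- matrix(stats::rnorm(n * k), n, k)
  if (phi != 0) {
    for (i in 2:n) e[i, ] <- phi * e[i - 1L, ] + e[i, ]
    e <- e * sqrt(1 - phi^2)
  }
  e * sd
}

#' Simulate one subject's ROI timeseries bundle
#'
#' Per run, a \code{n_vol x n_rois} BOLD matrix: network-node task signal
#' (HRF-convolved delay events; maintenance nodes weighted by relative
#' level, manipulation nodes by sorting steps), per-network latent series
#' built from per-trial innovations whose across-network correlation is
#' \code{rho0 - delta * gain * (level - 1)}, idiosyncratic AR(1) noise, and
#' linear leakage of 8 smooth confound series (6 motion + WM + CSF) into
#' all nodes.
#'
#' @param table the subject's trial table (behavior already simulated).
#' @param truth a [ground_truth()].
#' @param spec the [subject_spec()] (for the reconfiguration gain).
#' @param hrf an [hrf_model()].
#' @param tr,n_vol acquisition timing.
#' @return list of class \code{roi_bundle}: \code{signal} and
#'   \code{confounds} (lists per run), \code{truth}, \code{tr},
#'   \code{n_vol}.
#' @export
simulate_timeseries <- function(table, truth = ground_truth(), spec,
                                hrf = hrf_model(), tr = 2, n_vol = 254L) {
  runs <- sort(unique(table$run))
  nroi <- truth$n_rois
  maint <- truth$maintenance_nodes
  manip <- truth$manipulation_nodes
  gain <- spec$reconfiguration_gain
  lam_maint <- truth$w_maint *
    exp(stats::rnorm(length(maint), 0, truth$loading_jitter))
  lam_manip <- truth$w_manip *
    exp(stats::rnorm(length(manip), 0, truth$loading_jitter))
  # level-specific coupling-pattern perturbations, scaled by the subject's
  # reconfiguration gain: zero mean over nodes, so level means are
  # untouched, but the edge pattern rotates across difficulty states
  kj <- truth$cross_jitter * gain
  zjm <- matrix(stats::rnorm(length(maint) * 4L, 0, kj), length(maint), 4L)
  zjp <- matrix(stats::rnorm(length(manip) * 4L, 0, kj), length(manip), 4L)
  # stable signed loadings on a global latent: a level-independent,
  # zero-mean edge pattern common to all difficulty states
  mu_m <- stats::rnorm(length(maint), 0, truth$stable_sd)
  mu_p <- stats::rnorm(length(manip), 0, truth$stable_sd)
  signal <- vector("list", length(runs))
  confounds <- vector("list", length(runs))
  for (ri in seq_along(runs)) {
    tt <- table[table$run == runs[ri], , drop = FALSE]
    nt <- nrow(tt)
    Y <- .ar1_noise(n_vol, nroi, truth$ar1, truth$noise_sd)
    # per-trial HRF-convolved delay event shapes (n_vol x n_trials)
    shapes <- vapply(seq_len(nt), function(i) {
      .convolve_events(tt$onset_delay[i], 5, 1, hrf, n_vol, tr)
    }, numeric(n_vol))
    # task activation: maintenance ~ level, manipulation ~ steps
    act_m <- shapes %*% (truth$amp_delay + truth$amp_set * tt$level)
    act_p <- shapes %*% (truth$amp_delay + truth$amp_steps * tt$steps)
    # correlated per-trial latent innovations
    rho <- pmax(-0.95, pmin(0.95,
      truth$rho0 - truth$delta * (tt$level - 1)))
    # latent innovations are coupling noise, independent of task demand:
    # enforce exact sample-orthogonality to the run's demand codes so they
    # cannot leak into the parametric activation estimates
    D <- cbind(1, tt$level, tt$steps)
    orth <- function(e) as.numeric(.residualize(e, D[, -1, drop = FALSE]))
    e1 <- orth(stats::rnorm(nt))
    e2 <- rho * e1 + sqrt(1 - rho^2) * orth(stats::rnorm(nt))
    lat_m <- shapes %*% e1
    lat_p <- shapes %*% e2
    # shared cross-pattern latent with level-specific node loadings
    cc <- orth(stats::rnorm(nt))
    shapes_c <- shapes * rep(cc, each = n_vol)
    jit_m <- shapes_c %*% t(zjm[, tt$level, drop = FALSE])
    jit_p <- shapes_c %*% t(zjp[, tt$level, drop = FALSE])
    ff <- shapes %*% orth(stats::rnorm(nt))
    Y[, maint] <- Y[, maint] + act_m %*% t(rep(1, length(maint))) +
      lat_m %*% t(lam_maint) + jit_m + ff %*% t(mu_m)
    Y[, manip] <- Y[, manip] + act_p %*% t(rep(1, length(manip))) +
      lat_p %*% t(lam_manip) + jit_p + ff %*% t(mu_p)
    # confounds: smooth random walks, mixed weakly into every node
    conf <- apply(matrix(stats::rnorm(n_vol * 8L, 0, 0.3), n_vol, 8L), 2, cumsum)
    colnames(conf) <- c(paste0("motion", 1:6), "wm", "csf")
    mix <- matrix(stats::rnorm(8L * nroi, 0, truth$confound_mix), 8L, nroi)
    Y <- Y + conf %*% mix
    signal[[ri]] <- Y
    confounds[[ri]] <- as.data.frame(conf)
  }
  structure(list(signal = signal, confounds = confounds, truth = truth,
                 tr = tr, n_vol = as.integer(n_vol)),
            class = "roi_bundle")
}

#' Generate a synthetic structural (FA) matrix
#'
#' Symmetric matrix over the two networks' nodes with within-network block
#' mean exceeding the between-network block mean by
#' \code{fa_within - fa_between}, plus Gaussian noise, clipped to [0, 1].
#'
#' @param truth a [ground_truth()].
#' @return symmetric matrix (2*n_nodes x 2*n_nodes), \code{NA} diagonal.
#' @export
generate_structural_matrix <- function(truth = ground_truth()) {
  k <- truth$n_nodes
  n <- 2L * k
  within <- matrix(FALSE, n, n)
  within[1:k, 1:k] <- TRUE
  within[(k + 1):n, (k + 1):n] <- TRUE
  mu <- ifelse(within, truth$fa_within, truth$fa_between)
  fa <- mu + matrix(stats::rnorm(n * n, 0, truth$fa_sd), n, n)
  fa[lower.tri(fa)] <- t(fa)[lower.tri(fa)]
  fa <- pmin(pmax(fa, 0), 1)
  diag(fa) <- NA_real_
  fa
}

#' Generate a full synthetic cohort
#'
#' Default conditions: 41 subjects with starting set sizes distributed
#' 12/19/9/1 over 3--6, each with 4 runs x 30 trials, simulated behavior,
#' and (optionally) ROI timeseries bundles with the ground-truth network
#' structure. Seeding is per subject (derived from the master seed), so
#' cohorts are reproducible and subjects independent.
#'
#' @param n_subjects cohort size.
#' @param seed master seed.
#' @param params a [behavior_params()].
#' @param truth a [ground_truth()]; used when \code{timeseries = TRUE}.
#' @param timeseries simulate BOLD bundles (slow) or behavior only.
#' @param start_prior probabilities of starting sizes 3:6 (used when
#'   \code{n_subjects != 41}; the default 41-subject cohort uses the exact
#'   12/19/9/1 counts).
#' @param criterion_link,gain_noise passed to [subject_spec()].
#' @param hrf an [hrf_model()] for the BOLD generator.
#' @return list of class \code{wm_cohort}: \code{subjects} (specs),
#'   \code{trials} (one combined data.frame), \code{bundles} (list or
#'   NULL), \code{truth}, \code{seed}.
#' @export
generate_cohort <- function(n_subjects = 41L, seed = 1L,
                            params = behavior_params(),
                            truth = ground_truth(),
                            timeseries = FALSE,
                            start_prior = c(12, 19, 9, 1) / 41,
                            criterion_link = 0.6, gain_noise = 0.25,
                            hrf = hrf_model()) {
  seed <- as.integer(seed)
  set.seed(seed)
  starts <- if (n_subjects == 41L) {
    sample(rep(3:6, c(12L, 19L, 9L, 1L)))
  } else {
    sample(3:6, n_subjects, replace = TRUE, prob = start_prior)
  }
  subjects <- vector("list", n_subjects)
  tables <- vector("list", n_subjects)
  bundles <- if (timeseries) vector("list", n_subjects) else NULL
  for (s in seq_len(n_subjects)) {
    set.seed(as.integer((as.numeric(seed) * 10007 + s) %% 2147483647))
    sp <- subject_spec(s, starts[s], params,
                       criterion_link = criterion_link,
                       gain_noise = gain_noise)
    tab <- generate_trial_table(sp)
    tab <- simulate_behavior(tab, params, sp)
    subjects[[s]] <- sp
    tables[[s]] <- tab
    if (timeseries) {
      bundles[[s]] <- simulate_timeseries(tab, truth, sp, hrf = hrf)
    }
  }
  structure(list(subjects = subjects,
                 trials = do.call(rbind, tables),
                 bundles = bundles, truth = truth, seed = seed),
            class = "wm_cohort")
}

#' @export
print.wm_cohort <- function(x, ...) {
  cat(sprintf("Synthetic WM cohort: %d subjects, %d trials%s\n",
              length(x$subjects), nrow(x$trials),
              if (is.null(x$bundles)) " (behavior only)" else
                sprintf(", %d-ROI timeseries", x$truth$n_rois)))
  st <- table(vapply(x$subjects, `[[`, 1L, "starting_set_size"))
  cat("  starting set sizes:",
      paste(names(st), as.integer(st), sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Write a cohort to disk as plain-text files
#'
#' Trial tables as TSV, per-run timeseries and confounds as TSV matrices
#' with a JSON sidecar (TR, volume and ROI counts), subject specs and
#' ground truth as JSON, plus a manifest carrying the master seed.
#'
#' @param cohort a \code{wm_cohort}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$trials, file.path(dir, "trials.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  specs <- lapply(cohort$subjects, function(s) s[names(s) != "class"])
  jsonlite::write_json(specs, file.path(dir, "subjects.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(cohort$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(cohort$bundles)) {
    for (s in seq_along(cohort$bundles)) {
      b <- cohort$bundles[[s]]
      for (r in seq_along(b$signal)) {
        utils::write.table(
          round(b$signal[[r]], 6),
          file.path(dir, sprintf("sub-%02d_run-%d_bold.tsv", s, r)),
          sep = "\t", row.names = FALSE, col.names = FALSE)
        utils::write.table(
          round(b$confounds[[r]], 6),
          file.path(dir, sprintf("sub-%02d_run-%d_confounds.tsv", s, r)),
          sep = "\t", row.names = FALSE, quote = FALSE)
      }
      jsonlite::write_json(
        list(tr = b$tr, n_volumes = b$n_vol, n_rois = ncol(b$signal[[1]])),
        file.path(dir, sprintf("sub-%02d_bold.json", s)), auto_unbox = TRUE)
    }
  }
  jsonlite::write_json(
    list(seed = cohort$seed, n_subjects = length(cohort$subjects),
         n_trials = nrow(cohort$trials)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Export trial events as a BIDS-style events table
#'
#' @param table a trial table.
#' @param run run number.
#' @return data.frame with \code{onset}, \code{duration},
#'   \code{trial_type}, \code{set_size}, \code{steps}, \code{level}.
#' @export
events_table <- function(table, run = 1L) {
  tt <- table[table$run == run, , drop = FALSE]
  do.call(rbind, lapply(seq_len(nrow(tt)), function(i) {
    data.frame(
      onset = c(tt$onset_array[i], tt$onset_delay[i], tt$onset_probe[i]),
      duration = c(3, 5, 4),
      trial_type = c("array", "delay", "probe"),
      set_size = tt$set_size[i], steps = tt$steps[i], level = tt$level[i])
  }))
}
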