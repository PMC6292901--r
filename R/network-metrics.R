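# Network summary statistics: within/between-network mean correlations,
# the segregation coefficient, the reconfiguration statistic across
# condition states, difficulty trends, and brain-behavior correlations.

# index helpers over a (maint, manip)-ordered square matrix
.part_index <- function(partition, n) {
  k <- length(partition$maintenance)
  stopifnot(n == 2L * k)
  list(maint = seq_len(k), manip = (k + 1L):(2L * k))
}

#' Within- and between-network mean correlations
#'
#' Signed means: within each network over the unordered node pairs (upper
#' triangle, diagonal excluded), between networks over all cross-network
#' pairs. Negative entries are included.
#'
#' @param mat symmetric connectivity matrix ordered maintenance nodes
#'   first, then manipulation nodes.
#' @param partition a \code{network_partition} (node counts).
#' @return named list \code{z_within_maint}, \code{z_within_manip},
#'   \code{z_between}.
#' @export
within_between_means <- function(mat, partition) {
  idx <- .part_index(partition, nrow(mat))
  if (length(idx$maint) < 2L) stop("no within-network pairs", call. = FALSE)
  wm_block <- mat[idx$maint, idx$maint]
  wp_block <- mat[idx$manip, idx$manip]
  bt_block <- mat[idx$maint, idx$manip]
  if (anyNA(wm_block[upper.tri(wm_block)]) || anyNA(bt_block)) {
    stop("missing connectivity entries", call. = FALSE)
  }
  list(z_within_maint = mean(wm_block[upper.tri(wm_block)]),
       z_within_manip = mean(wp_block[upper.tri(wp_block)]),
       z_between = mean(bt_block))
}

#' Network segregation coefficient
#'
#' \code{(z_within - z_between) / z_within}: 0 when within equals between,
#' 1 when between is zero, > 1 when between-network correlations are
#' negative.
#'
#' @param z_within mean within-network correlation (nonzero).
#' @param z_between mean between-network correlation.
#' @return the segregation coefficient.
#' @export
segregation <- function(z_within, z_between) {
  if (z_within == 0) {
    warning("z_within = 0: segregation undefined")
    return(NA_real_)
  }
  (z_within - z_between) / z_within
}

#' Node-level segregation, averaged per network
#'
#' For each node, (mean of its within-network edges - mean of its
#' between-network edges) / mean within-network edges; averaged over the
#' nodes of each network.
#'
#' @inheritParams within_between_means
#' @return list \code{maint}, \code{manip}.
#' @export
node_segregation <- function(mat, partition) {
  idx <- .part_index(partition, nrow(mat))
  per_node <- function(own, other) {
    vapply(own, function(i) {
      w <- mean(mat[i, setdiff(own, i)])
      b <- mean(mat[i, other])
      if (w == 0) NA_real_ else (w - b) / w
    }, numeric(1))
  }
  list(maint = mean(per_node(idx$maint, idx$manip), na.rm = TRUE),
       manip = mean(per_node(idx$manip, idx$maint), na.rm = TRUE))
}

#' Network reconfiguration across condition states
#'
#' One minus the mean pairwise state similarity over all ordered state
#' pairs: \code{1 - (1/(n(n-1))) * sum_{x != y} rho_xy}, where
#' \code{rho_xy} is the rank (Spearman) correlation between the two
#' states' connection profiles restricted to one connection subset
#' (within-maintenance, within-manipulation, or between-network entries).
#'
#' @param matrices list of >= 2 condition-level connectivity matrices
#'   (same node order, maintenance first).
#' @param partition a \code{network_partition}.
#' @param subset \code{"within_maintenance"}, \code{"within_manipulation"}
#'   or \code{"between"}.
#' @param method correlation type for state similarity.
#' @return list of class \code{reconfiguration_record}: \code{value},
#'   \code{n_states}, \code{similarities} (matrix), \code{subset}.
#' @export
reconfiguration <- function(matrices, partition,
                            subset = c("between", "within_maintenance",
                                       "within_manipulation"),
                            method = c("spearman", "pearson")) {
  subset <- match.arg(subset)
  method <- match.arg(method)
  n <- length(matrices)
  if (n < 2L) stop("need at least 2 states", call. = FALSE)
  idx <- .part_index(partition, nrow(matrices[[1]]))
  vec <- function(m) {
    switch(subset,
      within_maintenance = m[idx$maint, idx$maint][upper.tri(diag(length(idx$maint)))],
      within_manipulation = m[idx$manip, idx$manip][upper.tri(diag(length(idx$manip)))],
      between = as.numeric(m[idx$maint, idx$manip]))
  }
  V <- sapply(matrices, vec)
  if (any(apply(V, 2, stats::sd) == 0)) {
    warning("constant connection profile: state similarity undefined")
  }
  S <- stats::cor(V, method = method)
  val <- 1 - sum(S[row(S) != col(S)]) / (n * (n - 1))
  structure(list(value = val, n_states = n, similarities = S,
                 subset = subset, method = method),
            class = "reconfiguration_record")
}

#' @export
print.reconfiguration_record <- function(x, ...) {
  cat(sprintf("Reconfiguration (%s, %s, %d states): %.4f\n",
              x$subset, x$method, x$n_states, x$value))
  invisible(x)
}

#' Brain-behavior correlation and comparison of two correlations
#'
#' Pearson correlation between a per-subject network statistic and the
#' per-subject criterion, with a two-sided p; optionally compares two
#' correlations observed on the same sample via the Fisher r-to-z test
#' \code{z = (z1 - z2) / sqrt(2 / (n - 3))}.
#'
#' @param x per-subject statistic (e.g. between-network reconfiguration).
#' @param criterion per-subject criterion set size.
#' @param x2 optional second statistic to compare against.
#' @return list \code{r}, \code{p}, \code{n}, and if \code{x2} given:
#'   \code{r2}, \code{z_diff}, \code{p_diff}.
#' @export
behavior_correlation <- function(x, criterion, x2 = NULL) {
  n <- length(x)
  if (n < 4L) stop("need at least 4 subjects", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(criterion) == 0) {
    stop("zero variance input", call. = FALSE)
  }
  ct <- stats::cor.test(x, criterion)
  out <- list(r = unname(ct$estimate), p = ct$p.value, n = n)
  if (!is.null(x2)) {
    r2 <- stats::cor(x2, criterion)
    z <- (atanh(out$r) - atanh(r2)) / sqrt(2 / (n - 3))
    out$r2 <- r2
    out$z_diff <- z
    out$p_diff <- 2 * stats::pnorm(-abs(z))
  }
  out
}

#' Linear difficulty trend of a network metric
#'
#' Mixed model \code{metric ~ level + (1 | subject)} fitted by maximum
#' likelihood, tested against the intercept-only model by likelihood
#' ratio.
#'
#' @param df data.frame with columns \code{subject}, \code{level},
#'   \code{metric} (4 levels per subject).
#' @return list \code{chisq}, \code{p}, \code{slope}, \code{converged}.
#' @export
difficulty_trend <- function(df) {
  stopifnot(all(c("subject", "level", "metric") %in% names(df)))
  within_var <- stats::aggregate(metric ~ subject, df, stats::var)$metric
  if (all(within_var < 1e-24)) {
    # metric constant within every subject: no level effect estimable
    return(list(chisq = 0, p = 1, slope = 0, converged = TRUE))
  }
  fit_full <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(metric ~ level + (1 | subject), data = df, REML = FALSE))),
    error = function(e) e)
  if (inherits(fit_full, "condition")) {
    return(list(chisq = NA_real_, p = NA_real_, slope = NA_real_,
                converged = FALSE, message = conditionMessage(fit_full)))
  }
  fit_null <- suppressMessages(suppressWarnings(
    stats::update(fit_full, . ~ . - level)))
  lrt <- stats::anova(fit_null, fit_full)
  list(chisq = lrt$Chisq[2], p = lrt$`Pr(>Chisq)`[2],
       slope = unname(lme4::fixef(fit_full)["level"]), converged = TRUE)
}
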