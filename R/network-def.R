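# Network definition: equal-size maintenance and manipulation networks from
# the group parametric map, ROI-level conjunction, structural validation.

#' Select equal-size top-fraction networks
#'
#' Ranks ROIs by each effect's group z statistic and takes the top
#' \code{floor(fraction * n_rois)} ROIs per effect (5% of 471 gives the
#' 23-node networks). An ROI qualifying for both networks is assigned to
#' the effect with the larger z and the other network backfills with its
#' next-ranked ROI, so the sets stay disjoint and equal-sized. Ties are
#' broken by ascending ROI id.
#'
#' @param map a \code{parametric_map} (columns \code{roi}, \code{z_set},
#'   \code{z_steps}).
#' @param fraction fraction of ROIs per network, in (0, 0.2].
#' @return list of class \code{network_partition}: \code{maintenance},
#'   \code{manipulation} (ROI ids), \code{fraction}, \code{k}.
#' @export
select_top_nodes <- function(map, fraction = 0.05) {
  if (fraction <= 0 || fraction > 0.2) {
    stop("fraction must lie in (0, 0.2]", call. = FALSE)
  }
  nroi <- nrow(map)
  k <- floor(fraction * nroi)
  if (k < 1L) stop("fraction selects zero nodes", call. = FALSE)
  ord_set <- map$roi[order(-map$z_set, map$roi)]
  ord_steps <- map$roi[order(-map$z_steps, map$roi)]
  z_set <- stats::setNames(map$z_set, map$roi)
  z_steps <- stats::setNames(map$z_steps, map$roi)
  maint <- ord_set[seq_len(k)]
  manip <- ord_steps[seq_len(k)]
  overlap <- intersect(maint, manip)
  while (length(overlap) > 0L) {
    roi <- overlap[1L]
    if (z_set[as.character(roi)] >= z_steps[as.character(roi)]) {
      manip <- setdiff(manip, roi)
      pool <- setdiff(ord_steps, c(manip, maint))
      manip <- c(manip, pool[1L])
    } else {
      maint <- setdiff(maint, roi)
      pool <- setdiff(ord_set, c(maint, manip))
      maint <- c(maint, pool[1L])
    }
    overlap <- intersect(maint, manip)
  }
  structure(list(maintenance = sort(maint), manipulation = sort(manip),
                 fraction = fraction, k = k),
            class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat(sprintf("Network partition: %d + %d nodes (top %.0f%%)\n",
              length(x$maintenance), length(x$manipulation),
              100 * x$fraction))
  invisible(x)
}

#' ROI-level conjunction of the two parametric effects
#'
#' @param map a \code{parametric_map}.
#' @param threshold z threshold (> 0); an ROI is returned when both its
#'   effects exceed it.
#' @return integer vector of ROI ids.
#' @export
conjunction <- function(map, threshold = 2.576) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  map$roi[map$z_set > threshold & map$z_steps > threshold]
}

#' Structural validation of a partition
#'
#' Per-subject mean FA within each network and between networks, and a
#' paired t test (within vs between) per network across subjects.
#'
#' @param fa_list list of symmetric FA matrices (one per subject), indexed
#'   by the partition's node order (\code{c(maintenance, manipulation)}),
#'   or a single matrix.
#' @param partition a \code{network_partition} (only the node counts are
#'   used; matrices are assumed ordered maintenance-first).
#' @return list with per-subject \code{within_maint}, \code{within_manip},
#'   \code{between} means and (if > 1 subject) paired \code{t_maint},
#'   \code{t_manip}, \code{p_maint}, \code{p_manip}.
#' @export
validate_structure <- function(fa_list, partition) {
  if (is.matrix(fa_list)) fa_list <- list(fa_list)
  k <- length(partition$maintenance)
  n <- 2L * k
  wm <- wp <- bt <- numeric(length(fa_list))
  for (s in seq_along(fa_list)) {
    fa <- fa_list[[s]]
    if (nrow(fa) != n) stop("FA matrix does not match partition", call. = FALSE)
    im <- seq_len(k); ip <- (k + 1L):n
    wm[s] <- mean(fa[im, im][upper.tri(fa[im, im])], na.rm = TRUE)
    wp[s] <- mean(fa[ip, ip][upper.tri(fa[ip, ip])], na.rm = TRUE)
    bt[s] <- mean(fa[im, ip], na.rm = TRUE)
  }
  out <- list(within_maint = wm, within_manip = wp, between = bt)
  paired_t <- function(d) {
    if (stats::sd(d) == 0) {
      t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      return(list(t = t, p = if (t > 0) 0 else 1))
    }
    tt <- stats::t.test(d, alternative = "greater")
    list(t = unname(tt$statistic), p = tt$p.value)
  }
  if (length(fa_list) > 1L) {
    tm <- paired_t(wm - bt)
    tp <- paired_t(wp - bt)
    out$t_maint <- tm$t; out$p_maint <- tm$p
    out$t_manip <- tp$t; out$p_manip <- tp$p
  } else {
    out$t_maint <- out$t_manip <- NA_real_
    out$note <- "single subject: paired t undefined"
  }
  out
}
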