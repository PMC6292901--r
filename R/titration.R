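# Day-1 titration: adaptive staircase over set size, sigmoid psychometric
# fit with peripheral anchors, and derivation of the four individually
# titrated (relative) set-size levels.

#' Run the set-size staircase
#'
#' Simulates the screening staircase: after a correct response the set size
#' increases by 1; after an incorrect response it decreases by 2; sizes are
#' clamped to the stimulus range \code{[3, 9]}.
#'
#' @param true_psychometric a function mapping set size to probability
#'   correct in \code{[0, 1]}, or a named numeric vector indexed by set size.
#' @param n_trials number of staircase trials (default 150 = 6 blocks of 25).
#' @param start starting set size.
#' @return data.frame with columns \code{trial}, \code{set_size},
#'   \code{correct}.
#' @export
run_staircase <- function(true_psychometric, n_trials = 150L, start = 5L) {
  if (n_trials < 1L) stop("n_trials must be >= 1", call. = FALSE)
  pfun <- if (is.function(true_psychometric)) {
    true_psychometric
  } else {
    tab <- true_psychometric
    function(s) unname(tab[as.character(s)])
  }
  size <- as.integer(start)
  sizes <- integer(n_trials)
  correct <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    p <- pfun(size)
    if (!is.finite(p) || p < 0 || p > 1) {
      stop("psychometric function returned invalid probability at size ",
           size, call. = FALSE)
    }
    sizes[i] <- size
    correct[i] <- stats::runif(1) < p
    size <- if (correct[i]) size + 1L else size - 2L
    size <- max(3L, min(9L, size))
  }
  data.frame(trial = seq_len(n_trials), set_size = sizes, correct = correct)
}

#' Fit the sigmoid psychometric function
#'
#' Aggregated accuracy per set size is fitted with a two-parameter logistic
#' with fixed asymptotes 1.0 and 0.5:
#' \deqn{acc(s) = 0.5 + 0.5 / (1 + exp((s - m) / k)), k > 0,}
#' which decreases from 1 toward 0.5 as set size grows. Before fitting,
#' observed sizes with fewer than 10 trials are replaced by 0.50 accuracy,
#' and peripheral anchors are appended: sizes 1 and 2 at 100% accuracy and
#' sizes 10 and 11 at 50%. The criterion set size is the (continuous)
#' abscissa where the fitted curve equals 0.82.
#'
#' @param accuracy_by_size data.frame with columns \code{set_size},
#'   \code{n_trials}, \code{n_correct} (one row per observed size), or a
#'   staircase trace as returned by [run_staircase()].
#' @param criterion accuracy criterion (default 0.82).
#' @return object of class \code{psychometric_fit} with elements
#'   \code{midpoint}, \code{slope}, \code{criterion_set_size},
#'   \code{fit_points} and \code{criterion}.
#' @export
fit_psychometric <- function(accuracy_by_size, criterion = 0.82) {
  df <- accuracy_by_size
  if (all(c("set_size", "correct") %in% names(df)) && !"n_trials" %in% names(df)) {
    agg <- stats::aggregate(correct ~ set_size, data = df,
                            FUN = function(x) c(n = length(x), k = sum(x)))
    df <- data.frame(set_size = agg$set_size,
                     n_trials = agg$correct[, "n"],
                     n_correct = agg$correct[, "k"])
  }
  if (!all(c("set_size", "n_trials", "n_correct") %in% names(df))) {
    stop("need columns set_size, n_trials, n_correct", call. = FALSE)
  }
  if (nrow(df) < 2L) {
    stop("degenerate titration data: need at least 2 observed set sizes",
         call. = FALSE)
  }
  acc <- df$n_correct / df$n_trials
  # the largest set sizes are under-visited by the staircase; pin those
  # with fewer than 10 trials at chance-like 0.50 so the upper tail of the
  # curve is not driven by a handful of trials
  smax <- suppressWarnings(max(df$set_size[df$n_trials >= 10]))
  if (is.finite(smax)) acc[df$n_trials < 10 & df$set_size > smax] <- 0.5
  pts <- data.frame(set_size = df$set_size, accuracy = acc)
  anchors <- data.frame(set_size = c(1, 2, 10, 11),
                        accuracy = c(1, 1, 0.5, 0.5))
  pts <- rbind(pts[!pts$set_size %in% anchors$set_size, , drop = FALSE], anchors)
  pts <- pts[order(pts$set_size), ]

  curve_fun <- function(s, m, k) 0.5 + 0.5 / (1 + exp((s - m) / k))
  obj <- function(par) {
    m <- par[1]; k <- exp(par[2])
    sum((pts$accuracy - curve_fun(pts$set_size, m, k))^2)
  }
  fit <- stats::optim(c(m = 6, logk = 0), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  m <- unname(fit$par[1]); k <- exp(unname(fit$par[2]))
  # acc(c) = criterion  =>  c = m + k * log(0.5/(criterion - 0.5) - 1)
  cs <- m + k * log(0.5 / (criterion - 0.5) - 1)
  cs <- max(1, min(11, cs))
  structure(
    list(midpoint = m, slope = 1 / k, criterion = criterion,
         criterion_set_size = cs, fit_points = pts, sse = fit$value),
    class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("Psychometric fit (logistic, asymptotes 1.0 / 0.5)\n")
  cat(sprintf("  midpoint: %.3f  slope: %.3f /item\n", x$midpoint, x$slope))
  cat(sprintf("  criterion set size (acc = %.2f): %.3f\n",
              x$criterion, x$criterion_set_size))
  invisible(x)
}

#' @export
coef.psychometric_fit <- function(object, ...) {
  c(midpoint = object$midpoint, slope = object$slope,
    criterion_set_size = object$criterion_set_size)
}

#' Predicted accuracy at given set sizes
#' @param object a \code{psychometric_fit}.
#' @param newdata numeric vector of set sizes (default 3:9).
#' @param ... unused.
#' @export
predict.psychometric_fit <- function(object, newdata = 3:9, ...) {
  s <- as.numeric(newdata)
  0.5 + 0.5 / (1 + exp((s - object$midpoint) * object$slope))
}

#' Derive the four relative set-size levels
#'
#' The two integer set sizes whose fitted accuracy lies immediately above
#' the criterion become Very Easy and Easy; the next two sizes (fitted
#' accuracy below criterion) are Medium and Hard. The starting set size is
#' the Very Easy size, and the four levels are consecutive integers. The
#' starting size is clamped to \code{[3, 6]} so all four levels fit the
#' stimulus range.
#'
#' @param fit a \code{psychometric_fit}.
#' @return list with \code{starting_set_size} and \code{levels} (length-4
#'   integer vector mapped to relative levels 1--4).
#' @export
derive_levels <- function(fit) {
  sizes <- 3:9
  acc <- predict(fit, sizes)
  above <- sizes[acc > fit$criterion]
  if (length(above) == length(sizes) || fit$criterion_set_size > 9) {
    stop("fitted accuracy never falls below criterion on [3, 9]; ",
         "cannot titrate levels", call. = FALSE)
  }
  easy <- if (length(above)) max(above) else 3L
  start <- max(3L, min(6L, as.integer(easy) - 1L))
  list(starting_set_size = start, levels = start + 0:3)
}
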