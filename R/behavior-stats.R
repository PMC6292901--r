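# Trial-level behavioral mixed models: binomial logistic accuracy and
# linear RT (correct trials only), with relative set size, sorting steps
# and their interaction as fixed effects, subject random intercepts and
# uncorrelated random slopes, and likelihood-ratio tests per term.

.lrt_terms <- function(full, data, terms, fitter) {
  out <- list()
  for (tm in terms) {
    reduced <- tryCatch(
      suppressMessages(suppressWarnings(
        stats::update(full, stats::as.formula(paste(". ~ . -", tm))))),
      error = function(e) NULL)
    if (is.null(reduced)) {
      out[[tm]] <- c(chisq = NA_real_, p = NA_real_)
      next
    }
    lrt <- stats::anova(reduced, full)
    out[[tm]] <- c(chisq = lrt$Chisq[2], p = lrt$`Pr(>Chisq)`[2])
  }
  out
}

.model_report <- function(fit, lrt, model_type) {
  sm <- summary(fit)$coefficients
  structure(list(
    model = model_type,
    estimates = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    lrt = lrt,
    fit = fit), class = "wm_model_report")
}

#' @export
print.wm_model_report <- function(x, ...) {
  cat(sprintf("Trial-level %s mixed model\n", x$model))
  tab <- data.frame(estimate = round(x$estimates, 3),
                    se = round(x$se, 3))
  for (tm in names(x$lrt)) {
    row <- match(tm, rownames(tab))
    if (!is.na(row)) {
      tab$chisq[row] <- round(x$lrt[[tm]]["chisq"], 2)
      tab$p[row] <- signif(x$lrt[[tm]]["p"], 2)
    }
  }
  print(tab)
  invisible(x)
}

#' Fit the trial-level accuracy model
#'
#' Binomial logistic mixed model on all responded trials:
#' \code{correct ~ level * steps + (1 + level + steps || subject)}
#' (uncorrelated random effects), fitted by maximum likelihood
#' (\code{nAGQ = 0} for speed and stability), with likelihood-ratio tests
#' of each fixed term.
#'
#' @param trials cohort trial data.frame (columns \code{subject},
#'   \code{level}, \code{steps}, \code{correct}, \code{responded}).
#' @param lrt compute likelihood-ratio tests (slower).
#' @return a \code{wm_model_report}.
#' @export
fit_accuracy_model <- function(trials, lrt = TRUE) {
  df <- trials[trials$responded, , drop = FALSE]
  if (length(unique(df$subject)) < 2L) {
    stop("need at least 2 subjects", call. = FALSE)
  }
  full <- suppressMessages(suppressWarnings(
    lme4::glmer(correct ~ level * steps + (1 + level + steps || subject),
                data = df, family = stats::binomial, nAGQ = 0L)))
  tests <- if (lrt) {
    .lrt_terms(full, df, c("level", "steps", "level:steps"))
  } else list()
  .model_report(full, tests, "accuracy (logistic)")
}

#' Fit the trial-level RT model
#'
#' Linear mixed model on correct responded trials with the same fixed and
#' random structure as the accuracy model. Estimates are reported from the
#' ML fit used for likelihood-ratio tests.
#'
#' @inheritParams fit_accuracy_model
#' @return a \code{wm_model_report}.
#' @export
fit_rt_model <- function(trials, lrt = TRUE) {
  df <- trials[trials$responded & trials$correct, , drop = FALSE]
  if (length(unique(df$subject)) < 2L) {
    stop("need at least 2 subjects", call. = FALSE)
  }
  full <- suppressMessages(suppressWarnings(
    lme4::lmer(rt ~ level * steps + (1 + level + steps || subject),
               data = df, REML = FALSE)))
  tests <- if (lrt) {
    .lrt_terms(full, df, c("level", "steps", "level:steps"))
  } else list()
  .model_report(full, tests, "RT (linear)")
}
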