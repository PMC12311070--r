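#' Root mean square error
#' @param estimated,truth equal-length numeric vectors.
#' @return `sqrt(mean((estimated - truth)^2))`.
#' @export
rmse <- function(estimated, truth) {
  if (length(estimated) == 0L || length(estimated) != length(truth))
    stop("`estimated` and `truth` must be nonempty and of equal length",
         call. = FALSE)
  sqrt(mean((estimated - truth)^2))
}

#' Coefficient of determination from OLS regression
#'
#' R-squared of the ordinary least-squares fit (with intercept) of
#' `estimated` on `truth`.
#'
#' @param estimated,truth numeric vectors, length >= 3; `truth` must not be
#'   constant.
#' @return scalar in \[0, 1\].
#' @export
r_squared <- function(estimated, truth) {
  if (length(estimated) != length(truth) || length(truth) < 3L)
    stop("need >= 3 paired points", call. = FALSE)
  if (stats::sd(truth) == 0)
    stop("undefined fit: `truth` is constant", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, truth), estimated)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((estimated - mean(estimated))^2)
  if (ss_tot == 0) return(1)
  1 - ss_res / ss_tot
}

#' Bland-Altman agreement statistics
#'
#' Differences are oriented `truth - estimated`; the limits of agreement are
#' `bias +/- 1.96 * SD(d)` (sample SD, n - 1).
#'
#' @param estimated,truth equal-length numeric vectors (n >= 2).
#' @return named numeric: `bias`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(estimated, truth) {
  if (length(estimated) != length(truth) || length(truth) < 2L)
    stop("`estimated` and `truth` must have equal length >= 2", call. = FALSE)
  d <- truth - estimated
  bias <- mean(d)
  s <- stats::sd(d)
  c(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' Summarize a benchmark run
#'
#' Per method x noise level x parameter: RMSE, R-squared and Bland-Altman
#' statistics of the recovered motion parameters, plus (when both methods are
#' present) the percent change in RMSE of TCBC relative to the NMI baseline
#' (positive = TCBC lower).
#'
#' @param results data.frame from [run_benchmark()].
#' @param min_trials minimum successful trials per cell; cells with fewer are
#'   flagged (`flagged = TRUE`, metrics NA) rather than failing.
#' @return list with `metrics` (long data.frame) and `rmse_change_pct`
#'   (data.frame, present when both methods occur).
#' @export
summarize_benchmark <- function(results, min_trials = 3L) {
  pnames <- c("tx", "ty", "tz", "rx", "ry", "rz")
  cells <- unique(results[, c("method", "duration_s")])
  out <- list()
  for (r in seq_len(nrow(cells))) {
    method <- cells$method[r]; dur <- cells$duration_s[r]
    sub <- results[results$method == method & results$duration_s == dur, ]
    sub <- sub[stats::complete.cases(sub[, paste0("est_", pnames)]), ]
    for (p in pnames) {
      est <- sub[[paste0("est_", p)]]
      tru <- sub[[paste0("true_", p)]]
      flagged <- nrow(sub) < min_trials
      ba <- if (flagged) c(bias = NA_real_, loa_low = NA_real_,
                           loa_high = NA_real_) else bland_altman(est, tru)
      out[[length(out) + 1L]] <- data.frame(
        method = method, duration_s = dur, param = p, n = nrow(sub),
        rmse = if (flagged) NA_real_ else rmse(est, tru),
        r_squared = if (flagged) NA_real_ else r_squared(est, tru),
        bias = ba[["bias"]], loa_low = ba[["loa_low"]],
        loa_high = ba[["loa_high"]], flagged = flagged,
        stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, out)
  res <- list(metrics = metrics)
  if (all(c("tcbc", "nmi") %in% metrics$method)) {
    ch <- list()
    for (dur in unique(metrics$duration_s)) {
      for (p in pnames) {
        a <- metrics[metrics$method == "tcbc" & metrics$duration_s == dur &
                       metrics$param == p, "rmse"]
        b <- metrics[metrics$method == "nmi" & metrics$duration_s == dur &
                       metrics$param == p, "rmse"]
        if (length(a) == 1L && length(b) == 1L)
          ch[[length(ch) + 1L]] <- data.frame(
            duration_s = dur, param = p, rmse_tcbc = a, rmse_baseline = b,
            change_pct = 100 * (b - a) / b, stringsAsFactors = FALSE)
      }
    }
    res$rmse_change_pct <- do.call(rbind, ch)
  }
  res
}
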