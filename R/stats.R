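#' Performance error of a TCI model (PE, MDPE, MDAPE)
#'
#' The per-sample performance error is
#' `PE = (Cm - Cp) / Cp * 100` (percent), with `Cm` the measured and `Cp`
#' the model-predicted brain concentration. MDPE (the median PE) measures
#' bias, MDAPE (the median absolute PE) precision. The 95% confidence
#' interval for MDPE is a seeded percentile bootstrap.
#'
#' @param measured,predicted equal-length concentration vectors;
#'   `predicted` must be strictly positive.
#' @param n_boot bootstrap resamples for the MDPE interval (default 10000).
#' @param seed bootstrap RNG seed.
#' @param conf confidence level (default 0.95).
#' @return An object of class `tci_performance`: `pe` (percent), `mdpe`,
#'   `mdape`, `mdpe_ci95` (length-2 vector).
#' @examples
#' performance_errors(measured = c(10.9, 9.8, 10.2), predicted = rep(10, 3))
#' @export
performance_errors <- function(measured, predicted, n_boot = 10000,
                               seed = 1, conf = 0.95) {
  if (length(measured) != length(predicted))
    stop("measured and predicted must have equal length")
  if (any(!is.finite(predicted)) || any(predicted <= 0))
    stop("predicted concentrations must be strictly positive")
  pe <- (measured - predicted) / predicted * 100
  boot <- with_seed(seed, {
    idx <- matrix(sample.int(length(pe), length(pe) * n_boot, replace = TRUE),
                  nrow = n_boot)
    apply(idx, 1, function(i) median(pe[i]))
  })
  a <- (1 - conf) / 2
  structure(list(pe = pe, mdpe = median(pe), mdape = median(abs(pe)),
                 mdpe_ci95 = unname(quantile(boot, c(a, 1 - a)))),
            class = "tci_performance")
}

#' @export
print.tci_performance <- function(x, ...) {
  cat(sprintf("MDPE %.2f%% [%.2f%%, %.2f%%], MDAPE %.2f%% (n = %d)\n",
              x$mdpe, x$mdpe_ci95[1], x$mdpe_ci95[2], x$mdape,
              length(x$pe)))
  invisible(x)
}

#' Concentration drift: best-fit slope and its standard error
#'
#' Fits the least-squares line to concentration versus time and reports its
#' slope `b` with a standard error and 95% interval `b +/- 1.96 se`. The
#' default `se_method = "literal"` uses
#' `se = sqrt( S(c) / ((n-2) S(t)) )` with `S(x) = sum((x - mean(x))^2)`,
#' i.e. the total (not residual) sum of squares of the concentrations in
#' the numerator; `"ols"` gives the textbook slope standard error with the
#' residual sum of squares instead. The two coincide only when the fitted
#' slope is zero.
#'
#' @param times sample times (seconds), not all equal, `n >= 3`.
#' @param concentrations concentrations at `times`.
#' @param se_method `"literal"` (default) or `"ols"`.
#' @return An object of class `drift_report`: `slope` (concentration per
#'   second), `intercept`, `se`, `ci95`, `n`, `se_method`.
#' @export
drift_slope <- function(times, concentrations,
                        se_method = c("literal", "ols")) {
  se_method <- match.arg(se_method)
  n <- length(times)
  if (n < 3L || length(concentrations) != n)
    stop("need at least 3 paired (time, concentration) samples")
  St <- sum((times - mean(times))^2)
  if (St == 0) stop("all sample times are equal: slope is undefined")
  b <- sum((times - mean(times)) * (concentrations - mean(concentrations))) /
    St
  a <- mean(concentrations) - b * mean(times)
  se <- if (se_method == "literal") {
    sqrt(sum((concentrations - mean(concentrations))^2) / ((n - 2) * St))
  } else {
    resid <- concentrations - (a + b * times)
    sqrt(sum(resid^2) / ((n - 2) * St))
  }
  structure(list(slope = b, intercept = a, se = se,
                 ci95 = c(b - 1.96 * se, b + 1.96 * se), n = n,
                 se_method = se_method),
            class = "drift_report")
}

#' @export
print.drift_report <- function(x, ...) {
  cat(sprintf("drift slope %.3g per s (se %.3g, 95%% CI [%.3g, %.3g], n=%d)\n",
              x$slope, x$se, x$ci95[1], x$ci95[2], x$n))
  invisible(x)
}

#' Ljung-Box portmanteau test for residual autocorrelation
#'
#' Computes `Q = n (n+2) sum_{j=1}^{L} rho_j^2 / (n - j)` from the sample
#' autocorrelations of the residual series and refers it to a chi-square
#' distribution with `L` degrees of freedom. Implemented from the formula;
#' the test suite validates it against an independent reference.
#'
#' @param residuals residual series; must have positive variance.
#' @param lags number of autocorrelation lags `L`
#'   (default `min(10, floor(n/5))`).
#' @return List with `statistic` (Q), `lags` and `p.value`.
#' @export
ljung_box <- function(residuals, lags = NULL) {
  n <- length(residuals)
  if (is.null(lags)) lags <- max(1L, min(10L, floor(n / 5)))
  if (lags < 1L || n <= lags)
    stop("need n > lags >= 1")
  if (sd(residuals) == 0)
    stop("residuals have zero variance: autocorrelations are undefined")
  rho <- acf(residuals, lag.max = lags, plot = FALSE)$acf[-1]
  q <- n * (n + 2) * sum(rho^2 / (n - seq_len(lags)))
  list(statistic = q, lags = lags,
       p.value = pchisq(q, df = lags, lower.tail = FALSE))
}

# two-sided rank-sum p-value; exact permutation enumeration (midranks, so
# ties are handled) for combined n <= 20, normal approximation with tie
# correction otherwise
rank_sum_test <- function(x, y) {
  m <- length(x); n <- length(y)
  if (m < 1L || n < 1L) stop("both groups must be nonempty")
  if (m + n <= 20L) {
    r <- rank(c(x, y))
    w_obs <- sum(r[seq_len(m)])
    sets <- utils::combn(m + n, m)
    w_all <- colSums(matrix(r[sets], nrow = m))
    center <- m * (m + n + 1) / 2
    mean(abs(w_all - center) >= abs(w_obs - center) - 1e-9)
  } else {
    suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
  }
}

#' Early-versus-late window comparison of infusion stability
#'
#' Nonparametric (Wilcoxon rank-sum) comparison of the concentrations
#' sampled during the first and the final window of an infusion — by
#' default the first and last 20 minutes of a one-hour infusion. The exact
#' permutation distribution is enumerated when the combined sample count is
#' at most 20; larger samples use the normal approximation with tie
#' correction.
#'
#' @param times sample times in seconds.
#' @param concentrations concentrations at `times`.
#' @param window window length in seconds (default 1200).
#' @param total infusion duration in seconds (default 3600).
#' @return Two-sided p-value.
#' @export
window_comparison <- function(times, concentrations, window = 1200,
                              total = 3600) {
  stopifnot(length(times) == length(concentrations), window > 0,
            total >= 2 * window)
  first <- concentrations[times <= window]
  last <- concentrations[times >= total - window & times <= total]
  if (length(first) < 1L || length(last) < 1L)
    stop("each window must contain at least one sample")
  rank_sum_test(first, last)
}

#' Target-normalized moving mean and standard deviation
#'
#' Normalizes measured concentrations by the target, sorts samples by time,
#' and summarizes them in sliding windows of `window` consecutive samples
#' stepped by `step` samples. Each window is reported at its median sample
#' time. A moving mean of 1 means the measurements sit on target.
#'
#' @param times sample times in seconds.
#' @param concentrations measured concentrations.
#' @param target targeted concentration (> 0).
#' @param window window length in samples (default 10).
#' @param step window step in samples (default 1).
#' @return Data frame `time_s, mean, sd`, one row per window.
#' @export
normalized_moving_stats <- function(times, concentrations, target,
                                    window = 10, step = 1) {
  n <- length(times)
  stopifnot(length(concentrations) == n, window >= 2, step >= 1)
  if (!is.finite(target) || target <= 0)
    stop("target must be positive")
  if (n < window)
    stop("fewer samples than the window length")
  ord <- order(times)
  tt <- times[ord]
  z <- concentrations[ord] / target
  starts <- seq.int(1L, n - window + 1L, by = step)
  data.frame(
    time_s = vapply(starts, function(i) median(tt[i:(i + window - 1L)]),
                    numeric(1)),
    mean = vapply(starts, function(i) mean(z[i:(i + window - 1L)]),
                  numeric(1)),
    sd = vapply(starts, function(i) sd(z[i:(i + window - 1L)]), numeric(1)))
}

#' Validation report for a TCI session
#'
#' Bundles the stability diagnostics for one validation data set: MDPE /
#' MDAPE with bootstrap interval, drift slope with interval, Ljung-Box
#' residual autocorrelation, and the first-versus-last window rank-sum
#' test.
#'
#' @param times sample times (seconds).
#' @param measured measured brain concentrations.
#' @param predicted model-predicted brain concentrations at `times`.
#' @param total infusion duration in seconds (default 3600).
#' @param window window length for the early/late comparison (default 1200).
#' @param seed bootstrap seed.
#' @return A list with components `performance`, `drift`, `ljung_box`,
#'   `window_test_p`.
#' @export
validation_report <- function(times, measured, predicted, total = 3600,
                              window = 1200, seed = 1) {
  perf <- performance_errors(measured, predicted, seed = seed)
  list(performance = perf,
       drift = drift_slope(times, measured),
       ljung_box = ljung_box(measured - predicted),
       window_test_p = window_comparison(times, measured, window = window,
                                         total = total))
}

#' @rdname validation_report
#' @param report a list from `validation_report`.
#' @param path JSON output path.
#' @export
write_validation_report <- function(report, path) {
  out <- list(
    mdpe = report$performance$mdpe,
    mdape = report$performance$mdape,
    mdpe_ci95 = report$performance$mdpe_ci95,
    slope = report$drift$slope,
    slope_ci95 = report$drift$ci95,
    ljung_box = list(Q = report$ljung_box$statistic,
                     p = report$ljung_box$p.value),
    window_test_p = report$window_test_p)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
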