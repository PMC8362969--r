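# Augmented Dickey-Fuller unit-root screening, per areal unit, with a
# regional acceptance-rate summary.
#
# The test regression includes a constant and no deterministic trend:
#   diff(x)_t = c + gamma * x_{t-1} + sum_j phi_j * diff(x)_{t-j} + e_t
# The null of a unit root corresponds to gamma = 0; the statistic is the
# t-ratio of gamma and its p-value comes from the MacKinnon (1994)
# response-surface approximation for the constant-only case.

# MacKinnon (1994) response-surface coefficients, one-variable, constant,
# no trend. p = Phi(c0 + c1*s + c2*s^2 [+ c3*s^3]).
MACKINNON_C <- list(
  smallp = c(2.1659, 1.4412, 0.038269),
  largep = c(1.7339, 0.93202, -0.12745, -0.010368),
  star = -1.61, min = -18.83, max = 2.74)

mackinnon_pvalue <- function(stat) {
  if (stat <= MACKINNON_C$min) return(0)
  if (stat >= MACKINNON_C$max) return(1)
  co <- if (stat <= MACKINNON_C$star) MACKINNON_C$smallp else MACKINNON_C$largep
  stats::pnorm(sum(co * stat^(seq_along(co) - 1L)))
}

adf_regression <- function(x, p, n_used) {
  # regression rows are the last n_used differences; p lagged differences
  dx <- diff(x)
  rows <- seq.int(length(dx) - n_used + 1L, length(dx))
  X <- cbind(const = 1, lag1 = x[rows])        # x_{t-1} aligned with dx_t
  if (p > 0) {
    for (j in seq_len(p)) X <- cbind(X, dx[rows - j])
  }
  y <- dx[rows]
  # deterministic series can make the lagged differences collinear; such a
  # lag order is unusable
  XtXinv <- tryCatch(chol2inv(chol(crossprod(X))), error = function(e) NULL)
  if (is.null(XtXinv)) return(NULL)
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  k <- ncol(X)
  sigma2 <- rss / (n_used - k)
  se_gamma <- sqrt(sigma2 * XtXinv[2L, 2L])
  list(stat = fit$coefficients[[2L]] / se_gamma, rss = rss, k = k,
       aic = n_used * log(rss / n_used) + 2 * k)
}

#' Augmented Dickey-Fuller test for a unit root
#'
#' Fits the ADF regression with a constant (no trend); the lag order is
#' chosen by AIC over `0..max_lags` on a common estimation sample, then the
#' selected regression is refitted on the longest sample that lag order
#' allows. The p-value uses the MacKinnon (1994) response-surface
#' approximation. Small p-values reject the unit root, i.e. indicate a
#' stationary series.
#'
#' @param series Numeric time series (a plain vector).
#' @param max_lags Maximum number of lagged differences considered
#'   (default 4, suited to short monthly panels).
#' @param alpha Significance level for the `stationary` verdict
#'   (default 0.05).
#' @return Object of class `adf_result`: `statistic`, `p_value`, `lags`,
#'   `stationary`, `alpha`, `n`.
#' @export
#' @examples
#' set.seed(1)
#' adf_test(rnorm(200))$stationary       # white noise: TRUE
#' adf_test(cumsum(rnorm(200)))$p_value  # random walk: large
adf_test <- function(series, max_lags = 4L, alpha = 0.05) {
  series <- as.numeric(series)
  if (any(!is.finite(series))) {
    stop_gtwr("series contains non-finite values", class = "gtwr_domain_error")
  }
  n <- length(series)
  if (n < max_lags + 10L) {
    stop_gtwr("series too short for ADF with max_lags = ", max_lags,
              class = "gtwr_domain_error")
  }
  if (stats::sd(series) == 0) {
    stop_gtwr("constant series: ADF test undefined",
              class = "gtwr_degenerate_series")
  }
  # lag selection on the common sample all candidates can use; singular
  # lag orders (collinear lagged differences) are excluded
  n_common <- n - 1L - max_lags
  aics <- vapply(0:max_lags, function(p) {
    reg <- adf_regression(series, p, n_common)
    if (is.null(reg)) Inf else reg$aic
  }, numeric(1))
  if (all(is.infinite(aics))) {
    stop_gtwr("ADF regression singular at every lag order",
              class = "gtwr_degenerate_series")
  }
  p_sel <- (0:max_lags)[which.min(aics)]
  final <- adf_regression(series, p_sel, n - 1L - p_sel)
  if (is.null(final)) {
    stop_gtwr("ADF regression singular at the selected lag order",
              class = "gtwr_degenerate_series")
  }
  pval <- mackinnon_pvalue(final$stat)
  structure(list(statistic = final$stat, p_value = pval, lags = p_sel,
                 stationary = pval < alpha, alpha = alpha, n = n),
            class = "adf_result")
}

#' @export
print.adf_result <- function(x, ...) {
  cat(sprintf("ADF statistic %.3f (lags %d), p = %.4f: %s\n",
              x$statistic, x$lags, x$p_value,
              if (x$stationary) "stationary" else "unit root not rejected"))
  invisible(x)
}

#' Regional summary of per-unit ADF results
#'
#' Summarizes a set of per-unit ADF tests for one variable: the range of
#' statistics and the share of units that fail to reject the unit root
#' (`accept_rate`). When the majority of units accept the null the regional
#' verdict is `nonstationary`.
#'
#' @param results List of `adf_result` objects (one per areal unit).
#' @param alpha Significance level (default 0.05).
#' @param variable Variable name carried into the summary.
#' @param verdict_threshold Acceptance share (percent) above which the
#'   verdict is `nonstationary` (default 50).
#' @return Object of class `regional_stationarity`: a one-row `data.frame`
#'   with `variable`, `min_stat`, `median_stat`, `max_stat`, `accept_rate`,
#'   `verdict`.
#' @export
regional_summary <- function(results, alpha = 0.05, variable = "value",
                             verdict_threshold = 50) {
  if (length(results) == 0L) {
    stop_gtwr("no ADF results supplied", class = "gtwr_domain_error")
  }
  stopifnot(all(vapply(results, inherits, logical(1), "adf_result")))
  stat <- vapply(results, `[[`, numeric(1), "statistic")
  pv <- vapply(results, `[[`, numeric(1), "p_value")
  accept <- 100 * mean(pv >= alpha)
  out <- data.frame(variable = variable,
                    min_stat = min(stat), median_stat = stats::median(stat),
                    max_stat = max(stat), accept_rate = accept,
                    verdict = if (accept > verdict_threshold) "nonstationary"
                              else "stationary",
                    stringsAsFactors = FALSE)
  class(out) <- c("regional_stationarity", class(out))
  out
}

#' ADF screen of panel variables
#'
#' Runs [adf_test()] on every unit's time series for each named variable
#' and assembles the per-variable regional summaries (the shape of a
#' stationarity screening table: statistic range, acceptance share,
#' verdict).
#'
#' @param panel Panel `data.frame` with `unit_id`, `t` and the variables.
#' @param variables Character vector of column names to screen.
#' @param max_lags,alpha Passed to [adf_test()].
#' @return `data.frame` with one row per variable.
#' @export
adf_screen <- function(panel, variables, max_lags = 4L, alpha = 0.05) {
  stopifnot(all(c("unit_id", "t") %in% names(panel)),
            all(variables %in% names(panel)))
  if (length(variables) == 0L) {
    return(data.frame(variable = character(), min_stat = numeric(),
                      median_stat = numeric(), max_stat = numeric(),
                      accept_rate = numeric(), verdict = character()))
  }
  panel <- panel[order(panel$unit_id, panel$t), , drop = FALSE]
  out <- lapply(variables, function(v) {
    res <- lapply(split(panel[[v]], panel$unit_id), function(x) {
      tryCatch(adf_test(x, max_lags = max_lags, alpha = alpha),
               gtwr_degenerate_series = function(e) NULL)
    })
    res <- Filter(Negate(is.null), res)
    if (length(res) == 0L) {
      stop_gtwr("all unit series for '", v, "' are degenerate",
                class = "gtwr_degenerate_series")
    }
    regional_summary(res, alpha = alpha, variable = v)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
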