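# OLS, GWR and GTWR estimation with Gaussian space-time kernel weights.
#
# GTWR solves, at every record i, the weighted least-squares problem
#   beta(u_i, v_i, t_i) = (X' W_i X)^{-1} X' W_i y
# with diagonal weights W_i built from the combined squared space-time
# distance d2 = (u_i-u_j)^2 + (v_i-v_j)^2 + tau * (t_i-t_j)^2 through the
# Gaussian kernel w = exp(-d2 / h^2). tau is the temporal-to-spatial scale
# ratio (mu/lambda with lambda fixed at 1); tau = 0 gives purely spatial
# (GWR) weights.

#' Space-time kernel specification
#'
#' @param bandwidth Kernel bandwidth `h` (> 0), in the projected coordinate
#'   units.
#' @param tau Temporal-to-spatial scale ratio (>= 0); `tau = 0` ignores
#'   time.
#' @param kernel Kernel family; only `"gaussian"` is implemented.
#' @return Object of class `kernel_spec`.
#' @export
kernel_spec <- function(bandwidth, tau = 0, kernel = "gaussian") {
  stopifnot(is.numeric(bandwidth), length(bandwidth) == 1L)
  if (bandwidth <= 0) stop_gtwr("bandwidth must be > 0", class = "gtwr_domain_error")
  if (tau < 0) stop_gtwr("tau must be >= 0", class = "gtwr_domain_error")
  kernel <- match.arg(kernel, "gaussian")
  structure(list(bandwidth = bandwidth, tau = tau, kernel = kernel),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("gaussian space-time kernel: h = %.6g, tau = %.6g\n",
              x$bandwidth, x$tau))
  invisible(x)
}

#' Combined squared space-time distance
#'
#' `d2 = (u_i - u_j)^2 + (v_i - v_j)^2 + tau * (t_i - t_j)^2`.
#'
#' @param a,b Numeric length-3 vectors `(u, v, t)`.
#' @param tau Temporal-to-spatial scale ratio (>= 0).
#' @return Squared combined distance.
#' @export
squared_st_distance <- function(a, b, tau) {
  stopifnot(length(a) == 3L, length(b) == 3L, all(is.finite(c(a, b))))
  if (tau < 0) stop_gtwr("tau must be >= 0", class = "gtwr_domain_error")
  (a[1] - b[1])^2 + (a[2] - b[2])^2 + tau * (a[3] - b[3])^2
}

#' Gaussian kernel weight
#'
#' `exp(-d2 / h^2)` for squared distance `d2` and bandwidth `h`; equals 1 at
#' zero distance and decays monotonically.
#'
#' @param sq_dist Squared distance(s), >= 0.
#' @param h Bandwidth, > 0.
#' @return Weight(s) in (0, 1].
#' @export
kernel_weight <- function(sq_dist, h) {
  if (any(sq_dist < 0)) stop_gtwr("squared distance must be >= 0",
                                  class = "gtwr_domain_error")
  if (h <= 0) stop_gtwr("bandwidth must be > 0", class = "gtwr_domain_error")
  exp(-sq_dist / h^2)
}

#' Corrected Akaike information criterion for local regression
#'
#' The small-sample AICc with the hat-matrix trace as the effective number
#' of parameters:
#' `n*log(rss/n) + n*log(2*pi) + n*(n + trace_S)/(n - 2 - trace_S)`.
#'
#' @param n Number of observations.
#' @param rss Residual sum of squares.
#' @param trace_S Trace of the hat matrix.
#' @return AICc value.
#' @export
aicc <- function(n, rss, trace_S) {
  stopifnot(n >= 1, rss >= 0, trace_S >= 0)
  if (n <= trace_S + 2) {
    stop_gtwr("overfit: n must exceed trace_S + 2", class = "gtwr_overfit")
  }
  n * log(rss / n) + n * log(2 * pi) + n * (n + trace_S) / (n - 2 - trace_S)
}

# ---- panel plumbing ---------------------------------------------------------

validate_panel <- function(panel, response, covariates) {
  need <- c("unit_id", "u", "v", "t", response, covariates)
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols) > 0L) {
    stop_gtwr("panel is missing column(s): ", paste(missing_cols, collapse = ", "),
              class = "gtwr_config_error")
  }
  if (anyDuplicated(panel[c("unit_id", "t")])) {
    stop_gtwr("duplicate (unit_id, t) records in panel", class = "gtwr_config_error")
  }
  vals <- panel[, c("u", "v", "t", response, covariates), drop = FALSE]
  if (any(!is.finite(as.matrix(vals)))) {
    stop_gtwr("panel contains non-finite values", class = "gtwr_config_error")
  }
  coord_sd <- tapply(panel$u + panel$v, panel$unit_id,
                     function(x) max(x) - min(x))
  if (any(coord_sd > 0)) {
    stop_gtwr("coordinates vary within a unit", class = "gtwr_config_error")
  }
  invisible(panel)
}

design_matrix <- function(panel, covariates) {
  X <- cbind(1, as.matrix(panel[, covariates, drop = FALSE]))
  colnames(X) <- c("(Intercept)", covariates)
  X
}

gtwr_prepare <- function(panel, response, covariates) {
  validate_panel(panel, response, covariates)
  X <- design_matrix(panel, covariates)
  list(X = X, y = panel[[response]], u = panel$u, v = panel$v, t = panel$t,
       panel = panel)
}

# Core local-fitting loop. Returns coefficients, hat diagonal, fitted values
# and leave-one-out predictions (weights with W_ii = 0, via rank-one
# downdate of the local normal equations). Distances are formed per
# regression point; no n x n matrix is materialized.
gtwr_core <- function(X, y, u, v, tvec, h, tau, cond_tol = 1e10) {
  n <- nrow(X); p <- ncol(X)
  h2 <- h * h
  B <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(X)))
  hat <- fitted <- loo <- numeric(n)
  n_ridge <- 0L
  for (i in seq_len(n)) {
    d2 <- (u - u[i])^2 + (v - v[i])^2
    if (tau > 0) d2 <- d2 + tau * (tvec - tvec[i])^2
    w <- exp(-d2 / h2)
    Xw <- X * w
    A <- crossprod(Xw, X)
    if (rcond(A) < 1 / cond_tol) {
      A <- A + diag(1e-8 * sum(diag(A)), p)
      n_ridge <- n_ridge + 1L
    }
    sol <- solve(A, cbind(crossprod(Xw, y), X[i, ]))
    beta <- sol[, 1L]
    g <- sol[, 2L]                      # A^{-1} x_i
    B[i, ] <- beta
    fitted[i] <- sum(X[i, ] * beta)
    q <- w[i] * sum(X[i, ] * g)         # hat value s_ii
    hat[i] <- q
    loo[i] <- if (q < 1 - 1e-10) (fitted[i] - q * y[i]) / (1 - q) else NA_real_
  }
  if (n_ridge > 0L) {
    warning(sprintf("%d near-singular local system(s) stabilised with a ridge term", n_ridge))
  }
  list(coefficients = B, fitted = fitted, hat = hat, loo = loo,
       n_ridge = n_ridge)
}

finish_local_fit <- function(core, X, y, model, spec, covariates, panel) {
  n <- length(y)
  resid <- y - core$fitted
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  trace_S <- sum(core$hat)
  aicc_val <- tryCatch(aicc(n, rss, trace_S), gtwr_overfit = function(e) {
    warning("effective parameters too close to n; AICc undefined")
    NA_real_
  })
  cv <- if (any(is.na(core$loo))) NA_real_ else sum((y - core$loo)^2)
  structure(
    list(model = model, spec = spec, covariates = covariates,
         coefficients = core$coefficients, fitted = core$fitted,
         residuals = resid, hat = core$hat, loo_predictions = core$loo,
         trace_S = trace_S, r_squared = 1 - rss / tss, rss = rss,
         aicc = aicc_val, cv_score = cv, n = n,
         unit_id = panel$unit_id, t = panel$t, n_ridge = core$n_ridge),
    class = "gtwr_fit")
}

#' @export
print.gtwr_fit <- function(x, ...) {
  cat(sprintf("%s fit: n = %d, trace(S) = %.2f, R2 = %.4f, AICc = %.2f, CV = %.4g\n",
              toupper(x$model), x$n, x$trace_S, x$r_squared, x$aicc, x$cv_score))
  cat("mean local coefficients:\n")
  print(colMeans(x$coefficients))
  invisible(x)
}

# ---- global OLS -------------------------------------------------------------

#' Global ordinary least squares fit of a panel
#'
#' The pooled (space- and time-constant) benchmark model. Residuals are
#' retained for the Moran's I screen.
#'
#' @param panel Panel `data.frame` with `unit_id`, `u`, `v`, `t` and the
#'   model columns.
#' @param response Name of the response column (log scale).
#' @param covariates Character vector of covariate column names.
#' @return Object of class `ols_fit`: coefficients, standard errors,
#'   `r_squared`, `aic`, `aicc`, residuals, fitted values.
#' @export
fit_ols <- function(panel, response, covariates) {
  validate_panel(panel, response, covariates)
  X <- design_matrix(panel, covariates)
  y <- panel[[response]]
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    bad <- colnames(X)[qr_X$pivot[seq.int(qr_X$rank + 1L, ncol(X))]]
    stop_gtwr("design matrix is rank deficient; collinear column(s): ",
              paste(bad, collapse = ", "), class = "gtwr_rank_deficient")
  }
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop_gtwr("need n > k + 1 observations", class = "gtwr_domain_error")
  beta <- qr.coef(qr_X, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - p)
  se <- sqrt(sigma2 * diag(chol2inv(qr.R(qr_X))))
  names(se) <- colnames(X)
  # gaussian log-likelihood AIC (p + 1 parameters incl. the error variance)
  aic <- n * log(2 * pi * rss / n) + n + 2 * (p + 1)
  structure(
    list(model = "ols", coefficients = beta, se = se, fitted = fitted,
         residuals = resid, r_squared = 1 - rss / tss, rss = rss,
         aic = aic, aicc = aicc(n, rss, p), trace_S = p, n = n,
         covariates = covariates, unit_id = panel$unit_id, t = panel$t),
    class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, R2 = %.4f, AIC = %.2f\n", x$n, x$r_squared, x$aic))
  print(data.frame(estimate = x$coefficients, se = x$se))
  invisible(x)
}

# ---- local models -----------------------------------------------------------

#' Fit a geographically and temporally weighted regression
#'
#' Solves the local weighted least-squares problem at every record using
#' Gaussian weights on the combined space-time distance. Near-singular
#' local systems (condition number above 1e10) fall back to a small ridge
#' term with a warning.
#'
#' @inheritParams fit_ols
#' @param spec A [kernel_spec()] giving bandwidth `h` and scale ratio `tau`.
#' @return Object of class `gtwr_fit` with per-record local coefficients,
#'   fitted values, residuals, hat values, `trace_S`, `r_squared`, `aicc`
#'   and the leave-one-out `cv_score`.
#' @export
fit_gtwr <- function(panel, response, covariates, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  prep <- gtwr_prepare(panel, response, covariates)
  core <- gtwr_core(prep$X, prep$y, prep$u, prep$v, prep$t,
                    spec$bandwidth, spec$tau)
  finish_local_fit(core, prep$X, prep$y, "gtwr", spec, covariates, prep$panel)
}

#' Fit a geographically weighted regression (spatial-only weights)
#'
#' Identical to [fit_gtwr()] with the temporal term removed from the
#' kernel; typically applied to one time slice of the panel
#' (cross-sectional GWR).
#'
#' @inheritParams fit_ols
#' @param h Spatial bandwidth (> 0).
#' @return Object of class `gtwr_fit` (with `model = "gwr"`).
#' @export
fit_gwr <- function(panel, response, covariates, h) {
  spec <- kernel_spec(h, tau = 0)
  prep <- gtwr_prepare(panel, response, covariates)
  core <- gtwr_core(prep$X, prep$y, prep$u, prep$v, prep$t, h, 0)
  fit <- finish_local_fit(core, prep$X, prep$y, "gwr", spec, covariates,
                          prep$panel)
  fit
}

#' Leave-one-out cross-validation score
#'
#' `CV = sum_i (y_i - yhat_(i))^2` where the prediction at record i uses
#' local weights with the record's own weight forced to zero.
#'
#' @inheritParams fit_gtwr
#' @param model `"gtwr"` or `"gwr"` (spatial-only weights, pooled over the
#'   panel given).
#' @return The CV score (a sum of squared errors, not a mean).
#' @export
cv_score <- function(panel, response, covariates, spec,
                     model = c("gtwr", "gwr")) {
  model <- match.arg(model)
  fit <- if (model == "gtwr") {
    fit_gtwr(panel, response, covariates, spec)
  } else {
    fit_gwr(panel, response, covariates, spec$bandwidth)
  }
  fit$cv_score
}

# CV of cross-sectional GWR: independent fit per time slice, summed.
cv_score_sliced_gwr <- function(panel, response, covariates, h) {
  sum(vapply(split(panel, panel$t), function(sl)
    fit_gwr(sl, response, covariates, h)$cv_score, numeric(1)))
}

# ---- bandwidth / scale selection --------------------------------------------

min_nn_spacing <- function(u, v) {
  pts <- unique(cbind(u, v))
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  min(apply(d, 1L, min))
}

domain_diameter <- function(u, v) {
  sqrt(diff(range(u))^2 + diff(range(v))^2)
}

golden_section <- function(f, lower, upper, tol) {
  gr <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    }
  }
  x <- (a + b) / 2
  list(minimum = x, objective = f(x))
}

#' Select kernel bandwidth (and space-time scale ratio) by cross-validation
#'
#' Golden-section search on the bandwidth over
#' `[minimum nearest-neighbor spacing, domain diameter]`; for GTWR an outer
#' grid over `tau` (default a logarithmic grid `{0, 1e-2, ..., 1e6}` scaled
#' by the squared nearest-neighbor spacing per squared month) picks the
#' `(h, tau)` pair with the smallest leave-one-out CV score. Deterministic
#' given the panel.
#'
#' @inheritParams fit_ols
#' @param model `"gtwr"` or `"gwr"` (for `"gwr"` the panel is typically one
#'   time slice and `tau` is fixed at 0).
#' @param tau_grid Candidate `tau` values for GTWR; `NULL` for the default
#'   grid.
#' @param h_range Length-2 search interval for `h`; defaults to the nearest
#'   neighbor spacing and the domain diameter.
#' @param tol Absolute golden-section tolerance on `h` (default 1% of the
#'   search interval).
#' @param criterion `"cv"` (leave-one-out score, the default) or `"aicc"`.
#'   CV tends to undersmooth local-regression bandwidths; AICc trades fit
#'   against the hat-matrix trace and is preferable when the local
#'   coefficient surfaces themselves are the object of interest.
#' @return A [kernel_spec()] with the winning `(h, tau)`; the winning
#'   criterion value and the tau-profile table are attached as attributes
#'   `cv_score` (or `aicc`) and `search`.
#' @export
select_bandwidth <- function(panel, response, covariates,
                             model = c("gtwr", "gwr"), tau_grid = NULL,
                             h_range = NULL, tol = NULL,
                             criterion = c("cv", "aicc")) {
  model <- match.arg(model)
  criterion <- match.arg(criterion)
  prep <- gtwr_prepare(panel, response, covariates)
  spacing <- min_nn_spacing(panel$u, panel$v)
  if (is.null(h_range)) {
    h_range <- c(spacing, domain_diameter(panel$u, panel$v))
  }
  stopifnot(length(h_range) == 2L, h_range[1] > 0, h_range[2] > h_range[1])
  tol <- tol %||% (0.01 * diff(h_range))
  if (model == "gwr") {
    tau_grid <- 0
  } else if (is.null(tau_grid)) {
    tau_grid <- c(0, 10^seq(-2, 6)) * spacing^2
  }
  score_at <- function(h, tau) {
    core <- suppressWarnings(
      gtwr_core(prep$X, prep$y, prep$u, prep$v, prep$t, h, tau))
    if (criterion == "cv") {
      if (any(is.na(core$loo))) return(Inf)
      sum((prep$y - core$loo)^2)
    } else {
      n <- length(prep$y)
      rss <- sum((prep$y - core$fitted)^2)
      tryCatch(aicc(n, rss, sum(core$hat)), gtwr_overfit = function(e) Inf)
    }
  }
  rows <- lapply(tau_grid, function(tau) {
    opt <- golden_section(function(h) score_at(h, tau),
                          h_range[1], h_range[2], tol)
    data.frame(tau = tau, h = opt$minimum, score = opt$objective)
  })
  search <- do.call(rbind, rows)
  names(search)[3] <- criterion
  best <- search[which.min(search[[criterion]]), ]
  if (best$h <= h_range[1] + tol || best$h >= h_range[2] - tol) {
    warning("selected bandwidth lies at the boundary of the search range")
  }
  out <- kernel_spec(best$h, tau = best$tau)
  attr(out, if (criterion == "cv") "cv_score" else "aicc") <- best[[criterion]]
  attr(out, "search") <- search
  out
}
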