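# Model diagnostics: collinearity (VIF), residual spatial autocorrelation
# (Moran's I with a permutation test), and the interquartile-vs-2*SE test
# for spatial nonstationarity of local coefficients.

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing covariate j
#' on all the others (with intercept). Covariates with VIF above
#' `threshold` are flagged; a perfectly collinear column yields `Inf`.
#'
#' @param design Numeric matrix or `data.frame` of covariates (no
#'   intercept column).
#' @param threshold Flagging threshold (default 5).
#' @return `data.frame` with `covariate`, `vif`, `flagged`.
#' @export
vif <- function(design, threshold = 5) {
  X <- as.matrix(design)
  stopifnot(is.numeric(X), ncol(X) >= 2L)
  if (nrow(X) <= ncol(X) + 1L) {
    stop_gtwr("need n > k + 1 rows for VIF", class = "gtwr_domain_error")
  }
  nms <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  v <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(covariate = nms, vif = v, flagged = v > threshold,
             stringsAsFactors = FALSE)
}

#' Row-standardized k-nearest-neighbor spatial weights
#'
#' Binary k-nearest-neighbor adjacency on point coordinates,
#' row-standardized so each row sums to one. Used for Moran's I when
#' polygon contiguity is unavailable.
#'
#' @param coords Two-column matrix (or `data.frame`) of point coordinates.
#' @param k Number of neighbors (default 8).
#' @return n x n weight matrix.
#' @export
knn_weights <- function(coords, k = 8L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(n > k)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    W[i, order(d[i, ])[seq_len(k)]] <- 1 / k
  }
  W
}

#' Moran's I with a permutation test
#'
#' `I = (n / S0) * (z' W z) / (z' z)` with `z` the centered values and `S0`
#' the sum of all weights. The p-value is the one-sided (greater)
#' permutation probability under random relabeling; `clustered` flags
#' significant positive autocorrelation (`I` above its expectation
#' `-1/(n-1)` with `p < 0.05`).
#'
#' @param values Numeric vector, one value per spatial unit.
#' @param W Spatial weight matrix, e.g. from [knn_weights()].
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed for the permutation draw.
#' @return Object of class `moran_result`: `I`, `expected_I`, `p_value`,
#'   `clustered`, `n_perm`.
#' @export
morans_i <- function(values, W, n_perm = 999L, seed = NULL) {
  n <- length(values)
  stopifnot(n >= 4L, nrow(W) == n, ncol(W) == n)
  if (stats::sd(values) == 0) {
    stop_gtwr("Moran's I undefined for constant values",
              class = "gtwr_degenerate_series")
  }
  if (!is.null(seed)) set.seed(seed)
  z <- values - mean(values)
  s0 <- sum(W)
  I_of <- function(z) (n / s0) * drop(z %*% W %*% z) / sum(z * z)
  I_obs <- I_of(z)
  perm <- vapply(seq_len(n_perm), function(i) I_of(sample(z)), numeric(1))
  p <- (1 + sum(perm >= I_obs)) / (n_perm + 1)
  expected <- -1 / (n - 1)
  structure(list(I = I_obs, expected_I = expected, p_value = p,
                 clustered = (I_obs > expected) && (p < 0.05),
                 n_perm = n_perm),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f), permutation p = %.4f%s\n",
              x$I, x$expected_I, x$p_value,
              if (x$clustered) " [clustered]" else ""))
  invisible(x)
}

#' Per-month Moran's I screen of OLS residuals
#'
#' Computes Moran's I of the pooled-OLS residuals separately for every
#' month (a single pooled statistic would mix temporal and spatial
#' structure) and reports the share of months with significant clustering.
#'
#' @param panel Panel `data.frame` (`unit_id`, `u`, `v`, `t`).
#' @param ols An `ols_fit` for the same panel (records aligned).
#' @param k Neighbors for [knn_weights()].
#' @param n_perm Permutations per month.
#' @param seed Seed for the permutation draws.
#' @return List with `per_month` (`t`, `I`, `p_value`, `clustered`) and
#'   `share_clustered` (percent of months).
#' @export
moran_screen <- function(panel, ols, k = 8L, n_perm = 999L, seed = NULL) {
  stopifnot(inherits(ols, "ols_fit"), nrow(panel) == ols$n)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(split(seq_len(nrow(panel)), panel$t), function(idx) {
    un <- panel[idx, ]
    W <- knn_weights(cbind(un$u, un$v), k = min(k, nrow(un) - 1L))
    m <- morans_i(ols$residuals[idx], W, n_perm = n_perm)
    data.frame(t = un$t[1L], I = m$I, p_value = m$p_value,
               clustered = m$clustered)
  })
  per_month <- do.call(rbind, rows)
  rownames(per_month) <- NULL
  list(per_month = per_month,
       share_clustered = 100 * mean(per_month$clustered))
}

#' Spatial nonstationarity table (local IQR vs twice the OLS SE)
#'
#' For every coefficient: the interquartile range (linear-interpolation
#' quartiles) of the GTWR local estimates, the smallest per-month IQR of
#' the cross-sectional GWR estimates, and twice the global-OLS standard
#' error. A coefficient whose local spread exceeds twice the OLS SE is
#' flagged spatially heterogeneous (on the GTWR column by default).
#'
#' @param gtwr_fit A `gtwr_fit` from [fit_gtwr()].
#' @param gwr_fits List of per-month `gtwr_fit` objects from [fit_gwr()].
#' @param ols An `ols_fit`.
#' @param flag_on `"gtwr"` or `"gwr_lowest"`: which IQR drives the flag.
#' @return `data.frame` with `variable`, `iqr_gtwr`, `iqr_gwr_lowest`,
#'   `twice_se_ols`, `heterogeneous`.
#' @export
nonstationarity_table <- function(gtwr_fit, gwr_fits, ols,
                                  flag_on = c("gtwr", "gwr_lowest")) {
  flag_on <- match.arg(flag_on)
  stopifnot(inherits(gtwr_fit, "gtwr_fit"), inherits(ols, "ols_fit"))
  vars <- colnames(gtwr_fit$coefficients)
  for (g in gwr_fits) {
    if (!identical(colnames(g$coefficients), vars)) {
      stop_gtwr("covariate sets differ between fits", class = "gtwr_config_error")
    }
  }
  if (!identical(names(ols$coefficients), vars)) {
    stop_gtwr("covariate sets differ between fits", class = "gtwr_config_error")
  }
  iqr7 <- function(x) diff(stats::quantile(x, c(0.25, 0.75), type = 7,
                                           names = FALSE))
  iqr_gtwr <- apply(gtwr_fit$coefficients, 2L, iqr7)
  iqr_gwr <- vapply(vars, function(v) {
    min(vapply(gwr_fits, function(g) iqr7(g$coefficients[, v]), numeric(1)))
  }, numeric(1))
  twice_se <- 2 * ols$se
  het <- if (flag_on == "gtwr") iqr_gtwr > twice_se else iqr_gwr > twice_se
  out <- data.frame(variable = vars, iqr_gtwr = iqr_gtwr,
                    iqr_gwr_lowest = iqr_gwr, twice_se_ols = twice_se,
                    heterogeneous = het, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
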