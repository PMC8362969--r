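# Station-to-centroid interpolation: inverse distance weighting and ordinary
# kriging with a spherical semivariogram, compared by leave-one-out MAPE.

#' Neighborhood specification for interpolation
#'
#' @param k_neighbors Number of nearest stations entering each prediction
#'   (default 12).
#' @param idw_power Inverse-distance power for IDW weights (default 2).
#' @return Object of class `neighborhood_spec`.
#' @export
neighborhood_spec <- function(k_neighbors = 12L, idw_power = 2) {
  stopifnot(k_neighbors >= 1, idw_power > 0)
  structure(list(k_neighbors = as.integer(k_neighbors), idw_power = idw_power),
            class = "neighborhood_spec")
}

#' Spherical semivariogram model
#'
#' @param nugget Nugget variance (>= 0).
#' @param partial_sill Partial sill (>= 0); total sill is
#'   `nugget + partial_sill`.
#' @param range Range `a` (> 0), the separation at which the sill is reached.
#' @return Object of class `variogram_model`.
#' @export
variogram_model <- function(nugget, partial_sill, range) {
  stopifnot(nugget >= 0, partial_sill >= 0, range > 0)
  structure(list(model = "spherical", nugget = nugget,
                 partial_sill = partial_sill, range = range),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("spherical variogram: nugget %.4g, partial sill %.4g, range %.4g\n",
              x$nugget, x$partial_sill, x$range))
  invisible(x)
}

#' Evaluate a spherical semivariogram
#'
#' gamma(h) = nugget + psill * (1.5 h/a - 0.5 (h/a)^3) for h < a, and
#' nugget + psill beyond the range; at h = 0 the nugget is returned (the
#' right-continuous convention).
#'
#' @param vgm A [variogram_model()].
#' @param h Numeric vector of separation distances (>= 0).
#' @return Semivariance values.
#' @export
semivariance <- function(vgm, h) {
  stopifnot(inherits(vgm, "variogram_model"), all(h >= 0))
  r <- pmin(h / vgm$range, 1)
  vgm$nugget + vgm$partial_sill * (1.5 * r - 0.5 * r^3)
}

st_coords <- function(stations) {
  stopifnot(all(c("u", "v", "value") %in% names(stations)))
  cbind(stations$u, stations$v)
}

# squared euclidean distances from each row of `coords` to `query` (length-2)
dist_to_query <- function(coords, query) {
  sqrt((coords[, 1] - query[1])^2 + (coords[, 2] - query[2])^2)
}

#' Inverse distance weighted prediction
#'
#' Weighted mean of the `k_neighbors` nearest station values with weights
#' `distance^(-idw_power)`. A query closer than 1e-9 to a station returns
#' that station's value exactly.
#'
#' @param stations `data.frame` with columns `u`, `v`, `value`.
#' @param query Numeric length-2 vector `(u, v)`, or a 2-column matrix of
#'   query points.
#' @param spec A [neighborhood_spec()].
#' @return Numeric prediction(s), one per query point.
#' @export
idw_predict <- function(stations, query, spec = neighborhood_spec()) {
  if (nrow(stations) == 0L) {
    stop_gtwr("no stations supplied", class = "gtwr_domain_error")
  }
  coords <- st_coords(stations)
  if (is.matrix(query)) {
    return(vapply(seq_len(nrow(query)),
                  function(i) idw_predict(stations, query[i, ], spec),
                  numeric(1)))
  }
  d <- dist_to_query(coords, query)
  if (any(d < 1e-9)) {
    return(stations$value[which.min(d)])
  }
  k <- min(spec$k_neighbors, nrow(stations))
  nn <- order(d)[seq_len(k)]
  w <- d[nn]^(-spec$idw_power)
  sum(w * stations$value[nn]) / sum(w)
}

#' Fit a spherical semivariogram to station data
#'
#' The empirical semivariogram uses the Matheron estimator (half the mean
#' squared difference per distance bin) over `n_bins` equal-width bins up to
#' `cutoff` (default half the maximum pairwise distance). Spherical
#' parameters are then fitted by least squares weighted by the bin pair
#' counts.
#'
#' @param stations `data.frame` with `u`, `v`, `value`.
#' @param n_bins Number of distance bins (default 15).
#' @param cutoff Maximum separation considered; default half the maximum
#'   pairwise distance.
#' @return A [variogram_model()] with the empirical variogram attached as
#'   attribute `"empirical"`.
#' @export
fit_spherical_variogram <- function(stations, n_bins = 15L, cutoff = NULL) {
  coords <- st_coords(stations)
  n <- nrow(coords)
  if (n * (n - 1) / 2 < 10) {
    stop_gtwr("need at least 10 station pairs to fit a variogram",
              class = "gtwr_domain_error")
  }
  d <- as.matrix(stats::dist(coords))
  iu <- which(upper.tri(d))
  h <- d[iu]
  dz2 <- (outer(stations$value, stations$value, "-")[iu])^2
  if (all(dz2 == 0)) {
    warning("all station values identical; returning a degenerate pure-nugget zero model")
    out <- variogram_model(0, 0, max(h))
    attr(out, "empirical") <- data.frame(dist = numeric(), gamma = numeric(),
                                         n_pairs = integer())
    return(out)
  }
  cutoff <- cutoff %||% (max(h) / 2)
  keep <- h <= cutoff & h > 0
  bin <- cut(h[keep], breaks = seq(0, cutoff, length.out = n_bins + 1L),
             include.lowest = TRUE)
  gamma_emp <- tapply(dz2[keep], bin, function(x) mean(x) / 2)
  hbar <- tapply(h[keep], bin, mean)
  npairs <- tapply(dz2[keep], bin, length)
  ok <- !is.na(gamma_emp)
  if (sum(ok) < 3L) {
    stop_gtwr("station pairs span fewer than 3 distance bins",
              class = "gtwr_domain_error")
  }
  emp <- data.frame(dist = as.numeric(hbar[ok]),
                    gamma = as.numeric(gamma_emp[ok]),
                    n_pairs = as.integer(npairs[ok]))
  obj <- function(par) {
    # finite-difference gradient steps may probe just outside the box
    par <- pmax(par, c(0, 0, cutoff * 1e-6))
    vgm <- variogram_model(par[1], par[2], par[3])
    sum(emp$n_pairs * (emp$gamma - semivariance(vgm, emp$dist))^2)
  }
  s2 <- stats::var(stations$value)
  # the WLS surface is multimodal (nugget vs short-range trade-off);
  # a small multi-start grid avoids local optima
  fit <- NULL
  for (ng in c(0, 0.25, 0.5) * s2) {
    for (rg in cutoff * c(0.25, 0.5, 1)) {
      f <- stats::optim(c(ng, max(s2 - ng, 1e-8 * s2), rg), obj,
                        method = "L-BFGS-B",
                        lower = c(0, 0, cutoff * 1e-3),
                        upper = c(10 * s2, 10 * s2, 4 * cutoff))
      if (is.null(fit) || f$value < fit$value) fit <- f
    }
  }
  out <- variogram_model(fit$par[1], fit$par[2], fit$par[3])
  attr(out, "empirical") <- emp
  out
}

#' Ordinary kriging prediction
#'
#' Solves the ordinary-kriging system over the `k_neighbors` nearest
#' stations under the unbiasedness constraint (weights sum to one). With a
#' zero nugget the predictor interpolates exactly at station sites.
#' Duplicate station locations in the neighborhood are averaged before
#' solving.
#'
#' @inheritParams idw_predict
#' @param vgm A [variogram_model()].
#' @return For a single query, a list with `estimate`, `variance` and
#'   `weights`; for a matrix of queries, a `data.frame` with `estimate` and
#'   `variance` columns.
#' @export
kriging_predict <- function(stations, query, vgm, spec = neighborhood_spec()) {
  stopifnot(inherits(vgm, "variogram_model"))
  if (nrow(stations) < 2L) {
    stop_gtwr("ordinary kriging needs at least 2 stations",
              class = "gtwr_domain_error")
  }
  if (is.matrix(query)) {
    rows <- lapply(seq_len(nrow(query)), function(i)
      kriging_predict(stations, query[i, ], vgm, spec))
    return(data.frame(estimate = vapply(rows, `[[`, numeric(1), "estimate"),
                      variance = vapply(rows, `[[`, numeric(1), "variance")))
  }
  coords <- st_coords(stations)
  d <- dist_to_query(coords, query)
  k <- min(spec$k_neighbors, nrow(stations))
  nn <- order(d)[seq_len(k)]
  sub <- stations[nn, , drop = FALSE]
  # collapse duplicate coordinates (mean value) so the system is nonsingular
  key <- paste(signif(sub$u, 12), signif(sub$v, 12))
  if (anyDuplicated(key)) {
    sub <- do.call(rbind, lapply(split(sub, key), function(g) {
      data.frame(u = g$u[1], v = g$v[1], value = mean(g$value))
    }))
  }
  m <- nrow(sub)
  if (m < 2L) {
    stop_gtwr("fewer than 2 distinct station locations in neighborhood",
              class = "gtwr_domain_error")
  }
  dm <- as.matrix(stats::dist(cbind(sub$u, sub$v)))
  G <- semivariance(vgm, dm)
  diag(G) <- 0  # a station knows its own value exactly
  A <- rbind(cbind(G, 1), c(rep(1, m), 0))
  g0 <- semivariance(vgm, dist_to_query(cbind(sub$u, sub$v), query))
  g0[dist_to_query(cbind(sub$u, sub$v), query) < 1e-9] <- 0
  rhs <- c(g0, 1)
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    stop_gtwr("singular kriging system: ", conditionMessage(e),
              class = "gtwr_singular_system")
  })
  w <- unname(sol[seq_len(m)])
  list(estimate = sum(w * sub$value),
       variance = max(0, sum(w * g0) + sol[m + 1L]),
       weights = w)
}

#' Leave-one-out mean absolute percentage error
#'
#' Each station is predicted from all the others with the chosen method;
#' MAPE is `100 * mean(|obs - pred| / |obs|)` over stations with non-zero
#' observations (zero observations are excluded with a message).
#'
#' @inheritParams kriging_predict
#' @param method `"idw"` or `"kriging"`.
#' @param vgm Variogram for `method = "kriging"`; refitted from the full
#'   station set when omitted.
#' @return MAPE in percent.
#' @export
loo_mape <- function(stations, method = c("idw", "kriging"),
                     spec = neighborhood_spec(), vgm = NULL) {
  method <- match.arg(method)
  if (nrow(stations) < 3L) {
    stop_gtwr("leave-one-out MAPE needs at least 3 stations",
              class = "gtwr_domain_error")
  }
  nonzero <- stations$value != 0
  if (!any(nonzero)) {
    stop_gtwr("MAPE undefined: all observations are zero",
              class = "gtwr_domain_error")
  }
  if (any(!nonzero)) {
    message(sum(!nonzero), " zero-valued station(s) excluded from MAPE")
  }
  if (method == "kriging" && is.null(vgm)) {
    vgm <- fit_spherical_variogram(stations)
  }
  idx <- which(nonzero)
  ape <- vapply(idx, function(i) {
    rest <- stations[-i, , drop = FALSE]
    q <- c(stations$u[i], stations$v[i])
    pred <- if (method == "idw") {
      idw_predict(rest, q, spec)
    } else {
      kriging_predict(rest, q, vgm, spec)$estimate
    }
    abs(stations$value[i] - pred) / abs(stations$value[i])
  }, numeric(1))
  100 * mean(ape)
}

#' Interpolate station series to unit centroids, month by month
#'
#' For each month, fits a variogram to that month's station values and
#' predicts at every unit centroid by both IDW and ordinary kriging;
#' leave-one-out MAPE per month and method is attached.
#'
#' @param stations `data.frame` with `station_id`, `u`, `v`, `t`, `value`.
#' @param units `data.frame` with `unit_id`, `u`, `v`.
#' @param spec A [neighborhood_spec()].
#' @return List with `predictions` (`unit_id`, `t`, `value_idw`,
#'   `value_kriging`, `kriging_variance`) and `mape` (`t`, `method`, `mape`,
#'   plus pooled means as attribute `"pooled"`).
#' @export
interpolate_to_units <- function(stations, units, spec = neighborhood_spec()) {
  stopifnot(all(c("station_id", "u", "v", "t", "value") %in% names(stations)),
            all(c("unit_id", "u", "v") %in% names(units)))
  qs <- cbind(units$u, units$v)
  months <- sort(unique(stations$t))
  preds <- vector("list", length(months))
  mapes <- vector("list", length(months))
  for (j in seq_along(months)) {
    st <- stations[stations$t == months[j], , drop = FALSE]
    vgm <- fit_spherical_variogram(st)
    kr <- kriging_predict(st, qs, vgm, spec)
    preds[[j]] <- data.frame(
      unit_id = units$unit_id, t = months[j],
      value_idw = idw_predict(st, qs, spec),
      value_kriging = kr$estimate,
      kriging_variance = kr$variance)
    mapes[[j]] <- data.frame(
      t = months[j], method = c("idw", "kriging"),
      mape = c(loo_mape(st, "idw", spec),
               loo_mape(st, "kriging", spec, vgm = vgm)))
  }
  mape <- do.call(rbind, mapes)
  pooled <- tapply(mape$mape, mape$method, mean)
  out <- list(predictions = do.call(rbind, preds), mape = mape)
  attr(out$mape, "pooled") <- pooled
  out
}
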