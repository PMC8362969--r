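# Seeded synthetic spatio-temporal panels with known coefficient surfaces.
#
# The generator emulates the study design the pipeline targets: ~129 areal
# units observed for 36 months (4,644 records), an AQI-like covariate that
# is spatially autocorrelated (Gaussian random field with exponential
# covariance) with a seasonal sinusoid and an optional random-walk
# component, unit-level socio-economic covariates, and a continuous
# log-scale response built from smooth spatially/temporally varying
# coefficient surfaces plus Gaussian noise. A sparse station network
# observes the same latent AQI field exactly, so interpolation error is
# measurable against ground truth.

#' Coefficient-surface specification
#'
#' A surface is evaluated as
#' `beta(u, v, t) = base + du * un + dv * vn + amplitude * sin(2*pi*t/12 + phase)`
#' where `un`, `vn` are coordinates normalized to `[0, 1]` over the domain
#' and `t` is the integer month. [beta_constant()], [beta_linear()] and
#' [beta_seasonal()] are convenience constructors for the pure cases.
#'
#' @param base Constant part.
#' @param du,dv Linear gradients per normalized coordinate.
#' @param amplitude,phase Seasonal sinusoid (12-month period).
#' @return Object of class `beta_surface`.
#' @export
beta_surface <- function(base = 0, du = 0, dv = 0, amplitude = 0, phase = 0) {
  structure(list(base = base, du = du, dv = dv,
                 amplitude = amplitude, phase = phase),
            class = "beta_surface")
}

#' @rdname beta_surface
#' @param value Constant coefficient value.
#' @export
beta_constant <- function(value) beta_surface(base = value)

#' @rdname beta_surface
#' @export
beta_linear <- function(base, du = 0, dv = 0) beta_surface(base, du, dv)

#' @rdname beta_surface
#' @export
beta_seasonal <- function(base, amplitude, phase = 0) {
  beta_surface(base, amplitude = amplitude, phase = phase)
}

eval_beta_surface <- function(s, un, vn, t) {
  s$base + s$du * un + s$dv * vn +
    s$amplitude * sin(2 * pi * t / 12 + s$phase)
}

#' Synthetic study configuration
#'
#' Defaults mirror the emulated study: 129 areal units over a 300 x 200 km
#' projected domain observed for 36 months, 87 monitoring stations, an AQI
#' field with mean ~40 index units, 60 km spatial correlation range,
#' seasonal amplitude 4 index units and a per-site random-walk component
#' (innovation SD 2.5 index units/month) that makes most per-unit AQI series
#' non-stationary at this series length. Response noise SD is 0.15 on the
#' log scale.
#'
#' @param n_units,n_months,n_stations Positive integers.
#' @param domain_extent Numeric `c(umin, umax, vmin, vmax)` in metres.
#' @param spatial_range Correlation range of the exponential Gaussian-field
#'   covariance (metres).
#' @param base_aqi Mean level of the latent AQI field (index units).
#' @param field_sd Marginal SD of the spatial Gaussian field (index units).
#' @param seasonal_amplitude Amplitude of the 12-month AQI sinusoid.
#' @param unit_root_sd Innovation SD of the per-site random-walk AQI
#'   component; innovations are spatially correlated with the same range
#'   as the static field, so every unit carries its own unit-root series
#'   while monthly maps stay smooth (0 disables the component).
#' @param noise_sd Response noise SD (log scale).
#' @param coefficient_surfaces Named list of [beta_surface()] objects; must
#'   contain `"(Intercept)"`. Every other name becomes a covariate: `aqi`
#'   maps to the latent field; any further name is drawn as a unit-level
#'   standard-normal covariate, constant over months.
#' @param seed Integer seed; identical seeds give identical output.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_units = 129L, n_months = 36L,
                             domain_extent = c(0, 3e5, 0, 2e5),
                             n_stations = 87L, spatial_range = 6e4,
                             base_aqi = 40, field_sd = 8,
                             seasonal_amplitude = 4, unit_root_sd = 2.5,
                             noise_sd = 0.15,
                             coefficient_surfaces = list(
                               "(Intercept)" = beta_constant(0.9),
                               aqi = beta_seasonal(0.015, 0.005),
                               unemployment = beta_constant(0.05),
                               income = beta_constant(-0.1)),
                             seed = 1L) {
  if (n_units < 1 || n_months < 1 || n_stations < 1) {
    stop_gtwr("n_units, n_months and n_stations must be positive",
              class = "gtwr_config_error")
  }
  if (length(domain_extent) != 4L ||
      domain_extent[2] <= domain_extent[1] ||
      domain_extent[4] <= domain_extent[3]) {
    stop_gtwr("domain_extent must be c(umin, umax, vmin, vmax) with positive area",
              class = "gtwr_config_error")
  }
  if (spatial_range <= 0 || field_sd < 0 || unit_root_sd < 0 || noise_sd < 0) {
    stop_gtwr("spatial_range must be > 0 and all SDs >= 0",
              class = "gtwr_config_error")
  }
  if (!"(Intercept)" %in% names(coefficient_surfaces)) {
    stop_gtwr("coefficient_surfaces must include \"(Intercept)\"",
              class = "gtwr_config_error")
  }
  stopifnot(all(vapply(coefficient_surfaces, inherits, logical(1),
                       "beta_surface")))
  structure(list(n_units = as.integer(n_units),
                 n_months = as.integer(n_months),
                 domain_extent = as.numeric(domain_extent),
                 n_stations = as.integer(n_stations),
                 spatial_range = spatial_range, base_aqi = base_aqi,
                 field_sd = field_sd, seasonal_amplitude = seasonal_amplitude,
                 unit_root_sd = unit_root_sd, noise_sd = noise_sd,
                 coefficient_surfaces = coefficient_surfaces,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Gaussian random field with exponential covariance, exact via Cholesky.
# `draws` independent replicates share one factorization.
grf_exponential <- function(coords, sd, range, draws = 1L) {
  n <- nrow(coords)
  if (sd == 0) return(matrix(0, n, draws))
  d <- as.matrix(stats::dist(coords))
  S <- sd^2 * exp(-d / range)
  L <- chol(S + diag(1e-8 * sd^2, n))
  crossprod(L, matrix(stats::rnorm(n * draws), n, draws))
}

# Everything the generator draws, in one deterministic pass.
generate_world <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  ext <- config$domain_extent
  nu <- config$n_units; nm <- config$n_months; ns <- config$n_stations
  units <- data.frame(
    unit_id = sprintf("U%03d", seq_len(nu)),
    u = stats::runif(nu, ext[1], ext[2]),
    v = stats::runif(nu, ext[3], ext[4]))
  stations <- data.frame(
    station_id = sprintf("S%03d", seq_len(ns)),
    u = stats::runif(ns, ext[1], ext[2]),
    v = stats::runif(ns, ext[3], ext[4]))
  sites <- rbind(cbind(units$u, units$v), cbind(stations$u, stations$v))
  g <- drop(grf_exponential(sites, config$field_sd, config$spatial_range))
  months <- 0:(nm - 1L)
  seasonal <- config$seasonal_amplitude * sin(2 * pi * months / 12)
  # per-site random walk with spatially correlated innovations, so each
  # unit carries its own unit-root series while the field stays smooth
  rw <- if (config$unit_root_sd > 0) {
    inn <- grf_exponential(sites, config$unit_root_sd, config$spatial_range,
                           draws = nm)
    if (nm > 1L) t(apply(inn, 1L, cumsum)) else inn
  } else matrix(0, nrow(sites), nm)
  # field value at site s, month t: base + g(s) + seasonal(t) + rw(s, t)
  field <- config$base_aqi + g + rw +
    matrix(seasonal, nrow(sites), nm, byrow = TRUE)
  unit_field <- field[seq_len(nu), , drop = FALSE]
  station_field <- field[nu + seq_len(ns), , drop = FALSE]

  surf <- config$coefficient_surfaces
  covar_names <- setdiff(names(surf), "(Intercept)")
  extra <- setdiff(covar_names, "aqi")
  extra_vals <- lapply(extra, function(nm_) stats::rnorm(nu))
  names(extra_vals) <- extra

  un <- (units$u - ext[1]) / (ext[2] - ext[1])
  vn <- (units$v - ext[3]) / (ext[4] - ext[3])
  beta_surface_mats <- lapply(surf, function(s)
    matrix(vapply(months, function(t) eval_beta_surface(s, un, vn, t),
                  numeric(nu)), nrow = nu))

  panel <- data.frame(
    unit_id = rep(units$unit_id, times = nm),
    u = rep(units$u, times = nm),
    v = rep(units$v, times = nm),
    t = rep(months, each = nu))
  panel$aqi <- as.vector(unit_field)
  for (nm_ in extra) panel[[nm_]] <- rep(extra_vals[[nm_]], times = nm)

  mu <- as.vector(beta_surface_mats[["(Intercept)"]])
  for (nm_ in covar_names) {
    mu <- mu + as.vector(beta_surface_mats[[nm_]]) * panel[[nm_]]
  }
  noise <- stats::rnorm(nu * nm, 0, config$noise_sd)
  panel$response <- mu + noise
  panel <- panel[c("unit_id", "u", "v", "t", "response", covar_names)]

  truth <- list(beta_surface = beta_surface_mats,
                station_values = station_field,
                units = units, stations = stations)
  list(panel = panel, truth = truth, config = config)
}

#' Generate a synthetic panel with known ground truth
#'
#' @param config A [synthetic_config()].
#' @return List with `panel` (`data.frame`: `unit_id`, `u`, `v`, `t`,
#'   `response`, covariates; exactly `n_units * n_months` records) and
#'   `truth` (per-covariate coefficient matrices indexed unit x month, the
#'   true station field values, and the unit/station layouts).
#' @export
#' @examples
#' gp <- generate_panel(synthetic_config(n_units = 20, n_months = 12))
#' nrow(gp$panel)  # 240
generate_panel <- function(config) {
  w <- generate_world(config)
  list(panel = w$panel, truth = w$truth)
}

#' Generate the synthetic station network
#'
#' Station values are exact evaluations of the same latent AQI field that
#' drives the panel's `aqi` covariate, so downstream interpolation error is
#' measurable.
#'
#' @param config A [synthetic_config()].
#' @return Long `data.frame` with `station_id`, `u`, `v`, `t`, `value`.
#' @export
generate_station_network <- function(config) {
  w <- generate_world(config)
  st <- w$truth$stations
  nm <- config$n_months
  data.frame(station_id = rep(st$station_id, times = nm),
             u = rep(st$u, times = nm),
             v = rep(st$v, times = nm),
             t = rep(0:(nm - 1L), each = nrow(st)),
             value = as.vector(w$truth$station_values))
}

#' Generate a pure random-walk series
#'
#' Cumulative sum of iid `N(0, sd^2)` innovations: a canonical unit-root
#' (non-stationary) fixture.
#'
#' @param n Series length (>= 2).
#' @param sd Innovation standard deviation (>= 0).
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
generate_unit_root_series <- function(n, sd, seed) {
  if (n < 2) stop_gtwr("n must be >= 2", class = "gtwr_config_error")
  if (sd < 0) stop_gtwr("sd must be >= 0", class = "gtwr_config_error")
  set.seed(seed)
  cumsum(stats::rnorm(n, 0, sd))
}

#' Write/read synthetic configuration as YAML
#'
#' @param config A [synthetic_config()].
#' @param path File path.
#' @return `write_synthetic_config` returns `path` invisibly;
#'   `read_synthetic_config` returns a [synthetic_config()].
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  x <- unclass(config)
  x$coefficient_surfaces <- lapply(x$coefficient_surfaces, unclass)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$coefficient_surfaces <- lapply(x$coefficient_surfaces, function(s)
    do.call(beta_surface, s))
  do.call(synthetic_config, x)
}
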