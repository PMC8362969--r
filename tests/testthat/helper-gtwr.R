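# Shared fixtures and independent oracles for the test suite.

# Small panel with known constant coefficients, built directly (independent
# of the package's generator) so model tests have a transparent truth.
toy_panel <- function(n_units = 5L, n_months = 4L, seed = 101L,
                      beta = c(1, 0.5, -0.25), noise_sd = 0) {
  set.seed(seed)
  u <- runif(n_units, 0, 1000)
  v <- runif(n_units, 0, 1000)
  n <- n_units * n_months
  panel <- data.frame(
    unit_id = rep(sprintf("U%02d", seq_len(n_units)), times = n_months),
    u = rep(u, times = n_months),
    v = rep(v, times = n_months),
    t = rep(0:(n_months - 1L), each = n_units),
    x1 = rnorm(n), x2 = rnorm(n))
  panel$response <- beta[1] + beta[2] * panel$x1 + beta[3] * panel$x2 +
    rnorm(n, 0, noise_sd)
  panel
}

# Brute-force GTWR at one regression point: explicit diagonal weight matrix
# and dense solve, coded without reference to the package internals.
brute_local_beta <- function(panel, response, covariates, i, h, tau) {
  X <- cbind(1, as.matrix(panel[, covariates, drop = FALSE]))
  y <- panel[[response]]
  d2 <- (panel$u - panel$u[i])^2 + (panel$v - panel$v[i])^2 +
    tau * (panel$t - panel$t[i])^2
  W <- diag(exp(-d2 / h^2))
  drop(solve(t(X) %*% W %*% X) %*% (t(X) %*% W %*% y))
}

# Rook adjacency on an nr x nc grid, row-standardized.
rook_weights <- function(nr, nc) {
  n <- nr * nc
  W <- matrix(0, n, n)
  idx <- function(r, c) (c - 1L) * nr + r
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    i <- idx(r, c)
    if (r > 1L) W[i, idx(r - 1L, c)] <- 1
    if (r < nr) W[i, idx(r + 1L, c)] <- 1
    if (c > 1L) W[i, idx(r, c - 1L)] <- 1
    if (c < nc) W[i, idx(r, c + 1L)] <- 1
  }
  W / rowSums(W)
}

# Stations observing a deterministic smooth surface (no randomness in the
# surface itself), for interpolation tests.
smooth_stations <- function(n = 40L, seed = 7L) {
  set.seed(seed)
  st <- data.frame(station_id = sprintf("S%02d", seq_len(n)),
                   u = runif(n, 0, 1e4), v = runif(n, 0, 1e4))
  st$value <- 50 + 10 * sin(st$u / 3e3) + 8 * cos(st$v / 4e3)
  st
}
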