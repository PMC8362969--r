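test_that("IDW follows the inverse-distance weight formula", {
  st <- data.frame(u = c(0, 0, 0), v = c(1, 2, 4),
                   value = c(10, 20, 40))
  # hand evaluation: weights (1, 1/4, 1/16) at distances 1, 2, 4
  expect_equal(idw_predict(st, c(0, 0)),
               (10 + 20 / 4 + 40 / 16) / (1 + 1 / 4 + 1 / 16),
               tolerance = 1e-12)
  # a query on a station returns that value exactly
  expect_equal(idw_predict(st, c(0, 2)), 20)
  # symmetric pair averages
  pair <- data.frame(u = c(-1, 1), v = c(0, 0), value = c(10, 20))
  expect_equal(idw_predict(pair, c(0, 0)), 15)
  expect_error(idw_predict(st[0, ], c(0, 0)), class = "gtwr_domain_error")
})

test_that("IDW predictions are bounded, linear in values, and exact on constants", {
  st <- smooth_stations()
  set.seed(5)
  queries <- cbind(runif(20, 0, 1e4), runif(20, 0, 1e4))
  pred <- idw_predict(st, queries)
  k <- 12
  for (j in seq_len(nrow(queries))) {
    d <- sqrt((st$u - queries[j, 1])^2 + (st$v - queries[j, 2])^2)
    nb <- st$value[order(d)[1:k]]
    expect_gte(pred[j], min(nb)); expect_lte(pred[j], max(nb))
  }
  st2 <- st; st2$value <- 2 * st$value
  expect_equal(idw_predict(st2, queries), 2 * pred, tolerance = 1e-12)
  stc <- st; stc$value <- 7
  expect_equal(idw_predict(stc, queries), rep(7, 20), tolerance = 1e-12)
})

test_that("spherical semivariogram evaluates in closed form", {
  vgm <- variogram_model(nugget = 0, partial_sill = 1, range = 5000)
  expect_equal(semivariance(vgm, 0), 0)
  expect_equal(semivariance(vgm, 2500), 1.5 * 0.5 - 0.5 * 0.5^3)  # 0.6875
  expect_equal(semivariance(vgm, 5000), 1)
  expect_equal(semivariance(vgm, 12000), 1)  # flat beyond the range
  vgm2 <- variogram_model(nugget = 0.3, partial_sill = 2, range = 100)
  expect_equal(semivariance(vgm2, 0), 0.3)
  expect_equal(semivariance(vgm2, 1e6), 2.3)
  # monotone non-decreasing on [0, a]
  h <- seq(0, 5000, length.out = 50)
  expect_true(all(diff(semivariance(vgm, h)) >= 0))
})

test_that("variogram fitting recovers a known spherical model", {
  # field drawn from spherical covariance: nugget 0, sill 1, range 5000 m
  set.seed(31)
  n <- 200
  st <- data.frame(u = runif(n, 0, 2e4), v = runif(n, 0, 2e4))
  d <- as.matrix(dist(cbind(st$u, st$v)))
  r <- pmin(d / 5000, 1)
  C <- 1 - (1.5 * r - 0.5 * r^3)
  st$value <- drop(crossprod(chol(C + diag(1e-8, n)), rnorm(n)))
  vgm <- fit_spherical_variogram(st)
  expect_lt(abs(vgm$range - 5000) / 5000, 0.25)
  expect_lt(abs(vgm$nugget + vgm$partial_sill - 1), 0.3)
})

test_that("degenerate and undersized variogram inputs are handled", {
  flat <- data.frame(u = runif(20), v = runif(20), value = rep(3, 20))
  expect_warning(vgm <- fit_spherical_variogram(flat), "identical")
  expect_equal(vgm$partial_sill, 0)
  expect_error(fit_spherical_variogram(
    data.frame(u = 1:3, v = 1:3, value = rnorm(3))),
    class = "gtwr_domain_error")
})

test_that("ordinary kriging is exact, unbiased, and linear", {
  st <- smooth_stations()
  vgm <- fit_spherical_variogram(st)
  # exactness at a station site with zero-nugget model
  vgm0 <- variogram_model(0, vgm$partial_sill + vgm$nugget, vgm$range)
  for (i in c(1L, 17L, 40L)) {
    kp <- kriging_predict(st, c(st$u[i], st$v[i]), vgm0)
    expect_lt(abs(kp$estimate - st$value[i]), 1e-6)
  }
  # weights sum to one at arbitrary queries
  set.seed(8)
  for (j in 1:10) {
    q <- c(runif(1, 0, 1e4), runif(1, 0, 1e4))
    kp <- kriging_predict(st, q, vgm)
    expect_lt(abs(sum(kp$weights) - 1), 1e-8)
    expect_gte(kp$variance, 0)
  }
  # two stations symmetric about the query split the weight equally
  pair <- data.frame(u = c(-500, 500), v = c(0, 0), value = c(10, 30))
  kp <- kriging_predict(pair, c(0, 0), vgm0)
  expect_equal(kp$weights, c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(kp$estimate, 20, tolerance = 1e-10)
  # linearity in the observed values
  q <- c(3000, 4000)
  st2 <- st; st2$value <- 2 * st$value
  expect_equal(kriging_predict(st2, q, vgm)$estimate,
               2 * kriging_predict(st, q, vgm)$estimate, tolerance = 1e-9)
  # constant field reproduced exactly (weights sum to 1)
  stc <- st; stc$value <- 40
  expect_equal(kriging_predict(stc, q, vgm)$estimate, 40, tolerance = 1e-8)
})

test_that("duplicate station locations are averaged before kriging", {
  st <- smooth_stations(n = 10)
  dup <- rbind(st, st[3, ])
  dup$value[11] <- st$value[3] + 4
  vgm <- variogram_model(0, 1, 3000)
  kp <- kriging_predict(dup, c(5000, 5000), vgm)
  expect_true(is.finite(kp$estimate))
  expect_lt(abs(sum(kp$weights) - 1), 1e-8)
})

test_that("leave-one-out MAPE matches its definition and prefers kriging on smooth fields", {
  # constant field: every LOO prediction equals the observation
  stc <- smooth_stations(); stc$value <- 25
  expect_equal(loo_mape(stc, "idw"), 0)
  st <- smooth_stations(n = 60)
  m_idw <- loo_mape(st, "idw")
  m_kri <- loo_mape(st, "kriging")
  expect_lte(m_kri, m_idw)
  expect_error(loo_mape(st[1:2, ], "idw"), class = "gtwr_domain_error")
  allz <- st; allz$value <- 0
  expect_error(loo_mape(allz, "idw"), class = "gtwr_domain_error")
  # zero observations are excluded with a message
  onez <- st; onez$value[1] <- 0
  expect_message(loo_mape(onez, "idw"), "excluded")
})

test_that("per-month unit interpolation returns both methods and MAPE", {
  cfg <- synthetic_config(n_units = 15L, n_months = 3L, n_stations = 40L,
                          seed = 13L)
  st <- generate_station_network(cfg)
  gp <- generate_panel(cfg)
  units <- unique(gp$panel[c("unit_id", "u", "v")])
  ip <- interpolate_to_units(st, units)
  expect_equal(nrow(ip$predictions), 15L * 3L)
  expect_equal(sort(unique(ip$mape$method)), c("idw", "kriging"))
  # kriged estimates track the true latent field at unit centroids
  err <- ip$predictions$value_kriging - gp$panel$aqi
  expect_lt(sqrt(mean(err^2)), sd(gp$panel$aqi))
})
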