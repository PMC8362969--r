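test_that("space-time distance and kernel weight follow their closed forms", {
  expect_equal(squared_st_distance(c(1, 2, 3), c(1, 2, 3), tau = 2), 0)
  expect_equal(squared_st_distance(c(0, 0, 0), c(3, 4, 0), tau = 5), 25)
  expect_equal(squared_st_distance(c(0, 0, 0), c(0, 0, 2), tau = 4), 16)
  expect_equal(squared_st_distance(c(0, 0, 0), c(1, 1, 1), tau = 0.5),
               squared_st_distance(c(1, 1, 1), c(0, 0, 0), tau = 0.5))
  expect_error(squared_st_distance(c(0, 0, 0), c(1, 1, 1), tau = -1),
               class = "gtwr_domain_error")

  h <- 3.7
  expect_equal(kernel_weight(0, h), 1)
  expect_equal(kernel_weight(h^2, h), exp(-1))
  expect_equal(kernel_weight(4 * h^2, h), kernel_weight(h^2, h)^4,
               tolerance = 1e-12)
  expect_true(all(diff(kernel_weight(seq(0, 50, 1), h)) < 0))
  expect_error(kernel_weight(1, 0), class = "gtwr_domain_error")
  expect_error(kernel_weight(-1, 1), class = "gtwr_domain_error")
})

test_that("corrected AIC penalizes effective parameters", {
  n <- 100; rss <- 50; tr <- 10
  direct <- n * log(rss / n) + n * log(2 * pi) + n * (n + tr) / (n - 2 - tr)
  expect_equal(aicc(n, rss, tr), direct)
  expect_gt(aicc(n, rss, 20), aicc(n, rss, 10))
  expect_error(aicc(10, 5, 8), class = "gtwr_overfit")
})

test_that("global OLS recovers exact linear relationships", {
  d <- data.frame(unit_id = sprintf("U%d", 1:30), u = runif(30), v = runif(30),
                  t = 0L, x = rnorm(30))
  d$response <- 1 + 2 * d$x
  ols <- fit_ols(d, "response", "x")
  expect_equal(unname(ols$coefficients), c(1, 2), tolerance = 1e-10)
  expect_equal(ols$r_squared, 1, tolerance = 1e-10)

  p <- toy_panel(n_units = 10, n_months = 6, noise_sd = 0)
  ols2 <- fit_ols(p, "response", c("x1", "x2"))
  expect_lt(max(abs(ols2$coefficients - c(1, 0.5, -0.25))), 1e-10)

  # response unrelated to covariates: R2 near zero at large n
  set.seed(4)
  big <- toy_panel(n_units = 129, n_months = 36, noise_sd = 0)
  big$response <- sample(big$response)
  expect_lt(fit_ols(big, "response", c("x1", "x2"))$r_squared, 0.05)
})

test_that("rank-deficient designs fail naming the collinear column", {
  p <- toy_panel()
  p$x3 <- 2 * p$x1
  expect_error(fit_ols(p, "response", c("x1", "x2", "x3")),
               regexp = "x3", class = "gtwr_rank_deficient")
})

test_that("local GTWR solve agrees with a brute-force oracle", {
  p <- toy_panel(n_units = 5, n_months = 4, noise_sd = 0.2)  # 20 records
  h <- 400; tau <- 150
  fit <- fit_gtwr(p, "response", c("x1", "x2"), kernel_spec(h, tau))
  for (i in seq_len(nrow(p))) {
    expect_lt(max(abs(fit$coefficients[i, ] -
                        brute_local_beta(p, "response", c("x1", "x2"),
                                         i, h, tau))), 1e-10)
  }
  expect_equal(fit$residuals, p$response - fit$fitted)
  expect_gt(fit$trace_S, 0)
  expect_lt(fit$trace_S, nrow(p))
})

test_that("GWR equals GTWR on a single slice and both reduce to OLS as h grows", {
  p <- toy_panel(n_units = 12, n_months = 3, noise_sd = 0.1)
  slice <- p[p$t == 1, ]
  h <- 300
  gwr <- fit_gwr(slice, "response", c("x1", "x2"), h)
  gtwr0 <- fit_gtwr(slice, "response", c("x1", "x2"), kernel_spec(h, tau = 0))
  expect_lt(max(abs(gwr$coefficients - gtwr0$coefficients)), 1e-10)
  for (i in seq_len(nrow(slice))) {
    expect_lt(max(abs(gwr$coefficients[i, ] -
                        brute_local_beta(slice, "response", c("x1", "x2"),
                                         i, h, 0))), 1e-10)
  }
  # flat-kernel limit
  ols <- fit_ols(p, "response", c("x1", "x2"))
  flat <- fit_gtwr(p, "response", c("x1", "x2"),
                   kernel_spec(1e6 * 1500, tau = 0))
  expect_lt(max(abs(sweep(flat$coefficients, 2, ols$coefficients))), 1e-6)
})

test_that("local weighted residuals are orthogonal to the weighted design", {
  p <- toy_panel(n_units = 8, n_months = 4, noise_sd = 0.3)
  h <- 350; tau <- 100
  fit <- fit_gtwr(p, "response", c("x1", "x2"), kernel_spec(h, tau))
  X <- cbind(1, p$x1, p$x2)
  for (i in c(1L, 9L, 25L)) {
    d2 <- (p$u - p$u[i])^2 + (p$v - p$v[i])^2 + tau * (p$t - p$t[i])^2
    w <- exp(-d2 / h^2)
    r_local <- p$response - drop(X %*% fit$coefficients[i, ])
    expect_lt(max(abs(crossprod(X * w, r_local))), 1e-8)
  }
})

test_that("fits are invariant to coordinate translation and joint scaling", {
  p <- toy_panel(n_units = 8, n_months = 4, noise_sd = 0.2)
  spec <- kernel_spec(300, tau = 50)
  base <- fit_gtwr(p, "response", c("x1", "x2"), spec)
  shifted <- p
  shifted$u <- p$u + 5e4; shifted$v <- p$v - 1e3; shifted$t <- p$t + 7L
  expect_equal(fit_gtwr(shifted, "response", c("x1", "x2"),
                        spec)$coefficients,
               base$coefficients, tolerance = 1e-9)
  scaled <- p
  scaled$u <- p$u * 3; scaled$v <- p$v * 3
  spec3 <- kernel_spec(300 * 3, tau = 50 * 9)  # tau scales with distance^2
  expect_equal(fit_gtwr(scaled, "response", c("x1", "x2"),
                        spec3)$coefficients,
               base$coefficients, tolerance = 1e-9)
})

test_that("hat-matrix trace decreases as the bandwidth grows", {
  p <- toy_panel(n_units = 15, n_months = 4, noise_sd = 0.2)
  traces <- vapply(c(150, 300, 600, 1200, 2400), function(h)
    fit_gtwr(p, "response", c("x1", "x2"), kernel_spec(h, tau = 100))$trace_S,
    numeric(1))
  expect_true(all(diff(traces) < 0))
})

test_that("leave-one-out CV behaves like a prediction error", {
  # noise-free response inside the local model family: CV is essentially 0
  p <- toy_panel(n_units = 15, n_months = 4, noise_sd = 0)
  cv_ok <- cv_score(p, "response", c("x1", "x2"), kernel_spec(800, tau = 0),
                    model = "gtwr")
  expect_lt(cv_ok, 1e-6 * sum(p$response^2))
  # far-undersized bandwidth predicts poorly (or degenerates)
  noisy <- toy_panel(n_units = 15, n_months = 4, noise_sd = 0.3, seed = 8)
  cv_opt <- suppressWarnings(cv_score(noisy, "response", c("x1", "x2"),
                                      kernel_spec(500, 0), model = "gtwr"))
  cv_tiny <- suppressWarnings(cv_score(noisy, "response", c("x1", "x2"),
                                       kernel_spec(12, 0), model = "gtwr"))
  expect_true(is.na(cv_tiny) || cv_tiny > cv_opt)
})

test_that("bandwidth selection is deterministic and responds to surface structure", {
  p <- toy_panel(n_units = 12, n_months = 4, noise_sd = 0.05, seed = 21)
  s1 <- suppressWarnings(select_bandwidth(p, "response", c("x1", "x2"),
                                          model = "gtwr", tau_grid = c(0, 100)))
  s2 <- suppressWarnings(select_bandwidth(p, "response", c("x1", "x2"),
                                          model = "gtwr", tau_grid = c(0, 100)))
  expect_identical(s1$bandwidth, s2$bandwidth)
  expect_identical(s1$tau, s2$tau)

  # spatially constant coefficients: selection pushes to the upper bound
  expect_warning(
    sc <- select_bandwidth(p, "response", c("x1", "x2"), model = "gwr"),
    "boundary")
  rng <- range(dist(cbind(unique(p$u), unique(p$v))))
  expect_gt(sc$bandwidth, 0.5 * rng[2])

  # purely temporal coefficient variation: a positive tau is selected
  pt <- toy_panel(n_units = 12, n_months = 8, noise_sd = 0.05, seed = 22)
  pt$response <- 1 + (0.5 + sin(2 * pi * pt$t / 8)) * pt$x1 - 0.25 * pt$x2
  st <- suppressWarnings(select_bandwidth(pt, "response", c("x1", "x2"),
                                          model = "gtwr"))
  expect_gt(st$tau, 0)
})

test_that("panel contracts are validated", {
  p <- toy_panel()
  dup <- rbind(p, p[1, ])
  expect_error(fit_ols(dup, "response", c("x1", "x2")),
               class = "gtwr_config_error")
  drift <- p; drift$u[1] <- drift$u[1] + 1
  expect_error(fit_gtwr(drift, "response", c("x1", "x2"), kernel_spec(100)),
               class = "gtwr_config_error")
  expect_error(fit_ols(p, "response", c("x1", "nope")),
               class = "gtwr_config_error")
})
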