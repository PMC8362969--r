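test_that("VIF is 1 for orthogonal designs and follows the bivariate closed form", {
  # columns exactly orthogonal to each other and to the intercept
  set.seed(12)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(200 * 3), 200, 3))))[, 2:4]
  colnames(Q) <- c("a", "b", "c")
  v <- vif(Q)
  expect_lt(max(abs(v$vif - 1)), 1e-8)
  expect_false(any(v$flagged))

  # construct a pair with sample correlation exactly 0.9
  x1 <- scale(rnorm(500))[, 1]
  z <- scale(resid(lm(rnorm(500) ~ x1)))[, 1]
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * z
  expect_equal(cor(x1, x2), 0.9, tolerance = 1e-12)
  v2 <- vif(cbind(x1 = x1, x2 = x2))
  expect_equal(v2$vif, rep(1 / (1 - 0.81), 2), tolerance = 1e-6)
  expect_true(all(v2$flagged))  # 5.263 > 5

  # duplicated column: infinite, flagged
  v3 <- vif(cbind(x1 = x1, x2 = x2, x3 = x1))
  expect_true(is.infinite(v3$vif[1]) && is.infinite(v3$vif[3]))
  expect_true(all(v3$flagged[c(1, 3)]))
})

test_that("VIF is invariant to affine rescaling of covariates", {
  set.seed(3)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  X[, 2] <- X[, 1] * 0.6 + X[, 2]
  v1 <- vif(X)$vif
  X2 <- X
  X2[, 1] <- 100 * X[, 1] - 7
  X2[, 3] <- X[, 3] / 1000 + 2
  expect_equal(vif(X2)$vif, v1, tolerance = 1e-9)
})

test_that("Moran's I expectation, sign behavior, and degeneracy match theory", {
  W <- rook_weights(6, 6)
  # perfect checkerboard: strong negative autocorrelation
  chk <- outer(1:6, 1:6, function(r, c) (-1)^(r + c))
  m_neg <- morans_i(as.vector(chk), W, n_perm = 199, seed = 1)
  expect_equal(m_neg$expected_I, -1 / 35)
  expect_lt(m_neg$I, -0.9)
  expect_false(m_neg$clustered)
  # smooth north-south gradient: strong positive autocorrelation
  grad <- outer(1:6, 1:6, function(r, c) r)
  m_pos <- morans_i(as.vector(grad), W, n_perm = 999, seed = 2)
  expect_gt(m_pos$I, 0.5)
  expect_lt(m_pos$p_value, 0.05)
  expect_true(m_pos$clustered)
  # expectation for the study's unit count
  vals <- rnorm(129)
  m129 <- morans_i(vals, knn_weights(cbind(runif(129), runif(129))),
                   n_perm = 99, seed = 3)
  expect_identical(m129$expected_I, -1 / 128)
  expect_error(morans_i(rep(1, 36), W), class = "gtwr_degenerate_series")
})

test_that("knn weights are row-standardized with k neighbors each", {
  set.seed(6)
  W <- knn_weights(cbind(runif(30), runif(30)), k = 8)
  expect_equal(rowSums(W), rep(1, 30))
  expect_equal(unname(apply(W, 1, function(r) sum(r > 0))), rep(8, 30))
  expect_equal(diag(W), rep(0, 30))
})

test_that("nonstationarity table compares local IQR against twice the OLS SE", {
  # quartile convention check on {1,2,3,4,5}: IQR = 2
  expect_equal(diff(quantile(1:5, c(0.25, 0.75), type = 7, names = FALSE)), 2)

  # constant true coefficients, generous bandwidth: homogeneous verdict
  p <- toy_panel(n_units = 20, n_months = 6, noise_sd = 0.05, seed = 31)
  ols <- fit_ols(p, "response", c("x1", "x2"))
  gtwr_c <- fit_gtwr(p, "response", c("x1", "x2"), kernel_spec(5e4, tau = 0))
  gwr_c <- lapply(split(p, p$t), function(sl)
    fit_gwr(sl, "response", c("x1", "x2"), 5e4))
  tab_c <- nonstationarity_table(gtwr_c, gwr_c, ols)
  expect_false(any(tab_c$heterogeneous))

  # strongly spatially varying coefficient: heterogeneous verdict for x1
  pv <- toy_panel(n_units = 40, n_months = 6, noise_sd = 0.05, seed = 32)
  pv$response <- 1 + 3 * (pv$u / 1000) * pv$x1 - 0.25 * pv$x2 +
    rnorm(nrow(pv), 0, 0.05)
  olsv <- fit_ols(pv, "response", c("x1", "x2"))
  gtwr_v <- fit_gtwr(pv, "response", c("x1", "x2"), kernel_spec(250, tau = 0))
  gwr_v <- lapply(split(pv, pv$t), function(sl)
    fit_gwr(sl, "response", c("x1", "x2"), 250))
  tab_v <- nonstationarity_table(gtwr_v, gwr_v, olsv)
  expect_true(tab_v$heterogeneous[tab_v$variable == "x1"])
  expect_gt(tab_v$iqr_gtwr[tab_v$variable == "x1"],
            tab_v$twice_se_ols[tab_v$variable == "x1"])

  # record order must not matter
  perm <- sample(nrow(pv))
  gtwr_p <- fit_gtwr(pv[perm, ], "response", c("x1", "x2"),
                     kernel_spec(250, tau = 0))
  tab_p <- nonstationarity_table(gtwr_p, gwr_v, olsv)
  expect_equal(tab_p$iqr_gtwr, tab_v$iqr_gtwr, tolerance = 1e-10)

  expect_error(nonstationarity_table(gtwr_v, gwr_v,
                                     fit_ols(pv, "response", "x1")),
               class = "gtwr_config_error")
})

test_that("per-month residual screen summarizes clustering share", {
  cfg <- synthetic_config(n_units = 30L, n_months = 6L, n_stations = 5L,
                          seed = 17L)
  gp <- generate_panel(cfg)
  ols <- fit_ols(gp$panel, "response", c("aqi", "unemployment", "income"))
  scr <- moran_screen(gp$panel, ols, n_perm = 99, seed = 5)
  expect_equal(nrow(scr$per_month), 6L)
  expect_true(all(scr$per_month$p_value > 0 & scr$per_month$p_value <= 1))
  expect_gte(scr$share_clustered, 0)
  expect_lte(scr$share_clustered, 100)
})
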