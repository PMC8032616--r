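sim_clustered <- function(n_clusters = 120, m = 3, beta = c(-0.4, 0.7),
                          re_sd = 0.7, seed = 1) {
  set.seed(seed)
  n <- n_clusters * m
  id <- rep(seq_len(n_clusters), each = m)
  x <- rnorm(n)
  u <- rnorm(n_clusters, 0, re_sd)[id]
  y <- rbinom(n, 1, plogis(beta[1] + beta[2] * x + u))
  data.frame(y = y, x = x, id = id)
}

test_that("GEE with singleton clusters equals ordinary logistic ML", {
  d <- sim_clustered(300, 1, re_sd = 0, seed = 2)
  fit <- fit_gee_logistic(y ~ x, d, id = "id", working_corr = "exchangeable")
  gl <- glm(y ~ x, binomial, d)
  expect_lt(max(abs(fit$coefficients - coef(gl))), 1e-6)
  fit2 <- fit_gee_logistic(y ~ x, d, id = "id", working_corr = "independence")
  expect_lt(max(abs(fit2$coefficients - coef(gl))), 1e-6)
})

test_that("independence-GEE point estimates and robust SEs match glm + vcovCL", {
  d <- sim_clustered(100, 4, seed = 3)
  fit <- fit_gee_logistic(y ~ x, d, id = "id", working_corr = "independence")
  gl <- glm(y ~ x, binomial, d)
  expect_lt(max(abs(fit$coefficients - coef(gl))), 1e-6)
  vc <- sandwich::vcovCL(gl, cluster = d$id, type = "HC0", cadjust = FALSE)
  expect_lt(max(abs(fit$robust_se - sqrt(diag(vc))) / fit$robust_se), 1e-6)
})

test_that("the sandwich variance matches a longhand cluster-loop computation", {
  # 10-row example, 4 clusters, computed with explicit per-cluster matrices
  d <- data.frame(
    y = c(1, 0, 0, 1, 1, 0, 1, 0, 1, 0),
    x = c(0.5, -1.2, 0.3, 2.0, -0.7, 0.1, 1.5, -0.3, 0.9, -1.8),
    id = c(1, 1, 1, 2, 2, 3, 3, 3, 4, 4)
  )
  fit <- fit_gee_logistic(y ~ x, d, id = "id", working_corr = "independence")
  beta <- fit$coefficients
  X <- cbind(1, d$x)
  mu <- plogis(drop(X %*% beta))
  A <- mu * (1 - mu)
  B <- matrix(0, 2, 2)
  M <- matrix(0, 2, 2)
  for (cl in unique(d$id)) {
    i <- which(d$id == cl)
    Dc <- A[i] * X[i, , drop = FALSE]         # dmu/dbeta
    Vc <- diag(A[i], nrow = length(i))        # independence working covariance
    rc <- d$y[i] - mu[i]
    B <- B + t(Dc) %*% solve(Vc) %*% Dc
    gc <- t(Dc) %*% solve(Vc) %*% rc
    M <- M + gc %*% t(gc)
  }
  V_long <- solve(B) %*% M %*% solve(B)
  expect_lt(max(abs(fit$vcov - V_long)), 1e-10)
  expect_lt(max(abs(fit$robust_se - sqrt(diag(V_long)))), 1e-8)
})

test_that("duplicating every cluster leaves point estimates unchanged", {
  d <- sim_clustered(80, 3, seed = 4)
  d2 <- rbind(d, transform(d, id = id + 1000))
  f1 <- fit_gee_logistic(y ~ x, d, id = "id")
  f2 <- fit_gee_logistic(y ~ x, d2, id = "id")
  expect_lt(max(abs(f1$coefficients - f2$coefficients)), 1e-6)
  # twice the clusters: robust SEs shrink by ~sqrt(2)
  expect_equal(unname(f1$robust_se / f2$robust_se), rep(sqrt(2), 2),
               tolerance = 1e-4)
})

test_that("exchangeable correlation is estimated and CIs bracket the OR", {
  d <- sim_clustered(400, 4, seed = 5)
  fit <- fit_gee_logistic(y ~ x, d, id = "id", working_corr = "exchangeable")
  expect_gt(fit$alpha, 0)
  expect_true(all(fit$ci_lower <= fit$or & fit$or <= fit$ci_upper))
  expect_equal(unname(fit$or), unname(exp(fit$coefficients)))
  td <- tidy_gee(fit)
  expect_equal(td$estimate, unname(fit$coefficients))
})

test_that("degenerate inputs are rejected or flagged, not silently fit", {
  d <- sim_clustered(50, 2, seed = 6)
  d$y <- 0
  expect_error(fit_gee_logistic(y ~ x, d, id = "id"), "single class")
  d2 <- sim_clustered(50, 2, seed = 7)
  d2$z <- 1
  expect_error(fit_gee_logistic(y ~ x + z, d2, id = "id"), "constant covariate")
  d3 <- data.frame(x = c(-2, -1, -0.5, 0.5, 1, 2), id = 1:6)
  d3$y <- as.integer(d3$x > 0)
  expect_error(fit_gee_logistic(y ~ x, d3, id = "id"), "separation")
})

test_that("predictions are probabilities consistent with the linear predictor", {
  d <- sim_clustered(100, 2, seed = 8)
  fit <- fit_gee_logistic(y ~ x, d, id = "id")
  p <- predict(fit, d)
  expect_true(all(p > 0 & p < 1))
  eta <- predict(fit, d, type = "link")
  expect_equal(p, plogis(eta))
  expect_equal(unname(eta[1]),
               unname(fit$coefficients[1] + fit$coefficients[2] * d$x[1]))
})
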