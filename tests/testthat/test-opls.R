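test_that("a single column equal to y gives a perfect univariate fit", {
  y <- center_uv_vec(c(1, 4, 2, 8, 5, 7))
  fit <- fit_opls(matrix(y, ncol = 1), y, n_ortho = 0)
  expect_equal(unname(fit$w), 1)
  expect_equal(fit$r2y, 1, tolerance = 1e-12)
  expect_equal(unname(p_corr(fit, matrix(y, ncol = 1))), 1, tolerance = 1e-12)
})

test_that("OPLS with no orthogonal components reproduces the PLS1 oracle", {
  for (seed in c(1, 2, 3, 4, 5)) {
    pr <- random_problem(20, 10, seed)
    X <- scale_uv(pr$x)[, ]
    y <- center_uv_vec(pr$y)
    fit <- fit_opls(X, y, n_ortho = 0)
    oracle <- pls1_one_component(X, y)
    expect_equal(unname(fit$coefficients), unname(oracle$b), tolerance = 1e-8)
    expect_equal(unname(fit$t), unname(oracle$t), tolerance = 1e-8)
    expect_equal(unname(fit$w), unname(oracle$w), tolerance = 1e-8)
  }
})

test_that("orthogonal components satisfy the model invariants", {
  for (seed in 1:8) {
    pr <- random_problem(25, 12, seed)
    X <- scale_uv(pr$x)[, ]
    y <- center_uv_vec(pr$y)
    n_o <- 1 + seed %% 3
    fit <- fit_opls(X, y, n_ortho = n_o)
    expect_equal(sum(fit$w^2), 1, tolerance = 1e-10)
    for (j in seq_len(n_o)) {
      expect_equal(sum(fit$w_ortho[, j]^2), 1, tolerance = 1e-10)
      expect_lt(abs(sum(fit$t * fit$t_ortho[, j])) /
                  sqrt(sum(fit$t^2) * sum(fit$t_ortho[, j]^2)), 1e-8)
    }
    expect_true(fit$r2y >= 0 && fit$r2y <= 1)
    # coefficients reproduce fitted values from unfiltered scaled X
    expect_equal(drop(X %*% fit$coefficients), fit$fitted, tolerance = 1e-8)
    # variance bookkeeping: total = predictive + orthogonal + residual
    ssx <- fit$ssx
    expect_equal(ssx$total, ssx$predictive + sum(ssx$orthogonal) + ssx$residual,
                 tolerance = 1e-8 * ssx$total)
    pc <- p_corr(fit, X)
    expect_true(all(pc >= -1 - 1e-12 & pc <= 1 + 1e-12))
  }
})

test_that("a large y-orthogonal direction is absorbed without hurting the fit", {
  set.seed(21)
  y <- center_uv_vec(rnorm(30))
  z <- rnorm(30)
  # nearly (not exactly) orthogonal to y: the orthogonal structure must leak
  # into the loading through sample correlation for OPLS to see it
  z <- center_uv_vec(residuals(lm(z ~ y)) + 0.005 * y)
  X <- cbind(y1 = y, z = 10 * z)
  fit_with <- fit_opls(X, y, n_ortho = 1)
  expect_equal(fit_with$r2y, 1, tolerance = 1e-6)
  expect_gt(abs(fit_with$w_ortho[2, 1]), 0.99)
})

test_that("prediction is consistent in-sample and matches a hand-rolled projection", {
  pr <- random_problem(12, 3, 31)
  X <- scale_uv(pr$x)[, ]
  y <- center_uv_vec(pr$y)
  fit <- fit_opls(X[1:7, ], y[1:7], n_ortho = 1)
  # training rows reproduce in-sample fitted values
  expect_equal(spotopls:::opls_project(fit, X[1:7, ])$yhat, fit$fitted,
               tolerance = 1e-10)
  # zero row predicts the centered-space origin
  expect_equal(spotopls:::opls_project(fit, matrix(0, 1, 3))$yhat, 0,
               tolerance = 1e-12)
  # held-out rows: apply the filter-then-project algebra explicitly
  for (i in 8:12) {
    xi <- X[i, ]
    xi_f <- xi - drop(xi %*% fit$w_ortho[, 1]) * fit$p_ortho[, 1]
    yhat_manual <- sum(xi_f * fit$w) * fit$c
    expect_equal(spotopls:::opls_project(fit, X[i, , drop = FALSE])$yhat,
                 yhat_manual, tolerance = 1e-10)
  }
})

test_that("the predictive score maximizes covariance with y over unit projections", {
  set.seed(41)
  for (rep in 1:20) {
    X <- scale_uv(matrix(rnorm(30), 10, 3))[, ]
    y <- center_uv_vec(rnorm(10))
    fit <- fit_opls(X, y, n_ortho = 1)
    Xf <- X - tcrossprod(drop(X %*% fit$w_ortho[, 1]), fit$p_ortho[, 1])
    cov_opt <- abs(sum(drop(Xf %*% fit$w) * y))
    for (k in 1:25) {
      v <- rnorm(3)
      v <- v / sqrt(sum(v^2))
      expect_lte(abs(sum(drop(Xf %*% v) * y)), cov_opt + 1e-10)
    }
  }
})

test_that("cross-validated Q2 behaves at the noiseless and null extremes", {
  set.seed(51)
  X <- matrix(rnorm(40 * 3), 40, 3)
  b <- c(2, -1, 0.5)
  y <- drop(X %*% b)
  # noiseless linear y needs K - 1 orthogonal components for an exact fit
  cv <- cross_validated_q2(X, y, n_ortho = 2, n_folds = 7)
  expect_gt(cv$q2, 0.99)

  set.seed(52)
  Xn <- matrix(rnorm(38 * 50), 38, 50)
  yn <- rnorm(38)
  cvn <- cross_validated_q2(Xn, yn, n_ortho = 1, n_folds = 7)
  expect_lte(cvn$q2, 0.1)

  expect_error(cross_validated_q2(X[1:4, ], y[1:4], n_folds = 2), "at least 3")
})

test_that("Q2 does not exceed R2Y across random problems", {
  worse <- 0L
  for (seed in 1:100) {
    pr <- random_problem(21, 7, seed + 100)
    m <- opls(pr$x, pr$y, n_ortho = 1, cv_folds = 7)
    worse <- worse + (m$q2 > m$r2y + 1e-9)
  }
  expect_identical(worse, 0L)
})

test_that("the opls() interface predicts on the response scale and exposes methods", {
  set.seed(61)
  X <- matrix(rexp(200, 1e-3), 20, 10, dimnames = list(sprintf("s%02d", 1:20), 1:10))
  y <- as.numeric(50 + drop(scale(X[, 1])) * 5 + rnorm(20, 0, 0.5))
  m <- opls(X, y, n_ortho = 1)
  expect_s3_class(m, "opls")
  expect_equal(predict(m), fitted(m), tolerance = 1e-10)
  expect_equal(residuals(m), y - fitted(m))
  expect_length(coef(m), 10L)
  expect_gt(m$r2y, 0.9)
  expect_output(print(m), "R2Y")
  expect_output(print(summary(m)), "CV-ANOVA")
  # zero-variance y refused
  expect_error(opls(X, rep(3, 20)), "zero variance")
})

test_that("p(corr) sits at the closed-form extremes and near zero for noise", {
  set.seed(71)
  pr <- random_problem(38, 5, 72)
  X <- scale_uv(pr$x)[, ]
  y <- center_uv_vec(pr$y)
  fit <- fit_opls(X, y, n_ortho = 0)
  Xp <- cbind(X, t_copy = fit$t, t_neg = -fit$t)
  pc <- p_corr(fit, Xp)
  expect_equal(unname(pc["t_copy"]), 1, tolerance = 1e-10)
  expect_equal(unname(pc["t_neg"]), -1, tolerance = 1e-10)
  inside <- 0L
  for (seed in 1:60) {
    set.seed(seed + 300)
    noise_col <- matrix(rnorm(38))
    inside <- inside + (abs(p_corr(fit, noise_col)) < 0.5)
  }
  expect_gte(inside / 60, 0.95)
})
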