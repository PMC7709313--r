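test_that("exactly determined systems are interpolated", {
  m <- fit_mlr(matrix(c(0, 1), 2, 1), c(1, 3))
  expect_equal(unname(m$coefficients), c(1, 2))
  expect_equal(predict(m, matrix(3, 1, 1)), 7)
  expect_equal(m$fitted, c(1, 3))
})

test_that("least squares matches the hand-solved normal equations and lm", {
  m <- fit_mlr(matrix(1:3, 3, 1), c(1, 2, 2))
  expect_equal(unname(m$coefficients), c(2 / 3, 1 / 2))

  withr::with_seed(13, {
    x <- matrix(rnorm(200), 50, 4)
    y <- rnorm(50)
    m2 <- fit_mlr(x, y)
    ref <- unname(coef(lm(y ~ x)))
    expect_equal(unname(m2$coefficients), ref, tolerance = 1e-8)
    # residual orthogonality to the design columns
    expect_lt(max(abs(crossprod(cbind(1, x), m2$residuals))), 1e-8)
  })
})

test_that("collinear features keep predictions finite and unchanged", {
  withr::with_seed(4, {
    x <- matrix(rnorm(60), 20, 3)
    y <- rnorm(20)
    dup <- cbind(x, x[, 3])
    m_dup <- fit_mlr(dup, y)
    expect_true(all(is.finite(m_dup$coefficients)))
    expect_equal(predict(m_dup, dup), predict(fit_mlr(x, y), x),
                 tolerance = 1e-8)
  })
  expect_error(fit_mlr(matrix(0, 0, 2), numeric()), "zero samples")
  m <- fit_mlr(matrix(c(0, 1), 2, 1), c(1, 3))
  expect_error(predict(m, matrix(0, 1, 5)), "dimension")
})

test_that("coefficient recovery improves with sample size", {
  withr::with_seed(77, {
    beta <- runif(8, -1, 1)
    rmse <- vapply(c(50, 500), function(n) {
      x <- matrix(runif(n * 8), n, 8)
      y <- x %*% beta + rnorm(n, sd = 0.1)
      est <- fit_mlr(x, y)$coefficients[-1]
      sqrt(mean((est - beta)^2))
    }, numeric(1))
    expect_lt(rmse[2], rmse[1])
  })
})

test_that("the hidden activation is the odd tanh-shaped sigmoid", {
  expect_equal(hidden_activation(0), 0)
  expect_equal(hidden_activation(1), 2 / (1 + exp(-2)) - 1)
  expect_equal(hidden_activation(1), tanh(1))
  x <- seq(-3, 3, by = 0.5)
  expect_equal(hidden_activation(-x), -hidden_activation(x))
  expect_true(all(abs(hidden_activation(c(-50, 50))) <= 1))
})

test_that("network training is seed-reproducible and respects its budget", {
  withr::with_seed(31, {
    x <- matrix(runif(300), 60, 5)
    y <- as.numeric(x %*% runif(5) / 5)
  })
  a <- fit_ann(x, y, seed = 11)
  b <- fit_ann(x, y, seed = 11)
  expect_identical(a$par, b$par)
  expect_lte(nrow(a$trace), 100)
  expect_true(a$stopped %in% c("max_epochs", "mse_goal", "patience",
                               "damping_limit"))
  g <- glance(a)
  expect_identical(g$hidden, 10)
  expect_true(is.finite(g$test_mse))
  # the 3:1:1 split covers all samples exactly once
  sp <- a$split
  expect_setequal(c(sp$train, sp$validation, sp$test), seq_len(60))
})

test_that("the network fits a constant target and simple structure", {
  withr::with_seed(17, x <- matrix(runif(150), 30, 5))
  const <- fit_ann(x, rep(0.5, 30), seed = 2)
  expect_equal(predict(const, x), rep(0.5, 30), tolerance = 0.05)

  expect_error(fit_ann(matrix(1, 3, 2), 1:3), "at least 5")
})

test_that("the forward pass matches a hand computation", {
  withr::with_seed(1, x <- matrix(runif(40), 8, 5))
  m <- fit_ann(x, runif(8), hidden = 1, seed = 3)
  # overwrite with transparent weights: hidden dead, output bias 0.3
  m$par$w1[] <- 0
  m$par$b1[] <- 0
  m$par$w2[] <- 1
  m$par$b2 <- 0.3
  expect_equal(predict(m, x), rep(0.3, 8))
  expect_true(all(is.finite(predict(m, x * 1e6))))
  expect_error(predict(m, matrix(0, 1, 9)), "dimension")
})

test_that("validation MSE varies across random initializations", {
  withr::with_seed(23, {
    x <- matrix(runif(200), 40, 5)
    y <- as.numeric(x %*% runif(5) / 5 + rnorm(40, sd = 0.05))
  })
  val <- vapply(1:5, function(s) fit_ann(x, y, seed = s)$val_mse, numeric(1))
  expect_gt(stats::sd(val), 0)
})

test_that("tidy and glance expose model structure", {
  m <- fit_mlr(matrix(c(0, 1), 2, 1), c(1, 3))
  td <- tidy(m)
  expect_identical(td$term[1], "(Intercept)")
  expect_equal(nrow(td), 2L)
  expect_equal(glance(m)$nobs, 2L)

  withr::with_seed(6, x <- matrix(runif(50), 10, 5))
  a <- fit_ann(x, runif(10), hidden = 3, seed = 1)
  td_a <- tidy(a)
  expect_equal(nrow(td_a), 5 * 3 + 3 + 3 + 1)
  expect_equal(td_a$weight[td_a$layer == "hidden" & td_a$from != "(bias)"],
               as.numeric(t(a$par$w1)))
})
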