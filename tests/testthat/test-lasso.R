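test_that("lambda at or above lambda_max gives the all-zero solution", {
  set.seed(1)
  x <- matrix(rnorm(100 * 8), 100)
  y <- rnorm(100)
  xs <- radtiles:::standardize_x(x)$xs
  lambda_max <- max(abs(crossprod(xs, y - mean(y)))) / 100
  fit <- lasso_fit(x, y, lambda = lambda_max)
  expect_true(all(fit$coefficients == 0))
  fit2 <- lasso_fit(x, y, lambda = lambda_max * 1.5)
  expect_true(all(fit2$coefficients == 0))
  # just below lambda_max at least one coefficient activates
  fit3 <- lasso_fit(x, y, lambda = lambda_max * 0.95)
  expect_gt(sum(fit3$coefficients != 0), 0)
})

test_that("lambda = 0 on a well-conditioned design recovers least squares", {
  set.seed(2)
  x <- matrix(rnorm(200 * 5), 200)
  y <- x %*% c(1, -2, 0.5, 0, 3) + rnorm(200, sd = 0.2)
  fit <- lasso_fit(x, y, lambda = 0)
  ls <- coef(lm(y ~ x))
  expect_equal(unname(fit$coefficients), unname(ls[-1]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(ls[1]), tolerance = 1e-6)
})

test_that("orthonormal designs soft-threshold each coordinate exactly", {
  set.seed(3)
  n <- 64
  p <- 8
  # mean-zero orthogonal columns with (1/n) x_j' x_j = 1 (QR of a centered
  # matrix: Q's columns are linear combinations of centered columns)
  q <- qr.Q(qr(scale(matrix(rnorm(n * p), n), scale = FALSE))) * sqrt(n)
  beta_true <- c(3, -2, 1.5, -1, 0.5, 0.25, 0, 0)
  y <- q %*% beta_true + rnorm(n, sd = 0.1)
  lambda <- 0.8
  fit <- lasso_fit(as.data.frame(q), y, lambda = lambda)
  yc <- y - mean(y)
  # per-coordinate closed form on the standardized design
  std <- radtiles:::standardize_x(q)
  z <- drop(crossprod(std$xs, yc)) / n
  expected_std <- radtiles:::soft_threshold(z, lambda)
  got_std <- unname(fit$coefficients * std$scale)
  expect_equal(got_std, unname(expected_std), tolerance = 1e-6)
})

test_that("KKT residuals are below 1e-6 on random problems, CV or fixed lambda", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 80
    p <- 12
    x <- matrix(rnorm(n * p), n) %*% diag(exp(runif(p, -1, 2)))
    y <- x[, 1:3] %*% c(1, -1, 0.5) + rnorm(n)
    fit <- lasso_fit(x, y, lambda = exp(runif(1, -3, 0)))
    expect_lt(fit$kkt_residual, 1e-6)
  }
  set.seed(9)
  x <- matrix(rnorm(60 * 6), 60)
  y <- x[, 1] + rnorm(60)
  fit_cv <- lasso_fit(x, y, cv_folds = 5, seed = 4)
  expect_lt(fit_cv$kkt_residual, 1e-6)
})

test_that("solutions agree with glmnet at matched penalties", {
  set.seed(6)
  x <- matrix(rnorm(150 * 10), 150)
  y <- x[, 1] * 2 - x[, 2] + rnorm(150)
  for (lambda in c(0.02, 0.1, 0.5)) {
    fit <- lasso_fit(x, y, lambda = lambda)
    g <- glmnet::glmnet(x, y, lambda = lambda, standardize = TRUE,
                        thresh = 1e-12)
    expect_equal(unname(fit$coefficients), as.numeric(coef(g))[-1],
                 tolerance = 1e-6)
    expect_equal(fit$intercept, as.numeric(coef(g))[1], tolerance = 1e-6)
  }
})

test_that("prediction is invariant to the standardization round-trip", {
  set.seed(7)
  x <- as.data.frame(matrix(rnorm(100 * 6), 100) %*% diag(c(1, 10, 100, 0.1, 1, 5)))
  y <- rnorm(100)
  fit <- lasso_fit(x, y, lambda = 0.05)
  direct <- as.matrix(x[, fit$coefficients != 0, drop = FALSE]) %*%
    fit$coefficients[fit$coefficients != 0] + fit$intercept
  expect_equal(predict(fit, x), drop(direct), tolerance = 1e-10)
})

test_that("published model scores follow the two printed coefficients", {
  m <- published_model()
  expect_false(m$intercept_known)
  d <- data.frame(
    glszm_gray_level_variance = 100,
    glszm_large_area_low_gray_level_emphasis = 10000
  )
  expect_equal(predict(m, d), 1.71e-3 * 100 - 2.48e-5 * 10000, tolerance = 1e-12)
  expect_equal(predict(m, d), -0.077, tolerance = 1e-12)
  # all-zero features: score 0 with the unknown-intercept convention
  d0 <- data.frame(glszm_gray_level_variance = 0,
                   glszm_large_area_low_gray_level_emphasis = 0)
  expect_equal(predict(m, d0), 0)
  # increasing GLV strictly increases the score
  d1 <- d
  d1$glszm_gray_level_variance <- 200
  expect_gt(predict(m, d1), predict(m, d))
  expect_error(predict(m, data.frame(glszm_gray_level_variance = 1)),
               "large_area_low_gray")
})

test_that("tidy and glance summarise fitted models; JSON round-trips", {
  set.seed(8)
  x <- matrix(rnorm(60 * 4), 60)
  colnames(x) <- paste0("f", 1:4)
  y <- x[, 1] + rnorm(60)
  fit <- lasso_fit(x, y, lambda = 0.1)
  td <- tidy(fit)
  expect_equal(td$term[1], "(Intercept)")
  expect_equal(nrow(td), 5)
  gl <- glance(fit)
  expect_equal(gl$p, 4)
  expect_lt(gl$kkt_residual, 1e-6)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(predict(back, as.data.frame(x)), predict(fit, as.data.frame(x)))
})
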