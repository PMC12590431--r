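test_that("SE kernel has the closed form and PSD Gram matrices", {
  h <- gp_hyperparams(l = 1, sigma2 = 1, noise2 = 1e-8)
  x0 <- matrix(0, 1, 3)
  expect_equal(drop(kernel_se(x0, x0, h)), 1)                 # zero distance
  x1 <- matrix(c(1, 0, 0), 1, 3)
  expect_equal(drop(kernel_se(x0, x1, h)), exp(-0.5), tolerance = 1e-12)
  h2 <- gp_hyperparams(l = 0.4, sigma2 = 2.5, noise2 = 1e-8)
  expect_equal(drop(kernel_se(x1, x1, h2)), 2.5)
  set.seed(5)
  X <- matrix(runif(30), ncol = 3)
  K <- kernel_se(X, X, h2)
  expect_equal(K, t(K))
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
            -1e-10)
})

test_that("single-point and constant-target fits behave as limits", {
  h <- gp_hyperparams(l = 0.5, sigma2 = 1, noise2 = 1e-6)
  m1 <- gp_fit(matrix(0.3, 1, 1), 2.7, h)
  p <- gp_predict(m1, matrix(0.3, 1, 1))
  expect_equal(p$mean, 2.7, tolerance = 1e-6)
  expect_lt(p$sd, 2e-3)                     # ~ sqrt(noise2) level
  # constant targets: centred residuals are zero -> flat posterior mean
  X <- matrix(seq(0, 1, length.out = 6), ncol = 1)
  mC <- gp_fit(X, rep(0.8, 6), h)
  pC <- gp_predict(mC, matrix(c(0.05, 0.41, 0.99), ncol = 1))
  expect_equal(pC$mean, rep(0.8, 3), tolerance = 1e-9)
})

test_that("weights equal an independent dense solve", {
  set.seed(7)
  X <- matrix(c(0.1, 0.5, 0.9), ncol = 1)
  y <- c(0.2, 0.9, 0.4)
  h <- gp_hyperparams(l = 0.3, sigma2 = 1.2, noise2 = 1e-4)
  m <- gp_fit(X, y, h)
  K <- kernel_se(X, X, h) + diag(h$noise2, 3)
  w <- solve(K, y - mean(y))
  expect_equal(m$alpha, w, tolerance = 1e-10)
})

test_that("one-point posterior matches the closed form", {
  h <- gp_hyperparams(l = 1, sigma2 = 1, noise2 = 1e-10)
  m <- gp_fit(matrix(0, 1, 1), 2, h)
  p <- gp_predict(m, matrix(1, 1, 1))
  # centred target is 0, so the posterior reverts to the target mean (2)
  # with variance 1 - k^2; the classical zero-mean closed form applies to
  # the deviation from the mean
  expect_equal(p$sd, sqrt(1 - exp(-1)), tolerance = 1e-5)
  # explicit zero-mean check against brute force
  b <- brute_gp(matrix(0, 1, 1), 2, matrix(1, 1, 1), 1, 1, 1e-10)
  expect_equal(p$mean, b$mean, tolerance = 1e-8)
  expect_equal(p$sd, b$sd, tolerance = 1e-6)
})

test_that("posterior agrees with dense brute force on random problems", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:9, 1)
    d <- sample(1:3, 1)
    X <- matrix(runif(n * d), ncol = d)
    y <- runif(n)
    h <- gp_hyperparams(l = runif(1, 0.2, 1.5), sigma2 = runif(1, 0.3, 3),
                        noise2 = 10^runif(1, -5, -2))
    Xs <- matrix(runif(5 * d), ncol = d)
    p <- gp_predict(gp_fit(X, y, h), Xs)
    b <- brute_gp(X, y, Xs, h$l, h$sigma2, h$noise2)
    expect_equal(p$mean, b$mean, tolerance = 1e-8)
    expect_lt(max(abs(p$sd - b$sd)), 1e-7)
  }
})

test_that("far-field predictions revert to the prior", {
  h <- gp_hyperparams(l = 0.1, sigma2 = 0.7, noise2 = 1e-6)
  X <- matrix(runif(12, 0, 0.2), ncol = 3)
  y <- runif(4)
  m <- gp_fit(X, y, h)
  p <- gp_predict(m, matrix(c(1, 1, 1) * 5, 1, 3))
  expect_equal(p$mean, mean(y), tolerance = 1e-8)
  expect_equal(p$sd, sqrt(0.7), tolerance = 1e-8)
})

test_that("posterior std is bounded and never grows with more data", {
  set.seed(33)
  h <- gp_hyperparams(l = 0.4, sigma2 = 1.1, noise2 = 1e-6)
  for (rep in 1:10) {
    X <- matrix(runif(15), ncol = 3)
    y <- runif(5)
    Xs <- matrix(runif(18), ncol = 3)
    m5 <- gp_fit(X, y, h)
    p5 <- gp_predict(m5, Xs)
    expect_true(all(p5$sd >= 0 & p5$sd <= sqrt(h$sigma2) + 1e-9))
    x_new <- matrix(runif(3), 1, 3)
    m6 <- gp_fit(rbind(X, x_new), c(y, runif(1)), h)
    p6 <- gp_predict(m6, Xs)
    expect_true(all(p6$sd <= p5$sd + 1e-7))   # information monotonicity
  }
})

test_that("log marginal likelihood matches direct dense evaluation", {
  # scalar case, centred target zero
  h <- gp_hyperparams(l = 1, sigma2 = 0.5, noise2 = 0.1)
  expect_equal(log_marginal_likelihood(matrix(0, 1, 1), 3, h),
               -0.5 * log(0.6) - 0.5 * log(2 * pi), tolerance = 1e-12)
  set.seed(8)
  for (rep in 1:5) {
    X <- matrix(runif(10), ncol = 2)
    y <- runif(5)
    h <- gp_hyperparams(l = runif(1, 0.2, 1), sigma2 = runif(1, 0.2, 2),
                        noise2 = 10^runif(1, -6, -1))
    K <- kernel_se(X, X, h) + diag(h$noise2, 5)
    yc <- y - mean(y)
    direct <- -0.5 * drop(t(yc) %*% solve(K, yc)) -
      0.5 * determinant(K)$modulus[1] - 2.5 * log(2 * pi)
    expect_equal(log_marginal_likelihood(X, y, h), direct,
                 tolerance = 1e-8)
  }
  # huge noise drives the evidence to -Inf through the determinant term
  X <- matrix(runif(10), ncol = 2)
  y <- runif(5)
  l1 <- log_marginal_likelihood(X, y, gp_hyperparams(0.5, 1, 1))
  l2 <- log_marginal_likelihood(X, y, gp_hyperparams(0.5, 1, 1e6))
  l3 <- log_marginal_likelihood(X, y, gp_hyperparams(0.5, 1, 1e12))
  expect_gt(l1, l2)
  expect_gt(l2, l3)
})

test_that("near-duplicate inputs are averaged before fitting", {
  h <- gp_hyperparams(l = 0.5, sigma2 = 1, noise2 = 1e-8)
  X <- matrix(c(0.2, 0.2 + 1e-14, 0.8), ncol = 1)
  m <- gp_fit(X, c(0.4, 0.6, 1.0), h)
  expect_equal(nrow(m$X), 2)
  expect_equal(m$y[1], 0.5)
})

test_that("model JSON round-trip reproduces predictions bit-exactly", {
  set.seed(12)
  X <- matrix(runif(24), ncol = 3)
  y <- runif(8)
  m <- gp_fit(X, y, gp_hyperparams(0.37, 0.9, 1e-6))
  f <- tempfile(fileext = ".json")
  gp_save(m, f)
  m2 <- gp_load(f)
  Xs <- matrix(runif(15), ncol = 3)
  expect_identical(gp_predict(m, Xs), gp_predict(m2, Xs))
})

test_that("fit and predict at n = 108 stay within the time budget", {
  set.seed(3)
  X <- matrix(runif(108 * 3), ncol = 3)
  y <- runif(108)
  h <- gp_hyperparams(0.3, 0.5, 1e-6)
  t0 <- proc.time()[3]
  m <- gp_fit(X, y, h)
  gp_predict(m, matrix(runif(30), ncol = 3))
  expect_lt(proc.time()[3] - t0, 0.05 * 10)  # generous CI margin over 50 ms
})
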