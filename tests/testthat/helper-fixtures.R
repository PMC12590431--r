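# Shared fixtures and small independent oracles used across the suite.

# L2 star discrepancy (Warnock's closed form): brute-force double sum,
# independent of the generator under test.
l2_star_discrepancy <- function(u) {
  n <- nrow(u)
  d <- ncol(u)
  t1 <- 3^(-d)
  t2 <- sum(apply(1 - u^2, 1, prod)) / (n * 2^d)
  s <- 0
  for (i in seq_len(n)) {
    m <- pmax(matrix(u[i, ], n, d, byrow = TRUE), u)
    s <- s + sum(apply(1 - m, 1, prod))
  }
  sqrt(t1 - 2 * t2 + s / n^2)
}

# dense brute-force GP posterior (independent of gp_fit/gp_predict)
brute_gp <- function(X, y, Xs, l, sigma2, noise2) {
  k <- function(A, B) {
    d2 <- as.matrix(stats::dist(rbind(A, B)))^2
    d2 <- d2[seq_len(nrow(A)), nrow(A) + seq_len(nrow(B)), drop = FALSE]
    sigma2 * exp(-d2 / (2 * l^2))
  }
  n <- nrow(X)
  K <- sigma2 * exp(-as.matrix(stats::dist(X))^2 / (2 * l^2)) +
    diag(noise2, n)
  Ks <- k(X, Xs)
  ym <- mean(y)
  Kinv <- solve(K)
  mu <- ym + drop(t(Ks) %*% Kinv %*% (y - ym))
  v <- sigma2 - diag(t(Ks) %*% Kinv %*% Ks)
  list(mean = unname(mu), sd = unname(sqrt(pmax(v, 0))))
}

# a small but non-trivial oracle parameter set for fast physics tests
fast_params <- function(...) {
  oracle_params(calibrated = TRUE, n_shells = 30, steps_ramp = 120,
                steps_unload = 30, steps_gap = 60, ...)
}
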