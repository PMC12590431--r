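# Gaussian-process regression with the isotropic squared-exponential
# kernel, exact Cholesky-based posterior, written against normalised
# (unit-cube) inputs.

#' GP hyperparameters
#'
#' @param l kernel length-scale in normalised input units.
#' @param sigma2 kernel variance.
#' @param noise2 observation-noise variance.
#' @return object of class `gp_hyperparams`.
#' @details The admissible search box is `l` in `[1e-2, 10]`, `sigma2` in
#'   `[1e-4, 1e2]`, `noise2` in `[1e-8, 1]`.
#' @export
gp_hyperparams <- function(l = 0.3, sigma2 = 1, noise2 = 1e-6) {
  stopifnot(l > 0, sigma2 > 0, noise2 > 0)
  structure(list(l = l, sigma2 = sigma2, noise2 = noise2),
            class = "gp_hyperparams")
}

.gp_box <- list(l = c(1e-2, 10), sigma2 = c(1e-4, 1e2), noise2 = c(1e-8, 1))

.as_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1)
  X
}

.sqdist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Squared-exponential kernel
#'
#' `k(x, x') = sigma2 * exp(-||x - x'||^2 / (2 l^2))`.
#'
#' @param X,X2 input matrices (rows are points); `X2` defaults to `X`.
#' @param h a [gp_hyperparams()].
#' @return covariance matrix `nrow(X)` x `nrow(X2)`.
#' @export
kernel_se <- function(X, X2 = X, h) {
  stopifnot(inherits(h, "gp_hyperparams"))
  A <- .as_matrix(X); B <- .as_matrix(X2)
  h$sigma2 * exp(-.sqdist(A, B) / (2 * h$l^2))
}

# average rows of X closer than tol (duplicate protection)
.dedupe <- function(X, y, tol = 1e-12) {
  n <- nrow(X)
  if (n < 2) return(list(X = X, y = y))
  key <- integer(n)
  grp <- 0L
  for (i in seq_len(n)) {
    if (key[i] == 0L) {
      grp <- grp + 1L
      d2 <- rowSums((X - matrix(X[i, ], n, ncol(X), byrow = TRUE))^2)
      key[d2 <= tol^2 & key == 0L] <- grp
    }
  }
  if (grp == n) return(list(X = X, y = y))
  Xo <- do.call(rbind, lapply(seq_len(grp), function(g)
    colMeans(X[key == g, , drop = FALSE])))
  yo <- vapply(seq_len(grp), function(g) mean(y[key == g]), numeric(1))
  list(X = Xo, y = yo)
}

.chol_jitter <- function(K, jitter0 = 1e-10, jitter_max = 1e-6) {
  j <- 0
  repeat {
    L <- tryCatch(t(chol(K + diag(j, nrow(K)))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = j))
    j <- if (j == 0) jitter0 else j * 100
    if (j > jitter_max)
      stop("covariance matrix ill-conditioned even after jitter")
  }
}

#' Fit an exact GP regression model
#'
#' Centres the targets, forms the SE-kernel Gram matrix plus noise,
#' factorises it (Cholesky, with jitter escalation on failure) and stores
#' the weight vector for posterior evaluation. Near-duplicate inputs
#' (closer than 1e-12) are averaged before fitting.
#'
#' @param X training inputs, rows in normalised coordinates.
#' @param y training targets (survival fractions).
#' @param h a [gp_hyperparams()].
#' @return object of class `gp_model`.
#' @export
gp_fit <- function(X, y, h) {
  X <- .as_matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 1,
            inherits(h, "gp_hyperparams"))
  dd <- .dedupe(X, y)
  X <- dd$X; y <- dd$y
  ymean <- mean(y)
  yc <- y - ymean
  K <- kernel_se(X, X, h) + diag(h$noise2, nrow(X))
  f <- .chol_jitter(K)
  alpha <- backsolve(t(f$L), forwardsolve(f$L, yc))
  structure(list(X = X, y = y, ymean = ymean, h = h, L = f$L,
                 alpha = alpha, jitter = f$jitter), class = "gp_model")
}

#' GP posterior mean and standard deviation
#'
#' @param model a [gp_model][gp_fit()].
#' @param Xs query inputs (rows in normalised coordinates).
#' @param include_noise if `TRUE`, add the observation-noise variance to
#'   the predictive variance; default is the latent-function std.
#' @return data.frame with columns `mean` and `sd`.
#' @export
gp_predict <- function(model, Xs, include_noise = FALSE) {
  stopifnot(inherits(model, "gp_model"))
  Xs <- .as_matrix(Xs)
  ks <- kernel_se(model$X, Xs, model$h)      # n x m
  mu <- model$ymean + drop(crossprod(ks, model$alpha))
  v <- forwardsolve(model$L, ks)
  var <- model$h$sigma2 - colSums(v^2)
  if (include_noise) var <- var + model$h$noise2
  data.frame(mean = mu, sd = sqrt(pmax(var, 0)))
}

#' Log marginal likelihood of a GP fit
#'
#' The standard Gaussian evidence on centred targets:
#' `-1/2 y' (K + s_n^2 I)^-1 y - 1/2 log det(K + s_n^2 I) - n/2 log(2 pi)`.
#' Returns `-Inf` if the Gram matrix cannot be factorised.
#'
#' @inheritParams gp_fit
#' @return scalar log marginal likelihood.
#' @export
log_marginal_likelihood <- function(X, y, h) {
  m <- tryCatch(gp_fit(X, y, h), error = function(e) NULL)
  if (is.null(m)) return(-Inf)
  yc <- m$y - m$ymean
  n <- length(yc)
  val <- -0.5 * sum(yc * m$alpha) - sum(log(diag(m$L))) -
    0.5 * n * log(2 * pi)
  if (!is.finite(val)) -Inf else val
}

#' Serialise / restore a GP model as JSON
#'
#' Stores hyperparameters, training data and the target-centring constant;
#' reloading refits deterministically so predictions reproduce bit-exactly.
#'
#' @param model a [gp_model][gp_fit()].
#' @param path JSON file path.
#' @return `gp_save`: `path` invisibly; `gp_load`: the restored model.
#' @export
gp_save <- function(model, path) {
  stopifnot(inherits(model, "gp_model"))
  obj <- list(hyperparams = unclass(model$h), X = model$X, y = model$y)
  # I(17) = 17 *significant* digits, enough for exact double round-trip
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname gp_save
#' @export
gp_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  h <- do.call(gp_hyperparams, as.list(obj$hyperparams))
  gp_fit(.as_matrix(obj$X), as.numeric(obj$y), h)
}
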