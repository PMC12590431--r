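# Near-optimal region extraction and fixed-pressure survival maps.
# Predicted survival means are truncated to the physical plateau (1.0)
# before thresholding: a Gaussian posterior can overshoot the saturation
# plateau near sharp features, and "within 99 % of the maximum" is only
# meaningful against the physical maximum.

#' Identify the near-optimal process region
#'
#' Samples `n_candidates` random constraint-respecting points in the
#' space, predicts survival with the surrogate (posterior means truncated
#' to the survival plateau of 1 before comparison), keeps candidates
#' whose predicted mean is within `frac` of the maximum (inclusive
#' threshold `mean >= frac * max(mean)`), and wraps the survivors in a
#' 3-D alpha shape computed in normalised coordinates.
#'
#' @param model a fitted [gp_model][gp_fit()] over normalised inputs.
#' @param space the [design_space()] the model was trained on.
#' @param n_candidates number of random candidates (default 5000).
#' @param frac threshold fraction of the maximum predicted mean.
#' @param alpha alpha-shape radius, `Inf`, or `"auto"` (smallest radius
#'   giving one connected component).
#' @param seed integer seed for the candidate draw.
#' @param candidate_space optional [design_space()] to sample candidates
#'   from (e.g. a restricted laboratory press window); must lie inside
#'   `space`, which remains the normalisation reference. Defaults to
#'   `space`.
#' @return object of class `region_result`: `candidates` (points with
#'   predicted `mean`/`sd`), `retained`, `threshold`, `shape` (an
#'   [alpha_shape_3d()] or `NULL`), `alpha` and `degenerate` flag.
#' @export
find_optimal_region <- function(model, space, n_candidates = 5000,
                                frac = 0.99, alpha = "auto", seed = 1L,
                                candidate_space = space) {
  stopifnot(inherits(model, "gp_model"), frac > 0, frac <= 1)
  cand <- random_design(candidate_space, n_candidates, seed)
  pr <- gp_predict(model, normalize_points(cand, space))
  cand$mean <- pmin(pr$mean, 1)
  cand$sd <- pr$sd
  threshold <- frac * max(cand$mean)
  retained <- cand[cand$mean >= threshold, , drop = FALSE]
  shape <- NULL
  degenerate <- FALSE
  if (nrow(retained) >= 4) {
    shape <- tryCatch(
      alpha_shape_3d(normalize_points(retained, space), alpha),
      error = function(e) NULL)
    if (is.null(shape)) degenerate <- TRUE
  } else degenerate <- TRUE
  structure(list(candidates = cand, retained = retained,
                 threshold = threshold, shape = shape,
                 alpha = if (!is.null(shape)) shape$alpha else NA_real_,
                 degenerate = degenerate, space = space),
            class = "region_result")
}

#' @export
print.region_result <- function(x, ...) {
  cat(sprintf(
    "Near-optimal region: %d of %d candidates retained (threshold %.4f)\n",
    nrow(x$retained), nrow(x$candidates), x$threshold))
  if (!is.null(x$shape))
    cat(sprintf("  alpha = %.4g, shape volume = %.4g (normalised units)\n",
                x$shape$alpha, x$shape$volume))
  if (x$degenerate) cat("  (no alpha shape: degenerate/too few points)\n")
  invisible(x)
}

#' Survival map over a fixed-main-pressure slice
#'
#' Evaluates an evaluator (the oracle or a fitted surrogate) on a regular
#' (speed x precompression) lattice at a fixed main compression pressure.
#'
#' @param evaluator either an [oracle_params()] bundle (evaluate the
#'   physics oracle) or a [gp_model][gp_fit()] (evaluate the surrogate
#'   posterior mean).
#' @param space a [design_space()] containing the slice.
#' @param fixed_main main compression pressure of the slice, MPa.
#' @param speed_range,pre_range numeric length-2 axis ranges.
#' @param n_speed,n_pre lattice resolution.
#' @return object of class `survival_map`: `speed` and `pre` axis vectors
#'   and `values`, an `n_speed` x `n_pre` matrix of survival fractions.
#' @export
survival_map <- function(evaluator, space, fixed_main,
                         speed_range = c(4000, 5000), pre_range = c(0, 50),
                         n_speed = 11, n_pre = 11) {
  grid <- slice_grid(space, fixed_main, speed_range, pre_range,
                     n_speed, n_pre)
  s <- if (inherits(evaluator, "oracle_params")) {
    evaluate_oracle(grid, evaluator)$survival_frac
  } else if (inherits(evaluator, "gp_model")) {
    gp_predict(evaluator, normalize_points(grid, space))$mean
  } else stop("evaluator must be oracle_params or gp_model")
  values <- t(matrix(s, nrow = n_pre, ncol = n_speed))  # [speed, pre]
  structure(list(main_MPa = fixed_main,
                 speed = seq(speed_range[1], speed_range[2],
                             length.out = n_speed),
                 pre = seq(pre_range[1], pre_range[2], length.out = n_pre),
                 values = values, grid = grid, survival = s),
            class = "survival_map")
}

#' @export
print.survival_map <- function(x, ...) {
  cat(sprintf(
    "Survival map at main = %g MPa: %d x %d grid, range %.4f - %.4f\n",
    x$main_MPa, length(x$speed), length(x$pre), min(x$values),
    max(x$values)))
  invisible(x)
}

#' Plot a survival map
#'
#' Filled image of survival fraction over (speed, precompression).
#'
#' @param x a [survival_map()].
#' @param ... passed to [graphics::image()].
#' @export
plot.survival_map <- function(x, ...) {
  graphics::image(x$speed, x$pre, x$values,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "compression speed (mm/min)",
                  ylab = "precompression pressure (MPa)",
                  main = sprintf("survival at main = %g MPa", x$main_MPa),
                  ...)
  invisible(x)
}
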