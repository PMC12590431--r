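#' Define the tabletting process-parameter space
#'
#' The design space is the box of admissible (compression speed,
#' precompression pressure, main compression pressure) settings, together
#' with the process constraint that precompression never exceeds the main
#' compression pressure. Defaults cover laboratory through industrial press
#' speeds (0-5000 mm/min) and main pressures of 50-400 MPa.
#'
#' @param speed numeric length-2, compression-speed bounds in mm/min.
#' @param main numeric length-2, main-compression-pressure bounds in MPa.
#' @param pre_max upper cap on precompression pressure in MPa, or the
#'   string `"main"` (the default) meaning precompression is bounded only
#'   by the main pressure of the same point.
#' @return an object of class `design_space`.
#' @examples
#' sp <- design_space()
#' lab <- design_space_lab()
#' @export
design_space <- function(speed = c(0, 5000), main = c(50, 400),
                         pre_max = "main") {
  stopifnot(length(speed) == 2L, length(main) == 2L,
            is.numeric(speed), is.numeric(main))
  if (speed[1] >= speed[2]) stop("speed bounds must satisfy lo < hi")
  if (main[1] >= main[2]) stop("main pressure bounds must satisfy lo < hi")
  if (main[1] <= 0) stop("main pressure must be positive")
  if (speed[1] < 0) stop("compression speed cannot be negative")
  pre_cap <- if (identical(pre_max, "main")) main[2] else as.numeric(pre_max)
  if (pre_cap < 0) stop("pre_max cannot be negative")
  structure(list(speed_lo = speed[1], speed_hi = speed[2],
                 main_lo = main[1], main_hi = main[2],
                 pre_lo = 0, pre_hi = min(pre_cap, main[2])),
            class = "design_space")
}

#' @describeIn design_space Restricted space matching a benchtop compaction
#'   analyser: speeds 10-180 mm/min, pressures up to 374 MPa.
#' @export
design_space_lab <- function() {
  design_space(speed = c(10, 180), main = c(50, 374), pre_max = 374)
}

#' @export
print.design_space <- function(x, ...) {
  cat("Tabletting design space\n")
  cat(sprintf("  speed: %g - %g mm/min\n", x$speed_lo, x$speed_hi))
  cat(sprintf("  main pressure: %g - %g MPa\n", x$main_lo, x$main_hi))
  cat(sprintf("  precompression: 0 - %g MPa (and always <= main)\n", x$pre_hi))
  invisible(x)
}

#' Construct a table of process points
#'
#' @param speed compression speed, mm/min (vector).
#' @param pre precompression pressure, MPa.
#' @param main main compression pressure, MPa.
#' @return data.frame with columns `speed_mm_min`, `pre_MPa`, `main_MPa`.
#' @export
process_points <- function(speed, pre, main) {
  d <- data.frame(speed_mm_min = as.numeric(speed),
                  pre_MPa = as.numeric(pre),
                  main_MPa = as.numeric(main))
  if (any(d$speed_mm_min < 0)) stop("compression speed cannot be negative")
  if (any(d$pre_MPa < 0)) stop("precompression pressure cannot be negative")
  if (any(d$main_MPa <= 0)) stop("main pressure must be positive")
  if (any(d$pre_MPa > d$main_MPa + 1e-9))
    stop("precompression pressure cannot exceed the main pressure")
  d
}

.check_in_space <- function(points, space, tol = 1e-9) {
  ok <- points$speed_mm_min >= space$speed_lo - tol &
    points$speed_mm_min <= space$speed_hi + tol &
    points$main_MPa >= space$main_lo - tol &
    points$main_MPa <= space$main_hi + tol &
    points$pre_MPa >= -tol &
    points$pre_MPa <= pmin(space$pre_hi, points$main_MPa) + tol
  ok
}

#' Sobol experimental design on the constrained process space
#'
#' Maps scrambled Sobol unit-cube points into the space. Speed and main
#' pressure use affine maps of the first and third coordinates; the
#' precompression coordinate is mapped measure-preservingly as
#' `pre = u2 * min(pre_cap, main)`, so the process constraint holds by
#' construction and the low-discrepancy structure is retained.
#'
#' @param space a [design_space()].
#' @param n number of points.
#' @param seed integer scrambling seed.
#' @return data.frame of process points (see [process_points()]).
#' @examples
#' head(sobol_design(design_space(), 30, seed = 1))
#' @export
sobol_design <- function(space, n, seed = 1L) {
  stopifnot(inherits(space, "design_space"))
  if (n < 0) stop("`n` must be >= 0")
  u <- sobol_unit_cube(n, seed)
  if (n == 0L) return(process_points(numeric(0), numeric(0), numeric(0)))
  speed <- space$speed_lo + u[, 1] * (space$speed_hi - space$speed_lo)
  main <- space$main_lo + u[, 3] * (space$main_hi - space$main_lo)
  pre <- u[, 2] * pmin(space$pre_hi, main)
  process_points(speed, pre, main)
}

#' Uniform random design with constraint rejection
#'
#' Draws points uniformly in the box and discards draws violating
#' `pre < main`, redrawing until `n` feasible points are kept. This is the
#' candidate generator used for the global near-optimum search.
#'
#' @inheritParams sobol_design
#' @return data.frame of process points satisfying `pre < main` strictly.
#' @export
random_design <- function(space, n, seed = 1L) {
  stopifnot(inherits(space, "design_space"))
  if (n < 0) stop("`n` must be >= 0")
  if (n == 0L) return(process_points(numeric(0), numeric(0), numeric(0)))
  with_local_seed(seed, {
    speed <- numeric(0); pre <- numeric(0); main <- numeric(0)
    while (length(speed) < n) {
      m <- max(n - length(speed), 64L)
      s_i <- stats::runif(m, space$speed_lo, space$speed_hi)
      p_i <- stats::runif(m, 0, space$pre_hi)
      q_i <- stats::runif(m, space$main_lo, space$main_hi)
      keep <- p_i < q_i
      speed <- c(speed, s_i[keep])
      pre <- c(pre, p_i[keep])
      main <- c(main, q_i[keep])
    }
    process_points(speed[seq_len(n)], pre[seq_len(n)], main[seq_len(n)])
  })
}

#' Map process points to normalised unit-cube coordinates
#'
#' Affine min-max scaling against the global bounds of the space; the
#' precompression axis is normalised by the global cap `min(pre_hi,
#' main_hi)`, not by each point's own main pressure, so the map is a fixed
#' affine transform and the isotropic kernel metric is well defined.
#'
#' @param points data.frame of process points.
#' @param space a [design_space()].
#' @return numeric matrix, `nrow(points)` x 3, all entries in `[0, 1]`.
#' @export
normalize_points <- function(points, space) {
  stopifnot(inherits(space, "design_space"))
  if (!all(.check_in_space(points, space)))
    stop("point outside the design space bounds")
  cbind(speed = (points$speed_mm_min - space$speed_lo) /
          (space$speed_hi - space$speed_lo),
        pre = points$pre_MPa / space$pre_hi,
        main = (points$main_MPa - space$main_lo) /
          (space$main_hi - space$main_lo))
}

#' Regular grid on a fixed-main-pressure slice
#'
#' Builds the `n_speed` x `n_pre` lattice (endpoints included, row-major
#' with precompression varying fastest) used for survival maps at a fixed
#' main compression pressure.
#'
#' @param space a [design_space()].
#' @param fixed_main main compression pressure of the slice, MPa.
#' @param speed_range,pre_range numeric length-2 ranges inside the space.
#' @param n_speed,n_pre lattice resolution per axis (>= 2).
#' @return data.frame of process points.
#' @export
slice_grid <- function(space, fixed_main, speed_range, pre_range,
                       n_speed, n_pre) {
  stopifnot(inherits(space, "design_space"), n_speed >= 2, n_pre >= 2)
  if (pre_range[2] > fixed_main)
    stop("slice precompression range exceeds the fixed main pressure")
  if (speed_range[1] < space$speed_lo || speed_range[2] > space$speed_hi ||
      fixed_main < space$main_lo || fixed_main > space$main_hi ||
      pre_range[2] > space$pre_hi)
    stop("slice not inside the design space")
  speed <- seq(speed_range[1], speed_range[2], length.out = n_speed)
  pre <- seq(pre_range[1], pre_range[2], length.out = n_pre)
  g <- expand.grid(pre_MPa = pre, speed_mm_min = speed,
                   KEEP.OUT.ATTRS = FALSE)
  process_points(g$speed_mm_min, g$pre_MPa, rep(fixed_main, nrow(g)))
}
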