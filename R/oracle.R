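#' Drucker-Prager Cap parameter set
#'
#' Parameters of the three-surface DPC yield description used for powder
#' compaction: shear failure line, elliptical cap and smoothing transition
#' surface.
#'
#' @param d cohesion, MPa.
#' @param beta internal friction angle, degrees (0 < beta < 90).
#' @param alpha_t transition-surface shape parameter (0 to 0.1).
#' @param R_ecc cap eccentricity (> 0).
#' @param pa_of_ev hardening law: function mapping volumetric plastic
#'   strain to the cap evolution parameter p_a (MPa), monotone
#'   non-decreasing.
#' @return object of class `dpc_params`.
#' @export
dpc_params <- function(d = 0.5, beta = 60, alpha_t = 0.02, R_ecc = 0.55,
                       pa_of_ev = function(ev) 5 + 250 * ev) {
  stopifnot(d >= 0, beta > 0, beta < 90, alpha_t >= 0, alpha_t <= 0.1,
            R_ecc > 0, is.function(pa_of_ev))
  structure(list(d = d, beta = beta, alpha_t = alpha_t, R_ecc = R_ecc,
                 pa_of_ev = pa_of_ev), class = "dpc_params")
}

#' Evaluate the three Drucker-Prager Cap surfaces
#'
#' Returns the shear-failure, cap and transition surface functions at a
#' stress state (p, q); a value of zero means the state lies on that
#' surface.
#'
#' @param p hydrostatic stress, MPa.
#' @param q von Mises equivalent stress, MPa.
#' @param params a [dpc_params()].
#' @param ev volumetric plastic strain (sets the cap position through the
#'   hardening law).
#' @return named list with components `Fs`, `Fc`, `Ft` (MPa).
#' @export
dpc_surfaces <- function(p, q, params, ev = 0) {
  stopifnot(inherits(params, "dpc_params"), is.finite(p), is.finite(q))
  beta <- params$beta * pi / 180
  d <- params$d
  alpha <- params$alpha_t
  R <- params$R_ecc
  pa <- params$pa_of_ev(ev)
  coh <- d + pa * tan(beta)            # cohesion arm at the cap position
  Fs <- q - p * tan(beta) - d
  Fc <- sqrt((p - pa)^2 + (R * q / (1 + alpha - alpha / cos(beta)))^2) -
    R * coh
  Ft <- sqrt((p - pa)^2 + (q - (1 - alpha / cos(beta)) * coh)^2) -
    alpha * coh
  list(Fs = Fs, Fc = Fc, Ft = Ft)
}

#' Reduced-order oracle parameters
#'
#' Parameter bundle for the compaction-thermal-viability simulator:
#' densification law, thermal material properties, heat-partition and
#' friction coefficients, press kinematics and the thermal-tolerance law.
#' `oracle_params()` returns the calibrated set shipped with the package
#' (anchored to the behaviour of the validated finite-element model it
#' emulates); `oracle_params(calibrated = FALSE)` returns the raw
#' engineering defaults used as the calibration starting point.
#'
#' @param calibrated logical; load the packaged calibrated parameter set.
#' @param ... named overrides of individual parameters.
#' @return object of class `oracle_params`.
#' @details Fields (units): `rho` kg/m3, `Cp` J/(kg K), `k_cond` W/(m K),
#'   `eta_pl` (-) fraction of plastic work to heat, `mu_fric` (-) wall
#'   friction coefficient, `K_rad` (-) radial-to-axial stress ratio,
#'   `h_wall` W/(m2 K) wall heat-transfer coefficient, `T_tool` C tooling
#'   temperature, `T_crit` C inactivation onset, `z_T` K per log-cycle
#'   kill, `s_max` survival plateau, `RD_0`/`RD_max` initial/limit
#'   relative density, `P_c` MPa densification pressure constant, `E_el`
#'   MPa effective unloading modulus, `radius` m, `H_final` m compact
#'   height, `gap_s` s inter-compression gap, `speed_min` mm/min internal
#'   speed clamp, `n_shells` radial cells, `steps_*` time resolution.
#' @export
oracle_params <- function(calibrated = TRUE, ...) {
  p <- list(
    rho = 1200, Cp = 1500, k_cond = 0.2,
    eta_pl = 0.9, mu_fric = 0.3, K_rad = 0.4,
    h_wall = 2000, T_tool = 25, T_crit = 42, z_T = 6, s_max = 1.0,
    RD_0 = 0.45, RD_max = 0.95, P_c = 80, E_el = 8000,
    radius = 3e-3, H_final = 3.4e-3, gap_s = 0.2, speed_min = 1,
    n_shells = 50, steps_ramp = 200, steps_unload = 40, steps_gap = 100,
    time_int = FALSE)
  if (calibrated) {
    f <- system.file("extdata", "oracle_params.json", package = "probitab")
    if (nzchar(f)) {
      cal <- jsonlite::read_json(f, simplifyVector = TRUE)
      p[names(cal$params)] <- cal$params
    }
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown oracle parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  stopifnot(p$rho > 0, p$Cp > 0, p$k_cond > 0, p$eta_pl > 0, p$eta_pl <= 1,
            p$K_rad > 0, p$K_rad < 1, p$z_T > 0,
            p$s_max >= 1, p$s_max <= 1.1,
            p$RD_0 > 0, p$RD_max > p$RD_0, p$RD_max < 1, p$P_c > 0)
  structure(p, class = "oracle_params")
}

# densification law and its inverse (pressures in MPa)
.rd_of_p <- function(P, par) par$RD_max - (par$RD_max - par$RD_0) *
  exp(-P / par$P_c)
.p_of_rd <- function(rd, par) -par$P_c *
  log((par$RD_max - rd) / (par$RD_max - par$RD_0))
# punch position (m) from powder fill, as a function of relative density
.x_of_rd <- function(rd, par) {
  h0 <- par$H_final * par$RD_max / par$RD_0   # fill height
  h0 * (1 - par$RD_0 / rd)
}

.seg <- function(label, t0, dur, n, P_fun, devdt_fun, vslip,
                 P_bound = 0) {
  if (dur <= 0) return(NULL)
  tm <- t0 + (seq_len(n) - 0.5) * dur / n
  list(label = rep(label, n), t_mid = tm, dt = rep(dur / n, n),
       P = P_fun(tm - t0), devdt = devdt_fun(tm - t0),
       vslip = rep(vslip, n), t_end = t0 + dur, P_bound = P_bound)
}

#' Build the compaction pressure schedule for a process point
#'
#' Converts a (speed, precompression, main pressure) setting into a
#' piecewise press schedule: plastic ramp to the precompression pressure,
#' elastic unload, a fixed inter-compression gap, elastic reload, plastic
#' ramp to the main pressure, and final unload. Ramp durations are punch
#' travel divided by punch speed, with travel given by the exponential
#' densification law `RD(P) = RD_max - (RD_max - RD_0) exp(-P/P_c)`.
#'
#' @param point one-row data.frame of process coordinates
#'   (see [process_points()]).
#' @param params an [oracle_params()] bundle.
#' @return object of class `compaction_schedule`: per-step midpoint arrays
#'   of time, axial pressure (MPa), volumetric strain rate (1/s) and punch
#'   slip speed (m/s), plus a segment summary table.
#' @export
build_schedule <- function(point, params = oracle_params()) {
  stopifnot(inherits(params, "oracle_params"), nrow(point) == 1L)
  speed <- max(point$speed_mm_min, params$speed_min)
  if (speed <= 0) stop("compression speed must be positive after clamping")
  v <- speed / 60000                       # mm/min -> m/s
  pre <- point$pre_MPa
  main <- point$main_MPa
  h0 <- params$H_final * params$RD_max / params$RD_0

  plastic_seg <- function(label, t0, P_from, P_to, n) {
    rd_a <- .rd_of_p(P_from, params)
    rd_b <- .rd_of_p(P_to, params)
    x_a <- .x_of_rd(rd_a, params)
    dur <- (.x_of_rd(rd_b, params) - x_a) / v
    rd_of_tau <- function(tau) params$RD_0 * h0 / (h0 - (x_a + v * tau))
    .seg(label, t0, dur, n,
         P_fun = function(tau) .p_of_rd(pmin(rd_of_tau(tau), rd_b), params),
         devdt_fun = function(tau) v * rd_of_tau(tau) / (params$RD_0 * h0),
         vslip = v, P_bound = P_to)
  }
  elastic_seg <- function(label, t0, P_hi, n, loading) {
    rd <- .rd_of_p(P_hi, params)
    h <- h0 * params$RD_0 / rd               # compact height at P_hi
    travel <- h * P_hi / params$E_el         # elastic recovery travel
    dur <- travel / v
    .seg(label, t0, dur, n,
         P_fun = if (loading) function(tau) P_hi * tau / dur
         else function(tau) P_hi * (1 - tau / dur),
         devdt_fun = function(tau) rep(0, length(tau)),
         vslip = v, P_bound = P_hi)
  }

  segs <- list()
  t0 <- 0
  add <- function(s) {
    if (!is.null(s)) {
      segs[[length(segs) + 1L]] <<- s
      t0 <<- s$t_end
    }
  }
  if (pre > 0) {
    add(plastic_seg("pre_ramp", t0, 0, pre, params$steps_ramp))
    add(elastic_seg("pre_unload", t0, pre, params$steps_unload,
                    loading = FALSE))
    add(.seg("gap", t0, params$gap_s, params$steps_gap,
             P_fun = function(tau) rep(0, length(tau)),
             devdt_fun = function(tau) rep(0, length(tau)), vslip = 0))
    add(elastic_seg("reload", t0, pre, params$steps_unload, loading = TRUE))
  }
  if (main > pre)
    add(plastic_seg("main_ramp", t0, pre, main, params$steps_ramp))
  add(elastic_seg("main_unload", t0, main, params$steps_unload,
                  loading = FALSE))

  segments <- do.call(rbind, lapply(segs, function(s) {
    data.frame(label = s$label[1], t_start = s$t_mid[1] - s$dt[1] / 2,
               t_end = s$t_end, P_peak = max(s$P, s$P_bound))
  }))
  structure(list(
    t_mid = unlist(lapply(segs, `[[`, "t_mid")),
    dt = unlist(lapply(segs, `[[`, "dt")),
    P = unlist(lapply(segs, `[[`, "P")),
    devdt = unlist(lapply(segs, `[[`, "devdt")),
    vslip = unlist(lapply(segs, `[[`, "vslip")),
    label = unlist(lapply(segs, `[[`, "label")),
    segments = segments, t_total = t0, point = point,
    speed_eff = speed), class = "compaction_schedule")
}

#' Plastic and frictional heat-source rates along a schedule
#'
#' The volumetric plastic source is `eta_pl * P * |de_v/dt|` (W/m3); the
#' frictional wall flux is `mu_fric * K_rad * P * v_slip` (W/m2), with the
#' radial wall stress taken as `K_rad` times the axial pressure. Unloading
#' and gap segments carry no plastic source (elastic recovery convention).
#'
#' @param schedule a [build_schedule()] result.
#' @param params an [oracle_params()] bundle.
#' @param t times (s) at which to evaluate; default: all step midpoints.
#' @return list with vectors `qp` (W/m3) and `qf` (W/m2).
#' @export
heat_sources <- function(schedule, params = oracle_params(),
                         t = schedule$t_mid) {
  stopifnot(inherits(schedule, "compaction_schedule"))
  idx <- findInterval(t, cumsum(schedule$dt) - schedule$dt, all.inside = TRUE)
  if (any(t < 0 | t > schedule$t_total + 1e-12))
    stop("time outside the schedule")
  P_pa <- schedule$P[idx] * 1e6
  list(qp = params$eta_pl * P_pa * abs(schedule$devdt[idx]),
       qf = params$mu_fric * params$K_rad * P_pa * schedule$vslip[idx])
}

#' Solve the radial thermal problem for a compaction schedule
#'
#' Integrates the 1-D radial energy balance with an implicit finite-volume
#' scheme: uniform volumetric plastic heating, frictional heating as a
#' lateral wall flux, Robin cooling into the die wall, a lumped axial
#' Robin sink for the punch-face contact (`2 h_wall / H_final` per unit
#' volume), symmetry at the centre and initial temperature equal to the
#' tooling temperature.
#'
#' @param schedule a [build_schedule()] result.
#' @param params an [oracle_params()] bundle.
#' @param n_shells number of radial finite-volume cells (>= 3).
#' @param substeps time-refinement factor (each schedule step is split
#'   into this many solver steps).
#' @param keep_history if `TRUE`, retain the full temperature history.
#' @return object of class `thermal_field`: shell centres and volumes (per
#'   unit height), final and running-peak temperature per shell, and an
#'   energy audit (enthalpy rise, source input, wall loss, all J/m).
#' @export
solve_thermal <- function(schedule, params = oracle_params(),
                          n_shells = params$n_shells, substeps = 1,
                          keep_history = FALSE) {
  stopifnot(inherits(schedule, "compaction_schedule"), n_shells >= 3,
            substeps >= 1)
  src <- heat_sources(schedule, params)
  dt <- rep(schedule$dt / substeps, each = substeps)
  qp <- rep(src$qp, each = substeps)
  qf <- rep(src$qf, each = substeps)
  sol <- .cpp_solve_radial_heat(dt, qp, qf, params$radius,
                                as.integer(n_shells), params$rho * params$Cp,
                                params$k_cond, params$h_wall,
                                2 * params$h_wall / params$H_final,
                                params$T_tool, params$T_tool, keep_history)
  sol$t_edges <- c(0, cumsum(dt))
  structure(sol, class = "thermal_field")
}

#' Thermal-tolerance survival law
#'
#' Log-linear (z-value) inactivation driven by the peak temperature a
#' location experiences: survival is the plateau `s_max` below the onset
#' temperature `T_crit` and falls one log-cycle per `z_T` kelvin above it.
#'
#' @param peak_T peak exposure temperature(s), degrees C.
#' @param params an [oracle_params()] bundle (uses `T_crit`, `z_T`,
#'   `s_max`).
#' @return survival fraction(s) in `(0, s_max]`.
#' @export
survival_of_history <- function(peak_T, params = oracle_params()) {
  stopifnot(all(is.finite(peak_T)))
  params$s_max * 10^(-pmax(0, peak_T - params$T_crit) / params$z_T)
}

#' Volume-averaged survival over a thermal field
#'
#' Shell-volume-weighted mean of the thermal-tolerance law applied to each
#' shell's peak temperature (cylindrical weights proportional to r dr).
#'
#' @param field a [solve_thermal()] result.
#' @param params an [oracle_params()] bundle.
#' @return scalar survival fraction.
#' @export
volume_average_survival <- function(field, params = oracle_params()) {
  stopifnot(inherits(field, "thermal_field"))
  s <- survival_of_history(field$T_peak, params)
  sum(s * field$shell_volumes) / sum(field$shell_volumes)
}

#' Evaluate the reduced-order oracle at process points
#'
#' Deterministic composition of [build_schedule()], [solve_thermal()] and
#' [volume_average_survival()]: the package's stand-in for the validated
#' finite-element compaction model as the source of survival labels.
#'
#' @param points data.frame of process points (one or more rows).
#' @param params an [oracle_params()] bundle.
#' @return data.frame with one row per point: `survival_frac`, `peak_T_C`
#'   (peak core temperature), `plastic_heat_J` and `friction_heat_J`
#'   (totals over the cycle for the whole compact).
#' @examples
#' evaluate_oracle(process_points(180, 0, 208))
#' @export
evaluate_oracle <- function(points, params = oracle_params()) {
  out <- lapply(seq_len(nrow(points)), function(i) {
    sch <- build_schedule(points[i, , drop = FALSE], params)
    fld <- solve_thermal(sch, params)
    src <- heat_sources(sch, params)
    vtot <- sum(fld$shell_volumes) * params$H_final
    aw <- 2 * pi * params$radius * params$H_final
    data.frame(survival_frac = volume_average_survival(fld, params),
               peak_T_C = max(fld$T_peak),
               plastic_heat_J = sum(src$qp * sch$dt) * vtot,
               friction_heat_J = sum(src$qf * sch$dt) * aw)
  })
  do.call(rbind, out)
}
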