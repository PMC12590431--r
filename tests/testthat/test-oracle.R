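test_that("DPC surfaces evaluate the three yield functions", {
  par <- dpc_params(d = 1, beta = 45)
  # shear line intercept: q = d at p = 0
  expect_equal(dpc_surfaces(0, 1, par)$Fs, 0)
  # hand evaluation: Fs = q - p tan(beta) - d
  expect_equal(dpc_surfaces(2, 4, par)$Fs, 4 - 2 - 1)
  # cap apex on the hydrostatic axis: q = 0, p = pa + R (d + pa tan beta)
  pa <- par$pa_of_ev(0.1)
  p_apex <- pa + par$R_ecc * (1 + pa * tan(45 * pi / 180))
  expect_equal(dpc_surfaces(p_apex, 0, par, ev = 0.1)$Fc, 0,
               tolerance = 1e-12)
  expect_error(dpc_params(beta = 95), "beta")
})

test_that("schedules have the right segments, peaks and speed scaling", {
  par <- fast_params()
  # no precompression -> no precompression segments
  s0 <- build_schedule(process_points(180, 0, 208), par)
  expect_false(any(c("pre_ramp", "pre_unload", "gap", "reload") %in%
                     s0$segments$label))
  expect_equal(max(s0$segments$P_peak), 208)
  # with precompression: all segments, and both peaks exact
  s1 <- build_schedule(process_points(180, 62, 208), par)
  expect_setequal(s1$segments$label,
                  c("pre_ramp", "pre_unload", "gap", "reload",
                    "main_ramp", "main_unload"))
  expect_equal(s1$segments$P_peak[s1$segments$label == "pre_ramp"], 62)
  expect_equal(s1$segments$P_peak[s1$segments$label == "main_ramp"], 208)
  gap <- s1$segments[s1$segments$label == "gap", ]
  expect_equal(gap$t_end - gap$t_start, par$gap_s)
  # doubling speed halves every ramp duration
  s2 <- build_schedule(process_points(360, 62, 208), par)
  d1 <- s1$segments$t_end - s1$segments$t_start
  d2 <- s2$segments$t_end - s2$segments$t_start
  ramps <- s1$segments$label != "gap"
  expect_equal(d2[ramps], d1[ramps] / 2, tolerance = 1e-12)
  # pressures never negative and within the main peak
  expect_true(all(s1$P >= 0 & s1$P <= 208 + 1e-9))
})

test_that("heat sources follow the constitutive forms", {
  par <- fast_params(eta_pl = 0.9, mu_fric = 0.2, K_rad = 0.4)
  sch <- build_schedule(process_points(600, 50, 300), par)
  src <- heat_sources(sch, par)
  # zero pressure (gap) -> both sources zero
  gap_idx <- sch$label == "gap"
  expect_true(all(src$qp[gap_idx] == 0 & src$qf[gap_idx] == 0))
  # unload segments carry no plastic source (elastic convention)
  un <- sch$label %in% c("pre_unload", "main_unload", "reload")
  expect_true(all(src$qp[un] == 0))
  expect_true(all(src$qp >= 0 & src$qf >= 0))
  # hand unit check: eta 0.9, P 100 MPa, |dev/dt| 0.5/s -> 4.5e7 W/m3
  i <- which.min(abs(sch$P - 100) + ifelse(sch$devdt > 0, 0, Inf))
  expect_equal(src$qp[i],
               0.9 * sch$P[i] * 1e6 * sch$devdt[i], tolerance = 1e-12)
  expect_equal(0.9 * 100e6 * 0.5, 4.5e7)
  expect_error(heat_sources(sch, par, t = -1), "outside")
})

test_that("thermal solver: equilibrium, lumped heating, grid convergence", {
  par <- fast_params()
  sch <- build_schedule(process_points(1000, 0, 200), par)
  # no sources at equilibrium temperature -> stays at T_tool
  par0 <- fast_params(eta_pl = 1e-12, mu_fric = 0)
  f0 <- solve_thermal(build_schedule(process_points(1000, 0, 200), par0),
                      par0)
  expect_equal(f0$T_final, rep(par0$T_tool, 30), tolerance = 1e-9)
  # uniform volumetric source, insulated wall: Delta T = q dt / (rho Cp)
  q <- 2e6
  dt <- rep(0.01, 100)
  sol <- probitab:::.cpp_solve_radial_heat(
    dt, rep(q, 100), rep(0, 100), 3e-3, 50, 2e6, 0.2, 0, 0, 25, 25, FALSE)
  expect_equal(sol$T_final, rep(25 + 1.0, 50), tolerance = 1e-9)
  # shell volumes tile the cylinder cross-section
  expect_equal(sum(sol$shell_volumes), pi * (3e-3)^2, tolerance = 1e-12)
  # refinement oracle: core peak temperature and the survival functional
  # are stable under an 8x finer grid (the outermost cell's value is an
  # O(dr) average of the frictional-flux boundary layer by construction,
  # so pointwise wall-cell temperature is not the convergence measure)
  f1 <- solve_thermal(sch, par, n_shells = 50)
  f2 <- solve_thermal(sch, par, n_shells = 400, substeps = 4)
  expect_equal(f1$T_peak[1], f2$T_peak[1], tolerance = 0.01)
  expect_equal(volume_average_survival(f1, par),
               volume_average_survival(f2, par), tolerance = 0.01)
})

test_that("energy is conserved with an insulated wall", {
  par <- fast_params(h_wall = 0)
  for (pt in list(c(4500, 0, 400), c(180, 133, 374), c(600, 50, 150))) {
    sch <- build_schedule(process_points(pt[1], pt[2], pt[3]), par)
    fld <- solve_thermal(sch, par)
    expect_equal(fld$enthalpy_rise, fld$energy_in,
                 tolerance = 5e-3)
    expect_equal(fld$energy_wall_loss, 0)
  }
})

test_that("temperatures never undershoot the tooling temperature", {
  par <- fast_params()
  for (pt in list(c(5000, 50, 400), c(10, 0, 50), c(180, 200, 250))) {
    fld <- solve_thermal(build_schedule(process_points(pt[1], pt[2],
                                                       pt[3]), par), par)
    expect_true(all(fld$T_peak >= par$T_tool - 1e-9))
    expect_true(all(fld$T_final >= par$T_tool - 1e-9))
  }
})

test_that("the survival law is the z-value form with a plateau", {
  par <- fast_params(T_crit = 40, z_T = 8, s_max = 1)
  expect_equal(survival_of_history(c(20, 39.9, 40), par), c(1, 1, 1))
  expect_equal(survival_of_history(48, par), 0.1)
  expect_equal(survival_of_history(56, par), 0.01)
  peaks <- seq(30, 120, by = 1)
  s <- survival_of_history(peaks, par)
  expect_true(all(diff(s) <= 0))
})

test_that("volume averaging is the shell-volume-weighted mean", {
  par <- fast_params()
  fld <- solve_thermal(build_schedule(process_points(1000, 0, 300), par),
                       par)
  # constant survival integrand: average equals the constant
  par_flat <- fast_params(T_crit = 1000)
  expect_equal(volume_average_survival(fld, par_flat), 1)
  # two equal-volume shells at survival 1 and 0.5 average to 0.75
  fake <- structure(list(T_peak = c(25, 40 + 8 * log10(2)),
                         shell_volumes = c(1, 1)),
                    class = "thermal_field")
  par2 <- fast_params(T_crit = 40, z_T = 8, s_max = 1)
  expect_equal(volume_average_survival(fake, par2), 0.75)
  # brute-force quadrature on the real field
  s <- survival_of_history(fld$T_peak, par)
  expect_equal(volume_average_survival(fld, par),
               sum(s * fld$shell_volumes) / sum(fld$shell_volumes),
               tolerance = 1e-6)
})

test_that("oracle evaluation is deterministic and within bounds", {
  par <- oracle_params()
  pts <- random_design(design_space(), 50, seed = 17)
  r1 <- evaluate_oracle(pts, par)
  r2 <- evaluate_oracle(pts, par)
  expect_identical(r1, r2)
  expect_true(all(r1$survival_frac > 0 & r1$survival_frac <= par$s_max))
})

test_that("survival decreases with main pressure above 150 MPa", {
  par <- oracle_params()
  mains <- seq(150, 400, length.out = 20)
  for (cond in list(c(4500, 0), c(800, 40), c(180, 0))) {
    s <- evaluate_oracle(process_points(rep(cond[1], 20), rep(cond[2], 20),
                                        mains), par)$survival_frac
    expect_true(all(diff(s) <= 1e-9))
  }
})

test_that("calibration is a fixed point when anchors are already met", {
  par <- oracle_params(calibrated = FALSE)
  anch <- list(list(name = "already_met", target = 1, scale = 1,
                    type = "ge", eval = function(p) 2))
  cal <- calibrate_oracle(par, anchors = anch, free = "z_T")
  expect_equal(cal$params$z_T, par$z_T)
  expect_equal(unname(cal$residuals), 0)
  expect_true(cal$converged)
})

test_that("calibration preconditions are enforced", {
  par <- oracle_params(calibrated = FALSE)
  expect_error(calibrate_oracle(par, anchors = list()), "anchor")
  one <- default_anchors()[4]
  expect_error(calibrate_oracle(par, anchors = one,
                                free = c("T_crit", "z_T")),
               "underdetermined")
  expect_error(calibrate_oracle(par, free = "radius"), "free")
})

test_that("the packaged calibrated parameters satisfy the anchors", {
  cal_file <- system.file("extdata", "oracle_params.json",
                          package = "probitab")
  expect_true(nzchar(cal_file))
  stored <- jsonlite::read_json(cal_file, simplifyVector = TRUE)
  expect_true(all(abs(unlist(stored$residuals)) < 0.15))
  # stored residuals reproduce from the shipped parameter set
  par <- oracle_params()
  vals <- vapply(default_anchors(), function(a) a$eval(par), numeric(1))
  expect_equal(unname(vals), unname(unlist(stored$anchor_values)),
               tolerance = 1e-8)
})
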