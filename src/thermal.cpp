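#include <Rcpp.h>
using namespace Rcpp;

// Implicit (backward-Euler) finite-volume solver for the 1-D radial energy
// balance  rho*Cp dT/dt = (1/r) d/dr (k r dT/dr) + qp,  with a Robin wall
// condition  -k dT/dr|_R = h (T_wall - T_tool) - qf  and symmetry at r = 0.
// Per-step plastic source qp [W/m^3] is volumetric and uniform; frictional
// source qf [W/m^2] enters as a lateral wall flux. Quantities are per unit
// tablet height (the axial direction is lumped). Diffusion and the Robin
// term are treated implicitly, sources explicitly, so the scheme is
// unconditionally stable and exactly conservative in the insulated case.
//
// The compact also touches the punches on its flat faces; that contact is
// not resolved axially but enters as a lumped volumetric Robin sink
// ax_loss * (T - T_tool) with ax_loss = 2 h / H [W/(m^3 K)] (fin
// approximation for a thin cylinder cooled on both faces).
//
// [[Rcpp::export(name = ".cpp_solve_radial_heat")]]
List solve_radial_heat(NumericVector dt, NumericVector qp, NumericVector qf,
                       double radius, int n_shells, double rho_cp,
                       double k_cond, double h_wall, double ax_loss,
                       double t_tool, double t0, bool keep_history) {
  const int M = dt.size();
  if (qp.size() != M || qf.size() != M)
    stop("dt, qp and qf must have equal length");
  if (n_shells < 3) stop("n_shells must be >= 3");
  const int N = n_shells;
  const double dr = radius / N;
  const double pi = M_PI;

  std::vector<double> rf(N + 1), vol(N), af(N + 1);
  for (int i = 0; i <= N; ++i) {
    rf[i] = dr * i;
    af[i] = 2.0 * pi * rf[i];           // face area per unit height
  }
  double vtot = 0.0;
  for (int i = 0; i < N; ++i) {
    vol[i] = pi * (rf[i + 1] * rf[i + 1] - rf[i] * rf[i]);
    vtot += vol[i];
  }
  const double aw = af[N];              // lateral wall area per unit height
  // half-cell resistance correction at the wall face: the Robin exchange
  // and the frictional flux act at the face, separated from the last cell
  // centre by dr/2 of conduction; beta rescales both onto the cell
  const double g_half = 2.0 * k_cond / dr;
  const double beta_w = g_half / (h_wall + g_half);
  const double h_eff = h_wall * beta_w;

  NumericVector T(N, t0), Tmax(N, t0);
  NumericMatrix hist;
  if (keep_history) hist = NumericMatrix(M + 1, N);
  if (keep_history) for (int i = 0; i < N; ++i) hist(0, i) = t0;

  std::vector<double> a(N), b(N), c(N), d(N), cp(N), dp(N);
  double e_source = 0.0, e_wall = 0.0;

  for (int m = 0; m < M; ++m) {
    const double h = dt[m];
    // face conductances k*A/dr between cells i and i+1
    for (int i = 0; i < N; ++i) {
      const double gw = (i == 0) ? 0.0 : k_cond * af[i] / dr;
      const double ge = (i == N - 1) ? 0.0 : k_cond * af[i + 1] / dr;
      a[i] = -h * gw;
      c[i] = -h * ge;
      b[i] = rho_cp * vol[i] + h * (gw + ge) + h * ax_loss * vol[i];
      d[i] = rho_cp * vol[i] * T[i] + h * qp[m] * vol[i] +
        h * ax_loss * vol[i] * t_tool;
    }
    // wall cell: implicit Robin cooling + explicit frictional flux
    b[N - 1] += h * h_eff * aw;
    d[N - 1] += h * (h_eff * aw * t_tool + beta_w * qf[m] * aw);

    // Thomas algorithm
    cp[0] = c[0] / b[0];
    dp[0] = d[0] / b[0];
    for (int i = 1; i < N; ++i) {
      const double den = b[i] - a[i] * cp[i - 1];
      cp[i] = c[i] / den;
      dp[i] = (d[i] - a[i] * dp[i - 1]) / den;
    }
    T[N - 1] = dp[N - 1];
    for (int i = N - 2; i >= 0; --i) T[i] = dp[i] - cp[i] * T[i + 1];

    for (int i = 0; i < N; ++i) {
      if (!R_finite(T[i]))
        stop("thermal solve produced non-finite temperature at step %d", m + 1);
      if (T[i] > Tmax[i]) Tmax[i] = T[i];
      if (keep_history) hist(m + 1, i) = T[i];
    }
    e_source += h * (qp[m] * vtot + beta_w * qf[m] * aw);
    e_wall += h * h_eff * aw * (T[N - 1] - t_tool);
    for (int i = 0; i < N; ++i)
      e_wall += h * ax_loss * vol[i] * (T[i] - t_tool);
  }

  double enthalpy = 0.0;
  for (int i = 0; i < N; ++i) enthalpy += rho_cp * vol[i] * (T[i] - t0);

  NumericVector rc(N), v_out(N);
  for (int i = 0; i < N; ++i) {
    rc[i] = 0.5 * (rf[i] + rf[i + 1]);
    v_out[i] = vol[i];
  }

  List out = List::create(
      _["T_final"] = T, _["T_peak"] = Tmax, _["r_centres"] = rc,
      _["shell_volumes"] = v_out, _["enthalpy_rise"] = enthalpy,
      _["energy_in"] = e_source, _["energy_wall_loss"] = e_wall);
  if (keep_history) out["history"] = hist;
  return out;
}
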