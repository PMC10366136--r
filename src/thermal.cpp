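#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Material codes must match R side: 0 air, 1 tissue, 2 vaporized (air-like).

static inline double harmonic_k(double ka, double kb) {
  if (ka <= 0.0 || kb <= 0.0) return 0.0;
  return 2.0 * ka * kb / (ka + kb);
}

// Advance the enthalpy field n_steps explicit FTCS steps of
//   dH/dt = div(k grad T) + S
// with a 7-point Laplacian, harmonic-mean face conductivity and adiabatic
// (zero-flux) lattice boundaries. Temperature is recovered from enthalpy each
// step: linear below the latent-heat plateau, clamped at T_v above it for
// tissue (voxel removal is decided by the caller between calls). Optionally
// accumulates the Arrhenius damage integral on tissue voxels whose
// temperature exceeds omega_T_min (the rate is numerically negligible below
// coagulation temperatures; the cutoff only skips exp() calls).
// [[Rcpp::export]]
List thermal_damage_steps_cpp(NumericVector H_in, NumericVector S,
                              NumericVector Omega_in, IntegerVector material,
                              IntegerVector dims, double h, double dt,
                              int n_steps,
                              double k_air, double rho_cp_air,
                              double k_tis, double rho_cp_tis,
                              double T_v,
                              double A, double Ea_over_R,
                              double omega_T_min,
                              bool accumulate_omega) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (H_in.size() != nvox || S.size() != nvox || material.size() != nvox)
    stop("field sizes do not match the grid");

  NumericVector H = clone(H_in);
  NumericVector Omega = clone(Omega_in);
  std::vector<double> T(nvox), inv_rcp(nvox);
  std::vector<char> is_tis(nvox);

  const double H_plateau = rho_cp_tis * T_v;  // enthalpy where T clamps
  for (R_xlen_t v = 0; v < nvox; ++v) {
    const bool tis = material[v] == 1;
    is_tis[v] = tis ? 1 : 0;
    inv_rcp[v] = tis ? 1.0 / rho_cp_tis : 1.0 / rho_cp_air;
  }

  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;

  // face conductivities are fixed within a call (materials change only
  // between calls, at voxel removal); precompute them scaled by dt/h^2,
  // with zero on the outer faces (adiabatic boundaries)
  const double dth2 = dt / (h * h);
  std::vector<double> kxp(nvox, 0.0), kyp(nvox, 0.0), kzp(nvox, 0.0);
  for (int kz = 0; kz < nz; ++kz)
    for (int jy = 0; jy < ny; ++jy)
      for (int ix = 0; ix < nx; ++ix) {
        const R_xlen_t v = (R_xlen_t)kz * sz + (R_xlen_t)jy * sy + ix;
        const double kc = is_tis[v] ? k_tis : k_air;
        if (ix < nx - 1)
          kxp[v] = dth2 * harmonic_k(kc, is_tis[v + sx] ? k_tis : k_air);
        if (jy < ny - 1)
          kyp[v] = dth2 * harmonic_k(kc, is_tis[v + sy] ? k_tis : k_air);
        if (kz < nz - 1)
          kzp[v] = dth2 * harmonic_k(kc, is_tis[v + sz] ? k_tis : k_air);
      }

  for (int step = 0; step < n_steps; ++step) {
    // temperature from enthalpy, and damage at the pre-step temperature
    for (R_xlen_t v = 0; v < nvox; ++v) {
      double t = H[v] * inv_rcp[v];
      if (is_tis[v]) {
        if (H[v] >= H_plateau) t = T_v;
        if (accumulate_omega && t > omega_T_min)
          Omega[v] += dt * A * std::exp(-Ea_over_R / (t + 273.15));
      }
      T[v] = t;
    }
    // explicit update: symmetric face fluxes conserve total enthalpy exactly
    for (R_xlen_t v = 0; v < nvox; ++v) {
      const double tc = T[v];
      double dH = dt * S[v];
      if (v >= sx)        dH += kxp[v - sx] * (T[v - sx] - tc);
      dH += kxp[v] * ((v + sx < nvox ? T[v + sx] : tc) - tc);
      if (v >= sy)        dH += kyp[v - sy] * (T[v - sy] - tc);
      dH += kyp[v] * ((v + sy < nvox ? T[v + sy] : tc) - tc);
      if (v >= sz)        dH += kzp[v - sz] * (T[v - sz] - tc);
      dH += kzp[v] * ((v + sz < nvox ? T[v + sz] : tc) - tc);
      H[v] += dH;
    }
  }
  // final temperature consistent with the returned enthalpy
  NumericVector T_out(nvox);
  for (R_xlen_t v = 0; v < nvox; ++v) {
    double t = H[v] * inv_rcp[v];
    if (is_tis[v] && H[v] >= H_plateau) t = T_v;
    T_out[v] = t;
  }
  T_out.attr("dim") = dims;
  H.attr("dim") = dims;
  Omega.attr("dim") = dims;
  return List::create(_["H"] = H, _["T"] = T_out, _["Omega"] = Omega);
}
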