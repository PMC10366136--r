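#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Voxel Monte Carlo photon-packet transport.
//
// Packets are launched downward (+z) from the top lattice face at lateral
// positions drawn from an axis-symmetric Gaussian (1/e^2 radius = 2 sigma).
// Free paths are sampled from the local mu_t = mu_a + mu_s; at each
// interaction a weight fraction mu_a/mu_t is deposited in the voxel (albedo
// weighting) and the survivor is deflected by the Henyey-Greenstein phase
// function. Unpolarized Fresnel reflection/refraction is applied at every
// voxel face across which the refractive index changes (air-tissue surface
// and crater walls); reflection is decided stochastically. Packets leaving
// the lattice are tallied as escaped, or as specularly reflected if they
// reflected at an index boundary without ever scattering. Russian roulette
// terminates low-weight packets; the weight it creates/destroys is tallied so
// the energy balance closes exactly per run:
//   absorbed + escaped + specular == launched + roulette_gain - roulette_loss.
//
// Uses R's RNG (unif_rand/norm_rand): results are reproducible via set.seed()
// on the R side.

static inline double fresnel_R(double n1, double n2, double ci, double *ct) {
  // ci = |cos incident|; returns reflectance, sets |cos transmitted|
  const double eta = n1 / n2;
  const double st2 = eta * eta * (1.0 - ci * ci);
  if (st2 >= 1.0) { *ct = 0.0; return 1.0; }  // total internal reflection
  const double c2 = std::sqrt(1.0 - st2);
  *ct = c2;
  const double rs = (n1 * ci - n2 * c2) / (n1 * ci + n2 * c2);
  const double rp = (n1 * c2 - n2 * ci) / (n1 * c2 + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

static inline void hg_scatter(double g, double *ux, double *uy, double *uz) {
  double ct;
  if (g == 0.0) {
    ct = 2.0 * unif_rand() - 1.0;
  } else {
    const double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * unif_rand());
    ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
    if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
  }
  const double st = std::sqrt(1.0 - ct * ct);
  const double phi = 2.0 * M_PI * unif_rand();
  const double cp = std::cos(phi), sp = std::sin(phi);
  const double x = *ux, y = *uy, z = *uz;
  double nx_, ny_, nz_;
  if (std::fabs(z) > 0.99999) {
    nx_ = st * cp; ny_ = st * sp; nz_ = (z >= 0.0 ? ct : -ct);
  } else {
    const double den = std::sqrt(1.0 - z * z);
    nx_ = st * (x * z * cp - y * sp) / den + x * ct;
    ny_ = st * (y * z * cp + x * sp) / den + y * ct;
    nz_ = -st * cp * den + z * ct;
  }
  const double norm = std::sqrt(nx_ * nx_ + ny_ * ny_ + nz_ * nz_);
  *ux = nx_ / norm; *uy = ny_ / norm; *uz = nz_ / norm;
}

// [[Rcpp::export]]
List mc_transport_cpp(NumericVector mu_a, NumericVector mu_s,
                      NumericVector n_idx, IntegerVector dims, double h,
                      double g, double cx, double cy, double sigma,
                      int n_photons, double w_threshold, double p_survive) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (nvox <= 0) stop("empty grid");
  if (mu_a.size() != nvox || mu_s.size() != nvox || n_idx.size() != nvox)
    stop("optical field sizes do not match the grid");
  if (n_photons < 1) stop("n_photons must be >= 1");

  NumericVector Aw(nvox);  // absorbed weight per voxel
  double absorbed = 0.0, escaped = 0.0, specular = 0.0;
  double r_gain = 0.0, r_loss = 0.0;
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  const double x0 = -0.5 * nx * h, y0 = -0.5 * ny * h;  // lattice corner
  const long max_events = 50000000L;  // safety valve, never hit in practice

  for (int ph = 0; ph < n_photons; ++ph) {
    double px = cx + sigma * norm_rand();
    double py = cy + sigma * norm_rand();
    double pz = 0.0;
    int ix = (int)std::floor((px - x0) / h);
    int iy = (int)std::floor((py - y0) / h);
    int iz = 0;
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) { escaped += 1.0; continue; }
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0;
    double tau = -std::log(unif_rand());
    bool scattered = false, reflected = false;
    long events = 0;

    for (;;) {
      if (++events > max_events) { escaped += w; break; }
      const R_xlen_t v = (R_xlen_t)iz * sz + (R_xlen_t)iy * sy + ix;
      const double mt = mu_a[v] + mu_s[v];
      // distance to the nearest voxel face along u
      double db = R_PosInf;
      int axis = -1, dir = 0;
      if (ux > 0) { double d = (x0 + (ix + 1) * h - px) / ux; if (d < db) { db = d; axis = 0; dir = 1; } }
      else if (ux < 0) { double d = (x0 + ix * h - px) / ux; if (d < db) { db = d; axis = 0; dir = -1; } }
      if (uy > 0) { double d = (y0 + (iy + 1) * h - py) / uy; if (d < db) { db = d; axis = 1; dir = 1; } }
      else if (uy < 0) { double d = (y0 + iy * h - py) / uy; if (d < db) { db = d; axis = 1; dir = -1; } }
      if (uz > 0) { double d = ((iz + 1) * h - pz) / uz; if (d < db) { db = d; axis = 2; dir = 1; } }
      else if (uz < 0) { double d = (iz * h - pz) / uz; if (d < db) { db = d; axis = 2; dir = -1; } }
      if (db < 0.0) db = 0.0;

      if (mt > 0.0 && tau < mt * db) {
        // interaction inside this voxel
        const double s = tau / mt;
        px += ux * s; py += uy * s; pz += uz * s;
        const double aw = w * mu_a[v] / mt;
        Aw[v] += aw; absorbed += aw; w -= aw;
        if (mu_s[v] <= 0.0 || w <= 0.0) break;  // pure absorber: fully deposited
        hg_scatter(g, &ux, &uy, &uz);
        scattered = true;
        tau = -std::log(unif_rand());
        if (w < w_threshold) {  // Russian roulette
          if (unif_rand() < p_survive) {
            r_gain += w * (1.0 / p_survive - 1.0);
            w /= p_survive;
          } else { r_loss += w; break; }
        }
      } else {
        // advance to the face and cross it
        px += ux * db; py += uy * db; pz += uz * db;
        if (mt > 0.0) tau -= mt * db;
        int jx = ix, jy = iy, jz = iz;
        if (axis == 0) jx += dir; else if (axis == 1) jy += dir; else jz += dir;
        if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz) {
          if (!scattered && reflected) specular += w; else escaped += w;
          break;
        }
        const R_xlen_t vn = (R_xlen_t)jz * sz + (R_xlen_t)jy * sy + jx;
        const double n1 = n_idx[v], n2 = n_idx[vn];
        if (n1 != n2) {
          double ci = (axis == 0) ? std::fabs(ux) : (axis == 1) ? std::fabs(uy) : std::fabs(uz);
          if (ci > 1.0) ci = 1.0;
          double ct;
          const double R = fresnel_R(n1, n2, ci, &ct);
          if (unif_rand() < R) {
            // reflect: flip the normal component, stay in the current voxel
            if (axis == 0) ux = -ux; else if (axis == 1) uy = -uy; else uz = -uz;
            reflected = true;
          } else {
            // refract: Snell's law, tangential components scaled by n1/n2
            const double eta = n1 / n2;
            if (axis == 0) { uy *= eta; uz *= eta; ux = (ux >= 0 ? ct : -ct); }
            else if (axis == 1) { ux *= eta; uz *= eta; uy = (uy >= 0 ? ct : -ct); }
            else { ux *= eta; uy *= eta; uz = (uz >= 0 ? ct : -ct); }
            const double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
            ux /= norm; uy /= norm; uz /= norm;
            ix = jx; iy = jy; iz = jz;
          }
        } else {
          ix = jx; iy = jy; iz = jz;
        }
      }
    }
  }

  Aw.attr("dim") = dims;
  return List::create(
    _["absorbed_weight"] = Aw,
    _["tallies"] = List::create(
      _["launched"] = 1.0,
      _["absorbed"] = absorbed / n_photons,
      _["escaped"] = escaped / n_photons,
      _["specular"] = specular / n_photons,
      _["roulette_gain"] = r_gain / n_photons,
      _["roulette_loss"] = r_loss / n_photons));
}
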