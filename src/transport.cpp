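#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Unpolarized Fresnel reflectance for a photon in medium n1 hitting a flat
// interface with medium n2 at cosine-of-incidence ci (0 < ci <= 1).
static inline double fresnel_R(double n1, double n2, double ci) {
  if (n1 == n2) return 0.0;
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = n1 / n2 * si;
  if (st >= 1.0) return 1.0;  // total internal reflection
  double ct = std::sqrt(1.0 - st * st);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Linear interpolation into a uniformly spaced table starting at x = 0.
static inline double interp_uniform(const double* y, int n, double dx, double x) {
  if (x < 0.0) return 0.0;
  double u = x / dx;
  int i = (int)u;
  if (i >= n - 1) return 0.0;  // beyond tabulated support: no collection
  double f = u - i;
  return y[i] * (1.0 - f) + y[i + 1] * f;
}

// Photon transport in a homogeneous semi-infinite medium (z >= 0), probe in
// contact at z = 0. Henyey-Greenstein scattering; steps sampled from the
// scattering coefficient; absorption by continuous weight attenuation.
// Exit radius is the lateral displacement from the launch point; the
// azimuthal average over launch position and exit azimuth is folded into the
// collection profile pcoll(r) (probability that such an exit lands on a
// collection fiber face).
//
// Returns collected reflectance (NA-filtered, pcoll-weighted), total diffuse
// reflectance, per-photon exit records (r, pathlength, weight) for exits that
// pass the NA cone and lie within r_store, and an optional radial tally of
// all exits (per annulus, NA ignored) for comparison with diffusion theory.
// [[Rcpp::export]]
List mc_transport(double mua, double mus, double g, int n_photons,
                  double cos_launch_min, double cos_accept_min,
                  double n_tissue, double n_ext,
                  double r_store, double l_max,
                  double w_roulette, double p_survive,
                  NumericVector pcoll, double pcoll_dr,
                  NumericVector radial_edges) {
  if (mus <= 0.0) stop("mus must be positive");
  if (mua < 0.0) stop("mua must be non-negative");
  RNGScope scope;

  const int np = pcoll.size();
  const double* pc = pcoll.begin();
  const int nedge = radial_edges.size();
  std::vector<double> radial(nedge > 1 ? nedge - 1 : 0, 0.0);

  std::vector<double> rec_r, rec_l, rec_w;
  rec_r.reserve(4096); rec_l.reserve(4096); rec_w.reserve(4096);

  double collected = 0.0, total = 0.0;

  for (int ip = 0; ip < n_photons; ip++) {
    // launch: direction inside the illumination NA cone (uniform in mu)
    double uz = cos_launch_min + unif_rand() * (1.0 - cos_launch_min);
    double st = std::sqrt(std::max(0.0, 1.0 - uz * uz));
    double phi = 2.0 * M_PI * unif_rand();
    double ux = st * std::cos(phi), uy = st * std::sin(phi);
    double x = 0.0, y = 0.0, z = 0.0;
    double w = 1.0, L = 0.0;
    bool alive = true;

    while (alive) {
      double s = -std::log(unif_rand()) / mus;
      double zb = z + uz * s;
      if (uz < 0.0 && zb <= 0.0) {
        // reaches the surface within this step
        double s1 = -z / uz;
        x += ux * s1; y += uy * s1; L += s1;
        if (mua > 0.0) w *= std::exp(-mua * s1);
        z = 0.0;
        double ci = -uz;
        double R = fresnel_R(n_tissue, n_ext, ci);
        if (unif_rand() >= R) {
          // transmitted: exits into the probe face
          total += w;
          double r = std::sqrt(x * x + y * y);
          if (ci >= cos_accept_min) {
            collected += w * interp_uniform(pc, np, pcoll_dr, r);
            if (r <= r_store) {
              rec_r.push_back(r); rec_l.push_back(L); rec_w.push_back(w);
            }
          }
          if (nedge > 1) {
            for (int k = 0; k < nedge - 1; k++)
              if (r >= radial_edges[k] && r < radial_edges[k + 1]) { radial[k] += w; break; }
          }
          break;
        }
        // internally reflected: flip and continue (new step is memoryless)
        uz = -uz;
        continue;
      }
      x += ux * s; y += uy * s; z = zb; L += s;
      if (mua > 0.0) w *= std::exp(-mua * s);
      if (L > l_max) break;          // pathlength cutoff
      if (w < w_roulette) {          // Russian roulette
        if (unif_rand() < p_survive) w /= p_survive; else break;
      }
      // Henyey-Greenstein deflection
      double ct;
      if (g == 0.0) {
        ct = 2.0 * unif_rand() - 1.0;
      } else {
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * unif_rand());
        ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
        if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
      }
      double snt = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double ph2 = 2.0 * M_PI * unif_rand();
      double cp = std::cos(ph2), sp = std::sin(ph2);
      double denom = std::sqrt(std::max(1e-12, 1.0 - uz * uz));
      double nux, nuy, nuz;
      if (denom < 1e-6) {
        nux = snt * cp; nuy = snt * sp; nuz = ct * (uz >= 0 ? 1.0 : -1.0);
      } else {
        nux = snt * (ux * uz * cp - uy * sp) / denom + ux * ct;
        nuy = snt * (uy * uz * cp + ux * sp) / denom + uy * ct;
        nuz = -snt * cp * denom + uz * ct;
      }
      double norm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
      ux = nux / norm; uy = nuy / norm; uz = nuz / norm;
    }
  }

  int nrec = rec_r.size();
  NumericMatrix records(nrec, 3);
  for (int i = 0; i < nrec; i++) {
    records(i, 0) = rec_r[i]; records(i, 1) = rec_l[i]; records(i, 2) = rec_w[i];
  }
  colnames(records) = CharacterVector::create("r", "L", "w");

  return List::create(_["collected"] = collected / n_photons,
                      _["total"] = total / n_photons,
                      _["records"] = records,
                      _["radial"] = NumericVector(radial.begin(), radial.end()),
                      _["n_photons"] = n_photons);
}

// Similarity rescaling of stored (or binned) exit records to target optical
// properties, per wavelength: scale factor s = musp_ref / musp_target shrinks
// both exit radius and pathlength; absorption applies Beer attenuation along
// the scaled path. cell_w are absorption-free collection weights.
// [[Rcpp::export]]
NumericVector scale_records_cpp(NumericVector cell_r, NumericVector cell_L,
                                NumericVector cell_w,
                                NumericVector s, NumericVector mua,
                                NumericVector pcoll, double pcoll_dr,
                                double n_photons) {
  const int nl = s.size();
  if (mua.size() != nl) stop("s and mua must have equal length");
  const int nc = cell_r.size();
  const int np = pcoll.size();
  const double* pc = pcoll.begin();
  NumericVector out(nl);
  for (int i = 0; i < nl; i++) {
    double si = s[i], ci = mua[i] * si, acc = 0.0;
    for (int j = 0; j < nc; j++) {
      double p = interp_uniform(pc, np, pcoll_dr, cell_r[j] * si);
      if (p > 0.0) acc += cell_w[j] * p * std::exp(-ci * cell_L[j]);
    }
    out[i] = acc / n_photons;
  }
  return out;
}
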