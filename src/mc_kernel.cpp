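// Monte Carlo photon transport in a plane-layered semi-infinite medium.
//
// Weight-based tracking with similarity-reduced (isotropic, musp') scattering,
// exponential step sampling at mut = mua + musp', Fresnel reflection/refraction
// at the top surface, Russian roulette, and a hard total-pathlength cap.
// Deterministic given the seed (single-threaded, own xoshiro256++ stream).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

namespace {

// splitmix64, used only to seed the main generator
inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97f4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1]; never exactly 0 so -log(u) is finite
  inline double runif() {
    return ((next() >> 11) + 1.0) * 0x1.0p-53;
  }
};

// Unpolarized Fresnel reflectance for incidence from medium n1 into n2 at
// cos(theta_i) = ci (> 0). Returns 1 beyond the critical angle.
inline double fresnel(double n1, double n2, double ci, double &ct_out) {
  double si2 = 1.0 - ci * ci;
  double st2 = (n1 / n2) * (n1 / n2) * si2;  // sin^2 of transmitted angle
  if (st2 >= 1.0) { ct_out = 0.0; return 1.0; }
  double ct = std::sqrt(1.0 - st2);
  ct_out = ct;
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

} // namespace

// [[Rcpp::export(name = ".mc_run_cpp")]]
Rcpp::List mc_run_cpp(Rcpp::NumericVector thickness,  // per layer, last = Inf
                      Rcpp::NumericVector mua,
                      Rcpp::NumericVector musp,
                      double n_tissue, double n_external,
                      double r_min, double r_max,
                      double n_photons_d,
                      double seed_d,
                      double roulette_threshold,
                      double roulette_survival,
                      double max_path) {
  const int nl = thickness.size();
  if (mua.size() != nl || musp.size() != nl)
    Rcpp::stop("layer property vectors must have equal length");
  const long n_photons = (long)n_photons_d;
  Xoshiro256pp rng((uint64_t)seed_d);

  // cumulative layer interface depths: layer i spans [z_top[i], z_top[i+1])
  std::vector<double> z_top(nl + 1);
  z_top[0] = 0.0;
  for (int i = 0; i < nl; ++i)
    z_top[i + 1] = (i == nl - 1) ? std::numeric_limits<double>::infinity()
                                 : z_top[i] + thickness[i];
  std::vector<double> mut(nl), albedo(nl);
  for (int i = 0; i < nl; ++i) {
    mut[i] = mua[i] + musp[i];
    albedo[i] = (mut[i] > 0.0) ? musp[i] / mut[i] : 1.0;
  }

  // specular reflection at normal incidence on entry
  double rsp = 0.0;
  if (n_tissue != n_external) {
    double r = (n_external - n_tissue) / (n_external + n_tissue);
    rsp = r * r;
  }

  double w_detected = 0.0, w_detected_sq = 0.0;
  double w_escaped = 0.0, w_absorbed = 0.0, w_roulette = 0.0, w_capped = 0.0;
  long n_detected = 0;
  std::vector<double> det_weight, det_maxdepth, det_total_path;
  std::vector<std::vector<double>> det_layer_path(nl);
  std::vector<double> layer_path(nl);

  for (long ip = 0; ip < n_photons; ++ip) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0 - rsp;
    int layer = 0;
    double total_path = 0.0, max_depth = 0.0;
    std::fill(layer_path.begin(), layer_path.end(), 0.0);
    bool alive = true;

    double su = -std::log(rng.runif());  // dimensionless step remainder

    while (alive) {
      // geometric distance available in this layer for the remaining su
      double step = (mut[layer] > 0.0) ? su / mut[layer]
                                       : std::numeric_limits<double>::infinity();
      // distance to the layer boundary along uz
      double d_bound = std::numeric_limits<double>::infinity();
      int next_layer = layer;
      if (uz > 0.0 && std::isfinite(z_top[layer + 1])) {
        d_bound = (z_top[layer + 1] - z) / uz;
        next_layer = layer + 1;
      } else if (uz < 0.0) {
        d_bound = (z_top[layer] - z) / uz;
        next_layer = layer - 1;
      }

      if (d_bound < step) {
        // move to the interface, carry the unused step across
        x += ux * d_bound; y += uy * d_bound; z += uz * d_bound;
        total_path += d_bound;
        layer_path[layer] += d_bound;
        if (z > max_depth) max_depth = z;
        su -= d_bound * mut[layer];
        if (total_path > max_path) { w_capped += w; break; }

        if (next_layer < 0) {
          // top surface: Fresnel reflect or escape
          double ci = -uz, ct;
          double R = (n_tissue == n_external) ? 0.0
                     : fresnel(n_tissue, n_external, ci, ct);
          if (rng.runif() < R) {
            uz = -uz;
            z = 0.0;
          } else {
            double r_exit = std::sqrt(x * x + y * y);
            if (r_exit >= r_min && r_exit < r_max) {
              w_detected += w; w_detected_sq += w * w; ++n_detected;
              det_weight.push_back(w);
              det_maxdepth.push_back(max_depth);
              det_total_path.push_back(total_path);
              for (int i = 0; i < nl; ++i) det_layer_path[i].push_back(layer_path[i]);
            } else {
              w_escaped += w;
            }
            break;
          }
        } else {
          // internal interface: matched indices between layers, pass through
          layer = next_layer;
        }
        continue;
      }

      // full scattering step inside the current layer
      x += ux * step; y += uy * step; z += uz * step;
      total_path += step;
      layer_path[layer] += step;
      if (z > max_depth) max_depth = z;
      if (total_path > max_path) { w_capped += w; break; }

      // absorb, then scatter isotropically
      double dw = w * (1.0 - albedo[layer]);
      w_absorbed += dw;
      w *= albedo[layer];

      if (w < roulette_threshold) {
        if (rng.runif() < roulette_survival) {
          w_roulette -= w * (1.0 / roulette_survival - 1.0);
          w /= roulette_survival;
        } else {
          w_roulette += w;
          break;
        }
      }

      double cz = 2.0 * rng.runif() - 1.0;
      double sz = std::sqrt(std::max(0.0, 1.0 - cz * cz));
      double phi = 2.0 * M_PI * rng.runif();
      ux = sz * std::cos(phi); uy = sz * std::sin(phi); uz = cz;
      su = -std::log(rng.runif());
    }
  }

  double area = M_PI * (r_max * r_max - r_min * r_min);
  double mean_contrib = w_detected / (double)n_photons;
  // per-launched-photon variance of the detected-weight contribution
  double var = (w_detected_sq - w_detected * w_detected / (double)n_photons) /
               ((double)n_photons - 1.0);
  double se = std::sqrt(var / (double)n_photons) / area;

  Rcpp::List layer_paths(nl);
  for (int i = 0; i < nl; ++i) layer_paths[i] = Rcpp::wrap(det_layer_path[i]);

  return Rcpp::List::create(
      Rcpp::Named("n_detected") = (double)n_detected,
      Rcpp::Named("detected_weight_sum") = w_detected,
      Rcpp::Named("reflectance") = mean_contrib / area,
      Rcpp::Named("reflectance_se") = se,
      Rcpp::Named("w_specular") = rsp * (double)n_photons,
      Rcpp::Named("w_escaped") = w_escaped,
      Rcpp::Named("w_absorbed") = w_absorbed,
      Rcpp::Named("w_roulette") = w_roulette,
      Rcpp::Named("w_capped") = w_capped,
      Rcpp::Named("det_weight") = det_weight,
      Rcpp::Named("det_maxdepth") = det_maxdepth,
      Rcpp::Named("det_total_path") = det_total_path,
      Rcpp::Named("det_layer_path") = layer_paths);
}
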