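// Condensed-history Monte Carlo transport for dose-point-kernel generation.
// Electrons: class II scheme -- continuous energy loss from a restricted
// (hard-collision-subtracted) range-energy table, per-step deflection from a
// screened-Rutherford distribution matched to the Highland variance, explicit
// delta electrons above the hard-collision threshold. Photons: exponential
// free path, full energy deposited at the first interaction. All random
// numbers come from R's RNG so results are reproducible under set.seed().
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double ME = 0.51099895; // electron rest mass, MeV

struct Particle {
  double E;
  double pos[3];
  double dir[3];
};

static inline double lin_lookup(const std::vector<double> &tab, double x,
                                double xmin, double xmax) {
  // uniform-grid linear interpolation, clamped
  int n = (int)tab.size();
  double t = (x - xmin) / (xmax - xmin) * (n - 1);
  if (t <= 0) return tab[0];
  if (t >= n - 1) return tab[n - 1];
  int i = (int)t;
  double f = t - i;
  return tab[i] * (1 - f) + tab[i + 1] * f;
}

static inline void iso_dir(double *u) {
  double z = 2.0 * unif_rand() - 1.0;
  double phi = 2.0 * M_PI * unif_rand();
  double s = std::sqrt(std::max(0.0, 1.0 - z * z));
  u[0] = s * std::cos(phi);
  u[1] = s * std::sin(phi);
  u[2] = z;
}

static inline void rotate_dir(double *u, double ct, double phi) {
  // rotate u by polar angle acos(ct), azimuth phi, about its own axis
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double a0, a1, a2;
  if (std::fabs(u[0]) < 0.9) { a0 = 1; a1 = 0; a2 = 0; }
  else { a0 = 0; a1 = 1; a2 = 0; }
  double d = a0 * u[0] + a1 * u[1] + a2 * u[2];
  double e1[3] = {a0 - d * u[0], a1 - d * u[1], a2 - d * u[2]};
  double n1 = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
  e1[0] /= n1; e1[1] /= n1; e1[2] /= n1;
  double e2[3] = {u[1] * e1[2] - u[2] * e1[1],
                  u[2] * e1[0] - u[0] * e1[2],
                  u[0] * e1[1] - u[1] * e1[0]};
  double cp = std::cos(phi), sp = std::sin(phi);
  double v[3];
  for (int k = 0; k < 3; ++k)
    v[k] = ct * u[k] + st * (cp * e1[k] + sp * e2[k]);
  double nv = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  for (int k = 0; k < 3; ++k) u[k] = v[k] / nv;
}

class Tally {
public:
  Tally(NumericVector dep, IntegerVector dims, NumericVector spacing)
      : dep_(dep) {
    for (int k = 0; k < 3; ++k) {
      n_[k] = dims[k];
      sp_[k] = spacing[k];
      c_[k] = (dims[k] - 1) / 2;
    }
  }
  inline void deposit(const double *pos, double E) {
    int idx[3];
    for (int k = 0; k < 3; ++k) {
      double t = pos[k] / sp_[k];
      int i = (int)std::lround(t) + c_[k];
      if (i < 0 || i >= n_[k]) return;
      idx[k] = i;
    }
    dep_[idx[0] + (R_xlen_t)n_[0] * (idx[1] + (R_xlen_t)n_[1] * idx[2])] += E;
  }
private:
  NumericVector dep_;
  int n_[3], c_[3];
  double sp_[3];
};

// [[Rcpp::export(name = "dpk_transport")]]
NumericVector dpk_transport(IntegerVector dims, NumericVector spacing,
                            NumericVector e_energies, NumericVector p_energies,
                            NumericVector e_of_r, double r_max,
                            NumericVector r_of_e, double loge_min,
                            double loge_max, NumericVector a_of_logv,
                            double logv_min, double logv_max, double kcol_mm,
                            double wc, double x0_mm, NumericVector mu_loge,
                            NumericVector mu_logmu, double cutoff,
                            double step_mm) {
  NumericVector dep((R_xlen_t)dims[0] * dims[1] * dims[2]);
  Tally tally(dep, dims, spacing);
  std::vector<double> EofR(e_of_r.begin(), e_of_r.end());
  std::vector<double> RofE(r_of_e.begin(), r_of_e.end());
  std::vector<double> AofV(a_of_logv.begin(), a_of_logv.end());

  RNGScope rng;
  std::vector<Particle> stack;
  stack.reserve(64);

  for (R_xlen_t h = 0; h < e_energies.size(); ++h) {
    Particle p0;
    p0.E = e_energies[h];
    p0.pos[0] = p0.pos[1] = p0.pos[2] = 0.0;
    iso_dir(p0.dir);
    stack.push_back(p0);
    while (!stack.empty()) {
      Particle p = stack.back();
      stack.pop_back();
      double E = p.E;
      if (E <= cutoff) { tally.deposit(p.pos, E); continue; }
      double R = lin_lookup(RofE, std::log(E), loge_min, loge_max);
      double pos[3] = {p.pos[0], p.pos[1], p.pos[2]};
      double u[3] = {p.dir[0], p.dir[1], p.dir[2]};
      while (E > cutoff) {
        double step = std::min(step_mm, R);
        double p2 = E * (E + 2 * ME);
        double beta2 = p2 / ((E + ME) * (E + ME));
        double sig = (E / 2 > wc) ? kcol_mm / beta2 * (1.0 / wc - 2.0 / E) : 0.0;
        double Rnew = R - step;
        double Enew = (Rnew <= 0) ? 0.0
                                  : lin_lookup(EofR, Rnew, 0.0, r_max);
        if (Enew <= cutoff) Enew = 0.0;
        double dE = E - Enew;
        double mid[3];
        for (int k = 0; k < 3; ++k) mid[k] = pos[k] + u[k] * step * 0.5;
        tally.deposit(mid, dE);
        for (int k = 0; k < 3; ++k) pos[k] += u[k] * step;
        E = Enew;
        R = (Rnew > 0) ? Rnew : 0.0;
        if (E <= 0) break;
        // hard Moller collision -> delta electron
        if (sig > 0 && unif_rand() < -std::expm1(-sig * step)) {
          double wmax = E / 2;
          if (wmax > wc) {
            double uu = unif_rand();
            double W = 1.0 / (1.0 / wc - uu * (1.0 / wc - 1.0 / wmax));
            if (W > wmax) W = wmax;
            Particle d;
            d.E = W;
            for (int k = 0; k < 3; ++k) d.pos[k] = pos[k];
            iso_dir(d.dir);
            stack.push_back(d);
            E -= W;
            if (E <= cutoff) { tally.deposit(pos, E); E = 0; break; }
            R = lin_lookup(RofE, std::log(E), loge_min, loge_max);
          }
        }
        // multiple scattering: screened-Rutherford step deflection with
        // mean (1 - cos theta) equal to the Highland variance theta0^2
        double pmom = std::sqrt(p2);
        double beta = pmom / (E + ME);
        double th0 = 13.6 / (beta * pmom) * std::sqrt(step / x0_mm);
        double v = th0 * th0;
        double mu;
        if (v >= 0.95) {
          mu = 2.0 * unif_rand();
        } else {
          if (v < 1e-6) v = 1e-6;
          double a = std::exp(lin_lookup(AofV, std::log(v), logv_min, logv_max));
          double N = 1.0 / (2 * a) - 1.0 / (2 + 2 * a);
          mu = 1.0 / (1.0 / (2 * a) - unif_rand() * N) - 2 * a;
          if (mu < 0) mu = 0;
          if (mu > 2) mu = 2;
        }
        rotate_dir(u, 1.0 - mu, 2.0 * M_PI * unif_rand());
      }
    }
  }

  // photons: exponential free path, deposit at first interaction
  int nmu = mu_loge.size();
  for (R_xlen_t h = 0; h < p_energies.size(); ++h) {
    double E = p_energies[h];
    double le = std::log(E);
    // log-log interpolation of the attenuation coefficient (1/mm)
    double lmu;
    if (le <= mu_loge[0]) lmu = mu_logmu[0];
    else if (le >= mu_loge[nmu - 1]) lmu = mu_logmu[nmu - 1];
    else {
      int i = 0;
      while (i < nmu - 2 && mu_loge[i + 1] < le) ++i;
      double f = (le - mu_loge[i]) / (mu_loge[i + 1] - mu_loge[i]);
      lmu = mu_logmu[i] * (1 - f) + mu_logmu[i + 1] * f;
    }
    double mu_mm = std::exp(lmu);
    double u[3];
    iso_dir(u);
    double path = -std::log(unif_rand()) / mu_mm;
    double pos[3] = {u[0] * path, u[1] * path, u[2] * path};
    tally.deposit(pos, E);
  }

  dep.attr("dim") = dims;
  return dep;
}
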