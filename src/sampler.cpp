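#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Adaptive Metropolis-within-Gibbs sampler for the hierarchical binomial
// critical-scale model.
//
// Per binomial cell c with scale factor s[c]:
//   eta_sc[c] = X(c,) beta_sc + sd_p_sc * zp_sc[pidx[c]] + sd_i_sc * zi_sc[iidx[c]]
//   eta_a [c] = X(c,) beta_a  + sd_p_a  * zp_a [pidx[c]] + sd_i_a  * zi_a [iidx[c]]
//   s_c = exp(eta_sc), alpha = exp(eta_a)
//   d'  = alpha * (1 - s_c^2/s^2) if s > s_c else 0
//   p   = g + (1-g) * (1 - exp(-(d'/lam)^k))         (Weibull oddity link)
//   k[c] ~ Binomial(n[c], p)
// Random effects are non-centered (z ~ N(0,1), group sds sampled on the
// log scale with half-Cauchy(0, cauchy_scale) priors plus log-Jacobian).
// Each scalar parameter gets a random-walk update whose step size adapts
// toward 0.44 acceptance during warmup (Robbins-Monro, frozen afterward).

static inline double cell_ll(double es, double ea, double sv, int nn,
                             int kk, double guess, double lam,
                             double kshape) {
  double sc = std::exp(es);
  double r = sc / sv;
  double p = guess;
  if (r < 1.0) {
    double dp = std::exp(ea) * (1.0 - r * r);
    p = guess + (1.0 - guess) * (1.0 - std::exp(-std::pow(dp / lam,
                                                          kshape)));
  }
  return kk * std::log(p) + (nn - kk) * std::log1p(-p);
}

// [[Rcpp::export]]
List run_cs_sampler(NumericVector s, IntegerVector n, IntegerVector k,
                    NumericMatrix X, IntegerVector pidx,
                    IntegerVector iidx, int np, int ni, double lam,
                    double kshape, double guess, NumericVector pm_sc,
                    NumericVector psd_sc, NumericVector pm_a,
                    NumericVector psd_a, double cauchy_scale, int chains,
                    int iter, int warmup, NumericMatrix Gp,
                    NumericMatrix Gi) {
  const int ncell = s.size();
  const int P = X.ncol();
  const int o_ba = P, o_zpsc = 2 * P, o_zpa = 2 * P + np;
  const int o_zisc = 2 * P + 2 * np, o_zia = 2 * P + 2 * np + ni;
  const int o_lsd = 2 * P + 2 * np + 2 * ni;
  const int d = o_lsd + 4;

  // cells affected by each scalar parameter
  std::vector<std::vector<int>> aff(d);
  for (int j = 0; j < P; ++j)
    for (int c = 0; c < ncell; ++c)
      if (X(c, j) != 0.0) { aff[j].push_back(c); aff[o_ba + j].push_back(c); }
  for (int c = 0; c < ncell; ++c) {
    aff[o_zpsc + pidx[c]].push_back(c);
    aff[o_zpa + pidx[c]].push_back(c);
    aff[o_zisc + iidx[c]].push_back(c);
    aff[o_zia + iidx[c]].push_back(c);
  }
  std::vector<int> allc(ncell);
  for (int c = 0; c < ncell; ++c) allc[c] = c;
  for (int j = 0; j < 4; ++j) aff[o_lsd + j] = allc;

  auto lprior = [&](int j, double v) -> double {
    if (j < P) { double z = (v - pm_sc[j]) / psd_sc[j]; return -0.5 * z * z; }
    if (j < 2 * P) { double z = (v - pm_a[j - P]) / psd_a[j - P];
                     return -0.5 * z * z; }
    if (j < o_lsd) return -0.5 * v * v;
    double sd = std::exp(v);
    double t = sd / cauchy_scale;
    return std::log(2.0 / (M_PI * cauchy_scale * (1.0 + t * t))) + v;
  };

  List out(chains);
  for (int ch = 0; ch < chains; ++ch) {
    std::vector<double> th(d);
    for (int j = 0; j < P; ++j) th[j] = pm_sc[j] + 0.3 * norm_rand();
    for (int j = 0; j < P; ++j) th[o_ba + j] = pm_a[j] + 0.3 * norm_rand();
    for (int j = o_zpsc; j < o_lsd; ++j) th[j] = 0.3 * norm_rand();
    for (int j = 0; j < 4; ++j)
      th[o_lsd + j] = std::log(0.1) + 0.3 * norm_rand();

    std::vector<double> esc(ncell), ea(ncell), cll(ncell);
    auto recompute = [&]() {
      double sp_sc = std::exp(th[o_lsd]), sp_a = std::exp(th[o_lsd + 1]);
      double si_sc = std::exp(th[o_lsd + 2]), si_a = std::exp(th[o_lsd + 3]);
      for (int c = 0; c < ncell; ++c) {
        double a = 0.0, b = 0.0;
        for (int j = 0; j < P; ++j) {
          a += X(c, j) * th[j];
          b += X(c, j) * th[o_ba + j];
        }
        esc[c] = a + sp_sc * th[o_zpsc + pidx[c]] + si_sc * th[o_zisc + iidx[c]];
        ea[c] = b + sp_a * th[o_zpa + pidx[c]] + si_a * th[o_zia + iidx[c]];
        cll[c] = cell_ll(esc[c], ea[c], s[c], n[c], k[c], guess, lam,
                         kshape);
      }
    };
    recompute();

    std::vector<double> lstep(d, std::log(0.1));
    std::vector<double> tstep(4 * P, std::log(0.2));
    std::vector<double> sstep(4, std::log(0.2));
    std::vector<double> nes(ncell), nea(ncell), ncl(ncell);
    NumericMatrix draws(iter - warmup, d);

    for (int it = 0; it < iter; ++it) {
      if (it % 256 == 0) Rcpp::checkUserInterrupt();
      double sp_sc = std::exp(th[o_lsd]), sp_a = std::exp(th[o_lsd + 1]);
      double si_sc = std::exp(th[o_lsd + 2]), si_a = std::exp(th[o_lsd + 3]);
      for (int j = 0; j < d; ++j) {
        double eps = std::exp(lstep[j]) * norm_rand();
        double v_new = th[j] + eps;
        double dll = 0.0;
        const std::vector<int>& A = aff[j];
        if (j < o_lsd) {
          for (size_t a = 0; a < A.size(); ++a) {
            int c = A[a];
            double es2 = esc[c], ea2 = ea[c];
            if (j < P) es2 += X(c, j) * eps;
            else if (j < 2 * P) ea2 += X(c, j - P) * eps;
            else if (j < o_zpa) es2 += sp_sc * eps;
            else if (j < o_zisc) ea2 += sp_a * eps;
            else if (j < o_zia) es2 += si_sc * eps;
            else ea2 += si_a * eps;
            nes[c] = es2; nea[c] = ea2;
            ncl[c] = cell_ll(es2, ea2, s[c], n[c], k[c], guess, lam,
                             kshape);
            dll += ncl[c] - cll[c];
          }
        } else {
          // group-sd update rescales every cell's random-effect term
          int which = j - o_lsd;
          double sd_old = std::exp(th[j]), sd_new = std::exp(v_new);
          double dsd = sd_new - sd_old;
          for (int c = 0; c < ncell; ++c) {
            double es2 = esc[c], ea2 = ea[c];
            if (which == 0) es2 += dsd * th[o_zpsc + pidx[c]];
            else if (which == 1) ea2 += dsd * th[o_zpa + pidx[c]];
            else if (which == 2) es2 += dsd * th[o_zisc + iidx[c]];
            else ea2 += dsd * th[o_zia + iidx[c]];
            nes[c] = es2; nea[c] = ea2;
            ncl[c] = cell_ll(es2, ea2, s[c], n[c], k[c], guess, lam,
                             kshape);
            dll += ncl[c] - cll[c];
          }
        }
        double lr = dll + lprior(j, v_new) - lprior(j, th[j]);
        double acc_p = lr >= 0.0 ? 1.0 : std::exp(lr);
        if (unif_rand() < acc_p) {
          th[j] = v_new;
          for (size_t a = 0; a < A.size(); ++a) {
            int c = A[a];
            esc[c] = nes[c]; ea[c] = nea[c]; cll[c] = ncl[c];
          }
          if (j >= o_lsd) {
            sp_sc = std::exp(th[o_lsd]); sp_a = std::exp(th[o_lsd + 1]);
            si_sc = std::exp(th[o_lsd + 2]); si_a = std::exp(th[o_lsd + 3]);
          }
        }
        if (it < warmup) {
          double gamma = std::min(0.25, 2.0 / std::sqrt(it + 1.0));
          lstep[j] += gamma * (acc_p - 0.44);
        }
      }
      // Likelihood-invariant translation moves: shift a fixed effect and
      // absorb the shift into the participant z's of the groups that
      // effect touches (eta unchanged, only priors enter the ratio).
      // Breaks the beta / mean(z) posterior correlation.
      for (int j = 0; j < 2 * P; ++j) {
        double eps = std::exp(tstep[j]) * norm_rand();
        int jj = j % P;
        bool is_sc = j < P;
        double sd_g = is_sc ? std::exp(th[o_lsd]) : std::exp(th[o_lsd + 1]);
        int zoff = is_sc ? o_zpsc : o_zpa;
        double lr = lprior(is_sc ? jj : o_ba + jj, th[(is_sc ? jj : o_ba + jj)] + eps) -
                    lprior(is_sc ? jj : o_ba + jj, th[(is_sc ? jj : o_ba + jj)]);
        double shift = eps / sd_g;
        for (int g = 0; g < np; ++g)
          if (Gp(g, jj) != 0.0) {
            double z0 = th[zoff + g], z1 = z0 - shift;
            lr += 0.5 * (z0 * z0 - z1 * z1);
          }
        double acc_p = lr >= 0.0 ? 1.0 : std::exp(lr);
        if (unif_rand() < acc_p) {
          th[is_sc ? jj : o_ba + jj] += eps;
          for (int g = 0; g < np; ++g)
            if (Gp(g, jj) != 0.0) th[zoff + g] -= shift;
        }
        if (it < warmup) {
          double gamma = std::min(0.25, 2.0 / std::sqrt(it + 1.0));
          tstep[j] += gamma * (acc_p - 0.44);
        }
      }
      // same move against the image z's
      for (int j = 0; j < 2 * P; ++j) {
        double eps = std::exp(tstep[2 * P + j]) * norm_rand();
        int jj = j % P;
        bool is_sc = j < P;
        int bj = is_sc ? jj : o_ba + jj;
        double sd_g = is_sc ? std::exp(th[o_lsd + 2])
                            : std::exp(th[o_lsd + 3]);
        int zoff = is_sc ? o_zisc : o_zia;
        double lr = lprior(bj, th[bj] + eps) - lprior(bj, th[bj]);
        double shift = eps / sd_g;
        for (int g = 0; g < ni; ++g)
          if (Gi(g, jj) != 0.0) {
            double z0 = th[zoff + g], z1 = z0 - shift;
            lr += 0.5 * (z0 * z0 - z1 * z1);
          }
        double acc_p = lr >= 0.0 ? 1.0 : std::exp(lr);
        if (unif_rand() < acc_p) {
          th[bj] += eps;
          for (int g = 0; g < ni; ++g)
            if (Gi(g, jj) != 0.0) th[zoff + g] -= shift;
        }
        if (it < warmup) {
          double gamma = std::min(0.25, 2.0 / std::sqrt(it + 1.0));
          tstep[2 * P + j] += gamma * (acc_p - 0.44);
        }
      }
      // Likelihood-invariant scaling ("funnel") moves: lsd += eps while
      // z *= exp(-eps); ratio = priors + log-Jacobian (-ng * eps).
      for (int w = 0; w < 4; ++w) {
        double eps = std::exp(sstep[w]) * norm_rand();
        int zoff = (w == 0) ? o_zpsc : (w == 1) ? o_zpa
                   : (w == 2) ? o_zisc : o_zia;
        int ng = (w < 2) ? np : ni;
        double f = std::exp(-eps);
        double lr = lprior(o_lsd + w, th[o_lsd + w] + eps) -
                    lprior(o_lsd + w, th[o_lsd + w]) - ng * eps;
        for (int g = 0; g < ng; ++g) {
          double z0 = th[zoff + g], z1 = z0 * f;
          lr += 0.5 * (z0 * z0 - z1 * z1);
        }
        double acc_p = lr >= 0.0 ? 1.0 : std::exp(lr);
        if (unif_rand() < acc_p) {
          th[o_lsd + w] += eps;
          for (int g = 0; g < ng; ++g) th[zoff + g] *= f;
        }
        if (it < warmup) {
          double gamma = std::min(0.25, 2.0 / std::sqrt(it + 1.0));
          sstep[w] += gamma * (acc_p - 0.44);
        }
      }
      if (it >= warmup)
        for (int j = 0; j < d; ++j) draws(it - warmup, j) = th[j];
    }
    out[ch] = draws;
  }
  return out;
}
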