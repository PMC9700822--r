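// Gibbs sampler for the hierarchical zero-inflated Poisson state-space model.
//
// Conjugate blocks (cell intercepts/slopes, BCR means, grand means, all
// variances, zero-inflation probabilities, latent structural-zero
// indicators) are drawn exactly; the Poisson-linked scalar nodes
// (log gamma, random effects, eta, checklist coefficients) have log-concave
// full conditionals and are updated by stepping-out slice sampling
// (Neal 2003). All sigma/tau parameters are variances; precision = 1/v.
//
// The chain RNG is a std::mt19937_64 seeded per chain, so a fit is
// bit-reproducible for a given seed on a given platform.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937_64 eng;
  std::normal_distribution<double> nd;
  std::uniform_real_distribution<double> ud;
  explicit Rng(uint64_t seed) : eng(seed), nd(0.0, 1.0), ud(0.0, 1.0) {}
  double norm() { return nd(eng); }
  double unif() { return ud(eng); }
  double expo() { return -std::log(1.0 - ud(eng)); }
  double gamma(double shape, double rate) {
    std::gamma_distribution<double> g(shape, 1.0 / rate);
    return g(eng);
  }
  double beta(double a, double b) {
    double x = gamma(a, 1.0), y = gamma(b, 1.0);
    return x / (x + y);
  }
};

// Stepping-out slice sampler for a univariate log-density f.
template <typename F>
double slice_sample(F f, double x0, Rng& rng, double w = 1.0, int m = 50) {
  double fx0 = f(x0);
  double logy = fx0 - rng.expo();
  double u = rng.unif();
  double L = x0 - w * u, R = L + w;
  int j = std::floor(m * rng.unif());
  int k = m - 1 - j;
  while (j-- > 0 && f(L) > logy) L -= w;
  while (k-- > 0 && f(R) > logy) R += w;
  for (int it = 0; it < 200; ++it) {
    double x1 = L + rng.unif() * (R - L);
    if (f(x1) > logy) return x1;
    if (x1 < x0) L = x1; else R = x1;
  }
  return x0;  // pathological shrinkage: keep the current value
}

inline double norm_draw(double mean, double var, Rng& rng) {
  return mean + std::sqrt(var) * rng.norm();
}

// draw variance ~ InvGamma(a0 + n/2, b0 + ss/2)
inline double invgamma_draw(double n, double ss, Rng& rng) {
  double shape = 0.01 + 0.5 * n, rate = 0.01 + 0.5 * ss;
  return 1.0 / rng.gamma(shape, rate);
}

}  // namespace

// [[Rcpp::export(name = ".run_abund_chain")]]
NumericMatrix run_abund_chain(List d, List init, List fixed,
                              int n_iter, int n_burn, int thin, double seed) {
  const int ncell = as<int>(d["ncell"]);
  const int nyear = as<int>(d["nyear"]);
  const int nbcr = as<int>(d["nbcr"]);
  const IntegerVector bcr = d["bcr"];          // 0-based, per cell
  const NumericVector yearc = d["yearc"];
  const double off = as<double>(d["off"]);
  // route-count stream
  const int nB = as<int>(d["nB"]);
  const int npair = as<int>(d["npair"]);
  const IntegerVector bc = d["bc"], bt = d["bt"], bp = d["bp"], bI = d["bI"];
  const IntegerVector by = d["by"];
  // checklist stream
  const bool has_e = as<bool>(d["has_e"]);
  const int nE = as<int>(d["nE"]);
  const int nobs = as<int>(d["nobs"]);
  IntegerVector ec, et, eo, ey;
  NumericMatrix X;
  if (has_e) {
    ec = as<IntegerVector>(d["ec"]); et = as<IntegerVector>(d["et"]);
    eo = as<IntegerVector>(d["eo"]); ey = as<IntegerVector>(d["ey"]);
    X = as<NumericMatrix>(d["X"]);
  }

  // state
  std::vector<double> alpha = as<std::vector<double>>(init["alpha"]);
  std::vector<double> beta = as<std::vector<double>>(init["beta"]);
  NumericMatrix lg0 = init["log_gamma"];
  std::vector<double> lgam(lg0.begin(), lg0.end());  // ncell x nyear, col-major
  std::vector<double> muA = as<std::vector<double>>(init["mu_alpha_bcr"]);
  std::vector<double> muB = as<std::vector<double>>(init["mu_beta_bcr"]);
  double gmA = as<double>(init["mu_alpha"]), gmB = as<double>(init["mu_beta"]);
  double va = as<double>(init["sigma_alpha"]), vb = as<double>(init["sigma_beta"]);
  double ta = as<double>(init["tau_alpha"]), tb = as<double>(init["tau_beta"]);
  double vg = as<double>(init["sigma_gamma"]);
  double omB = as<double>(init["omega_bbs"]), vB = as<double>(init["sigma_bbs"]);
  double eta = as<double>(init["eta"]);
  std::vector<double> epsB = as<std::vector<double>>(init["eps_bbs"]);
  std::vector<double> b(7, 0.0), epsE;
  double omE = 0.0, vE = 1.0;
  if (has_e) {
    b = as<std::vector<double>>(init["b"]);
    omE = as<double>(init["omega_ebird"]);
    vE = as<double>(init["sigma_ebird"]);
    epsE = as<std::vector<double>>(init["eps_ebird"]);
  }

  auto flag = [&](const char* nm) {
    return fixed.containsElementNamed(nm) && as<bool>(fixed[nm]);
  };
  const bool fx_vg = flag("sigma_gamma"), fx_va = flag("sigma_alpha"),
             fx_vb = flag("sigma_beta"), fx_ta = flag("tau_alpha"),
             fx_tb = flag("tau_beta"), fx_vB = flag("sigma_bbs"),
             fx_vE = flag("sigma_ebird"), fx_omB = flag("omega_bbs"),
             fx_omE = flag("omega_ebird"), fx_eta = flag("eta"),
             fx_beta = flag("beta"), fx_lgam = flag("log_gamma"),
             fx_epsB = flag("eps_bbs"), fx_epsE = flag("eps_ebird"),
             fx_b = flag("b");

  // index lists
  const int nit = ncell * nyear;
  std::vector<std::vector<int>> bbs_it(nit), e_it, bbs_pair(npair), e_obs;
  std::vector<int> bit(nB), eit;
  for (int n = 0; n < nB; ++n) {
    bit[n] = bc[n] + ncell * bt[n];
    bbs_it[bit[n]].push_back(n);
    bbs_pair[bp[n]].push_back(n);
  }
  std::vector<int> eta_recs;
  for (int n = 0; n < nB; ++n) if (bI[n] == 1) eta_recs.push_back(n);
  if (has_e) {
    e_it.resize(nit); e_obs.resize(nobs); eit.resize(nE);
    for (int n = 0; n < nE; ++n) {
      eit[n] = ec[n] + ncell * et[n];
      e_it[eit[n]].push_back(n);
      e_obs[eo[n]].push_back(n);
    }
  }
  double sum_yc2 = 0.0;
  for (int t = 0; t < nyear; ++t) sum_yc2 += yearc[t] * yearc[t];
  std::vector<int> bcr_cells_count(nbcr, 0);
  for (int i = 0; i < ncell; ++i) bcr_cells_count[bcr[i]]++;

  std::vector<int> zB(nB, 0), zE(nE, 0);
  std::vector<double> dotX(nE, 0.0);  // b1..b6 part of the linear predictor

  Rng rng(static_cast<uint64_t>(seed));

  const int n_keep = (n_iter - n_burn) / thin;
  const int np_proc = 7 + 2 * nbcr + 2 * ncell + nit;
  const int np_bbs = 3 + npair;
  const int np_e = has_e ? (7 + 2 + nobs) : 0;
  NumericMatrix out(n_keep, np_proc + np_bbs + np_e);
  int keep_row = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    // ---- latent z and omega, route stream ----
    {
      int sz = 0;
      for (int n = 0; n < nB; ++n) {
        if (by[n] > 0) { zB[n] = 0; continue; }
        double lam = std::exp(lgam[bit[n]] + off + epsB[bp[n]] + eta * bI[n]);
        double p1 = omB, p0 = (1.0 - omB) * std::exp(-lam);
        zB[n] = (rng.unif() * (p0 + p1) < p1) ? 1 : 0;
        sz += zB[n];
      }
      if (!fx_omB) omB = rng.beta(1.0 + sz, 1.0 + nB - sz);
    }
    // ---- latent z and omega, checklist stream ----
    if (has_e) {
      if (nE > 0) {
        for (int n = 0; n < nE; ++n) {
          double s = 0.0;
          for (int j = 0; j < 6; ++j) s += b[j + 1] * X(n, j);
          dotX[n] = s;
        }
      }
      int sz = 0;
      for (int n = 0; n < nE; ++n) {
        if (ey[n] > 0) { zE[n] = 0; continue; }
        double lam = std::exp(lgam[eit[n]] + b[0] + dotX[n] + epsE[eo[n]]);
        double p1 = omE, p0 = (1.0 - omE) * std::exp(-lam);
        zE[n] = (rng.unif() * (p0 + p1) < p1) ? 1 : 0;
        sz += zE[n];
      }
      if (!fx_omE) omE = rng.beta(1.0 + sz, 1.0 + nE - sz);
    }
    // ---- log gamma ----
    if (!fx_lgam) {
      std::vector<double> A(nit, 0.0), C(nit, 0.0);
      for (int n = 0; n < nB; ++n) {
        if (zB[n]) continue;
        A[bit[n]] += by[n];
        C[bit[n]] += std::exp(off + epsB[bp[n]] + eta * bI[n]);
      }
      if (has_e) {
        for (int n = 0; n < nE; ++n) {
          if (zE[n]) continue;
          A[eit[n]] += ey[n];
          C[eit[n]] += std::exp(b[0] + dotX[n] + epsE[eo[n]]);
        }
      }
      for (int t = 0; t < nyear; ++t) {
        for (int i = 0; i < ncell; ++i) {
          int it = i + ncell * t;
          double m = alpha[i] + beta[i] * yearc[t];
          if (C[it] == 0.0 && A[it] == 0.0) {
            lgam[it] = norm_draw(m, vg, rng);
          } else {
            double Ait = A[it], Cit = C[it];
            lgam[it] = slice_sample([&](double x) {
              double r = x - m;
              return -0.5 * r * r / vg + Ait * x - Cit * std::exp(x);
            }, lgam[it], rng);
          }
        }
      }
    }
    // ---- cell intercepts and slopes (conjugate) ----
    for (int i = 0; i < ncell; ++i) {
      int k = bcr[i];
      double s1 = 0.0;
      for (int t = 0; t < nyear; ++t)
        s1 += lgam[i + ncell * t] - beta[i] * yearc[t];
      double prec = nyear / vg + 1.0 / va;
      alpha[i] = norm_draw((s1 / vg + muA[k] / va) / prec, 1.0 / prec, rng);
      if (!fx_beta) {
        double s2 = 0.0;
        for (int t = 0; t < nyear; ++t)
          s2 += yearc[t] * (lgam[i + ncell * t] - alpha[i]);
        double precb = sum_yc2 / vg + 1.0 / vb;
        beta[i] = norm_draw((s2 / vg + muB[k] / vb) / precb, 1.0 / precb, rng);
      }
    }
    // ---- BCR means and grand means (conjugate) ----
    for (int k = 0; k < nbcr; ++k) {
      double sa = 0.0, sb = 0.0;
      for (int i = 0; i < ncell; ++i) {
        if (bcr[i] != k) continue;
        sa += alpha[i]; sb += beta[i];
      }
      int nk = bcr_cells_count[k];
      double pa = nk / va + 1.0 / ta;
      muA[k] = norm_draw((sa / va + gmA / ta) / pa, 1.0 / pa, rng);
      double pb = nk / vb + 1.0 / tb;
      muB[k] = norm_draw((sb / vb + gmB / tb) / pb, 1.0 / pb, rng);
    }
    {
      double sa = 0.0, sb = 0.0;
      for (int k = 0; k < nbcr; ++k) { sa += muA[k]; sb += muB[k]; }
      double pa = nbcr / ta + 0.01;  // prior N(0, 100)
      gmA = norm_draw((sa / ta) / pa, 1.0 / pa, rng);
      double pb = nbcr / tb + 0.01;
      gmB = norm_draw((sb / tb) / pb, 1.0 / pb, rng);
    }
    // ---- variances (conjugate inverse gamma) ----
    if (!fx_va || !fx_vb) {
      double ssa = 0.0, ssb = 0.0;
      for (int i = 0; i < ncell; ++i) {
        double ra = alpha[i] - muA[bcr[i]], rb = beta[i] - muB[bcr[i]];
        ssa += ra * ra; ssb += rb * rb;
      }
      if (!fx_va) va = invgamma_draw(ncell, ssa, rng);
      if (!fx_vb) vb = invgamma_draw(ncell, ssb, rng);
    }
    if (!fx_ta || !fx_tb) {
      double ssa = 0.0, ssb = 0.0;
      for (int k = 0; k < nbcr; ++k) {
        double ra = muA[k] - gmA, rb = muB[k] - gmB;
        ssa += ra * ra; ssb += rb * rb;
      }
      if (!fx_ta) ta = invgamma_draw(nbcr, ssa, rng);
      if (!fx_tb) tb = invgamma_draw(nbcr, ssb, rng);
    }
    if (!fx_vg) {
      double ss = 0.0;
      for (int t = 0; t < nyear; ++t)
        for (int i = 0; i < ncell; ++i) {
          double r = lgam[i + ncell * t] - alpha[i] - beta[i] * yearc[t];
          ss += r * r;
        }
      vg = invgamma_draw(nit, ss, rng);
    }
    // ---- route-by-observer effects ----
    if (!fx_epsB) {
      for (int p = 0; p < npair; ++p) {
        double A = 0.0, C = 0.0;
        for (int n : bbs_pair[p]) {
          if (zB[n]) continue;
          A += by[n];
          C += std::exp(lgam[bit[n]] + off + eta * bI[n]);
        }
        if (C == 0.0 && A == 0.0) {
          epsB[p] = norm_draw(0.0, vB, rng);
        } else {
          epsB[p] = slice_sample([&](double x) {
            return -0.5 * x * x / vB + A * x - C * std::exp(x);
          }, epsB[p], rng);
        }
      }
      if (!fx_vB) {
        double ss = 0.0;
        for (int p = 0; p < npair; ++p) ss += epsB[p] * epsB[p];
        vB = invgamma_draw(npair, ss, rng);
      }
    }
    // ---- first-year observer effect ----
    if (!fx_eta) {
      double A = 0.0, C = 0.0;
      for (int n : eta_recs) {
        if (zB[n]) continue;
        A += by[n];
        C += std::exp(lgam[bit[n]] + off + epsB[bp[n]]);
      }
      eta = slice_sample([&](double x) {
        return -0.5 * x * x / 100.0 + A * x - C * std::exp(x);
      }, eta, rng);
    }
    // ---- checklist coefficients and observer effects ----
    if (has_e) {
      if (!fx_b && nE > 0) {
        // base linear predictor without b0 and without the covariate part
        std::vector<double> base(nE);
        for (int n = 0; n < nE; ++n)
          base[n] = lgam[eit[n]] + epsE[eo[n]];
        // b0: aggregated exponential sum
        {
          double A = 0.0, C = 0.0;
          for (int n = 0; n < nE; ++n) {
            if (zE[n]) continue;
            A += ey[n];
            C += std::exp(base[n] + dotX[n]);
          }
          b[0] = slice_sample([&](double x) {
            return -0.5 * x * x / 100.0 + A * x - C * std::exp(x);
          }, b[0], rng);
        }
        for (int j = 1; j <= 6; ++j) {
          double S = 0.0;
          std::vector<double> g; g.reserve(nE);
          std::vector<double> xv; xv.reserve(nE);
          for (int n = 0; n < nE; ++n) {
            if (zE[n]) continue;
            double xnj = X(n, j - 1);
            S += ey[n] * xnj;
            g.push_back(base[n] + b[0] + dotX[n] - b[j] * xnj);
            xv.push_back(xnj);
          }
          double bold = b[j];
          double bnew = slice_sample([&](double x) {
            double s = 0.0;
            for (size_t q = 0; q < g.size(); ++q)
              s += std::exp(g[q] + x * xv[q]);
            return -0.5 * x * x / 100.0 + S * x - s;
          }, bold, rng, 0.5);
          b[j] = bnew;
          if (bnew != bold)
            for (int n = 0; n < nE; ++n) dotX[n] += (bnew - bold) * X(n, j - 1);
        }
      } else if (!fx_b && nE == 0) {
        for (int j = 0; j < 7; ++j) b[j] = norm_draw(0.0, 100.0, rng);
      }
      if (!fx_epsE) {
        for (int s = 0; s < nobs; ++s) {
          double A = 0.0, C = 0.0;
          for (int n : e_obs[s]) {
            if (zE[n]) continue;
            A += ey[n];
            C += std::exp(lgam[eit[n]] + b[0] + dotX[n]);
          }
          if (C == 0.0 && A == 0.0) {
            epsE[s] = norm_draw(0.0, vE, rng);
          } else {
            epsE[s] = slice_sample([&](double x) {
              return -0.5 * x * x / vE + A * x - C * std::exp(x);
            }, epsE[s], rng);
          }
        }
        if (!fx_vE) {
          double ss = 0.0;
          for (int s = 0; s < nobs; ++s) ss += epsE[s] * epsE[s];
          vE = invgamma_draw(nobs, ss, rng);
        }
      }
    }
    // ---- store ----
    if (iter >= n_burn && (iter - n_burn) % thin == 0) {
      int c = 0;
      out(keep_row, c++) = gmA; out(keep_row, c++) = gmB;
      out(keep_row, c++) = ta; out(keep_row, c++) = tb;
      out(keep_row, c++) = va; out(keep_row, c++) = vb;
      out(keep_row, c++) = vg;
      for (int k = 0; k < nbcr; ++k) out(keep_row, c++) = muA[k];
      for (int k = 0; k < nbcr; ++k) out(keep_row, c++) = muB[k];
      for (int i = 0; i < ncell; ++i) out(keep_row, c++) = alpha[i];
      for (int i = 0; i < ncell; ++i) out(keep_row, c++) = beta[i];
      for (int it2 = 0; it2 < nit; ++it2) out(keep_row, c++) = lgam[it2];
      out(keep_row, c++) = omB; out(keep_row, c++) = vB;
      out(keep_row, c++) = eta;
      for (int p = 0; p < npair; ++p) out(keep_row, c++) = epsB[p];
      if (has_e) {
        for (int j = 0; j < 7; ++j) out(keep_row, c++) = b[j];
        out(keep_row, c++) = omE; out(keep_row, c++) = vE;
        for (int s = 0; s < nobs; ++s) out(keep_row, c++) = epsE[s];
      }
      ++keep_row;
    }
    if (iter % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
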