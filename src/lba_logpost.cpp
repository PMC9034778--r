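// Log-posterior, analytic gradient, and the HMC chain driver for the
// LBA race model on the unconstrained scale.
//
// Parameter vector xi has length K + 3 for K response options:
//   xi[0..K-1] -> v_i = exp(xi_i)        (drift rates, > 0)
//   xi[K]      -> A   = exp(xi_K)        (max start point, > 0)
//   xi[K+1]    -> k   = exp(xi_{K+1})    (relative threshold, > 0)
//   xi[K+2]    -> t0  = u * sigmoid(.)   (nondecision time in (0, u))
// with b = k + A and s fixed (1 by convention).
//
// Priors (on the constrained scale): v_i, A, k truncated-normal with
// lower bound 0 (the truncation constant is parameter-free and
// dropped); t0 uniform on (0, u). Log-Jacobians of the transforms are
// included so the density is correct over xi.
//
// With `normalize` the likelihood conditions on race termination
// (divides each trial's defective density by 1 - prod Phi(-v_i/s)),
// matching a sampler that resamples all-negative-drift trials.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double Z_CLIP = 38.0;
static const double DENS_FLOOR = 1e-290;
static const double INV_SQRT_2PI = 0.3989422804014327;

static inline double clipz(double z) {
  if (z > Z_CLIP) return Z_CLIP;
  if (z < -Z_CLIP) return -Z_CLIP;
  return z;
}

static inline double Phi(double z) { return 0.5 * std::erfc(-z * M_SQRT1_2); }
static inline double phi(double z) { return INV_SQRT_2PI * std::exp(-0.5 * z * z); }

struct Priors {
  int K;
  double v_mean, v_sd, A_mean, A_sd, k_mean, k_sd, t0_upper, s;
  bool normalize;
};

// Core: log posterior and gradient at xi. grad must have length K+3.
static double logpost_core(const double *xi, const double *rt,
                           const int *choice, int n, const Priors &pr,
                           bool use_lik, double *grad) {
  const int K = pr.K;
  const int d = K + 3;
  std::vector<double> v(K);
  for (int j = 0; j < K; ++j) v[j] = std::exp(xi[j]);
  const double A = std::exp(xi[K]);
  const double k = std::exp(xi[K + 1]);
  const double b = k + A;
  const double sg = 1.0 / (1.0 + std::exp(-xi[K + 2]));
  const double t0 = pr.t0_upper * sg;
  const double s = pr.s;

  double lp = 0.0;
  std::vector<double> g(d, 0.0); // grad wrt constrained (v, A, k, t0)

  for (int j = 0; j < K; ++j) {
    lp += -0.5 * std::pow((v[j] - pr.v_mean) / pr.v_sd, 2.0);
    g[j] += -(v[j] - pr.v_mean) / (pr.v_sd * pr.v_sd);
  }
  lp += -0.5 * std::pow((A - pr.A_mean) / pr.A_sd, 2.0);
  g[K] += -(A - pr.A_mean) / (pr.A_sd * pr.A_sd);
  lp += -0.5 * std::pow((k - pr.k_mean) / pr.k_sd, 2.0);
  g[K + 1] += -(k - pr.k_mean) / (pr.k_sd * pr.k_sd);
  // t0 uniform: flat on (0, u)

  if (use_lik && n > 0) {
    double gA = 0.0, gb = 0.0, gt0 = 0.0;
    std::vector<double> gv(K, 0.0);
    for (int tr = 0; tr < n; ++tr) {
      const double t = rt[tr] - t0;
      const int c = choice[tr] - 1;
      if (t <= 0.0) { lp += std::log(DENS_FLOOR); continue; }
      const double ts = t * s;
      double dl_dt = 0.0;
      for (int j = 0; j < K; ++j) {
        const double u1 = b - A - t * v[j];
        const double u2 = b - t * v[j];
        const double z1 = clipz(u1 / ts);
        const double z2 = clipz(u2 / ts);
        const double P1 = Phi(z1), P2 = Phi(z2);
        const double p1 = phi(z1), p2 = phi(z2);
        double f = (-v[j] * P1 + s * p1 + v[j] * P2 - s * p2) / A;
        if (j == c) {
          if (f < DENS_FLOOR) { lp += std::log(DENS_FLOOR); continue; }
          lp += std::log(f);
          const double df_dv = (P2 - P1 + p1 * (b - A) / t - p2 * b / t) / A;
          const double df_db = (b * p2 - (b - A) * p1) / (A * ts * t);
          const double df_dA = -f / A + p1 * (b - A) / (A * t * t * s);
          const double df_dt =
            ((b - A) * (b - A) * p1 - b * b * p2) / (A * t * t * t * s * s);
          gv[j] += df_dv / f;
          gb += df_db / f;
          gA += df_dA / f;
          dl_dt += df_dt / f;
        } else {
          double F = 1.0 + (u1 * P1 - u2 * P2) / A + ts * (p1 - p2) / A;
          if (F < 0.0) F = 0.0;
          double S = 1.0 - F;
          if (S < DENS_FLOOR) S = DENS_FLOOR;
          lp += std::log(S);
          const double dF_dv = (t / A) * (P2 - P1);
          const double dF_db = (P1 - P2) / A;
          const double dF_dA = (u2 * (P2 - P1) + ts * (p2 - p1)) / (A * A);
          const double dF_dt = (f > 0.0) ? f : 0.0;
          gv[j] += -dF_dv / S;
          gb += -dF_db / S;
          gA += -dF_dA / S;
          dl_dt += -dF_dt / S;
        }
      }
      gt0 += -dl_dt; // t = rt - t0
    }
    if (pr.normalize) {
      // condition on termination: subtract n * log(1 - prod Phi(-v/s))
      double Q = 1.0;
      std::vector<double> Pneg(K);
      for (int j = 0; j < K; ++j) {
        Pneg[j] = Phi(clipz(-v[j] / s));
        Q *= Pneg[j];
      }
      double T = 1.0 - Q;
      if (T < 1e-12) T = 1e-12;
      lp -= n * std::log(T);
      for (int j = 0; j < K; ++j) {
        // d/dv_j log T = (phi(-v_j/s)/s) * (Q / Pneg_j) / T
        double dQ_dv = -(phi(clipz(-v[j] / s)) / s);
        double prod_others = (Pneg[j] > 1e-300) ? Q / Pneg[j] : 0.0;
        gv[j] -= n * (-(dQ_dv * prod_others)) / T;
      }
    }
    for (int j = 0; j < K; ++j) g[j] += gv[j];
    g[K] += gA + gb;   // A enters directly and through b = k + A
    g[K + 1] += gb;    // k enters through b only
    g[K + 2] += gt0;
  }

  // transforms: Jacobians and chain rule to the xi scale
  for (int j = 0; j < K; ++j) {
    lp += xi[j];
    grad[j] = g[j] * v[j] + 1.0;
  }
  lp += xi[K];
  grad[K] = g[K] * A + 1.0;
  lp += xi[K + 1];
  grad[K + 1] = g[K + 1] * k + 1.0;
  lp += std::log(pr.t0_upper) + std::log(sg) + std::log1p(-sg);
  grad[K + 2] = g[K + 2] * pr.t0_upper * sg * (1.0 - sg) + (1.0 - 2.0 * sg);
  return lp;
}

// [[Rcpp::export(name = ".lba_logpost_grad")]]
List lba_logpost_grad(NumericVector xi,
                      NumericVector rt,
                      IntegerVector choice,
                      int n_opt,
                      double v_mean, double v_sd,
                      double A_mean, double A_sd,
                      double k_mean, double k_sd,
                      double t0_upper,
                      double s,
                      bool use_likelihood,
                      bool normalize) {
  Priors pr{n_opt, v_mean, v_sd, A_mean, A_sd, k_mean, k_sd, t0_upper,
            s, normalize};
  const int d = n_opt + 3;
  if (xi.size() != d) stop("xi has wrong length");
  NumericVector grad(d);
  const int *ch = choice.size() ? INTEGER(choice) : nullptr;
  const double *rp = rt.size() ? REAL(rt) : nullptr;
  double lp = logpost_core(REAL(xi), rp, ch, rt.size(), pr,
                           use_likelihood, REAL(grad));
  return List::create(_["lp"] = lp, _["grad"] = grad);
}

// in-place Cholesky of a small SPD matrix (row-major, d x d); returns
// false if not positive definite
static bool chol_small(std::vector<double> &a, int d) {
  for (int i = 0; i < d; ++i) {
    for (int j = 0; j <= i; ++j) {
      double sum = a[i * d + j];
      for (int q = 0; q < j; ++q) sum -= a[i * d + q] * a[j * d + q];
      if (i == j) {
        if (sum <= 0.0) return false;
        a[i * d + j] = std::sqrt(sum);
      } else {
        a[i * d + j] = sum / a[j * d + j];
      }
    }
    for (int j = i + 1; j < d; ++j) a[i * d + j] = 0.0;
  }
  return true;
}

// One HMC chain: dual-averaging step size targeting `target_accept`,
// dense mass matrix (position covariance) estimated once mid-warmup,
// jittered leapfrog path length. Uses R's RNG, so results are
// reproducible from set.seed() on the R side. Returns post-warmup
// draws on the unconstrained scale.
// [[Rcpp::export(name = ".lba_hmc_chain")]]
List lba_hmc_chain(NumericVector xi0,
                   NumericVector rt,
                   IntegerVector choice,
                   int n_opt,
                   double v_mean, double v_sd,
                   double A_mean, double A_sd,
                   double k_mean, double k_sd,
                   double t0_upper,
                   double s,
                   bool use_likelihood,
                   bool normalize,
                   int warmup, int iterations,
                   double target_accept,
                   int L_base) {
  Priors pr{n_opt, v_mean, v_sd, A_mean, A_sd, k_mean, k_sd, t0_upper,
            s, normalize};
  const int d = n_opt + 3;
  const int n = rt.size();
  const int *ch = n ? INTEGER(choice) : nullptr;
  const double *rp = n ? REAL(rt) : nullptr;

  std::vector<double> xi(xi0.begin(), xi0.end());
  std::vector<double> grad(d), g_p(d), p(d), z(d);
  // position-covariance Sigma = C C^T; momentum p ~ N(0, Sigma^{-1})
  // drawn as p = C^{-T} z; kinetic energy = 0.5 |C^T p|^2; the
  // position update uses Sigma p. Start from the identity.
  std::vector<double> C(d * d, 0.0);
  for (int i = 0; i < d; ++i) C[i * d + i] = 1.0;
  bool dense = false;

  double cur_lp = logpost_core(xi.data(), rp, ch, n, pr,
                               use_likelihood, grad.data());

  double eps = 0.1;
  double mu = std::log(10.0 * eps);
  double log_eps_bar = 0.0, H_bar = 0.0;
  const double da_gamma = 0.05, da_t0 = 10.0, da_kappa = 0.75;
  int adapt_iter = 0;

  const int n_keep = iterations - warmup;
  NumericMatrix keep(n_keep, d);
  int n_div_warm = 0, n_div_post = 0;

  const int win_lo = (int)std::floor(warmup * 0.45);
  const int win_hi = (int)std::floor(warmup * 0.85);
  std::vector<double> wsum(d, 0.0);
  std::vector<double> wxx(d * d, 0.0);
  int wn = 0;

  const int L_lo = std::max(2, L_base / 2);
  const int L_hi = L_base + L_base / 2;

  // helpers for the dense metric
  auto draw_momentum = [&](std::vector<double> &pm) {
    for (int i = 0; i < d; ++i) z[i] = R::norm_rand();
    if (!dense) { pm = z; return; }
    // solve C^T pm = z (C lower-triangular => back substitution)
    for (int i = d - 1; i >= 0; --i) {
      double sum = z[i];
      for (int q = i + 1; q < d; ++q) sum -= C[q * d + i] * pm[q];
      pm[i] = sum / C[i * d + i];
    }
  };
  auto kinetic = [&](const std::vector<double> &pm) {
    if (!dense) {
      double kk = 0.0;
      for (int i = 0; i < d; ++i) kk += pm[i] * pm[i];
      return 0.5 * kk;
    }
    double kk = 0.0;
    for (int i = 0; i < d; ++i) { // (C^T p)_i = sum_q C[q*d+i] p_q, q>=i
      double ci = 0.0;
      for (int q = i; q < d; ++q) ci += C[q * d + i] * pm[q];
      kk += ci * ci;
    }
    return 0.5 * kk;
  };
  std::vector<double> Sp(d);
  auto position_step = [&](std::vector<double> &x,
                           const std::vector<double> &pm) {
    if (!dense) {
      for (int i = 0; i < d; ++i) x[i] += eps * pm[i];
      return;
    }
    // Sigma p = C (C^T p)
    std::vector<double> ct(d, 0.0);
    for (int i = 0; i < d; ++i) {
      double ci = 0.0;
      for (int q = i; q < d; ++q) ci += C[q * d + i] * pm[q];
      ct[i] = ci;
    }
    for (int i = 0; i < d; ++i) {
      double si = 0.0;
      for (int q = 0; q <= i; ++q) si += C[i * d + q] * ct[q];
      Sp[i] = si;
      x[i] += eps * si;
    }
  };

  std::vector<double> xi_p(d), pp(d), gg(d);
  for (int it = 1; it <= iterations; ++it) {
    draw_momentum(p);
    int L = L_lo + (int)std::floor(R::unif_rand() * (L_hi - L_lo + 1));
    if (L > L_hi) L = L_hi;

    double H0 = -cur_lp + kinetic(p);
    xi_p = xi; pp = p; gg = grad;
    bool bad = false;
    double prop_lp = 0.0;
    for (int i = 0; i < d; ++i) pp[i] += 0.5 * eps * gg[i];
    for (int l = 0; l < L; ++l) {
      position_step(xi_p, pp);
      prop_lp = logpost_core(xi_p.data(), rp, ch, n, pr,
                             use_likelihood, g_p.data());
      if (!std::isfinite(prop_lp)) { bad = true; break; }
      gg = g_p;
      if (l < L - 1) for (int i = 0; i < d; ++i) pp[i] += eps * gg[i];
    }
    double a = 0.0, dH = 0.0;
    if (!bad) {
      for (int i = 0; i < d; ++i) pp[i] += 0.5 * eps * gg[i];
      dH = (-prop_lp + kinetic(pp)) - H0;
      if (!std::isfinite(dH) || dH > 1000.0) bad = true;
    }
    if (bad) {
      if (it <= warmup) ++n_div_warm; else ++n_div_post;
    } else {
      a = dH < 0 ? 1.0 : std::exp(-dH);
      if (R::unif_rand() < a) {
        xi = xi_p;
        grad = gg;
        cur_lp = prop_lp;
      }
    }
    if (it <= warmup) {
      ++adapt_iter;
      H_bar = (1.0 - 1.0 / (adapt_iter + da_t0)) * H_bar +
        (target_accept - a) / (adapt_iter + da_t0);
      double log_eps = mu - std::sqrt((double)adapt_iter) / da_gamma * H_bar;
      double w = std::pow((double)adapt_iter, -da_kappa);
      log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
      eps = std::exp(log_eps);
      if (it > win_lo && it <= win_hi) {
        ++wn;
        for (int i = 0; i < d; ++i) {
          wsum[i] += xi[i];
          for (int j = 0; j <= i; ++j) wxx[i * d + j] += xi[i] * xi[j];
        }
      }
      if (it == win_hi && wn > 5 * d) {
        // regularized covariance -> Cholesky factor; fall back to the
        // identity metric if the estimate is not positive definite
        std::vector<double> S(d * d, 0.0);
        for (int i = 0; i < d; ++i) {
          for (int j = 0; j <= i; ++j) {
            double cij = (wxx[i * d + j] -
                          wsum[i] * wsum[j] / wn) / (wn - 1.0);
            cij *= (double)wn / (wn + 5.0); // shrink toward diagonal
            S[i * d + j] = cij; S[j * d + i] = cij;
          }
          S[i * d + i] += 1e-5;
        }
        if (chol_small(S, d)) { C = S; dense = true; }
        adapt_iter = 0; H_bar = 0.0;
        mu = std::log(10.0 * std::exp(log_eps_bar));
        log_eps_bar = 0.0;
      }
      if (it == warmup) eps = std::exp(log_eps_bar);
    } else {
      for (int i = 0; i < d; ++i) keep(it - warmup - 1, i) = xi[i];
    }
  }
  return List::create(_["draws"] = keep, _["eps"] = eps,
                      _["n_divergent_warmup"] = n_div_warm,
                      _["n_divergent"] = n_div_post);
}
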