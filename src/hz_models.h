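#ifndef HZ_MODELS_H
#define HZ_MODELS_H

#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <memory>
#include <vector>

// Log posterior densities with analytic gradients on unconstrained scales.
// Conventions shared with the R-level loglik functions:
//  * binomial coefficients are omitted in known-genotype/ancestry kernels
//    (constant in the parameters) but kept inside genotype-likelihood
//    mixtures where they weight the states;
//  * constrained parameters are mapped via logit (probabilities), softmax
//    (simplexes) and log (scales), with Jacobians included here.
// Known-genotype data reach the hybrid-index and ancestry-class models as
// sufficient statistics (counts collapsed over loci sharing parental
// frequencies), computed in R; genotype-likelihood data stay per-cell.

namespace hz {

inline double plogis_stable(double x) {
  if (x >= 0.0) {
    return 1.0 / (1.0 + std::exp(-x));
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

// log(1 + exp(x))
inline double softplus(double x) {
  return x > 0.0 ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}

inline double clamp01(double p) {
  const double eps = 1e-12;
  if (p < eps) return eps;
  if (p > 1.0 - eps) return 1.0 - eps;
  return p;
}

class Model {
 public:
  virtual ~Model() {}
  virtual int dim() const = 0;
  // returns log posterior density (unnormalized) and fills grad
  virtual double logp_grad(const std::vector<double>& q,
                           std::vector<double>& grad) = 0;
};

// binomial count kernel: y log(p) + (n - y) log(1 - p), with the logs
// evaluated only when their weight is nonzero; accumulates d/dp
inline double count_kernel(double y, double n, double p, double& dldp) {
  double lp = 0.0;
  if (y > 0.0) {
    lp += y * std::log(p);
    dldp += y / p;
  }
  if (n - y > 0.0) {
    lp += (n - y) * std::log(1.0 - p);
    dldp -= (n - y) / (1.0 - p);
  }
  return lp;
}

// ---------------------------------------------------------------------------
// Genotype-likelihood mixture helpers: w = P(data | p) for one cell, where p
// is the probability that a sampled allele copy derives from source 1 state.
// Diploid: w = L0 (1-p)^2 + 2 L1 p (1-p) + L2 p^2 ; haploid: w = L0 (1-p) + L1 p.
inline void gl_cell(double l0, double l1, double l2, int nij, double p,
                    double& w, double& dwdp) {
  if (nij == 2) {
    double q1 = 1.0 - p;
    w = l0 * q1 * q1 + 2.0 * l1 * p * q1 + l2 * p * p;
    dwdp = 2.0 * (-l0 * q1 + l1 * (1.0 - 2.0 * p) + l2 * p);
  } else {
    w = l0 * (1.0 - p) + l1 * p;
    dwdp = l1 - l0;
  }
}

// ---------------------------------------------------------------------------
// Per-locus allele frequency model: x_i = logit(p_i), Beta(a, b) prior.
class FreqModel : public Model {
 public:
  int L;
  int mode;  // 0 = counts, 1 = genotype likelihoods
  double a, b;
  // counts mode
  std::vector<double> y, n;
  // GL mode
  Rcpp::NumericMatrix L0, L1, L2;
  Rcpp::IntegerMatrix N;
  Rcpp::LogicalMatrix miss;
  int nind;

  int dim() const override { return L; }

  double logp_grad(const std::vector<double>& q,
                   std::vector<double>& grad) override {
    double lp = 0.0;
    for (int i = 0; i < L; ++i) {
      double p = plogis_stable(q[i]);
      double pc = clamp01(p);
      // Beta prior plus logit Jacobian
      lp += a * std::log(pc) + b * std::log(1.0 - pc);
      double g = a * (1.0 - p) - b * p;
      if (mode == 0) {
        double dldp = 0.0;
        lp += count_kernel(y[i], n[i], pc, dldp);
        g += dldp * p * (1.0 - p);
      } else {
        const double* l0 = L0.begin() + (R_xlen_t)i * nind;
        const double* l1 = L1.begin() + (R_xlen_t)i * nind;
        const double* l2 = L2.begin() + (R_xlen_t)i * nind;
        const int* nn = N.begin() + (R_xlen_t)i * nind;
        const int* ms = miss.begin() + (R_xlen_t)i * nind;
        for (int j = 0; j < nind; ++j) {
          if (ms[j]) continue;
          double w, dwdp;
          gl_cell(l0[j], l1[j], l2[j], nn[j], pc, w, dwdp);
          if (w <= 0.0) return -std::numeric_limits<double>::infinity();
          lp += std::log(w);
          g += (dwdp / w) * p * (1.0 - p);
        }
      }
      grad[i] = g;
    }
    return lp;
  }
};

// ---------------------------------------------------------------------------
// Hybrid index model: x_j = logit(H_j), Beta(0.5, 0.5) prior.
// Ancestry mode is genotype mode with P0 = 0, P1 = 1 and G = Z.
// mode 0: per-cell counts; mode 1: genotype likelihoods; mode 2: sufficient
// statistics Y, M (allele and copy counts per frequency group).
class HiModel : public Model {
 public:
  int nind, L;
  int mode;
  double a, b;  // beta prior
  Rcpp::NumericMatrix G;
  Rcpp::NumericMatrix L0, L1, L2;
  Rcpp::IntegerMatrix N;
  Rcpp::LogicalMatrix miss;
  std::vector<double> P0, P1;
  // sufficient-statistic mode: K frequency groups
  int K;
  Rcpp::NumericMatrix Ysuff, Msuff;  // nind x K
  std::vector<double> P0g, P1g;

  int dim() const override { return nind; }

  double logp_grad(const std::vector<double>& q,
                   std::vector<double>& grad) override {
    double lp = 0.0;
    for (int j = 0; j < nind; ++j) {
      double H = plogis_stable(q[j]);
      double Hc = clamp01(H);
      lp += a * std::log(Hc) + b * std::log(1.0 - Hc);
      double dH = 0.0;  // d lp / d H from the data
      if (mode == 2) {
        for (int k = 0; k < K; ++k) {
          double m = Msuff(j, k);
          if (m <= 0.0) continue;
          double d = P1g[k] - P0g[k];
          double p = clamp01(H * d + P0g[k]);
          double dldp = 0.0;
          lp += count_kernel(Ysuff(j, k), m, p, dldp);
          dH += dldp * d;
        }
      } else if (mode == 0) {
        for (int i = 0; i < L; ++i) {
          if (miss(j, i)) continue;
          double d = P1[i] - P0[i];
          double p = clamp01(H * d + P0[i]);
          double dldp = 0.0;
          lp += count_kernel(G(j, i), N(j, i), p, dldp);
          dH += dldp * d;
        }
      } else {
        for (int i = 0; i < L; ++i) {
          if (miss(j, i)) continue;
          double d = P1[i] - P0[i];
          double p = clamp01(H * d + P0[i]);
          double w, dwdp;
          gl_cell(L0(j, i), L1(j, i), L2(j, i), N(j, i), p, w, dwdp);
          if (w <= 0.0) return -std::numeric_limits<double>::infinity();
          lp += std::log(w);
          dH += (dwdp / w) * d;
        }
      }
      grad[j] = dH * H * (1.0 - H) + (a * (1.0 - H) - b * H);
    }
    return lp;
  }
};

// ---------------------------------------------------------------------------
// Ancestry-class proportions model.  Per individual j, the simplex
// (Q00, Q10, Q11) = softmax(y1, y2, 0); parameter layout (y1_j, y2_j) pairs.
// The per-observation likelihood is linear in Q: w = a0 Q00 + a1 Q10 + a2 Q11.
// Grouped form: M distinct coefficient triples with per-individual counts W
// (known genotypes); per-cell form: coefficients per individual x locus
// (genotype likelihoods).  Prior Dirichlet(1,1,1); Jacobian sum(log Q).
class QModel : public Model {
 public:
  int nind, L;
  bool grouped;
  Rcpp::NumericMatrix A0, A1, A2;  // per-cell coefficients (nind x L)
  Rcpp::LogicalMatrix miss;
  int M;
  std::vector<double> a0g, a1g, a2g;  // grouped coefficients (M)
  Rcpp::NumericMatrix W;              // counts, nind x M

  int dim() const override { return 2 * nind; }

  double logp_grad(const std::vector<double>& q,
                   std::vector<double>& grad) override {
    double lp = 0.0;
    for (int j = 0; j < nind; ++j) {
      double y1 = q[2 * j], y2 = q[2 * j + 1];
      double mx = std::max(0.0, std::max(y1, y2));
      double e1 = std::exp(y1 - mx), e2 = std::exp(y2 - mx),
             e3 = std::exp(-mx);
      double S = e1 + e2 + e3;
      double Q0 = e1 / S, Q1 = e2 / S, Q2 = e3 / S;
      lp += std::log(clamp01(Q0)) + std::log(clamp01(Q1)) +
            std::log(clamp01(Q2));
      double g1 = 1.0 - 3.0 * Q0;
      double g2 = 1.0 - 3.0 * Q1;
      if (grouped) {
        for (int m = 0; m < M; ++m) {
          double wt = W(j, m);
          if (wt <= 0.0) continue;
          double w = a0g[m] * Q0 + a1g[m] * Q1 + a2g[m] * Q2;
          if (w <= 0.0) return -std::numeric_limits<double>::infinity();
          lp += wt * std::log(w);
          g1 += wt * Q0 * (a0g[m] - w) / w;
          g2 += wt * Q1 * (a1g[m] - w) / w;
        }
      } else {
        for (int i = 0; i < L; ++i) {
          if (miss(j, i)) continue;
          double a0 = A0(j, i), a1 = A1(j, i), a2 = A2(j, i);
          double w = a0 * Q0 + a1 * Q1 + a2 * Q2;
          if (w <= 0.0) return -std::numeric_limits<double>::infinity();
          lp += std::log(w);
          g1 += Q0 * (a0 - w) / w;
          g2 += Q1 * (a1 - w) / w;
        }
      }
      grad[2 * j] = g1;
      grad[2 * j + 1] = g2;
    }
    return lp;
  }
};

// ---------------------------------------------------------------------------
// Hierarchical logit-logistic genomic cline model.
// logit(phi_ij) = v_i (logit(H_j) - logit(c_i)); data kernels as in HiModel
// with phi in place of H.  Parameter layout:
//   [raw_v (L), raw_c (L), (log sigma_v, log sigma_c), (mu_v, mu_c)]
// est_sigma: non-centered, log10(v_i) = mu_v + sigma_v raw_v_i,
//            logit(c_i) = mu_c + sigma_c raw_c_i, raw ~ N(0,1),
//            sigma ~ half-Normal(0, sigma0) (+ log Jacobian).
// !est_sigma (fixed-SD / non-hierarchical): centered, raw_v = log10(v),
//            raw_c = logit(c), priors N(0, fixed sigma).
// Ancestry data (P0 = 0, P1 = 1) use the direct binomial-in-phi kernel.
class ClineModel : public Model {
 public:
  int nind, L;
  int mode;  // 0 = genotype/ancestry counts, 1 = genotype likelihoods
  bool est_sigma, est_mu;
  double sigma0, mu0, sv_fixed, sc_fixed;
  Rcpp::NumericMatrix G;
  Rcpp::NumericMatrix L0, L1, L2;
  Rcpp::IntegerMatrix N;
  Rcpp::LogicalMatrix miss;
  std::vector<double> P0, P1, t;  // t_j = logit(H_j)

  int dim() const override {
    return 2 * L + (est_sigma ? 2 : 0) + (est_mu ? 2 : 0);
  }

  double logp_grad(const std::vector<double>& q,
                   std::vector<double>& grad) override {
    const double LN10 = 2.302585092994045684;
    double sv = sv_fixed, sc = sc_fixed, mv = 0.0, mc = 0.0;
    int idx = 2 * L;
    if (est_sigma) {
      sv = std::exp(q[idx]);
      sc = std::exp(q[idx + 1]);
    }
    if (est_mu) {
      mv = q[idx + 2];
      mc = q[idx + 3];
    }
    double lp = 0.0;
    double gsv = 0.0, gsc = 0.0, gmv = 0.0, gmc = 0.0;
    const double* tt = t.data();

    for (int i = 0; i < L; ++i) {
      double rv = q[i], rc = q[L + i];
      double lv, th;
      double gprior_v, gprior_c;
      if (est_sigma) {
        lv = mv + sv * rv;
        th = mc + sc * rc;
        lp += -0.5 * rv * rv - 0.5 * rc * rc;
        gprior_v = -rv;
        gprior_c = -rc;
      } else {
        lv = rv;
        th = rc;
        lp += -0.5 * lv * lv / (sv * sv) - 0.5 * th * th / (sc * sc);
        gprior_v = -lv / (sv * sv);
        gprior_c = -th / (sc * sc);
      }
      // plateau guard: beyond this the likelihood is flat in v
      if (lv > 100.0) lv = 100.0;
      if (lv < -100.0) lv = -100.0;
      double v = std::pow(10.0, lv);
      double p0 = P0[i], p1 = P1[i];
      double d = p1 - p0;
      bool anc = (mode == 0 && p0 == 0.0 && p1 == 1.0);
      double gv = 0.0, gt = 0.0;  // d lp / d v, d lp / d theta
      const int* ms = miss.begin() + (R_xlen_t)i * nind;
      if (mode == 0) {
        const double* gc = G.begin() + (R_xlen_t)i * nind;
        const int* nn = N.begin() + (R_xlen_t)i * nind;
        if (anc) {
          // binomial in phi: Z eta - N log(1 + e^eta)
          for (int j = 0; j < nind; ++j) {
            if (ms[j]) continue;
            double x = tt[j] - th;
            double eta = v * x;
            double ph = plogis_stable(eta);
            lp += gc[j] * eta - nn[j] * softplus(eta);
            double dldeta = gc[j] - nn[j] * ph;
            gv += dldeta * x;
            gt -= dldeta * v;
          }
        } else {
          for (int j = 0; j < nind; ++j) {
            if (ms[j]) continue;
            double x = tt[j] - th;
            double ph = plogis_stable(v * x);
            double p = clamp01(ph * d + p0);
            double dldp = 0.0;
            lp += count_kernel(gc[j], nn[j], p, dldp);
            double dldeta = dldp * d * ph * (1.0 - ph);
            gv += dldeta * x;
            gt -= dldeta * v;
          }
        }
      } else {
        const double* l0 = L0.begin() + (R_xlen_t)i * nind;
        const double* l1 = L1.begin() + (R_xlen_t)i * nind;
        const double* l2 = L2.begin() + (R_xlen_t)i * nind;
        const int* nn = N.begin() + (R_xlen_t)i * nind;
        for (int j = 0; j < nind; ++j) {
          if (ms[j]) continue;
          double x = tt[j] - th;
          double ph = plogis_stable(v * x);
          double p = clamp01(ph * d + p0);
          double w, dwdp;
          gl_cell(l0[j], l1[j], l2[j], nn[j], p, w, dwdp);
          if (w <= 0.0) return -std::numeric_limits<double>::infinity();
          lp += std::log(w);
          double dldeta = (dwdp / w) * d * ph * (1.0 - ph);
          gv += dldeta * x;
          gt -= dldeta * v;
        }
      }
      double gv_lv = gv * v * LN10;  // d lp / d log10(v)
      if (est_sigma) {
        grad[i] = gprior_v + gv_lv * sv;
        grad[L + i] = gprior_c + gt * sc;
        gsv += gv_lv * rv * sv;
        gsc += gt * rc * sc;
        gmv += gv_lv;
        gmc += gt;
      } else {
        grad[i] = gprior_v + gv_lv;
        grad[L + i] = gprior_c + gt;
      }
    }
    if (est_sigma) {
      // half-normal(sigma0) on sigma plus log Jacobian of exp
      lp += -0.5 * sv * sv / (sigma0 * sigma0) + q[idx];
      lp += -0.5 * sc * sc / (sigma0 * sigma0) + q[idx + 1];
      grad[idx] = gsv - sv * sv / (sigma0 * sigma0) + 1.0;
      grad[idx + 1] = gsc - sc * sc / (sigma0 * sigma0) + 1.0;
    }
    if (est_mu) {
      lp += -0.5 * mv * mv / (mu0 * mu0) - 0.5 * mc * mc / (mu0 * mu0);
      grad[idx + 2] = gmv - mv / (mu0 * mu0);
      grad[idx + 3] = gmc - mc / (mu0 * mu0);
    }
    return lp;
  }
};

// ---------------------------------------------------------------------------
// Arbitrary target supplied as an R function returning list(value, grad).
class RFunModel : public Model {
 public:
  Rcpp::Function f;
  int d;
  RFunModel(Rcpp::Function fn, int dim_) : f(fn), d(dim_) {}
  int dim() const override { return d; }
  double logp_grad(const std::vector<double>& q,
                   std::vector<double>& grad) override {
    Rcpp::NumericVector qv(q.begin(), q.end());
    Rcpp::List res = f(qv);
    double lp = Rcpp::as<double>(res[0]);
    Rcpp::NumericVector g = res[1];
    for (int i = 0; i < d; ++i) grad[i] = g[i];
    return lp;
  }
};

std::unique_ptr<Model> build_model(Rcpp::List spec);

}  // namespace hz

#endif
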