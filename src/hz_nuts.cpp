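#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <memory>
#include <vector>

#include "hz_models.h"
#include "hz_rng.h"

using namespace Rcpp;

namespace hz {

std::unique_ptr<Model> build_model(List spec) {
  std::string type = as<std::string>(spec["type"]);
  if (type == "freq") {
    auto m = std::make_unique<FreqModel>();
    m->L = as<int>(spec["n_loci"]);
    m->mode = as<int>(spec["mode"]);
    m->a = as<double>(spec["a"]);
    m->b = as<double>(spec["b"]);
    if (m->mode == 0) {
      m->y = as<std::vector<double>>(spec["y"]);
      m->n = as<std::vector<double>>(spec["n"]);
      m->nind = 0;
    } else {
      m->L0 = as<NumericMatrix>(spec["L0"]);
      m->L1 = as<NumericMatrix>(spec["L1"]);
      m->L2 = as<NumericMatrix>(spec["L2"]);
      m->N = as<IntegerMatrix>(spec["N"]);
      m->miss = as<LogicalMatrix>(spec["miss"]);
      m->nind = m->L0.nrow();
    }
    return m;
  }
  if (type == "hi") {
    auto m = std::make_unique<HiModel>();
    m->mode = as<int>(spec["mode"]);
    m->a = as<double>(spec["a"]);
    m->b = as<double>(spec["b"]);
    if (m->mode == 2) {
      m->Ysuff = as<NumericMatrix>(spec["Y"]);
      m->Msuff = as<NumericMatrix>(spec["M"]);
      m->P0g = as<std::vector<double>>(spec["P0g"]);
      m->P1g = as<std::vector<double>>(spec["P1g"]);
      m->K = m->Ysuff.ncol();
      m->nind = m->Ysuff.nrow();
      m->L = 0;
    } else {
      m->N = as<IntegerMatrix>(spec["N"]);
      m->miss = as<LogicalMatrix>(spec["miss"]);
      m->P0 = as<std::vector<double>>(spec["P0"]);
      m->P1 = as<std::vector<double>>(spec["P1"]);
      if (m->mode == 0) {
        m->G = as<NumericMatrix>(spec["G"]);
      } else {
        m->L0 = as<NumericMatrix>(spec["L0"]);
        m->L1 = as<NumericMatrix>(spec["L1"]);
        m->L2 = as<NumericMatrix>(spec["L2"]);
      }
      m->nind = m->N.nrow();
      m->L = m->N.ncol();
    }
    return m;
  }
  if (type == "q") {
    auto m = std::make_unique<QModel>();
    m->grouped = as<bool>(spec["grouped"]);
    if (m->grouped) {
      m->W = as<NumericMatrix>(spec["W"]);
      m->a0g = as<std::vector<double>>(spec["a0"]);
      m->a1g = as<std::vector<double>>(spec["a1"]);
      m->a2g = as<std::vector<double>>(spec["a2"]);
      m->M = m->W.ncol();
      m->nind = m->W.nrow();
      m->L = 0;
    } else {
      m->A0 = as<NumericMatrix>(spec["A0"]);
      m->A1 = as<NumericMatrix>(spec["A1"]);
      m->A2 = as<NumericMatrix>(spec["A2"]);
      m->miss = as<LogicalMatrix>(spec["miss"]);
      m->nind = m->A0.nrow();
      m->L = m->A0.ncol();
    }
    return m;
  }
  if (type == "cline") {
    auto m = std::make_unique<ClineModel>();
    m->mode = as<int>(spec["mode"]);
    m->est_sigma = as<bool>(spec["est_sigma"]);
    m->est_mu = as<bool>(spec["est_mu"]);
    m->sigma0 = as<double>(spec["sigma0"]);
    m->mu0 = as<double>(spec["mu0"]);
    m->sv_fixed = as<double>(spec["sv_fixed"]);
    m->sc_fixed = as<double>(spec["sc_fixed"]);
    m->N = as<IntegerMatrix>(spec["N"]);
    m->miss = as<LogicalMatrix>(spec["miss"]);
    m->P0 = as<std::vector<double>>(spec["P0"]);
    m->P1 = as<std::vector<double>>(spec["P1"]);
    m->t = as<std::vector<double>>(spec["t"]);
    if (m->mode == 0) {
      m->G = as<NumericMatrix>(spec["G"]);
    } else {
      m->L0 = as<NumericMatrix>(spec["L0"]);
      m->L1 = as<NumericMatrix>(spec["L1"]);
      m->L2 = as<NumericMatrix>(spec["L2"]);
    }
    m->nind = m->N.nrow();
    m->L = m->N.ncol();
    return m;
  }
  if (type == "rfun") {
    Function f = spec["logp"];
    int d = as<int>(spec["n_pars"]);
    return std::make_unique<RFunModel>(f, d);
  }
  stop("unknown model type");
}

// ---------------------------------------------------------------------------
// No-U-Turn sampler (Hoffman & Gelman 2014, Alg. 6) with dual-averaging step
// size adaptation and windowed diagonal mass-matrix (metric) estimation.

struct Tree {
  std::vector<double> qm, rm, gm;   // backward end
  std::vector<double> qp, rp, gp;   // forward end
  std::vector<double> qprop, gprop;
  double lpprop;
  double n;
  bool s;
  bool div;
  double alpha;
  int nalpha;
};

class Nuts {
 public:
  Model* m;
  HZRng rng;
  int d;
  std::vector<double> minv;  // inverse metric (posterior variance estimate)
  double eps;
  int max_depth;

  Nuts(Model* model, uint64_t seed, int max_depth_)
      : m(model), rng(seed), d(model->dim()), minv(model->dim(), 1.0),
        eps(1.0), max_depth(max_depth_) {}

  double ke(const std::vector<double>& r) const {
    double k = 0.0;
    for (int i = 0; i < d; ++i) k += minv[i] * r[i] * r[i];
    return 0.5 * k;
  }

  void draw_momentum(std::vector<double>& r) {
    for (int i = 0; i < d; ++i) r[i] = rng.norm() / std::sqrt(minv[i]);
  }

  // one leapfrog step; lp/grad updated in place; returns false on nonfinite
  bool leapfrog(std::vector<double>& q, std::vector<double>& r,
                std::vector<double>& grad, double& lp, double e) {
    for (int i = 0; i < d; ++i) r[i] += 0.5 * e * grad[i];
    for (int i = 0; i < d; ++i) q[i] += e * minv[i] * r[i];
    lp = m->logp_grad(q, grad);
    if (!std::isfinite(lp)) {
      lp = -std::numeric_limits<double>::infinity();
      for (int i = 0; i < d; ++i)
        if (!std::isfinite(grad[i])) grad[i] = 0.0;
      return false;
    }
    for (int i = 0; i < d; ++i) r[i] += 0.5 * e * grad[i];
    return true;
  }

  bool no_uturn(const std::vector<double>& qm, const std::vector<double>& qp,
                const std::vector<double>& rm,
                const std::vector<double>& rp) const {
    double sm = 0.0, sp = 0.0;
    for (int i = 0; i < d; ++i) {
      double dq = qp[i] - qm[i];
      sm += dq * minv[i] * rm[i];
      sp += dq * minv[i] * rp[i];
    }
    return sm >= 0.0 && sp >= 0.0;
  }

  Tree build_tree(const std::vector<double>& q, const std::vector<double>& r,
                  const std::vector<double>& grad, double lp, double log_u,
                  int dir, int depth, double joint0) {
    if (depth == 0) {
      Tree t;
      t.qm = q;
      t.rm = r;
      t.gm = grad;
      double lp1 = lp;
      bool ok = leapfrog(t.qm, t.rm, t.gm, lp1, dir * eps);
      double joint = ok ? lp1 - ke(t.rm)
                        : -std::numeric_limits<double>::infinity();
      if (!std::isfinite(joint))
        joint = -std::numeric_limits<double>::infinity();
      t.qp = t.qm;
      t.rp = t.rm;
      t.gp = t.gm;
      t.qprop = t.qm;
      t.gprop = t.gm;
      t.lpprop = lp1;
      t.n = (log_u <= joint) ? 1.0 : 0.0;
      t.div = (joint - joint0) < -1000.0 || !std::isfinite(joint);
      t.s = !t.div;
      double a = std::exp(joint - joint0);
      t.alpha = (std::isfinite(a) && a < 1.0) ? a : 1.0;
      if (!std::isfinite(joint)) t.alpha = 0.0;
      t.nalpha = 1;
      return t;
    }
    Tree t1 = build_tree(q, r, grad, lp, log_u, dir, depth - 1, joint0);
    if (!t1.s) return t1;
    Tree t2 = (dir == 1)
                  ? build_tree(t1.qp, t1.rp, t1.gp, 0.0, log_u, dir,
                               depth - 1, joint0)
                  : build_tree(t1.qm, t1.rm, t1.gm, 0.0, log_u, dir,
                               depth - 1, joint0);
    // note: lp argument is unused at depth>0 entry (leapfrog recomputes)
    if (dir == 1) {
      t1.qp = t2.qp;
      t1.rp = t2.rp;
      t1.gp = t2.gp;
    } else {
      t1.qm = t2.qm;
      t1.rm = t2.rm;
      t1.gm = t2.gm;
    }
    double ntot = t1.n + t2.n;
    if (ntot > 0.0 && rng.unif() < t2.n / ntot) {
      t1.qprop = t2.qprop;
      t1.gprop = t2.gprop;
      t1.lpprop = t2.lpprop;
    }
    t1.n = ntot;
    t1.alpha += t2.alpha;
    t1.nalpha += t2.nalpha;
    t1.div = t1.div || t2.div;
    t1.s = t2.s && no_uturn(t1.qm, t1.qp, t1.rm, t1.rp);
    return t1;
  }

  double find_reasonable_eps(const std::vector<double>& q0,
                             const std::vector<double>& grad0, double lp0) {
    eps = 1.0;
    std::vector<double> r(d);
    draw_momentum(r);
    double joint0 = lp0 - ke(r);
    std::vector<double> q = q0, g = grad0, r1 = r;
    double lp = lp0;
    leapfrog(q, r1, g, lp, eps);
    double joint1 = lp - ke(r1);
    if (!std::isfinite(joint1))
      joint1 = joint0 - 1000.0;
    double a = (joint1 - joint0 > std::log(0.5)) ? 1.0 : -1.0;
    for (int it = 0; it < 100; ++it) {
      q = q0;
      g = grad0;
      r1 = r;
      lp = lp0;
      leapfrog(q, r1, g, lp, eps);
      joint1 = lp - ke(r1);
      if (!std::isfinite(joint1)) joint1 = joint0 - 1000.0;
      if (a * (joint1 - joint0) <= a * std::log(0.5)) break;
      eps *= std::pow(2.0, a);
      if (eps > 1e7 || eps < 1e-10) break;
    }
    return eps;
  }
};

}  // namespace hz

// [[Rcpp::export]]
List hz_model_logp(List model_spec, NumericVector q) {
  auto m = hz::build_model(model_spec);
  std::vector<double> qq(q.begin(), q.end());
  std::vector<double> grad(m->dim(), 0.0);
  double lp = m->logp_grad(qq, grad);
  return List::create(Named("value") = lp,
                      Named("grad") = NumericVector(grad.begin(), grad.end()));
}

// [[Rcpp::export]]
List hz_nuts_chain(List model_spec, NumericVector init, int n_iter,
                   int n_warmup, int thin, double target_accept,
                   int max_treedepth, double seed) {
  auto model = hz::build_model(model_spec);
  int d = model->dim();
  hz::Nuts nuts(model.get(), static_cast<uint64_t>(seed), max_treedepth);

  std::vector<double> q(init.begin(), init.end());
  std::vector<double> grad(d, 0.0);
  double lp = model->logp_grad(q, grad);
  if (!std::isfinite(lp)) stop("non-finite log density at initial value");

  nuts.eps = nuts.find_reasonable_eps(q, grad, lp);

  // dual averaging state (Hoffman & Gelman defaults)
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  double mu = std::log(10.0 * nuts.eps);
  double log_eps_bar = 0.0, hbar = 0.0;
  int da_t = 0;

  // metric adaptation windows (Stan-style schedule)
  int init_buf = std::min(75, static_cast<int>(0.15 * n_warmup));
  int term_buf = std::min(150, static_cast<int>(0.15 * n_warmup));
  int window = 25;
  int win_start = init_buf;
  int win_end = std::min(win_start + window, n_warmup - term_buf);
  if (n_warmup < 20) win_end = -1;  // no metric adaptation for tiny warmups
  std::vector<double> wmean(d, 0.0), wm2(d, 0.0);
  int wn = 0;

  int n_keep = (n_iter - n_warmup) / thin;
  NumericMatrix draws(n_keep, d);
  int kept = 0;
  int n_div = 0;
  double accept_sum = 0.0;
  double depth_sum = 0.0;

  std::vector<double> r0(d);
  for (int iter = 0; iter < n_iter; ++iter) {
    nuts.draw_momentum(r0);
    double joint0 = lp - nuts.ke(r0);
    double log_u = joint0 - nuts.rng.expo();

    std::vector<double> qm = q, qp = q, rm = r0, rp = r0, gm = grad, gp = grad;
    double n_tot = 1.0;
    bool s = true;
    bool any_div = false;
    double alpha = 0.0;
    int nalpha = 0;
    int depth = 0;

    while (s && depth < max_treedepth) {
      int dir = (nuts.rng.unif() < 0.5) ? -1 : 1;
      hz::Tree t =
          (dir == 1)
              ? nuts.build_tree(qp, rp, gp, 0.0, log_u, dir, depth, joint0)
              : nuts.build_tree(qm, rm, gm, 0.0, log_u, dir, depth, joint0);
      if (dir == 1) {
        qp = t.qp;
        rp = t.rp;
        gp = t.gp;
      } else {
        qm = t.qm;
        rm = t.rm;
        gm = t.gm;
      }
      if (t.s && t.n > 0.0 && nuts.rng.unif() < t.n / n_tot) {
        q = t.qprop;
        grad = t.gprop;
        lp = t.lpprop;
      }
      n_tot += t.n;
      alpha += t.alpha;
      nalpha += t.nalpha;
      any_div = any_div || t.div;
      s = t.s && nuts.no_uturn(qm, qp, rm, rp);
      ++depth;
    }

    double astat = (nalpha > 0) ? alpha / nalpha : 0.0;

    if (iter < n_warmup) {
      ++da_t;
      hbar = (1.0 - 1.0 / (da_t + t0)) * hbar +
             (target_accept - astat) / (da_t + t0);
      double log_eps = mu - std::sqrt(static_cast<double>(da_t)) / gamma * hbar;
      double w = std::pow(static_cast<double>(da_t), -kappa);
      log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
      nuts.eps = std::exp(log_eps);

      // metric window bookkeeping
      if (iter >= win_start && win_end > 0 && iter < n_warmup - term_buf) {
        ++wn;
        for (int i = 0; i < d; ++i) {
          double delta = q[i] - wmean[i];
          wmean[i] += delta / wn;
          wm2[i] += delta * (q[i] - wmean[i]);
        }
        if (iter + 1 == win_end) {
          if (wn > 2) {
            for (int i = 0; i < d; ++i) {
              double var = wm2[i] / (wn - 1);
              nuts.minv[i] =
                  var * wn / (wn + 5.0) + 1e-3 * (5.0 / (wn + 5.0));
            }
          }
          std::fill(wmean.begin(), wmean.end(), 0.0);
          std::fill(wm2.begin(), wm2.end(), 0.0);
          wn = 0;
          window *= 2;
          win_start = iter + 1;
          win_end = win_start + window;
          if (win_end + 2 * window > n_warmup - term_buf)
            win_end = n_warmup - term_buf;
          // restart step-size adaptation around the current value
          mu = std::log(10.0 * nuts.eps);
          hbar = 0.0;
          log_eps_bar = std::log(nuts.eps);
          da_t = 0;
        }
      }
      if (iter + 1 == n_warmup) nuts.eps = std::exp(log_eps_bar);
    } else {
      accept_sum += astat;
      depth_sum += depth;
      if (any_div) ++n_div;
      if ((iter - n_warmup) % thin == 0 && kept < n_keep) {
        for (int i = 0; i < d; ++i) draws(kept, i) = q[i];
        ++kept;
      }
    }
    if (iter % 256 == 0) Rcpp::checkUserInterrupt();
  }

  int n_samp = n_iter - n_warmup;
  return List::create(
      Named("draws") = draws, Named("n_divergent") = n_div,
      Named("step_size") = nuts.eps,
      Named("accept_mean") = n_samp > 0 ? accept_sum / n_samp : NA_REAL,
      Named("treedepth_mean") = n_samp > 0 ? depth_sum / n_samp : NA_REAL);
}
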