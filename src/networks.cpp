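// Recurrent network core: forward dynamics, backpropagation through time,
// and the Adam training loop, for the gated (GRU-style) architecture and
// its ablations. Written directly against the update equations:
//   r = sigmoid(Wxr x + bxr + Whr h + bhr)
//   z = sigmoid(Wxz x + bxz + Whz h + bhz)
//   c = tanh(Wxh x + bxh + r .* (Whh h) + bhh)   (bhh outside the r product)
//   h' = z .* h + (1 - z) .* c
// Without gating, r == 1 and z == 0: h' = tanh(Wxh x + bxh + Whh h + bhh).
// Without lateral connections the Wh* matrices are diagonal (enforced by
// zero initialisation plus gradient masking). The output unit is
// p = sigmoid(whp . h + bhp) for every architecture.
//
// The prediction emitted after consuming observation t is scored against
// observation t+1; the pre-observation output (h = 0) is emitted but never
// scored, so each sequence contributes T-1 loss terms.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

inline double sigmoid(double u) { return 1.0 / (1.0 + std::exp(-u)); }

struct Par {
  int N;
  bool gated;
  std::vector<double> Wxr, bxr, Whr, bhr;
  std::vector<double> Wxz, bxz, Whz, bhz;
  std::vector<double> Wxh, bxh, Whh, bhh;
  std::vector<double> whp;
  double bhp;
};

std::vector<double> as_vec(SEXP s) {
  NumericVector v(s);
  return std::vector<double>(v.begin(), v.end());
}

Par unpack(const List& params) {
  Par p;
  p.N = as<int>(params["n_units"]);
  std::string arch = as<std::string>(params["arch"]);
  p.gated = arch != "no_gating";
  if (p.gated) {
    p.Wxr = as_vec(params["Wxr"]); p.bxr = as_vec(params["bxr"]);
    p.Whr = as_vec(params["Whr"]); p.bhr = as_vec(params["bhr"]);
    p.Wxz = as_vec(params["Wxz"]); p.bxz = as_vec(params["bxz"]);
    p.Whz = as_vec(params["Whz"]); p.bhz = as_vec(params["bhz"]);
  }
  p.Wxh = as_vec(params["Wxh"]); p.bxh = as_vec(params["bxh"]);
  p.Whh = as_vec(params["Whh"]); p.bhh = as_vec(params["bhh"]);
  p.whp = as_vec(params["whp"]);
  p.bhp = as<double>(params["bhp"]);
  return p;
}

// W stored column-major N x N, entry (i, j) = weight from unit j to unit i.
inline void matvec(const std::vector<double>& W, const double* h, int N,
                   double* out) {
  for (int i = 0; i < N; ++i) out[i] = 0.0;
  for (int j = 0; j < N; ++j) {
    const double hj = h[j];
    if (hj == 0.0) continue;
    const double* col = &W[(size_t)j * N];
    for (int i = 0; i < N; ++i) out[i] += col[i] * hj;
  }
}

inline void matvec_t(const std::vector<double>& W, const double* d, int N,
                     double* out) {  // out = W^T d
  for (int j = 0; j < N; ++j) {
    const double* col = &W[(size_t)j * N];
    double s = 0.0;
    for (int i = 0; i < N; ++i) s += col[i] * d[i];
    out[j] = s;
  }
}

// One forward step; h_prev and h_new may not alias. Work buffers r, z, c, a
// (a = Whh h_prev, the ungated recurrent drive) are filled when gated.
void step(const Par& p, const double* h_prev, double x,
          double* h_new, double* r, double* z, double* c, double* a) {
  const int N = p.N;
  std::vector<double> tmp(N);
  if (p.gated) {
    matvec(p.Whr, h_prev, N, tmp.data());
    for (int i = 0; i < N; ++i)
      r[i] = sigmoid(p.Wxr[i] * x + p.bxr[i] + tmp[i] + p.bhr[i]);
    matvec(p.Whz, h_prev, N, tmp.data());
    for (int i = 0; i < N; ++i)
      z[i] = sigmoid(p.Wxz[i] * x + p.bxz[i] + tmp[i] + p.bhz[i]);
    matvec(p.Whh, h_prev, N, a);
    for (int i = 0; i < N; ++i) {
      c[i] = std::tanh(p.Wxh[i] * x + p.bxh[i] + r[i] * a[i] + p.bhh[i]);
      h_new[i] = z[i] * h_prev[i] + (1.0 - z[i]) * c[i];
    }
  } else {
    matvec(p.Whh, h_prev, N, tmp.data());
    for (int i = 0; i < N; ++i)
      h_new[i] = std::tanh(p.Wxh[i] * x + p.bxh[i] + tmp[i] + p.bhh[i]);
  }
}

inline double output(const Par& p, const double* h) {
  double u = p.bhp;
  for (int i = 0; i < p.N; ++i) u += p.whp[i] * h[i];
  return sigmoid(u);
}

struct Grad {
  std::vector<double> Wxr, bxr, Whr, bhr;
  std::vector<double> Wxz, bxz, Whz, bhz;
  std::vector<double> Wxh, bxh, Whh, bhh;
  std::vector<double> whp;
  double bhp;
  void init(int N, bool gated) {
    size_t n = N, nn = (size_t)N * N;
    if (gated) {
      Wxr.assign(n, 0); bxr.assign(n, 0); Whr.assign(nn, 0); bhr.assign(n, 0);
      Wxz.assign(n, 0); bxz.assign(n, 0); Whz.assign(nn, 0); bhz.assign(n, 0);
    }
    Wxh.assign(n, 0); bxh.assign(n, 0); Whh.assign(nn, 0); bhh.assign(n, 0);
    whp.assign(n, 0); bhp = 0;
  }
};

// Forward + BPTT on one sequence; adds scaled gradients into g and returns
// the summed (unscaled) loss over the T-1 scored steps. `scale` multiplies
// the per-term gradient (caller passes 1 / (minibatch * (T-1))).
double seq_loss_grad(const Par& p, const int* x, int T, double scale,
                     Grad& g) {
  const int N = p.N;
  // forward with full storage
  std::vector<double> H((size_t)T * N), R, Z, C, A;
  if (p.gated) {
    R.resize((size_t)T * N); Z.resize((size_t)T * N);
    C.resize((size_t)T * N); A.resize((size_t)T * N);
  }
  std::vector<double> h0(N, 0.0), dummy(N);
  std::vector<double> ps(T);
  for (int t = 0; t < T; ++t) {
    const double* hp = (t == 0) ? h0.data() : &H[(size_t)(t - 1) * N];
    double* hn = &H[(size_t)t * N];
    if (p.gated)
      step(p, hp, (double)x[t], hn, &R[(size_t)t * N], &Z[(size_t)t * N],
           &C[(size_t)t * N], &A[(size_t)t * N]);
    else
      step(p, hp, (double)x[t], hn, nullptr, nullptr, nullptr, nullptr);
    ps[t] = output(p, hn);
  }
  double loss = 0.0;
  for (int t = 0; t + 1 < T; ++t) {
    double lik = (x[t + 1] == 1) ? ps[t] : 1.0 - ps[t];
    loss += -std::log(lik);
  }
  // backward
  std::vector<double> dh(N, 0.0), dh_prev(N), buf(N);
  std::vector<double> dpr(N), dpz(N), dpc(N), da(N);
  for (int t = T - 2; t >= 0; --t) {
    const double* h = &H[(size_t)t * N];
    const double* hprev = (t == 0) ? h0.data() : &H[(size_t)(t - 1) * N];
    const double xt = (double)x[t];
    // output-layer contribution of step t
    double du = (ps[t] - (double)x[t + 1]) * scale;
    g.bhp += du;
    for (int i = 0; i < N; ++i) {
      g.whp[i] += du * h[i];
      dh[i] += du * p.whp[i];
    }
    if (p.gated) {
      const double* r = &R[(size_t)t * N];
      const double* z = &Z[(size_t)t * N];
      const double* c = &C[(size_t)t * N];
      const double* a = &A[(size_t)t * N];
      for (int i = 0; i < N; ++i) {
        double dz = dh[i] * (hprev[i] - c[i]);
        dpz[i] = dz * z[i] * (1.0 - z[i]);
        double dc = dh[i] * (1.0 - z[i]);
        dpc[i] = dc * (1.0 - c[i] * c[i]);
        double dr = dpc[i] * a[i];
        dpr[i] = dr * r[i] * (1.0 - r[i]);
        da[i] = dpc[i] * r[i];
      }
      for (int i = 0; i < N; ++i) {
        g.Wxh[i] += dpc[i] * xt; g.bxh[i] += dpc[i]; g.bhh[i] += dpc[i];
        g.Wxr[i] += dpr[i] * xt; g.bxr[i] += dpr[i]; g.bhr[i] += dpr[i];
        g.Wxz[i] += dpz[i] * xt; g.bxz[i] += dpz[i]; g.bhz[i] += dpz[i];
      }
      for (int j = 0; j < N; ++j) {
        const double hj = hprev[j];
        double* colh = &g.Whh[(size_t)j * N];
        double* colr = &g.Whr[(size_t)j * N];
        double* colz = &g.Whz[(size_t)j * N];
        for (int i = 0; i < N; ++i) {
          colh[i] += da[i] * hj;
          colr[i] += dpr[i] * hj;
          colz[i] += dpz[i] * hj;
        }
      }
      matvec_t(p.Whh, da.data(), N, dh_prev.data());
      matvec_t(p.Whr, dpr.data(), N, buf.data());
      for (int i = 0; i < N; ++i) dh_prev[i] += buf[i];
      matvec_t(p.Whz, dpz.data(), N, buf.data());
      for (int i = 0; i < N; ++i)
        dh_prev[i] += buf[i] + dh[i] * z[i];
    } else {
      for (int i = 0; i < N; ++i) dpc[i] = dh[i] * (1.0 - h[i] * h[i]);
      for (int i = 0; i < N; ++i) {
        g.Wxh[i] += dpc[i] * xt; g.bxh[i] += dpc[i]; g.bhh[i] += dpc[i];
      }
      for (int j = 0; j < N; ++j) {
        const double hj = hprev[j];
        double* colh = &g.Whh[(size_t)j * N];
        for (int i = 0; i < N; ++i) colh[i] += dpc[i] * hj;
      }
      matvec_t(p.Whh, dpc.data(), N, dh_prev.data());
    }
    std::swap(dh, dh_prev);
  }
  return loss;
}

void grad_to_list(const Grad& g, const Par& p, List& out) {
  if (p.gated) {
    out["Wxr"] = NumericVector(g.Wxr.begin(), g.Wxr.end());
    out["bxr"] = NumericVector(g.bxr.begin(), g.bxr.end());
    out["Whr"] = NumericMatrix(p.N, p.N, g.Whr.begin());
    out["bhr"] = NumericVector(g.bhr.begin(), g.bhr.end());
    out["Wxz"] = NumericVector(g.Wxz.begin(), g.Wxz.end());
    out["bxz"] = NumericVector(g.bxz.begin(), g.bxz.end());
    out["Whz"] = NumericMatrix(p.N, p.N, g.Whz.begin());
    out["bhz"] = NumericVector(g.bhz.begin(), g.bhz.end());
  }
  out["Wxh"] = NumericVector(g.Wxh.begin(), g.Wxh.end());
  out["bxh"] = NumericVector(g.bxh.begin(), g.bxh.end());
  out["Whh"] = NumericMatrix(p.N, p.N, g.Whh.begin());
  out["bhh"] = NumericVector(g.bhh.begin(), g.bhh.end());
  out["whp"] = NumericVector(g.whp.begin(), g.whp.end());
  out["bhp"] = g.bhp;
}

struct Adam {
  std::vector<double> m, v;
  double b1, b2, eps, lr;
  long t;
  Adam(size_t n, double lr_, double b1_, double b2_, double eps_)
      : m(n, 0.0), v(n, 0.0), b1(b1_), b2(b2_), eps(eps_), lr(lr_), t(0) {}
  void update(double* theta, const double* grad, size_t n) {
    double c1 = 1.0 - std::pow(b1, (double)t);
    double c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t i = 0; i < n; ++i) {
      m[i] = b1 * m[i] + (1.0 - b1) * grad[i];
      v[i] = b2 * v[i] + (1.0 - b2) * grad[i] * grad[i];
      theta[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_forward(List params, IntegerVector x) {
  Par p = unpack(params);
  const int T = x.size(), N = p.N;
  NumericMatrix H(T, N);
  NumericVector preds(T + 1);
  std::vector<double> h(N, 0.0), hn(N), r(N), z(N), c(N), a(N);
  preds[0] = output(p, h.data());
  for (int t = 0; t < T; ++t) {
    step(p, h.data(), (double)x[t], hn.data(),
         p.gated ? r.data() : nullptr, p.gated ? z.data() : nullptr,
         p.gated ? c.data() : nullptr, p.gated ? a.data() : nullptr);
    h = hn;
    for (int i = 0; i < N; ++i) H(t, i) = h[i];
    preds[t + 1] = output(p, h.data());
  }
  return List::create(_["predictions"] = preds, _["hidden"] = H);
}

// Mean loss (over sequences and their T-1 scored steps) and its gradient
// on a minibatch; X is n_seq x T, one sequence per row.
// [[Rcpp::export]]
List cpp_loss_grad(List params, IntegerMatrix X) {
  Par p = unpack(params);
  const int M = X.nrow(), T = X.ncol();
  Grad g;
  g.init(p.N, p.gated);
  double scale = 1.0 / ((double)M * (double)(T - 1));
  double loss = 0.0;
  std::vector<int> xrow(T);
  for (int s = 0; s < M; ++s) {
    for (int t = 0; t < T; ++t) xrow[t] = X(s, t);
    loss += seq_loss_grad(p, xrow.data(), T, scale, g);
  }
  List grads;
  grad_to_list(g, p, grads);
  return List::create(_["loss"] = loss * scale, _["gradients"] = grads);
}

// Single-pass minibatch training with Adam. X holds the training sequences
// in the (already shuffled) order they will be consumed. Parameter masking:
// train_recurrent = false updates only the output weights and bias;
// lateral = false zeroes off-diagonal recurrent-weight gradients so those
// entries stay at their (zero) initial values.
// [[Rcpp::export]]
List cpp_train(List params, IntegerMatrix X, int minibatch, double eta0,
               double beta1, double beta2, double eps,
               bool train_recurrent, bool lateral) {
  Par p = unpack(params);
  const int n_seq = X.nrow(), T = X.ncol(), N = p.N;
  const int n_batches = n_seq / minibatch;
  if (n_batches < 1) stop("dataset smaller than one minibatch");
  NumericVector losses(n_batches);

  // flatten trainable parameters into one vector for Adam
  std::vector<double*> blocks;
  std::vector<std::vector<double> Grad::*> gmembers;
  std::vector<std::vector<double> Par::*> pmembers;
  std::vector<size_t> sizes;
  size_t nn = (size_t)N * N;
  auto add = [&](std::vector<double> Par::*pm, std::vector<double> Grad::*gm,
                 size_t sz) {
    pmembers.push_back(pm); gmembers.push_back(gm); sizes.push_back(sz);
  };
  if (train_recurrent) {
    if (p.gated) {
      add(&Par::Wxr, &Grad::Wxr, N); add(&Par::bxr, &Grad::bxr, N);
      add(&Par::Whr, &Grad::Whr, nn); add(&Par::bhr, &Grad::bhr, N);
      add(&Par::Wxz, &Grad::Wxz, N); add(&Par::bxz, &Grad::bxz, N);
      add(&Par::Whz, &Grad::Whz, nn); add(&Par::bhz, &Grad::bhz, N);
    }
    add(&Par::Wxh, &Grad::Wxh, N); add(&Par::bxh, &Grad::bxh, N);
    add(&Par::Whh, &Grad::Whh, nn); add(&Par::bhh, &Grad::bhh, N);
  }
  add(&Par::whp, &Grad::whp, N);
  size_t total = 1;  // + bhp
  for (size_t s : sizes) total += s;
  Adam adam(total, eta0, beta1, beta2, eps);

  std::vector<double> theta(total), gflat(total);
  std::vector<int> xrow(T);
  Grad g;
  for (int b = 0; b < n_batches; ++b) {
    g.init(N, p.gated);
    double scale = 1.0 / ((double)minibatch * (double)(T - 1));
    double loss = 0.0;
    for (int s = 0; s < minibatch; ++s) {
      int row = b * minibatch + s;
      for (int t = 0; t < T; ++t) xrow[t] = X(row, t);
      loss += seq_loss_grad(p, xrow.data(), T, scale, g);
    }
    losses[b] = loss * scale;
    if (!std::isfinite(losses[b]))
      stop("training failure: non-finite loss at minibatch %d", b + 1);
    if (!lateral && train_recurrent) {
      // keep recurrent weights diagonal
      auto zero_offdiag = [&](std::vector<double>& W) {
        for (int j = 0; j < N; ++j)
          for (int i = 0; i < N; ++i)
            if (i != j) W[(size_t)j * N + i] = 0.0;
      };
      if (p.gated) { zero_offdiag(g.Whr); zero_offdiag(g.Whz); }
      zero_offdiag(g.Whh);
    }
    // flatten, update, unflatten
    size_t off = 0;
    for (size_t k = 0; k < sizes.size(); ++k) {
      std::vector<double>& pv = p.*(pmembers[k]);
      std::vector<double>& gv = g.*(gmembers[k]);
      std::copy(pv.begin(), pv.end(), theta.begin() + off);
      std::copy(gv.begin(), gv.end(), gflat.begin() + off);
      off += sizes[k];
    }
    theta[off] = p.bhp;
    gflat[off] = g.bhp;
    adam.t += 1;
    adam.update(theta.data(), gflat.data(), total);
    off = 0;
    for (size_t k = 0; k < sizes.size(); ++k) {
      std::vector<double>& pv = p.*(pmembers[k]);
      std::copy(theta.begin() + off, theta.begin() + off + sizes[k],
                pv.begin());
      off += sizes[k];
    }
    p.bhp = theta[off];
    if (b % 16 == 0) Rcpp::checkUserInterrupt();
  }

  List out = clone(params);
  if (p.gated) {
    out["Wxr"] = NumericVector(p.Wxr.begin(), p.Wxr.end());
    out["bxr"] = NumericVector(p.bxr.begin(), p.bxr.end());
    out["Whr"] = NumericMatrix(N, N, p.Whr.begin());
    out["bhr"] = NumericVector(p.bhr.begin(), p.bhr.end());
    out["Wxz"] = NumericVector(p.Wxz.begin(), p.Wxz.end());
    out["bxz"] = NumericVector(p.bxz.begin(), p.bxz.end());
    out["Whz"] = NumericMatrix(N, N, p.Whz.begin());
    out["bhz"] = NumericVector(p.bhz.begin(), p.bhz.end());
  }
  out["Wxh"] = NumericVector(p.Wxh.begin(), p.Wxh.end());
  out["bxh"] = NumericVector(p.bxh.begin(), p.bxh.end());
  out["Whh"] = NumericMatrix(N, N, p.Whh.begin());
  out["bhh"] = NumericVector(p.bhh.begin(), p.bhh.end());
  out["whp"] = NumericVector(p.whp.begin(), p.whp.end());
  out["bhp"] = p.bhp;
  return List::create(_["params"] = out, _["loss"] = losses);
}

// Streak-probe runner: for each prefix sequence, run the network through
// the prefix then a query observation (recording the output, p_before),
// then continue with repeated streak observations; after m of them
// (for every m in `ms`, increasing) feed the query from a copy of the
// state and record p_after.
// [[Rcpp::export]]
List cpp_streak_probe(List params, IntegerMatrix prefixes, int query_value,
                      int streak_value, IntegerVector ms) {
  Par p = unpack(params);
  const int n = prefixes.nrow(), L = prefixes.ncol(), N = p.N;
  const int nm = ms.size();
  NumericVector p_before(n);
  NumericMatrix p_after(n, nm);
  std::vector<double> h(N), hn(N), hq(N), r(N), z(N), c(N), a(N);
  double* rp = p.gated ? r.data() : nullptr;
  double* zp = p.gated ? z.data() : nullptr;
  double* cp = p.gated ? c.data() : nullptr;
  double* ap = p.gated ? a.data() : nullptr;
  int max_m = 0;
  for (int k = 0; k < nm; ++k) if (ms[k] > max_m) max_m = ms[k];
  for (int s = 0; s < n; ++s) {
    std::fill(h.begin(), h.end(), 0.0);
    for (int t = 0; t < L; ++t) {
      step(p, h.data(), (double)prefixes(s, t), hn.data(), rp, zp, cp, ap);
      h = hn;
    }
    step(p, h.data(), (double)query_value, hn.data(), rp, zp, cp, ap);
    h = hn;
    p_before[s] = output(p, h.data());
    int next_k = 0;
    for (int m = 1; m <= max_m && next_k < nm; ++m) {
      step(p, h.data(), (double)streak_value, hn.data(), rp, zp, cp, ap);
      h = hn;
      while (next_k < nm && ms[next_k] == m) {
        step(p, h.data(), (double)query_value, hq.data(), rp, zp, cp, ap);
        p_after(s, next_k) = output(p, hq.data());
        ++next_k;
      }
    }
  }
  return List::create(_["p_before"] = p_before, _["p_after"] = p_after);
}
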