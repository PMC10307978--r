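// Compiled hot paths: batched forward dynamics, the training loop
// (forward + analytic gradients + Adam), and noise-augmented response
// generation for decoding. Mirrors the reference R implementation in
// R/objective.R; the test suite checks the two agree.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

static const double SIG_EPS = 2.220446049250313e-16;

static inline mat sigmoid(const mat& x) {
  mat out = 1.0 / (1.0 + arma::exp(-x));
  out.clamp(SIG_EPS, 1.0 - SIG_EPS);
  return out;
}

struct Net {
  std::vector<mat> W_bu, W_rec, W_td;
  mat W_gen;
  std::vector<vec> b;
  vec b_gen;
  int H;

  static Net from_list(List W_bu_, List W_rec_, List W_td_,
                       const mat& W_gen_, List b_, const vec& b_gen_) {
    Net n;
    n.H = W_bu_.size();
    for (int h = 0; h < n.H; ++h) {
      n.W_bu.push_back(as<mat>(W_bu_[h]));
      n.W_rec.push_back(as<mat>(W_rec_[h]));
      n.b.push_back(as<vec>(b_[h]));
    }
    for (int h = 0; h + 1 < n.H; ++h) n.W_td.push_back(as<mat>(W_td_[h]));
    n.W_gen = W_gen_;
    n.b_gen = b_gen_;
    return n;
  }
};

// One synchronous update from the previous state (input x0_prev, hidden
// prev); writes the new hidden states and the generated input.
static void step(const Net& net, const mat& x0_prev,
                 const std::vector<mat>& prev, std::vector<mat>& next,
                 mat& gen, bool want_gen = true) {
  for (int h = 0; h < net.H; ++h) {
    const mat& below = (h == 0) ? x0_prev : prev[h - 1];
    mat a = below * net.W_bu[h] + prev[h] * net.W_rec[h];
    if (h + 1 < net.H) a += prev[h + 1] * net.W_td[h];
    a.each_row() += net.b[h].t();
    next[h] = sigmoid(a);
  }
  if (want_gen) {
    mat ag = prev[0] * net.W_gen;
    ag.each_row() += net.b_gen.t();
    gen = sigmoid(ag);
  }
}

// [[Rcpp::export]]
List cpp_forward_batch(List W_bu, List W_rec, List W_td, NumericMatrix W_gen,
                       List b, NumericVector b_gen, List frames) {
  Net net = Net::from_list(W_bu, W_rec, W_td, as<mat>(W_gen), b,
                           as<vec>(b_gen));
  int T = frames.size();
  std::vector<mat> fr(T);
  for (int t = 0; t < T; ++t) fr[t] = as<mat>(frames[t]);
  int B = fr[0].n_rows;
  std::vector<std::vector<mat>> hid(net.H,
                                    std::vector<mat>(T));
  std::vector<mat> gen(T);
  std::vector<mat> state(net.H);
  for (int h = 0; h < net.H; ++h)
    state[h] = mat(B, net.b[h].n_elem, arma::fill::value(0.5));
  gen[0] = mat(B, net.W_gen.n_cols, arma::fill::value(0.5));
  for (int h = 0; h < net.H; ++h) hid[h][0] = state[h];
  std::vector<mat> next(net.H);
  for (int t = 1; t < T; ++t) {
    step(net, fr[t - 1], state, next, gen[t]);
    state = next;
    for (int h = 0; h < net.H; ++h) hid[h][t] = state[h];
  }
  List hidden(net.H);
  for (int h = 0; h < net.H; ++h) {
    List per_t(T);
    for (int t = 0; t < T; ++t) per_t[t] = wrap(hid[h][t]);
    hidden[h] = per_t;
  }
  List gen_l(T);
  for (int t = 0; t < T; ++t) gen_l[t] = wrap(gen[t]);
  return List::create(_["hidden"] = hidden, _["gen"] = gen_l);
}

// Soft-histogram KL objective: value (sum over units) and gradient per
// response element. Mirrors spatial_loss / spatial_loss_grad with the
// unit-count aggregate folded in.
struct SpatialOut { double value; mat grad; };

static SpatialOut spatial_term(const mat& R, const vec& q, int K,
                               double bw, bool want_grad) {
  int N = R.n_rows, J = R.n_cols;
  vec centers(K);
  for (int k = 0; k < K; ++k) centers[k] = (k + 0.5) / K;
  SpatialOut out;
  out.value = 0.0;
  if (want_grad) out.grad.zeros(N, J);
  mat logpq(K, J);
  // per unit: soft assignment, histogram, KL
  std::vector<mat> phi_store;
  if (want_grad) phi_store.resize(J);
  for (int j = 0; j < J; ++j) {
    mat phi(N, K);
    for (int i = 0; i < N; ++i) {
      double r = R(i, j), s = 0.0;
      for (int k = 0; k < K; ++k) {
        double d = r - centers[k];
        double w = std::exp(-d * d / (2.0 * bw * bw));
        phi(i, k) = w;
        s += w;
      }
      for (int k = 0; k < K; ++k) phi(i, k) /= s;
    }
    rowvec p = arma::mean(phi, 0);
    double kl = 0.0;
    for (int k = 0; k < K; ++k) {
      if (p[k] > 0) kl += p[k] * std::log(p[k] / q[k]);
      logpq(k, j) = std::log(p[k] / q[k]) + 1.0;
    }
    out.value += kl;
    if (want_grad) phi_store[j] = phi;
  }
  if (want_grad) {
    for (int j = 0; j < J; ++j) {
      const mat& phi = phi_store[j];
      for (int i = 0; i < N; ++i) {
        double r = R(i, j), ubar = 0.0;
        for (int k = 0; k < K; ++k)
          ubar += phi(i, k) * (-(r - centers[k]) / (bw * bw));
        double g = 0.0;
        for (int k = 0; k < K; ++k) {
          double u = -(r - centers[k]) / (bw * bw);
          g += logpq(k, j) * phi(i, k) * (u - ubar);
        }
        out.grad(i, j) = g / N;   // aggregate: J * (mean over units) folds out
      }
    }
  }
  return out;
}

struct Grads {
  std::vector<mat> W_bu, W_rec, W_td;
  mat W_gen;
  std::vector<vec> b;
  vec b_gen;
  void zero_like(const Net& net) {
    W_bu.clear(); W_rec.clear(); W_td.clear(); b.clear();
    for (int h = 0; h < net.H; ++h) {
      W_bu.push_back(mat(arma::size(net.W_bu[h]), arma::fill::zeros));
      W_rec.push_back(mat(arma::size(net.W_rec[h]), arma::fill::zeros));
      b.push_back(vec(arma::size(net.b[h]), arma::fill::zeros));
    }
    for (int h = 0; h + 1 < net.H; ++h)
      W_td.push_back(mat(arma::size(net.W_td[h]), arma::fill::zeros));
    W_gen = mat(arma::size(net.W_gen), arma::fill::zeros);
    b_gen = vec(arma::size(net.b_gen), arma::fill::zeros);
  }
};

// Forward + loss + gradients on one minibatch; mirrors
// minibatch_loss_grads() in R.
static void loss_grads(const Net& net, const std::vector<mat>& fr,
                       double lambda, const std::vector<vec>& comp,
                       int n_bins, double bw, bool bptt,
                       double& total, double& temporal, vec& spatial,
                       Grads& g) {
  int T = fr.size(), B = fr[0].n_rows;
  int H = net.H;
  std::vector<std::vector<mat>> X(H, std::vector<mat>(T));
  std::vector<mat> gen(T);
  {
    std::vector<mat> state(H), next(H);
    for (int h = 0; h < H; ++h)
      state[h] = mat(B, net.b[h].n_elem, arma::fill::value(0.5));
    for (int h = 0; h < H; ++h) X[h][0] = state[h];
    for (int t = 1; t < T; ++t) {
      step(net, fr[t - 1], state, next, gen[t]);
      state = next;
      for (int h = 0; h < H; ++h) X[h][t] = state[h];
    }
  }
  // loss values
  temporal = 0.0;
  for (int t = 1; t < T; ++t) {
    temporal += arma::accu(arma::square(gen[t] - fr[t]));
    for (int h = 0; h < H; ++h)
      temporal += arma::accu(arma::square(X[h][t] - X[h][t - 1]));
  }
  int denomT = T - 1;
  temporal /= (double)(B * denomT);
  spatial.set_size(H);
  std::vector<mat> sgrad(H);
  bool want_sg = lambda > 0 && bw > 0;
  for (int h = 0; h < H; ++h) {
    int n_h = net.b[h].n_elem;
    mat pooled(B * denomT, n_h);
    for (int t = 1; t < T; ++t)
      pooled.rows((t - 1) * B, t * B - 1) = X[h][t];
    SpatialOut so = spatial_term(pooled, comp[h], n_bins, bw, want_sg);
    spatial[h] = so.value;
    if (want_sg) sgrad[h] = so.grad;
  }
  total = temporal + lambda * arma::accu(spatial);
  if (!std::isfinite(total)) return;

  // direct dL/dX and dL/dgen
  double scale = 2.0 / (denomT * (double)B);
  std::vector<std::vector<mat>> dX(H, std::vector<mat>(T));
  for (int h = 0; h < H; ++h) {
    for (int t = 1; t < T; ++t) {
      mat d = scale * (X[h][t] - X[h][t - 1]);
      if (t + 1 < T) d -= scale * (X[h][t + 1] - X[h][t]);
      if (want_sg)
        d += lambda * sgrad[h].rows((t - 1) * B, t * B - 1);
      dX[h][t] = d;
    }
  }
  std::vector<mat> dAg(T);
  for (int t = 1; t < T; ++t) {
    mat dG = scale * (gen[t] - fr[t]);
    dAg[t] = dG % gen[t] % (1.0 - gen[t]);
  }
  // backward through the sigmoids (and through time if bptt)
  std::vector<std::vector<mat>> dA(H, std::vector<mat>(T));
  for (int t = T - 1; t >= 1; --t) {
    for (int h = 0; h < H; ++h) {
      mat D = dX[h][t];
      if (bptt && t + 1 < T) {
        D += dA[h][t + 1] * net.W_rec[h].t();
        if (h + 1 < H) D += dA[h + 1][t + 1] * net.W_bu[h + 1].t();
        if (h > 0) D += dA[h - 1][t + 1] * net.W_td[h - 1].t();
        if (h == 0) D += dAg[t + 1] * net.W_gen.t();
      }
      dA[h][t] = D % X[h][t] % (1.0 - X[h][t]);
    }
  }
  g.zero_like(net);
  for (int t = 1; t < T; ++t) {
    for (int h = 0; h < H; ++h) {
      const mat& below_prev = (h == 0) ? fr[t - 1] : X[h - 1][t - 1];
      g.W_bu[h] += below_prev.t() * dA[h][t];
      g.W_rec[h] += X[h][t - 1].t() * dA[h][t];
      if (h + 1 < H) g.W_td[h] += X[h + 1][t - 1].t() * dA[h][t];
      g.b[h] += arma::sum(dA[h][t], 0).t();
    }
    g.W_gen += X[0][t - 1].t() * dAg[t];
    g.b_gen += arma::sum(dAg[t], 0).t();
  }
}

struct AdamState {
  Grads m, v;
  long t = 0;
  void reset(const Net& net) { m.zero_like(net); v.zero_like(net); t = 0; }
};

static void adam_leaf(mat& p, const mat& g, mat& m, mat& v,
                      double a, double b1, double b2, double eps,
                      double bc1, double bc2) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * arma::square(g);
  p -= a * (m / bc1) / (arma::sqrt(v / bc2) + eps);
}

static void adam_leaf_v(vec& p, const vec& g, vec& m, vec& v,
                        double a, double b1, double b2, double eps,
                        double bc1, double bc2) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * arma::square(g);
  p -= a * (m / bc1) / (arma::sqrt(v / bc2) + eps);
}

// [[Rcpp::export]]
List cpp_train_loop(List W_bu, List W_rec, List W_td, NumericMatrix W_gen,
                    List b, NumericVector b_gen,
                    List scenes, IntegerMatrix draws,
                    int iterations, int repetitions, int minibatch, int steps,
                    double lambda, List compensation, int n_bins,
                    double bandwidth, double alpha, double beta1,
                    double beta2, double eps, bool bptt, int trace_every,
                    int patch) {
  Net net = Net::from_list(W_bu, W_rec, W_td, as<mat>(W_gen), b,
                           as<vec>(b_gen));
  std::vector<mat> sc;
  for (int s = 0; s < scenes.size(); ++s) sc.push_back(as<mat>(scenes[s]));
  std::vector<vec> comp;
  for (int h = 0; h < net.H; ++h) comp.push_back(as<vec>(compensation[h]));
  int n_in = patch * patch;
  std::vector<mat> fr(steps, mat(minibatch, n_in));
  AdamState adam;
  Grads g;
  std::vector<double> trace_it, trace_tmp, trace_tot;
  std::vector<vec> trace_sp;
  long total_iter = 0;
  bool diverged = false;
  for (int rep = 0; rep < repetitions && !diverged; ++rep) {
    adam.reset(net);
    for (int it = 0; it < iterations; ++it) {
      // assemble the minibatch frames from the drawn gaze trajectories
      for (int bi = 0; bi < minibatch; ++bi) {
        int row = total_iter * minibatch + bi;
        const mat& scene = sc[draws(row, 0) - 1];
        int r0 = draws(row, 1), c0 = draws(row, 2);
        int vr = draws(row, 3), vc = draws(row, 4);
        for (int t = 0; t < steps; ++t) {
          int rr = r0 + t * vr, cc = c0 + t * vc;
          for (int j = 0; j < patch; ++j)
            for (int i = 0; i < patch; ++i)
              fr[t](bi, j * patch + i) = scene(rr + i, cc + j);
        }
      }
      double total, temporal;
      vec spatial;
      loss_grads(net, fr, lambda, comp, n_bins, bandwidth, bptt,
                 total, temporal, spatial, g);
      ++total_iter;
      if (!std::isfinite(total)) { diverged = true; break; }
      adam.t += 1;
      double bc1 = 1.0 - std::pow(beta1, (double)adam.t);
      double bc2 = 1.0 - std::pow(beta2, (double)adam.t);
      for (int h = 0; h < net.H; ++h) {
        adam_leaf(net.W_bu[h], g.W_bu[h], adam.m.W_bu[h], adam.v.W_bu[h],
                  alpha, beta1, beta2, eps, bc1, bc2);
        adam_leaf(net.W_rec[h], g.W_rec[h], adam.m.W_rec[h], adam.v.W_rec[h],
                  alpha, beta1, beta2, eps, bc1, bc2);
        adam_leaf_v(net.b[h], g.b[h], adam.m.b[h], adam.v.b[h],
                    alpha, beta1, beta2, eps, bc1, bc2);
      }
      for (int h = 0; h + 1 < net.H; ++h)
        adam_leaf(net.W_td[h], g.W_td[h], adam.m.W_td[h], adam.v.W_td[h],
                  alpha, beta1, beta2, eps, bc1, bc2);
      adam_leaf(net.W_gen, g.W_gen, adam.m.W_gen, adam.v.W_gen,
                alpha, beta1, beta2, eps, bc1, bc2);
      adam_leaf_v(net.b_gen, g.b_gen, adam.m.b_gen, adam.v.b_gen,
                  alpha, beta1, beta2, eps, bc1, bc2);
      if (total_iter % trace_every == 0 || total_iter == 1) {
        trace_it.push_back((double)total_iter);
        trace_tmp.push_back(temporal);
        trace_sp.push_back(spatial);
        trace_tot.push_back(total);
      }
      if (total_iter % 200 == 0) Rcpp::checkUserInterrupt();
    }
  }
  List W_bu_o(net.H), W_rec_o(net.H), W_td_o(std::max(net.H - 1, 0)),
      b_o(net.H);
  for (int h = 0; h < net.H; ++h) {
    W_bu_o[h] = wrap(net.W_bu[h]);
    W_rec_o[h] = wrap(net.W_rec[h]);
    b_o[h] = wrap(vec(net.b[h]));
  }
  for (int h = 0; h + 1 < net.H; ++h) W_td_o[h] = wrap(net.W_td[h]);
  int n_tr = trace_it.size();
  mat sp_tr(n_tr, net.H);
  for (int i = 0; i < n_tr; ++i) sp_tr.row(i) = trace_sp[i].t();
  return List::create(
      _["W_bu"] = W_bu_o, _["W_rec"] = W_rec_o, _["W_td"] = W_td_o,
      _["W_gen"] = wrap(net.W_gen), _["b"] = b_o,
      _["b_gen"] = wrap(vec(net.b_gen)),
      _["trace_iteration"] = wrap(trace_it),
      _["trace_temporal"] = wrap(trace_tmp),
      _["trace_spatial"] = wrap(sp_tr),
      _["trace_total"] = wrap(trace_tot),
      _["diverged"] = diverged,
      _["iterations_run"] = (double)total_iter);
}

// Gaussian pixel noise from a dedicated counter-based stream; one
// mt19937_64 per call, seeded from R.
static void add_noise_inplace(mat& frame, double sigma,
                              std::mt19937_64& rng) {
  if (sigma <= 0) return;
  std::normal_distribution<double> gauss(0.0, sigma);
  for (arma::uword j = 0; j < frame.n_cols; ++j)
    for (arma::uword i = 0; i < frame.n_rows; ++i)
      frame(i, j) += gauss(rng);
}

// [[Rcpp::export]]
List cpp_static_responses(List W_bu, List W_rec, List W_td,
                          NumericMatrix W_gen, List b, NumericVector b_gen,
                          NumericMatrix frame_rows, int n_samples,
                          int steps, double sigma, double seed) {
  Net net = Net::from_list(W_bu, W_rec, W_td, as<mat>(W_gen), b,
                           as<vec>(b_gen));
  mat stimuli = as<mat>(frame_rows);       // n_stim x n_in
  int n_stim = stimuli.n_rows, n_in = stimuli.n_cols;
  std::mt19937_64 rng((uint64_t)seed);
  List out(net.H);
  std::vector<mat> acc(net.H);
  for (int h = 0; h < net.H; ++h)
    acc[h] = mat(n_stim * n_samples, net.b[h].n_elem);
  mat gen;   // unused sink
  for (int s = 0; s < n_stim; ++s) {
    mat base = arma::repmat(stimuli.row(s), n_samples, 1);
    mat x0 = base;
    add_noise_inplace(x0, sigma, rng);
    std::vector<mat> state(net.H), next(net.H);
    for (int h = 0; h < net.H; ++h)
      state[h] = mat(n_samples, net.b[h].n_elem, arma::fill::value(0.5));
    for (int t = 1; t < steps; ++t) {
      step(net, x0, state, next, gen, false);
      state = next;
      x0 = base;
      add_noise_inplace(x0, sigma, rng);
    }
    for (int h = 0; h < net.H; ++h)
      acc[h].rows(s * n_samples, (s + 1) * n_samples - 1) = state[h];
  }
  for (int h = 0; h < net.H; ++h) out[h] = wrap(acc[h]);
  return out;
}

// [[Rcpp::export]]
List cpp_moving_responses(List W_bu, List W_rec, List W_td,
                          NumericMatrix W_gen, List b, NumericVector b_gen,
                          NumericMatrix bar_rows, LogicalVector forward,
                          double sigma, double seed) {
  Net net = Net::from_list(W_bu, W_rec, W_td, as<mat>(W_gen), b,
                           as<vec>(b_gen));
  mat bars = as<mat>(bar_rows);            // n_pos x n_in
  int n_pos = bars.n_rows;
  int B = forward.size();
  std::mt19937_64 rng((uint64_t)seed);
  mat gen;
  auto frame_at = [&](int t) {             // t is 0-based step index
    mat f(B, bars.n_cols);
    for (int r = 0; r < B; ++r) {
      int p = forward[r] ? t : (n_pos - 1 - t);
      f.row(r) = bars.row(p);
    }
    add_noise_inplace(f, sigma, rng);
    return f;
  };
  std::vector<mat> state(net.H), next(net.H);
  for (int h = 0; h < net.H; ++h)
    state[h] = mat(B, net.b[h].n_elem, arma::fill::value(0.5));
  mat x0 = frame_at(0);
  List out(net.H);
  // n_pos + 1 recorded states: the last frame gets its own encoding step
  // (the state at index t+1 is the first one driven by frame t)
  std::vector<std::vector<mat>> keep(net.H, std::vector<mat>(n_pos + 1));
  for (int h = 0; h < net.H; ++h) keep[h][0] = state[h];
  for (int t = 1; t <= n_pos; ++t) {
    step(net, x0, state, next, gen, false);
    state = next;
    for (int h = 0; h < net.H; ++h) keep[h][t] = state[h];
    if (t < n_pos) x0 = frame_at(t);
  }
  for (int h = 0; h < net.H; ++h) {
    List per_t(n_pos + 1);
    for (int t = 0; t <= n_pos; ++t) per_t[t] = wrap(keep[h][t]);
    out[h] = per_t;
  }
  return out;
}
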