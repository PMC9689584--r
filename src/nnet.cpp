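// Training loop for the normalized neural dwell-density estimator.
//
// The network maps a standardized log dwell time z to a nonnegative raw
// output: tanh hidden layers, a ReLU penultimate layer, and an output
// layer whose weights are squared parameters (u^2, c^2) so the raw output
// is nonnegative by construction.  The density is raw(z(t)) divided by a
// trapezoidal integral of raw over the sample range, and the training
// criterion is the negative log-likelihood of the samples under that
// normalized density:
//   L = -sum_j log raw(z_j) + n_samp * log sum_i tw_i raw(g_i).
// Full-batch Adam.  Initial parameters come from R so all randomness is
// controlled by R's RNG.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Net {
  int nh, w;
  // W[0]: w x 1, W[l]: w x w (l>=1), row-major [out][in]; b[l]: w
  std::vector<std::vector<double> > W, b;
  std::vector<double> u, c; // output weights (squared on use), c length 1
};

static Net unpack(const List& params) {
  Net net;
  List Ws = params["W"], bs = params["b"];
  net.nh = Ws.size();
  net.u = as<std::vector<double> >(params["u"]);
  net.c = as<std::vector<double> >(params["c"]);
  net.w = net.u.size();
  for (int l = 0; l < net.nh; ++l) {
    net.W.push_back(as<std::vector<double> >(Ws[l]));
    net.b.push_back(as<std::vector<double> >(bs[l]));
  }
  return net;
}

static List pack(const Net& net) {
  List Ws(net.nh), bs(net.nh);
  for (int l = 0; l < net.nh; ++l) {
    Ws[l] = wrap(net.W[l]);
    bs[l] = wrap(net.b[l]);
  }
  return List::create(_["W"] = Ws, _["b"] = bs, _["u"] = wrap(net.u),
                      _["c"] = wrap(net.c));
}

// forward pass; acts[l] holds post-activation values (N x w, row-major)
static void forward(const Net& net, const std::vector<double>& z,
                    std::vector<std::vector<double> >& acts,
                    std::vector<double>& raw) {
  int N = z.size(), w = net.w, nh = net.nh;
  acts.assign(nh, std::vector<double>(N * w));
  raw.assign(N, 0.0);
  for (int i = 0; i < N; ++i) {
    for (int l = 0; l < nh; ++l) {
      for (int o = 0; o < w; ++o) {
        double a = net.b[l][o];
        if (l == 0) {
          a += net.W[0][o] * z[i];
        } else {
          const std::vector<double>& prev = acts[l - 1];
          const double* Wrow = &net.W[l][o * w];
          for (int in = 0; in < w; ++in) a += Wrow[in] * prev[i * w + in];
        }
        acts[l][i * w + o] = (l == nh - 1) ? (a > 0 ? a : 0.0) : std::tanh(a);
      }
    }
    double r = net.c[0] * net.c[0];
    for (int o = 0; o < w; ++o)
      r += acts[nh - 1][i * w + o] * net.u[o] * net.u[o];
    raw[i] = r;
  }
}

// [[Rcpp::export]]
NumericVector nnet_raw(List params, NumericVector z) {
  Net net = unpack(params);
  std::vector<double> zz = as<std::vector<double> >(z), raw;
  std::vector<std::vector<double> > acts;
  forward(net, zz, acts, raw);
  return wrap(raw);
}

// [[Rcpp::export]]
List nnet_train(List params, NumericVector z, int nsamp, NumericVector tw,
                int epochs, double lr) {
  Net net = unpack(params);
  int N = z.size(), w = net.w, nh = net.nh;
  int ngrid = N - nsamp;
  if (tw.size() != ngrid) stop("trapezoid weights must match grid size");
  std::vector<double> zz = as<std::vector<double> >(z);
  const double eps = 1e-12, b1 = 0.9, b2 = 0.999, aeps = 1e-8;

  // Adam state mirrors parameter layout
  Net m = net, v = net;
  for (int l = 0; l < nh; ++l) {
    std::fill(m.W[l].begin(), m.W[l].end(), 0.0);
    std::fill(m.b[l].begin(), m.b[l].end(), 0.0);
    std::fill(v.W[l].begin(), v.W[l].end(), 0.0);
    std::fill(v.b[l].begin(), v.b[l].end(), 0.0);
  }
  std::fill(m.u.begin(), m.u.end(), 0.0);
  std::fill(v.u.begin(), v.u.end(), 0.0);
  m.c[0] = v.c[0] = 0.0;

  std::vector<std::vector<double> > acts;
  std::vector<double> raw;
  Net g = net; // gradient accumulator
  std::vector<double> delta(w), delta_prev(w);
  double loss = NA_REAL;
  bool ok = true;

  for (int ep = 1; ep <= epochs; ++ep) {
    forward(net, zz, acts, raw);
    double I = 0.0;
    for (int i = 0; i < ngrid; ++i) I += tw[i] * raw[nsamp + i];
    if (!(I > 0.0) || !std::isfinite(I)) { ok = false; break; }
    loss = nsamp * std::log(I);
    for (int j = 0; j < nsamp; ++j) loss -= std::log(raw[j] + eps);
    if (!std::isfinite(loss)) { ok = false; break; }

    // zero gradients
    for (int l = 0; l < nh; ++l) {
      std::fill(g.W[l].begin(), g.W[l].end(), 0.0);
      std::fill(g.b[l].begin(), g.b[l].end(), 0.0);
    }
    std::fill(g.u.begin(), g.u.end(), 0.0);
    g.c[0] = 0.0;

    for (int i = 0; i < N; ++i) {
      double dr = (i < nsamp) ? -1.0 / (raw[i] + eps)
                              : nsamp * tw[i - nsamp] / I;
      // output layer
      g.c[0] += dr * 2.0 * net.c[0];
      const double* hlast = &acts[nh - 1][i * w];
      for (int o = 0; o < w; ++o) {
        g.u[o] += dr * 2.0 * net.u[o] * hlast[o];
        // into penultimate ReLU layer
        delta[o] = (hlast[o] > 0.0) ? dr * net.u[o] * net.u[o] : 0.0;
      }
      for (int l = nh - 1; l >= 0; --l) {
        const double* hin = (l > 0) ? &acts[l - 1][i * w] : NULL;
        for (int o = 0; o < w; ++o) {
          double d = delta[o];
          if (d == 0.0) continue;
          g.b[l][o] += d;
          if (l == 0) {
            g.W[0][o] += d * zz[i];
          } else {
            double* grow = &g.W[l][o * w];
            for (int in = 0; in < w; ++in) grow[in] += d * hin[in];
          }
        }
        if (l > 0) {
          // propagate through tanh of layer l-1
          for (int in = 0; in < w; ++in) {
            double s = 0.0;
            for (int o = 0; o < w; ++o)
              s += delta[o] * net.W[l][o * w + in];
            double h = acts[l - 1][i * w + in];
            delta_prev[in] = s * (1.0 - h * h);
          }
          std::swap(delta, delta_prev);
        }
      }
    }

    // Adam update
    double c1 = 1.0 - std::pow(b1, ep), c2 = 1.0 - std::pow(b2, ep);
    #define ADAM(P, M, V, G) do {                                   \
      (M) = b1 * (M) + (1 - b1) * (G);                              \
      (V) = b2 * (V) + (1 - b2) * (G) * (G);                        \
      (P) -= lr * ((M) / c1) / (std::sqrt((V) / c2) + aeps);        \
    } while (0)
    for (int l = 0; l < nh; ++l) {
      for (size_t j = 0; j < net.W[l].size(); ++j)
        ADAM(net.W[l][j], m.W[l][j], v.W[l][j], g.W[l][j]);
      for (int j = 0; j < w; ++j)
        ADAM(net.b[l][j], m.b[l][j], v.b[l][j], g.b[l][j]);
    }
    for (int j = 0; j < w; ++j) ADAM(net.u[j], m.u[j], v.u[j], g.u[j]);
    ADAM(net.c[0], m.c[0], v.c[0], g.c[0]);
    #undef ADAM
  }

  return List::create(_["params"] = pack(net), _["loss"] = loss,
                      _["ok"] = ok);
}
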