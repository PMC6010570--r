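// Event-driven simulation kernel.
//
// The network advances purely on input events: no clock, no leak, no
// refractory period. Each neuron carries two accumulators — a learning
// accumulator that triggers STDP + WTA inhibition ("pseudo-spikes", never
// propagated) and an inference accumulator that triggers spike propagation.
// Time enters only through event ordering, so uniformly rescaling all input
// times leaves spike sequences and final weights bit-identical.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cstring>
#include <cmath>

using namespace Rcpp;

namespace {

// source layer: 0 = input pixels, i+1 = layers[i]
struct Ev {
  double t;
  int layer, map, row, col;
  long long seq;
};

// min-heap order: time, then (layer, map, row, col) ascending, then insertion
struct EvCmp {
  bool operator()(const Ev& a, const Ev& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.layer != b.layer) return a.layer > b.layer;
    if (a.map != b.map) return a.map > b.map;
    if (a.row != b.row) return a.row > b.row;
    if (a.col != b.col) return a.col > b.col;
    return a.seq > b.seq;
  }
};

enum { CONV = 0, POOL = 1, FC = 2 };

struct Layer {
  int kind;
  int in_side, in_maps, out_side, maps, ksize, stride, window;
  double t_learn, t_infer;
  int r_learn, r_infer;          // r_infer < 0 disables inference inhibition
  double ap, am, bp, bm;
  bool simple;                   // drop the exponential weight dependence
  bool plastic;
  std::vector<double> w;         // conv: dim (k, k, in_maps, maps); fc: (n_in, maps)
  std::vector<double> vl, vi;    // learning / inference accumulators
  std::vector<double> trl, tri;  // reference times of the last resets
  std::vector<uint8_t> act;      // per neuron: presynapses active since last learning reset
  int nk;                        // presynaptic slots per neuron
  int n_neurons;
  double n_integr = 0, n_pseudo = 0, n_prop = 0;
};

struct Rec {
  std::vector<double> t;
  std::vector<int> layer, map, row, col;
  void add(double tt, int l, int m, int r, int c) {
    t.push_back(tt); layer.push_back(l); map.push_back(m);
    row.push_back(r); col.push_back(c);
  }
};

inline double clip01(double x) { return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x); }

void reset_learning(Layer& L, size_t ni, double t) {
  L.vl[ni] = 0.0;
  L.trl[ni] = t;
  std::memset(&L.act[ni * (size_t)L.nk], 0, (size_t)L.nk);
}

void stdp_apply(Layer& L, size_t w_base, size_t a_base) {
  for (int j = 0; j < L.nk; ++j) {
    double& wv = L.w[w_base + j];
    if (L.act[a_base + j]) {
      wv += L.simple ? L.ap : L.ap * std::exp(-L.bp * wv);
    } else {
      wv += L.simple ? L.am : L.am * std::exp(-L.bm * (1.0 - wv));
    }
    wv = clip01(wv);
  }
}

// Resolve all threshold crossings in layer `li` at time t. Learning
// crossings are handled before inference crossings; within each kind,
// neurons are visited in (map, row, col) ascending order, re-scanning
// after every reset so that inhibited neurons never fire.
void resolve(std::vector<Layer>& layers, int li, double t,
             std::priority_queue<Ev, std::vector<Ev>, EvCmp>& pq,
             long long& seq, Rec& rec, int n_layers) {
  Layer& L = layers[li];
  const int S = L.out_side;

  for (;;) {  // learning / WTA side
    long long win = -1;
    for (int ni = 0; ni < L.n_neurons; ++ni)
      if (L.vl[ni] >= L.t_learn) { win = ni; break; }
    if (win < 0) break;
    L.n_pseudo += 1;

    if (L.kind == CONV) {
      int m = (int)(win / ((long long)S * S));
      int pos = (int)(win % ((long long)S * S));
      int r = pos / S, c = pos % S;
      if (L.plastic)
        stdp_apply(L, (size_t)L.nk * m, (size_t)L.nk * win);
      // intra-map: every position of the winning map (incl. the winner itself)
      for (int p = 0; p < S * S; ++p)
        reset_learning(L, (size_t)m * S * S + p, t);
      // inter-map: Chebyshev neighborhood of the winner in every other map
      int rlo = std::max(0, r - L.r_learn), rhi = std::min(S - 1, r + L.r_learn);
      int clo = std::max(0, c - L.r_learn), chi = std::min(S - 1, c + L.r_learn);
      for (int m2 = 0; m2 < L.maps; ++m2) {
        if (m2 == m) continue;
        for (int r2 = rlo; r2 <= rhi; ++r2)
          for (int c2 = clo; c2 <= chi; ++c2)
            reset_learning(L, ((size_t)m2 * S + r2) * S + c2, t);
      }
    } else {  // FC: all-to-all competition
      if (L.plastic)
        stdp_apply(L, (size_t)L.nk * win, (size_t)L.nk * win);
      for (int n = 0; n < L.n_neurons; ++n)
        reset_learning(L, n, t);
    }
  }

  for (;;) {  // inference / propagation side
    long long win = -1;
    for (int ni = 0; ni < L.n_neurons; ++ni)
      if (L.vi[ni] >= L.t_infer) { win = ni; break; }
    if (win < 0) break;
    L.n_prop += 1;

    int m, r = 0, c = 0;
    if (L.kind == CONV) {
      m = (int)(win / ((long long)S * S));
      int pos = (int)(win % ((long long)S * S));
      r = pos / S; c = pos % S;
    } else {
      m = (int)win;
    }
    rec.add(t, li + 1, m, r, c);
    if (li + 1 < n_layers)
      pq.push(Ev{t, li + 1, m, r, c, seq++});
    L.vi[win] = 0.0;
    L.tri[win] = t;

    if (L.kind == CONV && L.r_infer >= 0) {
      // inter-map only: inference accumulators at the winner's neighborhood
      // in all *other* maps (r = 0 means the same position only)
      int rlo = std::max(0, r - L.r_infer), rhi = std::min(S - 1, r + L.r_infer);
      int clo = std::max(0, c - L.r_infer), chi = std::min(S - 1, c + L.r_infer);
      for (int m2 = 0; m2 < L.maps; ++m2) {
        if (m2 == m) continue;
        for (int r2 = rlo; r2 <= rhi; ++r2)
          for (int c2 = clo; c2 <= chi; ++c2) {
            size_t ni2 = ((size_t)m2 * S + r2) * S + c2;
            L.vi[ni2] = 0.0;
            L.tri[ni2] = t;
          }
      }
    }
  }
}

void deliver(Layer& L, int im, int ix, int iy) {
  if (L.kind == CONV) {
    const int k = L.ksize, s = L.stride, S = L.out_side;
    int rlo = ix - k + 1; rlo = rlo > 0 ? (rlo + s - 1) / s : 0;
    int clo = iy - k + 1; clo = clo > 0 ? (clo + s - 1) / s : 0;
    int rhi = std::min(S - 1, ix / s), chi = std::min(S - 1, iy / s);
    for (int orow = rlo; orow <= rhi; ++orow) {
      int kx = ix - orow * s;
      for (int ocol = clo; ocol <= chi; ++ocol) {
        int ky = iy - ocol * s;
        int a = kx + k * (ky + k * im);  // kernel slot, aligned with weight layout
        for (int m = 0; m < L.maps; ++m) {
          size_t ni = ((size_t)m * S + orow) * S + ocol;
          double wv = L.w[a + (size_t)L.nk * m];
          L.vl[ni] += wv;
          L.vi[ni] += wv;
          L.act[ni * (size_t)L.nk + a] = 1;
          L.n_integr += 1;
        }
      }
    }
  } else {  // FC
    size_t flat = ((size_t)im * L.in_side + ix) * L.in_side + iy;
    for (int n = 0; n < L.n_neurons; ++n) {
      double wv = L.w[flat + (size_t)L.nk * n];
      L.vl[n] += wv;
      L.vi[n] += wv;
      L.act[(size_t)n * L.nk + flat] = 1;
      L.n_integr += 1;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_run_stream(List net_layers, int input_side,
                    NumericVector ev_t, IntegerVector ev_map,
                    IntegerVector ev_row, IntegerVector ev_col,
                    LogicalVector layer_plastic,
                    NumericVector boundaries) {
  const int n_layers = net_layers.size();
  std::vector<Layer> layers(n_layers);

  for (int i = 0; i < n_layers; ++i) {
    List ls = net_layers[i];
    Layer& L = layers[i];
    std::string kind = as<std::string>(ls["kind"]);
    L.kind = kind == "conv" ? CONV : (kind == "pool" ? POOL : FC);
    L.in_side = as<int>(ls["in_side"]);
    L.in_maps = as<int>(ls["in_maps"]);
    L.out_side = as<int>(ls["out_side"]);
    L.maps = as<int>(ls["maps"]);
    L.plastic = layer_plastic[i];
    if (L.kind == POOL) {
      L.window = as<int>(ls["window"]);
      continue;
    }
    L.ksize = L.kind == CONV ? as<int>(ls["kernel"]) : 0;
    L.stride = L.kind == CONV ? as<int>(ls["stride"]) : 0;
    L.t_learn = as<double>(ls["t_learn"]);
    L.t_infer = as<double>(ls["t_infer"]);
    L.r_learn = L.kind == CONV ? as<int>(ls["r_inh_learn"]) : 0;
    L.r_infer = L.kind == CONV ? as<int>(ls["r_inh_infer"]) : -1;
    List sp = ls["stdp"];
    L.ap = as<double>(sp["alpha_plus"]);
    L.am = as<double>(sp["alpha_minus"]);
    L.bp = as<double>(sp["beta_plus"]);
    L.bm = as<double>(sp["beta_minus"]);
    L.simple = as<bool>(sp["simple"]);
    NumericVector wv = ls["w"];
    L.w.assign(wv.begin(), wv.end());
    L.nk = L.kind == CONV ? L.ksize * L.ksize * L.in_maps
                          : L.in_side * L.in_side * L.in_maps;
    L.n_neurons = L.kind == CONV ? L.maps * L.out_side * L.out_side : L.maps;
    L.vl.assign(L.n_neurons, 0.0);
    L.vi.assign(L.n_neurons, 0.0);
    L.trl.assign(L.n_neurons, 0.0);
    L.tri.assign(L.n_neurons, 0.0);
    L.act.assign((size_t)L.n_neurons * L.nk, 0);
  }

  std::priority_queue<Ev, std::vector<Ev>, EvCmp> pq;
  long long seq = 0;
  const int n_ev = ev_t.size();
  for (int i = 0; i < n_ev; ++i) {
    if (!(ev_t[i] >= 0) || !R_finite(ev_t[i]))
      stop("event times must be finite and non-negative");
    if (ev_row[i] < 0 || ev_row[i] >= input_side ||
        ev_col[i] < 0 || ev_col[i] >= input_side || ev_map[i] != 0)
      stop("input event address out of range for the network geometry");
    pq.push(Ev{ev_t[i], 0, ev_map[i], ev_row[i], ev_col[i], seq++});
  }

  Rec rec;
  int bi = 0;
  const int nb = boundaries.size();
  double n_boundary_resets = 0;

  while (!pq.empty()) {
    Ev e = pq.top(); pq.pop();

    // reset-per-example ablation: wipe all accumulators at stimulus onsets
    while (bi < nb && e.t >= boundaries[bi]) {
      for (auto& L : layers) {
        if (L.kind == POOL) continue;
        std::fill(L.vl.begin(), L.vl.end(), 0.0);
        std::fill(L.vi.begin(), L.vi.end(), 0.0);
        std::fill(L.trl.begin(), L.trl.end(), boundaries[bi]);
        std::fill(L.tri.begin(), L.tri.end(), boundaries[bi]);
        std::fill(L.act.begin(), L.act.end(), 0);
      }
      n_boundary_resets += 1;
      ++bi;
    }

    if (e.layer >= n_layers) continue;
    Layer& tgt = layers[e.layer];

    if (tgt.kind == POOL) {
      // relay: every spike is propagated, coordinates floor-divided
      int pr = e.row / tgt.window, pc = e.col / tgt.window;
      rec.add(e.t, e.layer + 1, e.map, pr, pc);
      tgt.n_prop += 1;
      if (e.layer + 1 < n_layers)
        pq.push(Ev{e.t, e.layer + 1, e.map, pr, pc, seq++});
      continue;
    }

    deliver(tgt, e.map, e.row, e.col);
    resolve(layers, e.layer, e.t, pq, seq, rec, n_layers);
  }

  List w_out(n_layers), vfin(n_layers);
  NumericVector integr(n_layers), pseudo(n_layers), prop(n_layers);
  for (int i = 0; i < n_layers; ++i) {
    Layer& L = layers[i];
    if (L.kind == POOL) {
      w_out[i] = R_NilValue;
      vfin[i] = R_NilValue;
    } else {
      w_out[i] = NumericVector(L.w.begin(), L.w.end());
      vfin[i] = List::create(_["v_learn"] = NumericVector(L.vl.begin(), L.vl.end()),
                             _["v_infer"] = NumericVector(L.vi.begin(), L.vi.end()));
    }
    integr[i] = L.n_integr;
    pseudo[i] = L.n_pseudo;
    prop[i] = L.n_prop;
  }

  return List::create(
    _["spike_t"] = wrap(rec.t),
    _["spike_layer"] = wrap(rec.layer),
    _["spike_map"] = wrap(rec.map),
    _["spike_row"] = wrap(rec.row),
    _["spike_col"] = wrap(rec.col),
    _["weights"] = w_out,
    _["state"] = vfin,
    _["integrations"] = integr,
    _["pseudo_spikes"] = pseudo,
    _["propagated_spikes"] = prop,
    _["boundary_resets"] = n_boundary_resets);
}
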