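// Search kernels: cached incremental evaluation of core-subset measures
// over the single-swap neighbourhood, random descent and parallel
// tempering engines, and a delta-vs-full evaluation checker.
//
// All randomness comes from a self-contained splitmix64 generator so
// that results are bit-identical across platforms for a given seed.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <chrono>
#include <limits>
#include <memory>
#include <vector>

using namespace Rcpp;

namespace {

struct RNG {
  uint64_t s;
  explicit RNG(uint64_t seed) : s(seed + 0x9e3779b97f4a7c15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int randint(int n) {  // uniform on 0..n-1, rejection sampled
    uint64_t nn = (uint64_t)n;
    uint64_t limit = UINT64_MAX - (UINT64_MAX % nn);
    uint64_t v;
    do { v = next(); } while (v >= limit);
    return (int)(v % nn);
  }
};

enum Measure { ENE = 0, ANE = 1, HE = 2, AVGEE = 3 };

struct ObjSpec {
  int measure;
  int dist_idx;    // index into the distance matrix list, -1 for HE
  double sign;     // +1 maximize, -1 minimize (A-NE)
  double weight;
  int normalize;   // 1: map sign-adjusted value through [L, U]
  int degenerate;  // 1: constant contribution 1
  double L, U;
};

// shared, read-only view of the problem data
struct Problem {
  int n = 0, k = 0;
  std::vector<const double*> dist;  // column-major n x n matrices
  std::vector<ObjSpec> objs;
  // genotype data (HE): n x A frequencies with NA -> 0 + observed flags
  std::vector<double> G;
  std::vector<char> obsG;   // n x L
  std::vector<int> locus_of;  // per column, 0-based
  int A = 0, Lg = 0;

  double dval(int m, int i, int j) const {
    return dist[m][(size_t)j * n + i];
  }
};

const double INF = std::numeric_limits<double>::infinity();

// nearest + second nearest bookkeeping helper
inline void push2(double d, int idx, double& d1, int& n1, double& d2,
                  int& n2) {
  if (d < d1 || (d == d1 && n1 < 0)) {
    d2 = d1; n2 = n1; d1 = d; n1 = idx;
  } else if (d < d2 || n2 < 0) {
    d2 = d; n2 = idx;
  }
}

struct EneState {  // per selected accession: nearest other entry
  std::vector<double> d1, d2;
  std::vector<int> n1, n2;
};
struct AneState {  // per accession: nearest core entry
  std::vector<double> d1, d2;
  std::vector<int> n1, n2;
};
struct HeState {
  std::vector<double> asum;  // per allele column, sum over core
  std::vector<int> lcnt;     // per locus, observed core entries
};

class Evaluator {
 public:
  const Problem* P;
  std::vector<char> sel;
  std::vector<int> selv, unselv;
  std::vector<int> pos;  // position in selv (selected) or unselv

  std::vector<EneState> ene;
  std::vector<AneState> ane;
  std::vector<HeState> he;
  std::vector<double> avgee;  // pairwise sums
  std::vector<double> raws;

  void init(const Problem& prob, const std::vector<int>& s0) {
    P = &prob;
    int n = P->n;
    sel.assign(n, 0);
    for (int i : s0) sel[i] = 1;
    selv.clear(); unselv.clear();
    pos.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      if (sel[i]) { pos[i] = (int)selv.size(); selv.push_back(i); }
      else { pos[i] = (int)unselv.size(); unselv.push_back(i); }
    }
    size_t m = P->objs.size();
    ene.assign(m, EneState());
    ane.assign(m, AneState());
    he.assign(m, HeState());
    avgee.assign(m, 0.0);
    raws.assign(m, 0.0);
    for (size_t o = 0; o < m; ++o) rebuild(o);
  }

  void rebuild(size_t o) {
    const ObjSpec& s = P->objs[o];
    int n = P->n, k = (int)selv.size();
    switch (s.measure) {
      case ENE: {
        EneState& st = ene[o];
        st.d1.assign(n, INF); st.d2.assign(n, INF);
        st.n1.assign(n, -1); st.n2.assign(n, -1);
        for (int a = 0; a < k; ++a) {
          int i = selv[a];
          for (int b = 0; b < k; ++b) {
            if (a == b) continue;
            int j = selv[b];
            push2(P->dval(s.dist_idx, i, j), j, st.d1[i], st.n1[i],
                  st.d2[i], st.n2[i]);
          }
        }
        break;
      }
      case ANE: {
        AneState& st = ane[o];
        st.d1.assign(n, INF); st.d2.assign(n, INF);
        st.n1.assign(n, -1); st.n2.assign(n, -1);
        for (int x = 0; x < n; ++x) {
          for (int b = 0; b < k; ++b) {
            int j = selv[b];
            push2(P->dval(s.dist_idx, x, j), j, st.d1[x], st.n1[x],
                  st.d2[x], st.n2[x]);
          }
        }
        break;
      }
      case HE: {
        HeState& st = he[o];
        st.asum.assign(P->A, 0.0);
        st.lcnt.assign(P->Lg, 0);
        for (int b = 0; b < k; ++b) {
          int i = selv[b];
          for (int c = 0; c < P->A; ++c) {
            st.asum[c] += P->G[(size_t)c * P->n + i];
          }
          for (int l = 0; l < P->Lg; ++l) {
            st.lcnt[l] += P->obsG[(size_t)l * P->n + i];
          }
        }
        break;
      }
      case AVGEE: {
        double sum = 0.0;
        for (int a = 0; a < k; ++a) {
          for (int b = a + 1; b < k; ++b) {
            sum += P->dval(s.dist_idx, selv[a], selv[b]);
          }
        }
        avgee[o] = sum;
        break;
      }
    }
  }

  // raw value of objective o from its caches (no state change)
  double raw(size_t o) const {
    const ObjSpec& s = P->objs[o];
    int n = P->n, k = (int)selv.size();
    switch (s.measure) {
      case ENE: {
        const EneState& st = ene[o];
        double sum = 0.0;
        for (int b = 0; b < k; ++b) sum += st.d1[selv[b]];
        return sum / k;
      }
      case ANE: {
        const AneState& st = ane[o];
        double sum = 0.0;
        for (int x = 0; x < n; ++x) sum += st.d1[x];
        return sum / n;
      }
      case HE: {
        const HeState& st = he[o];
        double tot = 0.0;
        int nl = 0;
        for (int l = 0; l < P->Lg; ++l) {
          if (st.lcnt[l] == 0) continue;
          ++nl;
          tot += 1.0;
        }
        for (int c = 0; c < P->A; ++c) {
          int l = P->locus_of[c];
          if (st.lcnt[l] == 0) continue;
          double p = st.asum[c] / st.lcnt[l];
          tot -= p * p;
        }
        if (nl == 0) stop("no locus observed in any core entry");
        return tot / nl;
      }
      case AVGEE:
        return avgee[o] / (k * (k - 1) / 2.0);
    }
    return 0.0;
  }

  // raw value of objective o if `out` were swapped for `in`
  double raw_after(size_t o, int out, int in) const {
    const ObjSpec& s = P->objs[o];
    int n = P->n, k = (int)selv.size();
    switch (s.measure) {
      case ENE: {
        const EneState& st = ene[o];
        double sum = 0.0, din = INF;
        for (int b = 0; b < k; ++b) {
          int i = selv[b];
          if (i == out) continue;
          double base = (st.n1[i] == out) ? st.d2[i] : st.d1[i];
          double da = P->dval(s.dist_idx, i, in);
          sum += (da < base) ? da : base;
          if (da < din) din = da;
        }
        sum += din;
        return sum / k;
      }
      case ANE: {
        const AneState& st = ane[o];
        double sum = 0.0;
        for (int x = 0; x < n; ++x) {
          double base = (st.n1[x] == out) ? st.d2[x] : st.d1[x];
          double da = P->dval(s.dist_idx, x, in);
          sum += (da < base) ? da : base;
        }
        return sum / n;
      }
      case HE: {
        const HeState& st = he[o];
        double tot = 0.0;
        int nl = 0;
        std::vector<double> locsum(P->Lg, 0.0);
        std::vector<int> cnt(P->Lg);
        for (int l = 0; l < P->Lg; ++l) {
          cnt[l] = st.lcnt[l] - P->obsG[(size_t)l * n + out] +
                   P->obsG[(size_t)l * n + in];
        }
        for (int c = 0; c < P->A; ++c) {
          int l = P->locus_of[c];
          if (cnt[l] == 0) continue;
          double v = st.asum[c] - P->G[(size_t)c * n + out] +
                     P->G[(size_t)c * n + in];
          double p = v / cnt[l];
          locsum[l] += p * p;
        }
        for (int l = 0; l < P->Lg; ++l) {
          if (cnt[l] == 0) continue;
          ++nl;
          tot += 1.0 - locsum[l];
        }
        if (nl == 0) stop("no locus observed in any core entry");
        return tot / nl;
      }
      case AVGEE: {
        double sum = avgee[o];
        for (int b = 0; b < k; ++b) {
          int i = selv[b];
          if (i == out) continue;
          sum += P->dval(s.dist_idx, i, in) - P->dval(s.dist_idx, i, out);
        }
        return sum / (k * (k - 1) / 2.0);
      }
    }
    return 0.0;
  }

  double combine(const std::vector<double>& rv) const {
    double total = 0.0;
    for (size_t o = 0; o < P->objs.size(); ++o) {
      const ObjSpec& s = P->objs[o];
      double v = s.sign * rv[o];
      double x;
      if (s.degenerate) {
        x = 1.0;
      } else if (s.normalize) {
        x = (v - s.L) / (s.U - s.L);
        if (x < 0) x = 0;
        if (x > 1) x = 1;
      } else {
        x = v;
      }
      total += s.weight * x;
    }
    return total;
  }

  double value() {
    for (size_t o = 0; o < P->objs.size(); ++o) raws[o] = raw(o);
    return combine(raws);
  }

  double propose(int out, int in, std::vector<double>* rv = nullptr) {
    std::vector<double> tmp(P->objs.size());
    for (size_t o = 0; o < P->objs.size(); ++o) {
      tmp[o] = raw_after(o, out, in);
    }
    if (rv) *rv = tmp;
    return combine(tmp);
  }

  void accept(int out, int in) {
    int n = P->n;
    // swap membership, keep selv/unselv dense
    int ps = pos[out], pu = pos[in];
    selv[ps] = in; unselv[pu] = out;
    pos[in] = ps; pos[out] = pu;
    sel[out] = 0; sel[in] = 1;
    int k = (int)selv.size();

    for (size_t o = 0; o < P->objs.size(); ++o) {
      const ObjSpec& s = P->objs[o];
      switch (s.measure) {
        case ENE: {
          EneState& st = ene[o];
          st.d1[out] = st.d2[out] = INF;
          st.n1[out] = st.n2[out] = -1;
          // entry `in`: full scan
          st.d1[in] = st.d2[in] = INF; st.n1[in] = st.n2[in] = -1;
          for (int b = 0; b < k; ++b) {
            int i = selv[b];
            if (i == in) continue;
            push2(P->dval(s.dist_idx, in, i), i, st.d1[in], st.n1[in],
                  st.d2[in], st.n2[in]);
          }
          for (int b = 0; b < k; ++b) {
            int i = selv[b];
            if (i == in) continue;
            if (st.n1[i] == out || st.n2[i] == out) {
              st.d1[i] = st.d2[i] = INF; st.n1[i] = st.n2[i] = -1;
              for (int c = 0; c < k; ++c) {
                int j = selv[c];
                if (j == i) continue;
                push2(P->dval(s.dist_idx, i, j), j, st.d1[i], st.n1[i],
                      st.d2[i], st.n2[i]);
              }
            } else {
              push2(P->dval(s.dist_idx, i, in), in, st.d1[i], st.n1[i],
                    st.d2[i], st.n2[i]);
            }
          }
          break;
        }
        case ANE: {
          AneState& st = ane[o];
          for (int x = 0; x < n; ++x) {
            if (st.n1[x] == out || st.n2[x] == out) {
              st.d1[x] = st.d2[x] = INF; st.n1[x] = st.n2[x] = -1;
              for (int b = 0; b < k; ++b) {
                int j = selv[b];
                push2(P->dval(s.dist_idx, x, j), j, st.d1[x], st.n1[x],
                      st.d2[x], st.n2[x]);
              }
            } else {
              push2(P->dval(s.dist_idx, x, in), in, st.d1[x], st.n1[x],
                    st.d2[x], st.n2[x]);
            }
          }
          break;
        }
        case HE: {
          HeState& st = he[o];
          for (int c = 0; c < P->A; ++c) {
            st.asum[c] += P->G[(size_t)c * n + in] -
                          P->G[(size_t)c * n + out];
          }
          for (int l = 0; l < P->Lg; ++l) {
            st.lcnt[l] += P->obsG[(size_t)l * n + in] -
                          P->obsG[(size_t)l * n + out];
          }
          break;
        }
        case AVGEE: {
          double delta = 0.0;
          for (int b = 0; b < k; ++b) {
            int i = selv[b];
            if (i == in) continue;
            delta += P->dval(s.dist_idx, i, in) -
                     P->dval(s.dist_idx, i, out);
          }
          avgee[o] += delta;
          break;
        }
      }
    }
  }
};

struct StopSpec {
  double max_evals, max_stall_evals, max_time, max_stall_time;
};

struct Tracker {
  std::chrono::steady_clock::time_point t0;
  StopSpec stop;
  double evals = 0.0, stall_evals = 0.0;
  double best = -INF;
  double last_improve_time = 0.0;
  std::vector<int> best_sel;
  std::vector<double> tr_evals, tr_time, tr_value;

  explicit Tracker(const StopSpec& s) : stop(s) {
    t0 = std::chrono::steady_clock::now();
  }
  double elapsed() const {
    return std::chrono::duration<double>(
               std::chrono::steady_clock::now() - t0)
        .count();
  }
  // returns true if this value improved the global best
  bool record(double value, const std::vector<int>& selv) {
    if (value > best) {
      best = value;
      best_sel = selv;
      stall_evals = 0.0;
      last_improve_time = elapsed();
      tr_evals.push_back(evals);
      tr_time.push_back(last_improve_time);
      tr_value.push_back(value);
      return true;
    }
    return false;
  }
  bool done() {
    if (evals >= stop.max_evals) return true;
    if (stall_evals >= stop.max_stall_evals) return true;
    if (std::isfinite(stop.max_time) || std::isfinite(stop.max_stall_time)) {
      double el = elapsed();
      if (el >= stop.max_time) return true;
      if (el - last_improve_time >= stop.max_stall_time) return true;
    }
    return false;
  }
};

Problem build_problem(List dist_list, DataFrame obj_spec,
                      Nullable<NumericMatrix> geno,
                      Nullable<IntegerVector> locus_of, int n, int k) {
  Problem P;
  P.n = n;
  P.k = k;
  for (int m = 0; m < dist_list.size(); ++m) {
    NumericMatrix d = dist_list[m];
    if (d.nrow() != n || d.ncol() != n) stop("distance matrix size mismatch");
    P.dist.push_back(REAL(d));
  }
  IntegerVector measure = obj_spec["measure"];
  IntegerVector dist_idx = obj_spec["dist_idx"];
  NumericVector sign = obj_spec["sign"];
  NumericVector weight = obj_spec["weight"];
  IntegerVector normalize = obj_spec["normalize"];
  IntegerVector degenerate = obj_spec["degenerate"];
  NumericVector L = obj_spec["lower"];
  NumericVector U = obj_spec["upper"];
  bool need_geno = false;
  for (int i = 0; i < measure.size(); ++i) {
    ObjSpec s;
    s.measure = measure[i];
    s.dist_idx = dist_idx[i];
    s.sign = sign[i];
    s.weight = weight[i];
    s.normalize = normalize[i];
    s.degenerate = degenerate[i];
    s.L = L[i];
    s.U = U[i];
    if (s.measure == HE) need_geno = true;
    else if (s.dist_idx < 0 || s.dist_idx >= (int)P.dist.size())
      stop("objective references a missing distance matrix");
    P.objs.push_back(s);
  }
  if (need_geno) {
    if (geno.isNull() || locus_of.isNull()) stop("HE requires genotype data");
    NumericMatrix G(geno);
    IntegerVector loc(locus_of);
    if (G.nrow() != n) stop("genotype matrix size mismatch");
    P.A = G.ncol();
    P.locus_of.assign(P.A, 0);
    int Lg = 0;
    for (int c = 0; c < P.A; ++c) {
      P.locus_of[c] = loc[c] - 1;
      if (P.locus_of[c] + 1 > Lg) Lg = P.locus_of[c] + 1;
    }
    P.Lg = Lg;
    P.G.assign((size_t)n * P.A, 0.0);
    P.obsG.assign((size_t)n * Lg, 0);
    for (int c = 0; c < P.A; ++c) {
      int l = P.locus_of[c];
      for (int i = 0; i < n; ++i) {
        double v = G(i, c);
        if (!ISNAN(v)) {
          P.G[(size_t)c * n + i] = v;
          P.obsG[(size_t)l * n + i] = 1;
        }
      }
    }
  }
  return P;
}

StopSpec build_stop(List stop) {
  StopSpec s;
  s.max_evals = as<double>(stop["max_evals"]);
  s.max_stall_evals = as<double>(stop["max_stall_evals"]);
  s.max_time = as<double>(stop["max_time"]);
  s.max_stall_time = as<double>(stop["max_stall_time"]);
  return s;
}

std::vector<int> random_subset(RNG& rng, int n, int k) {
  // Floyd's algorithm for a uniform k-subset
  std::vector<char> in(n, 0);
  std::vector<int> out;
  for (int j = n - k; j < n; ++j) {
    int t = rng.randint(j + 1);
    if (in[t]) t = j;
    in[t] = 1;
    out.push_back(t);
  }
  return out;
}

List result_list(const Tracker& trk) {
  IntegerVector sel(trk.best_sel.begin(), trk.best_sel.end());
  sel = sel + 1;
  return List::create(
      _["selected"] = sel, _["value"] = trk.best,
      _["evals"] = trk.evals,
      _["trace"] = DataFrame::create(_["evals"] = trk.tr_evals,
                                     _["time"] = trk.tr_time,
                                     _["value"] = trk.tr_value));
}

}  // namespace

// [[Rcpp::export]]
List cpp_random_descent(List dist_list, DataFrame obj_spec,
                        Nullable<NumericMatrix> geno,
                        Nullable<IntegerVector> locus_of, int n, int k,
                        IntegerVector init, double seed, List stop) {
  Problem P = build_problem(dist_list, obj_spec, geno, locus_of, n, k);
  RNG rng((uint64_t)seed);
  std::vector<int> s0;
  if (init.size() > 0) {
    for (int i = 0; i < init.size(); ++i) s0.push_back(init[i] - 1);
  } else {
    s0 = random_subset(rng, n, k);
  }
  Evaluator ev;
  ev.init(P, s0);
  Tracker trk(build_stop(stop));
  double cur = ev.value();
  trk.evals = 1;
  trk.record(cur, ev.selv);
  while (!trk.done()) {
    int out = ev.selv[rng.randint(k)];
    int in = ev.unselv[rng.randint(n - k)];
    double cand = ev.propose(out, in);
    trk.evals += 1;
    trk.stall_evals += 1;
    if (cand > cur) {  // strict improvement only; ties rejected
      ev.accept(out, in);
      cur = cand;
      trk.record(cur, ev.selv);
    }
  }
  return result_list(trk);
}

// [[Rcpp::export]]
List cpp_parallel_tempering(List dist_list, DataFrame obj_spec,
                            Nullable<NumericMatrix> geno,
                            Nullable<IntegerVector> locus_of, int n,
                            int k, double seed, List stop, int replicas,
                            double t_min, double t_max, int q) {
  Problem P = build_problem(dist_list, obj_spec, geno, locus_of, n, k);
  RNG master((uint64_t)seed);
  int p = replicas;
  std::vector<double> temp(p);
  for (int r = 0; r < p; ++r) {
    temp[r] = t_min + (t_max - t_min) * r / (p - 1.0);
  }
  std::vector<std::unique_ptr<Evaluator>> ev;
  std::vector<std::unique_ptr<RNG>> rng;
  std::vector<double> cur(p);
  Tracker trk(build_stop(stop));
  for (int r = 0; r < p; ++r) {
    rng.emplace_back(new RNG(master.next()));
    ev.emplace_back(new Evaluator());
    ev[r]->init(P, random_subset(*rng[r], n, k));
    cur[r] = ev[r]->value();
    trk.evals += 1;
    trk.record(cur[r], ev[r]->selv);
  }
  while (!trk.done()) {
    // one round: q Metropolis steps per replica, then one exchange pass
    for (int r = 0; r < p && !trk.done(); ++r) {
      Evaluator& e = *ev[r];
      RNG& g = *rng[r];
      for (int s = 0; s < q && !trk.done(); ++s) {
        int out = e.selv[g.randint(k)];
        int in = e.unselv[g.randint(n - k)];
        double cand = e.propose(out, in);
        trk.evals += 1;
        trk.stall_evals += 1;
        double delta = cand - cur[r];
        bool acc = delta > 0 || g.unif() < std::exp(delta / temp[r]);
        if (acc) {
          e.accept(out, in);
          cur[r] = cand;
          trk.record(cur[r], e.selv);
        }
      }
    }
    for (int r = 0; r + 1 < p; ++r) {
      double delta = cur[r + 1] - cur[r];
      bool swap = delta > 0 ||
                  master.unif() <
                      std::exp((1.0 / temp[r] - 1.0 / temp[r + 1]) * delta);
      if (swap) {
        std::swap(ev[r], ev[r + 1]);
        std::swap(cur[r], cur[r + 1]);
      }
    }
  }
  return result_list(trk);
}

// [[Rcpp::export]]
List cpp_evaluate_selection(List dist_list, DataFrame obj_spec,
                            Nullable<NumericMatrix> geno,
                            Nullable<IntegerVector> locus_of, int n,
                            int k, IntegerVector selected) {
  Problem P = build_problem(dist_list, obj_spec, geno, locus_of, n, k);
  std::vector<int> s0;
  for (int i = 0; i < selected.size(); ++i) s0.push_back(selected[i] - 1);
  Evaluator ev;
  ev.init(P, s0);
  double v = ev.value();
  return List::create(_["value"] = v,
                      _["raw"] = NumericVector(ev.raws.begin(),
                                               ev.raws.end()));
}

// Evaluate many selections (columns of `sels`, 1-based) in one call;
// used by the exhaustive-enumeration oracle.
// [[Rcpp::export]]
NumericVector cpp_evaluate_many(List dist_list, DataFrame obj_spec,
                                Nullable<NumericMatrix> geno,
                                Nullable<IntegerVector> locus_of, int n,
                                int k, IntegerMatrix sels) {
  Problem P = build_problem(dist_list, obj_spec, geno, locus_of, n, k);
  int m = sels.ncol();
  NumericVector out(m);
  Evaluator ev;
  std::vector<int> s0(k);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < k; ++i) s0[i] = sels(i, j) - 1;
    ev.init(P, s0);
    out[j] = ev.value();
  }
  return out;
}

// Perform a random walk of accepted swaps; at every step report each
// objective's incrementally computed post-swap value next to a from-
// scratch re-evaluation, to bound delta-evaluation error.
// [[Rcpp::export]]
List cpp_delta_check(List dist_list, DataFrame obj_spec,
                     Nullable<NumericMatrix> geno,
                     Nullable<IntegerVector> locus_of, int n, int k,
                     int n_swaps, double seed) {
  Problem P = build_problem(dist_list, obj_spec, geno, locus_of, n, k);
  RNG rng((uint64_t)seed);
  Evaluator ev;
  ev.init(P, random_subset(rng, n, k));
  size_t m = P.objs.size();
  NumericMatrix inc(n_swaps, m), full(n_swaps, m);
  for (int s = 0; s < n_swaps; ++s) {
    int out = ev.selv[rng.randint(k)];
    int in = ev.unselv[rng.randint(n - k)];
    std::vector<double> rv;
    ev.propose(out, in, &rv);
    ev.accept(out, in);
    Evaluator fresh;
    fresh.init(P, ev.selv);
    fresh.value();
    for (size_t o = 0; o < m; ++o) {
      inc(s, o) = rv[o];
      full(s, o) = fresh.raws[o];
    }
  }
  return List::create(_["incremental"] = inc, _["full"] = full);
}
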