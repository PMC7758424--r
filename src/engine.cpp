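#include <Rcpp.h>
using namespace Rcpp;

// Per-trial simulation loop. Mirrors run_trial_reference() in R/engine.R
// draw for draw: both use R's RNG stream in the identical order, so the
// two engines produce bit-identical trials from the same seed.
//
// Draw order per trial:
//   init: u (object pick), u (attribute pick)
//   each step:
//     if not locked: u (attention shift); on shift to a new location:
//       u (attribute pick)
//     on dwell_attr cadence: u (attribute pick)
//     if mem noise > 0: N normals
//     if sigma > 0: L normals
//     on a decision tie: u (tie break)

static inline double clip01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// [[Rcpp::export]]
List cpp_run_trial(List plan, bool traces) {
  const int N = as<int>(plan["n"]);
  const int L = as<int>(plan["L"]);
  const NumericVector s = plan["s"];
  const NumericMatrix feat = plan["feat"];
  const IntegerVector attr_start = plan["attr_start"];
  const IntegerVector attr_count = plan["attr_count"];
  const IntegerVector obj_loc = plan["obj_loc"];
  const int n_obj = obj_loc.size();
  const NumericVector v = plan["v"];
  const NumericMatrix Ws = plan["Ws"];
  const NumericMatrix We = plan["We"];

  const double dt = as<double>(plan["dt"]);
  const int tau_fast = as<int>(plan["tau_fast"]);
  const int tau_slow = as<int>(plan["tau_slow"]);
  const double dep_gain = as<double>(plan["dep_gain"]);
  const double dep_rec = as<double>(plan["dep_rec"]);
  const double mleak = as<double>(plan["mem_leak"]);
  const double mnoise = as<double>(plan["mem_noise"]);

  const double alpha = as<double>(plan["alpha"]);
  const double beta = as<double>(plan["beta"]);
  const double gamma = as<double>(plan["gamma"]);
  const double delta = as<double>(plan["delta"]);
  const double lambda = as<double>(plan["lambda"]);
  const double sigma = as<double>(plan["sigma"]);
  const double threshold = as<double>(plan["threshold"]);
  const bool clamp_state = as<bool>(plan["clamp_state"]);

  const double eps = as<double>(plan["epsilon"]);
  const double phi = as<double>(plan["phi"]);
  const double ncontrast = as<double>(plan["ncontrast"]);

  const double input_gain = as<double>(plan["input_gain"]);
  const int dwell_attr = as<int>(plan["dwell_attr"]);
  const int max_steps = as<int>(plan["max_steps"]);

  const int depth = tau_slow > tau_fast ? tau_slow : tau_fast;
  const double *Wsp = Ws.begin();
  const double *Wep = We.begin();
  const double *featp = feat.begin();
  const bool use_dep = (dep_gain > 0.0 || dep_rec > 0.0);

  std::vector<double> xm(N, 0.0), m(N, 0.0), rec(N, 0.0), I(N, 0.0);
  std::vector<double> D(use_dep ? (size_t)N * N : 0, 0.0);
  std::vector<double> hist((size_t)N * depth, 0.0);
  std::vector<double> fa(L, 0.0), acc(L, 0.0), p(L, 0.0), w(L, 0.0);
  std::vector<int> dwell(L, 0);
  int t_mem = 0;

  NumericMatrix acc_tr, mem_tr;
  IntegerVector att_tr;
  NumericVector v_tr;
  if (traces) {
    acc_tr = NumericMatrix(max_steps, L);
    mem_tr = NumericMatrix(max_steps, N);
    att_tr = IntegerVector(max_steps);
    v_tr = NumericVector(max_steps);
  }

  RNGScope scope;

  // initial attention: uniform over objects, then one of its attributes
  int oi = (int)(unif_rand() * n_obj);
  if (oi >= n_obj) oi = n_obj - 1;
  int current = obj_loc[oi];
  int k = attr_count[current];
  int ai = (int)(unif_rand() * k);
  if (ai >= k) ai = k - 1;
  int attr_col = attr_start[current] + ai;
  int dwell_steps = 0;
  bool locked = false;

  int choice = -1, rt = -1, steps_run = 0;

  for (int t = 1; t <= max_steps; ++t) {
    // --- attention ---
    if (!locked) {
      double tot = 0.0;
      for (int i = 0; i < L; ++i) {
        double g = acc[i] > 0.0 ? acc[i] : 0.0;
        w[i] = s[i] + phi * std::pow(g, ncontrast);
        tot += w[i];
      }
      if (tot <= 0.0) stop("degenerate scene: zero total salience+feedback");
      double u = unif_rand();
      double cum = 0.0;
      int target = -1;
      for (int i = 0; i < L; ++i) {
        cum += eps * w[i] / tot;
        if (u < cum) { target = i; break; }
      }
      if (target >= 0 && target != current) {
        current = target;
        // memory reset on shift; depression persists
        std::fill(xm.begin(), xm.end(), 0.0);
        std::fill(hist.begin(), hist.end(), 0.0);
        t_mem = 0;
        k = attr_count[current];
        int a2 = (int)(unif_rand() * k);
        if (a2 >= k) a2 = k - 1;
        attr_col = attr_start[current] + a2;
        dwell_steps = 0;
      }
    }
    dwell[current] += 1;
    dwell_steps += 1;
    if (dwell_steps >= dwell_attr) {
      k = attr_count[current];
      int a2 = (int)(unif_rand() * k);
      if (a2 >= k) a2 = k - 1;
      attr_col = attr_start[current] + a2;
      dwell_steps = 0;
    }

    // --- memory step ---
    int sf = t_mem - tau_fast + 1, ss = t_mem - tau_slow + 1;
    const double *ff = sf >= 1 ? &hist[(size_t)((sf - 1) % depth) * N] : NULL;
    const double *fs = ss >= 1 ? &hist[(size_t)((ss - 1) % depth) * N] : NULL;
    for (int i = 0; i < N; ++i) rec[i] = 0.0;
    if (use_dep) {
      for (int j = 0; j < N; ++j) {
        double fj_f = ff ? ff[j] : 0.0, fj_s = fs ? fs[j] : 0.0;
        if (fj_f == 0.0 && fj_s == 0.0) continue;
        const double *ws = Wsp + (size_t)j * N, *we = Wep + (size_t)j * N;
        const double *dcol = &D[(size_t)j * N];
        for (int i = 0; i < N; ++i) {
          rec[i] += (1.0 - dcol[i]) * (ws[i] * fj_f + we[i] * fj_s);
        }
      }
    } else {
      for (int j = 0; j < N; ++j) {
        double fj_f = ff ? ff[j] : 0.0, fj_s = fs ? fs[j] : 0.0;
        if (fj_f == 0.0 && fj_s == 0.0) continue;
        const double *ws = Wsp + (size_t)j * N, *we = Wep + (size_t)j * N;
        for (int i = 0; i < N; ++i) rec[i] += ws[i] * fj_f + we[i] * fj_s;
      }
    }
    for (int i = 0; i < N; ++i) I[i] = input_gain * featp[(size_t)attr_col * N + i];
    bool bad = false;
    for (int i = 0; i < N; ++i) {
      xm[i] += dt * (I[i] + rec[i] - mleak * xm[i]);
    }
    if (mnoise > 0.0) {
      double sd = mnoise * std::sqrt(dt);
      for (int i = 0; i < N; ++i) xm[i] += sd * norm_rand();
    }
    for (int i = 0; i < N; ++i) if (!std::isfinite(xm[i])) bad = true;
    if (bad) stop("memory state diverged (non-finite activation) at step %d", t);
    if (use_dep) {
      // depression grows with the signal through each connection
      for (int j = 0; j < N; ++j) {
        double fj_f = ff ? ff[j] : 0.0, fj_s = fs ? fs[j] : 0.0;
        const double *ws = Wsp + (size_t)j * N, *we = Wep + (size_t)j * N;
        double *dcol = &D[(size_t)j * N];
        for (int i = 0; i < N; ++i) {
          double sig = ws[i] * fj_f + we[i] * fj_s;
          double dn = dcol[i] +
            dt * (dep_gain * sig * (1.0 - dcol[i]) - dep_rec * dcol[i]);
          dcol[i] = dn < 0.0 ? 0.0 : (dn > 1.0 ? 1.0 : dn);
        }
      }
    }
    t_mem += 1;
    double *hcol = &hist[(size_t)((t_mem - 1) % depth) * N];
    double V = 0.0;
    for (int i = 0; i < N; ++i) {
      m[i] = clip01(xm[i]);
      hcol[i] = m[i];
      V += v[i] * m[i];
    }

    // --- accumulators ---
    double sumf = 0.0;
    for (int i = 0; i < L; ++i) {
      fa[i] = acc[i] > 0.0 ? acc[i] : 0.0;
      sumf += fa[i];
    }
    for (int i = 0; i < L; ++i) {
      double Ii = (i == current) ? V : 0.0;
      double dx = -lambda * acc[i] + alpha * Ii - beta * (V - Ii) +
        gamma * fa[i] - delta * (sumf - fa[i]);
      acc[i] += dt * dx;
    }
    if (sigma > 0.0) {
      double sd = sigma * std::sqrt(dt);
      for (int i = 0; i < L; ++i) acc[i] += sd * norm_rand();
    }
    for (int i = 0; i < L; ++i) {
      if (!std::isfinite(acc[i]))
        stop("accumulator state diverged (non-finite) at step %d", t);
      if (clamp_state && acc[i] < 0.0) acc[i] = 0.0;
    }

    if (traces) {
      for (int i = 0; i < L; ++i) acc_tr(t - 1, i) = acc[i];
      for (int i = 0; i < N; ++i) mem_tr(t - 1, i) = m[i];
      att_tr[t - 1] = current;
      v_tr[t - 1] = V;
    }
    steps_run = t;

    // --- decision ---
    double best = -1.0;
    int n_cross = 0;
    for (int i = 0; i < L; ++i) {
      if (acc[i] >= threshold && acc[i] > best) best = acc[i];
    }
    if (best >= threshold) {
      std::vector<int> top;
      for (int i = 0; i < L; ++i) {
        if (acc[i] >= threshold && acc[i] == best) top.push_back(i);
      }
      n_cross = (int)top.size();
      int win;
      if (n_cross == 1) {
        win = top[0];
      } else {
        int ti = (int)(unif_rand() * n_cross);
        if (ti >= n_cross) ti = n_cross - 1;
        win = top[ti];
      }
      choice = win;
      rt = t;
      locked = true;
      current = win;
      for (int i = 0; i < L; ++i) acc[i] = 0.0; // decision layer resets
      break;
    }
  }

  List out = List::create(
    _["choice"] = choice, _["rt"] = rt,
    _["dwell"] = IntegerVector(dwell.begin(), dwell.end()),
    _["steps"] = steps_run);
  if (traces) {
    out["acc_trace"] = acc_tr(Range(0, steps_run - 1), _);
    out["mem_trace"] = mem_tr(Range(0, steps_run - 1), _);
    out["att_trace"] = IntegerVector(att_tr.begin(), att_tr.begin() + steps_run);
    out["v_trace"] = NumericVector(v_tr.begin(), v_tr.begin() + steps_run);
  }
  return out;
}
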