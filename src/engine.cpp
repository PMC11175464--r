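#include <Rcpp.h>
using namespace Rcpp;

// Model codes: 0 = surprise-minimization (free epsilon, dynamic omega)
//              1 = fixed-weight variant (epsilon inert, weight constant)
//              2 = joint-action TD learner over the 2x2 action space
// Counterfactual modes for the unchosen option within each policy/decision:
//              0 = counterfactual (V -= alpha * delta)
//              1 = learning-rate decay (V *= 1 - alpha)
//              2 = free decay parameter (V *= 1 - decay)

static inline double inv_logit_clamped(double x) {
  if (x > 700.0) x = 700.0;
  if (x < -700.0) x = -700.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// numerically stable two-option softmax; returns P(option 1)
static inline double softmax2(double u1, double u2) {
  double m = u1 > u2 ? u1 : u2;
  double e1 = std::exp(u1 - m), e2 = std::exp(u2 - m);
  return e1 / (e1 + e2);
}

// [[Rcpp::export]]
List engine_run(int model_code, double fixed_w, int cf_mode,
                double alpha, double beta, double rho,
                double epsilon, double decay,
                IntegerVector block,
                NumericVector o1_pts, NumericVector o2_pts,
                IntegerVector a1_obs, IntegerVector a2_obs,
                NumericVector P, NumericVector Q,
                bool simulate) {
  const int n = block.size();
  RNGScope rng;

  // latent storage (per trial)
  IntegerVector a1(n), a2(n);
  NumericVector out1(n), out2(n);
  NumericVector p1_d1(n), p1_d2(n);
  NumericVector vc_d1_a1(n), vc_d1_a2(n), vc_d2_a1(n), vc_d2_a2(n);
  NumericVector vi_d1_a1(n), vi_d1_a2(n), vi_d2_a1(n), vi_d2_a2(n);
  NumericVector dc1(n), dc2(n), di1(n), di2(n);
  NumericVector sc1(n), sc2(n), si1(n), si2(n);
  NumericVector ev1(n), ev2(n), omega(n), weight(n);
  // joint-action latents
  NumericVector vj_chosen(n), dj(n), pj_chosen(n);
  IntegerVector jact(n);
  NumericMatrix pj(model_code == 2 ? n : 0, 4);

  double Vc[2][2], Vi[2][2], Vj[4];
  double om = 0.0;
  int prev1 = 0, prev2 = 0, prevj = 0; // 0 = no previous action (block start)
  double nll = 0.0;
  double om_final = 0.0;

  for (int t = 0; t < n; ++t) {
    if (t == 0 || block[t] != block[t - 1]) {
      for (int d = 0; d < 2; ++d)
        for (int a = 0; a < 2; ++a) { Vc[d][a] = 0.0; Vi[d][a] = 0.0; }
      for (int j = 0; j < 4; ++j) Vj[j] = 0.0;
      om = 0.0; prev1 = 0; prev2 = 0; prevj = 0;
    }

    double w = (model_code == 1) ? fixed_w : inv_logit_clamped(om);
    omega[t] = om;
    weight[t] = w;

    int ca1, ca2;
    double r1, r2;

    if (model_code == 2) {
      // joint-action model: softmax over the four action combinations
      double u[4], pmax = -1e300;
      for (int j = 0; j < 4; ++j) {
        u[j] = beta * Vj[j] + rho * ((j + 1) == prevj ? 1.0 : 0.0);
        if (u[j] > pmax) pmax = u[j];
      }
      double Z = 0.0, pj_t[4];
      for (int j = 0; j < 4; ++j) { pj_t[j] = std::exp(u[j] - pmax); Z += pj_t[j]; }
      for (int j = 0; j < 4; ++j) { pj_t[j] /= Z; pj(t, j) = pj_t[j]; }

      int j_ch;
      if (simulate) {
        double uu = unif_rand(), cum = 0.0;
        j_ch = 3;
        for (int j = 0; j < 4; ++j) { cum += pj_t[j]; if (uu < cum) { j_ch = j; break; } }
      } else {
        j_ch = (a1_obs[t] - 1) * 2 + (a2_obs[t] - 1);
      }
      ca1 = j_ch / 2 + 1;
      ca2 = j_ch % 2 + 1;
      nll -= std::log(pj_t[j_ch] > 1e-300 ? pj_t[j_ch] : 1e-300);

      double o1 = simulate ? (ca1 == 1 ? P[t] : 100.0 - P[t]) : o1_pts[t];
      double o2 = simulate ? (ca2 == 1 ? Q[t] : 100.0 - Q[t]) : o2_pts[t];
      r1 = o1 / 50.0 - 1.0;
      r2 = o2 / 50.0 - 1.0;

      vj_chosen[t] = Vj[j_ch];
      pj_chosen[t] = pj_t[j_ch];
      jact[t] = j_ch + 1;
      double d = (r1 + r2) - Vj[j_ch];
      dj[t] = d;
      Vj[j_ch] += alpha * d;
      prevj = j_ch + 1;
      a1[t] = ca1; a2[t] = ca2; out1[t] = o1; out2[t] = o2;
      continue;
    }

    // two-policy models: per-decision softmax on weighted net values
    // decision 1
    double vn1_a1 = w * Vc[0][0] + (1.0 - w) * Vi[0][0];
    double vn1_a2 = w * Vc[0][1] + (1.0 - w) * Vi[0][1];
    double u1 = beta * vn1_a1 + rho * (prev1 == 1 ? 1.0 : 0.0);
    double u2 = beta * vn1_a2 + rho * (prev1 == 2 ? 1.0 : 0.0);
    double p1 = softmax2(u1, u2);
    p1_d1[t] = p1;
    ca1 = simulate ? (unif_rand() < p1 ? 1 : 2) : a1_obs[t];
    nll -= std::log((ca1 == 1 ? p1 : 1.0 - p1) > 1e-300 ? (ca1 == 1 ? p1 : 1.0 - p1) : 1e-300);

    // decision 2
    double vn2_a1 = w * Vc[1][0] + (1.0 - w) * Vi[1][0];
    double vn2_a2 = w * Vc[1][1] + (1.0 - w) * Vi[1][1];
    double v1 = beta * vn2_a1 + rho * (prev2 == 1 ? 1.0 : 0.0);
    double v2 = beta * vn2_a2 + rho * (prev2 == 2 ? 1.0 : 0.0);
    double p2 = softmax2(v1, v2);
    p1_d2[t] = p2;
    ca2 = simulate ? (unif_rand() < p2 ? 1 : 2) : a2_obs[t];
    nll -= std::log((ca2 == 1 ? p2 : 1.0 - p2) > 1e-300 ? (ca2 == 1 ? p2 : 1.0 - p2) : 1e-300);

    double o1 = simulate ? (ca1 == 1 ? P[t] : 100.0 - P[t]) : o1_pts[t];
    double o2 = simulate ? (ca2 == 1 ? Q[t] : 100.0 - Q[t]) : o2_pts[t];
    r1 = o1 / 50.0 - 1.0;
    r2 = o2 / 50.0 - 1.0;

    // record pre-update values
    vc_d1_a1[t] = Vc[0][0]; vc_d1_a2[t] = Vc[0][1];
    vc_d2_a1[t] = Vc[1][0]; vc_d2_a2[t] = Vc[1][1];
    vi_d1_a1[t] = Vi[0][0]; vi_d1_a2[t] = Vi[0][1];
    vi_d2_a1[t] = Vi[1][0]; vi_d2_a2[t] = Vi[1][1];

    // prediction errors against pre-update values of the chosen actions.
    // Correct mapping: d1 -> o1, d2 -> o2. Incorrect mapping: d1 -> o2, d2 -> o1.
    int i1 = ca1 - 1, i2 = ca2 - 1;
    dc1[t] = r1 - Vc[0][i1];
    dc2[t] = r2 - Vc[1][i2];
    di1[t] = r2 - Vi[0][i1];
    di2[t] = r1 - Vi[1][i2];

    // value updates: chosen option moves with the PE; the unchosen option
    // either mirrors it (counterfactual) or decays
    double deltas[2][2] = { { dc1[t], dc2[t] }, { di1[t], di2[t] } };
    for (int pol = 0; pol < 2; ++pol) {
      double (*V)[2] = pol == 0 ? Vc : Vi;
      int chosen[2] = { i1, i2 };
      for (int d = 0; d < 2; ++d) {
        int ch = chosen[d], un = 1 - ch;
        V[d][ch] += alpha * deltas[pol][d];
        if (cf_mode == 0) V[d][un] -= alpha * deltas[pol][d];
        else if (cf_mode == 1) V[d][un] *= (1.0 - alpha);
        else V[d][un] *= (1.0 - decay);
      }
    }

    sc1[t] = std::fabs(dc1[t]); sc2[t] = std::fabs(dc2[t]);
    si1[t] = std::fabs(di1[t]); si2[t] = std::fabs(di2[t]);

    // evidence pairs surprise signals across decisions per outcome color
    ev1[t] = si2[t] - sc1[t];
    ev2[t] = si1[t] - sc2[t];

    if (model_code == 0) om += epsilon * (ev1[t] + ev2[t]);

    prev1 = ca1; prev2 = ca2;
    a1[t] = ca1; a2[t] = ca2; out1[t] = o1; out2[t] = o2;
    om_final = om;
  }

  List res = List::create(
    _["nll"] = nll,
    _["a1"] = a1, _["a2"] = a2,
    _["o1"] = out1, _["o2"] = out2,
    _["omega_final"] = om_final);
  if (model_code == 2) {
    res["joint"] = List::create(
      _["j"] = jact, _["v_chosen"] = vj_chosen, _["delta"] = dj,
      _["p_chosen"] = pj_chosen, _["p_all"] = pj,
      _["omega"] = omega, _["weight"] = weight);
  } else {
    res["latents"] = List::create(
      _["p1_d1"] = p1_d1, _["p1_d2"] = p1_d2,
      _["vc_d1_a1"] = vc_d1_a1, _["vc_d1_a2"] = vc_d1_a2,
      _["vc_d2_a1"] = vc_d2_a1, _["vc_d2_a2"] = vc_d2_a2,
      _["vi_d1_a1"] = vi_d1_a1, _["vi_d1_a2"] = vi_d1_a2,
      _["vi_d2_a1"] = vi_d2_a1, _["vi_d2_a2"] = vi_d2_a2,
      _["dc1"] = dc1, _["dc2"] = dc2, _["di1"] = di1, _["di2"] = di2,
      _["sc1"] = sc1, _["sc2"] = sc2, _["si1"] = si1, _["si2"] = si2,
      _["ev1"] = ev1, _["ev2"] = ev2,
      _["omega"] = omega, _["weight"] = weight);
  }
  return res;
}

// Bounded Gaussian random walk on integer points.
// scheme: 0 = negate the step when it would leave the bounds,
//         1 = reflect off the bounds, 2 = clip to the bounds
// [[Rcpp::export]]
NumericVector walk_cpp(int n, double sd, double lo, double hi, int scheme,
                       double start) {
  RNGScope rng;
  NumericVector x(n);
  double cur = start;
  x[0] = std::round(cur);
  for (int t = 1; t < n; ++t) {
    double z = norm_rand() * sd;
    double v = cur + z;
    if (scheme == 0) {
      if (v < lo || v > hi) v = cur - z;
      if (v < lo) v = lo;
      if (v > hi) v = hi;
    } else if (scheme == 1) {
      while (v < lo || v > hi) {
        if (v < lo) v = 2.0 * lo - v; else v = 2.0 * hi - v;
      }
    } else {
      if (v < lo) v = lo;
      if (v > hi) v = hi;
    }
    cur = v;
    x[t] = std::round(v);
    if (x[t] < lo) x[t] = lo;
    if (x[t] > hi) x[t] = hi;
  }
  return x;
}

// Signed supra-threshold clusters over a channels x time t-map.
// adj: per-channel 0-based neighbor index vectors; time adjacency is
// consecutive samples. Returns labels (0 = subthreshold) plus per-cluster
// mass (sum of t) and sign.
// [[Rcpp::export]]
List cluster_label_cpp(NumericMatrix tmap, double thresh, List adj) {
  const int C = tmap.nrow(), T = tmap.ncol();
  IntegerMatrix labels(C, T);
  std::vector<double> masses;
  std::vector<int> signs;
  std::vector<int> stack;
  stack.reserve(C * T);

  for (int c0 = 0; c0 < C; ++c0) {
    for (int t0 = 0; t0 < T; ++t0) {
      if (labels(c0, t0) != 0) continue;
      double v = tmap(c0, t0);
      if (std::fabs(v) < thresh) { labels(c0, t0) = -1; continue; }
      int sgn = v > 0 ? 1 : -1;
      int lab = (int)masses.size() + 1;
      double mass = 0.0;
      stack.clear();
      stack.push_back(c0 * T + t0);
      labels(c0, t0) = lab;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int c = idx / T, t = idx % T;
        mass += tmap(c, t);
        // time neighbors
        for (int dt = -1; dt <= 1; dt += 2) {
          int tt = t + dt;
          if (tt < 0 || tt >= T) continue;
          if (labels(c, tt) != 0) continue;
          double w = tmap(c, tt);
          if (std::fabs(w) >= thresh && ((w > 0) == (sgn > 0))) {
            labels(c, tt) = lab;
            stack.push_back(c * T + tt);
          }
        }
        // channel neighbors
        IntegerVector nb = adj[c];
        for (int k = 0; k < nb.size(); ++k) {
          int cc = nb[k];
          if (labels(cc, t) != 0) continue;
          double w = tmap(cc, t);
          if (std::fabs(w) >= thresh && ((w > 0) == (sgn > 0))) {
            labels(cc, t) = lab;
            stack.push_back(cc * T + t);
          }
        }
      }
      masses.push_back(mass);
      signs.push_back(sgn);
    }
  }
  // reset subthreshold marker to 0
  for (int i = 0; i < C * T; ++i) if (labels[i] == -1) labels[i] = 0;
  return List::create(_["labels"] = labels,
                      _["mass"] = wrap(masses),
                      _["sign"] = wrap(signs));
}

// Maximal absolute cluster mass for one t-map (permutation null helper).
// [[Rcpp::export]]
double cluster_max_mass_cpp(NumericMatrix tmap, double thresh, List adj) {
  List lab = cluster_label_cpp(tmap, thresh, adj);
  NumericVector mass = lab["mass"];
  double mx = 0.0;
  for (int i = 0; i < mass.size(); ++i) {
    double m = std::fabs(mass[i]);
    if (m > mx) mx = m;
  }
  return mx;
}
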