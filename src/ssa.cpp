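#include <Rcpp.h>
using namespace Rcpp;

// Gillespie dynamics of a single cell's oDNA population.
//
// State: (w_fused, w_single, m_fused, m_single) integer copy numbers.
// Reactions (rates):
//   replication, per molecule, rate r(N) = max(0, nu + (lam - nu)(1 - alpha N));
//     mutant pools scaled by (1 + delta); daughter molecule joins parent pool
//   autophagy of singletons: event rate nu * pool / n_d, removes
//     min(n_d, pool) same-type singleton molecules (per-molecule rate nu)
//   gene conversion, fused pool only, mass action in discordant pairs:
//     W->M at kappa (1 + eps) Wf Mf ; M->W at kappa (1 - eps) Wf Mf
//   fission (fused -> singleton) per molecule at rate_fission;
//   fusion (singleton -> fused) per molecule at rate_fusion.
// N = 0 is absorbing (all propensities vanish).

static inline double rep_rate(double N, double lam, double nu, double alpha) {
  double r = nu + (lam - nu) * (1.0 - alpha * N);
  return r > 0.0 ? r : 0.0;
}

struct SSAPar {
  double lam, nu, alpha, kappa, delta, eps, fis, fus;
  int nd;
};

static SSAPar unpack(const List& params) {
  SSAPar p;
  p.lam   = as<double>(params["lam"]);
  p.nu    = as<double>(params["nu"]);
  p.alpha = as<double>(params["alpha"]);
  p.kappa = as<double>(params["kappa"]);
  p.delta = as<double>(params["delta"]);
  p.eps   = as<double>(params["eps"]);
  p.nd    = as<int>(params["n_d"]);
  p.fis   = as<double>(params["rate_fission"]);
  p.fus   = as<double>(params["rate_fusion"]);
  return p;
}

// Simulate one trajectory, recording state at record_times (sorted,
// nonnegative). Returns integer matrix with one row per record time.
// [[Rcpp::export]]
IntegerMatrix ssa_run_cpp(IntegerVector init, List params,
                          NumericVector record_times) {
  SSAPar p = unpack(params);
  int wf = init[0], ws = init[1], mf = init[2], ms = init[3];
  const int ntime = record_times.size();
  IntegerMatrix out(ntime, 4);
  double t = 0.0;
  int idx = 0;
  double a[12];

  RNGScope scope;
  for (;;) {
    double N = wf + ws + mf + ms;
    double r = rep_rate(N, p.lam, p.nu, p.alpha);
    a[0] = r * wf;
    a[1] = r * ws;
    a[2] = r * (1.0 + p.delta) * mf;
    a[3] = r * (1.0 + p.delta) * ms;
    a[4] = p.nu * ws / p.nd;
    a[5] = p.nu * ms / p.nd;
    a[6] = p.kappa * (1.0 + p.eps) * (double)wf * (double)mf;
    a[7] = p.kappa * (1.0 - p.eps) * (double)wf * (double)mf;
    a[8] = p.fis * wf;
    a[9] = p.fis * mf;
    a[10] = p.fus * ws;
    a[11] = p.fus * ms;
    double atot = 0.0;
    for (int i = 0; i < 12; ++i) atot += a[i];

    if (atot <= 0.0 || N <= 0.0) {
      // absorbed (extinct or frozen): state constant for remaining records
      for (; idx < ntime; ++idx) {
        out(idx, 0) = wf; out(idx, 1) = ws; out(idx, 2) = mf; out(idx, 3) = ms;
      }
      break;
    }

    double dt = exp_rand() / atot;
    double tnext = t + dt;
    while (idx < ntime && record_times[idx] <= tnext) {
      out(idx, 0) = wf; out(idx, 1) = ws; out(idx, 2) = mf; out(idx, 3) = ms;
      ++idx;
    }
    if (idx >= ntime) break;
    t = tnext;

    double u = unif_rand() * atot;
    int ev = 0;
    double acc = a[0];
    while (u > acc && ev < 11) acc += a[++ev];
    switch (ev) {
      case 0: ++wf; break;
      case 1: ++ws; break;
      case 2: ++mf; break;
      case 3: ++ms; break;
      case 4: ws -= (ws < p.nd ? ws : p.nd); break;
      case 5: ms -= (ms < p.nd ? ms : p.nd); break;
      case 6: --wf; ++mf; break;
      case 7: --mf; ++wf; break;
      case 8: --wf; ++ws; break;
      case 9: --mf; ++ms; break;
      case 10: --ws; ++wf; break;
      case 11: --ms; ++mf; break;
    }
  }
  return out;
}

// Ensemble of independent trajectories; returns per-replicate heteroplasmy
// (NA where the cell went extinct) and copy number at each record time.
// [[Rcpp::export]]
List ssa_ensemble_cpp(IntegerVector init, List params,
                      NumericVector record_times, int n_reps) {
  const int ntime = record_times.size();
  NumericMatrix h(n_reps, ntime), n(n_reps, ntime);
  for (int rep = 0; rep < n_reps; ++rep) {
    IntegerMatrix tr = ssa_run_cpp(init, params, record_times);
    for (int j = 0; j < ntime; ++j) {
      double N = tr(j, 0) + tr(j, 1) + tr(j, 2) + tr(j, 3);
      n(rep, j) = N;
      h(rep, j) = (N > 0) ? (tr(j, 2) + tr(j, 3)) / N : NA_REAL;
    }
    if (rep % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["h"] = h, _["n"] = n);
}

// Short-range pairwise repulsion of points in the unit square with
// reflecting boundaries. Iterated displacement along inverse-distance
// forces with a decaying step, stopping when the largest per-point
// displacement falls below tol.
// [[Rcpp::export]]
NumericMatrix spatial_relax_cpp(NumericMatrix pos, double step, double tol,
                                int max_iter, double cutoff) {
  int npt = pos.nrow();
  NumericMatrix x = clone(pos);
  std::vector<double> fx(npt), fy(npt);
  double c2 = cutoff * cutoff;
  for (int it = 0; it < max_iter; ++it) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    for (int i = 0; i < npt; ++i) {
      for (int j = i + 1; j < npt; ++j) {
        double dx = x(i, 0) - x(j, 0), dy = x(i, 1) - x(j, 1);
        double d2 = dx * dx + dy * dy;
        if (d2 > c2 || d2 < 1e-12) continue;
        // force magnitude 1/d along the separation vector
        double w = 1.0 / d2;
        fx[i] += dx * w; fy[i] += dy * w;
        fx[j] -= dx * w; fy[j] -= dy * w;
      }
    }
    double eta = step / (1.0 + 0.02 * it);
    double maxdisp = 0.0;
    for (int i = 0; i < npt; ++i) {
      double ddx = eta * fx[i], ddy = eta * fy[i];
      // cap the per-iteration move to keep the relaxation stable
      double mag = std::sqrt(ddx * ddx + ddy * ddy);
      if (mag > 0.05) { ddx *= 0.05 / mag; ddy *= 0.05 / mag; mag = 0.05; }
      if (mag > maxdisp) maxdisp = mag;
      double nx = x(i, 0) + ddx, ny = x(i, 1) + ddy;
      while (nx < 0.0 || nx > 1.0) nx = (nx < 0.0) ? -nx : 2.0 - nx;
      while (ny < 0.0 || ny > 1.0) ny = (ny < 0.0) ? -ny : 2.0 - ny;
      x(i, 0) = nx; x(i, 1) = ny;
    }
    if (maxdisp < tol) break;
  }
  return x;
}
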