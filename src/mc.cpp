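#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Discrete worm-like chain with intrinsic curvature and breakable lateral
// springs. Geometry convention: node 0 at the origin, subunit s (1..N) points
// from node s-1 to node s with direction angle Theta_s = sum_{k<=s} theta_k
// (theta_1 is the clamp angle of subunit 1, held at 0 during sampling). The
// rigid neighbor runs parallel to x at y = -l0 so the preferred curl
// (+theta_D) peels away from it; the spring of subunit s attaches its distal
// node to the fixed point (s*b, -l0).

static inline double lat_energy(double l, double l0, double lmax, double ks) {
  double d = (l < lmax) ? (l - l0) : (lmax - l0);
  return 0.5 * ks * d * d;
}

static inline double bend_energy(double th, double pref, double kb) {
  return kb * (1.0 - std::cos(th - pref));
}

struct Chain {
  int N;
  double b, l0, lmax, ks, kb;
  std::vector<double> theta, pref, ang, x, y; // ang,x,y indexed 1..N (0 = base)

  Chain(int N_, double b_, double l0_, double lmax_, double ks_, double kb_,
        const std::vector<double>& theta0, const std::vector<double>& pref_)
    : N(N_), b(b_), l0(l0_), lmax(lmax_), ks(ks_), kb(kb_),
      theta(theta0), pref(pref_), ang(N_ + 1), x(N_ + 1), y(N_ + 1) {
    rebuild(1);
  }

  void rebuild(int from) {
    for (int s = from; s <= N; ++s) {
      ang[s] = (s == 1 ? 0.0 : ang[s - 1]) + theta[s - 1];
      x[s] = x[s - 1] + b * std::cos(ang[s]);
      y[s] = y[s - 1] + b * std::sin(ang[s]);
    }
  }

  double lat(int s) const { // lateral energy of subunit s
    double dx = x[s] - s * b, dy = y[s] + l0;
    return lat_energy(std::sqrt(dx * dx + dy * dy), l0, lmax, ks);
  }

  double total_energy() const {
    double e = 0.0;
    for (int s = 0; s < N; ++s) e += bend_energy(theta[s], pref[s], kb);
    for (int s = 1; s <= N; ++s) e += lat(s);
    return e;
  }

  double rx() const { return N * b - x[N]; }
};

// Single-protofilament Metropolis sampler with optional harmonic bias on Rx.
// Histogram over uniform bins [hist_lo, hist_lo + nbins*hist_w). Returns the
// post-burn-in histogram (split into two halves for convergence checks),
// moments of Rx, acceptance rate, a thinned trace, and the final angles.
// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(NumericVector theta_init, NumericVector pref,
                double b, double l0, double lmax, double ks, double kb,
                double beta, double n_steps, double burn_in,
                int record_every, double max_rot,
                double bias_k, double bias_center,
                double hist_lo, double hist_w, int nbins,
                int trace_every) {
  int N = theta_init.size();
  if (pref.size() != N) stop("theta/pref size mismatch");
  Chain ch(N, b, l0, lmax, ks, kb,
           as<std::vector<double>>(theta_init), as<std::vector<double>>(pref));

  long long nst = (long long)n_steps, nburn = (long long)burn_in;
  std::vector<double> cnt1(nbins, 0.0), cnt2(nbins, 0.0);
  double sum = 0.0, sumsq = 0.0;
  long long nsamp = 0, nacc = 0;
  double e_phys = ch.total_energy();

  long long ntr = trace_every > 0 ? nst / trace_every + 1 : 0;
  std::vector<double> tr_step, tr_rx, tr_e;
  std::vector<int> tr_acc;
  if (ntr > 0) { tr_step.reserve(ntr); tr_rx.reserve(ntr); tr_e.reserve(ntr); tr_acc.reserve(ntr); }

  std::vector<double> sx(N + 1), sy(N + 1), sang(N + 1);
  long long half = nburn + (nst - nburn) / 2;

  for (long long step = 1; step <= nst; ++step) {
    // pivot move: perturb one movable relative angle (clamp excluded)
    int j = 1 + (int)(unif_rand() * (N - 1)); // theta index 1..N-1 (0-based)
    if (j > N - 1) j = N - 1;
    double delta = (2.0 * unif_rand() - 1.0) * max_rot;

    double rx_old = ch.rx();
    double de = -bend_energy(ch.theta[j], ch.pref[j], kb);
    for (int s = j + 1; s <= N; ++s) {
      sx[s] = ch.x[s]; sy[s] = ch.y[s]; sang[s] = ch.ang[s];
      de -= ch.lat(s);
    }
    ch.theta[j] += delta;
    ch.rebuild(j + 1);
    de += bend_energy(ch.theta[j], ch.pref[j], kb);
    for (int s = j + 1; s <= N; ++s) de += ch.lat(s);

    double dw = 0.0;
    if (bias_k > 0.0) {
      double ro = rx_old - bias_center, rn = ch.rx() - bias_center;
      dw = 0.5 * bias_k * (rn * rn - ro * ro);
    }
    double darg = beta * (de + dw);
    bool accept = (darg <= 0.0) || (unif_rand() < std::exp(-darg));
    if (accept) {
      e_phys += de;
      ++nacc;
    } else {
      ch.theta[j] -= delta;
      for (int s = j + 1; s <= N; ++s) { ch.x[s] = sx[s]; ch.y[s] = sy[s]; ch.ang[s] = sang[s]; }
    }

    if ((step & 0xFFFFFLL) == 0) e_phys = ch.total_energy(); // kill fp drift

    if (step > nburn && step % record_every == 0) {
      double rx = ch.rx();
      int bin = (int)std::floor((rx - hist_lo) / hist_w);
      if (bin >= 0 && bin < nbins) {
        if (step <= half) cnt1[bin] += 1.0; else cnt2[bin] += 1.0;
      }
      sum += rx; sumsq += rx * rx; ++nsamp;
    }
    if (trace_every > 0 && step % trace_every == 0) {
      tr_step.push_back((double)step);
      tr_rx.push_back(ch.rx());
      tr_e.push_back(e_phys);
      tr_acc.push_back(accept ? 1 : 0);
    }
  }

  double mean = nsamp > 0 ? sum / nsamp : NA_REAL;
  double sd = nsamp > 1 ? std::sqrt(std::max(0.0, (sumsq - sum * sum / nsamp) / (nsamp - 1))) : NA_REAL;

  List out = List::create(
    _["counts1"] = wrap(cnt1), _["counts2"] = wrap(cnt2),
    _["n_samples"] = (double)nsamp, _["mean_rx"] = mean, _["sd_rx"] = sd,
    _["acc_rate"] = (double)nacc / (double)nst,
    _["theta_final"] = wrap(ch.theta),
    _["energy_final"] = ch.total_energy());
  if (trace_every > 0)
    out["trace"] = DataFrame::create(_["step"] = wrap(tr_step), _["Rx_nm"] = wrap(tr_rx),
                                     _["energy_kBT"] = wrap(tr_e), _["accepted"] = wrap(tr_acc));
  return out;
}

// Three protofilaments at 120 degrees, each confined to the plane spanned by
// the tube axis (x) and its own radial direction. Base nodes sit on a circle
// of radius rho = l0/sqrt(3) so the straight cross-section is an equilateral
// triangle of side l0. Lateral bond of subunit s on PF a connects to subunit
// s on PF a+1 (cyclic); with in-plane coordinates (x, v) and radial offsets
// r = rho + v, the 3-D distance obeys l^2 = dx^2 + r_a^2 + r_b^2 + r_a*r_b.
struct Chain3 {
  int N;
  double b, l0, lmax, ks, kb, rho;
  std::vector<std::vector<double>> theta, pref, ang, x, v;

  Chain3(int N_, double b_, double l0_, double lmax_, double ks_, double kb_,
         const NumericMatrix& theta0, const NumericMatrix& pref_)
    : N(N_), b(b_), l0(l0_), lmax(lmax_), ks(ks_), kb(kb_), rho(l0_ / std::sqrt(3.0)) {
    theta.assign(3, std::vector<double>(N));
    pref.assign(3, std::vector<double>(N));
    ang.assign(3, std::vector<double>(N + 1, 0.0));
    x.assign(3, std::vector<double>(N + 1, 0.0));
    v.assign(3, std::vector<double>(N + 1, 0.0));
    for (int a = 0; a < 3; ++a)
      for (int s = 0; s < N; ++s) { theta[a][s] = theta0(s, a); pref[a][s] = pref_(s, a); }
    for (int a = 0; a < 3; ++a) rebuild(a, 1);
  }

  void rebuild(int a, int from) {
    for (int s = from; s <= N; ++s) {
      ang[a][s] = (s == 1 ? 0.0 : ang[a][s - 1]) + theta[a][s - 1];
      x[a][s] = x[a][s - 1] + b * std::cos(ang[a][s]);
      v[a][s] = v[a][s - 1] + b * std::sin(ang[a][s]);
    }
  }

  double ldist(int a, int s) const { // distance PF a <-> PF (a+1)%3, subunit s
    int c = (a + 1) % 3;
    double dx = x[a][s] - x[c][s];
    double ra = rho + v[a][s], rb = rho + v[c][s];
    return std::sqrt(dx * dx + ra * ra + rb * rb + ra * rb);
  }

  double lat(int a, int s) const { return lat_energy(ldist(a, s), l0, lmax, ks); }

  double total_energy() const {
    double e = 0.0;
    for (int a = 0; a < 3; ++a) {
      for (int s = 0; s < N; ++s) e += bend_energy(theta[a][s], pref[a][s], kb);
      for (int s = 1; s <= N; ++s) e += lat(a, s);
    }
    return e;
  }

  double rx(int a) const { return N * b - x[a][N]; }
};

// [[Rcpp::export(name = ".mc3_run_cpp")]]
List mc3_run_cpp(NumericMatrix theta_init, NumericMatrix pref,
                 double b, double l0, double lmax, double ks, double kb,
                 double beta, double n_steps, double burn_in,
                 int record_every, double max_rot, LogicalVector bendable,
                 double hist_lo, double hist_w, int nbins) {
  int N = theta_init.nrow();
  Chain3 ch(N, b, l0, lmax, ks, kb, theta_init, pref);
  std::vector<int> mv;
  for (int a = 0; a < 3; ++a) if (bendable[a]) mv.push_back(a);
  if (mv.empty()) stop("at least one protofilament must be bendable");

  long long nst = (long long)n_steps, nburn = (long long)burn_in;
  NumericMatrix counts(nbins, 3);
  std::vector<double> sum(3, 0.0), sumsq(3, 0.0);
  long long nsamp = 0, nacc = 0;
  std::vector<double> sxx(N + 1), svv(N + 1), sa(N + 1);

  for (long long step = 1; step <= nst; ++step) {
    int a = mv[(int)(unif_rand() * mv.size()) % mv.size()];
    int j = 1 + (int)(unif_rand() * (N - 1));
    if (j > N - 1) j = N - 1;
    double delta = (2.0 * unif_rand() - 1.0) * max_rot;
    int prev = (a + 2) % 3;

    double de = -bend_energy(ch.theta[a][j], ch.pref[a][j], kb);
    for (int s = j + 1; s <= N; ++s) {
      sxx[s] = ch.x[a][s]; svv[s] = ch.v[a][s]; sa[s] = ch.ang[a][s];
      de -= ch.lat(a, s) + ch.lat(prev, s);
    }
    ch.theta[a][j] += delta;
    ch.rebuild(a, j + 1);
    de += bend_energy(ch.theta[a][j], ch.pref[a][j], kb);
    for (int s = j + 1; s <= N; ++s) de += ch.lat(a, s) + ch.lat(prev, s);

    double darg = beta * de;
    bool accept = (darg <= 0.0) || (unif_rand() < std::exp(-darg));
    if (accept) ++nacc;
    else {
      ch.theta[a][j] -= delta;
      for (int s = j + 1; s <= N; ++s) { ch.x[a][s] = sxx[s]; ch.v[a][s] = svv[s]; ch.ang[a][s] = sa[s]; }
    }

    if (step > nburn && step % record_every == 0) {
      ++nsamp;
      for (int p = 0; p < 3; ++p) {
        double rx = ch.rx(p);
        sum[p] += rx; sumsq[p] += rx * rx;
        int bin = (int)std::floor((rx - hist_lo) / hist_w);
        if (bin >= 0 && bin < nbins) counts(bin, p) += 1.0;
      }
    }
  }

  NumericVector mean(3), sd(3);
  for (int p = 0; p < 3; ++p) {
    mean[p] = nsamp > 0 ? sum[p] / nsamp : NA_REAL;
    sd[p] = nsamp > 1 ? std::sqrt(std::max(0.0, (sumsq[p] - sum[p] * sum[p] / nsamp) / (nsamp - 1))) : NA_REAL;
  }
  NumericMatrix theta_final(N, 3);
  for (int a = 0; a < 3; ++a) for (int s = 0; s < N; ++s) theta_final(s, a) = ch.theta[a][s];
  return List::create(_["counts"] = counts, _["n_samples"] = (double)nsamp,
                      _["mean_rx"] = mean, _["sd_rx"] = sd,
                      _["acc_rate"] = (double)nacc / (double)nst,
                      _["theta_final"] = theta_final,
                      _["energy_final"] = ch.total_energy());
}

// Overdamped Langevin dynamics of the tip coordinate on a tabulated force
// field (force = -dF/dRx in kBT/nm, linearly interpolated on a uniform grid),
// with reflecting boundaries and optional Poisson subunit dissociation gated
// at rx > rx_gate. On each dissociation the tip is remapped through the
// zero-temperature peel geometry (tables remap_from -> remap_to) and the
// observable length drops by b. Integration stops early if lobs reaches 0.
// [[Rcpp::export(name = ".langevin_cpp")]]
List langevin_cpp(double grid_lo, double grid_dx, NumericVector force,
                  double D, double dt, double n_steps, int record_every,
                  double x0, double xmin, double xmax,
                  double koff, double rx_gate, double b,
                  NumericVector remap_from, NumericVector remap_to,
                  double L0, double l_d) {
  int ng = force.size();
  long long nst = (long long)n_steps;
  double x = x0, sig = std::sqrt(2.0 * D * dt);
  long long nd = 0;
  double expose_left = (koff > 0.0) ? exp_rand() / koff : R_PosInf;

  long long nrec = nst / record_every + 1;
  std::vector<double> rt, rrx, rnd, rlo;
  rt.reserve(nrec); rrx.reserve(nrec); rnd.reserve(nrec); rlo.reserve(nrec);
  double sum_rx = 0.0, sumsq_rx = 0.0, max_rx = x;
  long long nsteps_done = 0;

  auto record = [&](double t) {
    rt.push_back(t); rrx.push_back(x); rnd.push_back((double)nd);
    rlo.push_back(L0 - x * l_d - b * (double)nd);
  };
  record(0.0);

  for (long long step = 1; step <= nst; ++step) {
    double u = (x - grid_lo) / grid_dx;
    int i = (int)std::floor(u);
    if (i < 0) i = 0;
    if (i > ng - 2) i = ng - 2;
    double w = u - i;
    double f = force[i] * (1.0 - w) + force[i + 1] * w;
    x += D * f * dt + sig * norm_rand();
    // reflecting boundaries
    for (int it = 0; it < 100 && (x < xmin || x > xmax); ++it) {
      if (x < xmin) x = 2.0 * xmin - x;
      if (x > xmax) x = 2.0 * xmax - x;
    }

    if (koff > 0.0 && x > rx_gate) {
      expose_left -= dt;
      if (expose_left <= 0.0) {
        ++nd;
        // remap tip through the shortened peel geometry
        int m = remap_from.size();
        if (m > 1) {
          if (x <= remap_from[0]) x = remap_to[0];
          else if (x >= remap_from[m - 1]) x = remap_to[m - 1];
          else {
            int lo = 0, hi = m - 1;
            while (hi - lo > 1) { int mid = (lo + hi) / 2; if (remap_from[mid] <= x) lo = mid; else hi = mid; }
            double ww = (x - remap_from[lo]) / (remap_from[hi] - remap_from[lo]);
            x = remap_to[lo] * (1.0 - ww) + remap_to[hi] * ww;
          }
          if (x < xmin) x = xmin;
        }
        expose_left = exp_rand() / koff;
      }
    }

    sum_rx += x; sumsq_rx += x * x;
    if (x > max_rx) max_rx = x;
    ++nsteps_done;
    if (step % record_every == 0) record(step * dt);
    if (L0 - x * l_d - b * (double)nd <= 0.0) { record(step * dt); break; }
  }

  double mrx = nsteps_done > 0 ? sum_rx / nsteps_done : NA_REAL;
  double sdrx = nsteps_done > 1 ? std::sqrt(std::max(0.0, (sumsq_rx - sum_rx * sum_rx / nsteps_done) / (nsteps_done - 1))) : NA_REAL;
  return List::create(
    _["trajectory"] = DataFrame::create(_["t_s"] = wrap(rt), _["Rx_nm"] = wrap(rrx),
                                        _["Nd"] = wrap(rnd), _["Lobs_nm"] = wrap(rlo)),
    _["mean_rx"] = mrx, _["sd_rx"] = sdrx, _["max_rx"] = max_rx,
    _["nd_final"] = (double)nd, _["n_steps_done"] = (double)nsteps_done);
}

// First-passage time of a single Langevin walker from x0 to the absorbing
// boundary at xabs (reflecting at xmin). Used as a simulation cross-check of
// the mean first-passage-time quadrature.
// [[Rcpp::export(name = ".langevin_fpt_cpp")]]
double langevin_fpt_cpp(double grid_lo, double grid_dx, NumericVector force,
                        double D, double dt, double x0, double xmin, double xabs,
                        double t_max) {
  int ng = force.size();
  double x = x0, sig = std::sqrt(2.0 * D * dt), t = 0.0;
  while (t < t_max) {
    double u = (x - grid_lo) / grid_dx;
    int i = (int)std::floor(u);
    if (i < 0) i = 0;
    if (i > ng - 2) i = ng - 2;
    double w = u - i;
    double f = force[i] * (1.0 - w) + force[i + 1] * w;
    x += D * f * dt + sig * norm_rand();
    if (x < xmin) x = 2.0 * xmin - x;
    t += dt;
    if (x >= xabs) return t;
  }
  return NA_REAL;
}
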