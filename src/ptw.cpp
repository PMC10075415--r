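#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// wrap an angle to (-pi, pi]
static inline double wrap_pi(double a) {
  const double two_pi = 2.0 * M_PI;
  double w = (a + M_PI) - two_pi * std::floor((a + M_PI) / two_pi);
  if (w <= 0.0) w += two_pi;
  return w - M_PI;
}

// Uniform-cell spatial index over flower positions; cell size >= perception
// distance so a 3x3 neighbourhood query is exhaustive.
struct FlowerIndex {
  int nf, gnx, gny;
  double x0, y0, cell, r2;
  std::vector<int> start, items;
  const NumericMatrix& fl;

  FlowerIndex(const NumericMatrix& flowers, double perc)
    : nf(flowers.nrow()), fl(flowers) {
    r2 = perc * perc;
    gnx = gny = 0;
    x0 = y0 = 0.0;
    cell = std::max(perc, 1e-9);
    if (nf == 0) return;
    double x1 = fl(0, 0), y1 = fl(0, 1);
    x0 = x1; y0 = y1;
    for (int i = 1; i < nf; ++i) {
      x0 = std::min(x0, fl(i, 0)); x1 = std::max(x1, fl(i, 0));
      y0 = std::min(y0, fl(i, 1)); y1 = std::max(y1, fl(i, 1));
    }
    gnx = (int)std::floor((x1 - x0) / cell) + 1;
    gny = (int)std::floor((y1 - y0) / cell) + 1;
    std::vector<int> counts(gnx * gny + 1, 0), ci(nf);
    for (int i = 0; i < nf; ++i) {
      int cx = (int)((fl(i, 0) - x0) / cell); if (cx >= gnx) cx = gnx - 1;
      int cy = (int)((fl(i, 1) - y0) / cell); if (cy >= gny) cy = gny - 1;
      ci[i] = cy * gnx + cx;
      counts[ci[i] + 1]++;
    }
    for (size_t k = 1; k < counts.size(); ++k) counts[k] += counts[k - 1];
    start = counts;
    items.resize(nf);
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (int i = 0; i < nf; ++i) items[fill[ci[i]]++] = i;
  }
};

// One Persistent-Turning-Walker integration run, at step dt:
//   M1 position <- position + v(theta_old) dt
//   M2 theta    <- theta + omega_old dt
//   M3 velocity from new theta (applied at the next M1)
//   M4 omega    <- omega a + omega_target (1 - a) + s N(0,1),
//       a = exp(-gamma dt), s^2 = sigma^2 (1 - exp(-2 gamma dt)) / (2 gamma)
// Exploration phase: omega_target = 0; return phase (clock >= tau):
// omega_target = eta_star * phi with phi the signed angle from the heading to
// the nest direction.  single_loop: stop at first return-phase nest entry or
// censor at max_loop_duration.  Trip mode: on nest entry reset to a fresh
// loop (uniform heading, omega = 0, fresh tau) and continue to `duration`.
// policy: 0 = record discoveries but never truncate; 1 = truncate at the
// f_stop-th discovery; 2 = depletion (truncate at the first non-depleted
// discovery or after f_depleted distinct depleted-flower encounters).
// [[Rcpp::export]]
List cpp_ptw_simulate(double gamma, double sigma, double eta_star,
                      double p_return, double speed, double dt,
                      double nest_radius, double max_loop_duration,
                      NumericVector nest, double duration, bool single_loop,
                      int record_every, NumericMatrix flowers,
                      double perc_dist, int policy, int f_stop,
                      double f_depleted, LogicalVector depleted) {
  const double a = std::exp(-gamma * dt);
  const double s = sigma * std::sqrt((1.0 - std::exp(-2.0 * gamma * dt)) /
                                     (2.0 * gamma));
  const double nx = nest[0], ny = nest[1];
  const double nr2 = nest_radius * nest_radius;
  const double mean_tau = 1.0 / p_return;

  FlowerIndex fidx(flowers, perc_dist);
  const int nf = fidx.nf;
  const bool have_dep = depleted.size() == nf && nf > 0;
  std::vector<char> seen(nf, 0);

  double x = nx, y = ny;
  double theta = R::runif(-M_PI, M_PI);
  double omega = 0.0;
  int phase = 0;
  double tau = R::rexp(mean_tau);
  double clock = 0.0;

  const long nsteps =
      (long)std::llround((single_loop ? max_loop_duration : duration) / dt);
  if (record_every < 1) record_every = 1;

  std::vector<double> rt, rx, ry;
  std::vector<int> rphase;
  size_t cap = (size_t)(nsteps / record_every) + 4;
  rt.reserve(cap); rx.reserve(cap); ry.reserve(cap); rphase.reserve(cap);
  rt.push_back(0.0); rx.push_back(x); ry.push_back(y); rphase.push_back(0);

  std::vector<int> disc_ids;
  std::vector<double> disc_t, loop_entry_t;
  int n_dep_seen = 0;
  bool stopped = false, disc_trunc = false;
  double end_t = 0.0;

  for (long i = 1; i <= nsteps; ++i) {
    x += speed * std::cos(theta) * dt;
    y += speed * std::sin(theta) * dt;
    theta = wrap_pi(theta + omega * dt);
    clock += dt;
    if (phase == 0 && clock >= tau) phase = 1;
    double omst = 0.0;
    if (phase == 1) {
      double hx = nx - x, hy = ny - y;
      if (hx != 0.0 || hy != 0.0)
        omst = eta_star * wrap_pi(std::atan2(hy, hx) - theta);
    }
    omega = omega * a + omst * (1.0 - a) + s * norm_rand();
    double t = i * dt;

    bool terminate = false;
    if (nf > 0) {
      int cx = (int)std::floor((x - fidx.x0) / fidx.cell);
      int cy = (int)std::floor((y - fidx.y0) / fidx.cell);
      for (int dyc = -1; dyc <= 1 && !terminate; ++dyc) {
        int gy = cy + dyc;
        if (gy < 0 || gy >= fidx.gny) continue;
        for (int dxc = -1; dxc <= 1 && !terminate; ++dxc) {
          int gx = cx + dxc;
          if (gx < 0 || gx >= fidx.gnx) continue;
          int c = gy * fidx.gnx + gx;
          for (int k = fidx.start[c]; k < fidx.start[c + 1]; ++k) {
            int fi = fidx.items[k];
            if (seen[fi]) continue;
            double ddx = flowers(fi, 0) - x, ddy = flowers(fi, 1) - y;
            if (ddx * ddx + ddy * ddy <= fidx.r2) {
              seen[fi] = 1;
              disc_ids.push_back(fi + 1);
              disc_t.push_back(t);
              bool dep = have_dep && depleted[fi];
              if (dep) n_dep_seen++;
              if (policy == 1) {
                if ((int)disc_ids.size() >= f_stop) {
                  terminate = disc_trunc = true; break;
                }
              } else if (policy == 2) {
                if (!dep || (double)n_dep_seen >= f_depleted) {
                  terminate = disc_trunc = true; break;
                }
              }
            }
          }
        }
      }
    }

    bool reset = false;
    if (!terminate && phase == 1) {
      double ddx = x - nx, ddy = y - ny;
      if (ddx * ddx + ddy * ddy <= nr2) {
        if (single_loop) terminate = true;
        else { reset = true; loop_entry_t.push_back(t); }
      }
    }

    if (i % record_every == 0 || terminate || i == nsteps) {
      rt.push_back(t); rx.push_back(x); ry.push_back(y);
      rphase.push_back(phase);
    }
    if (reset) {
      phase = 0; omega = 0.0; clock = 0.0;
      theta = R::runif(-M_PI, M_PI);
      tau = R::rexp(mean_tau);
    }
    end_t = t;
    if (terminate) { stopped = true; break; }
  }

  int n = (int)rt.size();
  NumericMatrix track(n, 3);
  for (int i = 0; i < n; ++i) {
    track(i, 0) = rt[i]; track(i, 1) = rx[i]; track(i, 2) = ry[i];
  }
  colnames(track) = CharacterVector::create("t", "x", "y");

  return List::create(
      _["track"] = track, _["phase"] = wrap(rphase),
      _["censored"] = single_loop && !stopped,
      _["switch_time"] = single_loop ? tau : NA_REAL,
      _["loop_entries"] = wrap(loop_entry_t),
      _["discovered"] = wrap(disc_ids), _["discovery_times"] = wrap(disc_t),
      _["n_depleted_encounters"] = n_dep_seen,
      _["truncated"] = disc_trunc, _["end_time"] = end_t);
}

// Mean squared distance to the nest of the loop-chained process, accumulated
// every `sample_every` steps over n_loops loops (censored loops contribute
// their samples up to the censoring time and are counted).
// [[Rcpp::export]]
List cpp_msd(double gamma, double sigma, double eta_star, double p_return,
             double speed, double dt, double nest_radius,
             double max_loop_duration, int n_loops, int sample_every) {
  const double a = std::exp(-gamma * dt);
  const double s = sigma * std::sqrt((1.0 - std::exp(-2.0 * gamma * dt)) /
                                     (2.0 * gamma));
  const double nr2 = nest_radius * nest_radius;
  const double mean_tau = 1.0 / p_return;
  const long nsteps = (long)std::llround(max_loop_duration / dt);
  if (sample_every < 1) sample_every = 1;

  double acc = 0.0;
  long cnt = 0;
  int n_censored = 0;

  for (int l = 0; l < n_loops; ++l) {
    double x = 0.0, y = 0.0;
    double theta = R::runif(-M_PI, M_PI);
    double omega = 0.0;
    int phase = 0;
    double tau = R::rexp(mean_tau);
    double clock = 0.0;
    bool done = false;
    for (long i = 1; i <= nsteps; ++i) {
      x += speed * std::cos(theta) * dt;
      y += speed * std::sin(theta) * dt;
      theta = wrap_pi(theta + omega * dt);
      clock += dt;
      if (phase == 0 && clock >= tau) phase = 1;
      double omst = 0.0;
      double d2 = x * x + y * y;
      if (phase == 1 && d2 > 0.0)
        omst = eta_star * wrap_pi(std::atan2(-y, -x) - theta);
      omega = omega * a + omst * (1.0 - a) + s * norm_rand();
      if (i % sample_every == 0) { acc += d2; cnt++; }
      if (phase == 1 && d2 <= nr2) { done = true; break; }
    }
    if (!done) n_censored++;
  }
  return List::create(_["msd"] = cnt > 0 ? acc / cnt : NA_REAL,
                      _["n_samples"] = (double)cnt,
                      _["n_censored"] = n_censored);
}
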