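#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// All lattice models use periodic boundaries and unit spacing; randomness
// is drawn from R's RNG so results are reproducible from set.seed().

static inline int wrap(int i, int n) { return (i + n) % n; }

// 5-point periodic Laplacian of column-major n x n field at (i, j)
static inline double lap(const std::vector<double>& f, int i, int j, int n) {
  return f[wrap(i - 1, n) + j * n] + f[wrap(i + 1, n) + j * n] +
         f[i + wrap(j - 1, n) * n] + f[i + wrap(j + 1, n) * n] -
         4.0 * f[i + j * n];
}

// [[Rcpp::export]]
List turing_sim_cpp(NumericMatrix u0, NumericMatrix v0,
                    double fu, double fv, double gu, double gv, double q,
                    double Du, double Dv, double dt, int steps,
                    int check_every, double tol) {
  const int n = u0.nrow();
  std::vector<double> u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
  std::vector<double> un(u.size()), vn(v.size());
  std::vector<double> uref(u);
  std::vector<int> ip(n), im(n);
  for (int i = 0; i < n; ++i) { ip[i] = wrap(i + 1, n); im[i] = wrap(i - 1, n); }
  int done = 0;
  const double* __restrict pu = u.data();
  const double* __restrict pv = v.data();
  double* __restrict qu = un.data();
  double* __restrict qv = vn.data();
  for (int s = 0; s < steps; ++s) {
    for (int j = 0; j < n; ++j) {
      const int jc = j * n, jp = ip[j] * n, jm = im[j] * n;
      // periodic end cells of the column
      for (int i : {0, n - 1}) {
        const int id = i + jc;
        const double uu = pu[id], vv = pv[id];
        const double lu = pu[im[i] + jc] + pu[ip[i] + jc] + pu[i + jm] +
                          pu[i + jp] - 4.0 * uu;
        const double lv = pv[im[i] + jc] + pv[ip[i] + jc] + pv[i + jm] +
                          pv[i + jp] - 4.0 * vv;
        qu[id] = uu + dt * (fu * uu - fv * vv + q * uu * uu - uu * uu * uu + Du * lu);
        qv[id] = vv + dt * (gu * uu - gv * vv + Dv * lv);
      }
      // contiguous interior (vectorizable)
      for (int i = 1; i < n - 1; ++i) {
        const int id = i + jc;
        const double uu = pu[id], vv = pv[id];
        const double lu = pu[id - 1] + pu[id + 1] + pu[i + jm] + pu[i + jp] - 4.0 * uu;
        const double lv = pv[id - 1] + pv[id + 1] + pv[i + jm] + pv[i + jp] - 4.0 * vv;
        qu[id] = uu + dt * (fu * uu - fv * vv + q * uu * uu - uu * uu * uu + Du * lu);
        qv[id] = vv + dt * (gu * uu - gv * vv + Dv * lv);
      }
    }
    u.swap(un);
    v.swap(vn);
    pu = u.data(); pv = v.data(); qu = un.data(); qv = vn.data();
    ++done;
    if ((s + 1) % check_every == 0 || s == steps - 1) {
      double num = 0, den = 0;
      bool finite = true;
      for (size_t id = 0; id < u.size(); ++id) {
        if (!std::isfinite(u[id]) || !std::isfinite(v[id])) { finite = false; break; }
        const double d = u[id] - uref[id];
        num += d * d;
        den += u[id] * u[id];
      }
      if (!finite) stop("Turing integration diverged at step %d", s + 1);
      uref = u;
      if (s + 1 < steps && den > 0 && std::sqrt(num / den) < tol) break;
    }
  }
  NumericMatrix uo(n, n), vo(n, n);
  std::copy(u.begin(), u.end(), uo.begin());
  std::copy(v.begin(), v.end(), vo.begin());
  return List::create(_["u"] = uo, _["v"] = vo, _["steps_run"] = done);
}

// [[Rcpp::export]]
List gray_scott_cpp(NumericMatrix u0, NumericMatrix v0,
                    double F, double k, double Du, double Dv,
                    double dt, IntegerVector capture_steps) {
  const int n = u0.nrow();
  std::vector<double> u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
  std::vector<double> un(u.size()), vn(v.size());
  const int ncap = capture_steps.size();
  List out(ncap);
  int next = 0;
  const int total = ncap > 0 ? capture_steps[ncap - 1] : 0;
  // capture at step 0 if requested
  while (next < ncap && capture_steps[next] == 0) {
    NumericMatrix uo(n, n);
    std::copy(u.begin(), u.end(), uo.begin());
    out[next++] = uo;
  }
  for (int s = 1; s <= total; ++s) {
    for (int j = 0; j < n; ++j) {
      for (int i = 0; i < n; ++i) {
        const int id = i + j * n;
        const double uu = u[id], vv = v[id], uvv = uu * vv * vv;
        un[id] = uu + dt * (Du * lap(u, i, j, n) - uvv + F * (1.0 - uu));
        vn[id] = vv + dt * (Dv * lap(v, i, j, n) + uvv - (F + k) * vv);
      }
    }
    u.swap(un);
    v.swap(vn);
    if (s % 1000 == 0) {
      for (size_t id = 0; id < u.size(); ++id)
        if (!std::isfinite(u[id])) stop("Gray-Scott integration diverged at step %d", s);
    }
    while (next < ncap && capture_steps[next] == s) {
      for (size_t id = 0; id < u.size(); ++id)
        if (!std::isfinite(u[id])) stop("Gray-Scott integration diverged at step %d", s);
      NumericMatrix uo(n, n);
      std::copy(u.begin(), u.end(), uo.begin());
      out[next++] = uo;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix edwards_wilkinson_cpp(NumericMatrix h0, double nu,
                                    double noise_amp, double dt, int steps) {
  const int n = h0.nrow();
  std::vector<double> h(h0.begin(), h0.end()), hn(h.size());
  const double sq = noise_amp * std::sqrt(dt);
  for (int s = 0; s < steps; ++s) {
    for (int j = 0; j < n; ++j) {
      for (int i = 0; i < n; ++i) {
        const int id = i + j * n;
        hn[id] = h[id] + dt * nu * lap(h, i, j, n) + sq * norm_rand();
      }
    }
    h.swap(hn);
  }
  NumericMatrix out(n, n);
  std::copy(h.begin(), h.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
List eden_cpp(int n_events, int size, int si, int sj) {
  // si, sj are 0-based seed coordinates
  std::vector<int> occ(size * size, 0), inper(size * size, 0);
  std::vector<int> per;  // linear indices of perimeter (empty, cluster-adjacent)
  const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
  occ[si + sj * size] = 1;
  bool truncated = false;
  int done = 0;
  auto add_neighbors = [&](int ci, int cj) {
    for (int d = 0; d < 4; ++d) {
      int ni = ci + di[d], nj = cj + dj[d];
      if (ni < 0 || ni >= size || nj < 0 || nj >= size) { truncated = true; continue; }
      int id = ni + nj * size;
      if (!occ[id] && !inper[id]) { inper[id] = 1; per.push_back(id); }
    }
  };
  add_neighbors(si, sj);
  for (int e = 0; e < n_events; ++e) {
    if (per.empty() || truncated) { truncated = true; break; }
    int pick = (int)(unif_rand() * per.size());
    if (pick >= (int)per.size()) pick = per.size() - 1;
    int id = per[pick];
    per[pick] = per.back();
    per.pop_back();
    inper[id] = 0;
    occ[id] = 1;
    ++done;
    add_neighbors(id % size, id / size);
  }
  NumericMatrix out(size, size);
  for (int id = 0; id < size * size; ++id) out[id] = occ[id];
  return List::create(_["grid"] = out, _["truncated"] = truncated,
                      _["events_done"] = done);
}

// [[Rcpp::export]]
List dla_cpp(int n_particles, int size, int si, int sj,
             double launch_pad, double kill_factor, int max_steps_per_walker) {
  std::vector<int> occ(size * size, 0);
  occ[si + sj * size] = 1;
  double rmax = 0.0;
  const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
  bool truncated = false;
  int done = 0;
  auto adjacent = [&](int i, int j) {
    for (int d = 0; d < 4; ++d) {
      int ni = i + di[d], nj = j + dj[d];
      if (ni < 0 || ni >= size || nj < 0 || nj >= size) continue;
      if (occ[ni + nj * size]) return true;
    }
    return false;
  };
  for (int p = 0; p < n_particles; ++p) {
    double rl = rmax + launch_pad;
    double rk = kill_factor * rl;
    if (rl >= size / 2.0 - 1.0) { truncated = true; break; }
    bool stuck = false;
    int guard = 0;
    while (!stuck && guard < 1000) {
      ++guard;
      double ang = 2.0 * M_PI * unif_rand();
      int i = si + (int)std::lround(rl * std::cos(ang));
      int j = sj + (int)std::lround(rl * std::sin(ang));
      for (int s = 0; s < max_steps_per_walker; ++s) {
        int d = (int)(unif_rand() * 4.0);
        if (d > 3) d = 3;
        i += di[d];
        j += dj[d];
        double dx = i - si, dy = j - sj;
        if (std::sqrt(dx * dx + dy * dy) > rk) break;  // kill, relaunch
        if (i < 1 || i >= size - 1 || j < 1 || j >= size - 1) break;
        if (adjacent(i, j)) {
          occ[i + j * size] = 1;
          double r = std::sqrt(dx * dx + dy * dy);
          if (r > rmax) rmax = r;
          stuck = true;
          ++done;
          break;
        }
      }
    }
    if (!stuck) { truncated = true; break; }
  }
  NumericMatrix out(size, size);
  for (int id = 0; id < size * size; ++id) out[id] = occ[id];
  return List::create(_["grid"] = out, _["truncated"] = truncated,
                      _["particles_done"] = done);
}

// Kobayashi-style anisotropic phase-field solidification: phase p coupled
// to a temperature field T, with anisotropic interface energy
// eps(theta) = eps_bar * (1 + delta * cos(j_mode * (theta - theta0))).
// [[Rcpp::export]]
List phase_field_cpp(NumericMatrix p0, NumericMatrix T0,
                     double eps_bar, double delta, int j_mode, double theta0,
                     double tau, double alpha, double gamma_c, double Teq,
                     double K, double dx, double dt, int steps) {
  const int n = p0.nrow();
  std::vector<double> p(p0.begin(), p0.end()), T(T0.begin(), T0.end());
  std::vector<double> pn(p.size()), Tn(T.size());
  std::vector<double> eps(p.size()), epsp(p.size()), px(p.size()), py(p.size());
  const double idx2 = 1.0 / (2.0 * dx), idxx = 1.0 / (dx * dx);
  for (int s = 0; s < steps; ++s) {
    for (int j = 0; j < n; ++j) {
      for (int i = 0; i < n; ++i) {
        const int id = i + j * n;
        const double gx = (p[wrap(i + 1, n) + j * n] - p[wrap(i - 1, n) + j * n]) * idx2;
        const double gy = (p[i + wrap(j + 1, n) * n] - p[i + wrap(j - 1, n) * n]) * idx2;
        px[id] = gx;
        py[id] = gy;
        const double th = std::atan2(gy, gx);
        eps[id] = eps_bar * (1.0 + delta * std::cos(j_mode * (th - theta0)));
        epsp[id] = -eps_bar * delta * j_mode * std::sin(j_mode * (th - theta0));
      }
    }
    for (int j = 0; j < n; ++j) {
      for (int i = 0; i < n; ++i) {
        const int id = i + j * n;
        const int ie = wrap(i + 1, n) + j * n, iw = wrap(i - 1, n) + j * n;
        const int jn_ = i + wrap(j + 1, n) * n, js = i + wrap(j - 1, n) * n;
        // anisotropic corrections: -d/dx(eps*eps'*py) + d/dy(eps*eps'*px)
        const double t1 = -((eps[ie] * epsp[ie] * py[ie]) -
                            (eps[iw] * epsp[iw] * py[iw])) * idx2;
        const double t2 = ((eps[jn_] * epsp[jn_] * px[jn_]) -
                           (eps[js] * epsp[js] * px[js])) * idx2;
        // div(eps^2 grad p) with face-averaged eps^2
        const double e2 = eps[id] * eps[id];
        const double e2e = 0.5 * (e2 + eps[ie] * eps[ie]);
        const double e2w = 0.5 * (e2 + eps[iw] * eps[iw]);
        const double e2n = 0.5 * (e2 + eps[jn_] * eps[jn_]);
        const double e2s = 0.5 * (e2 + eps[js] * eps[js]);
        const double divg = (e2e * (p[ie] - p[id]) - e2w * (p[id] - p[iw]) +
                             e2n * (p[jn_] - p[id]) - e2s * (p[id] - p[js])) * idxx;
        const double m = (alpha / M_PI) * std::atan(gamma_c * (Teq - T[id]));
        const double pp = p[id];
        double dpdt = (t1 + t2 + divg + pp * (1.0 - pp) * (pp - 0.5 + m)) / tau;
        pn[id] = pp + dt * dpdt;
        if (pn[id] < 0.0) pn[id] = 0.0;
        if (pn[id] > 1.0) pn[id] = 1.0;
        Tn[id] = T[id] + dt * (lap(T, i, j, n) * idxx) + K * (pn[id] - pp);
      }
    }
    p.swap(pn);
    T.swap(Tn);
    if ((s + 1) % 500 == 0) {
      for (size_t id = 0; id < p.size(); ++id)
        if (!std::isfinite(p[id]) || !std::isfinite(T[id]))
          stop("phase-field integration diverged at step %d", s + 1);
    }
  }
  NumericMatrix po(n, n), To(n, n);
  std::copy(p.begin(), p.end(), po.begin());
  std::copy(T.begin(), T.end(), To.begin());
  return List::create(_["phase"] = po, _["temperature"] = To);
}
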