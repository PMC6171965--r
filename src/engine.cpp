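// Per-step engine for the 2D actomyosin cortex model.
//
// The update order within one step is fixed and documented:
//   (1) free-motor (and free cross-linker) diffusion
//   (2) motor search/bind      (3) cross-linker search/bind
//   (4) motor walk             (5) release checks
//   (6) force accumulation     (7) overdamped filament update
//   (8) filament turnover      (9) boundary enforcement
//   (10) scheduled parameter switches   (11) recording
//
// Randomness comes from R's RNG stream (unif_rand), so trajectories are
// bit-reproducible given set.seed(). Draw-order contract: a Bernoulli draw is
// consumed only when 0 < rate*dt < 1; a direction draw only when the free
// diffusion step is > 0. Neighbour search uses a uniform grid whose results
// are identical to brute force (filaments are binned into every cell
// intersecting their r-inflated bounding box, so a head's own cell lists
// every filament within r of it).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

const int FREE = 0, BOUND = 1, ANCHORED = 2;

struct Params {
  double L, di, k, v, p1, p0, p2, r, eta, dt, R;
  double diff_step, xl_reach, xl_tol, xl_k, xl_p1, xl_p0;
  bool exempt_immobile, free_capture, site_random, head_follows, tip_hold;
  double g_par, g_perp, g_rot;
  void update_drags() {
    double p = L / di, lp = std::log(p);
    g_perp = 4.0 * M_PI * eta * L / (lp + 0.84);
    g_par  = 2.0 * M_PI * eta * L / (lp + 0.114);
    g_rot  = (1.0 / 3.0) * M_PI * eta * L * L * L / (lp - 0.662);
  }
};

inline bool rbern(double P) {
  if (P <= 0.0) return false;
  if (P >= 1.0) return true;
  return unif_rand() < P;
}

inline bool hex_contains(double x, double y, double R) {
  double apothem = 0.8660254037844386 * R;   // sqrt(3)/2
  double tol = 1e-12 * R;
  for (int kk = 0; kk < 3; ++kk) {
    double a = M_PI / 6.0 + kk * M_PI / 3.0;
    if (std::fabs(x * std::cos(a) + y * std::sin(a)) > apothem + tol)
      return false;
  }
  return true;
}

// Uniform point in the hexagon: triangle fan, fixed three draws.
inline void sample_hex(double R, double &x, double &y) {
  int tri = (int)std::floor(unif_rand() * 6.0);
  if (tri > 5) tri = 5;
  double s = std::sqrt(unif_rand());
  double t = unif_rand();
  double a1 = tri * M_PI / 3.0, a2 = (tri + 1) * M_PI / 3.0;
  double ax = R * std::cos(a1), ay = R * std::sin(a1);
  double bx = R * std::cos(a2), by = R * std::sin(a2);
  x = s * ((1 - t) * ax + t * bx);
  y = s * ((1 - t) * ay + t * by);
}

inline double pt_seg(double px, double py, double cx, double cy,
                     double th, double L, double &tout) {
  double ux = std::cos(th), uy = std::sin(th), h = L / 2.0;
  double t = (px - cx) * ux + (py - cy) * uy;
  if (t > h) t = h; else if (t < -h) t = -h;
  double dx = px - (cx + t * ux), dy = py - (cy + t * uy);
  tout = t;
  return std::sqrt(dx * dx + dy * dy);
}

inline double seg_seg(double c1x, double c1y, double th1,
                      double c2x, double c2y, double th2, double L,
                      double &t1, double &t2) {
  double u1x = std::cos(th1), u1y = std::sin(th1);
  double u2x = std::cos(th2), u2y = std::sin(th2);
  double h = L / 2.0;
  double wx = c1x - c2x, wy = c1y - c2y;
  double b = u1x * u2x + u1y * u2y;
  double d = u1x * wx + u1y * wy;
  double e = u2x * wx + u2y * wy;
  double denom = 1.0 - b * b;
  if (denom > 1e-12) {
    t1 = (b * e - d) / denom;
  } else {
    t1 = 0.0;
  }
  if (t1 > h) t1 = h; else if (t1 < -h) t1 = -h;
  t2 = u2x * (c1x + t1 * u1x - c2x) + u2y * (c1y + t1 * u1y - c2y);
  if (t2 > h) t2 = h; else if (t2 < -h) t2 = -h;
  t1 = u1x * (c2x + t2 * u2x - c1x) + u1y * (c2y + t2 * u2y - c1y);
  if (t1 > h) t1 = h; else if (t1 < -h) t1 = -h;
  double p1x = c1x + t1 * u1x, p1y = c1y + t1 * u1y;
  double p2x = c2x + t2 * u2x, p2y = c2y + t2 * u2y;
  return std::sqrt((p1x - p2x) * (p1x - p2x) + (p1y - p2y) * (p1y - p2y));
}

inline double orient_diff(double th1, double th2) {
  double d = th1 - th2;
  d -= 2.0 * M_PI * std::floor(d / (2.0 * M_PI));
  return std::min(d, 2.0 * M_PI - d);
}

// Uniform grid over the (inflated) hexagon bounding box.
struct Grid {
  double x0, y0, cell;
  int nx, ny;
  std::vector<std::vector<int> > bins;
  void init(double R, double L, double r) {
    double margin = L + r + 1.0;
    x0 = -R - margin;
    y0 = -0.8660254037844386 * R - margin;
    cell = std::max(r, 1e-3);
    nx = (int)std::ceil((2.0 * (R + margin)) / cell) + 1;
    ny = (int)std::ceil((2.0 * (0.8660254037844386 * R + margin)) / cell) + 1;
    bins.assign((size_t)nx * ny, std::vector<int>());
  }
  inline int clampi(int v, int hi) const {
    return v < 0 ? 0 : (v >= hi ? hi - 1 : v);
  }
  inline int cell_of(double x, double y) const {
    int ix = clampi((int)std::floor((x - x0) / cell), nx);
    int iy = clampi((int)std::floor((y - y0) / cell), ny);
    return iy * nx + ix;
  }
  void fill(const std::vector<double> &fx, const std::vector<double> &fy,
            const std::vector<double> &fth, double L, double r) {
    for (size_t c = 0; c < bins.size(); ++c) bins[c].clear();
    double h = L / 2.0, eps = 1e-9;
    for (int i = 0; i < (int)fx.size(); ++i) {
      double ux = std::cos(fth[i]) * h, uy = std::sin(fth[i]) * h;
      double xa = fx[i] - ux, xb = fx[i] + ux;
      double ya = fy[i] - uy, yb = fy[i] + uy;
      double lox = std::min(xa, xb) - r - eps, hix = std::max(xa, xb) + r + eps;
      double loy = std::min(ya, yb) - r - eps, hiy = std::max(ya, yb) + r + eps;
      int i0 = clampi((int)std::floor((lox - x0) / cell), nx);
      int i1 = clampi((int)std::floor((hix - x0) / cell), nx);
      int j0 = clampi((int)std::floor((loy - y0) / cell), ny);
      int j1 = clampi((int)std::floor((hiy - y0) / cell), ny);
      for (int j = j0; j <= j1; ++j)
        for (int ii = i0; ii <= i1; ++ii)
          bins[(size_t)j * nx + ii].push_back(i);
    }
  }
};

struct Engine {
  Params P;
  int n_fil, n_mot, n_xl;
  // filaments
  std::vector<double> fx, fy, fth;
  std::vector<int> fmob, fbirth;
  // motors: head 0 = a, head 1 = b
  std::vector<int> mstate[2], mfil[2], mbind[2];
  std::vector<double> mlen[2], mx[2], my[2];
  std::vector<char> mplus[2];
  // cross-linkers
  std::vector<int> xstate, xfil[2];
  std::vector<double> xlen[2], xx, xy;
  // force accumulators
  std::vector<double> Fx, Fy, Tq;
  std::vector<double> mforce;
  Grid grid;

  // lab-frame position of a head (idx h of motor m)
  inline void head_pos(int m, int h, double &px, double &py) const {
    if (mstate[h][m] == BOUND) {
      int f = mfil[h][m];
      px = fx[f] + mlen[h][m] * std::cos(fth[f]);
      py = fy[f] + mlen[h][m] * std::sin(fth[f]);
    } else {
      px = mx[h][m];
      py = my[h][m];
    }
  }

  inline void release_head(int m, int h) {
    double px, py;
    head_pos(m, h, px, py);
    mstate[h][m] = FREE;
    mfil[h][m] = -1;
    mlen[h][m] = 0.0;
    mbind[h][m] = -1;
    mx[h][m] = px;
    my[h][m] = py;
    mplus[h][m] = 0;
  }

  inline void release_xl(int x) {
    double px[2], py[2];
    for (int h = 0; h < 2; ++h) {
      int f = xfil[h][x];
      px[h] = fx[f] + xlen[h][x] * std::cos(fth[f]);
      py[h] = fy[f] + xlen[h][x] * std::sin(fth[f]);
    }
    xstate[x] = FREE;
    xfil[0][x] = xfil[1][x] = -1;
    xlen[0][x] = xlen[1][x] = 0.0;
    xx[x] = 0.5 * (px[0] + px[1]);
    xy[x] = 0.5 * (py[0] + py[1]);
  }

  // nearest filament segment within r of (px,py), excluding `excl`
  inline int nearest_filament(double px, double py, int excl,
                              double &best_t) const {
    const std::vector<int> &cand = grid.bins[grid.cell_of(px, py)];
    int best = -1;
    double best_d = P.r;
    for (size_t q = 0; q < cand.size(); ++q) {
      int f = cand[q];
      if (f == excl) continue;
      double t, d = pt_seg(px, py, fx[f], fy[f], fth[f], P.L, t);
      if (d < best_d || (best < 0 && d <= P.r && d <= best_d)) {
        // strict improvement, except accept the first candidate at d == r
        if (best >= 0 && !(d < best_d)) continue;
        best = f; best_d = d; best_t = t;
      }
    }
    return best;
  }

  // uniform-random candidate among the filaments within r of (px,py),
  // bound at that filament's closest point (the contact point); one
  // uniform draw for the candidate choice
  inline int random_filament(double px, double py, int excl,
                             double &t_out) const {
    const std::vector<int> &cand = grid.bins[grid.cell_of(px, py)];
    int n_in = 0;
    for (size_t q = 0; q < cand.size(); ++q) {
      int f = cand[q];
      if (f == excl) continue;
      double t, d = pt_seg(px, py, fx[f], fy[f], fth[f], P.L, t);
      if (d <= P.r) ++n_in;
    }
    if (n_in == 0) return -1;
    int pick = (int)std::floor(unif_rand() * n_in);
    if (pick >= n_in) pick = n_in - 1;
    for (size_t q = 0; q < cand.size(); ++q) {
      int f = cand[q];
      if (f == excl) continue;
      double t, d = pt_seg(px, py, fx[f], fy[f], fth[f], P.L, t);
      if (d > P.r) continue;
      if (pick-- > 0) continue;
      t_out = t;
      return f;
    }
    return -1;
  }

  inline int pick_filament(double px, double py, int excl, double &t_out) {
    return P.site_random ? random_filament(px, py, excl, t_out)
                         : nearest_filament(px, py, excl, t_out);
  }
};

} // namespace

// [[Rcpp::export]]
List sim_engine_cpp(List cfg, DataFrame sched,
                    DataFrame filaments, DataFrame motors, DataFrame xlinks,
                    int n_steps, int start_step, int record_stride) {
  Engine E;
  Params &P = E.P;
  P.L = cfg["filament_length"]; P.di = cfg["filament_diameter"];
  P.k = cfg["motor_stiffness"]; P.v = cfg["motor_velocity"];
  P.p1 = cfg["motor_attach_rate"]; P.p0 = cfg["motor_detach_rate"];
  P.p2 = cfg["filament_turnover_rate"]; P.r = cfg["motor_reach"];
  P.eta = cfg["dynamic_viscosity"]; P.dt = cfg["timestep"];
  P.R = cfg["hexagon_circumradius"];
  P.diff_step = cfg["free_motor_diffusion_step"];
  P.xl_reach = cfg["crosslinker_reach"];
  P.xl_tol = cfg["crosslinker_angle_tol"];
  P.xl_k = cfg["crosslinker_stiffness"];
  P.xl_p1 = cfg["crosslinker_attach_rate"];
  P.xl_p0 = cfg["crosslinker_detach_rate"];
  P.exempt_immobile = as<bool>(cfg["turnover_exempt_immobile"]);
  P.free_capture = as<bool>(cfg["deterministic_free_capture"]);
  P.site_random = as<std::string>(cfg["binding_site"]) == "random";
  P.head_follows = as<bool>(cfg["free_head_follows"]);
  P.tip_hold = as<bool>(cfg["tethered_tip_hold"]);
  P.update_drags();

  IntegerVector s_step = sched["step"], s_field = sched["field"];
  NumericVector s_value = sched["value"];

  // unpack state -----------------------------------------------------------
  {
    NumericVector x = filaments["x"], y = filaments["y"],
                  th = filaments["theta"];
    IntegerVector mob = filaments["mobile"], birth = filaments["birth_step"];
    E.n_fil = x.size();
    E.fx.assign(x.begin(), x.end());
    E.fy.assign(y.begin(), y.end());
    E.fth.assign(th.begin(), th.end());
    E.fmob.assign(mob.begin(), mob.end());
    E.fbirth.assign(birth.begin(), birth.end());
  }
  {
    const char *sc[2] = {"a_state", "b_state"};
    const char *fc[2] = {"a_fil", "b_fil"};
    const char *lc[2] = {"a_len", "b_len"};
    const char *xc[2] = {"a_x", "b_x"};
    const char *yc[2] = {"a_y", "b_y"};
    const char *bc[2] = {"a_bind_step", "b_bind_step"};
    E.n_mot = Rf_length(motors[0]);
    for (int h = 0; h < 2; ++h) {
      IntegerVector st = motors[sc[h]], fl = motors[fc[h]], bs = motors[bc[h]];
      NumericVector ln = motors[lc[h]], px = motors[xc[h]], py = motors[yc[h]];
      E.mstate[h].assign(st.begin(), st.end());
      E.mfil[h].assign(fl.begin(), fl.end());
      E.mbind[h].assign(bs.begin(), bs.end());
      E.mlen[h].assign(ln.begin(), ln.end());
      E.mx[h].assign(px.begin(), px.end());
      E.my[h].assign(py.begin(), py.end());
      E.mplus[h].assign(E.n_mot, 0);
    }
  }
  {
    IntegerVector st = xlinks["state"], fa = xlinks["a_fil"],
                  fb = xlinks["b_fil"];
    NumericVector la = xlinks["a_len"], lb = xlinks["b_len"],
                  px = xlinks["x"], py = xlinks["y"];
    E.n_xl = st.size();
    E.xstate.assign(st.begin(), st.end());
    E.xfil[0].assign(fa.begin(), fa.end());
    E.xfil[1].assign(fb.begin(), fb.end());
    E.xlen[0].assign(la.begin(), la.end());
    E.xlen[1].assign(lb.begin(), lb.end());
    E.xx.assign(px.begin(), px.end());
    E.xy.assign(py.begin(), py.end());
  }

  E.Fx.assign(E.n_fil, 0.0);
  E.Fy.assign(E.n_fil, 0.0);
  E.Tq.assign(E.n_fil, 0.0);
  E.mforce.assign(E.n_mot, 0.0);
  E.grid.init(P.R, P.L, std::max(P.r, 0.05));

  // series storage
  std::vector<double> se_force(n_steps), se_exert(n_steps), se_max(n_steps),
      se_elastic(n_steps), se_dissip(n_steps);
  std::vector<int> se_two(n_steps), se_one(n_steps), se_free(n_steps),
      se_xl(n_steps), se_step(n_steps);
  List snapshots;
  std::vector<int> snap_steps;

  std::vector<char> turn(E.n_fil, 0);
  std::vector<double> old_x(E.n_fil), old_y(E.n_fil), old_th(E.n_fil);
  double run_max_force = 0.0;

  for (int is = 0; is < n_steps; ++is) {
    int step = start_step + is + 1;

    // (1) diffusion of fully free motors / cross-linkers ---------------
    if (P.diff_step > 0) {
      for (int m = 0; m < E.n_mot; ++m) {
        if (E.mstate[0][m] == FREE && E.mstate[1][m] == FREE) {
          double ang = 2.0 * M_PI * unif_rand();
          double nxp = E.mx[0][m] + P.diff_step * std::cos(ang);
          double nyp = E.my[0][m] + P.diff_step * std::sin(ang);
          E.mx[0][m] = E.mx[1][m] = nxp;
          E.my[0][m] = E.my[1][m] = nyp;
        }
      }
      for (int x = 0; x < E.n_xl; ++x) {
        if (E.xstate[x] == FREE) {
          double ang = 2.0 * M_PI * unif_rand();
          E.xx[x] += P.diff_step * std::cos(ang);
          E.xy[x] += P.diff_step * std::sin(ang);
        }
      }
    }

    // spatial index for this step's searches
    E.grid.fill(E.fx, E.fy, E.fth, P.L, P.r);

    // (2) motor search and bind ----------------------------------------
    // A free-diffusing motor grabs the first filament it discovers
    // deterministically; the pair-forming second attachment — whether in
    // the same step or on a later one — is gated by the attachment rate p1.
    for (int m = 0; m < E.n_mot; ++m) {
      if (P.free_capture && E.mstate[0][m] == FREE &&
          E.mstate[1][m] == FREE) {
        double px = E.mx[0][m], py = E.my[0][m];
        double t;
        int f1 = E.pick_filament(px, py, -1, t);
        if (f1 >= 0) {
          E.mstate[0][m] = BOUND; E.mfil[0][m] = f1; E.mlen[0][m] = t;
          E.mbind[0][m] = step; E.mplus[0][m] = 0;
          if (rbern(P.p1 * P.dt)) {
            int f2 = E.pick_filament(px, py, f1, t);
            if (f2 >= 0) {
              E.mstate[1][m] = BOUND; E.mfil[1][m] = f2; E.mlen[1][m] = t;
              E.mbind[1][m] = step; E.mplus[1][m] = 0;
            }
          }
        }
        continue;
      }
      for (int h = 0; h < 2; ++h) {
        if (E.mstate[h][m] != FREE) continue;
        if (!rbern(P.p1 * P.dt)) continue;
        int o = 1 - h;
        // a free head searches around its own coordinates (its release
        // point) or, if configured, around the walking partner head
        double px = E.mx[h][m], py = E.my[h][m];
        if (P.head_follows && E.mstate[o][m] != FREE) E.head_pos(m, o, px, py);
        int excl = (E.mstate[o][m] == BOUND) ? E.mfil[o][m] : -1;
        double t;
        int f = E.pick_filament(px, py, excl, t);
        if (f >= 0) {
          E.mstate[h][m] = BOUND;
          E.mfil[h][m] = f;
          E.mlen[h][m] = t;
          E.mbind[h][m] = step;
          E.mplus[h][m] = 0;
        }
      }
    }

    // (3) cross-linker search and bind ---------------------------------
    for (int x = 0; x < E.n_xl; ++x) {
      if (E.xstate[x] != FREE) continue;
      if (!rbern(P.xl_p1 * P.dt)) continue;
      const std::vector<int> &cand =
          E.grid.bins[E.grid.cell_of(E.xx[x], E.xy[x])];
      // filaments within the motor search radius of the cross-linker
      std::vector<int> near;
      for (size_t q = 0; q < cand.size(); ++q) {
        int f = cand[q];
        double t, d = pt_seg(E.xx[x], E.xy[x], E.fx[f], E.fy[f], E.fth[f],
                             P.L, t);
        if (d <= P.r) near.push_back(f);
      }
      int bi = -1, bj = -1;
      double bt1 = 0, bt2 = 0, bd = P.xl_reach;
      for (size_t a = 0; a < near.size(); ++a) {
        for (size_t b = a + 1; b < near.size(); ++b) {
          int i = near[a], j = near[b];
          if (orient_diff(E.fth[i], E.fth[j]) > P.xl_tol) continue;
          double t1, t2;
          double d = seg_seg(E.fx[i], E.fy[i], E.fth[i],
                             E.fx[j], E.fy[j], E.fth[j], P.L, t1, t2);
          if (d < bd || (bi < 0 && d <= P.xl_reach && !(d > bd))) {
            if (bi >= 0 && !(d < bd)) continue;
            bi = i; bj = j; bt1 = t1; bt2 = t2; bd = d;
          }
        }
      }
      if (bi >= 0) {
        E.xstate[x] = BOUND;
        E.xfil[0][x] = bi; E.xlen[0][x] = bt1;
        E.xfil[1][x] = bj; E.xlen[1][x] = bt2;
      }
    }

    // (4) walk ----------------------------------------------------------
    for (int m = 0; m < E.n_mot; ++m) {
      for (int h = 0; h < 2; ++h) {
        if (E.mstate[h][m] != BOUND) continue;
        E.mlen[h][m] += P.v * P.dt;
        if (E.mlen[h][m] >= P.L / 2.0) {
          E.mlen[h][m] = P.L / 2.0;
          // the free leg of a tethered motor dwells at the tip and reels
          // the filament in; every other head is shed at the plus-end
          if (!(P.tip_hold && E.mstate[1 - h][m] == ANCHORED))
            E.mplus[h][m] = 1;
        }
      }
    }

    // (5) release -------------------------------------------------------
    for (int m = 0; m < E.n_mot; ++m) {
      for (int h = 0; h < 2; ++h) {
        if (E.mstate[h][m] != BOUND) continue;
        if (E.mplus[h][m]) { E.release_head(m, h); continue; }
        if (rbern(P.p0 * P.dt)) E.release_head(m, h);
      }
      bool la = E.mstate[0][m] != FREE, lb = E.mstate[1][m] != FREE;
      if (la && lb) {
        double ax, ay, bx, by;
        E.head_pos(m, 0, ax, ay);
        E.head_pos(m, 1, bx, by);
        double d = std::sqrt((ax - bx) * (ax - bx) + (ay - by) * (ay - by));
        if (d > P.r) {
          int h;
          if (E.mstate[0][m] == ANCHORED) h = 1;
          else if (E.mstate[1][m] == ANCHORED) h = 0;
          else if (E.mbind[0][m] > E.mbind[1][m]) h = 0;
          else if (E.mbind[1][m] > E.mbind[0][m]) h = 1;
          else h = (unif_rand() < 0.5) ? 0 : 1;
          E.release_head(m, h);
        }
      }
    }
    for (int x = 0; x < E.n_xl; ++x) {
      if (E.xstate[x] != BOUND) continue;
      if (P.xl_p0 > 0 && rbern(P.xl_p0 * P.dt)) { E.release_xl(x); continue; }
      double px[2], py[2];
      for (int h = 0; h < 2; ++h) {
        int f = E.xfil[h][x];
        px[h] = E.fx[f] + E.xlen[h][x] * std::cos(E.fth[f]);
        py[h] = E.fy[f] + E.xlen[h][x] * std::sin(E.fth[f]);
      }
      double d = std::sqrt((px[0] - px[1]) * (px[0] - px[1]) +
                           (py[0] - py[1]) * (py[0] - py[1]));
      if (d > P.xl_reach) E.release_xl(x);
    }

    // (6) forces --------------------------------------------------------
    std::fill(E.Fx.begin(), E.Fx.end(), 0.0);
    std::fill(E.Fy.begin(), E.Fy.end(), 0.0);
    std::fill(E.Tq.begin(), E.Tq.end(), 0.0);
    double elastic = 0.0, force_sum = 0.0, force_max = 0.0;
    int n_exert = 0, n_two = 0, n_one = 0, n_free = 0, n_xlb = 0;
    for (int m = 0; m < E.n_mot; ++m) {
      int nb = (E.mstate[0][m] != FREE) + (E.mstate[1][m] != FREE);
      bool two_fil = E.mstate[0][m] == BOUND && E.mstate[1][m] == BOUND;
      bool loaded = nb == 2;
      if (nb == 2 && two_fil) ++n_two;
      else if (nb >= 1 && !loaded) ++n_one;
      else if (nb == 0) ++n_free;
      else ++n_two;                        // tethered + bound counts as two
      E.mforce[m] = 0.0;
      if (!loaded) continue;
      double ax, ay, bx, by;
      E.head_pos(m, 0, ax, ay);
      E.head_pos(m, 1, bx, by);
      double dx = bx - ax, dy = by - ay;
      double d = std::sqrt(dx * dx + dy * dy);
      double fmag = P.k * d;
      E.mforce[m] = fmag;
      elastic += 0.5 * P.k * d * d;
      force_sum += fmag;
      if (fmag > 0) ++n_exert;
      if (fmag > force_max) force_max = fmag;
      if (E.mstate[0][m] == BOUND) {
        int f = E.mfil[0][m];
        double fxc = P.k * dx, fyc = P.k * dy;
        E.Fx[f] += fxc; E.Fy[f] += fyc;
        E.Tq[f] += E.mlen[0][m] *
                   (-std::sin(E.fth[f]) * fxc + std::cos(E.fth[f]) * fyc);
      }
      if (E.mstate[1][m] == BOUND) {
        int f = E.mfil[1][m];
        double fxc = -P.k * dx, fyc = -P.k * dy;
        E.Fx[f] += fxc; E.Fy[f] += fyc;
        E.Tq[f] += E.mlen[1][m] *
                   (-std::sin(E.fth[f]) * fxc + std::cos(E.fth[f]) * fyc);
      }
    }
    for (int x = 0; x < E.n_xl; ++x) {
      if (E.xstate[x] != BOUND) continue;
      ++n_xlb;
      double px[2], py[2];
      for (int h = 0; h < 2; ++h) {
        int f = E.xfil[h][x];
        px[h] = E.fx[f] + E.xlen[h][x] * std::cos(E.fth[f]);
        py[h] = E.fy[f] + E.xlen[h][x] * std::sin(E.fth[f]);
      }
      double dx = px[1] - px[0], dy = py[1] - py[0];
      elastic += 0.5 * P.xl_k * (dx * dx + dy * dy);
      for (int h = 0; h < 2; ++h) {
        int f = E.xfil[h][x];
        double sgn = (h == 0) ? 1.0 : -1.0;
        double fxc = sgn * P.xl_k * dx, fyc = sgn * P.xl_k * dy;
        E.Fx[f] += fxc; E.Fy[f] += fyc;
        E.Tq[f] += E.xlen[h][x] *
                   (-std::sin(E.fth[f]) * fxc + std::cos(E.fth[f]) * fyc);
      }
    }

    // (7) filament update ------------------------------------------------
    double dissip = 0.0;
    for (int f = 0; f < E.n_fil; ++f) {
      if (!E.fmob[f]) continue;
      double ct = std::cos(E.fth[f]), st = std::sin(E.fth[f]);
      double fpar = ct * E.Fx[f] + st * E.Fy[f];
      double fperp = -st * E.Fx[f] + ct * E.Fy[f];
      double dpar = P.dt * fpar / P.g_par;
      double dperp = P.dt * fperp / P.g_perp;
      double dth = P.dt * E.Tq[f] / P.g_rot;
      E.fx[f] += dpar * ct - dperp * st;
      E.fy[f] += dpar * st + dperp * ct;
      E.fth[f] += dth;
      dissip += (P.g_par * dpar * dpar + P.g_perp * dperp * dperp +
                 P.g_rot * dth * dth) / P.dt;
    }

    // (8) turnover --------------------------------------------------------
    bool any_turn = false;
    for (int f = 0; f < E.n_fil; ++f) {
      turn[f] = 0;
      bool eligible = E.fmob[f] || !P.exempt_immobile;
      if (!eligible) continue;
      if (rbern(P.p2 * P.dt)) {
        turn[f] = 1;
        any_turn = true;
        old_x[f] = E.fx[f]; old_y[f] = E.fy[f]; old_th[f] = E.fth[f];
        sample_hex(P.R, E.fx[f], E.fy[f]);
        E.fth[f] = 2.0 * M_PI * unif_rand();
        E.fbirth[f] = step;
      }
    }
    if (any_turn) {
      for (int m = 0; m < E.n_mot; ++m) {
        for (int h = 0; h < 2; ++h) {
          if (E.mstate[h][m] == BOUND && turn[E.mfil[h][m]]) {
            int f = E.mfil[h][m];
            E.mx[h][m] = old_x[f] + E.mlen[h][m] * std::cos(old_th[f]);
            E.my[h][m] = old_y[f] + E.mlen[h][m] * std::sin(old_th[f]);
            E.mstate[h][m] = FREE;
            E.mfil[h][m] = -1;
            E.mlen[h][m] = 0.0;
            E.mbind[h][m] = -1;
            E.mplus[h][m] = 0;
          }
        }
      }
      for (int x = 0; x < E.n_xl; ++x) {
        if (E.xstate[x] != BOUND) continue;
        if (turn[E.xfil[0][x]] || turn[E.xfil[1][x]]) {
          double px[2], py[2];
          for (int h = 0; h < 2; ++h) {
            int f = E.xfil[h][x];
            double cx = turn[f] ? old_x[f] : E.fx[f];
            double cy = turn[f] ? old_y[f] : E.fy[f];
            double th = turn[f] ? old_th[f] : E.fth[f];
            px[h] = cx + E.xlen[h][x] * std::cos(th);
            py[h] = cy + E.xlen[h][x] * std::sin(th);
          }
          E.xstate[x] = FREE;
          E.xfil[0][x] = E.xfil[1][x] = -1;
          E.xlen[0][x] = E.xlen[1][x] = 0.0;
          E.xx[x] = 0.5 * (px[0] + px[1]);
          E.xy[x] = 0.5 * (py[0] + py[1]);
        }
      }
    }

    // (9) boundary enforcement -------------------------------------------
    for (int f = 0; f < E.n_fil; ++f) {
      if (!E.fmob[f]) continue;
      if (hex_contains(E.fx[f], E.fy[f], P.R)) continue;
      for (int m = 0; m < E.n_mot; ++m)
        for (int h = 0; h < 2; ++h)
          if (E.mstate[h][m] == BOUND && E.mfil[h][m] == f)
            E.release_head(m, h);
      for (int x = 0; x < E.n_xl; ++x)
        if (E.xstate[x] == BOUND &&
            (E.xfil[0][x] == f || E.xfil[1][x] == f))
          E.release_xl(x);
      sample_hex(P.R, E.fx[f], E.fy[f]);   // orientation preserved
    }
    for (int m = 0; m < E.n_mot; ++m) {
      if (E.mstate[0][m] == FREE && E.mstate[1][m] == FREE &&
          !hex_contains(E.mx[0][m], E.my[0][m], P.R)) {
        double nxp, nyp;
        sample_hex(P.R, nxp, nyp);
        E.mx[0][m] = E.mx[1][m] = nxp;
        E.my[0][m] = E.my[1][m] = nyp;
      }
    }
    for (int x = 0; x < E.n_xl; ++x) {
      if (E.xstate[x] == FREE && !hex_contains(E.xx[x], E.xy[x], P.R)) {
        sample_hex(P.R, E.xx[x], E.xy[x]);
      }
    }

    // (10) scheduled parameter switches ----------------------------------
    for (int s = 0; s < s_step.size(); ++s) {
      if (s_step[s] != step) continue;
      double val = s_value[s];
      bool geom = false;
      switch (s_field[s]) {
        case 1: P.k = val; break;
        case 2: P.r = val; break;
        case 3: P.L = val; geom = true; break;
        case 4: P.v = val; break;
        case 5: P.p0 = val; break;
        case 6: P.p1 = val; break;
        case 7: P.p2 = val; break;
        case 8: P.eta = val; geom = true; break;
      }
      if (geom) P.update_drags();
      if (s_field[s] == 3) {               // length change: shed stranded heads
        for (int m = 0; m < E.n_mot; ++m)
          for (int h = 0; h < 2; ++h)
            if (E.mstate[h][m] == BOUND &&
                std::fabs(E.mlen[h][m]) > P.L / 2.0)
              E.release_head(m, h);
        for (int x = 0; x < E.n_xl; ++x)
          if (E.xstate[x] == BOUND &&
              (std::fabs(E.xlen[0][x]) > P.L / 2.0 ||
               std::fabs(E.xlen[1][x]) > P.L / 2.0))
            E.release_xl(x);
      }
    }

    // (11) record ---------------------------------------------------------
    se_step[is] = step;
    se_force[is] = E.n_mot > 0 ? force_sum / E.n_mot : 0.0;
    se_exert[is] = n_exert > 0 ? force_sum / n_exert : 0.0;
    se_max[is] = force_max;
    if (force_max > run_max_force) run_max_force = force_max;
    se_two[is] = n_two; se_one[is] = n_one; se_free[is] = n_free;
    se_xl[is] = n_xlb;
    se_elastic[is] = elastic;
    se_dissip[is] = dissip;

    if (record_stride > 0 && (step % record_stride == 0 || is == n_steps - 1)) {
      snap_steps.push_back(step);
      List fil = List::create(
          _["x"] = NumericVector(E.fx.begin(), E.fx.end()),
          _["y"] = NumericVector(E.fy.begin(), E.fy.end()),
          _["theta"] = NumericVector(E.fth.begin(), E.fth.end()),
          _["mobile"] = IntegerVector(E.fmob.begin(), E.fmob.end()),
          _["birth_step"] = IntegerVector(E.fbirth.begin(), E.fbirth.end()));
      NumericVector hx0(E.n_mot), hy0(E.n_mot), hx1(E.n_mot), hy1(E.n_mot);
      for (int m = 0; m < E.n_mot; ++m) {
        double px, py;
        E.head_pos(m, 0, px, py); hx0[m] = px; hy0[m] = py;
        E.head_pos(m, 1, px, py); hx1[m] = px; hy1[m] = py;
      }
      List mot = List::create(
          _["a_state"] = IntegerVector(E.mstate[0].begin(), E.mstate[0].end()),
          _["a_fil"] = IntegerVector(E.mfil[0].begin(), E.mfil[0].end()),
          _["a_len"] = NumericVector(E.mlen[0].begin(), E.mlen[0].end()),
          _["a_x"] = hx0, _["a_y"] = hy0,
          _["b_state"] = IntegerVector(E.mstate[1].begin(), E.mstate[1].end()),
          _["b_fil"] = IntegerVector(E.mfil[1].begin(), E.mfil[1].end()),
          _["b_len"] = NumericVector(E.mlen[1].begin(), E.mlen[1].end()),
          _["b_x"] = hx1, _["b_y"] = hy1,
          _["force"] = NumericVector(E.mforce.begin(), E.mforce.end()));
      List xl = List::create(
          _["state"] = IntegerVector(E.xstate.begin(), E.xstate.end()),
          _["x"] = NumericVector(E.xx.begin(), E.xx.end()),
          _["y"] = NumericVector(E.xy.begin(), E.xy.end()),
          _["a_fil"] = IntegerVector(E.xfil[0].begin(), E.xfil[0].end()),
          _["a_len"] = NumericVector(E.xlen[0].begin(), E.xlen[0].end()),
          _["b_fil"] = IntegerVector(E.xfil[1].begin(), E.xfil[1].end()),
          _["b_len"] = NumericVector(E.xlen[1].begin(), E.xlen[1].end()));
      snapshots.push_back(List::create(_["step"] = step, _["filaments"] = fil,
                                       _["motors"] = mot,
                                       _["crosslinkers"] = xl));
    }
  }

  // final state back to R ----------------------------------------------
  List fil_out = List::create(
      _["x"] = NumericVector(E.fx.begin(), E.fx.end()),
      _["y"] = NumericVector(E.fy.begin(), E.fy.end()),
      _["theta"] = NumericVector(E.fth.begin(), E.fth.end()),
      _["mobile"] = IntegerVector(E.fmob.begin(), E.fmob.end()),
      _["birth_step"] = IntegerVector(E.fbirth.begin(), E.fbirth.end()));
  List mot_out = List::create(
      _["a_state"] = IntegerVector(E.mstate[0].begin(), E.mstate[0].end()),
      _["a_fil"] = IntegerVector(E.mfil[0].begin(), E.mfil[0].end()),
      _["a_len"] = NumericVector(E.mlen[0].begin(), E.mlen[0].end()),
      _["a_x"] = NumericVector(E.mx[0].begin(), E.mx[0].end()),
      _["a_y"] = NumericVector(E.my[0].begin(), E.my[0].end()),
      _["a_bind_step"] = IntegerVector(E.mbind[0].begin(), E.mbind[0].end()),
      _["b_state"] = IntegerVector(E.mstate[1].begin(), E.mstate[1].end()),
      _["b_fil"] = IntegerVector(E.mfil[1].begin(), E.mfil[1].end()),
      _["b_len"] = NumericVector(E.mlen[1].begin(), E.mlen[1].end()),
      _["b_x"] = NumericVector(E.mx[1].begin(), E.mx[1].end()),
      _["b_y"] = NumericVector(E.my[1].begin(), E.my[1].end()),
      _["b_bind_step"] = IntegerVector(E.mbind[1].begin(), E.mbind[1].end()),
      _["force"] = NumericVector(E.mforce.begin(), E.mforce.end()));
  List xl_out = List::create(
      _["state"] = IntegerVector(E.xstate.begin(), E.xstate.end()),
      _["x"] = NumericVector(E.xx.begin(), E.xx.end()),
      _["y"] = NumericVector(E.xy.begin(), E.xy.end()),
      _["a_fil"] = IntegerVector(E.xfil[0].begin(), E.xfil[0].end()),
      _["a_len"] = NumericVector(E.xlen[0].begin(), E.xlen[0].end()),
      _["b_fil"] = IntegerVector(E.xfil[1].begin(), E.xfil[1].end()),
      _["b_len"] = NumericVector(E.xlen[1].begin(), E.xlen[1].end()));
  List series = List::create(
      _["step"] = IntegerVector(se_step.begin(), se_step.end()),
      _["mean_motor_force"] = NumericVector(se_force.begin(), se_force.end()),
      _["mean_exerting_force"] =
          NumericVector(se_exert.begin(), se_exert.end()),
      _["max_motor_force"] = NumericVector(se_max.begin(), se_max.end()),
      _["n_two_bound"] = IntegerVector(se_two.begin(), se_two.end()),
      _["n_one_bound"] = IntegerVector(se_one.begin(), se_one.end()),
      _["n_free"] = IntegerVector(se_free.begin(), se_free.end()),
      _["n_xl_bound"] = IntegerVector(se_xl.begin(), se_xl.end()),
      _["elastic_energy"] =
          NumericVector(se_elastic.begin(), se_elastic.end()),
      _["dissipation"] = NumericVector(se_dissip.begin(), se_dissip.end()));

  return List::create(_["series"] = series, _["filaments"] = fil_out,
                      _["motors"] = mot_out, _["crosslinkers"] = xl_out,
                      _["snapshots"] = snapshots,
                      _["snapshot_steps"] =
                          IntegerVector(snap_steps.begin(), snap_steps.end()),
                      _["max_motor_force"] = run_max_force);
}
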