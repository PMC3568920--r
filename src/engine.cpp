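// Monte Carlo duty-cycle engine: Brownian + electrodiffusive particle
// propagation, radial concentration binning, mean-field receptor kinetics,
// intracleft ion perturbation and the open-conductance-dependent cleft
// voltage profile, advanced one 0.1-us step at a time.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----
// Counter-based per-particle streams: every draw is a pure hash of
// (seed, particle id, step, counter), so runs are bit-reproducible, results
// do not depend on particle update order, and two runs that share a seed
// share per-particle streams regardless of their time step.
static inline uint64_t mix64(uint64_t x) {
  x ^= x >> 30; x *= 0xBF58476D1CE4E5B9ULL;
  x ^= x >> 27; x *= 0x94D049BB133111EBULL;
  x ^= x >> 31; return x;
}

static inline double u01(uint64_t seed, uint64_t pid, uint64_t step,
                         uint64_t ctr) {
  uint64_t x = (seed + 1) * 0x9E3779B97F4A7C15ULL;
  x ^= (pid  + 1) * 0xA0761D6478BD642FULL;
  x ^= (step + 1) * 0xE7037ED1A0B428DBULL;
  x ^= (ctr  + 1) * 0x8EBC6AF09C88C6E3ULL;
  x = mix64(mix64(x));
  return (double)(x >> 11) * 0x1.0p-53;
}

// Marsaglia (1972) uniform point on the unit sphere
static inline void unit_dir(uint64_t seed, uint64_t pid, uint64_t step,
                            double* d) {
  for (uint64_t a = 0;; ++a) {
    double u = 2.0 * u01(seed, pid, step, 2 * a)     - 1.0;
    double v = 2.0 * u01(seed, pid, step, 2 * a + 1) - 1.0;
    double s = u * u + v * v;
    if (s < 1.0 && s > 1e-300) {
      double f = 2.0 * std::sqrt(1.0 - s);
      d[0] = u * f; d[1] = v * f; d[2] = 1.0 - 2.0 * s;
      return;
    }
  }
}

static inline void gauss3(uint64_t seed, uint64_t pid, uint64_t step,
                          double* g) {
  // Box-Muller on counter draws (counters 0..3)
  double u1 = 1.0 - u01(seed, pid, step, 0);
  double u2 = u01(seed, pid, step, 1);
  double u3 = 1.0 - u01(seed, pid, step, 2);
  double u4 = u01(seed, pid, step, 3);
  double r1 = std::sqrt(-2.0 * std::log(u1));
  double r2 = std::sqrt(-2.0 * std::log(u3));
  g[0] = r1 * std::cos(2.0 * M_PI * u2);
  g[1] = r1 * std::sin(2.0 * M_PI * u2);
  g[2] = r2 * std::cos(2.0 * M_PI * u4);
}

//' Unit direction vectors from the engine's counter-based random streams
//'
//' One uniformly distributed 3-D unit vector per particle, as used by the
//' fixed-step Brownian update. Pure function of (seed, particle id, step).
//'
//' @param n number of particles
//' @param seed integer seed
//' @param step step index
//' @return n x 3 matrix of unit vectors
//' @export
// [[Rcpp::export]]
NumericMatrix cpp_unit_directions(int n, int seed, int step) {
  NumericMatrix out(n, 3);
  double d[3];
  for (int i = 0; i < n; ++i) {
    unit_dir((uint64_t)seed, (uint64_t)i, (uint64_t)step, d);
    out(i, 0) = d[0]; out(i, 1) = d[1]; out(i, 2) = d[2];
  }
  return out;
}

//' Standard-normal increments from the engine's counter-based streams
//'
//' @param n number of particles
//' @param seed integer seed
//' @param step step index
//' @return n x 3 matrix of N(0,1) draws
//' @export
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_increments(int n, int seed, int step) {
  NumericMatrix out(n, 3);
  double g[3];
  for (int i = 0; i < n; ++i) {
    gauss3((uint64_t)seed, (uint64_t)i, (uint64_t)step, g);
    out(i, 0) = g[0]; out(i, 1) = g[1]; out(i, 2) = g[2];
  }
  return out;
}

// ------------------------------------------------------------- Bessel ----
// I1 lookup table (linear interpolation) for the per-particle drift; I0/I1
// at the per-step shunt parameter use std::cyl_bessel_i directly.
static std::vector<double> I1_TAB;
static const double I1_XMAX = 40.0;
static const int    I1_N    = 40001;

static void ensure_i1_tab() {
  if (!I1_TAB.empty()) return;
  I1_TAB.resize(I1_N);
  for (int i = 0; i < I1_N; ++i)
    I1_TAB[i] = std::cyl_bessel_i(1.0, I1_XMAX * i / (I1_N - 1));
}

static inline double i1_fast(double x) {
  if (x >= I1_XMAX) return std::cyl_bessel_i(1.0, x);
  double u = x / I1_XMAX * (I1_N - 1);
  int i = (int)u;
  double f = u - i;
  return I1_TAB[i] * (1.0 - f) + I1_TAB[i + 1] * f;
}

// ----------------------------------------------------- receptor groups ----
struct Group {
  int n;                         // states
  std::vector<int> from, to, lig;   // lig: 0 none, 1 glu, 2 ant
  std::vector<double> rate;
  std::vector<int> open_idx, active_idx;
  std::vector<double> p;
  double count, gamma_pS, erev_mV, block, ant_mM;
  int type;                      // 0 AMPAR, 1 NMDAR, 2 mGluR1
  int bin;
  std::vector<double> Q;         // scratch generator, row-major
};

static void build_Q(Group& g, double c_glu) {
  std::fill(g.Q.begin(), g.Q.end(), 0.0);
  int n = g.n;
  for (size_t k = 0; k < g.rate.size(); ++k) {
    double r = g.rate[k];
    if (g.lig[k] == 1) r *= c_glu;
    else if (g.lig[k] == 2) r *= g.ant_mM;
    g.Q[g.from[k] * n + g.to[k]] += r;
  }
  for (int i = 0; i < n; ++i) {
    double s = 0;
    for (int j = 0; j < n; ++j) if (j != i) s += g.Q[i * n + j];
    g.Q[i * n + i] = -s;
  }
}

// exact action of exp(Q dt) on the probability row-vector by uniformization
static void propagate(Group& g, double dt) {
  int n = g.n;
  double lam = 0;
  for (int i = 0; i < n; ++i) lam = std::max(lam, -g.Q[i * n + i]);
  if (lam * dt <= 0) return;
  int nsub = (int)std::ceil(lam * dt / 100.0);
  if (nsub < 1) nsub = 1;
  double h = dt / nsub;
  std::vector<double> v(n), vn(n), acc(n);
  for (int s = 0; s < nsub; ++s) {
    double w = std::exp(-lam * h);
    for (int j = 0; j < n; ++j) { v[j] = g.p[j]; acc[j] = w * v[j]; }
    double remaining = 1.0 - w;
    int k = 0;
    while (remaining > 1e-14 && k < 1000000) {
      ++k;
      for (int j = 0; j < n; ++j) {
        double s2 = v[j];
        for (int i = 0; i < n; ++i) s2 += v[i] * g.Q[i * n + j] / lam;
        vn[j] = s2;
      }
      w *= lam * h / k;
      for (int j = 0; j < n; ++j) acc[j] += w * vn[j];
      remaining -= w;
      std::swap(v, vn);
    }
    double tot = 0;
    for (int j = 0; j < n; ++j) { if (acc[j] < 0) acc[j] = 0; tot += acc[j]; }
    for (int j = 0; j < n; ++j) g.p[j] = acc[j] / tot;
  }
}

// --------------------------------------------------------------- engine ----
// [[Rcpp::export]]
List cpp_engine_run(List state, int n_steps, int c_record_every) {
  state = clone(state);  // value semantics: never mutate the caller's state
  List par = state["params"];
  const double dt      = par["dt_ms"];
  const double delta   = par["cleft_height_nm"];
  const double half    = par["half_nm"];
  const double H       = par["structure_height_nm"];
  const double pitch   = par["pitch_nm"];
  const double esc2    = std::pow((double)par["escape_radius_nm"], 2);
  const double ra      = par["ra_nm"];
  const double Rout    = par["R_out_nm"];
  const double binw    = par["bin_width_nm"];
  const int    nb      = par["n_bins"];
  const double D_in    = (double)par["D_cleft_um2_ms"] * 1e6;  // nm^2/ms
  const double D_out   = (double)par["D_out_um2_ms"] * 1e6;
  const int    stepmode = par["step_mode"];     // 0 fixed, 1 gaussian
  const double mu      = par["mu_cleft"];       // nm^2/(ms mV), signed
  const bool   field_on = par["field_on"];
  const double rex     = par["rex_ohm_m"];
  const double gscale  = par["gamma_scale"];    // driving-force scale
  const double mg_mM   = par["mg_mM"];
  const double max_embed = par["max_embed_nm"];
  const int    release_step = par["release_step"];
  const double erev_a  = par["erev_ampar_mV"];
  const double erev_n  = par["erev_nmdar_mV"];

  NumericMatrix pos = state["pos"];
  LogicalVector alive = state["alive"];
  const int npart = pos.nrow();
  NumericVector vmvec = state["vm"];
  int step0 = state["step"];
  bool released = state["released"];
  double L_prev = state["L_prev"];
  double vm_prev = state["vm_prev"];
  const uint64_t seed = (uint64_t)(int)state["seed"];

  if (step0 + n_steps > vmvec.size())
    stop("membrane-potential vector shorter than the requested run");

  ensure_i1_tab();

  // receptor groups
  List glist = state["groups"];
  std::vector<Group> groups(glist.size());
  for (int gi = 0; gi < glist.size(); ++gi) {
    List gl = glist[gi];
    Group& g = groups[gi];
    g.n = gl["n_states"];
    g.from = as<std::vector<int>>(gl["tr_from"]);
    g.to   = as<std::vector<int>>(gl["tr_to"]);
    g.lig  = as<std::vector<int>>(gl["tr_lig"]);
    g.rate = as<std::vector<double>>(gl["tr_rate"]);
    g.open_idx   = as<std::vector<int>>(gl["open_idx"]);
    g.active_idx = as<std::vector<int>>(gl["active_idx"]);
    g.p = as<std::vector<double>>(gl["p"]);
    g.count = gl["count"]; g.gamma_pS = gl["gamma_pS"];
    g.erev_mV = gl["erev_mV"]; g.block = gl["block"];
    g.ant_mM = gl["ant_mM"]; g.type = gl["type"]; g.bin = gl["bin"];
    g.Q.assign(g.n * g.n, 0.0);
  }

  // ions
  List ion = state["ions"];
  const bool ions_on = ion["enabled"];
  NumericMatrix ionc = ion["conc_mM"];       // nb x 3 (na, k, cl)
  NumericVector ion_base = ion["baseline_mM"];
  NumericVector ion_D = ion["D_nm2_ms"];
  const double f_na = ion["f_na"], f_k = ion["f_k"];
  const double e_na = ion["e_na_mV"], e_k = ion["e_k_mV"];
  const int ion_sub = ion["substeps"];

  // bin geometry
  std::vector<double> vol(nb + 1), edge(nb + 1), iface_area(nb), ctr_dr(nb);
  for (int b = 0; b <= nb; ++b) edge[b] = std::min(binw * b, Rout);
  for (int b = 0; b < nb; ++b)
    vol[b] = M_PI * (edge[b + 1] * edge[b + 1] - edge[b] * edge[b]) * delta;
  vol[nb] = (4.0 * half * half - M_PI * Rout * Rout) * delta; // square corners
  for (int b = 0; b + 1 < nb; ++b) {
    iface_area[b] = 2.0 * M_PI * edge[b + 1] * delta;
    ctr_dr[b] = 0.5 * (edge[b + 2] + edge[b + 1]) - 0.5 * (edge[b + 1] + edge[b]);
  }

  const double KCONC = 1e27 / 6.02214076e23;  // molecules/nm^3 -> mM
  const double FARADAY = 96485.33212;

  // trace storage
  const int NC = 12;
  NumericMatrix traces(n_steps, NC);
  CharacterVector tracenames = CharacterVector::create(
    "t_ms", "vm_mV", "L", "cleft_count", "i_ampar_pA", "i_nmdar_pA",
    "p_open_ampar", "p_open_nmdar", "mglur_active",
    "na_dev_pct", "k_dev_pct", "cl_dev_pct");
  int n_crec = (c_record_every > 0) ? (n_steps + c_record_every - 1) / c_record_every : 0;
  NumericMatrix cbins(n_crec, nb + 1);
  NumericVector crec_t(n_crec);
  int crow = 0;

  std::vector<double> conc(nb + 1), count(nb + 1);
  std::vector<double> iflux_na(nb), iflux_k(nb);

  // raw column pointers into the position matrix and alive flags
  double* PX = REAL((SEXP)pos);
  double* PY = PX + npart;
  double* PZ = PY + npart;
  int* AL = LOGICAL((SEXP)alive);

  // the in-cleft predicate: pitch > apposition width, so |x|,|y| <= half
  // already implies the central cell
  std::vector<char> fincleft(npart);
  for (int i = 0; i < npart; ++i)
    fincleft[i] = AL[i] && std::fabs(PX[i]) <= half &&
      std::fabs(PY[i]) <= half && PZ[i] >= 0.0 && PZ[i] <= delta;

  const double sl_in  = std::sqrt(6.0 * D_in * dt);
  const double sl_out = std::sqrt(6.0 * D_out * dt);
  const double sd_in  = std::sqrt(2.0 * D_in * dt);
  const double sd_out = std::sqrt(2.0 * D_out * dt);

  for (int s = 0; s < n_steps; ++s) {
    const int gstep = step0 + s;
    const double vm = vmvec[gstep];

    if (!released && gstep >= release_step) released = true;

    // (1) move particles (Brownian + previous-step field drift, boundary
    // handling) and (2) rebuild the radial concentration profile of the
    // central cleft in the same pass
    std::fill(count.begin(), count.end(), 0.0);
    int ncleft = 0;
    if (released && npart > 0) {
      // field parameters of the previous step
      double lambda = 0, den = 1, I1L = 0;
      bool drift_now = field_on && L_prev > 0;
      if (drift_now) {
        lambda = ra / L_prev;
        I1L = std::cyl_bessel_i(1.0, L_prev);
        den = std::cyl_bessel_i(0.0, L_prev) + L_prev * I1L * std::log(Rout / ra);
      }
      for (int i = 0; i < npart; ++i) {
        if (!AL[i]) continue;
        double x = PX[i], y = PY[i], z = PZ[i];
        bool incleft = fincleft[i];
        double d[3];
        if (stepmode == 0) {
          unit_dir(seed, (uint64_t)i, (uint64_t)gstep, d);
          double sl = incleft ? sl_in : sl_out;
          d[0] *= sl; d[1] *= sl; d[2] *= sl;
        } else {
          gauss3(seed, (uint64_t)i, (uint64_t)gstep, d);
          double sd = incleft ? sd_in : sd_out;
          d[0] *= sd; d[1] *= sd; d[2] *= sd;
        }
        double nx = x + d[0], ny = y + d[1], nz = z + d[2];
        if (incleft && drift_now) {
          double r = std::sqrt(x * x + y * y);
          if (r > 1e-9 && r < Rout) {
            // v_r = mu * dV/dr (force from the extracellular cleft
            // potential phi = Vo - V; see drift_displacement())
            double dvdr = (r < ra)
              ? vm_prev * i1_fast(r / lambda) / (lambda * den)
              : vm_prev * L_prev * I1L / (r * den);
            double f = mu * dvdr * dt / r;
            nx += x * f; ny += y * f;
          }
        }
        // boundaries: reflect off solids (nearest-face specular), max 5 passes
        for (int pass = 0; pass < 5; ++pass) {
          double cx = pitch * std::round(nx / pitch);
          double cy = pitch * std::round(ny / pitch);
          double dxc = nx - cx, dyc = ny - cy;
          if (std::fabs(dxc) > half || std::fabs(dyc) > half) break;
          bool lower = (nz < 0.0 && nz > -H);
          bool upper = (nz > delta && nz < delta + H);
          if (!lower && !upper) break;
          double px = half - std::fabs(dxc);
          double py = half - std::fabs(dyc);
          double z_near = lower ? 0.0 : delta;
          double z_far  = lower ? -H  : delta + H;
          double pzn = std::fabs(nz - z_near);
          double pzf = std::fabs(nz - z_far);
          double pmin = std::min(std::min(px, py), std::min(pzn, pzf));
          if (pmin > max_embed)
            stop("particle embedded %.2f nm inside a solid: time step too large", pmin);
          if (pmin == px)
            nx = cx + ((dxc >= 0) ? 1.0 : -1.0) * (2.0 * half - std::fabs(dxc));
          else if (pmin == py)
            ny = cy + ((dyc >= 0) ? 1.0 : -1.0) * (2.0 * half - std::fabs(dyc));
          else if (pmin == pzn) nz = 2.0 * z_near - nz;
          else nz = 2.0 * z_far - nz;
        }
        PX[i] = nx; PY[i] = ny; PZ[i] = nz;
        if (nx * nx + ny * ny + nz * nz > esc2) {
          AL[i] = 0;
          fincleft[i] = 0;
          continue;
        }
        bool inc = std::fabs(nx) <= half && std::fabs(ny) <= half &&
          nz >= 0.0 && nz <= delta;
        fincleft[i] = inc;
        if (inc) {
          double r = std::sqrt(nx * nx + ny * ny);
          int b = (r >= Rout) ? nb : std::min((int)(r / binw), nb - 1);
          count[b] += 1.0;
          ++ncleft;
        }
      }
    }
    for (int b = 0; b <= nb; ++b) conc[b] = KCONC * count[b] / vol[b];

    // (3) receptor occupancies from local concentration
    for (auto& g : groups) {
      build_Q(g, conc[g.bin]);
      propagate(g, dt);
    }

    // (4) currents, ions, next-step field
    double mgf = 1.0;
    if (mg_mM > 0)  // standard voltage-dependent Mg block factor (NMDAR)
      mgf = 1.0 / (1.0 + mg_mM / 3.57 * std::exp(-0.062 * vm));
    double g_open[3] = {0, 0, 0}, psum[3] = {0, 0, 0}, cnt[3] = {0, 0, 0};
    double active_sum = 0, active_cnt = 0;
    std::fill(iflux_na.begin(), iflux_na.end(), 0.0);
    std::fill(iflux_k.begin(), iflux_k.end(), 0.0);
    for (auto& g : groups) {
      double po = 0;
      for (int j : g.open_idx) po += g.p[j];
      double geff = g.count * g.gamma_pS * po * (1.0 - g.block) * gscale;
      if (g.type == 1) geff *= mgf;
      g_open[g.type] += geff;
      psum[g.type] += g.count * po;
      cnt[g.type] += g.count;
      if (g.type == 2) {
        double pa = 0;
        for (int j : g.active_idx) pa += g.p[j];
        active_sum += g.count * pa;
        active_cnt += g.count;
      }
      if (ions_on && g.gamma_pS > 0 && g.bin < nb) {
        iflux_na[g.bin] += geff * f_na * (vm - e_na) / 1000.0;  // pA
        iflux_k[g.bin]  += geff * f_k  * (vm - e_k)  / 1000.0;
      }
    }
    double i_ampar = g_open[0] * (vm - erev_a) / 1000.0;  // pA
    double i_nmdar = g_open[1] * (vm - erev_n) / 1000.0;

    double dev[3] = {0, 0, 0};
    if (ions_on) {
      // channel flux into bins, Cl- electroneutral, then radial diffusion
      for (int b = 0; b < nb; ++b) {
        double dna = iflux_na[b] * dt * 1e12 / (FARADAY * vol[b]);
        double dk  = iflux_k[b]  * dt * 1e12 / (FARADAY * vol[b]);
        ionc(b, 0) += dna;
        ionc(b, 1) += dk;
        ionc(b, 2) += dna + dk;
      }
      double h = dt / ion_sub;
      for (int io = 0; io < 3; ++io) {
        double D = ion_D[io];
        for (int ss = 0; ss < ion_sub; ++ss) {
          double Jprev = 0.0;
          double c0 = ionc(0, io);
          for (int b = 0; b < nb - 1; ++b) {
            double J = -D * (ionc(b + 1, io) - c0) / ctr_dr[b] * iface_area[b];
            double cnew = c0 + h * (Jprev - J) / vol[b];
            c0 = ionc(b + 1, io);
            ionc(b, io) = cnew;
            Jprev = J;
          }
          ionc(nb - 1, io) = ion_base[io];  // edge clamped to bath
        }
        double base = ion_base[io];
        if (base > 0)
          for (int b = 0; b < nb; ++b) {
            if (ionc(b, io) < 0)
              stop("negative ion concentration: time step too large");
            dev[io] = std::max(dev[io], std::fabs(ionc(b, io) - base) / base * 100.0);
          }
      }
    }

    // field for the next duty cycle
    double g_tot_S = (g_open[0] + g_open[1]) * 1e-12;
    L_prev = std::sqrt(g_tot_S * rex / (M_PI * delta * 1e-9));
    vm_prev = vm;

    traces(s, 0) = (gstep + 1) * dt;
    traces(s, 1) = vm;
    traces(s, 2) = L_prev;
    traces(s, 3) = ncleft;
    traces(s, 4) = i_ampar;
    traces(s, 5) = i_nmdar;
    traces(s, 6) = cnt[0] > 0 ? psum[0] / cnt[0] : 0.0;
    traces(s, 7) = cnt[1] > 0 ? psum[1] / cnt[1] : 0.0;
    traces(s, 8) = active_cnt > 0 ? active_sum / active_cnt : 0.0;
    traces(s, 9)  = dev[0];
    traces(s, 10) = dev[1];
    traces(s, 11) = dev[2];

    if (c_record_every > 0 && s % c_record_every == 0) {
      for (int b = 0; b <= nb; ++b) cbins(crow, b) = conc[b];
      crec_t[crow] = (gstep + 1) * dt;
      ++crow;
    }
  }

  // write receptor states back
  for (int gi = 0; gi < glist.size(); ++gi) {
    List gl = glist[gi];
    gl["p"] = wrap(groups[gi].p);
    glist[gi] = gl;
  }
  state["groups"] = glist;
  state["step"] = step0 + n_steps;
  state["released"] = released;
  state["L_prev"] = L_prev;
  state["vm_prev"] = vm_prev;
  state["pos"] = pos;
  state["alive"] = alive;
  ion["conc_mM"] = ionc;
  state["ions"] = ion;

  colnames(traces) = tracenames;
  return List::create(_["state"] = state, _["traces"] = traces,
                      _["c_bins"] = cbins, _["c_t_ms"] = crec_t);
}
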