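// Conductance-based spiking network core: Wang-Buzsaki neurons, bi-exponential
// synapses with conduction delays, per-neuron Poisson background drive and an
// optional light-evoked (ChR2) conductance shared per area. The integrator is
// exponential-Euler for the gating variables and forward Euler for the
// membrane potential at a fixed step. All stochasticity lives in per-neuron
// counter-seeded RNG streams whose state is part of the serialisable
// simulation state, so that perturbed/unperturbed run pairs share identical
// noise ("frozen noise") and runs can be checkpointed and resumed
// bit-identically.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
#include <cstdint>
using namespace Rcpp;

static inline uint64_t splitmix64_next(uint64_t &x) {
  x += 0x9E3779B97f4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// xorshift128+ stream, 16 bytes of state per neuron
struct RngStream {
  uint64_t s0, s1;
  double unif() { // in (0, 1]
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    uint64_t r = s1 + y;
    return ((r >> 11) + 1) * (1.0 / 9007199254740992.0);
  }
};

// Wang-Buzsaki gating rate functions (V in mV, rates in 1/ms)
static inline double wb_am(double V) {
  double d = V + 35.0;
  if (std::fabs(d) < 1e-6) return 1.0;
  return 0.1 * d / (1.0 - std::exp(-d / 10.0));
}
static inline double wb_bm(double V) { return 4.0 * std::exp(-(V + 60.0) / 18.0); }
static inline double wb_ah(double V) { return 0.07 * std::exp(-(V + 58.0) / 20.0); }
static inline double wb_bh(double V) { return 1.0 / (1.0 + std::exp(-(V + 28.0) / 10.0)); }
static inline double wb_an(double V) {
  double d = V + 34.0;
  if (std::fabs(d) < 1e-6) return 0.1;
  return 0.01 * d / (1.0 - std::exp(-d / 10.0));
}
static inline double wb_bn(double V) { return 0.125 * std::exp(-(V + 44.0) / 80.0); }

// peak-normalisation constant of the bi-exponential kernel
static inline double kernel_norm(double tr, double td) {
  double tpk = tr * td / (td - tr) * std::log(td / tr);
  return 1.0 / (std::exp(-tpk / td) - std::exp(-tpk / tr));
}

// [[Rcpp::export]]
List wb_run_cpp(List net, List prm, double duration_ms, List glight,
                Nullable<List> state_in, NumericVector init_v,
                double noise_seed, double nu_noise_khz,
                NumericVector checkpoint_times, bool record_v,
                int sample_every) {
  const IntegerVector adj = net["adj"];        // 0-based targets
  const IntegerVector adj_ptr = net["adj_ptr"]; // length n+1
  const IntegerVector cls = net["cls"];        // per-edge class (0-based)
  const IntegerVector area = net["area"];      // 0-based area per neuron
  const NumericVector kappa = net["kappa"];
  const int n = area.size();
  const int n_areas = net["n_areas"];

  const double dt = prm["dt"];
  const double C = prm["C"], gL = prm["gL"], VL = prm["VL"];
  const double gNa = prm["gNa"], VNa = prm["VNa"];
  const double gK = prm["gK"], VK = prm["VK"];
  const double phi = prm["phi"], v_thresh = prm["v_thresh"];
  const NumericMatrix classes = prm["classes"]; // cols: tr, td, delay, g, vrev
  const int ncls = classes.nrow();              // last class = noise (delay 0)
  const int noise_cls = ncls - 1;

  std::vector<double> er(ncls), ed(ncls), gnorm(ncls), vrev(ncls);
  std::vector<int> dsteps(ncls), ringlen(ncls);
  for (int c = 0; c < ncls; ++c) {
    double tr = classes(c, 0), td = classes(c, 1);
    if (tr >= td) stop("synaptic kernel requires tau_decay > tau_rise");
    er[c] = std::exp(-dt / tr);
    ed[c] = std::exp(-dt / td);
    gnorm[c] = classes(c, 3) * kernel_norm(tr, td);
    vrev[c] = classes(c, 4);
    dsteps[c] = (int)std::lround(classes(c, 2) / dt);
    ringlen[c] = dsteps[c] + 1;
  }

  const long nsteps = (long)std::lround(duration_ms / dt);

  // --- state ---------------------------------------------------------
  std::vector<double> V(n), h(n), nv(n);
  std::vector<double> xr(n * ncls, 0.0), xd(n * ncls, 0.0);
  std::vector< std::vector<double> > ring(ncls);
  std::vector<double> next_noise(n);
  std::vector<RngStream> rng(n);
  long step0 = 0;

  for (int c = 0; c < ncls; ++c) ring[c].assign((size_t)ringlen[c] * n, 0.0);

  if (state_in.isNotNull()) {
    List st(state_in);
    double t0 = st["t"];
    step0 = (long)std::lround(t0 / dt);
    NumericVector sV = st["V"], sh = st["h"], sn = st["n"];
    NumericVector sxr = st["xr"], sxd = st["xd"], snn = st["next_noise"];
    for (int i = 0; i < n; ++i) {
      V[i] = sV[i]; h[i] = sh[i]; nv[i] = sn[i]; next_noise[i] = snn[i];
    }
    std::copy(sxr.begin(), sxr.end(), xr.begin());
    std::copy(sxd.begin(), sxd.end(), xd.begin());
    List srings = st["rings"];
    for (int c = 0; c < ncls; ++c) {
      NumericVector rc = srings[c];
      std::copy(rc.begin(), rc.end(), ring[c].begin());
    }
    RawVector rraw = st["rng"];
    std::memcpy(&rng[0], RAW(rraw), (size_t)n * sizeof(RngStream));
  } else {
    uint64_t master = (uint64_t)noise_seed;
    for (int i = 0; i < n; ++i) {
      uint64_t s = master * 0x100000001B3ULL + (uint64_t)i;
      rng[i].s0 = splitmix64_next(s);
      rng[i].s1 = splitmix64_next(s);
      V[i] = init_v[i];
      double ah = wb_ah(V[i]), bh = wb_bh(V[i]);
      double an = wb_an(V[i]), bn = wb_bn(V[i]);
      h[i] = ah / (ah + bh);
      nv[i] = an / (an + bn);
      next_noise[i] = nu_noise_khz > 0
        ? -std::log(rng[i].unif()) / nu_noise_khz : R_PosInf;
    }
  }

  // --- per-area light conductance traces (nS), one value per local step
  std::vector<const double*> gl(n_areas, (const double*)nullptr);
  std::vector<long> gl_len(n_areas, 0);
  std::vector<NumericVector> gl_keep;
  for (int a = 0; a < n_areas && a < glight.size(); ++a) {
    if (!Rf_isNull(glight[a])) {
      gl_keep.push_back(as<NumericVector>(glight[a]));
      gl[a] = gl_keep.back().begin();
      gl_len[a] = gl_keep.back().size();
    }
  }

  // --- recording -----------------------------------------------------
  const long nsamp = nsteps / sample_every;
  NumericMatrix lfp(nsamp, n_areas);
  NumericVector lfp_t(nsamp);
  NumericMatrix vrec(record_v ? nsamp : 0, record_v ? n : 0);
  std::vector<int> area_count(n_areas, 0);
  for (int i = 0; i < n; ++i) area_count[area[i]]++;
  std::vector<int> sp_id; std::vector<double> sp_t;
  sp_id.reserve(4096); sp_t.reserve(4096);

  // checkpoints (absolute times, must align with the step grid)
  std::vector<long> cp_steps(checkpoint_times.size());
  for (int k = 0; k < checkpoint_times.size(); ++k)
    cp_steps[k] = (long)std::lround(checkpoint_times[k] / dt);
  List cp_out(checkpoint_times.size());
  int cp_next = 0;

  auto snapshot = [&](long step_abs) -> List {
    NumericVector sV(n), sh(n), sn(n), snn(n);
    NumericVector sxr(xr.size()), sxd(xd.size());
    for (int i = 0; i < n; ++i) {
      sV[i] = V[i]; sh[i] = h[i]; sn[i] = nv[i]; snn[i] = next_noise[i];
    }
    std::copy(xr.begin(), xr.end(), sxr.begin());
    std::copy(xd.begin(), xd.end(), sxd.begin());
    List srings(ncls);
    for (int c = 0; c < ncls; ++c) {
      NumericVector rc(ring[c].size());
      std::copy(ring[c].begin(), ring[c].end(), rc.begin());
      srings[c] = rc;
    }
    RawVector rraw((size_t)n * sizeof(RngStream));
    std::memcpy(RAW(rraw), &rng[0], (size_t)n * sizeof(RngStream));
    return List::create(_["t"] = step_abs * dt, _["V"] = sV, _["h"] = sh,
                        _["n"] = sn, _["xr"] = sxr, _["xd"] = sxd,
                        _["rings"] = srings, _["next_noise"] = snn,
                        _["rng"] = rraw);
  };

  long samp_i = 0;
  for (long k = 0; k < nsteps; ++k) {
    const long s_abs = step0 + k;
    const double t = s_abs * dt;

    while (cp_next < (int)cp_steps.size() && cp_steps[cp_next] == s_abs) {
      cp_out[cp_next] = snapshot(s_abs);
      ++cp_next;
    }

    // apply delayed synaptic arrivals and decay the filters
    for (int c = 0; c < ncls; ++c) {
      double *rg = &ring[c][(size_t)(s_abs % ringlen[c]) * n];
      double erc = er[c], edc = ed[c];
      double *xrc = &xr[(size_t)c * n], *xdc = &xd[(size_t)c * n];
      for (int i = 0; i < n; ++i) {
        double a = rg[i];
        xrc[i] = xrc[i] * erc + a;
        xdc[i] = xdc[i] * edc + a;
        rg[i] = 0.0;
      }
    }

    // Poisson background events (event times strictly reproducible)
    if (nu_noise_khz > 0) {
      double *xrn = &xr[(size_t)noise_cls * n], *xdn = &xd[(size_t)noise_cls * n];
      for (int i = 0; i < n; ++i) {
        while (next_noise[i] <= t) {
          xrn[i] += 1.0; xdn[i] += 1.0;
          next_noise[i] += -std::log(rng[i].unif()) / nu_noise_khz;
        }
      }
    }

    // membrane update
    for (int i = 0; i < n; ++i) {
      const double v = V[i];
      const double am = wb_am(v), bm = wb_bm(v);
      const double minf = am / (am + bm);
      const double ah = wb_ah(v), bh = wb_bh(v);
      const double an = wb_an(v), bn = wb_bn(v);
      // exponential Euler on h, n
      const double rh = phi * (ah + bh), rn = phi * (an + bn);
      h[i] += (ah / (ah + bh) - h[i]) * (1.0 - std::exp(-dt * rh));
      nv[i] += (an / (an + bn) - nv[i]) * (1.0 - std::exp(-dt * rn));

      // collect total conductance and conductance-weighted reversal; the
      // membrane is then advanced by exponential Euler on
      // dV/dt = -(g_tot/C) (V - V_eff), unconditionally stable even under
      // the large compensated conductances of scaled networks
      double gtot = gL;
      double gv = gL * VL;
      double gna_eff = gNa * minf * minf * minf * h[i];
      gtot += gna_eff; gv += gna_eff * VNa;
      double gk_eff = gK * nv[i] * nv[i] * nv[i] * nv[i];
      gtot += gk_eff; gv += gk_eff * VK;
      for (int c = 0; c < ncls; ++c) {
        const double s = xd[(size_t)c * n + i] - xr[(size_t)c * n + i];
        const double ge = gnorm[c] * s;
        gtot += ge; gv += ge * vrev[c];
      }
      if (kappa[i] > 0.0 && gl[area[i]] && k < gl_len[area[i]]) {
        gtot += kappa[i] * gl[area[i]][k]; // V_ChR2 = 0 adds nothing to gv
      }
      const double veff = gv / gtot;
      const double vnew = veff + (v - veff) * std::exp(-dt * gtot / C);
      if (!(vnew > -200.0 && vnew < 200.0)) {
        stop("membrane potential out of range (|V| > 200 mV) for neuron %d at t = %.2f ms: numerical blow-up", i + 1, t);
      }
      // spike: upward threshold crossing
      if (vnew >= v_thresh && v < v_thresh) {
        sp_id.push_back(i + 1);
        sp_t.push_back(t + dt);
        for (int e = adj_ptr[i]; e < adj_ptr[i + 1]; ++e) {
          const int c = cls[e];
          const long slot = (s_abs + dsteps[c]) % ringlen[c];
          ring[c][(size_t)slot * n + adj[e]] += 1.0;
        }
      }
      V[i] = vnew;
    }

    // sampling
    if ((s_abs + 1) % sample_every == 0) {
      if (samp_i < nsamp) {
        std::vector<double> acc(n_areas, 0.0);
        for (int i = 0; i < n; ++i) acc[area[i]] += V[i];
        for (int a = 0; a < n_areas; ++a) lfp(samp_i, a) = acc[a] / area_count[a];
        lfp_t[samp_i] = t + dt;
        if (record_v) for (int i = 0; i < n; ++i) vrec(samp_i, i) = V[i];
        ++samp_i;
      }
    }
  }

  List state_out = snapshot(step0 + nsteps);
  return List::create(
    _["spike_id"] = IntegerVector(sp_id.begin(), sp_id.end()),
    _["spike_t"] = NumericVector(sp_t.begin(), sp_t.end()),
    _["lfp"] = lfp, _["lfp_t"] = lfp_t,
    _["v"] = vrec,
    _["state"] = state_out,
    _["checkpoints"] = cp_out);
}
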