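// Batched integrator for the collicular neural field.
//
// The eight component inputs are piecewise-linear in time with fixed Gaussian
// spatial profiles, so their per-step increments admit exact closed forms;
// the external contribution is evaluated directly at each time point (the
// pure-R reference engine applies the literal per-step increments and the two
// are verified equivalent in the test suite). The lateral term W * a is one
// BLAS dgemm per step across all still-active trials; finished trials are
// compacted out. Pre-stimulus dynamics depend only on (onset delay,
// vol-prep/vol-fix/gate/periph-inhib MaxVal), so the caller may deduplicate
// trials into shared pre-stimulus configurations.

#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <vector>
#include <cmath>

#ifndef FCONE
#define FCONE
#endif

using namespace Rcpp;

namespace {

struct Ctx {
  int n;                       // nodes
  double dt, tau, beta, threshold, amp;
  double t_start, fix_off, stim_on, t_max;
  // fixed input attributes
  double vt_delay, vt_ror, vt_max, vt_rise;
  double am_delay, af_delay, af_ror, af_max, vf_ror;
  double crosstalk;            // 0 = disabled
  // spatial profiles (length n)
  const double *kS;            // stimulus site
  const double *kM;            // mirror of stimulus site
  const double *kF;            // fovea
  const double *kP;            // two-peaked preparation profile
  const double *piShape;       // peripheral-inhibition shape (1 - kF/amp)
  const double *W;             // n x n lateral weights, column-major
  const double *x;             // node positions (mm)
  std::vector<int> elig;       // eligible node indices (0-based)
};

// per-column trial parameters, kept compacted alongside the state columns
struct Cols {
  std::vector<double> delay, amror, ammax, vmror, vfmax, vpror, vpmax,
      gror, gmax, piror, pimax;
  std::vector<int> anti, owner;  // owner: output slot for this column
  int size() const { return (int)owner.size(); }
  void copy_col(int dst, int src) {
    delay[dst] = delay[src]; amror[dst] = amror[src]; ammax[dst] = ammax[src];
    vmror[dst] = vmror[src]; vfmax[dst] = vfmax[src]; vpror[dst] = vpror[src];
    vpmax[dst] = vpmax[src]; gror[dst] = gror[src]; gmax[dst] = gmax[src];
    piror[dst] = piror[src]; pimax[dst] = pimax[src];
    anti[dst] = anti[src]; owner[dst] = owner[src];
  }
  void resize(int b) {
    delay.resize(b); amror.resize(b); ammax.resize(b); vmror.resize(b);
    vfmax.resize(b); vpror.resize(b); vpmax.resize(b); gror.resize(b);
    gmax.resize(b); piror.resize(b); pimax.resize(b);
    anti.resize(b); owner.resize(b);
  }
};

inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// external contribution for column b at time t
void build_cext(const Ctx &cx, const Cols &cp, int b, double t, double *out) {
  const int n = cx.n;
  // shared (stimulus-locked) amplitudes
  double phiVT = 0.0;
  double dvt = t - (cx.stim_on + cx.vt_delay);
  if (dvt > 0) {
    phiVT = cx.vt_ror * std::min(dvt, cx.vt_rise) -
            0.5 * cx.vt_ror * std::max(0.0, dvt - cx.vt_rise);
    phiVT = clampd(phiVT, 0.0, cx.vt_max / cx.amp);
  }
  double afA = cx.af_max / cx.amp -
               cx.af_ror * std::max(0.0, t - (cx.fix_off + cx.af_delay));
  if (afA < 0) afA = 0;
  // per-trial amplitudes
  double dvol = std::max(0.0, t - (cx.stim_on + cp.delay[b]));
  double amA = std::min(cp.amror[b] * std::max(0.0, t - (cx.stim_on + cx.am_delay)),
                        cp.ammax[b] / cx.amp);
  double vmA = cp.vmror[b] * dvol;
  double vfA = std::max(0.0, cp.vfmax[b] / cx.amp - cx.vf_ror * dvol);
  double ramp = (cx.stim_on - cx.t_start) - cp.delay[b];
  double vpA = cp.vpror[b] *
               clampd(t - (cx.t_start + cp.delay[b]), 0.0, ramp);
  double gO = cp.gror[b] * dvol;
  double piR = cx.amp * cp.piror[b] * dvol;
  double gmaxb = cp.gmax[b], pimaxb = cp.pimax[b];
  const double *kg = cp.anti[b] ? cx.kM : cx.kS;
  const double *kgm = cp.anti[b] ? cx.kS : cx.kM;  // mirror of goal profile
  const double xf = cx.crosstalk;
  for (int i = 0; i < n; ++i) {
    double am = cx.kS[i] * amA;   // profile-shaped cap via amA
    if (xf > 0) {
      am -= xf * kgm[i] * vmA;
      if (am < 0) am = 0;
    }
    double vp = cx.kP[i] * vpA;
    double gate = kg[i] * gO - gmaxb;
    if (gate > 0) gate = 0;
    double peri = piR - pimaxb * cx.piShape[i];
    if (peri > 0) peri = 0;
    out[i] = cx.kS[i] * phiVT + am + cx.kF[i] * afA + kg[i] * vmA +
             cx.kF[i] * vfA + vp + gate + peri;
  }
}

// winning node among eligible crossings; -1 if none
int detect_col(const Ctx &cx, const double *a) {
  int best = -1;
  double abest = -1.0, xbest = 0.0;
  for (size_t e = 0; e < cx.elig.size(); ++e) {
    int i = cx.elig[e];
    double ai = a[i];
    if (ai < cx.threshold) continue;
    if (best < 0 || ai > abest ||
        (ai == abest && (std::fabs(cx.x[i]) < std::fabs(xbest) ||
                         (std::fabs(cx.x[i]) == std::fabs(xbest) &&
                          cx.x[i] < xbest)))) {
      best = i; abest = ai; xbest = cx.x[i];
    }
  }
  return best;
}

// Step the active columns over (t0, t1]. U/A are n x B column-major.
// srt/node are indexed by column owner. If stop_at_cross, finished columns
// are removed (B shrinks). Trace buffers, when given, receive u and a after
// every step (columns must not be compacted: callers pass stop_at_cross =
// false when tracing).
void run_span(const Ctx &cx, Cols &cp, std::vector<double> &U,
              std::vector<double> &A, int &B, double t0, double t1,
              bool stop_at_cross, double *srt, int *node,
              double *traceU, double *traceA, R_xlen_t traceOffset,
              const std::vector<int> &trial_ids) {
  const int n = cx.n;
  long nsteps = (long)std::llround((t1 - t0) / cx.dt);
  std::vector<double> Cext(U.size());
  std::vector<double> Cint(U.size());
  const double r = cx.dt / cx.tau, keep = 1.0 - r;
  const double one = 1.0, zero = 0.0;
  for (long s = 1; s <= nsteps && B > 0; ++s) {
    double t_new = t0 + s * cx.dt;
    // inputs are advanced to the new time point before the field update
    for (int b = 0; b < B; ++b) build_cext(cx, cp, b, t_new, &Cext[(size_t)b * n]);
    // c_int = W * a(t_prev)
    F77_CALL(dgemm)("N", "N", &n, &B, &n, &one, cx.W, &n, A.data(), &n,
                    &zero, Cint.data(), &n FCONE FCONE);
    bool any_done = false;
    std::vector<char> done(stop_at_cross ? B : 0, 0);
    for (int b = 0; b < B; ++b) {
      double *u = &U[(size_t)b * n];
      double *a = &A[(size_t)b * n];
      const double *ce = &Cext[(size_t)b * n];
      const double *ci = &Cint[(size_t)b * n];
      bool finite = true;
      for (int i = 0; i < n; ++i) {
        double ui = keep * u[i] + r * (ce[i] + ci[i]);
        u[i] = ui;
        a[i] = 1.0 / (1.0 + std::exp(-cx.beta * ui));
        finite = finite && std::isfinite(ui);
      }
      if (!finite)
        stop("non-finite internal state in trial %d", trial_ids[cp.owner[b]]);
      if (ISNA(srt[cp.owner[b]])) {
        int w = detect_col(cx, a);
        if (w >= 0) {
          srt[cp.owner[b]] = t_new;
          node[cp.owner[b]] = w + 1;  // 1-based
          if (stop_at_cross) { done[b] = 1; any_done = true; }
        }
      }
    }
    if (traceU) {
      R_xlen_t off = traceOffset + (R_xlen_t)(s - 1) * n * B;
      std::copy(U.begin(), U.begin() + (size_t)n * B, traceU + off);
      std::copy(A.begin(), A.begin() + (size_t)n * B, traceA + off);
    }
    if (any_done) {  // stable compaction of the surviving columns
      int dst = 0;
      for (int src = 0; src < B; ++src) {
        if (done[src]) continue;
        if (dst != src) {
          std::copy(U.begin() + (size_t)src * n, U.begin() + (size_t)(src + 1) * n,
                    U.begin() + (size_t)dst * n);
          std::copy(A.begin() + (size_t)src * n, A.begin() + (size_t)(src + 1) * n,
                    A.begin() + (size_t)dst * n);
          cp.copy_col(dst, src);
        }
        ++dst;
      }
      B = dst;
    }
    if ((s & 63) == 0) Rcpp::checkUserInterrupt();
  }
}

}  // namespace

// [[Rcpp::export]]
List sim_batch_cpp(List par, List tl, List trials, List opts) {
  Ctx cx;
  cx.n = as<int>(par["n_nodes"]);
  cx.dt = as<double>(par["dt"]);
  cx.tau = as<double>(par["tau"]);
  cx.beta = as<double>(par["beta"]);
  cx.threshold = as<double>(par["threshold"]);
  cx.amp = as<double>(par["input_amp"]);
  double resting = as<double>(par["resting_potential"]);
  cx.t_start = as<double>(tl["fixation_acquired_t"]);
  cx.fix_off = as<double>(tl["fixation_off_t"]);
  cx.stim_on = as<double>(tl["stimulus_on_t"]);
  cx.t_max = as<double>(tl["max_sim_t"]);
  cx.vt_delay = as<double>(opts["vt_delay"]);
  cx.vt_ror = as<double>(opts["vt_ror"]);
  cx.vt_max = as<double>(opts["vt_max"]);
  cx.vt_rise = as<double>(opts["vt_rise"]);
  cx.am_delay = as<double>(opts["am_delay"]);
  cx.af_delay = as<double>(opts["af_delay"]);
  cx.af_ror = as<double>(opts["af_ror"]);
  cx.af_max = as<double>(opts["af_max"]);
  cx.vf_ror = as<double>(opts["vf_ror"]);
  cx.crosstalk = as<double>(opts["crosstalk"]);
  bool trace = as<bool>(opts["trace"]);
  bool dedup = as<bool>(opts["dedup"]);

  NumericVector kS = par["k_stim"], kM = par["k_mirror"], kF = par["k_fix"],
                kP = par["k_prep"], piShape = par["pi_shape"], xpos = par["x"];
  NumericMatrix W = par["w"];
  IntegerVector elig = par["eligible"];  // 0-based
  cx.kS = kS.begin(); cx.kM = kM.begin(); cx.kF = kF.begin();
  cx.kP = kP.begin(); cx.piShape = piShape.begin(); cx.W = W.begin();
  cx.x = xpos.begin();
  cx.elig.assign(elig.begin(), elig.end());

  NumericVector delay = trials["onset_delay"], amror = trials["am_ror"],
                ammax = trials["am_max"], vmror = trials["vm_ror"],
                vfmax = trials["vf_max"], vpror = trials["vp_ror"],
                vpmax = trials["vp_max"], gror = trials["gate_ror"],
                gmax = trials["gate_max"], piror = trials["pi_ror"],
                pimax = trials["pi_max"];
  IntegerVector anti = trials["anti"], id = trials["trial_id"];
  const int nT = delay.size();
  std::vector<int> trial_ids(id.begin(), id.end());

  NumericVector srt(nT, NA_REAL);
  IntegerVector node(nT, NA_INTEGER);

  const int n = cx.n;
  double a_rest = 1.0 / (1.0 + std::exp(-cx.beta * resting));

  auto fill_cols = [&](Cols &cp, const std::vector<int> &idx) {
    cp.resize((int)idx.size());
    for (size_t k = 0; k < idx.size(); ++k) {
      int b = idx[k];
      cp.delay[k] = delay[b]; cp.amror[k] = amror[b]; cp.ammax[k] = ammax[b];
      cp.vmror[k] = vmror[b]; cp.vfmax[k] = vfmax[b]; cp.vpror[k] = vpror[b];
      cp.vpmax[k] = vpmax[b]; cp.gror[k] = gror[b]; cp.gmax[k] = gmax[b];
      cp.piror[k] = piror[b]; cp.pimax[k] = pimax[b];
      cp.anti[k] = anti[b]; cp.owner[k] = b;
    }
  };

  NumericVector traceU(0), traceA(0);
  long nsteps_total = (long)std::llround((cx.t_max - cx.t_start) / cx.dt);

  if (!dedup) {
    // every trial simulated as its own column over the full timeline
    if (trace) {
      if (nT > 64) stop("tracing is limited to 64 trials");
      traceU = NumericVector((R_xlen_t)n * nT * nsteps_total);
      traceA = NumericVector((R_xlen_t)n * nT * nsteps_total);
    }
    Cols cp;
    std::vector<int> all(nT);
    for (int b = 0; b < nT; ++b) all[b] = b;
    fill_cols(cp, all);
    int B = nT;
    std::vector<double> U((size_t)n * nT, resting), A((size_t)n * nT, a_rest);
    run_span(cx, cp, U, A, B, cx.t_start, cx.t_max, !trace, srt.begin(),
             node.begin(), trace ? traceU.begin() : nullptr,
             trace ? traceA.begin() : nullptr, 0, trial_ids);
    List out = List::create(_["srt"] = srt, _["node"] = node);
    if (trace) {
      traceU.attr("dim") = IntegerVector::create(n, nT, (int)nsteps_total);
      traceA.attr("dim") = IntegerVector::create(n, nT, (int)nsteps_total);
      out["trace_u"] = traceU;
      out["trace_a"] = traceA;
      out["trace_t"] = cx.t_start +
        cx.dt * as<NumericVector>(wrap(seq_len((int)nsteps_total)));
    }
    return out;
  }

  // phase A: shared pre-stimulus configurations
  IntegerVector cfg_of = trials["config_id"];     // 0-based, length nT
  IntegerVector cfg_rep = trials["config_rep"];   // 0-based trial index per config
  const int nC = cfg_rep.size();
  Cols cpa;
  std::vector<int> reps(cfg_rep.begin(), cfg_rep.end());
  fill_cols(cpa, reps);
  for (int c = 0; c < nC; ++c) cpa.owner[c] = c;
  NumericVector srtC(nC, NA_REAL);
  IntegerVector nodeC(nC, NA_INTEGER);
  std::vector<double> Uc((size_t)n * nC, resting), Ac((size_t)n * nC, a_rest);
  // keep all configs stepping to the stimulus even if one crosses early:
  // crossings are recorded but the shared state must exist for every config
  int Bc = nC;
  run_span(cx, cpa, Uc, Ac, Bc, cx.t_start, cx.stim_on, false, srtC.begin(),
           nodeC.begin(), nullptr, nullptr, 0, trial_ids);

  // trials whose configuration crossed before the stimulus are anticipatory
  std::vector<int> live;
  live.reserve(nT);
  for (int b = 0; b < nT; ++b) {
    int c = cfg_of[b];
    if (!ISNA(srtC[c])) { srt[b] = srtC[c]; node[b] = nodeC[c]; }
    else live.push_back(b);
  }

  // phase B: expand configurations into trial columns and run to t_max
  Cols cpb;
  fill_cols(cpb, live);
  int B = (int)live.size();
  std::vector<double> U((size_t)n * std::max(B, 1)),
                      A((size_t)n * std::max(B, 1));
  for (int k = 0; k < B; ++k) {
    int c = cfg_of[live[k]];
    std::copy(Uc.begin() + (size_t)c * n, Uc.begin() + (size_t)(c + 1) * n,
              U.begin() + (size_t)k * n);
    std::copy(Ac.begin() + (size_t)c * n, Ac.begin() + (size_t)(c + 1) * n,
              A.begin() + (size_t)k * n);
  }
  run_span(cx, cpb, U, A, B, cx.stim_on, cx.t_max, true, srt.begin(),
           node.begin(), nullptr, nullptr, 0, trial_ids);
  return List::create(_["srt"] = srt, _["node"] = node);
}
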