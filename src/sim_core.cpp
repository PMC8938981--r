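// Integration core for the basal-ganglia network: LIF / AdEx membranes with
// conductance-based alpha synapses, conduction delays (per-edge ring buffer),
// refractoriness, spike-triggered adaptation, Poisson background drive and a
// rate-modulated Poisson stimulus channel.  Synaptic alpha states use the
// exact exponential update; membrane equations use midpoint (RK2) at dt.
// All randomness is drawn from R's RNG so a set.seed() on the R side fixes
// the realization.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact inversion sampling of a Poisson count from one uniform draw;
// efficient for the small means (lambda*dt) that arise per time step.
static inline int rpois_small(double lambda, double p0) {
  if (lambda <= 0.0) return 0;
  double u = unif_rand();
  if (u <= p0) return 0;
  int k = 0;
  double p = p0, cum = p0;
  while (u > cum) {
    ++k;
    p *= lambda / k;
    cum += p;
    if (k > 1000) break;  // unreachable for sane rates
  }
  return k;
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericVector C_m, NumericVector g_L, NumericVector E_L,
              NumericVector V_th, NumericVector V_reset,
              NumericVector E_ex, NumericVector E_in,
              NumericVector tau_ex, NumericVector tau_in,
              NumericVector I_e, NumericVector t_ref,
              IntegerVector is_adex,
              NumericVector a, NumericVector b, NumericVector Delta_T,
              NumericVector tau_w, NumericVector V_peak,
              IntegerVector out_ptr, IntegerVector out_tgt,
              NumericVector out_w, IntegerVector out_dstep,
              NumericVector bg_rate, NumericVector bg_w,
              IntegerVector stim_mask, NumericVector stim_w,
              IntegerVector stim_shift,
              NumericVector stim_rate, NumericVector bg_mod,
              IntegerVector ext_step, IntegerVector ext_tgt,
              NumericVector ext_w,
              double duration, double dt, int record_traces) {
  const int n = C_m.size();
  const int n_steps = (int)std::lround(duration / dt);
  const double ms = 1.0 / 1000.0;  // Hz * ms -> expected count scale

  // per-neuron precomputed constants (reciprocals avoid divisions in the
  // inner loop)
  std::vector<double> Dex(n), Din(n), Dex2(n), Din2(n), kex(n), kin(n),
      invC(n), invTw(n), invDT(n), gDT(n);
  std::vector<int> ref_steps(n);
  const double e1 = std::exp(1.0);
  for (int i = 0; i < n; ++i) {
    Dex[i] = std::exp(-dt / tau_ex[i]);
    Din[i] = std::exp(-dt / tau_in[i]);
    Dex2[i] = std::exp(-0.5 * dt / tau_ex[i]);
    Din2[i] = std::exp(-0.5 * dt / tau_in[i]);
    kex[i] = e1 / tau_ex[i];  // h-impulse per unit peak conductance
    kin[i] = e1 / tau_in[i];
    invC[i] = 1.0 / C_m[i];
    invTw[i] = 1.0 / tau_w[i];
    invDT[i] = 1.0 / Delta_T[i];
    gDT[i] = g_L[i] * Delta_T[i];
    ref_steps[i] = (int)std::lround(t_ref[i] / dt);
  }

  // state
  std::vector<double> V(n), w(n, 0.0), gex(n, 0.0), hex(n, 0.0),
      gin(n, 0.0), hin(n, 0.0);
  std::vector<int> refr(n, 0);
  for (int i = 0; i < n; ++i) {
    double lo = std::min(E_L[i], V_th[i]), hi = std::max(E_L[i], V_th[i]);
    V[i] = lo + unif_rand() * (hi - lo);
  }

  // delay ring buffer of pending h-impulses, per neuron and channel
  int max_d = 1;
  for (int k = 0; k < out_dstep.size(); ++k)
    if (out_dstep[k] > max_d) max_d = out_dstep[k];
  const int ring_len = max_d + 1;
  std::vector<double> ring((size_t)ring_len * n * 2, 0.0);

  // background Poisson constants
  std::vector<double> bg_lam(n), bg_p0(n);
  for (int i = 0; i < n; ++i) {
    bg_lam[i] = bg_rate[i] * dt * ms;
    bg_p0[i] = std::exp(-bg_lam[i]);
  }

  std::vector<int> sp_id;
  std::vector<double> sp_t;
  sp_id.reserve(1 << 16);
  sp_t.reserve(1 << 16);

  const bool traces = record_traces > 0;
  const int tr = record_traces - 1;
  NumericVector trV, trGex, trGin;
  if (traces) {
    trV = NumericVector(n_steps);
    trGex = NumericVector(n_steps);
    trGin = NumericVector(n_steps);
  }

  int ext_i = 0;
  const int n_ext = ext_step.size();
  const bool have_stim = stim_rate.size() > 0;

  // raw pointers for the hot loop
  const double *pC = invC.data(), *pTw = invTw.data(), *pDT = invDT.data(),
      *pgDT = gDT.data();
  const double *pgL = REAL(g_L), *pEL = REAL(E_L), *pVth = REAL(V_th),
      *pVres = REAL(V_reset), *pEex = REAL(E_ex), *pEin = REAL(E_in),
      *pIe = REAL(I_e), *pa = REAL(a), *pb = REAL(b), *pVpk = REAL(V_peak),
      *pbgw = REAL(bg_w), *pstw = REAL(stim_w);
  const int *pmask = INTEGER(stim_mask), *pshift = INTEGER(stim_shift),
      *padex = INTEGER(is_adex), *pptr = INTEGER(out_ptr),
      *ptgt = INTEGER(out_tgt), *pdst = INTEGER(out_dstep);
  const double *pow_ = REAL(out_w);

  for (int step = 0; step < n_steps; ++step) {
    const int slot = step % ring_len;
    double *ring_slot = &ring[(size_t)slot * n * 2];

    // external spike sources (pre-generated trains), already delay-resolved
    while (ext_i < n_ext && ext_step[ext_i] == step) {
      const int tgt = ext_tgt[ext_i];
      const double wgt = ext_w[ext_i];
      if (wgt >= 0.0) hex[tgt] += wgt * kex[tgt];
      else hin[tgt] += -wgt * kin[tgt];
      ++ext_i;
    }

    // fused per-neuron pass: delayed-impulse delivery, Poisson drive,
    // exact synaptic alpha-state advance, RK2 membrane update, spike test
    for (int i = 0; i < n; ++i) {
      // delayed synaptic impulses scheduled for this step
      double pe = ring_slot[2 * i], pi = ring_slot[2 * i + 1];
      if (pe != 0.0) { hex[i] += pe * kex[i]; ring_slot[2 * i] = 0.0; }
      if (pi != 0.0) { hin[i] += pi * kin[i]; ring_slot[2 * i + 1] = 0.0; }

      // background + stimulus Poisson drive; the stimulus rate profile and
      // the background-suppression profile are read with each neuron's
      // cortical conduction delay (stim_shift, in steps)
      double mod = 1.0, srate = 0.0;
      if (have_stim && pmask[i]) {
        const int sidx = step - pshift[i];
        if (sidx >= 0 && sidx < n_steps) {
          mod = bg_mod[sidx];
          srate = stim_rate[sidx];
        }
      }
      if (bg_lam[i] > 0.0) {
        int cnt;
        if (mod != 1.0) {
          const double lam = bg_lam[i] * mod;
          cnt = rpois_small(lam, std::exp(-lam));
        } else {
          cnt = rpois_small(bg_lam[i], bg_p0[i]);
        }
        if (cnt > 0) hex[i] += cnt * pbgw[i] * kex[i];
      }
      if (srate > 0.0) {
        const double slam = srate * dt * ms;
        const int cnt = rpois_small(slam, std::exp(-slam));
        if (cnt > 0) {
          const double wgt = pstw[i];
          if (wgt >= 0.0) hex[i] += cnt * wgt * kex[i];
          else hin[i] += cnt * (-wgt) * kin[i];
        }
      }

      const double ge0 = gex[i], gi0 = gin[i];
      const double gem = Dex2[i] * (ge0 + 0.5 * dt * hex[i]);
      const double gim = Din2[i] * (gi0 + 0.5 * dt * hin[i]);
      // advance alpha states exactly
      gex[i] = Dex[i] * (ge0 + dt * hex[i]);
      hex[i] *= Dex[i];
      gin[i] = Din[i] * (gi0 + dt * hin[i]);
      hin[i] *= Din[i];

      bool spiked = false;
      if (refr[i] > 0) {
        V[i] = pVres[i];
        --refr[i];
        if (padex[i]) {  // adaptation keeps evolving during refractoriness
          const double dv = V[i] - pEL[i];
          const double k1 = (pa[i] * dv - w[i]) * pTw[i];
          const double wm = w[i] + 0.5 * dt * k1;
          w[i] += dt * (pa[i] * dv - wm) * pTw[i];
        }
      } else if (padex[i]) {
        double v = V[i], ww = w[i];
        double ex1 = (v - pVth[i]) * pDT[i];
        ex1 = ex1 > 20.0 ? 20.0 : ex1;
        const double k1v = (-pgL[i] * (v - pEL[i]) + pgDT[i] * std::exp(ex1)
                            - ge0 * (v - pEex[i]) - gi0 * (v - pEin[i])
                            + pIe[i] - ww) * pC[i];
        const double k1w = (pa[i] * (v - pEL[i]) - ww) * pTw[i];
        // clamp the midpoint at the spike cutoff: during the exponential
        // blow-up the raw midpoint is unbounded and would corrupt the
        // adaptation update
        double vm = v + 0.5 * dt * k1v;
        if (vm > pVpk[i]) vm = pVpk[i];
        const double wm = ww + 0.5 * dt * k1w;
        double ex2 = (vm - pVth[i]) * pDT[i];
        ex2 = ex2 > 20.0 ? 20.0 : ex2;
        const double k2v = (-pgL[i] * (vm - pEL[i]) + pgDT[i] * std::exp(ex2)
                            - gem * (vm - pEex[i]) - gim * (vm - pEin[i])
                            + pIe[i] - wm) * pC[i];
        v += dt * k2v;
        ww += dt * (pa[i] * (vm - pEL[i]) - wm) * pTw[i];
        if (!std::isfinite(v))
          stop("membrane potential diverged (neuron %d, t = %.1f ms)", i + 1,
               step * dt);
        if (v >= pVpk[i]) {
          spiked = true;
          v = pVres[i];
          ww += pb[i];
        }
        V[i] = v;
        w[i] = ww;
      } else {
        double v = V[i];
        const double k1 = (-pgL[i] * (v - pEL[i]) - ge0 * (v - pEex[i])
                           - gi0 * (v - pEin[i]) + pIe[i]) * pC[i];
        const double vm = v + 0.5 * dt * k1;
        const double k2 = (-pgL[i] * (vm - pEL[i]) - gem * (vm - pEex[i])
                           - gim * (vm - pEin[i]) + pIe[i]) * pC[i];
        v += dt * k2;
        if (!std::isfinite(v))
          stop("membrane potential diverged (neuron %d, t = %.1f ms)", i + 1,
               step * dt);
        if (v >= pVth[i]) {
          spiked = true;
          v = pVres[i];
        }
        V[i] = v;
      }

      if (spiked) {
        sp_id.push_back(i + 1);
        sp_t.push_back((step + 1) * dt);
        refr[i] = ref_steps[i];
        // fan out with per-edge delay
        for (int k = pptr[i]; k < pptr[i + 1]; ++k) {
          const int dslot = (step + pdst[k]) % ring_len;
          double *rs = &ring[(size_t)dslot * n * 2];
          const double wgt = pow_[k];
          if (wgt >= 0.0) rs[2 * ptgt[k]] += wgt;
          else rs[2 * ptgt[k] + 1] += -wgt;
        }
      }
    }

    if (traces) {
      trV[step] = V[tr];
      trGex[step] = gex[tr];
      trGin[step] = gin[tr];
    }
    if ((step & 0x3fff) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
      _["id"] = IntegerVector(sp_id.begin(), sp_id.end()),
      _["t"] = NumericVector(sp_t.begin(), sp_t.end()));
  if (traces) {
    out["V"] = trV;
    out["g_ex"] = trGex;
    out["g_in"] = trGin;
  }
  return out;
}
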