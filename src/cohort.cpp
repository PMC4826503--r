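#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Discrete-time cohort engine over the expanded state space
//   T(k)        transplantation cycle, k-th transplant        (k = 1..K)
//   F(k,c)      full graft function, c cycles since transplant (c capped at C+1)
//   P(k,c)      partial graft function
//   IIT_N       intensive insulin therapy, no diabetes-related complications
//   IIT_D       IIT with diabetes-related complications
//   DEAD        absorbing
// c <= C is the early post-transplant phase (~first 6 months); c = C+1 pools
// everything after. Competing risks are composed in fixed order within a
// cycle: death, then DRC, then immunosuppression-stopping complications,
// then graft events; the residual mass stays.
//
// After the re-transplantation cascade has played out (every transient slot
// exactly empty), occupancy lives in {F(.,C+1), P(.,C+1), IIT_N, IIT_D,
// DEAD} whose dynamics no longer depend on the transplant count, so the
// engine drops to a reduced five-state recursion for the remaining cycles.
//
// Column orders of `trans`, `costs`, `utils` are a contract with
// R/model_inputs.R (TRANS_COLS / COST_COLS / UTIL_COLS).

// trans columns
enum { tP_FULL1, tP_FULL2, tP_FULL34, tP_F2P, tP_FFAIL, tP_PFAIL_E,
       tP_PFAIL_L, tP_DRC_N, tP_DRC_F, tP_DRC_P, tP_MAJOR, tR_STOP,
       tHR_IIT, tHR_DRC };
// costs columns
enum { cLUMP1, cLUMP2, cLUMP3, cLUMP4, cFULL_F, cFULL_A, cPART_F, cPART_A,
       cIIT, cDRC, cMAJ_EV };
// utils columns
enum { uTX1, uTX_RE, uFULL, uPART, uIIT, uDRC, uDU_INIT, uDU_MAJ };

// [[Rcpp::export]]
List cohort_engine(bool transplant_arm,
                   NumericMatrix trans, NumericMatrix costs,
                   NumericMatrix utils,
                   NumericVector q_bg, NumericVector log1q,
                   NumericVector disc_mid, NumericVector disc_end,
                   int n_cycles, int cycles_per_year,
                   int first_phase, int max_tx,
                   int record_every, bool trace) {
  const int D = trans.nrow();
  const int K = max_tx;
  const int C = first_phase;        // early-phase cycles; slot C+1 = "after"
  const int nslot = C + 1;
  const int iF0 = K;
  const int iP0 = K + K * nslot;
  const int iIIT_N = K + 2 * K * nslot;
  const int iIIT_D = iIIT_N + 1;
  const int iDEAD = iIIT_N + 2;
  const int S = iDEAD + 1;
  const double dt = 1.0 / cycles_per_year;

  NumericMatrix out(D, 6);
  colnames(out) = CharacterVector::create("cost", "qaly", "ly",
                                          "cost_undisc", "qaly_undisc",
                                          "ly_undisc");
  int ncp = (record_every > 0) ? n_cycles / record_every : 0;
  NumericMatrix cp_cost(ncp > 0 ? D : 1, ncp > 0 ? ncp : 1);
  NumericMatrix cp_qaly(ncp > 0 ? D : 1, ncp > 0 ? ncp : 1);
  NumericMatrix tr(trace ? n_cycles + 1 : 1, trace ? S : 1);
  if (trace && D != 1) stop("trace mode requires a single draw");

  std::vector<double> old(S), nw(S);
  std::vector<double> lump(K), retx(K);

  for (int d = 0; d < D; ++d) {
    const double pf1 = trans(d, tP_FULL1), pf2 = trans(d, tP_FULL2),
                 pf34 = trans(d, tP_FULL34);
    const double p_f2p = trans(d, tP_F2P), p_ffail = trans(d, tP_FFAIL);
    const double p_pe = trans(d, tP_PFAIL_E), p_pl = trans(d, tP_PFAIL_L);
    const double p_drc_n = trans(d, tP_DRC_N), p_drc_f = trans(d, tP_DRC_F),
                 p_drc_p = trans(d, tP_DRC_P);
    const double p_maj = trans(d, tP_MAJOR), r_stop = trans(d, tR_STOP);
    const double hr_iit = trans(d, tHR_IIT), hr_drc = trans(d, tHR_DRC);
    const double c_ff = costs(d, cFULL_F), c_fa = costs(d, cFULL_A);
    const double c_pf = costs(d, cPART_F), c_pa = costs(d, cPART_A);
    const double c_iit = costs(d, cIIT), c_drc = costs(d, cDRC);
    const double c_majev = costs(d, cMAJ_EV);
    const double u_tx1 = utils(d, uTX1), u_txre = utils(d, uTX_RE);
    const double u_full = utils(d, uFULL), u_part = utils(d, uPART);
    const double u_iit = utils(d, uIIT), u_drc = utils(d, uDRC);
    const double du_init = utils(d, uDU_INIT), du_maj = utils(d, uDU_MAJ);
    lump[0] = costs(d, cLUMP1);
    if (K > 1) lump[1] = costs(d, cLUMP2);
    if (K > 2) lump[2] = costs(d, cLUMP3);
    if (K > 3) lump[3] = costs(d, cLUMP4);

    std::fill(old.begin(), old.end(), 0.0);
    double costD = 0, qalyD = 0, lyD = 0, costU = 0, qalyU = 0, lyU = 0;
    if (transplant_arm) {
      old[0] = 1.0;                          // T(1), time 0
      if (n_cycles >= 1) {
        costD += lump[0]; costU += lump[0];
        qalyD -= du_init; qalyU -= du_init;
      }
    } else {
      old[iIIT_N] = 1.0;
    }
    if (trace) for (int s = 0; s < S; ++s) tr(0, s) = old[s];

    double q_iit = 0, q_drcM = 0, l1q_prev = 1.0;  // 1.0: impossible sentinel
    bool settled = false;
    double f9 = 0, p9 = 0, iitn = 0, iitd = 0, dead = 0;

    for (int i = 1; i <= n_cycles; ++i) {
      const double qb = q_bg[i - 1];
      const double l1q = log1q[i - 1];
      if (l1q != l1q_prev) {
        q_iit = 1.0 - std::exp(hr_iit * l1q);
        q_drcM = 1.0 - std::exp(hr_drc * l1q);
        l1q_prev = l1q;
      }

      if (!settled && !trace) {
        // transient slots exactly empty?  (no inflow -> exact zeros)
        double transient = 0;
        for (int k = 0; k < K; ++k) transient += old[k];
        for (int k = 0; k < K; ++k)
          for (int c = 1; c <= C; ++c)
            transient += old[iF0 + k * nslot + c - 1] +
                         old[iP0 + k * nslot + c - 1];
        if (transient == 0.0) {
          settled = true;
          f9 = p9 = 0;
          for (int k = 0; k < K; ++k) {
            f9 += old[iF0 + k * nslot + nslot - 1];
            p9 += old[iP0 + k * nslot + nslot - 1];
          }
          iitn = old[iIIT_N]; iitd = old[iIIT_D]; dead = old[iDEAD];
        }
      }

      double ev_major, cost_cyc, qaly_cyc, ly_cyc;
      if (settled) {
        // reduced recursion: F(.,C+1), P(.,C+1), IIT_N, IIT_D, DEAD
        const double remF = f9 * (1.0 - qb);
        const double drcF = remF * p_drc_f;
        const double rem2F = remF - drcF;
        const double stopF = rem2F * p_maj * r_stop;
        const double rem3F = rem2F - stopF;
        const double toP = rem3F * p_f2p;
        const double rem4F = rem3F - toP;
        const double failF = rem4F * p_ffail;
        const double nf9 = rem4F - failF;
        const double remP = p9 * (1.0 - qb);
        const double drcP = remP * p_drc_p;
        const double rem2P = remP - drcP;
        const double stopP = rem2P * p_maj * r_stop;
        const double rem3P = rem2P - stopP;
        const double failP = rem3P * p_pl;
        const double np9 = rem3P - failP + toP;
        ev_major = (rem2F + rem2P) * p_maj;
        const double exits = stopF + stopP + failF + failP;
        const double remN = iitn * (1.0 - q_iit);
        const double drcN = remN * p_drc_n;
        const double niitn = remN - drcN + exits * (1.0 - p_drc_n);
        const double niitd = iitd * (1.0 - q_drcM) + drcN + drcF + drcP +
                             exits * p_drc_n;
        const double ndead = dead + f9 * qb + p9 * qb + iitn * q_iit +
                             iitd * q_drcM;
        const double tot = nf9 + np9 + niitn + niitd + ndead;
        if (std::fabs(tot - 1.0) > 1e-8)
          stop("occupancy mass leak at draw %d, cycle %d (sum = %.12f)",
               d + 1, i, tot);
        const double midF = 0.5 * (f9 + nf9), midP = 0.5 * (p9 + np9);
        const double midN = 0.5 * (iitn + niitn), midD = 0.5 * (iitd + niitd);
        cost_cyc = midF * c_fa + midP * c_pa + midN * c_iit + midD * c_drc +
                   ev_major * c_majev;
        qaly_cyc = midF * u_full + midP * u_part + midN * u_iit +
                   midD * u_drc - ev_major * du_maj;
        ly_cyc = (midF + midP + midN + midD) * dt;
        f9 = nf9; p9 = np9; iitn = niitn; iitd = niitd; dead = ndead;
      } else {
        std::fill(nw.begin(), nw.end(), 0.0);
        std::fill(retx.begin(), retx.end(), 0.0);
        ev_major = 0.0;

        // transplantation states
        for (int k = 0; k < K; ++k) {
          const double m = old[k];
          if (m <= 0) continue;
          const double pf = (k == 0) ? pf1 : (k == 1) ? pf2 : pf34;
          const double rem = m * (1.0 - qb);
          nw[iDEAD] += m * qb;
          const double drc = rem * p_drc_n;
          nw[iIIT_D] += drc;
          const double rem2 = rem - drc;
          nw[iF0 + k * nslot] += rem2 * pf;        // F(k, c = 1)
          nw[iP0 + k * nslot] += rem2 * (1.0 - pf);
        }

        // full graft function
        for (int k = 0; k < K; ++k) {
          for (int c = 1; c <= nslot; ++c) {
            const double m = old[iF0 + k * nslot + (c - 1)];
            if (m <= 0) continue;
            const double rem = m * (1.0 - qb);
            nw[iDEAD] += m * qb;
            const double drc = rem * p_drc_f;
            nw[iIIT_D] += drc;
            const double rem2 = rem - drc;
            ev_major += rem2 * p_maj;
            const double stopf = rem2 * p_maj * r_stop;
            nw[iIIT_N] += stopf * (1.0 - p_drc_n);
            nw[iIIT_D] += stopf * p_drc_n;
            const double rem3 = rem2 - stopf;
            const int cn = (c < nslot) ? c + 1 : nslot;
            const double to_part = rem3 * p_f2p;
            nw[iP0 + k * nslot + (cn - 1)] += to_part;
            const double rem4 = rem3 - to_part;
            const double fail = rem4 * p_ffail;
            nw[iIIT_N] += fail * (1.0 - p_drc_n);
            nw[iIIT_D] += fail * p_drc_n;
            nw[iF0 + k * nslot + (cn - 1)] += rem4 - fail;
          }
        }

        // partial graft function
        for (int k = 0; k < K; ++k) {
          for (int c = 1; c <= nslot; ++c) {
            const double m = old[iP0 + k * nslot + (c - 1)];
            if (m <= 0) continue;
            const double rem = m * (1.0 - qb);
            nw[iDEAD] += m * qb;
            const double drc = rem * p_drc_p;
            nw[iIIT_D] += drc;
            const double rem2 = rem - drc;
            ev_major += rem2 * p_maj;
            const double stopf = rem2 * p_maj * r_stop;
            nw[iIIT_N] += stopf * (1.0 - p_drc_n);
            nw[iIIT_D] += stopf * p_drc_n;
            const double rem3 = rem2 - stopf;
            if (c <= C && k < K - 1) {
              // early phase with re-transplantation available
              const double fail = rem3 * p_pe;
              nw[iIIT_N] += fail * (1.0 - p_drc_n);
              nw[iIIT_D] += fail * p_drc_n;
              const double rt = rem3 - fail;
              nw[k + 1] += rt;                    // T(k+1) next cycle
              retx[k + 1] += rt;
            } else {
              const double fail = rem3 * p_pl;
              nw[iIIT_N] += fail * (1.0 - p_drc_n);
              nw[iIIT_D] += fail * p_drc_n;
              const int cn = (c < nslot) ? c + 1 : nslot;
              nw[iP0 + k * nslot + (cn - 1)] += rem3 - fail;
            }
          }
        }

        // IIT states
        {
          const double m = old[iIIT_N];
          const double rem = m * (1.0 - q_iit);
          nw[iDEAD] += m * q_iit;
          const double drc = rem * p_drc_n;
          nw[iIIT_D] += drc;
          nw[iIIT_N] += rem - drc;
        }
        {
          const double m = old[iIIT_D];
          nw[iDEAD] += m * q_drcM;
          nw[iIIT_D] += m * (1.0 - q_drcM);
        }
        nw[iDEAD] += old[iDEAD];

        double tot = 0;
        for (int s = 0; s < S; ++s) tot += nw[s];
        if (std::fabs(tot - 1.0) > 1e-8)
          stop("occupancy mass leak at draw %d, cycle %d (sum = %.12f)",
               d + 1, i, tot);

        // membership rewards at mid-cycle occupancy (half-cycle correction)
        double c_mem = 0, u_mem = 0, alive_mid = 0;
        for (int k = 0; k < K; ++k) {
          const double midT = 0.5 * (old[k] + nw[k]);
          u_mem += midT * ((k == 0) ? u_tx1 : u_txre);
          alive_mid += midT;
          for (int c = 1; c <= nslot; ++c) {
            const double midF = 0.5 * (old[iF0 + k * nslot + c - 1] +
                                       nw[iF0 + k * nslot + c - 1]);
            const double midP = 0.5 * (old[iP0 + k * nslot + c - 1] +
                                       nw[iP0 + k * nslot + c - 1]);
            c_mem += midF * ((c <= C) ? c_ff : c_fa);
            c_mem += midP * ((c <= C) ? c_pf : c_pa);
            u_mem += midF * u_full + midP * u_part;
            alive_mid += midF + midP;
          }
        }
        const double midN = 0.5 * (old[iIIT_N] + nw[iIIT_N]);
        const double midD = 0.5 * (old[iIIT_D] + nw[iIIT_D]);
        c_mem += midN * c_iit + midD * c_drc;
        u_mem += midN * u_iit + midD * u_drc;
        alive_mid += midN + midD;

        cost_cyc = c_mem + ev_major * c_majev;
        qaly_cyc = u_mem - ev_major * du_maj;
        ly_cyc = alive_mid * dt;

        // re-transplantation lumps on the mass entering T(k)
        for (int k = 1; k < K; ++k) {
          if (retx[k] <= 0) continue;
          costD += retx[k] * lump[k] * disc_end[i - 1];
          costU += retx[k] * lump[k];
          qalyD -= retx[k] * du_init * disc_end[i - 1];
          qalyU -= retx[k] * du_init;
        }
        std::swap(old, nw);
        if (trace) for (int s = 0; s < S; ++s) tr(i, s) = old[s];
      }

      costD += cost_cyc * disc_mid[i - 1];
      qalyD += qaly_cyc * disc_mid[i - 1];
      lyD += ly_cyc * disc_mid[i - 1];
      costU += cost_cyc; qalyU += qaly_cyc; lyU += ly_cyc;

      if (ncp > 0 && i % record_every == 0) {
        const int j = i / record_every - 1;
        cp_cost(d, j) = costD;
        cp_qaly(d, j) = qalyD;
      }
    }
    out(d, 0) = costD; out(d, 1) = qalyD; out(d, 2) = lyD;
    out(d, 3) = costU; out(d, 4) = qalyU; out(d, 5) = lyU;
  }

  List res = List::create(_["totals"] = out);
  if (ncp > 0) {
    res["cp_cost"] = cp_cost;
    res["cp_qaly"] = cp_qaly;
  }
  if (trace) res["trace"] = tr;
  return res;
}
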