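#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Shared permutation engine for ADA and the burden comparators.
//
// All statistics are functions of the per-site case minor-allele counts
// a_i (plus, for WS, the per-subject weighted scores), and the pooled
// minor-allele count m_i at each site is invariant under phenotype
// permutation.  Per-site mid-P values and Madsen-Browning weights are
// therefore supplied as lookup tables indexed by a_i (resp. the control
// count c_i = m_i - a_i), precomputed once per data set on the R side.
//
// perm_case holds one column of 0-based case-subject indices per
// "permutation"; by convention column 0 is the observed assignment.
//
// Genotypes arrive in subject-major sparse form (sub_ptr/sub_site/sub_dose):
// rare-variant dosage matrices are overwhelmingly zero, so accumulating the
// a_i for one permutation costs O(nonzeros among its cases).
//
// ADA scores are binned by the first threshold that admits each site
// (strict p < theta) and prefix-summed, so the per-threshold score vectors
// S^D_j, S^P_j cost O(K + J) per permutation.
//
// [[Rcpp::export]]
List rv_engine_cpp(IntegerVector sub_ptr, IntegerVector sub_site,
                   IntegerVector sub_dose,
                   int K, int n_case, int n_ctrl,
                   IntegerMatrix perm_case,
                   IntegerVector mtot,
                   IntegerVector midp_off, NumericVector midp_flat,
                   NumericVector wtab, NumericVector wfixed, bool recompute_w,
                   NumericVector thresholds,
                   bool do_ada, bool do_sigma, bool do_t1, bool do_t5,
                   bool do_ws, bool do_vt,
                   LogicalVector t1_mask, LogicalVector t5_mask,
                   IntegerVector vt_ord, IntegerVector vt_bnd,
                   NumericVector vt_var, NumericVector vt_cumtot) {
  const int n = sub_ptr.size() - 1;
  const int P = perm_case.ncol();
  const int J = thresholds.size();

  NumericMatrix SD(do_ada ? J : 0, do_ada ? P : 0);
  NumericMatrix SP(do_ada ? J : 0, do_ada ? P : 0);
  NumericVector sigma(do_sigma ? P : 0);
  NumericVector t1s(do_t1 ? P : 0), t5s(do_t5 ? P : 0);
  NumericVector wss(do_ws ? P : 0), vts(do_vt ? P : 0);

  std::vector<int> a(K);
  std::vector<double> binD(J), binP(J);
  std::vector<double> x;                 // WS per-subject weighted scores
  std::vector<char> is_case;
  std::vector<int> idx;
  if (do_ws) { x.resize(n); is_case.resize(n); idx.resize(n); }

  const double thr_max = J > 0 ? thresholds[J - 1] : 0.0;

  for (int p = 0; p < P; ++p) {
    std::fill(a.begin(), a.end(), 0);
    for (int i = 0; i < n_case; ++i) {
      const int s = perm_case(i, p);
      for (int e = sub_ptr[s]; e < sub_ptr[s + 1]; ++e)
        a[sub_site[e]] += sub_dose[e];
    }

    if (do_ada || do_sigma) {
      std::fill(binD.begin(), binD.end(), 0.0);
      std::fill(binP.begin(), binP.end(), 0.0);
      double sig = 0.0;
      for (int i = 0; i < K; ++i) {
        const int m = mtot[i];
        if (m == 0) continue;                     // monomorphic: p = 1, tied
        const int ai = a[i], ci = m - ai;
        const double pv = midp_flat[midp_off[i] + ai];
        const double w = recompute_w ? wtab[ci] : wfixed[i];
        if (do_sigma && ai != ci)                 // exclude equal-count sites
          sig += w * (-2.0 * std::log(pv));
        if (do_ada && pv < thr_max) {
          const long long fd = (long long)ai * n_ctrl;
          const long long fp = (long long)ci * n_case;
          if (fd == fp) continue;                 // tied frequencies
          int j0 = 0;
          while (pv >= thresholds[j0]) ++j0;      // first theta with p < theta
          const double contrib = w * (-std::log(pv));
          if (fd > fp) binD[j0] += contrib; else binP[j0] += contrib;
        }
      }
      if (do_ada) {
        double cd = 0.0, cp = 0.0;
        for (int j = 0; j < J; ++j) {
          cd += binD[j]; cp += binP[j];
          SD(j, p) = cd; SP(j, p) = cp;
        }
      }
      if (do_sigma) sigma[p] = sig;
    }

    if (do_t1 || do_t5) {
      long long a1 = 0, m1 = 0, a5 = 0, m5 = 0;
      for (int i = 0; i < K; ++i) {
        if (do_t1 && t1_mask[i]) { a1 += a[i]; m1 += mtot[i]; }
        if (do_t5 && t5_mask[i]) { a5 += a[i]; m5 += mtot[i]; }
      }
      // difference in mean per-subject genetic score, cases minus controls
      if (do_t1) t1s[p] = (double)a1 / n_case - (double)(m1 - a1) / n_ctrl;
      if (do_t5) t5s[p] = (double)a5 / n_case - (double)(m5 - a5) / n_ctrl;
    }

    if (do_ws) {
      std::fill(x.begin(), x.end(), 0.0);
      std::fill(is_case.begin(), is_case.end(), 0);
      for (int i = 0; i < n_case; ++i) is_case[perm_case(i, p)] = 1;
      for (int s = 0; s < n; ++s)
        for (int e = sub_ptr[s]; e < sub_ptr[s + 1]; ++e) {
          const int i = sub_site[e];
          const double w = recompute_w ? wtab[mtot[i] - a[i]] : wfixed[i];
          x[s] += sub_dose[e] * w;
        }
      for (int s = 0; s < n; ++s) idx[s] = s;
      std::sort(idx.begin(), idx.end(),
                [&](int u, int v) { return x[u] < x[v]; });
      double rsum = 0.0;
      int i = 0;
      while (i < n) {                             // average ranks over ties
        int j = i;
        while (j + 1 < n && x[idx[j + 1]] == x[idx[i]]) ++j;
        const double avg = 0.5 * (i + j) + 1.0;   // ranks i+1 .. j+1
        for (int k2 = i; k2 <= j; ++k2)
          if (is_case[idx[k2]]) rsum += avg;
        i = j + 1;
      }
      wss[p] = rsum;
    }

    if (do_vt) {
      double best = 0.0; long long cumA = 0; int bi = 0;
      const double inv = 1.0 / n_case + 1.0 / n_ctrl;
      for (int q = 0; q < K; ++q) {
        cumA += a[vt_ord[q]];
        if (vt_bnd[q]) {
          const double v = vt_var[bi];
          if (v > 0) {
            const double diff = (double)cumA / n_case -
                                (vt_cumtot[bi] - (double)cumA) / n_ctrl;
            const double z = std::fabs(diff / std::sqrt(v * inv));
            if (z > best) best = z;
          }
          ++bi;
        }
      }
      vts[p] = best;
    }
  }

  return List::create(_["SD"] = SD, _["SP"] = SP, _["sigma"] = sigma,
                      _["t1"] = t1s, _["t5"] = t5s, _["ws"] = wss,
                      _["vt"] = vts);
}
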