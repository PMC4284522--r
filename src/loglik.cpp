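#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Power-law / plateau contact intensity per bp^2.
// s is floored at sfl (>= 1 bp); beyond s0 and for trans pairs the
// intensity is the plateau Pt.
static inline double pc_rate(double s, double sfl, double b, double s0,
                             double Pt) {
  if (s < sfl) s = sfl;
  if (s >= s0) return Pt;
  return Pt * std::exp(b * std::log(s / s0));
}

// Poisson log-likelihood of a genome structure given unit-level contact
// counts.  Placed half-bin units are passed as parallel arrays (scaffold
// group, midpoint position in bp, unit length, data-unit id); duplicated
// bins appear as multiple placements of the same data unit and their
// expected counts sum over copy pairs.  Units absent from the placement
// arrays are unplaced and score the floor intensity eps * Pt per bp^2.
//
// The data term is decomposed against the "everything trans" baseline,
// whose total is a dataset constant (k_tot, kw_tot): only same-scaffold
// pairs closer than s0 and pairs involving special units (unplaced or
// multi-copy) deviate from the baseline, so the cost per call is
// O(placements + intra-scaffold pairs + special rows), independent of the
// number of non-zero contact pairs.  K is the dense unit-level count
// matrix; csr_* hold its non-zero rows for the special pass.
// [[Rcpp::export]]
double cpp_loglik(IntegerVector p_scaf, NumericVector p_pos,
                  NumericVector p_len, IntegerVector p_unit,
                  NumericVector u_len, NumericMatrix K,
                  IntegerVector csr_ptr, IntegerVector csr_col,
                  NumericVector csr_k, NumericVector csr_w,
                  double k_tot, double kw_tot,
                  double b, double s0, double Pt, double eps,
                  double exposure, double lgamma_const) {
  const int P = p_scaf.size();
  const int U = u_len.size();
  const double ls0 = std::log(s0);
  const double lEPt = std::log(exposure * Pt);
  const double lept = std::log(exposure * eps * Pt);

  // group placements by scaffold (counting sort)
  int S = 0;
  for (int p = 0; p < P; ++p) if (p_scaf[p] > S) S = p_scaf[p];
  std::vector<int> shead(S + 2, 0), sidx(P);
  for (int p = 0; p < P; ++p) shead[p_scaf[p] + 1]++;
  for (int s = 1; s <= S + 1; ++s) shead[s] += shead[s - 1];
  {
    std::vector<int> cur(shead.begin(), shead.end() - 1);
    for (int p = 0; p < P; ++p) sidx[cur[p_scaf[p]]++] = p;
  }

  // placements grouped by data unit (for copies / special units)
  std::vector<int> uhead(U + 2, 0), uidx(P);
  for (int p = 0; p < P; ++p) uhead[p_unit[p] + 1]++;
  for (int u = 1; u <= U + 1; ++u) uhead[u] += uhead[u - 1];
  {
    std::vector<int> cur(uhead.begin(), uhead.end() - 1);
    for (int p = 0; p < P; ++p) uidx[cur[p_unit[p]]++] = p;
  }
  std::vector<bool> special(U + 1, false);
  bool any_special = false;
  for (int u = 1; u <= U; ++u)
    if (uhead[u + 1] - uhead[u] != 1) { special[u] = true; any_special = true; }

  // expected mass (lam_sum) and data-term correction (kcorr) in one sweep:
  // cis pairs explicitly, trans mass in closed form
  double lam_sum = 0.0, sumW = 0.0, sumW2 = 0.0, kcorr = 0.0;
  for (int s = 1; s <= S; ++s) {
    double W = 0.0;
    for (int a = shead[s]; a < shead[s + 1]; ++a) {
      const int p = sidx[a];
      const int up = p_unit[p];
      W += p_len[p];
      // self term: within-placement contacts at the floored distance
      double sfl = std::max(1.0, 0.5 * p_len[p]);
      double selfrate = pc_rate(0.0, sfl, b, s0, Pt);
      lam_sum += 0.5 * selfrate * p_len[p] * p_len[p];
      if (!special[up]) {
        double kd = K(up - 1, up - 1);
        if (kd > 0)
          kcorr += kd * (std::log(0.5 * selfrate / Pt));
      }
      for (int c = a + 1; c < shead[s + 1]; ++c) {
        const int q = sidx[c];
        const int uq = p_unit[q];
        double d = std::fabs(p_pos[p] - p_pos[q]);
        double fl = std::max(1.0, 0.5 * std::min(p_len[p], p_len[q]));
        if (d < fl) d = fl;
        if (d >= s0) {
          lam_sum += Pt * p_len[p] * p_len[q];
          // baseline already accounts for this pair exactly
        } else {
          double lr = b * (std::log(d) - ls0); // log(rate / Pt)
          lam_sum += Pt * std::exp(lr) * p_len[p] * p_len[q];
          if (!special[up] && !special[uq]) {
            double kd = K(up - 1, uq - 1);
            if (kd > 0) kcorr += kd * lr;
          }
        }
      }
    }
    sumW += W;
    sumW2 += W * W;
  }
  lam_sum += 0.5 * Pt * (sumW * sumW - sumW2);

  // unplaced units: floor intensity against everything
  double Wunpl = 0.0;
  for (int u = 1; u <= U; ++u)
    if (uhead[u + 1] == uhead[u]) Wunpl += u_len[u - 1];
  lam_sum += eps * Pt * (Wunpl * sumW + 0.5 * Wunpl * Wunpl);

  // special pass: exact data term (minus baseline) for rows of unplaced or
  // multi-copy units
  if (any_special) {
    for (int u = 1; u <= U; ++u) {
      if (!special[u]) continue;
      const int nu = uhead[u + 1] - uhead[u];
      for (int e = csr_ptr[u - 1]; e < csr_ptr[u]; ++e) {
        const int v = csr_col[e];
        if (special[v] && v < u) continue; // counted from the other side
        const double kd = csr_k[e];
        const int nv = uhead[v + 1] - uhead[v];
        double loglam;
        if (nu == 0 || nv == 0) {
          int copies = (nu == 0 && nv == 0) ? 1 : std::max(nu, nv);
          double Srate = (u == v) ? 0.5 : (double)copies;
          loglam = lept + std::log(Srate) + csr_w[e];
        } else {
          double Ssum = 0.0;
          for (int a = uhead[u]; a < uhead[u + 1]; ++a) {
            const int p = uidx[a];
            int cstart = (u == v) ? a : uhead[v];
            for (int c = cstart; c < uhead[v + 1]; ++c) {
              const int q = uidx[c];
              double rate;
              if (p == q) {
                double sfl = std::max(1.0, 0.5 * p_len[p]);
                rate = 0.5 * pc_rate(0.0, sfl, b, s0, Pt);
              } else if (p_scaf[p] == p_scaf[q]) {
                double d = std::fabs(p_pos[p] - p_pos[q]);
                double fl = std::max(1.0, 0.5 * std::min(p_len[p], p_len[q]));
                rate = pc_rate(d, fl, b, s0, Pt);
              } else rate = Pt;
              Ssum += rate;
            }
          }
          loglam = std::log(exposure * Ssum) + csr_w[e];
        }
        kcorr += kd * (loglam - (lEPt + csr_w[e]));
      }
    }
  }

  const double kterm = lEPt * k_tot + kw_tot + kcorr;
  return kterm - exposure * lam_sum - lgamma_const;
}
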