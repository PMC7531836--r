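#include <Rcpp.h>
using namespace Rcpp;

// Derivative kernel for the reaction network.
//
// Rate-law kinds: 1 = first-order mass action, 2 = second-order mass
// action, 3 = Michaelis-Menten (k1 = kcat, k2 = Km, ie = enzyme index),
// 4 = zero-order synthesis, 5 = reversible mass action (k1 = kon,
// k2 = koff, ie = complex index).
//
// The stoichiometry matrix is passed in triplet form (ti = species row,
// tj = reaction column, tv = net stoichiometric coefficient).
//
// When hemo_on is true the state-dependent hemolytic elimination
// k_H = -log(1 - H/100)/tau, with H the Hill response of MAC per cell,
// is applied on top of the encoded first-order clearances to every
// species listed in mask (surface-bound species and the cells).
// [[Rcpp::export]]
NumericVector ap_rhs_eval(NumericVector y,
                          IntegerVector kind, IntegerVector i1,
                          IntegerVector i2, IntegerVector ie,
                          NumericVector k1, NumericVector k2,
                          IntegerVector ti, IntegerVector tj,
                          NumericVector tv, int nsp,
                          bool hemo_on, IntegerVector mask,
                          int mac_i, int e_i, double gamma,
                          double mac50, double tau, double h_cap) {
  const int nrx = kind.size();
  std::vector<double> yc(y.size());
  for (int i = 0; i < (int)yc.size(); ++i)
    yc[i] = y[i] > 0 ? y[i] : 0.0;

  std::vector<double> v(nrx);
  for (int j = 0; j < nrx; ++j) {
    switch (kind[j]) {
    case 1: v[j] = k1[j] * yc[i1[j]]; break;
    case 2: v[j] = k1[j] * yc[i1[j]] * yc[i2[j]]; break;
    case 3: { double s = yc[i1[j]];
              v[j] = k1[j] * yc[ie[j]] * s / (k2[j] + s); } break;
    case 4: v[j] = k1[j]; break;
    case 5: v[j] = k1[j] * yc[i1[j]] * yc[i2[j]] - k2[j] * yc[ie[j]]; break;
    default: v[j] = 0.0;
    }
  }
  NumericVector d(nsp);
  const int nt = ti.size();
  for (int t = 0; t < nt; ++t)
    d[ti[t]] += tv[t] * v[tj[t]];

  if (hemo_on) {
    double e = yc[e_i];
    if (e > 0) {
      double mac = yc[mac_i] / e;
      if (mac > 0) {
        double H = 100.0 / (1.0 + std::pow(mac50 / mac, gamma));
        if (H > h_cap) H = h_cap;
        double kH = -std::log(1.0 - H / 100.0) / tau;
        if (kH > 0)
          for (int m = 0; m < mask.size(); ++m)
            d[mask[m]] -= kH * yc[mask[m]];
      }
    }
  }
  return d;
}
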