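#include <Rcpp.h>
using namespace Rcpp;

// Match-counting kernel shared by ApEn and cross-ApEn.
//
// For standardized series u (query) and v (target) it accumulates, in one
// O(N^2) pass, the template match counts at embedding dimensions m and m+1
// for BOTH comparison directions: the Chebyshev distance between the i-th
// u-template and the j-th v-template equals the distance between the j-th
// v-template and the i-th u-template, so one distance evaluation feeds both
// Phi_{u->v} and Phi_{v->u}.
//
// Returns phi_m / phi_m1 per direction, the template counts, and how many
// log arguments were floored (a zero match count replaced by 1/n_targets;
// cross comparison has no guaranteed self-match, so zero counts are legal).
// [[Rcpp::export(name = ".capen_kernel")]]
List capen_kernel(NumericVector u, NumericVector v, int m, int lag, double r,
                  bool use_floor) {
  const int N = u.size();
  if (v.size() != N) stop("u and v must have equal length");
  const int Nm = N - (m - 1) * lag;   // templates at dimension m
  const int Nm1 = N - m * lag;        // templates at dimension m+1
  if (Nm1 < 1) stop("series too short for m=%d, lag=%d (need length > %d)",
                    m, lag, m * lag);

  std::vector<int> cm_u(Nm, 0), cm_v(Nm, 0);    // dimension-m counts
  std::vector<int> cm1_u(Nm1, 0), cm1_v(Nm1, 0); // dimension-(m+1) counts

  const double *pu = REAL(u), *pv = REAL(v);
  for (int i = 0; i < Nm; ++i) {
    for (int j = 0; j < Nm; ++j) {
      double dmax = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(pu[i + k * lag] - pv[j + k * lag]);
        if (d > dmax) dmax = d;
        if (dmax > r) break;
      }
      if (dmax <= r) {
        ++cm_u[i];
        ++cm_v[j];
        if (i < Nm1 && j < Nm1) {
          double d = std::fabs(pu[i + m * lag] - pv[j + m * lag]);
          if (d <= r && dmax <= r) {
            ++cm1_u[i];
            ++cm1_v[j];
          }
        }
      }
    }
  }

  int floored = 0;
  bool zero_unfloored = false;
  auto phi = [&](const std::vector<int> &c, int n_tpl) -> double {
    double s = 0.0;
    for (int i = 0; i < n_tpl; ++i) {
      int ci = c[i];
      if (ci == 0) {
        if (!use_floor) { zero_unfloored = true; return NA_REAL; }
        ++floored;
        ci = 1; // floor: probability 1/n_targets
      }
      s += std::log((double)ci / (double)n_tpl);
    }
    return s / n_tpl;
  };

  double phi_m_uv = phi(cm_u, Nm);
  double phi_m_vu = phi(cm_v, Nm);
  double phi_m1_uv = phi(cm1_u, Nm1);
  double phi_m1_vu = phi(cm1_v, Nm1);
  if (zero_unfloored)
    stop("zero match fraction encountered with floor disabled (log undefined)");

  return List::create(
    _["phi_m_uv"] = phi_m_uv, _["phi_m1_uv"] = phi_m1_uv,
    _["phi_m_vu"] = phi_m_vu, _["phi_m1_vu"] = phi_m1_vu,
    _["n_templates_m"] = Nm, _["n_templates_m1"] = Nm1,
    _["n_floored"] = floored);
}
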