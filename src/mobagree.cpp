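#include <Rcpp.h>
using namespace Rcpp;

// Mean Earth radius (metres); all package distances use this sphere.
static const double EARTH_R = 6371008.8;

static inline double hav_m(double lat1, double lon1, double lat2, double lon2) {
  const double d2r = M_PI / 180.0;
  double dlat = (lat2 - lat1) * d2r / 2.0;
  double dlon = (lon2 - lon1) * d2r / 2.0;
  double a = sin(dlat) * sin(dlat) +
             cos(lat1 * d2r) * cos(lat2 * d2r) * sin(dlon) * sin(dlon);
  if (a > 1.0) a = 1.0;
  return 2.0 * EARTH_R * asin(sqrt(a));
}

// [[Rcpp::export]]
NumericVector cpp_haversine(NumericVector lat1, NumericVector lon1,
                            NumericVector lat2, NumericVector lon2) {
  R_xlen_t n1 = lat1.size(), n2 = lat2.size();
  R_xlen_t n = std::max(n1, n2);
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = hav_m(lat1[n1 == 1 ? 0 : i], lon1[n1 == 1 ? 0 : i],
                   lat2[n2 == 1 ? 0 : i], lon2[n2 == 1 ? 0 : i]);
  }
  return out;
}

// Forward scan anchored on the last *retained* fix, so a burst of
// consecutive jumps is removed entirely.
// [[Rcpp::export]]
LogicalVector cpp_speed_filter(NumericVector lat, NumericVector lon,
                               NumericVector t, double vmax_ms) {
  R_xlen_t n = lat.size();
  LogicalVector keep(n);
  if (n == 0) return keep;
  keep[0] = true;
  R_xlen_t last = 0;
  for (R_xlen_t i = 1; i < n; ++i) {
    double dt = t[i] - t[last];
    if (dt <= 0) { keep[i] = false; continue; }
    double v = hav_m(lat[last], lon[last], lat[i], lon[i]) / dt;
    if (v <= vmax_ms) { keep[i] = true; last = i; } else {
      keep[i] = false;
    }
  }
  return keep;
}

// Time-based sequential stop detection. A candidate cluster opens at the
// current anchor fix; a subsequent fix joins while it lies within dmax_m of
// the anchor AND the time gap to the immediately preceding fix is <= tmax_s.
// When the prefix can no longer be extended the candidate closes: a stop if
// its time span reaches tmin_s (members i..j are claimed and the scan resumes
// after them), otherwise the anchor advances by a single fix. Returns a
// 1-based stop id per fix (0 = not part of any stop).
// [[Rcpp::export]]
IntegerVector cpp_detect_stops(NumericVector lat, NumericVector lon,
                               NumericVector t, double dmax_m,
                               double tmin_s, double tmax_s) {
  R_xlen_t n = lat.size();
  IntegerVector id(n);
  int next_id = 1;
  R_xlen_t i = 0;
  while (i < n) {
    R_xlen_t j = i;
    while (j + 1 < n &&
           (t[j + 1] - t[j]) <= tmax_s &&
           hav_m(lat[i], lon[i], lat[j + 1], lon[j + 1]) <= dmax_m) {
      ++j;
    }
    if ((t[j] - t[i]) >= tmin_s) {
      for (R_xlen_t k = i; k <= j; ++k) id[k] = next_id;
      ++next_id;
      i = j + 1;
    } else {
      ++i;
    }
  }
  return id;
}
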