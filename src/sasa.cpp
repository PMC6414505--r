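#include <Rcpp.h>
using namespace Rcpp;

// Deterministic unit sphere points via the golden-spiral (Fibonacci) lattice.
static std::vector<double> sphere_points(const int n) {
  std::vector<double> pts(3 * n);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = golden * k;
    pts[3 * k]     = r * std::cos(th);
    pts[3 * k + 1] = r * std::sin(th);
    pts[3 * k + 2] = z;
  }
  return pts;
}

//' @noRd
// [[Rcpp::export(name = ".sasa_atoms_cpp")]]
NumericVector sasa_atoms_cpp(NumericMatrix coords, NumericVector radii,
                             double probe, int n_points) {
  const int n = coords.nrow();
  NumericVector area(n);
  if (n == 0) return area;
  std::vector<double> pts = sphere_points(n_points);
  std::vector<double> rs(n);
  for (int i = 0; i < n; ++i) rs[i] = radii[i] + probe;

  for (int i = 0; i < n; ++i) {
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    const double ri = rs[i];
    // neighbours whose expanded spheres can occlude points on sphere i;
    // exactly coincident equal spheres are deduplicated (only the first
    // keeps its surface)
    std::vector<int> nb;
    bool dup_of_earlier = false;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi, dz = coords(j, 2) - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < 1e-18 && std::abs(rs[j] - ri) < 1e-12) {
        if (j < i) { dup_of_earlier = true; break; }
        continue;
      }
      double lim = ri + rs[j];
      if (d2 < lim * lim) nb.push_back(j);
    }
    if (dup_of_earlier) { area[i] = 0.0; continue; }
    int accessible = 0;
    for (int k = 0; k < n_points; ++k) {
      const double px = xi + ri * pts[3 * k];
      const double py = yi + ri * pts[3 * k + 1];
      const double pz = zi + ri * pts[3 * k + 2];
      bool free_pt = true;
      for (size_t m = 0; m < nb.size(); ++m) {
        const int j = nb[m];
        double dx = px - coords(j, 0), dy = py - coords(j, 1), dz = pz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < rs[j] * rs[j]) { free_pt = false; break; }
      }
      if (free_pt) ++accessible;
    }
    area[i] = 4.0 * M_PI * ri * ri * accessible / n_points;
  }
  return area;
}

//' @noRd
// [[Rcpp::export(name = ".contact_pairs_cpp")]]
IntegerMatrix contact_pairs_cpp(NumericMatrix ax, IntegerVector apos,
                                NumericMatrix bx, IntegerVector bpos,
                                double cutoff) {
  const int na = ax.nrow(), nb = bx.nrow();
  const double c2 = cutoff * cutoff;
  std::set<std::pair<int, int> > hits;
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      double dx = ax(i, 0) - bx(j, 0);
      double dy = ax(i, 1) - bx(j, 1);
      double dz = ax(i, 2) - bx(j, 2);
      if (dx * dx + dy * dy + dz * dz <= c2)
        hits.insert(std::make_pair(apos[i], bpos[j]));
    }
  }
  IntegerMatrix out(hits.size(), 2);
  int r = 0;
  for (std::set<std::pair<int, int> >::const_iterator it = hits.begin();
       it != hits.end(); ++it, ++r) {
    out(r, 0) = it->first;
    out(r, 1) = it->second;
  }
  return out;
}
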