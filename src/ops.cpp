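#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Discrete operators shared by the solvers and exposed for testing.
// Axisymmetric fields are nr x nz matrices, node i at r = i*dx (axis on the
// first row), node k at z = k*dx. Standalone operators use mirror (Neumann)
// ghosts at domain edges; the solvers impose their own boundary conditions.

static inline double mirror(const NumericMatrix& f, int i, int k) {
  int nr = f.nrow(), nz = f.ncol();
  if (i < 0) i = 1;            // axis symmetry ghost
  if (i > nr - 1) i = nr - 2;
  if (k < 0) k = 1;
  if (k > nz - 1) k = nz - 2;
  return f(i, k);
}

// [[Rcpp::export]]
NumericMatrix cpp_lap_axisym(const NumericMatrix& f, double dx) {
  int nr = f.nrow(), nz = f.ncol();
  NumericMatrix out(nr, nz);
  double idx2 = 1.0 / (dx * dx);
  for (int k = 0; k < nz; ++k) {
    for (int i = 0; i < nr; ++i) {
      double fz = (mirror(f, i, k + 1) - 2.0 * f(i, k) + mirror(f, i, k - 1)) * idx2;
      double fr;
      if (i == 0) {
        fr = 4.0 * (mirror(f, 1, k) - f(0, k)) * idx2;  // on-axis limit 2*d2/dr2
      } else {
        double ri = i * dx;
        fr = ((ri + 0.5 * dx) * (mirror(f, i + 1, k) - f(i, k)) -
              (ri - 0.5 * dx) * (f(i, k) - mirror(f, i - 1, k))) * idx2 / ri;
      }
      out(i, k) = fr + fz;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_div_axisym(const NumericMatrix& vr, const NumericMatrix& vz,
                             double dx) {
  int nr = vr.nrow(), nz = vr.ncol();
  NumericMatrix out(nr, nz);
  for (int k = 0; k < nz; ++k) {
    for (int i = 0; i < nr; ++i) {
      double dz = (mirror(vz, i, k + 1) - mirror(vz, i, k - 1)) / (2.0 * dx);
      double dr;
      if (i == 0) {
        // 2 * d(vr)/dr with odd symmetry vr(-dx) = -vr(dx)
        dr = 2.0 * mirror(vr, 1, k) / dx;
      } else {
        double ri = i * dx;
        double rp = (i + 1 <= nr - 1) ? (ri + dx) : (ri - dx);
        double rm = ri - dx;
        dr = (rp * mirror(vr, i + 1, k) - rm * mirror(vr, i - 1, k)) /
             (2.0 * dx * ri);
      }
      out(i, k) = dr + dz;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_grad_axisym(const NumericMatrix& f, double dx) {
  int nr = f.nrow(), nz = f.ncol();
  NumericMatrix gr(nr, nz), gz(nr, nz), gm(nr, nz);
  for (int k = 0; k < nz; ++k) {
    for (int i = 0; i < nr; ++i) {
      double dr = (i == 0) ? 0.0
        : (mirror(f, i + 1, k) - mirror(f, i - 1, k)) / (2.0 * dx);
      double dz = (mirror(f, i, k + 1) - mirror(f, i, k - 1)) / (2.0 * dx);
      gr(i, k) = dr; gz(i, k) = dz;
      gm(i, k) = std::sqrt(dr * dr + dz * dz);
    }
  }
  return List::create(_["gr"] = gr, _["gz"] = gz, _["gmag"] = gm);
}

static inline double mirror3(const NumericVector& f, const IntegerVector& d,
                             int i, int j, int k) {
  if (i < 0) i = 1; if (i > d[0] - 1) i = d[0] - 2;
  if (j < 0) j = 1; if (j > d[1] - 1) j = d[1] - 2;
  if (k < 0) k = 1; if (k > d[2] - 1) k = d[2] - 2;
  return f[i + d[0] * (j + d[1] * k)];
}

// [[Rcpp::export]]
NumericVector cpp_lap_cart3(const NumericVector& f, double dx) {
  IntegerVector d = f.attr("dim");
  NumericVector out(f.size());
  out.attr("dim") = d;
  double idx2 = 1.0 / (dx * dx);
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        double c = f[i + d[0] * (j + d[1] * k)];
        out[i + d[0] * (j + d[1] * k)] =
          (mirror3(f, d, i + 1, j, k) + mirror3(f, d, i - 1, j, k) +
           mirror3(f, d, i, j + 1, k) + mirror3(f, d, i, j - 1, k) +
           mirror3(f, d, i, j, k + 1) + mirror3(f, d, i, j, k - 1) -
           6.0 * c) * idx2;
      }
  return out;
}

// Scan the closure-detection line r = dx (first off-axis row) from the top
// of the domain downward, counting 0 -> 1 transitions of phi (threshold
// 0.5). Returns the count and the z indices of the first (zt) and second
// (zb) transition nodes.
// [[Rcpp::export]]
List cpp_closure_scan(const NumericMatrix& phi) {
  int nz = phi.ncol();
  int count = 0, kt = -1, kb = -1;
  bool prev_in = false;  // scanning starts outside the cell at z = Lz
  for (int k = nz - 1; k >= 0; --k) {
    bool in = phi(1, k) >= 0.5;
    if (in && !prev_in) {
      ++count;
      if (count == 1) kt = k;
      else if (count == 2) kb = k;
    }
    prev_in = in;
  }
  return List::create(_["count"] = count, _["kt"] = kt, _["kb"] = kb);
}

// Enclosed extracellular volume at closure: within zb <= z <= zt, each
// z-slice contributes the phi < 0.5 region that is bounded on the outside
// by cell material -- either a disk around the axis or, when the slice has
// cell material at the center, an annulus ("a disk with a hole").
// Integration uses 2*pi*r node weights.
// [[Rcpp::export]]
double cpp_enclosed_volume(const NumericMatrix& phi, double dx,
                           int kb, int kt) {
  int nr = phi.nrow();
  if (kb < 0 || kt < 0) return 0.0;
  if (kb > kt) std::swap(kb, kt);
  double vol = 0.0, w = 2.0 * M_PI * dx * dx;
  for (int k = kb; k <= kt; ++k) {
    // locate the first vacant run scanning outward, skipping any central
    // cell material
    int i = 0;
    while (i < nr && phi(i, k) >= 0.5) ++i;   // skip central material
    int start = i;
    while (i < nr && phi(i, k) < 0.5) ++i;    // the candidate cavity run
    if (i >= nr) continue;                    // ran to the wall: exterior
    for (int m = start; m < i; ++m) vol += w * (m * dx);
  }
  return vol;
}

// Volume of interior cavities of a 3-D phase field: connected components
// (6-connectivity) of the phi < 0.5 region that do not touch the domain
// boundary. Returns total volume and the number of cavities.
// [[Rcpp::export]]
List cpp_cavity_3d(const NumericVector& phi, double dx) {
  IntegerVector d = phi.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  long n = (long)nx * ny * nz;
  std::vector<signed char> lab(n, 0);  // 0 unseen, 1 vacant-exterior, 2 cavity
  std::vector<long> stack;
  // flood the exterior from all boundary vacant nodes
  auto idx = [&](int i, int j, int k) { return (long)i + nx * ((long)j + (long)ny * k); };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i > 0 && i < nx - 1 && j > 0 && j < ny - 1 && k > 0 && k < nz - 1)
          continue;
        long p = idx(i, j, k);
        if (phi[p] < 0.5 && lab[p] == 0) { lab[p] = 1; stack.push_back(p); }
      }
  auto flood = [&](signed char tag) {
    while (!stack.empty()) {
      long p = stack.back(); stack.pop_back();
      int k = p / ((long)nx * ny), rem = p % ((long)nx * ny);
      int j = rem / nx, i = rem % nx;
      const int di[6] = {1, -1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, 1, -1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, 1, -1};
      for (int q = 0; q < 6; ++q) {
        int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        long pp = idx(ii, jj, kk);
        if (phi[pp] < 0.5 && lab[pp] == 0) { lab[pp] = tag; stack.push_back(pp); }
      }
    }
  };
  flood(1);
  long cav_nodes = 0; int ncav = 0;
  for (long p = 0; p < n; ++p) {
    if (phi[p] < 0.5 && lab[p] == 0) {
      ++ncav;
      lab[p] = 2; stack.push_back(p);
      long before = cav_nodes;
      // count while flooding
      while (!stack.empty()) {
        long q = stack.back(); stack.pop_back();
        ++cav_nodes;
        int k = q / ((long)nx * ny), rem = q % ((long)nx * ny);
        int j = rem / nx, i = rem % nx;
        const int di[6] = {1, -1, 0, 0, 0, 0};
        const int dj[6] = {0, 0, 1, -1, 0, 0};
        const int dk[6] = {0, 0, 0, 0, 1, -1};
        for (int t = 0; t < 6; ++t) {
          int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          long pp = idx(ii, jj, kk);
          if (phi[pp] < 0.5 && lab[pp] == 0) { lab[pp] = 2; stack.push_back(pp); }
        }
      }
      (void)before;
    }
  }
  return List::create(_["volume"] = cav_nodes * dx * dx * dx,
                      _["n_cavities"] = ncav);
}

// Connected components (4-connectivity) of a logical matrix; returns the
// component count. Used to count distinct active patches in the (r, z)
// half-plane.
// [[Rcpp::export]]
int cpp_count_components(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nz = mask.ncol();
  std::vector<signed char> seen(nr * nz, 0);
  std::vector<int> stack;
  int ncomp = 0;
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nr; ++i) {
      int p = i + nr * k;
      if (!mask(i, k) || seen[p]) continue;
      ++ncomp;
      seen[p] = 1; stack.push_back(p);
      while (!stack.empty()) {
        int q = stack.back(); stack.pop_back();
        int kk = q / nr, ii = q % nr;
        const int di[4] = {1, -1, 0, 0};
        const int dk[4] = {0, 0, 1, -1};
        for (int t = 0; t < 4; ++t) {
          int i2 = ii + di[t], k2 = kk + dk[t];
          if (i2 < 0 || i2 >= nr || k2 < 0 || k2 >= nz) continue;
          int p2 = i2 + nr * k2;
          if (mask(i2, k2) && !seen[p2]) { seen[p2] = 1; stack.push_back(p2); }
        }
      }
    }
  return ncomp;
}

// Connected components (6-connectivity) of a 3-D logical mask.
// [[Rcpp::export]]
int cpp_count_components_3d(const LogicalVector& mask) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  long n = (long)nx * ny * nz;
  std::vector<signed char> seen(n, 0);
  std::vector<long> stk;
  int ncomp = 0;
  auto idx = [&](int i, int j, int k) {
    return (long)i + nx * ((long)j + (long)ny * k); };
  for (long p = 0; p < n; ++p) {
    if (!mask[p] || seen[p]) continue;
    ++ncomp; seen[p] = 1; stk.push_back(p);
    while (!stk.empty()) {
      long q = stk.back(); stk.pop_back();
      int k = q / ((long)nx * ny), rem = q % ((long)nx * ny);
      int j = rem / nx, i = rem % nx;
      const int di[6] = {1, -1, 0, 0, 0, 0}, dj[6] = {0, 0, 1, -1, 0, 0},
        dk[6] = {0, 0, 0, 0, 1, -1};
      for (int u = 0; u < 6; ++u) {
        int ii = i + di[u], jj = j + dj[u], kk = k + dk[u];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        long pp = idx(ii, jj, kk);
        if (mask[pp] && !seen[pp]) { seen[pp] = 1; stk.push_back(pp); }
      }
    }
  }
  return ncomp;
}

// Exterior-connected vacant region of an axisymmetric phase field:
// flood-fills phi < 0.5 from the outer boundaries (r = Lr, z = 0, z = Lz;
// the symmetry axis is not a boundary). Nodes in the returned mask are
// extracellular space communicating with the domain edge.
// [[Rcpp::export]]
LogicalMatrix cpp_exterior_mask_axisym(const NumericMatrix& phi) {
  int nr = phi.nrow(), nz = phi.ncol();
  LogicalMatrix out(nr, nz);
  std::vector<signed char> seen(nr * nz, 0);
  std::vector<int> stk;
  auto push = [&](int i, int k) {
    int p = i + nr * k;
    if (!seen[p] && phi(i, k) < 0.5) { seen[p] = 1; stk.push_back(p); }
  };
  for (int k = 0; k < nz; ++k) push(nr - 1, k);
  for (int i = 0; i < nr; ++i) { push(i, 0); push(i, nz - 1); }
  while (!stk.empty()) {
    int p = stk.back(); stk.pop_back();
    int k = p / nr, i = p % nr;
    if (i > 0) push(i - 1, k);
    if (i < nr - 1) push(i + 1, k);
    if (k > 0) push(i, k - 1);
    if (k < nz - 1) push(i, k + 1);
  }
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nr; ++i) out(i, k) = seen[i + nr * k] != 0;
  return out;
}

// 3-D analogue: vacant region connected to any domain face.
// [[Rcpp::export]]
LogicalVector cpp_exterior_mask_3d(const NumericVector& phi) {
  IntegerVector d = phi.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  long n = (long)nx * ny * nz;
  std::vector<signed char> seen(n, 0);
  std::vector<long> stk;
  auto idx = [&](int i, int j, int k) {
    return (long)i + nx * ((long)j + (long)ny * k); };
  auto push = [&](int i, int j, int k) {
    long p = idx(i, j, k);
    if (!seen[p] && phi[p] < 0.5) { seen[p] = 1; stk.push_back(p); }
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (i == 0 || i == nx - 1 || j == 0 || j == ny - 1 ||
            k == 0 || k == nz - 1)
          push(i, j, k);
  while (!stk.empty()) {
    long p = stk.back(); stk.pop_back();
    int k = p / ((long)nx * ny), rem = p % ((long)nx * ny);
    int j = rem / nx, i = rem % nx;
    if (i > 0) push(i - 1, j, k);
    if (i < nx - 1) push(i + 1, j, k);
    if (j > 0) push(i, j - 1, k);
    if (j < ny - 1) push(i, j + 1, k);
    if (k > 0) push(i, j, k - 1);
    if (k < nz - 1) push(i, j, k + 1);
  }
  LogicalVector out(n);
  out.attr("dim") = d;
  for (long p = 0; p < n; ++p) out[p] = seen[p] != 0;
  return out;
}
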