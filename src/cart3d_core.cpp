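#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Full 3-D Cartesian explicit-Euler core. Fields are nx x ny x nz arrays
// with spacing dx; boundary condition is no-flux (mirror) on all faces.
// Optional solid bead (static indicator chi with excluded-volume repulsion
// and adhesion) with a uniform drift velocity subtracted to keep the net
// force zero, and optional stochastic patch nucleation.

static inline double ipow3(double x, int n) {
  double r = 1.0;
  while (n-- > 0) r *= x;
  return r;
}
static inline double hillpow3(double x, double nh, int nhi, bool is_int) {
  if (x <= 0.0) return 0.0;
  return is_int ? ipow3(x, nhi) : std::pow(x, nh);
}

// [[Rcpp::export]]
List cpp_run_cart3(NumericVector phi_, NumericVector A_, NumericVector I_,
                   const List& par, const List& ctl) {
  IntegerVector dim = phi_.attr("dim");
  const int nx = dim[0], ny = dim[1], nzz = dim[2];
  const long N = (long)nx * ny * nzz;
  const double tau = par["tau"], eta = par["eta"], eps = par["eps"],
    MV = par["MV"], R0 = par["R0"], V0 = par["V0"], Fmag = par["F"],
    K = par["K"], Kp = par["Kp"], nh = par["nh"], DA = par["DA"],
    DI = par["DI"], at = par["at"], alpha = par["alpha"], k1 = par["k1"],
    k2 = par["k2"], beta = par["beta"], theta = par["theta"],
    dx = par["dx"], dt = par["dt"], gamma2 = par["gamma2"],
    psi_cut = par["psi_cut"], grad_cut = par["grad_cut"],
    clamp_max = par["clamp_max"], clamp_max_I = par["clamp_max_I"];
  const int p_exp = par["p"];
  const std::string law = as<std::string>(par["force_law"]);
  const int law_id = (law == "edge") ? 0 : (law == "edge_linear" ? 1 : 2);
  const bool alpha_inf = !R_finite(alpha);
  const int nhi = (int)std::lround(nh);
  const bool nh_int = std::fabs(nh - nhi) < 1e-12;

  const long n_steps = (long)as<double>(ctl["n_steps"]);
  const int record_every = ctl["record_every"];
  const double extinct_tol = ctl["extinct_tol"];
  const double extinct_window = ctl["extinct_window"];
  const double t0 = ctl["t0"];
  const bool drift = ctl["drift"];
  const bool freeze_phi = ctl["freeze_phi"];   // static-geometry mode
  const bool has_noise = ctl.containsElementNamed("noise") &&
    !Rf_isNull(ctl["noise"]);
  double nz_sigma = 0, nz_d = 1, nz_lambda = 0;
  if (has_noise) {
    List no = ctl["noise"];
    nz_sigma = no["sigma"]; nz_d = no["d"]; nz_lambda = no["lambda"];
  }
  const bool has_bead = ctl.containsElementNamed("chi") &&
    !Rf_isNull(ctl["chi"]);
  double Aatt = 0, Arep = 0;
  std::vector<double> chi, gchi;

  auto at3 = [&](const std::vector<double>& f, int i, int j, int k) {
    if (i < 0) i = 1; if (i > nx - 1) i = nx - 2;
    if (j < 0) j = 1; if (j > ny - 1) j = ny - 2;
    if (k < 0) k = 1; if (k > nzz - 1) k = nzz - 2;
    return f[(long)i + nx * ((long)j + (long)ny * k)];
  };

  if (has_bead) {
    NumericVector chia = ctl["chi"];
    Aatt = as<double>(ctl["Aatt"]); Arep = as<double>(ctl["Arep"]);
    chi.assign(chia.begin(), chia.end());
    gchi.assign(N, 0.0);
    for (int k = 0; k < nzz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          double gx = (at3(chi, i + 1, j, k) - at3(chi, i - 1, j, k)) / (2 * dx);
          double gy = (at3(chi, i, j + 1, k) - at3(chi, i, j - 1, k)) / (2 * dx);
          double gz = (at3(chi, i, j, k + 1) - at3(chi, i, j, k - 1)) / (2 * dx);
          gchi[(long)i + nx * ((long)j + (long)ny * k)] =
            std::sqrt(gx * gx + gy * gy + gz * gz);
        }
  }

  std::vector<double> phi(phi_.begin(), phi_.end()),
    A(A_.begin(), A_.end()), I(I_.begin(), I_.end());
  std::vector<double> psi(N), fden(N, 0.0), vx(N, 0.0), vy(N, 0.0),
    vz(N, 0.0), phinew(N), Anew(N), Inew(N);
  const double dV = dx * dx * dx, eps2 = eps * eps;
  const double At_tot = at * 4.0 * M_PI * R0 * R0;
  const double Vdom = N * dV;

  bool has_I = (k1 > 0) || (k2 > 0);
  for (long q = 0; q < N && !has_I; ++q) if (I[q] > 0) has_I = true;

  std::vector<double> ser;
  const int SER_NC = 12;
  double t = t0, extinct_time = 0.0;
  std::string status = "t_max";
  int n_Bclip = 0;
  long step = 0;

  auto cavity = [&]() {  // interior-cavity volume via exterior flood fill
    std::vector<signed char> lab(N, 0);
    std::vector<long> stk;
    auto idx = [&](int i, int j, int k) {
      return (long)i + nx * ((long)j + (long)ny * k); };
    for (int k = 0; k < nzz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          if (i > 0 && i < nx - 1 && j > 0 && j < ny - 1 && k > 0 && k < nzz - 1)
            continue;
          long p = idx(i, j, k);
          if (phi[p] < 0.5 && !lab[p]) { lab[p] = 1; stk.push_back(p); }
        }
    while (!stk.empty()) {
      long p = stk.back(); stk.pop_back();
      int k = p / ((long)nx * ny), rem = p % ((long)nx * ny);
      int j = rem / nx, i = rem % nx;
      const int di[6] = {1, -1, 0, 0, 0, 0}, dj[6] = {0, 0, 1, -1, 0, 0},
        dk[6] = {0, 0, 0, 0, 1, -1};
      for (int u = 0; u < 6; ++u) {
        int ii = i + di[u], jj = j + dj[u], kk = k + dk[u];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nzz)
          continue;
        long pp = idx(ii, jj, kk);
        if (phi[pp] < 0.5 && !lab[pp]) { lab[pp] = 1; stk.push_back(pp); }
      }
    }
    long nodes = 0;
    for (long p = 0; p < N; ++p) if (phi[p] < 0.5 && !lab[p]) ++nodes;
    return nodes * dV;
  };

  for (step = 0; step < n_steps; ++step) {
    double V = 0, S = 0, intA = 0, cx = 0, cy = 0, cz = 0;
    for (long q = 0; q < N; ++q) {
      double ph = phi[q];
      double u = ph * (1.0 - ph);
      double ps = 1.0 / (1.0 + std::exp(-beta * (u - theta)));
      psi[q] = ps;
      V += ph; S += ps; intA += A[q] * ps;
    }
    V *= dV; S *= dV / eps; intA *= dV / eps;
    if (!std::isfinite(V) || S <= 0.0)
      stop("3-D solver blow-up at t = %g (V = %g, S = %g)", t, V, S);
    double B = At_tot / S - intA / S;
    if (B < 0) { B = 0; ++n_Bclip; }
    if (drift) {
      for (int k = 0; k < nzz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            double ph = phi[(long)i + nx * ((long)j + (long)ny * k)];
            cx += ph * i; cy += ph * j; cz += ph * k;
          }
      double tot = V / dV;
      cx = cx / tot * dx; cy = cy / tot * dx; cz = cz / tot * dx;
    }

    double fx = 0, fy = 0, fz = 0;
    if (!freeze_phi)
    for (int k = 0; k < nzz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          long q = (long)i + nx * ((long)j + (long)ny * k);
          double ph = phi[q];
          double lap = (at3(phi, i + 1, j, k) + at3(phi, i - 1, j, k) +
                        at3(phi, i, j + 1, k) + at3(phi, i, j - 1, k) +
                        at3(phi, i, j, k + 1) + at3(phi, i, j, k - 1) -
                        6.0 * ph) / (dx * dx);
          double gx = (at3(phi, i + 1, j, k) - at3(phi, i - 1, j, k)) / (2 * dx);
          double gy = (at3(phi, i, j + 1, k) - at3(phi, i, j - 1, k)) / (2 * dx);
          double gz = (at3(phi, i, j, k + 1) - at3(phi, i, j, k - 1)) / (2 * dx);
          double g = std::sqrt(gx * gx + gy * gy + gz * gz);
          double Gp = 16.0 * ph * (1.0 - ph) * (1.0 - 2.0 * ph);
          double x = hillpow3(A[q] / K, nh, nhi, nh_int);
          double sup = (law_id == 0)
            ? hillpow3(A[q] * A[q] / Kp, nh, nhi, nh_int)
            : (law_id == 1 ? hillpow3(A[q] / Kp, nh, nhi, nh_int)
                           : hillpow3(I[q] / Kp, nh, nhi, nh_int));
          double Fp = Fmag * (x / (1.0 + x)) / (1.0 + sup);
          double fd = eta * (lap - Gp / eps2) - MV * (V - V0) * g + Fp * g;
          if (has_bead)
            fd += -Arep * chi[q] * chi[q] * ph + Aatt * gchi[q] * g;
          fden[q] = fd;
          if (g > grad_cut) {
            double s = fd / (tau * g);
            vx[q] = -s * gx / g; vy[q] = -s * gy / g; vz[q] = -s * gz / g;
          } else { vx[q] = vy[q] = vz[q] = 0.0; }
          if (drift) {
            fx += (i * dx - cx) * fd; fy += (j * dx - cy) * fd;
            fz += (k * dx - cz) * fd;
          }
        }
    double vtx = 0, vty = 0, vtz = 0;
    if (drift && !freeze_phi) {
      vtx = -fx * dV / (V * tau); vty = -fy * dV / (V * tau);
      vtz = -fz * dV / (V * tau);
    }

    if (!freeze_phi)
    for (int k = 0; k < nzz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          long q = (long)i + nx * ((long)j + (long)ny * k);
          double d = (dt / tau) * fden[q];
          if (drift) {
            double gx = (at3(phi, i + 1, j, k) - at3(phi, i - 1, j, k)) / (2 * dx);
            double gy = (at3(phi, i, j + 1, k) - at3(phi, i, j - 1, k)) / (2 * dx);
            double gz = (at3(phi, i, j, k + 1) - at3(phi, i, j, k - 1)) / (2 * dx);
            d -= dt * (vtx * gx + vty * gy + vtz * gz);
          }
          phinew[q] = phi[q] + d;
        }
    if (drift && !freeze_phi)
      for (long q = 0; q < N; ++q) { vx[q] += vtx; vy[q] += vty; vz[q] += vtz; }

    double maxA = 0.0;
    for (int k = 0; k < nzz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          long q = (long)i + nx * ((long)j + (long)ny * k);
          if (psi[q] > psi_cut) {
            auto upwind = [&](const std::vector<double>& Q,
                              const std::vector<double>& vv,
                              int di, int dj, int dk2) {
              // flux difference along one axis with mirror ghosts
              double vfp = 0.5 * (vv[q] +
                at3(vv, i + di, j + dj, k + dk2));
              double qfp = vfp > 0 ? Q[q] : at3(Q, i + di, j + dj, k + dk2);
              double vfm = 0.5 * (at3(vv, i - di, j - dj, k - dk2) + vv[q]);
              double qfm = vfm > 0 ? at3(Q, i - di, j - dj, k - dk2) : Q[q];
              return (vfp * qfp - vfm * qfm) / dx;
            };
            // band-confined transport (1/psi) div(psi grad Q) in
            // conservative flux form with geometric-mean face weights
            // (see the axisymmetric core for rationale)
            // faces into the off-band decay zone are no-flux walls
            auto band_diff = [&](const std::vector<double>& Q) {
              double tot = 0.0;
              const int di[3] = {1, 0, 0}, dj[3] = {0, 1, 0},
                dk2[3] = {0, 0, 1};
              for (int ax = 0; ax < 3; ++ax) {
                double Qp = at3(Q, i + di[ax], j + dj[ax], k + dk2[ax]);
                double Qm = at3(Q, i - di[ax], j - dj[ax], k - dk2[ax]);
                double pp = at3(psi, i + di[ax], j + dj[ax], k + dk2[ax]);
                double pm = at3(psi, i - di[ax], j - dj[ax], k - dk2[ax]);
                if (pp > psi_cut)
                  tot += std::sqrt(psi[q] * pp) * (Qp - Q[q]);
                if (pm > psi_cut)
                  tot -= std::sqrt(psi[q] * pm) * (Q[q] - Qm);
              }
              return tot / (dx * dx * psi[q]);
            };
            double sat = alpha_inf ? 1.0
              : (1.0 + A[q] * A[q] / (alpha * alpha));
            double RA = A[q] * A[q] * B / (sat * (1.0 + I[q])) - A[q];
            double adv = upwind(A, vx, 1, 0, 0) + upwind(A, vy, 0, 1, 0) +
                         upwind(A, vz, 0, 0, 1);
            double dA = -adv + DA * band_diff(A) + RA;
            Anew[q] = A[q] + dt * dA;
            if (has_I) {
              double RI = k1 * (p_exp == 2 ? A[q] * A[q] : A[q]) - k2 * I[q];
              double advI = upwind(I, vx, 1, 0, 0) + upwind(I, vy, 0, 1, 0) +
                            upwind(I, vz, 0, 0, 1);
              double dI = -advI + DI * band_diff(I) + RI;
              Inew[q] = I[q] + dt * dI;
            }
          } else {
            Anew[q] = A[q] * (1.0 - gamma2 * dt);
            if (has_I) Inew[q] = I[q] * (1.0 - gamma2 * dt);
          }
          if (Anew[q] < 0) Anew[q] = 0;
          if (Anew[q] > clamp_max) Anew[q] = clamp_max;
          if (has_I) {
            if (Inew[q] < 0) Inew[q] = 0;
            if (Inew[q] > clamp_max_I) Inew[q] = clamp_max_I;
          }
          if (Anew[q] > maxA) maxA = Anew[q];
        }
    if (!freeze_phi) phi.swap(phinew);
    A.swap(Anew);
    if (has_I) I.swap(Inew);
    if (drift && !freeze_phi)
      for (long q = 0; q < N; ++q) { vx[q] -= vtx; vy[q] -= vty; vz[q] -= vtz; }
    t += dt;

    if (has_noise) {
      int nev = (int)R::rpois(nz_lambda * Vdom * dt);
      for (int e = 0; e < nev; ++e) {
        double xc = (nx - 1) * dx * R::unif_rand();
        double yc = (ny - 1) * dx * R::unif_rand();
        double zc = (nzz - 1) * dx * R::unif_rand();
        double N0 = R::exp_rand() * nz_sigma;
        for (int k = 0; k < nzz; ++k)
          for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i) {
              long q = (long)i + nx * ((long)j + (long)ny * k);
              if (psi[q] <= psi_cut) continue;
              double ddx = i * dx - xc, ddy = j * dx - yc, ddz = k * dx - zc;
              double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
              if (d2 > 25.0 * nz_d * nz_d) continue;
              A[q] += N0 * std::exp(-d2 / (2.0 * nz_d * nz_d));
              if (A[q] > clamp_max) A[q] = clamp_max;
              if (A[q] > maxA) maxA = A[q];
            }
      }
    }
    if (!std::isfinite(maxA))
      stop("3-D solver blow-up at t = %g (non-finite A)", t);

    if (maxA < extinct_tol) {
      extinct_time += dt;
      if (extinct_time >= extinct_window) { status = "extinct"; ++step; break; }
    } else extinct_time = 0.0;

    if (step % record_every == 0 || step == n_steps - 1) {
      double cav = cavity();
      double engulf = NA_REAL;
      if (has_bead) {
        double num = 0, den = 0;
        for (long q = 0; q < N; ++q) { num += chi[q] * phi[q]; den += chi[q]; }
        engulf = num / den;
      }
      double ccx = 0, ccy = 0, ccz = 0, tot = 0;
      for (int k = 0; k < nzz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            double ph = phi[(long)i + nx * ((long)j + (long)ny * k)];
            ccx += ph * i; ccy += ph * j; ccz += ph * k; tot += ph;
          }
      double row[SER_NC] = {t, V, S, B, intA / S, maxA, cav, cav / V0,
                            engulf, ccx / tot * dx, ccy / tot * dx,
                            ccz / tot * dx};
      ser.insert(ser.end(), row, row + SER_NC);
    }
    if (step % 200 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector phio(phi.begin(), phi.end()), Ao(A.begin(), A.end()),
    Io(I.begin(), I.end()), psio(psi.begin(), psi.end());
  phio.attr("dim") = dim; Ao.attr("dim") = dim; Io.attr("dim") = dim;
  psio.attr("dim") = dim;
  int nrow_ser = ser.size() / SER_NC;
  NumericMatrix serm(nrow_ser, SER_NC);
  for (int r = 0; r < nrow_ser; ++r)
    for (int c = 0; c < SER_NC; ++c) serm(r, c) = ser[r * SER_NC + c];
  colnames(serm) = CharacterVector::create(
    "t", "V", "S", "B", "meanA", "maxA", "cavity_volume", "cavity_frac",
    "engulf_frac", "centroid_x", "centroid_y", "centroid_z");
  return List::create(
    _["phi"] = phio, _["A"] = Ao, _["I"] = Io, _["psi"] = psio,
    _["t"] = t, _["status"] = status, _["steps_done"] = (double)step,
    _["n_Bclip"] = n_Bclip, _["series"] = serm);
}
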