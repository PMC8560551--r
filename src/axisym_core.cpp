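#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Quasi-3D (axisymmetric) explicit-Euler core for the coupled phase-field /
// membrane reaction-diffusion model. Fields live on an nr x nz node grid,
// r = i*dx with the symmetry axis on row 0, z = k*dx. Boundary conditions:
// Neumann (mirror) at r = 0, Dirichlet phi = A = I = 0 at z = 0, z = Lz and
// r = Lr. Integrals use midpoint quadrature with the 2*pi*r Jacobian.

static inline double ipow(double x, int n) {
  double r = 1.0;
  while (n-- > 0) r *= x;
  return r;
}

static inline double hillpow(double x, double nh, int nhi, bool is_int) {
  if (x <= 0.0) return 0.0;
  return is_int ? ipow(x, nhi) : std::pow(x, nh);
}

// [[Rcpp::export]]
List cpp_run_axisym(NumericMatrix phi_, NumericMatrix A_, NumericMatrix I_,
                    const List& par, const List& ctl) {
  const int nr = phi_.nrow(), nz = phi_.ncol();
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
  const int stop_after_closures = ctl["stop_after_closures"];
  const double extinct_tol = ctl["extinct_tol"];
  const double extinct_window = ctl["extinct_window"];
  const double patch_thresh = ctl["patch_thresh"];
  const double t0 = ctl["t0"];
  const bool drift = ctl["drift"];
  const bool freeze_phi = ctl["freeze_phi"];   // static-geometry mode
  const bool react_off = ctl["react_off"];     // pure advection-diffusion
  const bool adv_off = ctl.containsElementNamed("adv_off") &&
    as<bool>(ctl["adv_off"]);                  // diagnostic: no advection
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
  const int N = nr * nz;
  if (has_bead) {
    NumericMatrix chim = ctl["chi"];
    Aatt = as<double>(ctl["Aatt"]); Arep = as<double>(ctl["Arep"]);
    chi.assign(chim.begin(), chim.end());
    gchi.assign(N, 0.0);
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nr; ++i) {
        double gr, gz;
        int ip = std::min(i + 1, nr - 1), im = std::abs(i - 1);
        int kp = std::min(k + 1, nz - 1), km = std::max(k - 1, 0);
        gr = (i == 0) ? 0.0 : (chi[ip + nr * k] - chi[im + nr * k]) / (2 * dx);
        gz = (chi[i + nr * kp] - chi[i + nr * km]) / (2 * dx);
        gchi[i + nr * k] = std::sqrt(gr * gr + gz * gz);
      }
  }

  std::vector<double> phi(phi_.begin(), phi_.end()),
    A(A_.begin(), A_.end()), I(I_.begin(), I_.end());
  std::vector<double> psi(N), fden(N, 0.0), vr(N, 0.0), vz(N, 0.0),
    Anew(N), Inew(N), phinew(N);
  std::vector<double> rw(nr), rnode(nr);
  const double w0 = 2.0 * M_PI * dx * dx;
  for (int i = 0; i < nr; ++i) { rnode[i] = i * dx; rw[i] = w0 * rnode[i]; }
  const double eps2 = eps * eps, At_tot = at * 4.0 * M_PI * R0 * R0;
  const double Vdom = M_PI * (nr - 1) * dx * (nr - 1) * dx * (nz - 1) * dx;

  bool has_I = (k1 > 0) || (k2 > 0);
  for (int q = 0; q < N && !has_I; ++q) if (I[q] > 0) has_I = true;

  // recorded time series and closure events
  std::vector<double> ser;             // row-major buffer, 10 cols
  const int SER_NC = 10;
  std::vector<double> ev_t, ev_vol, ev_frac, ev_zb, ev_zt;
  int n_closures = 0, n_Bclip = 0;
  bool in_closed_state = false;
  double t = t0, extinct_time = 0.0, last_frac = 0.0;
  std::string status = "t_max";

  auto record = [&](double V, double S, double B, double meanA, double maxA,
                    int scount) {
    // distinct active patches: psi > 0.5 band nodes with A above threshold
    std::vector<signed char> seen(N, 0);
    std::vector<int> stk;
    int npatch = 0;
    for (int q = 0; q < N; ++q) {
      if (seen[q] || psi[q] <= 0.5 || A[q] <= patch_thresh) continue;
      ++npatch; seen[q] = 1; stk.push_back(q);
      while (!stk.empty()) {
        int s = stk.back(); stk.pop_back();
        int kk = s / nr, ii = s % nr;
        const int di[4] = {1, -1, 0, 0}, dk[4] = {0, 0, 1, -1};
        for (int u = 0; u < 4; ++u) {
          int i2 = ii + di[u], k2 = kk + dk[u];
          if (i2 < 0 || i2 >= nr || k2 < 0 || k2 >= nz) continue;
          int p2 = i2 + nr * k2;
          if (!seen[p2] && psi[p2] > 0.5 && A[p2] > patch_thresh) {
            seen[p2] = 1; stk.push_back(p2);
          }
        }
      }
    }
    double row[SER_NC] = {t, V, S, B, meanA, maxA, (double)n_closures,
                          last_frac, meanA * S + B * S, (double)npatch};
    ser.insert(ser.end(), row, row + SER_NC);
    (void)scount;
  };

  long step = 0;
  for (step = 0; step < n_steps; ++step) {
    // ---- psi and global scalars ----
    double V = 0, S = 0, intA = 0, zmom = 0;
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nr; ++i) {
        int q = i + nr * k;
        double ph = phi[q];
        double u = ph * (1.0 - ph);
        double ps = 1.0 / (1.0 + std::exp(-beta * (u - theta)));
        psi[q] = ps;
        double w = rw[i];
        V += ph * w; S += ps * w / eps; intA += A[q] * ps * w / eps;
        if (drift) zmom += ph * w * (k * dx);
      }
    if (!std::isfinite(V) || S <= 0.0)
      stop("axisym solver blow-up at t = %g (V = %g, S = %g)", t, V, S);
    double B = At_tot / S - intA / S;
    if (B < 0) { B = 0; ++n_Bclip; }
    double zc = drift ? zmom / V : 0.0;

    // ---- force density on the interface ----
    double fmom = 0.0;  // z-moment of the force density, for drift velocity
    if (!freeze_phi)
    for (int k = 1; k < nz - 1; ++k)
      for (int i = 0; i < nr - 1; ++i) {
        int q = i + nr * k;
        double ph = phi[q];
        double phr_p = (i + 1 <= nr - 1) ? phi[q + 1] : 0.0;
        double phr_m = (i >= 1) ? phi[q - 1] : phi[q + 1];
        double phz_p = phi[q + nr], phz_m = phi[q - nr];
        double lap;
        if (i == 0)
          lap = 4.0 * (phi[q + 1] - ph) / (dx * dx);
        else
          lap = ((rnode[i] + 0.5 * dx) * (phr_p - ph) -
                 (rnode[i] - 0.5 * dx) * (ph - phr_m)) / (rnode[i] * dx * dx);
        lap += (phz_p - 2.0 * ph + phz_m) / (dx * dx);
        double gr = (i == 0) ? 0.0 : (phr_p - phr_m) / (2.0 * dx);
        double gz = (phz_p - phz_m) / (2.0 * dx);
        double g = std::sqrt(gr * gr + gz * gz);
        double Gp = 16.0 * ph * (1.0 - ph) * (1.0 - 2.0 * ph);
        double x = hillpow(A[q] / K, nh, nhi, nh_int);
        double suppress = (law_id == 0)
          ? hillpow(A[q] * A[q] / Kp, nh, nhi, nh_int)
          : (law_id == 1 ? hillpow(A[q] / Kp, nh, nhi, nh_int)
                         : hillpow(I[q] / Kp, nh, nhi, nh_int));
        double Fp = Fmag * (x / (1.0 + x)) / (1.0 + suppress);
        double fd = eta * (lap - Gp / eps2) - MV * (V - V0) * g + Fp * g;
        if (has_bead)
          fd += -Arep * chi[q] * chi[q] * ph + Aatt * gchi[q] * g;
        fden[q] = fd;
        vr[q] = 0.0; vz[q] = 0.0;
        if (g > grad_cut) {
          double s = fd / (tau * g);
          vr[q] = -s * gr / g;
          vz[q] = -s * gz / g;
        }
        if (drift) fmom += (k * dx - zc) * fd * rw[i];
      }
    double vtz = (drift && !freeze_phi) ? -fmom / (V * tau) : 0.0;

    // ---- phi update ----
    if (!freeze_phi) {
    for (int k = 1; k < nz - 1; ++k)
      for (int i = 0; i < nr - 1; ++i) {
        int q = i + nr * k;
        double d = (dt / tau) * fden[q];
        if (drift) {
          double gz = (phi[q + nr] - phi[q - nr]) / (2.0 * dx);
          d -= dt * vtz * gz;
        }
        phinew[q] = phi[q] + d;
      }
    for (int i = 0; i < nr; ++i) { phinew[i] = 0.0; phinew[i + nr * (nz - 1)] = 0.0; }
    for (int k = 0; k < nz; ++k) phinew[(nr - 1) + nr * k] = 0.0;
    }
    if (drift && !freeze_phi) for (int q = 0; q < N; ++q) vz[q] += vtz;

    // ---- A (and I) update on the old geometry ----
    double maxA = 0.0;
    for (int k = 1; k < nz - 1; ++k)
      for (int i = 0; i < nr - 1; ++i) {
        int q = i + nr * k;
        if (psi[q] > psi_cut) {
          // conservative first-order upwind advection, axisym weights
          auto adv = [&](const std::vector<double>& Q) {
            double vf, qf, Gp_, Gm_, div;
            // r faces
            vf = 0.5 * (vr[q] + ((i + 1 <= nr - 1) ? vr[q + 1] : 0.0));
            qf = vf > 0 ? Q[q] : ((i + 1 <= nr - 1) ? Q[q + 1] : 0.0);
            Gp_ = vf * qf;
            if (i == 0) {
              div = 4.0 * Gp_ / dx;
            } else {
              vf = 0.5 * (vr[q - 1] + vr[q]);
              qf = vf > 0 ? Q[q - 1] : Q[q];
              Gm_ = vf * qf;
              div = ((rnode[i] + 0.5 * dx) * Gp_ -
                     (rnode[i] - 0.5 * dx) * Gm_) / (rnode[i] * dx);
            }
            // z faces
            vf = 0.5 * (vz[q] + vz[q + nr]);
            qf = vf > 0 ? Q[q] : Q[q + nr];
            Gp_ = vf * qf;
            vf = 0.5 * (vz[q - nr] + vz[q]);
            qf = vf > 0 ? Q[q - nr] : Q[q];
            Gm_ = vf * qf;
            div += (Gp_ - Gm_) / dx;
            return div;
          };
          // Band-confined transport (1/psi) div(psi grad Q): the
          // confinement drift and the Laplacian of the operational
          // equations combined, in conservative flux form with
          // geometric-mean face weights -- conserves the banded mass
          // int(Q psi) and stays stable where the drift's cell Peclet
          // number exceeds 2 (coarse grids)
          // faces into the off-band decay zone are no-flux walls: the
          // transport system ends at the psi cutoff
          auto wface = [&](double ps_nb) {
            return ps_nb > psi_cut ? std::sqrt(psi[q] * ps_nb) : 0.0;
          };
          auto band_diff = [&](const std::vector<double>& Q) {
            double Qr_p = (i + 1 <= nr - 1) ? Q[q + 1] : 0.0;
            double ps_rp = (i + 1 <= nr - 1) ? psi[q + 1] : 0.0;
            double fr_p = wface(ps_rp) * (Qr_p - Q[q]);
            double rad;
            if (i == 0) {
              rad = 4.0 * fr_p / (dx * dx);
            } else {
              double fr_m = wface(psi[q - 1]) * (Q[q] - Q[q - 1]);
              rad = ((rnode[i] + 0.5 * dx) * fr_p -
                     (rnode[i] - 0.5 * dx) * fr_m) / (rnode[i] * dx * dx);
            }
            double fz_p = wface(psi[q + nr]) * (Q[q + nr] - Q[q]);
            double fz_m = wface(psi[q - nr]) * (Q[q] - Q[q - nr]);
            return (rad + (fz_p - fz_m) / (dx * dx)) / psi[q];
          };
          double sat = alpha_inf ? 1.0 : (1.0 + A[q] * A[q] / (alpha * alpha));
          double RA = react_off ? 0.0
            : A[q] * A[q] * B / (sat * (1.0 + I[q])) - A[q];
          double dA = (adv_off ? 0.0 : -adv(A)) + DA * band_diff(A) + RA;
          Anew[q] = A[q] + dt * dA;
          if (has_I) {
            double RI = react_off ? 0.0
              : k1 * (p_exp == 2 ? A[q] * A[q] : A[q]) - k2 * I[q];
            double dI = (adv_off ? 0.0 : -adv(I)) + DI * band_diff(I) + RI;
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
    for (int i = 0; i < nr; ++i) { Anew[i] = 0; Anew[i + nr * (nz - 1)] = 0; }
    for (int k = 0; k < nz; ++k) Anew[(nr - 1) + nr * k] = 0;
    if (has_I) {
      for (int i = 0; i < nr; ++i) { Inew[i] = 0; Inew[i + nr * (nz - 1)] = 0; }
      for (int k = 0; k < nz; ++k) Inew[(nr - 1) + nr * k] = 0;
    }
    if (!freeze_phi) phi.swap(phinew);
    A.swap(Anew);
    if (has_I) I.swap(Inew);
    if (drift && !freeze_phi)
      for (int q = 0; q < N; ++q) vz[q] -= vtz;  // restore buffer
    t += dt;

    // ---- stochastic nucleation ----
    if (has_noise) {
      int nev = (int)R::rpois(nz_lambda * Vdom * dt);
      for (int e = 0; e < nev; ++e) {
        double rc = (nr - 1) * dx * std::sqrt(R::unif_rand());
        double zcn = (nz - 1) * dx * R::unif_rand();
        double N0 = R::exp_rand() * nz_sigma;
        for (int k = 0; k < nz; ++k)
          for (int i = 0; i < nr; ++i) {
            int q = i + nr * k;
            if (psi[q] <= psi_cut) continue;
            double dr = rnode[i] - rc, dz = k * dx - zcn;
            double d2 = dr * dr + dz * dz;
            if (d2 > 25.0 * nz_d * nz_d) continue;
            A[q] += N0 * std::exp(-d2 / (2.0 * nz_d * nz_d));
            if (A[q] > clamp_max) A[q] = clamp_max;
            if (A[q] > maxA) maxA = A[q];
          }
      }
    }
    if (!std::isfinite(maxA))
      stop("axisym solver blow-up at t = %g (non-finite A)", t);

    // ---- closure detection (every step, debounced) ----
    {
      int count = 0, kt = -1, kb = -1;
      bool prev_in = false;
      for (int k = nz - 1; k >= 0; --k) {
        bool in = phi[1 + nr * k] >= 0.5;
        if (in && !prev_in) {
          ++count;
          if (count == 1) kt = k; else if (count == 2) kb = k;
        }
        prev_in = in;
      }
      bool closed = count >= 2;
      if (closed && !in_closed_state) {
        double vol = 0.0;
        int klo = std::min(kb, kt), khi = std::max(kb, kt);
        for (int k = klo; k <= khi; ++k) {
          int i = 0;
          while (i < nr && phi[i + nr * k] >= 0.5) ++i;
          int start = i;
          while (i < nr && phi[i + nr * k] < 0.5) ++i;
          if (i >= nr) continue;
          for (int m = start; m < i; ++m) vol += w0 * rnode[m];
        }
        ++n_closures;
        last_frac = vol / V0;
        ev_t.push_back(t); ev_vol.push_back(vol); ev_frac.push_back(vol / V0);
        ev_zb.push_back(klo * dx); ev_zt.push_back(khi * dx);
      }
      in_closed_state = closed;
    }
    if (stop_after_closures > 0 && n_closures >= stop_after_closures) {
      record(V, S, B, intA / S, maxA, 0);
      status = "closures"; ++step; break;
    }

    // ---- patch extinction ----
    if (maxA < extinct_tol) {
      extinct_time += dt;
      if (extinct_time >= extinct_window) {
        record(V, S, B, intA / S, maxA, 0);
        status = "extinct"; ++step; break;
      }
    } else extinct_time = 0.0;

    if (step % record_every == 0) record(V, S, B, intA / S, maxA, 0);
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix phio(nr, nz), Ao(nr, nz), Io(nr, nz), psio(nr, nz);
  std::copy(phi.begin(), phi.end(), phio.begin());
  std::copy(A.begin(), A.end(), Ao.begin());
  std::copy(I.begin(), I.end(), Io.begin());
  std::copy(psi.begin(), psi.end(), psio.begin());
  int nrow_ser = ser.size() / SER_NC;
  NumericMatrix serm(nrow_ser, SER_NC);
  for (int r = 0; r < nrow_ser; ++r)
    for (int c = 0; c < SER_NC; ++c) serm(r, c) = ser[r * SER_NC + c];
  colnames(serm) = CharacterVector::create(
    "t", "V", "S", "B", "meanA", "maxA", "n_closures", "last_frac",
    "mass_total", "n_patches");
  return List::create(
    _["phi"] = phio, _["A"] = Ao, _["I"] = Io, _["psi"] = psio,
    _["t"] = t, _["status"] = status, _["steps_done"] = (double)step,
    _["n_closures"] = n_closures, _["n_Bclip"] = n_Bclip,
    _["series"] = serm,
    _["events"] = List::create(
      _["t"] = ev_t, _["volume"] = ev_vol, _["fraction"] = ev_frac,
      _["zb"] = ev_zb, _["zt"] = ev_zt));
}

// Phase-field-only relaxation under a prescribed static protrusive-force
// field (the reduced patch-boundary model drives phi this way between
// boundary-marker updates). Volume constraint and tension are active.
// [[Rcpp::export]]
List cpp_phi_relax_axisym(NumericMatrix phi_, const NumericMatrix& Fpoly,
                          const List& par, int n_steps) {
  const int nr = phi_.nrow(), nz = phi_.ncol();
  const double tau = par["tau"], eta = par["eta"], eps = par["eps"],
    MV = par["MV"], V0 = par["V0"], dx = par["dx"], dt = par["dt"];
  const int N = nr * nz;
  std::vector<double> phi(phi_.begin(), phi_.end()), phinew(N, 0.0);
  std::vector<double> rw(nr), rnode(nr);
  const double w0 = 2.0 * M_PI * dx * dx;
  for (int i = 0; i < nr; ++i) { rnode[i] = i * dx; rw[i] = w0 * rnode[i]; }
  const double eps2 = eps * eps;
  double V = 0;
  for (int s = 0; s < n_steps; ++s) {
    V = 0;
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nr; ++i) V += phi[i + nr * k] * rw[i];
    if (!std::isfinite(V))
      stop("reduced-model phi relaxation blow-up (non-finite volume)");
    for (int k = 1; k < nz - 1; ++k)
      for (int i = 0; i < nr - 1; ++i) {
        int q = i + nr * k;
        double ph = phi[q];
        double phr_p = (i + 1 <= nr - 1) ? phi[q + 1] : 0.0;
        double phr_m = (i >= 1) ? phi[q - 1] : phi[q + 1];
        double lap;
        if (i == 0)
          lap = 4.0 * (phi[q + 1] - ph) / (dx * dx);
        else
          lap = ((rnode[i] + 0.5 * dx) * (phr_p - ph) -
                 (rnode[i] - 0.5 * dx) * (ph - phr_m)) / (rnode[i] * dx * dx);
        lap += (phi[q + nr] - 2.0 * ph + phi[q - nr]) / (dx * dx);
        double gr = (i == 0) ? 0.0 : (phr_p - phr_m) / (2.0 * dx);
        double gz = (phi[q + nr] - phi[q - nr]) / (2.0 * dx);
        double g = std::sqrt(gr * gr + gz * gz);
        double Gp = 16.0 * ph * (1.0 - ph) * (1.0 - 2.0 * ph);
        double fd = eta * (lap - Gp / eps2) - MV * (V - V0) * g +
                    Fpoly(i, k) * g;
        phinew[q] = ph + (dt / tau) * fd;
      }
    for (int i = 0; i < nr; ++i) { phinew[i] = 0; phinew[i + nr * (nz - 1)] = 0; }
    for (int k = 0; k < nz; ++k) phinew[(nr - 1) + nr * k] = 0;
    phi.swap(phinew);
  }
  NumericMatrix out(nr, nz);
  std::copy(phi.begin(), phi.end(), out.begin());
  return List::create(_["phi"] = out, _["V"] = V);
}
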