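// Time-stepping core for the spatially extended Epileptor-2 system.
//
// All quantities are in the package-internal unit system: s, mm, mV, mM, Hz.
// Fields are nx x ny matrices; row index i is x, column index j is y.
//
// The presynaptic-rate elliptic problem (I - lambda^2 Lap) phi = nu with
// Neumann boundaries is solved exactly in the DCT-II eigenbasis of the
// 5-point Neumann Laplacian (two small GEMMs each way). Lesioned domains
// break separability, so there the system is solved by warm-started
// conjugate gradients with phi = 0 Dirichlet rows on lesion cells.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::mat;
using arma::imat;

// 5-point Laplacian in flux form (units: field units, caller divides by dx^2).
// Zero-flux (mirror) at outer boundaries; if block_lesion, edges touching a
// lesion cell carry no flux (impermeable cut).
static void lap_flux(const mat& F, mat& L, const imat& lesion,
                     bool has_lesion, bool block_lesion, int cut_after) {
  const int nx = F.n_rows, ny = F.n_cols;
  const bool blk = has_lesion && block_lesion;
  // cut_after >= 0: the x-flux across the interface between rows
  // cut_after and cut_after + 1 is zeroed (an impermeable blade cut)
  const bool cut = block_lesion && cut_after >= 0;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      const double c = F(i, j);
      double s = 0.0;
      if (i > 0      && !(blk && (lesion(i-1,j) || lesion(i,j)))
                     && !(cut && i - 1 == cut_after)) s += F(i-1,j) - c;
      if (i < nx - 1 && !(blk && (lesion(i+1,j) || lesion(i,j)))
                     && !(cut && i == cut_after))     s += F(i+1,j) - c;
      if (j > 0      && !(blk && (lesion(i,j-1) || lesion(i,j)))) s += F(i,j-1) - c;
      if (j < ny - 1 && !(blk && (lesion(i,j+1) || lesion(i,j)))) s += F(i,j+1) - c;
      L(i, j) = s;
    }
  }
}

// Apply A = I - beta * LapD to P, where LapD is the 5-point Laplacian with
// Neumann mirroring at the outer boundary and Dirichlet phi = 0 on lesion
// cells (lesion rows are identity). beta = lambda^2 / dx^2.
static void apply_screened(const mat& P, mat& AP, const imat& lesion, double beta) {
  const int nx = P.n_rows, ny = P.n_cols;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (lesion(i, j)) { AP(i, j) = P(i, j); continue; }
      const double c = P(i, j);
      double s = 0.0;
      if (i > 0)      s += (lesion(i-1,j) ? 0.0 : P(i-1,j)) - c;
      if (i < nx - 1) s += (lesion(i+1,j) ? 0.0 : P(i+1,j)) - c;
      if (j > 0)      s += (lesion(i,j-1) ? 0.0 : P(i,j-1)) - c;
      if (j < ny - 1) s += (lesion(i,j+1) ? 0.0 : P(i,j+1)) - c;
      AP(i, j) = c - beta * s;
    }
  }
}

// Conjugate gradients on the screened-Poisson system, warm-started from phi.
// Returns iterations used; throws if the relative residual never reaches tol.
static int solve_cg(mat& phi, const mat& rhs, const imat& lesion,
                    double beta, double tol, int maxit) {
  const double bnorm = arma::norm(rhs, "fro");
  if (bnorm == 0.0) { phi.zeros(); return 0; }
  mat r(arma::size(phi)), p(arma::size(phi)), Ap(arma::size(phi));
  apply_screened(phi, Ap, lesion, beta);
  r = rhs - Ap;
  // keep lesion rows exactly consistent (rhs is 0 there, phi forced 0)
  p = r;
  double rs = arma::dot(r, r);
  if (std::sqrt(rs) / bnorm <= tol) return 0;
  int it = 0;
  for (; it < maxit; ++it) {
    apply_screened(p, Ap, lesion, beta);
    const double alpha = rs / arma::dot(p, Ap);
    phi += alpha * p;
    r   -= alpha * Ap;
    const double rs_new = arma::dot(r, r);
    if (std::sqrt(rs_new) / bnorm <= tol) return it + 1;
    p = r + (rs_new / rs) * p;
    rs = rs_new;
  }
  stop("presynaptic-rate solver failed to converge: relative residual %g after %d iterations",
       std::sqrt(rs) / bnorm, maxit);
  return it;
}

// [[Rcpp::export(name = ".run_core")]]
List run_core(arma::mat K, arma::mat Na, arma::mat V, arma::mat xD,
              List par,
              const arma::mat& Gsyn, const arma::mat& Kbath,
              const arma::mat& VK0,
              const arma::imat& lesion, bool has_lesion, bool block_diffusion,
              int model,
              bool noise_inhomog, double noise_scale,
              double dt, int n_steps, double t0,
              const arma::ivec& probe_i, const arma::ivec& probe_j,
              int probe_every,
              int snap_every,
              List spectral_blocks, const arma::mat& Vy,
              bool use_spectral, double cg_tol, int cg_maxit,
              int cut_after,
              int strip_i, int strip_from, int strip_to) {
  const int nx = K.n_rows, ny = K.n_cols;

  const double tauK   = par["tau_K"],   tauNa  = par["tau_Na"];
  const double tauM   = par["tau_m"],   tauD   = par["tau_D"];
  const double DK     = par["D_K"];
  const double dK     = par["delta_K"], dNa    = par["delta_Na"];
  const double dx_dep = par["delta_x"];
  const double sigma  = par["sigma_over_gL"];
  const double rho    = par["rho"],     gam    = par["gamma"];
  const double cIE    = par["c_IE"],    gKl    = par["gK_leak_over_gL"];
  const double Nai0   = par["Na_i0"];
  const double numax  = par["nu_max"],  lam    = par["lambda_conn"];
  const double Vth    = par["V_th"],    kv     = par["k_v"];
  const double dx     = par["dx"];

  const double beta    = lam * lam / (dx * dx);   // CG operator coefficient
  const double dcoef   = DK / (dx * dx);          // diffusion, flux-form scaling
  const double sig_eff = sigma * noise_scale;
  const bool   diffuse = (model != 2) && DK > 0.0;
  const bool   elliptic = (model != 1);

  const int np = probe_i.n_elem;
  const int n_rec = (probe_every > 0) ? (n_steps / probe_every + 1) : 0;
  arma::cube probes(n_rec, 8, std::max(np, 1), arma::fill::zeros);
  arma::vec rec_t(std::max(n_rec, 1), arma::fill::zeros);

  const int n_snap = (snap_every > 0) ? (n_steps / snap_every + 1) : 0;
  arma::cube snapK(nx, ny, std::max(n_snap, 1)), snapV(nx, ny, std::max(n_snap, 1)),
             snapP(nx, ny, std::max(n_snap, 1)), snapE(nx, ny, std::max(n_snap, 1));
  arma::vec snap_t(std::max(n_snap, 1), arma::fill::zeros);
  // running per-cell mean of nu since the previous snapshot: an alias-free
  // sustained-activity envelope at snapshot cadence (bursts are far shorter
  // than the snapshot period, so an instantaneous sample would alias)
  mat nu_env(nx, ny, arma::fill::zeros);
  int env_count = 0;

  const bool strip_on = strip_i >= 0;
  const int n_strip = strip_on ? std::max(0, strip_to - strip_from + 1) : 0;
  mat stripV(std::max(n_strip, 1), ny, arma::fill::zeros);
  arma::vec strip_t(std::max(n_strip, 1), arma::fill::zeros);

  mat nu(nx, ny), phi(nx, ny, arma::fill::zeros), u(nx, ny), Ip(nx, ny),
      lap(nx, ny, arma::fill::zeros), VK(nx, ny), xi(nx, ny);
  mat T1;
  long cg_total = 0;

  // unpack the per-block spectral factorisations (a complete vertical cut
  // splits the sheet into independent rectangles, each separable)
  const int n_blocks = use_spectral ? spectral_blocks.size() : 0;
  std::vector<int> blk_i0(n_blocks);
  std::vector<mat> blk_Vx(n_blocks), blk_denom(n_blocks);
  for (int b = 0; b < n_blocks; ++b) {
    List blk = spectral_blocks[b];
    blk_i0[b] = as<int>(blk["i0"]);
    blk_Vx[b] = as<mat>(blk["Vx"]);
    blk_denom[b] = as<mat>(blk["denom"]);
  }

  RNGScope scope;

  int i_rec = 0, i_snap = 0, i_strip = 0;
  double t = t0;

  for (int step = 0; step <= n_steps; ++step) {
    // --- closures of the current state ---
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const double v = V(i, j);
        nu(i, j) = (v <= Vth) ? 0.0
                 : numax * (2.0 / (1.0 + std::exp(-2.0 * (v - Vth) / kv)) - 1.0);
      }

    if (!elliptic) {
      phi = nu;
      if (has_lesion) phi.elem(arma::find(lesion != 0)).zeros();
    } else if (use_spectral) {
      if (has_lesion) phi.zeros();
      for (int b = 0; b < n_blocks; ++b) {
        const int i0 = blk_i0[b], nb = blk_Vx[b].n_rows;
        T1 = blk_Vx[b].t() * nu.rows(i0, i0 + nb - 1) * Vy;
        T1 /= blk_denom[b];
        phi.rows(i0, i0 + nb - 1) = blk_Vx[b] * T1 * Vy.t();
      }
    } else {
      mat rhs = nu;
      rhs.elem(arma::find(lesion != 0)).zeros();
      cg_total += solve_cg(phi, rhs, lesion, beta, cg_tol, cg_maxit);
    }

    const mat& theta = (model == 1) ? nu : phi;
    if (snap_every > 0) { nu_env += nu; ++env_count; }

    VK = 26.6 * arma::log(K / 130.0);
    Ip = rho / ((1.0 + arma::exp(3.5 - K)) % (1.0 + arma::exp((25.0 - Na) / 3.0)));

    if (noise_inhomog) {
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) xi(i, j) = norm_rand();
    } else {
      xi.fill(norm_rand());
    }
    u = gKl * (VK - VK0) + Gsyn % phi % (xD - cIE) + sig_eff * xi;

    // --- recording (state at time t, with its derived quantities) ---
    if (probe_every > 0 && step % probe_every == 0) {
      for (int p = 0; p < np; ++p) {
        const int pi = probe_i(p), pj = probe_j(p);
        probes(i_rec, 0, p) = K(pi, pj);
        probes(i_rec, 1, p) = Na(pi, pj);
        probes(i_rec, 2, p) = V(pi, pj);
        probes(i_rec, 3, p) = xD(pi, pj);
        probes(i_rec, 4, p) = phi(pi, pj);
        probes(i_rec, 5, p) = nu(pi, pj);
        probes(i_rec, 6, p) = u(pi, pj);
        probes(i_rec, 7, p) = Ip(pi, pj);
      }
      rec_t(i_rec) = t;
      ++i_rec;
    }
    if (snap_every > 0 && step % snap_every == 0) {
      snapK.slice(i_snap) = K;
      snapV.slice(i_snap) = V;
      snapP.slice(i_snap) = phi;
      snapE.slice(i_snap) = nu_env / std::max(env_count, 1);
      snap_t(i_snap) = t;
      ++i_snap;
      nu_env.zeros();
      env_count = 0;
    }
    if (strip_on && step >= strip_from && step <= strip_to && i_strip < n_strip) {
      stripV.row(i_strip) = V.row(strip_i);
      strip_t(i_strip) = t;
      ++i_strip;
    }

    if (step == n_steps) break;

    // --- explicit Euler-Maruyama update ---
    if (diffuse) {
      lap_flux(K, lap, lesion, has_lesion, block_diffusion, cut_after);
      K += dt * (dcoef * lap + (Kbath - K) / tauK - 2.0 * gam * Ip + dK * theta);
    } else {
      K += dt * ((Kbath - K) / tauK - 2.0 * gam * Ip + dK * theta);
    }
    Na += dt * ((Nai0 - Na) / tauNa - 3.0 * Ip + dNa * theta);
    V  += (dt / tauM) * (u - V);
    xD += dt * ((1.0 - xD) / tauD - dx_dep * xD % theta);
    xD.clamp(0.0, 1.0);
    t = t0 + (step + 1) * dt;

    if (step % 2000 == 0) {
      if (!K.is_finite() || !V.is_finite() || !Na.is_finite())
        stop("non-finite field value at t = %g s (step %d); reduce dt or check parameters",
             t, step);
      Rcpp::checkUserInterrupt();
    }
  }

  return List::create(
    _["probes"] = probes, _["probe_t"] = rec_t.head(std::max(i_rec, 1)),
    _["n_rec"] = i_rec,
    _["snap_K"] = snapK, _["snap_V"] = snapV, _["snap_phi"] = snapP,
    _["snap_nu_env"] = snapE, _["snap_t"] = snap_t.head(std::max(i_snap, 1)),
    _["n_snap"] = i_snap,
    _["strip_V"] = stripV, _["strip_t"] = strip_t.head(std::max(i_strip, 1)),
    _["n_strip"] = i_strip,
    _["final"] = List::create(_["K_o"] = K, _["Na_i"] = Na, _["V"] = V,
                              _["x_D"] = xD, _["phi"] = phi, _["t"] = t),
    _["cg_iterations"] = (double) cg_total);
}
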