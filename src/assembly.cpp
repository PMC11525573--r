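// Element-level assembly kernels for the coupled growth/transport problem.
// Bilinear quadrilaterals, 2x2 Gauss quadrature, plane strain.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double GP = 0.5773502691896258; // 1/sqrt(3)
// local node order matches the mesh: (-1,-1), (1,-1), (1,1), (-1,1)
static const double XI[4]  = {-GP,  GP, GP, -GP};
static const double ETA[4] = {-GP, -GP, GP,  GP};

static inline void shape(double xi, double eta, double N[4], double dN[4][2]) {
  N[0] = 0.25 * (1 - xi) * (1 - eta);
  N[1] = 0.25 * (1 + xi) * (1 - eta);
  N[2] = 0.25 * (1 + xi) * (1 + eta);
  N[3] = 0.25 * (1 - xi) * (1 + eta);
  dN[0][0] = -0.25 * (1 - eta); dN[0][1] = -0.25 * (1 - xi);
  dN[1][0] =  0.25 * (1 - eta); dN[1][1] = -0.25 * (1 + xi);
  dN[2][0] =  0.25 * (1 + eta); dN[2][1] =  0.25 * (1 + xi);
  dN[3][0] = -0.25 * (1 + eta); dN[3][1] =  0.25 * (1 - xi);
}

// reference-geometry gradient of shape functions; returns det of the
// isoparametric Jacobian
static inline double grad_ref(const double Xe[4][2], const double dN[4][2],
                              double dNdX[4][2]) {
  double J0[2][2] = {{0, 0}, {0, 0}};
  for (int a = 0; a < 4; ++a)
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j) J0[i][j] += Xe[a][i] * dN[a][j];
  double det = J0[0][0] * J0[1][1] - J0[0][1] * J0[1][0];
  double inv[2][2] = {{ J0[1][1] / det, -J0[0][1] / det},
                      {-J0[1][0] / det,  J0[0][0] / det}};
  for (int a = 0; a < 4; ++a)
    for (int i = 0; i < 2; ++i)
      dNdX[a][i] = dN[a][0] * inv[0][i] + dN[a][1] * inv[1][i];
  return det;
}

// [[Rcpp::export(name = "cf_qp_coords")]]
List cf_qp_coords(NumericMatrix nodes, IntegerMatrix elems) {
  int ne = elems.nrow();
  NumericMatrix qx(ne, 4), qy(ne, 4);
  double N[4], dN[4][2];
  for (int e = 0; e < ne; ++e) {
    for (int q = 0; q < 4; ++q) {
      shape(XI[q], ETA[q], N, dN);
      double x = 0, y = 0;
      for (int a = 0; a < 4; ++a) {
        int n = elems(e, a) - 1;
        x += N[a] * nodes(n, 0);
        y += N[a] * nodes(n, 1);
      }
      qx(e, q) = x; qy(e, q) = y;
    }
  }
  return List::create(_["x"] = qx, _["y"] = qy);
}

// [[Rcpp::export(name = "cf_field_at_qp")]]
NumericMatrix cf_field_at_qp(IntegerMatrix elems, NumericVector field) {
  int ne = elems.nrow();
  NumericMatrix out(ne, 4);
  double N[4], dN[4][2];
  for (int q = 0; q < 4; ++q) {
    shape(XI[q], ETA[q], N, dN);
    for (int e = 0; e < ne; ++e) {
      double v = 0;
      for (int a = 0; a < 4; ++a) v += N[a] * field[elems(e, a) - 1];
      out(e, q) = v;
    }
  }
  return out;
}

// Deformation gradient, Jacobians and reference quadrature weights.
// [[Rcpp::export(name = "cf_kinematics")]]
List cf_kinematics(NumericMatrix nodes, IntegerMatrix elems,
                   NumericMatrix u) {
  int ne = elems.nrow();
  NumericMatrix J(ne, 4), F11(ne, 4), F12(ne, 4), F21(ne, 4), F22(ne, 4),
      wdet(ne, 4);
  double N[4], dN[4][2], dNdX[4][2];
  for (int e = 0; e < ne; ++e) {
    double Xe[4][2], Ue[4][2];
    for (int a = 0; a < 4; ++a) {
      int n = elems(e, a) - 1;
      Xe[a][0] = nodes(n, 0); Xe[a][1] = nodes(n, 1);
      Ue[a][0] = u(n, 0); Ue[a][1] = u(n, 1);
    }
    for (int q = 0; q < 4; ++q) {
      shape(XI[q], ETA[q], N, dN);
      double det0 = grad_ref(Xe, dN, dNdX);
      double F[2][2] = {{1, 0}, {0, 1}};
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 2; ++i)
          for (int Jj = 0; Jj < 2; ++Jj) F[i][Jj] += Ue[a][i] * dNdX[a][Jj];
      F11(e, q) = F[0][0]; F12(e, q) = F[0][1];
      F21(e, q) = F[1][0]; F22(e, q) = F[1][1];
      J(e, q) = F[0][0] * F[1][1] - F[0][1] * F[1][0];
      wdet(e, q) = det0; // unit Gauss weights
    }
  }
  return List::create(_["J"] = J, _["F11"] = F11, _["F12"] = F12,
                      _["F21"] = F21, _["F22"] = F22, _["wdet"] = wdet);
}

// Mechanics residual and consistent tangent (total Lagrangian).
// th_perp/th_par: growth multipliers per quadrature point; nx/ny: referential
// unit normal; mu/lam: Lame parameters per quadrature point.
// [[Rcpp::export(name = "cf_mech_assemble")]]
List cf_mech_assemble(NumericMatrix nodes, IntegerMatrix elems,
                      NumericMatrix u, NumericMatrix th_perp,
                      NumericMatrix th_par, NumericMatrix nx,
                      NumericMatrix ny, NumericMatrix mu_qp,
                      NumericMatrix lam_qp) {
  int ne = elems.nrow();
  int nn = nodes.nrow();
  IntegerVector ti(ne * 64), tj(ne * 64);
  NumericVector tx(ne * 64);
  NumericVector resid(2 * nn);
  NumericMatrix Jout(ne, 4);
  double min_Je = R_PosInf;
  int bad_elem = 0; // 0 = all elements admissible
  double N[4], dN[4][2], dNdX[4][2];
  R_xlen_t pos = 0;
  for (int e = 0; e < ne; ++e) {
    double Xe[4][2], Ue[4][2];
    int gid[8];
    for (int a = 0; a < 4; ++a) {
      int n = elems(e, a) - 1;
      Xe[a][0] = nodes(n, 0); Xe[a][1] = nodes(n, 1);
      Ue[a][0] = u(n, 0); Ue[a][1] = u(n, 1);
      gid[2 * a] = 2 * n; gid[2 * a + 1] = 2 * n + 1;
    }
    double Ke[8][8] = {{0}};
    double Re[8] = {0};
    for (int q = 0; q < 4; ++q) {
      shape(XI[q], ETA[q], N, dN);
      double det0 = grad_ref(Xe, dN, dNdX);
      double F[2][2] = {{1, 0}, {0, 1}};
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 2; ++i)
          for (int Jj = 0; Jj < 2; ++Jj) F[i][Jj] += Ue[a][i] * dNdX[a][Jj];
      Jout(e, q) = F[0][0] * F[1][1] - F[0][1] * F[1][0];
      // growth tensor and its (symmetric) inverse
      double tp = th_perp(e, q), tr = th_par(e, q);
      double n1 = nx(e, q), n2 = ny(e, q);
      double Fg[2][2] = {{tp + (tr - tp) * n1 * n1, (tr - tp) * n1 * n2},
                         {(tr - tp) * n1 * n2, tp + (tr - tp) * n2 * n2}};
      double Jg = tp * tr;
      double dFg = Fg[0][0] * Fg[1][1] - Fg[0][1] * Fg[1][0];
      double Gi[2][2] = {{ Fg[1][1] / dFg, -Fg[0][1] / dFg},
                         {-Fg[1][0] / dFg,  Fg[0][0] / dFg}};
      // Fe = F Gi
      double Fe[2][2];
      for (int i = 0; i < 2; ++i)
        for (int Jj = 0; Jj < 2; ++Jj)
          Fe[i][Jj] = F[i][0] * Gi[0][Jj] + F[i][1] * Gi[1][Jj];
      double Je = Fe[0][0] * Fe[1][1] - Fe[0][1] * Fe[1][0];
      if (Je < min_Je) { min_Je = Je; if (Je <= 0) bad_elem = e + 1; }
      if (Je <= 0) continue; // caller aborts on flag; skip NaN poisoning
      double Fei[2][2] = {{ Fe[1][1] / Je, -Fe[0][1] / Je},
                          {-Fe[1][0] / Je,  Fe[0][0] / Je}};
      double mu = mu_qp(e, q), lam = lam_qp(e, q);
      double lnJe = std::log(Je);
      double cpe = lam * lnJe - mu;
      // Pe = mu Fe + cpe Fe^{-T}
      double Pe[2][2];
      for (int i = 0; i < 2; ++i)
        for (int M = 0; M < 2; ++M) Pe[i][M] = mu * Fe[i][M] + cpe * Fei[M][i];
      // P = Jg Pe Gi
      double P[2][2];
      for (int i = 0; i < 2; ++i)
        for (int Jj = 0; Jj < 2; ++Jj)
          P[i][Jj] = Jg * (Pe[i][0] * Gi[0][Jj] + Pe[i][1] * Gi[1][Jj]);
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 2; ++i)
          Re[2 * a + i] += (P[i][0] * dNdX[a][0] + P[i][1] * dNdX[a][1]) *
                           det0;
      // material tangent Ae_{iMkN}, then A_{iJkL} = Jg Gi[J][M] Ae Gi[L][N]
      double A[2][2][2][2];
      for (int i = 0; i < 2; ++i)
        for (int M = 0; M < 2; ++M)
          for (int k = 0; k < 2; ++k)
            for (int Nn = 0; Nn < 2; ++Nn) {
              double ae = lam * Fei[M][i] * Fei[Nn][k] -
                          cpe * Fei[M][k] * Fei[Nn][i];
              if (i == k && M == Nn) ae += mu;
              A[i][M][k][Nn] = ae;
            }
      double Ag[2][2][2][2];
      for (int i = 0; i < 2; ++i)
        for (int Jj = 0; Jj < 2; ++Jj)
          for (int k = 0; k < 2; ++k)
            for (int L = 0; L < 2; ++L) {
              double s = 0;
              for (int M = 0; M < 2; ++M)
                for (int Nn = 0; Nn < 2; ++Nn)
                  s += Gi[Jj][M] * A[i][M][k][Nn] * Gi[L][Nn];
              Ag[i][Jj][k][L] = Jg * s;
            }
      for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b)
          for (int i = 0; i < 2; ++i)
            for (int k = 0; k < 2; ++k) {
              double s = 0;
              for (int Jj = 0; Jj < 2; ++Jj)
                for (int L = 0; L < 2; ++L)
                  s += dNdX[a][Jj] * Ag[i][Jj][k][L] * dNdX[b][L];
              Ke[2 * a + i][2 * b + k] += s * det0;
            }
    }
    for (int p = 0; p < 8; ++p) {
      resid[gid[p]] += Re[p];
      for (int r = 0; r < 8; ++r) {
        ti[pos] = gid[p] + 1;
        tj[pos] = gid[r] + 1;
        tx[pos] = Ke[p][r];
        ++pos;
      }
    }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx,
                      _["resid"] = resid, _["J"] = Jout,
                      _["min_Je"] = min_Je, _["bad_elem"] = bad_elem);
}

// Transport system for one species: A c_new = b with
//   A = (J_n/dt) M - J_n C(vhat) + J_n D(dtot),  b = M(J_prev c_prev)/dt
//       + J_n f
// all pulled back to the reference mesh (spatial gradients via F^{-T}).
// Streamline-upwind Petrov-Galerkin stabilization: each Galerkin test
// function N_a is augmented by tau vhat . grad(N_a) acting on the strong
// residual (time term, advection, explicit source; diffusion dropped for
// bilinear elements).  Since sum_a grad(N_a) = 0 the augmented test
// functions still sum to one and global mass conservation is exact.
// [[Rcpp::export(name = "cf_density_assemble")]]
List cf_density_assemble(NumericMatrix nodes, IntegerMatrix elems,
                         NumericMatrix u, NumericMatrix Jprev,
                         NumericVector cprev, NumericMatrix vqx,
                         NumericMatrix vqy, NumericMatrix dtot,
                         NumericMatrix fq, NumericMatrix tau,
                         double dt, bool lump) {
  int ne = elems.nrow();
  int nn = nodes.nrow();
  IntegerVector ti(ne * 16), tj(ne * 16);
  NumericVector tx(ne * 16);
  NumericVector rhs(nn);
  double N[4], dN[4][2], dNdX[4][2];
  R_xlen_t pos = 0;
  for (int e = 0; e < ne; ++e) {
    double Xe[4][2], Ue[4][2];
    int gid[4];
    for (int a = 0; a < 4; ++a) {
      int n = elems(e, a) - 1;
      Xe[a][0] = nodes(n, 0); Xe[a][1] = nodes(n, 1);
      Ue[a][0] = u(n, 0); Ue[a][1] = u(n, 1);
      gid[a] = n;
    }
    double Ae[4][4] = {{0}};
    double be[4] = {0};
    for (int q = 0; q < 4; ++q) {
      shape(XI[q], ETA[q], N, dN);
      double det0 = grad_ref(Xe, dN, dNdX);
      double F[2][2] = {{1, 0}, {0, 1}};
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 2; ++i)
          for (int Jj = 0; Jj < 2; ++Jj) F[i][Jj] += Ue[a][i] * dNdX[a][Jj];
      double Jn = F[0][0] * F[1][1] - F[0][1] * F[1][0];
      double Fi[2][2] = {{ F[1][1] / Jn, -F[0][1] / Jn},
                         {-F[1][0] / Jn,  F[0][0] / Jn}};
      double gx[4][2]; // spatial gradients of shape functions
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 2; ++i)
          gx[a][i] = dNdX[a][0] * Fi[0][i] + dNdX[a][1] * Fi[1][i];
      double cq = 0;
      for (int a = 0; a < 4; ++a) cq += N[a] * cprev[gid[a]];
      double vx = vqx(e, q), vy = vqy(e, q), dd = dtot(e, q);
      double tq = tau(e, q);
      double rhs_strong = Jprev(e, q) / Jn * cq / dt + fq(e, q);
      for (int a = 0; a < 4; ++a) {
        double adv_a = vx * gx[a][0] + vy * gx[a][1];
        double w_supg = tq * adv_a;
        for (int b = 0; b < 4; ++b) {
          double adv_b = vx * gx[b][0] + vy * gx[b][1];
          double mass = Jn / dt * N[a] * N[b];
          double val = -Jn * adv_a * N[b] +
                       Jn * dd * (gx[a][0] * gx[b][0] + gx[a][1] * gx[b][1]);
          // SUPG: tau (v.grad Na) (c/dt + v.grad c) on the current config
          val += Jn * w_supg * (N[b] / dt + adv_b);
          if (lump) Ae[a][a] += mass * det0; else val += mass;
          Ae[a][b] += val * det0;
        }
        be[a] += ((Jprev(e, q) * cq / dt + Jn * fq(e, q)) * N[a] +
                  Jn * w_supg * rhs_strong) * det0;
      }
    }
    for (int a = 0; a < 4; ++a) {
      rhs[gid[a]] += be[a];
      for (int b = 0; b < 4; ++b) {
        ti[pos] = gid[a] + 1;
        tj[pos] = gid[b] + 1;
        tx[pos] = Ae[a][b];
        ++pos;
      }
    }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx, _["rhs"] = rhs);
}
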