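// Finite-strain kernels for the thin-slice vessel model.
//
// Kinematics: generalized plane strain. The in-plane deformation
// gradient F2d is augmented with a fixed axial stretch lambda_z, so
// F = diag(F2d, lambda_z) and all tensors keep a 2x2-plus-zz block
// structure. Units: mm, kPa.
//
// Material: modified Mooney-Rivlin on deviatoric invariants
//   W = c1(I1b-3) + c2(I2b-3) + D1[exp(D2(I1b-3))-1]
//     + (K1/K2)[exp(K2(I4-1)^2)-1]            (anisotropic only)
//     + kappa (J-1)^2
// with I1b = J^(-2/3) I1, I2b = J^(-4/3) I2, I4 = n.C.n for the
// circumferential fibre direction n (in-plane, reference config).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Mat2 { double a11, a21, a12, a22; };

static inline double det2(const Mat2 &m) { return m.a11 * m.a22 - m.a12 * m.a21; }

struct MatState {
  double S11, S22, S12, Szz;   // 2nd Piola-Kirchhoff
  double W;                    // energy density
  double I1, I2, I4, J;
  Mat2 C;                      // in-plane right Cauchy-Green
};

// par: c1, c2, D1, D2, K1, K2, kappa, aniso
// pbar: volumetric stress factor 2*kappa*(Jvol - 1). Pointwise
// evaluation passes Jvol = J; elements pass the element-averaged J
// (mean dilatation), which removes spurious volumetric wiggle modes of
// the displacement-penalty formulation.
static bool evalMaterial(const Mat2 &F, double lz, const double *par,
                         double nx, double ny, double Jvol, MatState &out) {
  const double c1 = par[0], c2 = par[1], D1 = par[2], D2 = par[3];
  const double K1 = par[4], K2 = par[5], kappa = par[6];
  const bool aniso = par[7] != 0.0;

  const double dF = det2(F);
  if (dF <= 0.0 || lz <= 0.0) return false;

  Mat2 C;
  C.a11 = F.a11 * F.a11 + F.a21 * F.a21;
  C.a22 = F.a12 * F.a12 + F.a22 * F.a22;
  C.a12 = F.a11 * F.a12 + F.a21 * F.a22;
  C.a21 = C.a12;
  const double Czz = lz * lz;

  const double I1 = C.a11 + C.a22 + Czz;
  const double trC2 = C.a11 * C.a11 + 2.0 * C.a12 * C.a12 + C.a22 * C.a22
                      + Czz * Czz;
  const double I2 = 0.5 * (I1 * I1 - trC2);
  const double J = dF * lz;
  if (Jvol <= 0.0) Jvol = J;  // pointwise evaluation
  const double J23 = std::pow(J, -2.0 / 3.0);
  const double J43 = J23 * J23;
  const double I1b = J23 * I1, I2b = J43 * I2;

  const double eD = (D1 != 0.0) ? std::exp(D2 * (I1b - 3.0)) : 1.0;
  const double W1 = c1 + D1 * D2 * eD;   // dW/dI1b
  const double W2 = c2;                  // dW/dI2b

  // inverse of in-plane C
  const double dC = det2(C);
  Mat2 Ci;
  Ci.a11 = C.a22 / dC; Ci.a22 = C.a11 / dC;
  Ci.a12 = -C.a12 / dC; Ci.a21 = Ci.a12;
  const double Cizz = 1.0 / Czz;

  double I4 = 1.0, W4 = 0.0, Wan = 0.0;
  if (aniso) {
    I4 = nx * (C.a11 * nx + C.a12 * ny) + ny * (C.a21 * nx + C.a22 * ny);
    const double q = I4 - 1.0;
    const double eK = std::exp(K2 * q * q);
    W4 = 2.0 * K1 * q * eK;              // dW/dI4
    Wan = (K1 / K2) * (eK - 1.0);
  }

  // S = 2 dW/dC, assembled term by term (deviatoric projections of the
  // isochoric parts, plus fibre and volumetric contributions)
  const double a1 = 2.0 * W1 * J23;                 // coefficient of I
  const double b1 = -2.0 * W1 * J23 * I1 / 3.0;    // coefficient of Cinv
  const double a2 = 2.0 * W2 * J43 * I1;           // I
  const double c2c = -2.0 * W2 * J43;              // C
  const double b2 = -2.0 * W2 * J43 * 2.0 * I2 / 3.0;  // Cinv
  const double bv = 2.0 * kappa * (Jvol - 1.0) * J;   // Cinv

  out.S11 = (a1 + a2) + c2c * C.a11 + (b1 + b2 + bv) * Ci.a11 + 2.0 * W4 * nx * nx;
  out.S22 = (a1 + a2) + c2c * C.a22 + (b1 + b2 + bv) * Ci.a22 + 2.0 * W4 * ny * ny;
  out.S12 = c2c * C.a12 + (b1 + b2 + bv) * Ci.a12 + 2.0 * W4 * nx * ny;
  out.Szz = (a1 + a2) + c2c * Czz + (b1 + b2 + bv) * Cizz;

  out.W = c1 * (I1b - 3.0) + c2 * (I2b - 3.0) + D1 * (eD - 1.0)
        + Wan + kappa * (Jvol - 1.0) * (Jvol - 1.0);
  out.I1 = I1; out.I2 = I2; out.I4 = I4; out.J = J; out.C = C;
  return true;
}

// [[Rcpp::export]]
double mrEnergyCpp(NumericVector F2d, double lambdaZ, NumericVector par,
                   NumericVector fiber) {
  Mat2 F{F2d[0], F2d[1], F2d[2], F2d[3]};  // column-major
  MatState st;
  if (!evalMaterial(F, lambdaZ, par.begin(), fiber[0], fiber[1], 0.0, st))
    stop("inverted deformation state (J <= 0)");
  return st.W;
}

// [[Rcpp::export]]
NumericMatrix mrCauchyCpp(NumericVector F2d, double lambdaZ, NumericVector par,
                          NumericVector fiber) {
  Mat2 F{F2d[0], F2d[1], F2d[2], F2d[3]};
  MatState st;
  if (!evalMaterial(F, lambdaZ, par.begin(), fiber[0], fiber[1], 0.0, st))
    stop("inverted deformation state (J <= 0)");
  // sigma = (1/J) F S F^T, block structure
  const double J = st.J;
  // P = F * S (in-plane)
  const double P11 = F.a11 * st.S11 + F.a12 * st.S12;
  const double P12 = F.a11 * st.S12 + F.a12 * st.S22;
  const double P21 = F.a21 * st.S11 + F.a22 * st.S12;
  const double P22 = F.a21 * st.S12 + F.a22 * st.S22;
  NumericMatrix sig(3, 3);
  sig(0, 0) = (P11 * F.a11 + P12 * F.a12) / J;
  sig(0, 1) = (P11 * F.a21 + P12 * F.a22) / J;
  sig(1, 0) = sig(0, 1);
  sig(1, 1) = (P21 * F.a21 + P22 * F.a22) / J;
  sig(2, 2) = lambdaZ * lambdaZ * st.Szz / J;
  return sig;
}

// ---- 6-node triangle machinery ----

static const double QP[3][2] = {{1.0 / 6.0, 1.0 / 6.0},
                                {2.0 / 3.0, 1.0 / 6.0},
                                {1.0 / 6.0, 2.0 / 3.0}};
static const double QW = 1.0 / 6.0;  // each, on the unit triangle

static void shapeDeriv(double xi, double eta, double dN[6][2], double N[6]) {
  const double L1 = 1.0 - xi - eta, L2 = xi, L3 = eta;
  N[0] = L1 * (2.0 * L1 - 1.0);
  N[1] = L2 * (2.0 * L2 - 1.0);
  N[2] = L3 * (2.0 * L3 - 1.0);
  N[3] = 4.0 * L1 * L2;
  N[4] = 4.0 * L2 * L3;
  N[5] = 4.0 * L3 * L1;
  dN[0][0] = -(4.0 * L1 - 1.0); dN[0][1] = -(4.0 * L1 - 1.0);
  dN[1][0] = 4.0 * L2 - 1.0;    dN[1][1] = 0.0;
  dN[2][0] = 0.0;               dN[2][1] = 4.0 * L3 - 1.0;
  dN[3][0] = 4.0 * (L1 - L2);   dN[3][1] = -4.0 * L2;
  dN[4][0] = 4.0 * L3;          dN[4][1] = 4.0 * L2;
  dN[5][0] = -4.0 * L3;         dN[5][1] = 4.0 * (L1 - L3);
}

// Residual of one element given its 12 local displacements. Returns
// false on an inverted state.
// Per-quadrature-point kinematics of one element; false on inversion.
static bool elementKinematics(const double X[6][2], const double ue[12],
                              double lz, double dNdX[3][6][2],
                              double detJ0[3], Mat2 F[3], double &Jbar) {
  double dN[6][2], N[6];
  double volRef = 0.0, volCur = 0.0;
  for (int q = 0; q < 3; ++q) {
    shapeDeriv(QP[q][0], QP[q][1], dN, N);
    double J11 = 0, J12 = 0, J21 = 0, J22 = 0;
    for (int a = 0; a < 6; ++a) {
      J11 += X[a][0] * dN[a][0]; J12 += X[a][0] * dN[a][1];
      J21 += X[a][1] * dN[a][0]; J22 += X[a][1] * dN[a][1];
    }
    const double detJ = J11 * J22 - J12 * J21;
    if (detJ <= 0.0) return false;
    for (int a = 0; a < 6; ++a) {
      dNdX[q][a][0] = ( J22 * dN[a][0] - J21 * dN[a][1]) / detJ;
      dNdX[q][a][1] = (-J12 * dN[a][0] + J11 * dN[a][1]) / detJ;
    }
    Mat2 Fq{1.0, 0.0, 0.0, 1.0};
    for (int a = 0; a < 6; ++a) {
      Fq.a11 += ue[2 * a] * dNdX[q][a][0];
      Fq.a12 += ue[2 * a] * dNdX[q][a][1];
      Fq.a21 += ue[2 * a + 1] * dNdX[q][a][0];
      Fq.a22 += ue[2 * a + 1] * dNdX[q][a][1];
    }
    const double dF = det2(Fq);
    if (dF <= 0.0) return false;
    F[q] = Fq;
    detJ0[q] = detJ;
    volRef += QW * detJ;
    volCur += QW * detJ * dF * lz;
  }
  Jbar = volCur / volRef;
  return true;
}

static bool elementResidual(const double X[6][2], const double ue[12],
                            double lz, const double *par,
                            double nx, double ny, double r[12]) {
  for (int k = 0; k < 12; ++k) r[k] = 0.0;
  double dNdX[3][6][2], detJ0[3], Jbar;
  Mat2 F[3];
  if (!elementKinematics(X, ue, lz, dNdX, detJ0, F, Jbar)) return false;
  for (int q = 0; q < 3; ++q) {
    MatState st;
    if (!evalMaterial(F[q], lz, par, nx, ny, Jbar, st)) return false;
    // first Piola-Kirchhoff (in-plane): P = F S
    const double P11 = F[q].a11 * st.S11 + F[q].a12 * st.S12;
    const double P12 = F[q].a11 * st.S12 + F[q].a12 * st.S22;
    const double P21 = F[q].a21 * st.S11 + F[q].a22 * st.S12;
    const double P22 = F[q].a21 * st.S12 + F[q].a22 * st.S22;
    const double w = QW * detJ0[q];
    for (int a = 0; a < 6; ++a) {
      r[2 * a]     += w * (P11 * dNdX[q][a][0] + P12 * dNdX[q][a][1]);
      r[2 * a + 1] += w * (P21 * dNdX[q][a][0] + P22 * dNdX[q][a][1]);
    }
  }
  return true;
}

// Assemble internal residual and tangent (forward-difference of the
// element residual; step 1e-6 mm on each local dof).
// [[Rcpp::export]]
List feAssembleCpp(NumericMatrix nodes, IntegerMatrix elems,
                   IntegerVector tissueIdx, NumericMatrix pars,
                   NumericMatrix fibers, NumericVector u, double lambdaZ,
                   bool wantTangent) {
  const int ne = elems.nrow();
  const int ndof = 2 * nodes.nrow();
  NumericVector R(ndof);
  std::vector<int> ti, tj;
  std::vector<double> tv;
  if (wantTangent) { ti.reserve(ne * 144); tj.reserve(ne * 144); tv.reserve(ne * 144); }
  const double h = 1e-6;

  double X[6][2], ue[12], r0[12], r1[12], par[8];
  for (int e = 0; e < ne; ++e) {
    int gdof[12];
    for (int a = 0; a < 6; ++a) {
      const int n = elems(e, a) - 1;
      X[a][0] = nodes(n, 0); X[a][1] = nodes(n, 1);
      gdof[2 * a] = 2 * n; gdof[2 * a + 1] = 2 * n + 1;
      ue[2 * a] = u[2 * n]; ue[2 * a + 1] = u[2 * n + 1];
    }
    const int t = tissueIdx[e];
    for (int k = 0; k < 8; ++k) par[k] = pars(t, k);
    const double nx = fibers(e, 0), ny = fibers(e, 1);
    if (!elementResidual(X, ue, lambdaZ, par, nx, ny, r0))
      stop("inverted element %d during assembly", e + 1);
    for (int k = 0; k < 12; ++k) R[gdof[k]] += r0[k];
    if (!wantTangent) continue;
    for (int k = 0; k < 12; ++k) {
      const double keep = ue[k];
      ue[k] = keep + h;
      if (!elementResidual(X, ue, lambdaZ, par, nx, ny, r1))
        stop("inverted element %d during tangent evaluation", e + 1);
      ue[k] = keep;
      for (int m = 0; m < 12; ++m) {
        const double kv = (r1[m] - r0[m]) / h;
        if (kv != 0.0) {
          ti.push_back(gdof[m] + 1);
          tj.push_back(gdof[k] + 1);
          tv.push_back(kv);
        }
      }
    }
  }
  return List::create(_["residual"] = R, _["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["v"] = wrap(tv));
}

// Follower pressure on quadratic lumen edges (a, b, mid), ordered CCW
// around the cavity so that (t_y, -t_x) points outward into the wall.
// [[Rcpp::export]]
List pressureLoadCpp(NumericMatrix nodes, IntegerMatrix edges,
                     NumericVector u, double p) {
  const int ndof = 2 * nodes.nrow();
  NumericVector f(ndof);
  std::vector<int> ti, tj;
  std::vector<double> tv;
  const double gx[3] = {-std::sqrt(3.0 / 5.0), 0.0, std::sqrt(3.0 / 5.0)};
  const double gw[3] = {5.0 / 9.0, 8.0 / 9.0, 5.0 / 9.0};

  for (int e = 0; e < edges.nrow(); ++e) {
    const int n[3] = {edges(e, 0) - 1, edges(e, 1) - 1, edges(e, 2) - 1};
    double x[3][2];
    for (int a = 0; a < 3; ++a) {
      x[a][0] = nodes(n[a], 0) + u[2 * n[a]];
      x[a][1] = nodes(n[a], 1) + u[2 * n[a] + 1];
    }
    for (int q = 0; q < 3; ++q) {
      const double xi = gx[q];
      const double N[3]  = {0.5 * xi * (xi - 1.0), 0.5 * xi * (xi + 1.0), 1.0 - xi * xi};
      const double dN[3] = {xi - 0.5, xi + 0.5, -2.0 * xi};
      double tx = 0.0, ty = 0.0;
      for (int a = 0; a < 3; ++a) { tx += dN[a] * x[a][0]; ty += dN[a] * x[a][1]; }
      for (int a = 0; a < 3; ++a) {
        f[2 * n[a]]     += gw[q] * p * N[a] * ty;
        f[2 * n[a] + 1] -= gw[q] * p * N[a] * tx;
        // d f / d x_b : linear in the edge dofs
        for (int b = 0; b < 3; ++b) {
          ti.push_back(2 * n[a] + 1);     tj.push_back(2 * n[b] + 2);
          tv.push_back(gw[q] * p * N[a] * dN[b]);       // df_x / dy_b
          ti.push_back(2 * n[a] + 2);     tj.push_back(2 * n[b] + 1);
          tv.push_back(-gw[q] * p * N[a] * dN[b]);      // df_y / dx_b
        }
      }
    }
  }
  return List::create(_["force"] = f, _["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["v"] = wrap(tv));
}

// Quadrature-averaged element fields in the converged state: in-plane
// maximum principal Cauchy stress and Green-Lagrange strain, plus
// reference element areas for the nodal recovery weights.
// [[Rcpp::export]]
List recoverFieldsCpp(NumericMatrix nodes, IntegerMatrix elems,
                      IntegerVector tissueIdx, NumericMatrix pars,
                      NumericMatrix fibers, NumericVector u, double lambdaZ) {
  const int ne = elems.nrow();
  NumericVector sMax(ne), eMax(ne), area(ne);
  double X[6][2], ue[12], par[8];
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < 6; ++a) {
      const int n = elems(e, a) - 1;
      X[a][0] = nodes(n, 0); X[a][1] = nodes(n, 1);
      ue[2 * a] = u[2 * n]; ue[2 * a + 1] = u[2 * n + 1];
    }
    const int t = tissueIdx[e];
    for (int k = 0; k < 8; ++k) par[k] = pars(t, k);
    double dNdX[3][6][2], detJ0[3], Jbar;
    Mat2 F[3];
    if (!elementKinematics(X, ue, lambdaZ, dNdX, detJ0, F, Jbar))
      stop("inverted element %d during field recovery", e + 1);
    double sAcc = 0.0, eAcc = 0.0, aAcc = 0.0;
    for (int q = 0; q < 3; ++q) {
      MatState st;
      if (!evalMaterial(F[q], lambdaZ, par, fibers(e, 0), fibers(e, 1),
                        Jbar, st))
        stop("inverted element %d during field recovery", e + 1);
      // Cauchy in-plane block
      const double P11 = F[q].a11 * st.S11 + F[q].a12 * st.S12;
      const double P12 = F[q].a11 * st.S12 + F[q].a12 * st.S22;
      const double P21 = F[q].a21 * st.S11 + F[q].a22 * st.S12;
      const double P22 = F[q].a21 * st.S12 + F[q].a22 * st.S22;
      const double s11 = (P11 * F[q].a11 + P12 * F[q].a12) / st.J;
      const double s22 = (P21 * F[q].a21 + P22 * F[q].a22) / st.J;
      const double s12 = (P11 * F[q].a21 + P12 * F[q].a22) / st.J;
      const double sm = 0.5 * (s11 + s22)
        + std::sqrt(0.25 * (s11 - s22) * (s11 - s22) + s12 * s12);
      const double e11 = 0.5 * (st.C.a11 - 1.0), e22 = 0.5 * (st.C.a22 - 1.0);
      const double e12 = 0.5 * st.C.a12;
      const double em = 0.5 * (e11 + e22)
        + std::sqrt(0.25 * (e11 - e22) * (e11 - e22) + e12 * e12);
      sAcc += sm; eAcc += em; aAcc += QW * detJ0[q];
    }
    sMax[e] = sAcc / 3.0; eMax[e] = eAcc / 3.0; area[e] = aAcc;
  }
  return List::create(_["stressMax"] = sMax, _["strainMax"] = eMax,
                      _["area"] = area);
}
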