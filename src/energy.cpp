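#include <Rcpp.h>
using namespace Rcpp;

// Full energy functional of the discrete filament bundle, with the analytic
// gradient with respect to the segment angles and the per-node gradient of
// the interaction energy (used for pressure maps).
//
// Conventions (0-based, matching the R wrappers' 1-based docs):
//   theta(i, k), i = 0..m-1 filaments, k = 0..n-1 segments.
//   Points P(i, j), j = 0..n;  P(i,0) = (0, i*d0) is fixed.
//   Segment k joins points k and k+1, so dP(i,j)/dtheta(i,k) != 0 iff k < j.
//
// Energy terms:
//   Eb   : discrete bending, sum over interior joints of (B_i/2l) tan^2(dth/2)
//   Ee1  : vertical springs between neighbour filaments at every point j=0..n
//   Ee1p : "+" diagonal springs, point (i,j) to (i+1,j+1), j = 0..n-1
//   Ee1m : "-" diagonal springs, point (i,j) to (i+1,j-1), j = 1..n
//   Ee2  : exponential overlap penalty on the two triangle areas of each quad
//   El1  : axial load, sum_i Nc_i * x_{i,n}
//   El2  : lateral (pinching) load, sum_{i,j>=1} Np(i,j) * (y_ij - y_i0)
//   Ec1  : pinned-end penalty C3 (y_in - y_i0)^2
//   Ec2  : clamped-end penalty C3 (theta_i1^2 + theta_in^2), clamped only

// [[Rcpp::export]]
List energy_core(NumericMatrix theta,
                 double l, double d0, double d0diag, double A0,
                 double K, NumericVector B,
                 double C1, double C2, double C3,
                 NumericVector Nc, NumericMatrix Np,
                 bool clamped,
                 bool want_grad, bool want_pressure) {
  const int m = theta.nrow(), n = theta.ncol();
  bool finite = true;

  NumericMatrix X(m, n + 1), Y(m, n + 1);
  for (int i = 0; i < m; ++i) {
    X(i, 0) = 0.0;
    Y(i, 0) = i * d0;
    for (int j = 1; j <= n; ++j) {
      X(i, j) = X(i, j - 1) + l * std::cos(theta(i, j - 1));
      Y(i, j) = Y(i, j - 1) + l * std::sin(theta(i, j - 1));
    }
  }

  const bool wantxy = want_grad || want_pressure;
  // coordinate-space gradients: interaction terms (ge*) kept separate from
  // load/constraint terms (gl*) so the pressure field uses only the former
  NumericMatrix gex, gey, glx, gly, gth;
  if (wantxy) {
    gex = NumericMatrix(m, n + 1);
    gey = NumericMatrix(m, n + 1);
  }
  if (want_grad) {
    glx = NumericMatrix(m, n + 1);
    gly = NumericMatrix(m, n + 1);
    gth = NumericMatrix(m, n);
  }

  // ---- bending -----------------------------------------------------------
  // per joint: (B_i / 2l) tan^2(dtheta); continuum limit (B_i/2) kappa^2,
  // singular (filament folds back on its circumscribed circle) at |dtheta|
  // = pi/2, reported as non-finite rather than clamped
  double Eb = 0.0;
  NumericVector Ebf(m);
  for (int i = 0; i < m; ++i) {
    const double c = B[i] / (2.0 * l);
    double acc = 0.0;
    for (int j = 1; j < n; ++j) {
      const double dth = theta(i, j) - theta(i, j - 1);
      if (std::abs(dth) >= M_PI_2 * (1.0 - 1e-12)) finite = false;
      const double t = std::tan(dth);
      acc += c * t * t;
      if (want_grad) {
        const double cs = std::cos(dth);
        const double dd = 2.0 * c * t / (cs * cs);
        gth(i, j) += dd;
        gth(i, j - 1) -= dd;
      }
    }
    Ebf[i] = acc;
    Eb += acc;
  }

  // ---- springs -----------------------------------------------------------
  double Ee1 = 0.0, Ee1p = 0.0, Ee1m = 0.0;
  const double ck = l * K / 2.0;
  for (int i = 0; i + 1 < m; ++i) {
    for (int j = 0; j <= n; ++j) {
      const double dx = X(i + 1, j) - X(i, j), dy = Y(i + 1, j) - Y(i, j);
      const double d = std::sqrt(dx * dx + dy * dy);
      const double s = (d - d0) / d0;
      Ee1 += ck * s * s;
      if (wantxy && d > 0.0) {
        const double f = l * K * s / (d0 * d);
        gex(i + 1, j) += f * dx;  gey(i + 1, j) += f * dy;
        gex(i, j) -= f * dx;      gey(i, j) -= f * dy;
      }
    }
    for (int j = 0; j < n; ++j) {  // "+" diagonal: (i,j) -> (i+1,j+1)
      const double dx = X(i + 1, j + 1) - X(i, j), dy = Y(i + 1, j + 1) - Y(i, j);
      const double d = std::sqrt(dx * dx + dy * dy);
      const double s = (d - d0diag) / d0diag;
      Ee1p += ck * s * s;
      if (wantxy && d > 0.0) {
        const double f = l * K * s / (d0diag * d);
        gex(i + 1, j + 1) += f * dx;  gey(i + 1, j + 1) += f * dy;
        gex(i, j) -= f * dx;          gey(i, j) -= f * dy;
      }
    }
    for (int j = 1; j <= n; ++j) {  // "-" diagonal: (i,j) -> (i+1,j-1)
      const double dx = X(i + 1, j - 1) - X(i, j), dy = Y(i + 1, j - 1) - Y(i, j);
      const double d = std::sqrt(dx * dx + dy * dy);
      const double s = (d - d0diag) / d0diag;
      Ee1m += ck * s * s;
      if (wantxy && d > 0.0) {
        const double f = l * K * s / (d0diag * d);
        gex(i + 1, j - 1) += f * dx;  gey(i + 1, j - 1) += f * dy;
        gex(i, j) -= f * dx;          gey(i, j) -= f * dy;
      }
    }
  }

  // ---- overlap penalty ---------------------------------------------------
  // quad (i, j): P0=(i,j), P1=(i+1,j), P2=(i+1,j+1), P3=(i,j+1)
  // triangle 1: vectors P1-P0 and P2-P0; triangle 2: vectors P2-P3 and P2-P0
  double Ee2 = 0.0;
  for (int i = 0; i + 1 < m; ++i) {
    for (int j = 0; j < n; ++j) {
      const double x0 = X(i, j),     y0 = Y(i, j);
      const double x1 = X(i + 1, j), y1 = Y(i + 1, j);
      const double x2 = X(i + 1, j + 1), y2 = Y(i + 1, j + 1);
      const double x3 = X(i, j + 1), y3 = Y(i, j + 1);
      const double cr1 = (x1 - x0) * (y2 - y0) - (y1 - y0) * (x2 - x0);
      const double cr2 = (x2 - x3) * (y2 - y0) - (y2 - y3) * (x2 - x0);
      const double A1 = 0.5 * std::abs(cr1);
      const double A2 = 0.5 * std::abs(cr2);
      const double g1 = C1 * std::exp(-C2 * A1 / A0);
      const double g2 = C1 * std::exp(-C2 * A2 / A0);
      Ee2 += g1 + g2;
      if (wantxy) {
        const double k1 = -0.5 * (C2 / A0) * g1 * (cr1 >= 0.0 ? 1.0 : -1.0);
        gex(i, j) += k1 * (y1 - y2);          gey(i, j) += k1 * (x2 - x1);
        gex(i + 1, j) += k1 * (y2 - y0);      gey(i + 1, j) += k1 * (x0 - x2);
        gex(i + 1, j + 1) += k1 * (y0 - y1);  gey(i + 1, j + 1) += k1 * (x1 - x0);
        const double k2 = -0.5 * (C2 / A0) * g2 * (cr2 >= 0.0 ? 1.0 : -1.0);
        gex(i + 1, j + 1) += k2 * (y3 - y0);  gey(i + 1, j + 1) += k2 * (x0 - x3);
        gex(i, j + 1) += k2 * (y0 - y2);      gey(i, j + 1) += k2 * (x2 - x0);
        gex(i, j) += k2 * (y2 - y3);          gey(i, j) += k2 * (x3 - x2);
      }
    }
  }

  // ---- loads and boundary penalties --------------------------------------
  double El1 = 0.0, El2 = 0.0, Ec1 = 0.0, Ec2 = 0.0;
  for (int i = 0; i < m; ++i) {
    El1 += Nc[i] * X(i, n);
    if (want_grad) glx(i, n) += Nc[i];
    for (int j = 1; j <= n; ++j) {
      const double np = Np(i, j - 1);
      if (np != 0.0) {
        El2 += np * (Y(i, j) - Y(i, 0));
        if (want_grad) { gly(i, j) += np; gly(i, 0) -= np; }
      }
    }
    const double s = Y(i, n) - Y(i, 0);
    Ec1 += C3 * s * s;
    if (want_grad) { gly(i, n) += 2.0 * C3 * s; gly(i, 0) -= 2.0 * C3 * s; }
    if (clamped) {
      Ec2 += C3 * (theta(i, 0) * theta(i, 0) + theta(i, n - 1) * theta(i, n - 1));
      if (want_grad) {
        gth(i, 0) += 2.0 * C3 * theta(i, 0);
        gth(i, n - 1) += 2.0 * C3 * theta(i, n - 1);
      }
    }
  }

  // ---- chain rule: coordinate gradients -> angle gradients ---------------
  // dP(i,j)/dtheta(i,k) = l * (-sin, cos)(theta_ik) for j > k, so each angle
  // collects the suffix sum of the point gradients of its own filament.
  if (want_grad) {
    for (int i = 0; i < m; ++i) {
      double sx = 0.0, sy = 0.0;
      for (int k = n - 1; k >= 0; --k) {
        const int j = k + 1;
        sx += gex(i, j) + glx(i, j);
        sy += gey(i, j) + gly(i, j);
        gth(i, k) += -l * std::sin(theta(i, k)) * sx + l * std::cos(theta(i, k)) * sy;
      }
    }
  }

  const double total = Eb + Ee1 + Ee1p + Ee1m + Ee2 + El1 + El2 + Ec1 + Ec2;
  if (!std::isfinite(total)) finite = false;

  List out = List::create(
      _["Eb"] = Eb, _["Eb_filament"] = Ebf,
      _["Ee1"] = Ee1, _["Ee1_plus"] = Ee1p, _["Ee1_minus"] = Ee1m,
      _["Ee2"] = Ee2, _["El1"] = El1, _["El2"] = El2,
      _["Ec1"] = Ec1, _["Ec2"] = Ec2,
      _["total"] = total, _["finite"] = finite);
  if (want_grad) out["grad"] = gth;
  if (want_pressure) {
    NumericMatrix press(m, n + 1);
    for (int i = 0; i < m; ++i)
      for (int j = 0; j <= n; ++j)
        press(i, j) = std::sqrt(gex(i, j) * gex(i, j) + gey(i, j) * gey(i, j));
    out["pressure"] = press;
  }
  return out;
}
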