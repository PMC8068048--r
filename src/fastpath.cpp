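// Fast evaluation of the protrusion motion model: constant-twist paths of the
// two condylar centres with even/odd mid-course wobble rotations, measured as
// the pipeline does (monotone-leg chord length; dwell-weighted total-least-
// squares sagittal and axial inclinations).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// rotate point p in place by angle ang about unit axis u (Rodrigues)
static void rotate_about(double* p, const double* u, double ang) {
  double c = std::cos(ang), s = std::sin(ang);
  double ux[3];
  cross3(u, p, ux);
  double ud = u[0] * p[0] + u[1] * p[1] + u[2] * p[2];
  for (int i = 0; i < 3; ++i)
    p[i] = p[i] * c + ux[i] * s + u[i] * ud * (1 - c);
}

// measured PCPL / SCI / TCI of one path (rows x 3, flattened row-major)
static void measure_path(const std::vector<double>& P, int n, double wfirst,
                         int sigma, double* out) {
  // monotone leg: truncate at maximal displacement from the first point
  int kmax = 0;
  double best = -1.0;
  for (int k = 0; k < n; ++k) {
    double dx = P[3 * k] - P[0], dy = P[3 * k + 1] - P[1], dz = P[3 * k + 2] - P[2];
    double d = dx * dx + dy * dy + dz * dz;
    if (d > best) { best = d; kmax = k; }
  }
  int m = kmax + 1;
  double len = 0.0;
  for (int k = 1; k < m; ++k) {
    double dx = P[3 * k] - P[3 * (k - 1)];
    double dy = P[3 * k + 1] - P[3 * (k - 1) + 1];
    double dz = P[3 * k + 2] - P[3 * (k - 1) + 2];
    len += std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  out[0] = len;
  // weighted TLS in (x, z) for SCI and (x, y) for TCI; first point carries
  // the dwell weight
  double sw = wfirst + (m - 1);
  double mx = 0, my = 0, mz = 0;
  for (int k = 0; k < m; ++k) {
    double w = (k == 0) ? wfirst : 1.0;
    mx += w * P[3 * k]; my += w * P[3 * k + 1]; mz += w * P[3 * k + 2];
  }
  mx /= sw; my /= sw; mz /= sw;
  double axx = 0, azz = 0, axz = 0, ayy = 0, axy = 0;
  for (int k = 0; k < m; ++k) {
    double w = (k == 0) ? wfirst : 1.0;
    double x = P[3 * k] - mx, y = P[3 * k + 1] - my, z = P[3 * k + 2] - mz;
    axx += w * x * x; azz += w * z * z; axz += w * x * z;
    ayy += w * y * y; axy += w * x * y;
  }
  double angs = 0.5 * std::atan2(2 * axz, axx - azz);
  double dh = std::cos(angs), dv = std::sin(angs);
  out[1] = std::atan2(std::fabs(dv), std::fabs(dh)) * 180.0 / M_PI;
  double anga = 0.5 * std::atan2(2 * axy, axx - ayy);
  double ax = std::cos(anga), ay = std::sin(anga);
  if (ax < 0) { ax = -ax; ay = -ay; }
  out[2] = std::atan2(-sigma * ay, ax) * 180.0 / M_PI;
}

// [[Rcpp::export]]
NumericVector cpp_protrusion_measure(NumericVector ccL, NumericVector ccR,
                                     NumericVector p, NumericVector s,
                                     double n_dwell) {
  int n = s.size();
  const double* w = &p[0];
  const double* v = &p[3];
  const double* m1 = &p[6];
  const double* m2 = &p[9];
  double th = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  double u[3] = {0, 0, 0};
  if (th > 1e-12) { u[0] = w[0] / th; u[1] = w[1] / th; u[2] = w[2] / th; }
  double n1 = std::sqrt(m1[0] * m1[0] + m1[1] * m1[1] + m1[2] * m1[2]);
  double u1[3] = {0, 0, 0};
  if (n1 > 1e-12) { u1[0] = m1[0] / n1; u1[1] = m1[1] / n1; u1[2] = m1[2] / n1; }
  double n2 = std::sqrt(m2[0] * m2[0] + m2[1] * m2[1] + m2[2] * m2[2]);
  double u2[3] = {0, 0, 0};
  if (n2 > 1e-12) { u2[0] = m2[0] / n2; u2[1] = m2[1] / n2; u2[2] = m2[2] / n2; }

  std::vector<double> PL(3 * n), PR(3 * n);
  double uv[3]; cross3(u, v, uv);
  double uvv[3]; cross3(u, uv, uvv);
  const double* cc[2] = {&ccL[0], &ccR[0]};
  std::vector<double>* out[2] = {&PL, &PR};
  for (int side = 0; side < 2; ++side) {
    double up[3], upp[3];
    cross3(u, cc[side], up);
    cross3(u, up, upp);
    for (int k = 0; k < n; ++k) {
      double sk = s[k];
      double q[3];
      if (th < 1e-12) {
        for (int i = 0; i < 3; ++i) q[i] = cc[side][i] + sk * v[i];
      } else {
        double sn = std::sin(th * sk), cs1 = 1 - std::cos(th * sk);
        for (int i = 0; i < 3; ++i)
          q[i] = cc[side][i] + sn * up[i] + cs1 * upp[i] + sk * v[i] +
                 cs1 / th * uv[i] + (th * sk - sn) / th * uvv[i];
      }
      double g1 = sk * (1 - sk), g2 = g1 * (1 - 2 * sk);
      if (n1 > 1e-12) rotate_about(q, u1, n1 * g1);
      if (n2 > 1e-12) rotate_about(q, u2, n2 * g2);
      (*out[side])[3 * k] = q[0];
      (*out[side])[3 * k + 1] = q[1];
      (*out[side])[3 * k + 2] = q[2];
    }
  }
  NumericVector res(6);
  double tmp[3];
  measure_path(PL, n, n_dwell + 1, +1, tmp);
  res[0] = tmp[0]; res[1] = tmp[1]; res[2] = tmp[2];
  measure_path(PR, n, n_dwell + 1, -1, tmp);
  res[3] = tmp[0]; res[4] = tmp[1]; res[5] = tmp[2];
  return res;
}

// ---- batch rigid registration (Horn's quaternion method) -------------------
// pts: n x (3*m) marker coordinates per frame (row-major per marker x,y,z);
// ref: m x 3 reference positions. Returns per-frame rotations (n x 9,
// row-major R11..R33) and translations (n x 3), mapping ref -> frame.

static void jacobi4(double A[4][4], double V[4][4]) {
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) V[i][j] = (i == j) ? 1.0 : 0.0;
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = 0;
    for (int i = 0; i < 4; ++i)
      for (int j = i + 1; j < 4; ++j) off += A[i][j] * A[i][j];
    if (off < 1e-24) break;
    for (int p = 0; p < 4; ++p) for (int q = p + 1; q < 4; ++q) {
      if (std::fabs(A[p][q]) < 1e-18) continue;
      double theta = (A[q][q] - A[p][p]) / (2 * A[p][q]);
      double t = (theta >= 0 ? 1.0 : -1.0) /
                 (std::fabs(theta) + std::sqrt(theta * theta + 1));
      double c = 1 / std::sqrt(t * t + 1), s = t * c;
      for (int k = 0; k < 4; ++k) {
        double akp = A[k][p], akq = A[k][q];
        A[k][p] = c * akp - s * akq;
        A[k][q] = s * akp + c * akq;
      }
      for (int k = 0; k < 4; ++k) {
        double apk = A[p][k], aqk = A[q][k];
        A[p][k] = c * apk - s * aqk;
        A[q][k] = s * apk + c * aqk;
        double vkp = V[k][p], vkq = V[k][q];
        V[k][p] = c * vkp - s * vkq;
        V[k][q] = s * vkp + c * vkq;
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_kabsch_poses(NumericMatrix pts, NumericMatrix ref) {
  int n = pts.nrow();
  int m = ref.nrow();
  NumericMatrix R9(n, 9), T(n, 3);
  // centred reference
  double cr[3] = {0, 0, 0};
  for (int i = 0; i < m; ++i)
    for (int d = 0; d < 3; ++d) cr[d] += ref(i, d) / m;
  std::vector<double> A(3 * m);
  for (int i = 0; i < m; ++i)
    for (int d = 0; d < 3; ++d) A[3 * i + d] = ref(i, d) - cr[d];
  for (int k = 0; k < n; ++k) {
    double cc[3] = {0, 0, 0};
    for (int i = 0; i < m; ++i)
      for (int d = 0; d < 3; ++d) cc[d] += pts(k, 3 * i + d) / m;
    double H[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (int i = 0; i < m; ++i) {
      double b[3];
      for (int d = 0; d < 3; ++d) b[d] = pts(k, 3 * i + d) - cc[d];
      for (int r = 0; r < 3; ++r)
        for (int c = 0; c < 3; ++c) H[r][c] += A[3 * i + r] * b[c];
    }
    // Horn: largest eigenvector of the 4x4 quaternion matrix N
    double tr = H[0][0] + H[1][1] + H[2][2];
    double N[4][4] = {
      {tr, H[1][2] - H[2][1], H[2][0] - H[0][2], H[0][1] - H[1][0]},
      {H[1][2] - H[2][1], 2 * H[0][0] - tr, H[0][1] + H[1][0], H[2][0] + H[0][2]},
      {H[2][0] - H[0][2], H[0][1] + H[1][0], 2 * H[1][1] - tr, H[1][2] + H[2][1]},
      {H[0][1] - H[1][0], H[2][0] + H[0][2], H[1][2] + H[2][1], 2 * H[2][2] - tr}};
    double V[4][4];
    jacobi4(N, V);
    int imax = 0;
    for (int i = 1; i < 4; ++i) if (N[i][i] > N[imax][imax]) imax = i;
    double q0 = V[0][imax], q1 = V[1][imax], q2 = V[2][imax], q3 = V[3][imax];
    double nq = std::sqrt(q0 * q0 + q1 * q1 + q2 * q2 + q3 * q3);
    q0 /= nq; q1 /= nq; q2 /= nq; q3 /= nq;
    double R[3][3] = {
      {1 - 2 * (q2 * q2 + q3 * q3), 2 * (q1 * q2 - q0 * q3), 2 * (q1 * q3 + q0 * q2)},
      {2 * (q1 * q2 + q0 * q3), 1 - 2 * (q1 * q1 + q3 * q3), 2 * (q2 * q3 - q0 * q1)},
      {2 * (q1 * q3 - q0 * q2), 2 * (q2 * q3 + q0 * q1), 1 - 2 * (q1 * q1 + q2 * q2)}};
    for (int r = 0; r < 3; ++r) {
      for (int c = 0; c < 3; ++c) R9(k, 3 * r + c) = R[r][c];
      T(k, r) = cc[r] - (R[r][0] * cr[0] + R[r][1] * cr[1] + R[r][2] * cr[2]);
    }
  }
  return List::create(Named("R9") = R9, Named("T") = T);
}
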