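// Hot numerical kernels: bonded and soft Lennard-Jones energies with
// analytic Cartesian gradients, geometric hydrogen-bond detection, and a
// batched Kabsch RMSD used by the tree search's neighbor queries.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::rowvec3 row3(const arma::mat& X, int i) { return X.row(i); }

// Harmonic bond + angle energy, optionally with gradient.
// bonds: m x 2 (1-based indices), angles: m x 3 (1-based, vertex in middle).
// [[Rcpp::export(name = ".cpp_bonded")]]
List cpp_bonded(const arma::mat& xyz,
                const arma::imat& bonds, const arma::vec& r0, const arma::vec& kb,
                const arma::imat& angles, const arma::vec& th0, const arma::vec& kth,
                bool want_grad) {
  double e_bond = 0.0, e_angle = 0.0;
  arma::mat grad;
  if (want_grad) grad.zeros(xyz.n_rows, 3);

  for (arma::uword m = 0; m < bonds.n_rows; ++m) {
    int i = bonds(m, 0) - 1, j = bonds(m, 1) - 1;
    arma::rowvec3 d = row3(xyz, i) - row3(xyz, j);
    double r = arma::norm(d);
    double dr = r - r0(m);
    e_bond += kb(m) * dr * dr;
    if (want_grad && r > 1e-12) {
      arma::rowvec3 g = (2.0 * kb(m) * dr / r) * d;
      grad.row(i) += g;
      grad.row(j) -= g;
    }
  }

  for (arma::uword m = 0; m < angles.n_rows; ++m) {
    int i = angles(m, 0) - 1, j = angles(m, 1) - 1, k = angles(m, 2) - 1;
    arma::rowvec3 u = row3(xyz, i) - row3(xyz, j);
    arma::rowvec3 v = row3(xyz, k) - row3(xyz, j);
    double nu = arma::norm(u), nv = arma::norm(v);
    if (nu < 1e-12 || nv < 1e-12) continue;
    double ct = arma::dot(u, v) / (nu * nv);
    ct = std::min(1.0, std::max(-1.0, ct));
    double th = std::acos(ct);
    double dth = th - th0(m);
    e_angle += kth(m) * dth * dth;
    if (want_grad) {
      double st = std::sqrt(std::max(1.0 - ct * ct, 1e-12));
      double pref = -2.0 * kth(m) * dth / st;  // dE/dcos(theta)... chain rule
      // d cos(th) / d xi
      arma::rowvec3 dci = (v / (nu * nv)) - (ct / (nu * nu)) * u;
      arma::rowvec3 dck = (u / (nu * nv)) - (ct / (nv * nv)) * v;
      grad.row(i) += pref * dci;
      grad.row(k) += pref * dck;
      grad.row(j) -= pref * (dci + dck);
    }
  }

  List out = List::create(_["e_bond"] = e_bond, _["e_angle"] = e_angle);
  if (want_grad) out["grad"] = grad;
  return out;
}

// Soft Lennard-Jones over a precomputed nonbonded pair list.  The repulsive
// wall is clamped: r is replaced by max(r, soft * rmin), so the energy is
// finite (and the gradient zero) inside the clamp radius.
// [[Rcpp::export(name = ".cpp_vdw")]]
List cpp_vdw(const arma::mat& xyz,
             const arma::imat& pairs, const arma::vec& rmin, const arma::vec& eps,
             double soft, double cutoff, bool want_grad) {
  double e = 0.0;
  arma::mat grad;
  if (want_grad) grad.zeros(xyz.n_rows, 3);
  double cut2 = cutoff * cutoff;
  for (arma::uword m = 0; m < pairs.n_rows; ++m) {
    int i = pairs(m, 0) - 1, j = pairs(m, 1) - 1;
    arma::rowvec3 d = row3(xyz, i) - row3(xyz, j);
    double r2 = arma::dot(d, d);
    if (r2 > cut2) continue;
    double r = std::sqrt(r2);
    double rc = std::max(r, soft * rmin(m));
    double q = rmin(m) / rc;
    double q6 = q * q * q; q6 *= q6;
    e += eps(m) * (q6 * q6 - 2.0 * q6);
    if (want_grad && r > soft * rmin(m) && r > 1e-12) {
      double dEdr = eps(m) * 12.0 * (q6 - q6 * q6) / rc;
      arma::rowvec3 g = (dEdr / r) * d;
      grad.row(i) += g;
      grad.row(j) -= g;
    }
  }
  List out = List::create(_["e_vdw"] = e);
  if (want_grad) out["grad"] = grad;
  return out;
}

// Full bounded steepest-descent loop on bond + angle + VdW, kept in C++ so a
// minimization costs one R/C++ crossing.  Step size starts at `step0` along
// the normalized negative gradient, halves on energy increase, and the
// descent stops once a step is rejected after `max_halvings` halvings.
// Raw-pointer evaluation of the minimization target (bond + angle + VdW).
// xyz/grad are n x 3 column-major; grad may be null.
static double target_energy(const double* X, int n,
                            const int* bi, const int* bj, int nb,
                            const double* r0, const double* kb,
                            const int* ai, const int* aj, const int* ak, int na,
                            const double* th0, const double* kth,
                            const int* pi_, const int* pj_, int np,
                            const double* rmin, const double* eps,
                            double soft, double cutoff,
                            double* G) {
  const double* x = X; const double* y = X + n; const double* z = X + 2 * n;
  double* gx = nullptr; double* gy = nullptr; double* gz = nullptr;
  if (G) {
    std::fill(G, G + 3 * n, 0.0);
    gx = G; gy = G + n; gz = G + 2 * n;
  }
  double e = 0.0;
  for (int m = 0; m < nb; ++m) {
    int i = bi[m] - 1, j = bj[m] - 1;
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - r0[m];
    e += kb[m] * dr * dr;
    if (G && r > 1e-12) {
      double c = 2.0 * kb[m] * dr / r;
      gx[i] += c * dx; gy[i] += c * dy; gz[i] += c * dz;
      gx[j] -= c * dx; gy[j] -= c * dy; gz[j] -= c * dz;
    }
  }
  for (int m = 0; m < na; ++m) {
    int i = ai[m] - 1, j = aj[m] - 1, k = ak[m] - 1;
    double ux = x[i] - x[j], uy = y[i] - y[j], uz = z[i] - z[j];
    double vx = x[k] - x[j], vy = y[k] - y[j], vz = z[k] - z[j];
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (nu < 1e-12 || nv < 1e-12) continue;
    double ct = (ux * vx + uy * vy + uz * vz) / (nu * nv);
    ct = std::min(1.0, std::max(-1.0, ct));
    double dth = std::acos(ct) - th0[m];
    e += kth[m] * dth * dth;
    if (G) {
      double st = std::sqrt(std::max(1.0 - ct * ct, 1e-12));
      double pref = -2.0 * kth[m] * dth / st;
      double invuv = 1.0 / (nu * nv), invu2 = ct / (nu * nu), invv2 = ct / (nv * nv);
      double dcix = vx * invuv - ux * invu2, dciy = vy * invuv - uy * invu2,
             dciz = vz * invuv - uz * invu2;
      double dckx = ux * invuv - vx * invv2, dcky = uy * invuv - vy * invv2,
             dckz = uz * invuv - vz * invv2;
      gx[i] += pref * dcix; gy[i] += pref * dciy; gz[i] += pref * dciz;
      gx[k] += pref * dckx; gy[k] += pref * dcky; gz[k] += pref * dckz;
      gx[j] -= pref * (dcix + dckx); gy[j] -= pref * (dciy + dcky);
      gz[j] -= pref * (dciz + dckz);
    }
  }
  double cut2 = cutoff * cutoff;
  for (int m = 0; m < np; ++m) {
    int i = pi_[m] - 1, j = pj_[m] - 1;
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 > cut2) continue;
    double r = std::sqrt(r2);
    double rc = std::max(r, soft * rmin[m]);
    double q = rmin[m] / rc;
    double q3 = q * q * q;
    double q6 = q3 * q3;
    e += eps[m] * (q6 * q6 - 2.0 * q6);
    if (G && r > soft * rmin[m] && r > 1e-12) {
      double c = eps[m] * 12.0 * (q6 - q6 * q6) / (rc * r);
      gx[i] += c * dx; gy[i] += c * dy; gz[i] += c * dz;
      gx[j] -= c * dx; gy[j] -= c * dy; gz[j] -= c * dz;
    }
  }
  return e;
}

// [[Rcpp::export(name = ".cpp_minimize")]]
List cpp_minimize(NumericMatrix xyz0,
                  IntegerMatrix bonds, NumericVector r0, NumericVector kb,
                  IntegerMatrix angles, NumericVector th0, NumericVector kth,
                  IntegerMatrix pairs, NumericVector rmin, NumericVector eps,
                  double soft, double cutoff,
                  int max_steps, double step0, int max_halvings) {
  int n = xyz0.nrow();
  int nb = bonds.nrow(), na = angles.nrow(), np = pairs.nrow();
  const int* bi = nb ? &bonds(0, 0) : nullptr;
  const int* bj = nb ? &bonds(0, 1) : nullptr;
  const int* ai = na ? &angles(0, 0) : nullptr;
  const int* aj = na ? &angles(0, 1) : nullptr;
  const int* ak = na ? &angles(0, 2) : nullptr;
  const int* pi_ = np ? &pairs(0, 0) : nullptr;
  const int* pj_ = np ? &pairs(0, 1) : nullptr;
  std::vector<double> xyz(xyz0.begin(), xyz0.end());
  std::vector<double> grad(3 * n), cand(3 * n);
  double e = target_energy(xyz.data(), n, bi, bj, nb, r0.begin(), kb.begin(),
                           ai, aj, ak, na, th0.begin(), kth.begin(),
                           pi_, pj_, np, rmin.begin(), eps.begin(),
                           soft, cutoff, grad.data());
  int steps = 0;
  bool moved = false;
  for (int s = 0; s < max_steps; ++s) {
    double gn2 = 0.0;
    for (int t = 0; t < 3 * n; ++t) gn2 += grad[t] * grad[t];
    double gn = std::sqrt(gn2);
    if (gn < 1e-10) break;
    double size = step0;
    bool accepted = false;
    for (int h = 0; h <= max_halvings; ++h) {
      double c = size / gn;
      for (int t = 0; t < 3 * n; ++t) cand[t] = xyz[t] - c * grad[t];
      double e_new = target_energy(cand.data(), n, bi, bj, nb, r0.begin(),
                                   kb.begin(), ai, aj, ak, na, th0.begin(),
                                   kth.begin(), pi_, pj_, np, rmin.begin(),
                                   eps.begin(), soft, cutoff, nullptr);
      if (e_new < e) {
        xyz.swap(cand);
        e = target_energy(xyz.data(), n, bi, bj, nb, r0.begin(), kb.begin(),
                          ai, aj, ak, na, th0.begin(), kth.begin(),
                          pi_, pj_, np, rmin.begin(), eps.begin(),
                          soft, cutoff, grad.data());
        accepted = true;
        moved = true;
        ++steps;
        break;
      }
      size *= 0.5;
    }
    if (!accepted) break;
  }
  NumericMatrix out(n, 3);
  std::copy(xyz.begin(), xyz.end(), out.begin());
  return List::create(_["xyz"] = out, _["energy"] = e,
                      _["steps"] = steps, _["moved"] = moved);
}

// Geometric hydrogen-bond detection between backbone carbonyl O (acceptor,
// residue i) and amide N (donor, residue j): sequence separation >= minsep,
// dmin <= |O-N| <= dmax, and CA(i)-O(i)...N(j) angle at O > angmin degrees.
// o_idx/n_idx/ca_idx are 1-based atom indices per residue (ca paired with o).
// Returns the detected pairs as residue index pairs plus atom index pairs.
// [[Rcpp::export(name = ".cpp_hbonds")]]
List cpp_hbonds(const arma::mat& xyz,
                const arma::ivec& o_idx, const arma::ivec& n_idx,
                const arma::ivec& ca_idx,
                int minsep, double dmin, double dmax, double angmin) {
  int n = o_idx.n_elem;
  std::vector<int> ri, rj, ai, aj;
  double cmin = std::cos(angmin * M_PI / 180.0);
  for (int i = 0; i < n; ++i) {
    if (o_idx(i) == NA_INTEGER) continue;
    arma::rowvec3 O = row3(xyz, o_idx(i) - 1);
    arma::rowvec3 CA = row3(xyz, ca_idx(i) - 1);
    for (int j = 0; j < n; ++j) {
      if (std::abs(i - j) < minsep) continue;
      if (n_idx(j) == NA_INTEGER) continue;
      arma::rowvec3 N = row3(xyz, n_idx(j) - 1);
      double d = arma::norm(N - O);
      if (d < dmin || d > dmax) continue;
      arma::rowvec3 u = CA - O, v = N - O;
      double ct = arma::dot(u, v) / (arma::norm(u) * arma::norm(v));
      if (ct < cmin) {  // angle > angmin  <=>  cos(angle) < cos(angmin)
        ri.push_back(i + 1); rj.push_back(j + 1);
        ai.push_back(o_idx(i)); aj.push_back(n_idx(j));
      }
    }
  }
  return List::create(_["res_o"] = wrap(ri), _["res_n"] = wrap(rj),
                      _["atom_o"] = wrap(ai), _["atom_n"] = wrap(aj));
}

// Least-RMSD (Kabsch) of a query point set against many stored point sets.
// pool is (m*K) x 3, stacked row blocks of m rows each.
// [[Rcpp::export(name = ".cpp_rmsd_batch")]]
arma::vec cpp_rmsd_batch(const arma::mat& query, const arma::mat& pool) {
  arma::uword m = query.n_rows;
  arma::uword K = pool.n_rows / m;
  arma::mat A = query;
  A.each_row() -= arma::mean(A, 0);
  arma::vec out(K);
  for (arma::uword k = 0; k < K; ++k) {
    arma::mat B = pool.rows(k * m, (k + 1) * m - 1);
    B.each_row() -= arma::mean(B, 0);
    arma::mat H = A.t() * B;
    arma::mat U, V;
    arma::vec s;
    if (!arma::svd(U, s, V, H)) { out(k) = NA_REAL; continue; }
    arma::mat D = arma::eye(3, 3);
    if (arma::det(V * U.t()) < 0) D(2, 2) = -1.0;
    arma::mat R = V * D * U.t();
    // explicit residual avoids catastrophic cancellation near rmsd 0
    arma::mat resid = A * R.t() - B;
    out(k) = std::sqrt(arma::accu(resid % resid) / m);
  }
  return out;
}
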