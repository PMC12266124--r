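// Corotational hexahedral element assembly.
//
// Per element: rotation R from polar decomposition (SVD) of the shape-matching
// matrix between current and rest offsets; internal force
//   f_e = -E_e * R * K0 * (R^T (x_e - c_e) - q_act)
// and tangent block  K_e = E_e * R K0 R^T, where K0 is the unit-modulus
// stiffness of the (identical) voxel element and q_act the rest offsets
// shortened by the prescribed contractile strain along the actuation axis.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List corot_assemble(const arma::mat& P,       // N x 3 current vertex positions (mm)
                    const arma::imat& hexes,  // M x 8 one-based connectivity
                    const arma::mat& K0,      // 24 x 24 unit-E element stiffness
                    const arma::vec& Escale,  // per-element Young's modulus (kPa)
                    const arma::mat& Q,       // 8 x 3 rest offsets from centroid (mm)
                    const arma::vec& dir,     // unit actuation direction
                    const arma::vec& eps) {   // per-element contractile strain
  const arma::uword M = hexes.n_rows;
  const arma::uword N = P.n_rows;
  arma::vec f(3 * N, arma::fill::zeros);
  arma::vec xval(M * 576);
  double energy = 0.0;

  arma::mat Pe(8, 3), A(3, 3), U, V, R(3, 3), Ke(24, 24);
  arma::vec s, d(24), fe(24);

  for (arma::uword e = 0; e < M; ++e) {
    for (int a = 0; a < 8; ++a) Pe.row(a) = P.row(hexes(e, a) - 1);
    arma::rowvec cen = arma::mean(Pe, 0);
    A.zeros();
    for (int a = 0; a < 8; ++a) A += (Pe.row(a) - cen).t() * Q.row(a);
    if (!arma::svd(U, s, V, A))
      stop("SVD failure in rotation extraction (element %d)", (int)e + 1);
    R = U * V.t();
    if (arma::det(R) < 0.0) { U.col(2) *= -1.0; R = U * V.t(); }
    if (arma::det(A) <= 0.0)
      stop("Inverted element %d (non-positive volume)", (int)e + 1);

    for (int a = 0; a < 8; ++a) {
      arma::vec q = Q.row(a).t();
      arma::vec qact = q - eps(e) * arma::dot(q, dir) * dir;
      arma::vec pl = R.t() * (Pe.row(a) - cen).t();
      d.subvec(3 * a, 3 * a + 2) = pl - qact;
    }
    fe = K0 * d;
    energy += 0.5 * Escale(e) * arma::dot(d, fe);
    fe *= -Escale(e);
    for (int a = 0; a < 8; ++a) {
      arma::vec fa = R * fe.subvec(3 * a, 3 * a + 2);
      arma::uword vi = hexes(e, a) - 1;
      f(3 * vi) += fa(0);
      f(3 * vi + 1) += fa(1);
      f(3 * vi + 2) += fa(2);
    }
    for (int a = 0; a < 8; ++a)
      for (int b = 0; b < 8; ++b)
        Ke.submat(3 * a, 3 * b, 3 * a + 2, 3 * b + 2) =
          Escale(e) * R * K0.submat(3 * a, 3 * b, 3 * a + 2, 3 * b + 2) * R.t();
    std::memcpy(xval.memptr() + (size_t)e * 576, Ke.memptr(),
                576 * sizeof(double));
  }
  return List::create(_["x"] = xval, _["f"] = f, _["energy"] = energy);
}
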