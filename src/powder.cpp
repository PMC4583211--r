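// Powder-averaged C-term design kernel.
//
// For each (B, T) point the C-term intensity is linear in the three signed
// effective transition dipole moment products:
//   I(B,T) = gamma * [A_x * M_yz + A_y * M_xz + A_z * M_xy],
//   A_u(B,T) = 1/(4*pi*S) * sum_orient w * l_u * sum_i N_i <s_u>_i
// with exact diagonalization of H = H0 + B*(l_x Zx + l_y Zy + l_z Zz) at
// every quadrature node. Each point carries an index into a list of spin
// operator sets (total spin, or one site's spin for a dimer), so bands
// coupling to different operators share every eigendecomposition. The
// kernel returns the n_points x 3 design matrix A; everything nonlinear
// (spin-Hamiltonian parameters) stays in R.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// subspace-average diagonal expectation values within degenerate groups so
// that the arbitrary mixing of a numerical eigensolver inside a degenerate
// block cannot affect the result (time-reversal pairs cancel at B = 0)
static void degeneracy_average(const vec &energies, vec &d, double tol) {
  const uword n = energies.n_elem;
  uword start = 0;
  for (uword i = 1; i <= n; ++i) {
    if (i == n || energies(i) - energies(i - 1) > tol) {
      if (i - start > 1) {
        double m = mean(d.subvec(start, i - 1));
        d.subvec(start, i - 1).fill(m);
      }
      start = i;
    }
  }
}

// [[Rcpp::export]]
arma::mat powder_design_cpp(const arma::cx_mat &H0,
                            const arma::cx_mat &Zx,
                            const arma::cx_mat &Zy,
                            const arma::cx_mat &Zz,
                            const Rcpp::List &mode_ops,  // list of list(x,y,z)
                            const arma::mat &nodes,      // cols: lx, ly, lz, w
                            const arma::vec &Bvec,
                            const arma::vec &Tvec,
                            const arma::uvec &mode_idx,  // 0-based, per point
                            double S_scale,
                            double kB,
                            double deg_tol) {
  const uword npts = Bvec.n_elem;
  const uword nor = nodes.n_rows;
  const uword nmodes = mode_ops.size();
  mat A(npts, 3, fill::zeros);

  std::vector<cx_mat> Sop(3 * nmodes);
  for (uword m = 0; m < nmodes; ++m) {
    Rcpp::List ops = mode_ops[m];
    Sop[3 * m + 0] = Rcpp::as<cx_mat>(ops["x"]);
    Sop[3 * m + 1] = Rcpp::as<cx_mat>(ops["y"]);
    Sop[3 * m + 2] = Rcpp::as<cx_mat>(ops["z"]);
  }

  // unique field values: the diagonalization depends on (orientation, B);
  // all modes and temperatures at a given B share it
  vec uB = unique(Bvec);
  std::vector<std::vector<uword>> ptsOfB(uB.n_elem);
  std::vector<std::vector<bool>> modeNeeded(uB.n_elem,
                                            std::vector<bool>(nmodes, false));
  for (uword p = 0; p < npts; ++p) {
    uword k = index_min(abs(uB - Bvec(p)));
    ptsOfB[k].push_back(p);
    modeNeeded[k][mode_idx(p)] = true;
  }

  vec energies;
  cx_mat V;
  mat d(H0.n_rows, 3 * nmodes);
  for (uword o = 0; o < nor; ++o) {
    const double lx = nodes(o, 0), ly = nodes(o, 1), lz = nodes(o, 2);
    const double w = nodes(o, 3);
    cx_mat Zl = lx * Zx + ly * Zy + lz * Zz;
    for (uword k = 0; k < uB.n_elem; ++k) {
      cx_mat H = H0 + uB(k) * Zl;
      H = 0.5 * (H + H.t());
      if (!eig_sym(energies, V, H)) {
        Rcpp::stop("eigendecomposition failed");
      }
      for (uword m = 0; m < nmodes; ++m) {
        if (!modeNeeded[k][m]) continue;
        for (uword u = 0; u < 3; ++u) {
          cx_mat OV = Sop[3 * m + u] * V;
          vec du(energies.n_elem);
          for (uword i = 0; i < energies.n_elem; ++i) {
            du(i) = real(cdot(V.col(i), OV.col(i)));
          }
          degeneracy_average(energies, du, deg_tol);
          d.col(3 * m + u) = du;
        }
      }
      for (uword pi = 0; pi < ptsOfB[k].size(); ++pi) {
        const uword p = ptsOfB[k][pi];
        const uword m = mode_idx(p);
        vec pop = exp(-(energies - energies.min()) / (kB * Tvec(p)));
        pop /= accu(pop);
        A(p, 0) += w * lx * dot(pop, d.col(3 * m + 0));
        A(p, 1) += w * ly * dot(pop, d.col(3 * m + 1));
        A(p, 2) += w * lz * dot(pop, d.col(3 * m + 2));
      }
    }
  }
  A /= (4.0 * datum::pi * S_scale);
  return A;
}
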