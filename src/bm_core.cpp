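#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Effective transverse relaxation rates R2eff(nu_cp) for an N-state
// Bloch-McConnell generator M = K - diag(R20) - i*diag(omega), with
// dm/dt = M m acting on the transverse magnetization of each state.
//
// The CPMG train is modeled as n repetitions of the echo unit
// (tau/2 - 180 - tau/2), where tau = 1/(2 nu_cp) is the spacing between
// successive refocusing pulses and the ideal 180-degree pulse is complex
// conjugation of the magnetization. n = 2 * t_relax * nu_cp must be an
// integer (checked to 1e-6) so the train fills t_relax exactly.
//
// m0 holds the initial (equilibrium) magnetization of each state; the
// detected signal is the real part of the summed magnetization, and
// R2eff = -log(I(T)/I(0)) / T.
//
// M is decomposed once (eig_gen) and each delay propagator is assembled
// from the eigensystem, so sweeping nu_cp is cheap.
arma::vec bm_r2eff_cpp(const arma::cx_mat& M, const arma::vec& m0,
                       const arma::vec& nu, double t_relax);

// Same computation for a batch of generators sharing one nu_cp grid:
// M is an N x N x S cube (one generator per sample), m0 an N x S matrix of
// initial magnetizations. Returns a (len(nu) x S) matrix of R2eff values.
// Used by the global fit, where one residue contributes S titration curves
// per residual evaluation.
// [[Rcpp::export]]
arma::mat bm_r2eff_batch(const arma::cx_cube& M, const arma::mat& m0,
                         const arma::vec& nu, double t_relax) {
  const uword S = M.n_slices;
  if (m0.n_cols != S) Rcpp::stop("m0 must have one column per generator");
  arma::mat out(nu.n_elem, S);
  for (uword s = 0; s < S; ++s) {
    arma::vec r2 = bm_r2eff_cpp(M.slice(s), m0.col(s), nu, t_relax);
    out.col(s) = r2;
  }
  return out;
}

// [[Rcpp::export]]
arma::vec bm_r2eff_cpp(const arma::cx_mat& M, const arma::vec& m0,
                       const arma::vec& nu, double t_relax) {
  const uword N = M.n_rows;
  if (M.n_cols != N || m0.n_elem != N)
    Rcpp::stop("generator and initial magnetization dimensions disagree");
  cx_vec eigval;
  cx_mat eigvec;
  if (!eig_gen(eigval, eigvec, M))
    Rcpp::stop("eigendecomposition of the evolution generator failed");
  cx_mat Vinv;
  if (!inv(Vinv, eigvec))
    Rcpp::stop("evolution generator has a defective eigenbasis");

  const double I0 = accu(m0);
  const cx_vec m0c = conv_to<cx_vec>::from(m0);
  vec r2(nu.n_elem);

  for (uword i = 0; i < nu.n_elem; ++i) {
    const double v = nu[i];
    if (!(v > 0)) Rcpp::stop("nu_cp must be positive");
    const double n_real = 2.0 * t_relax * v;
    const double n_round = std::round(n_real);
    if (std::abs(n_real - n_round) > 1e-6)
      Rcpp::stop("nu_cp = %g Hz does not give an integer echo count in t_relax = %g s",
                 v, t_relax);
    const uword n = static_cast<uword>(n_round);
    const double delta = 1.0 / (4.0 * v);  // tau/2, half the pulse spacing
    cx_mat U = eigvec * diagmat(exp(eigval * delta)) * Vinv;
    cx_vec m = m0c;
    for (uword j = 0; j < n; ++j) {
      m = U * conj(U * m);
    }
    const double I = accu(real(m));
    r2[i] = (I > 0) ? (-std::log(I / I0) / t_relax) : NA_REAL;
  }
  return r2;
}
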