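// Felsenstein pruning for a 4-state joint chain of two binary traits.
// Likelihood of tip states under exp(Q t) transition probabilities per
// branch, accumulated in post-order with per-node rescaling.
//
// Q is eigendecomposed once per call and each branch's transition matrix is
// reconstructed from the spectrum (model fitting evaluates the likelihood
// hundreds of times, each over hundreds of branches). If Q is defective or
// the eigenvector matrix is ill-conditioned the code falls back to a Pade
// scaling-and-squaring matrix exponential per branch.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::mat expm_generator(const arma::mat& Q, double t) {
  if (Q.n_rows != Q.n_cols) Rcpp::stop("Q must be square");
  if (t < 0) Rcpp::stop("branch length must be >= 0");
  if (t == 0) return arma::eye(Q.n_rows, Q.n_cols);
  return arma::expmat(Q * t);
}

static inline void transition_from_spectrum(const arma::cx_mat& V,
                                            const arma::cx_mat& Vinv,
                                            const arma::cx_vec& eigval,
                                            double t, arma::mat& P) {
  arma::cx_mat Pc = V * arma::diagmat(arma::exp(eigval * t)) * Vinv;
  P = arma::real(Pc);
  P.clamp(0.0, arma::datum::inf);
}

// edge: n_edge x 2 integer matrix in ape post-order (children before
// parents), 1-based node indices; tip_state: state index 1..4 per tip
// (tips are nodes 1..n_tip); root_prior: length-4 probability vector.
// [[Rcpp::export]]
double pruning_loglik_cpp(const arma::imat& edge,
                          const arma::vec& edge_length,
                          int n_tip,
                          const arma::ivec& tip_state,
                          const arma::mat& Q,
                          const arma::vec& root_prior) {
  const int n_state = 4;
  if ((int)tip_state.n_elem != n_tip) Rcpp::stop("one tip state per tip required");
  int n_node = std::max((int)edge.max(), n_tip);
  arma::mat L(n_node, n_state, arma::fill::ones);
  for (int i = 0; i < n_tip; ++i) {
    int s = tip_state(i);
    if (s < 1 || s > n_state) Rcpp::stop("tip state out of range at tip %d", i + 1);
    L.row(i).zeros();
    L(i, s - 1) = 1.0;
  }

  arma::cx_vec eigval;
  arma::cx_mat V, Vinv;
  bool use_eig = arma::eig_gen(eigval, V, Q);
  if (use_eig) use_eig = arma::inv(Vinv, V);
  if (use_eig) {
    // accept the spectrum only if it reproduces exp(Q t) at a typical scale
    double tref = edge_length.max() > 0 ? edge_length.max() : 1.0;
    arma::mat Pref;
    transition_from_spectrum(V, Vinv, eigval, tref, Pref);
    arma::mat Pexact = arma::expmat(Q * tref);
    Pexact.clamp(0.0, arma::datum::inf);
    use_eig = arma::abs(Pref - Pexact).max() < 1e-9;
  }

  double logscale = 0.0;
  arma::mat P(n_state, n_state);
  for (arma::uword e = 0; e < edge.n_rows; ++e) {
    int parent = edge(e, 0) - 1;
    int child = edge(e, 1) - 1;
    if (edge_length(e) == 0.0) {
      P.eye();
    } else if (use_eig) {
      transition_from_spectrum(V, Vinv, eigval, edge_length(e), P);
    } else {
      P = arma::expmat(Q * edge_length(e));
      P.clamp(0.0, arma::datum::inf);
    }
    arma::rowvec contrib = L.row(child) * P.t(); // contrib(s)=sum_j P(s,j) L(c,j)
    L.row(parent) %= contrib;
    double m = L.row(parent).max();
    if (m > 0.0 && m < 1e-250) {
      L.row(parent) /= m;
      logscale += std::log(m);
    }
  }
  int root = n_tip; // ape convention: root is node n_tip + 1 (0-based n_tip)
  double lik = arma::dot(root_prior, L.row(root).t());
  if (lik <= 0.0) return R_NegInf;
  return std::log(lik) + logscale;
}
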