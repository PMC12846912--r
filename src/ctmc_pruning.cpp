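// Felsenstein pruning likelihood for a k-state CTMC on a rooted tree.
//
// The generator Q is eigendecomposed once per call and per-edge transition
// matrices are assembled as P(t) = Re(U diag(exp(lambda t)) U^-1); when the
// eigenvector matrix is ill-conditioned we fall back to arma::expmat per
// edge. Partial likelihoods are rescaled at every node so trees with
// thousands of tips stay in range.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct EigQ {
  // real path: P(t) = sum_m exp(lambda_m t) B_m with B_m the spectral
  // projectors, stored flattened as proj(m, i*k+j)
  arma::mat proj;
  arma::vec lambda_re;
  // complex fallback path
  arma::cx_mat U;
  arma::cx_mat Uinv;
  arma::cx_vec lambda;
  arma::mat Q;
  bool ok;
  bool real_spec;
};

EigQ decompose(const arma::mat& Q) {
  EigQ e;
  e.Q = Q;
  e.ok = false;
  e.real_spec = false;
  arma::cx_vec lam;
  arma::cx_mat U;
  if (!arma::eig_gen(lam, U, Q)) return e;
  arma::cx_mat Uinv;
  if (!arma::inv(Uinv, U)) return e;
  // reject decompositions too ill-conditioned to reproduce Q accurately
  arma::mat recon = arma::real(U * arma::diagmat(lam) * Uinv);
  double scale = arma::norm(Q, "inf");
  if (scale < 1e-300) scale = 1.0;
  if (arma::norm(recon - Q, "inf") / scale > 1e-9) return e;
  e.U = U;
  e.Uinv = Uinv;
  e.lambda = lam;
  e.ok = true;
  const arma::uword k = Q.n_rows;
  if (k <= 16 && arma::norm(arma::imag(lam), "inf") < 1e-12 * (1.0 + scale)) {
    e.real_spec = true;
    e.lambda_re = arma::real(lam);
    e.proj.set_size(k, k * k);
    for (arma::uword m = 0; m < k; ++m) {
      for (arma::uword i = 0; i < k; ++i) {
        for (arma::uword j = 0; j < k; ++j) {
          e.proj(m, i * k + j) = (U(i, m) * Uinv(m, j)).real();
        }
      }
    }
  }
  return e;
}

// P(t) for one edge; result clamped to [0, 1]
void edge_pmat(const EigQ& e, double t, arma::mat& P) {
  const arma::uword k = e.Q.n_rows;
  if (e.ok && e.real_spec) {
    double w[16];  // k <= 16 assumed for the fast path buffer
    for (arma::uword m = 0; m < k; ++m) w[m] = std::exp(e.lambda_re(m) * t);
    const double* pr = e.proj.memptr();  // column-major: proj(m, c)
    for (arma::uword i = 0; i < k; ++i) {
      for (arma::uword j = 0; j < k; ++j) {
        const double* col = pr + (i * k + j) * k;
        double s = 0.0;
        for (arma::uword m = 0; m < k; ++m) s += w[m] * col[m];
        if (s < 0.0) s = 0.0;
        if (s > 1.0) s = 1.0;
        P(i, j) = s;
      }
    }
  } else if (e.ok) {
    arma::cx_vec w = arma::exp(e.lambda * t);
    for (arma::uword i = 0; i < k; ++i) {
      for (arma::uword j = 0; j < k; ++j) {
        std::complex<double> s(0.0, 0.0);
        for (arma::uword m = 0; m < k; ++m) s += e.U(i, m) * w(m) * e.Uinv(m, j);
        double v = s.real();
        if (v < 0.0) v = 0.0;
        if (v > 1.0) v = 1.0;
        P(i, j) = v;
      }
    }
  } else {
    P = arma::expmat(e.Q * t);
    P.clamp(0.0, 1.0);
  }
}

// Core pruning pass. edge is postorder, 1-based node ids as in ape:
// tips 1..n_tip, root n_tip+1. Returns log-likelihood and (optionally)
// the rescaled downward partials for every node.
double pruning_pass(const arma::umat& edge, const arma::vec& edge_length,
                    const arma::mat& tip_partials, int n_node_total,
                    const arma::mat& Q, int root_mode,
                    const arma::vec& root_prior, arma::mat* keep_partials,
                    arma::vec* keep_logscale) {
  const arma::uword k = Q.n_rows;
  const arma::uword n_tip = tip_partials.n_rows;
  arma::mat part(k, n_node_total, arma::fill::ones);
  arma::vec logscale(n_node_total, arma::fill::zeros);
  for (arma::uword i = 0; i < n_tip; ++i) part.col(i) = tip_partials.row(i).t();

  EigQ e = decompose(Q);
  arma::mat P(k, k);
  arma::vec v(k);

  for (arma::uword r = 0; r < edge.n_rows; ++r) {
    const arma::uword p = edge(r, 0) - 1;
    const arma::uword c = edge(r, 1) - 1;
    // normalize the (now complete) child partial
    double s = arma::accu(part.col(c));
    if (!(s > 0.0)) return R_NegInf;
    part.col(c) /= s;
    logscale(c) += std::log(s);
    edge_pmat(e, edge_length(r), P);
    v = P * part.col(c);
    part.col(p) %= v;
    logscale(p) += logscale(c);
  }

  const arma::uword root = edge(edge.n_rows - 1, 0) - 1;
  double lik = 0.0;
  double tot = arma::accu(part.col(root));
  if (!(tot > 0.0)) return R_NegInf;
  if (root_mode == 0) {  // uniform
    lik = tot / static_cast<double>(k);
  } else if (root_mode == 1) {  // FitzJohn: weight by each state's own partial
    lik = arma::accu(arma::square(part.col(root))) / tot;
  } else {  // fixed vector
    lik = arma::dot(root_prior, part.col(root));
  }
  if (!(lik > 0.0)) return R_NegInf;
  if (keep_partials) {
    *keep_partials = part;
    *keep_logscale = logscale;
  }
  return std::log(lik) + logscale(root);
}

}  // namespace

// [[Rcpp::export]]
double ctmc_loglik_cpp(const arma::umat& edge, const arma::vec& edge_length,
                       const arma::mat& tip_partials, int n_node_total,
                       const arma::mat& Q, int root_mode,
                       const arma::vec& root_prior) {
  return pruning_pass(edge, edge_length, tip_partials, n_node_total, Q,
                      root_mode, root_prior, nullptr, nullptr);
}

// [[Rcpp::export]]
List ctmc_partials_cpp(const arma::umat& edge, const arma::vec& edge_length,
                       const arma::mat& tip_partials, int n_node_total,
                       const arma::mat& Q, int root_mode,
                       const arma::vec& root_prior) {
  arma::mat part;
  arma::vec logscale;
  double ll = pruning_pass(edge, edge_length, tip_partials, n_node_total, Q,
                           root_mode, root_prior, &part, &logscale);
  return List::create(_["loglik"] = ll, _["partials"] = part.t(),
                      _["logscale"] = logscale);
}
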