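// Felsenstein pruning over arbitrary finite alphabets.
//
// The R side supplies the eigen-decomposition of the (reversible,
// mean-rate-1) rate matrix, tip partial-likelihood matrices on compressed
// site patterns, the postorder edge list of a tree rooted at an internal
// node, and the per-category rate multipliers of the discrete-gamma /
// invariant-sites mixture.  All functions treat a rate of exactly 0 as the
// identity transition matrix (the invariant class).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat pmatrix(const vec& lambda, const mat& U, const mat& Uinv,
                   double t, double rate) {
  if (rate <= 0.0 || t <= 0.0) {
    return eye<mat>(U.n_rows, U.n_rows);
  }
  mat P = U * diagmat(exp(lambda * (t * rate))) * Uinv;
  P.clamp(0.0, datum::inf);
  return P;
}

// Per-category site likelihoods at the root.
// edge: nedge x 2 (parent, child), 1-based node ids, postorder.
// tippart: k x npat x ntip cube of tip partials.
// Returns ncat x npat matrix of site likelihoods (bf already applied).
// [[Rcpp::export]]
arma::mat percat_site_lik_cpp(const arma::imat& edge, int ntip, int nnode,
                              const arma::cube& tippart,
                              const arma::vec& lambda, const arma::mat& U,
                              const arma::mat& Uinv, const arma::vec& bf,
                              const arma::vec& tlen, const arma::vec& rates) {
  const int k = tippart.n_rows, npat = tippart.n_cols;
  const int nedge = edge.n_rows, ncat = rates.n_elem;
  mat out(ncat, npat);
  int root = edge(nedge - 1, 0);
  for (int c = 0; c < ncat; ++c) {
    std::vector<mat> partial(nnode + 1);
    std::vector<bool> seen(nnode + 1, false);
    for (int e = 0; e < nedge; ++e) {
      int u = edge(e, 0), v = edge(e, 1);
      mat down = (v <= ntip) ? mat(tippart.slice(v - 1)) : partial[v];
      mat P = pmatrix(lambda, U, Uinv, tlen(e), rates(c));
      mat contrib = P * down;
      if (!seen[u]) { partial[u] = contrib; seen[u] = true; }
      else partial[u] %= contrib;
    }
    out.row(c) = bf.t() * partial[root];
  }
  return out;
}

// Down ("below") and up ("above") partials for every edge and category,
// for fast single-edge branch-length optimization.  below[, , e + nedge*c]
// is the partial of the child subtree of edge e; above[, , e + nedge*c] is
// the partial of everything else, indexed by the state at the parent and
// already carrying the root frequencies.  For any edge and any t,
//   L_s(c) = sum_x above[x, s] * (P_c(t) * below[, s])[x].
// [[Rcpp::export]]
Rcpp::List edge_arrays_cpp(const arma::imat& edge, int ntip, int nnode,
                           const arma::cube& tippart,
                           const arma::vec& lambda, const arma::mat& U,
                           const arma::mat& Uinv, const arma::vec& bf,
                           const arma::vec& tlen, const arma::vec& rates) {
  const int k = tippart.n_rows, npat = tippart.n_cols;
  const int nedge = edge.n_rows, ncat = rates.n_elem;
  int root = edge(nedge - 1, 0);
  cube below(k, npat, nedge * ncat), above(k, npat, nedge * ncat);
  // children edge indices per node
  std::vector<std::vector<int>> childedges(nnode + 1);
  std::vector<int> paredge(nnode + 1, -1);
  for (int e = 0; e < nedge; ++e) {
    childedges[edge(e, 0)].push_back(e);
    paredge[edge(e, 1)] = e;
  }
  for (int c = 0; c < ncat; ++c) {
    std::vector<mat> D(nnode + 1);   // node below-partials
    std::vector<mat> PD(nedge);      // P_e * D[child(e)]
    std::vector<mat> P(nedge);
    for (int e = 0; e < nedge; ++e) {
      int v = edge(e, 1);
      mat down = (v <= ntip) ? mat(tippart.slice(v - 1)) : D[v];
      if (v > ntip && D[v].n_elem == 0) Rcpp::stop("postorder violated");
      P[e] = pmatrix(lambda, U, Uinv, tlen(e), rates(c));
      PD[e] = P[e] * down;
      below.slice(e + nedge * c) = down;
      int u = edge(e, 0);
      if (D[u].n_elem == 0) D[u] = PD[e];
      else D[u] %= PD[e];
    }
    // preorder (reverse postorder) for above partials
    for (int e = nedge - 1; e >= 0; --e) {
      int u = edge(e, 0);
      mat G;
      if (u == root) {
        G = repmat(bf, 1, npat);
      } else {
        int pe = paredge[u];
        G = P[pe].t() * above.slice(pe + nedge * c);
      }
      for (int f : childedges[u]) if (f != e) G %= PD[f];
      above.slice(e + nedge * c) = G;
    }
  }
  return Rcpp::List::create(Rcpp::Named("below") = below,
                            Rcpp::Named("above") = above);
}

// Total log-likelihood as a function of one edge's length, given that
// edge's above/below arrays (slices e + nedge*c as produced above).
// [[Rcpp::export]]
double edge_loglik_cpp(const arma::cube& above, const arma::cube& below,
                       int e, int nedge,
                       const arma::vec& lambda, const arma::mat& U,
                       const arma::mat& Uinv, const arma::vec& rates,
                       const arma::vec& weights, const arma::vec& patw,
                       double t) {
  const int npat = above.n_cols, ncat = rates.n_elem;
  rowvec lik(npat, fill::zeros);
  for (int c = 0; c < ncat; ++c) {
    mat P = pmatrix(lambda, U, Uinv, t, rates(c));
    lik += weights(c) *
      sum(above.slice(e + nedge * c) % (P * below.slice(e + nedge * c)), 0);
  }
  return accu(conv_to<rowvec>::from(log(lik)) % patw.t());
}

// Spectral coefficients for single-edge optimization: for edge e and
// category c, C(k, s) = (U^T above)(k, s) * (Uinv below)(k, s), so that
//   L_s(t) = sum_k C(k, s) * exp(lambda_k * rate_c * t).
// One GEMM pair per category here buys near-free branch-length trials.
// [[Rcpp::export]]
arma::cube edge_spectral_coef_cpp(const arma::cube& above,
                                  const arma::cube& below,
                                  int e, int nedge,
                                  const arma::mat& U, const arma::mat& Uinv,
                                  int ncat) {
  const int k = above.n_rows, npat = above.n_cols;
  cube C(k, npat, ncat);
  for (int c = 0; c < ncat; ++c) {
    C.slice(c) = (U.t() * above.slice(e + nedge * c)) %
                 (Uinv * below.slice(e + nedge * c));
  }
  return C;
}

// [[Rcpp::export]]
double edge_loglik_spectral_cpp(const arma::cube& C, const arma::vec& lambda,
                                const arma::vec& rates,
                                const arma::vec& weights,
                                const arma::vec& patw, double t) {
  const int npat = C.n_cols, ncat = rates.n_elem;
  rowvec lik(npat, fill::zeros);
  for (int c = 0; c < ncat; ++c) {
    vec ev = (rates(c) * t <= 0) ? vec(lambda.n_elem, fill::ones)
                                 : vec(exp(lambda * (rates(c) * t)));
    lik += weights(c) * (ev.t() * C.slice(c));
  }
  // tiny negative values can appear from cancellation in the eigenbasis
  lik.clamp(std::numeric_limits<double>::min(), datum::inf);
  return accu(conv_to<rowvec>::from(log(lik)) % patw.t());
}
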