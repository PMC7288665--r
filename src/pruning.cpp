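// Felsenstein pruning over the 61 sense-codon state space, evaluated for
// several site classes that differ only in which rate matrix each branch
// uses (branch-site models assign the foreground branch a different
// omega in the selected classes).
//
// Per-branch transition matrices are built from the symmetrised
// eigendecomposition of the reversible rate matrix:
//   P(t) = Vh * diag(exp(lam * t)) * W .
//
// Classes are evaluated incrementally: node partials of an already
// computed class are shared by pointer, and only the nodes above
// branches whose rate matrix differs (typically just the path from the
// foreground branch to the root) are recomputed.

#include <RcppArmadillo.h>
#include <deque>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat edgeP(const mat& Vh, const mat& W, const vec& lam, double t) {
  mat S = W;
  S.each_col() %= exp(lam * t);   // diag(exp(lam t)) * W
  mat P = Vh * S;
  P = clamp(P, 0.0, datum::inf);  // clip tiny negative round-off
  return P;
}

// edge:      nEdge x 2 (parent, child), 1-based node ids, postorder
//            (every child edge appears before the edge above it).
// tipState:  nTip x nPat, 0-based sense-codon index, -1 = missing.
// eig:       list of list(Vh, W, lam), one per distinct omega.
// tvec:      branch length per edge.
// edgeOmega: nEdge x nClass, 1-based index into eig per edge per class.
// rateScale: per-omega multiplier applied to branch lengths (common
//            mixture scaling: class omega rate / background average).
// pi:        61 root frequencies.
// Returns nPat x nClass matrix of log site likelihoods per class.
// [[Rcpp::export]]
arma::mat prune_class_loglik(const arma::imat& edge,
                             int nTip, int nNode,
                             const arma::imat& tipState,
                             const Rcpp::List& eig,
                             const arma::vec& tvec,
                             const arma::imat& edgeOmega,
                             const arma::vec& rateScale,
                             const arma::vec& pi) {
  const int nEdge = edge.n_rows;
  const int nPat = tipState.n_cols;
  const int nClass = edgeOmega.n_cols;
  const int nState = pi.n_elem;
  const int nOmega = eig.size();
  const int root = edge(nEdge - 1, 0);

  std::vector<mat> Vh(nOmega), W(nOmega);
  std::vector<vec> lam(nOmega);
  for (int k = 0; k < nOmega; ++k) {
    Rcpp::List e = eig[k];
    Vh[k] = Rcpp::as<mat>(e["Vh"]);
    W[k] = Rcpp::as<mat>(e["W"]);
    lam[k] = Rcpp::as<vec>(e["lam"]);
  }

  // cache of per-(omega, edge) transition matrices
  std::vector<mat> Pcache(static_cast<size_t>(nOmega) * nEdge);
  std::vector<char> Phave(static_cast<size_t>(nOmega) * nEdge, 0);
  auto getP = [&](int om, int e) -> const mat& {
    const size_t key = static_cast<size_t>(om) * nEdge + e;
    if (!Phave[key]) {
      Pcache[key] = edgeP(Vh[om], W[om], lam[om],
                          tvec[e] * rateScale[om]);
      Phave[key] = 1;
    }
    return Pcache[key];
  };

  // arena of computed node partials and log-scalers; classes share the
  // nodes they do not change by pointer instead of copying
  std::deque<mat> arena;
  std::deque<rowvec> scaleArena;
  std::vector<std::vector<const mat*>> partials(
      nClass, std::vector<const mat*>(nNode + 1, nullptr));
  std::vector<std::vector<const rowvec*>> scales(
      nClass, std::vector<const rowvec*>(nNode + 1, nullptr));

  mat out(nPat, nClass);

  for (int cl = 0; cl < nClass; ++cl) {
    // reuse the already-computed class with the fewest differing edges
    int ref = -1, bestDiff = nEdge + 1;
    for (int c2 = 0; c2 < cl; ++c2) {
      int d = 0;
      for (int e = 0; e < nEdge; ++e)
        if (edgeOmega(e, c2) != edgeOmega(e, cl)) ++d;
      if (d < bestDiff) { bestDiff = d; ref = c2; }
    }

    std::vector<char> affected(nNode + 1, 0);
    if (ref < 0) {
      std::fill(affected.begin(), affected.end(), 1);
    } else {
      for (int e = 0; e < nEdge; ++e)
        if (edgeOmega(e, ref) != edgeOmega(e, cl) ||
            affected[edge(e, 1)])
          affected[edge(e, 0)] = 1;
      partials[cl] = partials[ref];   // pointer copies only
      scales[cl] = scales[ref];
    }

    std::vector<char> have(nNode + 1, 0);
    std::vector<mat*> fresh(nNode + 1, nullptr);
    std::vector<rowvec*> freshScale(nNode + 1, nullptr);

    for (int e = 0; e < nEdge; ++e) {
      const int parent = edge(e, 0);
      if (!affected[parent]) continue;
      const int child = edge(e, 1);
      const mat& P = getP(edgeOmega(e, cl) - 1, e);

      mat contrib;
      const rowvec* childScale = nullptr;
      if (child <= nTip) {
        contrib.set_size(nState, nPat);
        for (int p = 0; p < nPat; ++p) {
          const int s = tipState(child - 1, p);
          if (s >= 0) contrib.col(p) = P.col(s);
          else contrib.col(p).ones();
        }
      } else {
        contrib = P * (*partials[cl][child]);
        // rescale to dodge underflow on deep trees
        rowvec m = max(contrib, 0);
        m.transform([](double v) { return v > 0 ? v : 1.0; });
        contrib.each_row() /= m;
        const rowvec* below = scales[cl][child];
        rowvec lm = log(m);
        if (below) lm += *below;
        scaleArena.push_back(std::move(lm));
        childScale = &scaleArena.back();
      }

      if (!have[parent]) {
        arena.push_back(std::move(contrib));
        fresh[parent] = &arena.back();
        partials[cl][parent] = fresh[parent];
        if (childScale) {
          scaleArena.push_back(*childScale);
          freshScale[parent] = &scaleArena.back();
          scales[cl][parent] = freshScale[parent];
        } else {
          scales[cl][parent] = nullptr;
        }
        have[parent] = 1;
      } else {
        (*fresh[parent]) %= contrib;
        if (childScale) {
          if (!freshScale[parent]) {
            scaleArena.push_back(*childScale);
            freshScale[parent] = &scaleArena.back();
          } else {
            (*freshScale[parent]) += *childScale;
          }
          scales[cl][parent] = freshScale[parent];
        }
      }
    }

    rowvec lik = pi.t() * (*partials[cl][root]);
    if (scales[cl][root])
      out.col(cl) = (log(lik) + *scales[cl][root]).t();
    else
      out.col(cl) = log(lik).t();
  }
  return out;
}

// Build the scaled GY94 rate matrix and its symmetrised
// eigendecomposition in one call (hot path of the optimiser).
// pairI/pairJ: 0-based single-step codon pair indices; pairType:
// 1 syn-tv, 2 syn-ts, 3 nonsyn-tv, 4 nonsyn-ts.
// [[Rcpp::export]]
Rcpp::List codon_eigen_cpp(double kappa, double omega,
                           const arma::uvec& pairI,
                           const arma::uvec& pairJ,
                           const arma::ivec& pairType,
                           const arma::vec& pi) {
  const int n = pi.n_elem;
  const double mult[5] = {0.0, 1.0, kappa, omega, omega * kappa};
  mat Q(n, n, fill::zeros);
  for (size_t k = 0; k < pairI.n_elem; ++k)
    Q(pairI[k], pairJ[k]) = mult[pairType[k]] * pi[pairJ[k]];
  vec rsum = sum(Q, 1);
  Q.diag() = -rsum;
  const double rate = dot(pi, rsum);   // mean equilibrium rate
  if (rate > 0) Q /= rate;
  vec s = sqrt(pi);
  mat A = Q % (s * (1.0 / s).t());
  A = (A + A.t()) / 2;                 // numerical symmetrisation
  vec lam;
  mat V;
  eig_sym(lam, V, A);
  mat Vh = V.each_col() / s;           // diag(1/s) * V
  mat W = V.t();
  W.each_row() %= s.t();               // t(V) * diag(s)
  return Rcpp::List::create(
      Rcpp::Named("Vh") = Vh,
      Rcpp::Named("W") = W,
      Rcpp::Named("lam") = Rcpp::NumericVector(lam.begin(), lam.end()));
}
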