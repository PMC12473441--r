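// Depth-truncated evaluation of a ranger classification forest.
//
// A random-forest tree is grown greedily, so the top d levels of a
// depth-30 tree are exactly the depth-d tree: the whole depth grid can be
// scored from one full-depth forest per fold. Ranger stores no class
// distributions at internal nodes, so the in-bag training samples are
// routed through every tree first to recover each node's class counts;
// a tree truncated at depth d then predicts the majority class of the
// node reached at that depth (or the stored leaf class when the path
// terminates above the cap).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// child_left/child_right/varid/splitval: per-tree node arrays (ranger
// layout, 0-based node ids and variable ids; both children 0 <=> leaf,
// where splitval holds the predicted class value).
// Xtr/Xte: samples x features. inbag: n_tr x n_trees bootstrap counts.
// Returns, for each depth cap, an (n_te x n_trees) matrix of predicted
// class values.
// [[Rcpp::export]]
Rcpp::List rf_predict_depths_cpp(const Rcpp::List& child_left,
                                 const Rcpp::List& child_right,
                                 const Rcpp::List& varid,
                                 const Rcpp::List& splitval,
                                 const arma::mat& Xtr,
                                 const arma::ivec& ytr,
                                 const arma::imat& inbag,
                                 const arma::mat& Xte,
                                 const arma::ivec& depths, int n_classes) {
  const int T = child_left.size();
  const int n_tr = Xtr.n_rows, n_te = Xte.n_rows, D = depths.n_elem;
  std::vector<arma::imat> out(D);
  for (int d = 0; d < D; ++d) out[d].set_size(n_te, T);

  for (int t = 0; t < T; ++t) {
    Rcpp::IntegerVector cl = child_left[t], cr = child_right[t],
                        vid = varid[t];
    Rcpp::NumericVector sv = splitval[t];
    const int n_nodes = cl.size();
    // node class counts from the in-bag samples
    std::vector<int> counts((size_t)n_nodes * n_classes, 0);
    std::vector<int> depth(n_nodes, 0);
    for (int nd = 0; nd < n_nodes; ++nd) {
      if (cl[nd] > 0) {
        depth[cl[nd]] = depth[nd] + 1;
        depth[cr[nd]] = depth[nd] + 1;
      }
    }
    for (int i = 0; i < n_tr; ++i) {
      const int w = inbag(i, t);
      if (w == 0) continue;
      int nd = 0;
      const int yi = ytr(i) - 1;
      while (true) {
        counts[(size_t)nd * n_classes + yi] += w;
        if (cl[nd] == 0 && cr[nd] == 0) break;
        nd = (Xtr(i, vid[nd]) <= sv[nd]) ? cl[nd] : cr[nd];
      }
    }
    // majority class per node (ties -> lowest class value)
    std::vector<int> maj(n_nodes, 0);
    for (int nd = 0; nd < n_nodes; ++nd) {
      int best = 0, bc = counts[(size_t)nd * n_classes];
      for (int k = 1; k < n_classes; ++k) {
        if (counts[(size_t)nd * n_classes + k] > bc) {
          bc = counts[(size_t)nd * n_classes + k];
          best = k;
        }
      }
      maj[nd] = best + 1;
    }
    // route test samples, recording the prediction at every depth cap
    for (int i = 0; i < n_te; ++i) {
      int nd = 0;
      int di = 0;
      int last_pred = maj[0];
      while (true) {
        const bool leaf = (cl[nd] == 0 && cr[nd] == 0);
        const int pred_here = leaf ? (int)sv[nd] : maj[nd];
        while (di < D && depths[di] == depth[nd]) {
          out[di](i, t) = pred_here;
          ++di;
        }
        if (leaf || di >= D) {
          last_pred = leaf ? (int)sv[nd] : -1;
          break;
        }
        nd = (Xte(i, vid[nd]) <= sv[nd]) ? cl[nd] : cr[nd];
      }
      // path ended above the remaining (deeper) caps: leaf class applies
      for (; di < D; ++di) out[di](i, t) = last_pred;
    }
  }
  Rcpp::List res(D);
  for (int d = 0; d < D; ++d) res[d] = out[d];
  return res;
}
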