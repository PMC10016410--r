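// Hot path of the subtype-and-stage likelihood: piecewise-linear trajectory
// evaluation and the stage-marginalised Gaussian log-likelihood, called many
// thousands of times by the greedy sequence search, the EM refinement and
// the MCMC sampler.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Build the sigma-scaled trajectory matrix Gs (I x (E+1)) for one ordering.
// bm_events holds 1-based event ids per biomarker (threshold order),
// bm_z the corresponding z-values, z_max the stage-(E+1) plateau anchors.
static arma::mat traj_scaled(const arma::ivec& ordering,
                             const List& bm_events, const List& bm_z,
                             const arma::vec& z_max, const arma::vec& sig) {
  const int E = ordering.n_elem;
  const int I = bm_events.size();
  arma::ivec pos(E + 1);  // 1-based event id -> position
  for (int p = 0; p < E; ++p) pos[ordering[p]] = p + 1;

  arma::mat Gs(I, E + 1);
  for (int i = 0; i < I; ++i) {
    IntegerVector ids = bm_events[i];
    NumericVector zs = bm_z[i];
    const int R = ids.size();
    // anchors: (0,0), (pos[e_r], z_r), (E+1, z_max)
    std::vector<double> xs(R + 2), ys(R + 2);
    xs[0] = 0.0; ys[0] = 0.0;
    for (int r = 0; r < R; ++r) { xs[r + 1] = pos[ids[r]]; ys[r + 1] = zs[r]; }
    xs[R + 1] = E + 1.0; ys[R + 1] = z_max[i];
    int seg = 0;
    for (int k = 0; k <= E; ++k) {
      while (seg + 1 < R + 1 && xs[seg + 1] <= k) ++seg;
      const double g = ys[seg] +
        (ys[seg + 1] - ys[seg]) * (k - xs[seg]) / (xs[seg + 1] - xs[seg]);
      Gs(i, k) = g / sig[i];
    }
  }
  return Gs;
}

// log P(x_j | S) for every subject: log-sum-exp over stages 0..E of the
// Gaussian stage likelihood, minus log(E + 1) (uniform stage prior).
// [[Rcpp::export(name = ".marginal_cpp")]]
arma::vec marginal_cpp(const arma::mat& Xs, const arma::vec& rs2,
                       double cst, const arma::vec& sig,
                       const List& bm_events, const List& bm_z,
                       const arma::vec& z_max, const arma::ivec& ordering) {
  const int E = ordering.n_elem;
  arma::mat Gs = traj_scaled(ordering, bm_events, bm_z, z_max, sig);
  arma::rowvec g2 = arma::sum(arma::square(Gs), 0);       // 1 x (E+1)
  arma::mat L = Xs * Gs;                                  // n x (E+1)
  L.each_row() -= 0.5 * g2;
  L.each_col() -= 0.5 * rs2;
  // logsumexp over columns
  arma::vec m = arma::max(L, 1);
  arma::vec out = m + arma::log(arma::sum(arma::exp(L.each_col() - m), 1));
  out += cst - std::log((double)(E + 1));
  return out;
}

static double objective(const arma::mat& Xs, const arma::vec& rs2,
                        double cst, const arma::vec& sig,
                        const List& bm_events, const List& bm_z,
                        const arma::vec& z_max, const arma::ivec& ordering,
                        const arma::vec& w) {
  const int E = ordering.n_elem;
  arma::mat Gs = traj_scaled(ordering, bm_events, bm_z, z_max, sig);
  arma::rowvec g2 = arma::sum(arma::square(Gs), 0);
  arma::mat L = Xs * Gs;
  L.each_row() -= 0.5 * g2;
  L.each_col() -= 0.5 * rs2;
  arma::vec m = arma::max(L, 1);
  arma::vec marg = m + arma::log(arma::sum(arma::exp(L.each_col() - m), 1));
  return arma::dot(w, marg) +
    arma::accu(w) * (cst - std::log((double)(E + 1)));
}

// Greedy coordinate search to convergence: repeated sweeps over the events
// (random sweep order via R's RNG, so seeds set in R are honoured); each
// event is re-inserted at its best position subject to within-biomarker
// threshold order, ties broken toward the lowest position; stops when a
// full sweep brings no improvement.
// [[Rcpp::export(name = ".greedy_cpp")]]
List greedy_cpp(const arma::mat& Xs, const arma::vec& rs2, double cst,
                const arma::vec& sig, const List& bm_events,
                const List& bm_z, const arma::vec& z_max,
                const IntegerVector& prev_event,
                const IntegerVector& next_event,
                arma::ivec ordering, const arma::vec& w, int max_passes) {
  const int E = ordering.n_elem;
  double cur = objective(Xs, rs2, cst, sig, bm_events, bm_z, z_max,
                         ordering, w);
  for (int pass = 0; pass < max_passes; ++pass) {
    bool improved = false;
    IntegerVector sweep = Rcpp::sample(E, E);  // 1-based, R RNG
    for (int s = 0; s < E; ++s) {
      const int e = sweep[s];
      arma::ivec reduced(E - 1);
      int idx = 0;
      for (int p = 0; p < E; ++p) if (ordering[p] != e) reduced[idx++] = ordering[p];
      // allowed slot range from the within-biomarker neighbours
      int lo = 1, hi = E;  // insertion slots 1..E (1-based)
      const int pe = prev_event[e - 1], ne = next_event[e - 1];
      for (int p = 0; p < E - 1; ++p) {
        if (pe != 0 && reduced[p] == pe) lo = p + 2;
        if (ne != 0 && reduced[p] == ne) hi = p + 1;
      }
      int best_slot = -1;
      double best_obj = cur;
      arma::ivec cand(E);
      for (int slot = lo; slot <= hi; ++slot) {
        for (int p = 0; p < slot - 1; ++p) cand[p] = reduced[p];
        cand[slot - 1] = e;
        for (int p = slot - 1; p < E - 1; ++p) cand[p + 1] = reduced[p];
        const double obj = objective(Xs, rs2, cst, sig, bm_events, bm_z,
                                     z_max, cand, w);
        if (obj > best_obj + 1e-12) { best_obj = obj; best_slot = slot; }
      }
      if (best_slot > 0) {
        for (int p = 0; p < best_slot - 1; ++p) ordering[p] = reduced[p];
        ordering[best_slot - 1] = e;
        for (int p = best_slot - 1; p < E - 1; ++p) ordering[p + 1] = reduced[p];
        cur = best_obj;
        improved = true;
      }
    }
    if (!improved) break;
  }
  return List::create(Named("ordering") = ordering,
                      Named("objective") = cur);
}

// n x (E+1) stage log-likelihood matrix (used by assignment and posteriors).
// [[Rcpp::export(name = ".stage_loglik_cpp")]]
arma::mat stage_loglik_cpp(const arma::mat& Xs, const arma::vec& rs2,
                           double cst, const arma::vec& sig,
                           const List& bm_events, const List& bm_z,
                           const arma::vec& z_max, const arma::ivec& ordering) {
  arma::mat Gs = traj_scaled(ordering, bm_events, bm_z, z_max, sig);
  arma::rowvec g2 = arma::sum(arma::square(Gs), 0);
  arma::mat L = Xs * Gs;
  L.each_row() -= 0.5 * g2;
  L.each_col() -= 0.5 * rs2;
  L += cst;
  return L;
}
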