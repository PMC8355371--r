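// Core dynamics of the deep Hebbian predictive coding network.
//
// Layout conventions (shared with the R level):
//  - activity of area l: cube (n_l x B x P_l); slice k = activities of
//    population k for the whole batch.
//  - weights of area pair (l-1, l): cube (M_l x n_l x P_l) with
//    M_l = s_l^2 * n_{l-1}; slice k = feedback weight matrix of population k,
//    rows ordered with the lower-neuron index fastest within each RF offset.
//  - rf index map: s_l^2 x P_l integer matrix of 1-based lower-population
//    indices (column-major offsets, consistent with rf_index_map() in R).
//
// One inference step is fully synchronous: all predictions, bottom-up errors
// and drives are evaluated from the pre-step state before any area updates.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Pair {
  arma::cube W;        // M x n_l x P
  arma::imat idx;      // s^2 x P (1-based)
  int n_low;
};

// gather the RF-stacked lower activities for upper population k: (M x B)
inline arma::mat gather_low(const arma::cube& low, const arma::imat& idx,
                            int k, int n_low, int B) {
  const int s2 = idx.n_rows;
  arma::mat out(s2 * n_low, B);
  for (int q = 0; q < s2; ++q)
    out.rows(q * n_low, (q + 1) * n_low - 1) = low.slice(idx(q, k) - 1);
  return out;
}

} // namespace

// Run n_steps synchronous inference steps with area 0 clamped to y0.
// Returns the final state and, if record_energy, an (n_steps+1) x N matrix of
// per-area total squared bottom-up error (row t = energy before step t; the
// final row is the energy of the returned state).
// [[Rcpp::export]]
List settle_cpp(const arma::cube& y0, List weights, List rf_index,
                List y_init, NumericVector eta, NumericVector alpha_y,
                double gamma_y, int n_steps, bool record_energy) {
  const int N = weights.size();
  const int B = y0.n_cols;

  std::vector<Pair> pairs(N);
  std::vector<arma::cube> y(N);
  for (int l = 0; l < N; ++l) {
    pairs[l].W = as<arma::cube>(weights[l]);
    pairs[l].idx = as<arma::imat>(rf_index[l]);
    // deep-copy the initial state: the cube exporter may alias R memory and
    // the state is updated in place below
    NumericVector yv = y_init[l];
    IntegerVector yd = yv.attr("dim");
    y[l] = arma::cube(yv.begin(), yd[0], yd[1], yd[2]);
    pairs[l].n_low = (l == 0) ? y0.n_rows : y[l - 1].n_rows;
  }

  arma::mat energy(record_energy ? n_steps + 1 : 0, N);

  std::vector<arma::cube> drive(N), td(N);
  for (int l = 0; l < N; ++l) {
    drive[l].set_size(arma::size(y[l]));
    td[l].set_size(arma::size(y[l]));
  }

  // per-pair work buffers, sized once
  std::vector<arma::mat> buf_low(N), buf_pred(N), buf_beta(N), buf_gb(N);
  for (int l = 0; l < N; ++l) {
    const int M = pairs[l].W.n_rows;
    buf_low[l].set_size(M, B);
    buf_pred[l].set_size(M, B);
    buf_beta[l].set_size(M, B);
    buf_gb[l].set_size(M, B);
  }

  for (int step = 0; step <= n_steps; ++step) {
    for (int l = 0; l < N; ++l) td[l].zeros();
    arma::rowvec e(N, arma::fill::zeros);

    for (int l = 0; l < N; ++l) {
      const arma::cube& low = (l == 0) ? y0 : y[l - 1];
      const Pair& pr = pairs[l];
      const int P = y[l].n_slices, n_low = pr.n_low;
      const int s2 = pr.idx.n_rows;
      arma::mat& ylow = buf_low[l];
      arma::mat& pred = buf_pred[l];
      arma::mat& beta = buf_beta[l];
      arma::mat& gb = buf_gb[l];
      for (int k = 0; k < P; ++k) {
        for (int q = 0; q < s2; ++q)
          ylow.rows(q * n_low, (q + 1) * n_low - 1) =
            low.slice(pr.idx(q, k) - 1);
        pred = pr.W.slice(k) * y[l].slice(k);
        // one pass: rectified prediction error, its gated copy, energy
        {
          const double* pp = pred.memptr();
          const double* lp = ylow.memptr();
          double* bp = beta.memptr();
          double* gp = gb.memptr();
          double esum = 0.0;
          const arma::uword n_el = pred.n_elem;
          for (arma::uword i = 0; i < n_el; ++i) {
            const double yh = pp[i] > 0.0 ? pp[i] : 0.0;
            const double b = lp[i] - yh;
            bp[i] = b;
            gp[i] = pp[i] > 0.0 ? b : 0.0;   // g = 1 iff prediction > 0
            esum += b * b;
          }
          if (record_energy) e(l) += esum;
        }
        drive[l].slice(k) = pr.W.slice(k).t() * gb;
        if (l >= 1)                          // top-down errors onto area l
          for (int q = 0; q < s2; ++q)
            td[l - 1].slice(pr.idx(q, k) - 1) +=
              beta.rows(q * n_low, (q + 1) * n_low - 1);
      }
    }
    if (record_energy) energy.row(step) = e;
    if (step == n_steps) break;

    for (int l = 0; l < N; ++l) {
      // Delta y = -gamma_y * (eta * sum(td errors) - sum(gated W'beta) + alpha_y)
      y[l] += gamma_y * (drive[l] - eta[l] * td[l] - alpha_y[l]);
      if (!y[l].is_finite())
        stop("non-finite activity in area %d at inference step %d",
             l + 1, step + 1);
      y[l].transform([](double v) { return v > 0.0 ? v : 0.0; });
    }
  }

  List out_y(N);
  for (int l = 0; l < N; ++l) out_y[l] = wrap(y[l]);
  return List::create(_["y"] = out_y, _["energy"] = wrap(energy));
}

// Gated Hebbian weight updates from a settled state, averaged over the batch:
// dW = gamma_w * (g(yhat) o beta) y' / B - gamma_w * alpha_w * sign(W).
// Returns the per-pair weight deltas.
// [[Rcpp::export]]
List learn_cpp(const arma::cube& y0, List weights, List rf_index, List y_state,
               double gamma_w, double alpha_w) {
  const int N = weights.size();
  const int B = y0.n_cols;
  List deltas(N);
  for (int l = 0; l < N; ++l) {
    arma::cube W = as<arma::cube>(weights[l]);
    arma::imat idx = as<arma::imat>(rf_index[l]);
    arma::cube yl = as<arma::cube>(y_state[l]);
    arma::cube low;
    if (l == 0) low = y0; else low = as<arma::cube>(y_state[l - 1]);
    const int n_low = low.n_rows, P = yl.n_slices;
    arma::cube dW(arma::size(W));
    for (int k = 0; k < P; ++k) {
      arma::mat ylow = gather_low(low, idx, k, n_low, B);
      arma::mat pred = W.slice(k) * yl.slice(k);
      arma::mat beta = ylow - arma::clamp(pred, 0.0, arma::datum::inf);
      arma::mat gb = beta;
      gb.elem(arma::find(pred <= 0.0)).zeros();
      dW.slice(k) = gamma_w * (gb * yl.slice(k).t() / B
                               - alpha_w * arma::sign(W.slice(k)));
      if (!dW.slice(k).is_finite())
        stop("non-finite weight update between areas %d and %d", l, l + 1);
    }
    deltas[l] = wrap(dW);
  }
  return deltas;
}
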