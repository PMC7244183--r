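#include <Rcpp.h>
using namespace Rcpp;

// Weighting f(x) = (x / x_max)^alpha capped at 1.
static inline double glove_f(double x, double x_max, double alpha) {
  return (x < x_max) ? std::pow(x / x_max, alpha) : 1.0;
}

// AdaGrad stochastic trainer for the weighted least-squares co-occurrence
// objective. Pairs are supplied as the upper triangle (i < j, 0-based) of a
// symmetric count matrix; each unordered pair is visited in both directions
// per epoch, in an order reshuffled each epoch with R's RNG (so results are
// reproducible under set.seed()). Parameter matrices are updated in place on
// copies made in R. loss_history[e] is the full objective after epoch e,
// summed over ordered pairs.
// [[Rcpp::export(name = ".glove_train_cpp")]]
List glove_train_cpp(IntegerVector pi, IntegerVector pj, NumericVector px,
                     NumericMatrix w, NumericMatrix wt,
                     NumericVector b, NumericVector bt,
                     double x_max, double alpha, double eta, int n_epochs) {
  const int np = pi.size();
  const int dim = w.ncol();
  const int ndir = 2 * np;

  std::vector<double> fx(np), logx(np);
  for (int p = 0; p < np; ++p) {
    fx[p] = glove_f(px[p], x_max, alpha);
    logx[p] = std::log(px[p]);
  }

  // AdaGrad accumulators, initialized to 1 (canonical choice: first steps
  // are plain SGD steps of size eta).
  NumericMatrix gw(w.nrow(), dim), gwt(w.nrow(), dim);
  NumericVector gb(b.size(), 1.0), gbt(b.size(), 1.0);
  std::fill(gw.begin(), gw.end(), 1.0);
  std::fill(gwt.begin(), gwt.end(), 1.0);

  std::vector<int> order(ndir);
  for (int k = 0; k < ndir; ++k) order[k] = k;

  NumericVector loss_history(n_epochs);
  int diverged_epoch = 0;

  GetRNGstate();
  for (int epoch = 0; epoch < n_epochs; ++epoch) {
    // Fisher-Yates shuffle driven by R's RNG.
    for (int k = ndir - 1; k > 0; --k) {
      int r = (int)(unif_rand() * (k + 1));
      if (r > k) r = k;
      std::swap(order[k], order[r]);
    }
    for (int k = 0; k < ndir; ++k) {
      const int idx = order[k];
      const int p = idx % np;
      const bool flip = idx >= np;      // direction: main <-> context
      const int a = flip ? pj[p] : pi[p];
      const int c = flip ? pi[p] : pj[p];

      double diff = b[a] + bt[c] - logx[p];
      for (int d = 0; d < dim; ++d) diff += w(a, d) * wt(c, d);
      const double fdiff = fx[p] * diff;

      for (int d = 0; d < dim; ++d) {
        const double ga = fdiff * wt(c, d);
        const double gc = fdiff * w(a, d);
        w(a, d) -= eta * ga / std::sqrt(gw(a, d));
        wt(c, d) -= eta * gc / std::sqrt(gwt(c, d));
        gw(a, d) += ga * ga;
        gwt(c, d) += gc * gc;
      }
      b[a] -= eta * fdiff / std::sqrt(gb[a]);
      bt[c] -= eta * fdiff / std::sqrt(gbt[c]);
      gb[a] += fdiff * fdiff;
      gbt[c] += fdiff * fdiff;
    }
    // Full objective over ordered pairs at the end of the epoch.
    double loss = 0.0;
    for (int p = 0; p < np; ++p) {
      for (int dir = 0; dir < 2; ++dir) {
        const int a = dir ? pj[p] : pi[p];
        const int c = dir ? pi[p] : pj[p];
        double diff = b[a] + bt[c] - logx[p];
        for (int d = 0; d < dim; ++d) diff += w(a, d) * wt(c, d);
        loss += fx[p] * diff * diff;
      }
    }
    loss_history[epoch] = loss;
    if (!std::isfinite(loss)) { diverged_epoch = epoch + 1; break; }
  }
  PutRNGstate();

  return List::create(_["w"] = w, _["w_tilde"] = wt, _["b"] = b, _["b_tilde"] = bt,
                      _["loss_history"] = loss_history,
                      _["diverged_epoch"] = diverged_epoch);
}
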