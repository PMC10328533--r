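#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static double sum_abs(const std::vector<double>& v) {
  double s = 0.0;
  for (double x : v) s += std::fabs(x);
  return s;
}

// Coordinate-wise boosting with L1 loss on a basis-response matrix.
// Ztrain / Zval: basis responses restricted to the training and
// validation samples (columns = (feature, lag-center) coordinates).
// At each step the single +/- delta coordinate update that most
// reduces the training L1 error is applied. With selective stopping
// (the default), an applied update that increases the validation
// error is undone and its coordinate frozen, so coordinates that only
// fit noise are retired early. When no unfrozen coordinate update of
// size delta reduces the training error, delta is halved, all
// coordinates are unfrozen, and the search repeats, down to
// delta / 2^anneal_halvings. Fitting stops at that floor, when every
// coordinate is frozen at the final step size, or when the validation
// error has not reached a new minimum for `patience` steps. The
// coefficients at the validation minimum are returned.
// [[Rcpp::export]]
List boost_fit_cpp(const NumericMatrix& Ztrain, const NumericMatrix& Zval,
                   const NumericVector& ytrain, const NumericVector& yval,
                   double delta, int patience, int max_steps,
                   int anneal_halvings, bool selective_stopping) {
  const int nt = Ztrain.nrow(), nv = Zval.nrow(), P = Ztrain.ncol();
  std::vector<double> rt(ytrain.begin(), ytrain.end());
  std::vector<double> rv(yval.begin(), yval.end());
  std::vector<double> gamma(P, 0.0), gamma_best(P, 0.0);
  std::vector<bool> frozen(P, false);
  double train_err = sum_abs(rt);
  double val_err = sum_abs(rv);
  double best_val = val_err;
  std::vector<double> train_curve, val_curve;
  int wait = 0, best_step = 0, step = 0, halvings = 0;
  const double tol = 1e-12 * (train_err > 0 ? train_err : 1.0);

  for (step = 0; step < max_steps; ++step) {
    double best = train_err - tol;
    int bp = -1;
    double bsign = 0.0, berr = 0.0;
    for (int p = 0; p < P; ++p) {
      if (frozen[p]) continue;
      const double* z = &Ztrain(0, p);
      double ep = 0.0, em = 0.0;
      for (int i = 0; i < nt; ++i) {
        const double d = delta * z[i];
        ep += std::fabs(rt[i] - d);
        em += std::fabs(rt[i] + d);
      }
      if (ep < best) { best = ep; bp = p; bsign = 1.0; berr = ep; }
      if (em < best) { best = em; bp = p; bsign = -1.0; berr = em; }
    }
    if (bp < 0) {  // resolution floor (or all frozen) at this step size
      if (halvings >= anneal_halvings) break;
      delta *= 0.5;
      ++halvings;
      std::fill(frozen.begin(), frozen.end(), false);
      --step;
      continue;
    }
    {
      const double* z = &Ztrain(0, bp);
      for (int i = 0; i < nt; ++i) rt[i] -= bsign * delta * z[i];
    }
    {
      const double* z = &Zval(0, bp);
      for (int i = 0; i < nv; ++i) rv[i] -= bsign * delta * z[i];
    }
    const double new_val = sum_abs(rv);
    if (selective_stopping && new_val > val_err + tol) {
      // undo: the update fits training noise, not signal
      const double* zt = &Ztrain(0, bp);
      for (int i = 0; i < nt; ++i) rt[i] += bsign * delta * zt[i];
      const double* zv = &Zval(0, bp);
      for (int i = 0; i < nv; ++i) rv[i] += bsign * delta * zv[i];
      frozen[bp] = true;
      --step;
      continue;
    }
    gamma[bp] += bsign * delta;
    train_err = berr;
    val_err = new_val;
    train_curve.push_back(train_err);
    val_curve.push_back(val_err);
    if (val_err < best_val - tol) {
      best_val = val_err;
      gamma_best = gamma;
      best_step = (int)train_curve.size();
      wait = 0;
    } else {
      if (++wait >= patience) { ++step; break; }
    }
  }
  return List::create(
      _["gamma"] = NumericVector(gamma_best.begin(), gamma_best.end()),
      _["train_curve"] = NumericVector(train_curve.begin(), train_curve.end()),
      _["val_curve"] = NumericVector(val_curve.begin(), val_curve.end()),
      _["n_steps"] = (int)train_curve.size(),
      _["best_step"] = best_step,
      _["best_val_error"] = best_val);
}
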