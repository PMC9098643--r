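// Sparse sampling-operator kernels and the augmented-Lagrangian /
// Barzilai-Borwein inner loop of the low-rank distance-completion solver.
// The pair sets are passed as 0-based index vectors; dense omega matrices
// are never materialized.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// f_i = ||P[a_i,] - P[b_i,]||^2 : the squared distance implied by the Gram
// matrix P P^T for pair (a_i, b_i).
// [[Rcpp::export]]
arma::vec cpp_pair_sqdist(const arma::mat& P, const arma::uvec& a,
                          const arma::uvec& b) {
  const arma::uword m = a.n_elem;
  arma::vec out(m);
  const double* x = P.colptr(0);
  const double* y = P.colptr(1);
  const double* z = P.colptr(2);
  for (arma::uword k = 0; k < m; ++k) {
    const arma::uword p = a(k), q = b(k);
    const double dx = x[p] - x[q], dy = y[p] - y[q], dz = z[p] - z[q];
    out(k) = dx * dx + dy * dy + dz * dz;
  }
  return out;
}

// Accumulate (A*(y)) P without forming A*(y): row a_i gains y_i (p_a - p_b),
// row b_i gains y_i (p_b - p_a).
// [[Rcpp::export]]
arma::mat cpp_adjoint_times_P(const arma::mat& P, const arma::uvec& a,
                              const arma::uvec& b, const arma::vec& y) {
  arma::mat out(P.n_rows, P.n_cols, arma::fill::zeros);
  const arma::uword m = a.n_elem;
  for (arma::uword c = 0; c < P.n_cols; ++c) {
    const double* pc = P.colptr(c);
    double* oc = out.colptr(c);
    for (arma::uword k = 0; k < m; ++k) {
      const arma::uword p = a(k), q = b(k);
      const double d = y(k) * (pc[p] - pc[q]);
      oc[p] += d;
      oc[q] -= d;
    }
  }
  return out;
}

// Dense A*(y) (used by the R-level operator surface and tests; small n).
// [[Rcpp::export]]
arma::mat cpp_adjoint_dense(int n, const arma::uvec& a, const arma::uvec& b,
                            const arma::vec& y) {
  arma::mat out(n, n, arma::fill::zeros);
  for (arma::uword k = 0; k < a.n_elem; ++k) {
    out(a(k), a(k)) += y(k);
    out(b(k), b(k)) += y(k);
    out(a(k), b(k)) -= y(k);
    out(b(k), a(k)) -= y(k);
  }
  return out;
}

namespace {

struct Problem {
  const arma::uvec& oa; const arma::uvec& ob; const arma::vec& bvals;
  const arma::uvec& ba; const arma::uvec& bb;       // sub-diagonal pairs
  double lambda; double r; double d_t;
  // optional integrative penalty gamma * ||A_E(X) - evals||^2
  const arma::uvec& ea; const arma::uvec& eb; const arma::vec& evals;
  double gamma;
};

double lagrangian(const arma::mat& P, const Problem& pb,
                  const arma::vec& Lambda) {
  double tr = arma::accu(arma::square(P));
  arma::vec g = cpp_pair_sqdist(P, pb.ba, pb.bb) - pb.d_t;
  arma::vec f = cpp_pair_sqdist(P, pb.oa, pb.ob) - pb.bvals + Lambda;
  double val = tr + 0.5 * pb.lambda * arma::dot(g, g)
                  + 0.5 * pb.r * arma::dot(f, f);
  if (pb.gamma > 0 && pb.ea.n_elem > 0) {
    arma::vec h = cpp_pair_sqdist(P, pb.ea, pb.eb) - pb.evals;
    val += pb.gamma * arma::dot(h, h);
  }
  return val;
}

arma::mat lagrangian_grad(const arma::mat& P, const Problem& pb,
                          const arma::vec& Lambda) {
  arma::vec g = cpp_pair_sqdist(P, pb.ba, pb.bb) - pb.d_t;
  arma::vec f = cpp_pair_sqdist(P, pb.oa, pb.ob) - pb.bvals + Lambda;
  arma::mat G = 2.0 * P
    + 2.0 * pb.lambda * cpp_adjoint_times_P(P, pb.ba, pb.bb, g)
    + 2.0 * pb.r * cpp_adjoint_times_P(P, pb.oa, pb.ob, f);
  if (pb.gamma > 0 && pb.ea.n_elem > 0) {
    arma::vec h = cpp_pair_sqdist(P, pb.ea, pb.eb) - pb.evals;
    G += 4.0 * pb.gamma * cpp_adjoint_times_P(P, pb.ea, pb.eb, h);
  }
  return G;
}

} // namespace

// [[Rcpp::export]]
double cpp_lagrangian_value(const arma::mat& P, const arma::uvec& oa,
                            const arma::uvec& ob, const arma::vec& bvals,
                            const arma::vec& Lambda, double lambda, double r,
                            double d_t) {
  int n = P.n_rows;
  arma::uvec ba = arma::regspace<arma::uvec>(0, n - 2);
  arma::uvec bb = ba + 1;
  arma::uvec e0; arma::vec ev0;
  Problem pb{oa, ob, bvals, ba, bb, lambda, r, d_t, e0, e0, ev0, 0.0};
  return lagrangian(P, pb, Lambda);
}

// [[Rcpp::export]]
arma::mat cpp_lagrangian_grad_r(const arma::mat& P, const arma::uvec& oa,
                                const arma::uvec& ob, const arma::vec& bvals,
                                const arma::vec& Lambda, double lambda,
                                double r, double d_t) {
  int n = P.n_rows;
  arma::uvec ba = arma::regspace<arma::uvec>(0, n - 2);
  arma::uvec bb = ba + 1;
  arma::uvec e0; arma::vec ev0;
  Problem pb{oa, ob, bvals, ba, bb, lambda, r, d_t, e0, e0, ev0, 0.0};
  return lagrangian_grad(P, pb, Lambda);
}

// Full alternating scheme: inner monotone-safeguarded Barzilai-Borwein
// descent on P with the multiplier fixed, then Lambda <- Lambda + (A(PP^T)-b),
// until the mean relative error between reconstructed and observed distances
// on the measured set drops below tol or max_outer is reached.
// [[Rcpp::export]]
List cpp_alm_solve(const arma::mat& P0, const arma::uvec& oa,
                   const arma::uvec& ob, const arma::vec& bvals,
                   double lambda, double r, double d_t, double tol,
                   int max_outer, int max_inner,
                   const arma::uvec& ea, const arma::uvec& eb,
                   const arma::vec& evals, double gamma,
                   int stall_window, double stall_rel) {
  int n = P0.n_rows;
  arma::uvec ba = arma::regspace<arma::uvec>(0, n - 2);
  arma::uvec bb = ba + 1;
  Problem pb{oa, ob, bvals, ba, bb, lambda, r, d_t, ea, eb, evals, gamma};

  arma::mat P = P0;
  arma::vec Lambda(oa.n_elem, arma::fill::zeros);
  arma::vec sqrt_b = arma::sqrt(bvals);

  std::vector<double> hist_obj, hist_err;
  std::vector<int> hist_outer;
  std::vector<double> outer_err;
  bool diverged = false;
  double err = arma::datum::inf;
  int outer = 0;

  const double c1 = 1e-4;
  // Stagnation stop: with noisy, over-determined measurements the error
  // plateaus above tol, and further multiplier updates interpolate the
  // noise (semi-convergence). Stop once the plateau is reached. The check
  // only engages after the warm-up phase (error halved from its initial
  // value) because the first multiplier updates are non-monotone.
  double best_err = arma::datum::inf;
  int best_outer = 0;
  double init_err = arma::datum::inf;
  bool stall_armed = false;

  for (outer = 1; outer <= max_outer; ++outer) {
    double fcur = lagrangian(P, pb, Lambda);
    arma::mat G = lagrangian_grad(P, pb, Lambda);
    arma::mat s_prev, y_prev;
    bool have_prev = false;
    double gn2 = arma::accu(arma::square(G));

    for (int it = 0; it < max_inner; ++it) {
      if (!std::isfinite(fcur)) { diverged = true; break; }
      double gnorm = std::sqrt(gn2);
      if (gnorm < 1e-12 * std::max(1.0, arma::norm(P, "fro"))) break;

      double t;
      if (!have_prev) {
        t = 1.0 / std::max(gnorm, 1e-12);
      } else {
        double ss = arma::accu(arma::square(s_prev));
        double sy = arma::accu(s_prev % y_prev);
        double yy = arma::accu(arma::square(y_prev));
        if (sy <= 1e-16) {
          t = 1.0 / std::max(gnorm, 1e-12);
        } else if (it % 2 == 0) {
          t = ss / sy;            // BB1
        } else {
          t = sy / std::max(yy, 1e-16);  // BB2
        }
        t = std::min(std::max(t, 1e-12), 1e12);
      }

      // monotone Armijo backtracking so accepted steps never increase L
      arma::mat Pnew;
      double fnew = arma::datum::inf;
      bool accepted = false;
      for (int bt = 0; bt < 40; ++bt) {
        Pnew = P - t * G;
        fnew = lagrangian(Pnew, pb, Lambda);
        if (std::isfinite(fnew) && fnew <= fcur - c1 * t * gn2) {
          accepted = true;
          break;
        }
        t *= 0.5;
      }
      if (!accepted) break;

      arma::mat Gnew = lagrangian_grad(Pnew, pb, Lambda);
      s_prev = Pnew - P;
      y_prev = Gnew - G;
      have_prev = true;
      P = Pnew;
      G = Gnew;
      gn2 = arma::accu(arma::square(G));
      fcur = fnew;
      hist_obj.push_back(fcur);
      hist_outer.push_back(outer);
    }
    if (diverged) break;

    arma::vec f = cpp_pair_sqdist(P, oa, ob);
    arma::vec resid = f - bvals;
    err = arma::mean(arma::abs(arma::sqrt(arma::clamp(f, 0.0,
                       arma::datum::inf)) - sqrt_b) / sqrt_b);
    outer_err.push_back(err);
    if (err < tol) break;
    if (outer == 1) init_err = err;
    if (!stall_armed && err < 0.5 * init_err) {
      stall_armed = true;
      best_err = err;
      best_outer = outer;
    } else if (stall_armed) {
      if (err < best_err * (1.0 - stall_rel)) {
        best_err = err;
        best_outer = outer;
      } else if (stall_window > 0 && outer - best_outer >= stall_window) {
        break;
      }
    }
    Lambda += resid;
    if (!Lambda.is_finite()) { diverged = true; break; }
  }

  // center the coordinates
  arma::rowvec ctr = arma::mean(P, 0);
  P.each_row() -= ctr;

  return List::create(
    _["P"] = P, _["Lambda"] = Lambda,
    _["iterations"] = std::min(outer, max_outer),
    _["measured_error"] = err, _["diverged"] = diverged,
    _["inner_objective"] = hist_obj, _["inner_outer_index"] = hist_outer,
    _["outer_error"] = outer_err);
}
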