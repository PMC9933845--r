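// Felsenstein-pruning kernels: two-directional conditional likelihoods with
// per-site/per-category log scaling, and O(sites) per-edge attachment
// scoring with coordinate-ascent geometry optimization.
//
// Layout: per-node partials are 4 x (S * k) matrices (states x site
// patterns, Gamma categories in consecutive column blocks). The inner
// loops are hand-fused over columns -- one 4x4 transition matrix-vector
// product per factor, no intermediate matrices -- because on one core the
// work is memory-bound, not flop-bound.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double SCALE_THRESHOLD = 1e-100;

// P(t) = A diag(exp(lambda * t)) B for the reversible eigendecomposition.
static arma::mat pmat(const arma::mat& A, const arma::mat& B,
                      const arma::vec& lambda, double t) {
  return A * arma::diagmat(arma::exp(lambda * t)) * B;
}

// y_a = max(0, sum_b P_ab x_b); negative round-off of the composite
// eigen-transform is clipped so partials stay non-negative.
static inline void mv4_clip(const double* P, const double* x, double* y) {
  for (int a = 0; a < 4; ++a) {
    double t = P[a] * x[0] + P[a + 4] * x[1] + P[a + 8] * x[2] +
               P[a + 12] * x[3];
    y[a] = t < 0.0 ? 0.0 : t;
  }
}

// acc_j *= P * child_j over ncol 4-row columns.
static void mult_transformed(const arma::mat& P, const double* child,
                             double* acc, arma::uword ncol) {
  const double* M = P.memptr();
  double y[4];
  for (arma::uword j = 0; j < ncol; ++j) {
    const double* x = child + 4 * j;
    double* a = acc + 4 * j;
    mv4_clip(M, x, y);
    a[0] *= y[0]; a[1] *= y[1]; a[2] *= y[2]; a[3] *= y[3];
  }
}

// Rescale a 4 x (S*k) partial in place; adds log factors into ls (S x k).
static void rescale(arma::mat& M, arma::mat& ls, arma::uword S) {
  const arma::uword k = ls.n_cols;
  for (arma::uword c = 0; c < k; ++c) {
    for (arma::uword s = 0; s < S; ++s) {
      arma::uword j = c * S + s;
      double m = M.col(j).max();
      if (m > 0.0 && m < SCALE_THRESHOLD) {
        M.col(j) /= m;
        ls(s, c) += std::log(m);
      }
    }
  }
}

// Per-site log-likelihood from a 1 x (S*k) likelihood row and S x k log
// scalers: logsumexp over categories minus log k.
static arma::vec site_loglik_from(const arma::rowvec& s_flat,
                                  const arma::mat& ls, arma::uword S) {
  const arma::uword k = ls.n_cols;
  const double logk = std::log((double)k);
  arma::mat percat(S, k);
  for (arma::uword c = 0; c < k; ++c) {
    percat.col(c) = arma::log(s_flat.cols(c * S, c * S + S - 1).t()) +
      ls.col(c);
  }
  arma::vec out(S);
  for (arma::uword s = 0; s < S; ++s) {
    double m = percat.row(s).max();
    out(s) = std::isfinite(m)
      ? m + std::log(arma::accu(arma::exp(percat.row(s) - m))) - logk
      : -std::numeric_limits<double>::infinity();
  }
  return out;
}

struct Partials {
  std::vector<arma::mat> down, up;
  std::vector<arma::mat> dls, uls;
  arma::vec site_ll;
};

static void compute_partials_impl(const IntegerVector& postorder,
                                  const IntegerVector& parent,
                                  const NumericVector& blen,
                                  const arma::cube& tipL, int ntip,
                                  const arma::mat& A, const arma::mat& B,
                                  const arma::vec& lambda,
                                  const arma::vec& pi,
                                  const arma::vec& rates,
                                  bool want_up, Partials& out) {
  const int n_all = parent.size();
  const arma::uword S = tipL.n_cols;
  const arma::uword k = rates.n_elem;
  const int root = postorder[postorder.size() - 1];

  out.down.assign(n_all, arma::mat());
  out.dls.assign(n_all, arma::mat());
  std::vector<std::vector<int>> kids(n_all + 1);
  for (int v = 1; v <= n_all; ++v)
    if (parent[v - 1] > 0) kids[parent[v - 1]].push_back(v);

  for (int i = 0; i < postorder.size(); ++i) {
    int v = postorder[i];
    if (v <= ntip) {
      arma::mat flat(4, S * k);
      for (arma::uword c = 0; c < k; ++c)
        flat.cols(c * S, c * S + S - 1) = tipL.slice(v - 1);
      out.down[v - 1] = std::move(flat);
      out.dls[v - 1] = arma::mat(S, k, arma::fill::zeros);
    } else {
      arma::mat acc(4, S * k, arma::fill::ones);
      arma::mat ls(S, k, arma::fill::zeros);
      for (int ch : kids[v]) {
        for (arma::uword c = 0; c < k; ++c) {
          arma::mat P = pmat(A, B, lambda, blen[ch - 1] * rates(c));
          mult_transformed(P, out.down[ch - 1].colptr(c * S),
                           acc.colptr(c * S), S);
        }
        ls += out.dls[ch - 1];
      }
      rescale(acc, ls, S);
      out.down[v - 1] = std::move(acc);
      out.dls[v - 1] = std::move(ls);
    }
  }

  out.site_ll = site_loglik_from(pi.t() * out.down[root - 1],
                                 out.dls[root - 1], S);

  if (want_up) {
    out.up.assign(n_all, arma::mat());
    out.uls.assign(n_all, arma::mat());
    for (int i = postorder.size() - 1; i >= 0; --i) {
      int v = postorder[i];
      if (v == root) continue;
      int p = parent[v - 1];
      arma::mat acc(4, S * k, arma::fill::ones);
      arma::mat ls(S, k, arma::fill::zeros);
      for (int sib : kids[p]) {
        if (sib == v) continue;
        for (arma::uword c = 0; c < k; ++c) {
          arma::mat P = pmat(A, B, lambda, blen[sib - 1] * rates(c));
          mult_transformed(P, out.down[sib - 1].colptr(c * S),
                           acc.colptr(c * S), S);
        }
        ls += out.dls[sib - 1];
      }
      if (p != root) {
        for (arma::uword c = 0; c < k; ++c) {
          arma::mat P = pmat(A, B, lambda, blen[p - 1] * rates(c));
          mult_transformed(P, out.up[p - 1].colptr(c * S),
                           acc.colptr(c * S), S);
        }
        ls += out.uls[p - 1];
      }
      rescale(acc, ls, S);
      out.up[v - 1] = std::move(acc);
      out.uls[v - 1] = std::move(ls);
    }
  }
}

// Conditional likelihoods for every node of a rooted tree; see the R-side
// compute_edge_partials() for the contract. Partials are 4 x (S*k)
// matrices with categories in consecutive column blocks.
// [[Rcpp::export]]
List cpp_partials(IntegerVector postorder, IntegerVector parent,
                  NumericVector blen, const arma::cube& tipL, int ntip,
                  const arma::mat& A, const arma::mat& B,
                  const arma::vec& lambda, const arma::vec& pi,
                  const arma::vec& rates, bool want_up) {
  Partials px;
  compute_partials_impl(postorder, parent, blen, tipL, ntip, A, B, lambda,
                        pi, rates, want_up, px);
  const int n_all = parent.size();
  List down_out(n_all), dls_out(n_all), up_out(n_all), uls_out(n_all);
  for (int v = 0; v < n_all; ++v) {
    down_out[v] = px.down[v];
    dls_out[v] = px.dls[v];
    if (want_up && px.up[v].n_elem > 0) {
      up_out[v] = px.up[v];
      uls_out[v] = px.uls[v];
    }
  }
  return List::create(_["down"] = down_out, _["down_ls"] = dls_out,
                      _["up"] = up_out, _["up_ls"] = uls_out,
                      _["site_loglik"] = px.site_ll);
}

// Total + per-pattern log-likelihood only (no partials exported); the fast
// path for repeated model-parameter evaluations.
// [[Rcpp::export]]
List cpp_tree_loglik(IntegerVector postorder, IntegerVector parent,
                     NumericVector blen, const arma::cube& tipL, int ntip,
                     const arma::mat& A, const arma::mat& B,
                     const arma::vec& lambda, const arma::vec& pi,
                     const arma::vec& rates, const arma::vec& wt) {
  Partials px;
  compute_partials_impl(postorder, parent, blen, tipL, ntip, A, B, lambda,
                        pi, rates, false, px);
  return List::create(_["site_loglik"] = px.site_ll,
                      _["loglik"] = arma::dot(px.site_ll, wt));
}

// Evaluation state for one edge: everything fixed except the attachment
// geometry (tx = distance to the child end, tu to the parent end, tp the
// pendant branch).
struct EdgeEval {
  const arma::mat& A; const arma::mat& B;
  const arma::vec& lambda; const arma::vec& pi; const arma::vec& rates;
  const arma::mat& D; const arma::mat& Dls;
  const arma::mat& U; const arma::mat& Uls;
  const arma::mat& Qtip; const arma::vec& wt;
  bool use_query, no_scale;
  arma::uword S, k;
  arma::vec acc;       // per-site category-summed likelihood (no_scale)
  arma::rowvec s_flat; // per (site, category) likelihood (scaled path)
  long evals = 0;

  EdgeEval(const arma::mat& A_, const arma::mat& B_, const arma::vec& l_,
           const arma::vec& pi_, const arma::vec& r_, const arma::mat& D_,
           const arma::mat& Dls_, const arma::mat& U_,
           const arma::mat& Uls_, const arma::mat& Q_, const arma::vec& w_,
           bool uq)
    : A(A_), B(B_), lambda(l_), pi(pi_), rates(r_), D(D_), Dls(Dls_),
      U(U_), Uls(Uls_), Qtip(Q_), wt(w_), use_query(uq) {
    k = rates.n_elem;
    S = D.n_cols / k;
    no_scale = arma::all(arma::vectorise(Dls) == 0.0) &&
               arma::all(arma::vectorise(Uls) == 0.0);
    if (no_scale) acc.set_size(S); else s_flat.set_size(S * k);
  }

  double operator()(double tx, double tu, double tp) {
    ++evals;
    const double* piv = pi.memptr();
    if (no_scale) acc.zeros();
    for (arma::uword c = 0; c < k; ++c) {
      double r = rates(c);
      arma::mat P1 = pmat(A, B, lambda, tx * r);
      arma::mat P2 = pmat(A, B, lambda, tu * r);
      arma::mat P3;
      if (use_query) P3 = pmat(A, B, lambda, tp * r);
      const double* dp = D.colptr(c * S);
      const double* up = U.colptr(c * S);
      const double* qp = use_query ? Qtip.memptr() : nullptr;
      double y1[4], y2[4], y3[4];
      for (arma::uword j = 0; j < S; ++j) {
        mv4_clip(P1.memptr(), dp + 4 * j, y1);
        mv4_clip(P2.memptr(), up + 4 * j, y2);
        double sj;
        if (use_query) {
          mv4_clip(P3.memptr(), qp + 4 * j, y3);
          sj = piv[0] * y1[0] * y2[0] * y3[0] +
               piv[1] * y1[1] * y2[1] * y3[1] +
               piv[2] * y1[2] * y2[2] * y3[2] +
               piv[3] * y1[3] * y2[3] * y3[3];
        } else {
          sj = piv[0] * y1[0] * y2[0] + piv[1] * y1[1] * y2[1] +
               piv[2] * y1[2] * y2[2] + piv[3] * y1[3] * y2[3];
        }
        if (no_scale) acc(j) += sj; else s_flat(c * S + j) = sj;
      }
    }
    if (no_scale) {
      double total = 0.0;
      for (arma::uword j = 0; j < S; ++j) {
        if (acc(j) <= 0.0)
          return -std::numeric_limits<double>::infinity();
        total += wt(j) * std::log(acc(j) / (double)k);
      }
      return total;
    }
    arma::vec site_ll = site_loglik_from(s_flat, Dls + Uls, S);
    if (!site_ll.is_finite())
      return -std::numeric_limits<double>::infinity();
    return arma::dot(site_ll, wt);
  }
};

// Brent's method (parabolic interpolation + golden section) maximizing f
// on [lo, hi] to absolute tolerance xtol.
template <typename F>
static double brent_max(F&& f, double lo, double hi, double xtol,
                        double* fbest) {
  const double gr = 0.3819660112501051;
  double a = lo, b = hi;
  double x = a + gr * (b - a), w = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int iter = 0; iter < 100; ++iter) {
    double m = 0.5 * (a + b);
    double tol1 = xtol * 0.5 + 1e-12 * std::fabs(x);
    if (std::fabs(x - m) <= 2.0 * tol1 - 0.5 * (b - a)) break;
    double use_golden = true;
    if (std::fabs(e) > tol1) {
      double rr = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * rr;
      q = 2.0 * (q - rr);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etemp = e; e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etemp) && p > q * (a - x) &&
          p < q * (b - x)) {
        d = p / q;
        double u = x + d;
        if (u - a < 2.0 * tol1 || b - u < 2.0 * tol1)
          d = (m > x) ? tol1 : -tol1;
        use_golden = false;
      }
    }
    if (use_golden) {
      e = (x < m) ? b - x : a - x;
      d = gr * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d
                                      : x + ((d > 0) ? tol1 : -tol1);
    double fu = f(u);
    if (fu >= fx) {
      if (u < x) b = x; else a = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu >= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
      else if (fu >= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  *fbest = fx;
  return x;
}

// Coordinate ascent over the attachment geometry on one edge, from cached
// directional partials. With split_edge, x is the distal offset in
// [xlo, xhi] = [0, b] and the parent-side length is b - x (query
// placement); without it, x is the full edge length searched in [xlo, xhi]
// (branch-length optimization). p is the pendant length in [plo, phi].
// Returns c(x, p, loglik, n_evaluations). Updates are only accepted when
// they improve the score, so the returned log-likelihood is >= the score
// at the initial geometry.
// [[Rcpp::export]]
NumericVector cpp_optimize_attachment(const arma::mat& A, const arma::mat& B,
                                      const arma::vec& lambda,
                                      const arma::vec& pi,
                                      const arma::vec& rates,
                                      const arma::mat& D,
                                      const arma::mat& Dls,
                                      const arma::mat& U,
                                      const arma::mat& Uls,
                                      const arma::mat& Qtip,
                                      const arma::vec& wt,
                                      double b, double xlo, double xhi,
                                      double x0, double p0,
                                      double plo, double phi,
                                      bool use_query, bool split_edge,
                                      bool opt_x, bool opt_p,
                                      int max_rounds, double tol,
                                      double xtol, double ptol,
                                      double stop_below) {
  EdgeEval ev(A, B, lambda, pi, rates, D, Dls, U, Uls, Qtip, wt, use_query);
  auto tu = [&](double x) { return split_edge ? b - x : 0.0; };
  double x = x0, p = p0;
  double score = ev(x, tu(x), p);
  for (int round = 0; round < max_rounds; ++round) {
    // edges hopelessly far below the running best cannot influence either
    // the argmax or the softmax (guarded at best - 50); stop refining them
    if (round > 0 && score < stop_below) break;
    double prev = score;
    if (opt_x && xhi - xlo > 1e-12) {
      auto fx = [&](double z) { return ev(z, tu(z), p); };
      double lo = xlo, hi = xhi;
      if (round == 0 && split_edge) {
        // the distal profile can be bimodal (the attachment may prefer
        // either end of the edge); bracket the best of a coarse scan
        // before the unimodal search
        const int mpts = 6;
        double step = (xhi - xlo) / mpts;
        double bestv = -std::numeric_limits<double>::infinity();
        int besti = 0;
        for (int i = 0; i < mpts; ++i) {
          double xi = xlo + (i + 0.5) * step;
          double v = fx(xi);
          if (v > bestv) { bestv = v; besti = i; }
        }
        lo = std::max(xlo, xlo + (besti - 0.5) * step);
        hi = std::min(xhi, xlo + (besti + 1.5) * step);
      }
      double fb;
      double xc = brent_max(fx, lo, hi, xtol, &fb);
      if (fb > score) { x = xc; score = fb; }
    }
    if (opt_p) {
      double fb;
      double pc = brent_max([&](double z) { return ev(x, tu(x), z); },
                            plo, phi, ptol, &fb);
      if (fb > score) { p = pc; score = fb; }
    }
    if (score - prev < tol) break;
  }
  return NumericVector::create(x, p, score, (double)ev.evals);
}

// Single attachment evaluation (exported for attachment_loglikelihood()).
// [[Rcpp::export]]
double cpp_attach_loglik(const arma::mat& A, const arma::mat& B,
                         const arma::vec& lambda, const arma::vec& pi,
                         const arma::vec& rates, const arma::mat& D,
                         const arma::mat& Dls, const arma::mat& U,
                         const arma::mat& Uls, const arma::mat& Qtip,
                         const arma::vec& wt, double tx, double tu,
                         double tp, bool use_query) {
  EdgeEval ev(A, B, lambda, pi, rates, D, Dls, U, Uls, Qtip, wt, use_query);
  return ev(tx, tu, tp);
}
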