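// Profiled restricted-maximum-likelihood solver for the single
// random-intercept linear mixed model
//   y = X beta + Z u + e,  u ~ N(0, s2_b I_G),  e ~ N(0, s2 I_n),
// with Z the dataset indicator matrix. With lambda = s2_b / s2 the
// covariance V = I + lambda Z Z' is block diagonal, so for fixed lambda
// the GLS quantities reduce to group-sum corrections of the ordinary
// crossproducts:
//   X'V^-1X = X'X - sum_g c_g s_g s_g',  c_g = lambda / (1 + lambda n_g),
// and analogously for X'V^-1y and y'V^-1y. The REML criterion
//   (n-p) log s2hat + sum_g log(1 + lambda n_g) + log det(X'V^-1X)
// is minimized over log(lambda) by a grid scan plus golden-section
// refinement. Only the crossproducts depend on the data, so one fit costs
// O(n p) plus O(G p^2 + p^3) per criterion evaluation, which is what makes
// 10,000-permutation refits per test affordable.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Xside {
  mat XtX;   // p x p
  mat Sx;    // G x p group sums of X rows
};

struct RemlFit {
  double lambda = 0.0, sigma2 = 0.0;
  vec beta, se;
  bool ok = false;
};

// criterion for one lambda; outputs beta/sigma2 when requested
static double reml_crit(double lam, const Xside& xs, const vec& Xty,
                        double yty, const vec& Sy, const vec& ng,
                        int n, int p, vec* beta_out, double* sigma2_out,
                        mat* A_out) {
  vec cg = lam / (1.0 + lam * ng);
  mat Sxc = xs.Sx;
  Sxc.each_col() %= cg;
  mat A = xs.XtX - xs.Sx.t() * Sxc;
  vec b = Xty - xs.Sx.t() * (cg % Sy);
  double yq = yty - dot(cg, Sy % Sy);
  mat R;
  if (!chol(R, A)) return datum::inf;
  vec beta = solve(trimatu(R), solve(trimatl(R.t()), b));
  double rss = yq - dot(b, beta);
  if (rss < 1e-300) rss = 1e-300;
  double sigma2 = rss / (n - p);
  double logdetA = 2.0 * accu(log(R.diag()));
  double crit = (n - p) * std::log(sigma2) + accu(log(1.0 + lam * ng)) +
                logdetA;
  if (beta_out) *beta_out = beta;
  if (sigma2_out) *sigma2_out = sigma2;
  if (A_out) *A_out = A;
  return crit;
}

// allocation-free criterion for the optimizer hot path (p <= 8); the
// final statistics at the optimum go through the Armadillo version above
static double crit_fast(double lam, const Xside& xs, const vec& Xty,
                        double yty, const vec& Sy, const vec& ng,
                        int n, int p, int G) {
  double A[64], R[64], bb[8], beta[8], u[8];
  double logv = 0.0, yq = yty;
  for (int j = 0; j < p; ++j) {
    bb[j] = Xty[j];
    for (int k = j; k < p; ++k) A[j * 8 + k] = xs.XtX(j, k);
  }
  for (int d = 0; d < G; ++d) {
    double c = lam / (1.0 + lam * ng[d]);
    logv += std::log(1.0 + lam * ng[d]);
    yq -= c * Sy[d] * Sy[d];
    for (int j = 0; j < p; ++j) {
      double sj = xs.Sx(d, j);
      double csj = c * sj;
      bb[j] -= csj * Sy[d];
      for (int k = j; k < p; ++k) A[j * 8 + k] -= csj * xs.Sx(d, k);
    }
  }
  // upper Cholesky A = R'R
  double logdet = 0.0;
  for (int j = 0; j < p; ++j) {
    double s = A[j * 8 + j];
    for (int q = 0; q < j; ++q) s -= R[q * 8 + j] * R[q * 8 + j];
    if (s <= 0.0 || !std::isfinite(s)) return std::numeric_limits<double>::infinity();
    double rjj = std::sqrt(s);
    R[j * 8 + j] = rjj;
    logdet += std::log(rjj);
    for (int k = j + 1; k < p; ++k) {
      double t = A[j * 8 + k];
      for (int q = 0; q < j; ++q) t -= R[q * 8 + j] * R[q * 8 + k];
      R[j * 8 + k] = t / rjj;
    }
  }
  // solve R'u = b, R beta = u
  for (int j = 0; j < p; ++j) {
    double t = bb[j];
    for (int q = 0; q < j; ++q) t -= R[q * 8 + j] * u[q];
    u[j] = t / R[j * 8 + j];
  }
  for (int j = p - 1; j >= 0; --j) {
    double t = u[j];
    for (int q = j + 1; q < p; ++q) t -= R[j * 8 + q] * beta[q];
    beta[j] = t / R[j * 8 + j];
  }
  double rss = yq;
  for (int j = 0; j < p; ++j) rss -= bb[j] * beta[j];
  if (rss < 1e-300) rss = 1e-300;
  return (n - p) * std::log(rss / (n - p)) + logv + 2.0 * logdet;
}

static RemlFit reml_fit_one(const Xside& xs, const vec& Xty, double yty,
                            const vec& Sy, const vec& ng, int n, int p) {
  RemlFit out;
  if (p > 8) Rcpp::stop("REML solver supports at most 8 fixed effects");
  const int G = ng.n_elem;
  // coarse scan over log(lambda), then golden-section refinement
  const int ngrid = 21;
  const double lo = -25.0, hi = 14.0;
  double best_u = lo, best_c = datum::inf;
  int best_i = 0;
  for (int i = 0; i < ngrid; ++i) {
    double u = lo + (hi - lo) * i / (ngrid - 1);
    double c = crit_fast(std::exp(u), xs, Xty, yty, Sy, ng, n, p, G);
    if (c < best_c) { best_c = c; best_u = u; best_i = i; }
  }
  if (!std::isfinite(best_c)) return out;  // singular design
  double step = (hi - lo) / (ngrid - 1);
  double a = (best_i == 0) ? lo : best_u - step;
  double b = (best_i == ngrid - 1) ? hi : best_u + step;
  const double invphi = 0.6180339887498949;
  double x1 = b - invphi * (b - a), x2 = a + invphi * (b - a);
  double f1 = crit_fast(std::exp(x1), xs, Xty, yty, Sy, ng, n, p, G);
  double f2 = crit_fast(std::exp(x2), xs, Xty, yty, Sy, ng, n, p, G);
  for (int it = 0; it < 40; ++it) {
    if (f1 < f2) {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - invphi * (b - a);
      f1 = crit_fast(std::exp(x1), xs, Xty, yty, Sy, ng, n, p, G);
    } else {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + invphi * (b - a);
      f2 = crit_fast(std::exp(x2), xs, Xty, yty, Sy, ng, n, p, G);
    }
  }
  double uhat = (f1 < f2) ? x1 : x2;
  double lam = std::exp(uhat);
  vec beta;
  double sigma2;
  mat A;
  double c = reml_crit(lam, xs, Xty, yty, Sy, ng, n, p, &beta, &sigma2, &A);
  if (!std::isfinite(c)) return out;
  mat Ainv = inv_sympd(A);
  out.lambda = lam;
  out.sigma2 = sigma2;
  out.beta = beta;
  out.se = sqrt(sigma2 * Ainv.diag());
  out.ok = true;
  return out;
}

static Xside make_xside(const mat& X, const uvec& g, int G) {
  Xside xs;
  xs.XtX = X.t() * X;
  xs.Sx.zeros(G, X.n_cols);
  for (uword i = 0; i < X.n_rows; ++i) xs.Sx.row(g[i]) += X.row(i);
  return xs;
}

// [[Rcpp::export]]
Rcpp::List reml_fit_cpp(const arma::mat& X, const arma::vec& y,
                        const arma::uvec& g, int G) {
  int n = X.n_rows, p = X.n_cols;
  vec ng(G, fill::zeros), Sy(G, fill::zeros);
  for (int i = 0; i < n; ++i) { ng[g[i]] += 1.0; Sy[g[i]] += y[i]; }
  Xside xs = make_xside(X, g, G);
  vec Xty = X.t() * y;
  double yty = dot(y, y);
  RemlFit f = reml_fit_one(xs, Xty, yty, Sy, ng, n, p);
  if (!f.ok) Rcpp::stop("singular fixed-effects design in REML fit");
  return Rcpp::List::create(
    Rcpp::Named("beta") = f.beta,
    Rcpp::Named("se") = f.se,
    Rcpp::Named("t") = f.beta / f.se,
    Rcpp::Named("sigma2") = f.sigma2,
    Rcpp::Named("lambda") = f.lambda,
    Rcpp::Named("df") = n - p);
}

// Full-pipeline permutation engine for degree centrality. For every label
// column in P (n x (1 + n_perm), observed labels first; 1 = case), the
// whole construction is re-run under that labeling: per-dataset control
// mean/SD recomputed from the pseudo-controls, all subjects re-standardized,
// each hemisphere's network re-thresholded at the top `m_keep` of the 561
// pairs (rank of |z_i - z_j| ascending, ties broken by pair enumeration
// order to match the R construction), degrees recounted, the left-right
// degree difference formed per node, and the mixed model refit with the
// permuted labels in design column `pcol`. Returns the t matrix
// (columns of P) x (34 nodes). This makes the permutation test exact when
// controls define the reference, at any control count.
// [[Rcpp::export]]
Rcpp::List pipeline_degree_perm_cpp(const arma::mat& thickL,
                                    const arma::mat& thickR,
                                    const arma::uvec& g, int G,
                                    const arma::mat& P, int m_keep,
                                    const arma::mat& Xbase, int pcol,
                                    const arma::uvec& nodes) {
  const int n = thickL.n_rows, nr = thickL.n_cols, nperm = P.n_cols;
  const int npair = nr * (nr - 1) / 2, nn = nodes.n_elem;
  vec ng(G, fill::zeros);
  for (int i = 0; i < n; ++i) ng[g[i]] += 1.0;
  // pair enumeration in R's upper.tri (column-major) order
  std::vector<int> pi(npair), pj(npair);
  {
    int q = 0;
    for (int j = 1; j < nr; ++j) for (int i = 0; i < j; ++i) {
      pi[q] = i; pj[q] = j; ++q;
    }
  }
  std::vector<double> dist(npair), tmp(npair);
  mat zL(n, nr), zR(n, nr), Y(n, nr), Yobs;
  mat X = Xbase;
  mat tmat(nperm, nn);
  for (int b = 0; b < nperm; ++b) {
    // control reference and z-scores per dataset, both hemispheres
    for (int d = 0; d < G; ++d) {
      rowvec mL(nr, fill::zeros), sL(nr, fill::zeros);
      rowvec mR(nr, fill::zeros), sR(nr, fill::zeros);
      double nc = 0.0;
      for (int i = 0; i < n; ++i) {
        if ((int)g[i] != d || P(i, b) != 0.0) continue;
        nc += 1.0;
        mL += thickL.row(i); sL += square(thickL.row(i));
        mR += thickR.row(i); sR += square(thickR.row(i));
      }
      if (nc < 2.0) Rcpp::stop("fewer than 2 controls in a dataset");
      mL /= nc; mR /= nc;
      sL = sqrt((sL - nc * square(mL)) / (nc - 1.0));
      sR = sqrt((sR - nc * square(mR)) / (nc - 1.0));
      for (int i = 0; i < n; ++i) {
        if ((int)g[i] != d) continue;
        for (int c = 0; c < nr; ++c) {
          zL(i, c) = (thickL(i, c) - mL[c]) / sL[c];
          zR(i, c) = (thickR(i, c) - mR[c]) / sR[c];
        }
      }
    }
    // binarized degrees and left-right difference; the retained set is
    // the m_keep smallest |dz| with ties resolved in enumeration order,
    // found by selection rather than a full sort
    Y.zeros();
    for (int i = 0; i < n; ++i) {
      for (int h = 0; h < 2; ++h) {
        const mat& z = h == 0 ? zL : zR;
        for (int q = 0; q < npair; ++q)
          dist[q] = std::abs(z(i, pi[q]) - z(i, pj[q]));
        tmp = dist;
        std::nth_element(tmp.begin(), tmp.begin() + (m_keep - 1),
                         tmp.end());
        const double thr = tmp[m_keep - 1];
        const double sgn = h == 0 ? 1.0 : -1.0;
        int below = 0;
        for (int q = 0; q < npair; ++q) if (dist[q] < thr) ++below;
        int at_thr = m_keep - below;
        for (int q = 0; q < npair; ++q) {
          if (dist[q] < thr || (dist[q] == thr && at_thr-- > 0)) {
            Y(i, pi[q]) += sgn;
            Y(i, pj[q]) += sgn;
          }
        }
      }
    }
    if (b == 0) Yobs = Y;
    // mixed-model refit with the permuted labels
    X.col(pcol) = P.col(b);
    Xside xs = make_xside(X, g, G);
    mat Ysel = Y.cols(nodes);
    mat Xty = X.t() * Ysel;
    mat Sy(G, nn, fill::zeros);
    for (int i = 0; i < n; ++i) Sy.row(g[i]) += Ysel.row(i);
    for (int j = 0; j < nn; ++j) {
      double yty = dot(Ysel.col(j), Ysel.col(j));
      RemlFit f = reml_fit_one(xs, Xty.col(j), yty, Sy.col(j), ng,
                               n, X.n_cols);
      tmat(b, j) = f.ok ? f.beta[pcol] / f.se[pcol] : datum::nan;
    }
    if (b % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("t") = tmat,
                            Rcpp::Named("y_obs") = Yobs);
}

// t-statistics of the predictor in column `pcol` (0-based) of X, for every
// permuted predictor column in P (n x n_perm) crossed with every outcome
// column in Y (n x m). Row j of the result corresponds to P column j.
// Failed (singular) fits yield NaN.
// [[Rcpp::export]]
arma::mat reml_perm_t_cpp(const arma::mat& Xbase, const arma::mat& Y,
                          const arma::uvec& g, int G, int pcol,
                          const arma::mat& P) {
  int n = Xbase.n_rows, p = Xbase.n_cols, m = Y.n_cols,
      nperm = P.n_cols;
  vec ng(G, fill::zeros);
  for (int i = 0; i < n; ++i) ng[g[i]] += 1.0;
  // outcome-side pieces do not depend on the permutation
  vec yty(m);
  mat Sy(G, m, fill::zeros);
  for (int j = 0; j < m; ++j) yty[j] = dot(Y.col(j), Y.col(j));
  for (int i = 0; i < n; ++i) Sy.row(g[i]) += Y.row(i);
  mat X = Xbase;
  mat tmat(nperm, m);
  for (int jp = 0; jp < nperm; ++jp) {
    X.col(pcol) = P.col(jp);
    Xside xs = make_xside(X, g, G);
    mat Xty = X.t() * Y;  // p x m
    for (int j = 0; j < m; ++j) {
      RemlFit f = reml_fit_one(xs, Xty.col(j), yty[j], Sy.col(j), ng, n, p);
      tmat(jp, j) = f.ok ? f.beta[pcol] / f.se[pcol] : datum::nan;
    }
    if (jp % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return tmat;
}
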