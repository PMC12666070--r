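// Numerical kernels: brute-force kNN, CPD E-step, GMM L2 cross-correlation
// (value + gradient), and FPFH descriptors. Sizes in this benchmark are a few
// thousand points, so O(M*N) brute force is both simple and fast enough.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// k nearest neighbours of each query row among ref rows (Euclidean).
// Returns 1-based indices and distances, each n_query x k.
// [[Rcpp::export]]
List cpp_knn(const arma::mat& query, const arma::mat& ref, const int k) {
  const int nq = query.n_rows, nr = ref.n_rows, nd = query.n_cols;
  if (k > nr) stop("k exceeds reference size");
  if ((int)ref.n_cols != nd) stop("dimension mismatch between query and ref");
  arma::imat idx(nq, k);
  arma::mat dst(nq, k);
  arma::vec d(nr);
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < nr; ++j) {
      double acc = 0.0;
      for (int c = 0; c < nd; ++c) {
        double dd = query(i, c) - ref(j, c);
        acc += dd * dd;
      }
      d(j) = acc;
    }
    arma::uvec ord = arma::sort_index(d, "ascend");
    for (int m = 0; m < k; ++m) {
      idx(i, m) = static_cast<int>(ord(m)) + 1;
      dst(i, m) = std::sqrt(d(ord(m)));
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

// E-step of rigid coherent point drift. ty: transformed moving centroids
// (M x 3); x: fixed data points (N x 3); sigma2: isotropic variance;
// w: uniform-outlier mixing weight in [0,1).
// Returns sufficient statistics P1 (M), Pt1 (N), PX (M x 3), Np and the
// log-likelihood of the mixture (outlier component included).
// [[Rcpp::export]]
List cpp_cpd_estep(const arma::mat& ty, const arma::mat& x,
                   const double sigma2, const double w) {
  const int M = ty.n_rows, N = x.n_rows;
  const double c = std::pow(2.0 * M_PI * sigma2, 1.5) * (w / (1.0 - w)) *
                   (static_cast<double>(M) / N);
  arma::vec P1(M, arma::fill::zeros), Pt1(N);
  arma::mat PX(M, 3, arma::fill::zeros);
  arma::vec num(M);
  double ll = 0.0, Np = 0.0;
  for (int n = 0; n < N; ++n) {
    double den = c;
    for (int m = 0; m < M; ++m) {
      double dx = x(n, 0) - ty(m, 0);
      double dy = x(n, 1) - ty(m, 1);
      double dz = x(n, 2) - ty(m, 2);
      num(m) = std::exp(-(dx * dx + dy * dy + dz * dz) / (2.0 * sigma2));
      den += num(m);
    }
    ll += std::log(den) - 1.5 * std::log(2.0 * M_PI * sigma2) - std::log((double)M);
    double pt1 = (den - c) / den;
    Pt1(n) = pt1;
    Np += pt1;
    for (int m = 0; m < M; ++m) {
      double p = num(m) / den;
      if (p > 0) {
        P1(m) += p;
        PX(m, 0) += p * x(n, 0);
        PX(m, 1) += p * x(n, 1);
        PX(m, 2) += p * x(n, 2);
      }
    }
  }
  return List::create(_["P1"] = P1, _["Pt1"] = Pt1, _["PX"] = PX,
                      _["Np"] = Np, _["loglik"] = ll);
}

// Cross-correlation term of the L2 distance between two isotropic,
// equal-weight Gaussian mixtures with common bandwidth sigma (per mixture):
//   C(A,B) = 1/(M N) sum_ij (4 pi sigma2)^{-3/2} exp(-||a_i-b_j||^2/(4 sigma2))
// Also returns the gradient with respect to the rows of A.
// [[Rcpp::export]]
List cpp_gmm_l2_cross(const arma::mat& A, const arma::mat& B,
                      const double sigma2) {
  const int M = A.n_rows, N = B.n_rows;
  const double norm = std::pow(4.0 * M_PI * sigma2, -1.5) / (double)(M * N);
  arma::mat grad(M, 3, arma::fill::zeros);
  double val = 0.0;
  for (int i = 0; i < M; ++i) {
    double gx = 0, gy = 0, gz = 0, v = 0;
    for (int j = 0; j < N; ++j) {
      double dx = A(i, 0) - B(j, 0);
      double dy = A(i, 1) - B(j, 1);
      double dz = A(i, 2) - B(j, 2);
      double g = std::exp(-(dx * dx + dy * dy + dz * dz) / (4.0 * sigma2));
      v += g;
      double s = -g / (2.0 * sigma2);
      gx += s * dx; gy += s * dy; gz += s * dz;
    }
    val += v;
    grad(i, 0) = norm * gx; grad(i, 1) = norm * gy; grad(i, 2) = norm * gz;
  }
  return List::create(_["value"] = norm * val, _["grad"] = grad);
}

// Soft (linearly interpolated) vote over 11 bins: keeps the descriptor
// Lipschitz in its inputs, so exact rigid motion leaves it unchanged to
// rounding error instead of flipping mass across hard bin edges.
static inline void vote11(arma::mat& H, const int row, const int offset,
                          double v, double lo, double hi) {
  double c = 11.0 * (v - lo) / (hi - lo) - 0.5;
  if (c < 0) c = 0;
  if (c > 10) c = 10;
  int b0 = static_cast<int>(std::floor(c));
  if (b0 > 9) b0 = 9;
  double frac = c - b0;
  H(row, offset + b0) += 1.0 - frac;
  H(row, offset + b0 + 1) += frac;
}

// Fast point feature histograms (33 bins: 11 per Darboux angle) from
// precomputed neighbour indices (1-based, first column may be the point
// itself and is skipped when so).
// [[Rcpp::export]]
arma::mat cpp_fpfh(const arma::mat& pts, const arma::mat& nrm,
                   const arma::imat& nn_idx, const arma::mat& nn_dist) {
  const int N = pts.n_rows, K = nn_idx.n_cols;
  arma::mat spfh(N, 33, arma::fill::zeros);
  for (int i = 0; i < N; ++i) {
    int cnt = 0;
    for (int kk = 0; kk < K; ++kk) {
      int j = nn_idx(i, kk) - 1;
      if (j == i) continue;
      arma::rowvec dvec = pts.row(j) - pts.row(i);
      double dn = arma::norm(dvec);
      if (dn < 1e-12) continue;
      // choose source point as the one whose normal has the smaller angle
      // with the connecting line (standard PFH convention)
      arma::rowvec ns = nrm.row(i), nt = nrm.row(j), d = dvec / dn;
      if (std::fabs(arma::dot(ns, d)) < std::fabs(arma::dot(nt, d))) {
        arma::rowvec tmp = ns; ns = nt; nt = tmp;
        d = -d;
      }
      arma::rowvec u = ns;
      arma::rowvec v = arma::cross(d, u);
      double vn = arma::norm(v);
      if (vn < 1e-12) continue;
      v /= vn;
      arma::rowvec w = arma::cross(u, v);
      double f1 = arma::dot(v, nt);                       // alpha in [-1,1]
      double f2 = arma::dot(u, d);                        // phi   in [-1,1]
      double f3 = std::atan2(arma::dot(w, nt), arma::dot(u, nt)); // theta
      vote11(spfh, i, 0, f1, -1.0, 1.0);
      vote11(spfh, i, 11, f2, -1.0, 1.0);
      vote11(spfh, i, 22, f3, -M_PI, M_PI);
      ++cnt;
    }
    if (cnt > 0) spfh.row(i) /= (double)cnt;
  }
  arma::mat fpfh(N, 33, arma::fill::zeros);
  for (int i = 0; i < N; ++i) {
    arma::rowvec acc(33, arma::fill::zeros);
    int used = 0;
    for (int kk = 0; kk < K; ++kk) {
      int j = nn_idx(i, kk) - 1;
      if (j == i) continue;
      double wgt = nn_dist(i, kk);
      if (wgt < 1e-9) wgt = 1e-9;
      acc += spfh.row(j) / wgt;
      ++used;
    }
    fpfh.row(i) = spfh.row(i);
    if (used > 0) fpfh.row(i) += acc / (double)used;
    double s = arma::accu(fpfh.row(i));
    if (s > 0) fpfh.row(i) /= s;
  }
  return fpfh;
}
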