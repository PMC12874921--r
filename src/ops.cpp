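// Hot numeric kernels for the autodiff engine: row gather/scatter, im2col
// for 1-d convolution, and segment max. Everything else stays in R (BLAS
// handles the matrix products).

#include <Rcpp.h>
using namespace Rcpp;

// rows of x selected by 1-based idx
// [[Rcpp::export]]
NumericMatrix dti_gather(const NumericMatrix& x, const IntegerVector& idx) {
  const int n = idx.size(), c = x.ncol(), nx = x.nrow();
  NumericMatrix out(n, c);
  for (int j = 0; j < c; ++j) {
    const double* xc = &x(0, j);
    double* oc = &out(0, j);
    for (int i = 0; i < n; ++i) oc[i] = xc[idx[i] - 1];
    (void)nx;
  }
  return out;
}

// out[g[i], ] += x[i, ] for 1-based groups; out has n rows
// [[Rcpp::export]]
NumericMatrix dti_scatter_add(const NumericMatrix& x,
                              const IntegerVector& group, int n) {
  const int m = x.nrow(), c = x.ncol();
  NumericMatrix out(n, c);
  for (int j = 0; j < c; ++j) {
    const double* xc = &x(0, j);
    double* oc = &out(0, j);
    for (int i = 0; i < m; ++i) oc[group[i] - 1] += xc[i];
  }
  return out;
}

// im2col: idx is (positions x k), 1-based into h, 0 = zero pad;
// output column block d holds h[idx[, d], ]
// [[Rcpp::export]]
NumericMatrix dti_im2col(const NumericMatrix& h, const IntegerMatrix& idx) {
  const int n = idx.nrow(), k = idx.ncol(), c = h.ncol();
  NumericMatrix out(n, k * c);
  for (int d = 0; d < k; ++d) {
    for (int j = 0; j < c; ++j) {
      const double* hc = &h(0, j);
      double* oc = &out(0, d * c + j);
      for (int i = 0; i < n; ++i) {
        const int r = idx(i, d);
        oc[i] = (r == 0) ? 0.0 : hc[r - 1];
      }
    }
  }
  return out;
}

// gradient of im2col: scatter column blocks of g back into dh (nh rows)
// [[Rcpp::export]]
NumericMatrix dti_im2col_grad(const NumericMatrix& g, const IntegerMatrix& idx,
                              int nh) {
  const int n = idx.nrow(), k = idx.ncol(), c = g.ncol() / k;
  NumericMatrix dh(nh, c);
  for (int d = 0; d < k; ++d) {
    for (int j = 0; j < c; ++j) {
      const double* gc = &g(0, d * c + j);
      double* hc = &dh(0, j);
      for (int i = 0; i < n; ++i) {
        const int r = idx(i, d);
        if (r != 0) hc[r - 1] += gc[i];
      }
    }
  }
  return dh;
}

// per-group column max with argmax rows (1-based); empty groups yield 0
// [[Rcpp::export]]
List dti_segment_max(const NumericMatrix& x, const IntegerVector& group,
                     int ngroups) {
  const int m = x.nrow(), c = x.ncol();
  NumericMatrix val(ngroups, c);
  IntegerMatrix amx(ngroups, c);
  std::fill(val.begin(), val.end(), R_NegInf);
  for (int j = 0; j < c; ++j) {
    const double* xc = &x(0, j);
    for (int i = 0; i < m; ++i) {
      const int g = group[i] - 1;
      if (xc[i] > val(g, j)) {
        val(g, j) = xc[i];
        amx(g, j) = i + 1;
      }
    }
  }
  for (int g = 0; g < ngroups; ++g) {
    for (int j = 0; j < c; ++j) {
      if (amx(g, j) == 0) val(g, j) = 0.0;
    }
  }
  return List::create(_["values"] = val, _["argmax"] = amx);
}

// per-group max of a vector (1-based groups); empty groups give -Inf
// [[Rcpp::export]]
NumericVector dti_segment_max_vec(const NumericVector& x,
                                  const IntegerVector& group, int ngroups) {
  NumericVector out(ngroups, R_NegInf);
  const int m = x.size();
  for (int i = 0; i < m; ++i) {
    const int g = group[i] - 1;
    if (x[i] > out[g]) out[g] = x[i];
  }
  return out;
}
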