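#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Symmetric (half-sample, edge included) reflection of i into [0, n).
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : (period - 1 - i);
}

static inline double pad_fetch(const double* line, int n, int i, int pad_mode,
                               double pad_value) {
  if (i >= 0 && i < n) return line[i];
  switch (pad_mode) {
  case 0: return line[reflect_idx(i, n)];                 // reflect
  case 1: return line[i < 0 ? 0 : n - 1];                 // replicate
  default: return pad_value;                              // constant
  }
}

// van Herk / Gil-Werman running min or max of window width w = 2r+1 over a
// padded line; O(n) independent of r.  buf holds the padded line (N = n+2r),
// s and t are the block prefix/suffix scratch arrays.
static void vanherk_line(const std::vector<double>& buf, int n, int r,
                         bool do_min, std::vector<double>& s,
                         std::vector<double>& t, double* out) {
  const int w = 2 * r + 1;
  const int N = n + 2 * r;
  // prefix extrema restarting every w samples
  for (int i = 0; i < N; ++i) {
    if (i % w == 0) s[i] = buf[i];
    else s[i] = do_min ? std::min(s[i - 1], buf[i]) : std::max(s[i - 1], buf[i]);
  }
  // suffix extrema restarting at block boundaries
  for (int i = N - 1; i >= 0; --i) {
    if (i == N - 1 || (i + 1) % w == 0) t[i] = buf[i];
    else t[i] = do_min ? std::min(t[i + 1], buf[i]) : std::max(t[i + 1], buf[i]);
  }
  for (int j = 0; j < n; ++j) {
    // window spans padded indices [j, j + w - 1]
    const int hi = j + w - 1;
    out[j] = do_min ? std::min(t[j], s[hi]) : std::max(t[j], s[hi]);
  }
}

// Filter every line of a 3D array along one axis.
// type: 0 = min, 1 = max, 2 = box mean.
// pad_mode: 0 = reflect, 1 = replicate, 2 = constant pad_value.
// [[Rcpp::export]]
NumericVector line_filter_cpp(NumericVector x, IntegerVector dim, int axis,
                              int r, int type, int pad_mode, double pad_value) {
  if (dim.size() != 3) stop("dim must have length 3");
  if (axis < 0 || axis > 2) stop("axis must be 0, 1 or 2");
  if (r < 0) stop("radius must be >= 0");
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  if ((R_xlen_t)d0 * d1 * d2 != x.size()) stop("dim does not match length(x)");
  NumericVector res(x.size());
  if (r == 0) { std::copy(x.begin(), x.end(), res.begin()); return res; }

  const R_xlen_t stride[3] = {1, (R_xlen_t)d0, (R_xlen_t)d0 * d1};
  const int dims[3] = {d0, d1, d2};
  const int n = dims[axis];
  const int ob = (axis == 0) ? 1 : 0;
  const int oc = (axis == 2) ? 1 : 2;
  const int nb = dims[ob], nc = dims[oc];
  const R_xlen_t sa = stride[axis], sb = stride[ob], sc = stride[oc];

  const int N = n + 2 * r;
  std::vector<double> buf(N), s(N), t(N), line(n), out(n);
  const double* xp = x.begin();
  double* rp = res.begin();

  for (int ic = 0; ic < nc; ++ic) {
    for (int ib = 0; ib < nb; ++ib) {
      const R_xlen_t base = ib * sb + ic * sc;
      for (int j = 0; j < n; ++j) line[j] = xp[base + j * sa];
      for (int i = -r; i < n + r; ++i)
        buf[i + r] = pad_fetch(line.data(), n, i, pad_mode, pad_value);
      if (type == 2) {
        // running sum via prefix sums of the padded line
        double acc = 0.0;
        const int w = 2 * r + 1;
        for (int i = 0; i < w; ++i) acc += buf[i];
        out[0] = acc / w;
        for (int j = 1; j < n; ++j) {
          acc += buf[j + w - 1] - buf[j - 1];
          out[j] = acc / w;
        }
      } else {
        vanherk_line(buf, n, r, type == 0, s, t, out.data());
      }
      for (int j = 0; j < n; ++j) rp[base + j * sa] = out[j];
    }
  }
  res.attr("dim") = dim;
  return res;
}

// 1D convolution along one axis with an arbitrary (odd-length) kernel,
// reflect padding.  Used for separable Gaussian smoothing.
// [[Rcpp::export]]
NumericVector line_conv_cpp(NumericVector x, IntegerVector dim, int axis,
                            NumericVector kernel) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int klen = kernel.size();
  if (klen % 2 != 1) stop("kernel length must be odd");
  const int kr = klen / 2;
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  if ((R_xlen_t)d0 * d1 * d2 != x.size()) stop("dim does not match length(x)");
  NumericVector res(x.size());
  const R_xlen_t stride[3] = {1, (R_xlen_t)d0, (R_xlen_t)d0 * d1};
  const int dims[3] = {d0, d1, d2};
  const int n = dims[axis];
  const int ob = (axis == 0) ? 1 : 0;
  const int oc = (axis == 2) ? 1 : 2;
  const int nb = dims[ob], nc = dims[oc];
  const R_xlen_t sa = stride[axis], sb = stride[ob], sc = stride[oc];

  std::vector<double> line(n);
  const double* xp = x.begin();
  const double* kp = kernel.begin();
  double* rp = res.begin();
  for (int ic = 0; ic < nc; ++ic) {
    for (int ib = 0; ib < nb; ++ib) {
      const R_xlen_t base = ib * sb + ic * sc;
      for (int j = 0; j < n; ++j) line[j] = xp[base + j * sa];
      for (int j = 0; j < n; ++j) {
        double acc = 0.0;
        for (int k = -kr; k <= kr; ++k)
          acc += kp[k + kr] * line[reflect_idx(j + k, n)];
        rp[base + j * sa] = acc;
      }
    }
  }
  res.attr("dim") = dim;
  return res;
}

// Full 3D bilateral filter: spatial Gaussian (std sigma, truncated to a cube
// of half-width support) times intensity kernel exp(-d^2 / (2*mu)), reflect
// padding.  mu is the variance of the range kernel.
// [[Rcpp::export]]
NumericVector bilateral3d_cpp(NumericVector x, IntegerVector dim, double sigma,
                              double mu, int support) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  if ((R_xlen_t)d0 * d1 * d2 != x.size()) stop("dim does not match length(x)");
  if (sigma <= 0 || mu <= 0) stop("sigma and mu must be positive");
  const int S = support;
  const int w = 2 * S + 1;
  std::vector<double> spat(w * w * w);
  {
    int idx = 0;
    for (int dz = -S; dz <= S; ++dz)
      for (int dy = -S; dy <= S; ++dy)
        for (int dx = -S; dx <= S; ++dx)
          spat[idx++] = std::exp(-0.5 * (dx * dx + dy * dy + dz * dz) /
                                 (sigma * sigma));
  }
  NumericVector res(x.size());
  const double* xp = x.begin();
  double* rp = res.begin();
  const double inv2mu = 1.0 / (2.0 * mu);
  for (int k = 0; k < d2; ++k) {
    for (int j = 0; j < d1; ++j) {
      for (int i = 0; i < d0; ++i) {
        const double v0 = xp[i + (R_xlen_t)d0 * (j + (R_xlen_t)d1 * k)];
        double num = 0.0, den = 0.0;
        int idx = 0;
        for (int dz = -S; dz <= S; ++dz) {
          const int kk = reflect_idx(k + dz, d2);
          for (int dy = -S; dy <= S; ++dy) {
            const int jj = reflect_idx(j + dy, d1);
            const R_xlen_t off = (R_xlen_t)d0 * (jj + (R_xlen_t)d1 * kk);
            for (int dx = -S; dx <= S; ++dx, ++idx) {
              const int ii = reflect_idx(i + dx, d0);
              const double v = xp[ii + off];
              const double dI = v - v0;
              const double wgt = spat[idx] * std::exp(-dI * dI * inv2mu);
              num += wgt * v;
              den += wgt;
            }
          }
        }
        rp[i + (R_xlen_t)d0 * (j + (R_xlen_t)d1 * k)] = num / den;
      }
    }
  }
  res.attr("dim") = dim;
  return res;
}

// 3D connected-component labeling of a logical mask under 6- or
// 26-connectivity.  Returns an integer array: 0 background, components
// labeled 1..n in scan order of their first voxel.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  if (dim.size() != 3) stop("dim must have length 3");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const R_xlen_t ntot = (R_xlen_t)d0 * d1 * d2;
  if (ntot != mask.size()) stop("dim does not match length(mask)");
  IntegerVector labels(ntot, 0);
  const int* mp = mask.begin();
  int* lp = labels.begin();

  std::vector<int> noff;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        noff.push_back(dx);
        noff.push_back(dy);
        noff.push_back(dz);
      }
  const int nn = (int)(noff.size() / 3);

  std::vector<R_xlen_t> stack;
  int next_label = 0;
  for (R_xlen_t start = 0; start < ntot; ++start) {
    if (!mp[start] || lp[start] != 0) continue;
    ++next_label;
    lp[start] = next_label;
    stack.push_back(start);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int ci = (int)(cur % d0);
      const int cj = (int)((cur / d0) % d1);
      const int ck = (int)(cur / ((R_xlen_t)d0 * d1));
      for (int q = 0; q < nn; ++q) {
        const int ii = ci + noff[3 * q];
        const int jj = cj + noff[3 * q + 1];
        const int kk = ck + noff[3 * q + 2];
        if (ii < 0 || ii >= d0 || jj < 0 || jj >= d1 || kk < 0 || kk >= d2)
          continue;
        const R_xlen_t nb = ii + (R_xlen_t)d0 * (jj + (R_xlen_t)d1 * kk);
        if (mp[nb] && lp[nb] == 0) {
          lp[nb] = next_label;
          stack.push_back(nb);
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}
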