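#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian convolution with half-sample reflection at the borders,
// so a constant image is reproduced exactly and total intensity is conserved
// away from the boundary. Kernel is truncated at ceil(4*sigma) and
// renormalized.
// [[Rcpp::export(name = ".gaussian_blur_cpp")]]
NumericMatrix gaussian_blur_cpp(const NumericMatrix& img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  int r = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;

  // reflect index into [0, n-1] (half-sample symmetric, scipy 'reflect')
  auto reflect = [](int i, int n) {
    if (n == 1) return 0;
    int period = 2 * n;
    i %= period;
    if (i < 0) i += period;
    return (i < n) ? i : period - 1 - i;
  };

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (vertical)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += k[d + r] * img(reflect(i + d, nr), j);
      tmp(i, j) = acc;
    }
  // along columns (horizontal)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += k[d + r] * tmp(i, reflect(j + d, nc));
      out(i, j) = acc;
    }
  return out;
}

// Grayscale morphological reconstruction by dilation (8-connected), hybrid
// raster/anti-raster algorithm with a FIFO queue (Vincent 1993). Requires
// seed <= mask elementwise; returns the reconstruction, which is the
// illumination background when seed = smoothed - h, mask = smoothed.
// [[Rcpp::export(name = ".reconstruct_dilation_cpp")]]
NumericMatrix reconstruct_dilation_cpp(const NumericMatrix& seed,
                                       const NumericMatrix& mask) {
  int nr = seed.nrow(), nc = seed.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("seed and mask dimensions differ");
  NumericMatrix J(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (seed(i, j) > mask(i, j)) stop("seed must be <= mask everywhere");
      J(i, j) = seed(i, j);
    }

  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  // raster order: neighbors already visited (N+ = above and left)
  const int drp[4] = {-1, -1, -1, 0};
  const int dcp[4] = {-1, 0, 1, -1};
  // anti-raster: below and right
  const int drm[4] = {0, 1, 1, 1};
  const int dcm[4] = {1, -1, 0, 1};

  // forward sweep
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double m = J(i, j);
      for (int t = 0; t < 4; ++t) {
        int ii = i + drp[t], jj = j + dcp[t];
        if (ii >= 0 && ii < nr && jj >= 0 && jj < nc && J(ii, jj) > m)
          m = J(ii, jj);
      }
      J(i, j) = std::min(m, mask(i, j));
    }

  // backward sweep, queueing pixels whose value can still propagate
  std::queue<std::pair<int, int> > fifo;
  for (int i = nr - 1; i >= 0; --i)
    for (int j = nc - 1; j >= 0; --j) {
      double m = J(i, j);
      for (int t = 0; t < 4; ++t) {
        int ii = i + drm[t], jj = j + dcm[t];
        if (ii >= 0 && ii < nr && jj >= 0 && jj < nc && J(ii, jj) > m)
          m = J(ii, jj);
      }
      J(i, j) = std::min(m, mask(i, j));
      for (int t = 0; t < 4; ++t) {
        int ii = i + drm[t], jj = j + dcm[t];
        if (ii >= 0 && ii < nr && jj >= 0 && jj < nc &&
            J(ii, jj) < J(i, j) && J(ii, jj) < mask(ii, jj)) {
          fifo.push(std::make_pair(i, j));
          break;
        }
      }
    }

  while (!fifo.empty()) {
    int i = fifo.front().first, j = fifo.front().second;
    fifo.pop();
    for (int t = 0; t < 8; ++t) {
      int ii = i + dr8[t], jj = j + dc8[t];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (J(ii, jj) < J(i, j) && mask(ii, jj) != J(ii, jj)) {
        J(ii, jj) = std::min(J(i, j), mask(ii, jj));
        fifo.push(std::make_pair(ii, jj));
      }
    }
  }
  return J;
}

// Regional maxima with plateau handling: a candidate pixel is >= all of its
// 8 neighbors; connected candidates of equal value form one plateau, reported
// once at its centroid. Coordinates are 0-based with x = column, y = row.
// Returns a list(x, y, value).
// [[Rcpp::export(name = ".local_maxima_cpp")]]
List local_maxima_cpp(const NumericMatrix& img) {
  int nr = img.nrow(), nc = img.ncol();
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  std::vector<char> cand((size_t)nr * nc, 0);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double v = img(i, j);
      bool ok = true;
      for (int t = 0; t < 8 && ok; ++t) {
        int ii = i + dr8[t], jj = j + dc8[t];
        if (ii >= 0 && ii < nr && jj >= 0 && jj < nc && img(ii, jj) > v)
          ok = false;
      }
      cand[(size_t)i + (size_t)j * nr] = ok ? 1 : 0;
    }

  // flood-fill equal-valued candidate plateaus
  std::vector<int> label((size_t)nr * nc, 0);
  std::vector<double> xs, ys, vals;
  int cur = 0;
  std::vector<std::pair<int, int> > stack;
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      size_t idx = (size_t)i + (size_t)j * nr;
      if (!cand[idx] || label[idx]) continue;
      double v = img(i, j);
      ++cur;
      double sx = 0.0, sy = 0.0;
      int npx = 0;
      bool is_max = true;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      label[idx] = cur;
      while (!stack.empty()) {
        int ci = stack.back().first, cj = stack.back().second;
        stack.pop_back();
        sx += cj; sy += ci; ++npx;
        for (int t = 0; t < 8; ++t) {
          int ii = ci + dr8[t], jj = cj + dc8[t];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          size_t nidx = (size_t)ii + (size_t)jj * nr;
          if (img(ii, jj) == v) {
            if (!cand[nidx]) is_max = false;  // plateau touches a non-candidate
            else if (!label[nidx]) {
              label[nidx] = cur;
              stack.push_back(std::make_pair(ii, jj));
            }
          }
        }
      }
      if (is_max) {
        xs.push_back(sx / npx);
        ys.push_back(sy / npx);
        vals.push_back(v);
      }
    }

  return List::create(_["x"] = wrap(xs), _["y"] = wrap(ys),
                      _["value"] = wrap(vals));
}

// Count query points having at least one reference point within `cutoff`
// under toroidal (wrap-around) distance on an L x L plane, via cell lists.
// [[Rcpp::export(name = ".count_within_torus_cpp")]]
int count_within_torus_cpp(const NumericVector& qx, const NumericVector& qy,
                           const NumericVector& rx, const NumericVector& ry,
                           double L, double cutoff) {
  int nq = qx.size(), nref = rx.size();
  if (nref == 0 || nq == 0) return 0;
  int ncell = std::max(1, (int)std::floor(L / std::max(cutoff, L / 512.0)));
  double cell = L / ncell;
  double c2 = cutoff * cutoff;

  std::vector<std::vector<int> > bins((size_t)ncell * ncell);
  auto binof = [&](double x, double y) {
    int bx = (int)std::floor(x / cell); if (bx >= ncell) bx = ncell - 1;
    int by = (int)std::floor(y / cell); if (by >= ncell) by = ncell - 1;
    return (size_t)bx + (size_t)by * ncell;
  };
  for (int k = 0; k < nref; ++k) bins[binof(rx[k], ry[k])].push_back(k);

  int hits = 0;
  for (int q = 0; q < nq; ++q) {
    double x = qx[q], y = qy[q];
    int bx = (int)std::floor(x / cell); if (bx >= ncell) bx = ncell - 1;
    int by = (int)std::floor(y / cell); if (by >= ncell) by = ncell - 1;
    bool found = false;
    for (int dy = -1; dy <= 1 && !found; ++dy)
      for (int dx = -1; dx <= 1 && !found; ++dx) {
        int cx = (bx + dx + ncell) % ncell;
        int cy = (by + dy + ncell) % ncell;
        const std::vector<int>& b = bins[(size_t)cx + (size_t)cy * ncell];
        for (size_t t = 0; t < b.size(); ++t) {
          double ddx = std::fabs(x - rx[b[t]]);
          double ddy = std::fabs(y - ry[b[t]]);
          if (ddx > L / 2) ddx = L - ddx;   // torus wrap
          if (ddy > L / 2) ddy = L - ddy;
          if (ddx * ddx + ddy * ddy <= c2) { found = true; break; }
        }
      }
    if (found) ++hits;
  }
  return hits;
}
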