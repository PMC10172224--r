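#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>

using namespace Rcpp;

// All routines use (row, col) indexing on column-major R matrices and
// 8-connected neighborhoods throughout, matching the package convention.

static const int DY[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DX[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Sliding-window median with edge replication. Window must be odd.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, int window) {
  if (window < 3 || window % 2 == 0)
    stop("window must be an odd integer >= 3");
  int ny = img.nrow(), nx = img.ncol(), r = (window - 1) / 2;
  int wlen = window * window;
  NumericMatrix out(ny, nx);
  std::vector<double> buf(wlen);
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      int k = 0;
      for (int dj = -r; dj <= r; ++dj) {
        int jj = j + dj;
        if (jj < 0) jj = 0; else if (jj >= nx) jj = nx - 1;
        for (int di = -r; di <= r; ++di) {
          int ii = i + di;
          if (ii < 0) ii = 0; else if (ii >= ny) ii = ny - 1;
          buf[k++] = img(ii, jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + wlen / 2, buf.end());
      out(i, j) = buf[wlen / 2];
    }
  }
  return out;
}

// Greyscale geodesic reconstruction by dilation (hybrid raster/anti-raster
// algorithm with a FIFO queue). marker must be pointwise <= mask; callers
// clamp beforehand. 8-connectivity.
// [[Rcpp::export]]
NumericMatrix grey_reconstruct_cpp(NumericMatrix marker, NumericMatrix mask) {
  int ny = marker.nrow(), nx = marker.ncol();
  if (mask.nrow() != ny || mask.ncol() != nx)
    stop("marker and mask must have identical dimensions");
  NumericMatrix J(clone(marker));

  // raster scan: neighbors already visited are (di,dj) with dj<0, or dj==0 && di<0
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i) {
      double m = J(i, j);
      for (int k = 0; k < 8; ++k) {
        int di = DY[k], dj = DX[k];
        if (dj > 0 || (dj == 0 && di > 0)) continue;
        int ii = i + di, jj = j + dj;
        if (ii < 0 || ii >= ny || jj < 0 || jj >= nx) continue;
        if (J(ii, jj) > m) m = J(ii, jj);
      }
      J(i, j) = std::min(m, mask(i, j));
    }

  std::queue<int> fifo;
  // anti-raster scan
  for (int j = nx - 1; j >= 0; --j)
    for (int i = ny - 1; i >= 0; --i) {
      double m = J(i, j);
      for (int k = 0; k < 8; ++k) {
        int di = DY[k], dj = DX[k];
        if (dj < 0 || (dj == 0 && di < 0)) continue;
        int ii = i + di, jj = j + dj;
        if (ii < 0 || ii >= ny || jj < 0 || jj >= nx) continue;
        if (J(ii, jj) > m) m = J(ii, jj);
      }
      J(i, j) = std::min(m, mask(i, j));
      for (int k = 0; k < 8; ++k) {
        int di = DY[k], dj = DX[k];
        if (dj < 0 || (dj == 0 && di < 0)) continue;
        int ii = i + di, jj = j + dj;
        if (ii < 0 || ii >= ny || jj < 0 || jj >= nx) continue;
        if (J(ii, jj) < J(i, j) && J(ii, jj) < mask(ii, jj)) {
          fifo.push(j * ny + i);
          break;
        }
      }
    }

  while (!fifo.empty()) {
    int p = fifo.front(); fifo.pop();
    int i = p % ny, j = p / ny;
    for (int k = 0; k < 8; ++k) {
      int ii = i + DY[k], jj = j + DX[k];
      if (ii < 0 || ii >= ny || jj < 0 || jj >= nx) continue;
      if (J(ii, jj) < J(i, j) && mask(ii, jj) != J(ii, jj)) {
        J(ii, jj) = std::min(J(i, j), mask(ii, jj));
        fifo.push(jj * ny + ii);
      }
    }
  }
  return J;
}

// 8-connected component labeling; labels assigned in raster order (column
// within row order of the first pixel encountered scanning columns last).
// [[Rcpp::export]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(ny, nx);
  int cur = 0;
  std::queue<int> q;
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++cur;
      q.push(j * ny + i);
      while (!q.empty()) {
        int p = q.front(); q.pop();
        int pi = p % ny, pj = p / ny;
        for (int k = 0; k < 8; ++k) {
          int ii = pi + DY[k], jj = pj + DX[k];
          if (ii < 0 || ii >= ny || jj < 0 || jj >= nx) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = cur;
            q.push(jj * ny + ii);
          }
        }
      }
    }
  return lab;
}

struct PQEntry {
  double v;
  long order;
  int idx;
};
struct PQCompare {
  // lowest relief first; FIFO (insertion order) on ties, so output is
  // deterministic and plateau pixels go to the marker reached first.
  bool operator()(const PQEntry &a, const PQEntry &b) const {
    if (a.v != b.v) return a.v > b.v;
    return a.order > b.order;
  }
};

// Marker-controlled watershed by priority flooding of `relief` from `seeds`
// restricted to `mask`. Every mask pixel 8-connected to a seed receives the
// label of the seed whose flood reaches it first; mask components with no
// seed stay 0.
// [[Rcpp::export]]
IntegerMatrix marker_watershed_cpp(NumericMatrix relief, IntegerMatrix seeds,
                                   LogicalMatrix mask) {
  int ny = relief.nrow(), nx = relief.ncol();
  if (seeds.nrow() != ny || seeds.ncol() != nx ||
      mask.nrow() != ny || mask.ncol() != nx)
    stop("relief, seeds and mask must have identical dimensions");
  IntegerMatrix lab(ny, nx);
  std::priority_queue<PQEntry, std::vector<PQEntry>, PQCompare> pq;
  long order = 0;
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i)
      if (seeds(i, j) > 0 && mask(i, j)) {
        lab(i, j) = seeds(i, j);
        pq.push({relief(i, j), order++, j * ny + i});
      }
  while (!pq.empty()) {
    PQEntry e = pq.top(); pq.pop();
    int i = e.idx % ny, j = e.idx / ny;
    for (int k = 0; k < 8; ++k) {
      int ii = i + DY[k], jj = j + DX[k];
      if (ii < 0 || ii >= ny || jj < 0 || jj >= nx) continue;
      if (mask(ii, jj) && lab(ii, jj) == 0) {
        lab(ii, jj) = lab(i, j);
        pq.push({relief(ii, jj), order++, jj * ny + ii});
      }
    }
  }
  return lab;
}

// Local density index over a 3x3 window: for each foreground pixel the
// count of foreground pixels among its 8 neighbors; borders are background.
// Background pixels get NA.
// [[Rcpp::export]]
IntegerMatrix ldi_count_cpp(LogicalMatrix mask) {
  int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix out(ny, nx);
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i) {
      if (!mask(i, j)) { out(i, j) = NA_INTEGER; continue; }
      int c = 0;
      for (int k = 0; k < 8; ++k) {
        int ii = i + DY[k], jj = j + DX[k];
        if (ii < 0 || ii >= ny || jj < 0 || jj >= nx) continue;
        if (mask(ii, jj)) ++c;
      }
      out(i, j) = c;
    }
  return out;
}
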