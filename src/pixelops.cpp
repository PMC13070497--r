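#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Seeded region growing with a running-mean homogeneity criterion.
//
// Breadth-first growth from the seed: a pixel is popped from a FIFO frontier
// and accepted iff |intensity - mean(region so far)| <= tol; the region mean
// is updated after every accepted pixel. Each pixel enters the frontier at
// most once (marked when pushed); 4-neighbours are pushed in row-major order
// (up, left, right, down), which fixes the scan order and makes the result
// deterministic. The seed is always accepted.
// [[Rcpp::export]]
LogicalMatrix region_grow_cpp(NumericMatrix img, int seed_r, int seed_c,
                              double tol) {
  const int nr = img.nrow(), nc = img.ncol();
  if (seed_r < 1 || seed_r > nr || seed_c < 1 || seed_c > nc)
    stop("seed outside image bounds");
  LogicalMatrix member(nr, nc);
  std::vector<char> queued(static_cast<size_t>(nr) * nc, 0);
  std::queue<int> frontier;  // linear index, column-major as in R
  const int dr[4] = {-1, 0, 0, 1};
  const int dc[4] = {0, -1, 1, 0};

  int s = (seed_c - 1) * nr + (seed_r - 1);
  frontier.push(s);
  queued[s] = 1;
  double sum = 0.0;
  long n = 0;

  while (!frontier.empty()) {
    int idx = frontier.front();
    frontier.pop();
    int c = idx / nr, r = idx % nr;
    double val = img(r, c);
    bool accept = (n == 0) || (std::fabs(val - sum / n) <= tol);
    if (!accept) continue;
    member(r, c) = true;
    sum += val;
    ++n;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int j = cc * nr + rr;
      if (!queued[j]) {
        queued[j] = 1;
        frontier.push(j);
      }
    }
  }
  return member;
}

// 8-connected component labelling of a binary mask (EBImage::bwlabel is
// 4-connected, which would split diagonally touching tumor fragments).
// Labels are assigned in column-major scan order starting at 1.
// [[Rcpp::export]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<int> q;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      ++next;
      lab(r0, c0) = next;
      q.push(c0 * nr + r0);
      while (!q.empty()) {
        int idx = q.front();
        q.pop();
        int c = idx / nr, r = idx % nr;
        for (int drr = -1; drr <= 1; ++drr) {
          for (int dcc = -1; dcc <= 1; ++dcc) {
            if (!drr && !dcc) continue;
            int rr = r + drr, cc = c + dcc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              q.push(cc * nr + rr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// 4-connected breadth-first (geodesic) distance inside `mask` from the set
// of pixels in `sources`. Unreachable or masked-out pixels get -1. Used by
// the scene generator to advance the tumor front contiguously from the lobe
// junction.
// [[Rcpp::export]]
IntegerMatrix geodesic_dist_cpp(LogicalMatrix mask, LogicalMatrix sources) {
  const int nr = mask.nrow(), nc = mask.ncol();
  if (sources.nrow() != nr || sources.ncol() != nc)
    stop("mask/sources shape mismatch");
  IntegerMatrix dist(nr, nc);
  std::fill(dist.begin(), dist.end(), -1);
  std::queue<int> q;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (sources(r, c) && mask(r, c)) {
        dist(r, c) = 0;
        q.push(c * nr + r);
      }
  const int dr[4] = {-1, 0, 0, 1};
  const int dc[4] = {0, -1, 1, 0};
  while (!q.empty()) {
    int idx = q.front();
    q.pop();
    int c = idx / nr, r = idx % nr;
    int d = dist(r, c);
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (mask(rr, cc) && dist(rr, cc) < 0) {
        dist(rr, cc) = d + 1;
        q.push(cc * nr + rr);
      }
    }
  }
  return dist;
}
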