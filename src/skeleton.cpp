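#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// Zhang-Suen two-subiteration thinning. Expects a logical matrix whose
// border ring is all FALSE (the R wrapper pads); reduces foreground to a
// 1-px-wide 8-connected skeleton.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  LogicalMatrix img(clone(m));
  std::vector<std::pair<int, int> > kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int j = 1; j < nc - 1; ++j) {
        for (int i = 1; i < nr - 1; ++i) {
          if (!img(i, j)) continue;
          int p2 = img(i - 1, j),     p3 = img(i - 1, j + 1);
          int p4 = img(i, j + 1),     p5 = img(i + 1, j + 1);
          int p6 = img(i + 1, j),     p7 = img(i + 1, j - 1);
          int p8 = img(i, j - 1),     p9 = img(i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (sub == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(i, j));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k)
        img(kill[k].first, kill[k].second) = false;
    }
  }
  return img;
}

// Geodesic path length per labelled skeleton component.  `lab` assigns each
// segment pixel a label in 1..nlab (0 = not a segment pixel).  Pixels are
// walked from an endpoint (or any pixel, for loops) through 8-neighbours of
// the same label, accumulating unit / sqrt(2) steps; disconnected remainders
// (staircase artefacts) are attached through their closest link.
// [[Rcpp::export]]
NumericVector cpp_path_lengths(IntegerMatrix lab, int nlab) {
  int nr = lab.nrow(), nc = lab.ncol();
  const double SQ2 = 1.4142135623730951;
  std::vector<std::vector<int> > px(nlab + 1);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l > 0) px[l].push_back(i + j * nr);
    }
  NumericVector out(nlab);
  LogicalMatrix visited(nr, nc);
  int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  for (int l = 1; l <= nlab; ++l) {
    std::vector<int> &p = px[l];
    int n = (int)p.size();
    if (n <= 1) { out[l - 1] = 0.0; continue; }
    // pick a start pixel with the fewest same-label neighbours (an endpoint)
    int start = p[0], best = 9;
    for (int k = 0; k < n; ++k) {
      int i = p[k] % nr, j = p[k] / nr, deg = 0;
      for (int d = 0; d < 8; ++d) {
        int ii = i + di[d], jj = j + dj[d];
        if (ii >= 0 && ii < nr && jj >= 0 && jj < nc && lab(ii, jj) == l) ++deg;
      }
      if (deg < best) { best = deg; start = p[k]; }
    }
    double len = 0.0;
    int cur = start, done = 1;
    visited(cur % nr, cur / nr) = true;
    while (done < n) {
      int i = cur % nr, j = cur / nr, next = -1;
      double stepd = 0.0;
      // prefer axial moves (d < 4) so the walk follows the pixel chain
      for (int d = 0; d < 8; ++d) {
        int ii = i + di[d], jj = j + dj[d];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        if (lab(ii, jj) == l && !visited(ii, jj)) {
          next = ii + jj * nr;
          stepd = (d < 4) ? 1.0 : SQ2;
          break;
        }
      }
      if (next < 0) {
        // dead end with pixels left: re-attach at any unvisited pixel that
        // touches the visited set
        for (int k = 0; k < n && next < 0; ++k) {
          int q = p[k];
          if (visited(q % nr, q / nr)) continue;
          int qi = q % nr, qj = q / nr;
          for (int d = 0; d < 8; ++d) {
            int ii = qi + di[d], jj = qj + dj[d];
            if (ii >= 0 && ii < nr && jj >= 0 && jj < nc &&
                lab(ii, jj) == l && visited(ii, jj)) {
              next = q;
              stepd = (d < 4) ? 1.0 : SQ2;
              break;
            }
          }
        }
        if (next < 0) break;  // truly disconnected; should not happen
      }
      visited(next % nr, next / nr) = true;
      len += stepd;
      cur = next;
      ++done;
    }
    out[l - 1] = len;
    for (int k = 0; k < n; ++k) visited(p[k] % nr, p[k] / nr) = false;
  }
  return out;
}

// 8-connected component labelling (iterative flood fill).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!m(i, j) || lab(i, j)) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int q = stack.back(); stack.pop_back();
        int qi = q % nr, qj = q / nr;
        for (int d = 0; d < 8; ++d) {
          int ii = qi + di[d], jj = qj + dj[d];
          if (ii >= 0 && ii < nr && jj >= 0 && jj < nc &&
              m(ii, jj) && !lab(ii, jj)) {
            lab(ii, jj) = next;
            stack.push_back(ii + jj * nr);
          }
        }
      }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}
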