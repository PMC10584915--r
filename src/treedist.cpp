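// Ordered labeled tree edit distance (Zhang-Shasha) plus a brute-force
// Tai-mapping search used as an exhaustive oracle on small trees.
//
// Trees arrive as postorder label vectors with leftmost-leaf indices (lml),
// 1-based from R; the brute-force oracle additionally takes preorder labels
// with parent pointers.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static double zs_dist(const std::vector<int>& lab1, const std::vector<int>& lml1,
                      const std::vector<int>& lab2, const std::vector<int>& lml2) {
  int n1 = lab1.size(), n2 = lab2.size();
  if (n1 == 0) return n2;
  if (n2 == 0) return n1;
  // keyroots: nodes with no left sibling on the path (standard definition)
  std::vector<int> kr1, kr2;
  {
    std::vector<bool> seen(n1 + 1, false);
    for (int i = n1 - 1; i >= 0; --i)
      if (!seen[lml1[i]]) { kr1.push_back(i); seen[lml1[i]] = true; }
    std::sort(kr1.begin(), kr1.end());
    std::vector<bool> seen2(n2 + 1, false);
    for (int i = n2 - 1; i >= 0; --i)
      if (!seen2[lml2[i]]) { kr2.push_back(i); seen2[lml2[i]] = true; }
    std::sort(kr2.begin(), kr2.end());
  }
  std::vector<std::vector<double> > td(n1, std::vector<double>(n2, 0.0));
  std::vector<std::vector<double> > fd(n1 + 2, std::vector<double>(n2 + 2, 0.0));

  for (size_t a = 0; a < kr1.size(); ++a) {
    int i = kr1[a];
    for (size_t b = 0; b < kr2.size(); ++b) {
      int j = kr2[b];
      int li = lml1[i], lj = lml2[j]; // 1-based
      fd[li - 1][lj - 1] = 0.0;
      for (int di = li; di <= i + 1; ++di) fd[di][lj - 1] = fd[di - 1][lj - 1] + 1.0;
      for (int dj = lj; dj <= j + 1; ++dj) fd[li - 1][dj] = fd[li - 1][dj - 1] + 1.0;
      for (int di = li; di <= i + 1; ++di) {
        for (int dj = lj; dj <= j + 1; ++dj) {
          if (lml1[di - 1] == li && lml2[dj - 1] == lj) {
            double rel = (lab1[di - 1] == lab2[dj - 1]) ? 0.0 : 1.0;
            fd[di][dj] = std::min(std::min(fd[di - 1][dj] + 1.0, fd[di][dj - 1] + 1.0),
                                  fd[di - 1][dj - 1] + rel);
            td[di - 1][dj - 1] = fd[di][dj];
          } else {
            fd[di][dj] = std::min(std::min(fd[di - 1][dj] + 1.0, fd[di][dj - 1] + 1.0),
                                  fd[lml1[di - 1] - 1][lml2[dj - 1] - 1] + td[di - 1][dj - 1]);
          }
        }
      }
    }
  }
  return td[n1 - 1][n2 - 1];
}

// [[Rcpp::export]]
double zs_tree_dist_cpp(IntegerVector lab1, IntegerVector lml1,
                        IntegerVector lab2, IntegerVector lml2) {
  return zs_dist(as<std::vector<int> >(lab1), as<std::vector<int> >(lml1),
                 as<std::vector<int> >(lab2), as<std::vector<int> >(lml2));
}

// [[Rcpp::export]]
NumericMatrix zs_dist_matrix_cpp(List labs, List lmls) {
  int n = labs.size();
  std::vector<std::vector<int> > L(n), M(n);
  for (int i = 0; i < n; ++i) {
    L[i] = as<std::vector<int> >(labs[i]);
    M[i] = as<std::vector<int> >(lmls[i]);
  }
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = zs_dist(L[i], M[i], L[j], M[j]);
      out(i, j) = d;
      out(j, i) = d;
    }
  return out;
}

// ---- brute-force minimal-cost Tai mapping (exhaustive, for small trees) ----

struct TaiCtx {
  std::vector<int> lab1, par1, lab2, par2;
  int n1, n2;
  double best;

  bool anc(const std::vector<int>& par, int a, int b) const { // a ancestor of b?
    int x = par[b];
    while (x >= 0) {
      if (x == a) return true;
      x = par[x];
    }
    return false;
  }

  // map holds the T2 index for each T1 node processed so far (-1 deleted)
  void rec(int a, std::vector<std::pair<int,int> >& M, int bmax,
           int nmatch, int mism) {
    // lower bound on final cost
    int remain1 = n1 - a;
    int avail2 = n2 - (bmax + 1);
    int maxMatch = nmatch + std::min(remain1, avail2);
    double lb = (double)n1 + n2 - 2.0 * maxMatch + mism;
    if (lb >= best) return;
    if (a == n1) {
      double cost = (double)n1 + n2 - 2.0 * nmatch + mism;
      if (cost < best) best = cost;
      return;
    }
    // option: map a to some b > bmax, consistent with ancestry vs all mapped
    for (int b = bmax + 1; b < n2; ++b) {
      bool ok = true;
      for (size_t q = 0; q < M.size(); ++q) {
        int a2 = M[q].first, b2 = M[q].second;
        if (anc(par1, a2, a) != anc(par2, b2, b)) { ok = false; break; }
      }
      if (!ok) continue;
      M.push_back(std::make_pair(a, b));
      rec(a + 1, M, b, nmatch + 1, mism + (lab1[a] == lab2[b] ? 0 : 1));
      M.pop_back();
    }
    // option: delete a
    rec(a + 1, M, bmax, nmatch, mism);
  }
};

// [[Rcpp::export]]
double tai_bruteforce_cpp(IntegerVector lab1, IntegerVector par1,
                          IntegerVector lab2, IntegerVector par2) {
  TaiCtx c;
  c.lab1 = as<std::vector<int> >(lab1);
  c.par1 = as<std::vector<int> >(par1);
  c.lab2 = as<std::vector<int> >(lab2);
  c.par2 = as<std::vector<int> >(par2);
  c.n1 = c.lab1.size();
  c.n2 = c.lab2.size();
  c.best = (double)c.n1 + c.n2 + 1.0;
  std::vector<std::pair<int,int> > M;
  c.rec(0, M, -1, 0, 0);
  return c.best;
}
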