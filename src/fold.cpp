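// Band-limited suboptimal folding under a reduced nearest-neighbour model.
//
// The grammar below is unambiguous (every structure has exactly one parse),
// so threshold enumeration generates each structure once with its exact
// energy:
//   W(j)     : external segment [0..j]
//   V(i,j)   : [i..j] with (i,j) paired (hairpin / two-loop / multiloop)
//   WM(i,j)  : multiloop segment with >=1 branch
//   WM2(i,j) : multiloop segment with >=2 branches
// Hard constraints: prohibited positions never pair, forced positions must
// pair with their designated partner, and no pair may cross a forced pair.

#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>
using namespace Rcpp;

static const double INF = 1e9;

struct Model {
  double stack[6][6];          // outer pair type x inner pair type
  std::vector<double> hairpin; // 1-based by loop length
  std::vector<double> bulge;
  std::vector<double> internal_;
  double asym_coef, asym_max;
  double ml_close, ml_branch, ml_unpaired;
  int min_hairpin, max_interior;
};

// pair types: 0 none, 1 CG, 2 GC, 3 GU, 4 UG, 5 AU, 6 UA  (A=0,C=1,G=2,U=3)
static int pair_type(int a, int b) {
  if (a == 1 && b == 2) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 2 && b == 3) return 3;
  if (a == 3 && b == 2) return 4;
  if (a == 0 && b == 3) return 5;
  if (a == 3 && b == 0) return 6;
  return 0;
}

static Model parse_model(List model) {
  Model m;
  NumericMatrix st = model["stack"];
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) m.stack[i][j] = st(i, j);
  m.hairpin = as<std::vector<double> >(model["hairpin"]);
  m.bulge = as<std::vector<double> >(model["bulge"]);
  m.internal_ = as<std::vector<double> >(model["internal"]);
  m.asym_coef = as<double>(model["asym_coef"]);
  m.asym_max = as<double>(model["asym_max"]);
  m.ml_close = as<double>(model["ml_close"]);
  m.ml_branch = as<double>(model["ml_branch"]);
  m.ml_unpaired = as<double>(model["ml_unpaired"]);
  m.min_hairpin = as<int>(model["min_hairpin"]);
  m.max_interior = as<int>(model["max_interior"]);
  return m;
}

static double loop_table(const std::vector<double>& tab, int len) {
  if (len <= 0) return INF;
  if (len <= (int)tab.size()) return tab[len - 1];
  return tab.back();
}

// energy of the two-loop (stack/bulge/internal) closed by (i,j) with inner (k,l)
static double two_loop_E(const Model& m, int pt_out, int pt_in, int l1, int l2) {
  if (l1 == 0 && l2 == 0) return m.stack[pt_out - 1][pt_in - 1];
  if (l1 == 0 || l2 == 0) return loop_table(m.bulge, l1 + l2);
  double asym = m.asym_coef * std::abs(l1 - l2);
  if (asym > m.asym_max) asym = m.asym_max;
  return loop_table(m.internal_, l1 + l2) + asym;
}

struct FoldCtx {
  int n;
  std::vector<int> seq;      // 0..3
  std::vector<int> forced;   // partner index or -1
  std::vector<bool> prohibit;
  std::vector<int> cumForced; // #forced in [0..i]
  std::vector<std::pair<int,int> > forcedPairs;
  Model m;
  std::vector<double> V, WM, WM2, W;
  std::vector<int> PT; // pair type cache

  double& v(int i, int j) { return V[i * n + j]; }
  double& wm(int i, int j) { return WM[i * n + j]; }
  double& wm2(int i, int j) { return WM2[i * n + j]; }
  int pt(int i, int j) const { return PT[i * n + j]; }

  bool allUnp(int i, int j) const { // [i..j] may be fully unpaired
    if (i > j) return true;
    int c = cumForced[j] - (i > 0 ? cumForced[i - 1] : 0);
    return c == 0;
  }
  bool okUnp(int i) const { return forced[i] < 0; }

  bool canPair(int i, int j) const {
    if (pt(i, j) == 0) return false;
    if (j - i - 1 < m.min_hairpin) return false;
    if (prohibit[i] || prohibit[j]) return false;
    if (forced[i] >= 0 && forced[i] != j) return false;
    if (forced[j] >= 0 && forced[j] != i) return false;
    for (size_t f = 0; f < forcedPairs.size(); ++f) {
      int a = forcedPairs[f].first, b = forcedPairs[f].second;
      if ((i < a && a < j && j < b) || (a < i && i < b && b < j)) return false;
    }
    return true;
  }
};

static void fill_dp(FoldCtx& c) {
  int n = c.n;
  const Model& m = c.m;
  c.V.assign((size_t)n * n, INF);
  c.WM.assign((size_t)n * n, INF);
  c.WM2.assign((size_t)n * n, INF);
  c.PT.assign((size_t)n * n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) c.PT[i * n + j] = pair_type(c.seq[i], c.seq[j]);

  for (int span = 2; span <= n; ++span) {
    for (int i = 0; i + span - 1 < n; ++i) {
      int j = i + span - 1;
      // ---- V(i,j)
      if (c.canPair(i, j)) {
        double best = INF;
        if (c.allUnp(i + 1, j - 1))
          best = loop_table(m.hairpin, j - i - 1);
        int maxk = std::min(j - 1, i + 1 + m.max_interior);
        for (int k = i + 1; k <= maxk; ++k) {
          if (!c.allUnp(i + 1, k - 1)) break;
          int l1 = k - i - 1;
          int minl = std::max(k + m.min_hairpin + 1, j - 1 - (m.max_interior - l1));
          for (int l = j - 1; l >= minl; --l) {
            if (!c.allUnp(l + 1, j - 1)) break;
            double vin = c.v(k, l);
            if (vin >= INF / 2) continue;
            double e = two_loop_E(m, c.pt(i, j), c.pt(k, l), l1, j - l - 1) + vin;
            if (e < best) best = e;
          }
        }
        if (j - i - 1 >= 2 * (m.min_hairpin + 2)) {
          double w2 = c.wm2(i + 1, j - 1);
          if (w2 < INF / 2) {
            double e = m.ml_close + m.ml_branch + w2;
            if (e < best) best = e;
          }
        }
        c.v(i, j) = best;
      }
      // ---- WM(i,j): >=1 branch
      {
        double best = INF;
        if (c.okUnp(j) && j > i && c.wm(i, j - 1) < INF / 2)
          best = c.wm(i, j - 1) + m.ml_unpaired;
        for (int k = i; k <= j; ++k) {
          double vv = c.v(k, j);
          if (vv >= INF / 2) continue;
          if (k == i) {
            best = std::min(best, vv + m.ml_branch);
          } else {
            if (c.allUnp(i, k - 1))
              best = std::min(best, vv + m.ml_branch + m.ml_unpaired * (k - i));
            if (c.wm(i, k - 1) < INF / 2)
              best = std::min(best, c.wm(i, k - 1) + vv + m.ml_branch);
          }
        }
        c.wm(i, j) = best;
      }
      // ---- WM2(i,j): >=2 branches
      {
        double best = INF;
        if (c.okUnp(j) && j > i && c.wm2(i, j - 1) < INF / 2)
          best = c.wm2(i, j - 1) + m.ml_unpaired;
        for (int k = i + 1; k <= j; ++k) {
          double vv = c.v(k, j);
          if (vv >= INF / 2) continue;
          if (c.wm(i, k - 1) < INF / 2)
            best = std::min(best, c.wm(i, k - 1) + vv + m.ml_branch);
        }
        c.wm2(i, j) = best;
      }
    }
  }
  // ---- external W
  c.W.assign(n, INF);
  for (int j = 0; j < n; ++j) {
    double best = INF;
    if (c.okUnp(j)) best = (j == 0 ? 0.0 : c.W[j - 1]);
    for (int i = 0; i <= j; ++i) {
      double vv = (i < j) ? c.v(i, j) : INF;
      if (vv >= INF / 2) continue;
      double pre = (i == 0 ? 0.0 : c.W[i - 1]);
      if (pre < INF / 2) best = std::min(best, pre + vv);
    }
    c.W[j] = best;
  }
}

// ---------------- threshold enumeration ----------------

struct Item { int type; int i; int j; }; // 0=W(0..j), 1=V, 2=WM, 3=WM2

struct Enumerator {
  FoldCtx* c;
  double thresh;
  size_t hardcap;
  bool overflow;
  std::vector<std::string> dbs;
  std::vector<double> energies;

  double val(const Item& it) {
    if (it.type == 0) return it.j < 0 ? 0.0 : c->W[it.j];
    if (it.type == 1) return c->v(it.i, it.j);
    if (it.type == 2) return c->wm(it.i, it.j);
    return c->wm2(it.i, it.j);
  }
  double restSum(const std::vector<Item>& todo) {
    double s = 0;
    for (size_t t = 0; t < todo.size(); ++t) s += val(todo[t]);
    return s;
  }

  void emit(const std::vector<std::pair<int,int> >& pairs, double acc) {
    std::string db(c->n, '.');
    for (size_t p = 0; p < pairs.size(); ++p) {
      db[pairs[p].first] = '(';
      db[pairs[p].second] = ')';
    }
    dbs.push_back(db);
    energies.push_back(acc);
    if (dbs.size() > hardcap) overflow = true;
  }

  void rec(std::vector<Item>& todo, double acc,
           std::vector<std::pair<int,int> >& pairs) {
    if (overflow) return;
    if (todo.empty()) {
      if (acc <= thresh + 1e-6) emit(pairs, acc);
      return;
    }
    Item it = todo.back();
    todo.pop_back();
    double rest = restSum(todo);
    const Model& m = c->m;
    const double eps = 1e-6;

    if (it.type == 0) { // W(0..j)
      int j = it.j;
      if (j < 0) {
        rec(todo, acc, pairs);
      } else {
        if (c->okUnp(j)) {
          double lb = acc + rest + (j == 0 ? 0.0 : c->W[j - 1]);
          if (lb <= thresh + eps) {
            todo.push_back(Item{0, 0, j - 1});
            rec(todo, acc, pairs);
            todo.pop_back();
          }
        }
        for (int i = 0; i <= j - 1; ++i) {
          double vv = c->v(i, j);
          if (vv >= INF / 2) continue;
          double pre = (i == 0 ? 0.0 : c->W[i - 1]);
          if (pre >= INF / 2) continue;
          if (acc + rest + pre + vv <= thresh + eps) {
            todo.push_back(Item{0, 0, i - 1});
            todo.push_back(Item{1, i, j});
            rec(todo, acc, pairs);
            todo.pop_back();
            todo.pop_back();
          }
        }
      }
    } else if (it.type == 1) { // V(i,j)
      int i = it.i, j = it.j;
      pairs.push_back(std::make_pair(i, j));
      if (c->allUnp(i + 1, j - 1)) {
        double e = loop_table(m.hairpin, j - i - 1);
        if (acc + e + rest <= thresh + eps) rec(todo, acc + e, pairs);
      }
      int maxk = std::min(j - 1, i + 1 + m.max_interior);
      for (int k = i + 1; k <= maxk; ++k) {
        if (!c->allUnp(i + 1, k - 1)) break;
        int l1 = k - i - 1;
        int minl = std::max(k + m.min_hairpin + 1, j - 1 - (m.max_interior - l1));
        for (int l = j - 1; l >= minl; --l) {
          if (!c->allUnp(l + 1, j - 1)) break;
          double vin = c->v(k, l);
          if (vin >= INF / 2) continue;
          double e = two_loop_E(m, c->pt(i, j), c->pt(k, l), l1, j - l - 1);
          if (acc + e + vin + rest <= thresh + eps) {
            todo.push_back(Item{1, k, l});
            rec(todo, acc + e, pairs);
            todo.pop_back();
          }
        }
      }
      if (j - i - 1 >= 2 * (m.min_hairpin + 2) && c->wm2(i + 1, j - 1) < INF / 2) {
        double e = m.ml_close + m.ml_branch;
        if (acc + e + c->wm2(i + 1, j - 1) + rest <= thresh + eps) {
          todo.push_back(Item{3, i + 1, j - 1});
          rec(todo, acc + e, pairs);
          todo.pop_back();
        }
      }
      pairs.pop_back();
    } else if (it.type == 2) { // WM(i,j)
      int i = it.i, j = it.j;
      if (c->okUnp(j) && j > i && c->wm(i, j - 1) < INF / 2) {
        if (acc + m.ml_unpaired + c->wm(i, j - 1) + rest <= thresh + eps) {
          todo.push_back(Item{2, i, j - 1});
          rec(todo, acc + m.ml_unpaired, pairs);
          todo.pop_back();
        }
      }
      for (int k = i; k <= j; ++k) {
        double vv = c->v(k, j);
        if (vv >= INF / 2) continue;
        if (k == i || c->allUnp(i, k - 1)) {
          double e = m.ml_branch + m.ml_unpaired * (k - i);
          if (acc + e + vv + rest <= thresh + eps) {
            todo.push_back(Item{1, k, j});
            rec(todo, acc + e, pairs);
            todo.pop_back();
          }
        }
        if (k > i && c->wm(i, k - 1) < INF / 2) {
          double e = m.ml_branch;
          if (acc + e + vv + c->wm(i, k - 1) + rest <= thresh + eps) {
            todo.push_back(Item{2, i, k - 1});
            todo.push_back(Item{1, k, j});
            rec(todo, acc + e, pairs);
            todo.pop_back();
            todo.pop_back();
          }
        }
      }
    } else { // WM2(i,j)
      int i = it.i, j = it.j;
      if (c->okUnp(j) && j > i && c->wm2(i, j - 1) < INF / 2) {
        if (acc + m.ml_unpaired + c->wm2(i, j - 1) + rest <= thresh + eps) {
          todo.push_back(Item{3, i, j - 1});
          rec(todo, acc + m.ml_unpaired, pairs);
          todo.pop_back();
        }
      }
      for (int k = i + 1; k <= j; ++k) {
        double vv = c->v(k, j);
        if (vv >= INF / 2 || c->wm(i, k - 1) >= INF / 2) continue;
        double e = m.ml_branch;
        if (acc + e + vv + c->wm(i, k - 1) + rest <= thresh + eps) {
          todo.push_back(Item{2, i, k - 1});
          todo.push_back(Item{1, k, j});
          rec(todo, acc + e, pairs);
          todo.pop_back();
          todo.pop_back();
        }
      }
    }
    todo.push_back(it);
  }

  void run() {
    overflow = false;
    dbs.clear();
    energies.clear();
    std::vector<Item> todo;
    todo.push_back(Item{0, 0, c->n - 1});
    std::vector<std::pair<int,int> > pairs;
    rec(todo, 0.0, pairs);
  }
};

// [[Rcpp::export]]
List fold_subopt_cpp(IntegerVector seq, IntegerVector forced,
                     LogicalVector prohibit, double band, double max_structures,
                     List model) {
  FoldCtx c;
  c.n = seq.size();
  c.seq = as<std::vector<int> >(seq);
  c.forced = as<std::vector<int> >(forced);
  c.prohibit = as<std::vector<bool> >(prohibit);
  c.m = parse_model(model);
  c.cumForced.assign(c.n, 0);
  int cf = 0;
  for (int i = 0; i < c.n; ++i) {
    if (c.forced[i] >= 0) {
      ++cf;
      if (c.forced[i] > i) c.forcedPairs.push_back(std::make_pair(i, c.forced[i]));
    }
    c.cumForced[i] = cf;
  }
  fill_dp(c);
  double mfe = (c.n > 0) ? c.W[c.n - 1] : 0.0;
  if (mfe >= INF / 2) { // constraints unsatisfiable
    return List::create(_["dotbracket"] = CharacterVector(0),
                        _["energy"] = NumericVector(0),
                        _["mfe"] = NA_REAL, _["satisfiable"] = false);
  }

  Enumerator en;
  en.c = &c;
  en.hardcap = 2000000;
  bool finite_band = R_finite(band);
  double b = finite_band ? std::min(band, 0.5) : 0.0;
  double lo = 0.0;
  std::vector<std::string> dbs;
  std::vector<double> energies;
  for (int iter = 0; iter < 200; ++iter) {
    en.thresh = finite_band ? mfe + b : INF / 4;
    en.run();
    if (en.overflow) { // too generous: bisect down (only with finite targets)
      double nb = (lo + b) / 2.0;
      if (!finite_band || nb <= lo + 1e-9) break; // give up shrinking
      b = nb;
      continue;
    }
    dbs = en.dbs;
    energies = en.energies;
    if (!finite_band) break;
    if (energies.size() >= (size_t)std::min(max_structures, 1e8) || b >= band - 1e-12)
      break;
    lo = b;
    b = std::min(band, b * 2 + 0.25);
  }

  // sort by (energy, dot-bracket lexicographic)
  std::vector<size_t> idx(dbs.size());
  for (size_t i = 0; i < idx.size(); ++i) idx[i] = i;
  // round to micro-kcal so summation-order noise cannot perturb tie-breaks
  std::sort(idx.begin(), idx.end(), [&](size_t a, size_t bb) {
    long ea = lround(energies[a] * 1e6), eb = lround(energies[bb] * 1e6);
    if (ea != eb) return ea < eb;
    return dbs[a] < dbs[bb];
  });
  size_t keep = idx.size();
  if (R_finite(max_structures) && (double)keep > max_structures)
    keep = (size_t)max_structures;
  CharacterVector out_db(keep);
  NumericVector out_e(keep);
  for (size_t i = 0; i < keep; ++i) {
    out_db[i] = dbs[idx[i]];
    out_e[i] = energies[idx[i]];
  }
  return List::create(_["dotbracket"] = out_db, _["energy"] = out_e,
                      _["mfe"] = mfe, _["satisfiable"] = true);
}

// Independent loop-decomposition evaluator (no DP): energy of a given
// structure under the model.  pairtab is 0-based partner or -1.
// [[Rcpp::export]]
double eval_energy_cpp(IntegerVector seq, IntegerVector pairtab, List model) {
  Model m = parse_model(model);
  int n = seq.size();
  std::vector<int> pt = as<std::vector<int> >(pairtab);
  std::vector<int> s = as<std::vector<int> >(seq);
  double total = 0.0;

  std::vector<std::pair<int,int> > stackp;
  for (int i = 0; i < n; ++i) {
    if (pt[i] > i) stackp.push_back(std::make_pair(i, pt[i]));
  }
  for (size_t q = 0; q < stackp.size(); ++q) {
    int i = stackp[q].first, j = stackp[q].second;
    // children pairs directly inside (i,j)
    std::vector<std::pair<int,int> > kids;
    int unp = 0;
    int k = i + 1;
    while (k < j) {
      if (pt[k] > k) {
        kids.push_back(std::make_pair(k, pt[k]));
        k = pt[k] + 1;
      } else {
        ++unp;
        ++k;
      }
    }
    if (kids.empty()) {
      total += loop_table(m.hairpin, unp);
    } else if (kids.size() == 1) {
      int a = kids[0].first, b = kids[0].second;
      int l1 = a - i - 1, l2 = j - b - 1;
      total += two_loop_E(m, pair_type(s[i], s[j]), pair_type(s[a], s[b]), l1, l2);
    } else {
      total += m.ml_close + m.ml_branch * (1.0 + kids.size()) + m.ml_unpaired * unp;
    }
  }
  return total;
}
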