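// Single-hairpin RNA folding under a constant nearest-neighbour-style
// stacking table, plus an explicit structure-enumeration oracle used by the
// test suite. Energies in kcal/mol; the model is deliberately simple (one
// terminal loop, constant stack/bulge/loop terms) and documented in the
// package vignette.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

const double NEG_EPS = 1e-9;

inline int baseCode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': case 'T': case 't': return 3;
  }
  return -1;
}

// pair class: -1 unpairable, 0 = GC/CG, 1 = AU/UA, 2 = GU/UG
inline int pairClass(int a, int b) {
  if ((a == 1 && b == 2) || (a == 2 && b == 1)) return 0;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 1;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 2;
  return -1;
}

struct EnergyPars {
  double stack_gc_gc;   // both pairs G:C
  double stack_gc_au;   // one G:C, one A:U
  double stack_au_au;   // both A:U
  double stack_gu;      // either pair a G:U wobble
  double loop_pen;      // terminal (hairpin) loop closure
  double bulge_pen;     // per bulged side between consecutive pairs
  int    min_loop;      // minimum unpaired nt in the terminal loop
  int    max_gap;       // max unpaired nt on one side between stem pairs
};

EnergyPars parsFromList(List p) {
  EnergyPars ep;
  ep.stack_gc_gc = as<double>(p["stack_gc_gc"]);
  ep.stack_gc_au = as<double>(p["stack_gc_au"]);
  ep.stack_au_au = as<double>(p["stack_au_au"]);
  ep.stack_gu    = as<double>(p["stack_gu"]);
  ep.loop_pen    = as<double>(p["loop_penalty"]);
  ep.bulge_pen   = as<double>(p["bulge_penalty"]);
  ep.min_loop    = as<int>(p["min_loop"]);
  ep.max_gap     = as<int>(p["max_gap"]);
  return ep;
}

inline double stackE(const EnergyPars& P, int c1, int c2) {
  if (c1 == 2 || c2 == 2) return P.stack_gu;
  if (c1 == 0 && c2 == 0) return P.stack_gc_gc;
  if (c1 == 1 && c2 == 1) return P.stack_au_au;
  return P.stack_gc_au;
}

std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    v[i] = baseCode(s[i]);
    if (v[i] < 0) stop("invalid nucleotide '%s' at position %d",
                       std::string(1, s[i]).c_str(), (int)i + 1);
  }
  return v;
}

// ---------------------------------------------------------------------------
// Dynamic programme.  A single-hairpin structure is a chain of nested pairs
// (i1,j1) supset (i2,j2) supset ... supset (ik,jk) with the terminal loop
// closed by (ik,jk).  V(i,j) = best energy of any chain whose outermost pair
// is (i,j).  Ties: lower energy, then more pairs, then 5'-most terminal loop.
// ---------------------------------------------------------------------------

struct Cell {
  double e;
  int npairs;
  int looppos;   // i-index of the loop-closing pair
  int tk, tl;    // traceback: inner pair, or -1 for hairpin closure
};

inline bool better(double e1, int np1, int lp1, const Cell& c2) {
  if (e1 < c2.e - NEG_EPS) return true;
  if (e1 > c2.e + NEG_EPS) return false;
  if (np1 != c2.npairs) return np1 > c2.npairs;
  return lp1 < c2.looppos;
}

// Fills the DP table; returns index of best outer pair or -1 for the empty
// structure.  `cells` is indexed i*n + j.
int runDP(const std::vector<int>& s, const EnergyPars& P,
          std::vector<Cell>& cells, int& best_i, int& best_j) {
  const int n = (int)s.size();
  cells.assign((size_t)n * n, Cell{0.0, 0, 0, -2, -2});
  Cell best{0.0, 0, n + 1, -2, -2};   // empty structure
  best_i = best_j = -1;
  bool found = false;
  for (int span = P.min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      const int j = i + span;
      if (pairClass(s[i], s[j]) < 0) continue;
      Cell c{HUGE_VAL, 0, 0, -2, -2};
      if (j - i - 1 >= P.min_loop) {        // close the terminal loop here
        c.e = P.loop_pen; c.npairs = 1; c.looppos = i; c.tk = c.tl = -1;
      }
      const int kmax = std::min(i + 1 + P.max_gap, j - P.min_loop - 2);
      for (int k = i + 1; k <= kmax; ++k) {
        const int lmin = std::max(k + P.min_loop + 1, j - 1 - P.max_gap);
        for (int l = lmin; l <= j - 1; ++l) {
          const int pc = pairClass(s[k], s[l]);
          if (pc < 0) continue;
          const Cell& in = cells[(size_t)k * n + l];
          if (in.tk == -2) continue;        // inner pair has no valid chain
          const int gapL = k - i - 1, gapR = j - l - 1;
          double add;
          if (gapL == 0 && gapR == 0)
            add = stackE(P, pairClass(s[i], s[j]), pc);
          else
            add = P.bulge_pen * ((gapL > 0) + (gapR > 0));
          const double e = in.e + add;
          if (c.tk == -2 || better(e, in.npairs + 1, in.looppos, c))
            c = Cell{e, in.npairs + 1, in.looppos, k, l};
        }
      }
      if (c.tk == -2) continue;             // no chain through (i,j)
      cells[(size_t)i * n + j] = c;
      // report a folded structure only when it beats the empty structure
      if (c.e < -NEG_EPS && better(c.e, c.npairs, c.looppos, best)) {
        best = c; best_i = i; best_j = j; found = true;
      }
    }
  }
  return found ? 0 : -1;
}

// Pure energy version of the DP used by the exhaustive checker.
double dpEnergy(const std::vector<int>& s, const EnergyPars& P,
                std::vector<double>& V) {
  const int n = (int)s.size();
  V.assign((size_t)n * n, HUGE_VAL);
  double best = 0.0;
  for (int span = P.min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      const int j = i + span;
      if (pairClass(s[i], s[j]) < 0) continue;
      double e = (j - i - 1 >= P.min_loop) ? P.loop_pen : HUGE_VAL;
      const int kmax = std::min(i + 1 + P.max_gap, j - P.min_loop - 2);
      for (int k = i + 1; k <= kmax; ++k) {
        const int lmin = std::max(k + P.min_loop + 1, j - 1 - P.max_gap);
        for (int l = lmin; l <= j - 1; ++l) {
          const int pc = pairClass(s[k], s[l]);
          if (pc < 0) continue;
          const double in = V[(size_t)k * n + l];
          if (in == HUGE_VAL) continue;
          const int gapL = k - i - 1, gapR = j - l - 1;
          const double add = (gapL == 0 && gapR == 0)
            ? stackE(P, pairClass(s[i], s[j]), pc)
            : P.bulge_pen * ((gapL > 0) + (gapR > 0));
          if (in + add < e) e = in + add;
        }
      }
      if (e == HUGE_VAL) continue;
      V[(size_t)i * n + j] = e;
      if (e < best) best = e;
    }
  }
  return best;
}

// ---------------------------------------------------------------------------
// Explicit enumeration over every single-hairpin chain (no memoisation):
// the independent oracle.
// ---------------------------------------------------------------------------

struct EnumBest { double e; long long nstruct; };

void enumChain(const std::vector<int>& s, const EnergyPars& P,
               int a, int b, double acc, EnumBest& best) {
  if (b - a - 1 >= P.min_loop) {            // close the loop at (a,b)
    const double tot = acc + P.loop_pen;
    ++best.nstruct;
    if (tot < best.e) best.e = tot;
  }
  const int pcOut = pairClass(s[a], s[b]);
  const int kmax = std::min(a + 1 + P.max_gap, b - P.min_loop - 2);
  for (int k = a + 1; k <= kmax; ++k) {
    const int lmin = std::max(k + P.min_loop + 1, b - 1 - P.max_gap);
    for (int l = lmin; l <= b - 1; ++l) {
      const int pc = pairClass(s[k], s[l]);
      if (pc < 0) continue;
      const int gapL = k - a - 1, gapR = b - l - 1;
      const double add = (gapL == 0 && gapR == 0)
        ? stackE(P, pcOut, pc)
        : P.bulge_pen * ((gapL > 0) + (gapR > 0));
      enumChain(s, P, k, l, acc + add, best);
    }
  }
}

double enumEnergy(const std::vector<int>& s, const EnergyPars& P,
                  long long* nstruct = nullptr) {
  const int n = (int)s.size();
  EnumBest best{0.0, 0};                    // empty structure, energy 0
  for (int i = 0; i < n; ++i)
    for (int j = i + P.min_loop + 1; j < n; ++j)
      if (pairClass(s[i], s[j]) >= 0)
        enumChain(s, P, i, j, 0.0, best);
  if (nstruct) *nstruct = best.nstruct;
  return std::min(0.0, best.e);
}

}  // namespace

// [[Rcpp::export(name = ".fold_core")]]
List fold_core(std::string seq, List pars) {
  const EnergyPars P = parsFromList(pars);
  const std::vector<int> s = encode(seq);
  const int n = (int)s.size();
  std::vector<Cell> cells;
  int bi, bj;
  const int status = runDP(s, P, cells, bi, bj);

  std::string db(n, '.');
  double energy = 0.0;
  int npairs = 0, loop_len = NA_INTEGER, largest_bulge = 0;
  int outer_i = NA_INTEGER, outer_j = NA_INTEGER;
  int loop_i = NA_INTEGER, loop_j = NA_INTEGER;
  if (status == 0) {
    const Cell& top = cells[(size_t)bi * n + bj];
    energy = top.e; npairs = top.npairs;
    outer_i = bi + 1; outer_j = bj + 1;
    int i = bi, j = bj;
    for (;;) {
      db[i] = '('; db[j] = ')';
      const Cell& c = cells[(size_t)i * n + j];
      if (c.tk == -1) { loop_i = i; loop_j = j; break; }
      largest_bulge = std::max(largest_bulge,
                               std::max(c.tk - i - 1, j - c.tl - 1));
      i = c.tk; j = c.tl;
    }
    loop_len = loop_j - loop_i - 1;
  }
  return List::create(
    _["energy"] = energy,
    _["structure"] = db,
    _["n_pairs"] = npairs,
    _["loop_length"] = loop_len,
    _["largest_bulge"] = largest_bulge,
    _["outer_start"] = outer_i,
    _["outer_end"] = outer_j,
    _["loop_start"] = (loop_i == NA_INTEGER) ? NA_INTEGER : loop_i + 1,
    _["loop_end"] = (loop_j == NA_INTEGER) ? NA_INTEGER : loop_j + 1);
}

// [[Rcpp::export(name = ".fold_enum_core")]]
List fold_enum_core(std::string seq, List pars) {
  const EnergyPars P = parsFromList(pars);
  const std::vector<int> s = encode(seq);
  long long nstruct = 0;
  const double e = enumEnergy(s, P, &nstruct);
  return List::create(_["energy"] = e, _["n_structures"] = (double)nstruct);
}

// Compares DP and enumeration energies for every sequence over {A,C,G,U}
// of length 1..kmax.  Returns the number of disagreements plus the first
// few offending sequences.
// [[Rcpp::export(name = ".fold_check_exhaustive")]]
List fold_check_exhaustive(int kmax, List pars, double tol = 1e-6) {
  const EnergyPars P = parsFromList(pars);
  long long checked = 0, bad = 0;
  std::vector<std::string> offenders;
  std::vector<double> V;
  const char alpha[4] = {'A', 'C', 'G', 'U'};
  for (int k = 1; k <= kmax; ++k) {
    std::vector<int> s(k, 0);
    for (;;) {
      ++checked;
      const double ed = dpEnergy(s, P, V);
      const double ee = enumEnergy(s, P);
      if (std::fabs(ed - ee) > tol) {
        ++bad;
        if (offenders.size() < 10) {
          std::string str(k, 'A');
          for (int t = 0; t < k; ++t) str[t] = alpha[s[t]];
          offenders.push_back(str);
        }
      }
      // odometer increment
      int pos = k - 1;
      while (pos >= 0 && s[pos] == 3) { s[pos] = 0; --pos; }
      if (pos < 0) break;
      ++s[pos];
      if (checked % 1000000 == 0) Rcpp::checkUserInterrupt();
    }
  }
  return List::create(_["n_checked"] = (double)checked,
                      _["n_mismatch"] = (double)bad,
                      _["offenders"] = wrap(offenders));
}
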