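// Dynamic-programming kernels for PRG alignment.
//
// Symbol codes used throughout: A=0 C=1 G=2 T=3 N=4, gap edge label = 5,
// read gap (no base) = -1, absent column (partial allele) = -2.
// Scoring: affine gaps, a run of k gap cells costs open + (k-1)*extend.
// Cells where a gap edge meets a read gap are transparent: they score 0 and
// do not interrupt gap runs.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct Scheme {
  double match, mismatch, go, ge, nscore;
  explicit Scheme(const NumericVector& s)
    : match(s[0]), mismatch(s[1]), go(s[2]), ge(s[3]), nscore(s[4]) {}
  double sub(int lab, int base) const {
    if (lab == 4 || base == 4) return nscore;
    return lab == base ? match : mismatch;
  }
};

// cell classes
enum CellClass { CMATCH = 0, CINS = 1, CDEL = 2, CTRANS = 3 };

static inline int classify(int edgeLab, int base) {
  if (base >= 0) return (edgeLab >= 0 && edgeLab <= 4) ? CMATCH : CINS;
  return (edgeLab >= 0 && edgeLab <= 4) ? CDEL : CTRANS;
}

// [[Rcpp::export]]
double cpp_score_cells(IntegerVector edgeLab, IntegerVector base,
                       NumericVector schemeV) {
  Scheme sc(schemeV);
  double score = 0.0;
  int state = 0;  // 0 none, 1 ins run, 2 del run
  for (int i = 0; i < edgeLab.size(); ++i) {
    int cls = classify(edgeLab[i], base[i]);
    switch (cls) {
    case CMATCH:
      score += sc.sub(edgeLab[i], base[i]);
      state = 0; break;
    case CINS:
      score += (state == 1) ? sc.ge : sc.go;
      state = 1; break;
    case CDEL:
      score += (state == 2) ? sc.ge : sc.go;
      state = 2; break;
    case CTRANS:
      break;  // transparent
    }
  }
  return score;
}

// ---------------------------------------------------------------------------
// Fixed-level polishing DP over one contiguous segment.
//
// Items arrive in walk order: one non-insertion item per level of the
// contiguous range [l0, l0+nLevels), interleaved with floating insertion
// items (edge-independent). For each level we re-choose the edge, subject to
// node connectivity; read base levels stay fixed.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_polish(IntegerVector itemBase, LogicalVector itemIsIns,
                IntegerVector edgeLevel, IntegerVector edgeFrom,
                IntegerVector edgeTo, IntegerVector edgeLab,
                int l0, int nLevels, NumericVector schemeV) {
  Scheme sc(schemeV);
  // group edges by level (edges are pre-sorted by level, then label)
  std::vector<std::vector<int>> byLevel(nLevels);
  for (int i = 0; i < edgeLevel.size(); ++i)
    byLevel[edgeLevel[i] - l0].push_back(i);

  int nItems = itemBase.size();
  // DP storage: per non-ins item (= per level), score[edge][state]
  // plus backpointers (prev edge choice index, prev state).
  std::vector<std::vector<double>> S(nLevels);
  std::vector<std::vector<int>> BPe(nLevels), BPs(nLevels);

  int levelIdx = -1;           // index of current level within segment
  // virtual pre-level state (before the first non-ins item)
  std::vector<double> pre(3, NEG_INF);
  pre[0] = 0.0;

  for (int it = 0; it < nItems; ++it) {
    if (itemIsIns[it]) {
      // floating insertion: edge-independent, forces state -> ins
      if (levelIdx < 0) {
        double best = NEG_INF;
        for (int g = 0; g < 3; ++g) {
          double v = pre[g] + ((g == 1) ? sc.ge : sc.go);
          if (v > best) best = v;
        }
        pre[0] = pre[2] = NEG_INF; pre[1] = best;
      } else {
        std::vector<double>& cur = S[levelIdx];
        int nE = (int)byLevel[levelIdx].size();
        for (int e = 0; e < nE; ++e) {
          double best = NEG_INF; int bg = 0;
          for (int g = 0; g < 3; ++g) {
            double v = cur[e * 3 + g] + ((g == 1) ? sc.ge : sc.go);
            if (v > best) { best = v; bg = g; }
          }
          cur[e * 3 + 0] = cur[e * 3 + 2] = NEG_INF;
          cur[e * 3 + 1] = best;
          // collapse backpointer: record the state we came from
          BPe[levelIdx][e * 3 + 1] = BPe[levelIdx][e * 3 + bg];
          BPs[levelIdx][e * 3 + 1] = BPs[levelIdx][e * 3 + bg];
        }
      }
      continue;
    }
    ++levelIdx;
    const std::vector<int>& edges = byLevel[levelIdx];
    int nE = (int)edges.size();
    S[levelIdx].assign(nE * 3, NEG_INF);
    BPe[levelIdx].assign(nE * 3, -1);
    BPs[levelIdx].assign(nE * 3, -1);
    int base = itemBase[it];
    for (int e = 0; e < nE; ++e) {
      int ei = edges[e];
      int lab = edgeLab[ei];
      int cls = classify(lab, base);
      // transitions from previous level (or virtual pre state)
      for (int pg = 0; pg < 3; ++pg) {
        if (levelIdx == 0) {
          double prev = pre[pg];
          if (prev == NEG_INF) continue;
          double add; int ng;
          if (cls == CMATCH) { add = sc.sub(lab, base); ng = 0; }
          else if (cls == CINS) { add = (pg == 1) ? sc.ge : sc.go; ng = 1; }
          else if (cls == CDEL) { add = (pg == 2) ? sc.ge : sc.go; ng = 2; }
          else { add = 0.0; ng = pg; }
          double v = prev + add;
          if (v > S[0][e * 3 + ng]) {
            S[0][e * 3 + ng] = v; BPe[0][e * 3 + ng] = -1;
            BPs[0][e * 3 + ng] = pg;
          }
        } else {
          const std::vector<int>& pedges = byLevel[levelIdx - 1];
          for (int pe = 0; pe < (int)pedges.size(); ++pe) {
            if (edgeTo[pedges[pe]] != edgeFrom[ei]) continue;
            double prev = S[levelIdx - 1][pe * 3 + pg];
            if (prev == NEG_INF) continue;
            double add; int ng;
            if (cls == CMATCH) { add = sc.sub(lab, base); ng = 0; }
            else if (cls == CINS) { add = (pg == 1) ? sc.ge : sc.go; ng = 1; }
            else if (cls == CDEL) { add = (pg == 2) ? sc.ge : sc.go; ng = 2; }
            else { add = 0.0; ng = pg; }
            double v = prev + add;
            if (v > S[levelIdx][e * 3 + ng]) {
              S[levelIdx][e * 3 + ng] = v;
              BPe[levelIdx][e * 3 + ng] = pe;
              BPs[levelIdx][e * 3 + ng] = pg;
            }
          }
        }
      }
    }
  }
  if (levelIdx + 1 != nLevels) stop("polish: item/level mismatch");

  // best final state
  double best = NEG_INF; int be = -1, bg = -1;
  int nE = (int)byLevel[nLevels - 1].size();
  for (int e = 0; e < nE; ++e)
    for (int g = 0; g < 3; ++g)
      if (S[nLevels - 1][e * 3 + g] > best) {
        best = S[nLevels - 1][e * 3 + g]; be = e; bg = g;
      }
  if (be < 0) stop("polish: no feasible path");

  IntegerVector choice(nLevels);
  int e = be, g = bg;
  for (int l = nLevels - 1; l >= 0; --l) {
    choice[l] = byLevel[l][e] + 1;  // 1-based index into edge vectors
    int pe = BPe[l][e * 3 + g], pg = BPs[l][e * 3 + g];
    e = pe; g = pg;
  }
  return List::create(_["score"] = best, _["choice"] = choice);
}

// ---------------------------------------------------------------------------
// Full graph alignment: affine-gap DP of a read against all level paths of a
// (sub)graph, with configurable end conditions. Exhaustive when no band is
// given; this is the package's alignment oracle and its extension engine.
// ---------------------------------------------------------------------------

struct Slab {
  // per boundary: nodes * (n+1) * 3 states
  std::vector<double> sc;
  std::vector<int> pnode, pstate, pedge, pj;
  int nNodes, width;
  void init(int nodes, int w) {
    nNodes = nodes; width = w;
    size_t sz = (size_t)nodes * w * 3;
    sc.assign(sz, NEG_INF);
    pnode.assign(sz, -1); pstate.assign(sz, -1);
    pedge.assign(sz, -1); pj.assign(sz, -1);
  }
  inline size_t at(int u, int j, int s) const {
    return ((size_t)u * width + j) * 3 + s;
  }
};

// pstate encodings for traceback starts
static const int PS_START = -2;      // fresh start (free level skip)
static const int PS_CLIPSTART = -3;  // started with clipped read prefix

// [[Rcpp::export]]
List cpp_full_align(IntegerVector readCode,
                    int nLevels, IntegerVector nodeBoundary,
                    IntegerVector edgeLevel, IntegerVector edgeFrom,
                    IntegerVector edgeTo, IntegerVector edgeLab,
                    NumericVector schemeV,
                    bool freeStart, bool freeEnd,
                    bool clipStart, bool clipEnd,
                    int startNode, int endNode,
                    IntegerVector jLo, IntegerVector jHi) {
  Scheme sc(schemeV);
  int n = readCode.size();
  int L = nLevels;
  int nNodesTotal = nodeBoundary.size();
  bool banded = jLo.size() > 0;

  // nodes per boundary, plus local index of each node within its boundary
  std::vector<std::vector<int>> nodesAt(L + 1);
  std::vector<int> localIdx(nNodesTotal);
  for (int u = 0; u < nNodesTotal; ++u) {
    localIdx[u] = (int)nodesAt[nodeBoundary[u]].size();
    nodesAt[nodeBoundary[u]].push_back(u);
  }
  std::vector<std::vector<int>> edgesAt(L);
  for (int i = 0; i < edgeLevel.size(); ++i)
    edgesAt[edgeLevel[i]].push_back(i);

  std::vector<Slab> slab(L + 1);
  auto bandLo = [&](int b) { return banded ? std::max(0, jLo[b]) : 0; };
  auto bandHi = [&](int b) { return banded ? std::min(n, jHi[b]) : n; };

  double bestScore = NEG_INF;
  int bestB = -1, bestU = -1, bestJ = -1, bestS = -1;

  for (int b = 0; b <= L; ++b) {
    int nb = (int)nodesAt[b].size();
    if (slab[b].sc.empty()) slab[b].init(nb, n + 1);
    Slab& cur = slab[b];
    int lo = bandLo(b), hi = bandHi(b);
    // start rules
    for (int ui = 0; ui < nb; ++ui) {
      int u = nodesAt[b][ui];
      bool startHere = (startNode >= 0) ? (u == startNode && b == 0)
                                        : (freeStart || b == 0);
      if (startHere && lo <= 0) {
        size_t ix = cur.at(ui, 0, 0);
        if (0.0 > cur.sc[ix]) { cur.sc[ix] = 0.0; cur.pstate[ix] = PS_START; }
      }
      if (clipStart && b == 0 && startNode < 0) {
        for (int j = lo; j <= hi; ++j) {
          size_t ix = cur.at(ui, j, 0);
          if (0.0 > cur.sc[ix]) {
            cur.sc[ix] = 0.0; cur.pstate[ix] = PS_CLIPSTART; cur.pj[ix] = j;
          }
        }
      }
    }
    // insertion closure within the boundary
    for (int ui = 0; ui < nb; ++ui) {
      for (int j = std::max(lo, 1); j <= hi; ++j) {
        double best = NEG_INF; int bs = -1;
        for (int s = 0; s < 3; ++s) {
          double v = cur.sc[cur.at(ui, j - 1, s)];
          if (v == NEG_INF) continue;
          v += (s == 1) ? sc.ge : sc.go;
          if (v > best) { best = v; bs = s; }
        }
        size_t ix = cur.at(ui, j, 1);
        if (best > cur.sc[ix]) {
          cur.sc[ix] = best;
          cur.pnode[ix] = ui; cur.pstate[ix] = bs; cur.pedge[ix] = -1;
          cur.pj[ix] = j - 1;
        }
      }
    }
    // end candidates
    for (int ui = 0; ui < nb; ++ui) {
      int u = nodesAt[b][ui];
      if (endNode >= 0) {
        if (b == L && u == endNode && n >= lo && n <= hi)
          for (int s = 0; s < 3; ++s) {
            double v = cur.sc[cur.at(ui, n, s)];
            if (v > bestScore) {
              bestScore = v; bestB = b; bestU = ui; bestJ = n; bestS = s;
            }
          }
      } else {
        if ((freeEnd || b == L) && n >= lo && n <= hi)
          for (int s = 0; s < 3; ++s) {
            double v = cur.sc[cur.at(ui, n, s)];
            if (v > bestScore) {
              bestScore = v; bestB = b; bestU = ui; bestJ = n; bestS = s;
            }
          }
        if (clipEnd && b == L)
          for (int j = lo; j <= hi; ++j)
            for (int s = 0; s < 3; ++s) {
              double v = cur.sc[cur.at(ui, j, s)];
              if (v > bestScore) {
                bestScore = v; bestB = b; bestU = ui; bestJ = j; bestS = s;
              }
            }
      }
    }
    if (b == L) break;
    // propagate along edges of level b into boundary b+1
    int nb1 = (int)nodesAt[b + 1].size();
    if (slab[b + 1].sc.empty()) slab[b + 1].init(nb1, n + 1);
    Slab& nxt = slab[b + 1];
    int lo1 = bandLo(b + 1), hi1 = bandHi(b + 1);
    for (int k = 0; k < (int)edgesAt[b].size(); ++k) {
      int ei = edgesAt[b][k];
      int ui = localIdx[edgeFrom[ei]];
      int vi = localIdx[edgeTo[ei]];
      int lab = edgeLab[ei];
      if (lab == 5) {  // gap edge: transparent for all states
        for (int j = std::max(lo, lo1); j <= std::min(hi, hi1); ++j)
          for (int s = 0; s < 3; ++s) {
            double v = cur.sc[cur.at(ui, j, s)];
            if (v == NEG_INF) continue;
            size_t ix = nxt.at(vi, j, s);
            if (v > nxt.sc[ix]) {
              nxt.sc[ix] = v;
              nxt.pnode[ix] = ui; nxt.pstate[ix] = s; nxt.pedge[ix] = ei;
              nxt.pj[ix] = j;
            }
          }
      } else {
        // deletion: consume the level, no read base
        for (int j = std::max(lo, lo1); j <= std::min(hi, hi1); ++j) {
          for (int s = 0; s < 3; ++s) {
            double v = cur.sc[cur.at(ui, j, s)];
            if (v == NEG_INF) continue;
            v += (s == 2) ? sc.ge : sc.go;
            size_t ix = nxt.at(vi, j, 2);
            if (v > nxt.sc[ix]) {
              nxt.sc[ix] = v;
              nxt.pnode[ix] = ui; nxt.pstate[ix] = s; nxt.pedge[ix] = ei;
              nxt.pj[ix] = j;
            }
          }
        }
        // match/mismatch: consume level and read base
        for (int j = std::max(lo, lo1 - 1); j <= std::min(hi, hi1 - 1); ++j) {
          if (j < 0 || j >= n) continue;
          double add = sc.sub(lab, readCode[j]);
          for (int s = 0; s < 3; ++s) {
            double v = cur.sc[cur.at(ui, j, s)];
            if (v == NEG_INF) continue;
            v += add;
            size_t ix = nxt.at(vi, j + 1, 0);
            if (v > nxt.sc[ix]) {
              nxt.sc[ix] = v;
              nxt.pnode[ix] = ui; nxt.pstate[ix] = s; nxt.pedge[ix] = ei;
              nxt.pj[ix] = j;
            }
          }
        }
      }
    }
  }

  if (bestScore == NEG_INF)
    return List::create(_["feasible"] = false);

  // traceback
  std::vector<int> cLevel, cEdge, cReadPos;  // reversed
  int clipPrefix = 0, clipSuffix = n - bestJ;
  int b = bestB, u = bestU, j = bestJ, s = bestS;
  int startBoundary = -1;
  while (true) {
    Slab& cur = slab[b];
    size_t ix = cur.at(u, j, s);
    int ps = cur.pstate[ix];
    if (ps == PS_START) { startBoundary = b; break; }
    if (ps == PS_CLIPSTART) { startBoundary = b; clipPrefix = cur.pj[ix]; break; }
    int pe = cur.pedge[ix];
    int pn = cur.pnode[ix];
    int pj = cur.pj[ix];
    if (pe >= 0) {
      int lab = edgeLab[pe];
      if (lab == 5) {
        cLevel.push_back(b - 1); cEdge.push_back(pe); cReadPos.push_back(-1);
      } else if (s == 0 && j == pj + 1) {
        cLevel.push_back(b - 1); cEdge.push_back(pe); cReadPos.push_back(j - 1);
      } else {
        cLevel.push_back(b - 1); cEdge.push_back(pe); cReadPos.push_back(-1);
      }
      b = b - 1; u = pn; j = pj; s = ps;
    } else {
      // insertion within boundary: attach to preceding level
      cLevel.push_back(b > 0 ? b - 1 : 0);
      cEdge.push_back(-1); cReadPos.push_back(j - 1);
      u = pn; j = pj; s = ps;
    }
  }
  int m = (int)cLevel.size();
  IntegerVector level(m), edge(m), readPos(m);
  for (int i = 0; i < m; ++i) {
    level[i] = cLevel[m - 1 - i];
    edge[i] = cEdge[m - 1 - i];
    readPos[i] = cReadPos[m - 1 - i];
  }
  return List::create(_["feasible"] = true, _["score"] = bestScore,
                      _["level"] = level, _["edge"] = edge,
                      _["readPos"] = readPos,
                      _["clipPrefix"] = clipPrefix,
                      _["clipSuffix"] = clipSuffix,
                      _["startBoundary"] = startBoundary,
                      _["endBoundary"] = bestB);
}

// Score-only variant of the full graph alignment: identical semantics,
// rolling slabs, no traceback. Used to test cheaply whether an exhaustive
// alignment could improve on the hybrid result.

// [[Rcpp::export]]
double cpp_full_align_score(IntegerVector readCode,
                            int nLevels, IntegerVector nodeBoundary,
                            IntegerVector edgeLevel, IntegerVector edgeFrom,
                            IntegerVector edgeTo, IntegerVector edgeLab,
                            NumericVector schemeV,
                            bool freeStart, bool freeEnd,
                            bool clipStart, bool clipEnd,
                            int startNode, int endNode) {
  Scheme sc(schemeV);
  int n = readCode.size();
  int L = nLevels;
  int nNodesTotal = nodeBoundary.size();
  std::vector<std::vector<int>> nodesAt(L + 1);
  std::vector<int> localIdx(nNodesTotal);
  for (int u = 0; u < nNodesTotal; ++u) {
    localIdx[u] = (int)nodesAt[nodeBoundary[u]].size();
    nodesAt[nodeBoundary[u]].push_back(u);
  }
  std::vector<std::vector<int>> edgesAt(L);
  for (int i = 0; i < edgeLevel.size(); ++i)
    edgesAt[edgeLevel[i]].push_back(i);

  double bestScore = NEG_INF;
  std::vector<double> cur, nxt;
  auto at = [&](int u, int j, int st) { return ((size_t)u * (n + 1) + j) * 3 + st; };
  for (int b = 0; b <= L; ++b) {
    int nb = (int)nodesAt[b].size();
    if (b == 0) cur.assign((size_t)nb * (n + 1) * 3, NEG_INF);
    // start rules
    for (int ui = 0; ui < nb; ++ui) {
      int u = nodesAt[b][ui];
      bool startHere = (startNode >= 0) ? (u == startNode && b == 0)
                                        : (freeStart || b == 0);
      if (startHere && 0.0 > cur[at(ui, 0, 0)]) cur[at(ui, 0, 0)] = 0.0;
      if (clipStart && b == 0 && startNode < 0)
        for (int j = 0; j <= n; ++j)
          if (0.0 > cur[at(ui, j, 0)]) cur[at(ui, j, 0)] = 0.0;
    }
    // insertion closure
    for (int ui = 0; ui < nb; ++ui)
      for (int j = 1; j <= n; ++j) {
        double best = NEG_INF;
        for (int st = 0; st < 3; ++st) {
          double v = cur[at(ui, j - 1, st)];
          if (v == NEG_INF) continue;
          v += (st == 1) ? sc.ge : sc.go;
          if (v > best) best = v;
        }
        if (best > cur[at(ui, j, 1)]) cur[at(ui, j, 1)] = best;
      }
    // end candidates
    for (int ui = 0; ui < nb; ++ui) {
      int u = nodesAt[b][ui];
      if (endNode >= 0) {
        if (b == L && u == endNode)
          for (int st = 0; st < 3; ++st)
            bestScore = std::max(bestScore, cur[at(ui, n, st)]);
      } else {
        if (freeEnd || b == L)
          for (int st = 0; st < 3; ++st)
            bestScore = std::max(bestScore, cur[at(ui, n, st)]);
        if (clipEnd && b == L)
          for (int j = 0; j <= n; ++j)
            for (int st = 0; st < 3; ++st)
              bestScore = std::max(bestScore, cur[at(ui, j, st)]);
      }
    }
    if (b == L) break;
    int nb1 = (int)nodesAt[b + 1].size();
    nxt.assign((size_t)nb1 * (n + 1) * 3, NEG_INF);
    for (int k = 0; k < (int)edgesAt[b].size(); ++k) {
      int ei = edgesAt[b][k];
      int ui = localIdx[edgeFrom[ei]];
      int vi = localIdx[edgeTo[ei]];
      int lab = edgeLab[ei];
      if (lab == 5) {
        for (int j = 0; j <= n; ++j)
          for (int st = 0; st < 3; ++st) {
            double v = cur[at(ui, j, st)];
            if (v > nxt[((size_t)vi * (n + 1) + j) * 3 + st])
              nxt[((size_t)vi * (n + 1) + j) * 3 + st] = v;
          }
      } else {
        for (int j = 0; j <= n; ++j) {
          double bestD = NEG_INF, bestM = NEG_INF;
          for (int st = 0; st < 3; ++st) {
            double v = cur[at(ui, j, st)];
            if (v == NEG_INF) continue;
            double vd = v + ((st == 2) ? sc.ge : sc.go);
            if (vd > bestD) bestD = vd;
            if (j < n) {
              double vm = v + sc.sub(lab, readCode[j]);
              if (vm > bestM) bestM = vm;
            }
          }
          size_t ixd = ((size_t)vi * (n + 1) + j) * 3 + 2;
          if (bestD > nxt[ixd]) nxt[ixd] = bestD;
          if (j < n) {
            size_t ixm = ((size_t)vi * (n + 1) + j + 1) * 3 + 0;
            if (bestM > nxt[ixm]) nxt[ixm] = bestM;
          }
        }
      }
    }
    cur.swap(nxt);
  }
  return bestScore;
}

// ---------------------------------------------------------------------------
// Diagonal chaining: highest-scoring traversal of the alignment matrix
// limited to gap-free exact-match diagonals connected by horizontal
// (reference skip) and vertical (contig skip) jumps. Semi-global: leading
// and trailing reference skips are free; contig skips are penalized.
// Transitions trim the start of the downstream diagonal minimally so that
// chains stay strictly monotone; with exhaustive anchors this DP is exact
// against the full-matrix semi-global DP under the same gap model.
// ---------------------------------------------------------------------------

static inline double affine(int g, double open, double ext) {
  return g > 0 ? open + (g - 1) * ext : 0.0;
}

// [[Rcpp::export]]
List cpp_chain_dp(IntegerVector cs, IntegerVector ce,
                  IntegerVector rs, IntegerVector re,
                  int contigLen, double match, double jumpOpen,
                  double jumpExt) {
  int d = cs.size();
  if (d == 0)
    return List::create(_["score"] = 0.0, _["chain"] = IntegerVector(0),
                        _["trim"] = IntegerVector(0));
  // order by contig start (ties: ref start) for the DP sweep
  std::vector<int> ord(d);
  for (int i = 0; i < d; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (cs[a] != cs[b]) return cs[a] < cs[b];
    return rs[a] < rs[b];
  });
  std::vector<double> best(d);
  std::vector<int> pred(d, -1), trim(d, 0);
  for (int oi = 0; oi < d; ++oi) {
    int i = ord[oi];
    int len = ce[i] - cs[i];
    best[i] = len * match + affine(cs[i], jumpOpen, jumpExt);
    for (int oj = 0; oj < oi; ++oj) {
      int j = ord[oj];
      int t = std::max(0, std::max(ce[j] - cs[i], re[j] - rs[i]));
      int effLen = len - t;
      if (effLen < 1) continue;
      int dc = cs[i] + t - ce[j];
      int dr = rs[i] + t - re[j];
      if (dc < 0 || dr < 0) continue;
      if (dc == 0 && dr == 0) continue;  // would be one diagonal
      double v = best[j] + effLen * match +
        affine(dc, jumpOpen, jumpExt) + affine(dr, jumpOpen, jumpExt);
      if (v > best[i]) { best[i] = v; pred[i] = j; trim[i] = t; }
    }
  }
  double bestFinal = NEG_INF; int bi = -1;
  for (int i = 0; i < d; ++i) {
    double v = best[i] + affine(contigLen - ce[i], jumpOpen, jumpExt);
    if (v > bestFinal ||
        (v == bestFinal && bi >= 0 &&
         (rs[i] < rs[bi] || (rs[i] == rs[bi] && cs[i] < cs[bi])))) {
      bestFinal = v; bi = i;
    }
  }
  std::vector<int> chain, trims;
  for (int i = bi; i >= 0; i = pred[i]) {
    chain.push_back(i + 1);
    trims.push_back(trim[i]);
  }
  std::reverse(chain.begin(), chain.end());
  std::reverse(trims.begin(), trims.end());
  return List::create(_["score"] = bestFinal,
                      _["chain"] = IntegerVector(chain.begin(), chain.end()),
                      _["trim"] = IntegerVector(trims.begin(), trims.end()));
}

// ---------------------------------------------------------------------------
// Per-read, all-alleles log-likelihood along a graph alignment.
// alleleLab: nLevels x nAlleles matrix of symbol codes (-2 = absent).
// Returns 2 x nAlleles: row 1 log-likelihood, row 2 evaluated column count.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_read_allele_loglik(IntegerVector cellLevel,
                                     IntegerVector cellBase,
                                     LogicalVector cellIsIns,
                                     IntegerMatrix alleleLab,
                                     NumericVector logp) {
  // logp: lmatch, lmis, lio, lie, ldo, lde
  double lmatch = logp[0], lmis = logp[1], lio = logp[2], lie = logp[3],
         ldo = logp[4], lde = logp[5];
  int nA = alleleLab.ncol();
  int nC = cellLevel.size();
  NumericMatrix out(2, nA);
  for (int k = 0; k < nA; ++k) {
    double ll = 0.0; int ne = 0; int g = 0;
    for (int i = 0; i < nC; ++i) {
      int lab = alleleLab(cellLevel[i], k);
      if (lab == -2) { g = 0; continue; }  // uncovered by this allele
      int base = cellBase[i];
      if (cellIsIns[i] || lab == 5) {
        if (base >= 0) { ll += (g == 1) ? lie : lio; g = 1; ++ne; }
        // gap-on-gap: transparent
      } else if (base >= 0) {
        ll += (base == lab || base == 4 || lab == 4) ? lmatch : lmis;
        g = 0; ++ne;
      } else {
        ll += (g == 2) ? lde : ldo; g = 2; ++ne;
      }
    }
    out(0, k) = ll; out(1, k) = ne;
  }
  return out;
}
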